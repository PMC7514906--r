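#' Pipeline configuration
#'
#' All tunable parameters of the detection pipeline with their canonical
#' defaults: denoising filter 3 px; multiscale set `D/48 ... D/3`;
#' entropy-rate segmentation `K = 2000`, `lambda = 0.08`, `sigma = 2`;
#' candidate darkness threshold 0.3; merge color distance 0.24; MLP with
#' 30 hidden units and regularization ratio 0.6. `K` and the 30-pixel
#' pathological threshold are defined at the reference working area
#' (`k_reference_area`, default 700 x 700) and rescale proportionally to
#' the actual working pixel area, so granularity and the decision rule
#' represent the same image fractions at any resolution. Sizes left `NULL`
#' follow their D-derived rules (`hm1` ~ D/5, `bmean` ~ D/10,
#' ASF `r_max` ~ D/60).
#'
#' @param ... named overrides of the defaults listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    denoise_size = 3L,
    scale_fractions = c(1 / 48, 1 / 24, 1 / 12, 1 / 6, 1 / 3),
    ers_k = 2000L,
    ers_lambda = 0.08,
    ers_sigma = 2,
    dark_threshold = 0.3,
    merge_distance = 0.24,
    n_hid = 30L,
    upsilon = 0.6,
    hm1_size = NULL,
    bmean_size = NULL,
    border_opening_radius = NULL,
    asf_r_max = NULL,
    entropy_bins = 256L,
    clahe_tiles = 8L,
    clahe_limit = 2,
    max_side = 700L,
    k_reference_area = 700L * 700L,
    min_lesion_pixels = 30L)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("pipeline_config: unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline_config: K = %d, lambda = %.3f, sigma = %.2f, tau = %.2f, d_max = %.2f, n_hid = %d, upsilon = %.2f\n",
              x$ers_k, x$ers_lambda, x$ers_sigma, x$dark_threshold,
              x$merge_distance, x$n_hid, x$upsilon))
  invisible(x)
}

#' Save / load a pipeline configuration (JSON)
#'
#' @param config a [pipeline_config].
#' @param path JSON file path.
#' @return `path` (write) or a [pipeline_config] (read); `load(save(x))`
#'   reproduces `x`.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  int_keys <- c("denoise_size", "ers_k", "n_hid", "border_opening_radius",
                "entropy_bins", "clahe_tiles", "max_side", "k_reference_area",
                "min_lesion_pixels")
  for (k in int_keys) if (!is.null(obj[[k]])) obj[[k]] <- as.integer(obj[[k]])
  do.call(pipeline_config, obj)
}

# K and min-pixel rule rescaled to the actual working area.
effective_k <- function(config, working_area) {
  max(2L, as.integer(round(config$ers_k * working_area / config$k_reference_area)))
}
effective_min_pixels <- function(config, working_area) {
  max(1L, as.integer(round(config$min_lesion_pixels * working_area /
                             config$k_reference_area)))
}

# Downscale a fundus image so max(dim) <= max_side; returns image + scale.
working_image <- function(image, max_side) {
  d <- dim(unclass(image))
  sc <- max_side / max(d[1:2])
  if (sc >= 1) return(list(image = image, scale = 1))
  h2 <- round(d[1] * sc); w2 <- round(d[2] * sc)
  a <- unclass(image)
  out <- array(0, c(h2, w2, 3))
  for (ch in 1:3) out[, , ch] <- EBImage::imageData(EBImage::resize(a[, , ch], w = h2, h = w2))
  list(image = as_fundus(out, image), scale = sc)
}

# Segmentation stages shared by training and detection: preprocess ->
# darkness -> ERS -> reduce -> merge (+ landmarks).
segment_candidates <- function(image, targets, config, landmarks = NULL,
                               fov = NULL) {
  wi <- working_image(image, config$max_side)
  prep <- preprocess(wi$image, targets, config, fov = fov)
  dk <- compute_darkness(prep, config$asf_r_max, config$scale_fractions)
  area <- prod(dim(prep$iprep)[1:2])
  K <- effective_k(config, area)
  lm <- ers_segment(dk$idark, K, config$ers_lambda, config$ers_sigma)
  cands <- reduce_candidates(lm, dk$idark, config$dark_threshold)
  cands <- merge_candidates(cands, dk$idark, config$merge_distance)
  if (is.null(landmarks)) {
    landmarks <- estimate_landmarks(prep$iprep, dk$iasf, prep$fov)
  } else if (wi$scale != 1) {
    landmarks <- landmark_set(landmarks$od_center * wi$scale,
                              landmarks$fovea_center * wi$scale,
                              prep$fov$diameter_D, landmarks$source)
  }
  list(prep = prep, dark = dk, labels = lm, cands = cands,
       landmarks = landmarks, scale = wi$scale, working_area = area)
}

#' Detect red lesions in a fundus image
#'
#' Runs the full pipeline: preprocessing, multiscale darkness mapping,
#' entropy-rate superpixel segmentation, candidate reduction and merging,
#' feature extraction, feature-subset selection, MLP classification at
#' threshold 0.5, and the image-level pathological decision.
#'
#' @param image a [fundus_image].
#' @param model a trained `mlp_model`.
#' @param selected the `selected_features` the model was trained with.
#' @param config a [pipeline_config].
#' @param targets the [normalization_targets] used in training.
#' @param landmarks optional provided `landmark_set` (native-resolution
#'   coordinates); estimated from the image when `NULL`.
#' @return A `detection_result`: `rl_mask` (working resolution),
#'   `per_candidate_prob`, `detected_candidate_ids`, `is_pathological`,
#'   `n_detected_pixels`, plus the `candidates`, `scale` and
#'   `working_area` for downstream evaluation.
#' @export
detect_red_lesions <- function(image, model, selected, config = pipeline_config(),
                               targets = normalization_targets(),
                               landmarks = NULL) {
  stopifnot(inherits(model, "mlp_model"), inherits(selected, "selected_features"))
  seg <- segment_candidates(image, targets, config, landmarks)
  shape <- seg$cands$source_shape
  if (n_candidates(seg$cands) == 0L) {
    return(structure(list(
      rl_mask = matrix(FALSE, shape[1], shape[2]),
      per_candidate_prob = numeric(0), detected_candidate_ids = integer(0),
      is_pathological = FALSE, n_detected_pixels = 0L,
      candidates = seg$cands, scale = seg$scale,
      working_area = seg$working_area), class = "detection_result"))
  }
  fm <- extract_features(seg$cands, seg$prep$iprep, seg$dark$idark, seg$landmarks)
  prob <- predict_proba(model, fm$values[, selected$indices, drop = FALSE])
  det <- which(prob > 0.5)
  mask <- candidate_mask(seg$cands, det)
  npx <- sum(mask)
  structure(list(
    rl_mask = mask, per_candidate_prob = prob, detected_candidate_ids = det,
    is_pathological = image_decision(mask,
                                     effective_min_pixels(config, seg$working_area)),
    n_detected_pixels = npx, candidates = seg$cands, scale = seg$scale,
    working_area = seg$working_area), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("detection_result: %d/%d candidates detected, %d px, %s\n",
              length(x$detected_candidate_ids), length(x$per_candidate_prob),
              x$n_detected_pixels,
              if (x$is_pathological) "PATHOLOGICAL" else "healthy"))
  invisible(x)
}

#' Train the full detection pipeline
#'
#' From training images with ground-truth lesion masks: estimates the
#' inter-image normalization targets, segments candidates in every image,
#' labels each candidate positive when it overlaps the ground truth in at
#' least one pixel (mirroring the evaluation relaxation), balances the two
#' classes by seeded undersampling of the majority, selects features with
#' FCBF, optionally grid-searches the MLP hyperparameters by stratified
#' cross-validation, and trains the final MLP on the balanced set.
#'
#' @param images list of [fundus_image] objects (>= 2; both candidate
#'   classes must occur).
#' @param gt_masks list of logical ground-truth masks (native resolution).
#' @param config a [pipeline_config].
#' @param seed integer seed driving undersampling, folds and weight
#'   initialization.
#' @param landmarks optional list of provided `landmark_set`s.
#' @param n_hid_grid,upsilon_grid hyperparameter grids; the defaults are
#'   the singleton canonical operating point, which skips the search.
#' @param cv_folds folds for the grid search.
#' @return list with `model`, `selected`, `targets`, `cv` (`NULL` for a
#'   singleton grid), `features` (the pooled labeled [feature_matrix]) and
#'   `n_candidates` per image.
#' @export
train_pipeline <- function(images, gt_masks, config = pipeline_config(),
                           seed = 1L, landmarks = NULL,
                           n_hid_grid = NULL, upsilon_grid = NULL,
                           cv_folds = 10L) {
  stopifnot(length(images) == length(gt_masks), length(images) >= 2L)
  targets <- compute_normalization_targets(images)
  feats <- list(); labs <- list(); ncand <- integer(length(images))
  for (i in seq_along(images)) {
    seg <- segment_candidates(images[[i]], targets, config,
                              if (is.null(landmarks)) NULL else landmarks[[i]])
    ncand[i] <- n_candidates(seg$cands)
    if (ncand[i] == 0L) next
    gt <- gt_masks[[i]]
    if (seg$scale != 1) {
      gt <- EBImage::imageData(EBImage::resize(gt * 1, w = seg$cands$source_shape[1],
                            h = seg$cands$source_shape[2])) > 0.5
    }
    fm <- extract_features(seg$cands, seg$prep$iprep, seg$dark$idark,
                           seg$landmarks)
    feats[[length(feats) + 1L]] <- fm$values
    labs[[length(labs) + 1L]] <- vapply(seg$cands$candidates, function(cand)
      as.numeric(any(gt[cand$pixel_indices])), numeric(1))
  }
  X <- do.call(rbind, feats)
  y <- unlist(labs)
  if (is.null(X) || sum(y) == 0L)
    stop("train_pipeline: no red-lesion candidates found in the training data")
  if (sum(y == 0) == 0L)
    stop("train_pipeline: no negative candidates found in the training data")

  bal <- balance_undersample(y, seed)
  Xb <- X[bal, , drop = FALSE]; yb <- y[bal]
  selected <- fcbf_select(Xb, yb)
  if (length(selected$indices) == 0L)
    stop("train_pipeline: feature selection returned an empty set")
  Xs <- Xb[, selected$indices, drop = FALSE]

  cv <- NULL
  n_hid <- config$n_hid; upsilon <- config$upsilon
  if (!is.null(n_hid_grid) || !is.null(upsilon_grid)) {
    cv <- cross_validate_grid(Xs, yb,
                              n_hid_grid = if (is.null(n_hid_grid)) config$n_hid else n_hid_grid,
                              upsilon_grid = if (is.null(upsilon_grid)) config$upsilon else upsilon_grid,
                              folds = cv_folds, seed = seed)
    n_hid <- cv$n_hid; upsilon <- cv$upsilon
  }
  model <- train_mlp(Xs, yb, n_hid, upsilon, seed = seed)
  fm_all <- feature_matrix(Xb, candidate_ids = bal, labels = yb)
  list(model = model, selected = selected, targets = targets, cv = cv,
       features = fm_all, n_candidates = ncand)
}

#' Evaluate a trained pipeline on labeled images
#'
#' Runs [detect_red_lesions] on every image and aggregates pixel-level
#' (SEp / PPVp, pooled over pathological images) and image-level
#' (SEi / SPi / ACCi) metrics against ground truth.
#'
#' @param images list of [fundus_image] objects.
#' @param gt_masks list of logical ground-truth masks (native resolution;
#'   `NULL` or all-`FALSE` for healthy images).
#' @param fit result of [train_pipeline] (or a list with `model`,
#'   `selected`, `targets`).
#' @param config a [pipeline_config].
#' @param landmarks optional list of provided `landmark_set`s.
#' @return list with `image_metrics`, `pixel` (pooled `pixel_metrics`
#'   counts), `per_image` data frame, and `detections`.
#' @export
evaluate_pipeline <- function(images, gt_masks, fit,
                              config = pipeline_config(), landmarks = NULL) {
  n <- length(images)
  decisions <- logical(n); truth <- logical(n)
  tp_px <- fp_px <- gt_px <- cov_px <- 0L
  per <- vector("list", n); dets <- vector("list", n)
  for (i in seq_len(n)) {
    det <- detect_red_lesions(images[[i]], fit$model, fit$selected, config,
                              fit$targets,
                              if (is.null(landmarks)) NULL else landmarks[[i]])
    gt <- gt_masks[[i]]
    if (is.null(gt)) gt <- matrix(FALSE, nrow(det$rl_mask), ncol(det$rl_mask))
    if (!all(dim(gt) == dim(det$rl_mask))) {
      gt <- EBImage::imageData(EBImage::resize(gt * 1, w = nrow(det$rl_mask),
                            h = ncol(det$rl_mask))) > 0.5
    }
    decisions[i] <- det$is_pathological
    truth[i] <- any(gt)
    pm <- pixel_metrics(det, gt, det$candidates)
    tp_px <- tp_px + pm$tp_px; fp_px <- fp_px + pm$fp_px
    gt_px <- gt_px + pm$gt_px
    if (pm$gt_px > 0) cov_px <- cov_px + round(pm$se_p * pm$gt_px)
    per[[i]] <- data.frame(image = i, n_detected_pixels = det$n_detected_pixels,
                           decision = decisions[i], truth = truth[i],
                           se_p = pm$se_p, ppv_p = pm$ppv_p)
    dets[[i]] <- det
  }
  list(image_metrics = image_metrics(decisions, truth),
       pixel = list(se_p = if (gt_px > 0) cov_px / gt_px else NaN,
                    ppv_p = if (tp_px + fp_px > 0) tp_px / (tp_px + fp_px) else NaN,
                    tp_px = tp_px, fp_px = fp_px, gt_px = gt_px),
       per_image = do.call(rbind, per),
       detections = dets)
}
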