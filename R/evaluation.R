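#' 8-connected component labeling of a binary mask
#'
#' Ground-truth lesions are 8-connected regions; this labels them (the
#' widely used 4-connected labelers would split diagonally touching
#' regions).
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(lab) <= 1) return(lab)
  # merge 4-connected labels that touch diagonally
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),
                 cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, unique(roots))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Pixel-level detection metrics under the superpixel relaxation
#'
#' A detected candidate is a true positive if it overlaps the ground-truth
#' lesion mask in at least one pixel; all pixels of such candidates count
#' as correct, and all pixels of non-overlapping detected candidates count
#' as false positives, giving `PPVp = TP / (TP + FP)` over pixels.
#' Symmetrically, a ground-truth lesion (8-connected component of the
#' mask) counts as detected when at least one detected candidate touches
#' it, and `SEp` is the pixel fraction of ground-truth lesions so covered.
#'
#' @param det a `detection_result` (see [detect_red_lesions]) or an integer
#'   vector of detected candidate indices into `cands`.
#' @param gt_mask logical ground-truth lesion mask.
#' @param cands the [candidate_set] the detections come from (needed to
#'   group detected pixels into candidates when `det` is a bare mask).
#' @return A `pixel_metrics` list: `se_p`, `ppv_p` (NaN with
#'   `undefined_*` flags when no ground truth / no detections exist),
#'   `tp_px`, `fp_px`, `gt_px`.
#' @export
pixel_metrics <- function(det, gt_mask, cands) {
  det_ids <- if (inherits(det, "detection_result")) det$detected_candidate_ids
             else as.integer(det)   # indices into cands$candidates
  stopifnot(is.logical(gt_mask))

  tp_px <- 0L; fp_px <- 0L
  tp_cand <- logical(length(det_ids))
  for (k in seq_along(det_ids)) {
    pix <- cands$candidates[[det_ids[k]]]$pixel_indices
    if (any(gt_mask[pix])) {
      tp_px <- tp_px + length(pix); tp_cand[k] <- TRUE
    } else {
      fp_px <- fp_px + length(pix)
    }
  }

  gt_px <- sum(gt_mask)
  det_mask <- candidate_mask(cands, det_ids)
  covered_px <- 0L
  if (gt_px > 0L) {
    lesions <- label_components8(gt_mask)
    for (l in seq_len(max(lesions))) {
      lp <- which(lesions == l)
      if (any(det_mask[lp])) covered_px <- covered_px + length(lp)
    }
  }
  se_p <- if (gt_px > 0L) covered_px / gt_px else NaN
  ppv_p <- if (tp_px + fp_px > 0L) tp_px / (tp_px + fp_px) else NaN
  structure(list(se_p = se_p, ppv_p = ppv_p, tp_px = tp_px, fp_px = fp_px,
                 gt_px = gt_px,
                 undefined_se = gt_px == 0L,
                 undefined_ppv = tp_px + fp_px == 0L),
            class = "pixel_metrics")
}

#' @export
print.pixel_metrics <- function(x, ...) {
  cat(sprintf("pixel_metrics: SEp = %.4f, PPVp = %.4f (TP %d px, FP %d px, GT %d px)\n",
              x$se_p, x$ppv_p, x$tp_px, x$fp_px, x$gt_px))
  invisible(x)
}

#' Image-level pathological decision
#'
#' An image is called pathological when at least `min_pixels` pixels are
#' detected as red lesions (tiny detections in healthy images are treated
#' as clinically non-significant noise). When the pipeline ran at a
#' reduced working resolution, the threshold is rescaled by the ratio of
#' working to native pixel area so it represents the same image fraction.
#'
#' @param det_mask logical detection mask (at working resolution).
#' @param min_pixels pathological threshold at native resolution
#'   (default 30).
#' @param native_area native image pixel count; defaults to the mask's own
#'   area (no rescaling).
#' @return logical: `TRUE` if pathological.
#' @export
image_decision <- function(det_mask, min_pixels = 30L, native_area = NULL) {
  stopifnot(min_pixels >= 1)
  n <- sum(det_mask)
  if (!is.null(native_area)) {
    min_pixels <- max(1, round(min_pixels * length(det_mask) / native_area))
  }
  n >= min_pixels
}

#' Image-level screening metrics
#'
#' Confusion-matrix rates over a set of images: sensitivity
#' `SEi = TP / (TP + FN)`, specificity `SPi = TN / (TN + FP)` and accuracy
#' `ACCi = (TP + TN) / n`, where a positive is a pathological image.
#'
#' @param decisions logical vector of pathological decisions.
#' @param truth logical vector of ground-truth pathological status.
#' @return An `image_metrics` list with `se_i`, `sp_i`, `acc_i` (NaN and a
#'   flag when a class is absent) and the confusion counts.
#' @export
image_metrics <- function(decisions, truth) {
  stopifnot(length(decisions) == length(truth))
  decisions <- as.logical(decisions); truth <- as.logical(truth)
  tp <- sum(decisions & truth);  fn <- sum(!decisions & truth)
  tn <- sum(!decisions & !truth); fp <- sum(decisions & !truth)
  se_i <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp_i <- if (tn + fp > 0) tn / (tn + fp) else NaN
  structure(list(se_i = se_i, sp_i = sp_i,
                 acc_i = (tp + tn) / length(truth),
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 undefined_se = tp + fn == 0, undefined_sp = tn + fp == 0),
            class = "image_metrics")
}

#' @export
print.image_metrics <- function(x, ...) {
  cat(sprintf("image_metrics: SEi = %.4f, SPi = %.4f, ACCi = %.4f (TP %d FP %d TN %d FN %d)\n",
              x$se_i, x$sp_i, x$acc_i, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
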