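#' Inter-image normalization targets
#'
#' Target statistics toward which illumination and color equalization pulls
#' every image: a global mean intensity `mu_intensity`, a circular mean hue
#' `mu_hue` (radians) and a mean saturation `mu_saturation`, all measured
#' inside the FOV. In training mode these are recomputed as the averages
#' over a training set ([compute_normalization_targets]); the shipped
#' defaults (mu = 0.5, hue 0.35 rad, saturation 0.35 — a mid-bright,
#' orange-red retina) support single-image use.
#'
#' @param mu_intensity target mean intensity in `[0, 1]`.
#' @param mu_hue target circular mean hue, radians in `[0, 2*pi)`.
#' @param mu_saturation target mean saturation in `[0, 1]`.
#' @param n_images_used number of images the targets were estimated from.
#' @return A `normalization_targets` object (list).
#' @export
normalization_targets <- function(mu_intensity = 0.5, mu_hue = 0.35,
                                  mu_saturation = 0.35, n_images_used = 0L) {
  stopifnot(mu_intensity >= 0, mu_intensity <= 1,
            mu_saturation >= 0, mu_saturation <= 1)
  mu_hue <- mu_hue %% (2 * pi)
  structure(list(mu_intensity = mu_intensity, mu_hue = mu_hue,
                 mu_saturation = mu_saturation,
                 n_images_used = as.integer(n_images_used)),
            class = "normalization_targets")
}

#' Estimate normalization targets from a training set
#'
#' Averages the in-FOV mean intensity, circular mean hue and mean saturation
#' over a list of images, after border-artifact removal and background
#' extension (the same state at which equalization is applied).
#'
#' @param images list of [fundus_image] objects.
#' @return A [normalization_targets].
#' @export
compute_normalization_targets <- function(images) {
  stopifnot(length(images) >= 1L)
  mi <- ms <- numeric(0); hx <- hy <- numeric(0)
  for (img in images) {
    fov <- detect_fov(img)
    rb <- remove_bright_border(img, fov)
    ext <- extend_background(rb$image, fov)
    hsi <- rgb_to_hsi(unclass(ext))
    m <- fov$mask
    mi <- c(mi, mean(hsi$i[m]))
    ms <- c(ms, mean(hsi$s[m]))
    hx <- c(hx, mean(cos(hsi$h[m])))
    hy <- c(hy, mean(sin(hsi$h[m])))
  }
  normalization_targets(mean(mi), atan2(mean(hy), mean(hx)) %% (2 * pi),
                        mean(ms), length(images))
}

#' Circular mean of hue angles
#'
#' Hue is an angle, so its mean is the direction of the resultant vector:
#' `atan2(sum(sin h), sum(cos h))`, mapped to `[0, 2*pi)`. Fails when the
#' hues are perfectly dispersed (resultant length ~ 0), where no mean
#' direction exists.
#'
#' @param hues numeric vector of angles in radians.
#' @param weights optional non-negative weights.
#' @return The circular mean angle in `[0, 2*pi)`.
#' @export
circular_mean_hue <- function(hues, weights = NULL) {
  stopifnot(length(hues) >= 1L)
  if (is.null(weights)) weights <- rep(1, length(hues))
  sx <- sum(weights * cos(hues)); sy <- sum(weights * sin(hues))
  if (sqrt(sx^2 + sy^2) < 1e-9 * sum(weights))
    stop("circular_mean_hue: hues are perfectly dispersed, mean undefined")
  atan2(sy, sx) %% (2 * pi)
}

#' Remove bright border artifacts
#'
#' Excessively bright crescents along the FOV rim (an acquisition
#' illumination defect) disturb later color and edge analysis. On the blue
#' channel, a bright-excess map `Bmask = Borig - Bmean` (mean filter of
#' width ~D/10) is reconstructed by greyscale morphological dilation seeded
#' from the FOV contour, so only bright structure connected to the rim
#' survives; Otsu thresholding and a disc opening give the binary artifact
#' mask, whose pixels are then replaced by the ring-fill mean of their
#' non-flagged FOV neighbors.
#'
#' @param image a [fundus_image].
#' @param fov the image's [fov_geometry].
#' @param bmean_size mean filter width; default the odd integer nearest D/10.
#' @param opening_radius disc radius of the cleanup opening; default scales
#'   with the FOV as `round(D/100)`, clamped to 2..8, so the opening never
#'   swallows the artifact band at small frames.
#' @return list with `image` (corrected [fundus_image]) and `artifact_mask`
#'   (logical `H x W`, a subset of the FOV mask; may be empty).
#' @export
remove_bright_border <- function(image, fov, bmean_size = NULL,
                                 opening_radius = NULL) {
  stopifnot(is_fundus_image(image), inherits(fov, "fov_geometry"))
  blue <- unclass(image)[, , 3]
  if (is.null(bmean_size)) bmean_size <- odd_near(fov$diameter_D / 10, 3L)
  if (is.null(opening_radius))
    opening_radius <- max(2L, min(8L, as.integer(round(fov$diameter_D / 100))))
  # masked (normalized) mean: the local blue average over in-FOV pixels only,
  # so the black surround does not drag the mean down at the rim and fake a
  # bright excess there
  mnum <- mean_filter(blue * fov$mask, bmean_size)
  mden <- mean_filter(fov$mask * 1, bmean_size)
  bmean <- mnum / pmax(mden, 1e-6)
  bmask <- pmax(blue - bmean, 0)
  bmask[!fov$mask] <- 0

  # marker: bright-excess values on a thin ring just inside the FOV contour
  r <- fov$diameter_D / 2
  ring <- fov$mask & !circle_mask(nrow(blue), ncol(blue),
                                  fov$center_row, fov$center_col, r - 3)
  marker <- matrix(0, nrow(blue), ncol(blue))
  marker[ring] <- bmask[ring]
  rec <- cpp_reconstruct_dilation(marker, bmask)
  rec[!fov$mask] <- 0

  if (max(rec) < 0.05) {
    amask <- matrix(FALSE, nrow(blue), ncol(blue))
  } else {
    # artifacts are *excessively* bright: besides Otsu's split, demand a
    # minimum absolute excess over the local mean so rim noise never counts
    thr <- max(EBImage::otsu(rec, range = c(0, max(rec))), 0.05)
    amask <- rec > thr
    amask <- EBImage::imageData(EBImage::opening(
      amask, EBImage::makeBrush(2L * opening_radius + 1L, "disc"))) > 0.5
    amask <- amask & fov$mask
  }
  if (!any(amask))
    return(list(image = image, artifact_mask = amask))

  known <- !amask                       # fill artifact pixels from the rest
  filled <- cpp_ring_fill(as.numeric(unclass(image)), as.logical(known),
                          nrow(blue), ncol(blue))
  out <- array(filled, dim(unclass(image)))
  list(image = as_fundus(out, image), artifact_mask = amask)
}

#' Extend the retinal background outside the FOV
#'
#' Replaces the black surround with colors grown outward from the FOV
#' boundary: ring by ring, each new pixel takes the mean of its
#' already-assigned 8-neighbors until the whole frame is filled. Later mean
#' filters then never mix retinal tissue with the black aperture surround,
#' avoiding strong spurious gradients at the FOV rim.
#'
#' @param image a [fundus_image].
#' @param fov the image's [fov_geometry].
#' @return A [fundus_image]; pixels inside the FOV are unchanged.
#' @export
extend_background <- function(image, fov) {
  stopifnot(is_fundus_image(image), inherits(fov, "fov_geometry"))
  if (all(fov$mask)) return(image)
  a <- unclass(image)
  filled <- cpp_ring_fill(as.numeric(a), as.logical(fov$mask),
                          nrow(fov$mask), ncol(fov$mask))
  out <- array(filled, dim(a))
  for (ch in 1:3) {                     # contract: interior is untouched
    pl <- out[, , ch]; pl[fov$mask] <- a[, , ch][fov$mask]; out[, , ch] <- pl
  }
  as_fundus(out, image)
}

#' Illumination and color equalization
#'
#' Works in HSI space. The intensity channel is flattened by subtracting its
#' own large-mean-filtered version (filter `hm1`, sized like the optic disc)
#' and re-centered on the target mean `mu`:
#' `I_eq = I + mu - I * hm1`. Hue and saturation are shifted additively so
#' their in-FOV means match the targets; the hue shift is applied modulo
#' 2*pi and the hue mean is the circular mean. The result is converted back
#' to RGB and clipped to `[0, 1]`.
#'
#' @param image a [fundus_image] (background-extended).
#' @param fov the image's [fov_geometry].
#' @param targets a [normalization_targets].
#' @param hm1_size odd width of the large mean filter; default the odd
#'   integer nearest D/5 (optic-disc scale).
#' @return A [fundus_image].
#' @export
equalize_illumination_color <- function(image, fov, targets = normalization_targets(),
                                        hm1_size = NULL) {
  stopifnot(is_fundus_image(image), inherits(fov, "fov_geometry"),
            inherits(targets, "normalization_targets"))
  if (is.null(hm1_size)) hm1_size <- odd_near(fov$diameter_D / 5, 3L)
  stopifnot(hm1_size %% 2L == 1L, hm1_size > 1L)
  hsi <- rgb_to_hsi(unclass(image))
  m <- fov$mask

  i_eq <- hsi$i + targets$mu_intensity - mean_filter(hsi$i, hm1_size)

  s_shift <- targets$mu_saturation - mean(hsi$s[m])
  s_eq <- hsi$s + s_shift

  if (mean(hsi$s[m]) < 1e-6) {
    warning("equalize_illumination_color: zero-saturation image, hue shift skipped")
    h_eq <- hsi$h
  } else {
    h_shift <- targets$mu_hue - circular_mean_hue(hsi$h[m])
    h_eq <- (hsi$h + h_shift) %% (2 * pi)
  }
  as_fundus(hsi_to_rgb(h_eq, s_eq, i_eq), image)
}

#' Denoising and local contrast enhancement
#'
#' A 3x3 mean filter per RGB channel suppresses capture/compression noise
#' while keeping the smallest lesions, then contrast-limited adaptive
#' histogram equalization (CLAHE) on the HSI intensity channel sharpens
#' local contrast — applied to intensity only so hue is not distorted.
#'
#' @param image a [fundus_image].
#' @param denoise_size mean-filter width in pixels (odd).
#' @param clahe_tiles CLAHE tile grid (`clahe_tiles x clahe_tiles`).
#' @param clahe_limit CLAHE clip limit (multiples of the uniform bin height).
#' @return A [fundus_image].
#' @export
denoise_and_enhance <- function(image, denoise_size = 3L, clahe_tiles = 8L,
                                clahe_limit = 2) {
  stopifnot(is_fundus_image(image))
  a <- unclass(image)
  den <- a
  for (ch in 1:3) den[, , ch] <- mean_filter(a[, , ch], denoise_size)
  den <- clip01(den)
  hsi <- rgb_to_hsi(den)
  # pad by edge replication to a multiple of the tile grid, then crop back
  x <- pmax(pmin(hsi$i, 1), 0)
  h <- nrow(x); w <- ncol(x)
  h2 <- clahe_tiles * ceiling(h / clahe_tiles)
  w2 <- clahe_tiles * ceiling(w / clahe_tiles)
  xp <- x[c(seq_len(h), rep(h, h2 - h)), c(seq_len(w), rep(w, w2 - w))]
  i_en <- EBImage::imageData(EBImage::clahe(xp, nx = clahe_tiles,
                                            ny = clahe_tiles, bins = 256L,
                                            limit = clahe_limit))[seq_len(h),
                                                                  seq_len(w)]
  as_fundus(hsi_to_rgb(hsi$h, hsi$s, i_en), image)
}

#' Full preprocessing pipeline
#'
#' Runs, in order: FOV detection, bright-border artifact removal, background
#' extension, illumination and color equalization, denoising + CLAHE. The
#' stage order matters: artifacts are removed before colors are grown
#' outward, and equalization sees a frame with no black surround.
#'
#' @param image a [fundus_image].
#' @param targets a [normalization_targets].
#' @param config a [pipeline_config] (only its preprocessing entries are
#'   used).
#' @param keep_stages if `TRUE`, intermediate images are kept in `$stages`.
#' @param fov optional pre-computed [fov_geometry] (skips detection).
#' @return A `preprocessed_image`: list with `iprep` ([fundus_image]),
#'   `fov`, `artifact_mask`, `stage_names`, and optionally `stages`.
#' @export
preprocess <- function(image, targets = normalization_targets(),
                       config = pipeline_config(), keep_stages = FALSE,
                       fov = NULL) {
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("preprocess [%s]: %s", stage, conditionMessage(e)), call. = FALSE))
  }
  if (is.null(fov)) fov <- run("detect_fov", detect_fov(image))
  rb   <- run("remove_bright_border",
              remove_bright_border(image, fov, config$bmean_size,
                                   config$border_opening_radius))
  ext  <- run("extend_background", extend_background(rb$image, fov))
  eq   <- run("equalize_illumination_color",
              equalize_illumination_color(ext, fov, targets, config$hm1_size))
  prep <- run("denoise_and_enhance",
              denoise_and_enhance(eq, config$denoise_size, config$clahe_tiles,
                                  config$clahe_limit))
  out <- list(iprep = prep, fov = fov, artifact_mask = rb$artifact_mask,
              stage_names = c("remove_bright_border", "extend_background",
                              "equalize_illumination_color",
                              "denoise_and_enhance"))
  if (keep_stages)
    out$stages <- list(irem = rb$image, iext = ext, ieq = eq, iden = prep)
  structure(out, class = "preprocessed_image")
}

#' @export
print.preprocessed_image <- function(x, ...) {
  cat(sprintf("preprocessed_image: %d x %d, D = %.1f, artifact px = %d\n",
              dim(x$iprep)[1], dim(x$iprep)[2], x$fov$diameter_D,
              sum(x$artifact_mask)))
  invisible(x)
}
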