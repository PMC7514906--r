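#' Field-of-view geometry
#'
#' The circular illuminated aperture (field of view, FOV) of a fundus
#' photograph, described by its center, diameter `D` and a filled boolean
#' mask. `D` is the length scale from which all resolution-dependent
#' parameters of the pipeline (filter sizes, morphological scales) derive.
#'
#' @param center_row,center_col circle center, 0-based pixel coordinates.
#' @param diameter_D FOV diameter in pixels.
#' @param mask `H x W` logical matrix, `TRUE` inside the FOV.
#' @return A `fov_geometry` object (list).
#' @export
fov_geometry <- function(center_row, center_col, diameter_D, mask) {
  stopifnot(diameter_D > 0, is.logical(mask), is.matrix(mask))
  area <- sum(mask)
  ideal <- pi * (diameter_D / 2)^2
  if (area < 0.8 * min(ideal, prod(dim(mask))) || area > 1.2 * ideal)
    stop("fov_geometry: mask area inconsistent with diameter")
  structure(list(center_row = center_row, center_col = center_col,
                 diameter_D = diameter_D, mask = mask),
            class = "fov_geometry")
}

#' @export
print.fov_geometry <- function(x, ...) {
  cat(sprintf("fov_geometry: center (%.1f, %.1f), D = %.1f px, mask %d px\n",
              x$center_row, x$center_col, x$diameter_D, sum(x$mask)))
  invisible(x)
}

# Filled circle mask intersected with the frame.
circle_mask <- function(h, w, cr, cc, radius) {
  rr <- matrix(0:(h - 1), h, w)
  ccm <- matrix(0:(w - 1), h, w, byrow = TRUE)
  (rr - cr)^2 + (ccm - cc)^2 <= radius^2
}

#' Detect the circular field of view
#'
#' Estimates the FOV of a fundus photograph from the red channel, where the
#' illuminated disc contrasts most with the dark surround. The initial
#' diameter comes from the intensity profile along the main image diagonal,
#' thresholded at half its dynamic range; the estimate is then refined by
#' gradient-magnitude edge detection followed by a circular Hough vote over
#' centers and radii within 10% of the initial guess. If the Hough
#' refinement finds no consistent circle, a circle is fitted to the largest
#' connected bright region instead.
#'
#' @param image a [fundus_image]; the red channel must show a bright disc on
#'   a darker surround.
#' @return A [fov_geometry].
#' @export
detect_fov <- function(image) {
  stopifnot(is_fundus_image(image))
  red <- unclass(image)[, , 1]
  h <- nrow(red); w <- ncol(red)

  # -- initial D from the main-diagonal red profile ------------------------
  n <- min(h, w)
  t <- seq_len(n)
  prof <- red[cbind(round(seq(1, h, length.out = n)),
                    round(seq(1, w, length.out = n)))]
  rng <- range(prof)
  if (diff(rng) < 0.05)
    stop("detect_fov: no FOV found (flat diagonal intensity profile)")
  thr <- mean(rng)
  above <- which(prof > thr)
  if (length(above) < 2L)
    stop("detect_fov: no FOV found (no rising/falling transition)")
  # chord length along the diagonal, in pixel units
  step <- sqrt((h / n)^2 + (w / n)^2)
  d0 <- (max(above) - min(above)) * step
  if (d0 < 32) stop("detect_fov: no FOV found (aperture too small)")

  # -- edge map: thresholded Sobel gradient magnitude ----------------------
  sm <- filt2(red, matrix(1 / 9, 3, 3))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- filt2(sm, kx)
  gy <- filt2(sm, t(kx))
  gmag <- sqrt(gx^2 + gy^2)
  ethr <- stats::quantile(gmag, 0.98)
  ep <- which(gmag >= ethr & gmag > 1e-3, arr.ind = TRUE) - 1L  # 0-based

  bright <- red > thr
  cr0 <- mean(which(bright, arr.ind = TRUE)[, 1]) - 1
  cc0 <- mean(which(bright, arr.ind = TRUE)[, 2]) - 1

  fit <- hough_circle(ep, cr0, cc0, d0 / 2)
  if (is.null(fit)) {
    # fallback: circle fit to the largest connected bright region
    lab <- EBImage::bwlabel(bright)
    sizes <- tabulate(lab[lab > 0])
    big <- lab == which.max(sizes)
    idx <- which(big, arr.ind = TRUE) - 1L
    fit <- list(cr = mean(idx[, 1]), cc = mean(idx[, 2]),
                r = sqrt(sum(big) / pi))
  }
  mask <- circle_mask(h, w, fit$cr, fit$cc, fit$r)
  fov_geometry(fit$cr, fit$cc, 2 * fit$r, mask)
}

# Circular Hough vote restricted to centers near (cr0, cc0) and radii within
# +/-10% of r0. Returns NULL when the best circle is supported by too few
# edge pixels to be credible.
hough_circle <- function(edge_pts, cr0, cc0, r0) {
  if (nrow(edge_pts) < 20L) return(NULL)
  span <- max(4, round(0.05 * r0))
  ctr <- expand.grid(cr = cr0 + seq(-span, span, length.out = 9),
                     cc = cc0 + seq(-span, span, length.out = 9))
  rlo <- 0.9 * r0; rhi <- 1.1 * r0
  best <- NULL; best_votes <- -1L
  for (k in seq_len(nrow(ctr))) {
    d <- sqrt((edge_pts[, 1] - ctr$cr[k])^2 + (edge_pts[, 2] - ctr$cc[k])^2)
    d <- d[d >= rlo & d <= rhi]
    if (length(d) < 20L) next
    hb <- tabulate(pmin(pmax(1L, as.integer(d - rlo) + 1L),
                        as.integer(rhi - rlo) + 1L))
    v <- max(hb)
    if (v > best_votes) {
      best_votes <- v
      best <- list(cr = ctr$cr[k], cc = ctr$cc[k],
                   r = rlo + which.max(hb) - 0.5)
    }
  }
  if (best_votes < 0.1 * 2 * pi * r0) return(NULL)
  best
}
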