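#' Multiscale analysis scales
#'
#' The darkness/brightness maps compare each pixel against mean-filtered
#' backgrounds at a set of window sizes derived from the FOV diameter:
#' `s = D/48, D/24, D/12, D/6, D/3`, rounded to odd integers. Small scales
#' respond to microaneurysms, large ones to hemorrhages.
#'
#' @param D FOV diameter in pixels.
#' @param fractions divisors of `D` defining the scales.
#' @return A `scale_set`: list with `scales` (odd, strictly increasing) and
#'   `D`.
#' @export
scale_set <- function(D, fractions = c(1 / 48, 1 / 24, 1 / 12, 1 / 6, 1 / 3)) {
  stopifnot(D > 0)
  s <- vapply(D * fractions, odd_near, integer(1), lo = 3L)
  s <- unique(s)
  stopifnot(all(diff(s) > 0), all(s < D))
  structure(list(scales = s, D = D), class = "scale_set")
}

#' Scale weight for the multiscale maps
#'
#' Down-weights coarse scales linearly: `alpha_s = 1 - 3.84 * s / D`.
#' Zero at `s = D/3.84`; negative beyond (at `s = D/3` it is -0.28, which
#' combined with the max over scales and the clip at zero makes that scale
#' contribute only in rare sign-reversed configurations — kept as specified).
#'
#' @param s scale (window size) in pixels.
#' @param D FOV diameter in pixels.
#' @return The scalar weight.
#' @export
alpha_scale <- function(s, D) {
  stopifnot(s > 0, D > 0)
  1 - 3.84 * s / D
}

#' Alternating sequential filtering
#'
#' Per RGB channel, applies closing-after-opening with disc structuring
#' elements of radius 1, 2, ..., `r_max` in increasing order. Dark
#' structures narrower than about `2 * r_max` (vessels, red lesions) are
#' removed, leaving an estimate of the lesion-free retina used to locate
#' bright structures.
#'
#' @param iprep a preprocessed [fundus_image].
#' @param D FOV diameter (sets the default `r_max`).
#' @param r_max largest disc radius; default `round(D / 60)` (a typical
#'   major-vessel half-width).
#' @return A [fundus_image].
#' @export
asf <- function(iprep, D, r_max = NULL) {
  stopifnot(is_fundus_image(iprep))
  if (is.null(r_max)) r_max <- max(1L, as.integer(round(D / 60)))
  stopifnot(r_max >= 1L)
  a <- unclass(iprep)
  for (r in seq_len(r_max)) {
    k <- EBImage::makeBrush(2L * r + 1L, "disc")
    for (ch in 1:3) {
      x <- EBImage::imageData(EBImage::opening(a[, , ch], k))
      a[, , ch] <- EBImage::imageData(EBImage::closing(x, k))
    }
  }
  as_fundus(a, iprep)
}

#' Multiscale brightness map
#'
#' Per channel, `Ibri = max over s of alpha_s * (Iasf - Ibg_s)`, where
#' `Ibg_s` is the `s x s` mean filter of `Iasf`; negative values are clipped
#' to zero. Bright structures (optic disc, artifacts) light up; the map is
#' subtracted before darkness estimation so that the rims of bright
#' structures are not mistaken for dark regions.
#'
#' @param iasf output of [asf].
#' @param scales a [scale_set].
#' @return `H x W x 3` array, non-negative.
#' @export
brightness_map <- function(iasf, scales) {
  stopifnot(is_fundus_image(iasf), inherits(scales, "scale_set"))
  a <- unclass(iasf)
  out <- array(0, dim(a))
  for (ch in 1:3) {
    x <- a[, , ch]
    acc <- matrix(-Inf, nrow(x), ncol(x))
    for (s in scales$scales) {
      al <- alpha_scale(s, scales$D)
      acc <- pmax(acc, al * (x - mean_filter(x, s)))
    }
    out[, , ch] <- pmax(0, acc)
  }
  out
}

#' Multiscale darkness map
#'
#' Scores how dark each pixel is relative to the retinal background: per
#' channel, `Idark = max over s of alpha_s * (Ibg_s - (Iprep - Ibri))`, with
#' `Ibg_s` the `s x s` mean filter of the brightness-corrected image
#' `Iprep - Ibri`. Dark pixels score high; the `Iprep - Ibri` term
#' suppresses false darkness at the edges of bright structures. Values are
#' clipped to `[0, 1]`, zeroed outside the FOV, and finally rescaled by
#' the maximum over the FOV (all channels jointly), so the map expresses
#' darkness relative to the image's own darkest structures. This keeps the
#' downstream 0.3 keep-threshold a coarse, contrast-independent rule — the
#' darkest vessels and lesions always score near 1 — rather than a hard
#' absolute-contrast cut.
#'
#' @param iprep a preprocessed [fundus_image].
#' @param ibri matching [brightness_map] output.
#' @param scales a [scale_set].
#' @param fov the image's [fov_geometry].
#' @return A `darkness_map`: list with `values` (`H x W x 3` in `[0, 1]`),
#'   `D` and `fov_mask`.
#' @export
darkness_map <- function(iprep, ibri, scales, fov) {
  stopifnot(is_fundus_image(iprep), inherits(scales, "scale_set"),
            inherits(fov, "fov_geometry"))
  a <- unclass(iprep)
  stopifnot(all(dim(ibri) == dim(a)))
  out <- array(0, dim(a))
  for (ch in 1:3) {
    x <- a[, , ch] - ibri[, , ch]
    acc <- matrix(-Inf, nrow(x), ncol(x))
    for (s in scales$scales) {
      al <- alpha_scale(s, scales$D)
      acc <- pmax(acc, al * (mean_filter(x, s) - x))
    }
    acc <- pmax(pmin(acc, 1), 0)
    acc[!fov$mask] <- 0
    out[, , ch] <- acc
  }
  m <- max(out)
  if (m > 1e-6) out <- out / m      # leave all-flat maps at zero
  structure(list(values = out, D = scales$D, fov_mask = fov$mask),
            class = "darkness_map")
}

#' @export
print.darkness_map <- function(x, ...) {
  cat(sprintf("darkness_map: %d x %d, D = %.1f, max green = %.3f\n",
              dim(x$values)[1], dim(x$values)[2], x$D, max(x$values[, , 2])))
  invisible(x)
}

#' Compute the darkness map of a preprocessed image
#'
#' Convenience wrapper chaining [asf], [brightness_map] and [darkness_map].
#'
#' @param prep a `preprocessed_image` from [preprocess].
#' @param r_max see [asf].
#' @param fractions see [scale_set].
#' @return list with `idark` (a `darkness_map`), `ibri`, `iasf` and
#'   `scales`.
#' @export
compute_darkness <- function(prep, r_max = NULL,
                             fractions = c(1 / 48, 1 / 24, 1 / 12, 1 / 6, 1 / 3)) {
  stopifnot(inherits(prep, "preprocessed_image"))
  sc <- scale_set(prep$fov$diameter_D, fractions)
  ia <- asf(prep$iprep, sc$D, r_max)
  ib <- brightness_map(ia, sc)
  id <- darkness_map(prep$iprep, ib, sc, prep$fov)
  list(idark = id, ibri = ib, iasf = ia, scales = sc)
}
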