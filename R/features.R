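#' Table of the 39 candidate feature names
#'
#' Shape (1-11), intensity statistics over the preprocessed image and the
#' darkness map (12-35), boundary edge strength (36), multiscale line
#' operator response (37) and normalized distances to the optic disc and
#' fovea (38-39).
#'
#' @return character vector of length 39.
#' @export
feature_names <- function() {
  stat <- c("mean", "median", "sd", "entropy")
  ch <- c("R", "G", "B")
  c("area", "bbox_width", "bbox_height", "convex_area", "eccentricity",
    "n_holes", "extent", "major_axis", "minor_axis", "perimeter", "solidity",
    paste0(rep(stat, each = 3), "_", rep(ch, 4), "_prep"),
    paste0(rep(stat, each = 3), "_", rep(ch, 4), "_dark"),
    "edge_prewitt", "line_operator", "dist_od", "dist_fovea")
}

#' Landmark coordinates (optic disc and fovea)
#'
#' @param od_center,fovea_center `(row, col)` 0-based pixel coordinates.
#' @param D FOV diameter in pixels.
#' @param source `"provided"`, `"estimated"` or `"fallback"`.
#' @return A `landmark_set`.
#' @export
landmark_set <- function(od_center, fovea_center, D, source = "provided") {
  structure(list(od_center = as.numeric(od_center),
                 fovea_center = as.numeric(fovea_center),
                 D = D, source = source), class = "landmark_set")
}

#' Baseline optic-disc and fovea localization
#'
#' A deliberately simple estimator used only when coordinates are not
#' provided: the optic disc (OD) center is the brightest point of the
#' ASF-smoothed intensity after an OD-scale (D/5) mean filter, refined to
#' the centroid of the near-maximal blob; the fovea is the darkest smoothed
#' point within an annulus 2-3 OD diameters from the OD center. When the
#' search region is empty the FOV center is returned with a warning and
#' `source = "fallback"`.
#'
#' @param iprep preprocessed [fundus_image] (unused by the baseline but part
#'   of the interface for richer estimators).
#' @param iasf the [asf]-filtered image.
#' @param fov the image's [fov_geometry].
#' @return A `landmark_set` with `source = "estimated"` (or `"fallback"`).
#' @export
estimate_landmarks <- function(iprep, iasf, fov) {
  stopifnot(is_fundus_image(iasf), inherits(fov, "fov_geometry"))
  D <- fov$diameter_D
  a <- unclass(iasf)
  inten <- (a[, , 1] + a[, , 2] + a[, , 3]) / 3
  inner <- circle_mask(nrow(inten), ncol(inten), fov$center_row,
                       fov$center_col, D / 2 - D / 12)
  sm <- mean_filter(inten, odd_near(D / 5, 3L))
  sm_od <- sm; sm_od[!inner] <- -Inf
  pk <- which(sm_od == max(sm_od), arr.ind = TRUE)[1, ]
  near <- circle_mask(nrow(inten), ncol(inten), pk[1] - 1, pk[2] - 1, D / 10) &
    sm_od > max(sm_od) * 0.98
  odc <- c(mean(which(near, arr.ind = TRUE)[, 1]) - 1,
           mean(which(near, arr.ind = TRUE)[, 2]) - 1)

  od_diam <- D / 5
  rr <- matrix(0:(nrow(inten) - 1), nrow(inten), ncol(inten))
  cc <- matrix(0:(ncol(inten) - 1), nrow(inten), ncol(inten), byrow = TRUE)
  dd <- sqrt((rr - odc[1])^2 + (cc - odc[2])^2)
  annulus <- dd >= 2 * od_diam & dd <= 3 * od_diam & inner
  if (!any(annulus)) {
    warning("estimate_landmarks: empty fovea search region, using FOV center")
    return(landmark_set(c(fov$center_row, fov$center_col),
                        c(fov$center_row, fov$center_col), D, "fallback"))
  }
  sm_f <- mean_filter(inten, odd_near(D / 10, 3L))
  sm_f[!annulus] <- Inf
  fv <- which(sm_f == min(sm_f), arr.ind = TRUE)[1, ] - 1
  landmark_set(odc, as.numeric(fv), D, "estimated")
}

# row/col (1-based) coordinates of a candidate's pixels
cand_rc <- function(cand, H) {
  cbind(row = (cand$pixel_indices - 1L) %% H + 1L,
        col = (cand$pixel_indices - 1L) %/% H + 1L)
}

# inner boundary: region pixels with a 4-neighbour outside the region
inner_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2); pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)] &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !core
}

#' Shape features of one candidate
#'
#' Area; bounding-box width and height; convex-hull area (hull of the pixel
#' squares, so a solid square has hull area equal to its area); eccentricity
#' of the equivalent second-moment ellipse; number of holes; extent
#' (area / bounding-box area); major and minor axis lengths; perimeter
#' (crack length of the region boundary); solidity (area / convex area).
#'
#' @param cand one candidate from a [candidate_set].
#' @param shape `c(H, W)` of the source image.
#' @return named numeric vector of length 11.
#' @export
shape_features <- function(cand, shape) {
  rc <- cand_rc(cand, shape[1])
  n <- nrow(rc)
  r0 <- range(rc[, 1]); c0 <- range(rc[, 2])
  bb_h <- diff(r0) + 1L; bb_w <- diff(c0) + 1L

  # cropped mask with 1-px pad
  m <- matrix(FALSE, bb_h + 2L, bb_w + 2L)
  m[cbind(rc[, 1] - r0[1] + 2L, rc[, 2] - c0[1] + 2L)] <- TRUE

  # convex hull over the 4 corners of every pixel square
  pts <- rbind(cbind(rc[, 1] - 0.5, rc[, 2] - 0.5), cbind(rc[, 1] - 0.5, rc[, 2] + 0.5),
               cbind(rc[, 1] + 0.5, rc[, 2] - 0.5), cbind(rc[, 1] + 0.5, rc[, 2] + 0.5))
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  k <- nrow(hp)
  hull_area <- if (k < 3) n else
    abs(sum(hp[, 1] * hp[c(2:k, 1), 2] - hp[c(2:k, 1), 1] * hp[, 2])) / 2

  # second-moment ellipse (pixel-square correction 1/12)
  mu_r <- mean(rc[, 1]); mu_c <- mean(rc[, 2])
  vrr <- mean((rc[, 1] - mu_r)^2) + 1 / 12
  vcc <- mean((rc[, 2] - mu_c)^2) + 1 / 12
  vrc <- mean((rc[, 1] - mu_r) * (rc[, 2] - mu_c))
  tr <- vrr + vcc; det2 <- sqrt(max(0, (vrr - vcc)^2 / 4 + vrc^2))
  l1 <- tr / 2 + det2; l2 <- max(tr / 2 - det2, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- sqrt(max(0, 1 - l2 / l1))

  # holes: components of (filled & !mask)
  filled <- EBImage::fillHull(m)
  holes_mask <- filled & !m
  n_holes <- if (any(holes_mask)) max(EBImage::bwlabel(holes_mask)) else 0

  # crack-length perimeter: region/background 4-neighbour transitions
  h2 <- nrow(m); w2 <- ncol(m)
  perim <- sum(m[1:(h2 - 1), ] != m[2:h2, ]) + sum(m[, 1:(w2 - 1)] != m[, 2:w2])

  c(area = n, bbox_width = bb_w, bbox_height = bb_h,
    convex_area = max(hull_area, n), eccentricity = ecc, n_holes = n_holes,
    extent = n / (bb_w * bb_h), major_axis = major, minor_axis = minor,
    perimeter = perim, solidity = n / max(hull_area, n))
}

# Shannon entropy of in-region values: 256 equal-width bins on [0,1], log2.
bin_entropy <- function(x, bins = 256L) {
  cnt <- tabulate(pmin(bins, floor(x * bins) + 1L), bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log2(p))
}

#' Intensity features of one candidate
#'
#' Mean, median, standard deviation and histogram entropy (256 bins, bits)
#' of the in-region pixels, per RGB channel, computed on the preprocessed
#' image and on the darkness map: 4 statistics x 3 channels x 2 images.
#'
#' @param cand one candidate.
#' @param iprep preprocessed [fundus_image].
#' @param idark matching `darkness_map`.
#' @return named numeric vector of length 24.
#' @export
intensity_features <- function(cand, iprep, idark) {
  plane <- prod(dim(unclass(iprep))[1:2])
  one <- function(arr) {
    out <- numeric(12)
    for (ch in 0:2) {
      x <- arr[cand$pixel_indices + ch * plane]
      out[ch + 1]     <- mean(x)
      out[ch + 4]     <- stats::median(x)
      out[ch + 7]     <- if (length(x) > 1) stats::sd(x) else 0
      out[ch + 10]    <- bin_entropy(x)
    }
    out
  }
  v <- c(one(unclass(iprep)), one(idark$values))
  names(v) <- feature_names()[12:35]
  v
}

#' Boundary edge strength (Prewitt)
#'
#' Mean Prewitt gradient magnitude of the green channel over the
#' candidate's one-pixel inner boundary. True lesions have closed, fairly
#' strong boundaries; background fragments do not.
#'
#' @param cand one candidate.
#' @param iprep preprocessed [fundus_image].
#' @param gmag optional precomputed gradient-magnitude matrix (one per
#'   image; computed if missing).
#' @return scalar.
#' @export
edge_feature <- function(cand, iprep, gmag = NULL) {
  if (is.null(gmag)) gmag <- prewitt_magnitude(unclass(iprep)[, , 2])
  H <- nrow(gmag)
  rc <- cand_rc(cand, H)
  r0 <- range(rc[, 1]); c0 <- range(rc[, 2])
  m <- matrix(FALSE, diff(r0) + 3L, diff(c0) + 3L)
  m[cbind(rc[, 1] - r0[1] + 2L, rc[, 2] - c0[1] + 2L)] <- TRUE
  b <- which(inner_boundary(m), arr.ind = TRUE)
  mean(gmag[cbind(b[, 1] + r0[1] - 2L, b[, 2] + c0[1] - 2L)])
}

#' @rdname edge_feature
#' @param x numeric matrix (one image channel).
#' @export
prewitt_magnitude <- function(x) {
  kx <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3)
  gx <- filt2(x, kx)
  gy <- filt2(x, t(kx))
  sqrt(gx^2 + gy^2)
}

#' Multiscale line-operator response map
#'
#' On the inverted green channel (vessels bright), the line strength at a
#' pixel is the maximum over 12 orientations of the mean along a length-L
#' line through the pixel minus the mean of the L x L window; the map takes
#' the maximum over L = odd integers nearest D/120, D/80, D/48 (vessel
#' calibre scales). Vessel-like elongated candidates score high, round
#' lesions low.
#'
#' @param iprep preprocessed [fundus_image].
#' @param D FOV diameter in pixels.
#' @param n_orient number of line orientations.
#' @param fractions scale divisors of `D`.
#' @return numeric `H x W` matrix.
#' @export
line_operator_map <- function(iprep, D, n_orient = 12L,
                              fractions = c(1 / 120, 1 / 80, 1 / 48)) {
  x <- 1 - unclass(iprep)[, , 2]
  out <- matrix(-Inf, nrow(x), ncol(x))
  for (f in fractions) {
    L <- odd_near(D * f, 5L)
    box <- mean_filter(x, L)
    half <- (L - 1L) / 2L
    for (th in (seq_len(n_orient) - 1L) * pi / n_orient) {
      t <- -half:half
      rr <- round(t * sin(th)); cc <- round(t * cos(th))
      k <- matrix(0, L, L)
      k[cbind(rr + half + 1L, cc + half + 1L)] <- 1
      k <- k / sum(k)
      lm <- filt2(x, k)
      out <- pmax(out, lm - box)
    }
  }
  out
}

#' Line-operator feature of one candidate
#'
#' Mean of the [line_operator_map] inside the candidate.
#'
#' @param cand one candidate.
#' @param iprep preprocessed [fundus_image].
#' @param D FOV diameter.
#' @param map optional precomputed [line_operator_map].
#' @return scalar.
#' @export
line_operator_feature <- function(cand, iprep, D, map = NULL) {
  if (is.null(map)) map <- line_operator_map(iprep, D)
  mean(map[cand$pixel_indices])
}

#' Feature matrix of a candidate set
#'
#' @param values `n x 39` numeric matrix.
#' @param candidate_ids candidate identifiers.
#' @param labels optional 0/1 class labels.
#' @return A `feature_matrix`.
#' @export
feature_matrix <- function(values, candidate_ids = seq_len(nrow(values)),
                           labels = NULL) {
  stopifnot(ncol(values) == 39L, all(is.finite(values)))
  colnames(values) <- feature_names()
  structure(list(values = values, feature_names = feature_names(),
                 candidate_ids = candidate_ids, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d candidates x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else
                sprintf(", %d positive labels", sum(x$labels))))
  invisible(x)
}

#' Extract all 39 features for every candidate
#'
#' Assembles shape, intensity, edge, line-operator and landmark-distance
#' features in the canonical order ([feature_names]). Distances to the
#' optic disc and fovea are centroid-to-landmark Euclidean distances
#' divided by `D`, making them resolution invariant.
#'
#' @param cands a [candidate_set].
#' @param iprep preprocessed [fundus_image].
#' @param idark matching `darkness_map`.
#' @param landmarks a `landmark_set`.
#' @return A [feature_matrix] (0-row if the candidate set is empty).
#' @export
extract_features <- function(cands, iprep, idark, landmarks) {
  stopifnot(inherits(cands, "candidate_set"), inherits(landmarks, "landmark_set"))
  nc <- n_candidates(cands)
  vals <- matrix(NA_real_, nc, 39L)
  if (nc == 0L) return(feature_matrix(vals))
  H <- cands$source_shape[1]
  gmag <- prewitt_magnitude(unclass(iprep)[, , 2])
  lmap <- line_operator_map(iprep, landmarks$D)
  for (i in seq_len(nc)) {
    cand <- cands$candidates[[i]]
    rc <- cand_rc(cand, H)
    cen <- c(mean(rc[, 1]) - 1, mean(rc[, 2]) - 1)
    vals[i, 1:11]  <- shape_features(cand, cands$source_shape)
    vals[i, 12:35] <- intensity_features(cand, iprep, idark)
    vals[i, 36]    <- edge_feature(cand, iprep, gmag)
    vals[i, 37]    <- line_operator_feature(cand, iprep, landmarks$D, lmap)
    vals[i, 38]    <- sqrt(sum((cen - landmarks$od_center)^2)) / landmarks$D
    vals[i, 39]    <- sqrt(sum((cen - landmarks$fovea_center)^2)) / landmarks$D
    if (!all(is.finite(vals[i, ])))
      stop(sprintf("extract_features: non-finite feature '%s' for candidate %d",
                   feature_names()[which(!is.finite(vals[i, ]))[1]], i))
  }
  feature_matrix(vals, candidate_ids = vapply(cands$candidates, `[[`,
                                              numeric(1), "label_id"))
}

#' Write / read a feature matrix as CSV
#'
#' @param fm a [feature_matrix].
#' @param path CSV path.
#' @return `path` (write) or a [feature_matrix] (read).
#' @export
write_feature_csv <- function(fm, path) {
  df <- as.data.frame(fm$values)
  df <- cbind(candidate_id = fm$candidate_ids, df)
  if (!is.null(fm$labels)) df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- if ("label" %in% names(df)) df$label else NULL
  ids <- df$candidate_id
  vals <- as.matrix(df[, feature_names(), drop = FALSE])
  feature_matrix(vals, ids, labels)
}
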