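sq_cand <- function(r0, c0, side, shape = c(64L, 64L)) {
  rc <- expand.grid(row = r0:(r0 + side - 1L), col = c0:(c0 + side - 1L))
  cand_from_pixels((rc$col - 1L) * shape[1] + rc$row, shape)
}

test_that("shape features are exact on squares and annuli", {
  sf <- shape_features(sq_cand(10L, 15L, 10L)$candidates[[1]], c(64L, 64L))
  expect_equal(unname(sf[c("area", "bbox_width", "bbox_height", "extent",
                           "solidity", "n_holes")]),
               c(100, 10, 10, 1, 1, 0))
  expect_equal(unname(sf["convex_area"]), 100)
  expect_equal(unname(sf["perimeter"]), 40)       # crack-length boundary

  # square annulus: 10x10 minus central 2x2
  rc <- expand.grid(row = 10:19, col = 15:24)
  drop <- rc$row %in% 14:15 & rc$col %in% 19:20
  rc <- rc[!drop, ]
  cand <- cand_from_pixels((rc$col - 1L) * 64L + rc$row, c(64L, 64L))
  sfa <- shape_features(cand$candidates[[1]], c(64L, 64L))
  expect_equal(unname(sfa["area"]), 96)
  expect_equal(unname(sfa["n_holes"]), 1)

  # random blobs: solidity <= 1, eccentricity in [0, 1)
  set.seed(2)
  for (i in 1:5) {
    pix <- sample(64L * 64L, 60)
    sfb <- shape_features(cand_from_pixels(pix, c(64L, 64L))$candidates[[1]],
                          c(64L, 64L))
    expect_lte(sfb[["solidity"]], 1 + 1e-12)
    expect_gte(sfb[["eccentricity"]], 0)
    expect_lt(sfb[["eccentricity"]], 1)
    expect_gte(sfb[["major_axis"]], sfb[["minor_axis"]])
  }
})

test_that("shape features are translation invariant", {
  a <- shape_features(sq_cand(5L, 5L, 7L)$candidates[[1]], c(64L, 64L))
  b <- shape_features(sq_cand(20L, 28L, 7L)$candidates[[1]], c(64L, 64L))
  expect_equal(a, b)
})

test_that("intensity statistics match direct recomputation", {
  set.seed(7)
  shape <- c(64L, 64L)
  img <- fundus_image(array(runif(64 * 64 * 3, 0.55, 0.95), c(64, 64, 3)))
  dk <- structure(list(values = array(runif(64 * 64 * 3, 0, 0.45),
                                      c(64, 64, 3)),
                       D = 58, fov_mask = matrix(TRUE, 64, 64)),
                  class = "darkness_map")
  pix <- sample(64L * 64L, 120)
  cand <- cand_from_pixels(pix, shape)$candidates[[1]]
  v <- intensity_features(cand, img, dk)
  for (ch in 1:3) {
    x <- unclass(img)[, , ch][cand$pixel_indices]
    expect_equal(unname(v[ch]), mean(x))
    expect_equal(unname(v[3 + ch]), median(x))
    expect_equal(unname(v[6 + ch]), sd(x))
    cnt <- tabulate(pmin(256L, floor(x * 256) + 1L), 256L)
    p <- cnt[cnt > 0] / length(x)
    expect_equal(unname(v[9 + ch]), -sum(p * log2(p)))
    y <- dk$values[, , ch][cand$pixel_indices]
    expect_equal(unname(v[12 + ch]), mean(y))
  }

  # degenerate cases: constant region, two-valued region
  imgc <- fundus_image(array(0.5, c(64, 64, 3)))
  dkc <- structure(list(values = array(0.2, c(64, 64, 3)), D = 58,
                        fov_mask = matrix(TRUE, 64, 64)), class = "darkness_map")
  vc <- intensity_features(cand, imgc, dkc)
  expect_true(all(vc[7:12] == 0))              # sd and entropy vanish
  a2 <- array(0.5, c(64, 64, 3)); a2[1:32, , ] <- 0.7
  half_pix <- c(1:10, 41:50)                   # 10 at 0.7, 10 at 0.5
  v2 <- intensity_features(cand_from_pixels(half_pix, shape)$candidates[[1]],
                           fundus_image(a2), dkc)
  expect_equal(unname(v2[10]), 1)              # entropy 1 bit
})

test_that("the Prewitt boundary feature responds linearly to step edges", {
  shape <- c(64L, 64L)
  cand <- sq_cand(15L, 15L, 8L)$candidates[[1]]
  flat <- fundus_image(array(0.5, c(64, 64, 3)))
  expect_equal(edge_feature(cand, flat), 0)

  step_img <- function(h) {
    a <- array(0.4, c(64, 64, 3)); a[, 19:64, ] <- 0.4 + h
    fundus_image(a)
  }
  e1 <- edge_feature(cand, step_img(0.1))
  e2 <- edge_feature(cand, step_img(0.2))
  expect_equal(e2 / e1, 2, tolerance = 1e-6)

  # equals a direct per-pixel computation on the boundary
  img <- step_img(0.15)
  gm <- prewitt_magnitude(unclass(img)[, , 2])
  m <- matrix(FALSE, 64, 64); m[cand$pixel_indices] <- TRUE
  b <- retsuperpix:::inner_boundary(m)
  expect_equal(edge_feature(cand, img), mean(gm[b]))
})

test_that("the line operator separates lines from blobs and tolerates rotation", {
  n <- 120L
  mk <- function(painter) {
    a <- array(0.6, c(n, n, 3))
    g <- a[, , 2]; g <- painter(g); a[, , 2] <- g
    fundus_image(retsuperpix:::clip01(a))
  }
  D <- 400                                     # scales 5, 5, 9
  flat_map <- line_operator_map(mk(identity), D)
  expect_lt(max(abs(flat_map)), 1e-9)

  # anti-aliased oriented line through the center: intensity dips by 0.3
  # within 1 px of the ideal line, identical rendering at any angle
  aa_line <- function(theta) {
    rr <- matrix(0:(n - 1), n, n); cc <- matrix(0:(n - 1), n, n, byrow = TRUE)
    d_perp <- abs(-sin(theta) * (cc - 59.5) + cos(theta) * (rr - 59.5))
    along <- abs(cos(theta) * (cc - 59.5) + sin(theta) * (rr - 59.5))
    g <- 0.6 - 0.3 * pmax(0, 1 - d_perp / 2) * (along <= 40)
    a <- array(0.6, c(n, n, 3)); a[, , 2] <- g
    list(img = fundus_image(retsuperpix:::clip01(a)),
         cand = cand_from_pixels(which(d_perp <= 1 & along <= 35),
                                 c(n, n))$candidates[[1]])
  }
  l0 <- aa_line(0)
  f_line <- line_operator_feature(l0$cand, l0$img, D)
  blob <- retsuperpix:::circle_mask(n, n, 59.5, 59.5, 5)
  blob_img <- mk(function(g) { g[blob] <- 0.3; g })
  blob_cand <- cand_from_pixels(which(blob), c(n, n))$candidates[[1]]
  f_blob <- line_operator_feature(blob_cand, blob_img, D)
  expect_gt(f_line, f_blob)

  # a 15-degree rotation changes the line response by < 20%
  l15 <- aa_line(15 * pi / 180)
  f_rot <- line_operator_feature(l15$cand, l15$img, D)
  expect_lt(abs(f_rot - f_line) / f_line, 0.2)
})

test_that("landmark estimation finds the planted disc; overrides pass through", {
  sc <- fix_scene(0L)
  prep <- fix_prep(0L)
  dk <- fix_dark(0L)
  est <- estimate_landmarks(prep$iprep, dk$iasf, prep$fov)
  D <- prep$fov$diameter_D
  expect_lt(sqrt(sum((est$od_center - sc$landmarks$od_center)^2)), D / 10)
  # fovea lies in the 2-3 OD-diameter annulus by construction
  dist_f <- sqrt(sum((est$fovea_center - est$od_center)^2))
  expect_gte(dist_f, 2 * D / 5 - 1)
  expect_lte(dist_f, 3 * D / 5 + 1)
  expect_equal(est$source, "estimated")

  given <- landmark_set(c(10, 20), c(30, 40), D, source = "provided")
  expect_identical(given$od_center, c(10, 20))
  expect_identical(given$fovea_center, c(30, 40))
})

test_that("feature extraction assembles 39 named, finite features", {
  sc <- fix_scene(0L)
  prep <- fix_prep(0L); dk <- fix_dark(0L)
  lm <- ers_segment(dk$idark, K = retsuperpix:::effective_k(pipeline_config(),
                                                            250 * 250),
                    0.08, 2)
  cands <- merge_candidates(reduce_candidates(lm, dk$idark), dk$idark)
  fm <- extract_features(cands, prep$iprep, dk$idark, sc$landmarks)
  expect_equal(ncol(fm$values), 39L)
  expect_equal(colnames(fm$values), feature_names())
  expect_true(all(is.finite(fm$values)))
  expect_equal(nrow(fm$values), n_candidates(cands))

  # a candidate centered on the OD has distance feature ~ 0
  odc <- sc$landmarks$od_center
  odpix <- which(retsuperpix:::circle_mask(250, 250, odc[1], odc[2], 3))
  odcand <- cand_from_pixels(odpix, c(250L, 250L))
  fm2 <- extract_features(odcand, prep$iprep, dk$idark, sc$landmarks)
  expect_lt(fm2$values[1, "dist_od"], 0.01)

  # CSV round trip preserves values and names
  path <- tempfile(fileext = ".csv")
  write_feature_csv(fm, path)
  back <- read_feature_csv(path)
  expect_equal(back$values, fm$values, tolerance = 1e-9)
})
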