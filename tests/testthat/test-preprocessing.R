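test_that("FOV detection recovers a planted circular aperture", {
  ff <- flat_fundus(160L, fov_frac = 0.42)
  fov <- detect_fov(ff$image)
  expect_lt(abs(fov$center_row - 79.5), 2)
  expect_lt(abs(fov$center_col - 79.5), 2)
  expect_lt(abs(fov$diameter_D - 2 * 0.42 * 160) / (2 * 0.42 * 160), 0.02)
  # mask area consistent with a filled circle of diameter D
  expect_lt(abs(sum(fov$mask) - pi * (fov$diameter_D / 2)^2) /
              (pi * (fov$diameter_D / 2)^2), 0.2)
})

test_that("FOV detection fails explicitly on degenerate frames", {
  expect_error(detect_fov(fundus_image(array(0, c(100, 100, 3)))), "no FOV")
  expect_error(detect_fov(fundus_image(array(0.8, c(100, 100, 3)))), "no FOV")
})

test_that("bright border artifacts are flagged and inpainted", {
  sc <- fix_scene(3L)                 # seed 3 carries a rim crescent
  fov <- detect_fov(sc$image)
  rb <- remove_bright_border(sc$image, fov)
  expect_gt(sum(rb$artifact_mask), 0)
  # flagged pixels lie inside the FOV and pixels outside the mask are untouched
  expect_true(all(fov$mask[rb$artifact_mask]))
  a0 <- unclass(sc$image); a1 <- unclass(rb$image)
  keep <- !rb$artifact_mask
  for (ch in 1:3)
    expect_identical(a0[, , ch][keep], a1[, , ch][keep])
  # the strongly brightened crescent core is almost fully flagged, and
  # essentially nothing away from the rim is
  expect_gte(mean(rb$artifact_mask[sc$artifact_core]), 0.8)
  n <- nrow(fov$mask)
  inner <- retsuperpix:::circle_mask(n, n, fov$center_row, fov$center_col,
                                     0.85 * fov$diameter_D / 2)
  expect_lte(mean(rb$artifact_mask[inner]), 0.01)
  rim <- fov$mask & !retsuperpix:::circle_mask(n, n, fov$center_row,
                                               fov$center_col,
                                               0.88 * fov$diameter_D / 2)
  expect_gt(mean(rim[rb$artifact_mask]), 0.9)
})

test_that("artifact-free scenes yield an essentially empty artifact mask", {
  sc <- fix_scene(1L)                 # healthy, no artifact
  fov <- detect_fov(sc$image)
  rb <- remove_bright_border(sc$image, fov)
  expect_lt(sum(rb$artifact_mask) / sum(fov$mask), 0.005)
})

test_that("background extension fills the surround and preserves the interior", {
  # exact geometry: a disc strictly inside the painted aperture, so the
  # interior is truly constant
  n <- 120L
  a <- array(0.02, c(n, n, 3))
  fov <- exact_fov(n, 0.45, 0)
  for (ch in 1:3) { pl <- a[, , ch]; pl[fov$mask] <- c(0.6, 0.35, 0.2)[ch]; a[, , ch] <- pl }
  img <- fundus_image(a)
  ext <- extend_background(img, fov)
  ff <- list(image = img)
  a0 <- unclass(ff$image); a1 <- unclass(ext)
  for (ch in 1:3) {
    expect_identical(a0[, , ch][fov$mask], a1[, , ch][fov$mask])
    # constant interior c propagates c everywhere outside
    expect_lt(max(abs(a1[, , ch][!fov$mask] - a0[, , ch][fov$mask][1])), 1e-9)
  }
  # the FOV rim gradient of a large mean filter shrinks after extension
  grad_energy <- function(img) {
    sm <- retsuperpix:::mean_filter(unclass(img)[, , 1], 21L)
    gx <- diff(sm); sum(gx^2)
  }
  sc <- fix_scene(1L)
  fov2 <- detect_fov(sc$image)
  expect_lt(grad_energy(extend_background(sc$image, fov2)),
            grad_energy(sc$image))
})

test_that("circular hue mean follows circular, not arithmetic, rules", {
  expect_angle_equal(circular_mean_hue(c(10, 350) * pi / 180), 0)
  expect_equal(circular_mean_hue(c(0, 90) * pi / 180), pi / 4)
  expect_equal(circular_mean_hue(rep(1.2, 5)), 1.2)
  # wraparound safety: shifting all hues by 2*pi is a no-op
  h <- runif(50, 0, 2 * pi)
  expect_equal(circular_mean_hue(h), circular_mean_hue(h + 2 * pi),
               tolerance = 1e-9)
  expect_error(circular_mean_hue(c(0, pi)), "dispersed")
})

test_that("equalization forces the intensity and hue targets", {
  cf <- const_frame(160L)
  tg <- normalization_targets(mu_intensity = 0.5, mu_hue = 0.4,
                              mu_saturation = 0.35)
  eq <- equalize_illumination_color(cf$image, cf$fov, tg, hm1_size = 31L)
  hsi <- rgb_to_hsi(unclass(eq))
  # constant input intensity -> constant mu (I + mu - I*hm1 = mu)
  expect_lt(diff(range(hsi$i[cf$fov$mask])), 1e-6)
  expect_equal(mean(hsi$i[cf$fov$mask]), 0.5, tolerance = 1e-6)
  expect_angle_equal(circular_mean_hue(hsi$h[cf$fov$mask]), 0.4, tol = 1e-3)

  # quadratic illumination gradient: smoothed-intensity spread halves
  sc <- generate_fundus_scene(scene_params(image_size = 250L, n_ma = 0L,
                                           n_he = 0L,
                                           illumination_gradient_strength = 0.3,
                                           seed = 11L))
  fov2 <- detect_fov(sc$image)
  ext <- extend_background(remove_bright_border(sc$image, fov2)$image, fov2)
  eq2 <- equalize_illumination_color(ext, fov2)
  hm1 <- retsuperpix:::odd_near(fov2$diameter_D / 5, 3L)
  spread <- function(img) {
    sm <- retsuperpix:::mean_filter(rgb_to_hsi(unclass(img))$i, hm1)
    stats::sd(sm[fov2$mask])
  }
  expect_lt(spread(eq2), 0.5 * spread(ext))
})

test_that("denoising and enhancement behave on flat and impulse inputs", {
  # 3x3 mean reduces an isolated impulse to a/9 at its center
  x <- matrix(0.2, 64, 64); x[32, 32] <- 0.2 + 0.45
  xm <- retsuperpix:::mean_filter(x, 3L)
  expect_equal(xm[32, 32] - 0.2, 0.45 / 9, tolerance = 1e-12)

  ff <- flat_fundus(120L)
  out <- denoise_and_enhance(ff$image)
  inner <- retsuperpix:::circle_mask(120, 120, 59.5, 59.5, 40)
  for (ch in 1:3)
    expect_lt(diff(range(unclass(out)[, , ch][inner])), 0.03)

  # CLAHE raises local RMS contrast around a faint lesion
  ff2 <- flat_fundus(120L)
  a <- unclass(ff2$image)
  d <- retsuperpix:::circle_mask(120, 120, 59.5, 59.5, 4)
  for (ch in 1:3) { pl <- a[, , ch]; pl[d] <- pl[d] - 0.05; a[, , ch] <- pl }
  img <- fundus_image(a)
  win <- retsuperpix:::circle_mask(120, 120, 59.5, 59.5, 10)
  rms <- function(im) stats::sd(rgb_to_hsi(unclass(im))$i[win])
  expect_gt(rms(denoise_and_enhance(img)), rms(img))
})

test_that("the full preprocessing chain is deterministic and normalizing", {
  sc <- fix_scene(0L)
  p1 <- preprocess(sc$image, keep_stages = TRUE)
  p2 <- preprocess(sc$image)
  expect_identical(unclass(p1$iprep), unclass(p2$iprep))
  expect_equal(p1$stage_names,
               c("remove_bright_border", "extend_background",
                 "equalize_illumination_color", "denoise_and_enhance"))
  expect_named(p1$stages, c("irem", "iext", "ieq", "iden"))

  # two color casts converge to nearby FOV mean intensities
  mk <- function(rgb, seed) generate_fundus_scene(scene_params(
    image_size = 250L, background_rgb = rgb, n_ma = 0L, n_he = 0L, seed = seed))
  a <- mk(c(0.8, 0.5, 0.3), 21L); b <- mk(c(0.6, 0.33, 0.22), 22L)
  mi <- function(s) {
    pr <- preprocess(s$image)
    mean(rgb_to_hsi(unclass(pr$iprep))$i[pr$fov$mask])
  }
  expect_lt(abs(mi(a) - mi(b)), 0.02)

  # every stage stays in [0,1] at unchanged dimensions
  for (st in p1$stages) {
    expect_true(all(unclass(st) >= 0 & unclass(st) <= 1))
    expect_equal(dim(unclass(st)), dim(unclass(sc$image)))
  }
})

test_that("stage failures carry the stage name", {
  img <- fundus_image(array(0, c(100, 100, 3)))
  expect_error(preprocess(img), "detect_fov")
})

test_that("HSI round trip is faithful on in-gamut colors", {
  set.seed(5)
  a <- array(runif(64 * 64 * 3, 0.1, 0.9), c(64, 64, 3))
  hsi <- rgb_to_hsi(a)
  back <- hsi_to_rgb(hsi$h, hsi$s, hsi$i)
  expect_lt(max(abs(back - a)), 1e-6)
})
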