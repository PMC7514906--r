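# Shared fixtures, memoized so expensive scenes are rendered once per run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

fix_scene <- function(seed, size = 250L) {
  memo(sprintf("scene_%d_%d", seed, size), make_fixture_scene(seed, size))
}

fix_prep <- function(seed, size = 250L) {
  memo(sprintf("prep_%d_%d", seed, size), {
    sc <- fix_scene(seed, size)
    preprocess(sc$image)
  })
}

fix_dark <- function(seed, size = 250L) {
  memo(sprintf("dark_%d_%d", seed, size), compute_darkness(fix_prep(seed, size)))
}

# Flat retina-colored frame with a centered FOV disc: the minimal valid scene.
flat_fundus <- function(n = 120L, rgb = c(0.7, 0.4, 0.25), fov_frac = 0.45) {
  a <- array(0.02, c(n, n, 3))
  m <- retsuperpix:::circle_mask(n, n, (n - 1) / 2, (n - 1) / 2, fov_frac * n)
  for (ch in 1:3) { pl <- a[, , ch]; pl[m] <- rgb[ch]; a[, , ch] <- pl }
  list(image = fundus_image(a), mask = m)
}

# A single-candidate set from explicit pixel linear indices.
cand_from_pixels <- function(pix, shape, mean_rgb = c(0.5, 0.5, 0.5)) {
  candidate_set(list(list(label_id = 1L, pixel_indices = sort(pix),
                          mean_dark_rgb = mean_rgb, mean_dark_green = mean_rgb[2])),
                matrix(integer(0), 0, 2), shape)
}

# Random small connected graph for the ERS oracle checks: a random spanning
# tree plus a few extra edges, capped so exhaustive search stays cheap.
random_small_graph <- function(n, max_edges = 9L) {
  perm <- sample(n)
  tree <- cbind(perm[-1], vapply(2:n, function(i)
    perm[sample(i - 1L, 1L)], integer(1)))
  pairs <- t(utils::combn(n, 2))
  key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  extra <- pairs[!(key(pairs) %in% key(tree)), , drop = FALSE]
  n_extra <- sample(0:min(nrow(extra), max_edges - (n - 1L)), 1L)
  if (n_extra > 0)
    tree <- rbind(tree, extra[sample(nrow(extra), n_extra), , drop = FALSE])
  edge_graph(n, tree, stats::runif(nrow(tree), 0.1, 1))
}

# Exhaustive optimum of H + gamma*B over all edge subsets with N_A >= K.
exhaustive_ers_optimum <- function(graph, K, gamma) {
  m <- length(graph$ew)
  best <- -Inf
  for (code in 0:(2^m - 1)) {
    A <- which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) > 0)
    if (retsuperpix:::selection_components(graph, A)$n_components < K) next
    v <- entropy_rate(graph, A) + gamma * balancing_term(graph, A)
    if (v > best) best <- v
  }
  best
}

# Small trained pipeline shared by the pipeline tests.
fix_fit <- function() {
  memo("fit_small", {
    scenes <- lapply(c(0L, 1L, 2L, 3L), fix_scene)
    cfg <- pipeline_config(max_side = 250L)
    fit <- train_pipeline(lapply(scenes, `[[`, "image"),
                          lapply(scenes, `[[`, "gt_lesion_mask"),
                          cfg, seed = 1L,
                          landmarks = lapply(scenes, `[[`, "landmarks"))
    list(fit = fit, cfg = cfg, scenes = scenes)
  })
}

# Constant full-frame image with a full-frame FOV (D chosen so the circle
# area matches the frame, satisfying the geometry validation).
const_frame <- function(n = 160L, rgb = c(0.7, 0.4, 0.25)) {
  a <- array(0, c(n, n, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  list(image = fundus_image(a),
       fov = fov_geometry((n - 1) / 2, (n - 1) / 2, 2 * n / sqrt(pi),
                          matrix(TRUE, n, n)))
}

# Exact circular FOV strictly inside the painted disc of flat_fundus().
exact_fov <- function(n = 120L, fov_frac = 0.45, shrink = 2) {
  r <- fov_frac * n - shrink
  fov_geometry((n - 1) / 2, (n - 1) / 2, 2 * r,
               retsuperpix:::circle_mask(n, n, (n - 1) / 2, (n - 1) / 2, r))
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- abs(((a - b + pi) %% (2 * pi)) - pi)
  expect_lt(d, tol)
}
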