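test_that("symmetrical uncertainty matches its information-theoretic limits", {
  set.seed(11)
  x <- rnorm(300)
  expect_equal(symmetrical_uncertainty(x, x), 1)
  # deterministic bijection between binary variables
  xb <- rep(c(0, 1), each = 50)
  expect_equal(symmetrical_uncertainty(xb, 1 - xb), 1)
  # exact independent uniform joint over 4 x 4 symbols
  joint <- expand.grid(a = 1:4, b = 1:4)
  expect_equal(symmetrical_uncertainty(rep(joint$a, 5), rep(joint$b, 5)), 0)
  # symmetry and bounds over random pairs
  for (i in 1:25) {
    a <- rnorm(60); b <- rnorm(60)
    s1 <- symmetrical_uncertainty(a, b); s2 <- symmetrical_uncertainty(b, a)
    expect_equal(s1, s2)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
  expect_equal(symmetrical_uncertainty(rep(1, 10), rep(2, 10)), 0)
  expect_error(symmetrical_uncertainty(1:5, 1:6), "length")
})

test_that("FCBF keeps the class variable and discards copies and noise", {
  set.seed(1)
  y <- rep(0:1, each = 50)
  X <- cbind(X1 = y, X2 = y, X3 = rnorm(100))
  sel <- fcbf_select(X, y)
  expect_equal(sel$indices, 1L)
  expect_true(all(diff(sel$su_with_target) <= 0))

  # threshold above the maximum SU empties the selection, with a warning
  expect_warning(s2 <- fcbf_select(X, y, delta = 1.1), "empty")
  expect_length(s2$indices, 0)

  # duplicating an already-selected feature never changes the selection
  d <- generate_feature_dataset(200, 2, 0, 4, effect_size = 2, seed = 3)
  base <- fcbf_select(d$X, d$y)
  dup <- cbind(d$X, d$X[, base$indices[1], drop = FALSE])
  again <- fcbf_select(dup, d$y)
  expect_setequal(again$indices[again$indices <= ncol(d$X)], base$indices)
  expect_false(ncol(dup) %in% again$indices)

  expect_error(fcbf_select(d$X, rep(1, 200)), "class")
})

test_that("feature normalization is an exact, reusable affine map", {
  set.seed(4)
  X <- cbind(matrix(rnorm(60, 5, 3), 20), const = rep(2, 20))
  expect_warning(nf <- normalize_features(X), "zero-variance")
  expect_equal(ncol(nf$values), 3L)
  expect_lt(max(abs(colMeans(nf$values))), 1e-9)
  expect_lt(max(abs(apply(nf$values, 2, sd) - 1)), 1e-9)
  # reusing the stats reproduces training-mode output exactly
  again <- normalize_features(X, nf$stats)
  expect_equal(again$values, nf$values)
  # affine inverse recovers the inputs
  rec <- sweep(sweep(nf$values, 2, nf$stats$sd, "*"), 2, nf$stats$mean, "+")
  expect_equal(rec, X[, nf$stats$keep], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("backpropagation gradients match finite differences", {
  set.seed(8)
  X <- matrix(rnorm(60), 15, 4); y <- rep(0:1, length.out = 15)
  th <- rnorm(4 * 6 + 6 + 6 + 1, 0, 0.4)
  for (ups in c(0, 0.6, 1)) {
    g <- retsuperpix:::mlp_gradient(th, X, y, 6L, ups)
    gn <- vapply(seq_along(th), function(i) {
      e <- 1e-6; tp <- th; tm <- th; tp[i] <- tp[i] + e; tm[i] <- tm[i] - e
      (retsuperpix:::mlp_objective(tp, X, y, 6L, ups) -
         retsuperpix:::mlp_objective(tm, X, y, 6L, ups)) / (2 * e)
    }, numeric(1))
    expect_lt(max(abs(g - gn)), 1e-7)
  }
})

test_that("the regularized MLP trains, regularizes and reproduces", {
  d <- generate_feature_dataset(400, 2, 0, 0, effect_size = 4, seed = 0)
  m <- train_mlp(d$X, d$y, n_hid = 30L, upsilon = 0.6, seed = 1L)
  acc <- mean((predict_proba(m, d$X) > 0.5) == (d$y == 1))
  expect_gte(acc, 0.95)

  # pure penalty: weights shrink, predictions collapse to 1/2
  m1 <- train_mlp(d$X, d$y, 30L, 1, seed = 1L)
  expect_lt(mean(m1$theta^2), 1e-4)
  expect_lt(max(abs(predict_proba(m1, d$X) - 0.5)), 0.01)

  # determinism under a fixed seed
  m2 <- train_mlp(d$X, d$y, 30L, 0.6, seed = 1L)
  expect_identical(m$theta, m2$theta)

  expect_error(train_mlp(d$X, rep(1, nrow(d$X)), 30L, 0.6, 1L), "single class")

  # probabilities live strictly inside (0,1) and ignore row order
  p <- predict_proba(m, d$X)
  expect_true(all(p > 0 & p < 1))
  perm <- sample(nrow(d$X))
  expect_equal(predict_proba(m, d$X[perm, ]), p[perm])
  expect_error(predict_proba(m, d$X[, 1, drop = FALSE]), "dimension")
})

test_that("the model JSON round trip preserves predictions", {
  d <- generate_feature_dataset(100, 2, 0, 1, effect_size = 3, seed = 5)
  m <- train_mlp(d$X, d$y, 5L, 0.4, seed = 2L)
  path <- tempfile(fileext = ".json")
  write_mlp_json(m, path, extra = list(note = "fit"))
  back <- read_mlp_json(path)
  expect_equal(predict_proba(back$model, d$X), predict_proba(m, d$X),
               tolerance = 1e-12)
  expect_equal(back$note, "fit")
})

test_that("class rebalancing is seed-deterministic and balanced", {
  y <- c(rep(0, 80), rep(1, 20))
  i1 <- balance_undersample(y, seed = 7L)
  i2 <- balance_undersample(y, seed = 7L)
  expect_identical(i1, i2)
  expect_equal(unname(table(y[i1])), c(20L, 20L), ignore_attr = TRUE)
  expect_false(identical(i1, balance_undersample(y, seed = 8L)))
})

test_that("stratified cross-validation partitions samples and picks a cell", {
  d <- generate_feature_dataset(160, 2, 0, 2, effect_size = 3, seed = 1)
  cv <- cross_validate_grid(d$X, d$y, n_hid_grid = 5L, upsilon_grid = 0.4,
                            folds = 4L, seed = 2L, max_epochs = 80L)
  expect_equal(nrow(cv$grid), 1L)
  expect_equal(cv$best, 1L)
  expect_gte(cv$grid$acc[1], 0.9)
  expect_error(cross_validate_grid(d$X[1:12, ], d$y[1:12], 5L, 0.4,
                                   folds = 10L), "folds")
})

test_that("FCBF + MLP recover planted signal far above a permuted control", {
  accs <- matrix(NA_real_, 6, 2)
  for (s in 1:6) {
    d <- generate_feature_dataset(300, 5, 0, 8, effect_size = 1.5, seed = s)
    tr <- seq_len(200); te <- 201:300
    run <- function(y) {
      sel <- fcbf_select(d$X[tr, ], y[tr])
      if (length(sel$indices) == 0) return(0.5)
      m <- train_mlp(d$X[tr, sel$indices, drop = FALSE], y[tr], 10L, 0.6,
                     seed = s, max_epochs = 200L)
      mean((predict_proba(m, d$X[te, sel$indices, drop = FALSE]) > 0.5) ==
             (y[te] == 1))
    }
    accs[s, 1] <- run(d$y)
    yperm <- retsuperpix:::with_seed(1000 + s, sample(d$y))
    accs[s, 2] <- run(yperm)
  }
  expect_gte(mean(accs[, 1]) - mean(accs[, 2]), 0.3)
})
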