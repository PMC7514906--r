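# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Equal-frequency discretization used by the information measures; inputs
# with at most `bins` distinct values are taken as categories directly.
discretize_ef <- function(x, bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 3L) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

# Largest bin count in 3..10 whose plug-in MI bias (bins-1)^2/(2n) nats
# stays below 5% of the marginal entropy log(bins).
su_default_bins <- function(n) {
  ok <- which((((3:10) - 1)^2 / (2 * n)) <= 0.05 * log(3:10))
  if (length(ok) == 0L) 3L else (3:10)[max(ok)]
}

shannon_H <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Symmetrical uncertainty between two variables
#'
#' Normalized mutual information
#' `SU(X, Y) = 2 * (H(X) - H(X|Y)) / (H(X) + H(Y))`, in `[0, 1]`: 0 for
#' independent variables, 1 for a deterministic one-to-one relation.
#' Continuous inputs are discretized into equal-frequency bins first; by
#' default the bin count adapts to the sample size: the plug-in
#' mutual-information estimate carries a positive bias of roughly
#' `(bins - 1)^2 / (2n)` nats, so the largest count in 3..10 is chosen for
#' which that bias stays below 5% of the marginal entropy `log(bins)` —
#' with a fixed fine binning and few samples, two independent continuous
#' variables would otherwise appear substantially dependent.
#' Returns 0 when both entropies vanish (two constants share no
#' information).
#'
#' @param x,y numeric vectors of equal length (>= 2); either may already be
#'   discrete.
#' @param bins number of equal-frequency bins for continuous inputs;
#'   `NULL` (default) applies the bias-bounded rule above.
#' @return scalar in `[0, 1]`.
#' @export
symmetrical_uncertainty <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("symmetrical_uncertainty: length mismatch")
  stopifnot(length(x) >= 2L)
  if (is.null(bins)) bins <- su_default_bins(length(x))
  xd <- discretize_ef(x, bins)
  yd <- discretize_ef(y, bins)
  joint <- table(xd, yd)
  hx <- shannon_H(rowSums(joint))
  hy <- shannon_H(colSums(joint))
  if (hx + hy == 0) return(0)
  hxy <- shannon_H(as.vector(joint))
  ig <- hx + hy - hxy                    # = H(X) - H(X|Y)
  max(0, min(1, 2 * ig / (hx + hy)))
}

#' Fast correlation-based filter feature selection
#'
#' Two stages: (1) relevance — features are ranked by symmetrical
#' uncertainty (SU) with the class and those with `SU <= delta` dropped;
#' (2) redundancy — walking down the ranking, every remaining feature
#' `X_j` is removed if some retained higher-ranked `X_i` has
#' `SU(X_i, X_j) >= SU(X_j, Y)` (the feature tells us more about an
#' already-kept feature than about the class).
#'
#' @param X a [feature_matrix] or plain numeric matrix.
#' @param y binary 0/1 labels.
#' @param delta relevance threshold (default 0: keep all `SU > 0`).
#' @param bins discretization bins for SU (`NULL`: sample-size adaptive,
#'   see [symmetrical_uncertainty]).
#' @return A `selected_features` object: `indices` (original column
#'   indices, ordered by decreasing SU), `su_with_target`, `bins`.
#' @export
fcbf_select <- function(X, y, delta = 0, bins = NULL) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  stopifnot(length(y) == nrow(vals), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L || min(table(y)) < 2L)
    stop("fcbf_select: need at least 2 samples per class")
  p <- ncol(vals)
  su_y <- vapply(seq_len(p), function(j)
    symmetrical_uncertainty(vals[, j], y, bins), numeric(1))
  ord <- order(su_y, decreasing = TRUE)
  ord <- ord[su_y[ord] > delta]
  if (length(ord) == 0L) {
    warning("fcbf_select: no feature has SU above delta; empty selection")
    return(structure(list(indices = integer(0), su_with_target = numeric(0),
                          bins = if (is.null(bins)) NA_integer_ else bins),
                     class = "selected_features"))
  }
  keep <- logical(p)
  remaining <- ord
  while (length(remaining) > 0L) {
    i <- remaining[1]
    keep[i] <- TRUE
    remaining <- remaining[-1]
    if (length(remaining) > 0L) {
      red <- vapply(remaining, function(j)
        symmetrical_uncertainty(vals[, i], vals[, j], bins) >= su_y[j],
        logical(1))
      remaining <- remaining[!red]
    }
  }
  sel <- ord[keep[ord]]
  structure(list(indices = sel, su_with_target = su_y[sel],
                 bins = if (is.null(bins)) NA_integer_ else bins),
            class = "selected_features")
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("selected_features: %d features (SU %.3f .. %.3f)\n",
              length(x$indices),
              if (length(x$indices)) max(x$su_with_target) else NA,
              if (length(x$indices)) min(x$su_with_target) else NA))
  invisible(x)
}

#' Z-score normalization of a feature matrix
#'
#' Training mode (no `stats`): each column is centered and scaled to mean 0,
#' standard deviation 1; zero-variance columns are dropped with a warning.
#' Prediction mode: the provided training statistics are applied.
#'
#' @param X numeric matrix (or [feature_matrix]).
#' @param stats optional list with `mean`, `sd`, `keep` from a previous
#'   training-mode call.
#' @return list with `values` (normalized matrix) and `stats`.
#' @export
normalize_features <- function(X, stats = NULL) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  if (is.null(stats)) {
    mu <- colMeans(vals)
    sdv <- apply(vals, 2, stats::sd)
    keep <- sdv > 0
    if (!all(keep))
      warning(sprintf("normalize_features: dropping %d zero-variance column(s)",
                      sum(!keep)))
    stats <- list(mean = mu[keep], sd = sdv[keep], keep = which(keep))
  }
  v <- vals[, stats$keep, drop = FALSE]
  v <- sweep(sweep(v, 2, stats$mean, "-"), 2, stats$sd, "/")
  list(values = v, stats = stats)
}

# ---- multilayer perceptron ------------------------------------------------

sigmoid <- function(a) 1 / (1 + exp(-a))

mlp_unpack <- function(theta, d, nh) {
  i1 <- nh * d
  list(W1 = matrix(theta[seq_len(i1)], nh, d),
       b1 = theta[i1 + seq_len(nh)],
       W2 = theta[i1 + nh + seq_len(nh)],
       b2 = theta[i1 + 2 * nh + 1])
}

mlp_forward <- function(theta, X, nh) {
  w <- mlp_unpack(theta, ncol(X), nh)
  Z <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  p <- sigmoid(as.vector(Z %*% w$W2) + w$b2)
  list(Z = Z, p = p, w = w)
}

# E = (1 - upsilon) * mean cross-entropy + upsilon * mean(theta^2)
mlp_objective <- function(theta, X, y, nh, upsilon) {
  f <- mlp_forward(theta, X, nh)
  p <- pmin(1 - 1e-12, pmax(1e-12, f$p))
  ce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  (1 - upsilon) * ce + upsilon * mean(theta^2)
}

mlp_gradient <- function(theta, X, y, nh, upsilon) {
  n <- nrow(X)
  f <- mlp_forward(theta, X, nh)
  d_a2 <- (f$p - y) / n                       # d(mean CE)/d pre-activation
  gW2 <- as.vector(t(f$Z) %*% d_a2)
  gb2 <- sum(d_a2)
  d_z <- outer(d_a2, f$w$W2) * (1 - f$Z^2)
  gW1 <- t(d_z) %*% X
  gb1 <- colSums(d_z)
  gdata <- c(as.vector(gW1), gb1, gW2, gb2)
  (1 - upsilon) * gdata + upsilon * 2 * theta / length(theta)
}

# Moller's scaled conjugate gradient minimizer (no line searches).
scg_minimize <- function(theta, fn, gr, max_epochs = 500L, grad_tol = 1e-6) {
  nw <- length(theta)
  lambda <- 1e-6; lambda_bar <- 0
  f <- fn(theta)
  r <- -gr(theta)
  p <- r
  success <- TRUE
  delta <- 0; mu <- 0
  for (k in seq_len(max_epochs)) {
    if (sqrt(sum(r^2)) < grad_tol) break
    p2 <- sum(p^2)
    if (success) {
      sigma <- 1e-6 / sqrt(max(p2, 1e-300))
      s <- (-(-gr(theta + sigma * p)) - (-r)) / sigma   # (g(theta+sp) - g(theta))/s
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    f_new <- fn(theta + alpha * p)
    Delta <- 2 * delta * (f - f_new) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- theta + alpha * p
      r_new <- -gr(theta)
      lambda_bar <- 0
      success <- TRUE
      f <- f_new
      if (k %% nw == 0) {
        p <- r_new
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (!is.finite(lambda) || lambda > 1e100) lambda <- 1e100
  }
  list(theta = theta, value = f, epochs = k)
}

#' Train the candidate-classifying multilayer perceptron
#'
#' A 3-layer network — tanh hidden units, one logistic output read as a
#' posterior probability — trained by scaled conjugate gradient on the
#' regularized objective
#' `E = (1 - upsilon) * cross-entropy + upsilon * mean(weights^2)`.
#' The performance-ratio regularizer penalizes large weights; at
#' `upsilon = 1` the objective is weight decay alone and predictions
#' collapse to 0.5. Inputs are z-scored internally and the statistics are
#' stored in the model for prediction. Weight initialization is uniform in
#' `+/- 1/sqrt(fan-in)`, seeded, so training is reproducible.
#'
#' @param X numeric matrix (or [feature_matrix]) of candidate features.
#' @param y binary 0/1 labels, both classes present.
#' @param n_hid number of hidden units.
#' @param upsilon regularization ratio in `[0, 1]`.
#' @param seed integer RNG seed for the weight initialization.
#' @param max_epochs optimizer iteration cap.
#' @param grad_tol gradient-norm stopping tolerance.
#' @return An `mlp_model`.
#' @export
train_mlp <- function(X, y, n_hid = 30L, upsilon = 0.6, seed = 1L,
                      max_epochs = 500L, grad_tol = 1e-6) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  y <- as.numeric(y)
  stopifnot(n_hid >= 1L, upsilon >= 0, upsilon <= 1)
  if (length(unique(y)) < 2L) stop("train_mlp: labels contain a single class")
  nf <- normalize_features(vals)
  Xn <- nf$values
  d <- ncol(Xn)
  theta0 <- with_seed(seed, {
    c(stats::runif(n_hid * d, -1, 1) / sqrt(d),
      stats::runif(n_hid, -1, 1) / sqrt(d),
      stats::runif(n_hid, -1, 1) / sqrt(n_hid),
      stats::runif(1, -1, 1) / sqrt(n_hid))
  })
  opt <- scg_minimize(theta0,
                      fn = function(t) mlp_objective(t, Xn, y, n_hid, upsilon),
                      gr = function(t) mlp_gradient(t, Xn, y, n_hid, upsilon),
                      max_epochs = max_epochs, grad_tol = grad_tol)
  structure(list(theta = opt$theta, input_dim = d, n_hidden = as.integer(n_hid),
                 reg_ratio = upsilon, norm_stats = nf$stats, seed = seed,
                 trained_epochs = opt$epochs, final_objective = opt$value),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d-%d-1 (tanh/logistic), upsilon = %.2f, %d epochs\n",
              x$input_dim, x$n_hidden, x$reg_ratio, x$trained_epochs))
  invisible(x)
}

#' Posterior probabilities from a trained MLP
#'
#' Applies the model's stored normalization and returns the logistic
#' outputs, strictly inside `(0, 1)`; classification downstream thresholds
#' at 0.5.
#'
#' @param model an `mlp_model`.
#' @param X numeric matrix (or [feature_matrix]) with the same columns the
#'   model was trained on.
#' @return numeric vector of probabilities.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  if (!is.matrix(vals)) vals <- matrix(vals, nrow = 1)
  if (ncol(vals) < max(model$norm_stats$keep))
    stop("predict_proba: feature dimension mismatch")
  Xn <- normalize_features(vals, model$norm_stats)$values
  if (ncol(Xn) != model$input_dim) stop("predict_proba: feature dimension mismatch")
  mlp_forward(model$theta, Xn, model$n_hidden)$p
}

#' Seeded class rebalancing by undersampling the majority class
#'
#' @param y binary labels.
#' @param seed RNG seed.
#' @return integer row indices of the balanced subset (sorted).
#' @export
balance_undersample <- function(y, seed = 1L) {
  i0 <- which(y == 0); i1 <- which(y == 1)
  if (length(i0) == length(i1)) return(sort(c(i0, i1)))
  maj <- if (length(i0) > length(i1)) i0 else i1
  mnr <- if (length(i0) > length(i1)) i1 else i0
  keep <- with_seed(seed, sample(maj, length(mnr)))
  sort(c(mnr, keep))
}

#' Stratified k-fold grid search over MLP hyperparameters
#'
#' For every `(n_hid, upsilon)` pair, trains on `folds - 1` stratified
#' folds and evaluates on the held-out fold; reports the mean validation
#' accuracy, sensitivity and specificity per cell. The selected cell
#' maximizes accuracy, ties broken toward the smaller sensitivity /
#' specificity imbalance and then toward fewer hidden units.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param n_hid_grid,upsilon_grid hyperparameter grids.
#' @param folds number of folds.
#' @param seed RNG seed (fold assignment and weight initialization).
#' @param max_epochs optimizer cap per fit.
#' @return A `cv_result`: data frame `grid` (one row per cell with
#'   `acc/se/sp`), `folds`, `best` (row index) and the chosen
#'   `n_hid` / `upsilon`.
#' @export
cross_validate_grid <- function(X, y, n_hid_grid = c(10L, 30L),
                                upsilon_grid = c(0.2, 0.6), folds = 10L,
                                seed = 1L, max_epochs = 200L) {
  vals <- if (inherits(X, "feature_matrix")) X$values else X
  y <- as.numeric(y)
  if (min(table(y)) < folds)
    stop("cross_validate_grid: too few samples per class for stratified folds")
  fold_of <- integer(length(y))
  with_seed(seed, for (cl in c(0, 1)) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  })
  grid <- expand.grid(n_hid = n_hid_grid, upsilon = upsilon_grid)
  grid$acc <- grid$se <- grid$sp <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- ses <- sps <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f
      m <- train_mlp(vals[tr, , drop = FALSE], y[tr], grid$n_hid[g],
                     grid$upsilon[g], seed = seed + f, max_epochs = max_epochs)
      pred <- predict_proba(m, vals[!tr, , drop = FALSE]) > 0.5
      truth <- y[!tr] == 1
      accs[f] <- mean(pred == truth)
      ses[f] <- if (any(truth)) mean(pred[truth]) else NA
      sps[f] <- if (any(!truth)) mean(!pred[!truth]) else NA
    }
    grid$acc[g] <- mean(accs)
    grid$se[g] <- mean(ses, na.rm = TRUE)
    grid$sp[g] <- mean(sps, na.rm = TRUE)
  }
  ord <- order(-grid$acc, abs(grid$se - grid$sp), grid$n_hid)
  structure(list(grid = grid, folds = folds, best = ord[1],
                 n_hid = grid$n_hid[ord[1]], upsilon = grid$upsilon[ord[1]]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d cells, best n_hid = %d, upsilon = %.2f (acc %.3f)\n",
              nrow(x$grid), x$n_hid, x$upsilon, x$grid$acc[x$best]))
  invisible(x)
}

#' Serialize / load an MLP model as JSON
#'
#' @param model an `mlp_model` (plus optional `selected` features and
#'   normalization `targets` stored alongside by the pipeline).
#' @param path JSON path.
#' @param extra named list stored verbatim next to the model.
#' @return `path` (write) / list with `model` and any extras (read).
#' @export
write_mlp_json <- function(model, path, extra = list()) {
  obj <- c(list(model = unclass(model)), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$model
  m$theta <- as.numeric(m$theta)
  m$norm_stats <- list(mean = as.numeric(m$norm_stats$mean),
                       sd = as.numeric(m$norm_stats$sd),
                       keep = as.integer(m$norm_stats$keep))
  class(m) <- "mlp_model"
  obj$model <- m
  obj
}
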