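test_that("the lattice graph has 8-neighbour structure and Gaussian weights", {
  # 2x2 image: 2 vertical + 2 horizontal + 2 diagonal edges
  g <- build_lattice_graph(array(0.5, c(2, 2, 3)), sigma = 2)
  expect_equal(length(g$ew), 6L)
  expect_true(all(abs(g$ew - 1) < 1e-12))      # constant image -> w = 1
  expect_equal(g$total_weight, 2 * sum(g$ew))
  # vertex strengths equal the sum of incident weights
  wi <- numeric(g$n_vertices)
  for (k in seq_along(g$ew)) {
    wi[g$ei[k]] <- wi[g$ei[k]] + g$ew[k]
    wi[g$ej[k]] <- wi[g$ej[k]] + g$ew[k]
  }
  expect_equal(wi, g$wi)

  # weights respond to intensity difference and spatial distance
  v <- array(0, c(2, 2, 3)); v[1, 1, ] <- 20 / 255
  g2 <- build_lattice_graph(v, sigma = 2)
  dpair <- function(i, j) g2$ew[g2$ei == i & g2$ej == j]
  expect_equal(dpair(1, 2), exp(-(3 * 20^2) / 4))          # axial
  expect_equal(dpair(1, 4), exp(-(3 * 20^2) * 2 / 4))      # diagonal
  expect_error(build_lattice_graph(v, sigma = 0), "sigma")
})

test_that("entropy rate and balancing match their defining formulas", {
  g <- edge_graph(2L, matrix(c(1, 2), 1), 1)
  expect_equal(entropy_rate(g, integer(0)), 0)
  # one unit edge on two vertices: each row becomes deterministic -> H = 0
  expect_equal(entropy_rate(g, 1L), 0)
  # hand-expanded value for a weighted pair
  g2 <- edge_graph(2L, matrix(c(1, 2), 1), 0.6)
  # wi = c(0.6, 0.6); p12 = 1, loop 0 -> H = 0 as well
  expect_equal(entropy_rate(g2, 1L), 0)
  # 3-vertex path, unequal weights: evaluate one row by hand
  g3 <- edge_graph(3L, rbind(c(1, 2), c(2, 3)), c(0.5, 0.25))
  # select edge (1,2): w1=0.5, w2=0.75, w3=0.25, total=1.5
  # row1: p=1 -> 0;  row2: p21=0.5/0.75, loop=1/3
  h2 <- -( (0.5 / 0.75) * log(0.5 / 0.75) + (1 / 3) * log(1 / 3) )
  expect_equal(entropy_rate(g3, 1L), (0.75 / 1.5) * h2 + 0)

  n <- 5L
  g5 <- edge_graph(n, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)), rep(1, 4))
  expect_equal(balancing_term(g5, integer(0)), log(n) - n)
  expect_equal(balancing_term(g5, 1:4), -1)          # single component
  g4 <- edge_graph(4L, rbind(c(1, 2), c(3, 4)), c(1, 1))
  expect_equal(balancing_term(g4, 1:2), log(2) - 2)  # two equal pairs
})

test_that("adding an inter-component edge never decreases the entropy rate", {
  set.seed(101)
  for (rep in 1:20) {
    g <- random_small_graph(sample(4:6, 1))
    m <- length(g$ew)
    for (code in sample(0:(2^m - 1), min(40, 2^m))) {
      A <- which(bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) > 0)
      comp <- retsuperpix:::selection_components(g, A)$component_of
      h0 <- entropy_rate(g, A)
      for (e in setdiff(seq_len(m), A)) {
        if (comp[g$ei[e]] != comp[g$ej[e]])
          expect_gte(entropy_rate(g, c(A, e)), h0 - 1e-12)
      }
    }
  }
})

test_that("the balancing weight is the single-edge gain ratio", {
  g <- edge_graph(3L, rbind(c(1, 2), c(2, 3)), c(1, 1))
  bw <- balance_weight(g, K = 2, lam = 0.08)
  # brute force over the two single-edge selections
  dH <- vapply(1:2, function(e) entropy_rate(g, e), numeric(1))
  dB <- vapply(1:2, function(e) balancing_term(g, e), numeric(1)) -
    balancing_term(g, integer(0))
  expect_equal(bw$beta, max(dH) / max(dB))
  expect_equal(bw$gamma, bw$beta * 2 * 0.08)
  expect_equal(balance_weight(g, 2, 0)$gamma, 0)
  expect_equal(balance_weight(g, 10, 0.08)$gamma, 5 * bw$gamma)
})

test_that("greedy segmentation matches structure and is deterministic", {
  # K = n: identity partition
  img <- array(0.4, c(4, 4, 3))
  lm <- ers_segment(img, K = 16, lam = 0.08, sigma = 2)
  expect_equal(sort(unique(as.vector(lm$labels))), 1:16)
  expect_equal(max(tabulate(lm$labels)), 1L)

  # two-half image: exact optimal 2-partition
  half <- array(0, c(8, 8, 3)); half[, 5:8, ] <- 200 / 255
  lm2 <- ers_segment(half, K = 2, lam = 0.08, sigma = 2)
  expect_true(all(lm2$labels[, 1:4] == lm2$labels[1, 1]))
  expect_true(all(lm2$labels[, 5:8] == lm2$labels[1, 5]))
  expect_false(lm2$labels[1, 1] == lm2$labels[1, 5])

  set.seed(9)
  noisy <- array(runif(16 * 16 * 3, 0, 0.4), c(16, 16, 3))
  a <- ers_segment(noisy, K = 12, lam = 0.08, sigma = 2)
  b <- ers_segment(noisy, K = 12, lam = 0.08, sigma = 2)
  expect_identical(a$labels, b$labels)
  expect_error(ers_segment(noisy, K = 0), "K")
  expect_error(ers_segment(noisy, K = 10000), "K")
})

test_that("every superpixel is an 8-connected region", {
  set.seed(13)
  noisy <- array(runif(20 * 20 * 3, 0, 0.5), c(20, 20, 3))
  lm <- ers_segment(noisy, K = 15, lam = 0.08, sigma = 2)
  for (k in seq_len(lm$K)) {
    m <- lm$labels == k
    expect_equal(max(label_components8(m)), 1)
  }
})

test_that("incremental greedy gains equal full objective re-evaluations", {
  set.seed(42)
  for (rep in 1:15) {
    g <- random_small_graph(sample(4:6, 1))
    K <- sample(1:3, 1)
    res <- ers_greedy(g, K, lam = 0.08, trace = TRUE)
    expect_equal(res$n_components, K)
    prev <- entropy_rate(g, integer(0)) +
      res$gamma * balancing_term(g, integer(0))
    for (t in seq_along(res$selected)) {
      A <- res$selected[seq_len(t)]
      obj <- entropy_rate(g, A) + res$gamma * balancing_term(g, A)
      expect_equal(obj - prev, res$dH[t] + res$gamma * res$dB[t],
                   tolerance = 1e-9)
      prev <- obj
    }
    expect_true(all(res$dH >= -1e-12))   # H monotone along the greedy path
  }
})

test_that("balancing produces even sizes on constant images when it dominates", {
  lm <- ers_segment(array(0.5, c(32, 32, 3)), K = 16, lam = 0.5, sigma = 2)
  sz <- tabulate(lm$labels)
  expect_lte(max(sz) / min(sz), 4)
})
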