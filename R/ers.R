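#' Similarity graph over the darkness map
#'
#' Builds the 8-connected pixel lattice graph whose edge weights are
#' Gaussian similarities of the 3-channel darkness values:
#' `w_ij = exp(-d(v_i, v_j)^2 / (2 * sigma))`, where `d` is the Euclidean
#' distance of the two pixels' darkness triples on a 0-255 scale multiplied
#' by their spatial distance (1 for axial, sqrt(2) for diagonal
#' neighbours). The 0-255 intensity scale makes the default bandwidth
#' `sigma = 2` meaningful. Weights are floored at 1e-12 so every vertex
#' keeps strictly positive strength.
#'
#' @param idark a `darkness_map` (or a plain `H x W (x 3)` array in
#'   `[0, 1]`, taken as-is).
#' @param sigma Gaussian kernel bandwidth, > 0.
#' @return A `similarity_graph`: list with 1-based edge endpoints `ei`,
#'   `ej` (column-major pixel indices), weights `ew`, vertex strengths
#'   `wi`, `n_vertices`, `total_weight`, `sigma`, and the lattice `dim`.
#' @export
build_lattice_graph <- function(idark, sigma = 2) {
  if (sigma <= 0) stop("build_lattice_graph: sigma must be > 0")
  v <- if (inherits(idark, "darkness_map")) idark$values else idark
  if (is.matrix(v)) v <- array(rep(v, 3L), c(dim(v), 3L))
  stopifnot(length(dim(v)) == 3L, dim(v)[3] == 3L)
  g <- cpp_lattice_graph(as.numeric(v), nrow(v), ncol(v), sigma)
  g$ei <- g$ei + 1L
  g$ej <- g$ej + 1L
  g$dim <- dim(v)[1:2]
  class(g) <- "similarity_graph"
  g
}

#' Arbitrary-graph constructor (testing and small-scale analysis)
#'
#' Wraps an explicit edge list as a `similarity_graph` so the entropy-rate
#' machinery can run on non-lattice graphs.
#'
#' @param n number of vertices.
#' @param edges `m x 2` integer matrix of 1-based endpoints.
#' @param weights positive edge weights in `(0, 1]`.
#' @return A `similarity_graph` (without a lattice `dim`).
#' @export
edge_graph <- function(n, edges, weights) {
  stopifnot(nrow(edges) == length(weights), all(weights > 0),
            all(edges >= 1), all(edges <= n))
  wi <- numeric(n)
  for (k in seq_along(weights)) {
    wi[edges[k, 1]] <- wi[edges[k, 1]] + weights[k]
    wi[edges[k, 2]] <- wi[edges[k, 2]] + weights[k]
  }
  structure(list(ei = as.integer(edges[, 1]), ej = as.integer(edges[, 2]),
                 ew = as.numeric(weights), wi = wi, n_vertices = n,
                 total_weight = sum(wi), sigma = NA_real_, dim = NULL),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d vertices, %d edges, sigma = %s\n",
              as.integer(x$n_vertices), length(x$ew), format(x$sigma)))
  invisible(x)
}

# Connected components of the subgraph (V, A); A = indices into the edge
# list. Used by the from-scratch objective evaluators and the tests.
selection_components <- function(graph, A) {
  n <- as.integer(graph$n_vertices)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in A) {
    ra <- find(graph$ei[e]); rb <- find(graph$ej[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp <- match(roots, unique(roots))
  list(component_of = comp, n_components = max(comp),
       component_sizes = tabulate(comp))
}

xlogx <- function(t) ifelse(t <= 0, 0, t * log(t))

#' Entropy rate of a random walk restricted to selected edges
#'
#' Full (non-incremental) evaluation of
#' `H(A) = -sum_i mu_i sum_j p_ij log p_ij`, with stationary distribution
#' `mu_i = w_i / sum(w)` and transitions `p_ij = w_ij / w_i` over selected
#' edges, the remaining mass `1 - sum_A w_ij / w_i` sitting on the implicit
#' self-loop. Natural logarithm; `0 log 0 = 0`. Selecting more edges moves
#' loop mass onto real transitions and never decreases `H`.
#'
#' @param graph a `similarity_graph`.
#' @param A integer vector of selected edge indices (possibly empty).
#' @return The entropy rate (scalar, >= 0).
#' @export
entropy_rate <- function(graph, A = integer(0)) {
  n <- as.integer(graph$n_vertices)
  mu <- graph$wi / graph$total_weight
  rowH <- numeric(n)
  loop <- rep(1, n)
  for (e in A) {
    i <- graph$ei[e]; j <- graph$ej[e]
    ci <- graph$ew[e] / graph$wi[i]; cj <- graph$ew[e] / graph$wi[j]
    rowH[i] <- rowH[i] - xlogx(ci); loop[i] <- loop[i] - ci
    rowH[j] <- rowH[j] - xlogx(cj); loop[j] <- loop[j] - cj
  }
  rowH <- rowH - xlogx(pmax(0, loop))
  sum(mu * rowH)
}

#' Balancing function of a selection
#'
#' `B(A) = -sum_i p_Z(i) log p_Z(i) - N_A`, where `p_Z(i) = |S_i| / |V|`
#' is the cluster-size distribution and `N_A` the number of connected
#' components. Favors many similarly sized clusters: the entropy term
#' rewards balance, the `-N_A` term rewards merging.
#'
#' @inheritParams entropy_rate
#' @return The balancing value (scalar).
#' @export
balancing_term <- function(graph, A = integer(0)) {
  cs <- selection_components(graph, A)
  p <- cs$component_sizes / graph$n_vertices
  -sum(xlogx(p)) - cs$n_components
}

#' Weight of the balancing term
#'
#' `gamma = beta * K * lambda`, where `beta` is the ratio of the maximal
#' single-edge entropy-rate gain to the maximal single-edge balancing gain
#' from the empty selection — it compensates the different magnitudes of
#' the two objective parts.
#'
#' @param graph a `similarity_graph`.
#' @param K target number of superpixels.
#' @param lam balancing strength, user-set, >= 0.
#' @return list with `gamma` and `beta`.
#' @export
balance_weight <- function(graph, K, lam) {
  stopifnot(K >= 1, lam >= 0)
  n <- graph$n_vertices
  if (n < 2 || length(graph$ew) == 0)
    stop("balance_weight: graph must have at least one edge")
  mu_i <- graph$wi[graph$ei] / graph$total_weight
  mu_j <- graph$wi[graph$ej] / graph$total_weight
  ci <- graph$ew / graph$wi[graph$ei]
  cj <- graph$ew / graph$wi[graph$ej]
  dH <- mu_i * (-xlogx(ci) - xlogx(1 - ci)) + mu_j * (-xlogx(cj) - xlogx(1 - cj))
  dB <- xlogx(1 / n) + xlogx(1 / n) - xlogx(2 / n) + 1   # same for every edge
  stopifnot(dB > 0)
  beta <- max(dH) / dB
  list(gamma = beta * K * lam, beta = beta)
}

#' Superpixel label map
#'
#' @param labels `H x W` integer matrix with values `1..K`.
#' @param K number of superpixels.
#' @return A `label_map`.
#' @export
label_map <- function(labels, K) {
  stopifnot(is.matrix(labels), max(labels) == K, min(labels) >= 1L)
  structure(list(labels = labels, K = as.integer(K)), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d, K = %d\n", nrow(x$labels), ncol(x$labels), x$K))
  invisible(x)
}

#' Entropy-rate superpixel segmentation
#'
#' Greedy maximization of `H(A) + gamma * B(A)`: starting from the empty
#' selection (every pixel its own component), the inter-component edge with
#' the largest objective gain is added repeatedly — lazy re-evaluation on a
#' max-heap, components tracked by union-find, ties broken toward the
#' lowest edge index — until exactly `K` components remain. Both gain terms
#' are submodular, so stale heap entries are upper bounds and the lazy
#' scheme reproduces exact greedy.
#'
#' @param idark a `darkness_map` (or array; see [build_lattice_graph]).
#' @param K target number of superpixels (1 to number of pixels).
#' @param lam balancing strength lambda.
#' @param sigma Gaussian kernel bandwidth.
#' @param trace if `TRUE`, attach per-merge `dH`/`dB` gain traces.
#' @return A `label_map` with exactly `K` 8-connected components; with
#'   `trace`, attributes `dH` and `dB`.
#' @export
ers_segment <- function(idark, K = 2000L, lam = 0.08, sigma = 2, trace = FALSE) {
  g <- build_lattice_graph(idark, sigma)
  res <- ers_greedy(g, K, lam, trace)
  lm <- label_map(matrix(res$labels, g$dim[1], g$dim[2]), res$n_components)
  if (trace) { attr(lm, "dH") <- res$dH; attr(lm, "dB") <- res$dB }
  lm
}

#' Greedy edge selection on an explicit graph
#'
#' The segmentation engine behind [ers_segment], exposed for non-lattice
#' graphs.
#'
#' @param graph a `similarity_graph`.
#' @param K target component count.
#' @param lam balancing strength.
#' @param trace keep per-merge gain traces.
#' @return list with `labels` (per-vertex component id, 1..K),
#'   `n_components`, `selected` (1-based indices of accepted edges in
#'   acceptance order), `gamma`, and optionally `dH`, `dB`.
#' @export
ers_greedy <- function(graph, K, lam = 0.08, trace = FALSE) {
  n <- as.integer(graph$n_vertices)
  if (K < 1 || K > n) stop("ers_greedy: K out of range")
  gamma <- if (K == n) 0 else balance_weight(graph, K, lam)$gamma
  res <- cpp_ers_greedy(graph$ei - 1L, graph$ej - 1L, graph$ew, graph$wi,
                        graph$total_weight, gamma, n, as.integer(K), trace)
  res$selected <- res$selected + 1L
  res$gamma <- gamma
  res
}
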