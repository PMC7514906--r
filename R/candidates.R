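#' Red-lesion candidate set
#'
#' Surviving superpixels after darkness thresholding, with their pixel
#' sets, mean darkness colors and the adjacency structure among them.
#'
#' @param candidates list of candidates; each has `label_id`,
#'   `pixel_indices` (linear, column-major), `mean_dark_rgb`,
#'   `mean_dark_green`.
#' @param adjacency 2-column integer matrix of adjacent candidate pairs
#'   (indices into `candidates`, symmetric pairs stored once).
#' @param source_shape `c(H, W)` of the source image.
#' @return A `candidate_set`.
#' @export
candidate_set <- function(candidates, adjacency, source_shape) {
  structure(list(candidates = candidates, adjacency = adjacency,
                 source_shape = as.integer(source_shape)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates, %d adjacent pairs, %d x %d\n",
              length(x$candidates), NROW(x$adjacency),
              x$source_shape[1], x$source_shape[2]))
  invisible(x)
}

#' Number of candidates
#' @param x a `candidate_set`.
#' @return integer count.
#' @export
n_candidates <- function(x) length(x$candidates)

# Adjacency among labeled regions: pairs of labels that touch (8-conn).
label_adjacency <- function(lab) {
  h <- nrow(lab); w <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-h, ]), as.vector(lab[-1, ])),        # vertical
    cbind(as.vector(lab[, -w]), as.vector(lab[, -1])),        # horizontal
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),    # diag \
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))    # diag /
  pairs <- pairs[pairs[, 1] != pairs[, 2] & pairs[, 1] > 0 & pairs[, 2] > 0,
                 , drop = FALSE]
  if (nrow(pairs) == 0L) return(matrix(integer(0), 0, 2))
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

#' Reduce superpixels to dark candidates
#'
#' Keeps exactly the superpixels whose mean green-channel darkness exceeds
#' `tau` (strict: a mean of exactly `tau` is removed). Darkness scores high
#' for dark pixels, so this coarsely discards every superpixel that is
#' clearly not a dark structure.
#'
#' @param labels a `label_map` from [ers_segment].
#' @param idark the matching `darkness_map`.
#' @param tau darkness threshold; default 0.3.
#' @return A [candidate_set] (possibly empty) with adjacency among the
#'   survivors.
#' @export
reduce_candidates <- function(labels, idark, tau = 0.3) {
  stopifnot(inherits(labels, "label_map"), inherits(idark, "darkness_map"))
  lab <- labels$labels
  v <- idark$values
  stopifnot(all(dim(lab) == dim(v)[1:2]))
  idx <- as.integer(lab)
  K <- labels$K
  npx <- tabulate(idx, K)
  mg <- unname(rowsum(as.vector(v[, , 2]), idx)[, 1]) / npx
  keep <- unname(which(mg > tau))
  if (length(keep) == 0L)
    return(candidate_set(list(), matrix(integer(0), 0, 2), dim(lab)))

  mr <- unname(rowsum(as.vector(v[, , 1]), idx)[, 1]) / npx
  mb <- unname(rowsum(as.vector(v[, , 3]), idx)[, 1]) / npx
  pix <- split(seq_along(idx), idx)           # names are label ids
  cands <- lapply(keep, function(k) list(
    label_id = k,
    pixel_indices = pix[[as.character(k)]],
    mean_dark_rgb = unname(c(mr[k], mg[k], mb[k])),
    mean_dark_green = unname(mg[k])))

  # adjacency among survivors only
  surv <- integer(K); surv[keep] <- seq_along(keep)
  adj <- label_adjacency(lab)
  adj <- adj[surv[adj[, 1]] > 0 & surv[adj[, 2]] > 0, , drop = FALSE]
  adj <- cbind(surv[adj[, 1]], surv[adj[, 2]])
  candidate_set(cands, adj, dim(lab))
}

# Mean darkness triple (interpreted as sRGB) -> CIELAB rescaled to unit
# ranges: L/100, (a+128)/255, (b+128)/255.  Raw Lab distances would make
# the 0.24 merge threshold nearly inoperative; the unit rescale puts it on
# the intended scale.  D65 white point.
lab_unit <- function(rgb) {
  lab <- grDevices::convertColor(matrix(rgb, ncol = 3), from = "sRGB",
                                 to = "Lab", to.ref.white = "D65")
  cbind(lab[, 1] / 100, (lab[, 2] + 128) / 255, (lab[, 3] + 128) / 255)
}

#' Merge similar neighboring candidates
#'
#' Entropy-rate superpixels often fragment a single structure (a vessel, a
#' large hemorrhage) into several superpixels. Adjacent candidates whose
#' mean darkness colors are close in CIELAB are therefore merged
#' iteratively: the globally closest adjacent pair (Euclidean distance in
#' unit-rescaled Lab) is merged first, means and adjacency are recomputed,
#' and the process repeats while the smallest distance is <= `d_max`.
#'
#' @param cands a [candidate_set].
#' @param idark the matching `darkness_map`.
#' @param d_max maximum Lab distance for a merge; default 0.24.
#' @return A [candidate_set] with merged candidates.
#' @export
merge_candidates <- function(cands, idark, d_max = 0.24) {
  stopifnot(inherits(cands, "candidate_set"))
  nc <- n_candidates(cands)
  if (nc <= 1L) return(cands)
  v <- idark$values
  plane <- prod(dim(v)[1:2])
  sum3 <- function(pixidx) c(sum(v[pixidx]), sum(v[pixidx + plane]),
                             sum(v[pixidx + 2 * plane]))

  pix <- lapply(cands$candidates, `[[`, "pixel_indices")
  sums <- t(vapply(pix, sum3, numeric(3)))
  npx <- vapply(pix, length, integer(1))
  alive <- rep(TRUE, nc)
  # adjacency as an edge set of index pairs (kept symmetric-once)
  adj <- cands$adjacency
  labcol <- lab_unit(sums / npx)

  pair_dist <- function(a, b) sqrt(sum((labcol[a, ] - labcol[b, ])^2))

  repeat {
    if (nrow(adj) == 0L) break
    d <- vapply(seq_len(nrow(adj)),
                function(k) pair_dist(adj[k, 1], adj[k, 2]), numeric(1))
    k <- which.min(d)                    # which.min takes the first = lowest pair
    if (d[k] > d_max) break
    a <- adj[k, 1]; b <- adj[k, 2]       # merge b into a (a < b by construction)
    pix[[a]] <- c(pix[[a]], pix[[b]])
    sums[a, ] <- sums[a, ] + sums[b, ]
    npx[a] <- npx[a] + npx[b]
    labcol[a, ] <- lab_unit(matrix(sums[a, ] / npx[a], 1))
    alive[b] <- FALSE
    adj[adj == b] <- a
    adj <- adj[adj[, 1] != adj[, 2], , drop = FALSE]
    if (nrow(adj)) {
      adj <- cbind(pmin(adj[, 1], adj[, 2]), pmax(adj[, 1], adj[, 2]))
      adj <- unique(adj)
    }
  }

  keep <- which(alive)
  remap <- integer(nc); remap[keep] <- seq_along(keep)
  out <- lapply(keep, function(i) list(
    label_id = cands$candidates[[i]]$label_id,
    pixel_indices = sort(pix[[i]]),
    mean_dark_rgb = sums[i, ] / npx[i],
    mean_dark_green = sums[i, 2] / npx[i]))
  adj2 <- if (nrow(adj)) cbind(remap[adj[, 1]], remap[adj[, 2]]) else adj
  candidate_set(out, adj2, cands$source_shape)
}

#' Binary mask of candidate pixels
#'
#' @param cands a [candidate_set].
#' @param which_cands candidate indices to include (default: all).
#' @return logical `H x W` matrix.
#' @export
candidate_mask <- function(cands, which_cands = seq_along(cands$candidates)) {
  m <- matrix(FALSE, cands$source_shape[1], cands$source_shape[2])
  for (i in which_cands) m[cands$candidates[[i]]$pixel_indices] <- TRUE
  m
}
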