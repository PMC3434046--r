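#' Ortholog graph from called pairs
#'
#' Builds the weighted undirected graph whose nodes are proteins and whose
#' edges are called ortholog pairs, weighted by the pairwise similarity.
#' Edges connect distinct species only, by construction of the pairs.
#'
#' @param calls An [call_orthologs()] result (rows with `is_ortholog = FALSE`
#'   are dropped).
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
ortholog_graph <- function(calls) {
  kept <- dplyr::filter(as_tibble(calls), .data$is_ortholog)
  tibble(from = kept$x, to = kept$y, weight = kept$similarity)
}

#' Markov clustering of a weighted graph
#'
#' A self-contained Markov-clustering (MCL) engine. The weighted adjacency
#' matrix is regularised with self-loops (each node's loop weight is its
#' maximum incident edge weight, 1 for isolated nodes), column-normalised to
#' a stochastic flow matrix, and then alternately *expanded* (matrix
#' squaring, simulating flow) and *inflated* (entrywise power then column
#' renormalisation, strengthening strong currents) with pruning of entries
#' below `prune_threshold`, until the matrix changes by less than `tolerance`
#' or `max_iter` rounds have run. Clusters are read off the attractor rows of
#' the limit matrix; nodes claimed by several overlapping attractor systems
#' are assigned to the cluster whose smallest member id sorts first, so the
#' partition is deterministic.
#'
#' @param graph An edge tibble with columns `from`, `to`, `weight`
#'   (undirected; duplicate edges are an error), e.g. from
#'   [ortholog_graph()]. Weights must be positive.
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param max_iter Maximum expansion/inflation rounds.
#' @param tolerance Convergence threshold on the max entrywise change.
#' @param prune_threshold Entries below this are zeroed after inflation.
#' @param nodes Optional character vector of node ids to cluster (defaults to
#'   the ids appearing in `graph`); extra ids become singleton clusters.
#' @return A tibble with columns `node`, `cluster` (integer labels, numbered
#'   by decreasing cluster size, ties by smallest member id). Attributes
#'   `iterations` (rounds run) and `col_sum_error` (max deviation of the
#'   column sums from 1 seen after any renormalisation).
#' @export
mcl <- function(graph, inflation = 2, max_iter = 100, tolerance = 1e-6,
                prune_threshold = 1e-5, nodes = NULL) {
  if (inflation <= 1) abort("inflation must be > 1")
  if (nrow(graph) > 0 && any(graph$weight <= 0)) {
    abort("edge weights must be positive")
  }
  ids <- sort(unique(c(graph$from, graph$to, nodes)))
  n <- length(ids)
  if (n == 0) {
    return(structure(tibble(node = character(0), cluster = integer(0)),
                     iterations = 0L, col_sum_error = 0))
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph) > 0) {
    if (anyDuplicated(pair_key(graph$from, graph$to))) {
      abort("duplicate edges in the input graph")
    }
    i <- match(graph$from, ids); j <- match(graph$to, ids)
    if (any(i == j)) abort("self-loop edges are not allowed in the input graph")
    A[cbind(i, j)] <- graph$weight
    A[cbind(j, i)] <- graph$weight
  }
  # self-loop regularisation: max incident weight, 1 for isolated nodes
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop

  normalise <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalise(A)
  col_err <- max(abs(colSums(M) - 1))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    E <- M %*% M              # expansion
    E <- E^inflation          # inflation
    E[E < prune_threshold] <- 0
    dead <- colSums(E) == 0   # guard: pruning emptied a column
    if (any(dead)) E[cbind(which(dead), which(dead))] <- 1
    E <- normalise(E)
    col_err <- max(col_err, abs(colSums(E) - 1))
    delta <- max(abs(E - M))
    M <- E
    if (delta < tolerance || iter >= max_iter) break
  }

  part <- clusters_from_limit(M, ids)
  structure(part, iterations = iter, col_sum_error = col_err)
}

# read clusters off the limit matrix: attractor rows (positive diagonal mass)
# span clusters; overlaps resolved toward the cluster with the smallest id.
clusters_from_limit <- function(M, ids) {
  eps <- 1e-9
  attractors <- which(diag(M) > eps)
  supports <- lapply(attractors, function(i) ids[M[i, ] > eps])
  supports <- unique(supports)
  assignment <- setNames(rep(NA_character_, length(ids)), ids)
  if (length(supports) > 0) {
    anchors <- vapply(supports, min, character(1))
    ord <- order(anchors)
    supports <- supports[ord]
    anchors <- anchors[ord]
    for (k in seq_along(supports)) {
      free <- supports[[k]][is.na(assignment[supports[[k]]])]
      assignment[free] <- anchors[k]
    }
  }
  orphan <- is.na(assignment)
  assignment[orphan] <- names(assignment)[orphan]

  sizes <- table(assignment)
  labels <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  tibble(
    node = ids,
    cluster = match(unname(assignment), labels)
  )
}
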