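# Independent oracles and fixture builders. Each oracle is coded from the
# definitions, on purpose along a different path than the package (loops and
# explicit enumeration instead of the package's vectorised/indexed routes).

# quartet score, written as (2*min - sum of the four cross terms) / 4
oracle_alpha <- function(s_xz1, s_yz2, s_xz2, s_yz1, s_xy, s_z1z2) {
  (2 * min(s_xz1, s_yz2) - (s_xz2 + s_yz1 + s_xy + s_z1z2)) / 4
}

# build a similarity store from a plain pair table via the public surface
toy_store <- function(pairs, species) {
  ids <- sort(unique(c(pairs$p1, pairs$p2, names(species))))
  registry <- read_length_registry(
    data.frame(protein_id = ids, length = 100L),
    data.frame(protein_id = ids, species_id = unname(species[ids]))
  )
  hits <- tibble::tibble(
    query = pairs$p1, subject = pairs$p2, bit_score = pairs$score,
    query_cover = 1, subject_cover = 1
  )
  build_store(hits, registry)
}

# random multi-species store: each unordered pair stored with prob `density`
random_store <- function(n_species = 4, genes_per_species = 3,
                         density = 0.7, score_range = c(60, 500)) {
  species <- rep(sprintf("sp%02d", seq_len(n_species)),
                 each = genes_per_species)
  ids <- sprintf("%s.g%d", species, rep(seq_len(genes_per_species),
                                        times = n_species))
  names(species) <- ids
  cmb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(cmb)) < density
  pairs <- tibble::tibble(
    p1 = cmb[1, keep], p2 = cmb[2, keep],
    score = stats::runif(sum(keep), score_range[1], score_range[2])
  )
  list(store = toy_store(pairs, species), species = species, pairs = pairs)
}

# brute-force directional best hit from the raw pair table
oracle_best_hit <- function(pairs, species, protein, target_species) {
  best <- NA_character_; best_s <- -Inf
  for (k in seq_len(nrow(pairs))) {
    other <- if (pairs$p1[k] == protein) pairs$p2[k]
             else if (pairs$p2[k] == protein) pairs$p1[k]
             else next
    if (species[[other]] != target_species) next
    if (pairs$score[k] > best_s ||
        (pairs$score[k] == best_s && other < best)) {
      best <- other; best_s <- pairs$score[k]
    }
  }
  best
}

# brute-force BBH pairs by double maximisation
oracle_bbh <- function(pairs, species) {
  ids <- sort(unique(names(species)))
  out <- character(0)
  for (x in ids) for (y in ids) {
    if (x >= y || species[[x]] == species[[y]]) next
    bx <- oracle_best_hit(pairs, species, x, species[[y]])
    by <- oracle_best_hit(pairs, species, y, species[[x]])
    if (identical(bx, y) && identical(by, x)) out <- c(out, paste(x, y))
  }
  sort(out)
}

oracle_sim <- function(pairs, a, b) {
  hit <- (pairs$p1 == a & pairs$p2 == b) | (pairs$p1 == b & pairs$p2 == a)
  if (any(hit)) pairs$score[hit][1] else NA_real_
}

# exhaustive max-alpha: enumerate every third species, find the BBH witness
# pair there, evaluate the score from the six similarities
oracle_max_alpha <- function(pairs, species, x, y) {
  thirds <- setdiff(unique(unname(species)), c(species[[x]], species[[y]]))
  best <- NA_real_
  for (ts in thirds) {
    z1 <- oracle_best_hit(pairs, species, x, ts)
    z2 <- oracle_best_hit(pairs, species, y, ts)
    if (is.na(z1) || is.na(z2) || z1 == z2) next
    if (!identical(oracle_best_hit(pairs, species, z1, species[[x]]), x)) next
    if (!identical(oracle_best_hit(pairs, species, z2, species[[y]]), y)) next
    s <- c(oracle_sim(pairs, x, z1), oracle_sim(pairs, y, z2),
           oracle_sim(pairs, x, z2), oracle_sim(pairs, y, z1),
           oracle_sim(pairs, x, y), oracle_sim(pairs, z1, z2))
    if (anyNA(s)) next
    a <- oracle_alpha(s[1], s[2], s[3], s[4], s[5], s[6])
    if (is.na(best) || a > best) best <- a
  }
  best
}

# independent dense Markov clustering, explicit per-column loops
oracle_mcl <- function(edges, inflation = 2, max_iter = 100,
                       tolerance = 1e-6, prune = 1e-5) {
  ids <- sort(unique(c(edges$from, edges$to)))
  n <- length(ids)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$from[k], ids); j <- match(edges$to[k], ids)
    A[i, j] <- edges$weight[k]; A[j, i] <- edges$weight[k]
  }
  for (i in seq_len(n)) {
    m <- max(A[i, ])
    A[i, i] <- if (m > 0) m else 1
  }
  norm_cols <- function(M) {
    for (j in seq_len(ncol(M))) M[, j] <- M[, j] / sum(M[, j])
    M
  }
  M <- norm_cols(A)
  for (iter in seq_len(max_iter)) {
    E <- M %*% M
    E <- E^inflation
    E[E < prune] <- 0
    for (j in seq_len(n)) if (sum(E[, j]) == 0) E[j, j] <- 1
    E <- norm_cols(E)
    if (max(abs(E - M)) < tolerance) { M <- E; break }
    M <- E
  }
  # attractor rows span clusters; overlaps toward smallest member id
  assignment <- rep(NA_character_, n)
  supports <- list()
  for (i in seq_len(n)) {
    if (M[i, i] > 1e-9) supports[[length(supports) + 1]] <- ids[M[i, ] > 1e-9]
  }
  supports <- unique(supports)
  if (length(supports) > 0) {
    anchors <- vapply(supports, min, character(1))
    for (k in order(anchors)) {
      for (m in supports[[k]]) {
        if (is.na(assignment[match(m, ids)])) {
          assignment[match(m, ids)] <- anchors[k]
        }
      }
    }
  }
  assignment[is.na(assignment)] <- ids[is.na(assignment)]
  sets <- split(ids, assignment)
  unname(sets[order(names(sets))])
}

# partitions as comparable canonical objects (list of sorted member vectors)
canonical_partition <- function(nodes, clusters) {
  sets <- split(nodes, clusters)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[`, character(1), 1))])
}

random_edge_graph <- function(n_nodes, p_edge = 0.15) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  cmb <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(cmb)) < p_edge
  tibble::tibble(
    from = cmb[1, keep], to = cmb[2, keep],
    weight = stats::runif(sum(keep), 0.5, 2)
  )
}

# graph components by repeated neighbour expansion (for the never-merged check)
oracle_components <- function(edges, nodes) {
  comp <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      m <- min(comp[[a]], comp[[b]])
      if (comp[[a]] != m || comp[[b]] != m) {
        comp[[a]] <- m; comp[[b]] <- m; changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

write_blast_rows <- function(rows, path) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

blast_row <- function(q, s, bit, qstart = 1, qend = 100, sstart = 1,
                      send = 100, pident = 90, alen = 100) {
  c(q, s, pident, alen, 0, 0, qstart, qend, sstart, send, "1e-30", bit)
}
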