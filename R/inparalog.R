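#' Highest cross-species similarity of a protein
#'
#' The "external ceiling": the largest stored similarity between a protein
#' and any protein of any other species, or 0 when no cross-species pair is
#' stored. A within-species protein set only qualifies as an inparalog group
#' when every internal similarity exceeds every member's external ceiling --
#' the signature of duplications more recent than the species' last
#' speciation.
#'
#' @param store A `similarity_store`.
#' @param protein Protein id vector.
#' @return Numeric vector of ceilings.
#' @export
external_ceiling <- function(store, protein) {
  p <- store_pairs(store, cross_species_only = TRUE)
  vapply(protein, function(id) {
    s <- c(p$score[p$p1 == id], p$score[p$p2 == id])
    if (length(s) == 0) 0 else max(s)
  }, double(1), USE.NAMES = FALSE)
}

#' Detect within-species inparalog groups
#'
#' Builds, per species, the graph whose edges are quality-filtered
#' within-species pairs (a, b) with `S(a, b)` strictly above both proteins'
#' external ceilings, and takes its connected components of two or more
#' proteins as candidate groups. Each candidate must then satisfy the
#' set-level condition -- its smallest internal pairwise similarity (an
#' unstored internal pair counts as 0) must exceed the largest external
#' ceiling of any member; a failing component is split by removing its
#' weakest internal edge (ties broken lexicographically) and its pieces
#' re-tested, so every emitted group literally satisfies the condition.
#' Members of a group are co-orthologs, as a set, of orthologs of any member
#' in other species.
#'
#' @param store A `similarity_store` (within-species pairs retained).
#' @param species Restrict to these species ids (default: all).
#' @return A tibble with columns `species`, `group_index` (per species),
#'   `members` (list of sorted ids), `min_internal`, `max_external`.
#' @export
inparalog_groups <- function(store, species = NULL) {
  if (is.null(species)) species <- store_species(store)
  purrr::map_dfr(sort(species), function(sp) inparalog_groups_one(store, sp))
}

inparalog_groups_one <- function(store, species) {
  empty <- tibble(species = character(0), group_index = integer(0),
                  members = list(), min_internal = double(0),
                  max_external = double(0))
  p <- store$pairs
  within <- p[p$species1 == species & p$species2 == species, c("p1", "p2", "score")]
  if (nrow(within) == 0) return(empty)
  prots <- sort(unique(c(within$p1, within$p2)))
  ceil <- setNames(external_ceiling(store, prots), prots)
  keep <- within$score > ceil[within$p1] & within$score > ceil[within$p2]
  edges <- within[keep, ]
  if (nrow(edges) == 0) return(empty)
  edges <- dplyr::arrange(edges, .data$p1, .data$p2)

  # candidate components, then set-level verification with weakest-edge splits
  queue <- split_components(edges)
  accepted <- list()
  while (length(queue) > 0) {
    comp <- queue[[1]]
    queue <- queue[-1]
    members <- sort(unique(c(comp$p1, comp$p2)))
    if (length(members) < 2) next
    internal <- internal_similarities(store, members)
    min_internal <- min(internal)
    max_external <- max(ceil[members])
    if (min_internal > max_external) {
      accepted[[length(accepted) + 1]] <- list(
        members = members, min_internal = min_internal,
        max_external = max_external
      )
    } else {
      weakest <- order(comp$score, comp$p1, comp$p2)[1]
      queue <- c(queue, split_components(comp[-weakest, ]))
    }
  }
  if (length(accepted) == 0) return(empty)
  ord <- order(vapply(accepted, function(g) g$members[1], character(1)))
  accepted <- accepted[ord]
  tibble(
    species = species,
    group_index = seq_along(accepted),
    members = purrr::map(accepted, "members"),
    min_internal = purrr::map_dbl(accepted, "min_internal"),
    max_external = purrr::map_dbl(accepted, "max_external")
  )
}

# all pairwise similarities inside a member set; absent pairs count as 0
internal_similarities <- function(store, members) {
  if (length(members) < 2) return(numeric(0))
  idx <- utils::combn(members, 2)
  s <- store_lookup(store, idx[1, ], idx[2, ])
  s[is.na(s)] <- 0
  s
}

# connected components of an edge table, as a list of edge tables
split_components <- function(edges) {
  if (nrow(edges) == 0) return(list())
  nodes <- sort(unique(c(edges$p1, edges$p2)))
  comp <- setNames(seq_along(nodes), nodes)
  find <- function(i) { while (comp[[i]] != i) i <- comp[[i]]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges$p1[k], nodes))
    b <- find(match(edges$p2[k], nodes))
    if (a != b) comp[[max(a, b)]] <- min(a, b)
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  lapply(unique(roots), function(r) {
    keep <- nodes[roots == r]
    edges[edges$p1 %in% keep, , drop = FALSE]
  })
}

#' Expand ortholog pairs into co-ortholog sets via inparalogs
#'
#' For each called ortholog pair (x, y), every protein in x's inparalog
#' group is a co-ortholog of every protein in y's group (and vice versa);
#' proteins without inparalogs expand to themselves alone.
#'
#' @param calls An [call_orthologs()] result.
#' @param inparalogs An [inparalog_groups()] tibble.
#' @return A tibble with columns `x`, `y` (the seeding ortholog pair),
#'   `co_x`, `co_y` (one row per expanded co-ortholog pair).
#' @export
co_orthologs <- function(calls, inparalogs) {
  kept <- dplyr::filter(as_tibble(calls), .data$is_ortholog)
  member_of <- list()
  for (k in seq_len(nrow(inparalogs))) {
    for (m in inparalogs$members[[k]]) member_of[[m]] <- inparalogs$members[[k]]
  }
  expand <- function(id) {
    g <- member_of[[id]]
    if (is.null(g)) id else g
  }
  purrr::map_dfr(seq_len(nrow(kept)), function(k) {
    cx <- expand(kept$x[k]); cy <- expand(kept$y[k])
    tidyr::expand_grid(co_x = cx, co_y = cy) |>
      dplyr::mutate(x = kept$x[k], y = kept$y[k], .before = 1)
  })
}
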