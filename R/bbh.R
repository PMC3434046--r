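#' Best similarity hit of a protein in a target species
#'
#' @param store A `similarity_store`.
#' @param protein Protein id.
#' @param target_species Species to search in; must differ from the
#'   protein's own species.
#' @return The id of the target-species protein with maximal stored
#'   similarity to `protein` (ties broken by lexicographically smallest id),
#'   or `NA` when no pair into that species is stored.
#' @export
best_hit <- function(store, protein, target_species) {
  own <- store$species_of[[protein]]
  if (identical(own, target_species)) {
    abort("target species must differ from the protein's own species")
  }
  nb <- store_neighbours(store, protein, target_species)
  if (nrow(nb) == 0) return(NA_character_)
  top <- nb$other[nb$score == max(nb$score)]
  min(top)
}

#' Directional best-hit index over the whole store
#'
#' Computes, for every protein and every other species it has stored
#' similarities into, its single best hit there (score ties broken by
#' lexicographically smallest partner id).
#'
#' @param store A `similarity_store`.
#' @return A tibble of class `best_hit_index` with columns `protein`,
#'   `target_species`, `best`, `score`.
#' @export
best_hit_index <- function(store) {
  p <- store_pairs(store, cross_species_only = TRUE)
  directed <- dplyr::bind_rows(
    tibble(protein = p$p1, target_species = p$species2,
           best = p$p2, score = p$score),
    tibble(protein = p$p2, target_species = p$species1,
           best = p$p1, score = p$score)
  )
  if (nrow(directed) == 0) {
    idx <- tibble(protein = character(0), target_species = character(0),
                  best = character(0), score = double(0))
    class(idx) <- c("best_hit_index", class(idx))
    return(idx)
  }
  idx <- directed |>
    dplyr::group_by(.data$protein, .data$target_species) |>
    dplyr::filter(.data$score == max(.data$score)) |>
    dplyr::slice_min(.data$best, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$protein, .data$target_species)
  class(idx) <- c("best_hit_index", class(idx))
  idx
}

#' Bidirectional best-hit (BBH) pairs
#'
#' A pair (x, y) across two species is BBH when each protein is the other's
#' best hit in the opposing species. BBH pairs that survive the corpus-wide
#' quality filter are the putative orthologs fed to quartet scoring.
#'
#' @param store A `similarity_store`.
#' @param species_a,species_b Restrict to one species pair (must be
#'   distinct); by default all species pairs are scanned.
#' @param index A precomputed [best_hit_index()] (computed on the fly if
#'   omitted).
#' @return A tibble with columns `x`, `y` (canonical order: `x < y`),
#'   `species_x`, `species_y`, `similarity`, sorted by `x`, `y`.
#' @export
bbh_pairs <- function(store, species_a = NULL, species_b = NULL, index = NULL) {
  if (!is.null(species_a) || !is.null(species_b)) {
    if (is.null(species_a) || is.null(species_b) ||
        identical(species_a, species_b)) {
      abort("species_a and species_b must be two distinct species")
    }
  }
  if (is.null(index)) index <- best_hit_index(store)
  # mutual best: forward edge (protein -> best) whose reverse edge comes back
  fwd <- index
  back <- setNames(index$best,
                   paste(index$protein, index$target_species, sep = "\t"))
  sp <- store$species_of
  mutual <- fwd[back[paste(fwd$best, sp[fwd$protein], sep = "\t")] == fwd$protein &
                  !is.na(back[paste(fwd$best, sp[fwd$protein], sep = "\t")]), ]
  out <- tibble(
    x = pmin(mutual$protein, mutual$best),
    y = pmax(mutual$protein, mutual$best)
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$x, .data$y)
  out$species_x <- unname(sp[out$x])
  out$species_y <- unname(sp[out$y])
  out$similarity <- store_lookup(store, out$x, out$y)
  if (!is.null(species_a)) {
    keep <- (out$species_x == species_a & out$species_y == species_b) |
      (out$species_x == species_b & out$species_y == species_a)
    out <- out[keep, ]
  }
  out
}
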