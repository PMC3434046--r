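#' Build a symmetric similarity store from filtered hits
#'
#' Collapses directional hits into a single similarity value `S` per unordered
#' protein pair, the quantity every downstream stage consumes. When a
#' direction has several high-scoring segment pairs only the best (highest
#' bit-score) is kept; when both directions are present `S` is their
#' arithmetic mean, and a single direction stands on its own. Pairs with no
#' surviving hit are simply absent -- absence is "no evidence", never a zero.
#' Within-species pairs are retained (inparalog detection needs them);
#' self-pairs never enter.
#'
#' @param hits A filtered hit tibble (see [quality_filter()]).
#' @param registry The protein registry; every hit id must be present.
#' @return A `similarity_store` object: under the hood a list with a
#'   canonical `pairs` tibble (`p1 < p2`, `score`, species of each side), a
#'   fast lookup table, and the registry.
#' @export
build_store <- function(hits, registry) {
  sp <- registry_species(registry)
  unknown <- setdiff(unique(c(hits$query, hits$subject)), names(sp))
  if (length(unknown) > 0) {
    abort(paste0("hits reference protein id(s) absent from registry: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (nrow(hits) == 0) {
    return(new_store(
      tibble(p1 = character(0), p2 = character(0), score = double(0),
             species1 = character(0), species2 = character(0)),
      registry))
  }
  pairs <- hits |>
    dplyr::filter(.data$query != .data$subject) |>
    dplyr::mutate(
      p1 = pmin(.data$query, .data$subject),
      p2 = pmax(.data$query, .data$subject),
      forward = .data$query == .data$p1
    ) |>
    # best segment pair per direction, then mean of the directions present
    dplyr::group_by(.data$p1, .data$p2, .data$forward) |>
    dplyr::summarise(score = max(.data$bit_score), .groups = "drop_last") |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$p1, .data$p2)
  pairs$species1 <- unname(sp[pairs$p1])
  pairs$species2 <- unname(sp[pairs$p2])
  new_store(pairs, registry)
}

new_store <- function(pairs, registry) {
  lookup <- new.env(parent = emptyenv(), size = max(1L, nrow(pairs)))
  if (nrow(pairs) > 0) {
    keys <- pair_key(pairs$p1, pairs$p2)
    for (i in seq_len(nrow(pairs))) assign(keys[i], pairs$score[i], envir = lookup)
  }
  structure(
    list(pairs = pairs, lookup = lookup, registry = registry,
         species_of = registry_species(registry)),
    class = "similarity_store"
  )
}

#' Look up stored similarities for protein pairs
#'
#' @param store A `similarity_store`.
#' @param x,y Protein id vectors (recycled to common length). Order is
#'   irrelevant: the store is symmetric by construction.
#' @return Numeric vector of similarities; `NA` where no pair is stored.
#' @export
store_lookup <- function(store, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  keys <- pair_key(x, y)
  vapply(keys, function(k) {
    v <- get0(k, envir = store$lookup, ifnotfound = NA_real_)
    as.double(v)
  }, double(1), USE.NAMES = FALSE)
}

#' @export
print.similarity_store <- function(x, ...) {
  cat(sprintf(
    "<similarity_store> %d proteins, %d species, %d stored pairs\n",
    nrow(x$registry), length(unique(x$registry$species)), nrow(x$pairs)
  ))
  invisible(x)
}

#' All stored pairs as a tibble
#'
#' @param store A `similarity_store`.
#' @param cross_species_only Drop within-species pairs?
#' @return Tibble with `p1`, `p2`, `score`, `species1`, `species2`.
#' @export
store_pairs <- function(store, cross_species_only = FALSE) {
  p <- store$pairs
  if (cross_species_only) p <- dplyr::filter(p, .data$species1 != .data$species2)
  p
}

store_species <- function(store) sort(unique(store$registry$species))

# neighbours of `protein` restricted to one species, as a tibble(other, score)
store_neighbours <- function(store, protein, species) {
  p <- store$pairs
  sel1 <- p$p1 == protein & p$species2 == species
  sel2 <- p$p2 == protein & p$species1 == species
  tibble(
    other = c(p$p2[sel1], p$p1[sel2]),
    score = c(p$score[sel1], p$score[sel2])
  )
}
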