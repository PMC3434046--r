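#' Quartet duplication score
#'
#' The analytic score that replaces explicit quartet gene-tree
#' reconstruction. For a candidate ortholog pair (x, y) and a witness pair
#' (z1, z2) in a third species -- z1 the BBH partner of x there, z2 the BBH
#' partner of y -- the score
#'
#' \deqn{\alpha = \tfrac12\,\min(S_{x,z1}, S_{y,z2}) -
#'   \tfrac14\,(S_{x,z2} + S_{y,z1} + S_{x,y} + S_{z1,z2})}
#'
#' estimates the likelihood that a duplication event separates x from y:
#' strong same-side similarities with weak cross similarities (large
#' \eqn{\alpha}) indicate that z1 and z2 straddle a duplication on the x--y
#' path. When all six similarities equal s the score collapses to
#' \eqn{-s/2}, and it scales linearly with the similarity scale.
#'
#' @param s_xz1,s_yz2,s_xz2,s_yz1,s_xy,s_z1z2 The six pairwise similarities
#'   (non-negative; vectorized).
#' @return Numeric vector of scores.
#' @export
#' @examples
#' quartet_alpha(100, 100, 100, 100, 100, 100) # -50
#' quartet_alpha(100, 100, 0, 0, 0, 0)         # 50: pure duplication signal
quartet_alpha <- function(s_xz1, s_yz2, s_xz2, s_yz1, s_xy, s_z1z2) {
  0.5 * pmin(s_xz1, s_yz2) - 0.25 * (s_xz2 + s_yz1 + s_xy + s_z1z2)
}

# BBH partner of `protein` in `species`, or NA: the directional best hit that
# points back. `back` is a named lookup protein\tspecies -> best.
bbh_partner <- function(back, sp, protein, species) {
  z <- back[[paste(protein, species, sep = "\t")]]
  if (is.null(z)) return(NA_character_)
  home <- back[[paste(z, sp[[protein]], sep = "\t")]]
  if (is.null(home) || home != protein) return(NA_character_)
  z
}

index_lookup <- function(index) {
  setNames(as.list(index$best),
           paste(index$protein, index$target_species, sep = "\t"))
}

#' Duplication witnesses for a candidate pair in one third species
#'
#' Yields the witness pair (z1, z2) of a third species: z1 the BBH partner of
#' x there, z2 the BBH partner of y. No witness is produced when either
#' partner is absent, when z1 = z2 (a single-copy third species cannot
#' witness a duplication), or -- under the default `"skip"` policy -- when any
#' of the six similarities entering the quartet score is not stored. The
#' `"impute_zero"` policy instead substitutes 0 for absent similarities,
#' which manufactures duplication evidence from filter drop-outs and is off
#' by default.
#'
#' @param store A `similarity_store`.
#' @param x,y The candidate ortholog pair (distinct species).
#' @param third_species A species distinct from those of `x` and `y`.
#' @param index A [best_hit_index()].
#' @param missing_policy `"skip"` (default) or `"impute_zero"`.
#' @return A tibble with columns `species`, `z1`, `z2`, `alpha`; zero rows
#'   when the species yields no witness.
#' @export
quartet_witnesses <- function(store, x, y, third_species, index,
                              missing_policy = c("skip", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  sp <- store$species_of
  if (third_species %in% c(sp[[x]], sp[[y]])) {
    abort("third_species must differ from the species of x and y")
  }
  back <- index_lookup(index)
  witness_row(store, x, y, third_species, back, sp, missing_policy)
}

witness_row <- function(store, x, y, third_species, back, sp, missing_policy) {
  empty <- tibble(species = character(0), z1 = character(0),
                  z2 = character(0), alpha = double(0))
  z1 <- bbh_partner(back, sp, x, third_species)
  z2 <- bbh_partner(back, sp, y, third_species)
  if (is.na(z1) || is.na(z2) || z1 == z2) return(empty)
  s <- store_lookup(store,
                    c(x, y, x, y, x, z1),
                    c(z1, z2, z2, z1, y, z2))
  if (anyNA(s)) {
    if (missing_policy == "skip") return(empty)
    s[is.na(s)] <- 0
  }
  tibble(species = third_species, z1 = z1, z2 = z2,
         alpha = quartet_alpha(s[1], s[2], s[3], s[4], s[5], s[6]))
}

#' Maximum quartet score of a candidate pair over all third species
#'
#' Scans every species other than the two of the pair, collects the witness
#' scores, and returns the largest -- the value stored per putative ortholog
#' so that any downstream cutoff can be applied without rescoring. `NA`
#' encodes "no witness anywhere": a corpus-wide search found no duplication
#' evidence, and such pairs are always called orthologs.
#'
#' @inheritParams quartet_witnesses
#' @return A single number, or `NA` when no species yields a witness.
#' @export
max_alpha <- function(store, x, y, index,
                      missing_policy = c("skip", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  sp <- store$species_of
  back <- index_lookup(index)
  thirds <- setdiff(store_species(store), c(sp[[x]], sp[[y]]))
  alphas <- purrr::map_dbl(thirds, function(ts) {
    w <- witness_row(store, x, y, ts, back, sp, missing_policy)
    if (nrow(w) == 0) NA_real_ else w$alpha
  })
  alphas <- alphas[!is.na(alphas)]
  if (length(alphas) == 0) NA_real_ else max(alphas)
}

#' Score putative ortholog pairs with their maximum quartet score
#'
#' @param store A `similarity_store`.
#' @param pairs A tibble of putative ortholog pairs from [bbh_pairs()].
#' @param index A [best_hit_index()] (recomputed if omitted).
#' @param missing_policy See [quartet_witnesses()].
#' @return `pairs` with an `alpha_max` column (`NA` = no witness evidence).
#' @export
score_quartets <- function(store, pairs, index = NULL,
                           missing_policy = c("skip", "impute_zero")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(index)) index <- best_hit_index(store)
  sp <- store$species_of
  back <- index_lookup(index)
  species <- store_species(store)
  pairs$alpha_max <- purrr::map2_dbl(pairs$x, pairs$y, function(x, y) {
    thirds <- setdiff(species, c(sp[[x]], sp[[y]]))
    best <- NA_real_
    for (ts in thirds) {
      w <- witness_row(store, x, y, ts, back, sp, missing_policy)
      if (nrow(w) > 0 && (is.na(best) || w$alpha > best)) best <- w$alpha
    }
    best
  })
  pairs
}

#' Call orthologs at a quartet-score cutoff
#'
#' A scored pair is called an ortholog when its maximum quartet score is at
#' most `omega` (inclusive), or when no witness evidence exists anywhere in
#' the corpus (`alpha_max` of `NA`). Smaller cutoffs yield fewer, more
#' accurate orthologs; larger cutoffs trade accuracy for coverage.
#'
#' @param scored_pairs Output of [score_quartets()].
#' @param omega The cutoff \eqn{\Omega} (default 20).
#' @return An `ortholog_calls` tibble: the input plus a logical
#'   `is_ortholog` column; the cutoff is recorded as attribute `omega`.
#' @export
call_orthologs <- function(scored_pairs, omega = 20) {
  if (!"alpha_max" %in% names(scored_pairs)) {
    abort("scored_pairs must carry an alpha_max column; run score_quartets() first")
  }
  out <- dplyr::mutate(
    scored_pairs,
    is_ortholog = is.na(.data$alpha_max) | .data$alpha_max <= omega
  )
  attr(out, "omega") <- omega
  class(out) <- c("ortholog_calls", class(out))
  out
}

#' @export
print.ortholog_calls <- function(x, ...) {
  cat(sprintf("<ortholog_calls> omega = %g: %d / %d pairs called orthologs\n",
              attr(x, "omega"), sum(x$is_ortholog), nrow(x)))
  NextMethod()
}

#' @rdname call_orthologs
#' @param x An `ortholog_calls` object.
#' @param ... Unused.
#' @method tidy ortholog_calls
#' @export
tidy.ortholog_calls <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ortholog_calls")
  out
}

#' @rdname call_orthologs
#' @method glance ortholog_calls
#' @export
glance.ortholog_calls <- function(x, ...) {
  tibble(
    omega = attr(x, "omega"),
    n_putative = nrow(x),
    n_ortholog = sum(x$is_ortholog),
    n_no_evidence = sum(is.na(x$alpha_max)),
    median_alpha = median(x$alpha_max, na.rm = TRUE)
  )
}
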