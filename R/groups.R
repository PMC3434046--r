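#' Form orthologous groups from an MCL partition
#'
#' Clusters spanning at least `min_species` distinct species become
#' orthologous groups; smaller clusters are dropped from the group output
#' (their members keep their pairwise ortholog calls). Group ids `QTS_1`,
#' `QTS_2`, ... are assigned by decreasing group size, ties broken by the
#' lexicographically smallest member, so identical inputs always yield
#' identical ids.
#'
#' @param partition A tibble with columns `node`, `cluster` from [mcl()].
#' @param registry The protein registry (supplies species).
#' @param min_species Minimum number of distinct species per group
#'   (default 3).
#' @return A tibble with columns `group_id`, `size`, `species_count`,
#'   `members` (list of sorted id vectors), `species` (list of sorted
#'   species vectors).
#' @export
form_groups <- function(partition, registry, min_species = 3) {
  sp <- registry_species(registry)
  unknown <- setdiff(partition$node, names(sp))
  if (length(unknown) > 0) {
    abort(paste0("partition references protein id(s) absent from registry: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  grp <- partition |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      members = list(sort(.data$node)),
      size = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      species = purrr::map(.data$members, ~ sort(unique(unname(sp[.x])))),
      species_count = lengths(.data$species),
      anchor = purrr::map_chr(.data$members, 1)
    ) |>
    dplyr::filter(.data$species_count >= min_species) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$anchor)
  tibble(
    group_id = paste0("QTS_", seq_len(nrow(grp))),
    size = grp$size,
    species_count = grp$species_count,
    members = grp$members,
    species = grp$species
  )
}

#' Consensus annotation of orthologous groups
#'
#' Each annotation facet -- gene symbol, functional description, and every GO
#' accession -- is adopted for a group only when it is shared by a strict
#' majority fraction above `threshold` of the group's proteins. With the
#' default denominator `"all"`, members lacking the facet still count in the
#' denominator, so 4 of 5 members agreeing (exactly 0.8) is *not* enough at
#' the default threshold while 5 of 6 (0.833) is. The `"annotated"`
#' denominator counts only members carrying the facet.
#'
#' @param groups A [form_groups()] tibble.
#' @param registry A registry carrying annotation columns (see
#'   [read_fasta_registry()]).
#' @param threshold Consensus fraction that must be exceeded (default 0.8).
#' @param denominator `"all"` members (default) or only `"annotated"` ones.
#' @return `groups` with columns `consensus_symbol`, `consensus_description`
#'   (character, `NA` = no consensus) and `consensus_go` (list of character
#'   vectors, possibly empty).
#' @export
annotate_groups <- function(groups, registry, threshold = 0.8,
                            denominator = c("all", "annotated")) {
  denominator <- match.arg(denominator)
  sym <- setNames(registry$gene_symbol, registry$id)
  des <- setNames(registry$description, registry$id)
  gos <- setNames(registry$go_terms, registry$id)

  consensus_scalar <- function(values, n_all) {
    values <- values[!is.na(values)]
    if (length(values) == 0) return(NA_character_)
    denom <- if (denominator == "all") n_all else length(values)
    tab <- sort(table(values), decreasing = TRUE)
    if (tab[1] / denom > threshold) names(tab)[1] else NA_character_
  }
  consensus_go <- function(term_lists, n_all) {
    terms <- unlist(term_lists, use.names = FALSE)
    if (length(terms) == 0) return(character(0))
    denom <- if (denominator == "all") n_all
             else sum(lengths(term_lists) > 0)
    tab <- table(terms)
    sort(names(tab)[tab / denom > threshold])
  }

  groups$consensus_symbol <- purrr::map_chr(
    groups$members, ~ consensus_scalar(unname(sym[.x]), length(.x)))
  groups$consensus_description <- purrr::map_chr(
    groups$members, ~ consensus_scalar(unname(des[.x]), length(.x)))
  groups$consensus_go <- purrr::map(
    groups$members, ~ consensus_go(gos[.x], length(.x)))
  groups
}

#' Query orthologous groups by species content and description text
#'
#' `mode = "any"` keeps groups containing orthologs in at least one of the
#' given species; `mode = "all"` keeps groups conserved in every one of
#' them. An optional case-insensitive substring filter on the consensus
#' description narrows the result further.
#'
#' @param groups A (possibly annotated) groups tibble.
#' @param species_filter Character vector of species ids.
#' @param mode `"any"` or `"all"`.
#' @param text_filter Optional substring matched (case-insensitively)
#'   against `consensus_description`.
#' @param known_species Species universe used to validate `species_filter`;
#'   defaults to the species seen in `groups`.
#' @return The matching rows of `groups`.
#' @export
query_groups <- function(groups, species_filter, mode = c("any", "all"),
                         text_filter = NULL, known_species = NULL) {
  mode <- match.arg(mode)
  if (is.null(known_species)) {
    known_species <- unique(unlist(groups$species, use.names = FALSE))
  }
  bad <- setdiff(species_filter, known_species)
  if (length(bad) > 0) {
    abort(paste0("unknown species id(s): ", paste(bad, collapse = ", ")))
  }
  keep <- purrr::map_lgl(groups$species, function(sp) {
    if (mode == "any") length(intersect(sp, species_filter)) > 0
    else all(species_filter %in% sp)
  })
  out <- groups[keep, ]
  if (!is.null(text_filter)) {
    if (!"consensus_description" %in% names(out)) {
      abort("text_filter requires annotated groups (run annotate_groups())")
    }
    hit <- stringr::str_detect(
      stringr::str_to_lower(dplyr::coalesce(out$consensus_description, "")),
      stringr::fixed(stringr::str_to_lower(text_filter))
    )
    out <- out[hit, ]
  }
  out
}

#' Conservation curve over a species panel
#'
#' For each n from 1 to the panel size, counts the orthologous groups that
#' contain orthologs in at least n of the listed species -- the standard
#' summary used to spot broadly conserved families (for example candidate
#' broad-spectrum drug targets across a pathogen panel). The curve is
#' non-increasing in n by construction.
#'
#' @param groups A groups tibble.
#' @param species_list Non-empty character vector of species ids.
#' @return A tibble of class `conservation_curve` with columns `n`,
#'   `n_groups`.
#' @export
conservation_curve <- function(groups, species_list) {
  if (length(species_list) == 0) abort("species_list must be non-empty")
  overlap <- purrr::map_int(groups$species,
                            ~ length(intersect(.x, species_list)))
  out <- tibble(
    n = seq_along(species_list),
    n_groups = purrr::map_int(seq_along(species_list),
                              ~ sum(overlap >= .x))
  )
  class(out) <- c("conservation_curve", class(out))
  out
}

#' Species-presence matrix of orthologous groups
#'
#' @param groups A groups tibble.
#' @param all_species Optional full species panel for the columns.
#' @return A tibble: one row per group, one 0/1 column per species.
#' @export
species_presence <- function(groups, all_species = NULL) {
  if (is.null(all_species)) {
    all_species <- sort(unique(unlist(groups$species, use.names = FALSE)))
  }
  pres <- purrr::map(groups$species,
                     ~ as.integer(all_species %in% .x))
  m <- do.call(rbind, c(pres, list(matrix(integer(0), 0, length(all_species)))))
  colnames(m) <- all_species
  dplyr::bind_cols(tibble(group_id = groups$group_id), as_tibble(m))
}
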