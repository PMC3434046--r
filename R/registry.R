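#' Build a protein registry from FASTA sequences and a species table
#'
#' The registry is the corpus-wide catalogue of proteins: one row per protein
#' with its species assignment and sequence length. Lengths are taken from the
#' FASTA records; the species table must cover every record. Sequences
#' themselves are discarded -- downstream stages only consume identifiers,
#' species and lengths.
#'
#' @param fasta_path Path to a protein FASTA file. Record identifiers are the
#'   first whitespace-delimited token of each header.
#' @param species_table A data frame with columns `protein_id` and
#'   `species_id`, or a path to a headerless 2-column TSV in that order.
#' @param annotations Optional per-protein annotation table (data frame or TSV
#'   path) with columns `protein_id`, `gene_symbol`, `description`,
#'   `go_accessions` (semicolon-separated); see [read_annotation_table()].
#'
#' @return A tibble of class `protein_registry` with columns `id`, `species`,
#'   `length`, and (always present) annotation columns `gene_symbol`,
#'   `description`, `go_terms` (a list column of character vectors), ordered
#'   by `id`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1", "MKVL", ">p2", "MATTTE"), fa)
#' sp <- data.frame(protein_id = c("p1", "p2"), species_id = "spA")
#' read_fasta_registry(fa, sp)
read_fasta_registry <- function(fasta_path, species_table, annotations = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0(
      "duplicate protein identifier(s) in FASTA: ",
      paste(dup, collapse = ", ")
    ))
  }
  build_registry(
    tibble(id = ids, length = Biostrings::width(seqs)),
    species_table, annotations
  )
}

#' Build a protein registry from a precomputed length table
#'
#' Bypasses FASTA parsing when sequence lengths are already known (for
#' instance when the similarity search tool reported them, or for simulated
#' corpora).
#'
#' @param lengths A data frame with columns `protein_id` and `length`, or a
#'   path to a headerless 2-column TSV in that order.
#' @inheritParams read_fasta_registry
#' @return A `protein_registry` tibble; see [read_fasta_registry()].
#' @export
read_length_registry <- function(lengths, species_table, annotations = NULL) {
  lengths <- read_two_col(lengths, c("protein_id", "length"))
  lengths$length <- as.integer(lengths$length)
  if (anyDuplicated(lengths$protein_id)) {
    dup <- unique(lengths$protein_id[duplicated(lengths$protein_id)])
    abort(paste0(
      "duplicate protein identifier(s) in length table: ",
      paste(dup, collapse = ", ")
    ))
  }
  build_registry(
    tibble(id = lengths$protein_id, length = lengths$length),
    species_table, annotations
  )
}

#' Read a per-protein annotation table
#'
#' @param path A TSV file with header columns `protein_id`, `gene_symbol`,
#'   `description`, `go_accessions`; GO accessions are semicolon-separated
#'   within the field. Empty fields mean "no annotation of that facet".
#' @return A tibble with columns `protein_id`, `gene_symbol`, `description`
#'   and `go_terms` (list column of character vectors).
#' @export
read_annotation_table <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("protein_id", "gene_symbol", "description", "go_accessions")
  if (!all(needed %in% names(ann))) {
    abort(paste0("annotation table must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  tibble(
    protein_id = ann$protein_id,
    gene_symbol = dplyr::na_if(ann$gene_symbol, ""),
    description = dplyr::na_if(ann$description, ""),
    go_terms = purrr::map(ann$go_accessions, function(x) {
      if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
    })
  )
}

build_registry <- function(core, species_table, annotations) {
  species_table <- read_two_col(species_table, c("protein_id", "species_id"))
  sp <- setNames(as.character(species_table$species_id),
                 species_table$protein_id)
  missing <- setdiff(core$id, names(sp))
  if (length(missing) > 0) {
    abort(paste0(
      "protein id(s) missing from species table: ",
      paste(head(missing, 5), collapse = ", "),
      if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else ""
    ))
  }
  if (any(core$length < 1)) {
    abort("all protein lengths must be >= 1")
  }
  reg <- tibble(
    id = core$id,
    species = unname(sp[core$id]),
    length = as.integer(core$length),
    gene_symbol = NA_character_,
    description = NA_character_,
    go_terms = rep(list(character(0)), nrow(core))
  )
  reg <- dplyr::arrange(reg, .data$id)
  if (!is.null(annotations)) {
    if (is.character(annotations)) annotations <- read_annotation_table(annotations)
    idx <- match(reg$id, annotations$protein_id)
    hit <- !is.na(idx)
    reg$gene_symbol[hit] <- annotations$gene_symbol[idx[hit]]
    reg$description[hit] <- annotations$description[idx[hit]]
    reg$go_terms[hit] <- annotations$go_terms[idx[hit]]
  }
  class(reg) <- c("protein_registry", class(reg))
  reg
}

read_two_col <- function(x, cols) {
  if (is.character(x) && length(x) == 1) {
    x <- readr::read_tsv(x, col_names = cols,
                         col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  }
  x <- as_tibble(x)
  if (!all(cols %in% names(x))) {
    if (ncol(x) >= length(cols)) names(x)[seq_along(cols)] <- cols
    else abort(paste0("expected columns ", paste(cols, collapse = ", ")))
  }
  x[cols]
}

registry_species <- function(registry) {
  setNames(registry$species, registry$id)
}
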