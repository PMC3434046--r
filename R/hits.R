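#' Parse all-vs-all similarity hits in 12-column tabular format
#'
#' Reads the standard 12-column tabular output of a protein similarity search
#' (query, subject, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit-score) and derives, for
#' each hit, the fraction of the query and subject sequences covered by the
#' aligned region. Coverage uses the inclusive span `|end - start| + 1`
#' divided by the full sequence length from the registry, so reversed
#' coordinates (minus-frame conventions) are handled transparently.
#'
#' @param path Path to a tab-separated 12-column hit file (no header; `#`
#'   comment lines ignored).
#' @param registry A [read_fasta_registry()] / [read_length_registry()]
#'   registry supplying sequence lengths; rows referencing identifiers absent
#'   from it are an error.
#' @return A tibble with columns `query`, `subject`, `bit_score`,
#'   `query_cover`, `subject_cover` (fractions in \[0, 1\]).
#' @export
read_blast_tab <- function(path, registry) {
  lines <- readr::read_lines(path, progress = FALSE)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(query = character(0), subject = character(0),
                  bit_score = double(0), query_cover = double(0),
                  subject_cover = double(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    bad <- line_no[which(nf != 12)[1]]
    abort(sprintf("line %d: expected 12 tab-separated columns, found %d",
                  bad, nf[which(nf != 12)[1]]))
  }
  m <- matrix(unlist(fields), ncol = 12, byrow = TRUE)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- line_no[which(is.na(v))[1]]
      abort(sprintf("line %d: non-numeric %s field", bad, what))
    }
    v
  }
  qstart <- num(7, "query start"); qend <- num(8, "query end")
  sstart <- num(9, "subject start"); send <- num(10, "subject end")
  bit <- num(12, "bit-score")

  lens <- setNames(registry$length, registry$id)
  unknown <- setdiff(c(m[, 1], m[, 2]), names(lens))
  if (length(unknown) > 0) {
    abort(paste0("hit table references protein id(s) absent from registry: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  tibble(
    query = m[, 1],
    subject = m[, 2],
    bit_score = bit,
    query_cover = unname((abs(qend - qstart) + 1) / lens[m[, 1]]),
    subject_cover = unname((abs(send - sstart) + 1) / lens[m[, 2]])
  )
}

#' Filter hits on alignment coverage and bit-score
#'
#' Keeps hits whose aligned region covers at least `coverage_threshold` of
#' *both* sequences and whose bit-score strictly exceeds `bit_threshold`;
#' self-hits are always dropped. The strict reading of the bit-score cutoff
#' means a hit scoring exactly the threshold is removed, while a hit covering
#' exactly half of each sequence survives the (inclusive) coverage condition.
#' The filter is applied corpus-wide, before any best-hit ranking, so
#' within-species hits that survive remain available to inparalog detection.
#'
#' @param hits A hit tibble from [read_blast_tab()].
#' @param bit_threshold Bit-score that must be exceeded (default 50).
#' @param coverage_threshold Minimum coverage fraction of each sequence
#'   (default 0.5).
#' @return The surviving rows, same columns.
#' @export
quality_filter <- function(hits, bit_threshold = 50, coverage_threshold = 0.5) {
  dplyr::filter(
    hits,
    .data$query != .data$subject,
    .data$query_cover >= coverage_threshold,
    .data$subject_cover >= coverage_threshold,
    .data$bit_score > bit_threshold
  )
}
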