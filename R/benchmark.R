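#' Score ortholog predictions against simulator truth
#'
#' Standard confusion-matrix ratios over the labelled cross-species pairs of
#' the candidate universe -- by default the BBH putative pairs the pipeline
#' actually scored, since pairs outside it were never candidates. Precision
#' is `NA` when nothing was predicted.
#'
#' @param calls An [call_orthologs()] result (or any tibble with `x`, `y`,
#'   `is_ortholog`).
#' @param truth A truth table with columns `x`, `y`, `label`
#'   (`"ortholog"`/`"paralog"`), e.g. `corpus$truth$pair_labels`.
#' @param universe Optional tibble of candidate pairs (`x`, `y`); defaults
#'   to all rows of `calls`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `false_positive_rate`, `n_evaluated`.
#' @export
benchmark_orthologs <- function(calls, truth, universe = NULL) {
  calls <- as_tibble(calls)
  if (is.null(universe)) universe <- calls[c("x", "y")]
  if (length(intersect(c(universe$x, universe$y),
                       c(truth$x, truth$y))) == 0 &&
      (nrow(universe) > 0 || nrow(truth) > 0)) {
    abort("prediction universe and truth share no proteins")
  }
  key_truth <- setNames(truth$label, pair_key(truth$x, truth$y))
  key_called <- pair_key(calls$x[calls$is_ortholog], calls$y[calls$is_ortholog])
  uni <- pair_key(universe$x, universe$y)
  lab <- key_truth[uni]
  eval_idx <- !is.na(lab)
  called <- uni %in% key_called
  tp <- sum(eval_idx & called & lab == "ortholog")
  fp <- sum(eval_idx & called & lab == "paralog")
  fn <- sum(eval_idx & !called & lab == "ortholog")
  tn <- sum(eval_idx & !called & lab == "paralog")
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    false_positive_rate = if (fp + tn == 0) NA_real_ else fp / (fp + tn),
    n_evaluated = sum(eval_idx)
  )
}

#' Sweep the ortholog-call cutoff
#'
#' Re-calls orthologs from already-scored pairs at each cutoff and tabulates
#' coverage (and accuracy, when truth is supplied). The predicted set is
#' nested and non-decreasing in the cutoff, trading accuracy for coverage.
#'
#' @param scored_pairs Output of [score_quartets()].
#' @param omegas Numeric vector of cutoffs (may include `Inf`).
#' @param truth Optional truth table (see [benchmark_orthologs()]).
#' @return A tibble of class `omega_sweep` with one row per cutoff:
#'   `omega`, `n_called`, and when truth is given `precision`, `recall`,
#'   `false_positive_rate`.
#' @export
omega_sweep <- function(scored_pairs, omegas, truth = NULL) {
  rows <- purrr::map_dfr(omegas, function(om) {
    calls <- call_orthologs(scored_pairs, omega = om)
    row <- tibble(omega = om, n_called = sum(calls$is_ortholog))
    if (!is.null(truth)) {
      row <- dplyr::bind_cols(
        row,
        benchmark_orthologs(calls, truth)[
          c("precision", "recall", "false_positive_rate")]
      )
    }
    row
  })
  class(rows) <- c("omega_sweep", class(rows))
  rows
}
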