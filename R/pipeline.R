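#' Pipeline configuration
#'
#' Collects every input path and tunable of an end-to-end run in one
#' serialisable object. Thresholds default to the published operating
#' point: bit-score must exceed 50, alignments must cover at least half of
#' both sequences, orthologs are called at \eqn{\Omega = 20}, and groups are
#' clustered at inflation 2.
#'
#' @param species_table Path to the 2-column species table
#'   (protein_id, species_id).
#' @param hits Path to the 12-column tabular hit file.
#' @param fasta,lengths Exactly one of: a protein FASTA path, or a 2-column
#'   length table path.
#' @param annotations Optional annotation TSV (see
#'   [read_annotation_table()]).
#' @param out_dir Output directory (created if needed).
#' @param omega Ortholog-call cutoff (default 20).
#' @param bit_threshold,coverage_threshold Quality-filter thresholds.
#' @param inflation MCL inflation (> 1).
#' @param missing_policy `"skip"` or `"impute_zero"`; see
#'   [quartet_witnesses()].
#' @param min_species Minimum species per orthologous group.
#' @param consensus_threshold,consensus_denominator See [annotate_groups()].
#' @param seed Integer seed recorded in the run report (the pipeline itself
#'   is deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(species_table, hits, fasta = NULL, lengths = NULL,
                            annotations = NULL, out_dir = ".",
                            omega = 20, bit_threshold = 50,
                            coverage_threshold = 0.5, inflation = 2,
                            missing_policy = c("skip", "impute_zero"),
                            min_species = 3, consensus_threshold = 0.8,
                            consensus_denominator = c("all", "annotated"),
                            seed = 1L) {
  if (is.null(fasta) == is.null(lengths)) {
    abort("provide exactly one of fasta or lengths")
  }
  if (coverage_threshold < 0 || coverage_threshold > 1) {
    abort("coverage_threshold must be in [0, 1]")
  }
  if (inflation <= 1) abort("inflation must be > 1")
  structure(
    list(species_table = species_table, hits = hits, fasta = fasta,
         lengths = lengths, annotations = annotations, out_dir = out_dir,
         omega = as.double(omega), bit_threshold = as.double(bit_threshold),
         coverage_threshold = as.double(coverage_threshold),
         inflation = as.double(inflation),
         missing_policy = match.arg(missing_policy),
         min_species = as.integer(min_species),
         consensus_threshold = as.double(consensus_threshold),
         consensus_denominator = match.arg(consensus_denominator),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration
#'
#' JSON round-trip of a [pipeline_config()], used by the command-line
#' wrapper; reading back an identical configuration is lossless.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `read_pipeline_config()` returns the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[!vapply(raw, is.null, logical(1))])
}

# fingerprint of the run parameters; the output location is not part of it
config_hash <- function(config) {
  rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
}

#' Run the whole orthology pipeline
#'
#' Executes every stage in order -- ingest, quality filter, BBH detection,
#' quartet scoring, ortholog calling, Markov clustering into groups,
#' consensus annotation, inparalog detection with co-ortholog expansion --
#' and writes the tabular artifacts plus a machine-readable run report to
#' `config$out_dir`. Identical configuration and inputs produce
#' byte-identical outputs; any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages on stderr?
#' @return A `quartet_result` object: list with `registry`, `store`,
#'   `putative` (BBH pairs), `calls`, `groups`, `inparalogs`,
#'   `co_orthologs`, `report` (stage counts), `config`, `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  # every artifact the run may produce, for cleanup on a failed stage
  artifact_paths <- file.path(config$out_dir, c(
    "pairwise_orthologs.tsv", "groups.tsv", "species_presence.tsv",
    "inparalogs.tsv", "co_orthologs.tsv", "run_report.jsonl"))
  report <- list()
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(
    "[%5.1fs] %s", as.numeric(difftime(Sys.time(), t0, units = "secs")),
    sprintf(...)))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(artifact_paths)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  registry <- stage("ingest", {
    say("ingest: reading registry and hits")
    if (!is.null(config$fasta)) {
      read_fasta_registry(config$fasta, config$species_table,
                          annotations = config$annotations)
    } else {
      read_length_registry(config$lengths, config$species_table,
                           annotations = config$annotations)
    }
  })
  hits <- stage("ingest", read_blast_tab(config$hits, registry))
  report$ingest <- list(n_proteins = nrow(registry),
                        n_species = length(unique(registry$species)),
                        n_hits = nrow(hits))

  filtered <- stage("filter", quality_filter(
    hits, bit_threshold = config$bit_threshold,
    coverage_threshold = config$coverage_threshold))
  report$filter <- list(n_hits_kept = nrow(filtered))

  store <- stage("bbh", build_store(filtered, registry))
  index <- stage("bbh", best_hit_index(store))
  putative <- stage("bbh", bbh_pairs(store, index = index))
  report$bbh <- list(n_stored_pairs = nrow(store$pairs),
                     n_putative = nrow(putative))
  say("bbh: %d putative ortholog pairs", nrow(putative))

  scored <- stage("score", score_quartets(
    store, putative, index = index, missing_policy = config$missing_policy))
  report$score <- list(
    n_with_evidence = sum(!is.na(scored$alpha_max)))

  calls <- stage("call", call_orthologs(scored, omega = config$omega))
  report$call <- list(omega = config$omega,
                      n_orthologs = sum(calls$is_ortholog))
  say("call: %d orthologs at omega = %g", sum(calls$is_ortholog),
      config$omega)

  groups <- stage("cluster", {
    part <- mcl(ortholog_graph(calls), inflation = config$inflation)
    form_groups(part, registry, min_species = config$min_species)
  })
  report$cluster <- list(n_groups = nrow(groups),
                         median_group_size = as.double(median(groups$size)))

  groups <- stage("annotate", annotate_groups(
    groups, registry, threshold = config$consensus_threshold,
    denominator = config$consensus_denominator))
  report$annotate <- list(
    n_with_symbol = sum(!is.na(groups$consensus_symbol)),
    n_with_description = sum(!is.na(groups$consensus_description)))

  inpar <- stage("inparalogs", inparalog_groups(store))
  coorth <- stage("inparalogs", co_orthologs(calls, inpar))
  report$inparalogs <- list(n_groups = nrow(inpar),
                            n_co_ortholog_pairs = nrow(coorth))
  say("inparalogs: %d groups", nrow(inpar))

  files <- stage("write",
                 write_outputs(config, calls, groups, inpar, coorth, report))
  structure(
    list(registry = registry, store = store, putative = putative,
         calls = calls, groups = groups, inparalogs = inpar,
         co_orthologs = coorth, report = report, config = config,
         files = files),
    class = "quartet_result"
  )
}

write_outputs <- function(config, calls, groups, inpar, coorth, report) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  header <- c(
    sprintf("# orthoquartet %s",
            as.character(utils::packageVersion("orthoquartet"))),
    sprintf("# config_hash %s", hash)
  )
  out <- function(name) file.path(config$out_dir, name)
  write_tsv_commented <- function(df, path) {
    body <- readr::format_tsv(df, na = "NA")
    readr::write_lines(c(header, sub("\n$", "", body)), path)
    path
  }
  files <- character(0)
  files <- c(files, write_tsv_commented(
    tibble(protein_x = calls$x, protein_y = calls$y,
           species_x = calls$species_x, species_y = calls$species_y,
           similarity = calls$similarity, alpha_max = calls$alpha_max,
           is_ortholog_at_omega = calls$is_ortholog),
    out("pairwise_orthologs.tsv")))
  files <- c(files, write_tsv_commented(
    tibble(group_id = groups$group_id, size = groups$size,
           species_count = groups$species_count,
           species = purrr::map_chr(groups$species, paste, collapse = ";"),
           members = purrr::map_chr(groups$members, paste, collapse = ";"),
           consensus_symbol = groups$consensus_symbol,
           consensus_description = groups$consensus_description,
           consensus_go = purrr::map_chr(groups$consensus_go, paste,
                                         collapse = ";")),
    out("groups.tsv")))
  files <- c(files, write_tsv_commented(
    species_presence(groups), out("species_presence.tsv")))
  files <- c(files, write_tsv_commented(
    tibble(species = inpar$species, group_index = inpar$group_index,
           members = purrr::map_chr(inpar$members, paste, collapse = ";"),
           min_internal = inpar$min_internal,
           max_external = inpar$max_external),
    out("inparalogs.tsv")))
  files <- c(files, write_tsv_commented(coorth, out("co_orthologs.tsv")))

  report_path <- out("run_report.jsonl")
  head_rec <- list(record = "run", tool = "orthoquartet",
                   version = as.character(
                     utils::packageVersion("orthoquartet")),
                   config_hash = hash, seed = config$seed)
  stage_recs <- purrr::imap(report, ~ c(list(record = "stage", stage = .y), .x))
  readr::write_lines(
    vapply(c(list(head_rec), stage_recs),
           function(r) jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA),
           character(1)),
    report_path)
  c(files, report_path)
}

#' @export
print.quartet_result <- function(x, ...) {
  cat("<quartet_result>\n")
  cat(sprintf("  proteins: %d  species: %d\n", x$report$ingest$n_proteins,
              x$report$ingest$n_species))
  cat(sprintf("  putative pairs: %d  orthologs (omega = %g): %d\n",
              x$report$bbh$n_putative, x$config$omega,
              x$report$call$n_orthologs))
  cat(sprintf("  orthologous groups: %d  inparalog groups: %d\n",
              x$report$cluster$n_groups, x$report$inparalogs$n_groups))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `quartet_result`.
#' @param ... Unused.
#' @method tidy quartet_result
#' @export
tidy.quartet_result <- function(x, ...) tidy(x$calls)

#' @rdname run_pipeline
#' @method glance quartet_result
#' @export
glance.quartet_result <- function(x, ...) {
  tibble(
    n_proteins = x$report$ingest$n_proteins,
    n_species = x$report$ingest$n_species,
    n_putative = x$report$bbh$n_putative,
    omega = x$config$omega,
    n_orthologs = x$report$call$n_orthologs,
    n_groups = x$report$cluster$n_groups,
    median_group_size = x$report$cluster$median_group_size,
    n_inparalog_groups = x$report$inparalogs$n_groups
  )
}

#' Write a simulated corpus in the pipeline's input formats
#'
#' Emits the species table, length table and a synthetic 12-column tabular
#' hit file (both directions per stored pair, full-length alignments), plus
#' the ground-truth labels and Newick trees, so a simulated corpus can be
#' consumed through exactly the same file interface as real data.
#'
#' @param corpus An [simulate_corpus()] object.
#' @param dir Output directory.
#' @return Named character vector of the file paths written (elements
#'   `species_table`, `lengths`, `hits`, `truth_pairs`, `truth_inparalogs`,
#'   `species_tree`, `gene_trees`).
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- corpus$registry
  p <- corpus$store$pairs
  paths <- c(
    species_table = file.path(dir, "species_table.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    hits = file.path(dir, "hits.tsv"),
    truth_pairs = file.path(dir, "truth_pairs.tsv"),
    truth_inparalogs = file.path(dir, "truth_inparalogs.tsv"),
    species_tree = file.path(dir, "species_tree.nwk"),
    gene_trees = file.path(dir, "gene_trees.nwk")
  )
  readr::write_lines(paste(reg$id, reg$species, sep = "\t"),
                     paths[["species_table"]])
  readr::write_lines(paste(reg$id, reg$length, sep = "\t"),
                     paths[["lengths"]])
  len <- setNames(reg$length, reg$id)
  one_way <- function(q, s) {
    sprintf("%s\t%s\t50.00\t%d\t0\t0\t1\t%d\t1\t%d\t1e-50\t%.6f",
            q, s, len[q], len[q], len[s], p$score)
  }
  readr::write_lines(c(one_way(p$p1, p$p2), one_way(p$p2, p$p1)),
                     paths[["hits"]])
  readr::write_tsv(corpus$truth$pair_labels, paths[["truth_pairs"]],
                   progress = FALSE)
  ti <- corpus$truth$inparalog_sets
  readr::write_tsv(
    tibble(species = ti$species,
           members = purrr::map_chr(ti$members, paste, collapse = ";")),
    paths[["truth_inparalogs"]], progress = FALSE)
  ape::write.tree(corpus$species_tree, paths[["species_tree"]])
  readr::write_lines(vapply(corpus$families, family_newick, character(1)),
                     paths[["gene_trees"]])
  paths
}
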