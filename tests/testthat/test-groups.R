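toy_registry <- function(species, annotations = NULL) {
  read_length_registry(
    data.frame(protein_id = names(species), length = 100L),
    data.frame(protein_id = names(species), species_id = unname(species)),
    annotations = annotations
  )
}

test_that("only clusters spanning three or more species become groups", {
  species <- c(a1 = "A", b1 = "B", c1 = "C", a2 = "A", b2 = "B",
               a3 = "A", a4 = "A", b3 = "B", c2 = "C", d1 = "D")
  reg <- toy_registry(species)
  partition <- tibble::tibble(
    node = names(species),
    cluster = c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4)
  )
  groups <- form_groups(partition, reg)
  # cluster 3 spans {A,B,C}, size 4 -> QTS_1; cluster 1 spans {A,B,C} size 3
  expect_equal(groups$group_id, c("QTS_1", "QTS_2"))
  expect_equal(groups$size, c(4L, 3L))
  expect_equal(groups$species_count, c(3L, 3L))
  expect_equal(groups$members[[2]], c("a1", "b1", "c1"))
})

test_that("consensus needs strictly more than the threshold share of all members", {
  species <- setNames(rep(c("A", "B", "C"), length.out = 11),
                      sprintf("p%02d", 1:11))
  ann <- tibble::tibble(
    protein_id = sprintf("p%02d", 1:11),
    gene_symbol = c(rep("recA", 4), NA,              # 4/5 in group 1
                    rep("gyrB", 5), NA),             # 5/6 in group 2
    description = c(rep("recombinase A", 4), NA,
                    rep("DNA gyrase subunit B", 5), NA),
    go_terms = c(rep(list("GO:0003677"), 4), list(character(0)),
                 rep(list("GO:0003918"), 5), list(character(0)))
  )
  reg <- toy_registry(species, annotations = ann)
  partition <- tibble::tibble(node = sprintf("p%02d", 1:11),
                              cluster = c(rep(1, 5), rep(2, 6)))
  groups <- annotate_groups(form_groups(partition, reg), reg)
  g5 <- groups[groups$size == 5, ]
  g6 <- groups[groups$size == 6, ]
  expect_true(is.na(g5$consensus_symbol))        # 0.8 is not > 0.8
  expect_equal(g5$consensus_go[[1]], character(0))
  expect_equal(g6$consensus_symbol, "gyrB")      # 0.833 > 0.8
  expect_equal(g6$consensus_description, "DNA gyrase subunit B")
  expect_equal(g6$consensus_go[[1]], "GO:0003918")
})

test_that("wholly unannotated groups get no consensus on any facet", {
  species <- c(q1 = "A", q2 = "B", q3 = "C")
  reg <- toy_registry(species)
  groups <- annotate_groups(
    form_groups(tibble::tibble(node = names(species), cluster = 1), reg),
    reg)
  expect_true(is.na(groups$consensus_symbol))
  expect_true(is.na(groups$consensus_description))
  expect_equal(groups$consensus_go[[1]], character(0))
})

test_that("the annotated-only denominator is available as an alternative", {
  species <- c(r1 = "A", r2 = "B", r3 = "C", r4 = "D", r5 = "E")
  ann <- tibble::tibble(
    protein_id = c("r1", "r2", "r3", "r4"),
    gene_symbol = c("ftsZ", "ftsZ", "ftsZ", "ftsZ"),
    description = NA_character_,
    go_terms = rep(list(character(0)), 4)
  )
  reg <- toy_registry(species, annotations = ann)
  groups <- form_groups(tibble::tibble(node = names(species), cluster = 1),
                        reg)
  expect_true(is.na(annotate_groups(groups, reg)$consensus_symbol))  # 4/5
  expect_equal(
    annotate_groups(groups, reg, denominator = "annotated")$consensus_symbol,
    "ftsZ")                                                          # 4/4
})

demo_groups <- function() {
  tibble::tibble(
    group_id = paste0("QTS_", 1:4),
    size = c(4L, 3L, 3L, 5L),
    species_count = c(4L, 3L, 3L, 3L),
    members = list(letters[1:4], letters[5:7], letters[8:10], letters[11:15]),
    species = list(c("A", "B", "C", "D"), c("A", "B", "C"),
                   c("B", "C", "E"), c("C", "D", "E")),
    consensus_symbol = c("tert", NA, "recA", NA),
    consensus_description = c("telomerase reverse transcriptase",
                              NA, "recombinase A", "hypothetical protein"),
    consensus_go = list(character(0), character(0), character(0), character(0))
  )
}

test_that("group queries honour ANY/ALL semantics and text filters", {
  g <- demo_groups()
  expect_equal(query_groups(g, c("A", "B", "C"), "all")$group_id,
               c("QTS_1", "QTS_2"))
  expect_equal(query_groups(g, "E", "any")$group_id, c("QTS_3", "QTS_4"))
  expect_equal(nrow(query_groups(g, "A", "any", text_filter = "dnaC")), 0)
  expect_equal(
    query_groups(g, c("A", "D"), "any", text_filter = "TELOMERASE")$group_id,
    "QTS_1")
  expect_error(query_groups(g, "Zz", "any"), "unknown species")
})

test_that("conservation curves count at-least-n presence and never increase", {
  g <- demo_groups()
  panel <- c("A", "B", "C", "D")
  curve <- conservation_curve(g, panel)
  # brute force: overlaps are 4 (QTS_1), 3 (QTS_2), 2 (QTS_3), 2 (QTS_4)
  expect_equal(curve$n_groups, c(4L, 4L, 2L, 1L))
  expect_true(all(diff(curve$n_groups) <= 0))
  expect_equal(conservation_curve(g, "E")$n_groups, 2L)
  expect_error(conservation_curve(g, character(0)), "non-empty")
})

test_that("the species-presence matrix mirrors group membership", {
  g <- demo_groups()
  m <- species_presence(g)
  expect_equal(names(m), c("group_id", "A", "B", "C", "D", "E"))
  expect_equal(m$A, c(1L, 1L, 0L, 0L))
  expect_equal(m$E, c(0L, 0L, 1L, 1L))
})
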