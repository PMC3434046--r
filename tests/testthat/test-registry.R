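test_that("FASTA registry records lengths and species assignments", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", paste(rep("M", 100), collapse = ""),
               ">p2", paste(rep("ACDEF", 50), collapse = "")), fa)
  reg <- read_fasta_registry(
    fa, data.frame(protein_id = c("p1", "p2"), species_id = "spA"))
  expect_equal(reg$id, c("p1", "p2"))
  expect_equal(sort(reg$length), c(100L, 250L))
  expect_equal(unique(reg$species), "spA")
})

test_that("empty FASTA yields an empty registry without error", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(character(0), fa)
  reg <- read_fasta_registry(
    fa, data.frame(protein_id = character(0), species_id = character(0)))
  expect_equal(nrow(reg), 0)
})

test_that("duplicate and unassigned identifiers are hard errors naming the id", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">dupX", "MKV", ">dupX", "MKVL"), fa)
  expect_error(
    read_fasta_registry(fa, data.frame(protein_id = "dupX",
                                       species_id = "spA")),
    "dupX")
  fa2 <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1", "MKV", ">orphan", "MKVL"), fa2)
  expect_error(
    read_fasta_registry(fa2, data.frame(protein_id = "p1",
                                        species_id = "spA")),
    "orphan")
})

test_that("length-table registry bypasses FASTA and validates the same way", {
  reg <- read_length_registry(
    data.frame(protein_id = c("b", "a"), length = c(7L, 3L)),
    data.frame(protein_id = c("a", "b"), species_id = c("s1", "s2")))
  expect_equal(reg$id, c("a", "b"))          # deterministic order by id
  expect_equal(reg$length, c(3L, 7L))
  expect_error(
    read_length_registry(
      data.frame(protein_id = c("a", "a"), length = c(3L, 3L)),
      data.frame(protein_id = "a", species_id = "s1")),
    "a")
})

test_that("tabular hits yield inclusive-span coverage fractions", {
  reg <- read_length_registry(
    data.frame(protein_id = c("q", "s"), length = c(100L, 200L)),
    data.frame(protein_id = c("q", "s"), species_id = c("A", "B")))
  f <- withr::local_tempfile()
  write_blast_rows(list(
    blast_row("q", "s", 75, qstart = 1, qend = 50, sstart = 1, send = 100),
    blast_row("q", "s", 80, qstart = 50, qend = 1, sstart = 200, send = 101)
  ), f)
  hits <- read_blast_tab(f, reg)
  expect_equal(hits$query_cover, c(0.5, 0.5))      # reversed span identical
  expect_equal(hits$subject_cover, c(0.5, 0.5))
  expect_equal(hits$bit_score, c(75, 80))
})

test_that("malformed rows and unknown ids are rejected with the line number", {
  reg <- read_length_registry(
    data.frame(protein_id = "q", length = 100L),
    data.frame(protein_id = "q", species_id = "A"))
  f <- withr::local_tempfile()
  writeLines(c("# comment", "q\tq\tonly-three-cols"), f)
  expect_error(read_blast_tab(f, reg), "line 2")
  f2 <- withr::local_tempfile()
  write_blast_rows(list(blast_row("q", "ghost", 80)), f2)
  expect_error(read_blast_tab(f2, reg), "ghost")
  f3 <- withr::local_tempfile()
  row <- blast_row("q", "q", 80); row[12] <- "not-a-number"
  write_blast_rows(list(row), f3)
  expect_error(read_blast_tab(f3, reg), "line 1")
})

test_that("annotation tables attach facets to the registry", {
  ann <- tibble::tibble(
    protein_id = "a", gene_symbol = "recA",
    description = "recombinase A",
    go_terms = list(c("GO:0003677", "GO:0006281"))
  )
  reg <- read_length_registry(
    data.frame(protein_id = c("a", "b"), length = 10L),
    data.frame(protein_id = c("a", "b"), species_id = "s1"),
    annotations = ann)
  expect_equal(reg$gene_symbol, c("recA", NA))
  expect_equal(reg$go_terms[[1]], c("GO:0003677", "GO:0006281"))
  expect_equal(reg$go_terms[[2]], character(0))
})
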