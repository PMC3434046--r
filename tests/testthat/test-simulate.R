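test_that("species trees are rooted, binary, seeded, and exponentially branched", {
  t2 <- simulate_species_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  t8a <- simulate_species_tree(8, seed = 5)
  t8b <- simulate_species_tree(8, seed = 5)
  expect_identical(ape::write.tree(t8a), ape::write.tree(t8b))
  expect_equal(t8a$Nnode, 7)            # n - 1 internal nodes, rooted binary
  expect_true(ape::is.rooted(t8a))
  expect_error(simulate_species_tree(1), ">= 2")
})

test_that("without duplication or loss every species carries exactly one gene", {
  tree <- simulate_species_tree(6, seed = 11)
  fam <- simulate_family(tree, dup_rate = 0, loss_rate = 0, seed = 2)
  leaves <- fam$nodes[fam$nodes$type == "leaf", ]
  expect_equal(sort(leaves$species), sort(tree$tip.label))
  truth <- family_truth(fam)
  expect_true(all(truth$pair_labels$label == "ortholog"))
  expect_equal(nrow(truth$inparalog_sets), 0)
  expect_false(any(fam$nodes$type == "duplication"))
})

test_that("truth labels agree with an independent LCA walk on the emitted newick", {
  set.seed(31)
  checked <- 0
  for (rep in 1:12) {
    tree <- simulate_species_tree(5)
    fam <- simulate_family(tree, dup_rate = 0.5, loss_rate = 0.2,
                           family_id = sprintf("f%d", rep))
    truth <- family_truth(fam)
    if (nrow(truth$pair_labels) == 0) next
    phy <- ape::read.tree(text = family_newick(fam))
    dmat <- ape::cophenetic.phylo(phy)
    for (k in seq_len(nrow(truth$pair_labels))) {
      x <- truth$pair_labels$x[k]; y <- truth$pair_labels$y[k]
      if (length(phy$tip.label) > 2) {
        mrca <- ape::getMRCA(phy, c(x, y))
        lab <- phy$node.label[mrca - length(phy$tip.label)]
        expect_equal(truth$pair_labels$label[k],
                     if (lab == "S") "ortholog" else "paralog")
      }
      expect_equal(truth$pair_labels$distance[k], dmat[x, y],
                   tolerance = 1e-6)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("a stem duplication makes all cross-subfamily pairs paralogs", {
  # this draw places its single duplication on the stem above the root and
  # loses nothing, so both sub-families reach all four species
  tree <- simulate_species_tree(4, seed = 3)
  fam <- simulate_family(tree, dup_rate = 0.4, loss_rate = 0, seed = 61,
                         stem_length = 3)
  dups <- which(fam$nodes$type == "duplication")
  expect_equal(length(dups), 1)
  expect_equal(fam$nodes$sp_node[dups], length(tree$tip.label) + 1L)
  expect_equal(sum(fam$nodes$type == "leaf"), 8)
  truth <- family_truth(fam)$pair_labels
  same_sp <- truth$species_x == truth$species_y
  expect_true(all(truth$label[same_sp] == "paralog"))
  # the two sub-families are mutual paralogs across species, orthologs within
  expect_equal(sum(truth$label == "paralog" & !same_sp), 12)
  expect_equal(sum(truth$label == "ortholog"), 12)
})

test_that("similarities decay monotonically with distance and reproduce under a seed", {
  tree <- simulate_species_tree(5, seed = 21)
  fam <- simulate_family(tree, 0.3, 0.1, seed = 4)
  truth <- family_truth(fam)$pair_labels
  sim1 <- similarities_from_families(fam, noise_sd = 0, seed = 9)
  sim2 <- similarities_from_families(fam, noise_sd = 0, seed = 9)
  expect_identical(sim1$store$pairs, sim2$store$pairs)
  s <- store_lookup(sim1$store, truth$x, truth$y)
  ok <- !is.na(s)
  expect_gt(sum(ok), 3)
  # noise-free: exact exponential decay in gene-tree distance
  expect_equal(s[ok], 500 * exp(-0.2 * truth$distance[ok]))
  expect_true(all(s[ok] > 50))     # below-threshold pairs were omitted
  expect_true(all(500 * exp(-0.2 * truth$distance[!ok]) <= 50))
})

test_that("corpus simulation is reproducible end to end under one seed", {
  c1 <- simulate_corpus(4, 5, seed = 77)
  c2 <- simulate_corpus(4, 5, seed = 77)
  expect_identical(c1$store$pairs, c2$store$pairs)
  expect_identical(c1$truth, c2$truth)
  expect_identical(ape::write.tree(c1$species_tree),
                   ape::write.tree(c2$species_tree))
})

test_that("benchmarking reproduces hand-computed confusion ratios", {
  truth <- tibble::tibble(
    x = sprintf("a%d", 1:5), y = sprintf("b%d", 1:5),
    label = c("ortholog", "ortholog", "ortholog", "ortholog", "paralog"))
  calls <- tibble::tibble(
    x = sprintf("a%d", 1:5), y = sprintf("b%d", 1:5),
    is_ortholog = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  b <- benchmark_orthologs(calls, truth)
  expect_equal(b$tp, 3); expect_equal(b$fp, 1); expect_equal(b$fn, 1)
  expect_equal(b$precision, 0.75)
  expect_equal(b$recall, 0.75)
  none <- benchmark_orthologs(
    dplyr::mutate(calls, is_ortholog = FALSE), truth)
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  expect_error(
    benchmark_orthologs(calls,
                        tibble::tibble(x = "zz1", y = "zz2",
                                       label = "ortholog")),
    "share no proteins")
})

test_that("cutoff sweeps report non-decreasing coverage", {
  set.seed(15)
  corpus <- simulate_corpus(6, 8, dup_rate = 0.3, loss_rate = 0.1)
  idx <- best_hit_index(corpus$store)
  sc <- score_quartets(corpus$store, bbh_pairs(corpus$store, index = idx),
                       index = idx)
  sweep <- omega_sweep(sc, c(-50, 0, 20, 50, Inf),
                       truth = corpus$truth$pair_labels)
  expect_true(all(diff(sweep$n_called) >= 0))
  expect_s3_class(autoplot(sweep), "ggplot")
})
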