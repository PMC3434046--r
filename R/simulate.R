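#' Simulate a random rooted species tree
#'
#' A random rooted binary coalescent tree: exponentially distributed
#' inter-coalescence times, hence an ultrametric (clock-like) tree, the
#' scaffold along which gene families are evolved. The clock matters: with
#' equal-rate divergence, similarity rank order mirrors node-time order, so
#' "more similar within the species than to any other species" coincides
#' with "duplicated after the last speciation" -- the premise of inparalog
#' detection. Tips are labelled `sp01`, `sp02`, ...
#'
#' @param n_species Number of species (>= 2).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so corpus-level simulation can drive everything from one seed).
#' @param depth_scale Multiplier applied to all branch lengths (default 1).
#' @return An ultrametric `phylo` object (see [ape::rcoal()]).
#' @export
simulate_species_tree <- function(n_species, seed = NULL, depth_scale = 1) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rcoal(n_species,
                     tip.label = sprintf("sp%02d", seq_len(n_species)))
  tree$edge.length <- tree$edge.length * depth_scale
  tree
}

#' Simulate one gene family by duplication and loss on a species tree
#'
#' A single ancestral gene enters a stem branch above the species-tree root
#' and evolves downwards: along every branch it duplicates at rate
#' `dup_rate` and is lost at rate `loss_rate` (per unit branch length, per
#' lineage); at every species-tree node each surviving lineage splits into
#' the daughter species (a *speciation* node of the gene tree), and each
#' duplication leaves a *duplication* node. Lineages reaching a tip become
#' genes of that species. Extinct subtrees are pruned and single-child
#' nodes suppressed, so the returned gene tree is binary with every internal
#' node labelled speciation or duplication -- the labels from which
#' ground-truth orthology is read off (see [family_truth()]).
#'
#' @param species_tree A `phylo` species tree with branch lengths.
#' @param dup_rate,loss_rate Event rates (>= 0).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param family_id Identifier woven into gene ids (`<species>|<family>_g<k>`).
#' @param stem_length Length of the stem branch above the root (default 1),
#'   on which pre-speciation duplications can occur.
#' @return A `gene_family` object: list with `nodes` (tibble: `id`,
#'   `parent`, `type`, `time`, `species`, `sp_node`, `gene`), `species_tree`,
#'   `family_id` and `params`. Leaves carry gene ids; `time` is the distance
#'   from the top of the stem, so gene-tree path lengths are differences of
#'   `time` through the most recent common ancestor.
#' @export
simulate_family <- function(species_tree, dup_rate, loss_rate, seed = NULL,
                            family_id = "f1", stem_length = 1) {
  if (dup_rate < 0 || loss_rate < 0) abort("rates must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(species_tree$tip.label)
  root <- n_tip + 1L
  kids <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  blen <- setNames(species_tree$edge.length, species_tree$edge[, 2])

  env <- new.env(parent = emptyenv())
  env$parent <- integer(0); env$type <- character(0)
  env$time <- double(0); env$species <- character(0); env$sp_node <- integer(0)
  add_node <- function(parent, type, time, species, sp_node) {
    k <- length(env$parent) + 1L
    env$parent[k] <- parent; env$type[k] <- type; env$time[k] <- time
    env$species[k] <- species; env$sp_node[k] <- sp_node
    k
  }

  at_sp_node <- function(sp_node, gene_parent, t_abs) {
    if (sp_node <= n_tip) {
      add_node(gene_parent, "leaf", t_abs,
               species_tree$tip.label[sp_node], sp_node)
      return(invisible())
    }
    g <- add_node(gene_parent, "speciation", t_abs, NA_character_, sp_node)
    for (child in kids[[as.character(sp_node)]]) {
      evolve_branch(child, blen[[as.character(child)]], g, t_abs)
    }
  }

  evolve_branch <- function(sp_bottom, remaining, gene_parent, t_abs) {
    total <- dup_rate + loss_rate
    repeat {
      wait <- if (total > 0) rexp(1, total) else Inf
      if (wait >= remaining) {
        at_sp_node(sp_bottom, gene_parent, t_abs + remaining)
        return(invisible())
      }
      t_abs <- t_abs + wait
      remaining <- remaining - wait
      if (runif(1) < dup_rate / total) {
        g <- add_node(gene_parent, "duplication", t_abs, NA_character_,
                      sp_bottom)
        evolve_branch(sp_bottom, remaining, g, t_abs)
        gene_parent <- g   # second copy continues in this loop
      } else {
        return(invisible()) # loss
      }
    }
  }

  evolve_branch(root, stem_length, NA_integer_, 0)
  nodes <- prune_gene_tree(env)
  if (nrow(nodes) > 0) {
    is_leaf <- nodes$type == "leaf"
    nodes$gene <- NA_character_
    nodes$gene[is_leaf] <- sprintf("%s|%s_g%d", nodes$species[is_leaf],
                                   family_id, seq_len(sum(is_leaf)))
  } else {
    nodes$gene <- character(0)
  }
  structure(
    list(nodes = nodes, species_tree = species_tree, family_id = family_id,
         params = list(dup_rate = dup_rate, loss_rate = loss_rate,
                       stem_length = stem_length)),
    class = "gene_family"
  )
}

# drop extinct subtrees, suppress single-child internal nodes; node creation
# order guarantees parent id < child id, so a single increasing pass works
prune_gene_tree <- function(env) {
  n <- length(env$parent)
  empty <- tibble(id = integer(0), parent = integer(0), type = character(0),
                  time = double(0), species = character(0),
                  sp_node = integer(0))
  if (n == 0) return(empty)
  surv <- env$type == "leaf"
  for (k in rev(seq_len(n))) {
    if (surv[k] && !is.na(env$parent[k])) surv[env$parent[k]] <- TRUE
  }
  nkids <- tabulate(env$parent[surv & !is.na(env$parent)], nbins = n)
  keep <- surv & (env$type == "leaf" | nkids >= 2)
  if (!any(keep)) return(empty)
  eff_parent <- function(k) {
    p <- env$parent[k]
    while (!is.na(p) && !keep[p]) p <- env$parent[p]
    p
  }
  ids <- which(keep)
  tibble(
    id = ids,
    parent = vapply(ids, eff_parent, integer(1)),
    type = env$type[ids],
    time = env$time[ids],
    species = env$species[ids],
    sp_node = env$sp_node[ids]
  )
}

#' @export
print.gene_family <- function(x, ...) {
  nl <- sum(x$nodes$type == "leaf")
  nd <- sum(x$nodes$type == "duplication")
  cat(sprintf("<gene_family %s> %d genes in %d species, %d duplication node(s)\n",
              x$family_id, nl, length(unique(stats::na.omit(x$nodes$species))),
              nd))
  invisible(x)
}

# most recent common ancestor of two node ids in the pruned table
family_lca <- function(nodes, a, b) {
  parent_of <- setNames(nodes$parent, nodes$id)
  anc <- integer(0)
  k <- a
  while (!is.na(k)) { anc <- c(anc, k); k <- parent_of[[as.character(k)]] }
  k <- b
  while (!is.na(k)) {
    if (k %in% anc) return(k)
    k <- parent_of[[as.character(k)]]
  }
  NA_integer_
}

#' Ground-truth orthology labels of a simulated family
#'
#' Reads the truth off the labelled gene tree: a pair of genes is
#' *orthologous* when its most recent common ancestor is a speciation node
#' and *paralogous* when it is a duplication (two genes of the same species
#' are always paralogs). True inparalog sets are the same-species gene sets
#' whose pairwise common ancestors are duplications with no speciation node
#' below them in the pruned gene tree -- duplications more recent than the
#' last speciation that left surviving descendants on its other side (a
#' speciation whose other side went wholly extinct is unobservable and has
#' been suppressed during pruning).
#'
#' @param family A [simulate_family()] object.
#' @return A list with `pair_labels` (tibble `x`, `y`, `species_x`,
#'   `species_y`, `label`, `distance`) over all unordered gene pairs of the
#'   family, and `inparalog_sets` (tibble `species`, `members`).
#' @export
family_truth <- function(family) {
  nodes <- family$nodes
  leaves <- nodes[nodes$type == "leaf", ]
  empty_pairs <- tibble(x = character(0), y = character(0),
                        species_x = character(0), species_y = character(0),
                        label = character(0), distance = double(0))
  empty_inpar <- tibble(species = character(0), members = list())
  if (nrow(leaves) < 2) {
    return(list(pair_labels = empty_pairs, inparalog_sets = empty_inpar))
  }
  type_of <- setNames(nodes$type, nodes$id)
  time_of <- setNames(nodes$time, nodes$id)

  idx <- utils::combn(seq_len(nrow(leaves)), 2)
  lca <- purrr::map2_int(idx[1, ], idx[2, ],
                         ~ family_lca(nodes, leaves$id[.x], leaves$id[.y]))
  a <- leaves[idx[1, ], ]; b <- leaves[idx[2, ], ]
  pair_labels <- tibble(
    x = pmin(a$gene, b$gene),
    y = pmax(a$gene, b$gene),
    species_x = ifelse(a$gene <= b$gene, a$species, b$species),
    species_y = ifelse(a$gene <= b$gene, b$species, a$species),
    label = unname(ifelse(type_of[as.character(lca)] == "speciation",
                          "ortholog", "paralog")),
    distance = a$time + b$time - 2 * unname(time_of[as.character(lca)])
  )

  # inparalog sets: union same-species pairs whose LCA is a duplication with
  # only duplications on the paths down to both genes (the relation is
  # transitive within a species)
  parent_of <- setNames(nodes$parent, nodes$id)
  dup_path <- function(leaf, top) {
    k <- parent_of[[as.character(leaf)]]
    while (!is.na(k) && k != top) {
      if (type_of[[as.character(k)]] != "duplication") return(FALSE)
      k <- parent_of[[as.character(k)]]
    }
    TRUE
  }
  same_sp <- a$species == b$species
  recent_dup <- same_sp & type_of[as.character(lca)] == "duplication" &
    purrr::pmap_lgl(
      list(a$id, b$id, lca),
      function(ia, ib, l) dup_path(ia, l) && dup_path(ib, l)
    )
  inpar <- empty_inpar
  if (any(recent_dup)) {
    grp <- setNames(leaves$gene, leaves$gene)
    find <- function(g) { while (grp[[g]] != g) g <- grp[[g]]; g }
    for (k in which(recent_dup)) {
      ra <- find(a$gene[k]); rb <- find(b$gene[k])
      if (ra != rb) grp[[max(ra, rb)]] <- min(ra, rb)
    }
    roots <- vapply(leaves$gene, find, character(1))
    sets <- split(leaves$gene, roots)
    sets <- sets[lengths(sets) >= 2]
    if (length(sets) > 0) {
      sets <- sets[order(vapply(sets, min, character(1)))]
      inpar <- tibble(
        species = vapply(sets, function(g) {
          leaves$species[match(g[1], leaves$gene)]
        }, character(1)),
        members = purrr::map(sets, ~ sort(unname(.x)))
      )
    }
  }
  list(pair_labels = pair_labels, inparalog_sets = inpar)
}

#' Similarity store of a simulated family or corpus
#'
#' Maps gene-tree path distance to a bit-score-like similarity,
#' `S = max(0, s0 * exp(-decay * d) + e)` with Gaussian noise `e`, drawn
#' once per unordered pair so the store is symmetric by construction. Pairs
#' whose similarity does not exceed `min_score` are omitted, mimicking hits
#' that fall below the corpus-wide bit-score filter; all simulated
#' alignments are full-length (coverage 1).
#'
#' @param families A `gene_family` or list of them (one store is built over
#'   their union; genes of different families share no similarity).
#' @param s0 Similarity at distance zero (default 500, the bit-score scale
#'   of a strong full-length protein hit).
#' @param decay Exponential decay per unit branch length (default 0.2).
#' @param noise_sd Standard deviation of the additive noise (default 10; use
#'   0 for noise-free runs).
#' @param min_score Similarities must exceed this to be stored (default 50,
#'   matching the default [quality_filter()] threshold).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param protein_length Registry length given to every simulated gene.
#' @return A list with `store` (a `similarity_store`) and `registry`.
#' @export
similarities_from_families <- function(families, s0 = 500, decay = 0.2,
                                       noise_sd = 10, min_score = 50,
                                       seed = NULL, protein_length = 300) {
  if (s0 <= 0 || decay <= 0 || noise_sd < 0) {
    abort("require s0 > 0, decay > 0, noise_sd >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  if (inherits(families, "gene_family")) families <- list(families)

  regs <- purrr::map_dfr(families, function(fam) {
    lv <- fam$nodes[fam$nodes$type == "leaf", ]
    tibble(id = lv$gene, species = lv$species)
  })
  registry <- build_registry(
    tibble(id = regs$id, length = protein_length),
    tibble(protein_id = regs$id, species_id = regs$species),
    annotations = NULL
  )

  pairs <- purrr::map_dfr(families, function(fam) {
    truth <- family_truth(fam)$pair_labels
    if (nrow(truth) == 0) return(NULL)
    s <- s0 * exp(-decay * truth$distance)
    if (noise_sd > 0) s <- s + rnorm(length(s), 0, noise_sd)
    s <- pmax(0, s)
    keep <- s > min_score
    tibble(p1 = truth$x[keep], p2 = truth$y[keep], score = s[keep])
  })
  if (nrow(pairs) == 0) {
    pairs <- tibble(p1 = character(0), p2 = character(0), score = double(0))
  }
  sp <- registry_species(registry)
  pairs <- dplyr::arrange(pairs, .data$p1, .data$p2)
  pairs$species1 <- unname(sp[pairs$p1])
  pairs$species2 <- unname(sp[pairs$p2])
  list(store = new_store(pairs, registry), registry = registry)
}

#' Simulate a whole test corpus with ground truth
#'
#' Draws a species tree, evolves `n_families` independent gene families on
#' it, and emits the merged similarity store plus the truth labels every
#' pipeline stage can be scored against. All randomness flows from the
#' single `seed`.
#'
#' @inheritParams simulate_family
#' @inheritParams similarities_from_families
#' @param n_species Number of species.
#' @param n_families Number of independent gene families.
#' @param seed Integer seed for the whole corpus.
#' @return An `ortholog_corpus` object: list with `store`, `registry`,
#'   `truth` (`pair_labels`, `inparalog_sets`), `species_tree`, `families`,
#'   `params`.
#' @export
simulate_corpus <- function(n_species, n_families, dup_rate = 0.3,
                            loss_rate = 0.1, s0 = 500, decay = 0.2,
                            noise_sd = 10, min_score = 50, stem_length = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_species_tree(n_species)
  families <- purrr::map(seq_len(n_families), function(i) {
    simulate_family(tree, dup_rate, loss_rate,
                    family_id = sprintf("f%03d", i),
                    stem_length = stem_length)
  })
  sim <- similarities_from_families(families, s0 = s0, decay = decay,
                                    noise_sd = noise_sd,
                                    min_score = min_score)
  truth_pairs <- purrr::map_dfr(families, ~ family_truth(.x)$pair_labels)
  truth_inpar <- purrr::map_dfr(families, ~ family_truth(.x)$inparalog_sets)
  structure(
    list(store = sim$store, registry = sim$registry,
         truth = list(pair_labels = truth_pairs,
                      inparalog_sets = truth_inpar),
         species_tree = tree, families = families,
         params = list(n_species = n_species, n_families = n_families,
                       dup_rate = dup_rate, loss_rate = loss_rate, s0 = s0,
                       decay = decay, noise_sd = noise_sd,
                       min_score = min_score, stem_length = stem_length,
                       seed = seed)),
    class = "ortholog_corpus"
  )
}

#' @export
print.ortholog_corpus <- function(x, ...) {
  cat(sprintf(
    "<ortholog_corpus> %d species, %d families, %d genes, %d stored pairs\n",
    x$params$n_species, x$params$n_families, nrow(x$registry),
    nrow(x$store$pairs)
  ))
  invisible(x)
}

#' Newick string of a simulated gene tree
#'
#' Internal nodes are labelled `S` (speciation) or `D` (duplication); branch
#' lengths are gene-tree times.
#'
#' @param family A `gene_family`.
#' @return A single Newick string (`";"`-terminated); `"();"` for an empty
#'   family.
#' @export
family_newick <- function(family) {
  nodes <- family$nodes
  if (nrow(nodes) == 0) return("();")
  kids <- split(nodes$id, factor(nodes$parent, levels = nodes$id))
  time_of <- setNames(nodes$time, nodes$id)
  rec <- function(id) {
    row <- nodes[nodes$id == id, ]
    p <- row$parent
    len <- if (is.na(p)) 0 else row$time - time_of[[as.character(p)]]
    if (row$type == "leaf") {
      return(sprintf("%s:%.10g", row$gene, len))
    }
    lab <- if (row$type == "speciation") "S" else "D"
    ch <- kids[[as.character(id)]]
    sprintf("(%s)%s:%.10g", paste(vapply(ch, rec, character(1)), collapse = ","),
            lab, len)
  }
  root <- nodes$id[is.na(nodes$parent)]
  paste0(rec(root[1]), ";")
}
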