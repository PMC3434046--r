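# 5-protein toy quartet: x (species A), y (B), witnesses z1, z2 (C)
quartet_toy <- function(drop = NULL, scores = c(xz1 = 200, yz2 = 300,
                                                xz2 = 80, yz1 = 80,
                                                xy = 120, z1z2 = 90)) {
  pairs <- tibble::tibble(
    p1 = c("x", "y", "x", "y", "x", "z1"),
    p2 = c("z1", "z2", "z2", "z1", "y", "z2"),
    score = unname(scores)
  )
  if (!is.null(drop)) pairs <- pairs[-drop, ]
  toy_store(pairs, c(x = "A", y = "B", z1 = "C", z2 = "C"))
}

test_that("quartet score reproduces hand-evaluated values", {
  expect_equal(quartet_alpha(100, 100, 100, 100, 100, 100), -50)
  expect_equal(quartet_alpha(100, 100, 0, 0, 0, 0), 50)
  expect_equal(quartet_alpha(200, 300, 80, 80, 120, 90), 7.5)
})

test_that("quartet score is exchange-symmetric and scale-equivariant", {
  set.seed(303)
  for (rep in 1:50) {
    s <- runif(6, 0, 500)
    a <- quartet_alpha(s[1], s[2], s[3], s[4], s[5], s[6])
    # swap (x <-> y, z1 <-> z2): same-side mins and cross terms exchange roles
    expect_equal(quartet_alpha(s[2], s[1], s[4], s[3], s[5], s[6]), a)
    cc <- runif(1, 0.1, 10)
    sc <- s * cc
    expect_equal(quartet_alpha(sc[1], sc[2], sc[3], sc[4], sc[5], sc[6]),
                 cc * a)
  }
})

test_that("a complete quartet yields one witness with the computed score", {
  st <- quartet_toy()
  w <- quartet_witnesses(st, "x", "y", "C", best_hit_index(st))
  expect_equal(nrow(w), 1)
  expect_equal(w$z1, "z1"); expect_equal(w$z2, "z2")
  expect_equal(w$alpha, 7.5)
  expect_error(quartet_witnesses(st, "x", "y", "A", best_hit_index(st)),
               "differ")
})

test_that("witnesses vanish when the third species is single-copy or a similarity is missing", {
  # z1 = z2: make z1 the best partner of both x and y
  st1 <- quartet_toy(scores = c(xz1 = 200, yz2 = 100, xz2 = 80, yz1 = 300,
                                xy = 120, z1z2 = 90))
  expect_equal(nrow(quartet_witnesses(st1, "x", "y", "C",
                                      best_hit_index(st1))), 0)
  # drop z1-z2 similarity: skip policy yields no witness, impute-0 scores it
  st2 <- quartet_toy(drop = 6)
  idx2 <- best_hit_index(st2)
  expect_equal(nrow(quartet_witnesses(st2, "x", "y", "C", idx2)), 0)
  w0 <- quartet_witnesses(st2, "x", "y", "C", idx2,
                          missing_policy = "impute_zero")
  expect_equal(w0$alpha, quartet_alpha(200, 300, 80, 80, 120, 0))
})

test_that("max_alpha takes the maximum over witnesses and NA means no evidence", {
  st <- quartet_toy()
  idx <- best_hit_index(st)
  expect_equal(max_alpha(st, "x", "y", idx), 7.5)
  # no third species at all: two-species corpus
  st2 <- toy_store(tibble::tibble(p1 = "x", p2 = "y", score = 100),
                   c(x = "A", y = "B"))
  expect_true(is.na(max_alpha(st2, "x", "y", best_hit_index(st2))))
})

test_that("ortholog calling is inclusive at the cutoff and trusts absent evidence", {
  scored <- tibble::tibble(
    x = c("a", "b", "c"), y = c("d", "e", "f"),
    species_x = "A", species_y = "B", similarity = 100,
    alpha_max = c(20, NA, 20.01)
  )
  calls <- call_orthologs(scored, omega = 20)
  expect_equal(calls$is_ortholog, c(TRUE, TRUE, FALSE))
})

test_that("called sets are nested and non-decreasing in the cutoff", {
  set.seed(404)
  scored <- tibble::tibble(
    x = sprintf("a%02d", 1:40), y = sprintf("b%02d", 1:40),
    alpha_max = c(rnorm(35, 0, 30), rep(NA, 5))
  )
  omegas <- c(-50, -10, 0, 10, 20, 50, Inf)
  prev <- character(0)
  for (om in omegas) {
    cur <- with(call_orthologs(scored, om), paste(x, y)[is_ortholog])
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  expect_equal(length(prev), 40)  # everything called at omega = Inf
})

test_that("max_alpha equals exhaustive enumeration on random small corpora", {
  set.seed(505)
  for (rep in 1:15) {
    rs <- random_store(sample(3:6, 1), sample(2:4, 1), density = 0.7)
    idx <- best_hit_index(rs$store)
    pp <- bbh_pairs(rs$store, index = idx)
    if (nrow(pp) == 0) next
    got <- score_quartets(rs$store, pp, index = idx)
    want <- mapply(function(x, y) oracle_max_alpha(rs$pairs, rs$species, x, y),
                   pp$x, pp$y)
    expect_equal(unname(got$alpha_max), unname(want))
  }
})

test_that("single-copy families across species produce no witnesses at all", {
  set.seed(42)
  corpus <- simulate_corpus(5, 8, dup_rate = 0, loss_rate = 0, noise_sd = 5)
  idx <- best_hit_index(corpus$store)
  pp <- bbh_pairs(corpus$store, index = idx)
  sc <- score_quartets(corpus$store, pp, index = idx)
  expect_true(all(is.na(sc$alpha_max)))
  expect_true(all(call_orthologs(sc, omega = -1e9)$is_ortholog))
})
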