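test_that("the MQVT worked example: layers, edges and state space", {
  g <- build_codon_graph("MQVT")
  expect_identical(lengths(g$layers), c(1L, 2L, 4L, 4L))
  sz <- lengths(g$layers)
  expect_identical(sz[2] * sz[3], 8L)   # Q -> V bipartite block
  expect_identical(sz[3] * sz[4], 16L)  # path extensions into the last layer
  expect_identical(state_space_size(g), 26L)
  expect_identical(candidate_combination_count("MQVT"), "32")
})

test_that("state-space size handles degenerate shapes", {
  expect_identical(state_space_size(build_codon_graph("M")), 0L)
  expect_identical(state_space_size(build_codon_graph(strrep("M", 7))), 6L)
  expect_identical(state_space_size(build_codon_graph("W", append_stop = TRUE)),
                   3L)
})

test_that("stop layers come from append_stop or an explicit trailing '*'", {
  g1 <- build_codon_graph("MQ", append_stop = TRUE)
  g2 <- build_codon_graph("MQ*")
  expect_identical(g1$layers, g2$layers)
  expect_identical(g1$layers[[3]], c("TAA", "TAG", "TGA"))
  res <- optimize_codon_pairs("MQ", RULE_TABLE, "best", append_stop = TRUE)
  expect_identical(translate_cds(res$dna), "MQ*")
  expect_length(res$junction_scores, 2L)
})

test_that("an all-zero table yields score 0 and the lexicographically-first path", {
  zero <- codon_pair_table(
    matrix(0, 64, 64, dimnames = list(all_codons(), all_codons())),
    provenance = "all zeros")
  res <- optimize_codon_pairs("MQVT", zero, "best")
  expect_identical(res$total_score, 0)
  expect_identical(res$codons, c("ATG", "CAA", "GTA", "ACA"))
  expect_gt(res$ties_encountered, 0L)
})

test_that("DP matches exhaustive enumeration on the MQVT example", {
  d <- optimize_codon_pairs("MQVT", RULE_TABLE, "best")
  o <- brute_force_oracle("MQVT", RULE_TABLE, "best")
  expect_identical(o$states_explored, 32L)
  expect_identical(d$total_score, o$total_score)
  expect_identical(d$codons, o$codons)
  expect_identical(d$states_explored, 26L)
})

test_that("oracle equivalence: objective and path agree over seeded trials", {
  for (s in 1:60) {
    p <- unname(random_proteins(1, c(3, 6), seed = 1000 + s))
    tab <- random_pair_table(seed = 2000 + s)
    for (m in c("best", "worst", "unbiased")) {
      d <- optimize_codon_pairs(p, tab, m)
      o <- brute_force_oracle(p, tab, m)
      expect_identical(mode_objective(d), mode_objective(o),
                       label = sprintf("objective seed %d mode %s (%s)", s, m, p))
      if (m != "unbiased") {
        expect_identical(d$codons, o$codons,
                         label = sprintf("path seed %d mode %s (%s)", s, m, p))
      }
    }
  }
})

test_that("worst <= unbiased <= best, and worst is the negated-table best", {
  for (s in 1:25) {
    p <- unname(random_proteins(1, c(3, 8), seed = 500 + s))
    tab <- random_pair_table(seed = 600 + s)
    b <- optimize_codon_pairs(p, tab, "best")$total_score
    w <- optimize_codon_pairs(p, tab, "worst")$total_score
    u <- optimize_codon_pairs(p, tab, "unbiased")$total_score
    expect_lte(w, u)
    expect_lte(u, b)
    expect_identical(w, -optimize_codon_pairs(p, negate_table(tab),
                                              "best")$total_score)
  }
})

test_that("every prefix of a best path is a best path to its end node", {
  for (s in 1:10) {
    p <- unname(random_proteins(1, c(4, 6), seed = 900 + s))
    tab <- random_pair_table(seed = 950 + s)
    res <- optimize_codon_pairs(p, tab, "best")
    g <- build_codon_graph(p)
    for (i in seq_along(res$codons)) {
      prefix <- res$codons[seq_len(i)]
      acc <- if (i == 1) 0 else sum(score_sequence(tab, prefix)$junctions$score)
      j <- match(prefix[i], g$layers[[i]])
      expect_equal(res$dp_scores[[i]][j], acc,
                   label = sprintf("prefix %d seed %d", i, s))
    }
  }
})

test_that("work grows with the state-space sum, not the candidate product", {
  p <- unname(random_proteins(1, c(10, 10), seed = 42))
  single <- optimize_codon_pairs(p, RULE_TABLE, "best")
  doubled <- optimize_codon_pairs(paste0(p, p), RULE_TABLE, "best")
  g <- build_codon_graph(p)
  sz <- lengths(g$layers)
  junction_term <- sz[length(sz)] * sz[1]
  expect_identical(doubled$states_explored,
                   2L * single$states_explored + as.integer(junction_term))
})

test_that("the oracle refuses problems beyond its enumeration cap", {
  err <- tryCatch(brute_force_oracle(strrep("L", 21), RULE_TABLE, "best"),
                  cpo_size_error = function(e) e)
  expect_s3_class(err, "cpo_size_error")
  expect_match(conditionMessage(err), candidate_combination_count(strrep("L", 21)),
               fixed = TRUE)
})

test_that("non-discretized tables optimize correctly with tolerance ties", {
  for (s in 1:10) {
    p <- unname(random_proteins(1, c(3, 5), seed = 4100 + s))
    codons <- all_codons()
    m <- with_seed_matrix(4200 + s)
    tab <- codon_pair_table(m, provenance = "continuous random")
    expect_false(tab$discretized)
    d <- optimize_codon_pairs(p, tab, "best")
    o <- brute_force_oracle(p, tab, "best")
    expect_equal(d$total_score, o$total_score, tolerance = 1e-8)
  }
})
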