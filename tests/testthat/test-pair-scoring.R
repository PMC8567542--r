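test_that("the rule-derived default table encodes the four context rules", {
  tab <- RULE_TABLE
  # the four base-combination rules at the codon junction
  expect_identical(score_pair(tab, "GGT", "ATT"), -1)  # T3-A1 rejected
  expect_identical(score_pair(tab, "GGC", "GAA"), -1)  # C3-G1 rejected
  expect_identical(score_pair(tab, "GGT", "GTT"), 1)   # T3-G1 favored
  expect_identical(score_pair(tab, "GGC", "AAA"), 1)   # C3-A1 favored
  expect_identical(score_pair(tab, "GGA", "GGG"), 0)   # no rule applies
  expect_true(tab$discretized)
})

test_that("rule-table census: each rule fixes one base per codon, 16x16 pairs", {
  cl <- pair_class(RULE_TABLE$scores)
  expect_identical(sum(cl == "rejected"), 512L)
  expect_identical(sum(cl == "preferred"), 512L)
  expect_identical(sum(cl == "neutral"), 3072L)
  # exhaustive: classification must follow the junction bases exactly
  codons <- all_codons()
  last5 <- substr(codons, 3, 3)
  first3 <- substr(codons, 1, 1)
  expected <- outer(last5, first3, function(a, b)
    ifelse((a == "T" & b == "A") | (a == "C" & b == "G"), "rejected",
    ifelse((a == "T" & b == "G") | (a == "C" & b == "A"), "preferred",
           "neutral")))
  expect_identical(unname(cl), unname(expected))
})

test_that("rule magnitudes are applied and validated", {
  tab <- default_rule_table(reject_magnitude = 2, favor_magnitude = 0.5)
  expect_identical(score_pair(tab, "GGT", "ATT"), -2)
  expect_identical(score_pair(tab, "GGT", "GTT"), 0.5)
  expect_error(default_rule_table(reject_magnitude = 0),
               class = "cpo_parameter_error")
  expect_error(default_rule_table(favor_magnitude = -1),
               class = "cpo_parameter_error")
})

test_that("sequence scoring sums junctions and is additive on concatenation", {
  sc <- score_sequence(RULE_TABLE, "ATGCAAGTT")
  expect_identical(sc$total, 0)
  expect_identical(sc$junctions$score, c(0, 0))
  one <- score_sequence(RULE_TABLE, "ATG")
  expect_identical(one$total, 0)
  expect_identical(nrow(one$junctions), 0L)
  for (s in 1:10) {
    tab <- random_pair_table(seed = 300 + s)
    a <- unname(random_proteins(1, c(2, 5), seed = 310 + s))
    s1 <- optimize_codon_pairs(a, tab, "best")$dna
    s2 <- optimize_codon_pairs(a, tab, "worst")$dna
    joint <- score_sequence(tab, paste0(s1, s2))$total
    last1 <- substr(s1, nchar(s1) - 2, nchar(s1))
    first2 <- substr(s2, 1, 3)
    expect_equal(joint,
                 score_sequence(tab, s1)$total + score_sequence(tab, s2)$total +
                   score_pair(tab, last1, first2))
  }
})

test_that("scoring is invariant under RNA/DNA spelling and negation flips sign", {
  tab <- random_pair_table(seed = 11)
  dna <- "ATGCAAGTTACT"
  rna <- chartr("T", "U", dna)
  expect_identical(score_sequence(tab, dna)$total,
                   score_sequence(tab, rna)$total)
  expect_identical(score_sequence(negate_table(tab), dna)$total,
                   -score_sequence(tab, dna)$total)
})

test_that("score-table TSV round-trips in both dialects", {
  tab <- random_pair_table(seed = 5)
  for (d in c("long-triples", "dense-matrix")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_pair_table(tab, path, dialect = d)
    back <- read_pair_table(path)
    expect_identical(back$scores, tab$scores, label = d)
    expect_true(back$discretized)
  }
})

test_that("RNA-spelled headers load and are queryable by DNA codons", {
  tab <- random_pair_table(seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- tab$scores
  dimnames(m) <- list(chartr("T", "U", rownames(m)),
                      chartr("T", "U", colnames(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  back <- read_pair_table(path, dialect = "dense-matrix")
  expect_identical(score_pair(back, "GTT", "TTT"),
                   score_pair(tab, "GTT", "TTT"))
  expect_identical(back$scores, tab$scores)
})

test_that("strict load rejects incomplete tables; sparse load zero-fills", {
  tab <- random_pair_table(seed = 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(tab, path, dialect = "long-triples")
  lines <- readLines(path)
  drop <- grepl("^ATG\tATG\t", lines)
  writeLines(lines[!drop], path)
  expect_error(read_pair_table(path), class = "cpo_incomplete_table_error")
  expect_warning(back <- read_pair_table(path, sparse = TRUE), "missing")
  expect_identical(score_pair(back, "ATG", "ATG"), 0)
})

test_that("conflicting duplicates and non-numeric scores are parse errors", {
  tab <- random_pair_table(seed = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_table(tab, path, dialect = "long-triples")
  bad <- sub("^(ATG\tATG\t).*", "\\1oops", readLines(path))
  writeLines(bad, path)
  expect_error(read_pair_table(path), class = "cpo_parse_error")
  write_pair_table(tab, path, dialect = "long-triples")
  conflicting <- sprintf("ATG\tATG\t%g", score_pair(tab, "ATG", "ATG") + 1)
  writeLines(c(readLines(path), conflicting), path)
  expect_error(read_pair_table(path), class = "cpo_conflict_error")
})
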