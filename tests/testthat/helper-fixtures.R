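# Shared fixtures built in code.

STD_CODE <- genetic_code()
RULE_TABLE <- default_rule_table()

# objective value a mode optimizes, extracted from a result
mode_objective <- function(res) {
  switch(res$mode,
         best = res$total_score,
         worst = res$total_score,
         unbiased = sum(abs(res$junction_scores)))
}

# continuous (non-discretized) random 64x64 score matrix
with_seed_matrix <- function(seed) {
  withr::with_seed(seed, {
    codons <- all_codons()
    matrix(stats::rnorm(4096), 64, 64, dimnames = list(codons, codons))
  })
}

# a small table where same-codon glycine pairs are penalized, so the best
# path must alternate glycine codons
alternation_table <- function() {
  codons <- all_codons()
  m <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  gly <- synonymous_codons("G", STD_CODE)
  m[cbind(gly, gly)] <- -1
  codon_pair_table(m, provenance = "glycine same-codon penalty")
}
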