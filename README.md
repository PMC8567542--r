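# cpoptim

Codon-pair context optimization of coding sequences for heterologous
protein expression, aimed at synthetic-gene designers working with hosts —
*Pichia pastoris* in particular — whose genomes show a strong codon *pair*
bias on top of ordinary codon usage bias.

## The problem and the method

A protein of length *K* can be back-translated into
*m*₁ × *m*₂ × ⋯ × *m*ₖ coding sequences, where *mᵢ* is the number of
synonymous codons of residue *i*. Since 18 of the 20 amino acids have 2–6
codons, the candidate count is at least 2^k over the k degenerate residues
(a 20-residue peptide already admits ≥ 10⁶ candidates), so exhaustive
search is hopeless. Yet adjacent codons are not used independently: each
ordered codon pair carries a context score (negative = rejected, positive
= preferred, zero = no significance), and sequences rich in rejected
contexts translate poorly.

`cpoptim` treats design as a longest-path problem on a **layered codon
graph**: one layer per residue, the layer's nodes being the residue's
synonymous codons in lexicographic order, with complete bipartite edges
between consecutive layers weighted by the pair score table. Dynamic
programming visits each of the

&nbsp;&nbsp;&nbsp;&nbsp;S = Σᵢ₌₁^(K−1) |rᵢ| × |rᵢ₊₁|

states once (|rᵢ| = layer size; S = 26 for the 4-residue example MQVT),
keeps the best accumulated score and a back-pointer per node, and recovers
the exact optimum by traceback — linear in K for the bounded layer widths
(≤ 6) of the standard code. Three objectives are supported: `best`
(maximize total pair score), `worst` (minimize it; a negative control),
and `unbiased` (prefer neutral contexts: minimize the sum of absolute
junction scores). A classic codon-usage comparator (`optimize_cub`) maps
every residue to its host-preferred codon, and diagnostic reports classify
every junction (rejected/preferred/neutral), lay the codons out in the
conventional 16-column context map, and tally synonymous-codon usage per
amino acid.

The built-in score table is derived from the four context rules observed
in the *P. pastoris* context map — pairs ending …T|A… or …C|G… are
rejected, …T|G… and …C|A… preferred — and any 64×64 table (e.g. a
discretized −2…+2 genome-derived map) can be loaded from TSV in either a
long-triples or dense-matrix dialect. A brute-force enumeration oracle
verifies the DP exactly on small proteins.

## Worked example

```r
library(cpoptim)
tab <- default_rule_table()
res <- optimize_codon_pairs("MDYKDDDDKGS", tab, mode = "best", append_stop = TRUE)
res
#> Codon optimization (mode = best)
#>   protein: MDYKDDDDKGS*
#>   cds:     ATGGACTACAAAGATGATGATGACAAAGGCAGCTAA
#>   total score 6 over 11 junctions; states 80; ties 16
#>   table:   rule-derived default (incl. stop codons)
```

The optimizer chose a coding sequence whose 11 junctions accumulate a
total context score of 6 after exploring all 80 DP states (16 decisions
were score ties, resolved toward the lexicographically smallest codon).
Note the aspartate run uses *both* GAT and GAC — pair-context optimization
deliberately alternates codons to chain preferred junctions, which a
one-codon-per-amino-acid usage table cannot do:

```r
u <- read_usage_table(system.file("extdata", "synthetic_codon_usage.tsv",
                                  package = "cpoptim"))
optimize_cub("MDYKDDDDKGS", u, append_stop = TRUE, table = tab)$total_score
#> [1] -1

rp <- classify_sequence(res$dna, tab)
rp
#> Codon-pair context report: 12 codons, total score 6
#>   rejected 0, preferred 6, neutral 5
cat(render_context_map(rp, "text"), sep = "\n")
#> ATG  GAC. TAC. AAA+ GAT. GAT+ GAT+ GAC+ AAA+ GGC. AGC+ TAA.
```

`+`/`-`/`.` mark each codon's preferred/rejected/neutral context relative
to its 5′ neighbor; the best-context design has zero rejected junctions
while the usage-optimized comparator scores −1.

A command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cpo.R", package = "cpoptim"))')" \
    optimize --in protein.faa --mode best --table default-rules --out cds.fna
```

Subcommands: `optimize` (best | worst | unbiased | cub), `score`,
`report`, `fixtures`, `convert-table`.

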