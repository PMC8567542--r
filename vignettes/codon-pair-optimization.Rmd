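---
title: "Designing coding sequences by codon-pair context optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing coding sequences by codon-pair context optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpoptim)
```

## The model

Synonymous codon choice leaves the protein unchanged but alters two
statistical signals the translation machinery is sensitive to: the
marginal frequency of each codon (codon usage bias, CUB) and the joint
frequency of adjacent codon pairs (codon pair bias, or codon-pair
context). The pair signal is thought to act through tRNA compatibility in
the ribosomal P- and A-sites, so a sequence threaded through preferred
pair contexts elongates faster and more accurately than one stumbling
through rejected contexts — even when both use the same codons overall.

`cpoptim` scores a coding sequence of codons $c_1 \dots c_K$ under a
$64 \times 64$ pair table $T$ as the sum of its junction scores
$\sum_{i=1}^{K-1} T(c_i, c_{i+1})$, with the sign convention that
$T < 0$ is a rejected context, $T > 0$ preferred, $T = 0$ neutral.
Design is then a best-path problem on a **layered codon graph**: layer
$i$ holds the $|r_i|$ synonymous codons of residue $i$ (sorted
lexicographically, A<C<G<T), and every node of layer $i$ connects to
every node of layer $i+1$ with weight $T(c_i, c_{i+1})$. The naive
search space is $\prod_i |r_i|$ — at least $2^k$ over the $k$ degenerate
residues, about $10^6$ already at $k = 20$ — but the additive objective
has optimal substructure, so dynamic programming solves it exactly:
each node keeps the best accumulated score of any path reaching it plus
a back-pointer, each of the

$$S = \sum_{i=1}^{K-1} |r_i| \times |r_{i+1}|$$

states is evaluated once, and the optimum is recovered by traceback.
With the standard code's layer widths bounded by 6, $S \le 36(K-1)$, so
runtime is linear in protein length. The DP is implemented iteratively
(bottom-up over layers): the recursive decomposition into a length
$K{-}1$ sub-problem plus one residue is the natural way to *derive* the
algorithm, but literal recursion would both recompute sub-problems and
overflow the call stack on real proteins, and the memoized
two-dimensional array it implies *is* the iterative table.

```{r mqvt}
g <- build_codon_graph("MQVT")
lengths(g$layers)        # 1 (M), 2 (Q), 4 (V), 4 (T)
state_space_size(g)      # 1*2 + 2*4 + 4*4 = 26
candidate_combination_count("MQVT")  # versus 32 naive candidates
```

## Objectives

Three pair-context objectives run on the same DP with transformed edge
weights, plus the classic usage comparator:

* **best** — maximize the total pair score: the production design.
* **worst** — minimize it (equivalently, best under the negated table):
  a negative-control design expected to express poorly.
* **unbiased** — prefer neutral contexts: minimize
  $\sum_i |T(c_i, c_{i+1})|$. The notion of an "unbiased context"
  variant admits several formalizations; this package defines it as the
  minimum-absolute-score path because that is the sequence closest to
  showing *no* context signal under the table. Because $|{\cdot}|$ of
  the *total* is not decomposable junction-by-junction, the secondary
  tie-break (signed prefix total nearest zero) is applied greedily at
  each DP step rather than globally; the primary objective is still
  exact, and the invariant worst $\le$ unbiased $\le$ best holds because
  the unbiased path is one feasible path among those best/worst bound.
* **cub** (`optimize_cub`) — each residue independently receives the
  highest-frequency synonymous codon of a host usage table. This is the
  strategy pair-context optimization is compared against; by
  construction it uses exactly one codon per amino acid, whereas the DP
  freely alternates codons to chain preferred junctions.

## Score tables and parameters

* **Default table** (`default_rule_table`). The shipped table encodes
  the four context rules conspicuous in the *Pichia pastoris* map: a 5′
  codon ending **T** followed by a 3′ codon starting **A**, or **C**
  followed by **G**, is rejected; **T**|**G** and **C**|**A** are
  preferred; all other 3′-base/5′-base combinations are neutral. Each
  rule fixes one base of each codon, so the census is exactly
  $16 \times 16 = 256$ pairs per rule cell — 512 rejected, 512
  preferred, 3072 neutral. `reject_magnitude` and `favor_magnitude`
  (both default 1, dimensionless score units) set the weights; with
  equal magnitudes only the *sign* pattern matters to the optimum.
  Pairs involving stop codons are scored by the same base rules (the
  provenance string records this), since nothing distinguishes them at
  the dinucleotide junction.
* **Loaded tables** (`read_pair_table`). Any complete 64×64 table loads
  from TSV in a `long-triples` (`codon5 TAB codon3 TAB score`, 4096
  rows) or `dense-matrix` (64×64 with codon headers) dialect; RNA
  spelling is normalized to DNA. Missing cells are an error by default —
  silent zero-filling hides truncated files — and `sparse = TRUE`
  zero-fills with a warning instead. Tables whose scores all lie in
  $\{-2,\dots,2\}$ are flagged `discretized`, matching the convention of
  genome-derived context maps quantized to five levels.
* **Stop handling** (`append_stop`). By default the optimizer covers
  exactly the residues given. `append_stop = TRUE` (or a trailing `*`)
  adds a stop layer that participates in the DP, so the junction *into*
  the stop codon is optimized too. Published context-optimized
  constructs carry stop codons but how theirs were chosen is not
  documented, so both behaviors are exposed rather than asserting one.
* **Ties.** With few distinct score levels, many decisions tie. Ties
  are broken toward the lexicographically smallest codon at every
  decision (predecessor choice and final node), making results
  deterministic and platform-independent; `ties_encountered` reports
  how much degeneracy the optimum had. For non-discretized
  (floating-point) tables, scores within `tol = 1e-9` are treated as
  tied; discretized tables compare exactly.

## Verification: the brute-force oracle

`brute_force_oracle` enumerates every back-translation (refusing beyond
`cap = 1e6` candidates) and returns the exact optimum. Its enumeration
order — last layer varying slowest — reproduces the DP's traceback
tie-break (smallest codon decided from the last position backwards), so
for `best` and `worst` the oracle and the DP return *identical paths*,
not just equal scores. The test suite asserts this on 200+ seeded
random protein/table trials; for `unbiased` only the objective value is
compared, since the greedy secondary key is not meaningful under
exhaustive enumeration.

## Diagnostics

`classify_sequence` classifies every junction by score sign, reports the
rejected/preferred/neutral census (which must sum to codon count − 1),
and arranges the codons row-major into the conventional 16-column
context-map grid — start codon in the first cell, stop codon (when
present) in the last, each cell colored by its class relative to its 5′
neighbor, the first codon carrying no class. `render_context_map` emits
a text rendering (`+`/`-`/`.`) or an HTML table with red/green/black
cells whose opacity scales with |score|. `synonymous_usage` tallies
per-amino-acid codon use for residues occurring at least `min_count`
times (default 10, the conventional threshold for "frequent" residues);
on CUB output every reported amino acid uses exactly one codon, while
pair-context output typically spreads across several — a feature, since
it also spreads demand across tRNA pools.

## The fixture generator

`generate_fixtures` (and `random_proteins` / `random_pair_table`) emits
seeded random proteins and discretized score tables so the whole suite
runs without downloads. Defaults emulate the desk-scale verification
setting: proteins of length 3–6 residues drawn uniformly over the 20
amino acids (short enough that the enumeration oracle covers at most
$6^6 < 10^6$ candidates), and tables drawn i.i.d. per cell from
$\{-2,\dots,2\}$ with probabilities $(0.1, 0.15, 0.5, 0.15, 0.1)$ — a
neutral-majority profile like a discretized context map. What these
fixtures do *not* emulate: real context maps are strongly structured by
the junction dinucleotide (not i.i.d.), real proteins have biased amino
acid composition, and the shipped usage table
(`inst/extdata/synthetic_codon_usage.tsv`) is synthetic, not a measured
host table. Passing tests therefore demonstrate algorithmic
correctness — exact optimality, determinism, conservation laws — not
expression outcomes; production use requires a genome-derived pair table
and a real usage table for the intended host.

## Numerical choices and degenerate inputs

Discretized tables are accumulated in exactly-representable integer
arithmetic (stored as doubles); continuous tables accumulate in floating
point with the `1e-9` tie tolerance, so over $K$ junctions the total can
deviate from the true optimum by at most $K \cdot 10^{-9}$ score units.
A single-residue protein yields one layer, zero junctions, score 0, and
the lexicographically first codon. Empty proteins, non-amino-acid
symbols, internal stops, non-triplet coding sequences and incomplete
tables raise classed errors (`cpo_*_error`) that the CLI maps to exit
codes (1 data, 2 usage). `candidate_combination_count` is computed in
exact arbitrary precision (decimal-digit arithmetic) and returned as a
string, since $6^{100}$-scale counts overflow doubles.

## Scope and limitations

The optimizer is single-objective: it does not jointly balance pair
context with codon usage, GC content, mRNA secondary structure, or
forbidden restriction motifs, and it does not estimate pair-score
tables from a CDS corpus — tables are inputs. Alternative genetic codes
can be supplied to `genetic_code()`, but only the standard nuclear code
is exercised by the suite. The test suite's problem sizes (proteins of
3–6 residues for oracle equivalence, tens of residues for reports, 200
randomized trials) were chosen so that exhaustive enumeration remains a
practical independent oracle while still covering every layer-width
combination of the standard code.
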