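Package: cpoptim
Title: Codon-Pair Context Optimization of Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs coding DNA sequences for a given protein by dynamic
    programming over a layered codon graph scored with a 64x64 codon-pair
    context table. Supports best, worst and unbiased codon-pair-context
    designs, a codon-usage-bias comparator that picks each residue's
    host-preferred codon, diagnostic reports (pair classification maps and
    synonymous-codon usage breakdowns), score-table and usage-table TSV
    I/O, FASTA I/O, a brute-force verification oracle, a seeded fixture
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
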