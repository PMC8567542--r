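# Standard genetic code: codon <-> amino acid maps, translation,
# synonymous-codon sets, and back-translation combinatorics.

DNA_BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic order
#'
#' Lexicographic order over the DNA alphabet (A < C < G < T) is the total
#' codon order used everywhere in the package for layer ordering and
#' deterministic tie-breaking.
#'
#' @return Character vector of the 64 codons, sorted.
#' @export
all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3), method = "radix")
}

#' Normalize codon spelling
#'
#' Upper-cases and converts RNA spelling (U) to DNA (T). Errors on anything
#' that is not a 3-mer over {A,C,G,T,U} after case folding.
#'
#' @param x Character vector of codons.
#' @return Character vector of normalized DNA codons.
#' @export
normalize_codons <- function(x) {
  x <- chartr("u", "U", toupper(as.character(x)))
  x <- chartr("U", "T", x)
  bad <- nchar(x) != 3L | grepl("[^ACGT]", x)
  if (any(bad)) {
    stop_alphabet(sprintf(
      "invalid codon(s): %s (must be 3-mers over A/C/G/T, U accepted as T)",
      paste(unique(x[bad]), collapse = ", ")))
  }
  x
}

AA_SYMBOLS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a genetic code
#'
#' Builds the bidirectional codon/amino-acid maps from a 64-entry named
#' character vector (names = codons, values = single-letter amino acids with
#' `*` for stop). The default is the standard nuclear code
#' ([Biostrings::GENETIC_CODE], NCBI translation table 1), which is the code
#' used by *Pichia pastoris* nuclear genes. Synonymous codon lists are sorted
#' in the package codon order so that layer construction and tie-breaking are
#' deterministic.
#'
#' @param table Named character vector mapping all 64 codons to amino acids.
#' @return An object of class `genetic_code` with elements `codon_to_aa`
#'   (named character, 64 sorted codons) and `aa_to_codons` (named list of
#'   sorted codon vectors, one per amino acid plus `*`).
#' @examples
#' code <- genetic_code()
#' code$aa_to_codons[["V"]]   # GTA GTC GTG GTT
#' @export
genetic_code <- function(table = Biostrings::GENETIC_CODE) {
  codons <- normalize_codons(names(table))
  if (length(codons) != 64L || anyDuplicated(codons)) {
    stop_input("a genetic code must map all 64 distinct codons")
  }
  aa <- toupper(unname(as.character(table)))
  ok <- aa %in% c(AA_SYMBOLS, "*")
  if (!all(ok)) {
    stop_alphabet(sprintf("unknown amino-acid symbol(s): %s",
                          paste(unique(aa[!ok]), collapse = ", ")))
  }
  ord <- order(codons, method = "radix")
  codon_to_aa <- stats::setNames(aa[ord], codons[ord])
  aa_to_codons <- split(names(codon_to_aa), codon_to_aa)
  structure(list(codon_to_aa = codon_to_aa, aa_to_codons = aa_to_codons),
            class = "genetic_code")
}

#' Read a genetic code from a two-column TSV
#'
#' Expects 64 rows of `codon<TAB>amino-acid` (single-letter, `*` for stop),
#' with or without a header line `codon<TAB>aa`.
#'
#' @param path Path to the TSV file.
#' @return A `genetic_code` object.
#' @export
read_genetic_code <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("codon", "aa"))
  if (identical(tolower(df$codon[1]), "codon")) df <- df[-1, , drop = FALSE]
  genetic_code(stats::setNames(df$aa, df$codon))
}

#' @export
print.genetic_code <- function(x, ...) {
  n_syn <- lengths(x$aa_to_codons)
  cat("Genetic code: 64 codons ->", length(x$aa_to_codons),
      "amino-acid symbols (incl. stop)\n")
  cat("Degeneracy:", paste(sprintf("%s=%d", names(n_syn), n_syn),
                           collapse = " "), "\n")
  invisible(x)
}

# Split a DNA string into codons; accepts a codon vector unchanged.
as_codons <- function(x) {
  x <- as.character(x)
  if (length(x) == 1L && nchar(x) != 3L) {
    x <- chartr("u", "U", toupper(x))
    x <- chartr("U", "T", x)
    if (nchar(x) == 0L) stop_input("empty coding sequence")
    if (grepl("[^ACGT]", x)) {
      stop_alphabet(sprintf("non-ACGT character at position %d",
                            regexpr("[^ACGTU]", x)))
    }
    if (nchar(x) %% 3L != 0L) {
      stop_frame(sprintf("coding sequence length %d is not a multiple of 3",
                         nchar(x)))
    }
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  normalize_codons(x)
}

#' Translate a coding sequence
#'
#' Decodes a DNA (or RNA) coding sequence with the given genetic code. A stop
#' codon is permitted only at the final position (where it is reported as a
#' trailing `*`); a stop anywhere else is a premature-stop error.
#'
#' @param cds A DNA string (length divisible by 3) or a character vector of
#'   codons.
#' @param code A `genetic_code` object.
#' @return Single-letter amino-acid string, possibly ending in `*`.
#' @examples
#' translate_cds("ATGCAGGTTACT")  # "MQVT"
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  codons <- as_codons(cds)
  if (length(codons) == 0L) stop_input("empty coding sequence")
  aa <- unname(code$codon_to_aa[codons])
  internal_stop <- which(aa == "*")
  internal_stop <- internal_stop[internal_stop < length(aa)]
  if (length(internal_stop)) {
    stop_premature(sprintf("premature stop codon %s at codon position %d",
                           codons[internal_stop[1]], internal_stop[1]))
  }
  paste(aa, collapse = "")
}

#' Validate and split a protein sequence
#'
#' Accepts a single-letter amino-acid string; `*` is allowed only as an
#' optional final residue (an explicit stop request).
#'
#' @param protein Amino-acid string or character vector of residues.
#' @return Character vector of residues.
#' @export
protein_residues <- function(protein) {
  res <- as.character(protein)
  if (length(res) == 1L) res <- strsplit(toupper(res), "")[[1]]
  else res <- toupper(res)
  if (length(res) == 0L) stop_input("empty protein sequence")
  bad <- !(res %in% c(AA_SYMBOLS, "*"))
  if (any(bad)) {
    stop_alphabet(sprintf("invalid amino-acid symbol '%s' at position %d",
                          res[which(bad)[1]], which(bad)[1]))
  }
  stops <- which(res == "*")
  if (length(stops) && any(stops < length(res))) {
    stop_premature(sprintf("'*' allowed only as final residue (found at %d)",
                           stops[stops < length(res)][1]))
  }
  res
}

#' Synonymous codons of an amino acid
#'
#' @param aa One amino-acid symbol (or `*` for the stop "layer").
#' @param code A `genetic_code` object.
#' @return Sorted character vector of the synonymous codons.
#' @examples
#' synonymous_codons("Q")  # "CAA" "CAG"
#' @export
synonymous_codons <- function(aa, code = genetic_code()) {
  aa <- toupper(as.character(aa))
  if (length(aa) != 1L || !(aa %in% names(code$aa_to_codons))) {
    stop_alphabet(sprintf("unknown amino-acid symbol '%s'", aa))
  }
  code$aa_to_codons[[aa]]
}

# exact product of small integers as little-endian decimal digit vector
big_mul_small <- function(digits, m) {
  prod <- digits * m
  carry <- 0L
  out <- integer(0)
  for (d in prod) {
    v <- d + carry
    out <- c(out, v %% 10L)
    carry <- v %/% 10L
  }
  while (carry > 0L) {
    out <- c(out, carry %% 10L)
    carry <- carry %/% 10L
  }
  out
}

#' Number of coding-sequence candidates for a protein
#'
#' The back-translation search space: the product over residues of the number
#' of synonymous codons. Grows exponentially (at least `2^k` over the `k`
#' residues with 2 or more codons), which is why exhaustive search is
#' infeasible and the dynamic program exists. Computed exactly in
#' arbitrary precision and returned as a decimal string.
#'
#' @param protein Amino-acid string (a trailing `*` adds the 3-codon stop set).
#' @param code A `genetic_code` object.
#' @return Exact count as a decimal character string.
#' @examples
#' candidate_combination_count("MQVT")  # "32"
#' @export
candidate_combination_count <- function(protein, code = genetic_code()) {
  res <- protein_residues(protein)
  sizes <- vapply(res, function(a) length(code$aa_to_codons[[a]]), integer(1))
  digits <- 1L
  for (m in sizes) digits <- big_mul_small(digits, m)
  paste(rev(digits), collapse = "")
}
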