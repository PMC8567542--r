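# FASTA I/O (through Biostrings) and the seeded fixture generator.

#' Read a FASTA file
#'
#' Sequences are upper-cased; CRLF input parses identically to LF. Duplicate
#' identifiers trigger a warning and are suffix-deduplicated (`.1`, `.2`,
#' ...). With `type = "protein"` each sequence is validated as amino acids
#' (error names the offending symbol and position); with `type = "dna"` as
#' a coding sequence alphabet.
#'
#' @param path FASTA file path.
#' @param type `"any"`, `"protein"` or `"dna"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("any", "protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_input(sprintf("empty FASTA file: %s", path))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA identifiers; deduplicating with numeric suffixes")
    ids <- make.unique(ids, sep = ".")
  }
  names(seqs) <- ids
  if (type == "protein") for (s in seq_along(seqs)) protein_residues(seqs[[s]])
  if (type == "dna") for (s in seq_along(seqs)) as_codons(seqs[[s]])
  seqs
}

#' Write a FASTA file
#'
#' @param records Named character vector (names = identifiers, values =
#'   sequences; descriptions may be embedded in the names).
#' @param path Output path.
#' @param wrap Line width (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  if (length(records) == 0L) stop_input("no records to write")
  set <- Biostrings::BStringSet(toupper(unname(records)))
  names(set) <- names(records)
  Biostrings::writeXStringSet(set, path, width = wrap)
  invisible(path)
}

# run expr with a local RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate random proteins
#'
#' @param n Number of proteins.
#' @param length_range Length range (inclusive), sampled uniformly.
#' @param alphabet Amino-acid alphabet to draw from (default all 20).
#' @param seed Integer seed; the global RNG state is untouched.
#' @return Named character vector of protein sequences.
#' @export
random_proteins <- function(n, length_range = c(3L, 6L),
                            alphabet = AA_SYMBOLS, seed = 1L) {
  with_local_seed(seed, {
    ks <- seq(length_range[1], length_range[2])
    lens <- if (length(ks) == 1L) rep(ks, n) else sample(ks, n, replace = TRUE)
    seqs <- vapply(lens, function(k)
      paste(sample(alphabet, k, replace = TRUE), collapse = ""), character(1))
    stats::setNames(seqs, sprintf("prot%03d", seq_len(n)))
  })
}

#' Generate a random discretized codon-pair score table
#'
#' Draws every one of the 4096 cell scores i.i.d. from `values` with
#' probabilities `probs` — emulating a discretized context map in which most
#' pairs are neutral and the rest preferred or rejected at two intensities.
#'
#' @param values Score values to draw from (default -2..2).
#' @param probs Sampling probabilities (default concentrated on 0).
#' @param seed Integer seed.
#' @return A `codon_pair_table`.
#' @export
random_pair_table <- function(values = -2:2,
                              probs = c(0.1, 0.15, 0.5, 0.15, 0.1),
                              seed = 1L) {
  codons <- all_codons()
  m <- with_local_seed(seed,
    matrix(sample(values, 4096L, replace = TRUE, prob = probs), 64L, 64L,
           dimnames = list(codons, codons)))
  codon_pair_table(m, provenance = sprintf("random (seed %d)", seed))
}

#' Generate fixture files: proteins FASTA, score-table TSV, usage-table TSV
#'
#' Reproducible under `seed` (byte-identical files for the same spec); the
#' tables satisfy all strict-load invariants.
#'
#' @param dir Output directory (created if needed).
#' @param n_proteins Number of random proteins.
#' @param length_range Protein length range.
#' @param seed Integer seed.
#' @param score_values,score_probs Passed to [random_pair_table()].
#' @return Named character vector of the three file paths (`proteins`,
#'   `score_table`, `usage_table`).
#' @export
generate_fixtures <- function(dir, n_proteins = 10L, length_range = c(3L, 6L),
                              seed = 1L, score_values = -2:2,
                              score_probs = c(0.1, 0.15, 0.5, 0.15, 0.1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteins = file.path(dir, "proteins.faa"),
             score_table = file.path(dir, "score_table.tsv"),
             usage_table = file.path(dir, "usage_table.tsv"))
  prots <- random_proteins(n_proteins, length_range, seed = seed)
  write_fasta(prots, paths[["proteins"]])
  tab <- random_pair_table(score_values, score_probs, seed = seed + 1L)
  write_pair_table(tab, paths[["score_table"]])
  counts <- with_local_seed(seed + 2L,
    stats::setNames(sample(1:1000, 64L, replace = TRUE), all_codons()))
  utils::write.table(
    data.frame(codon = names(counts), frequency = unname(counts)),
    paths[["usage_table"]], sep = "\t", quote = FALSE, row.names = FALSE)
  paths
}
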