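# Codon-usage-bias comparator: classic single-codon optimization that
# replaces every residue's codon with the host-preferred (highest-frequency)
# synonymous codon.

#' Construct a codon usage table
#'
#' Accepts raw counts or frequencies over all 64 codons and normalizes them
#' to relative frequencies within each synonymous set (fractions summing to 1
#' per amino acid).
#'
#' @param usage Named numeric vector (names = codons, DNA or RNA spelling)
#'   of non-negative counts or frequencies for all 64 codons.
#' @param code A `genetic_code` used to define the synonymous sets.
#' @param provenance Free-text origin label.
#' @return Object of class `codon_usage_table`: `usage` (normalized, named by
#'   the 64 sorted codons), `provenance`.
#' @export
codon_usage_table <- function(usage, code = genetic_code(),
                              provenance = "user") {
  codons <- all_codons()
  nm <- normalize_codons(names(usage))
  if (anyDuplicated(nm)) stop_conflict("duplicate codon in usage table")
  if (!setequal(nm, codons)) {
    miss <- setdiff(codons, nm)
    stop_incomplete(sprintf("usage table missing %d codon(s): %s",
                            length(miss),
                            paste(utils::head(miss, 5), collapse = ", ")))
  }
  u <- as.numeric(usage)
  if (anyNA(u)) stop_parse("non-numeric usage value")
  if (any(u < 0)) stop_parse("negative usage value")
  names(u) <- nm
  u <- u[codons]
  for (syn in code$aa_to_codons) {
    tot <- sum(u[syn])
    u[syn] <- if (tot > 0) u[syn] / tot else 1 / length(syn)
  }
  structure(list(usage = u, provenance = provenance),
            class = "codon_usage_table")
}

#' Read a codon usage table from TSV
#'
#' Expects a header `codon<TAB>frequency` (counts are accepted; values are
#' renormalized within each synonymous set).
#'
#' @param path File path.
#' @param code A `genetic_code`.
#' @return A `codon_usage_table`.
#' @export
read_usage_table <- function(path, code = genetic_code()) {
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character"))
  if (ncol(df) != 2L) stop_parse("usage table must have 2 columns")
  v <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(v)) {
    stop_parse(sprintf("non-numeric frequency '%s'",
                       df[[2]][which(is.na(v))[1]]))
  }
  codon_usage_table(stats::setNames(v, df[[1]]), code,
                    provenance = paste0("loaded: ", path))
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("Codon usage table (", x$provenance, ")\n", sep = "")
  cat("  64 codons, frequencies normalized within synonymous sets\n")
  invisible(x)
}

#' Codon-usage optimization (CUB comparator)
#'
#' The classic single-codon strategy: every residue is independently mapped
#' to the highest-frequency synonymous codon of the host usage table (arg-max
#' ties broken lexicographically). Because the map is per-residue, a given
#' amino acid always receives the same codon throughout the sequence. The
#' result's codon-pair total score under `table` is reported so CUB output
#' can be compared against the pair-context optimizer on the same footing.
#'
#' @param protein Amino-acid string.
#' @param usage A `codon_usage_table`.
#' @param code A `genetic_code`.
#' @param append_stop Also emit the preferred stop codon.
#' @param table A `codon_pair_table` used only to score the result.
#' @return A `codon_optimization` with mode `"cub"` (`states_explored` is 0:
#'   no search is performed).
#' @export
optimize_cub <- function(protein, usage, code = genetic_code(),
                         append_stop = FALSE, table = default_rule_table()) {
  stopifnot(inherits(usage, "codon_usage_table"),
            inherits(table, "codon_pair_table"))
  graph <- build_codon_graph(protein, code, append_stop)
  ties <- 0L
  codons <- vapply(graph$layers, function(syn) {
    f <- usage$usage[syn]
    top <- which(f == max(f))
    if (length(top) > 1L) ties <<- ties + 1L
    syn[top[1L]]  # synonymous sets are sorted: first = lexicographic
  }, character(1))
  sc <- score_sequence(table, codons)
  structure(list(codons = codons, dna = paste(codons, collapse = ""),
                 protein = paste(graph$residues, collapse = ""),
                 total_score = sc$total,
                 junction_scores = sc$junctions$score,
                 mode = "cub",
                 states_explored = 0L,
                 ties_encountered = ties,
                 provenance = paste0(usage$provenance, " / scored by ",
                                     table$provenance)),
            class = "codon_optimization")
}
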