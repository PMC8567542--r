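# Diagnostic reports: junction-by-junction pair classification with a
# 16-column map layout, and synonymous-codon usage breakdowns.

#' Classify every adjacent codon pair of a coding sequence
#'
#' Each of the n-1 junctions is classified by the sign of its pair score
#' (rejected / preferred / neutral). The codons are also arranged row-major
#' into a 16-column grid — the conventional context-map layout with the
#' start codon in the upper-left cell and the stop codon (when present) in
#' the final cell — each cell carrying the class of the codon relative to
#' its 5' neighbor; the first codon has no 5' neighbor and carries no class.
#'
#' @param cds DNA string or codon vector.
#' @param table A `codon_pair_table`.
#' @return Object of class `pair_context_report`: `junctions` (data.frame
#'   pos/codon5/codon3/score/class), `summary` (named counts rejected,
#'   preferred, neutral), `map` (data.frame row/col/codon/score/class with NA
#'   score/class for the first codon), `total`.
#' @export
classify_sequence <- function(cds, table = default_rule_table()) {
  stopifnot(inherits(table, "codon_pair_table"))
  codons <- as_codons(cds)
  sc <- score_sequence(table, codons)
  counts <- c(rejected = sum(sc$junctions$class == "rejected"),
              preferred = sum(sc$junctions$class == "preferred"),
              neutral = sum(sc$junctions$class == "neutral"))
  n <- length(codons)
  idx <- seq_len(n) - 1L
  map <- data.frame(row = idx %/% 16L + 1L, col = idx %% 16L + 1L,
                    codon = codons,
                    score = c(NA_real_, sc$junctions$score),
                    class = c(NA_character_, sc$junctions$class),
                    stringsAsFactors = FALSE)
  structure(list(junctions = sc$junctions, summary = counts, map = map,
                 total = sc$total),
            class = "pair_context_report")
}

#' @export
print.pair_context_report <- function(x, ...) {
  cat(sprintf(
    "Codon-pair context report: %d codons, total score %g\n",
    nrow(x$map), x$total))
  cat(sprintf("  rejected %d, preferred %d, neutral %d\n",
              x$summary[["rejected"]], x$summary[["preferred"]],
              x$summary[["neutral"]]))
  invisible(x)
}

#' Render the 16-column context map as text or HTML
#'
#' Text rendering marks each codon with `-` (rejected), `+` (preferred) or
#' `.` (neutral) relative to its 5' neighbor; the first codon is unmarked
#' (` `). HTML rendering colors cells red / green / black following the
#' conventional map coloring, with opacity scaled by |score| when the table
#' is discretized-style (|score| <= 2).
#'
#' @param report A `pair_context_report`.
#' @param format `"text"` or `"html"`.
#' @return Character vector of lines (text) or a single HTML string.
#' @export
render_context_map <- function(report, format = c("text", "html")) {
  stopifnot(inherits(report, "pair_context_report"))
  format <- match.arg(format)
  m <- report$map
  if (format == "text") {
    mark <- c(rejected = "-", preferred = "+", neutral = ".")
    cell <- paste0(m$codon, ifelse(is.na(m$class), " ", mark[m$class]))
    vapply(split(cell, m$row), paste, character(1), collapse = " ")
  } else {
    col <- c(rejected = "red", preferred = "green", neutral = "black")
    op <- ifelse(is.na(m$score), 1, pmin(1, abs(m$score) / 2 + 0.5))
    cells <- sprintf(
      '<td style="color:%s;opacity:%.2f">%s</td>',
      ifelse(is.na(m$class), "black", col[m$class]), op, m$codon)
    rows <- vapply(split(cells, m$row), function(r)
      paste0("<tr>", paste(r, collapse = ""), "</tr>"), character(1))
    paste0("<table>", paste(rows, collapse = "\n"), "</table>")
  }
}

#' Write a pair-context report as TSV files
#'
#' Emits `<prefix>_junctions.tsv` (pos, codon5, codon3, score, class; pos is
#' the 1-based junction index) and `<prefix>_summary.tsv` (class, count).
#'
#' @param report A `pair_context_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_context_report <- function(report, prefix) {
  stopifnot(inherits(report, "pair_context_report"))
  pj <- paste0(prefix, "_junctions.tsv")
  ps <- paste0(prefix, "_summary.tsv")
  utils::write.table(report$junctions, pj, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(class = names(report$summary), count = unname(report$summary)),
    ps, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(pj, ps))
}

#' Synonymous-codon usage breakdown of a coding sequence
#'
#' Tallies, per amino acid, how many times it occurs and which synonymous
#' codons encode it, reporting amino acids occurring at least `min_count`
#' times (the conventional threshold for "frequent" residues is 10). CUB
#' output uses exactly one codon per amino acid; pair-context output
#' typically spreads across several.
#'
#' @param cds DNA string or codon vector (must translate cleanly).
#' @param code A `genetic_code`.
#' @param min_count Minimum occurrence count for an amino acid to be listed.
#' @return Object of class `synonymous_usage_report`: data.frame with
#'   columns `aa`, `count` (occurrences of the amino acid), `codon`,
#'   `tally` (uses of that codon); attribute `n_residues` = total codons.
#' @export
synonymous_usage <- function(cds, code = genetic_code(), min_count = 10L) {
  codons <- as_codons(cds)
  aa <- strsplit(translate_cds(codons, code), "")[[1]]
  tab <- table(aa = aa, codon = codons)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  names(df)[3] <- "tally"
  occ <- tapply(df$tally, df$aa, sum)
  df$count <- as.integer(occ[df$aa])
  df <- df[df$count >= min_count, c("aa", "count", "codon", "tally")]
  df <- df[order(df$aa, df$codon), ]
  rownames(df) <- NULL
  structure(df, class = c("synonymous_usage_report", "data.frame"),
            n_residues = length(codons))
}

#' @export
print.synonymous_usage_report <- function(x, ...) {
  cat(sprintf("Synonymous-codon usage (%d codons total):\n",
              attr(x, "n_residues")))
  print.data.frame(x, ...)
  invisible(x)
}
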