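# 64x64 codon-pair context score tables: construction, TSV I/O, lookup,
# sequence scoring and sign-based classification.

#' Construct a codon-pair score table
#'
#' A total map from ordered (5' codon, 3' codon) pairs to a real context
#' score. Sign carries the classification: negative = rejected 3' context,
#' positive = preferred, zero = no significance. Tables whose scores all lie
#' in {-2,-1,0,1,2} (the discretized context-map convention) are flagged
#' `discretized`, which enables exact integer tie detection in the optimizer.
#'
#' @param scores 64x64 numeric matrix; dimnames are codons (rows = 5' codon,
#'   columns = 3' codon), any spelling/order; reordered internally to the
#'   package codon order.
#' @param provenance Free-text label recording where the table came from.
#' @return Object of class `codon_pair_table` with elements `scores`
#'   (reordered matrix), `provenance`, `discretized`.
#' @export
codon_pair_table <- function(scores, provenance = "user") {
  if (!is.matrix(scores) || !is.numeric(scores) ||
      nrow(scores) != 64L || ncol(scores) != 64L) {
    stop_input("scores must be a numeric 64x64 matrix with codon dimnames")
  }
  rn <- normalize_codons(rownames(scores))
  cn <- normalize_codons(colnames(scores))
  codons <- all_codons()
  if (!setequal(rn, codons) || !setequal(cn, codons)) {
    stop_incomplete("score matrix dimnames must cover all 64 codons")
  }
  dimnames(scores) <- list(rn, cn)
  scores <- scores[codons, codons]
  storage.mode(scores) <- "double"
  if (anyNA(scores)) stop_incomplete("score matrix contains missing values")
  discretized <- all(scores == round(scores)) && all(abs(scores) <= 2)
  structure(list(scores = scores, provenance = provenance,
                 discretized = discretized),
            class = "codon_pair_table")
}

#' @export
print.codon_pair_table <- function(x, ...) {
  cl <- pair_class(x$scores)
  cat("Codon-pair score table (", x$provenance, ")\n", sep = "")
  cat(sprintf("  discretized: %s; rejected %d, preferred %d, neutral %d of 4096 pairs\n",
              x$discretized, sum(cl == "rejected"), sum(cl == "preferred"),
              sum(cl == "neutral")))
  invisible(x)
}

#' Default rule-derived score table
#'
#' Builds the built-in table from the four codon-pair context rules observed
#' in the *Pichia pastoris* context map: pairs X1X2T3-A1Y2Y3 and X1X2C3-G1Y2Y3
#' are rejected, and X1X2T3-G1Y2Y3 and X1X2C3-A1Y2Y3 are favored, for any
#' bases X and Y. Every other pair is neutral (score 0). Pairs involving stop
#' codons are scored by the same base rules.
#'
#' @param reject_magnitude Positive score magnitude assigned (negated) to
#'   rejected pairs. Default 1.
#' @param favor_magnitude Positive magnitude assigned to favored pairs.
#'   Default 1.
#' @return A `codon_pair_table`.
#' @examples
#' tab <- default_rule_table()
#' score_pair(tab, "GGT", "ATT")  # -1: T3-A1 is a rejected context
#' @export
default_rule_table <- function(reject_magnitude = 1, favor_magnitude = 1) {
  if (!is.numeric(reject_magnitude) || length(reject_magnitude) != 1L ||
      reject_magnitude <= 0 || !is.numeric(favor_magnitude) ||
      length(favor_magnitude) != 1L || favor_magnitude <= 0) {
    stop_parameter("rule magnitudes must be positive scalars")
  }
  codons <- all_codons()
  last5 <- substr(codons, 3L, 3L)   # 3rd base of the 5' codon
  first3 <- substr(codons, 1L, 1L)  # 1st base of the 3' codon
  m <- matrix(0, 64L, 64L, dimnames = list(codons, codons))
  rej <- outer(last5 == "T", first3 == "A") | outer(last5 == "C", first3 == "G")
  fav <- outer(last5 == "T", first3 == "G") | outer(last5 == "C", first3 == "A")
  m[rej] <- -reject_magnitude
  m[fav] <- favor_magnitude
  codon_pair_table(m, provenance = "rule-derived default (incl. stop codons)")
}

#' Look up the score of one ordered codon pair
#'
#' @param table A `codon_pair_table`.
#' @param five_prime,three_prime Codons (DNA or RNA spelling).
#' @return Numeric score.
#' @export
score_pair <- function(table, five_prime, three_prime) {
  stopifnot(inherits(table, "codon_pair_table"))
  unname(table$scores[normalize_codons(five_prime),
                      normalize_codons(three_prime)])
}

#' Classify pair scores by sign
#'
#' @param score Numeric vector of pair scores.
#' @return Character vector over {"rejected","preferred","neutral"}.
#' @export
pair_class <- function(score) {
  ifelse(score < 0, "rejected", ifelse(score > 0, "preferred", "neutral"))
}

#' Score a coding sequence under a pair table
#'
#' Total score is the sum over the n-1 adjacent ordered codon pairs; the
#' per-junction scores are returned alongside. A single codon scores 0 with
#' no junctions.
#'
#' @param table A `codon_pair_table`.
#' @param cds DNA string or codon vector.
#' @return List with `total` (numeric) and `junctions` (data.frame with
#'   1-based `pos` of the junction, `codon5`, `codon3`, `score`, `class`).
#' @export
score_sequence <- function(table, cds) {
  stopifnot(inherits(table, "codon_pair_table"))
  codons <- as_codons(cds)
  if (length(codons) < 1L) stop_input("empty coding sequence")
  if (length(codons) == 1L) {
    junc <- data.frame(pos = integer(0), codon5 = character(0),
                       codon3 = character(0), score = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
    return(list(total = 0, junctions = junc))
  }
  c5 <- codons[-length(codons)]
  c3 <- codons[-1L]
  s <- table$scores[cbind(c5, c3)]
  junc <- data.frame(pos = seq_along(s), codon5 = c5, codon3 = c3,
                     score = s, class = pair_class(s),
                     stringsAsFactors = FALSE)
  list(total = sum(s), junctions = junc)
}

#' Negate a score table
#'
#' Utility for the worst-path duality: the minimum-score path under a table
#' is the maximum-score path under its negation.
#'
#' @param table A `codon_pair_table`.
#' @return A `codon_pair_table` with all scores negated.
#' @export
negate_table <- function(table) {
  stopifnot(inherits(table, "codon_pair_table"))
  codon_pair_table(-table$scores,
                   provenance = paste0("negated: ", table$provenance))
}

#' Read a codon-pair score table from TSV
#'
#' Two dialects are supported. `long-triples`: a header line
#' `codon5<TAB>codon3<TAB>score` followed by one row per ordered pair.
#' `dense-matrix`: an empty first header cell, 64 codon column headers, then
#' 64 rows each starting with the 5' codon. RNA codon spelling is normalized
#' to DNA. By default the table must be total (all 4096 pairs); with
#' `sparse = TRUE` unlisted pairs are filled with 0 and a warning is issued.
#'
#' @param path File path.
#' @param dialect `"long-triples"` or `"dense-matrix"` (default: sniffed from
#'   the header line).
#' @param sparse Fill missing pairs with 0 instead of erroring.
#' @return A `codon_pair_table` with provenance `"loaded: <path>"`.
#' @export
read_pair_table <- function(path, dialect = c("auto", "long-triples",
                                              "dense-matrix"),
                            sparse = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input(sprintf("no such file: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (dialect == "auto") {
    dialect <- if (length(header) == 65L) "dense-matrix" else "long-triples"
  }
  codons <- all_codons()
  if (dialect == "long-triples") {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "character", "character"))
    if (ncol(df) != 3L) stop_parse("long-triples table must have 3 columns")
    sc <- suppressWarnings(as.numeric(df[[3]]))
    if (anyNA(sc)) {
      stop_parse(sprintf("non-numeric score '%s'", df[[3]][which(is.na(sc))[1]]))
    }
    c5 <- normalize_codons(df[[1]])
    c3 <- normalize_codons(df[[2]])
    key <- paste(c5, c3)
    dup <- duplicated(key)
    if (any(dup)) {
      first <- match(key[dup], key)
      if (any(sc[dup] != sc[first])) {
        stop_conflict("duplicate codon pair with conflicting scores")
      }
      c5 <- c5[!dup]; c3 <- c3[!dup]; sc <- sc[!dup]
    }
    m <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
    m[cbind(c5, c3)] <- sc
  } else {
    raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    mm <- as.matrix(raw)
    if (!is.numeric(mm)) {
      had_na <- is.na(mm)
      suppressWarnings(storage.mode(mm) <- "double")
      if (any(is.na(mm) & !had_na)) {
        stop_parse("non-numeric score cell in dense-matrix table")
      }
    }
    rn <- normalize_codons(rownames(mm))
    cn <- normalize_codons(colnames(mm))
    m <- matrix(NA_real_, 64L, 64L, dimnames = list(codons, codons))
    m[rn, cn] <- mm
  }
  missing <- which(is.na(m), arr.ind = TRUE)
  if (nrow(missing)) {
    if (!sparse) {
      stop_incomplete(sprintf(
        "incomplete score table: %d of 4096 pairs missing (first: %s-%s); use sparse = TRUE to zero-fill",
        nrow(missing), codons[missing[1, 1]], codons[missing[1, 2]]))
    }
    warning(sprintf("sparse load: %d missing pairs filled with 0",
                    nrow(missing)))
    m[is.na(m)] <- 0
  }
  codon_pair_table(m, provenance = paste0("loaded: ", path))
}

#' Write a codon-pair score table to TSV
#'
#' @param table A `codon_pair_table`.
#' @param path Output file path.
#' @param dialect `"long-triples"` (default) or `"dense-matrix"`.
#' @export
write_pair_table <- function(table, path,
                             dialect = c("long-triples", "dense-matrix")) {
  stopifnot(inherits(table, "codon_pair_table"))
  dialect <- match.arg(dialect)
  codons <- all_codons()
  if (dialect == "long-triples") {
    df <- data.frame(codon5 = rep(codons, each = 64L),
                     codon3 = rep(codons, times = 64L),
                     score = as.vector(t(table$scores)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(table$scores, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
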