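# Dynamic programming over the layered codon graph.
#
# One layer per residue, nodes = the residue's synonymous codons in
# lexicographic order, complete bipartite scored edges between consecutive
# layers. The optimum path is found bottom-up: for each node of layer i the
# best accumulated score over all paths from layer 1 is kept together with a
# back-pointer, so each of the S = sum |r_i| x |r_{i+1}| states is evaluated
# exactly once and the optimum is recovered by traceback.

#' Build the layered codon graph of a protein
#'
#' @param protein Amino-acid string; a trailing `*` requests a stop layer.
#' @param code A `genetic_code`.
#' @param append_stop Add a stop-codon layer after the last residue (the stop
#'   codon then participates in scoring like any other layer).
#' @return Object of class `layered_codon_graph`: `residues` (character),
#'   `layers` (list of sorted codon vectors).
#' @examples
#' g <- build_codon_graph("MQVT")
#' lengths(g$layers)  # 1 2 4 4
#' @export
build_codon_graph <- function(protein, code = genetic_code(),
                              append_stop = FALSE) {
  res <- protein_residues(protein)
  if (append_stop && res[length(res)] != "*") res <- c(res, "*")
  layers <- lapply(res, function(a) code$aa_to_codons[[a]])
  structure(list(residues = res, layers = layers),
            class = "layered_codon_graph")
}

#' @export
print.layered_codon_graph <- function(x, ...) {
  sz <- lengths(x$layers)
  cat(sprintf("Layered codon graph: %d layers, %d edges, state space %d\n",
              length(sz), state_space_size(x), state_space_size(x)))
  cat("Layer sizes:", paste(sz, collapse = " "), "\n")
  invisible(x)
}

#' State-space size of the layered graph
#'
#' The number of DP states, S = sum over junctions of |r_i| x |r_(i+1)| —
#' also the edge count, since the bipartite blocks are complete. This is the
#' quantity the optimizer's work is proportional to, linear in protein length
#' for the bounded layer widths (at most 6) of the standard code.
#'
#' @param graph A `layered_codon_graph`.
#' @return Non-negative integer.
#' @examples
#' state_space_size(build_codon_graph("MQVT"))  # 1*2 + 2*4 + 4*4 = 26
#' @export
state_space_size <- function(graph) {
  stopifnot(inherits(graph, "layered_codon_graph"))
  sz <- lengths(graph$layers)
  if (length(sz) < 2L) return(0L)
  sum(sz[-length(sz)] * sz[-1L])
}

# effective edge weight to MAXIMIZE, per mode
mode_weight <- function(w, mode) {
  switch(mode, best = w, worst = -w, unbiased = -abs(w))
}

#' Optimize the codon path of a protein
#'
#' Finds the coding sequence whose adjacent codon-pair context scores achieve
#' the exact optimum of the chosen objective over every one of the
#' `candidate_combination_count()` back-translations:
#' \describe{
#'   \item{best}{maximize the total pair score,}
#'   \item{worst}{minimize the total pair score,}
#'   \item{unbiased}{minimize the sum of absolute junction scores (prefer
#'     neutral contexts), with the signed prefix total nearest zero as a
#'     secondary key at each DP step.}
#' }
#' Ties at every decision are broken toward the lexicographically smallest
#' codon, so results are deterministic; `ties_encountered` reports how often
#' degeneracy arose. Runtime is proportional to the state-space size.
#'
#' @param protein Amino-acid string.
#' @param table A `codon_pair_table`.
#' @param mode `"best"`, `"worst"` or `"unbiased"`.
#' @param code A `genetic_code`.
#' @param append_stop Also choose a stop codon, scored by the same DP.
#' @param tol Tie-detection tolerance for non-discretized tables (ignored,
#'   i.e. exact comparison, when the table is discretized).
#' @return Object of class `codon_optimization`: `codons`, `dna`, `protein`,
#'   `total_score`, `junction_scores`, `mode`, `states_explored`,
#'   `ties_encountered`, `provenance`.
#' @examples
#' res <- optimize_codon_pairs("MQVT", default_rule_table(), mode = "best")
#' res$dna
#' @export
optimize_codon_pairs <- function(protein, table = default_rule_table(),
                                 mode = c("best", "worst", "unbiased"),
                                 code = genetic_code(), append_stop = FALSE,
                                 tol = 1e-9) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "codon_pair_table"))
  graph <- build_codon_graph(protein, code, append_stop)
  layers <- graph$layers
  K <- length(layers)
  eps <- if (table$discretized) 0 else tol
  ties <- 0L

  D <- vector("list", K)      # best accumulated effective score per node
  Tsig <- vector("list", K)   # signed total of the chosen prefix per node
  BP <- vector("list", K)     # back-pointer (predecessor index)
  D[[1]] <- numeric(length(layers[[1]]))
  Tsig[[1]] <- numeric(length(layers[[1]]))
  BP[[1]] <- rep(NA_integer_, length(layers[[1]]))

  if (K > 1L) {
    for (i in 2:K) {
      W <- table$scores[layers[[i - 1L]], layers[[i]], drop = FALSE]
      ni <- length(layers[[i]])
      D[[i]] <- numeric(ni); Tsig[[i]] <- numeric(ni); BP[[i]] <- integer(ni)
      for (j in seq_len(ni)) {
        w <- W[, j]
        cand <- D[[i - 1L]] + mode_weight(w, mode)
        arg <- which(cand >= max(cand) - eps)
        if (length(arg) > 1L && mode == "unbiased") {
          sec <- abs(Tsig[[i - 1L]][arg] + w[arg])
          arg <- arg[sec <= min(sec) + eps]
        }
        if (length(arg) > 1L) ties <- ties + 1L
        p <- arg[1L]  # layers are sorted, so first index = smallest codon
        D[[i]][j] <- cand[p]
        Tsig[[i]][j] <- Tsig[[i - 1L]][p] + w[p]
        BP[[i]][j] <- p
      }
    }
  }

  fin <- which(D[[K]] >= max(D[[K]]) - eps)
  if (length(fin) > 1L && mode == "unbiased") {
    sec <- abs(Tsig[[K]][fin])
    fin <- fin[sec <= min(sec) + eps]
  }
  if (length(fin) > 1L) ties <- ties + 1L
  path <- integer(K)
  path[K] <- fin[1L]
  if (K > 1L) for (i in K:2) path[i - 1L] <- BP[[i]][path[i]]
  codons <- vapply(seq_len(K), function(i) layers[[i]][path[i]], character(1))

  sc <- score_sequence(table, codons)
  structure(list(codons = codons, dna = paste(codons, collapse = ""),
                 protein = paste(graph$residues, collapse = ""),
                 total_score = sc$total,
                 junction_scores = sc$junctions$score,
                 mode = mode,
                 states_explored = state_space_size(graph),
                 ties_encountered = ties,
                 provenance = table$provenance,
                 dp_scores = D),
            class = "codon_optimization")
}

#' @export
print.codon_optimization <- function(x, ...) {
  cat(sprintf("Codon optimization (mode = %s)\n", x$mode))
  cat("  protein:", x$protein, "\n")
  cat("  cds:    ", x$dna, "\n")
  cat(sprintf("  total score %g over %d junctions; states %d; ties %d\n",
              x$total_score, length(x$junction_scores), x$states_explored,
              x$ties_encountered))
  cat("  table:  ", x$provenance, "\n")
  invisible(x)
}

#' Brute-force enumeration oracle
#'
#' Exhaustively scores every back-translation of the protein and returns the
#' exact optimum of the same objective as [optimize_codon_pairs()]. Used to
#' verify the dynamic program on small inputs; refuses proteins whose
#' candidate count exceeds `cap`. For modes `best` and `worst` the tie-break
#' matches the DP exactly (smallest codon decided from the last position
#' backwards), so the returned path is identical; for `unbiased` the
#' objective value (minimum sum of absolute junction scores) is guaranteed to
#' match but the DP's stepwise secondary key is not replicated.
#'
#' @inheritParams optimize_codon_pairs
#' @param cap Maximum candidate count enumerated (default 1e6).
#' @return A `codon_optimization` (with `states_explored` = number of
#'   candidates enumerated).
#' @export
brute_force_oracle <- function(protein, table = default_rule_table(),
                               mode = c("best", "worst", "unbiased"),
                               code = genetic_code(), append_stop = FALSE,
                               cap = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "codon_pair_table"))
  graph <- build_codon_graph(protein, code, append_stop)
  layers <- graph$layers
  count <- prod(lengths(layers))
  if (count > cap) {
    stop_size(sprintf(
      "candidate count %s exceeds enumeration cap %g",
      candidate_combination_count(paste(graph$residues, collapse = "")), cap))
  }
  # expand.grid varies the first layer fastest: rows are ordered by the last
  # codon first — exactly the DP's traceback tie-break order.
  paths <- as.matrix(expand.grid(layers, stringsAsFactors = FALSE,
                                 KEEP.OUT.ATTRS = FALSE))
  K <- ncol(paths)
  totals <- numeric(nrow(paths))
  abstot <- numeric(nrow(paths))
  if (K > 1L) {
    for (i in seq_len(K - 1L)) {
      s <- table$scores[cbind(paths[, i], paths[, i + 1L])]
      totals <- totals + s
      abstot <- abstot + abs(s)
    }
  }
  obj <- switch(mode, best = totals, worst = -totals, unbiased = -abstot)
  pick <- which.max(obj)  # first row achieving the optimum
  codons <- unname(paths[pick, ])
  sc <- score_sequence(table, codons)
  structure(list(codons = codons, dna = paste(codons, collapse = ""),
                 protein = paste(graph$residues, collapse = ""),
                 total_score = sc$total,
                 junction_scores = sc$junctions$score,
                 mode = mode,
                 states_explored = nrow(paths),
                 ties_encountered = sum(obj == obj[pick]) - 1L,
                 provenance = table$provenance),
            class = "codon_optimization")
}
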