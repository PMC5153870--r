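#' Stage one: greedy seed generation from sequence similarity
#'
#' Builds the seed set of the aligner from BLAST bit-scores. Among all couples
#' with bit-score at least `ell`, couples are matched greedily in descending
#' score order; matching a couple forbids every other couple sharing either of
#' its proteins. When several admissible couples tie on the maximal score, one
#' is drawn uniformly at random (tied couples are considered in lexicographic
#' order so a fixed RNG state gives a reproducible draw).
#'
#' Couples whose proteins do not occur in the networks being aligned are still
#' admissible (the rule operates on the similarity table alone); the aligner
#' warns about them later since they cannot gain percolation neighbours.
#'
#' @param sim a [similarity_table()].
#' @param ell non-negative bit-score threshold; couples scoring below `ell`
#'   are never matched. Default 150.
#' @return A seed-only [make_alignment()] object (all origins `"seed"`).
#' @seealso [map_percolation()] for stage two, [proper()] for the full run.
#' @export
generate_seeds <- function(sim, ell = 150) {
  if (!inherits(sim, "similarity_table"))
    stop("sim must be a similarity_table")
  if (!is.numeric(ell) || length(ell) != 1L || is.na(ell) || ell < 0)
    stop("ell must be a single non-negative number")
  df <- sim$cross[sim$cross$score >= ell, , drop = FALSE]
  if (!nrow(df)) return(make_alignment())
  # descending score; lexicographic within a score group fixes the tie order
  df <- df[order(-df$score, df$protein1, df$protein2), , drop = FALSE]
  p1 <- df$protein1; p2 <- df$protein2
  out1 <- character(nrow(df)); out2 <- character(nrow(df)); k <- 0L
  groups <- split(seq_len(nrow(df)), factor(-df$score, levels = unique(-df$score)))
  for (g in groups) {
    # drop couples already forbidden by higher-scoring matches, then match
    # within the group; each match only forbids couples sharing an endpoint
    alive <- !(p1[g] %in% out1[seq_len(k)]) & !(p2[g] %in% out2[seq_len(k)])
    repeat {
      cand <- g[alive]
      if (!length(cand)) break
      pick <- if (length(cand) == 1L) cand else
        cand[floor(stats::runif(1) * length(cand)) + 1L]
      k <- k + 1L
      out1[k] <- p1[pick]; out2[k] <- p2[pick]
      alive <- alive & p1[g] != p1[pick] & p2[g] != p2[pick]
    }
  }
  make_alignment(out1[seq_len(k)], out2[seq_len(k)], origin = "seed")
}
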