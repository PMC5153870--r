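# Independent reference implementations, kept deliberately naive.

# Percolation by full rescan: at every step recompute the score of every
# unmatched couple from scratch, apply the same selection and tie-break rules
# as the engine (max score, min degree gap, min degree sum, uniform draw over
# the lexicographically ordered tied set), and stop when the best score drops
# below r. Consumes the RNG exactly as the engine does: one uniform per
# genuinely tied choice.
naive_percolation <- function(net1, net2, seeds, r) {
  n1 <- n_nodes(net1); n2 <- n_nodes(net2)
  d1 <- lengths(net1$adj); d2 <- lengths(net2$adj)
  m1 <- rep(NA_integer_, n1); m2 <- rep(NA_integer_, n2)
  i1 <- match(seeds$protein1, net1$nodes)
  i2 <- match(seeds$protein2, net2$nodes)
  m1[i1] <- i2; m2[i2] <- i1
  out <- list()
  repeat {
    S <- matrix(0L, n1, n2)
    for (k in which(!is.na(m1))) {
      nb1 <- net1$adj[[k]]
      nb2 <- net2$adj[[m1[k]]]
      if (length(nb1) && length(nb2))
        S[nb1, nb2] <- S[nb1, nb2] + 1L
    }
    S[!is.na(m1), ] <- -1L
    S[, !is.na(m2)] <- -1L
    mx <- max(S)
    if (mx < r) break
    cand <- which(S == mx, arr.ind = TRUE)
    gap <- abs(d1[cand[, 1]] - d2[cand[, 2]])
    cand <- cand[gap == min(gap), , drop = FALSE]
    dsum <- d1[cand[, 1]] + d2[cand[, 2]]
    cand <- cand[dsum == min(dsum), , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    pick <- if (nrow(cand) == 1L) 1L else
      min(floor(stats::runif(1) * nrow(cand)) + 1L, nrow(cand))
    i <- cand[pick, 1]; j <- cand[pick, 2]
    m1[i] <- j; m2[j] <- i
    out[[length(out) + 1L]] <- c(i, j, mx)
  }
  if (!length(out))
    return(make_alignment(seeds$protein1, seeds$protein2))
  m <- do.call(rbind, out)
  make_alignment(c(seeds$protein1, net1$nodes[m[, 1]]),
                 c(seeds$protein2, net2$nodes[m[, 2]]),
                 origin = rep(c("seed", "percolated"),
                              c(nrow(seeds), nrow(m))),
                 match_score = c(rep(NA_integer_, nrow(seeds)), m[, 3]))
}

# Greedy seed matching by explicit sort (valid when all scores are distinct):
# sort by descending score then lexicographic couple order, take every couple
# not conflicting with one already taken.
naive_seeds <- function(sim, ell) {
  df <- sim$cross[sim$cross$score >= ell, , drop = FALSE]
  df <- df[order(-df$score, df$protein1, df$protein2), , drop = FALSE]
  used1 <- character(); used2 <- character()
  keep <- logical(nrow(df))
  for (k in seq_len(nrow(df))) {
    if (!(df$protein1[k] %in% used1) && !(df$protein2[k] %in% used2)) {
      keep[k] <- TRUE
      used1 <- c(used1, df$protein1[k])
      used2 <- c(used2, df$protein2[k])
    }
  }
  make_alignment(df$protein1[keep], df$protein2[keep])
}

# Termination certificate: no fully-unmatched couple may still have r or more
# common matched neighbours (scores only grow as the alignment grows, so
# checking the final state is sufficient).
check_termination <- function(net1, net2, aln, r) {
  free1 <- setdiff(net1$nodes, aln$protein1)
  free2 <- setdiff(net2$nodes, aln$protein2)
  for (u in free1)
    for (v in free2)
      if (couple_score(u, v, aln, net1, net2) >= r) return(FALSE)
  TRUE
}
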