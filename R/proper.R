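#' Align two PPI networks by seed generation and percolation matching
#'
#' The main fitting function of the package. Runs the two-stage aligner:
#' first a seed set is matched greedily from the BLAST bit-score table
#' (couples scoring at least `ell`, highest first; see [generate_seeds()]);
#' then the alignment percolates outwards from the seeds using network
#' structure only, matching at each step the couple with the most
#' already-matched common neighbours, as long as that count is at least `r`
#' (see [map_percolation()]). Both stages draw tie-break randomness from one
#' RNG stream, so a fixed `seed` makes the whole run reproducible.
#'
#' @param net1,net2 `ppi_network` objects (conventionally `net1` is the
#'   smaller network, but any order is accepted and preserved).
#' @param sim a [similarity_table()] of cross bit-scores between `net1` and
#'   `net2` proteins.
#' @param ell sequence-similarity threshold for seeding (default 150).
#' @param r structural-evidence threshold for percolation (default 1).
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   before stage one.
#' @return An object of class `proper`: a list with elements `alignment`
#'   (a `ppi_alignment`), `n_seed`, `n_percolated`, `ell`, `r`, `seed`,
#'   `net1_size`, `net2_size` (node/edge counts) and `call`. Methods:
#'   [print.proper()], [summary.proper()], [coef.proper()] (the mapping as a
#'   named character vector), `as.data.frame`, [plot.proper()].
#' @examples
#' g <- ppi_network(rbind(c("a", "b"), c("b", "c")))
#' h <- ppi_network(rbind(c("x", "y"), c("y", "z")))
#' sim <- similarity_table("a", "x", 500)
#' fit <- proper(g, h, sim, ell = 150, r = 1, seed = 1)
#' coef(fit)
#' @export
proper <- function(net1, net2, sim, ell = 150, r = 1, seed = NULL) {
  stopifnot(inherits(net1, "ppi_network"), inherits(net2, "ppi_network"))
  if (!is.null(seed)) set.seed(seed)
  seeds <- generate_seeds(sim, ell = ell)
  aln <- map_percolation(net1, net2, seeds, r = r)
  structure(list(
    alignment = aln,
    n_seed = nrow(seeds),
    n_percolated = nrow(aln) - nrow(seeds),
    ell = ell, r = r, seed = seed,
    net1_size = c(nodes = n_nodes(net1), edges = n_edges(net1)),
    net2_size = c(nodes = n_nodes(net2), edges = n_edges(net2)),
    call = match.call()), class = "proper")
}

#' @export
print.proper <- function(x, ...) {
  cat("Two-stage percolation network alignment\n")
  cat(sprintf("  networks: %d/%d proteins, %d/%d interactions\n",
              x$net1_size["nodes"], x$net2_size["nodes"],
              x$net1_size["edges"], x$net2_size["edges"]))
  cat(sprintf("  thresholds: ell = %g (sequence), r = %d (structure)\n",
              x$ell, as.integer(x$r)))
  cat(sprintf("  couples: %d seed + %d percolated = %d total\n",
              x$n_seed, x$n_percolated, nrow(x$alignment)))
  invisible(x)
}

#' Summarise a fitted alignment
#'
#' @param object a `proper` fit.
#' @param ... unused.
#' @return A list of class `summary.proper` with the two-stage accounting,
#'   coverage of the smaller network, and the distribution of percolation
#'   match scores.
#' @export
summary.proper <- function(object, ...) {
  sc <- object$alignment$match_score
  sc <- sc[!is.na(sc)]
  out <- list(
    n_seed = object$n_seed,
    n_percolated = object$n_percolated,
    n_total = nrow(object$alignment),
    coverage = nrow(object$alignment) /
      min(object$net1_size["nodes"], object$net2_size["nodes"]),
    score_table = if (length(sc)) table(sc) else table(integer()),
    ell = object$ell, r = object$r)
  class(out) <- "summary.proper"
  out
}

#' @export
print.summary.proper <- function(x, ...) {
  cat(sprintf("Alignment of %d couples (%d seed, %d percolated)\n",
              x$n_total, x$n_seed, x$n_percolated))
  cat(sprintf("Coverage of smaller network: %.3f\n", x$coverage))
  if (length(x$score_table)) {
    cat("Match-score distribution (percolated couples):\n")
    print(x$score_table)
  }
  invisible(x)
}

#' Extract the fitted node mapping
#' @param object a `proper` fit.
#' @param ... unused.
#' @return Named character vector: names are network-1 proteins, values their
#'   aligned network-2 partners.
#' @export
coef.proper <- function(object, ...) alignment_map(object$alignment)

#' @export
as.data.frame.proper <- function(x, ...) as.data.frame(x$alignment, ...)

#' Plot the growth of a percolation alignment
#'
#' Shows the cumulative number of matched couples over match steps, split at
#' the seed/percolation boundary, and the match-score trajectory of the
#' percolated couples.
#'
#' @param x a `proper` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.proper <- function(x, ...) {
  n <- nrow(x$alignment)
  graphics::plot(seq_len(n), seq_len(n), type = "l",
                 xlab = "match step", ylab = "couples matched",
                 main = "Alignment growth", ...)
  graphics::abline(v = x$n_seed + 0.5, lty = 2)
  graphics::mtext(sprintf("seeds: %d | percolated: %d",
                          x$n_seed, x$n_percolated), cex = 0.8)
  invisible(x)
}
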