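#' Erdős–Rényi random PPI network
#'
#' Samples a G(n, p) graph: each of the `choose(n, 2)` unordered protein
#' pairs interacts independently with probability `p`. Draws from R's RNG
#' stream (`set.seed()` upstream makes it reproducible).
#'
#' @param n node count.
#' @param p edge probability in \[0, 1\].
#' @param prefix node-id prefix; ids are `prefix` plus a zero-padded index.
#' @return A `ppi_network`.
#' @export
erdos_renyi <- function(n, p, prefix = "p") {
  stopifnot(n >= 0, p >= 0, p <= 1)
  ids <- sprintf("%s%0*d", prefix, max(1L, nchar(n)), seq_len(n))
  g <- igraph::sample_gnp(n, p)
  e <- igraph::as_edgelist(g, names = FALSE)
  ppi_network(cbind(ids[e[, 1L]], ids[e[, 2L]]), nodes = ids)
}

#' Sample a descendant network by node and edge deletion
#'
#' Models divergence from a common ancestor by pure loss: each protein of `g`
#' survives independently with probability `t`; each interaction whose
#' endpoints both survive is retained independently with probability `s`.
#' The descendant never contains an edge absent from the ancestor.
#'
#' @param g ancestor `ppi_network`.
#' @param t node survival probability in \[0, 1\].
#' @param s edge survival probability in \[0, 1\].
#' @param prefix prefix prepended to surviving node ids, so descendant ids
#'   are a deterministic relabeling of ancestor ids and ground truth is
#'   recoverable without positional assumptions.
#' @return `list(net =, survival =)`: the descendant `ppi_network` and a
#'   named character vector mapping surviving ancestor ids to descendant ids.
#' @export
evolve <- function(g, t, s, prefix = "") {
  stopifnot(t >= 0, t <= 1, s >= 0, s <= 1)
  n <- n_nodes(g)
  keep_node <- stats::runif(n) < t
  e <- g$edges
  both <- keep_node[e[, 1L]] & keep_node[e[, 2L]]
  keep_edge <- both & stats::runif(nrow(e)) < s
  surv <- g$nodes[keep_node]
  survival <- stats::setNames(paste0(prefix, surv, recycle0 = TRUE), surv)
  e <- e[keep_edge, , drop = FALSE]
  net <- ppi_network(cbind(paste0(prefix, g$nodes[e[, 1L]], recycle0 = TRUE),
                           paste0(prefix, g$nodes[e[, 2L]], recycle0 = TRUE)),
                     nodes = survival)
  list(net = net, survival = survival)
}

#' Sample a correlated random bigraph
#'
#' The G(n, p; t, s) model: an Erdős–Rényi ancestor G(n, p) and two
#' descendants drawn by two independent [evolve()] processes with the same
#' `t` and `s`. The ground truth couples the copies of every ancestor protein
#' surviving in both descendants.
#'
#' @inheritParams erdos_renyi
#' @inheritParams evolve
#' @return A list of class `bigraph_sample`: `ancestor`, `net1`, `net2`
#'   (`ppi_network`s, node ids prefixed `x_` and `y_`), and `truth` (named
#'   character vector, net1 id -> net2 id).
#' @export
sample_bigraph <- function(n, p, t, s) {
  anc <- erdos_renyi(n, p)
  d1 <- evolve(anc, t, s, prefix = "x_")
  d2 <- evolve(anc, t, s, prefix = "y_")
  common <- intersect(names(d1$survival), names(d2$survival))
  structure(list(
    ancestor = anc, net1 = d1$net, net2 = d2$net,
    truth = stats::setNames(d2$survival[common], d1$survival[common])),
    class = "bigraph_sample")
}

#' @export
print.bigraph_sample <- function(x, ...) {
  cat(sprintf(
    "Correlated bigraph: ancestor %d/%d, net1 %d/%d, net2 %d/%d, truth %d\n",
    n_nodes(x$ancestor), n_edges(x$ancestor), n_nodes(x$net1),
    n_edges(x$net1), n_nodes(x$net2), n_edges(x$net2), length(x$truth)))
  invisible(x)
}

#' Noisy copy of a network
#'
#' Samples each node and each surviving interaction of `g` with the same
#' probability `s` (so `1 - s` is the noise level). Nodes left without any
#' interaction are removed by default, since an isolated protein carries no
#' structural signal for percolation.
#'
#' @inheritParams evolve
#' @param s node and edge sampling probability in \[0, 1\].
#' @param drop_isolated remove nodes of degree zero after edge sampling
#'   (default TRUE).
#' @param prefix prefix for copy node ids (default `"c_"`).
#' @return `list(net =, survival =)` as for [evolve()]; the survival map only
#'   covers nodes retained in the copy.
#' @export
noisy_copy <- function(g, s, drop_isolated = TRUE, prefix = "c_") {
  out <- evolve(g, t = s, s = s, prefix = prefix)
  if (drop_isolated) {
    deg <- net_degree(out$net)
    keep <- names(deg)[deg > 0]
    out$survival <- out$survival[out$survival %in% keep]
    e <- edge_list(out$net)
    out$net <- ppi_network(e, nodes = keep)
  }
  out
}

#' Synthetic sequence-similarity side information
#'
#' Emits a cross bit-score for a random subset of the true couples (each
#' couple independently with probability `fraction`), plus unit self-scores
#' for the proteins involved, emulating partial BLAST knowledge in synthetic
#' benchmarks. By default every emitted score is `2 * ell` — strictly above
#' the seeding threshold — and no spurious couples are emitted; a score
#' generator and a spurious-couple rate are available for robustness studies.
#'
#' @param truth named character vector of true couples (net1 id -> net2 id).
#' @param fraction probability that a true couple is revealed, in \[0, 1\].
#' @param ell seeding threshold the scores must clear (default 150).
#' @param scores `NULL` (every revealed couple scores `2 * ell`) or a
#'   `function(k)` returning `k` bit-scores.
#' @param spurious_rate expected number of random false couples emitted per
#'   revealed true couple (default 0).
#' @return A [similarity_table()].
#' @export
sideinfo_table <- function(truth, fraction, ell = 150, scores = NULL,
                           spurious_rate = 0) {
  stopifnot(fraction >= 0, fraction <= 1, spurious_rate >= 0)
  truth <- as_truth(truth)
  pick <- stats::runif(length(truth)) < fraction
  p1 <- names(truth)[pick]
  p2 <- unname(truth[pick])
  k <- length(p1)
  sc <- if (is.null(scores)) rep(2 * ell, k) else as.numeric(scores(k))
  if (spurious_rate > 0 && k > 0 && length(truth) > 1) {
    ns <- stats::rbinom(1L, k, min(1, spurious_rate))
    if (ns > 0) {
      f1 <- sample(names(truth), ns, replace = TRUE)
      f2 <- sample(unname(truth), ns, replace = TRUE)
      ok <- truth[f1] != f2
      p1 <- c(p1, f1[ok]); p2 <- c(p2, f2[ok])
      sc <- c(sc, rep(2 * ell, sum(ok)))
    }
  }
  similarity_table(p1, p2, sc,
                   self_scores = stats::setNames(rep(1, length(p1) + length(p2)),
                                                 c(p1, p2)))
}

#' Noise-robustness experiment on a base network
#'
#' The standard synthetic benchmark: for each noise level and replicate, draw
#' a [noisy_copy()] of the base network, reveal similarity side information
#' for a fraction of the surviving true couples, run the full aligner and
#' score node correctness and precision against the known ground truth (the
#' smaller network — the copy — provides the NC denominator).
#'
#' @param base base `ppi_network` (plays the ancestor and network 1).
#' @param noise numeric vector of noise levels `1 - s` in \[0, 1\].
#' @param sideinfo_fraction fraction of surviving true couples revealed
#'   (default 0.5).
#' @param reps replicates per noise level (default 10).
#' @param ell,r aligner thresholds (defaults 150 and 1).
#' @param seed optional integer seed for the whole experiment.
#' @param scores optional score generator passed to [sideinfo_table()].
#' @return A list of class `alignment_experiment`: `per_rep` data frame
#'   (`noise`, `sideinfo_fraction`, `rep`, `n_seed`, `n_aligned`, `nc`,
#'   `precision`) and `summary` (mean and SD of NC and precision per noise
#'   level).
#' @export
run_experiment <- function(base, noise, sideinfo_fraction = 0.5, reps = 10,
                           ell = 150, r = 1, seed = NULL, scores = NULL) {
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (nz in noise) {
    for (rep in seq_len(reps)) {
      cp <- noisy_copy(base, s = 1 - nz)
      sim <- sideinfo_table(cp$survival, sideinfo_fraction, ell = ell,
                            scores = scores)
      fit <- proper(base, cp$net, sim, ell = ell, r = r)
      rows[[length(rows) + 1L]] <- data.frame(
        noise = nz, sideinfo_fraction = sideinfo_fraction, rep = rep,
        n_seed = fit$n_seed, n_aligned = nrow(fit$alignment),
        nc = node_correctness(fit$alignment, cp$survival,
                              n_nodes(cp$net)),
        precision = alignment_precision(fit$alignment, cp$survival))
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$noise), function(d)
    data.frame(noise = d$noise[1L], reps = nrow(d),
               nc_mean = mean(d$nc), nc_sd = stats::sd(d$nc),
               precision_mean = mean(d$precision),
               precision_sd = stats::sd(d$precision))))
  rownames(summ) <- NULL
  structure(list(per_rep = per_rep, summary = summ),
            class = "alignment_experiment")
}

#' @export
print.alignment_experiment <- function(x, ...) {
  cat("Synthetic alignment experiment\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
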