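#' Common-matched-neighbour score of a couple
#'
#' The percolation score of a couple (u, v) is the number of already-matched
#' couples (i, j) such that u interacts with i in network 1 and v interacts
#' with j in network 2. This is the structural evidence on which stage two of
#' the aligner decides which couple to match next.
#'
#' @param u a network-1 protein id.
#' @param v a network-2 protein id.
#' @param aln current alignment (any object accepted by the package's
#'   alignment coercion: a `ppi_alignment`, a fitted `proper` object, or a
#'   two-column table).
#' @param net1,net2 `ppi_network` objects containing `u` and `v`.
#' @return Integer score.
#' @export
couple_score <- function(u, v, aln, net1, net2) {
  iu <- node_index(net1, u)
  iv <- node_index(net2, v)
  aln <- as_alignment(aln)
  if (!nrow(aln)) return(0L)
  map <- alignment_map(aln)
  nb1 <- net1$nodes[net1$adj[[iu]]]
  img <- map[nb1]
  img <- img[!is.na(img)]
  sum(img %in% net2$nodes[net2$adj[[iv]]])
}

#' Stage two: percolation graph matching from a seed alignment
#'
#' Starting from the seed couples, repeatedly matches the unmatched couple
#' with the largest common-matched-neighbour score (see [couple_score()]),
#' provided that score is at least `r`. Ties on the score are broken by the
#' smallest degree difference between the two proteins, then by the smallest
#' degree sum (fewest mismatched interactions), then by a uniform random draw.
#' Matches are permanent; the procedure stops when no fully-unmatched couple
#' has score at least `r`. Only network structure is used: sequence
#' similarity never enters this stage.
#'
#' @param net1,net2 `ppi_network` objects.
#' @param seeds a seed alignment (injective); couples referencing proteins
#'   absent from the networks are kept in the output but cannot percolate (a
#'   warning is issued).
#' @param r minimum score required to match a couple (positive integer;
#'   default 1, which admits degree-1 proteins — a larger `r` demands more
#'   structural evidence but cannot align nodes of degree below `r`).
#' @return A [make_alignment()] object: the seeds plus the percolated couples
#'   in match order, each percolated couple carrying its score at match time.
#' @export
map_percolation <- function(net1, net2, seeds, r = 1) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r != round(r))
    stop("r must be a single positive integer")
  seeds <- as_alignment(seeds)
  i1 <- match(seeds$protein1, net1$nodes)
  i2 <- match(seeds$protein2, net2$nodes)
  half <- is.na(i1) | is.na(i2)
  if (any(half))
    warning(sprintf(
      "%d seed couple(s) reference proteins absent from the networks and cannot percolate",
      sum(half)))
  res <- .percolate_engine(
    lapply(net1$adj, function(v) v - 1L),
    lapply(net2$adj, function(v) v - 1L),
    i1[!half] - 1L, i2[!half] - 1L,
    i1[half & !is.na(i1)] - 1L, i2[half & !is.na(i2)] - 1L,
    as.integer(r))
  make_alignment(
    c(seeds$protein1, net1$nodes[res$i + 1L]),
    c(seeds$protein2, net2$nodes[res$j + 1L]),
    origin = rep(c("seed", "percolated"), c(nrow(seeds), length(res$i))),
    match_score = c(rep(NA_integer_, nrow(seeds)), res$score))
}
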