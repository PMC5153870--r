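#' Topological and functional alignment-quality measures
#'
#' These functions score an alignment `pi` of a smaller network G1 into a
#' larger network G2. Node correctness and precision need a ground-truth
#' mapping and so apply to synthetic benchmarks; the remaining measures work
#' on real data. Measures with a zero denominator are undefined and returned
#' as `NA` (never 0), so they cannot be mistaken for poor scores.
#'
#' @name alignment-measures
#' @param aln alignment (anything accepted by the package's alignment
#'   coercion).
#' @param truth ground-truth mapping: named character vector (names =
#'   network-1 proteins, values = true network-2 partners) or two-column
#'   table.
#' @param net1,net2 `ppi_network` objects.
#' @param n1 number of nodes of the smaller network (the NC and ANBS
#'   denominator).
NULL

as_truth <- function(truth) {
  if (is.null(names(truth)) || !is.character(truth)) {
    truth <- as.data.frame(truth, stringsAsFactors = FALSE)
    if (anyDuplicated(truth[[1L]]))
      stop("ground truth maps a protein twice")
    truth <- stats::setNames(as.character(truth[[2L]]),
                             as.character(truth[[1L]]))
  }
  truth
}

count_correct <- function(aln, truth) {
  aln <- as_alignment(aln)
  truth <- as_truth(truth)
  sum(!is.na(truth[aln$protein1]) & truth[aln$protein1] == aln$protein2)
}

#' @describeIn alignment-measures fraction of the smaller network's nodes
#'   aligned to their true partners: correct couples / `n1`.
#' @export
node_correctness <- function(aln, truth, n1) {
  if (!is.numeric(n1) || length(n1) != 1L || is.na(n1) || n1 < 1)
    stop("n1 must be a positive count")
  count_correct(aln, truth) / n1
}

#' @describeIn alignment-measures correct couples / total couples; `NA` for an
#'   empty alignment.
#' @export
alignment_precision <- function(aln, truth) {
  aln <- as_alignment(aln)
  if (!nrow(aln)) return(NA_real_)
  count_correct(aln, truth) / nrow(aln)
}

#' @describeIn alignment-measures number of conserved interactions
#'   Delta-pi = |pi(E1) intersect E2|.
#' @export
conserved_interactions <- function(aln, net1, net2) {
  n_edges(intersection_graph(net1, net2, aln))
}

#' @describeIn alignment-measures edge correctness EC = Delta-pi / |E1|.
#' @export
edge_correctness <- function(aln, net1, net2) {
  if (!n_edges(net1)) return(NA_real_)
  conserved_interactions(aln, net1, net2) / n_edges(net1)
}

# |E_{G2[pi(V1)]}|: edges of G2 induced by the image of the alignment
image_induced_edges <- function(aln, net2) {
  aln <- as_alignment(aln)
  idx <- node_index(net2, aln$protein2)
  inset <- logical(length(net2$nodes))
  inset[idx] <- TRUE
  sum(inset[net2$edges[, 1L]] & inset[net2$edges[, 2L]])
}

#' @describeIn alignment-measures induced conserved structure
#'   ICS = Delta-pi / |E_{G2\[pi(V1)\]}|; penalises mapping into dense regions
#'   of G2.
#' @export
induced_conserved_structure <- function(aln, net1, net2) {
  denom <- image_induced_edges(aln, net2)
  if (!denom) return(NA_real_)
  conserved_interactions(aln, net1, net2) / denom
}

#' @describeIn alignment-measures symmetric substructure score
#'   S3 = Delta-pi / (|E1| + |E_{G2\[pi(V1)\]}| - Delta-pi); penalises density
#'   mismatch in both directions.
#' @export
symmetric_substructure <- function(aln, net1, net2) {
  dp <- conserved_interactions(aln, net1, net2)
  denom <- n_edges(net1) + image_induced_edges(aln, net2) - dp
  if (denom <= 0) return(NA_real_)
  dp / denom
}

#' @describeIn alignment-measures largest connected shared component: size
#'   (nodes) of the largest connected component of the conserved intersection
#'   graph, and its share of |V1|. Returns `list(size =, share =)`.
#' @export
lcsc <- function(aln, net1, net2) {
  if (!n_nodes(net1)) stop("net1 has no nodes")
  g0 <- intersection_graph(net1, net2, aln)
  size <- if (!n_nodes(g0)) 0L else
    max(igraph::components(as_igraph(g0))$csize)
  list(size = as.integer(size), share = size / n_nodes(net1))
}

#' GO-consistency of one aligned couple
#'
#' Jaccard similarity between the GO term sets of the two proteins, after an
#' optional evidence-code filter. An empty term union gives 0 (not `NA`), so
#' the GOC sum over all of V1 stays well defined.
#'
#' @param u,v protein ids in networks 1 and 2.
#' @param ann1,ann2 [annotation_set()] objects; proteins absent from them have
#'   empty term sets.
#' @param evidence_filter optional character vector of evidence codes to keep
#'   (e.g. [experimental_evidence_codes]); `NULL` keeps all terms.
#' @return Jaccard coefficient in \[0, 1\].
#' @export
goc_couple <- function(u, v, ann1, ann2, evidence_filter = NULL) {
  t1 <- go_terms(ann1, u, evidence_filter)
  t2 <- go_terms(ann2, v, evidence_filter)
  un <- length(union(t1, t2))
  if (!un) return(0)
  length(intersect(t1, t2)) / un
}

#' Total GO-consistency score of an alignment
#'
#' Sum of [goc_couple()] over all aligned couples (unaligned network-1
#' proteins contribute 0, so this is the sum over V1).
#'
#' @inheritParams alignment-measures
#' @inheritParams goc_couple
#' @return Non-negative number, at most the number of couples.
#' @export
goc_total <- function(aln, ann1, ann2, evidence_filter = NULL) {
  aln <- as_alignment(aln)
  if (!nrow(aln)) return(0)
  sum(vapply(seq_len(nrow(aln)), function(k)
    goc_couple(aln$protein1[k], aln$protein2[k], ann1, ann2,
               evidence_filter), numeric(1)))
}

#' Average normalized bit-score of an alignment
#'
#' For each aligned couple the cross bit-score is normalized by the geometric
#' mean of the two self bit-scores; the sum over aligned couples is divided by
#' `n1`, the node count of the smaller network. Couples with no recorded
#' cross-score contribute 0, but every aligned protein must have a positive
#' self-score.
#'
#' @inheritParams alignment-measures
#' @param sim a [similarity_table()] with `self_scores`.
#' @return Fraction in \[0, 1\].
#' @export
anbs <- function(aln, sim, n1) {
  if (!is.numeric(n1) || length(n1) != 1L || is.na(n1) || n1 < 1)
    stop("n1 must be a positive count")
  aln <- as_alignment(aln)
  if (!nrow(aln)) return(0)
  s1 <- sim$self_scores[aln$protein1]
  s2 <- sim$self_scores[aln$protein2]
  bad <- c(aln$protein1[is.na(s1) | s1 <= 0], aln$protein2[is.na(s2) | s2 <= 0])
  if (length(bad))
    stop("missing or zero self bit-score for aligned protein(s): ",
         paste(unique(bad), collapse = ", "))
  cs <- cross_score(sim, aln$protein1, aln$protein2)
  cs[is.na(cs)] <- 0
  sum(cs / sqrt(s1 * s2)) / n1
}

#' Evaluate an alignment with the full measure battery
#'
#' Computes every applicable quality measure for an alignment of `net1` into
#' `net2`. The measures assume |V1| <= |V2|; when `net2` is the smaller
#' network the inputs (and the alignment) are reoriented internally and the
#' report records the orientation used. Measures whose inputs are absent
#' (ground truth, annotations, similarity) or whose denominator is zero are
#' reported as `NA`.
#'
#' @inheritParams alignment-measures
#' @param sim optional [similarity_table()] (enables ANBS).
#' @param ann1,ann2 optional [annotation_set()] objects (enable GOC).
#' @param evidence_filter optional evidence-code filter for GOC, e.g.
#'   [experimental_evidence_codes].
#' @return A list of class `measure_report` with fields `nc`, `precision`,
#'   `delta_pi`, `ec`, `ics`, `s3`, `lcsc_size`, `lcsc_share`, `goc`, `anbs`,
#'   `n_couples` and `swapped` (TRUE if the roles of the inputs were
#'   exchanged so that the smaller network is G1).
#' @export
evaluate_alignment <- function(aln, net1, net2, truth = NULL, sim = NULL,
                               ann1 = NULL, ann2 = NULL,
                               evidence_filter = NULL) {
  aln <- as_alignment(aln)
  swapped <- n_nodes(net2) < n_nodes(net1)
  if (swapped) {
    tmp <- net1; net1 <- net2; net2 <- tmp
    aln <- make_alignment(aln$protein2, aln$protein1, aln$origin,
                          aln$match_score)
    tmp <- ann1; ann1 <- ann2; ann2 <- tmp
    if (!is.null(truth)) {
      truth <- as_truth(truth)
      truth <- stats::setNames(names(truth), truth)
    }
    if (!is.null(sim))
      sim <- similarity_table(sim$cross$protein2, sim$cross$protein1,
                              sim$cross$score, sim$self_scores)
  }
  n1 <- n_nodes(net1)
  comp <- lcsc(aln, net1, net2)
  structure(list(
    nc = if (is.null(truth)) NA_real_ else node_correctness(aln, truth, n1),
    precision = if (is.null(truth)) NA_real_ else
      alignment_precision(aln, truth),
    delta_pi = conserved_interactions(aln, net1, net2),
    ec = edge_correctness(aln, net1, net2),
    ics = induced_conserved_structure(aln, net1, net2),
    s3 = symmetric_substructure(aln, net1, net2),
    lcsc_size = comp$size,
    lcsc_share = comp$share,
    goc = if (is.null(ann1) || is.null(ann2)) NA_real_ else
      goc_total(aln, ann1, ann2, evidence_filter),
    anbs = if (is.null(sim)) NA_real_ else anbs(aln, sim, n1),
    n_couples = nrow(aln),
    swapped = swapped), class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat("Alignment quality report",
      if (x$swapped) "(networks reoriented so G1 is the smaller)" else "",
      "\n")
  for (f in c("n_couples", "delta_pi", "lcsc_size"))
    cat(sprintf("  %-10s %d\n", f, x[[f]]))
  for (f in c("nc", "precision", "ec", "ics", "s3", "lcsc_share", "goc",
              "anbs"))
    cat(sprintf("  %-10s %s\n", f,
                if (is.na(x[[f]])) "NA" else format(x[[f]], digits = 4)))
  invisible(x)
}
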