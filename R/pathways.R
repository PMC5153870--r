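#' Pathway membership table for two species
#'
#' Pathways (e.g. KEGG pathways sharing the same number across species) with
#' their member proteins in each of the two aligned networks. Only pathways
#' present in both species are retained; pathways listed for one species only
#' are dropped with a message.
#'
#' @param pathway,species,protein character/integer vectors of equal length:
#'   one membership row per element, `species` in `{1, 2}`.
#' @return An object of class `pathway_table`: a named list, one element per
#'   pathway id, each `list(sp1 = <protein set>, sp2 = <protein set>)`.
#' @export
pathway_table <- function(pathway = character(), species = integer(),
                          protein = character()) {
  pathway <- as.character(pathway)
  species <- as.integer(species)
  protein <- as.character(protein)
  n <- length(pathway)
  if (length(species) != n || length(protein) != n)
    stop("pathway, species and protein must have equal length")
  if (n && !all(species %in% c(1L, 2L)))
    stop("species index must be 1 or 2")
  ids <- unique(pathway)
  tab <- lapply(ids, function(id) list(
    sp1 = unique(protein[pathway == id & species == 1L]),
    sp2 = unique(protein[pathway == id & species == 2L])))
  names(tab) <- ids
  both <- vapply(tab, function(p) length(p$sp1) > 0 && length(p$sp2) > 0,
                 logical(1))
  if (any(!both))
    message(sprintf("dropped %d pathway(s) present in only one species",
                    sum(!both)))
  structure(tab[both], class = "pathway_table")
}

#' @export
print.pathway_table <- function(x, ...) {
  cat(sprintf("Pathway table: %d pathways present in both species\n",
              length(x)))
  invisible(x)
}

#' Conserved interactions within one pathway
#'
#' Counts the network-1 interactions between proteins of the pathway whose
#' images under the alignment are interactions between proteins of the same
#' pathway in network 2.
#'
#' @param aln alignment.
#' @param net1,net2 `ppi_network` objects.
#' @param pw one pathway entry: `list(sp1 =, sp2 =)` protein sets.
#' @return Integer count (Delta-pi restricted to the pathway).
#' @export
pathway_conserved <- function(aln, net1, net2, pw) {
  aln <- as_alignment(aln)
  keep <- aln$protein1 %in% intersect(pw$sp1, net1$nodes) &
    aln$protein2 %in% intersect(pw$sp2, net2$nodes)
  aln <- aln[keep, , drop = FALSE]
  if (!nrow(aln)) return(0L)
  sub1 <- induced_network(net1, aln$protein1)
  sub2 <- induced_network(net2, aln$protein2)
  conserved_interactions(aln, sub1, sub2)
}

# induced subgraph on a protein set (ids must exist in net)
induced_network <- function(net, ids) {
  idx <- node_index(net, ids)
  inset <- logical(length(net$nodes))
  inset[idx] <- TRUE
  keep <- inset[net$edges[, 1L]] & inset[net$edges[, 2L]]
  e <- net$edges[keep, , drop = FALSE]
  ppi_network(cbind(net$nodes[e[, 1L]], net$nodes[e[, 2L]]), nodes = ids)
}

#' Accuracy of aligning one pathway
#'
#' Fraction of correctly mapped pathway proteins:
#' `2 |PW1 intersect pi^-1(PW2)| / (|PW1| + |PW2|)`. A protein counts as
#' correctly mapped only when its image belongs to the same pathway's
#' network-2 set.
#'
#' @inheritParams pathway_conserved
#' @return Fraction in \[0, 1\], `NA` when both protein sets are empty.
#' @export
pathway_accuracy <- function(aln, pw) {
  denom <- length(pw$sp1) + length(pw$sp2)
  if (!denom) return(NA_real_)
  map <- alignment_map(aln)
  img <- map[pw$sp1]
  2 * sum(!is.na(img) & img %in% pw$sp2) / denom
}

#' Pathway-level evaluation of an alignment
#'
#' A pathway is eligible when it has at least `delta` intra-pathway
#' interactions in each network, and successfully aligned when at least
#' `delta` of those interactions are conserved under the alignment. Recall is
#' the fraction of eligible pathways successfully aligned; accuracies are
#' averaged over all pathways and over the successfully aligned ones.
#'
#' @inheritParams pathway_conserved
#' @param pwt a [pathway_table()].
#' @param delta conserved-interaction threshold (default 4; values >= 2 are
#'   recommended so that "success" requires real shared structure).
#' @return A list of class `pathway_report`: `per_pathway` data frame
#'   (`pathway`, `edges1`, `edges2`, `eligible`, `conserved`,
#'   `correct_mapped`, `acc`, `success`), and aggregates `n_eligible`
#'   (#PW_delta), `n_success` (#FPW_delta), `recall`, `mean_acc` (over all
#'   pathways) and `mean_acc_success` (over successfully aligned eligible
#'   pathways).
#' @export
pathway_recall <- function(aln, net1, net2, pwt, delta = 4) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) || delta < 1)
    stop("delta must be a positive integer")
  aln <- as_alignment(aln)
  map <- alignment_map(aln)
  rows <- lapply(names(pwt), function(id) {
    pw <- pwt[[id]]
    e1 <- n_edges(induced_network(net1, intersect(pw$sp1, net1$nodes)))
    e2 <- n_edges(induced_network(net2, intersect(pw$sp2, net2$nodes)))
    img <- map[pw$sp1]
    data.frame(
      pathway = id, edges1 = e1, edges2 = e2,
      eligible = e1 >= delta && e2 >= delta,
      conserved = pathway_conserved(aln, net1, net2, pw),
      correct_mapped = sum(!is.na(img) & img %in% pw$sp2),
      acc = pathway_accuracy(aln, pw),
      stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  if (is.null(per))
    per <- data.frame(pathway = character(), edges1 = integer(),
                      edges2 = integer(), eligible = logical(),
                      conserved = integer(), correct_mapped = integer(),
                      acc = numeric(), stringsAsFactors = FALSE)
  per$success <- per$eligible & per$conserved >= delta
  n_eligible <- sum(per$eligible)
  n_success <- sum(per$success)
  structure(list(
    per_pathway = per,
    delta = delta,
    n_eligible = n_eligible,
    n_success = n_success,
    recall = if (n_eligible) n_success / n_eligible else NA_real_,
    mean_acc = if (nrow(per)) mean(per$acc, na.rm = TRUE) else NA_real_,
    mean_acc_success = if (n_success) mean(per$acc[per$success]) else
      NA_real_), class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  cat(sprintf(
    "Pathway report (delta = %d): %d eligible, %d successfully aligned\n",
    x$delta, x$n_eligible, x$n_success))
  cat(sprintf("  recall: %s  mean acc: %s  mean acc (successful): %s\n",
              format(x$recall, digits = 4), format(x$mean_acc, digits = 4),
              format(x$mean_acc_success, digits = 4)))
  invisible(x)
}

#' Non-overlapping subset of a pathway table
#'
#' Greedily selects pathways so that no protein belongs to two selected
#' pathways on either side. Pathways are visited by decreasing total size
#' (ties by pathway id), keeping each one iff it shares no protein with any
#' already-kept pathway; the rule is deterministic.
#'
#' @param pwt a [pathway_table()].
#' @return A `pathway_table` containing the selected pathways.
#' @export
nonoverlap_subset <- function(pwt) {
  if (!length(pwt)) return(pwt)
  sizes <- vapply(pwt, function(p) length(p$sp1) + length(p$sp2), numeric(1))
  ord <- names(pwt)[order(-sizes, names(pwt))]
  used1 <- character(); used2 <- character()
  keep <- character()
  for (id in ord) {
    pw <- pwt[[id]]
    if (!any(pw$sp1 %in% used1) && !any(pw$sp2 %in% used2)) {
      keep <- c(keep, id)
      used1 <- c(used1, pw$sp1)
      used2 <- c(used2, pw$sp2)
    }
  }
  structure(pwt[names(pwt) %in% keep], class = "pathway_table")
}
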