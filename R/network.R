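#' Construct an undirected PPI network
#'
#' Builds a simple undirected graph over opaque protein identifiers. Self-loops
#' and duplicate edges are dropped with a warning; isolated nodes may be added
#' explicitly and are kept (they enter the denominators of coverage-style
#' measures such as node correctness and the LCSC share).
#'
#' @param edges two-column character matrix or data frame of interacting
#'   protein pairs, or a list of length-2 character vectors. May have zero rows.
#' @param nodes additional protein identifiers to include as isolated nodes.
#' @return An object of class `ppi_network` with elements `nodes` (character
#'   vector), `edges` (integer matrix, one row per edge, columns indexing into
#'   `nodes`, smaller index first) and `adj` (adjacency list of sorted integer
#'   neighbour indices).
#' @examples
#' net <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' net_degree(net)
#' @export
ppi_network <- function(edges = NULL, nodes = character()) {
  if (is.null(edges)) {
    em <- matrix(character(), ncol = 2L)
  } else if (is.list(edges) && !is.data.frame(edges)) {
    em <- do.call(rbind, lapply(edges, as.character))
    if (is.null(em)) em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    storage.mode(em) <- "character"
  }
  if (ncol(em) != 2L && nrow(em) > 0L)
    stop("edges must have exactly two columns")
  nodes <- as.character(nodes)
  if (any(!nzchar(c(em, nodes))) || anyNA(c(em, nodes)))
    stop("protein identifiers must be non-empty strings")

  ids <- sort(unique(c(em[, 1L], em[, 2L], nodes)))
  loops <- nrow(em) > 0L & em[, 1L] == em[, 2L]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    em <- em[!loops, , drop = FALSE]
  }
  i <- match(em[, 1L], ids)
  j <- match(em[, 2L], ids)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- (i - 1) * length(ids) + j
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge(s)", sum(dup)))
    i <- i[!dup]; j <- j[!dup]
  }
  o <- order(i, j)
  e <- cbind(i = i[o], j = j[o])
  adj <- rep(list(integer()), length(ids))
  if (nrow(e)) {
    half <- c(split(e[, 2L], factor(e[, 1L], levels = seq_along(ids))),
              split(e[, 1L], factor(e[, 2L], levels = seq_along(ids))))
    adj <- lapply(seq_along(ids), function(v)
      sort(c(half[[v]], half[[length(ids) + v]])))
  }
  structure(list(nodes = ids, edges = e, adj = adj), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d proteins, %d interactions\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a PPI network
#' @param net a `ppi_network`.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node degrees
#'
#' @param net a `ppi_network`.
#' @param v optional character vector of protein ids; default all nodes.
#' @return Named integer vector of degrees.
#' @export
net_degree <- function(net, v = NULL) {
  d <- lengths(net$adj)
  names(d) <- net$nodes
  if (is.null(v)) d else d[node_index(net, v)]
}

#' Neighbours of a protein
#' @inheritParams net_degree
#' @param v a single protein id.
#' @return Character vector of interaction partners.
#' @export
net_neighbors <- function(net, v) {
  net$nodes[net$adj[[node_index(net, v)]]]
}

# index lookup with an informative error for unknown proteins
node_index <- function(net, v) {
  idx <- match(v, net$nodes)
  if (anyNA(idx))
    stop("unknown protein(s): ", paste(v[is.na(idx)], collapse = ", "))
  idx
}

#' Edge list of a network
#' @param net a `ppi_network`.
#' @return Two-column character matrix of interacting pairs.
#' @export
edge_list <- function(net) {
  cbind(net$nodes[net$edges[, 1L]], net$nodes[net$edges[, 2L]])
}

# canonical "i|j" keys (i < j, integer indices) for fast edge membership
edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character())
  paste(net$edges[, 1L], net$edges[, 2L], sep = "|")
}

has_edge_idx <- function(keys, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  paste(lo, hi, sep = "|") %in% keys
}

#' Conserved intersection graph of an alignment
#'
#' For networks G1, G2 and a (partial, injective) alignment pi, returns the
#' graph G0 whose vertices are the aligned nodes of G1 and whose edges are the
#' G1 interactions conserved under pi, i.e. those whose images are also
#' interactions of G2. The largest connected component of G0 is the LCSC.
#'
#' @param net1,net2 `ppi_network` objects.
#' @param aln an alignment (see [make_alignment()]); its couples must reference
#'   nodes present in the networks.
#' @return A `ppi_network` on the aligned G1 nodes.
#' @export
intersection_graph <- function(net1, net2, aln) {
  aln <- as_alignment(aln)
  i1 <- node_index(net1, aln$protein1)
  i2 <- node_index(net2, aln$protein2)
  map <- rep(NA_integer_, length(net1$nodes))
  map[i1] <- i2
  e <- net1$edges
  both <- !is.na(map[e[, 1L]]) & !is.na(map[e[, 2L]])
  e <- e[both, , drop = FALSE]
  keep <- has_edge_idx(edge_keys(net2), map[e[, 1L]], map[e[, 2L]])
  ppi_network(cbind(net1$nodes[e[keep, 1L]], net1$nodes[e[keep, 2L]]),
              nodes = aln$protein1)
}

#' Convert a PPI network to an igraph object
#' @param net a `ppi_network`.
#' @return An undirected `igraph` graph with vertex name attribute set.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_edgelist(edge_list(net), directed = FALSE) +
    igraph::vertices(setdiff(net$nodes, net$nodes[unique(c(net$edges))]))
}
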