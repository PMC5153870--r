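#' Construct a partial network alignment
#'
#' An alignment is an injective partial mapping from proteins of network 1 to
#' proteins of network 2. Each matched couple records its provenance: `"seed"`
#' for couples matched on sequence similarity in stage one, `"percolated"` for
#' couples matched on topology in stage two (these also record the
#' common-neighbour score they had when matched).
#'
#' @param protein1,protein2 character vectors: the matched couples, in match
#'   order.
#' @param origin character vector, `"seed"` or `"percolated"`.
#' @param match_score integer common-neighbour score at match time
#'   (`NA` for seed couples).
#' @return A data frame of class `ppi_alignment` with columns `protein1`,
#'   `protein2`, `origin`, `match_score`.
#' @export
make_alignment <- function(protein1 = character(), protein2 = character(),
                           origin = "seed", match_score = NA_integer_) {
  n <- length(protein1)
  if (length(protein2) != n)
    stop("protein1 and protein2 must have equal length")
  origin <- rep_len(as.character(origin), n)
  match_score <- rep_len(as.integer(match_score), n)
  if (n && !all(origin %in% c("seed", "percolated")))
    stop("origin must be \"seed\" or \"percolated\"")
  if (anyDuplicated(protein1))
    stop("alignment is not injective: duplicated network-1 protein(s): ",
         paste(unique(protein1[duplicated(protein1)]), collapse = ", "))
  if (anyDuplicated(protein2))
    stop("alignment is not injective: duplicated network-2 protein(s): ",
         paste(unique(protein2[duplicated(protein2)]), collapse = ", "))
  structure(
    data.frame(protein1 = as.character(protein1),
               protein2 = as.character(protein2),
               origin = origin, match_score = match_score,
               stringsAsFactors = FALSE),
    class = c("ppi_alignment", "data.frame"))
}

# accept a ppi_alignment, a fitted proper object, or a bare two-column thing
as_alignment <- function(x) {
  if (inherits(x, "proper")) return(x$alignment)
  if (inherits(x, "ppi_alignment")) return(x)
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("protein1", "protein2") %in% names(x)) && ncol(x) >= 2L)
    names(x)[1:2] <- c("protein1", "protein2")
  make_alignment(x$protein1, x$protein2,
                 origin = if ("origin" %in% names(x)) x$origin else "seed",
                 match_score = if ("match_score" %in% names(x))
                   x$match_score else NA_integer_)
}

#' @export
print.ppi_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d couples (%d seed, %d percolated)\n",
              nrow(x), sum(x$origin == "seed"),
              sum(x$origin == "percolated")))
  if (nrow(x)) print.data.frame(utils::head(x, 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# alignment as a named lookup vector: names are network-1 proteins
alignment_map <- function(aln) {
  aln <- as_alignment(aln)
  stats::setNames(aln$protein2, aln$protein1)
}
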