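#' GO annotation set
#'
#' Maps proteins to their GO terms, each carrying an evidence code. Proteins
#' not listed simply have an empty term set.
#'
#' @param protein,term,evidence character vectors of equal length: one
#'   annotation triple per element.
#' @return An object of class `annotation_set` wrapping a data frame
#'   `protein`, `term`, `evidence` (duplicate triples collapsed).
#' @export
annotation_set <- function(protein = character(), term = character(),
                           evidence = character()) {
  protein <- as.character(protein)
  term <- as.character(term)
  evidence <- toupper(as.character(evidence))
  n <- length(protein)
  if (length(term) != n || length(evidence) != n)
    stop("protein, term and evidence must have equal length")
  df <- unique(data.frame(protein = protein, term = term,
                          evidence = evidence, stringsAsFactors = FALSE))
  structure(list(terms = df), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("Annotation set: %d terms over %d proteins\n",
              nrow(x$terms), length(unique(x$terms$protein))))
  invisible(x)
}

#' GO terms of a protein
#'
#' @param ann an [annotation_set()].
#' @param protein a single protein id.
#' @param evidence_filter optional character vector; keep only terms whose
#'   evidence code is in this set.
#' @return Character vector of GO term ids (possibly empty).
#' @export
go_terms <- function(ann, protein, evidence_filter = NULL) {
  df <- ann$terms
  keep <- df$protein == protein
  if (!is.null(evidence_filter))
    keep <- keep & df$evidence %in% toupper(evidence_filter)
  unique(df$term[keep])
}

#' Evidence codes of experimentally verified GO annotations
#'
#' The standard experimental evidence codes; passing this as
#' `evidence_filter` restricts GO-consistency scoring to experimentally
#' verified terms, excluding annotations inferred computationally (which are
#' often themselves derived from sequence similarity and would inflate the
#' score).
#' @export
experimental_evidence_codes <- c("EXP", "IDA", "IMP", "IGI", "IEP", "IPI")
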