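#' Pairwise sequence-similarity table
#'
#' Holds BLAST bit-scores for couples (protein in network 1, protein in
#' network 2) plus optional self-scores (a protein against itself), used by
#' seed generation and by the average normalized bit-score (ANBS) measure.
#' Duplicate entries for the same ordered couple are collapsed keeping the
#' maximum score.
#'
#' @param protein1,protein2 character vectors of equal length: couple members.
#' @param score numeric vector of non-negative bit-scores.
#' @param self_scores optional named numeric vector of self bit-scores.
#' @return An object of class `similarity_table` with elements `cross`
#'   (data frame `protein1`, `protein2`, `score`) and `self_scores`.
#' @export
similarity_table <- function(protein1 = character(), protein2 = character(),
                             score = numeric(), self_scores = NULL) {
  protein1 <- as.character(protein1)
  protein2 <- as.character(protein2)
  score <- as.numeric(score)
  if (length(protein1) != length(protein2) || length(protein1) != length(score))
    stop("protein1, protein2 and score must have equal length")
  if (anyNA(score) || any(score < 0))
    stop("bit-scores must be non-negative numbers")
  if (any(!nzchar(c(protein1, protein2))))
    stop("protein identifiers must be non-empty strings")
  if (!is.null(self_scores)) {
    self_scores <- unlist(tapply(as.numeric(self_scores),
                                 names(self_scores), max, simplify = FALSE))
    if (anyNA(self_scores) || any(self_scores < 0))
      stop("self bit-scores must be non-negative numbers")
  } else {
    self_scores <- numeric()
  }
  if (length(protein1)) {
    o <- order(protein1, protein2, -score)
    dup <- duplicated(paste(protein1[o], protein2[o], sep = "\r"))
    keep <- o[!dup]
    cross <- data.frame(protein1 = protein1[keep], protein2 = protein2[keep],
                        score = score[keep], stringsAsFactors = FALSE)
  } else {
    cross <- data.frame(protein1 = character(), protein2 = character(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(cross = cross, self_scores = self_scores),
            class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("Similarity table: %d cross-scores, %d self-scores\n",
              nrow(x$cross), length(x$self_scores)))
  invisible(x)
}

#' Look up cross bit-scores
#' @param sim a `similarity_table`.
#' @param protein1,protein2 couple members (recycled to equal length).
#' @return Numeric vector of scores, `NA` where no score is recorded.
#' @export
cross_score <- function(sim, protein1, protein2) {
  key <- paste(protein1, protein2, sep = "\r")
  tab <- paste(sim$cross$protein1, sim$cross$protein2, sep = "\r")
  sim$cross$score[match(key, tab)]
}
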