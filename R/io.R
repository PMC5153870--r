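#' Read a PPI network from a tab-separated edge list
#'
#' Two id columns per line; lines starting with `#` are comments. A line with
#' a single id declares an isolated node. Self-loops and duplicate edges are
#' dropped with a warning, as in [ppi_network()].
#'
#' @param path file path.
#' @return A `ppi_network`.
#' @export
read_edge_list <- function(path) {
  fields <- read_tsv_fields(path, n_fields = c(1L, 2L), comment = "#")
  if (!length(fields)) return(ppi_network())
  iso <- lengths(fields) == 1L
  edges <- fields[!iso]
  ppi_network(if (length(edges)) do.call(rbind, edges) else NULL,
              nodes = unlist(fields[iso]))
}

#' Read a similarity table (3-column TSV or 12-column BLAST tabular)
#'
#' Accepts either `query<TAB>subject<TAB>bitscore` or the 12-column BLAST
#' tabular format (outfmt 6), from which columns 1, 2 and 12 are used. Rows
#' with `query == subject` populate the self-scores; duplicate couples keep
#' the maximum score.
#'
#' @param path file path.
#' @return A [similarity_table()].
#' @export
read_similarities <- function(path) {
  fields <- read_tsv_fields(path, n_fields = c(3L, 12L), comment = "#")
  if (!length(fields))
    return(similarity_table())
  q <- vapply(fields, `[[`, character(1), 1L)
  s <- vapply(fields, `[[`, character(1), 2L)
  sc <- suppressWarnings(as.numeric(
    vapply(fields, function(f) f[[length(f)]], character(1))))
  if (anyNA(sc)) {
    bad <- attr(fields, "line_numbers")[which(is.na(sc))[1L]]
    stop(sprintf("%s: non-numeric bit-score on line %d", path, bad))
  }
  self <- q == s
  self_scores <- NULL
  if (any(self))
    self_scores <- stats::setNames(sc[self], q[self])
  similarity_table(q[!self], s[!self], sc[!self], self_scores = self_scores)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Skips `!` comment lines; uses the object id (column 2), GO id (column 5)
#' and evidence code (column 7). Annotations whose qualifier (column 4)
#' carries a `NOT` negation are dropped, with a message giving the count.
#'
#' @param path file path.
#' @return An [annotation_set()].
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) return(annotation_set())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 7L
  if (any(short))
    stop(sprintf("%s: line with fewer than 7 columns (line %d)",
                 path, which(short)[1L]))
  qual <- vapply(fields, `[[`, character(1), 4L)
  negated <- grepl("(^|\\|)NOT($|\\|)", qual)
  if (any(negated))
    message(sprintf("dropped %d NOT-qualified annotation(s)", sum(negated)))
  fields <- fields[!negated]
  annotation_set(protein = vapply(fields, `[[`, character(1), 2L),
                 term = vapply(fields, `[[`, character(1), 5L),
                 evidence = vapply(fields, `[[`, character(1), 7L))
}

#' Read a pathway membership table
#'
#' Format: `pathway_id<TAB>species_index(1|2)<TAB>protein_id`, `#` comments
#' allowed. Pathways present in only one species are dropped (message).
#'
#' @param path file path.
#' @return A [pathway_table()].
#' @export
read_pathways <- function(path) {
  fields <- read_tsv_fields(path, n_fields = 3L, comment = "#")
  if (!length(fields)) return(pathway_table())
  sp <- vapply(fields, `[[`, character(1), 2L)
  if (!all(sp %in% c("1", "2"))) {
    bad <- attr(fields, "line_numbers")[which(!sp %in% c("1", "2"))[1L]]
    stop(sprintf("%s: species index must be 1 or 2 (line %d)", path, bad))
  }
  pathway_table(pathway = vapply(fields, `[[`, character(1), 1L),
                species = as.integer(sp),
                protein = vapply(fields, `[[`, character(1), 3L))
}

#' Read a ground-truth node mapping
#'
#' Two tab-separated id columns; a duplicated source id is an error.
#'
#' @param path file path.
#' @return Named character vector (network-1 id -> network-2 id).
#' @export
read_truth <- function(path) {
  fields <- read_tsv_fields(path, n_fields = 2L, comment = "#")
  p1 <- vapply(fields, `[[`, character(1), 1L)
  p2 <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(p1))
    stop(sprintf("%s: duplicated source id \"%s\"", path,
                 p1[duplicated(p1)][1L]))
  stats::setNames(p2, p1)
}

#' Write / read an alignment file
#'
#' Tab-separated columns `protein1 protein2 origin match_score`, preceded by
#' `#`-prefixed metadata lines recording the aligner parameters. The
#' write/read pair round-trips couples, origins and scores.
#'
#' @param aln an alignment or fitted `proper` object.
#' @param path file path.
#' @param params optional named list recorded in the header (for a `proper`
#'   fit, `ell`, `r` and `seed` are recorded automatically).
#' @return `write_alignment` returns `path` invisibly; `read_alignment`
#'   returns a `ppi_alignment`.
#' @export
write_alignment <- function(aln, path, params = NULL) {
  if (inherits(aln, "proper") && is.null(params))
    params <- list(ell = aln$ell, r = aln$r,
                   seed = if (is.null(aln$seed)) "NA" else aln$seed)
  aln <- as_alignment(aln)
  hdr <- c(
    sprintf("# properalign alignment, %d couples", nrow(aln)),
    if (length(params))
      sprintf("# %s = %s", names(params), vapply(params, format, character(1))),
    "# protein1\tprotein2\torigin\tmatch_score")
  body <- sprintf("%s\t%s\t%s\t%s", aln$protein1, aln$protein2, aln$origin,
                  ifelse(is.na(aln$match_score), "NA", aln$match_score))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  fields <- read_tsv_fields(path, n_fields = 4L, comment = "#")
  if (!length(fields)) return(make_alignment())
  make_alignment(
    vapply(fields, `[[`, character(1), 1L),
    vapply(fields, `[[`, character(1), 2L),
    origin = vapply(fields, `[[`, character(1), 3L),
    match_score = suppressWarnings(
      as.integer(vapply(fields, `[[`, character(1), 4L))))
}

#' Write a measure or pathway report
#'
#' Flat key-value TSV (one `key<TAB>value` line per defined field); a
#' `pathway_report` additionally writes its per-pathway table above the
#' aggregate footer.
#'
#' @param report a `measure_report` or `pathway_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (inherits(report, "pathway_report")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# per-pathway", con)
    utils::write.table(report$per_pathway, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines("# aggregate", con)
    agg <- report[c("delta", "n_eligible", "n_success", "recall", "mean_acc",
                    "mean_acc_success")]
    writeLines(sprintf("%s\t%s", names(agg),
                       vapply(agg, format, character(1))), con)
  } else {
    keys <- setdiff(names(report), "swapped")
    vals <- vapply(report[keys], function(v)
      if (is.na(v)) "NA" else format(v, digits = 10), character(1))
    writeLines(c(sprintf("# orientation_swapped\t%s", report$swapped),
                 sprintf("%s\t%s", keys, vals)), path)
  }
  invisible(path)
}

#' Write networks, similarity tables and truth mappings
#'
#' Counterparts of the readers, producing the same tab-separated formats
#' (self-scores are written as `id<TAB>id<TAB>score` rows).
#'
#' @param net a `ppi_network`.
#' @param sim a [similarity_table()].
#' @param truth named character vector (network-1 id -> network-2 id).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- edge_list(net)
  iso <- setdiff(net$nodes, unique(c(e)))
  writeLines(c(sprintf("%s\t%s", e[, 1L], e[, 2L]), iso), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_similarities <- function(sim, path) {
  lines <- c(
    sprintf("%s\t%s\t%s", sim$cross$protein1, sim$cross$protein2,
            format(sim$cross$score, trim = TRUE, scientific = FALSE)),
    if (length(sim$self_scores))
      sprintf("%s\t%s\t%s", names(sim$self_scores), names(sim$self_scores),
              format(unname(sim$self_scores), trim = TRUE,
                     scientific = FALSE)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_truth <- function(truth, path) {
  writeLines(sprintf("%s\t%s", names(truth), unname(truth)), path)
  invisible(path)
}

# shared TSV reader: returns list of field vectors with line numbers,
# errors (with the 1-based line number) on a row with the wrong field count
read_tsv_fields <- function(path, n_fields, comment = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, comment)
  nums <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- !(lengths(fields) %in% n_fields)
  if (any(bad))
    stop(sprintf("%s: expected %s tab-separated field(s) on line %d, got %d",
                 path, paste(n_fields, collapse = " or "),
                 nums[which(bad)[1L]], lengths(fields)[which(bad)[1L]]))
  structure(fields, line_numbers = nums)
}
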