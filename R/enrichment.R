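#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in a selected id list
#' against a universe: the p-value is the upper tail of the hypergeometric
#' distribution, P(overlap >= observed) when drawing `n_selected` ids from
#' the universe, with BH adjustment across terms. Gene sets are intersected
#' with the universe before testing, so ids outside the universe never
#' influence a term's size.
#'
#' @param selected character vector of selected ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all testable ids.
#' @param gene_sets named list mapping term id -> character vector of ids.
#' @param descriptions optional named character vector of term descriptions.
#' @return data.frame of class `term_table`: term_id, term_name,
#'   n_universe, n_term, n_selected, n_overlap, p, p_adjust, ordered by p.
#' @export
hypergeometric_ora <- function(selected, universe, gene_sets,
                               descriptions = NULL) {
  universe <- unique(universe)
  selected <- unique(selected)
  if (length(universe) == 0L) abort_input("empty universe")
  if (length(selected) == 0L) abort_input("empty selection")
  outside <- setdiff(selected, universe)
  if (length(outside) > 0L)
    abort_input("selected id(s) outside the universe: %s",
                paste(utils::head(outside, 5L), collapse = ", "))
  if (is.null(names(gene_sets)) || length(gene_sets) == 0L)
    abort_input("gene_sets must be a non-empty named list")
  N <- length(universe)
  n_sel <- length(selected)
  rows <- lapply(names(gene_sets), function(term) {
    term_ids <- intersect(unique(gene_sets[[term]]), universe)
    K <- length(term_ids)
    k <- length(intersect(term_ids, selected))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n_sel, lower.tail = FALSE)
    data.frame(term_id = term,
               term_name = if (!is.null(descriptions) &&
                               term %in% names(descriptions))
                 unname(descriptions[term]) else term,
               n_universe = N, n_term = K, n_selected = n_sel,
               n_overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_table", "data.frame")
  out
}

#' Read / write gene sets in GMT format
#'
#' GMT is tab-separated: term id, description, then one id per remaining
#' field.
#'
#' @param file path to a GMT file.
#' @return `read_gmt`: list with `gene_sets` (named list) and
#'   `descriptions` (named character).
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    abort_input("GMT line %d has fewer than 3 fields", short[1L])
  terms <- vapply(fields, `[`, character(1L), 1L)
  list(
    gene_sets = stats::setNames(lapply(fields, function(f) f[-(1:2)]), terms),
    descriptions = stats::setNames(
      vapply(fields, `[`, character(1L), 2L), terms)
  )
}

#' @rdname read_gmt
#' @param gene_sets named list of id vectors.
#' @param descriptions optional named descriptions (defaults to term ids).
#' @return `write_gmt`: invisibly, the file path.
#' @export
write_gmt <- function(gene_sets, file, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(term) {
    desc <- if (!is.null(descriptions) && term %in% names(descriptions))
      descriptions[[term]] else term
    paste(c(term, desc, gene_sets[[term]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, file)
  invisible(file)
}
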