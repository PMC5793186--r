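#' Expression matrix with a stage/replicate design
#'
#' Container pairing a transcripts-by-samples FPKM matrix with the sample
#' design (stage and replicate per sample column). All values must be finite
#' and non-negative; every stage must have at least one replicate.
#'
#' @param values numeric matrix, rows = transcripts (rownames required),
#'   columns = samples (colnames required), FPKM units.
#' @param design data.frame with columns `sample`, `stage`, `replicate`;
#'   `sample` must match the matrix column names exactly (any order).
#' @return an object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, design) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    abort_input("expression matrix needs row (transcript) and column (sample) names")
  if (!all(is.finite(values)) || any(values < 0))
    abort_input("FPKM values must be finite and >= 0")
  req <- c("sample", "stage", "replicate")
  if (!all(req %in% names(design)))
    abort_input("design needs columns: %s", paste(req, collapse = ", "))
  design <- as.data.frame(design)[, req]
  design$sample <- as.character(design$sample)
  design$stage <- as.character(design$stage)
  if (!setequal(design$sample, colnames(values)) ||
      anyDuplicated(design$sample))
    abort_input("design samples must match matrix columns one-to-one")
  design <- design[match(colnames(values), design$sample), , drop = FALSE]
  rownames(design) <- NULL
  obj <- list(values = values, design = design)
  class(obj) <- "expression_matrix"
  obj
}

#' @export
print.expression_matrix <- function(x, ...) {
  st <- table(x$design$stage)
  cat(sprintf("expression_matrix: %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Stages of an expression design, in their sampling order
#' @param expr an `expression_matrix`.
#' @return character vector of unique stages (first-appearance order).
#' @export
stages <- function(expr) unique(expr$design$stage)

#' Sample columns belonging to one stage
#' @param expr an `expression_matrix`.
#' @param stage stage label.
#' @return character vector of sample names.
#' @export
stage_samples <- function(expr, stage) {
  s <- expr$design$sample[expr$design$stage == stage]
  if (length(s) == 0L) abort_input("no samples for stage '%s'", stage)
  s
}

#' Per-stage mean expression profiles
#'
#' @param expr an `expression_matrix`.
#' @param features optional row subset.
#' @return numeric matrix, features x stages, of replicate-mean FPKM.
#' @export
stage_mean_profiles <- function(expr, features = NULL) {
  v <- expr$values
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(v))
    if (length(missing) > 0L)
      abort_input("feature(s) absent from expression matrix: %s",
                  paste(utils::head(missing, 5L), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  st <- stages(expr)
  out <- vapply(st, function(s) {
    rowMeans(v[, stage_samples(expr, s), drop = FALSE])
  }, numeric(nrow(v)))
  if (nrow(v) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(rownames(v), st))
  out
}

#' FPKM from fragment counts
#'
#' FPKM = count * 1e9 / (transcript length in bp * library size in
#' fragments): fragments per kilobase of exon per million mapped fragments.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths per-transcript mature length in bp (named or in row order).
#' @param library_sizes per-sample total mapped fragments (named or in
#'   column order).
#' @param design sample design passed through to [expression_matrix()].
#' @return an `expression_matrix` of FPKM values.
#' @export
fpkm_from_counts <- function(counts, lengths, library_sizes, design) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (!is.null(names(library_sizes)))
    library_sizes <- library_sizes[colnames(counts)]
  if (length(lengths) != nrow(counts))
    abort_input("need one length per transcript row")
  if (length(library_sizes) != ncol(counts))
    abort_input("need one library size per sample column")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    abort_input("transcript lengths must be positive")
  if (any(!is.finite(library_sizes)) || any(library_sizes <= 0))
    abort_input("library sizes must be positive")
  fpkm <- sweep(sweep(counts * 1e9, 1L, lengths, "/"), 2L, library_sizes, "/")
  expression_matrix(fpkm, design)
}

#' Write / read an expression matrix as TSV plus a design sidecar
#'
#' The matrix file is tab-separated with a `transcript_id` column followed by
#' one column per sample; the design file has columns sample, stage,
#' replicate.
#'
#' @param expr an `expression_matrix`.
#' @param matrix_file,design_file output paths.
#' @return `write_expression`: invisibly, the two paths.
#' @export
write_expression <- function(expr, matrix_file, design_file) {
  tab <- data.frame(transcript_id = rownames(expr$values),
                    expr$values, check.names = FALSE)
  utils::write.table(tab, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(expr$design, design_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_file, design_file))
}

#' @rdname write_expression
#' @return `read_expression`: an `expression_matrix`.
#' @export
read_expression <- function(matrix_file, design_file) {
  tab <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  design <- utils::read.delim(design_file, stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(v) <- tab[[1L]]
  expression_matrix(v, design)
}
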