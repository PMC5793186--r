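#' Cis-target genes within a genomic window of lncRNAs
#'
#' Pairs each lncRNA with every protein-coding gene whose genomic span lies
#' within `window_bp` of the lncRNA's span (closest-end distance, inclusive,
#' same chromosome, either strand). Overlapping or abutting spans count as
#' distance 0. Distance is measured between spans — not TSS to TSS — so the
#' pairing is symmetric in the two loci. The relative position is reported
#' with respect to the coding gene's reading direction: a lncRNA 5' of the
#' gene is `upstream`.
#'
#' @param lnc [transcript_set()] of lncRNAs (one locus per transcript).
#' @param coding [transcript_set()] of protein-coding transcripts; spans are
#'   collapsed per gene_id.
#' @param window_bp window size in bp (default 10000).
#' @return data.frame with columns `lnc_id`, `gene_id`, `distance` (bp,
#'   0 when overlapping), `position` (`upstream`/`downstream`/`overlapping`
#'   of the coding gene).
#' @export
predict_cis_targets <- function(lnc, coding, window_bp = 10000) {
  if (!is.numeric(window_bp) || window_bp <= 0)
    abort_input("window_bp must be > 0")
  h <- .common_seqlevels(spans_granges(lnc), spans_granges(coding, by = "gene"))
  gl <- h[[1L]]; gg <- h[[2L]]
  # maxgap = window: ranges separated by a gap of <= window_bp pair up
  hits <- GenomicRanges::findOverlaps(gl, gg, maxgap = window_bp,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(lnc_id = character(), gene_id = character(),
                      distance = numeric(), position = character(),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(gl[qh], gg[sh], ignore.strand = TRUE)
  ls <- GenomicRanges::start(gl)[qh]; le <- GenomicRanges::end(gl)[qh]
  gs <- GenomicRanges::start(gg)[sh]; ge <- GenomicRanges::end(gg)[sh]
  gstr <- as.character(GenomicRanges::strand(gg))[sh]
  lnc_before <- le < gs   # lnc entirely left of the gene
  lnc_after <- ls > ge
  position <- ifelse(d == 0 & !(lnc_before | lnc_after), "overlapping",
              ifelse(xor(lnc_before, gstr == "-"), "upstream", "downstream"))
  out <- data.frame(lnc_id = gl$transcript_id[qh], gene_id = gg$gene_id[sh],
                    distance = as.numeric(d), position = position,
                    stringsAsFactors = FALSE)
  out <- out[out$distance <= window_bp, , drop = FALSE]   # inclusive bound
  out <- out[order(out$lnc_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson correlation with the classical two-sided test
#' t = r * sqrt(n - 2) / sqrt(1 - r^2) against t with n - 2 degrees of
#' freedom. A numerically perfect |r| = 1 yields the underflow limit (the
#' smallest representable double) rather than an error, so thresholding on
#' p never drops perfect correlations.
#'
#' @param x,y numeric vectors of equal length >= 3, each non-constant.
#' @return list with elements `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort_input("x and y must have equal length")
  if (n < 3L) abort_input("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_input("correlation undefined for a constant vector")
  r <- stats::cor(x, y)
  denom <- 1 - r^2
  p <- if (denom <= .Machine$double.eps) {
    .Machine$double.xmin
  } else {
    max(2 * stats::pt(-abs(r * sqrt(n - 2) / sqrt(denom)), df = n - 2),
        .Machine$double.xmin)
  }
  list(r = r, p = p)
}

#' Trans-target co-expression network
#'
#' Tests every lncRNA x gene pair by Pearson correlation across the shared
#' sample columns and keeps edges with |r| strictly above `r_threshold` and
#' p strictly below `p_threshold` (raw p; the co-expression screen uses no
#' multiple-testing correction by default, an optional BH mode is provided).
#' Constant (zero-variance) rows cannot be correlated; they are skipped and
#' counted.
#'
#' @param lnc_expr numeric matrix of lncRNA expression, rows = lncRNAs,
#'   named columns = samples (or an [expression_matrix()]).
#' @param gene_expr matching matrix for protein-coding genes; identical
#'   sample columns required.
#' @param r_threshold absolute-correlation threshold in (0,1)
#'   (default 0.95).
#' @param p_threshold p-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` the p filter is
#'   applied to BH-adjusted p-values across all tested pairs.
#' @return object of class `trans_network`: list with `edges` (lnc_id,
#'   gene_id, r, p, sign), `counts` (n_edges, n_positive, n_negative, n_lnc,
#'   n_gene), and `skipped_constant` (per input matrix).
#' @export
predict_trans_targets <- function(lnc_expr, gene_expr, r_threshold = 0.95,
                                  p_threshold = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(lnc_expr, "expression_matrix")) lnc_expr <- lnc_expr$values
  if (inherits(gene_expr, "expression_matrix")) gene_expr <- gene_expr$values
  if (!identical(colnames(lnc_expr), colnames(gene_expr)))
    abort_input("lnc and gene matrices must share identical sample columns")
  if (!(r_threshold > 0 && r_threshold < 1))
    abort_input("r_threshold must be in (0,1)")
  n <- ncol(lnc_expr)
  if (n < 3L) abort_input("need at least 3 samples")

  lnc_sd <- apply(lnc_expr, 1L, stats::sd)
  gene_sd <- apply(gene_expr, 1L, stats::sd)
  skipped <- c(lnc = sum(lnc_sd == 0), gene = sum(gene_sd == 0))
  lm_ <- lnc_expr[lnc_sd > 0, , drop = FALSE]
  gm_ <- gene_expr[gene_sd > 0, , drop = FALSE]

  edges <- data.frame(lnc_id = character(), gene_id = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (nrow(lm_) > 0L && nrow(gm_) > 0L) {
    rmat <- stats::cor(t(lm_), t(gm_))
    rmat <- pmin(pmax(rmat, -1), 1)
    denom <- pmax(1 - rmat^2, .Machine$double.eps)
    tmat <- abs(rmat) * sqrt(n - 2) / sqrt(denom)
    pmat <- 2 * stats::pt(-tmat, df = n - 2)
    pmat[1 - rmat^2 <= .Machine$double.eps] <- .Machine$double.xmin
    pmat <- pmax(pmat, .Machine$double.xmin)
    pflt <- if (adjust == "BH") {
      matrix(bh_adjust(as.vector(pmat)), nrow = nrow(pmat))
    } else {
      pmat
    }
    keep <- which(abs(rmat) > r_threshold & pflt < p_threshold,
                  arr.ind = TRUE)
    if (nrow(keep) > 0L) {
      edges <- data.frame(
        lnc_id = rownames(lm_)[keep[, 1L]],
        gene_id = rownames(gm_)[keep[, 2L]],
        r = rmat[keep], p = pmat[keep],
        sign = ifelse(rmat[keep] > 0, "positive", "negative"),
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$lnc_id, edges$gene_id), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  counts <- c(n_edges = nrow(edges),
              n_positive = sum(edges$sign == "positive"),
              n_negative = sum(edges$sign == "negative"),
              n_lnc = length(unique(edges$lnc_id)),
              n_gene = length(unique(edges$gene_id)))
  structure(list(edges = edges, counts = counts,
                 skipped_constant = skipped,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "trans_network")
}

#' @export
print.trans_network <- function(x, ...) {
  cat(sprintf(
    "trans_network: %d edges (%d positive, %d negative) between %d lncRNAs and %d genes\n",
    x$counts["n_edges"], x$counts["n_positive"], x$counts["n_negative"],
    x$counts["n_lnc"], x$counts["n_gene"]))
  if (sum(x$skipped_constant) > 0)
    cat(sprintf("  skipped constant rows: %d lncRNA, %d gene\n",
                x$skipped_constant["lnc"], x$skipped_constant["gene"]))
  invisible(x)
}
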