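#' Relative expression by the 2^-ddCt method
#'
#' Completes a qPCR cycle-threshold table: per sample,
#' dCt = Ct(target) - mean Ct(reference genes); ddCt = dCt(sample) -
#' dCt(calibrator); relative expression = 2^-ddCt. Multiple reference genes
#' are combined by arithmetic-mean Ct. The calibrator sample's relative
#' expression is 1 by construction, and the result is invariant to adding a
#' constant to every Ct.
#'
#' @param ct_table data.frame with columns `sample`, `gene`, `ct`, `role`
#'   (`"target"` or `"reference"`). One row per (sample, gene); replicate
#'   wells should be averaged beforehand.
#' @param calibrator sample id used as the ddCt baseline.
#' @return data.frame: sample, target_gene, dct, ddct, rel_expr.
#' @export
ddct_relative_expression <- function(ct_table, calibrator) {
  req <- c("sample", "gene", "ct", "role")
  if (!all(req %in% names(ct_table)))
    abort_input("ct_table needs columns: %s", paste(req, collapse = ", "))
  if (!all(ct_table$role %in% c("target", "reference")))
    abort_input("role must be 'target' or 'reference'")
  if (!calibrator %in% ct_table$sample)
    abort_input("calibrator sample '%s' not in table", calibrator)
  samples <- unique(ct_table$sample)
  targets <- unique(ct_table$gene[ct_table$role == "target"])
  if (length(targets) == 0L) abort_input("no target genes in table")

  ref_mean <- vapply(samples, function(s) {
    ct <- ct_table$ct[ct_table$sample == s & ct_table$role == "reference"]
    if (length(ct) == 0L || anyNA(ct))
      abort_input("sample '%s' lacks reference-gene Ct values", s)
    mean(ct)
  }, numeric(1L))

  rows <- lapply(targets, function(g) {
    ct <- vapply(samples, function(s) {
      v <- ct_table$ct[ct_table$sample == s & ct_table$gene == g &
                         ct_table$role == "target"]
      if (length(v) != 1L || is.na(v))
        abort_input("sample '%s' lacks a Ct for target '%s'", s, g)
      v
    }, numeric(1L))
    dct <- ct - ref_mean
    ddct <- dct - dct[samples == calibrator]
    data.frame(sample = samples, target_gene = g, dct = dct, ddct = ddct,
               rel_expr = 2^(-ddct), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Spearman agreement between qPCR and RNA-seq profiles
#'
#' Rank correlation (average ranks for ties) between matched per-stage
#' relative-expression and FPKM vectors.
#'
#' @param qpcr numeric vector of per-stage qPCR relative expression.
#' @param rnaseq matched numeric vector of per-stage FPKM.
#' @return Spearman's rho.
#' @export
spearman_agreement <- function(qpcr, rnaseq) {
  if (length(qpcr) != length(rnaseq))
    abort_input("vectors must have equal length")
  if (length(qpcr) < 3L) abort_input("need at least 3 stages")
  stats::cor(qpcr, rnaseq, method = "spearman")
}
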