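#' Run the full lncRNA dissection pipeline
#'
#' Convenience wrapper chaining every stage on in-memory inputs: filter
#' cascade, lincRNA/antisense classification, novelty against the known
#' reference, cis- and trans-target prediction, the four stage-wise DE
#' comparisons with Venn intersections, K-means archetype clustering of the
#' DEG stage profiles, and over-representation of each archetype cluster.
#'
#' @param merged candidate [transcript_set()].
#' @param reference biotyped reference [transcript_set()].
#' @param known known-lncRNA [transcript_set()].
#' @param expr [expression_matrix()] over all candidates.
#' @param scores coding-potential score table.
#' @param gene_sets optional named list of gene sets for ORA (NULL skips).
#' @param thresholds a [filter_thresholds()].
#' @param comparisons list of `c(stage_b, stage_a)` pairs; default the four
#'   canonical transitions A1/A0, A3/A1, A5/A3, A5/A0.
#' @param r_threshold,p_threshold trans-network retention thresholds.
#' @param k number of temporal clusters (default 4).
#' @param seed RNG seed for clustering restarts.
#' @return list of class `lnc_pipeline`: `records`, `lnc_ids`, `cis`,
#'   `trans`, `de` (per-comparison tables), `de_sets`, `venn` (lncRNA and
#'   mRNA region counts), `clusters`, `ora` (per cluster, when gene sets
#'   are given).
#' @export
run_lnc_pipeline <- function(merged, reference, known, expr, scores,
                             gene_sets = NULL,
                             thresholds = filter_thresholds(),
                             comparisons = list(c("A1", "A0"), c("A3", "A1"),
                                                c("A5", "A3"), c("A5", "A0")),
                             r_threshold = 0.95, p_threshold = 0.05,
                             k = 4, seed = 17) {
  records <- apply_filter_cascade(merged, expr, scores, reference, thresholds)
  records <- classify_lncrna(records, merged, reference)
  records <- match_known(records, merged, known)
  lnc_ids <- records$transcript_id[records$final_call]

  ref_coding <- subset_transcripts(reference, biotype = "protein_coding")
  lnc_ts <- if (length(lnc_ids) > 0L) subset_transcripts(merged, ids = lnc_ids)
  cis <- if (length(lnc_ids) > 0L) {
    predict_cis_targets(lnc_ts, ref_coding, thresholds$cis_window_bp)
  }

  # mRNA candidates: same-strand exonic match with a reference coding locus
  coding_pairs <- .exonic_overlap_pairs(merged, ref_coding)
  mrna_ids <- setdiff(unique(coding_pairs$a[coding_pairs$same_strand]), lnc_ids)
  trans <- if (length(lnc_ids) > 0L && length(mrna_ids) > 0L) {
    predict_trans_targets(expr$values[lnc_ids, , drop = FALSE],
                          expr$values[mrna_ids, , drop = FALSE],
                          r_threshold, p_threshold)
  }

  de <- lapply(comparisons, function(cmp) differential_test(expr, cmp))
  names(de) <- vapply(comparisons, function(cmp)
    paste(cmp[1L], "vs", cmp[2L]), character(1L))
  de_sets <- call_de_sets(de)
  sets_all <- lapply(de_sets, `[[`, "de")
  venn <- list(
    lncRNA = venn_intersections(lapply(sets_all, intersect, lnc_ids)),
    mRNA = venn_intersections(lapply(sets_all, intersect, mrna_ids)))

  deg_ids <- unique(unlist(sets_all))
  clusters <- NULL
  if (length(deg_ids) >= k) {
    profiles <- stage_mean_profiles(expr, deg_ids)
    clusters <- kmeans_cluster(profiles, k = k, seed = seed)
  }

  ora <- NULL
  if (!is.null(gene_sets) && !is.null(clusters)) {
    universe <- mrna_ids
    ora <- lapply(split(clusters$assignments$feature_id,
                        clusters$assignments$cluster), function(ids) {
      sel <- intersect(ids, universe)
      if (length(sel) == 0L) return(NULL)
      hypergeometric_ora(sel, universe, gene_sets)
    })
  }

  structure(list(records = records, lnc_ids = lnc_ids, mrna_ids = mrna_ids,
                 cis = cis, trans = trans, de = de, de_sets = de_sets,
                 venn = venn, clusters = clusters, ora = ora),
            class = "lnc_pipeline")
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  cat("lncRNA dissection pipeline\n")
  cat(sprintf("  candidates: %d; called lncRNAs: %d (%d lincRNA, %d antisense; %d annotated, %d novel)\n",
              nrow(x$records), length(x$lnc_ids),
              sum(x$records$class == "lincRNA", na.rm = TRUE),
              sum(x$records$class == "antisense", na.rm = TRUE),
              sum(x$records$novelty == "annotated", na.rm = TRUE),
              sum(x$records$novelty == "novel", na.rm = TRUE)))
  if (!is.null(x$cis))
    cat(sprintf("  cis pairs (<=10 kb): %d involving %d lncRNAs\n",
                nrow(x$cis), length(unique(x$cis$lnc_id))))
  if (!is.null(x$trans))
    cat(sprintf("  trans edges: %d (%d positive, %d negative)\n",
                x$trans$counts["n_edges"], x$trans$counts["n_positive"],
                x$trans$counts["n_negative"]))
  for (nm in names(x$de))
    cat(sprintf("  DE %s: %d up, %d down\n", nm,
                length(x$de_sets[[nm]]$up), length(x$de_sets[[nm]]$down)))
  if (!is.null(x$clusters))
    cat(sprintf("  clusters: %s\n",
                paste(sprintf("%s=%d",
                              if (!is.null(x$clusters$labels))
                                x$clusters$labels else
                                  rownames(x$clusters$centroids),
                              x$clusters$sizes), collapse = ", ")))
  invisible(x)
}
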