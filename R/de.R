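#' Stage-wise differential expression test
#'
#' Compares two stages of an [expression_matrix()] feature by feature.
#' The fold change is computed on stage-mean FPKM with a pseudocount:
#' log2FC = log2(mean_b + eps) - log2(mean_a + eps), which keeps fold
#' changes bounded when one stage is silent. The p-value comes from a
#' Welch (unequal-variance) two-sample t-test on log2(FPKM + eps) replicate
#' values, adjusted by Benjamini-Hochberg within the comparison. A feature
#' is called `up`/`down` when |log2FC| exceeds `lfc_threshold` and the
#' adjusted p is below `q_threshold`, else `ns`. Features with identical
#' replicate values in both stages are assigned p = 1.
#'
#' @param expr an [expression_matrix()].
#' @param comparison character pair `c(stage_b, stage_a)` read as "b vs a".
#' @param eps pseudocount added to FPKM before log2 (default 1).
#' @param lfc_threshold absolute log2 fold-change cutoff (default 1,
#'   i.e. 2-fold).
#' @param q_threshold adjusted-p cutoff (default 0.05).
#' @return data.frame of class `de_result`: feature_id, comparison, log2fc,
#'   p, p_adjust, call.
#' @export
differential_test <- function(expr, comparison, eps = 1,
                              lfc_threshold = 1, q_threshold = 0.05) {
  if (length(comparison) != 2L)
    abort_input("comparison must be c(stage_b, stage_a)")
  sb <- stage_samples(expr, comparison[1L])
  sa <- stage_samples(expr, comparison[2L])
  if (length(sb) < 2L || length(sa) < 2L)
    abort_input("each stage needs >= 2 replicates")
  vb <- expr$values[, sb, drop = FALSE]
  va <- expr$values[, sa, drop = FALSE]
  log2fc <- log2(rowMeans(vb) + eps) - log2(rowMeans(va) + eps)

  yb <- log2(vb + eps); ya <- log2(va + eps)
  nb <- ncol(yb); na_ <- ncol(ya)
  mb <- rowMeans(yb); ma <- rowMeans(ya)
  s2b <- apply(yb, 1L, stats::var); s2a <- apply(ya, 1L, stats::var)
  se2 <- s2b / nb + s2a / na_
  tt <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((s2b / nb)^2 / (nb - 1) + (s2a / na_)^2 / (na_ - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  zero_var <- se2 == 0
  p[zero_var & mb == ma] <- 1          # flat, identical replicates
  p[zero_var & mb != ma] <- .Machine$double.xmin
  p[is.na(p)] <- 1                     # degenerate variance estimates

  p_adjust <- bh_adjust(p)
  call <- rep("ns", length(p))
  sig <- abs(log2fc) > lfc_threshold & p_adjust < q_threshold
  call[sig & log2fc > 0] <- "up"
  call[sig & log2fc < 0] <- "down"
  out <- data.frame(
    feature_id = rownames(expr$values),
    comparison = paste(comparison[1L], "vs", comparison[2L]),
    log2fc = log2fc, p = p, p_adjust = p_adjust, call = call,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Up/down id sets for a list of comparisons
#'
#' Re-applies shared significance thresholds to a set of per-comparison DE
#' tables and returns the up- and down-regulated feature ids for each.
#'
#' @param tables named list of `de_result` tables (names = comparison
#'   labels).
#' @param lfc_threshold,q_threshold shared cutoffs (defaults 1 and 0.05).
#' @return named list; each element has `up`, `down` and `de` (union) id
#'   vectors.
#' @export
call_de_sets <- function(tables, lfc_threshold = 1, q_threshold = 0.05) {
  lapply(tables, function(tab) {
    sig <- abs(tab$log2fc) > lfc_threshold & tab$p_adjust < q_threshold
    up <- tab$feature_id[sig & tab$log2fc > 0]
    down <- tab$feature_id[sig & tab$log2fc < 0]
    list(up = up, down = down, de = c(up, down))
  })
}

#' Exclusive Venn-region counts for 2-5 id sets
#'
#' Enumerates every element's membership pattern across the sets and counts
#' each exclusive region (2^n - 1 regions for n sets). The region with all
#' sets present is the "common to all comparisons" count.
#'
#' @param sets named list of 2-5 character vectors.
#' @return data.frame: one row per region with the binary `pattern`
#'   (set order = list order), the member set names, and `count`; plus
#'   attribute `elements`, a list of region member ids.
#' @export
venn_intersections <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 5L) abort_input("need between 2 and 5 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_len(k))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[, k:1, drop = FALSE]
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  rows <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    in_region <- if (length(universe) == 0L) logical(0) else
      apply(membership, 1L, function(m) all(m == pat))
    data.frame(
      pattern = paste(as.integer(pat), collapse = ""),
      sets = paste(names(sets)[pat], collapse = "&"),
      count = sum(in_region),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "elements") <- lapply(seq_len(nrow(patterns)), function(i) {
    pat <- unlist(patterns[i, ])
    if (length(universe) == 0L) character(0) else
      universe[apply(membership, 1L, function(m) all(m == pat))]
  })
  out
}
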