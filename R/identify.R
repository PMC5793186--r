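#' Filter thresholds for the lncRNA identification cascade
#'
#' Bundles every cutoff of the candidate-lncRNA cascade. Size is strict
#' (> `min_length_bp` of mature length), exon count is inclusive
#' (>= `min_exons`), and each coding-potential score carries an explicit
#' retained side because the upstream tools disagree on sign conventions:
#' by those conventions a noncoding transcript scores CNCI < 0, CPC < 0,
#' Pfam E-value > 0.001 (no protein-domain hit) and a low PhyloCSF score.
#' `as_printed = TRUE` flips CNCI/CPC/PhyloCSF to the retained-if-greater
#' reading some pipelines print.
#'
#' @param min_length_bp minimum mature transcript length, exclusive
#'   (default 200).
#' @param min_exons minimum exon count, inclusive (default 2).
#' @param min_fpkm expression cutoff in FPKM (default 0.5), applied per
#'   `fpkm_rule`.
#' @param fpkm_rule `"any_sample"` (default) keeps a transcript whose FPKM
#'   reaches `min_fpkm` in at least one sample; `"all_samples"` requires it
#'   in every sample.
#' @param cnci_cutoff,cpc_cutoff,phylocsf_cutoff,pfam_evalue_cutoff score
#'   cutoffs (defaults 0, 0, -20, 0.001).
#' @param cnci_retain,cpc_retain,phylocsf_retain,pfam_retain side retained
#'   as noncoding, `"less"` or `"greater"` (strict inequality).
#' @param cis_window_bp window used downstream for cis-target pairing
#'   (default 10000).
#' @param missing_scores `"fail"` (default, conservative) or `"pass"` for
#'   transcripts absent from the score table.
#' @param as_printed logical; use the retained-if-greater preset for
#'   CNCI/CPC/PhyloCSF.
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_length_bp = 200, min_exons = 2,
                              min_fpkm = 0.5,
                              fpkm_rule = c("any_sample", "all_samples"),
                              cnci_cutoff = 0, cnci_retain = "less",
                              cpc_cutoff = 0, cpc_retain = "less",
                              pfam_evalue_cutoff = 0.001,
                              pfam_retain = "greater",
                              phylocsf_cutoff = -20, phylocsf_retain = "less",
                              cis_window_bp = 10000,
                              missing_scores = c("fail", "pass"),
                              as_printed = FALSE) {
  fpkm_rule <- match.arg(fpkm_rule)
  missing_scores <- match.arg(missing_scores)
  if (as_printed) {
    cnci_retain <- "greater"; cpc_retain <- "greater"
    phylocsf_retain <- "greater"
  }
  side <- function(x) match.arg(x, c("less", "greater"))
  th <- list(
    min_length_bp = min_length_bp, min_exons = min_exons,
    min_fpkm = min_fpkm, fpkm_rule = fpkm_rule,
    scores = list(
      cnci = list(cutoff = cnci_cutoff, retain = side(cnci_retain)),
      cpc = list(cutoff = cpc_cutoff, retain = side(cpc_retain)),
      pfam_evalue = list(cutoff = pfam_evalue_cutoff, retain = side(pfam_retain)),
      phylocsf = list(cutoff = phylocsf_cutoff, retain = side(phylocsf_retain))
    ),
    cis_window_bp = cis_window_bp, missing_scores = missing_scores
  )
  cuts <- vapply(th$scores, function(s) s$cutoff, numeric(1L))
  if (any(!is.finite(cuts))) abort_input("score cutoffs must be finite")
  structure(th, class = "filter_thresholds")
}

# put two GRanges on the union of their seqlevels so findOverlaps never
# warns about disjoint chromosome sets
.common_seqlevels <- function(ga, gb) {
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

# transcript-id pairs with >= 1 bp exonic overlap between two sets,
# annotated with the strand relation; also returns summed overlap bp
.exonic_overlap_pairs <- function(ts_a, ts_b) {
  h <- .common_seqlevels(exons_granges(ts_a), exons_granges(ts_b))
  ga <- h[[1L]]; gb <- h[[2L]]
  hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(data.frame(a = character(), b = character(),
                      same_strand = logical(), overlap_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(ga)[qh], IRanges::ranges(gb)[sh]))
  key <- data.frame(
    a = ga$transcript_id[qh], b = gb$transcript_id[sh],
    same_strand = as.character(GenomicRanges::strand(ga)[qh]) ==
      as.character(GenomicRanges::strand(gb)[sh]),
    overlap_bp = ov, stringsAsFactors = FALSE)
  out <- stats::aggregate(overlap_bp ~ a + b + same_strand, data = key, FUN = sum)
  out[order(out$a, out$b), , drop = FALSE]
}

# candidate transcript ids whose genomic span overlaps any span in ts_b
.span_overlap_ids <- function(ts_a, ts_b) {
  h <- .common_seqlevels(spans_granges(ts_a), spans_granges(ts_b))
  ga <- h[[1L]]; gb <- h[[2L]]
  hits <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  unique(ga$transcript_id[S4Vectors::queryHits(hits)])
}

#' Apply the candidate-lncRNA filter cascade
#'
#' Runs the conjunctive identification filters over every transcript of a
#' merged assembly: mature length, exon count, expression level, exclusion
#' of transcripts matching known protein-coding loci (same-strand exonic or
#' intronic overlap; opposite-strand exonic overlap is retained so antisense
#' lncRNAs survive), exclusion of transcripts with exonic overlap of known
#' pseudogene/small-RNA loci (pre-miRNA, tRNA, rRNA, snoRNA), and the four
#' coding-potential thresholds (CNCI, CPC, Pfam E-value, PhyloCSF). Every
#' filter's verdict is recorded for every transcript (the audit does not
#' short-circuit); the final call is the conjunction.
#'
#' @param ts merged-assembly [transcript_set()] of candidate transcripts.
#' @param expr [expression_matrix()] covering every candidate.
#' @param scores data.frame with columns `transcript_id`, `cnci`, `cpc`,
#'   `pfam_evalue`, `phylocsf`.
#' @param ref reference [transcript_set()] whose biotypes mark
#'   protein-coding, pseudogene and small-RNA loci.
#' @param thresholds a [filter_thresholds()] object.
#' @return data.frame of class `lncrna_records`: one row per candidate with
#'   per-filter `pass_*` columns, `final_call`, and `class`/`novelty`
#'   placeholders filled by [classify_lncrna()] and [match_known()].
#' @export
apply_filter_cascade <- function(ts, expr, scores, ref,
                                 thresholds = filter_thresholds()) {
  idx <- ts$index
  ids <- idx$transcript_id
  missing_expr <- setdiff(ids, rownames(expr$values))
  if (length(missing_expr) > 0L)
    abort_input("candidate(s) without an expression row: %s",
                paste(utils::head(missing_expr, 5L), collapse = ", "))

  pass_length <- idx$length > thresholds$min_length_bp
  pass_exons <- idx$n_exons >= thresholds$min_exons

  v <- expr$values[ids, , drop = FALSE]
  pass_expression <- if (thresholds$fpkm_rule == "any_sample") {
    apply(v >= thresholds$min_fpkm, 1L, any)
  } else {
    apply(v >= thresholds$min_fpkm, 1L, all)
  }

  ref_coding <- subset_transcripts(ref, biotype = "protein_coding")
  ref_small <- subset_transcripts(ref, biotype = c("pseudogene", "small_rna"))

  span_hit <- ids %in% .span_overlap_ids(ts, ref_coding)
  expairs <- .exonic_overlap_pairs(ts, ref_coding)
  sense_exonic <- ids %in% unique(expairs$a[expairs$same_strand])
  anti_exonic <- ids %in% unique(expairs$a[!expairs$same_strand])
  # retained iff clear of coding loci, or a clean antisense configuration
  pass_coding_overlap <- !span_hit | (anti_exonic & !sense_exonic)

  small_pairs <- .exonic_overlap_pairs(ts, ref_small)
  pass_noncoding_overlap <- !(ids %in% unique(small_pairs$a))

  sc <- as.data.frame(scores)
  need <- c("transcript_id", names(thresholds$scores))
  if (!all(need %in% names(sc)))
    abort_input("score table needs columns: %s", paste(need, collapse = ", "))
  row <- match(ids, sc$transcript_id)
  score_pass <- function(name) {
    spec <- thresholds$scores[[name]]
    val <- sc[[name]][row]
    ok <- if (spec$retain == "less") val < spec$cutoff else val > spec$cutoff
    ok[is.na(val)] <- thresholds$missing_scores == "pass"
    ok
  }
  pass_cnci <- score_pass("cnci")
  pass_cpc <- score_pass("cpc")
  pass_pfam <- score_pass("pfam_evalue")
  pass_phylocsf <- score_pass("phylocsf")

  rec <- data.frame(
    transcript_id = ids,
    pass_length = pass_length, pass_exons = pass_exons,
    pass_expression = pass_expression,
    pass_coding_overlap = pass_coding_overlap,
    pass_noncoding_overlap = pass_noncoding_overlap,
    pass_cnci = pass_cnci, pass_cpc = pass_cpc, pass_pfam = pass_pfam,
    pass_phylocsf = pass_phylocsf,
    stringsAsFactors = FALSE
  )
  pass_cols <- grep("^pass_", names(rec), value = TRUE)
  rec$final_call <- Reduce(`&`, rec[pass_cols])
  rec$class <- ifelse(rec$final_call, NA_character_, "none")
  rec$novelty <- ifelse(rec$final_call, NA_character_, "n/a")
  class(rec) <- c("lncrna_records", "data.frame")
  rec
}

#' Classify called lncRNAs as lincRNA or antisense
#'
#' A called candidate is `antisense` when at least one of its exons overlaps
#' a protein-coding transcript's exon on the opposite strand by >= 1 bp, and
#' `lincRNA` when its genomic span overlaps no protein-coding locus on
#' either strand. The cascade guarantees these two cases are exhaustive for
#' called records; anything else signals a contract violation.
#'
#' @param records `lncrna_records` from [apply_filter_cascade()].
#' @param ts the candidate [transcript_set()] the records were computed from.
#' @param ref_coding reference [transcript_set()] restricted (or
#'   restrictable) to protein-coding transcripts.
#' @return `records` with `class` filled for every called transcript.
#' @export
classify_lncrna <- function(records, ts, ref_coding) {
  ref_coding <- subset_transcripts(ref_coding, biotype = "protein_coding")
  called <- records$transcript_id[records$final_call]
  if (length(called) == 0L) return(records)
  sub <- subset_transcripts(ts, ids = called)
  expairs <- .exonic_overlap_pairs(sub, ref_coding)
  anti <- unique(expairs$a[!expairs$same_strand])
  span_hit <- .span_overlap_ids(sub, ref_coding)
  cls <- ifelse(called %in% anti, "antisense",
                ifelse(called %in% span_hit, NA_character_, "lincRNA"))
  if (anyNA(cls))
    stop("internal error: called lncRNA overlaps a coding locus without an ",
         "antisense exonic overlap; the cascade should have excluded it")
  records$class[match(called, records$transcript_id)] <- cls
  records
}

#' Flag called lncRNAs as previously annotated or novel
#'
#' A called candidate is `annotated` when its same-strand exonic overlap
#' with some single known lncRNA covers at least `min_overlap_fraction` of
#' the candidate's mature length (and is > 0 bp); otherwise `novel`.
#' Coordinate overlap against a known-lncRNA annotation stands in for a
#' sequence-similarity search, which needs real sequence databases.
#'
#' @param records `lncrna_records` with final calls.
#' @param ts the candidate [transcript_set()].
#' @param known known-lncRNA reference [transcript_set()].
#' @param min_overlap_fraction required overlap as a fraction of the
#'   candidate's mature length (default 0.5).
#' @return `records` with `novelty` filled for every called transcript.
#' @export
match_known <- function(records, ts, known, min_overlap_fraction = 0.5) {
  called <- records$transcript_id[records$final_call]
  if (length(called) == 0L) return(records)
  sub <- subset_transcripts(ts, ids = called)
  pairs <- .exonic_overlap_pairs(sub, known)
  pairs <- pairs[pairs$same_strand, , drop = FALSE]
  best <- if (nrow(pairs) > 0L) {
    tapply(pairs$overlap_bp, pairs$a, max)
  } else {
    numeric(0)
  }
  len <- sub$index$length[match(called, sub$index$transcript_id)]
  ov <- as.numeric(best[called])
  ov[is.na(ov)] <- 0
  annotated <- ov > 0 & ov >= min_overlap_fraction * len
  records$novelty[match(called, records$transcript_id)] <-
    ifelse(annotated, "annotated", "novel")
  records
}

#' @export
print.lncrna_records <- function(x, ...) {
  n <- nrow(x)
  called <- sum(x$final_call)
  cat(sprintf("lncrna_records: %d candidates, %d called lncRNAs\n", n, called))
  if (called > 0L && !anyNA(x$class[x$final_call])) {
    cl <- table(x$class[x$final_call])
    cat("  classes:", paste(sprintf("%s=%d", names(cl), cl), collapse = ", "), "\n")
  }
  if (called > 0L && !anyNA(x$novelty[x$final_call])) {
    nv <- table(x$novelty[x$final_call])
    cat("  novelty:", paste(sprintf("%s=%d", names(nv), nv), collapse = ", "), "\n")
  }
  invisible(x)
}
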