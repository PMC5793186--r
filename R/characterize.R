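#' Length of the longest open reading frame
#'
#' Scans the three sense-strand reading frames of a spliced transcript
#' sequence for the longest ATG-initiated, in-frame, stop-terminated ORF and
#' returns its length in bases including the stop codon (0 when none
#' exists). Transcripts are stranded, so only the sense strand is read.
#' Codons containing `N` match neither start nor stop. Ties are broken
#' toward the 5'-most start, which also makes the result deterministic.
#'
#' @param sequence nucleotide string over A/C/G/T/N (case-insensitive).
#' @param allow_open_orf when TRUE, an ATG with no downstream in-frame stop
#'   scores the run to the last complete codon instead of 0.
#' @return integer ORF length in bases, always a multiple of 3.
#' @export
longest_orf <- function(sequence, allow_open_orf = FALSE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (grepl("[^ACGTN]", s)) abort_input("sequence contains non-nucleotide characters")
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (frame in 0:2) {
    n_codon <- (n - frame) %/% 3L
    if (n_codon < 1L) next
    pos <- frame + seq(1L, by = 3L, length.out = n_codon)
    codons <- substring(s, pos, pos + 2L)
    start_i <- which(codons == "ATG")
    stop_i <- which(codons %in% stops)
    for (si in start_i) {
      down <- stop_i[stop_i > si]
      len <- if (length(down) > 0L) {
        (down[1L] - si + 1L) * 3L
      } else if (allow_open_orf) {
        (n_codon - si + 1L) * 3L
      } else {
        0L
      }
      # strict > keeps the 5'-most start among equal-length ORFs
      if (len > best) best <- len
    }
  }
  as.integer(best)
}

#' Spliced sense-strand sequences of transcripts
#'
#' Concatenates exon sequences in genomic order and reverse-complements
#' minus-strand transcripts.
#'
#' @param ts a [transcript_set()].
#' @param genome a [Biostrings::DNAStringSet] named by chromosome, or a
#'   named character vector of chromosome sequences.
#' @param ids transcripts to extract (default all).
#' @return named character vector of mature transcript sequences.
#' @export
mature_sequences <- function(ts, genome, ids = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(ids)) ids <- transcript_ids(ts)
  ex <- ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE]
  missing_chrom <- setdiff(unique(ex$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    abort_input("chromosome(s) absent from genome: %s",
                paste(missing_chrom, collapse = ", "))
  out <- vapply(ids, function(tx) {
    e <- ex[ex$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    chrom_seq <- genome[[e$chrom[1L]]]
    parts <- vapply(seq_len(nrow(e)), function(i) {
      as.character(Biostrings::subseq(chrom_seq, e$start[i] + 1L, e$end[i]))
    }, character(1L))
    seqc <- paste(parts, collapse = "")
    if (e$strand[1L] == "-")
      seqc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqc)))
    seqc
  }, character(1L))
  names(out) <- ids
  out
}

#' Descriptive features of lncRNA vs mRNA sets
#'
#' Computes, per set, the genomic feature summaries used to contrast lncRNAs
#' with mRNAs: transcript counts, mature-length and exon-count means and
#' medians, per-chromosome counts, class proportions across the two sets,
#' and (when a genome is supplied) longest-ORF statistics.
#'
#' @param ts a [transcript_set()] containing both sets.
#' @param lnc_ids,mrna_ids disjoint transcript-id vectors.
#' @param genome optional genome (see [mature_sequences()]); when NULL, ORF
#'   fields are `NA`.
#' @return object of class `feature_summary`: a list with `per_transcript`
#'   (one row per transcript: set, length, exons, orf_length) and `summary`
#'   (one row per set).
#' @export
summarize_features <- function(ts, lnc_ids, mrna_ids, genome = NULL) {
  if (length(intersect(lnc_ids, mrna_ids)) > 0L)
    abort_input("lnc_ids and mrna_ids must be disjoint")
  all_ids <- c(lnc_ids, mrna_ids)
  unknown <- setdiff(all_ids, transcript_ids(ts))
  if (length(unknown) > 0L)
    abort_input("id(s) not in transcript set: %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  idx <- ts$index[match(all_ids, ts$index$transcript_id), , drop = FALSE]
  per <- data.frame(
    transcript_id = all_ids,
    set = rep(c("lncRNA", "mRNA"), c(length(lnc_ids), length(mrna_ids))),
    chrom = idx$chrom,
    length = idx$length,
    n_exons = idx$n_exons,
    orf_length = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    seqs <- mature_sequences(ts, genome, ids = all_ids)
    per$orf_length <- vapply(seqs, longest_orf, integer(1L))
  }
  summ <- do.call(rbind, lapply(split(per, per$set), function(d) {
    data.frame(
      set = d$set[1L], n = nrow(d),
      mean_length = mean(d$length), median_length = stats::median(d$length),
      mean_exons = mean(d$n_exons), median_exons = stats::median(d$n_exons),
      mean_orf = mean(d$orf_length), median_orf = stats::median(d$orf_length),
      proportion = nrow(d) / nrow(per),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  chrom_counts <- table(set = per$set, chrom = per$chrom)
  structure(list(per_transcript = per, summary = summ,
                 chromosome_counts = chrom_counts),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat("feature_summary\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
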