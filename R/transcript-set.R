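#' Transcript set: the package's annotation container
#'
#' A `transcript_set` holds one row per exon with internal 0-based half-open
#' coordinates. GTF input/output converts to/from the standard 1-based
#' inclusive convention at the boundary; all interval arithmetic inside the
#' package is half-open, so lengths are simply `end - start`.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand` (`"+"` or `"-"`), `start`, `end` (0-based half-open), and
#'   optionally `biotype` (one of `"protein_coding"`, `"pseudogene"`,
#'   `"small_rna"`, `"candidate"`, `"known_lncRNA"`; default `"candidate"`).
#'   Exons belonging to one transcript must be non-overlapping.
#' @return an object of class `transcript_set`: the validated, sorted exon
#'   table plus a derived per-transcript index.
#' @export
transcript_set <- function(exons) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0L)
    abort_input("exon table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (!"biotype" %in% names(exons)) exons$biotype <- "candidate"
  exons <- as.data.frame(exons)[, c(required, "biotype")]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  exons$biotype <- as.character(exons$biotype)

  if (nrow(exons) > 0L) {
    if (!all(exons$strand %in% c("+", "-")))
      abort_input("strand must be '+' or '-'")
    bad <- exons$start >= exons$end
    if (any(bad))
      abort_input("exon with start >= end for transcript %s",
                  exons$transcript_id[which(bad)[1L]])
    known_bt <- c("protein_coding", "pseudogene", "small_rna", "candidate",
                  "known_lncRNA")
    if (!all(exons$biotype %in% known_bt))
      abort_input("unknown biotype: %s",
                  paste(setdiff(exons$biotype, known_bt), collapse = ", "))
    exons <- exons[order(exons$chrom, exons$start, exons$end,
                         exons$transcript_id), , drop = FALSE]
    rownames(exons) <- NULL
    # per-transcript: single chrom/strand/gene, exons non-overlapping
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(unique(exons$chrom[idx])) != 1L ||
          length(unique(exons$strand[idx])) != 1L ||
          length(unique(exons$gene_id[idx])) != 1L)
        abort_input("transcript %s has inconsistent chrom/strand/gene_id",
                    exons$transcript_id[idx[1L]])
      s <- exons$start[idx]; e <- exons$end[idx]
      o <- order(s)
      if (length(idx) > 1L && any(s[o][-1L] < e[o][-length(o)]))
        abort_input("transcript %s has overlapping exons",
                    exons$transcript_id[idx[1L]])
    }
  }

  obj <- list(exons = exons, index = .tx_index(exons))
  class(obj) <- "transcript_set"
  obj
}

# per-transcript summary table (genomic span, mature length, exon count)
.tx_index <- function(exons) {
  if (nrow(exons) == 0L) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      span_start = numeric(), span_end = numeric(),
                      n_exons = integer(), length = numeric(),
                      biotype = character(), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  ids <- names(sp)
  first <- vapply(sp, `[`, integer(1L), 1L)
  idx <- data.frame(
    transcript_id = ids,
    gene_id = exons$gene_id[first],
    chrom = exons$chrom[first],
    strand = exons$strand[first],
    span_start = vapply(sp, function(i) min(exons$start[i]), numeric(1L)),
    span_end = vapply(sp, function(i) max(exons$end[i]), numeric(1L)),
    n_exons = lengths(sp),
    length = vapply(sp, function(i) sum(exons$end[i] - exons$start[i]),
                    numeric(1L)),
    biotype = exons$biotype[first],
    stringsAsFactors = FALSE
  )
  idx <- idx[order(idx$chrom, idx$span_start, idx$transcript_id), , drop = FALSE]
  rownames(idx) <- NULL
  idx
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts (%d exons) on %d chromosome(s)\n",
              nrow(x$index), nrow(x$exons), length(unique(x$exons$chrom))))
  if (nrow(x$index) > 0L) {
    bt <- table(x$index$biotype)
    cat("  biotypes:", paste(sprintf("%s=%d", names(bt), bt), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$index)

#' Transcript ids of a transcript set
#' @param ts a `transcript_set`.
#' @return character vector of transcript ids (index order).
#' @export
transcript_ids <- function(ts) ts$index$transcript_id

#' Per-transcript summary table
#'
#' @param ts a `transcript_set`.
#' @return data.frame with one row per transcript: gene id, chromosome,
#'   strand, genomic span, exon count, mature (summed-exon) length, biotype.
#' @export
transcript_index <- function(ts) ts$index

#' Restrict a transcript set to chosen transcripts or biotypes
#'
#' @param ts a `transcript_set`.
#' @param ids transcript ids to keep (NULL = no id filter).
#' @param biotype biotypes to keep (NULL = no biotype filter).
#' @return a `transcript_set` with the selected transcripts.
#' @export
subset_transcripts <- function(ts, ids = NULL, biotype = NULL) {
  keep <- rep(TRUE, nrow(ts$exons))
  if (!is.null(ids)) {
    unknown <- setdiff(ids, ts$index$transcript_id)
    if (length(unknown) > 0L)
      abort_input("unknown transcript id(s): %s",
                  paste(utils::head(unknown, 5L), collapse = ", "))
    keep <- keep & ts$exons$transcript_id %in% ids
  }
  if (!is.null(biotype)) keep <- keep & ts$exons$biotype %in% biotype
  transcript_set(ts$exons[keep, , drop = FALSE])
}

# exon-level GRanges (1-based closed, as GenomicRanges expects)
exons_granges <- function(ts) {
  ex <- ts$exons
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand,
    transcript_id = ex$transcript_id,
    gene_id = ex$gene_id,
    biotype = ex$biotype
  )
}

# transcript-span GRanges; by = "gene" collapses spans over each gene's
# transcripts (used for cis windows, which the field defines at gene level)
spans_granges <- function(ts, by = c("transcript", "gene")) {
  by <- match.arg(by)
  idx <- ts$index
  if (by == "transcript") {
    return(GenomicRanges::GRanges(
      seqnames = idx$chrom,
      ranges = IRanges::IRanges(start = idx$span_start + 1L, end = idx$span_end),
      strand = idx$strand,
      transcript_id = idx$transcript_id,
      gene_id = idx$gene_id,
      biotype = idx$biotype
    ))
  }
  sp <- split(seq_len(nrow(idx)), idx$gene_id)
  gid <- names(sp)
  first <- vapply(sp, `[`, integer(1L), 1L)
  GenomicRanges::GRanges(
    seqnames = idx$chrom[first],
    ranges = IRanges::IRanges(
      start = vapply(sp, function(i) min(idx$span_start[i]), numeric(1L)) + 1L,
      end = vapply(sp, function(i) max(idx$span_end[i]), numeric(1L))
    ),
    strand = idx$strand[first],
    gene_id = gid
  )
}

#' Test equality of two transcript sets
#' @param a,b `transcript_set` objects.
#' @return TRUE if both describe the same exons (id, coordinates, strand,
#'   biotype), FALSE otherwise.
#' @export
same_transcript_set <- function(a, b) {
  ea <- a$exons[order(a$exons$transcript_id, a$exons$start), , drop = FALSE]
  eb <- b$exons[order(b$exons$transcript_id, b$exons$start), , drop = FALSE]
  rownames(ea) <- rownames(eb) <- NULL
  isTRUE(all.equal(ea, eb))
}
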