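#' Parse a GTF annotation into a transcript set
#'
#' Reads exon features from GTF text (1-based inclusive coordinates) and
#' builds the package's internal [transcript_set()] (0-based half-open).
#' Only `exon` features are used; attributes must carry `transcript_id` and
#' `gene_id`. The biotype is taken from `biotype_key` when present and
#' defaults to `"candidate"` otherwise (merged-assembly GTFs carry no
#' biotype; reference annotations do).
#'
#' @param gtf path to a GTF file, or a character vector of GTF lines.
#' @param biotype_key attribute name holding the biotype (default
#'   `"gene_biotype"`).
#' @return a [transcript_set()].
#' @export
parse_gtf <- function(gtf, biotype_key = "gene_biotype") {
  lines <- if (length(gtf) == 1L && !grepl("\t", gtf) && file.exists(gtf)) {
    readLines(gtf)
  } else {
    as.character(gtf)
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(transcript_set(data.frame(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = numeric(), end = numeric(),
      biotype = character(), stringsAsFactors = FALSE)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    abort_input("malformed GTF line %d: expected 9 tab-separated columns, got %d",
                lineno[which(nf != 9L)[1L]], nf[which(nf != 9L)[1L]])
  m <- do.call(rbind, fields)
  is_exon <- m[, 3L] == "exon"
  m <- m[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  if (nrow(m) == 0L) {
    return(transcript_set(data.frame(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = numeric(), end = numeric(),
      biotype = character(), stringsAsFactors = FALSE)))
  }
  start1 <- suppressWarnings(as.numeric(m[, 4L]))
  end1 <- suppressWarnings(as.numeric(m[, 5L]))
  if (anyNA(start1) || anyNA(end1))
    abort_input("malformed GTF line %d: non-numeric coordinates",
                lineno[which(is.na(start1) | is.na(end1))[1L]])
  bad <- end1 < start1
  if (any(bad))
    abort_input("invalid GTF line %d: end (%s) < start (%s)",
                lineno[which(bad)[1L]], m[which(bad)[1L], 5L],
                m[which(bad)[1L], 4L])

  attr_get <- function(attrs, key) {
    pat <- paste0('(^|; ?)', key, ' +"([^"]*)"')
    mm <- regmatches(attrs, regexec(pat, attrs))
    vapply(mm, function(g) if (length(g) == 3L) g[3L] else NA_character_,
           character(1L))
  }
  tx <- attr_get(m[, 9L], "transcript_id")
  gn <- attr_get(m[, 9L], "gene_id")
  if (anyNA(tx) || anyNA(gn))
    abort_input("GTF line %d lacks a transcript_id or gene_id attribute",
                lineno[which(is.na(tx) | is.na(gn))[1L]])
  bt <- attr_get(m[, 9L], biotype_key)
  bt[is.na(bt)] <- "candidate"

  transcript_set(data.frame(
    transcript_id = tx, gene_id = gn, chrom = m[, 1L], strand = m[, 7L],
    start = start1 - 1, end = end1, biotype = bt, stringsAsFactors = FALSE))
}

#' Write a transcript set as GTF text
#'
#' Emits one `exon` feature per exon, 1-based inclusive, deterministically
#' ordered by (chromosome, start, transcript id), so identical transcript
#' sets always serialize to identical bytes. `parse_gtf(write_gtf(ts))`
#' round-trips to an identical set.
#'
#' @param ts a [transcript_set()].
#' @param file optional path; when given, lines are written there.
#' @param source value for the GTF source column (default `"lncdissect"`).
#' @return character vector of GTF lines (invisibly when `file` is given).
#' @export
write_gtf <- function(ts, file = NULL, source = "lncdissect") {
  ex <- ts$exons
  ex <- ex[order(ex$chrom, ex$start, ex$transcript_id, ex$end), , drop = FALSE]
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, source, as.integer(ex$start) + 1L, as.integer(ex$end),
    ex$strand, ex$gene_id, ex$transcript_id, ex$biotype)
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
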