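# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately written in plain base R, independently of the
# package's GenomicRanges-based implementations.

# one-transcript exon table
tx_rows <- function(id, chrom, strand, starts, ends, gene = id,
                    biotype = "candidate") {
  data.frame(transcript_id = id, gene_id = gene, chrom = chrom,
             strand = strand, start = starts, end = ends, biotype = biotype,
             stringsAsFactors = FALSE)
}

make_ts <- function(...) transcript_set(do.call(rbind, list(...)))

# expression matrix with the standard 4 x 3 design from a feature x 12 matrix
make_expr <- function(values, ids = rownames(values)) {
  st <- c("A0", "A1", "A3", "A5")
  samples <- as.vector(t(outer(st, 1:3, function(s, r) paste0(s, "_R", r))))
  colnames(values) <- samples
  rownames(values) <- ids
  expression_matrix(values, data.frame(
    sample = samples, stage = rep(st, each = 3), replicate = rep(1:3, 4)))
}

# half-open interval overlap in bp
.ov_bp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# O(n^2) oracle: per pair of transcripts, summed exonic overlap bp split by
# strand relation
oracle_exonic_overlap <- function(ts_a, ts_b) {
  ea <- ts_a$exons; eb <- ts_b$exons
  ia <- transcript_index(ts_a); ib <- transcript_index(ts_b)
  out <- list()
  for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
    if (ia$chrom[i] != ib$chrom[j]) next
    exa <- ea[ea$transcript_id == ia$transcript_id[i], ]
    exb <- eb[eb$transcript_id == ib$transcript_id[j], ]
    bp <- 0
    for (p in seq_len(nrow(exa))) for (q in seq_len(nrow(exb)))
      bp <- bp + .ov_bp(exa$start[p], exa$end[p], exb$start[q], exb$end[q])
    if (bp > 0)
      out[[length(out) + 1L]] <- data.frame(
        a = ia$transcript_id[i], b = ib$transcript_id[j],
        same_strand = ia$strand[i] == ib$strand[j], overlap_bp = bp,
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(a = character(), b = character(),
                      same_strand = logical(), overlap_bp = numeric()))
  do.call(rbind, out)
}

# O(n^2) oracle for span overlap of transcripts in a with transcripts in b
oracle_span_overlap_ids <- function(ts_a, ts_b) {
  ia <- transcript_index(ts_a); ib <- transcript_index(ts_b)
  hits <- character(0)
  for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
    if (ia$chrom[i] != ib$chrom[j]) next
    if (.ov_bp(ia$span_start[i], ia$span_end[i],
               ib$span_start[j], ib$span_end[j]) > 0)
      hits <- c(hits, ia$transcript_id[i])
  }
  unique(hits)
}

# O(n^2) oracle for cis pairing: closest-end distance between the lncRNA
# span and the gene-level span (union over the gene's transcripts)
oracle_cis_pairs <- function(lnc, coding, window) {
  il <- transcript_index(lnc)
  ic <- transcript_index(coding)
  genes <- do.call(rbind, lapply(split(ic, ic$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               s = min(g$span_start), e = max(g$span_end),
               stringsAsFactors = FALSE)))
  out <- list()
  for (i in seq_len(nrow(il))) for (j in seq_len(nrow(genes))) {
    if (il$chrom[i] != genes$chrom[j]) next
    d <- if (.ov_bp(il$span_start[i], il$span_end[i], genes$s[j], genes$e[j]) > 0)
      0
    else if (il$span_end[i] <= genes$s[j]) genes$s[j] - il$span_end[i]
    else il$span_start[i] - genes$e[j]
    if (d <= window)
      out[[length(out) + 1L]] <- data.frame(
        lnc_id = il$transcript_id[i], gene_id = genes$gene_id[j],
        distance = d, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(lnc_id = character(), gene_id = character(),
                      distance = numeric()))
  do.call(rbind, out)
}

# exhaustive scan-all-substrings ORF oracle
oracle_orf <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  for (i in seq_len(max(0, n - 2))) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      if (substr(s, j, j + 2) %in% stops) {
        len <- j + 3L - i
        if (len > best) best <- len
        break
      }
      j <- j + 3L
    }
  }
  as.integer(best)
}

# textbook BH step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# per-element membership enumeration for Venn regions
oracle_venn_count <- function(sets, pattern) {
  universe <- unique(unlist(sets))
  sum(vapply(universe, function(el) {
    all(vapply(seq_along(sets), function(i)
      (el %in% sets[[i]]) == (substr(pattern, i, i) == "1"), logical(1)))
  }, logical(1)))
}

# closed-form hypergeometric upper tail by direct combinatorial summation
oracle_hyper_upper <- function(k, K, N, n) {
  j <- seq(k, min(K, n))
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# rank-then-Pearson Spearman oracle (average ranks)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mean((rx - mean(rx)) * (ry - mean(ry))) / (stats::sd(rx) * stats::sd(ry)) *
    length(x) / (length(x) - 1)
}

# small simulated dataset used by several test files (kept modest for speed)
small_config <- function(seed = 11, ...) {
  simulation_config(seed = seed, n_chroms = 2, chrom_length = 1.6e6,
                    n_coding_genes = 36, n_linc = 20, n_antisense = 6,
                    n_pseudogene = 3, n_small_rna = 3, trans_pair_count = 5,
                    ...)
}
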