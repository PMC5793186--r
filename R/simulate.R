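#' Configuration for the synthetic-data generator
#'
#' Describes a synthetic study emulating a four-stage differentiation time
#' course (stages A0/A1/A3/A5, i.e. 0/24/72/120 h, three replicates each):
#' a genome annotation with protein-coding genes, intergenic and antisense
#' lncRNAs, pseudogene and small-RNA loci; an FPKM matrix with planted
#' temporal archetypes and co-expression pairs; and coding-potential scores
#' placed on the correct side of the identification thresholds. Every
#' planted lncRNA passes all identification filters by construction, and
#' every planted non-lncRNA fails at least one, so downstream recovery is
#' exactly checkable.
#'
#' @param seed integer; all randomness flows from it.
#' @param n_chroms,chrom_length genome shape (default 3 chromosomes of
#'   3.6 Mb).
#' @param n_coding_genes,n_linc,n_antisense,n_pseudogene,n_small_rna
#'   feature counts (defaults 120/60/12/8/8).
#' @param cis_pair_fraction fraction of lincRNAs placed within 10 kb of a
#'   designated coding gene (default 0.4); the rest are placed > 10 kb from
#'   every coding gene. Antisense lncRNAs overlap their host gene and are
#'   cis by construction.
#' @param de_fraction fraction of coding and of lncRNA transcripts given a
#'   temporal archetype (default 0.3).
#' @param archetype_mix proportions of the K1-K4 archetypes among DE
#'   features; the default mirrors the 1436/440/1762/784 split of a
#'   four-cluster myoblast differentiation time course.
#' @param de_log2fc planted per-step effect size in log2 units (default 2).
#' @param noise_sd multiplicative lognormal replicate noise scale (sdlog;
#'   default 0.1). 0 gives noise-free data.
#' @param trans_pair_count number of planted high-|r| lncRNA-mRNA
#'   co-expression pairs (default 20).
#' @param prop_positive_trans fraction of planted trans pairs with positive
#'   correlation (default 0.74).
#' @param known_fraction fraction of planted lncRNAs also present in the
#'   known-lncRNA reference (default 0.5).
#' @param n_replicates replicates per stage (default 3).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_chroms = 3, chrom_length = 3.6e6,
                              n_coding_genes = 120, n_linc = 60,
                              n_antisense = 12, n_pseudogene = 8,
                              n_small_rna = 8, cis_pair_fraction = 0.4,
                              de_fraction = 0.3,
                              archetype_mix = c(K1 = 1436, K2 = 440,
                                                K3 = 1762, K4 = 784) / 4422,
                              de_log2fc = 2, noise_sd = 0.1,
                              trans_pair_count = 20,
                              prop_positive_trans = 0.74,
                              known_fraction = 0.5, n_replicates = 3) {
  counts <- c(n_chroms, n_coding_genes, n_linc, n_antisense, n_pseudogene,
              n_small_rna, trans_pair_count, n_replicates)
  if (any(counts < 0) || any(counts != floor(counts)))
    abort_input("feature counts must be non-negative integers")
  props <- c(cis_pair_fraction, de_fraction, known_fraction,
             prop_positive_trans)
  if (any(props < 0 | props > 1))
    abort_input("fractions must lie in [0, 1]")
  if (length(archetype_mix) != 4L ||
      abs(sum(archetype_mix) - 1) > 1e-8 || any(archetype_mix < 0))
    abort_input("archetype_mix must be 4 non-negative proportions summing to 1")
  names(archetype_mix) <- c("K1", "K2", "K3", "K4")
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  if (de_log2fc < 0) abort_input("de_log2fc must be >= 0")
  structure(list(
    seed = as.integer(seed), n_chroms = n_chroms,
    chrom_length = chrom_length, n_coding_genes = n_coding_genes,
    n_linc = n_linc, n_antisense = n_antisense,
    n_pseudogene = n_pseudogene, n_small_rna = n_small_rna,
    cis_pair_fraction = cis_pair_fraction, de_fraction = de_fraction,
    archetype_mix = archetype_mix, de_log2fc = de_log2fc,
    noise_sd = noise_sd, trans_pair_count = trans_pair_count,
    prop_positive_trans = prop_positive_trans,
    known_fraction = known_fraction, n_replicates = n_replicates,
    stages = c("A0", "A1", "A3", "A5"), cis_window_bp = 10000
  ), class = "simulation_config")
}

# log2 offsets of the four temporal archetypes relative to baseline, per
# unit effect size: K1 decreasing, K2 late-rising, K3 rising from the
# start, K4 peaked at the second stage
.archetype_steps <- list(K1 = c(3, 2, 1, 0), K2 = c(0, 0, 1, 3),
                         K3 = c(0, 1, 2, 3), K4 = c(0, 3, 1, 0))

# integer allocation of n items to proportions p (largest-remainder)
.allocate <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate the synthetic genome annotation with planted truth
#'
#' Places non-overlapping protein-coding genes along each chromosome with
#' wide intergenic gaps, then plants lincRNAs (strictly intergenic; a
#' `cis_pair_fraction` of them within 10 kb of a designated gene, the rest
#' beyond 10 kb of every gene), antisense lncRNAs (exonic overlap of a host
#' gene on the opposite strand), and pseudogene/small-RNA loci. The merged
#' candidate set contains an mRNA candidate per coding gene, all planted
#' lncRNAs, and decoy candidates copying pseudogene/small-RNA loci (these
#' must be removed by the overlap filters, not by the score thresholds).
#'
#' @param cfg a [simulation_config()].
#' @return list with `merged` (candidate [transcript_set()]), `reference`
#'   (biotyped reference set), `known` (known-lncRNA reference), and
#'   `truth` (per-candidate data.frame: true_class, cis partner/distance,
#'   known flag).
#' @export
generate_annotation <- function(cfg) {
  with_seed(cfg$seed, .generate_annotation_impl(cfg))
}

.generate_annotation_impl <- function(cfg) {
  tcons <- function(i) sprintf("TCONS_%05d", i)
  xloc <- function(i) sprintf("XLOC_%05d", i)
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))

  ## --- 1. coding genes, laid out sequentially with wide gaps ------------
  gene_rows <- list()
  gene_tab <- list()   # per-gene bookkeeping for later placement
  per_chrom <- .allocate(cfg$n_coding_genes, rep(1 / cfg$n_chroms, cfg$n_chroms))
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    cursor <- 10000
    for (g in seq_len(per_chrom[ci])) {
      gi <- gi + 1L
      n_ex <- sample(4:12, 1L)
      ex_len <- sample(120:300, n_ex, replace = TRUE)
      introns <- if (n_ex > 1L) sample(500:3000, n_ex - 1L, replace = TRUE) else integer(0)
      starts <- cursor + c(0, cumsum(ex_len[-n_ex] + introns))
      ends <- starts + ex_len
      strand <- sample(c("+", "-"), 1L)
      gid <- sprintf("GENE%04d", gi)
      if (max(ends) + 10000 > cfg$chrom_length)
        abort_input("chromosome %s too short for the requested features", chroms[ci])
      gene_rows[[gi]] <- data.frame(
        transcript_id = paste0(gid, "_T1"), gene_id = gid,
        chrom = chroms[ci], strand = strand, start = starts, end = ends,
        biotype = "protein_coding", stringsAsFactors = FALSE)
      gene_tab[[gi]] <- data.frame(
        gene_id = gid, chrom = chroms[ci], strand = strand,
        span_start = min(starts), span_end = max(ends),
        stringsAsFactors = FALSE)
      cursor <- max(ends) + sample(45000:75000, 1L)
    }
  }
  genes <- do.call(rbind, gene_tab)

  ## interior gaps between consecutive genes on a chromosome
  gaps <- do.call(rbind, lapply(split(genes, genes$chrom), function(g) {
    g <- g[order(g$span_start), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    data.frame(chrom = g$chrom[-nrow(g)],
               gap_start = g$span_end[-nrow(g)],
               gap_end = g$span_start[-1L],
               left_gene = g$gene_id[-nrow(g)],
               right_gene = g$gene_id[-1L],
               stringsAsFactors = FALSE)
  }))
  rownames(gaps) <- NULL
  n_gap_features <- cfg$n_linc + cfg$n_pseudogene + cfg$n_small_rna
  if (is.null(gaps) || nrow(gaps) < n_gap_features)
    abort_input("not enough intergenic gaps (%d) for %d requested features; increase n_coding_genes or n_chroms",
                if (is.null(gaps)) 0L else nrow(gaps), n_gap_features)
  gap_pick <- sample(nrow(gaps), n_gap_features)
  linc_gaps <- gap_pick[seq_len(cfg$n_linc)]
  pseudo_gaps <- gap_pick[cfg$n_linc + seq_len(cfg$n_pseudogene)]
  small_gaps <- gap_pick[cfg$n_linc + cfg$n_pseudogene + seq_len(cfg$n_small_rna)]

  ## --- 2. lincRNAs ------------------------------------------------------
  # multi-exon noncoding structure; mature length always > 200
  rna_structure <- function(n_ex_range = 2:4) {
    n_ex <- sample(n_ex_range, 1L)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    introns <- if (n_ex > 1L) sample(300:1500, n_ex - 1L, replace = TRUE) else integer(0)
    offsets <- c(0, cumsum(ex_len[-n_ex] + introns))
    list(starts = offsets, ends = offsets + ex_len,
         span = offsets[n_ex] + ex_len[n_ex])
  }
  n_cis <- round(cfg$cis_pair_fraction * cfg$n_linc)
  cand_rows <- list()
  truth_rows <- list()
  ti <- 0L
  add_candidate <- function(starts, ends, chrom, strand, true_class,
                            cis_partner = NA_character_,
                            cis_distance = NA_real_) {
    ti <<- ti + 1L
    id <- tcons(ti)
    cand_rows[[length(cand_rows) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = xloc(ti), chrom = chrom,
      strand = strand, start = starts, end = ends, biotype = "candidate",
      stringsAsFactors = FALSE)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      transcript_id = id, true_class = true_class,
      cis_partner = cis_partner, cis_distance = cis_distance,
      stringsAsFactors = FALSE)
    id
  }

  for (j in seq_len(cfg$n_linc)) {
    gp <- gaps[linc_gaps[j], ]
    st <- rna_structure()
    if (j <= n_cis) {
      # within the 10-kb window of one designated flanking gene
      d <- sample(200:8000, 1L)
      left <- sample(c(TRUE, FALSE), 1L)
      if (left) {
        s0 <- gp$gap_start + d
        partner <- gp$left_gene
      } else {
        s0 <- gp$gap_end - d - st$span
        partner <- gp$right_gene
      }
    } else {
      # beyond the window of both flanking genes
      lo <- gp$gap_start + 12000
      hi <- gp$gap_end - 12000 - st$span
      if (hi <= lo)
        abort_input("intergenic gap too small to place a non-cis lincRNA")
      s0 <- sample(seq(lo, hi), 1L)
      partner <- NA_character_
      d <- NA_real_
    }
    add_candidate(s0 + st$starts, s0 + st$ends, gp$chrom,
                  sample(c("+", "-"), 1L), "lincRNA",
                  partner, if (j <= n_cis) d else NA_real_)
  }

  ## --- 3. antisense lncRNAs --------------------------------------------
  if (cfg$n_antisense > nrow(genes))
    abort_input("more antisense lncRNAs than host genes")
  hosts <- sample(nrow(genes), cfg$n_antisense)
  for (h in hosts) {
    host <- genes[h, ]
    host_ex <- gene_rows[[h]]
    # first exon overlaps the host's first exon; second exon downstream
    e1s <- host_ex$start[1L] + sample(0:30, 1L)
    e1e <- e1s + sample(200:280, 1L)
    e2s <- e1e + sample(400:900, 1L)
    e2e <- e2s + sample(150:300, 1L)
    add_candidate(c(e1s, e2s), c(e1e, e2e), host$chrom,
                  if (host$strand == "+") "-" else "+", "antisense",
                  host$gene_id, 0)
  }

  ## --- 4. pseudogene / small-RNA reference loci and their decoys --------
  ref_extra <- list()
  place_in_gap <- function(gp, span) {
    lo <- gp$gap_start + 2000
    hi <- gp$gap_end - 2000 - span
    sample(seq(lo, hi), 1L)
  }
  for (j in seq_along(pseudo_gaps)) {
    gp <- gaps[pseudo_gaps[j], ]
    st <- rna_structure(2:3)
    s0 <- place_in_gap(gp, st$span)
    strand <- sample(c("+", "-"), 1L)
    pid <- sprintf("PSEUDO%03d", j)
    ref_extra[[length(ref_extra) + 1L]] <- data.frame(
      transcript_id = paste0(pid, "_T1"), gene_id = pid, chrom = gp$chrom,
      strand = strand, start = s0 + st$starts, end = s0 + st$ends,
      biotype = "pseudogene", stringsAsFactors = FALSE)
    # decoy candidate copying the locus: passes length/exon/score filters,
    # must be caught by the known-noncoding overlap exclusion
    add_candidate(s0 + st$starts, s0 + st$ends, gp$chrom, strand, "pseudogene")
  }
  for (j in seq_along(small_gaps)) {
    gp <- gaps[small_gaps[j], ]
    len <- sample(80:150, 1L)
    s0 <- place_in_gap(gp, len)
    strand <- sample(c("+", "-"), 1L)
    sid <- sprintf("SRNA%03d", j)
    ref_extra[[length(ref_extra) + 1L]] <- data.frame(
      transcript_id = paste0(sid, "_T1"), gene_id = sid, chrom = gp$chrom,
      strand = strand, start = s0, end = s0 + len,
      biotype = "small_rna", stringsAsFactors = FALSE)
    add_candidate(s0, s0 + len, gp$chrom, strand, "small_rna")
  }

  ## --- 5. mRNA candidates: merged-set copies of the coding genes --------
  for (h in seq_len(nrow(genes))) {
    host_ex <- gene_rows[[h]]
    add_candidate(host_ex$start, host_ex$end, host_ex$chrom[1L],
                  host_ex$strand[1L], "mRNA", genes$gene_id[h], 0)
  }

  merged <- transcript_set(do.call(rbind, cand_rows))
  reference <- transcript_set(do.call(rbind, c(gene_rows, ref_extra)))
  truth <- do.call(rbind, truth_rows)

  ## --- 6. known-lncRNA reference: a fraction of the planted lncRNAs -----
  lnc_ids <- truth$transcript_id[truth$true_class %in% c("lincRNA", "antisense")]
  n_known <- round(cfg$known_fraction * length(lnc_ids))
  known_ids <- if (n_known > 0L) sort(sample(lnc_ids, n_known)) else character(0)
  truth$known_lncrna <- truth$transcript_id %in% known_ids
  known_ex <- merged$exons[merged$exons$transcript_id %in% known_ids, , drop = FALSE]
  if (nrow(known_ex) > 0L) {
    ix <- match(known_ex$transcript_id, known_ids)
    known_ex$transcript_id <- sprintf("ALDB%04d", ix)
    known_ex$gene_id <- sprintf("ALDBG%04d", ix)
    known_ex$biotype <- "known_lncRNA"
  }
  known <- transcript_set(known_ex)

  rownames(truth) <- NULL
  list(merged = merged, reference = reference, known = known, truth = truth)
}

#' Generate the synthetic FPKM matrix with planted temporal signal
#'
#' Assigns a `de_fraction` of mRNA and of lncRNA candidates one of the four
#' temporal archetypes (per `archetype_mix`): stage-mean log2 profiles are
#' the baseline plus `de_log2fc`-scaled archetype steps (K1 monotone
#' decreasing, K2 late-rising, K3 rising from the first transition, K4
#' peaked at A1); all other features are flat. Planted trans pairs share
#' the lncRNA's stage-mean profile up to a positive scale (positive pairs)
#' or mirror it linearly (negative pairs), so the noise-free sample-level
#' Pearson correlation is exactly +1 / -1. Replicates receive multiplicative
#' lognormal noise with sdlog `noise_sd`.
#'
#' @param merged candidate [transcript_set()] from [generate_annotation()].
#' @param truth truth table from [generate_annotation()].
#' @param cfg the same [simulation_config()].
#' @return list with `expr` (an [expression_matrix()]), `truth` (augmented
#'   with `archetype`, per-comparison `de_*` flags computed from the
#'   noise-free stage means), and `trans_pairs` (lnc_id, gene_id, sign).
#' @export
generate_expression <- function(merged, truth, cfg) {
  with_seed(cfg$seed + 1L, .generate_expression_impl(merged, truth, cfg))
}

.generate_expression_impl <- function(merged, truth, cfg) {
  ids <- truth$transcript_id
  n <- length(ids)
  st <- cfg$stages
  baseline <- stats::runif(n, 3, 6)

  is_mrna <- truth$true_class == "mRNA"
  is_lnc <- truth$true_class %in% c("lincRNA", "antisense")
  pick_de <- function(mask) {
    k <- round(cfg$de_fraction * sum(mask))
    if (k == 0L) return(character(0))
    sample(ids[mask], k)
  }
  de_ids <- c(pick_de(is_mrna), pick_de(is_lnc))
  archetype <- rep("none", n)
  if (length(de_ids) > 0L) {
    counts <- .allocate(length(de_ids), cfg$archetype_mix)
    labels <- sample(rep(names(cfg$archetype_mix), counts))
    archetype[match(de_ids, ids)] <- labels
  }

  log2_means <- matrix(baseline, n, length(st),
                       dimnames = list(ids, st))
  for (k in names(.archetype_steps)) {
    rows <- archetype == k
    if (any(rows))
      log2_means[rows, ] <- log2_means[rows, , drop = FALSE] +
        rep(cfg$de_log2fc * .archetype_steps[[k]], each = sum(rows))
  }
  means <- 2^log2_means

  ## planted trans pairs: shared / mirrored stage-mean profiles
  trans_pairs <- data.frame(lnc_id = character(), gene_id = character(),
                            sign = character(), stringsAsFactors = FALSE)
  if (cfg$trans_pair_count > 0L) {
    de_lnc <- ids[is_lnc & archetype != "none"]
    free_mrna <- ids[is_mrna & archetype == "none"]
    if (length(de_lnc) < cfg$trans_pair_count ||
        length(free_mrna) < cfg$trans_pair_count)
      abort_input("trans_pair_count (%d) exceeds available DE lncRNAs (%d) or non-DE mRNAs (%d)",
                  cfg$trans_pair_count, length(de_lnc), length(free_mrna))
    pl <- sample(de_lnc, cfg$trans_pair_count)
    pg <- sample(free_mrna, cfg$trans_pair_count)
    pos <- stats::runif(cfg$trans_pair_count) < cfg$prop_positive_trans
    for (q in seq_len(cfg$trans_pair_count)) {
      x <- means[pl[q], ]
      means[pg[q], ] <- if (pos[q]) {
        2^(baseline[match(pg[q], ids)] - baseline[match(pl[q], ids)]) * x
      } else {
        (max(x) + min(x)) - x
      }
    }
    trans_pairs <- data.frame(lnc_id = pl, gene_id = pg,
                              sign = ifelse(pos, "positive", "negative"),
                              stringsAsFactors = FALSE)
  }

  ## replicate-level values with multiplicative lognormal noise
  samples <- as.vector(t(outer(st, seq_len(cfg$n_replicates),
                               function(s, r) paste0(s, "_R", r))))
  design <- data.frame(
    sample = samples,
    stage = rep(st, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(st)),
    stringsAsFactors = FALSE)
  mean_expanded <- means[, design$stage, drop = FALSE]
  colnames(mean_expanded) <- design$sample
  noise <- matrix(stats::rlnorm(n * nrow(design), 0, cfg$noise_sd),
                  n, nrow(design))
  expr <- expression_matrix(mean_expanded * noise, design)

  ## ground-truth DE flags from the noise-free means (pseudocount 1)
  truth$archetype <- archetype
  comparisons <- list(c("A1", "A0"), c("A3", "A1"), c("A5", "A3"),
                      c("A5", "A0"))
  for (cmp in comparisons) {
    lfc <- log2(means[, cmp[1L]] + 1) - log2(means[, cmp[2L]] + 1)
    truth[[sprintf("de_%s_vs_%s", cmp[1L], cmp[2L])]] <- abs(lfc) > 1
    truth[[sprintf("log2fc_%s_vs_%s", cmp[1L], cmp[2L])]] <- unname(lfc)
  }
  list(expr = expr, truth = truth, trans_pairs = trans_pairs)
}

#' Generate coding-potential scores consistent with the planted classes
#'
#' Noncoding candidates (lincRNA, antisense, and the pseudogene/small-RNA
#' decoys, which must be excluded by overlap rather than by score) receive
#' all four scores on the retained (noncoding) side of the supplied
#' thresholds; mRNA candidates receive all four on the rejected (coding)
#' side. Margins are drawn with seeded noise so no score sits on a cutoff.
#'
#' @param truth truth table from [generate_annotation()].
#' @param cfg a [simulation_config()].
#' @param thresholds the [filter_thresholds()] the scores should respect.
#' @return data.frame: transcript_id, cnci, cpc, pfam_evalue, phylocsf.
#' @export
generate_scores <- function(truth, cfg, thresholds = filter_thresholds()) {
  with_seed(cfg$seed + 2L, {
    n <- nrow(truth)
    noncoding <- truth$true_class != "mRNA"
    draw <- function(spec, retained, margin) {
      above <- (spec$retain == "greater") == retained
      ifelse(above, spec$cutoff + margin, spec$cutoff - margin)
    }
    sc <- thresholds$scores
    data.frame(
      transcript_id = truth$transcript_id,
      cnci = draw(sc$cnci, noncoding, stats::runif(n, 0.2, 3)),
      cpc = draw(sc$cpc, noncoding, stats::runif(n, 0.2, 3)),
      pfam_evalue = ifelse(
        noncoding == (sc$pfam_evalue$retain == "greater"),
        sc$pfam_evalue$cutoff * stats::runif(n, 5, 1000),
        sc$pfam_evalue$cutoff * stats::runif(n, 1e-6, 0.5)),
      phylocsf = draw(sc$phylocsf, noncoding, stats::runif(n, 2, 60)),
      stringsAsFactors = FALSE)
  })
}

#' Generate a gene-set (GMT-style) annotation with planted signatures
#'
#' Builds one "signature" term per temporal archetype (drawing most of its
#' members from that archetype's mRNAs, the rest at random) plus a number
#' of fully random terms, over the universe of mRNA candidate ids.
#'
#' @param truth augmented truth table from [generate_expression()].
#' @param cfg a [simulation_config()].
#' @param n_random_terms number of random terms (default 10).
#' @param signature_purity fraction of a signature term drawn from its
#'   archetype (default 0.8).
#' @return list with `gene_sets`, `descriptions`, and `universe`.
#' @export
generate_gene_sets <- function(truth, cfg, n_random_terms = 10,
                               signature_purity = 0.8) {
  if (!"archetype" %in% names(truth))
    abort_input("truth lacks archetypes; run generate_expression first")
  with_seed(cfg$seed + 3L, {
    universe <- truth$transcript_id[truth$true_class == "mRNA"]
    gene_sets <- list()
    descriptions <- character(0)
    for (k in c("K1", "K2", "K3", "K4")) {
      members <- truth$transcript_id[truth$true_class == "mRNA" &
                                       truth$archetype == k]
      if (length(members) == 0L) next
      n_in <- max(1L, round(signature_purity * length(members)))
      n_out <- max(1L, ceiling(n_in * (1 - signature_purity) /
                                 signature_purity))
      term <- unique(c(sample(members, n_in),
                       sample(setdiff(universe, members),
                              min(n_out, length(universe) - length(members)))))
      gene_sets[[paste0("SIG_", k)]] <- term
      descriptions[paste0("SIG_", k)] <-
        sprintf("signature of the %s temporal archetype", k)
    }
    for (j in seq_len(n_random_terms)) {
      sz <- sample(5:min(40, length(universe)), 1L)
      gene_sets[[sprintf("RND_%03d", j)]] <- sample(universe, sz)
      descriptions[sprintf("RND_%03d", j)] <- sprintf("random term %d", j)
    }
    list(gene_sets = gene_sets, descriptions = descriptions,
         universe = universe)
  })
}

#' Generate a qPCR cycle-threshold table for selected features
#'
#' Emulates validation qPCR: per stage, the target Ct decreases by one
#' cycle per doubling of the underlying noise-free expression
#' (Ct = intercept - log2(FPKM + 1) plus Gaussian cycle noise); two
#' reference genes have stage-independent Ct. The 2^-ddCt relative
#' expression computed from this table therefore tracks the RNA-seq stage
#' profile.
#'
#' @param truth augmented truth table from [generate_expression()].
#' @param cfg a [simulation_config()].
#' @param target_ids features to assay; default picks up to 4 DE features.
#' @param ct_noise_sd Gaussian Ct noise in cycles (default 0.05).
#' @return list with `ct_table` (sample, gene, ct, role) using stages as
#'   samples, and `calibrator` (= the first stage).
#' @export
generate_qpcr <- function(truth, cfg, target_ids = NULL, ct_noise_sd = 0.05) {
  if (!"archetype" %in% names(truth))
    abort_input("truth lacks archetypes; run generate_expression first")
  with_seed(cfg$seed + 4L, {
    st <- cfg$stages
    if (is.null(target_ids)) {
      de <- truth$transcript_id[truth$archetype != "none"]
      if (length(de) == 0L) abort_input("no DE features to assay")
      target_ids <- sample(de, min(4L, length(de)))
    }
    lfc_cols <- grep("^log2fc_", names(truth), value = TRUE)
    rows <- list()
    for (g in target_ids) {
      r <- match(g, truth$transcript_id)
      if (is.na(r)) abort_input("unknown target id '%s'", g)
      # rebuild the noise-free log2 stage profile from the truth log2fcs
      prof <- c(0, truth[[lfc_cols[1L]]][r],
                truth[[lfc_cols[1L]]][r] + truth[[lfc_cols[2L]]][r],
                truth[[lfc_cols[4L]]][r])
      rows[[g]] <- data.frame(
        sample = st, gene = g,
        ct = 28 - prof + stats::rnorm(length(st), 0, ct_noise_sd),
        role = "target", stringsAsFactors = FALSE)
    }
    refs <- rbind(
      data.frame(sample = st, gene = "REF1",
                 ct = 19 + stats::rnorm(length(st), 0, ct_noise_sd),
                 role = "reference", stringsAsFactors = FALSE),
      data.frame(sample = st, gene = "REF2",
                 ct = 23 + stats::rnorm(length(st), 0, ct_noise_sd),
                 role = "reference", stringsAsFactors = FALSE))
    list(ct_table = rbind(do.call(rbind, rows), refs),
         calibrator = st[1L])
  })
}

#' Generate a genome sequence with planted open reading frames
#'
#' Draws uniform random nucleotides for every chromosome, then writes a
#' long ATG...stop open reading frame across most of each coding
#' transcript's spliced sequence (respecting exon structure and strand).
#' Random sequence hits a stop codon every ~21 codons in expectation, so
#' lncRNA ORFs stay short while mRNA ORFs approach the mature length —
#' reproducing the ORF-length contrast between the two classes.
#'
#' @param annotation result of [generate_annotation()].
#' @param cfg a [simulation_config()].
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
generate_genome <- function(annotation, cfg) {
  with_seed(cfg$seed + 5L, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
    genome <- vapply(chroms, function(cn) {
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1L))

    stops <- c("TAA", "TAG", "TGA")
    all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                    c("A", "C", "G", "T")), 1L, paste,
                        collapse = "")
    safe_codons <- setdiff(all_codons, stops)

    coding <- subset_transcripts(annotation$reference,
                                 biotype = "protein_coding")
    for (tx in transcript_ids(coding)) {
      e <- coding$exons[coding$exons$transcript_id == tx, , drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      L <- sum(e$end - e$start)
      n_codons <- (L - 6L) %/% 3L          # leave a 3-nt UTR either side
      if (n_codons < 3L) next
      orf <- paste0("ATG",
                    paste(sample(safe_codons, n_codons - 2L, replace = TRUE),
                          collapse = ""),
                    "TAA")
      pad_3p <- L - 3L - nchar(orf)
      mature <- paste0(
        paste(sample(c("A", "C", "G"), 3L, replace = TRUE), collapse = ""),
        orf,
        paste(sample(c("A", "C", "G"), pad_3p, replace = TRUE), collapse = ""))
      genomic <- if (e$strand[1L] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(mature)))
      } else {
        mature
      }
      offset <- 0L
      cn <- e$chrom[1L]
      for (i in seq_len(nrow(e))) {
        w <- e$end[i] - e$start[i]
        piece <- substr(genomic, offset + 1L, offset + w)
        substr(genome[[cn]], e$start[i] + 1L, e$end[i]) <- piece
        offset <- offset + w
      }
    }
    Biostrings::DNAStringSet(genome)
  })
}

#' Generate a complete synthetic dataset, optionally written to disk
#'
#' Runs every generator under one configuration and (when `dir` is given)
#' writes the standard input files: `merged.gtf`, `reference.gtf`,
#' `known_lncrna.gtf`, `expression.tsv` + `design.tsv`, `scores.tsv`,
#' `gene_sets.gmt`, `qpcr_ct.tsv`, `truth.tsv`, and `genome.fa` when the
#' genome is requested. With a fixed configuration the outputs are
#' byte-identical between runs.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory (created if missing).
#' @param include_genome also generate the genome FASTA (default FALSE).
#' @return list with `config`, `merged`, `reference`, `known`, `truth`,
#'   `expr`, `trans_pairs`, `scores`, `gene_sets`, `qpcr`, and optionally
#'   `genome`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = NULL,
                             include_genome = FALSE) {
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann$merged, ann$truth, cfg)
  scores <- generate_scores(ex$truth, cfg)
  gs <- generate_gene_sets(ex$truth, cfg)
  qp <- if (any(ex$truth$archetype != "none")) generate_qpcr(ex$truth, cfg)
  out <- list(config = cfg, merged = ann$merged, reference = ann$reference,
              known = ann$known, truth = ex$truth, expr = ex$expr,
              trans_pairs = ex$trans_pairs, scores = scores,
              gene_sets = gs, qpcr = qp)
  if (include_genome) out$genome <- generate_genome(ann, cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_gtf(out$merged, file.path(dir, "merged.gtf"))
    write_gtf(out$reference, file.path(dir, "reference.gtf"))
    write_gtf(out$known, file.path(dir, "known_lncrna.gtf"))
    write_expression(out$expr, file.path(dir, "expression.tsv"),
                     file.path(dir, "design.tsv"))
    utils::write.table(out$scores, file.path(dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(out$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gmt(out$gene_sets$gene_sets, file.path(dir, "gene_sets.gmt"),
              out$gene_sets$descriptions)
    if (!is.null(out$qpcr))
      utils::write.table(out$qpcr$ct_table, file.path(dir, "qpcr_ct.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (include_genome)
      Biostrings::writeXStringSet(out$genome, file.path(dir, "genome.fa"))
  }
  out
}
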