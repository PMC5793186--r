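test_that("the generator is byte-deterministic given a configuration", {
  cfg <- small_config(seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(write_gtf(d1$merged), write_gtf(d2$merged))
  expect_identical(write_gtf(d1$reference), write_gtf(d2$reference))
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$scores, d2$scores)
  expect_identical(d1$truth, d2$truth)
  d3 <- simulate_dataset(small_config(seed = 6))
  expect_false(identical(write_gtf(d1$merged), write_gtf(d3$merged)))
})

test_that("planted lncRNA geometry matches its truth labels (brute-force oracle)", {
  cfg <- small_config(seed = 7)
  ann <- generate_annotation(cfg)
  coding <- subset_transcripts(ann$reference, biotype = "protein_coding")
  lnc_ids <- ann$truth$transcript_id[ann$truth$true_class %in%
                                       c("lincRNA", "antisense")]
  expect_length(lnc_ids, cfg$n_linc + cfg$n_antisense)
  lnc <- subset_transcripts(ann$merged, ids = lnc_ids)

  span_hits <- oracle_span_overlap_ids(lnc, coding)
  ex_pairs <- oracle_exonic_overlap(lnc, coding)
  anti_oracle <- sort(unique(ex_pairs$a[!ex_pairs$same_strand]))
  linc_oracle <- sort(setdiff(lnc_ids, span_hits))
  truth_anti <- sort(ann$truth$transcript_id[ann$truth$true_class == "antisense"])
  truth_linc <- sort(ann$truth$transcript_id[ann$truth$true_class == "lincRNA"])
  expect_identical(anti_oracle, truth_anti)
  expect_identical(linc_oracle, truth_linc)
  # lincRNAs never touch coding exons on either strand
  expect_false(any(ex_pairs$a %in% truth_linc))
})

test_that("cis placement respects the 10-kb window on both sides", {
  cfg <- small_config(seed = 8)
  ann <- generate_annotation(cfg)
  coding <- subset_transcripts(ann$reference, biotype = "protein_coding")
  tr <- ann$truth
  lincs <- tr[tr$true_class == "lincRNA", ]
  expect_equal(sum(!is.na(lincs$cis_partner)),
               round(cfg$cis_pair_fraction * cfg$n_linc))
  pairs <- oracle_cis_pairs(
    subset_transcripts(ann$merged, ids = lincs$transcript_id),
    coding, cfg$cis_window_bp)
  cis_truth <- lincs[!is.na(lincs$cis_partner), ]
  # every designated partner appears at its recorded distance
  for (i in seq_len(nrow(cis_truth))) {
    hit <- pairs[pairs$lnc_id == cis_truth$transcript_id[i] &
                   pairs$gene_id == cis_truth$cis_partner[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$distance, cis_truth$cis_distance[i])
  }
  # non-cis lincRNAs are beyond the window of every coding gene
  noncis <- lincs$transcript_id[is.na(lincs$cis_partner)]
  expect_false(any(pairs$lnc_id %in% noncis))
})

test_that("empty lncRNA requests produce no planted lncRNAs", {
  cfg <- simulation_config(seed = 1, n_chroms = 2, chrom_length = 1.6e6,
                           n_coding_genes = 30, n_linc = 0, n_antisense = 0,
                           n_pseudogene = 2, n_small_rna = 2,
                           trans_pair_count = 0)
  ann <- generate_annotation(cfg)
  expect_equal(sum(ann$truth$true_class %in% c("lincRNA", "antisense")), 0L)
  expect_equal(length(ann$known), 0L)
})

test_that("a chromosome too short for the requested features raises an error", {
  cfg <- simulation_config(seed = 1, n_chroms = 1, chrom_length = 5e4,
                           n_coding_genes = 10, n_linc = 2, n_antisense = 1,
                           n_pseudogene = 0, n_small_rna = 0,
                           trans_pair_count = 0)
  expect_error(generate_annotation(cfg), "too short")
})

test_that("noise-free expression carries the planted signal exactly", {
  cfg <- small_config(seed = 9, noise_sd = 0)
  d <- simulate_dataset(cfg)
  # replicates are identical without noise
  pm <- stage_mean_profiles(d$expr)
  expect_identical(d$expr$values[, "A0_R1"], d$expr$values[, "A0_R3"])

  # a K4 feature rises by de_log2fc * 3 between A0 and A1 (before the
  # pseudocount), then falls
  k4 <- d$truth$transcript_id[d$truth$archetype == "K4"][1]
  expect_false(is.na(k4))
  expect_equal(log2(pm[k4, "A1"]) - log2(pm[k4, "A0"]), 3 * cfg$de_log2fc)
  expect_equal(which.max(pm[k4, ]), c(A1 = 2L))

  # K1 decreases monotonically; K2 rises later than K3
  k1 <- d$truth$transcript_id[d$truth$archetype == "K1"][1]
  expect_true(all(diff(pm[k1, ]) < 0))

  # planted trans pairs are exactly +/-1 correlated across the 12 samples
  for (i in seq_len(nrow(d$trans_pairs))) {
    r <- cor(d$expr$values[d$trans_pairs$lnc_id[i], ],
             d$expr$values[d$trans_pairs$gene_id[i], ])
    expect_equal(r, if (d$trans_pairs$sign[i] == "positive") 1 else -1)
  }

  # non-DE features are flat
  flat <- d$truth$transcript_id[d$truth$archetype == "none" &
                                  !d$truth$transcript_id %in%
                                    d$trans_pairs$gene_id][1]
  expect_equal(diff(range(pm[flat, ])), 0)
})

test_that("planted scores sit strictly on the intended side of each threshold", {
  cfg <- small_config(seed = 10)
  d <- simulate_dataset(cfg)
  th <- filter_thresholds()
  noncoding <- d$truth$true_class != "mRNA"
  sc <- d$scores[match(d$truth$transcript_id, d$scores$transcript_id), ]
  expect_true(all(sc$cnci[noncoding] < th$scores$cnci$cutoff))
  expect_true(all(sc$cpc[noncoding] < th$scores$cpc$cutoff))
  expect_true(all(sc$pfam_evalue[noncoding] > th$scores$pfam_evalue$cutoff))
  expect_true(all(sc$phylocsf[noncoding] < th$scores$phylocsf$cutoff))
  # coding transcripts fail every score filter (coding side throughout)
  expect_true(all(sc$cnci[!noncoding] > th$scores$cnci$cutoff))
  expect_true(all(sc$pfam_evalue[!noncoding] < th$scores$pfam_evalue$cutoff))

  # scores generated for the as-printed preset respect that preset instead
  thp <- filter_thresholds(as_printed = TRUE)
  scp <- generate_scores(d$truth, cfg, thp)
  expect_true(all(scp$cnci[noncoding] > 0))
  expect_true(all(scp$phylocsf[noncoding] > -20))
})

test_that("file output is complete and byte-stable", {
  cfg <- small_config(seed = 12)
  dir1 <- file.path(tempdir(), "sim1"); dir2 <- file.path(tempdir(), "sim2")
  simulate_dataset(cfg, dir = dir1)
  simulate_dataset(cfg, dir = dir2)
  files <- c("merged.gtf", "reference.gtf", "known_lncrna.gtf",
             "expression.tsv", "design.tsv", "scores.tsv", "truth.tsv",
             "gene_sets.gmt", "qpcr_ct.tsv")
  for (f in files) {
    expect_true(file.exists(file.path(dir1, f)))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
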