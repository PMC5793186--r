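# A tiny hand-built scenario exercising each cascade filter:
#  - coding gene GENE1 (+) at 1000-2950 on chr1 (two exons)
#  - t_anti: 2 exons, first overlapping GENE1 exon 1 on the minus strand
#  - t_linc: intergenic 2-exon transcript far from everything
#  - t_short: mature length exactly 200 (boundary, must fail)
#  - t_mono: single-exon 5000 bp (must fail the exon filter)
#  - t_low: like t_linc but below the FPKM cutoff
#  - t_sense: same-strand copy of GENE1 exon structure (coding overlap)
#  - t_pseudo: copies the PSEU1 pseudogene locus
cascade_fixture <- function() {
  ref <- make_ts(
    tx_rows("GENE1_T1", "chr1", "+", c(1000, 2500), c(1600, 2950),
            gene = "GENE1", biotype = "protein_coding"),
    tx_rows("PSEU1_T1", "chr1", "+", c(40000, 40600), c(40400, 40900),
            gene = "PSEU1", biotype = "pseudogene"))
  cand <- make_ts(
    tx_rows("t_anti", "chr1", "-", c(1200, 2000), c(1500, 2200)),
    tx_rows("t_linc", "chr1", "+", c(90000, 91000), c(90400, 91400)),
    tx_rows("t_short", "chr1", "+", c(60000, 60500), c(60100, 60600)),
    tx_rows("t_mono", "chr1", "+", 70000, 75000),
    tx_rows("t_low", "chr1", "-", c(80000, 81000), c(80400, 81400)),
    tx_rows("t_sense", "chr1", "+", c(1000, 2500), c(1600, 2950)),
    tx_rows("t_pseudo", "chr1", "+", c(40000, 40600), c(40400, 40900)))
  ids <- transcript_ids(cand)
  v <- matrix(10, length(ids), 12)
  rownames(v) <- ids
  v["t_low", ] <- 0.2
  expr <- make_expr(v, ids)
  scores <- data.frame(transcript_id = ids, cnci = -1, cpc = -1,
                       pfam_evalue = 0.5, phylocsf = -40)
  scores[scores$transcript_id == "t_sense",
         c("cnci", "cpc", "phylocsf")] <- c(2, 2, 50)
  scores$pfam_evalue[scores$transcript_id == "t_sense"] <- 1e-8
  list(ref = ref, cand = cand, expr = expr, scores = scores)
}

test_that("each cascade filter rejects its designated candidate", {
  fx <- cascade_fixture()
  rec <- apply_filter_cascade(fx$cand, fx$expr, fx$scores, fx$ref)
  g <- function(id) rec[rec$transcript_id == id, ]
  expect_false(g("t_short")$pass_length)       # exactly 200 bp: strict >
  expect_true(g("t_linc")$pass_length)
  expect_false(g("t_mono")$pass_exons)         # 5000 bp but single exon
  expect_true(g("t_mono")$pass_length)
  expect_false(g("t_low")$pass_expression)
  expect_false(g("t_sense")$pass_coding_overlap)
  expect_true(g("t_anti")$pass_coding_overlap) # antisense survives
  expect_false(g("t_pseudo")$pass_noncoding_overlap)
  expect_false(any(rec[rec$transcript_id == "t_sense",
                       c("pass_cnci", "pass_cpc", "pass_pfam",
                         "pass_phylocsf")] == TRUE))
  expect_setequal(rec$transcript_id[rec$final_call], c("t_anti", "t_linc"))
  # audit is complete even for failing transcripts
  expect_false(anyNA(as.matrix(rec[grep("^pass_", names(rec))])))
})

test_that("the FPKM rule distinguishes any-sample from all-samples", {
  fx <- cascade_fixture()
  v <- fx$expr$values
  v["t_linc", ] <- c(0.6, rep(0.1, 11))        # one sample above 0.5
  expr <- expression_matrix(v, fx$expr$design)
  any_rule <- apply_filter_cascade(fx$cand, expr, fx$scores, fx$ref,
                                   filter_thresholds(fpkm_rule = "any_sample"))
  all_rule <- apply_filter_cascade(fx$cand, expr, fx$scores, fx$ref,
                                   filter_thresholds(fpkm_rule = "all_samples"))
  expect_true(any_rule$pass_expression[any_rule$transcript_id == "t_linc"])
  expect_false(all_rule$pass_expression[all_rule$transcript_id == "t_linc"])
})

test_that("missing inputs are handled per contract", {
  fx <- cascade_fixture()
  short_expr <- expression_matrix(
    fx$expr$values[-1, , drop = FALSE], fx$expr$design)
  expect_error(apply_filter_cascade(fx$cand, short_expr, fx$scores, fx$ref),
               "without an expression row")
  sc <- fx$scores[fx$scores$transcript_id != "t_linc", ]
  rec_fail <- apply_filter_cascade(fx$cand, fx$expr, sc, fx$ref)
  expect_false(rec_fail$final_call[rec_fail$transcript_id == "t_linc"])
  rec_pass <- apply_filter_cascade(fx$cand, fx$expr, sc, fx$ref,
                                   filter_thresholds(missing_scores = "pass"))
  expect_true(rec_pass$final_call[rec_pass$transcript_id == "t_linc"])
})

test_that("the as-printed preset flips the retained sides", {
  fx <- cascade_fixture()
  # scores as the literal text reads them: positive CNCI/CPC retained
  sc <- fx$scores
  noncoding <- sc$transcript_id != "t_sense"
  sc[noncoding, c("cnci", "cpc")] <- 1
  sc$phylocsf[noncoding] <- -10
  rec <- apply_filter_cascade(fx$cand, fx$expr, sc, fx$ref,
                              filter_thresholds(as_printed = TRUE))
  expect_setequal(rec$transcript_id[rec$final_call], c("t_anti", "t_linc"))
})

test_that("classification is definitional for antisense and lincRNA", {
  fx <- cascade_fixture()
  rec <- apply_filter_cascade(fx$cand, fx$expr, fx$scores, fx$ref)
  rec <- classify_lncrna(rec, fx$cand, fx$ref)
  expect_equal(rec$class[rec$transcript_id == "t_anti"], "antisense")
  expect_equal(rec$class[rec$transcript_id == "t_linc"], "lincRNA")
  expect_equal(rec$class[rec$transcript_id == "t_sense"], "none")
})

test_that("novelty calling respects the overlap fraction", {
  fx <- cascade_fixture()
  rec <- apply_filter_cascade(fx$cand, fx$expr, fx$scores, fx$ref)
  # identical coordinates: annotated at the default fraction
  known_same <- make_ts(tx_rows("K1", "chr1", "+", c(90000, 91000),
                                c(90400, 91400), biotype = "known_lncRNA"))
  r <- match_known(rec, fx$cand, known_same)
  expect_equal(r$novelty[r$transcript_id == "t_linc"], "annotated")
  # reference on a different chromosome: novel at any threshold
  known_far <- make_ts(tx_rows("K2", "chr9", "+", c(90000, 91000),
                               c(90400, 91400), biotype = "known_lncRNA"))
  r <- match_known(rec, fx$cand, known_far, min_overlap_fraction = 0)
  expect_equal(r$novelty[r$transcript_id == "t_linc"], "novel")
  # half-overlapping known transcript: verdict depends on the fraction
  known_half <- make_ts(tx_rows("K3", "chr1", "+", 90000, 90400,
                                biotype = "known_lncRNA"))
  r0 <- match_known(rec, fx$cand, known_half, min_overlap_fraction = 0)
  r1 <- match_known(rec, fx$cand, known_half, min_overlap_fraction = 1)
  expect_equal(r0$novelty[r0$transcript_id == "t_linc"], "annotated")
  expect_equal(r1$novelty[r1$transcript_id == "t_linc"], "novel")
})

test_that("tightening any single threshold never enlarges the called set", {
  d <- simulate_dataset(small_config(seed = 21))
  base <- filter_thresholds()
  called <- function(th) {
    r <- apply_filter_cascade(d$merged, d$expr, d$scores, d$reference, th)
    r$transcript_id[r$final_call]
  }
  base_set <- called(base)
  tighter <- list(
    filter_thresholds(min_length_bp = 400),
    filter_thresholds(min_exons = 3),
    filter_thresholds(min_fpkm = 5, fpkm_rule = "all_samples"),
    filter_thresholds(cnci_cutoff = -1),
    filter_thresholds(cpc_cutoff = -1),
    filter_thresholds(pfam_evalue_cutoff = 0.1),
    filter_thresholds(phylocsf_cutoff = -40))
  for (th in tighter) {
    expect_true(all(called(th) %in% base_set))
  }
})

test_that("classification matches the brute-force oracle on a generated instance", {
  d <- simulate_dataset(small_config(seed = 22))
  rec <- apply_filter_cascade(d$merged, d$expr, d$scores, d$reference)
  rec <- classify_lncrna(rec, d$merged, d$reference)
  called <- rec$transcript_id[rec$final_call]
  coding <- subset_transcripts(d$reference, biotype = "protein_coding")
  sub <- subset_transcripts(d$merged, ids = called)
  pairs <- oracle_exonic_overlap(sub, coding)
  anti_oracle <- unique(pairs$a[!pairs$same_strand])
  span_oracle <- oracle_span_overlap_ids(sub, coding)
  for (id in called) {
    expected <- if (id %in% anti_oracle) "antisense"
      else if (!id %in% span_oracle) "lincRNA" else NA_character_
    expect_equal(rec$class[rec$transcript_id == id], expected)
  }
  # partition: every call classified, counts add up
  expect_true(all(rec$class[rec$final_call] %in% c("lincRNA", "antisense")))
  expect_equal(sum(rec$class == "lincRNA", na.rm = TRUE) +
                 sum(rec$class == "antisense", na.rm = TRUE),
               length(called))
})
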