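test_that("cis pairing follows the inclusive 10-kb span-distance rule", {
  lnc <- make_ts(tx_rows("l1", "chr1", "+", 10000, 12000))
  gene_at <- function(s, e, strand = "+")
    make_ts(tx_rows("g_T1", "chr1", strand, s, e, gene = "g",
                    biotype = "protein_coding"))
  # 8000-bp gap: paired
  p <- predict_cis_targets(lnc, gene_at(20000, 25000))
  expect_equal(nrow(p), 1L)
  expect_equal(p$distance, 8000)
  expect_equal(p$position, "upstream")       # lnc 5' of a + gene
  # boundary: exactly 10,000 intervening bases is in; 10,001 is out
  expect_equal(nrow(predict_cis_targets(lnc, gene_at(22000, 25000))), 1L)
  expect_equal(nrow(predict_cis_targets(lnc, gene_at(22001, 25000))), 0L)
  # overlap: distance 0
  p0 <- predict_cis_targets(lnc, gene_at(11000, 11500))
  expect_equal(p0$distance, 0)
  expect_equal(p0$position, "overlapping")
  # orientation flips with the gene's strand
  expect_equal(predict_cis_targets(lnc, gene_at(20000, 25000, "-"))$position,
               "downstream")
  expect_equal(predict_cis_targets(lnc, gene_at(1000, 2000, "-"))$position,
               "upstream")
  # other chromosome: never paired
  far <- make_ts(tx_rows("g2_T1", "chr2", "+", 10000, 12000, gene = "g2",
                         biotype = "protein_coding"))
  expect_equal(nrow(predict_cis_targets(lnc, far)), 0L)
})

test_that("cis pairs equal the all-pairs distance oracle on a random fixture", {
  set.seed(31)
  rand_ts <- function(n, prefix, biotype = "candidate") {
    rows <- lapply(seq_len(n), function(i) {
      s <- sample(1:400000, 1)
      tx_rows(sprintf("%s%03d", prefix, i), sample(c("chr1", "chr2"), 1),
              sample(c("+", "-"), 1), s, s + sample(200:4000, 1),
              gene = sprintf("%sg%03d", prefix, i), biotype = biotype)
    })
    transcript_set(do.call(rbind, rows))
  }
  lnc <- rand_ts(80, "L")
  coding <- rand_ts(120, "C", biotype = "protein_coding")
  got <- predict_cis_targets(lnc, coding, window_bp = 10000)
  want <- oracle_cis_pairs(lnc, coding, 10000)
  key <- function(d) sort(paste(d$lnc_id, d$gene_id, d$distance))
  expect_identical(key(got), key(want))
  # symmetry of the window logic: swapping roles preserves the pair set
  # (ids map transcript <-> gene: L001 <-> Lg001, C001 <-> Cg001)
  rev <- predict_cis_targets(coding, lnc, window_bp = 10000)
  expect_identical(sort(paste(sub("^Cg", "C", got$gene_id), got$lnc_id)),
                   sort(paste(rev$lnc_id, sub("^Lg", "L", rev$gene_id))))
})

test_that("pearson_r matches closed-form cases and handles degeneracy", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)
  expect_gt(pearson_r(c(1, 2, 3, 4), c(2, 4, 6, 8))$p, 0)  # underflow limit
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:4, 1:3), "equal length")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("pearson p-values match t-density quadrature to 1e-6 at n = 12", {
  set.seed(12)
  n <- 12
  for (i in 1:10) {
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    res <- pearson_r(x, y)
    tval <- abs(res$r) * sqrt(n - 2) / sqrt(1 - res$r^2)
    quad <- 2 * stats::integrate(function(u) stats::dt(u, df = n - 2),
                                 lower = tval, upper = Inf,
                                 rel.tol = 1e-10)$value
    expect_equal(res$p, quad, tolerance = 1e-6)
    # cross-check against the standard test
    expect_equal(res$p, stats::cor.test(x, y)$p.value, tolerance = 1e-12)
  }
})

test_that("trans networks match a brute-force per-pair oracle", {
  set.seed(33)
  n_l <- 30; n_g <- 100; n_s <- 12
  lm <- matrix(rlnorm(n_l * n_s), n_l,
               dimnames = list(paste0("L", 1:n_l), paste0("s", 1:n_s)))
  gm <- matrix(rlnorm(n_g * n_s), n_g,
               dimnames = list(paste0("G", 1:n_g), paste0("s", 1:n_s)))
  # plant a few strong pairs so the edge set is non-trivial
  gm[1, ] <- 2 * lm[1, ]; gm[2, ] <- 10 - lm[2, ] * 0.5
  gm[3, ] <- lm[3, ] + rnorm(n_s, 0, 1e-3)
  net <- predict_trans_targets(lm, gm, r_threshold = 0.9, p_threshold = 0.05)

  oracle_edges <- list()
  for (i in 1:n_l) for (j in 1:n_g) {
    ct <- suppressWarnings(stats::cor.test(lm[i, ], gm[j, ]))
    if (abs(ct$estimate) > 0.9 && ct$p.value < 0.05)
      oracle_edges[[length(oracle_edges) + 1L]] <-
        c(rownames(lm)[i], rownames(gm)[j], unname(ct$estimate))
  }
  oracle_keys <- sort(vapply(oracle_edges, function(e)
    paste(e[1], e[2]), character(1)))
  expect_identical(sort(paste(net$edges$lnc_id, net$edges$gene_id)),
                   oracle_keys)
  for (e in oracle_edges) {
    row <- net$edges[net$edges$lnc_id == e[1] & net$edges$gene_id == e[2], ]
    expect_equal(row$r, as.numeric(e[3]), tolerance = 1e-12)
  }
})

test_that("trans-network invariants hold", {
  set.seed(34)
  lm <- matrix(rlnorm(10 * 12), 10, dimnames = list(paste0("L", 1:10),
                                                    paste0("s", 1:12)))
  gm <- matrix(rlnorm(40 * 12), 40, dimnames = list(paste0("G", 1:40),
                                                    paste0("s", 1:12)))
  gm[1, ] <- lm[1, ] * 3
  net <- predict_trans_targets(lm, gm, r_threshold = 0.8)
  expect_equal(net$counts[["n_positive"]] + net$counts[["n_negative"]],
               net$counts[["n_edges"]])
  expect_true(all(abs(net$edges$r) > 0.8 & net$edges$p < 0.05))
  expect_true(all((net$edges$sign == "positive") == (net$edges$r > 0)))

  # monotone filtering: stricter thresholds never add edges
  stricter_r <- predict_trans_targets(lm, gm, r_threshold = 0.9)
  stricter_p <- predict_trans_targets(lm, gm, r_threshold = 0.8,
                                      p_threshold = 0.001)
  ekey <- function(n) paste(n$edges$lnc_id, n$edges$gene_id)
  expect_true(all(ekey(stricter_r) %in% ekey(net)))
  expect_true(all(ekey(stricter_p) %in% ekey(net)))

  # at n = 12, |r| > 0.95 already implies p < 0.05
  r_crit <- 0.95
  t_crit <- r_crit * sqrt(10) / sqrt(1 - r_crit^2)
  expect_lt(2 * stats::pt(-t_crit, df = 10), 0.05)

  # planted noise-free positive pair: r exactly 1
  lm2 <- lm; gm2 <- gm; gm2[2, ] <- lm2[2, ] * 0.5
  net2 <- predict_trans_targets(lm2, gm2, r_threshold = 0.99)
  e <- net2$edges[net2$edges$lnc_id == "L2" & net2$edges$gene_id == "G2", ]
  expect_equal(e$r, 1)
  expect_equal(e$sign, "positive")

  # constant rows are skipped and counted, never correlated
  lm3 <- rbind(lm, Lconst = rep(5, 12))
  net3 <- predict_trans_targets(lm3, gm, r_threshold = 0.8)
  expect_equal(net3$skipped_constant[["lnc"]], 1)
  expect_false("Lconst" %in% net3$edges$lnc_id)

  expect_error(predict_trans_targets(lm[, 1:6], gm, 0.9), "sample columns")
  expect_error(predict_trans_targets(lm, gm, r_threshold = 1), "in \\(0,1\\)")
})
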