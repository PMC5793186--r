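#' K-means clustering of temporal expression profiles
#'
#' Clusters per-feature stage-mean profiles with Lloyd's K-means under the
#' Euclidean metric, running `nstart` seeded restarts and keeping the
#' solution with the lowest total within-cluster sum of squares. Profiles
#' are z-scored per feature by default, so clusters capture temporal shape
#' rather than expression magnitude. With the seed fixed the assignment is
#' deterministic and independent of feature order.
#'
#' @param profiles numeric matrix, features x ordered stages (rownames =
#'   feature ids, colnames = stages).
#' @param k number of clusters (default 4).
#' @param seed RNG seed for the restarts.
#' @param nstart number of random restarts (default 10).
#' @param standardize z-score each row before clustering (default TRUE);
#'   constant rows become all-zero profiles.
#' @param label_archetypes attach temporal archetype labels (K1-K4) to the
#'   centroids via [archetype_label()] when `k == 4` (default TRUE).
#' @return object of class `cluster_assignment`: `assignments` (feature_id,
#'   cluster, archetype), `centroids` (k x stages, on the clustered scale),
#'   `sizes`, `labels` (cluster -> archetype, or NULL), `tot_withinss`.
#' @export
kmeans_cluster <- function(profiles, k = 4, seed = 1, nstart = 10,
                           standardize = TRUE, label_archetypes = TRUE) {
  profiles <- as.matrix(profiles)
  if (k < 1L) abort_input("k must be >= 1")
  if (nrow(profiles) < k)
    abort_input("fewer features (%d) than clusters (%d)", nrow(profiles), k)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("f", seq_len(nrow(profiles)))
  x <- profiles
  if (standardize) {
    mu <- rowMeans(x)
    sdev <- apply(x, 1L, stats::sd)
    sdev[sdev == 0] <- 1            # constant profiles map to the origin
    x <- (x - mu) / sdev
  }
  # feature order must not matter: cluster on a canonically ordered copy
  ord <- order(rownames(x))
  xs <- x[ord, , drop = FALSE]
  fit <- with_seed(seed, {
    best <- NULL
    successes <- 0L
    attempts <- 0L
    while (successes < nstart && attempts < 20L * nstart) {
      attempts <- attempts + 1L
      cand <- tryCatch(
        stats::kmeans(xs, centers = k, iter.max = 100L,
                      algorithm = "Lloyd"),
        warning = function(w) NULL,   # non-convergence: re-seed and retry
        error = function(e) NULL)     # empty cluster: re-seed and retry
      if (!is.null(cand)) {
        successes <- successes + 1L
        if (is.null(best) || cand$tot.withinss < best$tot.withinss)
          best <- cand
      }
    }
    if (is.null(best))
      stop("k-means failed to produce a valid partition after restarts")
    best
  })
  cl <- fit$cluster[match(rownames(x), rownames(xs))]
  names(cl) <- rownames(x)
  centroids <- fit$centers
  rownames(centroids) <- paste0("cluster", seq_len(k))
  labels <- NULL
  archetype <- rep(NA_character_, length(cl))
  if (label_archetypes && k == 4L) {
    labels <- archetype_label(centroids)
    archetype <- unname(labels[cl])
  }
  assignments <- data.frame(feature_id = rownames(x), cluster = unname(cl),
                            archetype = archetype, stringsAsFactors = FALSE)
  structure(list(assignments = assignments, centroids = centroids,
                 sizes = as.integer(table(factor(cl, levels = seq_len(k)))),
                 labels = labels, tot_withinss = fit$tot.withinss),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- nrow(x$centroids)
  cat(sprintf("cluster_assignment: %d features in %d clusters\n",
              nrow(x$assignments), k))
  for (i in seq_len(k)) {
    lab <- if (!is.null(x$labels)) sprintf(" [%s]", x$labels[i]) else ""
    cat(sprintf("  cluster %d%s: %d features\n", i, lab, x$sizes[i]))
  }
  invisible(x)
}

#' Canonical K1-K4 temporal archetype profiles
#'
#' Stage-mean log2 expression offsets of the four differentiation
#' archetypes over the ordered stages (A0, A1, A3, A5), scaled by the
#' per-step effect size: K1 monotone decreasing, K2 late-rising, K3 rising
#' from the first transition, K4 peaked at A1. These are the profiles the
#' synthetic-data generator plants.
#'
#' @param de_log2fc per-step effect size in log2 units (default 2).
#' @return 4 x 4 numeric matrix, rownames K1-K4, colnames A0/A1/A3/A5.
#' @export
archetype_profiles <- function(de_log2fc = 2) {
  m <- de_log2fc * do.call(rbind, .archetype_steps)
  colnames(m) <- c("A0", "A1", "A3", "A5")
  m
}

#' Map cluster centroids to the K1-K4 temporal archetypes
#'
#' Assigns the four canonical differentiation archetypes to centroids over
#' the ordered stages: K1 is the centroid with the most negative Spearman
#' trend against stage order (overall decreasing, the proliferation
#' signature); K4 is the centroid peaking at the second stage (the
#' differentiation-onset burst); the remaining two rising centroids split
#' into K3 (earlier rise) and K2 (later rise) by the center of gravity of
#' their above-baseline mass. Labels are unique; degenerate inputs (e.g.
#' all-flat centroids) are resolved by a deterministic lowest-index
#' tie-break with a warning.
#'
#' @param centroids numeric matrix, 4 x stages, stage columns in temporal
#'   order.
#' @return named character vector: for each centroid row, its archetype.
#' @export
archetype_label <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != 4L)
    abort_input("archetype labelling requires exactly 4 centroids")
  ns <- ncol(centroids)
  labels <- rep(NA_character_, 4L)
  degenerate <- FALSE

  trend <- apply(centroids, 1L, function(v) {
    if (stats::sd(v) == 0) 0 else stats::cor(v, seq_len(ns), method = "spearman")
  })
  i_k1 <- which.min(trend)            # which.min takes the lowest index on ties
  if (sum(trend == trend[i_k1]) > 1L) degenerate <- TRUE
  labels[i_k1] <- "K1"

  rest <- setdiff(seq_len(4L), i_k1)
  peak_at_2 <- rest[apply(centroids[rest, , drop = FALSE], 1L, which.max) == 2L]
  if (length(peak_at_2) == 0L) {
    degenerate <- TRUE
    i_k4 <- rest[1L]
  } else {
    if (length(peak_at_2) > 1L) degenerate <- TRUE
    i_k4 <- peak_at_2[1L]
  }
  labels[i_k4] <- "K4"

  rest <- setdiff(rest, i_k4)
  # later rise => larger center of gravity of above-minimum mass
  cog <- apply(centroids[rest, , drop = FALSE], 1L, function(v) {
    w <- v - min(v)
    if (sum(w) == 0) (ns + 1) / 2 else sum(seq_len(ns) * w) / sum(w)
  })
  if (cog[1L] == cog[2L]) degenerate <- TRUE
  i_k2 <- if (cog[2L] > cog[1L]) rest[2L] else rest[1L]
  labels[i_k2] <- "K2"
  labels[setdiff(rest, i_k2)] <- "K3"

  if (degenerate)
    warning("ambiguous archetype assignment; resolved by deterministic tie-break")
  names(labels) <- rownames(centroids)
  labels
}
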