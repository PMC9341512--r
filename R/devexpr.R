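#' Median-of-ratios normalization, optionally on spike-in rows
#'
#' Computes per-sample size factors as the median across reference rows of
#' the ratio to the per-row geometric mean, rescaled to geometric mean 1,
#' and divides each column by its factor. In `size_factor` mode the
#' reference rows are all rows with positive counts everywhere; in
#' `spike_in` mode only the declared spike-in rows, so the factors track
#' library size rather than biology.
#'
#' @param x A [count_matrix()].
#' @param mode `"size_factor"` or `"spike_in"`.
#' @return List with `normalized` (numeric matrix), `size_factors` (named
#'   vector, geometric mean 1) and the `design` tibble.
#' @export
normalize_counts <- function(x, mode = c("size_factor", "spike_in")) {
  mode <- match.arg(mode)
  counts <- x$counts
  ref_rows <- if (mode == "spike_in") {
    if (length(x$spike_in_rows) == 0) {
      abort("spike_in normalization requires spike_in_rows.")
    }
    counts[x$spike_in_rows, , drop = FALSE]
  } else {
    counts
  }
  log_ref <- log(ref_rows)
  log_ref[!is.finite(log_ref)] <- NA
  row_gm <- rowMeans(log_ref, na.rm = FALSE) # geometric mean over all samples
  usable <- is.finite(row_gm)
  if (!any(usable)) {
    abort("No reference row with positive counts in every sample.")
  }
  lr <- log_ref[usable, , drop = FALSE] - row_gm[usable]
  sf <- exp(apply(lr, 2, median))
  if (any(!is.finite(sf) | sf <= 0)) {
    abort(sprintf("Sample '%s' has no usable reference counts.",
                  colnames(counts)[which(!is.finite(sf) | sf <= 0)[1]]))
  }
  sf <- sf / geomean(sf)
  list(
    normalized = sweep(counts, 2, sf, "/"),
    size_factors = setNames(sf, colnames(counts)),
    design = x$design
  )
}

#' Filter rows to expressed loci/genes
#'
#' Keeps a row iff its raw count strictly exceeds `min_reads` in at least
#' `min_samples` samples.
#'
#' @param x A [count_matrix()] (filtered on raw counts).
#' @param min_reads Strict per-sample read threshold (default 5).
#' @param min_samples Minimum number of qualifying samples (default 2).
#' @return The filtered [count_matrix()].
#' @export
filter_expressed <- function(x, min_reads = 5, min_samples = 2) {
  keep <- rowSums(x$counts > min_reads) >= min_samples
  count_matrix(x$counts[keep, , drop = FALSE], x$design,
               stage_order = levels(x$design$stage),
               spike_in_rows = intersect(x$spike_in_rows,
                                         rownames(x$counts)[keep]))
}

#' Pairwise stage tests under a negative-binomial model
#'
#' For every unordered pair of developmental stages, tests each row for a
#' difference in mean normalized count between the two stages. The model
#' is a per-row negative binomial with a method-of-moments dispersion
#' pooled across stages (floored at `dispersion_floor`); the test is a
#' Wald test on the difference of log stage means, with a t reference on
#' `n_a + n_b - 2` degrees of freedom for small-sample calibration. All
#' rows x pairs are stacked into one long table, ready for a single
#' multiple-testing correction pass.
#'
#' @param normalized Output of [normalize_counts()], or a numeric matrix
#'   plus `design`.
#' @param design Required when `normalized` is a bare matrix.
#' @param dispersion_floor Lower bound for the dispersion estimate.
#' @return Tibble: `row_id`, `stage_a`, `stage_b`, `mean_a`, `mean_b`,
#'   `log2fc`, `stat`, `p`.
#' @export
pairwise_stage_tests <- function(normalized, design = NULL,
                                 dispersion_floor = 0.01) {
  if (is.list(normalized) && !is.data.frame(normalized) &&
      !is.matrix(normalized)) {
    design <- normalized$design
    mat <- normalized$normalized
  } else {
    mat <- normalized
  }
  if (is.null(design)) abort("A design is required.")
  stages <- levels(design$stage)
  reps <- table(design$stage)
  usable <- names(reps)[reps >= 2]
  skipped <- setdiff(stages, usable)
  if (length(skipped) > 0) {
    warn(sprintf("Stage(s) with < 2 replicates skipped: %s",
                 paste(skipped, collapse = ", ")))
  }
  by_stage <- lapply(usable, function(s) {
    mat[, design$sample_id[design$stage == s], drop = FALSE]
  })
  names(by_stage) <- usable
  mu <- vapply(by_stage, rowMeans, numeric(nrow(mat)))
  v <- vapply(by_stage, function(m) apply(m, 1, var), numeric(nrow(mat)))
  # method-of-moments dispersion pooled over stages with non-zero mean
  disp_num <- rowSums((v - mu) * (mu > 0), na.rm = TRUE)
  disp_den <- rowSums(mu^2 * (mu > 0), na.rm = TRUE)
  alpha <- pmax(dispersion_floor, disp_num / pmax(disp_den, 1e-12))
  pairs <- utils::combn(usable, 2)
  out <- vector("list", ncol(pairs))
  pseudo <- 0.5
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    na <- reps[[a]]; nb <- reps[[b]]
    ma <- mu[, a]; mb <- mu[, b]
    l2 <- log2((ma + pseudo) / (mb + pseudo))
    # delta-method variance of log(stage mean + pseudocount) under the NB
    se <- sqrt(
      (ma + alpha * ma^2) / (na * (ma + pseudo)^2) +
        (mb + alpha * mb^2) / (nb * (mb + pseudo)^2)
    )
    stat <- ifelse(se > 0, log((ma + pseudo) / (mb + pseudo)) / se, 0)
    p <- ifelse(se > 0, 2 * pt(-abs(stat), df = na + nb - 2), 1)
    out[[j]] <- tibble(
      row_id = rownames(mat), stage_a = a, stage_b = b,
      mean_a = ma, mean_b = mb, log2fc = l2, stat = stat, p = p
    )
  }
  bind_rows(out)
}

#' Call differentially expressed loci from the stacked pair table
#'
#' Applies one Benjamini-Hochberg correction across the entire stacked
#' table (all rows x all stage pairs), then calls a row differentially
#' expressed iff its smallest adjusted p-value is below `alpha` *and* its
#' maximum stage-mean normalized count reaches `min_stage_reads` (rows
#' never reaching that level in any stage are removed as noise).
#'
#' @param stacked Output of [pairwise_stage_tests()].
#' @param normalized Output of [normalize_counts()] (for stage means).
#' @param alpha Adjusted p-value threshold (default 0.01).
#' @param min_stage_reads Required maximum stage mean (default 10).
#' @return A `de_result` tibble: `row_id`, `min_padj`, `max_stage_mean`,
#'   `is_de`; the stacked table with `padj` is attached as attribute
#'   `"stacked"`.
#' @export
call_de <- function(stacked, normalized, alpha = 0.01, min_stage_reads = 10) {
  if (nrow(stacked) == 0) {
    res <- tibble(row_id = character(), min_padj = numeric(),
                  max_stage_mean = numeric(), is_de = logical())
    attr(res, "stacked") <- stacked
    return(res)
  }
  stacked$padj <- p.adjust(stacked$p, method = "BH")
  sm <- stage_means(normalized)
  mx <- apply(sm, 1, max)
  res <- stacked |>
    group_by(.data$row_id) |>
    summarise(min_padj = min(.data$padj), .groups = "drop") |>
    mutate(
      max_stage_mean = mx[.data$row_id],
      is_de = .data$min_padj < alpha & .data$max_stage_mean >= min_stage_reads
    )
  class(res) <- c("de_result", class(res))
  attr(res, "stacked") <- stacked
  res
}

#' Stage-mean matrix of normalized counts
#'
#' Replicate means of normalized counts per developmental stage.
#'
#' @param normalized Output of [normalize_counts()].
#' @return Numeric matrix rows x stages.
#' @export
stage_means <- function(normalized) {
  design <- normalized$design
  mat <- normalized$normalized
  stages <- levels(design$stage)
  out <- vapply(stages, function(s) {
    rowMeans(mat[, design$sample_id[design$stage == s], drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), stages))
}

#' Z-score standardization of stage profiles
#'
#' Per row: subtract the mean and divide by the sample (n-1) standard
#' deviation. Constant rows cannot be standardized; they are excluded and
#' reported in the `"excluded"` attribute.
#'
#' @param profiles Numeric matrix (rows = loci, columns = stages).
#' @return Standardized matrix with attribute `excluded` (row ids).
#' @export
zscore_profiles <- function(profiles) {
  s <- apply(profiles, 1, sd)
  excluded <- rownames(profiles)[s == 0 | !is.finite(s)]
  keep <- setdiff(rownames(profiles), excluded)
  z <- (profiles[keep, , drop = FALSE] -
          rowMeans(profiles[keep, , drop = FALSE])) / s[keep]
  attr(z, "excluded") <- excluded
  z
}

#' Lloyd k-means clustering of expression profiles
#'
#' Best-of-`n_starts` Lloyd k-means (the classic batch algorithm), seeded
#' and therefore fully reproducible; reported inertia is the minimum
#' within-cluster sum of squares over the starts. Cluster labels are
#' re-ordered by the stage at which their centroid peaks, so cluster 1 is
#' always the earliest-peaking profile.
#'
#' @param z Numeric matrix (typically [zscore_profiles()] output).
#' @param k Number of clusters (default 7).
#' @param max_iter,n_starts Lloyd iterations cap and number of restarts.
#' @param seed Seed making the restarts deterministic.
#' @return A `te_clustering` list: `cluster` (named vector), `centers`,
#'   `inertia`, `k`, `sizes`.
#' @export
lloyd_kmeans <- function(z, k = 7, max_iter = 500, n_starts = 50,
                         seed = NULL) {
  if (k > nrow(z)) abort("k exceeds the number of rows.")
  km <- with_seed(seed, {
    fit <- NULL
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(
          kmeans(z, centers = k, iter.max = max_iter, nstart = n_starts,
                 algorithm = "Lloyd")
        ),
        error = function(e) NULL
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) abort("k-means failed to produce a clustering.")
    fit
  })
  # relabel clusters by centroid peak stage (ties: earlier mean profile)
  peak <- apply(km$centers, 1, which.max)
  ord <- order(peak, apply(km$centers, 1, which.min))
  relabel <- match(seq_len(k), ord)
  cluster <- setNames(relabel[km$cluster], rownames(z))
  structure(
    list(
      cluster = cluster, centers = km$centers[ord, , drop = FALSE],
      inertia = km$tot.withinss, k = k,
      sizes = as.integer(table(factor(cluster, levels = seq_len(k))))
    ),
    class = "te_clustering"
  )
}

#' @export
print.te_clustering <- function(x, ...) {
  cat(sprintf("<te_clustering: k=%d, n=%d, inertia=%.1f>\nsizes: %s\n",
              x$k, length(x$cluster), x$inertia,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.te_clustering <- function(x, ...) {
  tibble(row_id = names(x$cluster), cluster = unname(x$cluster))
}

#' @export
glance.te_clustering <- function(x, ...) {
  tibble(k = x$k, n = length(x$cluster), inertia = x$inertia)
}

#' Class/superfamily enrichment per expression cluster
#'
#' For every (unit, cluster) pair, builds the 2x2 contingency table
#' (unit & cluster, unit & not cluster, not unit & cluster, neither) over
#' the clustered loci and applies a two-sided Fisher exact test; BH
#' correction across all records; direction by odds ratio relative to 1.
#'
#' @param clustering A `te_clustering` (or tibble `row_id`, `cluster`).
#' @param unit_labels Tibble `row_id`, `unit` (class or superfamily per
#'   locus).
#' @param alpha Significance threshold recorded in `significant`.
#' @return Tibble of `EnrichmentRecord`s: `unit`, `cluster`, `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `p`, `padj`, `direction`, `significant`.
#' @export
cluster_enrichment <- function(clustering, unit_labels, alpha = 0.05) {
  assign <- if (inherits(clustering, "te_clustering")) {
    tidy(clustering)
  } else {
    clustering
  }
  df <- left_join(assign, unit_labels, by = "row_id") |>
    filter(!is.na(.data$unit))
  units <- unique(df$unit)
  clusters <- sort(unique(df$cluster))
  n <- nrow(df)
  rows <- list()
  for (u in units) {
    in_u <- df$unit == u
    for (cl in clusters) {
      in_c <- df$cluster == cl
      a <- sum(in_u & in_c); b <- sum(in_u & !in_c)
      c_ <- sum(!in_u & in_c); d <- sum(!in_u & !in_c)
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
      rows[[length(rows) + 1]] <- tibble(
        unit = u, cluster = cl, a = a, b = b, c = c_, d = d,
        odds_ratio = unname(ft$estimate), p = ft$p.value
      )
    }
  }
  out <- bind_rows(rows) |>
    mutate(
      padj = p.adjust(.data$p, method = "BH"),
      direction = ifelse(.data$odds_ratio > 1, "enriched", "depleted"),
      significant = .data$padj < alpha
    )
  out
}

#' Fraction of reads from self-expressed TE loci per stage
#'
#' Sums raw counts over the self-expressed TE loci and divides by the
#' total raw counts over all rows (genes plus TE loci, spike-ins
#' excluded), replicate-summed per stage.
#'
#' @param te_counts,gene_counts [count_matrix()] objects on the same
#'   design.
#' @param self_expressed_ids Row ids of self-expressed TE loci.
#' @return Tibble: `stage`, `self_reads`, `total_reads`, `fraction`.
#' @export
self_expressed_read_fraction <- function(te_counts, gene_counts,
                                         self_expressed_ids) {
  te <- te_counts$counts[
    setdiff(rownames(te_counts$counts), te_counts$spike_in_rows), ,
    drop = FALSE
  ]
  ge <- gene_counts$counts[
    setdiff(rownames(gene_counts$counts), gene_counts$spike_in_rows), ,
    drop = FALSE
  ]
  self <- te[intersect(rownames(te), self_expressed_ids), , drop = FALSE]
  design <- te_counts$design
  stages <- levels(design$stage)
  rows <- lapply(stages, function(s) {
    cols <- design$sample_id[design$stage == s]
    tot <- sum(te[, cols]) + sum(ge[, cols])
    tibble(
      stage = s, self_reads = sum(self[, cols]), total_reads = tot,
      fraction = if (tot > 0) sum(self[, cols]) / tot else NA_real_
    )
  })
  bind_rows(rows)
}
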