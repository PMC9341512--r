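#' TE class coverage in fixed genome windows
#'
#' Splits each chromosome into non-overlapping windows (2 Mb by default;
#' the last window of a chromosome may be short) and computes, per window
#' and TE class, the fraction of window bp covered by the union of that
#' class's locus hulls. Overlapping same-class loci are counted once.
#'
#' @param loci Locus tibble (needs `chrom`, `start`, `end`, `te_class`).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @param window_bp Window width in bp.
#' @return Long tibble: `chrom`, `window_index`, `start`, `end`,
#'   `te_class`, `coverage` (fraction in `[0, 1]`), with a row for every
#'   window x class combination.
#' @export
window_coverage <- function(loci, chrom_sizes, window_bp = 2e6) {
  if (any(loci$end > chrom_sizes[loci$chrom])) {
    abort("Locus extends beyond its chromosome size.")
  }
  classes <- sort(unique(loci$te_class))
  out <- list()
  for (chrom in names(chrom_sizes)) {
    len <- chrom_sizes[[chrom]]
    w_start <- seq(0, len - 1, by = window_bp)
    w_end <- pmin(w_start + window_bp, len)
    wins <- as_iranges0(w_start, w_end)
    sub <- loci[loci$chrom == chrom, ]
    for (cls in classes) {
      cl <- sub[sub$te_class == cls, ]
      covered <- rep(0, length(wins))
      if (nrow(cl) > 0) {
        red <- IRanges::reduce(as_iranges0(cl$start, cl$end))
        ov <- IRanges::findOverlaps(wins, red)
        if (length(ov) > 0) {
          inter_w <- pmin(
            IRanges::end(wins)[S4Vectors::queryHits(ov)],
            IRanges::end(red)[S4Vectors::subjectHits(ov)]
          ) - pmax(
            IRanges::start(wins)[S4Vectors::queryHits(ov)],
            IRanges::start(red)[S4Vectors::subjectHits(ov)]
          ) + 1
          agg <- tapply(inter_w, S4Vectors::queryHits(ov), sum)
          covered[as.integer(names(agg))] <- agg
        }
      }
      out[[length(out) + 1]] <- tibble(
        chrom = chrom, window_index = seq_along(wins),
        start = w_start, end = w_end, te_class = cls,
        coverage = covered / (w_end - w_start)
      )
    }
  }
  bind_rows(out)
}

#' Spearman rank correlation with tie-aware ranks
#'
#' Average ranks for ties; p-value from the large-sample t approximation.
#' A constant input vector leaves the correlation undefined and is flagged
#' rather than an error.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @return One-row tibble: `rho`, `p`, `n`, `undefined`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) abort("Need at least 4 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = length(x),
                  undefined = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
         undefined = FALSE)
}

# Per-locus distance to the nearest gene span (0 iff overlap, else gap+1),
# optionally restricted to genes of one strand.
locus_gene_distance <- function(loci, genes) {
  if (nrow(genes) == 0) return(rep(Inf, nrow(loci)))
  te_gr <- GenomicRanges::GRanges(loci$chrom, as_iranges0(loci$start, loci$end))
  g_gr <- GenomicRanges::GRanges(genes$chrom, as_iranges0(genes$start, genes$end))
  d <- rep(Inf, nrow(loci))
  hit <- GenomicRanges::distanceToNearest(te_gr, g_gr, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hit)
  d[q] <- S4Vectors::mcols(hit)$distance
  ov <- GenomicRanges::countOverlaps(te_gr, g_gr, ignore.strand = TRUE) > 0
  ifelse(ov, 0, ifelse(is.finite(d), d + 1, Inf))
}

#' Classify TE families as preferentially intragenic or intergenic
#'
#' For each family, measures the distance from every locus hull to the
#' nearest gene span (0 iff they overlap) and takes the family median. A
#' zero median — most copies overlap gene bodies at least partially —
#' makes the family preferentially intragenic; otherwise it is
#' preferentially intergenic.
#'
#' @param loci Locus tibble.
#' @param genes A [gene_models()] object or a gene span tibble.
#' @return Per-family tibble: `family`, `te_class`, `n_loci`,
#'   `n_overlapping_gene`, `median_distance_bp`, `label`.
#' @export
classify_intragenic <- function(loci, genes) {
  if (nrow(loci) == 0) abort("No loci supplied.")
  gene_spans <- if (inherits(genes, "gene_models")) genes$genes else genes
  loci$.dist <- locus_gene_distance(loci, gene_spans)
  loci |>
    group_by(.data$family, .data$te_class) |>
    summarise(
      n_loci = dplyr::n(),
      n_overlapping_gene = sum(.data$.dist == 0),
      median_distance_bp = median(.data$.dist),
      .groups = "drop"
    ) |>
    mutate(label = ifelse(.data$median_distance_bp == 0,
                          "preferentially_intragenic",
                          "preferentially_intergenic"))
}

#' Label-shuffle null for intragenic enrichment per TE class
#'
#' Compares the observed fraction of preferentially intragenic families in
#' each class to the fraction expected when family identities are shuffled
#' across the fixed locus positions (the overall TE positional
#' distribution is preserved exactly; only the family-to-position pairing
#' is broken). Significance per class is a two-sided exact binomial test
#' of the observed intragenic family count against the shuffle-expected
#' fraction.
#'
#' @param loci Locus tibble.
#' @param genes A [gene_models()] object or gene span tibble.
#' @param n_shuffles Number of label shuffles.
#' @param seed Seed for the shuffles.
#' @return Per-class tibble: `te_class`, `n_families`, `observed_fraction`,
#'   `expected_fraction`, `p`.
#' @export
intragenic_enrichment_test <- function(loci, genes, n_shuffles = 1000,
                                       seed = NULL) {
  gene_spans <- if (inherits(genes, "gene_models")) genes$genes else genes
  dist <- locus_gene_distance(loci, gene_spans)
  fam <- loci$family
  fam_class <- loci |> distinct(.data$family, .data$te_class)
  obs_med <- tapply(dist, fam, median)
  obs_intra <- obs_med == 0
  shuffle_frac <- matrix(NA_real_, n_shuffles, nrow(fam_class),
                         dimnames = list(NULL, fam_class$family))
  with_seed(seed, {
    for (s in seq_len(n_shuffles)) {
      perm <- sample(fam)
      med <- tapply(dist, perm, median)
      shuffle_frac[s, names(med)] <- med == 0
    }
  })
  per_class <- fam_class |>
    group_by(.data$te_class) |>
    summarise(families = list(.data$family), .groups = "drop")
  rows <- lapply(seq_len(nrow(per_class)), function(i) {
    fams <- per_class$families[[i]]
    if (length(fams) == 0) return(NULL)
    k_obs <- sum(obs_intra[fams])
    expected <- mean(shuffle_frac[, fams, drop = FALSE])
    p <- if (expected <= 0 || expected >= 1) {
      if ((expected <= 0 && k_obs == 0) ||
          (expected >= 1 && k_obs == length(fams))) 1 else 0
    } else {
      binom.test(k_obs, length(fams), p = expected)$p.value
    }
    tibble(
      te_class = per_class$te_class[i], n_families = length(fams),
      observed_fraction = k_obs / length(fams),
      expected_fraction = expected, p = p
    )
  })
  bind_rows(rows)
}

#' Strand-aware distance of intergenic TE families to genes
#'
#' For loci that overlap no gene at all, measures the distance to the
#' nearest gene on the same strand and on the opposite strand, summarises
#' per family (medians), and compares the two per-family distributions
#' within each TE class by a Wilcoxon rank-sum test (normal approximation
#' with tie correction).
#'
#' @param loci Locus tibble (stranded).
#' @param genes A [gene_models()] object or gene span tibble (stranded).
#' @return List of two tibbles: `families` (per-family medians) and
#'   `classes` (`te_class`, `n_families`, `W`, `p`).
#' @export
strand_distance_analysis <- function(loci, genes) {
  gene_spans <- if (inherits(genes, "gene_models")) genes$genes else genes
  all_dist <- locus_gene_distance(loci, gene_spans)
  inter <- loci[all_dist > 0, ]
  if (nrow(inter) == 0) {
    abort("No intergenic loci to analyse.")
  }
  d_same <- rep(NA_real_, nrow(inter))
  d_opp <- rep(NA_real_, nrow(inter))
  for (s in c("+", "-")) {
    sel <- inter$strand == s
    if (!any(sel)) next
    d_same[sel] <- locus_gene_distance(inter[sel, ],
                                       gene_spans[gene_spans$strand == s, ])
    d_opp[sel] <- locus_gene_distance(inter[sel, ],
                                      gene_spans[gene_spans$strand != s, ])
  }
  families <- inter |>
    mutate(.same = d_same, .opp = d_opp) |>
    group_by(.data$family, .data$te_class) |>
    summarise(
      n_intergenic = dplyr::n(),
      median_dist_same_strand = median(.data$.same[is.finite(.data$.same)]),
      median_dist_opposite_strand = median(.data$.opp[is.finite(.data$.opp)]),
      .groups = "drop"
    )
  classes <- families |>
    filter(is.finite(.data$median_dist_same_strand),
           is.finite(.data$median_dist_opposite_strand)) |>
    group_by(.data$te_class) |>
    summarise(
      n_families = dplyr::n(),
      W = if (dplyr::n() >= 2) {
        suppressWarnings(wilcox.test(
          .data$median_dist_same_strand, .data$median_dist_opposite_strand,
          exact = FALSE, correct = TRUE
        ))$statistic
      } else NA_real_,
      p = if (dplyr::n() >= 2) {
        suppressWarnings(wilcox.test(
          .data$median_dist_same_strand, .data$median_dist_opposite_strand,
          exact = FALSE, correct = TRUE
        ))$p.value
      } else NA_real_,
      .groups = "drop"
    )
  list(families = families, classes = classes)
}

#' Partition loci by divergence from consensus
#'
#' Young insertions are those strictly below `young_lt` percent diverged
#' from their family consensus; old ones strictly above `old_gt`; the rest
#' are `mid`. Loci without a divergence value are excluded (their count is
#' reported via a message).
#'
#' @param loci Locus tibble with `divergence_pct`.
#' @param young_lt,old_gt Partition thresholds in percent.
#' @return The loci tibble with an `age_group` factor column
#'   (`young`/`mid`/`old`), missing-divergence rows dropped.
#' @export
partition_by_divergence <- function(loci, young_lt = 1.0, old_gt = 15.0) {
  n_missing <- sum(is.na(loci$divergence_pct))
  if (n_missing > 0) {
    message(sprintf("Excluding %d loci without divergence.", n_missing))
    loci <- loci[!is.na(loci$divergence_pct), ]
  }
  loci |>
    mutate(age_group = factor(
      dplyr::case_when(
        .data$divergence_pct < young_lt ~ "young",
        .data$divergence_pct > old_gt ~ "old",
        .default = "mid"
      ),
      levels = c("young", "mid", "old")
    ))
}

#' Rank correlation between family age and a family attribute
#'
#' Spearman correlation between the median terminal-branch age of families
#' (status `ok` only) and a per-family attribute such as copy number or
#' consensus length.
#'
#' @param ages A family-age tibble from [estimate_family_ages()].
#' @param attributes Tibble with `family` and the attribute column.
#' @param attribute Name of the attribute column in `attributes`.
#' @return One-row tibble as [rank_correlation()].
#' @export
family_summary_correlation <- function(ages, attributes,
                                       attribute = "copy_number") {
  ok <- ages |>
    filter(.data$status == "ok") |>
    left_join(distinct(attributes, .data$family, .keep_all = TRUE),
              by = "family")
  if (nrow(ok) < 4) abort("Fewer than 4 usable families.")
  rank_correlation(ok$median_terminal_branch, ok[[attribute]])
}
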