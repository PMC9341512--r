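default_stages <- function() {
  tibble(
    stage = c("zygote", "cleavage", "dome", "shield", "somite", "larva"),
    pre_zga = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
}

# Stage-mean archetype profiles over the default 6-stage series. The
# maternal archetype is high before zygotic genome activation and exactly
# zero after; the others peak progressively later.
archetype_profiles <- function(stages = default_stages()$stage) {
  k <- length(stages)
  profs <- list(
    maternal = c(1, 1, rep(0, k - 2)),
    early_zygotic = c(0, 0, 1, 1, 0.25, 0.05)[seq_len(k)],
    mid_somite = c(0, 0, 0.15, 0.6, 1, 0.3)[seq_len(k)],
    late_larval = c(0, 0, 0.05, 0.1, 0.5, 1)[seq_len(k)],
    constant = rep(1, k),
    flat_low = rep(1, k)
  )
  lapply(profs, function(p) setNames(p, stages))
}

#' Simulate stage-structured expression for genes and TE loci
#'
#' Draws negative-binomial counts for a developmental stage series with
#' replicates. Genes receive archetype stage profiles (a fraction are
#' never expressed); TE loci receive means according to their planted
#' provenance: gene-dependent loci are proportional to their host gene's
#' stage means, self-expressed loci follow their own archetype, and
#' spike-in rows are stage-constant. Counts are
#' `NB(mean = stage_mean * size_factor, dispersion)` with log-normal
#' per-sample library size factors.
#'
#' @param genome Output of [simulate_genome()].
#' @param truth Truth tibble from [simulate_insertions()] (with
#'   `position_category` and `host_gene`).
#' @param stages Tibble with `stage` and `pre_zga` columns, in
#'   developmental order.
#' @param replicates Replicates per stage.
#' @param dispersion NB dispersion (Var = mu + dispersion * mu^2).
#' @param libsize_sdlog Log-normal sigma of library size factors.
#' @param n_spike_in Number of spike-in control rows.
#' @param p_gene_silent Fraction of genes that are never expressed.
#' @param seed Optional seed.
#' @return List with `gene_counts` and `te_counts` ([count_matrix()]
#'   objects, both containing the spike-in rows), `truth` (updated with
#'   `provenance` and `archetype`), `gene_truth`, and `stage_means`
#'   (long tibble of true TE stage means).
#' @export
simulate_expression <- function(genome, truth, stages = default_stages(),
                                replicates = 3, dispersion = 0.2,
                                libsize_sdlog = 0.15, n_spike_in = 20,
                                p_gene_silent = 0.2, seed = NULL) {
  with_seed(seed, {
    stage_names <- stages$stage
    k <- length(stage_names)
    design <- tibble(
      sample_id = paste0(rep(stage_names, each = replicates), "_r",
                         rep(seq_len(replicates), k)),
      stage = rep(stage_names, each = replicates),
      replicate = rep(seq_len(replicates), k),
      pre_zga = rep(stages$pre_zga, each = replicates)
    )
    sf <- rlnorm(nrow(design), 0, libsize_sdlog)
    profs <- archetype_profiles(stage_names)
    gene_ids <- genome$genes$genes$gene_id
    n_genes <- length(gene_ids)
    gene_arch <- sample(
      c("silent", "maternal", "constant", "early_zygotic", "mid_somite",
        "late_larval"),
      n_genes, replace = TRUE,
      prob = c(p_gene_silent, 0.15, 0.25, 0.15, 0.15, 0.1)
    )
    gene_base <- rlnorm(n_genes, log(300), 0.7)
    gene_means <- t(vapply(seq_len(n_genes), function(i) {
      if (gene_arch[i] == "silent") rep(0, k)
      else gene_base[i] * profs[[gene_arch[i]]]
    }, numeric(k)))
    dimnames(gene_means) <- list(gene_ids, stage_names)
    # TE provenance from position + gene expression status
    silent_genes <- gene_ids[gene_arch == "silent"]
    truth$provenance <- dplyr::case_when(
      truth$position_category %in% c("exon_overlapping", "extended_3utr") ~
        "gene_dependent",
      truth$position_category == "intron" &
        !(truth$host_gene %in% silent_genes) ~ "gene_dependent",
      .default = "self_expressed"
    )
    truth$position_category <- ifelse(
      truth$position_category == "intron",
      ifelse(truth$host_gene %in% silent_genes, "intron_nonexpressed",
             "intron_expressed"),
      truth$position_category
    )
    n_te <- nrow(truth)
    te_arch <- rep(NA_character_, n_te)
    self <- truth$provenance == "self_expressed"
    te_arch[self] <- sample(
      c("maternal", "early_zygotic", "mid_somite", "late_larval", "flat_low"),
      sum(self), replace = TRUE, prob = c(0.2, 0.25, 0.2, 0.2, 0.15)
    )
    truth$archetype <- te_arch
    te_scale <- rlnorm(n_te, log(80), 0.6)
    te_means <- matrix(0, n_te, k, dimnames = list(truth$locus_id, stage_names))
    for (i in seq_len(n_te)) {
      if (self[i]) {
        base <- if (te_arch[i] == "flat_low") 15 else te_scale[i]
        te_means[i, ] <- base * profs[[te_arch[i]]]
      } else if (!is.na(truth$host_gene[i])) {
        te_means[i, ] <- runif(1, 0.05, 0.3) * gene_means[truth$host_gene[i], ]
      }
    }
    spike_ids <- sprintf("ERCC_%03d", seq_len(n_spike_in))
    spike_means <- matrix(
      rep(rlnorm(n_spike_in, log(400), 0.5), k), n_spike_in, k,
      dimnames = list(spike_ids, stage_names)
    )
    draw <- function(means) {
      mu <- means[, design$stage, drop = FALSE] *
        rep(sf, each = nrow(means))
      cnt <- matrix(
        rnbinom(length(mu), mu = mu, size = 1 / dispersion),
        nrow = nrow(means),
        dimnames = list(rownames(means), design$sample_id)
      )
      cnt
    }
    gene_counts <- count_matrix(
      rbind(draw(gene_means), draw(spike_means)),
      design, stage_order = stage_names, spike_in_rows = spike_ids
    )
    te_counts <- count_matrix(
      rbind(draw(te_means), draw(spike_means)),
      design, stage_order = stage_names, spike_in_rows = spike_ids
    )
    stage_means <- as_tibble(te_means, rownames = "locus_id") |>
      tidyr::pivot_longer(-"locus_id", names_to = "stage", values_to = "mean")
    list(
      gene_counts = gene_counts, te_counts = te_counts, truth = truth,
      gene_truth = tibble(gene_id = gene_ids, archetype = gene_arch,
                          base_mean = ifelse(gene_arch == "silent", 0, gene_base)),
      stage_means = stage_means, size_factors = setNames(sf, design$sample_id)
    )
  })
}
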