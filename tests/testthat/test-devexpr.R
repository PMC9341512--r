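two_stage_design <- function(reps = 3) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(2 * reps)),
    stage = factor(rep(c("A", "B"), each = reps), c("A", "B")),
    replicate = rep(seq_len(reps), 2)
  )
}

test_that("median-of-ratios factors match the hand computation", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
              dimnames = list(paste0("r", 1:3), c("s1", "s2")))
  design <- tibble::tibble(sample_id = c("s1", "s2"), stage = c("A", "B"),
                           replicate = 1)
  cm <- count_matrix(m, design)
  norm <- normalize_counts(cm, "size_factor")
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(norm$normalized[, 1], norm$normalized[, 2])
  expect_equal(teeco:::geomean(norm$size_factors), 1)

  # identical columns -> unit factors
  cm2 <- count_matrix(cbind(s1 = c(5, 8, 9), s2 = c(5, 8, 9)), design)
  expect_equal(unname(normalize_counts(cm2)$size_factors), c(1, 1))
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(21)
  m <- matrix(rnbinom(600, mu = 100, size = 5), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  design <- two_stage_design()
  cm <- count_matrix(m, design)
  got <- normalize_counts(cm, "size_factor")$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(got), unname(ref), tolerance = 1e-10)
})

test_that("spike-in factors track library size, not biology", {
  set.seed(22)
  design <- two_stage_design()
  spike <- matrix(rpois(20 * 6, 200), 20, 6)
  rownames(spike) <- paste0("ERCC_", 1:20)
  # genes triple their expression in stage B; spikes are stage-constant
  genes <- rbind(
    matrix(c(rpois(50 * 3, 100), rpois(50 * 3, 300)), 50, 6)
  )
  rownames(genes) <- paste0("g", 1:50)
  m <- rbind(genes, spike)
  colnames(m) <- design$sample_id
  cm <- count_matrix(m, design, spike_in_rows = rownames(spike))
  sf_spike <- normalize_counts(cm, "spike_in")$size_factors
  sf_all <- normalize_counts(cm, "size_factor")$size_factors
  # spike factors stay near 1 across the shift; all-row factors absorb it
  expect_lt(max(abs(log(sf_spike))), 0.15)
  expect_gt(mean(sf_all[4:6]) / mean(sf_all[1:3]), 1.5)
})

test_that("expression filter keeps rows with >5 reads in >=2 samples", {
  m <- rbind(r1 = c(6, 6, 0), r2 = c(6, 5, 0), r3 = c(0, 0, 0),
             r4 = c(100, 7, 2))
  colnames(m) <- paste0("s", 1:3)
  design <- tibble::tibble(sample_id = paste0("s", 1:3), stage = "A",
                           replicate = 1:3)
  kept <- filter_expressed(count_matrix(m, design))
  expect_equal(rownames(kept$counts), c("r1", "r4"))
})

test_that("pairwise tests stack all stage pairs and skip 1-replicate stages", {
  set.seed(23)
  design <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    stage = factor(rep(c("A", "B", "C", "D"), each = 3),
                   c("A", "B", "C", "D")),
    replicate = rep(1:3, 4)
  )
  m <- matrix(rnbinom(10 * 12, mu = 50, size = 5), 10,
              dimnames = list(paste0("r", 1:10), design$sample_id))
  stk <- pairwise_stage_tests(m, design)
  expect_equal(nrow(stk), 10 * 6) # 4 stages -> 6 unordered pairs

  design1 <- design[-(1:2), ] # stage A keeps one replicate
  m1 <- m[, design1$sample_id]
  expect_warning(stk1 <- pairwise_stage_tests(m1, design1), "skipped")
  expect_equal(nrow(stk1), 10 * 3)
})

test_that("the NB test is calibrated under the null and powered at 8-fold", {
  design <- two_stage_design()
  set.seed(24)
  null <- matrix(rnbinom(1000 * 6, mu = 50, size = 5), 1000,
                 dimnames = list(paste0("r", 1:1000), design$sample_id))
  stk <- pairwise_stage_tests(null, design)
  expect_lt(mean(stk$p < 0.05), 1.5 * 0.05)

  set.seed(25)
  alt <- cbind(matrix(rnbinom(500 * 3, mu = 200, size = 10), 500),
               matrix(rnbinom(500 * 3, mu = 25, size = 10), 500))
  dimnames(alt) <- list(paste0("r", 1:500), design$sample_id)
  stk <- pairwise_stage_tests(alt, design)
  expect_gte(mean(stk$p < 0.01), 0.90)
})

test_that("DE calls apply stacked BH and the stage-mean floor", {
  design <- two_stage_design(2)
  m <- matrix(5L, 10, 4, dimnames = list(paste0("r", 1:10), design$sample_id))
  cm <- count_matrix(m, design)
  norm <- normalize_counts(cm)
  stk <- pairwise_stage_tests(norm)
  expect_true(all(stk$p > 0.9))
  de <- call_de(stk, norm)
  expect_false(any(de$is_de))

  # hand-checked BH on a constructed 10-row stack
  stk2 <- tibble::tibble(
    row_id = paste0("r", 1:10), stage_a = "A", stage_b = "B",
    mean_a = 50, mean_b = 50, log2fc = 0, stat = 0,
    p = c(0.001, 0.02, 0.03, 0.04, 0.2, 0.3, 0.5, 0.7, 0.9, 1)
  )
  de2 <- call_de(stk2, norm = list(
    normalized = matrix(50, 10, 4, dimnames = list(paste0("r", 1:10),
                                                   design$sample_id)),
    design = design
  ))
  expect_equal(attr(de2, "stacked")$padj, oracle_bh(stk2$p))
  expect_true(all(attr(de2, "stacked")$padj >= attr(de2, "stacked")$p))

  # min padj below alpha but stage means below the floor -> not DE
  stk3 <- stk2[1, ]
  de3 <- call_de(stk3, norm = list(
    normalized = matrix(8, 1, 4, dimnames = list("r1", design$sample_id)),
    design = design
  ))
  expect_equal(de3$min_padj, 0.001)
  expect_false(de3$is_de)
})

test_that("z-scoring centres rows and excludes constant profiles", {
  m <- rbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(1, 0, 2))
  colnames(m) <- paste0("st", 1:3)
  z <- zscore_profiles(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(attr(z, "excluded"), "b")
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
})

test_that("Lloyd k-means separates planted archetypes deterministically", {
  set.seed(26)
  z <- rbind(
    matrix(rnorm(40 * 4, mean = rep(c(2, 2, -2, -2), each = 40), sd = 0.3),
           40, 4),
    matrix(rnorm(40 * 4, mean = rep(c(-2, -2, 2, 2), each = 40), sd = 0.3),
           40, 4)
  )
  dimnames(z) <- list(paste0("r", 1:80), paste0("st", 1:4))
  cl <- lloyd_kmeans(z, k = 2, seed = 1)
  truth <- rep(1:2, each = 40)
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)

  cl2 <- lloyd_kmeans(z, k = 2, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  small <- z[1:5, ]
  expect_equal(lloyd_kmeans(small, k = 5, seed = 1)$inertia, 0)
  expect_error(lloyd_kmeans(small, k = 6), "exceeds")
})

test_that("reported inertia is the within-cluster sum of squares", {
  set.seed(27)
  z <- matrix(rnorm(60), 20, 3,
              dimnames = list(paste0("r", 1:20), paste0("st", 1:3)))
  cl <- lloyd_kmeans(z, k = 3, seed = 2)
  wss <- sum(vapply(1:3, function(k) {
    rows <- z[cl$cluster == k, , drop = FALSE]
    sum(sweep(rows, 2, colMeans(rows))^2)
  }, numeric(1)))
  expect_equal(cl$inertia, wss, tolerance = 1e-8)
})

test_that("cluster enrichment matches the hypergeometric oracle", {
  # planted table (a,b,c,d) = (10,10,10,70)
  assign <- tibble::tibble(
    row_id = paste0("r", 1:100),
    cluster = c(rep(1, 20), rep(2, 80))
  )
  labels <- tibble::tibble(
    row_id = paste0("r", 1:100),
    unit = c(rep("X", 10), rep("Y", 10), rep("X", 10), rep("Y", 70))
  )
  enr <- cluster_enrichment(assign, labels)
  rec <- enr[enr$unit == "X" & enr$cluster == 1, ]
  expect_equal(rec$a, 10); expect_equal(rec$b, 10)
  expect_equal(rec$c, 10); expect_equal(rec$d, 70)
  expect_equal(rec$p, oracle_fisher_p(10, 10, 10, 70), tolerance = 1e-12)
  expect_equal(rec$direction, "enriched")
  expect_equal(sum(enr$a + enr$b + enr$c + enr$d == 100), nrow(enr))

  # uniformly distributed unit -> nothing significant
  set.seed(28)
  flat_labels <- tibble::tibble(row_id = paste0("r", 1:100),
                                unit = sample(c("X", "Y"), 100, TRUE))
  enr2 <- cluster_enrichment(assign, flat_labels)
  expect_true(all(!enr2$significant) || mean(enr2$significant) < 0.2)
})

test_that("self-expressed read fractions match hand arithmetic", {
  design <- tibble::tibble(sample_id = c("s1", "s2"), stage = c("A", "B"),
                           replicate = 1)
  tem <- rbind(te1 = c(10L, 0L), te2 = c(10L, 30L), te3 = c(0L, 10L))
  gem <- rbind(g1 = c(60L, 40L), g2 = c(20L, 20L))
  colnames(tem) <- colnames(gem) <- c("s1", "s2")
  te <- count_matrix(tem, design)
  ge <- count_matrix(gem, design)
  frac <- self_expressed_read_fraction(te, ge, c("te1", "te2"))
  expect_equal(frac$fraction, c(20 / 100, 30 / 100))

  frac0 <- self_expressed_read_fraction(te, ge, character())
  expect_equal(frac0$fraction, c(0, 0))
})

test_that("fixture read fractions track the planted expectation", {
  eco <- default_fixture()
  self_ids <- eco$truth$locus_id[eco$truth$provenance == "self_expressed"]
  frac <- self_expressed_read_fraction(eco$te_counts, eco$gene_counts,
                                       self_ids)
  # pre-ZGA (maternal-dominated) and post-ZGA fractions are both present
  pre <- frac$fraction[frac$stage %in%
                         eco$te_counts$design$stage[eco$te_counts$design$pre_zga]]
  post <- frac$fraction[!frac$stage %in%
                          eco$te_counts$design$stage[eco$te_counts$design$pre_zga]]
  expect_true(all(frac$fraction > 0))
  expect_true(all(frac$fraction < 0.5))
})

test_that("the full expression pipeline recovers planted archetype clusters", {
  eco <- default_fixture()
  te <- filter_expressed(eco$te_counts)
  norm <- normalize_counts(te, "spike_in")
  de <- call_de(pairwise_stage_tests(norm), norm)
  self_ids <- eco$truth$locus_id[eco$truth$provenance == "self_expressed"]
  de_self <- de$row_id[de$is_de & de$row_id %in% self_ids]
  z <- zscore_profiles(stage_means(norm)[de_self, ])
  truth_arch <- eco$truth$archetype[match(rownames(z), eco$truth$locus_id)]
  cl <- lloyd_kmeans(z, k = length(unique(truth_arch)), seed = 11)
  ari <- mclust::adjustedRandIndex(cl$cluster, truth_arch)
  expect_gte(ari, 0.8)

  # the maternal cluster is expressed only before ZGA
  mat_cluster <- names(which.max(table(
    cl$cluster[truth_arch == "maternal"]
  )))
  mat_ids <- names(cl$cluster)[cl$cluster == as.integer(mat_cluster)]
  post_cols <- eco$te_counts$design$sample_id[!eco$te_counts$design$pre_zga]
  pre_cols <- eco$te_counts$design$sample_id[eco$te_counts$design$pre_zga]
  post_mean <- mean(eco$te_counts$counts[mat_ids, post_cols])
  pre_mean <- mean(eco$te_counts$counts[mat_ids, pre_cols])
  expect_gt(pre_mean, 50 * max(post_mean, 0.01))
})
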