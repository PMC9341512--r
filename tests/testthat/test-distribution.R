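test_that("window coverage computes unioned per-class fractions", {
  sizes <- c(chr1 = 4e6)
  loci <- make_loci(0, 1e6, te_class = "LTR")
  wc <- window_coverage(loci, sizes)
  ltr <- wc[wc$te_class == "LTR", ]
  expect_equal(ltr$coverage, c(0.5, 0))

  # overlapping same-class loci count once
  loci2 <- make_loci(c(0, 5e5), c(1e6, 1.5e6), te_class = "LTR")
  wc2 <- window_coverage(loci2, sizes)
  expect_equal(wc2$coverage[wc2$te_class == "LTR"], c(0.75, 0))

  # a class with no loci in a window is all zero
  loci3 <- dplyr::bind_rows(loci, make_loci(3e6, 3.1e6, te_class = "DNA"))
  wc3 <- window_coverage(loci3, sizes)
  expect_equal(wc3$coverage[wc3$te_class == "DNA"], c(0, 0.05))
  expect_equal(wc3$coverage[wc3$te_class == "LTR"], c(0.5, 0))

  expect_error(window_coverage(make_loci(3.9e6, 4.1e6), sizes), "beyond")
})

test_that("window coverage conserves per-class covered bp", {
  eco <- default_fixture()
  loci <- default_loci()
  wc <- window_coverage(loci, eco$genome$chrom_sizes)
  for (cls in unique(loci$te_class)) {
    got <- wc |>
      dplyr::filter(te_class == cls) |>
      dplyr::summarise(bp = sum(coverage * (end - start))) |>
      dplyr::pull(bp)
    want <- sum(vapply(names(eco$genome$chrom_sizes), function(ch) {
      sub <- loci[loci$te_class == cls & loci$chrom == ch, ]
      if (nrow(sub) == 0) return(0)
      sum(IRanges::width(IRanges::reduce(teeco:::as_iranges0(sub$start, sub$end))))
    }, numeric(1)))
    expect_equal(got, want)
  }
})

test_that("rank correlation handles perfect, inverse, tied and constant input", {
  expect_equal(rank_correlation(1:4, 1:4)$rho, 1)
  expect_equal(rank_correlation(1:4, 4:1)$rho, -1)

  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  got <- rank_correlation(x, y)
  # brute-force average-rank formula
  rx <- rank(x); ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, rho)

  const <- rank_correlation(rep(1, 5), 1:5)
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
})

test_that("intragenic classification uses the zero-median rule", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 10000, end = 20000)
  # distances: overlap, overlap, 500 -> median 0 -> intragenic
  loci <- make_loci(c(11000, 19500, 20500), c(12000, 20500, 21000))
  loci$.d <- NULL
  call <- classify_intragenic(loci, genes)
  expect_equal(call$median_distance_bp, 0)
  expect_equal(call$label, "preferentially_intragenic")
  expect_equal(call$n_overlapping_gene, 2L)

  # distances: 0, 500, 600 -> median 500 -> intergenic
  loci2 <- make_loci(c(11000, 20499, 20599), c(12000, 20600, 20700))
  call2 <- classify_intragenic(loci2, genes)
  expect_equal(call2$median_distance_bp, 500)
  expect_equal(call2$label, "preferentially_intergenic")

  # fully inside -> 0
  call3 <- classify_intragenic(make_loci(15000, 15400), genes)
  expect_equal(call3$median_distance_bp, 0)

  expect_error(classify_intragenic(make_loci(numeric(), numeric()), genes),
               "No loci")
})

test_that("label shuffling degenerates to p = 1 for a single family", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          start = 0, end = 50000)
  loci <- make_loci(seq(10000, 90000, by = 10000),
                    seq(10000, 90000, by = 10000) + 500)
  res <- intragenic_enrichment_test(loci, genes, n_shuffles = 50, seed = 1)
  expect_equal(res$observed_fraction, res$expected_fraction)
  expect_equal(res$p, 1)
})

test_that("planted intergenic preference is detected against the shuffle null", {
  set.seed(33)
  # genes cover the left half of the chromosome
  genes <- tibble::tibble(gene_id = paste0("g", 1:25), chrom = "chr1",
                          strand = "+", start = seq(0, 4.8e6, by = 2e5),
                          end = seq(0, 4.8e6, by = 2e5) + 1.9e5)
  # class A: all loci far from genes; class B: inside gene bodies
  posA <- runif(240, 5.2e6, 9.9e6)
  host <- sample(nrow(genes), 240, replace = TRUE)
  posB <- genes$start[host] + runif(240, 0, 1.8e5)
  loci <- dplyr::bind_rows(
    make_loci(posA, posA + 300, family = rep(paste0("A", 1:30), each = 8),
              te_class = "A"),
    make_loci(posB, posB + 300, family = rep(paste0("B", 1:30), each = 8),
              te_class = "B")
  )
  res <- intragenic_enrichment_test(loci, genes, n_shuffles = 300, seed = 9)
  a <- res[res$te_class == "A", ]
  expect_lt(a$observed_fraction, a$expected_fraction)
  expect_lt(a$p, 0.05)
})

test_that("strand-aware distances produce hand-computed family medians", {
  genes <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    start = c(0, 30000), end = c(10000, 40000)
  )
  # two plus-strand loci between the genes:
  #   L1 at 12000-12500: same-strand gap 2000 -> d 2001; opposite 17500 -> 17501
  #   L2 at 28000-28500: same-strand gap 18000 -> 18001; opposite 1500 -> 1501
  loci <- make_loci(c(12000, 28000), c(12500, 28500), family = "f1")
  res <- strand_distance_analysis(loci, genes)
  expect_equal(res$families$median_dist_same_strand, mean(c(2001, 18001)))
  expect_equal(res$families$median_dist_opposite_strand, mean(c(17501, 1501)))

  # equidistant locus contributes equal same/opposite distances
  loci_eq <- make_loci(20000 - 250, 20000 + 250, family = "f2")
  genes_eq <- tibble::tibble(
    gene_id = c("gp", "gm"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000, 21000), end = c(19000, 30000)
  )
  res_eq <- strand_distance_analysis(loci_eq, genes_eq)
  expect_equal(res_eq$families$median_dist_same_strand,
               res_eq$families$median_dist_opposite_strand)
})

test_that("divergence partition uses strict thresholds", {
  loci <- make_loci(c(0, 100, 200, 300), c(50, 150, 250, 350))
  loci$divergence_pct <- c(0.5, 15.0, 20, 1.0)
  parts <- partition_by_divergence(loci)
  expect_equal(as.character(parts$age_group), c("young", "mid", "old", "mid"))

  loci$divergence_pct[2] <- NA
  expect_message(parts <- partition_by_divergence(loci), "Excluding 1")
  expect_equal(nrow(parts), 3)
})

test_that("family age correlates with attributes as planted", {
  ages <- tibble::tibble(
    family = paste0("f", 1:10), n_loci_total = 10, n_used = 10,
    median_terminal_branch = seq(0.01, 0.1, by = 0.01),
    median_divergence_pct = seq(1, 10), status = "ok"
  )
  attrs <- tibble::tibble(family = paste0("f", 1:10),
                          copy_number = seq(10, 100, by = 10))
  expect_equal(
    family_summary_correlation(ages, attrs, "copy_number")$rho, 1
  )
  attrs$copy_number <- 5
  expect_true(family_summary_correlation(ages, attrs, "copy_number")$undefined)
  expect_error(family_summary_correlation(ages[1:3, ], attrs[1:3, ]),
               "Fewer than 4")
})
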