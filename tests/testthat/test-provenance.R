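test_that("position annotation follows the printed priority with strand rule", {
  gm <- toy_genes()
  # same-strand 3' UTR of geneP [2200,2600) while inside geneM's "intron"
  # region on the opposite strand: 3UTR wins under the strand rule
  loci <- make_loci(2300, 2500, strand = "+")
  res <- annotate_position(loci, gm)
  expect_equal(res$raw_category, "3UTR")
  expect_equal(res$host_gene, "geneP")

  # overlapping the 5' UTR of geneP and (hypothetically) an exon of geneM:
  # 5UTR is evaluated first
  loci2 <- make_loci(1100, 1150, strand = "+")
  expect_equal(annotate_position(loci2, gm)$raw_category, "5UTR")

  # far from everything -> intergenic
  loci3 <- make_loci(50000, 50500)
  expect_equal(annotate_position(loci3, gm)$raw_category, "intergenic")

  # intron of geneP (between its exons), same strand
  loci4 <- make_loci(1500, 1900, strand = "+")
  res4 <- annotate_position(loci4, gm)
  expect_equal(res4$raw_category, "intron")
  expect_equal(res4$host_gene, "geneP")

  # same interval on the minus strand: geneP features no longer count and
  # no minus-strand feature is nearby -> intergenic
  loci5 <- make_loci(1500, 1900, strand = "-")
  expect_equal(annotate_position(loci5, gm)$raw_category, "intergenic")
})

test_that("strand-blind mode attributes features regardless of orientation", {
  gm <- toy_genes()
  loci <- make_loci(2300, 2500, strand = "-") # in geneP 3'UTR, wrong strand
  aware <- annotate_position(loci, gm, strand_aware = TRUE)
  blind <- annotate_position(loci, gm, strand_aware = FALSE)
  expect_false(aware$raw_category == "3UTR")
  expect_equal(blind$raw_category, "3UTR")
})

test_that("expressed-gene threshold is strict", {
  m <- matrix(c(10, 3, 11, 0, 0, 0), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  m[1, ] <- c(10, 10); m[2, ] <- c(11, 0); m[3, ] <- c(0, 0)
  expect_equal(expressed_genes(m), "g2")
  expect_equal(expressed_genes(matrix(numeric(), 0, 0)), character())
})

test_that("extended 3' UTRs are derived per strand and unioned", {
  ref <- toy_genes() # geneP + ends 2600; geneM - 3' end at 5000
  asm <- gene_models(exons = tibble::tibble(
    transcript_id = c("st1", "st2", "st3"),
    gene_id = c("sg1", "sg2", "sg3"),
    chrom = "chr1",
    strand = c("+", "+", "-"),
    start = c(2000, 2100, 4400),
    end = c(3100, 2550, 5600)
  ))
  ext <- extended_three_prime_utrs(asm, ref)
  # st1 extends geneP from 2600 to 3100; st2 ends inside -> nothing;
  # st3 extends geneM (3' end = start 5000) down to 4400
  expect_equal(nrow(ext), 2)
  plus <- ext[ext$strand == "+", ]
  expect_equal(c(plus$start, plus$end), c(2600, 3100))
  expect_equal(plus$gene_id, "geneP")
  minus <- ext[ext$strand == "-", ]
  expect_equal(c(minus$start, minus$end), c(4400, 5000))

  # isoform overlapping no gene is skipped with a message
  asm2 <- gene_models(exons = tibble::tibble(
    transcript_id = "st9", gene_id = "sg9", chrom = "chr1", strand = "+",
    start = 90000, end = 91000
  ))
  expect_message(ext2 <- extended_three_prime_utrs(asm2, ref), "skipped")
  expect_equal(nrow(ext2), 0)
})

test_that("provenance collapse, hierarchy and partition invariants hold", {
  gm <- toy_genes()
  loci <- dplyr::bind_rows(
    make_loci(1100, 1300, strand = "+"),   # 5UTR -> exon_overlapping
    make_loci(1500, 1900, strand = "+"),   # intron of geneP
    make_loci(50000, 50500),               # intergenic
    make_loci(5100, 5400, strand = "-")    # exon of geneM
  )
  loci$locus_id <- paste0("L", 1:4)
  raw <- annotate_position(loci, gm)
  # geneP not expressed, geneM expressed
  calls <- classify_provenance(loci, raw, expressed_set = "geneM")
  expect_equal(calls$position_category,
               c("exon_overlapping", "intron_nonexpressed", "intergenic",
                 "exon_overlapping"))
  expect_equal(calls$provenance,
               c("gene_dependent", "self_expressed", "self_expressed",
                 "gene_dependent"))
  # every locus gets exactly one category and provenance
  expect_equal(nrow(calls), nrow(loci))
  expect_false(any(is.na(calls$position_category)))

  # with geneP expressed the intronic locus flips to gene-dependent
  calls2 <- classify_provenance(loci, raw, expressed_set = c("geneP", "geneM"))
  expect_equal(calls2$position_category[2], "intron_expressed")
  expect_equal(calls2$provenance[2], "gene_dependent")

  # fragment-group hierarchy: exon-overlapping + intergenic -> whole group
  # exon_overlapping
  groups <- tibble::tibble(locus_id = c("L1", "L3"), group_id = "grp1")
  calls3 <- classify_provenance(loci, raw, "geneM", groups = groups)
  expect_equal(calls3$position_category[calls3$locus_id == "L3"],
               "exon_overlapping")
  expect_equal(calls3$provenance[calls3$locus_id == "L3"], "gene_dependent")
  expect_equal(calls3$host_gene[calls3$locus_id == "L3"], "geneP")

  # idempotence: reapplying the collapse is a fixed point
  calls4 <- classify_provenance(loci, raw, "geneM", groups = groups)
  expect_identical(calls3, calls4)
})

test_that("extended-3'UTR overlap outranks intron but not exon overlap", {
  gm <- toy_genes()
  ext <- tibble::tibble(chrom = "chr1", start = 2600, end = 3200,
                        strand = "+", gene_id = "geneP")
  loci <- dplyr::bind_rows(
    make_loci(2700, 3000, strand = "+"),  # inside the extension
    make_loci(2700, 3000, strand = "-")   # wrong strand
  )
  loci$locus_id <- c("L1", "L2")
  raw <- annotate_position(loci, gm)
  calls <- classify_provenance(loci, raw, character(), extended_utrs = ext)
  expect_equal(calls$position_category[1], "extended_3utr")
  expect_equal(calls$provenance[1], "gene_dependent")
  expect_equal(calls$position_category[2], "intergenic")
})

test_that("TSS containment requires the full peak inside the locus", {
  gd <- make_loci(90, 200)
  se <- make_loci(1000, 1200)
  peaks <- tibble::tibble(
    chrom = "chr1", start = c(100, 100, 1050), end = c(150, 250, 1080)
  )
  res <- tss_containment(gd, se, peaks)
  # peak (100,150) contained in (90,200); (100,250) is not; (1050,1080) in se
  expect_equal(res$n_with_peak_gd, 1L)
  expect_equal(res$n_with_peak_se, 1L)

  gd2 <- make_loci(90, 200)
  peaks2 <- tibble::tibble(chrom = "chr1", start = 100, end = 250)
  res2 <- tss_containment(gd2, se, peaks2)
  expect_equal(res2$n_with_peak_gd, 0L)
})

test_that("planted TSS peaks enrich self-expressed DE loci on the fixture", {
  eco <- default_fixture()
  tr <- eco$truth
  se_de <- tr[tr$provenance == "self_expressed" & !is.na(tr$archetype) &
                tr$archetype != "flat_low", ]
  gd <- tr[tr$provenance == "gene_dependent", ]
  res <- tss_containment(gd, se_de, eco$cage_peaks)
  expect_gt(res$rate_ratio, 5)
  expect_lt(res$p, 0.01)
})

test_that("provenance recovery on the fixture is at least 95%", {
  eco <- default_fixture()
  tr <- eco$truth
  raw <- annotate_position(tr, eco$genome$genes)
  norm <- normalize_counts(eco$gene_counts, "size_factor")
  mat <- norm$normalized[setdiff(rownames(norm$normalized),
                                 eco$gene_counts$spike_in_rows), ]
  expr_set <- expressed_genes(mat)
  ext <- extended_three_prime_utrs(eco$assembled, eco$genome$genes)
  calls <- classify_provenance(tr, raw, expr_set, ext)
  agree <- mean(calls$provenance == tr$provenance)
  expect_gte(agree, 0.95)
})

test_that("planted age asymmetry appears in the classified groups", {
  eco <- default_fixture()
  tr <- eco$truth
  med_self <- median(tr$age_t[tr$provenance == "self_expressed"])
  med_gd <- median(tr$age_t[tr$provenance == "gene_dependent"])
  expect_lt(med_self, med_gd)
})
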