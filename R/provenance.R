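#' Annotate TE locus position relative to genes
#'
#' Assigns each locus hull its raw positional category by evaluating
#' feature overlaps in a fixed priority order — 5UTR, 3UTR, exon,
#' promoter, intron, downstream, intergenic — the first category whose
#' feature set the hull overlaps wins, together with the gene supplying
#' the feature. With `strand_aware = TRUE` (default) only same-strand
#' gene features count for the 5UTR/3UTR/exon/intron categories, i.e. a
#' TE is only attributed to a gene it could be co-transcribed with;
#' promoter and downstream windows are positional and ignore the locus
#' strand. Because a gene span is the hull of its exons, a locus that
#' overlaps a gene span but none of its exons (tested earlier in the
#' priority order) necessarily lies in an intron.
#'
#' @param loci Locus tibble.
#' @param genes A [gene_models()] object.
#' @param promoter_up Promoter window upstream of the TSS in bp.
#' @param downstream_bp Downstream window past the 3' end in bp.
#' @param strand_aware Restrict gene-body features to the locus strand.
#' @return Tibble: `locus_id`, `raw_category`, `host_gene`.
#' @export
annotate_position <- function(loci, genes, promoter_up = 3000,
                              downstream_bp = 300, strand_aware = TRUE) {
  gm <- genes
  te_gr <- GenomicRanges::GRanges(
    loci$chrom, as_iranges0(loci$start, loci$end), strand = loci$strand
  )
  feat_gr <- function(tbl) {
    GenomicRanges::GRanges(
      tbl$chrom, as_iranges0(tbl$start, tbl$end), strand = tbl$strand,
      gene_id = tbl$gene_id
    )
  }
  g <- gm$genes
  plus <- g$strand == "+"
  promoter <- tibble(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = ifelse(plus, pmax(0, g$start - promoter_up), g$end),
    end = ifelse(plus, g$start, g$end + promoter_up)
  )
  downstream <- tibble(
    gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
    start = ifelse(plus, g$end, pmax(0, g$start - downstream_bp)),
    end = ifelse(plus, g$end + downstream_bp, g$start)
  )
  sets <- list(
    `5UTR` = list(tbl = gm$utr5, stranded = strand_aware),
    `3UTR` = list(tbl = gm$utr3, stranded = strand_aware),
    exon = list(tbl = gm$exons, stranded = strand_aware),
    promoter = list(tbl = promoter, stranded = FALSE),
    intron = list(tbl = tibble(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end
    ), stranded = strand_aware),
    downstream = list(tbl = downstream, stranded = FALSE)
  )
  raw <- rep("intergenic", nrow(loci))
  host <- rep(NA_character_, nrow(loci))
  unassigned <- rep(TRUE, nrow(loci))
  for (nm in names(sets)) {
    tbl <- sets[[nm]]$tbl
    if (nrow(tbl) == 0 || !any(unassigned)) next
    tbl <- tbl[tbl$end > tbl$start, ]
    hits <- GenomicRanges::findOverlaps(
      te_gr, feat_gr(tbl), ignore.strand = !sets[[nm]]$stranded
    )
    q <- S4Vectors::queryHits(hits)
    keep <- q %in% which(unassigned)
    if (!any(keep)) next
    q <- q[keep]
    s <- S4Vectors::subjectHits(hits)[keep]
    first_gene <- tapply(tbl$gene_id[s], q, function(x) sort(x)[1])
    idx <- as.integer(names(first_gene))
    raw[idx] <- nm
    host[idx] <- as.character(first_gene)
    unassigned[idx] <- FALSE
  }
  tibble(locus_id = loci$locus_id, raw_category = raw, host_gene = host)
}

#' Genes expressed above a normalized-count threshold
#'
#' A gene counts as expressed iff its normalized count strictly exceeds
#' `threshold` in at least one sample. Spike-in rows are ignored.
#'
#' @param gene_counts A [count_matrix()] of *normalized* gene counts
#'   (see [normalize_counts()]) or a plain numeric matrix.
#' @param threshold Normalized-count threshold (strict, default 10).
#' @return Character vector of expressed gene ids.
#' @export
expressed_genes <- function(gene_counts, threshold = 10) {
  mat <- if (inherits(gene_counts, "count_matrix")) {
    m <- gene_counts$counts
    m[setdiff(rownames(m), gene_counts$spike_in_rows), , drop = FALSE]
  } else {
    gene_counts
  }
  if (length(mat) == 0) return(character())
  mx <- apply(mat, 1, max)
  rownames(mat)[mx > threshold]
}

#' Extended 3' UTR regions from assembled transcripts
#'
#' Each assembled isoform is assigned to a reference gene on the same
#' strand whose exons it overlaps; the extended region is the part of the
#' isoform's 3'-most exon lying 3' of the reference gene's annotated 3'
#' end and contiguous with it (the exon must span the annotated end).
#' Isoforms that do not extend past their gene yield nothing; isoforms
#' overlapping no known gene are skipped (a count is messaged). Per-strand
#' regions are unioned into a single annotation.
#'
#' @param assembled A [gene_models()] object of assembled transcripts.
#' @param reference A [gene_models()] object of reference annotations.
#' @return Tibble of stranded intervals: `chrom`, `start`, `end`,
#'   `strand`, `gene_id` (the reference gene extended).
#' @export
extended_three_prime_utrs <- function(assembled, reference) {
  tx <- assembled$transcripts
  if (nrow(tx) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), gene_id = character()))
  }
  ref_ex <- reference$exons
  ref_genes <- reference$genes
  asm_ex_gr <- GenomicRanges::GRanges(
    assembled$exons$chrom,
    as_iranges0(assembled$exons$start, assembled$exons$end),
    strand = assembled$exons$strand
  )
  ref_ex_gr <- GenomicRanges::GRanges(
    ref_ex$chrom, as_iranges0(ref_ex$start, ref_ex$end), strand = ref_ex$strand
  )
  hits <- GenomicRanges::findOverlaps(asm_ex_gr, ref_ex_gr,
                                      ignore.strand = FALSE)
  asm2gene <- tibble(
    transcript_id = assembled$exons$transcript_id[S4Vectors::queryHits(hits)],
    gene_id = ref_ex$gene_id[S4Vectors::subjectHits(hits)]
  ) |> distinct()
  skipped <- setdiff(tx$transcript_id, asm2gene$transcript_id)
  if (length(skipped) > 0) {
    message(sprintf("%d assembled isoform(s) overlap no known gene; skipped.",
                    length(skipped)))
  }
  rows <- list()
  for (i in seq_len(nrow(asm2gene))) {
    tid <- asm2gene$transcript_id[i]
    gid <- asm2gene$gene_id[i]
    ex <- assembled$exons[assembled$exons$transcript_id == tid, ]
    gene <- ref_genes[ref_genes$gene_id == gid, ]
    if (gene$strand == "+") {
      lastex <- ex[which.max(ex$end), ]
      if (lastex$end > gene$end && lastex$start < gene$end) {
        rows[[length(rows) + 1]] <- tibble(
          chrom = gene$chrom, start = gene$end, end = lastex$end,
          strand = "+", gene_id = gid
        )
      }
    } else {
      lastex <- ex[which.min(ex$start), ]
      if (lastex$start < gene$start && lastex$end > gene$start) {
        rows[[length(rows) + 1]] <- tibble(
          chrom = gene$chrom, start = lastex$start, end = gene$start,
          strand = "-", gene_id = gid
        )
      }
    }
  }
  ext <- bind_rows(rows)
  if (nrow(ext) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  strand = character(), gene_id = character()))
  }
  # collapse overlapping extensions into a single annotation per strand
  out <- list()
  for (key in split(seq_len(nrow(ext)),
                    paste(ext$chrom, ext$strand, sep = "\r"))) {
    sub <- ext[key, ]
    red <- IRanges::reduce(as_iranges0(sub$start, sub$end))
    ov <- IRanges::findOverlaps(red, as_iranges0(sub$start, sub$end))
    first_gene <- tapply(sub$gene_id[S4Vectors::subjectHits(ov)],
                         S4Vectors::queryHits(ov), function(x) sort(x)[1])
    out[[length(out) + 1]] <- tibble(
      chrom = sub$chrom[1], start = IRanges::start(red) - 1,
      end = as.numeric(IRanges::end(red)), strand = sub$strand[1],
      gene_id = as.character(first_gene)
    )
  }
  bind_rows(out)
}

position_hierarchy <- c(
  "exon_overlapping" = 1, "extended_3utr" = 2, "intron_expressed" = 3,
  "intron_nonexpressed" = 4, "intergenic" = 5
)

#' Classify the expression provenance of TE loci
#'
#' Collapses raw positional categories onto the five position categories
#' and the binary provenance call. Exonic and UTR overlaps are
#' `exon_overlapping`; loci overlapping a same-strand extended 3' UTR are
#' `extended_3utr`; intronic loci split on whether their residing gene is
#' in `expressed_set`; promoter, downstream and intergenic collapse to
#' `intergenic` (a TE upstream of a promoter is not transcribed from that
#' gene). Within a fragment group (loci reconstructed as parts of one
#' element) every member receives the group's highest category in the
#' hierarchy exon > extended 3' UTR > intron expressed > intron
#' nonexpressed > intergenic. Exon-overlapping, extended-3'UTR and
#' intron-expressed loci are gene-dependent; the rest are self-expressed.
#'
#' @param loci Locus tibble.
#' @param raw Output of [annotate_position()] for the same loci.
#' @param expressed_set Character vector from [expressed_genes()].
#' @param extended_utrs Tibble from [extended_three_prime_utrs()] (may be
#'   empty).
#' @param groups Optional tibble `locus_id`, `group_id` linking loci that
#'   belong to one reconstructed element; loci absent from it form their
#'   own group.
#' @return Tibble: `locus_id`, `raw_category`, `position_category`,
#'   `provenance`, `host_gene`.
#' @export
classify_provenance <- function(loci, raw, expressed_set,
                                extended_utrs = NULL, groups = NULL) {
  calls <- left_join(select(loci, "locus_id", "chrom", "start", "end",
                            "strand"),
                     raw, by = "locus_id")
  pos <- dplyr::case_when(
    calls$raw_category %in% c("5UTR", "3UTR", "exon") ~ "exon_overlapping",
    calls$raw_category == "intron" &
      calls$host_gene %in% expressed_set ~ "intron_expressed",
    calls$raw_category == "intron" ~ "intron_nonexpressed",
    .default = "intergenic"
  )
  # extended 3' UTR outranks everything except exon overlap
  if (!is.null(extended_utrs) && nrow(extended_utrs) > 0) {
    te_gr <- GenomicRanges::GRanges(
      calls$chrom, as_iranges0(calls$start, calls$end), strand = calls$strand
    )
    ext_gr <- GenomicRanges::GRanges(
      extended_utrs$chrom,
      as_iranges0(extended_utrs$start, extended_utrs$end),
      strand = extended_utrs$strand
    )
    hits <- GenomicRanges::findOverlaps(te_gr, ext_gr, ignore.strand = FALSE)
    q <- unique(S4Vectors::queryHits(hits))
    in_ext <- q[pos[q] != "exon_overlapping"]
    pos[in_ext] <- "extended_3utr"
    first_ext <- tapply(
      extended_utrs$gene_id[S4Vectors::subjectHits(hits)],
      S4Vectors::queryHits(hits), function(x) sort(x)[1]
    )
    calls$host_gene[in_ext] <- as.character(first_ext[as.character(in_ext)])
  }
  calls$position_category <- pos
  # fragment-group hierarchy: best category wins for the whole group
  calls$group_id <- calls$locus_id
  if (!is.null(groups)) {
    m <- match(calls$locus_id, groups$locus_id)
    calls$group_id[!is.na(m)] <- groups$group_id[m[!is.na(m)]]
  }
  calls <- calls |>
    group_by(.data$group_id) |>
    mutate(
      .rank = unname(position_hierarchy[.data$position_category]),
      .best = min(.data$.rank),
      host_gene = {
        hb <- .data$host_gene[.data$.rank == .data$.best]
        hb <- hb[!is.na(hb)]
        if (length(hb) > 0) hb[1] else NA_character_
      },
      position_category = names(position_hierarchy)[.data$.best]
    ) |>
    ungroup() |>
    select(-".rank", -".best")
  calls |>
    mutate(provenance = ifelse(
      .data$position_category %in%
        c("exon_overlapping", "extended_3utr", "intron_expressed"),
      "gene_dependent", "self_expressed"
    )) |>
    select("locus_id", "raw_category", "position_category", "provenance",
           "host_gene")
}

#' TSS-peak containment in gene-dependent vs self-expressed loci
#'
#' Counts, per locus set, how many loci fully contain at least one TSS
#' peak (containment means the entire peak lies inside the locus hull),
#' and compares the two containment rates with a chi-square test of
#' association (Fisher's exact test when any expected cell count is
#' small). A rate ratio well above 1 for the self-expressed set evidences
#' TE-internal promoters.
#'
#' @param loci_gene_dependent,loci_self_expressed Locus tibbles.
#' @param tss_peaks Interval tibble (`chrom`, `start`, `end`).
#' @return One-row tibble: `n_gene_dependent`, `n_with_peak_gd`,
#'   `rate_gd`, `n_self_expressed`, `n_with_peak_se`, `rate_se`,
#'   `rate_ratio`, `p`, `test`.
#' @export
tss_containment <- function(loci_gene_dependent, loci_self_expressed,
                            tss_peaks) {
  contained <- function(loci) {
    if (nrow(loci) == 0) return(NA_integer_)
    if (nrow(tss_peaks) == 0) return(0L)
    te_gr <- GenomicRanges::GRanges(loci$chrom,
                                    as_iranges0(loci$start, loci$end))
    pk_gr <- GenomicRanges::GRanges(tss_peaks$chrom,
                                    as_iranges0(tss_peaks$start, tss_peaks$end))
    hits <- GenomicRanges::findOverlaps(pk_gr, te_gr, type = "within")
    sum(seq_len(nrow(loci)) %in% S4Vectors::subjectHits(hits))
  }
  n_gd <- nrow(loci_gene_dependent)
  n_se <- nrow(loci_self_expressed)
  k_gd <- contained(loci_gene_dependent)
  k_se <- contained(loci_self_expressed)
  if (is.na(k_gd) || is.na(k_se)) {
    return(tibble(
      n_gene_dependent = n_gd, n_with_peak_gd = k_gd,
      rate_gd = NA_real_, n_self_expressed = n_se, n_with_peak_se = k_se,
      rate_se = NA_real_, rate_ratio = NA_real_, p = NA_real_,
      test = "undefined"
    ))
  }
  tab <- matrix(c(k_se, n_se - k_se, k_gd, n_gd - k_gd), 2)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ht <- fisher.test(tab)
    test <- "fisher"
  } else {
    ht <- suppressWarnings(stats::chisq.test(tab))
    test <- "chi-square"
  }
  rate_gd <- k_gd / n_gd
  rate_se <- k_se / n_se
  tibble(
    n_gene_dependent = n_gd, n_with_peak_gd = k_gd, rate_gd = rate_gd,
    n_self_expressed = n_se, n_with_peak_se = k_se, rate_se = rate_se,
    rate_ratio = rate_se / rate_gd, p = ht$p.value, test = test
  )
}
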