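#' Simulate a complete TE ecosystem fixture
#'
#' One-call wrapper chaining [simulate_genome()], [simulate_te_families()],
#' [simulate_insertions()] and [simulate_expression()], then planting
#' extended-3'UTR read-through insertions (with matching assembled
#' transcripts) and CAGE TSS peaks inside self-expressed loci. The default
#' scale — 2 chromosomes x 5 Mb, ~40 families, a few thousand insertions,
#' 6 stages x 3 replicates — runs in seconds and carries ground truth for
#' every downstream recovery test.
#'
#' @param seed Integer seed controlling every random choice.
#' @param n_ext_utr Number of genes given a read-through extension hosting
#'   a TE.
#' @param cage_rate_self,cage_rate_gene Probability of planting a fully
#'   contained TSS peak in a self-expressed (non-flat archetype)
#'   respectively gene-dependent locus.
#' @param ... Passed on to [simulate_insertions()].
#' @inheritParams simulate_genome
#' @inheritParams simulate_expression
#' @return A list with elements `genome`, `families`, `fragments`,
#'   `fragment_map`, `truth`, `sequences`, `gene_counts`, `te_counts`,
#'   `gene_truth`, `stage_means`, `assembled`, `cage_peaks`.
#' @export
simulate_te_ecosystem <- function(seed = 1, n_chroms = 2, chrom_len = 5e6,
                                  genic_fraction = 0.6, n_families = 40,
                                  replicates = 3, dispersion = 0.2,
                                  n_ext_utr = 8, cage_rate_self = 0.8,
                                  cage_rate_gene = 0.005, ...) {
  set.seed(seed)
  genome <- simulate_genome(n_chroms = n_chroms, chrom_len = chrom_len,
                            genic_fraction = genic_fraction)
  families <- simulate_te_families(n_families = n_families)
  ins <- simulate_insertions(genome, families, ...)
  ext <- plant_extended_utrs(genome, families, ins, n_ext_utr)
  ins <- ext$ins
  expr <- simulate_expression(genome, ins$truth, replicates = replicates,
                              dispersion = dispersion)
  truth <- expr$truth
  cage <- plant_cage_peaks(truth, cage_rate_self, cage_rate_gene)
  list(
    genome = genome, families = families, fragments = ins$fragments,
    fragment_map = ins$fragment_map, truth = truth,
    sequences = ins$sequences, gene_counts = expr$gene_counts,
    te_counts = expr$te_counts, gene_truth = expr$gene_truth,
    stage_means = expr$stage_means, assembled = ext$assembled,
    cage_peaks = cage, seed = seed
  )
}

# Add one read-through insertion past the 3' end of `n_ext` genes, plus the
# assembled transcripts whose last exon spans the gene end and the TE.
plant_extended_utrs <- function(genome, families, ins, n_ext) {
  genes <- genome$genes$genes
  if (n_ext == 0 || nrow(genes) == 0) {
    return(list(ins = ins, assembled = gene_models(exons = tibble(
      transcript_id = character(), gene_id = character(), chrom = character(),
      strand = character(), start = numeric(), end = numeric()
    ))))
  }
  cand_fams <- families |>
    filter(is.na(.data$ltr_role), .data$consensus_len <= 1500)
  if (nrow(cand_fams) == 0) {
    cand_fams <- families |> filter(is.na(.data$ltr_role))
  }
  picks <- sample(nrow(genes), min(n_ext * 3, nrow(genes)))
  frag_rows <- list(); truth_rows <- list(); seq_rows <- list(); asm <- list()
  done <- 0
  n0 <- nrow(ins$truth)
  for (g in picks) {
    if (done >= n_ext) break
    gene <- genes[g, ]
    fam <- cand_fams[sample(nrow(cand_fams), 1), ]
    gap <- round(runif(1, 100, 400))
    if (gene$strand == "+") {
      te_start <- gene$end + gap
      if (te_start + fam$consensus_len + 50 > max(genome$chrom_sizes)) next
    } else {
      te_start <- gene$start - gap - fam$consensus_len
      if (te_start < 50) next
    }
    other <- genes[genes$chrom == gene$chrom & genes$gene_id != gene$gene_id, ]
    te_end <- te_start + fam$consensus_len
    if (any(other$start < te_end + 200 & other$end > te_start - 200)) next
    done <- done + 1
    locus_id <- sprintf("teext%03d", done)
    plan <- build_insertion(fam, NULL, locus_id, fragment = FALSE,
                            truncate = FALSE, kappa = 2, cpg_multiplier = 1)
    plan$strand <- gene$strand
    laid <- lay_out(plan, list(chrom = gene$chrom, start = te_start))
    laid$truth$position_category <- "extended_3utr"
    laid$truth$host_gene <- gene$gene_id
    frag_rows <- c(frag_rows, list(laid$fragments))
    truth_rows <- c(truth_rows, list(laid$truth))
    seq_rows <- c(seq_rows, list(laid$sequences))
    # assembled isoform: last exon runs from inside the gene across the TE
    ex <- genome$genes$exons |> filter(.data$gene_id == gene$gene_id)
    if (gene$strand == "+") {
      last_ex <- ex[which.max(ex$end), ]
      ext_exon <- tibble(start = last_ex$start, end = te_end + 50)
    } else {
      last_ex <- ex[which.min(ex$start), ]
      ext_exon <- tibble(start = te_start - 50, end = last_ex$end)
    }
    asm[[done]] <- tibble(
      transcript_id = sprintf("STRG.%d.1", done),
      gene_id = sprintf("STRG.%d", done),
      chrom = gene$chrom, strand = gene$strand,
      start = ext_exon$start, end = ext_exon$end
    )
  }
  new_frags <- bind_rows(frag_rows)
  if (nrow(new_frags) > 0) {
    new_frags$rm_id <- sprintf("%d", nrow(ins$fragments) + seq_len(nrow(new_frags)))
    frag_map_new <- tibble(rm_id = new_frags$rm_id, locus_id = new_frags$locus_id)
    ins$fragments <- bind_rows(ins$fragments,
                               select(new_frags, -"locus_id")) |>
      arrange(.data$chrom, .data$start)
    ins$fragment_map <- bind_rows(ins$fragment_map, frag_map_new)
    ins$truth <- bind_rows(ins$truth, bind_rows(truth_rows))
    ins$sequences <- bind_rows(ins$sequences, bind_rows(seq_rows))
  }
  list(ins = ins, assembled = gene_models(exons = bind_rows(asm)))
}

# Plant fixed-width TSS peaks fully inside locus hulls.
plant_cage_peaks <- function(truth, rate_self, rate_gene, width = 30) {
  p <- ifelse(
    truth$provenance == "self_expressed" &
      !is.na(truth$archetype) & truth$archetype != "flat_low",
    rate_self, rate_gene
  )
  hit <- runif(nrow(truth)) < p & (truth$end - truth$start) > width + 10
  t <- truth[hit, ]
  if (nrow(t) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character()))
  }
  off <- vapply(t$end - t$start - width - 2, function(m) runif(1, 1, m),
                numeric(1))
  tibble(
    chrom = t$chrom, start = round(t$start + off),
    end = round(t$start + off) + width,
    name = paste0("cage_", t$locus_id), score = 100,
    strand = NA_character_
  )
}

#' Write a simulated ecosystem to disk as standard-format fixtures
#'
#' Emits the RepeatMasker-style `.out`, gene and assembled-transcript GTFs,
#' CAGE peak BED, count TSVs with a design sidecar, and a JSON truth file
#' sufficient to score every recovery test. All files are parseable by the
#' package's readers and round-trip exactly.
#'
#' @param eco Output of [simulate_te_ecosystem()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
emit_fixtures <- function(eco, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_repeatmasker_out(eco$fragments, p("repeats.out"))
  write_gtf(eco$genome$genes, p("genes.gtf"))
  write_gtf(eco$assembled, p("assembled.gtf"))
  write_bed(eco$cage_peaks, p("cage_peaks.bed"))
  write_bed(
    eco$truth |> rename(name = "locus_id") |> mutate(score = 0),
    p("truth_loci.bed")
  )
  write_count_matrix(eco$te_counts, p("te_counts.tsv"), p("design.tsv"))
  write_count_matrix(eco$gene_counts, p("gene_counts.tsv"), p("design_genes.tsv"))
  jsonlite::write_json(
    list(
      truth = eco$truth, fragment_map = eco$fragment_map,
      families = select(eco$families, -"consensus_seq"),
      gene_truth = eco$gene_truth, stage_means = eco$stage_means,
      seed = eco$seed
    ),
    p("truth.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(list(
    repeats = p("repeats.out"), genes = p("genes.gtf"),
    assembled = p("assembled.gtf"), cage = p("cage_peaks.bed"),
    truth_bed = p("truth_loci.bed"), te_counts = p("te_counts.tsv"),
    design = p("design.tsv"), gene_counts = p("gene_counts.tsv"),
    truth_json = p("truth.json")
  ))
}
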