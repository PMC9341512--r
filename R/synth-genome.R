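#' Simulate a toy annotated genome
#'
#' Builds a small multi-chromosome genome populated with non-overlapping
#' protein-coding gene models. Gene lengths are log-normal; each gene gets
#' one transcript with several exons, a CDS and derived UTRs. Genes are laid
#' out left to right with random intergenic gaps whose total is chosen so
#' that the realized genic fraction matches `genic_fraction` (the zebrafish
#' genome is gene dense, with genic regions covering roughly 60% of
#' chromosomal DNA — the default emulates that).
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_len Length of each chromosome in bp.
#' @param genic_fraction Target fraction of the genome covered by gene
#'   bodies, in (0, 1).
#' @param n_genes Total gene count; `NULL` derives it from the mean gene
#'   length and the genic target.
#' @param gene_len_meanlog,gene_len_sdlog Log-normal parameters of gene
#'   length (bp).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A list with `chrom_sizes` (named numeric) and `genes`
#'   (a [gene_models()] object).
#' @export
simulate_genome <- function(n_chroms = 2, chrom_len = 5e6,
                            genic_fraction = 0.6, n_genes = NULL,
                            gene_len_meanlog = log(11000),
                            gene_len_sdlog = 0.45, seed = NULL) {
  stopifnot(genic_fraction >= 0, genic_fraction < 1)
  with_seed(seed, {
    chrom_sizes <- setNames(rep(chrom_len, n_chroms),
                            paste0("chr", seq_len(n_chroms)))
    total_bp <- sum(chrom_sizes)
    target_bp <- genic_fraction * total_bp
    mean_len <- exp(gene_len_meanlog + gene_len_sdlog^2 / 2)
    n_genes <- n_genes %||% max(0L, round(target_bp / mean_len))
    if (n_genes == 0) {
      return(list(
        chrom_sizes = chrom_sizes,
        genes = gene_models(exons = tibble(
          transcript_id = character(), gene_id = character(),
          chrom = character(), strand = character(),
          start = numeric(), end = numeric()
        ))
      ))
    }
    lens <- pmax(600, round(rlnorm(n_genes, gene_len_meanlog, gene_len_sdlog)))
    lens <- pmax(600, round(lens * target_bp / sum(lens)))
    # round-robin genes over chromosomes, then lay out with random gaps
    chrom_of <- rep(names(chrom_sizes), length.out = n_genes)
    exon_rows <- vector("list", n_genes)
    cds_rows <- vector("list", n_genes)
    for (chrom in names(chrom_sizes)) {
      idx <- which(chrom_of == chrom)
      gl <- lens[idx]
      slack <- chrom_sizes[[chrom]] - sum(gl)
      if (slack < length(idx) + 1) {
        abort("Genic fraction target infeasible for this gene length distribution.")
      }
      w <- rgamma(length(idx) + 1, 1) + 1e-9
      gaps <- floor(slack * w / sum(w))
      starts <- cumsum(c(0, gl)) [seq_along(idx)] + cumsum(gaps)[seq_along(idx)]
      for (k in seq_along(idx)) {
        i <- idx[k]
        g <- build_gene_structure(
          gene_id = sprintf("gene%04d", i), chrom = chrom,
          start = starts[k], len = gl[k],
          strand = sample(c("+", "-"), 1)
        )
        exon_rows[[i]] <- g$exons
        cds_rows[[i]] <- g$cds
      }
    }
    list(
      chrom_sizes = chrom_sizes,
      genes = gene_models(
        exons = bind_rows(exon_rows),
        cds = bind_rows(cds_rows)
      )
    )
  })
}

# One transcript per gene: exons alternating with introns, CDS in the middle
# of the exonic sequence so both UTRs are non-empty.
build_gene_structure <- function(gene_id, chrom, start, len, strand) {
  tx_id <- paste0(gene_id, ".t1")
  n_ex <- 1L + stats::rpois(1, 3)
  exonic <- max(300, round(len * runif(1, 0.08, 0.3)))
  w_ex <- rgamma(n_ex, 2) + 1e-9
  ex_len <- pmax(60, round(exonic * w_ex / sum(w_ex)))
  if (n_ex > 1) {
    w_in <- rgamma(n_ex - 1, 2) + 1e-9
    in_len <- pmax(80, round((len - sum(ex_len)) * w_in / sum(w_in)))
    in_len <- pmax(80, in_len)
  } else {
    in_len <- numeric()
  }
  piece_len <- as.vector(rbind(ex_len, c(in_len, 0)))[seq_len(2 * n_ex - 1)]
  piece_start <- start + cumsum(c(0, head(piece_len, -1)))
  ex_starts <- piece_start[seq(1, 2 * n_ex - 1, by = 2)]
  exons <- tibble(
    transcript_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
    start = ex_starts, end = ex_starts + ex_len
  )
  # CDS occupies the middle of the exonic sequence in transcription order
  exonic_total <- sum(ex_len)
  utr5_len <- max(30, round(0.1 * exonic_total))
  utr3_len <- max(60, round(0.2 * exonic_total))
  ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
  cum <- cumsum(c(0, ex_len[ord]))
  off2pos <- function(off) {
    k <- min(max(findInterval(off, cum), 1L), n_ex)
    within <- off - cum[k]
    e <- ord[k]
    if (strand == "+") exons$start[e] + within else exons$end[e] - within
  }
  p1 <- off2pos(utr5_len)
  p2 <- off2pos(exonic_total - utr3_len)
  cds_lo <- min(p1, p2); cds_hi <- max(p1, p2)
  s <- pmax(exons$start, cds_lo)
  e <- pmin(exons$end, cds_hi)
  keep <- e > s
  cds <- tibble(
    transcript_id = tx_id, gene_id = gene_id, chrom = chrom, strand = strand,
    start = s[keep], end = e[keep]
  )
  list(exons = exons, cds = cds)
}
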