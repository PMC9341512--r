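#' Construct a gene-model set
#'
#' Bundles gene, transcript and exon tables (plus optional CDS and UTR
#' tables) into a validated `gene_models` object, the substrate of every
#' proximity and provenance computation in the package. All coordinates are
#' internal 0-based half-open. When `cds` is supplied and UTRs are not, the
#' 5' and 3' UTRs are derived per transcript as the exonic sequence upstream
#' respectively downstream of the CDS, respecting strand.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#'   Span is recomputed from the exons when they are present.
#' @param transcripts Tibble with `transcript_id`, `gene_id` (+ coordinates,
#'   recomputed from exons).
#' @param exons Tibble with `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param cds,utr5,utr3 Optional tibbles in the same shape as `exons`.
#' @return A `gene_models` object (a named list of tibbles).
#' @export
gene_models <- function(genes = NULL, transcripts = NULL, exons, cds = NULL,
                        utr5 = NULL, utr3 = NULL) {
  stopifnot(all(exons$end > exons$start))
  exons <- arrange(exons, .data$chrom, .data$start)
  if (nrow(exons) == 0) {
    empty_gene <- tibble(gene_id = character(), chrom = character(),
                         strand = character(), start = numeric(),
                         end = numeric())
    empty_tx <- tibble(transcript_id = character(), gene_id = character(),
                       chrom = character(), strand = character(),
                       start = numeric(), end = numeric())
    return(structure(
      list(genes = empty_gene, transcripts = empty_tx, exons = exons,
           cds = exons, utr5 = exons, utr3 = exons),
      class = "gene_models"
    ))
  }
  transcripts <- exons |>
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  genes <- transcripts |>
    group_by(.data$gene_id, .data$chrom, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop")
  if (!is.null(cds) && (is.null(utr5) || is.null(utr3))) {
    u <- derive_utrs(exons, cds)
    utr5 <- utr5 %||% u$utr5
    utr3 <- utr3 %||% u$utr3
  }
  empty_feat <- tibble(
    transcript_id = character(), gene_id = character(), chrom = character(),
    strand = character(), start = numeric(), end = numeric()
  )
  structure(
    list(
      genes = genes, transcripts = transcripts, exons = exons,
      cds = cds %||% empty_feat, utr5 = utr5 %||% empty_feat,
      utr3 = utr3 %||% empty_feat
    ),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf(
    "<gene_models: %d genes, %d transcripts, %d exons>\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons)
  ))
  invisible(x)
}

#' @export
tidy.gene_models <- function(x, ...) {
  bind_rows(
    mutate(x$exons, feature = "exon"),
    mutate(x$cds, feature = "cds"),
    mutate(x$utr5, feature = "five_utr"),
    mutate(x$utr3, feature = "three_utr")
  ) |>
    arrange(.data$chrom, .data$start)
}

# Exonic sequence upstream (5') / downstream (3') of the CDS, per transcript.
derive_utrs <- function(exons, cds) {
  per_tx <- split(exons, exons$transcript_id)
  cds_tx <- split(cds, cds$transcript_id)
  res5 <- list(); res3 <- list()
  for (tx in names(per_tx)) {
    ex <- per_tx[[tx]]
    cd <- cds_tx[[tx]]
    if (is.null(cd) || nrow(cd) == 0) next
    cds_lo <- min(cd$start); cds_hi <- max(cd$end)
    ir_ex <- as_iranges0(ex$start, ex$end)
    up <- IRanges::restrict(ir_ex, end = cds_lo)         # 1-based: <= cds_lo
    dn <- IRanges::restrict(ir_ex, start = cds_hi + 1L)
    to_tbl <- function(ir) {
      ir <- ir[IRanges::width(ir) > 0]
      if (length(ir) == 0) return(NULL)
      tibble(
        transcript_id = tx, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
        strand = ex$strand[1],
        start = IRanges::start(ir) - 1, end = as.numeric(IRanges::end(ir))
      )
    }
    if (ex$strand[1] == "+") {
      res5[[tx]] <- to_tbl(up); res3[[tx]] <- to_tbl(dn)
    } else {
      res5[[tx]] <- to_tbl(dn); res3[[tx]] <- to_tbl(up)
    }
  }
  list(utr5 = bind_rows(res5), utr3 = bind_rows(res3))
}

#' Read gene models from GTF or GFF3
#'
#' Thin wrapper over `rtracklayer::import()` that normalises either dialect
#' onto the package's `gene_models` container. Exons lacking a parent
#' transcript are skipped with a warning; intervals with `end < start` are
#' an error. GTF and GFF3 encodings of the same gene yield identical
#' objects.
#'
#' @param path Path to a `.gtf` or `.gff3` file.
#' @param dialect `"GTF"`, `"GFF3"` or `"auto"` (by file extension).
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, dialect = c("auto", "GTF", "GFF3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else "GTF"
  }
  gr <- rtracklayer::import(path, format = if (dialect == "GTF") "gtf" else "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$type <- as.character(df$type)
  if (dialect == "GFF3") {
    # recover gene_id / transcript_id linkage from ID/Parent attributes
    parent <- vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
    id <- as.character(df$ID)
    tx_rows <- df$type %in% c("mRNA", "transcript")
    tx2gene <- setNames(parent[tx_rows], id[tx_rows])
    df$transcript_id <- ifelse(tx_rows, id, parent)
    df$gene_id <- ifelse(
      df$type == "gene", id,
      ifelse(tx_rows, parent, unname(tx2gene[parent]))
    )
  }
  if (any(df$end < df$start)) abort("Gene annotation interval with end < start.")
  is_exon <- df$type == "exon"
  known_tx <- df$transcript_id[df$type %in% c("mRNA", "transcript")]
  orphan <- is_exon & (is.na(df$transcript_id) |
    (length(known_tx) > 0 & !(df$transcript_id %in% known_tx)))
  if (any(orphan)) {
    warn(sprintf("Skipping %d exon(s) without a parent transcript.", sum(orphan)))
    df <- df[!orphan, ]
    is_exon <- df$type == "exon"
  }
  feat <- function(types) {
    sel <- df[df$type %in% types, ]
    tibble(
      transcript_id = sel$transcript_id, gene_id = sel$gene_id,
      chrom = as.character(sel$seqnames), strand = as.character(sel$strand),
      start = sel$start - 1, end = as.numeric(sel$end)
    )
  }
  exons <- feat("exon")
  cds <- feat("CDS")
  utr5 <- feat(c("five_prime_utr", "five_prime_UTR", "5UTR"))
  utr3 <- feat(c("three_prime_utr", "three_prime_UTR", "3UTR"))
  gene_models(
    genes = NULL, transcripts = NULL, exons = exons,
    cds = if (nrow(cds)) cds else NULL,
    utr5 = if (nrow(utr5)) utr5 else NULL,
    utr3 = if (nrow(utr3)) utr3 else NULL
  )
}

#' Write gene models as GTF
#'
#' Emits gene, transcript, exon (and, when present, CDS and UTR) features
#' with 1-based inclusive coordinates and `gene_id`/`transcript_id`
#' attributes; the inverse of [read_gene_models()].
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @export
write_gtf <- function(models, path) {
  line <- function(chrom, type, start, end, strand, gene_id, tx_id = NULL) {
    attrs <- sprintf('gene_id "%s";', gene_id)
    if (!is.null(tx_id)) {
      attrs <- paste0(attrs, sprintf(' transcript_id "%s";', tx_id))
    }
    sprintf("%s\tteeco\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(start + 1), as.integer(end), strand, attrs)
  }
  out <- c(
    line(models$genes$chrom, "gene", models$genes$start, models$genes$end,
         models$genes$strand, models$genes$gene_id),
    line(models$transcripts$chrom, "transcript", models$transcripts$start,
         models$transcripts$end, models$transcripts$strand,
         models$transcripts$gene_id, models$transcripts$transcript_id)
  )
  feat_lines <- function(tbl, type) {
    if (nrow(tbl) == 0) return(character())
    line(tbl$chrom, type, tbl$start, tbl$end, tbl$strand, tbl$gene_id,
         tbl$transcript_id)
  }
  out <- c(
    out,
    feat_lines(models$exons, "exon"),
    feat_lines(models$cds, "CDS"),
    feat_lines(models$utr5, "five_prime_utr"),
    feat_lines(models$utr3, "three_prime_utr")
  )
  writeLines(out, path)
  invisible(path)
}
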