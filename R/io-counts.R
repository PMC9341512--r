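#' Construct a count matrix with a stage x replicate design
#'
#' The central expression container: a nonnegative integer matrix with row
#' identifiers (TE loci or genes) and a column design mapping every sample
#' to a developmental stage and replicate. Stages are an ordered factor —
#' the developmental series — and a subset of rows may be flagged as
#' spike-in controls for spike-in normalization.
#'
#' @param counts Integer matrix, rows named by locus/gene id, columns by
#'   sample id. Negative or non-integer values are an error.
#' @param design Tibble with `sample_id`, `stage`, `replicate`; optionally
#'   `pre_zga` (logical, stages before zygotic genome activation).
#' @param stage_order Character vector giving the developmental order of
#'   stages; defaults to order of first appearance in `design`.
#' @param spike_in_rows Character vector of spike-in row ids.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, design, stage_order = NULL,
                         spike_in_rows = character()) {
  counts <- as.matrix(counts)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Count at row '%s', sample '%s' is negative or non-integral (%s).",
      rownames(counts)[bad[1, 1]] %||% bad[1, 1],
      colnames(counts)[bad[1, 2]] %||% bad[1, 2],
      format(counts[bad[1, , drop = FALSE]])
    ))
  }
  if (!setequal(colnames(counts), design$sample_id) ||
      ncol(counts) != nrow(design)) {
    abort("`design` must list exactly the samples in `colnames(counts)`.")
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  stage_order <- stage_order %||% unique(design$stage)
  if (!all(design$stage %in% stage_order)) {
    abort("Sample with a stage missing from `stage_order`.")
  }
  design$stage <- factor(design$stage, levels = stage_order)
  if (!all(spike_in_rows %in% rownames(counts))) {
    abort("`spike_in_rows` must be a subset of rownames(counts).")
  }
  structure(
    list(counts = counts, design = design, spike_in_rows = spike_in_rows),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix: %d rows x %d samples, %d stages, %d spike-ins>\n",
    nrow(x$counts), ncol(x$counts), nlevels(x$design$stage),
    length(x$spike_in_rows)
  ))
  invisible(x)
}

#' @export
tidy.count_matrix <- function(x, ...) {
  as_tibble(x$counts, rownames = "row_id") |>
    tidyr::pivot_longer(-"row_id", names_to = "sample_id", values_to = "count") |>
    left_join(x$design, by = "sample_id")
}

#' Read/write count matrices as TSV with a design sidecar
#'
#' The matrix TSV has the row id in the first column and one column per
#' sample; the design TSV declares the `(stage, replicate)` of every
#' sample. Round trips are exact.
#'
#' @param path Matrix TSV path.
#' @param design_path Design TSV path (columns `sample_id`, `stage`,
#'   `replicate`, optional `pre_zga`).
#' @param spike_in_rows Spike-in row ids.
#' @inheritParams count_matrix
#' @export
read_count_matrix <- function(path, design_path, stage_order = NULL,
                              spike_in_rows = character()) {
  tab <- read.delim(path, check.names = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  design <- as_tibble(read.delim(design_path, check.names = FALSE))
  design$stage <- as.character(design$stage)
  missing <- setdiff(colnames(mat), design$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Sample '%s' missing from the design sidecar.", missing[1]))
  }
  if ("pre_zga" %in% names(design)) design$pre_zga <- as.logical(design$pre_zga)
  count_matrix(mat, design, stage_order, spike_in_rows)
}

#' @rdname read_count_matrix
#' @param x A `count_matrix`.
#' @export
write_count_matrix <- function(x, path, design_path) {
  tab <- data.frame(row_id = rownames(x$counts), x$counts, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  design <- x$design
  design$stage <- as.character(design$stage)
  write.table(design, design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
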