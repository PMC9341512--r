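#' Read and write BED intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#' A `.` strand is stored as `NA` (strand unknown). Writing then reading is
#' the identity on `(chrom, start, end, name, strand)`.
#'
#' @param path File path.
#' @return `read_bed()` returns a tibble with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand` (columns absent from the file are
#'   filled with defaults).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      name = character(), score = numeric(), strand = character()
    ))
  }
  fields <- stringr::str_split(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("BED line %d has fewer than 3 fields.", which(nf < 3)[1]))
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[i] else default, character(1))
  }
  strand <- get(6, ".")
  tibble(
    chrom = get(1, NA_character_),
    start = as.numeric(get(2, NA_character_)),
    end = as.numeric(get(3, NA_character_)),
    name = get(4, "."),
    score = suppressWarnings(as.numeric(get(5, "0"))),
    strand = ifelse(strand == ".", NA_character_, strand)
  )
}

#' @rdname read_bed
#' @param intervals Tibble with at least `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @export
write_bed <- function(intervals, path) {
  col_or <- function(nm, default) {
    if (nm %in% names(intervals)) intervals[[nm]] else rep(default, nrow(intervals))
  }
  name <- col_or("name", ".")
  score <- col_or("score", 0)
  strand <- col_or("strand", NA_character_)
  strand[is.na(strand)] <- "."
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t%g\t%s",
    intervals$chrom, as.integer(intervals$start), as.integer(intervals$end),
    name, score, strand
  ), path)
  invisible(path)
}
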