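# Shared internal helpers.

# Convert internal 0-based half-open intervals to an IRanges object.
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = end)
}

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Distance in bp between two half-open intervals: 0 iff they overlap,
# otherwise the gap plus one (bedtools `closest -d` convention), so that a
# zero distance always means genuine overlap.
interval_distance <- function(start1, end1, start2, end2) {
  gap <- pmax(start2 - end1, start1 - end2)
  ifelse(gap < 0, 0, gap + 1)
}

# Seeded evaluation that does not disturb the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Stop unless `x` is a single finite number.
check_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  invisible(x)
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
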