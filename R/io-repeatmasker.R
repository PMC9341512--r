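#' Map RepeatMasker class/family strings to TE classes and superfamilies
#'
#' RepeatMasker annotates each hit with a `class/superfamily` string such as
#' `"DNA/hAT-Charlie"` or `"LTR/Gypsy"`. This helper splits that string and
#' collapses the class token onto the eight-way TE class set used throughout
#' the package: `DNA`, `RC` (rolling-circle / Helitron), `LTR`, `LINE`,
#' `SINE`, `RetroOther` (retroelements outside the three canonical classes),
#' `Satellite` and `Other`. `RC` and `Satellite` are kept distinct from `DNA`
#' and `Other` because rolling-circle elements and pericentromeric satellites
#' behave differently in every downstream distribution analysis.
#'
#' @param class_family Character vector of RepeatMasker `class/family`
#'   strings.
#' @param class_map Optional two-column data frame (`rm_class`, `te_class`)
#'   overriding the default mapping of the leading token.
#' @return A tibble with columns `te_class` and `superfamily`.
#' @export
te_class_map <- function(class_family, class_map = NULL) {
  pieces <- stringr::str_split_fixed(class_family, "/", 2)
  rm_class <- sub("\\?$", "", pieces[, 1])
  superfamily <- sub("\\?$", "", pieces[, 2])
  superfamily[superfamily == ""] <- rm_class[superfamily == ""]
  default <- c(
    DNA = "DNA", RC = "RC", LTR = "LTR", LINE = "LINE", SINE = "SINE",
    Retroposon = "RetroOther", SVA = "RetroOther", Satellite = "Satellite"
  )
  te_class <- unname(default[rm_class])
  te_class[is.na(te_class)] <- "Other"
  if (!is.null(class_map)) {
    idx <- match(rm_class, class_map$rm_class)
    te_class[!is.na(idx)] <- class_map$te_class[idx[!is.na(idx)]]
  }
  tibble(te_class = te_class, superfamily = superfamily)
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the standard RepeatMasker `.out` dialect: three header lines
#' followed by whitespace-delimited hit records. Genome coordinates are
#' converted from the file's 1-based inclusive convention to the package's
#' internal 0-based half-open convention. Minus-strand hits (flagged `C`)
#' report their consensus coordinates in reversed column order
#' (`(left) end begin`); these are normalised so that
#' `cons_start <= cons_end` always holds, with `strand` set to `"-"`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @param class_map Optional class mapping passed to [te_class_map()].
#' @return A tibble of TE fragments with columns `chrom`, `start`, `end`,
#'   `strand`, `family`, `superfamily`, `te_class`, `divergence_pct`,
#'   `score`, `cons_start`, `cons_end`, `cons_left`, `rm_id`.
#' @export
read_repeatmasker_out <- function(path, class_map = NULL) {
  lines <- readLines(path)
  body <- if (length(lines) > 3) lines[-(1:3)] else character()
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) return(empty_fragments())
  fields <- stringr::str_split(trimws(body), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 14)
  if (length(bad) > 0) {
    abort(sprintf(
      "Malformed RepeatMasker record at line %d: expected >= 14 columns, got %d.",
      bad[1] + 3L, nf[bad[1]]
    ))
  }
  mat <- t(vapply(fields, function(f) f[1:15], character(15)))
  num <- function(j, what, paren = FALSE) {
    x <- mat[, j]
    if (paren) x <- gsub("[()]", "", x)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-numeric %s ('%s') at line %d of RepeatMasker file.",
        what, x[bad[1]], bad[1] + 3L
      ))
    }
    out
  }
  strand_raw <- mat[, 9]
  strand <- ifelse(strand_raw == "C", "-", strand_raw)
  # consensus columns: plus strand 'begin end (left)', C strand '(left) end begin'
  c12 <- num(12, "consensus coordinate", paren = TRUE)
  c13 <- num(13, "consensus coordinate", paren = TRUE)
  c14 <- num(14, "consensus coordinate", paren = TRUE)
  minus <- strand == "-"
  cons_start <- ifelse(minus, c14, c12)
  cons_end <- c13
  cons_left <- ifelse(minus, c12, c14)
  rm_id <- mat[, 15]
  rm_id[is.na(rm_id) | rm_id == "*" | rm_id == ""] <- NA_character_
  cls <- te_class_map(mat[, 11], class_map)
  tibble(
    chrom = mat[, 5],
    start = num(6, "genome start") - 1,
    end = num(7, "genome end"),
    strand = strand,
    family = mat[, 10],
    superfamily = cls$superfamily,
    te_class = cls$te_class,
    divergence_pct = num(2, "divergence"),
    score = num(1, "score"),
    cons_start = cons_start,
    cons_end = cons_end,
    cons_left = cons_left,
    rm_id = rm_id
  )
}

empty_fragments <- function() {
  tibble(
    chrom = character(), start = numeric(), end = numeric(),
    strand = character(), family = character(), superfamily = character(),
    te_class = character(), divergence_pct = numeric(), score = numeric(),
    cons_start = numeric(), cons_end = numeric(), cons_left = numeric(),
    rm_id = character()
  )
}

#' Write TE fragments as a RepeatMasker .out file
#'
#' Emits the inverse of [read_repeatmasker_out()]: internal 0-based
#' half-open coordinates become 1-based inclusive, minus strands are written
#' as `C` with consensus columns in reversed order. Round-tripping through
#' the reader recovers the input tibble field by field.
#'
#' @param fragments Fragment tibble (see [read_repeatmasker_out()]).
#' @param path Output path.
#' @param class_family Optional character vector of `class/family` strings;
#'   by default rebuilt as `te_class/superfamily`.
#' @export
write_repeatmasker_out <- function(fragments, path, class_family = NULL) {
  hdr <- c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""
  )
  if (is.null(class_family)) {
    class_family <- paste0(fragments$te_class, "/", fragments$superfamily)
  }
  minus <- fragments$strand == "-"
  c12 <- ifelse(minus, sprintf("(%d)", as.integer(fragments$cons_left)),
                sprintf("%d", as.integer(fragments$cons_start)))
  c13 <- sprintf("%d", as.integer(fragments$cons_end))
  c14 <- ifelse(minus, sprintf("%d", as.integer(fragments$cons_start)),
                sprintf("(%d)", as.integer(fragments$cons_left)))
  rows <- sprintf(
    "%d %.1f 0.0 0.0 %s %d %d (0) %s %s %s %s %s %s %s",
    as.integer(fragments$score), fragments$divergence_pct, fragments$chrom,
    as.integer(fragments$start + 1), as.integer(fragments$end),
    ifelse(minus, "C", "+"), fragments$family, class_family,
    c12, c13, c14,
    ifelse(is.na(fragments$rm_id), "*", fragments$rm_id)
  )
  writeLines(c(hdr, rows), path)
  invisible(path)
}
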