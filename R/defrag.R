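#' Default defragmentation parameters
#'
#' `max_gap_bp` bounds the genomic gap bridged between two fragments of one
#' interrupted insertion (a nested element sits inside that gap);
#' `cons_tolerance_bp` is the slack allowed on consensus-coordinate
#' collinearity (repeat margins overlap slightly in practice).
#'
#' @param max_gap_bp Maximum genomic gap in bp between chained fragments.
#' @param cons_tolerance_bp Tolerance on consensus collinearity in bp.
#' @export
defrag_params <- function(max_gap_bp = 5000, cons_tolerance_bp = 50) {
  list(max_gap_bp = max_gap_bp, cons_tolerance_bp = cons_tolerance_bp)
}

#' Can two fragments be merged into one locus?
#'
#' Pure predicate on an ordered fragment pair (`f1` upstream of `f2` in
#' genome order): they chain iff they share chromosome, strand and family,
#' their genomic gap is at most `max_gap_bp`, and their consensus
#' coordinates are collinear in the strand-appropriate direction within
#' `cons_tolerance_bp` — on the plus strand the downstream fragment must
#' resume at or after `cons_end - tolerance` of the upstream one; on the
#' minus strand the mirror condition applies (consensus runs right to left
#' along the genome).
#'
#' @param f1,f2 Single-row fragment tibbles (or lists) with `chrom`,
#'   `start`, `end`, `strand`, `family`, `cons_start`, `cons_end`.
#' @param params See [defrag_params()].
#' @return Logical scalar.
#' @export
is_mergeable <- function(f1, f2, params = defrag_params()) {
  if (f1$chrom != f2$chrom || f1$strand != f2$strand ||
      f1$family != f2$family) {
    return(FALSE)
  }
  gap <- f2$start - f1$end
  if (gap > params$max_gap_bp) return(FALSE)
  if (f1$strand == "+") {
    f2$cons_start >= f1$cons_end - params$cons_tolerance_bp
  } else {
    f2$cons_end <= f1$cons_start + params$cons_tolerance_bp
  }
}

#' Reconstruct TE loci from fragmented repeat hits
#'
#' Merges annotation fragments that represent one interrupted insertion.
#' Fragments sharing a non-missing `rm_id` are always merged (split by
#' chromosome with a warning if an id spans chromosomes). Beyond that,
#' fragments are grouped by (chromosome, strand, family) and consecutive
#' group members satisfying [is_mergeable()] are chained; connected chains
#' form one locus. An interruption by a different family does not break a
#' chain as long as the bridged gap stays within `max_gap_bp`. The family
#' copy number is its locus count.
#'
#' @param fragments Fragment tibble (see [read_repeatmasker_out()]).
#' @param params See [defrag_params()].
#' @return A locus tibble with one row per reconstructed locus: `locus_id`,
#'   `chrom`, `start`, `end` (hull), `strand`, `family`, `superfamily`,
#'   `te_class`, `n_fragments`, `total_bp` (summed fragment lengths),
#'   `divergence_pct` (length-weighted mean), `is_full_length_ltr`
#'   (all `FALSE` here; see [reconstruct_ltr()]), and a `fragments`
#'   list-column holding each locus's member fragments.
#' @export
defragment <- function(fragments, params = defrag_params()) {
  n <- nrow(fragments)
  if (n == 0) {
    return(empty_loci())
  }
  fragments <- arrange(fragments, .data$chrom, .data$start, .data$end)
  comp <- seq_len(n) # union-find parent vector
  find <- function(i) {
    while (comp[i] != i) {
      comp[i] <<- comp[comp[i]]
      i <- comp[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) comp[max(ri, rj)] <<- min(ri, rj)
  }
  # rm_id groups merge unconditionally (within one chromosome)
  if (!all(is.na(fragments$rm_id))) {
    grp <- split(seq_len(n), fragments$rm_id)
    for (idx in grp) {
      if (length(idx) < 2) next
      chroms <- fragments$chrom[idx]
      if (length(unique(chroms)) > 1) {
        warn(sprintf("rm_id '%s' spans multiple chromosomes; split by chromosome.",
                     fragments$rm_id[idx[1]]))
      }
      for (ch in unique(chroms)) {
        sub <- idx[chroms == ch]
        if (length(sub) > 1) for (j in sub[-1]) union_(sub[1], j)
      }
    }
  }
  # chain genome-order neighbours within (chrom, strand, family) groups
  key <- paste(fragments$chrom, fragments$strand, fragments$family, sep = "\r")
  for (idx in split(seq_len(n), key)) {
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      if (is_mergeable(fragments[a, ], fragments[b, ], params)) union_(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  build_loci(fragments, roots)
}

empty_loci <- function() {
  tibble(
    locus_id = character(), chrom = character(), start = numeric(),
    end = numeric(), strand = character(), family = character(),
    superfamily = character(), te_class = character(),
    n_fragments = integer(), total_bp = numeric(), divergence_pct = numeric(),
    is_full_length_ltr = logical(), fragments = list()
  )
}

build_loci <- function(fragments, roots) {
  fragments$.root <- roots
  loci <- fragments |>
    group_by(.data$.root) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand), family = first(.data$family),
      superfamily = first(.data$superfamily),
      te_class = first(.data$te_class),
      n_fragments = dplyr::n(),
      # fragment-level quantities must precede the hull collapse below:
      # summarise evaluates sequentially and start/end become scalars
      total_bp = sum(.data$end - .data$start),
      divergence_pct = sum(.data$divergence_pct * (.data$end - .data$start)) /
        sum(.data$end - .data$start),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start)
  frag_split <- split(select(fragments, -".root"), fragments$.root)
  loci$fragments <- unname(frag_split[as.character(loci$.root)])
  loci |>
    mutate(
      locus_id = sprintf("locus%05d", row_number()),
      is_full_length_ltr = FALSE
    ) |>
    select(-".root") |>
    select("locus_id", dplyr::everything())
}

#' Merge LTR-internal-LTR triples into full-length LTR loci
#'
#' LTR retroelements are annotated as separate long-terminal-repeat and
#' internal-sequence families (`<stem>-LTR` / `<stem>-int` by naming
#' convention, or an explicit pairing table). A run
#' LTR - internal - LTR of one stem on one strand, with genomic gaps at
#' most `max_gap_bp`, collapses into a single locus flagged
#' `is_full_length_ltr`. An internal locus with only one flanking LTR is
#' merged too but not flagged (full length requires both LTRs); solo LTRs
#' stay as separate unflagged loci.
#'
#' @param loci Locus tibble from [defragment()].
#' @param pairing Optional tibble with `ltr_name`, `internal_name`; by
#'   default derived from family names (`-LTR`/`_LTR` vs `-int`/`-I`/`_I`
#'   suffixes).
#' @param params See [defrag_params()].
#' @return Locus tibble in the same shape, with triples merged.
#' @export
reconstruct_ltr <- function(loci, pairing = NULL, params = defrag_params()) {
  if (nrow(loci) == 0) return(loci)
  stem_of <- function(fam, role) {
    if (is.null(pairing)) {
      if (role == "ltr") sub("([-_](LTR|ltr))$", "", fam)
      else sub("([-_](int|INT|I))$", "", fam)
    } else {
      map <- if (role == "ltr") {
        setNames(pairing$ltr_name, pairing$ltr_name)
      } else {
        setNames(pairing$ltr_name, pairing$internal_name)
      }
      unname(map[fam])
    }
  }
  is_ltr_name <- if (is.null(pairing)) {
    grepl("[-_](LTR|ltr)$", loci$family)
  } else {
    loci$family %in% pairing$ltr_name
  }
  is_int_name <- if (is.null(pairing)) {
    grepl("[-_](int|INT|I)$", loci$family)
  } else {
    loci$family %in% pairing$internal_name
  }
  stem <- rep(NA_character_, nrow(loci))
  stem[is_ltr_name] <- vapply(loci$family[is_ltr_name], stem_of,
                              character(1), role = "ltr")
  stem[is_int_name] <- vapply(loci$family[is_int_name], stem_of,
                              character(1), role = "int")
  int_stems <- unique(stem[is_int_name])
  orphan <- setdiff(int_stems, stem[is_ltr_name])
  if (length(orphan) > 0) {
    warn(sprintf("Internal famil%s without an LTR partner: %s",
                 if (length(orphan) > 1) "ies" else "y",
                 paste(orphan, collapse = ", ")))
  }
  loci <- arrange(loci, .data$chrom, .data$start)
  n <- nrow(loci)
  group <- seq_len(n)
  full <- logical(n)
  used <- logical(n)
  ints <- which(is_int_name)
  for (i in ints) {
    # nearest unused same-stem LTR locus within max_gap_bp on either side
    # (an unrelated insertion between the LTR and the internal part does
    # not break the pairing)
    cand <- which(
      is_ltr_name & !used & stem == stem[i] &
        loci$chrom == loci$chrom[i] & loci$strand == loci$strand[i]
    )
    up <- cand[loci$end[cand] <= loci$start[i] &
                 loci$start[i] - loci$end[cand] <= params$max_gap_bp]
    dn <- cand[loci$start[cand] >= loci$end[i] &
                 loci$start[cand] - loci$end[i] <= params$max_gap_bp]
    prev <- if (length(up) > 0) up[which.max(loci$end[up])] else NA
    nxt <- if (length(dn) > 0) dn[which.min(loci$start[dn])] else NA
    if (!is.na(prev)) { group[prev] <- group[i]; used[prev] <- TRUE }
    if (!is.na(nxt)) { group[nxt] <- group[i]; used[nxt] <- TRUE }
    full[i] <- !is.na(prev) && !is.na(nxt)
  }
  merged <- loci |>
    mutate(.grp = group, .full = full, .is_int = is_int_name) |>
    group_by(.data$.grp) |>
    summarise(
      chrom = first(.data$chrom), strand = first(.data$strand),
      family = if (any(.data$.is_int)) .data$family[.data$.is_int][1]
               else first(.data$family),
      superfamily = first(.data$superfamily),
      te_class = first(.data$te_class),
      n_fragments = sum(.data$n_fragments),
      divergence_pct = sum(.data$divergence_pct * .data$total_bp) /
        sum(.data$total_bp),
      total_bp = sum(.data$total_bp),
      is_full_length_ltr = any(.data$.full),
      fragments = list(bind_rows(.data$fragments)),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop"
    ) |>
    select(-".grp") |>
    arrange(.data$chrom, .data$start) |>
    mutate(locus_id = sprintf("locus%05d", row_number())) |>
    select("locus_id", dplyr::everything())
  merged
}
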