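#' Global alignment of a TE copy to its family consensus
#'
#' Needleman-Wunsch global alignment with affine gap penalties, via
#' Biostrings. Returns the two aligned rows (equal length, gaps as `-`).
#'
#' @param copy_seq,consensus_seq Nucleotide strings (A/C/G/T/N).
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Affine gap penalties (positive numbers).
#' @return List with `copy` and `consensus` aligned strings and `score`.
#' @export
align_to_consensus <- function(copy_seq, consensus_seq, match = 2,
                               mismatch = -2, gap_open = 8, gap_extend = 1) {
  if (!nzchar(copy_seq) || !nzchar(consensus_seq)) {
    abort("Cannot align an empty sequence.")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = copy_seq, subject = consensus_seq, type = "global",
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend
  )
  list(
    copy = as.character(Biostrings::alignedPattern(aln)),
    consensus = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Kimura two-parameter divergence with optional CpG correction
#'
#' Computes `d = -1/2 * ln[(1 - 2P - Q) * sqrt(1 - 2Q)]`, where `P` and `Q`
#' are the transition and transversion proportions over ungapped aligned
#' columns. With `exclude_cpg = TRUE`, columns whose *consensus* base is
#' part of a CpG dinucleotide (in consensus coordinates) are dropped before
#' computing `P` and `Q` — CpG sites are hypermutable, so including them
#' overestimates the age of old elements. Saturated alignments (formula
#' argument non-positive) return `d = NA` with `saturated = TRUE`.
#'
#' @param copy_row,consensus_row Equal-length aligned rows (gaps `-`).
#' @param exclude_cpg Drop CpG consensus columns before counting.
#' @return Tibble with `d` (substitutions/site), `divergence_pct`
#'   (`100 * d`), `P`, `Q`, `n_sites`, `saturated`.
#' @export
kimura_divergence <- function(copy_row, consensus_row, exclude_cpg = FALSE) {
  a <- strsplit(toupper(copy_row), "")[[1]]
  b <- strsplit(toupper(consensus_row), "")[[1]]
  if (length(a) != length(b)) {
    abort("Aligned rows must have equal length.")
  }
  if (exclude_cpg) {
    # CpG status lives in consensus coordinates: project out gaps first
    cons_pos <- which(b != "-")
    cons <- b[cons_pos]
    nc <- length(cons)
    cpg <- rep(FALSE, nc)
    if (nc > 1) {
      is_cg <- cons[-nc] == "C" & cons[-1] == "G"
      cpg[which(is_cg)] <- TRUE
      cpg[which(is_cg) + 1] <- TRUE
    }
    drop <- cons_pos[cpg]
    if (length(drop) > 0) {
      a <- a[-drop]
      b <- b[-drop]
    }
  }
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[valid]; b <- b[valid]
  n <- length(a)
  if (n == 0) {
    return(tibble(d = NA_real_, divergence_pct = NA_real_, P = NA_real_,
                  Q = NA_real_, n_sites = 0L, saturated = FALSE))
  }
  diffs <- a != b
  purine <- c("A", "G")
  ts <- diffs & ((a %in% purine) == (b %in% purine))
  P <- sum(ts) / n
  Q <- sum(diffs & !ts) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) {
    return(tibble(d = NA_real_, divergence_pct = NA_real_, P = P, Q = Q,
                  n_sites = n, saturated = TRUE))
  }
  d <- -0.5 * log(arg1 * sqrt(arg2))
  tibble(d = d, divergence_pct = 100 * d, P = P, Q = Q, n_sites = n,
         saturated = FALSE)
}

#' Consensus-anchored multiple alignment of family copies
#'
#' Aligns each copy to the consensus with [align_to_consensus()] and
#' projects it onto the consensus columns: copy insertions relative to the
#' consensus are dropped, copy deletions appear as gaps. Columns occupied
#' by fewer than `occupancy_min` of the copies are then removed (the
#' column-occupancy trimming rule; default 0.01).
#'
#' @param copies Character vector (optionally named) of copy sequences.
#' @param consensus Consensus sequence.
#' @param occupancy_min Minimum fraction of non-gap characters per column.
#' @inheritParams align_to_consensus
#' @return List with `msa` (character matrix, rows = copies, columns =
#'   retained consensus positions), `consensus_row` (character vector) and
#'   `kept_columns` (indices into the consensus).
#' @export
consensus_anchored_msa <- function(copies, consensus, occupancy_min = 0.01,
                                   match = 2, mismatch = -2, gap_open = 8,
                                   gap_extend = 1) {
  nc <- nchar(consensus)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(copies), subject = consensus,
    type = "global", substitutionMatrix = mat, gapOpening = gap_open,
    gapExtension = gap_extend
  )
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  rows <- matrix("-", nrow = length(copies), ncol = nc)
  for (i in seq_along(copies)) {
    ca <- strsplit(pat[i], "")[[1]]
    sa <- strsplit(sub[i], "")[[1]]
    rows[i, ] <- ca[sa != "-"]
  }
  occ <- colMeans(rows != "-")
  kept <- which(occ >= occupancy_min)
  list(
    msa = rows[, kept, drop = FALSE],
    consensus_row = strsplit(consensus, "")[[1]][kept],
    kept_columns = kept
  )
}

#' Neighbor-joining tree with terminal branch lengths
#'
#' Classic neighbor joining on a symmetric distance matrix, with negative
#' estimated branch lengths clamped to zero. The statistic of interest
#' downstream is the terminal (pendant) branch length of each tip — the
#' distance from a TE copy to its most recent shared node.
#'
#' @param d Symmetric numeric matrix (or `dist`) with zero diagonal,
#'   `n >= 3` taxa.
#' @return List with `tree` (an `ape` `phylo`) and `terminal` (named
#'   numeric vector of pendant branch lengths per tip).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("Neighbor joining needs at least 3 taxa.")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  term_idx <- match(seq_along(tree$tip.label), tree$edge[, 2])
  terminal <- setNames(tree$edge.length[term_idx], tree$tip.label)
  list(tree = tree, terminal = terminal)
}

#' Estimate the age of a TE family from its copies
#'
#' Implements the family-age statistic: defragmented copy sequences shorter
#' than `min_len` are dropped; a family with fewer than `min_copies`
#' suitable copies is reported as `too_few_copies`; large families are
#' down-sampled to `max_sample` copies (seeded). The retained copies are
#' rendered into a consensus-anchored alignment, pairwise K2P distances
#' (pairwise deletion of gapped sites) feed a neighbor-joining tree, and
#' the family age is the median terminal branch length in substitutions per
#' site. The median CpG-corrected K2P divergence to the consensus is
#' reported alongside as the alternative age measure.
#'
#' @param copies Character vector of defragmented copy sequences.
#' @param consensus Family consensus sequence.
#' @param min_len Minimum copy length in bp (default 100).
#' @param min_copies Minimum suitable copies (default 10).
#' @param max_sample Copy cap for the alignment/tree (default 1250).
#' @param occupancy_min Column-occupancy trimming threshold.
#' @param exclude_cpg_divergence CpG correction for the consensus-divergence
#'   measure (default on; tree distances are uncorrected).
#' @param family Family name carried into the result.
#' @param seed Seed for the down-sampling step.
#' @return One-row tibble: `family`, `n_loci_total`, `n_used`,
#'   `median_terminal_branch`, `median_divergence_pct`, `status`.
#' @export
estimate_family_age <- function(copies, consensus, min_len = 100,
                                min_copies = 10, max_sample = 1250,
                                occupancy_min = 0.01,
                                exclude_cpg_divergence = TRUE,
                                family = NA_character_, seed = NULL) {
  if (is.null(consensus) || is.na(consensus) || !nzchar(consensus)) {
    abort("A family consensus sequence is required.")
  }
  n_total <- length(copies)
  copies <- copies[nchar(copies) >= min_len]
  if (length(copies) < min_copies) {
    return(tibble(
      family = family, n_loci_total = n_total, n_used = length(copies),
      median_terminal_branch = NA_real_, median_divergence_pct = NA_real_,
      status = "too_few_copies"
    ))
  }
  if (length(copies) > max_sample) {
    copies <- with_seed(seed, sample(copies, max_sample))
  }
  msa <- consensus_anchored_msa(copies, consensus,
                                occupancy_min = occupancy_min)
  cons_row <- paste(msa$consensus_row, collapse = "")
  divs <- vapply(seq_len(nrow(msa$msa)), function(i) {
    kimura_divergence(paste(msa$msa[i, ], collapse = ""), cons_row,
                      exclude_cpg = exclude_cpg_divergence)$divergence_pct
  }, numeric(1))
  dmat <- k2p_distance_matrix(msa$msa)
  terminal <- if (nrow(dmat) == 2) {
    rep(dmat[1, 2] / 2, 2)
  } else {
    nj_tree(dmat)$terminal
  }
  tibble(
    family = family, n_loci_total = n_total, n_used = length(copies),
    median_terminal_branch = median(terminal, na.rm = TRUE),
    median_divergence_pct = median(divs, na.rm = TRUE),
    status = "ok"
  )
}

# Pairwise K2P distances over MSA rows with pairwise deletion, via
# ape::dist.dna (saturated/NaN pairs fall back to the maximum observed
# finite distance).
k2p_distance_matrix <- function(msa) {
  rownames(msa) <- paste0("c", seq_len(nrow(msa)))
  bin <- ape::as.DNAbin(tolower(msa))
  d <- as.matrix(ape::dist.dna(bin, model = "K80", pairwise.deletion = TRUE))
  bad <- !is.finite(d)
  if (any(bad)) {
    mx <- max(d[is.finite(d)], 0)
    d[bad] <- mx
    diag(d) <- 0
  }
  d
}

#' Estimate ages for many families
#'
#' Maps [estimate_family_age()] over a sequence table, one family at a
#' time.
#'
#' @param sequences Tibble with `family` and `seq` columns (one row per
#'   defragmented copy).
#' @param consensi Named character vector or tibble (`family`,
#'   `consensus_seq`) of family consensus sequences.
#' @param ... Passed to [estimate_family_age()].
#' @param seed Seed used (plus an offset per family) for down-sampling.
#' @return A `family_age` tibble, one row per family.
#' @export
estimate_family_ages <- function(sequences, consensi, ..., seed = NULL) {
  if (is.data.frame(consensi)) {
    consensi <- setNames(consensi$consensus_seq, consensi$family)
  }
  fams <- unique(sequences$family)
  out <- vector("list", length(fams))
  for (i in seq_along(fams)) {
    fam <- fams[i]
    if (!fam %in% names(consensi)) next
    out[[i]] <- estimate_family_age(
      sequences$seq[sequences$family == fam], consensi[[fam]],
      family = fam, seed = if (is.null(seed)) NULL else seed + i, ...
    )
  }
  res <- bind_rows(out)
  class(res) <- c("family_age", class(res))
  res
}

#' @export
glance.family_age <- function(x, ...) {
  ok <- filter(x, .data$status == "ok")
  tibble(
    n_families = nrow(x), n_ok = nrow(ok),
    median_age = median(ok$median_terminal_branch),
    median_divergence_pct = median(ok$median_divergence_pct)
  )
}
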