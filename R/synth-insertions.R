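#' Simulate a panel of TE families
#'
#' Draws a family table spanning the major TE classes (DNA, RC, LTR, LINE,
#' SINE, Satellite) with log-spread copy numbers and per-family ages. By
#' default the planted age `t` (expected substitutions/site) increases with
#' log copy number plus noise, reproducing the positive age/copy-number
#' rank correlation observed in real TE demographies. LTR families come as
#' `<stem>-LTR` / `<stem>-int` pairs sharing a stem, so full-length
#' reconstruction is exercised.
#'
#' @param n_families Number of families (LTR pairs count once).
#' @param copy_log10_range Range of log10 copy number, uniform.
#' @param age_slope,age_noise_sd Age rule: `t = age_slope * log10(copies) +
#'   N(0, age_noise_sd)`, floored at `age_floor`.
#' @param age_floor Minimum planted age.
#' @param seed Optional seed.
#' @return Tibble with columns `family`, `superfamily`, `te_class`,
#'   `consensus_len`, `consensus_seq`, `copy_number`, `age_t`,
#'   `ltr_stem` (NA unless part of an LTR pair), `ltr_role`
#'   (`"ltr"`/`"int"`/NA).
#' @export
simulate_te_families <- function(n_families = 40,
                                 copy_log10_range = c(0.6, 1.9),
                                 age_slope = 0.05, age_noise_sd = 0.015,
                                 age_floor = 0.004, seed = NULL) {
  with_seed(seed, {
    class_pool <- c(
      DNA = 0.35, LINE = 0.2, LTR = 0.15, SINE = 0.12, RC = 0.1,
      Satellite = 0.08
    )
    classes <- sample(names(class_pool), n_families, replace = TRUE,
                      prob = class_pool)
    sup_of <- list(
      DNA = c("hAT-Charlie", "TcMar-Tc1", "PIF-Harbinger", "CMC-EnSpm"),
      RC = "Helitron", LTR = c("Gypsy", "ERV1", "Pao"),
      LINE = c("L1", "L2", "Rex-Babar", "I"), SINE = c("tRNA", "tRNA-V"),
      Satellite = "Satellite"
    )
    len_of <- list(
      DNA = c(800, 2500), RC = c(1500, 3000), LTR = c(2500, 4200),
      LINE = c(3000, 5000), SINE = c(150, 400), Satellite = c(200, 600)
    )
    log10cn <- runif(n_families, copy_log10_range[1], copy_log10_range[2])
    rows <- vector("list", n_families)
    for (i in seq_len(n_families)) {
      cls <- classes[i]
      sup <- sample(sup_of[[cls]], 1)
      fam <- sprintf("%s-%d_DR", sup, i)
      cn <- max(1L, round(10^log10cn[i]))
      age <- max(age_floor, age_slope * log10cn[i] + rnorm(1, 0, age_noise_sd))
      clen <- round(runif(1, len_of[[cls]][1], len_of[[cls]][2]))
      if (cls == "LTR") {
        ltr_len <- round(runif(1, 250, 500))
        rows[[i]] <- tibble(
          family = c(paste0(fam, "-LTR"), paste0(fam, "-int")),
          superfamily = sup, te_class = cls,
          consensus_len = c(ltr_len, clen),
          consensus_seq = c(random_dna(ltr_len), random_dna(clen)),
          copy_number = cn, age_t = age,
          ltr_stem = fam, ltr_role = c("ltr", "int")
        )
      } else {
        rows[[i]] <- tibble(
          family = fam, superfamily = sup, te_class = cls,
          consensus_len = clen, consensus_seq = random_dna(clen),
          copy_number = cn, age_t = age,
          ltr_stem = NA_character_, ltr_role = NA_character_
        )
      }
    }
    bind_rows(rows)
  })
}

#' Evolve a sequence under a two-rate (Kimura) substitution process
#'
#' Each site substitutes independently with transition and transversion
#' probabilities implied by the K2P model at total expected divergence `t`
#' substitutions/site and transition:transversion rate ratio `kappa`, so
#' the downstream K2P estimator is unbiased for `t`. Optionally, sites
#' whose consensus dinucleotide is CpG evolve at `cpg_multiplier` times the
#' base rate.
#'
#' @param seq Consensus nucleotide string (A/C/G/T).
#' @param t Expected substitutions/site (>= 0).
#' @param kappa Transition:transversion rate ratio (alpha/beta).
#' @param cpg_multiplier Rate multiplier for CpG consensus sites (1 = off).
#' @return The evolved sequence (character scalar).
#' @export
evolve_sequence <- function(seq, t, kappa = 2, cpg_multiplier = 1) {
  stopifnot(t >= 0)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  tt <- rep(t, n)
  if (cpg_multiplier != 1 && n > 1) {
    cpg <- which(x[-n] == "C" & x[-1] == "G")
    cpg_sites <- unique(c(cpg, cpg + 1))
    tt[cpg_sites] <- t * cpg_multiplier
  }
  # K2P transition probabilities at distance d: with alpha*t = kappa*d/(kappa+2),
  # beta*t = d/(kappa+2):
  #   P = 1/4 + 1/4 exp(-4 beta t) - 1/2 exp(-2 (alpha+beta) t)
  #   Q = 1/2 - 1/2 exp(-4 beta t)
  bt <- tt / (kappa + 2)
  at <- kappa * tt / (kappa + 2)
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  u <- runif(n)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  transversions_of <- list(
    A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
  )
  out <- x
  is_ts <- u < P
  is_tv <- !is_ts & u < P + Q
  out[is_ts] <- transition_of[x[is_ts]]
  if (any(is_tv)) {
    pick <- runif(sum(is_tv)) < 0.5
    out[is_tv] <- mapply(function(b, p) transversions_of[[b]][1 + p],
                         x[is_tv], pick)
  }
  paste(out, collapse = "")
}

# Realized K2P divergence between two equal-length ungapped strings.
realized_k2p <- function(a, b) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  ok <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  va <- va[ok]; vb <- vb[ok]
  diffs <- va != vb
  purine <- c("A", "G")
  ts <- diffs & ((va %in% purine) == (vb %in% purine))
  P <- mean(ts); Q <- mean(diffs & !ts)
  arg1 <- 1 - 2 * P - Q; arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Plant TE insertions in a simulated genome
#'
#' Places every copy of every family, evolving its sequence from the family
#' consensus at the planted age, with optional 5' truncation (retroelements),
#' fragmentation into collinear pieces, nesting of one insertion inside
#' another, and LTR-internal-LTR triples for LTR families. Young families
#' can be biased towards intergenic placement (`young_intergenic_bias`),
#' planting the age asymmetry between self-expressed and gene-dependent
#' loci.
#'
#' @param genome Output of [simulate_genome()].
#' @param families Family tibble from [simulate_te_families()]; an optional
#'   `p_intergenic` column forces per-family intergenic placement
#'   probability.
#' @param fragmentation_prob Probability an insertion is annotated as >= 2
#'   collinear fragments.
#' @param nesting_prob Probability an insertion is nested inside a
#'   dedicated host insertion of another family.
#' @param truncation_prob Probability a LINE/LTR-internal copy is 5'
#'   truncated.
#' @param young_intergenic_bias When `TRUE` (default), families younger
#'   than the median age get intergenic placement probability 0.85 and
#'   older families 0.45; otherwise placement is uniform.
#' @param kappa,cpg_multiplier Substitution process parameters
#'   (see [evolve_sequence()]).
#' @param share_rm_id When `TRUE`, fragments of one insertion share a
#'   RepeatMasker-style ID (making defragmentation trivial); the default
#'   `FALSE` gives every fragment its own ID so reconstruction must rely on
#'   the collinearity rules.
#' @param seed Optional seed.
#' @return List with `fragments` (TE fragment tibble as from
#'   [read_repeatmasker_out()]), `truth` (one row per planted insertion),
#'   and `sequences` (tibble `locus_id`, `family`, `seq`).
#' @export
simulate_insertions <- function(genome, families,
                                fragmentation_prob = 0.25,
                                nesting_prob = 0.04,
                                truncation_prob = 0.3,
                                young_intergenic_bias = TRUE,
                                kappa = 2, cpg_multiplier = 1,
                                share_rm_id = FALSE, seed = NULL) {
  with_seed(seed, {
    chrom_sizes <- genome$chrom_sizes
    genes <- genome$genes$genes
    gaps <- intergenic_gaps(chrom_sizes, genes)
    med_age <- median(families$age_t)
    if (!"p_intergenic" %in% names(families)) {
      families$p_intergenic <- if (young_intergenic_bias) {
        ifelse(families$age_t <= med_age, 0.85, 0.45)
      } else NA_real_
    }
    # expand one row per insertion (LTR pairs expand as triples)
    fam_units <- families |>
      filter(is.na(.data$ltr_role) | .data$ltr_role == "int")
    frag_rows <- list(); truth_rows <- list(); seq_rows <- list()
    rmid <- 0L; locus_n <- 0L
    for (i in seq_len(nrow(fam_units))) {
      fam <- fam_units[i, ]
      is_ltr <- !is.na(fam$ltr_stem)
      ltr_row <- if (is_ltr) {
        families[families$ltr_stem %in% fam$ltr_stem &
                   families$ltr_role == "ltr", ]
      }
      for (copy in seq_len(fam$copy_number)) {
        locus_n <- locus_n + 1L
        locus_id <- sprintf("te%05d", locus_n)
        outer_cand <- which(
          is.na(families$ltr_role) & families$consensus_len >= 1200 &
            families$family != fam$family
        )
        nested <- runif(1) < nesting_prob && !is_ltr &&
          fam$consensus_len <= 4200 && length(outer_cand) > 0
        ins <- build_insertion(
          fam, ltr_row, locus_id,
          fragment = runif(1) < fragmentation_prob,
          truncate = fam$te_class %in% c("LINE", "LTR") &&
            runif(1) < truncation_prob,
          kappa = kappa, cpg_multiplier = cpg_multiplier
        )
        footprint <- ins$footprint
        host <- NULL
        if (nested) {
          # wrap this insertion inside a dedicated host copy of another family
          outer_fam <- families[outer_cand[sample.int(length(outer_cand), 1)], ]
          locus_n <- locus_n + 1L
          outer_id <- sprintf("te%05d", locus_n)
          outer <- build_insertion(outer_fam, NULL, outer_id, fragment = FALSE,
                                   truncate = FALSE, kappa = kappa,
                                   cpg_multiplier = cpg_multiplier)
          placed <- place_insertion(outer$footprint + footprint, chrom_sizes,
                                    gaps, outer_fam$p_intergenic)
          split_at <- round(outer$footprint * runif(1, 0.3, 0.7))
          nest <- nest_fragments(outer, ins, placed, split_at)
          frag_rows <- c(frag_rows, list(nest$fragments))
          truth_rows <- c(truth_rows, list(nest$truth))
          seq_rows <- c(seq_rows, list(nest$sequences))
          next
        }
        placed <- place_insertion(footprint, chrom_sizes, gaps,
                                  fam$p_intergenic)
        laid <- lay_out(ins, placed)
        frag_rows <- c(frag_rows, list(laid$fragments))
        truth_rows <- c(truth_rows, list(laid$truth))
        seq_rows <- c(seq_rows, list(laid$sequences))
      }
    }
    fragments <- bind_rows(frag_rows)
    if (share_rm_id) {
      fragments$rm_id <- fragments$locus_id
    } else {
      fragments$rm_id <- sprintf("%d", seq_len(nrow(fragments)))
    }
    frag_out <- fragments |>
      select(-"locus_id") |>
      arrange(.data$chrom, .data$start)
    frag_map <- fragments |>
      arrange(.data$chrom, .data$start) |>
      select("rm_id", "locus_id")
    truth <- bind_rows(truth_rows) |>
      annotate_truth_position(genome)
    list(
      fragments = frag_out,
      fragment_map = frag_map,
      truth = truth,
      sequences = bind_rows(seq_rows)
    )
  })
}

intergenic_gaps <- function(chrom_sizes, genes) {
  out <- list()
  for (chrom in names(chrom_sizes)) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0) {
      out[[chrom]] <- tibble(start = 0, end = chrom_sizes[[chrom]])
      next
    }
    cov <- IRanges::reduce(as_iranges0(g$start, g$end))
    gap <- IRanges::gaps(cov, start = 1L, end = chrom_sizes[[chrom]])
    out[[chrom]] <- tibble(
      start = IRanges::start(gap) - 1,
      end = as.numeric(IRanges::end(gap))
    )
  }
  out
}

# Choose a genomic position for an insertion of `len` bp. With probability
# `p_intergenic` the insertion is forced into an intergenic gap that fits.
place_insertion <- function(len, chrom_sizes, gaps, p_intergenic) {
  if (!is.na(p_intergenic) && runif(1) < p_intergenic) {
    all_gaps <- bind_rows(imap(gaps, ~ mutate(.x, chrom = .y)))
    fit <- all_gaps[all_gaps$end - all_gaps$start > len + 2, ]
    if (nrow(fit) > 0) {
      w <- fit$end - fit$start - len
      k <- sample(nrow(fit), 1, prob = w)
      start <- round(runif(1, fit$start[k] + 1, fit$end[k] - len - 1))
      return(list(chrom = fit$chrom[k], start = start))
    }
  }
  chrom <- sample(names(chrom_sizes), 1, prob = unlist(chrom_sizes))
  list(chrom = chrom, start = round(runif(1, 0, chrom_sizes[[chrom]] - len)))
}

# Build the strand-agnostic plan of one insertion: consensus pieces, their
# evolved sequences, inter-piece genomic gaps and realized divergences.
build_insertion <- function(fam, ltr_row, locus_id, fragment, truncate,
                            kappa, cpg_multiplier) {
  strand <- sample(c("+", "-"), 1)
  t <- fam$age_t
  piece <- function(row, c_lo, c_hi, role) {
    cons_piece <- substr(row$consensus_seq, c_lo, c_hi)
    seq <- evolve_sequence(cons_piece, t, kappa, cpg_multiplier)
    div <- realized_k2p(cons_piece, seq)
    tibble(
      family = row$family, superfamily = row$superfamily,
      te_class = row$te_class,
      cons_start = c_lo, cons_end = c_hi,
      cons_left = row$consensus_len - c_hi,
      len = c_hi - c_lo + 1,
      seq = seq,
      divergence_pct = round(100 * ifelse(is.na(div), 0, div), 1),
      role = role
    )
  }
  is_full_length <- FALSE
  if (!is.null(ltr_row) && nrow(ltr_row %||% tibble()) > 0) {
    form <- sample(c("full", "solo", "no3"), 1, prob = c(0.7, 0.2, 0.1))
    L_ltr <- ltr_row$consensus_len
    L_int <- fam$consensus_len
    if (form == "solo") {
      pieces <- piece(ltr_row, 1, L_ltr, "ltr5")
      gaps <- numeric()
    } else if (form == "no3") {
      pieces <- bind_rows(piece(ltr_row, 1, L_ltr, "ltr5"),
                          piece(fam, 1, L_int, "int"))
      gaps <- round(runif(1, 2, 30))
    } else {
      pieces <- bind_rows(piece(ltr_row, 1, L_ltr, "ltr5"),
                          piece(fam, 1, L_int, "int"),
                          piece(ltr_row, 1, L_ltr, "ltr3"))
      gaps <- round(runif(2, 2, 30))
      is_full_length <- TRUE
    }
  } else {
    L <- fam$consensus_len
    c0 <- if (truncate) max(1, round(L * runif(1, 0.1, 0.6))) else 1
    if (fragment && (L - c0 + 1) >= 160) {
      k <- sample(2:3, 1)
      cuts <- sort(sample(seq(c0 + 50, L - 50), k - 1))
      bounds <- unique(c(c0 - 1, cuts, L))
      k <- length(bounds) - 1
      pieces <- bind_rows(lapply(seq_len(k), function(j) {
        piece(fam, bounds[j] + 1, bounds[j + 1], "frag")
      }))
      gaps <- round(runif(k - 1, 100, 3000))
    } else {
      pieces <- piece(fam, c0, L, "single")
      gaps <- numeric()
    }
  }
  list(
    locus_id = locus_id, pieces = pieces, gaps = gaps, strand = strand,
    footprint = sum(pieces$len) + sum(gaps),
    is_full_length = is_full_length,
    family = fam$family, superfamily = fam$superfamily,
    te_class = fam$te_class, age_t = t
  )
}

# Place a planned insertion at a genomic position, producing fragment rows,
# a truth row and sequence rows. On the minus strand the genome order of the
# pieces is the reverse of the consensus order.
lay_out <- function(ins, placed) {
  p <- ins$pieces
  gaps <- ins$gaps
  ord <- seq_len(nrow(p))
  if (ins$strand == "-") {
    ord <- rev(ord)
    gaps <- rev(gaps)
  }
  pg <- p[ord, ]
  starts <- placed$start + cumsum(c(0, head(pg$len + c(gaps, 0), -1)))
  fragments <- tibble(
    chrom = placed$chrom, start = starts, end = starts + pg$len,
    strand = ins$strand, family = pg$family, superfamily = pg$superfamily,
    te_class = pg$te_class, divergence_pct = pg$divergence_pct,
    score = round(1000 - 10 * pg$divergence_pct),
    cons_start = pg$cons_start, cons_end = pg$cons_end,
    cons_left = pg$cons_left, rm_id = NA_character_,
    locus_id = ins$locus_id
  )
  truth <- tibble(
    locus_id = ins$locus_id, family = ins$family,
    superfamily = ins$superfamily, te_class = ins$te_class,
    chrom = placed$chrom, start = min(fragments$start),
    end = max(fragments$end), strand = ins$strand, age_t = ins$age_t,
    n_fragments = nrow(fragments), is_full_length_ltr = ins$is_full_length,
    nested_in = NA_character_
  )
  seq_main <- p[p$role %in% c("single", "frag", "int"), ]
  seqs <- list()
  if (nrow(seq_main) > 0) {
    seqs <- c(seqs, list(tibble(
      locus_id = ins$locus_id, family = seq_main$family[1],
      seq = paste(seq_main$seq, collapse = "")
    )))
  }
  ltr5 <- p[p$role == "ltr5", ]
  if (nrow(ltr5) > 0) {
    seqs <- c(seqs, list(tibble(
      locus_id = ins$locus_id, family = ltr5$family[1], seq = ltr5$seq[1]
    )))
  }
  list(fragments = fragments, truth = truth, sequences = bind_rows(seqs))
}

# Interrupt a single-piece outer insertion with a nested inner one.
nest_fragments <- function(outer, inner, placed, split_at) {
  L <- outer$pieces$cons_end[1]
  split_at <- min(max(split_at, 60), L - 60)
  sp <- outer$pieces[1, ]
  split_piece <- function(c_lo, c_hi) {
    q <- sp
    q$cons_start <- c_lo; q$cons_end <- c_hi
    q$cons_left <- L - c_hi
    q$len <- c_hi - c_lo + 1
    q$seq <- substr(sp$seq, c_lo, c_hi)
    q
  }
  outer$pieces <- bind_rows(split_piece(1, split_at),
                            split_piece(split_at + 1, L))
  outer$gaps <- inner$footprint
  laid_outer <- lay_out(outer, placed)
  inner_start <- sort(laid_outer$fragments$start)[2] - inner$footprint
  laid_inner <- lay_out(inner, list(chrom = placed$chrom, start = inner_start))
  laid_inner$truth$nested_in <- outer$locus_id
  list(
    fragments = bind_rows(laid_outer$fragments, laid_inner$fragments),
    truth = bind_rows(laid_outer$truth, laid_inner$truth),
    sequences = bind_rows(laid_outer$sequences, laid_inner$sequences)
  )
}

# Planted position category of each truth insertion against the gene set:
# same-strand exon overlap -> exon_overlapping; same-strand gene-span
# overlap -> intron (host gene recorded); otherwise intergenic.
annotate_truth_position <- function(truth, genome) {
  gm <- genome$genes
  truth$position_category <- "intergenic"
  truth$host_gene <- NA_character_
  if (nrow(gm$genes) == 0 || nrow(truth) == 0) return(truth)
  te_gr <- GenomicRanges::GRanges(
    truth$chrom, as_iranges0(truth$start, truth$end), strand = truth$strand
  )
  ex_gr <- GenomicRanges::GRanges(
    gm$exons$chrom, as_iranges0(gm$exons$start, gm$exons$end),
    strand = gm$exons$strand
  )
  gene_gr <- GenomicRanges::GRanges(
    gm$genes$chrom, as_iranges0(gm$genes$start, gm$genes$end),
    strand = gm$genes$strand
  )
  hit_ex <- GenomicRanges::findOverlaps(te_gr, ex_gr, ignore.strand = FALSE)
  hit_gene <- GenomicRanges::findOverlaps(te_gr, gene_gr, ignore.strand = FALSE)
  in_gene <- unique(S4Vectors::queryHits(hit_gene))
  first_gene <- tapply(S4Vectors::subjectHits(hit_gene),
                       S4Vectors::queryHits(hit_gene), min)
  truth$position_category[in_gene] <- "intron"
  truth$host_gene[in_gene] <- gm$genes$gene_id[first_gene[as.character(in_gene)]]
  in_ex <- unique(S4Vectors::queryHits(hit_ex))
  ex_gene <- tapply(S4Vectors::subjectHits(hit_ex),
                    S4Vectors::queryHits(hit_ex), min)
  truth$position_category[in_ex] <- "exon_overlapping"
  truth$host_gene[in_ex] <- gm$exons$gene_id[ex_gene[as.character(in_ex)]]
  truth
}
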