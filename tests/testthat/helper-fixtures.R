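# Shared fixtures and independent oracles used across the suite.

# Memoised default ecosystem fixture (seeded once; ~10 s to build).
.fixture_env <- new.env()
default_fixture <- function() {
  if (is.null(.fixture_env$eco)) {
    .fixture_env$eco <- simulate_te_ecosystem(seed = 101)
  }
  .fixture_env$eco
}

# Reconstructed loci for the default fixture (defragment + LTR pass).
default_loci <- function() {
  if (is.null(.fixture_env$loci)) {
    eco <- default_fixture()
    .fixture_env$loci <- reconstruct_ltr(defragment(eco$fragments))
  }
  .fixture_env$loci
}

# Map each reconstructed locus to the planted insertions its fragments came
# from; recovery = planted insertions represented by exactly one pure locus.
recovery_rate <- function(eco, loci) {
  id_of <- setNames(eco$fragment_map$locus_id, eco$fragment_map$rm_id)
  truth_sets <- lapply(loci$fragments, function(f) unique(id_of[f$rm_id]))
  pure <- vapply(truth_sets, function(s) length(s) == 1, logical(1))
  counts <- table(unlist(truth_sets))
  ok <- names(counts)[counts == 1]
  ok <- ok[ok %in% unlist(truth_sets[pure])]
  length(ok) / nrow(eco$truth)
}

# --- independent oracles -------------------------------------------------

# Naive defragmentation oracle: explicit pairwise mergeability graph over
# genome-order neighbours within (chrom, strand, family) groups plus rm_id
# edges, components by breadth-first search. Shares no code with
# defragment()'s union-find.
oracle_defrag_components <- function(fragments, params = defrag_params()) {
  fragments <- fragments[order(fragments$chrom, fragments$start,
                               fragments$end), ]
  n <- nrow(fragments)
  adj <- matrix(FALSE, n, n)
  key <- paste(fragments$chrom, fragments$strand, fragments$family)
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      f1 <- fragments[a, ]; f2 <- fragments[b, ]
      gap_ok <- (f2$start - f1$end) <= params$max_gap_bp
      col_ok <- if (f1$strand == "+") {
        f2$cons_start >= f1$cons_end - params$cons_tolerance_bp
      } else {
        f2$cons_end <= f1$cons_start + params$cons_tolerance_bp
      }
      if (gap_ok && col_ok) adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  if (!all(is.na(fragments$rm_id))) {
    for (id in unique(stats::na.omit(fragments$rm_id))) {
      idx <- which(fragments$rm_id %in% id)
      for (ch in unique(fragments$chrom[idx])) {
        sub <- idx[fragments$chrom[idx] == ch]
        if (length(sub) > 1) {
          for (j in sub[-1]) adj[sub[1], j] <- adj[j, sub[1]] <- TRUE
        }
      }
    }
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Random small fragment instance for oracle-equivalence testing.
random_fragment_instance <- function(max_frags = 6) {
  n <- sample(1:max_frags, 1)
  fams <- sample(c("famA", "famB"), n, replace = TRUE)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  start <- sort(sample(0:20000, n))
  len <- sample(100:800, n, replace = TRUE)
  cons_start <- sample(1:600, n, replace = TRUE)
  tibble::tibble(
    chrom = "chr1", start = start, end = start + len, strand = strands,
    family = fams, superfamily = fams, te_class = "DNA",
    divergence_pct = round(runif(n, 0, 30), 1), score = 100,
    cons_start = cons_start, cons_end = cons_start + len,
    cons_left = 0, rm_id = NA_character_
  )
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b       # unit row total
  n_ <- c + d
  k <- a + c       # cluster column total
  lo <- max(0, k - n_); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided exact binomial p by enumeration (small-probability method).
oracle_binom_p <- function(k, n, p) {
  probs <- stats::dbinom(0:n, n, p)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Benjamini-Hochberg by hand.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Tiny gene-model fixture: two genes on opposite strands.
#   geneP (+): exons [1000,1400) and [2000,2600); CDS [1200,2200)
#   geneM (-): exons [5000,5600) and [6400,7000); CDS [5300,6700)
toy_genes <- function() {
  exons <- tibble::tibble(
    transcript_id = c("tP.1", "tP.1", "tM.1", "tM.1"),
    gene_id = c("geneP", "geneP", "geneM", "geneM"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(1000, 2000, 5000, 6400),
    end = c(1400, 2600, 5600, 7000)
  )
  cds <- tibble::tibble(
    transcript_id = c("tP.1", "tP.1", "tM.1", "tM.1"),
    gene_id = c("geneP", "geneP", "geneM", "geneM"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(1200, 2000, 5300, 6400),
    end = c(1400, 2200, 5600, 6700)
  )
  gene_models(exons = exons, cds = cds)
}

make_loci <- function(start, end, strand = "+", family = "fam1",
                      te_class = "DNA", chrom = "chr1") {
  tibble::tibble(
    locus_id = sprintf("L%03d", seq_along(start)),
    chrom = chrom, start = start, end = end, strand = strand,
    family = family, superfamily = family, te_class = te_class
  )
}
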