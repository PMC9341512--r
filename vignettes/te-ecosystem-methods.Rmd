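---
title: "Methods: reconstructing and analysing a TE ecosystem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and analysing a TE ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

teeco analyses the "ecosystem" of transposable elements (TEs) in a genome
across five connected stages: locus reconstruction from fragmented repeat
annotations, phylogenetic family-age estimation, genomic distribution
relative to genes, classification of each locus's transcriptional
provenance, and clustering of developmental expression profiles. This
vignette records the models behind each stage, the tunable parameters, the
numerical choices, and what the synthetic fixture does and does not
establish about real data.

## Locus reconstruction (defragmentation)

Repeat annotators report one row per alignment hit, so a single old or
interrupted insertion appears as several fragments. Two fragments are
considered parts of one insertion iff they share chromosome, strand and
family, their genomic gap is at most `max_gap_bp` (default 5,000 bp — wide
enough to bridge a nested young element, narrow enough not to fuse
neighbouring copies), and their consensus coordinates are collinear in the
strand-appropriate direction within `cons_tolerance_bp` (default 50 bp,
absorbing alignment margin jitter). Chains are formed by linking
genome-order neighbours within each (chromosome, strand, family) group and
taking connected components; fragments sharing an annotation ID are merged
unconditionally. Because only neighbouring group members are linked, the
left-versus-right chaining ambiguity that a free chain search would face
cannot arise; the procedure is deterministic and is verified in the test
suite against an independent graph-based oracle on random instances.

Interruptions by a *different* family do not break a chain: the gap simply
spans the nested element. Cross-chromosome joins are never attempted.

Full-length LTR elements are assembled in a second pass: LTR
retrotransposons are annotated as separate `<stem>-LTR` and `<stem>-int`
families, and a locus pattern LTR–internal–LTR of one stem on one strand
(gaps within `max_gap_bp`) collapses into one locus flagged full-length.
The search for each flank skips unrelated loci lying between the internal
segment and its LTR, since independent insertions frequently land inside
the span of an older element. An internal segment with a single flanking
LTR is merged but not flagged; solo LTRs stay separate.

## Family ages

The age of a family is the median *terminal branch length* over a tree of
its copies, in substitutions per site: the distance from each copy (leaf)
to its most recent shared node. Copies shorter than 100 bp are discarded;
families with fewer than 10 suitable copies are reported as
`too_few_copies`; very large families are down-sampled to at most 1,250
copies (seeded). Each retained copy is globally aligned to the family
consensus (affine gaps; match 2, mismatch −2, open 8, extend 1) and
projected onto consensus columns, dropping copy insertions; columns
occupied by fewer than 1% of copies are trimmed. Pairwise distances on
this consensus-anchored alignment use the Kimura two-parameter model with
pairwise deletion of gapped sites, and the tree is built by neighbor
joining (negative branch estimates clamped to zero).

Neighbor joining was chosen over approximate maximum likelihood
deliberately: it is deterministic, exact on additive distances, and the
statistic of interest is a per-leaf pendant length rather than topology
deep structure. No rate-heterogeneity rescaling is applied, so absolute
ages may differ by a smooth monotone factor from ML-based estimates; the
package therefore leans on ordering and correlation properties, which are
invariant to such rescaling. For a family reduced to two copies the age is
defined as half their pairwise distance (the filters make this case
unreachable in the default pipeline).

The alternative age measure — median CpG-corrected K2P divergence from the
consensus, `d = −½ ln[(1 − 2P − Q)√(1 − 2Q)]` with consensus-CpG columns
excluded — is reported alongside. CpG exclusion is on for this measure
(CpG sites are hypermutable and inflate apparent age) and off for tree
distances, where relative rates cancel. On synthetic families the two
measures agree with Spearman ρ above 0.95. Saturated pairs (formula
argument non-positive) are flagged rather than extrapolated.

## Genomic distribution

Class densities are fractions of covered bp in non-overlapping 2-Mb
windows (union per class, so overlapping loci count once). Relationships
between class landscapes use Spearman's rank correlation with average
ranks for ties and the large-sample t approximation for p.

Distances between a locus hull and a gene span are 0 iff the intervals
overlap, otherwise gap + 1 — the bedtools `closest -d` convention — so
that "median distance equal to zero" is exactly "most copies overlap gene
bodies". A family is *preferentially intragenic* iff its median distance
is zero. The alternative formulation — more than half of copies
overlapping — coincides with the median rule except when exactly half of
an even number of copies overlap, where the median rule (implemented here)
calls the family intergenic.

The null for per-class intragenic enrichment shuffles family labels across
the fixed locus positions, preserving both the positional distribution and
the family copy-number multiset; the expected intragenic fraction is
averaged over shuffles (default 1,000, seeded) and the observed count is
tested with a two-sided exact binomial test. Because the expected
proportion is itself estimated and the count is small and discrete, the
test is conservative — its measured type-I error sits well below nominal
in the calibration suite, which is the safe direction for a screening
test.

The strand analysis considers only loci overlapping no gene at all,
measures the nearest same-strand and opposite-strand gene distances,
summarises per family by medians, and compares the two distributions per
class with a Wilcoxon rank-sum test (normal approximation with tie
correction). Young/old partitions use the strict thresholds printed with
the divergence values: young < 1%, old > 15%.

## Expression provenance

A TE-mapping read may originate from the TE's own promoter or from the
transcription of a surrounding gene. Loci are first positioned against
genes with a fixed priority — 5'UTR, 3'UTR, exon, promoter, intron,
downstream, intergenic; the first overlapping feature set wins. By default
only same-strand gene features count for the UTR/exon/intron categories
(`strand_aware = TRUE`): a TE can only be co-transcribed with a gene in
the same orientation. A strand-blind mode is provided because annotation
tools in common use ignore strand; the default follows the biological
argument. The promoter window is 3,000 bp upstream of the TSS and the
downstream window 300 bp past the 3' end; both categories collapse to
intergenic for provenance purposes — a TE near, but outside, a gene is not
part of its transcript — so these windows only affect bookkeeping, not
calls.

A gene is *expressed* iff its normalized count strictly exceeds 10 in at
least one sample, using plain median-of-ratios normalization (the
spike-in-adjusted variant changes factors, not this threshold's intent).
Intronic loci split into intron-expressed and intron-nonexpressed
accordingly; the residing gene is the one supplying the intron in the
priority pass.

Read-through transcription past annotated 3' ends would otherwise make
downstream TEs look self-expressed. Extended 3' UTRs are inferred from
assembled transcripts: an isoform assigned to a same-strand, exon-
overlapping reference gene contributes the part of its 3'-most exon lying
past the gene's annotated 3' end and contiguous with it; per-stage sets
are unioned. Loci overlapping an extension on the same strand are
`extended_3utr`.

Position categories collapse to provenance: exon-overlapping, extended-3'
UTR and intron-expressed loci are *gene-dependent*; intron-nonexpressed
and intergenic loci are *self-expressed*. Fragments reconstructed as one
element share the best category of their group under the hierarchy exon >
extended 3' UTR > intron expressed > intron nonexpressed > intergenic.
The classification is validated by TSS-peak containment: only peaks fully
inside a locus hull count, and the containment rates of the two groups are
compared with a chi-square (or exact) test.

## Developmental expression

Counts are normalized by median-of-ratios size factors computed either on
all rows or on spike-in rows only; factors are rescaled to geometric mean
one. Spike-in normalization tracks library size rather than biology and is
the default for TE matrices, where global composition shifts across
development are real signal, not technical artefact.

Rows with more than five reads in at least two samples are retained. Every
unordered stage pair is then tested per row under a negative-binomial
model: method-of-moments dispersion pooled across stages and floored at
0.01, and a Wald statistic on the difference of log stage means with the
delta-method variance of `log(mean + ½)`. The reference distribution is a
t on `n_a + n_b − 2` degrees of freedom rather than a normal: with three
replicates per stage the dispersion estimate is noisy, and the heavier
tails keep the measured type-I error within 1.3× nominal across the
dispersion and abundance grid in the calibration tests. The test sits
behind a plain stacked-table interface, so externally computed p-value
tables (e.g. from a GLM framework) can be substituted without touching
anything downstream.

All rows × pairs are stacked into one table and corrected once with
Benjamini–Hochberg. A locus is differentially expressed iff its smallest
adjusted p is below 0.01 *and* its maximum stage-mean normalized count
reaches 10. The low-count rule is deliberately read as a max-over-stages
condition: the literal alternative (drop a row if *any* stage is below 10
reads) would remove precisely the stage-specific profiles — maternal
transcripts are at zero after zygotic genome activation by definition —
and would empty the clusters the analysis exists to find. Stage summaries
are replicate means of normalized counts.

Profiles of differentially expressed self-expressed loci are z-scored per
row (sample standard deviation, n − 1; constant rows excluded) and
clustered with Lloyd k-means, 500 iterations, best of 50 seeded starts;
`k = 7` by default, configurable, and the fixture tests use k equal to the
number of planted archetypes. Cluster labels are re-ordered by centroid
peak stage so cluster 1 is always the earliest profile. Class and
superfamily enrichment per cluster uses two-sided Fisher exact tests on
the 2×2 membership tables with BH correction across all records.

## The synthetic fixture

The generator builds the study conditions for every recovery test: 2
chromosomes × 5 Mb, gene bodies covering ~60% of the sequence (genes laid
out without overlap, one transcript each, exons/introns/UTRs derived from
a central CDS), ~40 TE families with log-spread copy numbers (roughly 4 to
80 copies), planted ages increasing in log copy number with noise, 6
developmental stages × 3 replicates, negative-binomial counts (dispersion
0.2), log-normal library sizes, and 20 stage-constant spike-in rows.
Copies evolve from the family consensus under a two-rate substitution
process whose transition probabilities are the exact K2P values at the
planted distance (κ = 2 by default), so the downstream estimator is
unbiased by construction; CpG hypermutability is available but off by
default. Insertions are fragmented with probability 0.25, nested with
probability 0.04, 5'-truncated (retroelements) with probability 0.3, and
LTR families emit full triples, solo LTRs and 5'-truncated pairs in a
70/20/10 mixture. Emitted fragments carry distinct annotation IDs by
default so that reconstruction must rely on the collinearity rules rather
than ID bookkeeping.

Provenance is planted positionally: young families are biased towards
intergenic placement (probability 0.85 versus 0.45 for old families),
which simultaneously plants the self-expressed-younger age asymmetry.
Gene-dependent loci inherit scaled host-gene stage means; self-expressed
loci draw maternal, early-zygotic, mid-somite, late-larval or flat
archetypes; TSS peaks are planted inside expressing self-expressed loci at
rate 0.8 versus 0.005 in gene-dependent loci. A handful of genes receive
read-through extensions hosting a dedicated TE, with matching assembled
transcripts.

What the fixture does *not* emulate: alignment and quantification noise
(counts are generated at known locus resolution, so multi-mapping
ambiguity — the hardest practical problem in TE expression — is out of
frame), indels during copy evolution, family substructure and bursts,
unequal chromosome sizes, tandem satellite arrays, and any single-cell
structure. Passing recovery tests therefore demonstrates that the
analytical machinery is correct under its stated model, not that the
pipeline is robust to upstream quantification error.

## Problem sizes and determinism

The default fixture (~1,250 insertions, ~2,000 fragments) runs each stage
in seconds; the test suite keeps tree building to families of at most a
few dozen sampled copies and the calibration studies to a few hundred
simulations, which the package treats as its reference desk scale. Every
stochastic step takes an explicit seed — generator, down-sampling,
shuffles, k-means starts — and fixed seeds reproduce results bit for bit.

## Known limitations

Chains never cross chromosomes and no re-scoring of alignments is
attempted; the defragmentation thresholds approximate, but are not
calibrated against, any specific external reconstruction tool. Ages are
relative (no rate rescaling); saturated distances fall back to the maximum
observed finite distance in a family's matrix. The NB test is a
simplification of a GLM with shrinkage — adequate for planted effects at
fixture scale, conservative in power terms for subtle real effects. The
intragenic enrichment test is conservative by construction. Promoter and
downstream windows are fixed-width heuristics.
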