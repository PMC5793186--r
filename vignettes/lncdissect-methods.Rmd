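---
title: "Methods: dissecting lncRNAs in a staged differentiation time course"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting lncRNAs in a staged differentiation time course}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncdissect)
```

## The analysis

`lncdissect` implements the downstream computational dissection of a bulk
RNA-seq differentiation time course — the motivating system is chicken
primary myoblasts sampled at 0, 24, 72 and 120 h of differentiation
(stages A0, A1, A3, A5; three biological replicates each) — starting from
the file products of a transcript-assembly workflow: a merged transcript
annotation (GTF), a reference gene annotation carrying biotypes, an FPKM
expression matrix, and a table of coding-potential scores computed by
external tools (CNCI, CPC, Pfam-scan, PhyloCSF). Everything upstream of
those files (sequencing, alignment, assembly, and the coding-potential
tools themselves) is out of scope; everything downstream is implemented
here and testable offline through a synthetic-data generator with planted
ground truth.

## Identification: the filter cascade

A candidate transcript is called a lncRNA when it passes **all** of:

1. mature (summed-exon) length strictly greater than 200 bp;
2. at least 2 exons;
3. expression of at least 0.5 FPKM in at least one sample;
4. no conflict with known protein-coding loci: same-strand exonic overlap
   with a coding transcript excludes a candidate, as does span overlap
   without any antisense exonic contact (an intron-contained candidate);
   exonic overlap on the *opposite* strand is retained — that is exactly
   the antisense class;
5. no exonic overlap (either strand) with known pseudogene or small-RNA
   loci (pre-miRNA, tRNA, rRNA, snoRNA);
6. all four coding-potential scores on their noncoding side.

The filters are conjunctive, so the final call is independent of their
order; the audit table records every filter's verdict for every
transcript, which is what makes threshold-monotonicity testable.

Two deliberate configuration switches deserve comment:

* **Expression rule.** Upstream descriptions of this filter are commonly
  ambiguous between "mean FPKM" and "per-sample FPKM", and between
  cutoffs of 0.5 and 5. The default is 0.5 FPKM in ≥ 1 sample
  (`fpkm_rule = "any_sample"`), the permissive reading; both the cutoff
  and the rule are explicit `filter_thresholds()` fields.
* **Score sides.** The coding-potential tools disagree on sign
  conventions, and pipeline write-ups frequently print "CNCI and CPC
  scores > 0" where the tools themselves emit *negative* scores for
  noncoding transcripts. Each score therefore carries an explicit
  retained side. Defaults follow the tools' conventions (CNCI < 0,
  CPC < 0, Pfam E-value > 0.001, PhyloCSF < −20); the
  `as_printed = TRUE` preset flips CNCI/CPC/PhyloCSF to
  retained-if-greater for users who want the literal printed reading.
  Transcripts missing from the score table fail by default
  (`missing_scores = "fail"`), the conservative choice.

Classification partitions every called lncRNA into **antisense** (≥ 1 bp
exonic overlap with a coding exon, opposite strand) or **lincRNA** (no
span overlap with any coding locus). Step 4 above was formulated so this
partition is exhaustive: candidates with span-only overlap are excluded
upstream, which costs a rare legitimate intronic lncRNA but keeps the
two-class contract exact. Novelty against a known-lncRNA annotation is
called by same-strand exonic overlap covering ≥ 50% of the candidate's
mature length (`min_overlap_fraction`, with a strict > 0 bp requirement
so empty overlaps are never "annotated"); coordinate overlap replaces the
original sequence-similarity search, which requires sequence databases
that have no desk-scale equivalent.

## Targets

**Cis.** A coding gene is a cis-target candidate of a lncRNA when the
closest distance between the lncRNA's genomic span and the gene's span
(union over its transcripts) is at most 10,000 bp, inclusive, on the same
chromosome, either strand. Distance is measured span-to-span, not
TSS-to-TSS — "upstream and downstream" neighborhood language without TSS
qualifiers warrants the weakest assumption, and span distance makes the
relation symmetric. Overlapping spans get distance 0.

**Trans.** Every lncRNA × mRNA pair is scored by the Pearson correlation
of expression across all 12 samples; an edge is kept when |r| > 0.95
(strict) and the two-sided p-value from t = r√(n−2)/√(1−r²) against
t(n−2) is below 0.05. At n = 12 the r-threshold dominates: |r| > 0.95
already implies p ≈ 2 × 10⁻⁶, a property the tests assert. Raw p-values
are the default (matching the original screen); BH adjustment is an
option. Zero-variance rows cannot be correlated and are skipped and
counted rather than silently dropped. A `stage_mean_profiles()` helper
supports correlating 4-point stage means instead, since "expression from
four developmental stages" is genuinely ambiguous between 4 and 12
points; 12 is the default because it is the stronger test.

## Differential expression and archetypes

The stage-wise test is a deliberate, documented stand-in for an
assembly-suite differential pipeline: log2 fold change is computed on
stage-mean FPKM with a pseudocount of 1 (bounded fold changes at zero
expression), and the p-value is a Welch unequal-variance t-test on
log2(FPKM + 1) replicate values, BH-adjusted within each comparison. A
feature is called up/down when |log2FC| > 1 (i.e. two-fold) and adjusted
p < 0.05 — the "|fold change| > 2, adjusted p < 0.05" convention written
out explicitly, since this criterion is notoriously often printed with
its inequalities inverted. The interface accepts
externally computed tables (`call_de_sets()` works on any `de_result`-shaped
data.frame), so a negative-binomial pipeline's output can be slotted in.
With three replicates per stage and lognormal noise this t-test is
well calibrated (type-I error within binomial bounds of 0.05 in the
acceptance checks) and essentially fully powered at |log2FC| = 2 with
noise sdlog 0.1.

The four canonical comparisons are A1/A0, A3/A1, A5/A3 and A5/A0; the
comparison list is configurable because additional transitions (e.g.
A5/A1) are legitimate. Venn regions over 2–5 comparison sets are counted
by exact membership-pattern enumeration.

DEG temporal profiles (stage means) are clustered with Lloyd's K-means
under the Euclidean metric, 10 seeded restarts keeping the best inertia,
k = 4 by default. Profiles are z-scored per feature before clustering
(`standardize = TRUE`) so clusters capture *shape* rather than magnitude —
the source material does not state its scaling, and shape-clustering is
the interpretation under which the four archetypes are meaningful.
Centroids are mapped to the archetypes deterministically: K1 is the most
negative Spearman trend against stage order (the proliferation
signature), K4 peaks at A1 (differentiation onset), and the two rising
centroids split into K3 (earlier rise) versus K2 (later rise) by the
center of gravity of their above-minimum mass. Ties resolve to the lowest
cluster index with a warning.

## Enrichment and qPCR agreement

Over-representation uses the upper-tail hypergeometric test per term
against a caller-supplied universe, BH across terms — a database-agnostic
replacement for web-service enrichment tools, consuming GMT files.
Term counts from any specific GO/KEGG snapshot are database-version
dependent and are deliberately not reproduction targets.

qPCR relative expression follows 2^−ΔΔCt: ΔCt = Ct(target) − mean
Ct(references) (two reference genes combined by arithmetic-mean Ct, the
simplest rule consistent with "normalized to two genes"), ΔΔCt against a
calibrator sample, and agreement with RNA-seq is Spearman's rank
correlation on matched per-stage vectors.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with every planted feature recorded in a truth table:

* **Geometry.** Coding genes (4–12 exons) laid non-overlapping along each
  chromosome with 45–75 kb intergenic gaps; lincRNAs (2–4 exons, mature
  length > 200 bp) placed one per gap — a configurable fraction within
  200–8000 bp of a designated gene (cis-planted), the rest beyond 12 kb
  of every gene; antisense lncRNAs overlapping a host gene's first exon
  on the opposite strand; pseudogene/small-RNA loci with *decoy*
  candidates copying their coordinates, so the overlap filters (not the
  score filters) must remove them. Defaults: 3 chromosomes × 3.6 Mb, 120
  coding genes, 60 lincRNAs, 12 antisense, 8 + 8 decoy loci — small
  enough for sub-minute runs, large enough that every filter sees both
  outcomes.
* **Expression.** A fraction (default 0.3) of coding and lncRNA features
  get one of four archetype profiles — log2 stage offsets
  K1 = (3,2,1,0)·d, K2 = (0,0,1,3)·d, K3 = (0,1,2,3)·d, K4 = (0,3,1,0)·d
  with per-step effect d = 2 — mixed in the 1436/440/1762/784 proportions
  of the motivating four-cluster time course; all other features are
  flat. Baselines are uniform on log2 FPKM ∈ (3, 6). Replicates get
  multiplicative lognormal noise (sdlog 0.1 by default; 0 gives exact
  noise-free data). Planted trans pairs share the lncRNA's stage-mean
  profile up to a positive scale (r = +1 noise-free) or mirror it
  linearly around its midrange (r = −1), rather than copying values, so
  correlation is high but not degenerate.
* **Scores** are drawn strictly on the intended side of whatever
  thresholds object they are generated against, with random margins.
* **Genome** (optional): uniform random sequence, with a long
  ATG…TAA ORF written across ~95% of each coding transcript's spliced
  sequence. Random sequence stops every ~21 codons in expectation, so
  lncRNA ORFs stay short without any explicit suppression.

All randomness flows from the single `seed` through scoped RNG state
(offset-derived seeds per generator stage), so identical configurations
produce byte-identical files and no generator call perturbs the caller's
RNG.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: read-level sampling noise and
length-dependent FPKM variance, positionally realistic gene density and
overlap complexity (sense-intronic transcripts, bidirectional promoters),
sequence composition (GC, codon usage), dispersion structure that would
challenge the Welch stand-in the way real count data challenges
negative-binomial models, and annotation errors in the reference sets.
Recovery results on this generator certify the *logic* of the pipeline,
not the biological error rates of the original study.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF I/O is 1-based
  inclusive at the boundary. Lengths are `end − start` sums with no ±1
  bookkeeping.
* `longest_orf()` scans the three sense-strand frames only (transcripts
  are stranded), requires a terminating stop by default
  (`allow_open_orf = FALSE` scores stop-less reading frames 0), counts
  the stop codon in the length, breaks ties toward the 5'-most start, and
  treats codons containing N as neither start nor stop.
* Perfect correlations return the smallest representable double as the
  p-value rather than 0 or an error, so `p < threshold` never drops them.
* Identical replicate sets in the DE test get p = 1 (an A-vs-A
  comparison produces zero calls at any threshold); zero-variance rows
  with unequal means get the underflow p.
* K-means restarts that fail (empty cluster under Lloyd's algorithm) are
  re-seeded and retried, up to 20× the restart count; assignment is
  invariant to feature order because clustering happens on a canonically
  sorted copy.
* FPKM can be computed at transcript level (default) or, by aggregating
  the caller's id column beforehand, at gene level; the expression
  container is agnostic to id granularity.

## Problem sizes

The shipped tests and the acceptance script use the defaults above
(≈ 200-candidate genomes, 12-sample matrices, 200-feature null panels,
200-profile clustering fixtures, brute-force oracles on ≤ 500 features) —
sizes chosen so each property is exercised meaningfully while the full
suite completes in well under a minute per file.

## Known limitations

* The cascade excludes sense- and antisense-intronic candidates with no
  exonic contact, by design (see above); single-exon lncRNAs are never
  rescued.
* The DE stand-in is not a count-model test: with very low expression or
  heavy-tailed noise its calibration guarantees weaken, which is why the
  interface accepts external DE tables.
* Novelty-by-coordinate-overlap cannot recognize a known lncRNA
  transposed to another locus, which a sequence search would.
* Archetype labelling assumes the four canonical shapes; with k ≠ 4 the
  clusters are reported unlabelled.
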