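---
title: "Methods and design of embryocirc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of embryocirc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryocirc)
```

# Scope

`embryocirc` implements the downstream analysis of single-embryo total
RNA-seq libraries (SUPeR-seq-style protocols that capture both polyA+ and
polyA− RNA) across a pre-implantation developmental series: exonic circRNA
annotation from chimeric alignments, absolute mRNA/circRNA copy-number
estimation from a dual spike-in design, junction-level circular/linear
statistics, maternal/zygotic gene classification, genomic-feature analysis
of circRNAs, and filtering of de novo transcript candidates. Alignment,
read counting and transcript assembly are upstream of this package:
chimeric alignments arrive in a documented TSV dialect and counts as a
feature-by-sample table.

# circRNA annotation

A back-splice joins the 3′ end of a downstream donor exon to the 5′ end of
an upstream acceptor exon. In genome space this is strand-symmetric, so
the caller matches on genomic exon boundaries: a chimeric read pair
supports the circle over exons *i..j* of a gene iff the genomically
upstream segment starts exactly at the annotated start of exon *i*, the
downstream segment ends exactly at the annotated end of exon *j*, both
exons belong to the *same* gene with *i ≤ j*, and the segments appear in
back-spliced (reversed genomic) order in the read. The pair-end linearity
check then requires the linearly aligned mate, when present, to fall
inside the circle span on the same chromosome; mates outside the span are
the signature of artefactual chimeras and such reads are rejected. A
circle is reported per sample only with at least two distinct supporting
read pairs (`min_reads = 2`).

Design choices that were genuinely open:

* **Boundary tolerance.** Default `tol = 0` — precise splice sites only. A
  tolerance parameter exists for noisy simulations; with `tol > 0` a read
  can match several junctions, in which case it is dropped as ambiguous
  and tallied in the caller diagnostics, so a read pair never supports
  more than one junction.
* **Canonical key.** Every circle is stored as (chromosome, genomic min
  boundary, genomic max boundary, strand of the hosting gene), one key per
  circle regardless of strand. Exon ordinals are kept in genomic order and
  converted to transcript orientation only where orientation matters.
* **Terminal-exon classes.** In transcript orientation, a circle is
  `first_exon` if its acceptor exon is the gene's annotated first exon and
  `last_exon` if its donor exon is the annotated last one. For
  `first_exon` circles, coverage upstream of the annotated first exon
  (window 1 kb, mean depth > 1) is summarized as `upstream_evidence`: such
  reads suggest the annotated first exon is not the true one. The window
  and threshold are fixed values chosen for testability.
* **Read deduplication.** Support is counted as distinct read pairs by
  read id before the ≥ 2 filter.

The caller is verified against a brute-force enumerator that tests every
read against every exon pair of every gene; the two must be set-identical
on randomized small instances.

# Absolute copy-number estimation

Two spike-in classes anchor the absolute scale:

* **Dilution panel (ERCC class, 92 species).** Per sample, ordinary least
  squares of log10(RPKM) on log10(attomole) over species with input
  > 0.001 attomole (strict, as specified for the protocol) and RPKM > 0;
  at least three usable species are required. The fitted line is solved
  for attomole at each gene's RPKM (genes at zero RPKM contribute zero),
  summed, and converted with 1 attomole = 6.02214 × 10⁵ molecules.
  Regressing RPKM on amount and *inverting* (rather than regressing amount
  on RPKM) mirrors how the calibration is applied to gene RPKM values.
  Inversion is not capped below the smallest retained species: the panel
  spans the gene RPKM range in practice, and a cap would bias totals that
  are dominated by many small contributions.
* **Long-polyA mix (RGC class: RFP, GFP, CRE at 100:10:1 molecules, 80 nt
  polyA tails).** Short-polyA spike-ins are captured about three-fold less
  efficiently than endogenous mRNA by polyA-anchored reverse transcription,
  which biases the dilution-panel route; the long-polyA mix matches
  endogenous capture. Each detected species yields
  (total gene RPKM / species RPKM) × spiked molecules, and species
  estimates are averaged arithmetically.

The final per-sample copy number fits log10(RGC-based) on log10(ERCC-based)
across all samples and evaluates the fitted line at each sample's
ERCC-based estimate. The direction of this combining fit and the use of
fitted values as finals are package choices (the underlying protocol fixes
neither); regressing the better-calibrated route on the more precise one
keeps the RGC scale while letting the many-gene ERCC route set each
sample's position, and smooths single-sample spike-in noise.

circRNA abundance uses junction RPKM with an effective length term: a
back-splice is only visible to reads overlapping the junction by more than
the aligner's anchor segment (25 bp), so the length term is
(read length − 25) × 2 — 150 bp for 100 bp reads. Total circRNA copies are
(Σ circRNA junction RPKM / Σ gene RPKM) × mRNA copies, which is linear in
the mRNA copy number by construction.

`subsample_counts()` implements seeded multivariate hypergeometric
subsampling (draws without replacement to an exact depth) for
equal-depth comparisons, and `ercc_qc()` applies the technical-error
screen: a species is retained when its RPKM is ≥ 1 in more than two
samples, and the between-sample Pearson correlation over retained species
estimates reproducibility.

# Differential expression and the maternal/zygotic split

Size factors are proportional to mapped reads per mRNA copy
(`total_mapped_reads / mrna_copies`), rescaled to geometric mean 1.
Depth-only normalization misreads the series because absolute mRNA content
changes several-fold across it; per-copy scaling keeps a degrading
maternal transcript from looking constant, and a constant one from looking
flat while total content doubles.

The pairwise test is deliberately lightweight: the package's contribution
is the size-factor definition and the classification rules, not a
negative-binomial engine, so the test uses per-gene normalized means, a
pooled method-of-moments NB dispersion floored at 0.01, and a Wald
statistic on the log fold change referenced against a t distribution with
nA + nB − 2 degrees of freedom (the t reference compensates the
small-replicate variance estimate; with three replicates per stage it
holds the empirical type-I rate near the nominal 0.05 where a normal
reference is anticonservative). P-values are BH-adjusted; calls are
`up` (fold change > 2, FDR < 0.05) and `down` (fold change < 0.5,
FDR < 0.05). The expression gate — normalized RPKM ≥ 1 in at least one
sample — is applied once per series before testing.

Classification across the ordered series: *maternal* = peak mean
normalized RPKM in the oocyte plus a significant down call in some
consecutive-stage pair at/after the 4-cell stage; *zygotic* = a
significant up call at/after the 4-cell stage with a non-oocyte peak;
otherwise *undetermined*. "Decreases sharply after the 4-cell stage" is
operationalized as *any* significant consecutive down call from the
4-cell stage on — a formal rule chosen here, since a sharpness criterion
needs a threshold and the DE machinery already provides one.

# Junction statistics and genomic features

The circular fraction of a junction is back/(back + forward); the
circular-to-linear ratio CLR is ratio/(1 − ratio) = back/forward. Both are
undefined at zero total, and CLR is flagged infinite when back > 0 with no
forward reads. Each circle has two junction loci (acceptor and donor
side); forward-spliced reads are counted at both and **averaged** — an
aggregation rule had to be fixed, and the mean treats the two loci
symmetrically. Hosting-gene linear expression is compared to non-hosting
genes after discounting: RPKM × (1 − circ ratio).

Feature extraction reads exon counts/lengths and flanking introns (the
intron immediately 5′ of the acceptor exon and 3′ of the donor exon, in
transcript orientation) off the gene models; terminal circles lack the
corresponding flanking intron. Hosting genes with ≥ 2 distinct isoforms
are hot-spot genes. Repeat enrichment counts elements per intron by
interval intersection (not containment), compares flanking introns to a
seeded, size-matched control sample of introns from expressed
(RPKM ≥ 1) non-hosting genes, and tests with a two-sided Wilcoxon
rank-sum.

# Novel-transcript filter

A candidate survives iff (1) overall RPKM > 0.5 and every replicate
> 0.25 (strict), (2) its genomic span is ≥ 10 kb from the span of every
known gene — span-to-span and strand-agnostic, since an interleaved
antisense transcript within 10 kb is as likely to be assembly bleed-through
as a sense one — and (3) it has ≥ 2 exons with summed length > 500 nt
(strict). Rejections are tallied under the first failed criterion in the
fixed order expression → distance → structure.

# Read cleaning

Per read, in order: discard when > 50 % of bases are at Phred ≤ 5; discard
when > 10 % of bases are undetermined; trim adaptors at the first exact
match; trim terminal poly(T)/poly(A) runs of ≥ 24 nt (5′ T, 3′ A, one
pass); then discard when the remaining sequence is > 80 % A/T or shorter
than 30 nt. All thresholds are strict inequalities as printed above.
Trimming precedes the AT-content test because the anchored-polyT priming
chemistry makes terminal runs artefactual — content should be judged on
the insert, and this ordering retains the most reads. The 30 nt minimum
keeps post-trim reads mappable (a value had to be fixed; 30 nt is a
common aligner floor). Accounting is conserved: input = output + every
discard counter.

# The synthetic embryo series

The generator is first-class, tested code, and defines the study
conditions the rest of the package is validated under:

* **Scale.** Nine stages, oocyte → hatched blastocyst, defaults of three
  embryos per stage; per-stage true totals 66.4, 29.0, 24.6, 17.0, 15.7,
  38.1, 45.9, 104.5, 150.7 million molecules — the observed scale of the
  series, spanning the 1×10⁷–1.5×10⁸ range.
* **Capture model.** Expected spike-in RPKM is efficiency × attomole on a
  log-linear curve with lognormal noise of 0.1 dex; the long-polyA mix and
  endogenous genes use three-fold the ERCC efficiency (matching the
  qualitative efficiency contrast the dual-spike design responds to).
  Spike-in counts are Poisson around their expectation; gene counts are
  negative binomial with dispersion 0.1, a typical bulk-like value for
  amplified single-embryo libraries.
* **Archetypes.** 30 % maternal genes (8-fold drop after the 4-cell
  stage), 30 % zygotic (8-fold rise from the 8-cell stage), the rest with
  constant library share. Note that "constant share" genes rise in
  absolute copies when totals rise, so on the per-copy scale many are
  genuinely up-regulated; classification accuracy is therefore scored on
  the maternal/zygotic archetypes, whose truth is unambiguous.
* **Circles.** Designated hosting genes (default 40 of 300, ~50 %
  with a second isoform) carry circles over internal exons whose
  boundaries coincide exactly with annotated splice sites. Per circle and
  sample, a fixed number of junction-spanning reads (default 60) is split
  binomially at the junction's true circular fraction (drawn uniformly in
  0.05–0.30); back reads become chimeric records with mates placed inside
  the span, forward reads are split evenly in expectation between the two
  loci. A 5 % contaminant fraction adds chimeras with mates outside the
  span, making the pair-end filter's effect observable.
* **Geometry.** Intron lengths are lognormal with median 1.6 kb;
  circle-flanking introns are lengthened four-fold and receive four-fold
  the baseline repeat density (0.8 elements/kb), emulating the
  long-flanking-intron and repeat-enrichment signatures of circularizing
  loci. Repeats are labelled `Alu_synth`: any labelled repeat class
  stands in for Alu elements in simulations.
* **Determinism.** Every component derives its RNG stream from the master
  seed and restores the caller's RNG state; identical configurations give
  byte-identical outputs.

What the generator does **not** emulate: sequence-level reads with errors
(the QC FASTQ is decorative, exercising the cleaning rules only),
polyA-tail biochemistry beyond a per-class efficiency scalar,
fragment-length effects, multi-mapping ambiguity, overlapping gene
annotations, or real genomic repeat structure. Passing tests therefore
demonstrate the correctness and calibration of the downstream methods
under a faithful abstraction of the protocol, not performance on real
embryo libraries.

# Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  inclusive) and BED are converted at the boundary.
* Copy-number regressions run in log10 space; samples need ≥ 3 usable
  dilution-panel species and the combining fit ≥ 3 samples with positive
  estimates from both routes, otherwise estimation errors name the sample.
* `junction_metrics(0, 0)` is undefined (NA), not zero.
* The NB Wald statistic uses a pseudo-mean of 0.5 to stay finite at zero
  counts; dispersion floors at 0.01.
* Trans-chromosomal chimeric records are skipped with a warning count, not
  errored: they are outside the exonic-circRNA scope.
* Subsampling requires depth ≤ total and reproduces exactly under a seed.

# Problem sizes used by the test suite

The packaged checks run at reduced but representative sizes, chosen so the
full suite completes in a couple of minutes while keeping every
statistical check well-powered: 9–27 samples with 40–300 genes and 8–54
circles for end-to-end runs; 50 randomized instances for caller/oracle
equivalence; 500 replicates for the circ-ratio coverage and binomial
moment checks; 2000 null and 500 powered genes for DE calibration. The
copy-number recovery check runs the full nine-stage series at one embryo
per stage with the default capture noise.

# Known limitations

* The NB test has no dispersion shrinkage or outlier filtering; it is
  calibrated for the simulated regime (n ≈ 3, dispersion ≈ 0.1) and is not
  a general-purpose DE engine.
* Distance in the novel-transcript filter is span-based; a candidate
  inside another gene's intron has distance 0 and is always rejected.
* The caller assumes non-overlapping exon chains per gene (multi-isoform
  annotations are unioned on read-in), and intronic/exon-intron circles
  are out of scope.
* Absolute quantification assumes log-linear spike-in capture; saturation
  or species-specific capture biases are not modelled.
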