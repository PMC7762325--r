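---
title: "Quantifying mutational and copy-number burden in IDH-wild-type glioma exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mutational and copy-number burden in IDH-wild-type glioma exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaburden)
```

## The problem

IDH-wild-type diffuse gliomas are a heterogeneous group in which different
oncogenic mechanisms leave different marks on the genome: some processes
change the nucleotide sequence (mismatch-repair deficiency, polymerase
errors), others change chromosome number and structure (mitotic
nondisjunction, chromothripsis, double-minute formation). This package
quantifies both families of marks from matched tumor–normal whole-exome data
and asks whether molecular subsets of these tumors differ in their burden of
each.

Five quantitative metrics are computed per sample, together with two
rule-based event calls and a signature decomposition:

* **SNV burden** and **indel burden** — filtered somatic events per captured
  megabase.
* **wGII** (weighted Genome Instability Index) — the mean, over the 22
  autosomes, of the fraction of captured bases in copy-number-altered
  segments.
* **CAER** (Chromosomal Arm Event Ratio) — the fraction of autosomal arms
  whose length-weighted mean Tumor/Normal ratio is altered.
* **Copy-number amplitude** — the highest copy number observed.
* **Chromothripsis (CT)** — windowed clustering of copy-number state
  switches.
* **Double minutes (DM)** — high-level amplicons with oncogene and
  structural-variant support.
* **Signature exposures** — non-negative least-squares refit of the
  96-channel catalog against a supplied signature matrix.

A cohort of this kind is typically controlled-access; the package therefore
ships a synthetic-cohort generator with planted ground truth, so that every
metric and caller can be validated by parameter recovery rather than by
re-analysis of protected reads.

## Variant filtering and burden

Somatic calls enter the burden metrics only when VAF > 5 %, tumor depth
> 20× and normal depth > 10× — all three strict inequalities, so a variant at
exactly VAF 0.05 is removed. Burden is then

$$\mathrm{SNV\ burden} = \frac{\#\,\mathrm{SNVs}}{\mathrm{exome\ length\ (Mb)}},$$

and likewise for indels. "Coding region" is operationalized as *within the
capture intervals*: numerator and denominator must share a universe, so
variants outside the capture design (or on sex chromosomes) are excluded from
the count while the denominator is always the full captured autosomal size
computed from the supplied BED. Multi-nucleotide substitutions with equal
allele lengths are rejected at typing time; they are expected to be split
upstream, and the generator never emits them.

## Copy-number metrics

Segments carry linear Tumor/Normal ratios (the native output of exome CNV
callers); a segment is *altered* when |log2 ratio| > 0.25 (strict).

**wGII.** Per autosome, the altered fraction is captured-bases-in-altered-
segments over captured-bases-of-the-chromosome; captured bases not covered by
any segment count as unaltered. The index is the *unweighted* mean of the 22
fractions, which removes the bias of unequal chromosome sizes.

**CAER.** Per arm, the arithmetic mean of the segment ratios weighted by bp
of overlap with the arm is computed **in linear space first and
log-transformed second** — the order matters and is deliberate. An arm with
|weighted-mean log2| > 0.25 carries an event, and

$$\mathrm{CAER} = \frac{\#\,\mathrm{arms\ with\ SCNA}}{\#\,\mathrm{all\ autosomal\ arms}}.$$

The default inventory is all 44 autosomal arms. How arms with no overlapping
segment should be treated is genuinely open; we fill them as neutral
(ratio 1), which is conservative for sparse exome segmentations. For
real-genome runs a flag drops the five acrocentric p arms (13p, 14p, 15p,
21p, 22p), which carry no captured sequence on standard kits, shrinking the
denominator to 39.

**Amplitude.** Copy number is taken as 2 × ratio (diploid assumption, no
purity or ploidy correction — the simplest faithful map from Tumor/Normal
ratios), rounded half-up; an empty segment table is diploid (amplitude 2).

All three metrics are invariant under segment splitting, and wGII is monotone
in added altered territory; both invariants are enforced by tests.

## Event callers

**Double minutes.** Segments with ratio ≥ 5 (inclusive) are merged into
amplicons when on the same chromosome and separated by ≤ 1 Mb; the merge gap
and the 10 kb breakend tolerance are configuration values because "distinct"
and "associated" are not quantified in the underlying rule. A sample is
DM-positive by rule (a) — at least two amplicons genome-wide, at least one
overlapping an oncogene — or rule (b) — exactly one amplicon that overlaps an
oncogene, is longer than 1 Mb (strict) and carries a structural-variant
breakend. "Multiple distinct segments" is read genome-wide (same or different
chromosomes); rule (b) exists precisely for the single-amplicon case.

**Chromothripsis.** Our caller is a sliding-window scan in the spirit of
CTLPScanner, not a reimplementation of it: segments are discretized to
{loss, neutral, gain}, uncovered stretches count as neutral, and windows of
10 Mb anchored at each state-switch point are scored with a Poisson log10
likelihood ratio

$$\mathrm{LR}(k) = k\log_{10}\frac{k}{\mu} - \frac{k-\mu}{\ln 10},$$

where μ is the genome-wide switch count scaled to one window. A window calls
when k ≥ 10 switches and LR ≥ 8; overlapping qualifying windows merge into
one call. Anchoring windows at switch points makes calls exactly
translation-invariant. The defaults (10 Mb / 10 switches / LR 8) are adapted
to the sparser segment counts of exome profiles and are all exposed; parity
with any external tool is not claimed, so the caller is validated against its
own window-scan oracle and against planted oscillating clusters.

## Signature refitting

Catalogs are refit by non-negative least squares on the normalized catalog:
minimize ‖c/Σc − S·e‖₂ with e ≥ 0 (via `pracma::lsqnonneg`), then normalize e
to fractions. The estimator behind the web tool originally used for this kind
of analysis is unpublished; NNLS is the standard, fully testable refitting
choice, and reproduction of any specific published exposure table is not
attempted. Only signatures contributing ≥ 10 % (inclusive) are accepted. The
package ships *synthetic* block-structured signature matrices for testing
(`synthetic_signature_matrix()`); any user matrix in the documented TSV
format is accepted, and the published CNS signature catalog remains external
data.

## Molecular subsets

A specimen is molecularly-defined glioblastoma (mGBM) when it carries TERT
promoter mutation (C228/C250) and/or EGFR amplification and/or combined
whole-chr7 gain + whole-chr10 loss; the rule is an evidence union. The
7+/10− flag can be derived from segments: both chr7 arms must exceed +0.25
and both chr10 arms fall below −0.25 on the CAER arm statistic. When a
curated `molecular_subset` label disagrees with the marker rule the package
warns and, by default, keeps the label — curation can rest on evidence
(e.g. methylation profiling) outside the three markers. In the packaged
45-specimen sheet two rows are genuinely discordant: one recurrence that
lost all three markers but keeps its patient-level mGBM label, and one
piloid-features astrocytoma labelled Others despite a 7+/10− pattern. Both
are surfaced, never silently overridden.

## Cohort statistics

Group comparisons use the two-sided Wilcoxon rank-sum test: exact enumeration
over all rank assignments (midranks under ties) when both groups have ≤ 10
samples, otherwise the normal approximation with tie correction. Event
prevalences are compared by chi-squared with Yates correction on by default
(small cohorts) and off by request. The metric correlogram uses Spearman
correlation (robust to the heavy right tails of burden distributions),
distance 1 − r, average-linkage clustering cut at two clusters; the age
association uses Pearson's R with the usual t test, matching the convention
of reporting a fitted line. Gene-by-metric association tests each gene with a
high-impact variant (VAF > 5 % and one of the nine protein-affecting MAF
classes — note: no depth condition here, unlike the burden filter) in ≥ 2
mutated and ≥ 2 wild-type samples; significance is unadjusted p < 0.05 by
default with an optional Benjamini–Hochberg flag, since gene counts of this
kind are conventionally reported unadjusted.

## The synthetic cohort

`simulate_cohort()` writes a complete cohort — variant, segment, SV,
sample-sheet, catalog tables and a JSON ground-truth manifest — from one seed.
Its defaults are the package's standing study conditions:

* **Mutation model.** Passing SNVs and indels are Poisson with rates 3.4/Mb
  and 0.4/Mb of capture (cohort-median scale for this tumor type); VAF ~
  Beta(8, 12) (mean 0.4, the bulk of clonal somatic VAFs); tumor/normal
  depths Poisson with means 200/120, mirroring typical clinical-exome
  coverage. 20 % of planted variants are sub-threshold "fodder" that must be
  removed by the filter, making filter behavior directly testable.
* **Copy-number model.** Whole-arm events with log2 shift ±0.585
  (ratio 1.5/0.5) at per-arm probability 0.08; neutral segments carry
  truncated log2 noise (sd 0.05, clamped at ±0.2) so that no neutral segment
  can cross the 0.25 threshold — planted-event recovery stays exact.
* **Events.** Chromothripsis is a contiguous 5 Mb span of 30 alternating
  switches between ratios 1.0 and 0.5 (the "clustered oscillation" character
  of the phenomenon; no rearrangement graph is simulated). Double minutes are
  ratio-8, 2 Mb amplicons centered on an oncogene, with breakends planted at
  the amplicon and, under rule (a), a second distinct amplicon. 40 % of
  samples receive each event class by default.
* **Coupling.** Two per-sample lognormal intensities (sd 0.8) scale the
  mutational rates and the arm-event rate respectively, and CT/DM are
  assigned to the samples of highest copy-number intensity. This is what
  makes the correlogram's two-cluster structure — mutational metrics vs
  copy-number metrics — recoverable from simulated cohorts.
* **Determinism.** All randomness flows from one `set.seed(config$seed)`
  (default 17); identical configurations reproduce every output file
  byte-for-byte.

What the generator does **not** emulate: purity/subclonality, germline
variation, read-level error, realistic gene models (genes are 100-kb
positional bins), hg19 chromosome-length heterogeneity, or rearrangement
topology. Passing tests therefore demonstrate the correctness of the
metric implementations and the internal consistency of the pipeline under
idealized inputs — not concordance with calls made on protected patient
data.

## Numerical choices and degenerate inputs

* All thresholds follow their stated strict/inclusive sides: VAF and depth
  cuts strict; |log2| > 0.25 strict; amplicon ratio ≥ 5 inclusive; DM length
  > 1 Mb strict; signature acceptance ≥ 10 % inclusive.
* Amplitude rounding is half-up (`floor(2r + 0.5)`), not banker's rounding.
* An empty segment table is diploid; a chromosome with zero captured bases is
  a configuration error for wGII; an empty arm inventory is a configuration
  error for CAER; an all-zero catalog cannot be refit.
* The chromothripsis LR is defined 0 at k = 0; a genome with no switches has
  no windows.
* Constant metrics in the correlogram get their undefined correlations set
  to 0 with a warning rather than an error, so one flat flag does not kill
  the cohort overview.

## Problem sizes

The test and acceptance suites run on the bundled toy genome (22 autosomes ×
10 Mb, centromere at 4 Mb, 1 kb capture tiles every 10 kb — 22 Mb captured):
cohorts of 12–45 samples for pipeline checks, 80 samples for cluster
recovery, 1000-replicate null simulations for calibration of the rank-sum
and chi-squared tests, and 50 catalogs of 20 000 mutations for exposure
recovery. These sizes keep the full suite within a couple of minutes while
leaving the statistical checks well-powered; an hg19-scale cytoband file and
capture BED can be supplied for real-scale runs through
`genome_from_cytoband()`.

## Known limitations

The copy-number conversion ignores purity and ploidy, so amplitude is a
lower bound in impure tumors. The chromothripsis caller scores copy-number
oscillation only; WGS-grade criteria (two-to-three-state oscillation with
breakpoint clustering on a rearrangement graph) are out of scope. CAER's
neutral fill of uncovered arms biases it downward in very sparse
segmentations. MSI prediction, kataegis detection and pathway enrichment are
external analyses and are deliberately not reimplemented here.
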