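---
title: "Methods: chromatin-state, enhancer and regulatory-network dynamics with cistro"
author: "cistro authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-state, enhancer and regulatory-network dynamics with cistro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cistro)
```

# Overview

`cistro` compares the regulatory landscape of two cell states — think of a
lung-metastatic derivative (cell B) against its parental breast-cancer line
(cell A) — from histone-mark ChIP-seq peak calls, an expression table, a
PWM library and a patient cohort. The pipeline has four analytic layers:

1. **Promoter chromatin states.** Each TSS ± 2 kb window is labelled
   Active, Repressive, Poised or None per cell from the combination of
   H3K4me3/H3K27ac (activation) and H3K27me3 (repression) enrichment, and
   the 4×4 state-transition table is related to expression fold change.
2. **Enhancer dynamics.** H3K27ac peaks at least 2 kb from every TSS are
   distal enhancers; gained/lost enhancers are called at ≥ 4-fold
   library-scaled tag difference with P < 10⁻⁴ from a Poisson tail test;
   enhancers stitched within 12.5 kb are ranked by signal and
   super-enhancers called above the inflection point of the scaled rank
   curve.
3. **Regulatory networks.** PWMs are scanned over cell-specific active
   promoters and enhancers (log-odds, both strands); enrichment is
   hypergeometric on element hit counts; TF→target edges are labelled
   proximal (promoter), distal (enhancer) or both, and TF–TF cooperation is
   the Jaccard index of shared target sets, with hub TFs at JI > 0.3 with
   more than 10 partners.
4. **Cohort validation.** Patients are clustered by NMF (k = 2) on a
   marker-gene panel, cluster membership is tested against the metastasis
   label by chi-square, and lung-metastasis-free survival of mean-split
   expression groups is compared by Kaplan–Meier curves and the log-rank
   test.

Every analysis stage is exercised end-to-end on seeded synthetic studies
with recorded ground truth; this vignette documents the models, the
defaults, the numerical choices, and what the synthetic data can and
cannot show.

# Models and key parameters

## Promoter states

A promoter window is TSS ± `halfwidth` (default 2000 bp), clipped at
chromosome edges. A mark is *enriched* when its peaks overlap the window
by at least `minOverlapBp` (default 1) and the overlap-weighted tag
density reaches `minDensity` (default 0): peak presence is the criterion
unless the caller raises the thresholds, which is deliberate — per-mark
numeric thresholds are a property of a particular dataset's depth, so they
are explicit configuration here rather than hidden constants. The state
rule is total over the eight flag combinations:

| H3K4me3 or H3K27ac | H3K27me3 | state      |
|--------------------|----------|------------|
| yes                | no       | Active     |
| yes                | yes      | Poised     |
| no                 | yes      | Repressive |
| no                 | no       | None       |

H3K4me1 and H3K9me3 deliberately do not enter the call; they matter for
profile plots and enhancer annotation, not for the promoter vocabulary.
Overlapping windows share peaks; no peak is consumed.

## Differential enhancers

Tag counts over the merged (single-linkage) enhancer universe are scaled
to a common 10 M library, and the reported ratio is
`(scaled_b + 1)/(scaled_a + 1)`. Significance is the upper Poisson tail of
the larger scaled count under a rate of the smaller + 1 — the model family
used by the differential-peak tools this step replaces. The test is
antisymmetric (swapping cells maps gained↔lost with the same p) and its p
equals direct pmf summation to machine precision; with count-based inputs
its null call rate at the default fold-4 / p < 10⁻⁴ thresholds is far
below 2 × 10⁻⁴ (measured on 10,000 null enhancers in the tests). Distance
to TSS is measured to the nearest peak edge for the distal filter but from
the region midpoint for nearest-gene assignment; both are configurable.

## Super-enhancers

Distal H3K27ac peaks (peaks fully inside TSS ± 2 kb are removed first) are
stitched across gaps ≤ 12.5 kb; each region's signal is the sum of its
constituent tag counts. Regions are sorted by increasing signal, ranks and
signals are rescaled to [0, 1], and the cutoff is the signal at the first
rank where the one-rank secant slope exceeds 1; regions strictly above it
are super-enhancers. On a smooth convex curve this is the unit-slope
tangent (the densely sampled curve y = x² yields a cutoff of 0.25), and
the cutoff is invariant under positive rescaling of all signals.

Two degeneracies are worth knowing. First, the discrete secant is
sensitive to single-rank granularity: one unusually weak region at the
bottom of the curve can produce a first-rank gap whose scaled slope
already exceeds 1, collapsing the cutoff; a configurable smoothing window
(`smoothWindow`, default 0 = none) damps this at the cost of departing
from the plain rule. Second, the rule presumes a hockey-stick geometry —
a low-signal continuum plus a high-signal class. On a curve without a
high-signal class (for example a cell with no super-enhancer loci), or on
integer-valued signals whose range is small relative to the number of
regions, the first unit integer step can trigger the rule and many
regions are called; interpret super-enhancer sets only where the rank
curve actually shows the characteristic elbow.

## Motif scanning and networks

The scanner computes `Σ log2(p_position(base)/bg(base))` at every offset
on both strands (the minus strand scans the reverse-complemented matrix)
and calls a hit at ≥ `scoreFraction` (default 0.8) of the maximum
achievable score. A fraction-of-max threshold was chosen over a per-PWM
p-value because it is deterministic and directly checkable against
exhaustive enumeration of all length-w words, which the test suite does.
Windows containing non-ACGT letters are skipped; background frequencies
default to uniform 0.25. Motif enrichment is the upper hypergeometric
tail on element hit/no-hit counts of a target set against a background
set; the display threshold for "significant" motifs defaults to 10⁻¹⁰.
Edges inherit the element→gene map (promoters map to their own gene,
enhancers to their nearest gene); duplicate (TF, gene) pairs collapse to
mode "both". "Cell-specific" elements are those not overlapping the other
cell's active set by ≥ 1 bp.

## Cohort validation

NMF uses Frobenius multiplicative updates, whose objective is
non-increasing every iteration (asserted per run); the best of
`n_restarts` (default 30) random initializations wins and patients take
the argmax coefficient component. Expression should be non-negative
(log2(x+1)-transform count-like data first). "High" expression means
strictly greater than the arithmetic mean — ties go low; a median split
is available. The chi-square test is Pearson without continuity
correction (the correction is available by flag since conventions vary);
Kaplan–Meier and the log-rank test are delegated to the survival package,
with hand-derived worked examples serving as independent checks in the
test suite.

# The synthetic-study generator

`simConfig()` + `simulateStudy()` generate a complete study: a
single-chromosome toy genome (multi-gene, TSSs spaced ≥ 25 kb so promoter
windows never interact and neighbouring enhancer clusters never stitch
together), per-mark peak calls in both cells, an expression table, element
sequences with planted motifs, a PWM library, gene sets, and a patient
cohort — plus ground-truth tables for every planted feature.

Key generative choices, and why:

* **Promoter peaks** follow the drawn state pair per gene: Active/Poised
  promoters emit H3K4me3 + H3K27ac, Repressive/Poised emit H3K27me3, with
  Poisson tag counts (mean 100 at 10 M depth).
* **Enhancers** are planted 5–8 kb downstream of their gene's TSS.
  A *gained* enhancer's peak exists only in cell B (and lost only in A):
  the other cell contributes zero tags over the union region. With
  `emit_residual_peaks = TRUE` the other cell instead carries a weak peak
  at 1/`gain_fold` of the intensity, making the measured expectation
  ratio exactly `gain_fold` (8 by default).
* **Per-enhancer intensities are Gamma-distributed** (shape 16, mean 60;
  both cells share one draw, so planted folds are exact in expectation and
  counts remain Poisson given the intensity). Real enhancer strengths are
  heterogeneous, and this continuous spectrum is what gives the stitched
  rank curve its hockey-stick elbow; with identical intensities the curve
  degenerates into discrete steps and the inflection rule has nothing to
  find. Super-enhancer loci are clusters of 3–5 constituents within one
  stitching distance at mean 250 — an order of magnitude more aggregate
  signal than a typical single enhancer, consistent with how
  super-enhancers separate from the bulk in ranked-signal plots.
* **Expression** couples to chromatin:
  `log2 FC = transition effect + enhancer effect × (gained − lost) +
  N(0, 0.5)`. The default effect matrix activates Repressive→Active most
  strongly (+3.2 log2 units) and represses None→Repressive most strongly
  (−3.2), with intermediate values elsewhere; the enhancer term is ±1.
  These magnitudes are chosen for testability — clear separation at a few
  hundred genes per class — not as estimates of any particular dataset.
* **Sequences** are i.i.d. uniform background with exact-consensus
  planting from one-hot PWMs, so recovery at the default scan threshold is
  deterministic and a missed edge is a genuine defect, never bad luck.
  Co-occurrence pairs each TF with its cyclic successor.
* **The cohort** has two latent groups (marker genes shifted +2 log2 units
  in group 2; metastasis rates 0.1 vs 0.5), exponential survival with the
  hazard multiplied by 3 for the high-marker half, and uniform censoring
  applied to 20% of patients. Setting the shift and hazard ratio to
  null values produces calibrated uniform p-values, which the tests verify
  by Kolmogorov–Smirnov.

**What passing tests do and do not show.** The generator matches the
analysis assumptions by construction: Poisson counts, independent genes,
uniform sequence background, exponential survival. Recovery on this data
demonstrates the implementation is correct and calibrated, not that the
thresholds are optimal for real chromatin, where counts are overdispersed
beyond the planted Gamma mixing, enhancer–gene assignment by proximity is
often wrong, and motif hits are confounded by GC content and repeats.

# Numerical and design notes

* Coordinates are 0-based half-open at every file boundary (BED
  convention) and 1-based closed inside GRanges; the conversion lives in
  one internal helper pair.
* Fold change on zero-abundance genes uses a pseudocount of 1 FPKM;
  down-regulation is symmetric on the ratio scale (fc ≤ 1/1.5).
* Tag-density profiles put a boundary tag into the lower bin
  (`floor((pos − start)/width)`); minus-strand profiles are reversed so
  bins run 5′→3′. Expression deciles break ties by gene id, so the split
  is deterministic; group sizes differ by at most 1.
* Nearest-gene ties go to the lexicographically smallest gene id.
* The hub rule uses strict inequalities on both thresholds (JI > 0.3,
  partners > 10).
* All generators and the NMF are seeded; `runPipeline()` writes a manifest
  with an MD5 checksum per stage output, and a rerun under the same seed
  is bit-identical. Stage outputs are write-once per run directory.
* Default problem sizes — 500 genes for recovery runs, 600 genes for
  per-class effect recovery, 10,000 regions for null calibration, 100
  seeds for power estimates, 20 seeds for clustering accuracy — were
  chosen so each property is measured with comfortable statistical margin
  while a full verification run stays interactive on a laptop.

# Known limitations

* Promoter-state thresholds are peak-presence by default; datasets with
  many weak spurious peaks need a real `minDensity`.
* The inflection cutoff degenerates without a high-signal class (see
  above); the package reports the full ranked table so the curve can be
  inspected.
* Enhancer–gene linking is nearest-TSS only; no chromatin-contact model.
* The expression model in the generator is log-normal around planted
  means; it does not emulate count noise at low abundance.
* The cohort model has a single marker axis; no competing risks, no
  covariates, no ER-stratified meta-analysis.
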