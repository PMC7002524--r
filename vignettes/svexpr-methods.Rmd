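---
title: "Methods: SV breakpoints, expression, enhancers and methylation"
author: "svexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SV breakpoints, expression, enhancers and methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svexpr)
```

## Scope and model

`svexpr` asks, across a tumor cohort, whether somatic structural-variant
(SV) breakpoints near a gene are associated with altered expression of
that gene, and whether two *cis* mechanisms — translocated enhancers and
altered promoter CpG-island methylation — accompany the expression
changes.

The core statistical object is a binary event matrix: for each gene, each
of five strand-aware windows (gene body; 0–20, 20–50 and 50–100 kb
upstream of the TSS; 0–20 kb downstream of the gene end), and each
sample, an indicator of at least one breakpoint in the window. Windows
are half-open and contiguous; a breakpoint inside the gene body is never
additionally counted in that same gene's upstream or downstream sets, and
coordinates are clipped at the chromosome origin. "Upstream" follows the
gene's strand, anchored at the annotated gene boundary (we do not use
transcript-level promoter annotations; for multi-promoter genes this is a
deliberate simplification).

For every testable (gene, window) — at least 3 SV-positive samples — we
fit three nested OLS models of log2(expression + 1): SV alone, SV plus
cancer type (factor, reference = most frequent type), and SV plus cancer
type plus gene copy number (continuous). The reported quantity is always
the SV coefficient: its slope (log2 units per event), t-statistic, and
two-sided p-value at residual degrees of freedom. The nesting is the
point: copy-number amplification frequently co-occurs with nearby
breakpoints, so the SV-only coefficient absorbs dosage effects that the
full model strips away; comparing |t| across models separates
dosage-driven from dosage-independent associations.

### Assumptions

* Expression noise is roughly log-normal given covariates; OLS on log2
  values is the working likelihood. No purity/ploidy covariates are
  included.
* Cancer-type effects are additive offsets; gene-specific type
  interactions are not modeled.
* Copy number enters linearly on the log2-expression scale (a
  `log_copies` flag switches to log2(copies + 1) for users who prefer
  dose–response saturation).

### Inference

Storey–Tibshirani q-values are computed per (window, model) family:
pi0 is the natural-cubic-spline smooth (df = 3) of
`mean(p > lambda)/(1 - lambda)` over lambda = 0.05…0.95, evaluated at the
largest lambda and clamped to (0, 1]; q-values are the usual running
minimum of `pi0 * m * p / rank`. The estimator needs families of at least
a few hundred p-values to be stable; families under 10 are left without
q-values. A permutation null complements the FDR: each replicate applies
one random permutation of sample labels to the entire event matrix
(preserving per-gene frequencies and between-gene co-occurrence), refits
the full model for every testable gene, and counts genes with p below the
nominal threshold (default 0.001). Per-gene shuffling is available behind
a flag for sensitivity analysis but is not the default, because it
destroys the co-occurrence structure that makes the global null honest.

## Breakend conventions

BEDPE strands are read as retained-side orientations: `+` means the fused
derivative retains the sequence at or below the breakend coordinate, `-`
the sequence above it. Because published BEDPE dialects disagree, the
reader exposes `orient_convention = "retained-right"` to mirror both
strands. Breakends are collapsed to the interval start (confidence
intervals are not propagated). For the enhancer analyses only SVs whose
near-gene breakend retains the gene side qualify: orientation `-` for a
`+`-strand gene, `+` for a `-`-strand gene.

## Enhancer translocation

For each qualifying rearrangement the juxtaposed enhancer count is the
number of enhancer elements overlapping (any bp) the 0.5 Mb interval on
the retained side of the mate breakend — the elements the derivative
chromosome places upstream of the gene. The native count is the number in
the 0.5 Mb immediately upstream of the unaltered TSS. We deliberately do
*not* add native elements retained between the breakend and the TSS in
the default count, reading "0.5 Mb upstream of the rearrangement
breakpoint" literally; `include_retained_native = TRUE` adds them for
users who prefer the alternative reading. Genes with ≥7 qualifying
breakpoints get a paired t-test of juxtaposed vs native counts (native is
constant per gene, so this equals the one-sample t on differences —
asserted to 1e-10 in the tests). Distances are measured to the proximal
enhancer edge; the nearest-distance test (≥5 qualifying breakpoints, near
breakend strictly between TSS and the native nearest enhancer, retained
mate window non-empty) compares (TSS→breakend) + (mate→nearest retained
enhancer) with the native distance; negative t means enhancers moved
closer.

## Methylation

Beta values are clamped to [0.001, 0.999] and logit-transformed; per gene
one CpG-island probe is kept — the one with maximal beta variance across
samples, ties broken by probe id. Two Pearson correlations are computed
per gene, each converted to t = r·sqrt((n−2)/(1−r²)): logit methylation
vs log2 expression, and logit methylation vs the binary SV indicator
(0–20 kb upstream window by default, subject to the ≥3-SV-sample rule).
The subset-shift test compares the expression–methylation t distribution
of an over-expressed gene subset against the full background with a
two-sample t-test; the subset deliberately remains part of the
background, mirroring how the two distributions are defined.
Cross-platform batch harmonization of methylation arrays is out of scope;
the functions accept pre-harmonized matrices.

## The synthetic cohort

`simulateCohort()` states a desk-scale world, not a dial to tune: 200
tumors over 5 cancer types; genes 10 kb long, spaced 2 Mb on simulated
chromosomes (50 per chromosome, 1 Mb padding) so neighboring windows
never collide; a dedicated donor chromosome carries every mate breakend.
Log2 expression is baseline (N(5, 1.5)) + per-type offset (N(0, 1)) +
0.5·copies + beta·SV + noise (SD 1), exponentiated to an FPKM-like scale
as 2^z − 1. Non-driver genes get breakpoints at rate 0.02 per
gene–sample in one randomly designated window; the default drivers plant
2, 1.5 and 1 log2-unit effects in 30 of 200 samples. Copy number is
diploid with SD 0.15, amplified to 5 + Exp(1) copies in 30% of
SV-positive samples (0.8 in the strongly-confounded acceptance scenario)
and 1% of others — so the SV-only model overstates effects and the full
model attenuates them. Methylation gives each gene one CpG-island probe
(unit logit SD) and one low-variance non-island probe; coupled genes
(default: the drivers) shift by +1 logit unit in SV-positive samples, and
70% of genes are "silenced" (expression decreases 0.3 log2 units per
logit of methylation), which reproduces the left-skewed background
expression–methylation correlation seen in tumor cohorts.

What the generator does *not* emulate: realistic SV mechanism classes and
breakpoint clustering, sequence context, purity/ploidy variation,
platform batch effects, and overlapping genes. A green test therefore
establishes correctness of the statistical machinery under the stated
generative model, not robustness to every artifact of real consortium
data.

`simulateHijackLocus()` plants a single gene with exactly k native
enhancers in its upstream 0.5 Mb and exactly k' in the retained window of
a donor mate breakend, plus decoy elements outside both windows; the
enhancer stage must reproduce the planted pair of counts exactly.

## Numerical choices

* Model fitting residualizes y and the SV indicator against the covariate
  block (QR of the shared type design, then one per-gene projection for
  copy number); this equals full OLS exactly and is cross-checked against
  `stats::lm` to 1e-9. Designs where the SV indicator lies in the
  covariate span (residual sum of squares of the indicator below 1e-10
  relative) are flagged non-estimable and excluded from FDR families;
  zero residual variance flags a degenerate fit.
* Pseudocount 1 for the log2 transform; logit clamp 0.001; both
  configurable.
* The cancer-type reference level is the most frequent type; SV inference
  is invariant to this choice (tested).
* Tie-breaks are deterministic everywhere: lexicographic probe ids,
  lexicographically first sample per donor, distance-ordered window
  labels in the alteration grouping (gene body, then nearest window by bp
  distance).
* All randomness flows through explicit seeds; the permutation stream is
  private to the call and leaves the global RNG untouched.

## Known limitations

* Upstream windows anchor at gene boundaries, not annotated promoters or
  TADs; enhancer–promoter specificity is purely distance-based.
* The Storey pi0 spline is unstable for families under ~100 tests; small
  cohorts should rely on the permutation null instead.
* Multi-sample donors are resolved deterministically rather than by
  random selection, trading fidelity for reproducibility.
* The alteration grouping assigns one label per sample by precedence
  (amplification over SV windows over annotation flags); samples with
  several co-occurring alterations are not multiply counted.
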