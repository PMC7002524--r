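# svexpr

Integrative analysis of somatic structural variants (SVs), gene
expression, enhancer translocation and DNA methylation in tumor cohorts.

Somatic rearrangements can deregulate a gene without touching its coding
sequence: a breakpoint upstream of a promoter may juxtapose distal
enhancers next to the gene ("enhancer hijacking"), remove a repressive
element, or co-occur with copy-number amplification. `svexpr` implements
the cohort-scale statistical machinery for detecting such *cis*-regulatory
effects, for analysts with SV calls (BEDPE), expression (FPKM-UQ-like),
copy-number and methylation matrices across hundreds of tumors.

## The model

Each gene is tested in five strand-aware windows — gene body, 0–20 kb,
20–50 kb and 50–100 kb upstream of the TSS, 0–20 kb downstream — with a
binary indicator per sample for "≥1 SV breakpoint in the window". A
(gene, window) is testable when at least 3 samples carry an event. For
testable pairs, three nested ordinary-least-squares models of
log2-transformed expression y are fitted:

    y ~ SV                          (SV_ONLY)
    y ~ cancer_type + SV            (SV_TYPE)
    y ~ cancer_type + copies + SV   (SV_TYPE_CN)

and the SV coefficient's t-statistic and two-sided p-value are reported,
with Storey–Tibshirani q-values per (window, model) family and a
permutation null that shuffles sample labels of the whole event matrix.
Enhancer hijacking is quantified per qualifying rearrangement (breakend
0–20 kb upstream, mate orientation retaining the gene side) as the number
of enhancer elements within 0.5 Mb on the retained side of the mate,
compared with the unaltered gene's upstream count by paired t-test;
nearest-enhancer distance changes are tested analogously. Methylation
enters as Pearson correlations of logit-transformed beta values (one
max-variance CpG-island probe per gene) with log2 expression and with SV
status, t = r·sqrt((n−2)/(1−r²)).

A synthetic-cohort generator (`simulateCohort()`) emits every input with
known ground truth, so the full pipeline is testable without consortium
data.

## Worked example

```r
library(svexpr)
cohort <- simulateCohort(simConfig(seed = 1))     # 100 genes x 200 samples
report <- runPipeline(cohort, n_perm = 200, seed = 2)
print(report)
```

```
Integrative SV-expression pipeline report
Significant genes per window (p < 0.001 ):
          SV_ONLY SV_TYPE SV_TYPE_CN
GENE_BODY       1       1          1
UP_0_20         1       1          1
UP_20_50        1       1          1
UP_50_100       1       2          0
DOWN_0_20       1       0          0
Permutation null (UP_0_20): 200 permutations of 12 testable genes at alpha = 0.001
  mean significant per permutation: 0.01 (sd 0.12)
  observed significant genes:      1
Enhancer count tests: 3 genes
Methylation correlations: 100 genes
Top gene: G0001 ( UP_0_20 , t = 7.55 )
```

The default cohort plants three driver genes; `G0001` carries a 2
log2-unit expression effect in 30 of 200 samples with breakpoints 0–20 kb
upstream, and tops the full-model ranking at t = 7.55. The permutation
null (0.01 significant genes per shuffle among 12 testable) shows the
observed hit is not a multiple-testing artifact. `multipleTestingReport()`
exposes the conservative cross-window arithmetic
(`n_regions * alpha * n_genes` and the implied global FDR percentage).

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on the
default synthetic cohort — simulate, annotate breakpoints, fit the three
models, permutation null, enhancer and methylation stages — and writes a
JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
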