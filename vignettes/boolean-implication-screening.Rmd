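---
title: "Boolean-implication biomarker screening: models, parameters and design"
author: "BoolScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean-implication biomarker screening: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BoolScreen)
library(SummarizedExperiment)
options(BoolScreen.verbose = FALSE)
```

## The scientific problem

Mesenchymal character in colorectal cancer — marked by high vimentin (VIM)
expression — is associated with poor prognosis. A way to find regulators of
that state is to look for genes X whose *low* expression is essentially never
observed together with *low* VIM: an asymmetric Boolean implication
"X-low ⇒ VIM-high". Genes with this property define a small, marker-low
patient subgroup that can then be tested for prognostic value in survival
cohorts. BoolScreen implements this discovery pipeline end to end on log2
expression matrices and clinical tables: step-function binarization of every
gene, a genome-wide implication search with a permutation false-discovery
rate, candidate filters (population support and differential expression
versus normal mucosa and inflammatory bowel disease tissue), two-gene
patient subgrouping, and the accompanying clinical statistics battery.

## Step-function binarization

For each gene the samples' log2 values are sorted ascending and fitted with
a one-step function: a breakpoint $i^\*$ splits the sorted vector into a
left segment with mean $\mu_L$ and a right segment with mean $\mu_R$, and
$i^\*$ minimizes

$$SSE_{step} = \sum_{j \le i^\*} (x_j - \mu_L)^2 +
  \sum_{j > i^\*} (x_j - \mu_R)^2, \qquad 1 \le i^\* \le n - 1 .$$

The high/low cutoff is placed at the midpoint $t = (\mu_L + \mu_R)/2$; the
placement rule is a package choice, since only the existence of a per-gene
cutoff is prescribed by the method this implements. An F statistic
$((SSE_{flat} - SSE_{step}))/(SSE_{step}/(n-2))$ compares the step fit with
the flat fit about the grand mean; it is reported but deliberately not used
as a filter. Ties in SSE break to the smallest breakpoint for determinism; a
fit needs at least $n = 4$ finite values (two per segment); a degenerate fit
($\mu_R = \mu_L$) classifies every sample as intermediate.

Calls use a symmetric margin $m$ around the cutoff: LOW below $t - m$, HIGH
above $t + m$, INTERMEDIATE within $\pm m$. Two defaults matter:

* $m = 0.5$ log2 units for the implication search — the conventional noise
  buffer for Boolean analysis of expression arrays, excluding samples too
  close to the cutoff to call confidently;
* $m = 0$ for patient-level subgrouping, so every patient receives a
  high/low label.

Only the one-step variant is implemented; adaptive multi-step fitting is out
of scope because the downstream search needs exactly one cutoff per gene.

## The implication statistic

With both genes binarized, samples with a LOW or HIGH call in both genes
form a 2×2 table $(n_{LL}, n_{LH}, n_{HL}, n_{HH})$ (X-call, Y-call). For
the relation "X-low ⇒ Y-high" the *sparse* quadrant is (X-low, Y-low):

$$e = \frac{(n_{LL}+n_{LH})(n_{LL}+n_{HL})}{n}, \qquad
  S = \frac{e - n_{LL}}{\sqrt{e}}, \qquad
  err = \frac12\left(\frac{n_{LL}}{n_{LL}+n_{LH}} +
  \frac{n_{LL}}{n_{LL}+n_{HL}}\right).$$

$S$ measures the deficit of the sparse quadrant against its independence
expectation in units of its Poisson-scale spread; $err$ is the mean
conditional leak into it. A pair passes when $S > s_{min}$ and
$err < err_{max}$; the defaults $s_{min} = 3$, $err_{max} = 0.1$ follow the
established Boolean-network convention for these statistics, and both are
arguments everywhere they are used. The other three relations permute the
quadrants analogously. A zero margin for the tested quadrant makes the pair
not evaluable rather than a pass or fail. Pairs contribute only if at least
`minN` (default 20) usable samples remain, for stability of $e$ and $err$.

The genome-wide search is target-centred: every gene is tested against one
fixed target (VIM in the motivating application) over a selected sample
population (typically the carcinoma arrays), and results carry a *support
fraction* — the share of the population usable for that pair. We interpret
support as "samples contributing to the implication test" (non-missing,
non-intermediate in both genes); the alternative platform-coverage reading
(gene measured at all) can be filtered from the same output since both the
pair count and the population size are reported.

### Permutation FDR

The false-discovery rate of a threshold configuration is estimated by
permutation: each round independently shuffles every non-target gene's calls
across samples — destroying all pairwise association while preserving each
gene's call composition — and re-counts passing pairs. The estimate is the
mean null passing count divided by the observed passing count (1.0 when
nothing passes, by convention). This within-gene permutation scheme is a
package design choice; the FDR machinery behind the original analysis is not
specified in its public description. Fixing the seed makes the estimate
bit-reproducible.

## Candidate screening

Implication hits are reduced to candidates by two filters, both strict
inequalities per their published wording:

1. **Support**: support fraction at least 0.40 — hits identified from a
   smaller slice of the population are dropped;
2. **Differential expression**: fold change $> 2$ at $p < 0.001$ in *both*
   comparisons, tumour vs. normal mucosa and tumour vs. IBD tissue. The
   published account reports genes differential in "either" comparison, but
   its surviving candidates satisfied both; every per-comparison flag is
   carried in the output so either conjunction can be audited.

The DE test is Welch's t on log2 values (the conservative default where the
source analysis does not name its test), with fold change $2^{|\Delta\bar
x|}$ so direction does not matter. No multiple-testing correction is applied
here — the raw-p cutoff is the published rule, and error control lives in
the implication stage's FDR. Polyp arrays are collected by the data model
but not used by the stated filter, matching the published procedure.

## Patient subgrouping and survival

Patient-level calls (margin 0) define a two-group label from the marker
alone (low/high) and a three-group label crossing it with the partner gene
(marker-low/VIM-high, marker-high/VIM-high, marker-high/VIM-low); the
leftover marker-low/VIM-low cell is sparse by construction and labelled
OTHER with a logged count.

The survival battery wraps the survival package: Kaplan–Meier product-limit
curves (`survfit`), with 5-year rates read as the step-function value at 60
months; the standard log-rank test (`survdiff`); and multivariate Cox
models (`coxph`) with Efron tie handling by default — Breslow (the default
of older commercial software) is available via `ties` since the original
analysis does not state its choice, and Efron is the less biased of the
two. Covariate encodings follow the conventions of the motivating study:
marker low vs. high (reference high), age dichotomized at 60 years, stage
entered as a numeric "per increase in stage", chemotherapy yes vs. no with
missing excluded complete-case (and the exclusion count logged).

The marker-by-chemotherapy 2×2 factorial interaction is assessed on both
scales: multiplicative, as the Wald test of the product term in a Cox model
with both main effects; and additive, as the relative excess risk due to
interaction from the joint-indicator parameterization,

$$RERI = HR_{11} - HR_{10} - HR_{01} + 1,$$

zero under hazard additivity, with a delta-method 95% CI. RERI with a
delta-method interval is the standard operationalization of "additive
interaction" for hazard models; no formula is given in the source analysis.

## Baseline-table statistics

The baseline comparison table dispatches per variable type: nominal
variables to the Pearson chi-square *without* continuity correction
(falling back to Fisher's exact test when any expected cell count is below
5 — the fallback rule is a convention, as the published footnote lists both
tests without one), continuous variables to the pooled-variance Student t,
and ordinal variables (stage, grade) to the Mann–Whitney U test with
midranks and the tie-corrected normal approximation, no continuity
correction. Missing/unknown levels are excluded from each test but shown as
rows. These exact variants — no Yates correction, pooled rather than Welch
t, asymptotic tie-corrected Mann–Whitney — are the ones that reproduce all
eleven printed baseline p-values of the motivating study's cohort tables
from their published counts and summaries, which is how the
`test-acceptance` suite pins them down. Serum CEA and CA19-9 are displayed
as median (range) without a test: a rank test on them needs patient-level
values, which published tables do not carry.

## The synthetic-cohort generator

Because the original cohorts (public array collections and a hospital
tissue-microarray series) are not redistributable, correctness is
established on synthetic studies with planted, recoverable truth. The
generator emulates:

* a tissue-class structure (CRC / polyp / IBD / normal mucosa), by default
  500 / 20 / 90 / 80 — roughly a one-fifth scale of the 2480 / 98 / 451 /
  396 array population the analysis was built on, chosen so the full search
  runs in seconds at test time;
* bimodal genes as two-Gaussian mixtures with modes at 5 and 9 log2 units
  and $\sigma = 0.5$, i.e. each mode 4$\sigma$ from the midpoint cutoff, so
  binarization is unambiguous (harder separations can be configured);
* a planted implication: the marker gene is low in $\pi_{low} = 0.226$ of
  carcinoma samples (the published subgroup fraction, 561/2480), and the
  target's mode is sampled *conditionally* on the marker's mode with leak
  $\varepsilon = P(\text{target LOW} \mid \text{marker LOW}) = 0.02$ —
  conditional generation rather than post-hoc editing keeps both marginals
  bimodal;
* differential expression of the marker (low mode outside CRC) and of a few
  unimodal genes shifted by 1.5 log2 units in CRC;
* MSI and BRAF labels enriched in the marker-low subgroup (odds ratio 4 on
  base rates 0.15 / 0.10);
* survival cohorts of n = 889 and n = 691 with planted marker log hazard
  ratios ln(1.37) and ln(4.05) — the multivariate and validation effect
  sizes printed by the motivating study — exponential event times with
  stage and age effects, and independent uniform censoring whose window is
  solved numerically to hit a 70% censoring rate (≈30% event rate) within a
  120-month accrual horizon.

Per-gene and per-cohort sub-seeds are derived from the master seed and the
unit's index, so enlarging a study never perturbs existing units. The
generator does **not** emulate platform or batch effects, probe-level
artifacts, normalization residuals, correlated gene modules, or informative
censoring; passing recovery tests therefore demonstrates correctness of the
estimators and the search under the model's own assumptions, not robustness
to the messiness of real array compendia. Cross-cohort renormalization is
likewise out of scope throughout the package: matrices are consumed as
already comparable (single-sample normalization is assumed upstream).

## Numerical and design notes

* Expression TSVs are written with 17 significant digits so write→read
  round-trips are bit-identical; "NA" or an empty cell is the only missing
  dialect on read, "NA" on write.
* Step-fit SSE is computed by prefix sums and clamped at zero; SSE ties
  within a $10^{-9}$ relative band resolve to the smallest breakpoint.
* The Fisher p sums hypergeometric probabilities with a $10^{-7}$ relative
  tolerance for floating-point ties, matching standard practice.
* Every filter (short genes, under-supported pairs, complete-case
  exclusions, non-positive survival times) logs the count removed and the
  rule applied; logging is silenced with `options(BoolScreen.verbose =
  FALSE)`.
* Expression data live in a `BooleanCallSet`, a `SummarizedExperiment`
  subclass carrying the log2 assay, the integer call assay and the per-gene
  fits in `rowData`; result tables are plain data frames.
* Multi-probe collapsing is out of scope: gene ids are opaque keys, one row
  per gene.

Test problem sizes (500-gene searches, 50-replicate Cox recoveries,
20-seed null batteries) are the package's choice of smallest scales at
which the planted effects are comfortably identifiable; all scale up by
configuration.

## A worked example

```{r example}
cfg <- studyConfig(nCRC = 300, nPolyp = 10, nIBD = 60, nNormal = 60,
                   nGenes = 200, nBimodal = 20)
study <- generateStudy(cfg, seed = 7)
cs <- thresholdAllGenes(study$se, margin = 0.5)
cs

pop <- colnames(cs)[colData(cs)$tissue_class == "CRC"]
res <- searchPartners(cs, cfg$targetGene, population = pop)
head(res[, c("gene", "n", "statistic", "errorRate", "supportFraction",
             "passes")], 3)

estimateFDR(cs, cfg$targetGene, population = pop, nPerm = 50, seed = 7)

fit <- coxFit(study$clinicalDiscovery, "DFS", c("group", "stage", "age60"))
fit$table
```

The planted marker tops the ranking, passes at the default thresholds with
a permutation FDR below 0.005, and its low group carries the planted excess
hazard in the Cox fit.

## Known limitations

* The implication search is target-centred; whole-network all-pairs graphs
  are not built.
* Equivalence/opposite relations are derivable from two implication calls
  but not searched directly — the motivating analysis uses one implication
  type.
* Continuous-covariate Cox scaling (e.g. VIM per log2 unit) is exposed but
  has no canonical unit here; treat such hazard ratios as
  configuration-dependent.
* Proportional-hazards diagnostics are not included.
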