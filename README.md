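# BoolScreen

Boolean-implication biomarker screening and prognostic stratification for
transcriptomics.

## What problem this solves

High vimentin (VIM) expression marks mesenchymal, stroma-rich colorectal
tumours with poor prognosis. A principled way to find candidate regulators
of that state is to search binarized expression data for genes X whose low
expression is (almost) never seen together with low VIM — an asymmetric
Boolean implication "X-low ⇒ VIM-high". Genes with that property define a
small marker-low patient subgroup whose prognostic value can then be tested
in survival cohorts. BoolScreen is for computational biologists who want
this discovery-and-validation pipeline as tested, reusable R functions:

1. **Step-function binarization** — for each gene, the sorted log2 values
   are fitted with a one-step function; the breakpoint minimizing
   `SSE_step = Σ_left (x − μL)² + Σ_right (x − μR)²` defines the cutoff
   `t = (μL + μR)/2`, with a configurable intermediate margin (default 0.5
   log2 units for implication analysis, 0 for patient labels).
2. **Implication search** — for the 2×2 low/high table of a gene pair, the
   sparse-quadrant statistic `S = (e − o)/√e` with
   `e = (n_LL + n_LH)(n_LL + n_HL)/n` and leak rate
   `err = (o/(n_LL + n_LH) + o/(n_LL + n_HL))/2`; a pair passes at
   `S > 3` and `err < 0.1`. Genome-wide, target-centred, with a
   within-gene permutation FDR.
3. **Candidate screening** — support fraction ≥ 0.40 of the searched
   population, plus >2-fold differential expression at p < 0.001 (Welch t)
   versus both normal mucosa and IBD tissue.
4. **Patient subgrouping and survival** — two-group (marker low/high) and
   three-group (marker × VIM) labels; Kaplan–Meier curves and 5-year rates,
   log-rank tests, multivariate Cox models (Efron ties), stage-restricted
   reruns, and the 2×2 marker-by-chemotherapy interaction on both the
   multiplicative scale (Cox product term) and the additive scale
   (RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1, delta-method CI).
5. **Baseline-table statistics** — Pearson χ² without continuity
   correction (Fisher fallback below expected count 5), pooled-variance
   Student t from group summaries, and the tie-corrected Mann–Whitney U on
   ordinal count tables.
6. **Synthetic cohorts** — a seeded generator that plants bimodal genes, a
   sparse-quadrant implication with leak ε, a 22.6% marker-low subgroup
   with MSI/BRAF enrichment, and proportional-hazards survival with known
   log hazard ratios, so every stage of the pipeline is testable against
   ground truth.

Expression data live in a `BooleanCallSet`, a `SummarizedExperiment`
subclass carrying the log2 assay, the call assay and the per-gene step fits.

## Worked example

```r
library(BoolScreen)
library(SummarizedExperiment)

cfg <- studyConfig(nCRC = 300, nPolyp = 10, nIBD = 60, nNormal = 60,
                   nGenes = 200, nBimodal = 20)
study <- generateStudy(cfg, seed = 7)           # planted marker: "MARKER1"
cs <- thresholdAllGenes(study$se, margin = 0.5)
cs
#> BooleanCallSet with 200 genes x 430 samples
#>   margin: 0.5 log2 units
#>   degenerate fits: 0

pop <- colnames(cs)[colData(cs)$tissue_class == "CRC"]
res <- searchPartners(cs, cfg$targetGene, population = pop)
head(res[, c("gene", "n", "statistic", "errorRate", "supportFraction",
             "passes")], 3)
#>      gene   n statistic errorRate supportFraction passes
#> 1 MARKER1 299  5.157065 0.0000000       0.9966667   TRUE
#> 2   g0005 299  1.640564 0.2780325       0.9966667  FALSE
#> 3   g0097 175  1.438905 0.3219616       0.5833333  FALSE

estimateFDR(cs, cfg$targetGene, population = pop, nPerm = 50, seed = 7)
#>   sMin errMax observed meanNull fdr
#> 1    3    0.1        1        0   0

fit <- coxFit(study$clinicalDiscovery, "DFS", c("group", "stage", "age60"))
fit$table
#>        term       HR        lo       hi            p
#> 1  grouplow 1.450505 1.0999302 1.912816 8.420766e-03
#> 2     stage 2.255808 1.8196118 2.796569 1.171206e-13
#> 3 age60>=60 1.178646 0.8961608 1.550175 2.397031e-01
```

The planted partner tops the ranking with `S = 5.16` and zero leak into the
sparse quadrant, it is the only pair passing the default thresholds
(permutation FDR 0 over 50 rounds), and the marker-low patients carry the
planted excess relapse hazard (HR 1.45 vs. the planted 1.37, CI covering
the truth) after adjustment for stage and age.

A thin command-line wrapper over the same functions ships in
`inst/cli/boolscreen.R` with subcommands `simulate`, `threshold`,
`implications`, `screen`, `survival` and `baseline`.

The methods vignette
(`vignettes/boolean-implication-screening.Rmd`) documents the models,
defaults, generator assumptions and design decisions.

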