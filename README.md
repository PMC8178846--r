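# dormsig

Tools for the computational side of tumor-dormancy studies: deriving a
cross-model dormancy gene-expression signature from grouped log2
expression data, scoring patient cohorts with signed gene lists, relating
median-dichotomized scores to survival by per-cohort Cox regression
combined in an inverse-variance meta-analysis, testing gene-set overlap
enrichment, and estimating tumor-initiating cell (TIC) frequency from
limiting-dilution transplants. A synthetic-data module generates inputs
with the statistical structure every stage assumes, so the whole pipeline
is testable without external data.

Intended users: computational biologists analyzing residual-disease /
dormancy expression experiments (sorted primary PT, residual RL, and
recurrent RT tumor-cell populations from two mouse models) and relating
derived signatures to breast-cancer cohort outcomes.

## Methods in brief

* **Differential expression** — variance-shrinkage (Cyber-T style) t-test:
  per-gene pooled variance `s²` shrunk toward the mean variance `σ₀²` of
  the `window` genes of nearest mean expression,
  `v = (ν₀σ₀² + (n−2)s²)/(ν₀ + n−2)`,
  `t = (x̄_A − x̄_B)/√(v(1/n_A + 1/n_B))` with `ν₀ + n − 2` df; at
  `ν₀ = 0` this is exactly the pooled Student t. FDR by
  Benjamini–Hochberg step-up.
* **Signature derivation** — a gene is kept iff `|FC| > 1.5` and
  `q < 0.1` with a concordant fold-change sign in all four comparisons
  (RL−PT, RL−RT in both models); weight = sign (+1 = up in residual
  lesions).
* **Scoring** — per-cohort weighted z-score average
  `score_j = Σ w_g z_gj / Σ|w_g|`; median-dichotomized (ties low).
* **Survival** — endpoint fallback RFS → DMFS → DSS; 5-year truncation or
  60-month landmark; Cox PH (Efron ties) for high vs low;
  inverse-variance meta-analysis with Cochran's Q heterogeneity test and
  DerSimonian–Laird random effects when Q's p < 0.05.
* **Limiting dilution** — single-hit Poisson `P(take|d) = 1 − e^{−fd}`,
  MLE on log f, profile-likelihood 95% CI, likelihood-ratio group
  comparison.
* **Enrichment** — one-sided hypergeometric overlap test.

## Worked example

```r
library(dormsig)

# two simulated mouse models with 60 planted concordant dormancy genes
m   <- generate_mouse_models(mouse_sim_config(planted_lfc = 2, seed = 42))
cmp <- mouse_comparisons(m$models)      # 4 regularized t-test tables
sig <- derive_dormancy_signature(cmp)
#> <gene_signature> 'dormancy': 58 genes (32 up, 26 down)

# 17 simulated cohorts (260 patients each) with a planted HR of 0.49
h <- generate_human_cohorts(human_sim_config(seed = 43), sig)
fits <- lapply(h$cohorts, function(ch) {
  sc <- dichotomize_by_median(score_samples(ch$expression, sig))
  cox_binary(truncate_5y(ch$survival), sc)
})
meta_analyze(fits)
#> <meta_result> 17 cohorts, fixed-effect model
#>   combined HR = 0.446 [0.401, 0.497], p = 8.54e-49
#>   Q = 7.93 (p = 0.951), tau^2 = 0.0000

# limiting-dilution TIC frequency (true f = 1/1500)
fit_frequency(generate_ld_assay(1/1500, doses = c(100, 300, 1000, 3000),
                                n_per_dose = 6, seed = 44))
#> <ld_fit> sim: f = 0.0005971 (1 in 1675), 95% CI [0.0002759, 0.001144], 4 dose(s)
```

The signature recovers 58 of the 60 planted genes; the combined hazard
ratio 0.446 [0.401, 0.497] brackets the planted 0.49 (dormancy-high
patients relapse at roughly half the rate of dormancy-low patients); the
heterogeneity test is null, so the fixed-effect model is selected; the
limiting-dilution CI covers the true frequency 1/1500.

## Command line

```sh
Rscript inst/cli/dormsig.R run-all --seed 1 --out results/
Rscript inst/cli/dormsig.R simulate --seed 1 --out simdata/
Rscript inst/cli/dormsig.R ld --assays assays.tsv --out ldout/
Rscript inst/cli/dormsig.R enrich --de de.txt --set set.txt --universe univ.txt --out enr/
```

`run-all` writes per-stage DE tables, the derived signature (GMT), score
tables, a forest table, and a JSON meta-analysis summary, and is
byte-reproducible for a fixed seed.

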