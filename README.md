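# hamgp — two-step genomic evaluation of dry-cured ham weight loss

Weight loss during dry-curing (WL) is a breeding goal of the Italian pig
lines used for protected-designation-of-origin hams: hams that lose too
much weight during the 12+ months of seasoning lose marketable product.
Phenotyping is slow (the trait exists only at the end of curing) and
expensive (every ham must be traced individually), so two workarounds are
combined in the design this package implements:

* **sib testing** — purebred nucleus boars (PB) are evaluated through the
  phenotypes of their crossbred half-sib finishing pigs (CB), and
* **an infrared proxy** — a spectroscopy-based prediction of WL available
  24 h after slaughter (IR), genetically correlated with the observed
  trait (OB) at about 0.85.

`hamgp` is a complete, testable re-implementation of the two-step genomic
evaluation used to compare models trained on OB versus IR:

1. **Animal model (pedigree BLUP).** The univariate/bivariate mixed model
   `y = Xb + Za + e`, with sex and slaughter-batch fixed effects and
   `a ~ N(0, A sigma_a^2)` on the pedigree relationship matrix `A`.
   Variance components come from EM-REML (with a guarded acceleration and
   a sparse-Cholesky + Takahashi selected-inverse backend, so the exact
   C-inverse traces and PEVs are available at pedigree scale). The model
   yields the two pseudo-phenotypes: the adjusted phenotype
   `y_adj = y - X b_hat` and the EBV with accuracy
   `r = sqrt(1 - PEV / sigma_g^2)`.
2. **Whole-genome regression (the Bayesian alphabet).** Five Gibbs-sampled
   marker models — Bayesian ridge regression, BayesA, BayesB, BayesC,
   Bayesian Lasso — regress CB pseudo-phenotypes on SNP dosages
   `y = 1 mu + W g + e` (EBV reliabilities enter as residual-precision
   weights), and direct genomic values are `DGV_i = sum_j w_ij g_hat_j`.
3. **Validation.** Nine training-validation scenarios (train on OB or IR,
   on `y_adj` or EBV; validate CB or their PB sires) under 5-fold random
   cross-validation and leave-one-family-out (LOFO) validation, with
   Pearson accuracies, Fisher-z confidence intervals and relative
   accuracy `r / sqrt(h2)`.

The original data are proprietary, so the package ships a first-class
synthetic-data module: a closed purebred sire line crossed to unrelated
dams producing half-sib families, gene-dropped biallelic SNPs, and a
bivariate (OB, IR) trait pair with configurable heritabilities, genetic
correlation and record-availability pattern.

## Worked example

```r
library(hamgp)

# a small sib-testing population: 12 boars x 20 crossbreds, 800 SNPs
p <- sim_params(n_sire_families = 12, n_offspring_per_sire = 20,
                n_purebred_generations = 1, n_snps = 800, n_qtl = 200,
                seed = 42)
pop <- simulate_population(p)

# step 0: genotype quality control + mean imputation
qc <- qc_filter(pop$genotypes)
qc$report
#> <ham_qc_report>
#>   SNPs in: 800 | sex-chr: 16 | call rate: 0 | MAF: 21 | retained: 763
#>   samples in: 435 | call rate: 0 | retained: 435

# step 1: animal model -> pseudo-phenotypes
ps <- compute_pseudophenotypes(pop$phenotypes, pop$pedigree)
round(ps$h2, 2)
#>   ob   ir
#> 0.61 0.57    # 12 families is far too small for a precise h2 -- the
#>              # simulation truth is 0.31/0.39; see the vignette

# step 2 + validation: BRR on scenario 2 (train and validate on OB EBV)
W <- mean_impute(qc$genotypes)$dosage
colnames(W) <- qc$genotypes$map$snp
keep <- pop$pedigree$id[pop$pedigree$population %in% c("CB", "PB")]
bundle <- validation_bundle(W[keep, ], ps$cb, ps$pb, h2 = ps$h2)
cfg <- marker_model_config("BRR", n_iter = 5000, burn_in = 1000, thin = 5)
run_scenarios(bundle, scenarios = 2, models = "BRR",
              scheme = "random_cv", config = cfg, seed = 1)
#>   scenario model    scheme   n    r r_fold_mean se_fold ci_lower ci_upper
#> 1        2   BRR random_cv 156 0.67       0.671  0.0448    0.573    0.748
```

The correlation `r` between DGV and EBV in the held-out crossbreds is the
model's accuracy for that scenario (the numbers above are from the seed
shown; a fresh R session reproduces them exactly).

An end-to-end run (simulate → QC → evaluate → train → validate → report)
with a JSON config and a reproducibility manifest:

```r
run_pipeline(as_pipeline_config(list(
  seed = 7, output_dir = "out",
  sim = list(n_sire_families = 10, n_offspring_per_sire = 10,
             n_snps = 500),
  validation = list(scenarios = c(2, 3), schemes = "random_cv",
                    models = "BRR", k = 3))))
```

or from a shell: `Rscript -e 'hamgp::hamgp_cli()' run-all --config cfg.json`.

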