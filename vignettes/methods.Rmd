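---
title: "Models, simulation design and numerical choices in hamgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation design and numerical choices in hamgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`hamgp` implements a two-step genomic evaluation for ham weight loss
during dry-curing in a crossbred sib-testing design, together with the
synthetic-data generator that makes the whole pipeline testable without
the proprietary records it was designed around. This vignette explains
the models, what the generator does and does not emulate, and the
numerical decisions a maintainer would want to know about. It states no
empirical result that the test suite or the acceptance script does not
itself compute.

## 1. The animal model and its pseudo-phenotypes

Step one is the pedigree animal model

```
y = X b + Z a + e,   a ~ N(0, A * sigma_a^2),   e ~ N(0, I * sigma_e^2)
```

with fixed effects `b` = sex (female / castrate) and slaughter batch, and
`A` the additive relationship matrix from the full pedigree. Two
pseudo-phenotypes are derived for each trait: the phenotype adjusted for
fixed effects, `y_adj = y - X b_hat`, and the EBV with its accuracy
`r = sqrt(1 - PEV / sigma_g^2)`, where `sigma_g^2` is interpreted as the
estimated additive genetic variance of the trait (the literature this
design comes from uses both symbols for the same quantity).

Fixed effects are parameterized for bit-reproducibility: the first sex
level is constrained to zero and every batch level keeps its own column,
so the batch block absorbs the intercept. With a single batch and a
single sex this reduces `y_adj` to centred phenotypes.

**Variance components** come from EM-REML. Each E-step solves Henderson's
mixed-model equations and extracts the exact entries of the inverse
coefficient matrix needed by the closed-form M-step updates:
`sigma_a^2 <- (a' A^-1 a + tr(A^-1 C^aa)) / q` and the per-record
residual corrections `w' C^-1 w`. For systems beyond ~2,500 equations,
those entries come from a simplicial sparse Cholesky factorization plus a
Takahashi selected inversion (a compiled kernel), which yields the
inverse exactly on the factor pattern — a superset of the entries the
traces, residual corrections and PEVs need. Both routes (dense
`chol2inv` and sparse selected inversion) implement one interface and are
tested to agree to machine precision; PEV is therefore always an exact
factorization quantity, never an approximation formula.

The **bivariate** model stacks the two traits with unstructured 2x2
genetic (`G0`) and residual (`R0`) matrices. Records may be missing
trait-wise; the residual covariance is estimable only from animals
recorded on both traits, and the M-step updates each `R0` element from
the animals that inform it. Interim non-positive-definite `G0`/`R0`
matrices are projected to the nearest PD matrix (eigenvalue clamping at
1e-10) and the event is counted in the convergence metadata.

**Acceleration and stopping.** Plain EM is robust but can crawl. Each
cycle applies two EM steps and then a guarded extrapolation of the EM map
(a SQUAREM-type step): the extrapolated point is accepted only if the
restricted likelihood did not decrease, so the accepted sequence stays
monotone up to a 1e-8 slack. Iteration stops when the largest relative
parameter change in a cycle falls below `tol`, or when the restricted
likelihood is flat to its own numerical noise floor (relative 1e-8) for
two consecutive cycles — near the optimum the likelihood of a
several-thousand-record model cannot be resolved more finely in double
precision, and insisting on parameter-change convergence there just burns
factorizations. Standard errors, when requested, come from the
numerically differentiated restricted likelihood.

**Pedigree pruning.** Before a REML fit, ancestors that cannot inform the
fit are removed by two rules that provably leave `A` over the remaining
animals unchanged: childless non-kept animals, and non-kept founders with
exactly one offspring (this removes the dams' placeholder parent and
grandparent chains). Inbreeding is handled exactly throughout
(Meuwissen-Luo coefficients feed Henderson's rules for the sparse
`A^-1`), because the purebred line is closed and ignoring `F` would bias
PEV.

## 2. Marker models

Step two regresses crossbred pseudo-phenotypes on SNP dosages,
`y = 1 mu + W g + e`, with five priors on the allele-substitution
effects: a common normal (BRR), per-SNP scaled-inverse-chi-square
variances (BayesA), the same with a point mass at zero (BayesB), a common
variance with a point mass (BayesC), and the double-exponential via the
exponential-mixture augmentation (Bayesian Lasso). All are single-site
Gibbs samplers with residual updating (O(n p) per sweep, compiled), using
R's RNG so `set.seed()` governs chains end to end.

Prior scales are elected from the training data: all variance priors use
df = 5, the marker-variance scale is chosen so its prior mode explains
R² = 0.5 of `var(y)` spread over the markers' `sum(2 p q)` mass, the
residual scale targets the complement, BayesB inflates the marker scale
by `1/pi`, and `pi ~ Beta` with prior mean 0.5 and 10 prior counts. The
Lasso's `lambda^2` gets a Gamma hyper-prior centred on the same R² split.
These elections follow the default-setting conventions of the widely
used Bayesian regression software for this model family; exact published
formulas vary slightly across versions, so one rule is fixed here and
validated behaviourally (a recovery test checks the elected priors give a
sane genomic heritability).

When training on EBV, the record weights default to squared accuracy
(reliability), entering as residual precision multipliers
(`var(e_i) = sigma_e^2 / w_i`); weighting by `r` instead of `r^2` is a
config switch, since the design this follows states only that accuracies
were used as weights. No deregression is applied — EBV are used as
pseudo-phenotypes exactly as produced, which is a known source of
shrinkage and is documented rather than corrected.

Dosages are **not** column-centred, matching the literal DGV definition
`DGV_i = sum_j w_ij g_hat_j` (no intercept term). All reported metrics
are correlations, which are location-invariant, so centring would not
change any result; the intercept absorbs the mean during training.

Chain defaults are 20,000 iterations / 4,000 burn-in / thin 20 — a
desk-scale compromise validated by the chain-robustness and
oracle-equivalence tests; `paper_chain = TRUE` selects the full
500,000 / 100,000 / 100 production chain.

## 3. Validation designs

The nine scenarios cross {training trait OB/IR} x {pseudo-phenotype
y_adj/EBV} x {validation population CB/PB}. Random cross-validation
splits the recorded crossbreds into five equal segments; leave-one-family
-out (LOFO) removes one paternal half-sib family per round and scores
both the held-out crossbreds and the family's sire. Random CV reports
the per-fold mean and SE of the correlation (the convention of the
design's accuracy tables); LOFO reports one pooled correlation over all
holdout predictions with a Fisher-z CI (`z` multiplier fixed at 1.96,
validated against printed intervals to three decimals). Purebred sires
in random CV are re-scored every fold (about 80% of each sire's progeny
remains in training — the mechanic that makes CV optimistic for sires);
in LOFO each sire is scored once, in the round that drops its own family.
Pseudo-phenotypes for random CV come from univariate fits; LOFO uses the
bivariate fit, which also equips crossbreds lacking the observed trait
with an EBV for it. p-values are reported exactly, with
`format_p_binned()` available for the journal-style bins.

## 4. The synthetic world

The generator emulates the statistical structure the analysis assumes:

* a closed purebred line (default two generations) ending in the nucleus
  boars, crossed to unrelated dams (litters of 10, so 35 offspring per
  sire means 4 dams); dams carry founder-placeholder parents and
  grandparents, mirroring a pedigree known only a couple of generations
  back on the maternal side;
* gene-dropped biallelic SNPs: founder B-allele frequencies uniform on
  `maf_range`, fair Mendelian transmission, 18 autosomes plus a small X
  block (2% of SNPs) so QC has something to remove, and a configurable
  missing-call rate. Loci are unlinked by design — population-wide LD
  beyond family structure is **not** simulated, so absolute DGV
  accuracies here lean on family LD and should not be read as forecasts
  for a real 50K panel;
* a bivariate trait pair: true breeding values either from bivariate
  effects at a finite QTL subset (default 500 of the SNPs, rescaled so
  the realized additive variance over crossbreds matches `h2 * sd^2`
  exactly) or from the pedigree Mendelian-sampling recursion
  (`trait_mode = "infinitesimal"`, the exact animal-model world, used for
  sampler-free parameter-recovery checks);
* phenotypes = trait mean + a symmetric sex contrast (default 0.3, in
  percent of green-ham weight) + zero-mean batch effects (default SD 0.5,
  batches of about 70) + TBV + residuals whose cross-trait correlation is
  solved from `r_p = r_g h h' + r_e e e'` to hit the target phenotypic
  correlation (default 0.65); infeasible combinations are an explicit
  error, never clamped;
* records only on crossbreds; the observed trait is recorded for a
  random 65% of them (the genotyped-cohort ratio of the motivating
  design, 640/956), always a subset of the proxy-recorded animals.

Defaults are the study's stated numbers where stated (means 27.8/26.5,
SDs 2.4/1.8, h² 0.31/0.39, genetic correlation 0.85, phenotypic
correlation 0.65, 35 offspring per sire, ~70 per batch); the sex and
batch magnitudes, dam litter structure and missing-call rate are not
stated anywhere and are fixed plumbing choices, documented above and not
revisited. `sd` parameters are interpreted as the within sex-by-batch
phenotypic SD, so the descriptive SD of simulated phenotypes slightly
exceeds them.

A single `seed` fans out to fixed per-stage streams (pedigree,
genotypes, traits, folds, samplers), so any stage can be re-run
independently and byte-identically.

What a green test establishes: the estimators recover the parameters of
*this* stated world and the pipeline's orderings match the qualitative
structure of the motivating study (EBV-trained > y_adj-trained, random
CV > LOFO, proxy-trained sire prediction below within-trait). What it
does not establish: the study's headline correlations, which are
properties of a proprietary dataset with real LD, real selection history
and a deep pedigree.

## 5. Numerical details and degenerate inputs

* Removal order in QC is fixed (sex chromosomes, SNP call rate, sample
  call rate, MAF on surviving samples) because MAF depends on the sample
  set; thresholds are strict inequalities. QC is idempotent and its
  report counts reconcile with matrix dimensions by construction.
* Mean imputation stands in for pedigree-haplotype imputation, which is
  out of scope; downstream samplers accept fractional dosages. A masking
  test keeps it honest against a random-fill baseline.
* `ebv_accuracy()` clamps tiny negative PEVs to zero and errors when PEV
  exceeds the genetic variance by more than 5% — that combination always
  indicates an inconsistent MME/REML pairing, not a numerical wobble.
* Singular fixed-effect blocks (e.g., batch perfectly confounded with
  sex) are reported with the names of the dependent columns.
* Variance parameters drifting to the boundary are clamped at 1e-10 and
  counted; pure-noise data drive heritability to that boundary, which is
  the correct degenerate answer.
* Scenario runs cache marker-model fits within a call: scenarios that
  share a training configuration (e.g., within-trait and sire-validated
  variants of the same training) reuse the same chains.

## 6. Known limitations

* No linkage/LD simulation (coalescent back-ends are a non-goal); no
  selection over generations; no maternal effects, repeated records or
  more than two traits.
* The infrared proxy is generated directly as a genetically correlated
  trait; the spectroscopy prediction model that produces it in reality is
  intentionally out of scope.
* EM-REML standard errors use numerical second derivatives and are
  approximate; they are reported for orientation, not inference.
* LOFO with all five marker models is supported but expensive; the
  Bayesian ridge is the default there, matching the design's own choice.
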