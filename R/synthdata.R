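#' Simulation parameters for the synthetic sib-testing population
#'
#' Bundles and checks every knob of the synthetic-data generator. Defaults
#' describe a purebred sire line whose nucleus boars (PB) are mated to
#' unrelated dams to produce crossbred (CB) paternal half-sib families, with
#' a bivariate trait pair: observed dry-curing weight loss (OB) and its
#' infrared prediction (IR), both in percent of green-ham weight.
#'
#' @param n_sire_families Number of PB nucleus boars / half-sib families.
#' @param n_offspring_per_sire CB offspring per boar (default 35).
#' @param n_purebred_generations Generations bred within the closed purebred
#'   line before the nucleus boars (0 = boars are founders).
#' @param n_snps Number of biallelic SNPs to gene-drop.
#' @param n_qtl Number of SNPs carrying true effects in `trait_mode = "qtl"`;
#'   default 500, capped at `n_snps`.
#' @param maf_range Founder B-allele frequency range, within (0, 0.5].
#' @param h2_ob,h2_ir Narrow-sense heritabilities in (0, 1).
#' @param r_g Additive genetic correlation between OB and IR.
#' @param r_p_target Target phenotypic correlation (residual correlation is
#'   solved from `r_g`, the heritabilities and this value).
#' @param mean_ob,sd_ob,mean_ir,sd_ir Trait means and within sex-by-batch
#'   phenotypic standard deviations, percent units.
#' @param n_batches Number of slaughter batches; `NULL` means about 70 CB
#'   per batch.
#' @param batch_effect_sd SD of the batch effects (percent units).
#' @param sex_effect Fixed female-vs-castrate contrast (percent units),
#'   applied symmetrically (-/+ half) so trait means are preserved.
#' @param frac_ob_recorded Fraction of CB with an OB record (IR is recorded
#'   for all CB; OB-recorded animals are a subset, mirroring the much larger
#'   availability of the infrared proxy).
#' @param missing_geno_rate Fraction of genotype calls masked as missing.
#' @param litter_size CB per dam (dams per sire = offspring / litter size).
#' @param dam_pedigree_depth Generations of founder-placeholder ancestors
#'   attached to each dam (2 = parents and grandparents known by name only).
#' @param n_sex_chr_snps SNPs placed on the X chromosome so that QC has
#'   something to remove; default 2 percent of `n_snps`.
#' @param trait_mode `"qtl"` (finite loci with bivariate effects, default)
#'   or `"infinitesimal"` (pedigree Mendelian-sampling recursion; no
#'   genotype needed, exact animal-model world for sampler-free tests).
#' @param seed Integer seed; all stages derive independent sub-seeds from it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_sire_families = 57L,
                       n_offspring_per_sire = 35L,
                       n_purebred_generations = 2L,
                       n_snps = 5000L,
                       n_qtl = NULL,
                       maf_range = c(0.05, 0.5),
                       h2_ob = 0.31, h2_ir = 0.39,
                       r_g = 0.85, r_p_target = 0.65,
                       mean_ob = 27.8, sd_ob = 2.4,
                       mean_ir = 26.5, sd_ir = 1.8,
                       n_batches = NULL,
                       batch_effect_sd = 0.5,
                       sex_effect = 0.3,
                       frac_ob_recorded = 0.65,
                       missing_geno_rate = 0.01,
                       litter_size = 10L,
                       dam_pedigree_depth = 2L,
                       n_sex_chr_snps = NULL,
                       trait_mode = c("qtl", "infinitesimal"),
                       seed = 1L) {
  trait_mode <- match.arg(trait_mode)
  if (is.null(n_sex_chr_snps)) n_sex_chr_snps <- round(0.02 * n_snps)
  if (is.null(n_qtl)) n_qtl <- min(500L, as.integer(n_snps))
  p <- list(n_sire_families = as.integer(n_sire_families),
            n_offspring_per_sire = as.integer(n_offspring_per_sire),
            n_purebred_generations = as.integer(n_purebred_generations),
            n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
            maf_range = as.numeric(maf_range),
            h2_ob = h2_ob, h2_ir = h2_ir, r_g = r_g,
            r_p_target = r_p_target,
            mean_ob = mean_ob, sd_ob = sd_ob,
            mean_ir = mean_ir, sd_ir = sd_ir,
            n_batches = if (is.null(n_batches)) NULL else as.integer(n_batches),
            batch_effect_sd = batch_effect_sd, sex_effect = sex_effect,
            frac_ob_recorded = frac_ob_recorded,
            missing_geno_rate = missing_geno_rate,
            litter_size = as.integer(litter_size),
            dam_pedigree_depth = as.integer(dam_pedigree_depth),
            n_sex_chr_snps = as.integer(n_sex_chr_snps),
            trait_mode = trait_mode,
            seed = as.integer(seed))
  with(p, {
    stopifnot(n_sire_families >= 1L, n_offspring_per_sire >= 1L,
              n_purebred_generations >= 0L,
              n_snps >= 1L, n_qtl >= 0L, n_qtl <= n_snps,
              length(maf_range) == 2L, maf_range[1] > 0,
              maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
              h2_ob > 0, h2_ob < 1, h2_ir > 0, h2_ir < 1,
              abs(r_g) <= 1, abs(r_p_target) <= 1,
              sd_ob > 0, sd_ir > 0,
              frac_ob_recorded > 0, frac_ob_recorded <= 1,
              missing_geno_rate >= 0, missing_geno_rate < 1,
              litter_size >= 1L, dam_pedigree_depth >= 0L,
              n_sex_chr_snps >= 0L, n_sex_chr_snps < n_snps)
  })
  class(p) <- "sim_params"
  p
}

# One global seed fans out to named per-stage streams so each stage can be
# re-run on its own and still be reproducible.
stage_seed <- function(seed, stage) {
  stages <- c(pedigree = 11L, genotypes = 29L, traits = 47L,
              folds = 83L, sampler = 131L)
  off <- stages[[stage]]
  (as.integer(seed) * 7919L + off * 104729L) %% 2147483647L
}

#' Simulate the pedigree of the sib-testing design
#'
#' Builds (a) a closed purebred line bred for `n_purebred_generations`,
#' ending in the nucleus boars (population `"PB"`); (b) unrelated dams with
#' founder-placeholder ancestors (`"DAM"`, `"DAM_ANC"`); and (c) crossbred
#' offspring in paternal half-sib families (`"CB"`), each with a sex
#' (`"F"` female / `"C"` castrate) and a slaughter batch of about 70
#' animals. Parents always precede offspring.
#'
#' @param params A [sim_params()] object.
#' @return A `ham_pedigree` with columns `id, sire, dam, sex, population,
#'   family, batch`.
#' @export
simulate_pedigree <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "pedigree"))
  S <- params$n_sire_families
  rec <- list()
  push <- function(id, sire, dam, sex, pop, fam = NA, batch = NA)
    rec[[length(rec) + 1L]] <<- data.frame(
      id = id, sire = sire, dam = dam, sex = sex, population = pop,
      family = fam, batch = batch, stringsAsFactors = FALSE)

  # --- purebred line ---
  if (params$n_purebred_generations == 0L) {
    boars <- paste0("PB", seq_len(S))
    push(boars, "0", "0", "M", "PB")
  } else {
    nm0 <- max(2L, ceiling(S / 4)); nf0 <- S
    males <- paste0("L0M", seq_len(nm0))
    females <- paste0("L0F", seq_len(nf0))
    push(males, "0", "0", "M", "PB_ANC")
    push(females, "0", "0", "F", "PB_ANC")
    for (g in seq_len(params$n_purebred_generations)) {
      last <- g == params$n_purebred_generations
      nm <- S; nf <- if (last) 0L else S
      new_m <- if (last) paste0("PB", seq_len(S))
               else paste0("L", g, "M", seq_len(nm))
      new_f <- if (nf) paste0("L", g, "F", seq_len(nf)) else character(0)
      kids <- c(new_m, new_f)
      push(kids, sample(males, length(kids), replace = TRUE),
           sample(females, length(kids), replace = TRUE),
           rep(c("M", "F"), c(length(new_m), length(new_f))),
           if (last) rep(c("PB", "F_UNUSED"), c(length(new_m), 0L))
           else "PB_ANC")
      males <- new_m; if (nf) females <- new_f
    }
    boars <- paste0("PB", seq_len(S))
  }

  # --- dams: unrelated founders of another line, placeholder ancestors ---
  dams_per_sire <- ceiling(params$n_offspring_per_sire / params$litter_size)
  n_dams <- S * dams_per_sire
  dam_id <- paste0("D", seq_len(n_dams))
  if (params$dam_pedigree_depth >= 1L) {
    # build each dam's private ancestor chain, deepest first
    anc_s <- paste0("DS", seq_len(n_dams)); anc_d <- paste0("DD", seq_len(n_dams))
    if (params$dam_pedigree_depth >= 2L) {
      gps <- paste0("DGS", rep(seq_len(n_dams), each = 2), c("a", "b"))
      gpd <- paste0("DGD", rep(seq_len(n_dams), each = 2), c("a", "b"))
      push(gps, "0", "0", "M", "DAM_ANC")
      push(gpd, "0", "0", "F", "DAM_ANC")
      push(anc_s, gps[c(TRUE, FALSE)], gpd[c(TRUE, FALSE)], "M", "DAM_ANC")
      push(anc_d, gps[c(FALSE, TRUE)], gpd[c(FALSE, TRUE)], "F", "DAM_ANC")
    } else {
      push(anc_s, "0", "0", "M", "DAM_ANC")
      push(anc_d, "0", "0", "F", "DAM_ANC")
    }
    push(dam_id, anc_s, anc_d, "F", "DAM")
  } else {
    push(dam_id, "0", "0", "F", "DAM")
  }

  # --- crossbred half-sib families ---
  n_cb <- S * params$n_offspring_per_sire
  cb_id <- paste0("CB", seq_len(n_cb))
  cb_sire <- rep(boars, each = params$n_offspring_per_sire)
  dam_of_sire <- matrix(dam_id, nrow = dams_per_sire)
  cb_dam <- unlist(lapply(seq_len(S), function(k) {
    rep(dam_of_sire[, k], each = params$litter_size,
        length.out = params$n_offspring_per_sire)
  }))
  cb_sex <- sample(c("F", "C"), n_cb, replace = TRUE)
  nb <- if (is.null(params$n_batches)) max(1L, round(n_cb / 70)) else
    params$n_batches
  batch <- sample(rep_len(seq_len(nb), n_cb))  # batches mix families
  push(cb_id, cb_sire, cb_dam, cb_sex, "CB", fam = cb_sire,
       batch = paste0("B", batch))
  ped <- do.call(rbind, rec)
  validate_pedigree(ped)
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founders draw B-allele counts from `Binomial(2, q_j)` with `q_j` uniform
#' on `maf_range`; every non-founder receives one allele per parent by fair
#' Mendelian transmission (an unknown parent transmits a population allele
#' at the founder frequency). SNPs sit on 18 autosomes plus an X block, and
#' a fraction of calls is masked missing. Loci are unlinked by design.
#'
#' @param pedigree A `ham_pedigree` from [simulate_pedigree()].
#' @param params A [sim_params()] object.
#' @param retain `"all"` (default) or `"cb_pb"` to keep only crossbreds and
#'   nucleus boars, the genotyped populations of the study design.
#' @return A `ham_geno` object: list with integer `dosage` matrix (animals x
#'   SNPs, `NA` = missing), `map` data.frame (`snp, chr, pos, allele_a,
#'   allele_b`), and founder frequencies `founder_freq`.
#' @export
simulate_genotypes <- function(pedigree, params, retain = c("all", "cb_pb")) {
  retain <- match.arg(retain)
  ped <- validate_pedigree(pedigree)
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "genotypes"))
  n <- nrow(ped); p <- params$n_snps
  q <- stats::runif(p, params$maf_range[1], params$maf_range[2])
  G <- matrix(0L, n, p, dimnames = list(ped$id, NULL))
  s <- ped$sire_idx; d <- ped$dam_idx
  for (i in seq_len(n)) {
    pat <- if (s[i] > 0L) stats::rbinom(p, 1L, G[s[i], ] / 2)
           else stats::rbinom(p, 1L, q)
    mat <- if (d[i] > 0L) stats::rbinom(p, 1L, G[d[i], ] / 2)
           else stats::rbinom(p, 1L, q)
    G[i, ] <- pat + mat
  }
  # deterministic layout: autosomes cycle 1..18 (sorted blocks), X block last
  n_aut <- p - params$n_sex_chr_snps
  chr <- c(sort(rep_len(as.character(1:18), n_aut)),
           rep("X", params$n_sex_chr_snps))
  map <- data.frame(snp = paste0("snp", seq_len(p)), chr = chr,
                    pos = as.integer(seq_len(p) * 1000L),
                    allele_a = "A", allele_b = "B",
                    stringsAsFactors = FALSE)
  if (retain == "cb_pb") {
    keep <- ped$population %in% c("CB", "PB")
    G <- G[keep, , drop = FALSE]
  }
  if (params$missing_geno_rate > 0) {
    nmiss <- round(params$missing_geno_rate * length(G))
    G[sample(length(G), nmiss)] <- NA_integer_
  }
  structure(list(dosage = G, map = map, founder_freq = q),
            class = "ham_geno")
}

#' @export
print.ham_geno <- function(x, ...) {
  cat("<ham_geno> ", nrow(x$dosage), " animals x ", ncol(x$dosage),
      " SNPs; ", round(100 * mean(is.na(x$dosage)), 2), "% missing\n",
      sep = "")
  invisible(x)
}

# upper-triangular U with U'U = [[1, c], [c, 1]]; exact at |c| = 1
chol_cor2 <- function(c) matrix(c(1, 0, c, sqrt(max(0, 1 - c^2))), 2, 2)

# residual correlation implied by target phenotypic correlation:
# r_p = r_g * h1 * h2 + r_e * e1 * e2 with h = sqrt(h2), e = sqrt(1 - h2)
implied_residual_cor <- function(h2_1, h2_2, r_g, r_p) {
  re <- (r_p - r_g * sqrt(h2_1 * h2_2)) / sqrt((1 - h2_1) * (1 - h2_2))
  if (abs(re) > 1)
    stop("infeasible (r_g, h2, r_p_target) combination: implied residual ",
         "correlation ", round(re, 3), " outside [-1, 1]")
  re
}

#' Simulate the bivariate OB/IR trait pair
#'
#' True breeding values come either from bivariate effects at a finite QTL
#' subset of the simulated SNPs (`trait_mode = "qtl"`, effect correlation
#' `r_g`, per-trait effects rescaled so the realized additive variance over
#' CB equals `h2 * sd^2`) or from the pedigree Mendelian-sampling recursion
#' (`"infinitesimal"`). Phenotypes add the trait mean, a symmetric sex
#' contrast, zero-mean batch effects and residuals whose cross-trait
#' correlation is solved so the phenotypic OB-IR correlation hits
#' `r_p_target`. Only CB are phenotyped; OB is recorded for a random
#' fraction `frac_ob_recorded` of them (a subset of the IR-recorded CB).
#'
#' @param pedigree A `ham_pedigree`.
#' @param genotypes A `ham_geno` covering all pedigree animals (`retain =
#'   "all"`), or `NULL` in infinitesimal mode.
#' @param params A [sim_params()] object.
#' @return List with `phenotypes` (data.frame `id, ob, ir, sex, batch,
#'   family`; `NA` = missing) and `truth` (per-animal TBV, QTL effects,
#'   realized variance components).
#' @export
simulate_traits <- function(pedigree, genotypes = NULL, params) {
  ped <- validate_pedigree(pedigree)
  stopifnot(inherits(params, "sim_params"))
  set.seed(stage_seed(params$seed, "traits"))
  va <- c(ob = params$h2_ob * params$sd_ob^2,
          ir = params$h2_ir * params$sd_ir^2)
  ve <- c(ob = (1 - params$h2_ob) * params$sd_ob^2,
          ir = (1 - params$h2_ir) * params$sd_ir^2)
  re <- implied_residual_cor(params$h2_ob, params$h2_ir,
                             params$r_g, params$r_p_target)
  is_cb <- ped$population == "CB"
  n <- nrow(ped)

  qtl <- NULL
  if (params$trait_mode == "qtl") {
    if (is.null(genotypes))
      stop("trait_mode 'qtl' needs genotypes for every pedigree animal")
    G <- genotypes$dosage
    if (!all(ped$id %in% rownames(G)))
      stop("genotypes must cover all pedigree animals (retain = 'all')")
    if (params$n_qtl < 1L) stop("n_qtl must be >= 1 in qtl mode")
    aut <- which(genotypes$map$chr != "X")
    qtl_idx <- sort(sample(aut, min(params$n_qtl, length(aut))))
    L <- chol_cor2(params$r_g)
    beta <- matrix(stats::rnorm(2L * length(qtl_idx)), ncol = 2) %*% L
    Wq <- G[ped$id, qtl_idx, drop = FALSE]
    Wq[is.na(Wq)] <- 0L  # truth built on the unmasked drop; mask is tiny
    tbv <- Wq %*% beta
    # rescale so realized additive variance over CB matches the target
    sc <- sqrt(va / c(stats::var(tbv[is_cb, 1]), stats::var(tbv[is_cb, 2])))
    tbv <- sweep(tbv, 2, sc, `*`)
    beta <- sweep(beta, 2, sc, `*`)
    tbv <- sweep(tbv, 2, colMeans(tbv[is_cb, , drop = FALSE]), `-`)
    qtl <- data.frame(snp = genotypes$map$snp[qtl_idx],
                      beta_ob = beta[, 1], beta_ir = beta[, 2])
  } else {
    L0 <- chol_cor2(params$r_g) %*% diag(sqrt(va))
    F <- inbreeding(ped); F0 <- c(0, F)
    s <- ped$sire_idx; d <- ped$dam_idx
    tbv <- matrix(0, n, 2)
    z <- matrix(stats::rnorm(2L * n), n, 2)
    for (i in seq_len(n)) {
      ms_var <- if (s[i] > 0L && d[i] > 0L)
        0.5 - 0.25 * (F0[s[i] + 1L] + F0[d[i] + 1L])
      else if (s[i] > 0L || d[i] > 0L) 0.75 - 0.25 * F0[max(s[i], d[i]) + 1L]
      else 1
      mid <- 0.5 * ((if (s[i] > 0L) tbv[s[i], ] else c(0, 0)) +
                    (if (d[i] > 0L) tbv[d[i], ] else c(0, 0)))
      tbv[i, ] <- mid + sqrt(ms_var) * drop(z[i, ] %*% L0)
    }
  }
  rownames(tbv) <- ped$id

  # residuals with solved cross-trait correlation, CB only
  cb <- ped[is_cb, ]
  ncb <- nrow(cb)
  eres <- matrix(stats::rnorm(2L * ncb), ncb, 2) %*%
    (chol_cor2(re) %*% diag(sqrt(ve)))

  nb <- length(unique(cb$batch))
  beff <- matrix(stats::rnorm(2L * nb, 0, params$batch_effect_sd), nb, 2,
                 dimnames = list(sort(unique(cb$batch)), NULL))
  sexc <- ifelse(cb$sex == "C", params$sex_effect / 2, -params$sex_effect / 2)

  ob <- params$mean_ob + sexc + beff[cb$batch, 1] + tbv[cb$id, 1] + eres[, 1]
  ir <- params$mean_ir + sexc + beff[cb$batch, 2] + tbv[cb$id, 2] + eres[, 2]
  keep_ob <- sample(ncb) <= round(params$frac_ob_recorded * ncb)
  ob[!keep_ob] <- NA_real_

  phen <- data.frame(id = cb$id, ob = ob, ir = ir, sex = cb$sex,
                     batch = cb$batch, family = cb$family,
                     stringsAsFactors = FALSE)
  truth <- list(
    tbv = data.frame(id = ped$id, tbv_ob = tbv[, 1], tbv_ir = tbv[, 2],
                     stringsAsFactors = FALSE),
    qtl = qtl,
    va = c(ob = stats::var(tbv[is_cb, 1]), ir = stats::var(tbv[is_cb, 2])),
    ve = ve, residual_cor = re,
    batch_effects = beff, sex_effect = params$sex_effect)
  list(phenotypes = phen, truth = truth)
}

#' Simulate a complete population bundle
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] (skipped in infinitesimal mode unless
#' `force_genotypes`) and [simulate_traits()].
#'
#' @param params A [sim_params()] object.
#' @param force_genotypes Simulate genotypes even in infinitesimal mode.
#' @return List `pedigree, genotypes, phenotypes, truth, params`.
#' @export
simulate_population <- function(params, force_genotypes = FALSE) {
  ped <- simulate_pedigree(params)
  gen <- NULL
  if (params$trait_mode == "qtl" || force_genotypes)
    gen <- simulate_genotypes(ped, params, retain = "all")
  tr <- simulate_traits(ped, gen, params)
  list(pedigree = ped, genotypes = gen, phenotypes = tr$phenotypes,
       truth = tr$truth, params = params)
}
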