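small_params <- function(...) {
  args <- utils::modifyList(
    list(n_sire_families = 8L, n_offspring_per_sire = 10L,
         n_purebred_generations = 1L, n_snps = 200L, n_qtl = 50L,
         missing_geno_rate = 0.02, seed = 99L),
    list(...))
  do.call(sim_params, args)
}

test_that("simulate_pedigree builds the sib-testing structure", {
  p <- sim_params(n_sire_families = 57L, n_offspring_per_sire = 35L,
                  n_purebred_generations = 1L, seed = 5L)
  ped <- simulate_pedigree(p)
  expect_s3_class(ped, "ham_pedigree")  # implies acyclic + parent-first
  cb <- ped[ped$population == "CB", ]
  expect_equal(sum(ped$population == "PB"), 57L)
  expect_equal(as.integer(table(cb$family)), rep(35L, 57L))
  expect_true(all(cb$sex %in% c("F", "C")))
  # batches of about 70 animals
  bt <- table(cb$batch)
  expect_true(all(bt >= 60 & bt <= 80))
  # founder trio limit
  p1 <- sim_params(n_sire_families = 1L, n_offspring_per_sire = 2L,
                   n_purebred_generations = 0L, litter_size = 1L,
                   dam_pedigree_depth = 0L, seed = 1L)
  ped1 <- simulate_pedigree(p1)
  A <- build_A(ped1)
  cbs <- ped1$id[ped1$population == "CB"]
  expect_equal(unname(A["PB1", cbs]), c(0.5, 0.5))
  expect_error(sim_params(n_sire_families = 0L), "n_sire_families")
})

test_that("gene dropping follows Mendelian transmission laws", {
  p <- small_params(missing_geno_rate = 0)
  ped <- simulate_pedigree(p)
  g <- simulate_genotypes(ped, p)
  expect_true(all(g$dosage %in% 0:2))
  s <- ped$sire_idx; d <- ped$dam_idx
  kids <- which(s > 0L & d > 0L)
  D <- g$dosage[ped$id, ]
  for (i in kids[1:20]) {
    hom0 <- D[s[i], ] == 0L & D[d[i], ] == 0L
    expect_true(all(D[i, hom0] == 0L))
    opp <- (D[s[i], ] == 2L & D[d[i], ] == 0L) |
           (D[s[i], ] == 0L & D[d[i], ] == 2L)
    expect_true(all(D[i, opp] == 1L))
  }
})

test_that("founder allele frequency matches the binomial oracle", {
  # founders only: frequency estimate ~ Binomial(2n, 0.3) / 2n
  p <- sim_params(n_sire_families = 5000L, n_offspring_per_sire = 1L,
                  n_purebred_generations = 0L, n_snps = 20L, n_qtl = 1L,
                  maf_range = c(0.3, 0.3), missing_geno_rate = 0,
                  litter_size = 1L, dam_pedigree_depth = 0L,
                  n_sex_chr_snps = 0L, seed = 3L)
  ped <- simulate_pedigree(p)
  founders <- ped$id[ped$sire_idx == 0L & ped$dam_idx == 0L]
  expect_gte(length(founders), 10000L)
  g <- simulate_genotypes(ped, p)
  freq <- colMeans(g$dosage[founders, ]) / 2
  expect_true(all(abs(freq - 0.3) < 0.01))
})

test_that("trait generator hits stated means, SDs and correlations", {
  p <- sim_params(n_sire_families = 57L, n_offspring_per_sire = 35L,
                  n_purebred_generations = 1L,
                  trait_mode = "infinitesimal", seed = 11L)
  pop <- simulate_population(p)
  ph <- pop$phenotypes
  expect_true(all(is.na(ph$ob) | !is.na(ph$ir)))  # OB subset of IR
  expect_equal(mean(!is.na(ph$ob)), 0.65, tolerance = 0.02)
  expect_equal(mean(ph$ob, na.rm = TRUE), 27.8, tolerance = 0.2)
  expect_equal(stats::sd(ph$ob, na.rm = TRUE), 2.4, tolerance = 0.15)
  expect_equal(mean(ph$ir), 26.5, tolerance = 0.2)

  # closed form r_p = r_g*h*h' + r_e*e*e'; with r_g = 1, equal h2 and
  # r_p_target = h2 the solved residual correlation is 0
  p2 <- sim_params(n_sire_families = 40L, n_offspring_per_sire = 35L,
                   n_purebred_generations = 0L, h2_ob = 0.4, h2_ir = 0.4,
                   r_g = 1, r_p_target = 0.4, batch_effect_sd = 0,
                   sex_effect = 0, frac_ob_recorded = 1,
                   trait_mode = "infinitesimal", seed = 21L)
  pop2 <- simulate_population(p2)
  expect_equal(pop2$truth$residual_cor, 0, tolerance = 1e-12)
  expect_lt(abs(cor(pop2$phenotypes$ob, pop2$phenotypes$ir) - 0.4), 0.07)

  # infeasible combination is reported, not silently clamped
  expect_error(
    simulate_population(sim_params(n_sire_families = 2L,
                                   n_offspring_per_sire = 2L, r_g = -0.9,
                                   r_p_target = 0.9,
                                   trait_mode = "infinitesimal")),
    "infeasible")
})

test_that("Mendelian sampling of TBV is centred on the mid-parent", {
  p <- sim_params(n_sire_families = 30L, n_offspring_per_sire = 35L,
                  n_purebred_generations = 1L,
                  trait_mode = "infinitesimal", seed = 13L)
  pop <- simulate_population(p)
  ped <- pop$pedigree
  tbv <- pop$truth$tbv; rownames(tbv) <- tbv$id
  cb <- ped[ped$population == "CB", ]
  dev <- tbv[cb$id, "tbv_ob"] -
    0.5 * (tbv[cb$sire, "tbv_ob"] + tbv[cb$dam, "tbv_ob"])
  expect_lt(abs(mean(dev)), 3 * stats::sd(dev) / sqrt(length(dev)))
})

test_that("identical seed and params give identical output", {
  p <- small_params()
  a <- simulate_population(p)
  b <- simulate_population(p)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  c_ <- simulate_population(small_params(seed = 100L))
  expect_false(identical(a$phenotypes$ob, c_$phenotypes$ob))
})
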