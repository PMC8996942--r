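## SNP and sample quality control for the genotype matrix, following the
## rules used on the 50K porcine array data: drop sex-chromosome SNPs,
## SNPs with call rate < 0.9, DNA samples with call rate < 0.9, and SNPs
## with minor allele frequency < 5%. The removal order is fixed (and
## documented) because MAF depends on the surviving sample set.

#' Quality-control filter for a genotype matrix
#'
#' Applies, in this order: (1) remove sex-chromosome SNPs; (2) remove SNPs
#' with call rate `< callrate_min`; (3) remove samples with call rate
#' `< callrate_min`; (4) remove SNPs with minor allele frequency
#' `< maf_min`, computed on the surviving samples. All removal thresholds
#' are strict inequalities.
#'
#' @param genotypes A `ham_geno` object.
#' @param maf_min Minimum minor allele frequency kept (default 0.05).
#' @param callrate_min Minimum call rate kept, SNP-wise and sample-wise
#'   (default 0.9).
#' @param drop_sex_chromosomes Remove SNPs with `chr` in `X, Y, MT` first
#'   (default TRUE).
#' @return List with the filtered `ham_geno` (`$genotypes`) and a
#'   `$report` (class `ham_qc_report`) whose counts reconcile exactly with
#'   the matrix dimensions.
#' @export
qc_filter <- function(genotypes, maf_min = 0.05, callrate_min = 0.9,
                      drop_sex_chromosomes = TRUE) {
  stopifnot(inherits(genotypes, "ham_geno"))
  G <- genotypes$dosage; map <- genotypes$map
  n0 <- nrow(G); p0 <- ncol(G)

  sex_snps <- if (drop_sex_chromosomes)
    which(map$chr %in% c("X", "Y", "MT")) else integer(0)
  keep_snp <- setdiff(seq_len(p0), sex_snps)

  cr_snp <- colMeans(!is.na(G[, keep_snp, drop = FALSE]))
  low_cr_snp <- keep_snp[cr_snp < callrate_min]
  keep_snp <- setdiff(keep_snp, low_cr_snp)

  cr_sample <- rowMeans(!is.na(G[, keep_snp, drop = FALSE]))
  bad_sample <- which(cr_sample < callrate_min)
  keep_sample <- setdiff(seq_len(n0), bad_sample)

  sub <- G[keep_sample, keep_snp, drop = FALSE]
  freq <- colMeans(sub, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  low_maf <- keep_snp[is.na(maf) | maf < maf_min]
  keep_snp <- setdiff(keep_snp, low_maf)

  if (!length(keep_snp))
    stop("quality control removed every SNP; check thresholds and data")

  out <- genotypes
  out$dosage <- G[keep_sample, keep_snp, drop = FALSE]
  out$map <- map[keep_snp, , drop = FALSE]
  out$founder_freq <- genotypes$founder_freq[keep_snp]
  report <- structure(list(
    snps_in = p0, samples_in = n0,
    snps_removed_sex_chr = length(sex_snps),
    snps_removed_callrate = length(low_cr_snp),
    snps_removed_maf = length(low_maf),
    samples_removed_callrate = length(bad_sample),
    snps_retained = length(keep_snp),
    samples_retained = length(keep_sample),
    maf_min = maf_min, callrate_min = callrate_min),
    class = "ham_qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.ham_qc_report <- function(x, ...) {
  cat("<ham_qc_report>\n",
      " SNPs in:", x$snps_in,
      "| sex-chr:", x$snps_removed_sex_chr,
      "| call rate:", x$snps_removed_callrate,
      "| MAF:", x$snps_removed_maf,
      "| retained:", x$snps_retained, "\n",
      " samples in:", x$samples_in,
      "| call rate:", x$samples_removed_callrate,
      "| retained:", x$samples_retained, "\n")
  invisible(x)
}

#' Parent-progeny genotype conflict check
#'
#' Flags genotyped parent-offspring pairs whose dosages are opposing
#' homozygotes (0 vs 2) at more than `max_conflict_rate` of the SNPs
#' where both are called -- the signature of a pedigree error.
#'
#' @param genotypes A `ham_geno`.
#' @param pedigree A `ham_pedigree`.
#' @param max_conflict_rate Tolerated fraction of opposing-homozygote SNPs
#'   (default 0.01; genotyping error makes a handful unavoidable).
#' @return Data.frame of flagged pairs (`parent, offspring, n_checked,
#'   n_conflict, rate`), zero rows when the pedigree is consistent.
#' @export
mendel_check <- function(genotypes, pedigree, max_conflict_rate = 0.01) {
  stopifnot(inherits(genotypes, "ham_geno"))
  ped <- validate_pedigree(pedigree)
  G <- genotypes$dosage
  gids <- rownames(G)
  out <- list()
  for (i in seq_len(nrow(ped))) {
    kid <- ped$id[i]
    if (!kid %in% gids) next
    for (par in c(ped$sire[i], ped$dam[i])) {
      if (par == "0" || !par %in% gids) next
      gk <- G[kid, ]; gp <- G[par, ]
      ok <- !is.na(gk) & !is.na(gp)
      conf <- sum((gk == 0L & gp == 2L) | (gk == 2L & gp == 0L), na.rm = TRUE)
      rate <- if (any(ok)) conf / sum(ok) else 0
      if (rate > max_conflict_rate)
        out[[length(out) + 1L]] <- data.frame(
          parent = par, offspring = kid, n_checked = sum(ok),
          n_conflict = conf, rate = rate, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(parent = character(0), offspring = character(0),
                  n_checked = integer(0), n_conflict = integer(0),
                  rate = numeric(0), stringsAsFactors = FALSE)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing call with the SNP's observed mean dosage (a real
#' number in `[0, 2]`). A stand-in for pedigree-haplotype imputation, which
#' is out of scope; downstream whole-genome regression accepts fractional
#' dosages. The imputation mask is kept as attribute `imputed`.
#'
#' @param genotypes A `ham_geno`, normally post-[qc_filter()].
#' @return A complete `ham_geno` with numeric (possibly fractional) dosages.
#' @export
mean_impute <- function(genotypes) {
  stopifnot(inherits(genotypes, "ham_geno"))
  G <- genotypes$dosage
  miss <- is.na(G)
  if (any(colSums(!miss) == 0L))
    stop("SNP(s) with zero observed calls cannot be mean-imputed: ",
         paste(utils::head(genotypes$map$snp[colSums(!miss) == 0L], 5),
               collapse = ", "))
  if (any(miss)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(miss, arr.ind = TRUE)
    G <- G * 1.0
    G[idx] <- mu[idx[, 2]]
  }
  out <- genotypes
  out$dosage <- G
  attr(out, "imputed") <- miss
  out
}
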