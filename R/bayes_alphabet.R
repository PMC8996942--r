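## Five Bayesian whole-genome regression models (the "Bayesian alphabet"):
## Bayesian ridge regression (BRR), BayesA, BayesB, BayesC and the Bayesian
## Lasso (BL), fitted by single-site Gibbs sampling with residual updating.
## Pseudo-phenotypes (y_adj or EBV) of crossbred pigs are regressed on SNP
## dosages; optional per-record weights carry the EBV reliabilities into
## the residual precision.

MODEL_CODES <- c(BRR = 0L, BayesA = 1L, BayesB = 2L, BayesC = 3L, BL = 4L)

#' Configuration for a marker regression model
#'
#' @param model One of `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BL"`.
#' @param n_iter,burn_in,thin Gibbs chain settings. The defaults
#'   (20,000 / 4,000 / 20) are a desk-scale chain for testing; the
#'   full-length production chain of 500,000 / 100,000 / 100 is available
#'   via `paper_chain = TRUE`.
#' @param paper_chain Use the full 500k/100k/100 chain.
#' @param df0 Prior degrees of freedom for all variance priors (default 5).
#' @param R2 Target proportion of variance explained used to elect prior
#'   scales (default 0.5).
#' @param pi0 Prior inclusion probability for BayesB/C (default 0.5).
#' @param pi_counts Prior "counts" of the Beta hyper-prior on pi
#'   (default 10).
#' @param update_pi Sample pi (TRUE) or keep it fixed at `pi0`.
#' @param weight_transform How EBV accuracies map to residual weights when
#'   a weighted fit is requested: `"r2"` (reliability, default) or `"r"`.
#' @param seed Chain seed.
#' @return A `marker_model_config` list.
#' @export
marker_model_config <- function(model = c("BRR", "BayesA", "BayesB",
                                          "BayesC", "BL"),
                                n_iter = 20000L, burn_in = 4000L,
                                thin = 20L, paper_chain = FALSE,
                                df0 = 5, R2 = 0.5,
                                pi0 = 0.5, pi_counts = 10,
                                update_pi = TRUE,
                                weight_transform = c("r2", "r"),
                                seed = 1L) {
  model <- match.arg(model)
  weight_transform <- match.arg(weight_transform)
  if (paper_chain) { n_iter <- 500000L; burn_in <- 100000L; thin <- 100L }
  stopifnot(burn_in < n_iter, thin >= 1L, pi0 > 0, pi0 <= 1)
  structure(list(model = model, n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 df0 = df0, R2 = R2, pi0 = pi0, pi_counts = pi_counts,
                 update_pi = update_pi,
                 weight_transform = weight_transform,
                 seed = as.integer(seed)),
            class = "marker_model_config")
}

#' Default prior hyper-parameters elected from the training data
#'
#' Scales of the scaled-inverse-chi-square priors are elected so that the
#' prior mode of the genetic variance explains `R2` (default 0.5) of
#' `var(y)`, partitioned across markers through the sum of `2 p_j q_j`
#' terms, and the residual scale targets the complement. For BayesB the
#' marker-variance scale is inflated by `1/pi0` to keep the a-priori
#' genomic variance constant. The Bayesian Lasso gets a Gamma hyper-prior
#' on `lambda^2` centred so the prior ratio of penalties matches the same
#' R2 split.
#'
#' @param model Model name (see [marker_model_config()]).
#' @param y Training pseudo-phenotypes.
#' @param W Training dosage matrix (no missing values).
#' @param df0,R2,pi0 See [marker_model_config()].
#' @return List of elected hyper-parameters, including `MSx` (the
#'   `sum(2 p q)` marker-variance mass).
#' @export
default_hyperparameters <- function(model, y, W, df0 = 5, R2 = 0.5,
                                    pi0 = 0.5) {
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0)
    stop("pseudo-phenotypes have zero variance; nothing to fit")
  pj <- colMeans(W) / 2
  MSx <- sum(2 * pj * (1 - pj))
  if (MSx <= 0) MSx <- ncol(W)  # degenerate all-fixed panel
  Sg <- R2 * vy * (df0 + 2) / (df0 * MSx)
  if (model == "BayesB") Sg <- Sg / pi0
  dfe <- 5
  Se <- (1 - R2) * vy * (dfe + 2) / dfe
  # lambda^2 ~ Gamma(shape, rate) centred on 2 * (1 - R2) / R2 * MSx
  bl_shape <- 1.1
  lambda2_0 <- 2 * (1 - R2) / R2 * MSx
  bl_rate <- (bl_shape - 1) / lambda2_0
  list(df0 = df0, Sg = Sg, dfe = dfe, Se = Se, pi0 = pi0,
       bl_shape = bl_shape, bl_rate = bl_rate, MSx = MSx, R2 = R2)
}

#' Fit a Bayesian whole-genome regression model
#'
#' Regresses pseudo-phenotypes on SNP dosages (coded as the count of the B
#' allele; fractional imputed dosages allowed) under one of the five
#' Bayesian alphabet priors. When `weights` are supplied, record i's
#' residual precision is multiplied by `w_i` (the standard carrier for EBV
#' reliability, `w = r^2`). Posterior means are computed from post-burn-in
#' thinned samples.
#'
#' @param W Numeric matrix, animals x SNPs, complete (see [mean_impute()]),
#'   with column names identifying the SNPs.
#' @param y Numeric vector of pseudo-phenotypes, aligned with rows of `W`.
#' @param config A [marker_model_config()].
#' @param weights Optional positive per-record weights.
#' @param hyper Optional hyper-parameter list overriding
#'   [default_hyperparameters()].
#' @param fix_var_g,fix_var_e Optional fixed values for the marker /
#'   residual variance (disables their sampling; used for closed-form
#'   validation against ridge regression).
#' @return A `ham_marker_fit`: posterior-mean intercept `mu`, effects `g`
#'   (named by SNP), inclusion frequencies `pip`, posterior means of the
#'   variances, kept scalar samples and effective sample sizes.
#' @export
fit_marker_model <- function(W, y, config = marker_model_config(),
                             weights = NULL, hyper = NULL,
                             fix_var_g = NULL, fix_var_e = NULL) {
  stopifnot(inherits(config, "marker_model_config"))
  W <- as.matrix(W)
  if (length(y) != nrow(W))
    stop("rows of W (", nrow(W), ") and length of y (", length(y),
         ") differ")
  if (anyNA(W)) stop("W contains missing dosages; impute first")
  if (anyNA(y)) stop("y contains missing values")
  if (is.null(weights)) weights <- rep(1, length(y))
  if (any(weights <= 0)) stop("weights must be positive")
  if (is.null(hyper))
    hyper <- default_hyperparameters(config$model, y, W,
                                     df0 = config$df0, R2 = config$R2,
                                     pi0 = config$pi0)
  set.seed(config$seed)
  res <- .gibbs_wgr(W, y, weights,
                    MODEL_CODES[[config$model]],
                    config$n_iter, config$burn_in, config$thin,
                    hyper$df0, hyper$Sg, hyper$dfe, hyper$Se,
                    config$pi0, config$pi_counts,
                    hyper$bl_shape, hyper$bl_rate,
                    !is.null(fix_var_g), ifelse(is.null(fix_var_g), 0,
                                                fix_var_g),
                    !is.null(fix_var_e), ifelse(is.null(fix_var_e), 0,
                                                fix_var_e),
                    isTRUE(config$update_pi))
  g <- as.numeric(res$g_mean)
  names(g) <- colnames(W)
  samples <- data.frame(mu = res$mu_samples, var_g = res$var_g_samples,
                        var_e = res$var_e_samples, pi = res$pi_samples)
  structure(list(model = config$model,
                 mu = mean(res$mu_samples),
                 g = g,
                 pip = stats::setNames(as.numeric(res$pip), colnames(W)),
                 var_g = mean(res$var_g_samples),
                 var_e = mean(res$var_e_samples),
                 pi = mean(res$pi_samples),
                 samples = samples,
                 ess = vapply(samples, effective_sample_size, 0.0),
                 n_kept = res$n_kept,
                 snps = colnames(W),
                 hyper = hyper, config = config),
            class = "ham_marker_fit")
}

#' @export
print.ham_marker_fit <- function(x, ...) {
  cat("<ham_marker_fit> ", x$model, ": ", length(x$g), " SNPs, ",
      x$n_kept, " kept samples\n", sep = "")
  cat("  post. means: mu =", signif(x$mu, 4),
      " var_g =", signif(x$var_g, 4),
      " var_e =", signif(x$var_e, 4), "\n")
  invisible(x)
}

# initial-sequence effective sample size (sum of autocorrelations cut at
# the first negative value)
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1]
  neg <- which(ac < 0)
  if (length(neg)) ac <- ac[seq_len(neg[1] - 1L)]
  n / (1 + 2 * sum(ac))
}

#' Direct genomic values from a fitted marker model
#'
#' `DGV_i = sum_j W_ij * g_hat_j`: dosages times posterior-mean allele
#' substitution effects, with no intercept term. Columns of `W_new` must
#' match the training SNPs in name and order.
#'
#' @param W_new Dosage matrix of the animals to score (fractional imputed
#'   dosages allowed).
#' @param fit A `ham_marker_fit`.
#' @return Named numeric vector of DGV.
#' @export
compute_dgv <- function(W_new, fit) {
  stopifnot(inherits(fit, "ham_marker_fit"))
  W_new <- as.matrix(W_new)
  if (!is.null(fit$snps)) {
    if (is.null(colnames(W_new)) || !identical(colnames(W_new), fit$snps)) {
      bad <- if (is.null(colnames(W_new))) "(no column names)"
             else paste(utils::head(
               c(setdiff(fit$snps, colnames(W_new)),
                 setdiff(colnames(W_new), fit$snps)), 5), collapse = ", ")
      stop("SNP columns of W_new do not match the training panel: ", bad)
    }
  } else if (ncol(W_new) != length(fit$g)) {
    stop("W_new has ", ncol(W_new), " SNPs; fit has ", length(fit$g))
  }
  dgv <- drop(W_new %*% fit$g)
  stats::setNames(as.numeric(dgv), rownames(W_new))
}
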