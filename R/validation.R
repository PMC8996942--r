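## Training-validation machinery: the nine scenario definitions, 5-fold
## random cross-validation, leave-one-family-out (LOFO) validation, and
## the accuracy metrics (Pearson r, Fisher-z confidence interval, t-test
## p-value, relative accuracy).

#' The nine training-validation scenarios
#'
#' Returns the scenario table: which trait and pseudo-phenotype the marker
#' model is trained on (always crossbred data), and which trait,
#' pseudo-phenotype and population it is validated on. Scenarios 1-3 train
#' on the observed trait, 4-6 on the infrared proxy validated on itself,
#' 7-9 on the proxy validated against the observed trait; scenarios 3, 6
#' and 9 score the purebred sires.
#'
#' @return Data.frame with columns `scenario, train_trait, train_pseudo,
#'   valid_trait, valid_pseudo, valid_pop`.
#' @export
scenario_table <- function() {
  data.frame(
    scenario = 1:9,
    train_trait = c("ob", "ob", "ob", "ir", "ir", "ir", "ir", "ir", "ir"),
    train_pseudo = c("yadj", "ebv", "ebv", "yadj", "ebv", "ebv",
                     "yadj", "ebv", "ebv"),
    valid_trait = c("ob", "ob", "ob", "ir", "ir", "ir", "ob", "ob", "ob"),
    valid_pseudo = c("yadj", "ebv", "ebv", "yadj", "ebv", "ebv",
                     "yadj", "ebv", "ebv"),
    valid_pop = c("CB", "CB", "PB", "CB", "CB", "PB", "CB", "CB", "PB"),
    stringsAsFactors = FALSE)
}

#' Random k-fold partition
#'
#' Splits ids into `k` disjoint segments of (near-)equal size,
#' deterministically under `seed`.
#'
#' @param animal_ids Character vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` character vectors partitioning `animal_ids`.
#' @export
make_random_folds <- function(animal_ids, k = 5L, seed = 1L) {
  n <- length(animal_ids)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("more folds than animals")
  set.seed(seed)
  idx <- sample(rep_len(seq_len(k), n))
  split(animal_ids, idx)
}

#' Leave-one-family-out splits
#'
#' One split per sire family: the holdout is every crossbred of that
#' family, the training set is all other crossbreds, and the family's
#' purebred sire is scored in the same round.
#'
#' @param family_map Data.frame with columns `id` (crossbred) and `family`
#'   (sire id).
#' @return Named list (by family) of `list(train =, holdout =, sire =)`.
#' @export
make_lofo_splits <- function(family_map) {
  stopifnot(all(c("id", "family") %in% names(family_map)))
  if (anyNA(family_map$family)) stop("every crossbred needs a sire family")
  fams <- unique(family_map$family)
  if (length(fams) < 2L)
    stop("leave-one-family-out needs at least two families")
  out <- lapply(fams, function(f) {
    hold <- family_map$id[family_map$family == f]
    list(train = setdiff(family_map$id, hold), holdout = hold, sire = f)
  })
  names(out) <- fams
  out
}

#' Pearson accuracy with Fisher-z confidence interval
#'
#' `r = cor(dgv, pseudo)`; 95 percent CI via the Fisher transform,
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`; two-sided p-value from
#' `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom.
#'
#' @param dgv,pseudo Numeric vectors (pairs with either value missing are
#'   dropped).
#' @param conf_z Normal multiplier of the CI (default 1.96).
#' @return List `r, n, ci_lower, ci_upper, p_value`.
#' @export
accuracy_metrics <- function(dgv, pseudo, conf_z = 1.96) {
  ok <- !is.na(dgv) & !is.na(pseudo)
  dgv <- dgv[ok]; pseudo <- pseudo[ok]
  n <- length(dgv)
  if (n < 4L) stop("need at least 4 pairs for a confidence interval")
  if (stats::sd(dgv) == 0 || stats::sd(pseudo) == 0)
    stop("zero-variance input to accuracy_metrics")
  r <- stats::cor(dgv, pseudo)
  c(list(r = r, n = n), fisher_ci(r, n, conf_z))
}

#' @rdname accuracy_metrics
#' @param r A correlation. @param n The pair count behind it.
#' @export
fisher_ci <- function(r, n, conf_z = 1.96) {
  z <- atanh(r)
  hw <- conf_z / sqrt(n - 3)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(ci_lower = tanh(z - hw), ci_upper = tanh(z + hw), p_value = p)
}

#' Relative accuracy
#'
#' Realized accuracy as a fraction of the maximum theoretical accuracy of
#' phenotype prediction, `r / sqrt(h2)`.
#'
#' @param r Realized accuracy (correlation).
#' @param h2 Trait heritability in (0, 1].
#' @return `r / sqrt(h2)`.
#' @export
relative_accuracy <- function(r, h2) {
  if (!is.numeric(h2) || any(h2 <= 0) || any(h2 > 1))
    stop("h2 must lie in (0, 1]")
  r / sqrt(h2)
}

# assemble the pseudo-phenotype table a scenario needs
scenario_pseudo <- function(bundle, trait, pseudo, pop) {
  key <- paste0(pseudo, "_", trait)
  tab <- if (pop == "CB") bundle$cb else bundle$pb
  if (!key %in% names(tab))
    stop("pseudo-phenotype ", key, " not available for ", pop)
  stats::setNames(tab[[key]], tab$id)
}

#' Bundle the inputs of the validation stage
#'
#' Collects the quantities every scenario run needs: the imputed dosage
#' matrix, the crossbred pseudo-phenotype table (`yadj_ob, yadj_ir,
#' ebv_ob, ebv_ir, acc_ob, acc_ir`, plus `family`), and the purebred sire
#' table (`ebv_ob, ebv_ir`).
#'
#' @param W Complete dosage matrix (CB and PB rows, named).
#' @param cb Crossbred table as above (column `id` required; missing
#'   entries allowed).
#' @param pb Purebred sire table (column `id` required).
#' @param h2 Optional named list/vector of heritabilities (`ob`, `ir`)
#'   used for relative accuracy.
#' @return A `ham_bundle` list.
#' @export
validation_bundle <- function(W, cb, pb, h2 = NULL) {
  stopifnot(!is.null(rownames(W)), "id" %in% names(cb), "id" %in% names(pb))
  miss <- setdiff(c(cb$id, pb$id), rownames(W))
  if (length(miss))
    stop("animals without genotypes: ",
         paste(utils::head(miss, 5), collapse = ", "))
  structure(list(W = W, cb = cb, pb = pb, h2 = h2), class = "ham_bundle")
}

#' Run training-validation scenarios
#'
#' For every requested scenario x model x split: trains a marker model on
#' the training crossbreds' pseudo-phenotypes (weighted by squared EBV
#' accuracy when training on EBV and weights are available), computes DGV
#' for the validation animals and accumulates (DGV, pseudo-phenotype)
#' pairs. Random cross-validation reports the per-fold mean and SE of the
#' correlation; LOFO pools all holdout predictions into a single
#' correlation with its Fisher CI (each validation animal is predicted
#' exactly once per scheme; purebred sires in LOFO are scored in the round
#' that drops their own family, in random CV in every fold).
#'
#' @param bundle A [validation_bundle()].
#' @param scenarios Integer subset of 1..9 (default all).
#' @param models Character vector of marker models (default `"BRR"` for
#'   LOFO compatibility; random CV commonly runs all five).
#' @param scheme `"random_cv"` or `"lofo"`.
#' @param k Folds for random CV.
#' @param config Base [marker_model_config()]; its seed is advanced per
#'   fit for chain independence.
#' @param weight_transform `"r2"` (reliability) or `"r"` accuracy weights.
#' @param seed Seed for the fold partition.
#' @return Data.frame of class `ham_validation`: one row per scenario x
#'   model with `r`, `n`, CI, p-value, per-fold SE (random CV), and
#'   relative accuracy where the validated pseudo-phenotype is `yadj` and
#'   a heritability is supplied in `bundle$h2`.
#' @export
run_scenarios <- function(bundle, scenarios = 1:9, models = "BRR",
                          scheme = c("random_cv", "lofo"), k = 5L,
                          config = marker_model_config(),
                          weight_transform = c("r2", "r"), seed = 1L) {
  scheme <- match.arg(scheme)
  weight_transform <- match.arg(weight_transform)
  stopifnot(inherits(bundle, "ham_bundle"))
  sc_tab <- scenario_table()
  sc_tab <- sc_tab[sc_tab$scenario %in% scenarios, , drop = FALSE]
  W <- bundle$W
  out <- list()
  fit_cache <- new.env(parent = emptyenv())  # scenarios often share training

  for (si in seq_len(nrow(sc_tab))) {
    sc <- sc_tab[si, ]
    y_train_all <- scenario_pseudo(bundle, sc$train_trait, sc$train_pseudo,
                                   "CB")
    y_valid_all <- scenario_pseudo(bundle, sc$valid_trait, sc$valid_pseudo,
                                   sc$valid_pop)
    train_ids_all <- bundle$cb$id[!is.na(y_train_all[bundle$cb$id])]
    wts_all <- NULL
    if (sc$train_pseudo == "ebv") {
      acc_col <- paste0("acc_", sc$train_trait)
      if (acc_col %in% names(bundle$cb)) {
        acc <- stats::setNames(bundle$cb[[acc_col]], bundle$cb$id)
        wts_all <- if (weight_transform == "r2") acc^2 else acc
        wts_all <- pmax(wts_all, 1e-4)
      }
    }
    splits <- if (scheme == "random_cv") {
      folds <- make_random_folds(train_ids_all, k = k, seed = seed)
      lapply(folds, function(f)
        list(train = setdiff(train_ids_all, f), holdout = f, sire = NULL))
    } else {
      fam <- bundle$cb[match(train_ids_all, bundle$cb$id), c("id", "family")]
      make_lofo_splits(fam)
    }

    for (mod in models) {
      pooled_dgv <- pooled_obs <- numeric(0)
      fold_r <- numeric(0)
      chain <- 0L
      for (sp in splits) {
        chain <- chain + 1L
        cfg <- config
        cfg$model <- mod
        cfg$seed <- config$seed + 1000L * chain
        tr_ids <- sp$train
        cache_key <- paste(mod, sc$train_trait, sc$train_pseudo, chain,
                           length(tr_ids), sep = "|")
        fit <- fit_cache[[cache_key]]
        if (is.null(fit)) {
          fit <- fit_marker_model(W[tr_ids, , drop = FALSE],
                                  unname(y_train_all[tr_ids]), cfg,
                                  weights = if (is.null(wts_all)) NULL
                                            else unname(wts_all[tr_ids]))
          fit_cache[[cache_key]] <- fit
        }
        val_ids <- if (sc$valid_pop == "CB") {
          intersect(sp$holdout, names(y_valid_all)[!is.na(y_valid_all)])
        } else if (scheme == "lofo") {
          intersect(sp$sire, names(y_valid_all)[!is.na(y_valid_all)])
        } else {
          names(y_valid_all)[!is.na(y_valid_all)]
        }
        if (!length(val_ids)) next
        dgv <- compute_dgv(W[val_ids, , drop = FALSE], fit)
        pooled_dgv <- c(pooled_dgv, dgv)
        pooled_obs <- c(pooled_obs, unname(y_valid_all[val_ids]))
        if (scheme == "random_cv" && length(val_ids) >= 4L)
          fold_r <- c(fold_r, stats::cor(dgv, unname(y_valid_all[val_ids])))
      }
      am <- accuracy_metrics(pooled_dgv, pooled_obs)
      rel <- NA_real_
      if (sc$valid_pseudo == "yadj" && !is.null(bundle$h2))
        rel <- relative_accuracy(am$r, bundle$h2[[sc$valid_trait]])
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc$scenario, model = mod, scheme = scheme,
        n = am$n, r = am$r,
        r_fold_mean = if (length(fold_r)) mean(fold_r) else NA_real_,
        se_fold = if (length(fold_r) > 1L)
          stats::sd(fold_r) / sqrt(length(fold_r)) else NA_real_,
        ci_lower = am$ci_lower, ci_upper = am$ci_upper,
        p_value = am$p_value, relative_accuracy = rel,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("ham_validation", "data.frame")
  res
}

#' Format p-values the way journals bin them
#'
#' @param p Numeric p-values.
#' @return Character vector with `<0.001`, `<0.01`, `<0.05` bins or the
#'   rounded value.
#' @export
format_p_binned <- function(p) {
  ifelse(p < 0.001, "<0.001",
  ifelse(p < 0.01, "<0.01",
  ifelse(p < 0.05, "<0.05", sprintf("%.2f", p))))
}
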