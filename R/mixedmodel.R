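## Animal-model machinery: Henderson's mixed-model equations, EM-REML
## variance components (univariate and bivariate with missing traits), and
## the two pseudo-phenotypes (adjusted phenotype, EBV with accuracy).
##
## Fixed-effect parameterization (fixed for bit-reproducible y_adj): the
## first sex level is constrained to zero and every slaughter-batch level
## gets its own column, so the batch block absorbs the intercept.

# fixed-effect design over records of one trait; returns q x f sparse matrix
# with zero rows for animals without a record
fixed_design <- function(ped, phen, recorded) {
  q <- nrow(ped)
  ridx <- match(phen$id, ped$id)
  blocks <- list()
  if ("sex" %in% names(phen)) {
    lev <- sort(unique(as.character(phen$sex[recorded])))
    for (lv in lev[-1]) {        # first sex level := 0
      v <- numeric(q)
      sel <- recorded & as.character(phen$sex) == lv
      v[ridx[sel]] <- 1
      blocks[[paste0("sex:", lv)]] <- v
    }
  }
  if ("batch" %in% names(phen)) { # batch block absorbs the intercept
    lev <- sort(unique(as.character(phen$batch[recorded])))
    for (lv in lev) {
      v <- numeric(q)
      sel <- recorded & as.character(phen$batch) == lv
      v[ridx[sel]] <- 1
      blocks[[paste0("batch:", lv)]] <- v
    }
  } else {                        # explicit mean column instead
    v <- numeric(q); v[ridx[recorded]] <- 1
    blocks[["mu"]] <- v
  }
  X <- do.call(cbind, blocks)
  Matrix::Matrix(X, sparse = TRUE)
}

# rank check with named confounded columns
check_full_rank <- function(X, recorded_rows) {
  Xd <- as.matrix(X[recorded_rows, , drop = FALSE])
  if (ncol(Xd) == 0L) return(invisible(TRUE))
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("fixed-effect design is singular; confounded levels: ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Assemble MME blocks for 1 or 2 traits with heterogeneous missingness.
# G0, R0: t x t matrices (scalars allowed for one trait). weights: optional
# per-animal residual weights (univariate only), residual variance se2/w.
build_mme <- function(phen, ped, traits, G0, R0, Ainv, weights = NULL) {
  q <- nrow(ped); nt <- length(traits)
  G0 <- matrix(G0, nt, nt); R0 <- matrix(R0, nt, nt)
  ridx <- match(phen$id, ped$id)
  if (anyNA(ridx))
    stop("phenotyped animals missing from pedigree: ",
         paste(utils::head(phen$id[is.na(ridx)], 5), collapse = ", "))
  rec <- lapply(traits, function(tr) !is.na(phen[[tr]]))
  y <- lapply(seq_len(nt), function(t) {
    v <- numeric(q); v[ridx[rec[[t]]]] <- phen[[traits[t]]][rec[[t]]]; v
  })
  has <- lapply(seq_len(nt), function(t) {
    v <- logical(q); v[ridx[rec[[t]]]] <- TRUE; v
  })
  X <- lapply(seq_len(nt), function(t) {
    Xt <- fixed_design(ped, phen, rec[[t]])
    check_full_rank(Xt, has[[t]])
    Xt
  })
  f <- vapply(X, ncol, 0L)

  w <- rep(1, q)
  if (!is.null(weights)) {
    if (nt > 1L) stop("record weights are supported for univariate models only")
    stopifnot(all(weights > 0), length(weights) == nrow(phen))
    w[ridx] <- weights
  }

  # per-animal elements of the inverse residual block
  rho <- array(0, c(q, nt, nt))
  if (nt == 1L) {
    rho[, 1, 1] <- ifelse(has[[1]], w / R0[1, 1], 0)
  } else {
    both <- has[[1]] & has[[2]]
    R0i <- solve(R0)
    for (t in 1:2) {
      only <- has[[t]] & !both
      rho[only, t, t] <- 1 / R0[t, t]
      rho[both, t, t] <- R0i[t, t]
    }
    rho[both, 1, 2] <- rho[both, 2, 1] <- R0i[1, 2]
  }

  G0i <- solve(G0)
  if (nt == 2L && G0i[1, 2] == 0)
    G0i[1, 2] <- G0i[2, 1] <- 1e-300   # keep the cross-block pattern alive
  D <- function(v) Matrix::Diagonal(q, v)
  # unknown order: b_1, ..., b_nt, a_1, ..., a_nt
  Cbb <- Cba <- list(); Caa <- list()
  rhs_b <- list(); rhs_a <- list()
  for (t in seq_len(nt)) {
    rb <- numeric(f[t]); ra <- numeric(q)
    for (u in seq_len(nt)) {
      rb <- rb + as.numeric(Matrix::crossprod(X[[t]], rho[, t, u] * y[[u]]))
      ra <- ra + rho[, t, u] * y[[u]]
    }
    rhs_b[[t]] <- rb; rhs_a[[t]] <- ra
    for (u in seq_len(nt)) {
      Cbb[[paste(t, u)]] <- Matrix::crossprod(X[[t]], D(rho[, t, u]) %*% X[[u]])
      Cba[[paste(t, u)]] <- Matrix::crossprod(X[[t]], D(rho[, t, u]))
      Caa[[paste(t, u)]] <- D(rho[, t, u]) + G0i[t, u] * Ainv
    }
  }
  row_blocks <- list()
  for (t in seq_len(nt)) {
    rowt <- list()
    for (u in seq_len(nt)) rowt[[u]] <- Cbb[[paste(t, u)]]
    for (u in seq_len(nt)) rowt[[nt + u]] <- Cba[[paste(t, u)]]
    row_blocks[[t]] <- do.call(cbind, rowt)
  }
  for (t in seq_len(nt)) {
    rowt <- list()
    for (u in seq_len(nt)) rowt[[u]] <- Matrix::t(Cba[[paste(u, t)]])
    for (u in seq_len(nt)) rowt[[nt + u]] <- Caa[[paste(t, u)]]
    row_blocks[[nt + t]] <- do.call(cbind, rowt)
  }
  C <- do.call(rbind, row_blocks)
  rhs <- c(unlist(rhs_b), unlist(rhs_a))
  off_b <- cumsum(c(0, f))[seq_len(nt)]
  off_a <- sum(f) + (seq_len(nt) - 1L) * q
  list(C = C, rhs = rhs, X = X, y = y, has = has, rho = rho, w = w,
       f = f, q = q, nt = nt, off_b = off_b, off_a = off_a,
       G0 = G0, R0 = R0, G0i = G0i, Ainv = Ainv,
       fixed_names = lapply(X, colnames), ridx = ridx, rec = rec)
}

# Solve the MME and expose entries of the inverse coefficient matrix.
# Two exact routes behind one interface:
#   dense  - Cholesky + chol2inv, fine up to a few thousand equations;
#   sparse - simplicial sparse Cholesky + Takahashi selected inversion,
#            which yields the inverse exactly on the factor pattern (all
#            entries the EM traces, residual corrections and PEV need).
# Returns list(sol, logdetC, get(i, j) vectorized accessor).
solve_mme_dense <- function(m, invert = FALSE) {
  Cd <- as.matrix(Matrix::forceSymmetric(m$C, "U"))
  ch <- tryCatch(chol(Cd), error = function(e)
    stop("mixed-model equations are singular (confounded fixed effects ",
         "or non-PD variance matrix): ", conditionMessage(e)))
  sol <- backsolve(ch, forwardsolve(ch, m$rhs, upper.tri = TRUE,
                                    transpose = TRUE))
  out <- list(sol = sol, logdetC = 2 * sum(log(diag(ch))))
  if (invert) {
    Cinv <- chol2inv(ch)
    out$Cinv <- Cinv
    out$get <- function(i, j) Cinv[cbind(i, j)]
  }
  out
}

solve_mme_sparse <- function(m) {
  C <- Matrix::forceSymmetric(m$C, "U")
  Ch <- tryCatch(Matrix::Cholesky(C, LDL = FALSE, super = FALSE,
                                  perm = TRUE),
                 error = function(e)
    stop("mixed-model equations are singular (confounded fixed effects ",
         "or non-PD variance matrix): ", conditionMessage(e)))
  sol <- as.numeric(Matrix::solve(Ch, m$rhs, system = "A"))
  L <- as(Ch, "CsparseMatrix")
  n <- ncol(L)
  dL <- L@x[L@p[seq_len(n)] + 1L]
  logdetC <- 2 * sum(log(dL))
  Zx <- .takahashi_selinv(L@p, L@i, L@x, n)
  qq <- Ch@perm + 1L                       # C[qq, qq] = L L'
  invq <- integer(n); invq[qq] <- seq_len(n)
  nf <- sum(m$f)
  # exact dense strip for the (small) fixed-effect columns
  B <- NULL
  if (nf > 0) {
    If <- Matrix::sparseMatrix(i = seq_len(nf), j = seq_len(nf), x = 1,
                               dims = c(n, nf))
    B <- as.matrix(Matrix::solve(Ch, If, system = "A"))
  }
  get <- function(i, j) {
    out <- numeric(length(i))
    fixed <- pmin(i, j) <= nf
    if (any(fixed)) {
      r <- pmax(i, j)[fixed]; c <- pmin(i, j)[fixed]
      out[fixed] <- B[cbind(r, c)]
    }
    if (any(!fixed))
      out[!fixed] <- .selinv_lookup(L@p, L@i, Zx,
                                    invq[i[!fixed]], invq[j[!fixed]])
    out
  }
  list(sol = sol, logdetC = logdetC, get = get)
}

# route by problem size unless forced
solve_mme_factor <- function(m, invert = TRUE,
                             method = getOption("hamgp.mme_method",
                                                "auto")) {
  n <- ncol(m$C)
  if (method == "auto") method <- if (n > 2500L) "sparse" else "dense"
  if (method == "sparse" && invert) solve_mme_sparse(m)
  else solve_mme_dense(m, invert = invert)
}

# restricted log-likelihood (up to an additive constant)
reml_loglik <- function(m, sv) {
  yPy <- 0
  for (t in seq_len(m$nt))
    yPy <- yPy + sum(m$y[[t]] * rowSums(sapply(seq_len(m$nt), function(u)
      m$rho[, t, u] * m$y[[u]])))
  yPy <- yPy - sum(m$rhs * sv$sol)
  if (m$nt == 1L) {
    n1 <- sum(m$has[[1]])
    logR <- n1 * log(m$R0[1, 1]) - sum(log(m$w[m$has[[1]]]))
    logG <- m$q * log(m$G0[1, 1])
  } else {
    both <- m$has[[1]] & m$has[[2]]
    logR <- sum(both) * determinant(m$R0)$modulus[1] +
      sum(m$has[[1]] & !both) * log(m$R0[1, 1]) +
      sum(m$has[[2]] & !both) * log(m$R0[2, 2])
    logG <- m$q * determinant(m$G0)$modulus[1]
  }
  -0.5 * (logR + logG + sv$logdetC + yPy)
}

# tr(Ainv %*% Cinv[block_t, block_u]) using Ainv sparsity only
trace_ainv_block <- function(Ainv, cinv_get, off_t, off_u) {
  T3 <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  sum(T3@x * cinv_get(off_t + T3@i + 1L, off_u + T3@j + 1L))
}

# per-record design column indices (fixed cols + animal col), used for the
# w' Cinv w residual corrections; returns list of index matrices per trait
record_cols <- function(m) {
  lapply(seq_len(m$nt), function(t) {
    Xt <- m$X[[t]]
    idx <- matrix(NA_integer_, m$q, ncol(Xt) + 1L)
    if (ncol(Xt)) {
      Tt <- as(Xt, "TsparseMatrix")
      # each animal row has few nonzero fixed columns
      for (k in seq_along(Tt@i)) {
        r <- Tt@i[k] + 1L
        slot <- which(is.na(idx[r, ]))[1L]
        idx[r, slot] <- m$off_b[t] + Tt@j[k] + 1L
      }
    }
    for (r in seq_len(m$q))
      idx[r, which(is.na(idx[r, ]))[1L]] <- m$off_a[t] + r
    idx
  })
}

# sum_{k,l} Cinv[cols_i[k], cols_j[l]] for each row i (NA-padded indices)
quad_correction <- function(cinv_get, cols_i, cols_j, rows) {
  out <- numeric(length(rows))
  ci <- cols_i[rows, , drop = FALSE]; cj <- cols_j[rows, , drop = FALSE]
  for (k in seq_len(ncol(ci))) for (l in seq_len(ncol(cj))) {
    ok <- !is.na(ci[, k]) & !is.na(cj[, l])
    if (any(ok))
      out[ok] <- out[ok] + cinv_get(ci[ok, k], cj[ok, l])
  }
  out
}

#' Solve the mixed-model equations of the animal model
#'
#' Fits `y = Xb + Za + e` with `a ~ N(0, A sigma_a^2)` (or `G0 (x) A` for two
#' traits) by Henderson's mixed-model equations, at fixed variance
#' components. Fixed effects are sex (first level constrained to zero) and
#' slaughter batch (all levels, absorbing the intercept). Animals without
#' records receive EBV through their pedigree links. Prediction error
#' variances come from the exact inverse of the coefficient matrix.
#'
#' @param phenotypes Data.frame with `id`, trait column(s), `sex`, `batch`.
#'   `NA` trait values are unrecorded.
#' @param pedigree A `ham_pedigree` (or coercible records).
#' @param traits Character vector of one or two trait column names.
#' @param varcomp For one trait, `list(sa2 =, se2 =)`; for two,
#'   `list(G0 = 2x2, R0 = 2x2)`.
#' @param weights Optional per-record residual weights (univariate):
#'   residual variance of record i is `se2 / w_i`.
#' @param pev Compute PEV and EBV accuracy (needs the dense inverse).
#' @return `ham_eval` object: `ebv` data.frame (per animal, per trait, with
#'   `pev` and `accuracy` when requested), `fixef`, `y_adj` per record,
#'   `varcomp`, plus solver internals used by [adjust_phenotypes()].
#' @export
solve_mme <- function(phenotypes, pedigree, traits, varcomp,
                      weights = NULL, pev = TRUE) {
  ped <- validate_pedigree(pedigree)
  nt <- length(traits); stopifnot(nt %in% 1:2)
  if (nt == 1L) {
    G0 <- varcomp$sa2; R0 <- varcomp$se2
  } else {
    G0 <- varcomp$G0; R0 <- varcomp$R0
  }
  if (any(eigen(matrix(G0, nt), symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("genetic (co)variance matrix must be positive definite")
  Ainv <- build_A_inverse(ped)
  m <- build_mme(phenotypes, ped, traits, G0, R0, Ainv, weights)
  sv <- solve_mme_factor(m, invert = pev)
  finish_eval(m, sv, ped, phenotypes, traits, pev = pev)
}

# shared packaging of an MME solution into the user-facing fit object
finish_eval <- function(m, sv, ped, phenotypes, traits, pev = TRUE,
                        varcomp_extra = NULL) {
  nt <- m$nt
  fixef <- lapply(seq_len(nt), function(t) {
    b <- sv$sol[m$off_b[t] + seq_len(m$f[t])]
    names(b) <- m$fixed_names[[t]]
    b
  })
  names(fixef) <- traits
  ebv <- data.frame(id = ped$id, stringsAsFactors = FALSE)
  for (t in seq_len(nt)) {
    a <- sv$sol[m$off_a[t] + seq_len(m$q)]
    ebv[[paste0("ebv_", traits[t])]] <- a
    if (pev) {
      pv <- sv$get(m$off_a[t] + seq_len(m$q), m$off_a[t] + seq_len(m$q))
      sg2 <- m$G0[t, t]
      ebv[[paste0("pev_", traits[t])]] <- pv
      ebv[[paste0("acc_", traits[t])]] <- ebv_accuracy(pv, sg2)
    }
  }
  yadj <- compute_yadj(m, fixef, phenotypes, traits)
  vc <- if (nt == 1L) list(sa2 = m$G0[1, 1], se2 = m$R0[1, 1],
                           h2 = m$G0[1, 1] / (m$G0[1, 1] + m$R0[1, 1]))
        else list(G0 = m$G0, R0 = m$R0,
                  r_g = m$G0[1, 2] / sqrt(m$G0[1, 1] * m$G0[2, 2]))
  structure(list(traits = traits, ebv = ebv, fixef = fixef, y_adj = yadj,
                 varcomp = c(vc, varcomp_extra),
                 loglik = reml_loglik(m, sv),
                 levels = lapply(seq_len(nt), function(t)
                   list(sex = sort(unique(as.character(
                          phenotypes$sex[m$rec[[t]]]))),
                        batch = sort(unique(as.character(
                          phenotypes$batch[m$rec[[t]]]))))),
                 pev_available = pev),
            class = "ham_eval")
}

compute_yadj <- function(m, fixef, phenotypes, traits) {
  out <- phenotypes[, "id", drop = FALSE]
  for (t in seq_len(m$nt)) {
    tr <- traits[t]
    xb <- as.numeric(m$X[[t]] %*% fixef[[tr]])  # q-vector, animal-indexed
    v <- rep(NA_real_, nrow(phenotypes))
    v[m$rec[[t]]] <- phenotypes[[tr]][m$rec[[t]]] - xb[m$ridx[m$rec[[t]]]]
    out[[paste0("yadj_", tr)]] <- v
  }
  out
}

#' @export
print.ham_eval <- function(x, ...) {
  cat("<ham_eval> traits:", paste(x$traits, collapse = ", "), "\n")
  if (!is.null(x$varcomp$h2))
    cat("  sa2 =", signif(x$varcomp$sa2, 5), " se2 =",
        signif(x$varcomp$se2, 5), " h2 =", signif(x$varcomp$h2, 4), "\n")
  if (!is.null(x$varcomp$r_g))
    cat("  genetic correlation =", signif(x$varcomp$r_g, 4), "\n")
  invisible(x)
}

#' EBV accuracy from prediction error variance
#'
#' `r = sqrt(1 - PEV / sg2)` where `sg2` is the estimated additive genetic
#' variance of the trait. Tiny negative PEV from finite-precision inversion
#' is clamped to zero; PEV materially above `sg2` signals an inconsistent
#' MME/REML pairing and errors.
#'
#' @param pev Prediction error variance(s).
#' @param sg2 Additive genetic variance.
#' @param tol Relative slack allowed above `sg2` before erroring.
#' @return Accuracy in `[0, 1]`.
#' @export
ebv_accuracy <- function(pev, sg2, tol = 0.05) {
  stopifnot(sg2 > 0)
  pev <- pmax(pev, 0)
  if (any(pev > sg2 * (1 + tol)))
    stop("PEV exceeds the genetic variance; MME and variance components ",
         "are inconsistent")
  sqrt(pmax(0, 1 - pev / sg2))
}

#' Pre-correct phenotypes for fixed effects
#'
#' `y_adj = y - X b_hat`, using the fixed-effect solutions of a fitted
#' animal model. Factor levels unseen at fit time raise an error.
#'
#' @param phenotypes Data.frame with `id`, trait column(s), `sex`, `batch`.
#' @param fit A `ham_eval` from [solve_mme()] / [reml_univariate()] /
#'   [reml_bivariate()].
#' @param trait Trait to adjust (default: all traits of the fit).
#' @return Data.frame `id` + `yadj_<trait>` columns (`NA` for unrecorded).
#' @export
adjust_phenotypes <- function(phenotypes, fit, trait = fit$traits) {
  stopifnot(inherits(fit, "ham_eval"))
  out <- phenotypes[, "id", drop = FALSE]
  for (tr in trait) {
    t <- match(tr, fit$traits)
    if (is.na(t)) stop("trait ", tr, " was not part of the fit")
    b <- fit$fixef[[tr]]
    lv <- fit$levels[[t]]
    rec <- !is.na(phenotypes[[tr]])
    for (f in c("sex", "batch")) {
      seen <- unique(as.character(phenotypes[[f]][rec]))
      new <- setdiff(seen, lv[[f]])
      if (length(new))
        stop("unseen ", f, " level(s) at prediction time: ",
             paste(new, collapse = ", "))
    }
    xb <- numeric(nrow(phenotypes))
    sx <- as.character(phenotypes$sex); bt <- as.character(phenotypes$batch)
    for (nm in names(b)) {
      part <- strsplit(nm, ":", fixed = TRUE)[[1]]
      hit <- if (nm == "mu") rep(TRUE, length(xb))
             else if (part[1] == "sex") sx == part[2]
             else bt == part[2]
      xb[hit] <- xb[hit] + b[[nm]]
    }
    v <- rep(NA_real_, nrow(phenotypes))
    v[rec] <- phenotypes[[tr]][rec] - xb[rec]
    out[[paste0("yadj_", tr)]] <- v
  }
  out
}

# one EM update; returns new parameter vector.
# theta packing: univariate c(sa2, se2); bivariate c(g11, g12, g22, r11,
# r12, r22). Returns also the pieces needed by the caller.
em_update <- function(theta, phen, ped, traits, Ainv, weights) {
  nt <- length(traits)
  if (nt == 1L) { G0 <- theta[1]; R0 <- theta[2] }
  else {
    G0 <- matrix(theta[c(1, 2, 2, 3)], 2)
    R0 <- matrix(theta[c(4, 5, 5, 6)], 2)
  }
  m <- build_mme(phen, ped, traits, G0, R0, Ainv, weights)
  sv <- solve_mme_factor(m, invert = TRUE)
  ll <- reml_loglik(m, sv)
  q <- m$q
  cols <- record_cols(m)
  a <- lapply(seq_len(nt), function(t) sv$sol[m$off_a[t] + seq_len(q)])
  # genetic block
  Gn <- matrix(0, nt, nt)
  for (t in seq_len(nt)) for (u in t:nt) {
    Gn[t, u] <- Gn[u, t] <-
      (sum(a[[t]] * as.numeric(Ainv %*% a[[u]])) +
         trace_ainv_block(Ainv, sv$get, m$off_a[t], m$off_a[u])) / q
  }
  # residual block
  ehat <- lapply(seq_len(nt), function(t) {
    fit_t <- as.numeric(m$X[[t]] %*% sv$sol[m$off_b[t] + seq_len(m$f[t])]) +
      a[[t]]
    ifelse(m$has[[t]], m$y[[t]] - fit_t, NA_real_)
  })
  Rn <- matrix(0, nt, nt)
  if (nt == 1L) {
    rows <- which(m$has[[1]])
    qq <- quad_correction(sv$get, cols[[1]], cols[[1]], rows)
    Rn[1, 1] <- sum(m$w[rows] * (ehat[[1]][rows]^2 + qq)) / length(rows)
  } else {
    both <- which(m$has[[1]] & m$has[[2]])
    for (t in 1:2) {
      rows <- which(m$has[[t]])
      qq <- quad_correction(sv$get, cols[[t]], cols[[t]], rows)
      Rn[t, t] <- sum(ehat[[t]][rows]^2 + qq) / length(rows)
    }
    if (length(both)) {
      qq <- quad_correction(sv$get, cols[[1]], cols[[2]], both)
      Rn[1, 2] <- Rn[2, 1] <-
        sum(ehat[[1]][both] * ehat[[2]][both] + qq) / length(both)
    }
  }
  theta_new <- if (nt == 1L) c(Gn[1, 1], Rn[1, 1])
               else c(Gn[1, 1], Gn[1, 2], Gn[2, 2],
                      Rn[1, 1], Rn[1, 2], Rn[2, 2])
  list(theta = theta_new, loglik = ll, m = m, sv = sv)
}

theta_valid <- function(theta, nt) {
  if (any(!is.finite(theta))) return(FALSE)
  if (nt == 1L) return(all(theta > 0))
  G0 <- matrix(theta[c(1, 2, 2, 3)], 2); R0 <- matrix(theta[c(4, 5, 5, 6)], 2)
  all(diag(G0) > 0, diag(R0) > 0) &&
    det(G0) > 0 && det(R0) > 0
}

clamp_theta <- function(theta, nt, floor = 1e-10) {
  flag <- FALSE
  if (nt == 1L) {
    if (any(theta < floor)) { theta <- pmax(theta, floor); flag <- TRUE }
    return(list(theta = theta, clamped = flag))
  }
  for (off in c(0L, 3L)) {
    M <- matrix(theta[off + c(1, 2, 2, 3)], 2)
    ev <- eigen(M, symmetric = TRUE)
    if (any(ev$values < floor)) {   # project to nearest PD
      M <- ev$vectors %*% diag(pmax(ev$values, floor)) %*% t(ev$vectors)
      theta[off + 1:3] <- c(M[1, 1], M[1, 2], M[2, 2])
      flag <- TRUE
    }
  }
  list(theta = theta, clamped = flag)
}

# EM-REML driver with optional monotone-guarded SQUAREM acceleration
reml_em <- function(phen, pedigree, traits, init, tol, max_iter,
                    weights = NULL, accelerate = TRUE, verbose = FALSE,
                    prune = TRUE, fix_idx = integer(0)) {
  ped <- validate_pedigree(pedigree)
  if (prune) ped <- prune_pedigree(ped, keep = phen$id)
  Ainv <- build_A_inverse(ped)
  nt <- length(traits)
  theta <- init
  clamp_events <- 0L
  fix_vals <- init[fix_idx]
  em_base <- em_update
  em_update <- function(th, ...) {
    th[fix_idx] <- fix_vals
    r <- em_base(th, ...)
    r$theta[fix_idx] <- fix_vals
    r
  }
  do_clamp <- function(th) {
    cl <- clamp_theta(th, nt)
    clamp_events <<- clamp_events + cl$clamped
    cl$theta
  }
  trace <- data.frame(iter = 0L, loglik = NA_real_,
                      t(stats::setNames(theta, paste0("p", seq_along(theta)))))
  iter <- 0L; converged <- FALSE; delta <- Inf
  ll_prev <- -Inf; flat_count <- 0L
  # each cycle: theta -> EM -> EM (-> guarded extrapolation -> EM)
  while (iter < max_iter) {
    iter <- iter + 1L
    F1 <- em_update(theta, phen, ped, traits, Ainv, weights)
    th1 <- do_clamp(F1$theta)
    F2 <- em_update(th1, phen, ped, traits, Ainv, weights)
    th2 <- do_clamp(F2$theta)
    cand <- th2; ll_cand <- F2$loglik      # ll evaluated at th1
    if (accelerate) {
      r <- th1 - theta; v <- (th2 - th1) - r
      if (sum(v^2) > 1e-300 && sum(r^2) > 0) {
        alpha <- max(-sqrt(sum(r^2) / sum(v^2)), -32)
        acc <- theta - 2 * alpha * r + alpha^2 * v
        if (theta_valid(acc, nt)) {
          Facc <- em_update(acc, phen, ped, traits, Ainv, weights)
          # accept the extrapolation (plus its stabilizing EM step) only
          # if the restricted likelihood did not drop
          if (Facc$loglik >= F2$loglik - 1e-8) {
            cand <- do_clamp(Facc$theta)
            ll_cand <- Facc$loglik
          }
        }
      }
    }
    delta <- max(abs(cand - theta) / pmax(abs(theta), 1e-8))
    theta <- cand
    trace <- rbind(trace, data.frame(iter = iter, loglik = ll_cand,
      t(stats::setNames(theta, paste0("p", seq_along(theta))))))
    if (verbose)
      message(sprintf("cycle %3d  logL %.6f  delta %.3g", iter,
                      ll_cand, delta))
    if (delta < tol) { converged <- TRUE; break }
    # restricted likelihood flat at the numerical noise floor for two
    # consecutive cycles: the remaining parameter drift is below the
    # resolution of the objective, treat as converged
    ll_tol <- 1e-8 * (1 + abs(ll_cand))
    if (is.finite(ll_prev) && abs(ll_cand - ll_prev) < ll_tol) {
      flat_count <- flat_count + 1L
      if (flat_count >= 2L) { converged <- TRUE; break }
    } else flat_count <- 0L
    ll_prev <- ll_cand
  }
  if (!converged)
    warning("EM-REML did not converge in ", max_iter,
            " cycles (last relative change ", signif(delta, 3),
            "); see the $convergence trace")
  last <- em_update(theta, phen, ped, traits, Ainv, weights)
  list(theta = theta, ped = ped, Ainv = Ainv, last = last,
       convergence = list(iterations = iter, converged = converged,
                          clamped = clamp_events, trace = trace),
       weights = weights)
}

#' Univariate EM-REML for the animal model
#'
#' Estimates `sigma_a^2` and `sigma_e^2` by EM-REML (expectation step =
#' Henderson's MME with the exact dense inverse; maximization = closed-form
#' variance updates), iterating until the largest relative parameter change
#' drops below `tol`. Acceleration extrapolates the EM map but keeps every
#' accepted step monotone in the restricted likelihood. Variances drifting
#' to the boundary are clamped at 1e-10 and flagged in `$convergence`.
#' Uninformative founder-placeholder ancestors are pruned before the fit.
#'
#' @inheritParams solve_mme
#' @param trait Trait column name.
#' @param init Starting values `c(sa2, se2)`; default splits the phenotypic
#'   variance in half.
#' @param tol Relative-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param accelerate Use the guarded extrapolation (default TRUE).
#' @param se Also compute approximate standard errors of `(sa2, se2)` and
#'   `h2` from the numerically differentiated restricted likelihood.
#' @param verbose Print the iteration trace.
#' @return `ham_eval` with `$varcomp` (`sa2`, `se2`, `h2`, optional SEs) and
#'   `$convergence`.
#' @export
reml_univariate <- function(phenotypes, pedigree, trait, init = NULL,
                            tol = 1e-8, max_iter = 500L, weights = NULL,
                            accelerate = TRUE, se = FALSE,
                            verbose = FALSE) {
  rec <- !is.na(phenotypes[[trait]])
  phen <- phenotypes[rec, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[rec]
  vy <- stats::var(phen[[trait]])
  n_eff <- nrow(phen)
  if (n_eff < 3L) stop("need at least 3 records for REML")
  if (is.null(init)) init <- c(0.5 * vy, 0.5 * vy)
  res <- reml_em(phen, pedigree, trait, init, tol, max_iter,
                 weights = weights, accelerate = accelerate,
                 verbose = verbose)
  extra <- list(convergence = res$convergence)
  if (se) {
    ll_fun <- function(th) {
      m <- build_mme(phen, res$ped, trait, th[1], th[2], res$Ainv,
                     res$weights)
      reml_loglik(m, solve_mme_factor(m, invert = FALSE))
    }
    H <- numeric_hessian(ll_fun, res$theta)
    V <- tryCatch(solve(-H), error = function(e) matrix(NA, 2, 2))
    sa2 <- res$theta[1]; se2 <- res$theta[2]; s <- sa2 + se2
    grad_h2 <- c(se2, -sa2) / s^2
    extra$se <- list(sa2 = sqrt(V[1, 1]), se2 = sqrt(V[2, 2]),
                     h2 = sqrt(drop(t(grad_h2) %*% V %*% grad_h2)))
  }
  fit <- finish_eval(res$last$m, res$last$sv, res$ped, phen, trait,
                     pev = TRUE, varcomp_extra = NULL)
  fit$convergence <- res$convergence
  if (!is.null(extra$se)) fit$varcomp$se <- extra$se
  fit
}

numeric_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- pmax(1e-4 * abs(x), 1e-6)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) for (j in i:p) {
    if (i == j) {
      xp <- x; xp[i] <- x[i] + h[i]; xm <- x; xm[i] <- x[i] - h[i]
      H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h[i]^2
    } else {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
      xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
      H[i, j] <- H[j, i] <-
        (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
    }
  }
  H
}

#' Bivariate EM-REML with missing-trait records
#'
#' Estimates the 2x2 genetic (`G0`) and residual (`R0`) covariance matrices
#' of the stacked two-trait animal model. Record sets may differ between
#' traits (the design's pattern: the infrared proxy recorded for many more
#' animals than the observed trait); the residual covariance is estimated
#' from animals recorded on both traits. Non-positive-definite interim
#' matrices are projected to the nearest PD matrix and flagged.
#'
#' @inheritParams reml_univariate
#' @param traits Character vector of the two trait column names.
#' @param init Optional `list(G0 =, R0 =)` start.
#' @param fix_residual_cov Keep the residual covariance fixed at zero
#'   (useful for consistency checks against univariate fits).
#' @return `ham_eval` with `$varcomp` (`G0`, `R0`, `r_g`) and
#'   `$convergence`; EBV/PEV/accuracy per animal and trait.
#' @export
reml_bivariate <- function(phenotypes, pedigree, traits, init = NULL,
                           tol = 1e-6, max_iter = 200L, accelerate = TRUE,
                           fix_residual_cov = FALSE, verbose = FALSE) {
  stopifnot(length(traits) == 2L)
  keep <- !is.na(phenotypes[[traits[1]]]) | !is.na(phenotypes[[traits[2]]])
  phen <- phenotypes[keep, , drop = FALSE]
  v1 <- stats::var(phen[[traits[1]]], na.rm = TRUE)
  v2 <- stats::var(phen[[traits[2]]], na.rm = TRUE)
  if (is.null(init)) {
    g12 <- 0.25 * sqrt(v1 * v2)
    init <- c(0.5 * v1, g12, 0.5 * v2, 0.5 * v1, 0.1 * sqrt(v1 * v2),
              0.5 * v2)
  } else {
    init <- c(init$G0[1, 1], init$G0[1, 2], init$G0[2, 2],
              init$R0[1, 1], init$R0[1, 2], init$R0[2, 2])
  }
  if (fix_residual_cov) init[5] <- 0
  res <- reml_em(phen, pedigree, traits, init, tol, max_iter,
                 accelerate = accelerate, verbose = verbose,
                 fix_idx = if (fix_residual_cov) 5L else integer(0))
  fit <- finish_eval(res$last$m, res$last$sv, res$ped, phen, traits,
                     pev = TRUE)
  fit$convergence <- res$convergence
  fit
}
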