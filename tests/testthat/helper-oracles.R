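# Independent oracles used across test files. These deliberately use naive
# recursions / dense formulas, not the package's production code paths.

# Recursive kinship phi(i, j); A = 2 * phi. Memoised on the pair key.
oracle_kinship_matrix <- function(ped) {
  ped <- hamgp::validate_pedigree(ped)
  n <- nrow(ped); s <- ped$sire_idx; d <- ped$dam_idx
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + phi(s[i], d[i]))
    } else {
      # j is the later animal, so i is not a descendant of j
      0.5 * (phi(i, s[j]) + phi(i, d[j]))
    }
    memo[[key]] <- v
    v
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- phi(i, j)
  dimnames(K) <- list(ped$id, ped$id)
  K
}

# Random valid pedigree: founders plus animals mating earlier animals.
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L), seed = 1L) {
  set.seed(seed)
  id <- paste0("a", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1L):n) {
    pair <- sample(seq_len(i - 1L), 2L)
    sire[i] <- id[pair[1L]]; dam[i] <- id[pair[2L]]
  }
  data.frame(id = id, sire = sire, dam = dam, stringsAsFactors = FALSE)
}

# Dense GLS/BLUP oracle for the animal model y = Xb + Za + e,
# a ~ N(0, A sa2), e ~ N(0, R se2) with R = diag(1/w).
oracle_gls_blup <- function(y, X, Z, A, sa2, se2, w = rep(1, length(y))) {
  V <- Z %*% A %*% t(Z) * sa2 + diag(se2 / w, length(y))
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- solve(XtVi %*% X, XtVi %*% y)
  a <- sa2 * A %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b = drop(b), a = drop(a))
}

# Restricted log-likelihood (univariate, up to a constant) for grid oracles.
oracle_reml_loglik <- function(y, X, Z, A, sa2, se2) {
  V <- Z %*% A %*% t(Z) * sa2 + diag(se2, length(y))
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            drop(t(y) %*% P %*% y))
}
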