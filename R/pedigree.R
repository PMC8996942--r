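#' Validate and order a pedigree
#'
#' Checks pedigree records for structural errors (duplicated ids, animals
#' appearing as their own ancestor, parents of the wrong sex when sexes are
#' supplied) and reorders them so that every parent precedes its offspring,
#' the ordering required by the tabular relationship-matrix method and by
#' Henderson's rules for the inverse.
#'
#' @param records A data.frame with at least columns `id`, `sire`, `dam`.
#'   Unknown parents are coded `0` (or `NA`, which is recoded to `0`). Any
#'   further columns (`sex`, `family`, `batch`, `population`, ...) are carried
#'   through unchanged.
#' @return An object of class `ham_pedigree`: the input data.frame,
#'   topologically sorted, with integer columns `sire_idx` and `dam_idx`
#'   giving the row index of each parent (0 when unknown).
#' @examples
#' ped <- validate_pedigree(data.frame(
#'   id = c("kid", "s", "d"), sire = c("s", 0, 0), dam = c("d", 0, 0)))
#' ped$id  # parents first
#' @export
validate_pedigree <- function(records) {
  if (inherits(records, "ham_pedigree")) return(records)
  stopifnot(is.data.frame(records),
            all(c("id", "sire", "dam") %in% names(records)))
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  rec$id <- as.character(rec$id)
  rec$sire <- as.character(rec$sire); rec$dam <- as.character(rec$dam)
  rec$sire[is.na(rec$sire)] <- "0"; rec$dam[is.na(rec$dam)] <- "0"
  if (anyDuplicated(rec$id))
    stop("duplicated pedigree ids: ",
         paste(unique(rec$id[duplicated(rec$id)]), collapse = ", "))
  if (any(rec$id == "0")) stop("'0' is reserved for unknown parents")
  own <- rec$id == rec$sire | rec$id == rec$dam
  if (any(own))
    stop("animal appears as its own parent: ",
         paste(rec$id[own], collapse = ", "))
  # parents referenced but not listed become implicit unknowns? No: require
  # every named parent to have its own record, so A is over a closed set.
  missing_par <- setdiff(c(rec$sire, rec$dam), c(rec$id, "0"))
  if (length(missing_par))
    stop("parents without their own pedigree record: ",
         paste(utils::head(missing_par, 5), collapse = ", "))

  n <- nrow(rec)
  idx <- seq_len(n); names(idx) <- rec$id
  s <- ifelse(rec$sire == "0", 0L, idx[rec$sire])
  d <- ifelse(rec$dam == "0", 0L, idx[rec$dam])

  # Kahn's algorithm on parent -> offspring edges; leftover nodes lie on a
  # cycle and are reported by id.
  indeg <- (s > 0L) + (d > 0L)
  kids_of <- split(rep(idx, 2L), c(s, d))
  kids_of[["0"]] <- NULL
  order_out <- integer(n); pos <- 0L
  queue <- idx[indeg == 0L]
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    pos <- pos + 1L; order_out[pos] <- v
    kv <- kids_of[[as.character(v)]]
    for (k in kv) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (pos < n) {
    bad <- rec$id[indeg > 0L]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  rec <- rec[order_out, , drop = FALSE]
  rownames(rec) <- NULL
  idx2 <- seq_len(n); names(idx2) <- rec$id
  rec$sire_idx <- ifelse(rec$sire == "0", 0L, as.integer(idx2[rec$sire]))
  rec$dam_idx  <- ifelse(rec$dam == "0", 0L, as.integer(idx2[rec$dam]))
  class(rec) <- c("ham_pedigree", "data.frame")
  rec
}

#' @export
print.ham_pedigree <- function(x, ...) {
  cat("<ham_pedigree> ", nrow(x), " animals (",
      sum(x$sire_idx == 0L & x$dam_idx == 0L), " founders)\n", sep = "")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients F without forming the dense
#' relationship matrix, tracing each animal's ancestor contributions
#' (L-vector) against the Mendelian-sampling variances D.
#'
#' @param pedigree A `ham_pedigree` (or records coercible via
#'   [validate_pedigree()]).
#' @return Numeric vector of F, in pedigree order.
#' @export
inbreeding <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped); s <- ped$sire_idx; d <- ped$dam_idx
  F <- numeric(n); D <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    D[i] <- if (si > 0L && di > 0L) 0.5 - 0.25 * (F[si] + F[di])
            else if (si > 0L) 0.75 - 0.25 * F[si]
            else if (di > 0L) 0.75 - 0.25 * F[di]
            else 1
    if (si == 0L || di == 0L) { F[i] <- 0; next }
    L[] <- 0; L[i] <- 1
    aii <- 0
    for (j in i:1) {
      lj <- L[j]
      if (lj != 0) {
        aii <- aii + lj * lj * D[j]
        if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
        if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      }
    }
    F[i] <- aii - 1
  }
  F
}

#' Additive (numerator) relationship matrix
#'
#' Tabular-method recursion: `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2` for
#' `j < i` and `a_ii = 1 + a_sire(i),dam(i) / 2`; unknown parents contribute
#' zero. Dense, intended for pedigrees up to a few thousand animals; use
#' [build_A_inverse()] alone beyond that.
#'
#' @inheritParams inbreeding
#' @param max_n Guard against accidentally densifying a huge pedigree.
#' @return A dense symmetric matrix with dimnames = animal ids, entries in
#'   `[0, 2]`, diagonal `1 + F`.
#' @export
build_A <- function(pedigree, max_n = 10000L) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  if (n > max_n)
    stop("pedigree has ", n, " animals; dense A capped at max_n = ", max_n)
  s <- ped$sire_idx; d <- ped$dam_idx
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (si > 0L) v <- v + A[j, si]
      if (di > 0L) v <- v + A[j, di]
      v <- v / 2
      A[j, i] <- v; A[i, j] <- v
    }
    A[i, i] <- 1 + if (si > 0L && di > 0L) 0.5 * A[si, di] else 0
  }
  A
}

#' Sparse inverse of the relationship matrix
#'
#' Henderson's rules with exact accounting for inbreeding: animal i
#' contributes `1/D_i` to the (i,i) cell, `-1/(2 D_i)` to animal-parent
#' cells and `1/(4 D_i)` to parent-parent cells, where `D_i` is the
#' Mendelian-sampling variance given the parents' inbreeding (from
#' [inbreeding()]).
#'
#' @inheritParams inbreeding
#' @return A sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped); s <- ped$sire_idx; d <- ped$dam_idx
  F <- inbreeding(ped)
  F0 <- c(0, F)  # F0[idx + 1]: unknown parent (idx 0) has F = 0
  Fs <- F0[s + 1L]; Fd <- F0[d + 1L]
  D <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(s > 0L, 0.75 - 0.25 * Fs,
       ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  # triplet assembly: at most 6 entries (upper triangle) per animal
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  ai <- 1 / D
  add <- function(i, j, x) {
    ii <<- c(ii, pmin(i, j)); jj <<- c(jj, pmax(i, j)); xx <<- c(xx, x)
  }
  add(seq_len(n), seq_len(n), ai)
  has_s <- s > 0L; has_d <- d > 0L
  w <- which(has_s)
  if (length(w)) { add(w, s[w], -0.5 * ai[w]); add(s[w], s[w], 0.25 * ai[w]) }
  w <- which(has_d)
  if (length(w)) { add(w, d[w], -0.5 * ai[w]); add(d[w], d[w], 0.25 * ai[w]) }
  w <- which(has_s & has_d)
  if (length(w)) add(s[w], d[w], 0.25 * ai[w])
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               symmetric = TRUE,
                               dimnames = list(ped$id, ped$id))
  Ainv
}

#' Drop uninformative ancestors from a pedigree
#'
#' Repeatedly removes animals that carry no information for the animals of
#' interest: not in `keep`, childless, or whose every descendant path leads
#' only to removed animals. Used to shrink founder-placeholder chains (e.g.
#' dam parents/grandparents known only by name) before building mixed-model
#' equations. Two removal rules, applied to a fixed point, both of which
#' leave A over the remaining animals unchanged: (1) a non-kept animal with
#' no offspring; (2) a non-kept founder with exactly one offspring -- it
#' cannot create covariance between remaining animals, and unlinking it
#' leaves the offspring's own diagonal untouched because founders are
#' non-inbred and unrelated to the other parent.
#'
#' @param pedigree A `ham_pedigree`.
#' @param keep Character vector of ids that must stay (typically all
#'   phenotyped/genotyped animals and their named relatives of interest).
#' @return Pruned `ham_pedigree`.
#' @export
prune_pedigree <- function(pedigree, keep) {
  ped <- validate_pedigree(pedigree)
  keep <- as.character(keep)
  repeat {
    n <- nrow(ped)
    nkids <- tabulate(c(ped$sire_idx, ped$dam_idx), nbins = n)
    is_founder <- ped$sire_idx == 0L & ped$dam_idx == 0L
    drop <- !(ped$id %in% keep) &
      ((nkids == 0L) | (is_founder & nkids == 1L))
    if (!any(drop)) break
    dropped_ids <- ped$id[drop]
    ped <- as.data.frame(ped)[!drop, , drop = FALSE]
    ped$sire[ped$sire %in% dropped_ids] <- "0"
    ped$dam[ped$dam %in% dropped_ids] <- "0"
    ped$sire_idx <- NULL; ped$dam_idx <- NULL
    ped <- validate_pedigree(ped)
    if (nrow(ped) == n) break
  }
  ped
}
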