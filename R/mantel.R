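#' Mantel permutation test between two dyadic matrices
#'
#' Pearson correlation of the lower-triangle entries of two symmetric
#' individual-by-individual matrices, with a two-sided permutation p-value:
#' row/column labels of the second matrix are permuted jointly and
#' `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)`. Used here to verify that
#' mother-offspring status and social association are not confounded before
#' both enter the dyadic model.
#'
#' @param m1,m2 square symmetric numeric matrices over the same
#'   individuals. If both carry dimnames, `m2` is aligned to `m1`'s order.
#' With `exact = TRUE` (feasible up to ~8 individuals) all `n!` label
#' permutations are enumerated instead and
#' `p = #{|r*| >= |r|} / n!` (the identity permutation counts itself, so
#' `p > 0`).
#'
#' @param n_perm number of label permutations (default 9,999).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations instead of sampling.
#' @return list with `r` (observed correlation), `p` (two-sided permutation
#'   p-value) and `n_perm` (`n! ` when exact).
#' @export
mantel_test <- function(m1, m2, n_perm = 9999, seed = 1, exact = FALSE) {
  m1 <- as.matrix(m1)
  m2 <- as.matrix(m2)
  if (nrow(m1) != ncol(m1) || nrow(m2) != ncol(m2)) {
    stop("Mantel test requires square matrices")
  }
  if (!identical(dim(m1), dim(m2))) stop("matrices must have the same size")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      stop("matrices cover different individuals")
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  if (n < 3) stop("need at least 3 individuals")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  if (stats::sd(v1) == 0 || stats::sd(m2[lt]) == 0) {
    stop("a matrix with constant off-diagonal entries has no Mantel correlation")
  }
  r_obs <- stats::cor(v1, m2[lt])
  if (exact) {
    if (n > 8) stop("exact enumeration is limited to 8 individuals")
    perms <- .all_perms(n)
    r_all <- vapply(perms, function(idx)
      stats::cor(v1, m2[idx, idx][lt]), 0)
    return(list(r = r_obs,
                p = mean(abs(r_all) >= abs(r_obs) - 1e-12),
                n_perm = length(perms)))
  }
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    r_star <- stats::cor(v1, m2[idx, idx][lt])
    if (abs(r_star) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  list(r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = n_perm)
}

# all permutations of 1:n, recursively
.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (s in sub) {
      v <- integer(n)
      v[i] <- n
      v[-i] <- s
      k <- k + 1L
      out[[k]] <- v
    }
  }
  out
}
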