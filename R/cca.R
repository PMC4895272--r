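#' First canonical correlation between two feature groups
#'
#' Finds coefficient vectors a, b maximizing the correlation between the
#' linear combinations a'X and b'Y of the two groups' expression profiles:
#'
#' \deqn{r = \max_{a, b} \frac{a' \Sigma_{XY} b}
#'           {\sqrt{a' \Sigma_{XX} a}\sqrt{b' \Sigma_{YY} b}}}
#'
#' Only the first canonical correlation is returned — it is the strength
#' score attached to a group pair. Three solvers are available:
#'
#' * `"classical"` — exact solution via the SVD of
#'   \eqn{\Sigma_{XX}^{-1/2} \Sigma_{XY} \Sigma_{YY}^{-1/2}}. Valid only when
#'   `n > |C_x| + |C_y|` and both covariance matrices are invertible;
#'   otherwise a singularity error instructs you to use a regularized
#'   method. (With more features than samples classical CCA always reaches
#'   r = 1 by overfitting, which is meaningless.)
#' * `"ridge"` — same machinery with \eqn{\Sigma_{XX} + \lambda \bar{d} I}
#'   (and likewise for Y), where \eqn{\bar{d}} is the mean covariance
#'   diagonal; usable at any dimension.
#' * `"sparse_pmd"` (default) — diagonal-penalized sparse CCA via penalized
#'   matrix decomposition: covariances are treated as identity and a'
#'   cross-covariance b is maximized under unit-L2 and L1 constraints
#'   \eqn{\|a\|_1 \le c_x \sqrt{|C_x|}} (likewise for b), solved by
#'   alternating soft-thresholded updates initialized from the leading
#'   singular vectors of the cross-product — fully deterministic. This is
#'   the appropriate regime here: mRNA groups can hold hundreds of features
#'   against a few dozen samples.
#'
#' Features are standardized to zero mean and unit variance across samples
#' before any solver runs (so the cross-product matrix is the correlation
#' matrix); the reported strength is always the empirical correlation of
#' the fitted canonical variates, in \[0, 1\].
#'
#' @param X_sub Expression submatrix for the miRNA group (|C_x| x n,
#'   features by samples).
#' @param Y_sub Expression submatrix for the mRNA group (|C_y| x n), same
#'   sample order.
#' @param method `"sparse_pmd"`, `"ridge"` or `"classical"`.
#' @param penalty_x,penalty_y L1 penalty fractions in (0, 1\] for
#'   `sparse_pmd`; the L1 bound is `max(1, penalty * sqrt(dim))`. Default
#'   0.3 on both sides.
#' @param lambda Ridge regularization fraction (default 0.1) for `ridge`.
#' @return A `cca_result`: list with `r` (first canonical correlation),
#'   coefficient vectors `a` and `b` (named by feature), and `method`.
#' @export
canonical_correlation <- function(X_sub, Y_sub,
                                  method = c("sparse_pmd", "ridge", "classical"),
                                  penalty_x = 0.3, penalty_y = 0.3,
                                  lambda = 0.1) {
  method <- match.arg(method)
  if (!is.matrix(X_sub) || !is.matrix(Y_sub)) {
    abort_mircore("X_sub and Y_sub must be feature-by-sample matrices", "mircore_type_error")
  }
  if (nrow(X_sub) < 2L || nrow(Y_sub) < 2L) {
    abort_mircore("canonical correlation requires at least 2 features per group",
                  class = "mircore_size_error")
  }
  n <- ncol(X_sub)
  if (ncol(Y_sub) != n || n < 3L) {
    abort_mircore("the two submatrices must share >= 3 samples in identical order",
                  class = "mircore_size_error")
  }
  Xs <- standardize_rows(X_sub)
  Ys <- standardize_rows(Y_sub)
  res <- switch(method,
                classical = cca_classical(Xs, Ys),
                ridge = cca_ridge(Xs, Ys, lambda),
                sparse_pmd = cca_sparse_pmd(Xs, Ys, penalty_x, penalty_y))
  names(res$a) <- rownames(X_sub)
  names(res$b) <- rownames(Y_sub)
  r <- variate_cor(res$a, res$b, Xs, Ys)
  structure(list(r = r, a = res$a, b = res$b, method = method),
            class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("canonical correlation r = %.4f (%s; %d x %d features)\n",
              x$r, x$method, length(x$a), length(x$b)))
  invisible(x)
}

standardize_rows <- function(m) {
  mu <- rowMeans(m)
  centred <- m - mu
  s <- sqrt(rowSums(centred^2) / (ncol(m) - 1))
  s[s == 0] <- 1        # constant feature: leave as all-zero after centring
  centred / s
}

variate_cor <- function(a, b, Xs, Ys) {
  va <- drop(crossprod(a, Xs))
  vb <- drop(crossprod(b, Ys))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
  min(1, abs(stats::cor(va, vb)))
}

# --- classical / ridge ------------------------------------------------------

inv_sqrt_check <- function(S, what) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < 1e-10 * max(e$values)) {
    abort_mircore(
      sprintf("%s covariance matrix is singular under the classical method; use method = \"ridge\" or \"sparse_pmd\"", what),
      class = "mircore_singular_error"
    )
  }
  e$vectors %*% diag(1 / sqrt(e$values), length(e$values)) %*% t(e$vectors)
}

cca_classical <- function(Xs, Ys) {
  n <- ncol(Xs)
  p <- nrow(Xs); q <- nrow(Ys)
  if (n <= p + q) {
    abort_mircore(
      sprintf("classical CCA needs n > |C_x| + |C_y| (n = %d, groups %d + %d); use method = \"ridge\" or \"sparse_pmd\"",
              n, p, q),
      class = "mircore_singular_error"
    )
  }
  Sxx <- tcrossprod(Xs) / (n - 1)
  Syy <- tcrossprod(Ys) / (n - 1)
  Sxy <- tcrossprod(Xs, Ys) / (n - 1)
  Wx <- inv_sqrt_check(Sxx, "miRNA-group")
  Wy <- inv_sqrt_check(Syy, "mRNA-group")
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K, nu = 1, nv = 1)
  a <- drop(Wx %*% sv$u[, 1L])
  b <- drop(Wy %*% sv$v[, 1L])
  list(a = fix_sign(a), b = fix_sign_pair(a, b, Xs, Ys))
}

cca_ridge <- function(Xs, Ys, lambda) {
  assert_scalar_number(lambda, "lambda", lower = 0)
  n <- ncol(Xs)
  Sxx <- tcrossprod(Xs) / (n - 1)
  Syy <- tcrossprod(Ys) / (n - 1)
  Sxy <- tcrossprod(Xs, Ys) / (n - 1)
  Rx <- Sxx + lambda * mean(diag(Sxx)) * diag(nrow(Sxx))
  Ry <- Syy + lambda * mean(diag(Syy)) * diag(nrow(Syy))
  Wx <- inv_sqrt_check(Rx, "regularized miRNA-group")
  Wy <- inv_sqrt_check(Ry, "regularized mRNA-group")
  K <- Wx %*% Sxy %*% Wy
  sv <- svd(K, nu = 1, nv = 1)
  a <- drop(Wx %*% sv$u[, 1L])
  b <- drop(Wy %*% sv$v[, 1L])
  list(a = fix_sign(a), b = fix_sign_pair(a, b, Xs, Ys))
}

# --- sparse PMD -------------------------------------------------------------

soft <- function(x, d) sign(x) * pmax(abs(x) - d, 0)

# Project x onto {u : ||u||_2 = 1, ||u||_1 <= c} by binary search on the
# soft-threshold level.
l1_l2_project <- function(x, c1) {
  if (sum(abs(x)) == 0) return(x)
  u <- x / sqrt(sum(x^2))
  if (sum(abs(u)) <= c1) return(u)
  lo <- 0
  hi <- max(abs(x))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    su <- soft(x, mid)
    nrm <- sqrt(sum(su^2))
    if (nrm == 0) { hi <- mid; next }
    if (sum(abs(su / nrm)) > c1) lo <- mid else hi <- mid
  }
  su <- soft(x, hi)
  su / sqrt(sum(su^2))
}

cca_sparse_pmd <- function(Xs, Ys, penalty_x, penalty_y,
                           max_iter = 200L, tol = 1e-10) {
  assert_scalar_number(penalty_x, "penalty_x", lower = 1e-12, upper = 1)
  assert_scalar_number(penalty_y, "penalty_y", lower = 1e-12, upper = 1)
  n <- ncol(Xs)
  Z <- tcrossprod(Xs, Ys) / (n - 1)   # p x q cross-correlation matrix
  cx <- max(1, penalty_x * sqrt(nrow(Z)))
  cy <- max(1, penalty_y * sqrt(ncol(Z)))
  sv <- svd(Z, nu = 1, nv = 1)
  a <- fix_sign(drop(sv$u))
  b <- fix_sign(drop(sv$v))
  for (i in seq_len(max_iter)) {
    a_new <- l1_l2_project(drop(Z %*% b), cx)
    b_new <- l1_l2_project(drop(crossprod(Z, a_new)), cy)
    if (max(abs(a_new - a)) < tol && max(abs(b_new - b)) < tol) {
      a <- a_new; b <- b_new
      break
    }
    a <- a_new; b <- b_new
  }
  list(a = fix_sign(a), b = fix_sign_pair(a, b, Xs, Ys))
}

# Deterministic sign convention: largest-magnitude coefficient positive.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

# Choose b's sign so the variate correlation is nonnegative.
fix_sign_pair <- function(a, b, Xs, Ys) {
  va <- drop(crossprod(a, Xs))
  vb <- drop(crossprod(b, Ys))
  if (stats::sd(va) > 0 && stats::sd(vb) > 0 && stats::cor(va, vb) < 0) -b else b
}

#' Score all miRNA-group x mRNA-group pairs and rank COREs
#'
#' Computes the canonical correlation for every pair of a miRNA group and
#' an mRNA group on the matched expression data, keeps pairs with
#' `r >= rho` and ranks them by descending strength. A retained, ranked
#' pair is a CORE (collective group relationship) — the quantitative form
#' of a candidate miRNA-mRNA regulatory module. A group may appear in
#' several COREs. The CORE set can only shrink as `rho` rises.
#'
#' A pair whose CCA fails (e.g. singular covariance under the classical
#' method) is recorded as skipped, not fatal.
#'
#' @param groups_mirna,groups_mrna Lists of `feature_group` objects from
#'   [discover_groups()].
#' @param pair The aligned `matched_pair` the groups were derived from.
#' @param rho Minimum canonical correlation to report (default 0.5).
#' @param method CCA solver passed to [canonical_correlation()].
#' @param ... Further arguments (penalties) for [canonical_correlation()].
#' @return A `core_set` data frame with one row per CORE: `rank`,
#'   `strength`, `n_mirnas`, `n_mrnas`, `mirna_group`, `mrna_group` (indices
#'   into the input lists), `method`, and list columns `mirna_members`,
#'   `mrna_members`. Ranks run 1..#C without gaps, strength descending;
#'   ties broken by larger total group size, then lexicographic member
#'   order. Skipped pairs are in `attr(, "skipped")`.
#' @export
score_group_pairs <- function(groups_mirna, groups_mrna, pair, rho = 0.5,
                              method = c("sparse_pmd", "ridge", "classical"),
                              ...) {
  method <- match.arg(method)
  assert_scalar_number(rho, "rho", lower = 0, upper = 1)
  stopifnot(inherits(pair, "matched_pair"))
  rows <- list()
  skipped <- list()
  for (i in seq_along(groups_mirna)) {
    gx <- groups_mirna[[i]]
    for (j in seq_along(groups_mrna)) {
      gy <- groups_mrna[[j]]
      res <- tryCatch(
        canonical_correlation(pair$mirna[gx$members, , drop = FALSE],
                              pair$mrna[gy$members, , drop = FALSE],
                              method = method, ...),
        mircore_error = function(e) e
      )
      if (inherits(res, "error")) {
        skipped[[length(skipped) + 1L]] <-
          list(mirna_group = i, mrna_group = j, reason = conditionMessage(res))
        next
      }
      if (res$r >= rho) {
        rows[[length(rows) + 1L]] <- list(
          strength = res$r,
          n_mirnas = length(gx$members), n_mrnas = length(gy$members),
          mirna_group = i, mrna_group = j,
          mirna_members = gx$members, mrna_members = gy$members
        )
      }
    }
  }
  if (length(skipped)) {
    message(sprintf("score_group_pairs: skipped %d pair(s); see attr(, \"skipped\")",
                    length(skipped)))
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), strength = numeric(0),
                      n_mirnas = integer(0), n_mrnas = integer(0),
                      mirna_group = integer(0), mrna_group = integer(0),
                      method = character(0), stringsAsFactors = FALSE)
    out$mirna_members <- list()
    out$mrna_members <- list()
  } else {
    strength <- vapply(rows, `[[`, numeric(1), "strength")
    total_size <- vapply(rows, function(r) r$n_mirnas + r$n_mrnas, numeric(1))
    member_key <- vapply(rows, function(r) {
      paste(c(r$mirna_members, r$mrna_members), collapse = "|")
    }, character(1))
    ord <- order(-strength, -total_size, member_key, method = "radix")
    rows <- rows[ord]
    out <- data.frame(
      rank = seq_along(rows),
      strength = vapply(rows, `[[`, numeric(1), "strength"),
      n_mirnas = vapply(rows, `[[`, numeric(1), "n_mirnas"),
      n_mrnas = vapply(rows, `[[`, numeric(1), "n_mrnas"),
      mirna_group = vapply(rows, `[[`, numeric(1), "mirna_group"),
      mrna_group = vapply(rows, `[[`, numeric(1), "mrna_group"),
      method = method, stringsAsFactors = FALSE
    )
    out$mirna_members <- lapply(rows, `[[`, "mirna_members")
    out$mrna_members <- lapply(rows, `[[`, "mrna_members")
  }
  structure(out, skipped = skipped, class = c("core_set", "data.frame"))
}
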