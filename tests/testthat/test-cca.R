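test_that("exact linear dependence gives r = 1", {
  set.seed(41)
  n <- 20
  X <- rand_matrix(2, n, c("m1", "m2"))
  Y <- rbind(g1 = 2 * X[1, ] - X[2, ], g2 = X[1, ] + 3 * X[2, ])
  colnames(Y) <- colnames(X)
  expect_equal(canonical_correlation(X, Y, method = "classical")$r, 1,
               tolerance = 1e-8)
  # regularized solvers shrink the coefficients, so they approach 1 from below
  expect_gte(canonical_correlation(X, Y, method = "ridge")$r, 0.99)
  expect_gte(canonical_correlation(X, Y, method = "sparse_pmd")$r, 0.95)
})

test_that("the classical solver reduces to |PCC| for single variates", {
  set.seed(42)
  x <- rnorm(30)
  y <- 0.6 * x + rnorm(30, sd = 0.8)
  Xs <- mircore:::standardize_rows(matrix(x, 1, 30))
  Ys <- mircore:::standardize_rows(matrix(y, 1, 30))
  res <- mircore:::cca_classical(Xs, Ys)
  r <- mircore:::variate_cor(res$a, res$b, Xs, Ys)
  expect_equal(r, abs(cor(x, y)), tolerance = 1e-10)
})

test_that("classical r agrees with the eigendecomposition oracle and cancor", {
  set.seed(43)
  for (rep in 1:10) {
    n <- 50
    X <- rand_matrix(2, n, c("m1", "m2"))
    Y <- rand_matrix(2, n, c("g1", "g2"))
    Y[1, ] <- Y[1, ] + 0.5 * X[1, ]
    r <- canonical_correlation(X, Y, method = "classical")$r
    expect_equal(r, cca_eigen_oracle(X, Y), tolerance = 1e-8)
    r_cancor <- max(cancor(scale(t(X)), scale(t(Y)))$cor)
    expect_equal(r, r_cancor, tolerance = 1e-8)
  }
})

test_that("group-size and singularity preconditions are enforced", {
  set.seed(44)
  X1 <- rand_matrix(1, 10, "m1")
  Y <- rand_matrix(2, 10, c("g1", "g2"))
  expect_error(canonical_correlation(X1, Y), class = "mircore_size_error")

  # n <= |C_x| + |C_y|: classical must refuse and point to regularization
  Xbig <- rand_matrix(6, 10, sprintf("m%d", 1:6))
  Ybig <- rand_matrix(6, 10, sprintf("g%d", 1:6))
  err <- expect_error(canonical_correlation(Xbig, Ybig, method = "classical"),
                      class = "mircore_singular_error")
  expect_match(conditionMessage(err), "ridge|sparse")
  # the regularized methods handle the same input
  expect_true(canonical_correlation(Xbig, Ybig, method = "ridge")$r <= 1)
  expect_true(canonical_correlation(Xbig, Ybig, method = "sparse_pmd")$r <= 1)

  # duplicated feature rows make the covariance singular
  Xdup <- rbind(m1 = X1[1, ], m2 = X1[1, ])
  colnames(Xdup) <- colnames(Y)
  expect_error(canonical_correlation(Xdup, Y, method = "classical"),
               class = "mircore_singular_error")
})

test_that("r is symmetric in the two views and affine-invariant (classical)", {
  set.seed(45)
  X <- rand_matrix(3, 40, sprintf("m%d", 1:3))
  Y <- rand_matrix(3, 40, sprintf("g%d", 1:3))
  Y[2, ] <- Y[2, ] + 0.7 * X[3, ]
  r_xy <- canonical_correlation(X, Y, method = "classical")$r
  r_yx <- canonical_correlation(Y, X, method = "classical")$r
  expect_equal(r_xy, r_yx, tolerance = 1e-10)

  r_sp_xy <- canonical_correlation(X, Y, method = "sparse_pmd")$r
  r_sp_yx <- canonical_correlation(Y, X, method = "sparse_pmd")$r
  expect_equal(r_sp_xy, r_sp_yx, tolerance = 1e-6)

  X2 <- X * 3.5 + 2           # per-feature affine maps
  Y2 <- Y * c(-1, 0.2, 10)
  expect_equal(canonical_correlation(X2, Y2, method = "classical")$r, r_xy,
               tolerance = 1e-8)
})

test_that("classical r upper-bounds the correlation of any fixed projection pair", {
  set.seed(46)
  X <- rand_matrix(3, 60, sprintf("m%d", 1:3))
  Y <- rand_matrix(4, 60, sprintf("g%d", 1:4))
  Y[1, ] <- Y[1, ] + 0.4 * X[1, ]
  r <- canonical_correlation(X, Y, method = "classical")$r
  for (rep in 1:25) {
    u <- rnorm(3); v <- rnorm(4)
    expect_lte(abs(cor(drop(u %*% X), drop(v %*% Y))), r + 1e-10)
  }
})

test_that("independent noise stays within the permutation null", {
  set.seed(47)
  n <- 80
  X <- rand_matrix(2, n, c("m1", "m2"))
  Y <- rand_matrix(2, n, c("g1", "g2"))
  r_obs <- canonical_correlation(X, Y, method = "classical")$r
  r_perm <- vapply(1:99, function(b) {
    Yp <- Y[, sample(n), drop = FALSE]
    colnames(Yp) <- colnames(Y)
    canonical_correlation(X, Yp, method = "classical")$r
  }, numeric(1))
  # r for truly unrelated views is an ordinary draw from the permutation null
  expect_lt(r_obs, quantile(r_perm, 0.95) + 0.05)
  expect_lt(r_obs, 0.5)
})

test_that("score_group_pairs ranks, thresholds, and nests monotonically in rho", {
  set.seed(48)
  n <- 40
  # one latent factor drives one miRNA group and 8 separate mRNA groups
  z <- rnorm(n)
  X <- rand_matrix(3, n, sprintf("m%d", 1:3), sd = 0.3)
  X <- X + matrix(z, 3, n, byrow = TRUE)
  Y <- rand_matrix(16, n, sprintf("g%02d", 1:16), sd = 0.3)
  Y <- Y - matrix(z, 16, n, byrow = TRUE)
  pair <- make_pair(X, Y)
  gx <- list(mircore:::new_feature_group(rownames(X), 1, "mirna"))
  gy <- lapply(seq(1, 16, by = 2), function(i) {
    mircore:::new_feature_group(rownames(Y)[i:(i + 1)], 1, "mrna")
  })
  cores <- score_group_pairs(gx, gy, pair, rho = 0.5, method = "classical")
  expect_identical(nrow(cores), 8L)
  expect_identical(cores$rank, 1:8)
  expect_true(all(diff(cores$strength) <= 0))
  expect_true(all(cores$strength >= 0.5))

  # rho nesting: the CORE set at a higher rho is a subset
  cores_hi <- score_group_pairs(gx, gy, pair, rho = 0.8, method = "classical")
  key <- function(cs) paste(cs$mirna_group, cs$mrna_group)
  expect_true(all(key(cores_hi) %in% key(cores)))
  none <- score_group_pairs(gx, gy, pair, rho = 1, method = "classical")
  expect_identical(nrow(none), 0L)

  # identical member sets listed twice score identically
  twice <- score_group_pairs(gx, c(gy[1], gy[1]), pair, rho = 0,
                             method = "classical")
  expect_equal(twice$strength[1], twice$strength[2], tolerance = 1e-12)
})

test_that("failing pairs are skipped and recorded, not fatal", {
  set.seed(49)
  n <- 8
  X <- rand_matrix(3, n, sprintf("m%d", 1:3))
  Y <- rand_matrix(8, n, sprintf("g%d", 1:8))
  pair <- make_pair(X, Y)
  gx <- list(mircore:::new_feature_group(rownames(X), 1, "mirna"))
  gy <- list(mircore:::new_feature_group(rownames(Y)[1:2], 1, "mrna"),
             mircore:::new_feature_group(rownames(Y), 1, "mrna"))  # 3+8 > n
  suppressMessages(
    cores <- score_group_pairs(gx, gy, pair, rho = 0, method = "classical")
  )
  skipped <- attr(cores, "skipped")
  expect_length(skipped, 1)
  expect_identical(skipped[[1]]$mrna_group, 2L)
  expect_identical(nrow(cores), 1L)
})
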