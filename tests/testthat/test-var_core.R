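test_that("lag alignment pairs each observation with its successor", {
  x <- matrix(c(1, 2, 3), 1)
  ld <- build_lagged_matrices(x)
  expect_equal(as.numeric(ld$Y), c(2, 3))
  expect_equal(as.numeric(ld$Z), c(1, 2))

  x4 <- matrix(rnorm(8), 2, 4)
  ld4 <- build_lagged_matrices(x4)
  expect_equal(dim(ld4$Y), c(2, 3))
  expect_equal(dim(ld4$Z), c(2, 3))
  expect_equal(ld4$Y, x4[, 2:4])
  expect_equal(ld4$Z, x4[, 1:3])

  const <- matrix(5, 2, 4)
  ldc <- build_lagged_matrices(const)
  expect_equal(ldc$Y, ldc$Z)

  expect_error(build_lagged_matrices(matrix(1, 2, 2)), "at least 3")
})

test_that("OLS recovers the generating matrix from noiseless data", {
  set.seed(101)
  A <- matrix(runif(16, -0.4, 0.4), 4, 4)
  A <- A * (0.9 / max(Mod(eigen(A)$values)))
  m <- var_model(A)
  x <- simulate_var(m, T = 8, y0 = rnorm(4), seed = 1)
  fit <- ols_estimate(build_lagged_matrices(x))
  expect_lt(max(abs(unname(fit$A) - A)), 1e-8)
  expect_lt(attr(fit, "residual_norm"), 1e-8)
})

test_that("a geometric scalar series forces the decay coefficient", {
  fit <- ols_estimate(build_lagged_matrices(matrix(c(1, 0.5, 0.25), 1)))
  expect_equal(unname(fit$A[1, 1]), 0.5)
})

test_that("OLS matches an explicit normal-equations solve entrywise", {
  set.seed(202)
  n <- 3
  A0 <- matrix(rnorm(9, sd = 0.25), 3, 3)
  x <- simulate_var(var_model(A0, noise_cov = diag(0.1, 3)), T = 50, seed = 7)
  ld <- build_lagged_matrices(x)
  fit <- ols_estimate(ld)
  oracle <- ld$Y %*% t(ld$Z) %*% solve(ld$Z %*% t(ld$Z))
  expect_equal(unname(fit$A), unname(oracle), tolerance = 1e-10)
})

test_that("OLS is invariant to permuting and unpermuting gene order", {
  set.seed(33)
  x <- simulate_var(var_model(diag(0.4, 4), noise_cov = diag(0.3, 4)),
                    T = 30, seed = 5)
  p <- c(3, 1, 4, 2)
  A1 <- unname(ols_estimate(build_lagged_matrices(x))$A)
  A2 <- unname(ols_estimate(build_lagged_matrices(x[p, ]))$A)
  expect_equal(A2[order(p), order(p)], A1, tolerance = 1e-12)
})

test_that("rank-deficient designs are reported as singular", {
  Y <- matrix(rnorm(9), 3)
  Z <- matrix(1, 3, 3)  # rank one
  expect_error(ols_estimate(lagged(Y, Z)), "singular design")
})

test_that("stability verdicts follow the eigenvalues", {
  expect_true(is_stable(diag(0.5, 3), "modulus")$stable)
  expect_false(is_stable(diag(1, 3), "modulus")$stable)
  tri <- rbind(c(-2, 0), c(1, -1))
  expect_true(is_stable(tri, "halfplane")$stable)
  expect_false(is_stable(tri, "modulus")$stable)
  expect_error(is_stable(matrix(1, 2, 3)), "square")
})

test_that("modulus verdict accepts spectral radius up to 0.99", {
  for (seed in 1:20) {
    set.seed(seed)
    A <- matrix(rnorm(25), 5, 5)
    A <- A * (runif(1, 0.1, 0.99) / max(Mod(eigen(A)$values)))
    expect_true(is_stable(A, "modulus")$stable)
  }
})

test_that("simulation follows the closed-form noiseless recursions", {
  m <- var_model(diag(0.5, 3))
  x <- simulate_var(m, T = 5, y0 = rep(1, 3))
  expect_equal(unname(x), outer(rep(1, 3), 0.5^(0:4)))

  mv <- var_model(matrix(0, 2, 2), intercept = c(2, -1))
  xv <- simulate_var(mv, T = 4, y0 = c(9, 9))
  expect_equal(unname(xv[, 2:4]), matrix(c(2, -1), 2, 3))

  expect_error(simulate_var(m, T = 2), "at least 3")
})

test_that("identical seeds give identical simulations", {
  m <- var_model(diag(0.5, 2), noise_cov = diag(0.2, 2))
  expect_identical(simulate_var(m, 20, seed = 4, burn_in = 10),
                   simulate_var(m, 20, seed = 4, burn_in = 10))
})

test_that("residual covariance of a long run approaches the noise covariance", {
  S <- rbind(c(0.5, 0.2, 0), c(0.2, 0.4, 0.1), c(0, 0.1, 0.3))
  A <- diag(0.5, 3)
  x <- simulate_var(var_model(A, noise_cov = S), T = 10000, seed = 99)
  u <- x[, 2:10000] - A %*% x[, 1:9999]
  S_hat <- tcrossprod(u) / (ncol(u) - 1)
  expect_lt(max(abs(S_hat - S)) / max(abs(S)), 0.05)
})

test_that("row centering removes means and is idempotent", {
  x <- rbind(a = c(1, 2, 3), b = c(4, 4, 4))
  cx <- center_rows(x)
  expect_equal(unname(cx[1, ]), c(-1, 0, 1))
  expect_equal(unname(cx[2, ]), c(0, 0, 0))
  expect_equal(attr(cx, "row_means"), c(a = 2, b = 4))
  expect_equal(unname(center_rows(cx)), unname(cx), ignore_attr = TRUE)
  expect_equal(dimnames(cx), dimnames(x))
})

test_that("expression validation names the offending cells", {
  x <- matrix(1:6, 2, 3, dimnames = list(c("a", "a"), NULL))
  expect_error(validate_expression(x), "duplicate gene id")
  y <- matrix(as.numeric(1:6), 2, 3,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  y[2, 3] <- NA
  expect_error(validate_expression(y), "gene 'b', observation 't3'")
  expect_error(validate_expression(y[, 1:2]), "at least 3")
})
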