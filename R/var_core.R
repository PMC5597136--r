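#' Construct a VAR(1) model object
#'
#' A first-order vector autoregression \eqn{y_t = v + A y_{t-1} + u_t}.
#' `A[i, j]` is the effect of gene `j` at time `t-1` on gene `i` at time
#' `t`, so a nonzero `A[i, j]` is a directed edge gene_j -> gene_i.
#'
#' @param A square numeric coefficient matrix.
#' @param intercept optional numeric vector `v` (default all zero).
#' @param noise_cov optional symmetric positive-semidefinite innovation
#'   covariance (default `NULL`, interpreted as the zero matrix by
#'   [simulate_var()] unless overridden).
#' @return an object of class `var_model`.
#' @export
var_model <- function(A, intercept = NULL, noise_cov = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  n <- nrow(A)
  if (is.null(intercept)) intercept <- rep(0, n)
  if (length(intercept) != n)
    stopf("intercept has length %d, expected %d", length(intercept), n)
  if (!is.null(noise_cov)) {
    if (!is.matrix(noise_cov) || any(dim(noise_cov) != n))
      stopf("noise_cov must be %d x %d", n, n)
    if (max(abs(noise_cov - t(noise_cov))) > 1e-8)
      stopf("noise_cov must be symmetric")
    ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      stopf("noise_cov must be positive semidefinite")
  }
  structure(list(A = A, intercept = as.numeric(intercept),
                 noise_cov = noise_cov),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("VAR(1) model: %d genes, %d nonzero coefficients\n",
              nrow(x$A), sum(x$A != 0)))
  invisible(x)
}

#' Build one-lag response and covariate matrices
#'
#' Aligns an expression matrix into the compact VAR(1) regression form
#' `Y ~ A Z`: column `k` of `Z` is observation `k` and column `k` of `Y`
#' is observation `k+1`, giving `T-1` usable lag pairs (the single-series
#' convention with no presample).
#'
#' @param expr numeric expression matrix, genes x T observations, T >= 3.
#' @return an object of class `lagged_data`: list with `Y` and `Z`
#'   (both genes x T-1).
#' @examples
#' build_lagged_matrices(matrix(1:8, 2, 4))
#' @export
build_lagged_matrices <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("expression data must be a numeric matrix")
  T <- ncol(expr)
  if (T < 3L)
    stopf("need at least 3 observations to form lag pairs, got %d", T)
  structure(list(Y = expr[, 2:T, drop = FALSE],
                 Z = expr[, 1:(T - 1), drop = FALSE]),
            class = "lagged_data")
}

#' Ordinary least squares estimate of a VAR(1)
#'
#' Solves the unpenalized multivariate least-squares problem
#' \eqn{\min_A \|Y - AZ\|_F^2} through the normal equations
#' \eqn{A = Y Z' (Z Z')^{-1}} (equivalent to the Kronecker-product closed
#' form). With `intercept = TRUE` the covariates are augmented with a
#' constant row and the intercept is estimated jointly; otherwise rows are
#' expected to be centered already.
#'
#' @param data a `lagged_data` object from [build_lagged_matrices()].
#' @param intercept estimate an intercept term? Default `FALSE`.
#' @return a `var_model` with attributes `residual_norm` (Frobenius norm of
#'   `Y - AZ - v`) and `objective` (half its square).
#' @export
ols_estimate <- function(data, intercept = FALSE) {
  stopifnot(inherits(data, "lagged_data"))
  Y <- data$Y
  Z <- data$Z
  if (intercept) Z <- rbind(Z, rep(1, ncol(Z)))
  G <- Z %*% t(Z)
  if (rcond(G) < 1e-12)
    stopf(paste0("singular design: Z Z' is numerically rank deficient ",
                 "(reciprocal condition %.2e); more independent ",
                 "observations are needed"), rcond(G))
  coefs <- t(solve(G, Z %*% t(Y)))
  if (intercept) {
    A <- coefs[, -ncol(coefs), drop = FALSE]
    v <- coefs[, ncol(coefs)]
  } else {
    A <- coefs
    v <- rep(0, nrow(Y))
  }
  dimnames(A) <- list(rownames(Y), rownames(Y))
  resid <- Y - coefs %*% Z
  out <- var_model(A, intercept = v)
  attr(out, "residual_norm") <- norm(resid, "F")
  attr(out, "objective") <- 0.5 * sum(resid^2)
  out
}

#' Stability report for a VAR(1) coefficient matrix
#'
#' Two notions of stability are reported. Mode `"modulus"` is the VAR
#' criterion: all eigenvalues of `A` must have modulus below one, so that
#' the process is stationary. Mode `"halfplane"` checks that all
#' eigenvalue real parts are non-positive, which is what the weighted
#' Gershgorin constraint used by [infer_network()] actually certifies.
#' Both modes are reported side by side in run reports because the
#' constraint guarantees the half-plane property, not the modulus one.
#'
#' @param A square numeric matrix.
#' @param mode `"modulus"` (max |eigenvalue| < 1 - tol) or `"halfplane"`
#'   (max Re eigenvalue <= tol).
#' @param tol small positive tolerance, default `1e-7`.
#' @return an object of class `stability_report`: list with `stable`,
#'   `eigenvalues`, `mode`, `tol`.
#' @examples
#' is_stable(diag(0.5, 3))
#' is_stable(rbind(c(-2, 0), c(1, -1)), mode = "halfplane")
#' @export
is_stable <- function(A, mode = c("modulus", "halfplane"), tol = 1e-7) {
  mode <- match.arg(mode)
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  if (!is.numeric(tol) || tol <= 0) stopf("tol must be a small positive real")
  ev <- eigen(A, only.values = TRUE)$values
  stable <- if (mode == "modulus") max(Mod(ev)) < 1 - tol else max(Re(ev)) <= tol
  structure(list(stable = stable, eigenvalues = ev, mode = mode, tol = tol),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("%s-stable: %s (max |ev| = %.4f, max Re ev = %.4f)\n",
              x$mode, x$stable, max(Mod(x$eigenvalues)),
              max(Re(x$eigenvalues))))
  invisible(x)
}

#' Simulate a VAR(1) trajectory
#'
#' Iterates \eqn{y_t = v + A y_{t-1} + u_t} with Gaussian innovations drawn
#' from the model's `noise_cov` (no noise when `noise_cov` is `NULL` or
#' zero). With `burn_in > 0`, that many initial steps are discarded so the
#' retained trajectory is approximately stationary; a warning is issued if
#' the model is not modulus-stable in that case, since the burn-in may
#' diverge.
#'
#' @param model a `var_model`.
#' @param T number of observations to return (>= 3).
#' @param y0 initial state: numeric vector or `"zero"`.
#' @param seed optional integer seed; identical seeds give identical output.
#' @param burn_in number of discarded leading steps, default 0.
#' @return numeric expression matrix, genes x T.
#' @examples
#' m <- var_model(diag(0.5, 2))
#' simulate_var(m, T = 4, y0 = c(1, 1))
#' @export
simulate_var <- function(model, T, y0 = "zero", seed = NULL, burn_in = 0) {
  stopifnot(inherits(model, "var_model"))
  if (T < 3L) stopf("T must be at least 3, got %d", T)
  n <- nrow(model$A)
  if (identical(y0, "zero")) y0 <- rep(0, n)
  if (length(y0) != n) stopf("y0 has length %d, expected %d", length(y0), n)
  if (burn_in > 0 && !is_stable(model$A, "modulus")$stable)
    warnf("model is not modulus-stable; burn-in trajectory may diverge")
  L <- NULL
  if (!is.null(model$noise_cov) && any(model$noise_cov != 0)) {
    e <- eigen(model$noise_cov, symmetric = TRUE)
    L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), n)
  }
  with_local_seed(seed, {
    # the trajectory starts at y0; with burn_in = 0 the first returned
    # column is y0 itself
    out <- matrix(0, n, T)
    y <- as.numeric(y0)
    for (t in seq_len(burn_in)) {
      u <- if (is.null(L)) 0 else as.numeric(L %*% rnorm(n))
      y <- model$intercept + as.numeric(model$A %*% y) + u
    }
    out[, 1] <- y
    for (t in seq_len(T - 1)) {
      u <- if (is.null(L)) 0 else as.numeric(L %*% rnorm(n))
      y <- model$intercept + as.numeric(model$A %*% y) + u
      out[, t + 1] <- y
    }
    rownames(out) <- rownames(model$A)
    if (is.null(rownames(out))) rownames(out) <- paste0("g", seq_len(n))
    colnames(out) <- paste0("t", seq_len(T))
    out
  })
}
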