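#' Deleted absolute row sums
#'
#' `R_i(A) = sum_{j != i} |a_ij|`, the radius of the i-th Gershgorin disc.
#'
#' @param A square numeric matrix.
#' @param i optional row index; when given, the scalar `R_i(A)` is
#'   returned, otherwise the full vector.
#' @return nonnegative numeric vector (or scalar).
#' @examples
#' deleted_row_sum(rbind(c(-2, 0), c(1, -1)))   # c(0, 1)
#' @export
deleted_row_sum <- function(A, i = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  r <- rowSums(abs(A)) - abs(diag(A))
  if (!is.null(i)) {
    if (i < 1 || i > nrow(A)) stopf("row index %d out of range 1..%d", i, nrow(A))
    return(r[[i]])
  }
  r
}

#' Average diagonal-dominance margin
#'
#' `beta = mean_i(|a_ii| - R_i(A))`, the average excess of the diagonal
#' magnitude over the deleted row sum. May be negative for matrices far
#' from diagonal dominance.
#'
#' @param A square numeric matrix.
#' @return a real scalar.
#' @examples
#' compute_beta(diag(c(-1, -3)))   # 2
#' @export
compute_beta <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  mean(abs(diag(A)) - deleted_row_sum(A))
}

#' Construct a Gershgorin weight object
#'
#' Container for the positive diagonal similarity-transform weights `v_i`
#' used by the stability constraint, together with the shape parameter
#' `delta` and the dominance margin `beta` of the matrix they were derived
#' from (`NA` for manually supplied weights).
#'
#' @param v strictly positive numeric vector.
#' @param delta real in (0, 1].
#' @param beta optional dominance margin used to derive `v`.
#' @return an object of class `gershgorin_weights`.
#' @export
gershgorin_weights <- function(v, delta = 0.5, beta = NA_real_) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
    stopf("weights v must all be strictly positive and finite")
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1)
    stopf("delta must lie in (0, 1]")
  structure(list(v = as.numeric(v), delta = delta, beta = beta),
            class = "gershgorin_weights")
}

#' @export
print.gershgorin_weights <- function(x, ...) {
  cat(sprintf("Gershgorin weights (delta = %g, beta = %g):\n", x$delta, x$beta))
  print(x$v)
  invisible(x)
}

#' Gershgorin weight schedule
#'
#' Computes the per-gene similarity weights from the current coefficient
#' matrix. With `m_i = |a_ii| - R_i(A)` and `beta` the mean of the `m_i`:
#' rows more diagonally dominant than average (`m_i > beta`) get
#' `v_i = 1 + (m_i - beta) / (delta + (m_i - beta))`, the rest get
#' `v_i = delta / (delta - (m_i - beta))`. Equality `m_i = beta` falls in
#' the second branch, where it gives `v_i = 1`, so the schedule is
#' continuous at the junction. All weights lie strictly in (0, 2):
#' dominant rows are inflated towards 2, weak rows deflated towards 0,
#' which loosens/tightens their discs in the weighted constraint.
#'
#' @param A square numeric matrix.
#' @param delta shape parameter in (0, 1]; default 0.5.
#' @return a [gershgorin_weights()] object.
#' @examples
#' compute_weights(rbind(c(-2, 0), c(1, -1)), delta = 0.5)  # v = (5/3, 1/3)
#' @export
compute_weights <- function(A, delta = 0.5) {
  if (!is.numeric(delta) || length(delta) != 1 || delta <= 0 || delta > 1)
    stopf("delta must lie in (0, 1]")
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  m <- abs(diag(A)) - deleted_row_sum(A)
  beta <- mean(m)
  d <- m - beta
  v <- ifelse(d > 0, 1 + d / (delta + d), delta / (delta - d))
  gershgorin_weights(v, delta = delta, beta = beta)
}

#' Weighted Gershgorin stability margins
#'
#' `g_i = a_ii + sum_{j != i} (v_j / v_i) |a_ij|`: the rightmost point of
#' the i-th disc of the similarity transform `V^{-1} A V`. When every
#' `g_i <= 0`, every eigenvalue of `A` has non-positive real part, which is
#' the convex stability certificate enforced by [infer_network()].
#'
#' @param A square numeric matrix.
#' @param weights a [gershgorin_weights()] object (default: unit weights),
#'   or a positive numeric vector.
#' @return numeric vector of margins, one per row.
#' @examples
#' stability_margins(rbind(c(-2, 0), c(1, -1)))  # c(-2, 0)
#' @export
stability_margins <- function(A, weights = NULL) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("A must be a square matrix")
  n <- nrow(A)
  if (is.null(weights)) weights <- gershgorin_weights(rep(1, n))
  if (is.numeric(weights)) weights <- gershgorin_weights(weights)
  v <- weights$v
  if (length(v) != n)
    stopf("weights have length %d but A is %d x %d", length(v), n, n)
  absA <- abs(A)
  diag(absA) <- 0
  diag(A) + as.numeric(absA %*% v) / v
}
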