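# shared fixtures and independent oracles, built in code at test time

# wrap raw Y/Z matrices as lagged data without going through alignment
lagged <- function(Y, Z) {
  structure(list(Y = Y, Z = Z), class = "lagged_data")
}

# random lagged regression data of a given size
random_lagged <- function(n, m, seed) {
  set.seed(seed)
  lagged(matrix(rnorm(n * m), n, m), matrix(rnorm(n * m), n, m))
}

# independent closed-form oracle for the N = 1 constrained fit:
# minimize 0.5 * sum((y - a z)^2) over |a| <= lam, a <= 0
clipped_ols_1d <- function(Y, Z, lam) {
  a_ols <- sum(Y * Z) / sum(Z * Z)
  min(max(a_ols, -lam), 0)
}

# independent brute-force oracle for the N = 2 constrained fit: dense
# grid search over the feasible set with successive refinement around the
# incumbent (valid because the objective is convex)
grid_search_n2 <- function(Y, Z, lam, v = c(1, 1), stages = 6, pts = 13) {
  G <- Z %*% t(Z)
  C <- Y %*% t(Z)
  c0 <- 0.5 * sum(Y^2)
  lo <- rep(-lam, 4)
  hi <- rep(lam, 4)
  best <- c(0, 0, 0, 0)
  best_obj <- c0
  for (s in seq_len(stages)) {
    gr <- expand.grid(a11 = seq(lo[1], hi[1], length.out = pts),
                      a12 = seq(lo[2], hi[2], length.out = pts),
                      a21 = seq(lo[3], hi[3], length.out = pts),
                      a22 = seq(lo[4], hi[4], length.out = pts))
    feas <- (abs(gr$a11) + abs(gr$a12) + abs(gr$a21) + abs(gr$a22) <=
               lam + 1e-12) &
      (gr$a11 + (v[2] / v[1]) * abs(gr$a12) <= 1e-12) &
      (gr$a22 + (v[1] / v[2]) * abs(gr$a21) <= 1e-12)
    obj <- c0 -
      (gr$a11 * C[1, 1] + gr$a12 * C[1, 2] +
         gr$a21 * C[2, 1] + gr$a22 * C[2, 2]) +
      0.5 * (G[1, 1] * gr$a11^2 + 2 * G[1, 2] * gr$a11 * gr$a12 +
               G[2, 2] * gr$a12^2 +
               G[1, 1] * gr$a21^2 + 2 * G[1, 2] * gr$a21 * gr$a22 +
               G[2, 2] * gr$a22^2)
    obj[!feas] <- Inf
    k <- which.min(obj)
    if (obj[k] < best_obj) {
      best_obj <- obj[k]
      best <- as.numeric(gr[k, ])
    }
    step <- (hi - lo) / (pts - 1)
    lo <- best - step
    hi <- best + step
  }
  list(A = rbind(best[1:2], best[3:4]), objective = best_obj)
}

# tiny signed networks from compact edge specs, e.g.
# net2(c("g1", "g2", "+")) over genes g1, g2
make_net <- function(genes, ...) {
  specs <- list(...)
  if (length(specs) == 0) return(signed_network(NULL, genes))
  e <- do.call(rbind, lapply(specs, function(s)
    data.frame(from = s[1], to = s[2],
               sign = if (s[3] == "+") 1L else -1L,
               stringsAsFactors = FALSE)))
  signed_network(e, genes)
}
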