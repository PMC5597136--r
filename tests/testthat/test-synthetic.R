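test_that("gershgorin-regime models are strictly feasible by construction", {
  for (seed in 1:15) {
    sim <- random_stable_sparse_model(6, density = 0.25, seed = seed)
    A <- sim$model$A
    # strictly negative unit-weight margins: the truth itself is strictly
    # feasible for the constrained program at any budget above its norm
    expect_true(all(stability_margins(A) < 0))
    expect_true(is_stable(A, "halfplane")$stable)
    expect_true(is_stable(A, "modulus")$stable)
  }
})

test_that("modulus-regime models satisfy the stationarity criterion", {
  for (seed in 1:10) {
    sim <- random_stable_sparse_model(5, density = 0.3, regime = "modulus",
                                      seed = seed)
    expect_true(is_stable(sim$model$A, "modulus")$stable)
  }
})

test_that("the ground-truth network is the sign pattern of the coefficients", {
  sim <- random_stable_sparse_model(5, density = 0.3, seed = 8)
  A <- sim$model$A
  S <- t(sign_matrix(sim$network))
  expect_equal(unname(S), unname(sign(A) * (A != 0)))
  # self-inhibition on every gene in the gershgorin regime
  expect_true(all(diag(A) < 0))
})

test_that("generation is deterministic under a fixed seed", {
  sim1 <- random_stable_sparse_model(4, density = 0.3, seed = 99)
  sim2 <- random_stable_sparse_model(4, density = 0.3, seed = 99)
  expect_identical(sim1$model$A, sim2$model$A)
  x1 <- generate_dataset(sim1$model, 20, noise_sd = 0.05, seed = 7)
  x2 <- generate_dataset(sim2$model, 20, noise_sd = 0.05, seed = 7)
  expect_identical(x1, x2)
  p1 <- generate_dataset(sim1$model, 15, kind = "perturbation",
                         noise_sd = 0.02, seed = 3)
  p2 <- generate_dataset(sim2$model, 15, kind = "perturbation",
                         noise_sd = 0.02, seed = 3)
  expect_identical(p1, p2)
})

test_that("noiseless data satisfies the generating recursion exactly", {
  sim <- random_stable_sparse_model(4, density = 0.3, seed = 13)
  A <- sim$model$A
  x <- generate_dataset(sim$model, 12, kind = "trajectory", noise_sd = 0,
                        seed = 1, burn_in = 0)
  expect_lt(max(abs(x[, 2:12] - A %*% x[, 1:11])), 1e-12)
})

test_that("perturbation responses respect graph reachability", {
  # impulses restricted to one gene: genes with no incoming path from it
  # must stay exactly zero in noiseless data
  A <- matrix(0, 4, 4)
  A[2, 1] <- 0.5           # g1 -> g2
  A[3, 2] <- 0.4           # g2 -> g3
  diag(A) <- -0.3          # self-loops only add paths to reached genes
  ids <- paste0("g", 1:4)
  dimnames(A) <- list(ids, ids)
  m <- var_model(A)
  x <- generate_dataset(m, 15, kind = "perturbation", noise_sd = 0,
                        seed = 5, perturb_genes = "g1")
  expect_true(all(x["g4", ] == 0))   # unreachable from g1
  expect_true(any(x["g3", ] != 0))   # reachable through g2
})

test_that("the recovery harness reports consistent seeded metrics", {
  r1 <- recovery_experiment(n_genes = 4, density = 0.25, T = 60,
                            replicates = 2, seed = 3)
  r2 <- recovery_experiment(n_genes = 4, density = 0.25, T = 60,
                            replicates = 2, seed = 3)
  expect_identical(r1$replicates, r2$replicates)
  expect_true(all(r1$replicates$support_sensitivity >= 0 &
                    r1$replicates$support_sensitivity <= 1))
  expect_true(all(r1$replicates$support_specificity >= 0 &
                    r1$replicates$support_specificity <= 1))
  expect_true(all(r1$replicates$coeff_rmse >= 0))
  # byte-identical serialization across runs at a fixed seed
  j1 <- jsonlite::toJSON(r1$replicates, digits = NA)
  j2 <- jsonlite::toJSON(r2$replicates, digits = NA)
  expect_identical(j1, j2)
})

test_that("estimation error shrinks with more noiseless perturbation data", {
  # impulses keep exciting the system even without noise, so the
  # least-squares coefficients converge to the truth as T grows
  sim <- random_stable_sparse_model(4, density = 0.25, seed = 31)
  err <- sapply(c(20, 320), function(T) {
    x <- generate_dataset(sim$model, T, kind = "perturbation",
                          noise_sd = 0, seed = 17)
    fit <- ols_estimate(build_lagged_matrices(x))
    sqrt(mean((unname(fit$A) - unname(sim$model$A))^2))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.1)
})
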