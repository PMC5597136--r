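test_that("a network scored against itself has no false calls", {
  net <- make_net(c("g1", "g2", "g3"),
                  c("g1", "g2", "+"), c("g2", "g3", "-"), c("g3", "g3", "-"))
  cc <- confusion(net, net)
  expect_equal(cc$tp, 3L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$tn, 9L - 3L)
})

test_that("an empty inference misses every reference edge", {
  truth <- make_net(c("a", "b", "c"), c("a", "b", "+"), c("b", "c", "-"))
  empty <- make_net(c("a", "b", "c"))
  cc <- confusion(empty, truth)
  expect_equal(cc$tp, 0L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 2L)
  expect_equal(cc$tn, 7L)
  expect_equal(cc$false_no_interactions, 2L)
})

test_that("sign mismatches are false positives, not false negatives", {
  # exhaustively checked by hand over the 4 ordered pairs of 2 genes
  truth <- make_net(c("g1", "g2"), c("g1", "g2", "+"))
  inferred <- make_net(c("g1", "g2"), c("g1", "g2", "-"), c("g2", "g2", "-"))
  cc <- confusion(inferred, truth)
  expect_equal(cc$tp, 0L)
  expect_equal(cc$fp, 2L)
  expect_equal(cc$tn, 2L)
  expect_equal(cc$fn, 0L)
  expect_equal(cc$false_inhibitions, 2L)
  expect_equal(cc$false_activations, 0L)
})

test_that("every ordered pair lands in exactly one confusion cell", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(2:6, 1)
    genes <- paste0("g", 1:n)
    rand_net <- function() {
      S <- matrix(sample(c(-1L, 0L, 1L), n * n, replace = TRUE,
                         prob = c(0.2, 0.6, 0.2)), n, n)
      idx <- which(S != 0, arr.ind = TRUE)
      signed_network(
        data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                   sign = S[idx], stringsAsFactors = FALSE), genes)
    }
    cc <- confusion(rand_net(), rand_net())
    expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, n^2)
    expect_equal(cc$false_activations + cc$false_inhibitions, cc$fp)
    expect_equal(cc$false_no_interactions, cc$fn)
  }
})

test_that("swapping inferred and truth mirrors FP and FN when signs agree", {
  # with a single shared sign there are no sign mismatches, so the roles
  # of spurious and missed edges are exactly exchanged
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:5, 1)
    genes <- paste0("g", 1:n)
    rand_pos <- function() {
      S <- matrix(sample(0:1, n * n, replace = TRUE), n, n)
      idx <- which(S != 0, arr.ind = TRUE)
      signed_network(
        data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]],
                   sign = 1L, stringsAsFactors = FALSE), genes)
    }
    a <- rand_pos()
    b <- rand_pos()
    ab <- confusion(a, b)
    ba <- confusion(b, a)
    expect_equal(ab$fp, ba$fn)
    expect_equal(ab$fn, ba$fp)
    expect_equal(ab$tp, ba$tp)
    expect_equal(ab$tn, ba$tn)
  }
})

test_that("mismatched gene sets are rejected with the difference listed", {
  a <- make_net(c("g1", "g2"), c("g1", "g2", "+"))
  b <- make_net(c("g1", "g3"), c("g1", "g3", "+"))
  expect_error(confusion(a, b), "g2")
  expect_error(confusion(a, b), "g3")
})

test_that("metrics match their ratio definitions and flag zero denominators", {
  m <- network_metrics(confusion_counts(39, 11, 5, 26))
  expect_equal(m$sensitivity, 0.60)
  expect_equal(m$specificity, 0.3125)
  expect_equal(m$precision, 0.78)

  m0 <- network_metrics(confusion_counts(0, 0, 12, 4))
  expect_equal(m0$sensitivity, 0)
  expect_true(is.na(m0$precision))
  expect_true("precision" %in% m0$undefined)

  # scale invariance of the ratios
  m1 <- network_metrics(confusion_counts(6, 2, 5, 3, n_genes = 4))
  m2 <- network_metrics(confusion_counts(24, 8, 20, 12, n_genes = 8))
  expect_equal(m1$sensitivity, m2$sensitivity)
  expect_equal(m1$specificity, m2$specificity)
  expect_equal(m1$precision, m2$precision)
})

test_that("summary rates count false identifications and inferred pairs", {
  cc <- confusion_counts(39, 11, 5, 26)
  r <- summary_rates(cc)
  expect_equal(r[["false_identification_pct"]], 100 * 37 / 81)
  expect_equal(r[["net_connectivity_pct"]], 100 * 50 / 81)

  genes <- paste0("g", 1:3)
  expect_equal(summary_rates(confusion(make_net(genes), make_net(genes))),
               c(false_identification_pct = 0, net_connectivity_pct = 0))
  full <- {
    idx <- expand.grid(from = genes, to = genes)
    signed_network(data.frame(from = idx$from, to = idx$to, sign = 1L),
                   genes)
  }
  expect_equal(summary_rates(confusion(full, full))[["net_connectivity_pct"]],
               100)
})

test_that("complex collapsing merges, deduplicates and drops internal edges", {
  genes <- c("a", "b", "c")
  net <- make_net(genes, c("a", "c", "+"), c("b", "c", "+"),
                  c("a", "b", "-"), c("b", "a", "+"))
  grouping <- c(a = "C1", b = "C1")
  out <- collapse_complexes(net, grouping)
  expect_setequal(out$genes, c("C1", "c"))
  expect_equal(nrow(out$edges), 1)
  expect_equal(out$edges$from, "C1")
  expect_equal(out$edges$to, "c")
  expect_equal(out$edges$sign, 1L)

  # identity grouping leaves the network unchanged
  same <- collapse_complexes(net, c(a = "a"))
  expect_equal(sign_matrix(same), sign_matrix(net))

  # conflicting signs resolved by the larger-magnitude contribution
  w <- signed_network(
    data.frame(from = c("a", "b"), to = c("c", "c"), sign = c(1L, -1L),
               weight = c(0.2, 0.9)), genes)
  out_w <- collapse_complexes(w, grouping)
  expect_equal(out_w$edges$sign, -1L)

  # conflicting signs without weights and an exact tie resolve to + with
  # a warning
  nw <- make_net(genes, c("a", "c", "+"), c("b", "c", "-"))
  expect_warning(out_t <- collapse_complexes(nw, grouping), "tie")
  expect_equal(out_t$edges$sign, 1L)

  expect_error(collapse_complexes(net, c(zz = "C1")), "unknown gene")
})
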