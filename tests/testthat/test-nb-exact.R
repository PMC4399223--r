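test_that("library-size equalization forces the geometric-mean depth", {
  m <- matrix(c(10, 30, 60, 40, 160, 200), nrow = 3)
  eq <- equalize_libsizes(m)
  expect_equal(eq$common_libsize, sqrt(100 * 400))
  expect_equal(eq$pseudo[, 1], m[, 1] * 2)
  expect_equal(eq$pseudo[, 2], m[, 2] * 0.5)
  expect_equal(colSums(eq$pseudo), c(200, 200))

  # equal depths: identity
  m2 <- matrix(c(1, 2, 3, 3, 2, 1), nrow = 3)
  expect_equal(equalize_libsizes(m2)$pseudo, m2)
  expect_error(equalize_libsizes(matrix(0, 2, 2)), "all-zero")
  # a zero column is tolerated and stays zero
  m3 <- cbind(m2, 0)
  expect_equal(equalize_libsizes(m3)$pseudo[, 3], c(0, 0, 0))
})

test_that("common dispersion is near zero for Poisson data", {
  set.seed(101)
  y <- matrix(rpois(1000 * 6, 100), ncol = 6)
  est <- common_dispersion(y, rep(c("T2", "T14"), each = 3))
  expect_lte(est$phi, 0.01)
  expect_error(common_dispersion(y[, 1:2], c("T2", "T14")),
               "not estimable")
})

test_that("optimizer argmax matches an exhaustive grid on a toy matrix", {
  set.seed(7)
  y <- matrix(rnbinom(20 * 6, mu = 80, size = 5), ncol = 6)
  groups <- rep(c("T2", "T14"), each = 3)
  est <- common_dispersion(y, groups)
  ll <- function(phi) {
    r <- 1 / phi
    sum(vapply(seq_len(nrow(y)), function(i)
      poolscreen:::cond_loglik_group(y[i, groups == "T2"], r) +
        poolscreen:::cond_loglik_group(y[i, groups == "T14"], r),
      numeric(1)))
  }
  coarse <- seq(1e-8, 20, length.out = 2000)
  g1 <- coarse[which.max(vapply(coarse, ll, numeric(1)))]
  fine <- seq(max(1e-8, g1 - 0.02), g1 + 0.02, length.out = 2000)
  g2 <- fine[which.max(vapply(fine, ll, numeric(1)))]
  expect_lt(abs(est$phi - g2), 1e-4)
})

test_that("exact test reproduces its closed-form examples", {
  # most likely split of S = 10 between single samples: p = 1
  r1 <- exact_test(matrix(c(5, 5), 1), c("T2", "T14"), phi = 0)
  expect_equal(r1$PValue, 1)
  # extreme split 0 vs 10: p = 2 * (1/2)^10
  r2 <- exact_test(matrix(c(0, 10), 1), c("T2", "T14"), phi = 0)
  expect_equal(r2$PValue, 2 / 1024)
  # arithmetic of the fold-change with prior 0
  r3 <- exact_test(matrix(c(50, 50, 200, 200), 1),
                   c("T2", "T2", "T14", "T14"), phi = 0.1, prior = 0)
  expect_equal(r3$logFC, 2)
  # S = 0 convention
  r4 <- exact_test(matrix(c(0, 0), 1), c("T2", "T14"), phi = 0.1)
  expect_equal(r4$PValue, 1)
  expect_equal(r4$logFC, 0)
  expect_error(exact_test(matrix(c(1, 1), 1), c("T2", "T14"), phi = -0.1),
               "non-negative")
  expect_error(exact_test(matrix(c(2e6, 1), 1), c("T2", "T14"), phi = 0.1),
               "enumeration cap")
})

test_that("exact test equals enumeration oracle on a spot-check grid", {
  for (phi in c(0, 0.1, 0.5)) for (n in c(1, 3)) {
    for (S in c(1, 7, 40)) {
      A <- 0:S
      p <- exact_test(pseudo_for_splits(A, S, n, n),
                      rep(c("T2", "T14"), c(n, n)), phi)$PValue
      ora <- vapply(A, oracle_exact_pvalue, numeric(1), S = S, n1 = n,
                    n2 = n, phi = phi)
      expect_equal(p, ora, tolerance = 1e-12)
    }
  }
  # unequal replicate numbers aggregate with group-level NB parameters
  p <- exact_test(pseudo_for_splits(0:20, 20, 2, 3),
                  rep(c("T2", "T14"), c(2, 3)), 0.2)$PValue
  ora <- vapply(0:20, oracle_exact_pvalue, numeric(1), S = 20, n1 = 2,
                n2 = 3, phi = 0.2)
  expect_equal(p, ora, tolerance = 1e-12)
})

test_that("at phi = 0 the conditional law is binomial", {
  for (S in c(5, 50, 200)) {
    lp <- poolscreen:::cond_null_logpmf(S, 1, 1, 0)
    expect_lt(sum(abs(exp(lp) - dbinom(0:S, S, 0.5))) / 2, 1e-12)
  }
})

test_that("swapping group labels negates logFC and keeps p-values", {
  set.seed(33)
  y <- matrix(rnbinom(50 * 6, mu = 60, size = 8), ncol = 6)
  gr <- rep(c("g1", "g2"), each = 3)
  a <- exact_test(y, gr, phi = 0.12)
  b <- exact_test(y, rev(gr), phi = 0.12)
  expect_equal(a$PValue, b$PValue)
  expect_equal(a$logFC, -b$logFC)
})

test_that("BH adjustment respects its step-up closed forms and ordering", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  p <- runif(200)
  q <- bh_fdr(p)
  expect_true(all(q >= p & q <= 1))
  expect_equal(order(q[order(p)]), seq_along(p))  # monotone in the inputs
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("dispersion and exact test agree with edgeR on equal-depth data", {
  skip_if_not_installed("edgeR")
  gr <- rep(c("T2", "T14"), each = 3)
  # dispersion recovery compared on overdispersed data
  set.seed(42)
  mu <- exp(rnorm(300, log(100), 0.5))
  ynb <- matrix(rnbinom(300 * 6, mu = rep(mu, 6), size = 1 / 0.15), ncol = 6)
  dnb <- edgeR::estimateCommonDisp(
    edgeR::DGEList(counts = ynb, group = factor(gr, levels = c("T2", "T14"))))
  mine <- common_dispersion(equalize_libsizes(ynb)$pseudo, gr)
  expect_equal(mine$phi, dnb$common.dispersion, tolerance = 0.005)
  # p-values compared on exactly equal depths, where the two depth
  # adjustments coincide
  w <- exp(rnorm(200, 0, 0.5))
  y <- sapply(1:6, function(i) rmultinom(1, 30000, w / sum(w)))
  d <- edgeR::DGEList(counts = y, group = factor(gr, levels = c("T2", "T14")))
  et <- edgeR::exactTest(d, dispersion = 0.1, rejection.region = "smallp")
  pm <- exact_test(equalize_libsizes(y)$pseudo, gr, 0.1)
  expect_equal(pm$PValue, et$table$PValue, tolerance = 1e-3)
  expect_equal(pm$logFC, et$table$logFC, tolerance = 0.05)
})

test_that("per-pool screen wrapper returns a coherent result table", {
  lib <- make_library(n_pools = 2, n = 30)
  sam <- make_samples(n_pools = 2, reps = 3)
  tr <- simulate_truth(lib, sam,
                       sim_config(hit_fraction = 0.1, mean_libsize = 3e4),
                       seed = 17)
  cm <- simulate_counts(tr, sam, seed = 18)
  res <- screen_exact_test(cm)
  expect_equal(nrow(res), nrow(lib))
  expect_true(all(res$FDR >= res$PValue))
  expect_true(all(res$PValue > 0 & res$PValue <= 1))
  expect_true(all(is.finite(res$logFC[rowSums(cm$counts) > 0])))
  expect_named(attr(res, "dispersion"), c("pool1", "pool2"))
  glob <- screen_exact_test(cm, fdr_scope = "global")
  expect_equal(glob$PValue, res$PValue)
  expect_equal(glob$FDR, bh_fdr(glob$PValue))
})
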