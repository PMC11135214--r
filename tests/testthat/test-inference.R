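test_that("pseudocount and CLR behave as exact arithmetic", {
  expect_equal(pseudocount(matrix(c(0, 2, 1, 0), 2), 1),
               matrix(c(1, 3, 2, 1), 2))
  expect_error(pseudocount(matrix(1, 1, 1), 0), "positive")

  expect_equal(clr(matrix(c(5, 5, 5), 1)), matrix(0, 1, 3))
  expect_equal(clr(matrix(c(1, 2, 4), 1)),
               matrix(c(-log(2), 0, log(2)), 1))
  x <- matrix(runif(12, 1, 9), 3, 4)
  expect_equal(clr(7.3 * x), clr(x))
  expect_true(all(abs(rowSums(clr(x))) < 1e-10))
  expect_error(clr(matrix(c(1, 0), 1)), "positive")
})

test_that("log-covariance method equals the empirical covariance of logs", {
  pc <- paired_counts(matrix(5L, 3, 2), matrix(7L, 3, 2))
  est <- log_covariance_method(pc)
  expect_true(all(est$matrix == 0)) # identical samples: no variance

  # hand-checkable 3-sample, 1-taxon-per-kingdom toy
  a <- matrix(c(1L, 3L, 7L), 3, 1)
  b <- matrix(c(2L, 2L, 4L), 3, 1)
  est2 <- log_covariance_method(paired_counts(a, b))
  la <- log(c(2, 4, 8))
  lb <- log(c(3, 3, 5))
  hand_cov <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / 2
  expect_equal(est2$matrix[1, 1], hand_cov(la, la))
  expect_equal(est2$matrix[1, 2], hand_cov(la, lb))
  expect_equal(est2$matrix, t(est2$matrix))
})

test_that("mixed and split CLR covariances match hand computation", {
  a <- matrix(c(1L, 4L, 2L, 9L, 0L, 3L), 3, 2)
  b <- matrix(c(5L, 1L, 2L, 0L, 7L, 4L), 3, 2)
  pc <- paired_counts(a, b)

  hand_clr <- function(m) {
    lg <- log(m + 1)
    lg - rowMeans(lg)
  }
  mixed <- clr_mixed_method(pc)
  expect_equal(mixed$matrix, cov(hand_clr(cbind(a, b))), ignore_attr = TRUE)
  expect_true(all(abs(rowSums(mixed$matrix)) < 1e-8)) # CLR null space

  split <- clr_split_method(pc)
  expect_equal(split$matrix, cov(cbind(hand_clr(a), hand_clr(b))),
               ignore_attr = TRUE)
  # per-block null space
  expect_true(all(abs(rowSums(split$matrix[, 1:2])) < 1e-8))
  expect_true(all(abs(rowSums(split$matrix[, 3:4])) < 1e-8))
})

test_that("split CLR is invariant to per-sample kingdom rescaling", {
  sim <- small_sim(n_taxa = 12, n_samples = 15, seed = 21)
  # strictly positive relative abundances (pseudocount once, up front)
  rel_a <- (sim$paired$counts_a + 1) / rowSums(sim$paired$counts_a + 1)
  rel_b <- (sim$paired$counts_b + 1) / rowSums(sim$paired$counts_b + 1)
  pc1 <- paired_counts(rel_a, rel_b)
  q <- exp(rnorm(15))
  pc2 <- paired_counts(rel_a, rel_b * q)
  e1 <- clr_split_method(pc1, pseudocount_value = 0)
  e2 <- clr_split_method(pc2, pseudocount_value = 0)
  expect_equal(e1$matrix, e2$matrix, tolerance = 1e-12)
  m1 <- clr_mixed_method(pc1, pseudocount_value = 0)
  m2 <- clr_mixed_method(pc2, pseudocount_value = 0)
  expect_gt(norm(m1$matrix - m2$matrix, "F"), 1e-3)
})

test_that("log-ratio variance is the same for absolute and relative data", {
  sim <- small_sim(n_taxa = 10, n_samples = 25, seed = 31)
  sf <- true_scale_factors(sim$abund, sim$model$kingdom)
  ia <- which(sim$model$kingdom == "A")
  a1 <- ia[1]
  a2 <- ia[2]
  vals <- sim$abund$values
  x1 <- vals[, a1] / sf$q
  x2 <- vals[, a2] / sf$q
  v_abs <- var(log(vals[, a1] / vals[, a2]))
  v_rel <- var(log(x1 / x2))
  expect_equal(v_abs, v_rel, tolerance = 1e-12)
})

test_that("cross-kingdom error decomposition is an exact identity", {
  sim <- small_sim(n_taxa = 14, n_samples = 30, seed = 41)
  ia <- which(sim$model$kingdom == "A")[1]
  ib <- which(sim$model$kingdom == "B")[1]
  dec <- error_decomposition(sim$abund, sim$model$kingdom, ia, ib)
  rhs <- dec$var_ratio_term + dec$var_scale_term + dec$covar_cross_term
  expect_lt(abs(dec$var_lhs - rhs) / abs(dec$var_lhs), 1e-10)

  # constant q/r: the paired-data error terms vanish
  set.seed(42)
  vals <- matrix(exp(rnorm(40)), 10, 4)
  q <- vals[, 1] + vals[, 2]
  vals[, 3] <- q * 0.7 # r = 2 q, so q/r = 0.5 in every sample
  vals[, 4] <- q * 1.3
  ab <- manual_abundances(vals)
  king <- c("A", "A", "B", "B")
  sf <- true_scale_factors(ab, king)
  expect_equal(var(log(sf$q / sf$r)), 0, tolerance = 1e-14)
  dec2 <- error_decomposition(ab, king, 1, 3)
  expect_equal(dec2$var_scale_term, 0, tolerance = 1e-12)
  expect_equal(dec2$covar_cross_term, 0, tolerance = 1e-12)
})

test_that("the full method battery returns consistent, reproducible estimates", {
  sim <- small_sim(n_taxa = 16, n_samples = 20, seed = 51)
  ests <- run_all_methods(sim$paired, seed = 7)
  expect_named(ests, c("log_covariance", "clr_mixed", "clr_split", "sparcc",
                       "glasso_mixed", "glasso_split"))
  for (e in ests) {
    expect_s3_class(e, "covariance_estimate")
    expect_equal(dim(e$matrix), c(16, 16))
    expect_equal(e$matrix, t(e$matrix))
  }
  with_oracle <- run_all_methods(sim$paired, seed = 7,
                                 abundances = sim$abund,
                                 kingdom = sim$model$kingdom)
  expect_length(with_oracle, 7)
  again <- run_all_methods(sim$paired, seed = 7)
  expect_identical(lapply(ests, `[[`, "matrix"),
                   lapply(again, `[[`, "matrix"))
})
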