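test_that("welch_t matches hand computation and is antisymmetric", {
  # equal-variance case where Welch equals the pooled Student statistic:
  # diff = -3, se = sqrt(1/3 + 1/3)
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)

  expect_equal(welch_t(c(2, 4, 9), c(2, 4, 9))$statistic, 0)

  a <- c(0.3, 1.9, 2.2, 5); b <- c(1.1, 0.2, 0.4)
  fwd <- welch_t(a, b); rev <- welch_t(b, a)
  expect_equal(fwd$statistic, -rev$statistic)
  expect_equal(fwd$p, rev$p)

  # cross-check statistic, df and p against stats::t.test
  tt <- t.test(a, b, var.equal = FALSE)
  expect_equal(fwd$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(fwd$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(fwd$p, tt$p.value, tolerance = 1e-12)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
})

test_that("permutation p-value equals exhaustive enumeration on n = 6", {
  set.seed(5)
  vals <- c(rnorm(3, 2), rnorm(3))
  labels <- rep(c(TRUE, FALSE), each = 3)
  res <- permutation_p(vals, labels)
  expect_true(res$exhaustive) # C(6,3) = 20 <= 20000
  expect_equal(res$p, brute_force_perm_p(vals, labels))
})

test_that("permutation p-value is 1 for constant values and seeded draws are
          deterministic", {
  expect_equal(permutation_p(rep(3, 8), rep(c(TRUE, FALSE), 4))$p, 1)
  vals <- rnorm(24); labels <- rep(c(TRUE, FALSE), each = 12)
  p1 <- permutation_p(vals, labels, n_perm = 200, seed = 9)
  p2 <- permutation_p(vals, labels, n_perm = 200, seed = 9)
  expect_false(p1$exhaustive) # C(24,12) > 20000
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0) # add-one correction
  expect_error(permutation_p(1:4, rep(TRUE, 4)), "both groups")
})

test_that("BH q-values match the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.07), 0.07)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  # independent step-up oracle on random p-values
  set.seed(11)
  p <- runif(50)
  o <- order(p); m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(q_sorted, 1)
  expect_equal(bh_fdr(p), oracle)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  res <- pearson_cor(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  # p via the t-transform with n - 2 df
  t_stat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-t_stat, 2), tolerance = 1e-12)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 2:1), "at least 3")
})

test_that("Kaplan-Meier estimate equals the hand product-limit", {
  k <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(k$surv, c(2 / 3, 1 / 3, 0))
  # all censored: survival stays at 1
  k2 <- km_estimate(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(k2$surv == 1))
  # one censored at t=2: S(1) = 2/3, then the last subject dies at t=3,
  # S(3) = 2/3 * (1 - 1/1) = 0
  k3 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(k3$surv[k3$time == 1], 2 / 3)
  expect_equal(k3$surv[k3$time == 3], 0)
  expect_error(km_estimate(numeric(), numeric()), "empty")
  expect_error(km_estimate(c(0, 1), c(1, 1)), "positive")
})

test_that("KM with no censoring equals one minus the empirical CDF", {
  set.seed(3)
  tm <- rexp(40) + 0.1
  k <- km_estimate(tm, rep(1, 40))
  expect_equal(k$surv, 1 - ecdf(tm)(k$time))
})

test_that("log-rank statistic matches a hand-built O/E table", {
  # group A events at 1,2,3; group B events at 10,11,12
  ta <- c(1, 2, 3); tb <- c(10, 11, 12)
  res <- logrank_test(ta, rep(1, 3), tb, rep(1, 3))
  # hand computation: at each event time, E_A = n_A/n, V = n_A n_B / n^2
  nA <- c(3, 2, 1, 0, 0, 0); nB <- c(3, 3, 3, 3, 2, 1)
  obs_a <- 3
  exp_a <- sum(nA / (nA + nB))
  v <- sum(nA * nB / (nA + nB)^2)
  expect_equal(res$statistic, (obs_a - exp_a)^2 / v, tolerance = 1e-12)
  expect_equal(res$statistic, 5.051661, tolerance = 1e-6)
  expect_equal(res$p, pchisq(5.051661, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(res$direction, 1) # early deaths: group A worse

  # symmetry and degenerate cases
  swapped <- logrank_test(tb, rep(1, 3), ta, rep(1, 3))
  expect_equal(swapped$statistic, res$statistic)
  expect_equal(swapped$p, res$p)
  same <- logrank_test(ta, rep(1, 3), ta, rep(1, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  none <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0))
  expect_equal(none$statistic, 0)
  expect_equal(none$p, 1)
})

test_that("log-rank p is uniform for equal exponential groups", {
  set.seed(21)
  p <- replicate(200, {
    lr <- logrank_test(rexp(15), rbinom(15, 1, 0.8),
                       rexp(15), rbinom(15, 1, 0.8))
    lr$p
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("average-linkage correlation clustering behaves as UPGMA", {
  # duplicated samples merge at height 0
  x <- rbind(s1 = c(1, 5, 2, 8), s2 = c(1, 5, 2, 8), s3 = c(9, 0, 3, 1))
  h <- hclust_avg_pearson(x)
  expect_equal(min(h$height), 0)

  # two well-separated blocks are recovered exactly by the k = 2 cut
  set.seed(8)
  base1 <- rnorm(30); base2 <- -base1
  blocks <- rbind(a1 = base1 + rnorm(30, sd = 0.1),
                  a2 = base1 + rnorm(30, sd = 0.1),
                  b1 = base2 + rnorm(30, sd = 0.1),
                  b2 = base2 + rnorm(30, sd = 0.1))
  cl <- cut_k(hclust_avg_pearson(blocks), 2)
  expect_equal(cl[["a1"]], cl[["a2"]])
  expect_equal(cl[["b1"]], cl[["b2"]])
  expect_true(cl[["a1"]] != cl[["b1"]])

  # merge heights are non-decreasing on random data
  for (i in 1:5) {
    set.seed(i)
    r <- matrix(rnorm(8 * 20), 8, dimnames = list(paste0("s", 1:8), NULL))
    expect_true(!is.unsorted(hclust_avg_pearson(r)$height))
  }

  flat <- rbind(s1 = rep(2, 4), s2 = c(1, 2, 3, 4))
  expect_error(hclust_avg_pearson(flat), "zero-variance.*s1")
})
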