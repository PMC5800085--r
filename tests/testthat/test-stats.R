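test_that("weighted mean pools counts and is invariant to replicate splitting", {
  expect_equal(weighted_mean(c(5, 30), c(10, 30)), 0.875)
  expect_equal(weighted_mean(10, 20), 0.5)
  set.seed(1)
  for (i in 1:20) {
    cov <- rpois(4, 30) + 1
    meth <- rbinom(4, cov, 0.3)
    # split the first replicate's reads across two rows; the pooled
    # fraction must not move
    h <- meth[1] %/% 2
    c1 <- h + (cov[1] - meth[1]) %/% 2
    split_m <- c(h, meth[1] - h, meth[-1])
    split_c <- c(c1, cov[1] - c1, cov[-1])
    expect_equal(weighted_mean(split_m, split_c),
                 weighted_mean(meth, cov))
  }
  expect_error(weighted_mean(0, 0), "ZeroCoverage")
  expect_error(weighted_mean(5, 3), "exceed")
})

test_that("weighted variance matches its definition and the unit-coverage special case", {
  expect_equal(weighted_variance(c(0, 10), c(10, 10)), 5 / 19)
  expect_equal(weighted_variance(c(3, 6, 9), c(10, 20, 30)), 0)
  set.seed(2)
  for (i in 1:50) {
    r <- sample(2:6, 1)
    meth <- rbinom(r, 1, 0.5)
    expect_equal(weighted_variance(meth, rep(1, r)), stats::var(meth))
  }
  # coverage scaling: multiplying all coverages by k leaves the mean
  # unchanged and rescales the variance denominator coherently
  meth <- c(2, 5, 9); cov <- c(10, 10, 20)
  expect_equal(weighted_mean(meth * 3, cov * 3),
               weighted_mean(meth, cov))
  expect_error(weighted_variance(5, 10), "InsufficientReplicates")
})

test_that("weighted Welch test is antisymmetric and reduces to Welch at unit coverage", {
  id <- weighted_welch_test(c(3, 4), c(10, 10), c(3, 4), c(10, 10))
  expect_equal(unname(id$statistic), 0)
  expect_equal(id$p.value, 1)
  set.seed(3)
  for (i in 1:30) {
    ra <- sample(2:4, 1); rb <- sample(2:4, 1)
    ca <- rpois(ra, 25) + 2; cb <- rpois(rb, 25) + 2
    ma <- rbinom(ra, ca, 0.3); mb <- rbinom(rb, cb, 0.6)
    fwd <- weighted_welch_test(ma, ca, mb, cb)
    rev <- weighted_welch_test(mb, cb, ma, ca)
    expect_equal(unname(fwd$statistic), -unname(rev$statistic))
    expect_equal(fwd$p.value, rev$p.value)
    # unit coverages: identical to the classical Welch t-test on the
    # replicate fractions (here 0/1 outcomes; keep both groups non-flat)
    ua <- c(0, 1, rbinom(ra - 2 + 2, 1, 0.5))[seq_len(max(ra, 3))]
    ub <- c(0, 1, rbinom(rb - 2 + 2, 1, 0.5))[seq_len(max(rb, 3))]
    wt <- weighted_welch_test(ua, rep(1, length(ua)),
                              ub, rep(1, length(ub)))
    ref <- stats::t.test(ub, ua, var.equal = FALSE)
    expect_lt(abs(wt$p.value - ref$p.value), 1e-10)
    expect_lt(abs(unname(wt$statistic) - unname(ref$statistic)), 1e-10)
  }
})

test_that("degenerate zero-variance Welch inputs follow the stated convention", {
  expect_warning(eq <- weighted_welch_test(c(5, 5), c(10, 10),
                                           c(5, 5), c(10, 10)),
                 "DegenerateVariance")
  expect_equal(eq$p.value, 1)
  expect_warning(ne <- weighted_welch_test(c(0, 0), c(10, 10),
                                           c(10, 10), c(10, 10)),
                 "DegenerateVariance")
  expect_equal(ne$p.value, 0)
})

test_that("Fisher's exact test matches enumeration and fisher.test on random tables", {
  expect_equal(fisher_exact_test(3, 1, 1, 3)$p.value, 34 / 70)
  expect_equal(fisher_exact_test(0, 7, 0, 9)$p.value, 1)
  expect_error(fisher_exact_test(0, 0, 0, 0), "EmptyTable")
  set.seed(4)
  for (i in 1:100) {
    cnt <- rpois(4, 6)
    if (sum(cnt) == 0) next
    mine <- fisher_exact_test(cnt[1], cnt[2], cnt[3], cnt[4])$p.value
    expect_equal(mine, enum_fisher_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(cnt, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-12)
    # group swap leaves p unchanged
    expect_equal(mine,
                 fisher_exact_test(cnt[3], cnt[4], cnt[1], cnt[2])$p.value)
  }
})

test_that("site_p_value dispatches on replicate counts", {
  expect_equal(site_p_value(5, 20, c(15, 16, 14), c(20, 20, 20))$test,
               "fisher_exact")
  expect_equal(site_p_value(c(5, 6, 4), c(20, 20, 20),
                            c(15, 16, 14), c(20, 20, 20))$test,
               "weighted_welch")
  # single-vs-single equals the Fisher operation directly
  expect_equal(site_p_value(5, 20, 15, 20)$p.value,
               fisher_exact_test(5, 15, 15, 5)$p.value)
})

test_that("BH adjustment matches a step-up reference and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, ref_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "InvalidP")
  expect_error(bh_adjust(numeric(0)), "InvalidP")
})

test_that("Welch p-values are approximately uniform under the null", {
  set.seed(6)
  n <- 12000
  cov_a <- matrix(rpois(n * 3, 30), n, 3)
  cov_b <- matrix(rpois(n * 3, 30), n, 3)
  theta <- rbeta(n, 5, 5)
  meth_a <- matrix(rbinom(n * 3, cov_a, theta), n, 3)
  meth_b <- matrix(rbinom(n * 3, cov_b, theta), n, 3)
  st <- wwedmr:::welch_site_stats(meth_a, cov_a, meth_b, cov_b)
  rate <- mean(st$p <= 0.05, na.rm = TRUE)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(rate - 0.05), 3 * se + 0.01)
})
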