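#' Coverage-weighted mean methylation
#'
#' The group-level methylation fraction where each replicate contributes in
#' proportion to its read coverage: \eqn{\bar m = \sum_r {}_m C_r / \sum_r
#' C_r}, with \eqn{{}_m C_r} the methylated read count and \eqn{C_r} the
#' coverage of replicate \eqn{r}.  Algebraically this equals the pooled
#' methylation fraction, so it is invariant under splitting or merging
#' replicate rows at fixed total counts.
#'
#' @param meth Integer vector of methylated read counts, one per replicate.
#' @param coverage Integer vector of total read counts, same length.
#' @return The weighted mean methylation fraction in \[0, 1\].
#' @examples
#' weighted_mean(c(5, 30), c(10, 30))  # 35/40
#' @seealso [weighted_variance()], [weighted_welch_test()]
#' @export
weighted_mean <- function(meth, coverage) {
  check_counts(meth, coverage)
  tot <- sum(coverage)
  if (tot <= 0) stop("ZeroCoverage: total coverage must be positive")
  sum(meth) / tot
}

#' Coverage-weighted methylation variance
#'
#' The between-replicate variance of methylation fractions with each
#' replicate's squared deviation from the weighted mean weighted by its
#' coverage: \eqn{s^2 = \sum_r C_r (\bar m - m_r)^2 / (\sum_r C_r - 1)},
#' where \eqn{m_r = {}_m C_r / C_r}.  With unit coverages this reduces to
#' the ordinary unbiased sample variance of the replicate fractions.
#'
#' @inheritParams weighted_mean
#' @return The weighted variance (non-negative scalar).
#' @examples
#' weighted_variance(c(0, 10), c(10, 10))  # 5/19
#' @export
weighted_variance <- function(meth, coverage) {
  check_counts(meth, coverage)
  if (length(meth) < 2)
    stop("InsufficientReplicates: variance needs at least 2 replicates")
  tot <- sum(coverage)
  if (tot <= 1) stop("ZeroCoverage: total coverage must exceed 1")
  m_bar <- sum(meth) / tot
  frac <- ifelse(coverage > 0, meth / coverage, 0)
  dev2 <- (m_bar - frac)^2
  sum(coverage * dev2) / (tot - 1)
}

#' Coverage-weighted Welch t-test between two replicate groups
#'
#' Welch's two-sample t-test on methylation fractions in which both the
#' group means and variances are coverage-weighted ([weighted_mean()],
#' [weighted_variance()]).  The statistic is
#' \deqn{t = (\bar m_B - \bar m_A) / \sqrt{s_A^2/R_A + s_B^2/R_B}}
#' with \eqn{R_A}, \eqn{R_B} the replicate counts, and the two-tailed
#' p-value uses Welch-Satterthwaite degrees of freedom.  When both
#' weighted variances are zero the p-value is 1 if the means are equal and
#' 0 otherwise (with a warning); this keeps degenerate sites usable by the
#' region caller instead of propagating NaN.
#'
#' @param meth_a,coverage_a Methylated counts and coverages for group A
#'   replicates (length \eqn{R_A \ge 2}).
#' @param meth_b,coverage_b Same for group B (\eqn{R_B \ge 2}).
#' @return An object of class `"htest"` with the t statistic, effective
#'   degrees of freedom (`parameter`), two-tailed `p.value`, and the group
#'   weighted means as `estimate`.
#' @examples
#' weighted_welch_test(c(1, 2, 1), c(10, 12, 9), c(8, 9, 10), c(10, 11, 12))
#' @export
weighted_welch_test <- function(meth_a, coverage_a, meth_b, coverage_b) {
  check_counts(meth_a, coverage_a)
  check_counts(meth_b, coverage_b)
  if (length(meth_a) < 2 || length(meth_b) < 2)
    stop("InsufficientReplicates: Welch's test needs >= 2 replicates per group; ",
         "use fisher_exact_test() / site_p_value() for single-replicate designs")
  r_a <- length(meth_a)
  r_b <- length(meth_b)
  m_a <- weighted_mean(meth_a, coverage_a)
  m_b <- weighted_mean(meth_b, coverage_b)
  v_a <- weighted_variance(meth_a, coverage_a)
  v_b <- weighted_variance(meth_b, coverage_b)
  se2 <- v_a / r_a + v_b / r_b
  if (se2 <= 0) {
    warning("DegenerateVariance: both weighted variances are zero; ",
            "p set by convention")
    stat <- if (m_b == m_a) 0 else sign(m_b - m_a) * Inf
    p <- if (m_b == m_a) 1 else 0
    df <- NA_real_
  } else {
    stat <- (m_b - m_a) / sqrt(se2)
    df <- se2^2 / ((v_a / r_a)^2 / (r_a - 1) + (v_b / r_b)^2 / (r_b - 1))
    p <- 2 * stats::pt(-abs(stat), df)
  }
  structure(list(
    statistic = c(t = stat),
    parameter = c(df = df),
    p.value = p,
    estimate = c(weighted.mean.A = m_a, weighted.mean.B = m_b),
    method = "Coverage-weighted Welch two-sample t-test",
    data.name = sprintf("group A (%d replicates) vs group B (%d replicates)",
                        r_a, r_b),
    test = "weighted_welch"
  ), class = "htest")
}

#' Two-tailed Fisher's exact test on pooled methylation counts
#'
#' Exact test of association in the 2x2 table (methylated/unmethylated) x
#' (group A/group B).  The two-tailed p-value sums hypergeometric point
#' probabilities of all tables, at the observed margins, whose probability
#' does not exceed that of the observed table (ties compared with the
#' conventional 1 + 1e-7 relative tolerance, as in [stats::fisher.test()]).
#' This is the fallback used when one of the groups has a single replicate,
#' where a t-test is impossible.
#'
#' @param meth_a,unmeth_a Methylated and unmethylated read counts in group A.
#' @param meth_b,unmeth_b Same for group B.
#' @return An object of class `"htest"` with the two-tailed `p.value`.
#' @examples
#' fisher_exact_test(3, 1, 1, 3)  # p = 34/70
#' @export
fisher_exact_test <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  cnt <- c(meth_a, unmeth_a, meth_b, unmeth_b)
  if (length(cnt) != 4 || any(!is.finite(cnt)) || any(cnt < 0) ||
      any(cnt != round(cnt)))
    stop("counts must be four non-negative integers")
  if (sum(cnt) == 0) stop("EmptyTable: all counts are zero")
  p <- fisher_p(meth_a, unmeth_a, meth_b, unmeth_b)
  structure(list(
    statistic = NULL,
    parameter = NULL,
    p.value = p,
    estimate = c(fraction.A = if ((meth_a + unmeth_a) > 0)
                   meth_a / (meth_a + unmeth_a) else NA_real_,
                 fraction.B = if ((meth_b + unmeth_b) > 0)
                   meth_b / (meth_b + unmeth_b) else NA_real_),
    method = "Fisher's exact test (two-tailed) on pooled methylation counts",
    data.name = sprintf("2x2 table [[%d,%d],[%d,%d]]",
                        meth_a, unmeth_a, meth_b, unmeth_b),
    test = "fisher_exact"
  ), class = "htest")
}

# Vectorised two-tailed Fisher p over parallel count vectors.
# meth_*/unmeth_* are equal-length vectors; returns p in [0,1], NA where
# the table is empty.
fisher_p <- function(meth_a, unmeth_a, meth_b, unmeth_b) {
  n <- length(meth_a)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ma <- meth_a[i]; ua <- unmeth_a[i]; mb <- meth_b[i]; ub <- unmeth_b[i]
    tot <- ma + ua + mb + ub
    if (!is.finite(tot) || tot == 0) next
    k <- ma + mb            # methylated margin
    n1 <- ma + ua           # group A margin
    n2 <- mb + ub
    sup <- max(0L, k - n2):min(k, n1)
    pr <- stats::dhyper(sup, n1, n2, k)
    p_obs <- pr[match(ma, sup)]
    out[i] <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }
  out
}

#' Per-site p-value with automatic test dispatch
#'
#' Computes the two-tailed p-value comparing methylation between two
#' replicate groups at a single site.  With at least two replicates in
#' both groups this is the coverage-weighted Welch t-test; if either group
#' has a single replicate, a t-test is impossible and Fisher's exact test
#' is applied to the pooled per-group counts.
#'
#' @param meth_a,coverage_a Counts for group A replicates (length >= 1).
#' @param meth_b,coverage_b Counts for group B replicates (length >= 1).
#' @return An `"htest"` object from [weighted_welch_test()] or
#'   [fisher_exact_test()]; the element `$test` is `"weighted_welch"` or
#'   `"fisher_exact"` accordingly.
#' @examples
#' site_p_value(5, 20, c(15, 18), c(20, 20))$test        # fisher_exact
#' site_p_value(c(5, 6), c(20, 20), c(15, 18), c(20, 20))$test
#' @export
site_p_value <- function(meth_a, coverage_a, meth_b, coverage_b) {
  check_counts(meth_a, coverage_a)
  check_counts(meth_b, coverage_b)
  if (length(meth_a) < 1 || length(meth_b) < 1)
    stop("InsufficientReplicates: each group needs at least one replicate")
  if (min(length(meth_a), length(meth_b)) == 1) {
    fisher_exact_test(sum(meth_a), sum(coverage_a) - sum(meth_a),
                      sum(meth_b), sum(coverage_b) - sum(meth_b))
  } else {
    weighted_welch_test(meth_a, coverage_a, meth_b, coverage_b)
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment applied to the family of region
#' p-values from one calling run: \eqn{q_{(i)} = \min_{j \ge i}
#' \min(1, p_{(j)} m / j)} in sorted order, mapped back to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order; `q >= p` elementwise.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("InvalidP: empty p-value vector")
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("InvalidP: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# shared count validation
check_counts <- function(meth, coverage) {
  if (length(meth) != length(coverage))
    stop("meth and coverage must have equal length")
  if (any(!is.finite(meth)) || any(!is.finite(coverage)))
    stop("counts must be finite")
  if (any(meth < 0) || any(coverage < 0))
    stop("counts must be non-negative")
  if (any(meth > coverage))
    stop("meth_count must not exceed coverage")
  invisible(TRUE)
}

# Vectorised site-level Welch machinery used by the caller: operates on
# count matrices (sites x replicates).  Returns weighted means, diff and
# two-tailed p per site.  Degenerate sites follow the same conventions as
# weighted_welch_test(); sites with zero total coverage in a group get NA.
welch_site_stats <- function(meth_a, cov_a, meth_b, cov_b) {
  r_a <- ncol(meth_a)
  r_b <- ncol(meth_b)
  tot_a <- rowSums(cov_a)
  tot_b <- rowSums(cov_b)
  m_a <- ifelse(tot_a > 0, rowSums(meth_a) / tot_a, NA_real_)
  m_b <- ifelse(tot_b > 0, rowSums(meth_b) / tot_b, NA_real_)
  fr_a <- ifelse(cov_a > 0, meth_a / cov_a, 0)
  fr_b <- ifelse(cov_b > 0, meth_b / cov_b, 0)
  v_a <- rowSums(cov_a * (m_a - fr_a)^2) / (tot_a - 1)
  v_b <- rowSums(cov_b * (m_b - fr_b)^2) / (tot_b - 1)
  v_a[tot_a <= 1] <- NA_real_
  v_b[tot_b <= 1] <- NA_real_
  se2 <- v_a / r_a + v_b / r_b
  diff <- m_b - m_a
  p <- rep(NA_real_, length(diff))
  ok <- is.finite(se2) & se2 > 0 & is.finite(diff)
  df <- (se2[ok])^2 /
    ((v_a[ok] / r_a)^2 / (r_a - 1) + (v_b[ok] / r_b)^2 / (r_b - 1))
  p[ok] <- 2 * stats::pt(-abs(diff[ok] / sqrt(se2[ok])), df)
  degen <- is.finite(se2) & se2 <= 0 & is.finite(diff)
  p[degen] <- ifelse(diff[degen] == 0, 1, 0)
  list(mean_a = m_a, mean_b = m_b, diff = diff, p = p)
}

# Vectorised site stats for the Fisher fallback path (min replicates == 1):
# counts are pooled per group per site before testing.
fisher_site_stats <- function(meth_a, cov_a, meth_b, cov_b) {
  tot_a <- rowSums(cov_a)
  tot_b <- rowSums(cov_b)
  sm_a <- rowSums(meth_a)
  sm_b <- rowSums(meth_b)
  m_a <- ifelse(tot_a > 0, sm_a / tot_a, NA_real_)
  m_b <- ifelse(tot_b > 0, sm_b / tot_b, NA_real_)
  p <- fisher_p(sm_a, tot_a - sm_a, sm_b, tot_b - sm_b)
  p[!is.finite(m_a) | !is.finite(m_b)] <- NA_real_
  list(mean_a = m_a, mean_b = m_b, diff = m_b - m_a, p = p)
}
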