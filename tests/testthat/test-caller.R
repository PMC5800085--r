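# helpers to build small deterministic instances: each site type gives
# 3v3 replicate counts at coverage 30
toy_counts <- list(
  up = list(a = c(2, 3, 2), b = c(27, 28, 27)),      # strong B-hyper
  down = list(a = c(27, 28, 27), b = c(2, 3, 2)),    # strong B-hypo
  same = list(a = c(15, 14, 16), b = c(15, 16, 14)), # no difference
  lowcov = list(a = c(2, 3, 2), b = c(27, 28, 27))   # strong but thin
)
toy_instance <- function(types, pos = NULL) {
  n <- length(types)
  if (is.null(pos)) pos <- seq_len(n) * 50L
  cov <- matrix(30L, n, 3)
  ma <- t(vapply(types, function(tp) toy_counts[[tp]]$a, numeric(3)))
  mb <- t(vapply(types, function(tp) toy_counts[[tp]]$b, numeric(3)))
  ca <- cov; cb <- cov
  thin <- types == "lowcov"
  ca[thin, 1] <- 9L
  ma[thin, 1] <- round(ma[thin, 1] * 9 / 30)
  grouped_counts(rep("chr1", n), pos, ma, ca, mb, cb)
}

test_that("site verdicts apply the coverage, difference and p criteria", {
  v <- site_verdict(c(2, 3, 2), c(30, 28, 31), c(27, 25, 28),
                    c(30, 29, 30))
  expect_true(v$qualifies)
  expect_equal(v$failed_criteria, character(0))
  low <- site_verdict(c(2, 3, 2), c(9, 28, 31), c(27, 25, 28),
                      c(30, 29, 30))
  expect_false(low$qualifies)
  expect_true("coverage" %in% low$failed_criteria)
  flat <- site_verdict(c(15, 15, 15), c(30, 30, 30),
                       c(15, 15, 15), c(30, 30, 30))
  expect_true(all(c("diff", "p") %in% flat$failed_criteria))
})

test_that("a clean differential block is called as one DMR with qualifying boundaries", {
  inst <- toy_instance(c("same", "same", rep("up", 8), "same", "same"))
  fit <- call_dmrs(inst)
  expect_equal(nrow(fit$dmrs), 1)
  expect_equal(fit$dmrs$start, inst$pos[3])
  expect_equal(fit$dmrs$end, inst$pos[10])
  expect_equal(fit$dmrs$n_cpn, 8L)
  expect_equal(fit$dmrs$direction, "hyper")
  expect_true(fit$dmrs$diff > 0.5)
})

test_that("interior non-qualifying sites are tolerated up to max_similar", {
  types <- c("same", rep("up", 4), "same", "same", rep("up", 4), "same")
  inst <- toy_instance(types)
  fit <- call_dmrs(inst)             # max_similar 5 bridges the two halves
  expect_equal(nrow(fit$dmrs), 1)
  expect_equal(fit$dmrs$n_cpn, 8L)
  expect_equal(fit$dmrs$start, inst$pos[2])
  expect_equal(fit$dmrs$end, inst$pos[11])
  strict <- call_dmrs(inst, dmr_criteria(max_similar = 0))
  expect_equal(nrow(strict$dmrs), 0) # each half has only 4 qualifying CpN
  halves <- call_dmrs(inst, dmr_criteria(max_similar = 0, min_cpn = 4))
  expect_equal(nrow(halves$dmrs), 2)
})

test_that("gaps beyond max_gap split regions; opposite direction reseeds", {
  pos <- c(50, 100, 150, 200, 250, 30000, 30050, 30100, 30150, 30200)
  inst <- toy_instance(rep("up", 10), pos = pos)
  fit <- call_dmrs(inst)             # 29750 nt gap exceeds 20 kb default
  expect_equal(nrow(fit$dmrs), 2)
  expect_equal(fit$dmrs$start, c(50L, 30000L))
  expect_equal(fit$dmrs$end, c(250L, 30200L))
  # exactly at max_gap the site is still included
  at <- toy_instance(rep("up", 6), pos = c(10, 20, 30, 40, 50, 20050))
  expect_equal(nrow(call_dmrs(at)$dmrs), 1)
  expect_equal(call_dmrs(at)$dmrs$end, 20050L)
  # sign flip mid-stream seeds a second candidate immediately
  flip <- toy_instance(c(rep("up", 5), rep("down", 5)))
  fit2 <- call_dmrs(flip)
  expect_equal(fit2$dmrs$direction, c("hyper", "hypo"))
  expect_equal(nrow(fit2$dmrs), 2)
})

test_that("region test aggregates replicate counts over the region's sites", {
  inst <- toy_instance(rep("up", 3))
  rt <- region_test(inst, "chr1", inst$pos[1], inst$pos[3])
  ma <- colSums(inst$meth_a); ca <- colSums(inst$cov_a)
  mb <- colSums(inst$meth_b); cb <- colSums(inst$cov_b)
  expect_equal(rt$mean_a, sum(ma) / sum(ca))
  expect_equal(rt$mean_b, sum(mb) / sum(cb))
  expect_equal(rt$p, weighted_welch_test(ma, ca, mb, cb)$p.value)
  # single-site region reproduces the site-level test
  one <- region_test(inst, "chr1", inst$pos[2], inst$pos[2])
  site <- site_p_value(inst$meth_a[2, ], inst$cov_a[2, ],
                       inst$meth_b[2, ], inst$cov_b[2, ])
  expect_equal(one$p, site$p.value)
  expect_error(region_test(inst, "chr1", 9e6, 9.1e6), "EmptyRegion")
})

test_that("caller output is deterministic, non-overlapping, and criteria-consistent", {
  sim <- simulate_methylation(sim_config(n_sites = 4000, n_dmrs = 4,
                                         seed = 21))
  f1 <- call_dmrs(sim$grouped)
  f2 <- call_dmrs(sim$grouped)
  expect_identical(f1$dmrs, f2$dmrs)
  d <- f1$dmrs
  expect_true(nrow(d) >= 1)
  for (chr in unique(d$chrom)) {
    dc <- d[d$chrom == chr, ]
    if (nrow(dc) > 1) expect_true(all(dc$start[-1] > dc$end[-nrow(dc)]))
  }
  cr <- f1$criteria
  expect_true(all(d$n_cpn >= cr$min_cpn))
  expect_true(all(d$end - d$start + 1 >= cr$min_span))
  # boundaries coincide with qualifying sites
  v <- wwedmr:::site_verdicts(sim$grouped, cr)
  key <- paste(sim$grouped$chrom, sim$grouped$pos)
  expect_true(all(v$qualifies[match(paste(d$chrom, d$start), key)]))
  expect_true(all(v$qualifies[match(paste(d$chrom, d$end), key)]))
})

test_that("tightening any criterion never increases the number of DMRs", {
  sim <- simulate_methylation(sim_config(n_sites = 6000, n_dmrs = 6,
                                         delta = 0.3, seed = 22))
  base <- nrow(call_dmrs(sim$grouped)$dmrs)
  tighter <- list(dmr_criteria(min_cpn = 8), dmr_criteria(min_diff = 20),
                  dmr_criteria(min_coverage = 20),
                  dmr_criteria(max_p = 0.005))
  for (cr in tighter)
    expect_lte(nrow(call_dmrs(sim$grouped, cr)$dmrs), base)
})

test_that("the scan agrees with the brute-force maximal-run oracle on random instances", {
  set.seed(23)
  for (i in 1:150) {
    inst <- random_instance(n_sites = sample(20:80, 1))
    cr <- random_criteria()
    fit <- call_dmrs(inst, cr)
    orc <- oracle_call_dmrs(inst, cr)
    expect_equal(nrow(fit$dmrs), nrow(orc))
    expect_equal(fit$dmrs$start, orc$start)
    expect_equal(fit$dmrs$end, orc$end)
    expect_equal(fit$dmrs$n_cpn, orc$n_cpn)
    expect_equal(fit$dmrs$direction == "hyper", orc$direction > 0)
  }
})

test_that("parameter sweep reduces to single calls and respects monotonicity", {
  sim <- simulate_methylation(sim_config(n_sites = 5000, n_dmrs = 5,
                                         delta = 0.4, seed = 24))
  single <- parameter_sweep(sim$grouped, list(min_cpn = 5))
  expect_equal(nrow(single), 1)
  expect_equal(single$n_dmrs, nrow(call_dmrs(sim$grouped)$dmrs))
  defaults_only <- parameter_sweep(sim$grouped)
  expect_equal(nrow(defaults_only), 1)
  expect_equal(defaults_only$n_dmrs, single$n_dmrs)
  sw <- parameter_sweep(sim$grouped, list(min_cpn = c(2, 4, 6, 8, 10)))
  expect_true(all(diff(sw$n_dmrs) <= 0))
  expect_error(parameter_sweep(sim$grouped, list(bogus = 1)), "unknown")
})
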