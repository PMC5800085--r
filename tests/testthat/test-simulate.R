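test_that("simulation is seed-deterministic and respects count invariants", {
  cfg <- sim_config(n_sites = 2000, n_dmrs = 3, seed = 41)
  s1 <- simulate_methylation(cfg)
  s2 <- simulate_methylation(cfg)
  expect_identical(s1$grouped$meth_a, s2$grouped$meth_a)
  expect_identical(s1$grouped$cov_b, s2$grouped$cov_b)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(s1$grouped$meth_a <= s1$grouped$cov_a))
  expect_true(all(s1$grouped$meth_b <= s1$grouped$cov_b))
  other <- simulate_methylation(sim_config(n_sites = 2000, n_dmrs = 3,
                                           seed = 42))
  expect_false(identical(s1$grouped$meth_a, other$grouped$meth_a))
  # truth intervals lie inside the simulated coordinate range
  expect_true(all(s1$truth$start >= min(s1$grouped$pos)))
  expect_true(all(s1$truth$end <= max(s1$grouped$pos)))
  # zero planted DMRs gives an empty truth set
  none <- simulate_methylation(sim_config(n_sites = 500, n_dmrs = 0,
                                          seed = 41))
  expect_equal(nrow(none$truth), 0)
})

test_that("background methylation converges to its Beta mean at low dispersion", {
  cfg <- sim_config(n_sites = 50000, n_dmrs = 0, rho = 0,
                    background_alpha = 0.6, background_beta = 0.4,
                    coverage_mean = 30, seed = 43)
  sim <- simulate_methylation(cfg)
  frac <- rowSums(sim$grouped$meth_a) / rowSums(sim$grouped$cov_a)
  target <- 0.6 / (0.6 + 0.4)
  se <- stats::sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - target), 3 * se + 0.002)
})

test_that("spacing models produce sorted coordinates of the requested size", {
  for (sp in c("fixed", "geometric", "clustered")) {
    sim <- simulate_methylation(sim_config(n_sites = 400, n_dmrs = 0,
                                           spacing = sp, seed = 44))
    expect_equal(length(sim$grouped$pos), 400)
    expect_true(all(diff(sim$grouped$pos) > 0))
  }
})

test_that("difficulty series shares coordinates and truth across effect sizes", {
  base <- sim_config(n_sites = 3000, n_dmrs = 3, seed = 45)
  series <- difficulty_series(base, c(0.6, 0.4, 0.2))
  expect_length(series, 3)
  for (s in series[-1]) {
    expect_identical(s$grouped$pos, series[[1]]$grouped$pos)
    expect_identical(s$truth[c("chrom", "start", "end")],
                     series[[1]]$truth[c("chrom", "start", "end")])
    expect_identical(s$grouped$cov_a, series[[1]]$grouped$cov_a)
  }
  # a single level reduces to plain simulation
  single <- difficulty_series(base, 0.6)
  direct <- simulate_methylation(base)
  expect_identical(single[[1]]$grouped$meth_b, direct$grouped$meth_b)
  expect_error(difficulty_series(base, c(0.2, 0.6)), "descending")
  # the planted shift is monotone in delta by construction
  in_truth <- series[[1]]$grouped$pos >= series[[1]]$truth$start[1] &
    series[[1]]$grouped$pos <= series[[1]]$truth$end[1]
  m_strong <- sum(series[[1]]$grouped$meth_b[in_truth, ])
  m_weak <- sum(series[[3]]$grouped$meth_b[in_truth, ])
  expect_gte(m_strong, m_weak)
})

test_that("fixture export writes every sample in every dialect and round-trips", {
  sim <- simulate_methylation(sim_config(n_sites = 120, n_dmrs = 1,
                                         n_rep_a = 2, n_rep_b = 2,
                                         seed = 46))
  dir <- file.path(tempdir(), "fixtures-test")
  man <- export_fixtures(sim, c("generic", "bismark_coverage"), dir)
  expect_equal(sum(man$kind == "sample"), 4 * 2)
  expect_equal(sum(man$kind == "truth"), 1)
  expect_true(all(file.exists(man$path)))
  # re-reading a fixture reproduces the in-memory table
  row <- man[man$kind == "sample" & man$dialect == "generic" &
               man$sample == "A1", ]
  back <- read_sample(row$path)
  expect_equal(back$meth, sim$samples_a[[1]]$meth)
  expect_equal(back$pos, sim$samples_a[[1]]$pos)
  # truth BED uses the 0-based half-open convention
  bed <- read.table(file.path(dir, "truth.bed"), sep = "\t")
  expect_equal(bed$V2, sim$truth$start - 1L)
  expect_equal(bed$V3, sim$truth$end)
  # empty dialect list still writes truth and config
  man2 <- export_fixtures(sim, character(0),
                          file.path(tempdir(), "fixtures-empty"))
  expect_setequal(man2$kind, c("truth", "config"))
})
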