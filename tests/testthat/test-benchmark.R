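test_that("directional overlay reproduces the worked geometry and stays in [0,100]", {
  pred <- data.frame(chrom = "c", start = 1L, end = 319L)
  truth <- data.frame(chrom = "c", start = c(1L, 181L), end = c(160L, 319L))
  expect_equal(dmr_overlay(pred, truth), (160 + 139) / 319 * 100)
  expect_equal(round(dmr_overlay(pred, truth), 1), 93.7)
  expect_equal(dmr_overlay(truth, pred), c(100, 100))
  one <- data.frame(chrom = "c", start = 5L, end = 50L)
  expect_equal(dmr_overlay(one, one), 100)
  far <- data.frame(chrom = "c", start = 500L, end = 600L)
  expect_equal(dmr_overlay(one, far), 0)
  expect_equal(dmr_overlay(far, data.frame(chrom = "other", start = 500L,
                                           end = 600L)), 0)
})

test_that("overlay is invariant under splitting the reference into abutting pieces", {
  q <- data.frame(chrom = "c", start = 10L, end = 99L)
  whole <- data.frame(chrom = "c", start = 20L, end = 80L)
  pieces <- data.frame(chrom = "c", start = c(20L, 41L, 61L),
                       end = c(40L, 60L, 80L))
  expect_equal(dmr_overlay(q, whole), dmr_overlay(q, pieces))
})

test_that("overlay and confusion counts match nucleotide-set brute force", {
  set.seed(31)
  for (i in 1:25) {
    q <- random_intervals(sample(2:6, 1))
    r <- random_intervals(sample(2:6, 1))
    expect_equal(dmr_overlay(q, r), bf_overlay(q, r), tolerance = 1e-12)
    cc <- confusion_counts(q, r)
    bf <- bf_confusion(q, r)
    expect_equal(cc$tp, bf$tp)
    expect_equal(cc$fp, bf$fp)
    expect_equal(cc$fn, bf$fn)
  }
})

test_that("confusion counts handle identity and empty predictions", {
  s <- data.frame(chrom = "c", start = c(1L, 50L, 200L),
                  end = c(10L, 60L, 210L))
  cc <- confusion_counts(s, s)
  expect_equal(cc, list(tp = 3L, fp = 0L, fn = 0L))
  none <- confusion_counts(s[0, ], s)
  expect_equal(none, list(tp = 0L, fp = 0L, fn = 3L))
})

test_that("precision, recall and F1 follow the stated conventions", {
  expect_equal(unname(precision_recall_f1(list(tp = 10, fp = 0, fn = 0))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f1(list(tp = 0, fp = 5, fn = 5))),
               c(0, 0, 0))
  prf <- precision_recall_f1(list(tp = 3, fp = 1, fn = 2))
  expect_equal(unname(prf), c(0.75, 0.6, 2 * 0.45 / 1.35))
  und <- precision_recall_f1(list(tp = 0, fp = 0, fn = 2))
  expect_true(is.na(und["precision"]))
  expect_equal(unname(und["recall"]), 0)
})

test_that("the bundled benchmark report composes its parts", {
  set.seed(32)
  p <- random_intervals(4)
  b <- random_intervals(4)
  rep <- benchmark_dmrs(p, b)
  cc <- confusion_counts(p, b)
  prf <- precision_recall_f1(cc)
  expect_equal(rep$counts, cc)
  expect_equal(rep$precision, unname(prf["precision"]))
  expect_equal(rep$recall, unname(prf["recall"]))
  expect_equal(rep$f1, unname(prf["f1"]))
  expect_equal(rep$overlay_pred_vs_truth, dmr_overlay(p, b))
  ident <- benchmark_dmrs(p, p)
  expect_equal(ident$f1, 1)
  expect_true(all(ident$overlay_pred_vs_truth == 100))
  out <- tempfile()
  write_benchmark(rep, out)
  expect_true(file.exists(out))
})
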