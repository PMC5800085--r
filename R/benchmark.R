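# Interval benchmarking: directional DMR overlay, confusion counts and
# precision/recall/F1 against a truth set.  Intervals are 1-based
# inclusive; lengths are end - start + 1.

# Coerce predicted/benchmark input (data.frame, dmr_result, or
# methylation_sim truth) to a validated interval data.frame.
as_intervals <- function(x) {
  if (inherits(x, "dmr_result")) x <- x$dmrs
  if (inherits(x, "methylation_sim")) x <- x$truth
  stopifnot(is.data.frame(x),
            all(c("chrom", "start", "end") %in% names(x)))
  df <- data.frame(chrom = as.character(x$chrom),
                   start = as.integer(x$start), end = as.integer(x$end),
                   stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("invalid interval: start > end")
  o <- order(df$chrom, df$start)
  df <- df[o, , drop = FALSE]
  if (nrow(df) > 1) {
    same <- df$chrom[-1] == df$chrom[-nrow(df)]
    if (any(same & df$start[-1] <= df$end[-nrow(df)]))
      stop("intervals overlap within the set")
  }
  rownames(df) <- NULL
  df
}

to_granges <- function(df)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))

#' Directional DMR overlay
#'
#' For each query interval, the percentage of its nucleotides covered by
#' the union of the reference intervals.  The metric is asymmetric: a
#' predicted region fully containing two truth regions of lengths 160 and
#' 139 within its 319 nucleotides has overlay (160+139)/319 = 93.7% with
#' respect to the truth, while each truth region's reverse overlay is
#' 100%.
#'
#' @param query,reference Interval sets: data.frames with `chrom`,
#'   `start`, `end` (1-based inclusive), or a `dmr_result`, or a
#'   simulated dataset (whose truth is used).
#' @return Numeric vector of per-query-interval percentages in
#'   \[0, 100\], in (chrom, start) order of the query set.
#' @examples
#' dmr_overlay(data.frame(chrom = "c", start = 1, end = 319),
#'             data.frame(chrom = "c", start = c(1, 181),
#'                        end = c(160, 319)))
#' @export
dmr_overlay <- function(query, reference) {
  q <- as_intervals(query)
  r <- as_intervals(reference)
  if (nrow(q) == 0) return(numeric(0))
  if (nrow(r) == 0) return(rep(0, nrow(q)))
  gq <- to_granges(q)
  gr <- GenomicRanges::reduce(to_granges(r))
  # disjoint chromosome sets are legitimate input, not a seqlevel clash
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gq, gr))
  inter <- suppressWarnings(
    IRanges::pintersect(gq[S4Vectors::queryHits(hits)],
                        gr[S4Vectors::subjectHits(hits)]))
  covered <- rep(0, nrow(q))
  w <- tapply(GenomicRanges::width(inter), S4Vectors::queryHits(hits), sum)
  covered[as.integer(names(w))] <- w
  100 * covered / (q$end - q$start + 1)
}

#' Confusion counts for interval prediction
#'
#' A predicted interval overlapping at least one benchmark interval by at
#' least one nucleotide is a true positive, otherwise a false positive; a
#' benchmark interval overlapped by no prediction is a false negative.
#' One prediction spanning several benchmark intervals counts as a single
#' TP, and each of those benchmark intervals counts as found.
#'
#' @inheritParams dmr_overlay
#' @param predicted,benchmark Interval sets (see [dmr_overlay()] for
#'   accepted forms).
#' @return List with integer `tp`, `fp`, `fn`.
#' @examples
#' confusion_counts(data.frame(chrom = "c", start = 10, end = 20),
#'                  data.frame(chrom = "c", start = c(15, 40),
#'                             end = c(30, 50)))
#' @export
confusion_counts <- function(predicted, benchmark) {
  p <- as_intervals(predicted)
  b <- as_intervals(benchmark)
  if (nrow(p) == 0) return(list(tp = 0L, fp = 0L, fn = nrow(b)))
  if (nrow(b) == 0) return(list(tp = 0L, fp = nrow(p), fn = 0L))
  gp <- to_granges(p)
  gb <- to_granges(b)
  tp <- sum(suppressWarnings(GenomicRanges::countOverlaps(gp, gb)) > 0)
  fn <- sum(suppressWarnings(GenomicRanges::countOverlaps(gb, gp)) == 0)
  list(tp = as.integer(tp), fp = as.integer(nrow(p) - tp),
       fn = as.integer(fn))
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2 * precision * recall / (precision + recall)`.  Undefined 0/0
#' ratios are reported as `NA`; `f1` is 0 when either component is 0 and
#' `NA` when either is `NA`.
#'
#' @param counts List with elements `tp`, `fp`, `fn` (from
#'   [confusion_counts()]).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @examples
#' precision_recall_f1(list(tp = 3, fp = 1, fn = 2))
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision == 0 || recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Benchmark predicted DMRs against truth intervals
#'
#' Bundles [confusion_counts()], [precision_recall_f1()] and both
#' directions of [dmr_overlay()] into one report.
#'
#' @inheritParams confusion_counts
#' @return An object of class `dmr_benchmark`: list with `counts`,
#'   `precision`, `recall`, `f1`, `overlay_pred_vs_truth`,
#'   `overlay_truth_vs_pred` (per-interval percent vectors).
#' @examples
#' sim <- simulate_methylation(sim_config(n_sites = 5000, n_dmrs = 3,
#'                                        seed = 11))
#' benchmark_dmrs(call_dmrs(sim$grouped), sim)
#' @export
benchmark_dmrs <- function(predicted, benchmark) {
  cc <- confusion_counts(predicted, benchmark)
  prf <- precision_recall_f1(cc)
  structure(list(
    counts = cc,
    precision = unname(prf["precision"]),
    recall = unname(prf["recall"]),
    f1 = unname(prf["f1"]),
    overlay_pred_vs_truth = dmr_overlay(predicted, benchmark),
    overlay_truth_vs_pred = dmr_overlay(benchmark, predicted)
  ), class = "dmr_benchmark")
}

#' @export
print.dmr_benchmark <- function(x, ...) {
  cat(sprintf("DMR benchmark: TP %d, FP %d, FN %d\n",
              x$counts$tp, x$counts$fp, x$counts$fn))
  cat(sprintf("precision %.4g | recall %.4g | F1 %.4g\n",
              x$precision, x$recall, x$f1))
  if (length(x$overlay_pred_vs_truth))
    cat(sprintf("mean overlay, predictions vs truth: %.1f%%\n",
                mean(x$overlay_pred_vs_truth)))
  if (length(x$overlay_truth_vs_pred))
    cat(sprintf("mean overlay, truth vs predictions: %.1f%%\n",
                mean(x$overlay_truth_vs_pred)))
  invisible(x)
}

#' Serialise a benchmark report to TSV
#'
#' @param x A `dmr_benchmark` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(x, path) {
  stopifnot(inherits(x, "dmr_benchmark"))
  df <- data.frame(
    metric = c("tp", "fp", "fn", "precision", "recall", "f1",
               "mean_overlay_pred_vs_truth", "mean_overlay_truth_vs_pred"),
    value = c(x$counts$tp, x$counts$fp, x$counts$fn, x$precision,
              x$recall, x$f1,
              mean(x$overlay_pred_vs_truth),
              mean(x$overlay_truth_vs_pred)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
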