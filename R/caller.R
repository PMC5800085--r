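#' DMR calling criteria
#'
#' The seven tunable thresholds that define a differentially methylated
#' region.  Defaults follow the method's reference settings; every one can
#' be overridden per call or from the command line.
#'
#' @param min_coverage Minimum read coverage required of *every* replicate
#'   in *both* groups at a qualifying site (reads; default 10).
#' @param min_diff Minimum absolute difference of the two group
#'   coverage-weighted mean methylation percentages (percentage points;
#'   default 10).
#' @param max_p Per-site two-tailed p-value threshold (default 0.05).
#' @param min_cpn Minimum number of qualifying CpN sites a DMR must
#'   contain (default 5).
#' @param min_span Minimum genomic length of a DMR, end - start + 1
#'   (nucleotides; default 0, i.e. unused).
#' @param max_gap Maximum distance between consecutive CpN inside a DMR
#'   (nucleotides; default 20000).
#' @param max_similar Maximum run of consecutive non-qualifying
#'   ("similarly methylated") CpN tolerated inside an expanding DMR
#'   (default 5).
#' @return An object of class `dmr_criteria` (named list).
#' @examples
#' dmr_criteria(min_cpn = 8, max_p = 0.01)
#' @export
dmr_criteria <- function(min_coverage = 10, min_diff = 10, max_p = 0.05,
                         min_cpn = 5, min_span = 0, max_gap = 20000,
                         max_similar = 5) {
  cr <- list(min_coverage = min_coverage, min_diff = min_diff,
             max_p = max_p, min_cpn = min_cpn, min_span = min_span,
             max_gap = max_gap, max_similar = max_similar)
  stopifnot(all(vapply(cr, is.numeric, logical(1))),
            all(unlist(cr) >= 0), cr$max_p > 0, cr$max_p <= 1,
            cr$min_cpn >= 1)
  structure(cr, class = c("dmr_criteria", "list"))
}

#' @export
print.dmr_criteria <- function(x, ...) {
  cat("DMR calling criteria:\n")
  cat(sprintf("  min_coverage %g reads/replicate | min_diff %g%% | max_p %g\n",
              x$min_coverage, x$min_diff, x$max_p))
  cat(sprintf("  min_cpn %g | min_span %g nt | max_gap %g nt | max_similar %g\n",
              x$min_cpn, x$min_span, x$max_gap, x$max_similar))
  invisible(x)
}

as_criteria <- function(x) {
  if (inherits(x, "dmr_criteria")) x else do.call(dmr_criteria, as.list(x))
}

# Vectorised per-site verdicts over a grouped_counts object.
# Returns a data.frame: mean_a, mean_b, diff, p, cov_ok, diff_ok, p_ok,
# qualifies, direction (sign of diff; 0 for exact ties).
site_verdicts <- function(data, criteria) {
  criteria <- as_criteria(criteria)
  single <- min(ncol(data$meth_a), ncol(data$meth_b)) == 1
  st <- if (single)
    fisher_site_stats(data$meth_a, data$cov_a, data$meth_b, data$cov_b)
  else
    welch_site_stats(data$meth_a, data$cov_a, data$meth_b, data$cov_b)
  cov_ok <- rowSums(data$cov_a >= criteria$min_coverage) == ncol(data$cov_a) &
    rowSums(data$cov_b >= criteria$min_coverage) == ncol(data$cov_b)
  diff_ok <- is.finite(st$diff) & abs(st$diff) >= criteria$min_diff / 100 &
    st$diff != 0
  p_ok <- is.finite(st$p) & st$p <= criteria$max_p
  data.frame(mean_a = st$mean_a, mean_b = st$mean_b, diff = st$diff,
             p = st$p, cov_ok = cov_ok, diff_ok = diff_ok, p_ok = p_ok,
             qualifies = cov_ok & diff_ok & p_ok,
             direction = sign(st$diff))
}

#' Per-site qualification verdict
#'
#' Evaluates the three site-level criteria (coverage, methylation
#' difference, p-value) for one genomic position.  The coverage criterion
#' requires every replicate in both groups to reach `min_coverage`; the
#' difference criterion compares the absolute difference of
#' coverage-weighted group means against `min_diff` percentage points; the
#' p criterion applies [site_p_value()] against `max_p`.
#'
#' @param meth_a,coverage_a Replicate counts for group A at this site.
#' @param meth_b,coverage_b Replicate counts for group B.
#' @param criteria A [dmr_criteria()] object.
#' @return A list: `qualifies` (logical), `failed_criteria` (character
#'   subset of `c("coverage", "diff", "p")`), `diff` (weighted-mean
#'   difference B - A, as a fraction), `p`.
#' @examples
#' site_verdict(c(1, 0, 2), c(30, 28, 31), c(25, 27, 24), c(30, 29, 30),
#'              dmr_criteria())
#' @export
site_verdict <- function(meth_a, coverage_a, meth_b, coverage_b,
                         criteria = dmr_criteria()) {
  gc <- grouped_counts(
    "site", 1L, matrix(meth_a, 1), matrix(coverage_a, 1),
    matrix(meth_b, 1), matrix(coverage_b, 1))
  v <- site_verdicts(gc, criteria)
  failed <- c("coverage", "diff", "p")[!c(v$cov_ok, v$diff_ok, v$p_ok)]
  list(qualifies = v$qualifies, failed_criteria = failed,
       diff = v$diff, p = v$p)
}

#' Call differentially methylated regions by weighted Welch expansion
#'
#' The core single-pass scan.  Per chromosome, going left to right over
#' the aligned sites:
#' a candidate region opens at a qualifying site (all three site criteria
#' hold), whose sign of methylation difference fixes the region's
#' direction; it expands over subsequent sites while qualifying sites keep
#' the same direction, tolerating up to `max_similar` consecutive
#' non-qualifying sites in its interior; it terminates when that run is
#' exceeded, when a qualifying site of opposite direction appears (which
#' immediately seeds the next candidate), when the gap to the previous
#' site exceeds `max_gap`, or at the chromosome end.  On termination the
#' region shrinks back to its last qualifying site, so both boundaries are
#' qualifying CpNs, and is emitted if it contains at least `min_cpn`
#' qualifying sites and spans at least `min_span` nucleotides.  Region
#' p-values come from [region_test()] on coverage-aggregated counts and
#' are Benjamini-Hochberg adjusted across all regions of the run.
#'
#' @param data A `grouped_counts` object from [align_groups()] (or a
#'   simulated dataset's `$grouped` element).
#' @param criteria A [dmr_criteria()] object (or named list of overrides).
#' @return An object of class `dmr_result`; its `$dmrs` data.frame has one
#'   row per DMR with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `n_cpn`, `mean_a`, `mean_b`, `diff`, `direction` (`"hyper"`/`"hypo"`,
#'   group B relative to A), `p`, `q`.
#' @examples
#' sim <- simulate_methylation(sim_config(n_sites = 2000, n_dmrs = 2,
#'                                        seed = 7))
#' fit <- call_dmrs(sim$grouped)
#' fit
#' @export
call_dmrs <- function(data, criteria = dmr_criteria()) {
  stopifnot(inherits(data, "grouped_counts"))
  criteria <- as_criteria(criteria)
  v <- site_verdicts(data, criteria)
  out <- list()
  for (chr in unique(data$chrom)) {
    idx <- which(data$chrom == chr)
    out[[chr]] <- scan_chromosome(data$pos[idx], v$qualifies[idx],
                                  v$direction[idx], criteria, chr)
  }
  regions <- do.call(rbind, unname(Filter(NROW, out)))
  if (is.null(regions) || nrow(regions) == 0) {
    dmrs <- data.frame(chrom = character(), start = integer(),
                       end = integer(), n_cpn = integer(),
                       mean_a = numeric(), mean_b = numeric(),
                       diff = numeric(), direction = character(),
                       p = numeric(), q = numeric(),
                       stringsAsFactors = FALSE)
  } else {
    tests <- lapply(seq_len(nrow(regions)), function(i)
      region_test(data, regions$chrom[i], regions$start[i], regions$end[i]))
    dmrs <- data.frame(
      chrom = regions$chrom,
      start = regions$start,
      end = regions$end,
      n_cpn = regions$n_cpn,
      mean_a = vapply(tests, `[[`, 0, "mean_a"),
      mean_b = vapply(tests, `[[`, 0, "mean_b"),
      diff = vapply(tests, `[[`, 0, "diff"),
      direction = ifelse(regions$direction > 0, "hyper", "hypo"),
      p = vapply(tests, `[[`, 0, "p"),
      stringsAsFactors = FALSE)
    dmrs$q <- bh_adjust(dmrs$p)
    o <- order(dmrs$chrom, dmrs$start)
    dmrs <- dmrs[o, , drop = FALSE]
    rownames(dmrs) <- NULL
  }
  structure(list(dmrs = dmrs, criteria = criteria,
                 n_sites = length(data$pos),
                 n_replicates = c(A = ncol(data$meth_a),
                                  B = ncol(data$meth_b)),
                 samples = list(A = data$samples_a, B = data$samples_b),
                 call = match.call()),
            class = "dmr_result")
}

# The expansion automaton for one chromosome.  pos/qual/dir are the
# chromosome's site vectors; returns a data.frame of candidate regions
# (start/end positions of first/last qualifying site, qualifying-site
# count, direction) that already passed min_cpn and min_span.
scan_chromosome <- function(pos, qual, dir, criteria, chrom) {
  res_start <- integer(); res_end <- integer()
  res_n <- integer(); res_dir <- numeric()
  open <- FALSE
  first_q <- 0L; last_q <- 0L; n_q <- 0L; d <- 0; run <- 0L
  emit <- function() {
    span <- pos[last_q] - pos[first_q] + 1L
    if (n_q >= criteria$min_cpn && span >= criteria$min_span) {
      res_start[length(res_start) + 1L] <<- pos[first_q]
      res_end[length(res_end) + 1L] <<- pos[last_q]
      res_n[length(res_n) + 1L] <<- n_q
      res_dir[length(res_dir) + 1L] <<- d
    }
  }
  n <- length(pos)
  for (i in seq_len(n)) {
    if (open && pos[i] - pos[i - 1L] > criteria$max_gap) {
      emit()
      open <- FALSE
    }
    if (!open) {
      if (qual[i]) {
        open <- TRUE
        first_q <- i; last_q <- i; n_q <- 1L; d <- dir[i]; run <- 0L
      }
    } else if (qual[i] && dir[i] == d) {
      last_q <- i; n_q <- n_q + 1L; run <- 0L
    } else if (qual[i]) {            # opposite direction: close, reseed
      emit()
      first_q <- i; last_q <- i; n_q <- 1L; d <- dir[i]; run <- 0L
    } else {
      run <- run + 1L
      if (run > criteria$max_similar) {
        emit()
        open <- FALSE
      }
    }
  }
  if (open) emit()
  if (length(res_start) == 0) return(NULL)
  data.frame(chrom = chrom, start = res_start, end = res_end,
             n_cpn = res_n, direction = res_dir, stringsAsFactors = FALSE)
}

#' Region-level aggregated test
#'
#' Summarises one genomic region: per replicate, methylated and total
#' counts are summed over all aligned sites inside `[start, end]`; group
#' means are the coverage-weighted means of the aggregated counts, and the
#' p-value applies [site_p_value()] to the aggregated per-replicate counts
#' (Welch when both groups have two or more replicates, Fisher on pooled
#' totals otherwise).  A single-site region therefore reproduces the
#' site-level test exactly.
#'
#' @param data A `grouped_counts` object.
#' @param chrom Chromosome name.
#' @param start,end Region bounds, 1-based inclusive.
#' @return List with `mean_a`, `mean_b`, `diff` (fractions) and `p`.
#' @export
region_test <- function(data, chrom, start, end) {
  stopifnot(inherits(data, "grouped_counts"))
  idx <- which(data$chrom == chrom & data$pos >= start & data$pos <= end)
  if (length(idx) == 0) stop("EmptyRegion: no aligned sites in region")
  agg <- function(m) colSums(m[idx, , drop = FALSE])
  ma <- agg(data$meth_a); ca <- agg(data$cov_a)
  mb <- agg(data$meth_b); cb <- agg(data$cov_b)
  mean_a <- sum(ma) / sum(ca)
  mean_b <- sum(mb) / sum(cb)
  p <- suppressWarnings(site_p_value(ma, ca, mb, cb)$p.value)
  list(mean_a = mean_a, mean_b = mean_b, diff = mean_b - mean_a, p = p)
}

#' @export
print.dmr_result <- function(x, ...) {
  cat(sprintf(paste0("Weighted Welch expansion DMR call: %d DMR(s) from ",
                     "%d aligned sites (%d vs %d replicates)\n"),
              nrow(x$dmrs), x$n_sites, x$n_replicates["A"],
              x$n_replicates["B"]))
  if (nrow(x$dmrs) > 0) {
    print.data.frame(utils::head(x$dmrs, 10), digits = 4)
    if (nrow(x$dmrs) > 10) cat(sprintf("... %d more\n", nrow(x$dmrs) - 10))
  }
  invisible(x)
}

#' @export
#' @method summary dmr_result
summary.dmr_result <- function(object, ...) {
  d <- object$dmrs
  s <- list(
    n_dmrs = nrow(d),
    n_hyper = sum(d$direction == "hyper"),
    n_hypo = sum(d$direction == "hypo"),
    n_sites = object$n_sites,
    criteria = object$criteria,
    span = if (nrow(d)) summary(d$end - d$start + 1) else NULL,
    abs_diff = if (nrow(d)) summary(abs(d$diff)) else NULL,
    q_below_05 = sum(d$q <= 0.05)
  )
  class(s) <- "summary.dmr_result"
  s
}

#' @export
print.summary.dmr_result <- function(x, ...) {
  cat(sprintf("%d DMR(s) (%d hypermethylated, %d hypomethylated in group B) from %d sites\n",
              x$n_dmrs, x$n_hyper, x$n_hypo, x$n_sites))
  cat(sprintf("%d DMR(s) with q <= 0.05\n", x$q_below_05))
  if (!is.null(x$span)) {
    cat("span (nt):\n"); print(x$span)
    cat("absolute weighted-mean difference:\n"); print(x$abs_diff)
  }
  print(x$criteria)
  invisible(x)
}

#' @export
#' @method as.data.frame dmr_result
as.data.frame.dmr_result <- function(x, ...) x$dmrs

#' @export
#' @method plot dmr_result
plot.dmr_result <- function(x, chrom = NULL, ...) {
  d <- x$dmrs
  if (nrow(d) == 0) {
    plot.new()
    title(main = "No DMRs called")
    return(invisible(x))
  }
  if (is.null(chrom)) chrom <- d$chrom[1]
  d <- d[d$chrom == chrom, , drop = FALSE]
  mid <- (d$start + d$end) / 2
  graphics::plot(mid, 100 * d$diff, type = "h",
                 col = ifelse(d$diff > 0, "firebrick", "navy"),
                 xlab = sprintf("position on %s (nt)", chrom),
                 ylab = "weighted-mean difference (B - A, %)",
                 main = "Called DMRs", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}
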