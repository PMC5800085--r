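#' Sweep calling criteria and count resulting DMRs
#'
#' Runs the region caller once per combination of the supplied criterion
#' values (Cartesian product) and tabulates the number of DMRs emitted.
#' Site-level statistics (weighted means, differences, p-values) depend
#' only on the data and are computed once and reused across combinations.
#'
#' @param data A `grouped_counts` object.
#' @param grid Named list mapping criterion names (see [dmr_criteria()])
#'   to vectors of values; an empty grid gives a single defaults-only row.
#' @param criteria Baseline criteria for parameters not in the grid.
#' @return An object of class `dmr_sweep`: a data.frame with one row per
#'   combination, the seven effective criterion values and `n_dmrs`.
#' @examples
#' sim <- simulate_methylation(sim_config(n_sites = 2000, n_dmrs = 2,
#'                                        seed = 5))
#' parameter_sweep(sim$grouped, list(min_cpn = c(3, 5, 8)))
#' @export
parameter_sweep <- function(data, grid = list(),
                            criteria = dmr_criteria()) {
  stopifnot(inherits(data, "grouped_counts"))
  criteria <- as_criteria(criteria)
  if (length(grid)) {
    bad <- setdiff(names(grid), names(criteria))
    if (length(bad)) stop("unknown criteria in grid: ",
                          paste(bad, collapse = ", "))
    combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  } else {
    combos <- data.frame(row.names = 1)
  }
  # precompute test statistics once; thresholds are applied per combo
  single <- min(ncol(data$meth_a), ncol(data$meth_b)) == 1
  st <- if (single)
    fisher_site_stats(data$meth_a, data$cov_a, data$meth_b, data$cov_b)
  else
    welch_site_stats(data$meth_a, data$cov_a, data$meth_b, data$cov_b)
  rows <- lapply(seq_len(max(1, nrow(combos))), function(i) {
    cr <- criteria
    for (nm in names(combos)) cr[[nm]] <- combos[i, nm]
    cr <- as_criteria(cr)
    cov_ok <- rowSums(data$cov_a >= cr$min_coverage) == ncol(data$cov_a) &
      rowSums(data$cov_b >= cr$min_coverage) == ncol(data$cov_b)
    qual <- cov_ok & is.finite(st$diff) &
      abs(st$diff) >= cr$min_diff / 100 & st$diff != 0 &
      is.finite(st$p) & st$p <= cr$max_p
    dir <- sign(st$diff)
    n_dmrs <- 0L
    for (chr in unique(data$chrom)) {
      idx <- which(data$chrom == chr)
      reg <- scan_chromosome(data$pos[idx], qual[idx], dir[idx], cr, chr)
      n_dmrs <- n_dmrs + NROW(reg)
    }
    cbind(as.data.frame(unclass(cr)), n_dmrs = n_dmrs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "varied") <- names(grid)
  class(out) <- c("dmr_sweep", "data.frame")
  out
}

#' @export
print.dmr_sweep <- function(x, ...) {
  varied <- attr(x, "varied")
  cat(sprintf("Criteria sweep: %d combination(s)%s\n", nrow(x),
              if (length(varied))
                paste0(" varying ", paste(varied, collapse = ", "))
              else " (defaults only)"))
  cols <- unique(c(varied, "n_dmrs"))
  print.data.frame(as.data.frame(x)[, cols, drop = FALSE])
  invisible(x)
}

#' @export
#' @method plot dmr_sweep
plot.dmr_sweep <- function(x, ...) {
  varied <- attr(x, "varied")
  if (!length(varied)) {
    graphics::barplot(x$n_dmrs, names.arg = "defaults",
                      ylab = "DMRs called")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(varied)))
  on.exit(graphics::par(old))
  for (v in varied) {
    agg <- stats::aggregate(x$n_dmrs, list(value = x[[v]]), mean)
    graphics::plot(agg$value, agg$x, type = "b", pch = 19,
                   xlab = v, ylab = "DMRs called (mean over grid)", ...)
  }
  invisible(x)
}
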