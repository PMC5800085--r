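#' Configuration for the beta-binomial methylation simulator
#'
#' Describes a two-group bisulfite experiment with planted DMRs.  Counts
#' are generated hierarchically: each site carries a latent group-mean
#' methylation (a draw from the bimodal background Beta, or a planted
#' level inside a DMR); each replicate's methylation fraction is Beta
#' distributed around that mean with dispersion `rho`
#' (\eqn{\alpha = \mu(1-\rho)/\rho}, \eqn{\beta = (1-\mu)(1-\rho)/\rho};
#' `rho = 0` is a point mass); coverage is negative-binomial per site per
#' replicate; the methylated count is Binomial(coverage, fraction).
#' Planted regions replace the background mean with a base level drawn
#' uniformly from \[0.1, 0.35\] (mirrored to \[0.65, 0.9\] for negative
#' `delta`) and shift group B by `delta`, clipped to \[0, 1\].
#'
#' All randomness is derived from `seed` through quantile transforms of a
#' single uniform stream whose length depends only on the structural
#' parameters, so two configurations differing only in `delta` share
#' coordinates, truth placement, coverages and comonotonically coupled
#' methylation draws.
#'
#' @param n_sites Total number of CpN sites (default 50000).
#' @param spacing Site spacing model: `"fixed"` (every `spacing_step` nt),
#'   `"geometric"` (gaps 1 + Geometric, mean `spacing_step`), or
#'   `"clustered"` (RRBS-like islands of ~20 sites ~30 nt apart separated
#'   by ~5 kb).
#' @param spacing_step Mean spacing in nucleotides (default 100).
#' @param n_rep_a,n_rep_b Replicates per group (default 3 and 3).
#' @param coverage_mean Mean read coverage per site per replicate
#'   (default 30).
#' @param coverage_size Negative-binomial size (inverse dispersion) of
#'   coverage; 20 gives the narrow, artificial-benchmark-like spread, 2
#'   the wide spread seen in real WGBS (default 20).
#' @param background_alpha,background_beta Background methylation Beta
#'   parameters; the default Beta(0.3, 0.3) is strongly bimodal, as CpG
#'   methylation is genome-wide.
#' @param n_dmrs Number of planted DMRs (default 20).
#' @param dmr_length Planted DMR length in consecutive CpNs (default 10).
#' @param delta Planted effect size: difference of group-B minus group-A
#'   mean methylation, in \[-1, 1\] (default 0.6).
#' @param rho Within-group beta-binomial dispersion in \[0, 1)
#'   (default 0.01).
#' @param chrom Chromosome name used for all sites (default `"chrS"`).
#' @param seed Integer RNG seed (default 1); echoed in the output.
#' @return A `sim_config` object (named list).
#' @examples
#' sim_config(n_sites = 1000, n_dmrs = 2)
#' @export
sim_config <- function(n_sites = 50000,
                       spacing = c("fixed", "geometric", "clustered"),
                       spacing_step = 100,
                       n_rep_a = 3, n_rep_b = 3,
                       coverage_mean = 30, coverage_size = 20,
                       background_alpha = 0.3, background_beta = 0.3,
                       n_dmrs = 20, dmr_length = 10,
                       delta = 0.6, rho = 0.01,
                       chrom = "chrS", seed = 1) {
  spacing <- match.arg(spacing)
  cfg <- list(n_sites = as.integer(n_sites), spacing = spacing,
              spacing_step = spacing_step,
              n_rep_a = as.integer(n_rep_a), n_rep_b = as.integer(n_rep_b),
              coverage_mean = coverage_mean, coverage_size = coverage_size,
              background_alpha = background_alpha,
              background_beta = background_beta,
              n_dmrs = as.integer(n_dmrs),
              dmr_length = as.integer(dmr_length),
              delta = delta, rho = rho, chrom = chrom,
              seed = as.integer(seed))
  if (abs(cfg$delta) > 1) stop("ConfigError: delta must lie in [-1, 1]")
  if (cfg$rho < 0 || cfg$rho >= 1) stop("ConfigError: rho must lie in [0, 1)")
  if (cfg$coverage_mean < 1) stop("ConfigError: coverage_mean must be >= 1")
  if (cfg$n_rep_a < 1 || cfg$n_rep_b < 1)
    stop("ConfigError: each group needs >= 1 replicate")
  if (cfg$n_dmrs > 0 &&
      cfg$n_dmrs * (cfg$dmr_length + 2L) > cfg$n_sites)
    stop("ConfigError: planted DMRs do not fit without overlapping")
  structure(cfg, class = c("sim_config", "list"))
}

#' Simulate a two-group methylation dataset with planted DMRs
#'
#' Seeded beta-binomial simulator (see [sim_config()] for the generative
#' model).  The same configuration and seed reproduce the dataset
#' byte-identically.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `methylation_sim`: list with `samples_a`,
#'   `samples_b` (lists of `site_table`, one per replicate), `grouped`
#'   (a ready-aligned `grouped_counts`), `truth` (data.frame of planted
#'   intervals: `chrom`, `start`, `end`, `delta`), and `config`.
#' @examples
#' sim <- simulate_methylation(sim_config(n_sites = 500, n_dmrs = 1,
#'                                        seed = 3))
#' sim$truth
#' @export
simulate_methylation <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_sites
  ra <- config$n_rep_a
  rb <- config$n_rep_b
  set.seed(config$seed)

  # 1. coordinates (draw count fixed given structural parameters)
  pos <- switch(config$spacing,
    fixed = 1L + (seq_len(n) - 1L) * as.integer(config$spacing_step),
    geometric = {
      gaps <- 1L + stats::qgeom(stats::runif(n - 1),
                                1 / max(1, config$spacing_step))
      as.integer(cumsum(c(1L, gaps)))
    },
    clustered = {
      per <- 20L
      ncl <- ceiling(n / per)
      cl_start <- as.integer(round(cumsum(
        5000 + 2000 * stats::runif(ncl))))
      within <- 1L + stats::qgeom(stats::runif(n), 1 / 30)
      idx <- rep(seq_len(ncl), each = per)[seq_len(n)]
      off <- stats::ave(within, idx, FUN = cumsum)
      as.integer(cl_start[idx] + off)
    })

  # 2. planted placement: one region per equal block, random offset
  truth <- NULL
  planted_region <- integer(n)      # 0 = background, else region id
  u_place <- stats::runif(max(1, config$n_dmrs))
  if (config$n_dmrs > 0) {
    block <- n %/% config$n_dmrs
    len <- config$dmr_length
    starts <- vapply(seq_len(config$n_dmrs), function(k) {
      lo <- (k - 1L) * block + 2L                 # leave a flanking site
      hi <- k * block - len - 1L
      lo + floor(u_place[k] * max(1, hi - lo + 1))
    }, numeric(1))
    for (k in seq_len(config$n_dmrs))
      planted_region[starts[k]:(starts[k] + len - 1L)] <- k
    truth <- data.frame(
      chrom = config$chrom,
      start = pos[starts],
      end = pos[starts + len - 1L],
      delta = config$delta,
      stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), delta = numeric(),
                        stringsAsFactors = FALSE)
  }

  # 3. latent site means
  mu_bg <- stats::qbeta(stats::runif(n), config$background_alpha,
                        config$background_beta)
  base <- stats::runif(max(1, config$n_dmrs), 0.1, 0.35)
  if (config$delta < 0) base <- 1 - base
  mu_a <- mu_bg
  mu_b <- mu_bg
  in_dmr <- planted_region > 0
  mu_a[in_dmr] <- base[planted_region[in_dmr]]
  mu_b[in_dmr] <- pmin(1, pmax(0, base[planted_region[in_dmr]] +
                                 config$delta))

  # 4-6. replicate fractions, coverage, methylated counts
  # clip latent means away from {0,1}: a Beta with a vanishing shape is a
  # point mass there anyway, and extreme shapes degrade qbeta's accuracy
  eps <- 1e-3
  draw_group <- function(mu, r) {
    mu <- pmin(1 - eps, pmax(eps, mu))
    u_theta <- matrix(stats::runif(n * r), n, r)
    theta <- if (config$rho > 0) {
      k <- (1 - config$rho) / config$rho
      suppressWarnings(stats::qbeta(u_theta, mu * k, (1 - mu) * k))
    } else matrix(mu, n, r)
    u_cov <- matrix(stats::runif(n * r), n, r)
    cov <- matrix(as.integer(stats::qnbinom(u_cov,
                                            size = config$coverage_size,
                                            mu = config$coverage_mean)),
                  n, r)
    u_meth <- matrix(stats::runif(n * r), n, r)
    meth <- matrix(as.integer(stats::qbinom(u_meth, cov, theta)), n, r)
    list(meth = meth, cov = cov)
  }
  ga <- draw_group(mu_a, ra)
  gb <- draw_group(mu_b, rb)

  ids_a <- paste0("A", seq_len(ra))
  ids_b <- paste0("B", seq_len(rb))
  mk_tables <- function(g, ids)
    lapply(seq_along(ids), function(j)
      new_site_table(config$chrom, pos, "+", g$meth[, j], g$cov[, j],
                     ids[j]))
  grouped <- grouped_counts(
    rep(config$chrom, n), pos, ga$meth, ga$cov, gb$meth, gb$cov,
    ids_a, ids_b)
  structure(list(samples_a = mk_tables(ga, ids_a),
                 samples_b = mk_tables(gb, ids_b),
                 grouped = grouped, truth = truth, config = config),
            class = "methylation_sim")
}

#' @export
print.methylation_sim <- function(x, ...) {
  cat(sprintf(paste0("Simulated methylation dataset: %d sites, %d vs %d ",
                     "replicates, %d planted DMR(s), delta = %g, seed = %d\n"),
              x$config$n_sites, x$config$n_rep_a, x$config$n_rep_b,
              nrow(x$truth), x$config$delta, x$config$seed))
  invisible(x)
}

#' Graded-difficulty simulation series
#'
#' Produces one dataset per planted effect size, from strongest to
#' weakest difference, all sharing the same seed and hence the same
#' coordinates, truth placement, coverages and coupled methylation draws:
#' only the planted effect differs.  Useful for recall-versus-difficulty
#' curves.
#'
#' @param base A [sim_config()] whose `delta` is replaced per level.
#' @param levels Numeric vector of `delta` values in descending order of
#'   magnitude.
#' @return List of `methylation_sim` objects, one per level.
#' @examples
#' s <- difficulty_series(sim_config(n_sites = 500, n_dmrs = 1),
#'                        c(0.6, 0.3))
#' identical(s[[1]]$truth[c("start", "end")], s[[2]]$truth[c("start", "end")])
#' @export
difficulty_series <- function(base, levels) {
  stopifnot(inherits(base, "sim_config"), length(levels) >= 1)
  if (is.unsorted(rev(abs(levels))))
    stop("levels must be in descending order of |delta|")
  lapply(levels, function(d) {
    cfg <- base
    cfg$delta <- d
    simulate_methylation(cfg)
  })
}

#' Export a simulated dataset as fixture files
#'
#' Writes every sample of a simulated dataset in each requested dialect,
#' plus the truth intervals as BED (0-based half-open) and the
#' configuration as a plain key=value text file, and returns a manifest.
#'
#' @param dataset A `methylation_sim` object.
#' @param dialects Character vector of dialect names (default: all
#'   registered dialects).
#' @param dir Output directory (created if missing).
#' @return Data.frame manifest with columns `kind`, `sample`, `dialect`,
#'   `path`; also written to `dir/manifest.tsv`.
#' @export
export_fixtures <- function(dataset, dialects = names(format_dialects()),
                            dir) {
  stopifnot(inherits(dataset, "methylation_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (tb in c(dataset$samples_a, dataset$samples_b)) {
    for (dn in dialects) {
      path <- file.path(dir, sprintf("%s.%s.txt", attr(tb, "sample_id"), dn))
      write_sample(tb, path, dn)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "sample", sample = attr(tb, "sample_id"), dialect = dn,
        path = path, stringsAsFactors = FALSE)
    }
  }
  truth_path <- file.path(dir, "truth.bed")
  tr <- dataset$truth
  data.table::fwrite(data.table::data.table(
    tr$chrom, tr$start - 1L, tr$end,
    paste0("dmr", seq_len(nrow(tr))),
    0L, ifelse(tr$delta >= 0, "+", "-")),
    truth_path, sep = "\t", col.names = FALSE, quote = FALSE)
  rows[[length(rows) + 1]] <- data.frame(kind = "truth", sample = NA,
                                         dialect = "bed", path = truth_path,
                                         stringsAsFactors = FALSE)
  cfg_path <- file.path(dir, "config.txt")
  cfg <- dataset$config
  writeLines(paste0(names(cfg), "=", vapply(cfg, format, "")), cfg_path)
  rows[[length(rows) + 1]] <- data.frame(kind = "config", sample = NA,
                                         dialect = "keyvalue",
                                         path = cfg_path,
                                         stringsAsFactors = FALSE)
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest
}
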