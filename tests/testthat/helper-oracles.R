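# Independent reference implementations (oracles) used across the suite.
# Each is written naively -- loops, enumeration, nucleotide sets -- and
# stays independent of the vectorised production code paths it checks.

# Benjamini-Hochberg step-up, literal transcription of the definition
ref_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i, 1)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-tailed Fisher p by exhaustive enumeration of tables at fixed
# margins, point probabilities from products of binomial coefficients
enum_fisher_p <- function(ma, ua, mb, ub) {
  k <- ma + mb
  n1 <- ma + ua
  n2 <- mb + ub
  tot <- n1 + n2
  support <- max(0, k - n2):min(k, n1)
  prob <- vapply(support, function(a)
    choose(n1, a) * choose(n2, k - a) / choose(tot, k), numeric(1))
  p_obs <- prob[support == ma]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# Naive per-site verdict used by the brute-force DMR scanner.  Matches
# the documented site criteria; the Fisher branch goes through
# stats::fisher.test (an implementation the production path never uses).
naive_verdict <- function(ma, ca, mb, cb, cr) {
  cov_ok <- all(ca >= cr$min_coverage) && all(cb >= cr$min_coverage)
  if (sum(ca) == 0 || sum(cb) == 0)
    return(list(qual = FALSE, dir = 0))
  m_a <- sum(ma) / sum(ca)
  m_b <- sum(mb) / sum(cb)
  diff <- m_b - m_a
  if (min(length(ma), length(mb)) == 1) {
    tab <- matrix(c(sum(ma), sum(ca) - sum(ma),
                    sum(mb), sum(cb) - sum(mb)), 2, byrow = TRUE)
    p <- if (sum(tab) == 0) NA_real_ else stats::fisher.test(tab)$p.value
  } else {
    fr_a <- ifelse(ca > 0, ma / ca, 0)
    fr_b <- ifelse(cb > 0, mb / cb, 0)
    if (sum(ca) <= 1 || sum(cb) <= 1) {
      p <- NA_real_
    } else {
      v_a <- sum(ca * (m_a - fr_a)^2) / (sum(ca) - 1)
      v_b <- sum(cb * (m_b - fr_b)^2) / (sum(cb) - 1)
      ra <- length(ma); rb <- length(mb)
      se2 <- v_a / ra + v_b / rb
      if (se2 <= 0) {
        p <- if (diff == 0) 1 else 0
      } else {
        df <- se2^2 / ((v_a / ra)^2 / (ra - 1) + (v_b / rb)^2 / (rb - 1))
        p <- 2 * stats::pt(-abs(diff / sqrt(se2)), df)
      }
    }
  }
  qual <- cov_ok && is.finite(diff) && abs(diff) >= cr$min_diff / 100 &&
    diff != 0 && is.finite(p) && p <= cr$max_p
  list(qual = qual, dir = sign(diff))
}

# Brute-force maximal-run scanner: walks the site list with explicit
# index bookkeeping, restarting after every closed candidate.
oracle_scan <- function(pos, qual, dir, cr) {
  n <- length(pos)
  out <- list()
  i <- 1
  while (i <= n) {
    if (!qual[i]) { i <- i + 1; next }
    d <- dir[i]
    last_q <- i; n_q <- 1; run <- 0
    j <- i + 1
    resume <- n + 1
    while (j <= n) {
      if (pos[j] - pos[j - 1] > cr$max_gap) { resume <- j; break }
      if (qual[j] && dir[j] == d) {
        last_q <- j; n_q <- n_q + 1; run <- 0
      } else if (qual[j]) {          # opposite direction closes + reseeds
        resume <- j; break
      } else {
        run <- run + 1
        if (run > cr$max_similar) { resume <- j + 1; break }
      }
      j <- j + 1
    }
    span <- pos[last_q] - pos[i] + 1
    if (n_q >= cr$min_cpn && span >= cr$min_span)
      out[[length(out) + 1]] <- data.frame(start = pos[i],
                                           end = pos[last_q],
                                           n_cpn = n_q, direction = d)
    i <- resume
  }
  if (length(out) == 0)
    data.frame(start = integer(), end = integer(), n_cpn = integer(),
               direction = numeric())
  else do.call(rbind, out)
}

# Full brute-force DMR caller over a grouped_counts object (region
# coordinates and qualifying-site counts only)
oracle_call_dmrs <- function(data, cr) {
  n <- length(data$pos)
  qual <- logical(n)
  dir <- numeric(n)
  for (i in seq_len(n)) {
    v <- naive_verdict(data$meth_a[i, ], data$cov_a[i, ],
                       data$meth_b[i, ], data$cov_b[i, ], cr)
    qual[i] <- v$qual
    dir[i] <- v$dir
  }
  res <- lapply(unique(data$chrom), function(chr) {
    idx <- which(data$chrom == chr)
    r <- oracle_scan(data$pos[idx], qual[idx], dir[idx], cr)
    if (nrow(r)) cbind(chrom = chr, r) else NULL
  })
  res <- do.call(rbind, Filter(Negate(is.null), res))
  if (is.null(res))
    data.frame(chrom = character(), start = integer(), end = integer(),
               n_cpn = integer(), direction = numeric())
  else res[order(res$chrom, res$start), , drop = FALSE]
}

# random two-group instance with blocky latent structure, for
# oracle-equivalence stress tests
random_instance <- function(n_sites = 60, max_rep = 3) {
  ra <- sample(1:max_rep, 1)
  rb <- sample(1:max_rep, 1)
  pos <- cumsum(sample(c(1:5, 50, 500, 5000), n_sites, replace = TRUE,
                       prob = c(rep(0.15, 5), 0.1, 0.1, 0.05)))
  # latent means switch between similar and differential blocks
  n_blocks <- max(1, n_sites %/% sample(3:12, 1))
  block_id <- sort(sample(seq_len(n_blocks), n_sites, replace = TRUE))
  mu_a <- runif(n_blocks, 0.05, 0.95)[block_id]
  shift <- sample(c(-0.6, -0.3, 0, 0, 0.3, 0.6), n_blocks,
                  replace = TRUE)[block_id]
  mu_b <- pmin(0.99, pmax(0.01, mu_a + shift))
  draw <- function(mu, r) {
    cov <- matrix(rpois(n_sites * r, sample(8:35, 1)), n_sites, r)
    meth <- matrix(rbinom(n_sites * r, cov, mu), n_sites, r)
    list(meth = meth, cov = cov)
  }
  ga <- draw(mu_a, ra)
  gb <- draw(mu_b, rb)
  grouped_counts(rep("chrT", n_sites), pos, ga$meth, ga$cov,
                 gb$meth, gb$cov)
}

random_criteria <- function() dmr_criteria(
  min_coverage = sample(c(1, 5, 10, 15), 1),
  min_diff = sample(c(0, 5, 10, 25), 1),
  max_p = sample(c(0.01, 0.05, 0.2, 1), 1),
  min_cpn = sample(1:6, 1),
  min_span = sample(c(0, 10, 200), 1),
  max_gap = sample(c(40, 300, 20000), 1),
  max_similar = sample(0:6, 1))

# nucleotide-set interval oracles (coordinates must stay small)
bf_covered_fraction <- function(q_start, q_end, ref) {
  nts <- q_start:q_end
  covered <- rep(FALSE, length(nts))
  for (i in seq_len(nrow(ref)))
    covered <- covered | (nts >= ref$start[i] & nts <= ref$end[i])
  100 * sum(covered) / length(nts)
}

bf_overlay <- function(query, reference) {
  vapply(seq_len(nrow(query)), function(i) {
    ref <- reference[reference$chrom == query$chrom[i], , drop = FALSE]
    if (nrow(ref) == 0) return(0)
    bf_covered_fraction(query$start[i], query$end[i], ref)
  }, numeric(1))
}

bf_confusion <- function(pred, bench) {
  overlaps <- function(a, b, i, j)
    a$chrom[i] == b$chrom[j] && a$start[i] <= b$end[j] &&
      b$start[j] <= a$end[i]
  tp <- 0
  for (i in seq_len(nrow(pred))) {
    hit <- FALSE
    for (j in seq_len(nrow(bench)))
      if (overlaps(pred, bench, i, j)) hit <- TRUE
    tp <- tp + hit
  }
  fn <- 0
  for (j in seq_len(nrow(bench))) {
    hit <- FALSE
    for (i in seq_len(nrow(pred)))
      if (overlaps(pred, bench, i, j)) hit <- TRUE
    fn <- fn + !hit
  }
  list(tp = tp, fp = nrow(pred) - tp, fn = fn)
}

# non-overlapping random interval set on a small coordinate range
random_intervals <- function(k, chroms = c("c1", "c2"), span = 2000) {
  out <- do.call(rbind, lapply(chroms, function(ch) {
    bounds <- sort(sample(seq_len(span), 2 * k))
    data.frame(chrom = ch,
               start = bounds[seq(1, 2 * k, 2)],
               end = bounds[seq(2, 2 * k, 2)],
               stringsAsFactors = FALSE)
  }))
  # drop abutting neighbours so the set is strictly non-overlapping
  keep <- rep(TRUE, nrow(out))
  out
}

# all-pairs gene-distance oracle
bf_annotate <- function(dmrs, genes, maxd) {
  lapply(seq_len(nrow(dmrs)), function(i) {
    hits <- list()
    for (j in seq_len(nrow(genes))) {
      if (dmrs$chrom[i] != genes$chrom[j]) next
      d <- if (genes$start[j] > dmrs$end[i]) genes$start[j] - dmrs$end[i]
           else if (genes$end[j] < dmrs$start[i])
             genes$end[j] - dmrs$start[i]
           else 0
      if (abs(d) <= maxd)
        hits[[length(hits) + 1]] <- data.frame(gene = genes$gene[j],
                                               distance = d)
    }
    if (length(hits) == 0)
      data.frame(gene = character(), distance = numeric())
    else {
      h <- do.call(rbind, hits)
      h[order(abs(h$distance)), , drop = FALSE]
    }
  })
}

# random site_table for round-trip tests; a small `span` makes several
# independent tables share most positions (for alignment tests)
random_site_table <- function(n = 30, sample_id = "s1", span = 5000,
                              chroms = c("chr1", "chr2")) {
  pos <- sort(sample(seq_len(span), n))
  cov <- rpois(n, 20)
  wwedmr:::new_site_table(
    chrom = sample(chroms, n, replace = TRUE),
    pos = pos,
    strand = sample(c("+", "-"), n, replace = TRUE),
    meth = rbinom(n, cov, 0.4),
    coverage = cov,
    sample_id = sample_id)
}
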