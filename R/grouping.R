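#' Align two groups of samples into position-matched count matrices
#'
#' Builds the `grouped_counts` container consumed by [call_dmrs()]: per
#' group, a methylated-count matrix and a coverage matrix of shape
#' (sites x replicates), sharing one (chrom, pos) index.  The default
#' (and only) policy keeps exactly the sites present in every sample of
#' both groups; requiring complete observation avoids the false positives
#' that partially-missing sites can introduce.
#'
#' @param group_a,group_b Lists of `site_table` objects (one per
#'   replicate), each non-empty.
#' @param policy Site-selection policy; only `"intersection"`.
#' @return A `grouped_counts` object: list with `chrom`, `pos`, matrices
#'   `meth_a`, `cov_a`, `meth_b`, `cov_b`, and sample id vectors
#'   `samples_a`, `samples_b`.
#' @examples
#' a <- lapply(1:2, function(i) read_sample(textConnection_file(
#'   sprintf("chr1\t%d\t+\t%d\t20", c(100, 200), c(2, 3)))))
#' b <- lapply(1:2, function(i) read_sample(textConnection_file(
#'   sprintf("chr1\t%d\t+\t%d\t20", c(100, 200), c(15, 16)))))
#' align_groups(a, b)
#' @export
align_groups <- function(group_a, group_b, policy = "intersection") {
  policy <- match.arg(policy, "intersection")
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  tables <- c(group_a, group_b)
  lapply(tables, function(tb) stopifnot(inherits(tb, "site_table")))
  keys <- lapply(tables, function(tb) paste(tb$chrom, tb$pos, sep = "\r"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0)
    stop("EmptyIntersection: no (chrom, pos) shared by all samples")
  ref <- tables[[1]]
  idx0 <- match(shared, keys[[1]])
  o <- order(ref$chrom[idx0], ref$pos[idx0])
  shared <- shared[o]
  take <- function(tb, key, col) tb[[col]][match(shared, key)]
  mat <- function(tbs, ks, col)
    do.call(cbind, Map(function(tb, k) take(tb, k, col), tbs, ks))
  n_a <- length(group_a)
  ids <- vapply(tables, function(tb) {
    id <- attr(tb, "sample_id")
    if (is.null(id)) NA_character_ else id
  }, character(1))
  structure(list(
    chrom = take(ref, keys[[1]], "chrom"),
    pos = take(ref, keys[[1]], "pos"),
    meth_a = mat(tables[seq_len(n_a)], keys[seq_len(n_a)], "meth"),
    cov_a = mat(tables[seq_len(n_a)], keys[seq_len(n_a)], "coverage"),
    meth_b = mat(tables[-seq_len(n_a)], keys[-seq_len(n_a)], "meth"),
    cov_b = mat(tables[-seq_len(n_a)], keys[-seq_len(n_a)], "coverage"),
    samples_a = ids[seq_len(n_a)],
    samples_b = ids[-seq_len(n_a)]
  ), class = "grouped_counts")
}

#' @export
print.grouped_counts <- function(x, ...) {
  cat(sprintf(paste0("grouped_counts: %d aligned sites on %d chromosome(s); ",
                     "group A: %d replicate(s), group B: %d replicate(s)\n"),
              length(x$pos), length(unique(x$chrom)),
              ncol(x$meth_a), ncol(x$meth_b)))
  invisible(x)
}

#' Build grouped counts directly from aligned matrices
#'
#' Low-level constructor for data already aligned by position (e.g. from
#' a simulator or an external pipeline): one (chrom, pos) index plus
#' per-group methylated-count and coverage matrices of shape
#' (sites x replicates).
#'
#' @param chrom,pos Site index vectors (equal length; `pos` 1-based).
#' @param meth_a,cov_a Group A matrices, `length(pos)` rows.
#' @param meth_b,cov_b Group B matrices.
#' @param samples_a,samples_b Optional replicate labels.
#' @return A `grouped_counts` object, sorted by (chrom, pos).
#' @export
grouped_counts <- function(chrom, pos, meth_a, cov_a, meth_b, cov_b,
                           samples_a = NULL, samples_b = NULL) {
  stopifnot(length(chrom) == length(pos),
            nrow(meth_a) == length(pos), nrow(meth_b) == length(pos),
            all(dim(meth_a) == dim(cov_a)), all(dim(meth_b) == dim(cov_b)),
            all(meth_a <= cov_a), all(meth_b <= cov_b))
  o <- order(chrom, pos)
  structure(list(
    chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
    meth_a = meth_a[o, , drop = FALSE], cov_a = cov_a[o, , drop = FALSE],
    meth_b = meth_b[o, , drop = FALSE], cov_b = cov_b[o, , drop = FALSE],
    samples_a = samples_a %||% paste0("A", seq_len(ncol(meth_a))),
    samples_b = samples_b %||% paste0("B", seq_len(ncol(meth_b)))
  ), class = "grouped_counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
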