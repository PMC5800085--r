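#' Write called DMRs to BED or TSV
#'
#' TSV output carries every DMR field (coordinates 1-based inclusive,
#' group means, difference, p, q, qualifying-site count, and annotation
#' when present) at full numeric precision, so [read_dmrs()] reproduces
#' the list exactly.  BED output converts to the 0-based half-open
#' convention (`start - 1`, `end`) with the direction in the strand
#' column (`+` hyper, `-` hypo in group B).
#'
#' @param dmrs A `dmr_result`, `annotated_dmrs`, or plain DMR data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @examples
#' d <- data.frame(chrom = "chr1", start = 100, end = 200, n_cpn = 6,
#'                 mean_a = 0.1, mean_b = 0.7, diff = 0.6,
#'                 direction = "hyper", p = 1e-8, q = 1e-7)
#' write_dmrs(d, tempfile(), "bed")
#' @export
write_dmrs <- function(dmrs, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  df <- if (inherits(dmrs, "dmr_result")) dmrs$dmrs else as.data.frame(dmrs)
  df$genes <- NULL                      # list-column: flat annotation only
  if (format == "bed") {
    bed <- data.frame(
      chrom = df$chrom,
      start = df$start - 1L,
      end = df$end,
      name = if (nrow(df)) paste0("dmr", seq_len(nrow(df))) else character(),
      score = if ("q" %in% names(df) && nrow(df))
        pmin(1000L, as.integer(round(-10 * log10(pmax(df$q, 1e-100)))))
      else integer(length(df$chrom)),
      strand = if ("direction" %in% names(df))
        ifelse(df$direction == "hyper", "+", "-")
      else ".")
    con <- file(path, "w")
    writeLines(paste0("track name=DMRs description=\"called DMRs\""), con)
    if (nrow(bed))
      writeLines(do.call(paste, c(bed, sep = "\t")), con)
    close(con)
  } else {
    out <- df
    for (nm in names(out))
      if (is.double(out[[nm]]))
        out[[nm]] <- formatC(out[[nm]], digits = 17, format = "g")
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read back a TSV DMR table written by [write_dmrs()]
#'
#' @param path Path to the TSV file.
#' @return DMR data.frame, numerically identical to what was written.
#' @export
read_dmrs <- function(path) {
  if (!file.exists(path)) stop("IOError: no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df)) {
    df$chrom <- as.character(df$chrom)
    if ("annotation" %in% names(df))
      df$annotation <- as.character(df$annotation)
  }
  df
}

#' Run the whole calling pipeline with one call
#'
#' Reads the per-sample count files of both groups (auto-detecting the
#' dialect unless one is forced), optionally merges CpG strand pairs,
#' aligns the groups on their shared sites, calls DMRs, optionally
#' annotates them with nearby genes, and writes `<out_prefix>.tsv`,
#' `<out_prefix>.bed` and a `<out_prefix>.log` echoing every effective
#' parameter, so any run is reproducible from its log.
#'
#' @param group_a_files,group_b_files Character vectors of count-file
#'   paths, one per replicate.
#' @param out_prefix Output path prefix.
#' @param format Dialect name or `"auto"`.
#' @param merge_strands Merge complementary CpG strand pairs before
#'   alignment (default `FALSE`).
#' @param criteria A [dmr_criteria()] object.
#' @param genes Optional path to a gene interval file (BED or TSV), or a
#'   gene data.frame from [read_gene_intervals()].
#' @param annotation_distance Maximum gene annotation distance in
#'   nucleotides (default 15000).
#' @param sweep Optional named list of criterion values to sweep instead
#'   of calling once; writes `<out_prefix>.sweep.tsv`.
#' @return Invisibly, the `dmr_result` (or `dmr_sweep` when sweeping).
#' @export
run_pipeline <- function(group_a_files, group_b_files, out_prefix,
                         format = "auto", merge_strands = FALSE,
                         criteria = dmr_criteria(), genes = NULL,
                         annotation_distance = 15000, sweep = NULL) {
  stopifnot(length(group_a_files) >= 1, length(group_b_files) >= 1)
  missing <- c(group_a_files, group_b_files)
  missing <- missing[!file.exists(missing)]
  if (length(missing))
    stop("IOError: missing input file(s): ", paste(missing, collapse = ", "))
  criteria <- as_criteria(criteria)
  read_group <- function(files) lapply(files, function(f) {
    tb <- read_sample(f, dialect = format)
    if (merge_strands) merge_cpg_strands(tb) else tb
  })
  ga <- read_group(group_a_files)
  gb <- read_group(group_b_files)
  data <- align_groups(ga, gb)

  log_path <- paste0(out_prefix, ".log")
  log_lines <- c(
    sprintf("wwedmr %s", as.character(utils::packageVersion("wwedmr"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("group_a: %s", paste(group_a_files, collapse = ",")),
    sprintf("group_b: %s", paste(group_b_files, collapse = ",")),
    sprintf("format: %s", if (is.list(format)) format$name else format),
    sprintf("merge_strands: %s", merge_strands),
    sprintf("aligned_sites: %d", length(data$pos)),
    paste0(names(criteria), ": ",
           vapply(unclass(criteria), function(v) base::format(v), "")),
    sprintf("annotation_distance: %g", annotation_distance))

  if (!is.null(sweep)) {
    sw <- parameter_sweep(data, sweep, criteria)
    utils::write.table(as.data.frame(sw), paste0(out_prefix, ".sweep.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(c(log_lines,
                 sprintf("sweep: %s", paste(names(sweep), collapse = ","))),
               log_path)
    return(invisible(sw))
  }

  fit <- call_dmrs(data, criteria)
  out <- fit$dmrs
  if (!is.null(genes)) {
    gtab <- if (is.character(genes)) read_gene_intervals(genes) else genes
    out <- annotate_dmrs(fit, gtab, annotation_distance)
    fit$dmrs <- out
  }
  write_dmrs(out, paste0(out_prefix, ".tsv"), "tsv")
  write_dmrs(out, paste0(out_prefix, ".bed"), "bed")
  writeLines(c(log_lines, sprintf("dmrs_called: %d", nrow(fit$dmrs))),
             log_path)
  invisible(fit)
}
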