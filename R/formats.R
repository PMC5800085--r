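# Format dialect registry for per-sample cytosine count files.
#
# A dialect is a list with:
#   name        identifier
#   description one-line column layout
#   ncol        expected field count
#   coord_base  0 or 1
#   match(fields)          TRUE if a split data line looks like this dialect
#   parse(dt, path)        data.table of raw fields -> site records
#   write(records, path)   inverse of parse (round-trip safe for counts
#                          and positions)
#
# Detection is by column count plus a column-type signature on the first
# line that matches any dialect at all (earlier non-matching lines are
# treated as headers/comments); two simultaneous matches are an error,
# never a silent guess.

.dialects <- new.env(parent = emptyenv())

is_int_field <- function(x) grepl("^-?[0-9]+$", x)
is_num_field <- function(x) suppressWarnings(!is.na(as.numeric(x)))
is_strand_field <- function(x) x %in% c("+", "-", ".", "*")

# round half away from zero (deterministic percent -> count conversion)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

new_site_table <- function(chrom, pos, strand, meth, coverage, sample_id) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), meth = as.integer(meth),
                   coverage = as.integer(coverage),
                   stringsAsFactors = FALSE)
  o <- order(df$chrom, df$pos)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(paste(df$chrom, df$pos)))
    stop("ParseError: duplicate (chrom, pos) records")
  if (any(df$pos < 1)) stop("CoordinateError: positions must be >= 1")
  if (any(df$meth > df$coverage))
    stop("ParseError: meth_count exceeds coverage")
  if (any(df$meth < 0) || any(df$coverage < 0))
    stop("ParseError: negative counts")
  structure(df, sample_id = sample_id,
            class = c("site_table", "data.frame"))
}

#' Register a methylation file dialect
#'
#' Adds (or replaces) a dialect in the format registry used by
#' [detect_format()] and [read_sample()].  Intended for extending the
#' built-in set; see the package source for the structure of a dialect.
#'
#' @param dialect A dialect list (fields `name`, `description`, `ncol`,
#'   `coord_base`, and functions `match`, `parse`, `write`).
#' @return The dialect, invisibly.
#' @export
register_dialect <- function(dialect) {
  stopifnot(is.list(dialect), is.character(dialect$name),
            is.function(dialect$match), is.function(dialect$parse),
            is.function(dialect$write))
  assign(dialect$name, dialect, envir = .dialects)
  invisible(dialect)
}

#' List registered methylation file dialects
#'
#' @return Named list of dialect objects, in registry order.
#' @examples
#' names(format_dialects())
#' @export
format_dialects <- function() {
  nm <- c("bismark_coverage", "bismark_cytosine", "methylkit",
          "bedmethyl", "generic")
  nm <- c(nm, setdiff(ls(.dialects), nm))
  stats::setNames(lapply(nm, get, envir = .dialects), nm)
}

get_dialect <- function(name) {
  if (is.list(name)) return(name)
  if (!exists(name, envir = .dialects))
    stop("UnknownFormat: no dialect named '", name, "'")
  get(name, envir = .dialects)
}

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

is_skip_line <- function(line) {
  grepl("^\\s*$", line) || grepl("^#", line) ||
    grepl("^(track|browser)\\b", line)
}

#' Auto-detect the dialect of a methylation count file
#'
#' Inspects raw text lines (typically the head of a file) and returns the
#' unique registered dialect whose column count and column-type signature
#' match the first recognisable data line.  Comment lines (`#`, `track`,
#' `browser`), blank lines and unrecognised header lines are skipped.
#'
#' @param first_lines Character vector of raw lines.
#' @return A dialect object (see [format_dialects()]).
#' @section Errors: `AmbiguousFormat` if two or more dialects match the
#'   same line (pass an explicit dialect to [read_sample()] instead);
#'   `UnknownFormat` if no line matches any dialect.
#' @examples
#' detect_format("chr1\t100\t+\t15\t20")$name  # generic
#' @export
detect_format <- function(first_lines) {
  if (length(first_lines) == 0 || all(vapply(first_lines, is_skip_line,
                                             logical(1))))
    stop("UnknownFormat: no data lines to inspect")
  reg <- format_dialects()
  for (line in first_lines) {
    if (is_skip_line(line)) next
    f <- split_fields(line)
    hits <- Filter(function(d) length(f) == d$ncol && isTRUE(d$match(f)), reg)
    if (length(hits) == 1) return(hits[[1]])
    if (length(hits) > 1)
      stop("AmbiguousFormat: line matches dialects ",
           paste(vapply(hits, `[[`, "", "name"), collapse = ", "),
           "; pass an explicit dialect")
  }
  stop("UnknownFormat: no registered dialect matches the input")
}

#' Read one sample's methylation counts
#'
#' Parses a per-sample cytosine count file into a `site_table`: a
#' data.frame with columns `chrom`, `pos` (1-based), `strand`, `meth`,
#' `coverage`, sorted by (chrom, pos) and unique per position.  Dialects
#' reporting percent methylation are converted to counts with
#' `meth = round(percent/100 * coverage)` (half away from zero); records
#' with zero coverage are retained (the caller's coverage criterion
#' filters them).
#'
#' @param path Path to the count file.
#' @param dialect `"auto"` (default), a dialect name from
#'   [format_dialects()], or a dialect object.
#' @param sample_id Sample label; defaults to the file name.
#' @param context For dialects carrying a cytosine context column
#'   (Bismark cytosine report), keep only this context (e.g. `"CpG"`);
#'   `NULL` (default) keeps all.
#' @return A `site_table` data.frame; attribute `sample_id` carries the
#'   label and `dialect` the dialect name used.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines("chr1\t100\t+\t15\t20", f)
#' read_sample(f)
#' @export
read_sample <- function(path, dialect = "auto", sample_id = basename(path),
                        context = NULL) {
  if (!file.exists(path)) stop("IOError: no such file: ", path)
  head_lines <- readLines(path, n = 100L, warn = FALSE)
  if (identical(dialect, "auto")) dialect <- detect_format(head_lines)
  dialect <- get_dialect(dialect)
  # skip leading comment/header lines that do not match the dialect
  skip <- 0L
  for (line in head_lines) {
    f <- if (is_skip_line(line)) character(0) else split_fields(line)
    if (length(f) == dialect$ncol && isTRUE(dialect$match(f))) break
    skip <- skip + 1L
  }
  if (skip >= length(head_lines))
    stop("ParseError: no data lines parse under dialect '", dialect$name, "'")
  dt <- data.table::fread(path, header = FALSE, skip = skip, sep = "\t",
                          data.table = TRUE, showProgress = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) == 1)   # space-separated fallback
    dt <- data.table::fread(path, header = FALSE, skip = skip, sep = " ",
                            data.table = TRUE, showProgress = FALSE,
                            colClasses = list(character = 1))
  if (ncol(dt) != dialect$ncol)
    stop("ParseError: expected ", dialect$ncol, " columns for dialect '",
         dialect$name, "', found ", ncol(dt))
  rec <- dialect$parse(dt, path)
  if (!is.null(context) && !is.null(rec$context)) {
    keep <- rec$context == context
    rec <- lapply(rec[c("chrom", "pos", "strand", "meth", "coverage")],
                  `[`, keep)
  }
  tb <- new_site_table(rec$chrom, rec$pos, rec$strand, rec$meth,
                       rec$coverage, sample_id)
  attr(tb, "dialect") <- dialect$name
  tb
}

#' Write one sample's methylation counts in a given dialect
#'
#' Inverse of [read_sample()]: serialises a `site_table` in any registered
#' dialect.  Counts and positions round-trip exactly through every
#' dialect's reader/writer pair; strand survives only in dialects that
#' carry a strand column.
#'
#' @param table A `site_table` (from [read_sample()] or built in code).
#' @param path Output path.
#' @param dialect Dialect name or object.
#' @return `path`, invisibly.
#' @export
write_sample <- function(table, path, dialect = "generic") {
  dialect <- get_dialect(dialect)
  dialect$write(table, path)
  invisible(path)
}

#' @export
print.site_table <- function(x, ...) {
  cat(sprintf("site_table '%s': %d sites on %d chromosome(s)\n",
              attr(x, "sample_id"), nrow(x),
              length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Merge counts of complementary CpG strand pairs
#'
#' Bisulfite data reports the C of a CpG on the plus strand and the
#' complementary C (the G position) on the minus strand one nucleotide
#' downstream.  This merges each (+, pos) / (-, pos+1) pair by summing
#' both methylated and total counts onto the plus-strand position, so the
#' pair is estimated at a single locus.  Unpaired sites pass through
#' unchanged; tables without strand information are returned as-is.
#' Total methylated count and total coverage are conserved.
#'
#' @param table A `site_table` with strand information.
#' @return A merged `site_table`.
#' @examples
#' tb <- read_sample(textConnection_file(c("chr1\t100\t+\t3\t10",
#'                                         "chr1\t101\t-\t5\t10")))
#' merge_cpg_strands(tb)
#' @export
merge_cpg_strands <- function(table) {
  stopifnot(inherits(table, "site_table"))
  if (all(table$strand %in% c("*", ".")) || nrow(table) == 0) return(table)
  plus <- which(table$strand == "+")
  minus <- which(table$strand == "-")
  key_plus <- paste(table$chrom[plus], table$pos[plus])
  hit <- match(paste(table$chrom[minus], table$pos[minus] - 1L), key_plus)
  paired_minus <- minus[!is.na(hit)]
  paired_plus <- plus[hit[!is.na(hit)]]
  meth <- table$meth
  cov <- table$coverage
  meth[paired_plus] <- meth[paired_plus] + meth[paired_minus]
  cov[paired_plus] <- cov[paired_plus] + cov[paired_minus]
  keep <- setdiff(seq_len(nrow(table)), paired_minus)
  new_site_table(table$chrom[keep], table$pos[keep], table$strand[keep],
                 meth[keep], cov[keep], attr(table, "sample_id"))
}

#' Helper: write lines to a temp file and return its path
#'
#' Small convenience used in examples and tests to build single-use
#' fixture files from literal lines.
#'
#' @param lines Character vector of file lines.
#' @return Path to a temporary file containing `lines`.
#' @export
textConnection_file <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

# ---- built-in dialects ------------------------------------------------

register_dialect(list(
  name = "bismark_coverage",
  description = "chrom, start, end, %methylation, count methylated, count unmethylated (1-based)",
  ncol = 6L, coord_base = 1L,
  match = function(f) {
    all(is_int_field(f[2:3])) && is_num_field(f[4]) &&
      all(is_int_field(f[5:6])) &&
      as.numeric(f[4]) >= 0 && as.numeric(f[4]) <= 100
  },
  parse = function(dt, path) {
    list(chrom = dt[[1]], pos = dt[[2]], strand = "*",
         meth = dt[[5]], coverage = dt[[5]] + dt[[6]])
  },
  write = function(tb, path) {
    pct <- ifelse(tb$coverage > 0, 100 * tb$meth / tb$coverage, 0)
    data.table::fwrite(data.table::data.table(
      tb$chrom, tb$pos, tb$pos, formatC(pct, digits = 17, format = "g"),
      tb$meth, tb$coverage - tb$meth),
      path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
))

register_dialect(list(
  name = "bismark_cytosine",
  description = "chrom, pos, strand, count methylated, count unmethylated, context, trinucleotide (1-based)",
  ncol = 7L, coord_base = 1L,
  match = function(f) {
    is_int_field(f[2]) && is_strand_field(f[3]) &&
      all(is_int_field(f[4:5])) && !is_num_field(f[6])
  },
  parse = function(dt, path) {
    list(chrom = dt[[1]], pos = dt[[2]], strand = dt[[3]],
         meth = dt[[4]], coverage = dt[[4]] + dt[[5]],
         context = dt[[6]])
  },
  write = function(tb, path) {
    strand <- ifelse(tb$strand %in% c("+", "-"), tb$strand, ".")
    data.table::fwrite(data.table::data.table(
      tb$chrom, tb$pos, strand, tb$meth, tb$coverage - tb$meth,
      "CpG", "CGG"),
      path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
))

register_dialect(list(
  name = "methylkit",
  description = "id, chrom, pos, strand (F/R), coverage, freqC, freqT (1-based, percent)",
  ncol = 7L, coord_base = 1L,
  match = function(f) {
    is_int_field(f[3]) && f[4] %in% c("F", "R", "+", "-", "*", ".") &&
      is_int_field(f[5]) && all(is_num_field(f[6:7])) &&
      abs(as.numeric(f[6]) + as.numeric(f[7]) - 100) < 1e-6
  },
  parse = function(dt, path) {
    strand <- c("F" = "+", "R" = "-")[dt[[4]]]
    strand[is.na(strand)] <- dt[[4]][is.na(strand)]
    list(chrom = dt[[2]], pos = dt[[3]], strand = strand,
         meth = as.integer(round_half_away(as.numeric(dt[[6]]) / 100 * dt[[5]])),
         coverage = dt[[5]])
  },
  write = function(tb, path) {
    freq_c <- ifelse(tb$coverage > 0, 100 * tb$meth / tb$coverage, 0)
    strand <- c("+" = "F", "-" = "R")[tb$strand]
    strand[is.na(strand)] <- "F"
    data.table::fwrite(data.table::data.table(
      paste0(tb$chrom, ".", tb$pos), tb$chrom, tb$pos, strand, tb$coverage,
      formatC(freq_c, digits = 17, format = "g"),
      formatC(100 - freq_c, digits = 17, format = "g")),
      path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
))

register_dialect(list(
  name = "bedmethyl",
  description = "ENCODE bedMethyl bed9+2: chrom, start (0-based), end, name, score, strand, thickStart, thickEnd, rgb, coverage, %methylation",
  ncol = 11L, coord_base = 0L,
  match = function(f) {
    all(is_int_field(f[c(2, 3, 5, 7, 8, 10)])) && is_strand_field(f[6]) &&
      is_num_field(f[11]) && grepl("^[0-9]+(,[0-9]+)*$", f[9])
  },
  parse = function(dt, path) {
    pos <- dt[[2]] + 1L
    if (any(pos < 1)) stop("CoordinateError: negative 0-based start")
    list(chrom = dt[[1]], pos = pos, strand = ifelse(dt[[6]] == ".", "*", dt[[6]]),
         meth = as.integer(round_half_away(as.numeric(dt[[11]]) / 100 * dt[[10]])),
         coverage = dt[[10]])
  },
  write = function(tb, path) {
    pct <- ifelse(tb$coverage > 0, 100 * tb$meth / tb$coverage, 0)
    strand <- ifelse(tb$strand %in% c("+", "-"), tb$strand, ".")
    data.table::fwrite(data.table::data.table(
      tb$chrom, tb$pos - 1L, tb$pos, ".", pmin(1000L, tb$coverage), strand,
      tb$pos - 1L, tb$pos, "0,0,0", tb$coverage,
      formatC(pct, digits = 17, format = "g")),
      path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
))

register_dialect(list(
  name = "generic",
  description = "chrom, pos, strand, count methylated, coverage (1-based)",
  ncol = 5L, coord_base = 1L,
  match = function(f) {
    is_int_field(f[2]) && is_strand_field(f[3]) &&
      all(is_int_field(f[4:5])) &&
      as.integer(f[4]) <= as.integer(f[5])
  },
  parse = function(dt, path) {
    list(chrom = dt[[1]], pos = dt[[2]],
         strand = ifelse(dt[[3]] == ".", "*", dt[[3]]),
         meth = dt[[4]], coverage = dt[[5]])
  },
  write = function(tb, path) {
    strand <- ifelse(tb$strand %in% c("+", "-"), tb$strand, ".")
    data.table::fwrite(data.table::data.table(
      tb$chrom, tb$pos, strand, tb$meth, tb$coverage),
      path, sep = "\t", col.names = FALSE, quote = FALSE)
  }
))
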