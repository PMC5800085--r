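#' Read gene intervals for DMR annotation
#'
#' Accepts BED (0-based half-open; converted to 1-based inclusive on
#' read; columns chrom, start, end, and optionally name and strand) or a
#' minimal GFF-like TSV (1-based: chrom, start, end, name, strand).
#' Format is chosen by file extension unless given explicitly.
#'
#' @param path Path to the interval file.
#' @param format `"auto"` (by extension), `"bed"` or `"tsv"`.
#' @return Data.frame with `chrom`, `start`, `end` (1-based inclusive),
#'   `gene`, `strand`.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("IOError: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "tsv"
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          showProgress = FALSE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("ParseError: need at least 3 columns")
  start <- if (format == "bed") dt[[2]] + 1L else dt[[2]]
  name <- if (ncol(dt) >= 4) as.character(dt[[4]])
          else paste0("feature", seq_len(nrow(dt)))
  strand_col <- if (format == "bed") 6L else 5L
  strand <- if (ncol(dt) >= strand_col) as.character(dt[[strand_col]])
            else "*"
  df <- data.frame(chrom = dt[[1]], start = as.integer(start),
                   end = as.integer(dt[[3]]), gene = name,
                   strand = strand, stringsAsFactors = FALSE)
  if (any(df$start > df$end)) stop("ParseError: start > end")
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Annotate DMRs with nearby genes
#'
#' Lists, for each DMR, every gene whose interval lies within
#' `max_distance` nucleotides.  Distance is the edge-to-edge coordinate
#' difference: 0 when the intervals overlap, `gene_start - dmr_end` for a
#' downstream gene, `gene_end - dmr_start` (negative) for an upstream
#' gene; a gene ending exactly `max_distance` before a DMR start is still
#' included.  Genes are sorted by increasing absolute distance per DMR.
#'
#' @param dmrs A `dmr_result` or a data.frame with `chrom`, `start`,
#'   `end`.
#' @param genes Gene intervals from [read_gene_intervals()] (or an
#'   equivalent data.frame with `chrom`, `start`, `end`, `gene`).
#' @param max_distance Maximum annotation distance in nucleotides
#'   (default 15000).
#' @return The DMR data.frame with a list-column `genes` (each element a
#'   data.frame `gene`, `distance`, `relation` with relation one of
#'   `"overlaps"`, `"upstream"`, `"downstream"`) and a flat character
#'   column `annotation` (`gene:distance:relation` entries joined by
#'   `;`), classed `annotated_dmrs`.
#' @examples
#' dmr <- data.frame(chrom = "chr1", start = 20000, end = 20500)
#' gen <- data.frame(chrom = "chr1", start = 4000, end = 5001,
#'                   gene = "g1", strand = "+")
#' annotate_dmrs(dmr, gen)$annotation
#' @export
annotate_dmrs <- function(dmrs, genes, max_distance = 15000) {
  df <- if (inherits(dmrs, "dmr_result")) dmrs$dmrs else as.data.frame(dmrs)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)),
            all(c("chrom", "start", "end", "gene") %in% names(genes)),
            max_distance >= 0)
  ann <- vector("list", nrow(df))
  flat <- character(nrow(df))
  if (nrow(df) > 0 && nrow(genes) > 0) {
    gd <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    # edge distance d (ours) equals the IRanges gap + 1 for disjoint
    # ranges, so d <= max_distance corresponds to maxgap = max_distance - 1
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gd, gg, maxgap = max_distance - 1L))
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    dist <- ifelse(genes$start[sh] > df$end[qh],
                   genes$start[sh] - df$end[qh],
                   ifelse(genes$end[sh] < df$start[qh],
                          genes$end[sh] - df$start[qh], 0L))
    keep <- abs(dist) <= max_distance
    qh <- qh[keep]; sh <- sh[keep]; dist <- dist[keep]
    rel <- ifelse(dist == 0, "overlaps",
                  ifelse(dist > 0, "downstream", "upstream"))
    for (i in seq_len(nrow(df))) {
      j <- which(qh == i)
      j <- j[order(abs(dist[j]))]
      ann[[i]] <- data.frame(gene = genes$gene[sh[j]],
                             distance = as.integer(dist[j]),
                             relation = rel[j], stringsAsFactors = FALSE)
      flat[i] <- paste(sprintf("%s:%d:%s", genes$gene[sh[j]], dist[j],
                               rel[j]), collapse = ";")
    }
  } else {
    for (i in seq_len(nrow(df)))
      ann[[i]] <- data.frame(gene = character(), distance = integer(),
                             relation = character(),
                             stringsAsFactors = FALSE)
  }
  df$genes <- ann
  df$annotation <- flat
  class(df) <- c("annotated_dmrs", "data.frame")
  df
}
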