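# Internal helpers shared across modules.
#
# All genomic coordinates inside the package are 0-based half-open
# ([start, end), BED convention). GenomicRanges/IRanges are 1-based
# closed, so conversion happens only inside these helpers.

#' @importFrom GenomicRanges GRanges seqnames start end strand countOverlaps
#'   findOverlaps coverage reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits runValue runLength
NULL

# data.frame(chrom, start, end[, strand]) [0-based half-open] -> GRanges
.as_granges <- function(df, use_strand = FALSE) {
  str <- if (use_strand && !is.null(df$strand)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = str
  )
}

.check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Overlap counts of 0-based intervals in `queries` against tag intervals in
# `tags` (both data.frames with chrom/start/end). >=1 bp overlap counts.
.count_overlaps0 <- function(queries, tags) {
  if (nrow(tags) == 0L) return(integer(nrow(queries)))
  q <- .as_granges(queries)
  s <- .as_granges(tags)
  GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE)
}

# Same, restricted to tags whose strand is opposite to each query's
# gene strand (PRO-seq sense-via-antisense convention).
.count_overlaps0_antisense <- function(queries, gene_strand, tags) {
  stopifnot(length(gene_strand) == nrow(queries))
  out <- integer(nrow(queries))
  if (nrow(tags) == 0L) return(out)
  for (gs in c("+", "-")) {
    idx <- which(gene_strand == gs)
    if (length(idx) == 0L) next
    anti <- tags[tags$strand == setdiff(c("+", "-"), gs), , drop = FALSE]
    out[idx] <- .count_overlaps0(queries[idx, , drop = FALSE], anti)
  }
  out
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0

.stop_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
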