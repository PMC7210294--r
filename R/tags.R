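# Aligned-tag processing: loading, assay-specific extension/reduction,
# region counting, binned TSS matrices, normalization, bedGraph export.

#' Construct a tag library from an in-memory tag table
#'
#' @param tags data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open intervals, one row per uniquely mapped read).
#' @param assay `"chip"` or `"proseq"`.
#' @param label Free-text condition label (e.g. `"PolII_rest"`).
#' @param state Processing state; new libraries are `"raw"`.
#' @param total Library depth used for per-10M normalization; fixed at load
#'   time, before any subsetting. Defaults to `nrow(tags)`.
#' @return An object of class `tag_library`.
#' @export
tag_library <- function(tags, assay = c("chip", "proseq"), label = "",
                        state = c("raw", "extended", "reduced"),
                        total = nrow(tags)) {
  assay <- match.arg(assay)
  state <- match.arg(state)
  .check_cols(tags, c("chrom", "start", "end", "strand"), "tag table")
  bad <- which(!(tags$start < tags$end))
  .stop_if(length(bad) > 0L, "tag record %d: start must be < end", bad[1])
  structure(list(tags = tags, total = as.numeric(total), assay = assay,
                 state = state, label = label),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library '%s': %d tags (total depth %g), assay=%s, state=%s\n",
              x$label, nrow(x$tags), x$total, x$assay, x$state))
  invisible(x)
}

#' Load aligned tags from a BED6 (or BAM) file
#'
#' Each record is one uniquely mapped read. Duplicates are retained.
#' A BED file without a strand column is an error for PRO-seq (the strand
#' convention is essential) and a warning for ChIP-seq (tags are assigned
#' strand `*` and treated as `+` during extension).
#'
#' @param path BED6 or BAM file (format chosen by extension).
#' @param assay `"chip"` or `"proseq"`.
#' @param label Condition label stored on the library.
#' @return A `tag_library` in state `"raw"` with `total` set to the number
#'   of records (mapped primary alignments for BAM).
#' @export
load_tags <- function(path, assay = c("chip", "proseq"), label = basename(path)) {
  assay <- match.arg(assay)
  .stop_if(!file.exists(path), "tag file not found: %s", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    tags <- .read_bam_tags(path)
  } else {
    x <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE, fill = TRUE)
    .stop_if(ncol(x) < 3L, "BED file must have >= 3 columns")
    if (ncol(x) < 6L) {
      .stop_if(assay == "proseq",
               "PRO-seq BED input must carry a strand column")
      warning("BED input has no strand column; assigning strand '*'")
      strand <- rep("*", nrow(x))
    } else {
      strand <- as.character(x[[6]])
    }
    tags <- data.frame(chrom = as.character(x[[1]]),
                       start = as.integer(x[[2]]),
                       end = as.integer(x[[3]]),
                       strand = strand, stringsAsFactors = FALSE)
  }
  bad <- which(!(tags$start < tags$end))
  .stop_if(length(bad) > 0L, "line %d: interval end must be > start", bad[1])
  tag_library(tags, assay = assay, label = label)
}

.read_bam_tags <- function(path) {
  .stop_if(!requireNamespace("Rsamtools", quietly = TRUE),
           "BAM input requires the Rsamtools package")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flag,
                               what = c("rname", "pos", "strand", "qwidth"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  data.frame(chrom = as.character(b$rname)[keep],
             start = b$pos[keep] - 1L,
             end = b$pos[keep] - 1L + b$qwidth[keep],
             strand = as.character(b$strand)[keep],
             stringsAsFactors = FALSE)
}

#' Extend ChIP-seq reads to the sequenced fragment length
#'
#' Each read is anchored at its 5' terminus and extended in its own
#' orientation until it spans `fragment_length` bp (`anchor = "five_prime"`,
#' the standard fragment-length model). `anchor = "three_prime"` instead
#' fixes the 3' end and extends upstream. Intervals are clipped at
#' chromosome bounds when a [genome_layout()] is supplied.
#'
#' @param lib A raw ChIP `tag_library`.
#' @param fragment_length Target fragment length in bp (default 150).
#' @param layout Optional `genome_layout` used for clipping.
#' @param anchor `"five_prime"` (default) or `"three_prime"`.
#' @return The library in state `"extended"`.
#' @export
extend_chip_tags <- function(lib, fragment_length = 150, layout = NULL,
                             anchor = c("five_prime", "three_prime")) {
  anchor <- match.arg(anchor)
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .stop_if(lib$assay != "chip", "extension applies to ChIP libraries only")
  .stop_if(lib$state != "raw", "library already processed (state=%s)", lib$state)
  t <- lib$tags
  plus <- t$strand != "-"  # '*' treated as '+'
  if (anchor == "five_prime") {
    s <- ifelse(plus, t$start, t$end - fragment_length)
    e <- ifelse(plus, t$start + fragment_length, t$end)
  } else {
    s <- ifelse(plus, t$end - fragment_length, t$start)
    e <- ifelse(plus, t$end, t$start + fragment_length)
  }
  t$start <- pmax(0L, as.integer(s))
  t$end <- as.integer(e)
  if (!is.null(layout)) {
    len <- layout$chrom_lengths[t$chrom]
    known <- !is.na(len)
    t$end[known] <- pmin(t$end[known], as.integer(len[known]))
  }
  t$end <- pmax(t$end, t$start + 1L)  # degenerate guard after clipping
  lib$tags <- t
  lib$state <- "extended"
  lib
}

#' Reduce PRO-seq reads to their 5' base
#'
#' The 5' terminus of the aligned read (in read orientation) marks the
#' transcription-active site; each tag becomes that single base, strand
#' preserved.
#'
#' @param lib A raw PRO-seq `tag_library`.
#' @return The library in state `"reduced"` (all tags 1 bp).
#' @export
reduce_proseq_tags <- function(lib) {
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .stop_if(lib$assay != "proseq", "reduction applies to PRO-seq libraries only")
  .stop_if(lib$state != "raw", "library already processed (state=%s)", lib$state)
  t <- lib$tags
  plus <- t$strand == "+"
  pos <- ifelse(plus, t$start, t$end - 1L)
  t$start <- as.integer(pos)
  t$end <- as.integer(pos + 1L)
  lib$tags <- t
  lib$state <- "reduced"
  lib
}

.assert_processed <- function(lib) {
  want <- if (lib$assay == "chip") "extended" else "reduced"
  .stop_if(lib$state != want,
           "library must be processed (%s) before counting; state=%s",
           want, lib$state)
}

#' Count tags in genomic intervals
#'
#' ChIP-seq mode (`strand_mode = "both"`) counts tags overlapping each
#' interval by at least 1 bp regardless of strand. PRO-seq mode
#' (`"sense_via_antisense"`) counts reduced 1-bp tags inside the interval
#' whose aligned strand is opposite to the gene strand: reads antisense to
#' the gene report sense-strand transcription.
#'
#' @param lib A processed `tag_library`.
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), one row per region.
#' @param gene_strand Character vector of gene strands, required for
#'   `"sense_via_antisense"`.
#' @param strand_mode `"both"` or `"sense_via_antisense"`.
#' @return Integer vector of counts, one per interval.
#' @export
count_tags <- function(lib, intervals, gene_strand = NULL,
                       strand_mode = c("both", "sense_via_antisense")) {
  strand_mode <- match.arg(strand_mode)
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .assert_processed(lib)
  .check_cols(intervals, c("chrom", "start", "end"), "interval table")
  if (strand_mode == "sense_via_antisense") {
    .stop_if(lib$assay != "proseq",
             "sense_via_antisense counting requires a PRO-seq library")
    .stop_if(is.null(gene_strand), "gene_strand required for PRO-seq counting")
    .count_overlaps0_antisense(intervals, gene_strand, lib$tags)
  } else {
    .count_overlaps0(intervals, lib$tags)
  }
}

#' Binned tag-count matrix around TSSs
#'
#' Counts tags in `bin`-bp bins from `upstream` bp before to `downstream`
#' bp after each TSS, in the direction of transcription (bin 1 is the most
#' upstream bin; minus-strand profiles are mirrored so bins always read
#' upstream to downstream). ChIP tags are counted by >=1 bp overlap with
#' each bin; PRO-seq tags by their 1-bp position on the antisense strand.
#'
#' @param lib A processed `tag_library`.
#' @param regions data.frame from [define_regions()].
#' @param upstream,downstream Window size in bp (defaults 1000/2000).
#' @param bin Bin width in bp (default 10); must divide both window sides.
#' @param strand_mode Counting mode; defaults to the assay's convention.
#' @return An object of class `signal_matrix`: list with `matrix`
#'   (genes x bins), `genes`, `bin_size`, `upstream`, `downstream`,
#'   `normalization`, `total`.
#' @export
tss_matrix <- function(lib, regions, upstream = 1000, downstream = 2000,
                       bin = 10,
                       strand_mode = if (lib$assay == "proseq")
                         "sense_via_antisense" else "both") {
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .assert_processed(lib)
  .check_cols(regions, c("symbol", "chrom", "strand", "tss_pos"),
              "regions table")
  .stop_if(nrow(regions) == 0L, "regions must be non-empty")
  .stop_if(upstream %% bin != 0 || downstream %% bin != 0,
           "upstream/downstream must be divisible by bin size")
  nbins <- as.integer((upstream + downstream) / bin)
  n <- nrow(regions)
  j <- rep(seq_len(nbins) - 1L, times = n)      # bin index within gene
  g <- rep(seq_len(n), each = nbins)
  plus <- regions$strand[g] == "+"
  tss <- regions$tss_pos[g]
  # + strand: bin j covers [tss - up + j*b, ... + b)
  # - strand: bin j covers [tss + up - (j+1)*b, tss + up - j*b)
  bs <- ifelse(plus, tss - upstream + j * bin, tss + upstream - (j + 1L) * bin)
  bins <- data.frame(chrom = regions$chrom[g], start = bs, end = bs + bin)
  cnt <- if (strand_mode == "sense_via_antisense") {
    .stop_if(lib$assay != "proseq",
             "sense_via_antisense counting requires a PRO-seq library")
    .count_overlaps0_antisense(bins, regions$strand[g], lib$tags)
  } else {
    .count_overlaps0(bins, lib$tags)
  }
  m <- matrix(cnt, nrow = n, ncol = nbins, byrow = TRUE,
              dimnames = list(regions$symbol, NULL))
  structure(list(matrix = m, genes = regions$symbol, bin_size = as.integer(bin),
                 upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 normalization = "raw", strand_mode = strand_mode,
                 total = lib$total),
            class = "signal_matrix")
}

#' Scale counts to tags per 10 million mapped reads
#'
#' @param x Numeric vector/matrix of counts, or a `signal_matrix`.
#' @param total Library depth; taken from the object for a `signal_matrix`.
#' @return Input scaled by `1e7 / total`.
#' @export
normalize_per10M <- function(x, total = NULL) {
  if (inherits(x, "signal_matrix")) {
    total <- if (is.null(total)) x$total else total
    .stop_if(is.null(total) || total <= 0, "library total must be > 0")
    x$matrix <- x$matrix * 1e7 / total
    x$normalization <- "per10M"
    return(x)
  }
  .stop_if(is.null(total) || total <= 0, "library total must be > 0")
  x * 1e7 / total
}

#' Average per-bin signal across genes
#'
#' @param m A `signal_matrix`.
#' @return Numeric vector of per-bin means (average reads per bin per gene).
#' @export
average_profile <- function(m) {
  .stop_if(!inherits(m, "signal_matrix"), "m must be a signal_matrix")
  .stop_if(nrow(m$matrix) == 0L, "matrix has no genes")
  colMeans(m$matrix)
}

#' Export per-base normalized coverage as bedGraph
#'
#' Coverage is computed at 1 bp resolution from the processed tags, scaled
#' per 10 million reads, and written with adjacent equal-value runs merged.
#' Zero-coverage runs are omitted (UCSC bedGraph dialect, 0-based
#' half-open).
#'
#' @param lib A processed `tag_library`.
#' @param path Output path.
#' @param track_name Name written in the track header.
#' @return Invisibly, the path.
#' @export
export_bedgraph <- function(lib, path, track_name = lib$label) {
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .assert_processed(lib)
  .stop_if(lib$total <= 0, "library total must be > 0")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  t <- lib$tags
  if (nrow(t) == 0L) return(invisible(path))
  scale <- 1e7 / lib$total
  for (chrom in sort(unique(t$chrom))) {
    tc <- t[t$chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(tc$start + 1L, tc$end))
    ends <- cumsum(S4Vectors::runLength(cov))
    starts <- ends - S4Vectors::runLength(cov)  # 0-based starts
    vals <- S4Vectors::runValue(cov)
    nz <- vals > 0
    if (!any(nz)) next
    writeLines(sprintf("%s\t%d\t%d\t%.10g", chrom, starts[nz], ends[nz],
                       vals[nz] * scale), con)
  }
  invisible(path)
}
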