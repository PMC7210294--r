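# Gene annotation handling: parsing, unique-longest-variant reduction, and
# strand-aware TSS / gene-body region definition.

#' Describe a genome as chromosome names and lengths
#'
#' The layout carries the effective genome size used as the denominator of
#' the Poisson background model, after optionally excluding mitochondrial
#' chromosomes (`chrM`, `chrMT`) and assembly-artifact chromosomes whose
#' names contain any of `drop_patterns`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param drop_mito Drop `chrM`/`chrMT` from the retained set.
#' @param drop_patterns Character patterns (fixed substrings); chromosomes
#'   whose names contain any of them are dropped.
#' @return An object of class `genome_layout` with elements `chrom_names`,
#'   `chrom_lengths`, `effective_size`.
#' @examples
#' genome_layout(c(chr1 = 1e7, chrM = 16299))
#' @export
genome_layout <- function(chrom_lengths, drop_mito = TRUE,
                          drop_patterns = c("random", "chrUn")) {
  .stop_if(is.null(names(chrom_lengths)) || any(names(chrom_lengths) == ""),
           "chrom_lengths must be a named vector")
  .stop_if(any(chrom_lengths <= 0), "chromosome lengths must be > 0")
  keep <- rep(TRUE, length(chrom_lengths))
  nm <- names(chrom_lengths)
  if (drop_mito) keep <- keep & !(nm %in% c("chrM", "chrMT"))
  for (p in drop_patterns) keep <- keep & !grepl(p, nm, fixed = TRUE)
  kept <- chrom_lengths[keep]
  structure(list(
    chrom_names = names(kept),
    chrom_lengths = kept,
    effective_size = sum(as.numeric(kept))
  ), class = "genome_layout")
}

.valid_strand <- function(s) s %in% c("+", "-")

#' Load transcript models from an annotation file
#'
#' Supported dialects: UCSC refFlat (tab-separated: geneName, name, chrom,
#' strand, txStart, txEnd, ...), BED12/BED6 (name column used as both gene
#' symbol and transcript id), and GTF (transcript records; 1-based inclusive
#' coordinates are shifted to the internal 0-based half-open convention).
#'
#' @param path Annotation file path.
#' @param format One of `"refflat"`, `"bed12"`, `"gtf"`.
#' @return data.frame with columns `symbol`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`, `length` (0-based half-open span).
#' @export
load_gene_annotation <- function(path, format = c("refflat", "bed12", "gtf")) {
  format <- match.arg(format)
  .stop_if(!file.exists(path), "annotation file not found: %s", path)
  genes <- switch(format,
    refflat = .parse_refflat(path),
    bed12 = .parse_bed12(path),
    gtf = .parse_gtf(path)
  )
  bad <- which(!.valid_strand(genes$strand))
  .stop_if(length(bad) > 0L, "line %d: invalid strand '%s'",
           genes$line[bad[1]], genes$strand[bad[1]])
  bad <- which(!(genes$start < genes$end))
  .stop_if(length(bad) > 0L, "line %d: span start must be < end",
           genes$line[bad[1]])
  genes$length <- genes$end - genes$start
  genes$line <- NULL
  rownames(genes) <- NULL
  genes
}

.parse_refflat <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE, fill = TRUE)
  .stop_if(ncol(x) < 6L, "refFlat file must have >= 6 tab-separated columns")
  data.frame(
    symbol = as.character(x[[1]]),
    transcript_id = as.character(x[[2]]),
    chrom = as.character(x[[3]]),
    strand = as.character(x[[4]]),
    start = as.integer(x[[5]]),
    end = as.integer(x[[6]]),
    line = seq_len(nrow(x)),
    stringsAsFactors = FALSE
  )
}

.parse_bed12 <- function(path) {
  x <- data.table::fread(path, header = FALSE, sep = "\t",
                         data.table = FALSE, fill = TRUE)
  .stop_if(ncol(x) < 6L, "BED input must have >= 6 columns (strand required)")
  data.frame(
    symbol = as.character(x[[4]]),
    transcript_id = as.character(x[[4]]),
    chrom = as.character(x[[1]]),
    strand = as.character(x[[6]]),
    start = as.integer(x[[2]]),
    end = as.integer(x[[3]]),
    line = seq_len(nrow(x)),
    stringsAsFactors = FALSE
  )
}

.parse_gtf <- function(path) {
  .stop_if(!requireNamespace("rtracklayer", quietly = TRUE),
           "GTF parsing requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  .stop_if(length(gr) == 0L, "GTF contains no transcript records")
  sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
  sym[is.na(sym)] <- gr$gene_id[is.na(sym)]
  data.frame(
    symbol = as.character(sym),
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    line = seq_along(gr),
    stringsAsFactors = FALSE
  )
}

#' Reduce transcripts to one longest variant per gene symbol
#'
#' Genes on mitochondrial (`chrM`/`chrMT`) or pattern-matched chromosomes
#' (default: names containing "random" or "chrUn") are removed first; then
#' the single longest variant per symbol is kept (ties broken by the
#' lexicographically smallest transcript id); finally genes shorter than
#' `min_length` are removed. Output is sorted by chromosome and start.
#'
#' @param genes data.frame from [load_gene_annotation()].
#' @param min_length Minimum gene length in bp kept after selection.
#' @param drop_mito,drop_patterns Chromosome filter, as in [genome_layout()].
#' @return data.frame with one row per surviving gene symbol.
#' @export
select_unique_longest <- function(genes, min_length = 1000,
                                  drop_mito = TRUE,
                                  drop_patterns = c("random", "chrUn")) {
  .check_cols(genes, c("symbol", "transcript_id", "chrom", "strand",
                       "start", "end", "length"), "gene table")
  .stop_if(nrow(genes) == 0L, "empty gene table")
  keep <- rep(TRUE, nrow(genes))
  if (drop_mito) keep <- keep & !(genes$chrom %in% c("chrM", "chrMT"))
  for (p in drop_patterns) keep <- keep & !grepl(p, genes$chrom, fixed = TRUE)
  g <- genes[keep, , drop = FALSE]
  if (nrow(g) > 0L) {
    ord <- order(g$symbol, -g$length, g$transcript_id)
    g <- g[ord, , drop = FALSE]
    g <- g[!duplicated(g$symbol), , drop = FALSE]
    g <- g[g$length >= min_length, , drop = FALSE]
    g <- g[order(g$chrom, g$start), , drop = FALSE]
  }
  if (nrow(g) == 0L) warning("no genes survive unique-longest selection")
  rownames(g) <- NULL
  g
}

#' Define strand-aware TSS windows and gene bodies
#'
#' The TSS window spans `tss_flank` bp on either side of the transcription
#' start site (span start for + genes, span end for - genes); the gene body
#' runs from the downstream edge of the TSS window (in the direction of
#' transcription) to the transcription termination site.
#'
#' @param genes data.frame of unique genes (see [select_unique_longest()]).
#' @param tss_flank Flank in bp on each side of the TSS (default 250).
#' @return data.frame with the gene columns plus `tss_pos`, `tss_start`,
#'   `tss_end`, `body_start`, `body_end`, `tss_flank`.
#' @export
define_regions <- function(genes, tss_flank = 250) {
  .check_cols(genes, c("symbol", "chrom", "strand", "start", "end", "length"),
              "gene table")
  .stop_if(!.is_count(tss_flank) || tss_flank <= 0,
           "tss_flank must be a positive number of bp")
  short <- genes$length <= tss_flank
  .stop_if(any(short), "gene %s (length %d) is not longer than tss_flank %d",
           genes$symbol[which(short)[1]], genes$length[which(short)[1]],
           as.integer(tss_flank))
  plus <- genes$strand == "+"
  tss_pos <- ifelse(plus, genes$start, genes$end)
  regions <- genes
  regions$tss_pos <- tss_pos
  regions$tss_start <- tss_pos - tss_flank
  regions$tss_end <- tss_pos + tss_flank
  regions$body_start <- ifelse(plus, tss_pos + tss_flank, genes$start)
  regions$body_end <- ifelse(plus, genes$end, tss_pos - tss_flank)
  regions$tss_flank <- as.integer(tss_flank)
  rownames(regions) <- NULL
  regions
}

# interval accessors used throughout counting code
.tss_intervals <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$tss_start,
             end = regions$tss_end, stringsAsFactors = FALSE)
}
.body_intervals <- function(regions) {
  data.frame(chrom = regions$chrom, start = regions$body_start,
             end = regions$body_end, stringsAsFactors = FALSE)
}

#' Write TSS windows and gene bodies as a BED6 audit file
#'
#' One row per TSS window and one per gene body, named `symbol:tss` and
#' `symbol:body`.
#'
#' @param regions data.frame from [define_regions()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_regions_bed <- function(regions, path) {
  .check_cols(regions, c("symbol", "chrom", "strand", "tss_start", "tss_end",
                         "body_start", "body_end"), "regions table")
  bed <- rbind(
    data.frame(chrom = regions$chrom, start = regions$tss_start,
               end = regions$tss_end, name = paste0(regions$symbol, ":tss"),
               score = 0L, strand = regions$strand),
    data.frame(chrom = regions$chrom, start = regions$body_start,
               end = regions$body_end, name = paste0(regions$symbol, ":body"),
               score = 0L, strand = regions$strand)
  )
  bed <- bed[order(bed$chrom, bed$start, bed$name), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
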