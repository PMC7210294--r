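# Poisson-background enrichment machinery: genome-wide sliding windows,
# FDR-derived integer count thresholds, peak calling with an optional
# condition-as-background differential mode, and peak annotation.

#' Sliding genome windows
#'
#' Half-overlapping windows (step = `window_size / 2`) tiled per retained
#' chromosome.
#'
#' @param layout A [genome_layout()].
#' @param window_size Window size in bp (default 500).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
genome_windows <- function(layout, window_size = 500) {
  .stop_if(!inherits(layout, "genome_layout"), "layout must be a genome_layout")
  step <- window_size / 2
  out <- lapply(layout$chrom_names, function(ch) {
    len <- layout$chrom_lengths[[ch]]
    if (len < window_size) return(NULL)
    starts <- seq(0, len - window_size, by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + window_size))
  })
  do.call(rbind, out)
}

#' Fit the uniform Poisson background model
#'
#' Expected tags per window under a uniform genome-wide background:
#' `lambda = total_tags * window_size / effective_size`.
#'
#' @param lib A `tag_library` (its fixed `total` is used).
#' @param layout A [genome_layout()] supplying the effective genome size.
#' @param window_size Search window in bp (default 500).
#' @return Object of class `background_model` with `lambda`, `window_size`,
#'   `step`, `n_windows`, `total_tags`, `effective_size`.
#' @export
fit_background <- function(lib, layout, window_size = 500) {
  .stop_if(!inherits(lib, "tag_library"), "lib must be a tag_library")
  .stop_if(lib$total <= 0, "zero-depth library")
  .stop_if(layout$effective_size <= window_size,
           "effective genome size must exceed the window size")
  step <- window_size / 2
  structure(list(
    lambda = lib$total * window_size / layout$effective_size,
    window_size = as.integer(window_size),
    step = step,
    n_windows = floor(layout$effective_size / step),
    total_tags = lib$total,
    effective_size = layout$effective_size
  ), class = "background_model")
}

#' Per-window tag counts over the genome
#'
#' @param lib Processed `tag_library`.
#' @param layout A [genome_layout()].
#' @param window_size Window size in bp (default 500).
#' @return Integer vector of counts aligned with [genome_windows()].
#' @export
window_counts <- function(lib, layout, window_size = 500) {
  .assert_processed(lib)
  wins <- genome_windows(layout, window_size)
  .count_overlaps0(wins, lib$tags)
}

#' FDR-derived integer tag-count threshold
#'
#' The estimated FDR at integer count `c` is the Poisson-expected number of
#' windows with at least `c` tags divided by the observed number; the
#' threshold is the smallest `c` whose estimated FDR falls below `fdr`.
#'
#' @param model A [fit_background()] model.
#' @param observed Integer vector of per-window tag counts.
#' @param fdr Nominal false discovery rate (default 0.001).
#' @return Object of class `enrichment_threshold` with `threshold`,
#'   `est_fdr` (at the threshold), `fdr`, `model`, and `table`
#'   (the estimated-FDR function over candidate counts).
#' @export
fdr_threshold <- function(model, observed, fdr = 0.001) {
  .stop_if(!inherits(model, "background_model"),
           "model must be a background_model")
  .stop_if(length(observed) == 0L, "observed counts must be non-empty")
  cmax <- max(observed)
  .stop_if(cmax < 1, "no significant enrichment")
  cand <- seq_len(cmax)
  # observed number of windows with count >= c, via reverse cumulative tally
  tab <- tabulate(pmin(observed, cmax) + 1L, nbins = cmax + 1L)  # counts of 0..cmax
  obs_ge <- rev(cumsum(rev(tab)))[-1L]                           # for c = 1..cmax
  exp_ge <- model$n_windows *
    stats::ppois(cand - 1L, model$lambda, lower.tail = FALSE)
  est <- exp_ge / pmax(1, obs_ge)
  ok <- which(est < fdr)
  .stop_if(length(ok) == 0L, "no significant enrichment")
  thr <- ok[1]
  structure(list(threshold = as.integer(thr), est_fdr = est[thr],
                 fdr = fdr, model = model,
                 table = data.frame(count = cand, expected = exp_ge,
                                    observed = obs_ge, est_fdr = est)),
            class = "enrichment_threshold")
}

#' @export
print.enrichment_threshold <- function(x, ...) {
  cat(sprintf("enrichment_threshold: %d tags (est. FDR %.3g at nominal %g, lambda %.4g)\n",
              x$threshold, x$est_fdr, x$fdr, x$model$lambda))
  invisible(x)
}

#' Flag genes with significantly occupied TSS windows
#'
#' A TSS is active when its window tag count strictly exceeds the
#' FDR-derived threshold (genes with "more than `threshold`" tags).
#'
#' @param counts Integer vector of per-gene TSS-window counts.
#' @param threshold An [fdr_threshold()] result (or a bare integer).
#' @return Logical vector, TRUE where the TSS is active.
#' @export
classify_active_tss <- function(counts, threshold) {
  thr <- if (inherits(threshold, "enrichment_threshold"))
    threshold$threshold else threshold
  .stop_if(any(counts < 0), "counts must be nonnegative")
  counts > thr
}

# first position of maximal 1-bp coverage inside [start, end) (0-based)
.peak_summits <- function(peaks, tags) {
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    tc <- tags[tags$chrom == p$chrom & tags$end > p$start &
                 tags$start < p$end, , drop = FALSE]
    if (nrow(tc) == 0L) return(as.integer(p$start))
    cov <- IRanges::coverage(
      IRanges::IRanges(pmax(tc$start, p$start) + 1L, pmin(tc$end, p$end)),
      width = p$end
    )
    v <- as.integer(cov[(p$start + 1L):p$end])
    as.integer(p$start + which.max(v) - 1L)
  }, integer(1))
}

#' Call enriched peaks against a Poisson background
#'
#' Half-overlapping `window_size` windows whose tag count reaches the
#' FDR-derived threshold are retained and merged when they overlap. With a
#' `background` library (condition-as-background differential mode), a
#' window is additionally required to have a per-10M target count at least
#' `min_fold_over_background` times the per-10M background count. If no
#' count threshold is attainable the peak set is empty.
#'
#' @param target Processed `tag_library` to call peaks on.
#' @param layout A [genome_layout()].
#' @param window_size Search window in bp (default 500).
#' @param fdr Nominal FDR (default 0.001).
#' @param background Optional `tag_library` used as differential background.
#' @param min_fold_over_background Fold cutoff in differential mode
#'   (default 4).
#' @return data.frame of class `peaks`: `chrom`, `start`, `end`, `summit`,
#'   `count` (raw tags in merged span), `score` (per-10M count).
#' @export
call_peaks <- function(target, layout, window_size = 500, fdr = 0.001,
                       background = NULL, min_fold_over_background = 4) {
  .assert_processed(target)
  model <- fit_background(target, layout, window_size)
  wins <- genome_windows(layout, window_size)
  counts <- .count_overlaps0(wins, target$tags)
  thr <- tryCatch(fdr_threshold(model, counts, fdr),
                  error = function(e) {
                    if (grepl("no significant enrichment", conditionMessage(e)))
                      NULL else stop(e)
                  })
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), count = integer(), score = numeric())
  class(empty) <- c("peaks", "data.frame")
  if (is.null(thr)) return(empty)
  sig <- counts >= thr$threshold
  if (!is.null(background)) {
    .stop_if(!inherits(background, "tag_library"),
             "background must be a tag_library")
    .stop_if(background$total <= 0, "zero-depth background library")
    bg_counts <- .count_overlaps0(wins, background$tags)
    t_norm <- counts * 1e7 / target$total
    b_norm <- bg_counts * 1e7 / background$total
    sig <- sig & (t_norm >= min_fold_over_background * b_norm)
  }
  if (!any(sig)) return(empty)
  sw <- wins[sig, , drop = FALSE]
  merged <- GenomicRanges::reduce(.as_granges(sw))
  peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(merged)),
                      start = GenomicRanges::start(merged) - 1L,
                      end = GenomicRanges::end(merged))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks$summit <- .peak_summits(peaks, target$tags)
  peaks$count <- .count_overlaps0(peaks, target$tags)
  peaks$score <- peaks$count * 1e7 / target$total
  rownames(peaks) <- NULL
  class(peaks) <- c("peaks", "data.frame")
  attr(peaks, "threshold") <- thr
  peaks
}

#' Annotate peaks by genomic context of their summit
#'
#' Category precedence is TSS > gene body > intergenic, decided by summit
#' membership: a summit inside any gene's TSS window is `tss` even when it
#' also lies in another gene's body.
#'
#' @param peaks A [call_peaks()] result.
#' @param regions data.frame from [define_regions()].
#' @return The peak table with `annotation` and `nearest_gene` columns; the
#'   per-category fraction summary is attached as attribute
#'   `"distribution"` and returned by [genomic_distribution()].
#' @export
annotate_peaks <- function(peaks, regions) {
  .check_cols(regions, c("symbol", "chrom", "tss_start", "tss_end",
                         "body_start", "body_end"), "regions table")
  n <- nrow(peaks)
  anno <- rep("intergenic", n)
  nearest <- rep(NA_character_, n)
  if (n > 0L) {
    summ <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                       end = peaks$summit + 1L)
    sg <- .as_granges(summ)
    tssg <- .as_granges(data.frame(chrom = regions$chrom,
                                   start = regions$tss_start,
                                   end = regions$tss_end))
    bodyg <- .as_granges(data.frame(chrom = regions$chrom,
                                    start = regions$body_start,
                                    end = regions$body_end))
    ht <- GenomicRanges::findOverlaps(sg, tssg, ignore.strand = TRUE)
    hb <- GenomicRanges::findOverlaps(sg, bodyg, ignore.strand = TRUE)
    in_body <- unique(S4Vectors::queryHits(hb))
    anno[in_body] <- "gene_body"
    first_b <- !duplicated(S4Vectors::queryHits(hb))
    nearest[S4Vectors::queryHits(hb)[first_b]] <-
      regions$symbol[S4Vectors::subjectHits(hb)[first_b]]
    in_tss <- unique(S4Vectors::queryHits(ht))
    anno[in_tss] <- "tss"
    first_t <- !duplicated(S4Vectors::queryHits(ht))
    nearest[S4Vectors::queryHits(ht)[first_t]] <-
      regions$symbol[S4Vectors::subjectHits(ht)[first_t]]
  }
  peaks$annotation <- anno
  peaks$nearest_gene <- nearest
  dist <- c(tss = mean(anno == "tss"),
            gene_body = mean(anno == "gene_body"),
            intergenic = mean(anno == "intergenic"))
  if (n == 0L) dist[] <- NaN
  attr(peaks, "distribution") <- dist
  peaks
}

#' Genomic-distribution summary of annotated peaks
#'
#' @param peaks Result of [annotate_peaks()].
#' @return Named numeric vector of fractions (`tss`, `gene_body`,
#'   `intergenic`).
#' @export
genomic_distribution <- function(peaks) {
  d <- attr(peaks, "distribution")
  .stop_if(is.null(d), "peaks have not been annotated; run annotate_peaks()")
  d
}

#' Write peaks as BED6 plus a full TSV
#'
#' BED score is the per-10M count times 10, capped at 1000.
#'
#' @param peaks A (possibly annotated) peak table.
#' @param bed_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, a character vector of the written paths.
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = peaks$chrom, start = peaks$start,
                      end = peaks$end,
                      name = sprintf("peak_%d", seq_len(nrow(peaks))),
                      score = pmin(1000, round(peaks$score * 10)),
                      strand = ".")
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    written <- c(written, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(peaks), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
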