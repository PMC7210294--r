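# Transcription-factor TSS occupancy across conditions: count tables,
# exact-binomial dismissal testing, peak-based dismissal calling and
# factor-positive gene calls.

#' Per-gene TSS occupancy across conditions
#'
#' Counts extended ChIP tags in each gene's TSS window for every supplied
#' condition library, with per-10M normalized columns alongside.
#'
#' @param libs Named list of processed (extended) ChIP `tag_library`
#'   objects, one per condition.
#' @param regions data.frame from [define_regions()].
#' @return data.frame: `symbol`, then `count_<cond>` and `norm_<cond>` per
#'   condition. Library totals are attached as attribute `"totals"`.
#' @export
tss_occupancy_table <- function(libs, regions) {
  .stop_if(length(libs) == 0L || is.null(names(libs)),
           "libs must be a named list of tag libraries")
  out <- data.frame(symbol = regions$symbol, stringsAsFactors = FALSE)
  totals <- numeric(0)
  tss <- .tss_intervals(regions)
  for (cond in names(libs)) {
    lib <- libs[[cond]]
    .stop_if(!inherits(lib, "tag_library"), "libs must contain tag libraries")
    .stop_if(lib$assay != "chip" || lib$state != "extended",
             "condition '%s': occupancy counting needs extended ChIP tags",
             cond)
    cnt <- count_tags(lib, tss)
    out[[paste0("count_", cond)]] <- cnt
    out[[paste0("norm_", cond)]] <- cnt * 1e7 / lib$total
    totals[cond] <- lib$total
  }
  attr(out, "totals") <- totals
  out
}

#' Exact-binomial test for factor dismissal between two conditions
#'
#' The fold change is the depth-normalized ratio
#' `(count_05h / total_05h) / (count_0h / total_0h)`. The p-value is a
#' two-sided exact binomial test of `count_05h` successes among
#' `count_0h + count_05h` trials with success probability
#' `total_05h / (total_0h + total_05h)` (conditional on the per-gene total,
#' the negative-binomial comparison with zero dispersion). A gene is
#' dismissed when `fc < fc_cut` and `p < p_cut`; the raw p gates the call,
#' a BH-adjusted column is reported alongside.
#'
#' @param count_0h,count_05h Per-gene TSS tag counts (vectorized).
#' @param total_0h,total_05h Library depths (> 0).
#' @param fc_cut,p_cut Dismissal thresholds (defaults 0.5 and 0.05).
#' @return data.frame: `fc`, `p`, `q`, `dismissed`. Genes with both counts
#'   zero get `fc = NA` and are never dismissed.
#' @export
test_dismissal <- function(count_0h, count_05h, total_0h, total_05h,
                           fc_cut = 0.5, p_cut = 0.05) {
  .stop_if(total_0h <= 0 || total_05h <= 0, "library totals must be > 0")
  stopifnot(length(count_0h) == length(count_05h))
  n <- count_0h + count_05h
  prob <- total_05h / (total_0h + total_05h)
  fc <- (count_05h / total_05h) / (count_0h / total_0h)
  fc[n == 0] <- NA_real_
  p <- vapply(seq_along(n), function(i) {
    if (n[i] == 0) return(NA_real_)
    stats::binom.test(count_05h[i], n[i], p = prob,
                      alternative = "two.sided")$p.value
  }, numeric(1))
  dismissed <- !is.na(fc) & !is.na(p) & fc < fc_cut & p < p_cut
  data.frame(fc = fc, p = p, q = stats::p.adjust(p, method = "BH"),
             dismissed = dismissed)
}

#' Dismissal calls from condition-as-background peak calling
#'
#' Calls peaks on the baseline library with the treated library as
#' background (windows must reach the Poisson-FDR count threshold and
#' exceed the background by `min_fold` in per-10M units), then flags each
#' gene whose TSS window contains a peak summit. The fold default of 2
#' mirrors the reciprocal of the count-based dismissal gate (fold change
#' below 0.5).
#'
#' @param lib_0h,lib_05h Processed baseline and treated ChIP libraries.
#' @param regions data.frame from [define_regions()].
#' @param layout A [genome_layout()].
#' @param window_size,fdr Peak-calling parameters (defaults 500, 0.001).
#' @param min_fold Fold-over-background cutoff (default 2).
#' @return Named logical vector (by gene symbol): TRUE where the gene's
#'   TSS shows significant dismissal.
#' @export
dismissal_by_peaks <- function(lib_0h, lib_05h, regions, layout,
                               window_size = 500, fdr = 0.001, min_fold = 2) {
  peaks <- call_peaks(lib_0h, layout, window_size = window_size, fdr = fdr,
                      background = lib_05h,
                      min_fold_over_background = min_fold)
  call_factor_positive(peaks, regions)
}

#' Factor-positive gene calls from baseline peaks
#'
#' A gene is factor-positive (e.g. NELF+ or PU.1+) when at least one peak
#' summit lies inside its TSS window.
#'
#' @param peaks A [call_peaks()] result.
#' @param regions data.frame from [define_regions()].
#' @return Named logical vector by gene symbol.
#' @export
call_factor_positive <- function(peaks, regions) {
  out <- stats::setNames(rep(FALSE, nrow(regions)), regions$symbol)
  if (nrow(peaks) == 0L) return(out)
  summ <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                     end = peaks$summit + 1L)
  hits <- GenomicRanges::findOverlaps(
    .as_granges(.tss_intervals(regions)), .as_granges(summ),
    ignore.strand = TRUE)
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}
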