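# Pausing index computation, gene grouping, distribution comparisons and
# group overlap summaries.

#' Pausing index from TSS and gene-body counts
#'
#' Ratio of per-kb tag densities, TSS window over gene body. An empty body
#' with a nonzero TSS count yields `Inf`; both counts zero yields `NaN`
#' (undefined).
#'
#' @param tss_count,body_count Nonnegative tag counts (vectorized).
#' @param tss_len,body_len Region lengths in bp (> 0).
#' @return Numeric vector of pausing indices.
#' @examples
#' pausing_index(100, 50, 500, 5000)  # densities 200 vs 10 per kb -> 20
#' @export
pausing_index <- function(tss_count, body_count, tss_len, body_len) {
  .stop_if(any(tss_count < 0) || any(body_count < 0), "counts must be >= 0")
  .stop_if(any(tss_len <= 0) || any(body_len <= 0), "lengths must be > 0")
  tss_d <- tss_count / (tss_len / 1000)
  body_d <- body_count / (body_len / 1000)
  pi <- tss_d / body_d
  pi[body_count == 0 & tss_count > 0] <- Inf
  pi[body_count == 0 & tss_count == 0] <- NaN
  pi
}

#' Classify genes into pausing groups
#'
#' Group 1 (highly paused): active TSS and PI >= `high` (including infinite
#' PI). Group 2 (moderately paused): active TSS and `moderate` <= PI <
#' `high`. Group 3 (non-paused): PI < `moderate`, undefined PI, or inactive
#' TSS regardless of PI.
#'
#' @param pi Numeric vector of pausing indices.
#' @param tss_active Logical vector of TSS activity flags.
#' @param high,moderate Group boundaries (defaults 3 and 1.5).
#' @return Integer vector of groups in `{1, 2, 3}`.
#' @export
classify_pausing <- function(pi, tss_active, high = 3, moderate = 1.5) {
  .stop_if(high <= moderate, "high cutoff must exceed moderate cutoff")
  stopifnot(length(pi) == length(tss_active))
  group <- rep(3L, length(pi))
  defined <- !is.nan(pi)
  group[tss_active & defined & pi >= high] <- 1L
  group[tss_active & defined & pi >= moderate & pi < high] <- 2L
  group
}

#' Per-gene pausing table
#'
#' Counts tags in each gene's TSS window and body (ChIP by overlap, PRO-seq
#' by antisense 1-bp position), flags active TSSs against the FDR-derived
#' threshold, computes pausing indices and assigns groups.
#'
#' @param lib Processed `tag_library` (ChIP extended or PRO-seq reduced).
#' @param regions data.frame from [define_regions()].
#' @param threshold [fdr_threshold()] result (or bare integer) for TSS
#'   activity.
#' @param high,moderate Group boundaries passed to [classify_pausing()].
#' @return data.frame of class `pausing_table`: `symbol`, `tss_count`,
#'   `body_count`, `tss_len`, `body_len`, `pi`, `tss_active`, `group`,
#'   `assay`.
#' @export
pausing_table <- function(lib, regions, threshold, high = 3, moderate = 1.5) {
  .assert_processed(lib)
  mode <- if (lib$assay == "proseq") "sense_via_antisense" else "both"
  tss_count <- count_tags(lib, .tss_intervals(regions),
                          gene_strand = regions$strand, strand_mode = mode)
  body_count <- count_tags(lib, .body_intervals(regions),
                           gene_strand = regions$strand, strand_mode = mode)
  tss_len <- regions$tss_end - regions$tss_start
  body_len <- regions$body_end - regions$body_start
  pi <- pausing_index(tss_count, body_count, tss_len, body_len)
  active <- classify_active_tss(tss_count, threshold)
  out <- data.frame(symbol = regions$symbol, tss_count = tss_count,
                    body_count = body_count, tss_len = tss_len,
                    body_len = body_len, pi = pi, tss_active = active,
                    group = classify_pausing(pi, active, high, moderate),
                    assay = lib$assay, stringsAsFactors = FALSE)
  class(out) <- c("pausing_table", "data.frame")
  out
}

#' Compare two pausing-index distributions
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on finite-valued PI
#' vectors; infinite indices are capped at the maximum finite value across
#' both samples before testing. ECDF curves over the pooled support are
#' returned for plotting.
#'
#' @param pi_a,pi_b Numeric vectors of pausing indices (length >= 2 each).
#' @return List with `statistic`, `p_value`, and `ecdf` (data.frame with
#'   `value`, `ecdf_a`, `ecdf_b`).
#' @export
compare_pi_distributions <- function(pi_a, pi_b) {
  pi_a <- pi_a[!is.na(pi_a) & !is.nan(pi_a)]
  pi_b <- pi_b[!is.na(pi_b) & !is.nan(pi_b)]
  .stop_if(length(pi_a) < 2 || length(pi_b) < 2,
           "each sample needs >= 2 defined pausing indices")
  cap <- max(c(pi_a[is.finite(pi_a)], pi_b[is.finite(pi_b)]), 0)
  pi_a[is.infinite(pi_a)] <- cap
  pi_b[is.infinite(pi_b)] <- cap
  ks <- suppressWarnings(stats::ks.test(pi_a, pi_b, alternative = "two.sided"))
  grid <- sort(unique(c(pi_a, pi_b)))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       ecdf = data.frame(value = grid,
                         ecdf_a = stats::ecdf(pi_a)(grid),
                         ecdf_b = stats::ecdf(pi_b)(grid)))
}

#' Rank-based group comparison of boxed TSS signal
#'
#' Sums each gene's bins inside a box (bp interval relative to the TSS,
#' aligned to the bin grid) of a [tss_matrix()], then runs pairwise
#' two-sided Mann-Whitney U tests between gene groups. The exact null
#' distribution is used when both groups have at most `exact_max` genes and
#' there are no ties; otherwise the normal approximation with tie
#' correction (no continuity correction) is used.
#'
#' @param m A `signal_matrix`.
#' @param groups Factor (aligned with the matrix genes) or named list of
#'   gene symbol vectors defining the groups.
#' @param box Length-2 numeric, bp interval relative to TSS, half-open
#'   (default `c(-250, 250)`).
#' @param exact_max Largest group size for which the exact test is used.
#' @return List with `box_counts` (named per-gene sums) and `tests`
#'   (data.frame: `group_a`, `group_b`, `n_a`, `n_b`, `U`, `p_value`).
#' @export
boxed_signal_test <- function(m, groups, box = c(-250, 250), exact_max = 20) {
  .stop_if(!inherits(m, "signal_matrix"), "m must be a signal_matrix")
  .stop_if(length(box) != 2 || box[1] >= box[2], "box must be an interval")
  .stop_if(box[1] < -m$upstream || box[2] > m$downstream,
           "box lies outside the matrix window")
  .stop_if((box[1] + m$upstream) %% m$bin_size != 0 ||
             (box[2] + m$upstream) %% m$bin_size != 0,
           "box must be aligned to the bin grid")
  first <- (box[1] + m$upstream) / m$bin_size + 1
  last <- (box[2] + m$upstream) / m$bin_size
  sums <- rowSums(m$matrix[, first:last, drop = FALSE])
  names(sums) <- m$genes
  if (is.list(groups)) {
    unknown <- setdiff(unlist(groups), m$genes)
    .stop_if(length(unknown) > 0, "unknown gene symbol in groups: %s",
             unknown[1])
    sets <- lapply(groups, function(g) sums[g])
  } else {
    stopifnot(length(groups) == length(sums))
    sets <- split(sums, groups)
  }
  .stop_if(length(sets) < 2, "need >= 2 groups to compare")
  pairs <- utils::combn(names(sets), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- sets[[pairs[1, i]]]; b <- sets[[pairs[2, i]]]
    ex <- length(a) <= exact_max && length(b) <= exact_max &&
      !any(duplicated(c(a, b)))
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = ex,
                                             correct = FALSE))
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               n_a = length(a), n_b = length(b),
               U = unname(w$statistic), p_value = w$p.value)
  }))
  list(box_counts = sums, tests = tests)
}

#' Cross-tabulate pausing groups against gene labels
#'
#' For each named boolean gene set (e.g. NELF+, PU.1+, LPS-inducible),
#' reports both conditional directions: the composition of the label set by
#' group, P(group | label), and the labeled fraction within each group,
#' P(label | group).
#'
#' @param records A [pausing_table()] result.
#' @param labels Named list of character vectors of gene symbols, or of
#'   named logical vectors.
#' @return Object of class `group_summary`: list with `group_counts`,
#'   `group_fractions`, and `by_label` (one data.frame per label).
#' @export
summarize_groups <- function(records, labels = list()) {
  .check_cols(records, c("symbol", "group"), "pausing table")
  syms <- records$symbol
  counts <- vapply(1:3, function(g) sum(records$group == g), integer(1))
  names(counts) <- paste0("group", 1:3)
  by_label <- lapply(labels, function(lab) {
    if (is.logical(lab)) lab <- names(lab)[lab]
    unknown <- setdiff(lab, syms)
    .stop_if(length(unknown) > 0, "unknown gene symbol in label set: %s",
             unknown[1])
    in_lab <- syms %in% lab
    data.frame(
      group = 1:3,
      n_group = counts,
      n_label_in_group = vapply(1:3, function(g)
        sum(in_lab & records$group == g), integer(1)),
      p_group_given_label = if (sum(in_lab) > 0)
        vapply(1:3, function(g)
          sum(in_lab & records$group == g) / sum(in_lab), numeric(1))
      else rep(0, 3),
      p_label_given_group = vapply(1:3, function(g)
        if (counts[g] > 0) sum(in_lab & records$group == g) / counts[g]
        else 0, numeric(1)),
      row.names = NULL
    )
  })
  structure(list(group_counts = counts,
                 group_fractions = counts / max(1, sum(counts)),
                 by_label = by_label),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("pausing group summary\n")
  print(data.frame(group = names(x$group_counts), n = x$group_counts,
                   fraction = round(x$group_fractions, 3), row.names = NULL))
  for (nm in names(x$by_label)) {
    cat(sprintf("\nlabel '%s':\n", nm))
    print(x$by_label[[nm]])
  }
  invisible(x)
}
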