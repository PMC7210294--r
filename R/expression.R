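# RNA-seq expression analysis: FPKM from replicate fragment-count tables
# and the pseudocounted fold-change classification scheme (expressed,
# LPS-inducible at 1 h, LPS-induced/-suppressed at 0.5 h, knockout up/down,
# superinduced / more-suppressed).

#' Assemble an expression table from counts and sample metadata
#'
#' @param counts Numeric matrix (genes x samples) of fragment counts, with
#'   gene symbols as rownames and sample ids as colnames.
#' @param lengths Named numeric vector of gene lengths in bp.
#' @param meta data.frame with columns `sample`, `genotype` (`WT`/`KO`),
#'   `time` (e.g. `"0h"`, `"0.5h"`, `"1h"`), `replicate`.
#' @param lib_sizes Per-sample library sizes; defaults to column sums.
#' @return Object of class `expression_table`.
#' @export
expression_table <- function(counts, lengths, meta,
                             lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  .check_cols(meta, c("sample", "genotype", "time", "replicate"),
              "sample metadata")
  .stop_if(any(counts < 0), "counts must be >= 0")
  .stop_if(is.null(rownames(counts)), "counts must carry gene rownames")
  .stop_if(!setequal(colnames(counts), meta$sample),
           "count columns and metadata samples must match")
  counts <- counts[, meta$sample, drop = FALSE]
  lengths <- lengths[rownames(counts)]
  .stop_if(any(is.na(lengths)) || any(lengths <= 0),
           "every gene needs a positive length")
  .stop_if(any(lib_sizes <= 0), "library sizes must be > 0")
  structure(list(counts = counts, lengths = lengths, meta = meta,
                 lib_sizes = lib_sizes[meta$sample]),
            class = "expression_table")
}

.condition_of <- function(meta) paste(meta$genotype, meta$time, sep = "_")

#' Compute FPKM per sample and per condition
#'
#' Per-sample FPKM is `count * 1e9 / (length * lib_size)`. The per-condition
#' value averages the fragment counts over replicates first and then
#' normalizes by the mean replicate library size (average-then-normalize);
#' per-replicate FPKM is kept alongside.
#'
#' @param tab An [expression_table()].
#' @return The table with `fpkm` (genes x samples) and `cond_fpkm`
#'   (genes x conditions, columns named `genotype_time`) added.
#' @export
compute_fpkm <- function(tab) {
  .stop_if(!inherits(tab, "expression_table"), "tab must be an expression_table")
  len <- tab$lengths
  tab$fpkm <- sweep(tab$counts * 1e9 / len, 2, tab$lib_sizes, "/")
  cond <- .condition_of(tab$meta)
  conds <- unique(cond)
  cm <- sapply(conds, function(cc) {
    idx <- which(cond == cc)
    mean_count <- rowMeans(tab$counts[, idx, drop = FALSE])
    mean_lib <- mean(tab$lib_sizes[idx])
    mean_count * 1e9 / (len * mean_lib)
  })
  tab$cond_fpkm <- as.matrix(cm)
  tab
}

#' Expressed-gene call from resting FPKM
#'
#' @param fpkm_rest Numeric vector of mean resting (WT, 0 h) FPKM.
#' @return Logical: expressed iff FPKM >= 1 (inclusive).
#' @export
classify_expressed <- function(fpkm_rest) {
  fpkm_rest >= 1
}

#' Per-gene replicate test between two conditions
#'
#' Welch t-test on log2(FPKM + 1) across replicates, with
#' Benjamini-Hochberg adjustment across genes. With a single replicate on
#' either side the p-value is NA (classification then proceeds on fold
#' change alone) and a warning is issued.
#'
#' @param tab An [expression_table()] with FPKM computed.
#' @param cond_a,cond_b Condition names (`genotype_time`, e.g. `"WT_0h"`).
#' @return data.frame: `symbol`, `p`, `q`.
#' @export
replicate_test <- function(tab, cond_a, cond_b) {
  .stop_if(is.null(tab$fpkm), "run compute_fpkm() first")
  cond <- .condition_of(tab$meta)
  ia <- which(cond == cond_a); ib <- which(cond == cond_b)
  .stop_if(length(ia) == 0L, "condition not present: %s", cond_a)
  .stop_if(length(ib) == 0L, "condition not present: %s", cond_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    warning(sprintf(
      "single replicate for %s vs %s: p-values unavailable, classification will use fold change only",
      cond_a, cond_b))
    p <- rep(NA_real_, nrow(tab$fpkm))
  } else {
    la <- log2(tab$fpkm[, ia, drop = FALSE] + 1)
    lb <- log2(tab$fpkm[, ib, drop = FALSE] + 1)
    p <- vapply(seq_len(nrow(la)), function(i) {
      a <- la[i, ]; b <- lb[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      } else {
        stats::t.test(a, b)$p.value
      }
    }, numeric(1))
  }
  data.frame(symbol = rownames(tab$fpkm), p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

.pseudo_fc <- function(f_num, f_den) (f_num + 1) / (f_den + 1)

#' LPS response classes from condition FPKM
#'
#' All fold changes are pseudocounted, `(FPKM + 1)` ratios. A gene is
#' `inducible_1h` when `q < q_cut` and the 1 h/0 h ratio is at least
#' `fc_inducible`; `induced_05h` / `suppressed_05h` when `p < p_cut` and
#' the 0.5 h/0 h ratio is at least `fc_up` / at most `fc_down`. All
#' boundaries are inclusive. NA significance values (single-replicate
#' designs) gate nothing: classification falls back to fold change alone.
#'
#' @param f0,f05,f1 Vectors of condition mean FPKM at 0 h, 0.5 h, 1 h.
#' @param q_1h BH-adjusted q-values for the 0 h vs 1 h contrast.
#' @param p_05h Raw p-values for the 0 h vs 0.5 h contrast.
#' @param fc_inducible,fc_up,fc_down FC cutoffs (defaults 1.5, 1.4, 0.6).
#' @param q_cut,p_cut Significance cutoffs (defaults 0.05).
#' @return data.frame: `fc_1h`, `fc_05h`, `inducible_1h`, `induced_05h`,
#'   `suppressed_05h`.
#' @export
classify_lps_response <- function(f0, f05, f1, q_1h, p_05h,
                                  fc_inducible = 1.5, fc_up = 1.4,
                                  fc_down = 0.6, q_cut = 0.05, p_cut = 0.05) {
  fc1 <- .pseudo_fc(f1, f0)
  fc05 <- .pseudo_fc(f05, f0)
  sig_q <- is.na(q_1h) | q_1h < q_cut
  sig_p <- is.na(p_05h) | p_05h < p_cut
  data.frame(
    fc_1h = fc1, fc_05h = fc05,
    inducible_1h = sig_q & fc1 >= fc_inducible,
    induced_05h = sig_p & fc05 >= fc_up,
    suppressed_05h = sig_p & fc05 <= fc_down
  )
}

#' Knockout effect classes within one condition
#'
#' @param f_wt,f_ko Condition mean FPKM for wild type and knockout.
#' @param p Raw p-values for the WT vs KO contrast.
#' @param fc_up,fc_down Pseudocounted FC cutoffs (defaults 1.4 and 0.6).
#' @param p_cut Significance cutoff (default 0.05).
#' @return data.frame: `fc_ko`, `ko_up`, `ko_down`.
#' @export
classify_ko_effect <- function(f_wt, f_ko, p, fc_up = 1.4, fc_down = 0.6,
                               p_cut = 0.05) {
  fc <- .pseudo_fc(f_ko, f_wt)
  sig <- is.na(p) | p < p_cut
  data.frame(fc_ko = fc, ko_up = sig & fc >= fc_up,
             ko_down = sig & fc <= fc_down)
}

#' Superinduced and more-suppressed classes
#'
#' A gene is superinduced when LPS-induced at 0.5 h in the wild type and
#' further upregulated in the knockout at the same timepoint;
#' more-suppressed is the mirrored combination.
#'
#' @param induced_05h,suppressed_05h Logical vectors (WT response classes).
#' @param ko_up,ko_down Logical vectors (knockout classes at LPS 0.5 h).
#' @return data.frame: `superinduced`, `more_suppressed`.
#' @export
classify_superinduced <- function(induced_05h, suppressed_05h, ko_up, ko_down) {
  data.frame(superinduced = induced_05h & ko_up,
             more_suppressed = suppressed_05h & ko_down)
}

#' Full response-class table for a WT/KO time-course experiment
#'
#' Convenience wrapper: computes FPKM, runs the replicate tests for the
#' 1 h (q-gated) and 0.5 h (p-gated) contrasts and the WT-vs-KO contrast at
#' LPS 0.5 h, and assembles every class flag.
#'
#' @param tab An [expression_table()] with `WT_0h`, `WT_0.5h`, `WT_1h` and
#'   `KO_0.5h` conditions.
#' @param ... Cutoffs forwarded to the classifiers.
#' @return data.frame of class `response_calls` with per-gene FPKM, fold
#'   changes, p/q values and all class flags.
#' @export
response_calls <- function(tab, ...) {
  tab <- compute_fpkm(tab)
  cf <- tab$cond_fpkm
  need <- c("WT_0h", "WT_0.5h", "WT_1h", "KO_0.5h")
  miss <- setdiff(need, colnames(cf))
  .stop_if(length(miss) > 0, "missing condition(s): %s",
           paste(miss, collapse = ", "))
  t1 <- replicate_test(tab, "WT_0h", "WT_1h")
  t05 <- replicate_test(tab, "WT_0h", "WT_0.5h")
  tko <- replicate_test(tab, "WT_0.5h", "KO_0.5h")
  expressed <- classify_expressed(cf[, "WT_0h"])
  lps <- classify_lps_response(cf[, "WT_0h"], cf[, "WT_0.5h"], cf[, "WT_1h"],
                               q_1h = t1$q, p_05h = t05$p, ...)
  ko <- classify_ko_effect(cf[, "WT_0.5h"], cf[, "KO_0.5h"], p = tko$p)
  sup <- classify_superinduced(lps$induced_05h & expressed,
                               lps$suppressed_05h & expressed,
                               ko$ko_up, ko$ko_down)
  out <- data.frame(symbol = rownames(cf),
                    fpkm_wt_0h = cf[, "WT_0h"],
                    fpkm_wt_05h = cf[, "WT_0.5h"],
                    fpkm_wt_1h = cf[, "WT_1h"],
                    fpkm_ko_05h = cf[, "KO_0.5h"],
                    expressed = expressed,
                    fc_1h = lps$fc_1h, fc_05h = lps$fc_05h,
                    fc_ko = ko$fc_ko,
                    q_1h = t1$q, p_05h = t05$p, p_ko = tko$p,
                    inducible_1h = lps$inducible_1h & expressed,
                    induced_05h = lps$induced_05h & expressed,
                    suppressed_05h = lps$suppressed_05h & expressed,
                    ko_up = ko$ko_up, ko_down = ko$ko_down,
                    superinduced = sup$superinduced,
                    more_suppressed = sup$more_suppressed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("response_calls", "data.frame")
  out
}
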