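# Poisson background model, FDR thresholds, peak calling and annotation.

test_that("background lambda follows the closed form", {
  lib <- tag_library(data.frame(chrom = "chr1", start = 0L, end = 36L,
                                strand = "+"), assay = "chip", total = 1e6)
  lay <- genome_layout(c(chr1 = 1e8))
  m <- fit_background(lib, lay, window_size = 500)
  expect_equal(m$lambda, 5)
  expect_equal(m$n_windows, 1e8 / 250)
  lib0 <- tag_library(data.frame(chrom = character(), start = integer(),
                                 end = integer(), strand = character()),
                      assay = "chip", total = 0)
  expect_error(fit_background(lib0, lay), "zero-depth")
  expect_error(fit_background(lib, genome_layout(c(chr1 = 400))), "exceed")
})

test_that("the FDR threshold matches a direct survival-function scan", {
  set.seed(21)
  lay <- genome_layout(c(chr1 = 5e7))
  lib <- reduce_proseq_tags(generate_null_background(
    chrom_length = 5e7, n_tags = 5e5, assay = "proseq"))
  model <- fit_background(lib, lay, 500)
  expect_equal(model$lambda, 5)
  cnt <- window_counts(lib, lay, 500)
  cnt[sample(length(cnt), 100)] <- 40L
  thr <- fdr_threshold(model, cnt, fdr = 0.001)
  # independent scan: smallest c with expected/observed below the rate
  est <- function(c) {
    model$n_windows * ppois(c - 1, model$lambda, lower.tail = FALSE) /
      max(1, sum(cnt >= c))
  }
  brute <- which(vapply(1:40, est, numeric(1)) < 0.001)[1]
  expect_equal(thr$threshold, brute)
  expect_lte(thr$threshold, 40)
  expect_lt(est(thr$threshold), 0.001)
  expect_gte(est(thr$threshold - 1), 0.001)
})

test_that("the threshold is monotone in lambda and in the nominal rate", {
  set.seed(22)
  lay <- genome_layout(c(chr1 = 2e7))
  lib <- reduce_proseq_tags(generate_null_background(
    chrom_length = 2e7, n_tags = 2e5, assay = "proseq"))
  cnt <- window_counts(lib, lay, 500)
  cnt[sample(length(cnt), 50)] <- 60L
  model <- fit_background(lib, lay, 500)
  t0 <- fdr_threshold(model, cnt, 0.001)$threshold
  hi <- model; hi$lambda <- model$lambda * 3
  expect_gte(fdr_threshold(hi, cnt, 0.001)$threshold, t0)
  expect_lte(fdr_threshold(model, cnt, 0.01)$threshold, t0)
})

test_that("pure-null counts yield no enrichment or a calibrated call set", {
  set.seed(23)
  lay <- genome_layout(c(chr1 = 1e7))
  lib <- reduce_proseq_tags(generate_null_background(
    chrom_length = 1e7, n_tags = 1e5, assay = "proseq"))
  cnt <- window_counts(lib, lay, 500)
  model <- fit_background(lib, lay, 500)
  thr <- tryCatch(fdr_threshold(model, cnt), error = function(e) {
    expect_match(conditionMessage(e), "no significant enrichment")
    NULL
  })
  if (!is.null(thr)) expect_lte(mean(cnt >= thr$threshold), 0.002)
})

test_that("TSS activity is a strict greater-than call", {
  thr <- structure(list(threshold = 38L), class = "enrichment_threshold")
  expect_equal(classify_active_tss(c(38L, 39L, 0L), thr),
               c(FALSE, TRUE, FALSE))
  expect_true(all(classify_active_tss(c(100L, 200L), thr)))
})

test_that("planted sites are recovered as exactly one peak each", {
  set.seed(42)
  lay <- genome_layout(c(chr1 = 1e7))
  bg <- generate_null_background(chrom_length = 1e7, n_tags = 4e4)
  sites <- sort(sample(seq(5e5, 9.5e6, by = 1e4), 10))
  planted <- data.frame(chrom = "chr1",
                        start = rep(sites - 18L, each = 60),
                        end = rep(sites + 18L, each = 60),
                        strand = "+")
  lib <- extend_chip_tags(tag_library(rbind(bg$tags, planted),
                                      assay = "chip", label = "planted"))
  pk <- call_peaks(lib, lay)
  expect_equal(nrow(pk), 10)
  expect_true(all(vapply(sites, function(p)
    any(pk$start <= p & pk$end >= p), logical(1))))
  expect_true(all(diff(order(pk$start)) == 1))  # deterministic order
})

test_that("differential mode drops everything on a self-comparison", {
  set.seed(43)
  lay <- genome_layout(c(chr1 = 1e6))
  t <- data.frame(chrom = "chr1",
                  start = rep(c(5e5, 5e5 + 10), each = 100),
                  strand = "+")
  t$end <- t$start + 36L
  lib <- extend_chip_tags(tag_library(t, assay = "chip"))
  expect_gt(nrow(call_peaks(lib, lay)), 0)
  expect_equal(nrow(call_peaks(lib, lay, background = lib)), 0)
  zero <- tag_library(t[0, ], assay = "chip", state = "extended", total = 0)
  expect_error(call_peaks(lib, lay, background = zero), "zero-depth")
})

test_that("a unit FDR admits every nonzero window on dense even coverage", {
  lay <- genome_layout(c(chr1 = 1e5))
  # evenly spaced point tags: every window occupied, fewer-than-expected
  # empty windows, so the count-1 estimated FDR already clears a unit rate
  pos <- seq(10L, 99900L, by = 100L)
  lib <- tag_library(data.frame(chrom = "chr1", start = pos, end = pos + 1L,
                                strand = "+"),
                     assay = "proseq", state = "reduced")
  pk <- call_peaks(lib, lay, fdr = 1.0)
  expect_equal(attr(pk, "threshold")$threshold, 1L)
  cnt <- window_counts(lib, lay, 500)
  wins <- genome_windows(lay, 500)
  nz <- wins[cnt > 0, ]
  covered <- vapply(seq_len(nrow(nz)), function(i)
    any(pk$chrom == nz$chrom[i] & pk$start <= nz$start[i] &
          pk$end >= nz$end[i]), logical(1))
  expect_true(all(covered))
})

test_that("summit annotation respects the tss > body > intergenic order", {
  genes <- data.frame(symbol = c("A", "B"), transcript_id = c("a", "b"),
                      chrom = "chr1", strand = "+",
                      start = c(10000L, 12000L), end = c(12200L, 20000L),
                      length = c(2200L, 8000L), stringsAsFactors = FALSE)
  reg <- define_regions(genes)
  # summits: in A's TSS; in B's TSS but inside A's body (tss wins);
  # in B's body; intergenic
  pk <- data.frame(chrom = "chr1", start = c(9900L, 11900L, 15000L, 50000L),
                   end = c(10100L, 12100L, 15200L, 50200L),
                   summit = c(10000L, 12000L, 15100L, 50100L),
                   count = 10L, score = 1)
  class(pk) <- c("peaks", "data.frame")
  ann <- annotate_peaks(pk, reg)
  expect_equal(ann$annotation, c("tss", "tss", "gene_body", "intergenic"))
  expect_equal(ann$nearest_gene[3], "B")
})

test_that("the genomic distribution summary recovers planted fractions", {
  genes <- data.frame(symbol = sprintf("g%d", 1:10),
                      transcript_id = sprintf("t%d", 1:10),
                      chrom = "chr1", strand = "+",
                      start = seq(10000L, 910000L, by = 100000L),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + 5000L
  genes$length <- 5000L
  reg <- define_regions(genes)
  summit <- c(reg$tss_pos[1:7],              # 7 in TSS windows
              reg$body_start[8:9] + 1000L,   # 2 in bodies
              5e6L)                          # 1 intergenic
  pk <- data.frame(chrom = "chr1", start = summit - 50L, end = summit + 50L,
                   summit = summit, count = 10L, score = 1)
  class(pk) <- c("peaks", "data.frame")
  expect_equal(unname(genomic_distribution(annotate_peaks(pk, reg))),
               c(0.7, 0.2, 0.1))
})
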