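# Tag loading, extension/reduction, counting, TSS matrices, normalization
# and bedGraph export.

mk_lib <- function(tags, assay = "chip", state = "raw", ...) {
  tag_library(tags, assay = assay, state = state, ...)
}

test_that("BED loading fixes total at load and validates intervals", {
  f <- tempfile(fileext = ".bed")
  writeLines(sprintf("chr1\t%d\t%d\tr%d\t0\t%s", seq(0, 400, 100),
                     seq(36, 436, 100), 1:5, c("+", "-", "+", "-", "+")), f)
  lib <- load_tags(f, assay = "chip")
  expect_equal(lib$total, 5)
  expect_equal(lib$state, "raw")

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t136\tr\t0\t+", "chr1\t200\t200\tr\t0\t+"), bad)
  expect_error(load_tags(bad, assay = "chip"), "line 2")
})

test_that("strandless records warn for ChIP and fail for PRO-seq", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t136", f)
  expect_warning(lib <- load_tags(f, assay = "chip"), "strand")
  expect_equal(lib$tags$strand, "*")
  expect_error(load_tags(f, assay = "proseq"), "strand")
})

test_that("BAM loading counts only mapped primary alignments", {
  skip_if_not_installed("Rsamtools")
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "r1\t0\tchr1\t101\t42\t36M\t*\t0\t0\t*\t*",
    "r2\t16\tchr1\t201\t42\t36M\t*\t0\t0\t*\t*",
    "r3\t0\tchr1\t301\t42\t36M\t*\t0\t0\t*\t*",
    "r4\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r5\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  lib <- load_tags(bam, assay = "chip")
  expect_equal(lib$total, 3)
  expect_equal(lib$tags$start, c(100L, 200L, 300L))
  expect_equal(lib$tags$strand, c("+", "-", "+"))
})

test_that("ChIP extension anchors the 5' end and clips at bounds", {
  t <- data.frame(chrom = "chr1", start = c(100L, 100L),
                  end = c(136L, 136L), strand = c("+", "-"))
  ext <- extend_chip_tags(mk_lib(t), fragment_length = 150)
  expect_equal(ext$tags$start, c(100L, 0L))  # minus read clipped at 0
  expect_equal(ext$tags$end, c(250L, 136L))
  expect_equal(ext$state, "extended")
  # extension to the read's own length is the identity
  id <- extend_chip_tags(mk_lib(t[1, ]), fragment_length = 36)
  expect_equal(id$tags$start, 100L)
  expect_equal(id$tags$end, 136L)
  expect_error(extend_chip_tags(ext), "already processed")
  # clipping at the chromosome end needs a layout
  t2 <- data.frame(chrom = "chr1", start = 980L, end = 1016L, strand = "+")
  lay <- genome_layout(c(chr1 = 1000))
  clipped <- extend_chip_tags(mk_lib(t2), layout = lay)
  expect_equal(clipped$tags$end, 1000L)
})

test_that("three-prime anchoring extends upstream instead", {
  t <- data.frame(chrom = "chr1", start = 1000L, end = 1036L, strand = "+")
  ext <- extend_chip_tags(mk_lib(t), anchor = "three_prime")
  expect_equal(ext$tags$start, 886L)
  expect_equal(ext$tags$end, 1036L)
})

test_that("PRO-seq reduction keeps the 5' base in read orientation", {
  t <- data.frame(chrom = "chr1", start = c(200L, 200L),
                  end = c(275L, 275L), strand = c("+", "-"))
  red <- reduce_proseq_tags(mk_lib(t, assay = "proseq"))
  expect_equal(red$tags$start, c(200L, 274L))
  expect_equal(red$tags$end, c(201L, 275L))
  expect_error(reduce_proseq_tags(red), "already processed")
  expect_error(reduce_proseq_tags(mk_lib(t, assay = "chip")), "PRO-seq")
})

test_that("counting uses >=1 bp overlap for ChIP, antisense 1-bp for PRO-seq", {
  ext <- mk_lib(data.frame(chrom = "chr1", start = 100L, end = 250L,
                           strand = "+"), state = "extended")
  iv <- data.frame(chrom = "chr1", start = 240L, end = 300L)
  expect_equal(count_tags(ext, iv), 1L)
  expect_equal(count_tags(ext, data.frame(chrom = "chr1", start = 250L,
                                          end = 300L)), 0L)
  pro <- mk_lib(data.frame(chrom = "chr1", start = c(150L, 160L),
                           end = c(151L, 161L), strand = c("-", "+")),
                assay = "proseq", state = "reduced")
  expect_equal(count_tags(pro, data.frame(chrom = "chr1", start = 100L,
                                          end = 200L),
                          gene_strand = "+",
                          strand_mode = "sense_via_antisense"), 1L)
  expect_error(count_tags(ext, iv, gene_strand = "+",
                          strand_mode = "sense_via_antisense"), "PRO-seq")
  empty <- mk_lib(data.frame(chrom = character(), start = integer(),
                             end = integer(), strand = character()),
                  state = "extended", total = 1)
  expect_equal(count_tags(empty, iv), 0L)
  expect_error(count_tags(mk_lib(data.frame(chrom = "chr1", start = 1L,
                                            end = 37L, strand = "+")), iv),
               "must be processed")
})

test_that("TSS matrix places tags in transcription-direction bins", {
  genes <- data.frame(symbol = c("gp", "gm"), transcript_id = c("a", "b"),
                      chrom = "chr1", strand = c("+", "-"),
                      start = c(5000L, 20000L), end = c(15000L, 30000L),
                      length = 10000L, stringsAsFactors = FALSE)
  reg <- define_regions(genes)
  # + gene: polymerase at TSS+5 -> 1-bp antisense tag at 5005
  # - gene: 5 bp upstream of its TSS (transcription direction) -> 30004
  tags <- data.frame(chrom = "chr1", start = c(5005L, 30004L),
                     end = c(5006L, 30005L), strand = c("-", "+"))
  m <- tss_matrix(mk_lib(tags, assay = "proseq", state = "reduced"), reg)
  expect_equal(ncol(m$matrix), 300)
  expect_equal(which(m$matrix[1, ] > 0), 101L)  # bin index 100, 0-based
  expect_equal(which(m$matrix[2, ] > 0), 100L)
  expect_error(tss_matrix(mk_lib(tags, assay = "proseq", state = "reduced"),
                          reg, upstream = 995), "divisible")
  empty <- mk_lib(data.frame(chrom = character(), start = integer(),
                             end = integer(), strand = character()),
                  assay = "proseq", state = "reduced", total = 1)
  expect_true(all(tss_matrix(empty, reg)$matrix == 0))
})

test_that("matrix box sums equal direct window counts for 1-bp tags", {
  set.seed(11)
  fx <- random_fixture(n_genes = 15, n_tags = 3000, assay = "proseq")
  m <- tss_matrix(fx$lib, fx$regions)
  box <- rowSums(m$matrix[, 76:125])  # bins covering [-250, 250)
  direct <- count_tags(fx$lib,
                       data.frame(chrom = fx$regions$chrom,
                                  start = fx$regions$tss_start,
                                  end = fx$regions$tss_end),
                       gene_strand = fx$regions$strand,
                       strand_mode = "sense_via_antisense")
  expect_equal(unname(box), direct)
})

test_that("sense-mode counts are invariant under a global strand flip", {
  set.seed(12)
  fx <- random_fixture(n_genes = 10, n_tags = 1000, assay = "proseq")
  flip <- function(s) ifelse(s == "+", "-", "+")
  lib2 <- fx$lib
  lib2$tags$strand <- flip(lib2$tags$strand)
  reg2 <- fx$regions
  reg2$strand <- flip(reg2$strand)
  iv <- data.frame(chrom = fx$regions$chrom, start = fx$regions$tss_start,
                   end = fx$regions$tss_end)
  expect_equal(
    count_tags(fx$lib, iv, fx$regions$strand, "sense_via_antisense"),
    count_tags(lib2, iv, reg2$strand, "sense_via_antisense"))
})

test_that("per-10M scaling is linear and guards a zero total", {
  expect_equal(normalize_per10M(50, 5e6), 100)
  expect_equal(normalize_per10M(7, 1e7), 7)
  expect_error(normalize_per10M(1, 0), "> 0")
  m <- matrix(1:6, 2)
  expect_equal(rowSums(normalize_per10M(m, 2e6)),
               normalize_per10M(rowSums(m), 2e6))
})

test_that("average profiles are per-bin means across genes", {
  m <- structure(list(matrix = rbind(c(0, 2), c(4, 0)), genes = c("a", "b"),
                      bin_size = 10L, upstream = 10L, downstream = 10L,
                      normalization = "raw", strand_mode = "both",
                      total = 10), class = "signal_matrix")
  expect_equal(average_profile(m), c(2, 1))
  m$matrix <- m$matrix[1, , drop = FALSE]
  expect_equal(average_profile(m), c(0, 2))
})

test_that("bedGraph export writes merged per-10M runs", {
  lib <- mk_lib(data.frame(chrom = "chr1", start = 0L, end = 150L,
                           strand = "+"), state = "extended", total = 1e7)
  f <- tempfile(fileext = ".bedgraph")
  export_bedgraph(lib, f)
  lines <- readLines(f)
  expect_match(lines[1], "^track type=bedGraph")
  expect_equal(lines[2], "chr1\t0\t150\t1")
  # two stacked tags pile to value 2 over the overlap
  lib2 <- mk_lib(data.frame(chrom = "chr1", start = c(0L, 100L),
                            end = c(150L, 250L), strand = "+"),
                 state = "extended", total = 1e7)
  export_bedgraph(lib2, f)
  bg <- read.table(f, skip = 1)
  expect_equal(bg$V4[bg$V2 == 100 & bg$V3 == 150], 2)
  # empty library -> header only
  empty <- mk_lib(data.frame(chrom = character(), start = integer(),
                             end = integer(), strand = character()),
                  state = "extended", total = 1)
  export_bedgraph(empty, f)
  expect_length(readLines(f), 1)
})

test_that("bedGraph coverage mass equals tag mass times the 10M scale", {
  set.seed(3)
  t <- data.frame(chrom = "chr1",
                  start = sample(1000:99000, 400, replace = TRUE),
                  strand = sample(c("+", "-"), 400, TRUE))
  t$end <- t$start + 36L
  lib <- extend_chip_tags(mk_lib(t, total = 2e6))
  f <- tempfile()
  export_bedgraph(lib, f)
  bg <- read.table(f, skip = 1)
  expect_equal(sum(bg$V4 * (bg$V3 - bg$V2)), 400 * 150 * 1e7 / 2e6)
})
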