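# PWM construction, scanning, binomial enrichment, promoter extraction.

test_that("PWM construction validates and normalizes the matrix", {
  m <- matrix(c(8, 0, 0, 0,  0, 8, 0, 0,  0, 0, 8, 0,  0, 0, 0, 8), 4)
  p <- make_pwm(m, name = "toy")
  expect_equal(colSums(p$mat), rep(1, 4))
  expect_equal(p$length, 4)
  expect_error(make_pwm(m[1:3, ]), "4 rows")
  expect_error(make_pwm(m[, 1:3]), ">= 4")
  expect_error(make_pwm(-m), "nonnegative")
})

test_that("a planted consensus is found at its planted position", {
  pwm <- pwm_from_consensus("TGACTG")
  seq <- paste0(strrep("A", 10), "TGACTG", strrep("A", 10))
  hits <- scan_pwm(seq, pwm)
  expect_true(11 %in% hits$start[hits$strand == "+"])
  # reverse-complement hit maps back to forward coordinates
  rc <- paste0(strrep("A", 4), "CAGTCA", strrep("A", 6))
  hits_rc <- scan_pwm(rc, pwm)
  expect_true(5 %in% hits_rc$start[hits_rc$strand == "-"])
  # shorter than the motif: empty
  expect_equal(nrow(scan_pwm("TGA", pwm)), 0)
})

test_that("a threshold of 1 admits only exact consensus matches", {
  pwm <- pwm_from_consensus("TGACTG", score_threshold = 1)
  expect_equal(nrow(scan_pwm("AAATGACTGAAA", pwm)), 1)
  expect_equal(nrow(scan_pwm("AAATGACAGAAA", pwm)), 0)  # one mismatch
})

test_that("scanning agrees with exhaustive scoring on both strands", {
  set.seed(71)
  base <- c("A", "C", "G", "T")
  pwm <- make_pwm(matrix(runif(16) + 0.05, 4), name = "rand",
                  score_threshold = 0.6)
  rc1 <- function(s) chartr("ACGT", "TGCA",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score1 <- function(s) {
    v <- match(strsplit(s, "")[[1]], base)
    sum(pwm$logodds[cbind(v, seq_along(v))])
  }
  for (rep in 1:10) {
    seq <- paste(sample(base, 20, replace = TRUE), collapse = "")
    cutoff <- pwm$score_threshold * pwm$max_score
    exp_hits <- list()
    for (i in 1:17) {
      w <- substr(seq, i, i + 3)
      if (score1(w) >= cutoff)
        exp_hits[[length(exp_hits) + 1]] <- c(i, "+")
      if (score1(rc1(w)) >= cutoff)
        exp_hits[[length(exp_hits) + 1]] <- c(i, "-")
    }
    got <- scan_pwm(seq, pwm)
    exp_df <- if (length(exp_hits)) {
      x <- do.call(rbind, exp_hits)
      o <- order(as.integer(x[, 1]), x[, 2])
      data.frame(start = as.integer(x[o, 1]), strand = x[o, 2])
    } else data.frame(start = integer(), strand = character())
    expect_equal(got$start, exp_df$start)
    expect_equal(got$strand, exp_df$strand)
  }
})

test_that("enrichment p equals the closed-form binomial tail on a grid", {
  for (n in c(10, 50, 200)) {
    for (k in unique(pmin(n, c(1, 3, n %/% 2, n)))) {
      for (rate in c(0.01, 0.2, 0.5, 0.9)) {
        p_pkg <- pbinom(k - 1, n, rate, lower.tail = FALSE)
        p_orc <- binom_tail_oracle(k, n, rate)
        expect_lt(abs(p_pkg - p_orc) / max(p_orc, 1e-300), 1e-10)
      }
    }
  }
})

test_that("motif enrichment compares hit fractions via the binomial tail", {
  pwm <- pwm_from_consensus("TGACTCA")
  set.seed(72)
  bg <- random_promoters(600, 200)
  targets <- plant_motif(random_promoters(50, 200), "TGACTCA",
                         fraction = 0.6)
  res <- motif_enrichment(targets, bg, pwm)
  k <- sum(pwm_hits(targets, pwm))
  rate <- mean(pwm_hits(bg, pwm))
  expect_equal(res$p, binom_tail_oracle(k, 50, rate),
               tolerance = 1e-10)
  expect_true(res$enriched)
  # target rate at the background rate: not enriched
  res0 <- motif_enrichment(bg[1:50], bg[51:600], pwm)
  expect_false(res0$enriched)
  expect_gt(res0$p, 0.05)
  # empty background rate with target hits: machine-floor p
  expect_warning(
    resf <- motif_enrichment(c("AAATGACTCAAAA"), rep("AAAAAAAAAAAAA", 130),
                             pwm),
    "machine-floor")
  expect_equal(resf$p, .Machine$double.xmin)
})

test_that("promoter extraction is strand-aware and clipped", {
  genes <- data.frame(symbol = c("P", "M"), transcript_id = c("p", "m"),
                      chrom = "chr1", strand = c("+", "-"),
                      start = c(5000L, 2000L), end = c(9000L, 7000L),
                      length = c(4000L, 5000L), stringsAsFactors = FALSE)
  reg <- define_regions(genes)
  set.seed(73)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chrseq))
  prom <- extract_promoters(reg, genome)
  expect_equal(nchar(prom[["P"]]), 1100)
  expect_equal(prom[["P"]], substr(chrseq, 4001, 5100))
  # minus-strand gene: reverse complement of [TSS-100, TSS+1000)
  fwd <- substr(chrseq, 6901, 8000)
  expect_equal(prom[["M"]],
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(fwd))))
  # a window beyond the chromosome start is clipped with a warning
  genes2 <- genes[1, ]; genes2$start <- 500L; genes2$end <- 4500L
  expect_warning(p2 <- extract_promoters(define_regions(genes2), genome),
                 "clipped")
  expect_equal(nchar(p2[["P"]]), 600)
})

test_that("AP-1 target calling restricts to factor-negative superinduced", {
  pwm <- pwm_from_consensus("TGACTCA")
  set.seed(74)
  prom <- random_promoters(8, 300)
  names(prom) <- sprintf("g%d", 1:8)
  prom[c("g1", "g2", "g3")] <- plant_motif(prom[c("g1", "g2", "g3")],
                                           "TGACTCA")
  nelf <- setNames(c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
                   names(prom))
  bg <- random_promoters(300, 300)
  res <- ap1_target_call(prom, superinduced = c("g1", "g2", "g3", "g4"),
                         nelf_positive = nelf, background_seqs = bg,
                         pwm = pwm)
  expect_setequal(res$genes, c("g1", "g2", "g4"))  # g3 is NELF-positive
  expect_true(res$is_target[["g1"]] && res$is_target[["g2"]])
  expect_equal(res$n, 3)
  expect_gte(res$k, 2)
})

test_that("JASPAR matrices round-trip into working PWMs", {
  f <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA_TEST test",
               "A [ 0 10  0  0 ]",
               "C [ 0  0 10  0 ]",
               "G [10  0  0  0 ]",
               "T [ 0  0  0 10 ]"), f)
  pwms <- read_jaspar(f)
  expect_named(pwms, "MA_TEST")
  hit <- scan_pwm("AAAGACTAAA", pwms$MA_TEST)
  expect_true(4 %in% hit$start[hit$strand == "+"])
})
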