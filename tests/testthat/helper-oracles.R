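# Independent brute-force oracles used to cross-check the package's
# counting and statistics. These deliberately avoid the code paths (and
# interval machinery) of the implementation.

# overlap count of tags (data.frame chrom/start/end[,strand]) in one
# 0-based half-open interval, by plain vector comparison
brute_count <- function(tags, chrom, start, end) {
  sum(tags$chrom == chrom & tags$start < end & tags$end > start)
}

brute_count_antisense <- function(tags, chrom, start, end, gene_strand) {
  anti <- setdiff(c("+", "-"), gene_strand)
  sum(tags$chrom == chrom & tags$strand == anti &
        tags$start < end & tags$end > start)
}

# two-sided Mann-Whitney U from first principles: rank-sum U plus either
# full enumeration (small n, no ties) or the tie-corrected normal
# approximation without continuity correction
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 8 && n2 <= 8) {
    # exact: enumerate all assignments of ranks to the first sample
    all_r <- seq_len(n1 + n2)
    combs <- utils::combn(all_r, n1)
    Us <- colSums(combs) - n1 * (n1 + 1) / 2
    p <- if (U > n1 * n2 / 2) 2 * mean(Us >= U) else 2 * mean(Us <= U)
    return(list(U = U, p = min(1, p)))
  }
  tie_tab <- table(r)
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (U - mu) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))))
}

# two-sample KS statistic by direct ECDF evaluation
ks_stat_oracle <- function(x, y) {
  g <- sort(unique(c(x, y)))
  max(abs(stats::ecdf(x)(g) - stats::ecdf(y)(g)))
}

# exact two-sided two-sample KS p-value by lattice path counting
# (probability that the ECDF difference ever reaches d, under the
# permutation null; no ties assumed)
ks_exact_p_oracle <- function(d, n, m) {
  q <- (0.5 + floor(d * m * n - 1e-7)) / (m * n)
  u <- numeric(m + 1)
  for (j in 0:m) u[j + 1] <- if (j / m > q) 0 else 1
  for (i in 1:n) {
    w <- i / (i + m)
    u[1] <- if (i / n > q) 0 else w * u[1]
    for (j in 1:m) {
      u[j + 1] <- if (abs(i / n - j / m) > q) 0 else w * u[j + 1] + u[j]
    }
  }
  1 - u[m + 1]
}

# upper binomial tail from log-space term summation
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Welch two-sample t-test p-value from the textbook formula
welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * stats::pt(-abs(t), df)
}

# random gene regions + tag set for oracle-equivalence fixtures
random_fixture <- function(n_genes = 30, n_tags = 2000, chrom_len = 2e6,
                           assay = "chip") {
  lens <- sample(1500:6000, n_genes, replace = TRUE)
  gaps <- sample(2000:8000, n_genes, replace = TRUE)
  starts <- 10000 + cumsum(gaps) + c(0, cumsum(lens[-n_genes]))
  genes <- data.frame(symbol = sprintf("f%03d", seq_len(n_genes)),
                      transcript_id = sprintf("ft%03d", seq_len(n_genes)),
                      chrom = "chr1",
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      start = as.integer(starts),
                      end = as.integer(starts + lens),
                      length = as.integer(lens), stringsAsFactors = FALSE)
  regions <- define_regions(genes)
  pos <- sample.int(chrom_len - 200, n_tags, replace = TRUE)
  width <- if (assay == "proseq") 1L else sample(c(36L, 150L), n_tags, TRUE)
  tags <- data.frame(chrom = "chr1", start = pos, end = pos + width,
                     strand = sample(c("+", "-"), n_tags, TRUE),
                     stringsAsFactors = FALSE)
  state <- if (assay == "proseq") "reduced" else "extended"
  list(regions = regions,
       lib = tag_library(tags, assay = assay, state = state,
                         label = "fixture"))
}

# 12-gene hand-built replicate count table covering every response class
# and its boundary cases. FPKM is arranged to equal the replicate-mean
# count exactly (length 1000 bp, library size 1e6), replicates are
# (x - d, x, x + d) so condition means are exact while p-values are tiny.
hand_table <- function() {
  cols <- c("WT_0h", "WT_0.5h", "WT_1h", "KO_0.5h")
  # per-gene condition mean counts
  spec <- rbind(
    # symbol       WT0   WT0.5  WT1  KO0.5   expected classes
    c_null     = c(10,   10,    10,  10),    # expressed only
    c_inducible= c(10,   10,    20,  10),    # inducible_1h (fc 21/11)
    c_ind_bound= c(4,    6,     4,   6),     # induced_05h at exactly 1.4
    c_induced  = c(10,   32,    32,  32),    # induced_05h (+inducible)
    c_sup_bound= c(9,    5,     9,   5),     # suppressed_05h at exactly 0.6
    c_suppress = c(20,   5,     5,   5),     # suppressed_05h
    c_ko_up    = c(10,   10,    10,  21),    # ko_up only (fc 2) not induced
    c_ko_bound = c(4,    4,     4,   6),     # ko_up at exactly 1.4
    c_ko_down  = c(10,   10,    10,  5.5),   # ko_down 6.5/11 ~ 0.59
    c_super    = c(10,   32,    32,  65),    # induced + ko_up = superinduced
    c_moresup  = c(20,   5,     5,   2),     # suppressed + ko_down
    c_unexpr   = c(0.5,  5,     5,   5)      # FPKM < 1 at rest: no classes
  )
  colnames(spec) <- cols
  reps <- 3
  meta <- do.call(rbind, lapply(cols, function(cc) {
    gt <- sub("_.*", "", cc); tm <- sub(".*_", "", cc)
    data.frame(sample = sprintf("%s_%s_r%d", gt, tm, 1:reps),
               genotype = gt, time = tm, replicate = 1:reps,
               stringsAsFactors = FALSE)
  }))
  counts <- matrix(0, nrow(spec), nrow(meta),
                   dimnames = list(rownames(spec), meta$sample))
  d <- 0.25  # binary-exact spread: condition means stay exact, p near zero
  for (cc in cols) {
    for (r in 1:reps) {
      s <- sprintf("%s_r%d", cc, r)
      counts[, s] <- spec[, cc] + (r - 2) * d
    }
  }
  expected <- data.frame(
    symbol = rownames(spec),
    expressed      = c(T, T, T, T, T, T, T, T, T, T, T, F),
    inducible_1h   = c(F, T, F, T, F, F, F, F, F, T, F, F),
    induced_05h    = c(F, F, T, T, F, F, F, F, F, T, F, F),
    suppressed_05h = c(F, F, F, F, T, T, F, F, F, F, T, F),
    ko_up          = c(F, F, F, F, F, F, T, T, F, T, F, F),
    ko_down        = c(F, F, F, F, F, F, F, F, T, F, T, F),
    superinduced   = c(F, F, F, F, F, F, F, F, F, T, F, F),
    more_suppressed= c(F, F, F, F, F, F, F, F, F, F, T, F),
    stringsAsFactors = FALSE
  )
  tab <- expression_table(counts,
                          stats::setNames(rep(1000, nrow(spec)),
                                          rownames(spec)),
                          meta,
                          lib_sizes = stats::setNames(rep(1e6, nrow(meta)),
                                                      meta$sample))
  list(tab = tab, expected = expected)
}
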