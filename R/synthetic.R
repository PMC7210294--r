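# Seeded synthetic multi-assay study generator. Produces an annotation,
# ChIP-seq and PRO-seq tag libraries across conditions, replicate RNA-seq
# counts, promoter sequences, and a per-gene ground-truth table for every
# label the pipeline calls. The generator never reads pipeline outputs.

#' Generator configuration
#'
#' Defaults describe a compact but realistic resting/stimulated macrophage
#' regime: 300 genes on one 10 Mb chromosome, half highly paused, a
#' transient factor dismissal at 0.5 h restored by 1 h, 3-fold
#' induction / 0.3-fold suppression of stimulus-responsive transcripts,
#' and negative-binomial replicate counts with dispersion 0.05.
#'
#' @param n_genes Number of genes (default 300).
#' @param chrom_name,chrom_length Single synthetic chromosome (10 Mb).
#' @param group_fractions Fractions of genes in pausing groups 1/2/3
#'   (default 0.50/0.26/0.24; must sum to 1).
#' @param pi_levels True pausing-index level per group (default 8/2/0.8).
#' @param tss_depth Expected Pol II tags in an active TSS window
#'   (default 100).
#' @param nelf_depth Expected factor (NELF/PU.1) tags in a positive TSS
#'   window (default 100).
#' @param depth_factor Global sequencing-depth multiplier applied to
#'   `tss_depth`, `nelf_depth` and the background rate (default 1).
#' @param bg_rate_per_kb Uniform background tag rate for Pol II ChIP-seq
#'   and PRO-seq libraries (default 0.5 / kb).
#' @param factor_bg_rate_per_kb Uniform background rate for the factor
#'   (NELF/PU.1) ChIP libraries (default 10 / kb). Factor ChIP libraries
#'   are background-dominated (low fraction of reads in peaks), which
#'   keeps library totals stable under global occupancy changes.
#' @param read_length Emitted read length in bp (default 36).
#' @param fragment_length ChIP fragment size the read geometry encodes
#'   (default 150).
#' @param tss_offset,tss_sd Center and spread (bp downstream of TSS) of
#'   promoter-proximal tag placement (defaults +50, sd 80, truncated to
#'   the TSS window).
#' @param inactive_fraction Fraction of group-3 genes with inactive
#'   (background-only) TSSs; these are also the unexpressed genes.
#' @param nelf_prob_by_group,pu1_prob_by_group P(factor-positive | group),
#'   enriched among paused genes.
#' @param nelf_dismissal_fraction Fraction of factor-positive genes whose
#'   occupancy drops at 0.5 h (default 0.5).
#' @param nelf_dismissal_factor Multiplier on dismissed-gene occupancy at
#'   0.5 h, restored at 1 h (default 0.5).
#' @param release_factor Pause-release strength: true PI of LPS-induced
#'   genes is divided by this in the stimulated Pol II library (default 3;
#'   implemented as TSS mass x 2/3 and body density x 2).
#' @param lps_induced_fraction,lps_suppressed_fraction,lps_inducible_fraction
#'   Fractions of genes induced / suppressed at 0.5 h and induced at 1 h
#'   only (defaults 0.2/0.15/0.1).
#' @param lps_fc_induced,lps_fc_suppressed True expression fold changes
#'   (defaults 3 and 0.3).
#' @param ko_effect_fraction Fraction of induced (suppressed) genes that
#'   are further up- (down-)regulated in the knockout (default 0.6).
#' @param ko_fc_up,ko_fc_down True knockout fold changes (defaults 3, 1/3).
#' @param nb_dispersion Negative-binomial dispersion (default 0.05).
#' @param n_replicates Biological replicates per condition (default 3).
#' @param base_expression_meanlog,base_expression_sdlog Log-normal
#'   parameters of baseline expected fragment counts.
#' @param unexpressed_mean Expected counts for unexpressed genes (0.1).
#' @param lib_size Mapped fragments per RNA-seq library (default 1e7). The
#'   simulated genes are a small panel within a stable transcriptome, so
#'   the per-million denominator is this fixed mapped total, not the panel
#'   column sum.
#' @param promoter_upstream,promoter_downstream Promoter window around the
#'   TSS (defaults 1000 and 100 bp).
#' @param ap1_plant_fraction Fraction of NELF-negative superinduced genes
#'   with a planted AP-1 consensus (default 0.7).
#' @param ets_plant_fraction Fraction of group-1 promoters with a planted
#'   ETS consensus (default 0.8).
#' @param seed Integer seed controlling every draw.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_genes = 300, chrom_name = "chr1",
                             chrom_length = 1e7,
                             group_fractions = c(0.50, 0.26, 0.24),
                             pi_levels = c(8, 2, 0.8),
                             tss_depth = 100, nelf_depth = 100,
                             depth_factor = 1, bg_rate_per_kb = 0.5,
                             factor_bg_rate_per_kb = 10,
                             read_length = 36, fragment_length = 150,
                             tss_offset = 50, tss_sd = 80,
                             inactive_fraction = 0.5,
                             nelf_prob_by_group = c(0.9, 0.5, 0.15),
                             pu1_prob_by_group = c(0.85, 0.4, 0.2),
                             nelf_dismissal_fraction = 0.5,
                             nelf_dismissal_factor = 0.5,
                             release_factor = 3,
                             lps_induced_fraction = 0.2,
                             lps_suppressed_fraction = 0.15,
                             lps_inducible_fraction = 0.1,
                             lps_fc_induced = 3, lps_fc_suppressed = 0.3,
                             ko_effect_fraction = 0.6,
                             ko_fc_up = 3, ko_fc_down = 1 / 3,
                             nb_dispersion = 0.05, n_replicates = 3,
                             base_expression_meanlog = log(1000),
                             base_expression_sdlog = 1,
                             unexpressed_mean = 0.1,
                             lib_size = 1e7,
                             promoter_upstream = 1000,
                             promoter_downstream = 100,
                             ap1_plant_fraction = 0.7,
                             ets_plant_fraction = 0.8,
                             seed = 1) {
  cfg <- as.list(environment())
  .stop_if(abs(sum(group_fractions) - 1) > 1e-9,
           "group_fractions must sum to 1")
  .stop_if(any(pi_levels <= 0) || tss_depth <= 0 || nelf_depth <= 0 ||
             depth_factor <= 0 || bg_rate_per_kb < 0, "rates must be positive")
  structure(cfg, class = "generator_config")
}

# -- tag emission helpers ----------------------------------------------------

# ChIP read from a fragment center: read 5' end at one fragment edge so
# that fragment-length extension reconstructs [c - fl/2, c + fl/2)
.emit_chip <- function(centers, chrom, read_length, fragment_length) {
  if (length(centers) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  half <- fragment_length / 2
  plus <- stats::runif(length(centers)) < 0.5
  start <- ifelse(plus, centers - half, centers + half - read_length)
  start <- pmax(0, round(start))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_length),
             strand = ifelse(plus, "+", "-"), stringsAsFactors = FALSE)
}

# PRO-seq read with 5' base (in read orientation) at `pos`, on `strand`
.emit_proseq <- function(pos, strand, chrom, read_length) {
  if (length(pos) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  start <- ifelse(strand == "+", pos, pos - (read_length - 1L))
  start <- pmax(0, round(start))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + read_length),
             strand = strand, stringsAsFactors = FALSE)
}

.rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- round(stats::rnorm(n, mean, sd))
  pmin(pmax(x, lo), hi)
}

.uniform_centers <- function(n, lo, hi) {
  if (n == 0L) return(numeric(0))
  floor(stats::runif(n, lo, hi))
}

# per-gene promoter-proximal centers for one chip library
.tss_centers <- function(n, gene, cfg) {
  dir <- if (gene$strand == "+") 1 else -1
  .rtrunc_norm(n, gene$tss_pos + dir * cfg$tss_offset, cfg$tss_sd,
               gene$tss_start + 1, gene$tss_end - 2)
}

# -- main generator ----------------------------------------------------------

#' Generate a complete synthetic multi-assay study
#'
#' Emits Pol II ChIP-seq tags for resting and LPS-stimulated conditions,
#' NELF-E ChIP-seq at 0 h / 0.5 h / 1 h (with transient dismissal at
#' 0.5 h), PU.1 ChIP-seq, PRO-seq (reads antisense to their gene, 5' base
#' at the polymerase position), replicate RNA-seq fragment counts for
#' WT/KO time courses, promoter sequences with planted motifs, and the
#' ground-truth table. All draws derive from `config$seed`; the same
#' configuration reproduces identical output (and identical files when
#' `dir` is given).
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; when given, all components are
#'   written as plain-text files (refFlat annotation, one BED6 per
#'   assay/condition, counts and sample TSVs, promoter FASTA, truth TSV).
#' @return List with `config`, `genes`, `regions`, `truth`, `libs` (named
#'   list of raw `tag_library` objects), `counts`, `meta`, `lengths`,
#'   `promoters`, and `files` (named paths, or NULL).
#' @export
generate_dataset <- function(config = generator_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  tss_depth <- cfg$tss_depth * cfg$depth_factor
  nelf_depth <- cfg$nelf_depth * cfg$depth_factor
  bg_rate <- cfg$bg_rate_per_kb * cfg$depth_factor

  ## gene models on one chromosome
  n <- cfg$n_genes
  lens <- round(stats::runif(n, 2000, 8000))
  gaps <- round(stats::runif(n, 8000, 20000))
  starts <- 60000 + cumsum(gaps) + c(0, cumsum(lens[-n]))
  ends <- starts + lens
  .stop_if(max(ends) + 2000 > cfg$chrom_length,
           "infeasible config: genes do not fit on the chromosome")
  genes <- data.frame(symbol = sprintf("g%03d", seq_len(n)),
                      transcript_id = sprintf("tx%03d", seq_len(n)),
                      chrom = cfg$chrom_name,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      start = as.integer(starts), end = as.integer(ends),
                      length = as.integer(lens), stringsAsFactors = FALSE)
  regions <- define_regions(genes, tss_flank = 250)

  ## ground-truth labels
  n_g <- round(n * cfg$group_fractions)
  n_g[3] <- n - n_g[1] - n_g[2]
  group <- sample(rep(1:3, n_g))
  true_pi <- cfg$pi_levels[group]
  tss_active <- rep(TRUE, n)
  g3 <- which(group == 3)
  inactive <- sample(g3, round(length(g3) * cfg$inactive_fraction))
  tss_active[inactive] <- FALSE
  nelf_positive <- stats::runif(n) < cfg$nelf_prob_by_group[group]
  nelf_positive[!tss_active] <- FALSE
  pu1_positive <- stats::runif(n) < cfg$pu1_prob_by_group[group]
  pu1_positive[!tss_active] <- FALSE
  dismissed <- rep(FALSE, n)
  pos_idx <- which(nelf_positive)
  dismissed[sample(pos_idx,
                   round(length(pos_idx) * cfg$nelf_dismissal_fraction))] <- TRUE

  ## expression program
  base_mu <- stats::rlnorm(n, cfg$base_expression_meanlog,
                           cfg$base_expression_sdlog)
  base_mu[inactive] <- cfg$unexpressed_mean
  responsive_pool <- setdiff(which(tss_active), inactive)
  paused_pool <- intersect(responsive_pool, which(group <= 2))
  n_ind <- round(n * cfg$lps_induced_fraction)
  induced <- sample(paused_pool, min(n_ind, length(paused_pool)))
  rest_pool <- setdiff(responsive_pool, induced)
  suppressed <- sample(rest_pool, round(n * cfg$lps_suppressed_fraction))
  rest_pool <- setdiff(rest_pool, suppressed)
  inducible1 <- sample(rest_pool, round(n * cfg$lps_inducible_fraction))
  lps_class <- rep("null", n)
  lps_class[induced] <- "induced"
  lps_class[suppressed] <- "suppressed"
  lps_class[inducible1] <- "inducible"
  fc05 <- ifelse(lps_class == "induced", cfg$lps_fc_induced,
                 ifelse(lps_class == "suppressed", cfg$lps_fc_suppressed, 1))
  fc1 <- ifelse(lps_class %in% c("induced", "inducible"), cfg$lps_fc_induced,
                ifelse(lps_class == "suppressed", cfg$lps_fc_suppressed, 1))
  ko_fc <- rep(1, n)
  ko_fc[sample(induced, round(length(induced) * cfg$ko_effect_fraction))] <-
    cfg$ko_fc_up
  ko_fc[sample(suppressed,
               round(length(suppressed) * cfg$ko_effect_fraction))] <-
    cfg$ko_fc_down

  ## truth flags from the classification rules applied to noiseless means
  true_fpkm <- function(mu_vec) {
    mu_vec * 1e9 / (genes$length * cfg$lib_size)
  }
  F0 <- true_fpkm(base_mu)
  F05 <- true_fpkm(base_mu * fc05)
  F1 <- true_fpkm(base_mu * fc1)
  FK05 <- true_fpkm(base_mu * fc05 * ko_fc)
  expressed <- F0 >= 1
  t_inducible <- expressed & fc1 != 1 & .pseudo_fc(F1, F0) >= 1.5
  t_induced <- expressed & fc05 != 1 & .pseudo_fc(F05, F0) >= 1.4
  t_suppressed <- expressed & fc05 != 1 & .pseudo_fc(F05, F0) <= 0.6
  t_ko_up <- expressed & ko_fc > 1 & .pseudo_fc(FK05, F05) >= 1.4
  t_ko_down <- expressed & ko_fc < 1 & .pseudo_fc(FK05, F05) <= 0.6
  t_super <- t_induced & t_ko_up
  t_moresup <- t_suppressed & t_ko_down

  ap1_pool <- which(t_super & !nelf_positive)
  ap1_target <- rep(FALSE, n)
  ap1_target[sample(ap1_pool,
                    round(length(ap1_pool) * cfg$ap1_plant_fraction))] <- TRUE

  if (tss_depth <= 10) {
    warning("TSS depth at or below the practical activity threshold: ",
            "group / factor recovery will be unreliable at this depth")
  }

  ## --- Pol II ChIP libraries -----------------------------------------------
  body_expected <- function(pi_vec) {
    (tss_depth / 0.5) / pi_vec * (regions$body_end - regions$body_start) / 1000
  }
  chip_library <- function(tss_mass, body_mass, label) {
    parts <- vector("list", n + 1L)
    for (i in seq_len(n)) {
      gi <- regions[i, ]
      cts <- numeric(0)
      if (tss_mass[i] > 0) {
        k <- stats::rpois(1, tss_mass[i])
        cts <- c(cts, .tss_centers(k, gi, cfg))
      }
      if (body_mass[i] > 0) {
        k <- stats::rpois(1, body_mass[i])
        cts <- c(cts, .uniform_centers(k, gi$body_start, gi$body_end))
      }
      parts[[i]] <- .emit_chip(cts, cfg$chrom_name, cfg$read_length,
                               cfg$fragment_length)
    }
    nbg <- stats::rpois(1, bg_rate * cfg$chrom_length / 1000)
    parts[[n + 1L]] <- .emit_chip(
      .uniform_centers(nbg, cfg$fragment_length / 2,
                       cfg$chrom_length - cfg$fragment_length / 2),
      cfg$chrom_name, cfg$read_length, cfg$fragment_length)
    tag_library(do.call(rbind, parts), assay = "chip", label = label)
  }

  act <- as.numeric(tss_active)
  polii_rest <- chip_library(tss_depth * act, body_expected(true_pi) * act,
                             "PolII_rest")
  released <- lps_class == "induced"
  tss_lps <- tss_depth * act * ifelse(released, 2 / 3, 1)
  body_lps <- body_expected(true_pi) * act * ifelse(released, 2, 1)
  polii_lps <- chip_library(tss_lps, body_lps, "PolII_LPS")

  ## --- factor ChIP libraries ----------------------------------------------
  fbg_rate <- cfg$factor_bg_rate_per_kb * cfg$depth_factor
  factor_library <- function(mass, label) {
    parts <- vector("list", n + 1L)
    for (i in seq_len(n)) {
      k <- if (mass[i] > 0) stats::rpois(1, mass[i]) else 0L
      parts[[i]] <- .emit_chip(.tss_centers(k, regions[i, ], cfg),
                               cfg$chrom_name, cfg$read_length,
                               cfg$fragment_length)
    }
    nbg <- stats::rpois(1, fbg_rate * cfg$chrom_length / 1000)
    parts[[n + 1L]] <- .emit_chip(
      .uniform_centers(nbg, cfg$fragment_length / 2,
                       cfg$chrom_length - cfg$fragment_length / 2),
      cfg$chrom_name, cfg$read_length, cfg$fragment_length)
    tag_library(do.call(rbind, parts), assay = "chip", label = label)
  }
  nelf_mass <- nelf_depth * as.numeric(nelf_positive)
  nelfe_0h <- factor_library(nelf_mass, "NELFE_0h")
  nelfe_05h <- factor_library(
    nelf_mass * ifelse(dismissed, cfg$nelf_dismissal_factor, 1), "NELFE_0.5h")
  nelfe_1h <- factor_library(nelf_mass, "NELFE_1h")
  pu1_rest <- factor_library(nelf_depth * as.numeric(pu1_positive), "PU1_rest")

  ## --- PRO-seq -------------------------------------------------------------
  proseq_parts <- vector("list", n + 1L)
  pro_body <- body_expected(true_pi)
  for (i in seq_len(n)) {
    if (!tss_active[i]) {
      proseq_parts[[i]] <- .emit_proseq(numeric(0), character(0),
                                        cfg$chrom_name, cfg$read_length)
      next
    }
    gi <- regions[i, ]
    tdir <- if (gi$strand == "+") 1 else -1
    k_p <- stats::rpois(1, tss_depth)
    pos_p <- gi$tss_pos + tdir * sample(20:60, k_p, replace = TRUE)
    k_b <- stats::rpois(1, pro_body[i])
    pos_b <- .uniform_centers(k_b, gi$body_start, gi$body_end)
    read_strand <- if (gi$strand == "+") "-" else "+"
    proseq_parts[[i]] <- .emit_proseq(c(pos_p, pos_b),
                                      rep(read_strand, k_p + k_b),
                                      cfg$chrom_name, cfg$read_length)
  }
  nbg <- stats::rpois(1, bg_rate * cfg$chrom_length / 1000)
  bg_pos <- .uniform_centers(nbg, cfg$read_length, cfg$chrom_length -
                               cfg$read_length)
  proseq_parts[[n + 1L]] <- .emit_proseq(
    bg_pos, sample(c("+", "-"), nbg, replace = TRUE),
    cfg$chrom_name, cfg$read_length)
  proseq_rest <- tag_library(do.call(rbind, proseq_parts), assay = "proseq",
                             label = "PROseq_rest")

  ## --- RNA-seq counts ------------------------------------------------------
  times <- c("0h", "0.5h", "1h")
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates), time = times,
                      genotype = c("WT", "KO"), stringsAsFactors = FALSE)
  meta$sample <- sprintf("%s_%s_r%d", meta$genotype, meta$time, meta$replicate)
  meta <- meta[, c("sample", "genotype", "time", "replicate")]
  meta$lib_size <- cfg$lib_size
  mu_for <- function(genotype, time) {
    fct <- switch(time, "0h" = rep(1, n), "0.5h" = fc05, "1h" = fc1)
    kf <- if (genotype == "KO" && time != "0h") ko_fc else rep(1, n)
    base_mu * fct * kf
  }
  counts <- sapply(seq_len(nrow(meta)), function(j) {
    stats::rnbinom(n, mu = mu_for(meta$genotype[j], meta$time[j]),
                   size = 1 / cfg$nb_dispersion)
  })
  dimnames(counts) <- list(genes$symbol, meta$sample)

  ## --- promoters with planted motifs --------------------------------------
  plen <- cfg$promoter_upstream + cfg$promoter_downstream
  promoters <- random_promoters(n, plen)
  names(promoters) <- genes$symbol
  ets_idx <- which(group == 1 & stats::runif(n) < cfg$ets_plant_fraction)
  promoters[ets_idx] <- plant_motif(promoters[ets_idx], "AGAGGAAGTG")
  ap1_idx <- which(ap1_target)
  promoters[ap1_idx] <- plant_motif(promoters[ap1_idx], "TGACTCA")

  truth <- data.frame(
    symbol = genes$symbol, chrom = genes$chrom, strand = genes$strand,
    start = genes$start, end = genes$end, length = genes$length,
    group = group, true_pi = true_pi, tss_active = tss_active,
    nelf_positive = nelf_positive, dismissed = dismissed,
    pu1_positive = pu1_positive, expressed = expressed,
    base_expression = base_mu, lps_class = lps_class,
    fc_05h_true = fc05, fc_1h_true = fc1, ko_fc_true = ko_fc,
    inducible_1h = t_inducible, induced_05h = t_induced,
    suppressed_05h = t_suppressed, ko_up = ko_fc > 1 & t_ko_up,
    ko_down = ko_fc < 1 & t_ko_down, superinduced = t_super,
    more_suppressed = t_moresup, ap1_target = ap1_target,
    stringsAsFactors = FALSE
  )

  libs <- list(polii_rest = polii_rest, polii_lps = polii_lps,
               nelfe_0h = nelfe_0h, nelfe_05h = nelfe_05h,
               nelfe_1h = nelfe_1h, pu1_rest = pu1_rest,
               proseq_rest = proseq_rest)

  files <- NULL
  if (!is.null(dir)) {
    files <- .write_dataset(dir, cfg, genes, libs, counts, meta, promoters,
                            truth)
  }
  list(config = cfg, genes = genes, regions = regions, truth = truth,
       libs = libs, counts = counts, meta = meta,
       lengths = stats::setNames(genes$length, genes$symbol),
       promoters = promoters, files = files)
}

.write_dataset <- function(dir, cfg, genes, libs, counts, meta, promoters,
                           truth) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  files$annotation <- file.path(dir, "annotation.refflat")
  rf <- genes[, c("symbol", "transcript_id", "chrom", "strand",
                  "start", "end")]
  data.table::fwrite(rf, files$annotation, sep = "\t", col.names = FALSE)
  for (nm in names(libs)) {
    f <- file.path(dir, paste0(nm, ".bed"))
    t <- libs[[nm]]$tags
    bed <- data.frame(t$chrom, t$start, t$end, ".", 0L, t$strand)
    data.table::fwrite(bed, f, sep = "\t", col.names = FALSE)
    files[[nm]] <- f
  }
  files$counts <- file.path(dir, "counts.tsv")
  ct <- data.frame(symbol = rownames(counts),
                   length = genes$length[match(rownames(counts),
                                               genes$symbol)],
                   counts, check.names = FALSE)
  data.table::fwrite(ct, files$counts, sep = "\t")
  files$samples <- file.path(dir, "samples.tsv")
  data.table::fwrite(meta, files$samples, sep = "\t")
  files$promoters <- file.path(dir, "promoters.fa")
  writeLines(paste0(">", names(promoters), "\n", promoters),
             files$promoters)
  files$truth <- file.path(dir, "truth.tsv")
  data.table::fwrite(truth, files$truth, sep = "\t")
  files$layout <- file.path(dir, "layout.tsv")
  data.table::fwrite(data.frame(chrom = cfg$chrom_name,
                                length = cfg$chrom_length),
                     files$layout, sep = "\t")
  lapply(files, normalizePath)
}

#' Uniform random promoter sequences
#'
#' Draws from the current RNG state (seed upstream for reproducibility).
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp (default 1100).
#' @return Character vector of sequences over A/C/G/T.
#' @export
random_promoters <- function(n, length = 1100) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Plant a consensus motif into sequences
#'
#' Overwrites a random window of each selected sequence with the consensus.
#'
#' @param seqs Character vector of sequences.
#' @param consensus Motif string to plant.
#' @param fraction Fraction of sequences to plant into (default 1).
#' @return The sequences with motifs planted.
#' @export
plant_motif <- function(seqs, consensus, fraction = 1) {
  if (length(seqs) == 0L) return(seqs)
  k <- nchar(consensus)
  idx <- which(stats::runif(length(seqs)) < fraction)
  for (i in idx) {
    L <- nchar(seqs[i])
    if (L < k) next
    at <- sample.int(L - k + 1L, 1L)
    substr(seqs[i], at, at + k - 1L) <- consensus
  }
  seqs
}

#' Generate a structure-free uniform background tag library
#'
#' Homogeneous Poisson tags with no planted sites; the calibration input
#' for enrichment false-discovery tests.
#'
#' @param chrom_length Chromosome length in bp (default 1e8).
#' @param n_tags Number of tags (default 1e6).
#' @param chrom_name Chromosome name (default `"chr1"`).
#' @param read_length Read length in bp (default 36).
#' @param assay `"chip"` or `"proseq"`.
#' @param path Optional BED6 output path.
#' @return A raw `tag_library` (and the BED file when `path` is given).
#' @export
generate_null_background <- function(chrom_length = 1e8, n_tags = 1e6,
                                     chrom_name = "chr1", read_length = 36,
                                     assay = "chip", path = NULL) {
  starts <- .uniform_centers(n_tags, 0, chrom_length - read_length)
  tags <- data.frame(chrom = rep(chrom_name, n_tags),
                     start = as.integer(starts),
                     end = as.integer(starts + read_length),
                     strand = sample(c("+", "-"), n_tags, replace = TRUE),
                     stringsAsFactors = FALSE)
  lib <- tag_library(tags, assay = assay, label = "null_background")
  if (!is.null(path)) {
    bed <- data.frame(tags$chrom, tags$start, tags$end, ".", 0L, tags$strand)
    data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  }
  lib
}
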