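# Pipeline orchestration: a single configuration object holding every
# numeric threshold, an end-to-end runner over a study directory, and
# cross-tabulation reporting.

#' Pipeline run configuration
#'
#' Central store of every numeric threshold the pipeline uses, with the
#' standard defaults: 250 bp TSS flank, 1 kb minimum gene length, 500 bp
#' Poisson search window at FDR 0.001, pausing-index cuts 3 / 1.5,
#' fold-change cuts 1.5 (1 h inducible), 1.4 / 0.6 (0.5 h and knockout),
#' 0.5 (dismissal), p/q cuts 0.05, 150 bp ChIP fragment extension,
#' promoter window -1000..+100.
#'
#' @param ... Named overrides of any default.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    tss_flank = 250, min_gene_length = 1000,
    window_size = 500, fdr = 0.001,
    pi_high = 3, pi_moderate = 1.5,
    fragment_length = 150, extension_anchor = "five_prime",
    fc_inducible = 1.5, fc_up = 1.4, fc_down = 0.6,
    q_cut = 0.05, p_cut = 0.05,
    dismissal_fc = 0.5, dismissal_p = 0.05, dismissal_min_fold = 2,
    peak_min_fold = 4,
    promoter_upstream = 1000, promoter_downstream = 100,
    motif_alpha = 0.001, motif_score_threshold = 0.8,
    profile_upstream = 1000, profile_downstream = 2000, profile_bin = 10,
    box = c(-250, 250),
    n_background_promoters = 1000,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  .stop_if(length(unknown) > 0, "unknown config key: %s", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration
#'
#' Round-trips losslessly through a YAML file.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config` the path (invisibly); `read_run_config` the
#'   configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.need_file <- function(dir, name) {
  p <- file.path(dir, name)
  .stop_if(!file.exists(p), "missing input file: %s", p)
  p
}

#' Run the full pausing analysis over a study directory
#'
#' Expects the file layout written by [generate_dataset()] (refFlat
#' annotation, `{assay}_{condition}.bed` tag files, `counts.tsv` +
#' `samples.tsv`, `promoters.fa`, `layout.tsv`) and executes the whole
#' analysis graph: annotation reduction and region definition; tag
#' processing; Poisson-FDR thresholds for Pol II ChIP-seq and PRO-seq;
#' pausing tables for resting and stimulated conditions with an ECDF/KS
#' comparison; NELF occupancy dynamics by both the exact-binomial and the
#' condition-as-background peak methods; NELF+/PU.1+ calls; expression
#' response classes; AP-1 promoter analysis of NELF-negative superinduced
#' genes; and group cross-tabulations.
#'
#' @param input_dir Directory of study inputs.
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, the main tables are
#'   written as TSVs.
#' @return List of class `run_report`.
#' @export
run_all <- function(input_dir, config = run_config(), output_dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)

  ## annotation
  ann <- load_gene_annotation(.need_file(input_dir, "annotation.refflat"),
                              format = "refflat")
  genes <- select_unique_longest(ann, min_length = cfg$min_gene_length)
  regions <- define_regions(genes, tss_flank = cfg$tss_flank)
  lay <- utils::read.table(.need_file(input_dir, "layout.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  layout <- genome_layout(stats::setNames(lay$length, lay$chrom))

  ## tag processing
  chip <- function(name) {
    extend_chip_tags(load_tags(.need_file(input_dir, paste0(name, ".bed")),
                               assay = "chip", label = name),
                     fragment_length = cfg$fragment_length, layout = layout,
                     anchor = cfg$extension_anchor)
  }
  polii_rest <- chip("polii_rest")
  polii_lps <- chip("polii_lps")
  nelfe <- list(`0h` = chip("nelfe_0h"), `0.5h` = chip("nelfe_05h"),
                `1h` = chip("nelfe_1h"))
  pu1 <- chip("pu1_rest")
  proseq <- reduce_proseq_tags(
    load_tags(.need_file(input_dir, "proseq_rest.bed"), assay = "proseq",
              label = "proseq_rest"))

  ## enrichment thresholds (genome-wide windows, applied to TSS windows)
  thr_chip <- fdr_threshold(fit_background(polii_rest, layout,
                                           cfg$window_size),
                            window_counts(polii_rest, layout,
                                          cfg$window_size), cfg$fdr)
  thr_pro <- fdr_threshold(fit_background(proseq, layout, cfg$window_size),
                           window_counts(proseq, layout, cfg$window_size),
                           cfg$fdr)

  ## pausing tables and pause-release comparison
  pt_rest <- pausing_table(polii_rest, regions, thr_chip,
                           high = cfg$pi_high, moderate = cfg$pi_moderate)
  thr_lps <- fdr_threshold(fit_background(polii_lps, layout, cfg$window_size),
                           window_counts(polii_lps, layout, cfg$window_size),
                           cfg$fdr)
  pt_lps <- pausing_table(polii_lps, regions, thr_lps,
                          high = cfg$pi_high, moderate = cfg$pi_moderate)
  pt_pro <- pausing_table(proseq, regions, thr_pro,
                          high = cfg$pi_high, moderate = cfg$pi_moderate)
  ks_release <- compare_pi_distributions(pt_rest$pi, pt_lps$pi)

  ## factor occupancy
  occ <- tss_occupancy_table(nelfe, regions)
  dis <- test_dismissal(occ$`count_0h`, occ$`count_0.5h`,
                        nelfe$`0h`$total, nelfe$`0.5h`$total,
                        fc_cut = cfg$dismissal_fc, p_cut = cfg$dismissal_p)
  occ <- cbind(occ, dis)
  dis_peaks <- dismissal_by_peaks(nelfe$`0h`, nelfe$`0.5h`, regions, layout,
                                  window_size = cfg$window_size,
                                  fdr = cfg$fdr,
                                  min_fold = cfg$dismissal_min_fold)
  nelf_peaks <- annotate_peaks(call_peaks(nelfe$`0h`, layout,
                                          cfg$window_size, cfg$fdr), regions)
  pu1_peaks <- annotate_peaks(call_peaks(pu1, layout, cfg$window_size,
                                         cfg$fdr), regions)
  nelf_pos <- call_factor_positive(nelf_peaks, regions)
  pu1_pos <- call_factor_positive(pu1_peaks, regions)

  ## expression classes
  counts <- data.table::fread(.need_file(input_dir, "counts.tsv"),
                              data.table = FALSE)
  meta <- utils::read.table(.need_file(input_dir, "samples.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  cmat <- as.matrix(counts[, meta$sample, drop = FALSE])
  rownames(cmat) <- counts$symbol
  lib_sizes <- if ("lib_size" %in% names(meta)) {
    stats::setNames(meta$lib_size, meta$sample)
  } else colSums(cmat)
  etab <- expression_table(cmat,
                           stats::setNames(counts$length, counts$symbol),
                           meta, lib_sizes = lib_sizes)
  resp <- response_calls(etab, fc_inducible = cfg$fc_inducible,
                         fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                         q_cut = cfg$q_cut, p_cut = cfg$p_cut)

  ## promoter motif analysis on NELF-negative superinduced genes
  promoters <- .read_promoter_fasta(.need_file(input_dir, "promoters.fa"))
  bg_prom <- random_promoters(cfg$n_background_promoters,
                              cfg$promoter_upstream +
                                cfg$promoter_downstream)
  ap1 <- ap1_target_call(promoters,
                         resp$symbol[resp$superinduced],
                         nelf_pos, bg_prom,
                         pwm = pwm_ap1(score_threshold =
                                         cfg$motif_score_threshold),
                         alpha = cfg$motif_alpha)

  ## summaries
  labels <- list(nelf_positive = names(nelf_pos)[nelf_pos],
                 pu1_positive = names(pu1_pos)[pu1_pos],
                 inducible_1h = resp$symbol[resp$inducible_1h])
  labels <- lapply(labels, intersect, y = pt_rest$symbol)
  groups <- summarize_groups(pt_rest, labels)

  report <- structure(list(
    config = cfg,
    n_genes = nrow(genes),
    thresholds = c(chip = thr_chip$threshold, chip_lps = thr_lps$threshold,
                   proseq = thr_pro$threshold),
    pausing_rest = pt_rest, pausing_lps = pt_lps, pausing_proseq = pt_pro,
    ks_release = ks_release[c("statistic", "p_value")],
    occupancy = occ, dismissal_by_peaks = dis_peaks,
    nelf_positive = nelf_pos, pu1_positive = pu1_pos,
    nelf_peak_distribution = genomic_distribution(nelf_peaks),
    n_nelf_peaks = nrow(nelf_peaks),
    response = resp, ap1 = ap1, group_summary = groups
  ), class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) utils::write.table(
      x, file.path(output_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    w(pt_rest, "pausing_rest.tsv")
    w(pt_lps, "pausing_lps.tsv")
    w(pt_pro, "pausing_proseq.tsv")
    w(occ, "occupancy.tsv")
    w(resp, "response_calls.tsv")
    w(data.frame(symbol = names(dis_peaks), dismissed = dis_peaks),
      "dismissal_by_peaks.tsv")
    w(data.frame(symbol = names(nelf_pos), nelf_positive = nelf_pos,
                 pu1_positive = pu1_pos), "factor_positive.tsv")
  }
  report
}

.read_promoter_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(s), sub("\\s.*", "", names(s)))
}

#' @export
print.run_report <- function(x, ...) {
  cat("pausing pipeline run\n")
  cat(sprintf("  genes: %d\n", x$n_genes))
  cat(sprintf("  activity thresholds: Pol II %d tags, PRO-seq %d tags\n",
              x$thresholds["chip"], x$thresholds["proseq"]))
  gc <- x$group_summary$group_counts
  cat(sprintf("  groups (rest, ChIP): %d / %d / %d (paused fraction %.2f)\n",
              gc[1], gc[2], gc[3], (gc[1] + gc[2]) / sum(gc)))
  cat(sprintf("  pause-release KS: D = %.3f, p = %.3g\n",
              x$ks_release$statistic, x$ks_release$p_value))
  cat(sprintf("  NELF dismissal: %d genes (binomial), %d genes (peaks)\n",
              sum(x$occupancy$dismissed, na.rm = TRUE),
              sum(x$dismissal_by_peaks)))
  cat(sprintf("  superinduced genes: %d; AP-1 targets among NELF-: %d of %d\n",
              sum(x$response$superinduced), x$ap1$k, x$ap1$n))
  invisible(x)
}

#' Cross-tabulate pipeline calls over a shared gene universe
#'
#' Conditional overlap tables between pausing groups and arbitrary boolean
#' gene labels (factor occupancy, response classes).
#'
#' @param pausing A [pausing_table()] result.
#' @param labels Named list of character vectors (or named logical
#'   vectors) of gene symbols.
#' @return A `group_summary` (see [summarize_groups()]).
#' @export
crosstab_report <- function(pausing, labels) {
  labels <- lapply(labels, function(lab) {
    if (is.logical(lab)) lab <- names(lab)[lab]
    intersect(lab, pausing$symbol)
  })
  summarize_groups(pausing, labels)
}
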