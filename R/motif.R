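# Promoter motif analysis: PWM construction and scanning, binomial
# enrichment against background promoters, AP-1 target calling.

.BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param mat 4 x L numeric matrix (rows A, C, G, T) of per-position base
#'   probabilities or counts (counts are normalized per column).
#' @param name Motif name.
#' @param background Base frequencies used for log-odds (default uniform).
#' @param score_threshold Fraction of the maximal log-odds score a window
#'   must reach to count as a hit (default 0.8).
#' @param pseudocount Added to every cell before log-odds (default 1e-3).
#' @return Object of class `pwm`.
#' @export
make_pwm <- function(mat, name = "motif", background = rep(0.25, 4),
                     score_threshold = 0.8, pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  .stop_if(nrow(mat) != 4, "PWM matrix must have 4 rows (A, C, G, T)")
  .stop_if(ncol(mat) < 4, "motif length must be >= 4")
  .stop_if(any(mat < 0), "PWM entries must be nonnegative")
  cs <- colSums(mat)
  .stop_if(any(cs == 0), "PWM has an empty column")
  mat <- sweep(mat, 2, cs, "/")
  rownames(mat) <- .BASES
  prob <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  logodds <- log(prob / background)
  structure(list(name = name, mat = mat, background = background,
                 score_threshold = score_threshold,
                 pseudocount = pseudocount, logodds = logodds,
                 length = ncol(mat), max_score = sum(apply(logodds, 2, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': length %d, hit threshold %.2f x max log-odds (%.3f)\n",
              x$name, x$length, x$score_threshold, x$max_score))
  invisible(x)
}

#' Build a PWM from an IUPAC consensus
#'
#' Each consensus position gives probability `match_prob` to its base
#' (split evenly over the bases of a degenerate IUPAC letter), the
#' remainder spread uniformly over the other bases.
#'
#' @param consensus Consensus string over IUPAC letters.
#' @param name Motif name (defaults to the consensus).
#' @param match_prob Probability mass on consensus bases (default 0.94).
#' @param ... Passed to [make_pwm()].
#' @return A `pwm` object.
#' @export
pwm_from_consensus <- function(consensus, name = consensus,
                               match_prob = 0.94, ...) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"),
                N = c("A", "C", "G", "T"))
  letters <- strsplit(toupper(consensus), "")[[1]]
  .stop_if(!all(letters %in% names(iupac)),
           "unsupported IUPAC letter in consensus")
  mat <- sapply(letters, function(l) {
    hits <- iupac[[l]]
    p <- rep((1 - match_prob) / (4 - length(hits)), 4)
    if (length(hits) == 4) p <- rep(0.25, 4)
    else p[match(hits, .BASES)] <- match_prob / length(hits)
    p
  })
  make_pwm(mat, name = name, ...)
}

#' AP-1 (TRE) position weight matrix
#'
#' Consensus TGASTCA, the 12-O-tetradecanoylphorbol-13-acetate response
#' element bound by Fos/Jun heterodimers.
#'
#' @param ... Passed to [pwm_from_consensus()].
#' @return A `pwm` object.
#' @export
pwm_ap1 <- function(...) pwm_from_consensus("TGASTCA", name = "AP-1", ...)

#' ETS-core (PU.1-like) position weight matrix
#'
#' Purine-rich GGAA-core consensus AGAGGAAGTG characteristic of ETS-family
#' factors such as PU.1.
#'
#' @param ... Passed to [pwm_from_consensus()].
#' @return A `pwm` object.
#' @export
pwm_ets <- function(...) pwm_from_consensus("AGAGGAAGTG", name = "ETS", ...)

#' Read PWMs from a JASPAR-style plain-text file
#'
#' Expects blocks of a `>name` header followed by four rows `A [ 1 2 ... ]`
#' (brackets optional) in A, C, G, T order.
#'
#' @param path File path.
#' @param ... Passed to [make_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, ...) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  .stop_if(length(starts) == 0L, "no JASPAR records (missing '>' headers)")
  out <- list()
  for (s in starts) {
    name <- sub("^>\\s*", "", lines[s])
    name <- strsplit(name, "\\s+")[[1]][1]
    rows <- lines[(s + 1):(s + 4)]
    mat <- t(sapply(rows, function(r) {
      r <- gsub("[][ACGTacgt]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    out[[name]] <- make_pwm(mat, name = name, ...)
  }
  out
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, anything else 0 (N)
.encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], .BASES)
  v[is.na(v)] <- 0L
  v
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# log-odds scores at every start offset of an encoded sequence (N scores 0)
.scan_scores <- function(enc, logodds) {
  L <- ncol(logodds)
  n <- length(enc) - L + 1L
  if (n < 1L) return(numeric(0))
  scores <- numeric(n)
  for (k in seq_len(L)) {
    b <- enc[k:(k + n - 1L)]
    contrib <- numeric(n)
    hit <- b > 0L
    contrib[hit] <- logodds[cbind(b[hit], k)]
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence for PWM hits on both strands
#'
#' Windows scoring at least `score_threshold` times the maximal possible
#' log-odds score are hits; the reverse complement is scanned and hit
#' positions mapped back to forward-strand start coordinates. `N` bases
#' score as background (zero log-odds contribution).
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @param pwm A `pwm` object.
#' @return data.frame: `start` (1-based, forward strand), `strand`,
#'   `score`. Zero rows when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(seq, pwm) {
  .stop_if(!inherits(pwm, "pwm"), "pwm must be a pwm object")
  cutoff <- pwm$score_threshold * pwm$max_score
  slen <- nchar(seq)
  hits <- list()
  fwd <- .scan_scores(.encode_seq(seq), pwm$logodds)
  i <- which(fwd >= cutoff)
  if (length(i) > 0)
    hits[["+"]] <- data.frame(start = i, strand = "+", score = fwd[i])
  rev <- .scan_scores(.encode_seq(.revcomp(seq)), pwm$logodds)
  i <- which(rev >= cutoff)
  if (length(i) > 0)
    hits[["-"]] <- data.frame(start = slen - (i + pwm$length - 1L) + 1L,
                              strand = "-", score = rev[i])
  if (length(hits) == 0)
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Which sequences contain at least one PWM hit
#'
#' @param seqs Character vector of sequences.
#' @param pwm A `pwm` object.
#' @return Logical vector.
#' @export
pwm_hits <- function(seqs, pwm) {
  vapply(seqs, function(s) nrow(scan_pwm(s, pwm)) > 0, logical(1),
         USE.NAMES = !is.null(names(seqs)))
}

#' Binomial motif enrichment of target vs background promoters
#'
#' The background hit rate is the fraction of background promoters with at
#' least one PWM hit; the enrichment p-value is the upper binomial tail
#' P(X >= k | n, rate) for `k` of `n` target promoters with a hit.
#'
#' @param target_seqs,background_seqs Character vectors of promoter
#'   sequences.
#' @param pwm A `pwm` object.
#' @param alpha Enrichment call cutoff on p (default 0.001).
#' @return Object of class `motif_enrichment`: list with `motif`,
#'   `n_target`, `k_target`, `background_rate`, `p`, `enriched`.
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwm,
                             alpha = 0.001) {
  .stop_if(length(target_seqs) == 0L, "no target sequences")
  .stop_if(length(background_seqs) == 0L, "no background sequences")
  if (length(background_seqs) < 10 * length(target_seqs)) {
    warning("background set is smaller than 10x the target set; ",
            "the background rate estimate may be unstable")
  }
  n <- length(target_seqs)
  k <- sum(pwm_hits(target_seqs, pwm))
  rate <- mean(pwm_hits(background_seqs, pwm))
  if (rate == 0 && k > 0) {
    warning("background hit rate is 0 with target hits present; ",
            "reporting machine-floor p-value")
    p <- .Machine$double.xmin
  } else if (rate == 0) {
    p <- 1
  } else {
    p <- stats::pbinom(k - 1, n, rate, lower.tail = FALSE)
  }
  structure(list(motif = pwm$name, n_target = n, k_target = k,
                 background_rate = rate, p = p, enriched = p < alpha),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf(
    "motif '%s': %d/%d target promoters with hits (background rate %.3f), binomial p = %.3g%s\n",
    x$motif, x$k_target, x$n_target, x$background_rate, x$p,
    if (x$enriched) " [enriched]" else ""))
  invisible(x)
}

#' Extract strand-aware promoter sequences
#'
#' Returns the `-upstream..+downstream` window around each TSS (default
#' −1000..+100 bp), reverse-complemented for minus-strand genes so every
#' sequence reads in the direction of transcription. Windows extending
#' past a chromosome end are clipped with a warning.
#'
#' @param regions data.frame from [define_regions()].
#' @param genome A named `Biostrings::DNAStringSet` (or FASTA path) of
#'   chromosome sequences.
#' @param upstream,downstream Window in bp around the TSS (defaults
#'   1000 and 100).
#' @return Named character vector of promoter sequences (by gene symbol).
#' @export
extract_promoters <- function(regions, genome, upstream = 1000,
                              downstream = 100) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*", "", names(genome))
  }
  miss <- setdiff(unique(regions$chrom), names(genome))
  .stop_if(length(miss) > 0, "genome sequence missing for chromosome: %s",
           miss[1])
  clipped <- FALSE
  out <- vapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    clen <- length(genome[[r$chrom]])
    if (r$strand == "+") {
      s0 <- r$tss_pos - upstream; e0 <- r$tss_pos + downstream
    } else {
      s0 <- r$tss_pos - downstream; e0 <- r$tss_pos + upstream
    }
    if (s0 < 0 || e0 > clen) clipped <<- TRUE
    s0 <- max(0, s0); e0 <- min(clen, e0)
    seq <- as.character(Biostrings::subseq(genome[[r$chrom]], s0 + 1, e0))
    if (r$strand == "-") .revcomp(seq) else seq
  }, character(1))
  if (clipped) warning("promoter window clipped at chromosome bounds")
  stats::setNames(out, regions$symbol)
}

#' AP-1 target calls for NELF-negative superinduced genes
#'
#' Restricts to superinduced genes without the factor (NELF-negative),
#' calls a gene an AP-1 target when its promoter contains at least one
#' AP-1 PWM hit, and reports the set-level binomial enrichment against the
#' background promoters.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param superinduced Character vector of superinduced gene symbols.
#' @param nelf_positive Named logical vector of factor status per gene.
#' @param background_seqs Background promoter sequences.
#' @param pwm AP-1 `pwm` (default [pwm_ap1()]).
#' @param alpha Enrichment cutoff (default 0.001).
#' @return List with `genes` (the restricted set), `is_target` (named
#'   logical), `n`, `k`, and `enrichment` (a `motif_enrichment`).
#' @export
ap1_target_call <- function(promoters, superinduced, nelf_positive,
                            background_seqs, pwm = pwm_ap1(),
                            alpha = 0.001) {
  set <- superinduced[!is.na(nelf_positive[superinduced]) &
                        !nelf_positive[superinduced]]
  set <- intersect(set, names(promoters))
  if (length(set) == 0L) {
    return(list(genes = character(), is_target = logical(), n = 0L, k = 0L,
                enrichment = NULL))
  }
  hits <- pwm_hits(promoters[set], pwm)
  enr <- motif_enrichment(promoters[set], background_seqs, pwm, alpha)
  list(genes = set, is_target = hits, n = length(set), k = sum(hits),
       enrichment = enr)
}
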