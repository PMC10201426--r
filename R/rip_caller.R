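#' Peak calling configuration
#'
#' Parameters of the internal input-normalized Poisson enrichment caller,
#' defaulting to the settings used throughout the RIP analysis: per-base
#' q-value cutoff 0.01, 38-nt 5'-end extension of single-end fragments in
#' genomic mode, effective genome length 6199501436 in genomic mode (twice
#' the genome, honoring the strand-split pseudo-chromosome trick) and
#' 289357337 in transcriptomic mode, duplicates kept, a 40-nt minimal peak
#' size, and the reference chromosome set chr1-chr22, X, Y with chrM
#' excluded.
#'
#' @param q_cutoff Per-base BH q-value cutoff (default 0.01), in (0, 1).
#' @param extsize 5'-end extension length in nt (default 38), >= 1.
#' @param max_gap Significant base runs separated by at most this many
#'   non-significant bases are stitched into one peak (default 100 nt,
#'   about the library fragment scale: sub-threshold coverage gaps shorter
#'   than a fragment cannot resolve genuine absence of binding).
#' @param gsize Effective genome length (default 6199501436 genomic /
#'   289357337 transcriptomic).
#' @param keep_dup Duplicate policy; only `"all"` is implemented (the
#'   setting used here).
#' @param min_peak_size Minimal retained peak length in nt (default 40).
#' @param reference_chromosomes Allowed chromosome names (default
#'   chr1-chr22, chrX, chrY; chrM is deliberately absent).
#' @param mode `"genomic"` (extend single-end fragments to `extsize`) or
#'   `"transcriptomic"` (use paired fragments as given, no extension).
#' @return A validated list of class `peak_call_config`.
#' @export
peak_call_config <- function(q_cutoff = 0.01, extsize = 38L,
                             max_gap = 100L, gsize = NULL,
                             keep_dup = "all", min_peak_size = 40L,
                             reference_chromosomes =
                               paste0("chr", c(1:22, "X", "Y")),
                             mode = c("genomic", "transcriptomic")) {
  mode <- match.arg(mode)
  if (is.null(gsize)) {
    gsize <- if (mode == "genomic") 6199501436 else 289357337
  }
  if (gsize <= 0) stop("gsize must be positive")
  if (q_cutoff <= 0 || q_cutoff >= 1) stop("q_cutoff must lie in (0, 1)")
  if (extsize < 1) stop("extsize must be >= 1")
  if (max_gap < 0) stop("max_gap must be >= 0")
  if (min_peak_size < 1) stop("min_peak_size must be >= 1")
  if (!identical(keep_dup, "all")) {
    stop("only keep_dup = 'all' is implemented")
  }
  structure(list(q_cutoff = q_cutoff, extsize = as.integer(extsize),
                 max_gap = as.integer(max_gap),
                 gsize = gsize, keep_dup = keep_dup,
                 min_peak_size = as.integer(min_peak_size),
                 reference_chromosomes = reference_chromosomes,
                 mode = mode),
            class = c("peak_call_config", "list"))
}

# Extend single-end fragments to extsize from their 5' end (internal).
# Unstranded fragments extend rightwards from their start.
extend_5prime <- function(gr, extsize) {
  GenomicRanges::resize(gr, width = extsize, fix = "start")
}

# Survival probability P(X >= k) for X ~ Poisson(lambda): the per-base
# enrichment p-value of the caller (internal).
poisson_tail <- function(k, lambda) {
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

# Truncated-window running mean of v over a centered window (internal).
running_mean <- function(v, window) {
  n <- length(v)
  h <- window %/% 2
  cs <- c(0, cumsum(v))
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(0, seq_len(n) - h - 1)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

#' Call enrichment peaks from IP and input fragments
#'
#' Minimal input-normalized Poisson peak caller modeled on the external
#' caller's fixed-extension mode. In genomic mode every single-end fragment
#' is extended to `extsize` from its 5' end; in transcriptomic mode
#' fragments are used as given. The per-base IP pileup is tested against a
#' local Poisson rate
#' \deqn{\lambda_{local} = \max(\lambda_{BG},\ s\,\bar\lambda_{1kb},\
#'       s\,\bar\lambda_{10kb})}
#' where \eqn{\lambda_{BG}} is the genome-wide IP background
#' (fragments x extension / `gsize`), the local terms are running means of
#' the input pileup over centered 1-kb and 10-kb windows, and
#' \eqn{s} scales the input to the IP library size. Per-base Poisson
#' survival p-values are BH-adjusted over all `gsize` bases (bases without
#' a computed value count as 1), and maximal runs of bases with
#' q < `q_cutoff` become peaks. Duplicate fragments are retained.
#'
#' @param ip,input `GRanges` of IP and input fragments (typically on
#'   strand-split pseudo-chromosomes).
#' @param cfg A [peak_call_config()].
#' @return A `GRanges` of peaks with metadata `pileup_max` (max IP pileup),
#'   `fold_enrichment` (pileup_max over the local rate at the summit) and
#'   `neg_log10_q` (of the best base).
#' @export
call_peaks <- function(ip, input, cfg = peak_call_config()) {
  if (length(ip) == 0) {
    warning("empty IP sample; returning no peaks")
    return(empty_peaks())
  }
  if (length(input) == 0) stop("empty input (control) sample")

  if (cfg$mode == "genomic") {
    ip <- extend_5prime(ip, cfg$extsize)
    input <- extend_5prime(input, cfg$extsize)
  }
  mean_w <- mean(GenomicRanges::width(ip))
  lambda_bg <- length(ip) * mean_w / cfg$gsize
  scale <- length(ip) / length(input)

  chroms <- unique(as.character(GenomicRanges::seqnames(ip)))
  cov_ip <- GenomicRanges::coverage(ip)
  cov_in <- GenomicRanges::coverage(input)

  runs <- list()
  for (chrom in chroms) {
    v_ip <- as.numeric(cov_ip[[chrom]])
    v_in <- if (chrom %in% names(cov_in)) {
      as.numeric(cov_in[[chrom]])
    } else numeric(0)
    L <- max(length(v_ip), length(v_in))
    if (length(v_ip) < L) v_ip <- c(v_ip, numeric(L - length(v_ip)))
    if (length(v_in) < L) v_in <- c(v_in, numeric(L - length(v_in)))
    lambda <- pmax(lambda_bg,
                   scale * running_mean(v_in, 1000L),
                   scale * running_mean(v_in, 10000L))
    p <- rep(1, L)
    nz <- v_ip > 0
    p[nz] <- poisson_tail(v_ip[nz], lambda[nz])
    r <- S4Vectors::Rle(p)
    runs[[chrom]] <- list(p = S4Vectors::runValue(r),
                          len = S4Vectors::runLength(r),
                          pileup = v_ip, lambda = lambda)
  }

  # weighted BH over all gsize bases (uncovered bases carry p = 1)
  all_p <- unlist(lapply(runs, `[[`, "p"), use.names = FALSE)
  all_len <- unlist(lapply(runs, `[[`, "len"), use.names = FALSE)
  o <- order(all_p)
  rank_hi <- cumsum(as.numeric(all_len[o]))
  q_sorted <- pmin(1, all_p[o] * cfg$gsize / rank_hi)
  q_sorted <- rev(cummin(rev(q_sorted)))
  all_q <- numeric(length(all_p))
  all_q[o] <- q_sorted

  peaks <- list()
  offset <- 0L
  for (chrom in chroms) {
    k <- length(runs[[chrom]]$p)
    q_runs <- all_q[offset + seq_len(k)]
    offset <- offset + k
    sig <- S4Vectors::Rle(q_runs < cfg$q_cutoff, runs[[chrom]]$len)
    if (!any(S4Vectors::runValue(sig))) next
    ir <- IRanges::IRanges(sig)  # maximal TRUE runs
    ir <- IRanges::reduce(ir, min.gapwidth = cfg$max_gap + 1L)
    qb <- S4Vectors::Rle(q_runs, runs[[chrom]]$len)
    pk <- vapply(seq_along(ir), function(i) {
      w <- IRanges::start(ir)[i]:IRanges::end(ir)[i]
      pu <- runs[[chrom]]$pileup[w]
      top <- w[which.max(pu)]
      c(max(pu), max(pu) / runs[[chrom]]$lambda[top],
        -log10(max(min(as.numeric(qb[w])), 1e-300)))
    }, numeric(3))
    peaks[[chrom]] <- data.frame(
      chrom = chrom, start = IRanges::start(ir), end = IRanges::end(ir),
      pileup_max = pk[1, ], fold_enrichment = pk[2, ],
      neg_log10_q = pk[3, ], stringsAsFactors = FALSE)
  }
  if (length(peaks) == 0) return(empty_peaks())
  df <- do.call(rbind, peaks)
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), ]
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end), strand = "*",
    pileup_max = df$pileup_max, fold_enrichment = df$fold_enrichment,
    neg_log10_q = df$neg_log10_q)
}

# Empty peak GRanges with the standard metadata columns (internal).
empty_peaks <- function() {
  GenomicRanges::GRanges(pileup_max = numeric(0),
                         fold_enrichment = numeric(0),
                         neg_log10_q = numeric(0))
}
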