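# Brute-force per-base oracles for the interval operations, plus small
# construction helpers shared across test files. Everything works on a
# single toy chromosome in 0-based half-open coordinates, mirroring the
# BED convention, and is deliberately independent of the package's
# GenomicRanges-based implementations.

# GRanges from 0-based half-open coordinates
gr_ho <- function(chrom, start, end, strand = "+", ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start + 1L, end),
                         strand = strand, ...)
}

ho_df <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# random interval set on [0, L)
random_intervals <- function(n, L, min_w = 1, max_w = 400) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample(0:(L - wi), 1), numeric(1))
  data.frame(start = s, end = s + w)
}

# oracle: MOCK subtraction with the 90 percent rule, per target peak
oracle_subtract <- function(target, mock, L, max_fraction = 0.9) {
  bm <- logical(L)
  for (i in seq_len(nrow(mock))) {
    bm[(mock$start[i] + 1):mock$end[i]] <- TRUE
  }
  out <- list()
  for (i in seq_len(nrow(target))) {
    span <- (target$start[i] + 1):target$end[i]
    frac <- sum(bm[span]) / length(span)
    if (frac > max_fraction) next
    keep <- !bm[span]
    r <- rle(keep)
    pos <- cumsum(c(0, r$lengths))
    for (j in which(r$values)) {
      out[[length(out) + 1]] <- c(target$start[i] + pos[j],
                                  target$start[i] + pos[j + 1])
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "end")
  df[order(df$start, df$end), ]
}

# oracle: replicate adjacency consensus + union merge
oracle_combine <- function(rep_list, L) {
  touches <- function(a, b) a$start <= b$end & b$start <= a$end  # 0-gap ok
  retained <- list()
  for (i in seq_along(rep_list)) {
    a <- rep_list[[i]]
    others <- do.call(rbind, rep_list[-i])
    keep <- vapply(seq_len(nrow(a)), function(k) {
      any(a$start[k] <= others$end & others$start <= a$end[k])
    }, logical(1))
    retained[[i]] <- a[keep, , drop = FALSE]
  }
  pool <- do.call(rbind, retained)
  if (nrow(pool) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  bm <- logical(L + 1)
  for (i in seq_len(nrow(pool))) {
    bm[(pool$start[i] + 1):pool$end[i]] <- TRUE
  }
  r <- rle(bm)
  pos <- cumsum(c(0, r$lengths))
  out <- do.call(rbind, lapply(which(r$values), function(j) {
    c(pos[j], pos[j + 1])
  }))
  df <- as.data.frame(out)
  names(df) <- c("start", "end")
  df
}

# oracle: per-base membership of 1-based site positions in peaks
oracle_site_hits <- function(pos, peaks, L) {
  bm <- logical(L)
  for (i in seq_len(nrow(peaks))) {
    bm[(peaks$start[i] + 1):peaks$end[i]] <- TRUE
  }
  bm[pos]
}

# exact Poisson upper tail by explicit summation (oracle for the caller's
# survival p-values); sums P(X = k), k = x..cap
oracle_poisson_tail <- function(x, lambda, cap = 200) {
  sum(stats::dpois(x:cap, lambda))
}

# minimal valid long site table for formats tests
toy_site_table <- function() {
  data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 250L, 40L),
    strand = c("+", "-", "+"),
    ref_base = "A",
    sample_id = c("p150_rep1", "p150_rep1", "p110_rep1"),
    coverage = c(50L, 20L, 0L),
    alt_count = c(5L, 1L, 0L),
    frequency = c(0.1, 0.05, NA),
    stringsAsFactors = FALSE)
}

# small fast synthetic configuration for pipeline-shaped unit tests
small_config <- function(seed = 11, ...) {
  synthetic_config(
    seed = seed,
    chrom_sizes = c(chr1 = 200000L, chr2 = 200000L),
    n_genes = 30L,
    n_sites = c(p150_specific = 60L, p110_specific = 60L, shared = 60L,
                snp_artifact = 10L, below_threshold = 60L),
    n_hyper_genes = c(p150 = 1L, p110 = 1L),
    n_truth_peaks = c(p150 = 6L, p110 = 6L),
    n_mock_peaks = 2L,
    n_fragments = 20000L,
    ...)
}
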