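#' Generate planted RIP truth peaks
#'
#' Draws stranded truth binding regions on the toy annotation: p150 peaks
#' from exons and 3'UTRs, p110 peaks from introns (mirroring the region
#' preference of the cytoplasmic and nuclear isoform), plus a set of
#' `nonspecific` peaks that will be enriched in every IP including the MOCK
#' control and must therefore disappear after MOCK subtraction. Peaks are
#' non-overlapping and lie on the transcript strand. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param annotation Output of [generate_annotation()].
#' @return A `GRanges` with metadata column `condition` in
#'   `p150`/`p110`/`nonspecific`.
#' @export
generate_truth_peaks <- function(cfg, annotation) {
  cfg <- validate_synthetic_config(cfg)
  set.seed(seed_for(cfg, "peaks"))
  feats <- as.data.frame(annotation$genes)
  w <- cfg$truth_peak_width
  # a peak is a width-w window centered on a feature of the preferred type;
  # like real genomic binding regions it may spill into flanking features
  pick <- function(n, feature_types) {
    pool <- feats[feats$feature %in% feature_types, ]
    if (nrow(pool) == 0 || n == 0) return(NULL)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      row <- pool[sample.int(nrow(pool), 1), ]
      mid <- row$start + (row$end - row$start) %/% 2L
      s <- max(0L, mid - w %/% 2L)
      e <- min(annotation$chrom_sizes[[row$chrom]], s + w)
      out[[i]] <- data.frame(chrom = row$chrom, start = s, end = e,
                             strand = row$strand, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  sets <- list(
    p150 = pick(cfg$n_truth_peaks[["p150"]], c("exon", "3UTR")),
    p110 = pick(cfg$n_truth_peaks[["p110"]], "intron"),
    nonspecific = pick(cfg$n_mock_peaks, c("exon", "intron", "3UTR"))
  )
  df <- do.call(rbind, lapply(names(sets), function(cond) {
    s <- sets[[cond]]
    if (is.null(s)) return(NULL)
    s$condition <- cond
    s
  }))
  if (is.null(df)) {
    return(GenomicRanges::GRanges(condition = character(0)))
  }
  gr <- gr_from_halfopen(df$chrom, df$start, df$end, df$strand,
                         condition = df$condition)
  # drop overlaps so every planted peak is unambiguous in truth matching
  keep <- rep(TRUE, length(gr))
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
  keep[unique(S4Vectors::subjectHits(ov))] <- FALSE
  sort(gr[keep])
}

#' Generate RIP-seq fragment files
#'
#' Emits aligned-fragment interval sets for every condition and replicate of
#' the RIP design (`p150`, `p110`, `MOCK`), each with a matched `input`
#' sample. Input fragments are uniform over both strands of the toy genome;
#' IP fragments have their start density multiplied by `cfg$rip_enrichment`
#' inside the truth peaks of their condition (plus the `nonspecific` peaks,
#' which are enriched in every IP including MOCK), on the peak strand only.
#'
#' A fraction `cfg$paired_fraction` of fragments is emitted as mate pairs —
#' two read-length intervals at the fragment ends sharing a name with `/1`
#' and `/2` suffixes (both mates carry the fragment strand) — the rest as
#' single-end read-length records, so pair splitting is exercised without
#' alignment files. Deterministic under `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param annotation Output of [generate_annotation()].
#' @param truth_peaks Output of [generate_truth_peaks()].
#' @return A list with `fragments` (named list of `GRanges`, names like
#'   `p150_rep1_IP` / `p150_rep1_input`, each with a `name` metadata
#'   column) and `truth_peaks`.
#' @export
generate_rip_fragments <- function(cfg, annotation, truth_peaks) {
  cfg <- validate_synthetic_config(cfg)
  set.seed(seed_for(cfg, "rip"))
  sizes <- annotation$chrom_sizes
  conds <- names(cfg$rip_replicates)
  cond_of <- as.character(S4Vectors::mcols(truth_peaks)$condition)

  out <- list()
  for (cond in conds) {
    enriched <- truth_peaks[cond_of %in% c(cond, "nonspecific")]
    for (rep_i in seq_len(cfg$rip_replicates[[cond]])) {
      for (role in c("IP", "input")) {
        sample_id <- sprintf("%s_rep%d_%s", cond, rep_i, role)
        peaks <- if (role == "IP") enriched else truth_peaks[0]
        out[[sample_id]] <- sample_fragments(cfg, sizes, peaks, sample_id)
      }
    }
  }
  list(fragments = out, truth_peaks = truth_peaks)
}

# Draw one sample's fragment records (internal).
sample_fragments <- function(cfg, sizes, peaks, sample_id) {
  n <- cfg$n_fragments
  fl <- cfg$fragment_length
  genome_w <- 2 * sum(sizes)                   # both strands
  # extra component range is [peak_start - fl, peak_end): any fragment
  # start there yields a fragment overlapping the peak, so the overlapping
  # fragment (and read) density inside the peak is exactly enrichment x
  # the background density, with sharp edges
  extra_w <- (cfg$rip_enrichment - 1) *
    (if (length(peaks)) GenomicRanges::width(peaks) + fl else numeric(0))
  w <- c(genome_w, extra_w)
  comp <- sample.int(length(w), n, replace = TRUE, prob = w) - 1L

  chrom <- character(n); start <- integer(n); strand <- character(n)
  bg <- comp == 0L
  n_bg <- sum(bg)
  if (n_bg > 0) {
    ch <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes)
    chrom[bg] <- ch
    start[bg] <- floor(stats::runif(n_bg) * (sizes[ch] - fl))
    strand[bg] <- sample(c("+", "-"), n_bg, replace = TRUE)
  }
  if (any(!bg)) {
    idx <- comp[!bg]
    ps <- GenomicRanges::start(peaks)[idx] - 1L
    pw <- GenomicRanges::width(peaks)[idx]
    chrom[!bg] <- as.character(GenomicRanges::seqnames(peaks))[idx]
    start[!bg] <- pmax(0L, ps - fl +
                         floor(stats::runif(sum(!bg)) * (pw + fl)))
    strand[!bg] <- as.character(GenomicRanges::strand(peaks))[idx]
  }
  end <- start + fl

  paired <- stats::runif(n) < cfg$paired_fraction
  rl <- cfg$read_length
  base <- sprintf("%s_f%06d", sample_id, seq_len(n))
  rec <- rbind(
    data.frame(chrom = chrom[paired], start = start[paired],
               end = start[paired] + rl,
               name = paste0(base[paired], "/1"),
               strand = strand[paired], stringsAsFactors = FALSE),
    data.frame(chrom = chrom[paired], start = end[paired] - rl,
               end = end[paired], name = paste0(base[paired], "/2"),
               strand = strand[paired], stringsAsFactors = FALSE),
    data.frame(chrom = chrom[!paired], start = start[!paired],
               end = start[!paired] + rl, name = base[!paired],
               strand = strand[!paired], stringsAsFactors = FALSE)
  )
  rec <- rec[order(rec$chrom, rec$start, rec$name, method = "radix"), ]
  gr_from_halfopen(rec$chrom, rec$start, rec$end, rec$strand,
                   name = rec$name)
}
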