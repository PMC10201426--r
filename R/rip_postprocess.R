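#' Combine replicate peak lists by cross-replicate adjacency
#'
#' A replicate peak is retained only when it overlaps, or is book-ended
#' with (zero gap), at least one peak from a *different* replicate. The
#' retained peaks of all replicates are then unioned — overlapping or
#' book-ended retained peaks merged — into one peak list per condition.
#' Strand-aware when peaks carry strands.
#'
#' @param peak_lists A list of >= 2 `GRanges`, one per replicate.
#' @return A merged `GRanges` of condition peaks (metadata columns are
#'   dropped by the union; `n_support` records how many retained replicate
#'   peaks each merged peak absorbed).
#' @export
combine_replicates <- function(peak_lists) {
  if (length(peak_lists) < 2) {
    stop("replicate combination needs at least 2 replicate peak lists")
  }
  levels <- unique(unlist(lapply(peak_lists, GenomeInfoDb::seqlevels)))
  peak_lists <- lapply(peak_lists, function(gr) {
    GenomeInfoDb::seqlevels(gr) <- levels
    gr
  })
  retained <- vector("list", length(peak_lists))
  for (i in seq_along(peak_lists)) {
    others <- do.call(c, unname(peak_lists[-i]))
    hit <- GenomicRanges::countOverlaps(peak_lists[[i]], others,
                                        maxgap = 0L) > 0
    retained[[i]] <- peak_lists[[i]][hit]
  }
  pool <- do.call(c, unname(retained))
  if (length(pool) == 0) return(GenomicRanges::GRanges(n_support = integer(0)))
  merged <- GenomicRanges::reduce(pool)  # merges overlap and 0-gap
  S4Vectors::mcols(merged)$n_support <-
    GenomicRanges::countOverlaps(merged, pool, maxgap = 0L)
  sort(merged)
}

#' Subtract MOCK control peaks
#'
#' For each target (isoform) peak, the fraction of *its* length covered by
#' the union of overlapping MOCK peaks decides its fate: more than 90%
#' covered and the peak is removed completely; otherwise only the covered
#' bases are excised and each remaining fragment becomes a peak inheriting
#' the parent's scores (fragments then face the downstream size filter
#' like any peak). Strand-aware.
#'
#' @param target A `GRanges` of condition peaks.
#' @param mock A `GRanges` of MOCK peaks.
#' @param max_fraction Removal threshold on the covered fraction
#'   (default 0.90, exclusive: exactly 90% keeps the remainder).
#' @return A `GRanges` of subtracted peaks; metadata columns of `target`
#'   are inherited by the fragments.
#' @export
subtract_control_peaks <- function(target, mock, max_fraction = 0.90) {
  if (length(target) == 0 || length(mock) == 0) return(target)
  ov <- GenomicRanges::findOverlaps(target, mock, ignore.strand = FALSE)
  if (length(ov) == 0) return(target)
  qh <- S4Vectors::queryHits(ov)
  inter <- GenomicRanges::pintersect(target[qh],
                                     mock[S4Vectors::subjectHits(ov)])
  S4Vectors::mcols(inter) <- NULL
  # per-target union of the mock overlap
  by_target <- GenomicRanges::reduce(
    S4Vectors::split(inter, factor(qh, levels = seq_along(target))))
  frac <- sum(GenomicRanges::width(by_target)) /
    GenomicRanges::width(target)

  trim <- frac > 0 & frac <= max_fraction
  frags <- GenomicRanges::psetdiff(target[trim], by_target[trim])
  nfrag <- lengths(frags)
  out_trim <- unlist(frags, use.names = FALSE)
  S4Vectors::mcols(out_trim) <-
    S4Vectors::mcols(target)[rep(which(trim), nfrag), , drop = FALSE]
  sort(c(target[frac == 0], out_trim))
}

#' Size and reference-chromosome peak filter
#'
#' Removes peaks shorter than the minimal peak size (40 nt by default; the
#' boundary is inclusive, a 40-nt peak is kept) and peaks on chromosomes
#' outside the reference set (chrM in particular is excluded).
#'
#' @param peaks A `GRanges`.
#' @param cfg A [peak_call_config()] providing `min_peak_size` and
#'   `reference_chromosomes`.
#' @return The filtered `GRanges`.
#' @export
filter_peaks <- function(peaks, cfg = peak_call_config()) {
  keep <- GenomicRanges::width(peaks) >= cfg$min_peak_size &
    as.character(GenomicRanges::seqnames(peaks)) %in%
      cfg$reference_chromosomes
  peaks[keep]
}

#' Remove redundant transcriptomic subpeaks
#'
#' Transcriptomic peaks projected to genomic coordinates can be redundant
#' across transcripts of one locus: a peak whose genomic projection is
#' fully contained in another peak's projection from a *different*
#' transcript is removed; exact duplicates keep the representative with
#' the lexicographically lowest transcript id.
#'
#' @param peaks A `GRanges` of genomic projections with a `transcript_id`
#'   metadata column.
#' @return The deduplicated `GRanges`.
#' @export
remove_subpeaks <- function(peaks) {
  if (length(peaks) < 2) return(peaks)
  tx <- as.character(S4Vectors::mcols(peaks)$transcript_id)
  if (is.null(tx) || any(is.na(tx))) {
    stop("peaks must carry a transcript_id metadata column")
  }
  ov <- GenomicRanges::findOverlaps(peaks, peaks, type = "within",
                                    ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same_span <- GenomicRanges::start(peaks)[qh] ==
    GenomicRanges::start(peaks)[sh] &
    GenomicRanges::end(peaks)[qh] == GenomicRanges::end(peaks)[sh]
  other_tx <- tx[qh] != tx[sh]
  # strict containment in a different transcript's peak
  drop <- unique(qh[other_tx & !same_span])
  # exact duplicates: keep the lowest transcript id
  dup <- other_tx & same_span & qh != sh & tx[qh] > tx[sh]
  drop <- union(drop, unique(qh[dup]))
  if (length(drop) == 0) return(peaks)
  peaks[-drop]
}

#' Exclude fragments overlapping a removal list
#'
#' Generic interval-exclusion step (e.g. an artifact-region blacklist):
#' fragments overlapping any interval of the exclusion set are dropped
#' before peak calling.
#'
#' @param fragments A `GRanges`.
#' @param exclusion A `GRanges` of regions to avoid (strand-ignorant).
#' @return The filtered fragments.
#' @export
exclude_intervals <- function(fragments, exclusion) {
  if (length(exclusion) == 0) return(fragments)
  hit <- GenomicRanges::countOverlaps(fragments, exclusion,
                                      ignore.strand = TRUE) > 0
  fragments[!hit]
}
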