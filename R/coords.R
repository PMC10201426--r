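#' Coordinate conventions
#'
#' Two conventions coexist in this package, matching the source formats
#' bit-exactly: genomic *intervals* (BED, peaks, fragments, gene features,
#' repeats) are 0-based half-open `[start, end)`; point editing *sites* are
#' 1-based positions, as emitted by per-site variant profilers. The only
#' conversion is: a site at 1-based position `p` occupies the half-open
#' interval `[p - 1, p)`.
#'
#' Internally, interval arithmetic is delegated to
#' [GenomicRanges::GRanges-class] objects, which are 1-based closed; the
#' translation (`start1 = start0 + 1`, `end1 = end0`) happens only at the
#' boundary of the two helper functions below and of the BED readers/writers.
#'
#' @name coordinates
NULL

#' Convert a 1-based site position to a half-open interval
#'
#' @param pos Integer vector of 1-based positions (must be >= 1).
#' @return A two-column data.frame with 0-based half-open `start`, `end`.
#' @seealso [interval_to_pos()]
#' @export
pos_to_interval <- function(pos) {
  if (any(pos < 1L)) stop("site positions are 1-based and must be >= 1")
  data.frame(start = pos - 1L, end = pos)
}

#' Convert half-open single-base intervals back to 1-based positions
#'
#' @param start,end 0-based half-open interval bounds; every interval must
#'   have length 1 (`end - start == 1`).
#' @return Integer vector of 1-based positions.
#' @export
interval_to_pos <- function(start, end) {
  if (any(end - start != 1L)) {
    stop("only single-base intervals correspond to point sites")
  }
  start + 1L
}

# GRanges from 0-based half-open coordinates (internal).
gr_from_halfopen <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand,
    ...
  )
}

# 0-based half-open data.frame view of a GRanges (internal).
halfopen_from_gr <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}
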