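#' Fold strands into pseudo-chromosomes
#'
#' The internal peak caller (like the external one it models) is not
#' strand-aware, so stranded fragments are moved onto per-strand
#' pseudo-chromosomes before calling — `chrN` becomes `chrN__fwd` (plus
#' strand) or `chrN__rev` (minus strand) — and the resulting peaks are
#' mapped back afterwards with [merge_strands()]. The round trip is
#' lossless. Unstranded (`*`) fragments go to `__fwd`.
#'
#' @param fragments A `GRanges` with strand information.
#' @return A `GRanges` on pseudo-chromosomes; original strand is kept on
#'   the ranges (the caller uses it for 5'-end extension).
#' @export
split_strands <- function(fragments) {
  s <- as.character(GenomicRanges::strand(fragments))
  suffix <- ifelse(s == "-", "__rev", "__fwd")
  chrom <- paste0(as.character(GenomicRanges::seqnames(fragments)), suffix)
  out <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(GenomicRanges::start(fragments),
                            GenomicRanges::end(fragments)),
    strand = GenomicRanges::strand(fragments))
  S4Vectors::mcols(out) <- S4Vectors::mcols(fragments)
  out
}

#' Restore real chromosomes and strand from pseudo-chromosomes
#'
#' Inverse of [split_strands()]: strips the `__fwd` / `__rev` suffix and
#' sets the strand accordingly. An unknown suffix is an error.
#'
#' @param gr A `GRanges` on pseudo-chromosomes (fragments or peaks).
#' @return A stranded `GRanges` on the original chromosomes.
#' @export
merge_strands <- function(gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  is_fwd <- grepl("__fwd$", chrom)
  is_rev <- grepl("__rev$", chrom)
  if (!all(is_fwd | is_rev)) {
    stop("unknown pseudo-chromosome suffix: ",
         paste(utils::head(unique(chrom[!(is_fwd | is_rev)]), 3),
               collapse = ", "))
  }
  out <- GenomicRanges::GRanges(
    sub("__(fwd|rev)$", "", chrom),
    IRanges::IRanges(GenomicRanges::start(gr), GenomicRanges::end(gr)),
    strand = ifelse(is_rev, "-", "+"))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

#' Split mate-pair records into single-end intervals
#'
#' Paired fragments are encoded as two interval records sharing a name with
#' `/1` and `/2` suffixes. Treating a pair as one long fragment would
#' produce peaks spanning unread interior (e.g. whole introns), so each
#' mate becomes its own single-end interval at its own coordinates;
#' unpaired records pass through unchanged. Mates of one pair reported on
#' different chromosomes are an error.
#'
#' @param fragments A `GRanges` with a `name` metadata column.
#' @return A `GRanges` of single-end intervals (pairs x 2 + singletons).
#' @export
split_pairs <- function(fragments) {
  nm <- S4Vectors::mcols(fragments)$name
  if (is.null(nm)) return(fragments)
  mate <- grepl("/[12]$", nm)
  base <- sub("/[12]$", "", nm)
  if (any(mate)) {
    pair_chrom <- split(as.character(
      GenomicRanges::seqnames(fragments))[mate], base[mate])
    bad <- vapply(pair_chrom, function(x) length(unique(x)) > 1, logical(1))
    if (any(bad)) {
      stop("mates on different chromosomes: ",
           paste(utils::head(names(pair_chrom)[bad], 3), collapse = ", "))
    }
  }
  out <- fragments
  S4Vectors::mcols(out)$name <- base
  out
}
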