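#' Summary statistics of final peak lists
#'
#' Deterministic summary across named peak lists: per-list count and
#' mean/median peak size (NA for empty lists), optional gene-region and
#' repeat distributions, and *directional* inter-condition overlap counts —
#' for each ordered pair of lists, how many peaks of the first overlap at
#' least one peak of the second. Because one peak may overlap several peaks
#' of the other list, the two directions of a pair may legitimately differ.
#'
#' @param peak_sets Named list of `GRanges`.
#' @param gene_models Optional `gene_models` for region distributions.
#' @param repeats Optional repeat `GRanges` for repeat distributions.
#' @param ignore_strand Overlap counting ignores strand when TRUE
#'   (default FALSE).
#' @return A list with `sizes` (count, mean_size, median_size per list),
#'   `overlaps` (directional counts), and optionally `regions`, `repeats`.
#' @export
peak_stats <- function(peak_sets, gene_models = NULL, repeats = NULL,
                       ignore_strand = FALSE) {
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  sizes <- do.call(rbind, lapply(names(peak_sets), function(nm) {
    w <- GenomicRanges::width(peak_sets[[nm]])
    data.frame(set = nm, n = length(w),
               mean_size = if (length(w)) mean(w) else NA_real_,
               median_size = if (length(w)) stats::median(w) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  pairs <- expand.grid(from = names(peak_sets), to = names(peak_sets),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  pairs$n_overlapping <- vapply(seq_len(nrow(pairs)), function(i) {
    sum(GenomicRanges::countOverlaps(peak_sets[[pairs$from[i]]],
                                     peak_sets[[pairs$to[i]]],
                                     ignore.strand = ignore_strand) > 0)
  }, numeric(1))
  out <- list(sizes = sizes, overlaps = pairs)

  if (!is.null(gene_models)) {
    out$regions <- do.call(rbind, lapply(names(peak_sets), function(nm) {
      pk <- peak_sets[[nm]]
      if (length(pk) == 0) return(NULL)
      t <- table(annotate_peak(pk, gene_models)$region)
      data.frame(set = nm, region = names(t), n = as.integer(t),
                 fraction = as.numeric(t) / length(pk),
                 stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(repeats)) {
    out$repeats <- do.call(rbind, lapply(names(peak_sets), function(nm) {
      pk <- peak_sets[[nm]]
      if (length(pk) == 0) return(NULL)
      t <- table(assign_repeat_class(pk, repeats))
      data.frame(set = nm, repeat_class = names(t), n = as.integer(t),
                 fraction = as.numeric(t) / length(pk),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
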