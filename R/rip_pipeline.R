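#' Run the RIP peak post-processing chain
#'
#' End-to-end per-condition peak workflow on stranded fragment sets:
#' optional interval exclusion, mate-pair splitting, strand folding onto
#' pseudo-chromosomes, per-replicate enrichment calling against the
#' matched input, strand restoration, cross-replicate adjacency consensus,
#' fractional MOCK subtraction, and the size / reference-chromosome
#' filter. Per-stage peak counts are collected as a funnel.
#'
#' @param fragments Named list of fragment `GRanges` with names
#'   `<condition>_rep<i>_IP` / `<condition>_rep<i>_input` (as produced by
#'   [generate_rip_fragments()]).
#' @param conditions Condition names to call peaks for (default `p150`,
#'   `p110`); the MOCK condition is processed the same way and then
#'   subtracted.
#' @param mock Name of the MOCK condition (default `"MOCK"`; set `NULL` to
#'   skip subtraction).
#' @param cfg A [peak_call_config()].
#' @param exclusion Optional `GRanges` of regions whose fragments are
#'   dropped before calling.
#' @return A list of class `rip_result`: `peaks` (named list of final
#'   `GRanges` per condition), `combined` (pre-subtraction consensus
#'   lists, including MOCK), `replicate_peaks` (nested per-replicate
#'   lists), and `funnel` (per-condition stage counts).
#' @export
run_rip <- function(fragments, conditions = c("p150", "p110"),
                    mock = "MOCK", cfg = peak_call_config(),
                    exclusion = NULL) {
  all_conds <- unique(c(conditions, mock))
  rep_peaks <- list()
  funnel <- list()
  for (cond in all_conds) {
    ips <- grep(sprintf("^%s_rep[0-9]+_IP$", cond), names(fragments),
                value = TRUE)
    if (length(ips) == 0) stop("no IP samples found for condition ", cond)
    rep_peaks[[cond]] <- lapply(ips, function(ip_name) {
      input_name <- sub("_IP$", "_input", ip_name)
      if (!input_name %in% names(fragments)) {
        stop("missing input sample: ", input_name)
      }
      ip <- fragments[[ip_name]]
      input <- fragments[[input_name]]
      if (!is.null(exclusion)) {
        ip <- exclude_intervals(ip, exclusion)
        input <- exclude_intervals(input, exclusion)
      }
      pk <- call_peaks(split_strands(split_pairs(ip)),
                       split_strands(split_pairs(input)), cfg)
      if (length(pk) > 0) merge_strands(pk) else
        GenomicRanges::GRanges(pileup_max = numeric(0),
                               fold_enrichment = numeric(0),
                               neg_log10_q = numeric(0))
    })
    names(rep_peaks[[cond]]) <- ips
    funnel[[cond]] <- c(replicate_peaks =
                          sum(vapply(rep_peaks[[cond]], length, integer(1))))
  }

  combined <- lapply(rep_peaks, combine_replicates)
  for (cond in all_conds) {
    funnel[[cond]]["combined"] <- length(combined[[cond]])
  }

  final <- list()
  for (cond in conditions) {
    pk <- combined[[cond]]
    if (!is.null(mock)) {
      pk <- subtract_control_peaks(pk, combined[[mock]])
      funnel[[cond]]["mock_subtracted"] <- length(pk)
    }
    pk <- filter_peaks(pk, cfg)
    funnel[[cond]]["filtered"] <- length(pk)
    final[[cond]] <- pk
  }
  structure(list(peaks = final, combined = combined,
                 replicate_peaks = rep_peaks, funnel = funnel),
            class = "rip_result")
}

#' Match called peaks against planted truth
#'
#' Reciprocal-overlap matching used for planted-truth recovery: a called
#' peak and a truth peak match when their intersection covers at least
#' `min_reciprocal` of *both* peaks. Recall is the fraction of truth peaks
#' matched; precision the fraction of called peaks matched.
#'
#' @param called,truth `GRanges`.
#' @param min_reciprocal Reciprocal overlap fraction (default 0.5).
#' @param ignore_strand Ignore strand when matching (default FALSE).
#' @return A list with `recall`, `precision`, `n_called`, `n_truth`.
#' @export
match_truth_peaks <- function(called, truth, min_reciprocal = 0.5,
                              ignore_strand = FALSE) {
  if (length(called) == 0 || length(truth) == 0) {
    return(list(recall = 0, precision = 0, n_called = length(called),
                n_truth = length(truth)))
  }
  ov <- GenomicRanges::findOverlaps(called, truth,
                                    ignore.strand = ignore_strand)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    called[S4Vectors::queryHits(ov)], truth[S4Vectors::subjectHits(ov)],
    ignore.strand = ignore_strand))
  good <- inter >= min_reciprocal *
    GenomicRanges::width(called)[S4Vectors::queryHits(ov)] &
    inter >= min_reciprocal *
      GenomicRanges::width(truth)[S4Vectors::subjectHits(ov)]
  list(recall = length(unique(S4Vectors::subjectHits(ov)[good])) /
         length(truth),
       precision = length(unique(S4Vectors::queryHits(ov)[good])) /
         length(called),
       n_called = length(called), n_truth = length(truth))
}
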