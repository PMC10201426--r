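#' Per-gene editing-event counts
#'
#' Counts qualifying editing sites per gene for an isoform subset and
#' summarizes the count distribution the way a box plot would (quartiles
#' and whiskers at 1.5x the interquartile range). Genes with zero
#' qualifying sites are excluded from the distribution. The stock subsets
#' mirror the hyperediting analysis: all efficiently edited sites per
#' isoform, and the strongly preferred sites (`log2fd <= -1` for p150,
#' `log2fd >= 1` for p110).
#'
#' @param classification Classification table from [run_editome()] with
#'   `gene_id` annotation.
#' @param subset One of `"efficient_p150"`, `"efficient_p110"`,
#'   `"preferred_p150"`, `"preferred_p110"`, or a logical vector over the
#'   classification rows.
#' @return A list with `counts` (data.frame `gene_id`, `n_sites`) and
#'   `summary` (q1, median, q3, whisker_low, whisker_high, n_genes).
#' @export
events_per_region <- function(classification, subset = "efficient_p150") {
  cls <- classification
  if (is.character(subset)) {
    pick <- switch(subset,
      efficient_p150 = cls$efficient_p150,
      efficient_p110 = cls$efficient_p110,
      preferred_p150 = cls$log2fd <= -1,
      preferred_p110 = cls$log2fd >= 1,
      stop("unknown subset: ", subset))
  } else {
    stopifnot(length(subset) == nrow(cls))
    pick <- subset
  }
  pick <- pick & !is.na(cls$gene_id)
  t <- table(cls$gene_id[pick])
  counts <- data.frame(gene_id = as.character(names(t)),
                       n_sites = as.integer(t),
                       stringsAsFactors = FALSE)
  counts <- counts[counts$n_sites > 0, , drop = FALSE]
  if (nrow(counts) == 0) {
    return(list(counts = counts,
                summary = data.frame(q1 = NA_real_, median = NA_real_,
                                     q3 = NA_real_, whisker_low = NA_real_,
                                     whisker_high = NA_real_, n_genes = 0L)))
  }
  q <- stats::quantile(counts$n_sites, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  inside <- counts$n_sites >= q[1] - 1.5 * iqr &
    counts$n_sites <= q[3] + 1.5 * iqr
  list(counts = counts,
       summary = data.frame(q1 = q[1], median = q[2], q3 = q[3],
                            whisker_low = min(counts$n_sites[inside]),
                            whisker_high = max(counts$n_sites[inside]),
                            n_genes = nrow(counts)))
}

#' Summary tables of an editome classification
#'
#' Deterministic summary of a classification table: counts per preference
#' label (which partition the classified sites), efficiency and exclusivity
#' counts, and — where the annotation columns are present — gene-region and
#' repeat-class distributions for the efficiently edited set of each
#' isoform.
#'
#' @param classification Classification table from [run_editome()].
#' @return A list of data.frames: `labels`, `efficiency`, and optionally
#'   `regions`, `repeats`.
#' @export
summarize_editome <- function(classification) {
  cls <- classification
  lab_levels <- c("shared", "p150_preferential", "p110_preferential",
                  "unclassified")
  labels <- data.frame(
    label = lab_levels,
    n = vapply(lab_levels, function(l) sum(cls$label == l), integer(1)),
    row.names = NULL)
  efficiency <- data.frame(
    measure = c("efficient_p150", "efficient_p110", "exclusive_p150",
                "exclusive_p110", "total"),
    n = c(sum(cls$efficient_p150), sum(cls$efficient_p110),
          sum(cls$exclusive == "p150"), sum(cls$exclusive == "p110"),
          nrow(cls)))
  out <- list(labels = labels, efficiency = efficiency)

  tab_by <- function(column) {
    do.call(rbind, lapply(c("p150", "p110"), function(iso) {
      pick <- cls[[paste0("efficient_", iso)]]
      if (sum(pick) == 0) return(NULL)
      t <- table(cls[[column]][pick])
      data.frame(isoform = iso, value = names(t), n = as.integer(t),
                 fraction = as.numeric(t) / sum(t),
                 stringsAsFactors = FALSE)
    }))
  }
  if ("region" %in% names(cls)) out$regions <- tab_by("region")
  if ("repeat_class" %in% names(cls)) out$repeats <- tab_by("repeat_class")
  out
}
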