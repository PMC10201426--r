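#' Remove sites with editing signal in the negative control
#'
#' A-to-G mismatches seen in the editase-free control condition are
#' presumed SNPs (or other artifacts), not editing, and are excluded from
#' all further analysis: a site is removed when any control replicate with
#' coverage at or above `min_control_cov` carries at least one
#' alternative-allele read.
#'
#' @param ct A [condition_tables()] object containing a `control` condition.
#' @param min_control_cov Minimum control coverage for a replicate to count
#'   (default 5).
#' @return A list with `keep` (logical vector over `ct$site_info`),
#'   `excluded` (the excluded subset of `site_info`), and `n_excluded`.
#' @export
subtract_control_sites <- function(ct, min_control_cov = 5) {
  if (is.null(ct$control)) {
    stop("no control condition present in the condition tables")
  }
  cov <- ct$control$coverage
  alt <- ct$control$alt
  flagged <- !is.na(cov) & cov >= min_control_cov & !is.na(alt) & alt >= 1
  excluded <- rowSums(flagged) > 0
  list(keep = !excluded,
       excluded = ct$site_info[excluded, , drop = FALSE],
       n_excluded = sum(excluded))
}

#' Per-replicate basic editing filter
#'
#' A replicate measurement calls a site "edited" when its editing rate and
#' coverage both clear the basic thresholds. Missing data never passes.
#'
#' @param frequency,coverage Numeric vectors or matrices (elementwise).
#' @param min_rate Minimum editing frequency (default 0.01, inclusive).
#' @param min_cov Minimum read coverage (default 5, inclusive).
#' @return Logical of the same shape.
#' @export
basic_site_filter <- function(frequency, coverage, min_rate = 0.01,
                              min_cov = 5) {
  pass <- !is.na(frequency) & !is.na(coverage) &
    frequency >= min_rate & coverage >= min_cov
  pass
}

#' Replicate-consistency filter
#'
#' A site passes for a condition when at least `k` of its replicates pass
#' the per-replicate basic filter. When fewer replicates than `n_expected`
#' are available the rule is evaluated on what is there, with a warning.
#'
#' @param pass Logical matrix (sites x replicates) from
#'   [basic_site_filter()].
#' @param k Minimum number of passing replicates (default 2).
#' @param n_expected Expected replicate count (default 3); only used for
#'   the warning.
#' @return Logical vector over sites.
#' @export
replicate_consistency_filter <- function(pass, k = 2, n_expected = 3) {
  if (ncol(pass) < n_expected) {
    warning("only ", ncol(pass), " of ", n_expected,
            " expected replicates present; evaluating on those")
  }
  rowSums(pass) >= k
}

#' Cross-isoform coverage filter
#'
#' Retains sites that are sufficiently covered in *both* isoform datasets:
#' in each isoform condition at least `min_reps` replicates must have data
#' and the mean coverage over the replicates with data must reach
#' `min_mean` (inclusive).
#'
#' @param cov_p150,cov_p110 Coverage matrices (sites x replicates).
#' @param min_mean Minimum mean coverage (default 10).
#' @param min_reps Minimum replicates with data (default 2).
#' @return Logical vector over sites.
#' @export
coverage_filter <- function(cov_p150, cov_p110, min_mean = 10,
                            min_reps = 2) {
  one <- function(cov) {
    d <- has_data(cov)
    n <- rowSums(d)
    mcov <- rowSums(cov * d, na.rm = TRUE) / pmax(n, 1)
    n >= min_reps & mcov >= min_mean
  }
  one(cov_p150) & one(cov_p110)
}

#' Efficient-editing call for one condition
#'
#' A site is "efficiently edited" by an isoform when at least `k` replicates
#' are edited at or above `min_rate` *and* covered by at least `min_cov`
#' reads in those same replicates.
#'
#' @param frequency,coverage Matrices (sites x replicates) for one
#'   condition.
#' @param min_rate Minimum editing frequency (default 0.01).
#' @param min_cov Minimum coverage within a qualifying replicate
#'   (default 10).
#' @param k Minimum qualifying replicates (default 2).
#' @return Logical vector over sites.
#' @export
call_efficient <- function(frequency, coverage, min_rate = 0.01,
                           min_cov = 10, k = 2) {
  ok <- !is.na(frequency) & !is.na(coverage) &
    frequency >= min_rate & coverage >= min_cov
  rowSums(ok) >= k
}
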