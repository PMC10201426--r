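#' Isoform-preference log2 fold-difference
#'
#' The per-site preference statistic: the mean editing level of each isoform
#' group is put on a percent scale with a pseudocount of 1 (avoiding
#' division by zero at unedited sites) and the log2 ratio is taken in
#' p110-over-p150 orientation, so negative values mark p150 preference and
#' positive values p110 preference:
#' \deqn{\mathrm{log2FD} = \log_2\frac{100\,\bar f_{p110} + 1}
#'                                    {100\,\bar f_{p150} + 1}}
#' Finite for all valid inputs; antisymmetric under swapping the two means.
#'
#' @param mean_p150,mean_p110 Mean editing frequencies in `[0, 1]`
#'   (vectorized; `NA` propagates).
#' @return Numeric vector of log2 fold-differences.
#' @examples
#' compute_log2fd(0.5, 0.1)   # log2(11/51), p150-preferred
#' compute_log2fd(0, 0.05)    # log2(6/1), p110-preferred
#' @export
compute_log2fd <- function(mean_p150, mean_p110) {
  chk <- c(mean_p150, mean_p110)
  if (any(chk < 0 | chk > 1, na.rm = TRUE)) {
    stop("editing means must lie in [0, 1]")
  }
  log2((100 * mean_p110 + 1) / (100 * mean_p150 + 1))
}

#' Welch two-sample test on per-replicate editing frequencies
#'
#' Two-sided unequal-variance (Welch) t-test comparing the replicate
#' frequencies of the two isoform conditions at one site. The degenerate
#' case of zero variance in both groups is defined explicitly: equal means
#' give p = 1 (no evidence of difference), unequal means p = 0. With fewer
#' than two non-missing replicates in either group the site is untested
#' (`NA`).
#'
#' @param x,y Numeric vectors of per-replicate frequencies (NAs dropped).
#' @return The two-sided p-value, or `NA` if either group has < 2 values.
#' @export
welch_p <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  vx <- stats::var(x); vy <- stats::var(y)
  se2 <- vx / length(x) + vy / length(y)
  if (se2 == 0) return(if (mean(x) == mean(y)) 1 else 0)
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                   (vy / length(y))^2 / (length(y) - 1))
  2 * stats::pt(-abs(t), df)
}

#' Per-site Welch tests over frequency matrices
#'
#' Row-wise wrapper of [welch_p()] for the site-by-replicate frequency
#' matrices of the two isoform conditions.
#'
#' @param freq_p150,freq_p110 Numeric matrices (sites x replicates).
#' @return Numeric vector of p-values (NA where untestable).
#' @export
site_test <- function(freq_p150, freq_p110) {
  stopifnot(nrow(freq_p150) == nrow(freq_p110))
  vapply(seq_len(nrow(freq_p150)), function(i) {
    welch_p(freq_p150[i, ], freq_p110[i, ])
  }, numeric(1))
}

#' Storey q-values
#'
#' False-discovery-rate adjusted significance by the Storey procedure. The
#' proportion of true nulls pi0 is estimated on the lambda grid
#' `seq(0.05, 0.95, 0.05)` via \eqn{\hat\pi_0(\lambda) = \#\{p >
#' \lambda\}/(n(1-\lambda))} with a cubic smoother (`stats::smooth.spline`,
#' df = 3) evaluated at the largest lambda; the estimate falls back to 1
#' when fewer than 100 p-values are supplied or when it exceeds 1, and is
#' floored at 1/n. Then
#' \deqn{q_i = \hat\pi_0 \min_{j:\ p_j \ge p_i} \frac{n\,p_j}{\mathrm{rank}(p_j)}}
#' which is monotone nondecreasing in p and bounded by 1. With `pi0 = 1`
#' this is exactly Benjamini-Hochberg.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed; returned
#'   as NA).
#' @param pi0 Optional fixed pi0 overriding the estimate (e.g. `1` for
#'   plain BH).
#' @param lambda Tuning grid for the pi0 estimate.
#' @return A list with `qvalues` (same length/order as `p`) and `pi0`.
#' @export
storey_qvalues <- function(p, pi0 = NULL,
                           lambda = seq(0.05, 0.95, by = 0.05)) {
  ok <- !is.na(p)
  pv <- p[ok]
  if (length(pv) == 0) return(list(qvalues = p, pi0 = NA_real_))
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pv)
  if (is.null(pi0)) {
    if (n < 100) {
      pi0 <- 1
    } else {
      pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
      if (is.na(pi0) || pi0 > 1) pi0 <- 1
      pi0 <- max(pi0, 1 / n)
    }
  } else {
    if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]")
  }
  r <- rank(pv, ties.method = "max")
  q_raw <- pmin(1, pi0 * n * pv / r)
  ord <- order(pv, decreasing = TRUE)
  q <- numeric(n)
  q[ord] <- cummin(q_raw[ord])
  out <- rep(NA_real_, length(p))
  out[ok] <- q
  list(qvalues = out, pi0 = pi0)
}
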