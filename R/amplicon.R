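#' Quantify editing from amplicon pileups at known sites
#'
#' Builds the raw site-by-construct editing matrix from base-count pileups.
#' The editing frequency is strand-aware and uses the informative bases
#' only: `G / (A + G)` for plus-strand sites and `C / (T + C)` for
#' minus-strand sites (robust to unrelated mismatches). Positions absent
#' from the known-site panel are ignored; a site/construct cell with zero
#' informative coverage is missing, never zero.
#'
#' @param pileups Data.frame with columns `chrom`, `pos`, `strand`, `A`,
#'   `C`, `G`, `T`, `sample_id` (one row per site per construct).
#' @param known_sites Data.frame with `chrom`, `pos`, `strand` defining the
#'   site panel (row order defines matrix row order).
#' @return A list of class `amplicon_matrix`: `freq` and `coverage`
#'   matrices (sites x constructs, rownames are site keys) and `sites`.
#' @export
quantify_sites <- function(pileups, known_sites) {
  known_sites$site <- site_key(known_sites$chrom, known_sites$pos,
                               known_sites$strand)
  pileups$site <- site_key(pileups$chrom, pileups$pos, pileups$strand)
  pileups <- pileups[pileups$site %in% known_sites$site, , drop = FALSE]
  constructs <- unique(pileups$sample_id)
  m <- matrix(NA_real_, nrow = nrow(known_sites), ncol = length(constructs),
              dimnames = list(known_sites$site, constructs))
  freq <- m; cov <- m
  plus <- pileups$strand == "+"
  edited <- ifelse(plus, pileups$G, pileups$C)
  ref <- ifelse(plus, pileups$A, pileups$T)
  informative <- edited + ref
  i <- match(pileups$site, known_sites$site)
  j <- match(pileups$sample_id, constructs)
  cov[cbind(i, j)] <- informative
  freq[cbind(i, j)] <- ifelse(informative > 0, edited / informative,
                              NA_real_)
  structure(list(freq = freq, coverage = cov, sites = known_sites),
            class = c("amplicon_matrix", "list"))
}

#' Subtract negative-control background
#'
#' Background signal observed in the negative-control construct is
#' subtracted per site from every other construct, floored at zero. The
#' control column is retained for reporting. Sites with a missing control
#' value are flagged and left unsubtracted.
#'
#' @param am An `amplicon_matrix` from [quantify_sites()].
#' @param control Name of the control column (default `"control"`).
#' @return The `amplicon_matrix` with adjusted `freq` and a logical
#'   `unsubtracted` attribute flagging sites without a control value.
#' @export
subtract_background <- function(am, control = "control") {
  if (!control %in% colnames(am$freq)) {
    stop("control column '", control, "' not present")
  }
  ctrl <- am$freq[, control]
  flagged <- is.na(ctrl)
  others <- setdiff(colnames(am$freq), control)
  adj <- am$freq
  adj[!flagged, others] <- pmax(0, am$freq[!flagged, others, drop = FALSE] -
                                  ctrl[!flagged])
  am$freq <- adj
  am$control <- control
  attr(am, "unsubtracted") <- flagged
  am
}

#' Inclusion filter on background-adjusted editing
#'
#' Retains sites edited at or above `threshold` (default 0.5%, inclusive)
#' by *any* non-control construct.
#'
#' @param am A background-adjusted `amplicon_matrix`.
#' @param threshold Minimum adjusted frequency (default 0.005).
#' @param control Name of the control column (default the one recorded by
#'   [subtract_background()], else `"control"`).
#' @return The filtered `amplicon_matrix` (possibly with zero rows).
#' @export
inclusion_filter <- function(am, threshold = 0.005, control = NULL) {
  control <- control %||% am$control %||% "control"
  others <- setdiff(colnames(am$freq), control)
  mx <- apply(am$freq[, others, drop = FALSE], 1, max, na.rm = TRUE)
  mx[!is.finite(mx)] <- -Inf
  keep <- mx >= threshold
  am$freq <- am$freq[keep, , drop = FALSE]
  am$coverage <- am$coverage[keep, , drop = FALSE]
  am$sites <- am$sites[keep, , drop = FALSE]
  am
}

#' Row max-normalization for heatmap display
#'
#' Scales each site's adjusted editing values so that the maximum across
#' the non-control constructs becomes exactly 1 and the rest is adjusted
#' proportionally (ties at the maximum all become 1). The control column
#' is normalized by the same row factor, for reference. All-zero rows are
#' dropped with a warning.
#'
#' @param am A filtered `amplicon_matrix`.
#' @param control Name of the control column.
#' @return The `amplicon_matrix` with an added `normalized` matrix.
#' @export
normalize_rows <- function(am, control = NULL) {
  control <- control %||% am$control %||% "control"
  others <- setdiff(colnames(am$freq), control)
  mx <- apply(am$freq[, others, drop = FALSE], 1, max, na.rm = TRUE)
  mx[!is.finite(mx)] <- 0
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero row(s) dropped before normalization")
    am$freq <- am$freq[!zero, , drop = FALSE]
    am$coverage <- am$coverage[!zero, , drop = FALSE]
    am$sites <- am$sites[!zero, , drop = FALSE]
    mx <- mx[!zero]
  }
  am$normalized <- sweep(am$freq, 1, mx, "/")
  am
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the amplicon matrices as TSV
#'
#' @param am An `amplicon_matrix`.
#' @param prefix Output path prefix; writes `<prefix>_raw.tsv`,
#'   `<prefix>_coverage.tsv` and, if present, `<prefix>_normalized.tsv`.
#' @return Invisibly, the paths written.
#' @export
write_amplicon_matrix <- function(am, prefix) {
  paths <- character(0)
  emit <- function(m, tag) {
    path <- paste0(prefix, "_", tag, ".tsv")
    df <- data.frame(site = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  paths <- c(paths, emit(am$freq, "raw"), emit(am$coverage, "coverage"))
  if (!is.null(am$normalized)) {
    paths <- c(paths, emit(am$normalized, "normalized"))
  }
  invisible(paths)
}
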