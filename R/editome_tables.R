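#' Pivot a long site table into per-condition matrices
#'
#' Reshapes the long (site x sample) editing table into one set of
#' site-by-replicate matrices per condition: `coverage`, `alt` and
#' `frequency`. A replicate absent at a site (no row, or a row with zero
#' coverage) is represented as missing data — `NA` frequency and, for the
#' no-row case, `NA` coverage — never as a fabricated zero frequency;
#' downstream filters treat missingness explicitly.
#'
#' @param sites Validated long site table (see [validate_site_records()]).
#' @param sample_map Data.frame with `sample_id`, `condition`, `replicate`.
#' @return An object of class `condition_tables`: a list with `site_info`
#'   (chrom, pos, strand, site key) and one element per condition, each a
#'   list of `coverage` / `alt` / `frequency` matrices whose columns are
#'   that condition's replicates.
#' @export
condition_tables <- function(sites, sample_map) {
  dup <- duplicated(sample_map[, c("condition", "replicate")])
  if (any(dup)) stop("a replicate appears more than once in a condition")
  keys <- unique(sites$site)
  info_idx <- match(keys, sites$site)
  site_info <- data.frame(site = keys,
                          chrom = sites$chrom[info_idx],
                          pos = sites$pos[info_idx],
                          strand = sites$strand[info_idx],
                          stringsAsFactors = FALSE)
  ord <- order(site_info$chrom, site_info$pos, site_info$strand,
               method = "radix")
  site_info <- site_info[ord, ]
  rownames(site_info) <- NULL

  out <- list(site_info = site_info)
  for (cond in unique(sample_map$condition)) {
    sm <- sample_map[sample_map$condition == cond, ]
    sm <- sm[order(sm$replicate), ]
    m <- function() {
      matrix(NA_real_, nrow = nrow(site_info), ncol = nrow(sm),
             dimnames = list(site_info$site, sm$sample_id))
    }
    cov <- m(); alt <- m(); freq <- m()
    for (j in seq_len(nrow(sm))) {
      rows <- sites[sites$sample_id == sm$sample_id[j], ]
      i <- match(rows$site, site_info$site)
      cov[i, j] <- rows$coverage
      alt[i, j] <- rows$alt_count
      freq[i, j] <- rows$frequency
    }
    out[[cond]] <- list(coverage = cov, alt = alt, frequency = freq)
  }
  class(out) <- c("condition_tables", "list")
  out
}

# TRUE where a replicate has usable data at a site (internal).
has_data <- function(cov) !is.na(cov) & cov > 0
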