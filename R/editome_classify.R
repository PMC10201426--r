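#' Classify isoform preference of editing sites
#'
#' Labels each site from the two condition means (unweighted means of
#' replicate frequencies over replicates with data):
#' \itemize{
#'   \item `shared` — both means at or above the 1% threshold;
#'   \item `p150_preferential` / `p110_preferential` — one mean at or above
#'     1%, the other strictly below 1% (the boundary is made disjoint: a
#'     site at exactly 1% in both is `shared`);
#'   \item `unclassified` — both means below 1%.
#' }
#' A preferential site is additionally `exclusive` for its isoform when
#' every replicate of the other condition carries zero edited reads (the
#' strictest reading of exclusive editing).
#'
#' @param mean_p150,mean_p110 Condition mean frequencies (NA allowed; a
#'   missing mean counts as below threshold).
#' @param alt_p150,alt_p110 Alt-read-count matrices (sites x replicates)
#'   used for the exclusivity call.
#' @param min_rate Preference threshold on the mean (default 0.01).
#' @return A data.frame with `label` and `exclusive`
#'   (`none`/`p150`/`p110`).
#' @export
classify_preference <- function(mean_p150, mean_p110, alt_p150, alt_p110,
                                min_rate = 0.01) {
  hi150 <- !is.na(mean_p150) & mean_p150 >= min_rate
  hi110 <- !is.na(mean_p110) & mean_p110 >= min_rate
  label <- rep("unclassified", length(mean_p150))
  label[hi150 & hi110] <- "shared"
  label[hi150 & !hi110] <- "p150_preferential"
  label[hi110 & !hi150] <- "p110_preferential"

  zero110 <- rowSums(alt_p110 > 0, na.rm = TRUE) == 0
  zero150 <- rowSums(alt_p150 > 0, na.rm = TRUE) == 0
  exclusive <- rep("none", length(label))
  exclusive[label == "p150_preferential" & zero110] <- "p150"
  exclusive[label == "p110_preferential" & zero150] <- "p110"
  data.frame(label = label, exclusive = exclusive,
             stringsAsFactors = FALSE)
}

# Unweighted condition mean over replicates with data (internal).
condition_means <- function(frequency, coverage) {
  d <- has_data(coverage)
  n <- rowSums(d)
  s <- rowSums(ifelse(d, frequency, 0), na.rm = TRUE)
  ifelse(n > 0, s / n, NA_real_)
}

#' Run the editome classification pipeline
#'
#' The fixed filtering and classification cascade applied to a long site
#' table: control subtraction, per-replicate basic filter, replicate
#' consistency (a site must be consistently edited in at least one isoform
#' condition), cross-isoform coverage filter, per-isoform efficiency calls,
#' preference/exclusivity classification, the log2 fold-difference
#' statistic, per-site Welch tests with Storey q-values, and gene-region /
#' repeat-class annotation. Each stage only removes or annotates sites,
#' never invents any; the per-stage in/out counts are returned as the
#' filtering funnel.
#'
#' @param sites Validated long site table.
#' @param sample_map Sample-to-condition map (`sample_id`, `condition`,
#'   `replicate`); conditions must include `p150`, `p110` and `control`.
#' @param gene_models Optional `gene_models` data.frame for region
#'   annotation.
#' @param repeats Optional repeat `GRanges` for repeat-class annotation.
#' @param params Threshold overrides: `min_rate` (0.01), `min_cov_basic`
#'   (5), `min_control_cov` (5), `consistency_k` (2), `min_mean_cov` (10),
#'   `efficient_cov` (10), `downstream_window` (3000).
#' @return A list of class `editome_result`: `classification` (one row per
#'   retained site), `excluded_control` (control-positive sites), `funnel`
#'   (named stage counts), and `pi0`.
#' @export
run_editome <- function(sites, sample_map, gene_models = NULL,
                        repeats = NULL, params = list()) {
  p <- utils::modifyList(list(
    min_rate = 0.01, min_cov_basic = 5, min_control_cov = 5,
    consistency_k = 2, min_mean_cov = 10, efficient_cov = 10,
    downstream_window = 3000L), params)
  if (p$min_rate < 0 || p$min_cov_basic < 0 || p$min_mean_cov < 0) {
    stop("thresholds must be non-negative")
  }
  for (cond in c("p150", "p110", "control")) {
    if (!cond %in% sample_map$condition) {
      stop("sample_map must provide condition '", cond, "'")
    }
  }

  ct <- condition_tables(sites, sample_map)
  funnel <- c(raw = nrow(ct$site_info))

  sub <- subtract_control_sites(ct, p$min_control_cov)
  keep <- sub$keep
  funnel["control_subtracted"] <- sum(keep)

  pass150 <- basic_site_filter(ct$p150$frequency, ct$p150$coverage,
                               p$min_rate, p$min_cov_basic)
  pass110 <- basic_site_filter(ct$p110$frequency, ct$p110$coverage,
                               p$min_rate, p$min_cov_basic)
  consistent <- replicate_consistency_filter(pass150, p$consistency_k,
                                             ncol(pass150)) |
    replicate_consistency_filter(pass110, p$consistency_k, ncol(pass110))
  keep <- keep & consistent
  funnel["replicate_consistent"] <- sum(keep)

  covered <- coverage_filter(ct$p150$coverage, ct$p110$coverage,
                             p$min_mean_cov)
  keep <- keep & covered
  funnel["coverage_filtered"] <- sum(keep)

  idx <- which(keep)
  cls <- ct$site_info[idx, , drop = FALSE]
  sel <- function(m) m[idx, , drop = FALSE]

  cls$mean_freq_p150 <- condition_means(sel(ct$p150$frequency),
                                        sel(ct$p150$coverage))
  cls$mean_freq_p110 <- condition_means(sel(ct$p110$frequency),
                                        sel(ct$p110$coverage))
  cls$efficient_p150 <- call_efficient(sel(ct$p150$frequency),
                                       sel(ct$p150$coverage),
                                       p$min_rate, p$efficient_cov,
                                       p$consistency_k)
  cls$efficient_p110 <- call_efficient(sel(ct$p110$frequency),
                                       sel(ct$p110$coverage),
                                       p$min_rate, p$efficient_cov,
                                       p$consistency_k)
  pref <- classify_preference(cls$mean_freq_p150, cls$mean_freq_p110,
                              sel(ct$p150$alt), sel(ct$p110$alt),
                              p$min_rate)
  cls$label <- pref$label
  cls$exclusive <- pref$exclusive
  cls$log2fd <- compute_log2fd(ifelse(is.na(cls$mean_freq_p150), 0,
                                      cls$mean_freq_p150),
                               ifelse(is.na(cls$mean_freq_p110), 0,
                                      cls$mean_freq_p110))
  cls$p_value <- site_test(sel(ct$p150$frequency), sel(ct$p110$frequency))
  st <- storey_qvalues(cls$p_value)
  cls$q_value <- st$qvalues

  if (!is.null(gene_models)) {
    ann <- annotate_site(cls, gene_models,
                         downstream_window = p$downstream_window)
    cls$region <- ann$region
    cls$gene_id <- ann$gene_id
  }
  if (!is.null(repeats)) {
    cls$repeat_class <- assign_repeat_class(
      gr_from_halfopen(cls$chrom, cls$pos - 1L, cls$pos, cls$strand),
      repeats)
  }
  funnel["classified"] <- nrow(cls)
  rownames(cls) <- NULL
  structure(list(classification = cls, excluded_control = sub$excluded,
                 funnel = funnel, pi0 = st$pi0),
            class = "editome_result")
}
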