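#' Generate per-sample editing tables with planted truth
#'
#' Plants editing sites of five categories on the toy annotation and samples
#' per-replicate read counts for every condition:
#' \describe{
#'   \item{p150_specific / p110_specific}{latent editing frequency
#'     `cfg$effects` in the matching isoform condition, 0 in the other.}
#'   \item{shared}{edited at the shared effect mean by both isoforms.}
#'   \item{snp_artifact}{an SNP-like heterozygous A-to-G signal (latent
#'     frequency 0.5) in *every* condition including the editase-free
#'     control; these are what control subtraction must remove.}
#'   \item{below_threshold}{sub-1% latent frequency in both isoform
#'     conditions; exercises the editing-rate threshold.}
#' }
#'
#' Coverage is negative binomial (`coverage_mean`, `coverage_size`);
#' edited-read counts are binomial given coverage and the latent frequency
#' plus, in the editase conditions, the sequencing-error floor
#' `cfg$error_rate`. The control condition carries edited reads only at the
#' planted SNP-artifact sites, mirroring the observed structure of an
#' editase-free transfection where residual A-to-G mismatches form a small
#' SNP-like set rather than a uniform error carpet (see the methods
#' vignette). Site regions and repeat contexts follow the per-category
#' `region_mix` and `nonrepetitive_prob`. Additionally, a few "hyperedited"
#' genes receive `cfg$hyper_sites_per_gene` clustered isoform-specific
#' sites. Deterministic under `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @param annotation Output of [generate_annotation()].
#' @return A list with `sites` (validated long site table: one row per site
#'   per sample), `sample_map` (sample/condition/replicate), and `truth`
#'   (the ground-truth manifest: one row per site with category, latent
#'   frequencies, gene, region and repeat context).
#' @export
generate_editome <- function(cfg, annotation) {
  cfg <- validate_synthetic_config(cfg)
  set.seed(seed_for(cfg, "editome"))

  truth <- plant_sites(cfg, annotation)
  sample_map <- editome_sample_map(cfg)

  if (nrow(truth) == 0) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), ref_base = character(0),
                        sample_id = character(0), coverage = integer(0),
                        alt_count = integer(0), frequency = numeric(0),
                        site = character(0), stringsAsFactors = FALSE)
    return(list(sites = sites, sample_map = sample_map, truth = truth))
  }

  per_sample <- lapply(seq_len(nrow(sample_map)), function(i) {
    cond <- sample_map$condition[i]
    f <- truth[[paste0("freq_", cond)]]
    if (cond != "control") f <- pmin(1, f + cfg$error_rate)
    cov <- stats::rnbinom(nrow(truth), mu = cfg$coverage_mean,
                          size = cfg$coverage_size)
    alt <- stats::rbinom(nrow(truth), cov, f)
    data.frame(chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
               ref_base = "A", sample_id = sample_map$sample_id[i],
               coverage = cov, alt_count = alt,
               frequency = ifelse(cov > 0, alt / cov, NA_real_),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, per_sample)
  sites <- validate_site_records(sites, context = "synthetic editome")
  list(sites = sites, sample_map = sample_map, truth = truth)
}

#' Sample map of the synthetic editome
#'
#' @param cfg A [synthetic_config()].
#' @return Data.frame with `sample_id`, `condition`, `replicate`.
#' @export
editome_sample_map <- function(cfg) {
  conds <- rep(names(cfg$n_replicates), cfg$n_replicates)
  reps <- unlist(lapply(cfg$n_replicates, seq_len), use.names = FALSE)
  data.frame(sample_id = paste0(conds, "_rep", reps),
             condition = conds, replicate = reps,
             stringsAsFactors = FALSE)
}

# Choose planted site positions for every category (internal).
plant_sites <- function(cfg, annotation) {
  genes <- annotation$genes
  feats <- as.data.frame(genes)[, c("chrom", "start", "end", "strand",
                                    "feature", "gene_id")]
  # intergenic windows per chromosome
  for (chrom in names(annotation$chrom_sizes)) {
    occ <- feats[feats$chrom == chrom, ]
    if (nrow(occ) > 0) {
      cov <- IRanges::reduce(IRanges::IRanges(occ$start + 1L, occ$end))
      gapr <- IRanges::gaps(cov, start = 1L,
                            end = annotation$chrom_sizes[[chrom]])
      gaps <- data.frame(chrom = chrom, start = IRanges::start(gapr) - 1L,
                         end = IRanges::end(gapr), strand = "+",
                         feature = "intergenic", gene_id = NA_character_)
    } else {
      gaps <- data.frame(chrom = chrom, start = 0L,
                         end = annotation$chrom_sizes[[chrom]], strand = "+",
                         feature = "intergenic", gene_id = NA_character_)
    }
    feats <- rbind(feats, gaps)
  }
  feats <- feats[feats$end > feats$start, ]
  rep_gr <- annotation$repeats

  # one vectorized candidate pool per region type, split by repeat context
  n_sites <- cfg$n_sites[rownames(cfg$effects)]
  n_sites[is.na(n_sites)] <- 0L
  need <- vapply(colnames(cfg$region_mix), function(r) {
    ceiling(sum(n_sites * cfg$region_mix[names(n_sites), r])) + 10L
  }, numeric(1))
  pools <- list()
  for (region in colnames(cfg$region_mix)) {
    pool <- feats[feats$feature == region, ]
    if (nrow(pool) == 0) pool <- feats
    m <- as.integer(4 * need[[region]] + 100L)
    rows_i <- sample.int(nrow(pool), m, replace = TRUE,
                         prob = pool$end - pool$start)
    pos <- pool$start[rows_i] +
      ceiling(stats::runif(m) * (pool$end[rows_i] - pool$start[rows_i]))
    cand <- data.frame(chrom = pool$chrom[rows_i], pos = pos,
                       strand = pool$strand[rows_i],
                       gene_id = pool$gene_id[rows_i],
                       region = region, stringsAsFactors = FALSE)
    cand <- cand[!duplicated(paste0(cand$chrom, ":", cand$pos)), ]
    hit <- gr_from_halfopen(cand$chrom, cand$pos - 1L, cand$pos)
    ov <- GenomicRanges::findOverlaps(hit, rep_gr, ignore.strand = TRUE)
    cand$repeat_class <- "nonrepetitive"
    if (length(ov) > 0) {
      first <- !duplicated(S4Vectors::queryHits(ov))
      cand$repeat_class[S4Vectors::queryHits(ov)[first]] <-
        S4Vectors::mcols(rep_gr)$repeat_class[
          S4Vectors::subjectHits(ov)[first]]
    }
    # intergenic candidates get a random strand
    inter <- is.na(cand$gene_id)
    cand$strand[inter] <- sample(c("+", "-"), sum(inter), replace = TRUE)
    pools[[region]] <- cand
  }
  used <- new.env(parent = emptyenv())
  take <- function(region, want_repeat) {
    cand <- pools[[region]]
    in_rep <- cand$repeat_class != "nonrepetitive"
    pref <- which(in_rep == want_repeat)
    for (i in c(pref, which(in_rep != want_repeat))) {
      key <- paste0(cand$chrom[i], ":", cand$pos[i])
      if (is.null(used[[key]])) {
        used[[key]] <- TRUE
        pools[[region]] <<- cand[-i, , drop = FALSE]
        return(cand[i, , drop = FALSE])
      }
    }
    NULL
  }

  rows <- list()
  for (cat in rownames(cfg$effects)) {
    n <- n_sites[[cat]]
    if (n == 0) next
    regions <- draw_classes(n, cfg$region_mix[cat, ])
    want_rep <- stats::runif(n) >= cfg$nonrepetitive_prob[[cat]]
    for (i in seq_len(n)) {
      got <- take(regions[i], want_rep[i])
      if (is.null(got)) next
      got$category <- cat
      got$hyper <- FALSE
      rows[[length(rows) + 1]] <- got
    }
  }

  # hyperedited genes: clustered isoform-specific sites in one feature
  for (iso in names(cfg$n_hyper_genes)) {
    n_hyper <- cfg$n_hyper_genes[[iso]]
    if (n_hyper == 0 || nrow(genes) == 0) next
    target_feat <- if (iso == "p150") "3UTR" else "intron"
    cand <- feats[feats$feature == target_feat & !is.na(feats$gene_id) &
                    feats$end - feats$start >=
                    cfg$hyper_sites_per_gene * 12L, ]
    if (nrow(cand) == 0) next
    picks <- cand[sample.int(nrow(cand), min(n_hyper, nrow(cand))), ]
    for (j in seq_len(nrow(picks))) {
      w <- picks[j, ]
      offs <- sort(sample.int(w$end - w$start,
                              cfg$hyper_sites_per_gene))
      for (pos in w$start + offs) {
        key <- paste0(w$chrom, ":", pos)
        if (!is.null(used[[key]])) next
        used[[key]] <- TRUE
        hit <- gr_from_halfopen(w$chrom, pos - 1L, pos)
        ov <- GenomicRanges::findOverlaps(hit, rep_gr, ignore.strand = TRUE)
        cls <- if (length(ov) > 0) {
          S4Vectors::mcols(rep_gr)$repeat_class[S4Vectors::subjectHits(ov)[1]]
        } else "nonrepetitive"
        rows[[length(rows) + 1]] <- data.frame(
          chrom = w$chrom, pos = pos, strand = w$strand,
          region = target_feat, gene_id = w$gene_id, repeat_class = cls,
          category = paste0(iso, "_specific"), hyper = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }

  if (length(rows) == 0) {
    return(data.frame(site = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      category = character(0), hyper = logical(0),
                      region = character(0), gene_id = character(0),
                      repeat_class = character(0),
                      freq_p150 = numeric(0), freq_p110 = numeric(0),
                      freq_control = numeric(0), stringsAsFactors = FALSE))
  }
  truth <- do.call(rbind, rows)
  truth$site <- site_key(truth$chrom, truth$pos, truth$strand)
  truth$freq_p150 <- cfg$effects[truth$category, "p150"]
  truth$freq_p110 <- cfg$effects[truth$category, "p110"]
  truth$freq_control <- cfg$effects[truth$category, "control"]
  truth <- truth[order(truth$chrom, truth$pos, method = "radix"),
                 c("site", "chrom", "pos", "strand", "category", "hyper",
                   "region", "gene_id", "repeat_class", "freq_p150",
                   "freq_p110", "freq_control")]
  rownames(truth) <- NULL
  truth
}
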