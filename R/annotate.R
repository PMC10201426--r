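#' Default feature-priority order
#'
#' The fixed priority list used to collapse multi-transcript annotation to
#' one label per site or peak: 5'UTR beats 3'UTR beats exon beats intron
#' beats downstream beats intergenic.
#'
#' @return Character vector of labels, highest priority first.
#' @export
region_priority <- function() {
  c("5UTR", "3UTR", "Exon", "Intron", "Downstream", "Intergenic")
}

# Map gene-model feature types to the label vocabulary (internal).
feature_label <- function(feature) {
  c(`5UTR` = "5UTR", `3UTR` = "3UTR", exon = "Exon", intron = "Intron")[feature]
}

# Priority annotation shared by sites and peaks (internal).
# query: GRanges; strand-aware feature overlap, then downstream windows.
priority_annotate <- function(query, gene_models, priority,
                              downstream_window) {
  n <- length(query)
  region <- rep("Intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0) return(data.frame(region = region, gene_id = gene_id))
  rank_of <- stats::setNames(seq_along(priority), priority)
  best <- rep(Inf, n)

  if (nrow(gene_models) > 0) {
    feat_gr <- gene_models_gr(gene_models)
    labels <- feature_label(S4Vectors::mcols(feat_gr)$feature)
    ov <- GenomicRanges::findOverlaps(query, feat_gr, ignore.strand = FALSE)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      rk <- rank_of[labels[S4Vectors::subjectHits(ov)]]
      o <- order(qh, rk)
      first <- !duplicated(qh[o])
      hit_q <- qh[o][first]
      best[hit_q] <- rk[o][first]
      region[hit_q] <- priority[best[hit_q]]
      gene_id[hit_q] <- S4Vectors::mcols(feat_gr)$gene_id[
        S4Vectors::subjectHits(ov)[o][first]]
    }

    # downstream windows past the transcript 3' end, strand-aware
    if ("Downstream" %in% priority && downstream_window > 0) {
      spans <- transcript_spans(gene_models)
      plus <- as.character(GenomicRanges::strand(spans)) == "+"
      ds_start <- ifelse(plus, GenomicRanges::end(spans) + 1L,
                         pmax(1L, GenomicRanges::start(spans) -
                                as.integer(downstream_window)))
      ds_end <- ifelse(plus, GenomicRanges::end(spans) +
                         as.integer(downstream_window),
                       GenomicRanges::start(spans) - 1L)
      okw <- ds_end >= ds_start
      if (any(okw)) {
        ds <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(spans)[okw],
          IRanges::IRanges(ds_start[okw], ds_end[okw]),
          strand = GenomicRanges::strand(spans)[okw])
        ovd <- GenomicRanges::findOverlaps(query, ds, ignore.strand = FALSE)
        if (length(ovd) > 0) {
          qh <- unique(S4Vectors::queryHits(ovd))
          better <- best[qh] > rank_of[["Downstream"]]
          upd <- qh[better]
          best[upd] <- rank_of[["Downstream"]]
          region[upd] <- "Downstream"
          firsts <- ovd[!duplicated(S4Vectors::queryHits(ovd))]
          gid <- S4Vectors::mcols(spans)$gene_id[okw][
            S4Vectors::subjectHits(firsts)]
          gene_id[upd] <- gid[match(upd, S4Vectors::queryHits(firsts))]
        }
      }
    }
  }
  data.frame(region = region, gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Annotate editing sites with a gene-region label
#'
#' Each site gets the highest-priority feature type among all transcripts
#' overlapping its position on the same strand; positions within
#' `downstream_window` nt past an annotated transcript 3' end are
#' `Downstream`; everything else is `Intergenic`.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based), `strand`.
#' @param gene_models A `gene_models` data.frame.
#' @param priority Ordered label list, highest first (default
#'   [region_priority()]).
#' @param downstream_window Window length in nt (default: the gene models'
#'   own attribute, else 3000).
#' @return Data.frame with `region` and `gene_id` per site.
#' @export
annotate_site <- function(sites, gene_models, priority = region_priority(),
                          downstream_window = NULL) {
  if (is.null(downstream_window)) {
    downstream_window <- attr(gene_models, "downstream_window")
    if (is.null(downstream_window)) downstream_window <- 3000L
  }
  query <- gr_from_halfopen(sites$chrom, sites$pos - 1L, sites$pos,
                            sites$strand)
  priority_annotate(query, gene_models, priority, downstream_window)
}

#' Annotate peaks with a gene-region label
#'
#' A peak gets the highest-priority feature type overlapped by *any* of its
#' bases, strand-aware, with the same downstream/intergenic fallback as
#' [annotate_site()].
#'
#' @param peaks A `GRanges` of peaks.
#' @inheritParams annotate_site
#' @return Data.frame with `region` and `gene_id` per peak.
#' @export
annotate_peak <- function(peaks, gene_models, priority = region_priority(),
                          downstream_window = NULL) {
  if (is.null(downstream_window)) {
    downstream_window <- attr(gene_models, "downstream_window")
    if (is.null(downstream_window)) downstream_window <- 3000L
  }
  priority_annotate(peaks, gene_models, priority, downstream_window)
}

#' Assign a repeat class to sites or intervals
#'
#' Returns the class of the repeat element overlapping each query, or
#' `"nonrepetitive"` when none does. Ties between several overlapping
#' repeats are broken by the largest overlap, then by the fixed class order
#' SINE > LINE > LTR > DNA > simple > other. Repeat overlap is not
#' strand-restricted (editable structures form on either strand).
#'
#' @param query A `GRanges` (single-base intervals for sites).
#' @param repeats A `GRanges` with metadata column `repeat_class`.
#' @return Character vector of repeat classes / `"nonrepetitive"`.
#' @export
assign_repeat_class <- function(query, repeats) {
  out <- rep("nonrepetitive", length(query))
  if (length(query) == 0 || length(repeats) == 0) return(out)
  ov <- GenomicRanges::findOverlaps(query, repeats, ignore.strand = TRUE)
  if (length(ov) == 0) return(out)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  width_ov <- GenomicRanges::width(GenomicRanges::pintersect(
    query[qh], repeats[sh], ignore.strand = TRUE))
  cls <- S4Vectors::mcols(repeats)$repeat_class[sh]
  cls_rank <- match(cls, repeat_classes())
  o <- order(qh, -width_ov, cls_rank)
  first <- !duplicated(qh[o])
  out[qh[o][first]] <- cls[o][first]
  out
}
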