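#' Intersect editing sites with peaks
#'
#' Flags each site whose single-base interval (1-based position `p` is the
#' half-open interval `[p-1, p)`) intersects at least one peak, and
#' reports the hit fraction. Site/peak sets with disjoint chromosome name
#' spaces usually indicate an assembly mismatch and trigger a warning.
#'
#' @param sites Data.frame with `chrom`, `pos` (1-based), `strand`.
#' @param peaks A `GRanges` of peaks.
#' @param strand_mode `"stranded"` (site and peak strand must agree) or
#'   `"unstranded"`.
#' @return A list with `hit` (logical per site), `n_hit`, `n_sites`, and
#'   `fraction`.
#' @export
intersect_sites_peaks <- function(sites, peaks,
                                  strand_mode = c("stranded",
                                                  "unstranded")) {
  strand_mode <- match.arg(strand_mode)
  if (nrow(sites) > 0 && length(peaks) > 0 &&
      !any(unique(sites$chrom) %in%
             unique(as.character(GenomicRanges::seqnames(peaks))))) {
    warning("site and peak chromosome names are disjoint; ",
            "possible assembly mismatch")
  }
  query <- gr_from_halfopen(sites$chrom, sites$pos - 1L, sites$pos,
                            sites$strand)
  # the seqlevel-disjointness warning is replaced by the explicit
  # assembly-mismatch warning above
  hit <- suppressWarnings(GenomicRanges::countOverlaps(
    query, peaks, ignore.strand = strand_mode == "unstranded")) > 0
  list(hit = hit, n_hit = sum(hit), n_sites = nrow(sites),
       fraction = if (nrow(sites) > 0) sum(hit) / nrow(sites) else 0)
}

#' Gene-level overlap between editome and peak gene sets
#'
#' Compares the set of genes carrying qualifying editing sites with a set
#' of peak-bearing genes. With `restrict = "nonrepetitive"` only sites
#' outside repeat elements qualify, so genes whose editing is purely
#' repetitive drop out — the comparison used to look for conserved
#' isoform-specific targets across datasets.
#'
#' @param classification Editome classification with `gene_id` and
#'   (for the restriction) `repeat_class` columns.
#' @param peak_genes Character vector of gene ids detected by the peak
#'   experiment.
#' @param qualifying Logical vector over classification rows selecting the
#'   qualifying sites (default: all rows).
#' @param restrict `"none"` or `"nonrepetitive"`.
#' @return A list with `editome_genes`, `peak_genes`, `overlap` (the
#'   intersection), `n_overlap`, and `fraction` (of editome genes found in
#'   the peak set).
#' @export
gene_level_overlap <- function(classification, peak_genes,
                               qualifying = NULL,
                               restrict = c("none", "nonrepetitive")) {
  restrict <- match.arg(restrict)
  pick <- qualifying %||% rep(TRUE, nrow(classification))
  stopifnot(length(pick) == nrow(classification))
  if (restrict == "nonrepetitive") {
    pick <- pick & classification$repeat_class == "nonrepetitive"
  }
  genes <- unique(stats::na.omit(classification$gene_id[pick]))
  peak_genes <- unique(peak_genes)
  ov <- intersect(genes, peak_genes)
  list(editome_genes = sort(genes), peak_genes = sort(peak_genes),
       overlap = sort(ov), n_overlap = length(ov),
       fraction = if (length(genes) > 0) length(ov) / length(genes) else 0)
}

#' Genes whose transcripts a peak set touches
#'
#' Gene assignment for set-level comparisons: any gene with a transcript
#' feature overlapped by a peak (priority labels are irrelevant for set
#' membership).
#'
#' @param peaks A `GRanges`.
#' @param gene_models A `gene_models` data.frame.
#' @param ignore_strand Ignore strand when assigning (default FALSE).
#' @return Character vector of gene ids.
#' @export
genes_for_peaks <- function(peaks, gene_models, ignore_strand = FALSE) {
  if (length(peaks) == 0 || nrow(gene_models) == 0) return(character(0))
  feat <- gene_models_gr(gene_models)
  ov <- GenomicRanges::findOverlaps(peaks, feat,
                                    ignore.strand = ignore_strand)
  sort(unique(S4Vectors::mcols(feat)$gene_id[S4Vectors::subjectHits(ov)]))
}

#' Build a replicate-support rule
#'
#' One clause of a site-grouping rule on an external per-replicate editing
#' table: the named condition must have between `min_edited` and
#' `max_edited` replicates called edited.
#'
#' @param condition Condition name (must match the table's conditions).
#' @param min_edited Minimum edited replicates (default 0).
#' @param max_edited Maximum edited replicates (default `Inf`).
#' @return A list of class `support_rule`.
#' @export
support_rule <- function(condition, min_edited = 0, max_edited = Inf) {
  if (min_edited < 0 || max_edited < min_edited) {
    stop("need 0 <= min_edited <= max_edited")
  }
  structure(list(condition = condition, min_edited = min_edited,
                 max_edited = max_edited), class = "support_rule")
}

#' Group sites by replicate support
#'
#' Applies a set of named rules — each a list of [support_rule()] clauses
#' that must all hold — to an external site table carrying per-replicate
#' editing evidence. A replicate counts as edited when its logical
#' edited-flag column is TRUE, or (frequency columns) when its frequency
#' is at or above `edited_threshold`. Groups may overlap unless the rules
#' are exclusive by construction.
#'
#' @param table Data.frame with a `site` column and per-replicate columns
#'   named `<condition>_rep<i>` (logical or numeric).
#' @param rules Named list; each element a list of [support_rule()]s.
#' @param edited_threshold Frequency threshold defining "edited" for
#'   numeric columns (default 0.01, consistent with the editome module).
#' @return Named list of site-key character vectors, one per rule.
#' @export
group_by_support <- function(table, rules, edited_threshold = 0.01) {
  cond_of <- sub("_rep[0-9]+$", "", names(table))
  lapply(rules, function(clauses) {
    keep <- rep(TRUE, nrow(table))
    for (cl in clauses) {
      cols <- which(cond_of == cl$condition &
                      grepl("_rep[0-9]+$", names(table)))
      if (length(cols) == 0) {
        stop("rule references unknown condition: ", cl$condition)
      }
      m <- as.matrix(table[, cols, drop = FALSE])
      edited <- if (is.logical(m)) m else {
        !is.na(m) & m >= edited_threshold
      }
      n_ed <- rowSums(edited, na.rm = TRUE)
      keep <- keep & n_ed >= cl$min_edited & n_ed <= cl$max_edited
    }
    table$site[keep]
  })
}

#' Coverage gate across genotype groups
#'
#' Retains sites whose mean read coverage reaches `min_mean` (inclusive)
#' in *every* genotype group.
#'
#' @param table Data.frame with a `site` column.
#' @param genotype_columns Named list mapping each genotype group to its
#'   coverage column names in `table`.
#' @param min_mean Minimum mean coverage per group (default 10).
#' @return The filtered table.
#' @export
coverage_gate <- function(table, genotype_columns, min_mean = 10) {
  keep <- rep(TRUE, nrow(table))
  for (cols in genotype_columns) {
    m <- as.matrix(table[, cols, drop = FALSE])
    keep <- keep & rowMeans(m, na.rm = TRUE) >= min_mean
  }
  table[keep, , drop = FALSE]
}
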