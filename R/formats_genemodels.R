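#' Read transcript gene models
#'
#' Gene models enter as a typed-feature table (one row per feature interval)
#' with a header: `transcript_id, gene_id, chrom, strand, feature, start,
#' end`; coordinates 0-based half-open, `feature` one of `5UTR`, `3UTR`,
#' `exon`, `intron`. This is the flattened equivalent of a BED12/GTF gene
#' model restricted to the feature types the pipeline needs.
#'
#' When a transcript carries no explicit `intron` rows, introns are inferred
#' as the gaps between consecutive exons of that transcript. Typed features
#' of one transcript must be non-overlapping; violations are an error, not a
#' repair.
#'
#' @param path Path to the gene model table.
#' @param downstream_window Length in nt of the downstream annotation window
#'   past the transcript 3' end (stored on the result; default 3000).
#' @return A data.frame of typed features (class `gene_models`) with the
#'   columns above, introns made explicit, plus attribute
#'   `downstream_window`.
#' @export
read_gene_models <- function(path, downstream_window = 3000L) {
  if (!file.exists(path)) stop("gene model table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_gene_models(df, context = path,
                       downstream_window = downstream_window)
}

#' Validate (and complete) a gene model feature table
#'
#' In-memory counterpart of [read_gene_models()]: checks the typed-feature
#' invariants and infers missing introns.
#'
#' @param df Data.frame with columns `transcript_id, gene_id, chrom, strand,
#'   feature, start, end` (0-based half-open).
#' @param context Label for error messages.
#' @inheritParams read_gene_models
#' @return Validated data.frame of class `gene_models`.
#' @export
validate_gene_models <- function(df, context = "gene models",
                                 downstream_window = 3000L) {
  required <- c("transcript_id", "gene_id", "chrom", "strand", "feature",
                "start", "end")
  if (!all(required %in% names(df))) {
    stop(context, ": needs columns ", paste(required, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start >= df$end)) stop(context, ": empty or inverted feature")
  if (!all(df$strand %in% c("+", "-"))) {
    stop(context, ": transcript strand must be '+' or '-'")
  }
  known <- c("5UTR", "3UTR", "exon", "intron")
  if (!all(df$feature %in% known)) {
    stop(context, ": unknown feature type: ",
         paste(setdiff(unique(df$feature), known), collapse = ", "))
  }

  pieces <- split(df, df$transcript_id)
  out <- lapply(pieces, function(tx) {
    tx <- tx[order(tx$start), ]
    if (length(unique(tx$chrom)) != 1 || length(unique(tx$strand)) != 1) {
      stop(context, ": transcript ", tx$transcript_id[1],
           " spans multiple chromosomes or strands")
    }
    if (nrow(tx) > 1 && any(tx$start[-1] < tx$end[-nrow(tx)])) {
      stop(context, ": overlapping typed features in transcript ",
           tx$transcript_id[1])
    }
    if (!"intron" %in% tx$feature) {
      ex <- tx[tx$feature == "exon", ]
      if (nrow(ex) > 1) {
        gaps <- data.frame(
          transcript_id = tx$transcript_id[1], gene_id = tx$gene_id[1],
          chrom = tx$chrom[1], strand = tx$strand[1], feature = "intron",
          start = ex$end[-nrow(ex)], end = ex$start[-1],
          stringsAsFactors = FALSE
        )
        gaps <- gaps[gaps$start < gaps$end, ]
        tx <- rbind(tx[, required], gaps)
        tx <- tx[order(tx$start), ]
      }
    }
    tx[, required]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$chrom, out$start, out$transcript_id, method = "radix"), ]
  attr(out, "downstream_window") <- as.integer(downstream_window)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' Write a gene model feature table
#'
#' Deterministic writer (sorted by chromosome, start, transcript); the
#' inverse of [read_gene_models()] up to intron inference, which is
#' idempotent.
#'
#' @param models A `gene_models` data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gene_models <- function(models, path) {
  cols <- c("transcript_id", "gene_id", "chrom", "strand", "feature",
            "start", "end")
  out <- as.data.frame(models)[, cols]
  out <- out[order(out$chrom, out$start, out$transcript_id, method = "radix"), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Gene model features as a GRanges
#'
#' @param models A `gene_models` data.frame.
#' @return `GRanges` with metadata columns `feature`, `transcript_id`,
#'   `gene_id`.
#' @export
gene_models_gr <- function(models) {
  gr_from_halfopen(models$chrom, models$start, models$end, models$strand,
                   feature = models$feature,
                   transcript_id = models$transcript_id,
                   gene_id = models$gene_id)
}

#' Transcript spans of a gene model set
#'
#' One interval per transcript, from the start of its first feature to the
#' end of its last (used for downstream-window annotation and gene-level
#' overlap).
#'
#' @param models A `gene_models` data.frame.
#' @return `GRanges` with metadata columns `transcript_id`, `gene_id`.
#' @export
transcript_spans <- function(models) {
  sp <- split(seq_len(nrow(models)), models$transcript_id)
  first <- vapply(sp, function(i) min(models$start[i]), numeric(1))
  last <- vapply(sp, function(i) max(models$end[i]), numeric(1))
  one <- vapply(sp, function(i) i[1], numeric(1))
  gr_from_halfopen(models$chrom[one], first, last, models$strand[one],
                   transcript_id = names(sp), gene_id = models$gene_id[one])
}
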