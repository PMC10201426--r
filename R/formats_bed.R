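#' Read intervals from a BED3/BED6 file
#'
#' BED coordinates are 0-based half-open and are preserved exactly (the
#' returned [GenomicRanges::GRanges-class] uses the usual 1-based closed
#' representation internally; `start(gr) - 1` / `end(gr)` recover the BED
#' values). Column 4 (name) and column 5 (score) are kept as metadata columns
#' when present. Validation rejects empty or inverted intervals
#' (`start >= end`) and unknown strand symbols.
#'
#' @param path Path to a BED3 or BED6 file (tab-separated, no header).
#' @param stranded When `FALSE`, any strand column is ignored and all
#'   intervals get strand `"*"` (written back as `"."`).
#' @return A `GRanges` with metadata columns `name`, `score` (BED6 input).
#' @export
read_intervals <- function(path, stranded = TRUE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (ncol(df) < 3) stop(path, ": BED needs at least 3 columns")
  names(df)[1:3] <- c("chrom", "start", "end")
  bed_df_to_gr(df, stranded = stranded, context = path)
}

# Shared BED data.frame -> GRanges conversion with validation (internal).
bed_df_to_gr <- function(df, stranded = TRUE, context = "BED input") {
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0L |
                 df$start >= df$end)
  if (length(bad) > 0) {
    stop(context, ": empty or inverted interval at line ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  strand <- rep("*", nrow(df))
  if (stranded && ncol(df) >= 6) {
    s <- as.character(df[[6]])
    ok <- s %in% c("+", "-", ".")
    if (!all(ok)) {
      stop(context, ": unknown strand symbol at line ",
           paste(utils::head(which(!ok), 5), collapse = ", "))
    }
    strand <- ifelse(s == ".", "*", s)
  }
  gr <- gr_from_halfopen(df$chrom, df$start, df$end, strand)
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5) {
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(df[[5]]))
  }
  gr
}

#' Write intervals to a BED6 file
#'
#' Deterministic writer: intervals are emitted sorted by (`chrom`, `start`,
#' `end`, `strand`) in BED 0-based half-open coordinates. The `name` and
#' `score` metadata columns are used when present (defaults `"."` and `0`);
#' strand `"*"` is written as `"."`.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param sort Sort the output (default `TRUE`); set `FALSE` to preserve the
#'   input order (used by round-trip checks of order-preserving dialects).
#' @return Invisibly, the path.
#' @export
write_intervals <- function(gr, path, sort = TRUE) {
  df <- halfopen_from_gr(gr)
  mc <- S4Vectors::mcols(gr)
  df$name <- if ("name" %in% names(mc)) as.character(mc$name) else "."
  df$score <- if ("score" %in% names(mc)) mc$score else 0
  df$strand <- ifelse(df$strand == "*", ".", df$strand)
  out <- df[, c("chrom", "start", "end", "name", "score", "strand")]
  if (sort) {
    out <- out[order(out$chrom, out$start, out$end, out$strand,
                     method = "radix"), ]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a repeat annotation table
#'
#' RepeatMasker-like tab-separated layout with a header:
#' `chrom, start, end, strand, repeat_class`, interval coordinates 0-based
#' half-open. The repeat class must come from the closed vocabulary
#' `SINE, LINE, LTR, DNA, simple, other`.
#'
#' @param path Path to the repeat table.
#' @return A `GRanges` with metadata column `repeat_class`.
#' @export
read_repeat_table <- function(path) {
  if (!file.exists(path)) stop("repeat table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  required <- c("chrom", "start", "end", "strand", "repeat_class")
  if (!all(required %in% names(df))) {
    stop(path, ": repeat table needs columns ",
         paste(required, collapse = ", "))
  }
  bad <- !df$repeat_class %in% repeat_classes()
  if (any(bad)) {
    stop(path, ": unknown repeat class at line ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
  }
  gr <- bed_df_to_gr(df[, c("chrom", "start", "end", "repeat_class",
                            "repeat_class", "strand")],
                     stranded = TRUE, context = path)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(repeat_class = df$repeat_class)
  gr
}

#' Write a repeat annotation table
#'
#' @param repeats `GRanges` with a `repeat_class` metadata column.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_repeat_table <- function(repeats, path) {
  df <- halfopen_from_gr(repeats)
  df$repeat_class <- S4Vectors::mcols(repeats)$repeat_class
  df <- df[order(df$chrom, df$start, df$end, method = "radix"),
           c("chrom", "start", "end", "strand", "repeat_class")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Closed vocabulary of repeat classes
#'
#' In descending tie-break priority, as used by [assign_repeat_class()].
#'
#' @return Character vector.
#' @export
repeat_classes <- function() {
  c("SINE", "LINE", "LTR", "DNA", "simple", "other")
}
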