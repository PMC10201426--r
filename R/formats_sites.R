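#' Read a per-site editing table
#'
#' Parses a tab-separated table of known-site editing measurements, one row
#' per site per sample, in the layout emitted by per-sample variant profilers:
#' a header row naming at least `chrom`, `pos`, `strand`, `ref_base`,
#' `sample_id`, `coverage`, `alt_count` and `frequency`. Extra columns are
#' carried through untouched, so any column superset of the required fields is
#' accepted.
#'
#' `alt_count` counts reads supporting A-to-G on the plus strand and T-to-C on
#' the minus strand (editing is read strand-aware; `ref_base` is the sense
#' strand base and is `A` for every genuine editing site). Rows are validated
#' against the site-record invariants and rejected (with the offending line
#' number) rather than silently coerced:
#' \itemize{
#'   \item `pos >= 1`, `strand` in `+`/`-`, `ref_base` in `A/C/G/T`;
#'   \item `0 <= alt_count <= coverage`;
#'   \item `coverage > 0` implies `frequency == alt_count / coverage`
#'     (within 1e-9); the stored frequency is recomputed from the counts;
#'   \item `coverage == 0` implies `frequency` is missing (`NA`), never a
#'     fabricated 0.
#' }
#'
#' @param path Path to the tab-separated site table.
#' @param sample_map Optional data.frame with columns `sample_id`,
#'   `condition`, `replicate` assigning each sample to an experimental
#'   condition; when given, the two columns are joined onto the result and
#'   unknown sample ids are an error.
#' @return A data.frame of validated site records, keyed by
#'   (`chrom`, `pos`, `strand`); a `site` key column is added.
#' @export
read_site_table <- function(path, sample_map = NULL) {
  if (!file.exists(path)) stop("site table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "", comment.char = "")
  validate_site_records(df, context = path, sample_map = sample_map)
}

#' Validate a data.frame of site records
#'
#' The in-memory counterpart of [read_site_table()]: applies the same
#' invariant checks to an already-constructed data.frame (e.g. from the
#' synthetic generator).
#'
#' @inheritParams read_site_table
#' @param df Data.frame with the required site-record columns.
#' @param context Label used in error messages (file name or description).
#' @return The validated data.frame with recomputed `frequency` and a `site`
#'   key column.
#' @export
validate_site_records <- function(df, context = "site table",
                                  sample_map = NULL) {
  required <- c("chrom", "pos", "strand", "ref_base", "sample_id",
                "coverage", "alt_count", "frequency")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(context, ": missing required columns: ",
         paste(missing, collapse = ", "))
  }
  line <- seq_len(nrow(df)) + 1L  # +1 for the header line
  bad <- function(cond, what) {
    if (any(cond)) {
      stop(context, ": ", what, " at line ",
           paste(utils::head(line[cond], 5), collapse = ", "),
           if (sum(cond) > 5) " (and more)" else "")
    }
  }
  df$pos <- as.integer(df$pos)
  df$coverage <- as.integer(df$coverage)
  df$alt_count <- as.integer(df$alt_count)
  bad(is.na(df$pos) | df$pos < 1L, "non-positive or unparseable position")
  bad(!df$strand %in% c("+", "-"), "strand must be '+' or '-'")
  bad(!df$ref_base %in% c("A", "C", "G", "T"), "invalid reference base")
  bad(is.na(df$coverage) | df$coverage < 0L, "negative or missing coverage")
  bad(is.na(df$alt_count) | df$alt_count < 0L, "negative or missing alt_count")
  bad(df$alt_count > df$coverage, "alt_count exceeds coverage")

  covered <- df$coverage > 0L
  freq_file <- suppressWarnings(as.numeric(df$frequency))
  bad(covered & is.na(freq_file), "missing frequency at covered site")
  recomputed <- ifelse(covered, df$alt_count / df$coverage, NA_real_)
  bad(covered & abs(freq_file - recomputed) > 1e-9,
      "frequency inconsistent with alt_count/coverage")
  bad(!covered & !is.na(freq_file),
      "frequency reported at zero coverage")
  df$frequency <- recomputed

  if (!is.null(sample_map)) {
    if (!all(c("sample_id", "condition", "replicate") %in% names(sample_map))) {
      stop("sample_map needs columns sample_id, condition, replicate")
    }
    unknown <- setdiff(unique(df$sample_id), sample_map$sample_id)
    if (length(unknown) > 0) {
      stop(context, ": sample ids absent from sample_map: ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(df$sample_id, sample_map$sample_id)
    df$condition <- sample_map$condition[idx]
    df$replicate <- sample_map$replicate[idx]
  }
  df$site <- site_key(df$chrom, df$pos, df$strand)
  df
}

#' Site key string
#'
#' Canonical `chrom:pos:strand` key identifying one editing site.
#'
#' @param chrom,pos,strand Site coordinates (1-based position).
#' @return Character vector of keys.
#' @export
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

#' Write a per-site editing table
#'
#' Deterministic writer: rows are sorted by (`chrom`, `pos`, `strand`,
#' `sample_id`) and columns are emitted in the canonical order, so a fixed
#' input always yields a byte-identical file. Zero-coverage frequencies are
#' written as `NA`.
#'
#' @param df Validated site-record data.frame (see [validate_site_records()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_site_table <- function(df, path) {
  cols <- c("chrom", "pos", "strand", "ref_base", "sample_id",
            "coverage", "alt_count", "frequency")
  ord <- order(df$chrom, df$pos, df$strand, df$sample_id, method = "radix")
  out <- df[ord, cols]
  out$frequency <- ifelse(is.na(out$frequency), "NA",
                          formatC(out$frequency, digits = 10, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
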