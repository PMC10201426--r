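#' Generate a toy gene and repeat annotation
#'
#' Places `cfg$n_genes` non-overlapping transcripts on the toy genome
#' declared in `cfg$chrom_sizes`. Each transcript carries, in transcription
#' order, a 5'UTR, 3-6 exons separated by introns, and a 3'UTR; minus-strand
#' transcripts are laid out mirrored in genomic coordinates. Repeat elements
#' are tiled inside gene features and intergenic gaps with classes drawn
#' from `cfg$repeat_mix` and class-typical lengths (SINEs short, LINEs
#' long). Deterministic under `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with elements `genes` (a `gene_models` data.frame),
#'   `repeats` (a `GRanges` with `repeat_class`), and `chrom_sizes`.
#' @export
generate_annotation <- function(cfg) {
  cfg <- validate_synthetic_config(cfg)
  set.seed(seed_for(cfg, "annotation"))

  genes <- place_genes(cfg)
  repeats <- place_repeats(cfg, genes)
  list(genes = genes, repeats = repeats, chrom_sizes = cfg$chrom_sizes)
}

# Lay out one transcript's typed features from a cursor (internal).
gene_features <- function(tx_id, gene_id, chrom, strand, cursor) {
  n_exons <- sample(3:6, 1)
  exon_len <- sample(120:400, n_exons, replace = TRUE)
  intron_len <- sample(400:2500, n_exons - 1, replace = TRUE)
  utr5 <- sample(100:250, 1)
  utr3 <- sample(400:1200, 1)
  # blocks in transcription order
  types <- c("5UTR", rbind(rep("exon", n_exons),
                           c(rep("intron", n_exons - 1), NA)))
  types <- types[!is.na(types)]
  types <- c(types, "3UTR")
  lens <- c(utr5, rbind(exon_len, c(intron_len, NA)))
  lens <- c(lens[!is.na(lens)], utr3)
  if (strand == "-") {            # mirror to genomic order
    types <- rev(types)
    lens <- rev(lens)
  }
  ends <- cursor + cumsum(lens)
  starts <- ends - lens
  data.frame(transcript_id = tx_id, gene_id = gene_id, chrom = chrom,
             strand = strand, feature = types, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

place_genes <- function(cfg) {
  chroms <- names(cfg$chrom_sizes)
  cursors <- stats::setNames(rep(2000L, length(chroms)), chroms)
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(max(cfg$n_genes, 0))) {
    tx_id <- sprintf("tx%04d", g)
    gene_id <- sprintf("gene%04d", g)
    strand <- sample(c("+", "-"), 1)
    placed <- FALSE
    for (chrom in sample(chroms)) {
      feats <- gene_features(tx_id, gene_id, chrom, strand, cursors[[chrom]])
      if (max(feats$end) + 2000 <= cfg$chrom_sizes[[chrom]]) {
        rows[[g]] <- feats
        cursors[[chrom]] <- max(feats$end) + sample(1500:4000, 1)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("toy genome too small to place ", cfg$n_genes,
           " genes; enlarge chrom_sizes or reduce n_genes")
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(transcript_id = character(0), gene_id = character(0),
                     chrom = character(0), strand = character(0),
                     feature = character(0), start = integer(0),
                     end = integer(0), stringsAsFactors = FALSE)
  }
  validate_gene_models(df, context = "synthetic gene models")
}

repeat_length <- function(class) {
  lo <- c(SINE = 120, LINE = 500, LTR = 300, DNA = 200, simple = 50,
          other = 100)
  hi <- c(SINE = 300, LINE = 2000, LTR = 800, DNA = 600, simple = 150,
          other = 300)
  sample(lo[[class]]:hi[[class]], 1)
}

place_repeats <- function(cfg, genes) {
  # candidate windows: gene features plus intergenic gaps
  wins <- as.data.frame(genes)[, c("chrom", "start", "end", "feature")]
  for (chrom in names(cfg$chrom_sizes)) {
    occ <- wins[wins$chrom == chrom, ]
    bounds <- sort(unique(c(0L, occ$start, occ$end,
                            cfg$chrom_sizes[[chrom]])))
    if (nrow(occ) == 0) {
      gaps <- data.frame(chrom = chrom, start = 0L,
                         end = cfg$chrom_sizes[[chrom]],
                         feature = "intergenic")
    } else {
      cov <- IRanges::reduce(IRanges::IRanges(occ$start + 1L, occ$end))
      gapr <- IRanges::gaps(cov, start = 1L,
                            end = cfg$chrom_sizes[[chrom]])
      gaps <- data.frame(chrom = chrom,
                         start = IRanges::start(gapr) - 1L,
                         end = IRanges::end(gapr),
                         feature = "intergenic")
    }
    if (nrow(gaps) == 0) next
    wins <- rbind(wins, gaps)
  }
  wins <- wins[wins$end - wins$start >= 60, ]
  density <- c(`5UTR` = 0.25, exon = 0.25, intron = 0.45, `3UTR` = 0.45,
               intergenic = 0.35)
  out <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    w <- wins[i, ]
    cur <- w$start
    acc <- list()
    while (cur < w$end - 60) {
      if (stats::runif(1) < density[[w$feature]]) {
        cls <- draw_classes(1, cfg$repeat_mix)
        len <- min(repeat_length(cls), w$end - cur)
        acc[[length(acc) + 1]] <- data.frame(
          chrom = w$chrom, start = cur, end = cur + len,
          strand = sample(c("+", "-"), 1), repeat_class = cls,
          stringsAsFactors = FALSE)
        cur <- cur + len + sample(100:400, 1)
      } else {
        cur <- cur + sample(150:600, 1)
      }
    }
    out[[i]] <- if (length(acc)) do.call(rbind, acc) else NULL
  }
  df <- do.call(rbind, out)
  if (is.null(df)) {
    return(GenomicRanges::GRanges(repeat_class = character(0)))
  }
  df <- df[order(df$chrom, df$start, method = "radix"), ]
  gr_from_halfopen(df$chrom, df$start, df$end, df$strand,
                   repeat_class = df$repeat_class)
}
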