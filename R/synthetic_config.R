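#' Synthetic study configuration
#'
#' Builds the seeded configuration from which every synthetic input the
#' pipeline consumes is generated: a toy genome with non-overlapping gene
#' models and repeat annotation, per-replicate editing tables for the two
#' ADAR1 isoform conditions and an editase-free negative control, RIP
#' IP/input fragment files with a MOCK condition, and amplicon pileups.
#'
#' The defaults emulate the study design the pipeline was built for: three
#' replicates per isoform plus a negative control; 500 planted sites per
#' editing category with isoform effect means of 0.10 versus 0; 78 planted
#' SNP-like artifact sites that carry A-to-G signal in the control; negative
#' binomial coverage with mean 50; a 0.1% A-to-G sequencing-error floor in
#' the editase conditions so the 1% editing-rate threshold is meaningfully
#' exercised; 8-fold IP-over-input enrichment inside planted RIP peaks at
#' 1e5 fragments per sample.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so a fixed seed gives byte-identical outputs.
#' @param ... Named overrides of any default listed below.
#' @return A validated configuration list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 1, n_genes = 10,
#'                         n_sites = c(p150_specific = 5, p110_specific = 5,
#'                                     shared = 5, snp_artifact = 2,
#'                                     below_threshold = 5))
#' @export
synthetic_config <- function(seed = 1L, ...) {
  categories <- c("p150_specific", "p110_specific", "shared",
                  "snp_artifact", "below_threshold")
  region_mix <- rbind(
    p150_specific   = c(`5UTR` = 0.02, exon = 0.15, intron = 0.30,
                        `3UTR` = 0.45, intergenic = 0.08),
    p110_specific   = c(0.01, 0.04, 0.85, 0.06, 0.04),
    shared          = c(0.02, 0.10, 0.55, 0.25, 0.08),
    snp_artifact    = c(0.05, 0.25, 0.40, 0.20, 0.10),
    below_threshold = c(0.03, 0.15, 0.50, 0.22, 0.10)
  )
  effects <- rbind(
    p150_specific   = c(p150 = 0.10, p110 = 0.00, control = 0.0),
    p110_specific   = c(0.00, 0.10, 0.0),
    shared          = c(0.10, 0.10, 0.0),
    snp_artifact    = c(0.50, 0.50, 0.5),
    below_threshold = c(0.002, 0.002, 0.0)
  )
  cfg <- list(
    seed = as.integer(seed),
    # toy genome and annotation
    chrom_sizes = c(chr1 = 600000L, chr2 = 600000L, chr3 = 600000L),
    n_genes = 120L,
    repeat_mix = c(SINE = 0.62, LINE = 0.12, LTR = 0.12, DNA = 0.06,
                   simple = 0.05, other = 0.03),
    # editome
    n_sites = c(p150_specific = 500L, p110_specific = 500L, shared = 500L,
                snp_artifact = 78L, below_threshold = 500L),
    effects = effects,
    region_mix = region_mix,
    nonrepetitive_prob = c(p150_specific = 0.23, p110_specific = 0.16,
                           shared = 0.20, snp_artifact = 0.50,
                           below_threshold = 0.30),
    n_replicates = c(p150 = 3L, p110 = 3L, control = 3L),
    coverage_mean = 50, coverage_size = 10,
    error_rate = 0.001,
    n_hyper_genes = c(p150 = 2L, p110 = 1L),
    hyper_sites_per_gene = 20L,
    # RIP
    rip_enrichment = 8,
    n_fragments = 100000L,
    fragment_length = 150L,
    read_length = 38L,
    paired_fraction = 0.9,
    n_truth_peaks = c(p150 = 25L, p110 = 25L),
    n_mock_peaks = 8L,
    truth_peak_width = 1000L,
    rip_replicates = c(p150 = 3L, p110 = 3L, MOCK = 2L),
    # amplicon
    amplicon_constructs = c("p150", "p110", "N_p150", "C_p110", "mZ_p150",
                            "Ad2", "C_Ad2", "control"),
    amplicon_control = "control",
    n_amplicon_sites = 17L,
    amplicon_coverage = 5000L,
    amplicon_error = 0.001,
    amplicon_multipliers = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  validate_synthetic_config(cfg)
}

#' Validate a synthetic configuration
#'
#' @param cfg Configuration list as built by [synthetic_config()].
#' @return The configuration, invisibly classed `synthetic_config`.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1)
  if (cfg$seed < 0 || cfg$seed >= 2^31 - 4e6) {
    stop("seed must lie in [0, 2^31 - 4e6)")
  }
  if (any(cfg$chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (cfg$n_genes < 0) stop("n_genes must be >= 0")
  if (any(cfg$n_sites < 0)) stop("site counts must be >= 0")
  if (any(cfg$effects < 0 | cfg$effects > 1)) {
    stop("effect means must lie in [0, 1]")
  }
  check_mix <- function(m, what) {
    if (any(m < 0 | m > 1)) stop(what, " probabilities must lie in [0, 1]")
    s <- if (is.matrix(m)) rowSums(m) else sum(m)
    if (any(abs(s - 1) > 1e-8)) stop(what, " probabilities must sum to 1")
  }
  check_mix(cfg$region_mix, "region_mix")
  check_mix(cfg$repeat_mix, "repeat_mix")
  if (any(cfg$nonrepetitive_prob < 0 | cfg$nonrepetitive_prob > 1)) {
    stop("nonrepetitive_prob must lie in [0, 1]")
  }
  if (cfg$rip_enrichment < 1) stop("rip_enrichment must be >= 1")
  if (cfg$error_rate < 0 || cfg$error_rate > 1 ||
      cfg$amplicon_error < 0 || cfg$amplicon_error > 1) {
    stop("error rates must lie in [0, 1]")
  }
  if (cfg$fragment_length < cfg$read_length) {
    stop("fragment_length must be >= read_length")
  }
  if (!cfg$amplicon_control %in% cfg$amplicon_constructs) {
    stop("amplicon constructs must include the negative control")
  }
  if (cfg$paired_fraction < 0 || cfg$paired_fraction > 1) {
    stop("paired_fraction must lie in [0, 1]")
  }
  class(cfg) <- c("synthetic_config", "list")
  cfg
}

# Derived per-generator seeds: fixed offsets keep the generator streams
# independent while remaining fully determined by the master seed.
seed_for <- function(cfg, stage) {
  offset <- c(annotation = 0L, editome = 1000003L, rip = 2000003L,
              amplicon = 3000003L, peaks = 2500001L)[[stage]]
  as.integer(cfg$seed + offset)
}

# Weighted categorical draw of n items from names(prob) (internal).
draw_classes <- function(n, prob) {
  if (n == 0) return(character(0))
  sample(names(prob), n, replace = TRUE, prob = prob)
}
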