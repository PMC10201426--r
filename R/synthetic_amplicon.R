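#' Generate amplicon deep-sequencing pileups with planted truth
#'
#' Emulates targeted amplicon sequencing of a panel of known editing sites
#' across a set of editase constructs (wild-type isoforms, mislocalized and
#' domain-mutant variants, and a negative control). Each site has a latent
#' base editing frequency; each non-control construct edits it at
#' `multiplier * base` where the multiplier matrix either comes from
#' `cfg$amplicon_multipliers` (sites x constructs) or is drawn from a few
#' archetypal preference profiles. The negative control edits nothing; every
#' construct additionally accrues background A-to-G (T-to-C on minus-strand
#' sites) miscalls at rate `cfg$amplicon_error`. Coverage is deep
#' (`cfg$amplicon_coverage` reads per site). Deterministic under `cfg$seed`.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `pileups` (long data.frame: chrom, pos, strand, A, C,
#'   G, T, sample_id), `known_sites` (site panel), and `truth` (latent base
#'   frequency and per-construct multipliers/true frequencies).
#' @export
generate_amplicon_pileups <- function(cfg) {
  cfg <- validate_synthetic_config(cfg)
  set.seed(seed_for(cfg, "amplicon"))
  constructs <- cfg$amplicon_constructs
  ctrl <- cfg$amplicon_control
  editases <- setdiff(constructs, ctrl)
  n <- cfg$n_amplicon_sites

  sites <- data.frame(
    chrom = "chr1",
    pos = sort(sample.int(5e5, n)),
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  sites$site <- site_key(sites$chrom, sites$pos, sites$strand)

  mult <- cfg$amplicon_multipliers
  if (is.null(mult)) {
    archetypes <- list(
      p150_pref = c(p150 = 1, mZ_p150 = 0.9, N_p150 = 0.25, p110 = 0.15,
                    C_p110 = 0.8, Ad2 = 0.1, C_Ad2 = 0.6),
      p110_pref = c(p150 = 0.3, mZ_p150 = 0.3, N_p150 = 0.9, p110 = 1,
                    C_p110 = 0.4, Ad2 = 0.5, C_Ad2 = 0.2),
      promiscuous = c(p150 = 1, mZ_p150 = 1, N_p150 = 0.7, p110 = 0.8,
                      C_p110 = 0.9, Ad2 = 0.6, C_Ad2 = 0.7),
      ad2_pref = c(p150 = 0.2, mZ_p150 = 0.2, N_p150 = 0.2, p110 = 0.3,
                   C_p110 = 0.2, Ad2 = 1, C_Ad2 = 0.9)
    )
    mult <- matrix(0, nrow = n, ncol = length(editases),
                   dimnames = list(sites$site, editases))
    kind <- sample(names(archetypes), n, replace = TRUE)
    for (i in seq_len(n)) {
      prof <- archetypes[[kind[i]]]
      mult[i, ] <- ifelse(editases %in% names(prof),
                          prof[editases], stats::runif(1, 0, 0.3))
    }
  } else {
    mult <- as.matrix(mult)
    if (nrow(mult) != n || !setequal(colnames(mult), editases)) {
      stop("amplicon_multipliers must be n_amplicon_sites x editase matrix")
    }
    mult <- mult[, editases, drop = FALSE]
    rownames(mult) <- sites$site
  }

  base_freq <- stats::runif(n, 0.05, 0.5)
  rows <- list()
  for (con in constructs) {
    f <- if (con == ctrl) rep(0, n) else base_freq * mult[, con]
    f <- pmin(1, f + cfg$amplicon_error)
    cov <- rep(cfg$amplicon_coverage, n)
    edited <- stats::rbinom(n, cov, f)
    noise1 <- stats::rbinom(n, cov - edited, 5e-4)
    noise2 <- stats::rbinom(n, cov - edited - noise1, 5e-4)
    ref <- cov - edited - noise1 - noise2
    plus <- sites$strand == "+"
    A <- ifelse(plus, ref, noise1)
    G <- ifelse(plus, edited, noise2)
    T_ <- ifelse(plus, noise1, ref)
    C <- ifelse(plus, noise2, edited)
    rows[[con]] <- data.frame(chrom = sites$chrom, pos = sites$pos,
                              strand = sites$strand, A = A, C = C, G = G,
                              T = T_, sample_id = con,
                              stringsAsFactors = FALSE)
  }
  pileups <- do.call(rbind, rows)
  rownames(pileups) <- NULL

  truth <- cbind(sites, base_freq = base_freq, as.data.frame(mult))
  rownames(truth) <- NULL
  list(pileups = pileups, known_sites = sites, truth = truth)
}
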