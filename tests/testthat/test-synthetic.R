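test_that("configuration validation rejects impossible settings", {
  expect_error(synthetic_config(rip_enrichment = 0.5), "rip_enrichment")
  expect_error(synthetic_config(nonsense = 1), "unknown configuration")
  expect_error(synthetic_config(error_rate = 2), "error rates")
  cfg <- synthetic_config()
  cfg$effects["shared", "p150"] <- 1.5
  expect_error(validate_synthetic_config(cfg), "effect means")
  cfg <- synthetic_config()
  cfg$region_mix["shared", ] <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(validate_synthetic_config(cfg), "sum to 1")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- generate_editome(cfg, a1)
  e2 <- generate_editome(cfg, a1)
  expect_identical(e1, e2)
  p1 <- generate_truth_peaks(cfg, a1)
  r1 <- generate_rip_fragments(cfg, a1, p1)
  r2 <- generate_rip_fragments(cfg, a1, p1)
  expect_identical(r1$fragments, r2$fragments)
  m1 <- generate_amplicon_pileups(cfg)
  m2 <- generate_amplicon_pileups(cfg)
  expect_identical(m1, m2)
})

test_that("a single gene still carries the full feature complement", {
  cfg <- small_config(seed = 6, n_genes = 1L)
  ann <- generate_annotation(cfg)
  f <- table(ann$genes$feature)
  expect_equal(length(unique(ann$genes$transcript_id)), 1)
  expect_gte(f[["exon"]], 1)
  expect_equal(f[["5UTR"]], 1)
  expect_equal(f[["3UTR"]], 1)
})

test_that("a genome too small for the requested genes is a sizing error", {
  expect_error(
    generate_annotation(small_config(chrom_sizes = c(chr1 = 20000L),
                                     n_genes = 50L)),
    "too small")
})

test_that("a degenerate repeat mix yields a single repeat class", {
  cfg <- small_config(seed = 7, n_genes = 10L,
                      repeat_mix = c(SINE = 1, LINE = 0, LTR = 0, DNA = 0,
                                     simple = 0, other = 0))
  ann <- generate_annotation(cfg)
  expect_true(all(S4Vectors::mcols(ann$repeats)$repeat_class == "SINE"))
})

test_that("empty site configuration yields empty tables and manifest", {
  cfg <- small_config(seed = 8,
                      n_sites = c(p150_specific = 0L, p110_specific = 0L,
                                  shared = 0L, snp_artifact = 0L,
                                  below_threshold = 0L),
                      n_hyper_genes = c(p150 = 0L, p110 = 0L))
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  expect_equal(nrow(edt$sites), 0)
  expect_equal(nrow(edt$truth), 0)
})

test_that("shared sites follow the binomial law at the configured mean", {
  cfg <- small_config(seed = 9,
                      n_sites = c(p150_specific = 0L, p110_specific = 0L,
                                  shared = 150L, snp_artifact = 0L,
                                  below_threshold = 0L),
                      n_hyper_genes = c(p150 = 0L, p110 = 0L),
                      coverage_mean = 100, error_rate = 0)
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  for (cond in c("p150", "p110")) {
    rows <- edt$sites[grepl(paste0("^", cond), edt$sites$sample_id) &
                        edt$sites$coverage > 0, ]
    est <- sum(rows$alt_count) / sum(rows$coverage)
    se <- sqrt(0.1 * 0.9 / sum(rows$coverage))
    expect_lt(abs(est - 0.10), 4 * se)
  }
  # truth manifest covers every emitted site exactly once
  expect_identical(anyDuplicated(edt$truth$site), 0L)
  expect_setequal(unique(edt$sites$site), edt$truth$site)
})

test_that("SNP-artifact sites carry control-condition signal", {
  cfg <- small_config(seed = 10)
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  snp <- edt$truth$site[edt$truth$category == "snp_artifact"]
  ctrl <- edt$sites[edt$sites$site %in% snp &
                      grepl("^control", edt$sites$sample_id), ]
  expect_true(all(ctrl$alt_count > 0))
  # non-artifact sites never show control signal
  other <- edt$sites[!edt$sites$site %in% snp &
                       grepl("^control", edt$sites$sample_id), ]
  expect_true(all(other$alt_count == 0))
})

test_that("IP enrichment inside truth peaks matches the configured fold", {
  cfg <- synthetic_config(seed = 12, n_fragments = 100000L,
                          chrom_sizes = c(chr1 = 400000L, chr2 = 400000L),
                          n_genes = 60L,
                          n_truth_peaks = c(p150 = 1L, p110 = 0L),
                          n_mock_peaks = 0L,
                          rip_replicates = c(p150 = 1L, p110 = 0L,
                                             MOCK = 0L))
  cfg$rip_replicates <- c(p150 = 1L)
  ann <- generate_annotation(cfg)
  tp <- generate_truth_peaks(cfg, ann)
  rip <- generate_rip_fragments(cfg, ann, tp)
  count_in <- function(gr) {
    frags <- split_pairs(gr)
    sum(GenomicRanges::countOverlaps(tp, frags,
                                     ignore.strand = FALSE))
  }
  n_ip <- count_in(rip$fragments$p150_rep1_IP)
  n_in <- count_in(rip$fragments$p150_rep1_input)
  expect_gt(n_ip / n_in, 8 * 0.7)
  expect_lt(n_ip / n_in, 8 * 1.3)
})

test_that("enrichment one makes IP and input indistinguishable in peaks", {
  cfg <- synthetic_config(seed = 13, rip_enrichment = 1,
                          n_fragments = 20000L,
                          chrom_sizes = c(chr1 = 400000L), n_genes = 20L,
                          n_truth_peaks = c(p150 = 3L, p110 = 0L),
                          n_mock_peaks = 0L)
  cfg$rip_replicates <- c(p150 = 1L)
  ann <- generate_annotation(cfg)
  tp <- generate_truth_peaks(cfg, ann)
  rip <- generate_rip_fragments(cfg, ann, tp)
  n_ip <- sum(GenomicRanges::countOverlaps(
    tp, rip$fragments$p150_rep1_IP))
  n_in <- sum(GenomicRanges::countOverlaps(
    tp, rip$fragments$p150_rep1_input))
  # two-sample Poisson rate test at alpha = 0.01
  p <- stats::poisson.test(c(n_ip, n_in), c(1, 1))$p.value
  expect_gt(p, 0.01)
})

test_that("amplicon truth is recovered within binomial error at depth", {
  mult <- matrix(rep(1, 6), ncol = 1, dimnames = list(NULL, "A"))
  cfg <- synthetic_config(seed = 14, amplicon_constructs = c("A", "control"),
                          n_amplicon_sites = 6L,
                          amplicon_multipliers = mult,
                          amplicon_coverage = 5000L)
  amp <- generate_amplicon_pileups(cfg)
  am <- quantify_sites(amp$pileups, amp$known_sites)
  obs <- am$freq[amp$truth$site, "A"]
  f <- pmin(1, amp$truth$base_freq + cfg$amplicon_error)
  se <- sqrt(f * (1 - f) / 5000)
  expect_true(all(abs(obs - f) < 4 * se))
  # negative control sits at the background error rate
  ctrl <- am$freq[, "control"]
  expect_true(all(ctrl < cfg$amplicon_error + 4 *
                    sqrt(cfg$amplicon_error / 5000)))
})

test_that("a written synthetic run is reproducible byte for byte", {
  cfg <- small_config(seed = 15, n_fragments = 3000L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_synthetic_run(cfg, d1)
  write_synthetic_run(cfg, d2)
  files <- list.files(d1)
  expect_gt(length(files), 10)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
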