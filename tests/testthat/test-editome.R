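test_that("basic site filter boundaries are inclusive as specified", {
  expect_true(basic_site_filter(0.01, 5))
  expect_false(basic_site_filter(0.009, 100))
  expect_false(basic_site_filter(0.5, 4))
  expect_false(basic_site_filter(NA, 50))
  expect_false(basic_site_filter(0.5, NA))
})

test_that("replicate consistency needs k passing replicates", {
  m <- function(...) matrix(c(...), nrow = 1)
  expect_true(replicate_consistency_filter(m(TRUE, FALSE, TRUE)))
  expect_false(replicate_consistency_filter(m(FALSE, TRUE, FALSE)))
  expect_true(replicate_consistency_filter(m(TRUE, TRUE, TRUE)))
  expect_warning(
    out <- replicate_consistency_filter(m(TRUE, TRUE), n_expected = 3),
    "2 of 3")
  expect_true(out)
})

test_that("coverage filter requires data in two replicates per isoform", {
  m <- function(...) matrix(c(...), nrow = 1, byrow = TRUE)
  # means 10.33 and 30, both with >= 2 replicates with data
  expect_true(coverage_filter(m(12, 9, 10), m(30, 30, NA)))
  expect_false(coverage_filter(m(40, NA, NA), m(30, 30, 30)))
  expect_false(coverage_filter(m(12, 9, 10), m(5, 5, 5)))
  # boundary: mean exactly 10 passes
  expect_true(coverage_filter(m(10, 10, NA), m(10, 10, 10)))
  # zero coverage counts as no data
  expect_false(coverage_filter(m(40, 0, 0), m(30, 30, 30)))
})

test_that("efficiency calls need rate and coverage in the same replicates", {
  f <- function(...) matrix(c(...), nrow = 1, byrow = TRUE)
  expect_true(call_efficient(f(0.02, 0.03, 0.0), f(15, 12, 40)))
  expect_false(call_efficient(f(0.02, 0.03, 0.05), f(9, 8, 9)))
  expect_false(call_efficient(f(0.02, 0.005, 0.004), f(15, 100, 100)))
  # one replicate has rate, another has coverage, but never together
  expect_false(call_efficient(f(0.02, 0.005, 0.02), f(9, 100, 9)))
})

test_that("preference labels partition and exclusivity needs zero reads", {
  alt0 <- matrix(0, nrow = 3, ncol = 3)
  alt_pos <- matrix(c(0, 1, 0), nrow = 3, ncol = 3, byrow = FALSE)
  cl <- classify_preference(c(0.05, 0.04, 0.009), c(0.03, 0.004, 0.009),
                            alt_pos, alt0)
  expect_equal(cl$label, c("shared", "p150_preferential", "unclassified"))
  expect_equal(cl$exclusive, c("none", "p150", "none"))
  # other condition with any edited read is preferential but not exclusive
  cl2 <- classify_preference(0.04, 0.004, matrix(2, 1, 3), matrix(1, 1, 3))
  expect_equal(cl2$label, "p150_preferential")
  expect_equal(cl2$exclusive, "none")
  # boundary is disjoint: exactly 1 percent on both sides is shared
  cl3 <- classify_preference(0.01, 0.01, matrix(1, 1, 3), matrix(1, 1, 3))
  expect_equal(cl3$label, "shared")
})

test_that("log2 fold-difference matches hand arithmetic", {
  expect_equal(compute_log2fd(0.3, 0.3), 0)
  expect_equal(compute_log2fd(0.50, 0.10), log2(11 / 51))
  expect_equal(round(compute_log2fd(0.50, 0.10), 3), -2.213)
  expect_equal(compute_log2fd(0.00, 0.05), log2(6))
  expect_equal(round(compute_log2fd(0.00, 0.05), 3), 2.585)
  # antisymmetry under swapping the means
  for (pair in list(c(0.2, 0.7), c(0, 1), c(0.01, 0.011))) {
    expect_equal(compute_log2fd(pair[1], pair[2]),
                 -compute_log2fd(pair[2], pair[1]))
  }
  expect_error(compute_log2fd(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(compute_log2fd(0.1, 1.5), "\\[0, 1\\]")
})

test_that("Welch test matches the reference implementation to 1e-10", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(sample(2:6, 1))
    y <- runif(sample(2:6, 1))
    expect_equal(welch_p(x, y), stats::t.test(x, y)$p.value,
                 tolerance = 1e-10)
    expect_identical(welch_p(x, y), welch_p(y, x))
  }
  expect_equal(welch_p(c(0.1, 0.12, 0.14), c(0.3, 0.32, 0.34)),
               stats::t.test(c(0.1, 0.12, 0.14),
                             c(0.3, 0.32, 0.34))$p.value,
               tolerance = 1e-10)
})

test_that("Welch degenerate and missing cases are defined", {
  expect_equal(welch_p(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1)), 1)
  expect_equal(welch_p(c(0.1, 0.1), c(0.4, 0.4)), 0)
  expect_true(is.na(welch_p(0.1, c(0.2, 0.3))))
  expect_true(is.na(welch_p(c(0.1, NA, NA), c(0.2, 0.3, 0.4))))
})

test_that("Storey q-values with pi0 pinned to 1 equal Benjamini-Hochberg", {
  # hand-computed example
  q <- storey_qvalues(c(0.01, 0.02, 0.9, 0.95), pi0 = 1)
  expect_equal(q$qvalues, c(0.04, 0.04, 0.95, 0.95))
  # random vectors against the stock BH implementation
  set.seed(99)
  for (n in c(5, 100, 2000, 10000)) {
    p <- c(runif(n %/% 2), rbeta(n - n %/% 2, 0.3, 4))
    expect_equal(storey_qvalues(p, pi0 = 1)$qvalues,
                 stats::p.adjust(p, method = "BH"))
  }
})

test_that("Storey procedure falls back and stays monotone and bounded", {
  expect_equal(storey_qvalues(0.5)$qvalues, 0.5)  # n < 100: pi0 = 1
  expect_equal(storey_qvalues(0.5)$pi0, 1)
  expect_true(all(storey_qvalues(rep(1, 5))$qvalues == 1))
  set.seed(3)
  p <- c(rbeta(400, 0.2, 5), runif(600))
  st <- storey_qvalues(p)
  expect_true(st$pi0 > 0 && st$pi0 <= 1)
  ord <- order(p)
  expect_true(all(diff(st$qvalues[ord]) >= -1e-12))
  expect_true(all(st$qvalues >= 0 & st$qvalues <= 1))
  # q is never below pi0-scaled p/1 consistency: q >= pi0 * p at the top
  expect_error(storey_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("site annotation follows the priority list", {
  gm <- validate_gene_models(data.frame(
    transcript_id = c("tA", "tA", "tB", "tB"),
    gene_id = c("gA", "gA", "gB", "gB"),
    chrom = "chr1", strand = "+",
    feature = c("exon", "3UTR", "exon", "intron"),
    start = c(100L, 300L, 250L, 400L),
    end = c(300L, 400L, 400L, 900L)))
  # 3UTR of tA beats intron of tB
  sites <- data.frame(chrom = "chr1", pos = c(350L, 1600L, 50L),
                      strand = "+")
  ann <- annotate_site(sites, gm, downstream_window = 3000L)
  expect_equal(ann$region[1], "3UTR")
  # 1 nt past the transcript end within the window is Downstream
  expect_equal(ann$region[2], "Downstream")
  expect_equal(ann$region[3], "Intergenic")
  # strand-aware: a minus-strand site misses plus-strand transcripts
  annm <- annotate_site(data.frame(chrom = "chr1", pos = 350L,
                                   strand = "-"), gm)
  expect_equal(annm$region, "Intergenic")
  # downstream window boundary: transcript tB ends at 900, window 3000
  far <- annotate_site(data.frame(chrom = "chr1", pos = 3900L,
                                  strand = "+"), gm,
                       downstream_window = 3000L)
  expect_equal(far$region, "Downstream")
  farther <- annotate_site(data.frame(chrom = "chr1", pos = 3901L,
                                      strand = "+"), gm,
                           downstream_window = 3000L)
  expect_equal(farther$region, "Intergenic")
})

test_that("peak annotation uses any overlapped base and the priority", {
  gm <- validate_gene_models(data.frame(
    transcript_id = c("tA", "tA", "tB"),
    gene_id = c("gA", "gA", "gB"),
    chrom = "chr1", strand = "+",
    feature = c("exon", "intron", "5UTR"),
    start = c(100L, 300L, 5000L), end = c(300L, 900L, 5100L)))
  pk <- gr_ho("chr1", c(250, 5050), c(600, 5080), "+")
  ann <- annotate_peak(pk, gm)
  expect_equal(ann$region, c("Exon", "5UTR"))
})

test_that("repeat class assignment breaks ties by overlap then order", {
  rep_gr <- gr_ho("chr1", c(100, 180, 500), c(210, 260, 600),
                  strand = "+",
                  repeat_class = c("SINE", "LINE", "LTR"))
  # site inside the SINE only
  q1 <- gr_ho("chr1", 120, 121)
  expect_equal(assign_repeat_class(q1, rep_gr), "SINE")
  # no repeat
  expect_equal(assign_repeat_class(gr_ho("chr1", 400, 401), rep_gr),
               "nonrepetitive")
  # interval overlapping SINE by 30 and LINE by 80: larger overlap wins
  q2 <- gr_ho("chr1", 180, 260)
  expect_equal(assign_repeat_class(q2, rep_gr), "LINE")
  # equal overlaps fall back to the class order
  rep_eq <- gr_ho("chr1", c(0, 0), c(100, 100), "+",
                  repeat_class = c("simple", "LTR"))
  expect_equal(assign_repeat_class(gr_ho("chr1", 10, 20), rep_eq), "LTR")
})

test_that("per-gene event counts summarize like a box plot", {
  cls <- data.frame(gene_id = c("gA", "gA", "gA", "gB", "gC"),
                    efficient_p150 = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                    efficient_p110 = FALSE,
                    log2fd = c(-2, -2, -2, -1.5, 0.5))
  ev <- events_per_region(cls, "efficient_p150")
  expect_setequal(ev$counts$n_sites, c(3, 1))
  expect_equal(ev$summary$median, 2)
  expect_equal(ev$summary$n_genes, 2)
  # zero-qualifying input yields an empty distribution
  none <- events_per_region(cls, rep(FALSE, 5))
  expect_equal(none$summary$n_genes, 0)
})

test_that("the full pipeline respects order and only removes sites", {
  cfg <- small_config(seed = 31)
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  res <- run_editome(edt$sites, edt$sample_map, ann$genes, ann$repeats)
  f <- res$funnel
  expect_true(all(diff(unname(f)) <= 0))  # monotone funnel
  expect_equal(unname(f["raw"]), length(unique(edt$sites$site)))
  # classification partition
  s <- summarize_editome(res$classification)
  expect_equal(sum(s$labels$n), nrow(res$classification))
  expect_true(all(res$classification$label %in% s$labels$label))
  # region distribution rows sum to the efficient subset totals
  for (iso in c("p150", "p110")) {
    n_eff <- sum(res$classification[[paste0("efficient_", iso)]])
    expect_equal(sum(s$regions$n[s$regions$isoform == iso]), n_eff)
  }
  # planted hyperedited genes surface in the per-gene distribution
  hyper <- unique(edt$truth$gene_id[edt$truth$hyper &
                                      edt$truth$category ==
                                        "p150_specific"])
  ev <- events_per_region(res$classification, "preferred_p150")
  expect_true(any(ev$counts$gene_id %in% hyper &
                    ev$counts$n_sites >= 10))
})

test_that("control subtraction requires a control condition", {
  cfg <- small_config(seed = 32)
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  sm <- edt$sample_map[edt$sample_map$condition != "control", ]
  sites <- edt$sites[edt$sites$sample_id %in% sm$sample_id, ]
  expect_error(run_editome(sites, sm), "condition 'control'")
  ct <- condition_tables(sites, sm)
  expect_error(subtract_control_sites(ct), "control")
})

test_that("invalid thresholds are rejected before computation", {
  cfg <- small_config(seed = 33)
  ann <- generate_annotation(cfg)
  edt <- generate_editome(cfg, ann)
  expect_error(run_editome(edt$sites, edt$sample_map,
                           params = list(min_rate = -1)),
               "non-negative")
})
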