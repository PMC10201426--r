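test_that("strand folding onto pseudo-chromosomes is a bijection", {
  fr <- gr_ho("chr1", 100, 200, "+")
  sp <- split_strands(fr)
  expect_equal(as.character(GenomicRanges::seqnames(sp)), "chr1__fwd")
  expect_equal(GenomicRanges::start(sp) - 1L, 100L)

  pk <- GenomicRanges::GRanges("chr2__rev", IRanges::IRanges(51, 150))
  bk <- merge_strands(pk)
  expect_equal(as.character(GenomicRanges::seqnames(bk)), "chr2")
  expect_equal(as.character(GenomicRanges::strand(bk)), "-")

  set.seed(17)
  iv <- random_intervals(100, 50000)
  fr <- gr_ho(sample(c("chr1", "chr2"), 100, replace = TRUE),
              iv$start, iv$end,
              strand = sample(c("+", "-"), 100, replace = TRUE))
  rt <- merge_strands(split_strands(fr))
  expect_equal(ho_df(rt), ho_df(fr))
  expect_equal(as.character(GenomicRanges::strand(rt)),
               as.character(GenomicRanges::strand(fr)))

  expect_error(merge_strands(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5))),
    "pseudo-chromosome suffix")
})

test_that("pair splitting yields the mates' own coordinates", {
  fr <- gr_ho("chr1", c(100, 212, 500), c(138, 250, 538), "+",
              name = c("p1/1", "p1/2", "s1"))
  out <- split_pairs(fr)
  expect_equal(length(out), 3)
  expect_equal(S4Vectors::mcols(out)$name, c("p1", "p1", "s1"))
  expect_equal(ho_df(out), ho_df(fr))

  # 0 pairs, 3 singletons pass through
  single <- gr_ho("chr1", c(1, 10, 20), c(5, 15, 25), "+",
                  name = c("a", "b", "c"))
  expect_equal(length(split_pairs(single)), 3)

  # 50 random pairs -> 100 intervals, multiset of coordinates preserved
  set.seed(23)
  iv <- random_intervals(100, 10000, min_w = 30, max_w = 40)
  nm <- paste0("pair", rep(1:50, each = 2), "/", rep(1:2, 50))
  fr <- gr_ho("chr1", iv$start, iv$end, "+", name = nm)
  out <- split_pairs(fr)
  expect_equal(length(out), 100)
  expect_setequal(paste(ho_df(out)$start, ho_df(out)$end),
                  paste(iv$start, iv$end))

  # inconsistent mate chromosomes are an error
  bad <- gr_ho(c("chr1", "chr2"), c(1, 1), c(40, 40), "+",
               name = c("x/1", "x/2"))
  expect_error(split_pairs(bad), "different chromosomes")
})

test_that("the per-base Poisson tail matches explicit summation", {
  expect_equal(isoedit:::poisson_tail(12, 2), oracle_poisson_tail(12, 2),
               tolerance = 1e-12)
  expect_equal(isoedit:::poisson_tail(12, 2), 1.35e-6, tolerance = 0.02)
  for (k in c(1, 3, 8, 20)) {
    for (lambda in c(0.5, 2, 10)) {
      expect_equal(isoedit:::poisson_tail(k, lambda),
                   oracle_poisson_tail(k, lambda), tolerance = 1e-12)
    }
  }
})

test_that("identical IP and input produce no peaks", {
  set.seed(31)
  for (seed in 1:3) {
    set.seed(seed)
    iv <- random_intervals(3000, 100000, min_w = 38, max_w = 38)
    fr <- gr_ho("chr1__fwd", iv$start, iv$end, "+")
    cfg <- peak_call_config(gsize = 200000)
    pk <- call_peaks(fr, fr, cfg)
    expect_equal(length(pk), 0)
  }
})

test_that("a planted enriched region is recovered as one peak", {
  set.seed(37)
  L <- 200000
  n_bg <- 20000
  bg <- random_intervals(n_bg, L, min_w = 38, max_w = 38)
  input <- gr_ho("chr1__fwd", bg$start, bg$end, "+")
  # 8x density inside [50000, 50500)
  extra <- random_intervals(round(n_bg / L * 500 * 7), 500,
                            min_w = 38, max_w = 38)
  ip <- c(gr_ho("chr1__fwd", bg$start, bg$end, "+"),
          gr_ho("chr1__fwd", extra$start + 50000, extra$end + 50000, "+"))
  cfg <- peak_call_config(gsize = 2 * L)
  pk <- call_peaks(ip, input, cfg)
  expect_equal(length(pk), 1)
  truth <- gr_ho("chr1__fwd", 50000, 50500)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(pk, truth))
  expect_gte(inter, 0.5 * GenomicRanges::width(pk))
  expect_gte(inter, 0.5 * 500)
  expect_gt(S4Vectors::mcols(pk)$fold_enrichment, 2)
  # empty IP warns and returns nothing
  expect_warning(none <- call_peaks(input[0], input, cfg), "empty IP")
  expect_equal(length(none), 0)
})

test_that("transcriptomic mode uses fragments unextended", {
  set.seed(43)
  L <- 50000
  bg <- random_intervals(4000, L, min_w = 150, max_w = 150)
  input <- gr_ho("tx1", bg$start, bg$end, "+")
  extra <- random_intervals(600, 800 - 150, min_w = 150, max_w = 150)
  ip <- c(input, gr_ho("tx1", extra$start + 20000, extra$end + 20000, "+"))
  cfg <- peak_call_config(mode = "transcriptomic", gsize = L)
  expect_equal(cfg$gsize, L)
  expect_equal(peak_call_config(mode = "transcriptomic")$gsize, 289357337)
  pk <- call_peaks(ip, input, cfg)
  expect_equal(length(pk), 1)
  inter <- GenomicRanges::width(GenomicRanges::pintersect(
    pk, gr_ho("tx1", 20000, 20800)))
  expect_gte(inter, 0.5 * GenomicRanges::width(pk))
})

test_that("replicate combination keeps cross-supported peaks and unions", {
  r1 <- gr_ho("chr1", 100, 200, "+")
  r2 <- gr_ho("chr1", 200, 250, "+")  # book-ended with r1
  out <- combine_replicates(list(r1, r2))
  expect_equal(ho_df(out), data.frame(start = 100L, end = 250L))

  # disjoint replicate peaks are dropped
  out2 <- combine_replicates(list(gr_ho("chr1", 100, 200, "+"),
                                  gr_ho("chr1", 300, 400, "+")))
  expect_equal(length(out2), 0)

  # union of overlapping retained peaks
  out3 <- combine_replicates(list(
    gr_ho("chr1", c(100, 150), c(200, 260), "+"),
    gr_ho("chr1", 180, 300, "+")))
  expect_equal(ho_df(out3), data.frame(start = 100L, end = 300L))

  expect_error(combine_replicates(list(r1)), "at least 2")
})

test_that("MOCK subtraction follows the fractional 90 percent rule", {
  t1 <- gr_ho("chr1", 100, 200, "+", pileup_max = 9)
  expect_equal(ho_df(subtract_control_peaks(t1, gr_ho("chr1", 500, 600,
                                                      "+"))),
               data.frame(start = 100L, end = 200L))
  # 50 percent covered: remainder [100,150)
  out <- subtract_control_peaks(t1, gr_ho("chr1", 150, 300, "+"))
  expect_equal(ho_df(out), data.frame(start = 100L, end = 150L))
  expect_equal(S4Vectors::mcols(out)$pileup_max, 9)  # scores inherited
  # 95 percent covered: removed entirely
  expect_equal(length(subtract_control_peaks(t1, gr_ho("chr1", 95, 195,
                                                       "+"))), 0)
  # exactly 90 percent keeps the remainder (rule is strict)
  out90 <- subtract_control_peaks(t1, gr_ho("chr1", 100, 190, "+"))
  expect_equal(ho_df(out90), data.frame(start = 190L, end = 200L))
  # strand-aware: opposite-strand mock does not subtract
  expect_equal(ho_df(subtract_control_peaks(t1, gr_ho("chr1", 100, 200,
                                                      "-"))),
               data.frame(start = 100L, end = 200L))
})

test_that("size and reference-chromosome filters behave at boundaries", {
  cfg <- peak_call_config()
  pk <- gr_ho(c("chr1", "chr1", "chrM", "chrX"), c(0, 0, 0, 0),
              c(40, 39, 500, 100), "+")
  out <- filter_peaks(pk, cfg)
  expect_equal(ho_df(out),
               data.frame(start = c(0L, 0L), end = c(40L, 100L)))
  expect_equal(as.character(GenomicRanges::seqnames(out)),
               c("chr1", "chrX"))
})

test_that("transcriptomic subpeaks are removed by containment", {
  pk <- gr_ho("chr1", c(100, 150), c(400, 300), "+",
              transcript_id = c("txA", "txB"))
  out <- remove_subpeaks(pk)
  expect_equal(S4Vectors::mcols(out)$transcript_id, "txA")
  # identical peaks keep the lowest transcript id
  dup <- gr_ho("chr1", c(100, 100), c(400, 400), "+",
               transcript_id = c("txB", "txA"))
  out2 <- remove_subpeaks(dup)
  expect_equal(S4Vectors::mcols(out2)$transcript_id, "txA")
  # partial overlap keeps both
  part <- gr_ho("chr1", c(100, 200), c(300, 500), "+",
                transcript_id = c("txA", "txB"))
  expect_equal(length(remove_subpeaks(part)), 2)
  # containment within the same transcript is untouched
  same <- gr_ho("chr1", c(100, 150), c(400, 300), "+",
                transcript_id = c("txA", "txA"))
  expect_equal(length(remove_subpeaks(same)), 2)
})

test_that("peak statistics report sizes and directional overlaps", {
  a <- gr_ho("chr1", 0, 100, "+")
  b <- gr_ho("chr1", c(10, 30), c(20, 40), "+")
  st <- peak_stats(list(A = a, B = b))
  expect_equal(st$sizes$n, c(1, 2))
  expect_equal(st$sizes$mean_size[2], 10)
  ov <- st$overlaps
  expect_equal(ov$n_overlapping[ov$from == "A" & ov$to == "B"], 1)
  expect_equal(ov$n_overlapping[ov$from == "B" & ov$to == "A"], 2)

  st0 <- peak_stats(list(E = a[0]))
  expect_equal(st0$sizes$n, 0)
  expect_true(is.na(st0$sizes$mean_size))

  sizes <- peak_stats(list(S = gr_ho("chr1", c(0, 100), c(40, 160),
                                     "+")))$sizes
  expect_equal(sizes$mean_size, 50)
})

test_that("fragments overlapping an exclusion list are dropped", {
  fr <- gr_ho("chr1", c(0, 100, 200), c(40, 140, 240), "+")
  excl <- gr_ho("chr1", 120, 130, "-")
  expect_equal(length(exclude_intervals(fr, excl)), 2)
  expect_equal(length(exclude_intervals(fr, excl[0])), 3)
})

test_that("a small end-to-end RIP run recovers its planted peaks", {
  cfg <- small_config(seed = 41)
  ann <- generate_annotation(cfg)
  tp <- generate_truth_peaks(cfg, ann)
  rip <- generate_rip_fragments(cfg, ann, tp)
  pcfg <- peak_call_config(gsize = 2 * sum(ann$chrom_sizes))
  res <- run_rip(rip$fragments, cfg = pcfg)
  cond_of <- as.character(S4Vectors::mcols(tp)$condition)
  for (cond in c("p150", "p110")) {
    m <- match_truth_peaks(res$peaks[[cond]], tp[cond_of == cond])
    expect_gte(m$recall, 0.8)
    expect_gte(m$precision, 0.8)
  }
  # funnel counts are recorded for every stage
  expect_true(all(c("replicate_peaks", "combined", "mock_subtracted",
                    "filtered") %in% names(res$funnel$p150)))
})
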