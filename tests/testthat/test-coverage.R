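flat_profile <- function(ratio, chrom = "chr1", ws = 200000L,
                         count_scale = 1000) {
  n <- length(ratio)
  starts <- seq(1, by = ws, length.out = n)
  depth_profile(chrom = rep(chrom, n), start = starts,
                end = starts + ws - 1, count = ratio * count_scale,
                window_size = ws, sample = "s",
                ratio = ratio)
}

test_that("normalization fixes the diploid baseline at 1 and is scale invariant", {
  p <- depth_profile(rep("chr1", 20), seq(1, by = 1e4, length.out = 20),
                     seq(1e4, by = 1e4, length.out = 20),
                     count = rep(500, 20), window_size = 1e4)
  n1 <- normalize_depth(p)
  expect_equal(n1$ratio, rep(1, 20))
  p2 <- p; p2$count <- p2$count * 2
  expect_equal(normalize_depth(p2)$ratio, n1$ratio)
  p$count <- rep(0, 20)
  expect_error(normalize_depth(p), "median depth is zero")
  expect_error(normalize_depth(p[1:5, ]), "at least 10")
})

test_that("trisomic chromosomes normalize near ratio 1.5 at low dispersion", {
  cfg <- sim_config(seed = 21, depth_dispersion = 1e-4)
  d <- simulate_depth("s", list(list(kind = "whole_chrom_trisomy",
                                     chrom = "chr3")), cfg, 200000L)
  nd <- normalize_depth(d)
  med <- median(nd$ratio[nd$chrom == "chr3"])
  expect_gte(med, 1.45); expect_lte(med, 1.55)
})

test_that("segment calling equals the brute-force run-length oracle on random vectors", {
  set.seed(55)
  for (rep in 1:30) {
    n <- sample(20:1000, 1)
    ratio <- sample(c(0.5, 0.6, 1.0, 1.1, 1.5, 1.7), n, replace = TRUE,
                    prob = c(1, 1, 8, 6, 1, 1))
    # keep the chromosome median diploid so no aneuploidy escalation
    if (median(ratio) < 0.7 || median(ratio) > 1.3) next
    np <- flat_profile(ratio)
    got <- call_segments(np)$segments
    want <- seg_oracle(ratio)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      ws <- 200000L
      expect_equal(got$start, (want$first - 1) * ws + 1)
      expect_equal(got$end, want$last * ws)
      expect_equal(got$state, want$state)
    }
  }
})

test_that("no calls on a quiet profile; two separated deletions stay distinct", {
  quiet <- flat_profile(rep(1, 50))
  calls <- call_segments(quiet)
  expect_equal(nrow(calls$segments), 0)
  expect_equal(nrow(calls$aneuploidy), 0)
  two <- flat_profile(c(rep(1, 10), rep(0.5, 5), rep(1, 4), rep(0.5, 6),
                        rep(1, 25)))
  segs <- call_segments(two)$segments
  expect_equal(nrow(segs), 2)
  expect_equal(segs$state, c("loss", "loss"))
})

test_that("a whole chromosome beyond threshold escalates to an aneuploidy call", {
  tri <- flat_profile(rep(1.5, 50), chrom = "chrT")
  dip <- flat_profile(rep(1.0, 50), chrom = "chrD")
  both <- rbind(tri, dip)
  attr(both, "window_size") <- 200000L
  calls <- call_segments(both)
  expect_equal(nrow(calls$segments), 0)
  expect_equal(calls$aneuploidy$chrom, "chrT")
  expect_equal(calls$aneuploidy$type, "trisomy")
  expect_equal(calls$aneuploidy$median_ratio, 1.5)
})

test_that("breakpoint refinement recovers a noise-free step exactly and declines flat data", {
  ws <- 10000L
  n <- 200
  ratio <- c(rep(1, 80), rep(0.5, 60), rep(1, 60))
  fine <- flat_profile(ratio, ws = ws)
  seg <- data.frame(chrom = "chr1", start = (80 * ws) + 1 + 3 * ws,
                    end = 140 * ws - 2 * ws, state = "loss")  # offset coarse
  ref <- refine_breakpoints(seg, fine, flank_bp = 100000)
  expect_true(ref$start_refined && ref$end_refined)
  expect_equal(ref$start, 80 * ws + 1)
  expect_equal(ref$end, 140 * ws)
  flat <- flat_profile(rep(1, 200), ws = ws)
  seg2 <- data.frame(chrom = "chr1", start = 50 * ws + 1, end = 100 * ws,
                     state = "loss")
  ref2 <- refine_breakpoints(seg2, flat, flank_bp = 100000)
  expect_false(ref2$start_refined)
  expect_equal(ref2$start, seg2$start)
})

test_that("refinement lands within one fine window of truth under noise", {
  hits <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = 1000 + s)
    ev <- list(list(kind = "segmental_deletion", chrom = "chr2",
                    start = 4000001, end = 7000000))
    fine <- normalize_depth(simulate_depth("s", ev, cfg, 10000L))
    seg <- data.frame(chrom = "chr2", start = 4000001 + 150000,
                      end = 7000000 - 150000, state = "loss")
    ref <- refine_breakpoints(seg, fine, flank_bp = 400000)
    if (abs(ref$start - 4000001) <= 10000 &&
          abs(ref$end - 7000000) <= 10000) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("interval sizes reproduce printed Mb values and overlap arithmetic", {
  expect_equal(interval_size_mb(106843549, 121215358), 14.37)
  expect_equal(interval_size_mb(102664648, 114505909), 11.84)
  expect_equal(interval_size_mb(107114315, 114505909), 7.39)
  expect_equal(interval_size_mb(1, 1000001), 1.00)
  expect_error(interval_size_mb(100, 100), "greater")
  ov <- interval_overlap(c(106843549, 121215358), c(107114315, 114505909))
  expect_equal(ov$start, 107114315)
  expect_equal(ov$end, 114505909)
  expect_equal(ov$size_mb, 7.39)
  expect_null(interval_overlap(c(1, 10), c(20, 30)))
  same <- interval_overlap(c(5, 15), c(5, 15))
  expect_equal(c(same$start, same$end), c(5, 15))
})
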