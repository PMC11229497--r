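test_that("event-free background genotypes are Hardy-Weinberg distributed", {
  cfg <- sim_config(seed = 5, n_controls = 100L, n_global_extra = 0L,
                    families = "solo", n_background_variants = 10000L)
  sim <- simulate_cohort(cfg, events = NULL)
  expect_equal(nrow(sim$truth), 0)
  ctrl <- sim$cohort$samples$role == "control"
  gt <- sim$cohort$gt[, ctrl]
  n <- ncol(gt)
  n_aa <- rowSums(gt == 0L); n_ab <- rowSums(gt == 1L)
  n_bb <- rowSums(gt == 2L)
  p <- (2 * n_aa + n_ab) / (2 * n)
  exp_counts <- cbind(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  obs <- cbind(n_aa, n_ab, n_bb)
  ok <- exp_counts > 0
  chi2 <- rowSums((obs - exp_counts)^2 / pmax(exp_counts, 1e-12))
  pval <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  expect_gte(mean(pval > 0.001), 0.99)
})

test_that("case genotypes are Mendelian-consistent with sequenced parents at background sites", {
  cfg <- sim_config(seed = 6, n_background_variants = 3000L)
  sim <- simulate_cohort(cfg, default_events(cfg))
  trio <- Filter(function(f) f$design == "trio", sim$families)[[1]]
  planted <- paste(sim$truth$chrom, sim$truth$start)
  bg <- !(paste(sim$cohort$variants$chrom, sim$cohort$variants$pos) %in%
            planted)
  g_case <- sim$cohort$gt[bg, trio$case]
  g_sire <- sim$cohort$gt[bg, trio$sire]
  g_dam <- sim$cohort$gt[bg, trio$dam]
  lo <- (g_sire == 2L) + (g_dam == 2L)          # forced alt transmissions
  hi <- (g_sire >= 1L) + (g_dam >= 1L)          # possible alt transmissions
  expect_true(all(g_case >= lo & g_case <= hi))
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- sim_config(seed = 123, n_background_variants = 500L)
  s1 <- simulate_cohort(cfg, default_events(cfg))
  s2 <- simulate_cohort(cfg, default_events(cfg))
  f1 <- tempfile(); f2 <- tempfile()
  write_vcf(s1$cohort, f1); write_vcf(s2$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)
})

test_that("planted scenarios force the contracted genotype patterns", {
  cfg <- sim_config(seed = 9, n_background_variants = 1000L)
  sim <- simulate_cohort(cfg, default_events(cfg))
  co <- sim$cohort
  glob <- co$samples$sample[co$samples$role %in% c("control", "global")]
  tr <- sim$truth

  rec_trio <- tr[which(tr$scenario == "recessive_trio"), ]
  fam <- Filter(function(f) f$case == rec_trio$sample, sim$families)[[1]]
  i <- match(paste(rec_trio$chrom, rec_trio$start),
             paste(co$variants$chrom, co$variants$pos))
  expect_equal(unname(co$gt[i, fam$case]), 2L)
  expect_equal(unname(co$gt[i, fam$sire]), 1L)
  expect_equal(unname(co$gt[i, fam$dam]), 1L)
  q <- cohort_allele_query(co, co$variants[i, c("chrom", "pos", "ref",
                                               "alt")], glob)
  expect_equal(unname(q[c("n_hom_alt", "n_het")]), c(0, 12))

  rec_solo <- tr[which(tr$scenario == "recessive_solo"), ]
  j <- match(paste(rec_solo$chrom, rec_solo$start),
             paste(co$variants$chrom, co$variants$pos))
  q2 <- cohort_allele_query(co, co$variants[j, c("chrom", "pos", "ref",
                                                "alt")], glob)
  expect_equal(unname(q2[c("n_hom_alt", "n_het")]), c(0, 7))

  dn <- tr[which(tr$scenario == "denovo"), ]
  k <- match(paste(dn$chrom, dn$start),
             paste(co$variants$chrom, co$variants$pos))
  non_case <- setdiff(co$samples$sample, dn$sample)
  q3 <- cohort_allele_query(co, co$variants[k, c("chrom", "pos", "ref",
                                                "alt")], non_case)
  expect_equal(unname(q3[c("n_hom_alt", "n_het")]), c(0, 0))
  expect_equal(unname(co$gt[k, dn$sample]), 1L)
})

test_that("scenario/design mismatches and carrier overflow are rejected", {
  cfg <- sim_config(seed = 2, n_background_variants = 200L)
  sim <- simulate_cohort(cfg, events = NULL)
  solo <- Filter(function(f) f$design == "solo", sim$families)[[1]]
  gm <- synthetic_gene_models()
  expect_error(plant_variant_scenario(sim$cohort, "recessive_trio", solo,
                                      gm$geneA), "incompatible")
  trio <- Filter(function(f) f$design == "trio", sim$families)[[1]]
  expect_error(plant_variant_scenario(sim$cohort, "recessive_trio", trio,
                                      gm$geneA, k_carriers = 999L),
               "exceeds")
  expect_error(plant_variant_scenario(sim$cohort, "denovo", trio,
                                      gm$geneC, k_carriers = 3L),
               "no carriers")
})

test_that("depth simulation respects copy-number expectations", {
  cfg <- sim_config(seed = 3, depth_dispersion = 0)
  ev <- list(list(kind = "whole_chrom_trisomy", chrom = "chr3"),
             list(kind = "segmental_deletion", chrom = "chr2",
                  start = 2000001, end = 5000000))
  d <- simulate_depth("s1", ev, cfg, 200000L)
  nd <- normalize_depth(d)
  tri <- nd$ratio[nd$chrom == "chr3"]
  expect_gte(mean(tri), 1.45); expect_lte(mean(tri), 1.55)
  del <- nd$ratio[nd$chrom == "chr2" & nd$start >= 2000001 &
                    nd$end <= 5000000]
  expect_gte(mean(del), 0.45); expect_lte(mean(del), 0.55)
  dip <- nd$ratio[nd$chrom == "chr1"]
  expect_lt(abs(mean(dip) - 1), 0.05)
  # overlapping deletions on one chromosome are rejected
  bad <- list(list(kind = "segmental_deletion", chrom = "chr2",
                   start = 1, end = 100),
              list(kind = "segmental_deletion", chrom = "chr2",
                   start = 50, end = 200))
  expect_error(simulate_depth("s1", bad, cfg, 200000L), "overlap")
})
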