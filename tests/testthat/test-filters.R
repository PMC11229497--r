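# genotype-predicate brute force: literal per-variant loops used as the
# equivalence oracle for all three filters
brute_case_recessive <- function(co, fam, ctrl, glob) {
  keep <- logical(nrow(co$variants))
  for (i in seq_len(nrow(co$variants))) {
    g <- co$gt[i, ]
    if (is.na(g[fam$case]) || g[fam$case] != 2L) next
    par_ok <- TRUE
    for (p in c(fam$sire, fam$dam)) if (!is.na(p))
      if (is.na(g[p]) || g[p] != 1L) par_ok <- FALSE
    if (!par_ok) next
    if (any(is.na(g[ctrl])) || any(g[ctrl] != 0L)) next
    if (any(is.na(g[glob])) || any(g[glob] == 2L)) next
    if (!isTRUE(co$variants$consequence[i] %in% PROTEIN_CHANGING)) next
    if (mean(!is.na(g)) < 0.9) next
    keep[i] <- TRUE
  }
  which(keep)
}

brute_denovo <- function(co, fam, ctrl, glob) {
  keep <- logical(nrow(co$variants))
  others <- union(ctrl, glob)
  for (i in seq_len(nrow(co$variants))) {
    g <- co$gt[i, ]
    if (is.na(g[fam$case]) || g[fam$case] != 1L) next
    bad <- FALSE
    for (p in c(fam$sire, fam$dam)) if (!is.na(p))
      if (is.na(g[p]) || g[p] != 0L) bad <- TRUE
    if (any(is.na(g[others])) || any(g[others] != 0L)) bad <- TRUE
    if (bad) next
    if (!isTRUE(co$variants$consequence[i] %in% PROTEIN_CHANGING)) next
    if (mean(!is.na(g)) < 0.9) next
    keep[i] <- TRUE
  }
  which(keep)
}

brute_shared <- function(co, cases, ctrl) {
  keep <- logical(nrow(co$variants))
  for (i in seq_len(nrow(co$variants))) {
    g <- co$gt[i, ]
    if (any(is.na(g[cases])) || any(g[cases] != 2L)) next
    if (!isTRUE(co$variants$consequence[i] %in% PROTEIN_CHANGING)) next
    if (any(is.na(g[ctrl])) || any(g[ctrl] != 0L)) next
    if (mean(!is.na(g)) < 0.9) next
    keep[i] <- TRUE
  }
  which(keep)
}

random_small_cohort <- function(seed) {
  set.seed(seed)
  n_v <- sample(50:200, 1)
  roles <- c("case", "sire", "dam", "case", rep("control", 6),
             rep("global", 4))
  gt <- matrix(sample(c(0L, 0L, 0L, 1L, 2L, NA), n_v * length(roles),
                      replace = TRUE), n_v, length(roles))
  tiny_cohort(gt, roles = roles,
              consequence = sample(c("missense", "synonymous", "non_coding",
                                     "frameshift"), n_v, replace = TRUE))
}

test_that("filters equal the literal genotype-predicate scan on random cohorts", {
  for (seed in 1:8) {
    co <- random_small_cohort(seed)
    ids <- co$samples$sample
    fam_trio <- case_family(ids[1], ids[2], ids[3])
    fam_solo <- case_family(ids[4])
    ctrl <- ids[co$samples$role == "control"]
    glob <- ids[co$samples$role %in% c("control", "global")]
    for (fam in list(fam_trio, fam_solo)) {
      fr <- filter_case_recessive(co, fam, ctrl, glob)
      expect_equal(as.integer(rownames(fr$candidates)),
                   brute_case_recessive(co, fam, ctrl, glob))
      fd <- filter_denovo_dominant(co, fam, ctrl, glob)
      expect_equal(as.integer(rownames(fd$candidates)),
                   brute_denovo(co, fam, ctrl, glob))
      expect_true(all(diff(fr$funnel$n) <= 0))
      expect_true(all(diff(fd$funnel$n) <= 0))
    }
    fs <- filter_shared_recessive(co, c(ids[1], ids[4]), ctrl)
    expect_equal(as.integer(rownames(fs$candidates)),
                 brute_shared(co, c(ids[1], ids[4]), ctrl))
  }
})

test_that("per-case planted recessives leave the shared-recessive scan empty", {
  cfg <- sim_config(seed = 31, n_background_variants = 2000L)
  sim <- simulate_cohort(cfg, default_events(cfg))
  cases <- vapply(sim$families, `[[`, "", "case")
  ctrl <- sim$cohort$samples$sample[sim$cohort$samples$role == "control"]
  fs <- filter_shared_recessive(sim$cohort, cases, ctrl)
  expect_equal(nrow(fs$candidates), 0)
  expect_equal(fs$funnel$n[length(fs$funnel$n)], 0)
  expect_error(filter_shared_recessive(sim$cohort, cases[1], ctrl),
               "at least 2")
})

test_that("a variant shared hom_alt by all cases and absent in controls is the sole shared candidate", {
  gt <- matrix(0L, 5, 8)
  gt[3, 1:2] <- 2L            # both cases hom alt
  gt[1, 1] <- 2L              # in one case only
  gt[2, 1:3] <- c(2L, 2L, 1L) # shared but a control carries it
  co <- tiny_cohort(gt, roles = c("case", "case", rep("control", 6)))
  ids <- co$samples$sample
  fs <- filter_shared_recessive(co, ids[1:2], ids[3:8])
  expect_equal(nrow(fs$candidates), 1)
  expect_equal(fs$candidates$pos, co$variants$pos[3])
})

test_that("trio recessive requires both parents heterozygous", {
  gt <- matrix(0L, 2, 9)
  gt[1, 1:3] <- c(2L, 1L, 1L)   # correct trio pattern
  gt[2, 1:3] <- c(2L, 1L, 0L)   # dam hom ref -> rejected
  co <- tiny_cohort(gt, roles = c("case", "sire", "dam", rep("control", 4),
                                  rep("global", 2)))
  ids <- co$samples$sample
  fam <- case_family(ids[1], ids[2], ids[3])
  fr <- filter_case_recessive(co, fam, ids[4:7], ids[4:9])
  expect_equal(nrow(fr$candidates), 1)
  expect_equal(fr$candidates$pos, co$variants$pos[1])
})

test_that("de novo candidates must be absent from parents and all controls", {
  gt <- matrix(0L, 3, 9)
  gt[1, 1] <- 1L                # true de novo
  gt[2, c(1, 2)] <- 1L          # inherited from sire -> rejected
  gt[3, c(1, 5)] <- 1L          # also in a control -> rejected
  co <- tiny_cohort(gt, roles = c("case", "sire", "dam", rep("control", 4),
                                  rep("global", 2)))
  ids <- co$samples$sample
  fam <- case_family(ids[1], ids[2], ids[3])
  fd <- filter_denovo_dominant(co, fam, ids[4:7], ids[4:9])
  expect_equal(nrow(fd$candidates), 1)
  expect_equal(fd$candidates$pos, co$variants$pos[1])
  expect_equal(unname(unlist(fd$candidates[1, c("n_hom_alt", "n_het")])),
               c(0, 0))
})

test_that("cohort_allele_query counts genotypes exactly and flags missing", {
  gt <- matrix(c(2L, 1L, 1L, 0L, NA), 1, 5)
  co <- tiny_cohort(gt, roles = rep("control", 5))
  v <- co$variants[1, c("chrom", "pos", "ref", "alt")]
  q <- cohort_allele_query(co, v, co$samples$sample)
  expect_equal(unname(q), c(1, 2, 1))
  expect_equal(unname(cohort_allele_query(co, v, character())), c(0, 0, 0))
  v2 <- v; v2$pos <- 999999
  expect_error(cohort_allele_query(co, v2, co$samples$sample), "not found")
})
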