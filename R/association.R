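#' Method-of-moments pairwise relatedness (IBD proportion, PI-HAT analogue)
#'
#' For each sample pair, identity-by-state counts over all polymorphic sites
#' are combined with per-site allele frequencies to estimate the probability
#' of sharing 0, 1 or 2 alleles identical by descent, PLINK-style; the
#' returned statistic is P(IBD=2) + P(IBD=1)/2, clamped to [0, 1].
#'
#' @param cohort A [cohort_genotypes()] or a genotype matrix (variants x
#'   samples, codes 0/1/2/NA).
#' @param sample_ids Optional subset of samples.
#' @return Symmetric matrix of relatedness estimates in [0, 1] with unit
#'   diagonal.
#' @export
pairwise_relatedness <- function(cohort, sample_ids = NULL) {
  gt <- if (inherits(cohort, "cohort_genotypes")) cohort$gt else cohort
  if (!is.null(sample_ids)) gt <- gt[, sample_ids, drop = FALSE]
  n <- ncol(gt)
  if (n < 2) stop("need at least 2 samples")
  p <- rowMeans(gt, na.rm = TRUE) / 2       # alt allele frequency
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic sites (allele frequencies undefined)")
  gt <- gt[poly, , drop = FALSE]
  p <- p[poly]; q <- 1 - p
  # per-site IBS-state probabilities conditional on IBD state
  e0_0 <- 2 * p^2 * q^2
  e1_0 <- 4 * p^3 * q + 4 * p * q^3
  e2_0 <- 1 - e0_0 - e1_0
  e1_1 <- 2 * p * q
  e2_1 <- 1 - e1_1
  out <- diag(1, n)
  dimnames(out) <- list(colnames(gt), colnames(gt))
  for (i in seq_len(n - 1)) {
    gi <- gt[, i]
    for (j in seq(i + 1, n)) {
      gj <- gt[, j]
      ok <- !is.na(gi) & !is.na(gj)
      d <- abs(gi[ok] - gj[ok])             # 2 - IBS
      m <- sum(ok)
      if (m == 0) { out[i, j] <- out[j, i] <- NA_real_; next }
      n0 <- sum(d == 2); n1 <- sum(d == 1); n2 <- m - n0 - n1
      s0 <- sum(e0_0[ok]); s1_0 <- sum(e1_0[ok]); s2_0 <- sum(e2_0[ok])
      s1_1 <- sum(e1_1[ok]); s2_1 <- sum(e2_1[ok])
      p0 <- if (s0 > 0) n0 / s0 else 0
      p1 <- if (s1_1 > 0) (n1 - p0 * s1_0) / s1_1 else 0
      p2 <- (n2 - p0 * s2_0 - p1 * s2_1) / m
      pr <- pmax(c(p0, p1, p2), 0)
      pr <- pr / sum(pr)
      pihat <- min(max(pr[3] + pr[2] / 2, 0), 1)
      out[i, j] <- out[j, i] <- pihat
    }
  }
  out
}

#' Greedily prune related samples
#'
#' Repeatedly removes the sample participating in the most pairs at or above
#' the relatedness threshold until no such pair remains. Ties break by
#' sample-id order (first id removed), making the result deterministic. This
#' reproduces the "not closely related controls" selection (IBD < 0.5).
#'
#' @param mat Symmetric relatedness matrix with sample ids as dimnames.
#' @param threshold Relatedness at or above which a pair is "related".
#' @return Character vector of retained sample ids.
#' @export
prune_related <- function(mat, threshold = 0.5) {
  stopifnot(nrow(mat) == ncol(mat))
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  keep <- ids
  repeat {
    m <- mat[keep, keep, drop = FALSE]
    diag(m) <- 0
    related <- !is.na(m) & m >= threshold
    if (!any(related)) break
    counts <- rowSums(related)
    worst <- keep[which.max(counts)]   # which.max breaks ties by order
    keep <- setdiff(keep, worst)
  }
  keep
}

#' Per-variant allelic case/control association (Fisher exact)
#'
#' Builds the 2x2 allele-count table (case alt/ref vs control alt/ref) at
#' every biallelic site, dropping missing genotypes per site, and tests it
#' with a two-sided Fisher exact test. Sites with no informative genotype in
#' either group get `NA` with `informative = FALSE`.
#'
#' @param cohort A [cohort_genotypes()].
#' @param case_ids,control_ids Sample id vectors.
#' @param alpha Optional family-wise error rate; when given, a `significant`
#'   flag is added using [bonferroni_threshold()] over the number of
#'   informative sites.
#' @return data.frame with per-variant allele counts, `p`, `informative`,
#'   and optionally `significant`.
#' @export
allelic_association <- function(cohort, case_ids, control_ids, alpha = NULL) {
  gt <- cohort$gt
  ca <- gt[, sample_index(cohort, case_ids), drop = FALSE]
  co <- gt[, sample_index(cohort, control_ids), drop = FALSE]
  case_alt <- rowSums(ca, na.rm = TRUE)
  case_n <- 2 * rowSums(!is.na(ca))
  ctrl_alt <- rowSums(co, na.rm = TRUE)
  ctrl_n <- 2 * rowSums(!is.na(co))
  informative <- case_n > 0 & ctrl_n > 0
  # Fisher p depends only on the table; dedupe identical tables for speed
  key <- paste(case_alt, case_n, ctrl_alt, ctrl_n)
  uk <- !duplicated(key) & informative
  pu <- vapply(which(uk), function(i) {
    stats::fisher.test(matrix(c(case_alt[i], case_n[i] - case_alt[i],
                                ctrl_alt[i], ctrl_n[i] - ctrl_alt[i]),
                              2, 2))$p.value
  }, numeric(1))
  p <- rep(NA_real_, nrow(gt))
  p[informative] <- pu[match(key[informative], key[uk])]
  out <- data.frame(cohort$variants[, c("chrom", "pos", "ref", "alt")],
                    case_alt = case_alt, case_ref = case_n - case_alt,
                    ctrl_alt = ctrl_alt, ctrl_ref = ctrl_n - ctrl_alt,
                    p = p, informative = informative)
  if (!is.null(alpha)) {
    thr <- bonferroni_threshold(alpha, sum(informative))
    out$significant <- !is.na(out$p) & out$p < thr
    attr(out, "threshold") <- thr
  }
  out
}

#' Bonferroni significance threshold
#'
#' `alpha / n_tests`; with alpha 0.05 over ~1.56e7 genome-wide tests this is
#' the 3.2e-9 order of magnitude used for sequence-based association scans.
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return The per-test threshold.
#' @examples
#' bonferroni_threshold(0.05, 15625000)  # 3.2e-9
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}
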