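#' Consequence classes counted as protein-changing
#'
#' Missense, nonsense (stop gained/lost), start loss, frameshift, in-frame
#' indels and the splice-region placeholder; synonymous and non-coding
#' classes are excluded.
#'
#' @export
PROTEIN_CHANGING <- c("missense", "stop_gained", "stop_lost", "start_lost",
                      "frameshift", "inframe_indel", "splice_region")

new_funnel <- function(stages, counts, candidates, carrier_counts = NULL) {
  stopifnot(length(stages) == length(counts), !is.unsorted(rev(counts)))
  obj <- list(funnel = data.frame(stage = stages, n = counts,
                                  stringsAsFactors = FALSE),
              candidates = candidates)
  if (!is.null(carrier_counts)) obj$candidates <- cbind(candidates,
                                                        carrier_counts)
  class(obj) <- "filter_funnel"
  obj
}

#' @export
print.filter_funnel <- function(x, ...) {
  cat("filter_funnel:\n")
  print(x$funnel, row.names = FALSE)
  cat(nrow(x$candidates), "candidate variant(s)\n")
  invisible(x)
}

# fraction of non-missing genotypes per variant, across all cohort samples
callable_fraction <- function(cohort) {
  rowMeans(!is.na(cohort$gt))
}

is_protein_changing <- function(cohort) {
  !is.na(cohort$variants$consequence) &
    cohort$variants$consequence %in% PROTEIN_CHANGING
}

# TRUE where no sample in `idx` carries the alt allele; missing genotypes
# are conservatively treated as potential carriers (strict mode)
absent_in <- function(gt, idx, strict_missing = TRUE) {
  if (length(idx) == 0) return(rep(TRUE, nrow(gt)))
  sub <- gt[, idx, drop = FALSE]
  if (strict_missing) {
    rowSums(sub != 0L | is.na(sub)) == 0L
  } else {
    rowSums(sub != 0L, na.rm = TRUE) == 0L
  }
}

#' Filter for a recessive allele shared by all cases
#'
#' The first inheritance scenario: a single recessive allele common to the
#' whole case series. Retains variants homozygous alternate in every listed
#' case, protein-changing, with the alternate allele entirely absent from
#' the controls, and callable (non-missing genotype in at least 90% of all
#' samples; the programmatic stand-in for visual alignment inspection).
#'
#' @param cohort A [cohort_genotypes()].
#' @param case_ids Character vector of case sample ids (>= 2).
#' @param control_ids Character vector of control sample ids.
#' @param strict_missing Treat missing genotypes as incompatible with the
#'   "homozygous in case" and "absent in controls" requirements (default).
#' @param min_callable Minimum fraction of non-missing genotypes.
#' @return A `filter_funnel` with stages `all`, `hom_in_all_cases`,
#'   `protein_changing`, `absent_in_controls`, `callable`.
#' @export
filter_shared_recessive <- function(cohort, case_ids, control_ids,
                                    strict_missing = TRUE,
                                    min_callable = 0.9) {
  if (length(case_ids) < 2) stop("need at least 2 cases")
  ci <- sample_index(cohort, case_ids)
  ki <- sample_index(cohort, control_ids)
  gt <- cohort$gt
  keep_all <- rep(TRUE, nrow(gt))
  sub <- gt[, ci, drop = FALSE]
  hom_all <- if (strict_missing) rowSums(sub == 2L & !is.na(sub)) ==
    length(ci) else rowSums(sub == 2L, na.rm = TRUE) +
    rowSums(is.na(sub)) == length(ci)
  pc <- hom_all & is_protein_changing(cohort)
  priv <- pc & absent_in(gt, ki, strict_missing)
  call <- priv & callable_fraction(cohort) >= min_callable
  new_funnel(c("all", "hom_in_all_cases", "protein_changing",
               "absent_in_controls", "callable"),
             c(sum(keep_all), sum(hom_all), sum(pc), sum(priv), sum(call)),
             cohort$variants[call, , drop = FALSE])
}

#' Filter for a private recessive allele in one case family
#'
#' The second inheritance scenario, applied per case. Retains variants
#' homozygous alternate in the case; in trio/duo designs every sequenced
#' parent must be heterozygous (obligate carrier); the alternate allele must
#' be entirely absent from the first-pass control cohort (privacy) and
#' without homozygous-alternate samples in the wider global cohort, where
#' heterozygous carriers are permitted and counted; protein-changing and
#' callable stages close the funnel.
#'
#' @param cohort A [cohort_genotypes()].
#' @param family A [case_family()].
#' @param control_ids First-pass control cohort (complete-absence filter).
#' @param global_ids Wider second-pass cohort (no hom-alt; het carriers
#'   tolerated and reported). Typically a superset of `control_ids`.
#' @param strict_missing,min_callable See [filter_shared_recessive()].
#' @return A `filter_funnel`; candidates carry `n_hom_alt`/`n_het`/
#'   `n_missing` carrier counts over `global_ids`.
#' @export
filter_case_recessive <- function(cohort, family, control_ids, global_ids,
                                  strict_missing = TRUE, min_callable = 0.9) {
  ci <- sample_index(cohort, family$case)
  ki <- sample_index(cohort, control_ids)
  gi <- sample_index(cohort, global_ids)
  gt <- cohort$gt
  g_case <- gt[, ci]
  hom <- !is.na(g_case) & g_case == 2L
  parents <- family_parents(family)
  par_het <- hom
  if (length(parents) > 0) {
    pp <- gt[, sample_index(cohort, parents), drop = FALSE]
    par_het <- hom & rowSums(pp == 1L & !is.na(pp)) == length(parents)
  }
  priv <- par_het & absent_in(gt, ki, strict_missing)
  gsub <- gt[, gi, drop = FALSE]
  no_hom_global <- if (strict_missing)
    rowSums(gsub == 2L | is.na(gsub)) == 0L
  else rowSums(gsub == 2L, na.rm = TRUE) == 0L
  glob <- priv & no_hom_global
  pc <- glob & is_protein_changing(cohort)
  call <- pc & callable_fraction(cohort) >= min_callable
  idx <- which(call)
  cc <- t(vapply(idx, function(i) {
    g <- gt[i, gi]
    c(n_hom_alt = sum(g == 2L, na.rm = TRUE),
      n_het = sum(g == 1L, na.rm = TRUE),
      n_missing = sum(is.na(g)))
  }, c(n_hom_alt = 0, n_het = 0, n_missing = 0)))
  if (length(idx) == 0)
    cc <- matrix(numeric(0), 0, 3,
                 dimnames = list(NULL, c("n_hom_alt", "n_het", "n_missing")))
  new_funnel(c("all", "hom_in_case", "parents_het", "private_in_controls",
               "no_hom_alt_in_global", "protein_changing", "callable"),
             c(nrow(gt), sum(hom), sum(par_het), sum(priv), sum(glob),
               sum(pc), sum(call)),
             cohort$variants[idx, , drop = FALSE],
             carrier_counts = as.data.frame(cc))
}

#' Filter for a dominant de novo allele in one case family
#'
#' The third inheritance scenario: a spontaneous dominant mutation. Retains
#' variants heterozygous in the case with the alternate allele absent from
#' the sequenced parents and from every control and global sample, then
#' protein-changing and callable.
#'
#' @inheritParams filter_case_recessive
#' @return A `filter_funnel`; candidates carry carrier counts over
#'   `global_ids` (expected 0/0 for a true de novo event).
#' @export
filter_denovo_dominant <- function(cohort, family, control_ids, global_ids,
                                   strict_missing = TRUE, min_callable = 0.9) {
  ci <- sample_index(cohort, family$case)
  gt <- cohort$gt
  g_case <- gt[, ci]
  het <- !is.na(g_case) & g_case == 1L
  parents <- family_parents(family)
  no_par <- het
  if (length(parents) > 0)
    no_par <- het & absent_in(gt, sample_index(cohort, parents),
                              strict_missing)
  others <- union(control_ids, global_ids)
  priv <- no_par & absent_in(gt, sample_index(cohort, others), strict_missing)
  pc <- priv & is_protein_changing(cohort)
  call <- pc & callable_fraction(cohort) >= min_callable
  idx <- which(call)
  gi <- sample_index(cohort, global_ids)
  cc <- t(vapply(idx, function(i) {
    g <- gt[i, gi]
    c(n_hom_alt = sum(g == 2L, na.rm = TRUE),
      n_het = sum(g == 1L, na.rm = TRUE),
      n_missing = sum(is.na(g)))
  }, c(n_hom_alt = 0, n_het = 0, n_missing = 0)))
  if (length(idx) == 0)
    cc <- matrix(numeric(0), 0, 3,
                 dimnames = list(NULL, c("n_hom_alt", "n_het", "n_missing")))
  new_funnel(c("all", "het_in_case", "absent_in_parents",
               "absent_in_controls_and_global", "protein_changing",
               "callable"),
             c(nrow(gt), sum(het), sum(no_par), sum(priv), sum(pc),
               sum(call)),
             cohort$variants[idx, , drop = FALSE],
             carrier_counts = as.data.frame(cc))
}

#' Genotype counts for one variant over a set of samples
#'
#' Exact counts of homozygous-alternate and heterozygous genotypes over the
#' listed samples; missing genotypes are excluded from both counts and
#' reported separately. This is the query behind per-candidate carrier
#' columns (hom/het in a global control cohort).
#'
#' @param cohort A [cohort_genotypes()].
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt`; must be present in the cohort.
#' @param sample_ids Samples to count over (may be empty).
#' @return Named numeric vector `c(n_hom_alt, n_het, n_missing)`.
#' @export
cohort_allele_query <- function(cohort, variant, sample_ids) {
  key <- variant_key(as.data.frame(as.list(variant)))
  i <- match(key, variant_key(cohort$variants))
  if (is.na(i)) stop("variant not found in cohort: ", key)
  if (length(sample_ids) == 0)
    return(c(n_hom_alt = 0, n_het = 0, n_missing = 0))
  g <- cohort$gt[i, sample_index(cohort, sample_ids)]
  c(n_hom_alt = sum(g == 2L, na.rm = TRUE),
    n_het = sum(g == 1L, na.rm = TRUE),
    n_missing = sum(is.na(g)))
}
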