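#' Multi-sample genotype container over biallelic sites
#'
#' The substrate of every filter in the package: an ordered table of biallelic
#' variants, an ordered sample sheet with roles, and a genotype matrix coded
#' 0 = hom ref, 1 = het, 2 = hom alt, NA = missing.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `gene` and `consequence`.
#' @param samples data.frame with columns `sample` and `role`
#'   (one of `"case"`, `"sire"`, `"dam"`, `"control"`, `"global"`), and
#'   optionally `family`.
#' @param gt Integer matrix, `nrow(variants)` x `nrow(samples)`, values in
#'   \{0, 1, 2, NA\}.
#' @param build Optional [genome_build()] used to validate coordinates.
#' @return An object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(variants, samples, gt, build = NULL) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            all(c("sample", "role") %in% names(samples)))
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  if (nrow(gt) != nrow(variants) || ncol(gt) != nrow(samples))
    stop("gt matrix dimensions do not match variants x samples")
  if (anyDuplicated(samples$sample))
    stop("sample ids must be unique")
  bad <- !(gt %in% c(0L, 1L, 2L) | is.na(gt))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  ok_allele <- grepl("^[ACGT]+$", variants$ref) & grepl("^[ACGT]+$", variants$alt)
  if (!all(ok_allele))
    stop("alleles must be non-empty strings over {A,C,G,T}")
  if (!is.null(build)) {
    len <- chrom_length(build, variants$chrom)
    if (any(variants$pos < 1 | variants$pos > len))
      stop("variant position outside chromosome bounds")
  }
  colnames(gt) <- samples$sample
  obj <- list(variants = variants, samples = samples, gt = gt, build = build)
  class(obj) <- "cohort_genotypes"
  obj
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes:", nrow(x$variants), "variants x",
      nrow(x$samples), "samples\n")
  cat("roles:", paste(sprintf("%s=%d", names(table(x$samples$role)),
                              table(x$samples$role)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.cohort_genotypes <- function(x) c(nrow(x$variants), nrow(x$samples))

variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

sample_index <- function(cohort, ids) {
  i <- match(ids, cohort$samples$sample)
  if (anyNA(i))
    stop("unknown sample id(s): ", paste(ids[is.na(i)], collapse = ", "))
  i
}

#' Describe a case family (trio, duo or solo design)
#'
#' One affected calf plus 0, 1 or 2 sequenced parents. The design is inferred
#' from which parents are given: both = trio, one = duo, none = solo.
#'
#' @param case Sample id of the affected animal.
#' @param sire,dam Sample ids of the sequenced parents, or `NA` when that
#'   parent was not sequenced.
#' @return An object of class `case_family` with fields `case`, `sire`,
#'   `dam` and `design`.
#' @export
case_family <- function(case, sire = NA, dam = NA) {
  stopifnot(is.character(case), length(case) == 1)
  n_par <- sum(!is.na(c(sire, dam)))
  design <- c("solo", "duo", "trio")[n_par + 1L]
  structure(list(case = case,
                 sire = if (is.na(sire)) NA_character_ else sire,
                 dam = if (is.na(dam)) NA_character_ else dam,
                 design = design),
            class = "case_family")
}

#' @export
print.case_family <- function(x, ...) {
  cat(sprintf("case_family [%s]: case=%s sire=%s dam=%s\n",
              x$design, x$case, x$sire, x$dam))
  invisible(x)
}

family_parents <- function(family) {
  p <- c(family$sire, family$dam)
  p[!is.na(p)]
}
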