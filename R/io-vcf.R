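#' Read a multi-sample VCF into a genotype cohort
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) and maps GT fields onto the
#' four-state genotype code used throughout the package. Positions stay
#' 1-based as in the VCF. Sample order is preserved.
#'
#' Multi-allelic records are rejected by default; `multiallelic = "split"`
#' decomposes them into one biallelic record per alternate allele, with
#' genotypes recoded per allele (other alternate alleles count as reference).
#'
#' @param path VCF file (plain or gzipped).
#' @param build Optional [genome_build()]; chromosomes not in the build are
#'   an error.
#' @param multiallelic `"error"` (default) or `"split"`.
#' @param roles Optional named character vector mapping sample id -> role;
#'   unnamed samples default to `"control"`.
#' @return A [cohort_genotypes()] object. `INFO` keys `GENE` and `CSQ` are
#'   recovered into the `gene` and `consequence` variant columns.
#' @export
read_vcf <- function(path, build = NULL, multiallelic = c("error", "split"),
                     roles = NULL) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  for (col in c("CHROM", "POS", "REF", "ALT", "INFO"))
    fix[[col]] <- as.character(fix[[col]])
  if (nrow(fix) == 0) {
    samp <- colnames(v@gt)[-1]
    if (is.null(samp)) samp <- character()
    return(cohort_genotypes(
      variants = data.frame(chrom = character(), pos = integer(),
                            ref = character(), alt = character()),
      samples = data.frame(sample = samp,
                           role = rep("control", length(samp))),
      gt = matrix(integer(), 0, length(samp)), build = build))
  }
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  info <- fix$INFO
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi) && multiallelic == "error")
    stop("multi-allelic record(s) at line(s): ",
         paste(utils::head(which(multi), 5), collapse = ", "),
         " (use multiallelic = \"split\")")

  parse_gt_allele <- function(x, allele) {
    # genotype dosage of `allele` (integer code); malformed -> stop
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    parts <- strsplit(x, "[/|]")[[1]]
    if (length(parts) != 2 || !all(parts %in% c(".", as.character(0:9))))
      stop("malformed GT field: '", x, "'")
    if (any(parts == ".")) return(NA_integer_)
    sum(as.integer(parts) == allele)
  }

  # fast path for biallelic rows: direct lookup of the common GT strings
  code_map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
                "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
                ".|." = NA_integer_, "." = NA_integer_)
  rows <- list()
  gts <- list()
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    raw <- gt_raw[i, , drop = TRUE]
    raw <- sub(":.*$", "", raw)  # GT is always first per VCF spec
    for (a in seq_along(alts)) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = fix$CHROM[i],
                              pos = as.integer(fix$POS[i]),
                              ref = fix$REF[i], alt = alts[a],
                              stringsAsFactors = FALSE)
      if (length(alts) == 1) {
        g <- unname(code_map[raw])
        g[is.na(raw)] <- NA_integer_
        unknown <- !is.na(raw) & !(raw %in% names(code_map))
        if (any(unknown))
          g[unknown] <- vapply(raw[unknown], function(x) {
            tryCatch(parse_gt_allele(x, a),
                     error = function(e) stop("line ", i, ": ",
                                              conditionMessage(e),
                                              call. = FALSE))
          }, integer(1))
      } else {
        g <- vapply(raw, function(x) {
          tryCatch(parse_gt_allele(x, a),
                   error = function(e) stop("line ", i, ": ",
                                            conditionMessage(e),
                                            call. = FALSE))
        }, integer(1))
      }
      gts[[k]] <- g
      rows[[k]]$gene <- info_field(info[i], "GENE")
      rows[[k]]$consequence <- info_field(info[i], "CSQ")
    }
  }
  variants <- do.call(rbind, rows)
  gt <- do.call(rbind, gts)
  if (!is.null(build)) chrom_factor(variants$chrom, build)  # validates
  samp <- colnames(gt_raw)
  role <- rep("control", length(samp))
  if (!is.null(roles)) {
    hit <- match(samp, names(roles))
    role[!is.na(hit)] <- roles[hit[!is.na(hit)]]
  }
  cohort_genotypes(variants,
                   data.frame(sample = samp, role = role,
                              stringsAsFactors = FALSE),
                   gt, build = build)
}

info_field <- function(info, key) {
  if (is.na(info)) return(NA_character_)
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (length(m) == 0) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

#' Write a genotype cohort as a plain-text VCF 4.2 file
#'
#' Records are written sorted by (chromosome in build order, position); an
#' unsorted cohort is sorted on write with a message. `gene` and
#' `consequence` variant columns are carried in INFO as `GENE=` / `CSQ=`.
#'
#' @param cohort A [cohort_genotypes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  if (!is.null(cohort$build)) {
    ord <- order(chrom_factor(v$chrom, cohort$build), v$pos)
  } else {
    ord <- order(match(v$chrom, unique(v$chrom)), v$pos)
  }
  if (is.unsorted(ord)) message("write_vcf: records sorted on write")
  v <- v[ord, , drop = FALSE]
  gt <- cohort$gt[ord, , drop = FALSE]

  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(cohort$build))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", cohort$build$chrom,
                       as.integer(cohort$build$length)), con)
  writeLines(paste0("##INFO=<ID=GENE,Number=1,Type=String,",
                    "Description=\"Gene symbol\">"), con)
  writeLines(paste0("##INFO=<ID=CSQ,Number=1,Type=String,",
                    "Description=\"Coding consequence class\">"), con)
  writeLines(paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", cohort$samples$sample),
                   collapse = "\t"), con)
  if (nrow(v) > 0) {
    info <- rep(".", nrow(v))
    has_g <- !is.null(v$gene) && any(!is.na(v$gene))
    has_c <- !is.null(v$consequence) && any(!is.na(v$consequence))
    if (has_g || has_c) {
      info <- vapply(seq_len(nrow(v)), function(i) {
        parts <- character()
        if (!is.null(v$gene) && !is.na(v$gene[i]))
          parts <- c(parts, paste0("GENE=", v$gene[i]))
        if (!is.null(v$consequence) && !is.na(v$consequence[i]))
          parts <- c(parts, paste0("CSQ=", v$consequence[i]))
        if (length(parts) == 0) "." else paste(parts, collapse = ";")
      }, character(1))
    }
    gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt))
    gt_str[is.na(gt)] <- "./."
    lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                   apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
    if (ncol(gt) == 0)
      lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
                     "GT", sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}
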