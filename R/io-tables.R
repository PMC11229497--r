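#' Read a per-window read-depth table (samtools bedcov dialect)
#'
#' Consumes the four-column TSV (`chrom`, `start`, `end`, `count`) produced
#' by `samtools bedcov` over a tiling window set. Input intervals follow the
#' BED convention (0-based half-open); they are converted exactly once here
#' to the package-internal 1-based inclusive convention.
#'
#' @param path TSV file, no header.
#' @param window_size Declared window size in bp; every window except the
#'   last of a chromosome must have this size.
#' @param sample Optional sample id to attach to the profile.
#' @return A `depth_profile`: data.frame with columns `chrom`, `start`,
#'   `end` (1-based inclusive), `count`, plus attributes `window_size` and
#'   `sample`.
#' @export
read_depth_table <- function(path, window_size, sample = NA_character_) {
  d <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("chrom", "start", "end", "count"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  if (any(d$count < 0)) stop("negative read counts")
  for (ch in unique(d$chrom)) {
    w <- d[d$chrom == ch, ]
    w <- w[order(w$start), ]
    if (w$start[1] != 0)
      stop("windows on ", ch, " do not start at 0")
    if (nrow(w) > 1 && any(w$end[-nrow(w)] != w$start[-1]))
      stop("overlapping or gapped windows on ", ch)
    len <- w$end - w$start
    if (any(len[-length(len)] != window_size) || len[length(len)] > window_size)
      stop("window sizes on ", ch, " inconsistent with declared ",
           window_size, " bp")
  }
  depth_profile(chrom = d$chrom, start = d$start + 1, end = d$end,
                count = d$count, window_size = window_size, sample = sample)
}

depth_profile <- function(chrom, start, end, count, window_size,
                          sample = NA_character_, ratio = NULL) {
  out <- data.frame(chrom = chrom, start = start, end = end, count = count,
                    stringsAsFactors = FALSE)
  if (!is.null(ratio)) out$ratio <- ratio
  attr(out, "window_size") <- window_size
  attr(out, "sample") <- sample
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Write a depth profile back to the bedcov TSV dialect
#'
#' The exact inverse of [read_depth_table()]: internal 1-based inclusive
#' windows are emitted as 0-based half-open rows.
#'
#' @param profile A `depth_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(profile, path) {
  utils::write.table(
    data.frame(profile$chrom, format(profile$start - 1, scientific = FALSE,
                                     trim = TRUE),
               format(profile$end, scientific = FALSE, trim = TRUE),
               format(profile$count, scientific = FALSE, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a PED-style pedigree file
#'
#' Whitespace-separated columns: individual, sire, dam, sex, and optionally a
#' genotype label (`hom_alt`, `het`, `hom_ref`, `unknown`). `0` or `NA` mark
#' unknown parents.
#'
#' @param path PED file, no header.
#' @return A [pedigree()] object.
#' @export
read_ped <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:min(5, ncol(d))] <-
    c("id", "sire", "dam", "sex", "genotype")[1:min(5, ncol(d))]
  for (col in c("sire", "dam")) {
    d[[col]] <- as.character(d[[col]])
    d[[col]][d[[col]] %in% c("0", "NA", ".")] <- NA_character_
  }
  pedigree(id = as.character(d$id), sire = d$sire, dam = d$dam,
           sex = if ("sex" %in% names(d)) d$sex else NULL,
           genotype = if ("genotype" %in% names(d)) d$genotype else NULL)
}

#' Write a pedigree as a PED-style file
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  d <- as.data.frame(ped)
  d$sire[is.na(d$sire)] <- "0"
  d$dam[is.na(d$dam)] <- "0"
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a case/phenotype table
#'
#' Tab-separated with header: `case_id`, `breed`, `sex`, `bw_kg` (birth
#' weight, kg), `ga_days` (gestation age, days). Missing values are `NA`.
#' The packaged fixture `table1_cases.tsv` transcribes the case series the
#' package's descriptive statistics are validated against.
#'
#' @param path TSV file with header.
#' @return data.frame with the five columns above.
#' @examples
#' tbl <- read_case_table(system.file("extdata", "table1_cases.tsv",
#'                                    package = "cscmsieve"))
#' summarize_case_table(tbl)
#' @export
read_case_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = c("NA", "NR"))
  stopifnot(all(c("case_id", "breed", "sex", "bw_kg", "ga_days") %in%
                  names(d)))
  if (any(d$bw_kg <= 0, na.rm = TRUE) || any(d$ga_days <= 0, na.rm = TRUE))
    stop("weights and gestation ages must be positive when present")
  d
}

#' Read gene models from a flat transcript TSV
#'
#' One row per transcript, tab-separated with header columns `gene`,
#' `transcript`, `chrom`, `strand`, `cds_starts`, `cds_ends` (comma-separated
#' 1-based inclusive segment coordinates, ordered by genomic position) and
#' `cds_seq` (the strand-corrected concatenated coding sequence).
#'
#' @param path TSV file.
#' @return List of [gene_model()] objects, named by gene.
#' @export
read_gene_models <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(d)), function(i) {
    gene_model(gene = d$gene[i], transcript = d$transcript[i],
               chrom = d$chrom[i], strand = d$strand[i],
               cds_starts = as.numeric(strsplit(as.character(d$cds_starts[i]),
                                                ",")[[1]]),
               cds_ends = as.numeric(strsplit(as.character(d$cds_ends[i]),
                                              ",")[[1]]),
               cds_seq = d$cds_seq[i])
  })
  names(models) <- d$gene
  models
}

#' Write gene models to the flat transcript TSV read by [read_gene_models()]
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  d <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene, transcript = m$transcript, chrom = m$chrom,
               strand = m$strand,
               cds_starts = paste(format(m$cds_starts, scientific = FALSE,
                                         trim = TRUE), collapse = ","),
               cds_ends = paste(format(m$cds_ends, scientific = FALSE,
                                       trim = TRUE), collapse = ","),
               cds_seq = m$cds_seq, stringsAsFactors = FALSE)
  }))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
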