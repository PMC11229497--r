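#' Define a genome build
#'
#' A genome build is the ordered set of chromosome names and lengths that all
#' coordinates in the package refer to. Every position elsewhere is 1-based
#' and must fall on a named chromosome.
#'
#' @param chrom Character vector of unique chromosome names, in karyotype
#'   order.
#' @param length Integer vector of chromosome lengths in bp (>= 1).
#' @return An object of class `genome_build`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_build(c("chr1", "chr2"), c(5e6, 4e6))
#' @export
genome_build <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom))
    stop("chromosome names must be unique")
  if (any(is.na(length)) || any(length < 1))
    stop("chromosome lengths must be >= 1")
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_build", "data.frame")
  out
}

#' Small synthetic genome build used throughout examples and simulations
#'
#' Three autosomes of 10 Mb each. Deliberately small so that a full cohort
#' simulation and analysis run in seconds; the scale of a real cattle genome
#' (~2.7 Gb over 29 autosomes) is not emulated.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @return A `genome_build`.
#' @export
synthetic_build <- function(n_chrom = 3L, chrom_length = 1e7) {
  genome_build(paste0("chr", seq_len(n_chrom)),
               rep(chrom_length, n_chrom))
}

#' @export
print.genome_build <- function(x, ...) {
  cat("genome_build:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

chrom_length <- function(build, chrom) {
  i <- match(chrom, build$chrom)
  if (anyNA(i))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  build$length[i]
}

# factor in build order; errors on unknown chromosome names
chrom_factor <- function(chrom, build) {
  f <- factor(chrom, levels = build$chrom)
  if (anyNA(f))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(f)]), collapse = ", "))
  f
}
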