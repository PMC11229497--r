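#' Coverage plot of a normalized depth profile
#'
#' Manhattan-style per-window normalized depth along the genome, one color
#' block per chromosome, with guide lines at the diploid ratio (1.0) and at
#' the monosomy/trisomy expectations (0.5 / 1.5). The visual signature of a
#' heterozygous segmental deletion is a block at ~0.5; a trisomic
#' chromosome sits wholly at ~1.5.
#'
#' @param nprofile A normalized `depth_profile` (see [normalize_depth()]).
#' @param main Plot title.
#' @return Invisibly, the x-axis offsets per chromosome.
#' @export
plot_coverage <- function(nprofile, main = attr(nprofile, "sample")) {
  stopifnot(!is.null(nprofile$ratio))
  chroms <- unique(nprofile$chrom)
  offs <- stats::setNames(numeric(length(chroms)), chroms)
  x <- numeric(nrow(nprofile))
  run <- 0
  for (ch in chroms) {
    sel <- nprofile$chrom == ch
    offs[ch] <- run
    x[sel] <- run + (nprofile$start[sel] + nprofile$end[sel]) / 2
    run <- run + max(nprofile$end[sel])
  }
  cols <- rep(c("grey30", "steelblue"), length.out = length(chroms))
  graphics::plot(x, nprofile$ratio, pch = 16, cex = 0.4,
                 col = cols[match(nprofile$chrom, chroms)],
                 xlab = "genome position", ylab = "normalized depth ratio",
                 main = main, ylim = c(0, max(2, nprofile$ratio)))
  graphics::abline(h = 1, col = "red")
  graphics::abline(h = c(0.5, 1.5), col = "red", lty = 3)
  invisible(offs)
}

#' Manhattan plot of association results
#'
#' -log10 p per position with the significance threshold drawn when the
#' association table carries one.
#'
#' @param assoc Result of [allelic_association()].
#' @param build Optional [genome_build()] for chromosome ordering.
#' @return Invisibly `NULL`.
#' @export
plot_manhattan <- function(assoc, build = NULL) {
  a <- assoc[!is.na(assoc$p), ]
  chroms <- if (!is.null(build)) build$chrom else unique(a$chrom)
  x <- numeric(nrow(a)); run <- 0
  for (ch in chroms) {
    sel <- a$chrom == ch
    x[sel] <- run + a$pos[sel]
    if (any(sel)) run <- run + max(a$pos[sel])
  }
  cols <- rep(c("grey30", "steelblue"), length.out = length(chroms))
  graphics::plot(x, -log10(a$p), pch = 16, cex = 0.4,
                 col = cols[match(a$chrom, chroms)],
                 xlab = "genome position", ylab = "-log10 p")
  thr <- attr(assoc, "threshold")
  if (!is.null(thr)) graphics::abline(h = -log10(thr), col = "red", lty = 2)
  invisible(NULL)
}
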