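#' Normalize a depth profile to copy-number ratios
#'
#' Divides every window's read count by the genome-wide median window count
#' at the same window size, so a diploid window is expected at ratio 1.0, a
#' heterozygous deletion at 0.5 and a trisomic chromosome at 1.5. The
#' median rather than the mean keeps the diploid baseline at 1.0 even when
#' an aberrant chromosome is a large fraction of a small genome (on a
#' full-size genome the two coincide for all practical purposes). Sex
#' chromosomes (or any listed chromosome) can be excluded from the
#' baseline.
#'
#' @param profile A `depth_profile` (see [read_depth_table()] /
#'   [simulate_depth()]).
#' @param exclude_chroms Chromosomes excluded from the genome-wide mean
#'   (e.g. sex chromosomes); their windows still receive ratios.
#' @return The profile with a `ratio` column and attribute `genome_mean`.
#' @export
normalize_depth <- function(profile, exclude_chroms = character()) {
  if (nrow(profile) < 10) stop("need at least 10 windows")
  use <- !(profile$chrom %in% exclude_chroms)
  gm <- stats::median(profile$count[use])
  if (!is.finite(gm) || gm <= 0) stop("genome-wide median depth is zero")
  out <- depth_profile(profile$chrom, profile$start, profile$end,
                       profile$count, attr(profile, "window_size"),
                       attr(profile, "sample"),
                       ratio = profile$count / gm)
  attr(out, "genome_mean") <- gm
  out
}

#' Call loss/gain segments and whole-chromosome aneuploidies
#'
#' Chromosome-level events are called first: a chromosome whose median
#' ratio is below `loss_max` or above `gain_min` is reported as a monosomy
#' or trisomy and excluded from segment scanning (a whole-chromosome event
#' is not also a segment). On the remaining chromosomes, runs of at least
#' `min_windows` consecutive windows all below `loss_max` (loss) or all
#' above `gain_min` (gain) are merged into segments.
#'
#' Thresholds sit between the copy-number ratio expectations (0.5, 1.0,
#' 1.5) with a noise margin; intended for coarse (200 kb) windows.
#'
#' @param nprofile A normalized `depth_profile` (see [normalize_depth()]).
#' @param loss_max Ratio below which a window is a loss candidate.
#' @param gain_min Ratio above which a window is a gain candidate.
#' @param min_windows Minimum consecutive windows per segment.
#' @return List with `segments` (chrom, start, end, state, mean_ratio,
#'   n_windows, size_mb) and `aneuploidy` (chrom, type, median_ratio).
#' @export
call_segments <- function(nprofile, loss_max = 0.7, gain_min = 1.3,
                          min_windows = 3) {
  stopifnot(!is.null(nprofile$ratio))
  segs <- list()
  aneu <- list()
  for (ch in unique(nprofile$chrom)) {
    w <- nprofile[nprofile$chrom == ch, ]
    w <- w[order(w$start), ]
    med <- stats::median(w$ratio)
    if (med < loss_max || med > gain_min) {
      aneu[[length(aneu) + 1]] <- data.frame(
        chrom = ch,
        type = if (med < loss_max) "monosomy" else "trisomy",
        median_ratio = med)
      next
    }
    state <- ifelse(w$ratio < loss_max, "loss",
                    ifelse(w$ratio > gain_min, "gain", "normal"))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (r$values[k] == "normal" || r$lengths[k] < min_windows) next
      i0 <- starts[k]; i1 <- ends[k]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ch, start = w$start[i0], end = w$end[i1],
        state = r$values[k],
        mean_ratio = mean(w$ratio[i0:i1]),
        n_windows = i1 - i0 + 1L,
        size_mb = interval_size_mb(w$start[i0], w$end[i1]))
    }
  }
  list(segments = if (length(segs)) do.call(rbind, segs) else
         data.frame(chrom = character(), start = numeric(), end = numeric(),
                    state = character(), mean_ratio = numeric(),
                    n_windows = integer(), size_mb = numeric()),
       aneuploidy = if (length(aneu)) do.call(rbind, aneu) else
         data.frame(chrom = character(), type = character(),
                    median_ratio = numeric()))
}

#' Refine segment breakpoints on a fine-window profile
#'
#' Each segment boundary is moved to the least-squares two-mean changepoint
#' of the fine-window (typically 10 kb) ratio series in a flank around the
#' coarse boundary: the split minimizing the summed squared deviations from
#' the left and right means. A refinement is accepted only when the fitted
#' step is substantial (|left mean - right mean| >= `min_step`); otherwise
#' the original boundary is kept and flagged unrefined. Flanks shorter than
#' 5 fine windows skip refinement.
#'
#' @param segment One segment row from [call_segments()] (`chrom`, `start`,
#'   `end`, `state`, ...).
#' @param fine_profile A normalized fine-window `depth_profile` covering the
#'   segment and flanks.
#' @param flank_bp Flank searched on each side of a boundary.
#' @param min_step Minimum |mean difference| for an accepted step.
#' @return The segment with refined `start`/`end`, recomputed `size_mb`, and
#'   logical fields `start_refined`, `end_refined`.
#' @export
refine_breakpoints <- function(segment, fine_profile, flank_bp = 200000,
                               min_step = 0.2) {
  stopifnot(!is.null(fine_profile$ratio))
  w <- fine_profile[fine_profile$chrom == segment$chrom, ]
  w <- w[order(w$start), ]

  refine_one <- function(boundary, left_edge) {
    # left_edge TRUE: boundary is the segment start (step happens at a
    # window start); FALSE: segment end (step at a window end)
    sel <- which(w$end >= boundary - flank_bp & w$start <= boundary + flank_bp)
    if (length(sel) < 10)          # < 5 fine windows per side
      return(list(pos = boundary, refined = FALSE))
    r <- w$ratio[sel]
    n <- length(r)
    best <- NULL
    css <- cumsum(r); css2 <- cumsum(r^2)
    sse <- function(a, b) {        # SSE of r[a..b] around its mean
      s <- css[b] - if (a > 1) css[a - 1] else 0
      s2 <- css2[b] - if (a > 1) css2[a - 1] else 0
      s2 - s^2 / (b - a + 1)
    }
    tot <- vapply(1:(n - 1), function(k) sse(1, k) + sse(k + 1, n),
                  numeric(1))
    k <- which.min(tot)
    mean_l <- mean(r[1:k]); mean_r <- mean(r[(k + 1):n])
    if (abs(mean_l - mean_r) < min_step)
      return(list(pos = boundary, refined = FALSE))
    pos <- if (left_edge) w$start[sel[k + 1]] else w$end[sel[k]]
    list(pos = pos, refined = TRUE)
  }

  s <- refine_one(segment$start, left_edge = TRUE)
  e <- refine_one(segment$end, left_edge = FALSE)
  segment$start <- s$pos
  segment$end <- e$pos
  segment$start_refined <- s$refined
  segment$end_refined <- e$refined
  segment$size_mb <- interval_size_mb(segment$start, segment$end)
  segment
}

#' Interval size in Mb, rounded half-up to 2 decimals
#'
#' Size convention is `(end - start) / 1e6` (not `end - start + 1`), which
#' reproduces printed Mb sizes from breakpoint coordinates; the 1 bp
#' difference is below rounding resolution.
#'
#' @param start,end Same-chromosome coordinates, `end > start`.
#' @return Size in Mb with 2 decimals.
#' @examples
#' interval_size_mb(106843549, 121215358)  # 14.37
#' @export
interval_size_mb <- function(start, end) {
  if (any(end <= start)) stop("end must be greater than start")
  floor((end - start) / 1e6 * 100 + 0.5) / 100
}

#' Overlap of two same-chromosome intervals
#'
#' @param a,b Numeric length-2 vectors `c(start, end)`.
#' @return `NULL` when disjoint, otherwise a list with `start`, `end` and
#'   `size_mb`.
#' @examples
#' interval_overlap(c(106843549, 121215358), c(107114315, 114505909))
#' @export
interval_overlap <- function(a, b) {
  lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
  if (hi <= lo) return(NULL)
  list(start = lo, end = hi, size_mb = interval_size_mb(lo, hi))
}
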