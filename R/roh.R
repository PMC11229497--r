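#' Detect runs of homozygosity in one sample
#'
#' Consecutive-runs scanner over the sample's sorted genotypes. A run is an
#' interval of SNPs, maximal under inclusion, that (i) starts and ends on a
#' homozygous call, (ii) contains at most `max_het` heterozygous calls,
#' (iii) has no inter-SNP gap larger than `max_gap_kb`, (iv) spans at least
#' `min_kb`, and (v) contains at least `min_snps` SNPs. Missing genotypes
#' are dropped before scanning. Because runs are maximal under inclusion
#' (not a greedy partition), a stretch interrupted by `max_het + 1`
#' heterozygous calls yields two (possibly overlapping) runs.
#'
#' @param cohort A [cohort_genotypes()] (or genotype matrix with a variant
#'   table attached via `variants`).
#' @param sample Sample id to scan.
#' @param min_snps Minimum SNP count per run.
#' @param min_kb Minimum run span in kb.
#' @param max_het Maximum heterozygous calls tolerated inside a run.
#' @param max_gap_kb Maximum distance between consecutive SNPs in a run, kb.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_snps`, `n_het`.
#' @export
detect_roh <- function(cohort, sample, min_snps = 20, min_kb = 500,
                       max_het = 1, max_gap_kb = 250) {
  g <- cohort$gt[, sample_index(cohort, sample)]
  v <- cohort$variants
  ok <- !is.na(g)
  out <- list()
  for (ch in unique(v$chrom[ok])) {
    sel <- ok & v$chrom == ch
    pos <- v$pos[sel]
    o <- order(pos)
    pos <- pos[o]
    het <- (g[sel][o] == 1L)
    runs <- roh_scan(pos, het, min_snps, min_kb * 1000, max_het,
                     max_gap_kb * 1000)
    if (nrow(runs) > 0)
      out[[length(out) + 1]] <- cbind(sample = sample, chrom = ch, runs)
  }
  if (length(out) == 0)
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), n_het = integer()))
  do.call(rbind, out)
}

# core scanner: positions sorted ascending, het logical; returns maximal
# intervals satisfying all constraints. Gap splitting first, then within a
# block maximal <=max_het windows are delimited by het sites.
roh_scan <- function(pos, het, min_snps, min_bp, max_het, max_gap_bp) {
  n <- length(pos)
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), n_het = integer())
  if (n == 0) return(empty)
  gap_break <- which(diff(pos) > max_gap_bp)
  block_start <- c(1, gap_break + 1)
  block_end <- c(gap_break, n)
  res <- list()
  for (b in seq_along(block_start)) {
    i0 <- block_start[b]; i1 <- block_end[b]
    h <- which(het[i0:i1]) + i0 - 1        # het indices within block
    # sentinel-delimited maximal windows with <= max_het het calls
    bounds <- c(i0 - 1, h, i1 + 1)
    m <- length(h)
    for (s in 0:m) {
      lo <- bounds[s + 1] + 1
      hi_idx <- s + max_het + 2            # index into bounds
      hi <- if (hi_idx <= length(bounds)) bounds[hi_idx] - 1 else i1
      if (lo <= hi) {
        # trim to homozygous endpoints
        while (lo <= hi && het[lo]) lo <- lo + 1
        while (hi >= lo && het[hi]) hi <- hi - 1
        if (lo <= hi) res[[length(res) + 1]] <- c(lo, hi)
      }
      if (hi_idx > length(bounds)) break   # window already reaches block end
    }
  }
  if (length(res) == 0) return(empty)
  iv <- unique(do.call(rbind, res))
  # drop intervals contained in another (maximality under inclusion)
  keep <- vapply(seq_len(nrow(iv)), function(i) {
    !any(iv[, 1] <= iv[i, 1] & iv[, 2] >= iv[i, 2] &
           (iv[, 1] != iv[i, 1] | iv[, 2] != iv[i, 2]))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  runs <- data.frame(start = pos[iv[, 1]], end = pos[iv[, 2]],
                     n_snps = iv[, 2] - iv[, 1] + 1L,
                     n_het = vapply(seq_len(nrow(iv)), function(i)
                       sum(het[iv[i, 1]:iv[i, 2]]), integer(1)))
  runs <- runs[runs$n_snps >= min_snps &
                 (runs$end - runs$start + 1) >= min_bp, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Intersect per-case homozygosity runs into shared regions
#'
#' Breakpoint sweep over all cases' ROH intervals: per-sample intervals are
#' first unioned, then the genome is cut at every interval boundary and
#' maximal stretches with a constant number of covering cases at or above
#' `min_cases` are reported with that count.
#'
#' @param roh A data.frame of runs as returned by [detect_roh()] (rows from
#'   several samples bound together).
#' @param min_cases Minimum number of cases covering a reported interval.
#' @return data.frame with `chrom`, `start`, `end`, `n_cases`.
#' @export
shared_homozygosity <- function(roh, min_cases = 2) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_cases = integer())
  if (nrow(roh) == 0) return(empty)
  out <- list()
  for (ch in unique(roh$chrom)) {
    r <- roh[roh$chrom == ch, ]
    # union per sample so one case never counts twice
    ivs <- do.call(rbind, lapply(split(r, r$sample), function(rs) {
      rs <- rs[order(rs$start), ]
      merged <- list()
      cur <- c(rs$start[1], rs$end[1])
      for (i in seq_len(nrow(rs))[-1]) {
        if (rs$start[i] <= cur[2] + 1) cur[2] <- max(cur[2], rs$end[i])
        else { merged[[length(merged) + 1]] <- cur
               cur <- c(rs$start[i], rs$end[i]) }
      }
      merged[[length(merged) + 1]] <- cur
      do.call(rbind, merged)
    }))
    # sweep: +1 at start, -1 at end+1
    ev <- rbind(cbind(ivs[, 1], 1), cbind(ivs[, 2] + 1, -1))
    ev <- ev[order(ev[, 1], -ev[, 2]), , drop = FALSE]
    cuts <- unique(ev[, 1])
    cov <- cumsum(vapply(cuts, function(x) sum(ev[ev[, 1] == x, 2]),
                         numeric(1)))
    seg <- data.frame(start = cuts,
                      end = c(cuts[-1] - 1, max(ivs[, 2])),
                      n = cov)
    seg <- seg[seg$n >= min_cases & seg$start <= seg$end, , drop = FALSE]
    if (nrow(seg) == 0) next
    # merge adjacent segments with equal coverage
    merged <- list()
    cur <- seg[1, ]
    for (i in seq_len(nrow(seg))[-1]) {
      if (seg$start[i] == cur$end + 1 && seg$n[i] == cur$n) {
        cur$end <- seg$end[i]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- seg[i, ]
      }
    }
    merged[[length(merged) + 1]] <- cur
    m <- do.call(rbind, merged)
    out[[length(out) + 1]] <- data.frame(chrom = ch, start = m$start,
                                         end = m$end, n_cases = m$n)
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
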