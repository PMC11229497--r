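# Independent brute-force oracles used to cross-check the package's
# implementations. Each is written as the most literal possible rendering
# of the definition, with no shared code with the implementation it checks.

# two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle <- function(case_alt, case_ref, ctrl_alt, ctrl_ref) {
  m <- case_alt + ctrl_alt          # total alt alleles
  n <- case_ref + ctrl_ref          # total ref alleles
  k <- case_alt + case_ref          # case alleles
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(case_alt, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all maximal-under-inclusion ROH intervals by O(n^2) enumeration
roh_oracle <- function(pos, het, min_snps, min_bp, max_het, max_gap_bp) {
  n <- length(pos)
  sat <- list()
  for (i in seq_len(n)) for (j in i:n) {
    idx <- i:j
    if (het[i] || het[j]) next
    if (sum(het[idx]) > max_het) next
    if (j > i && max(diff(pos[idx])) > max_gap_bp) next
    if (length(idx) < min_snps) next
    if ((pos[j] - pos[i] + 1) < min_bp) next
    sat[[length(sat) + 1]] <- c(i, j)
  }
  if (length(sat) == 0)
    return(data.frame(start = numeric(), end = numeric(),
                      n_snps = integer(), n_het = integer()))
  iv <- do.call(rbind, sat)
  keep <- vapply(seq_len(nrow(iv)), function(r) {
    !any(iv[, 1] <= iv[r, 1] & iv[, 2] >= iv[r, 2] &
           (iv[, 1] != iv[r, 1] | iv[, 2] != iv[r, 2]))
  }, logical(1))
  iv <- iv[keep, , drop = FALSE]
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  data.frame(start = pos[iv[, 1]], end = pos[iv[, 2]],
             n_snps = iv[, 2] - iv[, 1] + 1L,
             n_het = vapply(seq_len(nrow(iv)), function(r)
               sum(het[iv[r, 1]:iv[r, 2]]), integer(1)))
}

# run-length segmentation of a ratio vector by a literal window-by-window
# walk (loss < loss_max, gain > gain_min, runs >= min_windows)
seg_oracle <- function(ratio, loss_max = 0.7, gain_min = 1.3,
                       min_windows = 3) {
  state <- function(r) if (r < loss_max) "loss" else
    if (r > gain_min) "gain" else "normal"
  runs <- list()
  i <- 1
  while (i <= length(ratio)) {
    s <- state(ratio[i])
    j <- i
    while (j < length(ratio) && state(ratio[j + 1]) == s) j <- j + 1
    if (s != "normal" && (j - i + 1) >= min_windows)
      runs[[length(runs) + 1]] <- data.frame(first = i, last = j, state = s)
    i <- j + 1
  }
  if (length(runs) == 0)
    return(data.frame(first = integer(), last = integer(),
                      state = character()))
  do.call(rbind, runs)
}

# per-bp coverage counting for shared homozygosity on a small chromosome
shared_oracle <- function(roh, chrom_len, min_cases) {
  cov <- integer(chrom_len)
  for (s in unique(roh$sample)) {
    hit <- logical(chrom_len)
    rs <- roh[roh$sample == s, ]
    for (r in seq_len(nrow(rs))) hit[rs$start[r]:rs$end[r]] <- TRUE
    cov <- cov + hit
  }
  ok <- cov >= min_cases
  if (!any(ok)) return(data.frame(start = numeric(), end = numeric(),
                                  n_cases = integer()))
  # maximal stretches of constant coverage among covered bp
  d <- data.frame(bp = which(ok), n = cov[ok])
  brk <- c(TRUE, diff(d$bp) != 1 | diff(d$n) != 0)
  grp <- cumsum(brk)
  do.call(rbind, lapply(split(d, grp), function(g)
    data.frame(start = min(g$bp), end = max(g$bp), n_cases = g$n[1])))
}

# consequence of a coding variant by mutating the full CDS and comparing
# codon strings / translations of the two sequences
retranslate_oracle <- function(cds, cds_pos, type = c("snv", "ins", "del"),
                               alt_base = NULL, ins_seq = NULL, del_len = 0) {
  type <- match.arg(type)
  mut <- switch(type,
    snv = { s <- cds; substr(s, cds_pos, cds_pos) <- alt_base; s },
    ins = paste0(substr(cds, 1, cds_pos), ins_seq,
                 substr(cds, cds_pos + 1, nchar(cds))),
    del = paste0(substr(cds, 1, cds_pos - 1),
                 substr(cds, cds_pos + del_len, nchar(cds))))
  codons <- function(s) substring(s, seq(1, nchar(s) - 2, 3),
                                  seq(3, nchar(s), 3))
  c0 <- codons(cds); c1 <- codons(mut)
  ncmp <- min(length(c0), length(c1))
  diffs <- which(c0[seq_len(ncmp)] != c1[seq_len(ncmp)])
  first_changed <- if (length(diffs)) diffs[1] else
    if (length(c0) != length(c1)) ncmp + 1 else NA_integer_
  tr <- function(cs) unname(Biostrings::GENETIC_CODE[cs])
  class <- if (type == "snv") {
    a0 <- tr(c0[first_changed]); a1 <- tr(c1[first_changed])
    if (identical(a0, a1)) "synonymous" else if (a1 == "*") "stop_gained"
    else if (a0 == "*") "stop_lost" else "missense"
  } else {
    if ((nchar(mut) - nchar(cds)) %% 3 != 0) "frameshift" else
      "inframe_indel"
  }
  list(class = class, first_changed_codon = first_changed)
}

# random pedigree: animals numbered 1..n; each non-founder draws parents
# uniformly from earlier animals (possibly the same line, creating loops)
random_pedigree <- function(n, p_founder = 0.3) {
  id <- sprintf("a%02d", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= 2 || stats::runif(1) < p_founder) next
    pick <- sample(i - 1, 2)
    sire[i] <- id[pick[1]]
    dam[i] <- id[pick[2]]
  }
  pedigree(id, sire, dam)
}
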