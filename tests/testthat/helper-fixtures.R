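# Small hand-built fixtures shared across test files.

tiny_build <- function() genome_build(c("chr1", "chr2"), c(1e6, 1e6))

# cohort from an explicit genotype matrix; samples named by role prefix
tiny_cohort <- function(gt, roles = NULL, pos = NULL, chrom = "chr1",
                        consequence = "missense", build = tiny_build()) {
  gt <- as.matrix(gt)
  n_v <- nrow(gt); n_s <- ncol(gt)
  if (is.null(roles)) roles <- rep("control", n_s)
  ids <- colnames(gt)
  if (is.null(ids)) {
    ids <- make.unique(paste0(roles, seq_len(n_s)), sep = "_")
    colnames(gt) <- ids
  }
  if (is.null(pos)) pos <- seq_len(n_v) * 1000
  cohort_genotypes(
    data.frame(chrom = rep_len(chrom, n_v), pos = pos,
               ref = rep("A", n_v), alt = rep("G", n_v),
               gene = NA_character_,
               consequence = rep_len(consequence, n_v)),
    data.frame(sample = ids, role = roles),
    gt, build = build)
}

# two-exon gene model on the plus or minus strand with a given CDS
two_exon_model <- function(strand = "+", cds_seq = NULL) {
  # CDS segments chr1:101-130 and chr1:161-190 (30 bp each)
  if (is.null(cds_seq))
    cds_seq <- paste(rep("ATG", 20), collapse = "")
  gene_model("gx", "gx.t1", "chr1", strand,
             cds_starts = c(101, 161), cds_ends = c(130, 190),
             cds_seq = cds_seq)
}

random_cds <- function(n_codon) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  paste(c("ATG", sample(codons, n_codon - 2, replace = TRUE), "TAA"),
        collapse = "")
}
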