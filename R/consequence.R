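#' Define a gene model (one transcript's CDS)
#'
#' Holds the ordered CDS segments of a transcript and its strand-corrected
#' coding sequence. Segments are given in genomic coordinates (1-based
#' inclusive), ordered by position; for minus-strand genes the 5'-most CDS
#' segment is therefore the last one listed.
#'
#' @param gene,transcript Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds_starts,cds_ends Numeric vectors of segment boundaries
#'   (1-based inclusive), non-overlapping, sorted ascending.
#' @param cds_seq Concatenated coding sequence read 5'->3' on the coding
#'   strand. Its length must equal the summed segment lengths and, for a
#'   complete model, be divisible by 3.
#' @param complete Is the model a complete CDS (start to stop)? Default TRUE.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, transcript, chrom, strand, cds_starts, cds_ends,
                       cds_seq, complete = TRUE) {
  stopifnot(strand %in% c("+", "-"),
            length(cds_starts) == length(cds_ends),
            all(cds_starts <= cds_ends))
  o <- order(cds_starts)
  cds_starts <- cds_starts[o]; cds_ends <- cds_ends[o]
  if (length(cds_starts) > 1 &&
      any(cds_starts[-1] <= cds_ends[-length(cds_ends)]))
    stop("CDS segments overlap")
  cds_seq <- toupper(cds_seq)
  if (!grepl("^[ACGT]+$", cds_seq)) stop("cds_seq must be over {A,C,G,T}")
  n <- sum(cds_ends - cds_starts + 1)
  if (nchar(cds_seq) != n)
    stop("cds_seq length (", nchar(cds_seq),
         ") != summed CDS segment length (", n, ")")
  if (complete && n %% 3 != 0)
    stop("complete CDS length must be divisible by 3")
  structure(list(gene = gene, transcript = transcript, chrom = chrom,
                 strand = strand, cds_starts = cds_starts,
                 cds_ends = cds_ends, cds_seq = cds_seq,
                 complete = complete),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%s strand %s, %d segment(s), CDS %d bp\n",
              x$gene, x$transcript, x$chrom,
              paste0(min(x$cds_starts), "-", max(x$cds_ends)),
              x$strand, length(x$cds_starts), nchar(x$cds_seq)))
  invisible(x)
}

#' Map a genomic position to a coding (cDNA) position
#'
#' Strand-aware cumulative offset across the CDS segments. Positions inside
#' an intron or outside the CDS span return `NA` (non-coding), not an error.
#'
#' @param model A [gene_model()].
#' @param pos Genomic position (1-based).
#' @return Integer cds position (1-based), or `NA_integer_` if non-coding.
#' @export
map_genomic_to_cds <- function(model, pos) {
  seg <- which(pos >= model$cds_starts & pos <= model$cds_ends)
  if (length(seg) == 0) return(NA_integer_)
  lens <- model$cds_ends - model$cds_starts + 1
  if (model$strand == "+") {
    before <- if (seg > 1) sum(lens[seq_len(seg - 1)]) else 0
    as.integer(before + (pos - model$cds_starts[seg]) + 1)
  } else {
    n_seg <- length(lens)
    after <- if (seg < n_seg) sum(lens[seq(seg + 1, n_seg)]) else 0
    as.integer(after + (model$cds_ends[seg] - pos) + 1)
  }
}

#' Map a coding position back to its genomic position
#'
#' Inverse of [map_genomic_to_cds()]; the two form a bijection over the CDS.
#'
#' @param model A [gene_model()].
#' @param cds_pos Coding position (1-based).
#' @return Genomic position (1-based).
#' @export
map_cds_to_genomic <- function(model, cds_pos) {
  n <- nchar(model$cds_seq)
  if (cds_pos < 1 || cds_pos > n) stop("cds_pos outside CDS")
  lens <- model$cds_ends - model$cds_starts + 1
  if (model$strand == "+") {
    cum <- cumsum(lens)
    seg <- which(cds_pos <= cum)[1]
    before <- if (seg > 1) cum[seg - 1] else 0
    model$cds_starts[seg] + (cds_pos - before) - 1
  } else {
    cum <- cumsum(rev(lens))        # 5'->3' order = descending genomic
    k <- which(cds_pos <= cum)[1]   # k-th segment from the 3' genomic end
    before <- if (k > 1) cum[k - 1] else 0
    seg <- length(lens) - k + 1
    model$cds_ends[seg] - (cds_pos - before) + 1
  }
}

#' Codon index of a coding position
#'
#' The 1-based index of the codon containing coding position `cds_pos`,
#' i.e. `ceiling(cds_pos / 3)`. This is the arithmetic behind protein-change
#' labels such as p.Gly20Trp (c.58) and p.Ala203Thr (c.607).
#'
#' @param cds_pos Coding position(s), 1-based.
#' @return Integer codon index(es).
#' @examples
#' codon_index(58)   # 20
#' codon_index(607)  # 203
#' @export
codon_index <- function(cds_pos) {
  stopifnot(all(cds_pos >= 1))
  as.integer(ceiling(cds_pos / 3))
}

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""),
                character(1)))
}

g_label <- function(chrom, pos, ref, alt) {
  num <- sub("^chr", "", chrom, ignore.case = TRUE)
  sprintf("Chr%s:g.%d%s>%s", num, pos, ref, alt)
}

consequence_call <- function(variant, model, class, cds_pos = NA_integer_,
                             codon = NA_integer_, aa_ref = NA_character_,
                             aa_alt = NA_character_, g = NA_character_,
                             c = NA_character_, p = NA_character_) {
  structure(list(variant = variant, gene = model$gene,
                 transcript = model$transcript, class = class,
                 cds_pos = cds_pos, codon_index = codon,
                 aa_ref = aa_ref, aa_alt = aa_alt,
                 g_label = g, c_label = c, p_label = p),
            class = "consequence_call")
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s [%s] %s %s %s\n", x$gene, x$class,
              ifelse(is.na(x$g_label), "", x$g_label),
              ifelse(is.na(x$c_label), "", x$c_label),
              ifelse(is.na(x$p_label), "", x$p_label)))
  invisible(x)
}

#' Annotate a single-nucleotide variant against a gene model
#'
#' Translates the affected codon before and after the substitution using the
#' standard genetic code and assigns a class: `synonymous` if the amino acid
#' is unchanged, `stop_gained` if the mutant codon is a stop, `stop_lost` if
#' a stop is lost, otherwise `missense`. Labels are HGVS-like: genomic (g.),
#' cDNA (c.) and protein (p.) strings regenerate deterministically from the
#' call's fields.
#'
#' @param model A [gene_model()].
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` (single bases, reference strand).
#' @return A `consequence_call`; class `non_coding` when the position falls
#'   outside the CDS.
#' @export
annotate_snv <- function(model, variant) {
  v <- as.list(variant)
  stopifnot(nchar(v$ref) == 1, nchar(v$alt) == 1)
  if (v$chrom != model$chrom)
    return(consequence_call(v, model, "non_coding"))
  cds_pos <- map_genomic_to_cds(model, v$pos)
  if (is.na(cds_pos))
    return(consequence_call(v, model, "non_coding",
                            g = g_label(v$chrom, v$pos, v$ref, v$alt)))
  ref_c <- if (model$strand == "+") v$ref else revcomp(v$ref)
  alt_c <- if (model$strand == "+") v$alt else revcomp(v$alt)
  if (substr(model$cds_seq, cds_pos, cds_pos) != ref_c)
    stop("reference allele inconsistent with gene model at cds position ",
         cds_pos)
  ci <- codon_index(cds_pos)
  codon_start <- (ci - 1L) * 3L + 1L
  ref_codon <- substr(model$cds_seq, codon_start, codon_start + 2L)
  within <- cds_pos - codon_start + 1L
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_c
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  class <- if (aa_ref == aa_alt) "synonymous"
           else if (aa_alt == "*") "stop_gained"
           else if (aa_ref == "*") "stop_lost"
           else "missense"
  p <- if (class == "synonymous") sprintf("p.%s%d=", AA3[[aa_ref]], ci)
       else sprintf("p.%s%d%s", AA3[[aa_ref]], ci, AA3[[aa_alt]])
  consequence_call(v, model, class, cds_pos, ci, aa_ref, aa_alt,
                   g = g_label(v$chrom, v$pos, v$ref, v$alt),
                   c = sprintf("c.%d%s>%s", cds_pos, ref_c, alt_c),
                   p = p)
}

#' Annotate a small insertion or deletion against a gene model
#'
#' VCF-style indels (anchor base shared between `ref` and `alt`). A net
#' length change not divisible by 3 is a `frameshift`, otherwise an
#' `inframe_indel`. The first affected codon is the codon containing the
#' first changed coding base: for an insertion/duplication after coding
#' position p this is `ceiling((p + 1) / 3)`; for a deletion it is the codon
#' of the first deleted base. An indel spanning a CDS/intron boundary is
#' classed `splice_region` (placeholder; splice effects are not modeled).
#'
#' @param model A [gene_model()].
#' @param variant List or one-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` where one of ref/alt is a prefix of the other (simple indel).
#' @return A `consequence_call`. Frameshift protein labels take the form
#'   `p.<Aaa><idx>fs` where `<Aaa>` is the reference residue at the first
#'   affected codon.
#' @export
annotate_indel <- function(model, variant) {
  v <- as.list(variant)
  net <- nchar(v$alt) - nchar(v$ref)
  if (net == 0) stop("not an indel (equal allele lengths)")
  if (v$chrom != model$chrom)
    return(consequence_call(v, model, "non_coding"))
  if (!(startsWith(v$alt, v$ref) || startsWith(v$ref, v$alt)))
    stop("only simple VCF-style indels (shared anchor base) are supported")
  g <- g_label(v$chrom, v$pos, v$ref, v$alt)

  if (net > 0) {                           # insertion after anchor pos
    left <- map_genomic_to_cds(model, v$pos)
    right <- map_genomic_to_cds(model, v$pos + 1L)
    if (is.na(left) && is.na(right))
      return(consequence_call(v, model, "non_coding", g = g))
    if (is.na(left) || is.na(right) || abs(left - right) != 1L)
      return(consequence_call(v, model, "splice_region", g = g))
    p <- min(left, right)                  # insertion sits after cds pos p
    ins <- substr(v$alt, nchar(v$ref) + 1L, nchar(v$alt))
    ins_c <- if (model$strand == "+") ins else revcomp(ins)
    first_codon <- codon_index(p + 1L)
    class <- if (net %% 3 != 0) "frameshift" else "inframe_indel"
    dup <- net == 1L &&
      substr(model$cds_seq, p, p) == ins_c
    c_lab <- if (dup) sprintf("c.%ddup%s", p, ins_c)
             else sprintf("c.%d_%dins%s", p, p + 1L, ins_c)
  } else {                                 # deletion of bases after anchor
    n_del <- -net
    del_gpos <- v$pos + seq_len(n_del)     # reference-strand coordinates
    cds <- vapply(del_gpos, function(gp) map_genomic_to_cds(model, gp),
                  integer(1))
    if (all(is.na(cds)))
      return(consequence_call(v, model, "non_coding", g = g))
    if (any(is.na(cds)) || (max(cds) - min(cds) + 1L) != n_del)
      return(consequence_call(v, model, "splice_region", g = g))
    first_codon <- codon_index(min(cds))
    class <- if (n_del %% 3 != 0) "frameshift" else "inframe_indel"
    c_lab <- if (n_del == 1) sprintf("c.%ddel", min(cds))
             else sprintf("c.%d_%ddel", min(cds), max(cds))
    p <- min(cds) - 1L
  }
  codon_start <- (first_codon - 1L) * 3L + 1L
  aa_ref <- if (codon_start + 2L <= nchar(model$cds_seq))
    translate_codon(substr(model$cds_seq, codon_start, codon_start + 2L))
  else NA_character_
  p_lab <- if (class == "frameshift" && !is.na(aa_ref))
    sprintf("p.%s%dfs", AA3[[aa_ref]], first_codon)
  else NA_character_
  consequence_call(v, model, class, cds_pos = p + 1L, codon = first_codon,
                   aa_ref = aa_ref, g = g, c = c_lab, p = p_lab)
}
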