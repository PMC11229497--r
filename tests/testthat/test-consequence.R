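test_that("genomic<->cds mapping walks exons correctly on both strands", {
  m <- two_exon_model("+")
  expect_equal(map_genomic_to_cds(m, 101), 1L)
  expect_equal(map_genomic_to_cds(m, 130), 30L)
  expect_equal(map_genomic_to_cds(m, 161), 31L)   # first base of exon 2
  expect_equal(map_genomic_to_cds(m, 145), NA_integer_)  # intron
  mm <- two_exon_model("-")
  expect_equal(map_genomic_to_cds(mm, 190), 1L)   # 3'-most genomic = cds 1
  expect_equal(map_genomic_to_cds(mm, 161), 30L)
  expect_equal(map_genomic_to_cds(mm, 130), 31L)
  expect_equal(map_genomic_to_cds(mm, 101), 60L)
})

test_that("cds mapping and its inverse form a bijection over the CDS", {
  for (strand in c("+", "-")) {
    m <- two_exon_model(strand)
    for (cp in 1:60) {
      g <- map_cds_to_genomic(m, cp)
      expect_equal(map_genomic_to_cds(m, g), cp)
    }
  }
})

test_that("codon_index implements ceil(cds_pos / 3)", {
  expect_equal(codon_index(58), 20L)
  expect_equal(codon_index(607), 203L)
  expect_equal(codon_index(3), 1L)
  expect_equal(codon_index(1:9), rep(1:3, each = 3))
})

test_that("annotate_snv reproduces the candidate missense labels", {
  gm <- synthetic_gene_models()
  a <- annotate_snv(gm$geneA,
                    list(chrom = gm$geneA$chrom,
                         pos = map_cds_to_genomic(gm$geneA, 58),
                         ref = "G", alt = "T"))
  expect_equal(a$class, "missense")
  expect_equal(a$codon_index, 20L)
  expect_equal(a$p_label, "p.Gly20Trp")
  expect_equal(a$c_label, "c.58G>T")
  b <- annotate_snv(gm$geneB,
                    list(chrom = gm$geneB$chrom,
                         pos = map_cds_to_genomic(gm$geneB, 607),
                         ref = "G", alt = "A"))
  expect_equal(b$p_label, "p.Ala203Thr")
})

test_that("annotate_snv classifies synonymous and stop-gain changes", {
  # codon 2 = CTG (Leu); CTG->CTA synonymous, CTG->TAG via pos 4 C->T? no:
  # build a model where codon 2 = TGG (Trp): TGG->TAG is a stop gain,
  # and codon 3 = CTG: third-base G->A gives CTA (synonymous Leu)
  seq <- paste0("ATG", "TGG", "CTG", "TAA")
  m <- gene_model("g", "t", "chr1", "+", 101, 112, seq)
  stopg <- annotate_snv(m, list(chrom = "chr1", pos = 105, ref = "G",
                                alt = "A"))  # cds 5: TGG->TAG
  expect_equal(stopg$class, "stop_gained")
  syn <- annotate_snv(m, list(chrom = "chr1", pos = 109, ref = "G",
                              alt = "A"))    # cds 9: CTG->CTA
  expect_equal(syn$class, "synonymous")
  expect_error(annotate_snv(m, list(chrom = "chr1", pos = 105, ref = "C",
                                    alt = "A")), "inconsistent")
})

test_that("annotate_indel applies the frameshift codon arithmetic", {
  gm <- synthetic_gene_models()
  p10773 <- map_cds_to_genomic(gm$geneC, 10773)
  base <- substr(gm$geneC$cds_seq, 10773, 10773)
  d <- annotate_indel(gm$geneC,
                      list(chrom = gm$geneC$chrom, pos = p10773,
                           ref = base, alt = paste0(base, base)))
  expect_equal(d$class, "frameshift")
  expect_equal(d$codon_index, 3592L)
  expect_equal(d$p_label, "p.Ser3592fs")
  expect_equal(d$c_label, "c.10773dupC")

  # dup after cds position 4 -> first affected codon 2
  m <- gene_model("g", "t", "chr1", "+", 101, 112,
                  paste0("ATG", "CCC", "GGG", "TAA"))
  d2 <- annotate_indel(m, list(chrom = "chr1", pos = 104, ref = "C",
                               alt = "CC"))
  expect_equal(d2$class, "frameshift")
  expect_equal(d2$codon_index, 2L)

  # 3-bp deletion wholly inside the CDS is in-frame
  d3 <- annotate_indel(m, list(chrom = "chr1", pos = 103, ref = "CCCG",
                               alt = "C"))
  expect_equal(d3$class, "inframe_indel")
})

test_that("an indel spanning a CDS/intron boundary is a splice placeholder", {
  m <- two_exon_model("+", random_cds(20))
  # deletion crossing the exon1/intron boundary at 130/131
  sp <- annotate_indel(m, list(chrom = "chr1", pos = 128,
                               ref = "AAAAAA", alt = "A"))
  expect_equal(sp$class, "splice_region")
})

test_that("arithmetic consequence rules agree with full re-translation on random coding variants", {
  set.seed(202)
  n_cases <- 0
  for (rep in 1:120) {
    n_codon <- sample(10:60, 1)
    cds <- random_cds(n_codon)
    start <- sample(1000:2000, 1)
    m <- gene_model("g", "t", "chr1", "+", start,
                    start + nchar(cds) - 1, cds)
    # a few random SNVs
    for (k in 1:6) {
      cp <- sample(4:(nchar(cds) - 3), 1)
      ref <- substr(cds, cp, cp)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      got <- annotate_snv(m, list(chrom = "chr1", pos = start + cp - 1,
                                  ref = ref, alt = alt))
      want <- retranslate_oracle(cds, cp, "snv", alt_base = alt)
      expect_equal(got$class, want$class)
      expect_equal(got$codon_index, want$first_changed_codon)
      n_cases <- n_cases + 1
    }
    # one random insertion and one random deletion
    cp <- sample(4:(nchar(cds) - 6), 1)
    ins <- paste(sample(c("A", "C", "G", "T"),
                        sample(c(1, 2, 3, 4), 1), TRUE), collapse = "")
    anchor <- substr(cds, cp, cp)
    got_i <- annotate_indel(m, list(chrom = "chr1", pos = start + cp - 1,
                                    ref = anchor,
                                    alt = paste0(anchor, ins)))
    want_i <- retranslate_oracle(cds, cp, "ins", ins_seq = ins)
    expect_equal(got_i$class, want_i$class)
    # first changed codon: the codon containing cds position cp + 1
    expect_equal(got_i$codon_index, codon_index(cp + 1))
    expect_equal(want_i$first_changed_codon >= got_i$codon_index ||
                   is.na(want_i$first_changed_codon), TRUE)

    dl <- sample(c(1, 2, 3), 1)
    got_d <- annotate_indel(m, list(chrom = "chr1", pos = start + cp - 1,
                                    ref = substr(cds, cp, cp + dl),
                                    alt = anchor))
    want_d <- retranslate_oracle(cds, cp + 1, "del", del_len = dl)
    expect_equal(got_d$class, want_d$class)
    n_cases <- n_cases + 2
  }
  expect_gte(n_cases, 900)
})
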