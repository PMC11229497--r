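#' Simulation configuration
#'
#' Defines the study conditions the synthetic cohorts emulate: a control
#' cohort of Hardy-Weinberg genotypes, case families of trio/duo/solo
#' design, background polymorphisms, and the read-depth model. With a fixed
#' seed every generator in the package is deterministic.
#'
#' The control samples play the role of the first-pass "privacy" cohort the
#' variant filters compare against; an additional `n_global_extra`
#' stratum extends it to the wider second-pass cohort in which heterozygous
#' carriers of recessive candidate alleles may segregate. The background
#' minor-allele-frequency floor (0.15) is chosen so that every background
#' polymorphism is expected to show at least one allele copy among the
#' controls (P(absent) = 0.85^100 ~ 9e-8 at 50 controls), which is the
#' desk-scale analogue of filtering for variants private against a
#' 1,000-genome cohort.
#'
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @param n_controls Number of control samples (first-pass cohort).
#' @param n_global_extra Additional samples forming, together with the
#'   controls, the wider second-pass ("global") cohort.
#' @param families Character vector of family designs, each one of
#'   `"trio"`, `"duo"`, `"solo"`.
#' @param n_background_variants Number of background biallelic sites.
#' @param background_maf_range Length-2 numeric in (0, 0.5]; per-site minor
#'   allele frequencies are drawn uniformly from this range.
#' @param mean_coverage Mean sequencing depth (reads per bp x read length /
#'   read length; i.e. fold-coverage).
#' @param read_length Read length in bp used to convert coverage to read
#'   counts per window.
#' @param depth_dispersion Negative-binomial overdispersion of window read
#'   counts; 0 gives Poisson counts. The window-count coefficient of
#'   variation is about `sqrt(1/mu + depth_dispersion)`; the default 0.005
#'   gives the ~5-10% window-to-window variability of a well-behaved WGS
#'   library at these window sizes.
#' @param window_sizes Window sizes (bp) for depth simulation, fine first.
#' @param missing_rate Per-genotype missingness probability.
#' @param build A [genome_build()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_controls = 50L, n_global_extra = 20L,
                       families = c("trio", "duo", "solo"),
                       n_background_variants = 20000L,
                       background_maf_range = c(0.15, 0.5),
                       mean_coverage = 20, read_length = 150,
                       depth_dispersion = 0.005,
                       window_sizes = c(10000L, 200000L),
                       missing_rate = 0,
                       build = synthetic_build()) {
  stopifnot(all(families %in% c("trio", "duo", "solo")),
            length(background_maf_range) == 2,
            background_maf_range[1] > 0, background_maf_range[2] <= 0.5,
            background_maf_range[1] <= background_maf_range[2],
            mean_coverage > 0, depth_dispersion >= 0,
            missing_rate >= 0, missing_rate < 1)
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 n_global_extra = as.integer(n_global_extra),
                 families = families,
                 n_background_variants = as.integer(n_background_variants),
                 background_maf_range = background_maf_range,
                 mean_coverage = mean_coverage, read_length = read_length,
                 depth_dispersion = depth_dispersion,
                 window_sizes = as.integer(window_sizes),
                 missing_rate = missing_rate, build = build),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Default planted events: one per event class the pipeline must recover
#'
#' Mirrors the finding classes of the motivating case series: a homozygous
#' recessive missense in a trio (12 global het carriers), a homozygous
#' recessive missense in a solo case (7 global het carriers), a private
#' heterozygous frameshift duplication (de novo, 0 carriers), two
#' heterozygous Mb-scale deletions on one chromosome with an overlapping
#' core, and a whole-chromosome trisomy.
#'
#' @param config A [sim_config()]; family indices refer to `config$families`.
#' @return List of planted-event descriptors.
#' @export
default_events <- function(config) {
  n_fam <- length(config$families)
  trio_i <- match("trio", config$families)
  solo_i <- match("solo", config$families)
  other_i <- setdiff(seq_len(n_fam), c(trio_i, solo_i))[1]
  if (is.na(trio_i) || is.na(solo_i) || is.na(other_i))
    stop("default events require at least a trio, a solo and one more family")
  list(
    list(kind = "recessive_snv", family = trio_i, gene = "geneA",
         k_carriers = 12L),
    list(kind = "recessive_snv", family = solo_i, gene = "geneB",
         k_carriers = 7L),
    list(kind = "denovo_indel", family = other_i, gene = "geneC",
         k_carriers = 0L),
    list(kind = "segmental_deletion", family = trio_i, chrom = "chr2",
         start = 6000001, end = 9000000),
    list(kind = "segmental_deletion", family = other_i, chrom = "chr2",
         start = 7000001, end = 9500000),
    list(kind = "whole_chrom_trisomy", family = solo_i, chrom = "chr3")
  )
}

#' Synthetic gene models carrying the candidate codon structures
#'
#' Three single-exon models on the synthetic build. `geneA` carries codon 20
#' = GGG so that a G>T at coding position 58 yields p.Gly20Trp; `geneB`
#' carries codon 203 = GCA so that a G>A at coding position 607 yields
#' p.Ala203Thr; `geneC` is a 3,600-codon CDS whose coding position 10773 is
#' a C ending codon 3591, so a single-base C duplication there is a
#' frameshift first affecting codon 3592 (a serine): p.Ser3592fs.
#'
#' @param build A [genome_build()] with at least 3 chromosomes.
#' @param seed Seed for the filler codons.
#' @return Named list of [gene_model()] objects.
#' @export
synthetic_gene_models <- function(build = synthetic_build(), seed = 99L) {
  set.seed(seed)
  # codons without stops, sampled as filler
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  make_cds <- function(n_codon, fixed = list()) {
    cds <- sample(codons, n_codon, replace = TRUE)
    cds[1] <- "ATG"
    for (i in seq_along(fixed)) cds[as.integer(names(fixed)[i])] <- fixed[[i]]
    cds[n_codon] <- "TAA"
    paste(cds, collapse = "")
  }
  a_seq <- make_cds(300, fixed = list(`20` = "GGG"))
  b_seq <- make_cds(350, fixed = list(`203` = "GCA"))
  c_seq <- make_cds(3600, fixed = list(`3591` = sub(".$", "C",
                                                    sample(codons, 1)),
                                       `3592` = "AGC"))
  mk <- function(gene, chrom, start, seq)
    gene_model(gene, paste0(gene, ".t1"), chrom, "+",
               cds_starts = start, cds_ends = start + nchar(seq) - 1,
               cds_seq = seq)
  list(geneA = mk("geneA", build$chrom[1], 2000001, a_seq),
       geneB = mk("geneB", build$chrom[min(3, nrow(build))], 2500001, b_seq),
       geneC = mk("geneC", build$chrom[1], 5000001, c_seq))
}

#' Simulate a genotype cohort with planted inheritance-scenario events
#'
#' Background variants are drawn per site under Hardy-Weinberg equilibrium
#' with minor allele frequency uniform over the configured range; parental
#' genotypes are transmitted Mendelianly to case calves (unsequenced parents
#' of duo/solo designs exist as latent genomes). Planted events override the
#' background at their loci and are recorded in the returned truth set.
#'
#' @param config A [sim_config()].
#' @param events List of planted-event descriptors as produced by
#'   [default_events()]; only variant-type events (`recessive_snv`,
#'   `denovo_indel`, `carrier_allele`, `shared_roh`) act here. Use
#'   [simulate_depth()] for depth-type events. `NULL` plants nothing.
#' @param gene_models Gene models used to place and annotate planted coding
#'   variants; defaults to [synthetic_gene_models()].
#' @return List with elements `cohort` ([cohort_genotypes()]), `pedigree`
#'   ([pedigree()]), `truth` (data.frame, one row per planted event) and
#'   `families` (list of [case_family()]).
#' @export
simulate_cohort <- function(config, events = NULL,
                            gene_models = synthetic_gene_models(config$build)) {
  set.seed(config$seed)
  build <- config$build

  ## ---- sample sheet -------------------------------------------------------
  n_fam <- length(config$families)
  fam_ids <- sprintf("fam%02d", seq_len(n_fam))
  samples <- list()
  families <- list()
  ped_rows <- list()
  for (i in seq_len(n_fam)) {
    design <- config$families[i]
    case <- sprintf("%s_case", fam_ids[i])
    sire <- sprintf("%s_sire", fam_ids[i])
    dam <- sprintf("%s_dam", fam_ids[i])
    seq_sire <- design == "trio" || design == "duo"
    seq_dam <- design == "trio"
    families[[i]] <- case_family(case,
                                 sire = if (seq_sire) sire else NA,
                                 dam = if (seq_dam) dam else NA)
    samples[[length(samples) + 1]] <-
      data.frame(sample = case, role = "case", family = fam_ids[i])
    if (seq_sire)
      samples[[length(samples) + 1]] <-
        data.frame(sample = sire, role = "sire", family = fam_ids[i])
    if (seq_dam)
      samples[[length(samples) + 1]] <-
        data.frame(sample = dam, role = "dam", family = fam_ids[i])
    ped_rows[[i]] <- data.frame(id = c(case, sire, dam),
                                sire = c(sire, NA, NA),
                                dam = c(dam, NA, NA),
                                sex = c("M", "M", "F"))
  }
  ctrl <- sprintf("ctrl%03d", seq_len(config$n_controls))
  glob <- if (config$n_global_extra > 0)
    sprintf("glob%03d", seq_len(config$n_global_extra)) else character()
  samples <- rbind(do.call(rbind, samples),
                   data.frame(sample = ctrl, role = "control", family = NA),
                   if (length(glob))
                     data.frame(sample = glob, role = "global", family = NA))
  n_samp <- nrow(samples)

  ## ---- background sites ---------------------------------------------------
  n_bg <- config$n_background_variants
  chrom_p <- build$length / sum(build$length)
  site_chrom <- sample(build$chrom, n_bg, replace = TRUE, prob = chrom_p)
  site_pos <- numeric(n_bg)
  for (ch in build$chrom) {
    sel <- site_chrom == ch
    site_pos[sel] <- sample.int(chrom_length(build, ch), sum(sel),
                                replace = TRUE)
  }
  o <- order(chrom_factor(site_chrom, build), site_pos)
  site_chrom <- site_chrom[o]; site_pos <- site_pos[o]
  dup <- duplicated(paste(site_chrom, site_pos))
  site_chrom <- site_chrom[!dup]; site_pos <- site_pos[!dup]
  # keep candidate coding positions free for planting
  cand <- vapply(gene_models, function(m) {
    cp <- candidate_site(m)$cds_pos
    paste(m$chrom, map_cds_to_genomic(m, cp))
  }, character(1))
  keep <- !(paste(site_chrom, site_pos) %in% cand)
  site_chrom <- site_chrom[keep]; site_pos <- site_pos[keep]
  n_bg <- length(site_pos)
  maf <- stats::runif(n_bg, config$background_maf_range[1],
                      config$background_maf_range[2])
  ref <- sample(BASES, n_bg, replace = TRUE)
  # alt: uniform over the three non-ref bases, vectorized
  shift <- sample.int(3, n_bg, replace = TRUE)
  alt <- BASES[(match(ref, BASES) - 1L + shift) %% 4L + 1L]
  csq <- sample(c("non_coding", "synonymous", "missense", "stop_gained",
                  "inframe_indel", "frameshift"),
                n_bg, replace = TRUE,
                prob = c(0.60, 0.15, 0.18, 0.03, 0.02, 0.02))

  ## ---- genotypes ----------------------------------------------------------
  gt <- matrix(NA_integer_, n_bg, n_samp,
               dimnames = list(NULL, samples$sample))
  hwe_draw <- function(q) stats::rbinom(length(q), 2L, q)
  non_case <- samples$sample[samples$role != "case"]
  for (s in non_case) gt[, s] <- hwe_draw(maf)
  transmit <- function(g_par) {
    # allele transmitted from a parent genotype (alt-allele dosage)
    ifelse(g_par == 0L, 0L,
           ifelse(g_par == 2L, 1L, stats::rbinom(length(g_par), 1L, 0.5)))
  }
  for (i in seq_len(n_fam)) {
    fam <- families[[i]]
    g_sire <- if (!is.na(fam$sire)) gt[, fam$sire] else hwe_draw(maf)
    g_dam <- if (!is.na(fam$dam)) gt[, fam$dam] else hwe_draw(maf)
    gt[, fam$case] <- transmit(g_sire) + transmit(g_dam)
  }

  variants <- data.frame(chrom = site_chrom, pos = site_pos, ref = ref,
                         alt = alt, gene = NA_character_, consequence = csq,
                         stringsAsFactors = FALSE)
  cohort <- cohort_genotypes(variants, samples, gt, build = build)

  ## ---- planted events -----------------------------------------------------
  truth <- list()
  if (!is.null(events)) {
    for (ev in events) {
      if (!ev$kind %in% c("recessive_snv", "denovo_indel", "carrier_allele",
                          "shared_roh"))
        next
      if (ev$kind == "shared_roh") {
        cohort <- plant_shared_roh(cohort, ev$chrom, ev$start, ev$end,
                                   vapply(families, `[[`, "", "case"))
        truth[[length(truth) + 1]] <-
          truth_row(kind = ev$kind, chrom = ev$chrom, start = ev$start,
                    end = ev$end, sample = "all_cases")
        next
      }
      fam <- families[[ev$family]]
      scenario <- switch(ev$kind,
                         recessive_snv = paste0("recessive_", fam$design),
                         denovo_indel = "denovo",
                         carrier_allele = "carrier")
      planted <- plant_variant_scenario(cohort, scenario, fam,
                                        gene_models[[ev$gene]],
                                        k_carriers = ev$k_carriers)
      cohort <- planted$cohort
      truth[[length(truth) + 1]] <-
        truth_row(kind = ev$kind, chrom = planted$variant$chrom,
                  start = planted$variant$pos, end = planted$variant$pos,
                  sample = fam$case, gene = ev$gene,
                  ref = planted$variant$ref, alt = planted$variant$alt,
                  k_carriers = ev$k_carriers, scenario = scenario)
    }
    # depth-type events are simulated by simulate_depth(); record truth here
    for (ev in events) {
      if (ev$kind == "segmental_deletion") {
        fam <- families[[ev$family]]
        truth[[length(truth) + 1]] <-
          truth_row(kind = ev$kind, chrom = ev$chrom, start = ev$start,
                    end = ev$end, sample = fam$case, expected_ratio = 0.5)
      } else if (ev$kind == "whole_chrom_trisomy") {
        fam <- families[[ev$family]]
        truth[[length(truth) + 1]] <-
          truth_row(kind = ev$kind, chrom = ev$chrom, start = 1,
                    end = chrom_length(build, ev$chrom), sample = fam$case,
                    expected_ratio = 1.5)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else truth_row()[0, ]

  ## ---- missingness --------------------------------------------------------
  if (config$missing_rate > 0) {
    planted_rows <- which(variant_key(cohort$variants) %in%
                            paste(truth$chrom, truth$start, truth$ref,
                                  truth$alt, sep = ":"))
    miss <- matrix(stats::runif(length(cohort$gt)) < config$missing_rate,
                   nrow(cohort$gt))
    miss[planted_rows, ] <- FALSE
    cohort$gt[miss] <- NA_integer_
  }

  ped <- do.call(rbind, ped_rows)
  ped <- pedigree(id = ped$id, sire = ped$sire, dam = ped$dam, sex = ped$sex)
  list(cohort = cohort, pedigree = ped, truth = truth, families = families)
}

truth_row <- function(kind = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      sample = character(0), gene = NA_character_,
                      ref = NA_character_, alt = NA_character_,
                      k_carriers = NA_integer_, scenario = NA_character_,
                      expected_ratio = NA_real_) {
  if (length(kind) == 0)
    return(data.frame(kind = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      sample = character(), gene = character(),
                      ref = character(), alt = character(),
                      k_carriers = integer(), scenario = character(),
                      expected_ratio = numeric(), stringsAsFactors = FALSE))
  data.frame(kind = kind, chrom = chrom, start = start, end = end,
             sample = sample, gene = gene, ref = ref, alt = alt,
             k_carriers = k_carriers, scenario = scenario,
             expected_ratio = expected_ratio, stringsAsFactors = FALSE)
}

#' Plant a candidate variant following an inheritance scenario
#'
#' Overrides cohort genotypes at one coding site of `gene_model` so that the
#' genotype pattern matches the scenario exactly:
#' * `recessive_trio`: case hom alt, both parents het, exactly `k_carriers`
#'   heterozygous samples in the global stratum, no other carriers.
#' * `recessive_duo`: as above with the single sequenced parent het.
#' * `recessive_solo`: case hom alt, no parent constraint.
#' * `denovo`: case het, sequenced parents hom ref, zero carriers anywhere.
#'
#' For missense scenarios the planted site is the gene's candidate codon
#' substitution; for `denovo` it is a single-base duplication (frameshift).
#' The variant is annotated against the gene model, so its consequence class
#' is computed, not asserted.
#'
#' @param cohort A [cohort_genotypes()].
#' @param scenario One of `"recessive_trio"`, `"recessive_duo"`,
#'   `"recessive_solo"`, `"denovo"`, `"carrier"`.
#' @param family A [case_family()]; its design must match the scenario.
#' @param gene_model A [gene_model()] present on the cohort's build.
#' @param k_carriers Number of heterozygous carriers to place in the global
#'   stratum (`role == "global"`); must not exceed its size. Must be 0 for
#'   `denovo`.
#' @return List with the updated `cohort` and the planted `variant` row.
#' @export
plant_variant_scenario <- function(cohort, scenario, family, gene_model,
                                   k_carriers = 0L) {
  scenario <- match.arg(scenario, c("recessive_trio", "recessive_duo",
                                    "recessive_solo", "denovo", "carrier"))
  if (startsWith(scenario, "recessive_")) {
    want <- sub("recessive_", "", scenario)
    if (family$design != want)
      stop("scenario ", scenario, " incompatible with a ", family$design,
           " family")
  }
  if (scenario == "denovo" && k_carriers != 0L)
    stop("de novo scenario admits no carriers")
  if (is.null(gene_model)) stop("gene model not found")

  # site: the model's candidate codon; missense for recessive, dup for denovo
  if (scenario == "denovo") {
    cds_pos <- candidate_site(gene_model)$cds_pos
    gpos <- map_cds_to_genomic(gene_model, cds_pos)
    base <- substr(gene_model$cds_seq, cds_pos, cds_pos)
    variant <- data.frame(chrom = gene_model$chrom, pos = gpos, ref = base,
                          alt = paste0(base, base), stringsAsFactors = FALSE)
    call <- annotate_indel(gene_model, variant)
  } else {
    site <- candidate_site(gene_model)
    gpos <- map_cds_to_genomic(gene_model, site$cds_pos)
    variant <- data.frame(chrom = gene_model$chrom, pos = gpos,
                          ref = site$ref, alt = site$alt,
                          stringsAsFactors = FALSE)
    call <- annotate_snv(gene_model, variant)
  }
  variant$gene <- gene_model$gene
  variant$consequence <- call$class

  key <- variant_key(variant)
  if (key %in% variant_key(cohort$variants))
    stop("planted locus collides with an existing variant: ", key)
  chrom_factor(variant$chrom, cohort$build)  # errors on unknown chromosome

  glob <- cohort$samples$sample[cohort$samples$role == "global"]
  if (k_carriers > length(glob))
    stop("k_carriers exceeds the global stratum size")

  g <- rep(0L, nrow(cohort$samples))
  names(g) <- cohort$samples$sample
  if (scenario == "denovo") {
    g[family$case] <- 1L
    for (p in family_parents(family)) g[p] <- 0L
  } else if (scenario == "carrier") {
    g[family$case] <- 1L
  } else {
    g[family$case] <- 2L
    for (p in family_parents(family)) g[p] <- 1L
  }
  if (k_carriers > 0) g[glob[seq_len(k_carriers)]] <- 1L

  variants <- rbind(cohort$variants[, c("chrom", "pos", "ref", "alt",
                                        "gene", "consequence")],
                    variant[, c("chrom", "pos", "ref", "alt",
                                "gene", "consequence")])
  gt <- rbind(cohort$gt, g)
  ord <- order(chrom_factor(variants$chrom, cohort$build), variants$pos)
  new_cohort <- cohort_genotypes(variants[ord, ], cohort$samples,
                                 gt[ord, , drop = FALSE],
                                 build = cohort$build)
  list(cohort = new_cohort, variant = variant)
}

# The single candidate site a synthetic gene model carries: geneA-style
# models use codon-20 G>T, geneB-style codon-203 G>A, long models the
# single-base duplication at the third base of codon 3591. Detected from the
# model's structure so user models work too: the first G of the first GGG
# codon, etc. For simplicity each packaged model declares its site by name.
candidate_site <- function(model) {
  if (model$gene == "geneA") return(list(cds_pos = 58L, ref = "G", alt = "T"))
  if (model$gene == "geneB") return(list(cds_pos = 607L, ref = "G", alt = "A"))
  if (model$gene == "geneC") return(list(cds_pos = 10773L))
  # generic fallback: first base of the second codon, transversion
  base <- substr(model$cds_seq, 4L, 4L)
  list(cds_pos = 4L, ref = base,
       alt = setdiff(BASES, base)[1])
}

plant_shared_roh <- function(cohort, chrom, start, end, case_ids) {
  idx <- which(cohort$variants$chrom == chrom &
                 cohort$variants$pos >= start & cohort$variants$pos <= end)
  if (length(idx) == 0) return(cohort)
  hom <- ifelse(stats::runif(length(idx)) < 0.5, 0L, 2L)
  for (s in case_ids) cohort$gt[idx, s] <- hom
  cohort
}

#' Simulate a windowed read-depth profile with copy-number events
#'
#' Window read counts are drawn from a negative binomial with mean
#' `mean_coverage * window_len * (copy_number / 2) / read_length` and
#' overdispersion `depth_dispersion` (Poisson when 0). Copy number is 1
#' inside heterozygous deletions, 3 on trisomic chromosomes and 2 elsewhere.
#'
#' @param sample Sample id the profile belongs to.
#' @param cnv_events List of events: `list(kind = "segmental_deletion",
#'   chrom =, start =, end =)` or `list(kind = "whole_chrom_trisomy",
#'   chrom =)`. Events must not overlap on a chromosome.
#' @param config A [sim_config()].
#' @param window_size Window size in bp (one profile per call).
#' @return A `depth_profile`.
#' @export
simulate_depth <- function(sample, cnv_events, config, window_size) {
  if (config$mean_coverage <= 0) stop("mean coverage must be positive")
  build <- config$build
  ev <- Filter(function(e) e$kind %in% c("segmental_deletion",
                                         "whole_chrom_trisomy"), cnv_events)
  by_chrom <- split(ev, vapply(ev, `[[`, "", "chrom"))
  for (ch in names(by_chrom)) {
    dels <- Filter(function(e) e$kind == "segmental_deletion", by_chrom[[ch]])
    if (length(dels) > 1) {
      iv <- t(vapply(dels, function(e) c(e$start, e$end), numeric(2)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
        stop("overlapping depth events on ", ch)
    }
  }
  out <- list()
  for (i in seq_len(nrow(build))) {
    ch <- build$chrom[i]
    len <- build$length[i]
    starts <- seq(1, len, by = window_size)
    ends <- pmin(starts + window_size - 1, len)
    cn <- rep(2, length(starts))
    for (e in by_chrom[[ch]]) {
      if (e$kind == "whole_chrom_trisomy") {
        cn[] <- 3
      } else {
        # a window takes the copy number of the event covering its midpoint
        mid <- (starts + ends) / 2
        cn[mid >= e$start & mid <= e$end] <- 1
      }
    }
    mu <- config$mean_coverage * (ends - starts + 1) * (cn / 2) /
      config$read_length
    counts <- if (config$depth_dispersion <= 0) stats::rpois(length(mu), mu)
              else stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$depth_dispersion)
    out[[i]] <- data.frame(chrom = ch, start = starts, end = ends,
                           count = counts)
  }
  d <- do.call(rbind, out)
  depth_profile(d$chrom, d$start, d$end, d$count, window_size, sample)
}
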