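#' Run the full simulate -> prioritize -> associate -> karyotype -> pedigree
#' pipeline
#'
#' Orchestrates every stage of the package on one simulated cohort: plants
#' the default event classes (or caller-supplied ones), runs the three
#' inheritance-scenario filters for each family plus the shared-recessive
#' scan, performs relatedness-pruned case/control association with
#' Bonferroni control, scans runs of homozygosity and their intersection,
#' calls depth-based segments/aneuploidies at the coarse window size and
#' refines breakpoints at the fine size, and computes pedigree inbreeding.
#' Re-running with the same config reproduces all outputs exactly.
#'
#' @param config A [sim_config()].
#' @param events Planted events; defaults to [default_events()].
#' @param outdir Optional directory; when given, VCF, PED, depth TSVs,
#'   truth TSV, candidate/funnel/segment TSVs and a JSON manifest are
#'   written there.
#' @return List with `manifest`, `candidates`, `funnels`, `association`,
#'   `roh`, `shared_roh`, `segments`, `aneuploidy`, `pedigree_f`, `truth`.
#' @export
run_pipeline <- function(config, events = default_events(config),
                         outdir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  sim <- simulate_cohort(config, events)
  cohort <- sim$cohort
  control_ids <- cohort$samples$sample[cohort$samples$role == "control"]
  global_ids <- cohort$samples$sample[cohort$samples$role %in%
                                        c("control", "global")]
  case_ids <- vapply(sim$families, `[[`, "", "case")

  ## variant prioritization --------------------------------------------------
  funnels <- list(shared_recessive =
                    filter_shared_recessive(cohort, case_ids, control_ids))
  candidates <- list()
  for (i in seq_along(sim$families)) {
    fam <- sim$families[[i]]
    fr <- filter_case_recessive(cohort, fam, control_ids, global_ids)
    fd <- filter_denovo_dominant(cohort, fam, control_ids, global_ids)
    funnels[[paste0(fam$case, "_recessive")]] <- fr
    funnels[[paste0(fam$case, "_denovo")]] <- fd
    if (nrow(fr$candidates) > 0)
      candidates[[length(candidates) + 1]] <-
        cbind(case = fam$case, scenario = "recessive", fr$candidates)
    if (nrow(fd$candidates) > 0)
      candidates[[length(candidates) + 1]] <-
        cbind(case = fam$case, scenario = "denovo", fd$candidates)
  }
  candidates <- if (length(candidates)) do.call(rbind, candidates) else
    data.frame()

  ## association + homozygosity ----------------------------------------------
  rel <- pairwise_relatedness(cohort, control_ids)
  pruned_controls <- prune_related(rel, 0.5)
  assoc <- allelic_association(cohort, case_ids, pruned_controls,
                               alpha = 0.05)
  roh <- do.call(rbind, lapply(case_ids, function(s)
    detect_roh(cohort, s)))
  shared <- shared_homozygosity(roh, min_cases = 2)

  ## coverage karyotyping -----------------------------------------------------
  fine_ws <- min(config$window_sizes)
  coarse_ws <- max(config$window_sizes)
  segs <- list(); aneu <- list()
  for (i in seq_along(sim$families)) {
    fam <- sim$families[[i]]
    ev_i <- Filter(function(e)
      e$kind %in% c("segmental_deletion", "whole_chrom_trisomy") &&
        e$family == i, events)
    coarse <- normalize_depth(simulate_depth(fam$case, ev_i, config,
                                             coarse_ws))
    fine <- normalize_depth(simulate_depth(fam$case, ev_i, config, fine_ws))
    calls <- call_segments(coarse)
    if (nrow(calls$segments) > 0) {
      refined <- do.call(rbind, lapply(seq_len(nrow(calls$segments)),
        function(k) refine_breakpoints(calls$segments[k, ], fine)))
      segs[[length(segs) + 1]] <- cbind(sample = fam$case, refined)
    }
    if (nrow(calls$aneuploidy) > 0)
      aneu[[length(aneu) + 1]] <- cbind(sample = fam$case, calls$aneuploidy)
  }
  segs <- if (length(segs)) do.call(rbind, segs) else data.frame()
  aneu <- if (length(aneu)) do.call(rbind, aneu) else data.frame()

  ## pedigree -----------------------------------------------------------------
  ped_f <- data.frame(id = case_ids,
                      f = vapply(case_ids, function(s)
                        wright_inbreeding(sim$pedigree, s), numeric(1)))

  manifest <- list(
    version = as.character(utils::packageVersion("cscmsieve")),
    seed = config$seed,
    config = config[setdiff(names(config), "build")],
    n_variants = nrow(cohort$variants),
    n_samples = nrow(cohort$samples),
    funnel_counts = lapply(funnels, function(f)
      stats::setNames(f$funnel$n, f$funnel$stage)),
    n_candidates = nrow(candidates),
    n_segments = nrow(segs),
    n_aneuploidy = nrow(aneu),
    association_threshold = attr(assoc, "threshold"),
    n_significant = sum(assoc$significant, na.rm = TRUE),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))

  out <- list(manifest = manifest, candidates = candidates,
              funnels = funnels, association = assoc, roh = roh,
              shared_roh = shared, segments = segs, aneuploidy = aneu,
              pedigree_f = ped_f, truth = sim$truth)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(cohort, file.path(outdir, "cohort.vcf"))
    write_ped(sim$pedigree, file.path(outdir, "pedigree.ped"))
    utils::write.table(sim$truth, file.path(outdir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in c("candidates", "segments", "aneuploidy", "shared_roh"))
      utils::write.table(out[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out$manifest$outdir <- outdir
  }
  out
}

#' Descriptive statistics of a case series (per breed)
#'
#' Per-breed mean, SD, min, max and n for body weight and gestation age.
#' Missing values are excluded; the SD uses divisor n (population form),
#' the convention under which the transcribed case-series fixture
#' reproduces its printed birth-weight summary. Raw (unrounded) values are
#' returned; round for display.
#'
#' @param case_table data.frame as returned by [read_case_table()].
#' @return data.frame, one row per breed x measure, with `n`, `mean`, `sd`,
#'   `min`, `max` (all `NA` with `n = 0` when a field is entirely missing).
#' @export
summarize_case_table <- function(case_table) {
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  rows <- list()
  for (breed in unique(case_table$breed)) {
    sub <- case_table[case_table$breed == breed, ]
    for (measure in c("bw_kg", "ga_days")) {
      x <- sub[[measure]]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1]] <- if (length(x) == 0)
        data.frame(breed = breed, measure = measure, n = 0L, mean = NA_real_,
                   sd = NA_real_, min = NA_real_, max = NA_real_)
      else
        data.frame(breed = breed, measure = measure, n = length(x),
                   mean = mean(x), sd = sd_pop(x), min = min(x),
                   max = max(x))
    }
  }
  do.call(rbind, rows)
}
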