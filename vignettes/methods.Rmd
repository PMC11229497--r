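---
title: "Models and methods behind cscmsieve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cscmsieve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscmsieve)
```

`cscmsieve` packages the inference a rare-disease sequencing study of a
livestock case series performs after variant calling: inheritance-scenario
variant filtering, coding-consequence annotation, case/control
association, homozygosity mapping, read-depth karyotyping and pedigree
analysis, all exercised end to end against a synthetic cohort generator
with a recorded truth set. This vignette explains the models, the
parameters that matter, and the design decisions, in that order.

## The three inheritance scenarios

The genetic architecture of a lethal congenital syndrome in a managed
dairy population admits three hypotheses, each of which maps onto a
genotype-predicate filter over a cohort of affected calves (sequenced as
case-parent trios, case-parent duos or solo cases), a first-pass control
cohort, and a wider "global" control cohort:

1. **Shared recessive** — one breed-specific allele homozygous in *every*
   case. `filter_shared_recessive()` keeps variants homozygous-alternate
   in all cases, protein-changing, and entirely absent from controls.
2. **Per-case recessive** — distinct recessive alleles in individual
   cases. `filter_case_recessive()` keeps variants homozygous in the
   case, with every *sequenced* parent heterozygous (an obligate-carrier
   constraint; for duos only the sequenced parent is constrained, the
   strictest check available), private against the first-pass cohort,
   and without homozygotes in the global cohort. Heterozygous carriers in
   the global cohort are tolerated — a rare recessive allele drifting
   through a breed is expected to show a handful of carriers — and their
   count is reported alongside each candidate.
3. **Dominant de novo** — a spontaneous mutation in one case.
   `filter_denovo_dominant()` keeps variants heterozygous in the case and
   absent from the sequenced parents and every control, the classical
   trio de novo predicate.

Two cohort passes are deliberately distinct: *privacy* (no copy of the
allele at all) is enforced against the first-pass cohort, while the wider
global cohort only disqualifies homozygotes for recessive candidates.
Cohort membership is explicit in every call — nothing is inferred from
sample roles — because studies of this kind accumulate overlapping
control panels of different sizes, and the analysis must state which
panel served which purpose.

"Protein-changing" means consequence class in missense, stop gained/lost,
start lost, frameshift, in-frame indel, or the splice-region placeholder;
synonymous and non-coding variants are excluded. Missing genotypes are
conservative by default: a missing call is incompatible with "homozygous
in the case" and with "absent in controls" (`strict_missing = TRUE`).
Each filter ends with a callability stage — at least 90% non-missing
genotypes across the cohort — a programmatic stand-in for the manual
alignment inspection that studies use to discard recurrent artefacts.

## Consequence annotation

Gene models are ordered CDS segments plus the strand-corrected coding
sequence. Genomic-to-cDNA mapping is a cumulative offset walk across
segments (reversed on the minus strand, with allele complementation); the
mapping and its inverse are bijective over the CDS, which a property test
verifies. The codon containing coding position $p$ is
$\lceil p/3 \rceil$; an SNV is annotated by translating its codon before
and after substitution under the standard genetic code. For indels, a net
length change not divisible by 3 is a frameshift, and the first affected
codon of an insertion after coding position $p$ is
$\lceil (p+1)/3 \rceil$ — the codon containing the first changed base.
Labels are *HGVS-like*, deterministic and regenerable from the call's
fields (`c.58G>T`, `p.Gly20Trp`, `c.10773dupC`, `p.Ser3592fs`); full
HGVS normalization (3'-shifting of duplications and the rarer edge cases)
is out of scope. The arithmetic rules are validated against an
independent oracle that mutates the entire coding sequence and locates
the first changed codon by string comparison, over ~1,000 random models
and variants.

External deleteriousness predictions and pLI scores are pass-through
annotation columns only, never computed.

## Association, relatedness and homozygosity

`allelic_association()` tests each biallelic site's 2×2 allele-count
table (case alt/ref vs control alt/ref) with a two-sided Fisher exact
test, dropping missing genotypes per site. Fisher was chosen over the
asymptotic allelic chi-square because case series of this kind are tiny
(around a dozen cases); the exact test is correct at any count. The
genome-wide threshold is plain Bonferroni, $\alpha/n_{tests}$ (0.05 over
~1.56×10⁷ sites gives the familiar 3.2×10⁻⁹ order); no genomic-control
or mixed-model correction is applied, matching the simple design the
filter-based analysis accompanies.

Controls are pruned of close relatives before testing:
`pairwise_relatedness()` implements the method-of-moments IBD estimator
(the PI-HAT analogue): per-site allele frequencies give the expected
identity-by-state distribution under each IBD state, observed IBS counts
are inverted into estimated $P(\text{IBD}=k)$, and the statistic is
$P(2) + P(1)/2$, clamped to $[0,1]$. `prune_related()` then greedily
removes the sample in the most pairs at or above 0.5 (ties broken by id
order) until none remain.

`detect_roh()` defines a run of homozygosity as an interval of SNPs,
*maximal under inclusion*, that starts and ends on homozygous calls,
contains at most `max_het` heterozygous calls (default 1), has no
inter-SNP gap over `max_gap_kb` (250), spans at least `min_kb` (500) and
contains at least `min_snps` (20). These are consecutive-run parameters
in the detectRUNS tradition; the maximal-interval semantics makes the
scanner exactly reproducible by an $O(n^2)$ brute-force enumeration,
which the test suite runs on random inputs. `shared_homozygosity()`
unions runs per case, then sweeps breakpoints to report maximal constant-
coverage intervals covered by at least `min_cases` cases.

## Read-depth karyotyping

Depth is consumed as bedcov-style per-window read counts at two window
sizes (default 10 kb and 200 kb). `normalize_depth()` divides by the
genome-wide **median** window count: at a realistic chromosome count the
median and mean coincide, but on the package's deliberately small
synthetic genome a whole-chromosome trisomy is a third of all windows and
would drag a mean-based baseline off the diploid level, so the median is
the right estimator of "normal" coverage in both regimes. Expected
ratios are then 1.0 (diploid), 0.5 (heterozygous deletion), 1.5
(trisomy).

`call_segments()` first classifies whole chromosomes: a chromosome median
ratio below 0.7 or above 1.3 is a monosomy/trisomy call, and such
chromosomes are excluded from segment scanning. Remaining windows are
segmented by run length: at least 3 consecutive 200 kb windows below 0.7
(loss) or above 1.3 (gain). The thresholds sit midway between the
copy-number expectations minus a noise margin; the minimum run suppresses
single-window noise. Breakpoints are then refined on the 10 kb profile by
a least-squares two-mean step fit in a flank around each coarse boundary;
a refinement is accepted only when the fitted step height is at least
0.2 (half the distance between adjacent copy-number expectations),
otherwise the original boundary is kept — this is what "no improvement"
means for flat data. Reported sizes use the convention
$(end - start)/10^6$ rounded half-up to 2 decimals, which reproduces
printed Mb sizes computed from breakpoint coordinates; the 1 bp
difference against an inclusive convention is below rounding resolution.

Copy-neutral events (inversions, balanced translocations) leave no depth
signal and are out of scope — their breakpoints, once known from
read-level evidence, can still be fed to `interval_size_mb()` and
`interval_overlap()` for reporting. GC-bias correction and mappability
masks are likewise out of scope; the synthetic data contain neither
artefact.

## Pedigree analysis

Wright's inbreeding coefficient is computed by explicit path counting:
$F_X = \sum_A \sum_{(p_1,p_2)} (1/2)^{n_1+n_2+1}(1+F_A)$ over common
ancestors $A$ of the parents and ancestor-disjoint path pairs, with
$F_A$ recursive and founders at 0. Unknown parents are unique non-inbred
founders. Path enumeration is exponential in principle but trivial at
the pedigree sizes involved; the tabular (additive-relationship) method
is implemented independently (`additive_relationship()`) and the two
agree to 1e-12 on random pedigrees, which is an acceptance property.

`trace_carriers()` intersects the ancestor closures of all labeled
carriers and reduces the common set to its most recent members (no
proper descendant also common) — the best-supported founder candidates,
since any earlier ancestor is only implicated transitively. Carriers
whose every descent path to every candidate passes through a confirmed
non-carrier are flagged as genotype inconsistencies (suggesting a second
origin, a de novo event, or pedigree error). Tracing depth is unlimited
by default; "closely related" in loop detection is operationalized as a
common ancestor within 3 generations, matching the three-generation base
pedigrees such studies obtain from herd databases.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions the package is validated under:

* genome: 3 chromosomes × 10 Mb (`synthetic_build()`); full-genome scale
  is explicitly not emulated so that an end-to-end run takes seconds;
* 20,000 background biallelic SNVs, per-site Hardy-Weinberg genotypes
  with MAF ~ Uniform(0.15, 0.5). The 0.15 floor makes every background
  polymorphism carry at least one allele copy among 50 controls with
  probability $1 - 0.85^{100} \approx 1 - 9\times10^{-8}$ — the
  desk-scale analogue of "private against a thousand-genome cohort",
  which is what lets planted-event recovery demand *zero* false
  candidates;
* families: one trio, one duo, one solo by default; parental genotypes
  are transmitted Mendelianly to cases, and unsequenced parents of
  duo/solo designs exist as latent genomes;
* cohorts: 50 controls (first pass) plus 20 "global-extra" samples; the
  two nested sets model the first-pass and global control panels, and
  planted heterozygous carriers (12 for the trio recessive, 7 for the
  solo recessive, 0 for the de novo) are placed in the global stratum;
* depth: window read counts are negative-binomial with mean
  $coverage \times window/read\_length \times (CN/2)$ at 20× coverage,
  150 bp reads, dispersion 0.005. The NB (not Poisson) choice emulates
  the overdispersion of real libraries; the window-count coefficient of
  variation is $\sqrt{1/\mu + \phi}$, so $\phi = 0.005$ gives the 5-10%
  window-to-window variability of a well-behaved genome, avoiding
  over-optimistic CNV tests while keeping copy-number states separable;
* planted events (one per class by default): trio recessive missense,
  solo recessive missense, de novo frameshift duplication, two
  overlapping heterozygous Mb-scale deletions on one chromosome in two
  different cases, and a whole-chromosome trisomy. Planted coding
  variants are placed at real coding positions of packaged synthetic
  gene models and annotated by the package's own annotator, so their
  consequence class is computed, not asserted.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: linkage disequilibrium and
recombination structure, population stratification, sequencing artefacts
and mappability-driven depth bias, multi-allelic sites and genotyping
error. The filters' zero-false-positive behaviour on synthetic cohorts
reflects idealized genotypes; on real data the callability stage and
manual review carry the corresponding burden.

## Numerical and reproducibility choices

* Genotypes are coded 0/1/2/NA; all internal coordinates are 1-based
  inclusive, with BED-dialect depth tables converted exactly once at I/O.
* Multi-allelic VCF records are rejected by default (`"split"`
  decomposes them); the analysis itself is biallelic throughout.
* One seed drives every generator; identical configuration yields
  byte-identical VCF/TSV/manifest outputs, which the suite asserts.
* Case-series descriptive statistics use the population (divisor-$n$)
  standard deviation; on the packaged transcribed case table this
  reproduces the printed birth-weight summary (mean 30.6, SD 3.3) and
  gestation-age mean (281), while the printed gestation-age SD of 8.5 is
  not reproducible from the tabulated Holstein values under any single
  convention (they give 8.44; including the crossbred case gives 8.47
  but shifts the mean to 280) — the discrepancy is documented rather
  than fitted.
* Problem sizes in the test suite (20 recovery seeds at the default
  conditions; 100 seeds for the type-I-error and breakpoint-precision
  properties; oracle sweeps over all 2×2 tables with margins ≤ 30) were
  chosen as the package's own validation budget: large enough that the
  binomial uncertainty on a ≥95% success criterion is well below the
  margin, small enough that the suite runs in a couple of minutes.

## Known limitations

Compound heterozygotes and X-linked models are not considered (matching
the scenario set the package implements); imputation and phasing are out
of scope; the ROH scanner assumes reasonably dense, sorted sites and
drops missing genotypes rather than modeling them; breakpoint refinement
assumes a single step per boundary within the flank; and the carrier
tracer reports *candidates*, not proof — a candidate founder may itself
have inherited the allele from an unrecorded ancestor.
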