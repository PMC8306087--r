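---
title: "Homozygosity mapping of recessive loci: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homozygosity mapping of recessive loci: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohmap)
```

This vignette documents the statistical models behind `rohmap`, the
parameters that matter, and the design decisions taken where the
methodology left genuine choices open.  It is the package's record of
*why* things are the way they are; the README shows *how* to run them.

## The mapping strategy

An autosomal-recessive disease allele in an inbred population is mapped
by combining two signals that a cohort of affected and unaffected
individuals carries jointly:

* an **association signal** — affected individuals are homozygous for
  the risk haplotype, so nearby SNPs separate cases from controls once
  the strong family structure of such cohorts is absorbed by a mixed
  model; and
* an **autozygosity signal** — affected individuals share a long run of
  homozygosity (ROH) around the locus, reflecting recent identity by
  descent, while unaffected individuals show only the population's
  background autozygosity there.

The intersection of the association peak and the case-specific ROH
region defines a candidate interval; within it, a recessive segregation
filter plus population-frequency and deleteriousness filters reduce
thousands of variants to a handful of candidates, which are then scored
in an independent validation cohort with contingency statistics.

## Quality control and inbreeding

`qc_filter()` removes variants with minor allele frequency at or below
`maf_min` (default 0.05; the boundary is excluded because the rule is
"MAF strictly greater than the cutoff"), variants with missing-call
rate above 0.1, then samples with missing rate above 0.1 — in that
order, so a badly typed variant does not condemn the samples carrying
it.  For sequencing data, `site_quality_filter()` keeps sites with
read depth ≥ 4 and calling quality ≥ 20, both boundaries inclusive on
the keep side ("fewer than 4 reads" removes only depth ≤ 3).

The inbreeding coefficient is the homozygote-excess (method-of-moments)
estimator over the `m` variants called in a sample:

$$F = \frac{O - E}{m - E}, \qquad
  E = \sum_i \left(1 - 2 p_i (1-p_i) \tfrac{n_i}{n_i-1}\right),$$

with allele frequencies estimated from the cohort and the
`n/(n−1)` small-sample correction on expected heterozygosity — the
convention of the standard genotype-QC toolchain, kept so the formula
is testable exactly as stated.  Frequencies default to all samples;
`freq_samples` restricts them (e.g. to controls) because the choice is
a genuine degree of freedom in small case-enriched cohorts.

## The mixed-model scan

Case/control status is analysed as a quantitative 0/1 trait under

$$y = W\alpha + x\beta + g + \varepsilon,\qquad
  g \sim N(0, \lambda \tau^{-1} G),\quad
  \varepsilon \sim N(0, \tau^{-1} I),$$

where `G` is the standardized genomic relationship matrix (missing
dosages imputed to `2p`; monomorphic variants skipped because they
cannot be standardized).  A linear, not logistic, mixed model is used
deliberately: with near-complete penetrance and strong relatedness the
linear model's Wald test is the field's standard workhorse for this
design.

`λ` is estimated once by REML under the null model (no SNP) and reused
for every SNP — the "null-λ" economy that large-scale scan software
uses — with `per_snp_lambda = TRUE` available where exactness matters
more than speed.  The profiled restricted likelihood is evaluated in
the eigenbasis of `G` (one eigendecomposition per scan), maximized on
`log10 λ ∈ [−5, 5]` by a 21-point grid followed by Brent search on the
bracketing interval; the grid is retained in the result so optimality
is auditable.  Per-SNP effects are GLS estimates in the rotated basis;
the Wald statistic `β̂²/se²` is referred to `F(1, n − c − 1)`,
two-sided, and extreme tail probabilities are floored at the smallest
normal double so p-values stay within `(0, 1]`.  The scan filter
(MAF < 0.01 or missingness > 0.05 discarded) mirrors the default
filtering of the emulated association tool and is configurable.

The Bonferroni threshold is `−log10(α/m)` with `m` passed explicitly,
because which panel size to correct for (the merged panel or the
post-filter count) is itself a reporting convention.

## ROH detection

`call_roh()` implements the five-criterion sliding-window scheme:
window size 15 SNPs; minimum segment length 1 Mb; maximum inverse
density 100 kb/SNP; maximum inter-SNP gap 1 Mb; minimum window hit
rate 0.05 (a SNP qualifies when at least 5% of the fully-contained
windows covering it are homozygous — equality passes).  Decisions the
criterion list leaves open, and how they were fixed:

* the "minimum SNP count" is read as **both** the scanning-window size
  and the minimum SNPs per final segment (the standard algorithm has
  both parameters; they default to the same value and are
  independently configurable);
* windows tolerate 0 heterozygous and 1 missing call by default —
  stricter than the common 1-het allowance because 15-SNP windows are
  short and one het in 15 would be disproportionately permissive;
* windows truncated at chromosome ends are dropped, and hit-rate
  denominators count only fully-contained windows;
* a SNP with a missing call can sit inside a run; a heterozygous call
  always breaks one.

Intervals are 1-based closed internally and converted to BED's 0-based
half-open convention only on export.

`autozygosity_track()` turns per-sample segments into per-position
coverage fractions for the affected and unaffected groups, and
`contrast_candidate_regions()` reports maximal intervals with case
fraction ≥ 0.7 and control fraction ≤ 0.2 at every SNP, merging
near-adjacent intervals and optionally padding (`pad_bp`) — padding is
an explicit parameter because widening the reported region beyond the
strict threshold run is a judgment call in the original procedure.

## The variant-filtering funnel

`run_funnel()` applies, inside a candidate region: homozygosity in all
non-excluded cases; the segregation test (no control homozygous for
the candidate allele — the phrase "homozygous for the alternative
allele" in the source description of controls is treated as an obvious
slip for *reference*, since the reported control genotype counts force
that reading); the reference-panel frequency cutoff (AF < 0.05, with
panel-absent variants passing — the strategy must be able to retain a
novel variant); then consequence restriction to exonic and missense;
then the deleteriousness consensus.  Missing control genotypes are
ignored by default (small cohorts), with a strict mode.  Structural
variants flow through segregation and frequency but skip the
score-based stages.  The per-tool deleterious calls are SIFT ≤ 0.05,
PROVEAN ≤ −2.5, PANTHER-PSEP ≥ 0.5, PolyPhen-2 ≥ 0.5, combined with
rule `all` by default; the PROVEAN cutoff follows the tool's
conventional deleterious threshold (−2.5) rather than the −0.25 that
appears in one table header of the source material, and is fully
configurable.  "Homozygous" in the funnel's first stage means
homozygous in *all* non-excluded cases (an `"any"` variant exists
behind a flag).

## Contingency statistics

Relative risk compares affection proportions between two genotype
rows; its p-value is the 2×2 chi-square with the Yates continuity
correction (`|ad − bc| − n/2`), the convention that reproduces the
published heterozygote p-values to the printed precision, where the
uncorrected statistic does not.  Exact tests go through the
conditional (Fisher / Freeman–Halton) formulation; a seeded Monte
Carlo mode covers tables too large to enumerate.  Two-sided exact
p-values use the probability-at-most-observed rule.  Reports round
relative risks to 2 decimals and percentages to integers; machine
output keeps full precision.

## The synthetic-data generator

`simulate_study()` emulates the *kind* of data this analysis consumes:
a small closed breed with mean homozygote-excess inbreeding around
0.5, an affected kindred sharing a long ROH that harbours a recessive,
fully penetrant causal variant, an array-density and a
sequencing-density genotype panel, and a VEP-style annotation table
with pathogenicity scores and reference-panel genotype counts.

Two layers of inbreeding are simulated separately because they have
different footprints:

* **Drift phase** — 4 sublines ("kennels") of 100 individuals mate
  randomly within line for 150 non-overlapping generations.  This
  yields strong homozygote excess against pooled cohort frequencies
  (line divergence plus within-line coalescence) whose autozygous
  tracts are *old and short*, so they mostly fall below the 1 Mb ROH
  detection scale: controls show high F but low per-locus ROH
  coverage, which is exactly the configuration observed in real inbred
  breeds.
* **Case kindred** — two members of one line found a two-tier full-sib
  kindred whose final sibship aggregates several litters of one mating
  pair.  The causal allele enters as a **single copy planted on one
  kindred-founder haplotype**, so affected offspring are autozygous
  for that haplotype and share a *recent, multi-Mb* ROH around the
  causal position (4 Mb on a 20 Mb chromosome).

Meioses draw crossovers as a Poisson process on the physical map
(Haldane, no interference — interference is irrelevant at the Mb
scales examined).  The drift phase runs in compiled code
(`src/drift.cpp`); the R-level `gene_drop()` serves arbitrary
pedigrees and is the reference for small cases.

The genetic-map density is 10 cM/Mb.  This is the one parameter set
for mechanism rather than realism: the separation between "old, short"
and "recent, long" tracts depends on the product of tract age and map
length, and at a literal 1 cM/Mb the drift phase would need thousands
of simulated generations to push background tracts below the ROH
scale.  Compressing genome-scale map length into the single 20 Mb
chromosome achieves the same tract-length contrast at a tractable
number of generations; all downstream geometry (ROH thresholds,
region sizes, SNP densities) is unchanged.

Ascertainment mirrors how such studies actually sample: kindred gene
drops are redrawn until the intermediate mating pairs carry the
planted allele and at least `min_cases` (default 9) sibship members
are affected — a family is studied *because* it segregates the
disease.  The emitted cohort is the affected sibship members plus 36
controls drawn evenly across the lines (~45–55 samples).  Phenotypes
follow `penetrance` (default 1) and `phenocopy_rate` (default 0);
phenocopies are flagged in an attribute that the analysis stages never
see, so the case-exclusion mechanism is testable without leaking the
label.

The annotation table gives the causal variant a missense consequence,
a deleterious score consensus (SIFT 0, PROVEAN −6.775, PANTHER-PSEP
0.89, PolyPhen-2 0.999) and no reference-panel record (a novel
variant); five "decoy" variants are planted in complete LD with the
causal allele (same carrier haplotype) but made *common* in the
722-genome reference panel, so they segregate perfectly yet must be
removed at the frequency stage — the failure mode that
population-frequency filtering exists to catch.  All other variants
receive benign annotations and panel counts drawn from their founder
frequencies.

What the generator does **not** emulate: coalescent founder history
(founder haplotypes are independent Bernoulli draws, so there is no
breed-level LD beyond what drift creates), genotyping error beyond
uniform missingness, X-linked inheritance, multi-chromosome genomes
(repeat the simulation independently per chromosome), and selection.
Passing tests on this generator therefore demonstrate that the
*pipeline logic* recovers a planted recessive locus under realistic
inbreeding geometry — not that any particular real dataset would yield
the same funnel counts.

## Numerical choices and degenerate inputs

* PCA uses SVD of the standardized dosage matrix (missing values
  imputed to the variant mean for the decomposition only, never
  written back); component signs are fixed by making the
  largest-magnitude loading positive.  `k` beyond the numerical rank
  is an error.
* GRM/PCA standardization skips monomorphic variants with a warning.
* The REML search reports an error advising a diagonal jitter when the
  GRM has eigenvalues below −10⁻⁶ (relative); small negative
  eigenvalues from numerical noise are clipped to zero.
* SNPs with zero variance after projection are flagged and given
  p = 1 rather than dropped, so result tables stay aligned with the
  input variant list.
* Ties at filter boundaries follow the stated conventions: QC MAF
  boundary excluded, depth/quality boundaries included, ROH hit-rate
  boundary included.
* PED reference alleles without an allele table use the majority
  allele, ties broken lexicographically — deterministic and
  documented, since PED text carries no reference orientation.
* The depth filter applies per site; a per-sample reading of the
  criterion is left to the `SiteQuality` columns a caller can supply,
  since multi-sample callers report depth site-wise.

## Problem sizes

The shipped tests exercise the pipeline at sizes chosen to keep the
full suite in the low minutes on one core while leaving every
mechanism active: 3,000-variant/600-SNP panels on one 20 Mb
chromosome, cohorts of ~45–55, 100 simulation replicates for the
recovery and calibration properties, a 200 × 10,000 null scan for
type-I error, and exhaustive ROH-oracle enumeration over all genotype
strings up to length 6 (alphabet 0/1/2/missing) with a 3-SNP window.
The acceptance script reports recovery rates over 20 replicate studies
per run.

## Known limitations

* The LMM treats binary status linearly; effect sizes are on the
  0/1 scale and attenuate under incomplete penetrance.
* The candidate-region contrast uses fixed thresholds (0.7/0.2); very
  small groups quantize coverage fractions coarsely, which is why the
  simulated cohorts keep ≥ 30 controls.
* Exact R×C enumeration is delegated to the standard conditional
  network algorithm; degenerate margins error out rather than being
  patched silently.
* The funnel assumes bi-allelic dosage coding throughout; split
  multi-allelic records are handled as separate variants sharing a
  position.
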