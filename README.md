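# rohmap

Homozygosity mapping of autosomal-recessive disease loci in inbred
populations.

## The problem

In closed, inbred populations — dog breeds are the canonical case — a
recessive disease allele spreads silently through carriers and surfaces
when a recent consanguineous mating makes it homozygous.  Affected
individuals then carry two copies of one ancestral haplotype, so the
disease locus sits inside a long **run of homozygosity (ROH)** shared by
cases and absent (as a shared run) from controls.  `rohmap` implements
the full mapping workflow around that signal:

1. **Genotype QC** — minor allele frequency, per-variant and per-sample
   missingness; site-level read-depth/quality filters for sequencing
   data.
2. **Population structure** — homozygote-excess inbreeding coefficients
   `F = (O − E)/(m − E)` with the small-sample heterozygosity correction
   `E_i = 1 − 2p_i q_i · n/(n−1)`; PCA of standardized dosages; the
   standardized genomic relationship matrix
   `G = (1/m) Σ_i (x_i − 2p_i)(x_i − 2p_i)ᵀ / (2p_i q_i)`.
3. **Mixed-model association** — the univariate LMM
   `y = Wα + xβ + g + ε`, `g ~ N(0, λτ⁻¹G)`, `ε ~ N(0, τ⁻¹I)`, with λ
   estimated by REML in the eigenbasis of `G`, per-SNP Wald tests
   `β̂²/se² ~ F(1, n−c−1)`, Bonferroni threshold `−log₁₀(α/m)`, and
   QQ/inflation diagnostics.
4. **ROH detection and contrast** — PLINK-style sliding-window calling
   (window size, minimum length, maximum inverse density, maximum gap,
   window hit rate), per-position case/control autozygosity tracks, and
   candidate-region delineation where case autozygosity is high and
   control autozygosity low.
5. **Recessive variant filtering** — the candidate-variant funnel:
   homozygous in all (non-excluded) cases, never homozygous in
   controls, rare in an external reference panel (novel variants pass),
   exonic, missense, and deleterious by consensus of SIFT, PROVEAN,
   PANTHER-PSEP and PolyPhen-2 scores.
6. **Validation statistics** — genotype-by-status contingency tables,
   relative risks `RR = [a/(a+b)]/[c/(c+d)]` with Yates-corrected
   chi-square p-values, exact (Fisher / Freeman–Halton) tests, allele
   frequencies from genotype counts, and cohort percentages.

A **gene-drop simulator** (`simulate_study()`) generates fully synthetic
study data — a drifted multi-line breed population plus a recent case
kindred with a planted recessive causal variant, emitted as VCF,
PED/MAP, sample sheet and annotation tables — so the whole pipeline is
testable without any external data.  See the methods vignette
(`vignettes/homozygosity-mapping.Rmd`) for the model and all parameter
choices.

## Worked example

```r
library(rohmap)

sim <- simulate_study(sim_config(seed = 1))
sim$wgs
#> <genotype_matrix> 46 samples (10 affected, 36 unaffected) x 3000 variants on 1 chromosome(s)

qc <- qc_filter(sim$wgs)
f  <- inbreeding_f(qc$gm)
mean(f$F)                                   # 0.49 — a highly inbred cohort
scan <- lmm_scan(qc$gm)
scan$results[which.min(scan$results$p), c("chrom", "pos")]
#> chr17 3985339                              # strongest association near 4 Mb

seg <- call_roh(sim$wgs)
tr  <- autozygosity_track(seg, sim$wgs)
contrast_candidate_regions(tr)
#>   chrom start_bp  end_bp mean_case_autozygosity mean_control_autozygosity
#> 1 chr17   686439 5964679              0.826                    0.084

fun <- run_funnel(sim$annotation, sim$wgs,
                  list(chrom = "chr17", start_bp = 686439, end_bp = 5964679))
fun$funnel
#> in_region homozygous_in_cases case_private rare_in_panel exonic missense deleterious
#>       793                 140            7             1      1        1           1
fun$retained[, c("pos", "gene", "consequence", "sift", "provean")]
#>     4000000 TPO_like missense 0 -6.775     # the planted causal variant
```

The funnel narrows 793 region variants to exactly the planted missense
variant: homozygous in every case, absent as a homozygote from
controls, missing from the 722-genome reference panel, and deleterious
by all four score consensus.  Validation-cohort statistics work from
plain genotype counts:

```r
tab <- genotype_count_table(aa = c(45, 9), ar = c(11, 56), rr = c(3, 58))
relative_risk(tab, "AA", "RR")$rr           # 16.94
fisher_exact(tab)                           # 8.0e-22
```

An end-to-end run (`run_pipeline()`, or `inst/cli/rohmap.R run
--config cfg.yaml`) chains all stages from one YAML configuration and
writes per-stage TSVs plus a JSON run report.

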