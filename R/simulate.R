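#' Simulation configuration
#'
#' Parameters of the gene-drop simulator.  The default `"breed_kindred"`
#' scheme emulates a closed breed segregating a fully penetrant
#' recessive disease.  Two layers of inbreeding are generated
#' separately, mirroring real inbred breeds: (1) a drift phase --
#' several small sublines ("kennels") mating randomly within line for
#' many generations -- produces breed-level homozygote excess (high
#' method-of-moments F against pooled cohort allele frequencies) whose
#' autozygous tracts are old and therefore mostly too short to be
#' called as ROH; (2) a recent case kindred -- repeated full-sib
#' matings started from two members of one line, with the causal allele
#' planted as a single copy on one kindred-founder haplotype --
#' produces affected offspring autozygous for a long, recent ROH around
#' the causal site.  Affected sibship members plus controls sampled
#' across all lines form the study cohort.
#'
#' @param mating_scheme `"breed_kindred"` (default) or one of the simple
#'   line schemes `"full_sib"`, `"half_sib"`, `"small_sire_pool"` used
#'   for structural testing.
#' @param n_founders founders per drift line (default `line_size`; for
#'   line schemes, an even number >= 2).
#' @param n_lines sublines in the drift phase (default 4).
#' @param line_size population size per line and generation
#'   (default 100).
#' @param n_hist_generations drift generations (default 150).
#' @param n_generations generations of a simple line scheme (ignored by
#'   `"breed_kindred"`; default 4).
#' @param kindred_generations tiers of the recent case kindred below
#'   its two founders (default 2: children, then the final sibship).
#' @param n_offspring_final size of the final kindred sibship
#'   (default 48; several litters of one mating pair).
#' @param n_outside_controls individuals sampled evenly across the
#'   drift lines as controls (default 36).
#' @param sire_pool_size sires per generation under
#'   `"small_sire_pool"` (default 2).
#' @param chromosome chromosome label (default `"chr17"`).
#' @param chromosome_length_bp simulated chromosome length
#'   (default 20 Mb).
#' @param cm_per_mb genetic-map density in cM/Mb (default 10; chosen so
#'   drift-phase autozygosity decays below the 1 Mb ROH scale within a
#'   tractable number of simulated generations while the recent kindred
#'   ROH stays several Mb long -- see the methods vignette).
#' @param n_array_snps array-density panel size (default 600).
#' @param n_wgs_variants sequencing-density panel size (default 3000).
#' @param causal_position bp position of the planted recessive variant
#'   (default 4e6).
#' @param causal_founder_copies copies of the causal allele planted on
#'   kindred-founder haplotypes (default 1).
#' @param n_decoys common "decoy" variants planted on the same carrier
#'   haplotype (in complete LD with the causal allele) but given a high
#'   reference-panel allele frequency (default 5).
#' @param penetrance P(affected | homozygous alternative) (default 1).
#' @param phenocopy_rate P(affected | not homozygous alternative)
#'   (default 0).
#' @param founder_maf range of the uniform founder alternative-allele
#'   frequency distribution (default c(0.05, 0.5)).
#' @param missing_rate uniform genotype missingness applied to emitted
#'   panels (default 0).
#' @param min_cases ascertainment: kindred gene drops are redrawn until
#'   at least this many sibship members are affected (default 9).
#' @param max_tries maximum kindred redraws (default 500).
#' @param seed RNG seed; a fixed seed makes the whole simulation
#'   deterministic.
#' @return a `sim_config` list.
#' @export
sim_config <- function(mating_scheme = c("breed_kindred", "full_sib",
                                         "half_sib", "small_sire_pool"),
                       n_founders = NULL, n_lines = 4, line_size = 100,
                       n_hist_generations = 150, n_generations = 4,
                       kindred_generations = 2,
                       n_offspring_final = 48, n_outside_controls = 36,
                       sire_pool_size = 2,
                       chromosome = "chr17",
                       chromosome_length_bp = 2e7, cm_per_mb = 10,
                       n_array_snps = 600, n_wgs_variants = 3000,
                       causal_position = 4e6, causal_founder_copies = 1,
                       n_decoys = 5,
                       penetrance = 1, phenocopy_rate = 0,
                       founder_maf = c(0.05, 0.5),
                       missing_rate = 0,
                       min_cases = 9, max_tries = 500,
                       seed = 1) {
  mating_scheme <- match.arg(mating_scheme)
  if (is.null(n_founders))
    n_founders <- if (mating_scheme == "breed_kindred") line_size else 2L
  cfg <- as.list(environment())
  if (penetrance < 0 || penetrance > 1 || phenocopy_rate < 0 ||
      phenocopy_rate > 1)
    stop("penetrance and phenocopy_rate must lie in [0, 1]")
  if (causal_position < 1 || causal_position > chromosome_length_bp)
    stop("causal_position outside the chromosome")
  if (n_array_snps > n_wgs_variants)
    stop("n_array_snps may not exceed n_wgs_variants")
  if (n_founders < 2) stop("need at least 2 founders")
  if (mating_scheme != "breed_kindred" && n_founders %% 2)
    stop("line schemes need an even n_founders")
  if (mating_scheme == "breed_kindred" && line_size < 4)
    stop("line_size must be at least 4")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a line-scheme pedigree
#'
#' Builds the mating structure of the simple line schemes (`full_sib`,
#' `half_sib`, `small_sire_pool`): each generation is produced by the
#' leading members of the previous one, and the final generation has
#' `n_offspring_final` members.  These deterministic pedigrees are the
#' substrate for structural tests and for the classical inbreeding
#' recursion; the default study generator is [simulate_study()], which
#' builds its two-phase population internally.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `id`, `sire`, `dam`, `generation`
#'   (founders have `NA` parents), class `pedigree`.
#' @export
simulate_pedigree <- function(config) {
  n_f <- config$n_founders
  ped <- data.frame(id = paste0("F", seq_len(n_f)),
                    sire = NA_character_, dam = NA_character_,
                    generation = 0L, stringsAsFactors = FALSE)
  if (config$n_generations == 0) {
    class(ped) <- c("pedigree", "data.frame")
    return(ped)
  }
  scheme <- config$mating_scheme
  if (scheme == "breed_kindred")
    stop("simulate_pedigree builds line-scheme pedigrees; ",
         "use simulate_study() for the breed_kindred scheme")
  prev <- if (scheme == "full_sib") ped$id[1:2] else ped$id
  for (g in seq_len(config$n_generations)) {
    final <- g == config$n_generations
    n_kids <- if (final) config$n_offspring_final else
      switch(scheme, full_sib = 2L, half_sib = 3L,
             small_sire_pool = max(4L, 2L * config$sire_pool_size))
    ids <- paste0("G", g, "_", seq_len(n_kids))
    if (scheme == "full_sib") {
      if (length(prev) < 2) stop("full_sib scheme needs >= 2 per generation")
      sires <- rep(prev[1], n_kids)
      dams <- rep(prev[2], n_kids)
    } else if (scheme == "half_sib") {
      if (length(prev) < 3) stop("half_sib scheme needs >= 3 per generation")
      sires <- rep(prev[1], n_kids)
      dams <- prev[1 + (seq_len(n_kids) - 1L) %% (length(prev) - 1L) + 1L]
    } else {
      k <- min(config$sire_pool_size, length(prev) - 1L)
      if (k < 1) stop("small_sire_pool scheme needs >= 2 per generation")
      sires <- prev[1 + (seq_len(n_kids) - 1L) %% k]
      dams <- prev[k + 1 + (seq_len(n_kids) - 1L) %% (length(prev) - k)]
    }
    ped <- rbind(ped, data.frame(id = ids, sire = sires, dam = dams,
                                 generation = g, stringsAsFactors = FALSE))
    prev <- ids
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Pedigree-expected inbreeding coefficients
#'
#' Classical tabular (numerator-relationship) recursion: F of an
#' individual is half the additive relationship between its parents.
#' Serves as the analytic reference for the realized inbreeding produced
#' by gene drop; for a repeated full-sib line it reproduces
#' F_t = (1 + 2 F_(t-1) + F_(t-2)) / 4.
#'
#' @param pedigree a pedigree data.frame (`id`, `sire`, `dam`), parents
#'   before offspring.
#' @return named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  n <- nrow(pedigree)
  A <- matrix(0, n, n, dimnames = list(pedigree$id, pedigree$id))
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (!is.na(si[i]) && !is.na(di[i]))
      0.5 * A[si[i], di[i]] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0
      if (!is.na(si[i])) a <- a + 0.5 * A[j, si[i]]
      if (!is.na(di[i])) a <- a + 0.5 * A[j, di[i]]
      A[i, j] <- A[j, i] <- a
    }
  }
  diag(A) - 1
}

# variant positions: evenly spaced, the causal site replacing its nearest
# neighbour so it is always typed
sim_positions <- function(config) {
  m <- config$n_wgs_variants
  pos <- round(seq(1, config$chromosome_length_bp, length.out = m + 2))
  pos <- pos[2:(m + 1)]
  pos[which.min(abs(pos - config$causal_position))] <- config$causal_position
  sort(unique(as.integer(pos)))
}

# one meiosis: crossovers as a Poisson process (Haldane, no interference)
meiosis <- function(h1, h2, positions, cm_per_mb, length_bp) {
  n_x <- stats::rpois(1, cm_per_mb * length_bp / 1e8)
  start <- stats::rbinom(1, 1, 0.5)
  if (n_x == 0) return(if (start == 0) h1 else h2)
  xo <- sort(stats::runif(n_x, 1, length_bp))
  seg <- findInterval(positions, xo)       # 0..n_x segments
  pick <- (start + seg) %% 2
  ifelse(pick == 0, h1, h2)
}

#' Drop founder haplotypes through a pedigree
#'
#' Transmits haplotypes down a pedigree with recombination modelled as a
#' Poisson crossover process (Haldane map function, no interference).
#' Every transmitted haplotype is a mosaic of the parent's two.
#'
#' @param pedigree data.frame with `id`, `sire`, `dam` (parents before
#'   offspring; founders have `NA` parents).
#' @param founder_haps 2 * n_founders x m 0/1 matrix; the i-th founder
#'   in pedigree order owns rows 2i-1 and 2i.
#' @param positions variant bp positions.
#' @param cm_per_mb recombination rate.
#' @param length_bp chromosome length.
#' @return 2n x m 0/1 matrix of haplotypes; individual i of the pedigree
#'   owns rows 2i-1 and 2i.
#' @export
gene_drop <- function(pedigree, founder_haps, positions, cm_per_mb,
                      length_bp) {
  n <- nrow(pedigree)
  m <- length(positions)
  haps <- matrix(0L, 2L * n, m)
  si <- match(pedigree$sire, pedigree$id)
  di <- match(pedigree$dam, pedigree$id)
  fcount <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      haps[2L * i - 1L, ] <- founder_haps[2L * fcount + 1L, ]
      haps[2L * i, ] <- founder_haps[2L * fcount + 2L, ]
      fcount <- fcount + 1L
    } else {
      haps[2L * i - 1L, ] <- meiosis(haps[2L * si[i] - 1L, ],
                                     haps[2L * si[i], ], positions,
                                     cm_per_mb, length_bp)
      haps[2L * i, ] <- meiosis(haps[2L * di[i] - 1L, ],
                                haps[2L * di[i], ], positions,
                                cm_per_mb, length_bp)
    }
  }
  rownames(haps) <- paste0(rep(pedigree$id, each = 2), c("_h1", "_h2"))
  haps
}

# drift phase of one line: constant-size random mating, implemented in
# compiled code (src/drift.cpp); only the final generation is returned
drift_line <- function(n, generations, fhaps, positions, cm_per_mb,
                       length_bp) {
  .drift_line_cpp(as.integer(n), as.integer(generations), fhaps,
                  as.numeric(positions),
                  cm_per_mb * length_bp / 1e8, length_bp)
}

#' Assign affection status from causal-site dosage
#'
#' Homozygous-alternative individuals are affected with probability
#' `penetrance`; all others with probability `phenocopy_rate`.
#' Phenocopies (affected without the homozygous genotype) are flagged in
#' the `phenocopy` attribute so the exclusion mechanism can be tested
#' without leaking the label to the analysis stages.
#'
#' @param dosage_at_causal integer vector of dosages (0/1/2).
#' @param penetrance,phenocopy_rate probabilities.
#' @return character vector `"affected"`/`"unaffected"` with a logical
#'   `phenocopy` attribute.
#' @export
assign_phenotypes <- function(dosage_at_causal, penetrance = 1,
                              phenocopy_rate = 0) {
  stopifnot(all(dosage_at_causal %in% 0:2))
  hom <- dosage_at_causal == 2
  p <- ifelse(hom, penetrance, phenocopy_rate)
  affected <- stats::runif(length(p)) < p
  status <- ifelse(affected, "affected", "unaffected")
  attr(status, "phenocopy") <- affected & !hom
  status
}

consequence_levels <- c("intergenic", "intronic", "synonymous", "missense",
                        "other-exonic", "SV-deletion", "SV-insertion")

#' Emit genotype panels and the annotation table
#'
#' Converts cohort haplotypes into a sequencing-density genotype matrix,
#' an array-density subsample, and a variant annotation table emulating
#' a VEP-style consequence/score/reference-panel export.  The causal
#' variant is missense with a deleterious score consensus (SIFT 0,
#' PROVEAN -6.775, PANTHER-PSEP 0.89, PolyPhen-2 0.999) and is absent
#' from the reference panel; decoy variants are intronic with panel
#' allele frequency above 0.05; all other variants receive benign
#' annotations and panel genotype counts drawn from their founder
#' frequency in a 722-genome panel.
#'
#' @param haps cohort haplotype matrix (2n x m), sample i owning rows
#'   2i-1, 2i.
#' @param sample_ids,status per-sample metadata (length n).
#' @param positions variant bp positions.
#' @param founder_freq per-variant founder alternative-allele
#'   frequencies.
#' @param causal_idx,decoy_idx variant indices of the causal and decoy
#'   sites.
#' @param config a [sim_config()].
#' @return list with `wgs`, `array` (genotype matrices) and `annotation`
#'   (data.frame, one row per WGS variant, logical columns `causal` and
#'   `decoy`).
#' @export
emit_panels <- function(haps, sample_ids, status, positions,
                        founder_freq, causal_idx, decoy_idx, config) {
  n <- length(sample_ids)
  m <- length(positions)
  dosage <- haps[seq(1, 2 * n, by = 2), , drop = FALSE] +
    haps[seq(2, 2 * n, by = 2), , drop = FALSE]
  storage.mode(dosage) <- "integer"
  if (config$missing_rate > 0) {
    drop <- stats::runif(length(dosage)) < config$missing_rate
    dosage[drop] <- NA_integer_
  }
  ref <- rep("A", m); alt <- rep("G", m)
  variants <- data.frame(chrom = config$chromosome, pos = positions,
                         id = NA_character_, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_ids, status = status,
                        excluded = FALSE, stringsAsFactors = FALSE)
  wgs <- genotype_matrix(dosage, variants, samples)
  array_idx <- unique(round(seq(1, m, length.out = config$n_array_snps)))
  arr <- wgs[, array_idx]

  causal <- seq_len(m) == causal_idx
  decoy <- seq_len(m) %in% decoy_idx
  csq <- sample(consequence_levels[1:5], m, replace = TRUE,
                prob = c(0.60, 0.30, 0.05, 0.04, 0.01))
  csq[causal] <- "missense"
  csq[decoy] <- "intronic"
  sift <- ifelse(csq == "missense", stats::runif(m, 0.2, 1), NA_real_)
  provean <- ifelse(csq == "missense", stats::runif(m, -1, 1), NA_real_)
  panther <- ifelse(csq == "missense", stats::runif(m, 0, 0.4), NA_real_)
  polyphen <- ifelse(csq == "missense", stats::runif(m, 0, 0.4), NA_real_)
  sift[causal] <- 0; provean[causal] <- -6.775
  panther[causal] <- 0.89; polyphen[causal] <- 0.999

  panel_n <- 722L
  p <- founder_freq
  hom_alt <- stats::rbinom(m, panel_n, p^2)
  het <- stats::rbinom(m, panel_n - hom_alt, pmin(1, 2 * p * (1 - p)))
  hom_ref <- panel_n - hom_alt - het
  # decoys: common in the reference panel (AF > 0.05 by construction)
  pd <- stats::runif(m, 0.15, 0.45)
  hom_alt[decoy] <- stats::rbinom(sum(decoy), panel_n, pd[decoy]^2)
  het[decoy] <- stats::rbinom(sum(decoy), panel_n - hom_alt[decoy],
                              pmin(1, 2 * pd[decoy] * (1 - pd[decoy])))
  hom_ref[decoy] <- panel_n - hom_alt[decoy] - het[decoy]
  hom_alt[causal] <- NA; het[causal] <- NA; hom_ref[causal] <- NA

  annotation <- data.frame(
    chrom = config$chromosome, pos = positions, ref = ref, alt = alt,
    gene = ifelse(causal, "TPO_like",
                  ifelse(decoy, "EIPR1_like", NA_character_)),
    consequence = csq,
    aa_change = ifelse(causal, "686F>V", NA_character_),
    sift = sift, provean = provean, panther = panther,
    polyphen = polyphen,
    panel_hom_alt = hom_alt, panel_het = het, panel_hom_ref = hom_ref,
    causal = causal, decoy = decoy, stringsAsFactors = FALSE)
  annotation$panel_af <- panel_allele_freq(annotation)
  list(wgs = wgs, array = arr, annotation = annotation)
}

# the recent case kindred below two line members K1 x K2: tiers of four
# children, the first two of each tier parenting the next; the last tier
# is the final sibship
kindred_pedigree <- function(config, k1, k2) {
  ped <- data.frame(id = c(k1, k2), sire = NA_character_,
                    dam = NA_character_, generation = 0L,
                    stringsAsFactors = FALSE)
  prev <- c(k1, k2)
  for (t in seq_len(config$kindred_generations)) {
    final <- t == config$kindred_generations
    ids <- if (final) paste0("S", seq_len(config$n_offspring_final)) else
      paste0("K", t, "_", 1:4)
    ped <- rbind(ped, data.frame(id = ids, sire = prev[1], dam = prev[2],
                                 generation = t, stringsAsFactors = FALSE))
    prev <- ids
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Simulate a complete study dataset
#'
#' End-to-end generator under the `"breed_kindred"` scheme: multi-line
#' drift phase, planting of the causal (and decoy) alleles on one
#' kindred-founder haplotype, kindred gene drop, phenotype assignment,
#' and panel emission.  Kindred drops are redrawn (ascertainment,
#' emulating the sampling of a family known to segregate the disease)
#' until every intermediate mating pair carries the planted allele and
#' at least `min_cases` sibship members are affected.  The emitted
#' cohort is the affected sibship members plus `n_outside_controls`
#' individuals sampled evenly across the drift lines.  Fully
#' deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with elements `wgs`, `array`, `annotation`,
#'   `kindred` (the recent pedigree), `positions`, `causal_idx`,
#'   `decoy_idx`, `phenocopy`, `tries`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  if (config$mating_scheme != "breed_kindred")
    stop("simulate_study implements the breed_kindred scheme; ",
         "line schemes are built with simulate_pedigree + gene_drop")
  set.seed(config$seed)
  positions <- sim_positions(config)
  m <- length(positions)
  freq <- stats::runif(m, config$founder_maf[1], config$founder_maf[2])
  causal_idx <- which(positions == config$causal_position)
  near <- order(abs(positions - config$causal_position))
  decoy_idx <- setdiff(near, causal_idx)[seq_len(config$n_decoys)]
  special <- c(causal_idx, decoy_idx)

  n <- config$line_size
  lines <- vector("list", config$n_lines)
  for (l in seq_len(config$n_lines)) {
    fhaps <- matrix(stats::rbinom(2L * n * m, 1L, rep(freq, each = 2L * n)),
                    nrow = 2L * n, ncol = m)
    fhaps[, special] <- 0L
    lines[[l]] <- drift_line(n, config$n_hist_generations, fhaps,
                             positions, config$cm_per_mb,
                             config$chromosome_length_bp)
  }

  # kindred founders: the first two members of line 1; the causal and
  # decoy alleles enter the kindred as single copies on K1's first
  # haplotype
  kh <- lines[[1]][1:4, , drop = FALSE]
  k <- min(config$causal_founder_copies, 2L)
  kh[seq_len(k), special] <- 1L
  kped <- kindred_pedigree(config, "K_sire", "K_dam")
  sib_rows <- which(kped$generation == config$kindred_generations)
  pair_rows <- lapply(seq_len(config$kindred_generations - 1L), function(t)
    match(paste0("K", t, "_", 1:2), kped$id))
  for (try in seq_len(config$max_tries)) {
    khaps <- gene_drop(kped, kh, positions, config$cm_per_mb,
                       config$chromosome_length_bp)
    carriers <- vapply(unlist(pair_rows), function(r)
      any(khaps[c(2L * r - 1L, 2L * r), causal_idx] == 1L), logical(1))
    if (length(carriers) && !all(carriers)) next
    hr <- as.vector(rbind(2L * sib_rows - 1L, 2L * sib_rows))
    sib_h <- khaps[hr, , drop = FALSE]
    sib_dos <- sib_h[seq(1, nrow(sib_h), 2), causal_idx] +
      sib_h[seq(2, nrow(sib_h), 2), causal_idx]
    per_line <- ceiling(config$n_outside_controls / config$n_lines)
    out_h <- do.call(rbind, lapply(seq_len(config$n_lines), function(l) {
      first <- if (l == 1) 3L else 1L   # line 1 members 1,2 founded the kindred
      rows <- 2L * (first + seq_len(per_line) - 1L)
      lines[[l]][as.vector(rbind(rows - 1L, rows)), , drop = FALSE]
    }))
    out_h <- out_h[seq_len(2L * config$n_outside_controls), , drop = FALSE]
    out_dos <- out_h[seq(1, nrow(out_h), 2), causal_idx] +
      out_h[seq(2, nrow(out_h), 2), causal_idx]
    status_all <- assign_phenotypes(c(sib_dos, out_dos),
                                    config$penetrance,
                                    config$phenocopy_rate)
    sib_status <- status_all[seq_along(sib_dos)]
    if (sum(sib_status == "affected") >= config$min_cases) break
    if (try == config$max_tries)
      stop("ascertainment failed after ", config$max_tries,
           " kindred gene drops")
  }
  aff_sib <- which(sib_status == "affected")
  sib_ids <- kped$id[sib_rows]
  outside_ids <- paste0("P", seq_len(config$n_outside_controls))
  cohort_ids <- c(sib_ids[aff_sib], outside_ids)
  ch <- rbind(sib_h[as.vector(rbind(2L * aff_sib - 1L, 2L * aff_sib)), ,
                    drop = FALSE],
              out_h)
  status <- c(sib_status[aff_sib], status_all[-seq_along(sib_dos)])
  phenocopy <- attr(status_all, "phenocopy")[
    c(aff_sib, length(sib_dos) + seq_len(config$n_outside_controls))]

  panels <- emit_panels(ch, cohort_ids, as.character(status), positions,
                        freq, causal_idx, decoy_idx, config)
  c(panels,
    list(kindred = kped, cohort_ids = cohort_ids, positions = positions,
         causal_idx = causal_idx, decoy_idx = decoy_idx,
         phenocopy = phenocopy, tries = try, config = config))
}

#' Write a simulated study to disk
#'
#' Emits the WGS panel as VCF, the array panel as PED/MAP, the
#' annotation table and sample sheet as TSV.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$wgs, file.path(dir, "wgs.vcf"))
  write_ped_map(sim$array, file.path(dir, "array.ped"),
                file.path(dir, "array.map"))
  utils::write.table(sim$annotation, file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$wgs$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
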