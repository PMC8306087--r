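#' Genotype quality control
#'
#' Removes variants with minor allele frequency at or below `maf_min` or
#' missing call rate above `max_variant_missing`, then samples with
#' missing genotype rate above `max_sample_missing`.  The MAF boundary is
#' exclusive on the keep side ("MAF > 0.05" keeps), the missingness
#' boundaries inclusive.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min MAF threshold (default 0.05; variants kept when
#'   MAF > `maf_min`).
#' @param max_variant_missing maximum per-variant missing rate
#'   (default 0.1).
#' @param max_sample_missing maximum per-sample missing rate
#'   (default 0.1).
#' @return list with `gm` (filtered) and `report` (counts removed per
#'   criterion).
#' @export
qc_filter <- function(gm, maf_min = 0.05, max_variant_missing = 0.1,
                      max_sample_missing = 0.1) {
  stopifnot(n_variants(gm) > 0)
  maf <- minor_allele_freq(gm)
  maf[is.nan(maf)] <- 0
  vm <- variant_missing_rate(gm)
  keep_v <- maf > maf_min & vm <= max_variant_missing
  n_rm_maf <- sum(maf <= maf_min)
  n_rm_vmiss <- sum(vm > max_variant_missing)
  if (!any(keep_v)) {
    rep <- list(n_removed_maf = n_rm_maf, n_removed_variant_missing =
                  n_rm_vmiss, n_removed_samples = 0L)
    stop("all variants removed by QC (maf: ", n_rm_maf, ", missing: ",
         n_rm_vmiss, ")")
  }
  gm2 <- gm[, keep_v]
  sm <- sample_missing_rate(gm2)
  keep_s <- sm <= max_sample_missing
  list(gm = gm2[keep_s, ],
       report = list(n_variants_in = n_variants(gm),
                     n_removed_maf = n_rm_maf,
                     n_removed_variant_missing = n_rm_vmiss,
                     n_variants_kept = sum(keep_v),
                     n_removed_samples = sum(!keep_s),
                     n_samples_kept = sum(keep_s)))
}

#' Homozygote-excess inbreeding coefficients
#'
#' Method-of-moments F per sample from the difference between observed
#' and expected counts of homozygous genotypes:
#' `F = (O - E) / (m - E)`, with the expected homozygosity at variant i
#' equal to `1 - 2 p q n/(n-1)` (allele frequency `p` estimated from the
#' cohort with the small-sample correction `n/(n-1)` on heterozygosity).
#' This is the convention of PLINK's `--het`.
#'
#' @param gm a `genotype_matrix` (at least 2 samples).
#' @param freq_samples optional sample indices used for allele-frequency
#'   estimation (default: all samples).
#' @return data.frame with columns `sample_id`, `observed_hom`,
#'   `expected_hom`, `m_used`, `F`.
#' @export
inbreeding_f <- function(gm, freq_samples = NULL) {
  stopifnot(n_samples(gm) >= 2)
  d <- gm$dosage
  n_i <- colSums(!is.na(if (is.null(freq_samples)) d else
    d[freq_samples, , drop = FALSE]))
  p <- alt_freq(gm, freq_samples)
  usable <- n_i >= 2 & !is.na(p)
  e_hom_var <- 1 - 2 * p * (1 - p) * n_i / (n_i - 1)
  obs <- exp_h <- m_used <- numeric(n_samples(gm))
  for (s in seq_len(n_samples(gm))) {
    called <- !is.na(d[s, ]) & usable
    obs[s] <- sum(d[s, called] != 1L)
    exp_h[s] <- sum(e_hom_var[called])
    m_used[s] <- sum(called)
  }
  f <- ifelse(m_used > exp_h, (obs - exp_h) / (m_used - exp_h), NA_real_)
  data.frame(sample_id = gm$samples$sample_id, observed_hom = obs,
             expected_hom = exp_h, m_used = m_used, F = f,
             stringsAsFactors = FALSE)
}

# per-variant standardized dosage matrix: missing imputed to the variant
# mean, columns centered and scaled; zero-variance columns dropped
standardize_dosage <- function(gm) {
  d <- gm$dosage
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  sdv <- apply(d, 2, stats::sd)
  keep <- sdv > 0 & !is.na(sdv)
  scale(d[, keep, drop = FALSE])
}

#' Principal component scores
#'
#' PCA of the per-variant standardized dosage matrix via SVD (numerically
#' equivalent to the eigendecomposition of the sample covariance).
#' Missing dosages are imputed to the variant mean for this computation
#' only.  Sign convention: the largest-magnitude variant loading of each
#' component is positive.
#'
#' @param gm a QC-filtered `genotype_matrix`.
#' @param k number of components (default 2).
#' @return n x k matrix of scores (rownames = sample ids), with the
#'   proportion of variance explained in attribute `var_explained`.
#' @export
pca_scores <- function(gm, k = 2) {
  z <- standardize_dosage(gm)
  sv <- svd(z)
  pos <- sum(sv$d > max(sv$d) * 1e-8)
  if (k > pos) stop("k = ", k, " exceeds matrix rank ", pos)
  flip <- vapply(seq_len(k), function(i) {
    l <- sv$v[, i]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  scores
}

#' Standardized genomic relationship matrix
#'
#' `G = (1/m) * sum_i (x_i - 2 p_i)(x_i - 2 p_i)' / (2 p_i (1 - p_i))`
#' over polymorphic variants, with missing dosages imputed to `2 p_i`.
#' This is the standardized ("GCTA"/"GEMMA -gk 2") relationship matrix
#' used as the covariance structure of the mixed-model scan.
#'
#' @param gm a QC-filtered `genotype_matrix`.
#' @return n x n symmetric matrix (dimnames = sample ids).
#' @export
grm_standardized <- function(gm) {
  d <- gm$dosage
  storage.mode(d) <- "double"
  p <- alt_freq(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (any(!poly))
    warning(sum(!poly), " monomorphic variant(s) skipped in GRM")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  z <- sweep(d, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  g <- tcrossprod(z) / ncol(z)
  dimnames(g) <- list(gm$samples$sample_id, gm$samples$sample_id)
  g
}
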