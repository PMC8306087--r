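#' Genotype matrix container
#'
#' The central data structure of the package: a samples x variants dosage
#' matrix with per-sample and per-variant metadata.  Dosages count copies of
#' the alternative allele (0 = homozygous reference, 1 = heterozygous,
#' 2 = homozygous alternative, `NA` = missing call).
#'
#' @param dosage integer matrix, samples in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt` and optionally `id`, `depth`, `qual`.  Must be sorted by
#'   (`chrom`, `pos`) with strictly increasing positions per chromosome.
#' @param samples data.frame with columns `sample_id`, `status` (one of
#'   `"affected"`, `"unaffected"`, `"unknown"`) and optionally `excluded`
#'   (logical) and `sex`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `variants`, `samples`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  if (is.null(variants$id)) variants$id <- rep(NA_character_, nrow(variants))
  if (is.null(samples$status)) samples$status <- rep("unknown", nrow(samples))
  if (is.null(samples$excluded)) samples$excluded <- rep(FALSE, nrow(samples))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  samples$sample_id <- as.character(samples$sample_id)
  samples$excluded <- as.logical(samples$excluded)
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variant_key(variants)
  gm <- structure(list(dosage = dosage, variants = variants,
                       samples = samples),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Canonical variant keys
#'
#' @param variants a variant data.frame (or a `genotype_matrix`).
#' @return character vector `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(variants) {
  if (inherits(variants, "genotype_matrix")) variants <- variants$variants
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: dosage codes in \{0,1,2,NA\}, unique
#' sample ids and variant keys, variants sorted with strictly increasing
#' positions per chromosome, conforming dimensions.
#'
#' @param gm a `genotype_matrix`.
#' @return `gm`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  if (nrow(d) != nrow(gm$samples))
    stop("dosage rows (", nrow(d), ") != samples (", nrow(gm$samples), ")")
  if (ncol(d) != nrow(gm$variants))
    stop("dosage cols (", ncol(d), ") != variants (", nrow(gm$variants), ")")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(gm$samples$sample_id))
    stop("duplicated sample ids")
  if (anyDuplicated(variant_key(gm$variants)))
    stop("duplicated variant keys")
  if (nrow(gm$variants)) {
    if (any(gm$variants$pos < 1L)) stop("positions must be >= 1")
    if (any(gm$variants$ref == gm$variants$alt))
      stop("ref and alt alleles must differ")
    by_chr <- split(gm$variants$pos,
                    factor(gm$variants$chrom,
                           levels = unique(gm$variants$chrom)))
    # non-decreasing (split multi-allelic records share a position;
    # uniqueness is enforced on the full variant key)
    for (p in by_chr)
      if (is.unsorted(p))
        stop("positions must be sorted within chromosome")
  }
  ok <- gm$samples$status %in% c("affected", "unaffected", "unknown")
  if (!all(ok)) stop("status must be affected/unaffected/unknown")
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  n_aff <- sum(x$samples$status == "affected")
  n_un <- sum(x$samples$status == "unaffected")
  cat(sprintf(
    "<genotype_matrix> %d samples (%d affected, %d unaffected) x %d variants on %d chromosome(s)\n",
    nrow(x$samples), n_aff, n_un, nrow(x$variants),
    length(unique(x$variants$chrom))))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a `genotype_matrix`.
#' @param i sample index (integer, logical, or sample ids).
#' @param j variant index (integer or logical).
#' @param ... unused.
#' @return the subsetted `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$samples))
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE],
                  x$samples[i, , drop = FALSE])
}

#' Number of samples / variants
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$samples)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Alternative-allele frequencies
#'
#' Per-variant alternative allele frequency estimated from non-missing
#' dosages; `NaN` for variants with no calls.
#'
#' @param gm a `genotype_matrix`.
#' @param samples optional subset of sample indices to estimate from.
#' @return numeric vector, one entry per variant.
#' @export
alt_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  colMeans(d, na.rm = TRUE) / 2
}

#' Minor-allele frequencies
#' @inheritParams alt_freq
#' @return numeric vector of per-variant MAF.
#' @export
minor_allele_freq <- function(gm, samples = NULL) {
  p <- alt_freq(gm, samples)
  pmin(p, 1 - p)
}

#' Per-variant and per-sample missing call rates
#' @param gm a `genotype_matrix`.
#' @return numeric vector of missing fractions.
#' @export
variant_missing_rate <- function(gm) colMeans(is.na(gm$dosage))

#' @rdname variant_missing_rate
#' @export
sample_missing_rate <- function(gm) rowMeans(is.na(gm$dosage))

# canonical chromosome-major ordering used by the readers
order_variants <- function(variants) {
  order(factor(variants$chrom, levels = unique(variants$chrom)),
        variants$pos)
}
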