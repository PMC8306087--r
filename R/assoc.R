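#' Genotype-by-status contingency table
#'
#' Builds the 3 x 2 table of genotype class (AA = homozygous alternative,
#' AR = heterozygous, RR = homozygous reference) against affection
#' status.  Samples with missing genotype or unknown status are dropped.
#'
#' @param dosages integer vector of dosages (0/1/2/NA).
#' @param status character vector (`"affected"`/`"unaffected"`/other).
#' @return 3 x 2 integer matrix with rows AA, AR, RR and columns
#'   affected, unaffected.
#' @export
genotype_status_table <- function(dosages, status) {
  stopifnot(length(dosages) == length(status))
  ok <- !is.na(dosages) & status %in% c("affected", "unaffected")
  if (!any(ok)) stop("no samples with called genotype and known status")
  g <- factor(c(`2` = "AA", `1` = "AR", `0` = "RR")[
    as.character(dosages[ok])], levels = c("AA", "AR", "RR"))
  s <- factor(status[ok], levels = c("affected", "unaffected"))
  unclass(table(g, s))
}

#' Build a contingency table from printed genotype counts
#'
#' Convenience constructor for validation-cohort tables reported as
#' affected/unaffected count pairs per genotype class.
#'
#' @param aa,ar,rr length-2 vectors `c(affected, unaffected)`.
#' @return 3 x 2 integer matrix (rows AA, AR, RR).
#' @export
genotype_count_table <- function(aa, ar, rr) {
  t <- rbind(AA = aa, AR = ar, RR = rr)
  colnames(t) <- c("affected", "unaffected")
  storage.mode(t) <- "integer"
  t
}

#' Relative risk between two genotype classes
#'
#' `RR = [a/(a+b)] / [c/(c+d)]` with (a, b) the affected/unaffected
#' counts of the exposed genotype and (c, d) those of the reference
#' genotype.  The accompanying p-value is the Yates-corrected chi-square
#' test on the 2 x 2 subtable of those two rows.
#'
#' @param table a 3 x 2 (or larger) genotype-by-status count matrix with
#'   named rows.
#' @param exposed,reference row names of the compared genotype classes.
#' @param conf_level confidence level for the optional log-scale Wald
#'   interval (default 0.95).
#' @return list with `rr`, `p_value`, `test_name`, `exposed`,
#'   `reference`, `ci` (lower/upper), `infinite` flag.
#' @export
relative_risk <- function(table, exposed = "AA", reference = "RR",
                          conf_level = 0.95) {
  a <- table[exposed, 1]; b <- table[exposed, 2]
  c_ <- table[reference, 1]; d <- table[reference, 2]
  if (a + b == 0 || c_ + d == 0)
    stop("exposed and reference rows must each contain subjects")
  risk_e <- a / (a + b)
  risk_r <- c_ / (c_ + d)
  inf <- risk_r == 0
  rr <- if (inf) Inf else risk_e / risk_r
  sub <- rbind(c(a, b), c(c_, d))
  p <- if (any(rowSums(sub) == 0) || any(colSums(sub) == 0)) NA_real_ else
    chi2_test(sub, yates = TRUE)$p
  ci <- c(NA_real_, NA_real_)
  if (!inf && a > 0 && c_ > 0) {
    se_log <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
    zq <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(log(rr) + c(-1, 1) * zq * se_log)
  }
  list(rr = rr, p_value = p, test_name = "chi-square (Yates)",
       exposed = exposed, reference = reference, ci = ci,
       infinite = inf)
}

#' Pearson chi-square test of independence
#'
#' Standard Pearson statistic on an R x C table; on 2 x 2 tables the
#' Yates continuity correction (the `|ad - bc| - n/2` convention) is
#' applied when `yates = TRUE`.
#'
#' @param table count matrix.
#' @param yates apply the continuity correction on 2 x 2 tables
#'   (default TRUE).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi2_test <- function(table, yates = TRUE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an empty margin")
  ct <- suppressWarnings(
    stats::chisq.test(table, correct = yates && all(dim(table) == 2)))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Exact test of independence
#'
#' Fisher's exact test on 2 x 2 tables, generalized to R x C by the
#' Freeman-Halton conditional enumeration; two-sided p by the
#' probability-at-most-observed rule.  Tables too large for exact
#' enumeration can be evaluated by seeded Monte Carlo.
#'
#' @param table count matrix.
#' @param monte_carlo use Monte Carlo instead of full enumeration.
#' @param B Monte Carlo replicates (default 1e5).
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(table, monte_carlo = FALSE, B = 1e5) {
  table <- as.matrix(table)
  if (monte_carlo)
    return(stats::fisher.test(table, simulate.p.value = TRUE,
                              B = B)$p.value)
  p <- tryCatch(stats::fisher.test(table, workspace = 2e7)$p.value,
                error = function(e)
                  stop("exact enumeration failed (", conditionMessage(e),
                       "); retry with monte_carlo = TRUE"))
  p
}

#' Allele frequency from genotype counts
#'
#' @param hom_alt,het,hom_ref non-negative genotype counts.
#' @return alternative allele frequency
#'   `(2 hom_alt + het) / (2 (hom_alt + het + hom_ref))`.
#' @export
allele_freq_from_counts <- function(hom_alt, het, hom_ref) {
  stopifnot(hom_alt >= 0, het >= 0, hom_ref >= 0)
  n <- hom_alt + het + hom_ref
  if (any(n == 0)) stop("genotype counts sum to zero")
  (2 * hom_alt + het) / (2 * n)
}

#' Cohort summary percentages
#'
#' The three headline proportions of a validation cohort: fraction of
#' cases homozygous for the candidate allele, fraction of homozygotes
#' affected, and fraction of controls homozygous.  Raw proportions and
#' integer-percent renderings are both returned.
#'
#' @param table 3 x 2 genotype-by-status count matrix (rows AA, AR, RR;
#'   columns affected, unaffected).
#' @return data.frame with `measure`, `proportion`, `percent` (integer),
#'   `defined`.
#' @export
cohort_percentages <- function(table) {
  n_cases <- sum(table[, "affected"])
  n_controls <- sum(table[, "unaffected"])
  n_hom <- sum(table["AA", ])
  props <- c(cases_homozygous =
               if (n_cases > 0) table["AA", "affected"] / n_cases else NA,
             homozygotes_affected =
               if (n_hom > 0) table["AA", "affected"] / n_hom else NA,
             controls_homozygous =
               if (n_controls > 0)
                 table["AA", "unaffected"] / n_controls else NA)
  data.frame(measure = names(props), proportion = unname(props),
             percent = round(100 * unname(props)),
             defined = !is.na(props), row.names = NULL,
             stringsAsFactors = FALSE)
}
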