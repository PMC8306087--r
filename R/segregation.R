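#' Read a variant annotation table
#'
#' TSV with columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`,
#' `aa_change`, `sift`, `provean`, `panther`, `polyphen`,
#' `panel_hom_alt`, `panel_het`, `panel_hom_ref`.  Reference-panel
#' columns may be missing/NA for novel variants.
#'
#' @param path TSV file.
#' @return annotation data.frame with a derived `panel_af` column.
#' @export
read_annotation <- function(path) {
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "consequence")
  if (!all(need %in% names(a)))
    stop("annotation table needs columns: ", paste(need, collapse = ", "))
  a$panel_af <- panel_allele_freq(a)
  a
}

# alternative-allele frequency from reference-panel genotype counts
panel_allele_freq <- function(a) {
  if (!all(c("panel_hom_alt", "panel_het", "panel_hom_ref") %in% names(a)))
    return(rep(NA_real_, nrow(a)))
  tot <- a$panel_hom_alt + a$panel_het + a$panel_hom_ref
  (2 * a$panel_hom_alt + a$panel_het) / (2 * tot)
}

#' Recessive segregation test for one variant
#'
#' TRUE when every non-excluded case is homozygous for the alternative
#' allele and no control is.  A missing genotype in a non-excluded case
#' fails the test; missing control genotypes are ignored by default
#' (strict mode counts them as failures).
#'
#' @param dosages named integer vector of dosages at one variant.
#' @param case_ids,control_ids sample ids per group.
#' @param excluded_cases case ids exempted from the homozygosity
#'   requirement (e.g. suspected phenocopies).
#' @param strict_controls fail on missing control genotypes
#'   (default FALSE).
#' @return logical scalar.
#' @export
segregation_pass <- function(dosages, case_ids, control_ids,
                             excluded_cases = character(),
                             strict_controls = FALSE) {
  cases <- setdiff(case_ids, excluded_cases)
  if (!length(cases)) stop("no cases remain after exclusions")
  dc <- dosages[cases]
  if (anyNA(dc) || any(dc != 2L)) return(FALSE)
  du <- dosages[control_ids]
  if (strict_controls && anyNA(du)) return(FALSE)
  !any(du == 2L, na.rm = TRUE)
}

#' Population allele-frequency filter
#'
#' TRUE when the reference-panel alternative allele frequency is below
#' `af_max`.  Variants absent from the panel (novel variants) pass.
#'
#' @param panel_af numeric panel allele frequency (NA = novel).
#' @param af_max frequency cutoff (default 0.05, exclusive).
#' @return logical vector.
#' @export
af_pass <- function(panel_af, af_max = 0.05) {
  is.na(panel_af) | panel_af < af_max
}

#' Deleteriousness score consensus
#'
#' Per-tool deleterious calls -- SIFT `<= sift_max`, PROVEAN
#' `<= provean_max`, PANTHER-PSEP `>= panther_min`, PolyPhen-2
#' `>= polyphen_min` -- combined across the tools with scores present.
#' Unscored variants are FALSE (flagged via the `unscored` attribute).
#'
#' @param variants annotation data.frame rows with `sift`, `provean`,
#'   `panther`, `polyphen` columns.
#' @param sift_max,provean_max,panther_min,polyphen_min per-tool cutoffs
#'   (defaults 0.05, -2.5, 0.5, 0.5).
#' @param rule `"all"` (default), `"majority"`, or `"any"`.
#' @return logical vector with attribute `unscored`.
#' @export
deleterious_consensus <- function(variants, sift_max = 0.05,
                                  provean_max = -2.5, panther_min = 0.5,
                                  polyphen_min = 0.5,
                                  rule = c("all", "majority", "any")) {
  rule <- match.arg(rule)
  calls <- cbind(variants$sift <= sift_max,
                 variants$provean <= provean_max,
                 variants$panther >= panther_min,
                 variants$polyphen >= polyphen_min)
  n_scored <- rowSums(!is.na(calls))
  n_del <- rowSums(calls, na.rm = TRUE)
  out <- switch(rule,
                all = n_scored > 0 & n_del == n_scored,
                majority = n_scored > 0 & n_del > n_scored / 2,
                any = n_del > 0)
  attr(out, "unscored") <- n_scored == 0
  out
}

#' Candidate-variant filtering funnel
#'
#' Applies the recessive candidate-variant procedure inside a candidate
#' region: region restriction, homozygous-in-all-cases,
#' case-private segregation, rare in the reference panel, exonic,
#' missense, deleterious-score consensus.  Structural variants
#' (consequence `SV-*`) flow through the segregation and frequency
#' stages but skip the consequence/deleteriousness stages and are
#' reported separately.
#'
#' @param annotation annotation data.frame (see [read_annotation()]); one
#'   row per variant, aligned with the variants available in `gm` by
#'   (chrom, pos, ref, alt).
#' @param gm `genotype_matrix` holding case/control dosages.
#' @param region list or one-row data.frame with `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), or a `"chrom:start-end"` string.
#' @param excluded_cases case ids exempted from segregation.
#' @param af_max reference-panel frequency cutoff (default 0.05).
#' @param hom_stage `"all"` (default) requires all non-excluded cases
#'   homozygous at the "homozygous" funnel stage; `"any"` requires at
#'   least one.
#' @param ... cutoffs passed to [deleterious_consensus()].
#' @return list with `retained` (annotation rows surviving all stages),
#'   `retained_sv` (SVs surviving segregation + frequency), and `funnel`
#'   (named stage counts, non-increasing).
#' @export
run_funnel <- function(annotation, gm, region,
                       excluded_cases = character(), af_max = 0.05,
                       hom_stage = c("all", "any"), ...) {
  hom_stage <- match.arg(hom_stage)
  region <- parse_region(region)
  keep <- !gm$samples$excluded
  case_ids <- gm$samples$sample_id[keep & gm$samples$status == "affected"]
  ctrl_ids <- gm$samples$sample_id[keep & gm$samples$status == "unaffected"]
  a <- annotation
  if (is.null(a$panel_af)) a$panel_af <- panel_allele_freq(a)
  a$.key <- paste(a$chrom, a$pos, a$ref, a$alt, sep = ":")
  gk <- variant_key(gm)

  in_region <- a$chrom == region$chrom & a$pos >= region$start_bp &
    a$pos <= region$end_bp
  a <- a[in_region, , drop = FALSE]
  if (!nrow(a)) {
    warning("candidate region contains no annotated variants")
    empty <- a
    return(list(retained = empty, retained_sv = empty,
                funnel = c(in_region = 0)))
  }
  is_sv <- grepl("^SV-", a$consequence)

  jj <- match(a$.key, gk)
  if (anyNA(jj))
    stop("annotation rows absent from the genotype matrix: ",
         paste(utils::head(a$.key[is.na(jj)], 3), collapse = ", "))
  dos <- gm$dosage[, jj, drop = FALSE]
  colnames(dos) <- a$.key
  cases_used <- setdiff(case_ids, excluded_cases)
  if (!length(cases_used)) stop("no cases remain after exclusions")

  hom_cases <- if (hom_stage == "all") {
    apply(dos[cases_used, , drop = FALSE], 2,
          function(x) !anyNA(x) && all(x == 2L))
  } else {
    apply(dos[cases_used, , drop = FALSE], 2,
          function(x) any(x == 2L, na.rm = TRUE))
  }
  seg <- vapply(seq_len(nrow(a)), function(r)
    segregation_pass(dos[, r], case_ids, ctrl_ids, excluded_cases),
    logical(1))
  rare <- af_pass(a$panel_af, af_max)
  exonic <- a$consequence %in% c("synonymous", "missense", "other-exonic")
  missense <- a$consequence == "missense"
  deleterious <- rep(FALSE, nrow(a))
  deleterious[missense] <- deleterious_consensus(
    a[missense, , drop = FALSE], ...)

  s1 <- hom_cases
  s2 <- s1 & seg
  s3 <- s2 & rare
  s4 <- s3 & exonic & !is_sv
  s5 <- s4 & missense
  s6 <- s5 & deleterious
  funnel <- c(in_region = nrow(a),
              homozygous_in_cases = sum(s1),
              case_private = sum(s2),
              rare_in_panel = sum(s3),
              exonic = sum(s4),
              missense = sum(s5),
              deleterious = sum(s6))
  a$.key <- NULL
  list(retained = a[s6, , drop = FALSE],
       retained_sv = a[s3 & is_sv, , drop = FALSE],
       funnel = funnel)
}

#' Parse a genomic region
#'
#' Accepts a `"chrom:start-end"` string, a list, or a one-row data.frame
#' with `chrom`, `start_bp`, `end_bp`.
#'
#' @param region the region specification.
#' @return list with `chrom`, `start_bp`, `end_bp`.
#' @export
parse_region <- function(region) {
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("cannot parse region string: ", region)
    return(list(chrom = m[2], start_bp = as.integer(m[3]),
                end_bp = as.integer(m[4])))
  }
  region <- as.list(region)
  stopifnot(all(c("chrom", "start_bp", "end_bp") %in% names(region)))
  list(chrom = as.character(region$chrom),
       start_bp = as.integer(region$start_bp),
       end_bp = as.integer(region$end_bp))
}
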