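#' Read a sample sheet
#'
#' Tab-separated file with columns `sample_id`, `status`
#' (affected/unaffected/unknown) and optionally `excluded` (logical).
#'
#' @param path path to the TSV file.
#' @return data.frame suitable for the `samples` slot of a
#'   [genotype_matrix()].
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(ss)))
    stop("sample sheet needs columns sample_id, status: ", path)
  if (is.null(ss$excluded)) ss$excluded <- FALSE
  ss$sample_id <- as.character(ss$sample_id)
  ss$excluded <- as.logical(ss$excluded)
  ss
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) into a [genotype_matrix()].
#' Dosage is the count of alternative alleles in the GT field; half calls
#' and non-diploid genotypes become missing.  Site depth is taken from
#' INFO/DP when present and stored, with QUAL, in the variant table.
#'
#' @param path VCF file.
#' @param sample_sheet optional data.frame (or TSV path) mapping
#'   `sample_id` to `status`/`excluded`; every sheet sample must be present
#'   in the VCF.
#' @param multiallelic `"split"` (default) decomposes multi-allelic records
#'   into one bi-allelic record per alternative allele; `"skip"` drops them.
#' @return a `genotype_matrix`; `depth`/`qual` columns on `$variants` carry
#'   site quality when available.
#' @export
read_vcf <- function(path, sample_sheet = NULL,
                     multiallelic = c("split", "skip")) {
  multiallelic <- match.arg(multiallelic)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", path, " (",
                                         conditionMessage(e), ")"))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  sample_ids <- colnames(v@gt)[-1]
  if (is.null(sample_ids)) sample_ids <- character(0)
  gt <- vcfR::extract.gt(v, element = "GT")

  qual <- suppressWarnings(as.numeric(fix$QUAL))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))

  rec <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1 && multiallelic == "skip") next
    gts <- gt[r, , drop = TRUE]
    parts <- strsplit(gsub("|", "/", gts, fixed = TRUE), "/", fixed = TRUE)
    for (ai in seq_along(alts)) {
      dos <- vapply(parts, function(p) {
        if (length(p) != 2 || anyNA(p) || any(p == ".")) return(NA_integer_)
        a <- suppressWarnings(as.integer(p))
        if (anyNA(a)) return(NA_integer_)
        sum(a == ai)
      }, integer(1))
      rec[[length(rec) + 1L]] <- list(
        chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        id = if (is.na(fix$ID[r]) || fix$ID[r] == ".") NA_character_ else fix$ID[r],
        ref = fix$REF[r], alt = alts[ai],
        qual = qual[r], depth = dp[r], dos = dos)
    }
  }
  variants <- data.frame(
    chrom = vapply(rec, `[[`, character(1), "chrom"),
    pos = vapply(rec, `[[`, integer(1), "pos"),
    id = vapply(rec, `[[`, character(1), "id"),
    ref = vapply(rec, `[[`, character(1), "ref"),
    alt = vapply(rec, `[[`, character(1), "alt"),
    depth = vapply(rec, `[[`, numeric(1), "depth"),
    qual = vapply(rec, `[[`, numeric(1), "qual"),
    stringsAsFactors = FALSE)
  dosage <- if (length(rec)) {
    do.call(cbind, lapply(rec, `[[`, "dos"))
  } else {
    matrix(integer(0), nrow = length(sample_ids), ncol = 0)
  }
  dosage <- matrix(as.integer(dosage), nrow = length(sample_ids))

  samples <- data.frame(sample_id = sample_ids,
                        status = "unknown", excluded = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(sample_sheet)) {
    if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
    miss <- setdiff(sample_sheet$sample_id, sample_ids)
    if (length(miss))
      stop("sample sheet ids absent from VCF: ", paste(miss, collapse = ", "))
    idx <- match(sample_ids, sample_sheet$sample_id)
    hit <- !is.na(idx)
    samples$status[hit] <- sample_sheet$status[idx[hit]]
    samples$excluded[hit] <- sample_sheet$excluded[idx[hit]]
  }
  o <- order_variants(variants)
  genotype_matrix(dosage[, o, drop = FALSE], variants[o, , drop = FALSE],
                  samples)
}

#' Write genotypes to a VCF file
#'
#' Emits a minimal standard-conformant VCF 4.2 (GT format; QUAL and
#' INFO/DP filled from the variant table when present).  Plain text, so
#' the output round-trips through [read_vcf()].
#'
#' @param gm a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  v <- gm$variants
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write VCF: ", path))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rohmap",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t")
  writeLines(header, con)
  if (!nrow(v)) return(invisible(path))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  for (j in seq_len(nrow(v))) {
    dos <- gm$dosage[, j]
    gts <- ifelse(is.na(dos), "./.", gt_code[as.character(dos)])
    qual <- if (!is.null(v$qual) && !is.na(v$qual[j]))
      format(v$qual[j], trim = TRUE) else "."
    info <- if (!is.null(v$depth) && !is.na(v$depth[j]))
      paste0("DP=", as.integer(v$depth[j])) else "."
    id <- if (is.na(v$id[j])) "." else v$id[j]
    writeLines(paste(c(v$chrom[j], v$pos[j], id, v$ref[j], v$alt[j],
                       qual, "PASS", info, "GT", gts), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Read genotypes from PED/MAP text files
#'
#' The PED file carries six leading columns (family, individual, sire, dam,
#' sex, phenotype) followed by two allele columns per variant; the MAP file
#' carries chromosome, variant id, genetic position and bp position.
#' Phenotype coding follows the standard dialect: 1 = unaffected,
#' 2 = affected, 0 or -9 = unknown.  `"0 0"` allele pairs are missing.
#'
#' @param ped_path PED file.
#' @param map_path MAP file.
#' @param ref_alleles optional character vector of reference alleles, one
#'   per MAP variant.  When absent, the majority allele across all samples
#'   is taken as reference (ties broken lexicographically).
#' @return a `genotype_matrix`.
#' @export
read_ped_map <- function(ped_path, map_path, ref_alleles = NULL) {
  map <- utils::read.table(map_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos"))
  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(ped_lines)]
  m <- nrow(map)
  n <- length(ped_lines)
  dosage <- matrix(NA_integer_, n, m)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  pheno <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("PED line ", i, " has ", length(f), " fields; expected ",
           6 + 2 * m, " for ", m, " MAP variants")
    ids[i] <- f[2]
    pheno[i] <- f[6]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  status <- c(`1` = "unaffected", `2` = "affected")[pheno]
  status[is.na(status)] <- "unknown"

  if (is.null(ref_alleles)) {
    ref_alleles <- character(m)
    for (j in seq_len(m)) {
      al <- c(a1[, j], a2[, j])
      al <- al[al != "0"]
      if (!length(al)) { ref_alleles[j] <- "A"; next }
      tab <- table(al)
      top <- tab[tab == max(tab)]
      ref_alleles[j] <- sort(names(top))[1]
    }
  }
  alt_alleles <- character(m)
  for (j in seq_len(m)) {
    al <- unique(c(a1[, j], a2[, j]))
    al <- setdiff(al, c("0", ref_alleles[j]))
    alt_alleles[j] <- if (length(al)) sort(al)[1] else
      setdiff(c("A", "C", "G", "T"), ref_alleles[j])[1]
    dosage[, j] <- ifelse(a1[, j] == "0" | a2[, j] == "0", NA_integer_,
                          (a1[, j] != ref_alleles[j]) +
                            (a2[, j] != ref_alleles[j]))
  }
  variants <- data.frame(chrom = as.character(map$chrom), pos = map$pos,
                         id = ifelse(map$id == ".", NA_character_, map$id),
                         ref = ref_alleles, alt = alt_alleles,
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ids, status = status, excluded = FALSE,
                        stringsAsFactors = FALSE)
  o <- order_variants(variants)
  genotype_matrix(dosage[, o, drop = FALSE], variants[o, , drop = FALSE],
                  samples)
}

#' Write genotypes to PED/MAP text files
#'
#' @param gm a `genotype_matrix`.
#' @param ped_path,map_path output file paths.
#' @return `ped_path`, invisibly.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  validate_genotype_matrix(gm)
  v <- gm$variants
  utils::write.table(
    data.frame(v$chrom, ifelse(is.na(v$id), ".", v$id), 0, v$pos),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  pheno <- c(affected = "2", unaffected = "1", unknown = "0")[
    gm$samples$status]
  lines <- character(n_samples(gm))
  for (i in seq_len(n_samples(gm))) {
    dos <- gm$dosage[i, ]
    g1 <- ifelse(is.na(dos), "0", ifelse(dos >= 1, v$alt, v$ref))
    g2 <- ifelse(is.na(dos), "0", ifelse(dos == 2, v$alt, v$ref))
    al <- character(2 * length(dos))
    al[seq(1, length(al), by = 2)] <- g1
    al[seq(2, length(al), by = 2)] <- g2
    lines[i] <- paste(c("FAM", gm$samples$sample_id[i], "0", "0", "0",
                        pheno[i], al), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(ped_path)
}

#' Intersect two genotype panels
#'
#' Restricts two genotype matrices with disjoint sample sets to the
#' variants they share, matched on (chrom, pos, ref, alt).  A site typed
#' with swapped ref/alt alleles in the second panel is matched after
#' complementing its dosages (0 <-> 2), so both panels count the same
#' allele.
#'
#' @param gm_a,gm_b genotype matrices with disjoint samples.
#' @return a merged `genotype_matrix` over the union of samples and the
#'   shared variants, using `gm_a`'s allele orientation.
#' @export
intersect_panels <- function(gm_a, gm_b) {
  if (length(intersect(gm_a$samples$sample_id, gm_b$samples$sample_id)))
    stop("panels must have disjoint sample sets")
  key_a <- variant_key(gm_a)
  key_b <- variant_key(gm_b)
  flip_b <- paste(gm_b$variants$chrom, gm_b$variants$pos,
                  gm_b$variants$alt, gm_b$variants$ref, sep = ":")
  direct <- match(key_a, key_b)
  flipped <- match(key_a, flip_b)
  use_flip <- is.na(direct) & !is.na(flipped)
  idx_b <- ifelse(use_flip, flipped, direct)
  keep <- !is.na(idx_b)
  if (!any(keep)) stop("panels share no variants")
  ja <- which(keep)
  jb <- idx_b[keep]
  dos_b <- gm_b$dosage[, jb, drop = FALSE]
  fl <- use_flip[keep]
  if (any(fl)) dos_b[, fl] <- 2L - dos_b[, fl]
  genotype_matrix(rbind(gm_a$dosage[, ja, drop = FALSE], dos_b),
                  gm_a$variants[ja, , drop = FALSE],
                  rbind(gm_a$samples[, c("sample_id", "status", "excluded")],
                        gm_b$samples[, c("sample_id", "status", "excluded")]))
}

#' Site-level depth and calling-quality filter
#'
#' Keeps variants covered by at least `min_depth` reads and called with
#' quality at least `min_qual` (both boundaries on the keep side).
#'
#' @param gm a `genotype_matrix` whose variant table carries `depth` and
#'   `qual` columns.
#' @param min_depth minimum read depth (default 4).
#' @param min_qual minimum phred-scaled calling quality (default 20).
#' @param missing_fails treat variants with missing depth/qual as failing
#'   (default `TRUE`).
#' @return list with `gm` (the filtered matrix) and `report`
#'   (`n_in`, `n_kept`, `n_removed_depth`, `n_removed_qual`).
#' @export
site_quality_filter <- function(gm, min_depth = 4, min_qual = 20,
                                missing_fails = TRUE) {
  v <- gm$variants
  if (is.null(v$depth) || is.null(v$qual))
    stop("variant table has no depth/qual columns")
  dp_ok <- v$depth >= min_depth
  q_ok <- v$qual >= min_qual
  fill <- !missing_fails
  dp_ok[is.na(dp_ok)] <- fill
  q_ok[is.na(q_ok)] <- fill
  keep <- dp_ok & q_ok
  list(gm = gm[, keep],
       report = list(n_in = nrow(v), n_kept = sum(keep),
                     n_removed_depth = sum(!dp_ok),
                     n_removed_qual = sum(!q_ok)))
}
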