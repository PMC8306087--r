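test_that("VCF reading maps genotype codes and missing calls to dosages", {
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b"), collapse = "\t"),
           "chr1\t100\t.\tA\tG\t50\tPASS\tDP=30\tGT\t0/0\t0/1",
           "chr1\t200\t.\tC\tT\t50\tPASS\tDP=12\tGT\t0/1\t1/1",
           "chr1\t300\t.\tG\tA\t50\tPASS\tDP=9\tGT\t1/1\t./.")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f)
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L))
  expect_equal(unname(gm$dosage[, 2]), c(1L, 2L))
  expect_equal(unname(gm$dosage[, 3]), c(2L, NA_integer_))
  expect_equal(gm$variants$depth, c(30, 12, 9))
  expect_equal(gm$samples$sample_id, c("a", "b"))
})

test_that("multi-allelic records are split into bi-allelic rows or skipped", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b"), collapse = "\t"),
           "chr1\t100\t.\tA\tG,T\t50\tPASS\t.\tGT\t1/2\t0/1",
           "chr1\t200\t.\tC\tT\t50\tPASS\t.\tGT\t0/0\t1/1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gm <- read_vcf(f, multiallelic = "split")
  expect_equal(n_variants(gm), 3)
  expect_equal(gm$variants$alt[1:2], c("G", "T"))
  # sample a is G/T: one copy of each alternative
  expect_equal(unname(gm$dosage[1, 1:2]), c(1L, 1L))
  expect_equal(unname(gm$dosage[2, 1:2]), c(1L, 0L))
  gm2 <- read_vcf(f, multiallelic = "skip")
  expect_equal(n_variants(gm2), 1)
})

test_that("sample sheet is applied and absent samples are reported", {
  vcf <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "a", "b"), collapse = "\t"),
           "chr1\t100\t.\tA\tG\t50\tPASS\t.\tGT\t0/0\t1/1")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  sheet <- data.frame(sample_id = c("a", "b"),
                      status = c("affected", "unaffected"),
                      excluded = c(FALSE, TRUE))
  gm <- read_vcf(f, sheet)
  expect_equal(gm$samples$status, c("affected", "unaffected"))
  expect_equal(gm$samples$excluded, c(FALSE, TRUE))
  bad <- data.frame(sample_id = "zz", status = "affected")
  expect_error(read_vcf(f, bad), "zz")
})

test_that("VCF writing round-trips the genotype matrix exactly", {
  set.seed(11)
  d <- random_dosage(6, 100, miss = 0.08)
  gm <- make_gm(d, status = rep(c("affected", "unaffected", "unknown"), 2))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  sheet <- gm$samples
  back <- read_vcf(f, sheet)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$variants$pos, gm$variants$pos)
  expect_equal(back$samples$status, gm$samples$status)
})

test_that("empty matrix writes a header-only VCF", {
  gm <- make_gm(matrix(integer(0), nrow = 2, ncol = 0))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines, "#")))
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("PED/MAP round-trips, with 0 0 as missing and phenotype codes", {
  set.seed(12)
  d <- random_dosage(5, 40, miss = 0.1)
  gm <- make_gm(d, status = c("affected", "unaffected", "unknown",
                              "affected", "unaffected"))
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  write_ped_map(gm, ped, map)
  back <- read_ped_map(ped, map, ref_alleles = gm$variants$ref)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$samples$status, gm$samples$status)
  expect_equal(back$variants$pos, gm$variants$pos)
})

test_that("PED majority-allele reference rule is deterministic", {
  # 3 samples at one variant: alleles A A / A C / C C -> A majority = ref
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("F a 0 0 0 2 A A", "F b 0 0 0 1 A C", "F c 0 0 0 1 C C"),
             ped)
  writeLines("1\tsnp1\t0\t500", map)
  gm <- read_ped_map(ped, map)
  expect_equal(gm$variants$ref, "A")
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, 2L))
  # tie: A and C equally common -> lexicographic ref = A
  writeLines(c("F a 0 0 0 1 A A", "F b 0 0 0 1 C C"), ped)
  gm2 <- read_ped_map(ped, map)
  expect_equal(gm2$variants$ref, "A")
  # "0 0" is missing
  writeLines(c("F a 0 0 0 1 A A", "F b 0 0 0 1 0 0"), ped)
  expect_true(is.na(read_ped_map(ped, map)$dosage[2, 1]))
})

test_that("PED/MAP length mismatch is reported with the offending line", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("F a 0 0 0 1 A A G G", "F b 0 0 0 1 A A"), ped)
  writeLines(c("1\tsnp1\t0\t500", "1\tsnp2\t0\t900"), map)
  expect_error(read_ped_map(ped, map), "line 2")
})

test_that("panel intersection matches shared variants and flips swapped alleles", {
  va <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  a <- genotype_matrix(matrix(c(0L, 1L, 2L, 0L, 1L, 2L), 2, byrow = TRUE),
                       va, data.frame(sample_id = c("a1", "a2"),
                                      status = "affected"))
  # panel b shares pos 100 (same orientation) and pos 200 (alleles
  # swapped); pos 999 is private
  vb <- data.frame(chrom = "chr1", pos = c(100L, 200L, 999L),
                   ref = c("A", "T", "C"), alt = c("G", "C", "G"))
  b <- genotype_matrix(matrix(c(2L, 0L, 1L, 1L, 2L, 0L), 2, byrow = TRUE),
                       vb, data.frame(sample_id = c("b1", "b2"),
                                      status = "unaffected"))
  merged <- intersect_panels(a, b)
  expect_equal(n_variants(merged), 2)
  expect_equal(merged$samples$sample_id, c("a1", "a2", "b1", "b2"))
  # b's dosages at the swapped site are complemented (0 <-> 2)
  j <- which(merged$variants$pos == 200)
  expect_equal(unname(merged$dosage[c("b1", "b2"), j]), c(2L, 0L))
  j1 <- which(merged$variants$pos == 100)
  expect_equal(unname(merged$dosage[c("b1", "b2"), j1]), c(2L, 1L))
  # identical panels: variant count unchanged
  b2 <- a
  b2$samples$sample_id <- c("x1", "x2")
  rownames(b2$dosage) <- b2$samples$sample_id
  expect_equal(n_variants(intersect_panels(a, b2)), n_variants(a))
  # symmetric in variant content (allele orientation follows the first
  # panel, so compare on position + unordered allele pair)
  site_key <- function(v) paste(v$chrom, v$pos,
                                pmin(v$ref, v$alt), pmax(v$ref, v$alt))
  expect_setequal(site_key(intersect_panels(a, b)$variants),
                  site_key(intersect_panels(b, a)$variants))
  # zero overlap errors
  c_gm <- genotype_matrix(matrix(0L, 1, 1),
                          data.frame(chrom = "chr9", pos = 5L, ref = "A",
                                     alt = "T"),
                          data.frame(sample_id = "zz", status = "unknown"))
  expect_error(intersect_panels(a, c_gm), "share no variants")
})

test_that("site quality filter keeps depth >= 4 and qual >= 20 inclusively", {
  v <- data.frame(chrom = "chr1", pos = c(1000L, 2000L, 3000L, 4000L),
                  ref = "A", alt = "G",
                  depth = c(4, 3, 100, NA), qual = c(20, 99, 19.9, 50))
  gm <- genotype_matrix(matrix(0L, 2, 4), v,
                        data.frame(sample_id = c("a", "b"),
                                   status = "unknown"))
  res <- site_quality_filter(gm)
  expect_equal(res$gm$variants$pos, 1000L)   # boundary case kept
  expect_equal(res$report$n_removed_depth, 2)  # depth 3 and missing depth
  expect_equal(res$report$n_removed_qual, 1)   # qual 19.9
  res2 <- site_quality_filter(gm, missing_fails = FALSE)
  expect_equal(res2$gm$variants$pos, c(1000L, 4000L))
})

test_that("site quality filter equals a brute-force predicate scan and is idempotent", {
  set.seed(5)
  n <- 1000
  v <- data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A",
                  alt = "G",
                  depth = sample(0:10, n, replace = TRUE),
                  qual = round(runif(n, 0, 40), 1))
  gm <- genotype_matrix(matrix(0L, 1, n), v,
                        data.frame(sample_id = "s", status = "unknown"))
  res <- site_quality_filter(gm)
  keep_oracle <- which(v$depth >= 4 & v$qual >= 20)
  expect_equal(variant_key(res$gm$variants), variant_key(v[keep_oracle, ]))
  # subset of input and idempotent
  expect_true(all(variant_key(res$gm$variants) %in% variant_key(v)))
  res2 <- site_quality_filter(res$gm)
  expect_equal(variant_key(res2$gm$variants), variant_key(res$gm$variants))
})
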