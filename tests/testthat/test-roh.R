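# relaxed parameters used for small constructed examples: tiny windows
# and lengths so segment structure is exercised on short genotype strings
relaxed_params <- function(...) {
  roh_params(window_snps = 3, min_length_bp = 1, max_kb_per_snp = 1e9,
             max_gap_bp = 1e9, window_missing_allow = 1,
             min_segment_snps = 3, ...)
}

test_that("forced small examples produce the segments the criteria dictate", {
  # fully heterozygous sample: no segments
  gm <- make_gm(matrix(1L, 1, 40), pos = seq(1, 2e6, length.out = 40))
  expect_equal(nrow(call_roh(gm)), 0)

  # 20 contiguous homozygous SNPs spanning 1.2 Mb flanked by hets:
  # exactly one segment containing those 20 SNPs
  dos <- c(1L, rep(0L, 20), 1L)
  pos <- as.integer(c(1000, seq(2000, 1202000, length.out = 20), 1300000))
  gm <- make_gm(matrix(dos, 1), pos = pos)
  seg <- call_roh(gm, roh_params(window_snps = 15, min_segment_snps = 15))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_snps, 20)
  expect_equal(seg$start_bp, 2000)
  expect_equal(seg$end_bp, 1202000)

  # 14 homozygous SNPs spanning 1.5 Mb: fails the minimum SNP count
  dos <- c(1L, rep(2L, 14), 1L)
  pos <- as.integer(c(500, seq(1000, 1501000, length.out = 14), 1600000))
  gm <- make_gm(matrix(dos, 1), pos = pos)
  expect_equal(nrow(call_roh(gm)), 0)
})

test_that("chromosomes shorter than the window produce a warning and no calls", {
  gm <- make_gm(matrix(0L, 1, 5), pos = (1:5) * 1e5)
  expect_warning(seg <- call_roh(gm), "fewer SNPs")
  expect_equal(nrow(seg), 0)
})

test_that("caller equals the brute-force oracle on random 300-SNP genotypes", {
  set.seed(31)
  params <- roh_params()
  for (rep in 1:25) {
    # block-structured genotypes so real runs occur
    m <- 300
    state <- 2L
    dos <- integer(m)
    for (j in seq_len(m)) {
      if (runif(1) < 0.04) state <- sample(0:2, 1)
      dos[j] <- if (state == 1L) 1L else sample(c(state, 1L), 1,
                                                prob = c(0.97, 0.03))
    }
    dos[runif(m) < 0.02] <- NA_integer_
    pos <- sort(sample(1:2e7, m))
    gm <- make_gm(matrix(dos, 1), pos = pos)
    seg <- call_roh(gm, params)
    orc <- roh_oracle_one(dos, pos, params)
    expect_equal(nrow(seg), nrow(orc))
    if (nrow(orc)) {
      expect_equal(seg$start_bp, pos[orc$start_idx])
      expect_equal(seg$end_bp, pos[orc$end_idx])
      expect_equal(seg$n_snps, orc$n_snps)
    }
  }
})

test_that("caller equals the oracle exhaustively on short genotype strings", {
  params <- relaxed_params()
  codes <- c(0L, 1L, 2L, NA_integer_)
  for (len in 3:7) {
    grid <- do.call(expand.grid, rep(list(codes), len))
    pos <- (seq_len(len)) * 1000L
    for (r in seq_len(nrow(grid))) {
      dos <- as.integer(grid[r, ])
      gm <- make_gm(matrix(dos, 1), pos = pos)
      seg <- call_roh(gm, params)
      orc <- roh_oracle_one(dos, pos, params)
      if (nrow(seg) != nrow(orc) ||
          (nrow(orc) && (any(seg$start_bp != pos[orc$start_idx]) ||
                         any(seg$end_bp != pos[orc$end_idx])))) {
        fail(sprintf("mismatch at len %d, genotypes [%s]", len,
                     paste(dos, collapse = ",")))
      }
    }
    succeed()
  }
})

test_that("every emitted segment satisfies the five criteria (independent audit)", {
  sim <- default_sim()
  params <- roh_params()
  seg <- call_roh(sim$wgs, params)
  expect_gt(nrow(seg), 0)
  v <- sim$wgs$variants
  for (r in seq_len(nrow(seg))) {
    j <- which(v$chrom == seg$chrom[r] & v$pos >= seg$start_bp[r] &
                 v$pos <= seg$end_bp[r])
    len <- seg$end_bp[r] - seg$start_bp[r] + 1
    expect_gte(seg$n_snps[r], params$min_segment_snps)
    expect_gte(len, params$min_length_bp)
    expect_lte(len / seg$n_snps[r], params$max_kb_per_snp * 1000)
    expect_lte(max(diff(v$pos[j])), params$max_gap_bp)
    dos <- sim$wgs$dosage[match(seg$sample_id[r],
                                sim$wgs$samples$sample_id), j]
    expect_equal(sum(dos == 1L, na.rm = TRUE), 0)  # strict het allowance
  }
})

test_that("raising the minimum length never increases the segment count", {
  sim <- default_sim()
  counts <- vapply(c(5e5, 1e6, 2e6, 4e6), function(L)
    nrow(call_roh(sim$wgs, roh_params(min_length_bp = L))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("autozygosity track equals a brute-force interval-stabbing count", {
  set.seed(32)
  gm <- make_gm(random_dosage(8, 50, 0), pos = (1:50) * 1e5,
                status = rep(c("affected", "unaffected"), each = 4))
  segs <- do.call(rbind, lapply(1:8, function(s) {
    k <- sample(0:2, 1)
    if (k == 0) return(NULL)
    st <- sort(sample(seq(1, 4.5e6, by = 5e5), k))
    data.frame(sample_id = paste0("s", s), chrom = "chr1",
               start_bp = st, end_bp = st + sample(c(4e5, 9e5), k, TRUE),
               n_snps = 5, length_bp = 0)
  }))
  tr <- autozygosity_track(segs, gm)
  for (j in seq_len(50)) {
    p <- gm$variants$pos[j]
    cover <- function(ids) mean(vapply(ids, function(s) {
      ss <- segs[segs$sample_id == s, , drop = FALSE]
      nrow(ss) > 0 && any(ss$start_bp <= p & ss$end_bp >= p)
    }, logical(1)))
    expect_equal(tr$frac_affected[j], cover(paste0("s", 1:4)))
    expect_equal(tr$frac_unaffected[j], cover(paste0("s", 5:8)))
  }
  # no segments: all-zero track
  empty <- segs[0, ]
  tr0 <- autozygosity_track(empty, gm)
  expect_true(all(tr0$frac_affected == 0) && all(tr0$frac_unaffected == 0))
  # a shared segment gives track 1 inside and 0 outside
  one <- do.call(rbind, lapply(paste0("s", 1:8), function(s)
    data.frame(sample_id = s, chrom = "chr1", start_bp = 1e6,
               end_bp = 2e6, n_snps = 10, length_bp = 1e6 + 1)))
  tr1 <- autozygosity_track(one, gm)
  inside <- gm$variants$pos >= 1e6 & gm$variants$pos <= 2e6
  expect_true(all(tr1$frac_affected[inside] == 1))
  expect_true(all(tr1$frac_affected[!inside] == 0))
})

test_that("candidate regions match a brute-force scan of the two thresholds", {
  set.seed(33)
  for (rep in 1:20) {
    m <- 60
    pos <- sort(sample(1:2e7, m))
    track <- data.frame(chrom = "chr1", pos = pos,
                        frac_affected = round(runif(m), 2),
                        frac_unaffected = round(runif(m, 0, 0.4), 2))
    reg <- contrast_candidate_regions(track, merge_gap_bp = 0)
    ok <- track$frac_affected >= 0.7 & track$frac_unaffected <= 0.2
    # brute force maximal runs
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    exp_reg <- data.frame(start = pos[starts[runs$values]],
                          end = pos[ends[runs$values]])
    expect_equal(nrow(reg), nrow(exp_reg))
    if (nrow(reg)) {
      expect_equal(reg$start_bp, exp_reg$start)
      expect_equal(reg$end_bp, exp_reg$end)
    }
  }
  # degenerate thresholds: one region spanning all SNPs per chromosome
  track <- data.frame(chrom = rep(c("c1", "c2"), each = 10),
                      pos = rep((1:10) * 1e6, 2),
                      frac_affected = runif(20),
                      frac_unaffected = runif(20))
  reg <- contrast_candidate_regions(track, case_min = 0, control_max = 1)
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start_bp, c(1e6, 1e6))
  expect_equal(reg$end_bp, c(1e7, 1e7))
})

test_that("region delineation follows an autozygosity drop like the mapped locus", {
  # case autozygosity 0.86 up to 4.74 Mb then dropping, controls low:
  # the region ends at the last SNP before the drop
  pos <- seq(1e5, 8e6, by = 1e5)
  aff <- ifelse(pos < 4741065, 0.86, 0.3)
  un <- rep(0.14, length(pos))
  track <- data.frame(chrom = "chr17", pos = pos, frac_affected = aff,
                      frac_unaffected = un)
  reg <- contrast_candidate_regions(track)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start_bp, 1e5)
  expect_equal(reg$end_bp, max(pos[pos < 4741065]))
  expect_equal(reg$mean_case_autozygosity, 0.86)
})

test_that("ROH burden counts segments at or above the length threshold", {
  segs <- data.frame(sample_id = c("a", "a", "b"), chrom = "chr1",
                     start_bp = c(1, 1, 1),
                     end_bp = c(1.5e6, 2.5e6, 3e6),
                     n_snps = 20,
                     length_bp = c(1.5e6, 2.5e6, 3e6))
  b <- roh_burden(segs, sample_ids = c("a", "b", "c"))
  expect_equal(b$n_segments, c(1, 1, 0))
  expect_equal(b$total_length_bp, c(2.5e6, 3e6, 0))

  sim <- default_sim()
  seg <- call_roh(sim$wgs)
  bb <- roh_burden(seg, sample_ids = sim$wgs$samples$sample_id)
  aff <- sim$wgs$samples$status == "affected"
  expect_gt(mean(bb$n_segments[aff]), mean(bb$n_segments[!aff]))
})
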