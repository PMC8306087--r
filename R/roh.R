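#' ROH detection parameters
#'
#' Sliding-window criteria for run-of-homozygosity detection:
#' (i) scanning-window size in SNPs (also the default minimum SNP count
#' of a final segment), (ii) minimum segment length, (iii) maximum
#' inverse SNP density, (iv) maximum gap between consecutive SNPs inside
#' a segment, (v) minimum fraction of homozygous scanning windows
#' containing a SNP for the SNP to enter a run.  Window tolerance for
#' heterozygous and missing calls is configurable; the defaults (0 hets,
#' 1 missing) are strict because 15-SNP windows are short.
#'
#' @param window_snps scanning-window size (default 15).
#' @param min_length_bp minimum segment length (default 1e6).
#' @param max_kb_per_snp maximum inverse density, kb per SNP
#'   (default 100).
#' @param max_gap_bp maximum inter-SNP gap inside a segment
#'   (default 1e6).
#' @param window_hit_rate minimum homozygous-window hit rate
#'   (default 0.05, inclusive).
#' @param window_het_allow heterozygous calls tolerated per window
#'   (default 0).
#' @param window_missing_allow missing calls tolerated per window
#'   (default 1).
#' @param min_segment_snps minimum SNPs per final segment (default
#'   `window_snps`).
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 15, min_length_bp = 1e6,
                       max_kb_per_snp = 100, max_gap_bp = 1e6,
                       window_hit_rate = 0.05, window_het_allow = 0,
                       window_missing_allow = 1,
                       min_segment_snps = window_snps) {
  stopifnot(window_snps >= 2, window_hit_rate > 0, window_hit_rate <= 1,
            min_length_bp > 0, max_kb_per_snp > 0, max_gap_bp > 0)
  structure(as.list(environment()), class = "roh_params")
}

# ROH calling for one genotype vector; returns data.frame(start_idx,
# end_idx, n_snps) of index runs surviving all criteria
roh_one <- function(dos, pos, params) {
  m <- length(dos)
  w <- params$window_snps
  if (m < w) return(NULL)
  het <- as.integer(!is.na(dos) & dos == 1L)
  mis <- as.integer(is.na(dos))
  n_win <- m - w + 1L
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  starts <- seq_len(n_win)
  hom_win <- (ch[starts + w] - ch[starts]) <= params$window_het_allow &
    (cm[starts + w] - cm[starts]) <= params$window_missing_allow
  chw <- c(0L, cumsum(as.integer(hom_win)))
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(seq_len(m), n_win)
  n_cover <- hi - lo + 1L
  n_hom <- chw[hi + 1L] - chw[lo]
  hit <- n_hom / n_cover
  eligible <- hit >= params$window_hit_rate & (het == 0L)
  # split eligible stretches at large gaps
  brk <- c(FALSE, diff(pos) > params$max_gap_bp)
  run_id <- cumsum(!eligible | brk)
  idx <- which(eligible)
  if (!length(idx)) return(NULL)
  grp <- split(idx, run_id[idx])
  out <- lapply(grp, function(ii) {
    n <- length(ii)
    len <- pos[ii[n]] - pos[ii[1]] + 1L
    if (n < params$min_segment_snps) return(NULL)
    if (len < params$min_length_bp) return(NULL)
    if (len / n > params$max_kb_per_snp * 1000) return(NULL)
    data.frame(start_idx = ii[1], end_idx = ii[n], n_snps = n)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Detect runs of homozygosity
#'
#' Sliding-window ROH detection per sample and chromosome under the five
#' criteria of [roh_params()].  A window is homozygous when it contains
#' at most `window_het_allow` heterozygous and `window_missing_allow`
#' missing calls; a SNP enters a run when the fraction of homozygous
#' windows covering it reaches `window_hit_rate` and its own call is
#' homozygous or missing.  Maximal runs are split at gaps above
#' `max_gap_bp` and filtered on SNP count, length and density.  Windows
#' truncated at chromosome ends are not scanned; chromosomes with fewer
#' SNPs than the window produce no calls (with a warning).
#'
#' @param gm a sorted `genotype_matrix`.
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample_id`, `chrom`, `start_bp`,
#'   `end_bp` (1-based inclusive), `n_snps`, `length_bp`.
#' @export
call_roh <- function(gm, params = roh_params()) {
  validate_genotype_matrix(gm)
  chroms <- unique(gm$variants$chrom)
  res <- list()
  for (chr in chroms) {
    j <- which(gm$variants$chrom == chr)
    if (length(j) < params$window_snps) {
      warning("chromosome ", chr, " has fewer SNPs (", length(j),
              ") than the scanning window; no calls")
      next
    }
    pos <- gm$variants$pos[j]
    for (s in seq_len(n_samples(gm))) {
      seg <- roh_one(gm$dosage[s, j], pos, params)
      if (is.null(seg)) next
      res[[length(res) + 1L]] <- data.frame(
        sample_id = gm$samples$sample_id[s], chrom = chr,
        start_bp = pos[seg$start_idx], end_bp = pos[seg$end_idx],
        n_snps = seg$n_snps, stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(sample_id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out$length_bp <- out$end_bp - out$start_bp + 1L
  rownames(out) <- NULL
  out
}

#' Per-position autozygosity by group
#'
#' For every variant position, the fraction of each group's samples whose
#' ROH calls cover the position.  Groups are the non-excluded affected
#' and unaffected samples of `gm`.
#'
#' @param segments output of [call_roh()].
#' @param gm the `genotype_matrix` the segments came from (supplies the
#'   variant index and sample groups).
#' @return data.frame: `chrom`, `pos`, `frac_affected`,
#'   `frac_unaffected`.
#' @export
autozygosity_track <- function(segments, gm) {
  keep <- !gm$samples$excluded
  cases <- gm$samples$sample_id[keep & gm$samples$status == "affected"]
  ctrls <- gm$samples$sample_id[keep & gm$samples$status == "unaffected"]
  if (!length(cases) || !length(ctrls))
    stop("both affected and unaffected groups must be non-empty")
  v <- gm$variants
  cover <- function(ids) {
    cnt <- numeric(nrow(v))
    seg <- segments[segments$sample_id %in% ids, , drop = FALSE]
    for (s in ids) {
      ss <- seg[seg$sample_id == s, , drop = FALSE]
      if (!nrow(ss)) next
      hitv <- logical(nrow(v))
      for (r in seq_len(nrow(ss)))
        hitv <- hitv | (v$chrom == ss$chrom[r] & v$pos >= ss$start_bp[r] &
                          v$pos <= ss$end_bp[r])
      cnt <- cnt + hitv
    }
    cnt / length(ids)
  }
  data.frame(chrom = v$chrom, pos = v$pos,
             frac_affected = cover(cases),
             frac_unaffected = cover(ctrls),
             stringsAsFactors = FALSE)
}

#' Delineate candidate regions from the autozygosity contrast
#'
#' Maximal intervals of consecutive variant positions where case
#' autozygosity is at least `case_min` and control autozygosity at most
#' `control_max`.  Intervals on a chromosome separated by less than
#' `merge_gap_bp` are merged; the result may be widened by `pad_bp` and
#' is clipped to chromosome bounds when `chrom_lengths` is given.
#'
#' @param track output of [autozygosity_track()].
#' @param case_min minimum case autozygosity (default 0.7).
#' @param control_max maximum control autozygosity (default 0.2).
#' @param pad_bp symmetric padding of the reported interval (default 0).
#' @param merge_gap_bp merge distance (default 1e6).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data.frame: `chrom`, `start_bp`, `end_bp`,
#'   `mean_case_autozygosity`, `mean_control_autozygosity`.
#' @export
contrast_candidate_regions <- function(track, case_min = 0.7,
                                       control_max = 0.2, pad_bp = 0,
                                       merge_gap_bp = 1e6,
                                       chrom_lengths = NULL) {
  out <- list()
  for (chr in unique(track$chrom)) {
    t <- track[track$chrom == chr, , drop = FALSE]
    ok <- t$frac_affected >= case_min & t$frac_unaffected <= control_max
    if (!any(ok)) next
    run <- cumsum(c(TRUE, diff(ok) != 0))
    ivs <- do.call(rbind, lapply(split(which(ok), run[ok]), function(ii)
      c(start = t$pos[ii[1]], end = t$pos[ii[length(ii)]])))
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    merged <- ivs[1, , drop = FALSE]
    if (nrow(ivs) > 1) for (r in 2:nrow(ivs)) {
      if (ivs[r, 1] - merged[nrow(merged), 2] < merge_gap_bp) {
        merged[nrow(merged), 2] <- ivs[r, 2]
      } else merged <- rbind(merged, ivs[r, , drop = FALSE])
    }
    for (r in seq_len(nrow(merged))) {
      s <- max(1, merged[r, 1] - pad_bp)
      e <- merged[r, 2] + pad_bp
      if (!is.null(chrom_lengths) && chr %in% names(chrom_lengths))
        e <- min(e, chrom_lengths[[chr]])
      inside <- t$pos >= merged[r, 1] & t$pos <= merged[r, 2]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start_bp = as.integer(s), end_bp = as.integer(e),
        mean_case_autozygosity = mean(t$frac_affected[inside]),
        mean_control_autozygosity = mean(t$frac_unaffected[inside]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start_bp = integer(),
                      end_bp = integer(),
                      mean_case_autozygosity = numeric(),
                      mean_control_autozygosity = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Per-sample ROH burden
#'
#' Number and total length of ROH segments at or above a length
#' threshold, one row per sample (samples without qualifying segments get
#' zeros).
#'
#' @param segments output of [call_roh()].
#' @param sample_ids samples to report (default: those present in
#'   `segments`).
#' @param min_len_bp length threshold (default 2e6).
#' @return data.frame: `sample_id`, `n_segments`, `total_length_bp`.
#' @export
roh_burden <- function(segments, sample_ids = NULL, min_len_bp = 2e6) {
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  big <- segments[segments$length_bp >= min_len_bp, , drop = FALSE]
  n <- vapply(sample_ids, function(s) sum(big$sample_id == s), integer(1))
  tot <- vapply(sample_ids, function(s)
    sum(big$length_bp[big$sample_id == s]), numeric(1))
  data.frame(sample_id = sample_ids, n_segments = n,
             total_length_bp = tot, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export candidate regions as BED
#'
#' Converts internal 1-based closed intervals to BED's 0-based half-open
#' convention.
#'
#' @param regions output of [contrast_candidate_regions()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(
    data.frame(regions$chrom, regions$start_bp - 1L, regions$end_bp),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(path)
}
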