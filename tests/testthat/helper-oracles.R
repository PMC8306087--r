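# Independent brute-force oracles used to cross-check the package
# implementations.  These are deliberately naive re-implementations
# written from the method definitions, not calls into the package code.

# --- ROH: naive sliding-window caller ------------------------------------
roh_oracle_one <- function(dos, pos, p) {
  m <- length(dos)
  w <- p$window_snps
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      n_snps = integer())
  if (m < w) return(empty)
  n_win <- m - w + 1
  win_hom <- vapply(seq_len(n_win), function(i) {
    win <- dos[i:(i + w - 1)]
    sum(win == 1, na.rm = TRUE) <= p$window_het_allow &&
      sum(is.na(win)) <= p$window_missing_allow
  }, logical(1))
  elig <- vapply(seq_len(m), function(j) {
    ws <- max(1, j - w + 1):min(j, n_win)
    hr <- mean(win_hom[ws])
    own <- is.na(dos[j]) || dos[j] != 1
    hr >= p$window_hit_rate && own
  }, logical(1))
  segs <- list()
  start <- NULL
  for (j in seq_len(m)) {
    if (elig[j]) {
      if (is.null(start)) {
        start <- j
      } else if (pos[j] - pos[j - 1] > p$max_gap_bp) {
        segs[[length(segs) + 1]] <- c(start, j - 1)
        start <- j
      }
    } else if (!is.null(start)) {
      segs[[length(segs) + 1]] <- c(start, j - 1)
      start <- NULL
    }
  }
  if (!is.null(start)) segs[[length(segs) + 1]] <- c(start, m)
  keep <- list()
  for (se in segs) {
    n <- se[2] - se[1] + 1
    len <- pos[se[2]] - pos[se[1]] + 1
    if (n >= p$min_segment_snps && len >= p$min_length_bp &&
        len / n <= p$max_kb_per_snp * 1000)
      keep[[length(keep) + 1]] <- data.frame(start_idx = se[1],
                                             end_idx = se[2], n_snps = n)
  }
  if (!length(keep)) return(empty)
  do.call(rbind, keep)
}

# --- Fisher/Freeman-Halton: full enumeration over fixed margins ---------
fisher_oracle <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  logp_tab <- function(x) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(x))
  }
  obs <- logp_tab(tab)
  total <- 0
  R <- nrow(tab); C <- ncol(tab)
  # enumerate non-negative tables with the given margins: rows 1..R-1
  # are filled cell by cell (last column forced), row R is forced
  x <- matrix(0L, R, C)
  rec <- function(r, c, row_rem, col_rem) {
    if (r == R) {
      x[R, ] <<- col_rem
      lp <- logp_tab(x)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (c == C) {
      v <- row_rem
      if (v <= col_rem[C]) {
        x[r, C] <<- v
        cc <- col_rem; cc[C] <- cc[C] - v
        rec(r + 1, 1, rs[r + 1], cc)
      }
      return()
    }
    for (v in 0:min(row_rem, col_rem[c])) {
      x[r, c] <<- v
      cc <- col_rem; cc[c] <- cc[c] - v
      rec(r, c + 1, row_rem - v, cc)
    }
  }
  rec(1, 1, rs[1], cs)
  min(1, total)
}

# --- GLS: direct dense-covariance fit of one SNP ------------------------
gls_oracle <- function(y, W, x, V) {
  X <- cbind(W, x)
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- solve(XtVi %*% X)
  b <- A %*% XtVi %*% y
  r <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- drop(t(r) %*% Vi %*% r) / df
  vb <- sigma2 * A
  k <- ncol(X)
  beta <- b[k]
  se <- sqrt(vb[k, k])
  wald <- (beta / se)^2
  list(beta = beta, se = se, wald = wald,
       p = stats::pf(wald, 1, df, lower.tail = FALSE))
}

# --- small genotype-matrix builder --------------------------------------
make_gm <- function(dosage, pos = NULL, chrom = "chr1", status = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(status)) status <- rep("unknown", n)
  genotype_matrix(
    dosage,
    data.frame(chrom = rep(chrom, m), pos = as.integer(pos),
               ref = rep("A", m), alt = rep("G", m),
               stringsAsFactors = FALSE),
    data.frame(sample_id = paste0("s", seq_len(n)), status = status,
               excluded = FALSE, stringsAsFactors = FALSE))
}

# deterministic small random dosage matrices (with missing values)
random_dosage <- function(n, m, miss = 0.05) {
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA_integer_
  d
}

# a small cached default simulation shared across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(sim_config(seed = 42))
    cache
  }
})
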