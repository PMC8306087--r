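#' REML estimate of the variance ratio
#'
#' Restricted maximum-likelihood estimate of `lambda`, the ratio of
#' genetic to residual variance in the model
#' `y = W alpha + g + e`, `g ~ N(0, lambda tau^-1 G)`,
#' `e ~ N(0, tau^-1 I)`.  The GRM is eigendecomposed once; the profiled
#' restricted likelihood is maximized over `log10(lambda)` in `[-5, 5]`
#' by a coarse 21-point grid followed by Brent search on the bracketing
#' interval.
#'
#' @param y numeric response (0/1 affection status treated
#'   quantitatively).
#' @param covariates fixed-effect design matrix `W` (default: intercept
#'   only).
#' @param grm_eigen eigendecomposition of the GRM as returned by
#'   [eigen()] (symmetric = TRUE).
#' @param psd_tol tolerance on negative GRM eigenvalues (default 1e-6
#'   relative to the largest).
#' @return list with `lambda` (the REML estimate), `loglik` (restricted
#'   log-likelihood up to a constant) and `grid` (the coarse profile).
#' @export
reml_lambda <- function(y, covariates = NULL, grm_eigen, psd_tol = 1e-6) {
  n <- length(y)
  if (is.null(covariates)) covariates <- matrix(1, n, 1)
  W <- as.matrix(covariates)
  ev <- grm_eigen$values
  if (min(ev) < -psd_tol * max(abs(ev)))
    stop("GRM is not positive semi-definite (min eigenvalue ",
         format(min(ev)), "); add a small diagonal jitter")
  ev <- pmax(ev, 0)
  U <- grm_eigen$vectors
  yt <- crossprod(U, y)
  Wt <- crossprod(U, W)
  c_ <- ncol(W)
  restricted_ll <- function(log10_lambda) {
    lam <- 10^log10_lambda
    d <- lam * ev + 1
    wd <- Wt / d
    WtHW <- crossprod(Wt, wd)
    beta <- solve(WtHW, crossprod(wd, yt))
    r <- yt - Wt %*% beta
    rss <- sum(r^2 / d)
    -0.5 * (sum(log(d)) + determinant(WtHW)$modulus[1] +
              (n - c_) * log(rss))
  }
  grid <- seq(-5, 5, length.out = 21)
  ll <- vapply(grid, restricted_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(restricted_ll, c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  best <- if (opt$objective >= ll[i]) opt else
    list(maximum = grid[i], objective = ll[i])
  list(lambda = 10^best$maximum, loglik = best$objective,
       grid = data.frame(log10_lambda = grid, loglik = ll))
}

#' Linear mixed model association scan
#'
#' Univariate LMM scan of a quantitative (here 0/1) phenotype with a
#' polygenic random effect structured by the standardized GRM.  `lambda`
#' is estimated once under the null model and reused for every SNP
#' (set `per_snp_lambda = TRUE` to re-estimate per SNP).  Each SNP's
#' effect is the GLS estimate in the GRM eigenbasis; significance is a
#' two-sided Wald test against `F(1, n - c - 1)`.  SNPs failing the scan
#' filter (MAF below `maf_min`, missing rate above `max_missing`) are
#' dropped before testing; remaining missing dosages are imputed to the
#' variant mean.
#'
#' @param gm a `genotype_matrix`; samples with unknown status are
#'   excluded.
#' @param grm GRM over the same samples as `gm` (default: computed from
#'   `gm`).
#' @param covariates optional fixed-effect matrix (intercept added
#'   automatically... supplied matrix must not contain it).
#' @param maf_min scan MAF filter (default 0.01; SNPs with MAF below are
#'   dropped).
#' @param max_missing scan missingness filter (default 0.05).
#' @param per_snp_lambda re-estimate `lambda` per SNP (default FALSE).
#' @return list with `results` (data.frame: chrom, pos, ref, alt, maf,
#'   beta, se, wald_stat, p, minus_log10_p, flag), `lambda`, and
#'   `n_filtered` (SNPs discarded by the scan filter).
#' @export
lmm_scan <- function(gm, grm = NULL, covariates = NULL, maf_min = 0.01,
                     max_missing = 0.05, per_snp_lambda = FALSE) {
  known <- gm$samples$status %in% c("affected", "unaffected")
  n_all <- n_samples(gm)
  gm <- gm[known, ]
  y <- as.numeric(gm$samples$status == "affected")
  n <- length(y)
  if (is.null(grm)) grm <- grm_standardized(gm)
  grm <- if (!is.null(dimnames(grm))) {
    grm[gm$samples$sample_id, gm$samples$sample_id]
  } else if (nrow(grm) == n_all) {
    grm[known, known, drop = FALSE]
  } else if (nrow(grm) == n) {
    grm
  } else stop("GRM dimension matches neither the full nor the ",
              "known-status sample set")

  maf <- minor_allele_freq(gm)
  maf[is.nan(maf)] <- 0
  miss <- variant_missing_rate(gm)
  keep <- maf >= maf_min & miss <= max_missing
  n_filtered <- sum(!keep)
  gm <- gm[, keep]
  maf <- maf[keep]

  W <- if (is.null(covariates)) matrix(1, n, 1) else
    cbind(1, as.matrix(covariates))
  c_ <- ncol(W)
  eg <- eigen(grm, symmetric = TRUE)
  null_fit <- reml_lambda(y, W, eg)
  lam <- null_fit$lambda

  U <- eg$vectors
  ev <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  Wt <- crossprod(U, W)
  X <- gm$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  Xt <- crossprod(U, X)

  m <- ncol(Xt)
  beta <- se <- wald <- pval <- rep(NA_real_, m)
  flag <- character(m)
  df <- n - c_ - 1
  for (j in seq_len(m)) {
    if (per_snp_lambda)
      lam <- reml_lambda(y, cbind(W, X[, j]), eg)$lambda
    d <- lam * ev + 1
    D <- cbind(Wt, Xt[, j])
    dd <- D / d
    XtHX <- crossprod(D, dd)
    # zero variance of the SNP after projecting out covariates
    s_xx <- XtHX[c_ + 1, c_ + 1] -
      XtHX[c_ + 1, 1:c_, drop = FALSE] %*%
      solve(XtHX[1:c_, 1:c_, drop = FALSE],
            XtHX[1:c_, c_ + 1, drop = FALSE])
    if (s_xx < 1e-12) {
      pval[j] <- 1; flag[j] <- "zero_variance"; next
    }
    bh <- solve(XtHX, crossprod(dd, yt))
    r <- yt - D %*% bh
    sigma2 <- sum(r^2 / d) / df
    vb <- sigma2 * solve(XtHX)
    beta[j] <- bh[c_ + 1]
    se[j] <- sqrt(vb[c_ + 1, c_ + 1])
    wald[j] <- (beta[j] / se[j])^2
    # floored so p stays in (0, 1] even when the F tail underflows
    pval[j] <- max(stats::pf(wald[j], 1, df, lower.tail = FALSE),
                   2.2e-308)
  }
  res <- data.frame(chrom = gm$variants$chrom, pos = gm$variants$pos,
                    ref = gm$variants$ref, alt = gm$variants$alt,
                    maf = maf, beta = beta, se = se, wald_stat = wald,
                    p = pval, minus_log10_p = -log10(pval), flag = flag,
                    stringsAsFactors = FALSE)
  list(results = res, lambda = null_fit$lambda, n_filtered = n_filtered)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return the threshold on the -log10(p) scale: `-log10(alpha / m)`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  -log10(alpha / m)
}

#' Quantile-quantile data and genomic inflation
#'
#' Sorted observed versus uniform expected -log10(p) pairs, plus the
#' genomic inflation factor `lambda_gc` = median observed 1-df chi-square
#' quantile / 0.4549 (the median of the chi-square(1) distribution).
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return list with `data` (data.frame: expected, observed) and
#'   `lambda_gc`.
#' @export
qq_data <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no p-values supplied")
  stopifnot(all(p > 0 & p <= 1))
  n <- length(p)
  obs <- -log10(sort(p))
  expd <- -log10((seq_len(n) - 0.5) / n)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(data = data.frame(expected = expd, observed = obs),
       lambda_gc = stats::median(chisq) / stats::qchisq(0.5, df = 1))
}
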