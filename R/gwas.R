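#' Single-marker association scan
#'
#' Per SNP, fits the analysis-of-variance model
#' \code{phenotype ~ block + dosage} (block a fixed factor, SNP an additive
#' dosage covariate, 1 df) and reports the F-test p-value for the SNP term.
#' Missing dosages are excluded casewise per SNP; SNPs are pre-filtered on
#' MAF and missingness. Benjamini-Hochberg q-values and the two
#' significance flags (FDR \code{q <= fdr_alpha}; hard \code{p <
#' hard_p}) are attached.
#'
#' For speed, SNPs without missing data are tested in one vectorized pass:
#' phenotype and dosages are residualized on the block design, and the SNP
#' F statistic is formed from the squared partial correlation.
#'
#' @param y named phenotype vector (BLUEs), one per sample.
#' @param vm a [variant_matrix()] covering the phenotyped samples.
#' @param block per-genotype factor (e.g. maturity group), aligned with
#'   \code{y}; a single level degenerates to a plain intercept.
#' @param maf_min,miss_max SNP filters applied first (defaults 0.05 / 0.2).
#' @param fdr_alpha FDR threshold (default 0.001).
#' @param hard_p hard p-value threshold (default 1e-10).
#' @return data frame of class \code{assoc_result}: \code{chrom, pos,
#'   effect, stat, p, q, n_used, significant_fdr, significant_hard}; SNPs
#'   with fewer than 3 informative samples get NA results.
#' @export
gwas_scan <- function(y, vm, block = NULL, maf_min = 0.05, miss_max = 0.2,
                      fdr_alpha = 0.001, hard_p = 1e-10) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (!is.null(names(y))) {
    ord <- match(vm$sample_ids, names(y))
    if (anyNA(ord)) stop("phenotypes missing for some samples")
    y <- y[ord]
  } else stopifnot(length(y) == nrow(vm$dosage))
  vm <- filter_variants(vm, maf_min = maf_min, miss_max = miss_max)
  n <- length(y)
  if (is.null(block)) block <- rep(1, n)
  B <- if (length(unique(block)) < 2) matrix(1, n, 1)
    else stats::model.matrix(~ factor(block))
  qrB <- qr(B)
  pB <- qrB$rank
  D <- vm$dosage
  m <- ncol(D)
  eff <- stat <- pval <- rep(NA_real_, m)
  n_used <- rep(NA_integer_, m)

  ry <- stats::residuals(stats::lm.fit(B, y))
  complete <- !colSums(is.na(D))
  if (any(complete)) {
    Dc <- D[, complete, drop = FALSE]
    RD <- Dc - B %*% qr.coef(qrB, Dc)
    sxy <- drop(crossprod(RD, ry))
    sxx <- colSums(RD^2)
    syy <- sum(ry^2)
    df <- n - pB - 1
    ok <- sxx > 1e-12
    b <- ifelse(ok, sxy / sxx, NA_real_)
    rss <- syy - ifelse(ok, sxy^2 / sxx, 0)
    Fst <- ifelse(ok, (sxy^2 / sxx) / (rss / df), NA_real_)
    eff[complete] <- b
    stat[complete] <- Fst
    pval[complete] <- stats::pf(Fst, 1, df, lower.tail = FALSE)
    n_used[complete] <- n
  }
  for (j in which(!complete)) {
    use <- !is.na(D[, j])
    nj <- sum(use)
    n_used[j] <- nj
    if (nj < 3) next
    Bj <- B[use, , drop = FALSE]
    xj <- D[use, j]
    fit0 <- stats::lm.fit(Bj, y[use])
    fitA <- stats::lm.fit(cbind(Bj, xj), y[use])
    dfj <- nj - fitA$rank
    if (dfj < 1 || fitA$rank <= fit0$rank) next
    rss0 <- sum(fit0$residuals^2)
    rssA <- sum(fitA$residuals^2)
    Fj <- (rss0 - rssA) / (rssA / dfj)
    eff[j] <- fitA$coefficients[length(fitA$coefficients)]
    stat[j] <- Fj
    pval[j] <- stats::pf(Fj, 1, dfj, lower.tail = FALSE)
  }
  q <- rep(NA_real_, m)
  okp <- !is.na(pval)
  q[okp] <- stats::p.adjust(pval[okp], method = "BH")
  out <- data.frame(chrom = vm$chrom, pos = vm$pos,
                    effect = eff, stat = stat, p = pval, q = q,
                    n_used = n_used,
                    significant_fdr = !is.na(q) & q <= fdr_alpha,
                    significant_hard = !is.na(pval) & pval < hard_p)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up adjusted q-values (monotone) and the rejection set at
#' \code{alpha}.
#'
#' @param p vector of p-values in [0, 1].
#' @param alpha FDR level (default 0.001).
#' @return list: \code{q} (adjusted values, input order), \code{reject}
#'   (logical), \code{n_rejected}.
#' @export
bh_fdr <- function(p, alpha = 0.001) {
  if (!length(p)) return(list(q = numeric(0), reject = logical(0),
                              n_rejected = 0L))
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha,
       n_rejected = sum(q <= alpha, na.rm = TRUE))
}

#' Quantile-quantile calibration of a p-value set
#'
#' Pairs the sorted observed \eqn{-\log_{10} p} with the expected
#' \eqn{-\log_{10}((i - 0.5)/m)} and reports the genomic inflation factor
#' \eqn{\lambda} (median observed 1-df chi-squared statistic over its
#' theoretical median).
#'
#' @param p vector of >= 10 p-values.
#' @return list of class \code{qq_calibration}: \code{expected},
#'   \code{observed} (-log10 scale, ascending) and \code{lambda}.
#' @export
qq_calibration <- function(p) {
  p <- p[!is.na(p)]
  m <- length(p)
  if (m < 10) stop("need >= 10 p-values")
  obs <- sort(-log10(pmax(p, 1e-300)))
  expd <- sort(-log10((seq_len(m) - 0.5) / m))
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  structure(list(expected = expd, observed = obs,
                 lambda = stats::median(chi) / stats::qchisq(0.5, 1)),
            class = "qq_calibration")
}

#' @export
print.qq_calibration <- function(x, ...) {
  cat(sprintf("qq_calibration: %d p-values, lambda = %.3f\n",
              length(x$observed), x$lambda))
  invisible(x)
}
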