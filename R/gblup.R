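#' Fit a G-BLUP model
#'
#' Single-kernel animal model \eqn{y = 1_n\mu + g + e}, with
#' \eqn{g \sim N(0, \sigma^2_g G)} and \eqn{e \sim N(0, \sigma^2_e I)}.
#' \eqn{\mu} is estimated by generalized least squares under
#' \eqn{V = \sigma^2_g G + \sigma^2_e I} and genomic values by
#' \eqn{\hat g = \sigma^2_g G V^{-1}(y - 1\hat\mu)}. When variance
#' components are not supplied they are estimated by REML on the
#' eigendecomposition of \eqn{G} (profile likelihood in the ratio
#' \eqn{\delta = \sigma^2_e/\sigma^2_g}). All solves are performed in the
#' eigenbasis of \eqn{G}, which stays exact down to \eqn{\sigma^2_e = 0};
#' a numerically singular \eqn{V} has its deficient eigenvalues floored
#' (a minimal directional jitter), with a message.
#'
#' @param y named phenotype vector (names matched against kinship ids) or a
#'   bare vector aligned with \code{K}; missing phenotypes are dropped
#'   casewise.
#' @param K a [grm()] kinship or a plain symmetric matrix with dimnames.
#' @param varcomp optional numeric \code{c(sigma2_g, sigma2_e)}.
#' @return object of class \code{gblup_model}: \code{mu}, \code{sigma2_g},
#'   \code{sigma2_e}, \code{g_hat}, \code{training_ids}, and the
#'   precomputed \code{Vinv_resid} used by [predict_gblup()].
#' @export
fit_gblup <- function(y, K, varcomp = NULL) {
  G <- if (inherits(K, "kinship")) K$G else as.matrix(K)
  ids <- rownames(G)
  if (!is.null(names(y)) && !is.null(ids)) {
    keep <- intersect(ids, names(y)[!is.na(y)])
    y <- y[keep]
    G <- G[keep, keep, drop = FALSE]
  } else {
    stopifnot(length(y) == nrow(G))
    keep <- !is.na(y)
    y <- y[keep]; G <- G[keep, keep, drop = FALSE]
    if (is.null(rownames(G))) dimnames(G) <- list(seq_along(y), seq_along(y))
  }
  n <- length(y)
  if (n < 3) stop("need >= 3 phenotyped samples")

  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  yr <- drop(crossprod(eg$vectors, y))
  xr <- drop(crossprod(eg$vectors, rep(1, n)))
  if (is.null(varcomp)) {
    prof <- function(logd) {
      d <- exp(logd)
      w <- 1 / (lam + d)
      mu <- sum(xr * yr * w) / sum(xr^2 * w)
      r2 <- sum((yr - xr * mu)^2 * w)
      s2g <- r2 / (n - 1)
      0.5 * ((n - 1) * log(s2g) + sum(log(lam + d)) + log(sum(xr^2 * w)))
    }
    opt <- stats::optimize(prof, c(-12, 12))
    d <- exp(opt$minimum)
    w <- 1 / (lam + d)
    mu0 <- sum(xr * yr * w) / sum(xr^2 * w)
    s2g <- sum((yr - xr * mu0)^2 * w) / (n - 1)
    varcomp <- c(sigma2_g = s2g, sigma2_e = s2g * d)
  }
  s2g <- varcomp[[1]]; s2e <- varcomp[[2]]
  if (s2g < 0 || s2e < 0) stop("variance components must be >= 0")

  # all solves in the eigenbasis of G: exact for any sigma2_e >= 0
  ev <- s2g * lam + s2e
  if (max(ev) <= 0) stop("V is singular (all eigenvalues zero)")
  tiny <- ev < 1e-12 * max(ev)
  if (any(tiny)) {
    message("V nearly singular; flooring ", sum(tiny), " eigenvalue(s)")
    ev[tiny] <- 1e-12 * max(ev)
  }
  w <- 1 / ev
  mu <- sum(xr * yr * w) / sum(xr^2 * w)
  rr <- (yr - xr * mu) * w             # rotated V^-1 (y - 1 mu)
  Vinv_r <- drop(eg$vectors %*% rr)
  g_hat <- drop(eg$vectors %*% (s2g * lam * rr))
  names(g_hat) <- rownames(G)
  structure(list(mu = mu, sigma2_g = s2g, sigma2_e = s2e,
                 g_hat = g_hat, training_ids = rownames(G),
                 Vinv_resid = Vinv_r),
            class = "gblup_model")
}

#' @export
print.gblup_model <- function(x, ...) {
  cat(sprintf(
    "gblup_model: n = %d, mu = %.4g, sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f)\n",
    length(x$g_hat), x$mu, x$sigma2_g, x$sigma2_e,
    x$sigma2_g / (x$sigma2_g + x$sigma2_e)))
  invisible(x)
}

#' Predict genomic values for new samples
#'
#' \eqn{\hat g_{new} = \sigma^2_g K_{cross} V^{-1}(y - 1\hat\mu)}; the
#' returned values include the fitted mean. \code{K_cross} must come from
#' the same marker set and denominator convention as the training kinship
#' (e.g. by building one [grm()] over all samples and slicing it).
#'
#' @param model a [fit_gblup()] model.
#' @param K_cross matrix of relationships, new samples in rows, training
#'   samples in columns (dimnames used for alignment when present).
#' @return named vector of predicted genotypic values \eqn{\hat\mu + \hat g}.
#' @export
predict_gblup <- function(model, K_cross) {
  K_cross <- as.matrix(K_cross)
  if (!is.null(colnames(K_cross))) {
    if (!all(model$training_ids %in% colnames(K_cross)))
      stop("K_cross columns must cover all training samples")
    K_cross <- K_cross[, model$training_ids, drop = FALSE]
    if (!is.null(rownames(K_cross)) &&
        length(intersect(rownames(K_cross), model$training_ids)))
      stop("new samples overlap the training set")
  } else stopifnot(ncol(K_cross) == length(model$training_ids))
  drop(model$mu + model$sigma2_g * K_cross %*% model$Vinv_resid)
}

#' Cross-validated prediction accuracy
#'
#' Repeated k-fold cross-validation of G-BLUP: per run, samples are
#' randomly partitioned into \code{folds} folds; each fold is predicted
#' from a model fitted (REML variance components re-estimated) on the
#' remainder, and the run's accuracy is the mean over folds of the Pearson
#' correlation between predicted and observed values in the held-out fold
#' (computing r within each test set avoids the spurious negative
#' between-fold mean correlation of pooled cross-validation predictions).
#' Accuracies are also standardized by \eqn{\sqrt{h^2}}.
#'
#' @param y named phenotype vector.
#' @param K a [grm()] kinship covering the phenotyped samples.
#' @param folds number of folds (default 5).
#' @param runs number of cross-validation runs (default 100).
#' @param h2 heritability used for standardization, in (0, 1].
#' @param seed integer seed (partitions are reproducible).
#' @return object of class \code{cv_result}: per-run data frame \code{runs}
#'   (r, standardized accuracy), \code{summary} (mean and sd of both),
#'   \code{h2_used} and the fold scheme.
#' @export
cross_validate <- function(y, K, folds = 5L, runs = 100L, h2 = 1, seed = 1L) {
  stopifnot(h2 > 0, h2 <= 1, folds >= 2, runs >= 1)
  G <- if (inherits(K, "kinship")) K$G else as.matrix(K)
  ids <- intersect(rownames(G), names(y)[!is.na(y)])
  y <- y[ids]
  n <- length(y)
  if (floor(n / folds) < 3) stop("folds would contain fewer than 3 samples")
  r_run <- numeric(runs)
  with_temp_seed(seed, {
    for (run in seq_len(runs)) {
      fold_of <- sample(rep_len(seq_len(folds), n))
      r_fold <- numeric(folds)
      for (f in seq_len(folds)) {
        test <- ids[fold_of == f]
        train <- ids[fold_of != f]
        m <- fit_gblup(y[train], G[train, train, drop = FALSE])
        pred <- predict_gblup(m, G[test, model_ids(m), drop = FALSE])
        r_fold[f] <- stats::cor(pred, y[test])
      }
      r_run[run] <- mean(r_fold)
    }
  })
  std <- r_run / sqrt(h2)
  structure(list(
    runs = data.frame(run = seq_len(runs), r = r_run, standardized = std),
    summary = c(mean_r = mean(r_run), sd_r = stats::sd(r_run),
                mean_standardized = mean(std),
                sd_standardized = stats::sd(std)),
    h2_used = h2,
    scheme = list(folds = folds, runs = runs, seed = seed, n = n)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "cv_result: %d-fold x %d runs (n = %d)\n  r = %.3f +/- %.3f; r/sqrt(h2 = %.2f) = %.3f +/- %.3f\n",
    x$scheme$folds, x$scheme$runs, x$scheme$n,
    s["mean_r"], s["sd_r"], x$h2_used,
    s["mean_standardized"], s["sd_standardized"]))
  invisible(x)
}

model_ids <- function(m) m$training_ids
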