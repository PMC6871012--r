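#' Enumerate single-cross combinations
#'
#' All unordered parent pairs (i < j), optionally restricted to
#' between-group (B x R) crosses. 580 parents give choose(580, 2) = 167,910
#' pairs.
#'
#' @param parent_ids character vector of unique parent ids.
#' @param restrict_between_groups keep only pairs whose \code{groups}
#'   labels differ.
#' @param groups per-parent group labels (required when restricting).
#' @return data frame with columns \code{parent1}, \code{parent2}.
#' @export
enumerate_crosses <- function(parent_ids, restrict_between_groups = FALSE,
                              groups = NULL) {
  if (anyDuplicated(parent_ids)) stop("duplicate parent ids")
  n <- length(parent_ids)
  if (n < 2) stop("need >= 2 parents")
  idx <- utils::combn(n, 2)
  out <- data.frame(parent1 = parent_ids[idx[1, ]],
                    parent2 = parent_ids[idx[2, ]],
                    stringsAsFactors = FALSE)
  if (restrict_between_groups) {
    if (is.null(groups) || length(groups) != n)
      stop("groups required to restrict between-group crosses")
    g <- stats::setNames(groups, parent_ids)
    out <- out[g[out$parent1] != g[out$parent2], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Additive and dominance design rows for hybrids
#'
#' For inbred parents with dosages \eqn{d_1, d_2 \in \{0, 2\}} per marker:
#' the additive code is \eqn{Z_A = (d_1 + d_2)/2 - 1 \in \{-1, 0, 1\}} and
#' the dominance code \eqn{Z_D = 1} iff the parents carry different
#' homozygous genotypes (the hybrid is heterozygous).
#'
#' @param parents a fully inbred [variant_matrix()].
#' @param pairs two-column matrix/data frame of parent ids.
#' @return object of class \code{hybrid_design}: matrices \code{Z_A},
#'   \code{Z_D} (pairs x markers) and the \code{pairs} data frame.
#' @export
hybrid_design <- function(parents, pairs) {
  stopifnot(inherits(parents, "variant_matrix"))
  if (!is_inbred(parents))
    stop("parents must be homozygous at every marker")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("parent1", "parent2")
  i1 <- match(pairs$parent1, parents$sample_ids)
  i2 <- match(pairs$parent2, parents$sample_ids)
  if (anyNA(i1) || anyNA(i2)) stop("unknown parent id(s) in pairs")
  D <- parents$dosage
  Z_A <- (D[i1, , drop = FALSE] + D[i2, , drop = FALSE]) / 2 - 1
  Z_D <- (D[i1, , drop = FALSE] != D[i2, , drop = FALSE]) * 1
  rn <- paste(pairs$parent1, pairs$parent2, sep = " x ")
  dimnames(Z_A) <- dimnames(Z_D) <- list(rn, NULL)
  structure(list(Z_A = Z_A, Z_D = Z_D, pairs = pairs,
                 n_markers = ncol(D)),
            class = "hybrid_design")
}

#' Fit additive + dominance ridge-regression BLUP
#'
#' \eqn{y = 1_n\mu + Z_A a + Z_D d + e} with
#' \eqn{a \sim N(0, \sigma^2_a I_m)}, \eqn{d \sim N(0, \sigma^2_d I_m)}.
#' The mixed-model solution uses the kernel form
#' \eqn{V = \sigma^2_a Z_A Z_A^\top + \sigma^2_d Z_D Z_D^\top +
#' \sigma^2_e I}; marker effects are recovered as
#' \eqn{\hat a = \sigma^2_a Z_A^\top V^{-1}(y - 1\hat\mu)} (ridge
#' parameters \eqn{\lambda_A = \sigma^2_e/\sigma^2_a},
#' \eqn{\lambda_D = \sigma^2_e/\sigma^2_d}). Unsupplied variance components
#' are estimated by REML (numerical maximisation over the two marker
#' kernels).
#'
#' @param y_hybrids phenotype vector (BLUEs), one per design row.
#' @param design a [hybrid_design()].
#' @param varcomp optional \code{c(sigma2_a, sigma2_d, sigma2_e)}
#'   (per-marker effect variances); \code{sigma2_a} and \code{sigma2_d}
#'   must not both be zero.
#' @return object of class \code{ad_model}: \code{mu}, effect vectors
#'   \code{a}, \code{d}, the three variance components, \code{fitted}
#'   values and \code{n_markers}.
#' @export
fit_ad_rrblup <- function(y_hybrids, design, varcomp = NULL) {
  stopifnot(inherits(design, "hybrid_design"))
  y <- as.numeric(y_hybrids)
  n <- length(y)
  if (n < 2 || n != nrow(design$Z_A))
    stop("need one phenotype per design row (>= 2 hybrids)")
  K_A <- tcrossprod(design$Z_A)
  K_D <- tcrossprod(design$Z_D)

  if (is.null(varcomp)) {
    vy <- stats::var(y)
    nll <- function(lt) reml_nll_kernels(exp(lt), list(K_A, K_D), y)
    opt <- stats::optim(log(c(vy / (2 * max(mean(diag(K_A)), 1)),
                              vy / (2 * max(mean(diag(K_D)), 1)),
                              vy / 2)),
                        nll, method = "L-BFGS-B",
                        lower = log(vy) - 25, upper = log(vy) + 5)
    th <- exp(opt$par)
    varcomp <- c(sigma2_a = th[1], sigma2_d = th[2], sigma2_e = th[3])
  }
  s2a <- varcomp[[1]]; s2d <- varcomp[[2]]; s2e <- varcomp[[3]]
  if (s2a < 0 || s2d < 0 || s2e < 0) stop("variance components must be >= 0")
  if (s2a == 0 && s2d == 0)
    stop("sigma2_a and sigma2_d cannot both be zero (no genetic model)")

  V <- s2a * K_A + s2d * K_D + diag(s2e, n)
  Vc <- tryCatch(chol(V), error = function(e) {
    message("V singular; applying diagonal jitter 1e-8")
    chol(V + diag(1e-8, n))
  })
  Vinv_y <- backsolve(Vc, forwardsolve(t(Vc), y))
  Vinv_1 <- backsolve(Vc, forwardsolve(t(Vc), rep(1, n)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  Vinv_r <- Vinv_y - mu * Vinv_1
  a <- drop(s2a * crossprod(design$Z_A, Vinv_r))
  d <- drop(s2d * crossprod(design$Z_D, Vinv_r))
  fitted <- drop(mu + design$Z_A %*% a + design$Z_D %*% d)
  structure(list(mu = mu, a = a, d = d,
                 sigma2_a = s2a, sigma2_d = s2d, sigma2_e = s2e,
                 fitted = fitted, n_markers = design$n_markers),
            class = "ad_model")
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf(
    "ad_model: %d markers; sigma2_a = %.4g, sigma2_d = %.4g, sigma2_e = %.4g\n",
    x$n_markers, x$sigma2_a, x$sigma2_d, x$sigma2_e))
  invisible(x)
}

#' Predict hybrid performance for crosses
#'
#' \eqn{\hat y = \hat\mu + Z_A\hat a + Z_D\hat d} per pair, ranked in
#' descending order (ties broken deterministically by pair id). Either an
#' explicit [hybrid_design()] or \code{parents} + \code{pairs} can be
#' given; the latter evaluates the identity
#' \eqn{Z_A\hat a = (v_1 + v_2)/2 - \sum_i a_i},
#' \eqn{Z_D\hat d = (u_1+u_2)/2 - (D\,\mathrm{diag}(\hat d)\,D^\top)_{12}/2}
#' on parent-level precomputations, so all 167,910 crosses of a 580-line
#' panel are scored without forming the full design.
#'
#' @param model an [fit_ad_rrblup()] model.
#' @param design optional [hybrid_design()] for the target pairs.
#' @param parents,pairs alternative input: inbred parent panel + pair table.
#' @return data frame of class \code{hybrid_prediction}: \code{parent1,
#'   parent2, value, rank}, sorted by rank.
#' @export
predict_hybrids <- function(model, design = NULL, parents = NULL,
                            pairs = NULL) {
  stopifnot(inherits(model, "ad_model"))
  if (!is.null(design)) {
    stopifnot(inherits(design, "hybrid_design"))
    if (design$n_markers != model$n_markers)
      stop("marker count mismatch between model and design")
    value <- drop(model$mu + design$Z_A %*% model$a +
                    design$Z_D %*% model$d)
    pairs <- design$pairs
  } else {
    stopifnot(inherits(parents, "variant_matrix"), !is.null(pairs))
    if (!is_inbred(parents)) stop("parents must be homozygous")
    if (ncol(parents$dosage) != model$n_markers)
      stop("marker count mismatch between model and parents")
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    names(pairs)[1:2] <- c("parent1", "parent2")
    D <- parents$dosage
    i1 <- match(pairs$parent1, parents$sample_ids)
    i2 <- match(pairs$parent2, parents$sample_ids)
    if (anyNA(i1) || anyNA(i2)) stop("unknown parent id(s) in pairs")
    v <- drop(D %*% model$a)            # additive parent scores
    u <- drop(D %*% model$d)            # dominance marginal scores
    # Z_D(1,2) = (d1 + d2)/2 - d1*d2/2 for 0/2 coded homozygotes
    Q <- tcrossprod(sweep(D, 2, model$d, `*`), D)
    value <- model$mu +
      (v[i1] + v[i2]) / 2 - sum(model$a) +
      (u[i1] + u[i2]) / 2 - Q[cbind(i1, i2)] / 2
  }
  ord <- order(-value, pairs$parent1, pairs$parent2)
  out <- data.frame(parent1 = pairs$parent1, parent2 = pairs$parent2,
                    value = value, stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hybrid_prediction", "data.frame")
  out
}

#' Select the top fraction of predicted crosses
#'
#' Keeps the \code{ceiling(fraction * N)} highest predicted crosses (ties
#' at the cutoff value are all included) and flags pairs that appear in an
#' optional list of previously tested combinations (order-insensitive
#' matching).
#'
#' @param pred a [predict_hybrids()] table.
#' @param fraction selected fraction in (0, 1] (default 0.001, the top
#'   0.1 percent).
#' @param tested_list optional two-column table of already-tested pairs.
#' @return \code{pred} with logical columns \code{selected} and
#'   \code{previously_tested} added.
#' @export
select_top <- function(pred, fraction = 0.001, tested_list = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  N <- nrow(pred)
  k <- ceiling(fraction * N)
  cutoff <- sort(pred$value, decreasing = TRUE)[k]
  pred$selected <- pred$value >= cutoff
  key <- pair_key(pred$parent1, pred$parent2)
  pred$previously_tested <- FALSE
  if (!is.null(tested_list)) {
    tl <- as.data.frame(tested_list, stringsAsFactors = FALSE)
    pred$previously_tested <- key %in% pair_key(tl[[1]], tl[[2]])
  }
  pred
}

#' Heterotic-group discovery from predicted cross performance
#'
#' Builds the symmetric parents x parents matrix of predicted hybrid
#' values (selfs excluded; absent pairs imputed with row means), clusters
#' its rows by hierarchical clustering on Euclidean distance, cuts the
#' dendrogram into \code{k_groups}, and reports the inter-group gain:
#' 100 x (mean predicted value of between-group crosses / mean over all
#' crosses - 1).
#'
#' @param pred a [predict_hybrids()] table.
#' @param parents optional parent id vector (default: ids seen in
#'   \code{pred}).
#' @param k_groups number of groups to cut (default 2).
#' @param linkage \code{hclust} agglomeration method (default
#'   \code{"average"}).
#' @return list of class \code{heterotic_groups}: \code{groups} (named
#'   integer vector), \code{gain_percent}, \code{matrix} (the filled
#'   performance matrix) and \code{hclust}.
#' @export
heterotic_groups <- function(pred, parents = NULL, k_groups = 2L,
                             linkage = "average") {
  if (is.null(parents))
    parents <- sort(unique(c(pred$parent1, pred$parent2)))
  n <- length(parents)
  if (k_groups > n) stop("k_groups exceeds the number of parents")
  P <- matrix(NA_real_, n, n, dimnames = list(parents, parents))
  i1 <- match(pred$parent1, parents)
  i2 <- match(pred$parent2, parents)
  ok <- !is.na(i1) & !is.na(i2) & i1 != i2
  P[cbind(i1[ok], i2[ok])] <- pred$value[ok]
  P[cbind(i2[ok], i1[ok])] <- pred$value[ok]
  rm_ <- rowMeans(P, na.rm = TRUE)
  for (i in seq_len(n)) {
    nas <- is.na(P[i, ]) & seq_len(n) != i
    P[i, nas] <- rm_[i]
  }
  hc <- stats::hclust(stats::dist(P, method = "euclidean"), method = linkage)
  groups <- stats::cutree(hc, k = k_groups)
  inter <- groups[i1[ok]] != groups[i2[ok]]
  vals <- pred$value[ok]
  gain <- if (any(inter) && mean(vals) != 0)
    100 * (mean(vals[inter]) / mean(vals) - 1) else 0
  structure(list(groups = groups, gain_percent = gain,
                 matrix = P, hclust = hc),
            class = "heterotic_groups")
}

#' @export
print.heterotic_groups <- function(x, ...) {
  cat(sprintf("heterotic_groups: %d parents in %d groups; inter-group gain %.2f%%\n",
              length(x$groups), length(unique(x$groups)), x$gain_percent))
  invisible(x)
}

# internal ------------------------------------------------------------------

pair_key <- function(a, b) {
  paste(pmin(as.character(a), as.character(b)),
        pmax(as.character(a), as.character(b)), sep = "||")
}

# REML negative log-likelihood for V = sum th_k K_k + th_e I, mean-only X
reml_nll_kernels <- function(theta, kernels, y) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (k in seq_along(kernels)) V <- V + theta[k] * kernels[[k]]
  Vc <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(Vc)) return(1e10)
  Vinv_y <- backsolve(Vc, forwardsolve(t(Vc), y))
  Vinv_1 <- backsolve(Vc, forwardsolve(t(Vc), rep(1, n)))
  mu <- sum(Vinv_y) / sum(Vinv_1)
  r <- y - mu
  Vinv_r <- Vinv_y - mu * Vinv_1
  0.5 * (2 * sum(log(diag(Vc))) + log(sum(Vinv_1)) + sum(r * Vinv_r))
}
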