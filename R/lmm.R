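#' Linear mixed model by EM-REML
#'
#' Fits \eqn{y = X\beta + \sum_k Z_k u_k + e} with independent random terms
#' \eqn{u_k \sim N(0, \sigma^2_k I)} by EM-REML on Henderson's mixed-model
#' equations: at each iterate the MME are solved with ridge terms
#' \eqn{\lambda_k = \sigma^2_e/\sigma^2_k} and the components updated as
#' \eqn{\sigma^2_k = (\hat u_k^\top \hat u_k + \sigma^2_e\,
#' \mathrm{tr}(C^{kk}))/q_k} and \eqn{\sigma^2_e = y^\top(y - X\hat\beta -
#' Z\hat u)/(N - \mathrm{rank}(X))}. Convergence: maximum relative change
#' below \code{tol} (default 1e-6) or \code{max_iter} iterations (500);
#' non-convergence is an error reporting the last iterate. Components are
#' kept non-negative by construction (boundary estimates come out as
#' numerically tiny values, reported as 0).
#'
#' Terms are column names of \code{records}; interactions are written
#' \code{"a:b"}. Fixed-term estimability is checked incrementally — a term
#' that adds no rank (fully confounded) is an error naming the term. When
#' the first fixed term is a factor, its coefficients are estimated as cell
#' means (no intercept), so a genotype-fixed fit returns the genotype BLUEs
#' directly.
#'
#' @param records phenotype data frame (see [simulate_phenotypes()] for the
#'   schema).
#' @param fixed character vector of fixed terms (may be empty: intercept
#'   only).
#' @param random character vector of random terms.
#' @param response response column name (default "value").
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return object of class \code{lmm_fit}: \code{varcomp} (named vector,
#'   random terms plus \code{residual}), \code{blues} (named vector of
#'   first-fixed-term estimates, when the first fixed term is a factor),
#'   \code{beta}, \code{u} (list), \code{n_iter}, \code{converged}.
#' @export
fit_lmm <- function(records, fixed = "genotype",
                    random = c("genotype:environment"),
                    response = "value", tol = 1e-6, max_iter = 500L) {
  y <- records[[response]]
  if (is.null(y)) stop("response column not found: ", response)
  keep <- !is.na(y)
  records <- records[keep, , drop = FALSE]
  y <- y[keep]
  N <- length(y)

  # fixed design with incremental estimability check
  X <- matrix(1, N, 1, dimnames = list(NULL, "(Intercept)"))
  first_factor_levels <- NULL
  for (i in seq_along(fixed)) {
    v <- term_column(records, fixed[i])
    if (i == 1 && (is.character(v) || is.factor(v))) {
      f <- factor(v)
      Xi <- stats::model.matrix(~ 0 + f)
      colnames(Xi) <- levels(f)
      first_factor_levels <- levels(f)
      X <- Xi
    } else {
      Xi <- if (is.character(v) || is.factor(v))
        stats::model.matrix(~f, data.frame(f = factor(v)))[, -1, drop = FALSE]
      else matrix(v, ncol = 1, dimnames = list(NULL, fixed[i]))
      r0 <- qr(X)$rank
      X2 <- cbind(X, Xi)
      if (qr(X2)$rank <= r0)
        stop("fixed term not estimable (confounded): ", fixed[i])
      X <- X2
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design is rank deficient")

  Z <- lapply(random, function(tm) {
    f <- factor(term_column(records, tm))
    if (nlevels(f) < 2) stop("random term needs >= 2 levels: ", tm)
    Zi <- stats::model.matrix(~ 0 + f)
    colnames(Zi) <- levels(f)
    Zi
  })
  names(Z) <- random
  q_k <- vapply(Z, ncol, integer(1))
  p <- ncol(X)

  if (!length(Z)) {
    # pure fixed model: OLS
    beta <- qr.coef(qr(X), y)
    e <- y - X %*% beta
    s2e <- sum(e^2) / (N - p)
    return(finish_lmm(beta, list(), stats::setNames(numeric(0), character(0)),
                      s2e, first_factor_levels, X, 0L, TRUE))
  }

  Zall <- do.call(cbind, Z)
  qs <- c(0, cumsum(q_k))
  XtX <- crossprod(X); XtZ <- crossprod(X, Zall); ZtZ <- crossprod(Zall)
  Xty <- crossprod(X, y); Zty <- crossprod(Zall, y); yty <- sum(y^2)

  vy <- stats::var(y)
  s2 <- rep(vy / (length(Z) + 1), length(Z))
  s2e <- vy / (length(Z) + 1)
  floor_v <- vy * 1e-10
  converged <- FALSE
  it <- 0L
  prev_delta <- NULL
  ll_prev <- NULL
  nq <- sum(q_k)
  em_step <- function(s2, s2e) {
    s2 <- pmax(s2, floor_v); s2e <- max(s2e, floor_v)
    lam <- s2e / s2
    Lam <- rep(lam, q_k)
    M <- rbind(cbind(XtX, XtZ),
               cbind(t(XtZ), ZtZ + diag(Lam, ncol(Zall))))
    ch <- tryCatch(chol(M), error = function(e)
      chol(M + diag(1e-8 * mean(diag(M)), nrow(M))))
    Cinv <- chol2inv(ch)
    rhs <- c(Xty, Zty)
    sol <- Cinv %*% rhs
    beta <- sol[seq_len(p)]
    u <- sol[-seq_len(p)]
    s2_new <- vapply(seq_along(Z), function(k) {
      idx <- p + (qs[k] + 1):qs[k + 1]
      (sum(sol[idx]^2) + s2e * sum(diag(Cinv)[idx])) / q_k[k]
    }, numeric(1))
    s2e_new <- (yty - sum(beta * Xty) - sum(u * Zty)) / (N - p)
    # restricted log-likelihood via the MME determinant identity:
    # log|V| + log|X'V^-1 X| = log|M| + (N - p - q) log s2e + sum q_k log s2_k
    yPy <- (yty - sum(sol * rhs)) / s2e
    ll <- -0.5 * (2 * sum(log(diag(ch))) + (N - p - nq) * log(s2e) +
                    sum(q_k * log(s2)) + yPy)
    list(s2 = s2_new, s2e = s2e_new, beta = beta, u = u, ll = ll)
  }
  beta <- NULL; u <- NULL
  while (it < max_iter) {
    it <- it + 1L
    st <- em_step(s2, s2e)
    delta_vec <- c(st$s2 - s2, st$s2e - s2e)
    delta <- max(abs(delta_vec) / pmax(c(st$s2, st$s2e), floor_v))
    # Aitken acceleration: EM converges linearly, so the per-component rate
    # is estimated from successive increments and the fixed point
    # extrapolated; the move is kept only if the restricted likelihood at
    # the extrapolated point is no worse
    if (!is.null(prev_delta) && it %% 3 == 0) {
      rate <- ifelse(abs(prev_delta) > 1e-300,
                     pmin(pmax(delta_vec / prev_delta, 0), 0.9999), 0)
      acc <- pmax(c(st$s2, st$s2e) + delta_vec * rate / (1 - rate), floor_v)
      st2 <- em_step(acc[seq_along(st$s2)], acc[length(acc)])
      if (st2$ll >= st$ll - 1e-10) {
        st <- st2
        delta_vec <- c(st$s2 - acc[seq_along(st$s2)],
                       st$s2e - acc[length(acc)])
        delta <- max(abs(delta_vec) / pmax(c(st$s2, st$s2e), floor_v))
      }
    }
    prev_delta <- delta_vec
    s2 <- pmax(st$s2, floor_v)
    s2e <- max(st$s2e, floor_v)
    beta <- st$beta; u <- st$u
    if (delta < tol) { converged <- TRUE; break }
    # secondary criterion: a flat restricted likelihood (components pinned
    # against the zero boundary keep changing relatively but not materially)
    if (!is.null(ll_prev) &&
        abs(st$ll - ll_prev) < 1e-11 * (1 + abs(st$ll))) {
      converged <- TRUE; break
    }
    ll_prev <- st$ll
  }
  if (!converged)
    stop(sprintf(
      "EM-REML did not converge in %d iterations (last components: %s, residual %.6g)",
      max_iter, paste(sprintf("%.6g", s2), collapse = ", "), s2e))

  u_list <- lapply(seq_along(Z), function(k) {
    idx <- (qs[k] + 1):qs[k + 1]
    stats::setNames(u[idx], colnames(Z[[k]]))
  })
  names(u_list) <- random
  vc <- stats::setNames(ifelse(s2 <= floor_v * 2, 0, s2), random)
  finish_lmm(stats::setNames(beta, colnames(X)), u_list, vc, s2e,
             first_factor_levels, X, it, converged)
}

finish_lmm <- function(beta, u_list, vc, s2e, first_levels, X, it, conv) {
  blues <- NULL
  if (!is.null(first_levels))
    blues <- beta[first_levels]
  structure(list(
    varcomp = c(vc, residual = s2e),
    blues = blues, beta = beta, u = u_list,
    n_iter = it, converged = conv),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("lmm_fit (EM-REML,", x$n_iter, "iterations)\n  variance components:\n")
  for (nm in names(x$varcomp))
    cat(sprintf("    %-24s %.6g\n", nm, x$varcomp[[nm]]))
  invisible(x)
}

# resolve a (possibly interaction) term to a vector
term_column <- function(records, term) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  miss <- setdiff(parts, names(records))
  if (length(miss)) stop("term column(s) not found: ",
                         paste(miss, collapse = ", "))
  if (length(parts) == 1) return(records[[parts]])
  interaction(records[parts], drop = TRUE, sep = ":")
}

#' Per-genotype BLUEs across environments
#'
#' Convenience wrapper: genotype fixed, chosen random terms, returning the
#' named BLUE vector used by the prediction modules.
#'
#' @param records phenotype data frame.
#' @param random random terms (default environment main effect and
#'   genotype-by-environment interaction).
#' @param response response column.
#' @return named numeric vector of genotype BLUEs.
#' @export
blues <- function(records, random = c("environment"), response = "value") {
  fit <- fit_lmm(records, fixed = "genotype", random = random,
                 response = response)
  fit$blues
}
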