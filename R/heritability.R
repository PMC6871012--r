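#' Line-mean heritability (testcross design)
#'
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_{GS}/s
#'  + \sigma^2_{GYS}/(ys) + \sigma^2_e/(ysr))}
#' with y years, s stress regimes and r replications. Interaction
#' components that are absent default to 0.
#'
#' @param vc named numeric vector of variance components: \code{G},
#'   optionally \code{GY}, \code{GS}, \code{GYS}, and \code{residual}.
#' @param y,s,r design counts (>= 1).
#' @return heritability in [0, 1] (NA when every component is 0).
#' @export
heritability_line_mean <- function(vc, y = 1, s = 1, r = 1) {
  stopifnot(y >= 1, s >= 1, r >= 1)
  g <- comp(vc, "G"); gy <- comp(vc, "GY"); gs <- comp(vc, "GS")
  gys <- comp(vc, "GYS"); e <- comp(vc, "residual")
  denom <- g + gy / y + gs / s + gys / (y * s) + e / (y * s * r)
  if (denom == 0) return(NA_real_)
  g / denom
}

#' Broad-sense heritability across environments
#'
#' \deqn{H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GE}/l +
#'   \sigma^2_e/(lr))}
#' with l environments and r the average number of replications per
#' environment.
#'
#' @param vc named vector with \code{G}, optionally \code{GE}, and
#'   \code{residual}.
#' @param l,r environment and replication counts (>= 1).
#' @return H-squared in [0, 1] (NA when every component is 0).
#' @export
heritability_broad <- function(vc, l = 1, r = 1) {
  stopifnot(l >= 1, r >= 1)
  g <- comp(vc, "G"); ge <- comp(vc, "GE"); e <- comp(vc, "residual")
  denom <- g + ge / l + e / (l * r)
  if (denom == 0) return(NA_real_)
  g / denom
}

#' Within-environment repeatability
#'
#' \eqn{w^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_e / N_R)} with
#' \eqn{N_R} replications.
#'
#' @param vc named vector with \code{G} and \code{residual}.
#' @param N_R number of replications (>= 1).
#' @return repeatability in [0, 1].
#' @export
repeatability <- function(vc, N_R) {
  if (N_R < 1) stop("N_R must be >= 1")
  g <- comp(vc, "G"); e <- comp(vc, "residual")
  denom <- g + e / N_R
  if (denom == 0) return(NA_real_)
  g / denom
}

#' Drop environments with low repeatability
#'
#' Applies the standard quality gate: environments whose repeatability is
#' below \code{threshold} (default 0.5) are removed before the
#' across-environment analysis.
#'
#' @param env_vc named list of per-environment variance-component vectors
#'   (each with \code{G} and \code{residual}).
#' @param N_R replications per environment (recycled).
#' @param threshold minimum repeatability to keep (default 0.5).
#' @return list with \code{kept} (environment names), \code{dropped}, and
#'   \code{repeatability} (named numeric vector).
#' @export
filter_environments <- function(env_vc, N_R, threshold = 0.5) {
  N_R <- rep_len(N_R, length(env_vc))
  w2 <- vapply(seq_along(env_vc),
               function(i) repeatability(env_vc[[i]], N_R[i]), numeric(1))
  names(w2) <- names(env_vc)
  list(kept = names(env_vc)[w2 >= threshold],
       dropped = names(env_vc)[w2 < threshold],
       repeatability = w2)
}

comp <- function(vc, nm) if (nm %in% names(vc)) max(0, vc[[nm]]) else 0
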