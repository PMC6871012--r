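#' Genomic relationship matrix
#'
#' VanRaden-type realized kinship: with \eqn{X} the samples x markers
#' dosage matrix, \eqn{p_j} the sample alt-allele frequency and
#' \eqn{W = X - 2p}, \eqn{G = WW^\top / (2\sum_j p_j(1-p_j))}. Monomorphic
#' markers are dropped (they contribute nothing and would inflate no
#' denominator). With missing data each pairwise entry is computed over the
#' markers non-missing in \emph{both} samples, with its own pair-specific
#' denominator; when nothing is missing this reduces exactly to the dense
#' formula.
#'
#' @param vm a [variant_matrix()] with >= 2 samples and >= 1 polymorphic
#'   marker.
#' @return an object of class \code{kinship}: \code{G} (n x n symmetric),
#'   \code{sample_ids}, \code{denominator} (the dense-case
#'   \eqn{2\sum p_j(1-p_j)}), \code{n_markers_used} (per-pair counts), and
#'   \code{p} (the frequencies used).
#' @export
grm <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  X <- vm$dosage
  if (nrow(X) < 2) stop("need >= 2 samples")
  p <- colMeans(X, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  pq <- p * (1 - p)
  W <- sweep(X, 2, 2 * p)
  if (anyNA(W)) {
    pw <- grm_pairwise(W, pq, vm$sample_ids)
    G <- pw$G
    nm <- pw$shared
  } else {
    G <- tcrossprod(W) / (2 * sum(pq))
    nm <- matrix(ncol(W), nrow(W), nrow(W))
  }
  G <- (G + t(G)) / 2
  dimnames(G) <- list(vm$sample_ids, vm$sample_ids)
  structure(list(G = G, sample_ids = vm$sample_ids,
                 denominator = 2 * sum(pq),
                 n_markers_used = nm, p = p),
            class = "kinship")
}

# pairwise-complete GRM: entry (i,k) uses only markers observed in both
# samples, with denominator 2 * sum of p_j q_j over those markers; on a
# complete matrix this is identical to the dense formula
grm_pairwise <- function(W, pq, ids) {
  M <- (!is.na(W)) * 1
  W0 <- W; W0[is.na(W0)] <- 0
  num <- tcrossprod(W0)
  den <- 2 * (M %*% (pq * t(M)))
  shared <- tcrossprod(M)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no non-missing markers",
                 ids[idx[1]], ids[idx[2]]))
  }
  list(G = num / den, shared = shared)
}

#' @export
print.kinship <- function(x, ...) {
  cat(sprintf("kinship: %d samples, mean diagonal %.3f, denominator %.2f\n",
              nrow(x$G), mean(diag(x$G)), x$denominator))
  invisible(x)
}
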