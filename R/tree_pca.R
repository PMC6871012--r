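#' Pairwise allele-sharing (p-) distance matrix
#'
#' For each sample pair: mean absolute dosage difference divided by 2 over
#' mutually non-missing sites. For inbred lines this equals the fraction of
#' shared sites with different homozygous genotypes, the dosage analogue of
#' the p-distance used for distance trees.
#'
#' @param vm a [variant_matrix()] with >= 2 samples.
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
p_distance_matrix <- function(vm) {
  stopifnot(inherits(vm, "variant_matrix"))
  D <- vm$dosage
  n <- nrow(D)
  if (n < 2) stop("need >= 2 samples")
  M <- !is.na(D)
  shared <- tcrossprod(M * 1)
  if (any(shared[upper.tri(shared)] == 0)) {
    idx <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)[1, ]
    stop(sprintf("samples %s and %s share no genotyped sites",
                 vm$sample_ids[idx[1]], vm$sample_ids[idx[2]]))
  }
  # |a - b| over {0,1,2} decomposed through value-indicator cross products
  A <- list(M & D == 0, M & D == 1, M & D == 2)
  A <- lapply(A, function(x) { x[is.na(x)] <- FALSE; x * 1 })
  absdiff <- tcrossprod(A[[1]], A[[2]]) + tcrossprod(A[[2]], A[[1]]) +
    tcrossprod(A[[2]], A[[3]]) + tcrossprod(A[[3]], A[[2]]) +
    2 * (tcrossprod(A[[1]], A[[3]]) + tcrossprod(A[[3]], A[[1]]))
  out <- absdiff / (2 * shared)
  diag(out) <- 0
  dimnames(out) <- list(vm$sample_ids, vm$sample_ids)
  out
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via \code{ape::nj}) with negative branch
#' lengths clamped to zero and their (negative) length transferred to the
#' adjacent branches so path lengths through the affected node are
#' preserved where possible.
#'
#' @param dist symmetric non-negative distance matrix (or \code{dist}
#'   object) over >= 3 taxa.
#' @param clamp_negative clamp negative branch lengths (default TRUE).
#' @return an \code{ape} \code{phylo} tree; write Newick with
#'   \code{ape::write.tree}.
#' @export
nj_tree <- function(dist, clamp_negative = TRUE) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  if (nrow(dist) < 3) stop("neighbour joining needs >= 3 taxa")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(stats::as.dist(dist))
  if (clamp_negative && any(tr$edge.length < 0)) {
    for (pass in 1:2) {
      for (e in which(tr$edge.length < 0)) {
        len <- tr$edge.length[e]
        child <- tr$edge[e, 2]
        tr$edge.length[e] <- 0
        down <- which(tr$edge[, 1] == child)
        if (length(down)) {
          tr$edge.length[down] <- tr$edge.length[down] + len
        } else {
          up <- which(tr$edge[, 2] == tr$edge[e, 1])
          if (length(up)) tr$edge.length[up] <- tr$edge.length[up] + len
        }
      }
    }
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Principal components of the genotype matrix
#'
#' Missing dosages are imputed to the column mean, columns are centred, and
#' sample coordinates are taken from the singular value decomposition
#' (equivalently the eigendecomposition of the sample covariance matrix).
#'
#' @param vm a [variant_matrix()].
#' @param n_components number of components to return.
#' @return list of class \code{genotype_pca}: \code{coordinates} (samples x
#'   components, column means zero), \code{var_explained} (per returned
#'   component, fractions of total variance, non-increasing), and
#'   \code{sdev} (all singular-value based standard deviations).
#' @export
pca_genotypes <- function(vm, n_components = 10L) {
  stopifnot(inherits(vm, "variant_matrix"))
  X <- vm$dosage
  if (nrow(X) < 2 || ncol(X) < 1) stop("need >= 2 samples and >= 1 variant")
  cm <- colMeans(X, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- cm[(idx - 1) %/% nrow(X) + 1]
  Xc <- sweep(X, 2, colMeans(X))
  n_components <- min(n_components, nrow(X) - 1, ncol(X))
  total <- sum(Xc^2)
  if (total < 1e-12) {
    coords <- matrix(0, nrow(X), n_components,
                     dimnames = list(vm$sample_ids,
                                     paste0("PC", seq_len(n_components))))
    return(structure(list(coordinates = coords,
                          var_explained = rep(0, n_components),
                          sdev = rep(0, n_components)),
                     class = "genotype_pca"))
  }
  sv <- svd(Xc, nu = n_components, nv = 0)
  coords <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(coords) <- list(vm$sample_ids,
                           paste0("PC", seq_len(n_components)))
  structure(list(
    coordinates = coords,
    var_explained = sv$d[seq_len(n_components)]^2 / sum(sv$d^2),
    sdev = sv$d / sqrt(max(1, nrow(X) - 1))
  ), class = "genotype_pca")
}

#' @export
print.genotype_pca <- function(x, ...) {
  cat(sprintf("genotype_pca: %d samples, %d components (%.1f%% variance)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * sum(x$var_explained)))
  invisible(x)
}
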