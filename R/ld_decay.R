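#' Linkage-disequilibrium decay
#'
#' Computes pairwise r-squared (squared Pearson correlation of dosages —
#' exact haplotype r2 for inbred lines, a close approximation otherwise)
#' for all same-chromosome SNP pairs within \code{max_distance}, after a
#' minor-allele-frequency filter. Pair r2 values are averaged in distance
#' bins and the decay distance is the first linearly interpolated crossing
#' of the binned curve below \code{r2_threshold}.
#'
#' @param vm a [variant_matrix()].
#' @param max_distance maximum pair distance in bp (default 250 kb).
#' @param maf_min MAF filter applied before pairing (default 0.05).
#' @param r2_threshold decay threshold on mean r2 (default 0.2).
#' @param bin_width distance bin width in bp.
#' @return list of class \code{ld_decay} with \code{bins} (data frame:
#'   \code{start, end, mid, mean_r2, n_pairs}), \code{decay_distance} (bp,
#'   NA if the curve never crosses) and \code{r2_threshold}. Empty bins
#'   data frame when no pairs are in range.
#' @export
ld_decay <- function(vm, max_distance = 250000, maf_min = 0.05,
                     r2_threshold = 0.2, bin_width = 1000) {
  stopifnot(inherits(vm, "variant_matrix"))
  vm <- filter_variants(vm, maf_min = maf_min, miss_max = 1)
  if (ncol(vm$dosage) < 2) stop("need >= 2 SNPs passing the MAF filter")
  dists <- r2s <- list()
  for (ch in unique(vm$chrom)) {
    j <- which(vm$chrom == ch)
    if (length(j) < 2) next
    D <- vm$dosage[, j, drop = FALSE]
    pos <- vm$pos[j]
    C <- suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))^2
    dd <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dd)
    keep <- ut & dd <= max_distance & dd >= 1 & !is.na(C)
    dists[[ch]] <- dd[keep]
    r2s[[ch]] <- C[keep]
  }
  d <- unlist(dists); r2 <- unlist(r2s)
  if (!length(d)) {
    return(structure(list(
      bins = data.frame(start = numeric(), end = numeric(),
                        mid = numeric(), mean_r2 = numeric(),
                        n_pairs = integer()),
      decay_distance = NA_real_, r2_threshold = r2_threshold),
      class = "ld_decay"))
  }
  brk <- seq(0, max_distance + bin_width, by = bin_width)
  bin <- cut(d, brk, include.lowest = TRUE)
  mean_r2 <- tapply(r2, bin, mean)
  n_pairs <- tapply(r2, bin, length)
  filled <- !is.na(mean_r2)
  bins <- data.frame(
    start = brk[-length(brk)][filled] + 1,
    end = brk[-1][filled],
    mid = (brk[-length(brk)][filled] + brk[-1][filled]) / 2,
    mean_r2 = as.numeric(mean_r2[filled]),
    n_pairs = as.integer(n_pairs[filled]))
  structure(list(bins = bins,
                 decay_distance = decay_crossing(bins, r2_threshold),
                 r2_threshold = r2_threshold),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf("ld_decay: %d bins, decay distance (r2 < %.2f): %s bp\n",
              nrow(x$bins), x$r2_threshold,
              if (is.na(x$decay_distance)) "not reached"
              else format(round(x$decay_distance))))
  invisible(x)
}

# first linearly interpolated crossing of the binned curve below thr
decay_crossing <- function(bins, thr) {
  if (!nrow(bins)) return(NA_real_)
  y <- bins$mean_r2; x <- bins$mid
  if (y[1] < thr) return(x[1])
  below <- which(y < thr)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  x[i - 1] + (thr - y[i - 1]) * (x[i] - x[i - 1]) / (y[i] - y[i - 1])
}
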