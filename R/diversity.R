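#' Per-site nucleotide diversity from allele counts
#'
#' Unbiased heterozygosity \eqn{2\hat p(1-\hat p)\, n/(n-1)} with \eqn{n}
#' the number of sampled alleles — identical to the mean pairwise difference
#' over all allele pairs at the site.
#'
#' @param alt_count number of alternate alleles observed (0..total).
#' @param total_alleles number of called alleles at the site (>= 2).
#' @return per-site pi (vectorized).
#' @export
site_diversity <- function(alt_count, total_alleles) {
  if (any(total_alleles < 2)) stop("need at least 2 alleles per site")
  if (any(alt_count < 0 | alt_count > total_alleles))
    stop("alt_count must lie in [0, total_alleles]")
  p <- alt_count / total_alleles
  2 * p * (1 - p) * total_alleles / (total_alleles - 1)
}

#' Watterson's theta per base pair
#'
#' \eqn{\theta_w = S / (a_{n-1} L)} with \eqn{a_{n-1} = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S number of segregating sites.
#' @param n_alleles number of sampled alleles (>= 2).
#' @param L effective (non-N) sequence length in bp (> 0).
#' @return theta_w per bp.
#' @export
watterson_theta <- function(S, n_alleles, L) {
  stopifnot(all(n_alleles >= 2), all(L > 0), all(S >= 0))
  S / (harmonic(n_alleles - 1) * L)
}

#' Tajima's D
#'
#' Standardized difference between the pairwise estimator
#' (\code{pi_sum}, the summed per-site pairwise diversity over the region,
#' not per bp) and the segregating-sites estimator \eqn{S/a_1}, using
#' Tajima's (1989) constants derived from the allele count. Undefined
#' (\code{NA}) when \eqn{S = 0}.
#'
#' @param S number of segregating sites.
#' @param pi_sum total pairwise diversity summed over sites.
#' @param n_alleles number of sampled alleles (>= 4 recommended).
#' @return Tajima's D (NA when undefined).
#' @export
tajima_d <- function(S, pi_sum, n_alleles) {
  n <- n_alleles
  if (n < 2 || S == 0) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / (seq_len(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  v <- e1 * S + e2 * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi_sum - S / a1) / sqrt(v)
}

#' Hudson's FST from two allele frequencies
#'
#' Per-site Hudson estimator with numerator
#' \eqn{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)} and
#' denominator \eqn{p_1(1-p_2) + p_2(1-p_1)}. Multi-site windows should
#' aggregate as a ratio of averages (summed numerators over summed
#' denominators), which [window_scan()] does.
#'
#' @param p1,p2 sample alt-allele frequencies in each population.
#' @param n1,n2 allele counts per population (>= 2).
#' @param components if TRUE, return the per-site numerator and denominator
#'   instead of their ratio (for ratio-of-averages aggregation).
#' @return FST estimate (vectorized), or a list with \code{num} and
#'   \code{den} when \code{components = TRUE}.
#' @export
hudson_fst <- function(p1, n1, p2, n2, components = FALSE) {
  stopifnot(all(n1 >= 2), all(n2 >= 2))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (components) return(list(num = num, den = den))
  ifelse(den > 0, num / den, NA_real_)
}

#' Negative log10 diversity ratio
#'
#' \eqn{-\log_{10}(\pi_{cultivated} / \pi_{wild})}: 0 when diversity is
#' maintained in the cultivated material, 1 at a tenfold loss, 2 at a
#' hundredfold loss. Undefined (NA) when either diversity is zero.
#'
#' @param pi_cult,pi_wild per-bp diversities (vectorized).
#' @return the statistic, NA where undefined.
#' @export
neg_log_ratio <- function(pi_cult, pi_wild) {
  out <- rep(NA_real_, length(pi_cult))
  ok <- !is.na(pi_cult) & !is.na(pi_wild) & pi_cult > 0 & pi_wild > 0
  out[ok] <- 0 - log10(pi_cult[ok] / pi_wild[ok])  # 0 - keeps +0 at parity
  out
}

# internal: harmonic number sum_{i=1}^{m} 1/i (vectorized)
harmonic <- function(m) {
  vapply(m, function(mm) if (mm < 1) 0 else sum(1 / seq_len(mm)), numeric(1))
}
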