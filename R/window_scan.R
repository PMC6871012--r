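#' Windowed diversity and differentiation scan
#'
#' Tiles each chromosome with windows of \code{window} bp (start positions
#' every \code{step} bp; the default non-overlapping tiling assigns a
#' variant at position P to window \code{ceiling(P / window)}, so position
#' 100,000 falls in the first 100-kb window). Within each window and
#' population it computes the segregating-site count S, per-bp pairwise
#' diversity theta_pi, per-bp Watterson's theta (per-site harmonic
#' correction, so varying missingness is handled) and Tajima's D (allele
#' count = the median per-site count in the window), plus the Hudson FST
#' between the two populations aggregated as a ratio of averages, and the
#' negative log10 ratio of cultivated to wild diversity.
#'
#' Inbred samples contribute two identical alleles by default;
#' \code{inbred_as_haploid = TRUE} counts each fully homozygous sample as a
#' single allele.
#'
#' @param vm a [variant_matrix()] with population labels.
#' @param wild,cult the two population labels to contrast.
#' @param window window size in bp (>= 1).
#' @param step distance between window starts (default: non-overlapping).
#' @param inbred_as_haploid count fully inbred samples as one allele.
#' @param effective_lengths optional per-window callable (non-N) lengths,
#'   recycled over windows; default: the clipped window span.
#' @return a data frame (class \code{window_stat}) with one row per window:
#'   coordinates (1-based inclusive), effective length, per-population
#'   statistics (suffixes \code{_wild}, \code{_cult}), \code{fst} and
#'   \code{neg_log_ratio}.
#' @export
window_scan <- function(vm, wild = "wild", cult = "cultivated",
                        window = 100000, step = window,
                        inbred_as_haploid = FALSE,
                        effective_lengths = NULL) {
  stopifnot(inherits(vm, "variant_matrix"))
  if (window < 1) stop("window must be >= 1")
  if (is.null(vm$population)) stop("population labels required")
  iw <- vm$population == wild
  ic <- vm$population == cult
  if (sum(iw) < 2 || sum(ic) < 2)
    stop("need >= 2 samples in each population")

  sw <- site_counts(vm$dosage[iw, , drop = FALSE], inbred_as_haploid)
  sc <- site_counts(vm$dosage[ic, , drop = FALSE], inbred_as_haploid)
  fst_cmp <- hudson_components(sw, sc)

  out <- list()
  for (ch in unique(vm$chrom)) {
    on_ch <- vm$chrom == ch
    pos <- vm$pos[on_ch]
    chlen <- if (!is.null(vm$chrom_length) && ch %in% names(vm$chrom_length))
      as.numeric(vm$chrom_length[[ch]]) else max(pos)
    starts <- seq(1, chlen, by = step)
    ends <- pmin(starts + window - 1, chlen)
    idx_all <- which(on_ch)
    for (k in seq_along(starts)) {
      sel <- idx_all[pos >= starts[k] & pos <= ends[k]]
      L <- ends[k] - starts[k] + 1
      if (!is.null(effective_lengths))
        L <- effective_lengths[((k - 1) %% length(effective_lengths)) + 1]
      row <- data.frame(chrom = ch, start = starts[k], end = ends[k],
                        effective_length = L)
      row <- cbind(row,
                   pop_window_stats(sw, sel, L, "wild"),
                   pop_window_stats(sc, sel, L, "cult"))
      ok <- sel[fst_cmp$valid[sel]]
      row$fst <- if (length(ok) && sum(fst_cmp$den[ok]) > 0)
        sum(fst_cmp$num[ok]) / sum(fst_cmp$den[ok]) else NA_real_
      row$neg_log_ratio <- neg_log_ratio(row$theta_pi_cult, row$theta_pi_wild)
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_stat", "data.frame")
  res
}

#' Joint diversity-loss / differentiation outlier regions
#'
#' Flags windows whose negative-log diversity ratio AND Hudson FST both lie
#' at or above the empirical \code{q}-quantile (type 7, computed over
#' windows where both statistics are defined), then merges adjacent flagged
#' windows into regions.
#'
#' @param stats a \code{window_stat} data frame from [window_scan()].
#' @param q quantile threshold (the classical unilateral 0.95, or the
#'   stringent 0.995).
#' @return a data frame of regions: \code{chrom, start, end, n_windows,
#'   max_neg_log_ratio, max_fst, mean_tajima_d_cult}, with the per-window
#'   logical flag vector attached as attribute \code{"flagged"} and the two
#'   thresholds as attribute \code{"thresholds"}.
#' @export
call_outliers <- function(stats, q = 0.95) {
  stopifnot(q > 0, q < 1)
  defined <- !is.na(stats$neg_log_ratio) & !is.na(stats$fst)
  if (sum(defined) < 20)
    stop("need at least 20 windows with both statistics defined")
  thr_nlr <- stats::quantile(stats$neg_log_ratio[defined], q, type = 7,
                             names = FALSE)
  thr_fst <- stats::quantile(stats$fst[defined], q, type = 7, names = FALSE)
  flag <- defined & stats$neg_log_ratio >= thr_nlr & stats$fst >= thr_fst

  regions <- list()
  i <- 1
  n <- nrow(stats)
  while (i <= n) {
    if (!flag[i]) { i <- i + 1; next }
    j <- i
    while (j < n && flag[j + 1] && stats$chrom[j + 1] == stats$chrom[i] &&
           stats$start[j + 1] <= stats$end[j] + 1) j <- j + 1
    blk <- stats[i:j, ]
    regions[[length(regions) + 1]] <- data.frame(
      chrom = stats$chrom[i], start = stats$start[i], end = stats$end[j],
      n_windows = j - i + 1,
      max_neg_log_ratio = max(blk$neg_log_ratio, na.rm = TRUE),
      max_fst = max(blk$fst, na.rm = TRUE),
      mean_tajima_d_cult = if (all(is.na(blk$tajima_d_cult))) NA_real_
        else mean(blk$tajima_d_cult, na.rm = TRUE))
    i <- j + 1
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_windows = integer(), max_neg_log_ratio = numeric(),
               max_fst = numeric(), mean_tajima_d_cult = numeric())
  attr(out, "flagged") <- flag
  attr(out, "thresholds") <- c(neg_log_ratio = thr_nlr, fst = thr_fst)
  out
}

#' Write outlier regions as BED
#'
#' BED uses 0-based half-open coordinates; the 1-based inclusive regions are
#' converted at this boundary.
#'
#' @param regions output of [call_outliers()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_outlier_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = round(1000 * pmin(1, pmax(0, regions$max_fst))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# internal ------------------------------------------------------------------

# per-site allele counts for one population's dosage block
site_counts <- function(D, inbred_as_haploid = FALSE) {
  nm <- colSums(!is.na(D))
  if (inbred_as_haploid) {
    inb <- apply(D, 1, function(r) all(r[!is.na(r)] %in% c(0, 2)))
    n_all <- colSums(!is.na(D[!inb, , drop = FALSE])) * 2 +
      colSums(!is.na(D[inb, , drop = FALSE]))
    alt <- colSums(D[!inb, , drop = FALSE], na.rm = TRUE) +
      colSums(D[inb, , drop = FALSE], na.rm = TRUE) / 2
  } else {
    n_all <- nm * 2
    alt <- colSums(D, na.rm = TRUE)
  }
  p <- ifelse(n_all > 0, alt / n_all, NA_real_)
  seg <- n_all >= 2 & alt > 0 & alt < n_all
  pi_site <- rep(0, length(alt))
  ok <- n_all >= 2
  pi_site[ok] <- 2 * p[ok] * (1 - p[ok]) * n_all[ok] / (n_all[ok] - 1)
  pi_site[!ok] <- NA_real_
  list(n = n_all, alt = alt, p = p, seg = seg, pi = pi_site)
}

pop_window_stats <- function(sc, sel, L, suffix) {
  sel <- sel[sc$n[sel] >= 2]
  S <- sum(sc$seg[sel])
  pi_sum <- sum(sc$pi[sel])
  seg_sel <- sel[sc$seg[sel]]
  theta_w_sum <- if (length(seg_sel))
    sum(1 / harmonic(sc$n[seg_sel] - 1)) else 0
  n_med <- if (length(sel)) stats::median(sc$n[sel]) else NA
  d <- if (L > 0 && !is.na(n_med) && n_med >= 4)
    tajima_d(S, pi_sum, round(n_med)) else NA_real_
  out <- data.frame(S, ifelse(L > 0, pi_sum / L, NA_real_),
                    ifelse(L > 0, theta_w_sum / L, NA_real_), d)
  names(out) <- paste0(c("S_", "theta_pi_", "theta_w_", "tajima_d_"), suffix)
  out
}

hudson_components <- function(sw, sc) {
  valid <- sw$n >= 2 & sc$n >= 2
  num <- den <- rep(NA_real_, length(valid))
  v <- which(valid)
  cmp <- hudson_fst(sw$p[v], sw$n[v], sc$p[v], sc$n[v], components = TRUE)
  num[v] <- cmp$num
  den[v] <- cmp$den
  list(num = num, den = den, valid = valid)
}
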