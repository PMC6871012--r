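#' Simulate wild and cultivated populations with divergence and sweeps
#'
#' Draws a wild/cultivated diversity panel under a Balding-Nichols model.
#' Per-locus ancestral frequencies come from \code{truth}; the cultivated
#' pool and the wild side each receive Beta-distributed population
#' frequencies around the ancestral value so that the expected Hudson FST
#' between cultivated and the pooled wild sample equals
#' \code{truth$fst_target}. The wild sample is further split into three
#' subgroups (strong internal structure), whose divergence is carved out of
#' the wild share of the total so the calibration is preserved. Cultivated
#' individuals are fully inbred (dosages 0/2); wild accessions are
#' Hardy-Weinberg diploids. Inside \code{truth$sweep_windows} the cultivated
#' frequencies are pushed toward fixation, mimicking the loss of diversity
#' plus differentiation signature of a domestication sweep.
#'
#' @param truth a [sim_truth()] object.
#' @param n_wild,n_cult number of wild / cultivated samples (each >= 2).
#' @param n_loci number of SNP loci; defaults to \code{truth$n_loci} (other
#'   values redraw ancestral frequencies deterministically from the seed).
#' @param chrom_length chromosome length in bp; positions are sampled
#'   uniformly (without replacement) on \code{[1, chrom_length]}.
#' @return a [variant_matrix()] with population labels \code{"wild"} /
#'   \code{"cultivated"}, a \code{wild_subgroup} attribute, and
#'   \code{chrom_length} metadata.
#' @export
simulate_populations <- function(truth, n_wild = 100L, n_cult = 100L,
                                 n_loci = truth$n_loci,
                                 chrom_length = 10e6) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (n_wild < 2 || n_cult < 2) stop("need at least 2 samples per population")
  p0 <- ancestral_freqs(truth, n_loci)
  Tt <- truth$fst_target
  # apportion divergence: cultivated at F_c = T from the ancestor; wild
  # subgroups at F_w around a wild centre itself at F_wc, chosen so the wild
  # pooled-sample variance also equals T * p(1-p).
  F_c <- Tt
  F_w <- min(truth$wild_subpop_fst, 3 * Tt)
  F_wc <- if (F_w >= 3 * Tt) 0 else (Tt - F_w / 3) / (1 - F_w / 3)

  with_temp_seed(truth$seed + 11L, {
    pos <- sort(sample.int(chrom_length, n_loci))
    p_cult <- bn_draw(p0, F_c)
    p_wc <- bn_draw(p0, F_wc)
    p_sub <- lapply(1:3, function(k) bn_draw(p_wc, F_w))

    if (!is.null(truth$sweep_windows)) {
      swept <- in_windows(pos, truth$sweep_windows)
      push <- truth$sweep_push
      p_cult[swept] <- p_cult[swept] * (1 - push) +
        round(p_cult[swept]) * push
    }

    # cultivated: inbred lines, one panmictic (weakly structured) pool
    cult <- matrix(2 * stats::rbinom(n_cult * n_loci, 1L,
                                     rep(p_cult, each = n_cult)),
                   nrow = n_cult)
    # wild: HWE diploids in three subgroups
    sub_of <- rep(1:3, length.out = n_wild)
    wild <- matrix(0, n_wild, n_loci)
    for (k in 1:3) {
      idx <- which(sub_of == k)
      wild[idx, ] <- matrix(stats::rbinom(length(idx) * n_loci, 2L,
                                          rep(p_sub[[k]], each = length(idx))),
                            nrow = length(idx))
    }
    ids <- c(sprintf("W%d_%03d", sub_of, seq_len(n_wild)),
             sprintf("C_%03d", seq_len(n_cult)))
    vm <- variant_matrix(
      rbind(wild, cult),
      chrom = rep("chr1", n_loci), pos = pos,
      sample_ids = ids,
      population = c(rep("wild", n_wild), rep("cultivated", n_cult)),
      chrom_length = c(chr1 = chrom_length)
    )
    attr(vm, "wild_subgroup") <- sub_of
    vm
  })
}

#' Simulate an inbred parent panel (B- and R-lines)
#'
#' Fully homozygous inbred lines without missing data, labelled \code{"B"}
#' (seed-parent / maintainer side) or \code{"R"} (restorer side). The two
#' groups are drawn around the ancestral frequencies with a mild
#' Balding-Nichols divergence \code{group_fst}.
#'
#' @param truth a [sim_truth()] object.
#' @param n_parents total number of lines (>= 2).
#' @param n_loci number of loci; defaults to \code{truth$n_loci}.
#' @param n_b number of B-lines; the remaining \code{n_parents - n_b} are
#'   R-lines. Default: half.
#' @param group_fst divergence between the B and R pools (0 = one pool).
#' @param chrom_length chromosome length for the uniformly placed loci.
#' @return a [variant_matrix()] with population labels \code{"B"}/\code{"R"}.
#' @export
simulate_parent_panel <- function(truth, n_parents = 580L,
                                  n_loci = truth$n_loci,
                                  n_b = floor(n_parents / 2),
                                  group_fst = 0.05,
                                  chrom_length = 10e6) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_parents < 2) stop("n_parents must be >= 2")
  if (n_b < 0 || n_b > n_parents) stop("invalid B/R split")
  p0 <- ancestral_freqs(truth, n_loci)
  with_temp_seed(truth$seed + 22L, {
    pos <- sort(sample.int(chrom_length, n_loci))
    n_r <- n_parents - n_b
    p_b <- bn_draw(p0, group_fst)
    p_r <- bn_draw(p0, group_fst)
    gb <- matrix(2 * stats::rbinom(n_b * n_loci, 1L, rep(p_b, each = n_b)),
                 nrow = n_b)
    gr <- matrix(2 * stats::rbinom(n_r * n_loci, 1L, rep(p_r, each = n_r)),
                 nrow = n_r)
    ids <- c(sprintf("B%03d", seq_len(n_b)), sprintf("R%03d", seq_len(n_r)))
    variant_matrix(rbind(gb, gr),
                   chrom = rep("chr1", n_loci), pos = pos,
                   sample_ids = ids,
                   population = c(rep("B", n_b), rep("R", n_r)),
                   chrom_length = c(chr1 = chrom_length))
  })
}

#' Construct F1 hybrid genotypes from inbred parents
#'
#' Each hybrid's dosage is the parental mean, \code{(d1 + d2) / 2}; because
#' parents are homozygous this lies in \{0, 1, 2\} and dosage 1 marks a
#' locus where the parents carry different homozygous genotypes
#' (the dominance-bearing heterozygous class).
#'
#' @param parents a [variant_matrix()] of fully inbred lines.
#' @param pairs two-column matrix or data frame of parent sample ids (or a
#'   list of length-2 vectors). Selfing pairs are allowed.
#' @return a [variant_matrix()] of hybrids named \code{"p1 x p2"}.
#' @export
make_hybrids <- function(parents, pairs) {
  stopifnot(inherits(parents, "variant_matrix"))
  if (!is_inbred(parents))
    stop("parents must be fully inbred (dosages 0/2): gametes are ambiguous otherwise")
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  i1 <- match(pairs[, 1], parents$sample_ids)
  i2 <- match(pairs[, 2], parents$sample_ids)
  if (anyNA(i1) || anyNA(i2))
    stop("unknown parent id(s): ",
         paste(unique(c(pairs[, 1][is.na(i1)], pairs[, 2][is.na(i2)])),
               collapse = ", "))
  d <- (parents$dosage[i1, , drop = FALSE] +
        parents$dosage[i2, , drop = FALSE]) / 2
  ids <- paste(pairs[, 1], pairs[, 2], sep = " x ")
  variant_matrix(d, chrom = parents$chrom, pos = parents$pos,
                 ref = parents$ref, alt = parents$alt,
                 sample_ids = ids,
                 population = rep("hybrid", nrow(pairs)),
                 chrom_length = parents$chrom_length)
}

# internal ------------------------------------------------------------------

# ancestral frequencies: reuse truth's when the locus count matches,
# otherwise redraw deterministically from the seed
ancestral_freqs <- function(truth, n_loci) {
  if (n_loci == truth$n_loci) truth$allele_freqs
  else with_temp_seed(truth$seed + 1000L + n_loci,
                      stats::runif(n_loci, 0.05, 0.95))
}

# Balding-Nichols draw: Beta(p(1-F)/F, (1-p)(1-F)/F); F -> 0 degenerates to p
bn_draw <- function(p, F) {
  if (F < 1e-9) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# logical: position inside any (chrom-agnostic single-chromosome) window
in_windows <- function(pos, windows) {
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(windows)))
    hit <- hit | (pos >= windows$start[i] & pos <= windows$end[i])
  hit
}
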