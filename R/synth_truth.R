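#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects every parameter the generators need: ancestral allele
#' frequencies, the population-divergence target, designated sweep intervals,
#' per-locus additive and dominance effects, the target heritability and the
#' multi-environment trial layout. All generator functions are pure in
#' (truth, arguments): the same seed reproduces bit-identical output.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param n_loci number of loci the genetic architecture covers (used to
#'   default \code{allele_freqs} and the effect vectors).
#' @param allele_freqs per-locus ancestral alt-allele frequency in (0, 1);
#'   defaults to Uniform(0.05, 0.95) draws.
#' @param fst_target expected Hudson FST between the cultivated pool and the
#'   pooled wild sample, in [0, 1).
#' @param wild_subpop_fst divergence among the three wild subgroups. The wild
#'   side of \code{fst_target} is apportioned between a shared wild shift and
#'   subgroup scatter, so the realized wild-vs-cultivated FST still matches
#'   \code{fst_target}; the usable subgroup divergence is capped at
#'   \code{3 * fst_target}.
#' @param sweep_windows data frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive): intervals where cultivated allele
#'   frequencies are pushed toward fixation. Must be disjoint and sorted.
#' @param sweep_push push strength in [0, 1): cultivated frequencies inside
#'   sweeps become \code{p * (1 - push) + round(p) * push}. The default 0.95
#'   yields roughly a 15- to 20-fold diversity loss.
#' @param n_causal number of causal loci for the trait (sampled among the
#'   \code{n_loci}); effects elsewhere are zero.
#' @param additive_effects,dominance_effects per-locus effect vectors
#'   (length \code{n_loci}); default: \code{n_causal} loci receive
#'   exponential(1) additive effects with random sign, and dominance effects
#'   at \code{dominance_ratio} times the additive scale.
#' @param dominance_ratio scale of dominance relative to additive effects
#'   for the default architecture (0 disables dominance).
#' @param target_h2 narrow/line-mean heritability target in [0, 1].
#' @param env_params list of trial-layout values: \code{l} environments,
#'   \code{y} years, \code{s} stress regimes, \code{r} replications, and
#'   variance components \code{sigma2_E} (environment main effect),
#'   \code{sigma2_GE}, \code{sigma2_GY}, \code{sigma2_GS}, \code{sigma2_GYS}
#'   (expressed as multiples of the realized genetic variance), plus
#'   \code{mu}, the trait grand mean.
#' @return an object of class \code{sim_truth}.
#' @export
sim_truth <- function(seed = 1L,
                      n_loci = 5000L,
                      allele_freqs = NULL,
                      fst_target = 0.1,
                      wild_subpop_fst = 0.15,
                      sweep_windows = NULL,
                      sweep_push = 0.95,
                      n_causal = 500L,
                      additive_effects = NULL,
                      dominance_effects = NULL,
                      dominance_ratio = 0.5,
                      target_h2 = 0.5,
                      env_params = list()) {
  stopifnot(n_loci >= 1, fst_target >= 0, fst_target < 1,
            sweep_push >= 0, sweep_push < 1,
            target_h2 >= 0, target_h2 <= 1)
  seed <- as.integer(seed)
  if (is.null(allele_freqs)) {
    allele_freqs <- with_temp_seed(seed + 1000L,
                                   stats::runif(n_loci, 0.05, 0.95))
  }
  stopifnot(length(allele_freqs) == n_loci,
            all(allele_freqs > 0), all(allele_freqs < 1))
  if (!is.null(sweep_windows)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(sweep_windows)))
    sw <- sweep_windows[order(sweep_windows$chrom, sweep_windows$start), ,
                        drop = FALSE]
    by_chr <- split(sw, sw$chrom)
    for (b in by_chr) {
      if (nrow(b) > 1 && any(b$start[-1] <= b$end[-nrow(b)]))
        stop("sweep_windows must be disjoint within each chromosome")
    }
    sweep_windows <- sw
  }
  n_causal <- min(as.integer(n_causal), n_loci)
  if (is.null(additive_effects)) {
    additive_effects <- numeric(n_loci)
    dom <- numeric(n_loci)
    eff <- with_temp_seed(seed + 2000L, {
      idx <- sample.int(n_loci, n_causal)
      a <- stats::rexp(n_causal) * sample(c(-1, 1), n_causal, replace = TRUE)
      d <- abs(stats::rnorm(n_causal)) * dominance_ratio
      list(idx = idx, a = a, d = d)
    })
    additive_effects[eff$idx] <- eff$a
    dom[eff$idx] <- eff$d
    if (is.null(dominance_effects)) dominance_effects <- dom
  }
  if (is.null(dominance_effects)) dominance_effects <- numeric(n_loci)
  stopifnot(length(additive_effects) == n_loci,
            length(dominance_effects) == n_loci)
  ep <- utils::modifyList(list(
    l = 2L, y = 2L, s = 2L, r = 2L,
    mu = 100,
    sigma2_E = 0.5, sigma2_GE = 0.25,
    sigma2_GY = 0.25, sigma2_GS = 0.25, sigma2_GYS = 0.25
  ), env_params)
  if (any(unlist(ep[c("sigma2_E", "sigma2_GE", "sigma2_GY",
                      "sigma2_GS", "sigma2_GYS")]) < 0))
    stop("variance components must be non-negative")
  structure(list(
    seed = seed, n_loci = n_loci, allele_freqs = allele_freqs,
    fst_target = fst_target, wild_subpop_fst = wild_subpop_fst,
    sweep_windows = sweep_windows, sweep_push = sweep_push,
    additive_effects = additive_effects,
    dominance_effects = dominance_effects,
    target_h2 = target_h2, env_params = ep
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "sim_truth: %d loci, fst_target %.3f, target_h2 %.2f, seed %d\n",
    x$n_loci, x$fst_target, x$target_h2, x$seed))
  if (!is.null(x$sweep_windows))
    cat(sprintf("  %d sweep window(s), push %.2f\n",
                nrow(x$sweep_windows), x$sweep_push))
  invisible(x)
}

# Run code under a local RNG seed without touching the caller's RNG state.
with_temp_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
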