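#' True genetic values under the additive + dominance architecture
#'
#' \eqn{g_j = \sum_i (x_{ij} - 1) a_i + \sum_i 1[x_{ij} = 1] d_i}: additive
#' effects on the centred dosage plus dominance effects on the heterozygous
#' indicator.
#'
#' @param genotypes a [variant_matrix()].
#' @param truth a [sim_truth()] whose effect vectors match the locus count.
#' @return named numeric vector of genetic values, one per sample.
#' @export
genetic_values <- function(genotypes, truth) {
  stopifnot(inherits(truth, "sim_truth"),
            ncol(genotypes$dosage) == truth$n_loci)
  X <- genotypes$dosage
  X[is.na(X)] <- 1  # missing contributes no additive deviation
  g <- drop((X - 1) %*% truth$additive_effects +
            (X == 1) %*% truth$dominance_effects)
  names(g) <- genotypes$sample_ids
  g
}

#' Simulate multi-environment trial phenotypes
#'
#' Generates one record per genotype x year x stress x replication. Each
#' record is
#' \deqn{y = \mu + g_j + E_{ys} + (gy)_{jy} + (gs)_{js} + (gys)_{jys} +
#'       (ge)_{je} + b + \epsilon}
#' with the interaction variances taken from \code{truth$env_params} as
#' multiples of the realized genetic variance \eqn{\sigma^2_G =
#' \mathrm{var}(g)}, and the residual variance solved from the line-mean
#' heritability identity
#' \deqn{h^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_{GY}/y + \sigma^2_{GS}/s +
#'       (\sigma^2_{GYS}+\sigma^2_{GE})/(ys) + \sigma^2_e/(ysr))}
#' so the realized line-mean heritability matches \code{truth$target_h2}.
#' An unattainable target (the interaction terms alone already exceed the
#' non-genetic budget) is an error.
#'
#' Environments are the year x stress cells; blocks are balanced and nested
#' within replications.
#'
#' @param genotypes a [variant_matrix()] of the phenotyped material.
#' @param truth a [sim_truth()].
#' @param n_blocks number of incomplete blocks per replication (genotypes
#'   assigned round-robin); block effects have variance
#'   \code{env_params$sigma2_block} (default 0).
#' @param trait trait name recorded in the output.
#' @return a data frame with columns \code{genotype, environment, year,
#'   stress, replication, block, trait, value} and attributes
#'   \code{genetic_values} (truth) and \code{sigma2} (the generating
#'   variance components).
#' @export
simulate_phenotypes <- function(genotypes, truth, n_blocks = 1L,
                                trait = "yield") {
  stopifnot(inherits(genotypes, "variant_matrix"))
  ep <- truth$env_params
  y_n <- ep$y; s_n <- ep$s; r_n <- ep$r
  g <- genetic_values(genotypes, truth)
  n_g <- length(g)
  vG <- stats::var(g) * (n_g - 1) / n_g
  if (!is.finite(vG)) vG <- 0

  # interactions with a single-level factor are degenerate (they would act
  # as genetic main effects), so they are dropped from the model
  vGY <- if (y_n > 1) ep$sigma2_GY * vG else 0
  vGS <- if (s_n > 1) ep$sigma2_GS * vG else 0
  vGYS <- if (y_n > 1 && s_n > 1) ep$sigma2_GYS * vG else 0
  vGE <- if (is.null(ep$sigma2_GE) || y_n * s_n < 2) 0
    else ep$sigma2_GE * vG
  vE <- ep$sigma2_E * max(vG, 1)
  vB <- if (is.null(ep$sigma2_block)) 0 else ep$sigma2_block * max(vG, 1)

  h2 <- truth$target_h2
  if (vG == 0) {
    ve <- 0; vGY <- vGS <- vGYS <- vGE <- 0
  } else {
    if (h2 <= 0) stop("target_h2 must be > 0 when genetic variance is present")
    ve <- y_n * s_n * r_n *
      (vG * (1 / h2 - 1) - vGY / y_n - vGS / s_n - (vGYS + vGE) / (y_n * s_n))
    if (ve < -1e-9)
      stop("target_h2 inconsistent with the requested interaction variances ",
           "(implied residual variance is negative)")
    ve <- max(ve, 0)
  }

  with_temp_seed(truth$seed + 33L, {
    ids <- genotypes$sample_ids
    env_grid <- expand.grid(year = seq_len(y_n), stress = seq_len(s_n))
    env_grid$environment <- sprintf("Y%d_S%d", env_grid$year, env_grid$stress)
    l_n <- nrow(env_grid)

    E_eff <- stats::rnorm(l_n, 0, sqrt(vE))
    gy <- matrix(stats::rnorm(n_g * y_n, 0, sqrt(vGY)), n_g, y_n)
    gs <- matrix(stats::rnorm(n_g * s_n, 0, sqrt(vGS)), n_g, s_n)
    gys <- matrix(stats::rnorm(n_g * l_n, 0, sqrt(vGYS)), n_g, l_n)
    ge <- matrix(stats::rnorm(n_g * l_n, 0, sqrt(vGE)), n_g, l_n)

    block_of <- ((seq_len(n_g) - 1L) %% n_blocks) + 1L
    recs <- vector("list", l_n * r_n)
    k <- 0L
    for (e in seq_len(l_n)) {
      for (r in seq_len(r_n)) {
        k <- k + 1L
        b_eff <- stats::rnorm(n_blocks, 0, sqrt(vB))
        val <- ep$mu + g + E_eff[e] +
          gy[, env_grid$year[e]] + gs[, env_grid$stress[e]] +
          gys[, e] + ge[, e] + b_eff[block_of] +
          stats::rnorm(n_g, 0, sqrt(ve))
        recs[[k]] <- data.frame(
          genotype = ids,
          environment = env_grid$environment[e],
          year = env_grid$year[e],
          stress = env_grid$stress[e],
          replication = r,
          block = sprintf("%s_R%d_B%d", env_grid$environment[e], r, block_of),
          trait = trait,
          value = val,
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    attr(out, "genetic_values") <- g
    attr(out, "sigma2") <- c(G = vG, GY = vGY, GS = vGS, GYS = vGYS,
                             GE = vGE, E = vE, block = vB, residual = ve)
    out
  })
}

#' Simulate a k-mer depth histogram from a random genome
#'
#' Builds a random genome, then either samples error-free reads at the given
#' mean coverage and counts canonical k-mers literally
#' (\code{mode = "reads"}), or draws an independent Poisson(depth) copy
#' number per distinct genomic k-mer (\code{mode = "poisson"}, the standard
#' approximation when read length is much smaller than the genome). Returns
#' the depth-to-count histogram used by [estimate_genome_size()].
#'
#' @param genome_length genome size in bp (must exceed \code{k}).
#' @param depth mean sequencing depth (> 0).
#' @param k k-mer length (default 17).
#' @param mode \code{"poisson"} or \code{"reads"}.
#' @param read_length read length for \code{mode = "reads"}.
#' @param error_free must be \code{TRUE}; sequencing-error simulation is out
#'   of scope.
#' @param seed integer seed.
#' @return a \code{kmer_histogram} (see [kmer_histogram()]).
#' @export
simulate_reads_kmer <- function(genome_length, depth, k = 17L,
                                mode = c("poisson", "reads"),
                                read_length = 100L,
                                error_free = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (depth <= 0) stop("depth must be > 0")
  if (genome_length <= k) stop("genome_length must exceed k")
  if (!isTRUE(error_free))
    stop("error_free = FALSE is not supported (no read-error model)")
  with_temp_seed(seed + 44L, {
    genome <- paste(sample(c("A", "C", "G", "T"), genome_length,
                           replace = TRUE), collapse = "")
    if (mode == "poisson") {
      kmers <- canonical_kmers(genome, k)
      n_distinct <- length(unique(kmers))
      depths <- stats::rpois(n_distinct, depth)
      depths <- depths[depths > 0]
      tab <- table(depths)
      counts <- as.integer(tab)
      names(counts) <- names(tab)
    } else {
      n_reads <- ceiling(depth * genome_length / read_length)
      starts <- sample.int(genome_length - read_length + 1L, n_reads,
                           replace = TRUE)
      reads <- substring(genome, starts, starts + read_length - 1L)
      kmers <- unlist(lapply(reads, canonical_kmers, k = k))
      tab <- table(table(kmers))
      counts <- as.integer(tab)
      names(counts) <- names(tab)
    }
    new_kmer_histogram(k = k, counts = counts)
  })
}
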