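test_that("population simulation hits its divergence targets", {
  # no divergence: mean per-site Hudson FST is essentially zero
  tr0 <- sim_truth(seed = 4, n_loci = 5000, fst_target = 0)
  vm0 <- simulate_populations(tr0, 200, 200)
  sw <- milletgp:::site_counts(vm0$dosage[vm0$population == "wild", , drop = FALSE])
  sc <- milletgp:::site_counts(vm0$dosage[vm0$population == "cultivated", , drop = FALSE])
  expect_lt(abs(mean(hudson_fst(sw$p, sw$n, sc$p, sc$n), na.rm = TRUE)), 0.01)

  # fst_target 0.1: genome-wide ratio-of-averages estimate within 0.02
  tr1 <- sim_truth(seed = 3, n_loci = 5000, fst_target = 0.1)
  vm1 <- simulate_populations(tr1, 100, 100)
  sw <- milletgp:::site_counts(vm1$dosage[vm1$population == "wild", , drop = FALSE])
  sc <- milletgp:::site_counts(vm1$dosage[vm1$population == "cultivated", , drop = FALSE])
  cmp <- hudson_fst(sw$p, sw$n, sc$p, sc$n, components = TRUE)
  expect_equal(sum(cmp$num) / sum(cmp$den), 0.1, tolerance = 0.2)
  expect_lt(abs(sum(cmp$num) / sum(cmp$den) - 0.1), 0.02)
})

test_that("generators are deterministic in the seed and validate input", {
  tr <- sim_truth(seed = 5, n_loci = 400)
  a <- simulate_populations(tr, 20, 20)
  b <- simulate_populations(tr, 20, 20)
  expect_identical(a$dosage, b$dosage)
  expect_identical(a$pos, b$pos)
  expect_error(simulate_populations(tr, 1, 20), "at least 2")
  expect_error(simulate_populations(tr, 20, 20, n_loci = 0), "n_loci")

  p1 <- simulate_parent_panel(tr, 30)
  p2 <- simulate_parent_panel(tr, 30)
  expect_identical(p1$dosage, p2$dosage)

  h1 <- simulate_reads_kmer(5000, 10, seed = 2)
  h2 <- simulate_reads_kmer(5000, 10, seed = 2)
  expect_identical(h1$counts, h2$counts)
})

test_that("parent panels are inbred, labelled, and frequency-calibrated", {
  tr <- sim_truth(seed = 6, n_loci = 50)
  par <- simulate_parent_panel(tr, 580, n_b = 260)
  expect_equal(sum(par$population == "B"), 260)
  expect_equal(sum(par$population == "R"), 320)
  expect_true(all(par$dosage %in% c(0, 2)))
  expect_false(anyNA(par$dosage))

  # with no group divergence, each locus frequency falls inside the exact
  # 99% binomial interval of its generating frequency in >= 98% of loci
  tr2 <- sim_truth(seed = 7, n_loci = 1000)
  par2 <- simulate_parent_panel(tr2, 400, n_loci = 1000, group_fst = 0)
  p_hat <- colMeans(par2$dosage) / 2
  covered <- vapply(seq_len(1000), function(j) {
    ci <- stats::binom.test(round(p_hat[j] * 400), 400,
                            tr2$allele_freqs[j])$p.value
    ci >= 0.01
  }, logical(1))
  expect_gte(mean(covered), 0.98)
})

test_that("hybrid construction follows Mendelian dosage rules", {
  dos <- rbind(p1 = c(0, 2), p2 = c(2, 2), p3 = c(0, 0))
  par <- variant_matrix(dos, chrom = rep("chr1", 2), pos = c(10, 20))
  hy <- make_hybrids(par, rbind(c("p1", "p2"), c("p2", "p2"),
                                c("p1", "p3"), c("p1", "p1")))
  expect_equal(unname(hy$dosage[1, ]), c(1, 2))   # 0x2 -> het; 2x2 -> hom
  expect_equal(unname(hy$dosage[2, ]), c(2, 2))
  expect_equal(unname(hy$dosage[3, ]), c(0, 1))
  expect_equal(unname(hy$dosage[4, ]), unname(par$dosage["p1", ]))  # selfing

  het <- variant_matrix(matrix(c(1, 2), 2, 1), chrom = "chr1", pos = 5,
                        sample_ids = c("a", "b"))
  expect_error(make_hybrids(het, rbind(c("a", "b"))), "inbred")
  expect_error(make_hybrids(par, rbind(c("p1", "nope"))), "unknown")
})

test_that("phenotype generator realizes the requested heritability", {
  # degenerate case: no effects, no noise -> all records equal the mean
  tr0 <- sim_truth(seed = 8, n_loci = 20,
                   additive_effects = numeric(20),
                   dominance_effects = numeric(20),
                   env_params = list(sigma2_E = 0, y = 2, s = 1, r = 2))
  par0 <- simulate_parent_panel(tr0, 10, n_loci = 20)
  ph0 <- simulate_phenotypes(par0, tr0)
  expect_true(all(abs(ph0$value - tr0$env_params$mu) < 1e-12))

  # line means regress on true genetic values with slope ~1 and R2 ~ h2
  tr <- sim_truth(seed = 100, n_loci = 1000, n_causal = 200, target_h2 = 0.5,
                  env_params = list(y = 2, s = 1, r = 2))
  par <- simulate_parent_panel(tr, 300, n_loci = 1000)
  ph <- simulate_phenotypes(par, tr)
  expect_equal(nrow(ph), 300 * 2 * 2)
  g <- attr(ph, "genetic_values")
  lm_means <- tapply(ph$value, ph$genotype, mean)[names(g)]
  fit <- stats::lm(lm_means ~ g)
  expect_equal(unname(stats::coef(fit)[2]), 1, tolerance = 0.12)
  expect_lt(abs(summary(fit)$r.squared - 0.5), 0.05)

  # determinism
  ph2 <- simulate_phenotypes(par, tr)
  expect_identical(ph$value, ph2$value)

  # h2 = 1 with positive interaction variances is inconsistent
  tr_bad <- sim_truth(seed = 9, n_loci = 100, target_h2 = 1,
                      env_params = list(y = 2, s = 2, r = 2))
  par_bad <- simulate_parent_panel(tr_bad, 20, n_loci = 100)
  expect_error(simulate_phenotypes(par_bad, tr_bad), "inconsistent")
})

test_that("realized line-mean heritability matches the target within 0.07", {
  tr <- sim_truth(seed = 202, n_loci = 1000, n_causal = 200, target_h2 = 0.5,
                  env_params = list(y = 2, s = 1, r = 2))
  par <- simulate_parent_panel(tr, 300, n_loci = 1000)
  ph <- simulate_phenotypes(par, tr)
  f <- fit_lmm(ph, fixed = character(0),
               random = c("genotype", "year", "genotype:year"))
  vc <- c(G = f$varcomp[["genotype"]],
          GY = f$varcomp[["genotype:year"]],
          residual = f$varcomp[["residual"]])
  expect_lt(abs(heritability_line_mean(vc, y = 2, s = 1, r = 2) - 0.5), 0.07)
})

test_that("swept windows lose at least ~7-fold cultivated diversity", {
  sw_win <- data.frame(chrom = "chr1",
                       start = seq(2e6, 38e6, by = 4e6) + 1,
                       end = seq(2e6, 38e6, by = 4e6) + 1e5)
  tr <- sim_truth(seed = 7, n_loci = 20000, fst_target = 0.1,
                  sweep_windows = sw_win)
  vm <- simulate_populations(tr, 100, 100, chrom_length = 40e6)
  ws <- window_scan(vm)
  inw <- ws$start %in% sw_win$start
  expect_equal(sum(inw), 10)
  ratio <- mean(ws$theta_pi_cult[inw]) / mean(ws$theta_pi_cult[!inw])
  expect_lte(ratio, 0.15)
})

test_that("k-mer read simulation matches Poisson coverage expectations", {
  # depth 1, literal error-free reads: total k-mer instances close to
  # L - k + 1 (long reads keep the per-read edge loss below 2%)
  h1 <- simulate_reads_kmer(5000, 1, k = 17, mode = "reads",
                            read_length = 1000, seed = 3)
  expect_equal(h1$total_kmers, 5000 - 17 + 1, tolerance = 0.05)
  # Poisson mode: histogram peaks near the nominal depth
  h30 <- simulate_reads_kmer(50000, 30, seed = 4)
  depths <- as.integer(names(h30$counts))
  expect_lte(abs(depths[which.max(h30$counts)] - 30), 2)
  expect_error(simulate_reads_kmer(5000, 0), "depth")
  expect_error(simulate_reads_kmer(5000, 10, error_free = FALSE), "error")
  expect_error(simulate_reads_kmer(10, 5, k = 17), "exceed")
})

test_that("sweep window specifications must be disjoint", {
  sw <- data.frame(chrom = "chr1", start = c(1, 50), end = c(100, 120))
  expect_error(sim_truth(seed = 1, n_loci = 10, sweep_windows = sw),
               "disjoint")
})
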