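test_that("the GRM reproduces the hand-computed two-sample case", {
  vm <- variant_matrix(matrix(c(0, 2), 2, 1), chrom = "c", pos = 1L)
  K <- grm(vm)
  expect_equal(unname(K$G), matrix(c(2, -2, -2, 2), 2))
  expect_equal(K$denominator, 0.5)
})

test_that("the GRM equals the naive triple-loop formula", {
  set.seed(61)
  X <- matrix(rbinom(6 * 50, 2, runif(50, 0.2, 0.8)), 6, byrow = FALSE)
  vm <- variant_matrix(X, chrom = rep("c", 50), pos = 1:50)
  K <- grm(vm)
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  W <- sweep(X[, keep], 2, 2 * p[keep])
  den <- 2 * sum(p[keep] * (1 - p[keep]))
  G0 <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    G0[i, j] <- sum(W[i, ] * W[j, ]) / den
  expect_equal(unname(K$G), G0, tolerance = 1e-12)
})

test_that("pairwise-missing GRM reduces to the dense formula when complete", {
  set.seed(62)
  X <- matrix(rbinom(10 * 80, 2, 0.5), 10)
  vm <- variant_matrix(X, chrom = rep("c", 80), pos = 1:80)
  K_dense <- grm(vm)
  # run the pairwise-complete path on the same (complete) data
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  W <- sweep(X[, keep], 2, 2 * p[keep])
  pw <- milletgp:::grm_pairwise(W, p[keep] * (1 - p[keep]), vm$sample_ids)
  expect_equal(unname(pw$G), unname(K_dense$G), tolerance = 1e-12)

  # with real missingness, each entry matches a per-pair brute-force loop
  Xm <- X; Xm[sample(800, 60)] <- NA
  vm_m <- variant_matrix(Xm, chrom = rep("c", 80), pos = 1:80)
  K_miss <- grm(vm_m)
  pm <- colMeans(Xm, na.rm = TRUE) / 2
  keepm <- !is.na(pm) & pm > 0 & pm < 1
  Wm <- sweep(Xm[, keepm], 2, 2 * pm[keepm])
  pqm <- (pm * (1 - pm))[keepm]
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !is.na(Wm[i, ]) & !is.na(Wm[j, ])
    expect_equal(K_miss$G[i, j],
                 sum(Wm[i, ok] * Wm[j, ok]) / (2 * sum(pqm[ok])),
                 tolerance = 1e-12)
  }
  # a pair sharing no markers errors with the pair named
  Xp <- rbind(a = c(0, NA), b = c(NA, 2), c = c(1, 1))
  vm_p <- variant_matrix(Xp, chrom = c("c", "c"), pos = 1:2,
                         sample_ids = c("a", "b", "c"))
  expect_error(grm(vm_p), "a and b")
})

test_that("the GRM diagonal averages 1 for HWE diploids and 2 for inbreds", {
  set.seed(63)
  p <- runif(5000, 0.1, 0.9)
  vm <- hwe_panel(200, p, seed = 63)
  expect_lt(abs(mean(diag(grm(vm)$G)) - 1), 0.05)
  tr <- sim_truth(seed = 64, n_loci = 2000)
  par <- simulate_parent_panel(tr, 100, n_loci = 2000, group_fst = 0)
  expect_lt(abs(mean(diag(grm(par)$G)) - 2), 0.1)
})

test_that("G-BLUP equals marker-space ridge regression", {
  set.seed(65)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    p <- sample(20:200, 1)
    X <- matrix(rbinom(n * p, 2, runif(p, 0.1, 0.9)), n)
    vm <- variant_matrix(X, chrom = rep("c", p), pos = seq_len(p))
    K <- grm(vm)
    y <- stats::setNames(rnorm(n, 10, 2), vm$sample_ids)
    s2g <- runif(1, 0.5, 3); s2e <- runif(1, 0.5, 3)
    m <- fit_gblup(y, K, varcomp = c(s2g, s2e))
    # independent ridge oracle in marker space
    pf <- colMeans(X) / 2
    keep <- pf > 0 & pf < 1
    W <- sweep(X[, keep, drop = FALSE], 2, 2 * pf[keep])
    den <- 2 * sum(pf[keep] * (1 - pf[keep]))
    V <- s2g * tcrossprod(W) / den + diag(s2e, n)
    mu <- sum(solve(V, y)) / sum(solve(V, rep(1, n)))
    lam <- s2e / (s2g / den)
    u <- solve(crossprod(W) + diag(lam, ncol(W)), crossprod(W, y - mu))
    expect_lt(max(abs((m$mu + m$g_hat) - (mu + drop(W %*% u)))), 1e-8)
  }
})

test_that("G-BLUP interpolates as sigma2_e approaches zero", {
  tr <- sim_truth(seed = 63, n_loci = 400)
  par <- simulate_parent_panel(tr, 40, n_loci = 400)
  K <- grm(par)
  set.seed(66)
  y <- stats::setNames(rnorm(40, 10, 2), par$sample_ids)
  m <- suppressMessages(fit_gblup(y, K, varcomp = c(1, 1e-12)))
  expect_lt(max(abs(m$mu + m$g_hat - y)), 1e-6)
  # constant phenotype: all signal goes to the mean
  yc <- stats::setNames(rep(7, 40), par$sample_ids)
  mc <- fit_gblup(yc, K, varcomp = c(1, 1))
  expect_equal(mc$mu, 7)
  expect_lt(max(abs(mc$g_hat)), 1e-10)
})

test_that("shrinkage is monotone in the noise-to-signal ratio", {
  tr <- sim_truth(seed = 67, n_loci = 300)
  par <- simulate_parent_panel(tr, 30, n_loci = 300)
  K <- grm(par)
  set.seed(68)
  y <- stats::setNames(rnorm(30), par$sample_ids)
  norms <- vapply(c(0.1, 0.5, 1, 5, 20), function(s2e) {
    sqrt(sum(fit_gblup(y, K, varcomp = c(1, s2e))$g_hat^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 1e-10))
})

test_that("out-of-sample prediction works and guards id overlap", {
  tr <- sim_truth(seed = 62, n_loci = 100, n_causal = 100, target_h2 = 0.5)
  par <- simulate_parent_panel(tr, 300, n_loci = 100)
  g <- genetic_values(par, tr)
  set.seed(69)
  y <- stats::setNames(g + rnorm(300, 0, sd(g)), par$sample_ids)
  K <- grm(par)
  train <- par$sample_ids[1:250]; new <- par$sample_ids[251:300]
  m <- fit_gblup(y[train], K$G[train, train])
  pr <- predict_gblup(m, K$G[new, train])
  expect_gt(cor(pr, g[new]), 0.5)
  expect_error(predict_gblup(m, K$G[c(train[1], new[-1]), train]),
               "overlap")
  # zero cross-kinship predicts the mean for everyone
  K0 <- matrix(0, 2, length(train),
               dimnames = list(c("x1", "x2"), train))
  expect_equal(unname(predict_gblup(m, K0)), rep(m$mu, 2))
})

test_that("cross-validation is deterministic, calibrated, and accurate", {
  tr <- sim_truth(seed = 61, n_loci = 50, n_causal = 50, target_h2 = 0.8)
  par <- simulate_parent_panel(tr, 300, n_loci = 50)
  g <- genetic_values(par, tr)
  K <- grm(par)
  # phenotype identical to the true genetic value: near-perfect accuracy
  cv1 <- cross_validate(g, K, folds = 5, runs = 10, h2 = 1, seed = 3)
  expect_gte(cv1$summary[["mean_standardized"]], 0.9)
  # pure noise: mean accuracy within the null band
  set.seed(7)
  y0 <- stats::setNames(rnorm(300), par$sample_ids)
  cv0 <- cross_validate(y0, K, folds = 5, runs = 20, h2 = 1, seed = 3)
  expect_lt(abs(cv0$summary[["mean_r"]]), 2 / sqrt(20 * 60))
  # same seed, same result
  cv0b <- cross_validate(y0, K, folds = 5, runs = 20, h2 = 1, seed = 3)
  expect_identical(cv0$runs, cv0b$runs)
  expect_error(cross_validate(y0[1:10], K, folds = 5, runs = 1, h2 = 1),
               "fewer than 3")
})
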