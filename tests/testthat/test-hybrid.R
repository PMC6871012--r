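test_that("cross enumeration matches n(n-1)/2 and the B x R product", {
  ids3 <- c("a", "b", "c")
  expect_equal(nrow(enumerate_crosses(ids3)), 3)
  ids <- sprintf("L%03d", 1:580)
  cr <- enumerate_crosses(ids)
  expect_equal(nrow(cr), 167910)
  expect_equal(nrow(cr), choose(580, 2))
  grp <- rep(c("B", "R"), c(260, 320))
  crr <- enumerate_crosses(ids, restrict_between_groups = TRUE, groups = grp)
  expect_equal(nrow(crr), 260 * 320)
  expect_error(enumerate_crosses(c("a", "a")), "duplicate")
  # property: count for random sizes
  for (n in c(2, 17, 101)) {
    expect_equal(nrow(enumerate_crosses(sprintf("p%d", 1:n))),
                 n * (n - 1) / 2)
  }
})

test_that("additive and dominance design codes follow the -1/0/1 and 0/1 rule", {
  dos <- matrix(c(0, 2, 0,
                  2, 2, 0), nrow = 3,
                dimnames = list(c("p1", "p2", "p3"), NULL))
  par <- variant_matrix(dos, chrom = c("c", "c"), pos = 1:2)
  des <- hybrid_design(par, rbind(c("p1", "p2"), c("p2", "p2"),
                                  c("p1", "p3")))
  expect_equal(unname(des$Z_A[1, ]), c(0, 1))   # 0x2 -> 0; 2x2 -> 1
  expect_equal(unname(des$Z_D[1, ]), c(1, 0))
  expect_equal(unname(des$Z_A[2, ]), c(1, 1))
  expect_equal(unname(des$Z_D[2, ]), c(0, 0))
  expect_equal(unname(des$Z_A[3, ]), c(-1, 0)) # 0x0 -> -1; 0x2 -> 0
  expect_equal(unname(des$Z_D[3, ]), c(0, 1))
  het <- variant_matrix(matrix(c(1, 0), 2, 1), chrom = "c", pos = 1,
                        sample_ids = c("p1", "p2"))
  expect_error(hybrid_design(het, rbind(c("p1", "p2"))), "homozygous")
})

test_that("hybrid dosages and Z_A agree across modules", {
  tr <- sim_truth(seed = 71, n_loci = 60)
  par <- simulate_parent_panel(tr, 12, n_loci = 60)
  pairs <- enumerate_crosses(par$sample_ids)
  hy <- make_hybrids(par, pairs)
  des <- hybrid_design(par, pairs)
  expect_equal(unname(hy$dosage - 1), unname(des$Z_A))
  expect_equal(unname(hy$dosage == 1) * 1, unname(des$Z_D))
})

test_that("A+D ridge BLUP recovers a purely additive architecture", {
  tr <- sim_truth(seed = 11, n_loci = 500, n_causal = 100)
  par <- simulate_parent_panel(tr, 100, n_loci = 500)
  cr <- enumerate_crosses(par$sample_ids)
  set.seed(13)
  pick <- cr[sample(nrow(cr), 200), ]
  des <- hybrid_design(par, pick)
  ga <- drop(des$Z_A %*% tr$additive_effects)
  y <- ga + rnorm(200, 0, sd(ga) * 0.5)
  m <- fit_ad_rrblup(y, des)
  expect_lt(m$sigma2_d / m$sigma2_a, 0.05)
  m_add <- fit_ad_rrblup(y, des, varcomp = c(m$sigma2_a, 0, m$sigma2_e))
  expect_lt(sqrt(mean((m$fitted - m_add$fitted)^2)), 1e-3)
  # constant phenotype: no effects
  mc <- fit_ad_rrblup(rep(3, 200), des, varcomp = c(1, 1, 1))
  expect_equal(mc$mu, 3)
  expect_lt(max(abs(c(mc$a, mc$d))), 1e-10)
  expect_error(fit_ad_rrblup(y, des, varcomp = c(0, 0, 1)), "both")
})

test_that("A+D fit equals the two-kernel BLUP and reduces to G-BLUP", {
  tr <- sim_truth(seed = 72, n_loci = 200)
  par <- simulate_parent_panel(tr, 30, n_loci = 200)
  cr <- enumerate_crosses(par$sample_ids)
  set.seed(73)
  pick <- cr[sample(nrow(cr), 40), ]
  des <- hybrid_design(par, pick)
  y <- rnorm(40, 50, 5)
  s2a <- 0.02; s2d <- 0.01; s2e <- 2
  m <- fit_ad_rrblup(y, des, varcomp = c(s2a, s2d, s2e))
  # independent two-kernel BLUP oracle
  KA <- tcrossprod(des$Z_A); KD <- tcrossprod(des$Z_D)
  V <- s2a * KA + s2d * KD + diag(s2e, 40)
  mu <- sum(solve(V, y)) / sum(solve(V, rep(1, 40)))
  gh <- (s2a * KA + s2d * KD) %*% solve(V, y - mu)
  expect_lt(max(abs(m$fitted - (mu + gh))), 1e-8)

  # sigma2_d = 0 collapses onto single-kernel G-BLUP with K = Z_A Z_A'
  m0 <- fit_ad_rrblup(y, des, varcomp = c(s2a, 0, s2e))
  rownames(KA) <- colnames(KA) <- paste0("h", 1:40)
  g0 <- fit_gblup(stats::setNames(y, rownames(KA)), KA,
                  varcomp = c(s2a, s2e))
  expect_lt(max(abs(m0$fitted - (g0$mu + g0$g_hat))), 1e-8)
})

test_that("hybrid prediction ranks, scales to full enumerations, and is exact", {
  tr <- sim_truth(seed = 71, n_loci = 100, n_causal = 100,
                  dominance_ratio = 0.5, target_h2 = 0.8)
  par <- simulate_parent_panel(tr, 60, n_loci = 100)
  cr <- enumerate_crosses(par$sample_ids)
  set.seed(12)
  tri <- sample(nrow(cr), 64)
  train_pairs <- cr[tri, ]
  htr <- make_hybrids(par, train_pairs)
  g_tr <- genetic_values(htr, tr)
  y <- g_tr + rnorm(64, 0, sd(g_tr) * 0.5)
  des <- hybrid_design(par, train_pairs)
  m <- fit_ad_rrblup(y, des)

  # training-set predictions equal fitted values
  p_tr <- predict_hybrids(m, design = des)
  key <- paste(p_tr$parent1, p_tr$parent2)
  expect_equal(
    p_tr$value[match(paste(train_pairs$parent1, train_pairs$parent2), key)],
    unname(m$fitted), tolerance = 1e-10)

  # identity (parent-level) path agrees with the explicit design path
  p_all_exp <- predict_hybrids(m, design = hybrid_design(par, cr))
  p_all_idt <- predict_hybrids(m, parents = par, pairs = cr)
  o1 <- order(p_all_exp$parent1, p_all_exp$parent2)
  o2 <- order(p_all_idt$parent1, p_all_idt$parent2)
  expect_lt(max(abs(p_all_exp$value[o1] - p_all_idt$value[o2])), 1e-10)
  expect_identical(p_all_exp$rank[o1], p_all_idt$rank[o2])

  # unseen crosses correlate with their true genotypic values
  test_pairs <- cr[sample(setdiff(seq_len(nrow(cr)), tri), 500), ]
  g_te <- genetic_values(make_hybrids(par, test_pairs), tr)
  p_te <- predict_hybrids(m, parents = par, pairs = test_pairs)
  gte <- g_te[match(paste(p_te$parent1, p_te$parent2),
                    paste(test_pairs$parent1, test_pairs$parent2))]
  expect_gt(cor(p_te$value, gte), 0.6)

  # a self has Z_D = 0 everywhere: prediction is mu + Z_A a
  selfp <- predict_hybrids(m, parents = par,
                           pairs = data.frame(p1 = par$sample_ids[1],
                                              p2 = par$sample_ids[1]))
  zav <- sum((par$dosage[1, ] - 1) * m$a)
  expect_equal(selfp$value, m$mu + zav, tolerance = 1e-10)

  expect_error(predict_hybrids(m, parents = par[, 1:50], pairs = cr[1:2, ]),
               "mismatch")
})

test_that("top-fraction selection respects ceil, ties, and tested flags", {
  pred <- data.frame(parent1 = sprintf("a%04d", 1:1000),
                     parent2 = sprintf("b%04d", 1:1000),
                     value = c(rep(10, 3), seq(9, 0, length.out = 997)),
                     rank = 1:1000)
  sel <- select_top(pred, fraction = 0.001)
  expect_equal(sum(sel$selected), 3)  # ties at the cutoff all included
  sel2 <- select_top(pred, fraction = 1)
  expect_true(all(sel2$selected))
  tested <- data.frame(p1 = c("b0002", "a0500"), p2 = c("a0002", "b0500"))
  sel3 <- select_top(pred, fraction = 0.01, tested_list = tested)
  expect_equal(sum(sel3$previously_tested), 2)  # order-insensitive match
  expect_true(sel3$previously_tested[sel3$parent1 == "a0002"])
})

test_that("heterotic grouping recovers planted structure and its gain", {
  set.seed(3)
  parents <- sprintf("P%02d", 1:40)
  gtrue <- rep(1:2, each = 20)
  pr <- enumerate_crosses(parents)
  inter <- gtrue[match(pr$parent1, parents)] !=
    gtrue[match(pr$parent2, parents)]
  f <- mean(inter)
  base <- 100
  bonus <- 0.1 * base / ((1 - f) - 0.1 * f)  # solves gain = 10%
  pr$value <- base + bonus * inter + rnorm(nrow(pr), 0, 0.5)
  hg <- heterotic_groups(pr)
  expect_gt(mclust::adjustedRandIndex(hg$groups[parents], gtrue), 0.9)
  expect_lt(abs(hg$gain_percent - 10), 2)

  # constant predictions: zero gain
  prc <- pr; prc$value <- 5
  expect_equal(heterotic_groups(prc)$gain_percent, 0)

  # permutation of parent order leaves the partition unchanged
  perm <- sample(nrow(pr))
  hg2 <- heterotic_groups(pr[perm, ], parents = sample(parents))
  tab <- table(hg$groups[parents], hg2$groups[parents])
  expect_equal(sum(tab > 0), 2)  # one-to-one label correspondence
  expect_error(heterotic_groups(pr, k_groups = 100), "exceeds")
})
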