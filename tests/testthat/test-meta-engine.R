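test_that("hedges_g reproduces hand-evaluated values", {
  # m1=3, m2=1, s=1, n=10+10: sp=1, d=2, J=1-3/71
  res <- hedges_g(3, 1, 10, 1, 1, 10)
  J <- 1 - 3 / 71
  expect_equal(res$g, J * 2, tolerance = 1e-12)
  expect_equal(res$vg, J^2 * (20 / 100 + 4 / 36), tolerance = 1e-12)
  expect_equal(round(res$g, 4), 1.9155)
  expect_equal(round(res$vg, 4), 0.2854)

  # minimal df: n1=n2=2 -> J = 1 - 3/7
  res2 <- hedges_g(1, 1, 2, 0, 1, 2)
  expect_equal(res2$g, (1 - 3 / 7) * 1, tolerance = 1e-12)

  # null difference: g = 0, vg = J^2 (n1+n2)/(n1 n2)
  res3 <- hedges_g(2, 1.5, 8, 2, 0.5, 12)
  expect_equal(res3$g, 0)
  expect_equal(res3$vg, (1 - 3 / (4 * 18 - 1))^2 * 20 / 96, tolerance = 1e-12)

  expect_error(hedges_g(1, 0, 10, 0, 0, 10), "> 0")
  expect_error(hedges_g(1, 1, 1, 0, 1, 10), ">= 2")
})

test_that("build_vcv gives the stated block structure", {
  V <- build_vcv(c(1, 4), cluster = c("a", "a"), rho = 0.5)
  expect_equal(V[1, 2], 1.0)
  expect_equal(diag(V), c(`1` = 1, `2` = 4))
  # independence limit
  V0 <- build_vcv(c(1, 4), cluster = c("a", "a"), rho = 0)
  expect_equal(unclass(V0), diag(c(1, 4)), ignore_attr = TRUE)
  # across clusters always zero
  V2 <- build_vcv(c(1, 4), cluster = c("a", "b"), rho = 0.9)
  expect_equal(V2[1, 2], 0)
  expect_error(build_vcv(c(1, 1), rho = 1), "rho")
  expect_error(build_vcv(c(1, -1)), "> 0")
})

test_that("fixed GLS matches the hand-derived 2x2 case and IVW limit", {
  V <- build_vcv(c(1, 1), cluster = c("a", "a"), rho = 0.5)
  p <- pool_fixed_gls(c(1, 3), V)
  expect_equal(p$estimate, 2)
  expect_equal(p$se, sqrt(0.75))
  expect_equal(p$ci_low, 2 - 1.959964 * sqrt(0.75), tolerance = 1e-9)

  # diagonal V reduces to inverse-variance weighting
  v <- c(0.2, 0.5, 1)
  y <- c(0.1, 0.4, -0.2)
  p2 <- pool_fixed_gls(y, build_vcv(v, cluster = letters[1:3], rho = 0.7))
  expect_equal(p2$estimate, sum(y / v) / sum(1 / v), tolerance = 1e-12)
  expect_equal(p2$se, sqrt(1 / sum(1 / v)), tolerance = 1e-12)

  # equal variances, rho = 0: arithmetic mean
  p3 <- pool_fixed_gls(y, build_vcv(rep(2, 3), cluster = letters[1:3]))
  expect_equal(p3$estimate, mean(y), tolerance = 1e-12)
})

test_that("equal-variance common-cluster limit gives se^2 = v(1+(n-1)rho)/n", {
  for (rho in c(0, 0.3, 0.8)) {
    for (n in c(2, 5, 9)) {
      v <- 0.37
      V <- build_vcv(rep(v, n), cluster = rep("c", n), rho = rho)
      p <- pool_fixed_gls(rnorm(n), V)
      expect_equal(p$se^2, v * (1 + (n - 1) * rho) / n, tolerance = 1e-12)
    }
  }
})

test_that("se is non-decreasing in rho for a common cluster", {
  set.seed(11)
  y <- rnorm(6); v <- runif(6, 0.5, 0.5)
  ses <- vapply(seq(0, 0.9, by = 0.1), function(r) {
    pool_fixed_gls(y, build_vcv(v, cluster = rep("c", 6), rho = r))$se
  }, numeric(1))
  expect_true(all(diff(ses) >= -1e-12))
})

test_that("estimates are invariant to permuting effect order", {
  set.seed(21)
  y <- rnorm(8); v <- runif(8, 0.1, 1)
  cl <- sample(letters[1:3], 8, replace = TRUE)
  base <- pool_fixed_gls(y, build_vcv(v, cl, rho = 0.4))
  rob <- robust_variance(y, build_vcv(v, cl, rho = 0.4))
  for (i in 1:5) {
    pm <- sample(8)
    p2 <- pool_fixed_gls(y[pm], build_vcv(v[pm], cl[pm], rho = 0.4))
    r2 <- robust_variance(y[pm], build_vcv(v[pm], cl[pm], rho = 0.4))
    expect_equal(p2$estimate, base$estimate, tolerance = 1e-12)
    expect_equal(p2$se, base$se, tolerance = 1e-12)
    expect_equal(r2$se, rob$se, tolerance = 1e-12)
  }
})

test_that("DerSimonian-Laird matches the closed-form k=2 case and metafor", {
  p <- pool_random_dl(c(0, 2), c(1, 1))
  expect_equal(p$tau2, 1)
  expect_equal(p$estimate, 1)
  expect_equal(p$se, 1)

  # homogeneity: tau2 = 0, equals fixed IVW
  ph <- pool_random_dl(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.3))
  expect_equal(ph$tau2, 0)
  expect_equal(ph$estimate, 0.5)

  # scale equivariance in the tau2 = 0 regime
  y <- c(0.5, 0.5, 0.5); v <- c(0.1, 0.2, 0.3)
  expect_equal(pool_random_dl(y, 4 * v)$se, 2 * pool_random_dl(y, v)$se,
               tolerance = 1e-12)

  # independent oracle: metafor's DL estimator
  set.seed(5)
  y <- rnorm(10, 0.3, 0.4); v <- runif(10, 0.05, 0.3)
  fit <- metafor::rma(yi = y, vi = v, method = "DL")
  mine <- pool_random_dl(y, v)
  expect_equal(mine$estimate, as.numeric(fit$beta), tolerance = 1e-10)
  expect_equal(mine$se, fit$se, tolerance = 1e-10)
  expect_equal(mine$tau2, fit$tau2, tolerance = 1e-10)

  expect_error(pool_random_dl(1, 1), "at least 2")
})

test_that("cluster-robust variance matches direct summation and metafor", {
  # each effect its own cluster, equal v, rho = 0: classic HC form
  set.seed(31)
  y <- rnorm(6); v <- rep(0.5, 6)
  V <- build_vcv(v, cluster = letters[1:6], rho = 0)
  r <- robust_variance(y, V)
  est <- mean(y)  # equal weights
  e <- y - est
  m <- 6
  expect_equal(r$estimate, est, tolerance = 1e-12)
  expect_equal(r$se^2, (m / (m - 1)) * sum(e^2) / m^2, tolerance = 1e-12)
  expect_equal(r$ci_high - r$estimate, qt(0.975, m - 1) * r$se,
               tolerance = 1e-12)

  # two clusters with mirror-image residuals: enumerate the two terms
  y2 <- c(1, -1); V2 <- build_vcv(c(1, 1), cluster = c("a", "b"), rho = 0)
  r2 <- robust_variance(y2, V2)
  expect_equal(r2$estimate, 0)
  expect_equal(r2$se^2, 2 * (1^2 + 1^2) / 4, tolerance = 1e-12)

  # zero residuals flagged degenerate
  r3 <- robust_variance(c(0.4, 0.4),
                        build_vcv(c(0.1, 0.1), cluster = c("a", "b")))
  expect_equal(r3$se, 0)
  expect_true(r3$degenerate)

  # general case against metafor's cluster-robust machinery
  set.seed(32)
  y <- rnorm(9, 0.2, 0.5); v <- runif(9, 0.05, 0.2)
  cl <- rep(c("a", "b", "c"), each = 3)
  V <- build_vcv(v, cluster = cl, rho = 0.5)
  mine <- robust_variance(y, V)
  fit <- metafor::rma.mv(yi = y, V = unclass(V), method = "FE",
                         sparse = FALSE)
  rob <- metafor::robust(fit, cluster = cl, adjust = TRUE)
  expect_equal(mine$estimate, as.numeric(rob$beta), tolerance = 1e-8)
  expect_equal(mine$se, rob$se, tolerance = 1e-8)

  expect_error(robust_variance(y, build_vcv(v, cluster = rep("a", 9))),
               "clusters")
})

test_that("leave-one-cluster-out matches subset-refit oracles", {
  ds <- toy_dataset()
  loo <- leave_one_cluster_out(ds, cluster_by = "study_id",
                               method = "fixed_gls", rho = 0.5)
  expect_equal(nrow(loo), 3)
  eff <- ds$effects
  for (i in seq_len(nrow(loo))) {
    keep <- eff$study_id != loo$cluster[i]
    V <- build_vcv(eff$vi[keep], cluster = eff$study_id[keep], rho = 0.5)
    orc <- oracle_gls(eff$yi[keep], unclass(V))
    expect_equal(loo$rest_estimate[i], orc$estimate, tolerance = 1e-10)
    expect_equal(loo$rest_se[i], orc$se, tolerance = 1e-10)
  }

  # 2 clusters: each complement equals the other's own estimate
  eff2 <- eff[eff$study_id %in% c("s1", "s2"), ]
  ds2 <- evimap_dataset(eff2)
  loo2 <- leave_one_cluster_out(ds2, cluster_by = "study_id",
                                method = "fixed_gls")
  expect_equal(loo2$rest_estimate[1], loo2$own_estimate[2], tolerance = 1e-12)
  expect_equal(loo2$rest_estimate[2], loo2$own_estimate[1], tolerance = 1e-12)

  expect_error(leave_one_cluster_out(
    evimap_dataset(eff[eff$study_id == "s1", ]), cluster_by = "study_id"),
    ">= 2")
})
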