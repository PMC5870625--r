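# Activity inference statistics against independent oracles and their
# structural properties.

test_that("z-test matches the textbook formula and its symmetries", {
  tf <- toy_fc(n = 200, n_sub = 5, shift = 2)
  r <- activity_ztest(tf$fc, tf$substrates)
  o <- oracle_ztest(tf$fc, tf$substrates)
  expect_equal(r$statistic, o$z, tolerance = 1e-10)
  expect_equal(r$p_value, o$p, tolerance = 1e-10)
  expect_equal(r$signed_score, sign(r$mean_fc) * -log10(r$p_value))

  # substrates at the background mean give z = 0, p = 1, score 0
  fc <- c(a_1 = -1, b_1 = 1, c_1 = 0, d_1 = 2, e_1 = -2)
  r0 <- activity_ztest(fc, "c_1")
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$signed_score, 0)

  # antisymmetry: negating all fold changes negates z and the signed score
  rneg <- activity_ztest(-tf$fc, tf$substrates)
  expect_equal(rneg$statistic, -r$statistic, tolerance = 1e-12)
  expect_equal(rneg$p_value, r$p_value, tolerance = 1e-12)
  expect_equal(rneg$signed_score, -r$signed_score, tolerance = 1e-10)

  # no quantified substrate -> no score (not score 0)
  expect_null(activity_ztest(tf$fc, "ZZZ_9"))
  # degenerate background
  expect_error(activity_ztest(c(a_1 = 1, b_1 = 1, c_1 = 1), "a_1"),
               "degenerate")
})

test_that("z-test agrees with the formula oracle on 100 random instances", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    k <- sample(1:10, 1)
    fc <- rnorm(n, 0, runif(1, 0.5, 2))
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    r <- activity_ztest(fc, subs)
    o <- oracle_ztest(fc, subs)
    expect_equal(r$statistic, o$z, tolerance = 1e-8)
    expect_equal(r$p_value, o$p, tolerance = 1e-8)
  }
})

test_that("KS statistic equals the explicit ECDF double loop", {
  set.seed(102)
  for (i in 1:100) {
    n <- sample(20:100, 1)
    k <- sample(2:8, 1)
    fc <- rnorm(n)
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    r <- activity_ks(fc, subs, exact = FALSE)
    x <- fc[names(fc) %in% subs]; y <- fc[!names(fc) %in% subs]
    expect_equal(r$statistic, oracle_ks_d(x, y), tolerance = 1e-12)
    expect_equal(r$p_value, oracle_kolmogorov_p(r$statistic, k, n - k),
                 tolerance = 1e-8)
  }
})

test_that("exact KS p equals label-assignment enumeration on small instances", {
  set.seed(110)
  for (i in 1:10) {
    n <- sample(8:12, 1)
    k <- sample(2:3, 1)
    fc <- rnorm(n)
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    r <- activity_ks(fc, subs) # tie-free draws take the exact path
    x <- fc[names(fc) %in% subs]; y <- fc[!names(fc) %in% subs]
    expect_equal(r$p_value, oracle_ks_exact_p(x, y), tolerance = 1e-10)
  }
})

test_that("KS edge cases and agreement with stats::ks.test", {
  # identical multisets -> D = 0, p = 1
  fc <- c(a_1 = 1, b_1 = 2, c_1 = 3, d_1 = 1, e_1 = 2, f_1 = 3)
  r <- activity_ks(fc, c("a_1", "b_1", "c_1"))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # complete separation -> D = 1
  fc2 <- c(a_1 = 10, b_1 = 11, c_1 = 1, d_1 = 2, e_1 = 0)
  expect_equal(activity_ks(fc2, c("a_1", "b_1"))$statistic, 1)
  # D identical to stats::ks.test, p to its asymptotic value
  set.seed(103)
  fc3 <- rnorm(80); names(fc3) <- sprintf("P%02d_1", 1:80)
  subs <- names(fc3)[1:10]
  r3 <- activity_ks(fc3, subs, exact = FALSE)
  ht <- suppressWarnings(ks.test(fc3[1:10], fc3[-(1:10)], exact = FALSE))
  expect_equal(r3$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(r3$p_value, ht$p.value, tolerance = 1e-4)
  # exact path agrees with ks.test(exact = TRUE)
  r4 <- activity_ks(fc3[1:20], subs[1:5])
  ht4 <- ks.test(fc3[1:5], fc3[6:20], exact = TRUE)
  expect_equal(r4$p_value, ht4$p.value, tolerance = 1e-12)
})

test_that("Wilcoxon matches the tie-corrected normal approximation oracle", {
  set.seed(104)
  for (i in 1:100) {
    n <- sample(20:100, 1)
    k <- sample(2:8, 1)
    fc <- round(rnorm(n), sample(1:2, 1)) # rounding induces ties
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    tied <- length(unique(fc)) == 1
    if (tied) next
    r <- activity_wilcoxon(fc, subs)
    o <- oracle_wilcoxon(fc[names(fc) %in% subs], fc[!names(fc) %in% subs])
    expect_equal(unname(r$statistic), o$W, tolerance = 1e-10)
    expect_equal(r$p_value, o$p, tolerance = 1e-8)
  }
  # label swap leaves the p-value unchanged
  tf <- toy_fc(n = 30, n_sub = 12, shift = 1)
  p1 <- activity_wilcoxon(tf$fc, tf$substrates)$p_value
  p2 <- activity_wilcoxon(tf$fc, setdiff(names(tf$fc), tf$substrates))$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("enrichment score matches the naive running-sum oracle", {
  set.seed(105)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    k <- sample(1:6, 1)
    fc <- rnorm(n)
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    r <- activity_ksea(fc, subs, n_perm = 10, seed = 1)
    expect_equal(r$statistic, oracle_es(fc, subs), tolerance = 1e-12)
  }
  # substrates occupying the top ranks give ES = 1
  fc <- c(a_1 = 5, b_1 = 4, c_1 = 1, d_1 = 0.5, e_1 = -1)
  r <- activity_ksea(fc, c("a_1", "b_1"), n_perm = 10, seed = 1)
  expect_equal(r$statistic, 1)
})

test_that("exhaustive enrichment p equals subset enumeration and MC agrees", {
  set.seed(106)
  for (i in 1:10) {
    n <- sample(8:15, 1)
    k <- sample(2:3, 1)
    fc <- rnorm(n)
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    subs <- names(fc)[sample(n, k)]
    r <- activity_ksea(fc, subs, exhaustive = TRUE)
    expect_equal(r$p_value, oracle_ksea_exhaustive_p(fc, subs),
                 tolerance = 1e-12)
  }
  # Monte-Carlo p within 3 binomial SDs of the exhaustive value
  fc <- toy_fc(n = 12, n_sub = 3, shift = 1, seed = 9)$fc
  subs <- names(fc)[1:3]
  p0 <- activity_ksea(fc, subs, exhaustive = TRUE)$p_value
  pm <- activity_ksea(fc, subs, n_perm = 10000, seed = 5)$p_value
  tol <- 3 * sqrt(p0 * (1 - p0) / 10000) + 1 / 10001
  expect_lt(abs(pm - p0), tol)
  # same seed -> identical p
  pm2 <- activity_ksea(fc, subs, n_perm = 10000, seed = 5)$p_value
  expect_identical(pm, pm2)
})

test_that("degenerate all-zero substrate fold changes are rejected", {
  fc <- c(a_1 = 0, b_1 = 0, c_1 = 1, d_1 = -1)
  expect_error(activity_ksea(fc, c("a_1", "b_1"), n_perm = 10),
               "degenerate")
})

test_that("ridge regression equals the closed form and the QR oracle", {
  set.seed(107)
  # lambda = 0, identity connectivity: beta recovers Y
  fc <- rnorm(5)
  names(fc) <- sprintf("P%d_1", 1:5)
  regs <- as.list(names(fc))
  names(regs) <- paste0("K", 1:5)
  r <- activity_mlr(fc, regs, lambda = 0)
  expect_equal(r$signed_score, unname(fc), tolerance = 1e-10)

  # random instances vs augmented-QR oracle
  for (i in 1:20) {
    n <- sample(30:80, 1)
    nk <- sample(3:8, 1)
    fc <- rnorm(n)
    names(fc) <- sprintf("P%03d_1", seq_len(n))
    regs <- lapply(seq_len(nk), function(j) names(fc)[sample(n, sample(3:10, 1))])
    names(regs) <- paste0("K", seq_len(nk))
    lambda <- runif(1, 0.05, 1)
    r <- activity_mlr(fc, regs, lambda = lambda)
    X <- vapply(regs, function(s) as.numeric(names(fc) %in% s), numeric(n))
    expect_equal(r$signed_score, unname(oracle_ridge(X, fc, lambda)),
                 tolerance = 1e-8)
  }

  # two kinases with identical regulons get equal coefficients
  fc <- rnorm(20); names(fc) <- sprintf("P%02d_1", 1:20)
  regs <- list(K1 = names(fc)[1:5], K2 = names(fc)[1:5])
  r2 <- activity_mlr(fc, regs, lambda = 0.1)
  expect_equal(r2$signed_score[1], r2$signed_score[2], tolerance = 1e-12)

  # antisymmetry
  regs3 <- list(K1 = names(fc)[1:5], K2 = names(fc)[8:15])
  b1 <- activity_mlr(fc, regs3, lambda = 0.1)$signed_score
  b2 <- activity_mlr(-fc, regs3, lambda = 0.1)$signed_score
  expect_equal(b1, -b2, tolerance = 1e-12)
})

test_that("infer_activities scores every quantified cell and is row-order invariant", {
  ds <- simulate_dataset(simulation_config(
    n_sites = 300, n_kinases = 3, regulon_size_range = c(5, 8),
    n_conditions = 3, regulated_per_condition = 1, missing_rate = 0,
    seed = 21
  ))
  sc <- infer_activities(ds$quant, ds$network, method = "ztest")
  expect_equal(nrow(sc), 3 * 3)
  expect_true(all(sc$n_sub >= 1))

  # permuting the site rows leaves every score unchanged
  perm <- sample(nrow(ds$quant$values))
  m2 <- site_quant(ds$quant$values[perm, ], normalized = TRUE)
  sc2 <- infer_activities(m2, ds$network, method = "ztest")
  o <- order(sc$kinase, sc$condition)
  o2 <- order(sc2$kinase, sc2$condition)
  expect_equal(sc$signed_score[o], sc2$signed_score[o2], tolerance = 1e-12)

  # a kinase with no quantified substrates in a condition yields no row
  v <- ds$quant$values
  reg1 <- regulons(ds$network)[[1]]
  kin1 <- names(regulons(ds$network))[1]
  v[ds$quant$sites$match_key %in% reg1, 1] <- NA
  m3 <- site_quant(v, normalized = TRUE)
  sc3 <- infer_activities(m3, ds$network, method = "ztest")
  expect_equal(nrow(sc3), 8)
  expect_false(any(sc3$kinase == kin1 & sc3$condition == ds$quant$conditions[1]))

  expect_error(infer_activities(ds$quant, ds$network, method = "bogus"))
})
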