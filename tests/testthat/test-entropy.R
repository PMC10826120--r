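test_that("entropy matches closed forms and hand-derived values", {
  expect_equal(entropy(c(1, 1, 1)), log(3), tolerance = 1e-12)
  expect_equal(entropy(c(7, 0, 0)), 0)
  expect_equal(entropy(c(1, 2, 3)), log(6) - (2 * log(2) + 3 * log(3)) / 6,
               tolerance = 1e-12)
  expect_error(entropy(c(0, 0)), "all-zero")
  expect_error(entropy(c(-1, 2)), "non-negative")
})

test_that("entropy, MI and interaction information match brute-force oracles", {
  set.seed(42)
  for (i in 1:300) {
    v <- rmultinom(1, 200, runif(9) + 0.05)
    expect_equal(entropy(v), oracle_entropy(v), tolerance = 1e-12)
    m <- matrix(v, 3)
    expect_equal(mutual_information(m), oracle_mi(m), tolerance = 1e-12)
    a <- array(rmultinom(1, 300, runif(27) + 0.05), c(3, 3, 3))
    expect_equal(interaction_information(a), oracle_ii(a), tolerance = 1e-12)
  }
})

test_that("MI is zero under independence, H(X) under determinism, symmetric", {
  m <- outer(c(10, 20, 30), c(5, 10, 5))       # product-form joint
  expect_equal(mutual_information(m), 0, tolerance = 1e-12)
  d <- diag(c(12, 7, 21))                       # perfectly coupled
  expect_equal(mutual_information(d), entropy(rowSums(d)), tolerance = 1e-12)
  set.seed(1)
  r <- matrix(rmultinom(1, 200, runif(9)), 3)
  expect_equal(mutual_information(r), mutual_information(t(r)),
               tolerance = 1e-12)
  expect_gte(mutual_information(r), -1e-12)
})

test_that("interaction information is exchangeable and captures XOR synergy", {
  set.seed(2)
  a <- array(rmultinom(1, 500, runif(27) + 0.02), c(3, 3, 3))
  base <- interaction_information(a)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(interaction_information(aperm(a, perm)), base,
                 tolerance = 1e-12)
  }
  # XOR parity on a 2x2x2 embedded support: pure synergy of -log(2)
  x <- array(0, c(3, 3, 3))
  for (i in 0:1) for (j in 0:1) x[i + 1, j + 1, bitwXor(i, j) + 1] <- 25
  expect_equal(interaction_information(x), -log(2), tolerance = 1e-12)
  # three independent margins -> zero
  ind <- outer(outer(c(1, 2, 1), c(3, 1, 2)), c(2, 2, 1))
  expect_equal(interaction_information(ind), 0, tolerance = 1e-12)
})

test_that("info_gain is zero for identical strata and antisymmetric under swap", {
  co <- fixture_small()
  sc <- stratified_counts(co, c("trip1_a", "trip1_b", "trip1_c"))
  swapped <- sc
  swapped$case_counts <- sc$control_counts
  swapped$control_counts <- sc$case_counts
  expect_equal(info_gain(swapped), -info_gain(sc), tolerance = 1e-12)

  same <- sc
  same$control_counts <- sc$case_counts
  expect_equal(info_gain(same), 0, tolerance = 1e-12)
})

test_that("stratified counts are exhaustive, tuple-wise deleted and match an oracle", {
  co <- random_cohort(80, 4, missing_rate = 0.15, seed = 9)
  ids <- snp_meta(co)$snp_id[1:3]
  sc <- stratified_counts(co, ids)
  orc <- oracle_triplet_counts(co, ids)
  expect_equal(sc$case_counts, orc$case)
  expect_equal(sc$control_counts, orc$control)
  g <- genotypes(co)[, ids]
  n_complete <- sum(stats::complete.cases(g))
  expect_equal(sc$n_case + sc$n_control, n_complete)
})

test_that("lambda scales as 1/N and floors for degenerate strata", {
  set.seed(5)
  co_counts <- matrix(rmultinom(1, 400, runif(9) + 0.1), 3)
  ca_counts <- matrix(rmultinom(1, 300, runif(9) + 0.1), 3)
  sc <- structure(list(k = 2L, case_counts = ca_counts,
                       control_counts = co_counts,
                       snp_ids = c("a", "b"), n_case = 300, n_control = 400),
                  class = "stratified_counts")
  sc2 <- sc
  sc2$case_counts <- 2 * ca_counts; sc2$control_counts <- 2 * co_counts
  sc2$n_case <- 600; sc2$n_control <- 800
  expect_equal(lambda_variance(sc2), lambda_variance(sc) / 2,
               tolerance = 1e-9)

  degen <- sc
  degen$case_counts <- matrix(c(300, rep(0, 8)), 3)
  degen$control_counts <- matrix(c(400, rep(0, 8)), 3)
  expect_equal(lambda_variance(degen), 1e-12)
})

test_that("stratum-weight lambda tracks the bootstrap variance of the gain", {
  # delta-method validity regime: dependent X,Y (non-zero weights), resampled
  # from fixed per-stratum distributions
  set.seed(8)
  p_ca <- matrix(c(0.22, 0.05, 0.03, 0.05, 0.25, 0.05, 0.03, 0.05, 0.27), 3)
  p_co <- matrix(c(0.25, 0.04, 0.04, 0.04, 0.22, 0.06, 0.03, 0.06, 0.26), 3)
  n1 <- 350; n0 <- 300
  gains <- replicate(500, {
    mutual_information(matrix(rmultinom(1, n1, p_ca), 3)) -
      mutual_information(matrix(rmultinom(1, n0, p_co), 3))
  })
  sc <- structure(list(k = 2L,
                       case_counts = matrix(round(p_ca * n1), 3),
                       control_counts = matrix(round(p_co * n0), 3),
                       snp_ids = c("a", "b"),
                       n_case = sum(round(p_ca * n1)),
                       n_control = sum(round(p_co * n0))),
                  class = "stratified_counts")
  lam <- lambda_variance(sc, weights = "stratum")
  expect_gt(lam, var(gains) / 2)
  expect_lt(lam, var(gains) * 2)
})

test_that("the test statistic maps printed T values to their p-values", {
  expect_equal(round(chisq1_pvalue(8.25), 3), 0.004)
  expect_equal(round(chisq1_pvalue(7.47), 3), 0.006)
  ts <- test_statistic(gain = 0, lambda_norm = 1e-4)
  expect_equal(ts$t_stat, 0)
  expect_equal(ts$p_chi2, 1)
  expect_error(test_statistic(0.1, 0), "positive")
})

test_that("planted-triplet IIG outranks null triplets in large cohorts", {
  spec <- simulation_spec(2000, 2000, n_background_snps = 20,
    planted_triplets = list(make_parity_penetrance(base = 0.1, effect = 0.08)),
    baseline_prevalence = 0.1, seed = 77)
  co <- simulate_cohort(spec)
  planted <- abs(info_gain(stratified_counts(
    co, c("trip1_a", "trip1_b", "trip1_c"))))
  bg <- snp_meta(co)$snp_id[1:20]
  set.seed(3)
  null_iigs <- replicate(100, {
    abs(info_gain(stratified_counts(co, sample(bg, 3))))
  })
  expect_gt(planted, quantile(null_iigs, 0.95))
})
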