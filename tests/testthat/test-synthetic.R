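test_that("fixed schedule without dropout yields exactly n x visits records", {
  truth <- small_truth()
  prof <- cohort_profile("A", c(0, 10), c(0, 1, 2, 5, 10),
                         schedule_jitter_sd = 0, dropout_hazard = 0,
                         n_children = 10)
  out <- generate_cohort(prof, truth, seed = 1)
  expect_equal(nrow(out$measurements), 50)
  expect_equal(nrow(out$children), 10)
})

test_that("degenerate noise puts every weight exactly on the fixed curve", {
  basis <- basis_spec("FP", powers = c(0, 1))
  truth <- truth_params(basis,
                        beta = list(baseline = c(3.5, 4.5, 2.2)),
                        G = matrix(0, 3, 3),
                        level1 = list(spec = level1_spec("segmented", 2),
                                      variances = c(0, 0)))
  prof <- cohort_profile("A", c(0, 10), c(0, 1, 2, 5, 10),
                         schedule_jitter_sd = 0, dropout_hazard = 0,
                         n_children = 4)
  out <- generate_cohort(prof, truth, seed = 2)
  expected <- drop(cbind(1, basis_matrix(out$measurements$age, basis)) %*%
                     c(3.5, 4.5, 2.2))
  expect_equal(out$measurements$weight, expected, tolerance = 1e-12)
})

test_that("per-child measurement counts track the schedule under dropout", {
  truth <- small_truth()
  prof <- cohort_profile("P", c(0, 16),
                         c(0, 1/12, 2/12, 0.25, 0.5, 0.75, 1, 2, 4, 6.5,
                           9, 11.5, 16),
                         schedule_jitter_sd = 0.05, dropout_hazard = 0.01,
                         n_children = 1000)
  out <- generate_cohort(prof, truth, seed = 3)
  counts <- table(out$measurements$child_id)
  expect_lte(abs(stats::median(counts) - 13), 2)
})

test_that("multi-cohort generation pools deterministically with unique ids", {
  truth <- small_truth()
  profs <- default_cohort_profiles(c(100, 50, 100, 50, 100))
  # small truth is 3-dimensional; use a 5-cohort run with the default truth
  dt <- default_truth()
  pooled <- generate_multi_cohort(profs, dt, seed = 11)
  expect_equal(nrow(pooled$children), 400)
  expect_equal(anyDuplicated(pooled$children$child_id), 0L)
  pooled2 <- generate_multi_cohort(profs, dt, seed = 11)
  expect_identical(pooled$measurements, pooled2$measurements)
  expect_identical(pooled$children, pooled2$children)
  expect_error(generate_multi_cohort(profs[1], dt, seed = 1),
               "at least two")
  expect_error(generate_multi_cohort(list(profs[[1]], profs[[1]]), dt,
                                     seed = 1), "duplicate")
})

test_that("non-overlapping age windows leave a gap in the pooled ages", {
  truth <- small_truth()
  p1 <- cohort_profile("A", c(0, 5), c(0, 1, 2, 5), 0.05, 0, 50)
  p2 <- cohort_profile("B", c(9, 18), c(9, 12, 15, 18), 0.05, 0, 50)
  pooled <- generate_multi_cohort(list(p1, p2), truth, seed = 4)
  agesA <- pooled$measurements$age[pooled$measurements$cohort == "A"]
  agesB <- pooled$measurements$age[pooled$measurements$cohort == "B"]
  expect_lte(max(agesA), 5)
  expect_gte(min(agesB), 9)
  expect_equal(sum(pooled$measurements$age > 5 &
                     pooled$measurements$age < 9), 0)
})

test_that("no measurement falls outside its cohort's age window", {
  pooled <- small_pooled(120, 80, seed = 5)
  agesA <- pooled$measurements$age[pooled$measurements$cohort == "A"]
  agesB <- pooled$measurements$age[pooled$measurements$cohort == "B"]
  expect_true(all(agesA >= 0 & agesA <= 10))
  expect_true(all(agesB >= 0 & agesB <= 5))
})

test_that("covariate missingness mechanism is null, calibrated and MAR", {
  pooled <- small_pooled(150, 100, seed = 6)
  proxy <- child_mean_weight(pooled)

  null_mech <- missingness_spec("maternal_education", intercept = -Inf)
  same <- apply_covariate_missingness(pooled$children, null_mech, proxy,
                                      seed = 1)
  expect_identical(same, pooled$children)

  # calibrated marginal rate: p = 0.2 with zero slope
  big <- data.frame(child_id = sprintf("c%06d", 1:10000), cohort = "A",
                    maternal_education = "degree or higher")
  bigproxy <- stats::setNames(rep(10, 10000), big$child_id)
  mech <- missingness_spec("maternal_education",
                           intercept = stats::qlogis(0.2))
  out <- apply_covariate_missingness(big, mech, bigproxy, seed = 2)
  frac <- mean(is.na(out$maternal_education))
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(frac - 0.2), 3 * se)

  # outcome-dependent: heavier children more often missing
  mar <- missingness_spec("maternal_education", intercept = -4,
                          slope = 0.25)
  out2 <- apply_covariate_missingness(pooled$children, mar, proxy,
                                      seed = 3)
  miss <- is.na(out2$maternal_education)
  expect_gt(sum(miss), 5)
  expect_gt(mean(proxy[as.character(out2$child_id[miss])]),
            mean(proxy[as.character(out2$child_id[!miss])]))
  expect_error(
    apply_covariate_missingness(pooled$children,
                                missingness_spec("nope", 0), proxy, 1),
    "unknown covariate")
})

test_that("between-child covariance and level-1 variances are recovered", {
  # dense single-cohort design so per-child OLS is well conditioned
  basis <- basis_spec("FP", powers = 1)
  G <- matrix(c(0.5, 0.1, 0.1, 0.08), 2, 2)
  truth <- truth_params(basis, beta = list(baseline = c(4, 2.5)), G = G,
                        level1 = list(spec = level1_spec("segmented", 2),
                                      variances = c(0.2, 0.8)))
  prof <- cohort_profile("A", c(0, 10), seq(0, 10, by = 1),
                         schedule_jitter_sd = 0.05, dropout_hazard = 0,
                         n_children = 5000)
  out <- generate_cohort(prof, truth, seed = 9)
  df <- out$measurements
  Z <- cbind(1, df$age)
  idx <- split(seq_len(nrow(df)), df$child_id)
  coefs <- t(vapply(idx, function(ii)
    qr.solve(Z[ii, ], df$weight[ii]), numeric(2)))
  emp <- stats::cov(coefs)
  # per-child OLS noise inflates the diagonal by E[(Z'Z)^-1 sigma^2]
  ZtZinv <- solve(crossprod(Z[idx[[1]], ])) * mean(c(0.2, 0.8))
  expect_equal(emp[1, 1], G[1, 1] + ZtZinv[1, 1], tolerance = 0.12)
  expect_equal(emp[2, 2], G[2, 2] + ZtZinv[2, 2], tolerance = 0.12)
  expect_equal(emp[1, 2], G[1, 2] + ZtZinv[1, 2], tolerance = 0.12)
  # level-1 variance by segment: with no random effects the residuals
  # about the population line estimate sigma^2_s directly
  truth0 <- truth_params(basis, beta = list(baseline = c(4, 2.5)),
                         G = matrix(0, 2, 2),
                         level1 = list(spec = level1_spec("segmented", 2),
                                       variances = c(0.2, 0.8)))
  out0 <- generate_cohort(prof, truth0, seed = 10)
  r0 <- stats::resid(stats::lm(weight ~ age, data = out0$measurements))
  seg <- out0$measurements$age > 2
  expect_equal(stats::var(r0[!seg]), 0.2, tolerance = 0.05)
  expect_equal(stats::var(r0[seg]), 0.8, tolerance = 0.05)
})

test_that("synthetic datasets round-trip with their truth sidecar", {
  truth <- small_truth()
  pooled <- small_pooled(20, 15, seed = 12, truth = truth)
  dir <- withr::local_tempdir()
  write_synthetic(pooled, dir)
  back <- read_truth(dir)
  expect_equal(back$G, truth$G)
  expect_equal(back$beta$baseline, truth$beta$baseline)
  expect_equal(back$level1$variances, truth$level1$variances)
  expect_equal(back$basis$powers, truth$basis$powers)
})
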