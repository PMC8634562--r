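test_that("profiled likelihood reduces to the normal density in trivial cases", {
  # one child, two visits, saturated fixed part, G = 0, sigma^2 = 1:
  # residuals are exactly zero and the density is that of two standard
  # normals
  meas <- data.frame(child_id = "c1", cohort = "A", age = c(1, 2),
                     weight = c(4.2, 6.6))
  pooled <- pooled_data(meas, data.frame(child_id = "c1", cohort = "A"))
  spec <- model_spec(basis_spec("FP", powers = 1),
                     cohort_as_fixed = FALSE,
                     level1 = level1_spec("segmented", cuts = numeric(0)))
  ll <- profiled_loglik(pooled, spec, G = matrix(0, 2, 2), sigma2 = 1,
                        method = "ML")
  expect_equal(ll, -log(2 * pi), tolerance = 1e-10)
})

test_that("fast Woodbury path matches the dense oracle to 1e-8", {
  for (seed in 1:5) {
    inst <- random_small_instance(seed)
    spec <- model_spec(basis_spec("FP", powers = c(0, 1)),
                       cohort_as_fixed = FALSE,
                       level1 = level1_spec("segmented", cuts = 2))
    for (method in c("ML", "REML")) {
      fast <- profiled_loglik(inst$pooled, spec, inst$G, inst$sigma2,
                              method)
      slow <- oracle_loglik(inst$pooled, spec, inst$G, inst$sigma2, method)
      expect_equal(fast, slow, tolerance = 1e-8)
    }
  }
})

test_that("marginal covariance assembles ZGZ' plus the level-1 diagonal", {
  G0 <- matrix(0, 2, 2)
  V <- marginal_covariance(cbind(1, c(1, 3)), c(1, 3), G0,
                           list(spec = level1_spec("segmented", 2),
                                variances = c(1, 4)))
  expect_equal(V, diag(c(1, 4)))
  V2 <- marginal_covariance(cbind(1, 2), 2, G0,
                            list(spec = level1_spec("age_linear"),
                                 variances = c(1, 1)))
  expect_equal(drop(V2), 5)
  # PSD + simulation oracle on a random child
  set.seed(42)
  Z <- cbind(1, sort(runif(3, 0, 10)))
  A <- matrix(rnorm(4, sd = 0.5), 2, 2)
  G <- crossprod(A) + diag(0.1, 2)
  lev1 <- list(spec = level1_spec("segmented", 2),
               variances = c(0.3, 1.1))
  V3 <- marginal_covariance(Z, Z[, 2], G, lev1)
  expect_true(all(eigen(V3, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  b <- matrix(rnorm(2 * 2e5), ncol = 2) %*% chol(G)
  e <- sapply(seq_len(3), function(j)
    rnorm(2e5, 0, sqrt(level1_variance_at(lev1, Z[j, 2]))))
  ysim <- b %*% t(Z) + e
  expect_equal(stats::cov(ysim), V3, tolerance = 0.05 * max(V3))
})

test_that("REML solution matches the closed-form balanced ANOVA estimators", {
  # balanced random-intercept design: same visit ages for every child
  set.seed(10)
  n <- 80; k <- 6
  ages <- seq(0, 10, length.out = k)
  b <- rnorm(n, 0, sqrt(2))
  df <- data.frame(child_id = rep(sprintf("c%03d", 1:n), each = k),
                   cohort = "A", age = rep(ages, n))
  df$weight <- 5 + 0.8 * df$age + rep(b, each = k) + rnorm(n * k, 0, 1.2)
  pooled <- pooled_data(df, data.frame(child_id = sprintf("c%03d", 1:n),
                                       cohort = "A"))
  spec <- model_spec(basis_spec("FP", powers = 1), cohort_as_fixed = FALSE,
                     random_trajectory = FALSE,
                     level1 = level1_spec("segmented", cuts = numeric(0)))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  expect_true(fit$converged)
  # oracle: within-child MSE and between-child mean variance
  ytil <- df$weight - rep(tapply(df$weight, df$child_id, mean), each = k)
  atil <- df$age - mean(ages)
  slope_w <- sum(ytil * atil) / sum(atil^2)
  rss_w <- sum((ytil - slope_w * atil)^2)
  msw <- rss_w / (n * k - n - 1)
  ybar <- tapply(df$weight, df$child_id, mean)
  sb <- stats::var(ybar) - msw / k
  expect_equal(unname(fit$level1_hat$variances), msw, tolerance = 1e-4)
  expect_equal(unname(fit$G_hat[1, 1]), sb, tolerance = 1e-4)
})

test_that("estimates agree with lme4 on a shared random-slope model", {
  skip_if_not_installed("lme4")
  pooled <- single_pooled(150, seed = 21)
  spec <- model_spec(basis_spec("FP", powers = 1), cohort_as_fixed = FALSE,
                     level1 = level1_spec("segmented", cuts = numeric(0)))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  df <- pooled$measurements
  lmer_fit <- lme4::lmer(weight ~ age + (1 + age | child_id), data = df,
                         REML = TRUE,
                         control = lme4::lmerControl(
                           optCtrl = list(xtol_rel = 1e-10)))
  vc <- lme4::VarCorr(lmer_fit)$child_id
  expect_equal(unname(fit$beta), unname(lme4::fixef(lmer_fit)),
               tolerance = 1e-4)
  expect_equal(unname(diag(fit$G_hat)), unname(diag(vc)),
               tolerance = 1e-3)
  expect_equal(unname(fit$level1_hat$variances),
               sigma(lmer_fit)^2, tolerance = 1e-3)
  expect_equal(unname(sqrt(diag(fit$beta_vcov))),
               unname(coef(summary(lmer_fit))[, "Std. Error"]),
               tolerance = 1e-3)
})

test_that("fit recovers generating parameters within model-based error", {
  truth <- small_truth()
  pooled <- small_pooled(300, 200, seed = 31)
  spec <- model_spec(truth$basis, covariates = "sex",
                     cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  expect_true(fit$converged)
  se <- sqrt(diag(fit$beta_vcov))
  expect_lt(abs(fit$beta[["(Intercept)"]] - 3.5) /
              se[["(Intercept)"]], 4)
  expect_lt(abs(fit$beta[["cohort=B"]] - 0.5) / se[["cohort=B"]], 4)
  expect_lt(abs(fit$beta[["sex=male"]] - 0.3) / se[["sex=male"]], 4)
  expect_equal(unname(fit$level1_hat$variances), c(0.3, 1.2),
               tolerance = 0.25)
})

test_that("optimum is stable across dispersed starting values", {
  pooled <- small_pooled(80, 60, seed = 41)
  spec <- model_spec(basis_spec("FP", powers = c(0, 1)),
                     cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  base <- fit_growth_model(pooled, spec, method = "ML")
  set.seed(5)
  for (r in 1:5) {
    A <- matrix(rnorm(9, sd = 0.3), 3, 3)
    init <- list(G = crossprod(A) + diag(runif(1, 0.05, 1), 3),
                 sigma2 = runif(2, 0.1, 3))
    refit <- fit_growth_model(pooled, spec, method = "ML", init = init)
    expect_equal(refit$loglik, base$loglik, tolerance = 1e-5)
  }
})

test_that("REML counters the downward bias of ML variance estimates", {
  sums <- c(ML = 0, REML = 0)
  for (seed in 1:6) {
    pooled <- single_pooled(40, seed = 50 + seed)
    spec <- model_spec(basis_spec("FP", powers = 1),
                       cohort_as_fixed = FALSE,
                       level1 = level1_spec("segmented", cuts = numeric(0)))
    for (m in c("ML", "REML")) {
      f <- fit_growth_model(pooled, spec, method = m)
      sums[m] <- sums[m] + f$G_hat[1, 1] + f$G_hat[2, 2]
    }
  }
  expect_gte(sums["REML"], sums["ML"])
})

test_that("random 50% measurement deletion leaves fixed effects stable (MAR)", {
  pooled <- small_pooled(250, 150, seed = 61)
  spec <- model_spec(basis_spec("FP", powers = c(0, 1)),
                     cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  full <- fit_growth_model(pooled, spec, method = "REML")
  set.seed(99)
  keep <- runif(nrow(pooled$measurements)) < 0.5
  # ensure every child keeps at least one row
  first <- !duplicated(pooled$measurements$child_id)
  keep <- keep | first
  half <- pooled_data(pooled$measurements[keep, ], pooled$children)
  hfit <- fit_growth_model(half, spec, method = "REML")
  se <- sqrt(diag(hfit$beta_vcov))
  expect_true(all(abs(hfit$beta - full$beta) / se < 3))
})

test_that("predictions, intervals and contrasts follow the delta method", {
  pooled <- small_pooled(200, 150, seed = 71)
  spec <- model_spec(basis_spec("FP", powers = 1), covariates = "sex",
                     cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  pat <- list(cohort = "A", sex = "female")
  # age 0 zeroes the single trajectory column; reference levels zero the
  # rest, so the prediction is the intercept
  pm <- predict_mean(fit, pat, ages = 0)
  expect_equal(pm$fit, unname(fit$beta["(Intercept)"]))
  # scaling the covariance by 4 doubles the half-width
  fat <- fit
  fat$beta_vcov <- 4 * fit$beta_vcov
  pm2 <- predict_mean(fat, pat, ages = c(0, 2, 4))
  pm1 <- predict_mean(fit, pat, ages = c(0, 2, 4))
  expect_equal(pm2$upr - pm2$lwr, 2 * (pm1$upr - pm1$lwr),
               tolerance = 1e-10)
  # truth curve within sampling error at a grid of ages, under the
  # correctly specified trajectory
  truth <- small_truth()
  spec_true <- model_spec(truth$basis, covariates = "sex",
                          cohort_as_fixed = TRUE,
                          level1 = level1_spec("segmented", cuts = 2))
  fit_true <- fit_growth_model(pooled, spec_true, method = "REML")
  Tm <- cbind(1, basis_matrix(c(1, 2, 4, 6, 8), truth$basis))
  true_curve <- drop(Tm %*% (truth$beta$baseline +
                               truth$beta$sex$female))
  pm3 <- predict_mean(fit_true, pat, ages = c(1, 2, 4, 6, 8))
  expect_true(all(abs(pm3$fit - true_curve) / pm3$se < 3.5))

  # contrasts: zero, antisymmetric, recovers the cohort offset
  c0 <- trajectory_contrast(fit_true, pat, pat, age = 2)
  expect_equal(unname(c0[c("difference", "lwr", "upr")]), c(0, 0, 0))
  patB <- list(cohort = "B", sex = "female")
  cab <- trajectory_contrast(fit_true, pat, patB, age = 2)
  cba <- trajectory_contrast(fit_true, patB, pat, age = 2)
  expect_equal(cab[["difference"]], -cba[["difference"]])
  truediff <- -drop(cbind(1, basis_matrix(2, truth$basis)) %*%
                      truth$beta$cohort$B)
  expect_lt(abs(cab[["difference"]] - truediff) / cab[["se"]], 3.5)
})

test_that("the extrapolation guard refuses ages beyond the cohort support", {
  pooled <- small_pooled(60, 50, seed = 81)
  spec <- model_spec(basis_spec("FP", powers = 1),
                     cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  # cohort B spans 0-5 only
  expect_error(predict_mean(fit, list(cohort = "B"), ages = 8),
               "outside the fitted age support")
  expect_silent(predict_mean(fit, list(cohort = "B"), ages = 8,
                             allow_extrapolation = TRUE))
})

test_that("empirical-Bayes predictions shrink and center correctly", {
  pooled <- single_pooled(200, seed = 91)
  spec <- model_spec(basis_spec("FP", powers = 1), cohort_as_fixed = FALSE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  eb <- eb_random_effects(fit, pooled)
  expect_equal(nrow(eb), 200)
  # mean EB deviation is near zero
  expect_true(all(abs(colMeans(eb)) <
                    3 * apply(eb, 2, stats::sd) / sqrt(nrow(eb))))
  # G -> 0 forces complete shrinkage
  tiny <- fit
  tiny$G_hat <- diag(1e-10, 2)
  eb0 <- eb_random_effects(tiny, pooled)
  expect_lt(max(abs(eb0)), 1e-6)
  # dense, low-noise child approaches its OLS deviation
  dense_prof <- cohort_profile("A", c(0, 10), seq(0, 10, by = 0.25),
                               schedule_jitter_sd = 0, dropout_hazard = 0,
                               n_children = 30)
  basis <- basis_spec("FP", powers = 1)
  truth2 <- truth_params(basis, beta = list(baseline = c(4, 2.5)),
                         G = diag(c(0.5, 0.1)),
                         level1 = list(spec = level1_spec("segmented", 2),
                                       variances = c(1e-4, 1e-4)))
  gen <- generate_cohort(dense_prof, truth2, seed = 5)
  dp <- pooled_data(gen$measurements, gen$children)
  spec2 <- model_spec(basis, cohort_as_fixed = FALSE,
                      level1 = level1_spec("segmented", cuts = 2))
  fit2 <- fit_growth_model(dp, spec2, method = "REML")
  eb2 <- eb_random_effects(fit2, dp)
  ii <- dp$measurements$child_id == dp$children$child_id[1]
  Zi <- cbind(1, dp$measurements$age[ii])
  ols_dev <- qr.solve(Zi, dp$measurements$weight[ii] -
                        drop(cbind(1, basis_matrix(
                          dp$measurements$age[ii], basis)) %*% fit2$beta))
  expect_equal(unname(eb2[1, ]), unname(ols_dev), tolerance = 1e-2)
})

test_that("information criteria implement the standard penalties", {
  fake <- structure(list(loglik = 0, n_params = 3, n_obs = exp(2)),
                    class = "growth_fit")
  ic <- information_criteria(fake)
  expect_equal(unname(ic), c(6, 6))
  # nesting: the larger model never has smaller ML loglik
  pooled <- small_pooled(80, 60, seed = 101)
  l1 <- level1_spec("segmented", cuts = 2)
  f_small <- fit_growth_model(pooled,
                              model_spec(basis_spec("FP", powers = 1),
                                         cohort_as_fixed = FALSE,
                                         level1 = l1), method = "ML")
  f_big <- fit_growth_model(pooled,
                            model_spec(basis_spec("FP", powers = c(0, 1)),
                                       cohort_as_fixed = FALSE,
                                       level1 = l1), method = "ML")
  expect_gte(f_big$loglik, f_small$loglik - 1e-4)
  # AIC ordering agrees with a direct recomputation from loglik
  for (f in list(f_small, f_big))
    expect_equal(information_criteria(f)[["AIC"]],
                 -2 * f$loglik + 2 * f$n_params)
})

test_that("MSPE is zero on noiseless truth and larger under misspecification", {
  basis <- basis_spec("FP", powers = c(0, 1))
  truth0 <- truth_params(basis,
                         beta = list(baseline = c(3.5, 4.5, 2.2)),
                         G = matrix(0, 3, 3),
                         level1 = list(spec = level1_spec("segmented", 2),
                                       variances = c(0, 0)))
  prof <- cohort_profile("A", c(0, 10), c(0, 0.5, 1, 2, 4, 7, 10),
                         schedule_jitter_sd = 0.1, dropout_hazard = 0,
                         n_children = 120)
  gen <- generate_cohort(prof, truth0, seed = 6)
  pooled0 <- pooled_data(gen$measurements, gen$children)
  sp <- split_sample(pooled0, 80, seed = 1)
  spec <- model_spec(basis, cohort_as_fixed = FALSE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit0 <- fit_growth_model(sp$selection, spec, method = "ML")
  expect_lt(mspe(fit0, sp$validation), 1e-10)
  expect_error(mspe(fit0, sp$selection), "overlap")

  # curved truth with noise: correctly specified beats a straight line
  pooled <- single_pooled(220, seed = 111)
  sp2 <- split_sample(pooled, 150, seed = 2)
  l1 <- level1_spec("segmented", cuts = 2)
  good <- fit_growth_model(sp2$selection,
                           model_spec(basis, cohort_as_fixed = FALSE,
                                      level1 = l1), method = "ML")
  lin <- fit_growth_model(sp2$selection,
                          model_spec(basis_spec("FP", powers = 1),
                                     cohort_as_fixed = FALSE, level1 = l1),
                          method = "ML")
  expect_lt(mspe(good, sp2$validation), mspe(lin, sp2$validation))
})

test_that("fitted models serialize to plain-text artifacts", {
  pooled <- small_pooled(60, 40, seed = 121)
  spec <- model_spec(basis_spec("FP", powers = 1), cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  fit <- fit_growth_model(pooled, spec, method = "REML")
  dir <- withr::local_tempdir()
  write_growth_fit(fit, dir)
  est <- utils::read.csv(file.path(dir, "estimates.csv"))
  expect_equal(est$estimate, unname(fit$beta))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  expect_equal(meta$loglik, fit$loglik)
  expect_true(file.exists(file.path(dir, "G.csv")))
  expect_true(file.exists(file.path(dir, "level1.csv")))
})
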