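test_that("stratified split matches cohort shares and partitions children", {
  pooled <- small_pooled(100, 300, seed = 3)
  sp <- split_sample(pooled, 200, seed = 9)
  expect_equal(sum(sp$selection$children$cohort == "A"), 50)
  expect_equal(sum(sp$selection$children$cohort == "B"), 150)
  all_ids <- sort(c(sp$selection$children$child_id,
                    sp$validation$children$child_id))
  expect_equal(all_ids, sort(pooled$children$child_id))
  expect_length(intersect(sp$selection$children$child_id,
                          sp$validation$children$child_id), 0)
  sp2 <- split_sample(pooled, 200, seed = 9)
  expect_identical(sp$selection$children$child_id,
                   sp2$selection$children$child_id)
  expect_error(split_sample(pooled, 400, seed = 1), "smaller")
})

test_that("stage-1 ranking is invariant to measurement row order", {
  pooled <- small_pooled(60, 40, seed = 13)
  shuf <- pooled_data(
    pooled$measurements[sample(nrow(pooled$measurements)), ],
    pooled$children)
  cfg <- selection_config(n_select = 70, seed = 5, rcs_n_knots = 3)
  r1 <- stage1_select(pooled, cfg)
  r2 <- stage1_select(shuf, cfg)
  expect_equal(r1$candidates$loglik, r2$candidates$loglik,
               tolerance = 1e-6)
  expect_equal(r1$winner_label, r2$winner_label)
})

test_that("stage 1 shortlists per family and adjudicates by validation MSPE", {
  pooled <- small_pooled(220, 160, seed = 17)
  cfg <- selection_config(n_select = 280, seed = 11)
  rep1 <- stage1_select(pooled, cfg)
  expect_lte(nrow(rep1$candidates), 40)
  expect_gte(nrow(rep1$candidates), 36)
  expect_lte(nrow(rep1$shortlist), 4)
  expect_setequal(unique(rep1$shortlist$family), c("FP", "RCS"))
  # winner attains the minimal shortlist MSPE (ties by parameters)
  expect_equal(min(rep1$shortlist$validation_mspe),
               rep1$shortlist$validation_mspe[
                 rep1$shortlist$candidate == rep1$winner_label])
  # truth is FP(0,1): the winning family should be FP on this instance
  expect_equal(rep1$winner_family, "FP")
})

test_that("summed likelihood adds per-cohort fits and rejects unfittable splines", {
  pooled <- small_pooled(80, 60, seed = 23)
  basis <- basis_spec("FP", powers = c(0, 1))
  # single cohort: identical to a direct fit
  single <- subset_pooled(pooled,
                          pooled$children$child_id[
                            pooled$children$cohort == "A"])
  sl <- summed_likelihood(basis, single)
  direct <- fit_growth_model(
    single, model_spec(basis, cohort_as_fixed = FALSE,
                       level1 = level1_spec("segmented", cuts = 2)),
    method = "ML")
  expect_equal(sl$loglik, direct$loglik, tolerance = 1e-6)
  # two identical copies double the log-likelihood
  copy <- single
  copy$measurements$cohort <- "A2"
  copy$measurements$child_id <- paste0("A2_", copy$measurements$child_id)
  copy$children$cohort <- "A2"
  copy$children$child_id <- paste0("A2_", copy$children$child_id)
  both <- pooled_data(rbind(single$measurements, copy$measurements),
                      rbind(single$children, copy$children))
  sl2 <- summed_likelihood(basis, both)
  expect_equal(sl2$loglik, 2 * sl$loglik, tolerance = 1e-4)
  expect_equal(sl2$n_params, 2 * sl$n_params)
  # spline with a knot outside cohort B's 0-5 window cannot be fitted
  # per cohort
  expect_error(
    summed_likelihood(basis_spec("RCS", knots = c(1, 5, 10)), pooled),
    "not fittable per cohort")
})

test_that("stage 2 ranks level-1 structures by REML criterion", {
  # truth with age-linear measurement variance
  basis <- basis_spec("FP", powers = 1)
  truth <- truth_params(
    basis, beta = list(baseline = c(4, 2.5)),
    G = matrix(c(0.4, 0.02, 0.02, 0.05), 2, 2),
    level1 = list(spec = level1_spec("age_linear"),
                  variances = c(0.2, 0.05)))
  prof <- cohort_profile("A", c(0, 10), c(0, 0.5, 1, 2, 4, 6, 8, 10),
                         schedule_jitter_sd = 0.1, dropout_hazard = 0,
                         n_children = 400)
  gen <- generate_cohort(prof, truth, seed = 29)
  pooled <- pool_cohorts(list(A = gen))$pooled
  s2 <- stage2_select(pooled, basis)
  expect_equal(s2$winner$kind, "age_linear")
  # homoscedastic truth: the single-band model is competitive
  truth0 <- truth_params(
    basis, beta = list(baseline = c(4, 2.5)),
    G = matrix(c(0.4, 0.02, 0.02, 0.05), 2, 2),
    level1 = list(spec = level1_spec("segmented", cuts = numeric(0)),
                  variances = 0.5))
  gen0 <- generate_cohort(prof, truth0, seed = 31)
  pooled0 <- pool_cohorts(list(A = gen0))$pooled
  cands <- list(level1_spec("segmented", cuts = numeric(0)),
                level1_spec("segmented", cuts = 2))
  s20 <- stage2_select(pooled0, basis, candidates = cands)
  crit <- s20$table$BIC
  expect_lte(crit[1] - min(crit, na.rm = TRUE), 2)
  # identical candidates: deterministic tie-break to the first
  tie <- stage2_select(pooled0, basis,
                       candidates = list(level1_spec("segmented", 2),
                                         level1_spec("segmented", 2)))
  expect_identical(tie$winner, level1_spec("segmented", 2))
})

test_that("interaction pruning drops unsupported and aliased terms only", {
  pooled <- small_pooled(150, 120, seed = 37)
  # spline column with knot at 5: cohort B (ages 0-5) has no support
  # beyond it
  spec <- model_spec(basis_spec("RCS", knots = c(0.5, 2, 5, 7, 9)),
                     covariates = "sex", cohort_as_fixed = TRUE,
                     level1 = level1_spec("segmented", cuts = 2))
  pr <- prune_unsupported_interactions(spec, pooled, min_children = 5,
                                       min_measurements = 10)
  dr <- pr$spec$dropped_interactions
  expect_true(any(dr$covariate == "cohort" & dr$level == "B" &
                    dr$column == "rcs.3"))
  # thresholds 0 keep every supported term (only structural zero-support
  # and aliased columns may go)
  pr0 <- prune_unsupported_interactions(spec, pooled, min_children = 0,
                                        min_measurements = 0)
  expect_true(all(pr0$log$dropped[pr0$log$n_measurements > 0] == FALSE,
                  na.rm = TRUE))
  # a covariate whose main effect is perfectly confounded with cohort is
  # surfaced as a hard error (interaction pruning cannot repair it)
  kids <- pooled$children
  kids$region <- ifelse(kids$cohort == "A", "north", "south")
  p2 <- pooled_data(pooled$measurements, kids)
  spec2 <- model_spec(basis_spec("FP", powers = 1),
                      covariates = "region", cohort_as_fixed = TRUE,
                      level1 = level1_spec("segmented", cuts = 2))
  expect_error(prune_unsupported_interactions(spec2, p2,
                                              min_children = 0,
                                              min_measurements = 0),
               "rank-deficient")
  # a single-level covariate contributes no columns at all and the model
  # still fits
  kids$source <- "clinic"
  p3 <- pooled_data(pooled$measurements, kids)
  spec3 <- model_spec(basis_spec("FP", powers = 1),
                      covariates = "source", cohort_as_fixed = TRUE,
                      level1 = level1_spec("segmented", cuts = 2))
  pr3 <- prune_unsupported_interactions(spec3, p3, min_children = 0,
                                        min_measurements = 0)
  fit <- fit_growth_model(p3, pr3$spec, method = "ML")
  expect_true(inherits(fit, "growth_fit"))
})

test_that("two-stage selection assembles a final specification", {
  pooled <- small_pooled(160, 120, seed = 41)
  cfg <- selection_config(n_select = 200, seed = 7, rcs_n_knots = 3:4)
  rep1 <- select_trajectory(pooled, cfg)
  expect_s3_class(rep1$final_spec, "model_spec")
  expect_s3_class(rep1$final_spec$level1, "level1_spec")
  expect_equal(nrow(rep1$stage2), 2)
  expect_output(print(rep1), "winner")
})
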