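# Synthetic multi-cohort longitudinal weight data with known truth, used to
# validate every downstream stage (harmonization, fitting, selection, MI)
# without access to restricted cohort data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Cohort generation profile
#'
#' Describes one synthetic cohort: its age window, target visit schedule,
#' visit-timing jitter, per-visit dropout hazard, size, and covariate
#' distributions, plus any covariates that the cohort "never measured"
#' (systematically missing for all of its children).
#'
#' @param cohort Cohort label.
#' @param age_window Length-2 numeric, `(min_age, max_age)` in years.
#' @param visit_schedule Target visit ages (years), inside the age window.
#' @param schedule_jitter_sd SD (years) of Gaussian jitter around each
#'   target age; jittered ages are clamped to the age window.
#' @param dropout_hazard Probability in `[0, 1)` that each visit after the
#'   first "fails"; the first failed visit and all later visits are lost
#'   (monotone dropout).
#' @param n_children Positive integer.
#' @param sex_ratio Probability that a child is male.
#' @param single_sex If `TRUE`, all children get the majority sex implied by
#'   `sex_ratio` (use `sex_ratio = 1` for an all-male cohort).
#' @param ethnicity_distribution Probabilities over the harmonized
#'   ethnicity categories (White European, South Asian, other); must sum
#'   to 1.
#' @param maternal_education_distribution,paternal_occupation_distribution
#'   Probabilities over the corresponding harmonized vocabularies.
#' @param systematically_missing Character vector of covariate names that
#'   are recorded as missing for every child in this cohort.
#' @return An object of class `cohort_profile`.
#' @export
cohort_profile <- function(cohort, age_window, visit_schedule,
                           schedule_jitter_sd = 0.1, dropout_hazard = 0,
                           n_children,
                           sex_ratio = 0.5, single_sex = FALSE,
                           ethnicity_distribution = c(1, 0, 0),
                           maternal_education_distribution = c(1, 1, 1) / 3,
                           paternal_occupation_distribution = c(1, 1, 1) / 3,
                           systematically_missing = character()) {
  stopifnot(length(age_window) == 2, diff(age_window) > 0,
            n_children >= 1, length(visit_schedule) >= 1)
  if (any(visit_schedule < age_window[1] - 1e-9) ||
      any(visit_schedule > age_window[2] + 1e-9))
    stop("visit_schedule ages must lie inside age_window", call. = FALSE)
  chk_prob <- function(p, k, nm) {
    if (length(p) != k || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop(nm, " must be ", k, " probabilities summing to 1", call. = FALSE)
  }
  chk_prob(ethnicity_distribution, 3, "ethnicity_distribution")
  chk_prob(maternal_education_distribution, 3,
           "maternal_education_distribution")
  chk_prob(paternal_occupation_distribution, 3,
           "paternal_occupation_distribution")
  if (dropout_hazard < 0 || dropout_hazard >= 1 ||
      sex_ratio < 0 || sex_ratio > 1)
    stop("dropout_hazard must be in [0,1) and sex_ratio in [0,1]",
         call. = FALSE)
  known <- c("sex", "ethnicity", "maternal_education", "paternal_occupation")
  if (length(setdiff(systematically_missing, known)))
    stop("unknown covariate in systematically_missing", call. = FALSE)
  structure(list(cohort = cohort, age_window = age_window,
                 visit_schedule = sort(visit_schedule),
                 schedule_jitter_sd = schedule_jitter_sd,
                 dropout_hazard = dropout_hazard, n_children = n_children,
                 sex_ratio = sex_ratio, single_sex = single_sex,
                 ethnicity_distribution = ethnicity_distribution,
                 maternal_education_distribution =
                   maternal_education_distribution,
                 paternal_occupation_distribution =
                   paternal_occupation_distribution,
                 systematically_missing = systematically_missing),
            class = "cohort_profile")
}

#' Default five-cohort study design
#'
#' Five cohort profiles emulating the structure of a real pooled life-course
#' weight study: a birth cohort followed to age 20 with moderate dropout, a
#' small intensively measured trial cohort to age 5, a birth cohort to age
#' 6 with sparse measurement and an ethnically diverse population, an
#' all-male school cohort covering ages 9--18 with very dense measurement,
#' and a large trial cohort to age 16. Maternal education is systematically
#' missing in the two historical cohorts (the trial cohort to age 5 and the
#' school cohort), which also never recorded ethnicity (all children are
#' White European).
#'
#' @param n_children Integer vector of length 5, one size per cohort, in
#'   the order ALSPAC-like, BCG-like, BiB-like, CHS-like, PROBIT-like.
#'   Defaults to the realistic sizes (14216, 951, 13445, 1547, 17046);
#'   validation studies typically scale these down proportionally.
#' @return Named list of five [cohort_profile()] objects.
#' @export
default_cohort_profiles <- function(n_children = c(14216, 951, 13445, 1547,
                                                   17046)) {
  stopifnot(length(n_children) == 5, all(n_children >= 1))
  list(
    ALSPAC = cohort_profile(
      "ALSPAC", c(0, 20),
      visit_schedule = c(0, 0.115, 0.83, 1.75, 4, 7, 8, 9, 10, 11, 12, 13,
                         15, 17),
      schedule_jitter_sd = 0.1, dropout_hazard = 0.07,
      n_children = n_children[1],
      ethnicity_distribution = c(0.95, 0, 0.05),
      maternal_education_distribution = c(0.65, 0.22, 0.13),
      paternal_occupation_distribution = c(0.28, 0.46, 0.26)),
    BCG = cohort_profile(
      "BCG", c(0, 5),
      visit_schedule = c(0, 0.027, 0.115, 0.25, 0.5, 0.75, 1, 1.5, 2, 2.5,
                         3, 3.5, 4, 5),
      schedule_jitter_sd = 0.02, dropout_hazard = 0.005,
      n_children = n_children[2],
      ethnicity_distribution = c(1, 0, 0),
      paternal_occupation_distribution = c(0.17, 0.59, 0.24),
      systematically_missing = "maternal_education"),
    BiB = cohort_profile(
      "BiB", c(0, 6),
      visit_schedule = c(0, 0.04, 0.115, 0.67, 4, 6),
      schedule_jitter_sd = 0.15, dropout_hazard = 0.08,
      n_children = n_children[3],
      ethnicity_distribution = c(0.42, 0.5, 0.08),
      maternal_education_distribution = c(0.57, 0.16, 0.27),
      paternal_occupation_distribution = c(0.17, 0.25, 0.58)),
    CHS = cohort_profile(
      "CHS", c(9, 18),
      visit_schedule = seq(9, 18, by = 1 / 6),
      schedule_jitter_sd = 0.03, dropout_hazard = 0,
      n_children = n_children[4],
      sex_ratio = 1, single_sex = TRUE,
      ethnicity_distribution = c(1, 0, 0),
      paternal_occupation_distribution = c(0.70, 0.26, 0.04),
      systematically_missing = "maternal_education"),
    PROBIT = cohort_profile(
      "PROBIT", c(0, 16),
      visit_schedule = c(0, 1 / 12, 2 / 12, 0.25, 0.5, 0.75, 1, 2, 4, 6.5,
                         9, 11.5, 16),
      schedule_jitter_sd = 0.08, dropout_hazard = 0.01,
      n_children = n_children[5],
      ethnicity_distribution = c(1, 0, 0),
      maternal_education_distribution = c(0.04, 0.82, 0.14),
      paternal_occupation_distribution = c(0.11, 0.63, 0.26))
  )
}

#' Generative truth parameters
#'
#' The data-generating analogue of the analysis model: a trajectory basis,
#' fixed-effect coefficient vectors on the trajectory columns for the
#' baseline curve and each covariate contrast, an individual-level
#' random-effect covariance matrix, and level-1 (measurement) variances.
#'
#' Coefficient vectors all have length `q = 1 + ncol(basis columns)`
#' (intercept first), so every covariate effect is a full
#' covariate-by-trajectory interaction; a main effect alone is a vector
#' that is zero beyond the intercept.
#'
#' @param basis A [basis_spec()] -- the generating trajectory family.
#' @param beta List with component `baseline` (length-`q` numeric) and
#'   optional named lists `cohort`, `sex`, `ethnicity`,
#'   `maternal_education`, `paternal_occupation`, each mapping a non-reference
#'   level to a length-`q` contrast vector (in kg per basis unit).
#' @param G Symmetric positive-definite `q x q` covariance matrix of the
#'   individual-level random effects.
#' @param level1 List with `spec` (a [level1_spec()]) and `variances`
#'   (positive numeric: one per age segment, or `(sigma0^2, sigma1^2)` for
#'   the age-linear form).
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(basis, beta, G, level1) {
  stopifnot(inherits(basis, "basis_spec"))
  q <- nrow(G)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("G must be positive semi-definite", call. = FALSE)
  if (length(beta$baseline) != q)
    stop("beta$baseline must have length nrow(G)", call. = FALSE)
  for (grp in c("cohort", "sex", "ethnicity", "maternal_education",
                "paternal_occupation")) {
    for (v in beta[[grp]])
      if (length(v) != q)
        stop("all effect vectors must have length nrow(G)", call. = FALSE)
  }
  stopifnot(inherits(level1$spec, "level1_spec"))
  if (any(level1$variances < 0))
    stop("level-1 variances must be non-negative", call. = FALSE)
  if (level1$spec$kind == "segmented" &&
      length(level1$variances) != length(level1$spec$cuts) + 1L)
    stop("segmented level-1 truth needs one variance per age band",
         call. = FALSE)
  if (level1$spec$kind == "age_linear" && length(level1$variances) != 2L)
    stop("age-linear level-1 truth needs variances (sigma0^2, sigma1^2)",
         call. = FALSE)
  structure(list(basis = basis, beta = beta, G = G, level1 = level1),
            class = "truth_params")
}

#' Default generative truth
#'
#' A realistic child-weight truth on ages 0--20: a restricted cubic spline
#' with 5 knots whose baseline curve passes close to (0, 3.5), (1, 10),
#' (5, 18), (10, 32), (15, 55) and (20, 62) kg -- an infant growth spurt, a
#' mid-childhood slowdown and a pubertal spurt, a shape outside the
#' fractional-polynomial family so that family selection has a recoverable
#' target. Cohort contrasts give the school cohort a markedly lower
#' trajectory; level-1 variance is segmented at age 2 (larger after
#' infancy).
#'
#' @return A [truth_params()].
#' @export
default_truth <- function() {
  basis <- basis_spec("RCS", knots = c(0.25, 1, 5, 10, 15))
  anchor_age <- c(0, 1, 5, 10, 15, 20)
  anchor_wt <- c(3.5, 10, 18, 32, 55, 62)
  Tm <- cbind(1, basis_matrix(anchor_age, basis))
  baseline <- qr.solve(Tm, anchor_wt)
  q <- length(baseline)
  vec <- function(intercept = 0, slope = 0) {
    v <- numeric(q); v[1] <- intercept; v[2] <- slope; v
  }
  beta <- list(
    baseline = baseline,
    cohort = list(BCG = vec(0.2, 0.02), BiB = vec(-0.2, -0.02),
                  CHS = vec(0, -0.45), PROBIT = vec(0, -0.062)),
    sex = list(female = vec(-0.25, -0.10)),
    ethnicity = list("South Asian" = vec(-0.45, -0.06),
                     other = vec(-0.1, 0)),
    maternal_education = list("left school 17-18" = vec(0.1, 0.015),
                              "degree or higher" = vec(0.2, 0.03)),
    paternal_occupation = list(intermediate = vec(-0.1, -0.01),
                               "routine/unskilled" = vec(-0.2, -0.02)))
  sds <- c(0.6, 0.12, rep(0.25, q - 2))
  R <- diag(q); R[1, 2] <- R[2, 1] <- -0.2
  G <- diag(sds) %*% R %*% diag(sds)
  truth_params(basis, beta, G,
               level1 = list(spec = level1_spec("segmented", cuts = 2),
                             variances = c(0.25, 2.25)))
}

truth_beta_child <- function(truth, cohort, sex, ethnicity,
                             maternal_education, paternal_occupation) {
  b <- truth$beta$baseline
  add <- function(b, grp, lev) {
    v <- truth$beta[[grp]][[lev]]
    if (!is.null(v)) b + v else b
  }
  b <- add(b, "cohort", cohort)
  b <- add(b, "sex", sex)
  if (!is.na(ethnicity)) b <- add(b, "ethnicity", ethnicity)
  if (!is.na(maternal_education))
    b <- add(b, "maternal_education", maternal_education)
  if (!is.na(paternal_occupation))
    b <- add(b, "paternal_occupation", paternal_occupation)
  b
}

#' Level-1 variance evaluated at given ages
#'
#' @param level1 List with `spec` (a [level1_spec()]) and `variances`.
#' @param ages Numeric vector of ages.
#' @return Numeric vector of measurement-level variances.
#' @export
level1_variance_at <- function(level1, ages) {
  sp <- level1$spec
  v <- level1$variances
  if (sp$kind == "segmented") {
    idx <- findInterval(ages, sp$cuts, left.open = TRUE) + 1L
    v[idx]
  } else {
    v[1] + v[2] * ages^2
  }
}

#' Generate one synthetic cohort
#'
#' Draws covariates from the profile's distributions, individual random
#' effects from the truth covariance, visit ages from the schedule with
#' jitter and monotone dropout, and weights as fixed part + random part +
#' level-1 noise whose variance follows the truth's level-1 structure at
#' the visit age. Covariates listed as systematically missing are recorded
#' as `NA` for every child (the data were still generated from the latent
#' values, exactly as in a cohort that simply never measured the variable).
#'
#' @param profile A [cohort_profile()].
#' @param truth A [truth_params()].
#' @param seed Integer seed; output is deterministic given
#'   `(profile, truth, seed)`.
#' @return List with data frames `measurements` (`child_id`, `cohort`,
#'   `age`, `weight`) and `children` (`child_id`, `cohort`, covariates).
#' @export
generate_cohort <- function(profile, truth, seed) {
  stopifnot(inherits(profile, "cohort_profile"),
            inherits(truth, "truth_params"))
  vocab <- harmonized_vocabulary()
  q <- nrow(truth$G)
  eg <- eigen(truth$G, symmetric = TRUE)
  Gfac <- t(eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), q))
  with_seed(seed, {
    n <- profile$n_children
    sex <- if (profile$single_sex) {
      rep(if (profile$sex_ratio >= 0.5) "male" else "female", n)
    } else {
      ifelse(stats::runif(n) < profile$sex_ratio, "male", "female")
    }
    draw_cat <- function(levels, probs)
      levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
    ethnicity <- draw_cat(vocab$ethnicity, profile$ethnicity_distribution)
    mat_edu <- draw_cat(vocab$maternal_education,
                        profile$maternal_education_distribution)
    pat_occ <- draw_cat(vocab$paternal_occupation,
                        profile$paternal_occupation_distribution)
    b_mat <- matrix(stats::rnorm(n * q), n, q) %*% Gfac
    k <- length(profile$visit_schedule)
    meas <- vector("list", n)
    ids <- sprintf("%05d", seq_len(n))
    for (i in seq_len(n)) {
      kept <- k
      if (profile$dropout_hazard > 0 && k > 1) {
        fail <- which(stats::runif(k - 1) < profile$dropout_hazard)
        if (length(fail)) kept <- min(fail)
      }
      ages <- profile$visit_schedule[seq_len(kept)]
      if (profile$schedule_jitter_sd > 0)
        ages <- ages + stats::rnorm(kept, 0, profile$schedule_jitter_sd)
      ages <- pmin(pmax(ages, profile$age_window[1]), profile$age_window[2])
      ages <- sort(ages)
      Tm <- cbind(1, basis_matrix(ages, truth$basis))
      beta_i <- truth_beta_child(truth, profile$cohort, sex[i], ethnicity[i],
                                 mat_edu[i], pat_occ[i])
      s2 <- level1_variance_at(truth$level1, ages)
      w <- drop(Tm %*% (beta_i + b_mat[i, ])) +
        stats::rnorm(kept, 0, sqrt(s2))
      meas[[i]] <- data.frame(child_id = ids[i], cohort = profile$cohort,
                              age = ages, weight = w)
    }
    children <- data.frame(child_id = ids, cohort = profile$cohort,
                           sex = sex, ethnicity = ethnicity,
                           maternal_education = mat_edu,
                           paternal_occupation = pat_occ,
                           stringsAsFactors = FALSE)
    for (v in profile$systematically_missing)
      children[[v]] <- NA_character_
    list(measurements = do.call(rbind, meas), children = children)
  })
}

#' Generate a pooled multi-cohort dataset
#'
#' Generates each cohort with a per-cohort seed derived deterministically
#' from the master seed, then pools them with globally unique child ids.
#' The truth object is attached as attribute `"truth"`.
#'
#' @param profiles List of at least two [cohort_profile()]s with distinct
#'   labels.
#' @param truth A [truth_params()].
#' @param seed Integer master seed.
#' @return A [pooled_data()] with attribute `"truth"`.
#' @export
generate_multi_cohort <- function(profiles, truth, seed) {
  if (length(profiles) < 2)
    stop("need at least two cohort profiles", call. = FALSE)
  labels <- vapply(profiles, function(p) p$cohort, character(1))
  if (anyDuplicated(labels))
    stop("duplicate cohort labels", call. = FALSE)
  tables <- list()
  for (i in seq_along(profiles)) {
    tab <- generate_cohort(profiles[[i]], truth,
                           seed = (seed + 7919L * i) %% .Machine$integer.max)
    tables[[labels[i]]] <- tab
  }
  pooled <- pool_cohorts(tables)$pooled
  attr(pooled, "truth") <- truth
  pooled
}

#' Covariate missingness mechanism
#'
#' Per-covariate logistic missingness model: a child's probability of having
#' the covariate missing is
#' `plogis(intercept + slope * proxy + cohort_offset[cohort])`, where
#' `proxy` is a per-child summary of the observed outcome trajectory. A
#' nonzero `slope` makes the mechanism missing-at-random given the observed
#' outcomes, mirroring studies where the chance of complete covariate data
#' depends on the outcome data.
#'
#' @param covariate Covariate name in the child table.
#' @param intercept,slope Logistic coefficients.
#' @param cohort_offsets Optional named numeric vector of per-cohort
#'   logit offsets (unnamed cohorts get 0).
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(covariate, intercept, slope = 0,
                             cohort_offsets = numeric()) {
  structure(list(covariate = covariate, intercept = intercept,
                 slope = slope, cohort_offsets = cohort_offsets),
            class = "missingness_spec")
}

#' Impose sporadic covariate missingness
#'
#' Applies one or more [missingness_spec()] mechanisms to a child table.
#' Covariates that are already fully missing (systematically missing) are
#' untouched by construction; the mechanisms only add sporadic missingness.
#'
#' @param children Child data frame.
#' @param mechanisms A [missingness_spec()] or list of them.
#' @param trajectory_proxy Numeric vector named by `child_id` (e.g. each
#'   child's mean observed weight); must cover every child.
#' @param seed Integer seed.
#' @return The child table with additional `NA`s.
#' @export
apply_covariate_missingness <- function(children, mechanisms,
                                        trajectory_proxy, seed) {
  if (inherits(mechanisms, "missingness_spec")) mechanisms <- list(mechanisms)
  proxy <- trajectory_proxy[as.character(children$child_id)]
  if (any(is.na(proxy)))
    stop("trajectory_proxy must cover every child", call. = FALSE)
  with_seed(seed, {
    for (m in mechanisms) {
      if (!m$covariate %in% names(children))
        stop("unknown covariate: ", m$covariate, call. = FALSE)
      off <- rep(0, nrow(children))
      if (length(m$cohort_offsets)) {
        hit <- children$cohort %in% names(m$cohort_offsets)
        off[hit] <- m$cohort_offsets[children$cohort[hit]]
      }
      p <- stats::plogis(m$intercept + m$slope * proxy + off)
      miss <- stats::runif(nrow(children)) < p
      children[[m$covariate]][miss] <- NA
    }
    children
  })
}

#' Per-child mean observed weight
#'
#' Convenience trajectory proxy for outcome-dependent missingness
#' mechanisms.
#'
#' @param pooled A [pooled_data()].
#' @return Numeric vector named by `child_id`.
#' @export
child_mean_weight <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_data"))
  tapply(pooled$measurements$weight, pooled$measurements$child_id, mean)
}

#' Write a synthetic dataset with its truth sidecar
#'
#' Writes the pooled tables via [write_pooled_data()] plus `truth.json`
#' recording the generating parameters, so recovery studies can reload both.
#'
#' @param pooled A [pooled_data()] carrying a `"truth"` attribute (or pass
#'   `truth` explicitly).
#' @param dir Output directory.
#' @param truth Optional [truth_params()] override.
#' @return Invisibly, the output directory.
#' @export
write_synthetic <- function(pooled, dir, truth = attr(pooled, "truth")) {
  write_pooled_data(pooled, dir)
  if (!is.null(truth)) {
    ser <- list(
      basis = unclass(truth$basis),
      beta = truth$beta,
      G = truth$G,
      level1 = list(kind = truth$level1$spec$kind,
                    cuts = truth$level1$spec$cuts,
                    variances = truth$level1$variances))
    jsonlite::write_json(ser, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}

#' Read the truth sidecar written by [write_synthetic()]
#'
#' @param dir Directory containing `truth.json`.
#' @return A [truth_params()].
#' @export
read_truth <- function(dir) {
  ser <- jsonlite::read_json(file.path(dir, "truth.json"),
                             simplifyVector = TRUE)
  basis <- basis_spec(ser$basis$family,
                      powers = ser$basis$powers,
                      knots = ser$basis$knots,
                      age_shift = ser$basis$age_shift)
  beta <- ser$beta
  beta$baseline <- as.numeric(beta$baseline)
  for (grp in setdiff(names(beta), "baseline"))
    beta[[grp]] <- lapply(beta[[grp]], as.numeric)
  truth_params(basis, beta, as.matrix(ser$G),
               level1 = list(spec = level1_spec(ser$level1$kind,
                                                cuts = ser$level1$cuts),
                             variances = as.numeric(ser$level1$variances)))
}

#' Synthetic per-cohort tables with the published count structure
#'
#' Builds five per-cohort child and measurement tables whose sizes and
#' covariate-missingness pattern mirror the published five-cohort pooled
#' weight analysis: 14,216 / 951 / 13,445 / 1,547 / 17,046 children with
#' 157,000 / 12,737 / 78,110 / 89,070 / 205,864 weight measurements;
#' maternal education systematically missing in the BCG- and CHS-like
#' cohorts (2,498 children) and sporadically missing for 5,734 children of
#' the two covariate-recording birth cohorts. Ages follow each cohort's
#' window and the weight column is a constant placeholder: the tables are
#' synthetic stand-ins for auditing and discard accounting, not simulated
#' growth data (use [generate_multi_cohort()] for that).
#'
#' @return Named list of five elements, each with `measurements` and
#'   `children` data frames, suitable for [pool_cohorts()].
#' @export
synthetic_count_structure <- function() {
  cohorts <- c("ALSPAC", "BCG", "BiB", "CHS", "PROBIT")
  n_children <- c(14216L, 951L, 13445L, 1547L, 17046L)
  n_meas <- c(157000L, 12737L, 78110L, 89070L, 205864L)
  age_lo <- c(0, 0, 0, 9, 0)
  age_hi <- c(20, 5, 6, 18, 16)
  sporadic <- c(ALSPAC = 4000L, BCG = 0L, BiB = 1734L, CHS = 0L,
                PROBIT = 0L)
  tables <- list()
  for (i in seq_along(cohorts)) {
    n <- n_children[i]
    ids <- sprintf("%05d", seq_len(n))
    edu <- rep("left school 15-16", n)
    if (cohorts[i] %in% c("BCG", "CHS")) {
      edu <- rep(NA_character_, n)          # systematically missing
    } else if (sporadic[[cohorts[i]]] > 0) {
      edu[seq_len(sporadic[[cohorts[i]]])] <- NA_character_
    }
    children <- data.frame(
      child_id = ids,
      sex = if (cohorts[i] == "CHS") "male" else
        rep(c("male", "female"), length.out = n),
      ethnicity = "White European",
      maternal_education = edu,
      paternal_occupation = "intermediate",
      stringsAsFactors = FALSE)
    per <- n_meas[i] %/% n
    extra <- n_meas[i] - per * n
    counts <- rep(per, n)
    if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
    meas <- data.frame(
      child_id = rep(ids, counts),
      age = rep(seq(age_lo[i], age_hi[i], length.out = 25),
                length.out = n_meas[i]),
      weight = 10)
    tables[[cohorts[i]]] <- list(measurements = meas, children = children)
  }
  tables
}
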