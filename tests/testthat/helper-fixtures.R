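# Shared fixtures, all built in code at test time.

# Small two-cohort truth on an FP(0,1) trajectory (q = 3 random effects),
# with covariate effects used by recovery and MI tests.
small_truth <- function(edu_effect = c(0.6, 0.4, 0)) {
  basis <- basis_spec("FP", powers = c(0, 1))
  truth_params(
    basis,
    beta = list(
      baseline = c(3.5, 4.5, 2.2),
      cohort = list(B = c(0.5, 0.2, 0)),
      sex = list(female = c(-0.3, -0.1, 0)),
      maternal_education = list("left school 17-18" = c(0.3, 0.2, 0),
                                "degree or higher" = edu_effect)),
    G = matrix(c(0.4, 0.05, 0.02,
                 0.05, 0.2, 0.01,
                 0.02, 0.01, 0.05), 3, 3),
    level1 = list(spec = level1_spec("segmented", cuts = 2),
                  variances = c(0.3, 1.2)))
}

small_profiles <- function(nA = 200, nB = 150) {
  list(
    cohort_profile("A", c(0, 10), c(0, 0.5, 1, 2, 4, 6, 8, 10),
                   schedule_jitter_sd = 0.1, dropout_hazard = 0.05,
                   n_children = nA,
                   maternal_education_distribution = c(0.5, 0.3, 0.2)),
    cohort_profile("B", c(0, 5), c(0, 0.5, 1, 2, 3, 5),
                   schedule_jitter_sd = 0.1, dropout_hazard = 0.02,
                   n_children = nB,
                   maternal_education_distribution = c(0.4, 0.4, 0.2)))
}

small_pooled <- function(nA = 200, nB = 150, seed = 7,
                         truth = small_truth()) {
  generate_multi_cohort(small_profiles(nA, nB), truth, seed = seed)
}

# single-cohort variant (generate_multi_cohort requires >= 2 cohorts)
single_pooled <- function(n = 200, seed = 7, truth = small_truth()) {
  prof <- small_profiles(n, 1)[[1]]
  out <- generate_cohort(prof, truth, seed = seed)
  pool_cohorts(list(A = out))$pooled
}

# Five-cohort tables reproducing the published pooled study's counts.
table1_fixture <- function() synthetic_count_structure()

# Independent dense log-likelihood oracle: per-child multivariate-normal
# density with explicit V_i construction and inversion, beta profiled by
# GLS, REML adjustment per the standard restricted likelihood.
oracle_loglik <- function(pooled, spec, G, sigma2, method) {
  df <- merge(pooled$measurements,
              pooled$children[, c("child_id", spec$covariates),
                              drop = FALSE],
              by = "child_id", sort = FALSE)
  df <- df[order(df$child_id, df$age), ]
  B <- basis_matrix(df$age, spec$trajectory)
  X <- cbind(1, B)
  Z <- if (spec$random_trajectory) X else X[, 1, drop = FALSE]
  if (spec$cohort_as_fixed) {
    for (lab in sort(unique(df$cohort))[-1]) {
      ind <- as.numeric(df$cohort == lab)
      X <- cbind(X, ind, ind * B)
    }
  }
  y <- df$weight
  rvar <- if (spec$level1$kind == "segmented") {
    band <- findInterval(df$age, spec$level1$cuts, left.open = TRUE) + 1L
    sigma2[band]
  } else sigma2[1] + sigma2[2] * df$age^2
  idx <- split(seq_along(y), factor(df$child_id,
                                    levels = unique(df$child_id)))
  p <- ncol(X)
  H <- matrix(0, p, p); g <- rep(0, p); ldV <- 0
  Vinvs <- list()
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    Zi <- Z[ii, , drop = FALSE]
    Vi <- Zi %*% G %*% t(Zi) + diag(rvar[ii], length(ii))
    ldV <- ldV + determinant(Vi, logarithm = TRUE)$modulus
    Vinvs[[k]] <- solve(Vi)
    H <- H + t(X[ii, , drop = FALSE]) %*% Vinvs[[k]] %*%
      X[ii, , drop = FALSE]
    g <- g + t(X[ii, , drop = FALSE]) %*% Vinvs[[k]] %*% y[ii]
  }
  beta <- solve(H, g)
  quad <- 0
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    r <- y[ii] - X[ii, , drop = FALSE] %*% beta
    quad <- quad + drop(t(r) %*% Vinvs[[k]] %*% r)
  }
  ll <- -0.5 * (length(y) * log(2 * pi) + ldV + quad)
  if (method == "REML")
    ll <- ll - 0.5 * determinant(H, logarithm = TRUE)$modulus +
      0.5 * p * log(2 * pi)
  as.numeric(ll)
}

# Random small mixed-model instance (<= 5 children x <= 6 visits) for the
# likelihood-oracle comparisons.
random_small_instance <- function(seed) {
  set.seed(seed)
  n_child <- sample(2:5, 1)
  meas <- do.call(rbind, lapply(seq_len(n_child), function(i) {
    n_i <- sample(3:6, 1)
    data.frame(child_id = sprintf("c%02d", i), cohort = "A",
               age = sort(runif(n_i, 0, 10)),
               weight = rnorm(n_i, 10, 3))
  }))
  children <- data.frame(child_id = sprintf("c%02d", seq_len(n_child)),
                         cohort = "A")
  A <- matrix(rnorm(9, sd = 0.4), 3, 3)
  list(pooled = pooled_data(meas, children),
       G = crossprod(A) + diag(0.05, 3),
       sigma2 = c(runif(1, 0.2, 1), runif(1, 0.5, 2)))
}
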