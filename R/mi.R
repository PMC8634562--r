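# Iterative multiple imputation of sporadically and systematically missing
# child-level categorical covariates.  Each cycle refits the full analysis
# model (with all its interactions) on the current completed data, derives
# per-child empirical-Bayes trajectory summaries from it, and redraws the
# missing covariate values from multinomial-logistic imputation models whose
# predictors are the other covariates, cohort indicators (where
# identifiable) and those summaries.  Because the same model generates the
# summaries, the imputation is congenial with the analysis model's
# nonlinear trajectory and interactions.

#' Multiple-imputation configuration
#'
#' @param M Number of imputed datasets (default 25).
#' @param n_cycles Fit-summarize-impute iterations per imputation
#'   (default 10).
#' @param imputation_order Covariate sequence per cycle.
#' @param summary_set Which child-specific trajectory summaries enter the
#'   imputation models: `"fitted"` (default) uses each child's fitted
#'   trajectory values \eqn{x_i(t)'\hat\beta + z(t)'\hat b_i} at the
#'   quartile ages of the child's cohort -- these track the child's
#'   observed data and stay essentially invariant to the current imputed
#'   covariate values, keeping the iteration stable; `"eb"` uses the raw
#'   empirical-Bayes random-effect predictions (residual deviations after
#'   the current covariate effects, which can feed back on the
#'   imputations).
#' @param seed Master seed; imputation `m` uses a seed derived
#'   deterministically from it.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(M = 25, n_cycles = 10,
                      imputation_order = c("ethnicity",
                                           "maternal_education",
                                           "paternal_occupation"),
                      summary_set = c("fitted", "eb"),
                      seed = 1) {
  stopifnot(M >= 2, n_cycles >= 1)
  summary_set <- match.arg(summary_set)
  structure(list(M = M, n_cycles = n_cycles,
                 imputation_order = imputation_order,
                 summary_set = summary_set, seed = seed),
            class = "mi_config")
}

#' Child-specific trajectory summaries for imputation
#'
#' For `type = "fitted"`: each child's fitted trajectory value
#' \eqn{x_i(t)'\hat\beta + z(t)'\hat b_i} at the 25th, 50th and 75th
#' percentile ages of the child's cohort. For `type = "eb"`: the
#' empirical-Bayes random-effect predictions themselves.
#'
#' @param fit A `growth_fit`.
#' @param pooled The completed dataset the fit was computed on.
#' @param type `"fitted"` or `"eb"`.
#' @return Numeric matrix with one row per child (child ids as row names).
#' @export
trajectory_summaries <- function(fit, pooled, type = c("fitted", "eb")) {
  type <- match.arg(type)
  eb <- eb_random_effects(fit, pooled)
  if (type == "eb") return(eb)
  kids <- pooled$children[match(rownames(eb), pooled$children$child_id), ,
                          drop = FALSE]
  qa <- lapply(split(pooled$measurements$age, pooled$measurements$cohort),
               stats::quantile, probs = c(0.25, 0.5, 0.75))
  out <- matrix(NA_real_, nrow(eb), 3,
                dimnames = list(rownames(eb), paste0("traj.q", 1:3)))
  for (lab in unique(kids$cohort)) {
    rows <- which(kids$cohort == lab)
    ages <- as.numeric(qa[[lab]])
    df <- kids[rep(rows, each = 3), , drop = FALSE]
    df$age <- rep(ages, length(rows))
    des <- build_design(df, fit$spec, fit$xlev)
    fitted <- drop(des$X %*% fit$beta) +
      rowSums(des$Z * eb[rep(rows, each = 3), , drop = FALSE])
    out[rows, ] <- matrix(fitted, ncol = 3, byrow = TRUE)
  }
  out
}

# Dummy-code the imputation-model predictors for a set of children:
# other covariates (current values), cohort indicators restricted to
# cohorts observed in the training subset, and the EB trajectory
# summaries.  Children from cohorts unseen in training get zero cohort
# dummies, so their imputations borrow the covariate-summary relationship
# estimated in the observed cohorts.
imputation_predictors <- function(children, target, covariates, cohorts_obs,
                                  eb) {
  n <- nrow(children)
  # the composite is a deterministic function of its components (and of
  # the target when the target is one of them): use the components instead
  if ("parental_composite" %in% covariates)
    covariates <- unique(c(setdiff(covariates, "parental_composite"),
                           "maternal_education", "paternal_occupation"))
  covariates <- setdiff(covariates, target)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (cv in covariates) {
    if (anyNA(children[[cv]]))
      stop("imputation predictor ", cv, " still contains missing values;",
           " add it to imputation_order", call. = FALSE)
    levs <- sort(unique(children[[cv]]))
    for (lev in levs[-1]) {
      col <- matrix(as.numeric(children[[cv]] == lev), ncol = 1,
                    dimnames = list(NULL, paste0(cv, "=", lev)))
      X <- cbind(X, col)
    }
  }
  if (length(cohorts_obs) > 1) {
    for (lab in cohorts_obs[-1]) {
      col <- matrix(as.numeric(children$cohort == lab), ncol = 1,
                    dimnames = list(NULL, paste0("cohort=", lab)))
      X <- cbind(X, col)
    }
  }
  ebm <- eb[match(children$child_id, rownames(eb)), , drop = FALSE]
  # standardize the trajectory summaries: keeps the multinomial fit and
  # its coefficient draws well conditioned
  ebm <- scale(ebm)
  ebm[, attr(ebm, "scaled:scale") == 0] <- 0
  colnames(ebm) <- paste0("eb.", seq_len(ncol(ebm)))
  X <- cbind(X, ebm)
  X
}

# Draw one set of multinomial-logistic coefficients from the asymptotic
# normal approximation of their sampling distribution and return drawn
# category probabilities for the prediction rows.
draw_multinom <- function(Xtrain, ytrain, Xpred) {
  keep <- c(TRUE, apply(Xtrain[, -1, drop = FALSE], 2,
                        function(col) stats::sd(col) > 0))
  Xt <- Xtrain[, keep, drop = FALSE]
  Xp <- Xpred[, keep, drop = FALSE]
  yf <- factor(ytrain)
  levs <- levels(yf)
  dat <- data.frame(.y = yf, Xt[, -1, drop = FALSE], check.names = FALSE)
  fit_once <- function(decay) tryCatch(
    nnet::multinom(.y ~ ., data = dat, trace = FALSE, maxit = 300,
                   MaxNWts = 5000, decay = decay),
    error = function(e) e)
  extract <- function(fit) {
    cf <- stats::coef(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
    est <- as.vector(t(cf))
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    if (!is.null(vc)) vc <- (vc + t(vc)) / 2
    ch <- if (is.null(vc) || any(!is.finite(vc)) ||
              nrow(vc) != length(est)) NULL else
      tryCatch(chol(vc), error = function(e) NULL)
    list(est = est, ch = ch)
  }
  fit <- fit_once(0)
  if (inherits(fit, "error"))
    stop("imputation model failed: ", conditionMessage(fit), call. = FALSE)
  par <- extract(fit)
  if (is.null(par$ch)) {
    # (near-)separation: refit with a small ridge penalty so both the
    # coefficients and their covariance are finite and stable
    warning("imputation model near separation; ridge-stabilized refit")
    fit <- fit_once(0.05)
    if (!inherits(fit, "error")) par <- extract(fit)
    if (is.null(par$ch)) {
      eg <- eigen(stats::vcov(fit) |> (\(v) (v + t(v)) / 2)(),
                  symmetric = TRUE)
      par$ch <- diag(sqrt(pmax(eg$values, 1e-8)), length(par$est)) %*%
        t(eg$vectors)
    }
  }
  est <- par$est
  npar <- length(est)
  draw <- est + drop(t(par$ch) %*% stats::rnorm(npar))
  Bmat <- matrix(draw, nrow = length(levs) - 1, byrow = TRUE)
  eta <- cbind(0, Xp %*% t(Bmat))
  eta <- eta - apply(eta, 1, max)   # overflow-safe softmax
  expeta <- exp(eta)
  probs <- expeta / rowSums(expeta)
  colnames(probs) <- levs
  probs
}

#' One completed dataset from the iterative imputation procedure
#'
#' Missing covariate values are initialized by draws from the observed
#' within-cohort category frequencies (pooled frequencies for cohorts
#' where the covariate is systematically missing). Then, for each of
#' `n_cycles` cycles: (1) the full analysis model is fitted to the current
#' completed data; (2) empirical-Bayes trajectory summaries are computed
#' for every child; (3) each incomplete covariate in turn is re-imputed
#' from a multinomial-logistic model fitted among children with the
#' covariate observed, with the other covariates, identifiable cohort
#' indicators and the trajectory summaries as predictors, coefficients
#' drawn from their asymptotic normal distribution, and missing values
#' drawn from the resulting category probabilities. The state after the
#' final cycle is returned. Observed values are never modified.
#'
#' @param pooled A [pooled_data()].
#' @param analysis_spec The analysis [model_spec()]; its covariates (or
#'   the components of `parental_composite`) drive which variables are
#'   imputed.
#' @param config An [mi_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A completed [pooled_data()] with attribute `"mi_log"` (one row
#'   per cycle and covariate: children imputed, analysis-model loglik).
#' @export
impute_once <- function(pooled, analysis_spec, config, seed = config$seed) {
  stopifnot(inherits(pooled, "pooled_data"),
            inherits(analysis_spec, "model_spec"),
            inherits(config, "mi_config"))
  children <- pooled$children
  targets <- intersect(config$imputation_order, names(children))
  miss <- lapply(targets, function(cv) is.na(children[[cv]]))
  names(miss) <- targets
  targets <- targets[vapply(miss, any, logical(1))]
  if (!length(targets)) return(pooled)
  uses_composite <- "parental_composite" %in% analysis_spec$covariates
  refresh <- function(children) {
    if (uses_composite)
      children$parental_composite <- derive_parental_composite(
        children$maternal_education, children$paternal_occupation)
    children
  }
  log_rows <- list()
  with_seed(seed, {
    # (0) initialize from observed category frequencies
    for (cv in targets) {
      m <- miss[[cv]]
      obs_tab <- table(children$cohort[!m], children[[cv]][!m])
      pooled_freq <- table(children[[cv]][!m])
      levs <- names(pooled_freq)
      for (lab in unique(children$cohort[m])) {
        rows <- which(m & children$cohort == lab)
        freq <- if (lab %in% rownames(obs_tab) &&
                    sum(obs_tab[lab, ]) > 0)
          obs_tab[lab, ] else pooled_freq
        children[[cv]][rows] <- levs[sample.int(length(levs), length(rows),
                                                replace = TRUE,
                                                prob = as.numeric(freq))]
      }
    }
    children <- refresh(children)
    fit <- NULL
    for (cycle in seq_len(config$n_cycles)) {
      completed <- pooled_data(pooled$measurements, children)
      new_fit <- tryCatch(
        fit_growth_model(completed, analysis_spec, method = "ML",
                         init = fit),
        error = function(e) e)
      if (inherits(new_fit, "error") && !is.null(fit)) {
        # retry cold
        new_fit <- tryCatch(
          fit_growth_model(completed, analysis_spec, method = "ML"),
          error = function(e) e)
      }
      if (inherits(new_fit, "error"))
        stop("analysis model failed in imputation cycle ", cycle, ": ",
             conditionMessage(new_fit), call. = FALSE)
      fit <- new_fit
      eb <- trajectory_summaries(fit, completed, type = config$summary_set)
      for (cv in targets) {
        m <- miss[[cv]]
        cohorts_obs <- sort(unique(children$cohort[!m]))
        Xall <- imputation_predictors(children, cv,
                                      unique(c(analysis_spec$covariates,
                                               targets)),
                                      cohorts_obs, eb)
        probs <- draw_multinom(Xall[!m, , drop = FALSE],
                               children[[cv]][!m],
                               Xall[m, , drop = FALSE])
        draws <- apply(probs, 1, function(p)
          colnames(probs)[sample.int(length(p), 1, prob = p)])
        children[[cv]][m] <- draws
        log_rows[[length(log_rows) + 1L]] <- data.frame(
          cycle = cycle, covariate = cv, n_imputed = sum(m),
          loglik = fit$loglik)
      }
      children <- refresh(children)
    }
    out <- pooled_data(pooled$measurements, children)
    attr(out, "mi_log") <- do.call(rbind, log_rows)
    out
  })
}

#' Generate M completed datasets
#'
#' Runs [impute_once()] `M` times with per-imputation seeds derived
#' deterministically from the master seed. Any failed imputation aborts
#' the whole run with the failing seeds listed -- the number of
#' imputations is never silently reduced.
#'
#' @inheritParams impute_once
#' @return List of `M` completed [pooled_data()] objects.
#' @export
multiple_impute <- function(pooled, analysis_spec, config) {
  seeds <- (config$seed + 104729L * seq_len(config$M)) %%
    .Machine$integer.max
  out <- vector("list", config$M)
  failed <- integer(0)
  msgs <- character(0)
  for (m in seq_len(config$M)) {
    r <- tryCatch(impute_once(pooled, analysis_spec, config,
                              seed = seeds[m]),
                  error = function(e) e)
    if (inherits(r, "error")) {
      failed <- c(failed, seeds[m])
      msgs <- c(msgs, conditionMessage(r))
    } else out[[m]] <- r
  }
  if (length(failed))
    stop("imputation failed for seed(s) ",
         paste(failed, collapse = ", "), ": ",
         paste(unique(msgs), collapse = "; "), call. = FALSE)
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' \eqn{\bar q = \frac1M \sum_m \hat q_m}; within-imputation variance
#' \eqn{W} = mean of the per-imputation variances; between-imputation
#' variance \eqn{B} = sample variance of the estimates; total variance
#' \eqn{T = W + (1 + 1/M) B}; degrees of freedom
#' \eqn{(M-1)\left(1 + \frac{W}{(1+1/M)B}\right)^2} (infinite when
#' \eqn{B = 0}); 95% intervals use the t distribution on those df.
#'
#' @param estimates `M x p` matrix of per-imputation estimates (or a list
#'   of vectors).
#' @param vcovs List of `M` per-imputation covariance matrices.
#' @return An object of class `pooled_estimate`: per-parameter table
#'   (`estimate`, `W`, `B`, `T`, `df`, `lwr`, `upr`) plus the pooled
#'   covariance matrix `T_mat`.
#' @export
pool_rubin <- function(estimates, vcovs) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  M <- nrow(estimates)
  if (M < 2)
    stop("Rubin's rules require M >= 2 imputations", call. = FALSE)
  stopifnot(length(vcovs) == M)
  q_bar <- colMeans(estimates)
  W_mat <- Reduce(`+`, vcovs) / M
  B_mat <- stats::cov(estimates)
  T_mat <- W_mat + (1 + 1 / M) * B_mat
  W <- diag(W_mat); B <- diag(B_mat); Tv <- diag(T_mat)
  df <- ifelse(B > 0, (M - 1) * (1 + W / ((1 + 1 / M) * B))^2, Inf)
  tq <- stats::qt(0.975, df)
  tab <- data.frame(estimate = q_bar, W = W, B = B, T = Tv, df = df,
                    lwr = q_bar - tq * sqrt(Tv),
                    upr = q_bar + tq * sqrt(Tv))
  rownames(tab) <- colnames(estimates)
  structure(list(table = tab, M = M, q_bar = q_bar, W_mat = W_mat,
                 B_mat = B_mat, T_mat = T_mat),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Rubin's-rules pooled estimates over M = %d imputations\n",
              x$M))
  print(round(utils::head(x$table, 15), 4))
  if (nrow(x$table) > 15) cat("  ...", nrow(x$table) - 15, "more\n")
  invisible(x)
}

#' Multiply-imputed analysis of the growth model
#'
#' Generates `M` completed datasets with [multiple_impute()], fits the
#' analysis model to each by REML, and pools the fixed effects by Rubin's
#' rules. The returned object carries a pooled `growth_fit` (point
#' estimates \eqn{\bar q}, covariance `T`) so [predict_mean()] and
#' [trajectory_contrast()] apply directly to the pooled inference.
#'
#' @inheritParams impute_once
#' @return An object of class `mi_result` with components `pooled`
#'   (a [pool_rubin()] result), `pooled_fit` (a `growth_fit` carrying the
#'   pooled estimates), `fits` (per-imputation fits) and `completed`
#'   (the M completed datasets).
#' @export
mi_analysis <- function(pooled, analysis_spec, config) {
  completed <- multiple_impute(pooled, analysis_spec, config)
  fits <- vector("list", config$M)
  for (m in seq_len(config$M)) {
    fits[[m]] <- fit_growth_model(completed[[m]], analysis_spec,
                                  method = "REML",
                                  init = if (m > 1) fits[[m - 1]] else NULL)
  }
  est <- do.call(rbind, lapply(fits, function(f) f$beta))
  pooled_est <- pool_rubin(est, lapply(fits, function(f) f$beta_vcov))
  pooled_fit <- fits[[1]]
  pooled_fit$beta <- pooled_est$q_bar
  pooled_fit$beta_vcov <- pooled_est$T_mat
  structure(list(pooled = pooled_est, pooled_fit = pooled_fit,
                 fits = fits, completed = completed, config = config),
            class = "mi_result")
}

#' @export
print.mi_result <- function(x, ...) {
  cat(sprintf("Multiply-imputed growth-model analysis (M = %d, %d cycles)\n",
              x$config$M, x$config$n_cycles))
  print(x$pooled)
  invisible(x)
}
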