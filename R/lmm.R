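# Two-level growth model: measurements nested in children, unstructured
# individual-level random effects on intercept + all trajectory columns,
# complex level-1 variance.  Estimation maximizes the exact block-diagonal
# marginal likelihood (ML or REML) with beta profiled out by GLS, over a
# log-Cholesky parameterization of G and log level-1 variances.

prepare_fit_data <- function(pooled, spec, xlev = NULL) {
  df <- assemble_analysis_frame(pooled, spec)
  if (is.null(xlev)) xlev <- design_levels(df, spec)
  des <- build_design(df, spec, xlev)
  lev1 <- spec$level1
  if (lev1$kind == "segmented") {
    seg <- findInterval(df$age, lev1$cuts, left.open = TRUE)
    nseg <- length(lev1$cuts) + 1L
    counts <- tabulate(seg + 1L, nseg)
    keep <- counts > 0L
    if (!all(keep)) {
      remap <- cumsum(keep) - 1L
      seg <- remap[seg + 1L]
      nseg <- sum(keep)
    }
    d <- numeric(length(seg))
    mode <- 0L
  } else {
    seg <- integer(nrow(df))
    d <- df$age^2
    nseg <- 2L
    keep <- c(TRUE, TRUE)
    mode <- 1L
  }
  child_len <- as.integer(table(factor(df$child_id,
                                       levels = unique(df$child_id))))
  list(df = df, X = des$X, Z = des$Z, traj_names = des$traj_names,
       xlev = xlev, seg = as.integer(seg), d = d, nseg = as.integer(nseg),
       seg_keep = keep, mode = mode, child_len = child_len,
       child_ids = unique(df$child_id))
}

theta_from_G <- function(G, sigma2) {
  L <- t(chol(G))
  q <- nrow(L)
  th <- numeric(0)
  for (j in seq_len(q))
    for (i in j:q)
      th <- c(th, if (i == j) log(L[i, j]) else L[i, j])
  c(th, log(sigma2))
}

#' Profiled marginal log-likelihood of a growth model
#'
#' Evaluates the exact block-diagonal ML or REML log-likelihood at given
#' variance parameters, with the fixed effects profiled out by generalized
#' least squares:
#' \deqn{\ell_{ML} = -\tfrac12 \sum_i \left[ n_i \log 2\pi + \log|V_i| +
#'   r_i' V_i^{-1} r_i \right],}
#' with \eqn{V_i = Z_i G Z_i' + R_i} and \eqn{r_i = y_i - X_i
#' \hat\beta(\theta)}; REML adds
#' \eqn{-\tfrac12 \log|\sum_i X_i'V_i^{-1}X_i| + \tfrac{p}{2}\log 2\pi}.
#' A positive-definite `G` is evaluated through the fast Woodbury path;
#' a singular `G` (e.g. the zero matrix) falls back to a dense per-child
#' construction of \eqn{V_i}.
#'
#' @param pooled A [pooled_data()] with complete covariates for `spec`.
#' @param spec A [model_spec()].
#' @param G Individual-level covariance matrix
#'   (`(1 + n trajectory columns)` square, PSD).
#' @param sigma2 Level-1 variance parameters: one per age band
#'   (segmented), or `(sigma0^2, sigma1^2)` (age-linear).
#' @param method `"ML"` or `"REML"`.
#' @return Log-likelihood (scalar).
#' @export
profiled_loglik <- function(pooled, spec, G, sigma2,
                            method = c("REML", "ML")) {
  method <- match.arg(method)
  pd <- prepare_fit_data(pooled, spec)
  if (pd$mode == 0L) sigma2 <- sigma2[pd$seg_keep]
  if (any(sigma2 < 0)) stop("sigma2 must be non-negative", call. = FALSE)
  pdG <- !inherits(try(chol(G), silent = TRUE), "try-error")
  if (pdG && all(sigma2 > 0)) {
    res <- lmm_eval(lmm_precompute(pd$X, pd$Z, pd$df$weight, pd$seg, pd$d,
                                   pd$child_len, pd$nseg, pd$mode),
                    theta_from_G(G, sigma2), method == "REML", FALSE, FALSE)
    if (!res$ok) stop("likelihood evaluation failed", call. = FALSE)
    return(res$loglik)
  }
  dense_profiled_loglik(pd, G, sigma2, method)
}

# Dense reference path: explicit per-child V_i (used for singular G).
dense_profiled_loglik <- function(pd, G, sigma2, method, beta = NULL) {
  y <- pd$df$weight
  idx <- split(seq_along(y), factor(pd$df$child_id,
                                    levels = unique(pd$df$child_id)))
  rvar <- if (pd$mode == 0L) sigma2[pd$seg + 1L] else
    sigma2[1] + sigma2[2] * pd$d
  p <- ncol(pd$X)
  H <- matrix(0, p, p); g <- numeric(p); yy <- 0; ldV <- 0
  Vi_inv <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    Zi <- pd$Z[ii, , drop = FALSE]
    Vi <- Zi %*% G %*% t(Zi) + diag(rvar[ii], length(ii))
    cV <- chol(Vi)
    ldV <- ldV + 2 * sum(log(diag(cV)))
    Vinv <- chol2inv(cV)
    Vi_inv[[k]] <- Vinv
    Xi <- pd$X[ii, , drop = FALSE]
    H <- H + t(Xi) %*% Vinv %*% Xi
    g <- g + t(Xi) %*% Vinv %*% y[ii]
    yy <- yy + drop(t(y[ii]) %*% Vinv %*% y[ii])
  }
  if (is.null(beta)) beta <- if (p > 0) solve(H, g) else numeric(0)
  rss <- if (p > 0) yy - 2 * sum(g * beta) + drop(t(beta) %*% H %*% beta)
         else yy
  ll <- -0.5 * (length(y) * log(2 * pi) + ldV + rss)
  if (method == "REML" && p > 0)
    ll <- ll - 0.5 * determinant(H, logarithm = TRUE)$modulus +
      0.5 * p * log(2 * pi)
  as.numeric(ll)
}

#' Marginal covariance of one child's measurements
#'
#' \eqn{V_i = Z_i G Z_i' + R_i} with diagonal \eqn{R_i}: segment variance
#' at each visit age (segmented) or
#' \eqn{\sigma_0^2 + \sigma_1^2 \, age^2} (age-linear; covariance between
#' the two measurement-level effects fixed at 0).
#'
#' @param Z Child random-effect design matrix (rows = visits).
#' @param ages Visit ages (length `nrow(Z)`).
#' @param G Individual-level covariance matrix.
#' @param level1 List with `spec` (a [level1_spec()]) and `variances`.
#' @return Symmetric covariance matrix.
#' @export
marginal_covariance <- function(Z, ages, G, level1) {
  stopifnot(nrow(Z) == length(ages), ncol(Z) == nrow(G))
  Z %*% G %*% t(Z) + diag(level1_variance_at(level1, ages), length(ages))
}

#' Fit the two-level growth model
#'
#' Maximizes the profiled ML or REML log-likelihood over an unconstrained
#' parameterization (log-Cholesky for the individual-level covariance
#' `G`, log for the level-1 variances) with analytic gradients, after
#' internally rescaling design columns to unit root-mean-square for
#' numerical stability (results are reported on the original scale).
#' The convergence flag requires the optimizer to report success and the
#' per-observation scaled gradient `max|grad| / n_obs` to fall below
#' `1e-4`.
#'
#' @param pooled A [pooled_data()]; covariates used by `spec` must be
#'   complete.
#' @param spec A [model_spec()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param init Optional warm start: a previous `growth_fit` or a list with
#'   elements `G` and `sigma2` (original scale).
#' @param max_iter Maximum optimizer iterations.
#' @param rel_tol Relative convergence tolerance of the optimizer on the
#'   log-likelihood scale.
#' @return An object of class `growth_fit` with elements `beta`,
#'   `beta_vcov`, `G_hat`, `level1_hat`, `loglik`, `method`, `n_obs`,
#'   `n_children`, `n_params`, `converged`, `gradient_norm`.
#' @export
fit_growth_model <- function(pooled, spec, method = c("REML", "ML"),
                             init = NULL, max_iter = 400,
                             rel_tol = 1e-8) {
  method <- match.arg(method)
  reml <- method == "REML"
  pd <- prepare_fit_data(pooled, spec)
  X <- pd$X; Z <- pd$Z; y <- pd$df$weight
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  if (length(pd$child_len) <= q)
    stop("need more children than random effects", call. = FALSE)
  sx <- sqrt(colMeans(X^2)); sx[sx == 0] <- 1
  sz <- sqrt(colMeans(Z^2)); sz[sz == 0] <- 1
  Xs <- sweep(X, 2, sx, "/"); Zs <- sweep(Z, 2, sz, "/")
  ptr <- lmm_precompute(Xs, Zs, y, pd$seg, pd$d, pd$child_len, pd$nseg,
                        pd$mode)
  nsig <- if (pd$mode == 0L) pd$nseg else 2L
  ntheta <- q * (q + 1) / 2 + nsig

  if (is.null(init)) {
    ols <- stats::.lm.fit(Xs, y)
    v <- max(sum(ols$residuals^2) / max(n - p, 1), 1e-6)
    mom <- lmm_mom_init(ptr, ols$coefficients)
    G0 <- (mom$G0 + t(mom$G0)) / 2
    # cap the overall size: the scaled columns have unit RMS, so diag(G)
    # sums to roughly the between-child variance share
    m <- mean(diag(G0))
    if (is.finite(m) && m > v) G0 <- G0 * (v / m)
    eg <- eigen(G0, symmetric = TRUE)
    floor_ev <- max(mean(diag(G0)), 1e-4) * 1e-3
    G0 <- eg$vectors %*% diag(pmax(eg$values, floor_ev), ncol(G0)) %*%
      t(eg$vectors)
    s0 <- pmax(as.numeric(mom$sigma2), 1e-6)
    th0 <- theta_from_G(G0, s0)
    # EM warm start: a few expectation-maximization updates move G's
    # scale and correlation structure near the optimum at the cost of a
    # couple of likelihood evaluations per step
    if (pd$mode == 0L) {
      ll_prev <- -Inf
      for (it in seq_len(40L)) {
        em <- lmm_em_step(ptr, th0)
        if (!isTRUE(em$ok)) break
        Gem <- (em$G + t(em$G)) / 2
        egm <- eigen(Gem, symmetric = TRUE)
        Gem <- egm$vectors %*%
          diag(pmax(egm$values, 1e-10 * max(egm$values, 1e-8)),
               ncol(Gem)) %*% t(egm$vectors)
        th0 <- theta_from_G(Gem, pmax(as.numeric(em$sigma2), 1e-10))
        if (is.finite(ll_prev) && em$loglik - ll_prev < 0.5) break
        ll_prev <- em$loglik
      }
    }
  } else {
    if (inherits(init, "growth_fit"))
      init <- list(G = init$G_hat, sigma2 = init$level1_hat$variances)
    Gs <- diag(sz) %*% init$G %*% diag(sz)
    s2 <- init$sigma2
    if (pd$mode == 0L) {
      s2 <- s2[!is.na(s2)]
      if (length(s2) != nsig) s2 <- rep(stats::median(s2), nsig)
    }
    Gs <- Gs + diag(q) * 1e-8 * mean(diag(Gs))
    th0 <- theta_from_G(Gs, pmax(s2, 1e-8))
  }

  env <- new.env()
  env$theta <- NULL
  evalat <- function(theta) {
    if (!identical(theta, env$theta)) {
      env$res <- lmm_eval(ptr, theta, reml, TRUE, FALSE)
      env$theta <- theta
    }
    env$res
  }
  fn <- function(theta) {
    r <- evalat(theta)
    if (!isTRUE(r$ok) || !is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  gr <- function(theta) {
    r <- evalat(theta)
    if (!isTRUE(r$ok)) return(rep(0, length(theta)))
    -as.numeric(r$grad)
  }
  is_logdiag <- logical(ntheta)
  k <- 0
  for (j in seq_len(q)) for (i in j:q) {
    k <- k + 1; is_logdiag[k] <- (i == j)
  }
  is_logdiag[(ntheta - nsig + 1):ntheta] <- TRUE
  lower <- ifelse(is_logdiag, -14, -Inf)
  upper <- ifelse(is_logdiag, 14, Inf)
  th <- th0
  iters <- 0L
  # low-dimensional problems converge fastest under L-BFGS-B; larger ones
  # under nlminb's trust-region steps.  Either way, finish with nlminb
  # restarts until the scaled gradient criterion is met.
  if (ntheta <= 10) {
    o0 <- stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower,
                       upper = upper,
                       control = list(maxit = max_iter, lmm = 25,
                                      factr = max(rel_tol /
                                                    .Machine$double.eps,
                                                  1e5)))
    th <- o0$par
    iters <- o0$counts[["function"]]
  }
  opt <- list(par = th, iterations = 0L, convergence = 0L,
              message = "warm start")
  for (attempt in 1:2) {
    chk <- lmm_eval(ptr, th, reml, TRUE, FALSE)
    if (isTRUE(chk$ok) && max(abs(chk$grad)) / n < 1e-4 && attempt > 1)
      break
    if (isTRUE(chk$ok) && max(abs(chk$grad)) / n < 1e-4 &&
        iters > 0L) break
    opt <- stats::nlminb(th, fn, gr, lower = lower, upper = upper,
                         control = list(iter.max = max_iter,
                                        eval.max = 4 * max_iter,
                                        rel.tol = rel_tol))
    th <- opt$par
    iters <- iters + opt$iterations
    if (opt$iterations <= 1) break   # stalled; restarting cannot help
  }
  opt$par <- th
  opt$iterations <- iters
  final <- lmm_eval(ptr, opt$par, reml, TRUE, TRUE)
  if (!isTRUE(final$ok))
    stop(paste("likelihood evaluation failed at the optimum;",
               "the fixed-effect design may be rank-deficient",
               "(see prune_unsupported_interactions)"), call. = FALSE)
  grad_norm <- max(abs(final$grad)) / n
  converged <- is.finite(final$loglik) && grad_norm < 1e-4

  beta <- as.numeric(final$beta) / sx
  names(beta) <- colnames(X)
  vb <- final$beta_vcov / tcrossprod(sx)
  dimnames(vb) <- list(colnames(X), colnames(X))
  Gh <- final$G / tcrossprod(sz)
  dimnames(Gh) <- list(colnames(Z), colnames(Z))
  sig2 <- as.numeric(final$sigma2)
  loglik <- final$loglik
  if (reml) loglik <- loglik - sum(log(sx))
  if (pd$mode == 0L) {
    full_sig <- rep(NA_real_, length(pd$seg_keep))
    full_sig[pd$seg_keep] <- sig2
    cuts <- spec$level1$cuts
    nm <- if (length(cuts))
      c(paste0("<=", cuts[1]),
        if (length(cuts) > 1)
          paste0("(", cuts[-length(cuts)], ",", cuts[-1], "]") else NULL,
        paste0(">", cuts[length(cuts)]))
    else "all"
    names(full_sig) <- nm
  } else {
    full_sig <- c(sigma0_sq = sig2[1], sigma1_sq = sig2[2])
  }
  age_support <- lapply(split(pd$df$age, pd$df$cohort), range)
  structure(list(
    beta = beta, beta_vcov = vb, G_hat = Gh,
    level1_hat = list(spec = spec$level1, variances = full_sig),
    loglik = loglik, method = method,
    n_obs = n, n_children = length(pd$child_len),
    n_params = p + q * (q + 1) / 2 + nsig,
    converged = converged, gradient_norm = grad_norm,
    spec = spec, xlev = pd$xlev, traj_names = pd$traj_names,
    age_support = age_support, age_range = range(pd$df$age),
    child_ids = pd$child_ids,
    opt = list(iterations = opt$iterations, message = opt$message,
               convergence = opt$convergence)),
    class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Two-level growth model (%s), %d obs / %d children\n",
              x$method, x$n_obs, x$n_children))
  cat("  ", format(x$spec$trajectory), "; ", format(x$spec$level1), "\n",
      sep = "")
  cat(sprintf("  logLik %.3f | %d parameters | %s (max|grad|/n = %.2g)\n",
              x$loglik, x$n_params,
              if (x$converged) "converged" else "NOT converged",
              x$gradient_norm))
  cat("  fixed effects:\n")
  est <- cbind(estimate = x$beta, se = sqrt(diag(x$beta_vcov)))
  print(round(utils::head(est, 12), 4))
  if (length(x$beta) > 12) cat("  ...", length(x$beta) - 12, "more\n")
  cat("  level-1 variances:",
      paste(sprintf("%s=%.4g", names(x$level1_hat$variances),
                    x$level1_hat$variances), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.growth_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Information criteria of a growth model fit
#'
#' `AIC = -2 loglik + 2 k` and `BIC = -2 loglik + k log(n_obs)`, with `k`
#' counting fixed effects plus free variance parameters.
#'
#' @param fit A `growth_fit`.
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  k <- fit$n_params
  c(AIC = -2 * fit$loglik + 2 * k,
    BIC = -2 * fit$loglik + k * log(fit$n_obs))
}

# Fixed-effect design rows for a covariate pattern at given ages.
pattern_design <- function(fit, pattern, ages) {
  df <- data.frame(age = ages)
  if (fit$spec$cohort_as_fixed) {
    if (is.null(pattern$cohort))
      stop("pattern must include cohort", call. = FALSE)
    df$cohort <- pattern$cohort
  } else df$cohort <- fit$xlev$cohort[1] %||% "all"
  for (cv in fit$spec$covariates) {
    if (is.null(pattern[[cv]]))
      stop("pattern must include ", cv, call. = FALSE)
    df[[cv]] <- pattern[[cv]]
  }
  build_design(df, fit$spec, fit$xlev)$X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_support <- function(fit, pattern, ages, allow_extrapolation) {
  rng <- if (!is.null(pattern$cohort) &&
             !is.null(fit$age_support[[pattern$cohort]]))
    fit$age_support[[pattern$cohort]] else fit$age_range
  out <- ages < rng[1] - 1e-9 | ages > rng[2] + 1e-9
  if (any(out) && !allow_extrapolation)
    stop(sprintf(paste("ages %s outside the fitted age support [%.2f, %.2f];",
                       "predictions beyond the data are refused unless",
                       "allow_extrapolation = TRUE"),
                 paste(signif(ages[out], 3), collapse = ", "),
                 rng[1], rng[2]), call. = FALSE)
}

#' Predicted mean trajectory for a covariate pattern
#'
#' Computes \eqn{x(t)'\hat\beta} on an age grid with pointwise 95%
#' delta-method confidence intervals. Ages beyond the age support of the
#' pattern's cohort are refused by default, since the pooled model is not
#' used to predict beyond the data.
#'
#' @param fit A `growth_fit`.
#' @param pattern Named list of covariate values (including `cohort` when
#'   cohort is a fixed effect).
#' @param ages Numeric age grid.
#' @param allow_extrapolation Override the support guard.
#' @return Data frame with columns `age`, `fit`, `se`, `lwr`, `upr` (kg).
#' @export
predict_mean <- function(fit, pattern, ages, allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "growth_fit"))
  check_support(fit, pattern, ages, allow_extrapolation)
  Xp <- pattern_design(fit, pattern, ages)
  est <- drop(Xp %*% fit$beta)
  se <- sqrt(pmax(rowSums((Xp %*% fit$beta_vcov) * Xp), 0))
  zc <- stats::qnorm(0.975)
  data.frame(age = ages, fit = est, se = se,
             lwr = est - zc * se, upr = est + zc * se)
}

#' Predicted mean difference between two covariate patterns
#'
#' \eqn{(x_a - x_b)'\hat\beta} at one age, with a 95% delta-method
#' confidence interval. Antisymmetric in its patterns by construction.
#'
#' @param fit A `growth_fit`.
#' @param pattern_a,pattern_b Covariate patterns as in [predict_mean()].
#' @param age Single age in years.
#' @param allow_extrapolation Override the support guard.
#' @return Named numeric vector `c(difference, se, lwr, upr)` in kg.
#' @export
trajectory_contrast <- function(fit, pattern_a, pattern_b, age,
                                allow_extrapolation = FALSE) {
  stopifnot(inherits(fit, "growth_fit"), length(age) == 1)
  check_support(fit, pattern_a, age, allow_extrapolation)
  check_support(fit, pattern_b, age, allow_extrapolation)
  d <- pattern_design(fit, pattern_a, age) -
    pattern_design(fit, pattern_b, age)
  est <- drop(d %*% fit$beta)
  se <- sqrt(max(drop(d %*% fit$beta_vcov %*% t(d)), 0))
  zc <- stats::qnorm(0.975)
  c(difference = est, se = se, lwr = est - zc * se, upr = est + zc * se)
}

#' Empirical-Bayes random-effect predictions
#'
#' Per-child shrinkage predictions
#' \eqn{\hat b_i = \hat G Z_i' \hat V_i^{-1} (y_i - X_i \hat\beta)} --
#' the child-specific trajectory summaries used, among other things, as
#' predictors in the covariate imputation models.
#'
#' @param fit A `growth_fit`.
#' @param pooled The dataset to predict for (defaults semantics: must be
#'   complete in the covariates of the fit's spec).
#' @return Numeric matrix (children x random effects) with child ids as
#'   row names.
#' @export
eb_random_effects <- function(fit, pooled) {
  stopifnot(inherits(fit, "growth_fit"))
  no_meas <- setdiff(pooled$children$child_id,
                     unique(pooled$measurements$child_id))
  if (length(no_meas))
    warning(length(no_meas), " children with no measurements excluded")
  pd <- prepare_fit_data(pooled, fit$spec, xlev = fit$xlev)
  r <- pd$df$weight - drop(pd$X %*% fit$beta)
  rvar <- if (pd$mode == 0L) {
    v <- fit$level1_hat$variances
    if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
    band <- findInterval(pd$df$age, fit$spec$level1$cuts,
                         left.open = TRUE) + 1L
    v[band]
  } else {
    fit$level1_hat$variances[1] + fit$level1_hat$variances[2] * pd$d
  }
  idx <- split(seq_len(nrow(pd$df)),
               factor(pd$df$child_id, levels = pd$child_ids))
  q <- ncol(pd$Z)
  out <- matrix(NA_real_, length(idx), q,
                dimnames = list(names(idx), colnames(pd$Z)))
  G <- fit$G_hat
  for (k in seq_along(idx)) {
    ii <- idx[[k]]
    Zi <- pd$Z[ii, , drop = FALSE]
    Vi <- Zi %*% G %*% t(Zi) + diag(rvar[ii], length(ii))
    out[k, ] <- drop(G %*% t(Zi) %*% solve(Vi, r[ii]))
  }
  out
}

#' Out-of-sample mean squared prediction error
#'
#' Mean over validation measurements of \eqn{(y - x(t)'\hat\beta)^2},
#' using fixed effects only (new children have no estimated random
#' effects). Validation children must be disjoint from the children the
#' model was fitted on.
#'
#' @param fit A `growth_fit`.
#' @param validation A [pooled_data()] of held-out children.
#' @return Scalar MSPE in kg^2.
#' @export
mspe <- function(fit, validation) {
  stopifnot(inherits(fit, "growth_fit"), inherits(validation, "pooled_data"))
  overlap <- intersect(fit$child_ids, validation$children$child_id)
  if (length(overlap))
    stop("validation children overlap the training children", call. = FALSE)
  pd <- prepare_fit_data(validation, fit$spec, xlev = fit$xlev)
  pred <- drop(pd$X %*% fit$beta)
  mean((pd$df$weight - pred)^2)
}

# Per-child sums of squared prediction errors (and counts) on validation
# data; used for paired, child-clustered comparisons of candidates.
mspe_by_child <- function(fit, validation) {
  pd <- prepare_fit_data(validation, fit$spec, xlev = fit$xlev)
  se2 <- (pd$df$weight - drop(pd$X %*% fit$beta))^2
  fac <- factor(pd$df$child_id, levels = pd$child_ids)
  list(sse = as.numeric(tapply(se2, fac, sum)),
       n = as.numeric(tapply(se2, fac, length)),
       child = pd$child_ids)
}

#' Serialize a fitted growth model to plain text
#'
#' Writes `estimates.csv` (named coefficients and standard errors),
#' `beta_vcov.csv`, `G.csv`, `level1.csv` and `meta.json` (log-likelihood,
#' method, sample sizes, convergence diagnostics) into `dir`.
#'
#' @param fit A `growth_fit`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_growth_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "growth_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(parameter = names(fit$beta),
                              estimate = fit$beta,
                              se = sqrt(diag(fit$beta_vcov))),
                   file.path(dir, "estimates.csv"), row.names = FALSE)
  utils::write.csv(fit$beta_vcov, file.path(dir, "beta_vcov.csv"))
  utils::write.csv(fit$G_hat, file.path(dir, "G.csv"))
  utils::write.csv(data.frame(band = names(fit$level1_hat$variances),
                              variance = fit$level1_hat$variances),
                   file.path(dir, "level1.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(loglik = fit$loglik, method = fit$method, n_obs = fit$n_obs,
         n_children = fit$n_children, n_params = fit$n_params,
         converged = fit$converged, gradient_norm = fit$gradient_norm,
         trajectory = format(fit$spec$trajectory),
         level1 = format(fit$spec$level1)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
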