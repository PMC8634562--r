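# Two-stage trajectory model selection on a cohort-stratified random
# subsample, with validation-set MSPE adjudication of the shortlisted
# candidates, plus the summed-likelihood alternative.

#' Selection configuration
#'
#' @param n_select Number of children in the selection sample (the
#'   remaining children form the validation set).
#' @param criterion `"BIC"` (default) or `"AIC"`: ranks candidates within
#'   each family at stage 1 and the covariance candidates at stage 2; both
#'   criteria are always reported.
#' @param top_k_per_family Candidates per family carried to the validation
#'   comparison (default 2, giving the usual 4-model showdown).
#' @param seed Integer seed for the child-level split.
#' @param stage1_level1 Level-1 structure used for every stage-1 fit
#'   (default: independent measurement-level random intercepts for ages
#'   `<= 2` and `> 2` years).
#' @param stage1_cohort_as_fixed Include cohort fixed effects in the
#'   stage-1 fits; default `FALSE` (stage-1 models contain the intercept
#'   and trajectory terms only).
#' @param rcs_n_knots Knot counts for the spline candidates.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(n_select, criterion = c("BIC", "AIC"),
                             top_k_per_family = 2, seed = 1,
                             stage1_level1 = level1_spec("segmented",
                                                         cuts = 2),
                             stage1_cohort_as_fixed = FALSE,
                             rcs_n_knots = 3:7) {
  criterion <- match.arg(criterion)
  stopifnot(n_select >= 1, top_k_per_family >= 1)
  structure(list(n_select = n_select, criterion = criterion,
                 top_k_per_family = top_k_per_family, seed = seed,
                 stage1_level1 = stage1_level1,
                 stage1_cohort_as_fixed = stage1_cohort_as_fixed,
                 rcs_n_knots = rcs_n_knots),
            class = "selection_config")
}

#' Restrict a pooled dataset to a set of children
#'
#' @param pooled A [pooled_data()].
#' @param child_ids Character vector of child ids to keep.
#' @return A [pooled_data()] with those children and their measurements.
#' @export
subset_pooled <- function(pooled, child_ids) {
  pooled_data(
    pooled$measurements[pooled$measurements$child_id %in% child_ids, ,
                        drop = FALSE],
    pooled$children[pooled$children$child_id %in% child_ids, ,
                    drop = FALSE])
}

#' Cohort-stratified child-level data split
#'
#' Draws a random selection sample of `n_select` children in which each
#' cohort is represented in proportion to its share of the pooled data
#' (largest-remainder rounding), all of a child's measurements travelling
#' with the child. The unselected children form the validation set.
#'
#' @param pooled A [pooled_data()].
#' @param n_select Number of children to select (must be below the total).
#' @param seed Integer seed; the split is deterministic given it.
#' @param stratify_by_cohort Stratify on cohort shares (default `TRUE`).
#' @return List with `selection` and `validation` ([pooled_data()]s).
#' @export
split_sample <- function(pooled, n_select, seed = 1,
                         stratify_by_cohort = TRUE) {
  stopifnot(inherits(pooled, "pooled_data"))
  kids <- pooled$children
  total <- nrow(kids)
  if (n_select >= total)
    stop("n_select must be smaller than the number of children",
         call. = FALSE)
  with_seed(seed, {
    if (stratify_by_cohort) {
      tab <- table(kids$cohort)
      exact <- as.numeric(tab) * n_select / total
      base <- floor(exact)
      rem <- n_select - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      names(base) <- names(tab)
      if (any(base == 0))
        warning("cohort(s) allocated 0 selection children: ",
                paste(names(base)[base == 0], collapse = ", "))
      sel_ids <- unlist(lapply(names(tab), function(lab) {
        ids <- kids$child_id[kids$cohort == lab]
        sample(ids, base[[lab]])
      }), use.names = FALSE)
    } else {
      sel_ids <- sample(kids$child_id, n_select)
    }
    list(selection = subset_pooled(pooled, sel_ids),
         validation = subset_pooled(pooled,
                                    setdiff(kids$child_id, sel_ids)))
  })
}

candidate_label <- function(spec) format(spec)

# Candidate ranking rides on criterion gaps far above the stopping
# tolerance, so screening fits use a slightly looser rel_tol than final
# inference fits.
fit_candidate <- function(pooled, basis, level1, cohort_as_fixed, method,
                          init = NULL, max_iter = 400, rel_tol = 1e-7) {
  spec <- model_spec(basis, covariates = character(),
                     cohort_as_fixed = cohort_as_fixed, level1 = level1)
  fit <- tryCatch(fit_growth_model(pooled, spec, method = method,
                                   init = init, max_iter = max_iter,
                                   rel_tol = rel_tol),
                  error = function(e) e)
  fit
}

#' Stage 1: select the trajectory form
#'
#' Fits every fractional-polynomial candidate (degrees 1--2 over the
#' 7-power set, 35 models) and every restricted-cubic-spline candidate
#' (3--7 knots placed at percentiles of the selection-sample measurement
#' ages) by maximum likelihood on the selection sample, with the stage-1
#' structure: fixed effects = intercept + trajectory terms, individual
#' random effects on all of them, and two independent measurement-level
#' variances for ages `<= 2` and `> 2` years. Candidates are ranked by the
#' configured criterion within family; the top `top_k_per_family` of each
#' family are then compared on validation-set MSPE, and the candidate with
#' the smallest MSPE wins (ties broken by fewer parameters, then canonical
#' order). Non-converged candidates are excluded from ranking and flagged
#' in the candidate table.
#'
#' @param pooled A [pooled_data()].
#' @param config A [selection_config()].
#' @return An object of class `selection_report`.
#' @export
stage1_select <- function(pooled, config) {
  stopifnot(inherits(config, "selection_config"))
  sp <- split_sample(pooled, config$n_select, seed = config$seed)
  selection <- sp$selection
  validation <- sp$validation
  ages_sel <- selection$measurements$age
  cands <- enumerate_fp_candidates()
  fams <- rep("FP", length(cands))
  rcs <- enumerate_rcs_candidates(ages_sel, config$rcs_n_knots)
  cands <- c(cands, rcs)
  fams <- c(fams, rep("RCS", length(rcs)))

  rows <- vector("list", length(cands))
  fits <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    fit <- fit_candidate(selection, cands[[i]], config$stage1_level1,
                         config$stage1_cohort_as_fixed, method = "ML")
    ok <- inherits(fit, "growth_fit")
    ic <- if (ok) information_criteria(fit) else c(AIC = NA_real_,
                                                   BIC = NA_real_)
    rows[[i]] <- data.frame(
      candidate = candidate_label(cands[[i]]), family = fams[i],
      n_params = if (ok) fit$n_params else NA_integer_,
      loglik = if (ok) fit$loglik else NA_real_,
      AIC = ic[["AIC"]], BIC = ic[["BIC"]],
      converged = ok && fit$converged,
      error = if (ok) "" else conditionMessage(fit))
    fits[[i]] <- if (ok) fit else NULL
  }
  tab <- do.call(rbind, rows)
  usable <- which(tab$converged)
  if (!length(usable))
    stop("no stage-1 candidate converged", call. = FALSE)
  crit <- tab[[config$criterion]]
  shortlist <- integer(0)
  for (fam in unique(fams)) {
    idx <- usable[fams[usable] == fam]
    idx <- idx[order(crit[idx], tab$n_params[idx], idx)]
    shortlist <- c(shortlist, utils::head(idx, config$top_k_per_family))
  }
  percand <- lapply(shortlist, function(i)
    mspe_by_child(fits[[i]], validation))
  n_val_obs <- sum(percand[[1]]$n)
  val_mspe <- vapply(percand, function(pc) sum(pc$sse) / n_val_obs,
                     numeric(1))
  # one-standard-error rule: MSPE differences within one SE of the paired
  # (child-clustered) difference from the best candidate are ties,
  # resolved toward fewer parameters, then canonical order
  best <- order(val_mspe, tab$n_params[shortlist], shortlist)[1]
  n_ch <- length(percand[[1]]$sse)
  tied <- vapply(seq_along(shortlist), function(k) {
    if (k == best) return(TRUE)
    d <- (percand[[k]]$sse - percand[[best]]$sse)
    se_d <- stats::sd(d) * sqrt(n_ch) / n_val_obs
    (val_mspe[k] - val_mspe[best]) <= se_d
  }, logical(1))
  cand_tied <- shortlist[tied]
  ordt <- order(tab$n_params[cand_tied], match(cand_tied, shortlist))
  winner_idx <- cand_tied[ordt[1]]
  structure(list(
    candidates = tab,
    shortlist = data.frame(candidate = tab$candidate[shortlist],
                           family = tab$family[shortlist],
                           n_params = tab$n_params[shortlist],
                           validation_mspe = val_mspe),
    winner = cands[[winner_idx]],
    winner_label = tab$candidate[winner_idx],
    winner_family = tab$family[winner_idx],
    winner_fit = fits[[winner_idx]],
    criterion = config$criterion,
    n_selection = nrow(selection$children),
    n_validation = nrow(validation$children),
    selection_ids = selection$children$child_id),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Stage-1 trajectory selection (%s within family, MSPE across)\n",
              x$criterion))
  cat(sprintf("  %d selection / %d validation children; %d candidates, %d converged\n",
              x$n_selection, x$n_validation, nrow(x$candidates),
              sum(x$candidates$converged)))
  cat("  shortlist:\n")
  print(x$shortlist, row.names = FALSE)
  cat("  winner:", x$winner_label, "\n")
  if (!is.null(x$stage2)) {
    cat("  stage 2 (level-1 structure, REML):\n")
    print(x$stage2, row.names = FALSE)
    cat("  final:", format(x$final_spec$level1), "\n")
  }
  invisible(x)
}

#' Summed-likelihood model comparison across cohorts
#'
#' Fits the same trajectory model separately to every cohort by maximum
#' likelihood and sums the log-likelihoods; the information-criterion
#' penalty counts the per-cohort parameters times the number of cohorts.
#' A spline candidate whose knots do not lie strictly inside every
#' cohort's age range cannot be fitted per cohort and raises an error --
#' the structural reason this route fails when cohorts cover different
#' age windows, and the random-sample approach is used instead.
#'
#' @param basis A [basis_spec()] trajectory candidate.
#' @param pooled A [pooled_data()].
#' @param level1 Level-1 structure for the per-cohort fits.
#' @return List with `loglik`, `AIC`, `n_params` and a `per_cohort` table.
#' @export
summed_likelihood <- function(basis, pooled,
                              level1 = level1_spec("segmented", cuts = 2)) {
  stopifnot(inherits(basis, "basis_spec"), inherits(pooled, "pooled_data"))
  labs <- sort(unique(pooled$children$cohort))
  if (basis$family == "RCS") {
    for (lab in labs) {
      rng <- range(pooled$measurements$age[pooled$measurements$cohort == lab])
      if (any(basis$knots <= rng[1]) || any(basis$knots >= rng[2]))
        stop(sprintf(paste("candidate not fittable per cohort: knots",
                           "outside the age range [%.2f, %.2f] of cohort %s"),
                     rng[1], rng[2], lab), call. = FALSE)
    }
  }
  rows <- lapply(labs, function(lab) {
    sub <- subset_pooled(pooled,
                         pooled$children$child_id[pooled$children$cohort ==
                                                    lab])
    fit <- fit_candidate(sub, basis, level1, cohort_as_fixed = FALSE,
                         method = "ML")
    if (!inherits(fit, "growth_fit"))
      stop("per-cohort fit failed for ", lab, ": ", conditionMessage(fit),
           call. = FALSE)
    data.frame(cohort = lab, n_children = fit$n_children,
               loglik = fit$loglik, n_params = fit$n_params,
               converged = fit$converged)
  })
  tab <- do.call(rbind, rows)
  ll <- sum(tab$loglik)
  k <- sum(tab$n_params)
  list(loglik = ll, AIC = -2 * ll + 2 * k, n_params = k, per_cohort = tab)
}

#' Stage 2: select the level-1 covariance structure
#'
#' Refits the winning trajectory under each candidate measurement-level
#' variance structure by REML (the fixed effects are identical across
#' candidates, so REML comparisons are valid) and ranks by the criterion.
#' Ties go to the earlier candidate in the list.
#'
#' @param pooled Data to fit on (typically the selection sample).
#' @param trajectory The winning [basis_spec()] from stage 1.
#' @param candidates List of [level1_spec()]s; default: the segmented
#'   structure with a cut at 2 years, and the age-linear structure.
#' @param criterion `"BIC"` or `"AIC"`.
#' @param cohort_as_fixed Passed to the fits (default `FALSE`, matching
#'   stage 1).
#' @return List with `winner` (a `level1_spec`), `table`, `criterion`.
#' @export
stage2_select <- function(pooled, trajectory,
                          candidates = list(
                            level1_spec("segmented", cuts = 2),
                            level1_spec("age_linear")),
                          criterion = c("BIC", "AIC"),
                          cohort_as_fixed = FALSE) {
  criterion <- match.arg(criterion)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    fit <- fit_candidate(pooled, trajectory, candidates[[i]],
                         cohort_as_fixed, method = "REML")
    ok <- inherits(fit, "growth_fit")
    ic <- if (ok) information_criteria(fit) else c(AIC = NA_real_,
                                                   BIC = NA_real_)
    rows[[i]] <- data.frame(
      level1 = format(candidates[[i]]),
      n_params = if (ok) fit$n_params else NA_integer_,
      loglik = if (ok) fit$loglik else NA_real_,
      AIC = ic[["AIC"]], BIC = ic[["BIC"]],
      converged = ok && fit$converged)
  }
  tab <- do.call(rbind, rows)
  usable <- which(tab$converged)
  if (!length(usable)) stop("no stage-2 candidate converged", call. = FALSE)
  crit <- tab[[criterion]]
  ord <- usable[order(crit[usable], tab$n_params[usable], usable)]
  list(winner = candidates[[ord[1]]], table = tab, criterion = criterion)
}

#' Two-stage trajectory and covariance selection
#'
#' Runs [stage1_select()] (trajectory form on the stratified selection
#' sample with validation MSPE) followed by [stage2_select()]
#' (measurement-level covariance of the winning trajectory, REML), and
#' assembles the final [model_spec()].
#'
#' @inheritParams stage1_select
#' @param level1_candidates Candidate structures for stage 2.
#' @return The `selection_report` from stage 1, augmented with `stage2`
#'   (stage-2 table) and `final_spec` (a [model_spec()] with no
#'   covariates; add covariates and prune interactions afterwards).
#' @export
select_trajectory <- function(pooled, config,
                              level1_candidates = list(
                                level1_spec("segmented", cuts = 2),
                                level1_spec("age_linear"))) {
  rep1 <- stage1_select(pooled, config)
  selection <- subset_pooled(pooled, rep1$selection_ids)
  s2 <- stage2_select(selection, rep1$winner,
                      candidates = level1_candidates,
                      criterion = config$criterion,
                      cohort_as_fixed = config$stage1_cohort_as_fixed)
  rep1$stage2 <- s2$table
  rep1$final_spec <- model_spec(rep1$winner, covariates = character(),
                                cohort_as_fixed = TRUE, level1 = s2$winner)
  rep1
}

#' Drop covariate-by-trajectory interactions unsupported by the data
#'
#' For each covariate level and each trajectory column, counts the
#' children and measurements carrying that level inside the column's
#' support region -- for a restricted-cubic-spline nonlinear column the
#' ages above its knot (the column is identically zero below it), for the
#' linear age column and fractional-polynomial columns the whole age
#' range. Interactions whose counts fall below the thresholds are removed
#' from the specification (they are at best weakly identified and at
#' worst collinear), and every drop is logged.
#'
#' @param spec A [model_spec()] with covariate interactions.
#' @param pooled A [pooled_data()].
#' @param min_children,min_measurements Support thresholds; set both to 0
#'   to keep everything.
#' @return List with `spec` (reduced [model_spec()]) and `log` (data frame
#'   of all level-by-column support counts with a `dropped` flag).
#' @export
prune_unsupported_interactions <- function(spec, pooled, min_children = 30,
                                           min_measurements = 100) {
  stopifnot(inherits(spec, "model_spec"), inherits(pooled, "pooled_data"))
  # NA-tolerant frame: support for a variable is counted over the rows
  # where that variable is observed
  df <- merge(pooled$measurements,
              pooled$children[, c("child_id", spec$covariates),
                              drop = FALSE],
              by = "child_id", sort = FALSE)
  df <- df[order(df$child_id, df$age), , drop = FALSE]
  B <- basis_matrix(df$age, spec$trajectory)
  traj_names <- colnames(B)
  knots <- spec$trajectory$knots
  rowsupport <- function(col_idx) {
    nm <- traj_names[col_idx]
    if (spec$trajectory$family == "RCS" && grepl("^rcs\\.", nm)) {
      j <- as.integer(sub("^rcs\\.", "", nm))
      df$age > knots[j]
    } else rep(TRUE, nrow(df))
  }
  logs <- list()
  drops <- list()
  vars <- spec$covariates[spec$interactions[seq_along(spec$covariates)]]
  # cohort-by-trajectory interactions are subject to the same support rule:
  # a spline column whose knot exceeds a cohort's age window is identically
  # zero there
  if (spec$cohort_as_fixed) vars <- c("cohort", vars)
  for (cv in vars) {
    obs <- !is.na(df[[cv]])
    levs <- sort(unique(df[[cv]][obs]))
    for (lev in levs[-1]) {
      in_lev <- obs & df[[cv]] == lev
      for (j in seq_along(traj_names)) {
        supp <- in_lev & rowsupport(j)
        n_meas <- sum(supp)
        n_kids <- length(unique(df$child_id[supp]))
        dropped <- n_kids < min_children || n_meas < min_measurements
        logs[[length(logs) + 1L]] <- data.frame(
          covariate = cv, level = lev, column = traj_names[j],
          n_children = n_kids, n_measurements = n_meas, dropped = dropped)
        if (dropped)
          drops[[length(drops) + 1L]] <- data.frame(
            covariate = cv, level = lev, column = traj_names[j])
      }
    }
  }
  log_tab <- if (length(logs)) do.call(rbind, logs) else
    data.frame(covariate = character(), level = character(),
               column = character(), n_children = integer(),
               n_measurements = integer(), dropped = logical())
  drop_tab <- if (length(drops)) do.call(rbind, drops) else NULL
  spec$dropped_interactions <- if (is.null(drop_tab))
    spec$dropped_interactions else
    unique(rbind(spec$dropped_interactions, drop_tab))

  # rank sweep: interaction columns can be aliased even with support
  # (e.g. spline columns whose knots all precede a cohort's age window
  # coincide with an affine function of age there); drop aliased
  # interaction columns so downstream fits have a full-rank design
  dfr <- df
  for (cv in spec$covariates) {
    miss <- is.na(dfr[[cv]])
    if (any(miss)) {
      ref <- sort(unique(dfr[[cv]][!miss]))[1]
      dfr[[cv]][miss] <- ref
    }
  }
  xlev <- design_levels(dfr, spec)
  X <- build_design(dfr, spec, xlev)$X
  aliased <- aliased_columns(X)
  for (nm in aliased) {
    parts <- regmatches(nm, regexpr(":", nm), invert = TRUE)[[1]]
    if (length(parts) != 2 || !grepl("=", parts[1]))
      stop("design is rank-deficient in non-interaction column ", nm,
           call. = FALSE)
    ve <- strsplit(parts[1], "=", fixed = TRUE)[[1]]
    row <- data.frame(covariate = ve[1],
                      level = paste(ve[-1], collapse = "="),
                      column = parts[2])
    spec$dropped_interactions <- unique(rbind(spec$dropped_interactions,
                                              row))
    log_tab <- rbind(log_tab,
                     data.frame(covariate = row$covariate,
                                level = row$level, column = row$column,
                                n_children = NA_integer_,
                                n_measurements = NA_integer_,
                                dropped = TRUE))
  }
  list(spec = spec, log = log_tab)
}

# Columns of X made redundant by the preceding columns.  LINPACK qr on the
# unit-scaled normal equations pivots only columns judged dependent, so
# earlier (main-effect) columns are preferred over later (interaction)
# columns.
aliased_columns <- function(X, tol = 1e-7) {
  sc <- sqrt(colSums(X^2))
  zero <- sc == 0
  keep <- which(!zero)
  Xn <- sweep(X[, keep, drop = FALSE], 2, sc[keep], "/")
  qrC <- qr(crossprod(Xn), tol = tol)
  out <- colnames(X)[zero]
  if (qrC$rank < ncol(Xn))
    out <- c(out, colnames(Xn)[qrC$pivot[(qrC$rank + 1):ncol(Xn)]])
  out
}
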