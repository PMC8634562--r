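#' Level-1 (measurement-level) variance structure
#'
#' Complex level-1 variation: the measurement-level residual variance is
#' allowed to change with age, either as independent random intercepts for
#' distinct age segments (constant variance within each band, all pairwise
#' covariances fixed at 0) or as independent intercept and linear-age
#' measurement-level random effects, giving variance
#' \eqn{\sigma_0^2 + \sigma_1^2 \, age^2}.
#'
#' @param kind `"segmented"` or `"age_linear"`.
#' @param cuts For `"segmented"`: strictly increasing age cut-points in
#'   years; the default single cut at 2 years gives bands `<= 2` and `> 2`.
#'   Use `numeric(0)` for a single homoscedastic band.
#' @return An object of class `level1_spec`.
#' @export
level1_spec <- function(kind = c("segmented", "age_linear"), cuts = 2) {
  kind <- match.arg(kind)
  if (kind == "segmented") {
    cuts <- as.numeric(cuts)
    if (length(cuts) && any(diff(cuts) <= 0))
      stop("cuts must be strictly increasing", call. = FALSE)
  } else cuts <- NULL
  structure(list(kind = kind, cuts = cuts), class = "level1_spec")
}

#' @export
format.level1_spec <- function(x, ...) {
  if (x$kind == "segmented") {
    if (!length(x$cuts)) "level-1: single band" else
      sprintf("level-1: segmented at %s years",
              paste(x$cuts, collapse = ", "))
  } else "level-1: sigma0^2 + sigma1^2 * age^2"
}

#' @export
print.level1_spec <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Growth model specification
#'
#' Full description of the two-level growth model: the trajectory basis,
#' the child-level covariates entering the fixed effects (each optionally
#' interacted with every trajectory column), cohort fixed effects with
#' cohort-by-trajectory interactions, the unstructured individual-level
#' random effects (intercept plus all trajectory columns), and the level-1
#' variance structure.
#'
#' @param trajectory A [basis_spec()].
#' @param covariates Character vector of child-table covariate names
#'   included as fixed effects.
#' @param interactions Logical scalar or vector (one per covariate):
#'   whether the covariate is interacted with the trajectory columns.
#' @param cohort_as_fixed Include cohort dummies and cohort-by-trajectory
#'   interactions, so each cohort has its own average trajectory.
#' @param level1 A [level1_spec()].
#' @param random_trajectory If `TRUE` (default), the individual-level
#'   random effects comprise the intercept and every trajectory column
#'   (unstructured covariance); `FALSE` keeps only a random intercept.
#' @param dropped_interactions Optional data frame with columns
#'   `covariate`, `level`, `column` naming covariate-level-by-trajectory
#'   interaction terms to omit (see
#'   [prune_unsupported_interactions()]).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(trajectory, covariates = character(),
                       interactions = TRUE, cohort_as_fixed = TRUE,
                       level1 = level1_spec("segmented", cuts = 2),
                       random_trajectory = TRUE,
                       dropped_interactions = NULL) {
  stopifnot(inherits(trajectory, "basis_spec"), inherits(level1, "level1_spec"))
  interactions <- rep_len(as.logical(interactions),
                          max(1L, length(covariates)))
  structure(list(trajectory = trajectory, covariates = covariates,
                 interactions = interactions,
                 cohort_as_fixed = cohort_as_fixed, level1 = level1,
                 random_trajectory = isTRUE(random_trajectory),
                 dropped_interactions = dropped_interactions),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Growth model specification\n")
  cat("  trajectory: ", format(x$trajectory), "\n", sep = "")
  cat("  covariates: ",
      if (length(x$covariates))
        paste0(x$covariates,
               ifelse(x$interactions, " (x trajectory)", ""),
               collapse = ", ") else "none", "\n", sep = "")
  cat("  cohort fixed effects: ", if (x$cohort_as_fixed)
        "yes (with trajectory interactions)" else "no", "\n", sep = "")
  cat("  ", format(x$level1), "\n", sep = "")
  nd <- NROW(x$dropped_interactions)
  if (nd) cat("  pruned interactions: ", nd, "\n", sep = "")
  invisible(x)
}

# Merge covariates onto measurements and check completeness of the
# covariates the spec uses.
assemble_analysis_frame <- function(pooled, spec) {
  stopifnot(inherits(pooled, "pooled_data"), inherits(spec, "model_spec"))
  need <- spec$covariates
  missing_cols <- setdiff(need, names(pooled$children))
  if (length(missing_cols))
    stop("covariates not in child table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- merge(pooled$measurements,
              pooled$children[, c("child_id", need), drop = FALSE],
              by = "child_id", sort = FALSE)
  if (length(need)) {
    bad <- rowSums(is.na(df[, need, drop = FALSE])) > 0
    if (any(bad))
      stop(sprintf(paste("%d measurement rows have missing covariates;",
                         "complete them first (complete_covariate_filter",
                         "or multiple imputation)"), sum(bad)),
           call. = FALSE)
  }
  df <- df[order(df$child_id, df$age), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Factor levels used by the design, recorded at fit time so predictions
# use identical coding.
design_levels <- function(df, spec) {
  xlev <- list()
  if (spec$cohort_as_fixed) xlev$cohort <- sort(unique(df$cohort))
  for (cv in spec$covariates) xlev[[cv]] <- sort(unique(df[[cv]]))
  xlev
}

# Build fixed (X) and random (Z) design matrices for rows of `df`
# (needs columns age, cohort and the spec covariates).  Treatment coding,
# first level as reference.  Interaction columns named
# "<var>=<level>:<trajectory column>".
build_design <- function(df, spec, xlev) {
  B <- basis_matrix(df$age, spec$trajectory)
  traj_names <- colnames(B)
  X <- cbind("(Intercept)" = rep(1, nrow(df)), B)
  Z <- if (isTRUE(spec$random_trajectory) || is.null(spec$random_trajectory))
    X else X[, 1, drop = FALSE]
  dropped <- spec$dropped_interactions
  add_factor <- function(X, var, interact) {
    levs <- xlev[[var]]
    vals <- as.character(df[[var]])
    unseen <- setdiff(unique(vals), levs)
    if (length(unseen))
      stop("level(s) of ", var, " not present at fit time: ",
           paste(unseen, collapse = ", "), call. = FALSE)
    for (lev in levs[-1]) {
      ind <- as.numeric(vals == lev)
      main <- matrix(ind, ncol = 1,
                     dimnames = list(NULL, paste0(var, "=", lev)))
      X <- cbind(X, main)
      if (interact) {
        for (j in seq_along(traj_names)) {
          if (!is.null(dropped) &&
              any(dropped$covariate == var & dropped$level == lev &
                  dropped$column == traj_names[j])) next
          cc <- matrix(ind * B[, j], ncol = 1,
                       dimnames = list(NULL, paste0(var, "=", lev, ":",
                                                    traj_names[j])))
          X <- cbind(X, cc)
        }
      }
    }
    X
  }
  if (spec$cohort_as_fixed && length(xlev$cohort) > 1)
    X <- add_factor(X, "cohort", interact = TRUE)
  for (i in seq_along(spec$covariates))
    X <- add_factor(X, spec$covariates[i], spec$interactions[i])
  list(X = X, Z = Z, traj_names = traj_names)
}
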