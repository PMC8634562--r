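#' Fractional-polynomial power set
#'
#' The conventional power set used for fractional-polynomial growth curves:
#' \eqn{-2, -1, 0, 0.5, 1, 2, 3}, where power 0 denotes the natural
#' logarithm.
#'
#' @return Numeric vector of the seven powers.
#' @export
fp_power_set <- function() c(-2, -1, 0, 0.5, 1, 2, 3)

#' Trajectory basis specification
#'
#' Describes a nonlinear transformation of age used as the trajectory part
#' of the growth model: either a fractional polynomial (FP) of degree 1 or 2,
#' or a restricted cubic spline (RCS) with 3--7 knots.
#'
#' @param family `"FP"` or `"RCS"`.
#' @param powers For FP: numeric vector of length 1 or 2 drawn from
#'   [fp_power_set()]. Repeated powers are allowed and follow the usual
#'   convention (the second copy of power `p` contributes
#'   \eqn{t^p \log t}).
#' @param knots For RCS: strictly increasing numeric vector of 3--7 knot
#'   ages in years.
#' @param age_shift Non-negative offset added to age before applying FP
#'   power transforms, so that non-positive powers and logarithms are
#'   defined at age 0. Defaults to 1 year whenever `powers` contains a
#'   non-positive power or a repeat, otherwise 0. Ignored for RCS.
#'
#' @return An object of class `basis_spec`.
#' @export
basis_spec <- function(family = c("FP", "RCS"), powers = NULL, knots = NULL,
                       age_shift = NULL) {
  family <- match.arg(family)
  if (family == "FP") {
    if (is.null(powers) || !length(powers) %in% c(1L, 2L))
      stop("FP basis requires 1 or 2 powers", call. = FALSE)
    if (!all(powers %in% fp_power_set()))
      stop("FP powers must come from fp_power_set()", call. = FALSE)
    powers <- sort(powers)
    needs_shift <- any(powers <= 0) || anyDuplicated(powers) > 0
    if (is.null(age_shift)) age_shift <- if (needs_shift) 1 else 0
    if (age_shift < 0) stop("age_shift must be non-negative", call. = FALSE)
    if (needs_shift && age_shift == 0)
      warning("age_shift = 0 with non-positive or repeated powers fails at age 0")
    knots <- NULL
  } else {
    if (is.null(knots) || length(knots) < 3L || length(knots) > 7L)
      stop("RCS basis requires 3 to 7 knots", call. = FALSE)
    if (any(diff(knots) <= 0))
      stop("RCS knots must be strictly increasing", call. = FALSE)
    powers <- NULL
    age_shift <- 0
  }
  structure(list(family = family, powers = powers, knots = knots,
                 age_shift = age_shift),
            class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.basis_spec <- function(x, ...) {
  if (x$family == "FP") {
    sprintf("FP(%s)%s", paste(x$powers, collapse = ", "),
            if (x$age_shift != 0) sprintf(" [age + %g]", x$age_shift) else "")
  } else {
    sprintf("RCS(%d knots: %s)", length(x$knots),
            paste(signif(x$knots, 4), collapse = ", "))
  }
}

#' Fractional-polynomial design columns
#'
#' Evaluates the FP transform of age for each power in the specification.
#' With transformed age \eqn{t = age + shift}, power \eqn{p} contributes
#' \eqn{t^p}, power 0 contributes \eqn{\log t}, and a repeated power
#' \eqn{(p, p)} contributes \eqn{(t^p, t^p \log t)}.
#'
#' @param ages Numeric vector of ages in years.
#' @param spec A `basis_spec` with `family = "FP"`.
#' @return Numeric matrix with one column per FP term.
#' @export
fp_basis <- function(ages, spec) {
  stopifnot(inherits(spec, "basis_spec"), spec$family == "FP")
  t <- ages + spec$age_shift
  if (any(t <= 0) && (any(spec$powers <= 0) || anyDuplicated(spec$powers) > 0))
    stop("non-positive transformed age with non-positive or repeated powers",
         call. = FALSE)
  p <- spec$powers
  one <- function(pow) if (pow == 0) log(t) else t^pow
  if (length(p) == 1L) {
    out <- cbind(one(p[1]))
    colnames(out) <- fp_label(p[1])
  } else if (p[1] == p[2]) {
    first <- one(p[1])
    out <- cbind(first, first * log(t))
    colnames(out) <- c(fp_label(p[1]), paste0(fp_label(p[1]), ".logt"))
  } else {
    out <- cbind(one(p[1]), one(p[2]))
    colnames(out) <- c(fp_label(p[1]), fp_label(p[2]))
  }
  out
}

fp_label <- function(pow) {
  if (pow == 0) "fp.log" else paste0("fp.", gsub("-", "m", format(pow)))
}

#' Enumerate fractional-polynomial candidate specifications
#'
#' All degree-1 specifications (one per power) plus all unordered degree-2
#' pairs including repeats. With the default 7-power set this yields
#' \eqn{7 + \binom{7}{2} + 7 = 35} candidates, in a deterministic canonical
#' order (degree 1 first, then pairs in lexicographic power order).
#'
#' @param max_degree 1 or 2.
#' @param powers Power set; defaults to [fp_power_set()].
#' @return List of `basis_spec` objects.
#' @export
enumerate_fp_candidates <- function(max_degree = 2, powers = fp_power_set()) {
  stopifnot(max_degree %in% c(1, 2))
  out <- lapply(powers, function(p) basis_spec("FP", powers = p))
  if (max_degree == 2) {
    for (i in seq_along(powers))
      for (j in i:length(powers))
        out[[length(out) + 1L]] <- basis_spec("FP", powers = c(powers[i], powers[j]))
  }
  out
}

#' Percentile knot placement for restricted cubic splines
#'
#' Places `n_knots` knots at Harrell's recommended percentiles of the
#' observed age distribution, so that each inter-knot segment contains an
#' adequate share of the measurements.
#'
#' @param ages Numeric vector of measurement ages.
#' @param n_knots Integer between 3 and 7.
#' @return Strictly increasing numeric vector of knot ages.
#' @export
rcs_knots <- function(ages, n_knots) {
  if (!(n_knots %in% 3:7))
    stop("n_knots must be between 3 and 7", call. = FALSE)
  pct <- switch(as.character(n_knots),
    "3" = c(10, 50, 90),
    "4" = c(5, 35, 65, 95),
    "5" = c(5, 27.5, 50, 72.5, 95),
    "6" = c(5, 23, 41, 59, 77, 95),
    "7" = c(2.5, 18.33, 34.17, 50, 65.83, 81.67, 97.5))
  if (length(unique(ages)) < n_knots)
    stop("need at least n_knots distinct age values", call. = FALSE)
  k <- unname(stats::quantile(ages, probs = pct / 100, type = 7))
  if (any(diff(k) <= 0))
    stop(paste("tied percentile knots (heavily discrete ages);",
               "supply explicit knots instead"), call. = FALSE)
  k
}

#' Restricted cubic spline design columns
#'
#' Builds the restricted truncated-power basis for a cubic spline that is
#' constrained to be linear before the first and after the last knot.
#' Column 1 is age itself; nonlinear column \eqn{j} (for knot \eqn{k_j},
#' \eqn{j = 1, \dots, K-2}) is
#' \deqn{C_j(x) = \frac{(x-k_j)_+^3
#'   - (x-k_{K-1})_+^3 (k_K-k_j)/(k_K-k_{K-1})
#'   + (x-k_K)_+^3 (k_{K-1}-k_j)/(k_K-k_{K-1})}{(k_K-k_1)^2},}
#' the normalization keeping coefficients on comparable scales.
#'
#' @param ages Numeric vector of ages.
#' @param knots Strictly increasing numeric vector, length \eqn{K \ge 3}.
#' @return Numeric matrix with \eqn{K - 1} named columns.
#' @export
rcs_basis <- function(ages, knots) {
  K <- length(knots)
  if (K < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0)) stop("knots must be strictly increasing", call. = FALSE)
  kK <- knots[K]; kK1 <- knots[K - 1L]; norm <- (kK - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(ages), K - 1L)
  out[, 1] <- ages
  for (j in seq_len(K - 2L)) {
    kj <- knots[j]
    out[, j + 1L] <- (pos3(ages - kj) -
      pos3(ages - kK1) * (kK - kj) / (kK - kK1) +
      pos3(ages - kK) * (kK1 - kj) / (kK - kK1)) / norm
  }
  colnames(out) <- c("age", paste0("rcs.", seq_len(K - 2L)))
  out
}

#' Evaluate a trajectory basis
#'
#' Dispatches to [fp_basis()] or [rcs_basis()] according to the family of
#' the specification.
#'
#' @inheritParams fp_basis
#' @param spec A `basis_spec`.
#' @return Numeric design matrix (without intercept).
#' @export
basis_matrix <- function(ages, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (spec$family == "FP") fp_basis(ages, spec) else rcs_basis(ages, spec$knots)
}

#' Enumerate restricted-cubic-spline candidates
#'
#' One candidate per knot count in `n_knots`, with knots placed on the
#' supplied measurement ages by [rcs_knots()]. Knot counts whose percentile
#' knots are tied on these ages are skipped with a warning.
#'
#' @param ages Measurement ages used for percentile placement.
#' @param n_knots Integer vector of knot counts, each in 3--7.
#' @return List of `basis_spec` objects.
#' @export
enumerate_rcs_candidates <- function(ages, n_knots = 3:7) {
  out <- list()
  for (k in n_knots) {
    kn <- tryCatch(rcs_knots(ages, k), error = function(e) e)
    if (inherits(kn, "error")) {
      warning(sprintf("skipping RCS with %d knots: %s", k, conditionMessage(kn)))
      next
    }
    out[[length(out) + 1L]] <- basis_spec("RCS", knots = kn)
  }
  out
}
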