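#' End-to-end pooled trajectory analysis
#'
#' Orchestrates the full analysis as one reproducible run: load (or
#' synthesize) the pooled data, audit the pooling, two-stage trajectory and
#' covariance selection, covariate inclusion with interaction pruning,
#' multiple imputation of incomplete covariates (skipped automatically when
#' the covariates are complete), the final pooled fit, and predicted mean
#' trajectories for requested covariate patterns. Every stage writes a
#' plain-text artifact into the run directory and a manifest records their
#' checksums, so a rerun with the same configuration is verifiably
#' identical for all deterministic stages.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{input_dir / synthetic}{exactly one of: a directory holding
#'       `measurements.csv` + `children.csv`, or a list
#'       `list(n_children = <5 sizes>)` for [default_cohort_profiles()] +
#'       [default_truth()] generation.}
#'     \item{covariates}{child-level covariates for the final model
#'       (default `c("sex", "ethnicity", "maternal_education")`).}
#'     \item{selection}{list passed to [selection_config()]
#'       (`n_select`, `criterion`, `top_k_per_family`).}
#'     \item{mi}{list passed to [mi_config()] (`M`, `n_cycles`).}
#'     \item{prediction}{list with `ages` and `patterns` (list of named
#'       lists).}
#'     \item{out_dir}{run directory.}
#'     \item{seed}{master seed feeding every stochastic stage.}
#'   }
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir required", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 1L
  has_input <- !is.null(config$input_dir)
  has_syn <- !is.null(config$synthetic)
  if (has_input == has_syn)
    stop("exactly one of config$input_dir or config$synthetic is required",
         call. = FALSE)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  put <- function(name, path) {
    artifacts[[name]] <<- path
    path
  }

  # -- data ----------------------------------------------------------------
  if (has_input) {
    pooled <- read_pooled_data(config$input_dir)
  } else {
    profs <- default_cohort_profiles(config$synthetic$n_children)
    truth <- config$synthetic$truth %||% default_truth()
    pooled <- generate_multi_cohort(profs, truth, seed = config$seed)
    write_synthetic(pooled, file.path(out, "data"))
    put("data", file.path(out, "data"))
  }

  # -- pooling audit -------------------------------------------------------
  per <- lapply(split(seq_len(nrow(pooled$children)),
                      pooled$children$cohort), function(i) i)
  audit <- data.frame(
    cohort = names(per),
    n_children = vapply(per, length, integer(1)),
    n_measurements = vapply(names(per), function(lab)
      sum(pooled$measurements$cohort == lab), integer(1)))
  audit <- rbind(audit,
                 data.frame(cohort = "TOTAL",
                            n_children = sum(audit$n_children),
                            n_measurements = sum(audit$n_measurements)))
  utils::write.csv(audit, put("audit", file.path(out, "pooling_audit.csv")),
                   row.names = FALSE)

  # -- model selection -----------------------------------------------------
  selcfg <- do.call(selection_config, utils::modifyList(
    list(n_select = max(2L, floor(nrow(pooled$children) * 0.75)),
         seed = config$seed),
    config$selection %||% list()))
  report <- select_trajectory(pooled, selcfg)
  utils::write.csv(report$candidates,
                   put("candidates", file.path(out, "stage1_candidates.csv")),
                   row.names = FALSE)
  utils::write.csv(report$stage2,
                   put("stage2", file.path(out, "stage2_candidates.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(winner = report$winner_label, family = report$winner_family,
         shortlist = report$shortlist,
         level1 = format(report$final_spec$level1)),
    put("selection", file.path(out, "selection_summary.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # -- covariates + pruning ------------------------------------------------
  covs <- config$covariates %||% c("sex", "ethnicity", "maternal_education")
  spec <- model_spec(report$winner, covariates = covs,
                     cohort_as_fixed = TRUE,
                     level1 = report$final_spec$level1)
  pr <- prune_unsupported_interactions(spec, pooled)
  spec <- pr$spec
  utils::write.csv(pr$log, put("pruning", file.path(out, "pruning_log.csv")),
                   row.names = FALSE)

  # -- fit (MI when covariates are incomplete) -----------------------------
  any_missing <- any(vapply(covs, function(cv)
    anyNA(pooled$children[[cv]]), logical(1)))
  if (any_missing) {
    micfg <- do.call(mi_config, utils::modifyList(
      list(seed = config$seed), config$mi %||% list()))
    res <- mi_analysis(pooled, spec, micfg)
    fit <- res$pooled_fit
    impdir <- file.path(out, "imputations")
    dir.create(impdir, showWarnings = FALSE)
    for (m in seq_along(res$completed)) {
      utils::write.csv(res$completed[[m]]$children,
                       file.path(impdir, sprintf("imputation_%02d.csv",
                                                 m)),
                       row.names = FALSE, na = "")
    }
    utils::write.csv(cbind(parameter = rownames(res$pooled$table),
                           res$pooled$table),
                     put("estimates", file.path(out, "pooled_estimates.csv")),
                     row.names = FALSE)
  } else {
    fit <- fit_growth_model(pooled, spec, method = "REML")
    est <- data.frame(parameter = names(fit$beta), estimate = fit$beta,
                      se = sqrt(diag(fit$beta_vcov)))
    utils::write.csv(est,
                     put("estimates", file.path(out, "pooled_estimates.csv")),
                     row.names = FALSE)
  }

  # -- predictions ---------------------------------------------------------
  pred_cfg <- config$prediction
  if (!is.null(pred_cfg)) {
    preds <- list()
    for (i in seq_along(pred_cfg$patterns)) {
      pat <- pred_cfg$patterns[[i]]
      pm <- predict_mean(fit, pat, pred_cfg$ages)
      pm$pattern <- paste(names(pat), unlist(pat), sep = "=",
                          collapse = "; ")
      preds[[i]] <- pm
    }
    utils::write.csv(do.call(rbind, preds),
                     put("predictions", file.path(out, "predictions.csv")),
                     row.names = FALSE)
  }

  # -- manifest ------------------------------------------------------------
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package = "growthpool",
    version = as.character(utils::packageVersion("growthpool")),
    seed = config$seed,
    covariates = covs,
    files = data.frame(file = sub(paste0("^", out, "/?"), "", files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts[["manifest"]] <- file.path(out, "manifest.json")
  invisible(unlist(artifacts))
}
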