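#' Harmonized covariate vocabularies
#'
#' The common category sets onto which cohort-specific variables are mapped:
#' sex, race/ethnicity, maternal education (years of schooling bands) and
#' paternal occupational class.
#'
#' @return Named list of character vectors.
#' @export
harmonized_vocabulary <- function() {
  list(
    sex = c("male", "female"),
    ethnicity = c("White European", "South Asian", "other"),
    maternal_education = c("left school 15-16", "left school 17-18",
                           "degree or higher"),
    paternal_occupation = c("professional/managerial", "intermediate",
                            "routine/unskilled")
  )
}

#' Raw-to-harmonized mapping table
#'
#' Describes how one cohort's raw categories for one variable map onto the
#' harmonized vocabulary. Raw values with no entry fall to `default`
#' (`"missing"` maps to `NA`). When `constant_fill` is set, every child is
#' assigned that harmonized value regardless of the raw data -- used for
#' cohorts that never recorded a variable but whose value can be assumed
#' (e.g. assigning White European ethnicity in ethnically homogeneous
#' historical cohorts).
#'
#' @param cohort Cohort label.
#' @param variable Harmonized variable name (one of
#'   `names(harmonized_vocabulary())`).
#' @param entries Named character vector: names are raw categories, values
#'   harmonized categories (or `"missing"`).
#' @param default Harmonized category, or `"missing"`, applied to unmapped
#'   raw values.
#' @param constant_fill Optional harmonized category applied to all children.
#' @return An object of class `mapping_table`.
#' @export
mapping_table <- function(cohort, variable, entries = character(),
                          default = "missing", constant_fill = NULL) {
  vocab <- harmonized_vocabulary()
  if (!variable %in% names(vocab))
    stop("unknown harmonized variable: ", variable, call. = FALSE)
  ok <- c(vocab[[variable]], "missing")
  if (length(entries)) {
    if (is.null(names(entries)) || anyDuplicated(names(entries)))
      stop("entries must be uniquely named by raw category", call. = FALSE)
    bad <- setdiff(unique(entries), ok)
    if (length(bad))
      stop("entries map to categories outside the harmonized vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!default %in% ok)
    stop("default outside the harmonized vocabulary", call. = FALSE)
  if (!is.null(constant_fill) && !constant_fill %in% vocab[[variable]])
    stop("constant_fill outside the harmonized vocabulary", call. = FALSE)
  structure(list(cohort = cohort, variable = variable, entries = entries,
                 default = default, constant_fill = constant_fill),
            class = "mapping_table")
}

#' Apply a mapping table to raw values
#'
#' Maps each raw value through the table's entries, falling back to the
#' table default for unmapped values; `"missing"` becomes `NA`. A warning
#' is emitted when more than 10% of non-missing raw values fall to the
#' default, since that usually signals an incomplete mapping. The counts of
#' raw values sent to each harmonized category are attached as attribute
#' `"mapping_counts"`.
#'
#' @param raw_values Character vector of raw categories (`NA` allowed).
#' @param table A `mapping_table`.
#' @return Character vector of harmonized categories with `NA` for missing.
#' @export
harmonize_variable <- function(raw_values, table) {
  stopifnot(inherits(table, "mapping_table"))
  raw_values <- as.character(raw_values)
  if (!is.null(table$constant_fill)) {
    out <- rep(table$constant_fill, length(raw_values))
  } else {
    out <- unname(table$entries[raw_values])
    unmapped <- is.na(out) & !is.na(raw_values) &
      !(raw_values %in% names(table$entries))
    out[unmapped] <- table$default
    n_raw <- sum(!is.na(raw_values))
    if (n_raw > 0 && sum(unmapped) > 0.10 * n_raw)
      warning(sprintf("%s/%s: %.1f%% of raw values fell to the default",
                      table$cohort, table$variable,
                      100 * sum(unmapped) / n_raw))
    out[out == "missing"] <- NA_character_
  }
  counts <- table(raw = raw_values, harmonized = out, useNA = "ifany")
  attr(out, "mapping_counts") <- counts
  out
}

#' Unit conversion for weight and age
#'
#' Converts weight to kilograms and age to years using exact definitional
#' factors (1 lb = 0.45359237 kg; 1 year = 365.25 days).
#'
#' @param value Non-negative finite numeric vector.
#' @param from One of `"g"`, `"kg"`, `"lb"`, `"days"`, `"weeks"`,
#'   `"months"`, `"years"`.
#' @return Numeric vector in kg (weight units) or years (time units).
#' @export
convert_units <- function(value, from = c("g", "kg", "lb", "days", "weeks",
                                          "months", "years")) {
  from <- match.arg(from)
  if (any(!is.finite(value)) || any(value < 0))
    stop("values must be finite and non-negative", call. = FALSE)
  switch(from,
         g = value / 1000,
         kg = value,
         lb = value * 0.45359237,
         days = value / 365.25,
         weeks = value * 7 / 365.25,
         months = value / 12,
         years = value)
}

#' Composite parental education/occupation variable
#'
#' Cross-classifies harmonized maternal education (3 levels) with harmonized
#' paternal occupation (3 levels) into a 9-level composite. The composite is
#' missing whenever either component is missing.
#'
#' @param maternal_education Character vector in the harmonized maternal
#'   education vocabulary (or `NA`).
#' @param paternal_occupation Character vector in the harmonized paternal
#'   occupation vocabulary (or `NA`).
#' @return Character vector of composite levels `"<education> x <occupation>"`.
#' @export
derive_parental_composite <- function(maternal_education, paternal_occupation) {
  vocab <- harmonized_vocabulary()
  chk <- function(x, nm) {
    bad <- !is.na(x) & !(x %in% vocab[[nm]])
    if (any(bad))
      stop("unharmonized ", nm, " category: ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  chk(maternal_education, "maternal_education")
  chk(paternal_occupation, "paternal_occupation")
  out <- paste(maternal_education, "x", paternal_occupation)
  out[is.na(maternal_education) | is.na(paternal_occupation)] <- NA_character_
  out
}

#' Pooled multi-cohort dataset container
#'
#' @param measurements Data frame with columns `child_id`, `cohort`,
#'   `age`, `weight`.
#' @param children Data frame with one row per child: `child_id`, `cohort`
#'   and harmonized covariate columns.
#' @return An object of class `pooled_data`.
#' @export
pooled_data <- function(measurements, children) {
  need_m <- c("child_id", "cohort", "age", "weight")
  if (!all(need_m %in% names(measurements)))
    stop("measurements must have columns ", paste(need_m, collapse = ", "),
         call. = FALSE)
  if (!all(c("child_id", "cohort") %in% names(children)))
    stop("children must have columns child_id, cohort", call. = FALSE)
  if (anyDuplicated(children$child_id))
    stop("duplicate child_id in child table", call. = FALSE)
  structure(list(measurements = as.data.frame(measurements),
                 children = as.data.frame(children)),
            class = "pooled_data")
}

#' @export
print.pooled_data <- function(x, ...) {
  tab <- table(x$children$cohort)
  cat(sprintf("Pooled dataset: %d children, %d measurements, %d cohorts\n",
              nrow(x$children), nrow(x$measurements), length(tab)))
  print(tab)
  invisible(x)
}

#' Pool harmonized cohort tables
#'
#' Concatenates per-cohort measurement and child tables into one pooled
#' dataset, qualifying child ids by cohort so they are globally unique, and
#' returns an audit of per-cohort and total counts.
#'
#' @param per_cohort_tables Named list (names = cohort labels); each element
#'   a list with components `measurements` (columns `child_id`, `age`,
#'   `weight`) and `children` (column `child_id` plus covariates).
#' @return List with components `pooled` (a [pooled_data()]) and `audit`
#'   (class `pooling_audit`: per-cohort and total child/measurement counts).
#' @export
pool_cohorts <- function(per_cohort_tables) {
  labels <- names(per_cohort_tables)
  if (is.null(labels) || anyDuplicated(labels))
    stop("per_cohort_tables must be uniquely named by cohort label",
         call. = FALSE)
  meas <- list(); kids <- list()
  audit <- data.frame(cohort = labels, n_children = NA_integer_,
                      n_measurements = NA_integer_)
  for (i in seq_along(labels)) {
    lab <- labels[i]
    tb <- per_cohort_tables[[i]]
    if (anyDuplicated(tb$children$child_id))
      stop("duplicate child ids within cohort ", lab, call. = FALSE)
    m <- as.data.frame(tb$measurements)
    k <- as.data.frame(tb$children)
    qualify <- function(id) {
      already <- startsWith(as.character(id), paste0(lab, "_"))
      ifelse(already, as.character(id), paste0(lab, "_", id))
    }
    m$child_id <- qualify(m$child_id)
    k$child_id <- qualify(k$child_id)
    m$cohort <- lab
    k$cohort <- lab
    audit$n_children[i] <- nrow(k)
    audit$n_measurements[i] <- nrow(m)
    meas[[i]] <- m[, c("child_id", "cohort",
                       setdiff(names(m), c("child_id", "cohort")))]
    kids[[i]] <- k[, c("child_id", "cohort",
                       setdiff(names(k), c("child_id", "cohort")))]
  }
  all_cols <- Reduce(union, lapply(kids, names))
  kids <- lapply(kids, function(k) {
    for (cl in setdiff(all_cols, names(k))) k[[cl]] <- NA_character_
    k[, all_cols]
  })
  pooled <- pooled_data(do.call(rbind, meas), do.call(rbind, kids))
  out_audit <- structure(
    list(per_cohort = audit,
         total_children = sum(audit$n_children),
         total_measurements = sum(audit$n_measurements)),
    class = "pooling_audit")
  list(pooled = pooled, audit = out_audit)
}

#' @export
print.pooling_audit <- function(x, ...) {
  cat("Pooling audit\n")
  print(x$per_cohort, row.names = FALSE)
  cat(sprintf("Total: %d children, %d measurements\n",
              x$total_children, x$total_measurements))
  invisible(x)
}

#' Complete-covariate restriction with discard report
#'
#' Restricts a pooled dataset to children with every listed covariate
#' observed -- the "complete covariate analysis" comparator -- and reports
#' how much data that discards, per cohort and overall (fraction to one
#' decimal place, as conventionally quoted).
#'
#' @param pooled A [pooled_data()].
#' @param covariates Character vector of child-table covariate names.
#' @return List with `subset` (a `pooled_data` of complete children) and
#'   `report` (class `discard_report`).
#' @export
complete_covariate_filter <- function(pooled, covariates) {
  stopifnot(inherits(pooled, "pooled_data"))
  missing_cov <- setdiff(covariates, names(pooled$children))
  if (length(missing_cov))
    stop("covariates not in child table: ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  kids <- pooled$children
  complete <- rowSums(is.na(kids[, covariates, drop = FALSE])) == 0
  by_cohort <- stats::aggregate(list(n_children = kids$child_id),
                                by = list(cohort = kids$cohort), FUN = length)
  disc <- stats::aggregate(list(n_discarded = !complete),
                           by = list(cohort = kids$cohort), FUN = sum)
  per_cohort <- merge(by_cohort, disc, by = "cohort")
  per_cohort$n_kept <- per_cohort$n_children - per_cohort$n_discarded
  keep_ids <- kids$child_id[complete]
  subset <- pooled_data(
    pooled$measurements[pooled$measurements$child_id %in% keep_ids, ,
                        drop = FALSE],
    kids[complete, , drop = FALSE])
  total <- nrow(kids)
  n_disc <- sum(!complete)
  report <- structure(
    list(per_cohort = per_cohort,
         covariates = covariates,
         total_children = total,
         total_discarded = n_disc,
         discard_fraction_pct = round(100 * n_disc / total, 1)),
    class = "discard_report")
  list(subset = subset, report = report)
}

#' @export
print.discard_report <- function(x, ...) {
  cat(sprintf("Complete-covariate filter on {%s}\n",
              paste(x$covariates, collapse = ", ")))
  print(x$per_cohort, row.names = FALSE)
  cat(sprintf("Discarded %d of %d children (%.1f%%)\n",
              x$total_discarded, x$total_children, x$discard_fraction_pct))
  invisible(x)
}

#' Write a pooled dataset to delimited text
#'
#' Writes `measurements.csv` and `children.csv` (comma-separated, header
#' row, UTF-8, empty string for missing values) into `dir`.
#'
#' @param pooled A [pooled_data()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_pooled_data <- function(pooled, dir) {
  stopifnot(inherits(pooled, "pooled_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(dir, "measurements.csv"),
             children = file.path(dir, "children.csv"))
  utils::write.csv(pooled$measurements, paths["measurements"],
                   row.names = FALSE, na = "")
  utils::write.csv(pooled$children, paths["children"], row.names = FALSE,
                   na = "")
  invisible(paths)
}

#' Read a pooled dataset from delimited text
#'
#' Counterpart of [write_pooled_data()]; empty strings are read as missing.
#'
#' @param dir Directory containing `measurements.csv` and `children.csv`.
#' @return A [pooled_data()].
#' @export
read_pooled_data <- function(dir) {
  m <- utils::read.csv(file.path(dir, "measurements.csv"),
                       na.strings = "", stringsAsFactors = FALSE)
  k <- utils::read.csv(file.path(dir, "children.csv"),
                       na.strings = "", stringsAsFactors = FALSE)
  pooled_data(m, k)
}

#' Shipped default mapping tables
#'
#' Raw-to-harmonized mappings reflecting the published harmonized
#' vocabularies for a five-cohort childhood weight pooling: ethnicity
#' recoding for the two cohorts that recorded it (with a constant
#' White European fill for the three that did not), schooling-age bands
#' for maternal education, and registrar-style occupational classes for
#' paternal occupation. Real deployments should treat these as templates
#' and supply their own tables; the mapping engine is driven entirely by
#' the table contents.
#'
#' @return Named list of [mapping_table()] objects
#'   (`"<cohort>.<variable>"`).
#' @export
default_mapping_tables <- function() {
  tabs <- list(
    mapping_table("ALSPAC", "ethnicity",
                  entries = c("White" = "White European"),
                  default = "other"),
    mapping_table("BiB", "ethnicity",
                  entries = c(Pakistani = "South Asian",
                              Indian = "South Asian",
                              Bangladeshi = "South Asian",
                              "White British" = "White European",
                              "White Other" = "White European"),
                  default = "other"),
    mapping_table("BCG", "ethnicity", constant_fill = "White European"),
    mapping_table("CHS", "ethnicity", constant_fill = "White European"),
    mapping_table("PROBIT", "ethnicity",
                  constant_fill = "White European"),
    mapping_table("ALSPAC", "maternal_education",
                  entries = c(CSE = "left school 15-16",
                              "O level" = "left school 15-16",
                              GCSE = "left school 15-16",
                              "A level" = "left school 17-18",
                              Degree = "degree or higher",
                              Postgraduate = "degree or higher")),
    mapping_table("BiB", "maternal_education",
                  entries = c("<5 GCSE" = "left school 15-16",
                              "5+ GCSE" = "left school 15-16",
                              "A level" = "left school 17-18",
                              "Higher than A level" = "degree or higher")),
    mapping_table("BCG", "paternal_occupation",
                  entries = c(I = "professional/managerial",
                              II = "professional/managerial",
                              III = "intermediate",
                              IV = "routine/unskilled",
                              V = "routine/unskilled",
                              other = "routine/unskilled")),
    mapping_table("CHS", "paternal_occupation",
                  entries = c(I = "professional/managerial",
                              II = "professional/managerial",
                              III = "intermediate",
                              IV = "routine/unskilled",
                              V = "routine/unskilled",
                              other = "routine/unskilled"))
  )
  stats::setNames(tabs, vapply(tabs, function(t)
    paste(t$cohort, t$variable, sep = "."), character(1)))
}

#' Write mapping tables as structured configuration
#'
#' One block per cohort-variable pair, JSON-encoded.
#'
#' @param tables List of [mapping_table()]s.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_mapping_tables <- function(tables, path) {
  ser <- lapply(unname(tables), function(t)
    list(cohort = t$cohort, variable = t$variable,
         entries = as.list(t$entries), default = t$default,
         constant_fill = t$constant_fill))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read mapping tables written by [write_mapping_tables()]
#'
#' @param path Configuration file.
#' @return Named list of [mapping_table()]s.
#' @export
read_mapping_tables <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  tabs <- lapply(ser, function(b)
    mapping_table(b$cohort, b$variable,
                  entries = unlist(b$entries) %||% character(),
                  default = b$default %||% "missing",
                  constant_fill = b$constant_fill))
  stats::setNames(tabs, vapply(tabs, function(t)
    paste(t$cohort, t$variable, sep = "."), character(1)))
}
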