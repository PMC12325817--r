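#' Construct a patient panel
#'
#' A patient panel is the person-level analysis table: one row per insured
#' person carrying the region of residence, the population-classification
#' group ("PopGroup") and its coarse macro group, demographic strata (age,
#' sex), and one column per outcome. Outcomes are declared as continuous
#' (non-negative costs in EUR/year, bed days, ...) or binary (0/1 indicators
#' such as hospitalization or mortality).
#'
#' @param data data.frame with at least the columns `person_id`, `region_id`,
#'   `popgroup_id`, `macro_popgroup_id`, `age`, `sex`, plus one column per
#'   declared outcome.
#' @param outcome_types named character vector mapping outcome column names to
#'   `"continuous"` or `"binary"`.
#' @return A `patient_panel`: a data.frame with the declared outcome typing
#'   attached as the `outcome_types` attribute. Row order is preserved.
#' @export
patient_panel <- function(data, outcome_types = character()) {
  stopifnot(is.data.frame(data))
  req <- c("person_id", "region_id", "popgroup_id", "macro_popgroup_id",
           "age", "sex")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L)
    stop("patient panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(outcome_types) > 0L) {
    if (is.null(names(outcome_types)) || any(names(outcome_types) == ""))
      stop("'outcome_types' must be a named vector", call. = FALSE)
    bad_type <- setdiff(outcome_types, c("continuous", "binary"))
    if (length(bad_type) > 0L)
      stop("unknown outcome type(s): ", paste(bad_type, collapse = ", "),
           call. = FALSE)
    absent <- setdiff(names(outcome_types), names(data))
    if (length(absent) > 0L)
      stop("declared outcome column(s) absent from data: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("person_id", "region_id", "popgroup_id", "macro_popgroup_id",
                "sex"))
    out[[col]] <- as.character(out[[col]])
  out$age <- as.integer(out$age)
  rownames(out) <- NULL
  attr(out, "outcome_types") <- outcome_types
  class(out) <- c("patient_panel", "data.frame")
  out
}

#' Outcome typing of a panel
#'
#' @param panel a `patient_panel`.
#' @return Named character vector of declared outcomes
#'   (`"continuous"`/`"binary"`).
#' @export
outcome_types <- function(panel) {
  attr(panel, "outcome_types")
}

#' @export
print.patient_panel <- function(x, ...) {
  ot <- outcome_types(x)
  cat(sprintf("patient_panel: %d persons, %d regions, %d PopGroups\n",
              nrow(x), length(unique(x$region_id)),
              length(unique(x$popgroup_id))))
  if (length(ot) > 0L)
    cat("outcomes: ",
        paste(sprintf("%s (%s)", names(ot), ot), collapse = ", "), "\n",
        sep = "")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L)
    cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Construct a PopGroup catalog
#'
#' The catalog lists every classification group with its macro group, its
#' severity score (a dimensionless index of relative complexity/severity),
#' and its share of the national study population.
#'
#' @param data data.frame with columns `popgroup_id`, `macro_popgroup_id`,
#'   `severity_score`, `national_share`.
#' @return A `popgroup_catalog` data.frame.
#' @export
popgroup_catalog <- function(data) {
  stopifnot(is.data.frame(data))
  req <- c("popgroup_id", "macro_popgroup_id", "severity_score",
           "national_share")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L)
    stop("catalog is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  out$popgroup_id <- as.character(out$popgroup_id)
  out$macro_popgroup_id <- as.character(out$macro_popgroup_id)
  if (anyDuplicated(out$popgroup_id))
    stop("duplicated popgroup_id in catalog", call. = FALSE)
  if (any(is.na(out$macro_popgroup_id) | out$macro_popgroup_id == ""))
    stop("macro mapping must be total: orphan PopGroups present",
         call. = FALSE)
  if (any(out$national_share < 0))
    stop("national_share must be non-negative", call. = FALSE)
  if (abs(sum(out$national_share) - 1) > 1e-9)
    stop(sprintf("national_share must sum to 1 (got %.12f)",
                 sum(out$national_share)), call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("popgroup_catalog", "data.frame")
  out
}

#' Construct a region covariate table
#'
#' One row per region with regional characteristics entering the multilevel
#' models as level-2 covariates: demographic factors (average population age,
#' population density), supply-side factors (GPs per 10,000, inpatient beds
#' per 1,000), urbanization, socioeconomic deprivation.
#'
#' @param data data.frame with a `region_id` column plus numeric covariates.
#' @return A `region_covariates` data.frame with one row per region.
#' @export
region_covariates <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"region_id" %in% names(data))
    stop("region covariate table needs a 'region_id' column", call. = FALSE)
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  out$region_id <- as.character(out$region_id)
  if (anyDuplicated(out$region_id))
    stop("region covariate table must have one row per region", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("region_covariates", "data.frame")
  out
}

.report_row <- function(severity, rule, message, n_rows) {
  data.frame(severity = severity, rule = rule, message = message,
             n_rows = as.integer(n_rows), stringsAsFactors = FALSE)
}

#' Validate a patient panel against its invariants
#'
#' Checks the structural invariants of the panel: unique person identifiers
#' (the classification is mutually exclusive), binary outcomes in {0,1},
#' continuous outcomes non-negative and finite, non-negative ages, and a
#' functional PopGroup-to-macro-group mapping. When a catalog is supplied the
#' panel's groups must exist in it and agree on the macro mapping.
#'
#' Validation never modifies the panel; the report is the entire payload.
#'
#' @param panel a `patient_panel`.
#' @param catalog optional `popgroup_catalog` to cross-check group membership.
#' @return A `validation_report`: data.frame with columns `severity`, `rule`,
#'   `message`, `n_rows`; zero rows iff all invariants hold.
#' @export
validate_panel <- function(panel, catalog = NULL) {
  stopifnot(inherits(panel, "patient_panel"))
  rep <- list()

  dup <- duplicated(panel$person_id) | duplicated(panel$person_id,
                                                  fromLast = TRUE)
  if (any(dup)) {
    ids <- unique(panel$person_id[dup])
    rep[[length(rep) + 1L]] <- .report_row(
      "error", "duplicate_person",
      sprintf("person_id not unique: %s",
              paste(utils::head(ids, 5L), collapse = ", ")),
      sum(dup))
  }

  if (any(!is.na(panel$age) & panel$age < 0))
    rep[[length(rep) + 1L]] <- .report_row(
      "error", "negative_age", "age must be >= 0",
      sum(panel$age < 0, na.rm = TRUE))

  ot <- outcome_types(panel)
  for (nm in names(ot)) {
    v <- panel[[nm]]
    if (ot[[nm]] == "binary") {
      bad <- !is.na(v) & !(v %in% c(0, 1))
      if (any(bad))
        rep[[length(rep) + 1L]] <- .report_row(
          "error", "binary_domain",
          sprintf("binary outcome '%s' has values outside {0,1}", nm),
          sum(bad))
    } else {
      bad <- !is.na(v) & (!is.finite(v) | v < 0)
      if (any(bad))
        rep[[length(rep) + 1L]] <- .report_row(
          "error", "continuous_domain",
          sprintf("continuous outcome '%s' has negative or non-finite values",
                  nm),
          sum(bad))
    }
  }

  # each PopGroup must map to exactly one macro group within the panel
  map <- unique(panel[, c("popgroup_id", "macro_popgroup_id")])
  multi <- map$popgroup_id[duplicated(map$popgroup_id)]
  if (length(multi) > 0L)
    rep[[length(rep) + 1L]] <- .report_row(
      "error", "macro_mapping",
      sprintf("PopGroup(s) mapped to several macro groups: %s",
              paste(unique(multi), collapse = ", ")),
      sum(panel$popgroup_id %in% multi))

  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "popgroup_catalog"))
    unknown <- setdiff(panel$popgroup_id, catalog$popgroup_id)
    if (length(unknown) > 0L)
      rep[[length(rep) + 1L]] <- .report_row(
        "error", "unknown_popgroup",
        sprintf("PopGroup(s) absent from catalog: %s",
                paste(unknown, collapse = ", ")),
        sum(panel$popgroup_id %in% unknown))
    cat_map <- stats::setNames(catalog$macro_popgroup_id, catalog$popgroup_id)
    known <- panel$popgroup_id %in% catalog$popgroup_id
    mismatch <- known & panel$macro_popgroup_id != cat_map[panel$popgroup_id]
    if (any(mismatch))
      rep[[length(rep) + 1L]] <- .report_row(
        "error", "macro_mismatch",
        "panel macro_popgroup_id disagrees with catalog mapping",
        sum(mismatch))
  }

  out <- if (length(rep) == 0L)
    .report_row("error", "none", "none", 0L)[0, ]
  else
    do.call(rbind, rep)
  rownames(out) <- NULL
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Does a validation report contain blocking errors?
#'
#' @param report a `validation_report`.
#' @return `TRUE` if any rule of severity `"error"` fired.
#' @export
has_errors <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  any(report$severity == "error")
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("validation_report: all invariants hold\n")
  } else {
    cat(sprintf("validation_report: %d violated rule(s)\n", nrow(x)))
    NextMethod()
  }
  invisible(x)
}
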