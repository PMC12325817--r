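#' Read a patient panel from a delimited text file
#'
#' Input is comma-separated UTF-8 text with a mandatory header row. A schema
#' mapping allows file columns to be renamed onto the canonical panel columns;
#' outcome columns are typed by `outcome_types`. Missing outcome values are
#' permitted at load (they are rejected at model/standardization entry per
#' outcome); malformed values raise row-level errors carrying the file line
#' number.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names (e.g. `person_id`) to the column names used in the file. Columns
#'   not mentioned are taken under their canonical name.
#' @param outcome_types named character vector, outcome name ->
#'   `"continuous"` or `"binary"`.
#' @return A [patient_panel()] with row order as in the file.
#' @seealso [write_patient_panel()], [read_schema_config()]
#' @export
read_patient_panel <- function(path, schema = NULL,
                               outcome_types = character()) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  req <- c("person_id", "region_id", "popgroup_id", "macro_popgroup_id",
           "age", "sex")
  wanted <- c(req, names(outcome_types))
  file_col <- stats::setNames(wanted, wanted)
  if (!is.null(schema)) {
    schema <- unlist(schema)
    file_col[names(schema)] <- schema
  }
  absent <- wanted[!file_col[wanted] %in% names(raw)]
  if (length(absent) > 0L)
    stop("schema error: column(s) not found in file: ",
         paste(sprintf("%s (file column '%s')", absent, file_col[absent]),
               collapse = ", "),
         call. = FALSE)

  df <- stats::setNames(raw[, file_col[wanted], drop = FALSE], wanted)
  df$age <- .parse_numeric_col(df$age, "age", integer = TRUE)
  for (nm in names(outcome_types)) {
    v <- .parse_numeric_col(df[[nm]], nm)
    if (outcome_types[[nm]] == "binary") {
      bad <- which(!is.na(v) & !(v %in% c(0, 1)))
      if (length(bad) > 0L)
        stop(sprintf(
          "binary outcome '%s' has value '%s' outside {0,1} at file line %d",
          nm, df[[nm]][bad[1L]], bad[1L] + 1L), call. = FALSE)
    }
    df[[nm]] <- v
  }
  patient_panel(df, outcome_types = outcome_types)
}

# numeric parser with row-level diagnostics; file line = row index + header
.parse_numeric_col <- function(x, name, integer = FALSE) {
  x[x == ""] <- NA_character_
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(v))
  if (length(bad) > 0L)
    stop(sprintf("unparseable value '%s' in column '%s' at file line %d",
                 x[bad[1L]], name, bad[1L] + 1L), call. = FALSE)
  if (integer) as.integer(v) else v
}

#' Write a patient panel to CSV
#'
#' Inverse of [read_patient_panel()]: a write/read round trip restores an
#' identical panel (given the same outcome typing).
#'
#' @param panel a `patient_panel`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_patient_panel <- function(panel, path) {
  stopifnot(inherits(panel, "patient_panel"))
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a region covariate table from CSV
#'
#' @param path path to a CSV with a `region_id` column and numeric covariate
#'   columns.
#' @return A [region_covariates()] table.
#' @export
read_region_covariates <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  region_covariates(utils::read.csv(path, check.names = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Write a region covariate table to CSV
#'
#' @param regions a `region_covariates` table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_region_covariates <- function(regions, path) {
  stopifnot(inherits(regions, "region_covariates"))
  utils::write.csv(as.data.frame(regions), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a schema/outcome configuration file
#'
#' The YAML config declares the column mapping and the outcome typing used by
#' [read_patient_panel()]:
#'
#' ```yaml
#' columns:
#'   person_id: pid
#'   region_id: kreis
#' outcomes:
#'   cost: continuous
#'   hospitalization: binary
#' ```
#'
#' @param path path to a YAML file.
#' @return List with elements `schema` (named character vector, possibly
#'   empty) and `outcome_types` (named character vector).
#' @export
read_schema_config <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  schema <- if (is.null(cfg$columns)) character() else unlist(cfg$columns)
  ot <- if (is.null(cfg$outcomes)) character() else unlist(cfg$outcomes)
  bad <- setdiff(ot, c("continuous", "binary"))
  if (length(bad) > 0L)
    stop("config declares unknown outcome type(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  list(schema = schema, outcome_types = ot)
}
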