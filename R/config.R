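#' Package configuration: vocabularies, parameter dictionary, thresholds
#'
#' All controlled vocabularies used by the validation checks and QC engine are
#' held in a configuration list so the tool can be adapted to any monitoring
#' program: valid activity types (WQX naming) and their roles, relative depth
#' names, depth units, the parameter dictionary (allowed units per parameter,
#' which parameters may be negative, which are log-distributed), qualifier
#' values counted against completeness, and the threshold overlay table for
#' plots. `qc_config()` returns the defaults, optionally overridden from a
#' YAML file or by named arguments.
#'
#' @param path optional path to a YAML file with entries to override; unnamed
#'   entries are ignored.
#' @param ... named overrides applied after the file, e.g.
#'   `depth_warn_m = 2`.
#'
#' @return A list of class `aqc_config` with elements `activity_types`
#'   (named character vector mapping activity type to role), `relative_depth_names`,
#'   `depth_units`, `depth_warn_m` (depth above which a warning is raised, metres),
#'   `parameters` (tibble: Parameter, Units, `Negative Ok`), `qualifier_attributes`
#'   (Result Attribute values counted as qualified samples),
#'   `frequency_excludes_qualified` (logical), `spreadsheet_rows` (logical: add
#'   header offset to reported row numbers), and `thresholds` (tibble with
#'   Parameter, Context, Label, Value, Unit, Source).
#'
#' @details Activity-type roles drive the whole QC engine: `regular_field` and
#'   `regular_lab` mark routine monitoring records; `field_blank`, `lab_blank`,
#'   `field_dup`, `lab_dup`, `spike`, and `instrument_check` mark the QC sample
#'   types. Calibration (instrument) checks are evaluated together with lab
#'   spikes, matching the five-column accuracy summary layout.
#'
#' @examples
#' cfg <- qc_config()
#' names(cfg$activity_types)
#' @export
qc_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    usr <- yaml::read_yaml(path)
    for (nm in intersect(names(usr), names(cfg))) {
      cfg[[nm]] <- config_coerce(nm, usr[[nm]])
    }
  }
  dots <- list(...)
  for (nm in intersect(names(dots), names(cfg))) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "aqc_config")
}

default_config <- function() {
  list(
    activity_types = c(
      "Field Msr/Obs"                            = "regular_field",
      "Sample-Routine"                           = "regular_lab",
      "Quality Control Sample-Field Blank"       = "field_blank",
      "Quality Control Sample-Lab Blank"         = "lab_blank",
      "Quality Control Sample-Field Duplicate"   = "field_dup",
      "Quality Control Sample-Lab Duplicate"     = "lab_dup",
      "Quality Control Sample-Lab Spike"         = "spike",
      "Quality Control-Calibration Check"        = "instrument_check"
    ),
    relative_depth_names = c("Surface", "Midwater", "Near Bottom", "Bottom"),
    depth_units = c("m", "ft"),
    depth_warn_m = 1,
    parameters = tibble::tibble(
      Parameter = c("DO", "Ammonia", "TP", "Nitrate", "pH",
                    "Sp Conductance", "E.coli", "Water Temp"),
      Units = c("mg/l", "mg/l", "mg/l", "mg/l", "s.u.",
                "uS/cm", "MPN/100ml", "deg C"),
      `Negative Ok` = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    qualifier_attributes = character(0),
    frequency_excludes_qualified = TRUE,
    spreadsheet_rows = FALSE,
    thresholds = tibble::tibble(
      Parameter = c("DO", "DO", "pH", "pH", "E.coli", "Water Temp"),
      Context   = c("fresh", "marine", "fresh", "fresh", "fresh", "fresh"),
      Label     = c("Aquatic life minimum", "Aquatic life minimum",
                    "Lower bound", "Upper bound",
                    "Recreational criterion", "Warmwater maximum"),
      Value     = c(5, 6, 6.5, 8.3, 126, 28.3),
      Unit      = c("mg/l", "mg/l", "s.u.", "s.u.", "MPN/100ml", "deg C"),
      Source    = c("USEPA example criteria", "USEPA example criteria",
                    "USEPA example criteria", "USEPA example criteria",
                    "USEPA 2012 RWQC", "Example state standard")
    )
  )
}

# coerce YAML-loaded entries back to package-native shapes
config_coerce <- function(name, value) {
  if (name %in% c("parameters", "thresholds")) {
    return(tibble::as_tibble(as.data.frame(value, check.names = FALSE,
                                           stringsAsFactors = FALSE)))
  }
  if (name == "activity_types") return(unlist(value))
  value
}

#' Write a configuration list to YAML
#'
#' @param config an `aqc_config` list from [qc_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$activity_types <- as.list(out$activity_types)
  out$parameters <- as.list(as.data.frame(out$parameters, check.names = FALSE))
  out$thresholds <- as.list(as.data.frame(out$thresholds, check.names = FALSE))
  yaml::write_yaml(out, path)
  invisible(path)
}

# results-file schema: fixed, ordered, exact (check 1 enforces exact names)
results_columns <- function() {
  c("Monitoring Location ID", "Activity Type", "Activity Start Date",
    "Activity Start Time", "Activity Depth/Height Measure",
    "Activity Depth/Height Unit", "Activity Relative Depth Name",
    "Characteristic Name", "Result Value", "QC Reference Value",
    "Result Unit", "Result Attribute")
}

accuracy_columns <- function() {
  c("Parameter", "MDL", "UQL", "Value Range", "Field Duplicate",
    "Lab Duplicate", "Field Blank", "Lab Blank", "Spike/Check Accuracy")
}

frecom_columns <- function() {
  c("Parameter", "Field Duplicate", "Lab Duplicate", "Field Blank",
    "Lab Blank", "Spike/Check Accuracy", "% Completeness")
}

sites_columns <- function() {
  c("Monitoring Location ID", "Monitoring Location Latitude",
    "Monitoring Location Longitude", "Location Group")
}

# the five accuracy check types, in summary-table order, with the role(s)
# of the activity types that feed each
check_types <- function() {
  list(
    "Field Duplicates" = "field_dup",
    "Lab Duplicates"   = "lab_dup",
    "Field Blanks"     = "field_blank",
    "Lab Blanks"       = "lab_blank",
    "Lab Spikes / Instrument Checks" = c("spike", "instrument_check")
  )
}

# accuracy-file column holding the criterion for each check type
criterion_column <- function(check_type) {
  c("Field Duplicates" = "Field Duplicate",
    "Lab Duplicates"   = "Lab Duplicate",
    "Field Blanks"     = "Field Blank",
    "Lab Blanks"       = "Lab Blank",
    "Lab Spikes / Instrument Checks" = "Spike/Check Accuracy")[[check_type]]
}

# frequency-file column per check type
frecom_column <- function(check_type) {
  c("Field Duplicates" = "Field Duplicate",
    "Lab Duplicates"   = "Lab Duplicate",
    "Field Blanks"     = "Field Blank",
    "Lab Blanks"       = "Lab Blank",
    "Lab Spikes / Instrument Checks" = "Spike/Check Accuracy")[[check_type]]
}
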