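# WQX submission workbook: three sheets (Project, Locations, Results)
# populated from the input bundle; row-level verification stays with the
# user before upload.

# default column set for the Results sheet, following the USEPA
# physical/chemical results template; held in config so template revisions
# don't require code changes
wqx_defaults <- function() {
  list(
    time_zone = "UTC",
    project_id = "project1",
    project_name = "",
    project_description = "",
    sample_collection_method_id = "",
    sample_collection_method_context = "",
    results_columns = c(
      "Activity ID", "Monitoring Location ID", "Activity Type",
      "Activity Media Name", "Activity Start Date", "Activity Start Time",
      "Activity Start Time Zone", "Activity Depth/Height Measure",
      "Activity Depth/Height Unit", "Activity Relative Depth Name",
      "Sample Collection Method ID", "Sample Collection Method Context",
      "Characteristic Name", "Result Value", "Result Unit",
      "Result Sample Fraction", "Result Analytical Method ID",
      "Result Analytical Method Context", "Result Detection Condition",
      "Result Detection/Quantitation Limit Type",
      "Result Detection/Quantitation Limit Measure",
      "Result Detection/Quantitation Limit Unit", "Result Comment")
  )
}

wqx_project_sheet <- function(wcfg) {
  tibble::tibble(
    `Project ID` = wcfg$project_id,
    `Project Name` = wcfg$project_name,
    `Project Description` = wcfg$project_description)
}

wqx_locations_sheet <- function(sites) {
  tibble::tibble(
    `Monitoring Location ID` = as_chr(sites[["Monitoring Location ID"]]),
    `Monitoring Location Name` = as_chr(sites[["Monitoring Location ID"]]),
    `Monitoring Location Latitude` = as_chr(sites[["Monitoring Location Latitude"]]),
    `Monitoring Location Longitude` = as_chr(sites[["Monitoring Location Longitude"]]),
    `Monitoring Location Type` = "",
    `Horizontal Coordinate Reference System` = "WGS84")
}

# detection-condition text for censored results (WQX convention: the value
# cell stays blank, the condition and the limit are reported instead)
wqx_censor_fields <- function(raw, rule) {
  tok <- toupper(as_chr(raw))
  if (tok == "BDL")
    return(list(value = "", cond = "Not Detected",
                lim_type = "Method Detection Level",
                lim = if (is.null(rule)) "" else as_chr(rule$MDL[1])))
  if (tok == "AQL")
    return(list(value = "", cond = "Present Above Quantification Limit",
                lim_type = "Upper Quantitation Limit",
                lim = if (is.null(rule)) "" else as_chr(rule$UQL[1])))
  list(value = as_chr(raw), cond = "", lim_type = "", lim = "")
}

wqx_results_rows <- function(bundle, wcfg) {
  results <- bundle$results
  config <- bundle$config
  roles <- record_roles(results, config)
  meta <- bundle$wqx
  meta_for <- function(param, col) {
    if (is.null(meta) || !col %in% names(meta)) return("")
    v <- meta[[col]][match(param, meta$Parameter)]
    if (is.na(v)) "" else v
  }
  rows <- list()
  n_expanded <- 0L
  for (i in seq_len(nrow(results))) {
    rec <- results[i, ]
    param <- as_chr(rec[["Characteristic Name"]])
    site <- as_chr(rec[["Monitoring Location ID"]])
    atype <- as_chr(rec[["Activity Type"]])
    rule <- rule_for(bundle$accuracy, param, num_or_na(rec[["Result Value"]]))
    has_ref <- nzchar(as_chr(rec[["QC Reference Value"]]))
    is_dup_pair <- roles[i] %in% c("field_dup", "lab_dup") && has_ref
    is_hosted_pair <- roles[i] %in% c("regular_field", "regular_lab") && has_ref
    base <- function(value_raw, atype_out, suffix) {
      cf <- wqx_censor_fields(value_raw, rule)
      out <- setNames(as.list(rep("", length(wcfg$results_columns))),
                      wcfg$results_columns)
      out[["Activity ID"]] <- paste0(paste(c(site[nzchar(site)], "ACT"),
                                           collapse = "-"), "-",
                                     as_chr(rec[["Activity Start Date"]]), "-",
                                     i, suffix)
      out[["Monitoring Location ID"]] <- site
      out[["Activity Type"]] <- atype_out
      out[["Activity Media Name"]] <- "Water"
      out[["Activity Start Date"]] <- as_chr(rec[["Activity Start Date"]])
      out[["Activity Start Time"]] <- as_chr(rec[["Activity Start Time"]])
      out[["Activity Start Time Zone"]] <- wcfg$time_zone
      out[["Activity Depth/Height Measure"]] <- as_chr(rec[["Activity Depth/Height Measure"]])
      out[["Activity Depth/Height Unit"]] <- as_chr(rec[["Activity Depth/Height Unit"]])
      out[["Activity Relative Depth Name"]] <- as_chr(rec[["Activity Relative Depth Name"]])
      out[["Sample Collection Method ID"]] <- wcfg$sample_collection_method_id
      out[["Sample Collection Method Context"]] <- wcfg$sample_collection_method_context
      out[["Characteristic Name"]] <- param
      out[["Result Value"]] <- cf$value
      out[["Result Unit"]] <- if (nzchar(cf$value)) as_chr(rec[["Result Unit"]]) else ""
      out[["Result Sample Fraction"]] <- meta_for(param, "Sample Fraction")
      out[["Result Analytical Method ID"]] <- meta_for(param, "Analytical Method")
      out[["Result Analytical Method Context"]] <- meta_for(param, "Analytical Method Context")
      out[["Result Detection Condition"]] <- cf$cond
      out[["Result Detection/Quantitation Limit Type"]] <- if (nzchar(cf$cond)) cf$lim_type else ""
      out[["Result Detection/Quantitation Limit Measure"]] <- if (nzchar(cf$cond)) cf$lim else ""
      out[["Result Detection/Quantitation Limit Unit"]] <- if (nzchar(cf$cond)) as_chr(rec[["Result Unit"]]) else ""
      tibble::as_tibble(out)
    }
    if (is_dup_pair) {
      # same-row duplicate pairs expand to the WQX paired activity types
      rows[[length(rows) + 1]] <- base(rec[["Result Value"]],
                                       paste(atype, "1"), "-1")
      rows[[length(rows) + 1]] <- base(rec[["QC Reference Value"]],
                                       paste(atype, "2"), "-2")
      n_expanded <- n_expanded + 1L
    } else if (is_hosted_pair) {
      # a regular row hosting a pair keeps its own type; the paired value
      # exports as a duplicate activity of the matching kind
      dup_type <- if (roles[i] == "regular_field")
        "Quality Control Sample-Field Duplicate" else
        "Quality Control Sample-Lab Duplicate"
      rows[[length(rows) + 1]] <- base(rec[["Result Value"]], atype, "")
      rows[[length(rows) + 1]] <- base(rec[["QC Reference Value"]],
                                       paste(dup_type, "2"), "-2")
      n_expanded <- n_expanded + 1L
    } else {
      rows[[length(rows) + 1]] <- base(rec[["Result Value"]], atype, "")
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_expanded") <- n_expanded
  out
}

#' Build the WQX submission workbook
#'
#' Writes a single workbook with exactly three sheets — `Project`,
#' `Locations`, and `Results` — populated with as much content as the input
#' files provide; remaining cells are left blank for the user to verify and
#' complete before upload. Censored values are exported as a detection
#' condition plus detection limit, never as fabricated numbers. Same-row
#' duplicate pairs are expanded into two Results rows with paired activity
#' types (`"... 1"` / `"... 2"`); the expansion count is logged. Time zone
#' and sample-collection defaults come from `wqx_config`.
#'
#' @inheritParams qc_accuracy
#' @param output_dir directory to write into.
#' @param file_name workbook file name.
#' @param wqx_config named list overriding entries of `wqx_defaults()`
#'   (`time_zone`, `project_id`, `results_columns`, ...).
#' @return The workbook path, invisibly; a success message names it.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' bd <- qc_bundle(b$results, b$accuracy, b$frecom, b$sites, b$wqx)
#' path <- build_wqx_workbook(bd, output_dir = tempdir())
#' names(read_workbook(path))
#' @export
build_wqx_workbook <- function(bundle, output_dir = ".",
                               file_name = "wqx_submission.xlsx",
                               wqx_config = list()) {
  require_components(bundle, "WQX formatting")
  wcfg <- utils::modifyList(wqx_defaults(), wqx_config)
  known <- as_chr(bundle$sites[["Monitoring Location ID"]])
  used <- unique(as_chr(bundle$results[["Monitoring Location ID"]]))
  used <- used[nzchar(used)]
  miss <- setdiff(used, known)
  if (length(miss))
    stop("Site(s) referenced in results but missing from Locations: ",
         collapse_vals(miss), call. = FALSE)
  res <- wqx_results_rows(bundle, wcfg)
  if (attr(res, "n_expanded") > 0)
    message(attr(res, "n_expanded"),
            " duplicate pair(s) expanded into paired activity rows")
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(output_dir, file_name)
  write_workbook(list(Project = wqx_project_sheet(wcfg),
                      Locations = wqx_locations_sheet(bundle$sites),
                      Results = res), path)
  message("Excel workbook created successfully! File located at ",
          normalizePath(path))
  invisible(path)
}
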