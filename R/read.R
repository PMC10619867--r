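#' Read and validate the monitoring results table
#'
#' Imports the results file (xlsx or csv, or an in-memory data frame), runs
#' the fifteen-member validation suite in its fixed order, and — once every
#' check passes — normalizes the table: dates are standardized to
#' `YYYY-MM-DD`, whitespace is trimmed, and the column order is fixed.
#' Validation stops at the first failing check with a row-addressed error so
#' the offending cells can be fixed in the source file and the import
#' repeated. Rows missing an Activity Start Time raise a warning (times are
#' optional but recommended for WQX submission).
#'
#' @param x path to an `.xlsx` or `.csv` file, or a data frame.
#' @param config configuration from [qc_config()].
#' @param strict promote warnings (e.g. the deep-sample check) to failures.
#' @param quiet suppress per-check console messages.
#' @return A tibble of class `aqc_results` with all cells as text, dates
#'   normalized; the check outcomes tibble is attached as attribute
#'   `"checks"`.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' res <- read_results(b$results, quiet = TRUE)
#' attr(res, "checks")$status
#' @export
read_results <- function(x, config = qc_config(), strict = FALSE, quiet = FALSE) {
  df <- read_table_any(x)
  chk <- check_results(df, config = config, strict = strict, quiet = quiet)
  if (any(chk$status == "fail")) {
    bad <- chk[chk$status == "fail", ]
    stop(bad$check_name[1], "…\n", bad$message[1], call. = FALSE)
  }
  out <- normalize_results(df, quiet = quiet)
  attr(out, "checks") <- chk
  class(out) <- c("aqc_results", class(out))
  out
}

# format step applied after all checks pass
normalize_results <- function(df, quiet = FALSE) {
  df <- df[, results_columns()]
  df[] <- lapply(df, as_chr)
  dt <- parse_result_date(df[["Activity Start Date"]])
  df[["Activity Start Date"]] <- ifelse(is.na(dt), "", format(dt, "%Y-%m-%d"))
  no_time <- sum(!nzchar(df[["Activity Start Time"]]))
  if (!quiet && no_time > 0)
    warning(no_time, " row(s) missing Activity Start Time", call. = FALSE)
  tibble::as_tibble(df)
}

#' Read the data-quality-objective accuracy table
#'
#' Each row gives one parameter's accuracy objectives: detection limits
#' (`MDL`, `UQL`), the value range the row applies to, and a criterion cell
#' for each QC check type (see [parse_criterion()] for the grammar). A
#' derived `scale_hint` column marks a parameter as log-distributed when the
#' token `log` appears in any of its criterion cells. Unparseable cells abort
#' with the cell address.
#'
#' @inheritParams read_results
#' @return A tibble of class `aqc_accuracy`: the raw columns plus
#'   `scale_hint` (`"log"` or `"linear"`).
#' @export
read_accuracy <- function(x, config = qc_config(), quiet = FALSE) {
  df <- read_table_any(x)
  missing <- setdiff("Parameter", names(df))
  if (length(missing))
    stop("Accuracy file missing column(s): ", collapse_vals(missing), call. = FALSE)
  for (col in setdiff(accuracy_columns(), names(df))) df[[col]] <- ""
  df <- df[, union(accuracy_columns(), names(df))]
  df[] <- lapply(df, as_chr)
  unknown <- setdiff(unique(df$Parameter), config$parameters$Parameter)
  if (length(unknown))
    stop("Unknown parameter(s) in accuracy file: ", collapse_vals(unknown),
         call. = FALSE)
  crit_cols <- c("Field Duplicate", "Lab Duplicate", "Field Blank",
                 "Lab Blank", "Spike/Check Accuracy")
  logflag <- rep(FALSE, nrow(df))
  for (col in crit_cols) {
    for (i in seq_len(nrow(df))) {
      crit <- tryCatch(parse_criterion(df[[col]][i]), error = function(e)
        stop("Accuracy file, column '", col, "', row ", i, ": ",
             conditionMessage(e), call. = FALSE))
      logflag[i] <- logflag[i] || crit$log
    }
  }
  for (col in c("MDL", "UQL")) {
    bad <- which(nzchar(df[[col]]) & is.na(num_or_na(df[[col]])))
    if (length(bad))
      stop("Accuracy file, column '", col, "', row ", bad[1],
           ": not a number: '", df[[col]][bad[1]], "'", call. = FALSE)
  }
  for (i in seq_len(nrow(df)))
    tryCatch(parse_value_range(df[["Value Range"]][i]), error = function(e)
      stop("Accuracy file, column 'Value Range', row ", i, ": ",
           conditionMessage(e), call. = FALSE))
  # scale hint is a property of the parameter: any log token marks all rows
  logpar <- unique(df$Parameter[logflag])
  df$scale_hint <- ifelse(df$Parameter %in% logpar, "log", "linear")
  if (!quiet) message("Accuracy data imported: ", nrow(df), " rule(s)")
  out <- tibble::as_tibble(df)
  class(out) <- c("aqc_accuracy", class(out))
  out
}

#' Read the QC frequency and completeness table
#'
#' One row per parameter: the required QC-check frequency (percent of regular
#' samples) for each check type and the required completeness percent. All
#' percents must lie in \[0, 100\]; out-of-range cells abort with the cell
#' address. Empty cells mean no requirement for that parameter/check.
#'
#' @inheritParams read_results
#' @return A tibble of class `aqc_frecom`.
#' @export
read_frecom <- function(x, config = qc_config(), quiet = FALSE) {
  df <- read_table_any(x)
  if (!"Parameter" %in% names(df))
    stop("Frequency/completeness file missing column(s): Parameter", call. = FALSE)
  for (col in setdiff(frecom_columns(), names(df))) df[[col]] <- ""
  df <- df[, union(frecom_columns(), names(df))]
  df[] <- lapply(df, as_chr)
  unknown <- setdiff(unique(df$Parameter), config$parameters$Parameter)
  if (length(unknown))
    stop("Unknown parameter(s) in frequency/completeness file: ",
         collapse_vals(unknown), call. = FALSE)
  for (col in setdiff(frecom_columns(), "Parameter")) {
    v <- num_or_na(df[[col]])
    badnum <- which(nzchar(df[[col]]) & is.na(v))
    if (length(badnum))
      stop("Frequency/completeness file, column '", col, "', row ", badnum[1],
           ": not a number: '", df[[col]][badnum[1]], "'", call. = FALSE)
    oor <- which(!is.na(v) & (v < 0 | v > 100))
    if (length(oor))
      stop("Frequency/completeness file, column '", col, "', row ", oor[1],
           ": percent out of [0, 100]: ", df[[col]][oor[1]], call. = FALSE)
  }
  if (!quiet) message("Frequency and completeness data imported: ",
                      nrow(df), " rule(s)")
  out <- tibble::as_tibble(df)
  class(out) <- c("aqc_frecom", class(out))
  out
}

#' Read the site metadata table
#'
#' Site ids must be unique; latitudes must lie in \[-90, 90\] and longitudes
#' in \[-180, 180\]. The optional Location Group column supports aggregation
#' of sites (e.g. a river mainstem versus its tributaries).
#'
#' @inheritParams read_results
#' @return A tibble of class `aqc_sites`.
#' @export
read_sites <- function(x, quiet = FALSE) {
  df <- read_table_any(x)
  need <- setdiff(sites_columns()[1:3], names(df))
  if (length(need))
    stop("Sites file missing column(s): ", collapse_vals(need), call. = FALSE)
  if (!"Location Group" %in% names(df)) df[["Location Group"]] <- ""
  df[] <- lapply(df, as_chr)
  dup <- unique(df[["Monitoring Location ID"]][duplicated(df[["Monitoring Location ID"]])])
  if (length(dup))
    stop("Duplicate Monitoring Location ID in sites file: ", collapse_vals(dup),
         call. = FALSE)
  lat <- num_or_na(df[["Monitoring Location Latitude"]])
  lon <- num_or_na(df[["Monitoring Location Longitude"]])
  bad <- which(is.na(lat) | lat < -90 | lat > 90)
  if (length(bad))
    stop("Invalid latitude in sites file row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(lon) | lon < -180 | lon > 180)
  if (length(bad))
    stop("Invalid longitude in sites file row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!quiet) message("Site data imported: ", nrow(df), " site(s)")
  out <- tibble::as_tibble(df)
  class(out) <- c("aqc_sites", class(out))
  out
}

#' Read the WQX submission metadata table
#'
#' Per-parameter metadata used to populate the Results sheet of the WQX
#' submission workbook (sample fraction, analytical method and context, and
#' any further columns the template requires — the column set is open). Rows
#' are keyed by `Parameter`, which must resolve against the parameter
#' dictionary.
#'
#' @inheritParams read_results
#' @return A tibble of class `aqc_wqx`.
#' @export
read_wqx_meta <- function(x, config = qc_config(), quiet = FALSE) {
  df <- read_table_any(x)
  if (!"Parameter" %in% names(df))
    stop("WQX metadata file missing column(s): Parameter", call. = FALSE)
  df[] <- lapply(df, as_chr)
  unknown <- setdiff(unique(df$Parameter), config$parameters$Parameter)
  if (length(unknown))
    stop("Unknown parameter(s) in WQX metadata file: ", collapse_vals(unknown),
         call. = FALSE)
  if (!quiet) message("WQX metadata imported: ", nrow(df), " row(s)")
  out <- tibble::as_tibble(df)
  class(out) <- c("aqc_wqx", class(out))
  out
}

#' Unique values per column, for troubleshooting formatting problems
#'
#' Scans a raw results file and lists the distinct entries found in every
#' column, in order of first appearance, so typos and stray categories can be
#' spotted quickly before validation. Optionally exported to a
#' one-sheet workbook or csv.
#'
#' @param x path or data frame (read as raw text; no checks are run).
#' @param output optional path (`.xlsx` or `.csv`) to write the view to.
#' @return A tibble with the original column names, each column listing that
#'   column's unique entries (padded with `""` to equal length).
#' @export
results_view <- function(x, output = NULL) {
  df <- read_table_any(x)
  uniq <- lapply(df, function(col) unique(col[!is.na(col)]))
  n <- max(c(1L, lengths(uniq)))
  padded <- lapply(uniq, function(u) c(u, rep("", n - length(u))))
  out <- tibble::as_tibble(padded, .name_repair = "minimal")
  names(out) <- names(df)
  if (!is.null(output)) {
    write_table_any(out, output, sheet_name = "Unique values")
    message("Unique-values view written to ", output)
  }
  out
}

#' Bundle validated inputs for the downstream workflow
#'
#' Collects the validated tables into a named list used by every downstream
#' function. Only `results`, `accuracy`, and `frecom` are always required at
#' bundle time; each workflow step re-checks that the components it needs are
#' present ([require_components()]).
#'
#' @param results,accuracy,frecom,sites,wqx validated tables from the
#'   `read_*()` functions (or raw tables/paths, which are validated here).
#' @param config configuration from [qc_config()].
#' @return A list of class `aqc_bundle` with elements `results`, `accuracy`,
#'   `frecom`, `sites`, `wqx`, `config`.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' bd <- qc_bundle(b$results, b$accuracy, b$frecom, b$sites, b$wqx)
#' names(bd)
#' @export
qc_bundle <- function(results, accuracy, frecom, sites = NULL, wqx = NULL,
                      config = qc_config()) {
  as_part <- function(x, cls, reader) {
    if (is.null(x)) return(NULL)
    if (inherits(x, cls)) x else reader(x)
  }
  out <- list(
    results  = as_part(results, "aqc_results",
                       function(x) read_results(x, config = config, quiet = TRUE)),
    accuracy = as_part(accuracy, "aqc_accuracy",
                       function(x) read_accuracy(x, config = config, quiet = TRUE)),
    frecom   = as_part(frecom, "aqc_frecom",
                       function(x) read_frecom(x, config = config, quiet = TRUE)),
    sites    = as_part(sites, "aqc_sites", function(x) read_sites(x, quiet = TRUE)),
    wqx      = as_part(wqx, "aqc_wqx",
                       function(x) read_wqx_meta(x, config = config, quiet = TRUE)),
    config   = config
  )
  structure(out, class = "aqc_bundle")
}

# per-step component requirements (workflow steps x input files)
step_requirements <- function() {
  list(
    "QC screening"   = c("results", "accuracy", "frecom"),
    "QC reporting"   = c("results", "accuracy", "frecom"),
    "Data analysis"  = c("results", "accuracy"),
    "WQX formatting" = c("results", "accuracy", "sites", "wqx")
  )
}

component_label <- function(x) {
  c(results = "results", accuracy = "DQO accuracy",
    frecom = "DQO frequency and completeness", sites = "sites",
    wqx = "WQX metadata")[x]
}

#' Assert that a bundle carries the components a workflow step needs
#'
#' @param bundle an `aqc_bundle`.
#' @param step one of `"QC screening"`, `"QC reporting"`, `"Data analysis"`,
#'   `"WQX formatting"`.
#' @return The bundle, invisibly; errors naming the step and the missing
#'   file(s) otherwise.
#' @export
require_components <- function(bundle, step) {
  stopifnot(inherits(bundle, "aqc_bundle"))
  need <- step_requirements()[[match.arg(step, names(step_requirements()))]]
  have <- vapply(need, function(k) !is.null(bundle[[k]]), TRUE)
  if (!all(have))
    stop("Step '", step, "' requires missing input file(s): ",
         paste(component_label(need[!have]), collapse = ", "), call. = FALSE)
  invisible(bundle)
}
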