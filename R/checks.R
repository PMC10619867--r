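# The fifteen-member results validation suite.
#
# Checks run in a fixed order, each one printed to the console as it
# completes; the first failure stops the run and reports the offending values
# with 1-based data-row indices (header excluded), e.g.
#   "Incorrect Activity Type found: Sample, Field in row(s) 4, 135"
# so the user can fix the named cells in the source spreadsheet and re-import.

check_names_results <- function() {
  c("Checking column names",
    "Checking all required columns are present",
    "Checking valid Activity Types",
    "Checking Activity Start Date formats",
    "Checking depth data present",
    "Checking for non-numeric values in Activity Depth/Height Measure",
    "Checking Activity Depth/Height Unit",
    "Checking Activity Relative Depth Name formats",
    "Checking values in Activity Depth/Height Measure > 1 m / 3.3 ft",
    "Checking Characteristic Name formats",
    "Checking Result Values",
    "Checking QC Reference Values",
    "Checking for missing entries for Result Unit",
    "Checking if more than one unit per Characteristic Name",
    "Checking acceptable units for each entry in Characteristic Name")
}

# date parsing: ISO, US month/day/year, or spreadsheet serial (days since
# 1899-12-30); returns Date or NA
parse_result_date <- function(x) {
  x <- as_chr(x)
  out <- rep(as.Date(NA), length(x))
  iso <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)
  out[iso] <- suppressWarnings(as.Date(x[iso], format = "%Y-%m-%d"))
  us <- grepl("^\\d{1,2}/\\d{1,2}/\\d{4}$", x)
  out[us] <- suppressWarnings(as.Date(x[us], format = "%m/%d/%Y"))
  ser <- grepl("^\\d{4,6}$", x) & !iso
  out[ser] <- as.Date(as.numeric(x[ser]), origin = "1899-12-30")
  out
}

# one outcome row; values/rows are list-columns to keep the tibble tidy
outcome_row <- function(check_name, status, values = character(0),
                        rows = integer(0), message = "") {
  tibble::tibble(check_name = check_name, status = status,
                 offending_values = list(as.character(values)),
                 offending_rows = list(as.integer(rows)),
                 message = message)
}

fmt_rows <- function(rows, config) {
  if (isTRUE(config$spreadsheet_rows)) rows <- rows + 1L
  paste(rows, collapse = ", ")
}

#' Run the results-file validation suite
#'
#' Applies the fifteen named checks to a results table, in a fixed order,
#' stopping at the first failure. Each check prints as it completes; failures
#' carry the offending values and 1-based data-row indices. The depth
#' warning check (values deeper than 1 m / 3.3 ft) reports `warn`, not
#' `fail`, unless `strict = TRUE` promotes warnings to failures.
#'
#' @param data results table (data frame; all cells treated as text).
#' @param config configuration from [qc_config()].
#' @param strict promote warnings to failures.
#' @param quiet suppress per-check console messages.
#' @return A tibble of outcomes with columns `check_name`, `status`
#'   (`ok`/`warn`/`fail`), `offending_values`, `offending_rows` (list-columns),
#'   and `message`. At most one `fail` row is present and it is always the
#'   last row (no later checks run).
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' out <- check_results(b$results, quiet = TRUE)
#' all(out$status == "ok")
#' @export
check_results <- function(data, config = qc_config(), strict = FALSE,
                          quiet = FALSE) {
  df <- read_table_any(data)
  nms <- check_names_results()
  outcomes <- vector("list", length(nms))
  say <- function(txt) if (!quiet) message(txt)
  if (!quiet) message("Running checks on results data…")
  for (i in seq_along(nms)) {
    res <- run_one_check(i, df, config)
    status <- res$status
    if (strict && status == "warn") status <- "fail"
    outcomes[[i]] <- outcome_row(nms[i], status, res$values, res$rows, res$message)
    if (status == "ok") {
      say(paste0(nms[i], "… OK"))
    } else if (status == "warn") {
      say(paste0(nms[i], "… WARNING"))
      if (!quiet && nzchar(res$message)) message(res$message)
    } else {
      say(paste0("Error: ", nms[i], "…"))
      if (!quiet && nzchar(res$message)) message(res$message)
      outcomes <- outcomes[seq_len(i)]
      break
    }
  }
  out <- dplyr::bind_rows(outcomes)
  if (!quiet && all(out$status != "fail")) message("All checks passed!")
  out
}

# dispatch for the i-th check; returns list(status, values, rows, message)
run_one_check <- function(i, df, config) {
  ok <- list(status = "ok", values = character(0), rows = integer(0), message = "")
  fail <- function(values, rows, msg)
    list(status = "fail", values = as.character(values), rows = as.integer(rows),
         message = msg)
  warn <- function(values, rows, msg)
    list(status = "warn", values = as.character(values), rows = as.integer(rows),
         message = msg)
  expected <- results_columns()
  pars <- config$parameters

  if (i == 1) {                       # unknown column names
    extra <- setdiff(names(df), expected)
    if (length(extra))
      return(fail(extra, integer(0),
                  paste0("Unrecognized column name(s) found: ", collapse_vals(extra))))
    return(ok)
  }
  if (i == 2) {                       # required columns present
    missing <- setdiff(expected, names(df))
    if (length(missing))
      return(fail(missing, integer(0),
                  paste0("Required column(s) missing: ", collapse_vals(missing))))
    return(ok)
  }
  at <- as_chr(df[["Activity Type"]])
  if (i == 3) {                       # controlled activity-type vocabulary
    bad <- which(!at %in% names(config$activity_types))
    if (length(bad)) {
      vals <- unique(at[bad])
      return(fail(vals, bad, paste0("Incorrect Activity Type found: ",
                                    collapse_vals(at[bad]), " in row(s) ",
                                    fmt_rows(bad, config))))
    }
    return(ok)
  }
  if (i == 4) {                       # parseable dates
    dt <- as_chr(df[["Activity Start Date"]])
    bad <- which(nzchar(dt) & is.na(parse_result_date(dt)))
    empty <- which(!nzchar(dt))
    bad <- sort(c(bad, empty))
    if (length(bad))
      return(fail(unique(dt[bad]), bad,
                  paste0("Incorrect Activity Start Date found: ",
                         collapse_vals(dt[bad]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  dep <- as_chr(df[["Activity Depth/Height Measure"]])
  if (i == 5) {                       # field rows need a depth or relative depth
    field <- config$activity_types[at] %in% "regular_field" & !is.na(config$activity_types[at])
    reld <- as_chr(df[["Activity Relative Depth Name"]])
    bad <- which(field & !nzchar(dep) & !nzchar(reld))
    if (length(bad))
      return(fail(character(0), bad,
                  paste0("Missing depth data in row(s) ", fmt_rows(bad, config))))
    return(ok)
  }
  if (i == 6) {                       # depth numeric
    bad <- which(nzchar(dep) & is.na(num_or_na(dep)))
    if (length(bad))
      return(fail(unique(dep[bad]), bad,
                  paste0("Non-numeric Activity Depth/Height Measure found: ",
                         collapse_vals(dep[bad]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  du <- as_chr(df[["Activity Depth/Height Unit"]])
  if (i == 7) {                       # depth unit vocabulary; required with a depth
    bad <- which((nzchar(du) & !du %in% config$depth_units) |
                   (nzchar(dep) & !nzchar(du)))
    if (length(bad))
      return(fail(unique(du[bad]), bad,
                  paste0("Incorrect Activity Depth/Height Unit found: ",
                         collapse_vals(du[bad][nzchar(du[bad])]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  if (i == 8) {                       # relative depth vocabulary
    reld <- as_chr(df[["Activity Relative Depth Name"]])
    bad <- which(nzchar(reld) & !reld %in% config$relative_depth_names)
    if (length(bad))
      return(fail(unique(reld[bad]), bad,
                  paste0("Incorrect Activity Relative Depth Name found: ",
                         collapse_vals(reld[bad]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  if (i == 9) {                       # deep samples: warning only
    dnum <- num_or_na(dep)
    lim <- ifelse(du == "ft", config$depth_warn_m * 3.3, config$depth_warn_m)
    bad <- which(!is.na(dnum) & dnum > lim)
    if (length(bad))
      return(warn(unique(dep[bad]), bad,
                  paste0("Depth values greater than ", config$depth_warn_m,
                         " m / ", fmt_num(config$depth_warn_m * 3.3),
                         " ft in row(s) ", fmt_rows(bad, config))))
    return(ok)
  }
  cn <- as_chr(df[["Characteristic Name"]])
  if (i == 10) {                      # parameter dictionary
    bad <- which(!cn %in% pars$Parameter)
    if (length(bad))
      return(fail(unique(cn[bad]), bad,
                  paste0("Incorrect Characteristic Name found: ",
                         collapse_vals(cn[bad]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  rv <- as_chr(df[["Result Value"]])
  if (i == 11) {                      # numeric or censoring token; sign rules
    num <- num_or_na(rv)
    nonnum <- nzchar(rv) & is.na(num) & !is_censor_token(rv)
    neg_ok <- pars$`Negative Ok`[match(cn, pars$Parameter)]
    neg <- !is.na(num) & num < 0 & !(neg_ok %in% TRUE)
    bad <- which(nonnum | neg)
    if (length(bad))
      return(fail(unique(rv[bad]), bad,
                  paste0("Incorrect Result Value found: ", collapse_vals(rv[bad]),
                         " in row(s) ", fmt_rows(bad, config))))
    return(ok)
  }
  if (i == 12) {                      # QC reference value format
    qv <- as_chr(df[["QC Reference Value"]])
    bad <- which(nzchar(qv) & is.na(num_or_na(qv)) & !is_censor_token(qv))
    if (length(bad))
      return(fail(unique(qv[bad]), bad,
                  paste0("Incorrect QC Reference Value found: ",
                         collapse_vals(qv[bad]), " in row(s) ",
                         fmt_rows(bad, config))))
    return(ok)
  }
  ru <- as_chr(df[["Result Unit"]])
  if (i == 13) {                      # unit required wherever a value exists
    bad <- which(nzchar(rv) & !nzchar(ru))
    if (length(bad))
      return(fail(character(0), bad,
                  paste0("Missing Result Unit in row(s) ", fmt_rows(bad, config))))
    return(ok)
  }
  if (i == 14) {                      # one unit per parameter
    tab <- unique(data.frame(p = cn, u = ru)[nzchar(ru), , drop = FALSE])
    multi <- names(which(table(tab$p) > 1))
    if (length(multi)) {
      vals <- vapply(multi, function(p)
        paste0(p, " (", collapse_vals(tab$u[tab$p == p]), ")"), "")
      return(fail(vals, integer(0),
                  paste0("More than one unit per Characteristic Name: ",
                         paste(vals, collapse = "; "))))
    }
    return(ok)
  }
  if (i == 15) {                      # unit must be acceptable for the parameter
    allowed <- strsplit(pars$Units, ",\\s*")
    names(allowed) <- pars$Parameter
    bad <- which(nzchar(ru) & cn %in% pars$Parameter &
                   !mapply(function(u, p) u %in% allowed[[p]], ru, cn))
    if (length(bad)) {
      vals <- unique(paste(cn[bad], ru[bad]))
      return(fail(vals, bad,
                  paste0("Unacceptable unit for Characteristic Name: ",
                         collapse_vals(vals), " in row(s) ",
                         fmt_rows(bad, config))))
    }
    return(ok)
  }
  stop("Unknown check index ", i)
}
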