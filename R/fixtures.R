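# Deterministic synthetic input bundles: a season of multi-site monitoring
# with interleaved QC activities, censored tokens, and injected anomalies
# recorded in a ground-truth sidecar, so every module is testable without
# external data.

#' Specification for a synthetic input bundle
#'
#' Defines the study conditions the generator emulates: one May–September
#' sampling season, several sites with coordinates and location groups,
#' eight parameters spanning field measurements (DO, pH, specific
#' conductance, water temperature) and lab analytes (ammonia, TP, nitrate,
#' E. coli — the last log-distributed), QC activities at roughly the 10%
#' frequency monitoring plans require, a small censored-value rate, and a
#' configurable list of injected outliers and forced QC misses whose ground
#' truth is returned alongside the data.
#'
#' @param seed integer seed; the whole bundle is reproducible given
#'   `(spec, seed)`.
#' @param n_sites number of monitoring sites.
#' @param year calendar year of the season.
#' @param sample_interval days between sampling events (May 1 start,
#'   events through September).
#' @param qc_rate target QC frequency as a fraction of regular samples per
#'   applicable check type.
#' @param censored_rate fraction of lab-analyte results reported as `BDL`.
#' @param qualified_rate fraction of regular lab rows carrying a same-row
#'   duplicate pair in `QC Reference Value` (counted as qualified samples).
#' @param outlier_injections list of `list(param =, month =, factor =)`
#'   entries; one extreme value is planted per entry, at `factor` times the
#'   typical level, within the given month ("May".."Sep").
#' @param inject_blank_miss plant one TP field blank exactly at its
#'   threshold (a MISS under the strict `<` criterion).
#' @return A list of class `aqc_fixture_spec`.
#' @export
fixture_spec <- function(seed = 42, n_sites = 6, year = 2022,
                         sample_interval = 14, qc_rate = 0.12,
                         censored_rate = 0.06, qualified_rate = 0.06,
                         outlier_injections = list(
                           list(param = "DO", month = "May", factor = 8)),
                         inject_blank_miss = TRUE) {
  stopifnot(qc_rate >= 0, qc_rate <= 1, censored_rate >= 0, censored_rate <= 1,
            qualified_rate >= 0, qualified_rate <= 1, n_sites >= 1)
  structure(list(seed = as.integer(seed), n_sites = n_sites, year = year,
                 sample_interval = sample_interval, qc_rate = qc_rate,
                 censored_rate = censored_rate, qualified_rate = qualified_rate,
                 outlier_injections = outlier_injections,
                 inject_blank_miss = inject_blank_miss),
            class = "aqc_fixture_spec")
}

# parameter generation settings: typical level and spread, lab vs field,
# and which QC activities apply
fixture_params <- function() {
  tibble::tribble(
    ~Parameter,       ~mu,   ~sigma, ~lab,  ~log,
    "DO",             8,     1.2,    FALSE, FALSE,
    "Ammonia",        0.15,  0.07,   TRUE,  FALSE,
    "TP",             0.05,  0.02,   TRUE,  FALSE,
    "Nitrate",        0.5,   0.2,    TRUE,  FALSE,
    "pH",             7.2,   0.35,   FALSE, FALSE,
    "Sp Conductance", 350,   70,     FALSE, FALSE,
    "E.coli",         120,   0.9,    TRUE,  TRUE,
    "Water Temp",     18,    4,      FALSE, FALSE)
}

# default DQO accuracy table for the synthetic parameters
fixture_accuracy <- function() {
  tibble::tribble(
    ~Parameter, ~MDL, ~UQL, ~`Value Range`, ~`Field Duplicate`, ~`Lab Duplicate`,
      ~`Field Blank`, ~`Lab Blank`, ~`Spike/Check Accuracy`,
    "DO",             "",      "",     "all", "<= 20%",     "",       "",       "",       "<= 10%",
    "Ammonia",        "0.05",  "",    "all", "<= 30%",     "<= 30%", "< 0.1",  "< 0.1",  "<= 20%",
    "TP",             "0.005", "",    "all", "<= 30%",     "<= 30%", "< 0.01", "< 0.01", "<= 15%",
    "Nitrate",        "0.05",  "",    "all", "<= 30%",     "<= 30%", "< 0.05", "< 0.05", "<= 10%",
    "pH",             "",      "",    "all", "<= 0.5",     "<= 0.5", "",       "",       "<= 5%",
    "Sp Conductance", "",      "",    "all", "<= 10%",     "",       "",       "< 10",   "<= 10%",
    "E.coli",         "1",     "2420", "all", "<= 50% log", "<= 50%", "< 1",   "",       "",
    "Water Temp",     "",      "",    "all", "<= 1",       "",       "",       "",       "<= 5%")
}

fixture_frecom <- function() {
  tibble::tribble(
    ~Parameter, ~`Field Duplicate`, ~`Lab Duplicate`, ~`Field Blank`,
      ~`Lab Blank`, ~`Spike/Check Accuracy`, ~`% Completeness`,
    "DO",             "10", "",   "",   "",   "10", "90",
    "Ammonia",        "10", "10", "10", "10", "10", "90",
    "TP",             "10", "10", "10", "10", "10", "90",
    "Nitrate",        "10", "10", "10", "10", "10", "90",
    "pH",             "10", "",   "",   "",   "10", "90",
    "Sp Conductance", "10", "",   "",   "",   "10", "90",
    "E.coli",         "10", "10", "10", "",   "",   "90",
    "Water Temp",     "10", "",   "",   "",   "10", "90")
}

fixture_wqx_meta <- function() {
  pars <- fixture_params()
  tibble::tibble(
    Parameter = pars$Parameter,
    `Sample Fraction` = ifelse(pars$lab, "Total", ""),
    `Analytical Method` = ifelse(pars$lab, paste0("SM-", seq_len(nrow(pars))), "PROBE"),
    `Analytical Method Context` = ifelse(pars$lab, "APHA", "Field"))
}

draw_value <- function(p, n) {
  if (p$log) {
    rlnorm(n, meanlog = log(p$mu), sdlog = p$sigma)
  } else {
    pmax(rnorm(n, p$mu, p$sigma), if (p$Parameter == "Water Temp") -Inf else p$mu / 20)
  }
}

fmt_val <- function(x, p) {
  digits <- if (p$mu < 1) 3 else if (p$mu < 20) 1 else 0
  format(round(x, digits), scientific = FALSE, trim = TRUE)
}

#' Generate a synthetic five-table input bundle
#'
#' Draws a full season of monitoring data under the conditions in the spec
#' and returns the five input tables plus a ground-truth sidecar of injected
#' anomalies. The generated results table passes all fifteen validation
#' checks by construction; the DQO tables parse; the sites table covers all
#' result site ids; E. coli is flagged log-distributed.
#'
#' @param spec an `aqc_fixture_spec` from [fixture_spec()].
#' @param dir optional directory: when given, the five tables are written as
#'   `results.xlsx`, `accuracy.xlsx`, `frecom.xlsx`, `sites.xlsx`,
#'   `wqx.xlsx`, plus `outlier_truth.csv` and `qc_miss_truth.csv` sidecars.
#' @return A list with `results`, `accuracy`, `frecom`, `sites`, `wqx`
#'   (tibbles), and sidecars `outlier_truth` (site, date, parameter, value,
#'   month) and `qc_miss_truth` (parameter, check type, count); plus
#'   `paths` when `dir` is given.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 7))
#' nrow(b$results) > 135
#' @export
generate_bundle <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "aqc_fixture_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(spec$seed)

  sites <- tibble::tibble(
    `Monitoring Location ID` = sprintf("WS-%03d", seq_len(spec$n_sites)),
    `Monitoring Location Latitude` = format(round(42.2 + runif(spec$n_sites, 0, 0.4), 5)),
    `Monitoring Location Longitude` = format(round(-71.7 + runif(spec$n_sites, 0, 0.5), 5)),
    `Location Group` = ifelse(seq_len(spec$n_sites) <= ceiling(spec$n_sites / 2),
                              "Mainstem", "Tributary"))
  dates <- seq(as.Date(sprintf("%d-05-01", spec$year)),
               as.Date(sprintf("%d-09-30", spec$year)),
               by = spec$sample_interval)
  pars <- fixture_params()
  wet <- runif(length(dates)) < 0.4   # per-event antecedent condition

  blank_result <- function(n) tibble::tibble(
    `Monitoring Location ID` = character(n), `Activity Type` = character(n),
    `Activity Start Date` = character(n), `Activity Start Time` = character(n),
    `Activity Depth/Height Measure` = character(n),
    `Activity Depth/Height Unit` = character(n),
    `Activity Relative Depth Name` = character(n),
    `Characteristic Name` = character(n), `Result Value` = character(n),
    `QC Reference Value` = character(n), `Result Unit` = character(n),
    `Result Attribute` = character(n))

  cfg <- qc_config()
  unit_of <- setNames(cfg$parameters$Units, cfg$parameters$Parameter)
  rows <- list()
  truth_out <- list()
  truth_miss <- list()

  for (k in seq_len(nrow(pars))) {
    p <- pars[k, ]
    n <- length(dates) * spec$n_sites
    grid <- expand.grid(site = sites$`Monitoring Location ID`,
                        date = as.character(dates), stringsAsFactors = FALSE)
    vals <- draw_value(p, n)
    censored <- p$lab & runif(n) < spec$censored_rate
    reg <- blank_result(n)
    reg$`Monitoring Location ID` <- grid$site
    reg$`Activity Type` <- if (p$lab) "Sample-Routine" else "Field Msr/Obs"
    reg$`Activity Start Date` <- grid$date
    reg$`Activity Start Time` <- sprintf("%02d:%02d", sample(6:10, n, TRUE),
                                         sample(0:59, n, TRUE))
    reg$`Activity Depth/Height Measure` <- "0.3"
    reg$`Activity Depth/Height Unit` <- "m"
    reg$`Activity Relative Depth Name` <- "Surface"
    reg$`Characteristic Name` <- p$Parameter
    reg$`Result Value` <- ifelse(censored, "BDL", fmt_val(vals, p))
    reg$`Result Unit` <- unit_of[[p$Parameter]]
    reg$`Result Attribute` <- ifelse(wet[match(grid$date, as.character(dates))],
                                     "WET", "DRY")

    # same-row duplicate pairs on a fraction of regular lab rows (qualified)
    if (p$lab && spec$qualified_rate > 0) {
      host <- which(!censored & runif(n) < spec$qualified_rate)
      pair <- vals[host] * (1 + rnorm(length(host), 0, 0.05))
      reg$`QC Reference Value`[host] <- fmt_val(pmax(pair, 0), p)
    }

    # planted outliers for this parameter
    for (inj in spec$outlier_injections) {
      if (!identical(inj$param, p$Parameter)) next
      cand <- which(format(as.Date(reg$`Activity Start Date`), "%b") == inj$month &
                      reg$`Result Value` != "BDL")
      pick <- cand[sample.int(length(cand), 1)]
      v <- p$mu * inj$factor
      reg$`Result Value`[pick] <- fmt_val(v, p)
      truth_out[[length(truth_out) + 1]] <- tibble::tibble(
        `Monitoring Location ID` = reg$`Monitoring Location ID`[pick],
        `Activity Start Date` = reg$`Activity Start Date`[pick],
        `Characteristic Name` = p$Parameter,
        `Result Value` = num_or_na(reg$`Result Value`[pick]),
        month = inj$month)
    }
    rows[[length(rows) + 1]] <- reg

    # QC activities at the target frequency
    n_qc <- max(1L, round(spec$qc_rate * n))
    qc_dates <- sample(as.character(dates), n_qc, replace = TRUE)
    qc_sites <- sample(sites$`Monitoring Location ID`, n_qc, replace = TRUE)
    add_qc <- function(type, value, ref = "", site = qc_sites) {
      q <- blank_result(n_qc)
      q$`Monitoring Location ID` <- site
      q$`Activity Type` <- type
      q$`Activity Start Date` <- qc_dates
      q$`Activity Start Time` <- sprintf("%02d:%02d", sample(6:10, n_qc, TRUE),
                                         sample(0:59, n_qc, TRUE))
      q$`Characteristic Name` <- p$Parameter
      q$`Result Value` <- value
      q$`QC Reference Value` <- ref
      q$`Result Unit` <- unit_of[[p$Parameter]]
      q
    }
    # duplicate precision: multiplicative for log parameters, additive at a
    # small fraction of the parameter spread otherwise
    jitter_pair <- function(x, frac) {
      if (p$log) x * exp(rnorm(length(x), 0, 0.08))
      else pmax(x + rnorm(length(x), 0, p$sigma * frac), 0.0001)
    }
    base <- draw_value(p, n_qc)
    rows[[length(rows) + 1]] <- add_qc("Quality Control Sample-Field Duplicate",
                                       fmt_val(base, p),
                                       fmt_val(jitter_pair(base, 0.12), p))
    if (p$lab) {
      base2 <- draw_value(p, n_qc)
      rows[[length(rows) + 1]] <- add_qc("Quality Control Sample-Lab Duplicate",
                                         fmt_val(base2, p),
                                         fmt_val(jitter_pair(base2, 0.08), p),
                                         site = rep("", n_qc))
      rows[[length(rows) + 1]] <- add_qc("Quality Control Sample-Field Blank",
                                         rep("BDL", n_qc))
      if (nzchar(fixture_accuracy()$`Lab Blank`[k]))
        rows[[length(rows) + 1]] <- add_qc("Quality Control Sample-Lab Blank",
                                           rep("BDL", n_qc), site = rep("", n_qc))
      if (nzchar(fixture_accuracy()$`Spike/Check Accuracy`[k])) {
        known <- rep(p$mu * 2, n_qc)
        meas <- known * (1 + rnorm(n_qc, 0, 0.02))
        rows[[length(rows) + 1]] <- add_qc("Quality Control Sample-Lab Spike",
                                           fmt_val(meas, p), fmt_val(known, p),
                                           site = rep("", n_qc))
      }
    } else {
      known <- rep(p$mu, n_qc)
      meas <- known * (1 + rnorm(n_qc, 0, 0.01))
      rows[[length(rows) + 1]] <- add_qc("Quality Control-Calibration Check",
                                         fmt_val(meas, p), fmt_val(known, p))
    }
  }

  results <- dplyr::bind_rows(rows)
  # forced TP field-blank miss: a blank exactly at its threshold
  if (isTRUE(spec$inject_blank_miss)) {
    q <- blank_result(1)
    q$`Activity Type` <- "Quality Control Sample-Field Blank"
    q$`Activity Start Date` <- as.character(dates[ceiling(length(dates) / 2)])
    q$`Activity Start Time` <- "08:00"
    q$`Characteristic Name` <- "TP"
    q$`Result Value` <- "0.01"
    q$`Result Unit` <- "mg/l"
    results <- dplyr::bind_rows(results, q)
    truth_miss[[length(truth_miss) + 1]] <- tibble::tibble(
      Parameter = "TP", `Check Type` = "Field Blanks", n = 1L)
  }

  out <- list(results = results,
              accuracy = fixture_accuracy(),
              frecom = fixture_frecom(),
              sites = sites,
              wqx = fixture_wqx_meta(),
              outlier_truth = dplyr::bind_rows(truth_out),
              qc_miss_truth = dplyr::bind_rows(truth_miss))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(results = file.path(dir, "results.xlsx"),
               accuracy = file.path(dir, "accuracy.xlsx"),
               frecom = file.path(dir, "frecom.xlsx"),
               sites = file.path(dir, "sites.xlsx"),
               wqx = file.path(dir, "wqx.xlsx"))
    for (nm in names(paths))
      write_workbook(setNames(list(out[[nm]]), "Sheet1"), paths[[nm]])
    readr::write_csv(out$outlier_truth, file.path(dir, "outlier_truth.csv"))
    readr::write_csv(out$qc_miss_truth, file.path(dir, "qc_miss_truth.csv"))
    out$paths <- paths
  }
  out
}

#' Apply targeted corruptions to a generated bundle
#'
#' Overwrites addressed cells (or drops columns) in one of the bundle's
#' tables, keeping a log of the mutations so tests can assert the expected
#' check failures. Row indices are 1-based over data rows.
#'
#' @param bundle a list as returned by [generate_bundle()].
#' @param mutations list of entries, each either
#'   `list(table =, row =, col =, value =)` or `list(table =, drop_col =)`.
#' @return The mutated bundle, with a `mutation_log` tibble attached.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' b2 <- corrupt_bundle(b, list(
#'   list(table = "results", row = 4, col = "Activity Type", value = "Sample")))
#' attr(b2, "mutation_log")
#' @export
corrupt_bundle <- function(bundle, mutations) {
  log <- list()
  for (m in mutations) {
    tab <- bundle[[m$table]]
    if (is.null(tab)) stop("No such table in bundle: ", m$table, call. = FALSE)
    if (!is.null(m$drop_col)) {
      if (!m$drop_col %in% names(tab))
        stop("No such column: ", m$drop_col, call. = FALSE)
      tab[[m$drop_col]] <- NULL
      log[[length(log) + 1]] <- tibble::tibble(
        table = m$table, row = NA_integer_, col = m$drop_col,
        value = NA_character_, action = "drop_col")
    } else {
      if (m$row < 1 || m$row > nrow(tab))
        stop("Row out of range: ", m$row, call. = FALSE)
      if (!m$col %in% names(tab)) stop("No such column: ", m$col, call. = FALSE)
      tab[m$row, m$col] <- m$value
      log[[length(log) + 1]] <- tibble::tibble(
        table = m$table, row = as.integer(m$row), col = m$col,
        value = as.character(m$value), action = "set")
    }
    bundle[[m$table]] <- tab
  }
  attr(bundle, "mutation_log") <- dplyr::bind_rows(log)
  bundle
}

#' Built-in field-blank demonstration records
#'
#' A small fixed set of field-blank QC records for two lab analytes —
#' seven ammonia blanks, all below detection, and eleven total-phosphorus
#' blanks of which one sits exactly at its 0.01 mg/l threshold (a MISS
#' under the strict `<` criterion) — together with matching accuracy and
#' frequency/completeness tables. Useful for demonstrating the accuracy
#' views on data small enough to inspect by eye.
#'
#' @return A list with `results`, `accuracy`, `frecom` tibbles.
#' @examples
#' d <- demo_field_blanks()
#' bd <- qc_bundle(d$results, d$accuracy, d$frecom)
#' qc_accuracy(bd, type = "summary")
#' @export
demo_field_blanks <- function() {
  mk <- function(param, dates, values, unit) {
    n <- length(dates)
    tibble::tibble(
      `Monitoring Location ID` = character(n),
      `Activity Type` = "Quality Control Sample-Field Blank",
      `Activity Start Date` = dates, `Activity Start Time` = character(n),
      `Activity Depth/Height Measure` = character(n),
      `Activity Depth/Height Unit` = character(n),
      `Activity Relative Depth Name` = character(n),
      `Characteristic Name` = param, `Result Value` = values,
      `QC Reference Value` = character(n), `Result Unit` = unit,
      `Result Attribute` = character(n))
  }
  results <- dplyr::bind_rows(
    mk("Ammonia",
       c("2022-05-15", "2022-06-12", "2022-07-17", "2022-07-17",
         "2022-08-14", "2022-08-14", "2022-09-11"),
       rep("BDL", 7), "mg/l"),
    mk("TP",
       c("2022-05-15", "2022-05-15", "2022-06-12", "2022-06-12",
         "2022-07-17", "2022-07-17", "2022-07-17", "2022-08-14",
         "2022-08-14", "2022-09-11", "2022-09-11"),
       c(rep("BDL", 6), "0.01", rep("BDL", 4)), "mg/l"))
  accuracy <- fixture_accuracy()[fixture_accuracy()$Parameter %in% c("Ammonia", "TP"), ]
  frecom <- fixture_frecom()[fixture_frecom()$Parameter %in% c("Ammonia", "TP"), ]
  list(results = results, accuracy = accuracy, frecom = frecom)
}
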