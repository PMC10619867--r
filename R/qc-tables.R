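# QC table views: individual, summary, and percent accuracy tables, and the
# frequency / completeness evaluations.

record_roles <- function(results, config) {
  unname(config$activity_types[as_chr(results[["Activity Type"]])])
}

# qualified samples: regular rows hosting a paired QC value, plus rows whose
# Result Attribute matches a configured qualifier value
is_qualified <- function(results, config) {
  roles <- record_roles(results, config)
  regular <- roles %in% c("regular_field", "regular_lab")
  paired <- nzchar(as_chr(results[["QC Reference Value"]]))
  flagged <- as_chr(results[["Result Attribute"]]) %in% config$qualifier_attributes
  regular & (paired | flagged)
}

# order parameters: dictionary order first, then any others alphabetically
param_order <- function(params, config) {
  dict <- config$parameters$Parameter
  c(intersect(dict, params), sort(setdiff(params, dict)))
}

#' Individual, summary, and percent views of the accuracy QC checks
#'
#' Evaluates every QC record in the results table against the accuracy
#' data-quality objectives and returns one of three views:
#' \describe{
#'   \item{individual}{one row per QC record with its result, threshold, and
#'     hit/miss verdict, grouped by check type;}
#'   \item{summary}{per check type and parameter: the number of checks, the
#'     number of misses, and the percent acceptance;}
#'   \item{percent}{a parameter-by-check-type matrix of acceptance percents,
#'     with `"-"` where no QC records were available; when the frequency and
#'     completeness table is present, a parallel `met` attribute tibble flags
#'     cells whose required QC frequency was not met.}
#' }
#' Duplicate pairs may appear either as dedicated duplicate activity rows or
#' as regular rows carrying the second measurement in `QC Reference Value`;
#' both are evaluated. Records without an applicable criterion are excluded
#' with a logged notice, never silently dropped.
#'
#' @param bundle an `aqc_bundle` from [qc_bundle()].
#' @param type `"summary"`, `"percent"`, or `"individual"`.
#' @param accchk optional filter: check-type names (e.g. `"Field Blanks"`)
#'   to restrict the individual view to.
#' @return A tibble (see Details); summary counts always equal the tally of
#'   individual rows.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' bd <- qc_bundle(b$results, b$accuracy, b$frecom)
#' qc_accuracy(bd, type = "summary")
#' @export
qc_accuracy <- function(bundle, type = c("summary", "percent", "individual"),
                        accchk = NULL) {
  type <- match.arg(type)
  require_components(bundle, "QC screening")
  indiv <- qc_individual_all(bundle)
  if (type == "individual") {
    if (!is.null(accchk)) {
      bad <- setdiff(accchk, names(check_types()))
      if (length(bad))
        stop("Unknown check type(s): ", collapse_vals(bad), call. = FALSE)
      indiv <- indiv[indiv$`Check Type` %in% accchk, , drop = FALSE]
    }
    return(indiv)
  }
  summary <- qc_summarize(indiv, bundle$config)
  if (type == "summary") return(summary)
  qc_percent(summary, bundle)
}

# evaluate every QC record once; exclusion notices are messages
qc_individual_all <- function(bundle) {
  results <- bundle$results
  acc <- bundle$accuracy
  config <- bundle$config
  roles <- record_roles(results, config)
  paired <- nzchar(as_chr(results[["QC Reference Value"]]))
  rows <- list()
  for (i in seq_len(nrow(results))) {
    rec <- results[i, , drop = FALSE]
    out <- switch(roles[i],
      field_blank = eval_blank(rec, acc, "field"),
      lab_blank   = eval_blank(rec, acc, "lab"),
      field_dup   = eval_duplicate(rec, acc, "field"),
      lab_dup     = eval_duplicate(rec, acc, "lab"),
      spike       = ,
      instrument_check = eval_spike(rec, acc),
      regular_field = if (paired[i]) eval_duplicate(rec, acc, "field"),
      regular_lab   = if (paired[i]) eval_duplicate(rec, acc, "lab"),
      NULL)
    if (!is.null(out)) rows[[length(rows) + 1]] <- out
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    out <- individual_row(character(0), character(0), character(0),
                          character(0), character(0), character(0), logical(0))
  ord <- match(out$`Check Type`, names(check_types()))
  out[order(ord, match(out$Parameter, param_order(unique(out$Parameter), bundle$config)),
            out$Date), , drop = FALSE]
}

qc_summarize <- function(indiv, config) {
  if (nrow(indiv) == 0)
    return(tibble::tibble(`Check Type` = character(0), Parameter = character(0),
                          `Number of QC Checks` = integer(0),
                          `Number of Misses` = integer(0),
                          `% Acceptance` = character(0)))
  out <- indiv |>
    dplyr::group_by(.data$`Check Type`, .data$Parameter) |>
    dplyr::summarise(`Number of QC Checks` = dplyr::n(),
                     `Number of Misses` = sum(.data$miss), .groups = "drop")
  out$`% Acceptance` <- vapply(seq_len(nrow(out)), function(i)
    paste0(percent_acceptance(out$`Number of QC Checks`[i],
                              out$`Number of Misses`[i]), "%"), "")
  ord <- order(match(out$`Check Type`, names(check_types())),
               match(out$Parameter, param_order(unique(out$Parameter), config)))
  out[ord, , drop = FALSE]
}

qc_percent <- function(summary, bundle) {
  config <- bundle$config
  params <- param_order(unique(c(summary$Parameter,
                                 bundle$results[["Characteristic Name"]])), config)
  types <- names(check_types())
  cells <- matrix("-", nrow = length(params), ncol = length(types),
                  dimnames = list(params, types))
  for (i in seq_len(nrow(summary))) {
    pct <- percent_acceptance_num(summary$`Number of QC Checks`[i],
                                  summary$`Number of Misses`[i])
    cells[summary$Parameter[i], summary$`Check Type`[i]] <- paste0(pct, "%")
  }
  out <- tibble::as_tibble(cbind(data.frame(Parameter = params,
                                            check.names = FALSE),
                                 as.data.frame(cells, check.names = FALSE)))
  if (!is.null(bundle$frecom)) {
    fre <- qc_frequency(bundle)
    met <- matrix(NA, nrow = length(params), ncol = length(types),
                  dimnames = list(params, types))
    for (i in seq_len(nrow(fre)))
      met[fre$Parameter[i], fre$`Check Type`[i]] <- fre$Met[i]
    attr(out, "met") <- tibble::as_tibble(cbind(
      data.frame(Parameter = params, check.names = FALSE),
      as.data.frame(met, check.names = FALSE)))
  }
  out
}

# count QC checks per parameter and check type (including same-row pairs)
qc_counts <- function(results, config) {
  roles <- record_roles(results, config)
  paired <- nzchar(as_chr(results[["QC Reference Value"]]))
  type_of <- rep(NA_character_, nrow(results))
  for (ct in names(check_types()))
    type_of[roles %in% check_types()[[ct]]] <- ct
  type_of[roles %in% "regular_field" & paired] <- "Field Duplicates"
  type_of[roles %in% "regular_lab" & paired] <- "Lab Duplicates"
  tibble::tibble(Parameter = as_chr(results[["Characteristic Name"]]),
                 `Check Type` = type_of)[!is.na(type_of), , drop = FALSE] |>
    dplyr::count(.data$Parameter, .data$`Check Type`, name = "n_qc")
}

#' Evaluate QC frequency against the data-quality objectives
#'
#' For each parameter and check type with a required frequency, compares the
#' observed QC frequency — `100 * n_qc / n_regular`, where `n_regular`
#' counts that parameter's regular (non-QC) records and `n_qc` counts its QC
#' checks of that type, including pairs entered in the `QC Reference Value`
#' column — against the required percent. Qualified samples are excluded
#' from the denominator by default (`config$frequency_excludes_qualified`).
#'
#' @inheritParams qc_accuracy
#' @return A tibble with `Parameter`, `Check Type`, `Number of Regular
#'   Samples`, `Number of QC Checks`, `Observed %`, `Required %`, `Met`.
#'   Parameters without a requirement are omitted; a zero denominator gives
#'   `NA` observed percent.
#' @export
qc_frequency <- function(bundle) {
  require_components(bundle, "QC reporting")
  results <- bundle$results
  config <- bundle$config
  roles <- record_roles(results, config)
  regular <- roles %in% c("regular_field", "regular_lab")
  if (isTRUE(config$frequency_excludes_qualified))
    regular <- regular & !is_qualified(results, config)
  n_reg <- tibble::tibble(Parameter = as_chr(results[["Characteristic Name"]])[regular]) |>
    dplyr::count(.data$Parameter, name = "n_regular")
  counts <- qc_counts(results, config)
  rows <- list()
  for (i in seq_len(nrow(bundle$frecom))) {
    param <- bundle$frecom$Parameter[i]
    for (ct in names(check_types())) {
      req <- num_or_na(bundle$frecom[[frecom_column(ct)]][i])
      if (is.na(req)) next
      nr <- n_reg$n_regular[match(param, n_reg$Parameter)]
      nr <- ifelse(is.na(nr), 0L, nr)
      nq <- counts$n_qc[counts$Parameter == param & counts$`Check Type` == ct]
      nq <- if (length(nq)) nq else 0L
      obs <- if (nr == 0) NA_real_ else 100 * nq / nr
      rows[[length(rows) + 1]] <- tibble::tibble(
        Parameter = param, `Check Type` = ct,
        `Number of Regular Samples` = nr, `Number of QC Checks` = nq,
        `Observed %` = obs, `Required %` = req,
        Met = !is.na(obs) & obs >= req)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble::tibble(Parameter = character(0), `Check Type` = character(0),
                          `Number of Regular Samples` = integer(0),
                          `Number of QC Checks` = integer(0),
                          `Observed %` = numeric(0), `Required %` = numeric(0),
                          Met = logical(0)))
  out[order(match(out$Parameter, param_order(unique(out$Parameter), config)),
            match(out$`Check Type`, names(check_types()))), , drop = FALSE]
}

#' Evaluate completeness against the data-quality objectives
#'
#' Completeness measures the proportion of a parameter's records usable as
#' regular data: `100 * (n_records - n_qualified) / n_records`, where
#' `n_records` counts regular (non-QC) records and `n_qualified` counts the
#' qualified ones among them (rows hosting a paired QC value or flagged by a
#' configured qualifier attribute). Parameters without a completeness
#' requirement are omitted.
#'
#' @inheritParams qc_accuracy
#' @return A tibble with `Parameter`, `Number of Records`,
#'   `Number Qualified`, `% Complete`, `Required %`, `Met`.
#' @export
qc_completeness <- function(bundle) {
  require_components(bundle, "QC reporting")
  results <- bundle$results
  config <- bundle$config
  roles <- record_roles(results, config)
  regular <- roles %in% c("regular_field", "regular_lab")
  qual <- is_qualified(results, config)
  params <- as_chr(results[["Characteristic Name"]])
  rows <- list()
  for (i in seq_len(nrow(bundle$frecom))) {
    param <- bundle$frecom$Parameter[i]
    req <- num_or_na(bundle$frecom[["% Completeness"]][i])
    if (is.na(req)) next
    n_rec <- sum(regular & params == param)
    n_qual <- sum(regular & qual & params == param)
    pct <- if (n_rec == 0) NA_real_ else 100 * (n_rec - n_qual) / n_rec
    rows[[length(rows) + 1]] <- tibble::tibble(
      Parameter = param, `Number of Records` = n_rec,
      `Number Qualified` = n_qual, `% Complete` = pct, `Required %` = req,
      Met = !is.na(pct) & pct >= req)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble::tibble(Parameter = character(0), `Number of Records` = integer(0),
                          `Number Qualified` = integer(0), `% Complete` = numeric(0),
                          `Required %` = numeric(0), Met = logical(0)))
  out[order(match(out$Parameter, param_order(unique(out$Parameter), config))), ,
      drop = FALSE]
}
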