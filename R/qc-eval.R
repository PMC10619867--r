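# Individual QC evaluators: blanks, duplicates, spikes/instrument checks,
# and the percent-acceptance arithmetic shared by all summary views.

#' Percent acceptance for a set of QC checks
#'
#' The acceptance rate shown in the QC summary tables:
#' `100 * (n_checks - n_misses) / n_checks`, rounded to the nearest integer
#' with halves away from zero (so 10/11 = 90.909 displays as 91 and 6/7 =
#' 85.714 as 86). When no checks are available the no-data marker `"-"` is
#' returned.
#'
#' @param n_checks number of QC checks evaluated (non-negative integer).
#' @param n_misses number of those checks that failed.
#' @param marker string returned when `n_checks` is zero.
#' @return Integer percent, or `marker` when there are no checks (hence the
#'   return value is character when any cell has no data; use
#'   `percent_acceptance_num()` for a numeric version with `NA`).
#' @examples
#' percent_acceptance(4, 1)   # 75
#' percent_acceptance(11, 1)  # 91
#' percent_acceptance(0, 0)   # "-"
#' @export
percent_acceptance <- function(n_checks, n_misses, marker = "-") {
  stopifnot(length(n_checks) == length(n_misses))
  if (any(n_checks < 0 | n_misses < 0, na.rm = TRUE))
    stop("Counts must be non-negative", call. = FALSE)
  if (any(n_misses > n_checks, na.rm = TRUE))
    stop("n_misses cannot exceed n_checks", call. = FALSE)
  num <- percent_acceptance_num(n_checks, n_misses)
  out <- as.character(num)
  out[is.na(num)] <- marker
  if (length(out) == 1 && !is.na(num)) return(num)
  out
}

#' @rdname percent_acceptance
#' @export
percent_acceptance_num <- function(n_checks, n_misses) {
  ifelse(n_checks == 0, NA_real_,
         round_half_up(100 * (n_checks - n_misses) / n_checks))
}

# select the accuracy rule row applicable to a parameter and measured value:
# rows are filtered by parameter and value range; the narrowest applicable
# range wins, ties broken by file order
rule_for <- function(accuracy, param, value = NA_real_) {
  rows <- accuracy[accuracy$Parameter == param, , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  ranges <- lapply(rows[["Value Range"]], parse_value_range)
  ok <- vapply(ranges, in_value_range, TRUE, value = value)
  if (!any(ok)) return(NULL)
  rows <- rows[ok, , drop = FALSE]
  widths <- vapply(ranges[ok], `[[`, numeric(1), "width")
  rows[which.min(widths), , drop = FALSE]
}

criterion_for <- function(rule, check_type) {
  if (is.null(rule)) return(structure(list(op = NA, magnitude = NA,
                                           kind = "none", log = FALSE),
                                      class = "aqc_criterion"))
  parse_criterion(rule[[criterion_column(check_type)]][1])
}

# shared display helpers (Table-style individual rows)
display_value <- function(raw, unit) {
  raw <- as_chr(raw)
  if (is_censor_token(raw)) return(toupper(raw))
  if (!nzchar(raw)) return("")
  paste(raw, unit)
}

display_threshold <- function(crit, unit) {
  switch(crit$kind,
    none = "",
    censored = crit$op,
    percent = paste0(fmt_num(crit$magnitude), "%"),
    absolute = paste(fmt_num(crit$magnitude), unit)
  )
}

individual_row <- function(check_type, param, date, site, result, threshold, miss) {
  tibble::tibble(`Check Type` = check_type, Parameter = param, Date = date,
                 Site = site, Result = result, Threshold = threshold,
                 `Hit/Miss` = ifelse(miss, "MISS", ""), miss = miss)
}

exclusion_notice <- function(check_type, param, why) {
  message("Excluded ", check_type, " record for ", param, ": ", why)
  NULL
}

#' Evaluate one blank QC record
#'
#' A blank (field or lab) verifies that an empty sample reads below a
#' threshold. A censored result (`BDL`) is a hit; a numeric result is a hit
#' iff it satisfies the criterion — under a strict `<` criterion a value
#' equal to the threshold is a MISS.
#'
#' @param record one-row results tibble (a blank activity row).
#' @param rule one-row accuracy tibble for the parameter (see
#'   [rule_for()]), or the full accuracy table (the applicable row is
#'   selected).
#' @param which `"field"` or `"lab"`: which blank criterion to apply.
#' @return One-row individual-result tibble (`Check Type`, `Parameter`,
#'   `Date`, `Site`, `Result`, `Threshold`, `Hit/Miss`, `miss`), or `NULL`
#'   with a logged notice when no criterion exists for the parameter.
#' @examples
#' acc <- tibble::tibble(Parameter = "TP", MDL = "0.005", UQL = "",
#'   `Value Range` = "all", `Field Duplicate` = "", `Lab Duplicate` = "",
#'   `Field Blank` = "< 0.01", `Lab Blank` = "", `Spike/Check Accuracy` = "")
#' rec <- tibble::tibble(`Characteristic Name` = "TP", `Result Value` = "0.01",
#'   `Result Unit` = "mg/l", `Activity Start Date` = "2022-07-17",
#'   `Monitoring Location ID` = "")
#' eval_blank(rec, acc, "field")$`Hit/Miss`  # "MISS": equal to a "<" threshold
#' @export
eval_blank <- function(record, rule, which = c("field", "lab")) {
  which <- match.arg(which)
  check_type <- if (which == "field") "Field Blanks" else "Lab Blanks"
  param <- as_chr(record[["Characteristic Name"]][1])
  raw <- as_chr(record[["Result Value"]][1])
  val <- num_or_na(raw)
  if (nrow(rule) != 1 || !identical(rule$Parameter[1], param))
    rule <- rule_for(rule, param, val)
  crit <- criterion_for(rule, check_type)
  if (is_na_criterion(crit))
    return(exclusion_notice(check_type, param, "no criterion in accuracy file"))
  unit <- as_chr(record[["Result Unit"]][1])
  if (crit$kind == "censored") {
    miss <- !identical(toupper(raw), crit$op)
  } else if (is_censor_token(raw)) {
    miss <- FALSE                       # below detection: blank is clean
  } else if (is.na(val)) {
    return(exclusion_notice(check_type, param, "no result value"))
  } else {
    miss <- !crit_compare(crit$op, val, crit$magnitude)
  }
  individual_row(check_type, param,
                 as_chr(record[["Activity Start Date"]][1]),
                 as_chr(record[["Monitoring Location ID"]][1]),
                 display_value(raw, unit), display_threshold(crit, unit), miss)
}

# substitute a censored member of a QC pair with the rule's limit
censored_sub <- function(raw, rule) {
  if (!is_censor_token(raw)) return(num_or_na(raw))
  lim <- if (toupper(trimws(raw)) == "BDL") num_or_na(rule$MDL[1]) else num_or_na(rule$UQL[1])
  lim
}

#' Evaluate one duplicate QC pair
#'
#' Duplicates assess precision. Under a percent criterion the pair is
#' compared by relative percent difference, `RPD = 100 |v - r| / mean(v, r)`;
#' under an absolute criterion by `|v - r|`. Both-censored pairs are hits
#' (the members are indistinguishable); mixed censored/numeric pairs
#' substitute the rule's MDL (for `BDL`) or UQL (for `AQL`) before
#' comparison, with the substitution logged. A zero pair mean with a percent
#' criterion falls back to an exact-equality test.
#'
#' @param record one-row results tibble carrying the pair: `Result Value`
#'   and `QC Reference Value`.
#' @inheritParams eval_blank
#' @export
eval_duplicate <- function(record, rule, which = c("field", "lab")) {
  which <- match.arg(which)
  check_type <- if (which == "field") "Field Duplicates" else "Lab Duplicates"
  param <- as_chr(record[["Characteristic Name"]][1])
  v_raw <- as_chr(record[["Result Value"]][1])
  r_raw <- as_chr(record[["QC Reference Value"]][1])
  if (!nzchar(r_raw))
    return(exclusion_notice(check_type, param, "no paired QC Reference Value"))
  if (nrow(rule) != 1 || !identical(rule$Parameter[1], param))
    rule <- rule_for(rule, param, num_or_na(v_raw))
  crit <- criterion_for(rule, check_type)
  if (is_na_criterion(crit))
    return(exclusion_notice(check_type, param, "no criterion in accuracy file"))
  unit <- as_chr(record[["Result Unit"]][1])
  date <- as_chr(record[["Activity Start Date"]][1])
  site <- as_chr(record[["Monitoring Location ID"]][1])
  res_disp <- paste(display_value(v_raw, unit), display_value(r_raw, unit), sep = " / ")
  if (is_censor_token(v_raw) && is_censor_token(r_raw))
    return(individual_row(check_type, param, date, site, res_disp,
                          display_threshold(crit, unit), FALSE))
  if (is_censor_token(v_raw) || is_censor_token(r_raw))
    message("Substituting detection limit for censored member of ", check_type,
            " pair (", param, ")")
  v <- censored_sub(v_raw, rule)
  r <- censored_sub(r_raw, rule)
  if (is.na(v) || is.na(r))
    return(exclusion_notice(check_type, param,
                            "censored member without MDL/UQL in accuracy file"))
  if (crit$kind == "percent") {
    m <- mean(c(v, r))
    stat <- if (m == 0) {
      if (v == r) 0 else Inf            # zero mean: hit iff identical
    } else 100 * abs(v - r) / m
  } else {
    stat <- abs(v - r)
  }
  miss <- !crit_compare(crit$op, stat, crit$magnitude)
  individual_row(check_type, param, date, site, res_disp,
                 display_threshold(crit, unit), miss)
}

#' Evaluate one spike or instrument-check record
#'
#' Spikes and calibration checks verify accuracy against a known quantity
#' held in `QC Reference Value`. Under a percent criterion the statistic is
#' `100 |measured - known| / known` (the deviation from 100% recovery);
#' under an absolute criterion, `|measured - known|`. A zero known quantity
#' with a percent criterion excludes the record with a notice.
#'
#' @inheritParams eval_duplicate
#' @export
eval_spike <- function(record, rule) {
  check_type <- "Lab Spikes / Instrument Checks"
  param <- as_chr(record[["Characteristic Name"]][1])
  v <- num_or_na(record[["Result Value"]][1])
  r <- num_or_na(record[["QC Reference Value"]][1])
  if (is.na(r))
    return(exclusion_notice(check_type, param, "no known quantity in QC Reference Value"))
  if (is.na(v))
    return(exclusion_notice(check_type, param, "no measured value"))
  if (nrow(rule) != 1 || !identical(rule$Parameter[1], param))
    rule <- rule_for(rule, param, v)
  crit <- criterion_for(rule, check_type)
  if (is_na_criterion(crit))
    return(exclusion_notice(check_type, param, "no criterion in accuracy file"))
  unit <- as_chr(record[["Result Unit"]][1])
  if (crit$kind == "percent") {
    if (r == 0)
      return(exclusion_notice(check_type, param,
                              "known quantity is zero with percent criterion"))
    stat <- 100 * abs(v - r) / r
  } else {
    stat <- abs(v - r)
  }
  miss <- !crit_compare(crit$op, stat, crit$magnitude)
  individual_row(check_type, param,
                 as_chr(record[["Activity Start Date"]][1]),
                 as_chr(record[["Monitoring Location ID"]][1]),
                 paste(display_value(record[["Result Value"]][1], unit), "vs",
                       display_value(record[["QC Reference Value"]][1], unit)),
                 display_threshold(crit, unit), miss)
}
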