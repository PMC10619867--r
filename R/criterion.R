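#' Data-quality-objective criterion grammar
#'
#' Accuracy criteria are written in the DQO accuracy table as small
#' expressions: a comparison operator and a number (`"< 0.1"`), optionally
#' suffixed with `%` for a relative criterion (`"<= 30%"`); the bare tokens
#' `BDL` or `AQL` meaning the QC result must itself be censored; and the token
#' `log`, which carries no pass/fail meaning but marks the parameter as
#' log-distributed for plotting and summarization. An empty cell means the
#' check does not apply. `parse_criterion()` parses one cell;
#' `format_criterion()` prints a parsed criterion back in canonical form
#' (parse/print round-trips).
#'
#' @param text one criterion cell as a string.
#' @return `parse_criterion()`: a list of class `aqc_criterion` with elements
#'   `op` (`"<" "<=" ">" ">="` or `NA`), `magnitude` (number or `NA`), `kind`
#'   (`"percent"`, `"absolute"`, `"censored"`, or `"none"`), and `log`
#'   (logical, `TRUE` if the `log` token was present). Malformed cells error
#'   with the offending text.
#' @examples
#' parse_criterion("<= 30%")
#' parse_criterion("< 0.1")
#' format_criterion(parse_criterion("<=30%"))
#' @export
parse_criterion <- function(text) {
  raw <- as_chr(text)[1]
  toks <- strsplit(raw, "\\s+")[[1]]
  has_log <- any(tolower(toks) == "log")
  rest <- paste(toks[tolower(toks) != "log"], collapse = " ")
  out <- list(op = NA_character_, magnitude = NA_real_, kind = "none", log = has_log)
  if (!nzchar(rest)) return(structure(out, class = "aqc_criterion"))
  if (toupper(rest) %in% c("BDL", "AQL")) {
    out$kind <- "censored"
    out$magnitude <- NA_real_
    out$op <- toupper(rest)  # which censoring token is required
    return(structure(out, class = "aqc_criterion"))
  }
  m <- regmatches(rest, regexec("^(<=|>=|<|>)\\s*([0-9]*\\.?[0-9]+)\\s*(%?)$", rest))[[1]]
  if (length(m) == 0)
    stop("Malformed criterion: '", raw, "'", call. = FALSE)
  out$op <- m[2]
  out$magnitude <- as.numeric(m[3])
  out$kind <- if (m[4] == "%") "percent" else "absolute"
  structure(out, class = "aqc_criterion")
}

#' @rdname parse_criterion
#' @param crit a parsed criterion.
#' @export
format_criterion <- function(crit) {
  body <- switch(crit$kind,
    none = "",
    censored = crit$op,
    percent = paste0(crit$op, " ", fmt_num(crit$magnitude), "%"),
    absolute = paste0(crit$op, " ", fmt_num(crit$magnitude))
  )
  if (crit$log) body <- trimws(paste(body, "log"))
  body
}

# apply the comparison operator
crit_compare <- function(op, x, magnitude) {
  switch(op,
    "<"  = x <  magnitude,
    "<=" = x <= magnitude,
    ">"  = x >  magnitude,
    ">=" = x >= magnitude,
    stop("No operator in criterion", call. = FALSE)
  )
}

is_na_criterion <- function(crit) identical(crit$kind, "none")

# parse a Value Range cell: "all"/"" (always applies) or "<op> number"
parse_value_range <- function(text) {
  raw <- as_chr(text)[1]
  if (!nzchar(raw) || tolower(raw) == "all") {
    return(list(op = NA_character_, magnitude = NA_real_, all = TRUE, width = Inf))
  }
  m <- regmatches(raw, regexec("^(<=|>=|<|>)\\s*([0-9]*\\.?[0-9]+)$", raw))[[1]]
  if (length(m) == 0) stop("Malformed value range: '", raw, "'", call. = FALSE)
  list(op = m[2], magnitude = as.numeric(m[3]), all = FALSE,
       width = as.numeric(m[3]))
}

# does a measured value fall inside a value range?
in_value_range <- function(range, value) {
  if (range$all) return(TRUE)
  if (is.na(value)) return(TRUE)  # censored values match any range
  crit_compare(range$op, value, range$magnitude)
}
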