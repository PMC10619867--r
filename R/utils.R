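# shared helpers: rounding, string coercion, numeric parsing

# round half away from zero (Table-style percent display: 90.909 -> 91, 85.5 -> 86)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# TRUE for empty-ish cells: NA or whitespace-only
is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

# coerce any cell to a trimmed string; NA -> ""
as_chr <- function(x) {
  out <- trimws(as.character(x))
  out[is.na(x)] <- ""
  out
}

# strict numeric parse: returns NA for anything that is not a plain number
num_or_na <- function(x) {
  x <- trimws(as.character(x))
  suppressWarnings(as.numeric(x))
}

is_censor_token <- function(x) toupper(trimws(as.character(x))) %in% c("BDL", "AQL")

# format a number for display without scientific notation or trailing zeros
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

# join values as "a, b" and rows as "4, 135" for row-addressed messages
collapse_vals <- function(x) paste(unique(x), collapse = ", ")

geomean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires positive values", call. = FALSE)
  exp(mean(log(x)))
}
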