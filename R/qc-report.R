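# Assembled QC review: all DQO and QC tables in one object, rendered to a
# single report document.

md_table <- function(df) {
  df <- as.data.frame(df, check.names = FALSE)
  if (nrow(df) == 0) return("*(no records)*")
  fmt <- function(x) {
    x <- vapply(x, function(v) {
      if (is.numeric(v)) return(fmt_num(round(v, 1)))
      as_chr(v)
    }, "", USE.NAMES = FALSE)
    gsub("|", "\\|", x, fixed = TRUE)
  }
  cells <- lapply(df, function(col) {
    if (is.logical(col)) ifelse(is.na(col), "", ifelse(col, "MET", "MISS"))
    else if (is.numeric(col)) ifelse(is.na(col), "-", fmt_num(round(col, 1)))
    else as_chr(col)
  })
  hdr <- paste0("| ", paste(fmt(names(df)), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- vapply(seq_len(nrow(df)), function(i)
    paste0("| ", paste(vapply(cells, function(c) gsub("|", "\\|", c[i], fixed = TRUE), ""),
                       collapse = " | "), " |"), "")
  paste(c(hdr, sep, body), collapse = "\n")
}

#' Assemble the full QC review
#'
#' Runs every QC evaluation against the bundle and collects the results in
#' one object: the data-quality objectives themselves (accuracy; frequency
#' and completeness), the frequency and completeness results with met/miss
#' flags, the accuracy summary, the acceptance-percent matrix, and the
#' individual tables per check type.
#'
#' @inheritParams qc_accuracy
#' @param organization organization name shown in the report header.
#' @param notes free-text notes appended to the report.
#' @return An object of class `aqc_review` (a named list of tibbles plus
#'   metadata). Use [write_qc_report()] to render it, [tidy()] for the
#'   accuracy summary, and [glance()] for one-row DQO pass rates.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' rev <- qc_review(qc_bundle(b$results, b$accuracy, b$frecom))
#' glance(rev)
#' @export
qc_review <- function(bundle, organization = "", notes = "") {
  require_components(bundle, "QC reporting")
  indiv <- qc_accuracy(bundle, type = "individual")
  structure(list(
    dqo_accuracy = tibble::as_tibble(bundle$accuracy),
    dqo_frecom = tibble::as_tibble(bundle$frecom),
    frequency = qc_frequency(bundle),
    completeness = qc_completeness(bundle),
    accuracy_summary = qc_summarize(indiv, bundle$config),
    accuracy_percent = qc_percent(qc_summarize(indiv, bundle$config), bundle),
    individual = indiv,
    organization = organization,
    notes = notes
  ), class = "aqc_review")
}

#' @export
print.aqc_review <- function(x, ...) {
  cat("QC review\n")
  cat("  Frequency checks:   ", nrow(x$frequency),
      " (", sum(x$frequency$Met), " met)\n", sep = "")
  cat("  Completeness checks:", nrow(x$completeness),
      " (", sum(x$completeness$Met), " met)\n", sep = "")
  cat("  Accuracy records:   ", nrow(x$individual),
      " (", sum(x$individual$miss), " misses)\n", sep = "")
  invisible(x)
}

#' @rdname qc_review
#' @param x an `aqc_review` object.
#' @param ... unused.
#' @method tidy aqc_review
#' @export
tidy.aqc_review <- function(x, ...) {
  out <- x$accuracy_summary
  out$`% Acceptance` <- NULL
  out$pct_accept <- percent_acceptance_num(out$`Number of QC Checks`,
                                           out$`Number of Misses`)
  out
}

#' @rdname qc_review
#' @method glance aqc_review
#' @export
glance.aqc_review <- function(x, ...) {
  tibble::tibble(
    n_accuracy_checks = nrow(x$individual),
    n_accuracy_misses = sum(x$individual$miss),
    n_frequency_rules = nrow(x$frequency),
    n_frequency_met = sum(x$frequency$Met),
    n_completeness_rules = nrow(x$completeness),
    n_completeness_met = sum(x$completeness$Met)
  )
}

# deterministic markdown body (no timestamps)
report_body <- function(review) {
  fre <- review$frequency
  com <- review$completeness
  pct <- review$accuracy_percent
  met <- attr(pct, "met")
  if (!is.null(met)) {
    # append the textual MISS marker so the flag survives uncolored formats
    for (ct in setdiff(names(pct), "Parameter"))
      pct[[ct]] <- ifelse(!is.na(met[[ct]]) & !met[[ct]] & pct[[ct]] != "-",
                          paste(pct[[ct]], "MISS"), pct[[ct]])
  }
  sections <- c(
    "# Quality Control Report",
    if (nzchar(review$organization)) paste0("Organization: ", review$organization),
    "## 1. Data Quality Objectives",
    "### Accuracy", md_table(review$dqo_accuracy),
    "### Frequency and Completeness", md_table(review$dqo_frecom),
    "## 2. Frequency Results", md_table(fre),
    "## Completeness Results", md_table(com),
    "## 3. Accuracy Summary", md_table(review$accuracy_summary),
    "## 4. Acceptance Percent Matrix", md_table(pct),
    "## 5. Individual Results"
  )
  for (ct in names(check_types())) {
    sub <- review$individual[review$individual$`Check Type` == ct, , drop = FALSE]
    sub$miss <- NULL
    sub$`Check Type` <- NULL
    sections <- c(sections, paste0("### ", ct), md_table(sub))
  }
  if (nzchar(review$notes)) sections <- c(sections, "## Notes", review$notes)
  paste(sections, collapse = "\n\n")
}

#' Write the QC report document
#'
#' Renders an assembled review to a single editable document. Markdown is
#' always available; `html` and `docx` require pandoc (via the rmarkdown
#' package). Section order: DQO tables, frequency and completeness results
#' (failing parameters carry a textual `MISS` marker), accuracy summary,
#' acceptance-percent matrix, then the individual tables per check type.
#' Identical reviews produce byte-identical report bodies.
#'
#' @param review an `aqc_review` from [qc_review()].
#' @param output_dir directory to write into (created if needed).
#' @param format `"md"`, `"html"`, or `"docx"`.
#' @param file_name base file name without extension.
#' @return The output path, invisibly; a success message names it.
#' @export
write_qc_report <- function(review, output_dir = ".", format = c("md", "html", "docx"),
                            file_name = "qc_report") {
  stopifnot(inherits(review, "aqc_review"))
  format <- match.arg(format)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir))
    stop("Cannot create output directory: ", output_dir, call. = FALSE)
  body <- report_body(review)
  md_path <- file.path(output_dir, paste0(file_name, ".md"))
  writeLines(body, md_path, useBytes = TRUE)
  out <- md_path
  if (format != "md") {
    if (!requireNamespace("rmarkdown", quietly = TRUE) ||
        !rmarkdown::pandoc_available())
      stop("Formats 'html' and 'docx' require pandoc (rmarkdown)", call. = FALSE)
    out <- file.path(output_dir, paste0(file_name, ".", format))
    rmarkdown::pandoc_convert(normalizePath(md_path), to = format,
                              output = normalizePath(out, mustWork = FALSE),
                              options = if (format == "html") "--standalone")
  }
  message("Report created successfully! File located at ", normalizePath(out))
  invisible(out)
}
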