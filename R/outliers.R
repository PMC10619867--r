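# Outlier screening with the 1.5 x IQR rule, per parameter within
# user-chosen groups.

#' Substitute censored values with detection-limit surrogates
#'
#' For analysis (outlier screening and summaries) censored tokens are
#' replaced with conventional surrogates: `BDL` becomes half the method
#' detection limit (`mdl / 2`), `AQL` becomes the upper quantification limit
#' (`uql`); numeric entries pass through. Tokens without the corresponding
#' limit yield `NA` and a logged notice (the record is excluded downstream).
#'
#' @param values character vector of raw result values (numbers or tokens).
#' @param mdl,uql detection limits from the accuracy rule for the parameter.
#' @param quiet suppress substitution notices.
#' @return Numeric vector, `NA` where no substitute exists.
#' @examples
#' substitute_censored(c("BDL", "0.3", "AQL"), mdl = 0.1, uql = 10)
#' @export
substitute_censored <- function(values, mdl = NA, uql = NA, quiet = FALSE) {
  raw <- as_chr(values)
  out <- num_or_na(raw)
  tok <- toupper(raw)
  bdl <- tok == "BDL"
  aql <- tok == "AQL"
  out[bdl] <- if (is.na(num_or_na(mdl))) NA_real_ else num_or_na(mdl) / 2
  out[aql] <- if (is.na(num_or_na(uql))) NA_real_ else num_or_na(uql)
  if (!quiet) {
    n_sub <- sum((bdl & !is.na(out)) | (aql & !is.na(out)))
    n_drop <- sum((bdl | aql) & is.na(out))
    if (n_sub > 0) message(n_sub, " censored value(s) substituted (BDL -> MDL/2, AQL -> UQL)")
    if (n_drop > 0) message(n_drop, " censored value(s) excluded: no MDL/UQL available")
  }
  out
}

#' Quartile bounds for the 1.5 x IQR outlier rule
#'
#' @param x numeric values (one group).
#' @param k whisker multiplier (default 1.5).
#' @return A list with `q1`, `q3`, `iqr`, `lo = q1 - k * iqr`,
#'   `hi = q3 + k * iqr`. Quartiles use linear interpolation between order
#'   statistics (the default type-7 estimator).
#' @export
outlier_bounds <- function(x, k = 1.5) {
  q <- unname(quantile(x, c(0.25, 0.75), type = 7, na.rm = TRUE))
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1],
       lo = q[1] - k * (q[2] - q[1]), hi = q[2] + k * (q[2] - q[1]))
}

# group labels for the x axis
outlier_groups <- function(dates, sites, group) {
  d <- as.Date(dates)
  switch(group,
    month = format(d, "%b"),
    week  = format(d, "%G-W%V"),       # ISO week
    year  = format(d, "%Y"),
    site  = sites,
    stop("Unknown group: ", group, call. = FALSE))
}

# regular records for one parameter with censored values substituted; the
# shared starting point for outlier screening and the summary views
analysis_frame <- function(bundle, param, quiet = FALSE, drop_nonpositive = TRUE) {
  results <- bundle$results
  config <- bundle$config
  if (!param %in% as_chr(results[["Characteristic Name"]]))
    stop("Parameter not present in results: ", param, call. = FALSE)
  roles <- record_roles(results, config)
  keep <- roles %in% c("regular_field", "regular_lab") &
    as_chr(results[["Characteristic Name"]]) == param
  df <- results[keep, , drop = FALSE]
  rule <- rule_for(bundle$accuracy, param)
  mdl <- if (is.null(rule)) NA else rule$MDL[1]
  uql <- if (is.null(rule)) NA else rule$UQL[1]
  df$value <- substitute_censored(df[["Result Value"]], mdl, uql, quiet = quiet)
  scale <- if (!is.null(rule) && identical(rule$scale_hint[1], "log")) "log" else "linear"
  if (scale == "log" && drop_nonpositive) {
    bad <- !is.na(df$value) & df$value <= 0
    if (any(bad) && !quiet)
      message(sum(bad), " non-positive value(s) excluded on log scale")
    df$value[bad] <- NA
  }
  df <- df[!is.na(df$value), , drop = FALSE]
  attr(df, "scale") <- scale
  df
}

# analysis frame plus group labels for the outlier x axis
outlier_frame <- function(bundle, param, group, quiet = FALSE) {
  df <- analysis_frame(bundle, param, quiet = quiet)
  scale <- attr(df, "scale")
  df$grp <- outlier_groups(df[["Activity Start Date"]],
                           df[["Monitoring Location ID"]], group)
  attr(df, "scale") <- scale
  df
}

#' Screen a parameter for outliers within groups
#'
#' Within each group (month, ISO week, year, or site), an observation is
#' flagged iff it falls strictly outside `[q1 - k*iqr, q3 + k*iqr]` of that
#' group's quartiles. For parameters marked log-distributed in the accuracy
#' DQOs, quartiles are computed on log10 values (flags are invariant to any
#' strictly monotone transform applied consistently, so this only matters
#' through the quantile interpolation). Censored values are substituted
#' first (see [substitute_censored()]). Groups with fewer than `min_n`
#' observations produce no flags and a logged notice. Note that flags are
#' specific to the grouping choice: the same value can be an outlier within
#' its month but not within its site.
#'
#' @inheritParams qc_accuracy
#' @param param parameter (Characteristic Name) to screen.
#' @param group `"month"`, `"week"`, `"year"`, or `"site"`.
#' @param k whisker multiplier (default 1.5).
#' @param min_n minimum group size for quartile stability (default 4).
#' @param quiet suppress notices.
#' @return A tibble of flagged observations with the six columns
#'   `Monitoring Location ID`, `Activity Start Date`, `Activity Start Time`,
#'   `Characteristic Name`, `Result Value` (numeric, after substitution),
#'   `Result Unit`.
#' @examples
#' b <- generate_bundle(fixture_spec(seed = 1))
#' bd <- qc_bundle(b$results, b$accuracy, b$frecom)
#' screen_outliers(bd, param = "DO", group = "month", quiet = TRUE)
#' @export
screen_outliers <- function(bundle, param, group = c("month", "week", "year", "site"),
                            k = 1.5, min_n = 4, quiet = FALSE) {
  group <- match.arg(group)
  require_components(bundle, "Data analysis")
  df <- outlier_frame(bundle, param, group, quiet = quiet)
  scale <- attr(df, "scale")
  flag <- rep(FALSE, nrow(df))
  for (g in unique(df$grp)) {
    idx <- which(df$grp == g)
    if (length(idx) < min_n) {
      if (!quiet) message("Group '", g, "' has fewer than ", min_n,
                          " observations; not screened")
      next
    }
    v <- df$value[idx]
    if (scale == "log") v <- log10(v)
    b <- outlier_bounds(v, k = k)
    flag[idx] <- v < b$lo | v > b$hi
  }
  hits <- df[flag, , drop = FALSE]
  tibble::tibble(
    `Monitoring Location ID` = as_chr(hits[["Monitoring Location ID"]]),
    `Activity Start Date` = as_chr(hits[["Activity Start Date"]]),
    `Activity Start Time` = as_chr(hits[["Activity Start Time"]]),
    `Characteristic Name` = as_chr(hits[["Characteristic Name"]]),
    `Result Value` = hits$value,
    `Result Unit` = as_chr(hits[["Result Unit"]]))
}

#' Boxplot of a parameter with outliers labelled by station
#'
#' @inheritParams screen_outliers
#' @return A ggplot object: boxplots per group, flagged points labelled with
#'   their Monitoring Location ID; log10 y-axis when the accuracy DQOs mark
#'   the parameter as log-distributed.
#' @export
plot_outliers <- function(bundle, param, group = c("month", "week", "year", "site"),
                          k = 1.5, min_n = 4, quiet = TRUE) {
  group <- match.arg(group)
  df <- outlier_frame(bundle, param, group, quiet = quiet)
  scale <- attr(df, "scale")
  hits <- screen_outliers(bundle, param, group, k = k, min_n = min_n, quiet = TRUE)
  df$is_out <- paste(df[["Monitoring Location ID"]], df[["Activity Start Date"]],
                     df$value) %in%
    paste(hits[["Monitoring Location ID"]], hits[["Activity Start Date"]],
          hits[["Result Value"]])
  if (group == "month")
    df$grp <- factor(df$grp, levels = month.abb)
  unit <- unique(as_chr(df[["Result Unit"]]))[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grp, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_point(data = df[df$is_out, , drop = FALSE], colour = "firebrick") +
    ggplot2::geom_text(data = df[df$is_out, , drop = FALSE],
                       ggplot2::aes(label = .data$`Monitoring Location ID`),
                       hjust = -0.15, size = 3) +
    ggplot2::labs(x = NULL, y = paste0(param, if (!is.na(unit) && nzchar(unit))
      paste0(" (", unit, ")") else ""), title = paste0(param, " by ", group)) +
    ggplot2::theme_minimal()
  if (scale == "log") p <- p + ggplot2::scale_y_log10()
  p
}

#' Outlier screening for every parameter, exported in batch
#'
#' Renders the outlier boxplot for every parameter in the results file,
#' either as one image file per parameter or as a single markdown document
#' embedding all plots (convertible to docx with pandoc). Parameters are
#' processed in dictionary order, so output is deterministic.
#'
#' @inheritParams screen_outliers
#' @param format `"images"` (one png per parameter) or `"doc"` (one
#'   markdown document embedding the pngs).
#' @param output_dir directory to write into.
#' @return Character vector of files written, invisibly.
#' @export
batch_outliers <- function(bundle, group = "month", format = c("images", "doc"),
                           output_dir = ".") {
  format <- match.arg(format)
  require_components(bundle, "Data analysis")
  params <- param_order(unique(as_chr(bundle$results[["Characteristic Name"]])),
                        bundle$config)
  if (length(params) == 0) stop("No parameters in results file", call. = FALSE)
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  safe <- gsub("[^A-Za-z0-9]+", "_", params)
  paths <- file.path(output_dir, paste0("outliers_", safe, ".png"))
  for (i in seq_along(params)) {
    p <- plot_outliers(bundle, params[i], group = group)
    ggplot2::ggsave(paths[i], p, width = 7, height = 4.5, dpi = 150)
  }
  if (format == "doc") {
    doc <- file.path(output_dir, "outliers.md")
    writeLines(c("# Outlier screening",
                 unlist(lapply(seq_along(params), function(i)
                   c(paste0("## ", params[i]),
                     paste0("![", params[i], "](", basename(paths[i]), ")"))))),
               doc)
    paths <- c(paths, doc)
  }
  message("Outlier output written to ", output_dir)
  invisible(paths)
}
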