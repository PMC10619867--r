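# Seasonal, date-series, per-site, and spatial summary views with
# DQO-driven scale and summary-function selection and threshold overlays.

stat_fun <- function(name) {
  switch(name,
    mean = function(x) mean(x),
    geomean = geomean,
    median = function(x) median(x),
    min = function(x) min(x),
    max = function(x) max(x),
    stop("Unknown summary function: ", name, call. = FALSE))
}

#' Resolve axis scale and summary function for a parameter
#'
#' With `sumfun = "auto"` and `yscl = "auto"` (the defaults) the behavior is
#' driven by the accuracy DQO table: parameters carrying the `log` token in
#' any criterion column get a log10 axis and are summarized with the
#' geometric mean; all others get a linear axis and the arithmetic mean.
#' Explicit settings override the automatic choice independently.
#'
#' @param param parameter name.
#' @param accuracy accuracy table from [read_accuracy()].
#' @param sumfun `"auto"`, `"mean"`, `"geomean"`, `"median"`, `"min"`, `"max"`.
#' @param yscl `"auto"`, `"linear"`, `"log"`.
#' @return List with `scale` (`"linear"`/`"log"`), `sumfun` (resolved name),
#'   and `fn` (the summary function).
#' @examples
#' acc <- tibble::tibble(Parameter = "E.coli", MDL = "", UQL = "",
#'   `Value Range` = "all", `Field Duplicate` = "<= 30% log",
#'   `Lab Duplicate` = "", `Field Blank` = "", `Lab Blank` = "",
#'   `Spike/Check Accuracy` = "", scale_hint = "log")
#' resolve_settings("E.coli", acc)$sumfun  # "geomean"
#' @export
resolve_settings <- function(param, accuracy,
                             sumfun = c("auto", "mean", "geomean", "median", "min", "max"),
                             yscl = c("auto", "linear", "log")) {
  sumfun <- match.arg(sumfun)
  yscl <- match.arg(yscl)
  rule <- rule_for(accuracy, param)
  hinted_log <- !is.null(rule) && identical(rule$scale_hint[1], "log")
  scale <- if (yscl == "auto") (if (hinted_log) "log" else "linear") else yscl
  fn_name <- if (sumfun == "auto") (if (hinted_log) "geomean" else "mean") else sumfun
  list(scale = scale, sumfun = fn_name, fn = stat_fun(fn_name))
}

# one summary point per group: stat plus optional 95% CI (normal theory;
# computed on the log scale then back-transformed for geometric means)
summarize_values <- function(df, fn_name, confint = FALSE) {
  fn <- stat_fun(fn_name)
  if (any(df$value <= 0) && fn_name == "geomean") {
    bad <- df[df$value <= 0, , drop = FALSE]
    stop("Geometric mean requires positive values; offending record(s): ",
         paste(utils::head(paste(bad[["Monitoring Location ID"]],
                                 bad[["Activity Start Date"]]), 5), collapse = "; "),
         call. = FALSE)
  }
  df |>
    dplyr::group_by(.data$grp) |>
    dplyr::summarise(stat = fn(.data$value), n = dplyr::n(),
                     lo = ci_bound(.data$value, fn_name, confint, lower = TRUE),
                     hi = ci_bound(.data$value, fn_name, confint, lower = FALSE),
                     .groups = "drop") |>
    dplyr::rename(group_label = "grp") |>
    dplyr::relocate("group_label", "stat", "lo", "hi", "n")
}

ci_bound <- function(x, fn_name, confint, lower) {
  if (!confint || length(x) < 2 || !fn_name %in% c("mean", "geomean"))
    return(NA_real_)
  z <- qnorm(0.975)
  if (fn_name == "geomean") {
    lx <- log(x)
    m <- mean(lx); se <- sd(lx) / sqrt(length(lx))
    exp(m + (if (lower) -1 else 1) * z * se)
  } else {
    m <- mean(x); se <- sd(x) / sqrt(length(x))
    m + (if (lower) -1 else 1) * z * se
  }
}

# threshold overlay rows for a parameter/context
threshold_lines <- function(config, param, thresh) {
  if (identical(thresh, "none")) return(config$thresholds[0, , drop = FALSE])
  th <- config$thresholds
  th[th$Parameter == param & th$Context == thresh, , drop = FALSE]
}

# restrict to requested Result Attribute values, erroring informatively
filter_resultatt <- function(df, resultatt) {
  if (is.null(resultatt)) return(df)
  avail <- unique(as_chr(df[["Result Attribute"]]))
  bad <- setdiff(resultatt, avail)
  if (length(bad))
    stop("Result Attribute value(s) not present: ", collapse_vals(bad),
         "; available: ", collapse_vals(avail[nzchar(avail)]), call. = FALSE)
  df[as_chr(df[["Result Attribute"]]) %in% resultatt, , drop = FALSE]
}

#' Seasonal summary of a parameter
#'
#' Groups regular records by calendar month or ISO week and computes one
#' summary point per group with the resolved summary function (see
#' [resolve_settings()]); optional 95% confidence intervals for mean and
#' geometric mean.
#'
#' @inheritParams qc_accuracy
#' @param param parameter to summarize.
#' @param group `"month"` or `"week"`.
#' @param sumfun,yscl see [resolve_settings()].
#' @param resultatt optional Result Attribute values to keep (e.g.
#'   `c("DRY", "WET")`); unknown values error listing what is available.
#' @param confint add 95% confidence bounds.
#' @return Tibble with `group_label`, `stat`, `lo`, `hi`, `n`.
#' @export
summarize_season <- function(bundle, param, group = c("month", "week"),
                             sumfun = "auto", yscl = "auto", resultatt = NULL,
                             confint = FALSE) {
  group <- match.arg(group)
  require_components(bundle, "Data analysis")
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df <- filter_resultatt(df, resultatt)
  df$grp <- outlier_groups(df[["Activity Start Date"]],
                           df[["Monitoring Location ID"]], group)
  out <- summarize_values(df, set$sumfun, confint)
  if (group == "month")
    out <- out[order(match(out$group_label, month.abb)), , drop = FALSE]
  out
}

#' Per-site summary of a parameter
#'
#' One summary point per site, optionally restricted to chosen sites (axis
#' order preserved as given) and split by Result Attribute values.
#'
#' @inheritParams summarize_season
#' @param site optional character vector of site ids to keep, in display
#'   order.
#' @param byresultatt split each site by Result Attribute value.
#' @return Tibble with `group_label` (site id), optional `result_attribute`,
#'   `stat`, `lo`, `hi`, `n`.
#' @export
summarize_site <- function(bundle, param, site = NULL, sumfun = "auto",
                           yscl = "auto", resultatt = NULL, byresultatt = FALSE,
                           confint = FALSE) {
  require_components(bundle, "Data analysis")
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df <- filter_resultatt(df, resultatt)
  if (!is.null(site)) {
    df <- df[as_chr(df[["Monitoring Location ID"]]) %in% site, , drop = FALSE]
  }
  df$grp <- as_chr(df[["Monitoring Location ID"]])
  if (byresultatt) {
    out <- df |>
      dplyr::group_by(ratt = as_chr(.data$`Result Attribute`)) |>
      dplyr::group_modify(~ summarize_values(.x, set$sumfun, confint)) |>
      dplyr::ungroup() |>
      dplyr::rename(result_attribute = "ratt") |>
      dplyr::relocate("group_label")
  } else {
    out <- summarize_values(df, set$sumfun, confint)
  }
  if (!is.null(site))
    out <- out[order(match(out$group_label, site)), , drop = FALSE]
  out
}

#' Time series of a parameter by date
#'
#' Aggregates records per sample date, either for each site
#' (`group = "site"`), for each location group from the site metadata file
#' (`group = "locgroup"`), or across all sites (`group = "all"`). The
#' statistic is the resolved summary function; optional 95% confidence
#' intervals apply to mean and geometric mean (computed on the log scale and
#' back-transformed for the latter). Sites with no Location Group entry are
#' dropped with a notice under `group = "locgroup"`.
#'
#' @inheritParams summarize_season
#' @param group `"site"`, `"locgroup"`, or `"all"`.
#' @return Tibble with `date`, `group_label`, `stat`, `lo`, `hi`, `n`.
#' @export
summarize_date <- function(bundle, param, group = c("site", "locgroup", "all"),
                           sumfun = "auto", yscl = "auto", confint = FALSE) {
  group <- match.arg(group)
  require_components(bundle, "Data analysis")
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df$site <- as_chr(df[["Monitoring Location ID"]])
  if (group == "locgroup") {
    if (is.null(bundle$sites))
      stop("Grouping by location group requires the sites file", call. = FALSE)
    lg <- setNames(as_chr(bundle$sites[["Location Group"]]),
                   as_chr(bundle$sites[["Monitoring Location ID"]]))
    df$gl <- unname(lg[df$site])
    drop <- is.na(df$gl) | !nzchar(df$gl)
    if (any(drop))
      message(length(unique(df$site[drop])),
              " site(s) without a Location Group dropped")
    df <- df[!drop, , drop = FALSE]
  } else if (group == "site") {
    df$gl <- df$site
  } else {
    df$gl <- "all"
  }
  out <- df |>
    dplyr::group_by(date = .data$`Activity Start Date`, grp = .data$gl) |>
    dplyr::group_modify(function(d, key) {
      d$grp <- "x"
      s <- summarize_values(d, set$sumfun, confint)
      s$group_label <- NULL
      s
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(group_label = "grp")
  out
}

#' Per-site spatial aggregate of a parameter
#'
#' One row per site with at least one observation: site id, coordinates from
#' the site metadata file, and the aggregate of all the site's values under
#' the resolved summary function. Sites present in the results but missing
#' from the sites file are dropped with a notice listing their ids. The
#' returned table is ready for a map rendering layer (see
#' [plot_sitemap()]), which accepts user-supplied vector layers.
#'
#' @inheritParams summarize_season
#' @return Tibble with `Monitoring Location ID`, `lat`, `lon`, `stat`, `n`.
#' @export
aggregate_sites <- function(bundle, param, sumfun = "auto") {
  require_components(bundle, "Data analysis")
  if (is.null(bundle$sites))
    stop("Spatial aggregation requires the sites file", call. = FALSE)
  set <- resolve_settings(param, bundle$accuracy, sumfun, "auto")
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df$grp <- as_chr(df[["Monitoring Location ID"]])
  known <- as_chr(bundle$sites[["Monitoring Location ID"]])
  miss <- setdiff(unique(df$grp), known)
  if (length(miss))
    message("Site(s) in results but not in sites file dropped: ",
            collapse_vals(miss))
  df <- df[df$grp %in% known, , drop = FALSE]
  agg <- summarize_values(df, set$sumfun, confint = FALSE)
  idx <- match(agg$group_label, known)
  tibble::tibble(
    `Monitoring Location ID` = agg$group_label,
    lat = num_or_na(bundle$sites[["Monitoring Location Latitude"]][idx]),
    lon = num_or_na(bundle$sites[["Monitoring Location Longitude"]][idx]),
    stat = agg$stat, n = agg$n)
}

# shared ggplot scaffolding: threshold overlay + scale
add_thresholds <- function(p, config, param, thresh) {
  th <- threshold_lines(config, param, thresh)
  if (nrow(th) == 0) return(p)
  th$legend <- paste0(th$Label, " (", th$Source, ")")
  p + ggplot2::geom_hline(data = th,
        ggplot2::aes(yintercept = .data$Value, linetype = .data$legend),
        colour = "steelblue") +
    ggplot2::labs(linetype = NULL) +
    ggplot2::theme(legend.position = "top")
}

#' Seasonal, site, and date-series plots
#'
#' ggplot renderings of the corresponding summary views: boxplots, barplots,
#' or jittered points by month/week ([plot_season()]) or by site
#' ([plot_site()]), and a date time series with optional confidence ribbon
#' ([plot_date()]). Threshold overlays come from the configuration threshold
#' table, labelled with their source in the legend; `thresh = "none"`
#' suppresses them. Axis scale follows [resolve_settings()].
#'
#' @inheritParams summarize_season
#' @param type `"box"`, `"jitterbox"`, `"bar"`, or `"jitter"`.
#' @param thresh `"fresh"`, `"marine"`, or `"none"`.
#' @return A ggplot object.
#' @export
plot_season <- function(bundle, param, group = c("month", "week"),
                        type = c("box", "jitterbox", "bar", "jitter"),
                        thresh = "none", sumfun = "auto", yscl = "auto",
                        resultatt = NULL) {
  group <- match.arg(group)
  type <- match.arg(type)
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df <- filter_resultatt(df, resultatt)
  df$grp <- outlier_groups(df[["Activity Start Date"]],
                           df[["Monitoring Location ID"]], group)
  if (group == "month") df$grp <- factor(df$grp, levels = month.abb)
  unit <- unique(as_chr(df[["Result Unit"]]))[1]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$grp, y = .data$value))
  p <- switch(type,
    box = p + ggplot2::geom_boxplot(fill = "grey90"),
    jitterbox = p + ggplot2::geom_boxplot(fill = "grey90", outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5),
    bar = {
      agg <- summarize_values(df, set$sumfun)
      ggplot2::ggplot(agg, ggplot2::aes(x = .data$group_label, y = .data$stat)) +
        ggplot2::geom_col(fill = "grey70")
    },
    jitter = p + ggplot2::geom_jitter(width = 0.15, alpha = 0.6))
  p <- p + ggplot2::labs(x = NULL, y = paste(param, if (nzchar(unit %||% ""))
    paste0("(", unit, ")") else "")) + ggplot2::theme_minimal()
  if (set$scale == "log") p <- p + ggplot2::scale_y_log10()
  add_thresholds(p, bundle$config, param, thresh)
}

#' @rdname plot_season
#' @inheritParams summarize_site
#' @export
plot_site <- function(bundle, param, site = NULL,
                      type = c("box", "jitterbox", "bar", "jitter"),
                      thresh = "none", sumfun = "auto", yscl = "auto",
                      resultatt = NULL, byresultatt = FALSE) {
  type <- match.arg(type)
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  df <- analysis_frame(bundle, param, quiet = TRUE)
  df <- filter_resultatt(df, resultatt)
  if (!is.null(site))
    df <- df[as_chr(df[["Monitoring Location ID"]]) %in% site, , drop = FALSE]
  df$grp <- as_chr(df[["Monitoring Location ID"]])
  if (!is.null(site)) df$grp <- factor(df$grp, levels = site)
  unit <- unique(as_chr(df[["Result Unit"]]))[1]
  aes_base <- if (byresultatt)
    ggplot2::aes(x = .data$grp, y = .data$value,
                 fill = as_chr(.data$`Result Attribute`))
  else ggplot2::aes(x = .data$grp, y = .data$value)
  p <- ggplot2::ggplot(df, aes_base)
  p <- switch(type,
    box = p + ggplot2::geom_boxplot(),
    jitterbox = p + ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.5),
    bar = p + ggplot2::stat_summary(fun = set$fn, geom = "col",
                                    position = "dodge"),
    jitter = p + ggplot2::geom_jitter(width = 0.15, alpha = 0.6))
  p <- p + ggplot2::labs(x = NULL, fill = "Result Attribute",
                         y = paste(param, if (nzchar(unit %||% ""))
                           paste0("(", unit, ")") else "")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (set$scale == "log") p <- p + ggplot2::scale_y_log10()
  add_thresholds(p, bundle$config, param, thresh)
}

#' @rdname plot_season
#' @inheritParams summarize_date
#' @param confint show a 95% confidence ribbon.
#' @export
plot_date <- function(bundle, param, group = c("site", "locgroup", "all"),
                      thresh = "none", sumfun = "auto", yscl = "auto",
                      confint = FALSE) {
  group <- match.arg(group)
  set <- resolve_settings(param, bundle$accuracy, sumfun, yscl)
  ts <- summarize_date(bundle, param, group, sumfun, yscl, confint = confint)
  ts$date <- as.Date(ts$date)
  p <- ggplot2::ggplot(ts, ggplot2::aes(x = .data$date, y = .data$stat,
                                        colour = .data$group_label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = param, colour = NULL) +
    ggplot2::theme_minimal()
  if (confint)
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi,
                                               fill = .data$group_label),
                                  alpha = 0.2, colour = NA) +
      ggplot2::labs(fill = NULL)
  if (set$scale == "log") p <- p + ggplot2::scale_y_log10()
  add_thresholds(p, bundle$config, param, thresh)
}

#' Map-style view of per-site aggregates
#'
#' Plots the [aggregate_sites()] table in coordinate space, point colour
#' encoding the aggregate value. Hydrography or basemap layers are not
#' bundled; pass pre-built ggplot layers (e.g. `geom_sf()` layers from
#' user-supplied vector data) through `layers` to add spatial context.
#'
#' @inheritParams aggregate_sites
#' @param layers optional list of ggplot layers drawn beneath the points.
#' @return A ggplot object.
#' @export
plot_sitemap <- function(bundle, param, sumfun = "auto", layers = NULL) {
  agg <- aggregate_sites(bundle, param, sumfun)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$lon, y = .data$lat))
  for (ly in layers) p <- p + ly
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$stat), size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$`Monitoring Location ID`),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_viridis_c(name = param) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
}
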