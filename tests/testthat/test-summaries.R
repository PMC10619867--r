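test_that("auto settings follow the log hint in the accuracy DQOs", {
  bd <- fix_bundle()
  s_log <- resolve_settings("E.coli", bd$accuracy)
  expect_equal(s_log$scale, "log")
  expect_equal(s_log$sumfun, "geomean")
  s_lin <- resolve_settings("DO", bd$accuracy)
  expect_equal(s_lin$scale, "linear")
  expect_equal(s_lin$sumfun, "mean")
  over <- resolve_settings("E.coli", bd$accuracy, sumfun = "median", yscl = "linear")
  expect_equal(over$sumfun, "median")
  expect_equal(over$scale, "linear")
  expect_equal(stat_fun("mean")(c(1, 100)), 50.5)
  expect_equal(stat_fun("geomean")(c(1, 100)), 10)
})

test_that("seasonal summaries cover the sampled months and match an oracle", {
  bd <- fix_bundle()
  out <- summarize_season(bd, "DO", group = "month")
  expect_setequal(out$group_label, c("May", "Jun", "Jul", "Aug", "Sep"))
  df <- outlier_frame(bd, "DO", "month", quiet = TRUE)
  for (g in out$group_label)
    expect_equal(out$stat[out$group_label == g], mean(df$value[df$grp == g]))
})

test_that("group summaries equal a brute-force group-then-reduce oracle", {
  bd <- fix_bundle()
  for (param in c("DO", "TP", "E.coli")) {
    df <- analysis_frame(bd, param, quiet = TRUE)
    fn <- resolve_settings(param, bd$accuracy)$fn
    bysite <- summarize_site(bd, param)
    for (s in bysite$group_label) {
      v <- df$value[df$`Monitoring Location ID` == s]
      expect_equal(bysite$stat[bysite$group_label == s], fn(v))
      expect_equal(bysite$n[bysite$group_label == s], length(v))
    }
  }
})

test_that("geometric mean never exceeds arithmetic mean within groups", {
  bd <- fix_bundle()
  df <- analysis_frame(bd, "E.coli", quiet = TRUE)
  df$grp <- format(as.Date(df$`Activity Start Date`), "%b")
  for (g in unique(df$grp)) {
    v <- df$value[df$grp == g]
    expect_lte(geomean(v), mean(v))
  }
  expect_equal(geomean(rep(42, 5)), mean(rep(42, 5)))  # equality iff constant
})

test_that("aggregates are invariant to record order", {
  bd <- fix_bundle()
  shuffled <- bd
  set.seed(9)
  shuffled$results <- bd$results[sample(nrow(bd$results)), ]
  a <- summarize_season(bd, "TP", group = "month")
  b <- summarize_season(shuffled, "TP", group = "month")
  expect_equal(a, b)
})

test_that("date series aggregate sites with normal-theory confidence intervals", {
  acc <- fix_raw()$accuracy
  fre <- fix_raw()$frecom
  sites <- fix_raw()$sites
  one <- result_row(value = "7.5", site = "WS-001")
  bd1 <- suppressMessages(suppressWarnings(qc_bundle(one, acc, fre, sites)))
  ts1 <- summarize_date(bd1, "DO", group = "all", confint = TRUE)
  expect_equal(ts1$stat, 7.5)
  expect_true(is.na(ts1$lo))                    # n = 1: no interval
  # two sites in one location group average together
  two <- dplyr::bind_rows(result_row(value = "4", site = "WS-001"),
                          result_row(value = "6", site = "WS-002"))
  bd2 <- suppressMessages(suppressWarnings(qc_bundle(two, acc, fre, sites)))
  ts2 <- summarize_date(bd2, "DO", group = "locgroup", confint = TRUE)
  expect_equal(ts2$stat, 5)
  expect_equal(ts2$group_label, "Mainstem")
  # CI equals the hand-computed normal-theory interval
  se <- sd(c(4, 6)) / sqrt(2)
  expect_equal(ts2$lo, 5 - qnorm(0.975) * se)
  expect_equal(ts2$hi, 5 + qnorm(0.975) * se)
  expect_true(ts2$lo <= ts2$stat && ts2$stat <= ts2$hi)
})

test_that("per-site spatial aggregates honor the summary function", {
  bd <- fix_bundle()
  for (fn_name in c("min", "median", "max")) {
    agg <- aggregate_sites(bd, "DO", sumfun = fn_name)
    df <- analysis_frame(bd, "DO", quiet = TRUE)
    for (s in agg$`Monitoring Location ID`)
      expect_equal(agg$stat[agg$`Monitoring Location ID` == s],
                   stat_fun(fn_name)(df$value[df$`Monitoring Location ID` == s]))
    expect_false(any(is.na(agg$lat)))
    expect_false(any(is.na(agg$lon)))
  }
  # log parameter defaults to the geometric mean per site
  aggl <- aggregate_sites(bd, "E.coli")
  dfl <- analysis_frame(bd, "E.coli", quiet = TRUE)
  s1 <- aggl$`Monitoring Location ID`[1]
  expect_equal(aggl$stat[1],
               exp(mean(log(dfl$value[dfl$`Monitoring Location ID` == s1]))))
})

test_that("sites missing from the metadata file are dropped with a notice", {
  b <- fix_raw()
  short_sites <- b$sites[-1, ]
  bd <- suppressMessages(suppressWarnings(
    qc_bundle(b$results, b$accuracy, b$frecom, short_sites)))
  expect_message(agg <- aggregate_sites(bd, "DO"), "WS-001")
  expect_false("WS-001" %in% agg$`Monitoring Location ID`)
})

test_that("unknown result-attribute filters error listing available values", {
  bd <- fix_bundle()
  expect_error(summarize_site(bd, "DO", resultatt = "SNOW"),
               "available.*DRY|available.*WET")
  wet <- summarize_site(bd, "DO", resultatt = "WET")
  expect_true(nrow(wet) > 0)
})

test_that("site filters keep the requested sites in input order", {
  bd <- fix_bundle()
  pick <- c("WS-003", "WS-001")
  out <- summarize_site(bd, "DO", site = pick)
  expect_equal(out$group_label, pick)
})

test_that("threshold overlays are pure presentation", {
  bd <- fix_bundle()
  p_none <- plot_season(bd, "DO", thresh = "none")
  p_fresh <- plot_season(bd, "DO", thresh = "fresh")
  expect_identical(p_none$data$value, p_fresh$data$value)
  # legend carries the threshold source
  th <- threshold_lines(bd$config, "DO", "fresh")
  expect_gt(nrow(th), 0)
  expect_true(all(nzchar(th$Source)))
  for (p in list(p_fresh, plot_site(bd, "DO", byresultatt = TRUE),
                 plot_date(bd, "DO", group = "locgroup", confint = TRUE),
                 plot_sitemap(bd, "DO")))
    expect_s3_class(p, "ggplot")
})

test_that("geometric-mean requests on non-positive data name offenders", {
  rows <- dplyr::bind_rows(result_row(param = "Water Temp", value = "-2",
                                      unit = "deg C"),
                           result_row(param = "Water Temp", value = "5",
                                      unit = "deg C"))
  bd <- suppressMessages(suppressWarnings(
    qc_bundle(rows, fix_raw()$accuracy, fix_raw()$frecom)))
  expect_error(summarize_season(bd, "Water Temp", sumfun = "geomean"),
               "positive")
})
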