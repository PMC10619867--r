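test_that("censored substitution follows the half-MDL / UQL convention", {
  expect_equal(substitute_censored(c("BDL", "0.3", "AQL"), mdl = 0.1, uql = 10,
                                   quiet = TRUE),
               c(0.05, 0.3, 10))
  expect_message(substitute_censored("BDL", mdl = 0.1, uql = NA), "substituted")
  expect_message(out <- substitute_censored("AQL", mdl = 0.1, uql = NA),
                 "excluded")
  expect_true(is.na(out))
})

test_that("flag sets equal the brute-force 1.5*IQR oracle on random groups", {
  set.seed(1408)
  for (trial in seq_len(1000)) {
    n <- sample(4:40, 1)
    x <- switch(sample(3, 1),
                rnorm(n, 10, 3),
                rlnorm(n, 1, 1),
                c(rnorm(n - 1, 5, 1), 50))   # ensure some planted extremes
    b <- outlier_bounds(x)
    got <- which(x < b$lo | x > b$hi)
    expect_identical(got, oracle_outliers(x))
  }
})

test_that("degenerate groups produce no flags", {
  b <- outlier_bounds(rep(3.3, 10))
  expect_equal(b$iqr, 0)
  expect_equal(b$lo, b$hi)                      # bounds collapse onto the value
  expect_length(oracle_outliers(rep(3.3, 10)), 0)
  # a clear extreme in a tiny group
  expect_equal(oracle_outliers(c(1, 2, 3, 4, 100)), 5L)
})

test_that("screening recovers injected outliers per the ground-truth sidecar", {
  b <- fix_raw()
  bd <- fix_bundle()
  truth <- b$outlier_truth
  expect_gt(nrow(truth), 0)
  for (param in unique(truth$`Characteristic Name`)) {
    hits <- screen_outliers(bd, param = param, group = "month", quiet = TRUE)
    t_p <- truth[truth$`Characteristic Name` == param, ]
    found <- paste(hits$`Monitoring Location ID`, hits$`Activity Start Date`,
                   hits$`Result Value`)
    planted <- paste(t_p$`Monitoring Location ID`, t_p$`Activity Start Date`,
                     t_p$`Result Value`)
    expect_true(all(planted %in% found))
  }
})

test_that("outlier hits carry the six tabular columns in order", {
  bd <- fix_bundle()
  hits <- screen_outliers(bd, "DO", group = "month", quiet = TRUE)
  expect_identical(names(hits),
                   c("Monitoring Location ID", "Activity Start Date",
                     "Activity Start Time", "Characteristic Name",
                     "Result Value", "Result Unit"))
  expect_true(is.numeric(hits$`Result Value`))
  expect_error(screen_outliers(bd, "Chlorophyll", group = "month"),
               "not present")
})

test_that("flags are grouping-specific and match a per-group oracle", {
  bd <- fix_bundle()
  for (grp in c("month", "site")) {
    df <- outlier_frame(bd, "DO", grp, quiet = TRUE)
    expected <- integer(0)
    for (g in unique(df$grp)) {
      idx <- which(df$grp == g)
      if (length(idx) < 4) next
      expected <- c(expected, idx[oracle_outliers(df$value[idx])])
    }
    hits <- screen_outliers(bd, "DO", group = grp, quiet = TRUE)
    expect_equal(nrow(hits), length(expected))
    expect_setequal(paste(hits$`Monitoring Location ID`, hits$`Result Value`),
                    paste(df$`Monitoring Location ID`[expected],
                          df$value[expected]))
  }
})

test_that("log-parameter screening works in log space and is scale-consistent", {
  bd <- fix_bundle()
  df <- outlier_frame(bd, "E.coli", "month", quiet = TRUE)
  expect_equal(attr(df, "scale"), "log")
  expected <- integer(0)
  for (g in unique(df$grp)) {
    idx <- which(df$grp == g)
    if (length(idx) < 4) next
    expected <- c(expected, idx[oracle_outliers(log10(df$value[idx]))])
  }
  hits <- screen_outliers(bd, "E.coli", group = "month", quiet = TRUE)
  expect_equal(nrow(hits), length(expected))
})

test_that("the median is never flagged, even after duplicating it", {
  # interpolated quartiles shift when a central point is added, so the flag
  # set of other points may legitimately change; the central value itself
  # always stays inside [q1 - k*iqr, q3 + k*iqr]
  set.seed(77)
  for (trial in seq_len(200)) {
    x <- rnorm(sample(5:30, 1), 10, 4)
    m <- median(x)
    expect_false(any(abs(x[oracle_outliers(x)] - m) < 1e-12))
    y <- c(x, m)
    b <- outlier_bounds(y)
    expect_true(m >= b$lo && m <= b$hi)
  }
})

test_that("small groups are skipped with a notice", {
  rows <- dplyr::bind_rows(
    result_row(value = "8.0", date = "2022-05-01"),
    result_row(value = "80", date = "2022-05-02"),
    result_row(value = "8.2", date = "2022-05-03"))
  acc <- fix_raw()$accuracy
  bd <- suppressMessages(suppressWarnings(
    qc_bundle(rows, acc, fix_raw()$frecom)))
  expect_message(hits <- screen_outliers(bd, "DO", group = "month"),
                 "fewer than 4")
  expect_equal(nrow(hits), 0)
})

test_that("batch export renders one image per parameter plus an optional doc", {
  bd <- fix_bundle()
  dir <- withr::local_tempdir()
  paths <- suppressMessages(batch_outliers(bd, group = "month",
                                           format = "doc", output_dir = dir))
  pngs <- grep("\\.png$", paths, value = TRUE)
  expect_length(pngs, length(unique(bd$results$`Characteristic Name`)))
  expect_true(all(file.exists(pngs)))
  expect_true(file.exists(grep("\\.md$", paths, value = TRUE)))
  p <- plot_outliers(bd, "DO", group = "month")
  expect_s3_class(p, "ggplot")
})
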