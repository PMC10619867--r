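test_that("a valid generated results table passes all fifteen checks in order", {
  b <- fix_raw()
  out <- check_results(b$results, quiet = TRUE)
  expect_equal(nrow(out), 15)
  expect_true(all(out$status == "ok"))
  expect_equal(out$check_name, check_names_results())
  msgs <- capture_messages(check_results(b$results))
  expect_match(msgs[length(msgs)], "All checks passed!")
})

test_that("invalid activity types abort at check 3 with values and row indices", {
  b <- corrupt_bundle(fix_raw(), list(
    list(table = "results", row = 4, col = "Activity Type", value = "Sample"),
    list(table = "results", row = 135, col = "Activity Type", value = "Field")))
  out <- check_results(b$results, quiet = TRUE)
  expect_equal(nrow(out), 3)                  # abort on first failure
  expect_equal(sum(out$status == "fail"), 1)
  expect_equal(out$check_name[3], "Checking valid Activity Types")
  expect_equal(out$message[3],
               "Incorrect Activity Type found: Sample, Field in row(s) 4, 135")
  expect_equal(out$offending_rows[[3]], c(4L, 135L))
  expect_equal(out$offending_values[[3]], c("Sample", "Field"))
  expect_error(read_results(b$results, quiet = TRUE),
               "Sample, Field in row\\(s\\) 4, 135")
})

test_that("a deleted required column fails at check 2 naming the column", {
  b <- corrupt_bundle(fix_raw(), list(list(table = "results",
                                           drop_col = "Result Value")))
  out <- check_results(b$results, quiet = TRUE)
  expect_equal(out$status[2], "fail")
  expect_match(out$message[2], "Result Value")
  # an unknown extra column instead fails at check 1
  res2 <- fix_raw()$results
  res2$Extra <- "x"
  out2 <- check_results(res2, quiet = TRUE)
  expect_equal(out2$status[1], "fail")
  expect_match(out2$message[1], "Extra")
})

test_that("result-value and unit checks catch bad cells row-addressed", {
  base <- fix_raw()$results
  neg <- corrupt_bundle(list(results = base), list(
    list(table = "results", row = 10, col = "Result Value", value = "-5")))
  out <- check_results(neg$results, quiet = TRUE)
  expect_equal(out$check_name[nrow(out)], "Checking Result Values")
  expect_equal(out$offending_rows[[nrow(out)]], 10L)
  # negative temperatures are legitimate
  wt <- result_row(param = "Water Temp", value = "-0.5", unit = "deg C")
  expect_true(all(check_results(wt, quiet = TRUE)$status == "ok"))
  # a second unit for one parameter trips the one-unit rule
  two <- corrupt_bundle(list(results = base), list(
    list(table = "results", row = 1, col = "Result Unit", value = "ug/l")))
  out2 <- check_results(two$results, quiet = TRUE)
  expect_equal(out2$check_name[nrow(out2)],
               "Checking if more than one unit per Characteristic Name")
})

test_that("deep samples warn rather than fail, and strict mode promotes them", {
  deep <- result_row(value = "8.0")
  deep$`Activity Depth/Height Measure` <- "2.5"
  out <- check_results(deep, quiet = TRUE)
  expect_equal(out$status[9], "warn")
  expect_equal(nrow(out), 15)                 # warnings do not abort
  out2 <- check_results(deep, strict = TRUE, quiet = TRUE)
  expect_equal(out2$status[9], "fail")
  expect_equal(nrow(out2), 9)
})

test_that("date normalization standardizes formats and is idempotent", {
  mixed <- dplyr::bind_rows(
    result_row(date = "2022-06-01"),
    result_row(date = "6/1/2022"),
    result_row(date = "44713"))              # spreadsheet serial for 2022-06-01
  res <- read_results(mixed, quiet = TRUE)
  expect_equal(unique(res$`Activity Start Date`), "2022-06-01")
  res2 <- read_results(res, quiet = TRUE)
  expect_equal(res2$`Activity Start Date`, res$`Activity Start Date`)
})

test_that("missing start times raise a warning during normalization", {
  r <- result_row(time = "")
  expect_warning(read_results(r, quiet = FALSE),
                 "missing Activity Start Time")
})

test_that("workbook write/read round-trips every cell bit-exact as strings", {
  b <- fix_raw()
  path <- withr::local_tempfile(fileext = ".xlsx")
  write_workbook(list(Sheet1 = b$results), path)
  back <- read_workbook(path, "Sheet1")
  expect_identical(names(back), names(b$results))
  for (col in names(back))
    expect_identical(back[[col]], as.character(b$results[[col]]))
})

test_that("csv input is accepted with the same schema and checks", {
  b <- fix_raw()
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(b$results, path, na = "")
  res <- read_results(path, quiet = TRUE)
  expect_equal(nrow(res), nrow(b$results))
  expect_true(all(attr(res, "checks")$status == "ok"))
})

test_that("results_view lists unique entries per column in first-appearance order", {
  df <- tibble::tibble(a = c("x", "y", "x", "z"), b = c("1", "1", "1", "2"))
  v <- results_view(df)
  expect_equal(v$a, c("x", "y", "z"))
  expect_equal(v$b, c("1", "2", ""))
  # matches a brute-force distinct scan on the full fixture
  full <- fix_raw()$results
  v2 <- results_view(full)
  for (col in names(full)) {
    expect_equal(v2[[col]][nzchar(v2[[col]])],
                 unique(as.character(full[[col]]))[nzchar(unique(as.character(full[[col]])))])
  }
})

test_that("accuracy and frecom readers validate cells with addresses", {
  acc <- fix_raw()$accuracy
  out <- read_accuracy(acc, quiet = TRUE)
  expect_s3_class(out, "aqc_accuracy")
  expect_equal(out$scale_hint[out$Parameter == "E.coli"], "log")
  expect_equal(unique(out$scale_hint[out$Parameter != "E.coli"]), "linear")
  bad <- acc
  bad$`Field Blank`[2] <- "~oops"
  expect_error(read_accuracy(bad, quiet = TRUE), "row 2")
  fre <- fix_raw()$frecom
  expect_s3_class(read_frecom(fre, quiet = TRUE), "aqc_frecom")
  badf <- fre
  badf$`Field Duplicate`[3] <- "120"
  expect_error(read_frecom(badf, quiet = TRUE), "out of \\[0, 100\\]")
})

test_that("sites reader enforces bounds and unique ids", {
  s <- fix_raw()$sites
  expect_s3_class(read_sites(s, quiet = TRUE), "aqc_sites")
  dup <- dplyr::bind_rows(s, s[1, ])
  expect_error(read_sites(dup, quiet = TRUE), "Duplicate Monitoring Location ID")
  bad <- s
  bad$`Monitoring Location Latitude`[1] <- "100"
  expect_error(read_sites(bad, quiet = TRUE), "latitude")
})

test_that("bundles gate workflow steps on the components they require", {
  b <- fix_raw()
  bd <- suppressMessages(qc_bundle(b$results, b$accuracy, b$frecom))
  expect_silent(require_components(bd, "QC reporting"))   # sites not needed
  expect_error(require_components(bd, "WQX formatting"), "WQX metadata")
  full <- fix_bundle()
  for (step in c("QC screening", "QC reporting", "Data analysis", "WQX formatting"))
    expect_silent(require_components(full, step))
})
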