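acc_one <- function(param = "TP", mdl = "0.005", uql = "", fb = "< 0.01",
                    lb = "", fd = "<= 30%", ld = "", spk = "<= 5%") {
  tibble::tibble(Parameter = param, MDL = mdl, UQL = uql, `Value Range` = "all",
                 `Field Duplicate` = fd, `Lab Duplicate` = ld,
                 `Field Blank` = fb, `Lab Blank` = lb,
                 `Spike/Check Accuracy` = spk, scale_hint = "linear")
}

test_that("percent acceptance matches printed QC-table arithmetic", {
  expect_equal(percent_acceptance(4, 1), 75)
  expect_equal(percent_acceptance(11, 1), 91)   # 90.909 rounds up
  expect_equal(percent_acceptance(7, 1), 86)    # 85.714 rounds up
  expect_equal(percent_acceptance(7, 0), 100)
  expect_identical(percent_acceptance(0, 0), "-")
  expect_error(percent_acceptance(-1, 0), "non-negative")
  expect_error(percent_acceptance(2, 3), "exceed")
})

test_that("percent acceptance agrees with a brute-force oracle for all n <= 50", {
  for (n in 0:50) for (m in 0:n) {
    got <- percent_acceptance_num(n, m)
    expect_identical(unname(got), oracle_percent(n, m),
                     info = sprintf("n=%d m=%d", n, m))
  }
})

test_that("percent acceptance is monotone in hits and misses", {
  for (n in 1:30) for (m in 0:(n - 1)) {
    # adding a miss never raises acceptance; adding a hit never lowers it
    expect_lte(percent_acceptance_num(n + 1, m + 1), percent_acceptance_num(n, m))
    expect_gte(percent_acceptance_num(n + 1, m), percent_acceptance_num(n, m))
  }
})

test_that("blank evaluation treats equality to a strict threshold as a miss", {
  acc <- acc_one()
  rec_bdl <- result_row(param = "TP", value = "BDL",
                        type = "Quality Control Sample-Field Blank")
  expect_equal(eval_blank(rec_bdl, acc, "field")$`Hit/Miss`, "")
  rec_eq <- result_row(param = "TP", value = "0.01",
                       type = "Quality Control Sample-Field Blank")
  expect_equal(eval_blank(rec_eq, acc, "field")$`Hit/Miss`, "MISS")
  rec_lo <- result_row(param = "TP", value = "0.005",
                       type = "Quality Control Sample-Field Blank")
  expect_equal(eval_blank(rec_lo, acc, "field")$`Hit/Miss`, "")
  # no criterion: excluded with a notice, not silently dropped
  expect_message(out <- eval_blank(rec_bdl, acc_one(fb = ""), "field"), "Excluded")
  expect_null(out)
})

test_that("duplicate evaluation uses relative percent difference", {
  acc <- acc_one(fd = "<= 30%")
  pair <- function(v, r) result_row(param = "TP", value = v, qcref = r,
                                    type = "Quality Control Sample-Field Duplicate")
  # RPD(10, 12) = 100*2/11 = 18.18% -> hit
  expect_equal(eval_duplicate(pair("10", "12"), acc, "field")$`Hit/Miss`, "")
  expect_equal(eval_duplicate(pair("5", "5"), acc, "field")$`Hit/Miss`, "")
  expect_equal(eval_duplicate(pair("10", "14"), acc, "field")$`Hit/Miss`, "MISS")
  # both censored: indistinguishable, a hit
  expect_equal(eval_duplicate(pair("BDL", "BDL"), acc, "field")$`Hit/Miss`, "")
  # mixed pair substitutes the MDL with a logged notice
  expect_message(mix <- eval_duplicate(pair("BDL", "0.005"), acc, "field"),
                 "Substituting detection limit")
  expect_equal(mix$`Hit/Miss`, "")             # RPD(0.005, 0.005) = 0
  # zero mean: hit iff exactly equal
  expect_equal(eval_duplicate(pair("0", "0"), acc, "field")$`Hit/Miss`, "")
  # absolute criterion branch
  accA <- acc_one(param = "pH", fd = "<= 0.5", mdl = "")
  pH <- function(v, r) result_row(param = "pH", value = v, qcref = r, unit = "s.u.",
                                  type = "Quality Control Sample-Field Duplicate")
  expect_equal(eval_duplicate(pH("7.0", "7.4"), accA, "field")$`Hit/Miss`, "")
  expect_equal(eval_duplicate(pH("7.0", "7.6"), accA, "field")$`Hit/Miss`, "MISS")
})

test_that("spike evaluation compares deviation from the known quantity", {
  acc <- acc_one(spk = "<= 5%")
  spk <- function(v, r) result_row(param = "TP", value = v, qcref = r,
                                   type = "Quality Control Sample-Lab Spike")
  expect_equal(eval_spike(spk("98", "100"), acc)$`Hit/Miss`, "")    # 2%
  expect_equal(eval_spike(spk("100", "100"), acc)$`Hit/Miss`, "")
  expect_equal(eval_spike(spk("90", "100"), acc)$`Hit/Miss`, "MISS") # 10%
  expect_message(out <- eval_spike(spk("1", "0"), acc), "zero")
  expect_null(out)
})

test_that("the built-in field-blank set reproduces the documented summary", {
  d <- demo_field_blanks()
  bd <- suppressMessages(suppressWarnings(
    qc_bundle(d$results, d$accuracy, d$frecom)))
  s <- suppressMessages(qc_accuracy(bd, type = "summary"))
  fb <- s[s$`Check Type` == "Field Blanks", ]
  expect_equal(fb$`Number of QC Checks`[fb$Parameter == "Ammonia"], 7L)
  expect_equal(fb$`Number of Misses`[fb$Parameter == "Ammonia"], 0L)
  expect_equal(fb$`% Acceptance`[fb$Parameter == "Ammonia"], "100%")
  expect_equal(fb$`Number of QC Checks`[fb$Parameter == "TP"], 11L)
  expect_equal(fb$`Number of Misses`[fb$Parameter == "TP"], 1L)
  expect_equal(fb$`% Acceptance`[fb$Parameter == "TP"], "91%")
  pct <- suppressMessages(qc_accuracy(bd, type = "percent"))
  expect_equal(pct$`Field Blanks`[pct$Parameter == "Ammonia"], "100%")
  expect_equal(pct$`Field Blanks`[pct$Parameter == "TP"], "91%")
  expect_equal(pct$`Lab Duplicates`[pct$Parameter == "TP"], "-")
  ind <- suppressMessages(qc_accuracy(bd, type = "individual",
                                      accchk = "Field Blanks"))
  miss <- ind[ind$`Hit/Miss` == "MISS", ]
  expect_equal(nrow(miss), 1)
  expect_equal(miss$Parameter, "TP")
  expect_equal(miss$Date, "2022-07-17")
  expect_equal(miss$Result, "0.01 mg/l")
  expect_equal(miss$Threshold, "0.01 mg/l")
})

test_that("summary, percent, and individual views are mutually coherent", {
  bd <- fix_bundle()
  ind <- suppressMessages(qc_accuracy(bd, type = "individual"))
  s <- suppressMessages(qc_accuracy(bd, type = "summary"))
  pct <- suppressMessages(qc_accuracy(bd, type = "percent"))
  for (i in seq_len(nrow(s))) {
    sub <- ind[ind$`Check Type` == s$`Check Type`[i] &
                 ind$Parameter == s$Parameter[i], ]
    expect_equal(nrow(sub), s$`Number of QC Checks`[i])
    expect_equal(sum(sub$miss), s$`Number of Misses`[i])
    cell <- pct[[s$`Check Type`[i]]][pct$Parameter == s$Parameter[i]]
    expect_equal(cell, paste0(percent_acceptance(s$`Number of QC Checks`[i],
                                                 s$`Number of Misses`[i]), "%"))
  }
  # cells with no QC records carry the no-data marker
  expect_true(any(unlist(pct[-1]) == "-"))
})

test_that("frequency evaluation compares observed QC rates to requirements", {
  reg <- dplyr::bind_rows(lapply(1:100, function(i)
    result_row(param = "DO", value = "8.0", date = "2022-06-01")))
  dups <- dplyr::bind_rows(lapply(1:12, function(i)
    result_row(param = "DO", value = "8.0", qcref = "8.1",
               type = "Quality Control Sample-Field Duplicate")))
  fre <- tibble::tibble(Parameter = "DO", `Field Duplicate` = "10",
                        `Lab Duplicate` = "", `Field Blank` = "",
                        `Lab Blank` = "", `Spike/Check Accuracy` = "",
                        `% Completeness` = "")
  bd <- suppressMessages(suppressWarnings(qc_bundle(
    dplyr::bind_rows(reg, dups), acc_one(param = "DO", fb = "", mdl = ""), fre)))
  out <- qc_frequency(bd)
  expect_equal(nrow(out), 1)                    # empty requirements omitted
  expect_equal(out$`Observed %`, 12)
  expect_true(out$Met)
  # no QC checks at all: 0% observed, not met
  bd0 <- suppressMessages(suppressWarnings(qc_bundle(
    reg, acc_one(param = "DO", fb = "", mdl = ""), fre)))
  out0 <- qc_frequency(bd0)
  expect_equal(out0$`Observed %`, 0)
  expect_false(out0$Met)
})

test_that("completeness counts qualified samples against the requirement", {
  rows <- dplyr::bind_rows(lapply(1:100, function(i)
    result_row(param = "TP", value = "0.05", type = "Sample-Routine",
               qcref = if (i <= 8) "0.05" else "")))
  fre <- tibble::tibble(Parameter = "TP", `Field Duplicate` = "",
                        `Lab Duplicate` = "", `Field Blank` = "",
                        `Lab Blank` = "", `Spike/Check Accuracy` = "",
                        `% Completeness` = "90")
  bd <- suppressMessages(suppressWarnings(qc_bundle(rows, acc_one(), fre)))
  out <- qc_completeness(bd)
  expect_equal(out$`Number of Records`, 100L)
  expect_equal(out$`Number Qualified`, 8L)
  expect_equal(out$`% Complete`, 92)
  expect_true(out$Met)
  # all qualified: nothing usable
  all_q <- rows
  all_q$`QC Reference Value` <- "0.05"
  bd2 <- suppressMessages(suppressWarnings(qc_bundle(all_q, acc_one(), fre)))
  expect_equal(qc_completeness(bd2)$`% Complete`, 0)
  expect_false(qc_completeness(bd2)$Met)
})

test_that("every QC record yields a verdict or a logged exclusion", {
  bd <- fix_bundle()
  roles <- record_roles(bd$results, bd$config)
  paired_regular <- roles %in% c("regular_field", "regular_lab") &
    nzchar(bd$results$`QC Reference Value`)
  n_qc <- sum(!roles %in% c("regular_field", "regular_lab") & !is.na(roles)) +
    sum(paired_regular)
  msgs <- capture_messages(ind <- qc_accuracy(bd, type = "individual"))
  n_excluded <- sum(grepl("^Excluded", msgs))
  expect_equal(nrow(ind) + n_excluded, n_qc)
})

test_that("the assembled report renders deterministically with all sections", {
  bd <- fix_bundle()
  rev1 <- suppressMessages(qc_review(bd, organization = "Test Watershed Org"))
  rev2 <- suppressMessages(qc_review(bd, organization = "Test Watershed Org"))
  dir <- withr::local_tempdir()
  expect_message(p1 <- write_qc_report(rev1, file.path(dir, "a")),
                 "Report created successfully! File located at")
  suppressMessages(p2 <- write_qc_report(rev2, file.path(dir, "b")))
  expect_identical(readLines(p1), readLines(p2))  # byte-identical bodies
  body <- paste(readLines(p1), collapse = "\n")
  for (h in c("Data Quality Objectives", "Frequency Results",
              "Completeness Results", "Accuracy Summary",
              "Acceptance Percent Matrix", "Individual Results"))
    expect_match(body, h)
  # the planted TP field-blank miss is marked in text
  expect_match(body, "MISS")
  g <- glance(rev1)
  expect_equal(g$n_accuracy_misses, sum(rev1$individual$miss))
  td <- tidy(rev1)
  expect_equal(td$pct_accept,
               percent_acceptance_num(td$`Number of QC Checks`,
                                      td$`Number of Misses`))
})

test_that("an empty accuracy table yields empty sections without crashing", {
  d <- demo_field_blanks()
  acc <- d$accuracy
  for (col in c("Field Duplicate", "Lab Duplicate", "Field Blank",
                "Lab Blank", "Spike/Check Accuracy")) acc[[col]] <- ""
  bd <- suppressMessages(suppressWarnings(qc_bundle(d$results, acc, d$frecom)))
  s <- suppressMessages(qc_accuracy(bd, type = "summary"))
  expect_equal(nrow(s), 0)
  rev <- suppressMessages(qc_review(bd))
  dir <- withr::local_tempdir()
  expect_no_error(suppressMessages(write_qc_report(rev, dir)))
})
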