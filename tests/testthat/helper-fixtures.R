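# shared fixtures, generated once per test run

fix_raw <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_bundle(fixture_spec(seed = 101))
    cache
  }
})

fix_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- fix_raw()
      cache <<- suppressMessages(suppressWarnings(
        qc_bundle(b$results, b$accuracy, b$frecom, b$sites, b$wqx)))
    }
    cache
  }
})

# a minimal hand-built results row
result_row <- function(param = "DO", value = "8.0", type = "Field Msr/Obs",
                       site = "WS-001", date = "2022-06-01", time = "07:00",
                       qcref = "", unit = "mg/l", attribute = "") {
  tibble::tibble(
    `Monitoring Location ID` = site, `Activity Type` = type,
    `Activity Start Date` = date, `Activity Start Time` = time,
    `Activity Depth/Height Measure` = "0.3", `Activity Depth/Height Unit` = "m",
    `Activity Relative Depth Name` = "Surface", `Characteristic Name` = param,
    `Result Value` = value, `QC Reference Value` = qcref,
    `Result Unit` = unit, `Result Attribute` = attribute)
}

# independent oracle for the 1.5*IQR rule: brute-force on type-7 quartiles
oracle_outliers <- function(x, k = 1.5) {
  q1 <- as.numeric(quantile(x, 0.25, type = 7))
  q3 <- as.numeric(quantile(x, 0.75, type = 7))
  iqr <- q3 - q1
  which(x < q1 - k * iqr | x > q3 + k * iqr)
}

# independent oracle for integer percent with half-away-from-zero ties:
# nearest candidate in 0..100, ties resolved upward (all inputs positive)
oracle_percent <- function(n, m) {
  if (n == 0) return(NA_real_)
  x <- 100 * (n - m) / n
  cand <- 0:100
  d <- abs(cand - x)
  as.numeric(max(cand[d == min(d)]))
}
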