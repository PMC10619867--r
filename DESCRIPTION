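Package: aquaqc
Title: Quality Control, Analysis, and Submission Formatting for Discrete
    Water-Quality Monitoring Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for volunteer and professional surface-water monitoring
    programs working with discrete water-quality data. Strictly formatted
    monitoring tables are validated with row-addressed error messages,
    screened for outliers with the 1.5 interquartile-range rule, and
    evaluated against data-quality objectives for accuracy (field and lab
    duplicates, blanks, spikes and instrument checks), QC frequency, and
    completeness. Results can be assembled into a quality-control report,
    summarized by season, date, site, or location, and exported as a
    three-sheet workbook formatted for submission to the United States
    Environmental Protection Agency Water Quality Exchange (WQX).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    readxl,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rmarkdown,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
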