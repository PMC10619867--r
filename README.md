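# aquaqc

Quality control, analysis, and submission formatting for discrete
surface-water monitoring data.

Volunteer watershed groups and monitoring programs collect large amounts of
discrete water-quality data (dissolved oxygen, nutrients, bacteria, pH, ...),
but those data are only usable by regulators and public databases if they
pass systematic quality control: strict file formats, documented data-quality
objectives (DQOs), and QC samples — blanks, duplicates, spikes — evaluated
against them. `aquaqc` automates that workflow for tabular monitoring data:

1. **Validate** the five strictly formatted input tables (results, DQO
   accuracy, DQO frequency & completeness, sites, WQX metadata) with fifteen
   named checks and row-addressed errors, e.g.
   `Incorrect Activity Type found: Sample, Field in row(s) 4, 135`.
2. **Screen outliers** per parameter within month/week/year/site groups using
   the 1.5 × IQR rule, with censored values (`BDL`/`AQL`) substituted by
   MDL/2 and UQL, and log10 screening for log-distributed parameters.
3. **Evaluate QC** records against the DQOs and assemble a QC report:
   - *blanks*: a result must sit below a threshold; `BDL` is a hit, and under
     a strict `<` criterion a value *equal* to the threshold is a MISS;
   - *duplicates*: relative percent difference
     `RPD = 100·|a − b| / mean(a, b)` (or absolute difference) within bounds;
   - *spikes / instrument checks*: deviation `100·|measured − known| / known`
     from a known quantity;
   - *frequency*: QC checks per regular sample, `100·n_qc / n_regular`,
     against the required percent (commonly ≥ 10%);
   - *completeness*: usable fraction `100·(n − n_qualified) / n`;
   - acceptance percentages `round(100·(n − misses)/n)` with halves away
     from zero, so 10/11 prints as 91%.
4. **Summarize** by season, date, site, or location with DQO-driven scaling:
   parameters carrying the `log` token in their accuracy criteria get a
   log10 axis and geometric-mean summaries, others a linear axis and
   arithmetic means; optional threshold overlays with cited sources.
5. **Export** a three-sheet (`Project`, `Locations`, `Results`) WQX
   submission workbook, censored values rendered as detection conditions and
   same-row duplicate pairs expanded to paired activity types.

A deterministic fixture generator (`fixture_spec()` / `generate_bundle()`)
produces a full season of synthetic multi-site monitoring data with planted
outliers and QC misses recorded in a ground-truth sidecar, so the whole
workflow is testable without external data.

## Worked example

```r
library(aquaqc)

# built-in demonstration set: 18 field-blank QC records for two lab analytes
d <- demo_field_blanks()
bd <- qc_bundle(d$results, d$accuracy, d$frecom)
qc_accuracy(bd, type = "summary")
#> # A tibble: 2 × 5
#>   `Check Type` Parameter `Number of QC Checks` `Number of Misses` `% Acceptance`
#> 1 Field Blanks Ammonia                       7                  0 100%
#> 2 Field Blanks TP                           11                  1 91%
```

All seven ammonia blanks read below detection (`BDL`), so ammonia accepts at
100%. One of the eleven total-phosphorus blanks reads 0.01 mg/l — exactly at
the `< 0.01 mg/l` objective, which under a strict less-than criterion is a
MISS — so TP accepts at 10/11 = 91%:

```r
qc_accuracy(bd, type = "individual", accchk = "Field Blanks")
#> ...
#> 14 Field Blanks TP  2022-07-17 ""  0.01 mg/l  0.01 mg/l  "MISS"
#> ...
```

The same engine runs on full bundles. With a generated season of data:

```r
b  <- generate_bundle(fixture_spec(seed = 42))
bd <- qc_bundle(b$results, b$accuracy, b$frecom, b$sites, b$wqx)

screen_outliers(bd, "DO", group = "month")      # 1.5*IQR flags, 6-column table
rev <- qc_review(bd)                            # full QC review object
write_qc_report(rev, "out")                     # "Report created successfully! ..."
build_wqx_workbook(bd, "out")                   # "Excel workbook created successfully! ..."
```

`glance(rev)` gives one-row totals and `tidy(rev)` the per-parameter
acceptance counts. Plot helpers (`plot_outliers()`, `plot_season()`,
`plot_date()`, `plot_site()`, `plot_sitemap()`) return ggplot objects.

A command-line front end over the same functions is installed at
`inst/scripts/aquaqc.R` (subcommands `validate`, `view`, `qc-report`,
`acc-table`, `outliers`, `summarize`, `wqx`, `fixture`).

## Scope

`aquaqc` handles discrete samples, not continuous sensor streams; it flags
potential outliers but never removes them; it prepares the WQX workbook but
does not upload it; map views accept user-supplied vector layers rather than
bundling hydrography. One unit of measurement is enforced per parameter —
unit conversion is out of scope. Controlled vocabularies, the parameter
dictionary, and plot thresholds are all editable configuration
(`qc_config()`, `inst/extdata/aquaqc-config.yaml`), not hard-coded.
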