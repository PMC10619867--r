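---
title: "Methods: QC evaluation, outlier screening, and summaries in aquaqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC evaluation, outlier screening, and summaries in aquaqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquaqc)
```

`aquaqc` implements a quality-control workflow for discrete surface-water
monitoring data. This vignette documents the statistical procedures, the
defaults and why they were chosen, the numerical edge cases, and what the
synthetic-data generator does and does not emulate.

## Input model and validation

All inputs are flat tables with fixed column names: a **results** table (one
row per monitoring or QC activity), **DQO accuracy** and **DQO frequency &
completeness** tables (one row per parameter), a **sites** table, and
per-parameter **WQX metadata**. Cells are treated as text throughout so that
censoring tokens (`BDL` = below detection limit, `AQL` = above
quantification limit) coexist with numbers and every write/read cycle is
exact.

The results validator runs fifteen named checks in a fixed order and stops
at the first failure, reporting the offending values with 1-based data-row
indices (the header is excluded; `spreadsheet_rows = TRUE` in the
configuration adds the +1 offset so indices match spreadsheet rows). This
fail-fast design matches how the files are actually fixed: a user edits the
named cells in the source spreadsheet and re-imports. Two conditions warn
rather than fail — samples deeper than 1 m / 3.3 ft (legitimate, but worth
flagging in wadeable-stream programs; `strict = TRUE` promotes warnings to
failures) and missing clock times (optional, but needed for WQX
submission). Negative result values are rejected except for parameters
marked `Negative Ok` in the parameter dictionary (by default only water
temperature): a negative concentration is a data-entry error, a negative
temperature is winter.

Dates are normalized to `YYYY-MM-DD` from ISO strings, US `m/d/Y` strings,
or spreadsheet serial numbers (days since 1899-12-30); normalization is
idempotent. Controlled vocabularies (activity types under WQX naming,
relative depth names, depth units) and the parameter dictionary (allowed
units, sign rules) ship as editable configuration, not code, so the tool is
usable by any monitoring program.

## Criterion grammar

Accuracy objectives are tiny expressions in the DQO table:
`<op> <number>[%]` with `op` one of `<`, `<=`, `>`, `>=`; a trailing `%`
marks a *relative* criterion. The bare tokens `BDL`/`AQL` mean the QC result
must itself be censored. The token `log` carries no pass/fail meaning; its
presence in any criterion cell marks the parameter as log-distributed for
plotting and summarization. An empty cell means the check does not apply. A
`Value Range` column restricts a rule row to a concentration band; when
ranges overlap the narrowest applicable range wins, ties broken by file
order — so a program can, say, tighten duplicate precision at low
concentrations without touching the general rule.

## QC evaluation

- **Blanks** (field or lab): a censored result is a hit; a numeric result is
  a hit iff it satisfies the criterion. The comparison uses the operator as
  written, so under `< 0.01` a blank of exactly 0.01 is a MISS — being *at*
  the detection limit is contamination, not a rounding courtesy.
- **Duplicates**: precision is measured by relative percent difference,
  `RPD = 100·|a − b| / mean(a, b)`, the standard duplicate-precision
  statistic; an absolute criterion compares `|a − b|` instead (used for pH
  and temperature, where percent differences are physically meaningless).
  Both-censored pairs are hits (the members are indistinguishable). A mixed
  censored/numeric pair substitutes the rule's MDL (for `BDL`) or UQL (for
  `AQL`) before comparison, with the substitution logged — treating such
  pairs as automatic hits would hide disagreements just above the detection
  limit. A zero pair mean with a percent criterion falls back to an
  exact-equality test. Pairs may appear as dedicated duplicate activity rows
  or as a regular row carrying the second measurement in `QC Reference
  Value`; both forms are evaluated.
- **Spikes and instrument checks**: the statistic is
  `100·|measured − known| / known`, i.e. the deviation from 100% recovery;
  a zero known quantity with a percent criterion excludes the record with a
  notice. Field calibration checks are folded into the same summary column
  as lab spikes, giving the five-column accuracy layout (field duplicates,
  lab duplicates, field blanks, lab blanks, spikes/instrument checks).
- Evaluators are total: every QC record yields exactly one verdict or one
  logged exclusion notice (no applicable criterion, missing limits, zero
  reference); nothing is dropped silently.

**Acceptance percentages** are `100·(n − misses)/n` rounded to the nearest
integer with halves away from zero — the only deterministic rule consistent
with displaying 10/11 as 91% and 6/7 as 86%. Cells with no QC records show
the no-data marker `-`.

**Frequency** compares `100·n_qc / n_regular` per parameter and check type
with the required percent; `n_qc` includes pairs entered in `QC Reference
Value`. The denominator excludes qualified samples by default
(`frequency_excludes_qualified`): a qualified record is not a regular sample
the QC program must cover. **Completeness** is `100·(n − n_qualified)/n`
over regular records. Because the results schema is closed (the validator
rejects unknown columns), qualified samples are identified as regular rows
hosting a paired `QC Reference Value`, plus rows whose `Result Attribute`
matches the configurable `qualifier_attributes` list (empty by default) —
not via a dedicated qualifier column.

The assembled review renders to Markdown (always; HTML/DOCX via pandoc when
available) in a fixed order — DQO tables, frequency and completeness
results, accuracy summary, acceptance-percent matrix, individual tables —
with failing cells carrying a textual `MISS` marker so the information
survives uncolored formats. The body contains no timestamps; identical
reviews produce byte-identical reports.

## Outlier screening

Within each group (calendar month, ISO week, year, or site) an observation
is flagged iff it lies strictly outside `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`.
Quartiles use linear interpolation between order statistics (R's default
type-7 estimator); groups with fewer than 4 observations are skipped with a
notice, since quartiles of three points are mostly noise. Censored values
are substituted first — `BDL → MDL/2` (the conventional half-detection-limit
surrogate), `AQL → UQL` — and for log-flagged parameters the quartiles are
computed on log10 values, with non-positive values excluded with a notice.
Flags are invariant to any strictly monotone transform applied consistently,
so the log-space computation matters only through the quantile
interpolation; it keeps the fences symmetric on the scale on which the data
actually vary. Flags are specific to the grouping choice: the same value can
be extreme within its month but unremarkable within its site.

One caveat worth knowing: with interpolated quartiles, appending a duplicate
of the group median shifts the quartile positions and can slightly narrow
the IQR, so the flag status of *borderline* points can change; the median
itself always stays inside the fences. The test suite checks the property
that actually holds.

Screening only identifies candidates — the six-column hit table and the
labelled boxplots exist so a human can decide; nothing is removed or
corrected automatically.

## Summaries

`resolve_settings()` centralizes the automatic behavior: with
`sumfun = "auto"` and `yscl = "auto"`, log-flagged parameters get a log10
axis and geometric-mean summaries, everything else a linear axis and
arithmetic means; explicit settings override either independently. 95%
confidence intervals are normal-theory `stat ± 1.96·SE`, computed on the log
scale and back-transformed for geometric means (an interval for the
geometric mean must be multiplicative; back-transforming the log-scale
interval is the standard choice and keeps `lo ≤ stat ≤ hi`). Intervals are
reported only for `n ≥ 2` and only for mean/geomean. Requesting a geometric
mean on non-positive data errors, naming offending records.

Seasonal views group by month name or ISO week; date series aggregate per
date by site, by the sites table's `Location Group`, or across all sites;
spatial aggregates give one row per site with coordinates, ready for a map
layer. Threshold overlays come from the configuration's editable threshold
table (parameter, fresh/marine context, value, unit, and a source shown in
the legend) — the shipped entries are examples to edit, since many such
thresholds are jurisdiction-specific. Overlays are pure presentation and
never alter computed statistics.

## WQX export

The submission workbook has exactly three sheets — `Project`, `Locations`,
`Results` — with the Results column set following the USEPA
physical/chemical template, held in configuration so template revisions
don't require code changes. Censored values export as a detection condition
(`Not Detected` / `Present Above Quantification Limit`) plus the detection
limit, never as fabricated numbers. Duplicate pairs expand to two rows with
paired activity types (`... 1` / `... 2`); a regular row hosting a pair
keeps its own activity type and emits the paired value as a duplicate
activity. The expansion count is logged, and re-reading the workbook
reproduces sheet names, column order, and every cell exactly. Time zone and
sample-collection defaults are configuration, not constants. Row-level
verification before upload remains the user's job.

Workbooks are written by the package's own small deterministic writer:
every cell is an inline string, which is precisely what makes the
string-exact round-trip guarantee possible — a typed writer would quietly
coerce censoring tokens and identifier-like numbers.

## The synthetic-data generator

`generate_bundle(fixture_spec(seed))` draws one May–September season:
6 sites (half "Mainstem", half "Tributary") sampled every 14 days, eight
parameters — DO, ammonia, TP, nitrate, pH, specific conductance, E. coli,
water temperature — with lognormal values for the log-flagged parameter
(E. coli) and zero-truncated normal values otherwise; QC activities at 12%
of regular samples per applicable check type (the common objective is
≥ 10%); a 6% `BDL` rate on lab analytes; 6% of regular lab rows hosting
same-row duplicate pairs (qualified samples); one planted extreme DO value
(8× typical level) and one TP field blank planted exactly at its threshold.
Planted anomalies are returned in ground-truth sidecars so recovery can be
asserted end to end. Everything is reproducible from `(spec, seed)`, and a
generated bundle passes all fifteen validation checks by construction.
These sizes (roughly 700–750 result rows) keep the full test suite and the
acceptance script fast while exceeding the row counts the row-addressing
behavior needs.

What the generator does *not* emulate: serial correlation within sites,
seasonal trends, detection-limit censoring that depends on concentration,
matrix-specific lab error, or messy real-world formatting (the corruption
helper exists to create specific format errors deliberately). Passing tests
on generated data therefore demonstrate the correctness of the arithmetic
and the plumbing — check ordering, verdict logic, table coherence, round
trips — not the field realism of any particular dataset.

## Known limitations

- One unit per parameter is enforced; there is no unit conversion.
- The report's DOCX/HTML formats require pandoc; Markdown is always
  available.
- Maps are coordinate scatters plus user-supplied layers; no hydrography or
  basemap retrieval is bundled.
- Value-range-dependent DQOs resolve by narrowest range; programs with
  deliberately overlapping equal-width ranges should order the file by
  priority.
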