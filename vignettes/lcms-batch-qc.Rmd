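---
title: "Batch QC for targeted LC-MS/MS: rules, cutoff calibration, and dashboard views"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batch QC for targeted LC-MS/MS: rules, cutoff calibration, and dashboard views}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcmsqc)
library(dplyr)
```

## The problem

Clinical toxicology laboratories running targeted LC-MS/MS confirmation
assays — here modelled on a multiplexed urine opioid panel with two dozen
compounds and isotope-labelled internal standards, split across two
instruments — accumulate a large stream of instrument metadata with every
injection: peak areas, retention times, signal-to-noise, confirming-ion
areas, and the paired internal-standard measurements. Automated review
software flags analytes that fail per-compound QC rules, and technologists
triage the flags by hand. Two maintenance questions then arise continuously:

1. **Are the configured cutoffs still right?** Rule thresholds are fixed at
   assay validation, but instrument sensitivity drifts, internal-standard
   lots vary, and different instruments have systematically different signal
   levels. A cutoff that is too high floods reviewers with false-positive
   flags; one that is too low misses real ion suppression.
2. **Is the instrument behaving?** Batch-to-batch trends in
   internal-standard signal, first-calibrator response and retention time
   reveal developing hardware problems before they become QC failures.

`lcmsqc` implements the full loop: parse batch XML exports into a
three-table relational store, evaluate the five QC rules, re-derive
candidate cutoffs from the historical distributions, quantify what a rule
change would have done to past flags, and compute the data behind five
monitoring views. A synthetic-batch generator with known ground truth makes
every step testable without clinical data.

## Data model

Each analytical batch arrives as one XML file and is decomposed into three
tables, each row carrying a surrogate integer key:

* **batch** — one row per file: file name (unique, making ingestion
  idempotent), acquisition timestamp, instrument id, injection time span,
  sample count.
* **calibration** — one row per compound per batch: internal standard,
  curve weighting, slope, r², curve type, origin handling. Stored for
  trending; curve acceptance itself is not flagged here.
* **results** — one row per (sample, compound) pair: sample type
  (calibrator / qc / patient / blank, normalised from the file's free-text
  vocabulary), quantifying and confirming ion peak areas, retention time,
  S/N, concentration, and the same quartet for the paired internal
  standard. The instrument id is denormalised onto every result row because
  every historical evaluation splits by instrument.

Timestamps are normalised to UTC at parse. Missing or non-numeric numeric
fields are stored as nulls — never coerced to zero, which would silently
drag percentile borders toward zero — and each one is recorded as a parse
warning. Date filters are half-open intervals `(start, end]` on injection
time so month-partitioned views cannot double-count boundary injections.
The store is treated as read-only history: nothing in the package mutates
a loaded row.

## The five QC rules

All rules share three conventions, chosen once and tested explicitly
because vendor documentation rarely states them:

* minima **pass at equality** (a value exactly at the cutoff is
  acceptable), and the RRT window is inclusive at both bounds;
* a **null input never fails** — the flag status is `not_evaluable`, so
  missing data is surfaced rather than punished;
* a **null threshold disables** the rule (status `pass`, threshold
  `"disabled"`), which permits partial rule sets during migration.

The rules, per compound and instrument (an instrument-specific entry beats
the `"*"` wildcard):

1. **RRT** — relative retention time, `rt / is_rt`. Analyte and its
   isotope-labelled internal standard co-elute, so values centre on 1.0;
   the default window is 0.984–1.024.
2. **Internal-standard peak area** — `is_peak_area >= is_peak_area_min`.
   The IS is spiked into every sample at constant amount, so a low area
   means injection failure or matrix ion suppression.
3. **First-calibrator (Std-A) signal** — a batch-level rule: the lowest
   calibrator's quantifying area gates batch sensitivity. The "first"
   calibrator is identified by ascending level label (`Std-A < Std-B <
   ...`), falling back to ascending nominal concentration when labels tie.
4. **S/N** — `sn >= sn_min` on the analyte peak. (Whether to also gate the
   internal standard's S/N is left out deliberately; only the analyte is
   flagged.)
5. **Ion ratio** — confirming/quantifying area against an expected ratio
   within a relative tolerance band (default ±20%). The expected value is
   the configured per-compound ratio when present, otherwise the mean ratio
   of the batch's own calibrators — the standard confirmation practice when
   a fixed expectation has not been established.

`evaluate_batch()` applies rules 1, 2, 4 and 5 to every QC and patient row
and rule 3 once per batch × compound. Reported totals are exact tallies of
the emitted flags, and the suite checks the whole engine against an
independently written brute-force per-row oracle, including boundary and
all-null cases.

### Internal-standard lot bias

Internal-standard working solutions prepared in-lab differ slightly between
lots. A relative bias of up to 10% (inclusive) between the new lot's mean
peak area and the reference mean is accepted without action; beyond that,
`adjust_is_cutoff_for_lot()` rescales the cutoff multiplicatively by the
lot/reference ratio. Rescaling the cutoff is arithmetically equivalent to
rescaling the observed areas for flagging purposes; the cutoff-side version
keeps stored data untouched.

## Cutoff calibration

`empirical_border()` computes the value below which a chosen fraction of
the historical distribution falls — by default the bottom 2%, the working
definition of a candidate cutoff that would exclude only the extreme low
tail. The estimator is fixed to linear interpolation between order
statistics (the classical "type 7" definition): deterministic, universally
implemented, and convergent, so borders re-derived next month are
comparable to this month's.

Two small conventions matter for consistency:

* `fraction_below()` uses **strict** inequality, mirroring
  pass-at-equality in the flag engine, so a predicted fail fraction equals
  the realised flag rate exactly — the suite asserts this identity on a
  planted corpus.
* The quantile bracketing property (`fraction_below(v, border(v, p)) <= p`,
  reaching `>= p` once the border's tied values are added) requires at
  least `1/p` observations. `derive_cutoffs()` therefore skips groups
  smaller than `min_n = 50` with a warning — exactly the floor for the
  default 2% level.

`derive_cutoffs()` groups the filtered history by (compound, instrument)
and emits one border per group, because instruments show systematically
different signal levels and a pooled border would fit neither machine. The
two-stage evaluation — controlled material first, then including patient
specimens to expose matrix effects — is one code path driven by the
`sample_types` filter, not two operations.

`compare_rulesets()` quantifies a proposed rule change: both rule sets are
evaluated on the identical (result, rule) observation pairs, restricted to
pairs evaluable under both; *new* flags fail only under the new rules,
*removed* flags only under the old, and the two percentages are reported
against the shared observation count. A (result, rule) pair can be at most
one of new, removed, or unchanged, so the three counts partition the
observations.

## The five views

Every view computes its numbers through the same primitives the rule engine
and calibration module use, so a dashboard can never disagree with the
flags; the suite asserts bit-identical agreement on shared selections.

* **Histogram** — equal-width bins (default 50) over one parameter's
  filtered selection, with the configured cutoff and the 2% border
  overlaid. Bins are half-open `[left, right)` with the last bin closed, so
  counts always sum to the number of non-null values. Bimodal
  internal-standard distributions — seen in practice when sub-LLOQ noise or
  interferents enter the history — show up here descriptively; no formal
  mixture test is applied.
* **Plotted average** — per-period summary statistics (calendar month in
  UTC, or per batch), each row contributing to exactly one group.
* **Plotted batch** — one batch's values in injection order with the
  cutoff overlay.
* **Std-A signal** — the first calibrator's area per batch × compound with
  pass/fail straight from `check_std_a()`, and a per-batch colour code
  (`all_pass` / `any_fail`).
* **Absolute RT vs monthly average** — per-batch mean retention time
  against its calendar month's mean, with exact deviations. The monthly
  mean is the **equal-weight mean over rows**, not a mean of batch means;
  with unequal batch sizes the two differ, and the row-weighted version was
  chosen so that the monthly mean equals the plain mean of the month's
  selection. (A batch shifted by δ then deviates by δ·(1 − batch n /
  month n), which the tests verify against brute-force recomputation.)

Each view object has an `autoplot()` method; the plots draw exactly the
numbers the view computed.

## The synthetic generator

`generator_config()` defines the statistical conditions; `generate_corpus()`
emits dialect XML plus a plain-CSV ground-truth sidecar that production code
never reads. The defaults model the assay setting the package is aimed at:

* six calibrator levels (Std-A lowest) at 1–500 ng/mL, two QC samples, the
  rest patient specimens, ~20 samples per batch, batches alternating between
  two instruments every 3.5 days;
* internal-standard peak areas drawn lognormal (meanlog 11, sdlog 0.4 —
  areas around 60,000 counts, right-skewed as positive signal intensities
  are), scaled per instrument (default second-instrument factor 0.7,
  reflecting routinely observed between-instrument differences in ion
  optics and detector gain);
* analyte RT = nominal × N(1, 0.005) with the IS at nominal, so RRTs centre
  on exactly 1.0 and roughly one injection per thousand falls outside the
  0.984–1.024 window;
* optional second lognormal mode for bimodal IS distributions, optional
  ion-suppression of patient rows (probability 2%, area multiplier 0.3)
  mimicking dilute-and-shoot matrix effects, and a configurable
  missing-field rate.

Planted-violation directives (`plant_below_cutoff()`, `plant_rrt_outside()`,
`plant_std_a()`) modify draws after generation so a corpus contains an
*exact* number of violations: the requested rows are forced below the
cutoff (or outside the window) and every other eligible row is reflected to
the passing side. That exactness is what lets the suite assert planted
fractions and flag-delta percentages as identities rather than
approximations.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: within-batch signal drift, chromatographic
peak shapes and integration artefacts, carryover, correlated
compound-to-compound suppression, and realistic concentration
pharmacology. The generator validates the machinery (parsing, storage,
rule semantics, estimators, view arithmetic), not the clinical performance
of any particular cutoff.

## Numerical choices and problem sizes

* Doubles are serialised to XML with 17 significant digits, so
  parse → write → parse round trips are bit-exact; the suite checks this on
  a 50-batch corpus with 5% missing fields.
* The rule-engine oracle comparison runs on a corpus of ≥10⁴ result rows
  with planted boundary-equality and null cases.
* Quantile recovery is checked against the closed-form lognormal 2% point
  `exp(μ + σ·z₀.₀₂)` at n = 10³, 10⁴, 10⁵ (mean error over 10 replicates,
  decreasing in n; <1% relative at 10⁵).
* Instrument separation uses 10⁴ rows per instrument with a planted 0.5
  scale factor, recovered by the border ratio within 5%.

These sizes keep the default check run around half a minute on one CPU
while leaving the statistical assertions comfortably powered.

## A worked pass through the loop

```{r pipeline}
cfg <- generator_config(seed = 20, n_batches = 10, samples_per_batch = 16,
                        missing_field_rate = 0.01)
dir <- file.path(tempdir(), "corpus")
man <- generate_corpus(cfg, dir)

con <- init_schema(":memory:")
for (pb in parse_folder(dir)) load_batch(pb, con)

rs <- ruleset(bind_rows(lapply(default_compounds()$name, function(cn)
  compound_cutoffs(cn, is_peak_area_min = 30000, sn_min = 50,
                   std_a_peak_area_min = 500))), name = "validation-era")

glance(evaluate_batch(man$batches[[1]], rs))

derive_cutoffs(con, result_filter(sample_types = c("calibrator", "qc")),
               "is_peak_area", level = 0.02, min_n = 20) |>
  select(compound, instrument_id, border, n) |>
  head()
```

```{r views, fig.width = 6, fig.height = 4}
autoplot(histogram_view(con, result_filter(compounds = "Morphine",
                                           instruments = "LCMS-1"),
                        "is_peak_area", ruleset = rs, n_bins = 20))
```

```{r cleanup, include = FALSE}
DBI::dbDisconnect(con)
```

## Known limitations

* The XML dialect is a documented minimal grammar, not a vendor schema; a
  vendor-specific reader can replace the parser layer without touching the
  rest of the package.
* One file is assumed to carry one instrument's batch, matching the
  batch-level instrument id in the data model.
* The continuing-calibration (CC) membership flag is stored but unused by
  the rule engine, and calibration-curve r² is stored but not gated.
* The LLOQ is carried per compound as metadata for filtering; no
  suppression rule is applied to sub-LLOQ concentrations.
* Cutoff proposals are descriptive: the package derives borders and
  quantifies rule-change impact, but accepting a new cutoff remains a human
  decision.
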