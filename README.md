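# lcmsqc

Quality-control toolkit for targeted LC-MS/MS batch data: parse
quantification batch XML exports into a relational three-table model,
evaluate per-sample QC rules, re-derive cutoffs from historical
distributions, compare rule sets by their flag deltas, and compute the data
behind instrument-performance dashboard views.

## Who this is for

Clinical and analytical laboratories running targeted LC-MS/MS
quantification — the motivating setting is a multiplexed urine opioid
confirmation assay with isotope-labelled internal standards split across
two instruments — where automated review software flags analytes failing
per-compound QC rules and staff need to (a) keep those rule thresholds
aligned with what the instruments actually do, and (b) watch instrument
performance batch to batch.

## The model

Every result row (one compound in one injection) carries its quantifying
and confirming ion peak areas, retention time *rt*, S/N, and the paired
internal-standard (IS) measurements. Five rules are evaluated per compound
× instrument:

| rule | quantity | fails when |
|---|---|---|
| RRT | rt / is_rt | outside the inclusive window [low, high] (default 0.984–1.024) |
| IS peak area | is_peak_area | strictly below the minimum |
| Std-A | first calibrator's peak area | strictly below the minimum (once per batch × compound) |
| S/N | sn | strictly below the minimum |
| ion ratio | confirming / quantifying area | relative deviation from the expected ratio exceeds the tolerance (default ±20%); expectation = configured value or the batch's calibrator mean |

Minima pass at equality; null inputs are `not_evaluable`, never failures;
null thresholds disable a rule. Candidate cutoffs are re-derived from
history as empirical percentile borders — the value excluding the bottom
2% of a (compound, instrument) group's distribution, computed with the
type-7 (linear-interpolation) quantile — and a proposed rule change is
quantified by evaluating both rule sets on identical (result, rule)
observations and counting new versus removed flags. An IS-lot bias of up
to 10% is accepted as-is; beyond that the IS cutoff is rescaled by the
lot/reference ratio.

A synthetic-batch generator (lognormal signal laws, per-instrument scale
factors, optional bimodality and ion suppression, exact-count failure
planting) makes the whole pipeline testable with known ground truth; no
real data ship with the package.

## Worked example

```r
library(lcmsqc)
library(dplyr)

# a seeded synthetic corpus standing in for a folder of batch exports
cfg <- generator_config(seed = 20, n_batches = 10, samples_per_batch = 16,
                        missing_field_rate = 0.01)
man <- generate_corpus(cfg, "corpus")

con <- init_schema("qc.sqlite")
for (pb in parse_folder("corpus")) load_batch(pb, con)

rs <- ruleset(bind_rows(lapply(default_compounds()$name, function(cn)
  compound_cutoffs(cn, is_peak_area_min = 30000, sn_min = 50,
                   std_a_peak_area_min = 500))), name = "validation-era")

evaluate_batch(man$batches[[1]], rs)
#> <qc_flag_report> ruleset 'validation-era': 246 flags (2 fail, 5 not evaluable)
#> # A tibble: 5 × 4
#>   rule          pass  fail not_evaluable
#>   <chr>        <int> <int>         <int>
#> 1 ion_ratio       60     0             0
#> 2 is_peak_area    58     2             0
#> 3 rrt             58     0             2
#> 4 sn              57     0             3
#> 5 std_a            6     0             0
```

96 results per batch (16 samples × 6 compounds) produce 246 flags: four
per-row rules on the 60 QC/patient rows, plus one batch-level Std-A flag
per compound. Two IS peak areas fell below the configured 30,000-count
cutoff; five flags are `not_evaluable` because the corpus was generated
with a 1% missing-field rate and missing inputs never fail.

```r
derive_cutoffs(con, result_filter(sample_types = c("calibrator", "qc")),
               "is_peak_area", level = 0.02, min_n = 20) |>
  select(compound, instrument_id, border, n)
#> # A tibble: 12 × 4
#>   compound             instrument_id border     n
#>   <chr>                <chr>          <dbl> <int>
#> 1 6-Monoacetylmorphine LCMS-1        27087.    40
#> 2 6-Monoacetylmorphine LCMS-2        19017.    40
#> 3 Codeine              LCMS-1        22629.    39
#> 4 Codeine              LCMS-2        22999.    37
#> # ...
```

These are the per-instrument 2% borders of the IS-area history on
controlled material — the empirical candidates to compare against the
configured 30,000 cutoff (which the borders here say is too high for this
corpus). `histogram_view()` overlays both on the distribution;
`compare_rulesets()` reports what adopting the new values would have done
to historical flags; `autoplot()` renders any view.

A thin command-line wrapper over the same functions ships in
`inst/cli/lcmsqc.R` (`synth`, `init-db`, `ingest`, `qc-run`,
`derive-cutoffs`, `compare-rulesets`, `export`).

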