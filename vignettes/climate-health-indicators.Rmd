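---
title: "Methods: local climate-and-health indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: local climate-and-health indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climvuln)
```

## The procedure

`climvuln` operationalizes a county-scale climate-and-health vulnerability
assessment for a rural district facing three hazards: extreme heat, drought
and flooding. The workflow has four stages — exposure detection,
vulnerability classification, hazard-matrix assembly and surveillance — and
a synthetic-data module that makes each stage testable without restricted
health data.

The assessment is deliberately non-statistical: county indicator values are
compared directly with state and national references rather than modelled,
which matches the resource constraints of local health departments and
produces a screening-level ranking, not an inferential one. Nothing in the
package performs significance testing, age standardization or spatial
smoothing; all indicator values are assumed pre-normalized to comparable
units (percentages, rates per 10,000, µg/m³).

## Exposure definitions and their parameters

All parameters live in one object, `detection_params()`:

| parameter | default | units | role |
|---|---|---|---|
| `heat_threshold` | 95 | °F | daily maximum temperature cut-off, inclusive |
| `min_run` | 3 | days | minimum consecutive qualifying days for a heat event |
| `season` | 05-01 … 09-30 | month-day | window inside which heat days are counted |
| `precip_threshold` | 2.0 | inches | heavy-precipitation cut-off, strict |
| `drought_min_severity` | D2 | USDM category | minimum category counting as drought exposure |

Two asymmetries are intentional and follow the wording of the definitions
the package encodes: the heat comparison is *inclusive* (a day at exactly
95.0 °F qualifies) while the precipitation comparison is *strict* (a day at
exactly 2.0 inches does not). Temperatures are Fahrenheit throughout; a
series declaring any other unit is rejected rather than converted, because
silent unit conversion is a classic source of threshold bugs.

Decisions where the definitions are silent:

* **Missing days break runs.** An unobserved day is never assumed hot; a
  10-day hot stretch with one missing value becomes two shorter runs. This
  is conservative — it can only under-report exposure, never invent it.
* **Season clipping.** Qualifying days are counted only inside the season
  window, so a run straddling September 30 is reported clipped to the
  season and must still have `min_run` in-season days to qualify.
* **District consolidation** merges county event windows that overlap or
  abut exactly (the next window starts the day after the previous ends);
  windows separated by one or more non-qualifying days stay separate.
  Counties whose longest overlapping run lasted exactly `min_run - 1` days
  are annotated as near-threshold rather than affected — mirroring the
  "reached threshold for 2 days" footnote convention in district reports.
* **Drought weeks expand to 7 days** starting at the week-start date when
  daily resolution is needed, matching the weekly US Drought Monitor
  cadence. A gap in the weekly grid (week starts more than 7 days apart)
  breaks a spell.

### Heat-drought overlap and the containment policy

`overlap_days()` counts distinct calendar days covered by at least one
heat event and lying inside a drought period. Published district totals do
not state how events partially inside the period were handled, so the
package offers both policies: under `"containment"` (the default) an event
contributes only if it lies entirely inside the period; under
`"intersection"` each event day inside the period counts. The containment
policy is the default because it reproduces the district's published
July–August 2012 total (26 + 3 + 4 = 33 days from the three fully
contained windows); the per-day intersection of the same windows gives 43.
Users comparing against other published totals should check which rule the
source used.

## The tier rule

For an observation with county value $x$, references $r_1, \dots, r_k$
($k \in \{1, 2\}$: state and/or national) and a direction $d \in \{+1,
-1\}$ (+1 when higher is worse), define the signed excess $e_i = d\,(x -
r_i)$. The tier is

$$
\text{tier}(x) =
\begin{cases}
\text{high} & e_i > 0 \;\forall i\\
\text{low} & e_i < 0 \;\forall i\\
\text{moderate} & \text{otherwise,}
\end{cases}
$$

and *unknown* when no reference is available. Three consequences worth
making explicit:

* **Ties are moderate.** "Worse than both" and "better than both" are read
  strictly, so equality with either reference lands in moderate. Ties are
  rare in continuous rates, and a county exactly at the state average is
  not "falling short" of it.
* **A single reference suffices**, and strictly worse than the sole
  reference is high. The district's own floodplain indicator is the
  precedent: a Kentucky-only comparison (13.6% vs 5.4%) was published as
  high vulnerability.
* The rule is translation-equivariant and antisymmetric under direction
  flip (high ↔ low, moderate fixed); the test suite asserts both over
  randomized inputs.

Federal standards **supplement** the state/national comparison — both
results are reported side by side (`tier` and `standard_result`), because
the standards were *also* compared, not substituted. The shipped registry
names the five standard-bearing indicators and their benchmark sources but
leaves the values as required configuration (`set_standard()`): benchmark
values are policy choices that get revised, and hard-coding them would
silently date the package.

One registry detail: the published hazard matrix flags poverty under
drought for one county although the indicator-source table lists poverty
as a heat/flood indicator only. The registry follows the matrix (poverty
maps to all three hazards) so the transcribed fixture validates; the wider
mapping is harmless because tiers only fan out to hazards the registry
permits.

## The hazard matrix and its counts

`build_matrix()` fans each (indicator, county) tier out to exactly the
hazards the registry lists for the indicator. "High-vulnerability
indicators per county" counts **distinct indicators** high under at least
one hazard, not indicator-hazard checkmarks — the only reading under which
the transcribed district matrix yields the published six-to-eight range.
The per-county and per-indicator tallies are linked by a conservation
identity (both sum to the number of distinct high (county, indicator)
pairs), asserted in the tests.

## Surveillance

Triggers follow the exposure definitions: a heat alert fires on the third
qualifying day of a run and on each subsequent day of the run (an alert
carries its run-start date, so the set of days covered by alerting runs
equals the set of detected heat-event days exactly — the form in which
trigger/detection consistency is tested); a drought alert fires per
county-week at D2 or worse; a flood alert per day strictly over 2 inches.

Outcome matching normalizes codes (uppercase, dots stripped) and accepts a
listed category code or any child subdivision of it (prefix at the
subdivision boundary): `x30`, `X30.0` and `X300` all match a listed `X30`;
`X3` does not, and malformed codes are rejected with a reason rather than
silently dropped. Heat-outcome matching is restricted to the May–September
window; flood matching is year-round. The drought outcome code set ships
empty (it is still in development in the source surveillance proposal) but
the drought trigger is active. ICD-9 morbidity codes are listed as
published; adding post-2015 ICD-10-CM morbidity equivalents is left to
configuration since the mapping is a coding-policy decision.

## What the synthetic data does and does not emulate

The generators exist to embed known structure, not to be a climate model:

* `gen_weather()` draws independent Gaussian daily maxima around a
  baseline (default mean 86 °F, sd 6 °F — a typical district July) with
  exponential wet-day precipitation (default wet-day probability 0.3, mean
  0.3 in). Embedded heat runs force exact values (`threshold + offset`),
  and a zero noise spread is allowed so construction-exact tests exist;
  noisy tests assert statistically. **Not emulated:** temporal
  autocorrelation of heat waves, humidity, spatial correlation between
  counties, or station-to-county aggregation. Passing tests therefore
  demonstrate algorithmic correctness of the run-length machinery, not
  realism of simulated summers.
* `gen_drought()` places D2+ spells (peak category mid-spell, D2
  shoulders) on a sub-D2 background; there is no drought persistence
  model.
* `gen_indicator_table()` displaces county values beyond the worst (high)
  or best (low) reference by a fixed offset, or strictly between the
  references (moderate), so classification recovers the embedded tier
  exactly — a round-trip identity, not a claim about real indicator
  distributions.
* `gen_claims()` draws independent Poisson counts per county-day
  (background distractor codes, plus per-hazard excess codes on exposure
  days); there is no within-person correlation, which is all surveillance
  matching needs (codes and dates).

All four generators are deterministic under a fixed seed
(`withr::with_seed`, so the caller's RNG state is untouched).

## Numerical and testing choices

* Run detection uses run-length encoding over a complete daily grid; the
  tests cross-check it against an independent exhaustive-window oracle
  (every (start, end) window tested for all-qualifying, minimum-length,
  non-extendable) on random series of 30–400 days — 60 seeds in the unit
  suite and 1,000 seeds in the acceptance suite, alongside a week-scan
  oracle for drought spells and a day-by-day oracle for overlap counts.
  These sizes keep the full suite under two minutes on one CPU while
  covering every boundary the algorithms have (season edges, missing-value
  breaks, runs at the series ends).
* Degenerate inputs are defined, not errors: empty series yield empty
  results; an empty observation table yields an empty matrix whose summary
  is all zeros; all-quiet inputs yield no alerts.
* Input validation is strict where silent damage is possible: unsorted or
  duplicated dates, out-of-range temperatures, negative precipitation,
  invalid drought categories, unknown indicator ids (listing the
  offenders) and non-Fahrenheit units all abort with stage-attributed
  messages.
* Pipeline outputs are written sorted, so reruns with identical inputs are
  byte-identical — asserted with checksums in the tests.

## Known limitations

* No spatial analysis: no mapping, interpolation or sub-county resolution;
  station-to-county consolidation of weather series is out of scope.
* No humidity-adjusted heat metrics (heat index) and no streamflow-based
  flood detection; flooding exposure is precipitation-only.
* The classification is a screening heuristic; it makes no claim about
  statistical significance of county-reference differences.
* Mental-health indicators are carried in the registry but real data for
  them is typically unavailable at county scale.
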