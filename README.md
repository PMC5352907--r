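# climvuln

Local climate-and-health environmental public health indicators for rural
health districts.

Rural health departments increasingly need to assess their communities'
vulnerability to climate-related hazards — extreme heat, drought and
flooding — but national tracking datasets thin out below the state level and
few tools exist for building a county-scale evidence base. `climvuln`
implements the full local indicator workflow for a multi-county district:

1. **Exposure detection** from daily weather and weekly drought series:
   - an *extreme heat event* is a maximal run of ≥ 3 consecutive days with
     daily maximum temperature T<sub>max</sub> ≥ 95 °F inside the May 1 –
     September 30 season;
   - a *heavy precipitation day* has daily precipitation strictly
     > 2 inches;
   - a *drought spell* is a maximal run of consecutive weeks declared at
     D2 (severe) or worse on the US Drought Monitor scale;
   - county events are consolidated into district events (overlapping or
     abutting windows merge), with near-threshold annotations for counties
     that stayed hot for only 2 consecutive days;
   - heat-drought coincidence is quantified as the number of distinct
     heat-event days inside a drought window.
2. **Vulnerability classification.** A county indicator value *x* is
   compared with its state reference *s* and national reference *n* under
   a per-indicator direction (usually "higher is worse"):
   *high* if strictly worse than both, *low* if strictly better than both,
   *moderate* otherwise (between them or tied). Five indicators are
   additionally compared with configurable federal benchmarks (EPA annual
   fine-particulate standard, Healthy People 2020 goals).
3. **Hazard matrix.** Classified tiers fan out to the hazards each
   indicator informs (a registry of 27 indicators across exposure, health
   outcome, population vulnerability and environmental vulnerability
   categories), giving the county × indicator × hazard matrix and its
   summary counts.
4. **Surveillance.** Exposure triggers (heat run day 3+, county-week at
   D2+, day over 2 inches of rain) and reportable-outcome matching of
   ICD-coded records (heat: ICD-10 X30, ICD-9 992/E900.0/E900.9,
   May–September; flooding: ICD-10 W69/W70/X38, ICD-9
   E908.2/E908.9/E910.8/E910.9, year-round).

A synthetic-data module generates weather, drought, indicator and claims
inputs with known embedded structure, so the whole pipeline is testable
without access to restricted health data. The package also ships the Green
River District (Western Kentucky) published event record and
high-vulnerability matrix as transcribed fixtures.

## Worked example

Generate a noise-free district summer with one embedded 14-day heat run in
Union County and a 2-day near miss in Daviess, then detect and consolidate:

```r
library(climvuln)

w <- gen_weather(weather_sim_config(
  c("Daviess", "Union"), "2012-05-01", "2012-09-30",
  baseline_tmax_mean = 84, baseline_tmax_sd = 0,
  embedded_heat_runs = tibble::tibble(
    county = c("Union", "Daviess"),
    start  = as.Date(c("2012-06-27", "2012-07-01")),
    length = c(14L, 2L), offset = c(2, 1)),
  seed = 42))

detect_heat_events(w)
#> # A tibble: 1 × 5
#>   county start      end        duration_days peak_tmax_f
#>   <chr>  <date>     <date>             <int>       <dbl>
#> 1 Union  2012-06-27 2012-07-10            14          97

dist <- consolidate_district_events(detect_heat_events(w), heat_runs(w))
dist$near_threshold[[1]]
#> # A tibble: 1 × 2
#>   county  length
#>   <chr>    <int>
#> 1 Daviess      2
```

Only the 14-day run is an event (2 days is below the 3-day minimum), but
the Daviess near miss is annotated on the district event. The same
machinery reproduces the district's published results: the six 2012 event
windows fully contained in the July–August 2012 drought cover

```r
ev <- green_river_heat_events()
overlap_days(ev[format(ev$start, "%Y") == "2012", ],
             as.Date(c("2012-07-01", "2012-08-31")))
#> [1] 33
```

33 days of coincident extreme heat, and the transcribed high-vulnerability
matrix gives per-county counts of distinct high indicators:

```r
matrix_summary(green_river_matrix())$per_county
#> # A tibble: 7 × 2
#>   county    n_high
#>   <chr>      <int>
#> 1 Daviess        6
#> 2 Hancock        8
#> 3 Henderson      8
#> 4 McLean         8
#> 5 Ohio           8
#> 6 Union          6
#> 7 Webster        8
```

ranging from 6 to 8 per county. Classification itself is a one-liner — the
district fine-particulate mean against the state and national means:

```r
classify_tier(14.1, 13.5, 11.1, "higher_is_worse")
#> [1] "high"
```

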