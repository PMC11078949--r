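# betadecay

Community samples collected again and again across a trap network — one
set of detected species per site and week — hold three intertwined
signals: communities drift apart with distance in space, with distance
in season, and faster or slower depending on where the pair sits along
the latitudinal diversity gradient. `betadecay` is an R package for
ecologists analysing such presence/absence "trapping event" data
(DNA-metabarcoding BIN tables, classical survey data) who want those
three signals separated, modelled and tested honestly.

## What it computes

For every unordered pair of trapping events, with `a` shared species and
`b`, `c` unique to each side:

- **Total beta-diversity** (Jaccard): `(b + c) / (a + b + c)`,
  partitioned (Podani family) into
- **species replacement** `2·min(b, c) / (a + b + c)` and
- **richness difference** `|b − c| / (a + b + c)`,
  which sum exactly to the total.

Each component is regressed on great-circle distance ΔS, circular
day-of-year distance ΔT (0.986°/day, folded to [0, 180]°), mean absolute
latitude `Lat = (|lat₁| + |lat₂|)/2`, and the interactions Lat×ΔS and
Lat×ΔT, with weights `1/n(s₁,s₂)` that give every *site pair* total
weight 1 regardless of sampling effort. Because event pairs are not
independent, each term is tested by a permutation log-likelihood-ratio
test that permutes the exchangeable units — site coordinate tuples, or
sampling dates within sites — rather than data rows. A configurable
metacommunity simulator provides null and structured campaigns on which
the test suite measures calibration and power.

## Worked example

```r
library(betadecay)

d <- make_worked_example()      # 3 sites, 7 events, 12 species
p <- build_pair_table(d)        # 21 pair records
p[1, c("event_i", "event_j", "delta_time_deg",
       "beta_total", "beta_repl", "beta_rich", "weight")]
#> # A tibble: 1 × 7
#>   event_i event_j delta_time_deg beta_total beta_repl beta_rich weight
#>   <chr>   <chr>            <dbl>      <dbl>     <dbl>     <dbl>  <dbl>
#> 1 EQ_w1   EQ_w2             6.90      0.667     0.667         0      1
```

The two equatorial events share 2 species of 6 observed, so total
dissimilarity is 4/6; `b = c = 2` makes it pure replacement (richness
difference 0). Their harvests are 7 days = 6.9° apart on the annual
circle, and as the only event pair joining this site with itself the
record carries the full site-pair weight 1.

A full analysis on a simulated structured campaign:

```r
ds  <- simulate_metacommunity(effect_preset(seed = 1))
res <- run_full_analysis(ds, scopes = "Global", responses = "total",
                         n_perm = 199, seed = 1)
res[, c("term", "p_value", "direction", "significant")]
#> # A tibble: 5 × 4
#>   term       p_value direction significant
#>   <chr>        <dbl> <chr>     <lgl>
#> 1 DeltaS       0     +         TRUE
#> 2 DeltaT       0     +         TRUE
#> 3 Lat          0     -         TRUE
#> 4 Lat:DeltaS   0.724 -         FALSE
#> 5 Lat:DeltaT   0     +         TRUE
```

Dissimilarity rises with spatial and seasonal distance and falls toward
high latitudes (direction `-`), the structure this preset builds in; in
this realisation the rate of seasonal decay also varies detectably with
latitude (Lat:DeltaT). A p-value is the share of 199 permutations whose
full-vs-reduced LLR exceeds the observed one.

The numbered scripts under `analysis/` run the same steps as a
documented workflow — `01_simulate.R`, `02_partition_pairs.R`,
`03_fit_models.R`, `04_permutation_tests.R` — writing tables under
`results/`. The methods vignette
(`vignettes/beta-diversity-decay.Rmd`) documents the model, the
permutation schemes, the simulator and its limits.

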