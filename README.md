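# ipvkit

Item Pool Visualization (IPV) for comparing psychological questionnaires
that target a common construct — here, four flourishing measures analysed
as one 47-item pool: the Mental Health Continuum-Short Form (MHC-SF, 14
items), the 15-item core of the PERMA-Profiler, the Flourishing Scale (FS,
8 items) and the Wellbeing Conceptual Framework (WBCF, 10 items). The
package is for psychometricians and wellbeing researchers who want to know
*which instrument sits closest to the shared core construct* rather than
merely whether the instruments correlate.

## The method

Two confirmatory factor models are estimated on the same pooled data:

* a **general factor model** — one factor over all items (the construct's
  core), giving each item a standardized loading λ<sub>g</sub>;
* a **correlated factor model** — one factor per sub-pool (facet or
  instrument), factors freely correlated, giving each item a specific
  loading λ<sub>s</sub>.

Each item's **center distance** is the proportional increase in explained
variance under its specific factor,

    cd = (λs² − λg²) / λg²,

and a sub-pool is summarized by the mean of its item cds and the pooled
aggregate acd = (Σλs² − Σλg²) / Σλg², which equals the λg²-weighted mean
of the raw item cds. Small cds mean an item (or pool) is well captured by
the core; the nested radar chart draws each instrument as a circle offset
from the chart center by its aggregate cd.

The package provides the instrument registry and response
validation/scoring, a maximum-likelihood CFA engine with Satorra-Bentler
scaled statistics and fit indices (χ²/df, RMSEA with 90% CI, SRMR, CFI,
robust variants), the center-distance computations, a seeded Likert
simulator with known ground truth, and deterministic SVG radar charts.

## Worked example

```r
library(ipvkit)

reg <- default_registry()                    # 47 items, 11 facets
pop <- default_flourishing_population()      # known population model
sim <- simulate_responses(pop, seed = 2026)  # n = 698 Likert responses
dat <- validate_responses(sim$responses, reg)

res <- run_nested_ipv(dat, reg)
res
#> <ipv_nested> 47 items
#>       level pool_id n_items mean_cd aggregate_cd
#>  instrument  MHC-SF      14  0.1113       0.1118
#>  instrument   PERMA      15  0.0827       0.0837
#>  instrument      FS       8  0.1053       0.1015
#>  instrument    WBCF      10  0.1029       0.0940

round(res$latent_corr, 3)
#>        MHC-SF PERMA    FS  WBCF
#> MHC-SF  1.000 0.925 0.913 0.931
#> PERMA   0.925 1.000 0.904 0.924
#> FS      0.913 0.904 1.000 0.925
#> WBCF    0.931 0.924 0.925 1.000
```

The instrument pool summaries say how far each questionnaire sits from the
pooled core (here PERMA is closest, as this particular simulated population
implies), and the latent correlations — estimated from a third, 4-factor
model — show the four instruments largely measuring the same thing. The
per-item table `res$item_table` holds both loading sets and per-item cds;
`layout_item_chart()` / `layout_nested_chart()` + `render_chart()` turn the
result into SVG radar maps.

Center distances can also be applied directly to published loading pairs:

```r
center_distance(0.520, 0.623)$cd   # 0.4353883 -> prints as 0.44
```

## Analysis workflow

The `analysis/` scripts run the full study pipeline end to end, writing
tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | simulate the 698 × 47 response pool + ground truth |
| `02_fit_cfa.R` | per-instrument CFAs (scaled χ², fit indices), WBCF 1- vs 2-factor comparison |
| `03_nested_ipv.R` | general/facet/instrument models, cds, pool summaries, latent correlations |
| `04_charts.R` | item-level and nested radar SVGs |
| `05_verify_reference.R` | regression check of the cd arithmetic against the bundled reference loadings |

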