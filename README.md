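# restsel

Resting-site selection and revisitation analysis for biologged, nocturnal
animals — developed for GPS + activity (ACT) collared wild boar
(*Sus scrofa*) in anthropized landscapes.

Animals that avoid people by foraging at night must rest through the day,
and the choice of the daily resting site (RS), made once around dawn,
fixes their exposure to disturbance — walkers, traffic, drive hunts — for
the whole day. `restsel` turns raw collar series (one 0–255 activity
score per 5 min, one GPS fix per 30 min) into an analysis of that
strategy:

* **Inactive-phase segmentation** — epochs are *resting* iff ACT ≤ 40;
  short activity bouts inside long rest are smoothed away and the longest
  merged rest run overlapping `[sunrise, sunset]` (NOAA solar geometry)
  becomes the day's inactive phase.
* **Relocation detection** — a within-phase activity bout (≥ 10 min above
  threshold) whose pre- and post-bout mean GPS positions lie **more than
  100 m** apart marks a relocation of the resting animal.
* **Resting sites** — daily resting locations (mean of pre-relocation
  fixes) are clustered per animal by average-linkage agglomeration cut at
  50 m; visits are counted by hunting season (NHS / HS, with hunting days
  = Wed/Sat/Sun + bank holidays inside the open season).
* **Landscape covariates** — villages derived from building footprints by
  a 50 m morphological closing with a 1.5 ha rule (signed distance,
  negative inside), roads filtered to the five traffic-bearing OSM
  categories, and a binary dense-vegetation class.
* **Models** — all through one mixed-model front-end
  (`fit_glmm()`, Laplace ML via glmmTMB, animal-within-study-site random
  intercepts, Nakagawa marginal R²):
  * RSF: used RSs vs 1000 uniform points from the 90% kernel home range,
    `used ~ veg × d(road) + veg × d(village)` (binomial); selection
    ratios `SR(x) = (n_avail / n_used) · exp(η(x))` with SR > 1 =
    selection; Boyce-style 5-fold / 10-bin / 20-replicate
    cross-validation (Spearman rank correlation of area-adjusted
    frequencies).
  * Revisitation: zero-truncated Poisson
    (`P(Y = k | k ≥ 1) = λ^k e^{−λ} / (k!(1 − e^{−λ}))`) on per-site
    seasonal visit counts, log survey length as control.
  * Relocation probability (binomial, 3-level season factor) and
    relocation distance (gamma, log link, km).
* **Synthetic data** — `sim_landscape()` / `sim_study()` generate a
  village–road–vegetation mosaic and collar series with full ground
  truth (phase bounds, bouts, site identities, relocations), so every
  stage is testable without field data.

## Worked example

A small fully simulated study (2 animals × ~60 days), pipeline end to
end:

```r
library(restsel)
cfg <- default_config(seed = 1,
                      simulate = sim_config(n_animals = 2, survey_days = 60),
                      n_avail_per_used = 100,
                      cv = cv_config(n_reps = 5))
pl <- run_pipeline(cfg)
print(pl)
#> Resting-strategy pipeline: 2 animals, 144 phases, 51 sites
#>   time in inactive phase: 58.6%
#>   phase end within 30/90 min of sunset: 44% / 92%
#>   phase start within 30/90 min of sunrise: 13% / 42%
#>   sites revisited more than once: 45%
#>   relocation probability by season (raw):
#>          season n_phases n_relocated p_relocation
#>             NHS       45           6   0.13333333
#>   HS_nonhunting       56           5   0.08928571
#>  HS_hunting_day       43           6   0.13953488
```

The animals rest ~59% of the time in one consolidated diurnal phase whose
end hugs sunset much more tightly than its start hugs sunrise; about half
the resting sites are reused; and the raw share of rest phases ending in
a relocation sits around 0.09–0.14 depending on the hunting season (at
this small scale the seasonal contrast is within noise — the full-scale
checks in `tests/testthat/test-acceptance.R` recover the simulated
0.08 / 0.12 / 0.17 rates to ±0.03). Model-based per-season probabilities
with Wald intervals:

```r
pl$relocation_prob
#>          season3        fit        lwr       upr
#> 1            NHS 0.12517007 0.05162683 0.2732877
#> 2  HS_nonhunting 0.09559246 0.03786418 0.2211078
#> 3 HS_hunting_day 0.14889027 0.06641893 0.3007735
```

`summary(pl$seasonal$NHS$rsf_fit)` prints the seasonal RSF coefficient
table (β, SE, z, p) and `pl$seasonal$NHS$cv` its cross-validation score.
The methods vignette (`vignettes/resting-strategy.Rmd`) documents the
segmentation rules, model assumptions, the generator's calibration, and
the numerical choices.

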