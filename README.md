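# nutrilight

Traffic-light scoring of daily food-group intakes.

`nutrilight` implements the NutriLight dietary scoring system for
nutritional-epidemiology workflows: dietitians and researchers who have
per-subject, per-day food-group intake records (g/day) and want a simple,
reproducible adherence score against EAT-Lancet-style reference amounts.

## The score

Fifteen food groups carry a traffic-light category and a recommended daily
amount *R* (g/day). The observed intake *X* of each group earns 0, 1 or 2
points:

| Category | 2 points | 1 point | 0 points |
|---|---|---|---|
| green (whole grains, vegetables, fruits, soy & legumes, nuts) | X ≥ R | 0 < X < R | X = 0 |
| yellow (refined grains, poultry, dairy, eggs, fish, plant oils, starchy vegetables) | X = R (± optional tolerance τ) | 0 < X < R or R < X < 2R | X = 0 or X ≥ 2R |
| red (red meat, animal oils, added sugars) | X ≤ R | R < X < 2R | X ≥ 2R |

The daily total ranges 0–30 (category maxima: green 10, yellow 14, red 6).
Totals aggregate longitudinally by mean, OLS adherence trend and cumulative
classification, and a balance index summarises how evenly points are earned
across the three categories. The default reference amounts transcribe the
EAT-Lancet reference diet at 2500 kcal/day and can be replaced by any
JSON/YAML configuration (`load_config()`); recommended amounts can be
rescaled to a subject's energy intake with `adjust_for_energy()`. A seeded
simulator generates synthetic populations with controllable adherence for
method checks. See `vignette("nutrilight-methods")` for the model's
assumptions and design choices.

## Worked example

```r
library(nutrilight)

cfg <- default_config()
max_possible_score(cfg)
#> [1] 30

# simulate 4 subjects x 5 days with increasing adherence, score, aggregate
pop <- generate_population(n_subjects = 4, n_days = 5,
                           theta = c(0.2, 0.5, 0.8, 1.0),
                           day_noise_cv = 0.25, seed = 2026)
scores <- score_intakes(pop$intakes, cfg)
scores$summary
#> # A tibble: 20 x 9
#>   subject_id   day total green_subscore yellow_subscore red_subscore
#> 1 S001           1    14              5               6            3
#> 2 S001           2     8              5               3            0
#> 3 S001           3    10              5               3            2
#> ...

summarize_adherence(scores$summary)
#> # A tibble: 4 x 5
#>   subject_id n_days mean_score trend_slope class_label
#> 1 S001            5       10.8   -5.00e- 1 moderate
#> 2 S002            5       13.4    3.00e- 1 moderate
#> 3 S003            5       18.4   -2.00e- 1 moderate
#> 4 S004            5       21.6    1.86e-15 high
```

Each summary row is one subject-day: the total out of 30, how the points
split across the traffic-light categories, and the balance index. The
per-subject aggregation reports the observation count, mean score, adherence
trend (score points per day; `NA` for single-day subjects) and the adherence
class under the default low/moderate/high cutpoints at 10 and 20. Here the
fully adherent subject S004 averages 21.6 rather than 30 because day-to-day
noise (cv 0.25) knocks yellow intakes off their exact-equality 2-point band —
the documented effect of the literal `yellow_tolerance = 0` rule on
continuous data.

The same pipeline runs from the shell:

```sh
inst/exec/nutrilight simulate --subjects 4 --days 5 --theta 0.8 --seed 1 --out intakes.csv
inst/exec/nutrilight score --intakes intakes.csv --out scores.csv
inst/exec/nutrilight aggregate --scores scores.csv --out adherence.csv
```

Every command writes a `.manifest.json` next to its output recording inputs,
options, the configuration hash and the package version.

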