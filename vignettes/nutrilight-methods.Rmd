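---
title: "The NutriLight scoring model: assumptions, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The NutriLight scoring model: assumptions, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrilight)
```

## The model

NutriLight scores a day of eating against a traffic-light taxonomy of 15 food
groups. Each group carries a recommended daily amount $R$ (g/day) and one of
three categories, and the observed intake $X$ earns 0, 1 or 2 points:

* **Green** (encouraged: whole grains, vegetables, fruits, soy and legumes,
  nuts): 2 points when $X \ge R$, 1 point for partial intake $0 < X < R$,
  0 points when absent. Exceeding a green recommendation is never penalised;
  these foods are emphasised and no downside is modelled, so the rule is
  monotone and capped at 2.
* **Yellow** (moderation: refined grains, poultry, dairy, eggs, fish and
  seafood, plant oils, starchy vegetables): 2 points for meeting the
  recommendation, 1 point for a mild deviation on either side
  ($0 < X < R$ or $R < X < 2R$), 0 points when absent or at $X \ge 2R$.
* **Red** (limited: red meat, animal oils, added sugars): 2 points within the
  limit ($X \le R$, including zero), 1 point for $R < X < 2R$, 0 points at
  $X \ge 2R$.

The daily total is the sum over groups: 0–30 under the default configuration,
partitioned into category subscores with maxima 10 (green), 14 (yellow) and
6 (red).

### Boundary conventions

The verbal band descriptions decide where boundary intakes fall: $X = R$ is
"meeting" the recommendation (green and yellow 2-point bands) and "within the
limit" (red 2-point band), while $X = 2R$ belongs to the 0-point band for both
yellow and red. All interval comparisons use a relative tolerance of
$10^{-9}$, so an intake computed as `sum(rep(R/10, 10))` scores identically to
a literal `R`. This matters because dietary records are routinely built by
summing eating occasions in floating point.

### The yellow "meeting" band

For continuous intakes, exact equality $X = R$ has measure zero, which would
make the yellow 2-point band practically unreachable with real data. The
configuration therefore carries a `yellow_tolerance` $\tau \in [0, 0.5)$: the
2-point band is $[(1-\tau)R,\ (1+\tau)R]$. The default is $\tau = 0$ — the
literal rule, with equality judged at the $10^{-9}$ relative tolerance — so
that the engine reproduces the published scoring exactly; $\tau = 0.1$ is a
pragmatic setting for real dietary data. The upper bound 0.5 keeps the 2-point
band disjoint from zero and well inside the $2R$ cutoff.

### Degenerate recommendations

$R = 0$ is meaningful only for red groups ("none of this food"): the rule's
limit as $R \to 0$ awards 2 points iff $X = 0$ and 0 otherwise, the 1-point
band being empty. Green and yellow groups require $R > 0$ and
`validate_config()` flags violations rather than throwing, so a configuration
can be inspected as data before use.

## Default reference amounts

The recommended amounts ship in a commented YAML file
(`system.file("extdata", "nutrilight_default.yaml", package = "nutrilight")`).
They transcribe the EAT-Lancet Commission reference diet at 2500 kcal/day
(range midpoints where a range is published), which is the source the
framework's recommendations are built on: vegetables 300 g, fruits 200 g,
whole grains 232 g, soy and legumes 75 g, nuts 50 g, dairy 250 g, poultry
29 g, eggs 13 g, fish 28 g, plant oils 40 g, starchy vegetables 50 g, red meat
14 g, animal oils 5 g, added sugars 31 g. The reference diet sets no separate
refined-grain amount — its entire grain target is whole grain — so the
100 g/day moderation allowance used here is this package's own choice,
documented in the data file and freely editable. Every amount is a
regional-adaptation point: the framework explicitly expects localisation, and
`load_config()` accepts any JSON or YAML file following the same schema.

### Energy adjustment

The reference amounts assume 2500 kcal/day (a moderately active adult).
`adjust_for_energy(config, e)` rescales every $R$ by $e/2500$. Adjustment is
**off by default** and applied only on explicit request (function call or the
CLI `--energy` flag), because the published amounts are stated at the
reference energy and silent rescaling would make scores incomparable across
analyses. Scoring a proportionally scaled intake profile against the original
configuration and scoring the original profile against the adjusted
configuration give identical points (scale invariance of all three rules),
which the test suite checks on random profiles.

## Missing food groups

A day's record may lack groups the configuration expects. Three explicit
policies are provided, because silent imputation corrupts totals:

* `strict` (default) — error naming the missing groups;
* `impute_zero` — treat missing as $X = 0$, with a warning. Note this is not
  neutral: a missing red group *gains* 2 points, a missing green group loses 2;
* `rescale` — score only the groups present and additionally report the total
  renormalised to the full 0–30 scale, `total * 30 / (2 * n_scored)`.

## Balance index

A given total can be reached through very different category profiles (e.g.
6 points earned entirely by avoiding red foods while eating nothing else).
Following the framework's suggestion that aggregate metrics should reflect the
proportional balance of the three categories, the package defines
$B = 1 - \tfrac12 \sum_c |p_c - q_c|$, where $p_c$ is the share of earned
points in category $c$ and $q_c$ the share of the attainable maximum
($q = (10, 14, 6)/30$ by default). $B$ is the complement of the
total-variation distance between the two distributions: 1 when points are
earned in exactly the proportions of the maxima, 0.2 for a day whose only
points are the red 6, and undefined (`NA`) for a zero-point day. The index is
this package's operationalisation of a balance metric the framework names but
does not define; treat it as descriptive, not validated.

## Longitudinal aggregation

Scores aggregate over time three ways, matching how cumulative dietary
quality is usually summarised:

* `mean_score()` — arithmetic mean of daily totals;
* `adherence_trend()` — ordinary least-squares slope of the total on the day
  index, in score units per day. Fewer than two distinct days gives `NA` with
  a warning. When records carry ISO dates, days since each subject's first
  observation are used, so calendar gaps are respected; integer indices are
  used as given.
* `classify_cumulative()` — labelled half-open bins over the mean. The
  framework names classification but fixes no thresholds; the defaults split
  0–30 into thirds (low $[0,10)$, moderate $[10,20)$, high $[20,30]$) and are
  fully configurable. Classification uses the mean rather than the raw sum
  because the mean is invariant to the length of the observation period;
  `use = "sum"` exposes the alternative for fixed-length periods.

## The synthetic-diet generator

`generate_population()` simulates subject-days with a single adherence
parameter $\theta \in [0,1]$ per subject. Each group's intake is
$X = R \cdot m(\theta) \cdot \varepsilon$ with linear target multipliers
$m$: green $0.1 + \theta$, yellow $2.4 - 1.4\,\theta$, red $2.5 - 2\,\theta$.
The endpoints are chosen so the generator's behaviour is analytically
checkable in the noise-free case: at $\theta = 1$ every group lands in its
2-point band (total 30) and at $\theta = 0$ the five green groups score 1 and
all others 0 (total 5). Day-to-day variation $\varepsilon$ is multiplicative
log-normal with mean 1 and coefficient of variation `day_noise_cv` (default
0.25, a typical within-person magnitude for food-group intakes), reflecting
that intakes are positive and right-skewed. Every generating call requires a
seed and identical seeds give bit-identical output.

What the generator does *not* emulate: correlation between food groups within
a day, weekday/weekend structure, under-reporting and other instrument error,
or any national consumption distribution. Tests passing on synthetic data
therefore demonstrate that the scoring and aggregation machinery is correct
and that the score separates adherence levels under noise — not that the
score is validated against real diets, which the framework itself lists as
future work.

## Numerical and scale choices

* All amounts are g/day inside the engine; unit conversion happens upstream.
* Interval comparisons use relative tolerance $10^{-9}$ (see boundary
  conventions above).
* OLS trends use `stats::lm`; on exactly linear series the slope is recovered
  to $10^{-9}$.
* Duplicate (subject, day, group) rows in intake CSVs are summed — multiple
  eating occasions per day are normal — with a logged notice.
* Simulation-based checks in the test suite run at desk scale (e.g. 200
  subjects per adherence level, one to seven days), which is ample for the
  sign and monotonicity properties they assert.

## Known limitations

* The 0/1/2 bands are coarse by design; the score cannot distinguish a mild
  from a severe green shortfall beyond one point.
* The balance index and the classification cutpoints are package choices, not
  published constants; report them alongside results.
* No environmental-footprint quantities are computed, and no nutrient-level
  modelling is attempted: the food group is the unit of analysis throughout.
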