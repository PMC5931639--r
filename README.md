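# streetcount

Predicting city-level travel patterns from road-user counts in archived
street imagery.

Census commute questions and telephone activity surveys give cities only a
sparse view of walking, cycling and motorised travel. Street imagery is an
alternative signal: sample random street locations, pull the archived
panorama closest in time to the survey you want to predict, count the road
users visible in each image, and regress the survey outcomes on the
per-city counts. `streetcount` implements that pipeline end to end for
analysts working with city-level travel surveillance data:

* staged location sampling over a street network (one point per link, a
  2000-point simple random subsample, year-prioritised selection of 1000
  locations, two images per location at opposite headings);
* aggregation of image-level ordinal count bins (0 / 1–3 / 4–6 / >6 for
  pedestrians, cyclists, parked cycles, cars, motorcycles, buses,
  vans/trucks) into per-city presence counts `GSV_Walk`, `GSV_Cycle`,
  `GSV_PCycle`, `GSV_Car`, `GSV_Bus`, `GSV_MC`, monthly image proportions
  and bootstrap SDs;
* the three model families used for the outcomes: beta regression with a
  logit mean link and constant precision φ, fitted by maximum likelihood

  f(y; μ, φ) = Γ(φ) / (Γ(μφ) Γ((1−μ)φ)) · y^(μφ−1) (1−y)^((1−μ)φ−1),
  logit(μ) = x'β,

  for mode shares and prevalences; Huber M-estimation (k = 1.345, MAD
  scale) for right-skewed cycling outcomes; OLS for walking outcomes;
* leave-one-out cross-validation with PRESS (Σ squared held-out errors),
  MAE/MDAE summaries and significance-guided PRESS-minimising backward
  elimination;
* a cyclist gender-split analysis over observation-balanced city groups;
* a seeded synthetic-city generator with known ground truth, so the whole
  pipeline is testable without downloading a single image.

## Worked example

Generate a 34-city synthetic world at study scale (2000 images per city),
build the city table, and fit the cycle-share model with cross-validation:

```r
library(streetcount)

world <- generate_world(generator_config(), seed = 1)
features <- build_feature_table(world$annotations)
cities <- merge(features, world$outcomes, by = "city_id")

cor(cities$GSV_Cycle, cities$Census_Cycle)
#> [1] 0.9110601

spec <- final_model_specs()$M2   # Census_Cycle ~ sqrt(GSV_Cycle), beta family
fit <- fit_beta(spec, cities)
coef(fit)
#>     (Intercept) sqrt(GSV_Cycle)
#>      -5.2938373       0.4751202

loocv(spec, cities)
#> LOOCV over 34 cities
#>   PRESS: 0.0019576   MAE: 0.005534   MDAE: 0.003805
#>   MSR: 0.8591   MDSR: 0.7387
```

The correlation of 0.91 between the cyclist presence count and the
simulated census cycle share is the headline mechanism: cycling varies so
much between cities that a thousand street images per city already rank
them accurately. The fitted intercept and slope are on the logit scale
(a city with 25 cyclist-containing images predicts a cycle share of
`plogis(-5.29 + 0.475 * sqrt(25))` ≈ 5.1%), and the LOOCV median absolute
error of 0.0038 means typical held-out predictions are within about 0.4
percentage points of the observed share.

Running against a deposited per-city CSV instead of a synthetic world:

```r
report <- run_pipeline(pipeline_config("s2", s2_path = "cities.csv"))
report$models$table          # ten models with MAE/MDAE/MSR/MDSR/PRESS
report$correlations          # Pearson matrix of features vs outcomes
```

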