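# kinnet

Household social networks from multi-reporter egocentric surveys: kinship
canonicalization, network fusion, tie-weighted assortativity, and models of
mutual health influence and dietary behaviour.

## The problem

Egocentric surveys elicit each respondent's "most important people" and
pairwise ratings of the relationships among them (interaction frequency,
emotional closeness, eating together, importance in each other's health, all
on a 0–9 agreement scale). When several members of one household are
surveyed — an index young adult plus 1–3 family members — their personal
networks overlap: the index adult's *father*, the surveyed mother's
*husband* and the surveyed grandmother's *son* are the same node. `kinnet`
fuses these reports into one network per household by

1. parsing free-text relation labels into a closed kinship vocabulary with
   generation offsets (grandparent +2 … grandchild −2),
2. composing each reporter's relation to the index adult with the alter's
   relation to the reporter via a kinship path algebra, surfacing genuine
   ambiguities (a grandmother's "son" may be the father *or* an uncle) for
   resolution by manual override or cross-reporter sex/age matching,
3. merging nodes, averaging duplicate dyadic ratings, and classifying every
   tie as spouse/partner, intergenerational, intragenerational, friend or
   other.

On the fused networks it computes category descriptives and assortativity
(weighted by eating together or mutual health importance), and fits the two
model families used in household network studies of diet:

* **cross-classified linear mixed models** of the directed 0–9
  "importance of the source in the target's health" rating, with crossed
  random intercepts for source node, target node and household
  (`fit_dyad_mixed()`, via lme4), and
* **logistic GEE models** of dichotomized diet outcomes (vegetables
  ≥2×/day, fruit ≥1×/day, fast food none vs any, snacks ≤3×/week) on
  network-average health, effort and shared meals, clustered by household
  with an exchangeable working correlation and robust standard errors
  (`fit_diet_gee()`; the GEE solver is implemented in the package and
  collapses to `glm()` for singleton clusters).

A synthetic survey generator (`generate_cohort()`) with known ground truth
— household templates, overlapping reports, category-dependent tie
strengths, a cross-sex eating preference, and diet outcomes drawn from a
logistic model on realized network averages — makes the whole pipeline
testable without any real data.

## Worked example

```r
library(kinnet)

cfg     <- generator_config(n_households = 36, seed = 2024)
cohort  <- generate_cohort(cfg)
dir     <- file.path(tempdir(), "demo"); write_cohort(cohort, dir)

surveys  <- read_household_surveys(file.path(dir, "participants.csv"),
                                   file.path(dir, "alters.csv"),
                                   file.path(dir, "ratings.csv"),
                                   file.path(dir, "overrides.csv"))
networks <- lapply(surveys, fuse_household)
networks[[1]]
#> household_network h001 - 9 nodes, 13 edges
#>            friend intergenerational intragenerational    spouse_partner
#>                 7                 4                 1                 1

summarize_networks(networks)$cohort
#>   measure     mean       sd
#> 1 n_nodes 10.00000 1.638815
#> 2 n_edges 18.44444 5.347600

assortativity_cohort(networks, attributes = "sex", weights = "eat_freq")
#>   attribute   weight n_networks n_undefined       mean        sd
#> 1       sex eat_freq         36           0 -0.3581976 0.1115659

records <- do.call(rbind, lapply(networks, build_directed_records))
fit <- fit_dyad_mixed(records, model_spec = 2)
fit$tidy[fit$tidy$term %in%
           c("closeness", "eat_freq", "category_dirspouse_partner"), ]
#>                         term estimate    se ci_low ci_high
#> 3                  closeness     0.41 0.024   0.36    0.46
#> 4                   eat_freq     0.36 0.020   0.32    0.40
#> 8 category_dirspouse_partner     1.31 0.234   0.85    1.77
```

Reading the output: households average 10 network members; the negative sex
assortativity (−0.36) says people eat more with household members of the
opposite sex (the generator's cross-sex preference, and the pattern such
surveys report); and in the dyadic model each extra point of emotional
closeness or eating together adds ≈0.4 points of perceived health
importance, with spouse/partner ties carrying a further +1.3 over friend
ties. `run_pipeline()` executes all stages (ingest → fuse → metrics →
scales → models) and writes tidy CSVs plus a reproducibility manifest.

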