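---
title: "Fusing multi-reporter household surveys into social networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multi-reporter household surveys into social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinnet)
```

## The problem

Egocentric (name-generator) surveys ask one respondent to list the most
important people in their life and to rate every pairwise relationship among
them. When several members of the *same household* are surveyed, their
personal networks overlap heavily: the index adult's "father", their mother's
"husband" and their grandmother's "son" are one person. Classical egocentric
analysis assumes no such overlap; household studies must instead *fuse* the
reports — identify common nodes, rename them consistently relative to the
index adult, and average the duplicate dyadic ratings — before any network
statistic or regression is meaningful.

`kinnet` implements that fusion pipeline end to end for a three-table survey
export (participants, alters, dyadic ratings), plus the analyses typically
run on the fused networks: relationship-category descriptives, tie-weighted
assortativity, cross-classified dyadic mixed models of perceived health
importance, and cluster-correlated logistic (GEE) models of dietary
behaviours on network-average characteristics.

## Kinship canonicalization

Every alter label is parsed into a closed canonical vocabulary (about twenty
terms: father, mother, grandparent, sibling, aunt_uncle, godparent, cousin,
child, niece_nephew, grandchild, spouse_partner, the in-law variants, friend,
other). Qualifiers ("oldest brother", "auntie AZ") and pseudonym fragments
are ignored for typing; colloquial Singaporean grandparent terms (ah ma, gong
gong, po po, nai nai, ye ye) are recognised. Each kin term carries a
generation offset relative to the index adult: grandparents +2, parents,
aunts/uncles, godparents and parents-in-law +1, the index adult's own
generation 0, children −1, grandchildren −2.

A family member's report is expressed relative to *themselves*, so the
pipeline composes two relations: the reporter's relation to the index adult
and the alter's relation to the reporter. Rather than a hand-maintained
cross-product table, composition is computed from a small kinship path
algebra: every canonical term is a string of pedigree steps (P parent, C
child, S sibling, M spouse), composition is string concatenation, and a set
of rewrite rules reduces the concatenated path. Crucially, some rules branch
— a parent's child is either the index adult or a sibling; a grandmother's
son is either the father or an uncle — so composition returns a *candidate
set*, and genuinely ambiguous compositions are surfaced rather than guessed:

```{r}
compose_relations("mother", "spouse_partner", "m")$candidates
compose_relations("grandparent", "child", "m")$candidates
```

Ambiguous sets are resolved in a fixed order: (1) a manual-override row (the
in-package analogue of the study team contacting the family to clarify); (2)
cross-reporter matching — another reporter's uniquely-resolved node whose
relation is among the candidates, whose sex agrees and whose reported age is
within ±5 years (nearest age wins; an exact tie stays unresolved rather than
risk a wrong merge); (3) otherwise the node keeps relation "other" and is
excluded from generational classification, never silently dropped. The ±5
year tolerance is a package choice: wide enough to absorb "approximate age"
reporting error, narrow enough that parents and children can never be
confused.

## Fusion and tie classification

Surveyed participants seed the node registry with their self-reported
attributes, which always take precedence over other reporters' perceptions.
Alters resolving to the same kin slot merge (father and mother are unique
slots; multi-slot relations like sibling additionally require compatible sex
and age); friends merge only on exact normalized label match, because no
cross-reporter identity information exists for non-kin; and two alters named
by the *same* reporter never merge. Perceived health/effort of merged
non-surveyed nodes are averaged across reporters, as are all five dyadic
ratings of a tie rated by several reporters (the two health-importance
ratings stay directional and are aligned before averaging).

Ties are classified with precedence spouse/partner > friend > generational.
Couples are detected primarily from the label a reporter used ("husband",
"girlfriend", ...), falling back to a fixed couple table over canonical
slots (father+mother, index+spouse_partner, sibling+sibling-in-law,
child+child-in-law). A tie with any non-family endpoint is a friend tie; a
family tie crossing at least one generation offset is intergenerational
(directionally subtyped by whether the target sits in an older or younger
generation), otherwise intragenerational. One known limitation: a
grandparent couple cannot be separated from a grandparent–granduncle pair on
labels alone, so same-offset grandparent ties classify as intragenerational
unless a spouse label says otherwise.

Every fused tie is then expanded into exactly two directed records (each
endpoint as source, with its rated importance in the other's health as the
outcome), which is the unit of analysis for the dyadic models.

## Models

**Dyadic mixed models.** The 0–9 importance outcome is modelled as
continuous, with crossed random intercepts for source node, target node and
household — the cross-classified structure that accommodates the overlap of
personal networks within a household. Specification 1 includes interaction
frequency, emotional closeness, relationship category (friend reference) and
both endpoints' age band, sex, health and effort; specification 2 adds
eating-together frequency; specification 3 restricts to surveyed source
nodes and adds their above-median individualism/collectivism flags. Because
"a random effect for each node" is ambiguous between separate source/target
effects and a single effect per node, both are implemented
(`node_effect_mode = "crossed"` default, `"shared"` via lme4's modular
interface by summing the two membership matrices); estimates agree closely
on simulated data. Missing covariates drop records listwise and the count is
reported with the fit.

**Diet GEE models.** Each dichotomized diet outcome is regressed on the
scope-specific network averages (members' health, members' effort, the
participant's eating-together ratings; odds ratios per rating point) with
households as clusters, an exchangeable working correlation and robust
sandwich standard errors, adjusted for participant age band, sex, race,
income, BMI, self-rated health and effort. The GEE solver is implemented in
the package (Fisher scoring on the estimating equations with
moment-estimated exchangeable correlation); with singleton clusters or an
independence working structure it reproduces `glm()` to numerical precision,
which the test suite asserts, and its robust standard errors match
`sandwich::vcovCL` in the independence case. Scope definitions: *full* = all
other network members; *family* = kin members excluding the participant's
own spouse/partner; *friends* = the friend nodes the participant themselves
named (friends, unlike kin, are not shared household members). Scopes with
zero members yield no row, so participants without friends simply drop from
the friends-scope models. The three scopes are fitted separately.

**Scales and diet coding.** The 4-item, 9-point individualism and
collectivism scales are summed (range 4–36) and split at the sample median
with ties going to the not-high group (the split rule is stated because an
attained median makes "above/below" ambiguous). Diet frequencies use seven
ordinal levels (none; 1–3×/week; 4–6×/week; 1–4+×/day) — the minimal
labelling consistent with all four dichotomization thresholds: vegetables
≥2×/day, fruit ≥1×/day, fast food none vs any, snacks ≤3×/week. Cronbach's
alpha is reported as a diagnostic, not a gate.

## The synthetic-data generator

No survey data ship with the package; instead a generator produces the three
tables with known ground truth so that every stage is testable. It emulates:

* households of a 21–35-year-old index adult plus 1–3 co-surveyed family
  members drawn from composition templates (always containing mother and
  father nodes; optional siblings, a paternal grandmother, a maternal
  aunt/uncle, a cousin, a spouse/partner), with 57% female draws where sex
  is free;
* each reporter naming 2–10 alters with reporter-relative labels (the
  mother calls the father "husband", the grandmother calls him "son"),
  deliberately overlapping so fusion is exercised; labels carry an initial
  suffix so one reporter's two "sons" stay distinct;
* category-dependent tie strengths on the 0–9 scale (spouse ≈7,
  intergenerational ≈5, intragenerational ≈4.5, friend ≈2, sd 1.5, drawn
  from discretized truncated normals) plus a cross-sex bonus on eating
  together that induces negative sex assortativity;
* directed importance from the dyadic linear model (defaults: closeness
  0.45, eating 0.43, spouse/partner +0.89, intergenerational +0.62/+0.36 by
  direction, node/household intercept sds 0.4/0.3, noise sd 1), discretized
  to the 0–9 grid;
* diet flags from a logistic model on the *realized* truth-network averages
  (defaults encode, on the healthy-flag scale, higher family effort →
  lower snack and fast-food consumption, higher perceived family health →
  higher snack consumption), with intercepts near the observed prevalences
  (28% vegetables, 33% no fast food);
* around 2% missing perceived health/effort reports, and ambiguous
  grandparent labels shipped with clarification override rows —
  `inject_ambiguity()` strips those rows to force resolution by
  cross-reporter matching.

What it does *not* emulate: free-text label noise beyond qualifiers,
Singapore-specific demographic marginals beyond the configured categories,
reporter-specific rating biases, or dependence of network size on
demographics. Passing tests therefore validate the pipeline's logic and the
estimators' calibration, not the substantive findings of any real cohort.

Two fast paths generate model-level data directly, bypassing the survey
representation: `generate_dyad_records()` (continuous outcome by default, so
parameter-recovery simulations test the estimator against the exact
generating coefficients rather than against discretization artefacts) and
`generate_gee_data()` for clustered binary outcomes.

## Numerical choices and test scales

* Weighted numeric assortativity is the weighted Pearson correlation over
  the symmetrized edge list; the categorical version is the Newman
  mixing-matrix coefficient on the weight-normalized matrix. Zero-weight
  edges contribute nothing; zero attribute variance or a single category
  returns NA, and NA networks are dropped (with a count) from cohort means.
  Both estimators are checked against brute-force enumeration on exhaustive
  small fixtures and against igraph in the equal-weight case.
* REML is used for the mixed models; Wald 95% intervals throughout.
* GEE iterations cap at 50 with tolerance 1e-8; near-separation is flagged
  on the fit rather than raised.
* Calibration suites run at 100 replicates × 200 households (mixed model)
  and 100–500 replicates × 300 households (GEE recovery and type-I error),
  sizes at which one replicate fits in well under a second and binomial
  noise on a 95% coverage estimate is ±2–3 points.
* The 36-household end-to-end checks match the scale of the motivating
  study design and run the full pipeline, asserting the qualitative
  ordering (spouse > intergenerational > friend) and the sign of sex
  assortativity rather than exact values, which depend on the generator's
  dispersion settings.

## Known limitations

Maternal/paternal qualifiers are not modelled, so some compositions (a
grandmother's "son") are irreducibly ambiguous and rely on matching or
overrides; exact sex+age ties between candidates stay unresolved by design.
Node attributes of non-surveyed alters are averaged perceptions, not ground
truth. BMI is carried as a covariate without further semantics. The pipeline
handles neither longitudinal change nor negative ties, and computes no
centrality or community structure.
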