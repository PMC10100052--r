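# conattract

Tools for analysing **conspecific attraction** in territorial songbirds:
why do males settle near other males, and does clustering pay off when
females choose mates?

The package implements, as reusable and tested R code, the two analyses
such a study needs, plus a seeded synthetic-data generator so the entire
pipeline can be exercised and validated without any field data.

## The two analyses

**Analysis 1 — settlement point-process models.** Male settlement
locations in each site and year form a spatial point pattern. Settlement
density is modelled as a loglinear inhomogeneous Poisson intensity

    lambda(u) = exp(beta0 + beta1 * S(u))

where the covariate `S` is either *hab* (habitat attractiveness: a
Gaussian kernel density of cumulative nest locations on a 10 m raster,
excluding nests from the site-year being analysed) or a playback-proximity
surface `exp(-d/200)` (distance in metres to the nearest conspecific
song-playback station; *prox.all* for all stations, *prox.lc* for
low-song-rate stations only). Models are fitted jointly across site-year
patterns with a Berman–Turner quadrature approximation to the likelihood
(weighted Poisson regression over data plus dummy points), compared by
AICc, and effect sizes are range-standardized as `exp(beta * range)` —
the factor by which predicted density varies across a covariate's span.

**Analysis 2 — conditional-logit mate choice.** Each female's settlement
decision is a choice among the males present in her site at her nest
initiation date (back-dated from clutch completion, clutch size and a
7-day building period). Male attractiveness is the power function

    A_i = H_i^alpha1 * C_i^alpha2,     p_i = A_i / sum_j A_j

with `H_i` the habitat value at male i's territory centre and
`C_i = sum_{j != i} exp(-d_ij / lambda_C)` a metapopulation-style
connectivity (playback stations can count as competitors but are never
choosable). Free exponents are estimated by maximum likelihood
(`l = sum ln p_chosen`); the four candidate models (null, habitat-only,
connectivity-only, full) are compared by AICc. An exponent translates to
a percent effect as `100 * (1.1^alpha - 1)` per 10% covariate increase.

## Worked example

```r
library(conattract)

res <- run_pipeline("demo_run", simulation_config(seed = 2), verbose = FALSE)
res$ppm$comparison
#>  Model          AICc    dAICc w
#>  prox.all       1326.60 0.00  0.74
#>  hab + prox.all 1328.81 2.21  0.25
#>  prox.lc        1335.89 9.29  0.01
#>  hab + prox.lc  1337.82 11.23 <0.01
#>  null           1343.47 16.87 <0.01
#>  hab            1345.26 18.66 <0.01
res$mate_choice$incl$comparison
#>  Model              AICc   dAICc w
#>  hab + connectivity 351.87 0.00  0.60
#>  hab                352.72 0.85  0.40
#>  null               367.96 16.10 <0.01
#>  connectivity       369.77 17.91 <0.01
```

The first table ranks the six settlement models: here proximity to
playbacks predicts male density best (the playback effect is simulated as
strong), with Akaike weight 0.74. The second ranks the four mate-choice
models on the 59 simulated female choices: habitat-dominated models carry
essentially all support, as expected when choices are generated with a
positive habitat exponent and a weak negative connectivity exponent.
Fitted exponents convert to interpretable effects with
`percent_change()`: an exponent of 0.625 means a male's chances of being
chosen rise 6.1% per 10% increase in habitat attractiveness.

The pipeline writes every intermediate table (`nests.csv`,
`territories.csv`, `playbacks.csv`, `choices.csv`), both comparison
tables and a `summary.json` to the run directory; rerunning with the same
seed reproduces them byte for byte. The same functions accept real field
tables in the documented CSV schemas.

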