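# coretransim

Community time series always contain **transient species** — taxa recorded
at a site where they cannot maintain a self-sustaining population, kept
there by dispersal from surrounding source habitat. A standard way to
separate them from **core** community members is *temporal occupancy*: the
fraction of survey years in which the species was detected, with species at
or below 1/3 of years called transient and above 2/3 called core. That
classifier fails in two directions: imperfect detection makes core species
look transient (a species with *n* individuals is detected in a year with
probability 1 − (1 − *p*)^*n*), and source–sink dynamics make transients
look core.

`coretransim` is a simulation laboratory for measuring those error rates.
It implements a two-habitat metacommunity model in which true status is
known by construction: a 32 × 32 lattice of local communities (carrying
capacity *K* = 100 each), 40 habitat-specialist species (20 per habitat)
with a lognormal regional abundance distribution, and yearly cycles of
death (*d* = 0.5) → birth (*f* = 2 in preferred habitat only) → half-normal
dispersal (99% of movements within 4 cells; mean 1.24 cells) →
establishment into empty slots with weak external immigration
(*m* = 0.001 per slot). A binomial detection overlay produces observed
focal-cell time series; crossing true status with occupancy-inferred status
gives the confusion counts *A*–*D* and the error rates *A*/(*A*+*C*)
(core called transient) and *D*/(*B*+*D*) (transient called core), which
are analysed against detection probability and landscape similarity (share
of the 7 × 7 window matching the focal habitat) by OLS, plus a logit-link
GLM of correct core classification against log relative abundance.

The package is tidyverse-shaped: sweeps and occupancy tables are tibbles,
fitted objects have `tidy()`/`glance()` methods, result types have
`autoplot()` methods.

## Worked example

One simulation plus a detection overlay at *p* = 0.5:

```r
library(coretransim)

rec <- run_simulation(sim_config(h_A = 0.9, seed = 7))
rec
#> <ct_simulation> h_A = 0.9, focal habitat A, similarity = 0.857,
#>   15-step window, 21/40 species ever present at focus

occ <- occupancy_from_record(rec, p = 0.5)
tabulate_confusion(occ)
#> # A tibble: 1 × 9
#>   n_obs_core n_obs_transient     A     B     C     D n_intermediate core_error transient_error
#> 1         20               0     5     0    13     0              2      0.278              NA
```

In this nearly homogeneous landscape (similarity 0.857) no transient
species was even observed at half detection, so the transient error rate
has an empty denominator and is reported as missing; 5 of 18 decisively
classified core species were mistaken for transients — all of them rare.

The reduced-scale replicate sweep (10 runs × 5 habitat proportions × 10
detection levels, a few minutes) and its regression battery:

```r
sw <- run_sweep(reps = 10, root_seed = 101, occupancy_at = 0.5)
fit_error_models(sw, joint = FALSE)
#> # A tibble: 8 × 6
#>   response        predictor    slope intercept r_squared     n
#> 1 n_obs_core      p            1.92    14.5       0.0129   500
#> 2 n_obs_core      similarity  15.1      6.50      0.613    500
#> 3 n_obs_transient p            3.84     8.77      0.0224   500
#> 4 n_obs_transient similarity -25.8     26.4       0.780    500
#> 5 core_error      p           -0.590    0.727     0.342    497
#> 6 core_error      similarity  -0.564    0.742     0.237    497
#> 7 transient_error p            0.423    0.0464    0.174    413
#> 8 transient_error similarity  -0.949    0.792     0.546    413
```

Reading the slopes: core misclassification falls with detection and with
similarity; transient misclassification falls with similarity but *rises*
with detection (better surveys detect the steady trickle of immigrants);
transient species counts are governed almost entirely by landscape
similarity (R² = 0.78) rather than detection (R² = 0.02). The
abundance–misclassification curve at *p* = 0.5:

```r
g <- fit_abundance_glm(attr(sw, "occupancy"))
g
#> <ct_abundance_glm> P(correct core classification) ~ log relative abundance
#>   logit intercept = -3.523, slope = 1.862, inflection at 6.64% relative
#>   abundance, n = 615
predict(g, 12)
#> # A tibble: 1 × 3
#>   relative_abundance p_correct p_misclassified
#> 1                 12     0.751           0.249
```

So a core species at 12% of the most abundant species' landscape-wide
abundance is misclassified about 25% of the time under these defaults —
the direction of the published abundance effect, at a higher level (the
vignette's "Limitations" section discusses why, and which unstated
generator choices it is sensitive to).

A thin CLI wrapping the same functions ships in `inst/scripts/coretransim`
(`simulate`, `sweep`, `analyze` subcommands).

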