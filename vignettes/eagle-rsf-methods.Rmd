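---
title: "Methods: count-based RSFs from detection-adjusted aerial surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-based RSFs from detection-adjusted aerial surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfcount)
```

## The estimation problem

Aerial line-transect surveys of golden eagles record groups of birds seen
from an aircraft flying fixed east-west transects, but only a fraction of
the groups present are detected, and the fraction depends on where the
observer sits, whether the group is flying or perched, and the survey
altitude (107 m above ground level over open terrain, 150 m over forested
or rugged terrain).  `rsfcount` turns such records into a landscape-scale
resource selection function (RSF): a model of the relative intensity with
which eagles use 2 km x 10 km landscape units, as a function of terrain and
land-cover covariates.

The pipeline has four stages.

1.  **Detection adjustment.**  Each detected group of size $s$ in stratum
    $t$ (observation type x observer position) is inflated to $s/\bar{P}_t$,
    where $\bar{P}_t$ is the stratum's mean detection probability, supplied
    as data with a standard error (`default_detection()`).  This is
    Horvitz–Thompson inflation: summed over a unit it is unbiased for the
    number of individuals present in surveyed unit-years.  Per-unit sums
    across survey years are rounded to integer *pseudocounts*.
2.  **Sampling units.**  Points are drawn uniformly with replacement along
    the transects; each becomes a 2 x 10 km rectangle unless it would
    overhang a transect end.  Overlapping units are retained as independent
    draws, and an observation is counted in every unit containing it: each
    unit is its own draw from the design, and de-duplicating would bias the
    with-replacement sample.
3.  **Model.**  Pseudocounts $y_i$ follow a log-link NB2 regression with a
    fixed effort offset,
    $$\ln E[y_i] = \ln(\mathrm{years}_i) + \beta_0 + \beta_1 x_{1i} + \dots
      + \beta_p x_{pi}, \qquad \mathrm{Var}[y_i] = \mu_i + \mu_i^2/\theta,$$
    fitted by maximum likelihood (`rsf_nb()`, built on `MASS::glm.nb`).
    The offset makes coefficients per-year intensities, so units surveyed
    2–5 times are comparable.  Quadratic terms are allowed for covariates
    where intermediate values may be preferred (elevation, solar
    radiation), subject to the structural rule that a quadratic term may
    stay in the model only while its linear parent does.
4.  **Selection, uncertainty, validation, mapping.**  Backwards BIC
    selection (`backwards_bic()`); a transect-level bootstrap with
    resampled detection probabilities (`bootstrap_rsf()`); utilization-bin
    validation against held-out years (`validate_rsf()`); and decile maps
    scaled to a regional abundance total (`classify_deciles()`,
    `scale_to_abundance()`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| transect length | 100 | km | survey design standard |
| transect spacing | 60 | km | east-west gap and north-south row spacing |
| unit size | 10 x 2 | km | 1,000 m searched each side; 10 km keeps zero counts manageable |
| effort floor (`min_years`) | 2 | years | observed minimum effort; units below it are dropped |
| miss probability | 0.04 | per transect-year | gives mean effort about 4.8 of 5 years, matching the survey |
| detection floor (`p_floor`) | 0.01 | probability | truncates bootstrap draws from $N(\bar{P}_t, SE)$ to (0.01, 1]; draws at or below zero would explode the inflation |
| bootstrap iterations | 1000 | – | survey standard; percentile CIs from the central 90% |
| Moran's I radius | 200 | km | neighbourhood for residual autocorrelation, flag at $I > 0.20$ |
| correlation screen | 0.6 | \|r\| | two covariates above this are not both allowed in the full model |

## The synthetic generator

No public eagle GPS data exist at this scale, so the package carries a
generator (`landscape()`, `simulate_survey()`) whose defaults reproduce the
*statistical* structure the analysis assumes: smooth Gaussian-correlated
covariate surfaces on a planar equal-area km grid (with logistic transforms
for land-cover shares, gradient-derived slope/aspect/ruggedness, an
NDVI-like proxy deliberately correlated with forest, and axis-parallel road
lines); systematic 100-km transects with a random start; latent NB2 group
counts per 10-km segment and year with mean $\exp(X\beta)$; group sizes
mostly 1 (probabilities 0.8/0.15/0.05 for sizes 1–3); equiprobable aircraft
side; the 150-m stratum where unit forest share exceeds 0.4; Bernoulli
detection at the stratum probabilities; and independent 4% transect-year
dropout.  Default coefficients are of the magnitude seen in late-summer
eagle surveys once covariates are standardized (slopes roughly 0.3–0.9,
concave elevation and solar responses, negative forest and developed
effects) with an intercept giving about 0.6 adjusted eagles per unit over
five years — the sparse, zero-heavy regime the method is designed for.

The generator draws the *latent count distribution* as NB2.  The fitting
model only specifies the distribution of the rounded pseudocounts, not of
the latent eagles; NB2 is the natural generative counterpart and makes
truth recoverable, but it is a package decision, not a property of the
survey.

What the generator does **not** emulate: real geographic layers and their
measurement error, alternate-transect substitution (dropout is modelled
directly as missed effort), exclusion zones, observer heterogeneity beyond
the stratum means, and movement of birds between years.  Passing tests
therefore demonstrate that the estimators are correct under the model's
own assumptions — not that those assumptions hold for any particular real
landscape.

Two consequences of the pipeline's structure are worth knowing when
interpreting simulations.  First, pseudocounts estimate *individuals* while
the latent model generates *groups*: the intercept recovered from a
simulation is shifted by the log mean group size (about $\log 1.25$ under
the defaults); slopes are unaffected, so recovery and coverage checks focus
on slopes.  Second, inflation and multi-year summation make unit-level
pseudocounts substantially more dispersed than the latent counts, so the
fitted $\hat\theta$ is legitimately much smaller than the generator's
$\theta$; it is a nuisance parameter, not a recovery target.

## Numerical choices

*   **Rounding**: half away from zero (`round_half_up`); banker's rounding
    is selectable.  The choice is immaterial for the headline worked
    example (7.734 rounds to 8 either way) but is fixed for
    reproducibility.
*   **Right-side strata**: the combined (front + back) right probability is
    the default for right-side detections; the front-right-only column is
    selectable for two-observer crews.
*   **BIC convention**: $-2\ell + k\ln n$ with $k$ counting the intercept,
    slopes *and* the NB dispersion, $n$ = number of modelled units
    (`bic_value()`).  This matches `stats::BIC` on a `glm.nb` fit and is
    held fixed across every comparison.
*   **Selection ties**: deletions whose BICs agree within $10^{-6}$ are
    broken by removing the term with the smallest $|\hat\beta/SE|$, so
    traces are deterministic.  Factor covariates are removed as blocks.
*   **$\theta$ estimation**: alternating ML to $10^{-8}$ on the
    log-likelihood.  For equi- or underdispersed responses the NB2
    likelihood is maximized at the Poisson boundary and $\theta$ estimation
    diverges; `rsf_nb()` then refits at the boundary and reports
    $\theta = \infty$ (BIC still counts $\theta$, keeping the convention
    constant).
*   **Moran's I**: binary weights within an inclusive 200-km radius on unit
    centres, unstandardized by default; the row-standardized variant
    (matching `ape::Moran.I`) is available.
*   **Detection draws in the bootstrap**: one truncated-normal draw per
    stratum per iteration — the draw represents uncertainty in the stratum
    *mean*, not per-observation noise.  Units keep their original transect
    identity and effort; the model structure is never reselected inside the
    bootstrap.
*   **Decile ties**: validation bins break ties stably by unit order (bins
    stay equal-count); map classes give all cells sharing a value the same
    class, so class sizes differ from equal area by at most a tie group.
*   **Flat aspect cells** have no defined quadrant; a unit's aspect is the
    modal non-flat quadrant, with "N" (the reference level) only when the
    whole unit is flat.

## Diagnostics calibration

The deviance goodness-of-fit test refers the residual deviance to
$\chi^2_{n-p-1}$.  That approximation is adequate only at moderate fitted
means; with very sparse counts the deviance is far from chi-square and the
test should not be trusted in either direction.  The package's calibration
check therefore runs in a moderate-count regime (mean 8, $\theta = 8$,
$n = 1000$), where the test rejects a correct model at roughly — in
practice slightly below — the nominal 5%.  The conservatism is a known
property of deviance-based GOF with an estimated dispersion, and is
documented rather than corrected.

The observed-versus-expected validation regression inherits a related
caveat: bin proportions are heteroscedastic (high-use bins carry most of
the counts), so the ordinary-least-squares 90% intervals under-cover
slightly and a perfectly specified model passes the slope/intercept
criteria in roughly 85% of replicates, not 90%.  The slope itself is
unbiased (Monte-Carlo mean within 0.1 of 1).  Proportion mode is the
default because it makes pooling across years scale-free (expected
proportions reduce to the utilizations); raw-count regression is available.

## Problem sizes used by the test suite

The statistical test suite works at the sizes the method is meant for:
coefficient recovery at 1,845 units over 50 replicates; bootstrap coverage
on replicate surveys of roughly 600 units with 200 bootstrap iterations
(scaled down from the 1,000 used for production intervals); selection
behaviour at 2,000 units; GOF calibration at 1,000; validation closure on a
study-scale survey of about 1,800 units.  These are package choices that
keep a full run to a few minutes on one core while leaving Monte-Carlo
error well inside the asserted bands.

## Known limitations

*   Planar equal-area geometry throughout; no geographic CRS handling.
*   Effort is whole-transect: a year counts for a unit only if its transect
    was flown, which ignores partially flown transects.
*   The latent-truth reconciliation is exact at segment level; analysis
    units that straddle segments inherit smooth-field approximation error
    (negligible at the default correlation ranges).
*   Region abundance estimates carry no precision measure — that would
    require a multi-level bootstrap over both the population total and the
    map, which is out of scope.
*   External interfaces are plain CSV/JSON; the package does not read or
    write geospatial raster/vector formats.
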