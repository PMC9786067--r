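---
title: "Micellar retention descriptors and QSAR models of blood-brain barrier permeation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micellar retention descriptors and QSAR models of blood-brain barrier permeation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcqsar)
```

## The problem

Whether a drug candidate crosses the blood-brain barrier is summarized by
log BB, the base-10 logarithm of its brain-to-blood concentration ratio at
equilibrium. Measuring log BB in vivo is slow and expensive, so early
screening relies on quantitative structure-activity relationship (QSAR)
models that predict it from measurable or computable molecular properties.
This package implements a complete such workflow for heterocyclic
drug-like compounds, combining one experimental descriptor — a
lipophilicity measure from micellar liquid chromatography (MLC) — with
in-silico descriptors of polarity, size and flexibility. It ships the
65-compound reference dataset on which the workflow was developed
(`bbb_compounds()`, `bbb_foley_parameters()`), so every statistic below is
reproducible from the installed package alone.

## Micellar retention and the lipophilicity descriptor

In MLC the mobile phase contains a surfactant (here SDS) above its
critical micellization concentration (cmc). Retention of a solute falls as
the micellized surfactant concentration [M] = total − cmc rises, following
the Foley model

1/k = 1/km + (KAM/km)·[M],

where k = (tR − tM)/tM is the retention factor, km is retention at zero
micelle concentration and KAM the solute-micelle binding constant.
`fit_foley()` estimates the line by unweighted ordinary least squares of
1/k on [M]; the reference measurements used four SDS levels (0.10, 0.105,
0.11, 0.12 mol/L) and no weighting scheme is implied by straight-line fits
with plain R².

For strongly retained solutes the fitted intercept 1/km is often
negative, which has no physical meaning; the package warns but does not
fail, because the descriptor used downstream, log(km/KAM) = −log10(slope),
depends on the slope only. Two numerical consequences are exploited as
invariants: the descriptor is exactly invariant to the assumed cmc
(shifting the abscissa by a constant cannot change an OLS slope), so `cmc`
defaults to 0 rather than an invented literature value; and base-10 is the
correct logarithm, since −log10 of the reference slopes reproduces the
printed descriptor column (e.g. slope 9.066 → −0.957). Observations with
k ≤ 0 are excluded from fitting with a warning, as 1/k is undefined.

One caveat discovered while validating the packaged tables: for compound
38 the slope-derived descriptor (−0.6875 from slope 4.870) and the printed
descriptor (−0.682) disagree by 0.0055, well beyond rounding of either
value; the tables are mutually inconsistent for that one compound, so
consistency checks assert agreement within 0.0015 for at least 63 of the
65 compounds rather than for all of them.

## Descriptor redundancy and grouping

Candidate descriptors are screened for redundancy with
`pairwise_similarity()`, which maps Pearson correlation r to a percentage
similarity 100·(1 + r)/2. This convention — rather than 100·r — is an
inference: it reproduces the reference TPSA-HBA similarity of 99.6% from
r ≈ 0.992, which 100·r would not. `cluster_variables()` then clusters on
the dissimilarity 100 − similarity (average linkage by default; the
structure on the reference data is robust to single/complete linkage as
well) and cuts at three groups:

```{r grouping}
sim <- pairwise_similarity(bbb_compounds(),
                           c("tpsa", "hba", "mw", "alpha", "parachor_P", "nrb"))
cluster_variables(sim)
```

Group I (TPSA, HBA) carries polarity and hydrogen-bond acceptor capacity,
group II (MW, polarizability, parachor) molecular size, and group III
(NRB) flexibility. The per-group "attained similarity" we report is 100
minus the merge height under the chosen linkage; for group II this gives
≈ 92%, close to but not exactly the 93.16% quoted for the reference
analysis, whose exact similarity measure and linkage were not stated — the
group membership, which is what the modeling uses, is identical.

## Model family and validation battery

`enumerate_models()` builds the family log SP = a0 + a1·log(km/KAM) +
a2·dI + a3·NRB + a4·dII over the two responses (log BB, and log BB*, an
alternative estimate of the same endpoint derived previously from 23
reference compounds): 2 responses × 2 group-I × 3 group-II choices = 12
models labeled M1-M12, plus reduced "starred" variants of M5, M11 and M12
that drop NRB after the full fits show its contribution is negligible.
Labels follow the fixed enumeration order (first response first; TPSA
before HBA; size members in the order polarizability, parachor, MW),
which reproduces the reference label-to-predictor mapping.

`model_statistics()` computes, for a fit with n rows and p predictors:

* SS = Σ(yᵢ − ȳ)², R² = 1 − RSS/SS, R²adj = 1 − (1 − R²)(n−1)/(n−p−1),
  MSE = RSS/(n−p−1);
* F = (R²/p)/((1−R²)/(n−p−1)) with its p-value from F(p, n−p−1)
  (reported to 5 decimals; smaller values print as 0.00000);
* leave-one-out PRESS by the exact hat-matrix identity
  PRESS = Σ(eᵢ/(1−hᵢ))², and R²pred = Q²LOO = 1 − PRESS/SS. The identity
  is verified in the test suite against an explicit n-refit loop at
  1e−10 relative tolerance on random designs — the shortcut is an exact
  algebraic rearrangement, not an approximation;
* VIFⱼ = 1/(1 − R²ⱼ) from regressing predictor j on the remaining
  predictors with intercept.

Two statistics of the reference report are knowingly not reproduced
because they are internally inconsistent there: the MSE column mixes two
magnitudes for near-identical fits, and the Q²LOO entries for M5/M11/M12
restate R² rather than 1 − PRESS/SS (for M12* the printed Q²LOO does
equal R²pred). We report the standard definitions above in both cases.
Likewise one printed F value (M3) disagrees with the F recomputed from
that model's own printed R²; the recomputed value is what this package
produces.

## Screening rules

`screen_models()` applies the acceptance rules: maximum VIF must stay
below 5, Q²LOO should exceed 0.6, and PRESS/SS should stay below 0.4;
survivors are ranked by higher R²pred with ties broken by lower PRESS. One
deliberate design choice: the VIF threshold is applied to the maximum VIF
*rounded to one decimal*, the precision at which VIF is conventionally
reported. Two models' exact maxima are 4.988 — below 5.0 in exact
arithmetic, yet reported and treated as 5.0 in the reference analysis.
Screening at reporting precision reproduces the reference exclusion set
{M1, M3, M4, M7, M9, M10} exactly; screening on exact values would retain
M3 and M9. The thresholds themselves are configurable via
`screening_rules()`.

```{r screening}
stats <- lapply(enumerate_models(), function(s)
  model_statistics(fit_mlr(s, bbb_compounds())))
screen_models(stats)[, c("label", "r2_pred", "press", "max_vif", "excluded", "rank")]
```

## Applicability domain

QSAR predictions are only trustworthy for compounds structurally similar
to the training set. `williams_data()` implements the leverage approach:
each compound's leverage hᵢ (hat-matrix diagonal) is compared with the
warning leverage h* = 3(p+1)/n, and its standardized residual with a
configurable band (default ±3, the conventional Williams-plot band; the
reference analysis does not state its band). Residuals are standardized as
eᵢ/s with s = √(RSS/(n−p−1)) by default; the internally studentized
variant eᵢ/(s√(1−hᵢ)) is available via `type = "internal"` — the
reference analysis does not specify which it used, so both are exposed and
the simpler one is the documented default. `predict()` on a fitted model
computes the leverage of new compounds against the training design and
flags extrapolations.

## Synthetic data: what it emulates and what it does not

`generator_config()` fixes the simulated study conditions: 65 compounds,
four SDS concentrations (0.10-0.12 mol/L), Foley intercepts drawn in the
negative range observed experimentally (−1.2 to −0.13), descriptor means
and standard deviations equal to the reference dataset's, and a
correlation structure with the same three-group geometry: TPSA-HBA at
ρ = 0.99, size-trio pairs at ρ = 0.93, across-group and NRB couplings at
ρ = 0.15, and the lipophilicity descriptor at ρ = −0.5 to the polar group
and +0.6 to the size group (values rounded from the reference data and
constrained jointly to keep the target correlation matrix positive
definite, which `generator_config()` verifies). Count descriptors (HBA,
NRB) are produced by rounding a latent Gaussian and clipping to the
observed ranges (5-8 and 2-6); correlation targets are therefore asserted
on the latent scale, where they are exact in expectation, because
discretization to a handful of levels attenuates sample correlations.
Retention noise (sd 0.01) enters additively on the 1/k scale — the scale
on which the model is fitted — so OLS recovery of the Foley truth is
unbiased by construction; response noise defaults to sd 0.08, which
yields fit qualities (R² ≈ 0.8-0.97) in the range of the reference
models. The generator does not emulate chromatographic peak shapes,
instrument drift, heteroscedastic retention noise, or non-normal
descriptor distributions, so passing recovery tests demonstrate
correctness of the estimators under the stated model, not robustness to
real-data pathologies.

The recovery criterion used in the acceptance suite — at least 99% of
estimated coefficients across 500 seeded replicates within ±3 standard
errors of truth — is evaluated pooled over coefficients. The joint
per-replicate version (all five coefficients simultaneously within ±3 SE)
has a theoretical ceiling near 98% under t(60) sampling and would fail
even for a perfect estimator, so the pooled form is the meaningful one.

## Numerical choices and degenerate inputs

* Two-point Foley series fit exactly (R² defined as 1).
* Zero variance in [M], non-positive slopes (descriptor undefined), and
  sub-cmc concentrations are errors, not silent results.
* Perfect regression fits report R² = 1 and F = Inf with a flag;
  standardized residuals and Williams tables are refused for them (the
  report pipeline skips those tables with a warning).
* Leverage exactly 1 (self-interpolating point) makes the LOO shortcut
  ill-defined and is an error.
* The report writer fixes R-type statistics at 4 decimals, coefficients
  at 3, VIF at 1 — matching the conventional reporting precision — and is
  byte-reproducible for identical inputs.
* Test-suite problem sizes: 100 random designs for the LOO oracle check,
  500 replicates for coefficient recovery, n = 2000 draws for correlation
  concentration checks; the full suite runs in seconds.

## Known limitations

The packaged tables are transcriptions of printed values rounded to 2-3
decimals, so statistics recomputed from them can differ from the original
unrounded analysis in the fourth decimal (the observed R² between the two
response columns is 0.9012, against 0.9010 reported from unrounded data).
The Foley parameters themselves cannot be re-derived here because the raw
retention factors per concentration were never published; they are inputs,
validated only for internal consistency with the descriptor column. The
similarity convention and linkage are inferences consistent with, but not
uniquely determined by, the reference figures.
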