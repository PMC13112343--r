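# fishspectra

Size-spectrum analysis of lake fish communities under non-native fish
invasion.

## The problem

The individual size distribution (ISD, or "size spectrum") of a fish
community — the frequency distribution of individual body masses —
typically declines as a power law: steep ("more negative") spectra are
dominated by small fish, flat spectra carry relatively more
large-bodied individuals. Biological invasions reshape this structure:
non-native (NN) fishes tend to be larger than natives, piscivorous
invaders prey on small natives, and lower-trophic-level invaders
compete with them. `fishspectra` provides the full analysis chain used
to quantify these effects across lakes and climates, for ecologists
working with individual-level gillnet catch data:

* maximum-likelihood estimation of the bounded power-law exponent per
  survey, with profile-likelihood intervals and cutoff sensitivity
  checks;
* per-survey invasion-pressure and trophic-dominance metrics, with
  biomass standardised per unit effort (BPUE, kg km⁻² h⁻¹);
* logarithmic size-class biomass correlations against NN trophic
  dominance;
* a four-model inference suite (robust MM-regression for exponent
  responses, lake-random-intercept mixed models for biomass responses)
  linking invasion × temperature to community size structure;
* a synthetic community generator with known ground truth, so every
  stage is testable end to end without field data.

## The model

Individual body masses `x` in a community are modelled as a bounded
power law (PLB) on `[xmin, xmax]` with exponent `λ`. The negative
log-likelihood minimised by `fit_plb()` is

    ℓ(λ; x) = −n·ln[ (λ+1) / (xmax^(λ+1) − xmin^(λ+1)) ] − λ·Σᵢ ln xᵢ ,   λ ≠ −1
    ℓ(λ; x) =  n·ln( ln xmax − ln xmin ) + Σᵢ ln xᵢ ,                     λ = −1

with the `λ = −1` branch a removable singularity handled exactly.
Downstream, each survey's estimated exponent `λ̂` (whole community and
native-only) and its BPUE enter standardized regressions whose key
predictors are a PCA-based composite invasion-pressure score
(`pca_inv`), the shares of individuals that are NN piscivores
(`pisc_nn`) or NN lower-trophic-level species (`ltl_nn`), mean annual
air temperature, and their interactions.

## Worked example

```r
library(fishspectra)

# fit a size spectrum to one community sample
set.seed(1)
fit <- fit_plb(rplb(2000, lambda = -1.8, xmin = 0.5, xmax = 2000))
fit
#> Bounded power-law (PLB) size-spectrum fit
#>   lambda = -1.802  [-1.838, -1.766] (95% profile CI)
#>   n = 2000 individuals, mass range [0.5, 1.88e+03] g
```

The estimate recovers the generating exponent (−1.8) and the 95%
profile interval covers it. A full pipeline run on a synthetic
campaign:

```r
cfg <- generator_config(n_lakes = 40, surveys_per_lake = c(1, 3),
                        n_fish_per_survey = c(60, 200), seed = 42)
ds  <- generate_direct(cfg)
res <- run_pipeline(ds)
res
#> size-spectrum pipeline result
#>   81 surveys retained (0 excluded)
#>   mean exponent: all = -1.201, native = -1.396
#>   invasion axis explains 73.4% of variance
#>   model suite: 4 models fitted

b <- res$models$coefficients
b[b$model == "exponent_all" & b$term %in% c("pca_inv", "temp", "pca_inv:temp"), ]
#>         model         term    beta     se  p_value n_obs
#>  exponent_all      pca_inv  0.2243 0.0945 1.76e-02    81
#>  exponent_all         temp -0.0445 0.1455 7.60e-01    81
#>  exponent_all pca_inv:temp  0.4627 0.0961 1.47e-06    81
```

The generator's true invasion effect and invasion × temperature
interaction on the exponent are both positive, and the suite recovers
their signs with the interaction clearly significant: under high
invasion pressure, warmer lakes show flatter spectra.

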