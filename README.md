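# sceneBayes

Modelling yes/no image-scene recognition when images are shown in
sequences of gradually changing naturalness.

In the task this package analyzes, each block presents six images
derived from one original scene at naturalness levels
α ∈ {0.0, 0.2, …, 1.0}, either descending (natural → unnatural, "NU")
or ascending ("UN"), plus binary control blocks showing only the
endpoints. After each image the participant reports whether the scene
is recognizable. Because all images of a gradual block share one
underlying scene, recognition at a given α depends on the presentation
history — participants keep recognizing a degrading scene longer than
they acquire a building one (hysteresis). The package is written for
cognitive-neuroscience researchers who want to fit this observer model
to behavioral data, generate model-based fMRI regressors from it, and
reproduce the accompanying behavioral and eye-tracking analyses.

## The model

The perceived naturalness of an image at level α is N(α, σ) with a
shared spread σ. A participant with threshold *C* recognizes the image
on its own with probability equal to the right tail beyond the
threshold,

    P(α | Yes) = Φ_{α,σ}(2α − C) = 1 − Φ_{α,σ}(C),

and updates the recognition probability sequentially with a
persistence weight λ ∈ [0, 1]:

    P(Yes | α) = e_y / (e_y + e_n),
    e_y = P(Yes)^λ · P(α | Yes)^{1−λ},
    e_n = (1 − P(Yes))^λ · (1 − P(α | Yes))^{1−λ},

the previous posterior serving as the next prior. Four variants — λ
free (M1), λ = 0 (M2), λ = 1 (M3), condition-specific λ (M4) — are fit
per participant by grid-search maximum likelihood and compared by BIC,
k·ln(n) − 2·logLik. From the per-trial traces the package derives the
three fMRI modulators (log-likelihood certainty, log-prior certainty,
Bernoulli-KL Bayesian surprise), serially orthogonalizes them, and
writes BIDS-style events tables. It also computes recognition-rate and
response-transition tables with paired Wilcoxon/Bonferroni contrasts,
fixation-density maps by anisotropic Gaussian KDE compared via MSE,
and a spectral (mean 2-D Fourier power) image-complexity feature.
Seeded synthetic generators for cohorts, gaze scanpaths, and image
families let the whole pipeline run without any recorded data. See
`vignettes/scene-recognition-model.Rmd` for the full methods account.

## Worked example

```r
library(sceneBayes)

pars  <- modelParams(C = 0.55, lam = 0.23, sigma = 0.3)
trace <- runBlock(blockDesign("NU"), pars)
trace
#> PosteriorTrace (NU, 6 trials)
#>   alpha likelihood  prior posterior
#> 1   1.0     0.9332 0.5000    0.8839
#> 2   0.8     0.7977 0.8839    0.8210
#> 3   0.6     0.5662 0.8210    0.6354
#> 4   0.4     0.3085 0.6354    0.3790
#> 5   0.2     0.1217 0.3790    0.1631
#> 6   0.0     0.0334 0.1631    0.0489
```

The likelihood column is how recognizable each image is on its own;
the posterior blends it with the carried-over prior, so at α = 0.6 the
observer still sits at 0.64 on the way down (the same image reached
ascending gives 0.40 — the model's hysteresis). Surprise peaks where
the image most changes the carried prior:

```r
round(bayesianSurprise(likelihoods(trace), priors(trace)), 4)
#> [1] 0.4478 0.0305 0.1737 0.2196 0.1663 0.0863
```

Fitting a simulated 30-participant cohort at those generating
parameters recovers them:

```r
sim <- simulateCohort(cohortSpec(nParticipants = 30, seed = 1))
cmp <- compareModels(sim$trials)
cmp$group[, c("variant", "sumBic", "meanC", "sdC", "meanLam", "sdLam")]
#>   variant sumBic meanC    sdC meanLam sdLam
#> 1      M1   6080 0.552 0.0802   0.223 0.132
#> 2      M2   6080 0.554 0.0829   0.000 0.000
#> 3      M3   8836 0.000 0.0000   1.000 0.000
#> 4      M4   6218 0.553 0.0837      NA    NA
```

The fitted threshold (0.552 ± 0.080) and persistence (0.223 ± 0.132)
sit on the generating values; the frozen-prior variant M3 is ruled out
outright, while M1 and M2 are nearly tied in summed BIC at this
persistence level — the vignette discusses why BIC discrimination of a
λ ≈ 0.23 effect is weak at this design size. The behavioral hysteresis
itself is clearly visible in the α-wise condition contrast
(`conditionContrast(sim$trials)`), e.g. mean recognition 0.386 (NU)
vs 0.254 (UN) at α = 0.4, corrected p = 0.0036 at α = 0.2 and 0.0009
at α = 0.4.

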