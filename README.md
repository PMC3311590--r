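# pepAAWS

Amino-acid-associated weights (AAWS) for antibody binding on
random-sequence peptide microarrays: a Langmuir binding simulator for
antibody mixtures, and a composition-only partial-least-squares regression
that predicts binding profiles and recovers per-residue binding
preferences.

## The problem

Serum antibody profiling incubates a complex antibody mixture on an array
of random peptides and reads one fluorescence intensity per peptide. Each
individual antibody binds position-dependently, yet for highly diverse
("unbiased") mixtures the aggregate signal becomes predictable from peptide
amino-acid **composition** alone. pepAAWS is for researchers who want to
(i) simulate this ensemble behaviour under controlled diversity, noise and
antibody-dominance conditions, and (ii) fit the composition-only model to
simulated or measured intensity profiles.

## The model

A 20-vector *h* ∈ [0,1]²⁰ of per-residue binding strengths encodes peptide
*i* as *p*ᵢ ∈ [0,1]ˡ; an antibody binding site is a unit-norm vector
*a*ₖ ∈ ℝˡ. Binding association is the dot product *y*ᵢₖ = *a*ₖᵀ*p*ᵢ, the
association constant is

    K_ik = exp((β₀ + β₁·y_ik) / (R·T)),      defaults: β₀ = 0, β₁ = RT  ⇒  K = exp(y)

and the simulated spot signal is the Langmuir bound fraction

    S_i = Σ_k c_k·K_ik / (1 + Σ_k c_k·K_ik),   Σ_k c_k = 1.

Signals are log-transformed, centred and scaled. The composition-only
regression *s* = *X w* + ε (X = peptide-by-amino-acid count matrix) is
fitted by PLS; *w* is the AAWS estimate, and predictive performance is the
cross-validated

    Q² = 1 − Σ(ŝ_leftout − s_leftout)² / Σ s_leftout².

## Worked example

```r
library(pepAAWS)

lib <- generateLibrary(255, 14, seed = 1)   # random 14-mers, no runs of 3
h   <- sampleAssignedAAWS(seed = 2)         # generative weights, U[0,1]^20
mix <- makeMixture(150, 14, seed = 3)       # 150 antibodies, equal conc.

prof <- applyNoise(simulateSignal(lib, mix, h), sigma = 0.01, seed = 4)
s <- normalizeSignal(prof)
#> BindingProfile (normalized): 255 peptides
#>   range: -3.086 .. 2.628

X <- compositionMatrix(lib)                 # 255 x 20, rows sum to 14
fit <- fitAAWS(s, X)
#> AAWSEstimate: 3 PLS component(s), fitted on profile
#>      A      C      D      E      F      G      H      I      K      L  ...
#> -0.232  0.130  0.004 -0.276  0.349  0.388 -0.187  0.141  0.005 -0.030 ...

q2(q2CrossValidation(s, X, seed = 5))
#> [1] 0.63
hRecovery(fit, h)
#> [1] 0.9687
```

The Q² of 0.63 says composition alone explains about two thirds of the
left-out signal variance for this 150-antibody mixture; the recovery
correlation 0.97 says the fitted weights closely track the generative
per-residue strengths, even though every simulated antibody binds
position-dependently. Single-realization Q² values scatter widely (sd ≈
0.13 across library/h/mixture draws); replicate means are the quantity to
quote.

Diversity is the controlling variable — with the same library and weights:

```r
sw <- diversitySweep(lib, h, nAbGrid = c(1, 16, 256, 4096), reps = 5, seed = 6)
#> SweepResult over n_Ab = 1, 16, 256, 4096
#>   median Q2: -0.0779, 0.195, 0.802, 0.988
```

A single antibody is unpredictable from composition (Q² ≈ 0); a
4096-antibody mixture is almost perfectly predictable.
`dominanceExperiment()` runs the complementary perturbation: raising one
antibody's concentration 10- or 1000-fold degrades prediction again.

Command-line runs are available through declarative configs:

```sh
Rscript inst/scripts/pepaaws.R --config run.cfg
```

See `?runFromConfig` for the modes (`generate-library`, `simulate`, `fit`,
`sweep`, `dominance`, `pca`, `correlate-scale`).

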