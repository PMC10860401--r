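# pident

Practical identifiability diagnostics for dynamic models in R.

Mechanistic plant-growth and epidemic models carry parameters with
biological meaning, so estimated values are only useful if the data
actually pin them down. Whether they do depends on the observation
protocol — which variables are measured, when, and with how much
noise — not just on the model equations. `pident` quantifies this
*practical* identifiability for discrete-time and continuous-time
dynamical systems

    x'(t) = f(x, θ, u, t),   y(t) = g(x, θ, u, t)

through three complementary indices:

* **Collinearity indices.** From the scaled sensitivity matrix
  S<sub>ij</sub> = (Δθ<sub>j</sub>/SC<sub>i</sub>) ∂η<sub>i</sub>/∂θ<sub>j</sub>
  of the noise-free measurement vector η(θ), the index of a parameter
  subset K is γ<sub>K</sub> = 1/√λ<sub>min</sub> of the Gram matrix of
  the unit-normalized columns S[, K]. A shift of one parameter in K can
  be compensated up to (1 − 1/γ<sub>K</sub>)·100 % by the others; γ = ∞
  when the columns are exactly dependent. Local (at a reference θ\*)
  and prior-averaged variants are provided, for every subset size.
* **Profile-likelihood confidence intervals and a risk index.** With
  χ²(θ) = Σ<sub>kl</sub> (y<sub>kl</sub> − η<sub>kl</sub>(θ))²/σ<sub>kl</sub>²,
  the profile of θ<sub>i</sub> minimizes χ² over the other parameters;
  the PLCI at level α is bounded by the crossings of the profile with
  χ²<sub>min</sub> + χ²(α, 1). The risk index
  r<sub>i</sub> = 1 / sup{α : PLCI finite} turns the binary
  practical-nonidentifiability diagnosis into a number: r ≈ 1 means
  identifiable at essentially every confidence level.
* **Average relative error.** ARE<sub>i</sub> = 100 · mean over N
  synthetic-data replicates of |θ\*<sub>i</sub> − θ̂<sub>i</sub>|/|θ\*<sub>i</sub>|,
  where each replicate re-runs the whole pipeline: fresh Gaussian
  noise, a random log-normal initial guess, and a Nelder–Mead fit.

Two case-study models ship with the package: **LNAS**, a daily
discrete-step sugar-beet growth model driven by temperature and
radiation (with a synthetic weather generator), and an SIR-type
**plant-population epidemic model** with carrying-capacity stem
production and an exponentially decaying force of infection.

## A worked example

```r
library(pident)
model    <- epidemicsModel()       # observes I and N = S + I + R
protocol <- epidemicsProtocol()    # days 2,4,...,12; noise sd = 1.5% of time-mean

## which parameter subsets can compensate each other?
S <- sensitivityMatrix(model, protocol, scaling = "global")
head(subsetCollinearity(S, 2, 2), 3)
#>       subset size     gamma compensation
#> 1       mu+d    2 43.228115     97.68669
#> 2  lambda0+d    2  3.439672     70.92746
#> 3 lambda0+mu    2  3.336104     70.02491
```

The (μ, d) pair dominates: a change in the decay rate of the force of
infection can be compensated to ~98 % by the death rate of infected
stems, so the two are hard to estimate jointly from this protocol.

```r
## how far can we push the confidence level before the interval
## for the carrying capacity becomes infinite?
dataset   <- simulateDataset(model, protocol, seed = 1)
objective <- chi2Objective(model, protocol, dataset)
riskIndex(objective, "kappa")
#> Risk index of 'kappa': 1.004 (sup alpha = 0.9961, bisection tol 0.005)
```

A risk index of ~1.00 says κ stays practically identifiable at every
usable confidence level — consistent with its near-1 collinearity
indices and with the smallest average relative error among the five
parameters (`areIndex(model, protocol, N = 100, seed = 1)`).

The whole pipeline (trajectory, dataset, collinearity, risk and ARE
tables as CSV plus a JSON summary) runs from a single config:

```r
cfg <- readAnalysisConfig(system.file("configs", "epidemics-case-study.yaml",
                                      package = "pident"))
runAnalysis(cfg, outdir = "epidemics-output")
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/pident.R run -c inst/configs/epidemics-case-study.yaml -o out
```

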