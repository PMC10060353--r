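# crowddiff

Per-particle diffusivity inference for interacting particle systems, with
an in-silico cell-migration laboratory.

## The problem

Tracking experiments on crowded cell populations (the motivating system is
in vitro glioblastoma migration) observe every cell at equally spaced
times and ask for each cell's intrinsic motility — the isotropic diffusion
parameter `σ_i` of the Itô SDE

    dx_i(t) = a_i(x(t)) dt + σ_i dW_i(t),
    a_i(x)  = − Σ_{j≠i} ∇_{x_i} U(‖x_i − x_j‖),

where `U` is a known attractive-repulsive pair potential (Morse, by
default). The classical mean-square-displacement (MSD) estimator,

    σ̂²_MSD = Σ_k ‖x_{i(k+1)} − x_{ik}‖² / (2KΔt),

is the maximum-likelihood estimator only for *free* Brownian motion; in a
dense population neighbour forces suppress net displacement and MSD
systematically under-reports σ (induced sub-diffusivity).

`crowddiff` implements a higher-order Gaussian transition density whose
covariance incorporates the drift Jacobian
`A_ik = −Σ_{j≠i} Hess U(‖x_ik − x_jk‖)`:

    x_i(t_{k+1}) ~ N(m_ik, S_ik),
    m_ik = x_ik + a_ik Δt,
    S_ik = S1ᵀS1 + S2ᵀS2,
    S1 = σ_i √Δt (I + (Δt/2) A_ik),   S2 = σ_i Δt^{3/2}/√12 · A_ik .

Because the precision `τ_i = σ_i⁻²` enters the resulting likelihood
linearly, it admits a Gamma conjugate posterior

    α_K = α_0 + K,
    β_K = β_0 + ½ Σ_k (x_{i(k+1)} − m_ik)ᵀ S̄_ik⁻¹ (x_{i(k+1)} − m_ik),

with `S̄ = σ⁻²S`, giving closed-form per-cell posteriors, the MLE
`σ̂² = β_K/K`, and posterior-mode point estimates — no sampling, no
optimisation. With interactions switched off everything reduces exactly
to the MSD machinery.

The package also ships the Brownian-dynamics generator used to validate
all of this (Morse-interacting populations with reflecting walls,
Euler–Maruyama at 1-second steps, the published experiment designs as
presets) and an evaluation harness comparing both estimators across
density × observation-frequency grids.

## A worked example

Simulate a day of a dense 128-cell population (the `exp3` published
design, every cell with σ = e^(−9/2) ≈ 0.01111), observed every
5 minutes, then fit both estimators:

```r
library(crowddiff)
cfg <- experiment_preset("exp3", N = 128L, duration = 86400,
                         obs_interval = 300, seed = 131)
obs <- simulate_system(cfg)
fit_hom <- fit_diffusivity(obs, method = "hom")
fit_msd <- fit_diffusivity(obs, method = "msd")
fit_hom
#> Diffusivity fit, higher-order transition model
#>   128 particles, K = 288 intervals of 300 s, prior Gamma(0, 0)
#>   posterior-mode sigma: mean 0.0120865, median 0.01213
#>   ground truth sigma: 0.011109; sum of mode deviations E = 0.012859
fit_msd
#> Diffusivity fit, MSD (free-Brownian) model
#>   128 particles, K = 288 intervals of 300 s, prior Gamma(0, 0)
#>   posterior-mode sigma: mean 0.0099597, median 0.0099163
#>   ground truth sigma: 0.011109; sum of mode deviations E = 0.015645
```

The MSD estimates sit ~10% below the truth (crowding bias); the
higher-order fit overshoots by less and wins on the sum of mode
deviations (E = 0.0129 vs 0.0156). `plot(fit_hom)` draws the
kernel-smoothed distribution of log posterior modes with the truth
marked; `coef()`, `summary()`, `residuals()` and `simulate()` behave as
for any fitted-model object, and `write_estimates()` /
`read_trajectories()` handle the CSV interchange formats. A thin
command-line wrapper over the same functions lives at
`inst/cli/crowddiff.R` (subcommands `simulate`, `infer`, `evaluate`,
`grid`).

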