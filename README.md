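# smolsensor

Quantitative analysis of single-molecule imaging of membrane lipid
biosensors and endogenously tagged effectors, for researchers doing
TIRF microscopy of living cells. Strongly overexpressed lipid biosensors
can sequester their target lipid and suppress endogenous signaling;
biosensors expressed at single-molecule densities avoid this, but
analyzing them means counting and characterizing discrete fluorescent
spots instead of bulk fluorescence. `smolsensor` provides that analysis
stack:

* **Multimer deconvolution** — the intensity distribution of N puncta is
  modeled as ρ(x) = (1/N) Σ_c A_c ρ_c(x), where ρ₁ comes from a monomeric
  calibration construct and higher-order bases ρ_c are derived from it
  (axis scaling ρ_c(x) = ρ₁(x/c)/c, or c-fold self-convolution). Weights
  A_c/N are fitted by reduced-χ² minimization against Monte-Carlo model
  histograms.
* **Spot quantification** — difference-of-Gaussians detection with
  sub-pixel Gaussian refinement, molecule densities per 100 µm², rolling
  averages, F/F₀ and modal-background utilities.
* **Two-phase kinetics** — recruitment traces are fitted to
  F(t) = F_max·[tⁿˢ/(tⁿˢ+τ_synⁿˢ) − tⁿᵈ/(tⁿᵈ+τ_degⁿᵈ)] (t ≥ 0; F₀ before
  stimulus), with rate constants k = 1/τ and residual-bootstrap 95% CIs.
* **IF quantification** — Huang fuzzy-entropy thresholding, watershed
  nucleus splitting, Voronoi-style cell territories, area/border ROI
  filters, and transfection gating at control mean + 3 SD.
* **Copy-number arithmetic** — densities → molecules per cell → ploidy
  scaling → proteome fraction, plus the Airy-disc crowding ceiling.
* **Synthetic data** — seeded generators for every input (intensity
  mixtures, TIRF frames and movies, noisy traces, IF fields) with ground
  truth, so the whole pipeline is testable without microscopy data.

## Worked example

Deconvolve a simulated 5,000-spot population that is 98.1% monomeric:

```r
library(smolsensor)

model <- monomer_model(log_mean = log(1000), log_sd = 0.4)
calib <- gen_monomer_intensities(5000, model, seed = 101)
rho1  <- build_histogram(calib)                  # 50 bins to the 99.9th pct
basis <- derive_basis(rho1, M = 3, mode = "scale")
expt  <- simulate_model_histogram(basis, c(0.981, 0.019, 0), 5000,
                                  seed = 201)
fit_mixture(expt, basis, seed = 301)
#> Multimer mixture fit (M = 3, scale basis)
#>   fractions: c=1: 0.984, c=2: 0.014, c=3: 0.002
#>   reduced chi-squared: 1.000 on 38 dof (seed 301)
```

The fitted fractions are the estimated shares of monomers, dimers and
trimers; a reduced χ² near 1 says the mixture model describes the
histogram to within counting noise.

Fit recruitment kinetics to a noisy synthetic trace and get rates:

```r
kp <- kinetic_params(F_max = 1, n_syn = 2, tau_syn = 1 / 1.09,
                     n_deg = 2, tau_deg = 1 / 0.13)
tc  <- gen_timecourse(kp, seq(-2, 15, 0.5), noise_sd = 0.05, seed = 4)
fit <- fit_timecourse(tc)
fit$rates
#> $k_syn
#> [1] 0.8654752
#>
#> $k_deg
#> [1] 0.1575657
```

Single traces at this sampling are intentionally noisy estimators (see
the methods vignette); medians over ~100 traces recover the generating
rates to a few percent.

Copy-number arithmetic for a measured density:

```r
unlist(copy_number_report(25)[c("molecules_per_allele",
                                "molecules_ploidy_scaled",
                                "proteome_percent_rounded",
                                "airy_area_um2_2sf",
                                "crowding_density_1sf")])
#>     molecules_per_allele  molecules_ploidy_scaled proteome_percent_rounded
#>                  375.000                 1125.000                    5.000
#>        airy_area_um2_2sf     crowding_density_1sf
#>                    0.035                 3000.000
```

An end-to-end run from one config:

```r
cfg <- default_config(seed = 1)
run_pipeline(cfg, "runs/demo")    # writes TIFFs, CSVs and JSON reports
```

A thin command-line wrapper over the same functions is included at
`inst/cli/smolsensor.R`.

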