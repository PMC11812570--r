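---
title: "Quantifying single-molecule lipid biosensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule lipid biosensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smolsensor)
```

# Scope

`smolsensor` implements the quantitative core of a single-molecule TIRF
workflow for membrane lipid biosensors and endogenously tagged effector
proteins: how many fluorophores sit in each diffraction-limited spot
(multimer deconvolution), how many spots sit on each patch of membrane
(spot detection and densities), how recruitment evolves after stimulation
(two-phase cooperative kinetics), which cells in an immunofluorescence
field express a construct (segmentation and gating), and what a measured
density implies for per-cell copy numbers. Because raw microscopy data of
this kind are rarely redistributable, the package carries a first-class
synthetic-data generator that produces every input with known ground
truth; all validation in the test suite runs against that generator.

# The multimer deconvolution model

The intensity distribution of a population of $N$ fluorescent puncta of
mixed stoichiometry is modeled as a mixture

$$\rho(x) = \frac{1}{N}\sum_{c=1}^{M} A_c\,\rho_c(x),$$

where $\rho_c$ is the intensity distribution of puncta carrying $c$
fluorophores, $A_c$ the number of such puncta and $M$ the largest
stoichiometry considered (default 3: monomer, dimer, trimer). $\rho_1$
is measured: a calibration construct expressed at single-molecule levels
gives a mono-modal, lognormal-looking intensity histogram. Higher-order
bases are *derived* from $\rho_1$, and the package exposes the two
transformations that appear in this literature as equal citizens:

* **scale** (default): $\rho_c(x) = \rho_1(x/c)/c$, a pure stretching of
  the intensity axis. A $c$-mer is $c$-fold brighter and keeps the
  monomer's *relative* spread. This is the axis-scaling transform of the
  calibration histogram.
* **convolve**: $\rho_c = \rho_1^{*c}$, the $c$-fold self-convolution.
  This is the model for $c$ *independent* emitters adding their photons:
  means and variances both scale by $c$, so relative spread shrinks as
  $1/\sqrt{c}$.

The two agree exactly at $c=1$ and differ in variance at $c\ge 2$
(variance $c^2$ vs $c$ times the monomer's). Which one is right depends
on whether spot-to-spot brightness variation is dominated by per-spot
factors (illumination field, axial position — favoring `scale`) or by
per-fluorophore photophysics (favoring `convolve`). The package does not
silently resolve this; `derive_basis(mode =)` makes it a visible choice,
and the test suite exercises both. The half-bin mean offset inherent in
discrete self-convolution is removed by splitting each convolved
coefficient across the two bins adjacent to its exact center, which
preserves the mean exactly at the price of $w^2/4$ extra variance per
fold ($w$ = bin width), negligible against the distribution's own width.

## Fitting

`fit_mixture()` estimates the weights $f_c = A_c/N$ by minimizing the
reduced $\chi^2$ between the observed histogram and the expectation
$n\,\sum_c f_c \rho_c$. Choices that the underlying literature leaves
open, fixed here as package defaults:

* **Binning**: 50 equal-width bins from 0 to the 99.9th percentile of
  the calibration samples; values above the range are tallied into the
  last bin so counts are conserved. The basis grid extends to $M$ times
  the calibration range.
* **Monte-Carlo smoothing**: each basis column is replaced by the
  empirical histogram of `n_draws = 20 × n` inverse-CDF draws, so the
  fitted model is literally a randomly generated intensity distribution
  derived from the basis histograms. Draws are taken once per fit under
  the fit seed, keeping the objective deterministic given the seed.
* **$\chi^2$ validity**: bins with fewer than 5 expected counts are
  pooled into their right-hand neighbours (trailing remainder into the
  last group). Inside the fit the pooling pattern is frozen from the
  observed counts so that the objective is continuous in $f$; the
  standalone `reduced_chi2()` pools on expected counts, the textbook
  convention.
* **Degrees of freedom**: pooled bins $-(M-1)-1$; the simplex constraint
  leaves $M-1$ free weights.
* **Optimization**: the simplex is parameterized by a softmax over
  $M-1$ logits and minimized with Nelder–Mead from 10 starting points
  (uniform weights first, then Gaussian random logits); the best restart
  is reported. The surface is low-dimensional and cheap, so restarts are
  the whole robustness strategy.
* **Power floor**: fits are refused below 100 spots — with 50 bins and
  two free weights there is no meaningful $\chi^2$ below that.

A self-consistency study in the test suite (mixtures drawn from the
basis, monomer fractions 0.5–1.0, 5,000 spots, 20 seeds each) recovers
monomer fractions with mean absolute error below 0.03 and median reduced
$\chi^2$ within [0.7, 1.4]. When the experimental samples are instead
drawn fresh from the generating lognormal (as the end-to-end pipeline
test does), the calibration histogram's own sampling noise is not part
of the model and the expected reduced $\chi^2$ rises toward
$1 + n_{\mathrm{expt}}/n_{\mathrm{calib}}$; fraction recovery is
unaffected. This is worth remembering whenever the calibration dataset
is not much larger than the experimental one.

# Two-phase cooperative kinetics

Recruitment traces following acute stimulation rise sigmoidally and then
decay. Both phases are modeled cooperatively with Hill terms:

$$F(t) = \begin{cases} F_0, & t < 0\\[2pt]
F_{\max}\left[\dfrac{t^{n_{\mathrm{syn}}}}{t^{n_{\mathrm{syn}}}+\tau_{\mathrm{syn}}^{n_{\mathrm{syn}}}}
 - \dfrac{t^{n_{\mathrm{deg}}}}{t^{n_{\mathrm{deg}}}+\tau_{\mathrm{deg}}^{n_{\mathrm{deg}}}}\right], & t \ge 0,\end{cases}$$

with rate constants $k = 1/\tau$ for each phase. $F_{\max}$ multiplies
the *difference* of the two terms, so $F \to 0$ as $t \to \infty$ — the
parenthesization matching traces that return to baseline. $F_0$ is fixed
to the pre-stimulus mean rather than fitted; after $\Delta F$
normalization it is 0, and the piecewise branch keeps it constant.

`fit_timecourse()` uses bounded Levenberg–Marquardt least squares
(`minpack.lm`) on the post-stimulus points, bounds
$\tau \in [0.05, 100]$ min, $n \in [0.5, 8]$, $F_{\max} \in [0, 10]$,
with data-driven starting values (peak position sets the $\tau$ scale)
jittered over 5 restarts; lowest RSS wins and non-convergence of all
restarts is flagged, never silently dropped.

Two properties of this model matter for interpreting fits. First, the
surface is *sloppy*: $n$, $\tau$ and $F_{\max}$ trade off along flat
valleys, so single-trace estimates of $k_{\mathrm{syn}}$ scatter widely
(quartiles roughly ±20% at 5% noise and 0.5-min sampling) even though
the median across traces is nearly unbiased. The simulation studies
therefore key on medians over many traces. Second, reparameterizing in
$k$ rather than $\tau$ changes nothing about the optimum in exact
arithmetic, but on the flat valley two optimizers will stop at points
that differ by about the optimizer step (~1% in the rates) while
agreeing on the objective to a fraction of a percent; the test suite
asserts exactly that.

The default simulation scenario pairs $k_{\mathrm{syn}} = 1.09$ min⁻¹
with $k_{\mathrm{deg}} = 0.13$ min⁻¹ (timescales 0.92 and 7.7 min),
Hill coefficients 2 (plausible cooperativity for multi-step pathway
activation; published fits of this kind do not report them), sampling
every 0.5 min from −2 to 15 min, Gaussian noise 5% of $F_{\max}$.

## Bootstrap confidence intervals

Published rate constants of this kind come with 95% CIs whose method is
typically unstated. The package uses a residual bootstrap: resample the
post-stimulus residuals with replacement, add them to the fitted curve,
refit, and read off percentile intervals from the resampled parameter
distribution. Two details matter a great deal on this surface and were
fixed by a coverage calibration study (200 simulated traces at the
default scenario):

* Residuals are mean-centered and inflated by $\sqrt{n/(n-p)}$
  ($p = 5$), correcting the downward bias of residual spread after
  fitting five parameters to ~30 points.
* Each refit applies the *same* estimator as the point fit — data-driven
  starting values with jittered restarts — rather than being seeded at
  the point estimate. Point-estimate-initialized refits stay inside the
  point fit's mode and miss the between-mode variability that dominates
  single-trace uncertainty here; calibrated coverage rises from the low
  80s to ~95% with full refits. Three refit restarts suffice: the
  estimator distribution is indistinguishable at 3, 5 or 15 restarts.

Alternative constructions (basic/reflected, normal-theory $t$, BCa) were
all further from nominal than the percentile interval in the same study,
counterintuitively but reproducibly, so percentile is the only
construction exposed. Intervals are clamped to contain the point
estimate. Default 1,000 resamples; the coverage suite uses 200 resamples
per trace to keep 200-simulation studies tractable, a study-size choice,
not a method change.

# Synthetic data: what it emulates, what it does not

The generator reproduces the *statistical* features the analyses rely
on, not microscope physics:

* **Monomer intensities**: lognormal, default median 1,000 ADU,
  log-SD 0.4. The calibration distribution's true parameters are not
  published; these defaults are a plausible camera scale and are fully
  configurable. Everything downstream is scale-free.
* **TIRF frames**: uniform background (default 100 ADU) plus integrated
  2D Gaussian spots (PSF σ 0.085 µm, pixel 0.087 µm — the 1.45 NA,
  150× magnification, 2×-binned sCMOS regime), Poisson shot noise on total photons and Gaussian read noise
  (2 ADU). No vignetting, no sCMOS fixed-pattern noise, no axial
  structure, no diffusion or blur: detection-rate results transfer to
  real data only to the extent that real backgrounds are locally flat.
* **Photobleaching**: per-frame Bernoulli disappearance of whole spots.
  Real bleaching is per-fluorophore and produces partial intensity
  steps; the simplification suffices for testing that measured densities
  decline, which is all the density pipeline claims.
* **Recruitment traces**: the two-phase model plus i.i.d. Gaussian
  noise. Real traces have correlated noise (shared illumination drift),
  so real-data CIs are likely wider than the simulation suggests.
* **IF fields**: cells as concentric disks (nucleus radius 3.5 µm, cell
  7 µm) with non-overlapping nuclei, Gaussian per-cell reporter and
  stain populations, mild pixel noise. Morphology is deliberately
  unrealistic; only the segmentation/gating *logic* (thresholding,
  watershed splitting, Voronoi partition, area/border filters, mean+3SD
  gating) is under test. Passing these tests says nothing about
  segmentation of irregular, crowded real cells.

Spot densities default to 25 per 100 µm² (the observed scale for an
endogenously tagged kinase at the plasma membrane, 5–35 across
conditions), and detection studies use SNR 10 spots, the regime where a
single fluorescent protein is comfortably above camera noise in TIRF.

# Spot detection

The detector is a deliberate stand-in for ThunderSTORM-style
localization: difference-of-Gaussians band-pass (σ and 1.6σ), 8-connected
local maxima above median + 5×MAD of the filtered image, then per-candidate
least-squares refinement of an axisymmetric Gaussian (amplitude, center,
σ, local background) on a ±3.5σ window, reporting sub-pixel positions and
integrated intensities. Maxima closer than twice the PSF σ are merged,
keeping the brighter — which means genuinely overlapping emitters count
as one, the same resolution limit the crowding arithmetic quantifies. At
25 spots per 100 µm², about half a spot pair per field sits below that
separation, which bounds achievable recall near 98%, and measured recall
at SNR 10 is ≥96% with ≲0.1 false positives per 100 µm² on blanks.
Densities are counts per 100 µm² of a user-supplied ROI area; the
manually drawn ROIs of interactive workflows become explicit arguments.

# IF segmentation and gating

Huang's fuzzy-entropy threshold is implemented from its definition over
a 256-bin histogram (the dialect of the common Fiji implementation):
exhaustive scan of candidate thresholds, class means from cumulative
sums, memberships $1/(1+|g-\mu_{\mathrm{class}}|/C)$, minimize the
histogram-weighted Shannon entropy of fuzziness. The scan is exact at
256 bins, so no optimizer is involved. One guard is added for the
degenerate case the original method does not contemplate: if the
resulting foreground differs from the background by less than 4
background-SDs, the field is declared empty rather than split along its
noise. Nuclei are separated with a distance-transform watershed
(EBImage, h-maxima-style tolerance 2 px), and cytoplasm territories are
assigned by seeded label propagation on the cell-body mask — the
label-geodesic equivalent of drawing Voronoi boundary lines between
nuclei. ROIs of area ≤ 10 µm² (strictly) and ROIs touching the image
border are discarded. Transfection gating takes the mean + 3 SD of a
non-transfected control population as cutoff (the published wording
"mean ± 3 SD" can only mean the upper bound in a positivity context);
a z = 3 one-sided cutoff implies a 0.13% false-positive rate on
Gaussian controls, which the suite confirms on 10,000 simulated cells.
Intensities keep the 12-bit convention so manual cutoffs stay
comparable.

# Copy-number arithmetic

Pure unit-checked arithmetic: density per 100 µm² × membrane area gives
molecules per cell (25 → 375 at 1,500 µm²); a single tagged allele in a
pseudotriploid line under-reports threefold (→ 1,125); against a
proteomic total of 23,000 copies that is ~5% membrane-localized. An
Airy disc of 210 nm diameter covers 0.0346 µm² (0.035 at 2 s.f.), so
fluorescence convolves into a continuous haze around 100/0.035 ≈ 2,857 ≈
3,000 molecules per 100 µm² (1 s.f.) — two orders of magnitude above the
single-molecule regime. Rounding conventions (integer percent, 2 s.f.
areas, 1 s.f. crowding density) are fixed so the familiar approximate
figures are reproduced deterministically; raw values are always returned
alongside.

# Pipeline and reproducibility

`run_pipeline()` executes simulate → deconvolve → kinetics → spots →
ifquant from a single declarative config (YAML-serializable), with the
run seed fanned out to per-stage seeds by a fixed affine rule
(`derive_seed()`), so any stage can be re-run in isolation. Stages
communicate only through files (CSV, TIFF, JSON), reports carry a hash
of the config, and no report contains timestamps — identical configs
produce byte-identical reports. Figures are intentionally not part of
any contract.

# Study sizes

The validation studies use 5,000-spot histograms (20 seeds), 100
simulated traces for rate recovery, 200 simulations × 200 resamples for
CI coverage, 20 rendered frames for detection, and 10,000-cell draws
for gating rates — sizes at which the Monte-Carlo error is comfortably
inside each assertion's tolerance while the whole suite stays quick to
run.

# Known limitations

* The deconvolution assumes all spots are in focus and equally
  illuminated; field-dependent gain would smear every basis equally and
  bias toward higher apparent stoichiometry.
* Single-trace kinetic fits are ill-conditioned by design of the
  experiment (few points on the fast rise); report medians over traces,
  or fix the Hill coefficients if single-trace rates are needed.
* The spot detector is not a multi-emitter fitter; above ~50 spots per
  100 µm² undercounting from merging becomes material.
* Segmentation targets well-separated adherent cells; it has no notion
  of confluent sheets or 3D stacks.
* `bootstrap_ci` coverage was calibrated on the default scenario;
  strongly different noise regimes deserve their own calibration.
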