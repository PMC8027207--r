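---
title: "Quantifying quantum-dot tagged phosphorus in mycorrhizal networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying quantum-dot tagged phosphorus in mycorrhizal networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qdflux)
```

## The measurement problem

Arbuscular mycorrhizal fungi move mineral nutrients through shared hyphal
networks that can connect several host roots. When rock-phosphate apatite is
conjugated to quantum dots (QDs) of three emission colors and injected into
one compartment of a two-host in vitro system at three time points, the
distribution of each color at harvest reports where the fungus moved each
week's phosphorus. `qdflux` implements the quantification chain for this
design:

1. **Spectral unmixing** of plate-reader emission spectra into per-color QD
   amounts (autofluorescence plus three overlapping QD peaks).
2. **Phosphorus accounting**: QD amounts to P budgets (708 nmol P per nmol
   QD-apatite), percent of root P derived from tracer, young/established
   allocation ratios and hyphae/root retention ratios.
3. **RICS** (raster image correlation spectroscopy): particle number and
   diffusion coefficient from confocal image series, separating QD
   concentration in intraradical hyphae from root cells.
4. **Growth imaging**: root area fraction and growth rate from time-lapse
   plate images.
5. **Statistics**: variance-stabilizing transforms, per-timepoint Student's
   t tests on allocation ratios, assumption checks, mean ± SEM summaries.

Every stage is driven by a synthetic-data generator with recorded ground
truth, so the whole chain is testable by parameter recovery without any
external data.

## Spectral model and unmixing

A well spectrum on the fixed 450–800 nm grid (2 nm steps, 176 points) is
modeled as a nonnegative linear mixture

$$ y(\lambda) \;=\; a_{\mathrm{af}}\, S_{\mathrm{af}}(\lambda) \;+\;
   \sum_{i \in \{\mathrm{g,y,r}\}} q_i\, B_i\, S_i(\lambda) \;+\;
   \varepsilon(\lambda), $$

where the $S$ are unit-area reference shapes, $q_i$ is the nmol of color
$i$ in the well, $B_i$ its brightness (integrated counts per nmol at the
calibration gain) and $\varepsilon$ Poisson shot noise (the reader is a
photon counter). Unmixing solves $\min \lVert y - A c\rVert^2$ subject to
$c \ge 0$ by active-set nonnegative least squares: loadings are physical
amounts and cannot be negative. The unconstrained normal-equations solve is
retained as a debug/oracle mode; on interior solutions the two agree to
numerical precision, which the test suite asserts.

Choices worth knowing:

* **Reference shapes.** QD emission is modeled as Gaussian with default
  FWHM 30 nm (typical for CdSeS/ZnS nanocrystals) at peaks 488, 572 and
  666 nm; the autofluorescence reference is a broad log-normal-shaped curve
  peaking near 520 nm. Only the peak positions are fixed by the assay;
  widths and the autofluorescence shape are configuration.
* **Order of operations.** The default chain is background subtraction →
  unmixing → Savitzky–Golay smoothing of the reconstructed component
  curves → integration. Smoothing the raw spectrum *before* unmixing is
  available (`smooth_stage = "before"`); for analytic reference shapes the
  two differ negligibly, and smoothing is most useful when reference shapes
  are measured rather than parametric.
* **Negative counts.** Background subtraction clips at zero (counts are
  physical) and reports the clip count. Back-calculated concentrations are
  floored at zero *except* in the detection-limit workflow (below).
* **Calibration.** Photon counts vs the seven-point dilution series (13.1,
  9.83, 7.37, 5.53, 4.15, 3.11, 2.33 mM) are fit by ordinary least squares
  with a free intercept (forced-through-origin by flag). With mM = nmol/µL,
  concentration × well volume (µL) is directly nmol; the assay convention
  of 150 µL buffer per mg dry tissue ties per-well nmol to per-mg amounts.

### Detection limit

The limit of detection is the classic three-sigma blank criterion: the
smallest per-mg amount whose calibrated estimate exceeds the blank mean
plus three blank standard deviations; by linearity of the calibrated
estimator this equals $3\,\sigma_{\mathrm{blank}}$ in amount units. Two
practical points. First, the blank ensemble must keep its spread, so the
detection-limit workflow uses signed (unfloored) calibrated estimates —
flooring at zero would collapse the blank variance whenever the calibration
intercept draw is positive and make the limit degenerate. Second, the
calibration intercept, fitted at mM signal levels, is many orders of
magnitude above femtomole signals; it shifts all blank estimates equally
and therefore cancels from the 3-sigma spread.

Under the default synthetic noise model (autofluorescence of $5\times10^4$
integrated counts per blank well, brightness $5\times10^9$ counts per nmol,
Poisson noise, five replicate wells averaged per sample), the green-channel
limit lands near 0.02 fmol per mg — comfortably inside the sub-femtomole
regime this assay is valued for. `scripts/acceptance.R` recomputes it from
scratch (100 seeds) and verifies it by downward titration.

## Phosphorus accounting

`qd_to_p()` applies the fixed conjugation stoichiometry (708 nmol P per
nmol QD-apatite, configurable for other chemistries);
`percent_p_from_qd()` divides tracer-derived P by total root P.
`allocation_ratio()` computes the young/established amount ratio *within a
plate*, which cancels plate-level multipliers such as extraction
efficiency; plates missing one member of the pair, or with a zero
established amount, are excluded and counted rather than propagated as
infinities — mirroring how damaged plates drop out of a real harvest.
`retention_ratio()` is the hyphae/root concentration ratio per biovolume
from the RICS fits; a value near 1 means equal tracer density in the two
tissue types. The qPCR and absorbance converters are generic standard-curve
inversions; the qPCR curve constants are required configuration because no
universal values exist, and the internal-standard correction multiplies by
expected/observed spike copies.

One known accounting caveat: per-mg root amounts include intraradical
fungal biomass in the denominator; no correction for fungal mass is
applied.

## RICS: model, simulator, conventions

The scan configuration mirrors the acquisition: 256 × 256 frames of 16 nm
pixels (a 4.096 µm field), 20 µs pixel dwell, 1.25 ms line time. The
correlation model fit to the spatial ACF is the standard 3D-diffusion RICS
surface

$$ G(\xi,\psi) = \frac{\gamma}{N}
   \left(1+\frac{4D\tau}{w_0^2}\right)^{-1}
   \left(1+\frac{4D\tau}{w_z^2}\right)^{-1/2}
   \exp\!\left(-\frac{\delta r^2(\xi^2+\psi^2)/w_0^2}
        {1+4D\tau/w_0^2}\right),
   \qquad \tau = \tau_p|\xi| + \tau_l|\psi|, $$

with $\delta r$ the pixel size, $\tau_p$ the dwell, $\tau_l$ the line
time, $\gamma = 2^{-3/2}$ and $(w_0, w_z)$ the PSF waists. The zero lag is
excluded (uncorrelated shot noise inflates it); lags are restricted to
$|\xi| \le 32$, $|\psi| \le 8$ by default — lateral lags carry the fast
dwell-time decorrelation. Weights are inverse across-frame variance when at
least 10 frames contribute. An additive baseline $G_\infty$ is fitted
alongside $G_0$ and $D$: per-frame mean subtraction biases the measured
ACF downward by a constant of order $G_0$ times the speckle-to-frame area
ratio (a few percent at 256², tens of percent on small frames), and the
baseline absorbs it. The ACF itself is computed per frame with mean
subtraction, via zero-padded FFTs normalized by the number of non-wrapping
pixel pairs; the test suite pins it to a brute-force double loop at 1e-10
on small images.

**Timing convention.** The stated line time (1.25 ms) is shorter than 256
pixels × 20 µs of dwell, so a literal per-pixel timeline is not
self-consistent. The package treats the line time as the interval between
line starts — the clock for particle motion across lines — while the pixel
dwell enters only the correlation model's lag time and the shot-noise
integration. These are independent configuration values.

**Amplitude convention.** For a 3D Gaussian PSF the zero-lag amplitude is
exactly $G(0) = 1/(c\,\pi^{3/2} w_0^2 w_z)$ for particle concentration
$c$. The fitted $N = \gamma/G_0$ therefore estimates the particle count in
the *γ-weighted* observation volume $\gamma\,\pi^{3/2} w_0^2 w_z$, and
that is the quantity the simulator records as ground truth.
`particles_to_concentration()` reports $C = N/(V_{\mathrm{eff}} N_A)$ with
$V_{\mathrm{eff}} = \pi^{3/2} w_0^2 w_z$; any fixed volume convention
cancels from hyphae/root *ratios*, which are the quantity of scientific
interest here.

**PSF waists.** The acquisition metadata do not determine the waists; the
defaults ($w_0 = 0.25$ µm, $w_z = 3 w_0$, plausible for a high-NA water
objective with 405 nm excitation) are documented estimates, and all
recovery claims are against synthetic ground truth generated with the same
configured waists.

**The Brownian simulator** places particles uniformly in a periodic box at
least 4 waists wide per dimension (laterally never smaller than the
scanned field, axially $4 w_z$), advances them by Euler–Maruyama steps on
the raster-line clock, and integrates a 3D Gaussian PSF per pixel with
Poisson counts. One update per line is the default: at the stated timing
and $D = 1$ µm²/s the rms step per line is 50 nm, a fifth of the lateral
waist, so sub-line motion is negligible; `substeps_per_line` refines the
cadence for oracle runs, and the suite checks that fitted $D$ agrees
between one step per line and 10× finer stepping. Recovery at the study's
conditions ($N = 20$, $D = 1$ µm²/s, 50 frames, standard scan) is within
20 % for both parameters (median over 20 seeds); with the fitted baseline
the residual biases are at the few-percent level (background offset
dilutes the relative fluctuations slightly; the update cadence shaves a
few percent off $D$), well inside the acceptance band.

## Growth imaging

Frames are thresholded by Otsu's method on the gel-masked histogram with
automatic polarity: the minority class is taken as root, which is invariant
to inverting the intensities (dark-field polarity is not guaranteed).
Area fraction is root pixels over gel pixels; multiplied by the gel area in
mm² it feeds a centered-moving-average smoother (12 frames = 24 h at the
2 h cadence) and a central-difference derivative, giving rates in mm²/h.
The synthetic generator plants a filled disk of known radius, so the area
estimate can be checked against $\pi r^2$ within pixelization error
(relative error ≲ 2 px / r px).

## Statistics

The headline contrast — does the young root in the low-P treatment receive
a larger share of the most recent injection? — is a per-timepoint
two-sample Student's t test (pooled variance by default, Welch by flag) on
square-root-transformed young/established ratios, one test per injection
color, reported uncorrected as three separate tests with a clearly labeled
Bonferroni column alongside. Amounts and their ratios are right-skewed,
hence the sqrt transform for amounts/ratios and log for retention ratios;
log excludes non-positive values with a count. Shapiro–Wilk (per group)
and Brown–Forsythe/Levene (across groups) checks are provided. Linear
mixed-effects modeling (plate as a random effect) is deliberately not
reimplemented: the within-plate ratio construction already absorbs the
plate pairing for the per-timepoint contrast, and standard mixed-model
software covers the rest.

## The synthetic experiment generator

`allocation_model()` fixes the study conditions the statistics are
validated under:

| parameter | default | meaning |
|---|---|---|
| `baseline_transfer_young` | 0.85 | expected young/established ratio away from the interaction cell (young roots carry ~15 % less tracer) |
| `treatment_time_effect` | +0.5 | added to the ratio only in the (low-P, 7-day red) cell — the interaction emerging at the third injection |
| `hyphal_retention_control` | 0.9 | hyphae/root per-biovolume ratio, slightly below one |
| `hyphal_retention_lowP_young_late` | 0.45 | retention in the late low-P young cell (more transfer, less storage) |
| `noise_cv` | 0.3 | lognormal plate-to-plate CV, a typical biological replicate spread |
| `n_plates_per_treatment` | 24 | plates per arm |
| `established_mean_nmol_per_mg` | 1.7e-3 | per-color tracer in the established root |
| `total_p_mean_nmol_per_mg` | 65 | total P per mg root, all sources |

The amount scales are chosen so the derived percent-of-P-from-tracer lands
in the mid-single-digit percent range when summed over the three colors,
the regime the assay operates in. Noise is multiplicative lognormal with
mean one (amounts are positive and right-skewed); `noise_cv = 0`
reproduces ground truth exactly, which the tests assert for every derived
quantity. Under the defaults, the per-timepoint test holds its nominal
size on null data (type-I error 0.05 ± 0.02 over 1000 seeds) and detects
the planted third-injection effect with power ≥ 0.8 at 24
plates/treatment.

What the generator does *not* emulate: apatite dissolution and endocytic
uptake kinetics (allocation is phenomenological), hyphal network topology,
correlated measurement error between compartments of a plate, or
instrument drift. Passing tests therefore demonstrate that the
quantification chain is correct and well calibrated under the stated noise
model — not that the biological effect sizes themselves generalize.

## Problem sizes and numerical choices

The validation suites run at deliberate scales: unmixing recovery at 100
seeds; detection limit at 24 blank samples × 5 wells (100 seeds in the
acceptance script); RICS recovery at 20 seeds × 50 frames of 256²; the
amplitude–number product on 128² frames over $N \in \{5, 20, 100\}$;
t-test size and power at 1000 and 500 seeds. Poisson draws above $10^7$
expected counts use a Gaussian approximation (relative error < 1e-3).
The NNLS solve is performed on a max-normalized spectrum (the active-set
solver is scale-sensitive at calibration-gain counts) and rescaled, which
is exact by linearity. Model fits use Levenberg–Marquardt with multiple
diffusion starts and box constraints at zero; non-convergence across all
starts is an error, never a silent fallback.

## Known limitations

* Calibration at mM scale with a free intercept makes *absolute*
  femtomole-scale estimates carry an intercept-sized offset; ratio and
  detection-limit statistics are unaffected, and forced-through-origin
  calibration is available where absolute trace quantities matter.
* The RICS concentration is convention-dependent (see above); use ratios
  across tissue types for interpretation.
* Per-line Brownian updates slightly underestimate within-line
  decorrelation; the effect on fitted $D$ is a few percent at the default
  timing and vanishes with `substeps_per_line`.
* The growth binarizer assumes roots are the minority class within the
  gel; a plate overgrown past 50 % coverage would flip the polarity
  heuristic.
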