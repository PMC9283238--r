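---
title: "Methods: colocalized bone-quality analysis in bonequal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalized bone-quality analysis in bonequal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bonequal` implements the analysis layer of a colocalized bone-quality
experiment: Raman spectroscopy and nanoindentation performed at the same
tissue locations (periosteal points between fluorochrome labels, and
perilacunar points at 1, 3, 5 and 7 µm from osteocyte lacunar walls),
plus quantitative backscattered electron imaging (QBEI) of the same
specimens, compared across three animal groups — control (CTRL), chronic
kidney disease (CKD) and calcimimetic-treated CKD (CKD_KP). This vignette
documents the models, the tunable parameters, the numerical choices, and
what the synthetic-data validation does and does not demonstrate.

```{r setup}
library(bonequal)
```

## Raman compositional parameters

A raw spectrum traverses a fixed state machine,
`raw → baselined → despiked → smoothed`, and the three bone-quality
parameters are computed from the smoothed result:

* **mineral-to-matrix ratio (MMR)** — ν1-phosphate band area / Amide I
  band area;
* **type B carbonate substitution** — ν1-carbonate area / ν1-phosphate
  area;
* **crystallinity** — 1 / FWHM (in cm) of a Gaussian fitted to the
  ν1-phosphate band, so `crystallinity * fwhm_phosphate == 1` by
  construction.

Default band windows are the standard bone-Raman choices: ν1-PO₄³⁻
930–980 cm⁻¹, ν1-CO₃²⁻ 1050–1100 cm⁻¹, Amide I 1620–1700 cm⁻¹. All are
configurable per analysis.

**Baseline.** An 11th-order polynomial is fitted to the fluorescence
background. A single least-squares pass through a spectrum is pulled up
by the bands, so the fit iterates: points more than 2 robust (MAD)
standard deviations above the current fit are excluded, the polynomial is
refitted, and the loop stops on convergence (relative baseline change
below 10⁻⁴ of the intensity range) or after 20 passes. The polynomial is
evaluated in an orthogonal basis; order 11 on a 1000-point grid is
numerically unproblematic there.

**Cosmic rays.** Spikes are detected in the second difference of the
intensity (threshold: 8 × the median absolute second difference, with a
small relative floor so that exactly-flat spectra do not flag their own
floating-point band tails). Candidate runs longer than four points are
genuine bands and are left alone — a band three or more grid points wide
always produces a long curvature run — and within short runs only points
that stand off the local chord are replaced, by linear interpolation from
their unflagged neighbours. The operation is idempotent.

**Smoothing.** Standard Savitzky–Golay filtering (default window 11 grid
points, polynomial order 4) behind a named `method` switch. The
instrument-software description this stage emulates ("modified
Savitzky-Golay with maximum-likelihood estimation") does not correspond
to a uniquely defined published algorithm, so the package implements the
standard filter and keeps the strategy switch so a variant can be added
without touching the pipeline; results in this package therefore
characterise the classical filter. Its variance-reduction factor for
white noise is exposed as `sg_variance_factor()` and is verified by
Monte Carlo in the test suite.

**Band areas.** Trapezoidal integration over the band window. A local
linear baseline through the window endpoints is available
(`local_baseline = TRUE`) but is **off by default**: the chord clips the
band tails wherever they approach the window edge, which biases areas by
3–6 % at physiological phosphate widths (FWHM 18–20 cm⁻¹ inside a
50 cm⁻¹ window), while the global polynomial baseline already leaves the
off-peak mean at zero. Enable the chord only for spectra with residual
background curvature that the global fit cannot capture.

**Known limitation.** With the default 930–980 cm⁻¹ window, phosphate
bands wider than ≈25 cm⁻¹ FWHM are truncated and their windowed area is
biased low by more than 3 %; such tissue requires a wider configured
window. The recovery grid used in validation therefore spans FWHM
12–24 cm⁻¹, the physiological range for bone.

## Oliver–Pharr nanoindentation

Indents are load-controlled: ramp to Pmax = 1000 µN, 45 s hold, unload.
`segment_curve()` finds the phase boundaries from the load plateau
(tolerance as a fraction of peak load; the hold ends at the last sample
still at the plateau, which is robust to load noise at the corners).

Stiffness comes from the power law *P = α(h − h_f)^m* fitted to the
95–40 % portion of the unloading branch, with *S = dP/dh* evaluated at
the peak displacement. Two numerical choices matter:

* the regression is performed as *h = h_f + (P/α)^{1/m}* — in a
  load-controlled indent the noise lives in the displacement channel, and
  regressing the noisy displacement as the predictor attenuates the
  fitted slope (the classical errors-in-variables bias, up to tens of
  percent at 0.5 % displacement noise);
* the peak displacement used for the derivative is the fitted curve
  evaluated at Pmax, which equals the observed maximum for clean data but
  does not inherit the positive bias of `max()` over noisy samples.

A `method = "secant"` switch reports the straight-line 95–40 % slope
instead, for comparison with analyses that used a secant convention.

Then, with ε = 0.75 and β = 1 (the standard spherical/paraboloid
values; the probe is a 1.03 µm radius sphere):

* contact depth `h_c = h_max − ε Pmax / S`;
* spherical contact area `A = π(2 R h_c − h_c²)`;
* reduced modulus `E_r = (1/β)(√π/2) S/√A`;
* hardness `H = Pmax / A`, so `H · A = Pmax` holds exactly.

**Known limitation.** At deep contacts (hardness ≈ 0.4 GPa puts
h_c ≈ 500 nm, half the probe radius, with stiff tissue) the 95–40 %
unloading span shrinks to tens of nanometres. Against 0.5 %-of-peak
displacement noise the exponent *m* and intercept *h_f* become jointly
unidentifiable, and since nonlinear least squares is the Gaussian
maximum-likelihood estimator here, the resulting ≈10 % modulus scatter is
close to the information bound rather than an implementation defect;
hardness is unaffected (it depends on the much better-determined contact
depth). The validation suite asserts < 5 % median recovery error on the
well-conditioned property cells and < 10 % on the two deep-contact cells.
No thermal-drift or creep-compliance correction is applied.

## QBEI and the bone mineral density distribution

Gray levels are standardised against carbon (25 ± 1) and aluminium
(225 ± 1) imaging standards; `check_standards()` applies exactly that
acceptance rule. Calcium content is affine in gray level. The anchors —
carbon gray ↔ 0 wt% Ca and aluminium gray ↔ 39.86 wt% Ca (the calcium
mass fraction of pure hydroxyapatite, the conventional upper anchor) —
are package conventions, overridable in `gray_calibration()`; synthetic
validation uses the same mapping for generation and analysis, so its
conclusions do not depend on the anchor truth.

The BMDD is the histogram of ROI calcium values at the native resolution
of one 8-bit gray step per bin (no re-binning), summarised by CaMean
(weighted mean), CaPeak (modal bin centre) and CaWidth (FWHM by linear
interpolation between the bins crossing half of the modal frequency).
Single-gray-level ROIs report one bin width with a degeneracy flag.
Regions of interest are supplied as explicit mask images; registration
against fluorescence images is out of scope. PNG and TIFF images are
supported (no installed reader exists for BMP; synthetic studies write
PNG).

## Statistics

**Periosteal layer.** Measurement values are averaged to one value per
specimen per parameter. Each parameter is routed by a Shapiro–Wilk gate
(parametric only if p ≥ 0.05 in every group) to one-way ANOVA with Tukey
HSD, or to Kruskal–Wallis. Note the gate's family behaviour: with a
0.05-level test per group, three truly normal groups pass all three
gates only ≈ 0.95³ ≈ 86 % of the time.

**Perilacunar layer.** Pooled samples (144 per group per distance under
the default design: 6 animals × 6 lacunae × 4 directions) are compared
pairwise per parameter and distance with two-sample Kolmogorov–Smirnov
(asymptotic p) and Anderson–Darling tests at the Bonferroni-adjusted
level 0.05/3 ≈ 0.0167. A shift is called **significant only when both
tests reject** (a conservative conjunction; `rule = "either"` is
available), and the significant sample with the larger median is
reported as *right-shifted*. Median ties yield direction `none` with a
tie flag.

The two-sample Anderson–Darling test is implemented in the package (no
installed R package provides it): the tie-adjusted midrank statistic,
its exact finite-sample null standard deviation, and a p-value by
monotone interpolation of the published critical surface of the
standardised statistic. A permutation p-value (fixed seed) is available
and agrees with the asymptotic one to within 0.02 in the validated
regime (n = 144). Monte-Carlo false-positive rates at α = 0.0167 with
n = 144 are ≈ 0.017 ± 0.01 for both tests, and the conjunction rule is
conservative by construction.

Lacuna-within-animal nesting is not modelled (no mixed effects): the
perilacunar layer pools 144 points per group per distance exactly as the
study design it reproduces, and this pseudo-replication caveat applies
equally to any conclusion drawn from it.

## Synthetic data: what it emulates, and what it does not

`generate_spectrum()` builds Gaussian bands (phosphate at 959 cm⁻¹ with
the requested FWHM; carbonate at 1073 cm⁻¹, FWHM 16; Amide I at
1660 cm⁻¹, FWHM 24 — centres and widths chosen so the fixed bands sit
more than 3σ inside their default windows, making windowed areas
unbiased), a cubic fluorescence-like background scaled to the phosphate
peak, optional cosmic spikes, and multiplicative Gaussian noise (default
1 %). `generate_indent_curve()` derives (A, h_c, S, h_max) from the
target (E_r, H) so the noiseless Oliver–Pharr analysis recovers the
targets exactly; the loading branch is a 3/2-power law scaled through
the peak point (a literal elastic Hertz constant would be discontinuous
with the plastic depth fixed by H), the hold creeps logarithmically at
constant load, the unloading branch is the anchored power law, and
sampling is at 100 Hz, the realistic acquisition rate for
load-controlled nanoindenters. `generate_bse_image()` quantises a
Gaussian calcium field through the inverse gray calibration into a
horizontal "new bone" band (the ROI) over a resin-level background.

`generate_study()` reproduces the full design — 12 periosteal animals
per group × 8 colocalized points, 6 perilacunar animals × 6 lacunae × 4
directions × 4 distances (= 144 per group per distance), one image per
perilacunar animal — at two fidelity levels. `"raw"` writes every signal
to disk in the reader formats; `"parameters"` returns the
per-measurement parameter draws directly. The parameter level exists
because large Monte-Carlo designs (e.g. 50-study null-soundness runs)
test the design and statistics layers, for which re-synthesising ~4600
raw signals per study would add two orders of magnitude of cost while
the signal chain's fidelity is already pinned by the roundtrip checks.
Group ground-truth means and SDs are configuration placeholders encoding
qualitative effect directions (CKD: lower carbonate, lower E_r and H;
treated CKD: higher crystallinity and MMR, lower carbonate, mechanics
near control) at plausible rat-cortical-bone magnitudes; the study being
emulated published its group results only as figures, so no numeric
means were available to copy. Perilacunar distance effects default to
zero and can be set per distance (piecewise offsets, not a parametric
curve in distance).

What passing synthetic validation does **not** show about real data: the
generator's bands are pure Gaussians matched to the analyzer's model (no
band overlap, no Voigt broadening, no instrument response); indentation
noise is white (no drift, no creep-compliance error); calcium fields are
spatially uncorrelated; and measurement values are drawn independently
(no lacuna- or animal-level random effects). Recovery and level results
are therefore statements about the pipeline's correctness, not about
instrument physics.

## Reproducibility and problem sizes

All generators consume a single RNG stream from an explicit seed; full
study generation is bit-reproducible, and `run_pipeline()` is
deterministic for identical inputs (byte-identical CSVs on rerun,
verified in the suite). The validation suite uses: 27 noiseless and
12 × 50 noisy spectra for Raman recovery (FWHM 12–24 cm⁻¹); a 3 × 3
property grid (noiseless, plus 50 noisy repeats per cell) for
indentation; 10⁵-pixel images for BMDD closed forms; 2000 null
replicates at n = 144 for test levels; and 50 zero-effect studies at the
full 144-per-cell design for end-to-end null soundness. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances.
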