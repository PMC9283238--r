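# bonequal

Colocalized bone-quality analysis: Raman spectroscopy, Oliver–Pharr
nanoindentation, and quantitative backscattered electron imaging (QBEI),
with the group and distribution statistics used to compare bone tissue
across animal groups (e.g. control vs chronic kidney disease vs treated
disease).

## Who this is for

Skeletal-tissue researchers who acquire Raman spectra, nanoindentation
load–displacement records and calibrated backscatter images at matched
locations — periosteal points between fluorochrome labels, or
perilacunar points at fixed distances (1, 3, 5, 7 µm) from osteocyte
lacunae — and need a tested, reproducible path from raw signals to
group-level conclusions. Every stage is validated against synthetic data
with known ground truth, so the pipeline can be trusted (and audited)
without access to the original instruments.

## What it computes

**Raman composition** (`process_spectrum`): from a raw spectrum via
11th-order polynomial baseline correction (iterative peak exclusion),
cosmic-ray removal, and Savitzky–Golay smoothing to

- mineral-to-matrix ratio `MMR = A(ν1-PO₄³⁻) / A(Amide I)`,
- type B carbonate substitution `A(ν1-CO₃²⁻) / A(ν1-PO₄³⁻)`,
- crystallinity `1 / FWHM` of a Gaussian fitted to ν1-PO₄³⁻.

**Nanoindentation mechanics** (`analyze_indent`): Oliver–Pharr analysis
of load-controlled indents (1000 µN peak, 45 s hold). Stiffness *S* from
a power-law fit `P = α(h − h_f)^m` to the 95–40 % unloading region,
contact depth `h_c = h_max − ε·P_max/S`, spherical contact area
`A = π(2Rh_c − h_c²)` for the 1.03 µm probe, and

    E_r = (1/β) · (√π / 2) · S / √A        H = P_max / A

**QBEI / BMDD** (`compute_bmdd`): gray levels calibrated against carbon
(25 ± 1) and aluminium (225 ± 1) standards, mapped affinely to calcium
wt%, and summarised as CaMean, CaPeak and CaWidth (FWHM) of the bone
mineral density distribution.

**Statistics** (`periosteal_tests`, `perilacunar_shifts`): per-specimen
group comparisons (Shapiro–Wilk gate → ANOVA + Tukey HSD or
Kruskal–Wallis), and pooled distribution-shift tests per parameter ×
lacunar distance: two-sample Kolmogorov–Smirnov *and* Anderson–Darling
at the Bonferroni level 0.05/3 ≈ 0.0167, a shift being called only when
both reject, directed toward the larger median ("right-shifted").

**Synthetic data** (`generate_spectrum`, `generate_indent_curve`,
`generate_bse_image`, `generate_study`): forward models with known
ground truth reproducing the full three-group design (12 periosteal
animals × 8 points; 6 perilacunar animals × 6 lacunae × 4 directions ×
4 distances = 144 points per group per distance), written to disk in the
package's reader formats or returned in memory.

## Worked example

```r
library(bonequal)

# a synthetic spectrum with known truth, through the full chain
s <- generate_spectrum(mmr = 3, carbonate = 0.15, fwhm = 18,
                       noise = 0.01, seed = 42)
process_spectrum(s)
#> <raman_parameters> MMR 3.012 | carbonate 0.1514 | crystallinity 0.05537 cm (FWHM 18.06 cm^-1)

# an indent with known mechanics, through Oliver-Pharr
cv <- generate_indent_curve(Er_true = 20, H_true = 0.7,
                            noise = 0.005, seed = 42)
analyze_indent(cv)
#> <indent_result> Er 20.11 GPa | H 0.700 GPa | S 27.126 uN/nm | hc 251.5 nm | A 1.4291 um^2

# a calibrated backscatter image, through the BMDD
compute_bmdd(generate_bse_image(22, 2, seed = 42))
#> <bmdd_metrics> CaMean 21.99 | CaPeak 22.32 | CaWidth 4.65 wt% (80000 px)

# a full three-group study and its perilacunar shift table
st <- generate_study(study_config(seed = 42), level = "parameters")
sh <- perilacunar_shifts(st$perilacunar, c("carbonate", "Er"))
head(sh[, c("parameter", "distance_um", "group_a", "group_b",
            "ks_p", "ad_p", "significant", "direction")])
#>   parameter distance_um group_a group_b     ks_p     ad_p significant direction
#> 1 carbonate           1    CTRL     CKD 4.04e-04 9.23e-06        TRUE      CTRL
#> 2 carbonate           1    CTRL  CKD_KP 5.78e-14 3.79e-19        TRUE      CTRL
#> 3 carbonate           1     CKD  CKD_KP 1.49e-04 9.12e-07        TRUE       CKD
#> 4 carbonate           3    CTRL     CKD 1.04e-03 1.48e-04        TRUE      CTRL
#> 5 carbonate           3    CTRL  CKD_KP 8.87e-13 1.72e-19        TRUE      CTRL
#> 6 carbonate           3     CKD  CKD_KP 5.30e-06 2.34e-08        TRUE       CKD
```

The recovered parameters sit within a percent of the generating truth
(MMR 3.012 vs 3, E_r 20.11 vs 20 GPa, CaMean 21.99 vs 22 wt%), and the
shift table reads as its laboratory counterpart would: here the
configured carbonate-lowering treatment effect is detected at every
distance, with the lower-carbonate group on the left of the
"right-shifted" direction column.

File-based workflows use `generate_study(..., level = "raw")` +
`run_pipeline(study_dir, out_dir)`, which write and read the plain-text
formats described in the function documentation, or the thin CLI in
`inst/scripts/bonequal-cli.R` (`simulate`, `run-all`).

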