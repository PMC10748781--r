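# airaqua

Targeted absolute quantification for 1D ¹H NMR spectra of complex samples
with broad background signals — the kind of minimally prepared extracts
(plant root exudates, biofluids) where sharp metabolite signals ride on
broad macromolecular humps and an irregular baseline. `airaqua` is aimed at
NMR metabolomics practitioners who have a curated signal library and want
automated, reproducible concentrations out of binned spectra.

## What it does

The workflow joins two pieces:

**1. airPLS baseline correction.** The baseline `z` of a spectrum `x` is
fitted by adaptive iteratively reweighted penalized least squares on a
Whittaker smoother,

    minimise  Σ wᵢ (xᵢ − zᵢ)² + λ Σ (Δ² z)ᵢ²,

solved via the sparse banded system `(W + λ DᵀD) z = W x`. Iterating,
points above the running baseline lose their weight (`w = 0`), points below
it are up-weighted (`w = exp(t·|d|/dssn)`), so peaks stop attracting the
fit and only the smooth background remains. The stiffness λ (default 1e7,
range 1–1e9) can be overridden per spectral region
(`region_lambda_map()`), with local fits stitched in by linear crossfade.

**2. AQuA quantification.** Each metabolite is modelled as a sum of
Lorentzians with one pre-selected *reporter signal*; concentrations come
from reporter heights through the interference system

    A c = h / scale,   A[m,k] = model of entry k at entry m's picked position,

where each entry's model is translated by its own picked offset (position
alignment) and `scale` is calibrated from the internal-standard singlet
(DSS at 0 ppm, 0.29 mM). Unknown interfering signals are carried in the
solve but suppressed from reports. Results are flagged (`negative`,
`edge`, `high_interference`, `below_loq`).

Around the core sit the study tools: a background-extraction algorithm
(spike detection → linear depletion → three smoothing levels → background
models A/B/C), a simulation study (backgrounds × scaling levels × λ values,
regression of corrected on true heights, R² < 0.9900 flagging), a spike-in
study (matrix arm vs blank arm regression with relative intercepts and
percent differences), and seeded synthetic-data generators for all of it.

## Worked example

Quantify a synthetic root-exudate-like spectrum (24-metabolite panel, four
unknown signals near 0.93–0.97 ppm, broad background, noise) on the
canonical 51 000-bin axis:

```r
library(airaqua)
axis <- default_axis()                       # -0.50..4.68 + 4.98..10.00 ppm
lib <- exudate_panel_library(seed = 1)       # 24 targets + 4 unknowns + DSS
set.seed(99)
truth <- setNames(runif(length(library_names(lib)), 0.1, 1),
                  library_names(lib))        # mM
spec <- synth_exudate_spectrum(
  lib, axis, concentrations = truth,
  background = synth_broad_background(axis, amplitude = 1, seed = 3),
  noise_sd = 0.002, seed = 3)
map <- region_lambda_map(regions = data.frame(
  start_ppm = 0.899, end_ppm = 0.967, lam = 1e6))
res <- extended_aqua(spec, lib, map)
res
```

```
<aqua_result> 24 target(s), scale = 0.9862, condition ~ 6.9
      metabolite concentration_uM  height picked_ppm  offset_ppm flags
1        leucine           555.06 0.52561     0.9601  1.1102e-16
2     isoleucine           197.89 0.20592     1.0043  0.0000e+00
3         valine           716.67 0.86668     1.0343  0.0000e+00
4      threonine           998.42 1.52619     1.3193  0.0000e+00
...
23  fumaric_acid           872.21 1.10661     6.5201  0.0000e+00
24   formic_acid           659.12 0.52846     8.4601  0.0000e+00
```

`concentration_uM` is the absolute concentration per metabolite; `height`
and `picked_ppm` document the reporter signal the number came from, and
`offset_ppm` the position alignment that was applied. Against the known
truth this run recovers concentrations with a median absolute error of
1.4% (worst case 11% for a reporter sitting on the strongest background).
The baseline diagnostics (`attr(res, "correction")`), the solved
interferents (`attr(res, "all_entries")`), and the calibration scale are
attached as attributes.

A thin command-line front end is shipped as `inst/scripts/aqua.R`
(`correct`, `quantify`, `backgrounds`, `simulate`, `spikein`, `synth`
subcommands over the same functions, YAML-configurable).

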