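---
title: "Baseline-corrected one-signal quantification for 1D 1H NMR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline-corrected one-signal quantification for 1D 1H NMR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airaqua)
```

## The problem

Minimally prepared biological extracts — plant root exudates are the
motivating case — give 1D ^1^H NMR spectra in which sharp metabolite signals
sit on broad, irregular background signals, most prominently in the
low-frequency (aliphatic) part of the spectrum. Targeted quantification from
such spectra needs two things: a baseline estimate that removes the broad
background without touching the sharp signals, and a quantification model
that converts signal heights into absolute concentrations while correcting
for overlap between neighbouring signals.

`airaqua` implements that workflow end to end:

1. **Baseline correction** by adaptive iteratively reweighted penalized
   least squares (airPLS) on a sparse Whittaker smoother, with
   region-specific stiffness.
2. **Quantification** from the height of one pre-selected *reporter signal*
   per metabolite, solved through a linear interference system built from a
   Lorentzian signal library, calibrated absolutely against an internal
   standard of known concentration (a DSS-type singlet at 0 ppm, 0.29 mM by
   default).
3. **Evaluation machinery**: a background-extraction algorithm that turns a
   measured spectrum into smooth background models, a simulation study
   (backgrounds × scaling levels × stiffness values), and a spike-in study
   comparing a matrix arm against a blank arm by regression.

## Spectra and axes

Spectra are uniformly binned intensity vectors on a segmented ppm axis.
The canonical layout is two segments, −0.50–4.68 ppm and 4.98–10.00 ppm at
0.0002 ppm/bin (51 000 bins at 600 MHz); the 4.68–4.98 ppm water region is
a true gap, not zero-filled bins, so baseline fitting never bridges the
solvent artefact. Bins are half-open `[lo, hi)` intervals anchored at the
segment start; storage order is ascending ppm. Conversion between ppm and
Hz always goes through the spectrometer frequency (`Hz = ppm × MHz`), and
linewidths are stored in Hz so that libraries transfer across field
strengths.

Line-shape quality is checked with `measure_fwhm()`: the apex is the
maximal bin in a window and the two half-height crossings are located by
linear interpolation between adjacent bins. At 0.0002 ppm/bin this carries
a small convexity bias (≈ +0.1% on a 1.2 Hz Lorentzian), so the pass/fail
gate compares at the threshold's printed precision (0.01 Hz) — a line
rendered exactly at the 1.20 Hz threshold passes.

## The Whittaker smoother and airPLS

`whittaker_smooth(x, w, lam, order)` returns the minimiser of

$$ \sum_i w_i (x_i - z_i)^2 \;+\; \lambda \sum_i (\Delta^d z)_i^2 , $$

solved through the banded normal equations `(W + λ DᵀD) z = W x` with a
sparse Cholesky factorisation — linear time and memory in the spectrum
length, which matters at 51 000 bins. With `order = 2` straight lines incur
no penalty, so the smoother's stiffness scale is roughly `λ^(1/4)` bins.

`airpls_fit()` iterates the smoother: at iteration *t* the residual
`d = x − z` is split at zero; the negative mass `dssn = |Σ d⁻|` drives both
termination (`dssn < 0.001 Σ|x|`, the published rule; a flat residual
also terminates) and reweighting (`w = 0` above the baseline,
`w = exp(t·|d|/dssn)` below it). Points above the running baseline are
thereby excluded, so peaks do not attract the fit. Defaults are the
published ones: `λ = 1e7` (valid range 1–1e9), `order = 2`, weight
exception proportion `wep = 0.1`, asymmetry parameter `p_asym = 0.05`,
`itermax = 20`.

**The endpoint exception.** The roles of `wep` and `p_asym` are not fully
specified in the source algorithm's description; this package implements
them as an endpoint anchor: the first and last `⌈wep·n⌉` points of each
fitted stretch never receive zero weight — at each reweighting they get
`max(exponential weight, p_asym)`. This stabilises the baseline ends
(order-2 extrapolation is otherwise unconstrained there) at a measurable
price: a tall signal inside the endpoint zone is never fully excluded from
the fit, so the baseline rides slightly into it. The 0-ppm internal
standard sits inside the first 10% of the low-field segment, which makes
the intensity calibration ≈1.4% low on otherwise baseline-free spectra;
reporters in the first/last 10% of a segment (e.g. anomeric sugar signals
just above the water gap) lose a few percent of height the same way. This
is the dominant accuracy floor of the full pipeline on clean spectra (see
*Accuracy floors* below).

**Stiffness choice.** A too-large λ leaves background under the signals; a
too-small λ lets the baseline climb into them — in the extreme (λ of order
10, wide lines) the first smooth already hugs the signal and correction
removes it entirely. λ is therefore a per-region choice:
`region_lambda_map()` holds a default plus local overrides; each local
region is re-fitted on the region extended by `blend_margin_bins`
(default 25) and stitched in with a linear crossfade over the margin, which
avoids baseline steps at region edges. A local region whose λ equals the
default is skipped — a genuine subwindow refit differs through its own
endpoint handling even at the same stiffness, and the intent of an
identical λ is "no override". Regions may not span the water gap.

## The signal library and the interference solve

Every metabolite is a sum of Lorentzian components
`h·γ²/((δ−δ₀)²+γ²)` with `γ = fwhm/2`; J-coupled multiplets are explicit
component lists (binomial-like height patterns), not a coupling simulator.
One reporter position per entry carries quantification; its model value per
1 mM is the entry's *unit response*, validated against the rendered model
to 0.1% whenever a library is built or loaded. Entries are `target`
(reported) or `interferent` (solved for, suppressed from reports — unknown
signals included only to protect their neighbours' accuracy).

Quantification proceeds in four steps:

1. **Calibrate**: the internal-standard singlet is picked and
   `scale = height / (known mM × unit response)` maps spectrum intensities
   onto library intensities. Multiplying a spectrum by any factor moves
   `scale` by the same factor, which is what makes reported concentrations
   scale invariant.
2. **Pick**: per entry, the maximal bin inside
   `reporter ± window_halfwidth` (ties toward the nominal centre; an edge
   flag marks maxima on the window boundary).
3. **Interference matrix**: `A[m,k]` is entry *k*'s closed-form model value
   at entry *m*'s picked position, with each entry's model translated by
   its own picked offset when it was confidently localised (edge flag
   clear), else kept at its nominal position. This is the position
   alignment that absorbs inter-spectral shifts.
4. **Solve** `A c = h / scale` directly. Negative solutions are kept and
   flagged (`negative`), not clipped — clipping would hide model
   mis-specification; an opt-in active-set non-negative mode exists for
   production use. Further flags: `edge`, `high_interference` (off-diagonal
   row mass above 50% of the diagonal), and `below_loq` against the
   10 × S/N limit of quantification when a quiet region is supplied.

`extended_aqua()` chains correction and quantification;
`aqua_quantify()` is the same inversion without the baseline stage, the
route used for blank samples whose spectra are already flat.

### Reporter windows and shift robustness

Pick windows must be narrower than the distance to the nearest *taller*
foreign line. The synthetic exudate panel deliberately contains the classic
hard case — threonine and lactic acid CH₃ doublets interleaved within
0.006 ppm — and gives those entries ±0.002 ppm windows (±0.004 ppm
elsewhere, ±0.003/±0.0016/±0.0025 for the unknown singlets near leucine).
With windows sized this way, a rigid shift of the whole spectrum up to the
smallest half-width moves every pick coherently and the alignment step
keeps concentrations within 1%. Shifts large enough to push a taller
neighbour into a foreign window defeat window-maximum picking *for any
library*: both entries pick the same bin, the matrix acquires two identical
rows, and the solve correctly refuses (singular system). That failure mode
is the reason window selection is part of library curation, not a tuning
afterthought.

## Accuracy floors of the corrected pipeline

Two small, systematic biases bound what baseline-corrected quantification
can achieve even on noiseless spectra:

* **Tail-floor bias.** airPLS anchors its baseline on the lowest points
  between peaks. For Lorentzian lines those points are not zero — they are
  the summed far tails, roughly `(γ/Δ)²` of an apex at distance Δ. The
  converged baseline therefore sits at the inter-peak tail floor, and the
  corrected apex is low by that floor: ~0.03% for isolated lines, up to
  ~1% inside the 0.93–0.97 ppm unknown-signal cluster.
* **Endpoint-zone bias.** As described above, the weight exception pulls
  the baseline ~1.4% into the internal standard, which propagates as a
  uniform scale bias to every concentration.

Together these put the full pipeline's noiseless round-trip accuracy at
the low-percent level (the package's own acceptance measurements: ≈1.8%
worst-case over the 24-metabolite panel, with the no-baseline route at
≈1e−5). Real-data noise dwarfs both effects, but they are the honest answer
to "what does the airPLS stage cost on a spectrum that did not need it".

## Background extraction

`make_backgrounds()` implements the four-step extraction used to build
evaluation backgrounds from a measured spectrum: spike localisation,
border determination, linear depletion, and average-based smoothing at
three levels (moving-average windows 51/201/801 bins → models A/B/C,
roughest to smoothest; roughness is compared as summed squared second
differences *per segment* — a concatenated comparison would count the
water-gap seam).

The detector (`detect_spikes()`) finds local maxima whose prominence over a
running-median reference (window 5 × max half-width) exceeds
`z_thresh = 4` times a robust noise scale. Several details matter and are
deliberate interpretations, exposed as parameters:

* the noise scale is the *largest* of the first-difference MAD (bin-level
  noise), the MAD of deviations from the reference (meaningful on smoothed,
  serially correlated data), and 0.2% of the spectrum's global dynamic
  range ("high-intensity" means relative to the spectrum — a noise
  undulation in an otherwise empty segment is not a spike, which is why the
  spectrum method applies the global range to every segment);
* a candidate must fall to a quarter of its prominence within
  `max_width_bins = 60` on both sides (tall Lorentzian tails stay above the
  local median for hundreds of bins, so requiring a full return would
  reject genuine spikes; broad humps barely fall at all on that scale and
  are still rejected);
* borders walk outward until the signal reaches the reference or rises for
  three consecutive bins by more than half the noise scale, up to
  5 × max half-width (tails belong to the spike, and noise jiggle must not
  truncate the walk);
* regions whose gap never returns to the reference are merged (the saddle
  between overlapping spikes belongs to the spikes);
* depletion bridges each region with the straight line through 3-bin
  flanks, iterated up to four detect/deplete rounds so that shoulders
  uncovered by one bridging round are caught by the next.

## The synthetic-data layer

All tests and the acceptance script run on synthetic data with known
ground truth; the generators are first-class, tested code.

* `exudate_panel_library()`: 24 metabolites (amino acids, organic acids,
  sugars) at literature-like shifts and multiplicities, four unknown
  interferent singlets between 0.93 and 0.97 ppm next to the leucine
  triplet, and the reference singlet at 0.29 mM. Apex heights are drawn
  once per seed from U(0.7, 1.6); positions and multiplicities are fixed.
* Line centres are snapped to the canonical axis' bin-centre grid (odd
  multiples of 1e−4 ppm; the reference singlet sits at 0.0001 ppm, the bin
  centre nearest 0). Sub-bin apex misalignment aliases into up to ~1%
  height error for a 1.2 Hz line, which would confound solver-level
  recovery checks; real spectra are of course not grid-aligned, and that
  regime is what the shift-robustness tolerance covers.
* `synth_broad_background()`: wide (0.1–0.5 ppm) *Gaussian* humps confined
  to 0.5–3.2 ppm under a broad envelope. Gaussian rather than Lorentzian,
  because Lorentzian far tails would lay a percent-level pedestal across
  the entire spectrum — real broad signals are localised, and the study
  design needs genuinely background-free reporters (the formate/fumarate
  analogues).
* `synth_untargeted_signals()`: ~80 random narrow singlets in the crowded
  0.8–4.6 ppm window, heights skewed weak. They make the
  background-extraction source realistic: depletion removes the tall ones,
  the weak ones survive into model A as fine structure.
* `synth_simulation_design()` assembles the full evaluation fixture:
  source spectrum (panel mixture + broad background at amplitude 2 +
  untargeted signals + noise sd 0.002), backgrounds A/B/C extracted from
  it, a 0.1 mM/entry narrow spectrum, and seven scaling levels — geometric
  over two decades, mirroring the dynamic range between real samples
  (10–3200 µM in the spike-in design).

What the generators do *not* emulate: peak-shape distortions (phasing
errors, field inhomogeneity beyond linewidth scaling), pH-driven
*differential* shifts (only rigid shifts are generated), J-coupling
second-order effects, and spectrometer drift. Passing tests on synthetic
data therefore demonstrate correctness of the algorithms under the stated
model, not performance on any particular real instrument.

## Evaluation studies

`run_simulation_study()` corrects all backgrounds × levels spectra at each
stiffness value, picks every reporter in corrected and truth spectra, and
regresses corrected on true heights per (metabolite, background, λ). Rows
with R² < 0.9900 are flagged. A practical finding worth recording:
*under*-correction of a **smoothed** background is nearly affine in the
scaling level — stiff λ on model A degrades slopes and intercepts but
leaves R² high, because conditional on the weight pattern the baseline is
linear in the input. The R² flag fires where residuals genuinely vary with
level: against rough, unsmoothed backgrounds (the spike-depleted source),
or through pick-position jumps at low signal levels. The package's
deliberate under-correction check is built accordingly.

`run_spikein_study()` quantifies paired matrix/blank spectrum sets sharing
one truth table: the matrix arm through the full extended pipeline, the
blank arm (flat spectra) without the baseline stage and optionally with a
reduced library (the spiked compounds plus known interferers). Reports
carry slope, intercept, intercept as percent of the per-metabolite maximum
concentration, R², and the mean percent difference
`100·|c_blank − c_sample|/c_blank`.

Noise and quantification limits: `estimate_noise()` is the standard
deviation of a signal-free region (≥50 bins) of the corrected spectrum;
`loq_concentration()` converts it to the concentration whose reporter apex
reaches 10 × noise.

## Problem sizes and determinism

Everything is deterministic given seeds; generators take explicit seeds and
restore the caller's RNG state. The shipped checks run the full
51 000-bin axis with the 24 + 4 panel: a single extended quantification
takes ~2 s; the simulation study (21 spectra × 2 stiffness values) a few
tens of seconds; the spike-in study (10 spectra) a few seconds.

## Known limitations

* Heights, not areas: linewidth distortions between library and spectrum
  (`fwhm_scale ≠ 1`) bias concentrations proportionally; no per-spectrum
  linewidth fit is attempted.
* No automatic λ selection: the map is user-curated, as in the source
  method; the per-spectrum λ choice that a strongly varying signal
  intensity can require is exposed but not automated.
* Window-maximum picking fails for shifts beyond the window/clearance
  geometry (see above); differential shifts (one metabolite moving
  relative to another) are corrected only as far as the per-entry offset
  alignment reaches.
* The non-negative solve is a simple active-set clamp, adequate for
  diagonally dominant systems, not a general NNLS.
* The background-extraction thresholds are interpretations of a sparsely
  documented procedure; they are exposed as parameters and their defaults
  are validated by the package's own invariants (no residual spikes,
  roughness ordering) rather than against the original implementation.
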