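# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Snap ppm values to the bin-centre grid of the canonical 0.0002 ppm/bin
# axis (odd multiples of 1e-4 ppm). The synthetic generators align line
# centres with this grid so that sub-bin apex aliasing (up to ~1% in height
# for a 1.2 Hz line) does not confound recovery experiments; real spectra
# are of course not aligned, which is what the shift-robustness tolerance
# covers.
snap_to_grid <- function(ppm, bin_width_ppm = 2e-4) {
  half <- bin_width_ppm / 2
  round((ppm - half) / bin_width_ppm) * bin_width_ppm + half
}

# Binomial-like multiplet pattern with n components, tallest normalised to 1.
multiplet_pattern <- function(n) {
  h <- choose(n - 1L, seq_len(n) - 1L)
  h / max(h)
}

make_multiplet_entry <- function(name, center_ppm, n_comp, apex_height,
                                 j_hz = 7, fwhm_hz = 1.2, role = "target",
                                 window_halfwidth_ppm = 0.004,
                                 frequency_mhz = 600) {
  j_ppm <- j_hz / frequency_mhz
  rel <- seq_len(n_comp) - (n_comp + 1) / 2
  centers <- snap_to_grid(center_ppm + rel * j_ppm)
  pat <- multiplet_pattern(n_comp) * apex_height
  reporter <- centers[which.max(pat)]
  metabolite_entry(
    name,
    data.frame(center_ppm = centers, rel_height = pat, fwhm_hz = fwhm_hz),
    reporter_center_ppm = reporter,
    window_halfwidth_ppm = window_halfwidth_ppm,
    role = role, frequency_mhz = frequency_mhz)
}

make_dss_entry <- function(frequency_mhz = 600) {
  # reference singlet placed on the bin centre nearest 0 ppm
  metabolite_entry(
    "DSS",
    data.frame(center_ppm = snap_to_grid(0), rel_height = 12, fwhm_hz = 1.2),
    window_halfwidth_ppm = 0.006, role = "target",
    frequency_mhz = frequency_mhz)
}

#' Generate a synthetic metabolite library
#'
#' Draws a deterministic (seeded) panel of multiplets (1-5 Lorentzian
#' components, ~1.2-1.4 Hz linewidths, J about 7 Hz) across 0.8-9.0 ppm,
#' skipping the water gap, plus optional unknown interferent singlets
#' placed between 0.93 and 0.97 ppm, plus a reference singlet (DSS-like)
#' next to 0 ppm at 0.29 mM. `overlap_level` controls the minimum reporter
#' spacing: `"low"` keeps all reporter windows disjoint, `"medium"` lets
#' windows touch, `"high"` packs entries into clusters.
#'
#' @param n_targets number of target entries (>= 1).
#' @param n_interferents number of interferent singlets (default 0).
#' @param seed RNG seed; identical seeds give identical libraries.
#' @param overlap_level `"low"`, `"medium"`, or `"high"`.
#' @param frequency_mhz spectrometer frequency.
#' @return an `nmr_library`.
#' @export
make_synthetic_library <- function(n_targets, n_interferents = 0L, seed = 1L,
                                   overlap_level = c("low", "medium", "high"),
                                   frequency_mhz = 600) {
  overlap_level <- match.arg(overlap_level)
  if (n_targets < 1L) stop("`n_targets` must be >= 1")
  min_sep <- switch(overlap_level, low = 0.06, medium = 0.02, high = 0.008)
  with_seed(seed, {
    # candidate reporter positions: jittered even spread over usable range
    usable <- c(0.80, 9.00)
    pos <- numeric(0)
    tries <- 0L
    while (length(pos) < n_targets && tries < 50000L) {
      p <- stats::runif(1, usable[1], usable[2])
      tries <- tries + 1L
      if (p > 4.60 && p < 5.06) next       # keep clear of the water gap
      if (!length(pos) || all(abs(pos - p) >= min_sep)) pos <- c(pos, p)
    }
    if (length(pos) < n_targets)
      stop("could not place all targets at the requested overlap level")
    pos <- sort(snap_to_grid(pos))
    targets <- lapply(seq_len(n_targets), function(i) {
      make_multiplet_entry(
        sprintf("met_%02d", i), pos[i],
        n_comp = sample(1:5, 1),
        apex_height = stats::runif(1, 0.7, 1.6),
        j_hz = stats::runif(1, 6, 8),
        fwhm_hz = stats::runif(1, 1.2, 1.4),
        frequency_mhz = frequency_mhz)
    })
    interferents <- lapply(seq_len(n_interferents), function(i) {
      p <- snap_to_grid(stats::runif(1, 0.931, 0.969))
      metabolite_entry(
        sprintf("unknown_%d", i),
        data.frame(center_ppm = p,
                   rel_height = stats::runif(1, 0.3, 1.2),
                   fwhm_hz = stats::runif(1, 1.2, 1.4)),
        window_halfwidth_ppm = 0.005, role = "interferent",
        frequency_mhz = frequency_mhz)
    })
    nmr_library(c(targets, interferents), make_dss_entry(frequency_mhz),
                known_concentration_mM = 0.29, frequency_mhz = frequency_mhz)
  })
}

#' The synthetic root-exudate panel
#'
#' A fixed 24-metabolite panel (amino acids, organic acids, sugars) with
#' reporter signals at literature-like chemical shifts, plus four unknown
#' interferent singlets between 0.93 and 0.97 ppm next to the leucine
#' reporter at 0.96 ppm, plus the DSS reference singlet at 0.29 mM. The
#' threonine (1.325 ppm) and lactic acid (1.330 ppm) reporters deliberately
#' overlap, as they do in real exudate spectra. Per-entry apex heights are
#' drawn once from the seed; positions and multiplicities are fixed.
#'
#' @param seed RNG seed for the apex heights.
#' @param frequency_mhz spectrometer frequency.
#' @return an `nmr_library` with 24 targets and 4 interferents.
#' @export
exudate_panel_library <- function(seed = 1L, frequency_mhz = 600) {
  panel <- data.frame(
    name = c("leucine", "isoleucine", "valine", "threonine", "lactic_acid",
             "alanine", "gaba", "acetic_acid", "glutamic_acid", "succinic_acid",
             "glutamine", "citric_acid", "malic_acid", "aspartic_acid",
             "asparagine", "glycine", "myo_inositol", "fructose",
             "tartaric_acid", "xylose", "glucose", "sucrose",
             "fumaric_acid", "formic_acid"),
    center = c(0.9601, 1.0101, 1.0401, 1.3251, 1.3301,
               1.4801, 1.8901, 1.9201, 2.3501, 2.4101,
               2.4501, 2.5401, 2.6801, 2.8001,
               2.9501, 3.5601, 4.0601, 4.1101,
               4.3401, 5.1901, 5.2301, 5.4101,
               6.5201, 8.4601),
    n_comp = c(3L, 2L, 2L, 2L, 2L,
               2L, 5L, 1L, 2L, 1L,
               2L, 2L, 2L, 2L,
               2L, 1L, 3L, 2L,
               1L, 2L, 2L, 2L,
               1L, 1L))
  # per-entry picking windows: the interleaved threonine/lactic doublets get
  # narrow windows so that a uniform shift up to the smallest half-width can
  # never pull a taller neighbour into a foreign window
  panel$window <- 0.004
  panel$window[panel$name %in% c("threonine", "lactic_acid")] <- 0.002
  with_seed(seed, {
    heights <- stats::runif(nrow(panel), 0.7, 1.6)
    inter_h <- stats::runif(4, 0.3, 1.0)
    targets <- lapply(seq_len(nrow(panel)), function(i)
      make_multiplet_entry(panel$name[i], panel$center[i], panel$n_comp[i],
                           apex_height = heights[i], j_hz = 7,
                           fwhm_hz = 1.2, frequency_mhz = frequency_mhz,
                           window_halfwidth_ppm = panel$window[i]))
    inter_pos <- c(0.9301, 0.9411, 0.9521, 0.9671)
    # unknown_3 and unknown_4 sit next to leucine multiplet lines
    inter_win <- c(0.003, 0.003, 0.0016, 0.0025)
    interferents <- lapply(1:4, function(i)
      metabolite_entry(
        sprintf("unknown_%d", i),
        data.frame(center_ppm = inter_pos[i], rel_height = inter_h[i],
                   fwhm_hz = 1.2),
        window_halfwidth_ppm = inter_win[i], role = "interferent",
        frequency_mhz = frequency_mhz))
    nmr_library(c(targets, interferents), make_dss_entry(frequency_mhz),
                known_concentration_mM = 0.29, frequency_mhz = frequency_mhz)
  })
}

#' Synthetic broad spectral background
#'
#' Emulates the broad low-frequency background of minimally prepared plant
#' root-exudate spectra: a sum of wide (0.1-0.5 ppm) Gaussian humps between
#' `region[1]` and `region[2]` under a broad envelope. Humps are Gaussian
#' rather than Lorentzian so that the background stays local: real broad
#' signals do not leave a pedestal across the whole spectrum. Purely
#' smooth; contains no narrow signals.
#'
#' @param axis an `nmr_axis`.
#' @param amplitude peak amplitude scale of the humps.
#' @param seed RNG seed.
#' @param n_humps number of humps (default 6).
#' @param region ppm interval holding the humps (default `c(0.5, 3.2)`).
#' @return an `nmr_spectrum`.
#' @export
synth_broad_background <- function(axis, amplitude = 1, seed = 1L,
                                   n_humps = 6L, region = c(0.5, 3.2)) {
  cent <- bin_centers(axis)
  with_seed(seed, {
    y <- numeric(length(cent))
    for (i in seq_len(n_humps)) {
      c0 <- stats::runif(1, region[1], region[2])
      gam <- stats::runif(1, 0.05, 0.25)          # half width at half height, ppm
      a <- amplitude * stats::runif(1, 0.3, 1)
      y <- y + a * exp(-log(2) * ((cent - c0) / gam)^2)
    }
    # one broad envelope under the hump region; the rest of the spectrum
    # stays background-free, as in minimally prepared exudate spectra where
    # the broad signals concentrate in the aliphatic region
    mid <- mean(region); halfspan <- diff(region) / 2
    y <- y + amplitude * 0.2 * exp(-((cent - mid) / halfspan)^2)
    nmr_spectrum(axis, y, label = sprintf("background_seed%d", seed))
  })
}

#' Untargeted narrow signals
#'
#' Real exudate spectra carry hundreds of narrow signals beyond the
#' quantified panel. This generator draws `n_signals` random Lorentzian
#' singlets (linewidths 1.2-3 Hz, heights up to `max_height`) in the
#' crowded low-frequency window (0.8-4.6 ppm). Used to make
#' background-extraction sources realistic:
#' depletion removes the tall ones, and the weaker ones survive into the
#' background models as fine structure.
#'
#' @param axis an `nmr_axis`.
#' @param n_signals number of signals (default 80).
#' @param max_height tallest apex (default 0.5).
#' @param seed RNG seed.
#' @return an `nmr_spectrum`.
#' @export
synth_untargeted_signals <- function(axis, n_signals = 80L, max_height = 0.5,
                                     seed = 1L) {
  cent <- bin_centers(axis)
  freq <- axis$frequency_mhz
  with_seed(seed, {
    y <- numeric(length(cent))
    for (i in seq_len(n_signals)) {
      p <- stats::runif(1, 0.8, 4.6)   # the crowded aliphatic/midfield window
      gam <- (stats::runif(1, 1.2, 3) / freq) / 2
      h <- max_height * stats::runif(1)^2     # many weak, few strong
      y <- y + h * gam^2 / ((cent - p)^2 + gam^2)
    }
    nmr_spectrum(axis, y, label = sprintf("untargeted_seed%d", seed))
  })
}

#' Build the standard synthetic simulation design
#'
#' One call constructing the whole simulation fixture: a source spectrum
#' (library mixture + broad background + untargeted narrow signals + noise)
#' from which the three background models are extracted, a unit-level
#' narrow-signal spectrum (0.1 mM per entry), and the scaling levels. The
#' defaults emulate minimally prepared root-exudate spectra: background
#' amplitude about twice the top narrow signals, seven scaling levels over
#' two decades mirroring the dynamic range between real samples.
#'
#' @param library an `nmr_library`.
#' @param axis an `nmr_axis`.
#' @param seed RNG seed driving the source spectrum and backgrounds.
#' @param amplitude broad-background amplitude (default 2).
#' @param noise_sd source-spectrum noise (default 0.002).
#' @param narrow_mM per-entry concentration of the narrow spectrum.
#' @param scaling_levels scaling levels (default 7, geometric over 2 decades).
#' @param lambdas smoothing factors to sweep.
#' @return a [simulation_design()]; the source spectrum is attached as
#'   attribute `source`.
#' @export
synth_simulation_design <- function(library, axis, seed = 1L, amplitude = 2,
                                    noise_sd = 0.002, narrow_mM = 0.1,
                                    scaling_levels = 10^seq(0, 2, length.out = 7) / 10,
                                    lambdas = c(1e6, 1e7, 1e8)) {
  base <- synth_exudate_spectrum(
    library, axis,
    background = synth_broad_background(axis, amplitude = amplitude, seed = seed),
    noise_sd = noise_sd, seed = seed, label = "sim_source")
  src <- nmr_spectrum(
    axis,
    base$intensities + synth_untargeted_signals(axis, seed = seed)$intensities,
    label = "sim_source")
  bgs <- make_backgrounds(src)
  nm <- library_names(library)
  narrow <- render_mixture(library, axis,
                           stats::setNames(rep(narrow_mM, length(nm)), nm),
                           label = "narrow")
  design <- simulation_design(bgs, narrow, scaling_levels = scaling_levels,
                              lambdas = lambdas)
  attr(design, "source") <- src
  design
}

#' Simulate a root-exudate-like spectrum with known ground truth
#'
#' Renders the library mixture (targets at the supplied or seeded
#' concentrations, internal standard at its known concentration), then adds
#' an optional broad background and white noise.
#'
#' @param library an `nmr_library`.
#' @param axis an `nmr_axis`.
#' @param concentrations named mM vector for targets/interferents; when
#'   `NULL`, drawn per entry from U(0.05, 1) mM under the seed.
#' @param background optional `nmr_spectrum` added as-is.
#' @param noise_sd standard deviation of added white noise (0 = noiseless).
#' @param shift_ppm rigid shift applied to every rendered entry.
#' @param seed RNG seed (concentration draw and noise).
#' @param label spectrum label.
#' @return an `nmr_spectrum` with attributes `concentrations_mM` (the truth,
#'   internal standard included) and `truth` (the noiseless narrow-signal
#'   spectrum, background excluded).
#' @export
synth_exudate_spectrum <- function(library, axis, concentrations = NULL,
                                   background = NULL, noise_sd = 0,
                                   shift_ppm = 0, seed = 1L,
                                   label = "synthetic") {
  stopifnot(inherits(library, "nmr_library"))
  with_seed(seed, {
    if (is.null(concentrations)) {
      nm <- library_names(library)
      concentrations <- stats::setNames(stats::runif(length(nm), 0.05, 1), nm)
    }
    conc <- concentrations
    isn <- library$internal_standard$name
    if (!isn %in% names(conc))
      conc[isn] <- library$known_concentration_mM
    offsets <- stats::setNames(rep(shift_ppm, length(conc)), names(conc))
    truth <- render_mixture(library, axis, conc, offsets = offsets,
                            label = paste0(label, "_truth"))
    y <- truth$intensities
    if (!is.null(background)) {
      stopifnot(inherits(background, "nmr_spectrum"))
      if (!axes_equal(background$axis, axis)) stop("background axis mismatch")
      y <- y + background$intensities
    }
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
    out <- nmr_spectrum(axis, y, label = label)
    attr(out, "concentrations_mM") <- conc
    attr(out, "truth") <- truth
    out
  })
}
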