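#' Simulation-study design: backgrounds x scaling levels
#'
#' Pairs three spectral background models with a unit-level narrow-signal
#' spectrum and a set of scaling levels; the default seven levels form a
#' geometric series over one decade, spanning the large dynamic range seen
#' between real samples. Correction is evaluated at each smoothing factor
#' in `lambdas`.
#'
#' @param backgrounds named list of three `nmr_spectrum` (A, B, C).
#' @param narrow_spectrum unit-level rendered mixture (`nmr_spectrum`).
#' @param scaling_levels non-negative multipliers (a zero level gives the
#'   bare background; default seven levels, geometric over one decade).
#' @param lambdas smoothing factors to sweep (default `c(1e6, 1e7, 1e8)`).
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(backgrounds, narrow_spectrum,
                              scaling_levels = 10^seq(0, 1, length.out = 7),
                              lambdas = c(1e6, 1e7, 1e8)) {
  stopifnot(length(backgrounds) == 3L, inherits(narrow_spectrum, "nmr_spectrum"))
  if (is.null(names(backgrounds))) names(backgrounds) <- c("A", "B", "C")
  for (b in backgrounds) {
    stopifnot(inherits(b, "nmr_spectrum"))
    if (!axes_equal(b$axis, narrow_spectrum$axis))
      stop("background and narrow-spectrum axes differ")
  }
  if (any(scaling_levels < 0)) stop("scaling levels must be non-negative")
  structure(list(backgrounds = backgrounds, narrow_spectrum = narrow_spectrum,
                 scaling_levels = scaling_levels, lambdas = lambdas),
            class = "simulation_design")
}

#' Construct the simulated spectra of a design
#'
#' Each simulated spectrum is `background + level * narrow_spectrum`; its
#' truth is `level * narrow_spectrum`. Three backgrounds and seven levels
#' yield 21 simulated spectra.
#'
#' @param design a [simulation_design()].
#' @return list with one element per (background, level) pair:
#'   `spectrum`, `truth`, `background` (name), `level`.
#' @export
simulate_spectra <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  axis <- design$narrow_spectrum$axis
  out <- list()
  for (bg in names(design$backgrounds)) {
    for (s in design$scaling_levels) {
      truth <- nmr_spectrum(axis, s * design$narrow_spectrum$intensities,
                            label = sprintf("truth_%s_x%g", bg, s))
      spec <- nmr_spectrum(
        axis,
        design$backgrounds[[bg]]$intensities + truth$intensities,
        label = sprintf("sim_%s_x%g", bg, s))
      out[[length(out) + 1L]] <- list(spectrum = spec, truth = truth,
                                      background = bg, level = s)
    }
  }
  out
}

#' Ordinary least-squares regression statistics
#'
#' Fits `y ~ x` by OLS and returns slope, intercept, R-squared
#' (`1 - SSres/SStot`; 0 by convention when `y` is constant) and n.
#'
#' @param x predictor vector (must not be constant).
#' @param y response vector, same length.
#' @return list of class `regression_stats`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2L) stop("need n >= 2")
  if (stats::var(x) == 0) stop("degenerate predictor: var(x) = 0")
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, n = length(x)),
            class = "regression_stats")
}

#' Percent difference between paired concentration estimates
#'
#' `100 * |c_ref - c_test| / c_ref`, the accuracy summary used to compare
#' the matrix arm against the blank arm of a spike-in study.
#'
#' @param c_ref reference concentration (non-zero).
#' @param c_test test concentration.
#' @return percent difference (vectorised).
#' @export
percent_difference <- function(c_ref, c_test) {
  if (any(c_ref == 0)) stop("reference concentration must be non-zero")
  100 * abs(c_ref - c_test) / c_ref
}

#' Regression intercept as percent of the maximum concentration
#'
#' @param intercept regression intercept (concentration units).
#' @param max_conc maximum spiked concentration for the metabolite (> 0).
#' @return `100 * intercept / max_conc` (vectorised).
#' @export
relative_intercept <- function(intercept, max_conc) {
  if (any(max_conc <= 0)) stop("`max_conc` must be > 0")
  100 * intercept / max_conc
}

#' Estimate the noise level from a signal-free region
#'
#' Standard deviation of the (baseline-corrected) intensities inside a quiet
#' ppm interval holding at least 50 bins.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param quiet_region length-2 ppm interval.
#' @return noise standard deviation (spectrum units).
#' @export
estimate_noise <- function(spectrum, quiet_region) {
  stopifnot(inherits(spectrum, "nmr_spectrum"), length(quiet_region) == 2L)
  idx <- bins_in_window(spectrum$axis, min(quiet_region), max(quiet_region))
  if (length(idx) < 50L)
    stop("quiet region must hold at least 50 bins inside the axis")
  stats::sd(spectrum$intensities[idx])
}

#' Limit of quantification for one entry
#'
#' The concentration whose reporter apex reaches ten times the noise level
#' (the 10 x S/N rule): `10 * noise / (scale * unit_response)`.
#'
#' @param entry a [metabolite_entry()].
#' @param noise noise standard deviation in spectrum units.
#' @param scale spectrum-to-library intensity scale.
#' @return LOQ in mM (same concentration units as `unit_response`).
#' @export
loq_concentration <- function(entry, noise, scale = 1) {
  stopifnot(inherits(entry, "metabolite_entry"))
  if (noise < 0 || scale <= 0) stop("need noise >= 0 and scale > 0")
  10 * noise / (scale * entry$unit_response)
}

#' Run the simulation study: correct, pick, regress
#'
#' For every smoothing factor in the design, all simulated spectra are
#' baseline corrected with that single factor applied globally; each
#' metabolite's reporter is picked in the corrected and in the truth
#' spectra; and, per (metabolite, background, lambda), the corrected height
#' is regressed on the true height across the scaling levels. Rows with
#' R-squared below 0.9900 are flagged.
#'
#' @param design a [simulation_design()].
#' @param library the `nmr_library` whose reporters are evaluated.
#' @param params an [airpls_params()] (lambda is overridden by the sweep).
#' @param r2_flag_threshold flagging threshold (default 0.9900).
#' @return data frame of class `eval_report`: `metabolite`, `background`,
#'   `lambda`, `slope`, `intercept`, `r2`, `n`, `r2_flag`.
#' @export
run_simulation_study <- function(design, library, params = airpls_params(),
                                 r2_flag_threshold = 0.9900) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(library, "nmr_library"))
  sims <- simulate_spectra(design)
  nms <- library_names(library)

  truth_heights <- lapply(sims, function(s)
    vapply(nms, function(m)
      pick_reporter(s$truth, library$entries[[m]])$height, numeric(1)))

  rows <- list()
  for (lam in design$lambdas) {
    pars <- params; pars$lam <- lam
    corr_heights <- lapply(sims, function(s) {
      corrected <- correct_spectrum(s$spectrum, NULL, pars)$spectrum
      vapply(nms, function(m)
        pick_reporter(corrected, library$entries[[m]])$height, numeric(1))
    })
    for (bg in names(design$backgrounds)) {
      sel <- which(vapply(sims, function(s) s$background == bg, logical(1)))
      for (m in seq_along(nms)) {
        xs <- vapply(sel, function(i) truth_heights[[i]][m], numeric(1))
        ys <- vapply(sel, function(i) corr_heights[[i]][m], numeric(1))
        st <- linear_regression(xs, ys)
        rows[[length(rows) + 1L]] <- data.frame(
          metabolite = nms[m], background = bg, lambda = lam,
          slope = st$slope, intercept = st$intercept, r2 = st$r2, n = st$n,
          r2_flag = st$r2 < r2_flag_threshold, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Run a spike-in evaluation study
#'
#' Quantifies paired spiked-matrix and spiked-blank spectrum sets that share
#' one truth table. The matrix arm goes through the full extended pipeline
#' (airPLS then interference solve); the blank arm, whose spectra are flat,
#' skips the baseline stage. Per metabolite, matrix concentrations are
#' regressed on blank concentrations; the report carries slope, intercept,
#' relative intercept (percent of the metabolite's maximum truth
#' concentration), R-squared, and the mean percent difference between arms.
#'
#' @param matrix_spectra list of `nmr_spectrum` (matrix arm), one per level.
#' @param blank_spectra list of `nmr_spectrum` (blank arm), paired by index.
#' @param truth data frame: `metabolite` plus one numeric column per level
#'   (uM), used for the relative intercept denominator.
#' @param library an `nmr_library` covering the spiked metabolites
#'   (matrix arm).
#' @param map optional [region_lambda_map()] for the matrix arm.
#' @param params an [airpls_params()].
#' @param blank_library library for the blank arm; defaults to `library`.
#'   Blank samples carry only the spiked compounds, so a reduced panel
#'   (spiked metabolites plus known interferers) is the typical choice.
#' @return data frame of class `eval_report`: `metabolite`, `slope`,
#'   `intercept_uM`, `relative_intercept_pct`, `r2`, `mean_pct_difference`,
#'   `n`. Per-level concentrations are attached as attribute `concentrations`.
#' @export
run_spikein_study <- function(matrix_spectra, blank_spectra, truth, library,
                              map = NULL, params = airpls_params(),
                              blank_library = library) {
  if (length(matrix_spectra) != length(blank_spectra))
    stop("matrix and blank spectrum sets must be paired (equal length)")
  if (length(matrix_spectra) < 2L) stop("need at least 2 paired levels")
  mets <- truth$metabolite
  if (is.null(mets)) stop("`truth` needs a metabolite column")
  max_truth <- apply(truth[, -1, drop = FALSE], 1, max)

  conc_of <- function(res) {
    stats::setNames(res$concentration_uM, res$metabolite)[mets]
  }
  m_conc <- vapply(matrix_spectra, function(s)
    conc_of(extended_aqua(s, library, map, params)), numeric(length(mets)))
  b_conc <- vapply(blank_spectra, function(s)
    conc_of(aqua_quantify(s, blank_library)), numeric(length(mets)))
  if (length(mets) == 1L) {
    m_conc <- matrix(m_conc, nrow = 1); b_conc <- matrix(b_conc, nrow = 1)
  }

  rows <- lapply(seq_along(mets), function(i) {
    st <- linear_regression(b_conc[i, ], m_conc[i, ])
    data.frame(
      metabolite = mets[i], slope = st$slope, intercept_uM = st$intercept,
      relative_intercept_pct = relative_intercept(st$intercept, max_truth[i]),
      r2 = st$r2,
      mean_pct_difference = mean(percent_difference(b_conc[i, ], m_conc[i, ])),
      n = st$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "concentrations") <- list(matrix = m_conc, blank = b_conc)
  class(out) <- c("eval_report", "data.frame")
  out
}
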