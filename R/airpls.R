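#' Whittaker smoother (weighted penalized least squares)
#'
#' Returns the minimiser z of
#' \deqn{\sum_i w_i (x_i - z_i)^2 + \lambda \sum_i (\Delta^d z)_i^2}
#' obtained from the banded symmetric positive-definite normal equations
#' `(W + lambda * t(D) D) z = W x`, where `D` is the order-`d` difference
#' operator. The system is solved with a sparse Cholesky factorisation, so
#' time and memory are linear in the vector length.
#'
#' @param x numeric data vector.
#' @param w non-negative weights, same length as `x` (default all 1).
#' @param lam smoothing factor, larger = stiffer fit.
#' @param order difference order `d` (default 2: straight lines incur no
#'   penalty).
#' @return numeric vector `z`, same length as `x`.
#' @export
whittaker_smooth <- function(x, w = rep(1, length(x)), lam, order = 2L) {
  n <- length(x)
  if (n < order + 1L) stop("need length(x) >= order + 1")
  if (length(w) != n) stop("length(w) must equal length(x)")
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and non-negative")
  if (all(w == 0)) stop("weights must not be all zero")
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0) stop("`lam` must be > 0")

  coefs <- (-1)^(0:order) * choose(order, 0:order)
  D <- Matrix::bandSparse(n - order, n, k = 0:order,
                          diagonals = lapply(coefs, rep, n - order))
  C <- Matrix::Diagonal(x = w) + lam * Matrix::crossprod(D)
  as.numeric(Matrix::solve(C, w * x))
}

#' airPLS iteration parameters
#'
#' Defaults follow the published algorithm and the values used for complex
#' root-exudate spectra: smoothing factor `lam = 1e7` (valid range 1 to
#' 1e9), difference `order = 2`, weight exception proportion `wep = 0.1`,
#' asymmetry parameter `p_asym = 0.05`, at most `itermax = 20` iterations,
#' and termination when the mass of the residual below the baseline drops
#' under `convergence_ratio` of the total absolute intensity.
#'
#' The weight exception anchors the baseline ends: the first and last
#' `ceiling(wep * n)` points of each fitted stretch never receive zero
#' weight; at every reweighting their weight is `max(exponential weight,
#' p_asym)`.
#'
#' @param lam smoothing factor in `[1, 1e9]`.
#' @param order difference order.
#' @param wep weight exception proportion in `[0, 1]`.
#' @param p_asym asymmetry parameter in `(0, 1)`.
#' @param itermax maximum number of iterations.
#' @param convergence_ratio termination ratio (default 0.001).
#' @return a list of class `airpls_params`.
#' @export
airpls_params <- function(lam = 1e7, order = 2L, wep = 0.1, p_asym = 0.05,
                          itermax = 20L, convergence_ratio = 0.001) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) ||
      lam < 1 || lam > 1e9)
    stop("`lam` must be a single number in [1, 1e9]")
  if (order < 1L) stop("`order` must be a positive integer")
  if (wep < 0 || wep > 1) stop("`wep` must be in [0, 1]")
  if (p_asym <= 0 || p_asym >= 1) stop("`p_asym` must be in (0, 1)")
  if (itermax < 1L) stop("`itermax` must be >= 1")
  if (convergence_ratio <= 0) stop("`convergence_ratio` must be > 0")
  structure(list(lam = lam, order = as.integer(order), wep = wep,
                 p_asym = p_asym, itermax = as.integer(itermax),
                 convergence_ratio = convergence_ratio),
            class = "airpls_params")
}

#' Adaptive iteratively reweighted penalized least squares baseline fit
#'
#' Iterates: fit `z` with [whittaker_smooth()] under the current weights,
#' compute the residual `d = x - z` and the negative-residual mass
#' `dssn = |sum(d[d < 0])|`; declare convergence when `dssn` falls below
#' `convergence_ratio * sum(|x|)` (or when the residual is flat); otherwise
#' set the weight of points at or above the baseline to zero, the weight of
#' points below it to `exp(t * |d| / dssn)` (t = iteration number), apply
#' the endpoint exception, and repeat. Points above the running baseline are
#' thereby progressively excluded, so peaks do not attract the fit.
#'
#' @param x numeric vector (one contiguous axis segment).
#' @param params an [airpls_params()] object.
#' @return list of class `airpls_fit` with `baseline`, `corrected`
#'   (`x - baseline`, exactly), `iterations_used`, `converged`,
#'   `final_weights`.
#' @export
airpls_fit <- function(x, params = airpls_params()) {
  stopifnot(inherits(params, "airpls_params"))
  n <- length(x)
  if (n < params$order + 2L) stop("vector too short for airPLS")
  if (any(!is.finite(x))) stop("`x` must be finite")

  w <- rep(1, n)
  total <- sum(abs(x))
  k <- ceiling(params$wep * n)
  endpoints <- if (k > 0L) unique(c(seq_len(min(k, n)),
                                    seq.int(max(n - k + 1L, 1L), n))) else integer(0)
  z <- numeric(n)
  converged <- FALSE
  iterations <- 0L
  for (t in seq_len(params$itermax)) {
    iterations <- t
    z <- whittaker_smooth(x, w, params$lam, params$order)
    if (any(!is.finite(z))) stop("non-finite baseline during airPLS iteration")
    d <- x - z
    neg <- d < 0
    dssn <- abs(sum(d[neg]))
    if (dssn == 0 || dssn < params$convergence_ratio * total) {
      converged <- TRUE
      break
    }
    w[!neg] <- 0
    w[neg] <- exp(t * abs(d[neg]) / dssn)
    if (length(endpoints)) w[endpoints] <- pmax(w[endpoints], params$p_asym)
  }
  structure(list(baseline = z, corrected = x - z,
                 iterations_used = iterations, converged = converged,
                 final_weights = w),
            class = "airpls_fit")
}

#' @export
print.airpls_fit <- function(x, ...) {
  cat(sprintf("<airpls_fit> %d bins, %d iteration(s), %s\n",
              length(x$baseline), x$iterations_used,
              if (x$converged) "converged" else "stopped at itermax"))
  invisible(x)
}

#' Region-specific smoothing factor map
#'
#' A default smoothing factor plus optional local overrides: for every local
#' region, airPLS is re-run with the local factor on the region extended by
#' `blend_margin_bins` bins on each side, and the local baseline replaces
#' the default one inside the region with a linear crossfade over the
#' margin (which avoids baseline steps at region edges).
#'
#' @param default_lam default smoothing factor (`NULL` = take it from the
#'   `airpls_params` in use).
#' @param regions data frame with columns `start_ppm`, `end_ppm`, `lam`
#'   (may be empty or `NULL`).
#' @param blend_margin_bins crossfade margin in bins (default 25, i.e.
#'   0.005 ppm at 0.0002 ppm/bin).
#' @return list of class `region_lambda_map`.
#' @export
region_lambda_map <- function(default_lam = NULL, regions = NULL,
                              blend_margin_bins = 25L) {
  if (is.null(regions))
    regions <- data.frame(start_ppm = numeric(0), end_ppm = numeric(0),
                          lam = numeric(0))
  regions <- as.data.frame(regions)
  if (nrow(regions)) {
    if (!all(c("start_ppm", "end_ppm", "lam") %in% names(regions)))
      stop("`regions` needs columns start_ppm, end_ppm, lam")
    if (any(regions$start_ppm >= regions$end_ppm))
      stop("region start_ppm must be < end_ppm")
    if (any(regions$lam < 1 | regions$lam > 1e9))
      stop("region lam must be in [1, 1e9]")
    o <- order(regions$start_ppm)
    regions <- regions[o, , drop = FALSE]
    if (nrow(regions) > 1L &&
        any(regions$start_ppm[-1L] < regions$end_ppm[-nrow(regions)]))
      stop("lambda-map regions must be non-overlapping")
  }
  if (blend_margin_bins < 0L) stop("`blend_margin_bins` must be >= 0")
  structure(list(default_lam = default_lam, regions = regions,
                 blend_margin_bins = as.integer(blend_margin_bins)),
            class = "region_lambda_map")
}

#' Baseline-correct a spectrum with region-specific smoothing factors
#'
#' Each contiguous axis segment is corrected independently with the default
#' smoothing factor; local map regions are then re-fit with their own factor
#' and stitched in with a linear crossfade. The water gap is a hard
#' boundary: a map region spanning it is rejected.
#'
#' @param spectrum an `nmr_spectrum`.
#' @param map a [region_lambda_map()] (`NULL` = default factor everywhere).
#' @param params an [airpls_params()] object.
#' @return list of class `baseline_correction` with elements `spectrum`
#'   (corrected), `baseline` (stitched baseline as `nmr_spectrum`) and
#'   `fits` (per-segment diagnostics; each contains the default-fit
#'   diagnostics plus any local fits).
#' @export
correct_spectrum <- function(spectrum, map = NULL, params = airpls_params()) {
  stopifnot(inherits(spectrum, "nmr_spectrum"),
            inherits(params, "airpls_params"))
  if (is.null(map)) map <- region_lambda_map()
  stopifnot(inherits(map, "region_lambda_map"))
  default_lam <- if (is.null(map$default_lam)) params$lam else map$default_lam
  axis <- spectrum$axis

  if (nrow(map$regions)) {
    ok <- vapply(seq_len(nrow(map$regions)), function(i)
      window_in_one_segment(axis, map$regions$start_ppm[i],
                            map$regions$end_ppm[i]), logical(1))
    if (!all(ok))
      stop(sprintf(
        "lambda-map region [%g, %g] spans a segment boundary (e.g. the water gap)",
        map$regions$start_ppm[which(!ok)[1]], map$regions$end_ppm[which(!ok)[1]]))
  }

  x <- spectrum$intensities
  baseline <- numeric(length(x))
  seg_idx <- segment_indices(axis)
  cent <- bin_centers(axis)
  fits <- vector("list", length(seg_idx))

  for (s in seq_along(seg_idx)) {
    idx <- seg_idx[[s]]
    pars_seg <- params; pars_seg$lam <- default_lam
    fit <- airpls_fit(x[idx], pars_seg)
    z <- fit$baseline
    local_fits <- list()

    if (nrow(map$regions)) {
      seg_lo <- axis$segments$start_ppm[s]; seg_hi <- axis$segments$end_ppm[s]
      in_seg <- map$regions$start_ppm >= seg_lo & map$regions$end_ppm <= seg_hi
      for (r in which(in_seg)) {
        reg <- map$regions[r, ]
        if (reg$lam == default_lam) next    # identical fit; nothing to refit
        rel <- which(cent[idx] >= reg$start_ppm & cent[idx] <= reg$end_ppm)
        if (!length(rel)) next
        m <- map$blend_margin_bins
        lo <- max(1L, min(rel) - m)
        hi <- min(length(idx), max(rel) + m)
        pars_loc <- params; pars_loc$lam <- reg$lam
        lfit <- airpls_fit(x[idx[lo:hi]], pars_loc)
        # crossfade weight: 0 at the extended-window edges, 1 inside region
        wloc <- rep(1, hi - lo + 1L)
        nleft <- min(rel) - lo
        nright <- hi - max(rel)
        if (nleft > 0L)
          wloc[seq_len(nleft)] <- seq(0, 1, length.out = nleft + 2L)[2:(nleft + 1L)]
        if (nright > 0L)
          wloc[(hi - lo + 1L) - seq_len(nright) + 1L] <-
            seq(0, 1, length.out = nright + 2L)[2:(nright + 1L)]
        span <- lo:hi
        z[span] <- (1 - wloc) * z[span] + wloc * lfit$baseline
        local_fits[[length(local_fits) + 1L]] <-
          list(region = reg, fit = lfit, segment = s)
      }
    }
    baseline[idx] <- z
    fits[[s]] <- list(default_fit = fit, local_fits = local_fits,
                      baseline = z, corrected = x[idx] - z)
  }

  corrected <- spectrum
  corrected$intensities <- x - baseline
  structure(list(
    spectrum = corrected,
    baseline = nmr_spectrum(axis, baseline,
                            label = paste0(spectrum$label, "_baseline")),
    fits = fits),
    class = "baseline_correction")
}

#' @export
print.baseline_correction <- function(x, ...) {
  iters <- vapply(x$fits, function(f) f$default_fit$iterations_used, integer(1))
  cat(sprintf("<baseline_correction> %d segment(s), airPLS iterations: %s\n",
              length(x$fits), paste(iters, collapse = ", ")))
  invisible(x)
}
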