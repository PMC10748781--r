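#' Smoothing level for background extraction
#'
#' @param name `"low"`, `"medium"`, or `"high"`.
#' @param window_bins odd moving-average window (defaults 51 / 201 / 801).
#' @param passes number of smoothing passes (default 1).
#' @return list of class `smoothing_level`.
#' @export
smoothing_level <- function(name = c("low", "medium", "high"),
                            window_bins = NULL, passes = 1L) {
  name <- match.arg(name)
  if (is.null(window_bins))
    window_bins <- switch(name, low = 51L, medium = 201L, high = 801L)
  window_bins <- as.integer(window_bins)
  if (window_bins < 3L || window_bins %% 2L == 0L)
    stop("`window_bins` must be an odd integer >= 3")
  if (passes < 1L) stop("`passes` must be >= 1")
  structure(list(name = name, window_bins = window_bins,
                 passes = as.integer(passes)),
            class = "smoothing_level")
}

#' Localise narrow high-intensity signals (spikes)
#'
#' Candidate apexes are local maxima whose prominence over a running-median
#' reference (window `5 * max_width_bins`) exceeds `z_thresh` times a robust
#' noise scale (the median absolute deviation of first differences, scaled
#' for differencing). A candidate is accepted only when the intensity falls
#' back to the reference on both sides within `max_width_bins` of the apex,
#' which rejects broad humps. Borders walk outward from the apex until the
#' intensity reaches the reference or the slope inverts for 3 consecutive
#' bins, capped at `max_width_bins`; overlapping regions are merged.
#'
#' @param x numeric vector (one contiguous segment) or an `nmr_spectrum`
#'   (each axis segment is scanned; indices in the result are global).
#' @param z_thresh prominence threshold in noise units (default 4).
#' @param max_width_bins maximum half width of a spike (default 60).
#' @param scale_ref intensity scale used for the dynamic-range floor
#'   (default: the range of `x`). The spectrum method passes the range of
#'   the whole spectrum, so a noise undulation in an otherwise empty
#'   segment does not count as "high-intensity".
#' @return data frame with columns `left`, `right`, `apex` (bin indices),
#'   possibly empty.
#' @export
detect_spikes <- function(x, z_thresh = 4, max_width_bins = 60L,
                          scale_ref = NULL) {
  UseMethod("detect_spikes")
}

#' @export
detect_spikes.nmr_spectrum <- function(x, z_thresh = 4, max_width_bins = 60L,
                                       scale_ref = NULL) {
  if (is.null(scale_ref)) scale_ref <- max(x$intensities) - min(x$intensities)
  out <- lapply(segment_indices(x$axis), function(idx) {
    reg <- detect_spikes(x$intensities[idx], z_thresh = z_thresh,
                         max_width_bins = max_width_bins,
                         scale_ref = scale_ref)
    reg$left <- reg$left + idx[1] - 1L
    reg$right <- reg$right + idx[1] - 1L
    reg$apex <- reg$apex + idx[1] - 1L
    reg
  })
  do.call(rbind, out)
}

#' @export
detect_spikes.default <- function(x, z_thresh = 4, max_width_bins = 60L,
                                  scale_ref = NULL) {
  if (any(!is.finite(x))) stop("`x` must be finite")
  if (is.null(scale_ref)) scale_ref <- max(x) - min(x)
  n <- length(x)
  if (n < 7L) return(data.frame(left = integer(0), right = integer(0),
                                apex = integer(0)))
  refw <- min(5L * max_width_bins, n)
  if (refw %% 2L == 0L) refw <- refw - 1L
  ref <- as.numeric(stats::runmed(x, refw, endrule = "median"))
  # robust noise scale: first-difference MAD catches bin-to-bin noise; the
  # deviation-from-reference MAD keeps the threshold meaningful on heavily
  # smoothed (serially correlated) input, where adjacent differences shrink
  # much faster than the residual undulations themselves; the dynamic-range
  # floor encodes "high-intensity" - bumps below 0.2% of the intensity range
  # are background texture, not spikes
  sigma <- max(stats::mad(diff(x)) / sqrt(2), stats::mad(x - ref),
               0.002 * scale_ref)
  thr <- z_thresh * sigma
  if (thr == 0) return(data.frame(left = integer(0), right = integer(0),
                                  apex = integer(0)))

  dx <- diff(x)
  is_max <- c(FALSE, dx[-length(dx)] > 0 & dx[-1L] <= 0, FALSE)
  cand <- which(is_max & (x - ref) > thr & (x - ref) > 0)
  if (!length(cand))
    return(data.frame(left = integer(0), right = integer(0), apex = integer(0)))

  # the walk may run past max_width_bins (up to 5x) as long as the signal
  # keeps falling toward the reference: the slowly decaying tails of tall
  # Lorentzians belong to the spike, not to the background. Only rises that
  # clear the bin-to-bin noise scale count as slope inversions, so noise
  # jiggle on a shallow tail does not truncate the walk.
  diff_noise <- stats::mad(diff(x)) / sqrt(2)
  walk <- function(apex, step) {
    i <- apex
    inversions <- 0L
    while (abs(i - apex) < 5L * max_width_bins) {
      j <- i + step
      if (j < 1L || j > n) break
      if (x[j] <= ref[j]) { i <- j; break }   # reached the background
      if (x[j] > x[i] + 0.5 * diff_noise) inversions <- inversions + 1L
      else if (x[j] <= x[i]) inversions <- 0L
      if (inversions >= 3L) break
      i <- j
    }
    i
  }
  # a spike must fall to a quarter of its prominence on both sides within
  # max_width_bins; the full return to the reference is too strict for tall
  # Lorentzians, whose tails stay above the local median for hundreds of
  # bins, while broad humps still fail because they barely fall at all on
  # that scale
  narrow_enough <- function(apex) {
    lo <- max(1L, apex - max_width_bins); hi <- min(n, apex + max_width_bins)
    drop <- 0.25 * (x[apex] - ref[apex])
    any(x[lo:apex] - ref[lo:apex] <= drop) &&
      any(x[apex:hi] - ref[apex:hi] <= drop)
  }

  cand <- cand[vapply(cand, narrow_enough, logical(1))]
  if (!length(cand))
    return(data.frame(left = integer(0), right = integer(0), apex = integer(0)))
  reg <- data.frame(
    left = vapply(cand, walk, integer(1), step = -1L),
    right = vapply(cand, walk, integer(1), step = 1L),
    apex = cand)
  reg <- reg[order(reg$left), , drop = FALSE]

  # merge overlapping regions, and close-by regions whose gap never returns
  # to the reference (the saddle between two overlapping spikes belongs to
  # the spikes, not to the background), keeping the tallest apex
  merged <- reg[1, , drop = FALSE]
  if (nrow(reg) > 1L) {
    for (i in 2:nrow(reg)) {
      last <- nrow(merged)
      gap <- (merged$right[last] + 1L):max(merged$right[last] + 1L, reg$left[i] - 1L)
      joined <- reg$left[i] <= merged$right[last] + 1L ||
        (reg$left[i] - merged$right[last] <= max_width_bins &&
           all(x[gap] > ref[gap]))
      if (joined) {
        merged$right[last] <- max(merged$right[last], reg$right[i])
        if (x[reg$apex[i]] > x[merged$apex[last]])
          merged$apex[last] <- reg$apex[i]
      } else {
        merged <- rbind(merged, reg[i, ])
      }
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Deplete spikes by linear bridging
#'
#' Inside each region, values are replaced by the straight line fitted
#' through the flanking points (3 bins on each side outside the borders).
#' When a region touches the end of the vector, the available flank is
#' extended as a constant.
#'
#' @param x numeric vector.
#' @param regions data frame from [detect_spikes()].
#' @return numeric vector with spikes bridged.
#' @export
deplete_spikes <- function(x, regions) {
  if (!nrow(regions)) return(x)
  n <- length(x)
  out <- x
  for (i in seq_len(nrow(regions))) {
    l <- regions$left[i]; r <- regions$right[i]
    if (l < 1L || r > n || l > r) stop("invalid spike region")
    li <- seq.int(max(1L, l - 3L), l - 1L)
    ri <- seq.int(r + 1L, min(n, r + 3L))
    li <- li[li >= 1L]; ri <- ri[ri <= n & ri > r]
    span <- l:r
    if (length(li) >= 1L && length(ri) >= 1L) {
      pts_x <- c(li, ri); pts_y <- x[c(li, ri)]
      fit <- stats::lm.fit(cbind(1, pts_x), pts_y)
      out[span] <- fit$coefficients[1] + fit$coefficients[2] * span
    } else if (length(li) >= 1L) {
      out[span] <- mean(x[li])      # one-sided: constant extension
    } else if (length(ri) >= 1L) {
      out[span] <- mean(x[ri])
    }
  }
  out
}

#' Average-based smoothing with reflective end padding
#'
#' Centred moving average, applied `passes` times. Ends are padded by
#' reflection (excluding the edge bin), so a linear ramp passes through
#' almost unchanged and the interior mean is preserved.
#'
#' @param x numeric vector.
#' @param level a [smoothing_level()].
#' @return smoothed numeric vector, same length.
#' @export
smooth_background <- function(x, level) {
  stopifnot(inherits(level, "smoothing_level"))
  n <- length(x)
  w <- level$window_bins
  if (w > n) stop("smoothing window longer than the vector")
  k <- (w - 1L) %/% 2L
  out <- x
  for (p in seq_len(level$passes)) {
    padded <- c(rev(out[2:(k + 1L)]), out, rev(out[(n - k):(n - 1L)]))
    sm <- stats::filter(padded, rep(1 / w, w), sides = 2)
    out <- as.numeric(sm[(k + 1L):(k + n)])
  }
  out
}

#' Extract three spectral background models from a spectrum
#'
#' Applies the four-step background-extraction algorithm per axis segment:
#' spike localisation, border determination, linear depletion, and
#' average-based smoothing at three levels, yielding background models A
#' (low smoothing, roughest), B (medium), and C (high, smoothest).
#'
#' @param spectrum an `nmr_spectrum`.
#' @param levels list of three [smoothing_level()] objects (defaults:
#'   low/medium/high with windows 51/201/801).
#' @param z_thresh,max_width_bins spike-detection parameters.
#' @param deplete_passes detect/deplete rounds before smoothing (default 4);
#'   repeated rounds catch the tail shoulders of tall singlets uncovered by
#'   the first bridging.
#' @return named list `A`, `B`, `C` of `nmr_spectrum`, with the
#'   spike-depleted intermediate attached as attribute `depleted`.
#' @export
make_backgrounds <- function(spectrum,
                             levels = list(smoothing_level("low"),
                                           smoothing_level("medium"),
                                           smoothing_level("high")),
                             z_thresh = 4, max_width_bins = 60L,
                             deplete_passes = 4L) {
  stopifnot(inherits(spectrum, "nmr_spectrum"), length(levels) == 3L)
  axis <- spectrum$axis
  x <- spectrum$intensities
  scale_ref <- max(x) - min(x)
  depleted <- x
  for (idx in segment_indices(axis)) {
    seg <- x[idx]
    for (p in seq_len(deplete_passes)) {
      reg <- detect_spikes(seg, z_thresh = z_thresh,
                           max_width_bins = max_width_bins,
                           scale_ref = scale_ref)
      if (!nrow(reg)) break
      seg <- deplete_spikes(seg, reg)
    }
    depleted[idx] <- seg
  }
  out <- lapply(levels, function(lv) {
    y <- depleted
    for (idx in segment_indices(axis))
      y[idx] <- smooth_background(depleted[idx], lv)
    nmr_spectrum(axis, y, label = sprintf("%s_bg_%s", spectrum$label, lv$name))
  })
  names(out) <- c("A", "B", "C")
  attr(out, "depleted") <- nmr_spectrum(axis, depleted,
                                        label = paste0(spectrum$label, "_depleted"))
  out
}
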