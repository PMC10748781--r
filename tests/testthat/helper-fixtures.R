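# Shared fixture builders. Everything is generated in code; line centres are
# snapped to the acquisition grid (bin centres of the 0.0002 ppm/bin axis)
# so that sub-bin apex aliasing does not blur solver-level checks.

snap <- function(ppm, w = 2e-4) round((ppm - w / 2) / w) * w + w / 2

tiny_axis <- function(start = 0, end = 1, w = 0.01, freq = 600) {
  build_axis(list(c(start, end)), bin_width_ppm = w, frequency_mhz = freq)
}

# acquisition-resolution axis over a narrow range
fine_axis <- function(lo = 0.8, hi = 1.8, freq = 600) {
  build_axis(list(c(lo, hi)), bin_width_ppm = 2e-4, frequency_mhz = freq)
}

# acquisition-resolution axis that also covers the reference singlet at 0 ppm
quant_axis <- function(hi = 2.5, freq = 600) {
  build_axis(list(c(-0.1, hi)), bin_width_ppm = 2e-4, frequency_mhz = freq)
}

singlet_entry <- function(name, center, height = 1, fwhm = 1.2, hw = 0.004,
                          role = "target") {
  metabolite_entry(
    name,
    data.frame(center_ppm = center, rel_height = height, fwhm_hz = fwhm),
    window_halfwidth_ppm = hw, role = role)
}

dss_entry <- function() singlet_entry("DSS", snap(0), height = 12, hw = 0.006)

# library of isolated singlets at the given (snapped) centres plus DSS
singlet_library <- function(centers, heights = rep(1, length(centers)),
                            roles = rep("target", length(centers)),
                            names = sprintf("met_%d", seq_along(centers))) {
  entries <- lapply(seq_along(centers), function(i)
    singlet_entry(names[i], snap(centers[i]), heights[i], role = roles[i]))
  nmr_library(entries, dss_entry(), known_concentration_mM = 0.29)
}

# dense (unbanded) solve of the Whittaker normal equations - the oracle
dense_whittaker <- function(x, w, lam, order = 2L) {
  n <- length(x)
  D <- diff(diag(n), differences = order)
  as.numeric(solve(diag(w, n) + lam * t(D) %*% D, w * x))
}

roughness <- function(x, order = 2L) sum(diff(x, differences = order)^2)
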