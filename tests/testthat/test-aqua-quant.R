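test_that("reporter picking finds the apex, tracks shifts, and flags edges", {
  ax <- fine_axis(1.25, 1.45)
  e <- singlet_entry("s", snap(1.33), hw = 0.006)
  sp <- render_entry(e, ax, 1)
  p <- pick_reporter(sp, e)
  expect_equal(p$picked_ppm, e$reporter_center_ppm, tolerance = 1e-4)
  expect_equal(p$height, 1, tolerance = 1e-12)
  expect_false(p$at_window_edge)

  shifted <- render_entry(e, ax, 1, shift_offset_ppm = 0.005)
  ps <- pick_reporter(shifted, e)
  expect_equal(ps$offset_ppm, 0.005, tolerance = 1.5e-4)

  zero <- nmr_spectrum(ax, numeric(n_bins(ax)))
  pz <- pick_reporter(zero, e)
  expect_equal(pz$height, 0)
  expect_true(pz$at_window_edge)
  expect_equal(pz$picked_ppm, e$reporter_center_ppm, tolerance = 1e-4)

  far <- singlet_entry("far", 9.0)
  expect_error(pick_reporter(sp, far), "outside the axis")
})

test_that("the interference matrix holds analytic cross-talk values", {
  # on-grid centres exactly 0.003 ppm apart
  lib <- singlet_library(c(1.2001, 1.2031), names = c("a", "b"))
  picked <- data.frame(
    metabolite = c("a", "b"),
    picked_ppm = c(lib$entries$a$reporter_center_ppm,
                   lib$entries$b$reporter_center_ppm),
    height = c(1, 1), offset_ppm = c(0, 0),
    at_window_edge = c(FALSE, FALSE), stringsAsFactors = FALSE)
  A <- build_interference_matrix(picked, lib)
  gam <- (1.2 / 600) / 2                      # 0.001 ppm
  tail <- gam^2 / (0.003^2 + gam^2)           # = 0.1 exactly
  expect_equal(diag(A$A), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(A$A["a", "b"], tail, tolerance = 1e-9)
  expect_equal(A$A["b", "a"], tail, tolerance = 1e-9)
})

test_that("well-separated entries give a near-diagonal matrix", {
  lib <- singlet_library(c(1.0, 2.0))
  picked <- data.frame(
    metabolite = library_names(lib),
    picked_ppm = vapply(lib$entries, `[[`, numeric(1), "reporter_center_ppm"),
    height = c(1, 1), offset_ppm = 0, at_window_edge = FALSE,
    stringsAsFactors = FALSE)
  A <- build_interference_matrix(picked, lib)
  expect_lt(max(abs(A$A[upper.tri(A$A)]), abs(A$A[lower.tri(A$A)])),
            1e-5 * min(diag(A$A)))
})

test_that("concentration solving inverts the height model", {
  mkA <- function(M, nms) structure(
    list(names = nms, A = M, condition_estimate = kappa(M)),
    class = "interference_matrix")
  A <- mkA(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))),
           c("a", "b"))
  expect_equal(unname(solve_concentrations(c(2, 2), A)), c(4 / 3, 4 / 3),
               tolerance = 1e-12)
  # scale divides heights before solving
  expect_equal(unname(solve_concentrations(c(4, 4), A, scale = 2)),
               c(4 / 3, 4 / 3), tolerance = 1e-12)
  # round trip on a random well-conditioned 24x24 system
  set.seed(12)
  M <- diag(24) + matrix(runif(576, 0, 0.5 / 24), 24)
  nms <- sprintf("m%02d", 1:24)
  dimnames(M) <- list(nms, nms)
  truth <- runif(24, 0.1, 2)
  got <- solve_concentrations(as.numeric(M %*% truth), mkA(M, nms))
  expect_lt(max(abs(got - truth) / truth), 1e-6)
  # non-negative mode clamps instead of reporting negatives
  h <- c(1, 0.49)   # second height below its own cross-talk share
  A2 <- mkA(matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b"))),
            c("a", "b"))
  plain <- solve_concentrations(h, A2)
  expect_lt(plain[["b"]], 0)
  nn <- solve_concentrations(h, A2, nonneg = TRUE)
  expect_equal(nn[["b"]], 0)
  expect_gte(nn[["a"]], 0)
})

test_that("a singular system is rejected with its condition estimate", {
  M <- matrix(c(1, 1, 1, 1 + 1e-15), 2, dimnames = list(c("a", "b"), c("a", "b")))
  A <- structure(list(names = c("a", "b"), A = M, condition_estimate = kappa(M)),
                 class = "interference_matrix")
  expect_error(solve_concentrations(c(1, 1), A), "singular")
})

test_that("internal-standard calibration returns the spectrum scale factor", {
  ax <- quant_axis(1.0)
  lib <- singlet_library(1.5)    # met off axis is fine; DSS is what matters
  sp <- render_entry(lib$internal_standard, ax, 0.29)
  expect_equal(calibrate_scale(sp, lib), 1, tolerance = 1e-9)
  sp2 <- sp; sp2$intensities <- 2.5 * sp$intensities
  expect_equal(calibrate_scale(sp2, lib), 2.5, tolerance = 1e-9)
  expect_error(calibrate_scale(nmr_spectrum(ax, numeric(n_bins(ax))), lib),
               "not positive")
})

test_that("calibration tolerates a neighbour beyond three linewidths", {
  ax <- quant_axis(1.0)
  lib <- singlet_library(0.5)
  # interferer 4 fwhm (0.008 ppm) from the DSS line
  intruder <- singlet_entry("intruder", snap(0.0081), height = 5)
  sp <- nmr_spectrum(ax, render_entry(lib$internal_standard, ax, 0.29)$intensities +
                       render_entry(intruder, ax, 0.2)$intensities)
  expect_equal(calibrate_scale(sp, lib), 1, tolerance = 0.01)
})

test_that("quantification recovers sparse noiseless panels through the full pipeline", {
  ax <- default_axis()
  lib <- singlet_library(c(1.2, 2.4, 3.6, 6.0, 8.0),
                         heights = c(1, 0.8, 1.2, 0.9, 1.1))
  conc <- stats::setNames(c(0.4, 0.15, 0.8, 0.25, 0.6), library_names(lib))
  full <- c(conc, DSS = 0.29)
  sp <- render_mixture(lib, ax, full)
  # without the baseline stage the inversion is essentially exact
  plain <- aqua_quantify(sp, lib)
  expect_lt(max(abs(plain$concentration_uM - 1000 * conc[plain$metabolite]) /
                  (1000 * conc[plain$metabolite])), 1e-4)
  # the extended pipeline adds the airPLS stage; its baseline sits on the
  # Lorentzian tail floor and the endpoint weight exception grazes the
  # reference singlet, which bounds accuracy at the percent level
  ext <- extended_aqua(sp, lib)
  expect_lt(max(abs(ext$concentration_uM - 1000 * conc[ext$metabolite]) /
                  (1000 * conc[ext$metabolite])), 2.5e-2)
})

test_that("reported concentrations are invariant to the spectrum scale", {
  ax <- default_axis()
  lib <- singlet_library(c(1.2, 3.6))
  sp <- render_mixture(lib, ax, c(met_1 = 0.4, met_2 = 0.7, DSS = 0.29))
  r1 <- extended_aqua(sp, lib)
  sp_k <- sp; sp_k$intensities <- 137.5 * sp$intensities
  r2 <- extended_aqua(sp_k, lib)
  expect_equal(r2$concentration_uM, r1$concentration_uM, tolerance = 1e-6)
  expect_equal(attr(r2, "scale") / attr(r1, "scale"), 137.5, tolerance = 1e-6)
})

test_that("raising one concentration raises its own report monotonically", {
  ax <- quant_axis(3.0)
  lib <- singlet_library(c(1.2, 1.21, 2.0), names = c("a", "b", "c"))
  base <- c(a = 0.3, b = 0.3, c = 0.3, DSS = 0.29)
  up <- base; up["b"] <- 0.6
  r_base <- aqua_quantify(render_mixture(lib, ax, base), lib)
  r_up <- aqua_quantify(render_mixture(lib, ax, up), lib)
  expect_gt(r_up$concentration_uM[r_up$metabolite == "b"],
            r_base$concentration_uM[r_base$metabolite == "b"])
})

test_that("modelling a known interferent improves the overlapped target", {
  ax <- quant_axis(2.0)
  target <- singlet_entry("target", snap(0.96))
  unknown <- singlet_entry("unknown", snap(0.9671), role = "interferent",
                           hw = 0.003)
  with_u <- nmr_library(list(target, unknown), dss_entry(), 0.29)
  without_u <- nmr_library(list(target), dss_entry(), 0.29)
  sp <- nmr_spectrum(ax, render_entry(target, ax, 0.3)$intensities +
                       render_entry(unknown, ax, 0.5)$intensities +
                       render_entry(dss_entry(), ax, 0.29)$intensities)
  err <- function(res) abs(res$concentration_uM[res$metabolite == "target"] - 300)
  expect_lt(err(aqua_quantify(sp, with_u)), err(aqua_quantify(sp, without_u)))
  # the interferent is solved but not reported
  res <- aqua_quantify(sp, with_u)
  expect_false("unknown" %in% res$metabolite)
  all_e <- attr(res, "all_entries")
  expect_equal(all_e$concentration_uM[all_e$metabolite == "unknown"], 500,
               tolerance = 1)
})

test_that("quality flags mark heavy interference and sub-LOQ concentrations", {
  ax <- quant_axis(2.0)
  a <- singlet_entry("a", 1.2001)
  # b's off-reporter line sits 0.0008 ppm from a's reporter: its tail there
  # is 0.9 * 1e-6/(0.64e-6 + 1e-6) = 0.55 of a's unit response, above the
  # 50% off-diagonal flagging threshold; b's own reporter stays clean
  b <- metabolite_entry("b", data.frame(center_ppm = c(1.2009, 1.2501),
                                        rel_height = c(0.9, 1.0),
                                        fwhm_hz = c(1.2, 1.2)),
                        reporter_center_ppm = 1.2501,
                        window_halfwidth_ppm = 0.004)
  lib <- nmr_library(list(a, b), dss_entry(), 0.29)
  sp <- nmr_spectrum(ax, render_entry(a, ax, 0.5)$intensities +
                       render_entry(b, ax, 0.2)$intensities +
                       render_entry(dss_entry(), ax, 0.29)$intensities)
  res <- aqua_quantify(sp, lib)
  expect_match(res$flags[res$metabolite == "a"], "high_interference")
  expect_false(grepl("high_interference", res$flags[res$metabolite == "b"]))
  # LOQ flag via a quiet region: b at 0.2 mM is far above 10 x S/N with
  # noise 1e-4, a third metabolite at trace level is not
  trace <- singlet_entry("trace", 1.9001)
  lib2 <- nmr_library(list(a, b, trace), dss_entry(), 0.29)
  set.seed(31)
  noisy <- nmr_spectrum(ax, sp$intensities +
                          render_entry(trace, ax, 0.001)$intensities +
                          rnorm(n_bins(ax), sd = 1e-3))
  res2 <- aqua_quantify(noisy, lib2, quiet_region = c(1.6, 1.8))
  expect_match(res2$flags[res2$metabolite == "trace"], "below_loq")
  expect_false(grepl("below_loq", res2$flags[res2$metabolite == "b"]))
})
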