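make_tiny_design <- function(lambdas = c(1e6, 1e7)) {
  ax <- quant_axis(2.5)
  lib <- singlet_library(c(1.2, 1.9), names = c("a", "b"))
  cent <- bin_centers(ax)
  bgs <- lapply(c(0.02, 0.01, 0.005), function(s)
    nmr_spectrum(ax, 0.5 * exp(-((cent - 1.5) / (40 * s))^2)))
  names(bgs) <- c("A", "B", "C")
  narrow <- render_mixture(lib, ax, c(a = 0.1, b = 0.1, DSS = 0.29))
  list(design = simulation_design(bgs, narrow,
                                  scaling_levels = 10^seq(0, 1, length.out = 7),
                                  lambdas = lambdas),
       lib = lib, ax = ax)
}

test_that("the simulation design yields a complete 3 x 7 factorial", {
  d <- make_tiny_design()
  sims <- simulate_spectra(d$design)
  expect_length(sims, 21L)
  expect_equal(sort(unique(vapply(sims, `[[`, character(1), "background"))),
               c("A", "B", "C"))
  # elementwise-sum oracle and truth bookkeeping
  s <- sims[[5]]
  expect_equal(s$spectrum$intensities,
               d$design$backgrounds[[s$background]]$intensities +
                 s$level * d$design$narrow_spectrum$intensities,
               tolerance = 1e-12)
  expect_equal(s$truth$intensities,
               s$level * d$design$narrow_spectrum$intensities)
  # a zero level reduces to the bare background
  d0 <- simulation_design(d$design$backgrounds, d$design$narrow_spectrum,
                          scaling_levels = c(0, 1))
  s0 <- simulate_spectra(d0)[[1]]
  expect_equal(s0$spectrum$intensities,
               d$design$backgrounds$A$intensities)
  expect_equal(max(abs(s0$truth$intensities)), 0)
})

test_that("simulation reports cover the metabolite x background x lambda grid", {
  d <- make_tiny_design(lambdas = c(1e6, 1e7))
  rep <- run_simulation_study(d$design, d$lib)
  expect_s3_class(rep, "eval_report")
  expect_equal(nrow(rep), length(library_names(d$lib)) * 3L * 2L)
  # a clean design regresses close to the identity at sensible lambda
  sub <- rep[rep$lambda == 1e7, ]
  expect_true(all(sub$slope > 0.9 & sub$slope < 1.1))
  expect_true(all(sub$r2 > 0.99))
})

test_that("background-free simulation recovers the identity regression", {
  ax <- quant_axis(2.0)
  lib <- singlet_library(1.2, names = "a")
  zero <- nmr_spectrum(ax, numeric(n_bins(ax)))
  narrow <- render_mixture(lib, ax, c(a = 0.1, DSS = 0.29))
  design <- simulation_design(list(A = zero, B = zero, C = zero), narrow,
                              scaling_levels = 10^seq(0, 1, length.out = 7),
                              lambdas = 1e7)
  rep <- run_simulation_study(design, lib)
  a_rows <- rep[rep$metabolite == "a", ]
  expect_true(all(abs(a_rows$slope - 1) < 1e-3))
  expect_true(all(a_rows$r2 > 0.9999))
  expect_true(all(abs(a_rows$intercept) < 1e-3 * max(narrow$intensities)))
})

test_that("ordinary least squares matches the closed-form normal equations", {
  st <- linear_regression(c(1, 2, 3), c(2, 4, 6))
  expect_equal(st$slope, 2); expect_equal(st$intercept, 0); expect_equal(st$r2, 1)
  st0 <- linear_regression(1:5, rep(3, 5))
  expect_equal(st0$slope, 0); expect_equal(st0$r2, 0)
  set.seed(41)
  x <- rnorm(40); y <- 1.7 * x - 0.4 + rnorm(40, sd = 0.3)
  st2 <- linear_regression(x, y)
  beta <- cov(x, y) / var(x)
  alpha <- mean(y) - beta * mean(x)
  expect_equal(st2$slope, beta, tolerance = 1e-12)
  expect_equal(st2$intercept, alpha, tolerance = 1e-12)
  expect_error(linear_regression(rep(1, 5), rnorm(5)), "degenerate")
  # noise-free affine data is recovered to near machine precision
  st3 <- linear_regression(x, 2.5 * x + 1)
  expect_equal(st3$slope, 2.5, tolerance = 1e-10)
  expect_equal(st3$intercept, 1, tolerance = 1e-10)
})

test_that("percent difference and relative intercept follow their formulas", {
  expect_equal(percent_difference(100, 90), 10)
  expect_equal(percent_difference(57, 57), 0)
  expect_error(percent_difference(0, 1), "non-zero")
  set.seed(42)
  for (i in 1:20) {
    r <- runif(1, 1, 100); t <- runif(1, 1, 100); k <- runif(1, 0.1, 10)
    expect_equal(percent_difference(r, t), 100 * abs(r - t) / r)
    expect_equal(percent_difference(k * r, k * t), percent_difference(r, t),
                 tolerance = 1e-12)
  }
  expect_equal(relative_intercept(0, 123), 0)
  expect_equal(relative_intercept(5, 200), 2.5)
  expect_equal(relative_intercept(3 * 5, 200), 3 * relative_intercept(5, 200))
  expect_error(relative_intercept(1, 0), "max_conc")
})

test_that("noise estimation and the 10xS/N quantification limit are consistent", {
  ax <- quant_axis(2.0)
  set.seed(43)
  sp <- nmr_spectrum(ax, rnorm(n_bins(ax), sd = 0.37))
  est <- estimate_noise(sp, c(1.0, 1.1))     # 500 bins
  expect_equal(est, 0.37, tolerance = 0.1 * 0.37)
  expect_error(estimate_noise(sp, c(1.0, 1.001)), "at least 50")

  e <- singlet_entry("s", snap(1.2), height = 100)  # 100 per mM = 0.1 per uM
  expect_equal(loq_concentration(e, noise = 1, scale = 1), 0.1)   # mM = 100 uM
  expect_equal(loq_concentration(e, noise = 2, scale = 1),
               2 * loq_concentration(e, noise = 1, scale = 1))
  expect_equal(loq_concentration(e, noise = 1, scale = 2),
               loq_concentration(e, noise = 1, scale = 1) / 2)
})

test_that("a spike-in study with identical arms regresses onto the identity", {
  ax <- quant_axis(2.5)
  lib <- singlet_library(c(1.2, 1.9), names = c("a", "b"))
  levels_uM <- c(50, 200, 800, 3200)
  mk <- function(i, seed) {
    conc <- c(a = levels_uM[i] / 1000, b = levels_uM[i] / 1000, DSS = 0.29)
    synth_exudate_spectrum(lib, ax, concentrations = conc, noise_sd = 2e-4,
                           seed = seed, label = sprintf("s%d", i))
  }
  sps <- lapply(seq_along(levels_uM), function(i) mk(i, 500 + i))
  truth <- data.frame(metabolite = c("a", "b"),
                      t(replicate(2, levels_uM)))
  rep <- run_spikein_study(sps, sps, truth, lib)
  # arms share spectra; the only difference is the airPLS stage of the
  # matrix arm, which perturbs heights at the low-percent level
  expect_true(all(abs(rep$slope - 1) < 0.03))
  expect_true(all(rep$r2 > 0.999))
  expect_true(all(abs(rep$relative_intercept_pct) < 0.5))
  expect_true(all(rep$mean_pct_difference < 5))
  expect_error(run_spikein_study(sps, sps[-1], truth, lib), "paired")
})

test_that("an injected 16% matrix bias surfaces as a 1.16 slope", {
  ax <- quant_axis(2.5)
  lib <- singlet_library(c(1.2, 1.9), names = c("a", "b"))
  levels_uM <- c(50, 200, 800, 3200)
  mk <- function(i, bias_a) {
    conc <- c(a = bias_a * levels_uM[i] / 1000, b = levels_uM[i] / 1000,
              DSS = 0.29)
    synth_exudate_spectrum(lib, ax, concentrations = conc, noise_sd = 2e-4,
                           seed = 700 + i, label = sprintf("s%d", i))
  }
  mats <- lapply(seq_along(levels_uM), function(i) mk(i, 1.16))
  blks <- lapply(seq_along(levels_uM), function(i) mk(i, 1.00))
  truth <- data.frame(metabolite = c("a", "b"), t(replicate(2, levels_uM)))
  rep <- run_spikein_study(mats, blks, truth, lib)
  slope_a <- rep$slope[rep$metabolite == "a"]
  slope_b <- rep$slope[rep$metabolite == "b"]
  expect_equal(slope_a / slope_b, 1.16, tolerance = 0.02)
  expect_gt(rep$mean_pct_difference[rep$metabolite == "a"], 10)
})
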