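test_that("fold enhancement is the ratio of integrated spectra", {
  wl <- seq(500, 800, by = 2)
  band <- exp(-((wl - 610) / 30)^2)
  s1 <- emission_spectrum(wl, band)
  expect_equal(fold_enhancement(s1, s1), 1.0)
  s2 <- emission_spectrum(wl, 2 * band)
  expect_equal(fold_enhancement(s1, s2), 2.0)
  expect_error(fold_enhancement(s1, emission_spectrum(wl + 1, band)),
               "grid")
  ## generator with I_bound/I_free = 4 driven to saturation
  cfg <- sim_config(seed = 12, emission_noise = 0)
  sim <- gen_titration_series(cfg, Ka = 1e7, I_free = 5e7, I_bound = 2e8,
                              dna_conc = c(0, 1e-6, 1e-5, 1e-4, 1e-3))
  enh <- fold_enhancement(sim$spectra[[1]], sim$spectra[[5]])
  expect_equal(enh, 4.0, tolerance = 0.02)
})

test_that("mole-ratio breakpoints land at the constructed knee", {
  dye <- 2e-6
  x <- seq(0, 4e-6, length.out = 13)
  ## knee at [DNA]/[dye] = 0.5: two dyes per quadruplex motif
  y1 <- ifelse(x < 1e-6, x / 1e-6, 1)
  mr1 <- mole_ratio_stoichiometry(binding_curve(x, 1 + 3 * y1), dye)
  expect_true(mr1$has_breakpoint)
  expect_equal(mr1$breakpoint, 0.5, tolerance = 0.02)

  ## knee at ratio 2.5: one dye per five bases, curve in base units
  xb <- seq(0, 2e-5, length.out = 13)
  y2 <- pmin(xb / 5e-6, 1)
  mr2 <- mole_ratio_stoichiometry(binding_curve(xb, 10 + 2 * y2), dye)
  expect_equal(mr2$breakpoint, 2.5, tolerance = 0.05)

  ## strictly linear data: no breakpoint
  mr3 <- mole_ratio_stoichiometry(binding_curve(x, 2 + 5e6 * x), dye)
  expect_false(mr3$has_breakpoint)
  expect_true(is.na(mr3$breakpoint))

  ## invariance under affine rescaling of the signal
  mr4 <- mole_ratio_stoichiometry(binding_curve(x, 7 - 3 * (1 + 3 * y1)),
                                  dye)
  expect_equal(mr4$knee_x, mr1$knee_x, tolerance = 1e-3)
})

test_that("the exact 1:1 mass balance has the closed-form bound fraction", {
  Ka <- 1e6
  ## D = L = 1/Ka gives bound fraction (3 - sqrt(5))/2
  x <- bound_1to1(1 / Ka, 1 / Ka, Ka)
  expect_equal(x * Ka, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  ## limits
  expect_equal(bound_1to1(0, 2e-6, Ka), 0)
  expect_lt(bound_1to1(1e-3, 2e-6, 1e9) / 2e-6, 1 + 1e-9)
})

test_that("1:1 binding fits recover Ka and satisfy first-order optimality", {
  ## noiseless curve: Ka back to within 1 %
  dye <- 2e-6
  D <- c(0, dye * c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5, 8, 15))
  y <- flprobe:::signal_1to1(D, dye, 1e6, 1, 4)
  bf <- fit_1to1(binding_curve(D, y), dye)
  expect_lt(abs(bf$Ka - 1e6) / 1e6, 0.01)
  expect_true(bf$converged)

  ## residuals orthogonal to the model gradient at the optimum
  g <- function(p) flprobe:::signal_1to1(D, dye, 10^p[1], p[2], p[3])
  p0 <- c(bf$log10Ka, bf$I_free, bf$I_bound)
  J <- vapply(1:3, function(i) {
    h <- pmax(abs(p0[i]), 1e-3) * 1e-6
    e <- numeric(3); e[i] <- h
    (g(p0 + e) - g(p0 - e)) / (2 * h)
  }, numeric(length(D)))
  expect_lt(max(abs(crossprod(J, y - g(p0)))) /
              max(abs(crossprod(J, y))), 1e-4)

  ## motif conversion: curve in base units, 5 bases per motif
  y5 <- flprobe:::signal_1to1(D, dye, 1e6, 1, 4)
  bf5 <- fit_1to1(binding_curve(D * 5, y5), dye, motif_size = 5)
  expect_lt(abs(bf5$Ka - 1e6) / 1e6, 0.01)
})

test_that("the stoichiometric limit of the 1:1 model is the mole-ratio knee", {
  dye <- 2e-6
  D <- seq(0, 6e-6, length.out = 25)
  y <- flprobe:::signal_1to1(D, dye, 1e12, 1, 4)
  mr <- mole_ratio_stoichiometry(binding_curve(D, y), dye)
  expect_true(mr$has_breakpoint)
  expect_equal(mr$breakpoint, 1.0, tolerance = 0.05)
})

test_that("saturated-only curves flag Ka as a lower bound", {
  dye <- 2e-6
  D <- dye * c(0, 50, 100, 200, 400, 800)
  y <- flprobe:::signal_1to1(D, dye, 1e8, 1, 4)
  expect_warning(bf <- fit_1to1(binding_curve(D, y), dye), "lower bound")
  expect_true(bf$lower_bound_only)
})

test_that("Beer-Lambert concentrations use the tabulated coefficients", {
  expect_equal(concentration_from_absorbance(0, 6600), 0)
  tab <- oligo_table()
  expect_equal(concentration_from_absorbance(0.1433, tab$TBA$epsilon, 1),
               1.0e-6, tolerance = 1e-9)
  ## doubling the path halves the concentration
  expect_equal(concentration_from_absorbance(0.5, 8910, 2),
               concentration_from_absorbance(0.5, 8910, 1) / 2)
  expect_error(concentration_from_absorbance(-0.1, 6600), "non-negative")
})
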