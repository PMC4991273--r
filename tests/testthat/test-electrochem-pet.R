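test_that("redox extraction finds midpoints and peak ratios", {
  cfg <- sim_config(seed = 3)
  ## reversible Nernstian pair at E0 = -0.30 V
  v <- gen_voltammogram(-0.30, 0.1, cfg)
  r <- extract_redox(v)
  expect_true(r$reversible)
  expect_equal(r$E_mid, -0.30, tolerance = 0.005)
  expect_lt(abs((r$E_pa - r$E_pc) - 0.059), 0.005)
  expect_equal(r$peak_ratio, 1.00, tolerance = 0.01)
  ## midpoint arithmetic on an asymmetric-looking pair
  expect_equal((0.10 + 0.04) / 2, 0.07)
  ## invariance under current scaling; translation moves E_mid equally
  v2 <- voltammogram(v$potential, 3.7 * v$current, v$scan_rate)
  expect_equal(extract_redox(v2)$E_mid, r$E_mid)
  v3 <- voltammogram(v$potential + 0.25, v$current, v$scan_rate)
  expect_equal(extract_redox(v3)$E_mid, r$E_mid + 0.25, tolerance = 1e-9)
})

test_that("single-wave processes are reported as irreversible", {
  cfg <- sim_config(seed = 3)
  v <- gen_voltammogram(1.2, 0.1, cfg, reversible = FALSE)
  r <- extract_redox(v)
  expect_false(r$reversible)
  expect_equal(r$E_pa, 1.2 + 0.059 / 2, tolerance = 0.005)
  expect_true(is.na(r$E_mid))
})

test_that("scan-rate diagnostics see sqrt(rate) scaling and constant E_mid", {
  cfg <- sim_config(seed = 5)
  nus <- c(0.025, 0.05, 0.1, 0.2, 0.4)
  vs <- lapply(nus, function(nu) gen_voltammogram(-0.30, nu, cfg))
  d <- scan_rate_diagnostics(vs)
  expect_gt(d$peak_current$r_squared, 0.999)
  expect_equal(d$peak_current$intercept, 0, tolerance = 1e-8)
  expect_lt(d$E_mid_range, 0.005)
  expect_lt(d$peak_ratio_range, 0.01)
  expect_error(scan_rate_diagnostics(vs[1:2]), ">= 3")
})

test_that("ferrocene-to-NHE referencing adds exactly +0.64 V", {
  expect_equal(reference_to_nhe(0), 0.64)
  expect_equal(reference_to_nhe(-0.64), 0)
  x <- seq(-2, 2, by = 0.25)
  expect_equal(reference_to_nhe(x) - 0.64, x)
})

test_that("Rehm-Weller free energies and the 0-0 energy behave as stated", {
  ## boundary: potential gap equal to the excitation energy
  rw0 <- rehm_weller_dG(E_ox_donor = 1.3, E_red_acceptor = -0.9,
                        dG00 = 2.2)
  expect_equal(rw0$dG, 0)
  expect_equal(rw0$verdict, "boundary")
  ## guanine donor vs the dye core acceptor
  rw <- rehm_weller_dG(E_red_acceptor = -0.61, dG00 = 2.20)
  expect_equal(rw$dG, -0.29, tolerance = 1e-12)
  expect_true(rw$favourable)
  ## affine with unit slopes (finite differences)
  h <- 1e-4
  base <- rehm_weller_dG(1.3, -0.5, 2.0, 0.1)$dG
  expect_equal((rehm_weller_dG(1.3 + h, -0.5, 2.0, 0.1)$dG - base) / h, 1,
               tolerance = 1e-6)
  expect_equal((rehm_weller_dG(1.3, -0.5 + h, 2.0, 0.1)$dG - base) / h,
               -1, tolerance = 1e-6)
  expect_equal((rehm_weller_dG(1.3, -0.5, 2.0 + h, 0.1)$dG - base) / h,
               -1, tolerance = 1e-6)

  ## 0-0 energy from the mean of absorption and emission maxima
  expect_equal(zero_zero_energy(620, 620), 1239.84 / 620)
  expect_equal(zero_zero_energy(500, 600), 1239.84 / 550)
  expect_gt(zero_zero_energy(500, 600), zero_zero_energy(510, 600))
  expect_error(zero_zero_energy(-1, 600), "positive")
})

test_that("thermodynamic-cycle potentials reference to NHE at 4.4 V", {
  expect_equal(thermo_cycle_potential(dG_gas = -4.4), 0)
  expect_equal(thermo_cycle_potential(dG_gas = -5.0), 0.60)
  ## equal solvation terms cancel
  expect_equal(thermo_cycle_potential(-4.8, dG_solv_initial = -1.3,
                                      dG_solv_final = -1.3),
               thermo_cycle_potential(-4.8))
  ## two-electron process divides the driving force
  expect_equal(thermo_cycle_potential(-10, n = 2), 0.6)
})

test_that("the CV-to-PET chain predicts quenching for the dye cores", {
  ## literature effective reduction potentials of the two cores, vs NHE
  cfg <- sim_config(seed = 9)
  dg00 <- zero_zero_energy(520, 580)
  for (E_nhe in c(-0.26, -0.61)) {
    v <- gen_voltammogram(E_nhe - 0.64, 0.1, cfg)  # recorded vs Fc+/Fc
    E_mid_nhe <- reference_to_nhe(extract_redox(v)$E_mid)
    expect_equal(E_mid_nhe, E_nhe, tolerance = 0.005)
    rw <- rehm_weller_dG(E_red_acceptor = E_mid_nhe, dG00 = dg00)
    expect_true(rw$favourable)
  }
})
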