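test_that("noiseless mono-exponential decays are recovered to optimizer tolerance", {
  cfg <- sim_config(seed = 1, n = 256)
  irf <- gen_irf(cfg)
  tr <- noiseless_decay(multiexp_params(tau = 15.8, scale = 1), irf)
  fit <- fit_single(tr, irf, ncomp = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$tau - 15.8) / 15.8, 1e-3)
  expect_lt(fit$chisq_r, 0.01)  # only count rounding remains
})

test_that("Poisson-noise mono-exponential fits recover the lifetime within 2 %", {
  res <- vapply(1:5, function(seed) {
    cfg <- sim_config(seed = seed, n = 256)
    irf <- gen_irf(cfg)
    tr <- gen_decay(multiexp_params(tau = 15.8, scale = 1), irf, cfg)
    fit <- fit_single(tr, irf, ncomp = 1)
    expect_true(fit$converged)
    c((fit$params$tau - 15.8) / 15.8, fit$chisq_r)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])), 0.02)
  ## a correct model is accepted on average (individual seeds fluctuate
  ## within the chi-square sampling distribution)
  expect_lt(mean(res[2, ]), chisq_acceptance(v = 200))
  expect_true(all(res[2, ] > 0.8 & res[2, ] < 1.4))
})

test_that("an under-specified model is flagged by the chi-square acceptance", {
  cfg <- sim_config(seed = 2, n = 256)
  irf <- gen_irf(cfg)
  tr <- gen_decay(multiexp_params(tau = c(2, 10), alpha = c(0.5, 0.5),
                                  scale = 1), irf, cfg)
  fit1 <- fit_single(tr, irf, ncomp = 1)
  v <- length(fit1$window) - fit1$n_free
  expect_gt(fit1$chisq_r, chisq_acceptance(v = v))
  fit2 <- fit_single(tr, irf, ncomp = 2)
  expect_lt(fit2$chisq_r, 1.3)
})

test_that("global analysis shares lifetimes and recovers the truth", {
  sim <- tri_sim(seed = 31)
  fit <- fit_global(sim$series, ncomp = 3, fixed_free_dye_tau = 1.3)
  expect_true(fit$converged)
  ## fixed lifetime is untouched; lifetimes come back sorted
  expect_equal(fit$shared_tau[1], 1.3)
  expect_true(fit$fixed_mask[1])
  expect_false(is.unsorted(fit$shared_tau))
  ## bound lifetimes recovered (single-seed sanity; the 20-seed bias
  ## study lives in the acceptance suite)
  expect_lt(abs(fit$shared_tau[2] - 6) / 6, 0.10)
  expect_lt(abs(fit$shared_tau[3] - 12) / 12, 0.10)
  ## bookkeeping: p = 2 free tau + 8 x (3 coefficients + shift)
  expect_equal(fit$p, 2 + 8 * 4)
  expect_equal(fit$v, 200 * 8)
  ## per-trace amplitude simplex
  for (s in fit$per_trace) {
    expect_equal(sum(s$alpha), 1, tolerance = 1e-9)
    expect_equal(sum(s$f), 1, tolerance = 1e-9)
  }
})

test_that("free-dye fractional contribution falls as DNA is titrated in", {
  sim <- tri_sim(seed = 8)
  fit <- fit_global(sim$series, ncomp = 3, fixed_free_dye_tau = 1.3)
  f_free <- vapply(fit$per_trace, function(s) s$f[1], 0)
  expect_true(all(diff(f_free) < 0.02))
  expect_gt(f_free[1] - f_free[length(f_free)], 0.5)
})

test_that("a degenerate series of identical traces matches the single fit", {
  cfg <- sim_config(seed = 4, n = 256)
  irf <- gen_irf(cfg)
  tr <- gen_decay(multiexp_params(tau = c(1.28, 5), alpha = c(0.4, 0.6),
                                  scale = 1), irf, cfg)
  series <- titration_series(list(tr, tr, tr), irf, c(0, 0, 0))
  gf <- fit_global(series, ncomp = 2, fixed_free_dye_tau = 1.28)
  sf <- fit_single(tr, irf, ncomp = 2, fixed_tau = 1.28)
  expect_equal(gf$global_chisq_r, sf$chisq_r, tolerance = 0.01)
  expect_equal(gf$shared_tau[2], sf$params$tau[2], tolerance = 1e-3)
})

test_that("trace order does not change the shared lifetimes", {
  cfg <- sim_config(seed = 9, n = 256)
  irf <- gen_irf(cfg)
  mk <- function(seed, a2)
    gen_decay(multiexp_params(tau = c(1.28, 5), alpha = c(1 - a2, a2),
                              scale = 1), irf, cfg, seed = seed)
  trs <- list(mk(11, 0.2), mk(12, 0.5), mk(13, 0.8))
  f1 <- fit_global(titration_series(trs, irf, c(0, 0, 0)),
                   ncomp = 2, fixed_free_dye_tau = 1.28)
  f2 <- fit_global(titration_series(rev(trs), irf, c(0, 0, 0)),
                   ncomp = 2, fixed_free_dye_tau = 1.28)
  expect_equal(f1$shared_tau, f2$shared_tau, tolerance = 1e-4)
})

test_that("linking lifetimes never beats trace-by-trace fits on total SSR", {
  sim <- tri_sim(seed = 21, tau_bound = 6, n = 256)
  series <- sim$series
  gf <- fit_global(series, ncomp = 2, fixed_free_dye_tau = 1.3)
  indiv <- sum(vapply(series$traces, function(tr) {
    f <- fit_single(tr, irf = series$irf, ncomp = 2, fixed_tau = 1.3)
    dof <- length(f$window) - f$n_free
    f$chisq_r * dof
  }, 0))
  expect_gte(gf$total_ssr * (1 + 1e-6), indiv)
})

test_that("degenerate inputs are rejected with informative errors", {
  cfg <- sim_config(seed = 1, n = 256, peak_counts = 150)
  irf <- gen_irf(cfg)
  tiny <- gen_decay(multiexp_params(tau = 4, scale = 1), irf, cfg)
  expect_warning(fit_single(tiny, irf, ncomp = 1), "peak counts")
  expect_error(fit_global(titration_series(list(tiny, tiny), irf,
                                           c(0, 0)),
                          ncomp = 2, fixed_free_dye_tau = -1),
               "positive")
})
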