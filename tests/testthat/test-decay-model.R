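test_that("multi-exponential decay law evaluates term by term", {
  ax <- time_axis(t0 = 0, dt = 1, n = 16)

  ## mono-exponential anchors: I(0) = I0, I(tau) = I0/e
  mono <- multiexp_params(tau = 5, scale = 100)
  y <- evaluate_multiexp(mono, ax)
  expect_equal(y[1], 100)
  expect_equal(y[6], 100 * exp(-1))

  ## tri-exponential at t = 1.3 ns against direct arithmetic
  p <- multiexp_params(tau = c(1.3, 3.7, 10), alpha = c(0.90, 0.07, 0.03),
                       scale = 1)
  ax2 <- time_axis(t0 = 0, dt = 1.3, n = 8)
  direct <- 0.90 * exp(-1.3 / 1.3) + 0.07 * exp(-1.3 / 3.7) +
    0.03 * exp(-1.3 / 10)
  expect_equal(evaluate_multiexp(p, ax2)[2], direct, tolerance = 1e-12)

  ## non-negative and monotone decreasing for t >= 0
  expect_true(all(y >= 0))
  expect_true(all(diff(y) < 0))

  ## amplitude given for components 2..n implies the first
  p2 <- multiexp_params(tau = c(1, 2, 3), alpha = c(0.07, 0.03))
  expect_equal(p2$alpha, c(0.90, 0.07, 0.03))

  expect_error(multiexp_params(tau = c(1, -2)), "positive")
  expect_error(multiexp_params(tau = 1, alpha = 0.5), "sum to 1")
})

test_that("equal lifetimes collapse any ncomp to the mono-exponential", {
  ax <- time_axis(dt = 0.2, n = 64)
  y1 <- evaluate_multiexp(multiexp_params(tau = 3, scale = 7), ax)
  y3 <- evaluate_multiexp(
    multiexp_params(tau = c(3, 3, 3), alpha = c(0.2, 0.5, 0.3),
                    scale = 7), ax)
  expect_equal(y3, y1, tolerance = 1e-12)
})

test_that("reconvolution matches the brute-force convolution oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(32:96, 1)
    ax <- time_axis(dt = 0.1, n = n)
    h <- stats::dnorm(axis_times(ax), mean = stats::runif(1, 0.5, 2),
                      sd = stats::runif(1, 0.05, 0.3)) +
      stats::runif(n, 0, 1e-4)
    irf <- instrument_response(ax, h)
    p <- multiexp_params(
      tau = sort(stats::runif(3, 0.3, 8)),
      alpha = c(d <- stats::runif(3), d)[1:3] / sum(d),
      scale = stats::runif(1, 10, 1e4))
    m <- evaluate_multiexp(p, ax)
    got <- reconvolve(m, irf)
    want <- direct_conv(h, m)
    expect_lt(max(abs(got - want)) / max(want), 1e-10)
  }
})

test_that("delta-kernel reconvolution is the identity and shifts invert", {
  ax <- time_axis(dt = 0.1, n = 64)
  delta <- numeric(64); delta[1] <- 1
  irf <- instrument_response(ax, delta)
  m <- evaluate_multiexp(multiexp_params(tau = 2, scale = 50), ax)
  expect_equal(reconvolve(m, irf), m, tolerance = 1e-12)

  ## shifting a smooth IRF by +s then -s returns it: exactly for
  ## whole-channel shifts, to interpolation tolerance for sub-channel ones
  g <- instrument_response(ax, stats::dnorm(axis_times(ax), 2, 0.4))
  once <- instrument_response(ax, flprobe:::shift_irf_counts(g, 0.2))
  back <- flprobe:::shift_irf_counts(once, -0.2)
  keep <- 5:60
  expect_equal(back[keep], g$counts[keep], tolerance = 1e-12)
  once_f <- instrument_response(ax, flprobe:::shift_irf_counts(g, 0.13))
  back_f <- flprobe:::shift_irf_counts(once_f, -0.13)
  expect_lt(max(abs(back_f - g$counts)) / max(g$counts), 0.02)

  expect_error(reconvolve(m[1:10], irf), "axis")
})

test_that("fractional intensities and average lifetime are amplitude-weighted", {
  expect_equal(fractional_intensities(1, 4.2), 1)
  expect_equal(fractional_intensities(c(0.5, 0.5), c(2, 2)), c(0.5, 0.5))

  ## free-dye bi-exponential: alpha = (0.974, 0.026), tau = (1.3, 3.7) ns
  ## gives f = (0.929, 0.071) (printed rounding makes these 93 % / 8 %)
  f <- fractional_intensities(c(0.974, 0.026), c(1.3, 3.7))
  expect_equal(f, c(0.92936, 0.07064), tolerance = 1e-4)
  expect_equal(sum(f), 1)

  expect_equal(average_lifetime(1, 15.8), 15.8)
  expect_equal(average_lifetime(c(0.5, 0.5), c(2, 4)), 3.0)
  expect_equal(average_lifetime(c(0.9, 0.1), c(1, 11)), 2.0)

  ## permutation invariance
  perm <- c(2, 3, 1)
  a <- c(0.6, 0.3, 0.1); tau <- c(1, 4, 9)
  expect_equal(sort(fractional_intensities(a[perm], tau[perm])),
               sort(fractional_intensities(a, tau)))
  expect_equal(average_lifetime(a[perm], tau[perm]),
               average_lifetime(a, tau))

  expect_error(fractional_intensities(c(0, 0), c(1, 2)), "sum to 1")
})

test_that("reduced chi-square reproduces a hand-computed weighted sum", {
  y <- c(100, 50, 25, 12)
  m <- c(90, 55, 20, 15)
  ## sum((y-m)^2/y) = 1 + 0.5 + 1 + 0.75 = 3.25; dof = 4 - 1
  expect_equal(reduced_chisq(y, m, n_free = 1), 3.25 / 3)
  expect_equal(reduced_chisq(y, y, n_free = 1), 0)

  ## constant data with a fixed residual ratio: chisq_r is window-size
  ## independent when no parameters are charged to the window
  yc <- rep(100, 40)
  mc <- yc * 1.03
  full <- reduced_chisq(yc, mc, n_free = 0)
  half <- reduced_chisq(yc, mc, n_free = 0, window = 1:20)
  expect_equal(full, half)

  expect_error(reduced_chisq(y, m, n_free = 4), "freedom")
})
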