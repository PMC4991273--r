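## shared fixtures, all generated in code

## independent O(n^2) causal convolution oracle: out[k] = sum_j h[j] m[k-j+1]
## with the kernel normalised to unit sum (mirrors the reconvolution
## contract but by brute-force summation)
direct_conv <- function(h, m) {
  h <- h / sum(h)
  n <- length(m)
  out <- numeric(n)
  for (k in seq_len(n))
    for (j in seq_len(k))
      out[k] <- out[k] + h[j] * m[k - j + 1]
  out
}

## noiseless decay trace: reconvolved model rounded to integer counts
noiseless_decay <- function(params, irf, peak = 1e4) {
  m <- reconvolve(evaluate_multiexp(params, irf$axis), irf,
                  shift = params$shift)
  decay_trace(irf$axis, round(m * peak / max(m)))
}

## standard full-scale simulated titration (8 traces, 10^4 peak counts)
tri_sim <- function(seed, Ka = 1e6, tau_bound = c(6, 12), n = 768,
                    peak = 1e4) {
  gen_titration_series(sim_config(seed = seed, n = n, peak_counts = peak),
                       Ka = Ka, tau_free = 1.3, tau_bound = tau_bound)
}

## compact bi-exponential series for fast statistics simulations:
## 3 traces, single free bound lifetime, no prompt-shift fitting
biexp_series <- function(seed, tau2 = 4, n = 256, peak = 1e4) {
  cfg <- sim_config(seed = seed, n = n, peak_counts = peak)
  gen_titration_series(cfg, Ka = 1e6, tau_free = 1.28, tau_bound = tau2,
                       bound_weights = 1,
                       dna_conc = c(0, 1e-6, 4e-6))$series
}

## 12-point emission binding curve with multiplicative noise
noisy_binding_curve <- function(Ka, dye = 2e-6, noise = 0.02,
                                i_free = 1, i_bound = 4) {
  D <- c(0, dye * c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5, 8, 15))
  x <- bound_1to1(D, dye, Ka)
  y <- (i_free * (dye - x) + i_bound * x) *
    (1 + noise * stats::rnorm(length(D)))
  binding_curve(D, pmax(y, 0))
}
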