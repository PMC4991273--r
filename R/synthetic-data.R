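#' Simulation configuration
#'
#' Collects the acquisition conditions emulated by the synthetic-data
#' generators: a ~200 ps excitation/detection response, 55 ps channels
#' (220 ps available for the coarse-timing case), and decays accumulated
#' to 10 000 counts in the peak channel.
#'
#' @param seed RNG seed for every stochastic generator.
#' @param irf_fwhm IRF full width at half maximum (ns); default 0.2.
#' @param dt channel width (ns); default 0.055.
#' @param n number of channels; default 512.
#' @param t0 time origin (ns).
#' @param irf_center centre of the Gaussian IRF (ns); default 1.0.
#' @param peak_counts target counts in the decay peak channel; default
#'   10000, minimum 100.
#' @param emission_noise multiplicative Gaussian noise on emission
#'   spectra (relative sd); default 0.02.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1, irf_fwhm = 0.2, dt = 0.055, n = 512,
                       t0 = 0, irf_center = 1.0, peak_counts = 10000,
                       emission_noise = 0.02) {
  if (peak_counts < 100) stop("'peak_counts' must be >= 100")
  structure(list(seed = as.integer(seed), irf_fwhm = irf_fwhm, dt = dt,
                 n = as.integer(n), t0 = t0, irf_center = irf_center,
                 peak_counts = peak_counts,
                 emission_noise = emission_noise),
            class = "sim_config")
}

## evaluate code under a local seed, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Generate a Gaussian instrument response
#'
#' A discretised Gaussian of the configured FWHM, centred at
#' \code{cfg$irf_center}, normalised to unit total (a stand-in for a
#' scatterer-measured IRF; a file-based IRF can be substituted anywhere
#' one is accepted). Deterministic: the seed plays no role.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An \code{\link{instrument_response}}.
#' @export
gen_irf <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$irf_fwhm <= cfg$dt / 2)
    stop("IRF fwhm must exceed dt/2 for a resolvable response")
  ax <- time_axis(t0 = cfg$t0, dt = cfg$dt, n = cfg$n)
  t <- axis_times(ax)
  sigma <- cfg$irf_fwhm / (2 * sqrt(2 * log(2)))
  y <- exp(-0.5 * ((t - cfg$irf_center) / sigma)^2)
  instrument_response(ax, y / sum(y))
}

#' Generate one Poisson-noise TCSPC decay
#'
#' Reconvolves the ground-truth decay law with the IRF, scales the
#' expected curve so its peak equals \code{cfg$peak_counts}, and draws
#' Poisson counts per channel.
#'
#' @param truth a \code{\link{multiexp_params}} ground truth (its
#'   \code{scale} is overridden by the peak-count normalisation; its
#'   \code{shift} and \code{background} are honoured).
#' @param irf an \code{\link{instrument_response}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param seed RNG seed; default \code{cfg$seed}. Use \code{NA} to draw
#'   from the current RNG stream (for sequential generation inside a
#'   larger seeded simulation).
#' @param label,meta passed to \code{\link{decay_trace}}.
#' @return A \code{\link{decay_trace}}.
#' @export
gen_decay <- function(truth, irf, cfg, seed = cfg$seed, label = "",
                      meta = list()) {
  stopifnot(inherits(truth, "multiexp_params"),
            inherits(irf, "instrument_response"),
            inherits(cfg, "sim_config"))
  shape <- reconvolve(evaluate_multiexp(truth, irf$axis), irf,
                      shift = truth$shift)
  expected <- shape * (cfg$peak_counts - truth$background) / max(shape) +
    truth$background
  counts <- with_local_seed(seed, stats::rpois(length(expected), expected))
  decay_trace(irf$axis, counts, label = label, meta = meta)
}

#' Generate a full lifetime + emission titration with known ground truth
#'
#' Emulates a DNA titration of a fluorescent dye: the bound fraction at
#' each DNA concentration follows the exact 1:1 binding-motif equilibrium
#' (\code{\link{bound_1to1}}); decay amplitudes are partitioned between
#' the free-dye lifetime and one or two bound-state lifetimes in
#' proportion to the bound fraction; each decay is reconvolved, scaled to
#' the target peak counts and Poisson-sampled. A matching set of emission
#' spectra (Gaussian band, brightness interpolating between free and
#' bound dye, multiplicative noise) is produced for the steady-state
#' analysis chain.
#'
#' @param cfg a \code{\link{sim_config}}; \code{cfg$seed} fixes the whole
#'   series.
#' @param Ka association constant (1/M, motif units).
#' @param dye_conc dye concentration (mol/L); default 2e-6.
#' @param dna_conc motif concentrations (mol/L), non-decreasing, first
#'   usually 0; default an 8-point ladder to ~8x dye.
#' @param tau_free free-dye lifetime (ns); default 1.28.
#' @param tau_bound bound-state lifetime(s) (ns), length 1 or 2; default
#'   c(6, 12).
#' @param bound_weights split of the bound amplitude across the bound
#'   lifetimes; default c(0.45, 0.55).
#' @param I_free,I_bound emission brightness coefficients (a.u. per M).
#' @param em_center,em_sd emission band centre and width (nm).
#' @return A list: \code{series} (a \code{\link{titration_series}}),
#'   \code{spectra} (list of \code{\link{emission_spectrum}}),
#'   \code{irf}, and \code{truth} (Ka, lifetimes, per-point amplitudes
#'   and bound fractions, brightness coefficients).
#' @export
gen_titration_series <- function(cfg, Ka = 1e6, dye_conc = 2e-6,
                                 dna_conc = NULL,
                                 tau_free = 1.28, tau_bound = c(6, 12),
                                 bound_weights = c(0.45, 0.55),
                                 I_free = 5e7, I_bound = 2e8,
                                 em_center = 609, em_sd = 28) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(dna_conc))
    dna_conc <- dye_conc * c(0, 0.25, 0.5, 1, 2, 4, 8, 16) / 2
  if (is.unsorted(dna_conc))
    stop("'dna_conc' must be non-decreasing")
  nb <- length(tau_bound)
  if (!nb %in% 1:2) stop("1 or 2 bound lifetimes supported")
  bound_weights <- bound_weights[seq_len(nb)]
  bound_weights <- bound_weights / sum(bound_weights)
  irf <- gen_irf(cfg)
  x <- bound_1to1(dna_conc, dye_conc, Ka)
  fb <- x / dye_conc
  alphas <- lapply(fb, function(fbi)
    c(1 - fbi, fbi * bound_weights))
  taus <- c(tau_free, tau_bound)
  wl <- seq(500, 800, by = 2)
  out <- with_local_seed(cfg$seed, {
    traces <- vector("list", length(dna_conc))
    spectra <- vector("list", length(dna_conc))
    band <- exp(-0.5 * ((wl - em_center) / em_sd)^2)
    for (i in seq_along(dna_conc)) {
      truth_i <- multiexp_params(tau = taus, alpha = alphas[[i]],
                                 scale = 1)
      traces[[i]] <- gen_decay(truth_i, irf, cfg, seed = NA,
                               label = sprintf("point%02d", i),
                               meta = list(dna_conc_M = dna_conc[i]))
      amp <- I_free * (dye_conc - x[i]) + I_bound * x[i]
      noise <- 1 + cfg$emission_noise * stats::rnorm(length(wl))
      spectra[[i]] <- emission_spectrum(
        wl, pmax(amp * band * noise, 0),
        dna_conc = dna_conc[i], dye_conc = dye_conc)
    }
    list(traces = traces, spectra = spectra)
  })
  series <- titration_series(out$traces, irf, dna_conc,
                             dye_conc = dye_conc)
  list(series = series, spectra = out$spectra, irf = irf,
       truth = list(Ka = Ka, dye_conc = dye_conc, dna_conc = dna_conc,
                    tau = taus, alpha = alphas, bound_fraction = fb,
                    I_free = I_free, I_bound = I_bound))
}

#' Generate a reversible cyclic voltammogram
#'
#' Parametric reversible peak-pair template: forward and reverse linear
#' sweeps with baseline-free Gaussian waves centred at
#' \eqn{E_0 \pm \Delta E_p/2} (\eqn{\Delta E_p = 59/n} mV) and peak
#' currents scaling with the square root of the scan rate
#' (Randles-Sevcik behaviour). Sufficient for exercising peak extraction
#' without a digital electrochemistry simulator.
#'
#' @param E0 formal potential (V).
#' @param scan_rate scan rate (V/s).
#' @param cfg a \code{\link{sim_config}} (seed used when \code{noise_sd >
#'   0}).
#' @param window sweep window (V); must contain \code{E0 +/- 0.2}.
#' @param n_electrons electrons transferred (sets the peak separation).
#' @param ip_coef peak-current coefficient (A per sqrt(V/s)).
#' @param peak_width Gaussian wave width (V).
#' @param ipa_over_ipc anodic/cathodic peak-current ratio of the
#'   template; default 1 (symmetric).
#' @param reversible if \code{FALSE}, only the anodic wave is generated
#'   (an irreversible oxidation).
#' @param noise_sd additive white current noise (A).
#' @param points_per_segment sweep sampling density.
#' @param seed RNG seed for the noise; default \code{cfg$seed}.
#' @return A \code{\link{voltammogram}}.
#' @export
gen_voltammogram <- function(E0, scan_rate, cfg,
                             window = E0 + c(-0.4, 0.4),
                             n_electrons = 1, ip_coef = 1e-4,
                             peak_width = 0.05, ipa_over_ipc = 1,
                             reversible = TRUE, noise_sd = 0,
                             points_per_segment = 400,
                             seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (window[1] > E0 - 0.2 || window[2] < E0 + 0.2)
    stop("sweep window must contain E0 +/- 0.2 V")
  dEp <- 0.059 / n_electrons
  ip <- ip_coef * sqrt(scan_rate)
  Ef <- seq(window[1], window[2], length.out = points_per_segment)
  Er <- rev(Ef)[-1]
  gauss <- function(E, mu) exp(-0.5 * ((E - mu) / peak_width)^2)
  If <- ip * ipa_over_ipc * gauss(Ef, E0 + dEp / 2)
  Ir <- if (reversible) -ip * gauss(Er, E0 - dEp / 2)
        else numeric(length(Er))
  E <- c(Ef, Er); I <- c(If, Ir)
  if (noise_sd > 0)
    I <- I + with_local_seed(seed,
                             stats::rnorm(length(I), 0, noise_sd))
  voltammogram(E, I, scan_rate = scan_rate, reference = "Fc+/Fc")
}
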