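#' Cyclic voltammogram
#'
#' A potential sweep (forward and reverse segments) with the measured
#' current and the scan rate. Segments are detected from sign changes of
#' the potential increments.
#'
#' @param potential potential sweep (V), at least two monotonic segments.
#' @param current current (A), same length.
#' @param scan_rate scan rate (V/s), positive.
#' @param reference reference-couple label, e.g. \code{"Fc+/Fc"}.
#' @return An object of class \code{"voltammogram"}.
#' @export
voltammogram <- function(potential, current, scan_rate,
                         reference = "Fc+/Fc") {
  potential <- as.numeric(potential); current <- as.numeric(current)
  if (length(potential) != length(current))
    stop("potential and current lengths differ")
  if (!is.finite(scan_rate) || scan_rate <= 0)
    stop("'scan_rate' must be positive")
  seg <- sweep_segments(potential)
  if (length(seg) < 2)
    stop("a cyclic voltammogram needs >= 2 sweep segments")
  structure(list(potential = potential, current = current,
                 scan_rate = scan_rate, reference = reference,
                 segments = seg),
            class = "voltammogram")
}

## split indices into monotonic sweep segments
sweep_segments <- function(E) {
  d <- sign(diff(E))
  d[d == 0] <- NA
  d <- zoo_fill(d)
  brk <- which(diff(d) != 0)
  bounds <- c(0, brk + 1, length(E))
  out <- list()
  for (i in seq_len(length(bounds) - 1)) {
    idx <- (bounds[i] + 1):bounds[i + 1]
    if (length(idx) >= 5)
      out[[length(out) + 1]] <- list(idx = idx,
                                     direction = d[min(idx[1],
                                                       length(d))])
  }
  out
}

## forward-fill NAs (plateau points in the sweep)
zoo_fill <- function(x) {
  if (all(is.na(x))) stop("potential sweep is constant")
  for (i in seq_along(x))
    if (is.na(x[i])) x[i] <- if (i > 1) x[i - 1] else x[which(!is.na(x))[1]]
  x
}

## baseline-subtracted peak on one segment: linear baseline fitted over
## the leading fraction of the sweep (before the wave), peak = extremum of
## the corrected current
segment_peak <- function(E, I, direction, baseline_frac = 0.15) {
  n <- length(E)
  nb <- max(3, floor(baseline_frac * n))
  base_idx <- seq_len(nb)
  bl <- stats::lm(I[base_idx] ~ E[base_idx])
  Icorr <- I - (stats::coef(bl)[1] + stats::coef(bl)[2] * E)
  k <- if (direction > 0) which.max(Icorr) else which.min(Icorr)
  list(E_p = E[k], i_p = Icorr[k], index = k)
}

#' Extract effective redox potentials from a cyclic voltammogram
#'
#' Locates the anodic and cathodic peaks (after linear baseline
#' subtraction per sweep segment) and reports the peak potentials and
#' currents, the midpoint potential \eqn{E_{mid} = (E_{pa} + E_{pc})/2}
#' -- the "effective" redox potential for quasi-reversible couples -- and
#' the peak-current ratio \eqn{i_{pa}/i_{pc}}. If only one peak is
#' resolvable the process is flagged irreversible and the single peak
#' reported.
#'
#' @param v a \code{\link{voltammogram}}.
#' @param baseline_frac fraction of each segment (from its start) used for
#'   the linear baseline fit.
#' @param min_peak_frac a peak is considered resolvable if its
#'   baseline-corrected amplitude exceeds this fraction of the largest
#'   peak amplitude.
#' @return An object of class \code{"redox_summary"}: \code{E_pa},
#'   \code{E_pc}, \code{i_pa}, \code{i_pc}, \code{E_mid},
#'   \code{peak_ratio}, \code{reversible}, \code{reference}.
#' @export
extract_redox <- function(v, baseline_frac = 0.15, min_peak_frac = 0.05) {
  stopifnot(inherits(v, "voltammogram"))
  an <- NULL; ca <- NULL
  for (s in v$segments) {
    pk <- segment_peak(v$potential[s$idx], v$current[s$idx], s$direction,
                       baseline_frac)
    if (s$direction > 0) {
      if (is.null(an) || pk$i_p > an$i_p) an <- pk
    } else {
      if (is.null(ca) || pk$i_p < ca$i_p) ca <- pk
    }
  }
  amp <- c(if (!is.null(an)) abs(an$i_p), if (!is.null(ca)) abs(ca$i_p))
  big <- max(amp)
  ok_an <- !is.null(an) && abs(an$i_p) >= min_peak_frac * big
  ok_ca <- !is.null(ca) && abs(ca$i_p) >= min_peak_frac * big
  if (ok_an && ok_ca) {
    out <- list(E_pa = an$E_p, E_pc = ca$E_p, i_pa = an$i_p, i_pc = ca$i_p,
                E_mid = (an$E_p + ca$E_p) / 2,
                peak_ratio = abs(an$i_p / ca$i_p),
                reversible = TRUE, reference = v$reference)
  } else {
    pk <- if (ok_an) an else ca
    out <- list(E_pa = if (ok_an) an$E_p else NA_real_,
                E_pc = if (ok_ca) ca$E_p else NA_real_,
                i_pa = if (ok_an) an$i_p else NA_real_,
                i_pc = if (ok_ca) ca$i_p else NA_real_,
                E_mid = NA_real_, peak_ratio = NA_real_,
                reversible = FALSE, reference = v$reference)
  }
  class(out) <- "redox_summary"
  out
}

#' @export
print.redox_summary <- function(x, ...) {
  if (x$reversible)
    cat(sprintf(
      "<redox_summary> E_mid = %.4f V (%s), E_pa = %.4f, E_pc = %.4f, ipa/ipc = %.3f\n",
      x$E_mid, x$reference, x$E_pa, x$E_pc, x$peak_ratio))
  else
    cat(sprintf(
      "<redox_summary> irreversible process; peak at %.4f V (%s)\n",
      if (is.na(x$E_pa)) x$E_pc else x$E_pa, x$reference))
  invisible(x)
}

#' Re-reference a potential from Fc+/Fc to NHE
#'
#' Adds the ferrocene-couple offset versus the normal hydrogen electrode
#' (+0.64 V).
#'
#' @param E_vs_fc potential (V) versus Fc+/Fc.
#' @param offset Fc+/Fc vs NHE (V); default +0.64.
#' @return Potential (V) versus NHE.
#' @export
reference_to_nhe <- function(E_vs_fc, offset = 0.64) E_vs_fc + offset

#' Scan-rate diagnostics for a voltammogram series
#'
#' Regresses peak potential and peak current on the square root of the
#' scan rate (a linear peak-current dependence on \eqn{\sqrt\nu} indicates
#' diffusion control) and checks the constancy of the midpoint potential
#' and peak-current ratio across rates.
#'
#' @param vs list of \code{\link{voltammogram}} objects at >= 3 scan
#'   rates.
#' @param ... passed to \code{\link{extract_redox}}.
#' @return A list with per-rate summaries and, for both the anodic peak
#'   potential and current, slope/intercept/\eqn{R^2} of the regression on
#'   \eqn{\sqrt\nu}; plus \code{E_mid_range} and \code{peak_ratio_range}.
#' @export
scan_rate_diagnostics <- function(vs, ...) {
  if (length(vs) < 3)
    stop("scan-rate diagnostics need >= 3 scan rates")
  nu <- vapply(vs, `[[`, 0, "scan_rate")
  red <- lapply(vs, extract_redox, ...)
  E_pa <- vapply(red, `[[`, 0, "E_pa")
  i_pa <- vapply(red, `[[`, 0, "i_pa")
  E_mid <- vapply(red, `[[`, 0, "E_mid")
  ratio <- vapply(red, `[[`, 0, "peak_ratio")
  reg <- function(yv) {
    f <- stats::lm(yv ~ sqrt(nu))
    list(slope = unname(stats::coef(f)[2]),
         intercept = unname(stats::coef(f)[1]),
         r_squared = suppressWarnings(summary(f)$r.squared))
  }
  list(scan_rates = nu,
       peak_potential = reg(E_pa),
       peak_current = reg(i_pa),
       E_mid = E_mid, E_mid_range = diff(range(E_mid, na.rm = TRUE)),
       peak_ratio = ratio,
       peak_ratio_range = diff(range(ratio, na.rm = TRUE)),
       summaries = red)
}

#' Rehm-Weller free energy of photoinduced electron transfer
#'
#' \deqn{\Delta G = e\,[E(0^+/0) - E(R/R^-)] - \Delta G_{0,0} - e^2/\epsilon d}
#' in eV for one electron: donor oxidation potential minus acceptor
#' reduction potential (both vs the same reference, NHE), minus the 0-0
#' excitation energy, minus the (normally negligible) charge-separation
#' Coulomb term. Negative values mean quenching by electron transfer is
#' thermodynamically favourable.
#'
#' @param E_ox_donor donor oxidation potential (V vs NHE); default 1.3 V,
#'   guanine.
#' @param E_red_acceptor acceptor (fluorophore) reduction potential (V vs
#'   NHE).
#' @param dG00 0-0 transition energy (eV), e.g. from
#'   \code{\link{zero_zero_energy}}.
#' @param coulomb_term charge-separation term \eqn{e^2/\epsilon d} (eV);
#'   default 0 (omitted).
#' @return A list: \code{dG} (eV), \code{favourable} (\code{TRUE} iff
#'   \code{dG < 0}), \code{verdict}.
#' @examples
#' rehm_weller_dG(E_red_acceptor = -0.61, dG00 = 2.20)
#' @export
rehm_weller_dG <- function(E_ox_donor = 1.3, E_red_acceptor, dG00,
                           coulomb_term = 0) {
  dG <- (E_ox_donor - E_red_acceptor) - dG00 - coulomb_term
  list(dG = dG, favourable = dG < 0,
       verdict = if (dG < 0) "favourable"
                 else if (dG > 0) "unfavourable" else "boundary")
}

#' 0-0 transition energy from absorption and emission maxima
#'
#' Photon energy at the arithmetic-mean wavelength of the absorption and
#' emission maxima: \eqn{\Delta G_{0,0} = hc / ((\lambda_{abs} +
#' \lambda_{em})/2)} with \eqn{hc = 1239.84} eV nm.
#'
#' @param lambda_abs_max absorption maximum (nm), positive.
#' @param lambda_em_max emission maximum (nm), positive.
#' @return Energy in eV.
#' @examples
#' zero_zero_energy(620, 620)  # 2.0 eV
#' @export
zero_zero_energy <- function(lambda_abs_max, lambda_em_max) {
  if (any(lambda_abs_max <= 0) || any(lambda_em_max <= 0))
    stop("wavelengths must be positive")
  1239.84 / ((lambda_abs_max + lambda_em_max) / 2)
}

#' Redox potential from a computed thermodynamic cycle
#'
#' Converts gas-phase electron attachment/detachment and solvation Gibbs
#' energies (eV) into a solution redox potential referenced to NHE:
#' \deqn{E_{abs} = -\frac{\Delta G_{gas} + \Delta G_{solv}(final) -
#'   \Delta G_{solv}(initial)}{n}, \qquad E_{NHE} = E_{abs} - 4.4.}
#'
#' @param dG_gas gas-phase reaction Gibbs energy (eV).
#' @param dG_solv_initial solvation Gibbs energy of the initial oxidation
#'   state (eV).
#' @param dG_solv_final solvation Gibbs energy of the final oxidation
#'   state (eV).
#' @param n electrons transferred (>= 1).
#' @param absolute_ref absolute potential of the reference electrode (V);
#'   default NHE = 4.4.
#' @return Potential (V) versus the reference.
#' @export
thermo_cycle_potential <- function(dG_gas, dG_solv_initial = 0,
                                   dG_solv_final = 0, n = 1,
                                   absolute_ref = 4.4) {
  if (n < 1) stop("'n' must be >= 1")
  dG_soln <- dG_gas + dG_solv_final - dG_solv_initial
  -dG_soln / n - absolute_ref
}
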