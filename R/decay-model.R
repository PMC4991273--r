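#' Uniform TCSPC time axis
#'
#' Defines the channel grid on which decays, instrument-response functions
#' and model curves live. The grid is strictly uniform: channel k (1-based)
#' sits at \code{t0 + (k - 1) * dt} nanoseconds.
#'
#' @param t0 time origin of the first channel (ns).
#' @param dt channel width (ns); must be positive.
#' @param n number of channels; at least 8.
#' @return An object of class \code{"time_axis"}.
#' @examples
#' ax <- time_axis(dt = 0.055, n = 512)
#' head(axis_times(ax))
#' @export
time_axis <- function(t0 = 0, dt, n) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ns)")
  n <- as.integer(n)
  if (is.na(n) || n < 8L)
    stop("'n' must be an integer >= 8")
  structure(list(t0 = as.numeric(t0), dt = as.numeric(dt), n = n),
            class = "time_axis")
}

#' @rdname time_axis
#' @param axis a \code{time_axis}.
#' @export
axis_times <- function(axis) {
  stopifnot(inherits(axis, "time_axis"))
  axis$t0 + axis$dt * (seq_len(axis$n) - 1)
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d channels, dt = %g ns, span %g-%g ns\n",
              x$n, x$dt, x$t0, x$t0 + x$dt * (x$n - 1)))
  invisible(x)
}

same_axis <- function(a, b, tol = 1e-9) {
  a$n == b$n && abs(a$dt - b$dt) < tol && abs(a$t0 - b$t0) < tol
}

#' Instrument response function
#'
#' A measured (or simulated) temporal profile of the excitation pulse plus
#' detection chain, on the same channel grid convention as the decays it
#' will be used to deconvolve.
#'
#' @param axis a \code{\link{time_axis}}.
#' @param counts non-negative counts per channel; must contain some signal.
#' @return An object of class \code{"instrument_response"}.
#' @export
instrument_response <- function(axis, counts) {
  stopifnot(inherits(axis, "time_axis"))
  counts <- as.numeric(counts)
  if (length(counts) != axis$n)
    stop("length(counts) must equal axis$n")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("IRF counts must be finite and non-negative")
  if (sum(counts) <= 0)
    stop("IRF must contain signal (sum of counts > 0)")
  structure(list(axis = axis, counts = counts), class = "instrument_response")
}

#' A single TCSPC decay histogram
#'
#' @param axis a \code{\link{time_axis}}.
#' @param counts non-negative integer-valued photon counts per channel.
#' @param label free-text label.
#' @param meta list of metadata; by convention may hold \code{dna},
#'   \code{dna_conc_M} (binding-motif concentration, mol/L) and
#'   \code{emission_nm}.
#' @return An object of class \code{"decay_trace"}.
#' @export
decay_trace <- function(axis, counts, label = "", meta = list()) {
  stopifnot(inherits(axis, "time_axis"))
  counts <- as.numeric(counts)
  if (length(counts) != axis$n)
    stop("length(counts) must equal axis$n")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("decay counts must be finite and non-negative")
  if (max(abs(counts - round(counts))) > 1e-6)
    stop("decay counts must be integral-valued photon counts")
  if (max(counts) <= 0)
    stop("decay has no photons (max(counts) == 0)")
  structure(list(axis = axis, counts = round(counts), label = label,
                 meta = meta),
            class = "decay_trace")
}

#' @export
print.decay_trace <- function(x, ...) {
  cat(sprintf("<decay_trace> '%s': %d channels, peak %d counts\n",
              x$label, x$axis$n, as.integer(max(x$counts))))
  invisible(x)
}

#' Multi-exponential decay parameters
#'
#' Parameter set for the decay law
#' \deqn{I(t) = I_0 \sum_i \alpha_i e^{-t/\tau_i},\qquad \sum_i \alpha_i = 1,}
#' with up to three components, an overall scale \eqn{I_0} in counts, a
#' prompt-shift (ns) applied to the IRF during reconvolution, and an
#' optional constant background per channel.
#'
#' \code{alpha} may be given either for all components (must sum to 1) or
#' for components \code{2..ncomp} only, in which case the first amplitude
#' is the remainder \eqn{1 - \sum_{i>1}\alpha_i}.
#'
#' @param tau lifetimes (ns), 1 to 3 components, all positive.
#' @param alpha amplitude fractions (see Details); defaults to equal shares.
#' @param scale overall intensity \eqn{I_0} (counts), positive.
#' @param shift prompt shift (ns).
#' @param background constant background (counts/channel), non-negative.
#' @return An object of class \code{"multiexp_params"}.
#' @examples
#' multiexp_params(tau = c(1.3, 3.7), alpha = c(0.974, 0.026), scale = 1e4)
#' @export
multiexp_params <- function(tau, alpha = NULL, scale = 1, shift = 0,
                            background = 0) {
  tau <- as.numeric(tau)
  ncomp <- length(tau)
  if (ncomp < 1L || ncomp > 3L)
    stop("between 1 and 3 lifetime components are supported")
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("all lifetimes must be positive and finite")
  if (is.null(alpha)) {
    alpha <- rep(1 / ncomp, ncomp)
  } else {
    alpha <- as.numeric(alpha)
    if (length(alpha) == ncomp - 1L)
      alpha <- c(1 - sum(alpha), alpha)
    if (length(alpha) != ncomp)
      stop("'alpha' must have length ncomp or ncomp - 1")
    if (any(alpha < -1e-12))
      stop("amplitude fractions must be non-negative")
    if (abs(sum(alpha) - 1) > 1e-8)
      stop("amplitude fractions must sum to 1")
    alpha <- pmax(alpha, 0)
  }
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  if (!is.finite(background) || background < 0)
    stop("'background' must be non-negative")
  structure(list(ncomp = ncomp, tau = tau, alpha = alpha,
                 scale = as.numeric(scale), shift = as.numeric(shift),
                 background = as.numeric(background)),
            class = "multiexp_params")
}

#' @export
print.multiexp_params <- function(x, ...) {
  cat(sprintf("<multiexp_params> %d component(s)\n", x$ncomp))
  cat("  tau (ns):  ", paste(signif(x$tau, 4), collapse = ", "), "\n")
  cat("  alpha:     ", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  cat(sprintf("  scale %.4g, shift %.4g ns, background %.4g\n",
              x$scale, x$shift, x$background))
  invisible(x)
}

#' Evaluate the multi-exponential decay law on a time grid
#'
#' Computes \eqn{I(t) = I_0 \sum_i \alpha_i e^{-t/\tau_i}} at the channel
#' times of \code{axis}. The law is causal: channels before \eqn{t = 0}
#' evaluate to zero, so the curve can be fed directly to
#' \code{\link{reconvolve}}. The background term is \emph{not} added here
#' (it is an additive offset on the reconvolved curve, see
#' \code{\link{model_counts}}).
#'
#' @param params a \code{\link{multiexp_params}}.
#' @param axis a \code{\link{time_axis}}.
#' @return Numeric vector of model intensities, one per channel.
#' @examples
#' ax <- time_axis(dt = 1, n = 16)
#' evaluate_multiexp(multiexp_params(tau = 5, scale = 100), ax)[1]  # 100
#' @export
evaluate_multiexp <- function(params, axis) {
  stopifnot(inherits(params, "multiexp_params"), inherits(axis, "time_axis"))
  t <- axis_times(axis)
  out <- numeric(axis$n)
  pos <- t >= 0
  for (i in seq_len(params$ncomp))
    out[pos] <- out[pos] + params$alpha[i] * exp(-t[pos] / params$tau[i])
  params$scale * out
}

## Shift the IRF along its own grid by `shift` ns using linear
## interpolation; sub-channel shifts are the point (the IRF is recorded at
## a different wavelength than the decays). Values shifted in from outside
## the record are zero.
shift_irf_counts <- function(irf, shift) {
  if (shift == 0) return(irf$counts)
  ax <- irf$axis
  if (abs(shift) >= ax$dt * (ax$n - 1))
    stop("|shift| must be smaller than the axis span")
  t <- axis_times(ax)
  stats::approx(x = t + shift, y = irf$counts, xout = t,
                method = "linear", yleft = 0, yright = 0)$y
}

#' Reconvolve a model decay with the instrument response
#'
#' Discrete causal convolution of the model curve with the (optionally
#' prompt-shifted) IRF. The IRF is unit-normalised before convolution so
#' the model's intensity scale is preserved in counts. Output has the same
#' length as the input.
#'
#' @param model numeric vector of model intensities on the IRF's axis.
#' @param irf an \code{\link{instrument_response}}.
#' @param shift prompt shift (ns) applied to the IRF (linear interpolation).
#' @return Numeric vector of reconvolved model counts.
#' @export
reconvolve <- function(model, irf, shift = 0) {
  stopifnot(inherits(irf, "instrument_response"))
  n <- irf$axis$n
  if (length(model) != n)
    stop("model and IRF must share one time axis (length mismatch)")
  h <- shift_irf_counts(irf, shift)
  s <- sum(h)
  if (s <= 0) stop("shifted IRF has no mass inside the record")
  h <- h / s
  ## full linear convolution via FFT; causal part = first n terms
  out <- stats::convolve(h, rev(model), type = "open")[seq_len(n)]
  ## FFT round-off can leave tiny negative values on an all-positive model
  out[abs(out) < 1e-12 * max(abs(out))] <- 0
  out
}

#' Full forward model for a TCSPC trace
#'
#' Convenience wrapper: evaluates the decay law, reconvolves with the IRF
#' using the parameter set's prompt shift, and adds the constant
#' background.
#'
#' @inheritParams evaluate_multiexp
#' @param irf an \code{\link{instrument_response}} on the same axis.
#' @return Numeric vector of expected counts per channel.
#' @export
model_counts <- function(params, irf) {
  stopifnot(inherits(irf, "instrument_response"))
  m <- evaluate_multiexp(params, irf$axis)
  reconvolve(m, irf, shift = params$shift) + params$background
}

#' Fractional steady-state intensities
#'
#' The share of steady-state emission contributed by each decay component,
#' \eqn{f_i = \alpha_i \tau_i / \sum_j \alpha_j \tau_j}.
#'
#' @param alpha amplitude fractions (summing to 1).
#' @param tau lifetimes (ns), positive, same length as \code{alpha}.
#' @return Numeric vector \code{f} with \code{sum(f) == 1}.
#' @examples
#' fractional_intensities(c(0.974, 0.026), c(1.3, 3.7))
#' @export
fractional_intensities <- function(alpha, tau) {
  check_alpha_tau(alpha, tau)
  w <- alpha * tau
  tot <- sum(w)
  if (tot <= 0) stop("all amplitudes are zero; fractions undefined")
  w / tot
}

#' Amplitude-weighted average lifetime
#'
#' \eqn{\bar\tau = \sum_j \alpha_j \tau_j} (ns).
#'
#' @inheritParams fractional_intensities
#' @return The average lifetime in ns.
#' @export
average_lifetime <- function(alpha, tau) {
  check_alpha_tau(alpha, tau)
  sum(alpha * tau)
}

check_alpha_tau <- function(alpha, tau) {
  if (length(alpha) != length(tau))
    stop("'alpha' and 'tau' must have the same length")
  if (any(tau <= 0)) stop("all lifetimes must be positive")
  if (any(alpha < 0)) stop("amplitudes must be non-negative")
  if (abs(sum(alpha) - 1) > 1e-6)
    stop("amplitudes must sum to 1")
  invisible(TRUE)
}

#' Default goodness-of-fit window
#'
#' Channels used for the chi-square statistic: from the peak of the IRF
#' (where the reconvolved model becomes informative) to the end of the
#' record.
#'
#' @param irf an \code{\link{instrument_response}}.
#' @return Integer vector of channel indices.
#' @export
default_fit_window <- function(irf) {
  stopifnot(inherits(irf, "instrument_response"))
  seq.int(which.max(irf$counts), irf$axis$n)
}

#' Reduced chi-square of a fitted decay
#'
#' Weighted residual statistic
#' \eqn{\chi^2_r = \frac{1}{\nu}\sum_{k \in W} \frac{(y_k - m_k)^2}{\max(y_k, 1)}}
#' with Poisson (Neyman) weights, over the fit window \eqn{W}, with
#' \eqn{\nu = |W| - p} degrees of freedom for \eqn{p} free parameters.
#'
#' @param observed a \code{\link{decay_trace}} or numeric count vector.
#' @param model numeric vector of model counts (same length).
#' @param n_free number of fitted parameters.
#' @param window integer channel indices; default all channels.
#' @return The reduced chi-square (non-negative scalar).
#' @export
reduced_chisq <- function(observed, model, n_free, window = NULL) {
  y <- if (inherits(observed, "decay_trace")) observed$counts else
    as.numeric(observed)
  if (length(y) != length(model))
    stop("observed and model lengths differ")
  if (is.null(window)) window <- seq_along(y)
  if (length(window) == 0) stop("fit window is empty")
  dof <- length(window) - n_free
  if (dof <= 0)
    stop("degrees of freedom <= 0 (window too small for n_free)")
  yw <- y[window]; mw <- model[window]
  sum((yw - mw)^2 / pmax(yw, 1)) / dof
}
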