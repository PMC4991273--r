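#' Steady-state emission spectrum at one titration point
#'
#' @param wavelength strictly increasing wavelength grid (nm).
#' @param intensity non-negative emission intensities (a.u.).
#' @param dna_conc DNA binding-motif concentration (mol/L).
#' @param dye_conc dye concentration (mol/L).
#' @return An object of class \code{"emission_spectrum"}.
#' @export
emission_spectrum <- function(wavelength, intensity, dna_conc = NA_real_,
                              dye_conc = NA_real_) {
  wavelength <- as.numeric(wavelength)
  intensity <- as.numeric(intensity)
  if (length(wavelength) != length(intensity))
    stop("wavelength and intensity lengths differ")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  structure(list(wavelength = wavelength, intensity = intensity,
                 dna_conc = dna_conc, dye_conc = dye_conc),
            class = "emission_spectrum")
}

#' Integrate an emission spectrum over a wavelength band
#'
#' Trapezoidal integral of the intensity over \code{band} (nm). The
#' default band, 584-634 nm, is the standard analysis band for the
#' triangulenium emission maximum.
#'
#' @param spectrum an \code{\link{emission_spectrum}}.
#' @param band length-2 numeric, band edges in nm.
#' @return The integrated intensity (a.u. * nm).
#' @export
integrate_band <- function(spectrum, band = c(584, 634)) {
  stopifnot(inherits(spectrum, "emission_spectrum"), length(band) == 2)
  sel <- spectrum$wavelength >= min(band) & spectrum$wavelength <= max(band)
  if (sum(sel) < 2) stop("fewer than 2 wavelength points inside the band")
  pracma::trapz(spectrum$wavelength[sel], spectrum$intensity[sel])
}

#' Fold enhancement of emission over a titration
#'
#' Ratio of integrated emission at the end of the titration to the
#' dye-only spectrum at the start. Values above 1 indicate enhancement,
#' below 1 quenching.
#'
#' @param first dye-only \code{\link{emission_spectrum}}.
#' @param last end-of-titration \code{\link{emission_spectrum}}.
#' @param band integration band (nm); \code{NULL} integrates the full
#'   shared grid.
#' @return The enhancement ratio.
#' @export
fold_enhancement <- function(first, last, band = NULL) {
  stopifnot(inherits(first, "emission_spectrum"),
            inherits(last, "emission_spectrum"))
  if (length(first$wavelength) != length(last$wavelength) ||
      any(abs(first$wavelength - last$wavelength) > 1e-9))
    stop("spectra must share one wavelength grid")
  if (is.null(band)) band <- range(first$wavelength)
  i0 <- integrate_band(first, band)
  i1 <- integrate_band(last, band)
  if (i0 <= 0) stop("initial integrated emission is zero; ratio undefined")
  i1 / i0
}

#' Binding curve: integrated emission versus DNA concentration
#'
#' @param x DNA binding-motif concentration (mol/L), non-decreasing.
#' @param y integrated emission (a.u.).
#' @param band the integration band used (nm), for record keeping.
#' @return An object of class \code{"binding_curve"}.
#' @export
binding_curve <- function(x, y, band = c(584, 634)) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 5) stop("a binding curve needs >= 5 points")
  if (is.unsorted(x)) stop("concentrations must be non-decreasing")
  structure(list(x = x, y = y, band = band), class = "binding_curve")
}

#' Build a binding curve from a titration's emission spectra
#'
#' @param spectra list of \code{\link{emission_spectrum}} objects with
#'   \code{dna_conc} set.
#' @param band integration band (nm).
#' @return A \code{\link{binding_curve}} ordered by DNA concentration.
#' @export
binding_curve_from_spectra <- function(spectra, band = c(584, 634)) {
  conc <- vapply(spectra, `[[`, 0, "dna_conc")
  y <- vapply(spectra, integrate_band, 0, band = band)
  o <- order(conc)
  binding_curve(conc[o], y[o], band = band)
}

#' Mole-ratio stoichiometry from the titration breakpoint
#'
#' Fits a continuous two-segment line with a free knee (grid search over
#' interior knee positions, then golden-section refinement) and reports
#' the abscissa of the gradient change as a mole ratio (DNA units per
#' dye). If the two-segment model is not supported over a single line by
#' BIC (or the single line already fits essentially perfectly), a
#' no-breakpoint result is returned.
#'
#' @param curve a \code{\link{binding_curve}} with >= 6 points.
#' @param dye_conc dye concentration (mol/L).
#' @return A list: \code{breakpoint} ([DNA]/[dye] at the knee, \code{NA}
#'   if none), \code{knee_x} (mol/L), \code{has_breakpoint}, segment
#'   \code{slopes}, and the residual sums of squares of the one- and
#'   two-segment models.
#' @export
mole_ratio_stoichiometry <- function(curve, dye_conc) {
  stopifnot(inherits(curve, "binding_curve"))
  x <- curve$x; y <- curve$y
  if (length(x) < 6) stop("need >= 6 points spanning the breakpoint")
  if (!is.finite(dye_conc) || dye_conc <= 0)
    stop("'dye_conc' must be positive")
  n <- length(x)
  ## single-line reference
  lf <- stats::lm(y ~ x)
  sse1 <- sum(stats::resid(lf)^2)
  tss <- sum((y - mean(y))^2)
  seg_sse <- function(k) {
    ## continuous piecewise-linear hinge at k
    h <- pmax(x - k, 0)
    f <- stats::lm(y ~ x + h)
    sum(stats::resid(f)^2)
  }
  ## grid over interior knee candidates, then refine
  lo <- x[2]; hi <- x[n - 1]
  grid <- seq(lo, hi, length.out = 64)
  sse_g <- vapply(grid, seg_sse, 0)
  k0 <- grid[which.min(sse_g)]
  w <- diff(range(grid)) / 63
  opt <- stats::optimize(seg_sse, lower = max(lo, k0 - 2 * w),
                         upper = min(hi, k0 + 2 * w))
  knee <- opt$minimum
  sse2 <- opt$objective
  ## model selection: single line (2 params) vs hinge (4 params incl knee)
  bic1 <- n * log(max(sse1, 1e-300) / n) + 2 * log(n)
  bic2 <- n * log(max(sse2, 1e-300) / n) + 4 * log(n)
  perfect_line <- sse1 <= 1e-12 * max(tss, 1e-300)
  if (perfect_line || bic2 >= bic1) {
    return(list(breakpoint = NA_real_, knee_x = NA_real_,
                has_breakpoint = FALSE, slopes = unname(stats::coef(lf)[2]),
                sse_line = sse1, sse_segments = sse2))
  }
  h <- pmax(x - knee, 0)
  f <- stats::lm(y ~ x + h)
  b <- stats::coef(f)
  list(breakpoint = knee / dye_conc, knee_x = knee, has_breakpoint = TRUE,
       slopes = c(before = unname(b[2]), after = unname(b[2] + b[3])),
       sse_line = sse1, sse_segments = sse2)
}

#' Bound-dye concentration under the exact 1:1 model
#'
#' Closed-form root of the 1:1 mass balance
#' \deqn{x = \frac{(D + L + 1/K_a) - \sqrt{(D + L + 1/K_a)^2 - 4DL}}{2}}
#' for DNA-motif concentration \eqn{D}, total dye \eqn{L} and association
#' constant \eqn{K_a}.
#'
#' @param D DNA binding-motif concentration (mol/L); vectorised.
#' @param L total dye concentration (mol/L).
#' @param Ka association constant (1/M).
#' @return Bound complex concentration (mol/L).
#' @examples
#' Ka <- 1e6
#' bound_1to1(1 / Ka, 1 / Ka, Ka) * Ka  # (3 - sqrt(5)) / 2
#' @export
bound_1to1 <- function(D, L, Ka) {
  if (any(Ka <= 0)) stop("'Ka' must be positive")
  s <- D + L + 1 / Ka
  disc <- pmax(s^2 - 4 * D * L, 0)
  (s - sqrt(disc)) / 2
}

## emission signal under the exact 1:1 model
signal_1to1 <- function(D, L, Ka, I_free, I_bound) {
  x <- bound_1to1(D, L, Ka)
  I_free * (L - x) + I_bound * x
}

#' Fit a 1:1 compound-to-binding-motif association constant
#'
#' Fits the emission binding curve with the exact 1:1 quadratic
#' mass-balance model: bound complex \eqn{x} from \code{\link{bound_1to1}}
#' and signal \eqn{y = I_{free}(L - x) + I_{bound}\,x}, with
#' \eqn{K_a}, \eqn{I_{free}} and \eqn{I_{bound}} free. Minimisation uses
#' Levenberg-Marquardt trust-region least squares
#' (\code{\link[minpack.lm]{nlsLM}}) on \eqn{\log_{10} K_a}.
#'
#' Concentrations on the curve may be in bases/base-pairs/strands; they
#' are divided by \code{motif_size} to obtain binding-motif units (e.g.
#' \code{motif_size = 5} for a 5-base motif).
#'
#' @param curve a \code{\link{binding_curve}}.
#' @param dye_conc total dye concentration (mol/L).
#' @param motif_size DNA units per binding motif (default 1).
#' @param start optional list with \code{log10Ka}, \code{I_free},
#'   \code{I_bound} starting values.
#' @return An object of class \code{"binding_fit"}: \code{Ka} (1/M, motif
#'   units), \code{log10Ka}, \code{I_free}, \code{I_bound},
#'   \code{motif_size}, fitted values, residual sum of squares, a
#'   convergence flag and \code{lower_bound_only} (\code{TRUE} when the
#'   curve is saturated from the first point and Ka is only bounded from
#'   below).
#' @export
fit_1to1 <- function(curve, dye_conc, motif_size = 1, start = NULL) {
  stopifnot(inherits(curve, "binding_curve"))
  if (!is.finite(dye_conc) || dye_conc <= 0)
    stop("'dye_conc' must be positive")
  if (motif_size <= 0) stop("'motif_size' must be positive")
  D <- curve$x / motif_size
  y <- curve$y
  L <- dye_conc
  ## starting values: brightness from curve ends, Ka from half-effect
  i_free0 <- max(y[which.min(D)] / L, .Machine$double.eps)
  i_bound0 <- max(y[which.max(D)] / L, .Machine$double.eps)
  half <- D[which.min(abs(y - (min(y) + max(y)) / 2))]
  ka0 <- 1 / max(half, min(D[D > 0], L) / 10, .Machine$double.eps)
  st <- utils::modifyList(
    list(log10Ka = log10(ka0), I_free = i_free0, I_bound = i_bound0),
    start %||% list())
  dat <- data.frame(D = D, y = y)
  fit <- minpack.lm::nlsLM(
    y ~ signal_1to1(D, L, 10^log10Ka, I_free, I_bound),
    data = dat, start = st,
    lower = c(log10Ka = 0, I_free = 0, I_bound = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  Ka <- unname(10^cf["log10Ka"])
  fb0 <- bound_1to1(min(D[D > 0]), L, Ka) / L
  saturated <- length(D[D > 0]) > 0 && fb0 > 0.95
  if (saturated)
    warning("curve is saturated over the measured range; ",
            "Ka is a lower bound only")
  out <- list(Ka = Ka, log10Ka = unname(cf["log10Ka"]),
              I_free = unname(cf["I_free"]),
              I_bound = unname(cf["I_bound"]),
              motif_size = motif_size,
              fitted = stats::fitted(fit),
              residuals = stats::resid(fit),
              rss = sum(stats::resid(fit)^2),
              converged = fit$convInfo$isConv %||% TRUE,
              lower_bound_only = saturated,
              model = fit)
  class(out) <- "binding_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> Ka = %.3g 1/M (motif of %g DNA units)%s\n",
              x$Ka, x$motif_size,
              if (x$lower_bound_only) "  [lower bound]" else ""))
  cat(sprintf("  I_free = %.3g, I_bound = %.3g, rss = %.3g\n",
              x$I_free, x$I_bound, x$rss))
  invisible(x)
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' \eqn{c = A / (\epsilon \ell)}.
#'
#' @param A absorbance (dimensionless), non-negative.
#' @param epsilon molar extinction coefficient (1/(M cm)), positive.
#' @param path_cm optical path length (cm), positive.
#' @return Concentration in mol/L.
#' @examples
#' concentration_from_absorbance(0.1433, oligo_table()$TBA$epsilon)  # 1e-6 M
#' @export
concentration_from_absorbance <- function(A, epsilon, path_cm = 1) {
  if (any(A < 0)) stop("absorbance must be non-negative")
  if (any(epsilon <= 0)) stop("'epsilon' must be positive")
  if (any(path_cm <= 0)) stop("'path_cm' must be positive")
  A / (epsilon * path_cm)
}

#' Reference oligonucleotides and extinction coefficients
#'
#' The oligonucleotide panel used for probe characterisation: a 17-mer
#' duplex (ds17) and its single strand (ss17), and the G-quadruplex
#' formers TBA, myc2345 and PDGF-A, with their molar extinction
#' coefficients (1/(M cm)).
#'
#' @return Named list; each element has \code{sequence} (for ds17 both
#'   strands, "+"-separated) and \code{epsilon}.
#' @export
oligo_table <- function() {
  list(
    ds17 = list(
      sequence = paste0("CCAGTTCGTAGTAACCC", "+", "GGGTTACTACGAACTGG"),
      epsilon = 6600),
    ss17 = list(sequence = "CCAGTTCGTAGTAACCC", epsilon = 8910),
    TBA = list(sequence = "GGTTGGTGTGGTTGG", epsilon = 143300),
    myc2345 = list(sequence = "TGAGGGTGGGGAGGGTGGGGAA", epsilon = 229900),
    `PDGF-A` = list(
      sequence = paste0("GGAGGCGGGGGGGGGGGGGCGGGGGCGGGGGCGGGGGAGGGG",
                        "CGCGGC"),
      epsilon = 467400)
  )
}
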