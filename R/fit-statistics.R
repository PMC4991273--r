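#' F-statistic specification for support-plane analysis
#'
#' Holds the significance level, fitted-parameter count and degrees of
#' freedom used to compute the critical chi-square ratio
#' \eqn{F_\chi = 1 + (p/v)\,F(P; p, v)}.
#'
#' @param P significance level, in (0, 1).
#' @param p number of fitted parameters (>= 1).
#' @param v degrees of freedom (>= 1).
#' @return An object of class \code{"fchi_spec"}.
#' @export
fchi_spec <- function(P = 0.05, p, v) {
  if (!is.numeric(P) || P <= 0 || P >= 1) stop("'P' must be in (0, 1)")
  p <- as.integer(p); v <- as.integer(v)
  if (is.na(p) || p < 1L) stop("'p' must be >= 1")
  if (is.na(v) || v < 1L) stop("'v' must be >= 1")
  structure(list(P = P, p = p, v = v), class = "fchi_spec")
}

#' Critical chi-square ratio for lifetime accuracy analysis
#'
#' The threshold on \eqn{\chi^2_r(\mathrm{parm})/\chi^2_r(\mathrm{min})}
#' below which a constrained lifetime is statistically indistinguishable
#' from the unconstrained optimum:
#' \deqn{F_\chi = 1 + \frac{p}{v} F(P; p, v),}
#' where \eqn{F(P; p, v)} is the upper-\eqn{P} critical value of Fisher's
#' F distribution. The numerator/denominator order of the F arguments is
#' the support-plane convention (numerator dof = \eqn{p}); the swapped
#' order is available via \code{order = "vp"}.
#'
#' @param spec an \code{\link{fchi_spec}}, or \code{P} if \code{p} and
#'   \code{v} are supplied directly.
#' @param p,v parameter count and degrees of freedom (if \code{spec} is a
#'   numeric significance level).
#' @param order \code{"pv"} (default): numerator dof \code{p}, denominator
#'   \code{v}; \code{"vp"}: swapped.
#' @return The critical ratio (> 1).
#' @examples
#' critical_fchi(fchi_spec(P = 0.05, p = 33, v = 1600))  # ~1.03
#' @export
critical_fchi <- function(spec, p = NULL, v = NULL,
                          order = c("pv", "vp")) {
  order <- match.arg(order)
  if (!inherits(spec, "fchi_spec")) spec <- fchi_spec(spec, p, v)
  Fcrit <- if (order == "pv")
    stats::qf(1 - spec$P, df1 = spec$p, df2 = spec$v)
  else
    stats::qf(1 - spec$P, df1 = spec$v, df2 = spec$p)
  1 + (spec$p / spec$v) * Fcrit
}

#' Acceptance threshold on the reduced chi-square
#'
#' The upper-\eqn{P} quantile of the \eqn{\chi^2} distribution with
#' \eqn{v} degrees of freedom, divided by \eqn{v}: a fitted decay with
#' \eqn{\chi^2_r} below this value is an acceptable single-photon-counting
#' model at significance \eqn{P}. At the conventional \eqn{v = 200},
#' \eqn{P = 0.05} this is 1.17.
#'
#' @param v degrees of freedom (>= 1).
#' @param P significance level.
#' @return The critical reduced chi-square.
#' @examples
#' chisq_acceptance(v = 200)  # 1.17
#' @export
chisq_acceptance <- function(v = 200, P = 0.05) {
  if (any(v < 1)) stop("'v' must be >= 1")
  stats::qchisq(1 - P, df = v) / v
}

#' Support-plane (F-statistic) accuracy analysis of a shared lifetime
#'
#' Profiles the global reduced chi-square over a grid of fixed values for
#' one shared lifetime: at each grid point that lifetime is held constant
#' and every other free parameter (the remaining free lifetimes and all
#' per-trace amplitudes, scales and shifts) is re-optimised. Grid values
#' whose chi-square ratio against the unconstrained minimum stays below
#' the critical \eqn{F_\chi} are accepted as statistically
#' indistinguishable. With \code{repeats > 1} each grid point is
#' re-optimised from jittered starts and the lowest chi-square is used.
#'
#' @param series the \code{\link{titration_series}} that was fitted.
#' @param fit the unconstrained \code{\link{fit_global}} result.
#' @param component index of the profiled lifetime in
#'   \code{fit$shared_tau}; must not be one of the fixed lifetimes.
#' @param grid fixed lifetime values (ns) to profile, e.g.
#'   \code{seq(2, 17, by = 1)}.
#' @param P significance level for the acceptance threshold.
#' @param repeats independent re-optimisations per grid point (lowest
#'   chi-square kept).
#' @param control optimiser control, as in \code{\link{fit_global}}.
#' @return An object of class \code{"support_plane"}: the grid, the
#'   profiled \code{chisq_r}, the \code{fchi} ratios, the unconstrained
#'   minimum, the threshold, a logical \code{accepted} vector, the accepted
#'   contiguous runs (list of ns intervals), and an \code{ok} flag per
#'   point (\code{FALSE} where re-optimisation failed to converge).
#' @export
tau_support_plane <- function(series, fit, component, grid, P = 0.05,
                              repeats = 1, control = list()) {
  stopifnot(inherits(series, "titration_series"),
            inherits(fit, "global_fit"))
  if (!fit$converged)
    stop("unconstrained fit did not converge; support plane undefined")
  component <- as.integer(component)
  if (component < 1L || component > fit$ncomp)
    stop("'component' out of range")
  if (fit$fixed_mask[component])
    stop("cannot profile a lifetime that was held fixed in the fit")
  grid <- as.numeric(grid)
  dtax <- series$irf$axis$dt
  if (any(grid <= dtax))
    stop("grid lifetimes must exceed the channel width")
  fixed_base <- fit$shared_tau[fit$fixed_mask]
  other_free <- fit$shared_tau[!fit$fixed_mask]
  other_free <- other_free[-match(fit$shared_tau[component], other_free)]
  ntr <- length(series$traces)
  chisq <- numeric(length(grid))
  okv <- logical(length(grid))
  denom <- ntr * length(fit$window) - fit$p
  for (g in seq_along(grid)) {
    best <- Inf; ok <- FALSE
    for (r in seq_len(repeats)) {
      init <- if (length(other_free))
        other_free * (if (r == 1) 1 else exp(stats::rnorm(
          length(other_free), 0, 0.15)))
      else NULL
      cf <- tryCatch(
        fit_global(series, ncomp = fit$ncomp,
                   fixed_free_dye_tau = fixed_base[1],
                   extra_fixed_tau = c(fixed_base[-1], grid[g]),
                   init = init, fit_shift = fit$fit_shift,
                   background = fit$background, window = fit$window,
                   dof_policy = fit$dof_policy, control = control),
        error = function(e) NULL)
      if (!is.null(cf)) {
        ## constrained model has one fewer varied parameter; use the same
        ## dof normalisation as the unconstrained minimum so the ratio is
        ## a pure chi-square ratio
        val <- cf$total_ssr / denom
        if (val < best) { best <- val; ok <- ok || cf$converged }
      }
    }
    chisq[g] <- best
    okv[g] <- ok
  }
  chisq_min <- fit$total_ssr / denom
  fchi <- chisq / chisq_min
  threshold <- critical_fchi(fchi_spec(P = P, p = fit$p, v = fit$v))
  accepted <- okv & fchi <= threshold
  out <- list(component = component, grid = grid, chisq_profile = chisq,
              chisq_min = chisq_min, fchi = fchi, threshold = threshold,
              accepted = accepted, accepted_runs = accepted_runs(grid,
                accepted), ok = okv, P = P,
              spec = fchi_spec(P = P, p = fit$p, v = fit$v))
  class(out) <- "support_plane"
  out
}

## contiguous accepted grid runs -> list of c(lo, hi) in ns
accepted_runs <- function(grid, accepted) {
  if (!any(accepted)) return(list())
  r <- rle(accepted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  idx <- which(r$values)
  lapply(idx, function(i) c(grid[starts[i]], grid[ends[i]]))
}

#' @export
print.support_plane <- function(x, ...) {
  cat(sprintf(
    "<support_plane> tau[%d]: %d grid points, threshold F_chi = %.4f\n",
    x$component, length(x$grid), x$threshold))
  for (r in x$accepted_runs)
    cat(sprintf("  accepted: %.3g - %.3g ns\n", r[1], r[2]))
  if (!length(x$accepted_runs)) cat("  no grid value accepted\n")
  invisible(x)
}

#' @export
as.data.frame.support_plane <- function(x, ...) {
  data.frame(tau_ns = x$grid, chisq_r = x$chisq_profile, f_chi = x$fchi,
             accepted = x$accepted, ok = x$ok)
}
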