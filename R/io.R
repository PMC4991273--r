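#' Run configuration with the standard constants
#'
#' Aggregates the constants used across the pipeline, all overridable:
#' guanine oxidation potential (1.3 V vs NHE), the Fc+/Fc vs NHE offset
#' (+0.64 V), the absolute NHE potential (4.4 V), the chi-square policy
#' degrees of freedom (v = 200 per trace), the fixed free-dye lifetimes
#' (1.28 ns for the morpholino dye, 15.75 ns for the propyl dye) and the
#' emission integration band (584-634 nm).
#'
#' @param ... named overrides of any default.
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(...) {
  cfg <- list(
    guanine_E_ox_V = 1.3,
    fc_offset_V = 0.64,
    nhe_absolute_V = 4.4,
    chisq_policy_v = 200,
    free_dye_tau_ns = c(morpholino = 1.28, propyl = 15.75),
    integration_band_nm = c(584, 634),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown run_config field(s): ",
                        paste(bad, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = "run_config")
}

## shared two-column reader: '# key: value' comments become metadata
read_two_column <- function(path, col1, col2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  meta <- list()
  is_comment <- grepl("^[[:space:]]*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#[[:space:]]*([^:]+):[[:space:]]*(.*)$",
                                cl))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  keep <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(keep)) stop("no data rows in ", path)
  header <- keep[1]
  sep <- if (grepl(",", lines[header])) "," else "[[:space:]]+"
  cols <- trimws(strsplit(lines[header], sep)[[1]])
  if (!identical(tolower(cols[1:2]), tolower(c(col1, col2))))
    stop(path, ": expected header '", col1, ",", col2, "' on line ",
         header, ", found '", lines[header], "'")
  rows <- keep[-1]
  vals <- matrix(NA_real_, length(rows), 2)
  for (i in seq_along(rows)) {
    p <- trimws(strsplit(lines[rows[i]], sep)[[1]])
    v <- suppressWarnings(as.numeric(p[1:2]))
    if (length(p) < 2 || any(is.na(v)))
      stop(path, ": malformed row at line ", rows[i], ": '",
           lines[rows[i]], "'")
    vals[i, ] <- v
  }
  list(x = vals[, 1], y = vals[, 2], meta = meta)
}

check_uniform_grid <- function(t, path, tol = 1e-6) {
  d <- diff(t)
  if (length(d) < 1 || any(d <= 0) ||
      max(abs(d - d[1])) > tol * abs(d[1]))
    stop(path, ": time grid is not uniform; resampling is not performed")
  d[1]
}

#' Read a decay or IRF file
#'
#' Two-column ASCII/CSV with header \code{time_ns,counts}; lines starting
#' with \code{#} are comments (and \code{# key: value} comments are
#' collected as metadata). The time grid must be uniform.
#'
#' @param path file path.
#' @return \code{read_decay}: a \code{\link{decay_trace}};
#'   \code{read_irf}: an \code{\link{instrument_response}}.
#' @export
read_decay <- function(path) {
  d <- read_two_column(path, "time_ns", "counts")
  dt <- check_uniform_grid(d$x, path)
  ax <- time_axis(t0 = d$x[1], dt = dt, n = length(d$x))
  meta <- d$meta
  lab <- meta[["label"]] %||% basename(path)
  decay_trace(ax, d$y, label = lab, meta = meta)
}

#' @rdname read_decay
#' @export
read_irf <- function(path) {
  d <- read_two_column(path, "time_ns", "counts")
  dt <- check_uniform_grid(d$x, path)
  ax <- time_axis(t0 = d$x[1], dt = dt, n = length(d$x))
  instrument_response(ax, d$y)
}

#' Write a decay trace or IRF to file
#'
#' @param x a \code{\link{decay_trace}} or
#'   \code{\link{instrument_response}}.
#' @param path output path.
#' @export
write_decay <- function(x, path) {
  ax <- x$axis
  t <- axis_times(ax)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "decay_trace")) {
    writeLines(sprintf("# label: %s", x$label), con)
    for (nm in names(x$meta))
      if (nm != "label")
        writeLines(sprintf("# %s: %s", nm, format(x$meta[[nm]],
                                                  digits = 15)), con)
  }
  writeLines("time_ns,counts", con)
  writeLines(sprintf("%.10g,%.15g", t, x$counts), con)
  invisible(path)
}

#' Read titration emission spectra
#'
#' CSV with a \code{wavelength_nm} column plus one intensity column per
#' titration point, and a manifest CSV with columns \code{column} (the
#' intensity column name) and \code{dna_conc_M}; an optional
#' \code{dye_conc_M} column applies to all points.
#'
#' @param path spectra CSV path.
#' @param manifest manifest CSV path.
#' @return List of \code{\link{emission_spectrum}} objects, ordered as in
#'   the manifest.
#' @export
read_spectra <- function(path, manifest) {
  sp <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"wavelength_nm" %in% names(sp))
    stop(path, ": missing 'wavelength_nm' column")
  mf <- utils::read.csv(manifest, comment.char = "#")
  if (!all(c("column", "dna_conc_M") %in% names(mf)))
    stop(manifest, ": needs columns 'column' and 'dna_conc_M'")
  missing_cols <- setdiff(mf$column, names(sp))
  if (length(missing_cols))
    stop(path, ": manifest names absent column(s): ",
         paste(missing_cols, collapse = ", "))
  dye <- if ("dye_conc_M" %in% names(mf)) mf$dye_conc_M else NA_real_
  lapply(seq_len(nrow(mf)), function(i)
    emission_spectrum(sp$wavelength_nm, sp[[mf$column[i]]],
                      dna_conc = mf$dna_conc_M[i],
                      dye_conc = if (length(dye) > 1) dye[i] else dye))
}

#' Read a cyclic voltammogram file
#'
#' Two-column CSV \code{potential_V,current_A}; metadata in comment
#' headers, e.g. \code{# scan_rate_V_s: 0.1} and \code{# reference:
#' Fc+/Fc}.
#'
#' @param path file path.
#' @param scan_rate scan rate (V/s); overrides any file metadata.
#' @return A \code{\link{voltammogram}}.
#' @export
read_cv <- function(path, scan_rate = NULL) {
  d <- read_two_column(path, "potential_V", "current_A")
  sr <- scan_rate %||%
    suppressWarnings(as.numeric(d$meta[["scan_rate_V_s"]]))
  if (is.null(sr) || length(sr) == 0 || is.na(sr))
    stop(path, ": scan rate not given (no '# scan_rate_V_s:' header)")
  voltammogram(d$x, d$y, scan_rate = sr,
               reference = d$meta[["reference"]] %||% "Fc+/Fc")
}

#' Write a voltammogram to file
#'
#' @param v a \code{\link{voltammogram}}.
#' @param path output path.
#' @export
write_cv <- function(v, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scan_rate_V_s: %g", v$scan_rate), con)
  writeLines(sprintf("# reference: %s", v$reference), con)
  writeLines("potential_V,current_A", con)
  writeLines(sprintf("%.9g,%.9g", v$potential, v$current), con)
  invisible(path)
}

## ---- structured reports -------------------------------------------------

#' Structured JSON report of an analysis result
#'
#' Serialises fit results to a stable key schema at full float precision.
#' Understands \code{\link{fit_global}}, \code{\link{fit_single}},
#' \code{\link{tau_support_plane}} and \code{\link{fit_1to1}} results;
#' anything else is serialised as-is.
#'
#' @param results an analysis object (or plain list).
#' @param path optional output path; if \code{NULL} the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_json <- function(results, path = NULL) {
  x <- report_list(results)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname report_json
#' @export
report_list <- function(results) {
  if (inherits(results, "global_fit")) {
    list(type = "global_fit",
         shared_tau_ns = results$shared_tau,
         fixed = results$fixed_mask,
         global_chisq_r = results$global_chisq_r,
         p = results$p, v = results$v,
         converged = results$converged,
         per_trace = lapply(results$per_trace, function(s)
           list(alpha = s$alpha, f = s$f, tau_bar_ns = s$tau_bar,
                scale = s$scale, shift_ns = s$shift,
                chisq_r = s$chisq_r)))
  } else if (inherits(results, "decay_fit")) {
    list(type = "decay_fit",
         tau_ns = results$params$tau, alpha = results$params$alpha,
         fixed = results$fixed_mask,
         f = results$f, tau_bar_ns = results$tau_bar,
         scale = results$params$scale,
         shift_ns = results$params$shift,
         chisq_r = results$chisq_r, n_free = results$n_free,
         converged = results$converged)
  } else if (inherits(results, "support_plane")) {
    list(type = "support_plane", component = results$component,
         threshold = results$threshold,
         P = results$P, p = results$spec$p, v = results$spec$v,
         profile = as.data.frame(results),
         accepted_ranges_ns = results$accepted_runs)
  } else if (inherits(results, "binding_fit")) {
    list(type = "binding_fit", Ka_per_M = results$Ka,
         log10Ka = results$log10Ka, I_free = results$I_free,
         I_bound = results$I_bound, motif_size = results$motif_size,
         lower_bound_only = results$lower_bound_only,
         converged = results$converged)
  } else if (inherits(results, "redox_summary")) {
    unclass(results)
  } else {
    results
  }
}
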