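#' @title Spectral preprocessing
#' @name preprocess
#' @description Inner-filter correction, band extraction, ratio tracking and
#'   emission-maximum tracking: the steps that turn a raw spectral grid into
#'   the 1-D observables the transition fits consume.
NULL

#' Correct fluorescence intensities for the inner-filter effect
#'
#' Absorbance of the sample at the excitation and emission wavelengths
#' attenuates observed fluorescence; the standard multiplicative correction
#' is F_cor = F_obs * exp((A_ex + A_em)/2), applied per condition. Series
#' without absorbances pass through unchanged with `applied = FALSE`.
#'
#' @param series a `spectrum_series` with a fluorescence probe kind
#'   (`trp_fluorescence` or `ans`).
#' @return a list with `series` (corrected `spectrum_series`) and `report`,
#'   a `correction_report` holding per-condition `applied` flags and the
#'   maximum correction factor (>= 1 for non-negative absorbances).
#' @export
correct_inner_filter <- function(series) {
  validate_spectrum_series(series)
  if (!series$probe_kind %in% c("trp_fluorescence", "ans"))
    stop("inner-filter correction applies to fluorescence probes only")
  nc <- length(series$condition_values)
  if (is.null(series$absorbances)) {
    report <- structure(list(applied = rep(FALSE, nc),
                             max_correction_factor = 1),
                        class = "correction_report")
    return(list(series = series, report = report))
  }
  ab <- series$absorbances
  if (any(ab$A_ex < 0) || any(ab$A_em < 0))
    stop("negative absorbance")
  factors <- exp((ab$A_ex + ab$A_em) / 2)
  series$intensities <- series$intensities * factors
  report <- structure(list(applied = rep(TRUE, nc),
                           max_correction_factor = max(factors)),
                      class = "correction_report")
  list(series = validate_spectrum_series(series), report = report)
}

#' Extract a single-wavelength band across conditions
#'
#' Returns the per-condition intensity at the requested wavelength. Exact
#' grid hits return the stored column; off-grid wavelengths are linearly
#' interpolated between the two bracketing grid points (emission grids are
#' 1-5 nm, so higher-order interpolation is not identifiable).
#'
#' @param series a `spectrum_series`.
#' @param wavelength_nm requested wavelength; must lie within the recorded
#'   range.
#' @return an `unfolding_curve` on the series' condition axis.
#' @export
extract_band <- function(series, wavelength_nm) {
  validate_spectrum_series(series)
  wl <- series$wavelengths_nm
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    stop(sprintf("wavelength %g nm outside recorded range [%g, %g]",
                 wavelength_nm, min(wl), max(wl)))
  hit <- which(abs(wl - wavelength_nm) < 1e-9)
  if (length(hit)) {
    y <- series$intensities[, hit[1L]]
  } else {
    hi <- findInterval(wavelength_nm, wl) + 1L
    lo <- hi - 1L
    w <- (wavelength_nm - wl[lo]) / (wl[hi] - wl[lo])
    y <- (1 - w) * series$intensities[, lo] + w * series$intensities[, hi]
  }
  unfolding_curve(series$axis_kind, series$condition_values, y,
                  observable_label = sprintf("I(%g nm)", wavelength_nm))
}

#' Per-condition intensity ratio between two emission bands
#'
#' The ratio of two band intensities (canonically F350/F335) tracks shifts
#' of the emission maximum without choosing baselines. Because the
#' inner-filter factor is per-condition, the ratio is exactly invariant
#' under [correct_inner_filter()].
#'
#' @param series a `spectrum_series`.
#' @param num_nm numerator wavelength (nm).
#' @param den_nm denominator wavelength (nm).
#' @return an `unfolding_curve` labelled with both wavelengths.
#' @export
intensity_ratio <- function(series, num_nm, den_nm) {
  num <- extract_band(series, num_nm)
  den <- extract_band(series, den_nm)
  zero <- which(den$y == 0)
  if (length(zero))
    stop(sprintf("zero denominator intensity at condition %g",
                 series$condition_values[zero[1L]]))
  unfolding_curve(series$axis_kind, series$condition_values,
                  num$y / den$y,
                  observable_label = sprintf("F%g/F%g", num_nm, den_nm))
}

#' Track the emission maximum wavelength across conditions
#'
#' Per condition, finds the grid argmax and refines it with a 3-point
#' parabolic fit through (argmax - 1, argmax, argmax + 1), giving sub-grid
#' resolution for smooth bands. Boundary maxima (monotone spectra) are
#' returned unrefined and flagged; flat spectra break ties toward the
#' lowest wavelength, flagged.
#'
#' @param series a `spectrum_series` with at least 3 wavelengths.
#' @return an `unfolding_curve` of lambda_max (nm) vs condition; boundary or
#'   flat conditions are listed in the curve's `flags`.
#' @export
lambda_max <- function(series) {
  validate_spectrum_series(series)
  wl <- series$wavelengths_nm
  if (length(wl) < 3L) stop("lambda_max needs >= 3 wavelengths")
  flags <- character()
  centers <- vapply(seq_along(series$condition_values), function(i) {
    row <- series$intensities[i, ]
    k <- which.max(row)  # ties -> lowest wavelength
    if (all(row == row[1L])) {
      flags <<- c(flags, sprintf("flat spectrum at condition %g",
                                 series$condition_values[i]))
      return(wl[1L])
    }
    if (k == 1L || k == length(wl)) {
      flags <<- c(flags, sprintf("boundary maximum at condition %g",
                                 series$condition_values[i]))
      return(wl[k])
    }
    # parabola through three points; vertex of the quadratic interpolant
    x3 <- wl[(k - 1L):(k + 1L)]
    y3 <- row[(k - 1L):(k + 1L)]
    denom <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
    a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) +
          x3[1] * (y3[3] - y3[2])) / denom
    b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) +
          x3[1]^2 * (y3[2] - y3[3])) / denom
    if (a == 0) return(wl[k])
    v <- -b / (2 * a)
    # guard: vertex must stay inside the bracketing interval
    if (v < x3[1] || v > x3[3]) wl[k] else v
  }, numeric(1))
  unfolding_curve(series$axis_kind, series$condition_values, centers,
                  observable_label = "lambda_max (nm)", flags = flags)
}
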