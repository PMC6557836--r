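#' @title Spectral denaturation data model
#' @name spectra_model
#' @description S3 containers and plain-text I/O for spectroscopic
#'   denaturation series: a probe's intensity grid over
#'   (condition value x emission wavelength), plus the derived 1-D curves the
#'   fitting stages consume.
NULL

PROBE_KINDS <- c("trp_fluorescence", "far_uv_cd", "ans", "rls")
AXIS_KINDS  <- c("temperature_C", "pH", "denaturant_M")

#' Construct a spectrum series
#'
#' A `spectrum_series` holds one probe's spectra across a denaturation axis:
#' an intensity matrix with one row per condition (temperature, pH, or
#' denaturant molarity) and one column per emission wavelength. Intensities
#' are in instrument units (mdeg for CD); no unit conversion is performed.
#'
#' @param probe_kind one of `"trp_fluorescence"`, `"far_uv_cd"`, `"ans"`,
#'   `"rls"`.
#' @param axis_kind one of `"temperature_C"`, `"pH"`, `"denaturant_M"`.
#' @param condition_values numeric, strictly monotone (ascending or
#'   descending; acid series naturally run pH 7 down to 1 and are stored as
#'   given).
#' @param wavelengths_nm numeric, strictly ascending.
#' @param intensities numeric matrix, `length(condition_values)` rows by
#'   `length(wavelengths_nm)` columns.
#' @param excitation_nm optional excitation wavelength (nm).
#' @param absorbances optional data frame with columns `A_ex`, `A_em`
#'   (dimensionless absorbances at excitation and emission wavelengths), one
#'   row per condition; used by the inner-filter correction.
#' @return an object of class `spectrum_series`.
#' @export
spectrum_series <- function(probe_kind, axis_kind, condition_values,
                            wavelengths_nm, intensities,
                            excitation_nm = NULL, absorbances = NULL) {
  probe_kind <- match.arg(probe_kind, PROBE_KINDS)
  axis_kind <- match.arg(axis_kind, AXIS_KINDS)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  obj <- structure(
    list(probe_kind = probe_kind,
         axis_kind = axis_kind,
         condition_values = as.numeric(condition_values),
         wavelengths_nm = as.numeric(wavelengths_nm),
         intensities = intensities,
         excitation_nm = if (is.null(excitation_nm)) NULL else
           as.numeric(excitation_nm),
         absorbances = if (is.null(absorbances)) NULL else
           as.data.frame(absorbances)),
    class = "spectrum_series")
  validate_spectrum_series(obj)
}

strictly_monotone <- function(x) {
  if (length(x) < 2) return(TRUE)
  d <- diff(x)
  all(d > 0) || all(d < 0)
}

#' Validate a spectrum series
#'
#' Checks the container invariants: matrix shape, monotone condition axis,
#' strictly ascending finite wavelengths, finite intensities, and (when
#' present) one non-negative absorbance pair per condition.
#'
#' @param x a `spectrum_series`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_spectrum_series <- function(x) {
  stopifnot(inherits(x, "spectrum_series"))
  nc <- length(x$condition_values)
  nw <- length(x$wavelengths_nm)
  if (nc < 1L || nw < 1L)
    stop("spectrum_series: empty condition or wavelength axis")
  if (!all(is.finite(x$condition_values)))
    stop("spectrum_series: non-finite condition values")
  if (!all(is.finite(x$wavelengths_nm)))
    stop("spectrum_series: non-finite wavelengths")
  if (!identical(dim(x$intensities), c(nc, nw)))
    stop(sprintf(
      "spectrum_series: intensities shape (%d,%d) != (conditions=%d, wavelengths=%d)",
      nrow(x$intensities), ncol(x$intensities), nc, nw))
  if (!all(is.finite(x$intensities)))
    stop("spectrum_series: non-finite intensities")
  if (!strictly_monotone(x$condition_values))
    stop("spectrum_series: condition_values must be strictly monotone")
  if (nw >= 2 && !all(diff(x$wavelengths_nm) > 0))
    stop("spectrum_series: wavelengths_nm must be strictly ascending")
  if (!is.null(x$absorbances)) {
    ab <- x$absorbances
    if (!all(c("A_ex", "A_em") %in% names(ab)))
      stop("spectrum_series: absorbances must have columns A_ex, A_em")
    if (nrow(ab) != nc)
      stop("spectrum_series: absorbances must have one row per condition")
    if (any(!is.finite(ab$A_ex)) || any(!is.finite(ab$A_em)))
      stop("spectrum_series: non-finite absorbances")
  }
  invisible(x)
}

#' @export
print.spectrum_series <- function(x, ...) {
  cat(sprintf("<spectrum_series> probe=%s axis=%s\n", x$probe_kind,
              x$axis_kind))
  cat(sprintf("  %d conditions [%g .. %g], %d wavelengths [%g .. %g] nm\n",
              length(x$condition_values), x$condition_values[1],
              x$condition_values[length(x$condition_values)],
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm)))
  if (!is.null(x$excitation_nm))
    cat(sprintf("  excitation %g nm\n", x$excitation_nm))
  if (!is.null(x$absorbances)) cat("  absorbances present\n")
  invisible(x)
}

#' Construct a 1-D unfolding observable curve
#'
#' Holds a single observable against the denaturation axis: a band
#' intensity, a CD signal, or an intensity ratio such as F350/F335.
#'
#' @param axis_kind condition axis kind (see [spectrum_series()]).
#' @param x numeric condition values, strictly monotone.
#' @param y numeric observable values, same length as `x`.
#' @param observable_label free-text description of the observable.
#' @param flags optional character vector of quality flags.
#' @return an `unfolding_curve`.
#' @export
unfolding_curve <- function(axis_kind, x, y, observable_label = "",
                            flags = character()) {
  axis_kind <- match.arg(axis_kind, AXIS_KINDS)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("unfolding_curve: x and y lengths differ")
  if (!strictly_monotone(x))
    stop("unfolding_curve: x must be strictly monotone")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("unfolding_curve: non-finite values")
  structure(list(axis_kind = axis_kind, x = x, y = y,
                 observable_label = observable_label, flags = flags),
            class = "unfolding_curve")
}

#' @export
print.unfolding_curve <- function(x, ...) {
  cat(sprintf("<unfolding_curve> %s vs %s, %d points\n",
              if (nzchar(x$observable_label)) x$observable_label else "y",
              x$axis_kind, length(x$x)))
  invisible(x)
}

#' Construct an unfolded-fraction curve
#'
#' The normalized unfolding observable f_u = (F_obs - F_n)/(F_d - F_n).
#' Values are expected in [0, 1] up to a small tolerance when `clipped`;
#' unclipped raw values (slightly outside due to noise) are allowed so that
#' downstream fits see the data unmodified.
#'
#' @param axis_kind condition axis kind.
#' @param x numeric condition values, strictly monotone.
#' @param f_u numeric unfolded fractions.
#' @param segment_label label of the transition segment this curve covers.
#' @param clipped logical; if `TRUE`, enforce 0 <= f_u <= 1 within 1e-9.
#' @return a `fraction_curve`.
#' @export
fraction_curve <- function(axis_kind, x, f_u, segment_label = "",
                           clipped = FALSE) {
  axis_kind <- match.arg(axis_kind, AXIS_KINDS)
  x <- as.numeric(x); f_u <- as.numeric(f_u)
  if (length(x) != length(f_u))
    stop("fraction_curve: x and f_u lengths differ")
  if (!strictly_monotone(x))
    stop("fraction_curve: x must be strictly monotone")
  if (clipped && (any(f_u < -1e-9) || any(f_u > 1 + 1e-9)))
    stop("fraction_curve: f_u outside [0,1] beyond tolerance")
  structure(list(axis_kind = axis_kind, x = x, f_u = f_u,
                 segment_label = segment_label, clipped = clipped),
            class = "fraction_curve")
}

#' @export
print.fraction_curve <- function(x, ...) {
  cat(sprintf("<fraction_curve> %d points on %s%s\n", length(x$x),
              x$axis_kind,
              if (nzchar(x$segment_label))
                paste0(" [", x$segment_label, "]") else ""))
  invisible(x)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a spectrum series from a delimited text file
#'
#' Accepts either long format (columns for condition, wavelength, intensity,
#' optionally `A_ex`/`A_em`) or wide format (first column = condition,
#' remaining column names = wavelengths). Comma or tab delimiters are
#' auto-detected; a header row is required; `.` is the decimal separator.
#'
#' @param path file path.
#' @param probe_kind,axis_kind series metadata (see [spectrum_series()]).
#' @param schema for long format, a named list mapping roles to column
#'   names: `condition`, `wavelength`, `intensity`, and optionally `A_ex`,
#'   `A_em`. Defaults to the column names [write_spectrum_series()] emits.
#' @param format `"long"` (canonical) or `"wide"`.
#' @param excitation_nm optional excitation wavelength to attach.
#' @return a validated `spectrum_series`.
#' @export
read_spectrum_series <- function(path, probe_kind, axis_kind,
                                 schema = list(condition = "condition",
                                               wavelength = "wavelength_nm",
                                               intensity = "intensity"),
                                 format = c("long", "wide"),
                                 excitation_nm = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  delim <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  if (format == "wide") {
    cond <- as.numeric(df[[1L]])
    wl <- suppressWarnings(as.numeric(names(df)[-1L]))
    if (any(is.na(wl)))
      stop("wide format: non-numeric wavelength column names")
    mat <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(mat) <- "double"
    ord_w <- order(wl)
    return(spectrum_series(probe_kind, axis_kind, cond, wl[ord_w],
                           mat[, ord_w, drop = FALSE],
                           excitation_nm = excitation_nm))
  }
  need <- c("condition", "wavelength", "intensity")
  for (role in need)
    if (is.null(schema[[role]]))
      stop(sprintf("schema missing role '%s'", role))
  missing_cols <- setdiff(unlist(schema[need]), names(df))
  if (length(missing_cols))
    stop(sprintf("missing columns in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  numify <- function(col) {
    v <- df[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric cell in column '%s' at data row %d: '%s'",
                   col, bad[1L], v[bad[1L]]))
    out
  }
  cond <- numify(schema$condition)
  wl <- numify(schema$wavelength)
  int <- numify(schema$intensity)
  key <- paste(format(cond, digits = 15), format(wl, digits = 15))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate (condition, wavelength) cell: %s", d))
  }
  cond_u <- unique(cond)
  # preserve the file's condition order (acid series may descend)
  wl_u <- sort(unique(wl))
  mat <- matrix(NA_real_, length(cond_u), length(wl_u))
  ci <- match(cond, cond_u)
  wi <- match(wl, wl_u)
  mat[cbind(ci, wi)] <- int
  if (any(is.na(mat)))
    stop("incomplete grid: every condition must record every wavelength")
  ab <- NULL
  if (!is.null(schema$A_ex) && !is.null(schema$A_em) &&
      all(c(schema$A_ex, schema$A_em) %in% names(df))) {
    aex <- numify(schema$A_ex); aem <- numify(schema$A_em)
    first_idx <- match(cond_u, cond)
    ab <- data.frame(A_ex = aex[first_idx], A_em = aem[first_idx])
  }
  spectrum_series(probe_kind, axis_kind, cond_u, wl_u, mat,
                  excitation_nm = excitation_nm, absorbances = ab)
}

#' Write a spectrum series as long-format delimited text
#'
#' Emits the canonical long format (`condition`, `wavelength_nm`,
#' `intensity`, and `A_ex`/`A_em` when absorbances are present) at 12
#' significant digits so that [read_spectrum_series()] round-trips the
#' numeric payload exactly at that precision.
#'
#' @param series a valid `spectrum_series`.
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_spectrum_series <- function(series, path, sep = ",") {
  validate_spectrum_series(series)
  nc <- length(series$condition_values)
  nw <- length(series$wavelengths_nm)
  df <- data.frame(
    condition = rep(series$condition_values, each = nw),
    wavelength_nm = rep(series$wavelengths_nm, times = nc),
    intensity = as.vector(t(series$intensities)))
  if (!is.null(series$absorbances)) {
    df$A_ex <- rep(series$absorbances$A_ex, each = nw)
    df$A_em <- rep(series$absorbances$A_em, each = nw)
  }
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  out <- df
  for (nm in names(out)) out[[nm]] <- fmt(out[[nm]])
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
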