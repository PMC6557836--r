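#' @title Unfolding thermodynamics and kinetics
#' @name energetics
#' @description Equilibrium-constant conventions, Gibbs free energy of
#'   unfolding, linear extrapolation of per-point free energies
#'   (intercept = free energy in the absence of perturbant, slope = m-value)
#'   and the half-chevron intercept giving the zero-denaturant unfolding
#'   constant.
NULL

#' Ideal gas constant, kcal mol^-1 K^-1
#' @export
R_KCAL <- 1.987204e-3

#' Equilibrium constant from the unfolded fraction
#'
#' Two conventions are supported. `"literal_fu"` takes K = f_u directly
#' (some spectroscopic treatments annotate the equilibrium constant as the
#' unfolded fraction itself); `"ratio"` is the conventional two-state
#' K = f_u / (1 - f_u). All round-trip identities in this package hold
#' under `"ratio"`.
#'
#' @param f_u unfolded fraction(s), strictly inside (0, 1).
#' @param convention `"literal_fu"` or `"ratio"`.
#' @return equilibrium constant(s).
#' @export
equilibrium_constant <- function(f_u, convention = c("literal_fu", "ratio")) {
  convention <- match.arg(convention)
  if (any(f_u <= 0) || any(f_u >= 1))
    stop("f_u must lie strictly in (0, 1)")
  switch(convention, literal_fu = f_u, ratio = f_u / (1 - f_u))
}

#' Gibbs free energy from an equilibrium constant
#'
#' Delta G = -R T ln K with R = 1.987204e-3 kcal mol^-1 K^-1. Temperatures
#' always enter in kelvin.
#'
#' @param K equilibrium constant(s), > 0.
#' @param T_kelvin absolute temperature(s), > 0 K.
#' @return free energy in kcal mol^-1.
#' @export
delta_g <- function(K, T_kelvin) {
  if (any(K <= 0)) stop("K must be positive")
  if (any(T_kelvin <= 0)) stop("T_kelvin must be positive")
  -R_KCAL * T_kelvin * log(K)
}

#' Linear extrapolation of per-point free energies
#'
#' Ordinary least squares of Delta G against the perturbant axis, reported
#' in the convention Delta G = intercept - slope * x, so a positive slope
#' (m-value) means destabilization with increasing perturbant. The
#' intercept is the free energy extrapolated to x = 0 (water, 0 M
#' denaturant, or 0 on the chosen temperature axis).
#'
#' @param x perturbant values (temperature or denaturant concentration).
#' @param dg free energies (kcal mol^-1), same length.
#' @return list with `intercept`, `slope`, `intercept_se`, `slope_se`,
#'   `r_squared`, `n`.
#' @export
linear_extrapolation <- function(x, dg) {
  x <- as.numeric(x); dg <- as.numeric(dg)
  if (length(x) != length(dg)) stop("x and dg lengths differ")
  if (length(unique(x)) < 2L) stop("need >= 2 distinct x values")
  fit <- stats::lm(dg ~ x)
  # summary() warns on exact (noise-free) lines; that case is legitimate
  # here, so the warning is silenced and the SEs come back as ~0
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  slope_se <- if (nrow(cf) >= 2 && !is.na(cf[2, 2])) cf[2, 2] else NA_real_
  int_se <- if (!is.na(cf[1, 2])) cf[1, 2] else NA_real_
  list(intercept = unname(stats::coef(fit)[1]),
       slope = -unname(stats::coef(fit)[2]),
       intercept_se = int_se, slope_se = slope_se,
       r_squared = sm$r.squared, n = length(x))
}

filter_transition_region <- function(x, f_u, lower = 0.05, upper = 0.95) {
  keep <- f_u >= lower & f_u <= upper
  list(x = x[keep], f_u = f_u[keep], kept = which(keep))
}

#' Thermal unfolding thermodynamics by linear extrapolation
#'
#' Chains the per-point equilibrium constant, Delta G_u = -R T ln K (T in
#' kelvin at each point), and the linear extrapolation
#' Delta G_u = Delta G^H2O - m T. Points with f_u outside the transition
#' region (default 0.05-0.95) are excluded because ln f diverges at the
#' plateaus.
#'
#' @param frac a `fraction_curve` on a temperature axis (degrees C).
#' @param convention equilibrium-constant convention (see
#'   [equilibrium_constant()]).
#' @param regression_axis `"celsius"` (as plotted in typical melts) or
#'   `"kelvin"`; affects only the regression abscissa, never Eq. 3's T.
#' @param f_limits transition-region inclusion bounds on f_u.
#' @return a `thermo_result`: `delta_g_h2o` (kcal mol^-1, the regression
#'   value at x = 0), `m_value` (kcal mol^-1 per axis unit), their SEs,
#'   `k_convention`, `regression_axis`, and `per_point` (x, f_u, K_eq,
#'   dG_u).
#' @export
thermal_energetics <- function(frac,
                               convention = c("literal_fu", "ratio"),
                               regression_axis = c("celsius", "kelvin"),
                               f_limits = c(0.05, 0.95)) {
  stopifnot(inherits(frac, "fraction_curve"))
  if (frac$axis_kind != "temperature_C")
    stop("thermal_energetics requires a temperature axis")
  convention <- match.arg(convention)
  regression_axis <- match.arg(regression_axis)
  fl <- filter_transition_region(frac$x, frac$f_u, f_limits[1], f_limits[2])
  if (length(fl$x) < 2L)
    stop("fewer than 2 points inside the transition region")
  Tk <- fl$x + 273.15
  K <- equilibrium_constant(fl$f_u, convention)
  dg <- delta_g(K, Tk)
  xr <- if (regression_axis == "celsius") fl$x else Tk
  lem <- linear_extrapolation(xr, dg)
  structure(list(delta_g_h2o = lem$intercept, m_value = lem$slope,
                 delta_g_h2o_se = lem$intercept_se, m_se = lem$slope_se,
                 k_convention = convention,
                 regression_axis = regression_axis,
                 per_point = data.frame(x = fl$x, f_u = fl$f_u, K_eq = K,
                                        dG_u = dg)),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf(
    "<thermo_result> dG_H2O = %.4g +/- %.2g kcal/mol, m = %.4g +/- %.2g kcal/mol per %s (%d pts, %s)\n",
    x$delta_g_h2o, x$delta_g_h2o_se, x$m_value, x$m_se,
    if (x$regression_axis == "celsius") "degC" else "K",
    nrow(x$per_point), x$k_convention))
  invisible(x)
}

#' Chemical unfolding constant
#'
#' K_ui = P_t f_u / [P_t (1 - f_u)]^n, where P_t is the total protein
#' concentration (M) and n the number of chains after denaturation. For a
#' monomer (n = 1) P_t cancels exactly and K_ui = f_u / (1 - f_u).
#'
#' @param f_u unfolded fraction(s) in (0, 1).
#' @param p_t protein concentration, M; consulted only when `n > 1`.
#' @param n integer number of product chains, >= 1.
#' @return unfolding constant(s).
#' @export
chemical_unfolding_constant <- function(f_u, p_t = 5e-6, n = 1L) {
  if (any(f_u <= 0) || any(f_u >= 1)) stop("f_u must lie in (0, 1)")
  if (n < 1L) stop("n must be >= 1")
  if (n == 1L) return(f_u / (1 - f_u))
  if (p_t <= 0) stop("p_t must be positive")
  p_t * f_u / (p_t * (1 - f_u))^n
}

#' Chemical denaturation energetics and half-chevron intercept
#'
#' Per point, K_ui and Delta G_ui = -R T ln K_ui; the zero-denaturant free
#' energy Delta G_0 is the y-intercept of Delta G_ui against denaturant
#' concentration, and log K_obs is the y-intercept of log10 K_ui against
#' concentration (half-chevron). The transition midpoint Cm is taken from a
#' sigmoid fit of the same fraction curve unless supplied.
#'
#' @param frac a `fraction_curve` on a denaturant axis (M).
#' @param p_t,n see [chemical_unfolding_constant()].
#' @param T_kelvin temperature of the experiment, K.
#' @param c_m optional transition midpoint (M); when `NULL` it is obtained
#'   by [fit_transition()] on `frac`.
#' @param f_limits transition-region inclusion bounds on f_u.
#' @param log_base base of the reported log K_obs (10, matching the usual
#'   tabulation; use `exp(1)` for natural log).
#' @return a `chem_result`: `c_m`, `delta_g0`, `log_k_obs`, SEs, `n_chains`,
#'   `p_t`, `per_point` (x, f_u, K_ui, dG_ui).
#' @export
chemical_energetics <- function(frac, p_t = 5e-6, n = 1L,
                                T_kelvin = 298.15, c_m = NULL,
                                f_limits = c(0.05, 0.95), log_base = 10) {
  stopifnot(inherits(frac, "fraction_curve"))
  if (frac$axis_kind != "denaturant_M")
    stop("chemical_energetics requires a denaturant axis")
  fl <- filter_transition_region(frac$x, frac$f_u, f_limits[1], f_limits[2])
  if (length(fl$x) < 2L)
    stop("fewer than 2 points inside the transition region")
  K <- chemical_unfolding_constant(fl$f_u, p_t, n)
  dg <- delta_g(K, T_kelvin)
  lem_g <- linear_extrapolation(fl$x, dg)
  lem_k <- linear_extrapolation(fl$x, log(K, base = log_base))
  if (is.null(c_m)) {
    fit <- fit_transition(frac)
    c_m <- fit$midpoint
  }
  structure(list(c_m = c_m, delta_g0 = lem_g$intercept,
                 delta_g0_se = lem_g$intercept_se,
                 m_chem = lem_g$slope, m_chem_se = lem_g$slope_se,
                 log_k_obs = lem_k$intercept,
                 log_k_obs_se = lem_k$intercept_se,
                 log_base = log_base,
                 n_chains = as.integer(n), p_t = p_t,
                 T_kelvin = T_kelvin,
                 per_point = data.frame(x = fl$x, f_u = fl$f_u, K_ui = K,
                                        dG_ui = dg)),
            class = "chem_result")
}

#' @export
print.chem_result <- function(x, ...) {
  cat(sprintf(
    "<chem_result> Cm = %.4g M, dG0 = %.4g +/- %.2g kcal/mol, m = %.4g, log K_obs = %.4g (%d pts)\n",
    x$c_m, x$delta_g0, x$delta_g0_se, x$m_chem, x$log_k_obs,
    nrow(x$per_point)))
  invisible(x)
}
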