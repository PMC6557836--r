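#' @title Synthetic data generators
#' @name synthetic_data
#' @description Seeded generators that produce spectra, unfolded-fraction
#'   curves and toy trajectories with known ground truth, giving every
#'   analysis stage a recoverable-truth test without any downloads. The
#'   emission band model is a Gaussian in wavelength whose center and
#'   amplitude interpolate linearly between native and denatured values
#'   with the unfolded fraction; under that model the log intensity ratio
#'   between two fixed wavelengths is exactly affine in the unfolded
#'   fraction, so sigmoid fits of the log-ratio recover latent midpoints
#'   without model bias.
NULL

#' Ground truth for a synthetic spectral denaturation series
#'
#' @param scheme `"one_step"` or `"two_step"`.
#' @param midpoints transition midpoint(s), one per segment, ordered along
#'   the unfolding direction.
#' @param steepness positive sigmoid steepness, one per segment (axis
#'   units).
#' @param band_center_native,band_center_denatured emission-band centers
#'   (nm); defaults 342 -> 350, the typical tryptophan red shift on
#'   unfolding.
#' @param amplitude_native,amplitude_denatured band peak amplitudes (a.u.);
#'   intensity typically falls on unfolding.
#' @param band_width_nm Gaussian band sigma (nm).
#' @param noise_sd Gaussian noise standard deviation as a fraction of the
#'   native amplitude.
#' @param seed integer RNG seed.
#' @return a `spectral_truth`.
#' @export
spectral_truth <- function(scheme = c("one_step", "two_step"),
                           midpoints = 54.57, steepness = 2,
                           band_center_native = 342,
                           band_center_denatured = 350,
                           amplitude_native = 1000,
                           amplitude_denatured = 400,
                           band_width_nm = 15,
                           noise_sd = 0, seed = 1L) {
  scheme <- match.arg(scheme)
  n_seg <- if (scheme == "two_step") 2L else 1L
  if (length(midpoints) != n_seg)
    stop(sprintf("%s scheme needs %d midpoint(s)", scheme, n_seg))
  steepness <- rep_len(steepness, n_seg)
  if (any(steepness <= 0)) stop("steepness must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(scheme = scheme, midpoints = as.numeric(midpoints),
                 steepness = as.numeric(steepness),
                 band_center_native = band_center_native,
                 band_center_denatured = band_center_denatured,
                 amplitude_native = amplitude_native,
                 amplitude_denatured = amplitude_denatured,
                 band_width_nm = band_width_nm,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spectral_truth")
}

# per-segment sigmoid progress, direction set by the axis: temperature and
# denaturant unfold with increasing x, pH with decreasing x
segment_progress <- function(x, midpoint, steepness, axis_kind) {
  if (axis_kind == "pH") 1 / (1 + exp((x - midpoint) / steepness))
  else 1 / (1 + exp(-(x - midpoint) / steepness))
}

unfolding_progress <- function(x, truth, axis_kind) {
  s <- vapply(seq_along(truth$midpoints), function(i)
    segment_progress(x, truth$midpoints[i], truth$steepness[i], axis_kind),
    numeric(length(x)))
  rowMeans(matrix(s, nrow = length(x)))
}

#' Generate a synthetic spectral denaturation series
#'
#' Per condition, the unfolded progress follows the truth's (possibly
#' two-step) sigmoid scheme; the emission band is a Gaussian whose center
#' and amplitude interpolate native -> denatured with the progress.
#' Noise is i.i.d. Gaussian on every grid intensity, scaled by the native
#' amplitude, from a stream seeded by `truth$seed` (same seed, bit-identical
#' output).
#'
#' @param truth a `spectral_truth`.
#' @param probe_kind probe label for the series.
#' @param axis_kind condition axis kind.
#' @param condition_values condition grid (stored as given; pH grids may
#'   descend).
#' @param wavelengths_nm emission wavelength grid.
#' @param excitation_nm optional excitation wavelength metadata.
#' @param absorbances optional `data.frame(A_ex, A_em)` attached verbatim.
#' @return a `spectrum_series`.
#' @export
generate_denaturation_series <- function(truth,
                                         probe_kind = "trp_fluorescence",
                                         axis_kind = "temperature_C",
                                         condition_values = seq(20, 95, 5),
                                         wavelengths_nm = seq(310, 400, 1),
                                         excitation_nm = 295,
                                         absorbances = NULL) {
  stopifnot(inherits(truth, "spectral_truth"))
  p <- unfolding_progress(condition_values, truth, axis_kind)
  center <- truth$band_center_native +
    (truth$band_center_denatured - truth$band_center_native) * p
  amp <- truth$amplitude_native +
    (truth$amplitude_denatured - truth$amplitude_native) * p
  M <- outer(seq_along(condition_values), seq_along(wavelengths_nm),
             function(i, j)
               amp[i] * exp(-(wavelengths_nm[j] - center[i])^2 /
                              (2 * truth$band_width_nm^2)))
  if (truth$noise_sd > 0) {
    set.seed(truth$seed)
    M <- M + matrix(stats::rnorm(length(M), sd = truth$noise_sd *
                                   truth$amplitude_native),
                    nrow = nrow(M))
  }
  spectrum_series(probe_kind, axis_kind, condition_values, wavelengths_nm,
                  M, excitation_nm = excitation_nm,
                  absorbances = absorbances)
}

#' Generate a synthetic ANS or RLS probe series over pH
#'
#' ANS: band centered at 488 nm whose amplitude follows a sigmoid in pH
#' (weak at neutral pH, full exposure at acidic pH) with midpoint = pKb.
#' RLS: band centered at 450 nm whose amplitude is a Gaussian in pH
#' centered at pKc (the aggregation peak) over a constant baseline. Band
#' centers do not drift, so the band intensity at the probe wavelength is
#' exactly affine in the latent amplitude.
#'
#' @param kind `"ans"` or `"rls"`.
#' @param midpoint pKb (ANS) or pKc (RLS).
#' @param width sigmoid steepness (ANS) or Gaussian sigma (RLS), pH units.
#' @param ph_values pH grid (descending by convention).
#' @param amplitude_low,amplitude_high amplitude range (a.u.): ANS goes
#'   low (native, neutral pH) to high (exposed); RLS peaks at
#'   `amplitude_high` over an `amplitude_low` baseline.
#' @param noise_sd Gaussian noise fraction of `amplitude_high`.
#' @param seed integer RNG seed.
#' @return a `spectrum_series` with the matching probe kind.
#' @export
generate_probe_series <- function(kind = c("ans", "rls"), midpoint,
                                  width = 0.3,
                                  ph_values = seq(7, 1, by = -0.25),
                                  amplitude_low = 50,
                                  amplitude_high = 1000,
                                  noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (amplitude_high == amplitude_low && kind == "ans")
    stop("zero-amplitude probe series")
  wl <- seq(400, 600, 2)
  band_center <- if (kind == "ans") 488 else 450
  band_sigma <- if (kind == "ans") 40 else 25
  amp <- if (kind == "ans") {
    s <- 1 / (1 + exp((ph_values - midpoint) / width))
    amplitude_low + (amplitude_high - amplitude_low) * s
  } else {
    amplitude_low + (amplitude_high - amplitude_low) *
      exp(-(ph_values - midpoint)^2 / (2 * width^2))
  }
  M <- outer(amp, wl, function(a, l)
    a * exp(-(l - band_center)^2 / (2 * band_sigma^2)))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    M <- M + matrix(stats::rnorm(length(M),
                                 sd = noise_sd * amplitude_high),
                    nrow = nrow(M))
  }
  spectrum_series(kind, "pH", ph_values, wl, M,
                  excitation_nm = if (kind == "ans") 380 else NA_real_)
}

#' Generate an unfolded-fraction curve consistent with linear energetics
#'
#' Inverts the linear free-energy model: with Delta G(x) = delta_g0 - m x
#' and the ratio convention K = f/(1 - f), f_u(x) = 1/(1 + exp(Delta
#' G(x)/RT)). On a temperature axis T is the per-point kelvin temperature
#' (x + 273.15); otherwise `T_kelvin` is used throughout. Feeding the
#' result to [thermal_energetics()] or [chemical_energetics()] under the
#' ratio convention recovers (delta_g0, m) exactly.
#'
#' @param delta_g0 intercept free energy, kcal mol^-1.
#' @param m slope (m-value), kcal mol^-1 per axis unit.
#' @param axis_kind `"temperature_C"` or `"denaturant_M"`.
#' @param axis_values condition grid.
#' @param T_kelvin temperature for non-thermal axes.
#' @param convention must be `"ratio"`: the literal-f_u convention is not
#'   invertible to a two-state curve.
#' @return a `fraction_curve`.
#' @export
generate_energetics_consistent_fractions <- function(delta_g0, m,
                                                     axis_kind = "denaturant_M",
                                                     axis_values = seq(0.5, 7, 0.5),
                                                     T_kelvin = 298.15,
                                                     convention = "ratio") {
  if (convention != "ratio")
    stop("unsupported convention: only 'ratio' is invertible")
  Tk <- if (axis_kind == "temperature_C") axis_values + 273.15 else
    rep(T_kelvin, length(axis_values))
  dg <- delta_g0 - m * axis_values
  f_u <- 1 / (1 + exp(dg / (R_KCAL * Tk)))
  fraction_curve(axis_kind, axis_values, f_u,
                 segment_label = "energetics-consistent")
}

#' Ground truth for a synthetic two-domain trajectory
#'
#' @param n_residues total C-alpha count, split between two rigid domains.
#' @param n_frames number of frames.
#' @param per_residue_sigma isotropic Gaussian jitter sigma per coordinate
#'   (angstrom), scalar or per residue.
#' @param domain_a_residues residue count of domain A (rest is domain B).
#' @param domain_separation_profile center-to-center separation (angstrom),
#'   scalar or per frame.
#' @param hbond_pairs list of pair specs: each a list with `res_a`,
#'   `atom_a`, `elem_a`, `res_b`, `atom_b`, `elem_b`, `occupancy`,
#'   `bound_distance`, `unbound_distance`.
#' @param seed integer RNG seed.
#' @return a `trajectory_truth`.
#' @export
trajectory_truth <- function(n_residues = 60L, n_frames = 100L,
                             per_residue_sigma = 0.5,
                             domain_a_residues = 20L,
                             domain_separation_profile = 20,
                             hbond_pairs = list(), seed = 1L) {
  sig <- rep_len(per_residue_sigma, n_residues)
  if (any(sig < 0)) stop("sigmas must be >= 0")
  sep <- rep_len(domain_separation_profile, n_frames)
  for (p in hbond_pairs) {
    if (p$occupancy < 0 || p$occupancy > 1)
      stop("occupancies must lie in [0, 1]")
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 per_residue_sigma = sig,
                 domain_a_residues = as.integer(domain_a_residues),
                 domain_separation_profile = sep,
                 hbond_pairs = hbond_pairs, seed = as.integer(seed)),
            class = "trajectory_truth")
}

# zero-centered helical backbone trace, ~3.8 A between consecutive CAs
helix_trace <- function(n) {
  t <- seq_len(n)
  X <- cbind(2.3 * cos(t * 1.75), 2.3 * sin(t * 1.75), 1.5 * t)
  sweep(X, 2, colMeans(X))
}

#' Generate a synthetic two-domain C-alpha trajectory
#'
#' Two rigid helical C-alpha domains; domain B's center is displaced from
#' domain A's along +x by the separation profile. Per-frame coordinates add
#' isotropic Gaussian jitter per residue. Designated hydrogen-bond pair
#' atoms are placed at their bound or unbound distance by independent
#' Bernoulli(occupancy) draws per frame. With all sigmas zero and a flat
#' profile the trajectory is exactly static.
#'
#' @param truth a `trajectory_truth`.
#' @return an `md_trajectory` whose topology carries residues 1..n with
#'   `CA` atoms (chain A) plus the named hydrogen-bond pair atoms.
#' @export
generate_trajectory <- function(truth) {
  stopifnot(inherits(truth, "trajectory_truth"))
  n <- truth$n_residues
  nA <- truth$domain_a_residues
  if (nA < 3L || n - nA < 3L)
    stop("each domain needs >= 3 residues")
  set.seed(truth$seed)
  baseA <- helix_trace(nA)
  baseB <- helix_trace(n - nA)
  atoms <- data.frame(serial = seq_len(n), atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = seq_len(n), element = "C",
                      stringsAsFactors = FALSE)
  extra <- list()
  for (p in truth$hbond_pairs) {
    extra[[length(extra) + 1L]] <-
      data.frame(serial = 0L, atom_name = p$atom_a, residue_name = "UNK",
                 chain_id = "A", residue_number = p$res_a,
                 element = p$elem_a %||% "N", stringsAsFactors = FALSE)
    extra[[length(extra) + 1L]] <-
      data.frame(serial = 0L, atom_name = p$atom_b, residue_name = "UNK",
                 chain_id = "A", residue_number = p$res_b,
                 element = p$elem_b %||% "N", stringsAsFactors = FALSE)
  }
  if (length(extra)) {
    extra <- do.call(rbind, extra)
    extra$serial <- n + seq_len(nrow(extra))
    atoms <- rbind(atoms, extra)
  }
  n_atoms <- nrow(atoms)
  # fixed anchor for H-bond pair atoms, well away from both domains
  pair_anchor <- function(k) c(-30 - 10 * k, -30, 0)
  bound_state <- lapply(truth$hbond_pairs, function(p)
    stats::runif(truth$n_frames) < p$occupancy)
  frames <- vector("list", truth$n_frames)
  for (f in seq_len(truth$n_frames)) {
    XA <- baseA + matrix(stats::rnorm(3 * nA),
                         ncol = 3) * truth$per_residue_sigma[seq_len(nA)]
    XB <- baseB + matrix(stats::rnorm(3 * (n - nA)),
                         ncol = 3) * truth$per_residue_sigma[(nA + 1):n]
    XB[, 1] <- XB[, 1] + truth$domain_separation_profile[f]
    X <- rbind(XA, XB)
    if (length(truth$hbond_pairs)) {
      for (k in seq_along(truth$hbond_pairs)) {
        p <- truth$hbond_pairs[[k]]
        a0 <- pair_anchor(k)
        d <- if (bound_state[[k]][f]) p$bound_distance else
          p$unbound_distance
        X <- rbind(X, matrix(a0, 1), matrix(a0 + c(d, 0, 0), 1))
      }
    }
    frames[[f]] <- X
  }
  topo <- md_structure(atoms, frames[[1L]])
  md_trajectory(topo, frames,
                frame_times = (seq_len(truth$n_frames) - 1) * 10)
}

#' Synthetic dual-histidine-motif fragment (labelled synthetic)
#'
#' A constructed stand-in for the catalytic-tetrad fragment of a
#' parvulin-family PPIase domain: His59, Cys113, Thr152 and His157 with the
#' motif heavy atoms placed so that the three hydrogen-bond pair distances
#' equal the crystallographically typical values
#' Cys113:SG-His59:NE2 = 3.3, His59:ND1-His157:ND1 = 2.9 and
#' His157:NE2-Thr152:OG1 = 2.7 angstrom. These coordinates are NOT the
#' deposited crystal structure — they are a synthetic geometry for testing
#' the selection and distance machinery offline. The same object is shipped
#' as `inst/extdata/synthetic_1pin_motif.pdb`.
#'
#' @return an `md_structure`.
#' @export
synthetic_pin1_motif <- function() {
  atoms <- data.frame(
    serial = 1:9,
    atom_name = c("CA", "ND1", "NE2",   # His59
                  "CA", "SG",           # Cys113
                  "CA", "OG1",          # Thr152
                  "CA", "ND1"),         # His157 (NE2 added below)
    residue_name = c("HIS", "HIS", "HIS", "CYS", "CYS", "THR", "THR",
                     "HIS", "HIS"),
    chain_id = "A",
    residue_number = c(59, 59, 59, 113, 113, 152, 152, 157, 157),
    element = c("C", "N", "N", "C", "S", "C", "O", "C", "N"),
    stringsAsFactors = FALSE)
  atoms <- rbind(atoms,
                 data.frame(serial = 10, atom_name = "NE2",
                            residue_name = "HIS", chain_id = "A",
                            residue_number = 157, element = "N",
                            stringsAsFactors = FALSE))
  coords <- rbind(
    c(-1.5, -2.0, -1.0),   # His59 CA
    c(2.2, 0.0, 0.0),      # His59 ND1
    c(0.0, 0.0, 0.0),      # His59 NE2
    c(-1.0, 1.5, 4.5),     # Cys113 CA
    c(0.0, 0.0, 3.3),      # Cys113 SG  (3.3 from His59 NE2)
    c(6.0, 4.0, 3.9),      # Thr152 CA
    c(4.4, 2.9, 2.7),      # Thr152 OG1 (2.7 from His157 NE2)
    c(3.3, 4.6, -1.2),     # His157 CA
    c(2.2, 2.9, 0.0),      # His157 ND1 (2.9 from His59 ND1)
    c(4.4, 2.9, 0.0))      # His157 NE2
  md_structure(atoms, coords)
}
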