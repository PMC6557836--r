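#' @title Trajectory stability metrics
#' @name traj_analysis
#' @description Kabsch superposition and the per-frame/per-atom stability
#'   metrics used to compare wild-type and mutant dynamics: RMSD (global or
#'   per domain), RMSF, radius of gyration, inter-domain distance, atom-pair
#'   distances, hydrogen-bond occupancy and backbone hydrogen-bond counts.
NULL

new_metric_series <- function(metric_kind, values, selection_label,
                              unit = "A", per = c("frame", "atom"),
                              flags = character()) {
  per <- match.arg(per)
  structure(list(metric_kind = metric_kind, values = as.numeric(values),
                 selection_label = selection_label, unit = unit,
                 per = per, mean = mean(values), flags = flags),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s over %s: %d values, mean %.4g %s [%s]\n",
              x$metric_kind, x$per, length(x$values), x$mean, x$unit,
              x$selection_label))
  invisible(x)
}

weighted_centroid <- function(X, w) colSums(X * w) / sum(w)

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares optimal proper rotation and translation mapping `mobile`
#' onto `reference`, by SVD of the weighted covariance with determinant
#' sign correction (no reflections). Returns the weighted post-fit RMSD.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix, same n >= 3.
#' @param weights optional non-negative weights (e.g. masses); default
#'   uniform.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3;
#'   the transform is `X %*% t(rotation) + translation`), `rmsd` (weighted,
#'   angstrom) and `flagged` (TRUE when the reflection sign correction
#'   fired on a degenerate configuration).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("point-count mismatch between mobile and reference")
  n <- nrow(mobile)
  if (n < 3L) stop("need >= 3 points")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  cm <- weighted_centroid(mobile, weights)
  cr <- weighted_centroid(reference, weights)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  C <- t(P * weights) %*% Q          # 3x3 weighted covariance
  sv <- svd(C)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)        # rotated = P %*% t(R)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum(weights * rowSums((moved - Q)^2)) / sum(weights))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, flagged = d < 0)
}

apply_rigid <- function(X, fit) {
  sweep(X %*% t(fit$rotation), 2, fit$translation, "+")
}

traj_weights <- function(traj, idx, mass_weighted) {
  if (mass_weighted) traj$topology$masses[idx] else rep(1, length(idx))
}

check_selection <- function(idx, what) {
  if (length(idx) == 0L) stop(sprintf("empty selection for %s", what))
  idx
}

#' Per-frame RMSD after superposition
#'
#' Each frame is superposed onto the reference frame over `fit_selection`,
#' then the RMSD is measured over `measure_selection` (defaults to the fit
#' selection, which reproduces the superposition's own RMSD exactly). For
#' per-domain RMSD in the two-domain convention, set both selections to
#' that domain's C-alpha atoms.
#'
#' @param traj an `md_trajectory`.
#' @param fit_selection integer atom indices used for superposition.
#' @param measure_selection atom indices the RMSD is reported over.
#' @param reference_frame frame index of the reference (default 1).
#' @param mass_weighted weight by atomic mass (default) or uniformly.
#' @return a `metric_series` (per frame, angstrom).
#' @export
rmsd_series <- function(traj, fit_selection,
                        measure_selection = fit_selection,
                        reference_frame = 1L, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  fit_selection <- check_selection(fit_selection, "fit")
  measure_selection <- check_selection(measure_selection, "measure")
  if (reference_frame < 1L || reference_frame > length(traj$frames))
    stop("reference frame out of range")
  ref <- traj$frames[[reference_frame]]
  wf <- traj_weights(traj, fit_selection, mass_weighted)
  wm <- traj_weights(traj, measure_selection, mass_weighted)
  vals <- vapply(traj$frames, function(F) {
    k <- kabsch_superpose(F[fit_selection, , drop = FALSE],
                          ref[fit_selection, , drop = FALSE], wf)
    moved <- apply_rigid(F[measure_selection, , drop = FALSE], k)
    sqrt(sum(wm * rowSums((moved - ref[measure_selection, , drop = FALSE])^2)) /
           sum(wm))
  }, numeric(1))
  new_metric_series("rmsd", vals,
                    sprintf("%d fit / %d measured atoms",
                            length(fit_selection),
                            length(measure_selection)))
}

#' Per-atom root-mean-square fluctuation
#'
#' After superposing every frame onto the reference frame over
#' `fit_selection` (pass `NULL` to skip superposition for pre-aligned
#' trajectories), fluctuations are measured about the mean structure:
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param selection atom indices profiled.
#' @param fit_selection atoms used for superposition (default: `selection`;
#'   `NULL` disables fitting).
#' @param reference_frame frame the others are superposed onto.
#' @param mass_weighted weights for the superposition.
#' @return a `metric_series` (per atom, angstrom).
#' @export
rmsf_profile <- function(traj, selection, fit_selection = selection,
                         reference_frame = 1L, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  selection <- check_selection(selection, "rmsf")
  if (length(traj$frames) < 2L) stop("RMSF needs >= 2 frames")
  ref <- traj$frames[[reference_frame]]
  aligned <- if (is.null(fit_selection)) {
    lapply(traj$frames, function(F) F[selection, , drop = FALSE])
  } else {
    fit_selection <- check_selection(fit_selection, "fit")
    wf <- traj_weights(traj, fit_selection, mass_weighted)
    lapply(traj$frames, function(F) {
      k <- kabsch_superpose(F[fit_selection, , drop = FALSE],
                            ref[fit_selection, , drop = FALSE], wf)
      apply_rigid(F[selection, , drop = FALSE], k)
    })
  }
  nT <- length(aligned)
  meanX <- Reduce(`+`, aligned) / nT
  ssq <- Reduce(`+`, lapply(aligned, function(A) rowSums((A - meanX)^2)))
  new_metric_series("rmsf", sqrt(ssq / nT),
                    sprintf("%d atoms", length(selection)), per = "atom")
}

#' Per-frame radius of gyration
#'
#' Rg = sqrt(sum_i w_i |r_i - r_com|^2 / sum_i w_i), with w the atomic
#' masses (default) or unity.
#'
#' @param traj an `md_trajectory`.
#' @param selection atom indices.
#' @param mass_weighted mass weights (default) or uniform.
#' @return a `metric_series` (per frame, angstrom).
#' @export
radius_of_gyration <- function(traj, selection, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "md_trajectory"))
  selection <- check_selection(selection, "Rg")
  w <- traj_weights(traj, selection, mass_weighted)
  vals <- vapply(traj$frames, function(F) {
    X <- F[selection, , drop = FALSE]
    com <- weighted_centroid(X, w)
    sqrt(sum(w * rowSums(sweep(X, 2, com)^2)) / sum(w))
  }, numeric(1))
  new_metric_series("rg", vals, sprintf("%d atoms", length(selection)))
}

#' Per-frame inter-domain distance
#'
#' Euclidean distance between the mass-weighted centers of the two domains'
#' C-alpha selections.
#'
#' @param traj an `md_trajectory`.
#' @param domain_a,domain_b `domain_definition`s.
#' @param atom_names atoms defining each domain's center (default C-alpha).
#' @return a `metric_series` (per frame, angstrom).
#' @export
interdomain_distance <- function(traj, domain_a, domain_b,
                                 atom_names = "CA") {
  ia <- check_selection(select_domain(traj, domain_a, atom_names),
                        domain_a$name)
  ib <- check_selection(select_domain(traj, domain_b, atom_names),
                        domain_b$name)
  wa <- traj$topology$masses[ia]
  wb <- traj$topology$masses[ib]
  vals <- vapply(traj$frames, function(F) {
    ca <- weighted_centroid(F[ia, , drop = FALSE], wa)
    cb <- weighted_centroid(F[ib, , drop = FALSE], wb)
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  new_metric_series("distance", vals,
                    sprintf("%s-%s", domain_a$name, domain_b$name))
}

#' Per-frame distance between two named atoms
#'
#' @param x an `md_structure` (one value) or `md_trajectory` (per frame).
#' @param atom_a,atom_b atom addresses: `list(residue =, atom =, chain =)`
#'   (chain optional).
#' @return a `metric_series` (angstrom).
#' @export
pair_distance_series <- function(x, atom_a, atom_b) {
  ia <- resolve_atom(x, atom_a$residue, atom_a$atom, atom_a$chain)
  ib <- resolve_atom(x, atom_b$residue, atom_b$atom, atom_b$chain)
  frames <- if (inherits(x, "md_trajectory")) x$frames else list(x$coords)
  vals <- vapply(frames, function(F)
    sqrt(sum((F[ia, ] - F[ib, ])^2)), numeric(1))
  new_metric_series("pair_distance", vals,
                    sprintf("%s:%s-%s:%s", atom_a$residue, atom_a$atom,
                            atom_b$residue, atom_b$atom))
}

#' Hydrogen-bond specification
#'
#' Donor/acceptor heavy-atom pair with a distance cutoff (default 3.5
#' angstrom) and an optional deviation-from-linearity angle cutoff that is
#' applied only when hydrogens are present in the topology.
#'
#' @param donor_heavy,acceptor_heavy atom addresses
#'   (`list(residue =, atom =, chain =)`).
#' @param distance_cutoff heavy-atom distance cutoff, angstrom.
#' @param angle_cutoff_deg optional donor-H-acceptor deviation from 180
#'   degrees.
#' @return an `hbond_spec`.
#' @export
hbond_spec <- function(donor_heavy, acceptor_heavy, distance_cutoff = 3.5,
                       angle_cutoff_deg = NULL) {
  if (distance_cutoff <= 0) stop("cutoff must be positive")
  if (identical(donor_heavy, acceptor_heavy))
    stop("donor and acceptor must differ")
  structure(list(donor_heavy = donor_heavy,
                 acceptor_heavy = acceptor_heavy,
                 distance_cutoff = distance_cutoff,
                 angle_cutoff_deg = angle_cutoff_deg),
            class = "hbond_spec")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Occupancy is the fraction of frames in which the donor/acceptor
#' heavy-atom distance is within the cutoff (and, when an angle cutoff is
#' set and a hydrogen bonded to the donor exists, the donor-H-acceptor
#' angle is within `angle_cutoff_deg` of linear). Equals the mean of the
#' per-frame indicator exactly.
#'
#' @param traj an `md_trajectory`.
#' @param spec an `hbond_spec`.
#' @return list with `occupancy` (fraction in [0, 1]), `distance_series` (a
#'   `metric_series`), and `satisfied` (logical per frame).
#' @export
hbond_occupancy <- function(traj, spec) {
  stopifnot(inherits(traj, "md_trajectory"), inherits(spec, "hbond_spec"))
  ds <- pair_distance_series(traj, spec$donor_heavy, spec$acceptor_heavy)
  ok <- ds$values <= spec$distance_cutoff
  if (!is.null(spec$angle_cutoff_deg)) {
    hidx <- find_donor_hydrogen(traj, spec$donor_heavy)
    if (!is.na(hidx)) {
      id <- resolve_atom(traj, spec$donor_heavy$residue,
                         spec$donor_heavy$atom, spec$donor_heavy$chain)
      ia <- resolve_atom(traj, spec$acceptor_heavy$residue,
                         spec$acceptor_heavy$atom,
                         spec$acceptor_heavy$chain)
      ang <- vapply(traj$frames, function(F)
        dha_angle(F[id, ], F[hidx, ], F[ia, ]), numeric(1))
      ok <- ok & (ang >= 180 - spec$angle_cutoff_deg)
    }
  }
  list(occupancy = mean(ok), distance_series = ds, satisfied = ok)
}

# donor-H-acceptor angle in degrees (180 = linear)
dha_angle <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

find_donor_hydrogen <- function(traj, donor) {
  atoms <- traj$topology$atoms
  cand <- which(atoms$residue_number == donor$residue &
                  atoms$element == "H")
  if (!is.null(donor$chain))
    cand <- cand[atoms$chain_id[cand] %in% donor$chain]
  if (!length(cand)) return(NA_integer_)
  id <- resolve_atom(traj, donor$residue, donor$atom, donor$chain)
  # nearest hydrogen within covalent range of the donor, frame 1
  F1 <- traj$frames[[1]]
  d <- sqrt(rowSums(sweep(F1[cand, , drop = FALSE], 2, F1[id, ])^2))
  if (min(d) > 1.3) return(NA_integer_)
  cand[which.min(d)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-frame backbone hydrogen-bond count
#'
#' Counts donor-acceptor pairs N(i) -> O(j) with residues at least 2 apart
#' (|i - j| >= 2) whose N-O distance is within the cutoff; when backbone
#' amide hydrogens exist and an angle cutoff is given, the N-H...O angle
#' must additionally be within `angle_cutoff_deg` of linear. Both
#' directions (i donor, j acceptor and vice versa) are counted as distinct
#' bonds.
#'
#' @param traj an `md_trajectory` whose topology contains backbone `N` and
#'   `O` atoms (missing atoms yield a flagged partial result).
#' @param distance_cutoff N-O cutoff, angstrom (default 3.5).
#' @param angle_cutoff_deg deviation-from-linearity cutoff, degrees
#'   (default 30, common VMD-style practice); applied only when amide
#'   hydrogens are present.
#' @return a `metric_series` (per frame, count).
#' @export
backbone_hbond_count <- function(traj, distance_cutoff = 3.5,
                                 angle_cutoff_deg = 30) {
  stopifnot(inherits(traj, "md_trajectory"))
  atoms <- traj$topology$atoms
  iN <- which(atoms$atom_name == "N")
  iO <- which(atoms$atom_name == "O")
  flags <- character()
  if (!length(iN) || !length(iO)) {
    flags <- "missing backbone N or O atoms"
    return(new_metric_series("hbond_count",
                             rep(0, length(traj$frames)), "backbone",
                             unit = "count", flags = flags))
  }
  resN <- atoms$residue_number[iN]
  resO <- atoms$residue_number[iO]
  iH <- which(atoms$atom_name %in% c("H", "HN"))
  resH <- atoms$residue_number[iH]
  hmatch <- match(resN, resH)          # amide H of each donor residue
  use_angle <- any(!is.na(hmatch)) && !is.null(angle_cutoff_deg)
  vals <- vapply(traj$frames, function(F) {
    cnt <- 0L
    for (a in seq_along(iN)) {
      for (b in seq_along(iO)) {
        if (abs(resN[a] - resO[b]) < 2) next
        dv <- F[iN[a], ] - F[iO[b], ]
        if (sum(dv * dv) > distance_cutoff^2) next
        if (use_angle && !is.na(hmatch[a])) {
          ang <- dha_angle(F[iN[a], ], F[iH[hmatch[a]], ], F[iO[b], ])
          if (ang < 180 - angle_cutoff_deg) next
        }
        cnt <- cnt + 1L
      }
    }
    as.numeric(cnt)
  }, numeric(1))
  new_metric_series("hbond_count", vals, "backbone", unit = "count",
                    flags = flags)
}
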