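# Independent oracles and fixture builders shared across the suite.
# These deliberately re-derive quantities by routes different from the
# package implementation (quaternion eigenproblem vs SVD Kabsch, naive
# all-pairs loops vs the vectorized kernels).

# --- quaternion-method superposition RMSD oracle ---------------------------
# Optimal rigid-body RMSD via the Horn quaternion eigenvalue method:
# build the 4x4 key matrix from the weighted covariance and take the
# largest eigenvalue. Completely independent of the SVD route.
quaternion_rmsd <- function(P, Q, w = NULL) {
  n <- nrow(P)
  if (is.null(w)) w <- rep(1, n)
  cp <- colSums(P * w) / sum(w)
  cq <- colSums(Q * w) / sum(w)
  P <- sweep(P, 2, cp); Q <- sweep(Q, 2, cq)
  S <- t(P * w) %*% Q
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(w * rowSums(P^2)) + sum(w * rowSums(Q^2)) - 2 * lam) / sum(w)
  sqrt(max(0, msd))
}

# --- brute-force backbone hydrogen-bond oracle -----------------------------
# Naive double loop over every atom pair of a single frame: count
# N(i) -> O(j) pairs with |res_i - res_j| >= 2 within the cutoff (no angle
# term; used on hydrogen-free fixtures).
brute_hbond_count <- function(atoms, frame, cutoff) {
  cnt <- 0L
  for (a in seq_len(nrow(atoms))) {
    if (atoms$atom_name[a] != "N") next
    for (b in seq_len(nrow(atoms))) {
      if (atoms$atom_name[b] != "O") next
      if (abs(atoms$residue_number[a] - atoms$residue_number[b]) < 2) next
      d <- sqrt(sum((frame[a, ] - frame[b, ])^2))
      if (d <= cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# --- random rigid transforms ----------------------------------------------
random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid_frames <- function(frames, R, t) {
  lapply(frames, function(F) sweep(F %*% t(R), 2, t, "+"))
}

# --- curve builders --------------------------------------------------------
# log intensity ratio: under the Gaussian band model this is exactly affine
# in the latent unfolded fraction, so sigmoid fits of it recover latent
# midpoints without model bias
log_ratio_curve <- function(series, num = 350, den = 335) {
  r <- intensity_ratio(series, num, den)
  unfolding_curve(r$axis_kind, r$x, log(r$y),
                  paste0("log ", r$observable_label))
}

# exact Boltzmann observable with known parameters
make_sigmoid_curve <- function(x, A, B, x0, k, axis = "temperature_C") {
  unfolding_curve(axis, x, A + (B - A) / (1 + exp(-(x - x0) / k)), "y")
}

# a tiny hydrogen-free backbone: N and O atoms on two helical strands whose
# contact pattern is nontrivial at a 3.5 A cutoff
helical_backbone_structure <- function(n_res = 8, radius = 2.3,
                                       turn = 1.7, rise = 0.9) {
  t <- seq_len(n_res)
  N <- cbind(radius * cos(turn * t), radius * sin(turn * t), rise * t)
  O <- cbind(radius * cos(turn * t + 0.9), radius * sin(turn * t + 0.9),
             rise * t + 0.8)
  atoms <- data.frame(
    serial = seq_len(2 * n_res),
    atom_name = rep(c("N", "O"), each = n_res),
    residue_name = "ALA", chain_id = "A",
    residue_number = rep(t, 2), element = rep(c("N", "O"), each = n_res),
    stringsAsFactors = FALSE)
  md_structure(atoms, rbind(N, O))
}

# write a minimal PDB text fixture from explicit lines
write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}
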