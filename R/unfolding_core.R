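#' @title Unfolding transition fitting
#' @name unfolding_core
#' @description Unfolded-fraction computation and Boltzmann sigmoid fitting
#'   of denaturation transitions, including the two-step segmental scheme
#'   used for three-state melts (native -> intermediate -> denatured).
NULL

#' Unfolded fraction from fixed baselines
#'
#' f_u = (F_obs - F_n)/(F_d - F_n): the observable normalized between the
#' native (`F_n`) and denatured (`F_d`) signals. Raw values are retained
#' (fits should see unclipped data); ask for `clip = TRUE` when reporting.
#'
#' @param curve an `unfolding_curve`.
#' @param F_n native-state observable value.
#' @param F_d denatured-state observable value (must differ from `F_n`).
#' @param clip clip the reported fractions into [0, 1]?
#' @return a `fraction_curve`.
#' @export
unfolded_fraction <- function(curve, F_n, F_d, clip = FALSE) {
  stopifnot(inherits(curve, "unfolding_curve"))
  if (F_n == F_d) stop("degenerate baselines: F_n == F_d")
  f <- (curve$y - F_n) / (F_d - F_n)
  if (clip) f <- pmin(1, pmax(0, f))
  fraction_curve(curve$axis_kind, curve$x, f,
                 segment_label = curve$observable_label, clipped = clip)
}

boltzmann <- function(x, A, B, x0, k) A + (B - A) / (1 + exp(-(x - x0) / k))

# Deterministic variable-projection fallback: for fixed (x0, k) the model
# is linear in the baselines, so scan a (midpoint x steepness) grid,
# solving the 2-parameter linear least squares at each node, and return
# the best node's full coefficient vector as a starting point. Used when
# nls fails to converge; the Gauss-Newton polish finishes the job.
varpro_boltzmann_grid <- function(x, y) {
  span <- diff(range(x))
  x0_grid <- seq(min(x), max(x), length.out = 41)
  k_grid <- span / c(2, 3, 5, 8, 12, 20, 35, 60, 100)
  best <- NULL; best_ssr <- Inf
  for (k in k_grid) {
    for (x0 in x0_grid) {
      s <- 1 / (1 + exp(-(x - x0) / k))
      X <- cbind(1 - s, s)
      ab <- tryCatch(qr.coef(qr(X), y), error = function(e) NULL)
      if (is.null(ab) || any(is.na(ab))) next
      ssr <- sum((y - X %*% ab)^2)
      if (ssr < best_ssr) {
        best_ssr <- ssr
        best <- c(A = ab[1], B = ab[2], x0 = x0, k = k)
      }
    }
  }
  if (!is.null(best)) names(best) <- c("A", "B", "x0", "k")
  best
}

# Damped Gauss-Newton polish with the analytic Jacobian: the port solver
# stops at ~1e-8 relative precision, which is not tight enough for the
# affine-equivariance contract, so the optimum is refined to machine
# precision. Returns coefficients and the midpoint standard error from the
# final-Jacobian covariance.
polish_boltzmann <- function(cf, x, y, max_iter = 50L) {
  A <- cf[["A"]]; B <- cf[["B"]]; x0 <- cf[["x0"]]; k <- cf[["k"]]
  ssr <- function(p) sum((y - boltzmann(x, p[1], p[2], p[3], p[4]))^2)
  p <- c(A, B, x0, k)
  cur <- ssr(p)
  lambda <- 1e-8
  jac <- function(p) {
    s <- 1 / (1 + exp(-(x - p[3]) / p[4]))
    cbind(1 - s, s,
          -(p[2] - p[1]) * s * (1 - s) / p[4],
          -(p[2] - p[1]) * s * (1 - s) * (x - p[3]) / p[4]^2)
  }
  for (it in seq_len(max_iter)) {
    J <- jac(p)
    r <- y - boltzmann(x, p[1], p[2], p[3], p[4])
    JtJ <- crossprod(J)
    step <- tryCatch(
      solve(JtJ + lambda * diag(diag(JtJ), 4), crossprod(J, r)),
      error = function(e) NULL)
    if (is.null(step)) break
    cand <- p + as.numeric(step)
    if (cand[4] == 0) break
    new <- ssr(cand)
    if (is.finite(new) && new <= cur) {
      moved <- max(abs(cand - p) / pmax(abs(p), 1e-12))
      p <- cand; cur <- new
      lambda <- max(lambda / 4, 1e-12)
      if (moved < 1e-14) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e6) break
    }
  }
  J <- jac(p)
  dof <- max(length(y) - 4L, 1L)
  s2 <- cur / dof
  se_x0 <- tryCatch(sqrt(s2 * solve(crossprod(J))[3, 3]),
                    error = function(e) NA_real_)
  list(coef = c(A = p[1], B = p[2], x0 = p[3], k = p[4]), se_x0 = se_x0)
}

new_sigmoid_fit <- function(midpoint, steepness, baseline_native,
                            baseline_denatured, midpoint_se, residual_norm,
                            n_points, segment, axis_kind,
                            coef_left, coef_right, rate) {
  structure(list(midpoint = midpoint, steepness = steepness,
                 baseline_native = baseline_native,
                 baseline_denatured = baseline_denatured,
                 midpoint_se = midpoint_se, residual_norm = residual_norm,
                 n_points = n_points, segment = segment,
                 axis_kind = axis_kind,
                 coef_left = coef_left, coef_right = coef_right,
                 rate = rate),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> midpoint %.4g +/- %.3g, steepness %.4g, baselines %.4g -> %.4g (n=%d)\n",
    x$midpoint, x$midpoint_se, x$steepness, x$baseline_native,
    x$baseline_denatured, x$n_points))
  invisible(x)
}

#' Fit a Boltzmann sigmoid to one transition segment
#'
#' Least-squares fit of
#' \deqn{y(x) = A + (B - A) / (1 + e^{-(x - x_0)/k})}
#' with constant baselines `A` (low-x plateau) and `B` (high-x plateau).
#' Baseline seeds are means of the two terminal points of the segment, the
#' midpoint seed is the x at which the data cross the mid-plateau value, and
#' failed fits are retried from 5 deterministically jittered seeds. The
#' native/denatured baseline assignment and the sign of the reported
#' steepness follow the axis: on a pH axis unfolding completes as pH
#' decreases, so the native baseline is the high-pH plateau and steepness is
#' reported negative.
#'
#' @param curve an `unfolding_curve` (or `fraction_curve`).
#' @param segment optional numeric length-2 x-range `c(lo, hi)` (order
#'   irrelevant); default is the full range.
#' @param min_separation_mad require the segment's y-range to exceed this
#'   multiple of the median absolute deviation of the two terminal plateaus
#'   (2 points each); set to 0 to disable. Guards against fitting noise.
#' @return a `sigmoid_fit` with fields `midpoint`, `steepness`,
#'   `baseline_native`, `baseline_denatured`, `midpoint_se`,
#'   `residual_norm`, `n_points`, `segment`.
#' @export
fit_transition <- function(curve, segment = NULL, min_separation_mad = 3) {
  stopifnot(inherits(curve, c("unfolding_curve", "fraction_curve")))
  y_all <- if (inherits(curve, "fraction_curve")) curve$f_u else curve$y
  x_all <- curve$x
  if (is.null(segment)) segment <- range(x_all)
  segment <- range(as.numeric(segment))
  keep <- x_all >= segment[1] - 1e-12 & x_all <= segment[2] + 1e-12
  x <- x_all[keep]; y <- y_all[keep]
  if (length(x) < 4L)
    stop(sprintf("segment [%g, %g] has %d < 4 points", segment[1],
                 segment[2], length(x)))
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (diff(range(y)) == 0) stop("constant observable in segment")
  n <- length(x)
  plateau_noise <- stats::mad(c(y[1:2] - mean(y[1:2]),
                                y[(n - 1):n] - mean(y[(n - 1):n])),
                              center = 0)
  if (min_separation_mad > 0 && plateau_noise > 0 &&
      diff(range(y)) <= min_separation_mad * plateau_noise)
    stop("observable does not vary beyond plateau noise")

  a0 <- mean(y[1:2]); b0 <- mean(y[(n - 1):n])
  mid_val <- (a0 + b0) / 2
  cross <- which(diff(sign(y - mid_val)) != 0)
  x0_seed <- if (length(cross)) {
    i <- cross[1L]
    # linear interpolation of the crossing
    x[i] + (mid_val - y[i]) * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i])
  } else mean(range(x))
  k_seed <- diff(range(x)) / 10

  df <- data.frame(x = x, y = y)
  try_fit <- function(a, b, x0, k) {
    tryCatch(
      stats::nls(y ~ A + (B - A) / (1 + exp(-(x - x0) / k)), data = df,
                 start = list(A = a, B = b, x0 = x0, k = k),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE),
                 algorithm = "port"),
      error = function(e) NULL)
  }
  fit <- try_fit(a0, b0, x0_seed, k_seed)
  if (is.null(fit)) {
    # deterministic jitter grid, no RNG
    jit <- list(c(1, 1, 1, 0.5), c(1, 1, 1, 2), c(1, 1, 0.9, 1),
                c(1, 1, 1.1, 1), c(0.95, 1.05, 1, 0.3))
    for (j in jit) {
      fit <- try_fit(a0 * j[1] + (j[1] - 1) * 0.1, b0 * j[2],
                     x0_seed * j[3] + (j[3] - 1) * 0.01, k_seed * j[4])
      if (!is.null(fit)) break
    }
  }
  start <- if (!is.null(fit)) stats::coef(fit) else
    varpro_boltzmann_grid(x, y)
  if (is.null(start))
    stop(errorCondition(sprintf(
      "sigmoid fit failed to converge on segment [%g, %g] (n=%d, seeds A=%g B=%g x0=%g k=%g)",
      segment[1], segment[2], n, a0, b0, x0_seed, k_seed),
      class = "foldstab_fit_error"))
  cf <- polish_boltzmann(start, x, y)
  A <- unname(cf$coef["A"]); B <- unname(cf$coef["B"])
  x0 <- unname(cf$coef["x0"]); k <- unname(cf$coef["k"])
  se_x0 <- cf$se_x0
  if (k < 0) { tmp <- A; A <- B; B <- tmp; k <- -k }  # canonical: A = low-x plateau
  if (A == B) stop("degenerate fit: equal baselines")
  if (x0 < segment[1] || x0 > segment[2])
    warning(sprintf("fitted midpoint %g outside segment [%g, %g]", x0,
                    segment[1], segment[2]))
  resid_vec <- y - boltzmann(x, A, B, x0, k)
  descending_unfolding <- identical(curve$axis_kind, "pH")
  if (descending_unfolding) {
    native <- B; denat <- A; steep <- -k
  } else {
    native <- A; denat <- B; steep <- k
  }
  new_sigmoid_fit(midpoint = x0, steepness = steep,
                  baseline_native = native, baseline_denatured = denat,
                  midpoint_se = se_x0,
                  residual_norm = sqrt(sum(resid_vec^2)),
                  n_points = n, segment = segment,
                  axis_kind = curve$axis_kind,
                  coef_left = A, coef_right = B, rate = k)
}

#' Define a segmentation scheme for multi-step denaturation
#'
#' Breakpoints split the condition axis into independently fitted segments;
#' the sample at a breakpoint is shared by both adjacent segments. An empty
#' breakpoint vector means a single one-step fit.
#'
#' @param breakpoints numeric condition values strictly inside the data
#'   range (checked at fit time).
#' @return a `segment_scheme`.
#' @export
segment_scheme <- function(breakpoints = numeric()) {
  structure(list(breakpoints = sort(as.numeric(breakpoints))),
            class = "segment_scheme")
}

#' Fit a segmented (multi-step) denaturation curve
#'
#' Splits the curve at the scheme's breakpoints and fits each segment
#' independently with [fit_transition()], each segment renormalized to its
#' own plateaus — the intermediate state is segment 1's denatured baseline
#' and segment 2's native baseline. Segments are returned in order along
#' the stored axis direction (20->60 then 60->95 C; pH 7->3 then 3->1).
#'
#' Adjacent transitions are not fully separated on real axes: the tail of
#' one sigmoid leaks into the neighbouring segment and, under constant
#' baselines, biases that segment's midpoint. After the initial independent
#' fits, `refine` passes subtract each other segment's fitted deviation
#' from its plateau adjacent to the segment being refitted and refit; each
#' segment remains an independently parameterized Boltzmann throughout.
#' Set `refine = 0` for strictly naive independent fits.
#'
#' @param curve an `unfolding_curve` or `fraction_curve`.
#' @param scheme a `segment_scheme`; an empty scheme reduces exactly to a
#'   single [fit_transition()] call over the full range.
#' @param refine number of cross-talk refinement passes (default 2).
#' @param ... passed to [fit_transition()].
#' @return a list of `sigmoid_fit`, one per segment, named `segment1`,
#'   `segment2`, ... in order along the unfolding direction.
#' @export
fit_two_step <- function(curve, scheme = segment_scheme(), refine = 2L,
                         ...) {
  stopifnot(inherits(scheme, "segment_scheme"))
  x <- curve$x
  y <- if (inherits(curve, "fraction_curve")) curve$f_u else curve$y
  bp <- scheme$breakpoints
  if (length(bp) == 0L)
    return(list(segment1 = fit_transition(curve, ...)))
  rng <- range(x)
  if (any(bp <= rng[1]) || any(bp >= rng[2]))
    stop("breakpoints must lie strictly inside the data range")
  edges <- c(rng[1], bp, rng[2])
  n_seg <- length(edges) - 1L
  descending <- x[1] > x[length(x)]
  seg_order <- if (descending) rev(seq_len(n_seg)) else seq_len(n_seg)

  fit_seg <- function(yy, seg, pos) {
    cv <- unfolding_curve(curve$axis_kind, x, yy, curve$observable_label)
    tryCatch(fit_transition(cv, segment = seg, ...),
             error = function(e)
               stop(sprintf("segment%d [%g, %g]: %s", pos, seg[1], seg[2],
                            conditionMessage(e)), call. = FALSE))
  }
  fits <- vector("list", n_seg)
  for (pos in seq_len(n_seg)) {
    i <- seg_order[pos]
    fits[[pos]] <- fit_seg(y, c(edges[i], edges[i + 1L]), pos)
  }
  # leak of fit f outside its own x-interval, relative to the plateau it
  # presents to points at x: the high-x asymptote for x above the segment,
  # the low-x asymptote for x below (coef_left/right are canonical k > 0)
  leak <- function(f, xs) {
    pred <- boltzmann(xs, f$coef_left, f$coef_right, f$midpoint, f$rate)
    ifelse(xs >= f$segment[2], pred - f$coef_right,
           ifelse(xs <= f$segment[1], pred - f$coef_left, 0))
  }
  for (pass in seq_len(refine)) {
    for (pos in seq_len(n_seg)) {
      others <- fits[-pos]
      dev <- Reduce(`+`, lapply(others, leak, xs = x))
      fits[[pos]] <- fit_seg(y - dev, fits[[pos]]$segment, pos)
    }
  }
  names(fits) <- paste0("segment", seq_len(n_seg))
  fits
}

#' Normalize a segment to its fitted baselines
#'
#' Applies the unfolded-fraction normalization with `F_n` and `F_d` taken
#' from a fitted transition, restricted to that fit's segment range.
#'
#' @param curve the `unfolding_curve` the fit was produced on.
#' @param fit a `sigmoid_fit`.
#' @return a `fraction_curve` over the fit's segment.
#' @export
normalize_segment <- function(curve, fit) {
  stopifnot(inherits(curve, "unfolding_curve"), inherits(fit, "sigmoid_fit"))
  keep <- curve$x >= fit$segment[1] - 1e-12 &
    curve$x <= fit$segment[2] + 1e-12
  sub <- unfolding_curve(curve$axis_kind, curve$x[keep], curve$y[keep],
                         curve$observable_label)
  unfolded_fraction(sub, fit$baseline_native, fit$baseline_denatured)
}

#' Serialize sigmoid fits to a JSON record
#'
#' @param fits a `sigmoid_fit` or list of them.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return path or JSON string, invisibly.
#' @export
sigmoid_fits_json <- function(fits, path = NULL) {
  if (inherits(fits, "sigmoid_fit")) fits <- list(segment1 = fits)
  rec <- lapply(fits, function(f)
    list(midpoint = f$midpoint, steepness = f$steepness,
         baseline_native = f$baseline_native,
         baseline_denatured = f$baseline_denatured,
         midpoint_se = f$midpoint_se, residual_norm = f$residual_norm,
         n_points = f$n_points, segment = f$segment,
         axis_kind = f$axis_kind))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(path)) }
  invisible(js)
}
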