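---
title: "Protein stability from denaturation spectra and trajectories: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein stability from denaturation spectra and trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldstab)
```

# Scope

`foldstab` implements the analysis layer of a classical protein-stability
study: spectroscopic denaturation (thermal, acidic, chemical) of a
two-domain protein followed with several probes, and stability metrics
over molecular-dynamics-style coordinate trajectories. The package
consumes tidy spectral tables and (multi-model) PDB coordinates; it does
not run simulations or deconvolute CD spectra, and it accepts
blank-subtracted CD input only.

# The denaturation model and its assumptions

## Observable and unfolded fraction

A denaturation experiment records a spectral grid: intensity over
(condition × emission wavelength), where the condition is temperature
(°C), pH, or denaturant molarity. Three observables are supported per
series:

* a single **band intensity** (e.g. 340 nm tryptophan emission, 208 or
  222 nm CD), linearly interpolated off-grid;
* an **intensity ratio** between two bands (canonically F350/F335), which
  tracks emission-maximum shifts without baseline choices and is exactly
  invariant to the inner-filter correction because the per-condition
  factor cancels;
* the **emission maximum** λ_max, refined by a 3-point parabola around
  the grid argmax (sub-grid resolution without smoothing choices; flat
  spectra break ties toward the lowest wavelength and are flagged, as are
  boundary maxima).

Observed fluorescence is corrected for the inner-filter effect as
F_cor = F_obs · e^{(A_ex + A_em)/2} when per-condition absorbances are
supplied; otherwise the series passes through, flagged unapplied.

The unfolded fraction is the two-point normalization
f_u = (F_obs − F_n)/(F_d − F_n). Raw (unclipped) values are retained for
fitting; clipping to [0, 1] is for reporting only.

## Transition fitting

Each transition segment is modelled as a Boltzmann sigmoid with constant
plateaus,

$$ y(x) = B_n + \frac{B_d - B_n}{1 + e^{-(x - x_0)/k}}, $$

the simplest model identifiable from the ~15–30 point curves typical of
these experiments. The source-style experiments never state a functional
form ("midpoint of the denaturation process"), so the Boltzmann form with
constant baselines is a package design choice; sloping baselines were
deliberately left out of the core model because on short segments they
trade off against the steepness parameter and destabilize midpoint
standard errors.

Assumptions worth stating: (i) the observable is affine in the state
populations (see the generator section for why the *log* ratio, not the
raw ratio, satisfies this under a drifting Gaussian band); (ii) plateaus
are reached — or nearly — at both segment ends; (iii) noise is additive
and roughly homoscedastic on the fitted observable.

## Three-state (two-step) melts

When an intermediate is visible (a plateau in the ratio curve around
60 °C thermally, or pH 3 in acid), the axis is split at a breakpoint and
each segment fitted separately; the shared breakpoint sample belongs to
both segments, and the intermediate is segment 1's denatured and segment
2's native baseline. Midpoints are reported in order along the unfolding
direction (rising temperature/denaturant, falling pH).

**Cross-talk refinement.** Strictly independent segment fits are biased
by the neighbouring transition's tail: with realistic acid steepness
(~0.2–0.25 pH units) the tail of the second transition contributes up to
~5% of amplitude inside the first segment and shifts its fitted midpoint
by ~0.03 pH units — larger than the recovery tolerance the package holds
itself to (0.02). `fit_two_step()` therefore runs `refine = 2` passes in
which each other segment's fitted deviation from its adjacent plateau is
subtracted before refitting; every segment remains an independently
parameterized Boltzmann (this is *not* a coupled three-state model), and
`refine = 0` restores the naive behaviour. Two passes reduce the bias to
under 0.001 axis units on noise-free curves.

## Probe-specific parameters

* **pKb** (ANS, hydrophobic exposure): midpoint of a Boltzmann fit of the
  488 nm band against pH — operationalizing "half of full exposure" as
  the sigmoid midpoint, which is robust to plateau noise; the literal
  half-of-observed-maximum crossing is available with `rule =
  "half_max"`.
* **pKc** (RLS, aggregation): center of a Gaussian-plus-constant fit of
  the 450 nm signal *against pH*. The peak could in principle be fitted
  over wavelength, but pKc is a pH, so the pH axis is the natural fit
  domain here. A failed Gaussian fit falls back to a flagged 3-point
  parabolic refinement of the argmax; a boundary maximum yields a flagged
  boundary value. The RLS wavelength defaults to 450 nm (some reports
  quote 440 nm; `wavelength_nm` is an argument, not a constant).

## Energetics

Per point in the transition region, K is formed from f_u and
ΔG_u = −RT ln K with R = 1.987204×10⁻³ kcal mol⁻¹ K⁻¹ and T always in
kelvin inside the logarithm term (per-point kelvin on a thermal axis; the
experiment temperature otherwise). Two K conventions coexist:

* `literal_fu` — K = f_u, the default, faithful to treatments that
  annotate the equilibrium constant as the unfolded fraction itself;
* `ratio` — K = f_u/(1 − f_u), the conventional two-state constant, used
  by every round-trip identity in the test suite.

Neither is asserted to be "the" correct reading; the switch is explicit
precisely because the literal convention is thermodynamically
unconventional. The two differ pointwise by −RT ln(1 − f_u).

The LEM regression ΔG_u = intercept − slope·x is ordinary least squares;
the slope is reported with the sign convention that positive m means
destabilization with increasing perturbant. The thermal regression axis
defaults to °C as melts are usually plotted — tabulated thermal m-values
sometimes carry ambiguous units (e.g. printed per molar on a thermal
axis), so the package labels the slope by the regression axis actually
used rather than guessing; `regression_axis = "kelvin"` shifts only the
intercept (by m·273.15), never the slope. When one ΔG/m pair is reported
for a two-step melt, the segment that feeds the regression is an explicit
selector defaulting to segment 1 (the 20–60 °C transition), since the
convention is not stated in the source-style tables.

Points with f_u outside [0.05, 0.95] are excluded from all
extrapolations (ln f diverges at the plateaus); the bounds are arguments.
The chemical route adds the half-chevron intercept: log₁₀ K_ui against
[GdnHCl], whose intercept is log K_obs (base 10 to match tabulated values
around −1.9; natural log by `log_base`). On noise-free ratio-convention
data both intercepts describe one line, so ΔG₀ = −RT ln10 · log K_obs to
machine precision — an identity the acceptance suite asserts at 1e-8. The
protein concentration P_t (default 5 μM, matching typical fluorescence
samples) and chain count n (default 1, monomer) enter only for n > 1,
where K_ui = P_t f_u/[P_t(1 − f_u)]ⁿ.

# Trajectory metrics

Superposition is SVD Kabsch with determinant sign correction (proper
rotations only; the degenerate reflection case is sign-corrected and
flagged). Defaults chosen where the source-style figures are silent:

* reference frame = frame 1 (`reference_frame` argument);
* per-domain RMSD superposes on that domain's own Cα atoms, matching the
  "relatively independent domains" framing; pass a global
  `fit_selection` for the alternative;
* RMSF is measured about the post-superposition *mean* structure (the
  standard fluctuation definition), not the reference frame;
* weights are atomic masses by default; Cα-only selections may use
  `mass_weighted = FALSE` (equal-mass Cα selections make the two
  identical anyway);
* the inter-domain distance is between mass-weighted centers of the two
  domains' Cα selections (which atoms define a domain center is not a
  settled convention; Cα is the default, `atom_names` the override);
* hydrogen bonds default to a 3.5 Å heavy-atom donor–acceptor distance
  criterion with *no* angle term, because crystal structures and Cα-level
  fixtures carry no hydrogens; when hydrogens exist and
  `angle_cutoff_deg` is set, a donor–H–acceptor linearity criterion
  activates (30° for backbone counts, common VMD-style practice — whether
  published backbone counts used 3.0 Å/20° or 3.5 Å is typically
  unstated, so both are config keys);
* backbone counts pair N(i)→O(j) with |i − j| ≥ 2, both directions
  counted.

Domain boundaries for the Pin1-style default split (WW 6–39, PPIase
50–163, author numbering) are conventional defaults exposed in
`pin1_default_domains()`, not assertions — published per-domain analyses
rarely print their exact residue windows.

# What the synthetic generators emulate — and what they don't

The generators produce data with the statistical structure the analysis
*assumes*, so that every stage has a recoverable-truth test:

* **Spectra**: a Gaussian emission band in wavelength whose center and
  amplitude interpolate linearly between native and denatured values with
  the unfolded progress; progress follows one or two Boltzmann steps
  (mean of segment sigmoids), with the unfolding direction tied to the
  axis (pH unfolds downward). Defaults emulate a tryptophan probe:
  center 342 → 350 nm, amplitude falling 1000 → 400 a.u., band σ 15 nm,
  sampled 310–400 nm — the typical red-shift-plus-quench signature.
  Noise is i.i.d. Gaussian per grid cell, scaled by the native amplitude
  (2% in the recovery studies, visually consistent with published melt
  scatter; 1% in the bundled end-to-end fixtures).

  A consequence worth exploiting: under this band model the **log** of a
  two-wavelength intensity ratio is *exactly affine* in the progress
  (log-Gaussian quadratics subtract), so sigmoid fits of
  log(F350/F335) recover latent midpoints without model bias. A raw
  band intensity at fixed wavelength is *not* affine in the progress once
  the center drifts — fitting it directly incurs a real midpoint bias
  (~0.1 °C at the default geometry), which is a property of the
  observable, not a fitting defect. The pipeline therefore tracks the
  log-ratio for midpoint work.
* **Probe curves**: ANS — fixed 488 nm band, amplitude sigmoidal in pH;
  RLS — fixed 450 nm band, amplitude Gaussian in pH over a constant
  baseline. Fixed centers make the probe-wavelength intensity exactly
  affine in the latent amplitude.
* **Fraction curves**: inversion of the linear free-energy model under
  the ratio convention, f_u(x) = 1/(1 + e^{ΔG(x)/RT}); the literal
  convention is not invertible to a two-state curve and is rejected.
* **Trajectories**: two rigid helical Cα domains (~3.8 Å spacing) with
  per-residue isotropic Gaussian jitter, a prescribed per-frame domain
  separation along +x, and designated hydrogen-bond pair atoms placed at
  bound/unbound distances by Bernoulli draws with a designed occupancy.
  One integer seed drives one RNG stream per generator call; identical
  seeds give bit-identical output.

Not emulated: heteroscedastic or correlated instrument noise, scatter
peaks and solvent Raman bands, sloping pre-transition baselines,
aggregation kinetics, any force field or thermodynamic coupling between
the spectral and trajectory worlds, and real protein geometry beyond the
Cα trace. A green recovery test therefore establishes that the estimator
is correct and well-calibrated *under the stated noise model* — it says
nothing about robustness to baseline drift or non-Gaussian outliers, and
trajectory tests validate the geometry kernels, not simulation physics.
The shipped `synthetic_1pin_motif.pdb` is likewise a constructed
fragment whose motif pair distances equal crystallographically typical
values; tests on it validate parsing, selection and distance code, not
any deposited structure.

# Numerical choices

* **Initialization**: baseline seeds are the means of each segment's two
  terminal points; the midpoint seed is the interpolated crossing of the
  mid-plateau level; the steepness seed is a tenth of the segment span.
  On failure, five deterministically jittered restarts (no RNG) are
  tried before a typed fit error carrying the seeds is raised.
* **Optimizer**: `stats::nls` (port) with five deterministic jittered
  restarts; if all attempts fail (which happens on unlucky noise draws of
  short noisy segments), a variable-projection fallback scans a
  41×9 (midpoint × steepness) grid — the model is linear in the two
  baselines at fixed midpoint and steepness, so each node costs one
  2-parameter linear solve — and the best node seeds the polish. Every
  accepted start is finished by a damped Gauss–Newton polish with the
  analytic Jacobian. The polish matters: port stops at
  ~1e-8 relative precision, which breaks the package's own
  affine-equivariance contract (midpoint and steepness invariant to
  y-scaling at 1e-8); polishing to machine precision restores it. The
  midpoint standard error comes from the final-Jacobian covariance.
* **Canonicalization**: the sigmoid has a (A,B,k) ↔ (B,A,−k) symmetry;
  fits are canonicalized to k > 0 (A = low-x plateau) and then mapped to
  native/denatured by axis direction, with steepness reported negative on
  pH axes (unfolding completes as pH falls).
* **Degenerate inputs**: constant observables, segments with fewer than
  4 points, and curves whose range does not exceed 3× the MAD of the
  terminal plateaus (when estimable; threshold an argument) are rejected
  before fitting.
* **Ties and boundaries**: argmax ties break toward the lowest
  wavelength/pH; boundary maxima are reported with flags rather than
  silently extrapolated; empty atom selections are flagged results, not
  errors.
* **I/O precision**: spectral tables round-trip at 12 significant
  digits; PDB coordinates at the format's 1e-3 Å.

# Known limitations

* No sloping-baseline or global multi-probe fitting; no van 't Hoff ΔH
  or ΔCp (Gibbs–Helmholtz) analysis; the chevron is half (unfolding arm
  only).
* The literal-f_u convention, while the default for fidelity, makes the
  LEM intercept depend on where the transition sits on the axis; use the
  ratio convention for thermodynamically interpretable numbers.
* PDB parsing is deliberately minimal: first model, altloc A, no mmCIF,
  no bond inference or hydrogen placement; trajectories must be
  multi-model PDB (convert binary MD formats upstream).
* Backbone hydrogen-bond counting is O(N·O pairs) per frame — fine for
  the intended fixture scale, not for all-atom systems with thousands of
  residues.
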