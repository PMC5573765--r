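---
title: "Models and methods behind avflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind avflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avflow)
```

`avflow` implements the computational chain that surrounds a patient-specific
3D CFD study of arterio-venous fistula (AVF) haemodynamics: inflow boundary
synthesis, lumped-parameter outlet calibration, and the unsteady and
time-averaged wall analyses. This vignette records the models, the numerical
choices, and the design decisions that were genuinely open — and what the
synthetic-data generators do and do not establish.

## Pulsatile inflow

A physiological inlet flow waveform is represented by its mean and the first
N complex Fourier harmonics of the pulse fundamental,
$$Q(t) = \bar Q + \sum_{k=1}^{N} \mathrm{Re}\{c_k e^{ik\omega t}\}, \qquad
\omega = 2\pi/T,$$
with $T = 1$ s and $N = 15$ for the canonical brachial inflow. "First 15
modes" is read as mean plus harmonics 1..15: that is the standard usage and
the only reading that preserves net flow. `fourier_fit()` extracts the
coefficients by DFT from one uniformly sampled period (the mean is preserved
exactly; asking beyond the Nyquist limit is an error), and
`scale_to_peak_reynolds()` multiplies a waveform by the unique positive
scalar that brings the peak of $Re = 4\rho|Q|/(\pi\mu D)$ to a target —
1300 at the brachial inlet with the blood properties
$\mu = 3.5\times10^{-3}$ Pa s, $\rho = 1060$ kg m$^{-3}$. The mean-velocity
Reynolds convention is used throughout; it is the standard pipe-flow form and
the one consistent with a peak value of 1300 in a brachial-scale vessel. The
inlet diameter is not a published constant and is therefore a required
configuration input.

In space each harmonic drives the classical Womersley oscillatory pipe-flow
profile,
$$u_k(r,t) = \mathrm{Re}\left\{\frac{Q_k}{\pi R^2}\,
\frac{1 - J_0(\beta_k r/R)/J_0(\beta_k)}
     {1 - 2 J_1(\beta_k)/(\beta_k J_0(\beta_k))}\, e^{ik\omega t}\right\},
\qquad \beta_k = i^{3/2}\alpha_k,$$
with $\alpha_k = (D/2)\sqrt{k\omega\rho/\mu}$ the harmonic's Womersley
number. The normalization makes each harmonic's cross-sectional flow equal
its coefficient exactly, so the profile integrates back to $Q(t)$ at every
instant — the property the tests verify to $10^{-6}$ against Simpson
quadrature. The complex Bessel functions are evaluated by power series,
which is accurate to well below the stated tolerances for $\alpha \lesssim
20$ (harmonic 15 of a 1 Hz pulse in a 5 mm vessel reaches $\alpha \approx
13$); below $\alpha = 0.1$ the series is abandoned for the exact
quasi-steady parabolic limit to avoid cancellation.

## The 0D Windkessel network

Each outlet carries a three-element RCR Windkessel,
$$P = Q(R_1+R_2) - R_2 C \frac{d}{dt}(P - R_1 Q),$$
referenced to zero distal pressure, with the radial and ulnar arterial
outlets tied to the same parameters and merged at one node. The interior of
the vessel network is represented by three inductive branches (proximal
artery, distal artery, vein) with quadratically non-linear resistors. The
constitutive law for those is taken sign-preserving, $\Delta P = R\,Q|Q|$:
the source specification says only "quadratically non-linear", and the
sign-preserving form is the standard choice that keeps the element
dissipative in both flow directions.

Internally each RCR terminal is integrated in its capacitor-node form
($P_c$ the pressure behind $R_1$; $C\dot P_c = Q - P_c/R_2$), and the
prescribed inlet flow eliminates one inductor state through Kirchhoff's law
at the anastomosis, leaving four states. The integrator is classical RK4 at
a fixed step (default $10^{-4}$ s, mirroring the reference CFD time step),
compiled in C++, run cycle by cycle until the cycle-to-cycle RMS change of
the inlet pressure falls below `tol` times its range (default
$5\times10^{-3}$; the reference gives none).

Two numerical points deserve emphasis:

- **Initialization.** The conventional uniform 78 mmHg start is the
  default, but the venous compliance is large (10.5 mL/mmHg against a
  ~4 mmHg s/mL charging resistance gives a time constant of tens of
  seconds), so a uniform start needs hundreds of cycles to settle.
  `P_init = "dc"` warm-starts every capacitor at its steady resistive-divider
  value — including the quadratic-resistor correction, solved by
  root-finding — and reaches periodic steady state in a few cycles. All
  cycle-averaged analyses in the package use it.
- **Stability.** Explicit RK4 is conditionally stable; the fastest network
  time constants are the inductor loop $L/R$ and the capacitor nodes
  $C(R_1\|R_2)$. The calibration evaluator refines its step below both for
  whatever parameter set the optimizer proposes, and treats a non-finite
  trace (an unstable excursion) as a very bad fit rather than an error.

In periodic steady state the cycle-averaged current into each compliance
vanishes, so the full-period venous:arterial flow split equals the resistive
divider $R_{art,par}/(R_{art,par}+R_{1,VO}+R_{2,VO})$ — 65.8% venous for the
packaged P1-IN parameters and 66.0% for P2-IN, both a ~66:34 split. This is
both a test invariant and the basis of the acceptance targets. The reported
cycle is mapped to $[T, 2T]$ (one settling cycle before it), which places
the canonical analysis windows at WT = [1.0, 2.0] s, WS = [1.1, 1.4] s,
WD = [1.4, 1.7] s for a 1 s pulse.

## Calibration

The calibration cost is
$$\Phi = \left(\frac{\max P_{BAI} - P_{RS}}{P_{RS}}\right)^2
+ \left(\frac{\min P_{BAI} - P_{RD}}{P_{RD}}\right)^2
+ \left(\frac{\int |Q_{VO} - Q_R|\,dt}{\int |Q_R|\,dt}\right)^2$$
with reference pressures 130/80 mmHg and a reference venous outflow
waveform. Integrals use trapezoidal quadrature on the reference grid;
pressure extrema are taken over the discrete samples without interpolation.

No optimizer is prescribed by the source, so the package uses derivative-free
Nelder-Mead on log-transformed parameters: the log transform enforces
positivity without constraints, and the RAO/UAO tie reduces the problem to
six dimensions. The search restarts from seeded log-normal jitters of the
initial guess, keeps the best cost, and polishes once from the incumbent; a
result worse than the initial guess is never returned.

The outer loop alternates this optimization with a (surrogate)
high-fidelity run and a per-branch least-squares fit of
$\Delta P = R\,Q|Q| + L\,\dot Q$ (central-difference $\dot Q$, nonnegative
clipping), stopping when the Windkessel parameters change by less than
`outer_tol` relatively. Monotonic decrease of $\Phi$ across outer iterations
is *not* asserted — the source does not claim it and the alternation does
not guarantee it.

**Identifiability.** With self-consistent references the recovery experiment
(20 seeded truths within ±50% of the packaged values, initial guess at
twice the truth) recovers the resistances and the arterial compliance to a
fraction of a percent; the *venous* compliance is weakly identifiable, and
individual seeds can miss it badly while reproducing every reference trace
to $\Phi \sim 10^{-9}$. That is physics, not a solver defect: at
physiological values the venous compliance shorts essentially all pulsatile
flow regardless of its exact value, so the data contain almost no
information about it. The headline acceptance property is therefore the
median relative error across all recovered parameters, which is robustly
below 5%.

## Wall-shear-stress unsteadiness

`ring_average_magnitude()` produces the scalar series
$\bar\sigma_l(t)$: the area-weighted mean of $|\sigma|$ over a transverse
ring of faces. Its spectral content is estimated per analysis window with a
single-segment, mean-removed, Hann-tapered one-sided periodogram —
the windows are short (0.3 s), so segment averaging would cost all
frequency resolution; the estimator is normalized so the integrated PSD
recovers the tapered segment's variance (verified to 5% on white noise).

Snapshot POD decomposes the fluctuation field $\sigma - \bar\sigma_t$ over a
region's faces. The inner product is area-weighted and summed over the three
vector components — the source does not state a weighting, and area
weighting is the choice that makes the decomposition stable under mesh
refinement. Implementation is by SVD of the $\sqrt{\text{area}}$-weighted,
temporally centred snapshot matrix: eigenvalues are the squared singular
values, spatial modes are orthonormal under the weighted inner product, and
eigenvalues below $10^{-12}$ of the largest are truncated to zero so mode
counts do not depend on floating-point noise. Mean-centring is per-window
(the full-cycle alternative for WT is not what the snapshot definition
implies). The canonical sampling — 1000 snapshots at 0.001 s for WT, 1500
at 0.0002 s for WS/WD — is the generator default, but the operations accept
any uniform sampling.

## Time-averaged wall maps

Oxygen enters through Henry's law $C = H\,p_{O_2}$
($H = 1.74\times10^{-3}$ mol m$^{-3}$ mmHg$^{-1}$; 75 mmHg at the inlet and
60 mmHg at the wall sink give $1.305\times10^{-1}$ and
$1.044\times10^{-1}$ mol m$^{-3}$). The lumen-to-wall normal oxygen flux is
$J = -2\kappa\,\mathbf n\cdot\nabla C$ with $\kappa = 1.2\times10^{-9}$
m$^2$ s$^{-1}$ and outward normal $\mathbf n$; the factor two accounts for
haemoglobin-augmented transport. The hypoxia threshold is the product of the
wall consumption rate $8.55\times10^{-3}$ mol m$^{-3}$ s$^{-1}$ and the
avascular wall thickness $5\times10^{-5}$ m: $4.275\times10^{-7}$
mol m$^{-2}$ s$^{-1}$.

Time averaging of WSS takes the magnitude *before* averaging (an
alternating field of constant magnitude averages to that magnitude, not
zero). Classification uses strict inequalities — a face exactly at a
threshold is unclassified, a measure-zero event for continuous fields — and
the display precedence overlap > low-WSS > high-WSS > low-flux. Area
percentages are computed on the 3D mesh directly; the "excised and
flattened" presentation of wall maps is treated as pure visualization.
Shear-rate exposure is the volume fraction whose *maximum* shear over the
pulse exceeds each threshold ("at some stage" semantics).

## Geometry

Centreline utilities mirror the vessel-reconstruction post-processing:
arclength-uniform resampling, discrete Frenet curvature from unit-tangent
differences, the Dean number $De = Re\sqrt{\kappa_A D_A/2}$, and radius
averaging over five equisized sections. "Equisized" is taken in arclength,
not point count — point spacing is an artefact of sampling. The smooth
radius interpolant between section means uses a monotone cubic through the
section midpoints; the NURBS lofting of the original CAD chain is
out of scope.

## The synthetic world

Every input the pipeline needs can be generated, seeded, with ground truth
attached:

- `gen_inflow_waveform()`: a raised-cosine systolic pulse on a constant
  base, band-limited to 15 harmonics, scaled to peak Re 1300 with a
  time-averaged-to-peak ratio of 750/1300 — the stated conditions of the
  modelled setting. The pulse amplitude is chosen after band-limiting, so
  the ratio is exact on the evaluation grid. The exact published waveform
  shape (digitized from a figure) is unavailable; the family mimics it
  qualitatively.
- `gen_cylinder_mesh()`: an open tube with artery/vein halves and closed
  transverse rings — a topological, not anatomical, stand-in for the AVF
  lumen.
- `gen_wss_field()`: exactly-rank-k fields built from area-orthonormal
  random patterns times discretely orthogonal sinusoids, optionally plus
  white noise. With zero noise the POD rank is exactly k and equal
  amplitudes give equal energies — which is what makes mode-count tests
  sharp.
- `gen_truth_network()`: truth Windkessel draws within ±50% of the packaged
  values, references derived from the truth run itself, and a surrogate
  that is the 0D model with optionally perturbed internal elements.
- `gen_oxygen_walldata()` / `gen_shear_volume()`: fields constructed so a
  configured fraction falls below/above each threshold, with the achieved
  fraction recorded. The default exposure fractions (100/99/93% above
  10/100/250 s$^{-1}$) state the canonical exposure pattern as a
  demonstration fixture.

What a green test establishes: that the operations compute their
definitions correctly (oracle equivalence), that the network honours its
conservation laws, and that calibration closes on self-consistent synthetic
truths. What it does not establish: agreement with any particular patient's
CFD fields — the published per-configuration mode counts, pressure ranges,
area percentages and Windkessel values depend on unpublished 3D solutions
and are explicitly out of reach at desk scale.

## Known limitations

- The network topology is fixed to the three-outlet AVF arrangement with
  the arterial pair tied; untied terminals are representable but the
  calibration parameterization assumes the tie.
- Inductor-free networks (`L2A + L1V = 0`) are rejected rather than solved
  algebraically.
- The venous compliance is weakly identifiable from the calibration data
  (see above); per-parameter guarantees are deliberately not made.
- PSD estimation uses a single segment; for long records a Welch-style
  average would reduce variance at the cost of resolution.
- PLY I/O is ASCII-only; binary PLY and HDF5 field I/O require `rhdf5`
  for the latter.
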