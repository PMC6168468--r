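---
title: "Modelling the emergence of 3D spatial cells with a lateral anti-Hebbian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the emergence of 3D spatial cells with a lateral anti-Hebbian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialnet3d)
```

# The model

`spatialnet3d` simulates how a population of neurons driven only by
self-motion signals can develop the full zoo of three-dimensional spatial
receptive fields — place, grid, border, plane and stack cells — through
unsupervised learning. The pipeline has four stages.

**Trajectory.** A virtual animal (think of a bat in a flight room) moves at
constant speed through a box. Its heading is described by an azimuth angle
(uniformly distributed over 360 degrees in the long run) and a pitch angle
(Gaussian around level flight, s.d. ~7.6 degrees by default — taking a
reported pitch variance of 58.25 deg^2 literally). Azimuth evolves as a
wrapped random walk, whose stationary distribution is exactly uniform on
the circle, and pitch as a reflected AR(1) process, whose stationary
distribution is exactly the configured Gaussian. This achieves the target
marginals by construction, without an acceptance step, while keeping the
flight smooth (no teleports: each step has length `speed * dt`). Steps that
would leave the box are reflected billiard-style, deflecting the heading
inward.

**Head-direction encoding.** Two populations of head-direction cells, 70
tuned to azimuth and 30 to pitch (a 7:3 ratio), with preferred directions
uniformly spanning 360 degrees, respond with the signed cosine of the
offset between current and preferred direction.

**Oscillatory path integration.** Each head-direction cell drives a phase
oscillator with base frequency f = 0.5 Hz: `dphase/dt = omega + beta*s*phi`
with speed `s` and modulation factor beta = 2. Displacement along each
preferred direction is thereby integrated into phase, and the outputs
`sin(phase)` form a 100-dimensional stream whose second-order statistics
encode position: along a straight run the output of an oscillator whose
preferred direction is aligned with the motion oscillates in *space* with
wavelength `2*pi / (omega/s + beta)`.

**Lateral anti-Hebbian network (LAHN).** Fifty linear neurons receive the
oscillator stream through afferent weights `q` trained with the Hebbian/Oja
rule, and inhibit each other through lateral weights `p` trained with the
anti-Hebbian (Stent) rule. The combination performs a neural principal
component analysis: afferent rows converge into the leading principal
subspace of the input while lateral inhibition decorrelates the outputs.
Spikes are assigned wherever a neuron's activity crosses a per-neuron
threshold (mean + 2 s.d. of its trace) upward, and the spikes are binned
into 41^3 voxel rate maps for scoring.

# Numerical dynamics of the LAHN

Three numerical properties of the discrete network required care; each is
an implementation finding of this package, established on the default
100-oscillator input.

1. **Learning-rate stability.** The per-sample input has squared norm
   around 50, so the one-step-lagged response recurrence diverges within
   tens of samples for learning rates of 1e-3 and above. Moreover, rates
   above ~1e-4 put the Oja dynamics in a "tracking" regime, where the
   afferent vectors chase the slowly rotating instantaneous input
   direction instead of averaging the session covariance: all neurons then
   collapse onto the same vector. The defaults `eta_f = 5e-5`,
   `eta_l = 5e-4` sit in the averaging regime with a comfortable margin;
   about ten passes over a 175,000-sample session suffice for the leading
   components to stabilize.

2. **Lateral connectivity.** With full all-to-all lateral weights, the
   decorrelating fixed point requires inhibition whose spectral radius
   exceeds 1. The steady-state response `gamma = (I - p)^-1 q y` is
   perfectly well defined there, but the one-step-lagged iteration that
   implements it oscillates and diverges, and capping the spectral radius
   leaves the recurrence dominated by its own feedback: at n = 50 the
   afferent rows progressively align instead of differentiating (we
   measured mean pairwise |cos| rising from 0.29 to 0.70 across epochs).
   The package therefore defaults to *hierarchical* lateral connectivity:
   neuron i is inhibited only by neurons k < i. The lateral matrix is then
   strictly triangular, hence nilpotent, the lagged recurrence is
   unconditionally stable, and the classical result for hierarchical
   anti-Hebbian networks applies: the neurons converge to the leading
   principal components themselves, in variance order (pairwise |cos| of
   trained afferent rows: 0.04). Full connectivity and a settled
   (steady-state) response remain available as options
   (`lahn_network(lateral=, response=)`).

3. **Convergence trace.** Training stops when the summed absolute *net*
   weight change over an epoch falls below a tolerance. The summed
   magnitude of per-sample updates would grow with epoch length and never
   cross a fixed tolerance under constant learning rates, so the net
   change per epoch is the meaningful trace; with constant rates it
   plateaus at the level of stochastic fluctuation around the attractor,
   and `max_epochs` (default 10) effectively governs run length.

# Spatial scales: arena, speed and turn rate

The arena size, flight speed and turn rate are free parameters of the
simulation (only `beta`, `f` and `dt` are fixed by the model table), yet
they set every spatial scale of the emerging maps:

- the oscillator interference wavelength is `2*pi/(omega/s + beta)` length
  units, so the number of grid periods across a box of side L is
  `L*(omega/s + beta)/(2*pi)`;
- trajectory coverage of the 41^3 voxel grid is limited by the path length
  `s * T`: a session can visit at most `s*T/(L/41)` voxels.

The defaults (L = 12, s = 25 units/s, 175,000 samples) were chosen so that
(i) roughly four grid periods span the arena, matching the multi-field
rate maps the model family is meant to produce, and (ii) the trajectory
visits ~90% of all voxels in a session. With the previous draft scale
(L = 5, s = 2.5) a single firing field filled half the box and 60% of the
voxels were never visited; no classification is meaningful in that regime.
The length unit is deliberately abstract. The default turn-rate s.d. is 3
degrees per 10-ms step (~300 deg/s): sharper turning (we first used 15
deg/step) destroys the straight-run phase coherence that builds lattice
structure, and is also outside the plausible range for flight.

# Rate maps and descriptors

**Rate maps.** Spike counts and occupancy time are accumulated in 41^3
voxels and both smoothed with a Gaussian kernel (sigma = 3 voxels,
renormalized over the visited support); the rate is their ratio. Smoothing
counts and occupancy separately — rather than smoothing the per-voxel
count/time quotient — keeps the estimator stable when individual voxels
hold only a few samples, which is the norm at flight speed. The unsmoothed
quotient map (with an occupancy floor) is kept alongside.

**Autocorrelograms.** Pearson correlation of the map with itself at every
3D (or 2D) lag, computed over the overlap of defined voxels with the
overlap count as the normalizer, FFT-accelerated; lags with fewer than 20
overlapping voxels are undefined.

**Gridness.** From a 2D autocorrelogram (a projection or a transection
slice), the central peak is masked to the radius where the radial profile
first falls below 0.2, the annulus extends to 1.25 times the median
distance of the six nearest peaks, and the annulus is correlated with
rotated copies: `HGS = min(cor60, cor120) - max(cor30, cor90, cor150)`,
`SGS = cor90 - max(cor45, cor135)`. The annulus is confined to the inner
half of the lag range: beyond it the overlap support shrinks and its shape
correlates with rotation angle, which we found biases SGS upward by
several tenths for stripe-like maps.

**FCC score.** An ideal face-centered-cubic firing pattern is the sum of
four cosine plane waves whose wave vectors point to alternating cube
vertices (pairwise ~109.47 degrees); its autocorrelogram has four
hexagonal transection planes ~72 degrees apart. The score scans ~500
Fibonacci-distributed plane normals through the 3D autocorrelogram's
centre, takes the best-HGS slice as reference, finds candidate planes at
72 +/- 3 degrees from it (and pairwise), averages the top three of their
HGS values, and normalizes by the same statistic computed on the analytic
FCC lattice; negatives clamp to 0 and the score caps at 1.

**Border score.** `BS = (C_M - d_M)/(C_M + d_M)` per orthogonal projection,
with C_M the maximal fraction of one wall covered by a single firing field
(connected components above 30% of the map peak) and d_M the rate-weighted
mean distance of bins to their nearest wall, normalized by half the
shorter side. The 3D aggregate is the mean of the top two projections; a
border cell must exceed threshold on two planes.

**Plane index.** Weighted least-squares regression of one voxel coordinate
on the other two over suprathreshold voxels, best axis kept; `PI = R^2`.
Because the regression form is blind to planes normal to a coordinate axis
(the dependent variable then carries only slab-thickness variance), a
total-least-squares planarity `1 - lambda_min/lambda_mid` substitutes for
genuinely thin fields (out-of-plane spread under ~2 voxels). Stack cells
are detected by segmenting the suprathreshold voxels into connected
components, fitting each, and merging coplanar components.

**Ellipsoid isotropy.** An axis-aligned ellipsoid is fitted to the boundary
voxels of the largest firing field by nonlinear least squares, initialized
from second moments; the elongation index is the ratio of the largest to
the smallest semi-axis, with isotropy below 1.38.

# Thresholds and their calibration

The classification thresholds are SI 1.0609 bits/spike, HGS 0.1686, SGS
0.1952, BS 0.5228, PI 0.7528 and elongation 1.38; all of these were
originally defined as high percentiles of shuffled (circularly
time-shifted) surrogate distributions. Two of them do not transfer across
map-making pipelines:

- spatial information scales with spike counts, voxel counts and
  smoothing: the identical neuron scores ~5 bits/spike on raw sparse maps
  and ~0.5 on smoothed ones;
- the border score of a dense, weakly modulated map sits near +0.5 by
  construction (a map-spanning field yields full wall coverage while the
  normalized mean wall distance of a uniform map is about one third).

The package therefore re-derives the SI and BS thresholds with the same
shuffling procedure under its own pipeline (`calibrate_thresholds()`: 95th
percentile of pooled circular-shift shuffles; default in
`run_spatial_model()`), while the rotation-correlation, R^2 and
axis-ratio thresholds — whose baselines are density-stable — keep their
fixed values. The fixed table remains available via
`default_thresholds()`.

A neuron is *spatially periodic* when the ring-averaged autocorrelation
beyond the central peak exceeds 0.15 in some projection: a genuine lattice
or stripe pattern lifts a whole ring of the correlogram, while isolated
noise bumps do not. Periodic neurons form the population whose planar
symmetry (hexagonal vs square) and FCC tendency are analyzed.

# Classification cascade

Labels are assigned by a most-specific-first cascade: non-spatial (SI
below threshold) -> border (BS above threshold on two orthogonal planes)
-> grid (hexagonal, then square, by best-projection gridness) -> plane or
stack (plane index above threshold with sub-threshold border score; stack
when several planes are accepted) -> place (a single compact connected
field) -> other spatial cell (OSC). Undefined descriptors fail their
tests. The place-cell SI requirement defaults to the calibrated spatial
threshold itself.

# What the synthetic generator does and does not emulate

The generator reproduces the *statistics* that drive the model — heading
marginals, smoothness, constant speed, box confinement — but not
aerodynamics, echolocation-guided steering, wall-following behaviour,
landing/roosting, or speed variability of real flight. Passing tests
establish that the model transforms those statistics into the reported map
types; they say nothing about whether real bats' trajectories carry the
same statistics. Plane-constrained modes (horizontal floor, vertical wall)
emulate the crawling-rodent comparisons; the pitch-s.d. sweep emulates
increasingly unconstrained vertical movement.

# Problem sizes and determinism

Default experiments use the full 175,000-sample session (29.2 simulated
minutes) and 50 neurons; the test suite exercises the same code on
shortened sessions and fewer retrainings, and the acceptance script runs
five full retrainings plus a horizontal-training/vertical-evaluation
sweep. All randomness flows from a single seed expanded into per-module
substreams, and identical seeds give bit-identical trajectories, weights
and summaries.

# Known limitations

- The emergent periodic cells are square/stripe-like rather than
  hexagonal, and this appears structural: the covariance between two
  oscillators depends only on the angle between their preferred
  directions (a stationary kernel on the circle of directions), so the
  principal components the network converges to are angular Fourier
  modes that weight all directions uniformly. Their amplitude envelopes
  are ring-spectrum random fields — correlogram rings, not lattices —
  with the box's billiard reflections tipping the balance toward
  axis-aligned (square) structure. Selecting the three-wave, 60-degree
  interference needed for hexagons requires information beyond the input
  stream's second-order statistics, which is all a linear
  Hebbian/anti-Hebbian network can use. Consequently the hexagonal
  fraction, the FCC score and the vertical-plane critical angle in this
  implementation fall well short of hexagon-rich reference populations.
- Billiard wall reflections concentrate occupancy and phase-coherent
  path segments along the walls, which inflates the border-cell fraction
  relative to softer wall-avoidance steering.
- The one-step-lagged full-lateral network is retained for fidelity but
  cannot reach strong decorrelation at n = 50 (see above); the
  hierarchical default changes the network's connectivity pattern, not its
  learning rules.
- Ellipsoid fits on sheet-like (planar) fields are degenerate and produce
  arbitrarily large elongation indices; isotropy statistics exclude
  indices above 10.
- Shuffling calibration adds ~1 minute per training run; it can be
  disabled (`threshold_calibration = "fixed"`) to use the fixed table.
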