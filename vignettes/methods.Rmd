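---
title: "Benchmarking regularized ECG imaging during atrial fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking regularized ECG imaging during atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgibench)
```

## The problem

Electrocardiographic imaging (ECGI) estimates the electrical potentials on
the heart surface from body-surface potential (BSP) recordings. The forward
model is linear: at each time instant $t$,

$$ y_t = A\, x_t + \epsilon, $$

where $x_t$ holds the epicardial potentials at $N$ atrial nodes, $y_t$ the
potentials at $M$ torso electrodes, and $A$ is the $M \times N$ transfer
matrix of the volume conductor. The map is severely ill-posed — the torso
smooths and attenuates the cardiac sources — so the inverse estimate must be
regularized, and during atrial fibrillation (AF) the sources are fast,
disorganized and non-stationary, which is exactly the regime where
regularization behaviour is least understood.

Clinically, the raw potentials are often not the quantity of interest.
During AF one cares about *dominant frequency* (DF) maps, which expose fast
driver regions, and about *phase singularities* (SPs), the pivot points of
reentrant rotors and candidate ablation targets. This package implements the
whole benchmarking chain: simulate known atrial activity, project it to the
torso, corrupt and filter it, reconstruct with fourteen regularization
methods, extract the clinical targets, and score every step against the
known truth.

## The synthetic study system

Anatomical meshes and a boundary-element transfer matrix are deliberately
out of scope. The package instead runs on synthetic geometry: ellipsoidal
icosphere meshes (`default_atrial_mesh()`, 40 x 35 x 50 mm semi-axes;
`default_torso_mesh()`, 120 x 100 x 160 mm) and an infinite-medium
monopole-kernel transfer operator weighted by barycentric node areas
(`kernel_transfer_matrix()`), Wilson-Central-Terminal referenced with
`apply_wct_reference()`. Any externally computed transfer matrix can be
loaded with `read_transfer_matrix()` and dropped into the same chain.

Three activity phantoms (`activity_pattern()` / `simulate_pattern()`) define
the study conditions:

* **SR** — sinus rhythm: a plane wave with every node activating at 1.2 Hz;
* **SAF** — simple AF: a single functional reentry rotating at 7.3 Hz inside
  a geodesic ball around the rotor core, remote tissue at 4.7 Hz;
* **CAF** — complex AF: rotor region at 6.8 Hz, remote tissue at 5.4 Hz,
  with 25% of nodes under fibrotic conditions (amplitude x 0.1 and
  activation-time jitter up to 10% of the cycle length).

The phantoms are *kinematic*: each node carries a prescribed phase
trajectory, and the potential is an action-potential-shaped waveform of that
phase (sharp upstroke, slow repolarization, $C^1$, range $[-1, 1]$). Inside
the rotor region the phase advances with the azimuthal angle about the core
in its tangent plane, which puts exactly one phase singularity at the core;
outside, a plane wave at the remote rate. This reproduces the *spectral and
phase structure* the inverse/target/metric chain consumes, which is all the
benchmark needs; it does not model restitution, rotor meander, or wavebreak,
so conclusions about those dynamics are outside what a passing suite shows.
The rotor-region radius is not fixed by the emulated study conditions; the
default is a 25 mm geodesic ball, configurable per pattern, with an optional
logistic frequency blend over 5 mm at the boundary for boundary-effect
studies.

Two discretization facts are worth recording. First, on a closed surface a
globally azimuthal phase field necessarily carries a second, counter-rotating
singularity (the Poincaré index theorem); in the phantoms the remote plane
wave replaces the azimuthal field outside the rotor ball, so the second
singularity does not occur, and the pure-vortex test fixtures therefore live
on an open disk mesh whose boundary nodes are skipped. Second, at a hard
rotor-region boundary the two incommensurate rates make the wrapped phase
difference across boundary edges sweep the circle once per beat period, so
frame-wise detection sees short-lived spurious charges there; these are
removed by the two-rotation persistence rule below, and the surviving track
sits at the true core.

## Forward pipeline

`forward_project()` applies the referenced operator; `add_noise()` injects
white Gaussian noise calibrated to a target SNR against the *global* mean
square over all leads and samples (the usual ECGI convention; a per-lead
convention would weight quiet electrodes differently); `bandpass_filter()`
applies a fourth-order Butterworth — 3–30 Hz for the fibrillatory models,
0–30 Hz (pure low-pass) for SR. Filtering is zero-phase (forward–backward),
a deliberate choice: phase maps are downstream consumers, and a causal
filter's group delay would bias singularity trajectories. The gold standard
for every potential metric is the true epicardial signal passed through the
same band filter as the torso data.

`perturb_transfer_matrix()` implements the model-error experiment: i.i.d.
Gaussian error added row-wise at a prescribed signal-to-error ratio (SER).

## The fourteen solvers

All methods share the registry names used in benchmark configs
(`solver_registry()`): `Tik-g0/g1/g2`, `Tik-i0/i1/i2`, `TSVD-0/1/2`,
`DSVD`, `TV`, `Bayes`, `GS`, `GMRES`.

**Tikhonov** minimizes $\|y_t - A x_t\|_2^2 + \lambda \|L x_t\|_2^2$ with
$L$ the identity (order 0), the edge-incidence gradient (order 1) or the
umbrella graph Laplacian (order 2). The gradient on a triangulated surface
is intrinsically edge-indexed, so $L$ is rectangular ($E \times N$, entries
$\pm 1/\text{edge length}$); only $L^\top L$ or its GSVD ever enters a
solve. The global variant (`Tik-g*`) uses one $\lambda$ for the whole
record (Frobenius objective); the instantaneous variant (`Tik-i*`) selects
$\lambda_t$ per time sample.

**TSVD / DSVD** filter the (generalized) singular spectrum: hard truncation
at $k$ components, or the smoother $\sigma/(\sigma + \lambda)$ damping.
Orders 1 and 2 of TSVD use the truncated GSVD of the pair $(A, L)$.

Internally every spectral method runs through one decomposition
(`reg_decomposition()`): the thin SVD when $L = I$, otherwise a GSVD built
by the QR + CS-decomposition route (QR of the stacked $[A; L]$, SVD of the
$A$-block of $Q$). Components in the null space of $L$ (sines below
$10^{-10}$, i.e. generalized values beyond $10^{10}$) are flagged exactly
unpenalized. The small-instance correctness of this route is tested against
an independent standard-form oracle (SVD of $L A^{-1}$).

**TV** minimizes $\|y - Ax\|_2^2 + \lambda \|L x\|_1$ by IRLS on the
$\varepsilon$-smoothed absolute value, warm-started from the first-order
Tikhonov solution, with $\varepsilon = 10^{-6} \cdot \mathrm{median}|L
x^0|$, at most 50 iterations and a $10^{-6}$ relative tolerance; the
majorize–minimize construction makes the smoothed objective non-increasing.

**Bayes** is the MAP/posterior-mean estimate
$\hat x_t = C_x A^\top (A C_x A^\top + C_n)^{-1} y_t$ under a zero-mean
Gaussian prior. In benchmark mode the prior covariance is sampled from 150
time columns of the *true* filtered epicardial potentials in a 1-s window
disjoint from the estimation window (`estimate_prior_covariance()`), and
$C_n = \sigma_n^2 I$ with the injected noise variance. This is an oracle
prior — deliberately so: it bounds what prior information could buy, and it
is why Bayes is expected to win every cell.

**GS** (Greensite) adds temporal structure through the isotropy assumption
(spatio-temporal covariance factorizes as a Kronecker product): SVD of the
data matrix, a first-order Tikhonov solve per leading temporal component
(each with its own L-curve parameter), recombination. The temporal rank
defaults to the components carrying 99% of the data energy.

**GMRES** regularizes by iteration count: GMRES is run on the square
normal-equations system $A^\top A x = A^\top y$ (plain GMRES needs a square
operator) for up to 30 iterations, every iterate is recorded, and the
iterate with the smallest data residual $\|y - A x_k\|$ is returned. On the
very smooth monopole kernel this selection semi-converges toward the
noise-fit solution — an expected property of minimal-residual selection on
severely ill-posed problems, visible in the benchmark results.

## Parameter selection

`lcurve_lambda()` evaluates the L-curve (log residual norm vs log seminorm)
on a log-spaced grid, by default 60 points constrained to
$[(10^{-4}\sigma_1)^2, \sigma_1^2]$ with $\sigma_1$ the largest singular
value of $A$. The corner is the *interior local maximum* of the three-point
circumscribed-circle (Menger) curvature, ties toward smaller $\lambda$.
Restricting to interior local maxima matters: truncating the curve at the
search bounds manufactures monotone curvature roll-off attached to the grid
ends, and an unconditioned argmax would select it — the very failure mode
that motivates constraining the search in the first place. If no positive
interior peak exists the global curvature argmax is returned with a
low-confidence flag.

For TSVD the truncation level is chosen on the discrete $(\rho(k),
\eta(k))$ curve. The discrete spectrum makes that curve jagged, so
three-point curvature is unstable there; the elbow criterion — the point
farthest from the chord joining the curve's endpoints, computed over the
positive-seminorm segment — is used instead.

`oracle_lambda()` implements benchmark-mode selection: the $\lambda$
minimizing RDMS against the known truth over a 1000-point logarithmic grid,
per instant or globally. It is the yardstick for how much the L-curve
choice costs.

## Targets and metrics

**DF**: Welch periodogram per node (2-s Hamming windows, 50% overlap),
zero-padded to a 0.05 Hz grid so the fibrillatory rates are exactly
representable (a raw 2-s window resolves only 0.5 Hz). Peaks in the search
band are discarded as harmonics when a peak within 0.25 Hz of half their
frequency carries at least 30% of their power; the highest surviving peak
wins. The default band is 3–15 Hz; sinus-rhythm analyses widen it to
0.5–15 Hz since the 1.2 Hz pacing fundamental lies below the fibrillatory
band. **RAE** is the node-averaged relative absolute percent DF error.

**Phase**: per node, zero-phase band-pass from 3 Hz to DF + 2 Hz (for slow
nodes where that band would collapse, the low edge drops to half the DF),
then the analytic-signal (Hilbert) phase. Phase maps are scored with the
same CC/RDMS machinery applied to the wrapped values; a circular-statistics
variant was considered and left out of the default because the wrapped
scoring is what the benchmark's consumers use.

**SP detection**: a node is charged when the wrapped phase differences
along its *ordered* one-ring sum to $\pm 2\pi$ (tolerance 0.5 rad against
discretization); adjacent same-chirality charges merge into one detection
at the node nearest the cluster centroid. `track_sps()` links detections
greedily within a 10 mm geodesic radius, tolerating 2-frame gaps, and keeps
a track only if it persists at least two full rotations at its core's DF.
The kept tracks define the **SMF** — the normalized spatial histogram of SP
locations — which is compared by WUI (probability-and-area-weighted missed
fraction of the true SP region), WOI (spurious fraction of the estimated
region), CC of the SMFs, and the geodesic mode distance. Node areas use the
barycentric convention (one third of incident face area), which conserves
total surface area — the property the weighted indicators implicitly rely
on; the raw incident-sum variant is available behind a flag.

Statistical comparisons between metric distributions use the two-sample
Wilcoxon rank-sum test (`wilcoxon_compare()`, two-sided, $\alpha = 0.05$).

## Benchmark harness and problem sizes

`bench_config()` + `run_benchmark()` sweep solvers x SNR
$\in \{10, 20, 30, 40\}$ dB x models x seeds, with an 8-s, 500 Hz record, a
4-s estimation window and a disjoint 1-s Bayes training window, and write
one tidy row per metric. The packaged study scale uses the 162-node atria /
42-lead torso ("tiny") geometry, which keeps a full 8-solver x 4-SNR x
2-model x 5-seed grid in the minutes range on one CPU while preserving the
qualitative structure of the results; `make_fixtures(scale = "small")`
generates the 642/162 version of the same study for heavier runs. The
ordinal findings the harness is expected to reproduce — Bayes best in
potential CC everywhere, DF error varying far less across solvers than
potential CC, graceful monotone degradation with falling SNR, near-identical
RDMS for instantaneous vs global zero-order Tikhonov despite widely
different selected parameters — are asserted in the test suite on exactly
that grid.

## Numerical choices and degenerate inputs

* RDMS is the Euclidean distance of unit-normalized signals (range
  $[0, 2]$); zero vectors are an error, constant signals make CC a sentinel
  `NA` rather than a silent 0.
* The TV objective uses the squared residual (the standard TV-regularized
  least-squares form); with $\lambda = 0$ it is exactly least squares.
* SMF "support" is exact non-zero mass; an epsilon threshold is available
  for noisy histograms but off by default.
* SMF mode ties resolve to the smallest node index; dominant-SP ties to the
  longer, then earlier track. "No SP detected" is an explicit flagged
  outcome (zero SMF, `NULL` dominant SP), not an error.
* All stochastic steps (noise, fibrotic draw, prior sampling, matrix
  perturbation) take explicit integer seeds and are bit-reproducible.
* WCT referencing is a projector (idempotent); the API still refuses to
  re-reference, since double application signals a caller bug.

## Known limitations

The phantoms are kinematic, the transfer operator is a monopole kernel on
smooth ellipsoids, and the study scale is small: absolute metric values are
not comparable to anatomical-model studies (the kernel here is *more*
ill-posed than a boundary-element operator, and model-error effects below
the noise floor — e.g. a 40 dB SER perturbation under 20 dB measurement
noise — can vanish or even act as incidental regularization). What the
package supports are the relative comparisons: solver orderings, target
robustness, and the behaviour of parameter-selection rules under the same
conditions for every method.
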