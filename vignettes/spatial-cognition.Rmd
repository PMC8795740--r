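---
title: "Modelling hippocampal spatial cognition with gridpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hippocampal spatial cognition with gridpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridpath)
```

`gridpath` simulates a hippocampus-inspired spatial-cognition stack for a
mobile agent: head-direction cells encode speed and heading, stripe-cell
continuous attractor networks (CANs) integrate velocity into periodic phase
codes, three stripe plates 60° apart assemble hexagonal grid-cell firing,
boundary cells memorise grid activity at arena walls and inject it back to
cancel accumulated drift, and a multi-scale maximum-likelihood decoder reads
position out of nested grid modules into a place-cell response. This
vignette describes the models, the parameters that matter, and the design
choices behind them.

## The stripe-cell attractor

Each stripe plate is a ring of `n_cells` rate units obeying

$$\tau \frac{ds_i}{dt} + s_i = f\Big[\sum_j W_{ij} s_j + B_i\Big],
  \qquad f(x) = \max(x, 0),$$

with all-inhibitory recurrent weights
$W_{ij} = w_0\,[e^{-\gamma d_{ij}^2} - e^{-\beta d_{ij}^2}]$ evaluated at the
signed ring distance $d_{ij}$ shifted by $k\,e_j$, where $e_j = \pm 1$
alternates with cell parity (interleaved preference signs). The drive is
$B_i = 1 + \alpha\, e_i\, v_\parallel$ with $v_\parallel$ the velocity
projection onto the plate's preferred direction. With $k$ and $\alpha$ both
nonzero the stationary periodic pattern flows at a speed proportional to
$v_\parallel$, so the unwrapped pattern phase path-integrates displacement.

Three numerical points deserve emphasis, because they decide whether a
one-dimensional plate works at all:

* **Weight amplitude.** With the conventional
  $\beta = 3/\lambda_k^2,\ \gamma = 1.035\beta$ kernel at unit amplitude,
  the Fourier gain of the pattern-forming mode on a 1-D ring is only
  $\approx 0.075$ — far below the unit recurrent gain a Turing-type
  instability needs (a 2-D sheet gets its gain from the 2-D neighbourhood
  sum). The plate therefore carries an explicit amplitude `w0_scale`
  (default 40); without it the uniform state is linearly stable and no
  stripes form.
* **Mode selection.** The fastest-growing wavelength of this kernel is
  $\approx 1.4685\,\lambda_k$, not $\lambda_k$ (from the argmax of the
  kernel's Fourier transform). `build_weight_matrix()` therefore converts
  the requested *pattern* period into the kernel wavelength internally, so a
  plate asked for period $\lambda$ actually forms period $\lambda$.
* **Discreteness pinning.** A discretely sampled pattern sits in a weak
  periodic potential and sticks at low drive and at movement reversals.
  Pinning falls off steeply with cells-per-period; accurate integration
  needs roughly 30 cells per period (15 per preference sign) together with
  an offset $k \approx \lambda/10$ and saturated weights. This is why the
  default integration plate is 360 cells with $\lambda = 60$ and $k = 6$,
  while the pattern-formation study keeps the classic 120-cell geometry
  (formation does not involve motion).

The integration defaults ($\alpha = 0.06$, $\tau = 3$ ms, Euler step
$\tau/5$) place the whole roam speed range (0–0.5 m/s) inside the plate's
linear-response window: the drive $\alpha v$ stays between the depinning
floor ($\sim 10^{-4}$) and the response plateau's upper knee
($\sim 0.03$), and the fast effective population time constant keeps the
transient left by each stepwise velocity-command change small. Under these
conditions a 120 s random roam in a 1 m × 1 m arena yields a
phase–displacement correlation of ≈ 0.99999 with maximum regression
residual ≈ 3 mm (`run_phase_linearity()`), comfortably at the
0.9997 / 0.02 m level the design targets. Experiments that trade accuracy
for speed (the long-roam boundary study, the full pipeline) use τ = 10–20 ms
plates: at a given phase speed the drive is proportional to τ, so slower
plates keep coarse, slowly flowing patterns above the depinning floor, at
the price of larger command-step transients — an acceptable trade at those
scales.

Pattern phase is read out as the argument of the population vector
$\sum_i s_i e^{2\pi i\,x_i/\lambda}$ and unwrapped by nearest-branch
continuation; `run_plate()` records phase at sub-intervals of each
trajectory sample so the per-record phase motion stays well below half a
period even for fast-flowing patterns.

**Formation detection.** `relax_to_pattern()` integrates from uniform noise
(`runif(0, 0.01)`, seeded) and reports the first time at which the profile's
dominant spatial period matches $\lambda$ within 10% *and* the profile has
changed by less than 1% (of its maximum) over a 50 ms window. With the
120-cell formation geometry ($\lambda = 24$, $k = 1$, $\tau = 10$ ms,
$dt = 1$ ms) the median formation time over 20 seeds is ≈ 465 ms. A finite
ring occasionally seeds a competing wavenumber and never stabilises at
$\lambda$; such runs are reported as failures (they are rare at five
periods per ring, where neighbouring modes are ±20% away), and callers that
only need *a* relaxed plate can ask for automatic re-seeding
(`retries > 0`).

**Calibration.** `calibrate_displacement_gain()` regresses true displacement
along the plate's direction on unwrapped phase; the slope (m/cell) converts
phase to meters. The gain is a property of the plate dynamics, not its
orientation, so one calibration serves all three directions of a grid
assembly; `set_plate_period()` rescales the velocity input so one pattern
period corresponds to any requested physical period, which is how nested
grid scales share a single calibrated plate design.

## Head-direction encoding

The head-direction ring is a feedforward encoder: cell $i$ carries
$v\cos(\theta_i - \theta_{head})$, deliberately unrectified — it is the
signed velocity projection a stripe plate consumes, and the plate's own
transfer function rectifies. A population-vector decoder
(`decode_ring()`) inverts the code exactly and serves as the module's
round-trip oracle. The ring could itself run attractor dynamics; here it is
kept feedforward because only the encoded projection enters the rest of the
stack.

## Grid assembly and the closed-form tuning

Grid firing is the rectified sum of three stripe-band responses with
preferred directions 60° apart (`superpose_stripes()`): the cell with phase
offset $\vec c_j$ reads each plate's profile at plate position
$(\vec k_l \cdot \vec c_j)/\text{gain}$. For decoding, the same geometry is
described in closed form by the periodic (von Mises) tuning

$$\Omega(\vec x) = n_{max} \exp\Big[\frac{\kappa}{3}
  \sum_{l=1}^3 \big(\cos(\omega \vec k_l \cdot \vec x) - 1\big)\Big],$$

with $\omega = 2\pi/\lambda$ and unit wave vectors at 30°, 90°, 150°
(a band oriented at angle $a$ has its wave vector at $a + 90°$, which
reconciles band orientations of 0°/60°/120° with these wave directions).
The conjugate firing lattice is spanned by $a_1 = a(1,0)$ and
$a_2 = a(\tfrac12, \tfrac{\sqrt3}{2})$ with $a = 2\lambda/\sqrt3$; cell
phase offsets tile one unit cell on a regular grid. Defaults
$n_{max} = 10$ Hz and $\kappa = 3$ give realistic single-cell fields
(sharp but not needle-like); neither value is prescribed by the underlying
theory, and both only rescale decoding error smoothly.

## Maximum-likelihood decoding

For Poisson counts $n_j$ the log posterior over position is, up to a
constant, $\frac{\kappa}{3}\sum_j \sum_l n_j
\cos(\omega \vec k_l\cdot(\vec x - \vec c_j))$. Its maximiser has the
closed form

$$\mu_l = \omega^{-1} \arg \sum_j n_j e^{i\omega \vec k_l \cdot \vec c_j},
 \qquad \hat{\vec x} = \tfrac{2}{3}\sum_l \mu_l \vec k_l,$$

exact because three unit vectors 60° apart satisfy
$\sum_l \vec k_l \vec k_l^\top = \tfrac32 I$. One subtlety: the three
projections are redundant ($\vec k_1 - \vec k_2 + \vec k_3 = 0$), so their
independently wrapped branches can be mutually inconsistent; the decoder
re-branches the largest projections until $\mu_1 - \mu_2 + \mu_3 = 0$,
which makes the estimate exact *modulo the firing lattice* everywhere, not
just in the central cell. `posterior_oracle()` evaluates the same log
posterior on a dense raster and is the independent ground truth the
closed-form decoders are tested against (200 noise-free cases match its
argmax within one raster step).

**Multi-scale refinement.** With nested modules (scale ratio 1.5 from a
10 m coarsest period by default, matching the study design) the coarsest
module anchors a unique estimate and each finer module contributes the
lattice branch of its own solution nearest the running estimate, weighted
by $\lambda_L^{-2} / \sum_{m \le L} \lambda_m^{-2}$ — a running
inverse-variance-weighted mean. The closed weighted-average form over all
scales and this recursion are algebraically identical for equal cell
counts; the package implements both and asserts their equality to 1e-10.
Branch offsets near half a period are flagged as ambiguous rather than
silently resolved, as is a flat or degenerate posterior. Monte-Carlo
decoding error falls strictly both with the number of scales (1→4) and
with cells per module (50²→100²), and Gaussian perturbation of the rates
at 10% and 20% of the peak activation displaces the decoded position by
well under 5% of the period, monotonically in the noise level.

**Place readout.** A place cell responds with
$\exp(-\lVert \vec x - \vec r_{i0}\rVert^2/\delta^2)$; the field width
default $\delta^2 = (\lambda_{min}/10)^2$ ties the readout sharpness to the
finest grid scale (no value is prescribed by the theory).

## Boundary-cell drift correction

Boundary cells tile the arena perimeter in short regions and fire when the
agent is within sensing distance of their segment. On a region's first
visit the plate's firing profile, occupancy-averaged over (at most the
first few samples of) the visit and scaled by $1/N$, is stored as weights
$W_{id}$; on later visits the dynamics gain the additive term
$\sum_d W_{id} B_d$. Because suppressed cells sit in deep recurrent
inhibition, the activation intensity must exceed that inhibition divided by
the learned weight scale before the injection can re-activate them; above
that threshold (default intensity 1000) the pattern *snaps* to the
remembered phase within tens of milliseconds and stays there, intact, after
release. Correction is applied as a fixed window (default 0.1 s) at each
entry into a learned band, and the phase track is bridged across the window
by nearest-branch continuation, since the snap transient itself carries no
usable phase. Three structural limits matter and are inherent to the
mechanism, not artefacts:

* drift beyond half a period aliases to the wrong branch and cannot be
  corrected;
* the remembered reference carries the spatial extent of its region —
  regions must be short relative to the physical period (defaults: 0.1 m
  regions for a 2 m period in the drift study) or the remembered average
  washes out;
* a revisit corrects to the *region's* phase, not the agent's exact
  position within it, so each correction leaves a residual of order the
  region size. Correction therefore bounds the error near that floor
  rather than eliminating it.

In the long-roam comparison (`run_boundary_comparison()`: 2 m × 2 m walled
arena, 1000 s, odometry noise of 20% on speed and 0.1 rad on heading, ten
seeds) the corrected path's error settles onto a plateau well below half
the stripe period while the uncorrected attractor and the raw dead-reckoned
odometry drift on; the corrected envelope is non-increasing between the
middle and final thirds of the roam.

## The synthetic trajectory generator

`generate_random_walk()` draws each step's speed uniformly from
(0, 0.5) m/s and increments the heading by a uniform draw from
(−π/2, π/2) — the study's roam statistics, read as per-step increments.
Steps that would leave the arena resample the heading uniformly until the
step stays inside, which preserves the speed distribution at walls. The
sampling step defaults to 0.1 s. `simulate_odometry()` re-integrates the
commands after independent Gaussian perturbation (multiplicative on speed,
additive on heading); the noise model is a deliberately simple stand-in for
encoder/compass error, with magnitudes (defaults 10% / 0.05 rad; the drift
studies use 20% / 0.1 rad) chosen so that dead reckoning drifts visibly
within the simulated durations. With zero noise it reproduces the generator
bitwise, which pins down the integration convention. The full-pipeline
experiment confines the roam to a 1.5 m band along the perimeter — the
"boundary area" of the arena — so wall contacts, and with them boundary
learning and correction, occur throughout the run; an unconfined walk in a
10 m arena can wander for hundreds of seconds without touching a wall,
which tests nothing.

What the generator does *not* emulate: continuous (finite-acceleration)
velocity profiles, wheel slip correlated over time, heading bias, or any
perceptual noise. Passing tests therefore show that the stack integrates,
assembles, corrects and decodes *under its own stated conditions*; they do
not certify performance on a physical platform.

## Problem sizes and reproducibility

Every experiment driver is a pure function of its configuration and seeds.
The shipped studies use desk-scale sizes chosen to keep a full run in
minutes on one core: formation over 20 seeds; calibration on a 120 s roam;
decoding studies with 50² and 100² cells per module and 200 trials;
the boundary comparison at 1000 s × 10 seeds on reduced 180-cell plates;
the full pipeline at 500 s with three scales and 50² cells per decoded
module (the full-size 5000 s / 200² configuration remains available
through the drivers' arguments and the command-line front end's
`--full-scale` flag). Euler integration uses `dt = tau/5` throughout; all
randomness flows through explicit integer seeds.

## Known limitations

* Positions are decodable only within the coarsest period's unit cell;
  environments larger than the coarsest grid period, or without walls,
  leave the readout ambiguous and the drift uncorrected.
* The boundary correction floor is set by region size and by drift accrued
  before a region is first learned; references are frozen at first visit
  (an optional update mode can overwrite them).
* Stripe plates are rate-based with constructed (non-plastic) weights; the
  head-direction stage is feedforward.
* The linear velocity response holds within the calibrated speed range;
  speeds far outside (0, 0.5) m/s leave the response plateau.
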