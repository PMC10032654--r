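---
title: "Models and methods behind thrustwake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thrustwake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrustwake)
```

`thrustwake` analyses how fish swim in the thrust wake of a flapping foil:
the foil's motion program and nondimensional numbers, the fish's midline
kinematics, planar pressure fields reconstructed from velocity data, and
the statistical comparisons between free-stream and thrust-wake swimming.
This vignette explains the models, the tunable parameters, the numerical
choices, and — importantly — what the synthetic data generators do and do
not emulate, hence what a passing test suite does and does not establish
about laboratory data.

## The foil model

The foil is actuated in two degrees of freedom,

$$y_\text{sway}(t) = a_\text{sway}\sin(2\pi f t), \qquad
  \varphi_\text{yaw}(t) = a_\text{yaw}\sin(2\pi f t - \pi/2),$$

with the quarter-period offset placing maximal yaw at the sway zero
crossing. The trailing edge sits a lever arm $r_\text{te}$ behind the
rotation center, so its lateral position is
$y_\text{te}(t) = y_\text{sway}(t) - r_\text{te}\sin\varphi_\text{yaw}(t)$
under the sign convention that positive yaw deflects the trailing edge
toward $-y$; with that convention the two motions add constructively and the
default program ($a_\text{sway} = 1$ cm, $a_\text{yaw} = 20^\circ$,
$r_\text{te} = 48$ mm, $f = 2$ Hz) produces a peak-to-peak excursion of
3.86 cm — 4 cm to the nearest centimetre. Exact trigonometric kinematics are
used rather than a small-angle linearisation, which at $20^\circ$ of yaw
would already err by about 2%. The section outline is the standard symmetric
four-digit thickness polynomial at 12% of chord, in its closed-trailing-edge
variant (last coefficient $-0.1036$); the analytic 12% of a 67 mm chord is
8.04 mm, about 1% below the 8.1 mm sometimes quoted for printed hardware,
and the analytic definition is used throughout.

Dimensionless numbers follow their definitions: $St = A f/U$ with $A$ a
peak-to-peak amplitude, and $Re = U L / \nu$ with the chord for the foil and
the body length for fish.

## Synthetic swimmers

`simulate_swimmer()` emulates 9-point, 125-frames-per-second ventral-video
digitisation of an undulating fish. The lateral displacement is a traveling
wave

$$y(s, t) = A(s)\,\sin(2\pi f t - 2\pi s/\lambda + \varphi_0),
  \qquad A(s) = a_\text{head} + (a_\text{tail} - a_\text{head})\,s^q,$$

with arclength fraction $s \in [0, 1]$ and $\lambda$ in body lengths. The
body is inextensible: the axial coordinate is integrated from
$dx = \sqrt{ds^2 - dy^2}$, which requires the wave slope to stay below one —
a 10% BL tail amplitude is therefore admissible at $\lambda \gtrsim 0.8$ BL
but not at $\lambda = 0.5$ BL, where the generator refuses the spec rather
than silently stretching the body. Defaults model the study conditions: a
0.19 m trout beating at 2 Hz with a quadratic, tail-growing envelope
($q = 2$, a common carangiform emulation) and tail amplitude 10% BL.
Tracking noise is i.i.d. Gaussian per marker and coordinate; temporal
correlation of digitisation error is not modelled. All randomness flows
through the spec's seed.

Two features of real data are deliberately absent: the swimmer does not
interact with the flow (kinematics are prescribed, not forced), and the
midline is exactly planar. Passing recovery tests therefore validates the
*estimators*, not the biology.

### Wake-locked followers

`simulate_inline_follower()` places swimmers on the wake centerline at gap
distances $d$, beating at the shedding frequency $U_c/\lambda_w$ with wave
phase $\varphi_0 = \text{const} - 2\pi d/\lambda_w$. The sign is chosen so
each follower is *delayed* by the vortex transit time $d/U_c$, which makes
the measured foil-to-fish phase difference grow linearly in $d$ with slope
$+2\pi/\lambda_w$ — the direction in which phase difference increases with
distance behind a flapping foil. (With the opposite sign the delay would
shrink with distance, contradicting that behaviour.)

## Synthetic wakes

`simulate_wake()` builds a kinematic vortex street from Lamb–Oseen vortices,

$$v_\theta(r) = \frac{\Gamma}{2\pi r}\left(1 - e^{-r^2/r_c^2}\right),$$

in two staggered rows at $y = \pm b/2$, spaced $\lambda_w$ within each row
and advected at $U_c$. With `street_sign = +1` the upper row rotates
counter-clockwise and the lower clockwise, which superposes a centerline
jet: the reverse (thrust-wake) arrangement. Flipping the sign yields the
classical drag-wake street with a centerline deficit; the excess and deficit
are exactly mirror images, which the tests exploit. Vortex positions wrap
modulo $\lambda_w$, so the street is statistically stationary and exactly
periodic with the shedding period $\lambda_w/U_c$ — pressure analysis can
therefore average over an integer number of periods.

Defaults emulate the foil wake: $U_\infty = 0.3$ m/s, shedding at 2 Hz with
$U_c = 1.1\,U_\infty$ (the advection speed of a foil wake is not a measured
constant of the study; 10% above free stream is a typical thrust-wake value
and is the package's fixed choice), hence $\lambda_w = U_c/f = 0.165$ m; row
spacing $b = 4$ cm matching the trailing-edge excursion; core radius 1 cm on
a 2.5 mm grid (the generator enforces at least four cells per core radius).
$\Gamma = 0.008\ \text{m}^2/\text{s}$ gives a centerline excess of roughly
15% of $U_\infty$, a moderate, realistic jet. The model is kinematic, not a
Navier–Stokes solution: cores do not diffuse, vortices do not deform, and a
body placed in the wake does not alter the velocity field (its mask only
blocks pressure-integration paths). Three-dimensional effects are out of
scope.

`analytic_flow()` supplies steady oracle flows with closed-form pressure
structure — uniform flow, solid-body rotation ($\Delta p = \rho\Omega^2
r^2/2$) and a steady Lamb–Oseen vortex ($dp/dr = \rho v_\theta^2/r$) — used
to validate the pressure chain end to end.

## Midline kinematics

**Resampling.** Digitised markers are interpolated per keyframe (default
every sixth frame, matching the digitisation protocol) with cubic splines
parameterised by cumulative chord length and resampled at equal-arclength
stations; intermediate frames are filled by linear interpolation of station
coordinates. Two numerical choices matter. First, the spline uses the
forward-difference ("fmm") end condition rather than natural boundary
conditions: forcing zero curvature at the snout and tail corrupts the phase
of the outermost joint angles and was measured (on a nine-marker sine wave)
to bias the overall phase lag by several percent on its own. Second,
`smooth = TRUE` replaces each keyframe's markers by generalised
cross-validated smoothing-spline fits before resampling. This is the
standard treatment for tracking noise and has a specific statistical
justification here: adjacent joint angles share midline stations with
opposite signs, so white marker noise is *negatively correlated* between
neighbouring joints; that correlation repels the cross-correlation peak
from zero lag and systematically inflates phase lags (about +7% at 1 mm
noise in development measurements). GCV smoothing removes the effect at its
source and degenerates gracefully to near-interpolation on noiseless input;
it is nonetheless off by default so that the resampler is strictly
interpolating unless asked otherwise.

**Tail-beat frequency** is the reciprocal mean period between positive
maxima of the heading-removed lateral tail-tip displacement over the final
three complete cycles (their placement within the trial is a free choice;
the end of the trial is used). Peaks require a prominence of at least 10% of
the signal half-range and are refined to sub-frame precision by a local
parabola. Because tracking noise is broadband while the beat is narrowband,
the series is first passed through a zero-phase moving average of about an
eighth of the dominant period (found from the discrete spectrum); symmetric
filters do not shift peak times.

**Joint angles and phase lags.** Each frame's midline is divided into
$N = 20$ equal-arclength segments; the signed angles between consecutive
segments form $N - 1$ joint signals. For each adjacent pair the delay at
the maximum of the circular cross-correlation — computed over an integer
number of cycles, restricted to $[0, T/2)$, ties resolved toward the
smallest lag, and refined by quadratic interpolation — is converted to a
phase $\Delta\varphi_i = 2\pi\,\text{lag}/T$. The signals are band-passed
around the beat frequency ($[0.25/T,\ 1.75/T]$, zero-phase FFT filter)
first; over an integer cycle count this leaves the wave untouched and
suppresses broadband noise. $T$ is estimated once per trial from the tail
beat, not per joint pair.

The overall lag is the sum along the body. With $N$ segments there are only
$N - 2$ adjacent-joint lags, spanning $(N-2)/N$ of the body; summing them
alone underestimates a uniform wave's full-body lag by exactly $2/N$ (10% at
$N = 20$). The default `method = "extrapolate"` therefore pads *both* body
ends with the mean adjacent lag — equivalent to $N \times$ the mean — which
recovers a uniform traveling wave exactly; `method = "measured"` returns the
bare sum for users who prefer the uncorrected quantity. The wavelength
follows as $\lambda = 2\pi/\Delta\Phi$ body lengths, with
$\lambda \cdot \Delta\Phi = 2\pi$ holding identically and
$\lambda = \infty$ for a standing wave ($\Delta\Phi = 0$).

One genuine subtlety deserves emphasis: with a tail-growing amplitude
envelope the *true* phase gradient of the joint-angle wave is not
$2\pi/\lambda$. Differentiating $A(s)\sin(\omega t - ks)$ along the body
mixes $A'(s)$ into the phase, shifting it by
$\arctan\!\big(2A'k/(Ak^2 - A'')\big)$-type terms that vary along the body;
at the default quadratic envelope this amounts to roughly 3% of the total.
The pipeline *measures the modified gradient correctly* — a dedicated test
documents the effect size — so recovery of exactly $2\pi/\lambda$ is only
the right expectation for a uniform envelope, and the package's validation
sweeps use one. Real fish have envelopes; reported wavelengths from
joint-angle phase lags carry this (small) systematic wherever envelopes
grow along the body, in any implementation of the procedure.

**Validation conditions.** The recovery sweeps run at 33 markers with
keyframe stride 1. Nine markers are exactly what the digitisation protocol
provides, but at $\lambda = 0.5$ BL they sample the spatial wave at four
points per wavelength — below what spline interpolation can faithfully
reconstruct (per-joint lag wobble of order the lag itself) — and stride-6
temporal interpolation leaves only about seven keyframes per cycle for a
3 Hz beat. The estimator sweep therefore uses sampling adequate to the
wave, and a separate test records the fidelity of the nine-marker pipeline
at the study's actual conditions (2 Hz, $\lambda \approx 1$ BL), where the
digitisation bias is a few percent.

**Amplitude envelope.** Forward and lateral axes are the principal
components of the pooled midline point cloud; the amplitude at a station is
half the range of its lateral projection over the trial. Axis signs follow
a fixed laboratory-frame convention (positive $y$ component, ties toward
positive $x$): a per-trial convention tied to the wave phase would flip the
lateral axis between trials and shift cross-trial phase comparisons by half
a cycle.

**Phase difference and distance.** The foil and fish trailing-edge series
are resampled onto the coarser of the two time bases over their shared
window (at least three cycles required), circularly cross-correlated, and
the delay expressed as a phase in $[0, 2\pi)$. Across a set of followers the
phases are unwrapped assuming the increment between neighbouring distances
is below one cycle — guaranteed when distance spacing is below
$\lambda_w$. Gap distance is the Euclidean distance between mean foil
trailing-edge and mean snout positions.

## Pressure reconstruction

The pressure gradient on fluid nodes comes from the Eulerian momentum
balance $\nabla p = -\rho\,(\partial_t \mathbf u + (\mathbf u\cdot\nabla)
\mathbf u) + \mu \nabla^2 \mathbf u$, with forward or central time
differencing over the frame interval and central spatial differences
(one-sided at domain boundaries and beside masked nodes). The viscous term
defaults off: at the Reynolds numbers of foil and fish wakes
($2\times10^4$–$5\times10^4$) its contribution is negligible, and the flag
exists for completeness. A pseudo-Lagrangian formulation was deliberately
not used — the Eulerian form needs only two or three frames, has a simple
contract, and is validated against analytic oracles.

Integration polls **eight families of straight paths** along the principal
grid directions (E, W, N, S and the four diagonals; diagonal steps use the
cell diagonal, trapezoidal accumulation throughout). Each family is one
*globally consistent sweep*: a seed edge is integrated from a single anchor
corner at $p = 0$, then every line marches across the domain in the family
direction. This construction is the package's key design choice. If instead
every path started independently at $p = 0$ on the boundary, the eight
candidates at a node would disagree by the (unknown) true pressure
differences between their boundary entry points — for a rotation-dominated
oracle flow that inconsistency reaches tens of percent of the field range
and cannot be polled away. With family-consistent sweeps each family
reproduces node-to-node pressure differences *exactly* for a conservative
gradient field; the median across families then preserves that exactness
while retaining robustness: corrupting a single family moves the median far
less than it moves a mean (a regression test verifies both properties).
Pressures are relative; the field is gauged to zero mean over the defined
boundary nodes, where the method assumes its reference.

Masks block paths: beyond a solid node a family's candidate is discarded.
Nodes losing all eight families are flagged undefined and filled from the
nearest defined fluid node (Euclidean distance, ties by row-major order);
solid nodes are never assigned pressures, so surface pressures are read
from adjacent fluid nodes. The mean **head pressure** is taken over a box
extending 10% of the body length backward from the snout and the body
width laterally, over defined fluid nodes only; multiplied by a frontal
area it estimates the pressure drag $F = p\,S$.

Because the synthetic wake imposes no body boundary condition, a static
mask in the simulated street measures the street's own pressure field
around the head: strong suction as cores pass, weak positive pressure at
the inter-vortex saddles (of order $\tfrac{\rho}{2}(U_c - U_\infty)^2$,
i.e. sub-pascal at the defaults). The sign of the head-pressure series
therefore alternates within each shedding period with asymmetric
magnitudes, while the same body in uniform flow yields an identically zero
series — the qualitative dichotomy the tests assert. A real fish adds
stagnation pressure and flow displacement that this kinematic model cannot
produce.

## Statistics

`welch_t()` wraps the unequal-variance t-test with Satterthwaite degrees of
freedom; the direction of a one-sided test is always an explicit argument.
Because the experimental design pairs individuals across conditions while
the Welch test assumes independent samples, `condition_report()` reports
both the Welch p-value (the analysis as specified) and a classical paired
t-test alongside. No multiple-testing correction is applied. Percent change
is reported relative to the reference (free-stream) condition, so a
decrease is positive. Summaries are computed on per-individual means;
pooling trials within individuals first is an assumption the report makes
explicit rather than hides. `linear_fit()` is ordinary least squares with
$R^2 = 1 - SS_\text{res}/SS_\text{tot}$ (defined as 0 when the response is
constant).

## Degenerate inputs and tie-breaks

Empty series, constant tracks, zero-variance angle signals, single-frame
sequences, fully masked grids, constant regressors and sub-two-point
samples all raise informative errors rather than returning numbers.
Correlation ties resolve to the smallest lag; nearest-neighbour fills break
ties in row-major order; the lateral-axis sign convention is fixed as
described above. Problem sizes used in the shipped tests — five-cycle
trials at 125 fps, $101\times101$ oracle grids, one-to-two shedding
periods of a $161\times81$ wake — were chosen as the smallest sizes at
which the statistical and numerical claims are comfortably resolved.

## Known limitations

- The wake is kinematic; no feedback between body and flow, no core
  diffusion, no three-dimensional effects.
- Swimmer kinematics are prescribed; energetics and forces on the fish are
  out of scope (only the head-pressure proxy for pressure drag is
  computed).
- Phase-lag wavelengths inherit the envelope-induced gradient shift
  discussed above; for strongly tapered envelopes the reported
  $\lambda$ is a property of the joint-angle wave, not of the midline
  displacement wave.
- The eight-family integrator assumes a usable $p \approx$ constant
  reference somewhere on the boundary; in fields whose boundary cuts
  through energetic structures (as the left/right edges of a vortex street
  do) the gauge and the median both degrade gracefully but measurably.
- Raw particle-image correlation, manual digitisation tooling, and reading
  vendor PIV formats are out of scope; velocity fields arrive as CSV frames
  plus a JSON sidecar, midlines as tidy CSV tables.
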