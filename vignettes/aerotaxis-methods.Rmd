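---
title: "Models and methods in choanotaxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in choanotaxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choanotaxis)
```

`choanotaxis` models how swimming microorganisms — the motivating system is
colonies of the choanoflagellate *Salpingoeca rosetta* — navigate oxygen
gradients in a PDMS microfluidic device, and provides everything needed to
exercise that analysis without microscopy data: a device-scale oxygen
solver, a population (Keller–Segel) solver with pluggable sensing laws,
single-swimmer navigation models with their analytic steady states, the
trajectory statistics that connect the two scales, a minimal tracker, and a
synthetic-data generator with known ground truth.

## 1. Oxygen transport in the device

The device cross-section is a PDMS slab bonded between glass slides, with a
water-filled observation chamber flanked symmetrically by two gas channels
of the same etched thickness (115 µm nominal). Oxygen obeys the diffusion
equation $\partial c/\partial t = \nabla\cdot(D_c\nabla c)$ with
$D_c = 3.55\times10^{-3}\,\mathrm{mm^2/s}$ in PDMS and
$2.10\times10^{-3}\,\mathrm{mm^2/s}$ in water. Channels perfused with air
impose $c = 20\%$ on their boundary, nitrogen imposes $c = 0$, and all
glass interfaces are no-flux. Concentration is carried in percent oxygen
throughout; lengths in µm.

Numerics: cell-centered finite volumes with harmonic-mean face
diffusivities (flux-continuous across the PDMS/water interface) and
backward-Euler time stepping; the resulting M-matrix system is factorised
once (sparse Cholesky) and reused every step, so a 90-minute default-device
run takes seconds. The discrete maximum principle keeps $c$ inside the
envelope of boundary and initial values, which the tests check directly.

The exact lateral footprint of such devices is not critical and is exposed
in configuration. The defaults — chamber 1000 µm wide, gas channels
1000 µm wide at a 500 µm PDMS gap, 500 µm outer margins, slab 575 µm
high — were fixed once as a plausible device of this type; the
residual-oxygen check (max chamber oxygen after 90 min of nitrogen/nitrogen
staying below 0.2%) is geometry-sensitive, and with these defaults the
drain time constant is a few minutes so the residual is far below that
bound. Solver correctness is instead anchored by an exact oracle: when the
channels span the full slab height the problem is one-dimensional, and the
steady profile must match the closed-form two-layer resistance solution
(`steady_two_layer_profile()`), which it does to discretisation accuracy.

## 2. Population dynamics and sensing laws

Colony density $\rho(y, t)$ along the gradient axis follows
$$\partial_t \rho = D\,\partial_y^2\rho - \partial_y(V[c]\,\rho),$$
with no-flux walls (zero *total* flux, so populations pile up against
chamber edges as observed in experiments). The response functional $V[c]$
encodes the sensing law:

* `tanh_abs` / `tanh_linear`: $V = v_\mathrm{drift}\tanh(\alpha c_y)$ —
  absolute-gradient sensing, linear for small gradients, saturating at
  $v_\mathrm{drift}$ (the two labels coincide in 1D; both are kept so fits
  under either name can be compared). $\alpha$ has units µm/%.
* `tanh_log`: $V = v_\mathrm{drift}\tanh(\alpha\, c_y/c)$ —
  relative-gradient (Weber-law, "logarithmic") sensing; $\alpha$ in µm.
  The division by $c$ is floored at `c_min` (default $10^{-3}$ %), an
  explicit modelling knob: no organism can sense relative gradients at
  arbitrarily low absolute concentration, and the floor is what keeps the
  functional defined when a nitrogen-only protocol drives $c \to 0$.
* `linear` ($V = \beta c_y$) and `constant` complete the set for
  reference.

The two sensing laws differ observably: absolute-gradient sensing cannot
produce a persistent mid-chamber density band under nitrogen in both
channels (gradients are tiny there), while relative sensing can, because
$c_y/c$ stays order-one as both decay. The model-selection test in the
acceptance suite rests on exactly this feature.

Numerics: implicit backward-Euler with first-order upwind advection.
Upwinding was chosen for positivity (the update matrix is an M-matrix, so
$\rho \ge 0$ without clamping) at the cost of some numerical diffusion
($\sim V \Delta y/2$, well below $D$ at the default resolutions); mass is
conserved to machine precision by construction. Drift fields are computed
at cell faces from the stored concentration frames and interpolated
linearly in time. Although the implicit scheme is unconditionally stable,
`solve_ks()` refuses advective Courant numbers above a documented cap
because accuracy (not stability) degrades.

Fitting (`fit_ks()`) is bounded multi-start least squares on the per-frame
normalized kymograph — the normalization matches how experimental densities
are reported, and makes the objective insensitive to colony count. The
objective (space–time sum of squares, L-BFGS-B, log-dispersed starts) is a
package choice: nothing in the source material pins the norm or optimizer.
With a protocol that includes saturated, linear, and nitrogen-only regimes,
$(D, \alpha, v_\mathrm{drift})$ are jointly identifiable; parameter
recovery within 15% from 5%-noise synthetic kymographs is part of the
acceptance suite.

Useful identities: with ensemble swimming speed $v$, the colony diffusion
constant maps to an effective rotational diffusion $D_r = v^2/2D$
(0.16 s$^{-1}$ at $v = 16.5$ µm/s, $D = 865$ µm²/s), and for an exponential
concentration profile $c \propto e^{ky}$ the log-sensing drift is constant,
$V = v_\mathrm{drift}\tanh(\alpha k)$, giving the closed-form steady state
$\rho \propto e^{Vy/D}$ used as a solver oracle.

## 3. Navigation strategies

Individual swimmers move at fixed speed $v$ with heading $\theta$
($\pi/2$ = up-gradient):

* deterministic steering:
  $d\theta = \epsilon_d\cos\theta\,dt + \sqrt{2d_r}\,dW$;
* stochastic (rotational-diffusion modulation, a continuous run-and-tumble):
  $d\theta = \sqrt{2d_r(1 - \epsilon_s\sin\theta)}\,dW$, multiplicative
  noise in the Itō sense, $|\epsilon_s| \le 1$.

Both are integrated by Euler–Maruyama (default $dt = 10^{-3}$ s, mandatory
seed, inner loop in C++). The stationary heading distributions are

$$p_d(\theta) = \frac{e^{\kappa\sin\theta}}{2\pi I_0(\kappa)},\qquad
  \kappa = \epsilon_d/d_r = 2k_d,\qquad
  p_s(\theta) = \frac{\sqrt{1-\epsilon_s^2}}{2\pi(1-\epsilon_s\sin\theta)}.$$

A note on $\kappa$: the zero-flux stationary solution of the steering
Fokker–Planck equation has von Mises concentration $\epsilon_d/d_r$; a
common single-parameter form writes the model in terms of
$k_d = \epsilon_d/2d_r$, and some sources print the concentration itself
as $k_d$. Long-run simulation settles the factor unambiguously (the suite
checks Kolmogorov–Smirnov distance $< 0.01$ against $p_d$ at
$\epsilon_d = 0.28$, $d_r = 0.52$), so the package uses
$\kappa = \epsilon_d/d_r$ while retaining $k_d$ as the fitted parameter
name.

The stochastic strategy's stationary drift is
$v_\mathrm{drift} = v\langle\sin\theta\rangle =
v\left[1/\epsilon_s - \sqrt{1/\epsilon_s^2 - 1}\right]$, $\approx 0.3v$ at
$\epsilon_s = 0.55$. The converse bound is the speed-modulation argument:
if taxis were achieved by swimming faster up-gradient,
$v(\hat p) = v(1 + \gamma\,\hat p\cdot\nabla c/|\nabla c|)$ with isotropic
headings gives drift $v\gamma/2$ (2D) or $v\gamma/3$ (3D), so a drift of
$v/3$ would need $\gamma = 2/3$ or $1$ — two orders of magnitude beyond
the percent-level speed modulation the trajectory statistics allow.

### Turn angles

Over a short lag $\Delta t$, the turn angle is defined as the decrease in
angular distance to the attractant,
$\Delta\phi = |\theta(t) - \pi/2| - |\theta(t+\Delta t) - \pi/2|$
(distances measured on the circle), positive for gradient-ward turns.
Assuming a uniform pre-swap heading, the deterministic family gives
$\Delta\phi = |\delta| + \xi$ with $\delta = \epsilon_d\cos\theta\,\Delta t$
(arcsine-distributed) and $\xi \sim N(0, 2d_r\Delta t)$; the density is a
convolution integral evaluated by 64-node Gauss–Legendre quadrature after
the substitution $\delta = \epsilon_d\Delta t\sin u$, which removes the
inverse-square-root endpoint singularity. The stochastic family
marginalizes $N(0, 2d_r(1-\epsilon_s\sin\theta)\Delta t)$ over uniform
$\theta$ — symmetric, mean exactly zero. This is the discriminating
statistic: steering shifts the turn-angle mean positive, modulated
diffusion does not.

Two caveats the tests respect. First, these densities describe the
*short-interval construction*, not full trajectories: on real (or
simulated) paths the angular distance folds at $0$ and $\pi$, which the
construction ignores; at the reported parameters and $\Delta t = 0.65$ s
the folding biases a $d_r$ fit on full-trajectory turn angles low by
roughly 15–25%. Parameter-recovery tests therefore draw turn-angle
ensembles from the construction itself, and model discrimination is run on
such ensembles so the data genuinely belong to the stochastic family.
Second, fits are single-parameter by design: the steady-state fit pins
$k_d$ or $\epsilon_s$, and the turn-angle fit then determines $d_r$ (for
the steering family under the constraint $\epsilon_d = 2k_d d_r$), by
maximum likelihood on unbinned samples — the estimator is a package
choice; a histogram $\chi^2$ is reported alongside for figure-style
comparison.

## 4. Trajectory statistics

Density profiles use a Gaussian kernel with a boundary correction: the
kernel mass is divided by the fraction of a kernel centred at the
evaluation point that falls inside the chamber (closed form via the normal
CDF), then normalized to a probability density. The bandwidth
$\sigma = 25$ µm (a few colony diameters) is a fixed package default — the
analysis conclusions do not hinge on it, and the tests use closed-form
single-point profiles (truncated Gaussian in the interior; a
$\log 2$-normalized half-kernel at a wall) as oracles.

Velocities are one-frame central differences, ensemble-averaged per frame,
optionally smoothed by a centred moving average (default 30 s — smoothing
is expected when these curves are plotted, and the window is a documented
choice). Headings come from one-frame displacement directions; when the
gradient points down, $\theta \to -\theta$ is applied before pooling so
$\pi/2$ always means up-gradient. Swap windows (when alignment statistics
are meaningful) are supplied by the caller, not auto-detected, and an
optional y-band filter excludes wall-adjacent samples — near a wall,
specular reflections symmetrize headings and the transit-time statistics
no longer apply. Finite-frame displacement estimation slightly blurs the
heading distribution relative to the instantaneous one, so pipeline-level
distribution checks carry a looser threshold (KS $< 0.08$) than
simulator-level ones.

## 5. Tracking

The tracker follows the standard recipe for bright-field colony videos:
per-pixel temporal running median (~2.5 s window, truncated — not
shrunken — at the stack ends) as background; subtraction; band-pass
(difference of Gaussians, defaults 2 px / 20 px); Gaussian smoothing
(2 px); strict local maxima above 3 robust (MAD) noise SDs; sub-pixel
refinement by a parabolic fit to log intensity (exact for Gaussian spots);
greedy nearest-neighbour linking with a per-frame displacement cap, a
3-frame gap memory, and removal of tracks shorter than 3 detections. Filter
scales and thresholds are configuration-level because the original optics
are not fixed by the analysis.

Known limitations, demonstrated in the tests: blobs closer than about the
detection scale merge into one detection; and when motion is well below a
pixel per frame the moving object contaminates the running-median
background and localization degrades — at a realistic scale
(~1 µm/px, ~1.6 px/frame at 16.5 µm/s and 10 fps) the end-to-end
round-trip recovers over 95% of planted positions within 1 px at SNR ≥ 5.

## 6. The synthetic-data generator

`generate_tracks()` couples the stochastic navigation model to a solved
oxygen field: the local bias is obtained by inverting the stationary drift
relation, $\epsilon(y, t) = 2v\tilde v/(v^2 + \tilde v^2)$ with
$\tilde v = |V[c]|$, signed by the gradient direction — chosen because this
is exactly the stated algebraic relation between bias, swimming speed and
drift speed, making the generator self-consistent with the analytic drift
formula (a constant-plateau scenario must and does drift at $\tilde v$).
Walls reflect positions and headings specularly (the source analysis is
silent on wall interactions; specular reflection is the simplest choice
that keeps swimmers in the chamber), and motion is quasi-2D.

Defaults emulate the experimental conditions: ~150 colonies, speed
16.5 µm/s, rotational diffusion 0.33 s$^{-1}$, 10 fps, position jitter
0.5 µm (sub-pixel centroid accuracy at ~1 µm/px), detection dropout 5% per
frame (gaps are almost always ≤ 3 frames, i.e. bridgeable). Seeds are
mandatory and identical seeds give bit-identical output.

What the generator does *not* emulate — so green tests do not establish —
includes: helical swimming (headings are planar; real colonies swim noisy
helices and only ensemble statistics are comparable), colony-to-colony
parameter variability, oxygen consumption by the population, in/out flux
of colonies through the chamber ends (number variation is emulated only by
dropout), and photorealistic imaging. At population steady state the
heading distribution near walls is symmetrized by reflections, so
generator-level distribution checks pool transit windows in the chamber
interior — the same restriction an experimentalist applies by analysing
post-swap windows.

## 7. Acceptance surface

The experimental kymographs, velocity curves and angle histograms cannot be
regenerated without the raw videos, so the acceptance suite checks (i) the
closed-form quantities (drift ratio 0.3 at $\epsilon_s = 0.55$;
$v^2/2D = 0.16\,\mathrm{s^{-1}}$; $\gamma = 2/3$ and $1$), (ii) the
device-simulation residual-oxygen bound, (iii) internal equivalences
(simulators vs Fokker–Planck steady states; quadrature densities vs
Monte-Carlo oracles), and (iv) recovery and model-selection properties on
synthetic data at the reported parameter values — including that
log-sensing beats absolute-gradient sensing on data containing a
nitrogen-only segment, and that the stochastic turn-angle model beats the
constrained deterministic one. Every number in those tests is computed at
run time by the package itself.
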