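---
title: "Methods: microwheel rolling physics, swarm transport and network targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microwheel rolling physics, swarm transport and network targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(uwheel)
```

# The physical model and its assumptions

A microwheel is a disc-like cluster of `n` superparamagnetic beads (radius
`a`) spinning about a near-horizontal axis under a rotating magnetic field
and rolling along a surface. The package's single-wheel model rests on four
assumptions:

1. **Torque balance for rotation.** The magnetic torque on the cluster,
   `n * nu * mu0 * chi'' * H^2`, balances the rotational drag of a disk,
   `32 * eta * omega * R^3 / 3`. With the bead-count law `n = (R/a)^2`
   this yields `omega = c / R`: bigger wheels spin more slowly, so the rim
   speed `omega * R` is size-independent.
2. **Electrostatically supported lubrication gap.** The wheel never touches
   the wall; the normal load `W_y = m g n cos(phi)` is carried by screened
   double-layer repulsion, giving the closed-form gap
   `delta = k1 * kappa^-1 * ln(F0 / W_y)` with
   `F0 = 4 pi eps eps0 a kappa zeta1 zeta2`. When `W_y >= F0` no gap can
   support the load and the package raises a distinct "pinned" error rather
   than returning a non-physical gap.
3. **Wet friction.** Traction comes from shearing the gap fluid with a
   linear velocity profile across `delta`; equating frictional and shear
   torques over a contact area `A ~ R a` gives
   `mu_k = eta a R (omega R - V) / (delta W_y)`. The load printed in the
   friction-coefficient expression is read as the normal component `W_y`
   (the only normal load defined in the model); note it cancels in
   `F_f = mu_k W_y`.
4. **Cylinder drag with a shape factor.** Translational drag uses the
   analytic near-wall cylinder solution scaled by `k2` for the bumpy
   bead-built surface.

The propulsion balance `F_f - F_d - W_x = 0` is linear in `V` and solved in
closed form. `V` is signed and never clamped: on steep inclines large
wheels enter a rolling-while-slipping-backwards regime (`V < 0`), which is
physically meaningful and exercised by the tests. Camber-angle dependence
of the load is deliberately omitted (the camber is small and held fixed),
and there is no hydrodynamic simulation of the film itself — the model is
the printed algebra, nothing more.

Angles are degrees at every interface and radians internally; all internal
quantities are SI, with µm/mT/Hz/mV/nm accepted at config boundaries.

# Parameters: what is measured, what is illustrative

Fitted and printed values shipped as defaults: `a = 2.25 µm`,
`rho_bead = 1600 kg/m^3`, `B = 3.7 mT`, `f = 40 Hz`, camber 30°,
`k1 = 1.50`, `k2 = 3.11`, truncation bounds 4.5 µm (single-bead scale),
20 µm (flipping-mode ceiling) and 60 µm (maximum steady-state size).

Several parameters the formulas need are *not* published: the imaginary
susceptibility `chi''`, the medium permittivity, the Debye length and both
zeta potentials. The shipped values — `kappa^-1 = 20 nm`,
`zeta1 = zeta2 = 60 mV`, `eps_rel = 80`, and a rotation calibration
`c_omega = 1e-4 m rad/s` (equivalently `chi'' = 0.0104` through the torque
route) — are **illustrative**. They were chosen once, before any test was
written, to land the model in the qualitatively documented regimes:

* translation of tens of µm/s on the flat, faster for larger wheels;
* small wheels (~10 µm) still climbing at 80° with a moderate velocity
  drop, while wheels above roughly 30–35 µm slip backwards (`V < 0`);
* gap widths of order 100–250 nm that shrink substantially as load grows.

Consequences: quantitative single-wheel observables (exact velocity-drop
percentages, the 70% gap-width reduction) are reproduced as orderings and
signs, not numbers, and all swarm-level speeds are of the right order but
not calibrated. The two headline experimental numbers of the source
platform (~38% mean targeting efficiency, model–experiment agreement
within ~25%) additionally depend on tracked swarm distributions and a
printed CAD geometry that are not available, so the package does not claim
them; every empirical statement in this vignette is computed by the test
suite or the acceptance script.

The per-bead mass defaults to the buoyancy-corrected
`m = (rho_bead - rho_fluid) * nu` since wheels operate submerged; a
`buoyant = FALSE` flag preserves the literal raw-mass reading. Bead counts
use `n = (R/a)^2` consistently in both the physics and the mass estimates;
the hexagonally-close-packed alternative (`0.9069 (R/a)^2`) is available as
an option wherever mass is derived.

# Swarm modes

Swarm modes are represented as truncated log-normal radius laws plus mode
kinematics; the location/scale defaults (e.g. rolling `lnN(log 20, 0.6)` on
[4.5, 60] µm) are declared illustrative — the source fingerprints are
plots, not tables — but they preserve the ranked spreads: rolling broadest
and largest, flipping smallest (all radii in [4.5, 20] µm), switchback and
corkscrew in between. An optional CSV loader accepts tracked per-wheel
tables for users who have real fingerprints.

Two kinematic choices were genuinely open and are package decisions:

* **Switchback projection.** The model defines only the effective climbing
  angle `phi_eff = asin(sin phi * cos phi_sb)`. Because the zig-zag path is
  longer than its projection, forward progress along the mean heading is
  computed as `V(R, phi_eff) * cos(phi_sb)`.
* **Corkscrew/flipping slowdown.** Described but never parameterized; it is
  exposed as a mode-level `speed_factor` multiplier defaulting to 1.

Wheel–wheel interactions are ignored (they are presumed weak); dispersion
arises from velocity heterogeneity alone, which is sufficient to make the
mass-weighted positional spread grow monotonically in time.

# The targeting simulation

Positions integrate `dx_i/dt = V(R_i, phi_i(x_i))` by Euler's method with
`dt = 0.1 s`. The network is intrinsically one-dimensional: each branch
carries a piecewise-linear incline function over arc length, switching to
the child branch's own function at each turn (continuity at the switch
point is the generator's responsibility and is property-tested). Steering
is open-loop on the centroid: when the mass-weighted mean passes a turn,
wheels within `0.5 sigma` of the turn point survive, wheels within
`0.5 sigma` of an annotated parallel channel are lost to it, everything
else is lost at the turn. After the last turn the swarm is integrated until
the centroid advances 1 mm; remaining alive mass counts as delivered.

Numerical and degenerate-case choices:

* **Window precedence.** A wheel inside both the keep window and a parallel
  window is lost (conservative reading); a `parallel_precedence = FALSE`
  switch inverts this.
* **`sigma = 0`.** A zero-spread swarm is perfectly steered: all wheels
  survive the turn.
* **Injection wall.** Positions are floored at `x = 0`; a slipping swarm
  piles up at the start rather than exiting backwards.
* **Termination.** Besides reaching the target, runs end `timed_out` at
  `max_time = 600 s` (the experimental cap) or `stalled` when no alive
  wheel has moved forward for 10 consecutive steps before the collection
  phase — the all-slip regime needs a finite guarantee the cap alone would
  make slow.
* **Windows symmetric.** The 0.5σ window is applied symmetrically about
  the turn point, as stated; whether losses ahead of the turn should be
  treated differently is unspecified and not second-guessed.

Mass bookkeeping is exact: `efficiency + sum(losses) + residual = 1` to
1e-12 at every termination, and the simulation is deterministic — no step
draws randomness, so a fixed generated swarm yields a bit-identical result.

One documented subtlety: the invariant "tightening `sigma_keep` never
raises efficiency" holds for the keep rule alone, but *not* jointly with
parallel-channel losses, whose windows shrink too (fewer wheels lost to the
parallel mouth can outweigh fewer kept). The property test therefore runs
on the preset with parallel annotations stripped; with annotations present
the combined effect is legitimately non-monotone.

# Synthetic data: what it emulates, what it does not

The generator provides (i) mode swarms as above; (ii) networks — a random
trunk-and-exits tree plus the fixed `"mca6"` preset, a hand-laid
six-terminal tree (~24 mm of arc, inclines −15° to +30°, 0.6 mm channel
diameter) standing in for a middle-cerebral-artery-like geometry whose true
CAD layout is unavailable (the preset is synthetic and labelled as such);
and (iii) 16-bit fluorescence scan pairs: the pre scan holds all signal in
an injection ROI, the post scan redistributes it by delivered fractions
with the remainder in the trunk, pixel values are Poisson-distributed about
their constructed means, and background is drawn strictly below the 3600
threshold so thresholding removes it exactly (a straddling background is
available for robustness testing). A single root seed fans out to per-stage
child seeds.

What a green test therefore establishes: internal consistency of the whole
chain (physics → swarm → network → simulation → scans → quantification) at
known ground truth, to stated tolerances. What it does not establish:
agreement with any laboratory measurement — real fingerprints, real
vascular geometry, flow, wheel–wheel interactions and optical artefacts
(PSF, tile stitching, flat-field) are all outside the generator.

Scans are stored as plain-text PGM (P2, maxval 65535) and ROI masks as
run-length JSON: exact, text-only containers for 16-bit rasters chosen
because no TIFF reader is guaranteed in the R dependency set; the
quantification semantics (threshold at 3600 inclusive-above,
beads-per-count calibration, post-ROI over pre-total division, both scans
thresholded before division) are unchanged by the container.

# Numerical verification strategy

Every closed form is checked against an independent numeric oracle: the
gap width (at `k1 = 1`) against a bracketed root of the raw normal balance
(1e-10 relative); the velocity against a `uniroot` solution of the
propulsion balance on a 20×9 grid over R ∈ [5, 70] µm, φ ∈ [0, 80]°
(1e-8 relative); weighted moments, interpolation and clipping against plain
re-implementations; the Euler integrator against a scalar step-by-step
loop; and `Mn = Pe / lambda` as an algebraic identity (1e-12). The k1/k2
refit (nonlinear least squares in log-parameter space, Nelder–Mead then
BFGS from `(1, 1)`) recovers the generating values from 200 noisy synthetic
points to about 1% — comfortably inside the 5% acceptance band — and is
insensitive to the 2% multiplicative noise seed.

# Known limitations

* Single-wheel quantitative accuracy is limited by the unpublished
  electrostatic/susceptibility parameters; only regimes are claimed.
* No flow advection, no field-waveform synthesis, no
  agglomeration/fragmentation dynamics (the Mason-number groups are
  computed but growth is not simulated), no closed-loop steering.
* The 1-D arc-length abstraction ignores channel cross-section effects;
  `channel_diameter` is informational.
* Efficiency from noisy scans can slightly exceed 1; raw values are
  reported unclamped and only display output rounds them.
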