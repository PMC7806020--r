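---
title: "Methods: Markov predator control, the virtual arena, and coupling detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov predator control, the virtual arena, and coupling detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predbot)
```

## The behavior policy

The robotic replica's behavior is modeled as a discrete-time Markov chain on
a 1 Hz clock. The state space depends on the control mode:

* **Closed loop** — six joint states, behavior × fish proximity, ordered
  St-C, St-F, Sw-C, Sw-F, A-C, A-F. At every second the controller reads the
  fish's position, classifies it as close or far, and draws the replica's
  next behavior from the row of `closed_loop_matrix()` indexed by the
  current (behavior, proximity) pair. The proximity component of the next
  joint state is *not* sampled — it is whatever the fish does next.
* **Open loop** — three behavior states evolving autonomously under
  `open_loop_matrix()`, starting stationary.

The 1 s tick is the only rate consistent with the policy's calibration
(per-second scoring) and with a 20-min schedule containing 1,200 events. No
dwell-time constraint is imposed on any state: the live-predator ethogram
required 4 s of immobility before scoring "stationary", but nothing
indicates the replica's chain was constrained that way, and adding one would
change the stationary occupancies away from the published values.

`stationary_distribution()` solves the linear system pi (P − I) = 0 with
sum(pi) = 1 by QR, rather than taking the eigenvector directly: the linear
route returns a real, nonnegative, normalized vector without complex
arithmetic or sign cleanup. The unit-eigenvalue multiplicity is still
checked first, so reducible or periodic chains (where "the" stationary
vector is not unique) raise an error instead of silently returning one of
many solutions; a test cross-checks the result against the eigendecomposition.

Marginalization to the open-loop chain weights each behavior's C and F rows
by their stationary shares. It reproduces the published three-state matrix
to ±0.002 (the residue is the three-decimal rounding of the published
six-state matrix), and it provably preserves stationarity: the stationary
vector of the marginalized chain equals the behavior-marginal of the joint
chain's stationary vector, which the suite checks to 1e-6.

Proximity uses measure-zero-unambiguous conventions: the 42 cm length is
split into half-open thirds [0, 14), [14, 28), [28, 42] with the third
adjacent to the replica "near"; vertical halves are split at the midline
with the midline itself assigned to the lower half.

## The virtual arena

The simulator replaces the physical platform, cameras, and live fish. It
aims to produce data with the *statistical structure the analysis assumes* —
correct sampling rates, arena geometry, state-conditioned replica motion,
and a switchable robot-to-fish coupling — not to be a behavioral model of
zebrafish making scientific claims.

**Geometry.** Central tank 42 × 30 cm, lateral replica tank 16 cm long,
origin at the bottom corner of the central tank on the replica side (the
replica occupies negative x). Water depth defaults to 15 cm: this is the
only depth reconciling "bottom third of the water column" with a 5 cm
bottom section and with five 3 cm depth bins, and it is configurable because
it is an inference, not a published number.

**Replica motion** (30 Hz, per 1 Hz state): stationary dives at 2 cm/s to a
0.5 cm bottom clearance and freezes; swimming orbits an ellipse with axes
2.35 × 10 cm at nominal axis speeds 1.01 and 1.33 cm/s, the y-speed
perturbed by ±0.1 cm/s with probability 0.1 and the height stepped ±1 cm
with probability 0.2 per swimming second; attacking sweeps along the shared
wall at 3 cm/s (the published account gives the attack path but no speed;
3 cm/s ≈ the orbit speed scale, configurable). Two implementation choices
keep the published statistics observable: after a behavior change the
replica glides linearly to the new program's entry point over one second, so
the 30 Hz trajectory is continuous and an in-progress attack sweep is simply
truncated at the next tick; and the vertical 1 cm step is forced inward at
the water-column boundaries, because a clamped step would silently vanish
there and the realized step rate would fall below the nominal 0.2.

**Synthetic fish.** A bounded correlated random walk: per-frame heading
noise (SD 0.35 rad at 30 Hz), per-frame speed `max(0, N(6, 2))` cm/s
(about two body lengths per second), an Ornstein-Uhlenbeck-like vertical
coordinate relaxing at 0.4 s^-1 toward a preferred height, and reflecting
walls. During habituation the preferred height is 0.25 × depth (novel-tank
bottom-dwelling); during observation it relaxes to mid-column. The coupling
contract: when the replica is visible (observation phase), attacking, and
`gain_vertical > 0`, the preferred height flips to the half opposite the
replica and a vertical drift of `gain_vertical × mean_speed / 2` (3 cm/s at
defaults) pushes the fish there; `gain_horizontal` adds a longitudinal push
out of the replica-side third. The published design needed vertical-only
coupling to be expressible, hence two gains instead of one; defaults are
`gain_vertical = 1`, `gain_horizontal = 0` — an avoidance drift of half the
swim speed, strong enough to be behaviorally unambiguous without pinning
the fish to the surface. With both gains zero the trajectory law is
provably independent of the robot's states (same seed, identical output),
which the suite asserts.

What the generator does **not** emulate: thigmotaxis and wall-following,
freezing bouts and erratic darting, habituation *within* the observation
window, any fish-to-robot influence on the fish side (the fish never
approaches the replica out of curiosity), visual occlusion, or tracking
noise. Passing tests therefore show that the *analysis pipeline* detects
exactly the couplings the generator injects — they are evidence about the
estimator and the platform logic, not about live zebrafish.

## Metrics

All kinematic series are computed on positions smoothed by an 18-frame
(0.6 s) centered moving average; the even window spans [t−9, t+8], and edge
windows shrink to the available samples so series keep their length. A
centered even window necessarily shifts an affine series by half a sample
step — exact interior preservation holds only for odd windows — and the
suite pins down both facts. Velocities are first differences over
Δt = 1/30 s; acceleration differentiates the smoothed velocity; the turn
rate is the angle between consecutive velocities over Δt with the cosine
clamped to [−1, 1], and frames with speed below 1e-6 cm/s emit no sample
(the angle is undefined at zero velocity). Bottom entries are downward
crossings of the bottom-section boundary between consecutive smoothed
samples, with no hysteresis. All averages use the observation window only,
tabulated in three 2-min bins.

## Transfer entropy and the surrogate test

Fish positions are binned at one body length (3 cm) — 14 length bins, 5
depth bins — and down-sampled to 1 Hz by decimation; the robot symbol is the
1 Hz state stream itself. The estimator is the plug-in conditional mutual
information with history length one and no embedding delay (the coarse
binning and 1 Hz rate are chosen to make longer histories unnecessary), in
bits. Zero-count cells contribute zero; no pseudo-counts. The estimate is
nonnegative and bounded by the target's conditional entropy, both tested.

The analysis window defaults to the 6-min observation (360 samples at 1 Hz).
A 10-min window including habituation is supported via the trial's phase
fields, but the default follows the principle that only the phase in which
the fish can see the replica is informative.

Significance: the 16 fish series are re-paired with the 16 robot series by
a uniformly random permutation (identity included), the mean transfer
entropy recomputed, 1,000 times; the observed mean is significant when it
lies strictly above the null's 95% quantile. The strict inequality matters
in one corner: a degenerate null (e.g., identical series, where every
pairing gives the same mean) must not be called significant. Because each
permutation only re-pairs whole series, all source × target pair entropies
are precomputed once and each surrogate mean is a table lookup, making the
1,000 permutations essentially free. Unequal series lengths are truncated
to the shorter member of each pair. For independent ensembles the test's
empirical type-I rate is ~5%, verified by simulation.

One caveat documented rather than hidden: under closed-loop control the
robot's states are a function of the fish's past positions, so even with
zero coupling gain the "ground-truth" transfer entropy from robot to fish
is not exactly zero — the robot state carries within-bin information about
the fish's position. At the study's sample sizes this effect is far below
detection, and the zero-gain configuration tests non-significant on both
axes.

## Problem sizes and reproducibility

The packaged study runs 16 trials per condition of 960 s each (sampled at
30 Hz), matching the published design; the test suite exercises the same
code at these sizes where the property demands it (e.g., 16-trial coupling
detection, 1e5-sample estimator calibration, 2e5-step chain recovery, 5e5
step occupancy) and at small closed-form sizes everywhere else. Every trial
carries a single integer seed recorded in its record; a study derives all
trial seeds from one base seed, and identical configuration yields
byte-identical output. Two sampling-length choices deliberately exceed the
minimum that first comes to mind: chain-recovery and occupancy checks use
2e5 and 5e5 steps because the chains' strong diagonal (persistence ~0.95)
inflates the variance of occupancy estimates by an integrated
autocorrelation time of roughly 20-40 ticks, and shorter runs would make a
correct implementation fail such checks with non-negligible probability.

## Known limitations

* The realized closed-loop joint sequence does not — and cannot — reproduce
  the full six-state matrix when re-calibrated: the proximity columns are
  fish-driven. Only the behavior-destination marginals of each visited row
  are controller-determined, and those are what the suite verifies.
* The synthetic fish is a statistical stand-in; effect sizes of metric
  differences between conditions are properties of the generator's gains,
  not predictions about animals.
* The replica's heading (its fourth degree of freedom on the physical
  platform) is not simulated; no analyzed quantity depends on it.
* Attack kinematics use a configurable default speed; published kinematic
  values measured on live animals are out of scope and not reproduced.
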