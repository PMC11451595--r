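---
title: "Knock-on permeation: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knock-on permeation: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvperm)
```

## The geometric pore model

All analyses are phrased in a frame of reference derived from named anchor
atoms, never from a general pore-finding algorithm. The axis runs through
the centroids of the four Y376:Cβ atoms (top) and the four V409:Cβ atoms
(bottom), oriented so the extracellular side is positive; the origin is the
midpoint of the two centroids. Five reference planes — the backbone carbonyl
oxygens of Y376, G375, V374 and T373 plus the T373 side-chain hydroxyl —
are each reduced to the mean projection of their four oxygens onto the axis.
The K⁺ sites are then:

* **S1–S4**: the intervals between consecutive planes;
* **S0**: from the Y376:O plane up to one mean inter-plane spacing above it
  (no experimental ceiling exists for S0; one spacing is the natural scale);
* **EXT** above the S0 ceiling, **CYTO** below the gate region.

Two conventions are fixed once and documented here:

* **Boundary tie-break.** A position exactly on a plane belongs to the site
  on its intracellular side (intervals are half-open, `(lo, hi]`). The
  choice is arbitrary; what matters is that it is deterministic.
* **S_cav placement.** The S_cav center is placed midway between the
  T373:OG1 plane and the midpoint of that plane and the gate (P408:Cα); the
  S_cav region extends 2 Å axially and 3 Å radially from it. No numerical
  definition of S_cav exists in the structural literature for this channel;
  the choice puts S_cav in the upper half of the cavity, directly under the
  filter, which is where a loading ion must sit to trigger the knock-on.
  Likewise, the TEA blocked site is described only as "about 1.5 Å" from
  S_cav; we place it 1.5 Å on the *intracellular* side, since TEA arrives
  through the gate and blocks loading from below.

Everything derived from the model (axial/radial coordinates, site labels) is
invariant under rigid motions applied jointly to scaffold and coordinates;
the in-plane basis for 2D histograms is anchored to subunit A's gate marker
so that azimuths are also rigid-motion covariant.

## The synthetic knock-on automaton

The generator is a continuous-time Markov chain over pore compartments
(Gillespie algorithm, exponential waiting times, mandatory seed). It is
*not* Brownian dynamics: the analyses only consume site-resolved statistics,
and a spatial model would add parameters that nothing in the package could
constrain. The resting state is a 3-ion single file. One cycle is:

1. **Loading** — a cytoplasmic ion enters the cavity (rate `k_enter`,
   scaled by the voltage factor φ = exp(V/V₀)) and transits to S_cav
   (`k_scav`);
2. **Resolution** — the 4-ion configuration either **returns** the incoming
   ion (`k_return`) or **ejects** the outermost filter ion (`k_eject`·φ),
   upon which the file shifts outward in concert and S_cav's ion enters S4.

A mirrored inward path (extracellular arrival at S0, ejection of the S4 ion
into the cytoplasm, forward rates scaled by exp(−V/V₀)) carries the reverse
flux, so the net flux vanishes at 0 mV; at +100 mV inward events are three
orders of magnitude rarer and do not perturb the outward budget.

Independently of the transport machinery, the resting file fluctuates
between its two registers, (S1,S3,S4) and (S0,S2,S4), at `k_breathe`
(default 20/μs, i.e. ~50 ns dwell): the outermost ion visits S0 and the
central ion S2, which is what gives the axial density profile its maxima at
*all* five filter sites. Breathing gates no rate, so it affects neither the
calibration nor the flux balance.

### Calibration

Defaults: `V₀ = 50 mV`, `k_return = 200/μs`, `k_eject = 32/μs`,
`k_scav = 100/μs`. At +100 mV these give an ejection branching probability
*p* = `k_eject`·φ / (`k_eject`·φ + `k_return`) ≈ 0.54 — the incoming ion
"often returns" — and a 4-ion lifetime of ~2.3 ns (metastable, short-lived).
`k_enter` is then solved in closed form (`calibrate_k_enter()`) so that the
mean time per outward permeation,

  T = (1/(k_enter·φ) + 1/k_scav + 1/(k_eject·φ + k_return)) / p,

equals 24.5/45 μs at +100 mV — the reference budget of 45 complete events
in a 24.5-μs window under voltage. This yields `k_enter ≈ 0.479/μs`. The
choice of V₀ is the minimal monotone single-factor voltage coupling; nothing
in the reference data constrains the shape of the rate-voltage relation.

### Inhibitor modes

* **TEA** occupies the on-axis site adjacent to S_cav and sets the whole
  loading path to zero while bound. The TEA-mode trajectory emulates the
  *post-binding* epoch (bound from t = 0), because the zero-permeation
  statistic of interest conditions on the bound state. Unbinding is
  permitted only at 0 mV (at +100 mV the bound state is treated as
  absorbing, matching the observation that TEA never left in a 5-μs
  trajectory under voltage); the binding/unbinding rates exist for the
  zero-voltage induced-knock-on protocol, where spontaneous dissociation
  was observed.
* **RY785** divides the loading path (cavity entry and S_cav transit) and
  the inward ejection through the cavity by the attenuation factor
  (default 4). Applying the attenuation to the whole path, rather than the
  first step only, keeps the expected uninhibited/RY785 rate ratio at 3.98
  rather than 3.87. RY785 is emitted as a rigid 3-site proxy (ring carbon
  most extracellular, central nitrogen, thiazole sulfur most intracellular,
  1.8 Å apart) parked at radial offset 6 Å against one subunit interface,
  with a small rigid-body wobble (σ = 0.3 Å) reflecting its single dominant
  binding mode; TEA's nitrogen proxy wobbles laterally with σ = 0.8 Å about
  the axis, the scale that makes its radial deviation "rarely more than
  2 Å" (Rayleigh 95th percentile 1.96 Å).

### The induced knock-on protocol

At `t_pull` (default 100 ns, zero voltage) the central filter ion is driven
outward: the outermost ion is ejected, the central ion takes its place, the
innermost moves to the filter center, and S4 is left vacant. The vacancy
refills at `k_reload` under the same inhibitor gating as ordinary loading.
`k_reload` is a separate, much faster rate (default 400/μs) than `k_enter`:
a post-knock-on S4 vacancy is strongly ion-attracting and refills within
nanoseconds (~10 ns with RY785 bound), whereas steady-state loading against
a full filter takes ~0.3 μs. A single rate cannot produce both time scales;
this is the one place the generator adds a parameter beyond the steady-state
cycle, and it is constrained directly by the reported ~10 ns reload time.

## Detection conventions

* **Permeation event**: a complete bulk-to-bulk passage (CYTO→…→EXT or the
  reverse) that visits at least one filter site; excursions that return to
  the side they came from count nothing. The entry time is the start of the
  last excursion from the bulk side that completes the passage. An EXT label
  is only awarded once the ion exceeds the S0 ceiling by a 1 Å hysteresis
  margin, so boundary jitter cannot fabricate exits. Ions that *start*
  inside the pore (the initial filter file) are treated as having entered
  from the cytoplasmic side at the first frame; with that convention the
  detector count equals the generator's ejection count exactly on noiseless
  frames. The complementary boundary effect (an ion still inside the pore
  when the trajectory ends) simply yields no event.
* **Knock-on cycle**: detection keys on the frame-to-frame transition of an
  ion from S1–S4 to EXT, which is robust to S_cav dwells shorter than one
  frame (at +100 mV the 4-ion lifetime, ~2.3 ns, is near the default 1-ns
  frame interval). S0→EXT counts only when S0 was reached from inside the
  filter; reached from EXT it is the return of an inward excursion.
* **S4 reload**: the latency is resolved on the frame grid; a reload faster
  than one frame interval reports latency 0 with no visible vacancy.
* **Missing frames** are an error, never interpolated; the frame interval
  must divide the duration exactly.
* **Uncertainty**: rate ratios carry a seeded percentile bootstrap
  (10,000 Poisson resamples of the event counts); no uncertainty method is
  prescribed by the reference data, and the percentile bootstrap is the
  assumption-light default.

## Restraint potentials

The dihedral structure bias is U(θ) = k·Σ_{m=1..6} (1 − cos m(θ−θ_exp))/m!,
with k = 1 k_BT at 298 K (0.592 kcal/mol) by default: zero and stationary at
the reference angle, non-negative, 360°-periodic. The published rendering of
this potential carries a garbled "(−1)^m … −180°" factor; since
cos(x − 180°) = −cos(x), the form above is the unique reading that actually
favors the reference structure, while the literal alternating-sign reading
has its minimum 180° away. Both are implemented (`form = "favoring"` /
`"literal"`); the favoring form is the default.

Flat-bottom confinements are zero inside d₀ and 0.5·k(d−d₀)² outside
(radial: d₀ = 10 Å, k = 100 kcal/mol/Å², i.e. a 20 Å-diameter cylinder about
the axis; axial: d₀ = 15 Å from the V409:Cβ center), with energy and force
continuous at d₀. The knock-on pull is a one-sided harmonic toward ~3 Å
(k = 3 kcal/mol/Å²). Voltage/field conversion is computed from the 2019 SI
constants — 1 kcal·mol⁻¹·Å⁻¹·e⁻¹ = 4184/(N_A·e) ≈ 43.364 mV/Å — never from
a hard-coded field value, since printed field strengths depend on the
(time-varying) box length.

## What the generator does and does not emulate

It reproduces: three-ion filter occupancy fluctuating over S0–S4; S_cav
loading and voltage-biased outward ejection with the calibrated ~0.54 μs
mean interval at +100 mV; four cycles per complete crossing; TEA's on-axis
block with zero permeation; RY785's off-axis wall binding, ~4-fold slower
loading and the S6 contact pattern (interface residues contacted in two
subunits at once, the rotated V409/I405 pair in one); and the
S4-vacancy/reload contrast of the induced protocol.

It does not emulate: water (including co-permeation), lipids or
electrostatics; continuous ion dynamics between sites; inhibitor entry
kinetics through the gate (both inhibitors start bound); RY785's internal
flexibility beyond the rigid 3-site proxy; or any force evaluation. Passing
tests on synthetic trajectories therefore validate the *analysis machinery*
(geometry, counting, statistics) and the internal consistency of the
transport model — they are not evidence about any particular real
trajectory. The reported bulk-ion imbalance of the reference simulation
(208 K⁺ vs 239 Cl⁻) is unexplained there and not emulated here.

## Problem sizes used in the tests

Unit tests run the generator for 1.5–24.5 μs; the rate-ratio checks use
24.5 μs per condition (parameter recovery across attenuations 1–8) and
245 μs (bootstrap-CI coverage of the 4-fold contrast); the acceptance script
uses 2450 μs per condition, which brings the stochastic error of the rate
ratio to about 3%. These sizes were chosen so each statistic's sampling
error is small against the tolerance it is compared at.
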