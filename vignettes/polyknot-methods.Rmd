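---
title: "Methods: two knots on a stretched semiflexible chain"
author: "polyknot developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two knots on a stretched semiflexible chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

polyknot studies how two trefoil knots tied on the same semiflexible
polymer, stretched between two walls as in an optical-tweezers setup,
distribute along the chain and interact — and how that interaction
depends on the chain's bending rigidity and on the *relative chirality*
of the two knots. This vignette is the package's own account of the
model, the algorithms, the tunable parameters, and the judgment calls;
it states no empirical number that the test suite or the acceptance
script does not itself compute.

## 1. The chain model

The chain is a Kremer–Grest bead–spring polymer of `N` beads in reduced
units (bead diameter `sigma`, energy `epsilon = kBT`, bead mass `m`,
time `tau_MD = sigma sqrt(m/epsilon)`). The potential energy has four
parts:

* **Excluded volume** — purely repulsive WCA between *all* distinct bead
  pairs: `4 eps [(sigma/r)^12 - (sigma/r)^6 + 1/4]` for
  `r <= 2^(1/6) sigma`, zero beyond, continuous at the cutoff. Bonded
  pairs are *not* excluded from the sum; combined with the finite FENE
  extension this gives bonds an impenetrable core, so chain topology is
  conserved exactly — the property everything downstream relies on.
* **Connectivity** — FENE bonds, `-(kappa R0^2/2) ln(1 - (b/R0)^2)` with
  the customary Kremer–Grest constants `kappa = 30 eps/sigma^2`,
  `R0 = 1.5 sigma`. A bond reaching `R0` is a hard error ("topology
  safety violation"), never silently clamped.
* **Bending** — `kappa_b (1 - cos phi)` at every interior joint. The
  persistence length is approximately `sigma kappa_b / kBT`; the
  interesting rigidity range is `kappa_b = 2.5–20 kBT`.
* **Walls** — the termini are frozen at `(0,0,0)` and `(L,0,0)`
  (constant-extension ensemble; the production geometry is `N = 300`,
  `L = 205 sigma`, extension ratio ~0.68). Interior beads are repelled
  from the planes `x = 0` and `x = L` by a truncated-and-shifted LJ 9-3
  wall, cut off at its minimum `(2/5)^(1/6) wall_sigma` with shift
  `sqrt(10)/3`, so energy *and* force vanish smoothly at the cutoff. No
  closed form for the wall potential is prescribed by the physics; a
  smooth repulsive wall was chosen over a hard wall so that forces are
  defined everywhere and the integrator needs no special-casing.

Forces are the analytic gradient of this energy (verified in the tests
against central finite differences on 100 random conformations,
max relative error < 1e-5).

## 2. Langevin dynamics

`integrate_chain()` runs underdamped Langevin dynamics: a velocity-Verlet
core where each force evaluation adds, per mobile bead and component, a
friction force `-(m/tau_frict) v` and a Gaussian kick of standard
deviation `sqrt(2 m kBT/(tau_frict dt))` (the LAMMPS-style
"friction + kick" splitting). `dt = 0.01 tau_MD`;
`tau_frict = 1000 tau_MD` is the production value. The two terminal
beads never move. One integer seed determines the entire noise stream;
runs are bit-reproducible.

Two practical consequences of the very weak production coupling
(`gamma = 1e-3`):

* Velocity relaxation takes ~`tau_frict` = 1e5 steps, so a desk-scale
  run started from a minimized conformation will *not* reach kinetic
  temperature 1 within 1e5 steps. Tests that check equipartition or
  Boltzmann statistics therefore use a flagged test-only coupling
  (`tau_frict = 5–10`); the topology-conservation and drift checks use
  the production value.
* With the thermostat off the integrator reduces to plain velocity
  Verlet; the energy-conservation check measures *secular* drift (mean
  of the last tenth of the run minus the first tenth, relative), since a
  symplectic integrator's energy fluctuates reversibly at
  O((dt·omega)^2) but must not drift.

## 3. Knot localization on open chains

A knotted portion of an open chain is defined operationally as the
*shortest* contiguous arc that, after closure, has the target topology.

**Closure (minimally interfering).** An arc is closed either directly
(terminus to terminus) or "at infinity": each terminus is pushed
radially away from the arc's centroid onto a sphere of ~2.2x the arc's
bounding radius and the two outward points are joined along that sphere.
The direct branch is taken when the terminus separation is smaller than
the sum of the termini's distances to the surface of the arc's
axis-aligned bounding box — a cheap, deterministic proxy for "how buried
each end is in the arc's hull" (a full 3-D convex hull would add a heavy
dependency for no accuracy the tests can detect). Degenerate inputs
(< 4 effective vertices) short-circuit to the unknot.

**Reduction.** Before any closure or projection the polygon is
simplified by KMT triangle elimination: a vertex is deleted whenever no
other segment pierces its elimination triangle. This preserves the
(closure) topology, shrinks 100-bead chains to ~10–20 vertices, and is
what makes the O(N^2) arc scans affordable.

**Classification.** The closed polygon is projected along a random
direction (deterministically seeded; degenerate projections — grazing
or collinear crossings — are re-drawn, up to 50 times). From the
crossing diagram the Alexander matrix is built and `|Delta(-1)|`,
`|Delta(-2)|` evaluated. Because the Alexander polynomial is defined up
to units `±t^m`, the value at `t = -2` is only defined up to powers of
2; all factors of 2 are divided out. The classifier is a pure lookup:
(1,1) unknot, (3,7) trefoil, (9,49) two-trefoil composite, anything
else `other` — all four determinant values are odd, so the power-of-2
normalization is lossless here. Determinants are projection-invariant
(tested over 20 random rotations per reference knot).

**Search.** `shortest_knotted_arc()` scans lengths bottom-up and stops
at the first length with a hit (ties to the smaller start). The tests
compare it against an independent exhaustive scan over all (s, e) on
fixtures of up to 80 beads.

**Isolated components.** On a chain whose full closure is the
two-trefoil composite, a prime component is *isolated* iff its arc can
be excised — flanks joined directly — without untying the other knot
(the remainder still closes to a trefoil). Two isolated components =
separated knots; one = intertwined, and the isolated arc is the nested
knot. The shortest arc with composite topology is reported alongside.
Frames where any arc touches bead 0 or N-1 are flagged
(`touches_end`) rather than silently kept, because the arc endpoints
are ambiguous against a wall.

**Chirality.** The handedness of a trefoil arc is the sign of the space
writhe of its closed, reduced polygon (Gauss-integral, exact per
segment pair) — equivalently, for a trefoil, the sign of the summed
signed crossings of its diagram; the tests verify both routes agree for
every projection and flip under mirror reflection. +1 is right-handed.

## 4. Order parameters

* `|D|` — the absolute distance in beads between knot centers
  (`c = (s+e)/2`). Separated: distance between the two isolated arcs'
  centers. Intertwined: distance between the nested knot's center and
  the composite arc's center (the host's boundaries are taken to be the
  composite's).
* The **director** `U` of a knot arc is the normalized sum of cross
  products of consecutive bond vectors — the oriented normal of the
  idealized loop. For the host knot of an intertwined pair, `U2` is
  built from the composite-arc bonds *complementary* to the nested arc.
  Written with the norm of the sum (normalize-after-sum): that is the
  only reading that yields a unit vector. Frames whose cross-product
  sum vanishes are flagged undefined and excluded from angle
  statistics, not imputed.
* `theta = arccos(U1 · U2)` (dot clamped to [-1, 1]).
* `theta_perp` — the signed angle between the YZ-plane projections of
  the directors: magnitude `atan2(|V1 x V2|, V1 · V2)`, sign from the x
  component of `U1 x U2`. Reflecting the system through the XZ plane
  flips its sign while leaving `theta` unchanged — the symmetry that
  maps a (+-) arrangement onto its chirality-swapped twin.

## 5. Free energy, entropy model, elastic model

`estimate_profile()` histograms pooled `|D|` samples (default bin width
2 beads) and sets `F = -kBT ln p`, zeroing the mean over the plateau
window `|D| in [0.35 N, 0.55 N]` — far from both the intertwined state
and the walls. Empty bins carry NA (never -Inf). Bins start at
`-bin_width/4` so the (half-)integer grid that `|D|` lives on is
symmetric about each bin center; without this half-bead alignment the
exact entropy subtraction below acquires a spurious tilt.

The entropic null model treats the two knots as indistinguishable rigid
segments of length `lk` (the measured mean separated-knot size) sliding
freely — overlap allowed — on a line of `N` beads. Counting placements
gives `omega(D) = 2(N - lk + 1 - D) / [(N - lk + 2)(N - lk + 1)]`,
normalized exactly; `S = kB ln omega`. The tests verify `omega` against
brute-force enumeration for every `3 <= lk < N <= 30`.
`subtract_entropy()` adds `T·S` back to F; on data generated by the
sliding-segment model itself the corrected profile is flat (fitted
slope's 95% CI covers zero at 1e5 samples).

`extract_features()` measures, on a profile with a resolved interaction
region: `eps_b` (barrier top minus plateau), `eps_d` (barrier top minus
the `|D| ~ 0` bin; undefined when there is no minimum at the origin, the
low-rigidity phenomenology), and `D_int` — the largest `|D| < N/2` at
which F exceeds the plateau by a detection threshold while scanning
downward. "Starts to increase" is qualitative, so the threshold is an
exposed parameter; the default is twice the plateau's own standard
deviation, and the tests check `D_int` moves < 2 beads when the
threshold varies ±50%.

The elastic model rationalizes the separated-knot size: a knot of `n`
beads is a loop of radius `R = sigma n/(2 pi + 2)` (braid included),
storing bending energy `E_b = 2 (pi+1)^2 kappa_b/(sigma n)`, against a
tension penalty `Q n^2/2`. Minimizing per knot gives
`n* = (2 (pi+1)^2 sigma kappa_b/Q)^(1/3)` — sublinear (cube-root) growth
with rigidity. `fit_Q()` inverts this at a calibration point; the units
of `Q` are energy per bead², implied by the quadratic form.

## 6. What the synthetic data does and does not emulate

Fixtures are built from a (2,3)-torus curve with major radius 2.4 and
unit winding amplitude — the aspect ratio that minimizes curve length
per unit strand clearance (~35.9 sigma at clearance ~2 sigma), found by
a small parameter scan; a fatter torus wastes chain slack, which is the
scarce resource at desk scale. Templates are cut at their outermost
vertex, opened by a 1.2 sigma shear along the end-to-end direction
(larger openings untie the template), spliced into a straight chain
between the walls, and relaxed at T = 0. The intertwined fixture
inserts the nested template into the host template's bead sequence,
trying insertion vertices innermost-first until the construction
verifies (composite closure *and* exactly one isolated component).
Every fixture is checked against the topology machinery at build time —
constructive ground truth.

Desk-scale defaults are `N = 100`, `L = 70 sigma` (the production
extension ratio) with 18-bead templates. What this does **not**
emulate: production statistics. The production study pools 30 runs of
2e7 tau_MD (~5.6e8 tau_MD per system); desk runs are 1e4–1e5 steps.
Consequently equilibrium knot sizes here are smaller than production
values (templates barely loosen), intertwining events are rare, and the
chirality splitting of the free-energy minimum — the headline
production result — is *not* resolvable. A green test establishes that
the machinery is correct (topology conserved, oracles matched,
models exact), not that the production phenomenology is reproduced.
The acceptance targets are therefore the analytic ones: the elastic
model's `n* -> 36` beads at `kappa_b = 20` with `Q = 0.015`, and the
inverse calibration `Q -> 0.015`.

The rigidity trend is still visible at reduced scale. A short
pipeline run (3e4 steps, 30 frames, seed 200 + kappa_b) gives:

```{r trend}
for (kb in c(5, 10, 20)) {
  p <- desk_params(N = 100, L_wall = 70, kappa_b = kb)
  conf <- build_two_knot_chain(p, knot_spec(+1, 30, 18),
                               knot_spec(+1, 70, 18))
  tr <- integrate_chain(conf, p, run_protocol(30000L, 1000L, 5000L,
                                              seed = 200 + kb))
  kt <- analyze_trajectory(tr)
  cat(kb, mean(c(kt$e1 - kt$s1, kt$e2 - kt$s2) + 1, na.rm = TRUE), "\n")
}
#> 5  14.4
#> 10 15.5
#> 20 16.3
```

increasing and clearly sublinear in `kappa_b`, consistent with the
cube-root law (documented as a qualitative, non-gating check).

## 7. Numerical choices and degenerate inputs

* Projection retries: capped at 50, seeded from the frame index;
  degeneracy tolerance 1e-9 on crossing parameters and heights.
* Determinants are computed by LU on the reduced diagram; after KMT the
  matrices are small enough that the integer determinant is exactly
  representable in doubles.
* Arc ties break to the smaller start bead; arcs are 0-based inclusive
  `[s, e]`, sizes `e - s + 1`.
* Dot products are clamped before `arccos`; vanishing director norms
  (< 1e-10) and vanishing YZ projections return flagged NA.
* The minimizer is steepest descent with backtracking, displacement
  capped at 0.05 sigma per step, so relaxation cannot jump a strand
  through another: energy is non-increasing and topology preserved.
* Zero-count histogram bins are masked; the entropy is masked where
  `omega = 0`.

## 8. Known limitations

* The handedness routine is specified for trefoil arcs only (writhe
  sign is not a chirality invariant for general knots); non-trefoil
  arcs raise an error.
* Knot vocabulary is limited to {unknot, 3_1, 4_1, 3_1#3_1}; the
  classifier reports anything else as `other`.
* `|Delta(-2)|` is reported with powers of two removed; knots whose
  true determinant at -2 is even (none among the supported labels)
  would be reported reduced.
* Constant-force (rather than constant-extension) stretching,
  electrostatics, torsional stiffness and real-unit (pN/nm) mappings
  are out of scope.
* The Metropolis/KS detailed-balance check and the equipartition check
  run at strengthened test-only friction; the production coupling is
  validated only through drift and topology conservation.
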