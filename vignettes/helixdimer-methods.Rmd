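---
title: "Descriptor methods for transmembrane helix dimer trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor methods for transmembrane helix dimer trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixdimer)
```

`helixdimer` measures how two transmembrane helices are packed against
each other along a trajectory and how that packing changes: the signed
crossing angle Ω, the lateral separation *L*, the terminal opening Δd,
and the rotation of each helix about its own axis. This vignette is the
package's account of those methods — the conventions chosen where the
geometry leaves freedom, the numerical choices, and what the synthetic
test bed does and does not demonstrate.

## The coordinate model

The analyzed object is a pair of helices with **one backbone bead per
residue** — a coarse-grained backbone bead or a Cα trace. The default
selection covers 28 residues per chain, numbered 765–792: a 25-residue
TM core (765–789) plus three linker residues that stabilize the
C-terminal segment geometry. Internally residue *i* = residue number −
764, so the core runs *i* = 1…25. All in-memory coordinates are nm; the
PDB writer/reader converts to/from Å per that format. Input is assumed
pre-imaged: no periodic-boundary treatment is applied, because box
handling upstream of a geometric analysis is trajectory-preparation work
and guessing an imaging convention silently would be worse than
requiring clean input.

## Helix axes

Two axis constructions are used, both from group centers rather than
fits:

- the **global axis** of a helix is the unit vector from the center of
  its first four beads to the center of its last four, pointing N→C;
- **segment axes** divide the 28 residues into seven 4-residue groups;
  the six unit vectors k₁…k₆ join consecutive group centers. A bent
  helix's k_j track the bend while the global axis does not, which is
  the point: residue rotation angles are measured about the *local*
  axis so that helix bending and wiggling does not masquerade as
  rotation.

On an ideal helix with 100°/residue twist, a 4-residue group center
sits ≈ 0.026 nm off the true axis (four 100°-spaced azimuths do not
cancel exactly), giving the global axis an intrinsic wobble of ≈ 0.7°
that co-rotates with helix spin. This is a property of the
center-point construction itself, shared by a principal-component axis
on the same 28 beads, and it bounds the accuracy of the rotation
descriptors discussed below.

## Crossing angle and handedness

|Ω| = acos(h₁·h₂) for the two global axes, mapped to the acute
equivalent: if the axes subtend more than 90°, one is flipped before
signing, so |Ω| < 90° always. The sign encodes packing handedness,
**negative = left-handed**. Operationally, with c the
common-perpendicular direction from helix A to helix B,
sign(Ω) = −sign((h₁×h₂)·c). The constant was calibrated on a
constructed fixture using the front-strand rule: viewed from outside,
the near helix of a right-handed crossing runs "/" (as in a
right-handed double helix), a left-handed crossing "\\". Axes within
0.5° of parallel after acute mapping are reported as Ω = 0 with a
degeneracy flag rather than an arbitrary sign.

*L* defaults to the centroid–centroid distance of the two bead sets:
reported packed-dimer separations (~1 nm) are on the scale of center
separation, not of closest bead contact. A `min_pair` mode (minimum
over all cross-helix bead pairs) is provided explicitly; the mode in
force is recorded in the descriptor CSV header and run log.

Δd = ‖N_A−N_B‖ − ‖C_A−C_B‖ on the 4-bead end centers: positive when
the dimer opens at the N-termini. It is antisymmetric under reversing
both chains' N/C labeling and symmetric under swapping helix labels.

## Residue rotation angles

The reference line for rotation is h ∥ h₁×h₂, oriented from the
measured helix toward its partner. When |Ω| < 14.4° the cross product
direction is unreliable, so the reference falls back to the vector from
the measured helix's midpoint (center of the four central residues,
777–780) to the partner's axis, perpendicular to that axis by
construction. The threshold is applied to the instantaneous signed Ω.

For residue *i*, the owning segment vector is k_j with j = ⌈i/4⌉
capped at 6 (residues 25–28 reuse k₆; there is no seventh vector). The
bead is projected onto the plane ⊥ k_j through its perpendicular foot
on the line through group center j along k_j; the angle from the
purified reference h⊥ = normalize(h − (h·k_j)k_j) to that projection is
θ, **positive counterclockwise viewed from the C-terminal side**
(looking along −k_j). The viewpoint fixes the sign convention
concretely; it is covered by a rotation-matrix construction oracle in
the tests.

Per-helix rotation is the arithmetic mean over the 25 core residues of
Δθ_i = θ_s,i − θ_0,i. Two details matter:

- **Unwrapping is per residue across time**: successive per-residue
  differences are wrapped into (−180°, 180°] and cumulatively summed
  before averaging. Direct subtraction from frame 0 is ambiguous once a
  helix has turned beyond ±180°, and rotations of ~300° do occur; the
  cumulative reading is the only consistent one, and requires frame
  spacing fine enough that no genuine inter-frame rotation exceeds
  180°.
- The arithmetic (not circular) mean is correct here because unwrapped
  values are real-valued displacements, not angles modulo 360°.

Residues whose projection onto the rotation plane nearly vanishes
(< 10⁻⁶ nm) are excluded from that frame's average; a frame with more
than 5 such residues per helix is flagged unreliable. Averaging over 25
rather than all 28 residues keeps the rotation a TM-core property; the
linker residues only serve the segmentation.

### Accuracy

On ideal noise-free geometry the axis wobble described above enters Δθ
through the reference vector, amplified by 1/sin|Ω| (the norm of
h₁×h₂). At |Ω| ≈ 25° the worst-case systematic error over a full turn
of scripted spin is ≈ 3°; at |Ω| = 50° it is ≈ 1.2°. The package's
spin-recovery scenarios are therefore scripted at a crossing angle of
−50°: mechanistically, large helix rotations occur while the dimer is
pivoted to large |Ω| — the crossing angle must change by roughly 45°
before the helices can rotate freely — so the pivoted geometry is the
regime in which rotation recovery is the meaningful claim. Under 0.05
nm positional noise, recovered spin ramps stay within ~4° RMS of the
script, comfortably inside the 10° contract.

## States, filtering and free energy landscapes

*L* classifies each frame: dimeric (*L* < 1.5 nm), pre-dimeric
(1.5 ≤ *L* < 3 nm), monomeric (*L* ≥ 3 nm). Interval notation leaves
the boundaries open in prose, so the package fixes them closed on the
right-hand state and documents that; the landscape filter retains
*L* ≤ 3 nm ("3 nm or less"), so the boundary frame is both retained
and classified monomeric — deliberately, since the filter and the
classifier answer different questions.

The free energy grid over (Δθ_A, Δθ_B) is a histogram inverted by
U = −k_B T ln p, k_B = 0.0019872 kcal mol⁻¹ K⁻¹, default T = 323 K
(the membrane simulation temperature) and 5° bins on a [−180°, 360°]
support that accommodates unwrapped rotations up to a full turn. Two
normalization conventions are provided and always tagged: `per_bin`
(p = bin probability; U ≥ 0, minimum at the most occupied bin) and
`density` (p per rad²; shifts U by a constant and can make well depths
negative, matching the common practice of quoting negative basin
depths). Only occupied bins carry U; empty bins are masked NA rather
than given an arbitrary cap. Averaging across trajectories pools
**counts** and re-inverts — averaging U values directly would weight
trajectories incorrectly and break the masking.

Region summaries (mean Ω, *L*, Δd and frame count over a rectangular
window in the rotation plane) use user-supplied windows: basins are
identified by inspection, and promising an automatic basin detector
would overstate what a histogram on limited sampling supports. An empty
window returns an explicitly empty result, never zeros.

## Event detection

The crossing-angle series is smoothed with a centered 5-frame moving
average for detection only; event records report raw values.

A **pivot** is an excursion-and-return: the smoothed series leaves a
hysteresis band (default 25% of the threshold) around its pre-excursion
baseline, and the total crossing-angle change spanned by the excursion
window — max − min of the smoothed series from the last in-band turning
point through the first turning point after the return — is at least
the threshold (default 45°, with 40° as a noted alternative preset).
The range definition, rather than peak deviation from baseline, is what
makes an excursion like −6.4° → −51° → +4.6° a single pivot spanning
55.6°: its outbound swing alone is 44.6°, but the motion sweeps well
past the threshold once the return overshoot is counted, which is the
physically meaningful "change in crossing angle" of a pivoting motion.
Sub-band chatter is absorbed by hysteresis-pruned turning points, which
also merges overlapping sub-excursions. Baselines reset to the return
value after each event; consequently exact time-reversal symmetry holds
for isolated excursions but not across sequences of events whose
baselines drift (the forward and reversed scans reference different
baselines).

A **handedness flip** is a sign change of the smoothed Ω that exits a
±5° dead band on both sides, timed at the interpolated zero crossing.
The dead band stops near-zero jitter from being read as repeated
interconversions — the excursion above returns only to +4.6° and is
correctly *not* a flip.

`associate_rotations()` attributes each event to the helix(es) whose
unwrapped rotation changed by ≥ 50° across the (optionally padded)
event window: "A-rotating", "B-rotating", "both" or "neither". On
scripted two-pivot trajectories with one 180° single-helix spin per
excursion, the two events are recovered with single-helix labels and
final rotations near (180°, 180°) — the two-stage interconversion
mechanism in miniature.

## Contact scoring

The residue–residue contact score between two residues is the sum over
cross-residue atom (or bead) pairs of a piecewise-linear kernel: weight
1 at distances ≤ inner cutoff, 0 at ≥ outer cutoff, linear in between.
The atomistic preset uses the published heavy-atom cutoffs
(3.23 / 4.63 Å). Because this package scores whatever coordinates it is
given — and coarse-grained beads are sparser than heavy atoms — a
clearly labeled non-canonical `cg` preset with widened cutoffs
(4.7 / 7.0 Å) is provided for bead-level input; canonical scoring
expects back-mapped atomistic structures (back-mapping itself is out of
scope). Tables cover all cross-chain pairs over residues 765–789 (the
TM core after dropping terminal loops, 625 pairs), top-30 lists break
score ties by ascending residue ids for determinism, and concordance
counts unordered shared pairs, passing at > 25 of 30 (better than 80%
agreement).

## The synthetic test bed

`build_ideal_helix()` places bead *i* at axial position (i−1)·rise,
azimuth (i−1)·twist, radius from the axis, with the canonical α-helix
backbone defaults rise 0.15 nm, twist 100°/residue, radius 0.23 nm.
`assemble_dimer()` realizes a pose symmetrically: each helix is spun
about its own axis, tilted by ±crossing/2 about the inter-axis
perpendicular (neither helix privileged), separated along the
perpendicular, and helix B slid along its own axis. The tilt signs are
calibrated so a scripted negative crossing angle is measured as
left-handed. `generate_trajectory()` interpolates every pose parameter
linearly between waypoints — angles are authored unwrapped, so a ramp
to 300° means 300° — then applies a half-sine axis bow (a single smooth
bending mode, enough to separate segment axes from the global axis) and
isotropic Gaussian noise, in that order, with bit-identical output for
equal seeds.

What this emulates: backbone-level dimer geometry, scripted
rearrangements, measurement noise, smooth bending. What it does not:
thermal kinetics, lipid/solvent forces, sequence-dependent packing,
side chains, sharp kinks, periodic boxes. Passing recovery tests
therefore demonstrates that the descriptors measure what they claim on
known geometry — not that any particular biological trajectory will be
sampled correctly. Problem sizes in the tests and acceptance script
(25–121-frame trajectories, 22 spin ramps, 100-sample histograms) were
chosen as the smallest sizes at which each contract is exercised away
from its edge cases.

## Degenerate inputs and failure behavior

Near-parallel axes: Ω = 0 with a degeneracy flag (crossing angle) and
the midpoint fallback (rotation reference). Beads on the local axis:
excluded per frame, with an unreliability flag past 5 exclusions.
Empty region windows: explicit empty result. Empty bins: masked.
Zero-length trajectories, single-frame rotation series, mismatched FES
edges, unequal pair lists, invalid cutoffs and non-increasing waypoint
times all raise immediate validation errors rather than propagating
NaNs.

## Known limitations

- The ~0.7° end-center axis wobble on ideal geometry sets a floor of a
  few degrees on rotation accuracy near small |Ω|; descriptors at
  |Ω| ≲ 15° lean on the midpoint fallback and should be read with that
  tolerance in mind.
- Pivot detection is baseline-referenced; slow monotonic drift of Ω is
  deliberately not an event, and detector parameters (threshold,
  smoothing, hysteresis) are exposed rather than claimed universal.
- The landscape is a histogram inversion of whatever sampling it is
  given; it is not an equilibrium free energy unless the input is
  equilibrated, and no reweighting or Markov-state machinery is
  offered.
- Absolute basin depths depend on the normalization convention and bin
  width; only differences within one convention are meaningful.
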