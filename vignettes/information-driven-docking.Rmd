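---
title: "Information-driven rigid-body docking with glowdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-driven rigid-body docking with glowdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowdock)
```

## The problem and the model

Rigid-body protein–protein docking searches the six-dimensional space of
relative placements of a ligand protein against a receptor protein for
poses close to the native complex. glowdock organizes this search as a
set of *swarms*: sampling loci placed on a shell outside the receptor
surface, each holding a population of *glowworm* agents. Every agent
carries a candidate ligand pose — a translation of the ligand centroid
plus a unit quaternion rotation about that centroid — together with a
*luciferin* level (its accumulated brightness) and an adaptive vision
range. Each optimization step, an agent's fitness is evaluated on its
current pose, luciferin is updated from that fitness, each agent picks a
brighter neighbor within its vision range with probability proportional
to the luciferin difference, and steps toward it: a fixed-length
translation step along the line to the target and a fixed-fraction
spherical interpolation of the orientation. Crowded agents shrink their
vision, lonely ones grow it. This glowworm-swarm scheme maintains many
local populations at once, which suits docking's multi-funnel energy
landscapes: distinct binding modes survive in distinct swarms instead of
collapsing onto a single global optimum.

Fitness is the negated energy of a distance-binned, atom-typed pair
potential over all receptor–ligand atom pairs within the table's cutoff
(a DFIRE-style statistical potential; the table is a loadable text
artifact, not re-derived by this package).

## Using interface information

The defining feature is that *ambiguous residue restraints* — lists of
residues believed to be at the interface, on either partner, without
pairwise assignments — act at three points:

1. **Swarm filtering (setup).** For every receptor-side restraint, only
   the ten swarm centers closest to the restraint residue's
   representative atom (CB, or CA for glycine) are retained; the run
   uses the de-duplicated union. With no receptor restraints all swarms
   survive. This excludes irrelevant sampling regions before any energy
   is evaluated.
2. **Ligand pre-orientation (setup).** When ligand-side restraints
   exist, each initial pose draws one receptor and one ligand restraint
   at random and replaces its random orientation with the rotation that
   points the ligand restraint (direction from the ligand centroid to
   the restraint's representative atom) at the receptor anchor, composed
   with a uniform random spin about that axis. The spin keeps
   orientation diversity; the alignment removes the half of rotation
   space that faces the restraint away from the receptor.
3. **Scoring bias (every step).** The fraction `s` of *active*
   restraints whose residue has any atom within the bias reach of the
   partner scales the fitness: positive fitness is multiplied by `s`,
   negative fitness by `2 - s`. Full satisfaction is the identity; any
   violation strictly worsens a nonzero fitness, continuously in `s`.
   Restraints marked *passive* take part in the two setup steps but are
   excluded from `s`.

Degraded-information scenarios are first-class constructors
(`buildScenario`): the full true interface (`TI`, residues within 3.9 Å
of the partner in the native complex), halves and quarters of it padded
with contiguous false-positive surface patches (`TI_50`, `TI_25`, with
disjoint replicates), receptor-only variants (`TI_REC`, `TI_REC_50`,
`TI_REC_25`), a single true contact pair (`TI_SINGLE`) and its
receptor-only reduction (`TI_ONE`). False positives are drawn from
non-interfacial surface residues and grown as one contiguous patch
seeded at the retained true residues, so a wrong-but-plausible interface
results; they never intersect the true interface, and the per-side size
of the degraded set equals the size of the original.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| contact cutoff | 3.9 Å | interface definition and restraint satisfaction for measurement |
| bias reach (`biasCutoff`) | 10 Å | distance at which a restraint counts as satisfied *during* optimization |
| swarms before filtering | 400 | quasi-uniform coverage of the receptor surface |
| swarms per restraint | 10 | retained centers per receptor restraint |
| glowworms per swarm | 200 | agents per sampling locus |
| surface distance | ligand bounding radius + 2 Å | shell height of swarm centers above the receptor |
| jitter radius | 2 Å | translation spread of initial poses inside a swarm |
| ρ, γ, l0 | 0.4, 0.6, 5 | luciferin decay, gain, initial level |
| n_t, β | 5, 0.08 | neighbor target and vision-range gain |
| r0 = r_s | 8 | initial and maximum vision range (pose-space units) |
| translation / rotation step | 0.5 Å / 0.1 | per-move advance |
| steps | 100 | optimization steps per swarm |
| wRot | 3 Å/rad | weight of the orientation term in the pose metric |

Three of these defaults were set against the package's own experiments
rather than first principles, and the reasoning is worth recording:

* **Bias reach of 10 Å instead of the 3.9 Å contact cutoff.** Initial
  poses start clash-free, a few Ångström off the surface, where no
  restraint is within 3.9 Å of the partner: `s = 0` for every agent,
  the multiplicative bias zeroes all positive fitness, luciferin decays
  uniformly, and no agent is ever strictly brighter than another — the
  swarm provably cannot move. A 10 Å reach gives the bias a gradient
  from the starting shell; measurement functions (`satisfiedFraction`,
  `postFilter`, scenario construction) keep the 3.9 Å convention.
* **Luciferin input is the per-step min-shifted fitness.** Luciferin is
  floored at zero; on an all-negative landscape (e.g. a purely repulsive
  region, or the analytic `-||t - t*||^2` objective) the raw update
  drives every agent to the floor within two steps, again freezing the
  swarm. Shifting the per-step fitness so the worst agent sits at zero
  preserves exactly the ordering and differences that drive neighbor
  selection. The `luciferinUpdate` rule itself is unchanged.
* **wRot = 3 Å/rad.** With the textbook 10 Å/rad, the orientation term
  between two random orientations (median ≈ 19 Å-equivalent) alone
  exceeds the default vision range, so differently-oriented agents can
  never interact and orientations are never refined; 3 Å/rad keeps the
  orientation term commensurate with the translation spread of a swarm.
* **Surface distance of bounding radius + 2 Å.** The bounding radius
  already covers the worst-case orientation; the looser + 5 Å margin
  costs three extra Ångström of approach that a finite-reach potential
  must be dragged across, which at a fixed step budget halves toy-scale
  recovery. Rare initial overlap is resolved by the short-range
  repulsive bin.

## Numerical choices

Rotation is about the ligand's coordinate centroid, which approximately
decouples the translation and rotation coordinates for the optimizer.
Quaternions are renormalized after every composition and interpolation
(unit norm within 1e-9); slerp takes the shorter arc, identifying `q`
with `-q`. Pose-space distance is the translation Euclidean distance
plus `wRot` times the quaternion geodesic angle. Ranking sorts by
descending biased fitness with deterministic (swarm id, glowworm id)
tie-breaks. Scoring bins are half-open `[lower, upper)` with an implicit
lower edge of zero; pairs at or beyond the last edge contribute nothing;
hydrogens and atoms without a table type are skipped and counted. The
accelerated cell-grid scorer is tested to equal a brute-force double
loop to 1e-9. Superpositions use the Kabsch SVD construction with the
determinant correction for proper rotations; tests cross-check it
against Horn's closed-form quaternion method to 1e-6. A degenerate
pre-orientation (restraint atom at the ligand centroid) falls back to
the unmodified random orientation with a warning. Each swarm derives an
independent RNG sub-seed from the global seed and its id, so results are
bit-identical under any swarm execution order.

## The synthetic-data generator

`generateToyComplex` builds two compact pseudo-protein globules —
residues on a jittered cubic lattice, five pseudo-atoms each (N, CA, C,
O, CB; glycine without CB), names drawn from the twenty standard amino
acids — and docks the ligand by construction by sliding it along +x into
the receptor until at least three residue pairs sit within 3.9 Å with no
heavy-atom pair under 2.5 Å. The native pose, its contact list, and a
scoring table whose attractive well is specialized to the native-contact
atom-type pairs (`generateToyScoringTable`, verified at construction to
score the bound pose below 2 Å and 5 Å perturbations) give every
pipeline stage a known ground truth. `generateDecoySet` produces poses
at 0/1/5/20 Å (with matched rotations) chosen to straddle the CAPRI
class boundaries.

What the toys do *not* emulate: real side-chain packing and chemistry,
conformational change on binding (the unbound-to-bound problem), the
statistics of a real DFIRE table, crystallographic artifacts, and
realistic protein sizes. Passing the toy-scale tests therefore
demonstrates the correctness and the information-driven behaviour of
the machinery — filtering, pre-orientation, bias, ranking, evaluation —
not benchmark-level accuracy on real complexes.

## Evaluation layer

Models are classified against the native complex by the CAPRI criteria:
fnat (fraction of native residue–residue contacts at 5 Å reproduced),
l-RMSD (ligand backbone RMSD after superposing the model receptor on
the native receptor backbone) and i-RMSD (backbone RMSD over native
interface residues, 10 Å definition, after superposing on those atoms).
high requires fnat ≥ 0.5 and (l-RMSD ≤ 1 or i-RMSD ≤ 1); medium
fnat ≥ 0.3 and (l-RMSD ≤ 5 or i-RMSD ≤ 2); acceptable fnat ≥ 0.1 and
(l-RMSD ≤ 10 or i-RMSD ≤ 4); otherwise incorrect. The Top-N success
rate over a case set is the percentage of cases with at least one
non-incorrect model among their N best-ranked models. `postFilter`
implements the a-posteriori baseline: discard, after a blind run, the
models whose satisfied restraint fraction at the contact cutoff falls
below a threshold, preserving rank order.

## Problem sizes used by the test suite

The shipped defaults (400 candidate swarms, 200 glowworms, 100 steps)
target real-protein runs. The test suite and the acceptance script
exercise the full pipeline at toy scale, a deliberate package choice so
the whole protocol — ten complexes, three restraint scenarios each —
runs in minutes: 28 + 14 residue complexes, 80 candidate swarm centers,
40 glowworms per swarm, 60 optimization steps, Top-10 evaluation. The
sampling-density and filtering defaults themselves are asserted
separately at their full values.

## Known limitations

Rigid bodies only: no backbone or side-chain flexibility enters the
optimization variables. The scoring table is an input; no parameters
are derived from structural statistics here. The bias functional form
(multiplicative, sign-split) is the simplest form that is the identity
at full satisfaction and strictly penalizing otherwise; published
information-driven docking implementations do not print theirs, so no
claim of equivalence is made. Swarm centers are placed by projection
from a Fibonacci sphere, which can under-cover deep concave pockets;
membrane-aware placement and swarm re-seeding are out of scope.
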