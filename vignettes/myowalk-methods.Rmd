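---
title: "The myowalk model: a hierarchic coarse-grained myosin-V walker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The myowalk model: a hierarchic coarse-grained myosin-V walker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myowalk)
```

## The model

`myowalk` simulates the processive walking of a two-headed myosin-V motor
along a closed circular actin track, at a deliberately coarse, mechanical
level of description. There is no molecular physics in the model: no
thermal energy scale, no solvent, no nucleotide chemistry. Molecules are
extended objects — spheres for domains, stick-capsules for
secondary-structure elements — organised in a three-level hierarchy
(molecule, domain, SSE stick) inside a tree of bounding volumes. Motion is
Brownian-like and inertia-free: at every frame each level of the hierarchy
receives a random displacement and rotation of fixed size, and the
integrity of the system is maintained entirely by pairwise distance
restraints, steric exclusion and a small set of non-physical orientation
corrections. What the model asks is: which mechanical ingredients are
*sufficient* for directional, processive stepping?

### The track

The actin filament is a ring of 52 dimer units spaced 5.70 nm apart
(circumference 296.4 nm, diameter just over 90 nm), closed so that no end
effects exist. The helical twist is distributed so that exactly eight half
repeats (37.05 nm each, "close to 36 nm") close the seam with no
discontinuity. Treating one *dimer* as the track unit makes the track size
N = 52 and the 5.70 nm unit spacing mutually consistent with the distance
bookkeeping D = C + L·N − S used by all analyses; the monomer spheres and
their twisted binding domains exist in the hierarchy for rendering and
geometry, not as separate binding targets. Because the twist carries
binding sites all the way around the filament tube, the *effective*
binding site of a unit is taken on the tube surface at the azimuth from
which the foot approaches. Sterically the filament body is a closed chain
of capsules of radius 2.8 nm between unit centres: a smooth tube, with
none of the artificial inter-unit pockets that a beads-only surface would
have. The ring is "well-restrained" by neighbour links at offsets 1, 2 and
4 (the short-range links applied twice per frame — in this model restraint
strength is set by how often a restraint is applied, not by larger steps).
The filament still distorts visibly under the reaction to myosin binding;
this is a feature of the model, not an artifact.

### The motor

Each half of the dimer is a foot (a 3 nm core sphere carrying two small
binding domains, the "toe" and the "heel", placed below the core so that a
well-posed approach has both domains closer to the filament than the foot
body) and a leg of IQ-motif segments. Leg lengths follow the printed
table: 9.3 nm (2 IQ), 14.60 nm (4 IQ), 19.90 nm (6 IQ). The leg is a
restrained chain — adjacent and adjacent-but-one links, two long braces
between the first and last segments (removed in the `weak_leg` variant),
and end-to-end braces that forbid arc-compression of the lever without
restricting the freely rotating ankle. The two halves are joined only at
the hip: a virtual hinge point per leg, restored to coincidence every
frame by translating one half (both halves when both are free; only the
free half when one is bound; the loosely bound half for tight + loose
pairs; a random half on ties), plus a permanent elastic link between the
two hinge points routed to the less firmly bound side.

### Binding, powerstroke, recovery

Binding is a two-stage state machine per head, re-evaluated every frame
with no hysteresis:

* **Capture (free → loose)** when the foot centroid comes within 15 nm of
  the filament axis *and* an unoccupied unit is in reach. Random
  translation is damped five-fold. The optional initial centroid
  attraction is off by default.
* **Loose, in the 12 nm zone**: random translation is frozen and rotation
  damped ten-fold; both binding domains are attracted to the closest
  unit's surface site (polarity without direction preference), repel-only
  restraints keep the fat core out of the track surface, and the binding
  face is steered toward the filament (roll and pitch toward zero, both
  fore–aft symmetric; yaw is left free). The choice of unit is
  re-evaluated every frame with a 2 nm dead-band, and units within two
  spacings of the partner's bound unit are excluded — tight binding
  engages the neighbouring sites, so a bound foot blocks them.
* **Tight** when, inside a 7 nm contact distance, both binding domains lie
  closer to the axis than the foot core. Restraints then hold the toe to
  the central and plus-side neighbour sites and the heel to the central
  and minus-side neighbour sites (this is where track polarity enters),
  rotation is damped a further ten-fold, and a non-physical correction
  rotates yaw and roll toward zero by at most 0.05 rad/frame. A tight head
  stays registered to its unit: if strain drags it nearer another unit, it
  demotes to loose rather than sliding.
* **Powerstroke**: once tight and aligned within ±1 rad in yaw and roll,
  the leg rotates about the foot centroid in the plane containing the
  local filament tangent, 0.05 rad (2.86°) per eligible frame, 70° in
  total (25 eligible frames); the head is then "swung" (rigor). Losing
  alignment or tight binding mid-swing halts the swing and reverts the
  head to loose binding.
* **Recovery**: only a free head re-primes, at double rate (0.1 rad/frame,
  13 frames), during which binding is forbidden.

The lever's angle relative to the foot is *maintained* only in the states
where the molecule holds a defined conformation: the swung (rigor) lever
is servo-held at its post-stroke elevation, and a free head's lever is
held at its current conformational angle — which, because the hinge is
pinned to the bound partner by the restoration, sweeps the free foot
forward about the hip during recovery. While loose or tight-pre-stroke the
ankle is free, so a landing head binds without lever strain. This division
resolves an ambiguity in the source description (a freely rotating ankle
versus a post-stroke conformation that must persist to generate strain);
maintaining the lever in all states was tried and systematically expelled
the newly landed head before it could stroke, inverting the release
statistics.

### Why it walks

Nothing in the rules prescribes direction. The bias emerges from the
asymmetry between the two bound heads when strain builds: the hinge
restoration and elastic link strain both feet, and either may slip
(roughly 50:50). If the *trailing*, post-powerstroke head slips, the
leader completes or holds its stroke, the hip is carried toward the plus
end, and the released head's recovery sweep plus the stiff-leg reach
constraint land it ahead of the new anchor. If the *leader* slips, it
stays near the filament and usually rebinds close to where it was — a null
cycle, occasionally a backstep. The stiff legs reach-limit the landing so
that the short-legged 2IQ model locks onto a three-unit separation.

Two bound post-powerstroke levers sharing one hinge are geometrically
infeasible with stiff legs, and the model encodes that infeasibility
explicitly rather than leaving it to the elastic network (whose capped
corrections would otherwise let a doubly-swung configuration settle by
quietly bending both legs): a powerstroke completing against a rigor
partner forces one head or the other to detach with even odds, and a
still-swung head cannot re-engage rigor while its partner holds rigor.
The SS cell of the coexistence table is therefore structurally zero, and
which head survives the resolution remains the 50:50 choice that
generates the directional statistics.

## Parameters

The interaction geometry is printed in the source material and is not
tuned: capture 15 nm, zone 12 nm, alignment ±1 rad, stroke 70° at
0.05 rad/frame, recovery at 0.1 rad/frame, 52 units at 5.70 nm, leg
lengths 9.3/14.60/19.90 nm. The magnitudes of the random moves and
restraint corrections are *not* printed anywhere and are treated as
calibration constants, chosen once against two anchors — the reported
mean lap time of the default long-legged model and the 2IQ three-unit
step lock — and then frozen:

| constant | value | units |
|---|---|---|
| molecule translation step | 0.8 | nm/frame |
| molecule rotation step | 0.08 | rad/frame |
| foot-group rotation step | 0.05 | rad/frame |
| domain jiggle | 0.10 | nm/frame |
| actin unit jiggle | 0.08 | nm/frame |
| restraint correction step (cap) | 0.25 | nm |
| binding restraint step (cap) | 0.25 | nm |
| lever servo cap | 0.15 | rad/frame |
| tight contact distance | 7 | nm |

Two numerical choices deserve note. First, restraint corrections are
proportional to the violation with the fixed step as a cap: a pure
fixed-size scheme deadlocks when several saturated restraints oppose one
another (constant opposing "forces" balance at arbitrary violation), while
the capped-proportional scheme relaxes those frustrated states and behaves
identically far from the target. Second, the orientation criterion for
tight binding compares the binding domains against the foot *core* rather
than the three-point centroid; the centroid version leaves sub-0.5 nm
margins that flicker under the domain jiggle.

## What the synthetic generator emulates

`make_fixture_staircase()` builds trajectories with programmed step
separations, exponentially distributed both-bound dwells and fixed search
gaps. It reproduces the *bookkeeping* of a walking run — attachment
states, cumulative distance, alternating heads — with exact ground truth
attached, and is the oracle for the analysis layer (step extraction
round-trips, dwell-rate recovery at k = 0.004–0.015 per frame, coexistence
recounts). It does not emulate pose wobble, loose-binding dither,
mid-swing reversals or detachment, so green analysis tests say nothing
about the dynamics; the simulation-level tests cover those.

## Problem sizes

The package's own ensembles (tests and the acceptance script) use five
seeded runs per leg-length model with a two-lap target and an 8 000-frame
budget, recorded every frame. At the frozen calibration most runs are
frame-limited rather than lap-limited; all stepping, dwell and duty
statistics are computed from whatever the runs produced, never from an
assumed run length.

## Known limitations

* The absolute clock is slow: the calibrated model walks at roughly
  0.002–0.005 units/frame against the reported 0.057 for the long-legged
  model, so reported lap times are several-fold longer than the published
  anchor (which the acceptance criteria treat as a calibration anchor, not
  a blind prediction). The leg-length *ordering* of velocities is
  reproduced.
* The long-legged mean separation comes out near 4 units against the
  published 6.07 ± 0.95: landings distribute over the reachable window
  rather than concentrating at full extension. The 2IQ three-unit lock,
  its near-degenerate spread, and the single-head duty ratio are
  reproduced; the double-headed duty ratio sits at the top of the
  published band because the two heads alternate almost perfectly (the
  model under-produces long both-bound dwells, which also leaves the
  dwell-time ordering across leg lengths unreproduced).
* Backstep fractions are in the published range for the 6IQ model but the
  strong 2IQ-versus-6IQ ordering is not cleanly reproduced.
* Long runs accumulate track distortion (the ring is never refreshed);
  ring-closure drift is measurable from the final-state coordinates.
* No load dependence, no explicit nucleotide states, no strain-gated ADP
  release: detachment kinetics are purely geometric.
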