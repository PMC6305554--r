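---
title: "Charting insect peripersonal space: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting insect peripersonal space: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periSpace)
```

## The scientific problem

A walking insect continuously samples the space around its body with its
antennae and legs. The region that any limb can physically reach — the
insect's *peripersonal space* — is where touch and movement can coincide,
and its inner structure matters for motor control: wherever the working
ranges of two limbs overlap, a contact sensed by one limb is a reachable
target for the other. periSpace implements this analysis chain for the
stick insect *Carausius morosus*: a standardized body model with leg and
antenna kinematics, occupancy-density estimation of per-limb movement
volumes, pairwise *affordance volumes* (overlaps), statistics of first
limb–rod contact locations, and a study of how complex a neural mapping
must be to translate the posture of one leg into the posture of a
neighboring leg with the same foot position.

Because the original motion-capture corpus is not publicly deposited, the
package pairs the analysis chain with a synthetic trial generator that
emulates the recording conditions. Everything downstream of trial input is
identical for synthetic and real data in the documented trial format.

## The body model and kinematic conventions

`standardBody()` returns the standardized adult female body: four
main-body segments (head, pro-/meso-/metathorax), insertion coordinates
and slanted thorax–coxa (ThCx) joint axes per leg, individual coxa /
femur / tibia / tarsus lengths, and total limb lengths. The published
measurement table is kept verbatim, including its two internal
inconsistencies (the left front leg's segments sum to 38.26 mm against a
printed total of 38.67 mm, and the right hind femur entry makes that leg's
sum exceed its printed total). We use the total column for length ratios
and the segment columns for kinematics, and do not attempt a correction.

Each leg has three degrees of freedom: protraction/retraction
$\alpha$ about a fixed, slanted ThCx axis (given by per-leg yaw and pitch
Euler angles), levation/depression $\beta$ of the femur, and the interior
femur–tibia angle $\gamma$ (extension/flexion, $180^\circ$ = straight).
The geometry is a planar two-link chain (femur, tibia) living in a "leg
plane" that contains the ThCx axis and rotates rigidly with $\alpha$; the
coxa is a fixed-length offset along the leg-plane base direction, and the
tarsus is a straight extension of the tibia (its joint angle was not
tracked experimentally, so full extension is assumed, maximizing radial
reach). Because the rotation axis is slanted, protraction/retraction
couples with pronation/supination of the leg plane, as it does in the
animal.

Inverse kinematics (`ikLeg`) inverts this chain analytically. Two
conventions pin down a unique solution branch: $\gamma \in (0, 180]$
("knee-up" flexion) and $\alpha \in (-90, 90]$ (the twin solution with the
leg plane flipped by $180^\circ$ is excluded). Within the per-leg
physiological bounds (`jointBounds()`), forward-then-inverse and
inverse-then-forward round trips are identities to well below $10^{-6}$
(degrees and mm respectively); this is checked over $10{,}000$ random
postures per leg in the test suite. Postures whose foot lies planar-behind
the coxa (strong depression) are handled by solving the two-link problem
with a signed planar abscissa, so the round trip also holds there.

The antennae are modeled as straight flagella of the published total
length with two rotational degrees of freedom (azimuth, elevation) at the
head insertion; the scape and pedicel are folded into the straight
segment, consistent with treating the flagellum as a set of points along
a single line. The published work does not specify antennal joint axis
conventions, so the two-angle spherical convention here is an internal
choice.

Angles are degrees everywhere in the interface; trigonometry is done in
radians internally. The body is rigid and straight (thoracic joints and
neck fixed), which is also the assumption used when aligning per-limb
grids into the common body frame.

## Volume estimation

The occupancy estimator follows a fixed recipe per limb and volume type:

1. **Point sampling** (`makeScheme`). *Action* volumes sample the whole
   limb: 8 equidistant points along the femur (fractions 0.1–1.0), 8
   along the tibia, 4 along the tarsus (20 points per frame), or 20
   points along the flagellum for antennae. *Contact* volumes sample the
   distal, contact-prone part: 10 points from scaling factor 0.67 to the
   distal limit — 1.0 for antennae, $(\text{tibia}+\text{tarsus})/\text{tibia}$
   for legs (about 1.33–1.39 tibia lengths). *Tip* volumes use the single
   most distal tracked point. Point $k$ of $n$ carries weight
   $2k/(n(n+1))$, ordered proximal to distal, so weights sum to exactly 1
   per frame and distal points (which sweep longer arcs per unit joint
   excursion) count more. The published distal limits (1.33–1.34 for
   front/hind, 1.38–1.39 for middle legs) disagree slightly with the
   ratio computed from the published segment lengths for two legs
   (1.346 for the left front, 1.378 for the right middle); the formula is
   authoritative here.
2. **Gridding** (`accumulateDensity`). Points are computed by forward
   kinematics from each trial animal's own body model, expressed relative
   to the limb base in the carrying-segment frame, scaled by the size
   standardization factor $B_{ref}/B_{curr}$ (reference over current
   segment-length sum: both femora + both tibiae + carrying segment for
   legs; both antennae + head for antennae), rounded to the nearest
   millimeter and accumulated on a $90^3$-node, 1 mm grid centered on the
   limb base. The $\pm 45$ mm extent exceeds the longest limb
   (38.67 mm). Out-of-extent weight is counted and reported as leakage.
3. **Smoothing** (`smoothDensity`). A $5^3$ cubic kernel with Gaussian
   weights ($\sigma = 1$ node) normalized to sum 1, truncated without
   renormalization at the grid edge (lost mass is recorded). In the grid
   interior the convolution conserves density exactly.
4. **Thresholding** (`extractVolume`). Nodes with density at least 1% of
   the grid maximum are retained (ties kept). On full-size synthetic runs
   this keeps well over 95% of the summed density, matching the behavior
   reported for the experimental data (95.3–98.6%); at very small trial
   counts retention is lower because the density is spread thinner
   relative to its maximum.

Affordance volumes (`intersectVolumes`) translate two limbs' binary
volumes into the common straight-body frame — limb-base offsets are
rounded to the 1 mm lattice so the node sets stay on a common grid — and
intersect node-wise. Intersection is commutative and idempotent and the
result is a subset of both parents; these properties are tested, along
with node-for-node equivalence of the whole accumulate–smooth–threshold
chain against a naive per-point reference implementation on small
fixtures.

Absolute volume sizes in ccm depend on the posture distribution of the
input data, so the published per-limb values are not reproduction targets
for synthetic runs. What the package does check, via
`checkReferenceConsistency()`, is every arithmetic identity among the
published numbers: percentage columns against ccm columns, length-ratio
and volume-ratio percentages, MSE means, RMSE relations and split sizes.
Two published numbers disagree with their own tables (a rear affordance
percentage printed as 24 where the table values give 22, and a swapped
left/right ordering of the middle-over-hind action ratio); these are
reported as "documented discrepancy", not failures.

## The synthetic trial generator

`generateWalkTrial`, `generateSearchTrial` and `generateRodTrial` emit
trials in the same structure the analysis consumes: 200 frames per
second, per-frame poses of head and thorax segments, three joint angles
per leg, two per antenna, plus derived world-frame foot and antennal-tip
positions. Defaults were chosen once, as plausible recording conditions,
and are not tuned to test outcomes:

* walking speed 15 mm/s, step-cycle frequency 1.5 Hz, alternating-tripod
  phasing (left/right and ipsilateral neighbors in anti-phase);
* joint oscillations spanning a fixed fraction (0.35 in walking, 0.48 in
  searching) of each leg's physiological range, which are the published
  per-leg angle bounds inside the affordance volumes; emitted angles are
  clamped so they never exit those bounds;
* smooth noise: white Gaussian noise low-pass filtered to a 5 Hz
  bandwidth and added in joint space, giving physically plausible
  trajectories at 200 fps;
* per-animal size jitter: all segment lengths scaled by one uniform
  factor within $\pm 10\%$, exercising the $B_{ref}/B_{curr}$
  standardization (gridded volumes are exactly size-invariant under this
  scaling, which is tested);
* rod trials place a horizontal rod (radius 1 mm — the published work
  does not state a rod diameter; contact is defined as distance-to-axis
  $\le$ radius) across the walkway beyond the antennal reach of the
  starting posture, so first contact happens during the approach, as in
  the experimental paradigm. The generator records ground-truth first
  contacts with its own frame-by-frame scan, which the vectorized
  detector in the contact module must reproduce exactly (a cross-module
  oracle in the tests).

What the generator does *not* emulate: calibrated stance geometry and
ground contact (the joint-angle zero conventions are internal, so
generated gaits are kinematically valid but not dynamically grounded),
postural correlations of real climbing, body pitch on stairs, and the
heavy-tailed variability of real behavior. Consequently, passing tests on
synthetic data validate the estimator machinery — conservation,
invariances, oracle equivalences, qualitative orderings — not the
absolute sizes or shapes real data would produce.

## Contact analysis

`detectFirstContact` samples each limb as a polyline at 1 mm arc-length
resolution (independent of the volume schemes) and returns the earliest
frame whose minimum point-to-rod-axis distance is within the rod radius;
within a frame, ties go to the most distal point. Leg contact locations
are standardized onto a common axis (`standardizeLegLocation`): femur
0–50%, tibia 50–100%, any tarsus contact = 100%. `summarizeContacts`
reports per-height medians, IQRs and ranges, the pooled histogram and
cumulative distribution, and the fraction of contacts in the distal third
(location $> 2/3$). With a tip-biased antennal sweep configuration
(narrow azimuth around the walking direction, elevation band matched to
the rod heights) the distal-third fraction on synthetic approaches is
0.8–1.0, the qualitative analog of the reported ~90%.

## Posture mapping

`buildPairs` turns an affordance volume into a supervised dataset: for
each grid node, inverse kinematics gives one joint-angle triplet per leg;
nodes failing either solution or the joint bounds are dropped and
counted. By construction both triplets place the tibia–tarsus joint at
the same point (asserted to $10^{-6}$ mm). `reachableAffordance`
constructs the purely geometric counterpart (all doubly reachable nodes
under the bounds), which yields large, noise-free datasets — for the
front–middle pair about 2,800 pairs.

The mapping study compares an analytic linear regression
(`fitLinear`, normal equation / pseudo-inverse; minimum-norm fallback for
rank-deficient designs) with single-hidden-layer feed-forward networks
(`trainMlp`): sigmoid hidden units, linear outputs, optional
input-to-output skip connections, Glorot uniform initialization,
mini-batches of 10, Adam at stock hyperparameters (learning rate 0.001,
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), batch order
reshuffled each epoch from the run seed. Design choices the source work
leaves open, fixed here: inputs are z-scored on training statistics while
outputs stay in raw degrees (so MSE is in deg$^2$); the 80% split uses
`floor` (matching the published 8,382 → 6,705); repetitions re-initialize
weights on a fixed split; the learning curve is stored every 10 epochs.

Correctness anchors in the tests: analytic gradients match finite
differences to $10^{-5}$; a planted affine map is recovered to
$10^{-8}$; a skip network with zeroed hidden-to-output weights and skip
weights set from the fitted regression reproduces the regression's test
MSE exactly (representational containment); training is bitwise
reproducible per seed. The qualitative complexity result — hidden sizes
1–2 without skips perform worse than the regression baseline
(bottleneck), sizes $\ge 8$ perform better — is reproduced on synthetic
affordance datasets with 500-epoch runs over five seeds; 500 epochs is
the package's standard desk-scale training length for these dataset
sizes, at which the effect is already stable, while full-length
(5,000-epoch) runs remain available through `mlpConfig`.

The published absolute MSE values (61.0, 10.0, 34.3, 18.2) describe
mappings over the experimentally observed posture distribution and are
out of reach of synthetic data by construction; the package instead
verifies their internal arithmetic (means of the per-DoF values, RMSE
relations) exactly.

## Pipeline and problem sizes

`runPipeline` composes the stages deterministically from one seed
(per-stage streams are derived from it) and assembles report tables whose
percentage columns are recomputed from their own ccm columns. Default
problem sizes are desk-scale: 6 walking + 3 searching trials of 2 s at
200 fps for volumes, 10 rod trials for contacts, and a reduced sweep
(hidden sizes 2 and 8, 2 repetitions, 150 epochs). The test suite uses
smaller sizes still; the acceptance script uses 12 + 6 trials for the
retention measurement and 30 rod trials for contact statistics.

## Known limitations

* The kinematic zero conventions are internal; joint angles are
  comparable within the package but not directly to measured angle traces
  from other conventions.
* Grid alignment rounds limb-base offsets to the 1 mm lattice; affordance
  volumes therefore carry up to half-node registration error, the same
  order as the gridding itself.
* The straight-flagellum antenna ignores flagellar bending during
  contact, which in real animals shifts post-contact location estimates.
* Synthetic gaits are kinematic, not dynamic: no ground-reaction
  constraint ties stance feet to the walkway.
* Boundary-envelope rendering of volumes (convex-hull style surfaces) is
  out of scope; volumes are exported as node sets.
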