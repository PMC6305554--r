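# periSpace

Charting the peripersonal space of a walking insect from whole-body
kinematics.

Stick insects sample the space around their body with two antennae and
six legs. The region any limb can reach — the insect's *peripersonal
space* — is where motor activity and touch can coincide, and wherever the
working ranges of two limbs overlap, a contact sensed by one limb becomes
a reachable target for the other (an *affordance volume*). periSpace
implements the full analysis chain for *Carausius morosus*, for
researchers in computational neuroethology, motor control and legged
robotics:

* a standardized body model with analytic forward/inverse kinematics of
  the 3-DoF legs (protraction/retraction α about a fixed slanted
  thorax–coxa axis, levation/depression β, femur–tibia extension γ) and
  2-DoF straight-flagellum antennae;
* occupancy-density estimation of per-limb **tip**, **contact** and
  **action volumes**: n weighted sample points per limb and frame
  (weights `2k/(n(n+1))`, k = 1…n proximal→distal, summing to 1 per
  frame), accumulated on a 90³-node 1 mm grid centered on the limb base,
  smoothed with a normalized 5³ Gaussian kernel (σ = 1 node) and
  thresholded at 1% of the maximum density;
* **affordance volumes** as node-wise intersections of two limbs' volumes
  in the common straight-body frame, with size standardization
  `B_ref/B_curr` per animal;
* first limb–rod **contact detection** (1 mm polyline sampling,
  distance-to-axis criterion, distal tie-break) and contact-location
  statistics (per-height medians/IQR, distal-third fraction);
* a **posture-mapping study**: matched joint-angle pairs with identical
  foot position from affordance volumes, analytic linear regression
  (pseudo-inverse) as baseline vs single-hidden-layer networks (sigmoid
  hidden units, linear outputs, optional skip connections, Adam,
  mini-batches of 10, Glorot init), swept over hidden-layer sizes — test
  MSE is reported in deg² per output joint;
* a synthetic motion-capture **trial generator** (walking, searching,
  rod climbing at 200 fps) with known ground truth, so the whole chain is
  testable without any external data.

## Worked example

```r
library(periSpace)

model <- standardBody()
lengthRatioPercent(limbLength(model, "L1"), limbLength(model, "LA"))
#> [1] 112     # front legs are 12% longer than the antennae

## chart the middle-leg action volume from synthetic walking trials
trials <- lapply(1:4, function(s) generateWalkTrial(model, generatorConfig(), s))
grid <- accumulateDensity(trials, "L2", makeScheme("action", "L2", model), model)
vol <- extractVolume(smoothDensity(grid))
vol
#> BinaryVolume: L2 action volume, 4.115 ccm (4115 nodes), retained 98.5%

## overlap with the hind leg: the region both legs can reach
v3 <- extractVolume(smoothDensity(accumulateDensity(
  trials, "L3", makeScheme("action", "L3", model), model)))
aff <- intersectVolumes(vol, v3, model)
aff
#> AffordanceVolume: L2 x L3, 1.638 ccm (1638 nodes)

## posture pairs with identical foot position, and the mapping benchmark
ds <- buildPairs(aff, "L2", "L3", model)
ds
#> PosturePairDataset: L2 -> L3 (front-to-back), 469 pairs (1169 nodes dropped)
sp <- splitDataset(ds, seed = 1)
fitLinear(sp$train, sp$test)$result
#> TrainResult (linear): mean MSE 12.271 deg^2 (RMSE 3.50 deg); per DoF
#>   alpha 27.064, beta 2.313, gamma 7.435
```

The 4.1 ccm middle-leg action volume is smaller than the published
~20 ccm because four 2-second synthetic trials sample far fewer postures
than the experimental corpus; the estimator, not the absolute size, is
the reproducible part. The retained 98.5% shows the 1%-of-maximum
threshold keeping essentially all of the density mass, as in the
original analysis (95.3–98.6%).

The regression error is the benchmark that hidden-layer networks must
beat: `complexitySweep(ds, c(1, 2, 8, 32))` shows 1–2 hidden units
bottlenecking above it and 8+ dropping below it. `runPipeline()` composes
all stages (trials → volumes → affordances → contacts → mapping) into
report tables, and `checkReferenceConsistency()` verifies every
arithmetic identity among the published reference numbers that ship with
the package.

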