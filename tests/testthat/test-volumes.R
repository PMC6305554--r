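test_that("sampling-scheme weights normalize and order proximal to distal", {
  for (n in c(1, 2, 5, 10, 20, 50, 100)) {
    w <- 2 * seq_len(n) / (n * (n + 1))
    expect_equal(sum(w), 1)
  }
  m <- standardBody()
  s <- makeScheme("contact", "LA", m)
  expect_equal(s$n, 10)
  expect_equal(s$weights, 2 * (1:10) / 110)
  expect_true(all(diff(s$weights) > 0))   # distal points weigh more
  a <- makeScheme("action", "L1", m)
  expect_equal(a$n, 20)
  expect_equal(sum(a$weights), 1)
  expect_equal(table(a$segments)[c("femur", "tibia", "tarsus")],
               table(factor(c(rep("femur", 8), rep("tibia", 8),
                              rep("tarsus", 4))))[c("femur", "tibia", "tarsus")])
  tp <- makeScheme("tip", "L2", m)
  expect_equal(tp$weights, 1)
})

test_that("leg contact schemes extend to the tarsus tip in tibia lengths", {
  m <- standardBody()
  expect_equal(max(makeScheme("contact", "L2", m)$fractions),
               (11.64 + 4.51) / 11.64, tolerance = 1e-12)
  ## the (tibia + tarsus) / tibia formula puts middle legs near 1.38 and
  ## front/hind legs near 1.33-1.35
  for (leg in c("L2", "R2"))
    expect_true(abs(max(makeScheme("contact", leg, m)$fractions) - 1.383) < 0.006)
  for (leg in c("L1", "R1", "L3", "R3")) {
    d <- max(makeScheme("contact", leg, m)$fractions)
    expect_true(d > 1.32 && d < 1.35)
  }
  expect_equal(min(makeScheme("contact", "LA", m)$fractions), 0.67)
})

test_that("accumulation conserves per-frame weight and matches a naive tally", {
  m <- standardBody()
  tr <- generateWalkTrial(m, fastCfg(sizeJitter = 0), 71L)
  scheme <- makeScheme("action", "L2", m)
  grid <- accumulateDensity(list(tr), "L2", scheme, m)
  expect_equal(sum(grid@density) + grid@leakage, nFrames(tr))

  ## naive reference: per-point loop, reimplemented from the definition
  small <- tr
  small@frames <- tr@frames[1:5, ]
  g5 <- accumulateDensity(list(small), "L2", scheme, m)
  ref <- array(0, rep(90, 3))
  A <- periSpace:::trialAngles(small, "L2")
  am <- small@bodyModel
  sfac <- sizeScalingFactor(referenceSegmentSum(m, "L2"),
                            referenceSegmentSum(am, "L2"))
  for (f in seq_len(nrow(A))) {
    J <- fkLeg(am, "L2", A[f, ])
    ends <- list(femur = J[c("CTr", "FTi"), ], tibia = J[c("FTi", "TiTa"), ],
                 tarsus = J[c("TiTa", "tip"), ])
    for (k in seq_len(scheme$n)) {
      sg <- ends[[scheme$segments[k]]]
      p <- sg[1, ] + scheme$fractions[k] * (sg[2, ] - sg[1, ])
      p <- (p - limbInsertion(am, "L2")) * sfac
      ij <- round(p) + 46   # 1-based index for origin -45
      if (all(ij >= 1 & ij <= 90))
        ref[ij[1], ij[2], ij[3]] <- ref[ij[1], ij[2], ij[3]] + scheme$weights[k]
    }
  }
  expect_equal(g5@density, ref, tolerance = 1e-12)
})

test_that("a single tip frame puts density 1 on exactly one node", {
  m <- standardBody()
  tr <- generateWalkTrial(m, fastCfg(sizeJitter = 0), 73L)
  tr@frames <- tr@frames[1, , drop = FALSE]
  g <- accumulateDensity(list(tr), "L1", makeScheme("tip", "L1", m), m)
  expect_equal(sum(g@density != 0), 1)
  expect_equal(sum(g@density), 1)
  ## a static posture held F frames concentrates density F on the same node
  trF <- generateWalkTrial(m, fastCfg(sizeJitter = 0), 73L)
  trF@frames <- trF@frames[rep(1, 7), ]
  gF <- accumulateDensity(list(trF), "L1", makeScheme("tip", "L1", m), m)
  expect_equal(max(gF@density), 7)
  expect_equal(sum(gF@density != 0), 1)
})

test_that("smoothing uses the normalized 5^3 Gaussian and conserves interior mass", {
  g <- periSpace:::emptyGrid("L1", "tip")
  g@density[45, 45, 45] <- 1
  g@frames <- 1
  s <- smoothDensity(g)
  expect_equal(sum(s@density), 1, tolerance = 1e-12)     # interior conservation
  ## kernel center weight from the closed-form Gaussian
  g1 <- exp(-(-2:2)^2 / 2); g1 <- g1 / sum(g1)
  expect_equal(s@density[45, 45, 45], g1[3]^3, tolerance = 1e-12)
  expect_equal(s@density[44, 45, 45], g1[2] * g1[3]^2, tolerance = 1e-12)
  ## support is exactly the 5^3 cube
  expect_equal(sum(s@density != 0), 125)
  ## edge truncation loses mass and reports it
  e <- periSpace:::emptyGrid("L1", "tip")
  e@density[1, 1, 1] <- 1; e@frames <- 1
  se <- smoothDensity(e)
  expect_lt(sum(se@density), 1)
  expect_equal(se@smoothLoss, 1 - sum(se@density), tolerance = 1e-12)
})

test_that("a uniform grid is unchanged by smoothing away from edges", {
  g <- periSpace:::emptyGrid("L1", "tip")
  g@density[] <- 0.5
  g@frames <- sum(g@density)
  s <- smoothDensity(g)
  interior <- s@density[10:80, 10:80, 10:80]
  expect_lt(max(abs(interior - 0.5)), 1e-12)
})

test_that("thresholding keeps ties, reports retained mass, and is monotone", {
  g <- periSpace:::emptyGrid("L2", "tip")
  g@density[] <- 2
  g@smoothed <- TRUE
  v <- extractVolume(g, 0.01)
  expect_equal(nrow(volumeNodes(v)), 90^3)
  expect_equal(v@retainedFraction, 1)
  ## single smoothed point mass: node set equals the kernel nodes above
  ## threshold, by brute-force enumeration
  p <- periSpace:::emptyGrid("L2", "tip")
  p@density[40, 45, 50] <- 1; p@frames <- 1
  sp <- smoothDensity(p)
  v1 <- extractVolume(sp, 0.01)
  thr <- 0.01 * max(sp@density)
  ref <- which(sp@density >= thr, arr.ind = TRUE) - 46L
  expect_setequal(periSpace:::nodeKeys(volumeNodes(v1)), periSpace:::nodeKeys(ref))
  ## raising the threshold never increases the volume
  fracs <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  sizes <- vapply(fracs, function(f) volumeSize(extractVolume(sp, f)), 1)
  expect_true(all(diff(sizes) <= 0))
  expect_error(extractVolume(periSpace:::emptyGrid("L2", "tip")),
               class = "periSpace_empty_volume")
})

test_that("affordance intersection is commutative, idempotent and bounded", {
  m <- standardBody()
  trs <- lapply(81:82, function(s) generateWalkTrial(m, fastCfg(), s))
  mk <- function(limb) extractVolume(smoothDensity(
    accumulateDensity(trs, limb, makeScheme("action", limb, m), m)))
  v2 <- mk("L2"); v3 <- mk("L3")
  ab <- intersectVolumes(v2, v3, m)
  ba <- intersectVolumes(v3, v2, m)
  expect_identical(volumeNodes(ab), volumeNodes(ba))     # commutative
  self <- intersectVolumes(v2, v2, m)
  expect_equal(volumeSize(self), volumeSize(v2))          # idempotent
  ## affordance nodes are a subset of both parents after registration
  k2 <- periSpace:::nodeKeys(periSpace:::bodyFrameNodes(v2, m))
  k3 <- periSpace:::nodeKeys(periSpace:::bodyFrameNodes(v3, m))
  ka <- periSpace:::nodeKeys(volumeNodes(ab))
  expect_true(all(ka %in% k2) && all(ka %in% k3))
  ## disjoint volumes yield an empty affordance volume
  vfar <- v3
  vfar@nodes <- volumeNodes(v3) + 500L
  expect_equal(volumeSize(intersectVolumes(v2, vfar, m)), 0)
  vbad <- v3; vbad@spacing <- 2
  expect_error(intersectVolumes(v2, vbad, m),
               class = "periSpace_incompatible_grids")
})

test_that("volume ratios round to integer percent", {
  expect_identical(volumeRatioPercent(8.736, 60.786), 14L)
  expect_identical(volumeRatioPercent(6.423, 19.937), 32L)
  expect_identical(volumeRatioPercent(3, 3), 100L)
  expect_error(volumeRatioPercent(1, 0), class = "periSpace_invalid_measurement")
})

test_that("size standardization makes gridded volumes size-invariant", {
  m <- standardBody()
  tr <- generateWalkTrial(m, fastCfg(sizeJitter = 0), 91L)
  scaled <- tr
  scaled@bodyModel <- scaleBody(tr@bodyModel, 1.15)
  g1 <- accumulateDensity(list(tr), "L2", makeScheme("action", "L2", m), m)
  g2 <- accumulateDensity(list(scaled), "L2", makeScheme("action", "L2", m), m)
  expect_equal(g1@density, g2@density)
})

test_that("volume grids and binary volumes round-trip through text files", {
  m <- standardBody()
  tr <- generateWalkTrial(m, fastCfg(), 95L)
  g <- smoothDensity(accumulateDensity(list(tr), "LA",
                                       makeScheme("tip", "LA", m), m))
  p <- withr::local_tempfile(fileext = ".txt")
  writeVolumeGrid(g, p)
  b <- readVolumeGrid(p)
  expect_equal(b@density, g@density, tolerance = 1e-15)
  expect_identical(b@limb, g@limb)
  v <- extractVolume(g)
  p2 <- withr::local_tempfile(fileext = ".txt")
  writeBinaryVolume(v, p2)
  v2 <- readBinaryVolume(p2)
  expect_identical(volumeNodes(v2), volumeNodes(v))
  expect_equal(volumeSize(v2), volumeSize(v))
})
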