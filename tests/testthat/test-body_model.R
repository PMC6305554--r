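test_that("standard body reproduces the published constants", {
  m <- standardBody()
  expect_equal(limbLength(m, "L1"), 38.67)
  expect_equal(limbLength(m, "LA"), 34.42)
  expect_equal(limbLength(m, "L2"), 29.68)
  expect_equal(unname(limbInsertion(m, "R2")), c(1.03, -1.70, -1.11))
  expect_equal(unname(limbInsertion(m, "L3")[2]), -unname(limbInsertion(m, "R3")[2]))
  expect_equal(unname(legSegmentLengths(m, "L1")),
               c(1.32, 16.57, 15.13, 5.24))
  expect_equal(segmentLength(m, "mesothorax"), 17.45)
  expect_equal(m@limbs$yaw[m@limbs$limb == "L3"], 114)
  expect_error(limbLength(m, "XX"), class = "periSpace_invalid_limb")
})

test_that("forward kinematics respects segment lengths and the chain limit", {
  m <- standardBody()
  A <- sampleAngles("L1", 50, seed = 7)
  J <- periSpace:::fkLegJoints(m, "L1", A)
  L <- legSegmentLengths(m, "L1")
  expect_equal(sqrt(rowSums((J$CTr - J$ThCx)^2)), rep(L[["coxa"]], 50))
  expect_equal(sqrt(rowSums((J$FTi - J$CTr)^2)), rep(L[["femur"]], 50))
  expect_equal(sqrt(rowSums((J$TiTa - J$FTi)^2)), rep(L[["tibia"]], 50))
  expect_equal(sqrt(rowSums((J$tip - J$TiTa)^2)), rep(L[["tarsus"]], 50))
  ## fully extended chain is collinear: tip distance equals the length sum
  ext <- fkLeg(m, "L1", c(0, 0, 180))
  expect_equal(sqrt(sum((ext["tip", ] - ext["ThCx", ])^2)), sum(L))
  ## tarsus tip collinear with knee and tibia-tarsus joint for any posture
  v1 <- J$TiTa - J$FTi; v2 <- J$tip - J$TiTa
  cr <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
              v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
              v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  expect_lt(max(abs(cr)), 1e-9)
})

test_that("fk and ik are mutually inverse over the physiological ranges", {
  m <- standardBody()
  for (leg in c("L1", "R1", "L2", "R2", "L3", "R3")) {
    A <- sampleAngles(leg, 500, seed = match(leg, c("L1", "R1", "L2", "R2", "L3", "R3")))
    P <- periSpace:::fkLegJoints(m, leg, A)$TiTa
    A2 <- ikLeg(m, leg, P)
    expect_lt(max(abs(A - A2)), 1e-6)                      # ik o fk identity
    P2 <- periSpace:::fkLegJoints(m, leg, A2)$TiTa
    expect_lt(max(abs(P - P2)), 1e-6)                      # fk o ik identity
    expect_true(all(A2[, 3] > 0 & A2[, 3] <= 180))
  }
})

test_that("ik agrees with a brute-force grid search", {
  m <- standardBody()
  target <- periSpace:::fkLegJoints(m, "L2", matrix(c(20, -40, 100), 1))$TiTa
  ## coarse-to-fine exhaustive search over the angle space, independent of
  ## the analytic solution
  best <- c(0, 0, 90); width <- c(180, 180, 90)
  for (it in 1:12) {
    g <- expand.grid(a = best[1] + seq(-width[1], width[1], length.out = 9),
                     b = best[2] + seq(-width[2], width[2], length.out = 9),
                     c = pmin(180, pmax(1e-3, best[3] +
                                          seq(-width[3], width[3], length.out = 9))))
    P <- periSpace:::fkLegJoints(m, "L2", as.matrix(g))$TiTa
    d <- rowSums(sweep(P, 2, as.vector(target))^2)
    best <- as.numeric(g[which.min(d), ])
    width <- width / 3
  }
  expect_lt(max(abs(best - ikLeg(m, "L2", as.vector(target)))), 0.1)
})

test_that("unreachable targets signal out-of-workspace", {
  m <- standardBody()
  far <- limbInsertion(m, "L1") + c(100, 0, 0)
  expect_error(ikLeg(m, "L1", far), class = "periSpace_out_of_workspace")
  A <- ikLeg(m, "L1", rbind(far, c(10, 18, -15)), onUnreachable = "na")
  expect_true(is.na(A[1, 1]) && !is.na(A[2, 1]))
})

test_that("segment-frame conversion is a rigid round trip", {
  pose <- c(3.2, -1.5, 8, 25, -10, 5)
  pts <- matrix(rnorm(30), 10, 3)
  back <- poseFromWorld(pose, poseToWorld(pose, pts))
  expect_lt(max(abs(back - pts)), 1e-12)
  ## pairwise distances preserved to 1e-9
  w <- poseToWorld(pose, pts)
  expect_lt(max(abs(dist(w) - dist(pts))), 1e-9)
})

test_that("bilateral symmetry holds on a symmetrized body", {
  m <- symmetricBody()
  A <- sampleAngles("L3", 20, seed = 3)
  JL <- periSpace:::fkLegJoints(m, "L3", A)$TiTa
  JR <- periSpace:::fkLegJoints(m, "R3", cbind(-A[, 1], A[, 2], A[, 3]))$TiTa
  expect_lt(max(abs(JL - JR %*% diag(c(1, -1, 1)))), 1e-9)
})

test_that("size scaling factor and length ratios behave as specified", {
  expect_equal(sizeScalingFactor(10, 10), 1)
  expect_equal(sizeScalingFactor(10, 9), 10 / 9)
  expect_error(sizeScalingFactor(0, 1), class = "periSpace_invalid_measurement")
  expect_identical(lengthRatioPercent(38.67, 34.42), 112L)
  expect_identical(lengthRatioPercent(38.67, 29.68), 130L)
  expect_identical(lengthRatioPercent(7, 7), 100L)
  expect_error(lengthRatioPercent(1, 0), class = "periSpace_invalid_measurement")
})

test_that("antenna kinematics places the tip at the flagellum length", {
  m <- standardBody()
  fk <- fkAntenna(m, "LA", c(20, 30))
  expect_equal(sqrt(sum((fk$tip - fk$base)^2)), limbLength(m, "LA"))
  fk2 <- fkAntenna(m, "LA", c(0, 0))
  expect_equal(unname(fk2$tip[1, ]),
               unname(limbInsertion(m, "LA") + c(limbLength(m, "LA"), 0, 0)))
})
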