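test_that("posture pairs coincide at the foot and respect bounds", {
  m <- standardBody()
  aff <- tinyAffordance(m)
  ds <- buildPairs(aff, "L2", "L3", m)
  expect_gt(nPairs(ds), 0)
  o2 <- c(periSpace:::segmentOriginX(m, "mesothorax"), 0, 0)
  p2 <- sweep(periSpace:::fkLegJoints(m, "L2", ds@senderAngles)$TiTa, 2, o2, "+")
  p3 <- periSpace:::fkLegJoints(m, "L3", ds@receiverAngles)$TiTa
  expect_lt(max(abs(p2 - p3)), 1e-6)
  expect_lt(max(abs(p2 - ds@positions)), 1e-6)
  b <- jointBounds("mid-hind")
  for (side in list(list(A = ds@senderAngles, leg = "L2"),
                    list(A = ds@receiverAngles, leg = "L3"))) {
    bb <- b[b$limb == side$leg, ]
    expect_true(all(side$A[, 1] >= bb$alphaMin & side$A[, 1] <= bb$alphaMax))
    expect_true(all(side$A[, 3] > 0 & side$A[, 3] < 180))
  }
  ## dataset size equals an independent per-node reachability scan
  nodes <- volumeNodes(aff)
  ok <- logical(nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    good <- TRUE
    for (leg in c("L2", "L3")) {
      ox <- c(periSpace:::segmentOriginX(m, limbCarrier(m, leg)), 0, 0)
      a <- tryCatch(ikLeg(m, leg, nodes[i, ] - ox), error = function(e) NULL)
      bb <- b[b$limb == leg, ]
      good <- good && !is.null(a) &&
        a[1] >= bb$alphaMin && a[1] <= bb$alphaMax &&
        a[2] >= bb$betaMin && a[2] <= bb$betaMax &&
        a[3] >= bb$gammaMin && a[3] <= bb$gammaMax
    }
    ok[i] <- good
  }
  expect_equal(nPairs(ds), sum(ok))
  expect_equal(ds@dropped, sum(!ok))
})

test_that("reversing a dataset swaps roles and keeps the pair count", {
  ds <- buildPairs(tinyAffordance(), "L2", "L3")
  rev <- reverseDataset(ds)
  expect_identical(rev@sender, "L3")
  expect_identical(rev@direction, "back-to-front")
  expect_identical(nPairs(rev), nPairs(ds))
  expect_identical(rev@senderAngles, ds@receiverAngles)
})

test_that("the 80% split has floor sizes, is disjoint and complete", {
  expect_identical(trainSize(5500), 4400L)
  expect_identical(trainSize(8382), 6705L)
  ds <- affineDataset(n = 10)$ds
  sp <- splitDataset(ds, seed = 3)
  expect_identical(nPairs(sp$train), 8L)
  expect_identical(nPairs(sp$test), 2L)
  all <- rbind(sp$train@senderAngles, sp$test@senderAngles)
  expect_setequal(apply(all, 1, paste, collapse = ","),
                  apply(ds@senderAngles, 1, paste, collapse = ","))
  tiny <- affineDataset(n = 4)$ds
  expect_error(splitDataset(tiny), class = "periSpace_empty_dataset")
})

test_that("regression recovers a planted affine map and its closed forms", {
  gen <- affineDataset(n = 300, seed = 13)
  sp <- splitDataset(gen$ds, seed = 5)
  fit <- fitLinear(sp$train, sp$test)
  expect_lt(max(abs(fit$map$W - gen$W)), 1e-8)
  expect_lt(max(abs(fit$map$b - gen$b)), 1e-8)
  expect_lt(fit$result@meanMSE, 1e-12)
  expect_false(fit$map$rankDeficient)
  ## constant target: zero weights, bias = mean, MSE = test variance
  cds <- gen$ds
  cds@receiverAngles <- matrix(rep(c(7, -2, 11), each = 300), 300, 3)
  spc <- splitDataset(cds, seed = 5)
  fc <- fitLinear(spc$train, spc$test)
  expect_lt(max(abs(fc$map$W)), 1e-10)
  expect_equal(fc$map$b, c(7, -2, 11), tolerance = 1e-10)
  expect_lt(fc$result@meanMSE, 1e-18)
})

test_that("train results keep their internal identities exactly", {
  r <- periSpace:::makeTrainResult(c(34.5, 45.3, 103.1))
  expect_identical(r@meanMSE, mean(c(34.5, 45.3, 103.1)))
  expect_identical(r@rmse, sqrt(r@meanMSE))
  expect_equal(round(r@meanMSE, 1), 61.0)
  r2 <- periSpace:::makeTrainResult(c(13.7, 8.4, 7.9))
  expect_equal(round(r2@meanMSE, 1), 10.0)
  expect_error(new("TrainResult", perDofMSE = c(1, 2, 3), meanMSE = 2.1,
                   rmse = sqrt(2.1), curve = data.frame(), config = list(),
                   seed = 1L),
               "meanMSE")
})

test_that("network gradients match finite differences", {
  cfg <- mlpConfig(hidden = 4, skip = TRUE, seed = 3)
  par <- periSpace:::withSeed(3, periSpace:::newMlpParams(cfg))
  set.seed(8)
  X <- matrix(rnorm(15), 5, 3)
  Y <- matrix(rnorm(15), 5, 3)
  lg <- periSpace:::mlpLossGrad(par, X, Y)
  eps <- 1e-6
  for (nm in names(lg$grad)) {
    for (i in seq_along(lg$grad[[nm]])) {
      pp <- pm <- par
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (periSpace:::mlpLossGrad(pp, X, Y)$loss -
                periSpace:::mlpLossGrad(pm, X, Y)$loss) / (2 * eps)
      expect_lt(abs(num - lg$grad[[nm]][i]) / max(1e-4, abs(num)), 1e-5)
    }
  }
})

test_that("the skip architecture contains the regression solution exactly", {
  ds <- buildPairs(tinyAffordance(), "L2", "L3")
  sp <- splitDataset(ds, seed = 7)
  fit <- fitLinear(sp$train, sp$test)
  net <- mlpFromLinearMap(fit$map, sp$train, hidden = 3)
  pred <- predictMlp(net, sp$test@senderAngles)
  mse <- mean(colMeans((pred - sp$test@receiverAngles)^2))
  expect_equal(mse, fit$result@meanMSE, tolerance = 1e-12)
})

test_that("training is bitwise deterministic and converges on a linear target", {
  gen <- affineDataset(n = 120, seed = 21)
  sp <- splitDataset(gen$ds, seed = 9)
  cfg <- mlpConfig(hidden = 8, epochs = 60, seed = 17)
  a <- trainMlp(sp$train, sp$test, cfg)
  b <- trainMlp(sp$train, sp$test, cfg)
  expect_identical(a$result@curve, b$result@curve)
  expect_identical(a$model$par, b$model$par)
  ## learning curve decreases substantially on a learnable target
  expect_lt(a$result@curve$train[nrow(a$result@curve)],
            a$result@curve$train[1])
})

test_that("sweep summaries agree with recomputation from the stored runs", {
  gen <- affineDataset(n = 80, seed = 31, noiseSD = 2)
  sw <- complexitySweep(gen$ds, hiddenSizes = c(2, 4), reps = 2,
                        cfg = mlpConfig(epochs = 20), seed = 5,
                        directions = "forward")
  runs <- sw$runs
  expect_true(all(c("direction", "hidden", "rep", "meanMSE") %in% names(runs)))
  for (h in c(2, 4)) {
    g <- runs[!is.na(runs$hidden) & runs$hidden == h, ]
    expect_equal(nrow(g), 2)
    srow <- sw$summary[!is.na(sw$summary$hidden) & sw$summary$hidden == h, ]
    expect_equal(srow$meanMSE, mean(g$meanMSE))
    expect_equal(srow$sdMSE, sd(g$meanMSE))
  }
  ## regression baseline present
  expect_true(any(is.na(runs$hidden)))
  ## per-run mean MSE equals the mean of the per-DoF columns
  expect_equal(runs$meanMSE,
               rowMeans(runs[, c("mseAlpha", "mseBeta", "mseGamma")]))
})

test_that("degenerate network configurations are rejected", {
  expect_error(mlpConfig(hidden = 0, skip = FALSE),
               class = "periSpace_config_error")
  expect_error(mlpConfig(epochs = 0), class = "periSpace_config_error")
  expect_error(buildPairs(tinyAffordance(), "L2", "L1"),
               class = "periSpace_config_error")
})

test_that("trained networks round-trip through the text serialization", {
  gen <- affineDataset(n = 60, seed = 41, noiseSD = 3)
  sp <- splitDataset(gen$ds, seed = 2)
  fit <- trainMlp(sp$train, sp$test, mlpConfig(hidden = 4, skip = TRUE,
                                               epochs = 10, seed = 6))
  p <- withr::local_tempfile(fileext = ".txt")
  writeMlpModel(fit$model, p)
  back <- readMlpModel(p)
  expect_equal(predictMlp(back, sp$test@senderAngles),
               predictMlp(fit$model, sp$test@senderAngles))
  expect_equal(back$par$W1, fit$model$par$W1)
  expect_equal(back$mu, unname(fit$model$mu))
})
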