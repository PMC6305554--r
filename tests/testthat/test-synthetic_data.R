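test_that("trial generation is deterministic under a fixed seed", {
  m <- standardBody()
  for (gen in list(function(s) generateWalkTrial(m, fastCfg(), s),
                   function(s) generateSearchTrial(m, fastCfg(), s),
                   function(s) generateRodTrial(m, fastCfg(), rodSpec(), s))) {
    a <- gen(11L); b <- gen(11L)
    expect_identical(a@frames, b@frames)
    expect_identical(a@bodyModel@limbs, b@bodyModel@limbs)
    expect_false(identical(a@frames, gen(12L)@frames))
  }
})

test_that("generated joint angles never exit the configured bounds", {
  m <- standardBody()
  for (tr in list(generateWalkTrial(m, fastCfg(), 21L),
                  generateSearchTrial(m, fastCfg(), 22L))) {
    for (leg in c("L1", "R1", "L2", "R2", "L3", "R3")) {
      b <- periSpace:::legBounds(leg)
      A <- periSpace:::trialAngles(tr, leg)
      expect_true(all(A[, 1] >= b$alphaMin & A[, 1] <= b$alphaMax))
      expect_true(all(A[, 2] >= b$betaMin & A[, 2] <= b$betaMax))
      expect_true(all(A[, 3] >= b$gammaMin & A[, 3] <= b$gammaMax))
    }
  }
})

test_that("stored foot positions are self-consistent with fk of the emitted angles", {
  m <- standardBody()
  tr <- generateWalkTrial(m, fastCfg(), 31L)
  am <- tr@bodyModel
  for (leg in c("L1", "L3")) {
    A <- periSpace:::trialAngles(tr, leg)
    foot <- periSpace:::fkLegJoints(am, leg, A)$TiTa
    carrier <- limbCarrier(am, leg)
    err <- max(abs(foot[, 1] + tr@frames[[paste0(carrier, "_x")]] -
                     tr@frames[[paste0(leg, "_foot_x")]]),
               abs(foot[, 2] - tr@frames[[paste0(leg, "_foot_y")]]),
               abs(foot[, 3] + tr@frames[[paste0(carrier, "_z")]] -
                     tr@frames[[paste0(leg, "_foot_z")]]))
    expect_lt(err, 1e-9)
  }
})

test_that("search trials exercise larger front-leg excursions than walk trials", {
  m <- standardBody()
  walk <- generateWalkTrial(m, generatorConfig(), 41L)
  search <- generateSearchTrial(m, generatorConfig(), 41L)
  exc <- function(tr, leg) {
    A <- periSpace:::trialAngles(tr, leg)
    apply(A, 2, function(x) diff(range(x)))
  }
  expect_true(all(exc(search, "L1") > exc(walk, "L1")))
  expect_true(all(exc(search, "R1") > exc(walk, "R1")))
  ## body stays put while searching
  expect_equal(diff(range(search@frames$prothorax_x)), 0)
})

test_that("frame count honors duration and sampling rate", {
  tr <- generateWalkTrial(standardBody(), generatorConfig(duration = 1.5), 5L)
  expect_identical(nFrames(tr), 300L)
  expect_equal(tr@fps, 200)
})

test_that("rod trials record ground truth consistent with geometry", {
  m <- standardBody()
  ## a rod far above any reachable point yields no contact
  high <- generateRodTrial(m, fastCfg(), rodSpec(height = 200), 51L)
  expect_true(all(vapply(high@groundTruth$contacts, is.null, logical(1))))
  ## a reachable rod yields an antennal contact with a plausible location
  tr <- generateRodTrial(m, generatorConfig(), rodSpec(height = 18), 52L)
  hits <- Filter(Negate(is.null), tr@groundTruth$contacts)
  expect_gt(length(hits), 0)
  for (e in hits) {
    expect_true(e$fraction >= 0 && e$fraction <= 1)
    expect_true(e$frame >= 0 && e$frame < nFrames(tr))
    ## the recorded contact point lies within a rod radius of the axis
    expect_lte(sqrt((e$point[1] - tr@rod$x)^2 + (e$point[3] - tr@rod$height)^2),
               tr@rod$radius + 1e-9)
  }
})

test_that("trial files round-trip losslessly and reject malformed input", {
  m <- standardBody()
  tr <- generateRodTrial(m, fastCfg(), rodSpec(height = 18), 61L)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTrial(tr, path)
  back <- readTrial(path)
  expect_identical(back@frames, tr@frames)
  expect_identical(back@bodyModel@limbs, tr@bodyModel@limbs)
  expect_equal(back@rod, tr@rod)
  expect_equal(back@groundTruth$contacts$LA$frame, tr@groundTruth$contacts$LA$frame)
  expect_identical(back@animal, tr@animal)

  ## dropped column -> parse error naming the file position
  lines <- readLines(path)
  hdrEnd <- max(grep("^#", lines))
  tab <- read.table(textConnection(lines[-seq_len(hdrEnd)]), header = TRUE, sep = ",")
  tab$L2_alpha <- NULL
  bad <- withr::local_tempfile(fileext = ".csv")
  con <- file(bad, "w")
  writeLines(lines[seq_len(hdrEnd)], con)
  write.table(tab, con, sep = ",", quote = FALSE, row.names = FALSE)
  close(con)
  expect_error(readTrial(bad), class = "periSpace_parse_error")
  expect_error(readTrial(bad), "L2_alpha")

  ## non-200 fps accepted but flagged
  tr2 <- tr; tr2@fps <- 100
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeTrial(tr2, p2)
  expect_message(readTrial(p2), "100 fps")
})

test_that("scaled bodies keep their proportions", {
  m <- standardBody()
  s <- scaleBody(m, 1.1)
  expect_equal(limbLength(s, "L1") / limbLength(m, "L1"), 1.1)
  expect_equal(referenceSegmentSum(s, "L2") / referenceSegmentSum(m, "L2"), 1.1)
  expect_error(generatorConfig(sizeJitter = 0.5), class = "periSpace_config_error")
})

test_that("antennal angles stay within the configured sweep bounds", {
  cfg <- generatorConfig()
  tr <- generateWalkTrial(standardBody(), cfg, 77L)
  for (ant in c("LA", "RA")) {
    sgn <- if (ant == "LA") 1 else -1
    A <- periSpace:::trialAngles(tr, ant)
    expect_true(all(A[, 1] >= sgn * cfg$azCenter - cfg$azAmp &
                      A[, 1] <= sgn * cfg$azCenter + cfg$azAmp))
    expect_true(all(A[, 2] >= cfg$elCenter - cfg$elAmp &
                      A[, 2] <= cfg$elCenter + cfg$elAmp))
  }
})
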