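# Shared fixtures, built in code.

# body model with exact left/right mirror symmetry (the published
# measurements differ slightly between sides; symmetry properties are
# checked on this symmetrized instance)
symmetricBody <- function() {
  m <- standardBody()
  l <- m@limbs
  for (p in list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"), c("LA", "RA"))) {
    i <- match(p[1], l$limb); j <- match(p[2], l$limb)
    for (cl in c("x", "z", "total", "coxa", "femur", "tibia", "tarsus"))
      l[[cl]][j] <- l[[cl]][i]
    l$y[j] <- -l$y[i]
    if (!is.na(l$yaw[i])) l$yaw[j] <- -l$yaw[i]
    if (!is.na(l$pitch[i])) l$pitch[j] <- l$pitch[i]
  }
  m@limbs <- l
  m
}

# random in-bounds joint-angle triplets for one leg
sampleAngles <- function(leg, n, seed = 1) {
  b <- periSpace:::legBounds(leg)
  withr::with_seed(seed, cbind(
    runif(n, b$alphaMin, b$alphaMax),
    runif(n, b$betaMin, b$betaMax),
    runif(n, b$gammaMin, b$gammaMax)))
}

# posture-pair dataset following an exactly affine map (for recovery tests)
affineDataset <- function(n = 200, seed = 1,
                          W = matrix(c(0.5, -0.2, 0.1, 0.3, 0.8, -0.4,
                                       0, 0.2, 1), 3, 3),
                          b = c(5, -3, 2), noiseSD = 0) {
  withr::with_seed(seed, {
    S <- matrix(runif(3 * n, -60, 60), n, 3)
    Y <- S %*% W + matrix(b, n, 3, byrow = TRUE)
    if (noiseSD > 0) Y <- Y + matrix(rnorm(3 * n, sd = noiseSD), n, 3)
    list(ds = new("PosturePairDataset", sender = "L2", receiver = "L3",
                  direction = "front-to-back", senderAngles = S,
                  receiverAngles = Y, positions = S * 0, nodes = S * 0,
                  dropped = 0),
         W = W, b = b)
  })
}

# small in-memory affordance volume around a point reachable by both legs
tinyAffordance <- function(model = standardBody(), legA = "L2", legB = "L3",
                           lo = c(17, -8, -16), hi = c(21, -4, -12)) {
  nodes <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                 z = lo[3]:hi[3]))
  storage.mode(nodes) <- "integer"
  colnames(nodes) <- c("x", "y", "z")
  new("AffordanceVolume", limbs = c(legA, legB), nodes = nodes,
      sizeCcm = nrow(nodes) / 1000, spacing = 1)
}

fastCfg <- function(duration = 0.5, ...) generatorConfig(duration = duration, ...)
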