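#' Configuration of the synthetic gait generator
#'
#' Parameters of the parametric walking / searching / rod-climbing trial
#' synthesis. Defaults emulate the recording conditions the analysis was
#' designed for: 200 frames per second, a 40 mm wide walkway, slow
#' straight walking, joint-angle excursions inside the per-leg
#' physiological ranges (\code{\link{jointBounds}}), rhythmic antennal
#' sweeping, and moderate per-animal size variation to exercise the size
#' standardization.
#'
#' @param duration trial duration in seconds.
#' @param fps sampling rate, frames per second.
#' @param speed walking speed in mm/s.
#' @param stepFreq step-cycle frequency in Hz.
#' @param walkAmpFrac fraction of the half joint range used as oscillation
#'   amplitude during walking.
#' @param searchAmpFrac as \code{walkAmpFrac} but for searching movements
#'   of the front legs and antennae (larger, by design).
#' @param noiseSD standard deviation of the smooth joint-angle noise, in
#'   degrees.
#' @param noiseCutHz low-pass cutoff of the noise, in Hz (noise is
#'   Gaussian increments smoothed to this bandwidth, giving physically
#'   plausible trajectories at 200 fps).
#' @param sizeJitter per-animal uniform size jitter fraction in [0, 0.2];
#'   all segment lengths of an animal are scaled by a common factor drawn
#'   from \code{1 +/- sizeJitter}.
#' @param bodyHeight height of the body axis above the walkway, mm.
#' @param azCenter,azAmp,elCenter,elAmp antennal sweep center and
#'   amplitude, degrees (azimuth given for the left antenna; mirrored on
#'   the right).
#' @param rodHeights default rod heights above the walkway, mm (the
#'   recordings this emulates used 18 and 36 mm, within an overall 5-50 mm
#'   range).
#' @param rodRadius rod radius, mm.
#' @return a validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(duration = 2, fps = 200, speed = 15,
                            stepFreq = 1.5, walkAmpFrac = 0.35,
                            searchAmpFrac = 0.48, noiseSD = 2,
                            noiseCutHz = 5, sizeJitter = 0.1,
                            bodyHeight = 8, azCenter = 25, azAmp = 30,
                            elCenter = 17, elAmp = 13,
                            rodHeights = c(18, 36), rodRadius = 1) {
  cfg <- list(duration = duration, fps = fps, speed = speed,
              stepFreq = stepFreq, walkAmpFrac = walkAmpFrac,
              searchAmpFrac = searchAmpFrac, noiseSD = noiseSD,
              noiseCutHz = noiseCutHz, sizeJitter = sizeJitter,
              bodyHeight = bodyHeight, azCenter = azCenter, azAmp = azAmp,
              elCenter = elCenter, elAmp = elAmp, rodHeights = rodHeights,
              rodRadius = rodRadius)
  bad <- duration <= 0 || fps <= 0 || speed < 0 || stepFreq <= 0 ||
    walkAmpFrac <= 0 || walkAmpFrac > 0.5 ||
    searchAmpFrac <= 0 || searchAmpFrac > 0.5 ||
    noiseSD < 0 || noiseCutHz <= 0 || sizeJitter < 0 || sizeJitter > 0.2 ||
    any(rodHeights < 5 | rodHeights > 50) || rodRadius <= 0
  if (bad) periStop("periSpace_config_error", "invalid generator configuration")
  structure(cfg, class = "GeneratorConfig")
}

#' Rod specification for rod-climbing trials
#'
#' The rod is horizontal, perpendicular to the walking direction (its axis
#' runs along y), at height \code{height} above the walkway and at
#' position \code{x} along the walking direction.
#'
#' @param height rod height above the walkway, mm (the apparatus range is
#'   5-50 mm; larger values are allowed to construct no-contact controls).
#' @param radius rod radius, mm.
#' @param x rod axis position along the walkway, mm; the default places
#'   the rod beyond the antennal reach of the starting posture, so contact
#'   happens during the approach.
#' @return a list of class \code{"RodSpec"}.
#' @export
rodSpec <- function(height = 18, radius = 1, x = 85) {
  if (radius <= 0) periStop("periSpace_config_error", "rod radius must be > 0")
  structure(list(height = height, radius = radius, x = x), class = "RodSpec")
}

## uniform per-animal size jitter: one common factor for all segments
jitterBody <- function(model, jitter) {
  if (jitter == 0) return(model)
  f <- runif(1, 1 - jitter, 1 + jitter)
  scaleBody(model, f)
}

#' Uniformly scale all segment lengths of a body model
#'
#' Scales every body-segment length, limb segment length, total limb
#' length and insertion coordinate by a common factor, emulating an animal
#' of different size with identical proportions.
#'
#' @inheritParams limbLength
#' @param factor positive scale factor.
#' @return the scaled \linkS4class{BodyModel}.
#' @export
scaleBody <- function(model, factor) {
  stopifnot(factor > 0)
  model@segments$length <- model@segments$length * factor
  for (cl in c("x", "y", "z", "total", "coxa", "femur", "tibia", "tarsus"))
    model@limbs[[cl]] <- model@limbs[[cl]] * factor
  validObject(model)
  model
}

## smooth noise: white Gaussian low-pass filtered with a Gaussian FIR whose
## bandwidth matches cutHz, rescaled to the requested SD
lowPassNoise <- function(n, fps, cutHz, sdTarget) {
  if (sdTarget == 0) return(numeric(n))
  sigma <- fps / (2 * pi * cutHz)      # samples
  half <- ceiling(3 * sigma)
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  x <- rnorm(n + 2 * half)
  y <- stats::filter(x, k, sides = 2)
  y <- y[(half + 1):(half + n)]
  y <- y - mean(y)
  s <- sd(y)
  if (is.na(s) || s == 0) return(numeric(n))
  y / s * sdTarget
}

## oscillation of one joint angle between bounds, with smooth noise,
## clamped so it never exits [lo, hi]
jointOsc <- function(t, lo, hi, freq, phase, ampFrac, cfg) {
  mid <- (lo + hi) / 2
  amp <- ampFrac * (hi - lo)
  x <- mid + amp * sin(2 * pi * freq * t + phase) +
    lowPassNoise(length(t), cfg$fps, cfg$noiseCutHz, cfg$noiseSD)
  pmin(pmax(x, lo), hi)
}

## leg phase offsets for an alternating-tripod walk: L1/R2/L3 vs R1/L2/R3
tripodPhase <- c(L1 = 0, R2 = 0, L3 = 0, R1 = pi, L2 = pi, R3 = pi)

segmentPoseCols <- function(seg) paste0(seg, c("_x", "_y", "_z", "_yaw", "_pitch", "_roll"))

## build the frames table plus world-frame foot/tip positions
assembleFrames <- function(model, cfg, t, bodyX, legA, antA, swing) {
  n <- length(t)
  fr <- data.frame(frame = seq_len(n) - 1L, time = t)
  for (seg in SEGMENT_IDS) {
    ox <- segmentOriginX(model, seg)
    fr[[paste0(seg, "_x")]] <- bodyX + ox
    fr[[paste0(seg, "_y")]] <- 0
    fr[[paste0(seg, "_z")]] <- cfg$bodyHeight
    fr[[paste0(seg, "_yaw")]] <- 0
    fr[[paste0(seg, "_pitch")]] <- 0
    fr[[paste0(seg, "_roll")]] <- 0
  }
  for (leg in LEG_IDS) {
    A <- legA[[leg]]
    fr[[paste0(leg, "_alpha")]] <- A[, 1]
    fr[[paste0(leg, "_beta")]] <- A[, 2]
    fr[[paste0(leg, "_gamma")]] <- A[, 3]
    foot <- fkLegJoints(model, leg, A)$TiTa
    ox <- segmentOriginX(model, limbCarrier(model, leg))
    fr[[paste0(leg, "_foot_x")]] <- foot[, 1] + bodyX + ox
    fr[[paste0(leg, "_foot_y")]] <- foot[, 2]
    fr[[paste0(leg, "_foot_z")]] <- foot[, 3] + cfg$bodyHeight
  }
  for (ant in ANTENNA_IDS) {
    A <- antA[[ant]]
    fr[[paste0(ant, "_az")]] <- A[, 1]
    fr[[paste0(ant, "_el")]] <- A[, 2]
    tip <- fkAntenna(model, ant, A)$tip
    ox <- segmentOriginX(model, "head")
    fr[[paste0(ant, "_tip_x")]] <- tip[, 1] + bodyX + ox
    fr[[paste0(ant, "_tip_y")]] <- tip[, 2]
    fr[[paste0(ant, "_tip_z")]] <- tip[, 3] + cfg$bodyHeight
  }
  for (leg in c("L1", "R1"))
    fr[[paste0(leg, "_swing")]] <- as.integer(swing[[leg]])
  fr
}

standPosture <- function(leg) {
  b <- legBounds(leg)
  c((b$alphaMin + b$alphaMax) / 2, (b$betaMin + b$betaMax) / 2,
    (b$gammaMin + b$gammaMax) / 2)
}

generateTrialCore <- function(model, cfg, seed, paradigm, rod = NULL) {
  withSeed(seed, {
    animal <- sprintf("synth-%06d", seed %% 1000000L)
    am <- jitterBody(model, cfg$sizeJitter)
    n <- round(cfg$duration * cfg$fps)
    t <- (seq_len(n) - 1) / cfg$fps
    moving <- paradigm != "search"
    bodyX <- if (moving) cfg$speed * t else rep(0, n)
    legA <- list(); swing <- list()
    for (leg in LEG_IDS) {
      b <- legBounds(leg)
      ph <- tripodPhase[[leg]]
      oscillate <- if (paradigm == "search") leg %in% c("L1", "R1") else TRUE
      amp <- if (paradigm == "search" && leg %in% c("L1", "R1"))
        cfg$searchAmpFrac else cfg$walkAmpFrac
      if (oscillate) {
        A <- cbind(
          jointOsc(t, b$alphaMin, b$alphaMax, cfg$stepFreq, ph, amp, cfg),
          jointOsc(t, b$betaMin, b$betaMax, cfg$stepFreq, ph + pi / 2, amp, cfg),
          jointOsc(t, b$gammaMin, b$gammaMax, cfg$stepFreq, ph + pi / 2, amp, cfg))
      } else {
        A <- matrix(standPosture(leg), n, 3, byrow = TRUE)
      }
      legA[[leg]] <- A
      ## swing when the leg is protracting (positive phase of the alpha
      ## oscillation for left legs, mirrored on the right)
      sgn <- if (substr(leg, 1, 1) == "L") 1 else -1
      swing[[leg]] <- sgn * sin(2 * pi * cfg$stepFreq * t + ph) > 0
    }
    antA <- list()
    ampF <- if (paradigm == "search") cfg$searchAmpFrac / cfg$walkAmpFrac else 1
    for (ant in ANTENNA_IDS) {
      sgn <- if (ant == "LA") 1 else -1
      ph <- if (ant == "LA") 0 else pi
      az <- sgn * cfg$azCenter +
        sgn * ampF * cfg$azAmp * sin(2 * pi * cfg$stepFreq * 1.3 * t + ph) +
        lowPassNoise(n, cfg$fps, cfg$noiseCutHz, cfg$noiseSD / 2)
      el <- cfg$elCenter +
        ampF * cfg$elAmp * sin(2 * pi * cfg$stepFreq * 1.7 * t + ph + pi / 3) +
        lowPassNoise(n, cfg$fps, cfg$noiseCutHz, cfg$noiseSD / 2)
      ## clamp to the configured sweep bounds, as for the legs
      azLo <- sgn * cfg$azCenter - ampF * cfg$azAmp
      azHi <- sgn * cfg$azCenter + ampF * cfg$azAmp
      az <- pmin(pmax(az, azLo), azHi)
      el <- pmin(pmax(el, cfg$elCenter - ampF * cfg$elAmp),
                 cfg$elCenter + ampF * cfg$elAmp)
      antA[[ant]] <- cbind(az, el)
    }
    fr <- assembleFrames(am, cfg, t, bodyX, legA, antA, swing)
    gt <- list()
    if (paradigm == "rod") {
      gt <- rodGroundTruth(am, cfg, fr, rod)
      gt$swing <- swing[c("L1", "R1")]
    }
    new("Trial", animal = animal, paradigm = paradigm, fps = cfg$fps,
        seed = as.integer(seed), bodyModel = am, frames = fr,
        rod = if (is.null(rod)) list() else unclass(rod), groundTruth = gt)
  })
}

#' Generate synthetic motion-capture trials
#'
#' \code{generateWalkTrial} synthesizes straight walking along the
#' walkway: the body translates forward at constant speed while all six
#' legs follow smooth periodic swing/stance joint-angle oscillations in
#' alternating-tripod coordination (left/right anti-phase, ipsilateral
#' neighbors anti-phase), with band-limited Gaussian noise, all angles
#' clamped inside the per-leg physiological bounds. The antennae sweep
#' rhythmically. \code{generateSearchTrial} keeps the body stationary at
#' the walkway edge and oscillates only front legs and antennae, with
#' larger amplitudes. \code{generateRodTrial} adds a horizontal rod across
#' the walkway and records, as generator ground truth, the first frame and
#' arc-length location at which any sampled point of an antenna or front
#' leg comes within the rod radius (per limb; absent if no contact
#' occurs).
#'
#' All generators are deterministic for a fixed seed.
#'
#' @param model the reference \linkS4class{BodyModel}; each trial animal is
#'   a size-jittered copy.
#' @param cfg a \code{\link{generatorConfig}}.
#' @param seed integer seed.
#' @param rod a \code{\link{rodSpec}}.
#' @return a \linkS4class{Trial}.
#' @export
generateWalkTrial <- function(model = standardBody(), cfg = generatorConfig(),
                              seed = 1L) {
  generateTrialCore(model, cfg, seed, "walk")
}

#' @rdname generateWalkTrial
#' @export
generateSearchTrial <- function(model = standardBody(), cfg = generatorConfig(),
                                seed = 1L) {
  generateTrialCore(model, cfg, seed, "search")
}

#' @rdname generateWalkTrial
#' @export
generateRodTrial <- function(model = standardBody(), cfg = generatorConfig(),
                             rod = rodSpec(), seed = 1L) {
  generateTrialCore(model, cfg, seed, "rod", rod = rod)
}

## --- generator-side contact ground truth -------------------------------
## Straightforward per-frame scan, kept independent of the vectorized
## detector in the contact-analysis module (same sampling definition, own
## arithmetic): limbs are polylines sampled at 1 mm arc length; contact is
## distance to the rod axis <= radius; ties go to the most distal point.
rodGroundTruth <- function(model, cfg, fr, rod) {
  events <- list()
  for (limb in c("LA", "RA", "L1", "R1")) {
    samp <- limbSampling(model, limb)
    carrier <- limbCarrier(model, limb)
    base <- limbInsertion(model, limb)
    reach <- if (isAntenna(limb)) limbLength(model, limb)
             else sum(legSegmentLengths(model, limb))
    ev <- NULL
    for (i in seq_len(nrow(fr))) {
      pose <- c(fr[[paste0(carrier, "_x")]][i], fr[[paste0(carrier, "_y")]][i],
                fr[[paste0(carrier, "_z")]][i])
      ## prune frames where even a fully extended limb cannot reach the rod
      bw <- base + pose
      if (sqrt((bw[1] - rod$x)^2 + (bw[3] - rod$height)^2) >
            reach + rod$radius) next
      if (isAntenna(limb)) {
        ang <- c(fr[[paste0(limb, "_az")]][i], fr[[paste0(limb, "_el")]][i])
        fk <- fkAntenna(model, limb, ang)
        pts <- outer(1 - samp$within, fk$base[1, ]) +
          outer(samp$within, fk$tip[1, ])
      } else {
        ang <- c(fr[[paste0(limb, "_alpha")]][i], fr[[paste0(limb, "_beta")]][i],
                 fr[[paste0(limb, "_gamma")]][i])
        J <- fkLeg(model, limb, ang)
        a <- rbind(femur = J["CTr", ], tibia = J["FTi", ], tarsus = J["TiTa", ])
        b <- rbind(femur = J["FTi", ], tibia = J["TiTa", ], tarsus = J["tip", ])
        pts <- (1 - samp$within) * a[samp$segment, ] +
          samp$within * b[samp$segment, ]
      }
      pts <- sweep(pts, 2, pose, "+")   # synthetic poses carry no rotation
      d <- sqrt((pts[, 1] - rod$x)^2 + (pts[, 3] - rod$height)^2)
      hit <- which(d <= rod$radius)
      if (length(hit)) {
        best <- hit[d[hit] == min(d[hit])]
        k <- max(best)                     # distal tie-break
        ev <- list(frame = fr$frame[i], fraction = samp$fraction[k],
                   segment = samp$segment[k],
                   point = pts[k, ], height = rod$height)
        break
      }
    }
    events[[limb]] <- ev
  }
  frames <- vapply(events, function(e) if (is.null(e)) NA_real_ else e$frame,
                   numeric(1))
  first <- if (all(is.na(frames))) NULL else names(which.min(frames))
  list(contacts = events, firstLimb = first)
}

## --- trial text serialization ------------------------------------------

fmtNum <- function(x) sprintf("%.17g", x)

#' Write / read a trial as delimited text
#'
#' One file per trial: '#'-prefixed header lines carry the metadata
#' (animal id, paradigm, fps, seed, rod spec, the trial animal's body
#' model, and any recorded ground-truth contact events), followed by a
#' comma-separated table with one row per frame. The round trip is
#' lossless (numbers serialized with 17 significant digits).
#'
#' @param trial a \linkS4class{Trial}.
#' @param path file path.
#' @return \code{readTrial} returns the reconstructed
#'   \linkS4class{Trial}. Files with a sampling rate other than 200 fps
#'   are accepted with a message.
#' @export
writeTrial <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  h <- c(paste0("# animal = ", trial@animal),
         paste0("# paradigm = ", trial@paradigm),
         paste0("# fps = ", fmtNum(trial@fps)),
         paste0("# seed = ", trial@seed))
  if (length(trial@rod))
    h <- c(h, paste0("# rod = ", paste(fmtNum(c(trial@rod$height,
                                                trial@rod$radius,
                                                trial@rod$x)), collapse = ",")))
  m <- trial@bodyModel
  h <- c(h, paste0("# segment.", m@segments$segment, " = ",
                   fmtNum(m@segments$length)))
  for (i in seq_len(nrow(m@limbs))) {
    r <- m@limbs[i, ]
    h <- c(h, paste0("# limb.", r$limb, " = ", r$carrier, ",",
                     paste(fmtNum(c(r$x, r$y, r$z, r$yaw, r$pitch, r$total,
                                    r$coxa, r$femur, r$tibia, r$tarsus)),
                           collapse = ",")))
  }
  for (lb in names(trial@groundTruth$contacts)) {
    e <- trial@groundTruth$contacts[[lb]]
    h <- c(h, paste0("# contact.", lb, " = ",
                     if (is.null(e)) "none"
                     else paste(c(e$frame, fmtNum(e$fraction), e$segment),
                                collapse = ",")))
  }
  writeLines(h, con)
  fr <- trial@frames
  for (cl in names(fr)) if (is.double(fr[[cl]])) fr[[cl]] <- fmtNum(fr[[cl]])
  write.table(fr, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrial
#' @export
readTrial <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  kv <- strsplit(sub("^# ", "", lines[hdr]), " = ")
  bad <- which(lengths(kv) != 2)
  if (length(bad))
    periStop("periSpace_parse_error",
             sprintf("malformed header at line %d of %s", hdr[bad[1]], path))
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  getv <- function(k) vals[match(k, keys)]
  segs <- sub("^segment\\.", "", grep("^segment\\.", keys, value = TRUE))
  segments <- data.frame(segment = segs,
                         length = as.numeric(vals[grep("^segment\\.", keys)]))
  limbKeys <- grep("^limb\\.", keys)
  num <- function(s) ifelse(s == "NA", NA_real_, suppressWarnings(as.numeric(s)))
  limbs <- do.call(rbind, lapply(limbKeys, function(i) {
    f <- strsplit(vals[i], ",")[[1]]
    data.frame(limb = sub("^limb\\.", "", keys[i]), carrier = f[1],
               x = num(f[2]), y = num(f[3]),
               z = num(f[4]), yaw = num(f[5]),
               pitch = num(f[6]), total = num(f[7]),
               coxa = num(f[8]), femur = num(f[9]),
               tibia = num(f[10]), tarsus = num(f[11]))
  }))
  model <- new("BodyModel", segments = segments, limbs = limbs)
  rod <- list()
  if (!is.na(getv("rod"))) {
    f <- as.numeric(strsplit(getv("rod"), ",")[[1]])
    rod <- list(height = f[1], radius = f[2], x = f[3])
  }
  gt <- list()
  ck <- grep("^contact\\.", keys)
  if (length(ck)) {
    contacts <- lapply(ck, function(i) {
      if (vals[i] == "none") return(NULL)
      f <- strsplit(vals[i], ",")[[1]]
      list(frame = as.numeric(f[1]), fraction = as.numeric(f[2]),
           segment = f[3], height = rod$height)
    })
    names(contacts) <- sub("^contact\\.", "", keys[ck])
    frames <- vapply(contacts, function(e) if (is.null(e)) NA_real_ else e$frame,
                     numeric(1))
    gt <- list(contacts = contacts,
               firstLimb = if (all(is.na(frames))) NULL
                           else names(which.min(frames)))
  }
  body <- lines[-hdr]
  fr <- tryCatch(
    read.table(textConnection(body), header = TRUE, sep = ","),
    error = function(e) periStop(
      "periSpace_parse_error",
      sprintf("malformed frame table in %s (near line %d): %s",
              path, length(hdr) + 1L, conditionMessage(e))))
  need <- c("frame", "time", unlist(lapply(SEGMENT_IDS, segmentPoseCols)),
            paste0(rep(LEG_IDS, each = 3), c("_alpha", "_beta", "_gamma")),
            paste0(rep(ANTENNA_IDS, each = 2), c("_az", "_el")))
  ## restore column types: frame and swing flags are integer, all other
  ## numeric columns double (read.table infers integer for whole numbers)
  for (cl in names(fr)) {
    if (cl == "frame" || grepl("_swing$", cl)) {
      fr[[cl]] <- as.integer(fr[[cl]])
    } else if (is.numeric(fr[[cl]])) {
      fr[[cl]] <- as.double(fr[[cl]])
    }
  }
  miss <- setdiff(need, names(fr))
  if (length(miss))
    periStop("periSpace_parse_error",
             sprintf("missing column(s) %s in %s (header ends at line %d)",
                     paste(miss, collapse = ", "), path, max(hdr)))
  fps <- as.numeric(getv("fps"))
  if (fps != 200)
    message("note: trial ", path, " sampled at ", fps, " fps (expected 200)")
  new("Trial", animal = getv("animal"), paradigm = getv("paradigm"),
      fps = fps, seed = as.integer(getv("seed")), bodyModel = model,
      frames = fr, rod = rod, groundTruth = gt)
}

setMethod("show", "Trial", function(object) {
  cat(sprintf("Trial: %s '%s', %d frames at %g fps (%.2f s), seed %d\n",
              object@paradigm, object@animal, nrow(object@frames),
              object@fps, nrow(object@frames) / object@fps, object@seed))
  if (length(object@rod))
    cat(sprintf("  rod at x = %g mm, height %g mm, radius %g mm\n",
                object@rod$x, object@rod$height, object@rod$radius))
})

#' Number of frames in a trial
#' @param trial a \linkS4class{Trial}.
#' @export
nFrames <- function(trial) nrow(trial@frames)
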