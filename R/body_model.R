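#' Standardized stick-insect body model
#'
#' Returns the standardized body shape of an adult female
#' \emph{Carausius morosus}: mean segment lengths, limb insertion
#' coordinates in the carrying-segment frame, the yaw/pitch Euler angles of
#' the slanted thorax-coxa rotation axes, and the individual leg segment
#' lengths. These constants define the reference body onto which all
#' trials are standardized before volumes are gridded.
#'
#' Note that the published segment-length columns and the total-length
#' column are not perfectly consistent for two legs (the segments of L1 sum
#' to 38.26 mm against a total of 38.67 mm, and the R3 femur entry makes
#' that leg's sum exceed its printed total). Both are kept verbatim: the
#' total column is used for length ratios, the segment columns for
#' kinematics.
#'
#' @return a \linkS4class{BodyModel}.
#' @examples
#' m <- standardBody()
#' limbLength(m, "L1")            # 38.67 mm
#' limbInsertion(m, "R2")         # c(1.03, -1.70, -1.11)
#' @export
standardBody <- function() {
  segments <- data.frame(
    segment = SEGMENT_IDS,
    length = c(4.30, 3.76, 17.45, 11.87))
  limbs <- data.frame(
    limb    = c("LA", "RA", "L1", "R1", "L2", "R2", "L3", "R3"),
    carrier = c("head", "head", "prothorax", "prothorax",
                "mesothorax", "mesothorax", "metathorax", "metathorax"),
    ## antennal x insertions differ by 0.01 mm left/right in the published
    ## measurements; kept verbatim
    x = c(3.88, 3.87, 2.03, 2.03, 1.03, 1.03, 1.34, 1.34),
    y = c(0.95, -0.95, 1.33, -1.33, 1.70, -1.70, 1.67, -1.67),
    z = c(0.84, 0.84, -0.73, -0.73, -1.11, -1.11, -1.05, -1.05),
    yaw   = c(NA, NA, 84, -84, 92, -92, 114, -114),
    pitch = c(NA, NA, 34, 34, 37, 37, 29, 29),
    total  = c(34.42, 34.44, 38.67, 38.60, 29.68, 29.76, 35.64, 35.51),
    coxa   = c(NA, NA, 1.32, 1.32, 1.42, 1.42, 1.54, 1.54),
    femur  = c(NA, NA, 16.57, 16.48, 12.12, 12.16, 14.55, 15.60),
    tibia  = c(NA, NA, 15.13, 15.61, 11.64, 11.75, 14.65, 14.71),
    tarsus = c(NA, NA, 5.24, 5.18, 4.51, 4.44, 4.77, 4.79))
  new("BodyModel", segments = segments, limbs = limbs)
}

limbRow <- function(model, limb) {
  i <- match(limb, model@limbs$limb)
  if (is.na(i)) periStop("periSpace_invalid_limb", paste("unknown limb id:", limb))
  model@limbs[i, ]
}

#' BodyModel accessors
#'
#' @param model a \linkS4class{BodyModel}.
#' @param limb a limb id (\code{"L1","R1","L2","R2","L3","R3","LA","RA"}).
#' @return \code{limbLength}: total limb length (mm); \code{limbInsertion}:
#'   insertion point in the carrying-segment frame (mm);
#'   \code{limbCarrier}: carrying segment id; \code{segmentLength}: length
#'   of a body segment (mm); \code{legSegmentLengths}: named coxa / femur /
#'   tibia / tarsus lengths of a leg (mm).
#' @export
limbLength <- function(model, limb) limbRow(model, limb)$total

#' @rdname limbLength
#' @export
limbInsertion <- function(model, limb) {
  r <- limbRow(model, limb)
  c(x = r$x, y = r$y, z = r$z)
}

#' @rdname limbLength
#' @export
limbCarrier <- function(model, limb) limbRow(model, limb)$carrier

#' @rdname limbLength
#' @param segment a body segment id.
#' @export
segmentLength <- function(model, segment) {
  i <- match(segment, model@segments$segment)
  if (is.na(i)) periStop("periSpace_invalid_limb", paste("unknown segment:", segment))
  model@segments$length[i]
}

#' @rdname limbLength
#' @export
legSegmentLengths <- function(model, limb) {
  if (!limb %in% LEG_IDS) periStop("periSpace_invalid_limb", "not a leg id")
  r <- limbRow(model, limb)
  c(coxa = r$coxa, femur = r$femur, tibia = r$tibia, tarsus = r$tarsus)
}

isLeg <- function(limb) limb %in% LEG_IDS
isAntenna <- function(limb) limb %in% ANTENNA_IDS

setMethod("show", "BodyModel", function(object) {
  cat("BodyModel:", nrow(object@limbs), "limbs on",
      nrow(object@segments), "body segments\n")
  cat("  body length:",
      format(sum(object@segments$length), digits = 4), "mm\n")
  cat("  limb totals (mm):",
      paste(object@limbs$limb, format(object@limbs$total), collapse = ", "),
      "\n")
})

## x-offset of each segment origin along the straight standardized body.
## Segment frames sit at the posterior boundary of their segment, x forward;
## the body frame origin is the posterior end of the metathorax.
segmentOriginX <- function(model, segment) {
  L <- function(s) segmentLength(model, s)
  switch(segment,
    metathorax = 0,
    mesothorax = L("metathorax"),
    prothorax  = L("metathorax") + L("mesothorax"),
    head       = L("metathorax") + L("mesothorax") + L("prothorax"),
    periStop("periSpace_invalid_limb", paste("unknown segment:", segment)))
}

#' Limb base position in the common (straight-body) frame
#'
#' Position of a limb's basal joint (thorax-coxa joint of a leg, head-scape
#' joint of an antenna) in the body frame of the straight, rigid
#' standardized body, with the origin at the posterior end of the
#' metathorax and x pointing forward.
#'
#' @inheritParams limbLength
#' @return numeric(3) position in mm.
#' @export
limbBaseBody <- function(model, limb) {
  r <- limbRow(model, limb)
  c(segmentOriginX(model, r$carrier) + r$x, r$y, r$z)
}

## Fixed per-leg frame: the unit ThCx rotation axis u (from the yaw/pitch
## Euler angles of the resting coxa) and an orthonormal basis (e1, e2) of
## its normal plane, with e1 the forward direction projected off the axis.
legAxisFrame <- function(model, leg) {
  r <- limbRow(model, leg)
  u <- as.vector(rotYPR(r$yaw, r$pitch) %*% c(0, 0, 1))
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  list(u = u, e1 = e1, e2 = e2)
}

#' Forward kinematics of a leg
#'
#' Computes the joint positions of a leg in its carrying-segment frame from
#' the three joint angles: protraction/retraction \code{alpha} about the
#' fixed slanted thorax-coxa axis, levation/depression \code{beta} of the
#' femur within the leg plane, and the interior femur-tibia angle
#' \code{gamma} (extension/flexion; 180 degrees = fully extended). The leg
#' plane contains the ThCx axis and rotates rigidly with \code{alpha}; the
#' coxa is a fixed-length offset along the leg-plane base direction; the
#' tarsus is treated as a straight extension of the tibia (the tibia-tarsus
#' angle is fixed at 0, maximally extending the radial working range).
#'
#' @inheritParams limbLength
#' @param leg a leg id.
#' @param angles numeric(3) \code{c(alpha, beta, gamma)} in degrees, or an
#'   n x 3 matrix of angle triplets.
#' @return for a single triplet, a 5 x 3 matrix with rows \code{ThCx},
#'   \code{CTr}, \code{FTi}, \code{TiTa}, \code{tip}; for a matrix input, a
#'   list of five n x 3 matrices with those names.
#' @examples
#' m <- standardBody()
#' fkLeg(m, "L1", c(10, -30, 120))
#' @export
fkLeg <- function(model, leg, angles) {
  single <- is.null(dim(angles))
  A <- if (single) matrix(angles, 1, 3) else angles
  if (!all(is.finite(A))) periStop("periSpace_invalid_angles", "angles must be finite")
  j <- fkLegJoints(model, leg, A)
  if (single) {
    out <- rbind(j$ThCx[1, ], j$CTr[1, ], j$FTi[1, ], j$TiTa[1, ], j$tip[1, ])
    rownames(out) <- c("ThCx", "CTr", "FTi", "TiTa", "tip")
    out
  } else j
}

## vectorized core: A is n x 3 (degrees); returns list of n x 3 matrices
fkLegJoints <- function(model, leg, A) {
  if (!isLeg(leg)) periStop("periSpace_invalid_limb", paste("not a leg:", leg))
  fr <- legAxisFrame(model, leg)
  L <- legSegmentLengths(model, leg)
  ins <- limbInsertion(model, leg)
  a <- deg2rad(A[, 1]); b <- deg2rad(A[, 2]); g <- deg2rad(A[, 3])
  d <- outer(cos(a), fr$e1) + outer(sin(a), fr$e2)      # leg-plane base dir
  f <- cos(b) * d + outer(sin(b), fr$u)                 # femur direction
  m <- sin(b) * d - outer(cos(b), fr$u)                 # in-plane flexion dir
  t <- -cos(g) * f + sin(g) * m                         # tibia direction
  n <- nrow(A)
  ThCx <- matrix(ins, n, 3, byrow = TRUE)
  CTr <- ThCx + L["coxa"] * d
  FTi <- CTr + L["femur"] * f
  TiTa <- FTi + L["tibia"] * t
  tip <- TiTa + L["tarsus"] * t
  list(ThCx = ThCx, CTr = CTr, FTi = FTi, TiTa = TiTa, tip = tip)
}

#' Inverse kinematics of a leg
#'
#' Finds the joint-angle triplet that places the tibia-tarsus joint at a
#' target point in the carrying-segment frame. A single solution branch is
#' returned: \code{alpha} in (-90, 90] degrees (the leg plane faces
#' forward/lateral) and \code{gamma} in (0, 180] (the "knee-up" flexion
#' branch). Targets whose coxa-relative planar distance falls outside
#' \code{[|femur - tibia|, femur + tibia]} are out of the workspace.
#'
#' @inheritParams fkLeg
#' @param target numeric(3) desired tibia-tarsus joint position (mm) or an
#'   n x 3 matrix of targets.
#' @param onUnreachable \code{"error"} to signal an out-of-workspace
#'   condition, \code{"na"} to return NA rows instead (useful when scanning
#'   grid nodes).
#' @return numeric(3) \code{c(alpha, beta, gamma)} in degrees, or an n x 3
#'   matrix for matrix input.
#' @examples
#' m <- standardBody()
#' p <- fkLeg(m, "L2", c(20, -40, 100))["TiTa", ]
#' ikLeg(m, "L2", p)   # recovers c(20, -40, 100)
#' @export
ikLeg <- function(model, leg, target, onUnreachable = c("error", "na")) {
  onUnreachable <- match.arg(onUnreachable)
  single <- is.null(dim(target))
  Tm <- if (single) matrix(target, 1, 3) else target
  if (!isLeg(leg)) periStop("periSpace_invalid_limb", paste("not a leg:", leg))
  fr <- legAxisFrame(model, leg)
  L <- legSegmentLengths(model, leg)
  ins <- limbInsertion(model, leg)
  v <- sweep(Tm, 2, ins, "-")
  h <- v %*% fr$u
  c1 <- v %*% fr$e1
  c2 <- v %*% fr$e2
  r <- sqrt(c1^2 + c2^2)
  alpha <- rad2deg(atan2(c2, c1))
  p <- r
  flip <- alpha <= -90 | alpha > 90
  alpha[flip] <- wrapDeg(alpha[flip] + 180)
  p[flip] <- -r[flip]
  ## two-link planar chain in (leg-plane base, axis) coordinates
  w1 <- p - L["coxa"]; w2 <- h
  dd <- sqrt(w1^2 + w2^2)
  tol <- 1e-9
  bad <- dd > L["femur"] + L["tibia"] + tol | dd < abs(L["femur"] - L["tibia"]) - tol
  if (any(bad) && onUnreachable == "error")
    periStop("periSpace_out_of_workspace",
             sprintf("%d target(s) outside the leg workspace", sum(bad)))
  cg <- (L["femur"]^2 + L["tibia"]^2 - dd^2) / (2 * L["femur"] * L["tibia"])
  cg <- pmin(1, pmax(-1, cg))
  gamma <- rad2deg(acos(cg))
  phi <- atan2(w2, w1)
  delta <- atan2(-L["tibia"] * sin(deg2rad(gamma)),
                 L["femur"] - L["tibia"] * cos(deg2rad(gamma)))
  beta <- wrapDeg(rad2deg(phi - delta))
  out <- cbind(alpha = as.vector(alpha), beta = as.vector(beta),
               gamma = as.vector(gamma))
  out[as.vector(bad), ] <- NA_real_
  if (single) out[1, ] else out
}

#' Forward kinematics of an antenna
#'
#' The antenna is modeled as a straight flagellum of the limb's total
#' length with two rotational degrees of freedom at the head insertion:
#' azimuth (about the head z axis, positive toward the left) and elevation
#' (positive up). Returns base and tip (and intermediate sample points on
#' request) in the head frame.
#'
#' @inheritParams limbLength
#' @param antenna \code{"LA"} or \code{"RA"}.
#' @param angles numeric(2) \code{c(azimuth, elevation)} in degrees, or an
#'   n x 2 matrix.
#' @param fractions optional numeric vector of length fractions in [0, 1]
#'   at which to return points along the flagellum.
#' @return a list with \code{base} and \code{tip} (n x 3 matrices), plus
#'   \code{points} (n x length(fractions) x 3 array) when \code{fractions}
#'   is given.
#' @export
fkAntenna <- function(model, antenna, angles, fractions = NULL) {
  if (!isAntenna(antenna))
    periStop("periSpace_invalid_limb", paste("not an antenna:", antenna))
  A <- if (is.null(dim(angles))) matrix(angles, 1, 2) else angles
  L <- limbLength(model, antenna)
  ins <- limbInsertion(model, antenna)
  az <- deg2rad(A[, 1]); el <- deg2rad(A[, 2])
  dir <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  n <- nrow(A)
  base <- matrix(ins, n, 3, byrow = TRUE)
  out <- list(base = base, tip = base + L * dir)
  if (!is.null(fractions)) {
    pts <- array(NA_real_, c(n, length(fractions), 3))
    for (i in seq_along(fractions))
      pts[, i, ] <- base + fractions[i] * L * dir
    out$points <- pts
  }
  out
}

#' Size-standardization scaling factor
#'
#' Ratio of the reference segment-length sum of the standardized body to
#' the corresponding sum for the current animal. Body-centered limb
#' coordinates are multiplied by this factor before gridding, so animals
#' of different size map onto the same standardized volume grid.
#'
#' @param refSum reference segment-length sum (mm), > 0.
#' @param curSum current animal's corresponding sum (mm), > 0.
#' @return dimensionless scaling factor \code{refSum / curSum}.
#' @export
sizeScalingFactor <- function(refSum, curSum) {
  if (!is.finite(refSum) || !is.finite(curSum) || refSum <= 0 || curSum <= 0)
    periStop("periSpace_invalid_measurement", "segment sums must be positive")
  refSum / curSum
}

#' Reference segment sum for size standardization
#'
#' For a pair of legs: the sum of both femora, both tibiae and the carrying
#' body segment. For the antennae: both antenna lengths plus the head
#' length. The ratio of this sum between the standardized body and the
#' recorded animal gives the per-limb-pair scaling factor.
#'
#' @inheritParams limbLength
#' @return segment-length sum in mm.
#' @export
referenceSegmentSum <- function(model, limb) {
  r <- limbRow(model, limb)
  if (isAntenna(limb)) {
    limbLength(model, "LA") + limbLength(model, "RA") +
      segmentLength(model, "head")
  } else {
    other <- chartr("LR", "RL", substr(limb, 1, 1))
    mate <- paste0(other, substr(limb, 2, 2))
    ra <- limbRow(model, mate)
    r$femur + ra$femur + r$tibia + ra$tibia + segmentLength(model, r$carrier)
  }
}

#' Integer percentage of a length ratio
#'
#' @param a,b lengths in mm; \code{b} must be > 0.
#' @return \code{round(100 * a / b)} as an integer.
#' @examples
#' lengthRatioPercent(38.67, 34.42)  # 112: front leg over antenna
#' @export
lengthRatioPercent <- function(a, b) {
  if (!is.finite(b) || b <= 0)
    periStop("periSpace_invalid_measurement", "denominator must be > 0")
  as.integer(round(100 * a / b))
}

#' Joint-angle bounds observed inside the affordance volumes
#'
#' Per-leg minimum and maximum of the three joint angles (degrees) inside
#' the affordance volume of an ipsilateral leg pair, as reported for the
#' left legs of the standardized animal; right-leg bounds are the mirror
#' (alpha sign flipped). These double as the physiological angle ranges of
#' the synthetic gait generator.
#'
#' @param set \code{"front-mid"} (front + middle leg pair) or
#'   \code{"mid-hind"} (middle + hind leg pair).
#' @return data.frame with columns \code{limb, alphaMin, alphaMax, betaMin,
#'   betaMax, gammaMin, gammaMax}.
#' @export
jointBounds <- function(set = c("front-mid", "mid-hind")) {
  set <- match.arg(set)
  left <- if (set == "front-mid") data.frame(
    limb = c("L1", "L2"),
    alphaMin = c(-22.9, -76.6), alphaMax = c(72.5, -1.4),
    betaMin = c(-114.1, -114.6), betaMax = c(-1.3, 26.4),
    gammaMin = c(42.9, 0.3), gammaMax = c(158.9, 136.3))
  else data.frame(
    limb = c("L2", "L3"),
    alphaMin = c(-4.6, -52.8), alphaMax = c(62.4, 10.6),
    betaMin = c(-95.6, -120.7), betaMax = c(22.5, 7.8),
    gammaMin = c(2.0, 59.2), gammaMax = c(113.1, 153.8))
  right <- left
  right$limb <- sub("^L", "R", right$limb)
  right$alphaMin <- -left$alphaMax
  right$alphaMax <- -left$alphaMin
  rbind(left, right)
}

## bounds rows for an arbitrary leg, choosing the set that contains it
legBounds <- function(leg) {
  cls <- substr(leg, 2, 2)
  set <- if (cls == "1") "front-mid" else "mid-hind"
  b <- jointBounds(set)
  b[b$limb == leg, ]
}
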