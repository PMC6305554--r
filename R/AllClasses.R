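#' @import methods
NULL

LEG_IDS <- c("L1", "R1", "L2", "R2", "L3", "R3")
ANTENNA_IDS <- c("LA", "RA")
LIMB_IDS <- c(LEG_IDS, ANTENNA_IDS)
SEGMENT_IDS <- c("head", "prothorax", "mesothorax", "metathorax")

#' BodyModel: standardized insect body geometry
#'
#' Holds the segment lengths of the main body axis (head and three thorax
#' segments), and per limb the carrying segment, the insertion coordinates
#' in the carrying-segment frame, the slanted thorax-coxa joint axis (yaw
#' and pitch, legs only), the individual leg segment lengths and the total
#' limb length. Coordinate convention: x forward, y left, z up, so right
#' limbs have negative y insertions.
#'
#' @slot segments data.frame with columns \code{segment}, \code{length}.
#' @slot limbs data.frame with one row per limb (\code{L1,R1,L2,R2,L3,R3,
#'   LA,RA}) and columns \code{limb, carrier, x, y, z, yaw, pitch, total,
#'   coxa, femur, tibia, tarsus} (lengths in mm, angles in degrees; leg-only
#'   columns are \code{NA} for antennae).
#' @export
setClass("BodyModel", representation(segments = "data.frame", limbs = "data.frame"))

setValidity("BodyModel", function(object) {
  s <- object@segments; l <- object@limbs
  msg <- character()
  if (!all(SEGMENT_IDS %in% s$segment)) msg <- c(msg, "missing body segments")
  if (any(s$length <= 0)) msg <- c(msg, "segment lengths must be > 0")
  if (!all(LIMB_IDS %in% l$limb)) msg <- c(msg, "missing limbs")
  if (any(l$total <= 0)) msg <- c(msg, "total limb lengths must be > 0")
  legs <- l[l$limb %in% LEG_IDS, ]
  if (any(is.na(legs[, c("coxa", "femur", "tibia", "tarsus", "yaw", "pitch")])))
    msg <- c(msg, "legs need segment lengths and a ThCx axis")
  if (any(legs[, c("coxa", "femur", "tibia", "tarsus")] <= 0, na.rm = TRUE))
    msg <- c(msg, "leg segment lengths must be > 0")
  ## bilateral mirror: left/right insertion y agree in magnitude, flip sign
  for (p in list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3"), c("LA", "RA"))) {
    a <- l[l$limb == p[1], ]; b <- l[l$limb == p[2], ]
    if (abs(a$y + b$y) > 1e-9)
      msg <- c(msg, sprintf("insertions of %s/%s do not mirror in y", p[1], p[2]))
  }
  if (length(msg)) msg else TRUE
})

#' Trial: one synthetic motion-capture episode
#'
#' Per-frame whole-body kinematics at a fixed sampling rate: segment poses
#' for head and the three thorax segments, three joint angles per leg, two
#' per antenna, plus derived world-frame foot and antennal-tip positions.
#'
#' @slot animal character animal id.
#' @slot paradigm one of \code{"walk"}, \code{"search"}, \code{"rod"}.
#' @slot fps frames per second (200 by default, as in the motion-capture
#'   recordings this generator emulates).
#' @slot seed integer seed the trial was generated with.
#' @slot bodyModel the (possibly size-jittered) \linkS4class{BodyModel} of
#'   this animal.
#' @slot frames data.frame, one row per frame.
#' @slot rod list rod specification (\code{height}, \code{radius}, \code{x})
#'   or empty list.
#' @slot groundTruth list of generator-side annotations (first-contact
#'   events per limb for rod trials, stance/swing phase, ...).
#' @export
setClass("Trial", representation(
  animal = "character", paradigm = "character", fps = "numeric",
  seed = "integer", bodyModel = "BodyModel", frames = "data.frame",
  rod = "list", groundTruth = "list"))

setValidity("Trial", function(object) {
  msg <- character()
  if (nrow(object@frames) < 1) msg <- c(msg, "trial needs at least one frame")
  if (object@fps <= 0) msg <- c(msg, "fps must be > 0")
  if (!object@paradigm %in% c("walk", "search", "rod"))
    msg <- c(msg, "unknown paradigm")
  num <- vapply(object@frames, is.numeric, logical(1))
  if (!all(is.finite(as.matrix(object@frames[, num]))))
    msg <- c(msg, "non-finite values in frames")
  if (length(msg)) msg else TRUE
})

#' VolumeGrid: weighted occupancy density on a cubic 1 mm grid
#'
#' Density of weighted limb sample points accumulated over frames, on a
#' 90 x 90 x 90 node grid centered on the limb base (node coordinates run
#' from \code{origin} to \code{origin + 89} mm on each axis).
#'
#' @slot limb limb id.
#' @slot type volume type (\code{"action"}, \code{"contact"}, \code{"tip"}).
#' @slot spacing grid spacing in mm (1).
#' @slot origin integer coordinate of the first node on each axis (-45).
#' @slot density non-negative 3D array of accumulated weights.
#' @slot frames number of frames accumulated.
#' @slot leakage total weight that fell outside the grid extent.
#' @slot smoothed logical, whether \code{\link{smoothDensity}} was applied.
#' @slot smoothLoss density mass lost to edge truncation during smoothing.
#' @export
setClass("VolumeGrid", representation(
  limb = "character", type = "character", spacing = "numeric",
  origin = "integer", density = "array", frames = "numeric",
  leakage = "numeric", smoothed = "logical", smoothLoss = "numeric"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (any(object@density < 0)) msg <- c(msg, "densities must be >= 0")
  if (length(dim(object@density)) != 3) msg <- c(msg, "density must be 3D")
  if (!object@smoothed) {
    ## each frame deposits total weight 1, minus counted out-of-extent leakage
    drift <- abs(sum(object@density) + object@leakage - object@frames)
    if (object@frames > 0 && drift > 1e-6 * max(1, object@frames))
      msg <- c(msg, "density + leakage does not match frame count")
  }
  if (length(msg)) msg else TRUE
})

#' BinaryVolume: thresholded occupancy volume
#'
#' The suprathreshold node set of a smoothed \linkS4class{VolumeGrid},
#' thresholded at a fraction of the maximum density (1\% by default).
#'
#' @slot limb limb id.
#' @slot type volume type.
#' @slot nodes integer n x 3 matrix of node coordinates (mm, limb-base frame).
#' @slot threshold absolute density threshold applied.
#' @slot sizeCcm volume in cubic centimeters (node count / 1000 at 1 mm
#'   spacing).
#' @slot retainedFraction fraction of total density inside the volume.
#' @slot spacing grid spacing in mm.
#' @export
setClass("BinaryVolume", representation(
  limb = "character", type = "character", nodes = "matrix",
  threshold = "numeric", sizeCcm = "numeric", retainedFraction = "numeric",
  spacing = "numeric"))

setValidity("BinaryVolume", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3) msg <- c(msg, "nodes must be n x 3")
  if (abs(object@sizeCcm - nrow(object@nodes) * object@spacing^3 / 1000) > 1e-9)
    msg <- c(msg, "sizeCcm inconsistent with node count")
  if (object@retainedFraction <= 0 || object@retainedFraction > 1 + 1e-12)
    msg <- c(msg, "retainedFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' AffordanceVolume: intersection of two limbs' volumes
#'
#' Node set shared by two neighboring limbs' binary volumes after aligning
#' both onto the straight standardized body, i.e. the region within reach
#' of both limbs.
#'
#' @slot limbs character(2), the two limb ids.
#' @slot nodes integer n x 3 node coordinates in the common body frame (mm).
#' @slot sizeCcm volume in ccm.
#' @slot spacing grid spacing in mm.
#' @export
setClass("AffordanceVolume", representation(
  limbs = "character", nodes = "matrix", sizeCcm = "numeric",
  spacing = "numeric"))

setValidity("AffordanceVolume", function(object) {
  msg <- character()
  if (length(object@limbs) != 2) msg <- c(msg, "need exactly two limbs")
  if (ncol(object@nodes) != 3) msg <- c(msg, "nodes must be n x 3")
  if (abs(object@sizeCcm - nrow(object@nodes) * object@spacing^3 / 1000) > 1e-9)
    msg <- c(msg, "sizeCcm inconsistent with node count")
  if (length(msg)) msg else TRUE
})

#' PosturePairDataset: matched postures of two legs with a common foot point
#'
#' One row per affordance-volume grid node for which inverse kinematics
#' succeeds for both legs: the sender-leg joint angles, the receiver-leg
#' joint angles, and the shared tibia-tarsus joint position.
#'
#' @slot sender,receiver leg ids.
#' @slot direction \code{"front-to-back"} or \code{"back-to-front"}.
#' @slot senderAngles,receiverAngles n x 3 matrices of (alpha, beta, gamma)
#'   in degrees.
#' @slot positions n x 3 matrix of the common foot positions (body frame, mm).
#' @slot nodes n x 3 integer matrix of the source grid nodes.
#' @slot dropped number of affordance nodes discarded because inverse
#'   kinematics failed or violated joint bounds for either leg.
#' @export
setClass("PosturePairDataset", representation(
  sender = "character", receiver = "character", direction = "character",
  senderAngles = "matrix", receiverAngles = "matrix", positions = "matrix",
  nodes = "matrix", dropped = "numeric"))

setValidity("PosturePairDataset", function(object) {
  msg <- character()
  n <- nrow(object@senderAngles)
  if (nrow(object@receiverAngles) != n || nrow(object@positions) != n)
    msg <- c(msg, "angle and position matrices must have equal row counts")
  if (!object@direction %in% c("front-to-back", "back-to-front"))
    msg <- c(msg, "unknown direction")
  if (length(msg)) msg else TRUE
})

#' TrainResult: accuracy of a fitted posture mapping
#'
#' @slot perDofMSE named numeric(3), test-set mean squared error per output
#'   joint angle, in squared degrees.
#' @slot meanMSE arithmetic mean of the three per-DoF MSEs (deg^2).
#' @slot rmse square root of \code{meanMSE} (degrees), the mean per-joint
#'   error scale.
#' @slot curve data.frame learning curve (\code{epoch}, \code{train},
#'   \code{test} mean MSE); empty for the analytic linear fit.
#' @slot config list of fitting parameters.
#' @slot seed integer seed (NA for deterministic fits).
#' @export
setClass("TrainResult", representation(
  perDofMSE = "numeric", meanMSE = "numeric", rmse = "numeric",
  curve = "data.frame", config = "list", seed = "integer"))

setValidity("TrainResult", function(object) {
  msg <- character()
  if (length(object@perDofMSE) != 3) msg <- c(msg, "need 3 per-DoF MSEs")
  if (!identical(object@meanMSE, mean(object@perDofMSE)))
    msg <- c(msg, "meanMSE must equal the mean of perDofMSE exactly")
  if (!identical(object@rmse, sqrt(object@meanMSE)))
    msg <- c(msg, "rmse must equal sqrt(meanMSE) exactly")
  if (length(msg)) msg else TRUE
})
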