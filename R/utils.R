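#' @importFrom stats median quantile rnorm runif sd setNames
#' @importFrom utils read.table write.table head
NULL

DEG2RAD <- pi / 180

deg2rad <- function(x) x * DEG2RAD
rad2deg <- function(x) x / DEG2RAD

## wrap angle (deg) into (-180, 180]
wrapDeg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## classed conditions so callers can distinguish failure modes
periStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "periSpaceError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

## Run expr with a private RNG stream, restoring the caller's state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## Derive a child seed from a parent seed and a stage label, staying < 2^31.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483591 + 1)
}

## rotation matrix from yaw (z), pitch (y), roll (x), degrees; columns are
## the rotated frame axes expressed in the parent frame
rotYPR <- function(yaw, pitch, roll = 0) {
  cy <- cos(deg2rad(yaw)); sy <- sin(deg2rad(yaw))
  cp <- cos(deg2rad(pitch)); sp <- sin(deg2rad(pitch))
  cr <- cos(deg2rad(roll)); sr <- sin(deg2rad(roll))
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Convert points between a segment frame and the world frame
#'
#' A segment pose is a length-6 numeric vector
#' \code{(x, y, z, yaw, pitch, roll)}: the world position of the segment
#' origin plus the intrinsic z-y-x Euler angles (degrees) of the segment
#' axes. \code{poseToWorld} maps segment-frame points to world coordinates;
#' \code{poseFromWorld} is its exact inverse.
#'
#' @param pose numeric(6) segment pose.
#' @param pts numeric vector of length 3 or an n x 3 matrix of points.
#' @return points in the target frame, same shape as \code{pts}.
#' @export
poseToWorld <- function(pose, pts) {
  R <- rotYPR(pose[4], pose[5], pose[6])
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  out <- pts %*% t(R)
  out <- sweep(out, 2, pose[1:3], "+")
  if (single) out[1, ] else out
}

#' @rdname poseToWorld
#' @export
poseFromWorld <- function(pose, pts) {
  R <- rotYPR(pose[4], pose[5], pose[6])
  single <- is.null(dim(pts))
  if (single) pts <- matrix(pts, 1, 3)
  out <- sweep(pts, 2, pose[1:3], "-") %*% R
  if (single) out[1, ] else out
}
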