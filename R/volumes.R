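GRID_DIM <- 90L
GRID_ORIGIN <- -45L   # node coordinates -45 .. 44 mm, centered on the limb base

#' Limb point-sampling scheme for volume density estimation
#'
#' Defines the discrete points along a limb whose positions are
#' accumulated on the grid, together with their weights. Points are
#' weighted \code{2k / (n (n + 1))} with \code{k = 1..n} ordered proximal
#' to distal, so that the weights sum to 1 per frame and distal points
#' (which sweep longer arcs per unit joint excursion) count more,
#' compensating the otherwise inflated density near the limb base.
#'
#' Point layouts per volume type:
#' \itemize{
#'   \item action, legs: 8 equidistant points along the femur (fractions
#'     0.1..1.0), 8 along the tibia, 4 along the tarsus (n = 20);
#'   \item action, antennae: 20 equidistant points along the flagellum
#'     (fractions 0.1..1.0);
#'   \item contact: 10 equidistant points from scaling factor 0.67 to the
#'     distal limit -- 1.0 for antennae, \code{(tibia + tarsus) / tibia}
#'     for legs, measured along the extended tibia direction (the tarsus is
#'     a straight extension of the tibia);
#'   \item tip: the single most distal tracked point (antennal tip, or the
#'     tibia-tarsus joint of a leg), weight 1.
#' }
#'
#' @param type volume type: \code{"action"}, \code{"contact"} or
#'   \code{"tip"}.
#' @param limb limb id.
#' @param model \linkS4class{BodyModel} supplying the tibia/tarsus lengths
#'   for the leg contact-scheme distal limit.
#' @return a list of class \code{"SamplingScheme"} with elements
#'   \code{type}, \code{limb}, \code{n}, \code{segments}, \code{fractions}
#'   and \code{weights}.
#' @examples
#' s <- makeScheme("contact", "L2", standardBody())
#' max(s$fractions)       # (11.64 + 4.51) / 11.64 = 1.387 tibia lengths
#' sum(s$weights)         # 1
#' @export
makeScheme <- function(type = c("action", "contact", "tip"), limb,
                       model = standardBody()) {
  type <- match.arg(type)
  if (!limb %in% LIMB_IDS)
    periStop("periSpace_invalid_limb", paste("unknown limb id:", limb))
  if (isAntenna(limb)) {
    def <- switch(type,
      action  = list(seg = rep("flagellum", 20), fr = seq(0.1, 1, length.out = 20)),
      contact = list(seg = rep("flagellum", 10), fr = seq(0.67, 1, length.out = 10)),
      tip     = list(seg = "flagellum", fr = 1))
  } else {
    L <- legSegmentLengths(model, limb)
    distal <- (L[["tibia"]] + L[["tarsus"]]) / L[["tibia"]]
    def <- switch(type,
      action  = list(seg = c(rep("femur", 8), rep("tibia", 8), rep("tarsus", 4)),
                     fr = c(seq(0.1, 1, length.out = 8),
                            seq(0.1, 1, length.out = 8),
                            seq(0.25, 1, length.out = 4))),
      contact = list(seg = rep("tibiaExt", 10),
                     fr = seq(0.67, distal, length.out = 10)),
      tip     = list(seg = "tibiaExt", fr = 1))
  }
  n <- length(def$fr)
  structure(list(type = type, limb = limb, n = n,
                 segments = def$seg, fractions = def$fr,
                 weights = 2 * seq_len(n) / (n * (n + 1))),
            class = "SamplingScheme")
}

## limb sample points for all frames of an angle matrix, in the
## carrying-segment frame; returns (nFrames * n) x 3 matrix, frame-major
schemePoints <- function(scheme, model, angles) {
  limb <- scheme$limb
  if (isAntenna(limb)) {
    fk <- fkAntenna(model, limb, angles, fractions = scheme$fractions)
    n <- nrow(fk$base)
    pts <- matrix(aperm(fk$points, c(2, 1, 3)), n * scheme$n, 3)
    return(pts)
  }
  J <- fkLegJoints(model, limb, angles)
  n <- nrow(J$ThCx)
  segStart <- list(femur = J$CTr, tibia = J$FTi, tarsus = J$TiTa, tibiaExt = J$FTi)
  segEnd <- list(femur = J$FTi, tibia = J$TiTa, tarsus = J$tip, tibiaExt = J$TiTa)
  out <- matrix(NA_real_, n * scheme$n, 3)
  for (i in seq_len(scheme$n)) {
    s <- scheme$segments[i]; f <- scheme$fractions[i]
    p <- segStart[[s]] + f * (segEnd[[s]] - segStart[[s]])
    out[seq(i, by = scheme$n, length.out = n), ] <- p
  }
  out
}

## angle matrix for one limb from a trial's frame table
trialAngles <- function(trial, limb) {
  cols <- if (isLeg(limb)) paste0(limb, c("_alpha", "_beta", "_gamma"))
          else paste0(limb, c("_az", "_el"))
  if (!all(cols %in% names(trial@frames)))
    periStop("periSpace_missing_limb",
             paste("trial does not track limb", limb))
  as.matrix(trial@frames[, cols])
}

emptyGrid <- function(limb, type) {
  new("VolumeGrid", limb = limb, type = type, spacing = 1,
      origin = GRID_ORIGIN,
      density = array(0, rep(GRID_DIM, 3)), frames = 0,
      leakage = 0, smoothed = FALSE, smoothLoss = 0)
}

#' Accumulate weighted limb occupancy on the standardized 1 mm grid
#'
#' For every frame of every trial, the scheme's sample points are computed
#' by forward kinematics from the trial's joint angles and the trial
#' animal's own body model, expressed relative to the limb base in the
#' carrying-segment frame, standardized by the size scaling factor
#' (reference segment sum over the animal's segment sum), rounded to the
#' nearest millimeter, and their weights added to the matching grid node.
#' Points falling outside the 90-node extent are counted as leakage.
#'
#' @param trials a list of \linkS4class{Trial} objects (or a single trial).
#' @param limb limb id; must be tracked in every trial.
#' @param scheme a \code{\link{makeScheme}} sampling scheme for this limb.
#' @param model the reference \linkS4class{BodyModel} defining the
#'   standardized size.
#' @return a \linkS4class{VolumeGrid}.
#' @export
accumulateDensity <- function(trials, limb, scheme, model = standardBody()) {
  if (is(trials, "Trial")) trials <- list(trials)
  if (length(trials) == 0)
    periStop("periSpace_config_error", "need at least one trial")
  stopifnot(scheme$limb == limb)
  grid <- emptyGrid(limb, scheme$type)
  dens <- grid@density
  leak <- 0; frames <- 0
  nd <- GRID_DIM
  for (tr in trials) {
    A <- trialAngles(tr, limb)
    tm <- tr@bodyModel
    pts <- schemePoints(scheme, tm, A)
    pts <- sweep(pts, 2, limbInsertion(tm, limb), "-")
    s <- sizeScalingFactor(referenceSegmentSum(model, limb),
                           referenceSegmentSum(tm, limb))
    ij <- round(pts * s) - GRID_ORIGIN + 1   # 1-based grid indices
    w <- rep(scheme$weights, times = nrow(A))
    ok <- ij[, 1] >= 1 & ij[, 1] <= nd & ij[, 2] >= 1 & ij[, 2] <= nd &
      ij[, 3] >= 1 & ij[, 3] <= nd
    leak <- leak + sum(w[!ok])
    if (any(ok)) {
      lin <- ij[ok, 1] + nd * (ij[ok, 2] - 1) + nd * nd * (ij[ok, 3] - 1)
      agg <- rowsum(w[ok], lin)
      dens[as.numeric(rownames(agg))] <- dens[as.numeric(rownames(agg))] + agg[, 1]
    }
    frames <- frames + nrow(A)
  }
  grid@density <- dens
  grid@leakage <- leak
  grid@frames <- frames
  validObject(grid)
  grid
}

## 5-tap normalized Gaussian (sigma = 1 node); the 5x5x5 cubic kernel is
## the separable product of this vector with itself
gauss5 <- function() {
  g <- exp(-(-2:2)^2 / 2)
  g / sum(g)
}

#' Smooth a volume grid with the cubic Gaussian kernel
#'
#' Convolves the accumulated counts with a 5 x 5 x 5 kernel with Gaussian
#' weights (standard deviation 1 grid node) normalized to sum 1. The
#' kernel is truncated at the grid edge without renormalization; the mass
#' lost this way is recorded in the \code{smoothLoss} slot. Away from the
#' edges the convolution conserves density exactly.
#'
#' @param grid a \linkS4class{VolumeGrid} from
#'   \code{\link{accumulateDensity}}.
#' @return the smoothed \linkS4class{VolumeGrid}.
#' @export
smoothDensity <- function(grid) {
  a <- grid@density
  nd <- dim(a)[1]
  g <- gauss5()
  K <- matrix(0, nd, nd)
  for (off in -2:2) {
    i <- seq_len(nd)
    j <- i + off
    ok <- j >= 1 & j <= nd
    K[cbind(i[ok], j[ok])] <- g[off + 3]
  }
  before <- sum(a)
  a <- array(K %*% matrix(a, nd, nd * nd), dim(a))                      # x
  a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), nd, nd * nd),
                   dim(a)), c(2, 1, 3))                                 # y
  a <- aperm(array(K %*% matrix(aperm(a, c(3, 2, 1)), nd, nd * nd),
                   dim(a)), c(3, 2, 1))                                 # z
  grid@density <- a
  grid@smoothed <- TRUE
  grid@smoothLoss <- grid@smoothLoss + (before - sum(a))
  grid
}

#' Threshold a smoothed density grid into a binary volume
#'
#' Keeps every node whose density is at least \code{frac} of the maximum
#' density of the grid (ties retained), the criterion used to delimit tip,
#' contact and action volumes. At the default 1\% threshold the retained
#' volumes typically contain well over 95\% of the summed density.
#'
#' @param grid a smoothed \linkS4class{VolumeGrid}.
#' @param frac threshold as a fraction of the maximum density, in (0, 1).
#' @return a \linkS4class{BinaryVolume}.
#' @export
extractVolume <- function(grid, frac = 0.01) {
  stopifnot(frac > 0, frac < 1)
  total <- sum(grid@density)
  if (total == 0)
    periStop("periSpace_empty_volume", "all-zero density grid")
  thr <- frac * max(grid@density)
  keep <- grid@density >= thr
  idx <- which(keep, arr.ind = TRUE)
  nodes <- idx + as.integer(grid@origin) - 1L
  storage.mode(nodes) <- "integer"
  colnames(nodes) <- c("x", "y", "z")
  new("BinaryVolume", limb = grid@limb, type = grid@type,
      nodes = nodes, threshold = thr,
      sizeCcm = nrow(nodes) * grid@spacing^3 / 1000,
      retainedFraction = sum(grid@density[keep]) / total,
      spacing = grid@spacing)
}

nodeKeys <- function(nodes) paste(nodes[, 1], nodes[, 2], nodes[, 3])

orderNodes <- function(nodes) nodes[order(nodes[, 1], nodes[, 2], nodes[, 3]), , drop = FALSE]

## binary-volume nodes translated from the limb-base frame to the common
## body frame; the base offset is rounded to keep the integer 1 mm lattice
bodyFrameNodes <- function(vol, model) {
  shift <- as.integer(round(limbBaseBody(model, vol@limb)))
  sweep(vol@nodes, 2, shift, "+")
}

#' Intersect two limbs' binary volumes into an affordance volume
#'
#' Translates both node sets into the common body frame of the straight
#' standardized body (via the limbs' insertion coordinates, rounded to the
#' grid lattice) and intersects them node-wise. The result is the region
#' reachable by both limbs: a contact sensed by one limb inside this
#' volume is a reachable target for the other.
#'
#' @param a,b \linkS4class{BinaryVolume}s of two distinct limbs computed
#'   from the same standardized body and grid spacing.
#' @param model the standardized \linkS4class{BodyModel} used to place the
#'   limb bases.
#' @return an \linkS4class{AffordanceVolume}.
#' @export
intersectVolumes <- function(a, b, model = standardBody()) {
  if (a@spacing != b@spacing)
    periStop("periSpace_incompatible_grids", "grids differ in spacing")
  na <- bodyFrameNodes(a, model)
  nb <- bodyFrameNodes(b, model)
  common <- na[nodeKeys(na) %in% nodeKeys(nb), , drop = FALSE]
  common <- orderNodes(common)
  storage.mode(common) <- "integer"
  new("AffordanceVolume", limbs = c(a@limb, b@limb), nodes = common,
      sizeCcm = nrow(common) * a@spacing^3 / 1000, spacing = a@spacing)
}

#' Integer percentage of a volume-size ratio
#'
#' @param part a \linkS4class{BinaryVolume} or \linkS4class{AffordanceVolume}
#'   (or a size in ccm).
#' @param whole a non-empty \linkS4class{BinaryVolume} (or a size in ccm).
#' @return \code{round(100 * size(part) / size(whole))} as an integer.
#' @examples
#' volumeRatioPercent(8.736, 60.786)  # 14
#' @export
volumeRatioPercent <- function(part, whole) {
  sz <- function(x) if (is.numeric(x)) x else x@sizeCcm
  if (sz(whole) <= 0)
    periStop("periSpace_invalid_measurement", "whole volume is empty")
  as.integer(round(100 * sz(part) / sz(whole)))
}

#' Volume accessors
#'
#' @param x a \linkS4class{BinaryVolume} or \linkS4class{AffordanceVolume}.
#' @return \code{volumeSize}: size in ccm; \code{volumeNodes}: the integer
#'   node coordinate matrix.
#' @export
volumeSize <- function(x) x@sizeCcm

#' @rdname volumeSize
#' @export
volumeNodes <- function(x) x@nodes

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid: %s %s volume, %d^3 nodes at %g mm\n",
              object@limb, object@type, dim(object@density)[1],
              object@spacing))
  cat(sprintf("  frames: %g, total density: %.3f, leakage: %.3g, smoothed: %s\n",
              object@frames, sum(object@density), object@leakage,
              object@smoothed))
})

setMethod("show", "BinaryVolume", function(object) {
  cat(sprintf("BinaryVolume: %s %s volume, %.3f ccm (%d nodes), retained %.1f%%\n",
              object@limb, object@type, object@sizeCcm, nrow(object@nodes),
              100 * object@retainedFraction))
})

setMethod("show", "AffordanceVolume", function(object) {
  cat(sprintf("AffordanceVolume: %s x %s, %.3f ccm (%d nodes)\n",
              object@limbs[1], object@limbs[2], object@sizeCcm,
              nrow(object@nodes)))
})

#' Write / read a volume grid as delimited text
#'
#' The format is a plain text table with '#'-prefixed header lines
#' (limb, type, spacing, origin, dim, frames, leakage, smoothed,
#' smoothLoss) followed by one \code{x y z density} row per nonzero node.
#' A \linkS4class{BinaryVolume} is exported in the same format with
#' density 1 per node.
#'
#' @param grid a \linkS4class{VolumeGrid}.
#' @param path file path.
#' @return \code{readVolumeGrid} returns the reconstructed
#'   \linkS4class{VolumeGrid}.
#' @export
writeVolumeGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(limb = grid@limb, type = grid@type, spacing = grid@spacing,
           origin = grid@origin, dim = dim(grid@density)[1],
           frames = grid@frames, leakage = grid@leakage,
           smoothed = grid@smoothed, smoothLoss = grid@smoothLoss)
  writeLines(paste0("# ", names(hdr), " = ", unname(hdr)), con)
  idx <- which(grid@density != 0, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1] + grid@origin - 1L,
                   y = idx[, 2] + grid@origin - 1L,
                   z = idx[, 3] + grid@origin - 1L,
                   density = grid@density[idx])
  write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
              con, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVolumeGrid
#' @export
readVolumeGrid <- function(path) {
  lines <- readLines(path)
  hl <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hl), " = "))
  meta <- setNames(kv[, 2], kv[, 1])
  nd <- as.integer(meta["dim"])
  grid <- new("VolumeGrid", limb = unname(meta["limb"]),
              type = unname(meta["type"]),
              spacing = as.numeric(meta["spacing"]),
              origin = as.integer(meta["origin"]),
              density = array(0, rep(nd, 3)),
              frames = as.numeric(meta["frames"]),
              leakage = as.numeric(meta["leakage"]),
              smoothed = as.logical(meta["smoothed"]),
              smoothLoss = as.numeric(meta["smoothLoss"]))
  df <- read.table(textConnection(lines[!grepl("^#", lines)]), header = TRUE)
  if (nrow(df)) {
    ij <- as.matrix(df[, c("x", "y", "z")]) - grid@origin + 1L
    grid@density[ij] <- df$density
  }
  grid
}

#' @rdname writeVolumeGrid
#' @param vol a \linkS4class{BinaryVolume}.
#' @export
writeBinaryVolume <- function(vol, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(limb = vol@limb, type = vol@type, spacing = vol@spacing,
           threshold = vol@threshold, sizeCcm = vol@sizeCcm,
           retainedFraction = vol@retainedFraction)
  writeLines(paste0("# ", names(hdr), " = ", unname(hdr)), con)
  df <- data.frame(x = vol@nodes[, 1], y = vol@nodes[, 2],
                   z = vol@nodes[, 3], density = 1)
  write.table(df, con, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVolumeGrid
#' @export
readBinaryVolume <- function(path) {
  lines <- readLines(path)
  hl <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hl), " = "))
  meta <- setNames(kv[, 2], kv[, 1])
  df <- read.table(textConnection(lines[!grepl("^#", lines)]), header = TRUE)
  nodes <- as.matrix(df[, c("x", "y", "z")])
  storage.mode(nodes) <- "integer"
  new("BinaryVolume", limb = unname(meta["limb"]), type = unname(meta["type"]),
      nodes = nodes, threshold = as.numeric(meta["threshold"]),
      sizeCcm = as.numeric(meta["sizeCcm"]),
      retainedFraction = as.numeric(meta["retainedFraction"]),
      spacing = as.numeric(meta["spacing"]))
}
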