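## Canonical 1 mm arc-length sampling of a limb polyline for contact
## detection, independent of the volume sampling schemes. Legs are the
## polyline femur -> tibia -> tarsus (contacts by the coxa are outside the
## standardized location axis); antennae are the straight flagellum.
## `fraction` is the standardized location along the limb (0 = base,
## 1 = tip for antennae; 50% femur + 50% tibia with tarsus = 1 for legs).
limbSampling <- function(model, limb) {
  if (isAntenna(limb)) {
    L <- limbLength(model, limb)
    np <- ceiling(L) + 1
    f <- seq(0, 1, length.out = np)
    return(data.frame(segment = "flagellum", within = f, fraction = f))
  }
  L <- legSegmentLengths(model, limb)
  out <- do.call(rbind, lapply(c("femur", "tibia", "tarsus"), function(s) {
    np <- ceiling(L[[s]]) + 1
    f <- seq(0, 1, length.out = np)
    data.frame(segment = s, within = f,
               fraction = standardizeLegLocation(s, f))
  }))
  rownames(out) <- NULL
  out
}

## sample points of one limb in world coordinates for a single frame row
limbWorldPoints <- function(model, frameRow, limb, samp = limbSampling(model, limb)) {
  carrier <- limbCarrier(model, limb)
  pose <- as.numeric(frameRow[segmentPoseCols(carrier)])
  if (isAntenna(limb)) {
    ang <- as.numeric(frameRow[paste0(limb, c("_az", "_el"))])
    fk <- fkAntenna(model, limb, ang, fractions = samp$within)
    pts <- matrix(fk$points[1, , ], ncol = 3)
  } else {
    ang <- as.numeric(frameRow[paste0(limb, c("_alpha", "_beta", "_gamma"))])
    J <- fkLeg(model, limb, ang)
    segA <- list(femur = J["CTr", ], tibia = J["FTi", ], tarsus = J["TiTa", ])
    segB <- list(femur = J["FTi", ], tibia = J["TiTa", ], tarsus = J["tip", ])
    pts <- t(vapply(seq_len(nrow(samp)), function(k) {
      s <- samp$segment[k]
      segA[[s]] + samp$within[k] * (segB[[s]] - segA[[s]])
    }, numeric(3)))
  }
  poseToWorld(pose, pts)
}

#' Standardize a contact location along a leg
#'
#' Maps a contact on a leg segment to the standardized location axis used
#' for contact-location statistics: femur contacts map proportionally to
#' [0, 0.5], tibia contacts to [0.5, 1), and any tarsus contact counts as
#' exactly 1 (100\% leg length). Coxa contacts are outside this axis and
#' map to 0 with a warning.
#'
#' @param segment leg segment of the contact (\code{"femur"},
#'   \code{"tibia"}, \code{"tarsus"}, or \code{"coxa"}); for antennae use
#'   \code{"flagellum"} (identity map).
#' @param fraction position along that segment in [0, 1] (ignored for the
#'   tarsus).
#' @return standardized location fraction in [0, 1].
#' @examples
#' standardizeLegLocation("femur", 0.5)   # 0.25
#' standardizeLegLocation("tarsus", 0.2)  # 1
#' @export
standardizeLegLocation <- function(segment, fraction = 0) {
  n <- max(length(segment), length(fraction))
  segment <- rep_len(segment, n); fraction <- rep_len(fraction, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- switch(segment[i],
      flagellum = fraction[i],
      femur = 0.5 * fraction[i],
      tibia = 0.5 + 0.5 * fraction[i],
      tarsus = 1,
      coxa = {
        warning("coxa contact mapped to 0 (outside the standardized axis)")
        0
      },
      periStop("periSpace_invalid_limb",
               paste("unknown segment:", segment[i])))
  }
  out
}

#' Detect the first limb-rod contact in a trial
#'
#' Scans the trial frame by frame for the earliest frame at which the
#' minimum distance between the limb's sampled polyline (1 mm arc-length
#' resolution) and the rod axis is at most the rod radius. The contact
#' location is the standardized arc-length fraction of the closest sample
#' point; ties within a frame are broken toward the most distal point.
#' Only the first contact is reported; absence of contact is a valid
#' outcome (\code{NULL}).
#'
#' @param trial a \linkS4class{Trial}.
#' @param rod a \code{\link{rodSpec}} (defaults to the trial's own rod).
#' @param limb limb id tracked in the trial.
#' @return a list of class \code{"ContactEvent"} with elements
#'   \code{trial}, \code{limb}, \code{frame}, \code{fraction},
#'   \code{segment}, \code{point} (world mm), \code{height} and
#'   \code{state} (\code{"swing"}/\code{"stance"} of the ipsilateral front
#'   leg at an antennal contact, when available), or \code{NULL} if the
#'   limb never touches the rod.
#' @export
detectFirstContact <- function(trial, rod = NULL, limb) {
  if (is.null(rod)) {
    if (!length(trial@rod))
      periStop("periSpace_config_error", "trial has no rod specification")
    rod <- trial@rod
  }
  model <- trial@bodyModel
  samp <- limbSampling(model, limb)
  fr <- trial@frames
  n <- nrow(fr)
  np <- nrow(samp)
  carrier <- limbCarrier(model, limb)
  ## segment-frame sample points for all frames (n x np each coordinate)
  if (isAntenna(limb)) {
    A <- trialAngles(trial, limb)
    fk <- fkAntenna(model, limb, A, fractions = samp$within)
    P <- fk$points                         # n x np x 3
  } else {
    A <- trialAngles(trial, limb)
    J <- fkLegJoints(model, limb, A)
    segA <- list(femur = J$CTr, tibia = J$FTi, tarsus = J$TiTa)
    segB <- list(femur = J$FTi, tibia = J$TiTa, tarsus = J$tip)
    P <- array(NA_real_, c(n, np, 3))
    for (k in seq_len(np)) {
      s <- samp$segment[k]
      P[, k, ] <- segA[[s]] + samp$within[k] * (segB[[s]] - segA[[s]])
    }
  }
  ## world transform per frame (poses may vary arbitrarily)
  pose <- as.matrix(fr[, segmentPoseCols(carrier)])
  ident <- all(pose[, 4:6] == 0)
  if (ident) {
    X <- P[, , 1] + pose[, 1]
    Z <- P[, , 3] + pose[, 3]
  } else {
    X <- Z <- matrix(NA_real_, n, np)
    for (i in seq_len(n)) {
      w <- poseToWorld(pose[i, ], matrix(P[i, , ], ncol = 3))
      X[i, ] <- w[, 1]; Z[i, ] <- w[, 3]
    }
  }
  D <- sqrt((X - rod$x)^2 + (Z - rod$height)^2)
  hitRows <- which(apply(D <= rod$radius, 1, any))
  if (!length(hitRows)) return(NULL)
  i <- hitRows[1]
  d <- D[i, ]
  inr <- which(d <= rod$radius)
  k <- max(inr[d[inr] == min(d[inr])])     # distal tie-break
  pt <- if (ident) P[i, k, ] + pose[i, 1:3]
        else poseToWorld(pose[i, ], P[i, k, ])
  state <- NA_character_
  if (isAntenna(limb)) {
    mate <- if (limb == "LA") "L1" else "R1"
    col <- paste0(mate, "_swing")
    if (col %in% names(fr))
      state <- if (fr[[col]][i] == 1) "swing" else "stance"
  }
  structure(list(trial = trial@animal, limb = limb, frame = fr$frame[i],
                 fraction = samp$fraction[k], segment = samp$segment[k],
                 point = pt, height = rod$height, state = state),
            class = "ContactEvent")
}

#' Tabulate contact events
#'
#' @param events a list of \code{ContactEvent}s (NULL entries dropped).
#' @return data.frame with one row per event: trial, limb, frame,
#'   fraction, segment, x, y, z, height, state.
#' @export
contactEventsTable <- function(events) {
  events <- Filter(Negate(is.null), events)
  if (!length(events)) periStop("periSpace_no_events", "no contact events")
  do.call(rbind, lapply(events, function(e) data.frame(
    trial = e$trial, limb = e$limb, frame = e$frame, fraction = e$fraction,
    segment = e$segment, x = e$point[1], y = e$point[2], z = e$point[3],
    height = e$height, state = if (is.null(e$state)) NA_character_ else e$state)))
}

#' Summarize contact locations
#'
#' Per rod height: median, interquartile range and min/max of the
#' standardized contact-location fractions; pooled over heights: a
#' histogram, the cumulative distribution, and the share of contacts in
#' the distal third of the limb (fraction > 2/3).
#'
#' @param events a list of \code{ContactEvent}s or a data.frame from
#'   \code{\link{contactEventsTable}}.
#' @param binWidth histogram bin width on the location axis.
#' @return a list of class \code{"ContactSummary"}: \code{perHeight}
#'   (data.frame height, n, median, q1, q3, iqr, min, max),
#'   \code{breaks}, \code{counts}, \code{cumulative},
#'   \code{distalThirdFraction}, \code{n}.
#' @export
summarizeContacts <- function(events, binWidth = 0.05) {
  df <- if (is.data.frame(events)) events else contactEventsTable(events)
  if (nrow(df) == 0) periStop("periSpace_no_events", "no contact events")
  ph <- do.call(rbind, lapply(split(df$fraction, df$height), function(x) {
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
               iqr = q[3] - q[1], min = min(x), max = max(x))
  }))
  ph <- cbind(height = as.numeric(rownames(ph)), ph)
  rownames(ph) <- NULL
  breaks <- seq(0, 1, by = binWidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- table(cut(df$fraction, breaks, include.lowest = TRUE))
  cum <- cumsum(as.numeric(counts)) / nrow(df)
  structure(list(perHeight = ph, breaks = breaks,
                 counts = as.numeric(counts), cumulative = cum,
                 distalThirdFraction = mean(df$fraction > 2 / 3),
                 n = nrow(df)),
            class = "ContactSummary")
}

#' @export
print.ContactSummary <- function(x, ...) {
  cat(sprintf("ContactSummary: %d events, %.0f%% in the distal third\n",
              x$n, 100 * x$distalThirdFraction))
  print(x$perHeight, row.names = FALSE)
  invisible(x)
}

#' @export
print.ContactEvent <- function(x, ...) {
  cat(sprintf(
    "ContactEvent: %s %s, frame %d, location %.3f (%s), height %g mm\n",
    x$trial, x$limb, as.integer(x$frame), x$fraction, x$segment, x$height))
  invisible(x)
}

#' Write / read contact events as delimited text
#'
#' @param events list of \code{ContactEvent}s or their table.
#' @param path file path.
#' @export
writeContactEvents <- function(events, path) {
  df <- if (is.data.frame(events)) events else contactEventsTable(events)
  num <- vapply(df, is.double, logical(1))
  for (cl in names(df)[num]) df[[cl]] <- fmtNum(df[[cl]])
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContactEvents
#' @export
readContactEvents <- function(path) {
  read.table(path, header = TRUE, sep = ",")
}
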