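#' Published reference values of the standardized-animal study
#'
#' The printed summary numbers that the pipeline's consistency checks are
#' evaluated against: regression errors of the inter-leg posture mappings
#' (per degree of freedom and their printed means, in deg^2), the
#' posture-pair dataset sizes and 80\% training-split sizes, the tip /
#' contact / action volume sizes per limb and the affordance volume sizes
#' per ipsilateral limb pair (ccm, with the printed percentage columns),
#' and the printed length- and volume-ratio percentages. These are
#' reference results of the original motion-capture analysis, shipped as a
#' fixture: the absolute volume and error values depend on that
#' experimental corpus and are not recomputable from synthetic data.
#'
#' @return a list of data.frames: \code{regression}, \code{datasets},
#'   \code{volumes}, \code{affordances}, \code{ratios}.
#' @export
referenceValues <- function() {
  regression <- data.frame(
    pair = rep(c("front-mid", "mid-hind"), each = 2),
    direction = rep(c("front-to-back", "back-to-front"), 2),
    mseAlpha = c(34.5, 48.3, 13.7, 7.1),
    mseBeta = c(45.3, 32.3, 8.4, 13.8),
    mseGamma = c(103.1, 22.4, 7.9, 33.8),
    printedMean = c(61.0, 34.3, 10.0, 18.2),
    printedRmse = c(7.8, 5.9, 3.2, 4.3))
  datasets <- data.frame(
    pair = rep(c("front-mid", "mid-hind"), each = 2),
    side = rep(c("left", "right"), 2),
    nPairs = c(5500, 8382, 2918, 3741),
    printedTrain = c(4400, 6705, NA, NA))
  volumes <- data.frame(
    side = rep(c("left", "right"), each = 12),
    limb = rep(rep(c("hind", "middle", "front", "antenna"), each = 3), 2),
    type = rep(c("tip", "contact", "action"), 8),
    ccm = c(13.023, 19.882, 21.542, 13.626, 20.677, 19.937,
            46.330, 65.630, 60.786, 12.082, 27.227, 31.615,
            14.884, 23.112, 23.290, 13.589, 21.757, 20.484,
            39.436, 61.113, 61.345, 10.751, 24.766, 30.531),
    printedPct = c(60, 92, 100, 68, 104, 100, 76, 108, 100, 38, 86, 100,
                   64, 99, 100, 66, 106, 100, 64, 100, 100, 35, 81, 100))
  affordances <- data.frame(
    side = rep(c("left", "right"), each = 9),
    pair = rep(rep(c("Leg3/Leg2", "Leg2/Leg1", "Leg1/Ant"), each = 3), 2),
    type = rep(c("tip", "contact", "action"), 6),
    ccm = c(2.635, 4.864, 4.263, 4.233, 7.825, 6.423, 0, 6.702, 8.736,
            3.279, 6.072, 5.080, 5.530, 10.551, 9.135, 0, 2.985, 5.963),
    printedPct = c(62, 114, 100, 66, 122, 100, 0, 77, 100,
                   65, 120, 100, 61, 116, 100, 0, 50, 100))
  ratios <- data.frame(
    name = c("front/antenna length", "front/middle length",
             "middle/hind length left", "middle/hind length right",
             "front affordance/action left", "front affordance/action right",
             "middle affordance/action left", "middle affordance/action right",
             "rear affordance/action left", "rear affordance/action right",
             "middle/hind action left", "middle/hind action right"),
    printedPct = c(112, 130, 83, 84, 14, 10, 32, 45, 20, 24, 88, 93))
  list(regression = regression, datasets = datasets, volumes = volumes,
       affordances = affordances, ratios = ratios)
}

checkRow <- function(check, computed, printed, note = "") {
  pass <- isTRUE(all.equal(computed, printed, tolerance = 1e-9))
  data.frame(check = check, computed = computed, printed = printed,
             status = if (pass) "pass"
                      else if (nzchar(note)) "documented discrepancy"
                      else "fail",
             note = note)
}

#' Arithmetic consistency checks against the published reference values
#'
#' Recomputes every arithmetic identity implied by the published summary
#' numbers and compares it with the printed value: means of the per-DoF
#' regression MSEs against the printed overall MSEs, the per-joint RMSE
#' relations, the 80\% training-split sizes, the limb length-ratio
#' percentages, and the volume-ratio percentages of the volume and
#' affordance tables. Two known printing inconsistencies (the rear
#' affordance percentage on the right side, and the left/right ordering of
#' the middle-over-hind action-volume ratio) are reported as "documented
#' discrepancy" rather than failures.
#'
#' @return data.frame with columns \code{check}, \code{computed},
#'   \code{printed}, \code{status}, \code{note}.
#' @export
checkReferenceConsistency <- function() {
  rv <- referenceValues()
  model <- standardBody()
  out <- list()
  for (i in seq_len(nrow(rv$regression))) {
    r <- rv$regression[i, ]
    m <- round(mean(c(r$mseAlpha, r$mseBeta, r$mseGamma)), 1)
    out[[length(out) + 1]] <- checkRow(
      sprintf("mean MSE %s %s", r$pair, r$direction), m, r$printedMean)
    out[[length(out) + 1]] <- checkRow(
      sprintf("RMSE %s %s", r$pair, r$direction),
      round(sqrt(r$printedMean), 1), r$printedRmse)
  }
  for (i in which(!is.na(rv$datasets$printedTrain))) {
    d <- rv$datasets[i, ]
    out[[length(out) + 1]] <- checkRow(
      sprintf("80%% split of %d pairs", d$nPairs),
      trainSize(d$nPairs), d$printedTrain)
  }
  len <- function(l) limbLength(model, l)
  out[[length(out) + 1]] <- checkRow("front/antenna length %",
    lengthRatioPercent(len("L1"), len("LA")), 112)
  out[[length(out) + 1]] <- checkRow("front/middle length %",
    lengthRatioPercent(len("L1"), len("L2")), 130)
  out[[length(out) + 1]] <- checkRow("middle/hind length % left",
    lengthRatioPercent(len("L2"), len("L3")), 83)
  out[[length(out) + 1]] <- checkRow("middle/hind length % right",
    lengthRatioPercent(len("R2"), len("R3")), 84)
  ## volume-table percentage columns recomputed from the ccm columns
  v <- rv$volumes
  for (i in seq_len(nrow(v))) {
    whole <- v$ccm[v$side == v$side[i] & v$limb == v$limb[i] &
                     v$type == "action"]
    out[[length(out) + 1]] <- checkRow(
      sprintf("volume %% %s %s %s", v$side[i], v$limb[i], v$type[i]),
      volumeRatioPercent(v$ccm[i], whole), v$printedPct[i])
  }
  a <- rv$affordances
  for (i in seq_len(nrow(a))) {
    whole <- a$ccm[a$side == a$side[i] & a$pair == a$pair[i] &
                     a$type == "action"]
    if (whole == 0) next
    out[[length(out) + 1]] <- checkRow(
      sprintf("affordance %% %s %s %s", a$side[i], a$pair[i], a$type[i]),
      volumeRatioPercent(a$ccm[i], whole), a$printedPct[i])
  }
  ## affordance over limb action volume, as quoted in the running text
  av <- function(side, pair) a$ccm[a$side == side & a$pair == pair & a$type == "action"]
  lv <- function(side, limb) v$ccm[v$side == side & v$limb == limb & v$type == "action"]
  quoted <- rv$ratios
  pct <- function(nm) quoted$printedPct[quoted$name == nm]
  out[[length(out) + 1]] <- checkRow("front affordance/action % left",
    volumeRatioPercent(av("left", "Leg1/Ant"), lv("left", "front")),
    pct("front affordance/action left"))
  out[[length(out) + 1]] <- checkRow("front affordance/action % right",
    volumeRatioPercent(av("right", "Leg1/Ant"), lv("right", "front")),
    pct("front affordance/action right"))
  out[[length(out) + 1]] <- checkRow("middle affordance/action % left",
    volumeRatioPercent(av("left", "Leg2/Leg1"), lv("left", "middle")),
    pct("middle affordance/action left"))
  out[[length(out) + 1]] <- checkRow("middle affordance/action % right",
    volumeRatioPercent(av("right", "Leg2/Leg1"), lv("right", "middle")),
    pct("middle affordance/action right"))
  out[[length(out) + 1]] <- checkRow("rear affordance/action % left",
    volumeRatioPercent(av("left", "Leg3/Leg2"), lv("left", "hind")),
    pct("rear affordance/action left"))
  out[[length(out) + 1]] <- checkRow("rear affordance/action % right",
    volumeRatioPercent(av("right", "Leg3/Leg2"), lv("right", "hind")),
    pct("rear affordance/action right"),
    note = "printed 24; the tabulated ccm values give 22")
  out[[length(out) + 1]] <- checkRow("middle/hind action % left",
    volumeRatioPercent(lv("left", "middle"), lv("left", "hind")),
    pct("middle/hind action left"),
    note = "printed as '88 and 93% in left and right'; the tabulated ccm values give 93 (left) and 88 (right)")
  out[[length(out) + 1]] <- checkRow("middle/hind action % right",
    volumeRatioPercent(lv("right", "middle"), lv("right", "hind")),
    pct("middle/hind action right"),
    note = "see left-side note: printed ordering swapped")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end analysis: trial
#' generation, volume estimation, affordance intersection, contact
#' analysis, and the mapping-complexity study. The default problem sizes
#' are desk-scale: a few synthetic trials per paradigm and a reduced
#' network sweep.
#'
#' @param generator a \code{\link{generatorConfig}}.
#' @param nWalk,nSearch,nRod trial counts per paradigm.
#' @param rodHeights rod heights (mm) cycled over the rod trials.
#' @param limbs limbs to chart.
#' @param volumeTypes volume types to compute per limb.
#' @param thresholdFrac density threshold as a fraction of the maximum.
#' @param pairs list of limb pairs to intersect.
#' @param mappingPair leg pair for the network-complexity study.
#' @param hiddenSizes,reps,epochs sweep parameters.
#' @param outDir optional output directory for artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @param verbose print per-stage progress.
#' @return a validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(generator = generatorConfig(), nWalk = 6,
                           nSearch = 3, nRod = 10,
                           rodHeights = c(18, 36),
                           limbs = LIMB_IDS,
                           volumeTypes = c("tip", "contact", "action"),
                           thresholdFrac = 0.01,
                           pairs = list(c("L3", "L2"), c("L2", "L1"),
                                        c("R3", "R2"), c("R2", "R1"),
                                        c("L1", "LA"), c("R1", "RA")),
                           mappingPair = c("L2", "L3"),
                           hiddenSizes = c(2, 8), reps = 2, epochs = 150,
                           outDir = NULL, seed = 1L, verbose = TRUE) {
  if (nWalk < 1 || nRod < 0 || nSearch < 0)
    periStop("periSpace_config_error", "invalid trial counts")
  if (thresholdFrac <= 0 || thresholdFrac >= 1)
    periStop("periSpace_config_error", "thresholdFrac must be in (0,1)")
  if (!all(limbs %in% LIMB_IDS))
    periStop("periSpace_config_error", "unknown limb id")
  structure(list(generator = generator, nWalk = nWalk, nSearch = nSearch,
                 nRod = nRod, rodHeights = rodHeights, limbs = limbs,
                 volumeTypes = volumeTypes, thresholdFrac = thresholdFrac,
                 pairs = pairs, mappingPair = mappingPair,
                 hiddenSizes = hiddenSizes, reps = reps, epochs = epochs,
                 outDir = outDir, seed = as.integer(seed),
                 verbose = verbose),
            class = "PipelineConfig")
}

#' Run the full peripersonal-space analysis pipeline
#'
#' Generates synthetic trials, estimates tip / contact / action volumes
#' for the configured limbs, intersects neighboring limbs' action volumes
#' into affordance volumes, detects and summarizes first antennal rod
#' contacts, runs the posture-mapping complexity study on the configured
#' leg pair, and assembles the report tables together with the
#' published-value consistency checks. The run is deterministic for a
#' fixed configuration; artifacts are written to \code{outDir} when set.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param model the reference \linkS4class{BodyModel}.
#' @return a list of class \code{"ReportTables"}: \code{volumeTable},
#'   \code{affordanceTable}, \code{mappingTable}, \code{contactSummary},
#'   \code{consistency}, plus the intermediate \code{volumes},
#'   \code{affordances}, \code{sweep} and trial lists.
#' @export
runPipeline <- function(config = pipelineConfig(), model = standardBody()) {
  say <- function(...) if (config$verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e) periStop(
      "periSpace_stage_error",
      sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    say("stage %-10s %6.1f s", name, proc.time()[["elapsed"]] - s)
    r
  }
  seed <- config$seed
  trials <- stage("simulate", {
    walks <- lapply(seq_len(config$nWalk), function(i)
      generateWalkTrial(model, config$generator, deriveSeed(seed, paste0("walk", i))))
    searches <- lapply(seq_len(config$nSearch), function(i)
      generateSearchTrial(model, config$generator, deriveSeed(seed, paste0("search", i))))
    rods <- lapply(seq_len(config$nRod), function(i) {
      h <- config$rodHeights[(i - 1) %% length(config$rodHeights) + 1]
      generateRodTrial(model, config$generator,
                       rodSpec(height = h, radius = config$generator$rodRadius),
                       deriveSeed(seed, paste0("rod", i)))
    })
    list(walk = walks, search = searches, rod = rods)
  })
  volTrials <- c(trials$walk, trials$search)
  volumes <- stage("volumes", {
    v <- list()
    for (limb in config$limbs) {
      v[[limb]] <- list()
      for (type in config$volumeTypes) {
        g <- accumulateDensity(volTrials, limb, makeScheme(type, limb, model),
                               model)
        v[[limb]][[type]] <- extractVolume(smoothDensity(g),
                                           config$thresholdFrac)
      }
    }
    v
  })
  affordances <- stage("affordance", {
    a <- list()
    for (p in config$pairs) {
      key <- paste(p, collapse = "-")
      a[[key]] <- lapply(setNames(config$volumeTypes, config$volumeTypes),
                         function(ty)
        intersectVolumes(volumes[[p[1]]][[ty]], volumes[[p[2]]][[ty]], model))
    }
    a
  })
  contacts <- stage("contacts", {
    if (!length(trials$rod)) NULL else {
      ev <- list()
      for (tr in trials$rod) for (limb in ANTENNA_IDS)
        ev[[length(ev) + 1]] <- detectFirstContact(tr, limb = limb)
      ev <- Filter(Negate(is.null), ev)
      if (length(ev)) summarizeContacts(ev) else NULL
    }
  })
  mapping <- stage("map", {
    key <- paste(config$mappingPair, collapse = "-")
    aff <- if (key %in% names(affordances)) affordances[[key]][["action"]]
           else intersectVolumes(volumes[[config$mappingPair[1]]][["action"]],
                                 volumes[[config$mappingPair[2]]][["action"]],
                                 model)
    ds <- buildPairs(aff, config$mappingPair[1], config$mappingPair[2], model)
    sweep <- complexitySweep(ds, config$hiddenSizes, reps = config$reps,
                             cfg = mlpConfig(epochs = config$epochs),
                             seed = deriveSeed(seed, "sweep"))
    list(dataset = ds, sweep = sweep)
  })
  report <- stage("report", {
    vt <- do.call(rbind, lapply(config$limbs, function(limb)
      do.call(rbind, lapply(config$volumeTypes, function(ty) {
        b <- volumes[[limb]][[ty]]
        data.frame(limb = limb, type = ty, ccm = b@sizeCcm,
                   pctOfAction = volumeRatioPercent(
                     b, volumes[[limb]][["action"]]),
                   retainedPct = 100 * b@retainedFraction)
      }))))
    at <- do.call(rbind, lapply(names(affordances), function(key)
      do.call(rbind, lapply(names(affordances[[key]]), function(ty) {
        av <- affordances[[key]][[ty]]
        act <- affordances[[key]][["action"]]
        data.frame(pair = key, type = ty, ccm = av@sizeCcm,
                   pctOfAction = if (act@sizeCcm > 0)
                     volumeRatioPercent(av, act) else NA_integer_)
      }))))
    ds <- mapping$dataset
    ranges <- data.frame(
      leg = c(ds@sender, ds@receiver),
      alphaMin = c(min(ds@senderAngles[, 1]), min(ds@receiverAngles[, 1])),
      alphaMax = c(max(ds@senderAngles[, 1]), max(ds@receiverAngles[, 1])),
      betaMin = c(min(ds@senderAngles[, 2]), min(ds@receiverAngles[, 2])),
      betaMax = c(max(ds@senderAngles[, 2]), max(ds@receiverAngles[, 2])),
      gammaMin = c(min(ds@senderAngles[, 3]), min(ds@receiverAngles[, 3])),
      gammaMax = c(max(ds@senderAngles[, 3]), max(ds@receiverAngles[, 3])))
    structure(list(volumeTable = vt, affordanceTable = at,
                   mappingTable = list(jointRanges = ranges,
                                       sweep = mapping$sweep$summary),
                   contactSummary = contacts,
                   consistency = checkReferenceConsistency(),
                   volumes = volumes, affordances = affordances,
                   sweep = mapping$sweep, trials = trials,
                   seed = seed),
              class = "ReportTables")
  })
  if (!is.null(config$outDir)) stage("write", {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    od <- config$outDir
    wt <- function(df, f) {
      df2 <- df
      for (cl in names(df2)) if (is.double(df2[[cl]])) df2[[cl]] <- fmtNum(df2[[cl]])
      write.table(df2, file.path(od, f), sep = ",", quote = FALSE,
                  row.names = FALSE)
    }
    wt(report$volumeTable, "volume_table.csv")
    wt(report$affordanceTable, "affordance_table.csv")
    wt(mapping$sweep$runs, "mapping_sweep.csv")
    wt(report$consistency, "consistency.csv")
    for (limb in config$limbs) for (ty in config$volumeTypes)
      writeBinaryVolume(volumes[[limb]][[ty]],
                        file.path(od, sprintf("volume_%s_%s.txt", limb, ty)))
    if (!is.null(contacts)) {
      ev <- list()
      for (tr in trials$rod) for (limb in ANTENNA_IDS)
        ev[[length(ev) + 1]] <- detectFirstContact(tr, limb = limb)
      writeContactEvents(ev, file.path(od, "contact_events.csv"))
    }
    writeLines(c(sprintf("seed = %d", seed),
                 sprintf("generated = %d walk, %d search, %d rod trials",
                         config$nWalk, config$nSearch, config$nRod),
                 sprintf("threshold = %g of max density", config$thresholdFrac),
                 sprintf("package periSpace %s",
                         as.character(utils::packageVersion("periSpace")))),
               file.path(od, "provenance.txt"))
    invisible(NULL)
  })
  say("pipeline done in %.1f s", proc.time()[["elapsed"]] - t0)
  report
}

#' @export
print.ReportTables <- function(x, ...) {
  cat("ReportTables (seed", x$seed, ")\n\nVolume table (ccm):\n")
  print(x$volumeTable, row.names = FALSE)
  cat("\nAffordance table (ccm):\n")
  print(x$affordanceTable, row.names = FALSE)
  cat("\nMapping sweep (test MSE, deg^2):\n")
  print(x$mappingTable$sweep, row.names = FALSE)
  if (!is.null(x$contactSummary)) {
    cat("\n"); print(x$contactSummary)
  }
  nc <- table(x$consistency$status)
  cat("\nConsistency checks:", paste(names(nc), nc, collapse = ", "), "\n")
  invisible(x)
}
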