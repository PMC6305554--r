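anteriorRank <- c(LA = 0, RA = 0, L1 = 1, R1 = 1, L2 = 2, R2 = 2, L3 = 3, R3 = 3)

#' Build a matched posture-pair dataset from an affordance volume
#'
#' For every grid node of the affordance volume, inverse kinematics is
#' solved for both legs; nodes for which either solution fails (out of
#' workspace) or violates the joint-angle bounds are dropped and counted.
#' Each retained node yields one training sample: the sender-leg joint
#' angles (input), the receiver-leg joint angles (target), and the shared
#' tibia-tarsus joint position.
#'
#' @param affordance an \linkS4class{AffordanceVolume} of two legs.
#' @param sender,receiver the two leg ids of the affordance volume, in the
#'   mapping direction of interest.
#' @param model the standardized \linkS4class{BodyModel}.
#' @param bounds optional joint-bounds data.frame (see
#'   \code{\link{jointBounds}}); defaults to the bound set matching the
#'   leg pair.
#' @param checkBounds logical; drop postures outside \code{bounds}. Set
#'   \code{FALSE} to keep every kinematically reachable node.
#' @return a \linkS4class{PosturePairDataset}.
#' @export
buildPairs <- function(affordance, sender, receiver, model = standardBody(),
                       bounds = NULL, checkBounds = TRUE) {
  if (!setequal(c(sender, receiver), affordance@limbs))
    periStop("periSpace_config_error",
             "sender/receiver must be the affordance volume's limbs")
  if (!isLeg(sender) || !isLeg(receiver))
    periStop("periSpace_invalid_limb", "posture mapping is defined for legs")
  nodes <- affordance@nodes
  if (nrow(nodes) == 0)
    periStop("periSpace_empty_dataset", "empty affordance volume")
  if (is.null(bounds) && checkBounds) {
    set <- if (any(c(sender, receiver) %in% c("L1", "R1"))) "front-mid" else "mid-hind"
    bounds <- jointBounds(set)
  }
  solveLeg <- function(leg) {
    ox <- c(segmentOriginX(model, limbCarrier(model, leg)), 0, 0)
    target <- sweep(nodes, 2, ox, "-")     # node in the carrying-segment frame
    A <- ikLeg(model, leg, target, onUnreachable = "na")
    ok <- !is.na(A[, 1])
    if (checkBounds) {
      b <- bounds[bounds$limb == leg, ]
      if (nrow(b) == 1)
        ok <- ok & A[, 1] >= b$alphaMin & A[, 1] <= b$alphaMax &
          A[, 2] >= b$betaMin & A[, 2] <= b$betaMax &
          A[, 3] >= b$gammaMin & A[, 3] <= b$gammaMax
    }
    list(A = A, ok = ok)
  }
  s <- solveLeg(sender)
  r <- solveLeg(receiver)
  keep <- s$ok & r$ok
  if (!any(keep))
    periStop("periSpace_empty_dataset", "no doubly reachable nodes")
  direction <- if (anteriorRank[sender] <= anteriorRank[receiver])
    "front-to-back" else "back-to-front"
  new("PosturePairDataset", sender = sender, receiver = receiver,
      direction = direction,
      senderAngles = s$A[keep, , drop = FALSE],
      receiverAngles = r$A[keep, , drop = FALSE],
      positions = nodes[keep, , drop = FALSE] + 0,
      nodes = nodes[keep, , drop = FALSE],
      dropped = sum(!keep))
}

#' Construct an affordance volume from doubly reachable grid nodes
#'
#' Scans the standardized 1 mm grid for nodes whose position is inside the
#' kinematic workspace of both legs under the given joint bounds. This is
#' the purely geometric counterpart of the occupancy-based
#' \code{\link{intersectVolumes}}: it asks where both legs \emph{could}
#' place their tibia-tarsus joints, rather than where they were observed
#' to move, and is useful for constructing large, noise-free posture-pair
#' datasets.
#'
#' @param model the standardized \linkS4class{BodyModel}.
#' @param legA,legB two leg ids.
#' @param bounds joint-bounds data.frame; defaults to the set matching the
#'   pair.
#' @return an \linkS4class{AffordanceVolume}.
#' @export
reachableAffordance <- function(model, legA, legB, bounds = NULL) {
  if (is.null(bounds)) {
    set <- if (any(c(legA, legB) %in% c("L1", "R1"))) "front-mid" else "mid-hind"
    bounds <- jointBounds(set)
  }
  ## candidate nodes: intersection of both limbs' grid extents in the body
  ## frame (nodes outside either extent cannot be in the affordance volume)
  shiftA <- as.integer(round(limbBaseBody(model, legA)))
  shiftB <- as.integer(round(limbBaseBody(model, legB)))
  lo <- pmax(GRID_ORIGIN + shiftA, GRID_ORIGIN + shiftB)
  hi <- pmin(GRID_ORIGIN + 89L + shiftA, GRID_ORIGIN + 89L + shiftB)
  if (any(lo > hi))
    periStop("periSpace_empty_dataset", "limb grid extents do not overlap")
  cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  ok <- rep(TRUE, nrow(cand))
  for (leg in c(legA, legB)) {
    ox <- c(segmentOriginX(model, limbCarrier(model, leg)), 0, 0)
    A <- ikLeg(model, leg, sweep(cand, 2, ox, "-"), onUnreachable = "na")
    good <- !is.na(A[, 1])
    b <- bounds[bounds$limb == leg, ]
    if (nrow(b) == 1)
      good <- good & A[, 1] >= b$alphaMin & A[, 1] <= b$alphaMax &
        A[, 2] >= b$betaMin & A[, 2] <= b$betaMax &
        A[, 3] >= b$gammaMin & A[, 3] <= b$gammaMax
    ok <- ok & good
  }
  nodes <- orderNodes(cand[ok, , drop = FALSE])
  storage.mode(nodes) <- "integer"
  colnames(nodes) <- c("x", "y", "z")
  new("AffordanceVolume", limbs = c(legA, legB), nodes = nodes,
      sizeCcm = nrow(nodes) / 1000, spacing = 1)
}

#' Reverse the mapping direction of a posture-pair dataset
#'
#' Swaps sender and receiver, producing the reverse-direction dataset with
#' the identical pair count.
#'
#' @param ds a \linkS4class{PosturePairDataset}.
#' @export
reverseDataset <- function(ds) {
  new("PosturePairDataset", sender = ds@receiver, receiver = ds@sender,
      direction = if (ds@direction == "front-to-back") "back-to-front"
                  else "front-to-back",
      senderAngles = ds@receiverAngles, receiverAngles = ds@senderAngles,
      positions = ds@positions, nodes = ds@nodes, dropped = ds@dropped)
}

#' Number of posture pairs
#' @param ds a \linkS4class{PosturePairDataset}.
#' @export
nPairs <- function(ds) nrow(ds@senderAngles)

takePairs <- function(ds, idx) {
  new("PosturePairDataset", sender = ds@sender, receiver = ds@receiver,
      direction = ds@direction,
      senderAngles = ds@senderAngles[idx, , drop = FALSE],
      receiverAngles = ds@receiverAngles[idx, , drop = FALSE],
      positions = ds@positions[idx, , drop = FALSE],
      nodes = ds@nodes[idx, , drop = FALSE], dropped = ds@dropped)
}

setMethod("show", "PosturePairDataset", function(object) {
  cat(sprintf(
    "PosturePairDataset: %s -> %s (%s), %d pairs (%g nodes dropped)\n",
    object@sender, object@receiver, object@direction, nPairs(object),
    object@dropped))
})

#' Split a posture-pair dataset into training and testing parts
#'
#' Uniform random partition without replacement; the training part has
#' \code{floor(trainFrac * n)} samples (so 5,500 pairs give 4,400 and
#' 8,382 give 6,705 at the default 80\%).
#'
#' @param ds a \linkS4class{PosturePairDataset} with at least 5 pairs.
#' @param trainFrac training fraction.
#' @param seed integer seed.
#' @return list with elements \code{train} and \code{test}.
#' @export
splitDataset <- function(ds, trainFrac = 0.8, seed = 1L) {
  n <- nPairs(ds)
  if (n < 5)
    periStop("periSpace_empty_dataset", "need at least 5 pairs to split")
  ntr <- trainSize(n, trainFrac)
  idx <- withSeed(seed, sample.int(n, ntr))
  list(train = takePairs(ds, sort(idx)),
       test = takePairs(ds, setdiff(seq_len(n), idx)))
}

#' Training-set size of an n-sample dataset at a split fraction
#'
#' @param n dataset size.
#' @param trainFrac training fraction (default 0.8).
#' @return \code{floor(trainFrac * n)}.
#' @examples
#' trainSize(5500)  # 4400
#' trainSize(8382)  # 6705
#' @export
trainSize <- function(n, trainFrac = 0.8) as.integer(floor(trainFrac * n))

makeTrainResult <- function(perDof, curve = data.frame(), config = list(),
                            seed = NA_integer_) {
  perDof <- setNames(as.numeric(perDof), c("alpha", "beta", "gamma"))
  m <- mean(perDof)
  new("TrainResult", perDofMSE = perDof, meanMSE = m, rmse = sqrt(m),
      curve = curve, config = config, seed = as.integer(seed))
}

setMethod("show", "TrainResult", function(object) {
  cat(sprintf(
    "TrainResult (%s): mean MSE %.3f deg^2 (RMSE %.2f deg); per DoF %s\n",
    if (!is.null(object@config$method)) object@config$method else "?",
    object@meanMSE, object@rmse,
    paste(sprintf("%s %.3f", names(object@perDofMSE), object@perDofMSE),
          collapse = ", ")))
})

#' Optimal linear posture mapping (regression baseline)
#'
#' Fits the least-squares affine map from sender to receiver joint angles
#' via the normal equation / pseudo-inverse; this is the no-hidden-layer
#' network benchmark. A rank-deficient design falls back to the
#' minimum-norm solution and is flagged.
#'
#' @param train,test \linkS4class{PosturePairDataset}s (the test part is
#'   used only for error reporting).
#' @return list with \code{map} (elements \code{W} 3 x 3, \code{b}
#'   length 3, \code{rankDeficient}) and \code{result} (a
#'   \linkS4class{TrainResult} with per-DoF and mean test MSE in deg^2).
#' @export
fitLinear <- function(train, test) {
  S <- train@senderAngles
  if (nrow(S) < 4)
    periStop("periSpace_empty_dataset", "need >= 4 training pairs")
  X <- cbind(1, S)
  Y <- train@receiverAngles
  qx <- qr(X)
  rankDeficient <- qx$rank < ncol(X)
  B <- if (rankDeficient) MASS::ginv(X) %*% Y else qr.coef(qx, Y)
  map <- list(W = B[-1, , drop = FALSE], b = as.numeric(B[1, ]),
              rankDeficient = rankDeficient)
  pred <- cbind(1, test@senderAngles) %*% B
  perDof <- colMeans((pred - test@receiverAngles)^2)
  list(map = map,
       result = makeTrainResult(perDof, config = list(
         method = "linear", rankDeficient = rankDeficient)))
}

#' Configuration of the feed-forward posture-mapping network
#'
#' A single-hidden-layer network with sigmoid hidden units and linear
#' outputs, optionally with skip connections from the inputs directly to
#' the outputs, trained with mini-batch Adam (stock hyperparameters:
#' learning rate 0.001, beta1 0.9, beta2 0.999, epsilon 1e-8) and Glorot
#' uniform weight initialization. Inputs are z-scored on training
#' statistics; outputs stay in raw degrees, so errors are in deg^2.
#'
#' @param hidden hidden-layer size \code{n1 >= 0} (0 requires
#'   \code{skip = TRUE}).
#' @param skip add input-to-output skip connections.
#' @param epochs training epochs.
#' @param batch mini-batch size.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param curveStride record the learning curve every this many epochs.
#' @param seed integer seed for initialization and batch shuffling.
#' @return validated list of class \code{"MLPConfig"}.
#' @export
mlpConfig <- function(hidden = 8, skip = FALSE, epochs = 5000, batch = 10,
                      lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      curveStride = 10, seed = 1L) {
  if (epochs < 1 || batch < 1 || hidden < 0 || (hidden == 0 && !skip))
    periStop("periSpace_config_error", "invalid network configuration")
  structure(list(hidden = as.integer(hidden), skip = skip,
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                 curveStride = as.integer(curveStride),
                 seed = as.integer(seed)),
            class = "MLPConfig")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

mlpForward <- function(par, X) {
  out <- matrix(par$b2, nrow(X), 3, byrow = TRUE)
  H <- NULL
  if (ncol(par$W1) > 0) {
    H <- sigmoid(sweep(X %*% par$W1, 2, par$b1, "+"))
    out <- out + H %*% par$W2
  }
  if (!is.null(par$Ws)) out <- out + X %*% par$Ws
  list(out = out, H = H)
}

## mean-squared-error loss (mean over samples and output DoF) and its
## gradients; used by the trainer and by the finite-difference check
mlpLossGrad <- function(par, X, Y) {
  fw <- mlpForward(par, X)
  E <- fw$out - Y
  loss <- mean(E^2)
  dOut <- 2 * E / length(E)
  g <- list(b2 = colSums(dOut))
  if (ncol(par$W1) > 0) {
    H <- fw$H
    g$W2 <- t(H) %*% dOut
    dH <- dOut %*% t(par$W2)
    dZ <- dH * H * (1 - H)
    g$W1 <- t(X) %*% dZ
    g$b1 <- colSums(dZ)
  } else {
    g$W2 <- matrix(0, 0, 3); g$W1 <- matrix(0, 3, 0); g$b1 <- numeric(0)
  }
  if (!is.null(par$Ws)) g$Ws <- t(X) %*% dOut
  list(loss = loss, grad = g)
}

newMlpParams <- function(cfg) {
  n1 <- cfg$hidden
  par <- list(W1 = glorot(3, max(n1, 0)), b1 = numeric(n1),
              W2 = glorot(max(n1, 0), 3), b2 = numeric(3))
  if (n1 == 0) { par$W1 <- matrix(0, 3, 0); par$W2 <- matrix(0, 0, 3) }
  if (cfg$skip) par$Ws <- glorot(3, 3)
  par
}

#' Train the posture-mapping network
#'
#' Mini-batch Adam training of the network defined by \code{cfg} on a
#' training dataset, with a learning curve recorded every
#' \code{curveStride} epochs (and at the final epoch). Batches are
#' reshuffled every epoch with the run seed; results are bitwise
#' reproducible for a fixed configuration and seed.
#'
#' @param train,test \linkS4class{PosturePairDataset}s.
#' @param cfg an \code{\link{mlpConfig}}.
#' @return list with \code{model} (parameters + input standardization,
#'   class \code{"MLPModel"}) and \code{result} (a
#'   \linkS4class{TrainResult}; per-DoF and mean test MSE in deg^2).
#' @export
trainMlp <- function(train, test, cfg = mlpConfig()) {
  mu <- colMeans(train@senderAngles)
  sg <- apply(train@senderAngles, 2, sd)
  sg[sg == 0] <- 1
  Xtr <- scale(train@senderAngles, center = mu, scale = sg)
  Xte <- scale(test@senderAngles, center = mu, scale = sg)
  Ytr <- train@receiverAngles
  Yte <- test@receiverAngles
  n <- nrow(Xtr)
  withSeed(cfg$seed, {
    par <- newMlpParams(cfg)
    mAdam <- lapply(par, function(p) p * 0)
    vAdam <- lapply(par, function(p) p * 0)
    tstep <- 0
    curve <- list()
    nb <- ceiling(n / cfg$batch)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * cfg$batch + 1):min(bi * cfg$batch, n)]
        lg <- mlpLossGrad(par, Xtr[idx, , drop = FALSE],
                          Ytr[idx, , drop = FALSE])
        if (!is.finite(lg$loss))
          periStop("periSpace_divergence",
                   sprintf("non-finite loss at epoch %d", epoch))
        tstep <- tstep + 1
        for (nm in names(lg$grad)) {
          g <- lg$grad[[nm]]
          mAdam[[nm]] <- cfg$beta1 * mAdam[[nm]] + (1 - cfg$beta1) * g
          vAdam[[nm]] <- cfg$beta2 * vAdam[[nm]] + (1 - cfg$beta2) * g^2
          mhat <- mAdam[[nm]] / (1 - cfg$beta1^tstep)
          vhat <- vAdam[[nm]] / (1 - cfg$beta2^tstep)
          par[[nm]] <- par[[nm]] - cfg$lr * mhat / (sqrt(vhat) + cfg$eps)
        }
      }
      if (epoch %% cfg$curveStride == 0 || epoch == cfg$epochs) {
        curve[[length(curve) + 1]] <- data.frame(
          epoch = epoch,
          train = mean((mlpForward(par, Xtr)$out - Ytr)^2),
          test = mean((mlpForward(par, Xte)$out - Yte)^2))
      }
    }
    pred <- mlpForward(par, Xte)$out
    perDof <- colMeans((pred - Yte)^2)
    model <- structure(list(par = par, mu = mu, sigma = sg, cfg = cfg),
                       class = "MLPModel")
    list(model = model,
         result = makeTrainResult(perDof, curve = do.call(rbind, curve),
                                  config = unclass(cfg), seed = cfg$seed))
  })
}

#' Predict receiver-leg angles with a trained network
#'
#' @param model an \code{"MLPModel"} from \code{\link{trainMlp}} or
#'   \code{\link{mlpFromLinearMap}}.
#' @param senderAngles n x 3 matrix of sender joint angles (degrees).
#' @return n x 3 matrix of predicted receiver joint angles (degrees).
#' @export
predictMlp <- function(model, senderAngles) {
  X <- scale(senderAngles, center = model$mu, scale = model$sigma)
  mlpForward(model$par, X)$out
}

#' Embed a fitted linear map into a skip-connection network
#'
#' Constructs a skip-connection network whose hidden-to-output weights are
#' zero and whose skip weights reproduce a fitted linear map exactly
#' (after accounting for the input standardization). Demonstrates that
#' the skip architecture contains the regression solution as a special
#' case: the returned network's predictions equal the linear map's.
#'
#' @param map the \code{map} element returned by \code{\link{fitLinear}}.
#' @param train the training \linkS4class{PosturePairDataset} defining the
#'   input standardization.
#' @param hidden hidden-layer size of the host network.
#' @return an \code{"MLPModel"}.
#' @export
mlpFromLinearMap <- function(map, train, hidden = 2) {
  mu <- colMeans(train@senderAngles)
  sg <- apply(train@senderAngles, 2, sd)
  sg[sg == 0] <- 1
  ## raw-space y = W' s + b; with z = (s - mu)/sigma the skip weights are
  ## sigma_i * W[i, j] and the bias absorbs mu' W + b
  par <- list(W1 = matrix(0, 3, hidden), b1 = numeric(hidden),
              W2 = matrix(0, hidden, 3),
              b2 = as.numeric(mu %*% map$W + map$b),
              Ws = map$W * sg)
  structure(list(par = par, mu = mu, sigma = sg,
                 cfg = mlpConfig(hidden = hidden, skip = TRUE)),
            class = "MLPModel")
}

#' Network-complexity sweep over hidden-layer sizes
#'
#' Trains the mapping network at each hidden-layer size for several
#' repetitions with distinct seeds (fixed train/test split, re-initialized
#' weights per repetition), in one or both mapping directions, and reports
#' the per-repetition and aggregated test errors together with the linear
#' regression baseline.
#'
#' @param ds a \linkS4class{PosturePairDataset}.
#' @param hiddenSizes integer vector of hidden-layer sizes.
#' @param reps repetitions per size.
#' @param cfg base \code{\link{mlpConfig}} (its \code{hidden} and
#'   \code{seed} are overridden per run).
#' @param seed master seed (drives the split and the per-run seeds).
#' @param directions \code{"both"}, \code{"forward"} (the dataset's own
#'   direction) or \code{"reverse"}.
#' @param trainFrac train/test split fraction.
#' @return list with \code{runs} (one row per trained network:
#'   direction, hidden, rep, per-DoF MSE, mean MSE), \code{summary}
#'   (mean and SD of mean MSE per direction and size, with the regression
#'   baseline as size \code{NA}), and \code{results} (the
#'   \linkS4class{TrainResult} objects).
#' @export
complexitySweep <- function(ds, hiddenSizes = c(1, 2, 4, 8, 16, 32),
                            reps = 5, cfg = mlpConfig(), seed = 1L,
                            directions = c("both", "forward", "reverse"),
                            trainFrac = 0.8) {
  directions <- match.arg(directions)
  sets <- list(forward = ds)
  if (directions %in% c("both", "reverse")) sets$reverse <- reverseDataset(ds)
  if (directions == "reverse") sets$forward <- NULL
  runs <- list(); summaries <- list(); results <- list()
  for (dn in names(sets)) {
    d <- sets[[dn]]
    sp <- splitDataset(d, trainFrac, seed = deriveSeed(seed, paste0("split-", dn)))
    lin <- fitLinear(sp$train, sp$test)
    runs[[length(runs) + 1]] <- data.frame(
      direction = d@direction, hidden = NA_integer_, rep = 1L,
      mseAlpha = lin$result@perDofMSE[1], mseBeta = lin$result@perDofMSE[2],
      mseGamma = lin$result@perDofMSE[3], meanMSE = lin$result@meanMSE)
    results[[paste0(dn, "-linear")]] <- lin$result
    for (h in hiddenSizes) for (r in seq_len(reps)) {
      rcfg <- cfg
      rcfg$hidden <- as.integer(h)
      rcfg$seed <- deriveSeed(seed, sprintf("%s-h%d-r%d", dn, h, r))
      fit <- trainMlp(sp$train, sp$test, rcfg)
      runs[[length(runs) + 1]] <- data.frame(
        direction = d@direction, hidden = as.integer(h), rep = as.integer(r),
        mseAlpha = fit$result@perDofMSE[1], mseBeta = fit$result@perDofMSE[2],
        mseGamma = fit$result@perDofMSE[3], meanMSE = fit$result@meanMSE)
      results[[sprintf("%s-h%d-r%d", dn, h, r)]] <- fit$result
    }
  }
  runs <- do.call(rbind, runs)
  rownames(runs) <- NULL
  summary <- do.call(rbind, lapply(
    split(runs, list(runs$direction, runs$hidden), drop = TRUE),
    function(g) data.frame(direction = g$direction[1], hidden = g$hidden[1],
                           meanMSE = mean(g$meanMSE),
                           sdMSE = if (nrow(g) > 1) sd(g$meanMSE) else 0)))
  base <- runs[is.na(runs$hidden), ]
  summary <- rbind(summary, data.frame(direction = base$direction,
                                       hidden = NA_integer_,
                                       meanMSE = base$meanMSE, sdMSE = 0))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary, results = results)
}

#' Write a complexity-sweep run table as delimited text
#'
#' @param sweep result of \code{\link{complexitySweep}}.
#' @param path file path.
#' @export
writeSweep <- function(sweep, path) {
  df <- sweep$runs
  for (cl in names(df)) if (is.double(df[[cl]])) df[[cl]] <- fmtNum(df[[cl]])
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a trained network as delimited text
#'
#' Serializes the layer shapes and row-major weight values, the input
#' standardization, and the architecture flags, so a trained mapping can
#' be stored and reloaded losslessly.
#'
#' @param model an \code{"MLPModel"}.
#' @param path file path.
#' @return \code{readMlpModel} returns the reconstructed \code{"MLPModel"};
#'   its predictions equal the original's exactly.
#' @export
writeMlpModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- model$cfg
  writeLines(c(paste0("# hidden = ", cfg$hidden),
               paste0("# skip = ", cfg$skip),
               paste0("# mu = ", paste(fmtNum(model$mu), collapse = ",")),
               paste0("# sigma = ", paste(fmtNum(model$sigma), collapse = ","))),
             con)
  for (nm in names(model$par)) {
    p <- model$par[[nm]]
    d <- if (is.matrix(p)) dim(p) else c(length(p), 1L)
    writeLines(paste(nm, d[1], d[2],
                     paste(fmtNum(as.vector(t(matrix(p, d[1], d[2])))),
                           collapse = " ")), con)
  }
  invisible(path)
}

#' @rdname writeMlpModel
#' @export
readMlpModel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " = "))
  meta <- setNames(kv[, 2], kv[, 1])
  par <- list()
  vecSlots <- c("b1", "b2")
  for (ln in lines[!grepl("^#", lines)]) {
    f <- strsplit(ln, " ")[[1]]
    nm <- f[1]; nr <- as.integer(f[2]); nc <- as.integer(f[3])
    vals <- as.numeric(f[-(1:3)])
    par[[nm]] <- if (nm %in% vecSlots) vals
                 else matrix(vals, nr, nc, byrow = TRUE)
  }
  structure(list(par = par,
                 mu = as.numeric(strsplit(meta[["mu"]], ",")[[1]]),
                 sigma = as.numeric(strsplit(meta[["sigma"]], ",")[[1]]),
                 cfg = mlpConfig(hidden = as.integer(meta[["hidden"]]),
                                 skip = as.logical(meta[["skip"]]))),
            class = "MLPModel")
}
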