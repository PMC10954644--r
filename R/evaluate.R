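# Forecast metrics and comparison drivers.

#' Normalised root-mean-square forecast error
#'
#' \deqn{RMSE(t) = \sqrt{\frac{1}{N}\sum_i
#'   \left[\frac{\hat x_i(t) - x_i(t)}{\sigma_i}\right]^2}}
#' with \eqn{\sigma_i} the standard deviation of variable \eqn{i}
#' (conventionally computed over the test-truth window).
#'
#' @param pred predicted state (vector) or matrix of states.
#' @param truth matching true state(s).
#' @param sigma per-variable scales \eqn{\sigma_i > 0}.
#' @return \code{rmseAt}: a scalar; \code{rmseSeries}: one value per row.
#' @examples
#' rmseAt(c(0.6, 0.8), c(0, 0), sigma = c(2, 2))  # sqrt((0.09 + 0.16)/2)
#' @export
rmseAt <- function(pred, truth, sigma) {
  if (any(sigma <= 0)) stopf("sigma must be positive (constant variable?)")
  z <- (as.numeric(pred) - as.numeric(truth)) / sigma
  sqrt(mean(z^2))
}

#' @rdname rmseAt
#' @export
rmseSeries <- function(pred, truth, sigma) {
  P <- if (is(pred, "Trajectory")) states(pred) else as.matrix(pred)
  Q <- if (is(truth, "Trajectory")) states(truth) else as.matrix(truth)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == ncol(Q))
  Z <- sweep(P - Q, 2, sigma, `/`)
  sqrt(rowMeans(Z^2))
}

#' Valid prediction steps
#'
#' The first forecast step whose normalised RMSE exceeds the threshold
#' \eqn{\epsilon_r} (0-based, i.e. the number of steps that stayed within
#' tolerance); the full series length if it never does.  The conventional
#' threshold is 0.01 (0.03 for noisy data).
#'
#' @param pred forecast ([Trajectory-class] or matrix).
#' @param truth matching truth.
#' @param epsR threshold \eqn{\epsilon_r}.
#' @param sigma per-variable scales; defaults to the column standard
#'   deviations of \code{truth}.
#' @return Integer count of valid steps.
#' @export
validPredictionSteps <- function(pred, truth, epsR = 0.01, sigma = NULL) {
  Q <- if (is(truth, "Trajectory")) states(truth) else as.matrix(truth)
  P <- if (is(pred, "Trajectory")) states(pred) else as.matrix(pred)
  if (nrow(P) == 0) return(0L)
  sigma <- sigma %||% apply(Q, 2, sd)
  r <- rmseSeries(P, Q[seq_len(nrow(P)), , drop = FALSE], sigma)
  bad <- which(r > epsR)
  if (length(bad) == 0) nrow(P) else bad[1] - 1L
}

#' Compare forecasting methods on one system
#'
#' Splits the trajectory into train/test, trains each requested method once
#' on the training segment, then forecasts from randomly chosen test
#' anchors and scores each forecast by its valid prediction steps against
#' the true continuation.  All methods share the training data, the
#' hyperparameters, and the anchor set; \eqn{\sigma_i} is computed over the
#' test-truth segment.  A forecast that diverges before the horizon scores
#' the steps it produced.
#'
#' @param traj full [Trajectory-class].
#' @param structure a [HigherOrderStructure-class] (for \code{"prc"} /
#'   \code{"hogrc"}).
#' @param methods subset of \code{c("rc", "prc", "hogrc")}.
#' @param cfg shared [ReservoirConfig-class].
#' @param nStarts number of forecast anchors.
#' @param horizon forecast length (steps).
#' @param trainFrac fraction of the data used for training (default 60\%).
#' @param warmLen true samples used to warm the reservoirs before each
#'   forecast.
#' @param epsR RMSE threshold for the step count.
#' @param seed seed for the anchor draw.
#' @return data.frame with columns \code{method}, \code{anchor},
#'   \code{vps}; summary statistics via [summarizeComparison()].
#' @export
runComparison <- function(traj, structure = NULL,
                          methods = c("rc", "prc", "hogrc"),
                          cfg = reservoirConfig(), nStarts = 50,
                          horizon = 1000, trainFrac = 0.6, warmLen = 200,
                          epsR = 0.01, seed = 1L) {
  X <- states(traj)
  Tn <- nrow(X)
  trainEnd <- floor(trainFrac * Tn)
  trainTraj <- windowTrajectory(traj, seq_len(trainEnd))
  testRows <- (trainEnd + 1):Tn
  sigma <- apply(X[testRows, , drop = FALSE], 2, sd)
  ok <- testRows[testRows - warmLen + 1 >= 1 & testRows + horizon <= Tn]
  if (length(ok) == 0) stopf("no test anchor leaves room for the horizon")
  anchors <- withSeed(seedStream(seed, "anchors"),
                      sort(sample(ok, min(nStarts, length(ok)))))
  out <- list()
  for (method in methods) {
    model <- trainForecaster(trainTraj, method, structure, cfg)
    vps <- vapply(anchors, function(a) {
      warm <- windowTrajectory(traj, (a - warmLen + 1):a)
      fc <- multiStepForecast(model, warm, horizon)
      P <- if (is(fc, "Trajectory")) states(fc) else fc
      truthSeg <- X[a + seq_len(nrow(P)), , drop = FALSE]
      as.integer(validPredictionSteps(P, truthSeg, epsR, sigma))
    }, integer(1))
    out[[method]] <- data.frame(method = method, anchor = anchors, vps = vps)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summary of a comparison run
#'
#' @param comparison output of [runComparison()].
#' @return data.frame of per-method median and quartiles of the valid
#'   prediction steps.
#' @export
summarizeComparison <- function(comparison) {
  do.call(rbind, lapply(split(comparison, comparison$method), function(d) {
    q <- quantile(d$vps, c(0.25, 0.5, 0.75))
    data.frame(method = d$method[1], n = nrow(d),
               q25 = q[1], median = q[2], q75 = q[3], row.names = NULL)
  }))
}

#' Sweep one experimental axis
#'
#' Repeats [runComparison()] along a grid of one factor — observation-noise
#' intensity, training length, network size, or topology kind — with shared
#' seeds, and returns a tidy long table.  Per-point failures are recorded
#' and the sweep continues.
#'
#' @param axis one of \code{"noise"}, \code{"train_size"},
#'   \code{"network_size"}, \code{"topology"}.
#' @param grid vector of axis values (noise intensities, training lengths,
#'   subsystem counts, or topology kind names).
#' @param sys a [SystemParams-class] describing the base system.
#' @param net base [CouplingNetwork-class] (rebuilt for network axes).
#' @param steps simulated length.
#' @param methods,cfg,nStarts,horizon,epsR,seed passed to
#'   [runComparison()].
#' @param noiseMode mode for [addObservationNoise()].
#' @param topology,degree topology parameters used when the axis rebuilds
#'   the network.
#' @return Long data.frame: \code{axis}, \code{value}, \code{method},
#'   \code{anchor}, \code{vps}; failures as attribute \code{"failures"}.
#' @export
runSweep <- function(axis = c("noise", "train_size", "network_size", "topology"),
                     grid, sys, net = NULL, steps = 5000,
                     methods = c("rc", "prc", "hogrc"),
                     cfg = reservoirConfig(), nStarts = 20, horizon = 500,
                     epsR = 0.01, seed = 1L, noiseMode = "per-variable-std",
                     topology = "regular", degree = 2) {
  axis <- match.arg(axis)
  base <- if (axis %in% c("noise", "train_size"))
    simulateSystem(sys, net, steps = max(steps, if (axis == "train_size")
      max(unlist(grid)) else 0), seed = seed)
  out <- list(); failures <- list()
  for (v in grid) {
    res <- tryCatch({
      if (axis == "noise") {
        traj <- addObservationNoise(base, v, mode = noiseMode, seed = seed)
        struct <- trueStructure(sys, net)
      } else if (axis == "train_size") {
        traj <- windowTrajectory(base, seq_len(v))
        struct <- trueStructure(sys, net)
      } else {
        m <- if (axis == "network_size") v else sys@m
        kind <- if (axis == "topology") v else topology
        netV <- generateNetwork(kind, m = m, degree = degree,
                                edges = round(1.1 * m), seed = seed)
        sysV <- systemParams(sys@name, m = m, dt = sys@dt,
                             params = sys@params[setdiff(names(sys@params),
                                                         c("h", "omega"))],
                             seed = seed)
        traj <- simulateSystem(sysV, netV, steps = steps, seed = seed)
        struct <- trueStructure(sysV, netV)
      }
      cmp <- runComparison(traj, struct, methods = methods, cfg = cfg,
                           nStarts = nStarts, horizon = horizon, epsR = epsR,
                           seed = seed)
      cbind(axis = axis, value = v, cmp)
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[as.character(v)]] <- conditionMessage(res)
    else out[[as.character(v)]] <- res
  }
  out <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(out, "failures") <- failures
  out
}
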