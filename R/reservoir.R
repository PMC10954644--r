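# Node-level echo-state reservoirs with higher-order structure masks.
#
# Three model families share one construction: a node reservoir built from a
# set of complexes S_u has its input matrix partitioned into |S_u| equal row
# blocks (block i sees only the variables of complex s_{u,i}) and a
# block-diagonal adjacency; the classic RC is the degenerate single-complex
# case over all variables with a multivariate readout, and the parallel RC
# (PRC) is the single-complex case over a node's pairwise neighbours.

#' Reservoir hyperparameters
#'
#' @slot n reservoir size (neurons per node); internally rounded down to a
#'   multiple of the number of complexes.
#' @slot leak leaky rate \eqn{l \in (0, 1]}.
#' @slot spectralRadius target spectral radius of the adjacency.
#' @slot inputScale magnitude of the uniform input-weight draw.
#' @slot density fraction of nonzeros in each adjacency block.
#' @slot biasScale magnitude of the uniform bias draw.
#' @slot ridge Tikhonov regularisation coefficient \eqn{\lambda_W}.
#' @slot washout initial driven steps excluded from the readout regression.
#' @slot seed master seed; matrix draws use substreams keyed by node and
#'   structure so candidate comparisons are reproducible.
#'
#' @exportClass ReservoirConfig
setClass("ReservoirConfig",
         representation(n = "integer", leak = "numeric",
                        spectralRadius = "numeric", inputScale = "numeric",
                        density = "numeric", biasScale = "numeric",
                        ridge = "numeric", washout = "integer",
                        seed = "integer"))

setValidity("ReservoirConfig", function(object) {
  msgs <- character(0)
  if (object@n < 1) msgs <- c(msgs, "n must be >= 1")
  if (object@leak <= 0 || object@leak > 1) msgs <- c(msgs, "leak must be in (0, 1]")
  if (object@spectralRadius < 0) msgs <- c(msgs, "spectralRadius must be >= 0")
  if (object@density <= 0 || object@density > 1) msgs <- c(msgs, "density in (0, 1]")
  if (object@ridge < 0) msgs <- c(msgs, "ridge must be >= 0")
  if (object@washout < 0) msgs <- c(msgs, "washout must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReservoirConfig
#'
#' Defaults are standard echo-state ranges: \code{n = 600} (divisible by
#' 1..6 so equal blocks are exact for up to six complexes), leak 0.6,
#' spectral radius 0.9, input scale 0.5, adjacency density 0.05, bias scale
#' 0.1, ridge 1e-6, washout 200.
#'
#' @param n,leak,spectralRadius,inputScale,density,biasScale,ridge,washout,seed
#'   see the class slots.
#' @return A [ReservoirConfig-class].
#' @export
reservoirConfig <- function(n = 600L, leak = 0.6, spectralRadius = 0.9,
                            inputScale = 0.5, density = 0.05, biasScale = 0.1,
                            ridge = 1e-6, washout = 200L, seed = 1L) {
  new("ReservoirConfig", n = as.integer(n), leak = leak,
      spectralRadius = spectralRadius, inputScale = inputScale,
      density = density, biasScale = biasScale, ridge = ridge,
      washout = as.integer(washout), seed = as.integer(seed))
}

#' One node's structured reservoir
#'
#' @slot node the output variable(s): one name for node-level models, all
#'   names for the classic shared reservoir.
#' @slot varNames input variable order (columns of \code{Win}).
#' @slot complexes the complex set the matrices encode.
#' @slot Win \eqn{n' \times N} input matrix, row-block \eqn{i} nonzero only
#'   in the columns of complex \eqn{i}.
#' @slot A \eqn{n' \times n'} block-diagonal sparse adjacency, rescaled to
#'   the configured spectral radius.
#' @slot b bias vector.
#' @slot leak leaky rate.
#' @slot blockSize rows per complex block (\eqn{\lfloor n/D_u \rfloor}).
#'
#' @exportClass NodeReservoir
setClass("NodeReservoir",
         representation(node = "character", varNames = "character",
                        complexes = "list", Win = "matrix", A = "matrix",
                        b = "numeric", leak = "numeric", blockSize = "integer"))

setValidity("NodeReservoir", function(object) {
  msgs <- character(0)
  n <- nrow(object@Win)
  if (ncol(object@Win) != length(object@varNames))
    msgs <- c(msgs, "Win width must match varNames")
  if (nrow(object@A) != n || ncol(object@A) != n)
    msgs <- c(msgs, "A must be square of the reservoir size")
  if (length(object@b) != n) msgs <- c(msgs, "bias length mismatch")
  D <- length(object@complexes)
  if (D < 1 || n != D * object@blockSize)
    msgs <- c(msgs, "reservoir size must be blockSize x number of complexes")
  # mask invariants: Win support confined to each block's complex, A block-diagonal
  for (i in seq_len(D)) {
    rows <- ((i - 1) * object@blockSize + 1):(i * object@blockSize)
    outside <- setdiff(seq_along(object@varNames),
                       match(object@complexes[[i]], object@varNames))
    if (length(outside) && any(object@Win[rows, outside] != 0))
      msgs <- c(msgs, "Win support leaks outside its complex")
    if (any(object@A[rows, -rows] != 0))
      msgs <- c(msgs, "A is not block-diagonal")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "NodeReservoir", function(object) {
  cat(sprintf("NodeReservoir for %s: n = %d (%d block(s) of %d), N = %d\n",
              paste(object@node, collapse = ","), nrow(object@Win),
              length(object@complexes), object@blockSize,
              length(object@varNames)))
})

#' Build a node-level higher-order reservoir
#'
#' Constructs the block-masked input matrix and block-diagonal adjacency
#' encoding a node's complex set: with \eqn{D_u} complexes and configured
#' size \eqn{n}, each complex receives a block of \eqn{\lfloor n/D_u\rfloor}
#' neurons whose input rows are nonzero only in that complex's variable
#' columns (uniform draws in \eqn{\pm}\code{inputScale}) and whose adjacency
#' block is sparse random, the whole adjacency rescaled to the configured
#' spectral radius.  Matrix draws are deterministic given
#' \code{(cfg@seed, node, canonical complexes)}.
#'
#' @param u the target variable.
#' @param complexes list of complexes (character vectors); the node's
#'   \eqn{S_u} or a candidate set.
#' @param names all input variable names, in column order.
#' @param cfg a [ReservoirConfig-class].
#' @return A [NodeReservoir-class].
#' @export
buildNodeReservoir <- function(u, complexes, names, cfg) {
  complexes <- orderComplexes(lapply(complexes, function(cx) sort(unique(cx))))
  D <- length(complexes)
  if (D < 1) stopf("need at least one complex")
  if (cfg@n < D) stopf("reservoir size %d < number of complexes %d", cfg@n, D)
  bad <- setdiff(unlist(complexes), names)
  if (length(bad)) stopf("unknown variables in complexes: %s", paste(bad, collapse = ","))
  nb <- cfg@n %/% D
  n <- nb * D
  N <- length(names)
  # Common random numbers: every complex owns one substream keyed by
  # (seed, node, complex) from which its input block, adjacency block and
  # bias are drawn at the full configured size and truncated to the block
  # size actually needed.  Candidate sets sharing a complex therefore share
  # its features (nested in block size), so error comparisons between
  # candidate sets isolate the complex under test instead of redrawing
  # everything.
  Win <- matrix(0, n, N)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in seq_len(D)) {
    cx <- complexes[[i]]
    rows <- ((i - 1) * nb + 1):(i * nb)
    cols <- match(cx, names)
    withSeed(seedStream(cfg@seed, "block", paste(u, collapse = ","),
                        complexKey(cx)), {
      Wfull <- matrix(runif(cfg@n * length(cols), -cfg@inputScale,
                            cfg@inputScale), cfg@n, length(cols))
      maskFull <- matrix(runif(cfg@n * cfg@n) < cfg@density, cfg@n, cfg@n)
      valsFull <- matrix(runif(cfg@n * cfg@n, -1, 1), cfg@n, cfg@n)
      bFull <- runif(cfg@n, -cfg@biasScale, cfg@biasScale)
    })
    Win[rows, cols] <- Wfull[seq_len(nb), , drop = FALSE]
    blk <- matrix(0, nb, nb)
    sel <- maskFull[seq_len(nb), seq_len(nb), drop = FALSE]
    blk[sel] <- valsFull[seq_len(nb), seq_len(nb), drop = FALSE][sel]
    # each decoupled block is scaled to the target spectral radius, which
    # gives the whole block-diagonal adjacency that radius as well;
    # a zero target removes the recurrence entirely (memoryless features)
    sr <- max(Mod(eigen(blk, only.values = TRUE)$values))
    blk <- if (sr > 0) blk * (cfg@spectralRadius / sr) else blk
    A[rows, rows] <- blk
    b[rows] <- bFull[seq_len(nb)]
  }
  new("NodeReservoir", node = u, varNames = as.character(names),
      complexes = complexes, Win = Win, A = A, b = b, leak = cfg@leak,
      blockSize = as.integer(nb))
}

#' Classic (single shared) reservoir
#'
#' The conventional echo-state construction: fully random dense input matrix
#' over all \eqn{N} variables, one sparse random adjacency, one reservoir
#' shared by an \eqn{N}-output readout.  Structurally this is the degenerate
#' single-complex case of [buildNodeReservoir()].
#'
#' @param names variable names.
#' @param cfg a [ReservoirConfig-class].
#' @return A [NodeReservoir-class] whose \code{node} is all variables.
#' @export
buildClassicRC <- function(names, cfg) {
  res <- buildNodeReservoir("__classic__", list(names), names, cfg)
  res@node <- as.character(names)
  res
}

#' Parallel-RC node reservoir
#'
#' A node-level reservoir fed by the node's pairwise neighbours only: one
#' undivided block whose input columns are restricted to
#' \code{neighbors} (which must include the node itself), with an
#' unconstrained sparse adjacency.
#'
#' @param u the target variable.
#' @param neighbors character vector of pairwise neighbours including
#'   \code{u}.
#' @param names all variable names.
#' @param cfg a [ReservoirConfig-class].
#' @return A [NodeReservoir-class].
#' @export
buildPRC <- function(u, neighbors, names, cfg) {
  if (!u %in% neighbors) stopf("PRC neighbour set of %s must include itself", u)
  buildNodeReservoir(u, list(neighbors), names, cfg)
}

#' Drive a reservoir with an input series
#'
#' Applies the leaky-tanh update
#' \eqn{r(t+\Delta t) = (1-l) r(t) + l \tanh[W_{in} x(t) + A r(t) + b]}
#' over every input row; row \eqn{t} of the result is the state reached
#' after input row \eqn{t} (so it pairs with the one-step-ahead target).
#'
#' @param res a [NodeReservoir-class].
#' @param x input: a [Trajectory-class] or a numeric matrix with columns in
#'   the reservoir's variable order.
#' @param r0 initial hidden state (defaults to zeros).
#' @return Numeric \eqn{T \times n} state matrix.
#' @export
driveReservoir <- function(res, x, r0 = NULL) {
  X <- if (is(x, "Trajectory")) states(x) else as.matrix(x)
  if (ncol(X) != ncol(res@Win))
    stopf("input has %d columns, reservoir expects %d", ncol(X), ncol(res@Win))
  r0 <- r0 %||% numeric(nrow(res@Win))
  esn_drive(res@Win, res@A, res@b, res@leak, X, r0)
}

#' Trained linear readout
#'
#' @slot Wout \eqn{k \times n} output weights (one row per predicted
#'   variable).
#' @slot ridge the regularisation used.
#' @slot node name(s) of the predicted variable(s).
#'
#' @exportClass Readout
setClass("Readout",
         representation(Wout = "matrix", ridge = "numeric", node = "character"))

setMethod("show", "Readout", function(object) {
  cat(sprintf("Readout for %s: %d x %d (ridge = %g)\n",
              paste(object@node, collapse = ","), nrow(object@Wout),
              ncol(object@Wout), object@ridge))
})

#' Fit the ridge readout
#'
#' Solves the Tikhonov-regularised least squares
#' \eqn{\min_W \sum_t \|W r(t+\Delta t) - [x(t+\Delta t) - x(t)]\|^2
#'   + \lambda_W \|W\|_F^2}
#' in closed form via the regularised normal equations.  Targets are
#' one-step residuals, so a zero readout is the persistence forecast.
#'
#' @param statesMat \eqn{T \times n} hidden states from
#'   [driveReservoir()] (row \eqn{t} = \eqn{r} after input \eqn{t}).
#' @param series \eqn{T}-row vector or matrix of the predicted variable(s),
#'   aligned with the inputs that produced \code{statesMat}.
#' @param ridge \eqn{\lambda_W \ge 0}; a singular system at 0 falls back to
#'   the pseudoinverse with a warning.
#' @param washout initial rows excluded from the regression.
#' @param node label(s) for the predicted variable(s).
#' @return A [Readout-class].
#' @export
fitReadout <- function(statesMat, series, ridge = 1e-6, washout = 0L,
                       node = "u") {
  Y <- as.matrix(series)
  Tn <- nrow(statesMat)
  stopifnot(nrow(Y) == Tn, Tn >= washout + 2)
  rows <- (washout + 1):(Tn - 1)
  R <- statesMat[rows, , drop = FALSE]
  targets <- Y[rows + 1, , drop = FALSE] - Y[rows, , drop = FALSE]
  G <- crossprod(R)
  diag(G) <- diag(G) + ridge
  W <- tryCatch(solve(G, crossprod(R, targets)), error = function(e) {
    warning("singular normal equations; using pseudoinverse")
    sv <- svd(R)
    keep <- sv$d > max(sv$d) * 1e-12
    sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], targets)) / sv$d[keep])
  })
  new("Readout", Wout = t(W), ridge = ridge,
      node = as.character(node))
}

#' One-step prediction from the residual readout
#'
#' \eqn{\hat u(t+\Delta t) = u(t) + W_{out} r(t+\Delta t)}.
#'
#' @param uNow current value(s) of the predicted variable(s).
#' @param rNext hidden state after the current input.
#' @param readout a [Readout-class].
#' @return Predicted next value(s).
#' @export
oneStep <- function(uNow, rNext, readout) {
  as.numeric(uNow + readout@Wout %*% as.numeric(rNext))
}

#' Trained forecasting model bundle
#'
#' One trained reservoir-plus-readout per node (or a single shared pair for
#' the classic method), ready for closed-loop forecasting.
#'
#' @slot method \code{"rc"}, \code{"prc"} or \code{"hogrc"}.
#' @slot varNames state variable order.
#' @slot reservoirs list of [NodeReservoir-class].
#' @slot readouts list of [Readout-class], parallel to \code{reservoirs}.
#' @slot config the [ReservoirConfig-class] used.
#' @slot center,scale per-variable standardisation (training mean and
#'   standard deviation) applied around the reservoirs; keeps the tanh
#'   nonlinearity in its responsive range whatever the state magnitudes.
#'
#' @exportClass ForecastModel
setClass("ForecastModel",
         representation(method = "character", varNames = "character",
                        reservoirs = "list", readouts = "list",
                        config = "ReservoirConfig",
                        center = "numeric", scale = "numeric"))

setMethod("show", "ForecastModel", function(object) {
  cat(sprintf("ForecastModel (%s): %d reservoir(s) over %d variables\n",
              object@method, length(object@reservoirs),
              length(object@varNames)))
})

#' Train a forecasting model on a trajectory
#'
#' Builds and trains one of the three model families on the full supplied
#' trajectory: \code{"rc"} (one shared reservoir, multivariate readout),
#' \code{"prc"} (per-node reservoirs over pairwise neighbours) or
#' \code{"hogrc"} (per-node reservoirs over the higher-order complexes of
#' \code{structure}).
#'
#' @param traj training [Trajectory-class].
#' @param method model family.
#' @param structure a [HigherOrderStructure-class]; required for
#'   \code{"prc"} (collapsed to pairwise neighbours) and \code{"hogrc"}.
#' @param cfg a [ReservoirConfig-class].
#' @return A [ForecastModel-class].
#' @export
trainForecaster <- function(traj, method = c("hogrc", "prc", "rc"),
                            structure = NULL, cfg = reservoirConfig()) {
  method <- match.arg(method)
  X <- states(traj)
  nm <- colnames(X)
  if (method != "rc" && is.null(structure))
    stopf("method '%s' needs a structure", method)
  center <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- standardizeStates(X, center, sdv)
  if (method == "rc") {
    res <- buildClassicRC(nm, cfg)
    R <- driveReservoir(res, Xs)
    ro <- fitReadout(R, Xs, cfg@ridge, cfg@washout, node = nm)
    return(new("ForecastModel", method = method, varNames = nm,
               reservoirs = list(res), readouts = list(ro), config = cfg,
               center = center, scale = sdv))
  }
  sets <- if (method == "prc") {
    lapply(pairwiseNeighbors(structure), list)
  } else {
    stats::setNames(lapply(nm, function(u) neighborsOf(structure, u)), nm)
  }
  reservoirs <- list(); readouts <- list()
  for (u in nm) {
    su <- sets[[u]]
    if (length(su) == 0) su <- list(u)
    res <- buildNodeReservoir(u, su, nm, cfg)
    R <- driveReservoir(res, Xs)
    reservoirs[[u]] <- res
    readouts[[u]] <- fitReadout(R, Xs[, u], cfg@ridge, cfg@washout, node = u)
  }
  new("ForecastModel", method = method, varNames = nm,
      reservoirs = reservoirs, readouts = readouts, config = cfg,
      center = center, scale = sdv)
}

# Column-wise standardisation with fixed statistics.
standardizeStates <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, `/`)
}

#' Closed-loop multi-step forecast
#'
#' Warms every reservoir on the supplied true samples (ending at the
#' forecast anchor), then iterates: each node predicts its next value from
#' the shared state, the full predicted state is fed back as the next
#' input, all nodes advancing synchronously.
#'
#' @param model a [ForecastModel-class].
#' @param warm [Trajectory-class] (or matrix) of true samples ending at the
#'   anchor state; its last row is the forecast starting point.
#' @param steps forecast horizon; \code{0} returns an empty matrix.
#' @return A [Trajectory-class] of up to \code{steps} predicted states
#'   (attribute \code{"diverged"} flags early truncation on non-finite
#'   values), or an empty matrix when no step was produced.
#' @export
multiStepForecast <- function(model, warm, steps) {
  W <- if (is(warm, "Trajectory")) states(warm) else as.matrix(warm)
  dt <- if (is(warm, "Trajectory")) timeStep(warm) else 1
  stopifnot(nrow(W) >= 1, steps >= 0)
  nm <- model@varNames
  Ws <- standardizeStates(W, model@center, model@scale)
  groups <- lapply(seq_along(model@reservoirs), function(g) {
    res <- model@reservoirs[[g]]
    # drive up to the sample before the anchor: the closed loop's first
    # update consumes the anchor state itself
    r0 <- if (nrow(Ws) > 1) {
      R <- driveReservoir(res, Ws[-nrow(Ws), , drop = FALSE])
      R[nrow(R), ]
    } else numeric(nrow(res@Win))
    list(Win = res@Win, A = res@A, b = res@b,
         Wout = model@readouts[[g]]@Wout,
         r = r0, outIdx = match(res@node, nm))
  })
  if (steps == 0)
    return(matrix(numeric(0), 0, length(nm), dimnames = list(NULL, nm)))
  # the closed loop runs in standardised space; outputs are de-standardised
  out <- esn_forecast(groups, model@config@leak, Ws[nrow(Ws), ], as.integer(steps))
  if (out$steps == 0) {
    empty <- matrix(numeric(0), 0, length(nm), dimnames = list(NULL, nm))
    attr(empty, "diverged") <- TRUE
    return(empty)
  }
  raw <- sweep(sweep(out$states, 2, model@scale, `*`), 2, model@center, `+`)
  colnames(raw) <- nm
  tr <- trajectory(raw, dt)
  attr(tr, "diverged") <- out$diverged
  tr
}

#' Angle codec for phase dynamics
#'
#' Phase systems are forecast through a wrapped encoding: inputs are the
#' interleaved pairs \eqn{(\sin\theta_i, \cos\theta_i)} and the readout
#' target is the phase velocity \eqn{\Delta\theta = (\theta(t+1) -
#' \theta(t))/\Delta t}; the decoded next phase is
#' \eqn{\hat\theta(t+1) = \theta(t) + \Delta\theta \, \Delta t}.
#'
#' @param theta a [Trajectory-class] or matrix of phases.
#' @return \code{encodeAngles}: a trajectory/matrix with \eqn{2N} columns
#'   \code{sin_<v>, cos_<v>} per variable.
#' @export
encodeAngles <- function(theta) {
  X <- if (is(theta, "Trajectory")) states(theta) else as.matrix(theta)
  nm <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  out <- matrix(NA_real_, nrow(X), 2 * ncol(X))
  cn <- character(2 * ncol(X))
  for (i in seq_len(ncol(X))) {
    out[, 2 * i - 1] <- sin(X[, i]); cn[2 * i - 1] <- paste0("sin_", nm[i])
    out[, 2 * i] <- cos(X[, i]);     cn[2 * i] <- paste0("cos_", nm[i])
  }
  colnames(out) <- cn
  if (is(theta, "Trajectory")) trajectory(out, timeStep(theta), t0 = theta@t0)
  else out
}

#' @rdname encodeAngles
#' @param dThetaPred predicted phase velocity.
#' @param thetaNow current phase(s).
#' @param dt time step.
#' @return \code{decodeDelta}: the next phase(s).
#' @export
decodeDelta <- function(dThetaPred, thetaNow, dt) {
  thetaNow + dThetaPred * dt
}
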