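# Greedy Granger-style inference of higher-order neighbours.
#
# A candidate complex is judged by the held-out one-step prediction error of
# a node reservoir built from the candidate set: deleting a complex that is
# not a causal factor does not worsen the error beyond a small threshold
# eps_e.  The search alternates deletion sweeps with dimensionality
# reduction (replacing a complex by its facets) until the set is stable.

#' Inference configuration
#'
#' @slot epsE acceptance threshold \eqn{\epsilon_e} on the (standardized)
#'   one-step error; \code{NA} (the default) calibrates it per node from
#'   the data, see [inferNeighbors()].
#' @slot epsScale coefficient of the data-calibrated deletion threshold:
#'   \code{epsScale} times the node's mean one-step increment
#'   (standardized).
#' @slot epsSplitScale like \code{epsScale} but for the dimensionality
#'   reduction (split) moves, which must additionally tolerate the
#'   discretization penalty of factoring a joint term; hence a larger
#'   default.
#' @slot errorSplit fraction of the supplied window held out for the
#'   one-step error evaluation (the remainder is the fit portion).
#' @slot maxIterations cap on delete/split rounds.
#' @slot epsReps matrix-draw replicates used when candidate errors are
#'   replicated across seeds (diagnostics; the default thresholds are
#'   analytic and do not consume replicates).
#' @slot reservoir the [ReservoirConfig-class] used for every candidate
#'   evaluation; its seed keys the per-candidate matrix substreams.
#'
#' @exportClass InferenceConfig
setClass("InferenceConfig",
         representation(epsE = "numeric", epsScale = "numeric",
                        epsSplitScale = "numeric", errorSplit = "numeric",
                        maxIterations = "integer", epsReps = "integer",
                        reservoir = "ReservoirConfig"))

setValidity("InferenceConfig", function(object) {
  msgs <- character(0)
  if (!is.na(object@epsE) && object@epsE < 0) msgs <- c(msgs, "epsE must be >= 0")
  if (object@errorSplit <= 0 || object@errorSplit >= 1)
    msgs <- c(msgs, "errorSplit must be in (0, 1)")
  if (object@maxIterations < 1) msgs <- c(msgs, "maxIterations must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct an InferenceConfig
#'
#' The evaluation reservoir deliberately differs from the forecasting
#' defaults: it is memoryless (leak 1, spectral radius 0, i.e. the
#' recurrence is switched off and each block is a bank of static random
#' tanh features of its complex's current values).  Memorylessness is
#' essential to the causal semantics: with any recurrence a block masked
#' to one variable can reconstruct the others from that variable's recent
#' history (a delay embedding -- e.g. a neighbour's value is encoded
#' linearly in the node's last two samples through the governing
#' equation), so masking would not discriminate structures.  Memoryless
#' blocks can only represent functions of their own complex's variables,
#' which is exactly what the deletion test needs.
#'
#' @param epsE,epsScale,epsSplitScale,errorSplit,maxIterations,epsReps see
#'   the class slots.
#' @param reservoir evaluation [ReservoirConfig-class].
#' @return An [InferenceConfig-class].
#' @export
inferenceConfig <- function(epsE = NA_real_, epsScale = 0.003,
                            epsSplitScale = 0.03, errorSplit = 0.2,
                            maxIterations = 20L, epsReps = 5L,
                            reservoir = reservoirConfig(n = 300L, leak = 1.0,
                                                        spectralRadius = 0,
                                                        inputScale = 0.7,
                                                        ridge = 1e-8,
                                                        washout = 50L)) {
  new("InferenceConfig", epsE = as.numeric(epsE),
      epsScale = as.numeric(epsScale),
      epsSplitScale = as.numeric(epsSplitScale),
      errorSplit = as.numeric(errorSplit),
      maxIterations = as.integer(maxIterations),
      epsReps = as.integer(epsReps), reservoir = reservoir)
}

# One candidate evaluation: train on the first (1 - errorSplit) share of the
# window, report mean absolute one-step error on the held-out remainder.
# `rep` > 0 re-keys the matrix substream (adaptive-threshold replicates).
#
# The regression target is the symmetric increment (u(t+1) - u(t-1))/2 and
# the prediction is u^(t+1) = u(t-1) + 2 W r(t): a central-difference
# derivative estimate that cancels the even-order discretization terms of
# the one-step map.  With a forward increment the O(dt^2) terms of the map
# (which mix variables beyond the vector field's structure) would be
# attributed to spurious cross complexes; with the symmetric increment the
# contamination is O(dt^3) and structure comparisons see the vector field.
# The predictor still uses only data up to time t.
.candidateError <- function(u, complexes, X, cfg, rep = 0L) {
  rcfg <- cfg@reservoir
  if (rep > 0L) {
    rcfg@seed <- seedStream(rcfg@seed, "eps-rep", rep)
  }
  Tn <- nrow(X)
  Tfit <- floor((1 - cfg@errorSplit) * Tn)
  if (Tfit < rcfg@washout + 3 || Tfit >= Tn - 1)
    stopf("window too short for washout %d and errorSplit %g",
          rcfg@washout, cfg@errorSplit)
  # standardise by fit-portion statistics (same affine map for every
  # candidate of a node, so error comparisons are unaffected)
  center <- colMeans(X[seq_len(Tfit), , drop = FALSE])
  sdv <- apply(X[seq_len(Tfit), , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  Xs <- standardizeStates(X, center, sdv)
  res <- buildNodeReservoir(u, complexes, colnames(X), rcfg)
  R <- driveReservoir(res, Xs)
  # symmetric targets: row t pairs r(t) with (u(t+1) - u(t-1))/2
  fitRows <- (rcfg@washout + 2):(Tfit - 1)
  targets <- (Xs[fitRows + 1, u] - Xs[fitRows - 1, u]) / 2
  Rf <- R[fitRows, , drop = FALSE]
  G <- crossprod(Rf)
  diag(G) <- diag(G) + rcfg@ridge
  W <- solve(G, crossprod(Rf, targets))
  ev <- Tfit:(Tn - 1)
  pred <- as.vector(R[ev, , drop = FALSE] %*% W)
  # reported on the standardized scale of u (errors are sigma-normalised
  # throughout, matching the sigma-normalised RMSE convention)
  mean(abs(Xs[ev + 1, u] - (Xs[ev - 1, u] + 2 * pred)))
}

#' Held-out one-step error of a candidate complex set
#'
#' Builds a node reservoir from the candidate set (matrix draws keyed by the
#' canonical set, so repeated evaluations are identical), trains its readout
#' on the first \code{1 - errorSplit} share of the window and returns the
#' mean absolute one-step prediction error on the held-out remainder.
#'
#' @param u the target variable.
#' @param complexes list of candidate complexes.
#' @param traj a [Trajectory-class] (typically the training split).
#' @param cfg an [InferenceConfig-class].
#' @return Mean absolute one-step error (scalar).
#' @export
candidateError <- function(u, complexes, traj, cfg = inferenceConfig()) {
  .candidateError(u, orderComplexes(lapply(complexes, sort)), states(traj), cfg)
}

# Standardized mean one-step increment of the noise-free signal component.
# var(first diff) = signal_step^2 + 2 sigma_n^2; the second difference of a
# densely sampled smooth signal is noise-dominated: var(second diff) ~
# 6 sigma_n^2.  Falls back to a floor of 10% of the raw step so a
# noise-dominated series still yields a usable positive scale.
signalStepScale <- function(u) {
  sdu <- sd(u); sdu <- if (sdu > 0) sdu else 1
  d1 <- diff(u)
  sigma2 <- noiseSdEstimate(u)^2
  sig2 <- max(stats::var(d1) - 2 * sigma2, (0.1 * sd(d1))^2)
  sqrt(sig2) * sqrt(2 / pi) / sdu   # E|N(0,s)| = s * sqrt(2/pi)
}

# Threshold scaled to theta x the signal step, shrunk under observation
# noise: with a noise floor F in the mean absolute error, a model
# difference of size d shifts the error by about d^2/(2F) rather than d,
# so a clean-data threshold t maps to roughly t^2/(t + 2F); the expression
# reduces to t when the noise floor vanishes.
noiseCorrectedEps <- function(theta, u) {
  t0 <- theta * signalStepScale(u)
  sdu <- sd(u); sdu <- if (sdu > 0) sdu else 1
  f <- sqrt(2) * noiseSdEstimate(u) * sqrt(2 / pi) / sdu
  t0^2 / (t0 + f)
}

# White-observation-noise standard deviation estimated from high-order
# differences.  Difference variances are modelled as a geometrically
# decaying smooth-signal part plus the white-noise part (whose variance
# grows with the central binomial coefficients 6, 20, 70 for orders
# 2..4): v_k = s^2 rho^(2(k-2)) + c_k sigma^2.  Eliminating s and rho
# gives the quadratic (v3 - 20 s2)(v3 - 20 s2) = (v2 - 6 s2)(v4 - 70 s2)
# in s2 = sigma^2; the root in [0, v2/6] is returned (0 if none).
noiseSdEstimate <- function(u) {
  d2 <- diff(u, differences = 2)
  d3 <- diff(u, differences = 3)
  d4 <- diff(u, differences = 4)
  v2 <- stats::var(d2); v3 <- stats::var(d3); v4 <- stats::var(d4)
  # (v3 - 20 x)^2 = (v2 - 6 x)(v4 - 70 x)
  A <- 400 - 420
  B <- -40 * v3 + 70 * v2 + 6 * v4
  C <- v3^2 - v2 * v4
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(0)
  roots <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  # sampling noise can push the root marginally past the feasibility
  # bounds; tolerate 10% overshoot and clamp
  cap <- min(v2 / 6, v3 / 20)
  roots <- roots[roots >= 0 & roots <= 1.1 * cap]
  if (length(roots) == 0) return(0)
  sqrt(min(min(roots), cap))
}

# Deletion threshold for explicit tests outside the main search loop:
# the configured epsE, or the data-calibrated value (see inferNeighbors).
.deletionEps <- function(u, baseComplexes, X, cfg) {
  if (!is.na(cfg@epsE)) return(cfg@epsE)
  noiseCorrectedEps(cfg@epsScale, X[, u])
}

#' Granger-style non-causality test for one complex
#'
#' A candidate complex \code{ck} is non-causal for node \code{u} if removing
#' it from the candidate set does not worsen the held-out one-step error by
#' more than \eqn{\epsilon_e}.  \code{ck} must not be a subcomplex of
#' another candidate (otherwise its variables remain available and the test
#' is vacuous).
#'
#' @param complexes candidate set containing \code{ck}.
#' @param ck the complex under test.
#' @param u the target variable.
#' @param traj a [Trajectory-class].
#' @param cfg an [InferenceConfig-class].
#' @return \code{TRUE} iff \code{ck} is judged non-causal; the two errors
#'   and the threshold used are attached as attribute \code{"errors"}.
#' @export
isNoncausal <- function(complexes, ck, u, traj, cfg = inferenceConfig()) {
  ck <- sort(unique(ck))
  keys <- vapply(lapply(complexes, sort), complexKey, character(1))
  pos <- match(complexKey(ck), keys)
  if (is.na(pos)) stopf("ck is not a member of the candidate set")
  others <- complexes[-pos]
  if (any(vapply(others, function(o) isSubcomplex(ck, sort(o)), logical(1))))
    stopf("ck is a subcomplex of another candidate")
  X <- states(traj)
  eps <- .deletionEps(u, orderComplexes(complexes), X, cfg)
  eFull <- .candidateError(u, orderComplexes(complexes), X, cfg)
  eMinus <- .candidateError(u, orderComplexes(others), X, cfg)
  out <- eFull + eps >= eMinus
  attr(out, "errors") <- c(full = eFull, minus = eMinus, eps = eps)
  out
}

#' Infer the higher-order neighbours of one node
#'
#' Greedy refinement of a candidate complex set: each round (i) sweeps the
#' candidates in reverse canonical order and deletes every complex whose
#' removal does not worsen the held-out one-step error beyond
#' \eqn{\epsilon_e}, (ii) reorders the set canonically, (iii) tries to
#' replace each remaining complex of dimension \eqn{\ge 1} by all of its
#' facets at once (accepting on the same non-worsening test; facets already
#' covered by a larger retained complex are absorbed), and stops when a
#' round changes nothing.
#'
#' @param u the target variable.
#' @param C0 initial candidate set (list of complexes); defaults to the
#'   single all-variables complex, i.e. no prior structural knowledge.
#' @param traj a [Trajectory-class] (typically the training split).
#' @param cfg an [InferenceConfig-class].
#' @return A list with elements \code{neighbors} (the inferred \eqn{S_u},
#'   canonical), \code{trace} (data.frame of every evaluation: iteration,
#'   action, the complex moved, candidate-set error, base error, accepted),
#'   \code{epsE} (the threshold used) and \code{converged}.
#' @export
inferNeighbors <- function(u, C0 = NULL, traj, cfg = inferenceConfig()) {
  X <- states(traj)
  if (is.null(C0)) C0 <- list(colnames(X))
  C <- canonicalizeComplexes(C0)
  if (length(C) == 0) stopf("empty initial candidate set")

  cache <- new.env(parent = emptyenv())
  err <- function(cxs, rep = 0L) {
    key <- paste(rep, paste(vapply(cxs, complexKey, character(1)),
                            collapse = ";"), sep = "#")
    if (!is.null(cache[[key]])) return(cache[[key]])
    e <- .candidateError(u, cxs, X, cfg, rep = rep)
    cache[[key]] <- e
    e
  }

  if (is.na(cfg@epsE)) {
    # Data-calibrated thresholds: fractions of the node's mean *signal*
    # one-step increment.  Sampled at step dt, the one-step map carries
    # O(dt^2) cross terms absent from the vector field, so factoring a
    # joint term into the true (vector-field) structure costs an
    # O(dt^2)-sized error penalty while dropping a genuine leading-order
    # term costs an O(dt)-sized one; the thresholds sit between those
    # orders, with a larger tolerance for splits (which pay the factoring
    # penalty) than for deletions (the Granger test proper).  Observation
    # noise inflates raw increments, so the signal step is denoised using
    # the second-difference noise estimate (second differences of a
    # densely sampled smooth signal are noise-dominated).
    epsDel <- noiseCorrectedEps(cfg@epsScale, X[, u])
    epsSplit <- noiseCorrectedEps(cfg@epsSplitScale, X[, u])
  } else {
    epsDel <- epsSplit <- cfg@epsE
  }

  eBase <- err(C)
  trace <- list(list(iteration = 0L, action = "init", complex = "",
                     error = eBase, base = eBase, accepted = TRUE))
  rec <- function(iter, action, cx, e, base, acc) {
    trace[[length(trace) + 1L]] <<- list(
      iteration = iter, action = action, complex = complexKey(cx),
      error = e, base = base, accepted = acc)
  }

  converged <- FALSE
  for (iter in seq_len(cfg@maxIterations)) {
    changed <- FALSE
    # Step 2: deletion sweep, best-first (the least important candidate --
    # the one whose removal leaves the lowest error -- is deleted first,
    # then the sweep repeats on the reduced set)
    repeat {
      if (length(C) < 2) break
      trials <- lapply(seq_along(C), function(k) {
        Cminus <- C[-k]
        list(k = k, set = Cminus, e = err(Cminus))
      })
      es <- vapply(trials, `[[`, numeric(1), "e")
      best <- trials[[which.min(es)]]
      acc <- eBase + epsDel >= best$e
      rec(iter, "delete", C[[best$k]], best$e, eBase, acc)
      if (!acc) {
        # record the rejected removals of the remaining candidates
        for (tr in trials[-which.min(es)])
          rec(iter, "delete", C[[tr$k]], tr$e, eBase, FALSE)
        break
      }
      C <- best$set; eBase <- best$e; changed <- TRUE
    }
    # Step 3: canonical reordering (high to low dimension)
    C <- canonicalizeComplexes(C)
    # Step 4: dimensionality reduction, best-first over the splittable
    # complexes (facets absorbed into larger retained complexes by
    # canonicalization)
    repeat {
      splittable <- which(lengths(C) >= 2)
      if (length(splittable) == 0) break
      trials <- lapply(splittable, function(k) {
        Cnew <- canonicalizeComplexes(c(C[-k], splitComplex(C[[k]])))
        list(k = k, set = Cnew, e = err(Cnew))
      })
      es <- vapply(trials, `[[`, numeric(1), "e")
      best <- trials[[which.min(es)]]
      acc <- eBase + epsSplit >= best$e
      rec(iter, "split", C[[best$k]], best$e, eBase, acc)
      if (!acc) {
        for (tr in trials[-which.min(es)])
          rec(iter, "split", C[[tr$k]], tr$e, eBase, FALSE)
        break
      }
      C <- best$set; eBase <- best$e; changed <- TRUE
    }
    if (!changed) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("node %s: iteration cap reached; returning best so far", u))
  trace <- do.call(rbind, lapply(trace, function(r) as.data.frame(r)))
  list(neighbors = C, trace = trace,
       epsE = c(delete = epsDel, split = epsSplit), converged = converged)
}

#' Infer the full higher-order structure
#'
#' Runs [inferNeighbors()] independently for every requested node (nodes are
#' mutually independent, so results do not depend on execution order).
#'
#' @param traj a [Trajectory-class].
#' @param nodes variables to infer (default: all).
#' @param C0builder optional function \code{u -> initial candidate list};
#'   default starts every node from the single all-variables complex.
#' @param cfg an [InferenceConfig-class].
#' @return A [HigherOrderStructure-class]; per-node traces are in attribute
#'   \code{"traces"}, per-node failures (as condition messages) in attribute
#'   \code{"failures"}.
#' @export
inferStructure <- function(traj, nodes = NULL, C0builder = NULL,
                           cfg = inferenceConfig()) {
  nm <- varNames(traj)
  nodes <- nodes %||% nm
  traces <- list(); failures <- list(); neighbors <- list()
  for (u in nodes) {
    res <- tryCatch(
      inferNeighbors(u, if (is.null(C0builder)) NULL else C0builder(u),
                     traj, cfg),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[u]] <- conditionMessage(res)
    } else {
      neighbors[[u]] <- res$neighbors
      traces[[u]] <- res$trace
    }
  }
  out <- higherOrderStructure(nm, neighbors)
  attr(out, "traces") <- traces
  attr(out, "failures") <- failures
  out
}

#' Leave-one-subsystem-out coupling scan
#'
#' Subsystem-level inference: evaluates the held-out one-step error of node
#' \code{u} with all candidate neighbour complexes present, then with each
#' candidate removed in turn.  A candidate is flagged as a true incoming
#' neighbour when its removal worsens the error beyond \eqn{\epsilon_e}.
#'
#' @param u the target variable (e.g. the coupled variable of subsystem
#'   \eqn{i}).
#' @param base list of complexes always kept (the node's own within-subsystem
#'   terms).
#' @param candidates named list: candidate label (e.g. the probed subsystem)
#'   -> complex, or list of complexes, representing that neighbour's
#'   influence.
#' @param traj a [Trajectory-class].
#' @param cfg an [InferenceConfig-class] (numeric \code{epsE}).
#' @return data.frame with one row per candidate: \code{candidate},
#'   \code{errAll}, \code{errMinus}, \code{flagged}; the all-candidates
#'   error is attached as attribute \code{"errAll"}.
#' @export
subsystemCouplingScan <- function(u, base, candidates, traj,
                                  cfg = inferenceConfig()) {
  X <- states(traj)
  candidates <- lapply(candidates, function(x) if (is.character(x)) list(x) else x)
  full <- canonicalizeComplexes(c(base, unlist(candidates, recursive = FALSE)))
  eps <- .deletionEps(u, full, X, cfg)
  eAll <- .candidateError(u, full, X, cfg)
  rows <- lapply(names(candidates), function(j) {
    keep <- canonicalizeComplexes(
      c(base, unlist(candidates[setdiff(names(candidates), j)],
                     recursive = FALSE)))
    eMinus <- .candidateError(u, keep, X, cfg)
    data.frame(candidate = j, errAll = eAll, errMinus = eMinus,
               flagged = eAll + eps < eMinus)
  })
  out <- do.call(rbind, rows)
  attr(out, "errAll") <- eAll
  attr(out, "eps") <- eps
  out
}
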