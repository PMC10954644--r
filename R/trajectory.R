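# Regularly sampled multivariate time series.

#' Sampled trajectory of a dynamical system
#'
#' A \eqn{T \times N} matrix of states sampled at a uniform step \eqn{\Delta t},
#' with variable names as column names.
#'
#' @slot states numeric matrix, one row per time step.
#' @slot dt sampling step (time units), positive.
#' @slot t0 time of the first sample.
#'
#' @exportClass Trajectory
setClass("Trajectory",
         representation(states = "matrix", dt = "numeric", t0 = "numeric"))

setValidity("Trajectory", function(object) {
  msgs <- character(0)
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    msgs <- c(msgs, "dt must be a single positive number")
  if (nrow(object@states) < 1) msgs <- c(msgs, "at least one sample required")
  if (is.null(colnames(object@states))) msgs <- c(msgs, "states need column names")
  if (!all(is.finite(object@states))) msgs <- c(msgs, "non-finite state values")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Trajectory
#'
#' @param states numeric matrix (rows = time steps, columns = variables).
#' @param dt sampling step.
#' @param names optional variable names (defaults to existing column names).
#' @param t0 time of the first sample.
#' @return A [Trajectory-class] object.
#' @export
trajectory <- function(states, dt, names = colnames(states), t0 = 0) {
  states <- as.matrix(states)
  if (!is.null(names)) colnames(states) <- names
  new("Trajectory", states = states, dt = as.numeric(dt), t0 = as.numeric(t0))
}

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d steps x %d variables (dt = %g)\n",
              nrow(object@states), ncol(object@states), object@dt))
  cat("  variables:", paste(colnames(object@states), collapse = ", "), "\n")
})

#' @describeIn trajectory State matrix.
#' @param x a \code{Trajectory}.
#' @export
states <- function(x) x@states

#' @describeIn trajectory Sampling step.
#' @export
timeStep <- function(x) x@dt

#' @describeIn trajectory Number of samples.
#' @export
nSteps <- function(x) nrow(x@states)

#' @describeIn trajectory Variable names.
#' @export
varNames <- function(x) colnames(x@states)

#' @describeIn trajectory Row subset (keeps dt; shifts t0).
#' @param rows integer indices of the rows to keep (must be contiguous).
#' @export
windowTrajectory <- function(x, rows) {
  rows <- as.integer(rows)
  if (length(rows) && any(diff(rows) != 1L))
    stopf("window must be contiguous")
  trajectory(x@states[rows, , drop = FALSE], x@dt,
             t0 = x@t0 + (rows[1] - 1) * x@dt)
}

#' Add observational Gaussian noise to a trajectory
#'
#' Measurement noise only: the dynamics that generated the data are
#' untouched.  In \code{"per-variable-std"} mode the noise applied to column
#' \eqn{i} has standard deviation \eqn{\sigma_n \sigma_i}, with
#' \eqn{\sigma_i} the column's sample standard deviation, so
#' \eqn{\sigma_n} is a relative intensity comparable across variables of
#' different scale (the same normalisation the RMSE metric uses).  In
#' \code{"absolute"} mode the standard deviation is \eqn{\sigma_n} itself.
#'
#' @param traj a [Trajectory-class].
#' @param sigmaN noise intensity, \eqn{\ge 0}; \code{0} returns the input
#'   unchanged.
#' @param mode \code{"per-variable-std"} (default) or \code{"absolute"}.
#' @param seed RNG seed for the noise draw.
#' @return A new \code{Trajectory}.
#' @export
addObservationNoise <- function(traj, sigmaN,
                                mode = c("per-variable-std", "absolute"),
                                seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(sigmaN >= 0)
  if (sigmaN == 0) return(traj)
  X <- states(traj)
  scale <- if (mode == "per-variable-std") apply(X, 2, sd) else rep(1, ncol(X))
  noise <- withSeed(seedStream(seed, "obs-noise"), {
    matrix(rnorm(length(X)), nrow(X), ncol(X))
  })
  noise <- sweep(noise, 2, sigmaN * scale, `*`)
  trajectory(X + noise, timeStep(traj), t0 = traj@t0)
}

#' Trajectory CSV I/O
#'
#' Writes the state matrix as a CSV (header = variable names, one row per
#' step) plus a JSON sidecar \code{<file>.json} holding \code{dt}, \code{t0}
#' and any extra metadata; the reader restores both.
#'
#' @param traj a [Trajectory-class].
#' @param file CSV path.
#' @param meta named list of extra metadata stored in the sidecar.
#' @return \code{readTrajectoryCsv} returns a \code{Trajectory} (metadata in
#'   attribute \code{"meta"}); \code{writeTrajectoryCsv} returns \code{file}
#'   invisibly.
#' @export
writeTrajectoryCsv <- function(traj, file, meta = list()) {
  write.csv(as.data.frame(states(traj)), file, row.names = FALSE)
  side <- c(list(dt = timeStep(traj), t0 = traj@t0), meta)
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname writeTrajectoryCsv
#' @export
readTrajectoryCsv <- function(file) {
  X <- as.matrix(read.csv(file, check.names = FALSE))
  side <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  out <- trajectory(X, dt = side$dt, t0 = side$t0 %||% 0)
  attr(out, "meta") <- side[setdiff(names(side), c("dt", "t0"))]
  out
}
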