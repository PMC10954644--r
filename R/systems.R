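# Benchmark dynamical systems and their simulators.
#
# All systems are integrated with a shared fixed-step RK4 scheme at the step
# size conventionally used for each system.  Coupled systems take a
# CouplingNetwork; the convention throughout is weights[i, j] = w_ij, the
# influence of subsystem j on subsystem i (row = receiver).

#' Weighted coupling network between subsystems
#'
#' @slot weights \eqn{m \times m} matrix, \code{weights[i, j]} = influence of
#'   subsystem \eqn{j} on \eqn{i}; zero means no edge; zero diagonal.
#' @slot triangles numeric matrix with columns \code{i, j, k, w}: weighted
#'   2-simplices (used by the higher-order Kuramoto model); may have 0 rows.
#'
#' @exportClass CouplingNetwork
setClass("CouplingNetwork",
         representation(weights = "matrix", triangles = "matrix"))

setValidity("CouplingNetwork", function(object) {
  W <- object@weights
  msgs <- character(0)
  if (nrow(W) != ncol(W)) msgs <- c(msgs, "weights must be square")
  if (any(diag(W) != 0)) msgs <- c(msgs, "diagonal must be zero (no self-edges)")
  Tr <- object@triangles
  if (ncol(Tr) != 4) msgs <- c(msgs, "triangles needs columns i, j, k, w")
  if (nrow(Tr)) {
    idx <- Tr[, 1:3, drop = FALSE]
    if (any(idx < 1) || any(idx > nrow(W)))
      msgs <- c(msgs, "triangle index out of range")
    if (any(apply(idx, 1, function(r) anyDuplicated(r) > 0)))
      msgs <- c(msgs, "triangle indices must be distinct")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CouplingNetwork
#'
#' @param weights square weight matrix (receiver rows).
#' @param triangles optional matrix/data.frame with columns \code{i, j, k, w}.
#' @return A [CouplingNetwork-class].
#' @export
couplingNetwork <- function(weights, triangles = NULL) {
  weights <- as.matrix(weights)
  if (is.null(triangles))
    triangles <- matrix(numeric(0), 0, 4,
                        dimnames = list(NULL, c("i", "j", "k", "w")))
  triangles <- as.matrix(triangles)
  colnames(triangles) <- c("i", "j", "k", "w")
  new("CouplingNetwork", weights = weights, triangles = triangles)
}

setMethod("show", "CouplingNetwork", function(object) {
  cat(sprintf("CouplingNetwork: %d subsystems, %d directed edges, %d triangles\n",
              nrow(object@weights), sum(object@weights != 0),
              nrow(object@triangles)))
})

#' @describeIn couplingNetwork Number of subsystems.
#' @param x a \code{CouplingNetwork}.
#' @export
nSubsystems <- function(x) nrow(x@weights)

#' @describeIn couplingNetwork Per-subsystem in-degree (count of nonzero
#'   incoming weights).
#' @export
inDegree <- function(x) rowSums(x@weights != 0)

#' Generate a coupling network
#'
#' Topology generators for the experiment drivers: \code{"regular"} is a ring
#' where every node is linked to its \code{degree} nearest neighbours,
#' \code{"er"} draws a uniform random edge set of the requested size,
#' \code{"ba"} grows a preferential-attachment tree, and \code{"explicit"}
#' takes a directed edge list as-is.  Undirected kinds produce a symmetric
#' weight pattern with one shared weight per edge; weights are drawn
#' uniformly from \code{weightRange}.  Deterministic given \code{seed}.
#'
#' @param kind one of \code{"regular"}, \code{"er"}, \code{"ba"},
#'   \code{"explicit"}.
#' @param m number of subsystems (\eqn{\ge 2}).
#' @param degree even per-node degree for \code{"regular"}.
#' @param edges edge count for \code{"er"}.
#' @param edgeList data.frame with columns \code{from, to} (and optionally
#'   \code{w}) for \code{"explicit"}; \code{from -> to} means the source
#'   influences the target (\code{weights[to, from]}).
#' @param weightRange range for the uniform weight draw.
#' @param seed RNG seed.
#' @return A [CouplingNetwork-class].
#' @export
generateNetwork <- function(kind = c("regular", "er", "ba", "explicit"),
                            m = NULL, degree = 2, edges = NULL, edgeList = NULL,
                            weightRange = c(0.5, 1.5), seed = 1L) {
  kind <- match.arg(kind)
  if (kind != "explicit") {
    if (is.null(m) || m < 2) stopf("need m >= 2 subsystems")
  }
  W <- switch(kind,
    regular = {
      if (degree %% 2 != 0 || degree >= m)
        stopf("regular networks need an even degree < m")
      A <- matrix(0, m, m)
      for (s in seq_len(degree / 2))
        for (i in seq_len(m)) {
          A[i, (i - 1 + s) %% m + 1] <- 1
          A[i, (i - 1 - s) %% m + 1] <- 1
        }
      A
    },
    er = {
      if (is.null(edges)) stopf("er networks need an edge count")
      g <- withSeed(seedStream(seed, "net", kind, m),
                    igraph::sample_gnm(m, edges, directed = FALSE))
      as.matrix(igraph::as_adjacency_matrix(g))
    },
    ba = {
      g <- withSeed(seedStream(seed, "net", kind, m),
                    igraph::sample_pa(m, power = 1, m = 1, directed = FALSE))
      as.matrix(igraph::as_adjacency_matrix(g))
    },
    explicit = {
      if (is.null(edgeList)) stopf("explicit networks need an edgeList")
      m <- max(edgeList$from, edgeList$to, m %||% 0)
      A <- matrix(0, m, m)
      for (r in seq_len(nrow(edgeList)))
        A[edgeList$to[r], edgeList$from[r]] <-
          if ("w" %in% names(edgeList)) edgeList$w[r] else 1
      A
    })
  if (kind != "explicit" || !("w" %in% names(edgeList %||% data.frame()))) {
    # draw one weight per undirected edge (symmetric pattern kinds) or per
    # directed edge (explicit without weights)
    W <- withSeed(seedStream(seed, "weights", kind, m), {
      if (kind == "explicit") {
        W[W != 0] <- runif(sum(W != 0), weightRange[1], weightRange[2])
        W
      } else {
        up <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
        w <- runif(nrow(up), weightRange[1], weightRange[2])
        out <- matrix(0, nrow(W), ncol(W))
        out[up] <- w
        out + t(out)
      }
    })
  }
  diag(W) <- 0
  couplingNetwork(W)
}

#' Enumerate the triangles (3-cliques) of a pairwise network
#'
#' Builds the 2-simplex list for higher-order Kuramoto dynamics from a
#' pairwise graph, one row per distinct triangle.
#'
#' @param net a [CouplingNetwork-class].
#' @param weight weight assigned to every triangle.
#' @return The network with its \code{triangles} slot filled.
#' @export
withTriangles <- function(net, weight = 1) {
  g <- igraph::graph_from_adjacency_matrix(net@weights != 0, mode = "max")
  tri <- matrix(as.integer(igraph::triangles(g)), ncol = 3, byrow = TRUE)
  couplingNetwork(net@weights,
                  cbind(tri, rep(weight, nrow(tri))))
}

#' Edge-list I/O for coupling networks
#'
#' Plain text, one directed edge per line, \code{i j w_ij}, 0-based indices,
#' \code{i} the receiver.  Triangles (if any) go to \code{<file>.triangles}
#' as \code{i j k w} lines.
#'
#' @param net a [CouplingNetwork-class].
#' @param file path.
#' @param m number of subsystems for the reader (defaults to the largest
#'   index seen).
#' @return \code{readEdgeList} returns a \code{CouplingNetwork}.
#' @export
writeEdgeList <- function(net, file) {
  idx <- which(net@weights != 0, arr.ind = TRUE)
  lines <- sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                   net@weights[idx])
  writeLines(lines, file)
  if (nrow(net@triangles)) {
    tl <- sprintf("%d %d %d %.17g", net@triangles[, 1] - 1L,
                  net@triangles[, 2] - 1L, net@triangles[, 3] - 1L,
                  net@triangles[, 4])
    writeLines(tl, paste0(file, ".triangles"))
  }
  invisible(file)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(file, m = NULL) {
  tab <- read.table(file, col.names = c("i", "j", "w"))
  m <- m %||% (max(tab$i, tab$j) + 1L)
  W <- matrix(0, m, m)
  W[cbind(tab$i + 1L, tab$j + 1L)] <- tab$w
  tri <- NULL
  tfile <- paste0(file, ".triangles")
  if (file.exists(tfile)) {
    tt <- read.table(tfile, col.names = c("i", "j", "k", "w"))
    tri <- cbind(tt$i + 1L, tt$j + 1L, tt$k + 1L, tt$w)
  }
  couplingNetwork(W, tri)
}

## ---------------------------------------------------------------------------
## System definitions

#' Parameters of a benchmark system
#'
#' Bundles the system name, subsystem count, sampling step and scalar
#' parameters.  \code{systemParams()} fills in the conventional parameter
#' values for each system; any entry can be overridden through \code{params}.
#' Per-subsystem scales \code{h} (coupled Lorenz63, coupled Roessler) and
#' Kuramoto natural frequencies \code{omega} are drawn from seeded uniform
#' distributions when not supplied, since only their ranges are conventional.
#'
#' @slot name system identifier.
#' @slot m number of subsystems.
#' @slot dt sampling/integration step.
#' @slot params named list of scalar (or per-subsystem vector) parameters.
#'
#' @exportClass SystemParams
setClass("SystemParams",
         representation(name = "character", m = "integer", dt = "numeric",
                        params = "list"))

setValidity("SystemParams", function(object) {
  msgs <- character(0)
  if (!object@name %in% names(.systemDefs)) msgs <- c(msgs, "unknown system")
  if (object@m < 1) msgs <- c(msgs, "m must be >= 1")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  def <- .systemDefs[[object@name]]
  if (!is.null(def)) {
    missing <- setdiff(def$required, names(object@params))
    if (length(missing))
      msgs <- c(msgs, paste("missing parameters:", paste(missing, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

.systemDefs <- list(
  lorenz63 = list(
    dt = 0.02, vars = c("x", "y", "z"),
    required = c("sigma", "rho", "beta"),
    defaults = list(sigma = 10, rho = 28, beta = 8 / 3),
    box = c(-5, 5)),
  cl63 = list(
    dt = 0.02, vars = c("x", "y", "z"),
    required = c("sigma", "rho", "beta", "gamma", "coupling"),
    defaults = list(sigma = 10, rho = 28, beta = 8 / 3, gamma = 0.5,
                    coupling = "linear"),
    box = c(-5, 5), perSub = "h"),
  fhn = list(
    dt = 0.25, vars = c("v", "w"),
    required = c("a", "b", "c", "gamma"),
    defaults = list(a = 0.28, b = 0.5, c = -0.04, gamma = 0.5),
    box = c(-1, 1)),
  cros = list(
    dt = 0.1, vars = c("x", "y", "z"),
    required = c("a", "b", "c", "gamma"),
    defaults = list(a = 0.2, b = 0.2, c = -6, gamma = 1),
    box = c(-5, 5), perSub = "h"),
  cshhs = list(
    dt = 0.04, vars = c("v", "w", "u"),
    required = c("a", "b", "c", "u", "s", "r", "x0", "Iext", "Vsyn",
                 "lambda", "Omega", "gamma"),
    defaults = list(a = 1, b = 3, c = 1, u = 5, s = 4, r = 0.005, x0 = -1.6,
                    Iext = 3.24, Vsyn = 2, lambda = 10, Omega = 1, gamma = 0.1),
    box = c(-1, 1)),
  kuramoto_ho = list(
    dt = 0.08, vars = "theta",
    required = c("gamma1", "gamma2"),
    defaults = list(gamma1 = 0.4, gamma2 = 0.4),
    box = c(0, 2 * pi), perSub = "omega")
)

#' @rdname SystemParams-class
#' @param name one of \code{"lorenz63"}, \code{"cl63"}, \code{"fhn"},
#'   \code{"cros"}, \code{"cshhs"}, \code{"kuramoto_ho"}.
#' @param m subsystem count (Lorenz63 is a single subsystem).
#' @param dt sampling step; defaults to the system's conventional value.
#' @param params named list overriding / adding parameters.
#' @param seed seed for the per-subsystem draws (\code{h}, \code{omega}).
#' @return A \code{SystemParams} object.
#' @export
systemParams <- function(name, m = 1L, dt = NULL, params = list(), seed = 1L) {
  def <- .systemDefs[[name]]
  if (is.null(def)) stopf("unknown system '%s'", name)
  p <- modifyList(def$defaults, params)
  if (!is.null(def$perSub) && is.null(p[[def$perSub]])) {
    p[[def$perSub]] <- withSeed(seedStream(seed, "persub", name, m),
      if (def$perSub == "omega") runif(m, -1, 1) else runif(m, 0.9, 1.1))
  }
  new("SystemParams", name = name, m = as.integer(m),
      dt = as.numeric(dt %||% def$dt), params = p)
}

setMethod("show", "SystemParams", function(object) {
  cat(sprintf("SystemParams: %s, m = %d, dt = %g\n",
              object@name, object@m, object@dt))
})

#' Variable names of a benchmark system
#'
#' Component letters with the subsystem index appended (plain letters for a
#' single subsystem), e.g. \code{c("x1","y1","z1","x2",...)} for the coupled
#' Lorenz63 system.
#'
#' @param sys a [SystemParams-class].
#' @return Character vector of variable names, grouped by subsystem.
#' @export
systemVarNames <- function(sys) {
  vars <- .systemDefs[[sys@name]]$vars
  if (sys@m == 1 && sys@name == "lorenz63") return(vars)
  as.vector(vapply(seq_len(sys@m), function(i) paste0(vars, i),
                   character(length(vars))))
}

#' Lorenz63 vector field
#'
#' \eqn{\dot x = \sigma(y - x)}, \eqn{\dot y = \rho x - y - xz},
#' \eqn{\dot z = -\beta z + xy}.
#'
#' @param state numeric 3-vector \code{(x, y, z)}.
#' @param params list with \code{sigma}, \code{rho}, \code{beta}.
#' @return The 3-vector derivative.
#' @examples
#' lorenz63Field(c(1, 1, 1), list(sigma = 10, rho = 28, beta = 8/3))
#' @export
lorenz63Field <- function(state, params) {
  x <- state[1]; y <- state[2]; z <- state[3]
  c(params$sigma * (y - x),
    params$rho * x - y - x * z,
    -params$beta * z + x * y)
}

#' Coupled Lorenz63 vector field
#'
#' \eqn{m} Lorenz63 subsystems coupled through the \eqn{y} variables:
#' \eqn{\dot x_i = -\sigma[x_i - y_i + \gamma \sum_j w_{ij} g(y_i, y_j)]},
#' \eqn{\dot y_i = \rho(1 + h_i) x_i - y_i - x_i z_i},
#' \eqn{\dot z_i = x_i y_i - \beta z_i}, with coupling function
#' \eqn{g} one of \eqn{y_j - y_i}, \eqn{\sin(y_j - y_i)}, \eqn{|y_j - y_i|}.
#'
#' @param state numeric \code{3m}-vector grouped per subsystem
#'   \code{(x1, y1, z1, x2, ...)}.
#' @param net a [CouplingNetwork-class] with \eqn{m} subsystems.
#' @param params list with \code{sigma}, \code{rho}, \code{beta},
#'   \code{gamma}, \code{coupling} and per-subsystem scales \code{h}.
#' @return The \code{3m}-vector derivative.
#' @export
cl63Field <- function(state, net, params) {
  m <- nSubsystems(net)
  if (length(state) != 3 * m) stopf("state length %d != 3m", length(state))
  idx <- matrix(seq_along(state), nrow = 3)
  x <- state[idx[1, ]]; y <- state[idx[2, ]]; z <- state[idx[3, ]]
  W <- net@weights
  cpl <- switch(params$coupling,
    linear = as.vector(W %*% y) - y * rowSums(W),
    sine   = rowSums(W * sin(outer(-y, y, `+`))),
    abs    = rowSums(W * abs(outer(-y, y, `+`))),
    stopf("unknown coupling '%s'", params$coupling))
  dx <- -params$sigma * (x - y + params$gamma * cpl)
  dy <- params$rho * (1 + params$h) * x - y - x * z
  dz <- x * y - params$beta * z
  out <- numeric(length(state))
  out[idx[1, ]] <- dx; out[idx[2, ]] <- dy; out[idx[3, ]] <- dz
  out
}

#' Network dynamical system vector fields
#'
#' Diffusively / synaptically coupled subsystems
#' \eqn{\dot x_i = F(x_i) + \gamma \sum_j w_{ij} G(x_i, x_j)} for three
#' self-dynamics: FitzHugh-Nagumo (\code{"fhn"}, 2 variables per subsystem,
#' \eqn{G = (x_i^1 - x_j^1)/k_i^{in}}), Roessler (\code{"cros"}, 3 variables,
#' \eqn{G = x_j^1 - x_i^1}) and simplified Hodgkin-Huxley (\code{"cshhs"},
#' 3 variables, synaptic \eqn{G = (V_{syn} - x_i^1)\,\mu(x_j^1)} with
#' sigmoid \eqn{\mu(x) = 1/(1 + e^{-\lambda(x - \Omega)})}).
#'
#' @param state stacked subsystem states, grouped per subsystem.
#' @param kind \code{"fhn"}, \code{"cros"} or \code{"cshhs"}.
#' @param net a [CouplingNetwork-class].
#' @param params system parameters (see [systemParams()]).
#' @return The derivative vector.
#' @export
ndsField <- function(state, kind = c("fhn", "cros", "cshhs"), net, params) {
  kind <- match.arg(kind)
  m <- nSubsystems(net)
  W <- net@weights
  g <- params$gamma
  if (kind == "fhn") {
    if (length(state) != 2 * m) stopf("state length %d != 2m", length(state))
    idx <- matrix(seq_along(state), nrow = 2)
    v <- state[idx[1, ]]; w <- state[idx[2, ]]
    kin <- pmax(inDegree(net), 1)  # zero in-degree has a zero coupling sum
    cpl <- (v * rowSums(W) - as.vector(W %*% v)) / kin
    dv <- v - v^3 - w + g * cpl
    dw <- params$a + params$b * v + params$c * w
    out <- numeric(length(state))
    out[idx[1, ]] <- dv; out[idx[2, ]] <- dw
    return(out)
  }
  if (length(state) != 3 * m) stopf("state length %d != 3m", length(state))
  idx <- matrix(seq_along(state), nrow = 3)
  x1 <- state[idx[1, ]]; x2 <- state[idx[2, ]]; x3 <- state[idx[3, ]]
  out <- numeric(length(state))
  if (kind == "cros") {
    cpl <- as.vector(W %*% x1) - x1 * rowSums(W)
    out[idx[1, ]] <- -params$h * x2 - x3 + g * cpl
    out[idx[2, ]] <- params$h * x1 + params$a * x2
    out[idx[3, ]] <- params$b + x3 * (x1 + params$c)
  } else {
    mu <- 1 / (1 + exp(-params$lambda * (x1 - params$Omega)))
    cpl <- (params$Vsyn - x1) * as.vector(W %*% mu)
    out[idx[1, ]] <- x2 - params$a * x1^3 + params$b * x1^2 - x3 +
      params$Iext + g * cpl
    out[idx[2, ]] <- params$c - params$u * x1^2 - x2
    out[idx[3, ]] <- params$r * (params$s * (x1 - params$x0) - x3)
  }
  out
}

#' Higher-order Kuramoto vector field
#'
#' \eqn{\dot\theta_i = \omega_i
#'   + \gamma_1 \sum_j A_{ij} \sin(\theta_j - \theta_i)
#'   + \gamma_2 \sum_{j,k} B_{ijk} \sin(\theta_j + \theta_k - 2\theta_i)},
#' where \eqn{A} is the pairwise weight matrix and the tensor \eqn{B} is
#' populated symmetrically in \eqn{(j, k)} from the network's triangle list.
#'
#' @param theta phase vector.
#' @param net a [CouplingNetwork-class]; its \code{triangles} slot supplies
#'   \eqn{B}.
#' @param params list with \code{gamma1}, \code{gamma2} and natural
#'   frequencies \code{omega}.
#' @return The phase-velocity vector.
#' @export
kuramotoHoField <- function(theta, net, params) {
  A <- net@weights
  dth <- params$omega +
    params$gamma1 * rowSums(A * sin(outer(-theta, theta, `+`)))
  tri <- net@triangles
  if (nrow(tri)) {
    for (r in seq_len(nrow(tri))) {
      i <- tri[r, 1]; j <- tri[r, 2]; k <- tri[r, 3]; w <- tri[r, 4]
      # B symmetric in (j,k): each unordered pair contributes twice
      dth[i] <- dth[i] + params$gamma2 * 2 * w * sin(theta[j] + theta[k] - 2 * theta[i])
      dth[j] <- dth[j] + params$gamma2 * 2 * w * sin(theta[i] + theta[k] - 2 * theta[j])
      dth[k] <- dth[k] + params$gamma2 * 2 * w * sin(theta[i] + theta[j] - 2 * theta[k])
    }
  }
  dth
}

#' Vector field of a configured system
#'
#' @param sys a [SystemParams-class].
#' @param net a [CouplingNetwork-class] (required for coupled systems).
#' @return A function \code{f(state) -> derivative}.
#' @export
systemField <- function(sys, net = NULL) {
  needsNet <- sys@name != "lorenz63"
  if (needsNet && is.null(net)) stopf("system '%s' needs a coupling network", sys@name)
  p <- sys@params
  switch(sys@name,
    lorenz63 = function(s) lorenz63Field(s, p),
    cl63 = function(s) cl63Field(s, net, p),
    fhn = function(s) ndsField(s, "fhn", net, p),
    cros = function(s) ndsField(s, "cros", net, p),
    cshhs = function(s) ndsField(s, "cshhs", net, p),
    kuramoto_ho = function(s) kuramotoHoField(s, net, p))
}

#' Fixed-step fourth-order Runge-Kutta integration
#'
#' Integrates \code{field} from \code{x0}, discards \code{transient} steps,
#' and records \code{steps} samples; the first recorded sample is the state
#' reached after the transient.
#'
#' @param field function mapping a state vector to its derivative.
#' @param x0 initial state.
#' @param dt step size (> 0).
#' @param steps number of recorded samples (\eqn{\ge 1}).
#' @param transient number of discarded initial steps.
#' @param names variable names for the trajectory columns.
#' @param t0 time of the first recorded sample.
#' @return A [Trajectory-class] of \code{steps} rows.
#' @examples
#' # one RK4 step of dx/dt = -x from 1 matches exp(-0.1) to O(dt^5)
#' tr <- rk4Integrate(function(x) -x, 1, dt = 0.1, steps = 2, names = "x")
#' states(tr)[2, ]
#' @export
rk4Integrate <- function(field, x0, dt, steps, transient = 0,
                         names = NULL, t0 = 0) {
  stopifnot(dt > 0, steps >= 1, transient >= 0)
  x <- as.numeric(x0)
  if (!all(is.finite(field(x)))) stopf("field is not finite at x0")
  out <- matrix(NA_real_, steps, length(x))
  colnames(out) <- names %||% paste0("v", seq_along(x))
  stepOnce <- function(x) {
    k1 <- field(x)
    k2 <- field(x + dt / 2 * k1)
    k3 <- field(x + dt / 2 * k2)
    k4 <- field(x + dt * k3)
    x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  for (s in seq_len(transient)) {
    x <- stepOnce(x)
    if (!all(is.finite(x))) stopf("integration diverged at step %d", s)
  }
  out[1L, ] <- x   # sample 1 is the state after the transient (x0 if none)
  for (r in seq_len(steps - 1L)) {
    x <- stepOnce(x)
    if (!all(is.finite(x)))
      stopf("integration diverged at step %d", transient + r)
    out[r + 1L, ] <- x
  }
  trajectory(out, dt, t0 = t0)
}

#' Simulate a benchmark system
#'
#' Draws an initial condition uniformly from a system-specific box (seeded),
#' integrates with RK4 at the system's step size, and discards a transient.
#'
#' @param sys a [SystemParams-class].
#' @param net a [CouplingNetwork-class] for coupled systems.
#' @param steps recorded samples (default 5000).
#' @param transient discarded steps (default 1000).
#' @param seed seed for the initial-condition draw.
#' @param x0 optional explicit initial condition (bypasses the draw).
#' @return A [Trajectory-class] with the system's variable names.
#' @export
simulateSystem <- function(sys, net = NULL, steps = 5000, transient = 1000,
                           seed = 1L, x0 = NULL) {
  nm <- systemVarNames(sys)
  if (is.null(x0)) {
    box <- .systemDefs[[sys@name]]$box
    x0 <- withSeed(seedStream(seed, "x0", sys@name),
                   runif(length(nm), box[1], box[2]))
  }
  rk4Integrate(systemField(sys, net), x0, sys@dt, steps, transient, names = nm)
}

## ---------------------------------------------------------------------------
## Ground-truth higher-order structures

# Canonical complex sets implied by each system's governing equations: one
# complex per inseparable term, with subsumed singletons absorbed.
#' Ground-truth higher-order structure of a benchmark system
#'
#' Hand-derived from the governing equations: each inseparable term of a
#' node's equation contributes the complex of its variables, and complexes
#' contained in a larger one are absorbed (e.g. the \eqn{\rho x} and
#' \eqn{-xz} terms of the Lorenz63 \eqn{\dot y} equation merge into the
#' single complex \eqn{\{x, z\}}).
#'
#' @param sys a [SystemParams-class].
#' @param net a [CouplingNetwork-class] for coupled systems.
#' @return A [HigherOrderStructure-class].
#' @examples
#' s <- trueStructure(systemParams("lorenz63"))
#' neighborsOf(s, "z")   # {z} and {x, y}
#' @export
trueStructure <- function(sys, net = NULL) {
  nm <- systemVarNames(sys)
  needsNet <- sys@name != "lorenz63"
  if (needsNet && is.null(net)) stopf("system '%s' needs a coupling network", sys@name)
  nbrOf <- function(i) which(net@weights[i, ] != 0)
  # paste0 maps zero-length input to "", not character(0)
  subVar <- function(prefix, idx) {
    if (length(idx) == 0) character(0) else paste0(prefix, idx)
  }
  neighbors <- switch(sys@name,
    lorenz63 = list(
      x = list("x", "y"),
      y = list("y", c("x", "z")),
      z = list("z", c("x", "y"))),
    cl63 = {
      out <- list()
      for (i in seq_len(sys@m)) {
        xi <- paste0("x", i); yi <- paste0("y", i); zi <- paste0("z", i)
        yj <- subVar("y", nbrOf(i))
        out[[xi]] <- if (sys@params$coupling == "linear")
          c(list(xi, yi), as.list(yj))
        else
          canonicalizeComplexes(c(list(xi, yi),
                                  lapply(yj, function(v) sort(c(yi, v)))))
        out[[yi]] <- list(yi, sort(c(xi, zi)))
        out[[zi]] <- list(zi, sort(c(xi, yi)))
      }
      out
    },
    fhn = {
      out <- list()
      for (i in seq_len(sys@m)) {
        vi <- paste0("v", i); wi <- paste0("w", i)
        out[[vi]] <- c(list(vi, wi), as.list(subVar("v", nbrOf(i))))
        out[[wi]] <- list(vi, wi)
      }
      out
    },
    cros = {
      out <- list()
      for (i in seq_len(sys@m)) {
        xi <- paste0("x", i); yi <- paste0("y", i); zi <- paste0("z", i)
        out[[xi]] <- c(list(xi, yi, zi), as.list(subVar("x", nbrOf(i))))
        out[[yi]] <- list(xi, yi)
        out[[zi]] <- list(sort(c(xi, zi)))
      }
      out
    },
    cshhs = {
      out <- list()
      for (i in seq_len(sys@m)) {
        vi <- paste0("v", i); wi <- paste0("w", i); ui <- paste0("u", i)
        pairs <- lapply(subVar("v", nbrOf(i)), function(vj) sort(c(vi, vj)))
        out[[vi]] <- canonicalizeComplexes(c(list(vi, wi, ui), pairs))
        out[[wi]] <- list(vi, wi)
        out[[ui]] <- list(vi, ui)
      }
      out
    },
    kuramoto_ho = {
      out <- list()
      tri <- net@triangles
      for (i in seq_len(sys@m)) {
        ti <- paste0("theta", i)
        pairs <- lapply(subVar("theta", nbrOf(i)), function(tj) sort(c(ti, tj)))
        trips <- list()
        if (nrow(tri)) {
          hit <- which(tri[, 1] == i | tri[, 2] == i | tri[, 3] == i)
          trips <- lapply(hit, function(r) sort(paste0("theta", tri[r, 1:3])))
        }
        out[[ti]] <- canonicalizeComplexes(c(list(ti), pairs, trips))
      }
      out
    },
    stopf("unknown system '%s'", sys@name))
  higherOrderStructure(nm, neighbors)
}

#' Default 5-subsystem coupling network
#'
#' A fixed directed 5-node topology (7 edges) with seeded uniform weights in
#' \eqn{[0.5, 1.5]}, used as the stock network for the coupled-system
#' examples and experiments.
#'
#' @param seed seed for the weight draw.
#' @return A [CouplingNetwork-class] with 5 subsystems.
#' @export
defaultNetwork5 <- function(seed = 1L) {
  edges <- data.frame(
    from = c(5, 1, 4, 1, 2, 3, 4),
    to   = c(1, 2, 2, 3, 3, 4, 5))
  withSeed(seedStream(seed, "net5"), {
    edges$w <- runif(nrow(edges), 0.5, 1.5)
  })
  generateNetwork("explicit", m = 5, edgeList = edges)
}
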