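lorenzP <- list(sigma = 10, rho = 28, beta = 8 / 3)

test_that("Lorenz63 field matches the governing equations", {
  expect_equal(lorenz63Field(c(0, 0, 0), lorenzP), c(0, 0, 0))
  expect_equal(lorenz63Field(c(1, 1, 1), lorenzP), c(0, 26, 1 - 8 / 3))
  expect_equal(lorenz63Field(c(1, 2, 3), lorenzP)[1], 10)
})

test_that("RK4 matches the exponential to fifth order and is globally fourth order", {
  tr <- rk4Integrate(function(x) -x, 1, dt = 0.1, steps = 2, names = "x")
  expect_equal(unname(states(tr)[2, 1]), exp(-0.1), tolerance = 1e-7)
  # halving the step cuts the global error ~16x on a fixed horizon
  err <- function(dt) {
    tr <- rk4Integrate(function(x) -x, 1, dt = dt, steps = round(1 / dt) + 1,
                       names = "x")
    max(abs(states(tr)[, 1] - exp(-(seq_len(nSteps(tr)) - 1) * dt)))
  }
  ratio <- err(0.1) / err(0.05)
  expect_gt(ratio, 12)
  expect_lt(ratio, 20)
})

test_that("the origin is a fixed point of Lorenz63 under integration", {
  tr <- rk4Integrate(function(s) lorenz63Field(s, lorenzP), c(0, 0, 0),
                     dt = 0.02, steps = 50, names = c("x", "y", "z"))
  expect_true(all(states(tr) == 0))
})

test_that("divergence is reported with the step index", {
  expect_error(rk4Integrate(function(x) x^2, 10, dt = 1, steps = 50),
               "diverged at step")
})

test_that("decoupled CL63 reduces to per-subsystem Lorenz with scaled rho", {
  net <- couplingNetwork(matrix(0, 2, 2))
  p <- c(lorenzP, list(gamma = 0.5, coupling = "linear", h = c(0.1, -0.1)))
  s <- c(1, 2, 3, -1, 0.5, 2)
  f <- cl63Field(s, net, p)
  for (i in 1:2) {
    sub <- s[(3 * i - 2):(3 * i)]
    pi <- lorenzP; pi$rho <- lorenzP$rho * (1 + p$h[i])
    expect_equal(f[(3 * i - 2):(3 * i)], lorenz63Field(sub, pi))
  }
})

test_that("difference couplings vanish on synchronized states", {
  W <- matrix(c(0, 1, 2, 0), 2, 2)
  net <- couplingNetwork(W)
  p <- c(lorenzP, list(gamma = 0.7, coupling = "linear", h = c(0, 0)))
  s <- rep(c(1.2, -0.4, 2.2), 2)     # identical subsystems
  pSine <- p; pSine$coupling <- "sine"
  expect_equal(cl63Field(s, net, p), cl63Field(s, net, pSine))
  # FHN: gamma = 0 second component is a + b v + c w
  pf <- list(a = 0.28, b = 0.5, c = -0.04, gamma = 0)
  sf <- c(0.3, -0.1, 0.7, 0.2)
  f <- ndsField(sf, "fhn", net, pf)
  expect_equal(f[2], 0.28 + 0.5 * 0.3 - 0.04 * (-0.1))
  expect_equal(f[4], 0.28 + 0.5 * 0.7 - 0.04 * 0.2)
})

test_that("Roessler self-dynamics at the origin", {
  net <- couplingNetwork(matrix(0, 1, 1))
  p <- list(a = 0.2, b = 0.2, c = -6, gamma = 1, h = 1)
  expect_equal(ndsField(c(0, 0, 0), "cros", net, p), c(0, 0, 0.2))
})

test_that("the synaptic sigmoid is 1/2 at its midpoint for any steepness", {
  W <- matrix(c(0, 0, 1, 0), 2, 2)   # subsystem 2 drives subsystem 1
  for (lambda in c(1, 10, 50)) {
    p <- list(a = 1, b = 3, c = 1, u = 5, s = 4, r = 0.005, x0 = -1.6,
              Iext = 3.24, Vsyn = 2, lambda = lambda, Omega = 1, gamma = 0.1)
    s <- c(0, 0, 0, p$Omega, 0, 0)   # presynaptic v at the midpoint
    f <- ndsField(s, "cshhs", couplingNetwork(W), p)
    fNoC <- ndsField(s, "cshhs", couplingNetwork(matrix(0, 2, 2)), p)
    expect_equal(f[1] - fNoC[1], p$gamma * (p$Vsyn - 0) * 0.5)
  }
})

test_that("Kuramoto field reduces to natural frequencies and is shift invariant", {
  net <- withTriangles(generateNetwork("regular", m = 6, degree = 2, seed = 3))
  omega <- seq(-1, 1, length.out = 6)
  p <- list(gamma1 = 0.4, gamma2 = 0.4, omega = omega)
  expect_equal(kuramotoHoField(rep(1.3, 6), net, p), omega)
  p0 <- list(gamma1 = 0, gamma2 = 0, omega = omega)
  theta <- runif(6, 0, 2 * pi)
  expect_equal(kuramotoHoField(theta, net, p0), omega)
  expect_equal(kuramotoHoField(theta + 2.345, net, p),
               kuramotoHoField(theta, net, p))
})

test_that("network generators are seed-deterministic with the requested shape", {
  ring <- generateNetwork("regular", m = 5, degree = 2, seed = 1)
  expect_true(all(inDegree(ring) == 2))
  expect_equal(sum(ring@weights != 0), 10)   # 5 undirected edges
  er <- generateNetwork("er", m = 30, edges = 33, seed = 7)
  expect_equal(mean(inDegree(er)), 2.2)
  expect_identical(generateNetwork("er", m = 30, edges = 33, seed = 7)@weights,
                   er@weights)
  ba <- generateNetwork("ba", m = 30, seed = 7)
  expect_equal(sum(ba@weights != 0), 2 * 29)  # tree: m - 1 undirected edges
})

test_that("edge lists round-trip, 0-based, receiver-first", {
  net <- defaultNetwork5(1)
  f <- tempfile(fileext = ".edges")
  writeEdgeList(net, f)
  back <- readEdgeList(f, m = 5)
  expect_equal(back@weights, net@weights)
})

test_that("observation noise respects mode and the zero-noise identity", {
  tr <- lorenzTraj(1)
  expect_identical(addObservationNoise(tr, 0), tr)
  noisy <- addObservationNoise(tr, 0.2, "per-variable-std", seed = 5)
  resid <- states(noisy) - states(tr)
  target <- 0.2 * apply(states(tr), 2, sd)
  expect_true(all(abs(apply(resid, 2, sd) / target - 1) < 0.05))
  abs1 <- addObservationNoise(tr, 0.3, "absolute", seed = 5)
  expect_true(all(abs(apply(states(abs1) - states(tr), 2, sd) - 0.3) < 0.02))
})

test_that("ground-truth structures follow the inseparable terms of each system", {
  st <- trueStructure(systemParams("lorenz63"))
  expect_equal(neighborsOf(st, "z"), list(c("x", "y"), "z"))
  expect_equal(neighborsOf(st, "x"), list("x", "y"))
  expect_equal(neighborsOf(st, "y"), list(c("x", "z"), "y"))
  # nonlinear coupling promotes the pairwise links to 1-simplices
  net <- defaultNetwork5(1)
  sysSin <- systemParams("cl63", m = 5, params = list(coupling = "sine"), seed = 1)
  stSin <- trueStructure(sysSin, net)
  nbr1 <- which(net@weights[1, ] != 0)[1]
  expect_true(any(vapply(neighborsOf(stSin, "x1"), function(cx)
    setequal(cx, c("y1", paste0("y", nbr1))), logical(1))))
  # decoupled network leaves no cross-subsystem complexes
  st0 <- trueStructure(systemParams("cl63", m = 2, seed = 1),
                       couplingNetwork(matrix(0, 2, 2)))
  expect_equal(neighborsOf(st0, "x1"), list("x1", "y1"))
})

test_that("simulated trajectories have the documented shape", {
  tr <- lorenzTraj(1)
  expect_equal(dim(states(tr)), c(5000, 3))
  expect_equal(timeStep(tr), 0.02)
  expect_equal(varNames(tr), c("x", "y", "z"))
})
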