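test_that("candidate evaluation is deterministic and near zero for constant targets", {
  tr <- lorenzShort(1)
  cfg <- inferCfg(3)
  e1 <- candidateError("z", list(c("x", "y"), "z"), tr, cfg)
  e2 <- candidateError("z", list("z", c("y", "x")), tr, cfg)
  expect_identical(e1, e2)        # canonicalization + seeded draws
  # constant target: the residual regression fits exactly
  X <- states(tr)
  X[, "z"] <- 5
  e0 <- candidateError("z", list(c("x", "y"), "z"), trajectory(X, 0.02), cfg)
  expect_lt(e0, 1e-10)
})

test_that("dropping a true complex worsens the held-out error", {
  tr <- windowTrajectory(lorenzTraj(1), 1:3000)
  cfg <- inferCfg(1)
  eTrue <- candidateError("z", list(c("x", "y"), "z"), tr, cfg)
  eNoXY <- candidateError("z", list("z"), tr, cfg)
  expect_gt(eNoXY, eTrue * 5)
})

test_that("the non-causality test accepts a decoupled distractor and rejects a true complex", {
  tr <- windowTrajectory(lorenzTraj(1), 1:3000)
  other <- simulateSystem(systemParams("lorenz63"), steps = 3000,
                          transient = 1000, seed = 77)
  X <- cbind(states(tr), w = states(other)[, "x"])
  aug <- trajectory(X, 0.02)
  cfg <- inferCfg(2)
  C <- list(c("x", "y"), "z", "w")
  expect_true(as.logical(isNoncausal(C, "w", "z", aug, cfg)))
  expect_false(as.logical(isNoncausal(C, c("x", "y"), "z", aug, cfg)))
  expect_error(isNoncausal(list(c("x", "y"), "x"), "x", "z", tr, cfg),
               "subcomplex")
})

test_that("two uncoupled variables are inferred as self-complexes", {
  tr <- linear2Traj(1)
  cfg <- inferCfg(4, reservoir = reservoirConfig(n = 60, leak = 1,
                                                 spectralRadius = 0,
                                                 inputScale = 0.7,
                                                 ridge = 1e-8, washout = 20,
                                                 seed = 4))
  st <- inferStructure(tr, cfg = cfg)
  expect_equal(neighborsOf(st, "u1"), list("u1"))
  expect_equal(neighborsOf(st, "u2"), list("u2"))
})

test_that("the true candidate set is a fixed point of the search", {
  tr <- windowTrajectory(lorenzTraj(1), 1:3000)
  cfg <- inferCfg(1)
  res <- inferNeighbors("z", list(c("x", "y"), "z"), tr, cfg)
  expect_equal(res$neighbors, list(c("x", "y"), "z"))
  expect_true(res$converged)
  # the final error never exceeds the initial error plus the accepted slack
  res0 <- inferNeighbors("z", NULL, tr, cfg)
  e0 <- res0$trace$error[1]
  eFinal <- res0$trace$error[max(which(res0$trace$accepted))]
  expect_lte(eFinal, e0 + sum(res0$epsE) * nrow(res0$trace))
})

test_that("per-node runs are independent of execution order", {
  tr <- windowTrajectory(lorenzShort(1), 1:1400)
  cfg <- inferCfg(5)
  a <- inferStructure(tr, nodes = c("x", "z"), cfg = cfg)
  b <- inferStructure(tr, nodes = c("z", "x"), cfg = cfg)
  expect_identical(a@neighbors[order(names(a@neighbors))],
                   b@neighbors[order(names(b@neighbors))])
})

test_that("the trace records every decision with finite errors", {
  tr <- windowTrajectory(lorenzTraj(1), 1:3000)
  res <- inferNeighbors("z", NULL, tr, inferCfg(1))
  expect_s3_class(res$trace, "data.frame")
  expect_equal(res$trace$action[1], "init")
  expect_true(all(is.finite(res$trace$error)))
  expect_true(all(res$trace$action %in% c("init", "delete", "split")))
})

test_that("an uncoupled network yields no flagged subsystem neighbours", {
  sys <- systemParams("cl63", m = 2, seed = 1)
  net0 <- couplingNetwork(matrix(0, 2, 2))
  tr <- simulateSystem(sys, net0, steps = 2000, transient = 500, seed = 2)
  cfg <- inferCfg(2)
  scan <- subsystemCouplingScan("x1", list("x1", "y1"),
                                list(S2 = "y2"), tr, cfg)
  expect_false(any(scan$flagged))
})
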