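test_that("normalised RMSE follows its formula and scale invariance", {
  expect_equal(rmseAt(c(1, 1), c(1, 1), c(2, 2)), 0)
  expect_equal(rmseAt(2, 1, 2), 0.5)
  expect_equal(rmseAt(c(0.6, 0.8), c(0, 0), c(2, 2)),
               sqrt((0.09 + 0.16) / 2))
  expect_error(rmseAt(1, 1, 0), "positive")
  # joint rescaling of prediction, truth and sigma leaves RMSE unchanged
  set.seed(1)
  p <- rnorm(5); q <- rnorm(5); s <- runif(5, 0.5, 2)
  expect_equal(rmseAt(3 * p, 3 * q, 3 * s), rmseAt(p, q, s))
})

test_that("valid prediction steps count until first exceedance", {
  truth <- matrix(0, 5, 1, dimnames = list(NULL, "x"))
  pred <- matrix(c(0.001, 0.005, 0.02, 0.001, 0.001), 5, 1,
                 dimnames = list(NULL, "x"))
  expect_equal(validPredictionSteps(pred, truth, 0.01, sigma = 1), 2)
  expect_equal(validPredictionSteps(truth, truth, 0.01, sigma = 1), 5)
  # non-decreasing in the tolerance
  set.seed(2)
  P <- matrix(cumsum(abs(rnorm(40, 0.01))), 40, 1, dimnames = list(NULL, "x"))
  Q <- matrix(0, 40, 1, dimnames = list(NULL, "x"))
  eps <- sort(runif(6, 0.01, 0.5))
  v <- vapply(eps, function(e) validPredictionSteps(P, Q, e, sigma = 1),
              integer(1))
  expect_true(all(diff(v) >= 0))
})

test_that("a perfect forecaster scores the full horizon", {
  tr <- lorenzShort(1)
  X <- states(tr)
  expect_equal(validPredictionSteps(X[101:200, ], X[101:200, ], 0.01),
               100)
})

test_that("the comparison harness is seed-deterministic and scores divergence", {
  tr <- lorenzShort(1)
  st <- trueStructure(systemParams("lorenz63"))
  cfg <- reservoirConfig(n = 60, seed = 2)
  c1 <- runComparison(tr, st, methods = c("rc", "hogrc"), cfg = cfg,
                      nStarts = 3, horizon = 40, seed = 5)
  c2 <- runComparison(tr, st, methods = c("rc", "hogrc"), cfg = cfg,
                      nStarts = 3, horizon = 40, seed = 5)
  expect_identical(c1, c2)
  expect_true(all(c1$vps >= 0 & c1$vps <= 40))
  s <- summarizeComparison(c1)
  expect_setequal(s$method, c("rc", "hogrc"))
})

test_that("a single-point noise sweep reproduces the plain comparison", {
  sys <- systemParams("lorenz63")
  sw <- runSweep("noise", grid = 0, sys = sys, steps = 1500,
                 methods = "hogrc", cfg = reservoirConfig(n = 60, seed = 3),
                 nStarts = 3, horizon = 30, seed = 3)
  tr <- simulateSystem(sys, steps = 1500, seed = 3)
  cmp <- runComparison(tr, trueStructure(sys), methods = "hogrc",
                       cfg = reservoirConfig(n = 60, seed = 3),
                       nStarts = 3, horizon = 30, seed = 3)
  expect_equal(sw$vps, cmp$vps)
})
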