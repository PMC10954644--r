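# Plain-R reference implementation of the leaky-tanh update (the classic
# shared-reservoir recursion), used as the oracle for the compiled drive.
referenceDrive <- function(Win, A, b, leak, X, r0) {
  R <- matrix(0, nrow(X), length(r0))
  r <- r0
  for (t in seq_len(nrow(X))) {
    r <- (1 - leak) * r + leak * tanh(Win %*% X[t, ] + A %*% r + b)
    R[t, ] <- r
  }
  R
}

nm3 <- c("x", "y", "z")
cfgSmall <- reservoirConfig(n = 60, washout = 10, seed = 11)

test_that("block construction enforces the input masks and block-diagonal adjacency", {
  res <- buildNodeReservoir("z", list("z", c("x", "y")), nm3, cfgSmall)
  expect_equal(nrow(res@Win), 60)
  expect_equal(res@blockSize, 30L)
  # canonical order puts {x,y} first: rows 1..30 see x,y only, rows 31..60 z only
  expect_true(all(res@Win[1:30, 3] == 0))
  expect_true(all(res@Win[1:30, 1:2] != 0))
  expect_true(all(res@Win[31:60, 1:2] == 0))
  expect_true(all(res@A[1:30, 31:60] == 0))
  expect_true(all(res@A[31:60, 1:30] == 0))
  # floor rule: D = 3 with n = 10 gives three 3-row blocks
  res3 <- buildNodeReservoir("x", list("x", "y", "z"), nm3,
                             reservoirConfig(n = 10, seed = 1))
  expect_equal(nrow(res3@Win), 9)
  expect_equal(res3@blockSize, 3L)
  expect_error(buildNodeReservoir("x", list("x", "y"), nm3,
                                  reservoirConfig(n = 1, seed = 1)),
               "number of complexes")
})

test_that("adjacency blocks hit the configured spectral radius exactly", {
  res <- buildNodeReservoir("z", list("z", c("x", "y")), nm3, cfgSmall)
  for (rows in list(1:30, 31:60)) {
    sr <- max(Mod(eigen(res@A[rows, rows], only.values = TRUE)$values))
    expect_equal(sr, 0.9, tolerance = 1e-6)
  }
  classic <- buildClassicRC(nm3, cfgSmall)
  expect_equal(dim(classic@Win), c(60, 3))
  expect_true(all(classic@Win != 0))
  expect_identical(buildClassicRC(nm3, cfgSmall)@Win, classic@Win)
})

test_that("PRC reservoirs restrict inputs to the pairwise neighbourhood", {
  res <- buildPRC("z", c("x", "y", "z"), nm3, cfgSmall)
  expect_equal(length(res@complexes), 1L)
  expect_true(all(res@Win != 0))
  resSelf <- buildPRC("x", "x", nm3, cfgSmall)
  expect_true(all(resSelf@Win[, 2:3] == 0))
  expect_error(buildPRC("x", c("y", "z"), nm3, cfgSmall), "include itself")
})

test_that("drive follows the leaky-tanh recursion bit-for-bit", {
  res <- buildNodeReservoir("z", list("z", c("x", "y")), nm3, cfgSmall)
  set.seed(5)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, nm3))
  R <- driveReservoir(res, X)
  Rref <- referenceDrive(res@Win, res@A, res@b, res@leak, X, numeric(60))
  expect_equal(R, Rref, tolerance = 1e-13)
  # zero input, zero bias, zero start stays at zero
  res0 <- res; res0@b <- numeric(60)
  expect_true(all(driveReservoir(res0, matrix(0, 5, 3)) == 0))
  # leak 1 keeps every coordinate strictly inside (-1, 1)
  cfg1 <- reservoirConfig(n = 40, leak = 1, seed = 2)
  r1 <- driveReservoir(buildClassicRC(nm3, cfg1), X * 10)
  expect_true(all(abs(r1) < 1))
})

test_that("a higher-order reservoir is a constrained classic reservoir (containment)", {
  # the structured (W_in, A) pair driven by the unconstrained recursion
  # reproduces the structured states exactly, and perturbing a variable
  # outside the complex union leaves states and prediction untouched
  res <- buildNodeReservoir("y", list("y", c("x", "y")), nm3, cfgSmall)
  set.seed(6)
  X <- matrix(rnorm(90), 30, 3, dimnames = list(NULL, nm3))
  expect_equal(driveReservoir(res, X),
               referenceDrive(res@Win, res@A, res@b, res@leak, X, numeric(60)),
               tolerance = 1e-13)
  Xz <- X; Xz[, "z"] <- Xz[, "z"] + rnorm(30)
  expect_identical(driveReservoir(res, X), driveReservoir(res, Xz))
})

test_that("the ridge readout solves the regularized normal equations", {
  set.seed(7)
  R <- matrix(rnorm(400), 50, 8)
  wTrue <- rnorm(8)
  # targets exactly linear in the states: recovered to numerical precision
  u <- cumsum(c(0, as.vector(R[-50, ] %*% wTrue)))
  ro <- fitReadout(R, u, ridge = 0, washout = 0, node = "u")
  expect_equal(as.vector(ro@Wout), wTrue, tolerance = 1e-8)
  # ridge limit: enormous penalty shrinks the readout to zero
  roBig <- fitReadout(R, u, ridge = 1e12, washout = 0)
  expect_true(all(abs(roBig@Wout) < 1e-6))
  # normal-equations residual
  ro2 <- fitReadout(R, u, ridge = 1e-4, washout = 0)
  rows <- 1:49
  G <- crossprod(R[rows, ]); diag(G) <- diag(G) + 1e-4
  rhs <- crossprod(R[rows, ], u[rows + 1] - u[rows])
  expect_lt(norm(G %*% t(ro2@Wout) - rhs, "F") / norm(rhs, "F"), 1e-8)
})

test_that("training error does not increase as the ridge penalty shrinks", {
  tr <- lorenzShort(1)
  res <- buildNodeReservoir("z", list("z", c("x", "y")), nm3,
                            reservoirConfig(n = 60, seed = 3))
  X <- scale(states(tr))
  R <- driveReservoir(res, X)
  trainErr <- function(ridge) {
    ro <- fitReadout(R, X[, "z"], ridge = ridge, washout = 50)
    rows <- 51:(nrow(X) - 1)
    pred <- as.vector(R[rows, ] %*% t(ro@Wout))
    mean((X[rows + 1, "z"] - X[rows, "z"] - pred)^2)
  }
  errs <- vapply(c(1e-2, 1e-4, 1e-6, 1e-8), trainErr, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("one-step prediction is the residual convention", {
  ro <- new("Readout", Wout = matrix(c(1, -1), 1, 2), ridge = 0, node = "u")
  expect_equal(oneStep(1.0, c(0.25, -0.25), ro), 1.5)
  expect_equal(oneStep(2.0, c(0, 0), ro), 2.0)
  ro0 <- new("Readout", Wout = matrix(0, 1, 2), ridge = 0, node = "u")
  expect_equal(oneStep(3.0, c(5, 5), ro0), 3.0)
})

test_that("closed-loop forecasting tracks a learnable linear system", {
  tr <- harmonicTraj()
  train <- windowTrajectory(tr, 1:1000)
  st <- higherOrderStructure(c("u1", "u2"),
                             list(u1 = list("u1", "u2"),
                                  u2 = list("u1", "u2")))
  cfg <- reservoirConfig(n = 60, leak = 1, spectralRadius = 0.1,
                         inputScale = 0.5, ridge = 1e-10, washout = 20,
                         seed = 4)
  m <- trainForecaster(train, "hogrc", st, cfg)
  fc <- multiStepForecast(m, windowTrajectory(tr, 801:1000), 50)
  expect_s4_class(fc, "Trajectory")
  expect_false(attr(fc, "diverged"))
  truth <- states(tr)[1001:1050, ]
  expect_lt(max(abs(states(fc) - truth)), 1e-2)
  # zero-step forecast is an empty matrix
  expect_equal(nrow(multiStepForecast(m, windowTrajectory(tr, 801:1000), 0)), 0)
})

test_that("forecasts are deterministic given seed, structure and config", {
  tr <- lorenzShort(1)
  st <- trueStructure(systemParams("lorenz63"))
  cfg <- reservoirConfig(n = 120, seed = 9)
  f1 <- multiStepForecast(trainForecaster(windowTrajectory(tr, 1:900), "hogrc", st, cfg),
                          windowTrajectory(tr, 801:1000), 30)
  f2 <- multiStepForecast(trainForecaster(windowTrajectory(tr, 1:900), "hogrc", st, cfg),
                          windowTrajectory(tr, 801:1000), 30)
  expect_identical(states(f1), states(f2))
})

test_that("the angle codec encodes, decodes and round-trips", {
  th <- matrix(c(0, 1, pi), 3, 1, dimnames = list(NULL, "theta1"))
  enc <- encodeAngles(th)
  expect_equal(enc[1, ], c(sin_theta1 = 0, cos_theta1 = 1))
  expect_equal(decodeDelta(0, 1.2, 0.08), 1.2)
  expect_equal(decodeDelta(0.5, 1.0, 0.08), 1.04)
  # encode/decode round-trips modulo 2 pi
  theta <- runif(10, -10, 10)
  rec <- atan2(sin(theta), cos(theta))
  expect_equal(sin(rec), sin(theta), tolerance = 1e-12)
  expect_equal(cos(rec), cos(theta), tolerance = 1e-12)
})
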