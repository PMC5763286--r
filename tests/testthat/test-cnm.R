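test_that("ssr follows the relative-residual definition", {
  expect_equal(ssr(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ssr(c(1.1, 0.9), c(1, 1)), 0.02)
  # relative residuals are scale invariant
  calc <- c(2, 5, 9); tgt <- c(1.5, 6, 10)
  expect_equal(ssr(calc, tgt), ssr(10 * calc, 10 * tgt))
  expect_equal(ssr(calc, tgt, residual = "absolute"),
               sum((calc - tgt)^2))
  expect_error(ssr(1:3, 1:2), "length mismatch")
  expect_error(ssr(c(1, 1), c(1, 0)), "positive")
})

test_that("initial cluster sampling respects bounds, masks and seeds", {
  b <- boundBox(rep(0.1, 5), rep(10, 5))
  mask <- constraintMask(3L, 1.7)
  cfg <- cnmConfig(n_points = 200, seed = 5)
  cl <- sampleInitialCluster(b, mask, cfg)
  expect_true(all(cl$points >= 0.1 & cl$points <= 10))
  expect_equal(unname(cl$points[, 3]), rep(1.7, 200))
  cl2 <- sampleInitialCluster(b, mask, cfg)
  expect_identical(cl$points, cl2$points)
  expect_error(sampleInitialCluster(b, constraintMask(1:5, rep(1, 5)), cfg),
               "mask fixes everything")

  # log-uniform sampling: the median sits at the geometric mean
  set.seed(31)
  draws <- sampleInitialCluster(boundBox(0.1, 10),
                                config = cnmConfig(n_points = 10000),
                                reseed = FALSE)$points[, 1]
  expect_gt(median(draws), 0.8)
  expect_lt(median(draws), 1.25)
})

test_that("affine surrogate fit recovers exact maps and matches normal equations", {
  toy <- affineToy(k = 2L, seed = 1)
  set.seed(2)
  pts <- matrix(runif(10, 0.5, 5), 5, 2)
  cl <- pbpkcnm:::newCluster(pts)
  cl$observables <- t(apply(pts, 1, toy$forward))
  cl$ssr <- rep(0.5, 5)
  cfg <- cnmConfig(n_points = 13, space = "linear")
  map <- fitLinearMap(cl, config = cfg)
  expect_equal(map$A, toy$A, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(map$b, toy$b, tolerance = 1e-8)
  # independent normal-equations oracle
  M <- cbind(1, pts)
  coef_oracle <- solve(t(M) %*% M, t(M) %*% cl$observables)
  expect_equal(unname(rbind(map$b, t(map$A))), unname(coef_oracle),
               tolerance = 1e-8)

  # constant observables give a zero slope
  cl$observables <- matrix(3, 5, 13)
  map0 <- fitLinearMap(cl, config = cfg)
  expect_equal(max(abs(map0$A)), 0, tolerance = 1e-10)
  expect_equal(map0$b, rep(3, 13))

  # rank deficiency is caught with advice
  cl$points[, 2] <- 2
  expect_error(fitLinearMap(cl, config = cfg), "cluster size")
})

test_that("cluster update solves affine problems in one step and honours dS", {
  toy <- affineToy(k = 2L, seed = 3)
  x_true <- c(2, 3)
  targets <- toy$forward(x_true)
  b <- boundBox(rep(0.1, 2), rep(10, 2))
  cfg <- cnmConfig(n_points = 30, eta = 0, ds = 0, space = "linear",
                   sampling = "linear", residual = "absolute", seed = 4)
  cl <- sampleInitialCluster(b, config = cfg)
  cl$observables <- t(apply(cl$points, 1, toy$forward))
  cl$ssr <- rowSums((cl$observables -
                       matrix(targets, 30, 13, byrow = TRUE))^2)
  map <- fitLinearMap(cl, config = cfg)

  up <- cnmUpdate(cl, map, targets, cfg, bounds = b)
  pred <- up$points %*% t(map$A) + matrix(map$b, 30, 13, byrow = TRUE)
  expect_lt(max(abs(pred - matrix(targets, 30, 13, byrow = TRUE))), 1e-6)
  # the unique consistent solution is recovered by every point
  expect_equal(up$points, matrix(x_true, 30, 2, byrow = TRUE),
               tolerance = 1e-6, ignore_attr = TRUE)

  # dS = 0 equals an independently computed full original-CNM step
  sv <- svd(toy$A)
  pinv <- sv$v %*% (t(sv$u) / sv$d)
  resid <- matrix(targets, 30, 13, byrow = TRUE) - cl$observables
  oracle <- cl$points + resid %*% t(pinv)
  expect_equal(up$points, oracle, tolerance = 1e-9, ignore_attr = TRUE)

  # dS = 1 leaves every point exactly in place
  cfg1 <- cfg; cfg1$ds <- 1
  up1 <- cnmUpdate(cl, map, targets, cfg1, bounds = b)
  expect_identical(up1$points, cl$points)

  # intermediate dS moves each point by (1 - dS) of the full step
  cfg2 <- cfg; cfg2$ds <- 0.2
  up2 <- cnmUpdate(cl, map, targets, cfg2, bounds = b)
  expect_equal(up2$points - cl$points, 0.8 * (up$points - cl$points),
               tolerance = 1e-9)
})

test_that("the full CNM loop collapses a linear toy and stays reproducible", {
  toy <- affineToy(k = 2L, seed = 5)
  toy$A <- toy$A / 10
  toy$b <- abs(toy$b) + 5     # keep targets positive
  fwd <- function(theta) as.numeric(toy$A %*% theta + toy$b)
  targets <- fwd(c(2, 3))
  b <- boundBox(rep(0.1, 2), rep(10, 2))
  # one iteration: an exact affine solve collapses every point onto the
  # unique consistent solution (a second surrogate fit would then be
  # rank-deficient by construction)
  cfg <- cnmConfig(n_points = 30, iterations = 1, eta = 0, ds = 0,
                   space = "linear", sampling = "linear",
                   residual = "absolute", seed = 6)
  h <- runCNM(fwd, targets, b, config = cfg)
  med0 <- median(h$clusters[[1]]$ssr)
  expect_lt(median(h$final$ssr), 1e-4 * med0)
  for (cl in h$clusters) {
    expect_true(all(cl$points >= 0.1 & cl$points <= 10))
  }
  h2 <- runCNM(fwd, targets, b, config = cfg)
  expect_identical(h$final$points, h2$final$points)

  # zero iterations return the evaluated initial cluster
  cfg0 <- cfg; cfg0$iterations <- 0L
  h0 <- runCNM(fwd, targets, b, config = cfg0)
  expect_equal(h0$final$iteration, 0L)
  expect_length(h0$clusters, 1L)
})

test_that("masked coordinates never move and failures are resampled", {
  mask <- constraintMask(unname(kpIndices()), rep(1, 70))
  cfg <- cnmConfig(n_points = 45, iterations = 2, seed = 8)
  targets <- toy105(rep(0.5, 105) + 0.5)
  fail_every <- local({
    k <- 0L
    function(theta) {
      k <<- k + 1L
      if (k %% 17L == 0L) return(NULL)    # sporadic forward failures
      toy105(theta)
    }
  })
  h <- runCNM(fail_every, targets, defaultBounds(), mask = mask,
              config = cfg)
  for (cl in h$clusters) {
    expect_equal(cl$points[, 1:70],
                 matrix(1, nrow(cl$points), 70), ignore_attr = TRUE)
    free_pts <- cl$points[, 71:105]
    tab <- parameterTable()
    expect_true(all(free_pts >= matrix(tab$min[71:105], nrow(cl$points),
                                       35, byrow = TRUE)))
    expect_true(all(free_pts <= matrix(tab$max[71:105], nrow(cl$points),
                                       35, byrow = TRUE)))
  }
})

test_that("median SSR decreases on a nonlinear toy across seeds", {
  for (seed in 1:10) {
    truth <- makeTruthParameters(seed = seed + 100)
    targets <- toy105(as.numeric(truth))
    cfg <- cnmConfig(n_points = 120, iterations = 3, seed = seed)
    h <- runCNM(toy105, targets, defaultBounds(), config = cfg)
    expect_lt(median(h$final$ssr, na.rm = TRUE),
              median(h$clusters[[1]]$ssr, na.rm = TRUE))
  }
})
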