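test_that("a uniform field at the steady state is a fixed point of the scheme", {
  p <- repKinetics()
  u0 <- equilibria(p)$u0_star
  cfg <- solverConfig(grid_n = 16, t_end = 1, dt = 1e-3)
  st <- rdStep(matrix(u0, 16, 16), p, cfg, nsteps = 50)
  expect_lt(max(abs(st$u - u0)), 1e-12)
})

test_that("the compiled stepper matches an independent naive R implementation", {
  p <- kineticParams(u_tot = 0.05)  # tiny store so the switch trips mid-test
  n <- 8
  set.seed(1)
  u <- matrix(runif(n * n, 0.1, 0.9), n, n)
  cfg <- solverConfig(grid_n = n, t_end = 1, dt = 1e-3)
  ref <- list(u = u, U = matrix(0, n, n), chi = matrix(1, n, n))
  for (k in 1:20)
    ref <- refStep2d(ref$u, ref$U, ref$chi, p, 1 / n, 1e-3)
  st <- rdStep(u, p, cfg, nsteps = 20)
  expect_equal(st$u, ref$u, tolerance = 1e-13)
  expect_equal(st$cum_release, ref$U, tolerance = 1e-13)
  expect_equal(st$chi, ref$chi)
})

test_that("pure diffusion with zero-flux boundaries conserves mass", {
  p <- kineticParams(gamma = 0, alpha0 = 0, alpha1 = 0, alpha2 = 0, mu = 0)
  n <- 32
  set.seed(2)
  u <- matrix(runif(n * n), n, n)
  cfg <- solverConfig(grid_n = n, t_end = 1, dt = 1e-3)
  st <- rdStep(u, p, cfg, nsteps = 1000)
  expect_lt(abs(sum(st$u) - sum(u)), 1e-10)
  expect_true(all(st$u >= 0))
})

test_that("a point release under pure diffusion matches the Gaussian kernel", {
  p <- kineticParams(gamma = 0, alpha0 = 0, alpha1 = 0, alpha2 = 0, mu = 0)
  # radial mode: axisymmetric delta of unit mass in the innermost cell
  n <- 512
  cfg <- solverConfig(grid_n = n, t_end = 30, dt = 0.02,
                      snapshot_interval = 30, radial_mode = TRUE)
  h <- cfg$domain_radius / n
  u <- rep(0, n); u[1] <- 1 / (pi * h^2)
  traj <- rdRun(p, u, whealParams(), cfg)
  uf <- traj$u[[length(traj$u)]]
  rc <- (seq_len(n) - 0.5) * h
  t <- max(traj$times)
  exact <- 1 / (4 * pi * p$d_u * t) * exp(-rc^2 / (4 * p$d_u * t))
  core <- exact > 1e-3 * max(exact)
  expect_gt(sqrt(4 * p$d_u * t) / h, 10)  # kernel resolved by >= 10 cells
  expect_lt(max(abs(uf[core] / exact[core] - 1)), 0.02)

  # 2-D: same oracle on a coarser grid
  n2 <- 96
  cfg2 <- solverConfig(grid_n = n2, t_end = 1400, dt = 0.15,
                       snapshot_interval = 1400)
  h2 <- 1 / n2
  u2 <- matrix(0, n2, n2); u2[n2 / 2, n2 / 2] <- 1 / h2^2
  traj2 <- rdRun(p, u2, whealParams(), cfg2)
  uf2 <- traj2$u[[length(traj2$u)]]
  ctr <- (n2 / 2 - 0.5) * h2
  xc <- (seq_len(n2) - 0.5) * h2
  rr2 <- outer(xc, xc, function(x, y) (x - ctr)^2 + (y - ctr)^2)
  t2 <- max(traj2$times)
  expect_gt(sqrt(4 * p$d_u * t2) * n2, 10)  # kernel resolved by >= 10 cells
  exact2 <- 1 / (4 * pi * p$d_u * t2) * exp(-rr2 / (4 * p$d_u * t2))
  core2 <- exact2 > 1e-2 * max(exact2)
  expect_lt(max(abs(uf2[core2] / exact2[core2] - 1)), 0.02)
})

test_that("t_end = 0 returns only the initial condition", {
  p <- repKinetics()
  u <- matrix(0.3, 8, 8)
  traj <- rdRun(p, u, whealParams(), solverConfig(grid_n = 8, t_end = 0))
  expect_length(traj$times, 1)
  expect_equal(traj$u[[1]], u)
})

test_that("without inhibition growth is spatially uniform and exponential", {
  p <- kineticParams(gamma = 4, alpha0 = 0.7, alpha1 = 0, alpha2 = 0,
                     mu = 1.5, u_tot = 1e12)
  n <- 24
  u <- matrix(0.3, n, n)
  cfg <- solverConfig(grid_n = n, t_end = 2, dt = 1e-4, snapshot_interval = 0.5)
  traj <- rdRun(p, u, whealParams(), cfg)
  means <- vapply(traj$u, mean, numeric(1))
  cv <- vapply(traj$u, function(m) stats::sd(m) / mean(m), numeric(1))
  expect_true(all(cv < 1e-6))
  expect_true(all(diff(means) > 0))
  k <- p$gamma - p$alpha0
  closed <- (0.3 + p$mu / k) * exp(k * traj$times) - p$mu / k
  expect_lt(max(abs(means / closed - 1)), 0.01)
})

test_that("a random stimulus on the representative kinetics forms a pattern", {
  p <- repKinetics()
  sp <- stimulusSpec(r = 0.5, s = 0, seed = 4)
  cfg <- solverConfig(grid_n = 64, t_end = 30, snapshot_interval = 5)
  traj <- rdRun(p, sp, whealParams(), cfg)
  contrast <- vapply(traj$u, function(u) max(u) / min(u), numeric(1))
  expect_gt(max(contrast), 10)  # strong transient spatial heterogeneity
  # determinism at fixed seed
  traj2 <- rdRun(p, sp, whealParams(), cfg)
  expect_identical(traj$u[[length(traj$u)]], traj2$u[[length(traj2$u)]])
})

test_that("store depletion is one-way and cumulative release never decreases", {
  p <- kineticParams(u_tot = 30)  # small store, depletes within the run
  sp <- stimulusSpec(r = 0.5, s = 0, seed = 4)
  cfg <- solverConfig(grid_n = 32, t_end = 30, snapshot_interval = 1)
  traj <- rdRun(p, sp, whealParams(), cfg)
  for (i in seq_along(traj$times)) {
    chi <- traj$chi[[i]]
    U <- traj$cum_release[[i]]
    expect_true(all(chi[U > p$u_tot] == 0))
    expect_true(all(traj$u[[i]] >= 0))
    if (i > 1) {
      expect_true(all(chi <= traj$chi[[i - 1]]))            # never re-arms
      expect_true(all(U >= traj$cum_release[[i - 1]] - 1e-12))
    }
  }
  expect_gt(sum(traj$chi[[length(traj$times)]] == 0), 0)    # depletion happened
})

test_that("the hysteretic wheal readout is a sigmoid with a sharper falling branch", {
  wp <- whealParams(u_r = 0.4, beta_rise = 30, beta_fall = 150)
  expect_equal(whealState(0.4, "rising", wp), 0.5)
  expect_equal(whealState(0.4, "falling", wp), 0.5)
  expect_gt(whealState(10, "rising", wp), 1 - 1e-10)
  expect_lt(whealState(0, "falling", wp), 1e-10)
  d <- 0.1 / wp$beta_rise
  # the falling branch is steeper: further from 1/2 on both sides of u_r
  expect_lt(whealState(0.4 - d, "falling", wp), whealState(0.4 - d, "rising", wp))
  expect_gt(whealState(0.4 + d, "falling", wp), whealState(0.4 + d, "rising", wp))
  expect_error(whealParams(beta_rise = 100, beta_fall = 50), "beta_rise")
})

test_that("front tracking recovers a constructed constant-speed expansion", {
  # synthetic radial trajectory: sharp front at R(t) = R0 + c t
  n <- 400; h <- 0.5 / n
  rc <- (seq_len(n) - 0.5) * h
  times <- seq(0, 20, by = 1)
  R0 <- 0.05; cc <- 0.008
  mk <- function(Rt) 0.8 / (1 + exp((rc - Rt) / (h / 2)))
  traj <- structure(list(
    times = times,
    u = lapply(times, function(t) mk(R0 + cc * t)),
    direction = lapply(times, function(t) rep(1, n)),
    h = h, wheal = whealParams(u_r = 0.4),
    config = solverConfig(grid_n = n, t_end = 20, radial_mode = TRUE)),
    class = "rdTrajectory")
  tr <- trackFront(traj)
  expect_equal(tr$status, "ok")
  expect_equal(tr$speed, cc, tolerance = 0.02)
  # stationary disk: zero speed
  traj$u <- lapply(times, function(t) mk(R0))
  tr0 <- trackFront(traj)
  expect_lt(abs(tr0$speed), 1e-8)
  # threshold never reached: empty trace
  traj$u <- lapply(times, function(t) rep(0.1, n))
  expect_equal(trackFront(traj)$status, "empty")
})

test_that("2-D front tracking agrees on a constructed expanding disk", {
  n <- 128; h <- 1 / n
  xc <- (seq_len(n) - 0.5) * h
  times <- seq(0, 10, by = 1)
  mk <- function(Rt) {
    rr <- outer(xc, xc, function(x, y) sqrt((x - 0.5)^2 + (y - 0.5)^2))
    0.8 / (1 + exp((rr - Rt) / (h / 2)))
  }
  traj <- structure(list(
    times = times,
    u = lapply(times, function(t) mk(0.1 + 0.02 * t)),
    direction = lapply(times, function(t) matrix(1, n, n)),
    h = h, wheal = whealParams(u_r = 0.4),
    config = solverConfig(grid_n = n, t_end = 10)),
    class = "rdTrajectory")
  tr <- trackFront(traj, n_rays = 32)
  expect_equal(tr$speed, 0.02, tolerance = 0.05)
  expect_true(all(tr$radius_sd[!is.na(tr$radius_sd)] < 2 * h))
})

test_that("halving dt leaves the ignited front solution essentially unchanged", {
  p <- repKinetics()
  cfg1 <- radialCfg(grid_n = 256, t_end = 15, dt = 5e-5, snap = 15)
  cfg2 <- radialCfg(grid_n = 256, t_end = 15, dt = 2.5e-5, snap = 15)
  u0 <- radialBump(p, cfg1)
  t1 <- rdRun(p, u0, whealParams(), cfg1)
  t2 <- rdRun(p, u0, whealParams(), cfg2)
  a <- t1$u[[length(t1$u)]]; b <- t2$u[[length(t2$u)]]
  expect_lt(max(abs(a - b)) / max(abs(b)), 0.005)
})

test_that("radial and 2-D front speeds agree for an axisymmetric stimulus", {
  p <- repKinetics()
  # radial measurement
  cfgr <- radialCfg(grid_n = 512, t_end = 30, dt = 2e-3, snap = 2)
  trr <- trackFront(rdRun(p, radialBump(p, cfgr), whealParams(), cfgr))
  # matched-resolution 2-D measurement (h = 1/256 ~ 2x radial h)
  n <- 256
  cfg2 <- solverConfig(grid_n = n, t_end = 30, dt = 2e-3, snapshot_interval = 2)
  u0s <- equilibria(p)$u0_star
  xc <- (seq_len(n) - 0.5) / n
  rr <- outer(xc, xc, function(x, y) sqrt((x - 0.5)^2 + (y - 0.5)^2))
  u0 <- u0s + 0.6 * exp(-(rr / 0.02)^2)
  tr2 <- trackFront(rdRun(p, u0, whealParams(), cfg2))
  expect_equal(tr2$speed, trr$speed, tolerance = 0.1)
})

test_that("instability and CFL violations are reported as errors", {
  p <- repKinetics()
  cfg <- solverConfig(grid_n = 64, t_end = 1, dt = 100)  # above the CFL limit
  expect_error(rdStep(matrix(0.2, 64, 64), p, cfg), "stability limit")
})

test_that("front traces and wheal masks round-trip through their file formats", {
  tmp <- withr::local_tempdir()
  p <- repKinetics()
  cfg <- radialCfg(grid_n = 128, t_end = 5, dt = 2e-3, snap = 1)
  traj <- rdRun(p, radialBump(p, cfg), whealParams(), cfg)
  tr <- trackFront(traj)
  f <- file.path(tmp, "front.csv")
  writeFrontTrace(tr, f)
  back <- read.csv(f)
  expect_equal(back$radius, tr$radii)
  # mask PNG: white exactly where the wheal is
  mask <- matrix(FALSE, 16, 16); mask[4:9, 6:12] <- TRUE
  fp <- file.path(tmp, "mask.png")
  writeWhealMask(mask, fp)
  img <- png::readPNG(fp)
  expect_equal(sum(img == 1), sum(mask))
  # trajectory RDS round trip
  writeTrajectory(traj, tmp)
  traj2 <- readRDS(file.path(tmp, "trajectory.rds"))
  expect_equal(traj2$u[[length(traj2$u)]], traj$u[[length(traj$u)]])
})
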