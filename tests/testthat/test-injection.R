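test_that("the point-source solution has the right center value and unit mass", {
  m <- injectionModel(u0 = 0.3, d = 0.0847)
  expect_equal(gaussianSolution(0, 1, m), 0.3 / (4 * pi * 0.0847))
  # plane integral by radial quadrature
  mass <- integrate(function(r) 2 * pi * r * gaussianSolution(r, 5, m),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, m$u0, tolerance = 1e-3)
  expect_error(gaussianSolution(1, 0, m), "positive")
})

test_that("threshold radius round-trips, peaks at the closed-form t*, and vanishes", {
  m <- injectionModel()
  tg <- seq(0.5, 70, length.out = 100)
  r <- thresholdRadius(tg, m, offset = FALSE)
  ok <- !is.na(r)
  expect_true(all(abs(gaussianSolution(r[ok], tg[ok], m) - m$u_r) < 1e-10))
  # maximizer: closed form u0/(4 pi D u_r e), cross-checked by grid search
  ts <- tStarMax(m)
  expect_equal(ts, 27.65, tolerance = 1e-3)
  tfine <- seq(1, 60, by = 0.01)
  expect_equal(tfine[which.max(thresholdRadius(tfine, m, offset = FALSE))],
               ts, tolerance = 0.01 / ts * 2)
  # at t*, the log factor is 1: radius is 2 sqrt(D t*) + r0
  expect_equal(thresholdRadius(ts, m), 2 * sqrt(m$d * ts) + m$r0,
               tolerance = 1e-10)
  # far beyond e t* the threshold is nowhere reached
  expect_true(is.na(thresholdRadius(3 * exp(1) * ts, m)))
})

test_that("expansion velocity matches finite differences and decays monotonically", {
  m <- injectionModel()
  tg <- seq(1, 25, by = 0.5)
  v <- expansionVelocity(tg, m)
  d <- 1e-6
  fd <- (thresholdRadius(tg + d, m) - thresholdRadius(tg - d, m)) / (2 * d)
  expect_lt(max(abs(v / fd - 1)), 1e-6)
  expect_true(all(diff(v) < 0))                       # monotone decreasing
  expect_equal(expansionVelocity(tStarMax(m), m), 0, tolerance = 1e-12)
  # mean over the first 15 minutes: direct evaluation of the radius gain
  mv <- meanExpansionVelocity(m, 15)
  expect_equal(mv, (thresholdRadius(15, m) - m$r0) / 15)
  expect_equal(mv, 0.19, tolerance = 0.01)
})

test_that("saturating-exponential fitting recovers parameters", {
  tt <- seq(0, 30, by = 1)
  truth <- c(Y0 = 3.2, P = 6.3, alpha = 0.15)
  y <- truth["Y0"] + (truth["P"] - truth["Y0"]) * (1 - exp(-truth["alpha"] * tt))
  ft <- fitSaturating(tt, y)
  expect_equal(c(ft$Y0, ft$P, ft$alpha), unname(truth), tolerance = 1e-6)
  # constant series: plateau equals baseline, rate unidentifiable
  ftc <- fitSaturating(tt, rep(4.2, length(tt)))
  expect_equal(ftc$P, 4.2)
  expect_equal(ftc$Y0, 4.2)
  expect_false(ftc$alpha_identifiable)
  expect_error(fitSaturating(1:3, 1:3), "at least 4")
  # 5% noise, 20 points: plateau recovered within 5% (median over 100 seeds)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    yn <- y[1:20] * (1 + rnorm(20, 0, 0.05))
    abs(fitSaturating(tt[1:20], yn)$P / truth["P"] - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("the expansion-stop time follows the closed form of the fitted curve", {
  ft <- list(Y0 = 3.2, P = 6.3, alpha = 0.15, alpha_identifiable = TRUE)
  eps <- 0.005
  ex <- extractTstarRmax(ft, eps)
  t_closed <- log(0.15 * (6.3 - 3.2) / eps) / 0.15
  expect_equal(ex$t_star, t_closed, tolerance = 1e-12)
  expect_equal(ex$r_max, 3.2 + 3.1 * (1 - exp(-0.15 * t_closed)))
  # numeric search on the derivative agrees
  tg <- seq(0, 100, by = 1e-4)
  deriv <- 0.15 * 3.1 * exp(-0.15 * tg)
  expect_equal(tg[which(deriv <= eps)[1]], t_closed, tolerance = 1e-3)
  # epsilon above the initial velocity: boundary case flagged
  exb <- extractTstarRmax(ft, epsilon = 1)
  expect_true(exb$boundary)
  expect_equal(exb$t_star, 0)
})

test_that("diffusion estimation recovers the generating coefficient", {
  fx <- makeDoseFixtures(d_true = 0.08, noise_sd = 0)
  est <- estimateDiffusion(fx)
  expect_equal(est$d_mean, 0.08, tolerance = 0.05)
  expect_length(est$d_pairwise, 3)
  # identical doses are flagged as unidentifiable and skipped
  s10 <- fx[["dose_10"]]
  expect_warning(est2 <- estimateDiffusion(list(s10, s10, fx[["dose_30"]])),
                 "identical doses")
  expect_true(is.na(est2$d_pairwise[1]))
  # the uniroot solution matches the closed-form solution of the pair equality
  i <- "dose_10"; j <- "dose_30"
  ext <- lapply(fx[c(i, j)], function(s) {
    ft <- fitSaturating(s$times, s$radii)
    c(extractTstarRmax(ft), Y0 = ft$Y0)
  })
  r1 <- ext[[1]]$r_max - ext[[1]]$Y0; t1 <- ext[[1]]$t_star
  r2 <- ext[[2]]$r_max - ext[[2]]$Y0; t2 <- ext[[2]]$t_star
  d_closed <- (r2^2 / t2 - r1^2 / t1) /
    (4 * log((0.03 * 30 * t1) / (0.03 * 10 * t2)))
  expect_equal(unname(est$d_pairwise["10v30"]), d_closed, tolerance = 1e-8)
})

test_that("fixtures are seeded, lie on the analytic curve, and plateau correctly", {
  fx1 <- makeDoseFixtures(noise_sd = 0.1, seed = 9)
  fx2 <- makeDoseFixtures(noise_sd = 0.1, seed = 9)
  expect_identical(fx1, fx2)
  # noise-free radii match the analytic curve during the expansion phase
  fx <- makeDoseFixtures(noise_sd = 0)
  s <- fx[["dose_10"]]
  m <- injectionModel(u0 = 0.3)
  rising <- s$times < tStarMax(m)
  expect_equal(s$radii[rising], thresholdRadius(s$times[rising], m),
               tolerance = 1e-12)
  # plateau radius: 2 sqrt(D t*) + r0
  expect_equal(max(s$radii), 2 * sqrt(m$d * tStarMax(m)) + m$r0,
               tolerance = 1e-3)
})

test_that("dose series round-trip through CSV", {
  fx <- makeDoseFixtures(noise_sd = 0.05, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeDoseSeries(fx, tmp)
  back <- readDoseSeries(tmp)
  expect_equal(length(back), 3)
  expect_equal(back[["dose_10"]]$radii, fx[["dose_10"]]$radii)
  expect_equal(back[["dose_3"]]$times, fx[["dose_3"]]$times)
})
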