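#' Point-source intradermal injection model
#'
#' After a bolus intradermal injection, histamine dispersal is dominated by
#' diffusion from a point source; the wheal is visible where the
#' concentration exceeds a threshold \code{u_r}.  Default parameter values
#' are the fitted 10 ug/ml set (D in mm^2/min, radii in mm, u0 the scaled
#' dose, r0 the initial wheal radius).
#'
#' @param u0 initial (scaled) histamine amount, positive.
#' @param d diffusion coefficient in mm^2/min, positive.
#' @param u_r wheal threshold concentration, positive.
#' @param r0 initial wheal radius in mm, nonnegative.
#' @return An object of class \code{"injectionModel"}.
#' @export
injectionModel <- function(u0 = 0.3, d = 0.08474977, u_r = 0.003748,
                           r0 = 3.20875) {
  if (u0 <= 0 || d <= 0 || u_r <= 0 || r0 < 0)
    stop("injectionModel: u0, d, u_r must be positive and r0 >= 0")
  structure(list(u0 = u0, d = d, u_r = u_r, r0 = r0),
            class = "injectionModel")
}

#' @export
print.injectionModel <- function(x, ...) {
  cat(sprintf("Injection model: u0 = %g, D = %g mm^2/min, u_r = %g, r0 = %g mm\n",
              x$u0, x$d, x$u_r, x$r0))
  invisible(x)
}

#' Point-source diffusion solution
#'
#' \eqn{u(r,t) = \frac{u_0}{4 D \pi t} \exp(-r^2 / (4 D t))}, the plane
#' solution of the diffusion equation with a Dirac initial condition of mass
#' \code{u0}.
#'
#' @param r radial distance(s), mm.
#' @param t time(s) after injection, min; must be positive.
#' @param m an \code{\link{injectionModel}}.
#' @return Concentration value(s).
#' @export
gaussianSolution <- function(r, t, m) {
  stopifnot(inherits(m, "injectionModel"))
  if (any(t <= 0)) stop("gaussianSolution: t must be positive")
  m$u0 / (4 * m$d * pi * t) * exp(-r^2 / (4 * m$d * t))
}

#' Radius at which the diffusing histamine equals the wheal threshold
#'
#' \eqn{r^*(t) = \sqrt{4 D t \log(u_0 / (4\pi D u_r t))}}; with
#' \code{offset = TRUE} the initial wheal radius \code{r0} is added, giving
#' the evolving wheal radius curve.
#'
#' @param t time(s) after injection, min.
#' @param m an \code{\link{injectionModel}}.
#' @param offset add \code{r0}.
#' @return Radius in mm; \code{NA} where the threshold is nowhere reached
#'   (wheal absent at that time).
#' @export
thresholdRadius <- function(t, m, offset = TRUE) {
  stopifnot(inherits(m, "injectionModel"))
  if (any(t <= 0)) stop("thresholdRadius: t must be positive")
  radicand <- 4 * m$d * t * log(m$u0 / (4 * pi * m$d * m$u_r * t))
  r <- ifelse(radicand > 0, sqrt(pmax(radicand, 0)), NA_real_)
  if (offset) r <- r + m$r0
  r
}

#' Time of maximal threshold radius
#'
#' Closed form \eqn{t^* = u_0 / (4\pi D u_r e)}; at this time the log factor
#' equals 1 and the radius is \eqn{2\sqrt{D t^*} (+ r_0)}.
#'
#' @param m an \code{\link{injectionModel}}.
#' @return Time in min.
#' @export
tStarMax <- function(m) {
  stopifnot(inherits(m, "injectionModel"))
  m$u0 / (4 * pi * m$d * m$u_r * exp(1))
}

#' Radial expansion velocity of the injection wheal
#'
#' Analytic derivative of the wheal radius curve:
#' \eqn{dr^*/dt = 2D(\Lambda - 1)/\sqrt{4 D t \Lambda}} with
#' \eqn{\Lambda(t) = \log(u_0/(4\pi D u_r t))}.  Monotone decreasing over
#' the visible window and zero at the maximizer \eqn{t^*}.
#'
#' @param t time(s) after injection, min.
#' @param m an \code{\link{injectionModel}}.
#' @return Velocity in mm/min; \code{NA} outside the wheal-visible window.
#' @export
expansionVelocity <- function(t, m) {
  stopifnot(inherits(m, "injectionModel"))
  if (any(t <= 0)) stop("expansionVelocity: t must be positive")
  L <- log(m$u0 / (4 * pi * m$d * m$u_r * t))
  ifelse(L > 0, 2 * m$d * (L - 1) / sqrt(4 * m$d * t * L), NA_real_)
}

#' Mean expansion velocity over an initial window
#'
#' \eqn{(r^*(t_w) - r_0)/t_w}, the average expansion speed of the injection
#' wheal over the first \code{t_window} minutes.
#'
#' @param m an \code{\link{injectionModel}}.
#' @param t_window window length in min (default 15).
#' @return Mean velocity in mm/min.
#' @export
meanExpansionVelocity <- function(m, t_window = 15) {
  (thresholdRadius(t_window, m, offset = TRUE) - m$r0) / t_window
}

#' A dose-labelled wheal radius time series
#'
#' @param dose injected histamine concentration, ug/ml.
#' @param times observation times in min, strictly increasing.
#' @param radii wheal radii in mm, nonnegative.
#' @return An object of class \code{"doseSeries"}.
#' @export
doseSeries <- function(dose, times, radii) {
  if (length(times) != length(radii))
    stop("doseSeries: times and radii must have equal length")
  if (any(diff(times) <= 0)) stop("doseSeries: times must be strictly increasing")
  if (any(radii < 0)) stop("doseSeries: radii must be nonnegative")
  structure(list(dose = dose, times = times, radii = radii),
            class = "doseSeries")
}

#' Fit the saturating-exponential wheal growth curve
#'
#' Nonlinear least squares for \eqn{Y = Y_0 + (P - Y_0)(1 - e^{-\alpha t})}:
#' baseline radius \code{Y0}, plateau \code{P}, rate \code{alpha} per min.
#' Constant series return \code{P = Y0} with \code{alpha} flagged
#' unidentifiable.
#'
#' @param times observation times, min (>= 4 points).
#' @param radii radii, mm.
#' @return List with \code{Y0}, \code{P}, \code{alpha}, \code{resid_norm},
#'   \code{alpha_identifiable}.
#' @export
fitSaturating <- function(times, radii) {
  if (length(times) < 4) stop("fitSaturating: need at least 4 points")
  if (stats::sd(radii) < 1e-12) {
    return(list(Y0 = radii[1], P = radii[1], alpha = NA_real_,
                resid_norm = 0, alpha_identifiable = FALSE))
  }
  df <- data.frame(t = times, y = radii)
  start <- list(Y0 = radii[1], P = max(radii),
                alpha = 1 / max(stats::median(times), 1e-6))
  ft <- tryCatch(
    minpack.lm::nlsLM(y ~ Y0 + (P - Y0) * (1 - exp(-alpha * t)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("fitSaturating: nonlinear fit failed to converge (",
           conditionMessage(e), ")"))
  co <- stats::coef(ft)
  list(Y0 = unname(co["Y0"]), P = unname(co["P"]),
       alpha = unname(co["alpha"]),
       resid_norm = sqrt(sum(stats::residuals(ft)^2)),
       alpha_identifiable = TRUE)
}

#' Extract the expansion-stop time and maximal radius from a fitted curve
#'
#' The expansion is deemed stopped at the first time the fitted curve's
#' derivative \eqn{\alpha (P - Y_0) e^{-\alpha t}} drops to \code{epsilon}:
#' closed form \eqn{t^* = \log(\alpha(P - Y_0)/\epsilon)/\alpha}, clipped to
#' 0 (flagged) when the initial derivative is already below \code{epsilon}.
#' The maximal radius is the fitted curve at \eqn{t^*}.
#'
#' @param fit result of \code{\link{fitSaturating}}.
#' @param epsilon derivative threshold in mm/min (default 0.005, the pixel
#'   resolution of the imaging analysis).
#' @return List with \code{t_star} (min), \code{r_max} (mm),
#'   \code{boundary} (TRUE when clipped to 0).
#' @export
extractTstarRmax <- function(fit, epsilon = 0.005) {
  if (!isTRUE(fit$alpha_identifiable))
    stop("extractTstarRmax: alpha not identifiable (constant series)")
  a <- fit$alpha; gain <- fit$P - fit$Y0
  v0 <- a * gain
  if (v0 <= epsilon)
    return(list(t_star = 0, r_max = fit$Y0, boundary = TRUE))
  t_star <- log(v0 / epsilon) / a
  r_max <- fit$Y0 + gain * (1 - exp(-a * t_star))
  list(t_star = t_star, r_max = r_max, boundary = FALSE)
}

#' Estimate the histamine diffusion coefficient from multi-dose series
#'
#' For each dose the saturating fit gives the stop time \code{t*} and
#' maximal radius \code{r*max}; since the wheal threshold \code{u_r} is the
#' same at every dose, equating the point-source solution
#' \eqn{u_0/(4\pi D t^*)\, e^{-r^2/(4 D t^*)}} between two doses gives one
#' equation per dose pair, solved for \code{D} by a log-spaced bracket scan
#' followed by root-finding.  The dose enters as \code{u0 = u_nd * dose}.
#' By default each dose uses its own diffusion radius
#' \code{r = r*max - Y0} (the initial wheal size is not part of the
#' diffusion footprint); \code{shared_r = TRUE} instead uses the pair mean
#' radius in both exponentials.
#'
#' @param series_list list of \code{\link{doseSeries}} (typically doses 3,
#'   10, 30 ug/ml).
#' @param epsilon derivative threshold passed to
#'   \code{\link{extractTstarRmax}}.
#' @param u_nd concentration scale (ml/ug) mapping dose to \code{u0}.
#' @param shared_r use a single shared radius per pair.
#' @param bracket search interval for \code{D} in mm^2/min.
#' @return An object of class \code{"estimationResult"}: per-dose
#'   \code{t_star}, \code{r_max}, pairwise \code{d_pairwise}, and their mean
#'   \code{d_mean} (mm^2/min).
#' @export
estimateDiffusion <- function(series_list, epsilon = 0.005, u_nd = 0.03,
                              shared_r = FALSE, bracket = c(1e-4, 10)) {
  stopifnot(length(series_list) >= 2)
  doses <- vapply(series_list, function(s) s$dose, numeric(1))
  ext <- lapply(series_list, function(s) {
    ft <- fitSaturating(s$times, s$radii)
    c(extractTstarRmax(ft, epsilon), list(Y0 = ft$Y0))
  })
  t_star <- vapply(ext, function(e) e$t_star, numeric(1))
  r_max <- vapply(ext, function(e) e$r_max, numeric(1))
  r_diff <- vapply(ext, function(e) e$r_max - e$Y0, numeric(1))
  pairs <- utils::combn(seq_along(series_list), 2, simplify = FALSE)
  d_pair <- rep(NA_real_, length(pairs))
  names(d_pair) <- vapply(pairs, function(ij)
    paste0(doses[ij[1]], "v", doses[ij[2]]), character(1))
  for (k in seq_along(pairs)) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    if (doses[i] == doses[j]) {
      warning("estimateDiffusion: identical doses ", doses[i],
              " ug/ml; pair unidentifiable, skipped")
      next
    }
    ri <- r_diff[i]; rj <- r_diff[j]
    if (shared_r) ri <- rj <- (r_diff[i] + r_diff[j]) / 2
    f <- function(D)
      log(u_nd * doses[i] / t_star[i]) - ri^2 / (4 * D * t_star[i]) -
      log(u_nd * doses[j] / t_star[j]) + rj^2 / (4 * D * t_star[j])
    grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = 200))
    fv <- vapply(grid, f, numeric(1))
    sgn <- which(diff(sign(fv)) != 0)
    if (length(sgn) == 0) {
      warning("estimateDiffusion: no root in bracket for pair ",
              names(d_pair)[k], "; skipped")
      next
    }
    d_pair[k] <- stats::uniroot(f, c(grid[sgn[1]], grid[sgn[1] + 1]),
                                tol = 1e-12)$root
  }
  if (all(is.na(d_pair)))
    stop("estimateDiffusion: no dose pair yielded a diffusion estimate")
  structure(list(doses = doses, t_star = t_star, r_max = r_max,
                 d_pairwise = d_pair,
                 d_mean = mean(d_pair, na.rm = TRUE)),
            class = "estimationResult")
}

#' @export
print.estimationResult <- function(x, ...) {
  cat("Diffusion-coefficient estimation:\n")
  for (i in seq_along(x$doses))
    cat(sprintf("  %g ug/ml: t* = %.3g min, r*max = %.4g mm\n",
                x$doses[i], x$t_star[i], x$r_max[i]))
  cat("  pairwise D (mm^2/min):",
      paste(sprintf("%s = %.5g", names(x$d_pairwise), x$d_pairwise),
            collapse = ", "), "\n")
  cat(sprintf("  mean D = %.6g mm^2/min\n", x$d_mean))
  invisible(x)
}

#' Generate synthetic dose series from the analytic wheal radius curve
#'
#' Stands in for clinical injection time courses: radii follow the
#' threshold-radius curve during the expansion phase and hold their maximum
#' afterwards (the wheal persists once formed; the diffusion footprint
#' recedes but the skin does not recover within the observation window), and
#' Gaussian observation noise is added.  By default each dose is sampled on
#' its own window reaching past its plateau time (2.5 times the stop time
#' \code{\link{tStarMax}}), so the expansion-stop criterion falls inside the
#' observed data for every dose.  Seeded and fully reproducible.
#'
#' @param d_true generating diffusion coefficient, mm^2/min.
#' @param u_r wheal threshold.
#' @param doses doses in ug/ml.
#' @param u_nd concentration scale (ml/ug).
#' @param r0 initial wheal radius (mm), recycled across doses.
#' @param times sampling times in min; \code{NULL} (default) for the
#'   per-dose adaptive grid, or a fixed vector applied to every dose.
#' @param n_times points per series when \code{times} is \code{NULL}.
#' @param noise_sd Gaussian noise standard deviation in mm.
#' @param seed RNG seed.
#' @return Named list of \code{\link{doseSeries}}, one per dose.
#' @export
makeDoseFixtures <- function(d_true = 0.08474977, u_r = 0.003748,
                             doses = c(3, 10, 30), u_nd = 0.03,
                             r0 = 3.20875, times = NULL, n_times = 40,
                             noise_sd = 0, seed = 1L) {
  r0 <- rep_len(r0, length(doses))
  out <- withSeed(seed, {
    lapply(seq_along(doses), function(i) {
      m <- injectionModel(u0 = u_nd * doses[i], d = d_true, u_r = u_r,
                          r0 = r0[i])
      tt <- if (is.null(times))
        seq(0.5, 2.5 * tStarMax(m), length.out = n_times) else times
      radicand <- 4 * m$d * tt * log(m$u0 / (4 * pi * m$d * m$u_r * tt))
      if (all(radicand <= 0))
        stop("makeDoseFixtures: threshold never reached for dose ", doses[i])
      rw <- cummax(ifelse(radicand > 0, sqrt(pmax(radicand, 0)), 0)) + m$r0
      radii <- pmax(0, rw + stats::rnorm(length(tt), 0, noise_sd))
      doseSeries(doses[i], tt, radii)
    })
  })
  names(out) <- paste0("dose_", doses)
  out
}

#' Read or write dose series as CSV
#'
#' Plain-text interchange with columns \code{dose_ug_per_ml},
#' \code{time_min}, \code{radius_mm}.
#'
#' @param series_list named list of \code{\link{doseSeries}}.
#' @param path CSV file path.
#' @return \code{writeDoseSeries}: \code{path} invisibly;
#'   \code{readDoseSeries}: a list of \code{doseSeries}.
#' @export
writeDoseSeries <- function(series_list, path) {
  df <- do.call(rbind, lapply(series_list, function(s)
    data.frame(dose_ug_per_ml = s$dose, time_min = s$times,
               radius_mm = s$radii)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDoseSeries
#' @export
readDoseSeries <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dose_ug_per_ml", "time_min", "radius_mm")
  if (!all(need %in% names(df)))
    stop("readDoseSeries: file must have columns ",
         paste(need, collapse = ", "))
  out <- lapply(split(df, df$dose_ug_per_ml), function(d)
    doseSeries(d$dose_ug_per_ml[1], d$time_min, d$radius_mm))
  names(out) <- paste0("dose_", vapply(out, function(s) s$dose, numeric(1)))
  out[order(vapply(out, function(s) s$dose, numeric(1)))]
}
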