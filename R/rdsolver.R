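#' Solver configuration
#'
#' Explicit Euler with a 5-point Laplacian on the unit square (zero-flux
#' boundaries via mirrored ghost cells), or an axisymmetric finite-volume
#' reduction on \code{r} in \code{[0, domain_radius]} when
#' \code{radial_mode = TRUE}.  When \code{dt} is \code{NULL} it is chosen as
#' 40\% of the diffusive stability limit at run time.
#'
#' @param grid_n cells per edge (2-D) or radial points (radial mode).
#' @param t_end final dimensionless time.
#' @param dt time step; \code{NULL} for automatic.
#' @param snapshot_interval time between stored snapshots (defaults to
#'   \code{t_end/50}).
#' @param radial_mode logical; use the 1-D axisymmetric reduction.
#' @param domain_radius outer radius in radial mode (default 0.5, half the
#'   unit domain edge).
#' @return An object of class \code{"solverConfig"}.
#' @export
solverConfig <- function(grid_n = 512, t_end = 50, dt = NULL,
                         snapshot_interval = NULL, radial_mode = FALSE,
                         domain_radius = 0.5) {
  if (grid_n < 4) stop("solverConfig: grid_n must be >= 4")
  if (t_end < 0) stop("solverConfig: t_end must be >= 0")
  if (!is.null(dt) && dt <= 0) stop("solverConfig: dt must be positive")
  if (is.null(snapshot_interval)) snapshot_interval <- max(t_end / 50, 1e-12)
  structure(list(grid_n = as.integer(grid_n), t_end = t_end, dt = dt,
                 snapshot_interval = snapshot_interval,
                 radial_mode = isTRUE(radial_mode),
                 domain_radius = domain_radius),
            class = "solverConfig")
}

#' Wheal readout parameters
#'
#' The visible wheal is a hysteretic sigmoid readout of histamine:
#' \eqn{H(u) = 1/(1 + e^{-\beta(u - u_r)})} with a shallower slope
#' (\code{beta_rise}) while histamine is rising than while it is falling
#' (\code{beta_fall}), reflecting that skin recovers more slowly than the
#' wheal appears.
#'
#' @param u_r wheal threshold concentration (dimensionless), positive.
#' @param beta_rise sigmoid steepness while u is increasing.
#' @param beta_fall steepness while u is decreasing; must exceed
#'   \code{beta_rise}.
#' @return An object of class \code{"whealParams"}.
#' @export
whealParams <- function(u_r = 0.4, beta_rise = 30, beta_fall = 150) {
  if (u_r <= 0) stop("whealParams: u_r must be positive")
  if (!(beta_rise < beta_fall))
    stop("whealParams: beta_rise must be smaller than beta_fall")
  structure(list(u_r = u_r, beta_rise = beta_rise, beta_fall = beta_fall),
            class = "whealParams")
}

#' Hysteretic wheal state function
#'
#' @param u histamine concentration(s).
#' @param direction \code{"rising"}/\code{"falling"} (or +1/-1), recycled
#'   against \code{u}.
#' @param wp a \code{\link{whealParams}} object.
#' @return Values in (0, 1); 0.5 exactly at \code{u = u_r}.
#' @export
whealState <- function(u, direction, wp = whealParams()) {
  stopifnot(inherits(wp, "whealParams"))
  if (is.character(direction))
    direction <- ifelse(direction == "rising", 1, -1)
  beta <- ifelse(direction >= 0, wp$beta_rise, wp$beta_fall)
  1 / (1 + exp(-beta * (u - wp$u_r)))
}

# resolve dt + stability checks; mode-aware diffusive limit
.resolveDt <- function(p, cfg) {
  h <- if (cfg$radial_mode) cfg$domain_radius / cfg$grid_n else 1 / cfg$grid_n
  ndim <- if (cfg$radial_mode) 2 else 4
  cfl <- h^2 / (ndim * p$d_u)
  rate_guard <- p$gamma + p$alpha0 + if (p$alpha2 > 0) p$alpha2 / p$alpha1 else 0
  dt <- cfg$dt
  if (is.null(dt))
    dt <- min(0.4 * cfl, if (rate_guard > 0) 0.05 / rate_guard else Inf)
  if (dt > cfl)
    stop("solver configuration error: dt = ", dt, " violates the diffusive ",
         "stability limit h^2/(", ndim, " D) = ", signif(cfl, 4))
  # accuracy guard on the kinetic rates
  rate_scale <- rate_guard
  if (dt * rate_scale > 0.1)
    warning("dt * max kinetic rate = ", signif(dt * rate_scale, 3),
            " > 0.1; results may be inaccurate")
  list(dt = dt, h = h)
}

# normalise a state argument (field or simulationState) into full state pieces
.asState <- function(init, cfg) {
  if (inherits(init, "simulationState")) return(init)
  if (cfg$radial_mode) {
    stopifnot(is.numeric(init), length(init) == cfg$grid_n)
    z <- rep(0, length(init)); o <- rep(1, length(init))
  } else {
    stopifnot(is.matrix(init), nrow(init) == cfg$grid_n,
              ncol(init) == cfg$grid_n)
    z <- matrix(0, nrow(init), ncol(init))
    o <- matrix(1, nrow(init), ncol(init))
  }
  structure(list(u = init, cum_release = z, chi = o, direction = o, t = 0),
            class = "simulationState")
}

#' Advance the simulation state by one (or more) explicit steps
#'
#' One step: the field is advanced by the 5-point Laplacian plus the reaction
#' term, the cumulative release is accumulated by the rectangle rule where the
#' store lasts, the depletion switch is turned off (permanently) where the
#' cumulative release exceeds \code{u_tot}, and the per-cell rising/falling
#' memory is updated from the sign of the change in \code{u}.
#'
#' @param state a \code{"simulationState"} (or a bare field, promoted with
#'   zero cumulative release and all stores intact).
#' @param p a \code{\link{kineticParams}} object.
#' @param cfg a \code{\link{solverConfig}}.
#' @param nsteps number of steps to take.
#' @return The advanced \code{"simulationState"}.
#' @export
rdStep <- function(state, p, cfg, nsteps = 1L) {
  stopifnot(inherits(p, "kineticParams"))
  state <- .asState(state, cfg)
  rs <- .resolveDt(p, cfg)
  core <- if (cfg$radial_mode) rd_core_radial else rd_core_2d
  out <- core(state$u, state$cum_release, state$chi, state$direction,
              p$gamma, p$alpha1, p$alpha2, p$alpha0, p$mu,
              p$d_u, p$u_tot, rs$h, rs$dt, as.integer(nsteps), 0L)
  structure(list(u = out$u_final, cum_release = out$U_final,
                 chi = out$chi_final, direction = out$dir_final,
                 t = state$t + nsteps * rs$dt),
            class = "simulationState")
}

#' Run a full simulation and collect snapshots
#'
#' Integrates the histamine equation from an initial condition built from a
#' \code{\link{stimulusSpec}} (around the minimal positive equilibrium of
#' \code{p}) or supplied directly as a field/state.  Returns the trajectory
#' of snapshots at \code{snapshot_interval} spacing; results are
#' deterministic given the stimulus seed.
#'
#' @param p a \code{\link{kineticParams}} object.
#' @param init a \code{\link{stimulusSpec}}, a numeric field (matrix, or
#'   vector in radial mode), or a \code{"simulationState"}.
#' @param wp a \code{\link{whealParams}} object (stored for downstream wheal
#'   masks).
#' @param cfg a \code{\link{solverConfig}}.
#' @return An object of class \code{"rdTrajectory"}: lists \code{u},
#'   \code{cum_release}, \code{chi}, \code{direction} indexed by snapshot
#'   (the initial state is snapshot 1 at time 0), \code{times}, the grid
#'   spacing \code{h}, and the configuration objects.
#' @export
rdRun <- function(p, init, wp = whealParams(), cfg = solverConfig()) {
  stopifnot(inherits(p, "kineticParams"))
  seed <- NA_integer_
  if (inherits(init, "stimulusSpec")) {
    seed <- init$seed
    u0 <- equilibria(p)$u0_star
    if (is.na(u0)) u0 <- 0
    if (cfg$radial_mode) {
      # radial mode has no random field; use the deterministic radial profile
      # u0* + r * exp(-(r/w)^2) with w = 1/50 of the domain radius
      rc <- (seq_len(cfg$grid_n) - 0.5) * (cfg$domain_radius / cfg$grid_n)
      init <- u0 + init$r * exp(-(rc / (cfg$domain_radius / 25))^2)
    } else {
      init <- initialCondition(u0, init, cfg$grid_n)
    }
  }
  state <- .asState(init, cfg)
  rs <- .resolveDt(p, cfg)
  nsteps <- as.integer(round(cfg$t_end / rs$dt))
  snap_every <- max(1L, as.integer(round(cfg$snapshot_interval / rs$dt)))
  if (nsteps == 0L) {
    out <- list(times = numeric(0), u = list(), U = list(), chi = list(),
                dir = list())
  } else {
    core <- if (cfg$radial_mode) rd_core_radial else rd_core_2d
    out <- core(state$u, state$cum_release, state$chi, state$direction,
                p$gamma, p$alpha1, p$alpha2, p$alpha0, p$mu,
                p$d_u, p$u_tot, rs$h, rs$dt, nsteps, snap_every)
  }
  structure(list(times = c(0, out$times),
                 u = c(list(state$u), out$u),
                 cum_release = c(list(state$cum_release), out$U),
                 chi = c(list(state$chi), out$chi),
                 direction = c(list(state$direction), out$dir),
                 h = rs$h, dt = rs$dt, params = p, wheal = wp, config = cfg,
                 seed = seed),
            class = "rdTrajectory")
}

#' @export
print.rdTrajectory <- function(x, ...) {
  mode <- if (x$config$radial_mode) "radial" else "2-D"
  cat(sprintf("%s trajectory: %d snapshots, t in [0, %g], grid %d (h = %g)\n",
              mode, length(x$times), max(x$times), x$config$grid_n, x$h))
  invisible(x)
}

#' Binary wheal mask of a snapshot
#'
#' \code{H(u) >= 0.5} with the hysteretic sigmoid of \code{\link{whealState}}.
#'
#' @param traj an \code{"rdTrajectory"}.
#' @param i snapshot index (default: last).
#' @param wp wheal parameters (default: those stored in the trajectory).
#' @return Logical matrix (or vector in radial mode).
#' @export
whealMask <- function(traj, i = length(traj$times), wp = traj$wheal) {
  H <- whealState(traj$u[[i]], traj$direction[[i]], wp)
  H >= 0.5
}

#' Track the expanding wheal front and fit its speed
#'
#' For each snapshot the radius of the outermost crossing of \code{u = u_r}
#' is measured: in radial mode directly on the profile (linear
#' interpolation); in 2-D as the angular mean over \code{n_rays} rays from
#' \code{center} (bilinear sampling at half-cell steps).  The constant
#' expansion speed is the least-squares slope over the longest time window in
#' which the linear fit's residuals stay below 5\% of the radius range.
#'
#' @param traj an \code{"rdTrajectory"}.
#' @param u_r threshold concentration (default: the trajectory's wheal
#'   threshold).
#' @param center front origin in domain coordinates (2-D only).
#' @param n_rays number of rays (2-D only, >= 32 recommended).
#' @return An object of class \code{"frontTrace"}: data frame fields
#'   \code{times}, \code{radii}, \code{radius_sd}, plus \code{speed},
#'   \code{speed_window} (index range of the fitted window) and
#'   \code{status} (\code{"ok"} or \code{"empty"} when no crossing is ever
#'   found).
#' @export
trackFront <- function(traj, u_r = traj$wheal$u_r, center = c(0.5, 0.5),
                       n_rays = 32) {
  stopifnot(inherits(traj, "rdTrajectory"))
  radial <- traj$config$radial_mode
  nt <- length(traj$times)
  radii <- rep(NA_real_, nt); rsd <- rep(NA_real_, nt)
  if (radial) {
    rc <- (seq_len(traj$config$grid_n) - 0.5) * traj$h
    for (i in seq_len(nt)) {
      radii[i] <- .outermostCrossing(rc, traj$u[[i]], u_r)
      rsd[i] <- 0
    }
  } else {
    ang <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
    rmax <- min(center, 1 - center)
    rs <- seq(0, rmax, by = traj$h / 2)
    for (i in seq_len(nt)) {
      u <- traj$u[[i]]
      per_ray <- vapply(ang, function(a) {
        prof <- .bilinear(u, traj$h,
                          center[1] + rs * cos(a), center[2] + rs * sin(a))
        .outermostCrossing(rs, prof, u_r)
      }, numeric(1))
      if (all(is.na(per_ray))) next
      radii[i] <- mean(per_ray, na.rm = TRUE)
      rsd[i] <- stats::sd(per_ray, na.rm = TRUE)
    }
  }
  res <- list(times = traj$times, radii = radii, radius_sd = rsd,
              speed = NA_real_, speed_window = c(NA_integer_, NA_integer_),
              status = if (all(is.na(radii))) "empty" else "ok")
  if (res$status == "ok") {
    fit <- .fitConstantSpeed(traj$times, radii)
    res$speed <- fit$speed
    res$speed_window <- fit$window
  }
  structure(res, class = "frontTrace")
}

#' @export
print.frontTrace <- function(x, ...) {
  if (x$status == "empty") {
    cat("Front trace: no threshold crossing found\n")
  } else {
    cat(sprintf("Front trace: %d snapshots, fitted speed %.4g per unit time over window [%d, %d]\n",
                length(x$times), x$speed, x$speed_window[1], x$speed_window[2]))
  }
  invisible(x)
}

# outermost x where y crosses thr downward, linearly interpolated; NA if y < thr
# everywhere, and the largest x if y >= thr out to the edge
.outermostCrossing <- function(x, y, thr) {
  ok <- !is.na(y)
  above <- which(ok & y >= thr)
  if (length(above) == 0) return(NA_real_)
  i <- max(above)
  if (i == length(y) || is.na(y[i + 1])) return(x[i])
  f <- (y[i] - thr) / (y[i] - y[i + 1])
  x[i] + f * (x[i + 1] - x[i])
}

# bilinear interpolation of a cell-centered field at points (px, py) in [0,1]
.bilinear <- function(u, h, px, py) {
  n <- nrow(u)
  gx <- px / h + 0.5; gy <- py / h + 0.5
  gx <- pmin(pmax(gx, 1), n); gy <- pmin(pmax(gy, 1), n)
  i0 <- pmin(floor(gx), n - 1); j0 <- pmin(floor(gy), n - 1)
  fx <- gx - i0; fy <- gy - j0
  u[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    u[cbind(i0 + 1, j0)] * fx * (1 - fy) +
    u[cbind(i0, j0 + 1)] * (1 - fx) * fy +
    u[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# longest contiguous window with linear-fit residuals < 5% of the radius range
.fitConstantSpeed <- function(times, radii, min_len = 5, rel_tol = 0.05) {
  ok <- which(!is.na(radii))
  if (length(ok) < 2)
    return(list(speed = NA_real_, window = c(NA_integer_, NA_integer_)))
  # work on the longest contiguous run of valid radii
  runs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  ok <- runs[[which.max(lengths(runs))]]
  t <- times[ok]; r <- radii[ok]; n <- length(ok)
  if (n < 2)
    return(list(speed = NA_real_, window = c(NA_integer_, NA_integer_)))
  if (diff(range(r)) < 1e-14)  # stationary front
    return(list(speed = 0, window = c(ok[1], ok[n])))
  min_len <- min(max(2, min_len), n)
  best <- NULL
  for (len in seq(n, min_len)) {
    for (s in seq_len(n - len + 1)) {
      idx <- s:(s + len - 1)
      ft <- stats::lm.fit(cbind(1, t[idx]), r[idx])
      rng <- diff(range(r[idx]))
      if (rng < 1e-14 || max(abs(ft$residuals)) < rel_tol * rng) {
        best <- list(speed = unname(ft$coefficients[2]),
                     window = c(ok[s], ok[s + len - 1]))
        break
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) {
    # fall back to the overall slope if no window satisfies the criterion
    ft <- stats::lm.fit(cbind(1, t), r)
    best <- list(speed = unname(ft$coefficients[2]), window = c(ok[1], ok[n]))
  }
  best
}

#' Write a front trace to CSV
#'
#' Columns \code{time}, \code{radius}, \code{radius_sd}.
#'
#' @param trace a \code{"frontTrace"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFrontTrace <- function(trace, path) {
  utils::write.csv(data.frame(time = trace$times, radius = trace$radii,
                              radius_sd = trace$radius_sd),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a wheal mask as a PNG image
#'
#' White pixels mark the wheal.
#'
#' @param mask logical matrix.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeWhealMask <- function(mask, path) {
  png::writePNG(t(matrix(as.numeric(mask), nrow(mask), ncol(mask))[, ncol(mask):1]),
                path)
  invisible(path)
}

#' Save a trajectory to disk
#'
#' The trajectory is stored as an RDS file plus, optionally, one CSV per
#' snapshot of the histamine field; the resolved configuration and seed are
#' stored inside the object.
#'
#' @param traj an \code{"rdTrajectory"}.
#' @param dir output directory (created if needed).
#' @param csv_snapshots also write plain-text snapshot matrices.
#' @return \code{dir}, invisibly.
#' @export
writeTrajectory <- function(traj, dir, csv_snapshots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(traj, file.path(dir, "trajectory.rds"))
  if (csv_snapshots) {
    for (i in seq_along(traj$times)) {
      utils::write.table(traj$u[[i]],
                         file.path(dir, sprintf("u_%04d.csv", i)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
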