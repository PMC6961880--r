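# Shared fixtures and independent oracles for the test suite.

repKinetics <- function(...) kineticParams(...)

# Brute-force equilibrium oracle: sign-scan of the reaction rate on (0, u_max]
# followed by bisection at every sign change.  Independent of equilibria().
scanRoots <- function(p, chi = 1, u_max = 5, step = 1e-3) {
  u <- seq(step, u_max, by = step)
  r <- reactionRate(u, p, chi)
  flips <- which(r[-1] * r[-length(r)] < 0)
  roots <- vapply(flips, function(i) {
    lo <- u[i]; hi <- u[i + 1]
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (reactionRate(mid, p, chi) * reactionRate(lo, p, chi) <= 0) hi <- mid
      else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  # include exact zeros at grid points
  sort(unique(c(roots, u[r == 0])))
}

# Independent single-step reference for the 2-D scheme: naive double loop
# with mirrored ghost cells, same update ordering as the solver.
refStep2d <- function(u, U, chi, p, h, dt) {
  n <- nrow(u)
  un <- u
  for (j in 1:n) for (i in 1:n) {
    ul <- if (i > 1) u[i - 1, j] else u[i, j]
    ur <- if (i < n) u[i + 1, j] else u[i, j]
    ud <- if (j > 1) u[i, j - 1] else u[i, j]
    uu <- if (j < n) u[i, j + 1] else u[i, j]
    lap <- p$d_u * (ul + ur + ud + uu - 4 * u[i, j]) / h^2
    rate <- chi[i, j] * p$gamma * u[i, j] + p$mu - p$alpha0 * u[i, j] -
      (if (p$alpha2 == 0) 0 else p$alpha2 * u[i, j] / (p$alpha1 + u[i, j]^2))
    if (chi[i, j] == 1) {
      U[i, j] <- U[i, j] + p$gamma * u[i, j] * dt
      if (U[i, j] > p$u_tot) chi[i, j] <- 0
    }
    un[i, j] <- u[i, j] + dt * (lap + rate)
  }
  list(u = un, U = U, chi = chi)
}

# Draw a filled disk on a logical matrix (n x n), center and radius in cells.
diskMask <- function(n, cx, cy, rad) {
  x <- matrix(seq_len(n), n, n)
  y <- t(x)
  (x - cx)^2 + (y - cy)^2 <= rad^2
}

# Annulus: outer radius r_out, inner radius r_in (cells).
annulusMask <- function(n, cx, cy, r_out, r_in) {
  diskMask(n, cx, cy, r_out) & !diskMask(n, cx, cy, r_in)
}

# Arc fragment: annulus restricted to an angular sector (degrees).
arcMask <- function(n, cx, cy, r_out, r_in, a_from, a_to) {
  x <- matrix(seq_len(n), n, n) - cx
  y <- t(matrix(seq_len(n), n, n)) - cy
  ang <- (atan2(y, x) * 180 / pi) %% 360
  annulusMask(n, cx, cy, r_out, r_in) & ang >= a_from & ang <= a_to
}

# A small radial solver config for fast front experiments.
radialCfg <- function(grid_n = 512, t_end = 40, dt = 2e-3, snap = 2)
  solverConfig(grid_n = grid_n, t_end = t_end, dt = dt,
               snapshot_interval = snap, radial_mode = TRUE)

# Deterministic central bump initial condition for radial runs.
radialBump <- function(p, cfg, amp = 0.6, w = 0.02) {
  u0 <- equilibria(p)$u0_star
  if (is.na(u0)) u0 <- 0
  rc <- (seq_len(cfg$grid_n) - 0.5) * (cfg$domain_radius / cfg$grid_n)
  u0 + amp * exp(-(rc / w)^2)
}
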