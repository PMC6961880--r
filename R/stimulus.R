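#' Stimulus specification for the initial histamine field
#'
#' The initial condition is a perturbation of the minimal homogeneous steady
#' state: \eqn{u(x,0) = u_0^* + r(\phi(x) + s\psi(x))/(1+s)}, where \eqn{\phi}
#' is an i.i.d. uniform [0,1] random field (one draw per grid cell, seeded) and
#' \eqn{\psi} is a cosine weight field selecting large-scale structure.
#'
#' @param r perturbation magnitude (maximal stimulus size, concentration
#'   units), nonnegative.
#' @param s weight strength, nonnegative; \code{s = 0} gives a purely random
#'   stimulus, large \code{s} a deterministic \eqn{\psi}-shaped one.
#' @param n,m nonnegative integer mode numbers of the weight field.
#' @param seed RNG seed for \eqn{\phi}; mandatory so stored runs are
#'   reproducible.
#' @return An object of class \code{"stimulusSpec"}.
#' @export
stimulusSpec <- function(r, s = 0, n = 0, m = 0, seed = 1L) {
  if (r < 0 || s < 0) stop("stimulusSpec: r and s must be >= 0")
  if (n < 0 || m < 0 || n != round(n) || m != round(m))
    stop("stimulusSpec: n and m must be nonnegative integers")
  structure(list(r = r, s = s, n = as.integer(n), m = as.integer(m),
                 seed = as.integer(seed)),
            class = "stimulusSpec")
}

#' Cosine weight function psi at arbitrary points
#'
#' \eqn{\psi(x,y) = (\cos(n\pi x/L)\cos(m\pi y/L) + 1)/2}, valued in [0,1].
#'
#' @param x,y coordinates in [0, L].
#' @param n,m integer mode numbers.
#' @param L domain edge length.
#' @return Numeric values in [0,1].
#' @export
psiWeight <- function(x, y, n, m, L = 1) {
  (cos(n * pi * x / L) * cos(m * pi * y / L) + 1) / 2
}

#' Evaluate the weight field on a simulation grid
#'
#' @param n,m integer mode numbers.
#' @param grid_n number of cells per edge.
#' @param L domain edge length.
#' @return A \code{grid_n} x \code{grid_n} matrix (cell centers), values in
#'   [0,1]; rows index x, columns y.
#' @export
weightField <- function(n, m, grid_n, L = 1) {
  h <- L / grid_n
  xc <- (seq_len(grid_n) - 0.5) * h
  outer(xc, xc, function(x, y) psiWeight(x, y, n, m, L))
}

#' Build the initial histamine field
#'
#' @param u0_star the minimal positive homogeneous equilibrium (from
#'   \code{\link{equilibria}}).
#' @param spec a \code{\link{stimulusSpec}}.
#' @param grid_n cells per edge.
#' @param L domain edge length.
#' @return Matrix of initial concentrations, bounded in
#'   \code{[u0_star, u0_star + r]}.  The same seed and spec give a
#'   bit-identical field; the random component has one draw per grid cell, so
#'   the field is resolution-dependent by construction.
#' @export
initialCondition <- function(u0_star, spec, grid_n, L = 1) {
  stopifnot(inherits(spec, "stimulusSpec"))
  phi <- withSeed(spec$seed, matrix(stats::runif(grid_n * grid_n),
                                    grid_n, grid_n))
  psi <- weightField(spec$n, spec$m, grid_n, L)
  u0_star + spec$r * (phi + spec$s * psi) / (1 + spec$s)
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Stimulus strength as a percentage
#'
#' \eqn{P_r = 100\, r / c_{max}}, the perturbation magnitude relative to a
#' reference maximal histamine concentration.
#'
#' @param r perturbation magnitude.
#' @param c_max reference concentration (default 1 in dimensionless units).
#' @return Percentage.
#' @export
stimulusStrength <- function(r, c_max = 1) {
  if (c_max <= 0) stop("stimulusStrength: c_max must be positive")
  100 * r / c_max
}

#' Minimal developing stimulus strength P_min
#'
#' Bisects the perturbation magnitude \code{r} for the smallest stimulus at
#' which a wheal develops, at a fixed random seed.  "Develops" means the
#' spatial maximum of \code{u} exceeds the wheal threshold \code{u_r} at some
#' time after a burn-in period \code{t_burn} (the burn-in discards the initial
#' transient, whose peaks can exceed \code{u_r} pointwise without triggering
#' anything).
#'
#' @param p a \code{\link{kineticParams}} object.
#' @param spec a \code{\link{stimulusSpec}} template; its \code{r} is ignored
#'   and replaced by the bisection iterate.
#' @param wp a \code{\link{whealParams}} object supplying \code{u_r}.
#' @param cfg a \code{\link{solverConfig}} used for the trial simulations.
#' @param r_hi upper bracket for \code{r}.
#' @param tol_rel relative bisection tolerance on \code{r}.
#' @param t_burn burn-in time excluded from the "develops" criterion.
#' @param c_max reference concentration for the percentage scale.
#' @return An object of class \code{"pMinResult"}: list with \code{status}
#'   (\code{"ok"}, \code{"never_develops"} when \eqn{\gamma - \alpha_0 < 0},
#'   or \code{"bracket_failure"}), \code{p_min} (percent, \code{NA} unless
#'   ok), \code{r_min}, \code{seed} and \code{grid_n}.
#' @export
findPMin <- function(p, spec, wp = whealParams(), cfg = solverConfig(grid_n = 64, t_end = 60),
                     r_hi = 1, tol_rel = 0.01, t_burn = 1, c_max = 1) {
  stopifnot(inherits(p, "kineticParams"), inherits(spec, "stimulusSpec"),
            inherits(wp, "whealParams"))
  res <- list(p_min = NA_real_, r_min = NA_real_, status = "ok",
              seed = spec$seed, grid_n = cfg$grid_n)
  class(res) <- "pMinResult"
  if (noPatternCondition(p)) {
    res$status <- "never_develops"
    return(res)
  }
  u0 <- equilibria(p)$u0_star
  if (is.na(u0)) u0 <- 0
  develops <- function(r) {
    sp <- spec; sp$r <- r
    traj <- rdRun(p, sp, wp, cfg)
    keep <- traj$times > t_burn
    if (!any(keep)) return(FALSE)
    any(vapply(traj$u[keep], max, numeric(1)) > wp$u_r)
  }
  if (!develops(r_hi)) {
    res$status <- "bracket_failure"
    return(res)
  }
  lo <- 0; hi <- r_hi
  for (it in 1:60) {
    # stop on relative width, or when hi has collapsed to ~0 (P_min ~ 0)
    if ((hi - lo) <= tol_rel * hi || hi <= 1e-6 * r_hi) break
    mid <- (lo + hi) / 2
    if (develops(mid)) hi <- mid else lo <- mid
  }
  res$r_min <- hi
  res$p_min <- stimulusStrength(hi, c_max)
  res
}

#' @export
print.pMinResult <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("P_min = %.4g%% (r_min = %.6g; seed %d, grid %d)\n",
                x$p_min, x$r_min, x$seed, x$grid_n))
  else
    cat(sprintf("P_min: %s\n", gsub("_", " ", x$status)))
  invisible(x)
}
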