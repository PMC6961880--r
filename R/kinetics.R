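#' Kinetic parameters of the histamine reaction-diffusion model
#'
#' Bundles the dimensionless rate constants of the single-species histamine
#' model: self-activation at rate \code{gamma} gated by the finite mast-cell
#' store \code{u_tot}, dose-dependent self-inhibition
#' \eqn{\alpha_2 u / (\alpha_1 + u^2)}, basal secretion \code{mu}, basal decay
#' \code{alpha0}, and the diffusion coefficient \code{d_u}.  Defaults are the
#' representative "Set I" dimensionless values (domain edge 27.4 cm, time unit
#' 250 s).
#'
#' @param gamma histamine release (self-activation) rate, per unit time.
#' @param alpha0 basal decay rate of histamine.
#' @param alpha1 concentration at which the inhibition effect peaks; must be
#'   positive whenever \code{alpha2 > 0}.
#' @param alpha2 maximal level of the self-inhibition effect.
#' @param mu basal secretion rate of histamine.
#' @param u_tot total histamine store per mast cell (time-integrated release
#'   capacity, dimensionless).
#' @param d_u dimensionless diffusion coefficient of histamine.
#' @return An object of class \code{"kineticParams"}.
#' @examples
#' p <- kineticParams()                    # Set I
#' p5 <- kineticParams(alpha2 = 5.0)       # stronger inhibition
#' @export
kineticParams <- function(gamma = 4.0, alpha0 = 0.7, alpha1 = 0.4,
                          alpha2 = 4.5, mu = 1.5, u_tot = 150,
                          d_u = 4.7e-6) {
  p <- list(gamma = gamma, alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
            mu = mu, u_tot = u_tot, d_u = d_u)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("kineticParams: '", nm, "' must be a single nonnegative number")
  }
  if (alpha2 > 0 && alpha1 <= 0)
    stop("kineticParams: alpha1 must be > 0 when alpha2 > 0 ",
         "(inhibition term must be finite at u = 0)")
  structure(p, class = "kineticParams")
}

#' @export
print.kineticParams <- function(x, ...) {
  cat("Histamine kinetics (dimensionless):\n")
  cat(sprintf("  gamma = %g, alpha0 = %g, alpha1 = %g, alpha2 = %g, mu = %g\n",
              x$gamma, x$alpha0, x$alpha1, x$alpha2, x$mu))
  cat(sprintf("  store u_tot = %g, diffusion d_u = %g\n", x$u_tot, x$d_u))
  invisible(x)
}

#' Space-free reaction rate of the histamine kinetics
#'
#' Evaluates \eqn{\chi \gamma u - \alpha_2 u/(\alpha_1 + u^2) + \mu - \alpha_0 u},
#' the local rate of change of histamine concentration in the absence of
#' diffusion.  \code{chi} is the store-depletion switch: 1 while the mast cell
#' still holds releasable histamine, 0 after exhaustion.
#'
#' @param u histamine concentration(s), nonnegative.
#' @param p a \code{\link{kineticParams}} object.
#' @param chi depletion switch, 0 or 1 (scalar or vector recycled against
#'   \code{u}).
#' @return Numeric vector of rates, same length as \code{u}.
#' @export
reactionRate <- function(u, p, chi = 1) {
  stopifnot(inherits(p, "kineticParams"))
  if (any(!is.finite(u)) || any(u < 0))
    stop("reactionRate: u must be finite and nonnegative")
  if (any(!chi %in% c(0, 1)))
    stop("reactionRate: chi must be 0 or 1")
  inhib <- if (p$alpha2 == 0) 0 else p$alpha2 * u / (p$alpha1 + u^2)
  chi * p$gamma * u - inhib + p$mu - p$alpha0 * u
}

#' Derivative of the space-free reaction rate
#'
#' Analytic \eqn{dR/du} used for linear stability of spatially uniform
#' equilibria.
#'
#' @inheritParams reactionRate
#' @return Numeric vector.
#' @export
reactionRateDeriv <- function(u, p, chi = 1) {
  stopifnot(inherits(p, "kineticParams"))
  dinhib <- if (p$alpha2 == 0) 0 else
    p$alpha2 * (p$alpha1 - u^2) / (p$alpha1 + u^2)^2
  chi * p$gamma - p$alpha0 - dinhib
}

#' Spatially uniform equilibria and their stability
#'
#' Finds all nonnegative real roots of the space-free kinetics
#' \code{reactionRate(u, p, chi) = 0}.  With \code{chi = 1} these are the roots
#' of the cubic
#' \eqn{(\gamma-\alpha_0)u^3 + \mu u^2 + ((\gamma-\alpha_0)\alpha_1 - \alpha_2)u
#' + \mu\alpha_1 = 0}; with \code{chi = 0} (store exhausted) the reduced
#' kinetics \eqn{-\alpha_2 u/(\alpha_1+u^2) + \mu - \alpha_0 u} are used.
#' Roots come from the polynomial companion matrix (\code{\link{polyroot}})
#' filtered to real nonnegative values (imaginary-part tolerance 1e-9), then
#' polished by one Newton step; degenerate linear kinetics
#' (\code{alpha2 == 0}) are solved in closed form.  Stability is the sign of
#' the analytic \eqn{dR/du} at each root.
#'
#' @param p a \code{\link{kineticParams}} object.
#' @param chi depletion switch, 0 or 1.
#' @param tol residual tolerance: every reported root satisfies
#'   \code{|reactionRate(root)| < tol}.
#' @return An object of class \code{"equilibriumSet"}: list with \code{roots}
#'   (ascending), \code{stability} (\code{"stable"}/\code{"unstable"}),
#'   \code{u0_star} (minimal positive equilibrium, \code{NA} if none) and
#'   \code{ul_star} (smallest unstable equilibrium above \code{u0_star},
#'   \code{NA} if none).
#' @examples
#' eq <- equilibria(kineticParams(alpha2 = 5.0))
#' eq$u0_star   # 0.181
#' @export
equilibria <- function(p, chi = 1, tol = 1e-8) {
  stopifnot(inherits(p, "kineticParams"), chi %in% c(0, 1))
  g <- chi * p$gamma
  if (p$alpha2 == 0) {
    # linear kinetics (g - alpha0) u + mu
    slope <- g - p$alpha0
    roots <- if (p$mu == 0) {
      0
    } else if (slope < 0) {
      p$mu / (-slope)
    } else {
      numeric(0)  # rate >= mu > 0 for all u >= 0
    }
  } else {
    # multiply R(u) = 0 by (alpha1 + u^2):
    # (g-a0) u^3 + mu u^2 + ((g-a0) a1 - a2) u + mu a1 = 0
    co <- c(p$mu * p$alpha1,
            (g - p$alpha0) * p$alpha1 - p$alpha2,
            p$mu,
            g - p$alpha0)
    while (length(co) > 1 && co[length(co)] == 0) co <- co[-length(co)]
    if (length(co) <= 1) {
      roots <- numeric(0)
    } else {
      z <- polyroot(co)
      roots <- Re(z)[abs(Im(z)) < 1e-9]
      roots <- roots[roots > -1e-12]
      roots[roots < 0] <- 0
      # one Newton polish on the full rational rate
      for (i in seq_along(roots)) {
        d <- reactionRateDeriv(roots[i], p, chi)
        if (is.finite(d) && abs(d) > 1e-12) {
          r2 <- roots[i] - reactionRate(roots[i], p, chi) / d
          if (is.finite(r2) && r2 >= 0) roots[i] <- r2
        }
      }
      roots <- sort(unique(roots))
      # collapse near-duplicates
      if (length(roots) > 1) {
        keep <- c(TRUE, diff(roots) > 1e-9)
        roots <- roots[keep]
      }
    }
  }
  roots <- roots[vapply(roots, function(r)
    abs(reactionRate(r, p, chi)) < tol, logical(1))]
  deriv <- reactionRateDeriv(roots, p, chi)
  stability <- ifelse(deriv < 0, "stable", "unstable")
  pos <- roots > 1e-12
  u0 <- if (any(pos)) min(roots[pos]) else NA_real_
  ul <- NA_real_
  if (!is.na(u0)) {
    cand <- roots > u0 & stability == "unstable"
    if (any(cand)) ul <- min(roots[cand])
  }
  structure(list(roots = roots, stability = stability,
                 u0_star = u0, ul_star = ul, chi = chi),
            class = "equilibriumSet")
}

#' @export
print.equilibriumSet <- function(x, ...) {
  cat(sprintf("Spatially uniform equilibria (chi = %d):\n", x$chi))
  if (length(x$roots) == 0) {
    cat("  none (no nonnegative root)\n")
  } else {
    for (i in seq_along(x$roots))
      cat(sprintf("  u = %.6g (%s)\n", x$roots[i], x$stability[i]))
  }
  cat(sprintf("  u0* = %s, ul* = %s\n",
              format(x$u0_star), format(x$ul_star)))
  invisible(x)
}

#' No-pattern condition
#'
#' Wheals cannot emerge, regardless of the stimulus, when the self-activation
#' rate does not exceed the basal decay rate: the condition is the strict
#' inequality \eqn{\gamma - \alpha_0 < 0} (which includes the activation-absent
#' case \eqn{\gamma = 0}).
#'
#' @param p a \code{\link{kineticParams}} object.
#' @return \code{TRUE} if wheal emergence is impossible.
#' @export
noPatternCondition <- function(p) {
  stopifnot(inherits(p, "kineticParams"))
  p$gamma - p$alpha0 < 0
}

#' Analytic traveling-wave speed bound
#'
#' Linear-spreading bound for a front invading the unstable equilibrium
#' \code{ul_star}:
#' \deqn{c_{min} = 2\sqrt{D_u\left(\gamma -
#'   \alpha_2\frac{\alpha_1 - u_l^{*2}}{(\alpha_1 + u_l^{*2})^2}
#'   - \alpha_0\right)}.}
#' The bound increases with \code{gamma} and decreases with \code{alpha0}.
#' Note this is a property of propagation into the unstable state; the
#' simulated wheal front (a front into the stable low state) is not claimed to
#' attain it.
#'
#' @param p a \code{\link{kineticParams}} object.
#' @param ul_star unstable equilibrium to linearize about; by default taken
#'   from \code{\link{equilibria}}.  An error of class
#'   \code{"whealdyn_no_ulstar"} is signalled when none exists.
#' @return The dimensionless minimal speed, or \code{NA} (with attribute
#'   \code{reason = "no positive bound"}) when the radicand is negative.
#' @export
waveSpeedBound <- function(p, ul_star = NULL) {
  stopifnot(inherits(p, "kineticParams"))
  if (is.null(ul_star)) {
    eq <- equilibria(p)
    ul_star <- eq$ul_star
    if (is.na(ul_star))
      stop(structure(class = c("whealdyn_no_ulstar", "error", "condition"),
                     list(message = paste("waveSpeedBound: kinetics have no",
                                          "unstable equilibrium above u0*;",
                                          "analysis not applicable"),
                          call = sys.call())))
  }
  dinhib <- if (p$alpha2 == 0) 0 else
    p$alpha2 * (p$alpha1 - ul_star^2) / (p$alpha1 + ul_star^2)^2
  radicand <- p$d_u * (p$gamma - dinhib - p$alpha0)
  if (radicand < 0)
    return(structure(NA_real_, reason = "no positive bound"))
  2 * sqrt(radicand)
}
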