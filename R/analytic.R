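#' Persistence margin of the well-mixed replicase-parasite system
#'
#' A spatially homogeneous population of replicases and parasites has a
#' positive steady state exactly when
#' \deqn{1 - m > \frac{a_P d_R}{a_R d_P},}
#' i.e. when replication losses to miscopying and the parasites' template
#' advantage do not together outweigh the replicases' own turnover.  This
#' function returns the signed margin `(1 - m) - aP*dR/(aR*dP)`; a positive
#' value means the inequality holds and coexistence is possible.
#'
#' @param params An [pde_params()] object.
#' @param aP Parasite affinity at which to evaluate the margin; defaults to
#'   `params$aP0`.
#' @return A single signed number; positive iff a positive steady state
#'   exists (for `0 < m < 1`).
#' @examples
#' persistence_margin(pde_params(dR = 0.1, dP = 0.1, m = 0), aP = 0.6) # 0.4
#' @seealso [steady_state()]
#' @export
persistence_margin <- function(params, aP = params$aP0) {
  stopifnot(inherits(params, "rp_pde_params"))
  if (params$dP <= 0) stop("'dP' must be positive")
  if (params$aR <= 0) stop("'aR' must be positive")
  if (!is.numeric(aP) || length(aP) != 1L || aP < 0)
    stop("'aP' must be a single non-negative number")
  (1 - params$m) - aP * params$dR / (params$aR * params$dP)
}

#' Well-mixed steady state of the replicase-parasite system
#'
#' Closed-form equilibrium of the spatially homogeneous dynamics with a
#' strictly interior miscopy probability `0 < m < 1`:
#' \deqn{A = \frac{m a_R d_R}{d_P (1-m) a_R - a_P d_R}, \quad
#'       n^* = \frac{d_R^2 (a_R + a_P A)}{n_0 [(1-m) a_R]^2}, \quad
#'       r^* = \frac{d_R}{(1-m) a_R n^*}, \quad p^* = A r^*.}
#' The parasite/replicase ratio `A` is constant along the equilibrium
#' branch.  The returned state has zero residuals in the three homogeneous
#' balance equations (resource, replicase, parasite) up to round-off.
#'
#' For `m = 0` the equilibrium degenerates: replicases and parasites can
#' coexist in any proportion if and only if `aR*dP == aP*dR`, otherwise no
#' mixed equilibrium exists.  In that case an object of class
#' `rp_degenerate_state` is returned instead of a point.  `m = 1` (fully
#' ineffective replication) and a non-positive persistence margin are
#' errors.
#'
#' @inheritParams persistence_margin
#' @return An object of class `rp_steady_state` with elements `r`, `p`,
#'   `n`, `A`, `margin`, plus the inputs; or an `rp_degenerate_state` when
#'   `m = 0`.
#' @examples
#' steady_state(pde_params(m = 0.01, aP0 = 0.5))
#' @export
steady_state <- function(params, aP = params$aP0) {
  stopifnot(inherits(params, "rp_pde_params"))
  m <- params$m
  if (m >= 1)
    stop("m = 1: replication is fully ineffective, no steady state exists")
  if (m == 0) {
    line <- isTRUE(all.equal(params$aR * params$dP, aP * params$dR))
    out <- list(degenerate = TRUE,
                coexistence_any_proportion = line,
                aP = aP, params = params)
    return(structure(out, class = "rp_degenerate_state"))
  }
  denom <- params$dP * (1 - m) * params$aR - aP * params$dR
  if (denom <= 0)
    stop("no positive steady state: persistence inequality violated ",
         "(dP*(1-m)*aR - aP*dR <= 0)")
  A <- m * params$aR * params$dR / denom
  n <- params$dR^2 * (params$aR + aP * A) /
    (params$n0 * ((1 - m) * params$aR)^2)
  r <- params$dR / ((1 - m) * params$aR * n)
  p <- A * r
  structure(list(r = r, p = p, n = n, A = A,
                 margin = persistence_margin(params, aP),
                 aP = aP, params = params),
            class = "rp_steady_state")
}

#' @export
print.rp_steady_state <- function(x, digits = 6, ...) {
  cat("Well-mixed steady state of the replicase-parasite system\n")
  cat(sprintf("  r = %.*g   p = %.*g   n = %.*g\n",
              digits, x$r, digits, x$p, digits, x$n))
  cat(sprintf("  parasite/replicase ratio A = %.*g\n", digits, x$A))
  cat(sprintf("  persistence margin = %.*g\n", digits, x$margin))
  invisible(x)
}

#' @export
print.rp_degenerate_state <- function(x, ...) {
  cat("Degenerate equilibrium (m = 0):\n")
  if (x$coexistence_any_proportion)
    cat("  aR*dP == aP*dR: replicases and parasites coexist in any",
        "proportion\n")
  else
    cat("  aR*dP != aP*dR: no mixed equilibrium exists\n")
  invisible(x)
}

#' Linearized self-amplification of replicase perturbations
#'
#' At a homogeneous state `(n, r)` the linearization of the replicase
#' balance about the equilibrium reduces to the rate `(1 - m) * aR * n * r`.
#' This is strictly positive at any interior equilibrium with `m < 1`, so a
#' perturbation of the replicase density is initially magnified: the
#' equilibrium cannot be shown stable by linearization alone, which is what
#' motivates the pendulum reduction of the full homogeneous dynamics.
#'
#' @inheritParams persistence_margin
#' @param n,r Resource and replicase densities at which to linearize.
#' @return The linear growth rate (per time), a non-negative number.
#' @seealso [pendulum_coefficients()]
#' @export
linear_growth_rate <- function(params, n, r) {
  stopifnot(inherits(params, "rp_pde_params"))
  if (n < 0 || r < 0) stop("'n' and 'r' must be >= 0")
  (1 - params$m) * params$aR * n * r
}

#' Pendulum reduction of the homogeneous dynamics
#'
#' With parasite density `p` held fixed, the substitution `y = 1/r` turns
#' the homogeneous resource/replicase dynamics into a second-order equation
#' \deqn{y'' = P(y) + Q(y)\, y'}
#' with position-dependent force
#' \deqn{P(y) = d_R a_P p - n_0 (1-m) a_R + d_R a_R / y}
#' and friction coefficient
#' \deqn{Q(y) = d_R - a_P p / y - a_R / y^2.}
#' `P` has a single positive root `yE` (the equilibrium inverse replicase
#' density) and is positive below it and negative above it.  `Q` is
#' non-positive for `y` up to the critical point
#' \deqn{y_C = \frac{a_P p + \sqrt{a_P^2 p^2 + 4 a_R d_R}}{2 d_R};}
#' below `yC` the system is a damped pendulum that settles at `yE`, beyond
#' `yC` friction changes sign and `y` escapes to infinity (replicase
#' collapse).
#'
#' The reduction treats `p` as a constant parameter; it is a good
#' approximation only while the parasite density changes slowly compared to
#' the replicase oscillation.
#'
#' @inheritParams persistence_margin
#' @param p_fixed Parasite density treated as a constant parameter.
#' @return An object of class `rp_pendulum` with elements `yE`, `yC`,
#'   `p_fixed`, the callables `P` and `Q`, and the inputs.
#' @examples
#' red <- pendulum_coefficients(pde_params(m = 0), aP = 1, p_fixed = 0)
#' red$yE  # 0.01  (= dR / n0 at these rates)
#' red$yC  # 10    (= sqrt(aR / dR))
#' @export
pendulum_coefficients <- function(params, aP = params$aP0, p_fixed) {
  stopifnot(inherits(params, "rp_pde_params"))
  if (params$dR <= 0) stop("'dR' must be positive")
  if (!is.numeric(p_fixed) || length(p_fixed) != 1L || p_fixed < 0)
    stop("'p_fixed' must be a single non-negative number")
  aR <- params$aR; dR <- params$dR; n0 <- params$n0; m <- params$m
  denom <- n0 * (1 - m) * aR - dR * aP * p_fixed
  if (denom <= 0)
    stop("no positive equilibrium: the fixed parasite density is too ",
         "high (p_fixed >= n0*(1-m)*aR / (dR*aP))")
  yE <- dR * aR / denom
  yC <- (aP * p_fixed + sqrt(aP^2 * p_fixed^2 + 4 * aR * dR)) / (2 * dR)
  force  <- function(y) dR * aP * p_fixed - n0 * (1 - m) * aR + dR * aR / y
  fric   <- function(y) dR - aP * p_fixed / y - aR / y^2
  structure(list(yE = yE, yC = yC, p_fixed = p_fixed,
                 P = force, Q = fric, aP = aP, params = params),
            class = "rp_pendulum")
}

#' @export
print.rp_pendulum <- function(x, digits = 6, ...) {
  cat("Pendulum reduction (y = 1/r, parasite density fixed)\n")
  cat(sprintf("  equilibrium yE = %.*g   critical point yC = %.*g\n",
              digits, x$yE, digits, x$yC))
  cat(sprintf("  fixed parasite density p = %.*g\n", digits, x$p_fixed))
  invisible(x)
}

# classic fixed-step RK4 on dx/dt = f(x), with a post-step projection
rk4 <- function(f, x0, nsteps, dt, project = identity) {
  out <- matrix(NA_real_, nrow = nsteps + 1L, ncol = length(x0))
  x <- x0
  out[1L, ] <- x
  for (s in seq_len(nsteps)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- project(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    out[s + 1L, ] <- x
    if (!all(is.finite(x))) {
      out <- out[seq_len(s + 1L), , drop = FALSE]
      break
    }
  }
  out
}

#' Integrate the spatially homogeneous (well-mixed) dynamics
#'
#' Fixed-step 4th-order Runge-Kutta integration of the homogeneous system
#' \deqn{n' = n_0 - n r (a_R r + a_P p), \quad
#'       r' = (1-m) a_R n r^2 - d_R r, \quad
#'       p' = m a_R n r^2 + a_P n r p - d_P p.}
#' Densities are projected onto `>= 0` after every step.  With
#' `clamp_p = TRUE` the parasite density is held constant at its initial
#' value, which is the regime analyzed by the pendulum reduction.
#'
#' @inheritParams persistence_margin
#' @param init Numeric vector `c(n, r, p)` of initial densities.
#' @param horizon Total integration time.
#' @param dt Integration step; defaults to the model's `dt`.
#' @param clamp_p Hold the parasite density fixed at `init[3]`?
#' @return A data frame with columns `t`, `n`, `r`, `p`.
#' @examples
#' ss <- steady_state(pde_params(m = 0.01, aP0 = 0.5))
#' tr <- integrate_well_mixed(pde_params(m = 0.01), aP = 0.5,
#'                            init = c(ss$n, ss$r, ss$p), horizon = 10)
#' max(abs(tr$r - ss$r) / ss$r)  # stays at the fixed point
#' @export
integrate_well_mixed <- function(params, aP = params$aP0, init,
                                 horizon, dt = params$dt,
                                 clamp_p = FALSE) {
  stopifnot(inherits(params, "rp_pde_params"))
  if (length(init) != 3L || any(init < 0))
    stop("'init' must be c(n, r, p) with non-negative components")
  nsteps <- max(1L, as.integer(round(horizon / dt)))
  aR <- params$aR; dR <- params$dR; dP <- params$dP
  m <- params$m; n0 <- params$n0
  p_hold <- init[3L]
  deriv <- function(x) {
    n <- x[1L]; r <- x[2L]; p <- x[3L]
    c(n0 - n * r * (aR * r + aP * p),
      (1 - m) * aR * n * r^2 - dR * r,
      if (clamp_p) 0 else m * aR * n * r^2 + aP * n * r * p - dP * p)
  }
  project <- function(x) {
    x[x < 0] <- 0
    if (clamp_p) x[3L] <- p_hold
    x
  }
  out <- rk4(deriv, as.numeric(init), nsteps, dt, project)
  data.frame(t = (seq_len(nrow(out)) - 1L) * dt,
             n = out[, 1L], r = out[, 2L], p = out[, 3L])
}

#' Integrate the pendulum equation for the inverse replicase density
#'
#' Fixed-step RK4 integration of `y'' = P(y) + Q(y) y'` from
#' [pendulum_coefficients()].  Starting below the critical point `yC` the
#' trajectory is a damped oscillation settling at `yE`; past `yC` the
#' friction term injects energy and `y` (the inverse replicase density)
#' grows without bound, i.e. the replicases collapse.  Divergence is
#' declared when `y` exceeds `cap_factor * yE` and the trajectory is
#' truncated there.
#'
#' @param red An `rp_pendulum` object.
#' @param y0 Initial inverse replicase density (`> 0`).
#' @param v0 Initial velocity `y'(0)`.  For a trajectory matched to the
#'   homogeneous system, `v0 = dR*y0 - (1-m)*aR*n(0)`.
#' @param horizon Total integration time.
#' @param dt Integration step.
#' @param cap_factor Divergence cap as a multiple of `yE`.
#' @return A data frame with columns `t`, `y`, `v` and attribute
#'   `diverged` (logical).
#' @export
integrate_pendulum <- function(red, y0, v0 = 0, horizon, dt = 0.1,
                               cap_factor = 1e6) {
  stopifnot(inherits(red, "rp_pendulum"))
  if (y0 <= 0) stop("'y0' must be positive (y is an inverse density)")
  nsteps <- max(1L, as.integer(round(horizon / dt)))
  cap <- cap_factor * red$yE
  deriv <- function(x) c(x[2L], red$P(x[1L]) + red$Q(x[1L]) * x[2L])
  out <- matrix(NA_real_, nrow = nsteps + 1L, ncol = 2L)
  x <- c(y0, v0)
  out[1L, ] <- x
  diverged <- FALSE
  last <- nsteps + 1L
  for (s in seq_len(nsteps)) {
    k1 <- deriv(x)
    k2 <- deriv(x + dt / 2 * k1)
    k3 <- deriv(x + dt / 2 * k2)
    k4 <- deriv(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[s + 1L, ] <- x
    if (!all(is.finite(x)) || x[1L] > cap || x[1L] <= 0) {
      diverged <- !is.finite(x[1L]) || x[1L] > cap
      last <- s + 1L
      break
    }
  }
  out <- out[seq_len(last), , drop = FALSE]
  res <- data.frame(t = (seq_len(nrow(out)) - 1L) * dt,
                    y = out[, 1L], v = out[, 2L])
  attr(res, "diverged") <- diverged
  res
}
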