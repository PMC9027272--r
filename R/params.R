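#' Parameters of the reaction-diffusion (macroscopic) model
#'
#' Bundles the rate constants of the replicase-parasite density model.  The
#' system tracks replicase density `r`, parasite density `p`, resource
#' density `n`, and (when mutation is enabled) the local mean parasite
#' affinity `a`.  Replication is a third-order reaction: replicase +
#' template + resource unit, with rate constant equal to the template's
#' affinity towards replicases.
#'
#' Defaults are the standard global parameter set of the density simulation
#' (decay 0.01, replicase affinity 1.0, time step 0.1, RNA diffusion 5.0,
#' resource diffusion 10.0, resource production 1.0, miscopy probability 0).
#'
#' @param aR Replicase affinity towards replicases (rate constant, per
#'   density squared per time).
#' @param aP0 Initial/fixed parasite affinity.  Also the initial value of
#'   the affinity field in lattice runs.
#' @param dR,dP Decay rates of replicases and parasites (per time).  The
#'   standard parameter set uses a single decay rate `d = 0.01` for both.
#' @param m Miscopy probability: chance that copying a replicase yields a
#'   parasite instead (in `[0, 1]`).
#' @param n0 Resource production rate (density per time).
#' @param D Diffusion constant of RNA molecules (lattice units squared per
#'   time; the lattice spacing is absorbed into `D`).
#' @param Dn Diffusion constant of resources.
#' @param sigma_a Magnitude of random affinity mutation (affinity per
#'   square-root time).  The per-step perturbation of the local mean
#'   affinity has standard deviation `sigma_a * sqrt(dt) / sqrt(p)`, so
#'   large local populations evolve slowly.  Set to 0 to disable mutation.
#' @param mut_floor Density floor inside the `1/sqrt(p)` mutation scaling.
#'   The noise aggregates per-molecule mutation events, so its standard
#'   deviation cannot exceed the single-molecule scale `sigma_a*sqrt(dt)`;
#'   the default floor of one density unit enforces exactly that bound in
#'   sparsely populated cells (and avoids division by zero in empty ones).
#' @param dt Time step of forward-Euler integration.
#' @param a_min,a_max Clamp bounds for the affinity field.
#' @return An object of class `rp_pde_params` (a validated list).
#' @examples
#' pde_params()                    # standard defaults
#' pde_params(aP0 = 0.5, m = 0.01) # fixed weaker parasite, rare miscopy
#' @export
pde_params <- function(aR = 1.0, aP0 = 1.0, dR = 0.01, dP = 0.01,
                       m = 0.0, n0 = 1.0, D = 5.0, Dn = 10.0,
                       sigma_a = 0.05, mut_floor = 1.0, dt = 0.1,
                       a_min = 0.0, a_max = 1.0) {
  p <- list(aR = aR, aP0 = aP0, dR = dR, dP = dP, m = m, n0 = n0,
            D = D, Dn = Dn, sigma_a = sigma_a, mut_floor = mut_floor,
            dt = dt, a_min = a_min, a_max = a_max)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (any(unlist(p[c("aR", "aP0", "dR", "dP", "n0", "D", "Dn",
                     "sigma_a")]) < 0))
    stop("rates, affinities, and diffusion constants must be >= 0")
  if (m < 0 || m > 1) stop("'m' is a probability and must lie in [0, 1]")
  if (dt <= 0) stop("'dt' must be positive")
  if (mut_floor <= 0) stop("'mut_floor' must be positive")
  if (a_min > a_max) stop("'a_min' must not exceed 'a_max'")
  if (aP0 < a_min || aP0 > a_max)
    stop("'aP0' must lie within [a_min, a_max]")
  structure(p, class = "rp_pde_params")
}

#' Parameters of the multi-agent (microscopic) model
#'
#' Bundles the global parameters of the Brownian-dynamics agent simulation.
#' Agents are circles of radius `agent_size` on a periodic arena; reactions
#' occur between overlapping circles.  Defaults give the standard parameter
#' set of the agent simulation (arena 800, radius 3.0, crowding cap 4,
#' decay 0.1, replicase-replicase probability 1.0, step 1.0, diffusion 15.0,
#' mutation half-range 0.05 via `delta = 0.1`, mutation probability 0.1).
#'
#' @param sizeX,sizeY Arena extent (length units).
#' @param agent_size Radius of the circle representing an agent; two agents
#'   interact when their center distance is strictly below `2 * agent_size`.
#' @param Nmax Crowding cap: an agent with more than `Nmax` overlapping
#'   neighbors is removed.
#' @param d Decay rate (per time); lifetimes are pre-sampled as
#'   remaining-life-time step counts, see [sample_rlt()].
#' @param kR Probability that a replicase-replicase encounter yields a copy.
#' @param dt Step length (time units).
#' @param D Diffusion constant; per-axis Brownian step s.d. is
#'   `sqrt(2 * D * dt)`.
#' @param delta Full width of the mutation step: a mutated parasite's
#'   replication probability changes by a uniform draw from
#'   `[-delta/2, +delta/2]`, clamped to `[0, 1]`.
#' @param mP Probability that a newly created parasite is mutated.
#' @param n_replicases0,n_parasites0 Initial molecule counts.
#' @param kP0 Initial replication probability shared by all parasites.
#' @param seed Integer seed for the simulation's random stream.
#' @param time_limit Maximum number of steps to simulate.
#' @return An object of class `rp_mas_params` (a validated list).
#' @examples
#' mas_params()
#' mas_params(sizeX = 400, sizeY = 400, n_replicases0 = 500,
#'            n_parasites0 = 500, D = 5)
#' @export
mas_params <- function(sizeX = 800, sizeY = 800, agent_size = 3.0,
                       Nmax = 4L, d = 0.1, kR = 1.0, dt = 1.0, D = 15.0,
                       delta = 0.1, mP = 0.1,
                       n_replicases0 = 2000L, n_parasites0 = 2000L,
                       kP0 = 0.5, seed = 1L, time_limit = 5000L) {
  p <- list(sizeX = sizeX, sizeY = sizeY, agent_size = agent_size,
            Nmax = as.integer(Nmax), d = d, kR = kR, dt = dt, D = D,
            delta = delta, mP = mP,
            n_replicases0 = as.integer(n_replicases0),
            n_parasites0 = as.integer(n_parasites0),
            kP0 = kP0, seed = as.integer(seed),
            time_limit = as.integer(time_limit))
  num <- c("sizeX", "sizeY", "agent_size", "d", "kR", "dt", "D",
           "delta", "mP", "kP0")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (p$sizeX <= 0 || p$sizeY <= 0) stop("arena size must be positive")
  if (p$agent_size <= 0) stop("'agent_size' must be positive")
  if (p$Nmax < 0) stop("'Nmax' must be >= 0")
  if (p$d < 0 || p$D < 0 || p$delta < 0) stop("rates must be >= 0")
  if (p$dt <= 0) stop("'dt' must be positive")
  for (nm in c("kR", "mP", "kP0"))
    if (p[[nm]] < 0 || p[[nm]] > 1)
      stop("'", nm, "' is a probability and must lie in [0, 1]")
  if (p$n_replicases0 < 0 || p$n_parasites0 < 0)
    stop("initial counts must be >= 0")
  if (p$time_limit < 0) stop("'time_limit' must be >= 0")
  structure(p, class = "rp_mas_params")
}

#' @export
print.rp_pde_params <- function(x, ...) {
  cat("Reaction-diffusion model parameters\n")
  cat(sprintf("  affinities  aR = %g, aP0 = %g\n", x$aR, x$aP0))
  cat(sprintf("  decay       dR = %g, dP = %g\n", x$dR, x$dP))
  cat(sprintf("  miscopy     m = %g\n", x$m))
  cat(sprintf("  resources   n0 = %g, Dn = %g\n", x$n0, x$Dn))
  cat(sprintf("  diffusion   D = %g\n", x$D))
  cat(sprintf("  mutation    sigma_a = %g, clamp [%g, %g]\n",
              x$sigma_a, x$a_min, x$a_max))
  cat(sprintf("  time step   dt = %g\n", x$dt))
  invisible(x)
}

#' @export
print.rp_mas_params <- function(x, ...) {
  cat("Multi-agent model parameters\n")
  cat(sprintf("  arena       %g x %g, agent radius %g, Nmax %d\n",
              x$sizeX, x$sizeY, x$agent_size, x$Nmax))
  cat(sprintf("  kinetics    d = %g, kR = %g, dt = %g, D = %g\n",
              x$d, x$kR, x$dt, x$D))
  cat(sprintf("  mutation    delta = %g, mP = %g\n", x$delta, x$mP))
  cat(sprintf("  initial     %d replicases + %d parasites, kP0 = %g\n",
              x$n_replicases0, x$n_parasites0, x$kP0))
  cat(sprintf("  run         seed %d, time limit %d steps\n",
              x$seed, x$time_limit))
  invisible(x)
}
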