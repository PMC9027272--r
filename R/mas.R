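#' Per-step decay probability of a molecule
#'
#' Spontaneous decay is a first-order reaction with rate `d`; over one step
#' of length `dt` a molecule decays with probability `1 - exp(-d*dt)`,
#' independent of its age.
#'
#' @param d Decay rate (per time).
#' @param dt Step length.
#' @return A probability in `[0, 1)`.
#' @examples
#' decay_probability(0.1, 1)  # ~0.09516
#' @export
decay_probability <- function(d, dt) {
  if (d < 0 || dt < 0) stop("'d' and 'dt' must be >= 0")
  1 - exp(-d * dt)
}

#' Sample a remaining life time (RLT)
#'
#' Instead of testing decay every step, each molecule is assigned at birth
#' the number of steps after which it decays:
#' `RLT = floor(-log(x) / (d*dt)) + 1` for a uniform draw `x` in `(0, 1]`.
#' This is statistically equivalent to per-step Bernoulli decay with
#' probability `1 - exp(-d*dt)`: the RLT is geometric with that success
#' probability and mean `1 / (1 - exp(-d*dt))`.
#'
#' @param d Decay rate (per time); `d * dt` must be positive.
#' @param dt Step length.
#' @param x Uniform draw in `(0, 1]`; defaults to a fresh `runif()` draw.
#' @return A positive integer number of steps.
#' @examples
#' sample_rlt(0.1, 1, x = exp(-0.25))  # floor(2.5) + 1 = 3
#' @export
sample_rlt <- function(d, dt, x = runif(1)) {
  if (d * dt <= 0) stop("'d * dt' must be positive")
  if (any(x <= 0) || any(x > 1)) stop("'x' must lie in (0, 1]")
  as.integer(floor(-log(x) / (d * dt)) + 1)
}

#' Brownian displacement over one step
#'
#' Brownian dynamics: over a step of length `dt` an agent with diffusion
#' constant `D` moves by `sqrt(2*D*dt)` times a standard Gaussian vector,
#' giving per-axis variance `2*D*dt` and mean squared displacement
#' `4*D*dt` in two dimensions.
#'
#' @param D Diffusion constant.
#' @param dt Step length.
#' @param xi A standard Gaussian vector (2D); defaults to a fresh draw.
#' @return The displacement vector `sqrt(2*D*dt) * xi`.
#' @export
brownian_displacement <- function(D, dt, xi = rnorm(2)) {
  if (D < 0 || dt < 0) stop("'D' and 'dt' must be >= 0")
  sqrt(2 * D * dt) * xi
}

#' Create an agent population table
#'
#' @param x,y Positions (wrapped into the arena).
#' @param type Character vector, `"replicase"` or `"parasite"`.
#' @param kP Replication probabilities (meaningful for parasites; `NA` for
#'   replicases).
#' @param rlt Remaining-life-time step counts.
#' @param params An [mas_params()] object (used to wrap positions).
#' @return A data frame with class `rp_population`.
#' @export
population <- function(x, y, type, kP, rlt, params) {
  stopifnot(inherits(params, "rp_mas_params"))
  if (!all(type %in% c("replicase", "parasite")))
    stop("'type' must be \"replicase\" or \"parasite\"")
  pop <- data.frame(x = x %% params$sizeX, y = y %% params$sizeY,
                    type = type, kP = kP, rlt = as.integer(rlt))
  if (any(!is.na(pop$kP) & (pop$kP < 0 | pop$kP > 1)))
    stop("'kP' values must lie in [0, 1]")
  if (any(pop$rlt < 1L)) stop("'rlt' must be >= 1 at creation")
  class(pop) <- c("rp_population", "data.frame")
  pop
}

#' Overlap neighbors of an agent
#'
#' Indices of all other agents whose center distance to the focal agent is
#' strictly below `2 * agent_size`, measured with periodic wrap.  Uses a
#' spatial-hash search (equal, by construction and by test, to the
#' all-pairs result).
#'
#' @param focal Index of the focal agent in `pop`.
#' @param pop An agent population table with columns `x` and `y`.
#' @param params An [mas_params()] object (supplies arena size and
#'   `agent_size`).
#' @return An integer vector of neighbor row indices.
#' @export
find_neighbors <- function(focal, pop, params) {
  stopifnot(inherits(params, "rp_mas_params"))
  focal <- as.integer(focal)
  if (focal < 1L || focal > nrow(pop)) stop("'focal' out of range")
  lst <- .neighbors_binned_cpp(pop$x, pop$y, params$sizeX, params$sizeY,
                               2 * params$agent_size)
  lst[[focal]]
}

#' Mutate a parasite's replication probability
#'
#' With probability `mP` the value is shifted by a uniform draw from
#' `[-delta/2, +delta/2]` and clamped to `[0, 1]`; otherwise it is
#' returned unchanged.  Uses R's random number stream.
#'
#' @param kP Current replication probability.
#' @param params An [mas_params()] object.
#' @return The (possibly mutated) probability.
#' @export
mutate_kp <- function(kP, params) {
  stopifnot(inherits(params, "rp_mas_params"))
  if (kP < 0 || kP > 1) stop("'kP' must lie in [0, 1]")
  if (runif(1) < params$mP)
    kP <- min(1, max(0, kP + (runif(1) - 0.5) * params$delta))
  kP
}

#' Attempt a replication reaction between two overlapping agents
#'
#' Two parasites never react.  A replicase-parasite pair replicates the
#' parasite with probability equal to the parasite's `kP`; a
#' replicase-replicase pair replicates the partner with probability `kR`.
#' The offspring is an exact copy of the template placed at the template's
#' position with a freshly sampled lifetime; a parasite offspring is then
#' subjected to mutation (replicase offspring never mutate -- kind cannot
#' change in this reaction).  Uses R's random number stream.
#'
#' @param xi,nj Row indices of the two agents in `pop`.
#' @param pop An agent population table.
#' @param params An [mas_params()] object.
#' @return A one-row data frame for the new agent, or `NULL` if no
#'   replication occurred.
#' @export
attempt_replication <- function(xi, nj, pop, params) {
  stopifnot(inherits(params, "rp_mas_params"))
  ti <- pop$type[xi]; tj <- pop$type[nj]
  if (ti == "parasite" && tj == "parasite") return(NULL)
  if (ti == "parasite") {                  # nj is the replicase
    tmpl <- xi; prob <- pop$kP[xi]
  } else if (tj == "parasite") {
    tmpl <- nj; prob <- pop$kP[nj]
  } else {
    tmpl <- nj; prob <- params$kR
  }
  if (runif(1) >= prob) return(NULL)
  kp <- pop$kP[tmpl]
  if (pop$type[tmpl] == "parasite") kp <- mutate_kp(kp, params)
  data.frame(x = pop$x[tmpl], y = pop$y[tmpl], type = pop$type[tmpl],
             kP = kp, rlt = sample_rlt(params$d, params$dt))
}

#' One step of the multi-agent dynamics (plain-R implementation)
#'
#' A direct R transcription of the agent update loop, useful for
#' inspecting the step semantics on small populations ([run_mas()] uses an
#' equivalent compiled engine).  The step: (1) decrement every agent's
#' remaining life time and remove the expired; (2) visit the surviving
#' agents in random order; (3) per agent, collect its overlap neighbors --
#' if more than `Nmax`, the agent dies of crowding; otherwise it takes a
#' Brownian step and then attempts one replication per neighbor (in random
#' order).  Offspring join the population immediately but are not visited
#' this step.  Uses R's random number stream.
#'
#' @param pop An agent population table.
#' @param params An [mas_params()] object.
#' @return The updated population table.
#' @export
mas_step <- function(pop, params) {
  stopifnot(inherits(params, "rp_mas_params"))
  pop$rlt <- pop$rlt - 1L
  alive <- pop$rlt > 0L
  pop <- pop[alive, , drop = FALSE]
  rownames(pop) <- NULL
  n_start <- nrow(pop)
  if (n_start == 0L) return(pop)
  live <- rep(TRUE, n_start)
  order_idx <- sample.int(n_start)
  radius <- 2 * params$agent_size
  for (xi in order_idx) {
    if (!live[xi]) next
    d2 <- per_dist2_r(pop$x[xi], pop$y[xi], pop$x, pop$y,
                      params$sizeX, params$sizeY)
    nbrs <- which(d2 < radius^2 & live[seq_len(nrow(pop))] &
                    seq_len(nrow(pop)) != xi)
    if (length(nbrs) > params$Nmax) {
      live[xi] <- FALSE
      next
    }
    if (length(nbrs) > 1L) nbrs <- nbrs[sample.int(length(nbrs))]
    mv <- brownian_displacement(params$D, params$dt)
    pop$x[xi] <- (pop$x[xi] + mv[1L]) %% params$sizeX
    pop$y[xi] <- (pop$y[xi] + mv[2L]) %% params$sizeY
    for (nj in nbrs) {
      if (!live[nj]) next
      child <- attempt_replication(xi, nj, pop, params)
      if (!is.null(child)) {
        pop <- rbind(pop, child)
        live <- c(live, TRUE)
      }
    }
  }
  pop <- pop[live, , drop = FALSE]
  rownames(pop) <- NULL
  pop
}

# squared periodic distance, vectorized over the second point set
per_dist2_r <- function(x1, y1, x2, y2, sizeX, sizeY) {
  dx <- abs(x1 - x2); dx <- pmin(dx, sizeX - dx)
  dy <- abs(y1 - y2); dy <- pmin(dy, sizeY - dy)
  dx^2 + dy^2
}

#' Run the multi-agent simulation
#'
#' Initializes `n_replicases0 + n_parasites0` agents at uniform-random
#' positions (all parasites sharing `kP0`) and advances the dynamics until
#' `time_limit` steps have elapsed or either species is gone.  Per-step
#' molecule counts and the mean/min/max parasite replication probability
#' are recorded.  Runs are deterministic given `params$seed` (the engine
#' uses its own random stream, independent of R's).
#'
#' @param params An [mas_params()] object.
#' @param snapshot_every Record full agent tables every this many steps
#'   (0 = none).
#' @return An object of class `c("rp_mas_run", "rp_run")` with elements
#'   `times`, `step`, `replicase_series`, `parasite_series`,
#'   `affinity_series` (mean parasite `kP`), `min_kP`, `max_kP`,
#'   `steps_run`, the `final` population table, optional `snapshots`, the
#'   `params`, and the `outcome` label (`"Alive"` iff both species are
#'   present at the end).
#' @examples
#' p <- mas_params(sizeX = 100, sizeY = 100, n_replicases0 = 50,
#'                 n_parasites0 = 50, time_limit = 20)
#' run <- run_mas(p)
#' run$outcome
#' @export
run_mas <- function(params, snapshot_every = 0L) {
  stopifnot(inherits(params, "rp_mas_params"))
  res <- .mas_run_cpp(unclass(params), as.integer(snapshot_every))
  final <- data.frame(x = res$final$x, y = res$final$y,
                      type = c("replicase", "parasite")[res$final$type + 1L],
                      kP = res$final$kP, rlt = res$final$rlt)
  class(final) <- c("rp_population", "data.frame")
  nr <- res$n_replicases; np <- res$n_parasites
  out <- list(times = res$step * params$dt,
              step = res$step,
              replicase_series = nr,
              parasite_series = np,
              affinity_series = res$mean_kP,
              min_kP = res$min_kP, max_kP = res$max_kP,
              steps_run = res$steps_run,
              final = final,
              snapshots = if (snapshot_every > 0) res$snapshots,
              snapshot_steps = if (snapshot_every > 0) res$snapshot_steps,
              params = params)
  last <- length(nr)
  out$outcome <- if (nr[last] > 0L && np[last] > 0L) "Alive" else "Extinction"
  structure(out, class = c("rp_mas_run", "rp_run"))
}
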