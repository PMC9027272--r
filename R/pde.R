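#' Configuration of a lattice (reaction-diffusion) run
#'
#' Couples an [pde_params()] parameter set with the lattice geometry and
#' run-control settings.  The lattice is a torus: diffusion exchanges
#' density with the adjacent neighbors under periodic wrap, and the
#' lattice spacing is 1 (absorbed into the diffusion constants).
#'
#' @param params An [pde_params()] object.
#' @param sizeX,sizeY Lattice dimensions (cells).
#' @param steps Number of forward-Euler steps to run.
#' @param seed Integer seed for the mutation noise stream.
#' @param boundary Boundary handling; only `"periodic"` is implemented.
#' @param neighborhood Which cells count as adjacent for the discrete
#'   diffusion average: the 8-cell `"moore"` ring (default) or the 4-cell
#'   `"von_neumann"` cross.  At the default parameters the resource
#'   update degenerates to plain neighbor-averaging (`Dn * dt = 1`), whose
#'   checkerboard mode is undamped under the 4-neighbor average and is
#'   rectified into unbounded growth by the non-negativity clamp; the
#'   8-neighbor average has no such mode, so it is the default.
#' @param snapshot_every Record full field snapshots every this many steps
#'   (0 = none).
#' @param trace_point Integer `c(i, j)` lattice coordinate (1-based) whose
#'   affinity value is traced every step; defaults to the central cell.
#' @param extinction_eps Mean-density threshold below which a species is
#'   declared extinct when labeling the run outcome.
#' @return An object of class `rp_pde_config`.
#' @export
pde_run_config <- function(params = pde_params(), sizeX = 256L,
                           sizeY = 256L, steps = 1000L, seed = 1L,
                           boundary = "periodic",
                           neighborhood = c("moore", "von_neumann"),
                           snapshot_every = 0L, trace_point = NULL,
                           extinction_eps = 1e-6) {
  stopifnot(inherits(params, "rp_pde_params"))
  neighborhood <- match.arg(neighborhood)
  sizeX <- as.integer(sizeX); sizeY <- as.integer(sizeY)
  steps <- as.integer(steps)
  if (sizeX < 1L || sizeY < 1L) stop("lattice dimensions must be >= 1")
  if (steps < 0L) stop("'steps' must be >= 0")
  boundary <- match.arg(boundary, "periodic")
  if (is.null(trace_point))
    trace_point <- c(max(1L, sizeX %/% 2L), max(1L, sizeY %/% 2L))
  trace_point <- as.integer(trace_point)
  if (length(trace_point) != 2L || any(trace_point < 1L) ||
      trace_point[1L] > sizeX || trace_point[2L] > sizeY)
    stop("'trace_point' must be a valid 1-based lattice coordinate")
  structure(list(params = params, sizeX = sizeX, sizeY = sizeY,
                 steps = steps, seed = as.integer(seed),
                 boundary = boundary, neighborhood = neighborhood,
                 snapshot_every = as.integer(snapshot_every),
                 trace_point = trace_point,
                 extinction_eps = extinction_eps),
            class = "rp_pde_config")
}

#' Uniform initial lattice state
#'
#' All four fields (replicase density, parasite density, mean parasite
#' affinity, resource density) start constant at 1.0, the standard
#' maximally uninformative start.  The affinity field starts at
#' `params$aP0` when that differs from 1.
#'
#' @param config An [pde_run_config()] object.
#' @return An object of class `rp_grid_state`: matrices `r`, `p`, `a`, `n`
#'   plus elapsed time `t` and step counter `step`.
#' @export
init_uniform <- function(config) {
  stopifnot(inherits(config, "rp_pde_config"))
  mk <- function(v) matrix(v, nrow = config$sizeX, ncol = config$sizeY)
  structure(list(r = mk(1.0), p = mk(1.0), a = mk(config$params$aP0),
                 n = mk(1.0), t = 0.0, step = 0L),
            class = "rp_grid_state")
}

#' @export
print.rp_grid_state <- function(x, ...) {
  cat(sprintf("Lattice state %d x %d at t = %g (step %d)\n",
              nrow(x$r), ncol(x$r), x$t, x$step))
  cat(sprintf("  mean r = %.6g  mean p = %.6g  mean n = %.6g\n",
              mean(x$r), mean(x$p), mean(x$n)))
  ap <- sum(x$a * x$p)
  cat(sprintf("  parasite-weighted mean affinity = %.6g\n",
              if (sum(x$p) > 0) ap / sum(x$p) else NA_real_))
  invisible(x)
}

#' Periodic neighbor average of a lattice field
#'
#' Arithmetic mean of the adjacent neighbors with periodic wrap; the
#' building block of the discretized diffusion term
#' `D * dt * (avg - self)`.  `"moore"` averages the 8 surrounding cells
#' (the lattice default, see [pde_run_config()]), `"von_neumann"` the 4
#' orthogonal ones.  On a 1-cell axis a cell wraps to itself.
#'
#' @param field A numeric matrix.
#' @param neighborhood `"moore"` (8 cells) or `"von_neumann"` (4 cells).
#' @param boundary Only `"periodic"` is implemented.
#' @return A matrix of the same shape.
#' @examples
#' f <- matrix(0, 3, 3); f[2, 2] <- 1
#' neighbor_average(f, "von_neumann")  # the 4 orthogonal neighbors see 0.25
#' neighbor_average(f)                 # all 8 surrounding cells see 0.125
#' @export
neighbor_average <- function(field,
                             neighborhood = c("moore", "von_neumann"),
                             boundary = "periodic") {
  neighborhood <- match.arg(neighborhood)
  boundary <- match.arg(boundary, "periodic")
  if (!is.matrix(field) || length(field) == 0L)
    stop("'field' must be a non-empty matrix")
  nx <- nrow(field); ny <- ncol(field)
  up <- if (nx == 1L) 1L else c(2:nx, 1L)
  dn <- if (nx == 1L) 1L else c(nx, seq_len(nx - 1L))
  lf <- if (ny == 1L) 1L else c(ny, seq_len(ny - 1L))
  rt <- if (ny == 1L) 1L else c(2:ny, 1L)
  s <- field[up, , drop = FALSE] + field[dn, , drop = FALSE] +
    field[, lf, drop = FALSE] + field[, rt, drop = FALSE]
  if (neighborhood == "von_neumann") return(s / 4)
  s <- s + field[up, lf, drop = FALSE] + field[up, rt, drop = FALSE] +
    field[dn, lf, drop = FALSE] + field[dn, rt, drop = FALSE]
  s / 8
}

# assemble the flat parameter list the C++ kernel expects
pde_par_list <- function(params) {
  list(aR = params$aR, dR = params$dR, dP = params$dP, m = params$m,
       n0 = params$n0, D = params$D, Dn = params$Dn,
       sigma_a = params$sigma_a, dt = params$dt,
       a_min = params$a_min, a_max = params$a_max,
       mut_eps = params$mut_floor)
}

#' Advance the lattice state by one forward-Euler step
#'
#' One step of the discretized reaction-diffusion update.  Per cell, in
#' order: replicase production `aR*dt*r^2*(1-m)*n` and parasite production
#' `dt*r*(aR*r*m + a*p)*n`; if their sum exceeds the available resource
#' `n`, both are rescaled by `n/sum` (resource limitation); growth, decay,
#' and neighbor-exchange diffusion are then applied to `r` and `p`; the
#' affinity mass `a*p` is diffused as a conserved quantity and divided by
#' the pre-step parasite density; resources gain `n0*dt`, lose the
#' consumed amount, and diffuse with constant `Dn`; the affinity is
#' perturbed by a Gaussian of s.d.
#' `sigma_a*sqrt(dt)/sqrt(max(p, mut_floor))` (mutation, slower in large
#' populations, capped at the single-molecule scale in sparse cells);
#' finally negatives are clamped to 0 and the affinity to
#' `[a_min, a_max]`.
#'
#' When stepping manually the mutation noise stream is re-seeded from
#' `config$seed + state$step` each call, so a step-by-step walk matches a
#' single [run_pde()] call exactly only when `sigma_a = 0`.
#'
#' @param state An `rp_grid_state`.
#' @param config An [pde_run_config()] object.
#' @return The updated `rp_grid_state`.
#' @export
pde_step <- function(state, config) {
  stopifnot(inherits(state, "rp_grid_state"),
            inherits(config, "rp_pde_config"))
  res <- .pde_run_cpp(state$r, state$p, state$a, state$n,
                      state$t, state$step, pde_par_list(config$params),
                      1L, config$seed + state$step,
                      config$trace_point[1L] - 1L,
                      config$trace_point[2L] - 1L, 0L,
                      config$neighborhood == "moore")
  structure(list(r = res$r, p = res$p, a = res$a, n = res$n,
                 t = res$t, step = res$step),
            class = "rp_grid_state")
}

#' Run the reaction-diffusion simulation
#'
#' Iterates the forward-Euler lattice update for `config$steps` steps,
#' recording per-step field totals, the parasite-density-weighted mean
#' affinity, the affinity trace at `config$trace_point`, and (optionally)
#' full field snapshots.  Runs are deterministic given `config$seed`.
#'
#' @param config An [pde_run_config()] object.
#' @param state Optional starting state; defaults to [init_uniform()].
#' @return An object of class `c("rp_pde_run", "rp_run")` with the time
#'   series (`times`, `replicase_series`, `parasite_series`,
#'   `resource_series`, `affinity_series`, `trace`), snapshots, the final
#'   `state`, the `config`, and an `outcome` label (`"Alive"` or
#'   `"Extinction"`, by mean density against `config$extinction_eps`).
#' @examples
#' cfg <- pde_run_config(pde_params(sigma_a = 0), sizeX = 8, sizeY = 8,
#'                       steps = 100)
#' run <- run_pde(cfg)
#' run$outcome
#' @export
run_pde <- function(config, state = init_uniform(config)) {
  stopifnot(inherits(config, "rp_pde_config"),
            inherits(state, "rp_grid_state"))
  res <- .pde_run_cpp(state$r, state$p, state$a, state$n,
                      state$t, state$step, pde_par_list(config$params),
                      config$steps, config$seed,
                      config$trace_point[1L] - 1L,
                      config$trace_point[2L] - 1L,
                      config$snapshot_every,
                      config$neighborhood == "moore")
  final <- structure(list(r = res$r, p = res$p, a = res$a, n = res$n,
                          t = res$t, step = res$step),
                     class = "rp_grid_state")
  ncell <- config$sizeX * config$sizeY
  out <- list(times = res$rec_t,
              step = seq_along(res$rec_t) - 1L + state$step,
              replicase_series = res$rec_r,
              parasite_series = res$rec_p,
              resource_series = res$rec_n,
              affinity_series = res$rec_a,
              trace = res$rec_trace,
              snapshots = if (config$snapshot_every > 0) res$snapshots,
              snapshot_steps = if (config$snapshot_every > 0) res$snap_steps,
              state = final, config = config, ncell = ncell)
  out$outcome <- if (min(utils::tail(res$rec_r, 1L),
                         utils::tail(res$rec_p, 1L)) / ncell <
                     config$extinction_eps) "Extinction" else "Alive"
  structure(out, class = c("rp_pde_run", "rp_run"))
}
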