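# Independent oracles used across the test files.

# residuals of the three homogeneous balance equations at a state (n, r, p)
balance_residuals <- function(params, aP, n, r, p) {
  c(resource  = params$n0 - n * r * (params$aR * r + aP * p),
    replicase = (1 - params$m) * params$aR * n * r^2 - params$dR * r,
    parasite  = params$m * params$aR * n * r^2 + aP * n * r * p -
      params$dP * p)
}

# literal R transcription of one lattice step (vectorized), kept separate
# from the compiled kernel so the two can be compared on small lattices
reference_pde_step <- function(st, params, neighborhood = "moore") {
  r <- st$r; pp <- st$p; a <- st$a; n <- st$n
  dt <- params$dt
  nb <- function(f) neighbor_average(f, neighborhood)
  new_r <- params$aR * dt * r^2 * (1 - params$m) * n
  new_p <- dt * r * (params$aR * r * params$m + a * pp) * n
  used <- new_r + new_p
  f <- ifelse(used > 0 & used > n, n / used, 1)
  new_r <- new_r * f; new_p <- new_p * f; used <- used * f
  ap <- a * pp
  r2 <- r + new_r - params$dR * dt * r + params$D * dt * (nb(r) - r)
  p2 <- pp + new_p - params$dP * dt * pp + params$D * dt * (nb(pp) - pp)
  nap <- ap + params$D * dt * (nb(ap) - ap)
  a2 <- ifelse(pp > 0, nap / pp, a)
  n2 <- n + params$n0 * dt - used + params$Dn * dt * (nb(n) - n)
  list(r = pmax(r2, 0), p = pmax(p2, 0),
       a = pmin(pmax(a2, params$a_min), params$a_max), n = pmax(n2, 0))
}

# all-pairs periodic neighbor search (quadratic, used as the oracle for
# the spatial-hash search)
brute_force_neighbors <- function(x, y, sizeX, sizeY, radius) {
  n <- length(x)
  lapply(seq_len(n), function(i) {
    dx <- abs(x[i] - x); dx <- pmin(dx, sizeX - dx)
    dy <- abs(y[i] - y); dy <- pmin(dy, sizeY - dy)
    setdiff(which(dx^2 + dy^2 < radius^2), i)
  })
}

# random parameter set with a guaranteed positive persistence margin and
# interior miscopy probability
random_persistent_params <- function() {
  repeat {
    p <- pde_params(aR = runif(1, 0.2, 2), aP0 = runif(1, 0, 1),
                    dR = runif(1, 0.01, 0.5), dP = runif(1, 0.01, 0.5),
                    m = runif(1, 0.01, 0.6), n0 = runif(1, 0.2, 2),
                    sigma_a = 0)
    if (persistence_margin(p) > 0.01) return(p)
  }
}
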