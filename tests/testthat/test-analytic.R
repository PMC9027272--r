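test_that("persistence margin matches its closed form and edge cases", {
  # symmetric rates sit exactly on the coexistence boundary
  expect_equal(persistence_margin(pde_params(aR = 1, dR = 0.1, dP = 0.1,
                                             m = 0), aP = 1), 0)
  # replicase affinity 1.0, parasite 0.6, equal decay: survival regime
  expect_equal(persistence_margin(pde_params(aR = 1, dR = 0.1, dP = 0.1,
                                             m = 0), aP = 0.6), 0.4)
  expect_error(persistence_margin(pde_params(dP = 0)), "dP")
  p <- pde_params(); p$aR <- 0   # bypass constructor check on purpose
  expect_error(persistence_margin(p), "aR")
})

test_that("steady state zeroes the homogeneous balance equations", {
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.01, dP = 0.01, m = 0.01,
                  n0 = 1)
  ss <- steady_state(p)
  res <- balance_residuals(p, 0.5, ss$n, ss$r, ss$p)
  expect_lt(max(abs(res)), 1e-12)
  expect_equal(ss$p, ss$A * ss$r)
  expect_true(ss$r > 0 && ss$p > 0 && ss$n > 0)
})

test_that("steady state residuals vanish across random persistent systems", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_persistent_params()
    ss <- steady_state(p)
    scale <- max(abs(c(p$n0, ss$r * p$dR, ss$p * p$dP)))
    res <- balance_residuals(p, p$aP0, ss$n, ss$r, ss$p)
    expect_lt(max(abs(res)) / scale, 1e-10)
  }
})

test_that("degenerate and impossible equilibria are signaled", {
  # m = 0 with matched rates: any proportion works, no unique point
  d0 <- steady_state(pde_params(m = 0, aR = 1, aP0 = 1, dR = 0.01,
                                dP = 0.01))
  expect_s3_class(d0, "rp_degenerate_state")
  expect_true(d0$coexistence_any_proportion)
  d1 <- steady_state(pde_params(m = 0, aR = 1, aP0 = 0.9, dR = 0.01,
                                dP = 0.01))
  expect_false(d1$coexistence_any_proportion)
  # m = 1: replication fully ineffective
  expect_error(steady_state(pde_params(m = 1)), "ineffective")
  # violated persistence inequality
  expect_error(steady_state(pde_params(m = 0.5, aP0 = 1, dR = 0.1,
                                       dP = 0.1)), "no positive")
})

test_that("margin sign is coherent with steady-state existence", {
  set.seed(7)
  for (i in 1:30) {
    p <- pde_params(aR = runif(1, 0.2, 2), aP0 = runif(1, 0, 1.5),
                    dR = runif(1, 0.01, 0.5), dP = runif(1, 0.01, 0.5),
                    m = runif(1, 0.01, 0.9), sigma_a = 0, a_max = 2)
    mar <- persistence_margin(p)
    if (mar > 0) expect_s3_class(steady_state(p), "rp_steady_state")
    else expect_error(steady_state(p))
  }
})

test_that("margin sign predicts the long-run parasite fate in the ODE", {
  set.seed(3)
  # positive margin: trajectory started near the fixed point stays interior
  p <- random_persistent_params()
  ss <- steady_state(p)
  tr <- integrate_well_mixed(p, init = c(ss$n, ss$r * 1.05, ss$p),
                             horizon = 2000, dt = 0.05)
  expect_gt(min(utils::tail(tr$r, 100)), 0.5 * ss$r)
  expect_gt(min(utils::tail(tr$p, 100)), 0)
  # negative margin: replicases collapse while parasites transiently grow
  pneg <- pde_params(aR = 1, aP0 = 1.5, dR = 0.2, dP = 0.2, m = 0.3,
                     sigma_a = 0, a_max = 2)
  expect_lt(persistence_margin(pneg), 0)
  trn <- integrate_well_mixed(pneg, init = c(1, 1, 0.5), horizon = 3000,
                              dt = 0.05)
  expect_lt(utils::tail(trn$r, 1), 1e-6)
  expect_gt(max(trn$p), 0.5)          # parasites grew before starving
  expect_lt(utils::tail(trn$p, 1), max(trn$p))
})

test_that("linearized replicase growth rate is positive at equilibria", {
  p <- pde_params(m = 0.01, aP0 = 0.5)
  ss <- steady_state(p)
  expect_equal(linear_growth_rate(p, ss$n, ss$r),
               (1 - p$m) * p$aR * ss$n * ss$r)
  expect_gt(linear_growth_rate(p, ss$n, ss$r), 0)
  expect_equal(linear_growth_rate(pde_params(m = 1), 1, 1), 0)
  expect_equal(linear_growth_rate(p, 0, 1), 0)
  set.seed(5)
  for (i in 1:10) {
    q <- random_persistent_params()
    s <- steady_state(q)
    expect_gt(linear_growth_rate(q, s$n, s$r), 0)
  }
})

test_that("pendulum coefficients collapse to closed forms at p = 0", {
  p <- pde_params(aR = 1, dR = 0.01, n0 = 1, m = 0)
  red <- pendulum_coefficients(p, aP = 1, p_fixed = 0)
  expect_equal(red$yE, 0.01)              # dR / n0
  expect_equal(red$yC, 10)                # sqrt(aR / dR)
  expect_equal(red$P(red$yE), 0)
})

test_that("pendulum equilibrium and critical point match root finders", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_persistent_params()
    ss <- steady_state(p)
    red <- pendulum_coefficients(p, p_fixed = ss$p)
    # yE is the root of the force term
    root <- stats::uniroot(red$P, c(red$yE / 100, red$yE * 100),
                           tol = 1e-14)$root
    expect_equal(red$yE, root, tolerance = 1e-8)
    expect_equal(red$yE, 1 / ss$r, tolerance = 1e-10)
    # yC is the largest root of the friction boundary dR*y^2 - aP*p*y - aR
    qr <- polyroot(c(-p$aR, -p$aP0 * ss$p, p$dR))
    expect_equal(red$yC, max(Re(qr)), tolerance = 1e-10)
    expect_lt(abs(red$Q(red$yC)), 1e-10)
    # force is positive below yE and negative above it
    expect_true(all(red$P(red$yE * c(0.2, 0.5, 0.9)) > 0))
    expect_true(all(red$P(red$yE * c(1.1, 2, 5)) < 0))
  }
  expect_error(pendulum_coefficients(pde_params(m = 0.1), aP = 1,
                                     p_fixed = 1e9), "no positive")
})

test_that("pendulum trajectory is damped below the critical point", {
  # a high-turnover regime where the friction term is weak enough for the
  # trajectory to be underdamped, as in the pendulum picture
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.8, dP = 0.8, m = 0.1,
                  sigma_a = 0)
  ss <- steady_state(p)
  red <- pendulum_coefficients(p, p_fixed = ss$p)
  y0 <- red$yE * 0.9
  expect_lt(y0, red$yC)
  pd <- integrate_pendulum(red, y0 = y0, v0 = 0, horizon = 200, dt = 0.01)
  expect_false(attr(pd, "diverged"))
  dev <- abs(pd$y - red$yE)
  third <- nrow(pd) %/% 3
  expect_lt(max(dev[(2 * third):nrow(pd)]), 0.2 * max(dev[1:third]))
  # it oscillates (crosses the equilibrium) before settling
  expect_gt(sum(diff(sign(pd$y - red$yE)) != 0), 2)
})

test_that("pendulum trajectory past the critical point diverges", {
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.3, dP = 0.3, m = 0.1,
                  sigma_a = 0)
  pfix <- 0.9 * p$n0 * (1 - p$m) * p$aR / (p$dR * 0.5)
  red <- pendulum_coefficients(p, p_fixed = pfix)
  y0 <- 1.2 * red$yC
  v0 <- p$dR * y0 - (1 - p$m) * p$aR * 0.01   # matched to a resource-poor state
  pd <- integrate_pendulum(red, y0 = y0, v0 = v0, horizon = 500, dt = 0.002)
  expect_true(attr(pd, "diverged"))
  expect_lt(nrow(pd), 500 / 0.002 + 1)        # truncated at the cap
})

test_that("pendulum reduction reproduces the parasite-clamped ODE", {
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.3, dP = 0.3, m = 0.1,
                  sigma_a = 0)
  ss <- steady_state(p)
  red <- pendulum_coefficients(p, p_fixed = ss$p)
  init <- c(ss$n, ss$r * 1.1, ss$p)
  y0 <- 1 / init[2]
  v0 <- p$dR * y0 - (1 - p$m) * p$aR * init[1]
  tr <- integrate_well_mixed(p, init = init, horizon = 40, dt = 0.002,
                             clamp_p = TRUE)
  pd <- integrate_pendulum(red, y0 = y0, v0 = v0, horizon = 40, dt = 0.002)
  expect_lt(max(abs(1 / tr$r - pd$y) / pd$y), 1e-3)
})

test_that("well-mixed integration holds the fixed point", {
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.8, dP = 0.8, m = 0.1,
                  sigma_a = 0)
  ss <- steady_state(p)
  tr <- integrate_well_mixed(p, init = c(ss$n, ss$r, ss$p), horizon = 50,
                             dt = 0.01)
  expect_lt(max(abs(tr$n - ss$n) / ss$n), 1e-9)
  expect_lt(max(abs(tr$r - ss$r) / ss$r), 1e-9)
  expect_lt(max(abs(tr$p - ss$p) / ss$p), 1e-9)
})

test_that("inverse replicase density oscillates with damping near balance", {
  p <- pde_params(aR = 1, aP0 = 0.5, dR = 0.8, dP = 0.8, m = 0.1,
                  sigma_a = 0)
  ss <- steady_state(p)
  tr <- integrate_well_mixed(p, init = c(ss$n, ss$r * 1.1, ss$p),
                             horizon = 100, dt = 0.01)
  y <- 1 / tr$r
  dev <- abs(y - 1 / ss$r)
  half <- length(y) %/% 2
  expect_lt(max(dev[half:length(y)]), max(dev[1:half]))
  expect_gt(sum(diff(sign(y - 1 / ss$r)) != 0), 2)
})
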