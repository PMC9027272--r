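test_that("decay probability follows the exponential law", {
  expect_equal(decay_probability(0, 1), 0)
  expect_equal(decay_probability(0.1, 1), 1 - exp(-0.1))
  expect_equal(decay_probability(0.1, 1e9), 1)
  expect_error(decay_probability(-1, 1))
})

test_that("remaining life times reproduce per-step Bernoulli decay", {
  expect_identical(sample_rlt(0.1, 1, x = 1), 1L)
  expect_identical(sample_rlt(0.1, 1, x = exp(-0.25)), 3L)  # floor(2.5)+1
  expect_error(sample_rlt(0.1, 1, x = 0))
  expect_error(sample_rlt(0, 1, x = 0.5))
  # geometric law: mean within 3 standard errors at n = 1e5
  set.seed(31)
  draws <- sample_rlt(0.1, 1, x = runif(1e5))
  mu <- 1 / (1 - exp(-0.1))
  expect_lt(abs(mean(draws) - mu), 3 * stats::sd(draws) / sqrt(1e5))
  # and the full distribution is geometric (chi-squared-free check via KS)
  emp <- stats::ecdf(draws)
  k <- 1:200
  ks <- max(abs(emp(k) - (1 - exp(-0.1 * k))))
  expect_lt(ks, 1.63 / sqrt(1e5))   # alpha = 0.01 critical value
})

test_that("Brownian displacements have the prescribed moments", {
  expect_equal(brownian_displacement(15, 1, xi = c(0, 0)), c(0, 0))
  set.seed(17)
  n <- 1e5
  steps <- matrix(brownian_displacement(15, 1, xi = rnorm(2 * n)),
                  ncol = 2)
  sd_theo <- sqrt(2 * 15 * 1)
  se <- sd_theo / sqrt(2 * n)       # SE of a sample s.d., approximately
  expect_lt(abs(stats::sd(steps) - sd_theo), 3 * se * sqrt(2))
  msd <- mean(rowSums(steps^2))
  expect_lt(abs(msd - 4 * 15 * 1),
            3 * stats::sd(rowSums(steps^2)) / sqrt(n))
})

test_that("spatial-hash neighbor search equals brute force", {
  par <- mas_params(sizeX = 200, sizeY = 200)
  set.seed(23)
  n <- 1000
  pop <- population(x = runif(n, 0, 200), y = runif(n, 0, 200),
                    type = rep("replicase", n), kP = NA_real_,
                    rlt = rep(5L, n), params = par)
  want <- brute_force_neighbors(pop$x, pop$y, 200, 200,
                                2 * par$agent_size)
  for (i in c(1L, 7L, 500L, 1000L))
    expect_identical(sort(find_neighbors(i, pop, par)),
                     as.integer(want[[i]]))
  # full agreement across every agent
  got <- .neighbors_binned_cpp(pop$x, pop$y, 200, 200,
                               2 * par$agent_size)
  expect_identical(lapply(got, sort), lapply(want, as.integer))
})

test_that("overlap uses a strict center-distance threshold with wrap", {
  par <- mas_params(sizeX = 100, sizeY = 100)   # interaction radius 6
  mk <- function(x1, x2) population(x = c(x1, x2), y = c(10, 10),
                                    type = rep("parasite", 2),
                                    kP = c(0.5, 0.5), rlt = c(5L, 5L),
                                    params = par)
  expect_identical(find_neighbors(1, mk(10, 10), par), 2L)    # coincident
  expect_identical(find_neighbors(1, mk(10, 15.999), par), 2L)
  expect_length(find_neighbors(1, mk(10, 16), par), 0L)       # exactly 2R
  # wrap-around: distance 4 across the boundary
  expect_identical(find_neighbors(1, mk(2, 98), par), 2L)
  expect_identical(find_neighbors(2, mk(2, 98), par), 1L)
})

test_that("replication respects pair types and probability endpoints", {
  par <- mas_params(mP = 0)
  pop <- population(x = c(0, 1), y = c(0, 0),
                    type = c("parasite", "parasite"), kP = c(1, 1),
                    rlt = c(9L, 9L), params = par)
  set.seed(1)
  for (i in 1:20) expect_null(attempt_replication(1, 2, pop, par))
  # replicase + parasite with kP = 1 always copies the parasite
  rp <- population(x = c(0, 1), y = c(0, 0),
                   type = c("replicase", "parasite"), kP = c(NA, 1),
                   rlt = c(9L, 9L), params = par)
  child <- attempt_replication(1, 2, rp, par)
  expect_identical(child$type, "parasite")
  expect_identical(child$x, rp$x[2])       # placed at the template
  expect_identical(child$kP, 1)            # mP = 0: no mutation
  expect_gte(child$rlt, 1L)
  # the parasite can be the visiting agent too; the template is itself
  child2 <- attempt_replication(2, 1, rp, par)
  expect_identical(child2$type, "parasite")
  expect_identical(child2$x, rp$x[2])
  # replicase pairs follow kR exactly at the endpoints
  rr <- population(x = c(0, 1), y = c(0, 0), type = rep("replicase", 2),
                   kP = c(NA_real_, NA_real_), rlt = c(9L, 9L),
                   params = par)
  par0 <- mas_params(kR = 0); par1 <- mas_params(kR = 1)
  for (i in 1:20) expect_null(attempt_replication(1, 2, rr, par0))
  expect_identical(attempt_replication(1, 2, rr, par1)$type, "replicase")
})

test_that("mutation shifts kP by at most half the mutation width", {
  par <- mas_params(mP = 1, delta = 0.1)
  set.seed(19)
  out <- replicate(500, mutate_kp(0.5, par))
  expect_true(all(abs(out - 0.5) <= 0.05 + 1e-12))
  expect_gt(stats::sd(out), 0)
  # clamping at the upper bound
  top <- replicate(200, mutate_kp(1, par))
  expect_true(all(top <= 1) && all(top >= 0.95))
  # mP = 0 never mutates
  par0 <- mas_params(mP = 0)
  expect_identical(replicate(50, mutate_kp(0.3, par0)), rep(0.3, 50))
})

test_that("the step decrements lifetimes and removes crowded agents", {
  par <- mas_params(sizeX = 100, sizeY = 100, Nmax = 4L, D = 0, kR = 0)
  expect_identical(nrow(mas_step(
    population(numeric(0), numeric(0), character(0), numeric(0),
               integer(0), par), par)), 0L)
  # a lone agent with rlt = 1 dies during the step (decrement then remove)
  solo <- population(x = 5, y = 5, type = "replicase", kP = NA_real_,
                     rlt = 1L, params = par)
  set.seed(2)
  expect_identical(nrow(mas_step(solo, par)), 0L)
  # an agent overlapped by Nmax + 1 others is removed by crowding; once
  # one has died the rest are at exactly Nmax neighbors and survive
  clump <- population(x = c(50, rep(50.1, 5)), y = c(50, rep(50, 5)),
                      type = rep("parasite", 6), kP = rep(0, 6),
                      rlt = rep(10L, 6), params = par)
  set.seed(3)
  out <- mas_step(clump, par)
  expect_identical(nrow(out), 5L)
})

test_that("parasite-only populations can only shrink", {
  par <- mas_params(sizeX = 200, sizeY = 200, D = 5)
  set.seed(4)
  pop <- population(x = runif(60, 0, 200), y = runif(60, 0, 200),
                    type = rep("parasite", 60), kP = runif(60),
                    rlt = sample(1:15, 60, TRUE), params = par)
  sizes <- nrow(pop)
  for (s in 1:10) {
    pop <- mas_step(pop, par)
    sizes <- c(sizes, nrow(pop))
  }
  expect_true(all(diff(sizes) <= 0))
})

test_that("agent runs are seed-deterministic and respect the stop rule", {
  par <- mas_params(sizeX = 150, sizeY = 150, n_replicases0 = 80,
                    n_parasites0 = 80, time_limit = 50, seed = 6)
  r1 <- run_mas(par); r2 <- run_mas(par)
  expect_identical(r1$replicase_series, r2$replicase_series)
  expect_identical(r1$parasite_series, r2$parasite_series)
  expect_identical(r1$final$x, r2$final$x)
  # without parasites the while condition fails immediately
  r0 <- run_mas(mas_params(n_parasites0 = 0, time_limit = 100))
  expect_identical(r0$steps_run, 0L)
  expect_identical(r0$outcome, "Extinction")
})

test_that("engine lifetimes follow the geometric law when inert", {
  # reactions off: count decrements are the lifetime distribution of the
  # initial cohort
  par <- mas_params(sizeX = 2000, sizeY = 2000, n_replicases0 = 5000,
                    n_parasites0 = 5000, kR = 0, kP0 = 0,
                    time_limit = 200, seed = 7)
  r <- run_mas(par)
  tot <- r$replicase_series + r$parasite_series
  deaths <- -diff(tot)
  n <- sum(deaths)
  expect_gt(n, 9000)
  emp <- cumsum(deaths) / n
  theo <- 1 - exp(-par$d * par$dt)^(seq_along(emp))
  expect_lt(max(abs(emp - theo)), 1.63 / sqrt(n))
  life <- rep(seq_along(deaths), deaths)
  mu <- 1 / (1 - exp(-par$d * par$dt))
  expect_lt(abs(mean(life) - mu), 3 * stats::sd(life) / sqrt(n))
})

test_that("engine displacement matches the diffusion law", {
  # immortal, inert agents; track everyone across one step via snapshots
  par <- mas_params(sizeX = 5000, sizeY = 5000, n_replicases0 = 5000,
                    n_parasites0 = 5000, kR = 0, kP0 = 0, d = 0,
                    Nmax = 1000L, D = 15, time_limit = 1, seed = 12)
  r <- run_mas(par, snapshot_every = 1)
  s0 <- r$snapshots[[1]]; s1 <- r$snapshots[[2]]
  dx <- abs(s1$x - s0$x); dx <- pmin(dx, par$sizeX - dx)
  dy <- abs(s1$y - s0$y); dy <- pmin(dy, par$sizeY - dy)
  sq <- dx^2 + dy^2
  msd <- mean(sq)
  expect_lt(abs(msd - 4 * par$D * par$dt),
            3 * stats::sd(sq) / sqrt(length(sq)))
})

test_that("selection pushes the mean replication probability upward", {
  # surviving spatial runs with mutation on: parasites evolve toward
  # better templates
  up <- 0
  surv <- 0
  for (s in 1:3) {
    par <- mas_params(sizeX = 400, sizeY = 400, n_replicases0 = 500,
                      n_parasites0 = 500, D = 5, mP = 0.1,
                      time_limit = 1000, seed = 40 + s)
    r <- run_mas(par)
    if (r$outcome == "Alive") {
      surv <- surv + 1
      fin <- r$affinity_series[length(r$affinity_series)]
      if (is.finite(fin) && fin > par$kP0) up <- up + 1
    }
  }
  expect_gt(surv, 0)
  expect_gt(up / surv, 0.5)
})
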