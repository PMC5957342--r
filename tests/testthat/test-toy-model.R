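test_that("potential energy matches hand-derived values and vanishes for inert species", {
  inert <- species("inert", charge = 0, lj_epsilon = 0)
  st0 <- site_model(centers = data.frame(x = 0.2, y = 0, z = 0, charge = 0.5,
                                         lj_epsilon = 1, lj_sigma = 0.3))
  for (x in list(c(0, 0, 0), c(0.4, -0.2, 0.1)))
    expect_equal(potential_energy(st0, inert, x), 0)

  # LJ zero crossing at r = sigma_ij
  lj <- species("lj", lj_epsilon = 0.5, lj_sigma = 0.3)
  st1 <- site_model(centers = data.frame(x = 0.3, y = 0, z = 0, charge = 0,
                                         lj_epsilon = 0.5, lj_sigma = 0.3))
  expect_equal(potential_energy(st1, lj, c(0, 0, 0)), 0, tolerance = 1e-12)

  # bare Coulomb pair: -f / (D r)
  ion <- species("ion", charge = -1)
  st2 <- site_model(centers = data.frame(x = 0.2, y = 0, z = 0, charge = 1,
                                         lj_epsilon = 0, lj_sigma = 0.3))
  expect_equal(potential_energy(st2, ion, c(0, 0, 0)),
               -138.935458 / 0.2, tolerance = 1e-10)

  # cage contributes K|x - c|^2 / 2
  stc <- cage_site(200)
  expect_equal(potential_energy(stc, inert, c(0.1, 0, 0)), 0.5 * 200 * 0.01)

  expect_error(potential_energy(st2, ion, c(0.2, 0, 0)), "singular")
})

test_that("constructors enforce the model invariants", {
  expect_error(species("x", lj_epsilon = -1), "lj_epsilon")
  expect_error(species("x", lj_sigma = 0), "lj_sigma")
  expect_error(site_model(escape_radius = 1.0, box_halfwidth = 0.9),
               "escape_radius")
  expect_error(site_model(dielectric = 0.5), "dielectric")
  expect_error(simulation_params(n_steps = 100, burn_in_steps = 100),
               "burn_in")
  expect_error(simulation_params(dt = 0), "dt")
})

test_that("Langevin sampling satisfies equipartition in a harmonic cage", {
  st <- cage_site(200)
  p <- simulation_params(n_steps = 4e5, seed = 7, sample_stride = 10)
  tr <- simulate_langevin(st, species("w"), p)
  expect_equal(dim(tr$positions), c(4e4, 3))
  target <- kT300 / 200
  # block-averaged standard error of the per-coordinate variance
  nb <- 10
  idx <- cut(seq_along(tr$times), nb, labels = FALSE)
  for (k in 1:3) {
    v <- var(tr$positions[, k])
    bv <- vapply(split(tr$positions[, k], idx), var, numeric(1))
    se <- sd(bv) / sqrt(nb)
    expect_lt(abs(v - target), 3 * se)
  }
})

test_that("the same seed reproduces a trajectory bit for bit", {
  st <- cage_site(150)
  p <- simulation_params(n_steps = 2e4, seed = 123)
  t1 <- simulate_langevin(st, species("w"), p)
  t2 <- simulate_langevin(st, species("w"), p)
  expect_identical(t1$positions, t2$positions)
  p2 <- p; p2$seed <- 124L
  t3 <- simulate_langevin(st, species("w"), p2)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("force-free motion reproduces the overdamped diffusion law", {
  # msd over T equals 2 kB T / (m gamma) * T per dimension at high friction
  gam <- 50; m <- 18.015; Tlen <- 20
  st <- site_model(box_halfwidth = 50, escape_radius = 49)
  sp <- ghost_species(mass = m)
  n_rep <- 120
  d2 <- vapply(seq_len(n_rep), function(r) {
    p <- simulation_params(n_steps = 2000, dt = 0.01, friction = gam,
                           seed = 9000 + r, sample_stride = 2000)
    tr <- simulate_langevin(st, sp, p, x0 = c(0, 0, 0))
    sum(tr$positions[1, ]^2)
  }, numeric(1))
  expected <- 3 * 2 * kT300 / (m * gam) * Tlen
  se <- sd(d2) / sqrt(n_rep)
  expect_lt(abs(mean(d2) - expected), 3 * se)
})

test_that("sampled configurations follow the Boltzmann distribution in a double well", {
  dw <- site_model(centers = data.frame(x = c(0.4, -0.4), y = 0, z = 0,
                                        charge = 0, lj_epsilon = 3.0,
                                        lj_sigma = 0.22),
                   cage_k = 80, box_halfwidth = 0.5, escape_radius = 0.45)
  sp <- species("p", lj_epsilon = 3.0, lj_sigma = 0.22)
  p <- simulation_params(n_steps = 2.5e7, seed = 17, dt = 0.004, friction = 2,
                         sample_stride = 250)
  tr <- simulate_langevin(dw, sp, p)
  x <- tr$positions[, 1]
  expect_length(x, 1e5)
  # independent oracle: numeric marginal of exp(-U/kT) over y, z
  yg <- seq(-0.5, 0.5, length.out = 51)
  xg <- seq(-0.5, 0.5, length.out = 201)
  marg <- vapply(xg, function(xx) {
    u <- 0
    for (cx in dw$centers$x) {
      r2 <- (xx - cx)^2 + outer(yg^2, yg^2, "+")
      s6 <- (0.22^2 / r2)^3
      u <- u + 4 * 3 * (s6^2 - s6)
    }
    u <- u + 0.5 * 80 * (xx^2 + outer(yg^2, yg^2, "+"))
    mean(exp(-pmin(u, 400) / kT300))
  }, numeric(1))
  pe <- approxfun(xg, marg, rule = 2)
  breaks <- seq(-0.5, 0.5, length.out = 26)
  probs <- vapply(1:25, function(i)
    integrate(pe, breaks[i], breaks[i + 1])$value, numeric(1))
  probs <- probs / sum(probs)
  obs <- hist(x, breaks = breaks, plot = FALSE)$counts
  gof <- merged_gof(obs, probs)
  expect_gt(gof$p.value, 0.01)
  # and the double well is genuinely bimodal with symmetric occupancy
  expect_gt(mean(x > 0), 0.4)
  expect_gt(mean(x < 0), 0.4)
})

test_that("dH/dlambda sampling matches the Gaussian closed form in a harmonic switch", {
  sp <- species("w")
  al <- alchemical_hamiltonian("relative",
                               state_A = list(site = cage_site(100), species = sp),
                               state_B = list(site = cage_site(400), species = sp))
  p <- simulation_params(n_steps = 1e5, burn_in_steps = 1e4, seed = 31,
                         sample_stride = 10)
  for (lam in c(0.3, 0.7)) {
    s <- sample_dhdl(al, lam, p)
    expect_equal(s$lam, lam)
    wm <- window_mean(s)
    Klam <- 100 + 300 * lam
    expected <- 0.5 * 300 * 3 * kT300 / Klam
    expect_lt(abs(wm$mean - expected), 3 * wm$sem)
  }
  # lambda-independent Hamiltonians give exactly zero derivatives
  al0 <- alchemical_hamiltonian("relative",
                                state_A = list(site = cage_site(100), species = sp),
                                state_B = list(site = cage_site(100), species = sp),
                                softcore = soft_core_params(alpha = 0))
  s0 <- sample_dhdl(al0, 0.4, simulation_params(n_steps = 5000, seed = 5))
  expect_true(all(s0$values == 0))
})

test_that("synthetic escape-time generation matches the exponential survival law", {
  # negligible censoring: every molecule escapes, mean near the true lifetime
  d1 <- generate_survival_synthetic(true_tau = 0.5, M = 2000, T_s = 40,
                                    seed = 2)
  expect_equal(sum(d1$events$escaped), 2000)
  expect_lt(abs(mean(d1$events$time) - 0.5), 3 * 0.5 / sqrt(2000))
  # overwhelming censoring: no escapes
  d2 <- generate_survival_synthetic(true_tau = 1e7, M = 50, T_s = 1, seed = 3)
  expect_equal(sum(d2$events$escaped), 0)
  # censored fraction ~ exp(-T_s / tau) within binomial 3 sigma
  d3 <- generate_survival_synthetic(true_tau = 50, M = 2000, T_s = 40,
                                    seed = 4)
  pc <- exp(-40 / 50)
  frac <- 1 - sum(d3$events$escaped) / 2000
  expect_lt(abs(frac - pc), 3 * sqrt(pc * (1 - pc) / 2000))
})

test_that("trajectory CSV export round-trips positions", {
  st <- cage_site(100)
  tr <- simulate_langevin(st, species("w"),
                          simulation_params(n_steps = 1000, seed = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  export_trajectory_csv(tr, f)
  df <- read.csv(f)
  expect_equal(df$x_nm, tr$positions[, 1], tolerance = 1e-12)
  expect_equal(df$time_ps, tr$times, tolerance = 1e-12)
})
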