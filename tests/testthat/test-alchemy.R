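test_that("soft-core distance has the Beutler form and its limits", {
  sc <- soft_core_params()      # alpha 0.5, sigma 0.3, power 1
  expect_equal(softcore_distance(0.5, 0, sc), 0.5)
  expect_equal(softcore_distance(0, 0.5, sc),
               (0.5 * 0.3^6 * 0.5)^(1 / 6), tolerance = 1e-12)
  expect_equal(softcore_distance(0, 0.5, sc), 0.23811, tolerance = 1e-4)
  # monotone non-decreasing in the soft-core weight
  for (r in c(0, 0.1, 0.35)) {
    d <- softcore_distance(r, seq(0, 1, 0.05), sc)
    expect_true(all(diff(d) >= 0))
  }
  expect_error(soft_core_params(power = 3), "power")
})

# two dissimilar interacting states over a 2-center site, used repeatedly
make_pair <- function() {
  st <- site_model(centers = data.frame(x = c(0.25, -0.2), y = c(0, 0.15),
                                        z = 0, charge = c(0.3, -0.2),
                                        lj_epsilon = c(1.5, 0.8),
                                        lj_sigma = c(0.28, 0.31),
                                        stringsAsFactors = FALSE),
                   dielectric = 2, cage_k = 30)
  ion <- species("ion", charge = -1, lj_epsilon = 0.6, lj_sigma = 0.35,
                 solvation = -20)
  wat <- species("wat", charge = 0, lj_epsilon = 1.2, lj_sigma = 0.3,
                 solvation = -5)
  alchemical_hamiltonian("relative", state_A = list(site = st, species = ion),
                         state_B = list(site = st, species = wat))
}

test_that("the coupled potential is exactly the end states at lambda 0 and 1", {
  al <- make_pair()
  stA <- al$state_A; stB <- al$state_B
  set.seed(42)
  for (i in 1:20) {
    x <- runif(3, -0.6, 0.6)
    expect_lt(abs(alchemical_potential(set_lambda(al, 0), x) -
                    potential_energy(stA$site, stA$species, x)), 1e-10)
    expect_lt(abs(alchemical_potential(set_lambda(al, 1), x) -
                    potential_energy(stB$site, stB$species, x)), 1e-10)
  }
})

test_that("soft-core removes the r = 0 singularity at intermediate coupling", {
  al <- make_pair()
  on_center <- c(0.25, 0, 0)   # exactly on an interacting center
  for (lam in c(0.05, 0.3, 0.5, 0.9, 0.95)) {
    a <- set_lambda(al, lam)
    expect_true(is.finite(alchemical_potential(a, on_center)))
    expect_true(is.finite(alchemical_dhdl(a, on_center)))
  }
  # vanishing single LJ center evaluated on top of the core:
  # (1-l) * 4 eps [ (s^6/(a s^6 l))^2 - s^6/(a s^6 l) ] at l = 0.5
  st <- site_model(centers = data.frame(x = 0, y = 0, z = 0, charge = 0,
                                        lj_epsilon = 0.5, lj_sigma = 0.3))
  lj <- species("p", lj_epsilon = 0.5, lj_sigma = 0.3)
  ghost <- ghost_species()
  alg <- alchemical_hamiltonian("relative",
                                state_A = list(site = st, species = lj),
                                state_B = list(site = st, species = ghost),
                                lam = 0.5)
  expect_equal(alchemical_potential(alg, c(0, 0, 0)),
               0.5 * 4 * 0.5 * (16 - 4), tolerance = 1e-10)
})

test_that("analytic dH/dlambda agrees with central finite differences", {
  al <- make_pair()
  set.seed(7)
  dl <- 1e-6
  worst <- 0
  for (i in 1:100) {
    lam <- runif(1, 0.02, 0.98)
    x <- runif(3, -0.5, 0.5)
    an <- alchemical_dhdl(set_lambda(al, lam), x)
    fd <- (alchemical_potential(set_lambda(al, lam + dl), x) -
             alchemical_potential(set_lambda(al, lam - dl), x)) / (2 * dl)
    worst <- max(worst, abs(an - fd) / max(1, abs(an)))
  }
  expect_lt(worst, 1e-5)
})

test_that("identical end states with no soft-core give zero derivative", {
  st <- site_model(centers = data.frame(x = 0.2, y = 0, z = 0, charge = 0.2,
                                        lj_epsilon = 1, lj_sigma = 0.3))
  sp <- species("s", charge = -0.4, lj_epsilon = 0.7)
  al <- alchemical_hamiltonian("relative",
                               state_A = list(site = st, species = sp),
                               state_B = list(site = st, species = sp),
                               softcore = soft_core_params(alpha = 0))
  set.seed(3)
  for (i in 1:10) {
    x <- runif(3, -0.5, 0.5)
    expect_equal(alchemical_dhdl(set_lambda(al, runif(1)), x), 0,
                 tolerance = 1e-12)
  }
})

test_that("restraint_on mode couples linearly: dV/dlambda equals the restraint energy", {
  st <- cage_site(50)
  sp <- species("w", lj_epsilon = 0.3)
  al <- alchemical_hamiltonian("restraint_on",
                               state_A = list(site = st, species = sp),
                               restraint = list(k = 200, center = c(0.1, 0, 0)))
  set.seed(11)
  for (i in 1:10) {
    x <- runif(3, -0.5, 0.5)
    ur <- 0.5 * 200 * sum((x - c(0.1, 0, 0))^2)
    expect_equal(alchemical_dhdl(set_lambda(al, runif(1)), x), ur,
                 tolerance = 1e-10)
  }
})

test_that("Coulomb decoupling leaves the LJ term at full, unsoftened strength", {
  st <- site_model(centers = data.frame(x = 0.28, y = 0, z = 0, charge = 0.5,
                                        lj_epsilon = 1, lj_sigma = 0.3))
  ion <- species("ion", charge = -1, lj_epsilon = 1, lj_sigma = 0.3)
  al <- alchemical_hamiltonian("decouple_coulomb",
                               state_A = list(site = st, species = ion))
  neutral <- ion; neutral$charge <- 0
  set.seed(5)
  for (i in 1:10) {
    x <- runif(3, -0.5, 0.5)
    # at lambda = 1 only the LJ (plus cage) part of state A remains
    expect_equal(alchemical_potential(set_lambda(al, 1), x),
                 potential_energy(st, neutral, x), tolerance = 1e-10)
  }
})

test_that("alchemical Hamiltonian construction validates its inputs", {
  st <- cage_site(10); sp <- species("s")
  expect_error(alchemical_hamiltonian("relative",
                                      state_A = list(site = st, species = sp)),
               "state_B")
  expect_error(alchemical_hamiltonian("restraint_on",
                                      state_A = list(site = st, species = sp)),
               "restraint")
  expect_error(alchemical_hamiltonian("plain",
                                      state_A = list(site = st, species = sp),
                                      lam = 1.2), "lam")
  expect_error(set_lambda(alchemical_hamiltonian(
    "plain", state_A = list(site = st, species = sp)), -0.1), "lam")
})
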