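test_that("the analytic restraint correction reproduces its closed form", {
  spec <- restraint_spec(k_x = 200, temperature = 300, v_standard = 0.02992)
  val <- restraint_free_energy(spec)
  expect_equal(as.numeric(val), 0.774225, tolerance = 0.0013)
  expect_equal(attr(val, "v_eff"), (2 * pi * kT300 / 200)^1.5,
               tolerance = 1e-12)
  # releasing into the larger standard volume is downhill
  expect_lt(attr(val, "release"), 0)
  # V-standard equal to V_eff gives zero
  veq <- restraint_spec(k_x = 200, temperature = 300,
                        v_standard = (2 * pi * kT300 / 200)^1.5)
  expect_equal(as.numeric(restraint_free_energy(veq)), 0, tolerance = 1e-12)
  # doubling V-standard at fixed V_eff adds kB T ln 2
  v2 <- restraint_spec(k_x = 200, temperature = 300, v_standard = 2 * 0.02992)
  expect_equal(as.numeric(restraint_free_energy(v2)) - as.numeric(val),
               kT300 * log(2), tolerance = 1e-10)
})

test_that("relative cycles combine legs with the Fig-2 sign convention", {
  mk <- function(g3, g2, s3 = 0, s2 = 0)
    relative_cycle(leg_g3 = leg_result("g3", g3, s3),
                   leg_g2 = leg_result("g2", g2, s2))
  expect_equal(relative_ddg(mk(7, 7))$ddg, 0)
  r <- relative_ddg(mk(-100, 135))
  expect_equal(r$ddg, -235)
  expect_equal(relative_ddg(mk(0, 0, 3, 4))$stderr, 5)
  # combined single-leg form
  rc <- relative_cycle(leg_site = leg_result("combined", -42, 1.5))
  expect_equal(relative_ddg(rc)$ddg, -42)
  expect_error(relative_cycle(leg_g3 = leg_result("g3", 1)), "leg_g2|leg_site")
})

test_that("absolute cycle assembly applies the analytic release and finds missing legs", {
  spec <- restraint_spec()
  legs_site <- list(leg_result("posre_on", 0), leg_result("coulomb_off", 0),
                    leg_result("lj_off", 0))
  legs_bulk <- list(leg_result("coulomb_off", 0), leg_result("lj_off", 0))
  out <- assemble_absolute(absolute_cycle(legs_site, legs_bulk), spec)
  expect_equal(abs(out$delta_g), as.numeric(restraint_free_energy(spec)),
               tolerance = 1e-12)
  expect_equal(out$stderr, 0)

  incomplete <- list(leg_result("coulomb_off", 1), leg_result("lj_off", 2))
  expect_error(assemble_absolute(absolute_cycle(incomplete, legs_bulk), spec),
               "posre_on")

  # error propagation in quadrature is sub-additive
  ls <- list(leg_result("posre_on", 1, 0.3), leg_result("coulomb_off", 2, 0.4),
             leg_result("lj_off", 3, 0.5))
  lb <- list(leg_result("coulomb_off", 4, 0.2), leg_result("lj_off", 5, 0.1))
  o2 <- assemble_absolute(absolute_cycle(ls, lb), spec)
  expect_lte(o2$stderr, 0.3 + 0.4 + 0.5 + 0.2 + 0.1)
  expect_equal(o2$stderr, sqrt(sum(c(0.3, 0.4, 0.5, 0.2, 0.1)^2)))
})

test_that("site identical to bulk yields zero binding free energy", {
  # both environments are the same solvated box; the standard volume is set
  # to the box volume so no net volume term remains
  h <- 0.31
  box <- site_model(box_halfwidth = h, escape_radius = 0.3,
                    solvation_scale = 1)
  sp <- species("w", lj_epsilon = 0, solvation = -12)
  spec <- restraint_spec(k_x = 200, temperature = 300, v_standard = (2 * h)^3)
  out <- absolute_binding_toy(box, box, sp, spec, n_steps = 4e4,
                              base_seed = 77, burn_in_steps = 4e3,
                              friction = 2, dt = 0.002, n_posre = 21)
  # simulated bulk and site posre legs are absent/present asymmetrically;
  # with identical Hamiltonians the assembly must still close to zero
  se <- max(out$stderr, 1e-3)
  expect_lt(abs(out$delta_g), 2 * se + 0.05)
})

test_that("a harmonic deep-well site matches the Gaussian closed form", {
  kc <- 120
  site <- site_model(cage_k = kc, box_halfwidth = 0.9, escape_radius = 0.6)
  bulk <- site_model(box_halfwidth = 0.9, escape_radius = 0.6,
                     solvation_scale = 1)
  # the well is 25 kJ/mol deeper than bulk: bulk solvation +25
  sp <- species("p", lj_epsilon = 0, solvation = 25)
  spec <- restraint_spec()
  out <- absolute_binding_toy(site, bulk, sp, spec, n_steps = 2e5,
                              base_seed = 31, burn_in_steps = 2e4,
                              friction = 2, dt = 0.001,
                              n_posre = 41, n_lj = 41)
  v_eff_cage <- (2 * pi * kT300 / kc)^1.5
  exact <- kT300 * log(spec$v_standard / v_eff_cage) - 25
  expect_lt(abs(out$delta_g - exact), 2 * out$stderr + 0.05)
})

test_that("occupancy ratios follow the Boltzmann relation", {
  expect_equal(occupancy_ratio(0, 55.5, 0.1), 555)
  # the inverse relation: the ratio is 1 when exp(-ddg/kT) cancels c_w/c_i
  ddg_inv <- kT300 * log(55.5 / 0.1)
  expect_equal(occupancy_ratio(ddg_inv, 55.5, 0.1), 1, tolerance = 1e-10)
  r <- occupancy_ratio(-235, 55.5, 0.1, 300)
  expect_equal(log10(r), log10(555) + 235 / (kT300 * log(10)),
               tolerance = 1e-10)
  expect_equal(log10(r), 43.7, tolerance = 0.02)
  big <- occupancy_ratio(-1e6, 55.5, 0.1)
  expect_true(is.infinite(big))
  expect_true(attr(big, "overflow"))
  expect_error(occupancy_ratio(0, -1, 1), "concentrations")
})
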