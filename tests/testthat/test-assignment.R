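test_that("the relative criterion separates robust from marginal differences", {
  expect_equal(criterion_relative(-235, 2, 20), "water_favored")
  expect_equal(criterion_relative(-6.2, 1.4, 20), "inconclusive")
  expect_equal(criterion_relative(0, 1, 20), "inconclusive")
  expect_equal(criterion_relative(150, 3, 20), "ion_favored")
  # beyond the threshold but not significant against its own error
  expect_equal(criterion_relative(-25, 30, 20), "inconclusive")
})

test_that("the absolute criterion accepts negative or near-zero binding", {
  expect_equal(criterion_absolute(-23.5, 0.5, 5), "plausible")
  expect_equal(criterion_absolute(-0.3, 0.9, 5), "plausible")
  expect_equal(criterion_absolute(50, 1, 5), "implausible")
  expect_equal(criterion_absolute(4.9, 0.1, 5), "plausible")
})

test_that("the stability criterion compares lifetimes conservatively", {
  b1600 <- lifetime_estimate(1600, lower_bound = TRUE)
  expect_equal(criterion_stability(b1600, lifetime_estimate(25)),
               "water_favored")
  expect_equal(criterion_stability(lifetime_estimate(50),
                                   lifetime_estimate(25)), "inconclusive")
  # a lower bound can only support its own species
  expect_equal(criterion_stability(lifetime_estimate(25), b1600),
               "ion_favored")
  short_bound <- lifetime_estimate(30, lower_bound = TRUE)
  expect_equal(criterion_stability(short_bound, lifetime_estimate(20)),
               "inconclusive")
  # two censored lifetimes never decide
  expect_equal(criterion_stability(short_bound, b1600), "inconclusive")
  # antisymmetry under swapping the species, over random cases
  set.seed(8)
  flip <- c(water_favored = "ion_favored", ion_favored = "water_favored",
            inconclusive = "inconclusive")
  for (i in 1:50) {
    tw <- lifetime_estimate(runif(1, 1, 2000), runif(1) < 0.3)
    ti <- lifetime_estimate(runif(1, 1, 2000), runif(1) < 0.3)
    expect_equal(criterion_stability(ti, tw),
                 unname(flip[criterion_stability(tw, ti)]))
  }
})

test_that("verdicts follow the conjunctive combination rule", {
  thr <- assignment_thresholds()
  # clear-cut water site: strongly negative relative difference, plausible
  # absolute binding, and a much longer water lifetime
  v1 <- verdict(site_assessment(
    ddg = -235, ddg_stderr = 2, dg_bind_water = -23.5, dg_bind_stderr = 0.5,
    tau_water = lifetime_estimate(1600, TRUE), tau_ion = lifetime_estimate(25),
    thresholds = thr))
  expect_equal(v1$call, "water_favored")
  expect_equal(v1$evidence$stability$label, "water_favored")

  # cation cage: free energies inconclusive, stability favors the ion
  v2 <- verdict(site_assessment(
    ddg = -6.2, ddg_stderr = 1.4,
    tau_water = lifetime_estimate(2), tau_ion = lifetime_estimate(100, TRUE),
    thresholds = thr))
  expect_equal(v2$call, "ion_favored")

  # all criteria inconclusive
  v3 <- verdict(site_assessment(ddg = 0, ddg_stderr = 1,
                                tau_water = lifetime_estimate(10),
                                tau_ion = lifetime_estimate(9),
                                thresholds = thr))
  expect_equal(v3$call, "inconclusive")

  # opposing evidence is surfaced as inconclusive, never averaged
  v4 <- verdict(site_assessment(
    ddg = -100, ddg_stderr = 1,
    tau_water = lifetime_estimate(1), tau_ion = lifetime_estimate(500),
    thresholds = thr))
  expect_equal(v4$call, "inconclusive")
  expect_match(v4$rationale, "disagree")

  # implausible water binding opposes an otherwise watery verdict
  v5 <- verdict(site_assessment(
    ddg = -100, ddg_stderr = 1, dg_bind_water = 40, dg_bind_stderr = 1,
    thresholds = thr))
  expect_equal(v5$call, "inconclusive")

  expect_error(verdict(site_assessment(thresholds = thr)), "evaluable")
})

test_that("species relabeling maps the verdict antisymmetrically", {
  thr <- assignment_thresholds()
  flip <- c(water_favored = "ion_favored", ion_favored = "water_favored",
            inconclusive = "inconclusive")
  set.seed(13)
  for (i in 1:40) {
    ddg <- runif(1, -60, 60)
    tw <- lifetime_estimate(runif(1, 1, 500))
    ti <- lifetime_estimate(runif(1, 1, 500))
    v <- verdict(site_assessment(ddg = ddg, ddg_stderr = 1, tau_water = tw,
                                 tau_ion = ti, thresholds = thr))
    vs <- verdict(site_assessment(ddg = -ddg, ddg_stderr = 1, tau_water = ti,
                                  tau_ion = tw, thresholds = thr))
    expect_equal(vs$call, unname(flip[v$call]))
  }
})

test_that("strengthening the water evidence never moves the verdict away from water", {
  thr <- assignment_thresholds()
  rank <- c(ion_favored = 1, inconclusive = 2, water_favored = 3)
  set.seed(21)
  for (i in 1:40) {
    ddg <- runif(1, -50, 50)
    tw <- lifetime_estimate(runif(1, 1, 500))
    ti <- lifetime_estimate(runif(1, 1, 500))
    v1 <- verdict(site_assessment(ddg = ddg, ddg_stderr = 1, tau_water = tw,
                                  tau_ion = ti, thresholds = thr))
    v2 <- verdict(site_assessment(ddg = ddg - runif(1, 0, 80), ddg_stderr = 1,
                                  tau_water = tw, tau_ion = ti,
                                  thresholds = thr))
    expect_gte(rank[v2$call], rank[v1$call])
  }
})
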