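# Shared fixtures and independent oracles, built in code.

kB <- densassign::phys_constants$kB
kT300 <- kB * 300

# harmonic-cage site (no pair centers)
cage_site <- function(k, h = 0.9) site_model(cage_k = k, box_halfwidth = h)

# a species with no interactions at all
ghost_species <- function(mass = 18.015) {
  species("ghost", charge = 0, lj_epsilon = 0, mass = mass)
}

# construct a toy_trajectory directly (for the geometric stability tests)
manual_trajectory <- function(times, positions,
                              site = site_model(), sp = ghost_species()) {
  structure(list(times = times, positions = positions, species = sp,
                 site = site, params = NULL), class = "toy_trajectory")
}

# independent oracle: censored-exponential log-likelihood, maximized
# numerically (never calls tau_ml's closed form)
loglik_tau <- function(tau, escapes, censor_spans) {
  sum(-log(tau) - escapes / tau) + sum(-censor_spans / tau)
}
brute_force_tau <- function(escapes, censor_spans, upper = 1e4) {
  optimize(loglik_tau, c(1e-6, upper), escapes = escapes,
           censor_spans = censor_spans, maximum = TRUE,
           tol = 1e-10)$maximum
}

# chi-square GOF against binned expected probabilities, merging adjacent
# bins until every group's expected count reaches min_expected
merged_gof <- function(obs, probs, min_expected = 10) {
  n <- sum(obs)
  grp <- integer(length(obs))
  g <- 1L; acc <- 0
  for (i in seq_along(obs)) {
    grp[i] <- g
    acc <- acc + probs[i] * n
    if (acc >= min_expected && i < length(obs)) { g <- g + 1L; acc <- 0 }
  }
  if (acc < min_expected && g > 1) grp[grp == g] <- g - 1L
  o <- tapply(obs, grp, sum)
  p <- tapply(probs, grp, sum)
  stats::chisq.test(o, p = p / sum(p))
}
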