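#' Define a chemical species for the toy model
#'
#' A species is a single tagged particle characterised by its charge, its
#' Lennard-Jones parameters, its mass, and an implicit-solvation free-energy
#' offset.  The solvation offset is a position-independent energy added
#' wherever a site model declares itself solvent-like (see
#' [site_model()]'s `solvation_scale`); it is the toy stand-in for the large
#' dehydration penalty an ion pays when it leaves bulk solvent.
#'
#' @param name label for reports.
#' @param charge charge in elementary charges.
#' @param lj_epsilon Lennard-Jones well depth, kJ/mol (>= 0).
#' @param lj_sigma Lennard-Jones diameter, nm (> 0).
#' @param mass particle mass, g/mol.
#' @param solvation implicit solvation free energy, kJ/mol (usually <= 0);
#'   active only in site models with `solvation_scale > 0`.
#' @return An object of class `toy_species`.
#' @export
species <- function(name, charge = 0, lj_epsilon = 0, lj_sigma = 0.3,
                    mass = 18.015, solvation = 0) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(charge)) stop("charge must be finite")
  if (lj_epsilon < 0) stop("lj_epsilon must be >= 0")
  if (lj_sigma <= 0) stop("lj_sigma must be > 0")
  if (mass <= 0) stop("mass must be > 0")
  structure(list(name = name, charge = charge, lj_epsilon = lj_epsilon,
                 lj_sigma = lj_sigma, mass = mass, solvation = solvation),
            class = "toy_species")
}

#' Define a toy binding-site (or bulk) model
#'
#' A site model is a set of fixed interaction centers (each with a partial
#' charge and LJ parameters), a uniform dielectric screening the Coulomb
#' interactions, an optional isotropic harmonic cage, a reflecting cubic
#' confinement box, and a flag saying how solvent-like the environment is.
#' A "bulk" model is simply a site model without centers and with
#' `solvation_scale = 1`.
#'
#' @param centers `NULL`, or a data frame with columns `x`, `y`, `z` (nm),
#'   `charge` (e), `lj_epsilon` (kJ/mol), `lj_sigma` (nm); one row per center.
#' @param dielectric relative dielectric constant (>= 1).
#' @param cage_k optional harmonic confinement, kJ mol^-1 nm^-2 (>= 0).
#' @param site_center center of the site/cage, nm 3-vector.
#' @param escape_radius radial escape threshold, nm (> 0).
#' @param box_halfwidth half-width of the reflecting cubic box, nm; must
#'   exceed `escape_radius`.
#' @param solvation_scale in \[0, 1\]: fraction of each species' solvation
#'   offset active in this environment (1 = bulk solvent, 0 = desolvated
#'   pore interior).
#' @param name label for reports.
#' @return An object of class `toy_site`.
#' @export
site_model <- function(centers = NULL, dielectric = 1, cage_k = 0,
                       site_center = c(0, 0, 0), escape_radius = 0.6,
                       box_halfwidth = 0.9, solvation_scale = 0,
                       name = "site") {
  if (is.null(centers)) {
    centers <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                          charge = numeric(0), lj_epsilon = numeric(0),
                          lj_sigma = numeric(0))
  }
  centers <- as.data.frame(centers)
  needed <- c("x", "y", "z", "charge", "lj_epsilon", "lj_sigma")
  if (!all(needed %in% names(centers)))
    stop("centers must have columns ", paste(needed, collapse = ", "))
  if (nrow(centers) > 0 && !all(is.finite(as.matrix(centers[, needed]))))
    stop("all center positions and parameters must be finite")
  if (any(centers$lj_epsilon < 0)) stop("center lj_epsilon must be >= 0")
  if (any(centers$lj_sigma <= 0)) stop("center lj_sigma must be > 0")
  if (dielectric < 1) stop("dielectric must be >= 1")
  if (cage_k < 0) stop("cage_k must be >= 0")
  if (escape_radius <= 0) stop("escape_radius must be > 0")
  if (escape_radius >= box_halfwidth)
    stop("escape_radius must be smaller than box_halfwidth")
  if (solvation_scale < 0 || solvation_scale > 1)
    stop("solvation_scale must lie in [0, 1]")
  stopifnot(length(site_center) == 3, all(is.finite(site_center)))
  structure(list(centers = centers, dielectric = dielectric, cage_k = cage_k,
                 site_center = as.numeric(site_center),
                 escape_radius = escape_radius,
                 box_halfwidth = box_halfwidth,
                 solvation_scale = solvation_scale, name = name),
            class = "toy_site")
}

#' Simulation parameters for Langevin dynamics
#'
#' @param temperature K (> 0).
#' @param friction Langevin friction, ps^-1; the default corresponds to a
#'   coupling time of 0.1 ps.
#' @param dt integration time step, ps.
#' @param n_steps number of integration steps.
#' @param burn_in_steps leading steps regarded as equilibration (must be
#'   smaller than `n_steps`); downstream estimators discard the matching
#'   span of samples.
#' @param seed integer seed; every simulation is bit-reproducible given the
#'   same seed and parameters.
#' @param sample_stride record every `sample_stride`-th step.
#' @return An object of class `sim_params`.
#' @export
simulation_params <- function(temperature = 300, friction = 10, dt = 0.002,
                              n_steps = 50000, burn_in_steps = 0, seed = 1,
                              sample_stride = 10) {
  if (temperature <= 0) stop("temperature must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (friction <= 0) stop("friction must be > 0")
  if (burn_in_steps < 0 || n_steps <= burn_in_steps)
    stop("need n_steps > burn_in_steps >= 0")
  if (sample_stride < 1) stop("sample_stride must be >= 1")
  structure(list(temperature = temperature, friction = friction, dt = dt,
                 n_steps = as.integer(n_steps),
                 burn_in_steps = as.integer(burn_in_steps),
                 seed = as.integer(seed),
                 sample_stride = as.integer(sample_stride)),
            class = "sim_params")
}

# internal: representation handed to the C++ engine
site_for_cpp <- function(site) {
  list(center_positions = unname(as.matrix(site$centers[, c("x", "y", "z"),
                                                        drop = FALSE])),
       center_charges = as.numeric(site$centers$charge),
       center_eps = as.numeric(site$centers$lj_epsilon),
       center_sigma = as.numeric(site$centers$lj_sigma),
       dielectric = site$dielectric, cage_k = site$cage_k,
       box_halfwidth = site$box_halfwidth,
       solvation_scale = site$solvation_scale,
       site_center = site$site_center)
}

species_for_cpp <- function(sp) {
  list(charge = sp$charge, lj_epsilon = sp$lj_epsilon, lj_sigma = sp$lj_sigma,
       mass = sp$mass, solvation = sp$solvation)
}

#' Potential energy of a species at a point in a site model
#'
#' Sum over interaction centers of Lennard-Jones plus screened Coulomb terms
#' (Lorentz-Berthelot combination: arithmetic sigma, geometric epsilon),
#' plus the optional harmonic cage and the solvation offset:
#' \deqn{U(x) = \sum_i 4\epsilon_{ij}\left(\frac{\sigma_{ij}^{12}}{r_i^{12}} -
#'   \frac{\sigma_{ij}^6}{r_i^6}\right) + \frac{f\, q_i q_j}{D\, r_i} +
#'   \frac{k_c}{2}|x - x_c|^2 + s\,\Delta G_{solv}}
#' with \eqn{f = 138.935458} kJ mol^-1 nm e^-2.
#'
#' @param site a [site_model()].
#' @param sp a [species()].
#' @param x position, nm 3-vector.
#' @return potential energy, kJ/mol.
#' @export
potential_energy <- function(site, sp, x) {
  stopifnot(inherits(site, "toy_site"), inherits(sp, "toy_species"))
  x <- as.numeric(x)
  if (length(x) != 3 || !all(is.finite(x))) stop("x must be a finite 3-vector")
  if (nrow(site$centers) > 0) {
    d <- sqrt((site$centers$x - x[1])^2 + (site$centers$y - x[2])^2 +
                (site$centers$z - x[3])^2)
    sing <- d == 0 & (sp$charge * site$centers$charge != 0 |
                        sp$lj_epsilon * site$centers$lj_epsilon > 0)
    if (any(sing))
      stop("singular configuration: particle exactly on an interacting center")
  }
  alch <- list(mode_code = 0L, lam = 0,
               state_A = list(site = site_for_cpp(site),
                              species = species_for_cpp(sp)),
               state_B = NULL,
               softcore = list(alpha = 0, sigma_sc = 0.3, power = 1),
               restraint = NULL)
  .cpp_alch_eval(alch, x)$energy
}

#' Simulate Langevin dynamics of one tagged particle
#'
#' Integrates the BAOAB splitting of Langevin dynamics at the requested
#' temperature, with reflecting walls at `+-box_halfwidth`.  The BAOAB scheme
#' is used for its small configurational sampling error at moderate time
#' steps.  Trajectories are bit-reproducible for a given seed.
#'
#' @param site a [site_model()]; ignored (except for the box) when
#'   `hamiltonian_override` is given.
#' @param sp a [species()].
#' @param params a [simulation_params()].
#' @param hamiltonian_override optional [alchemical_hamiltonian()] evaluated
#'   at its fixed lambda instead of the plain site potential.
#' @param x0 starting position (defaults to the site center).
#' @return A `toy_trajectory`: list with `times` (ps), `positions`
#'   (matrix, nm), `species`, `site`, `params`.
#' @export
simulate_langevin <- function(site, sp, params, hamiltonian_override = NULL,
                              x0 = NULL) {
  stopifnot(inherits(params, "sim_params"))
  alch <- if (is.null(hamiltonian_override)) {
    stopifnot(inherits(site, "toy_site"), inherits(sp, "toy_species"))
    alchemical_hamiltonian("plain", state_A = list(site = site, species = sp))
  } else {
    stopifnot(inherits(hamiltonian_override, "alch_hamiltonian"))
    hamiltonian_override
  }
  if (is.null(x0)) x0 <- alch$state_A$site$site_center
  raw <- withr::with_seed(params$seed,
    .cpp_simulate(alch_for_cpp(alch), as.numeric(x0), params$n_steps,
                  params$dt, params$temperature, params$friction,
                  params$sample_stride, FALSE))
  structure(list(times = raw$times, positions = raw$positions,
                 species = alch$state_A$species, site = alch$state_A$site,
                 params = params),
            class = "toy_trajectory")
}

#' Record dH/dlambda along a Langevin trajectory
#'
#' Runs [simulate_langevin()] under the alchemical Hamiltonian fixed at
#' `lam` and records the analytic lambda-derivative of the potential at every
#' `sample_stride`-th configuration.
#'
#' @param alch an [alchemical_hamiltonian()].
#' @param lam coupling parameter in \[0, 1\].
#' @param params a [simulation_params()]; `burn_in_steps * dt` becomes the
#'   burn-in span attached to the returned series.
#' @param x0 starting position (defaults to the state-A site center).
#' @return A [derivative_series()] tagged with `lam` and the sample spacing.
#' @export
sample_dhdl <- function(alch, lam, params, x0 = NULL) {
  stopifnot(inherits(alch, "alch_hamiltonian"), inherits(params, "sim_params"))
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  alch <- set_lambda(alch, lam)
  if (is.null(x0)) x0 <- alch$state_A$site$site_center
  raw <- withr::with_seed(params$seed,
    .cpp_simulate(alch_for_cpp(alch), as.numeric(x0), params$n_steps,
                  params$dt, params$temperature, params$friction,
                  params$sample_stride, TRUE))
  derivative_series(values = raw$dhdl, lam = lam,
                    dt = params$dt * params$sample_stride,
                    burn_in = params$burn_in_steps * params$dt)
}

#' Draw synthetic censored escape-time data
#'
#' Escape times are exponential with mean `true_tau`; each of the `M`
#' monitored molecules is observed for `T_s` nanoseconds and escapes later
#' than that are censored.  This emulates a set of fixed-length replica
#' simulations in which only some molecules leave the binding site.
#'
#' @param true_tau true mean lifetime, ns (> 0).
#' @param M number of monitored molecules (>= 1).
#' @param T_s observation span per molecule, ns (> 0).
#' @param seed integer seed.
#' @return A [survival_data()] object.
#' @export
generate_survival_synthetic <- function(true_tau, M, T_s, seed = 1) {
  if (true_tau <= 0) stop("true_tau must be > 0")
  if (M < 1) stop("M must be >= 1")
  if (T_s <= 0) stop("T_s must be > 0")
  t_all <- withr::with_seed(as.integer(seed), rexp(M, rate = 1 / true_tau))
  survival_data(M = M, T_s = T_s, escape_times = t_all[t_all <= T_s])
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("toy_trajectory: %d frames, %.1f ps, species '%s', site '%s'\n",
              length(x$times), max(x$times), x$species$name, x$site$name))
  invisible(x)
}

#' Export a trajectory as CSV (time_ps, x_nm, y_nm, z_nm)
#' @param traj a `toy_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  df <- data.frame(time_ps = traj$times, x_nm = traj$positions[, 1],
                   y_nm = traj$positions[, 2], z_nm = traj$positions[, 3])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a trajectory in XYZ format (element taken from the species name)
#' @inheritParams export_trajectory_csv
#' @return `path`, invisibly.
#' @export
export_trajectory_xyz <- function(traj, path) {
  stopifnot(inherits(traj, "toy_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  el <- substr(traj$species$name, 1, 2)
  for (i in seq_along(traj$times)) {
    writeLines(c("1", sprintf("t = %.4f ps", traj$times[i]),
                 sprintf("%s %.6f %.6f %.6f", el, traj$positions[i, 1],
                         traj$positions[i, 2], traj$positions[i, 3])), con)
  }
  invisible(path)
}
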