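#' One leg of a thermodynamic cycle
#'
#' @param name leg label, e.g. `"posre_on"`, `"coulomb_off"`, `"lj_off"`.
#' @param delta_g free energy, kJ/mol.
#' @param stderr standard error, kJ/mol (>= 0).
#' @return An object of class `leg_result`.
#' @export
leg_result <- function(name, delta_g, stderr = 0) {
  stopifnot(is.character(name), length(name) == 1, is.finite(delta_g))
  if (stderr < 0) stop("stderr must be >= 0")
  structure(list(name = name, delta_g = delta_g, stderr = stderr),
            class = "leg_result")
}

#' Harmonic position-restraint specification
#'
#' @param k_x isotropic force constant, kJ mol^-1 nm^-2 (> 0).
#' @param temperature K (> 0).
#' @param v_standard standard-state volume, nm^3 (> 0).  The default
#'   0.02992 nm^3 is the molecular volume of pure water, tying the absolute
#'   binding free energy to a water-replacement interpretation.
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(k_x = 200, temperature = 300,
                           v_standard = 0.02992) {
  if (k_x <= 0 || temperature <= 0 || v_standard <= 0)
    stop("k_x, temperature and v_standard must all be > 0")
  structure(list(k_x = k_x, temperature = temperature,
                 v_standard = v_standard),
            class = "restraint_spec")
}

#' Analytic free energy of a harmonic translational restraint
#'
#' A restraint \eqn{U_r = K_x |x - x_0|^2 / 2} confines a non-interacting
#' particle to the effective volume
#' \deqn{V_{eff} = (2\pi k_B T / K_x)^{3/2},}
#' and the free energy of confining it from the standard volume
#' \eqn{V^\circ} is \eqn{k_B T \ln(V^\circ / V_{eff})} up to sign.  This
#' function returns the magnitude \eqn{|k_B T \ln(V^\circ/V_{eff})|}; the
#' signed contribution is applied by [assemble_absolute()], where releasing
#' the restraint on the non-interacting particle into \eqn{V^\circ}
#' contributes \eqn{-k_B T \ln(V^\circ/V_{eff})} (negative for
#' \eqn{V^\circ > V_{eff}}: releasing into a larger volume is downhill).
#' The signed release value and \eqn{V_{eff}} are attached as attributes
#' `release` and `v_eff`.
#'
#' @param spec a [restraint_spec()].
#' @return magnitude of the restraint free energy, kJ/mol.
#' @export
restraint_free_energy <- function(spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  kT <- phys_constants$kB * spec$temperature
  v_eff <- (2 * pi * kT / spec$k_x)^(3 / 2)
  signed <- -kT * log(spec$v_standard / v_eff) # release into V-standard
  structure(abs(signed), release = signed, v_eff = v_eff)
}

#' Relative binding cycle
#'
#' Either the combined transformation (ion -> water at the binding site while
#' water -> ion in bulk, a single simulated leg) or the two legs separately:
#' `leg_g3` (alchemical transformation at the site) and `leg_g2` (the same
#' transformation in bulk solvent).
#'
#' @param leg_site combined-leg [leg_result()], or `NULL`.
#' @param leg_g3,leg_g2 separate-leg [leg_result()]s, or `NULL`.
#' @return An object of class `relative_cycle`.
#' @export
relative_cycle <- function(leg_site = NULL, leg_g3 = NULL, leg_g2 = NULL) {
  if (is.null(leg_site) && (is.null(leg_g3) || is.null(leg_g2)))
    stop("provide either leg_site or both leg_g3 and leg_g2")
  for (l in list(leg_site, leg_g3, leg_g2))
    if (!is.null(l) && !inherits(l, "leg_result"))
      stop("cycle legs must be leg_result objects")
  structure(list(leg_site = leg_site, leg_g3 = leg_g3, leg_g2 = leg_g2),
            class = "relative_cycle")
}

#' Relative binding free energy difference
#'
#' \eqn{\Delta\Delta G_{bind} = \Delta G_3 - \Delta G_2}; a negative value
#' means binding of water is favored over the ion.  Standard errors combine
#' in quadrature.
#'
#' @param cycle a [relative_cycle()].
#' @return list with `ddg` and `stderr`, kJ/mol.
#' @export
relative_ddg <- function(cycle) {
  stopifnot(inherits(cycle, "relative_cycle"))
  if (!is.null(cycle$leg_site))
    return(list(ddg = cycle$leg_site$delta_g, stderr = cycle$leg_site$stderr))
  if (is.null(cycle$leg_g3)) stop("missing leg: leg_g3 (site transformation)")
  if (is.null(cycle$leg_g2)) stop("missing leg: leg_g2 (bulk transformation)")
  list(ddg = cycle$leg_g3$delta_g - cycle$leg_g2$delta_g,
       stderr = sqrt(cycle$leg_g3$stderr^2 + cycle$leg_g2$stderr^2))
}

#' Absolute binding cycle
#'
#' `legs_site` holds the simulated sub-steps of decoupling the molecule at
#' the binding site (must include `posre_on`, `coulomb_off`, `lj_off`);
#' `legs_bulk` holds the solvent decoupling legs.  The translation of the
#' fully decoupled, restrained particle between environments carries
#' exactly zero free energy and is hard-coded as such.
#'
#' @param legs_site,legs_bulk lists of [leg_result()]s.
#' @return An object of class `absolute_cycle`.
#' @export
absolute_cycle <- function(legs_site, legs_bulk) {
  chk <- function(legs, what) {
    if (!length(legs) || !all(vapply(legs, inherits, logical(1), "leg_result")))
      stop(what, " must be a non-empty list of leg_result objects")
    legs
  }
  legs_site <- chk(legs_site, "legs_site")
  legs_bulk <- chk(legs_bulk, "legs_bulk")
  structure(list(legs_site = legs_site, legs_bulk = legs_bulk),
            class = "absolute_cycle")
}

#' Assemble an absolute binding free energy
#'
#' Combines the cycle legs as
#' \deqn{\Delta G_1 = \Delta G_{posre} + \Delta G_{Coulomb} + \Delta G_{LJ}
#'   + 0 - k_B T \ln(V^\circ/V_{eff}),}
#' \deqn{\Delta G_{bind} = \Delta G_2 - \Delta G_1,}
#' where the zero is the translation of the non-interacting restrained
#' particle and the analytic term (zero statistical error) releases the
#' restraint on the non-interacting particle into the standard volume
#' \eqn{V^\circ}.  With this bookkeeping \eqn{\Delta G_{bind}} is the
#' standard-state free energy of transferring the molecule from a bulk
#' volume \eqn{V^\circ} into the site.  A negative value marks a plausible
#' occupant.
#'
#' @param cycle an [absolute_cycle()]; `legs_site` must contain legs named
#'   `posre_on`, `coulomb_off` and `lj_off`.
#' @param spec a [restraint_spec()] describing the restraint and standard
#'   state.
#' @return list with `delta_g`, `stderr`, `dg1`, `dg2`, `restraint_release`
#'   (the signed analytic term inside `dg1`) and `sign_convention`.
#' @export
assemble_absolute <- function(cycle, spec) {
  stopifnot(inherits(cycle, "absolute_cycle"), inherits(spec, "restraint_spec"))
  nm <- vapply(cycle$legs_site, `[[`, character(1), "name")
  for (req in c("posre_on", "coulomb_off", "lj_off"))
    if (!req %in% nm) stop("legs_site is missing required leg: ", req)
  release <- attr(restraint_free_energy(spec), "release")
  dg1 <- sum(vapply(cycle$legs_site, `[[`, numeric(1), "delta_g")) + release
  se1 <- sqrt(sum(vapply(cycle$legs_site, `[[`, numeric(1), "stderr")^2))
  dg2 <- sum(vapply(cycle$legs_bulk, `[[`, numeric(1), "delta_g"))
  se2 <- sqrt(sum(vapply(cycle$legs_bulk, `[[`, numeric(1), "stderr")^2))
  list(delta_g = dg2 - dg1, stderr = sqrt(se1^2 + se2^2),
       dg1 = dg1, dg2 = dg2, restraint_release = release,
       sign_convention = paste(
         "restraint release of the non-interacting particle into V_standard",
         "contributes -kB*T*ln(V_standard/V_eff) to dg1;",
         "delta_g = dg2 - dg1 is the standard-state binding free energy"))
}

#' Equilibrium occupancy ratio implied by a relative binding free energy
#'
#' \deqn{P^{wat}_{bind} / P^{ion}_{bind} = (c_{wat}/c_{ion})
#'   \exp(-\Delta\Delta G_{bind}/k_B T).}
#'
#' @param ddg relative binding free energy (water vs ion), kJ/mol.
#' @param c_wat,c_ion solvent concentrations, mol/L (> 0).
#' @param temperature K.
#' @return the dimensionless probability ratio; `+Inf` with attribute
#'   `overflow = TRUE` if the exponential overflows.
#' @export
occupancy_ratio <- function(ddg, c_wat, c_ion, temperature = 300) {
  if (c_wat <= 0 || c_ion <= 0) stop("concentrations must be > 0")
  kT <- phys_constants$kB * temperature
  r <- (c_wat / c_ion) * exp(-ddg / kT)
  if (!is.finite(r)) return(structure(Inf, overflow = TRUE))
  r
}
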