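#' Soft-core parameters
#'
#' Parameters of the Beutler-style soft-core modification that replaces the
#' interatomic distance `r` by `(alpha sigma_sc^6 lam^p + r^6)^(1/6)` in the
#' vanishing interaction, removing the r -> 0 singularity at intermediate
#' coupling.  Defaults follow the common engine convention: `alpha = 0.5`,
#' `sigma_sc = 0.3` nm, power 1, one shared parameter set for Lennard-Jones
#' and Coulomb terms.
#'
#' @param alpha dimensionless (>= 0).
#' @param sigma_sc global soft-core radius, nm (> 0).
#' @param power soft-core lambda power, 1 or 2.
#' @return An object of class `soft_core_params`.
#' @export
soft_core_params <- function(alpha = 0.5, sigma_sc = 0.3, power = 1) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (sigma_sc <= 0) stop("sigma_sc must be > 0")
  if (!power %in% c(1, 2)) stop("power must be 1 or 2")
  structure(list(alpha = alpha, sigma_sc = sigma_sc, power = power),
            class = "soft_core_params")
}

#' Soft-cored distance
#'
#' @param r distance, nm (>= 0).
#' @param lam_off weight of the soft-core term: 0 for a fully coupled
#'   interaction (returns `r` exactly), growing as the interaction is
#'   switched off.
#' @param sc a [soft_core_params()].
#' @return effective distance, nm; monotone non-decreasing in `lam_off`.
#' @export
softcore_distance <- function(r, lam_off, sc = soft_core_params()) {
  stopifnot(all(r >= 0), all(lam_off >= 0))
  (sc$alpha * sc$sigma_sc^6 * lam_off^sc$power + r^6)^(1 / 6)
}

.mode_codes <- c(plain = 0L, relative = 1L, decouple_coulomb = 2L,
                 decouple_lj = 3L, restraint_on = 4L)

#' Construct a lambda-coupled (alchemical) Hamiltonian
#'
#' Supported coupling modes:
#' \describe{
#'   \item{`relative`}{linear interpolation between two fully interacting
#'     (site, species) states: \eqn{V(\lambda) = (1-\lambda) V_A(r_A) +
#'     \lambda V_B(r_B)}, with the soft-core distance \eqn{r_A} using weight
#'     \eqn{\lambda} (state A vanishes as \eqn{\lambda \to 1}) and \eqn{r_B}
#'     using \eqn{1-\lambda}.  Both LJ and Coulomb terms are soft-cored.}
#'   \item{`decouple_coulomb`}{charges and the solvation offset scale with
#'     \eqn{1-\lambda} on the soft-cored distance; LJ stays at full strength
#'     and unsoftened (charges are removed before LJ).}
#'   \item{`decouple_lj`}{LJ and the cage scale with \eqn{1-\lambda} on the
#'     soft-cored distance; charges are assumed already off.}
#'   \item{`restraint_on`}{the full state-A potential plus
#'     \eqn{\lambda U_r} with \eqn{U_r = K|x-x_0|^2/2}.}
#'   \item{`plain`}{the uncoupled state-A potential (no lambda dependence).}
#' }
#' At the endpoints the potential reduces exactly to the pure end-state
#' potentials; for `0 < lambda < 1` both the energy and the analytic
#' lambda-derivative remain finite at r = 0.
#'
#' @param mode one of the modes above.
#' @param state_A list with elements `site` ([site_model()]) and `species`
#'   ([species()]).
#' @param state_B as `state_A`; required for `relative`, ignored otherwise.
#' @param softcore a [soft_core_params()].
#' @param lam coupling parameter in \[0, 1\].
#' @param restraint `NULL`, or `list(k = <kJ mol-1 nm-2>, center = <nm
#'   3-vector>)`.  Constant in all modes except `restraint_on`, where it is
#'   the lambda-scaled term.
#' @return An object of class `alch_hamiltonian`.
#' @export
alchemical_hamiltonian <- function(mode, state_A, state_B = NULL,
                                   softcore = soft_core_params(), lam = 0,
                                   restraint = NULL) {
  mode <- match.arg(mode, names(.mode_codes))
  stopifnot(inherits(state_A$site, "toy_site"),
            inherits(state_A$species, "toy_species"))
  if (mode == "relative") {
    if (is.null(state_B))
      stop("relative mode requires state_B")
    stopifnot(inherits(state_B$site, "toy_site"),
              inherits(state_B$species, "toy_species"))
  }
  if (mode == "restraint_on" && is.null(restraint))
    stop("restraint_on mode requires a restraint")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (!is.null(restraint)) {
    stopifnot(is.numeric(restraint$k), restraint$k >= 0,
              length(restraint$center) == 3)
  }
  structure(list(mode = mode, state_A = state_A, state_B = state_B,
                 softcore = softcore, lam = lam, restraint = restraint),
            class = "alch_hamiltonian")
}

#' Set the coupling parameter of an alchemical Hamiltonian
#' @param alch an [alchemical_hamiltonian()].
#' @param lam new lambda in \[0, 1\].
#' @return The modified Hamiltonian.
#' @export
set_lambda <- function(alch, lam) {
  stopifnot(inherits(alch, "alch_hamiltonian"))
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  alch$lam <- lam
  alch
}

# internal: flatten to the C++ representation
alch_for_cpp <- function(alch) {
  list(mode_code = .mode_codes[[alch$mode]], lam = alch$lam,
       state_A = list(site = site_for_cpp(alch$state_A$site),
                      species = species_for_cpp(alch$state_A$species)),
       state_B = if (is.null(alch$state_B)) NULL else
         list(site = site_for_cpp(alch$state_B$site),
              species = species_for_cpp(alch$state_B$species)),
       softcore = list(alpha = alch$softcore$alpha,
                       sigma_sc = alch$softcore$sigma_sc,
                       power = alch$softcore$power),
       restraint = alch$restraint)
}

#' Alchemical potential energy at a configuration
#' @param alch an [alchemical_hamiltonian()].
#' @param x position, nm 3-vector.
#' @return V(lambda) in kJ/mol.
#' @export
alchemical_potential <- function(alch, x) {
  stopifnot(inherits(alch, "alch_hamiltonian"))
  .cpp_alch_eval(alch_for_cpp(alch), as.numeric(x))$energy
}

#' Analytic lambda-derivative of the alchemical potential
#' @inheritParams alchemical_potential
#' @return dV/dlambda in kJ/mol, exact (no finite differencing).
#' @export
alchemical_dhdl <- function(alch, x) {
  stopifnot(inherits(alch, "alch_hamiltonian"))
  .cpp_alch_eval(alch_for_cpp(alch), as.numeric(x))$dhdl
}
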