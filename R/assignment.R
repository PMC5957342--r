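#' Decision thresholds for density assignment
#'
#' @param ddg_robust minimum magnitude (kJ/mol) for a relative binding free
#'   energy to be called robustly in favor of one species.  The default of
#'   20 kJ/mol sits well below the hundreds of kJ/mol seen for clear-cut
#'   water-vs-anion swaps yet above the force-field-uncertainty regime
#'   where single-digit differences are not significant.
#' @param dg_plausible largest absolute binding free energy (kJ/mol) still
#'   counted as "close to zero": occupancy of a site is plausible only if
#'   the binding free energy is negative or at most this far above zero.
#' @param tau_ratio minimum lifetime ratio (default one order of magnitude)
#'   for the stability criterion to favor a species.
#' @return An object of class `assignment_thresholds`.
#' @export
assignment_thresholds <- function(ddg_robust = 20, dg_plausible = 5,
                                  tau_ratio = 10) {
  if (ddg_robust <= 0 || dg_plausible <= 0 || tau_ratio <= 0)
    stop("all thresholds must be > 0")
  structure(list(ddg_robust = ddg_robust, dg_plausible = dg_plausible,
                 tau_ratio = tau_ratio), class = "assignment_thresholds")
}

#' Relative-free-energy criterion
#'
#' Water is favored when the relative binding free energy (water vs ion;
#' negative favors water) is below `-ddg_robust` and differs from zero by
#' more than two standard errors; symmetric for the ion; otherwise
#' inconclusive.
#'
#' @param ddg relative binding free energy, kJ/mol.
#' @param stderr its standard error (>= 0).
#' @param ddg_robust robustness threshold, kJ/mol.
#' @return `"water_favored"`, `"ion_favored"` or `"inconclusive"`.
#' @export
criterion_relative <- function(ddg, stderr, ddg_robust = 20) {
  if (stderr < 0) stop("stderr must be >= 0")
  if (ddg < -ddg_robust && abs(ddg) > 2 * stderr) "water_favored"
  else if (ddg > ddg_robust && abs(ddg) > 2 * stderr) "ion_favored"
  else "inconclusive"
}

#' Absolute-free-energy plausibility criterion
#'
#' A density assignment is plausible only if the candidate's absolute
#' binding free energy is negative or close to zero.
#'
#' @param dg_bind absolute binding free energy, kJ/mol.
#' @param stderr its standard error (>= 0).
#' @param dg_plausible near-zero tolerance, kJ/mol.
#' @return `"plausible"` or `"implausible"`.
#' @export
criterion_absolute <- function(dg_bind, stderr, dg_plausible = 5) {
  if (stderr < 0) stop("stderr must be >= 0")
  if (dg_bind <= dg_plausible) "plausible" else "implausible"
}

#' Comparative-stability criterion
#'
#' Favors the species whose residence lifetime exceeds the other's by at
#' least `ratio_threshold`.  Lower bounds (censored estimates) are compared
#' conservatively: a lower bound can only support the species it bounds,
#' and two censored lifetimes are always inconclusive.
#'
#' @param tau_water,tau_ion [lifetime_estimate()]s (or bare positive
#'   numbers, taken as point estimates), ns.
#' @param ratio_threshold minimum lifetime ratio.
#' @return `"water_favored"`, `"ion_favored"` or `"inconclusive"`.
#' @export
criterion_stability <- function(tau_water, tau_ion, ratio_threshold = 10) {
  as_est <- function(x) if (inherits(x, "lifetime_estimate")) x
                        else lifetime_estimate(x)
  w <- as_est(tau_water); i <- as_est(tau_ion)
  if (w$is_lower_bound && i$is_lower_bound) return("inconclusive")
  if (w$is_lower_bound) {
    if (w$tau / i$tau >= ratio_threshold) return("water_favored")
    return("inconclusive")
  }
  if (i$is_lower_bound) {
    if (i$tau / w$tau >= ratio_threshold) return("ion_favored")
    return("inconclusive")
  }
  if (w$tau / i$tau >= ratio_threshold) "water_favored"
  else if (i$tau / w$tau >= ratio_threshold) "ion_favored"
  else "inconclusive"
}

#' Collect the evidence for one candidate site
#'
#' @param ddg,ddg_stderr relative binding free energy (water vs ion) and its
#'   error, kJ/mol; `NULL` if not computed.
#' @param dg_bind_water,dg_bind_stderr absolute binding free energy of water
#'   and its error, kJ/mol; `NULL` if not computed.
#' @param tau_water,tau_ion [lifetime_estimate()]s; `NULL` if not computed.
#' @param thresholds an [assignment_thresholds()].
#' @return An object of class `site_assessment`.
#' @export
site_assessment <- function(ddg = NULL, ddg_stderr = 0,
                            dg_bind_water = NULL, dg_bind_stderr = 0,
                            tau_water = NULL, tau_ion = NULL,
                            thresholds = assignment_thresholds()) {
  stopifnot(inherits(thresholds, "assignment_thresholds"))
  structure(list(ddg = ddg, ddg_stderr = ddg_stderr,
                 dg_bind_water = dg_bind_water,
                 dg_bind_stderr = dg_bind_stderr,
                 tau_water = tau_water, tau_ion = tau_ion,
                 thresholds = thresholds),
            class = "site_assessment")
}

#' Combine the three criteria into a verdict
#'
#' Conjunctive combination, mirroring how the three lines of evidence are
#' weighed in practice: the relative and stability criteria contribute
#' directional calls; the absolute criterion cannot by itself favor water
#' (a plausible water binding free energy is merely non-opposing) but an
#' implausible one opposes the water assignment.  The verdict is a species
#' only when at least one criterion favors it and none opposes it; any
#' disagreement, or all criteria inconclusive, yields `inconclusive`.
#' Disagreements are surfaced in the evidence, never averaged away.
#'
#' @param assessment a [site_assessment()] with at least one evaluable
#'   criterion.
#' @return An object of class `assignment_verdict`: `call`, per-criterion
#'   `evidence`, and a `rationale` string.
#' @export
verdict <- function(assessment) {
  stopifnot(inherits(assessment, "site_assessment"))
  th <- assessment$thresholds
  ev <- list()
  directional <- character(0)
  if (!is.null(assessment$ddg)) {
    lab <- criterion_relative(assessment$ddg, assessment$ddg_stderr,
                              th$ddg_robust)
    ev$relative <- list(label = lab, value = assessment$ddg,
                        stderr = assessment$ddg_stderr)
    directional <- c(directional, lab)
  }
  if (!is.null(assessment$dg_bind_water)) {
    lab <- criterion_absolute(assessment$dg_bind_water,
                              assessment$dg_bind_stderr, th$dg_plausible)
    ev$absolute <- list(label = lab, value = assessment$dg_bind_water,
                        stderr = assessment$dg_bind_stderr)
    # implausible water binding opposes the water assignment
    directional <- c(directional,
                     if (lab == "implausible") "ion_favored" else "inconclusive")
  }
  if (!is.null(assessment$tau_water) && !is.null(assessment$tau_ion)) {
    lab <- criterion_stability(assessment$tau_water, assessment$tau_ion,
                               th$tau_ratio)
    ev$stability <- list(label = lab,
                         tau_water = assessment$tau_water,
                         tau_ion = assessment$tau_ion)
    directional <- c(directional, lab)
  }
  if (length(ev) == 0)
    stop("no evaluable criterion in the assessment")
  wat <- any(directional == "water_favored")
  ion <- any(directional == "ion_favored")
  call <- if (wat && !ion) "water_favored"
          else if (ion && !wat) "ion_favored"
          else "inconclusive"
  rationale <- sprintf(
    "%d criteria evaluated (%s); %s",
    length(ev), paste(names(ev), vapply(ev, `[[`, character(1), "label"),
                      sep = "=", collapse = ", "),
    switch(call,
           water_favored = "evidence favors water with no opposition",
           ion_favored = "evidence favors the ion with no opposition",
           inconclusive = if (wat && ion)
             "criteria disagree; surfaced, not averaged"
           else "no criterion reaches its decision threshold"))
  structure(list(call = call, evidence = ev, rationale = rationale),
            class = "assignment_verdict")
}

#' @export
print.assignment_verdict <- function(x, ...) {
  cat("assignment verdict:", x$call, "\n")
  for (nm in names(x$evidence))
    cat(sprintf("  %-9s %s\n", nm, x$evidence[[nm]]$label))
  cat(" ", x$rationale, "\n")
  invisible(x)
}
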