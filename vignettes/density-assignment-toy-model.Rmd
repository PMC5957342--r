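---
title: "Assigning ambiguous densities with free-energy and stability inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning ambiguous densities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Crystallographic maps of proteins routinely contain small, disconnected
electron densities that could equally well be a water molecule, a halide, or
a cation: the scatterers are nearly isoelectronic and the coordination
geometry is often ambiguous. `densassign` implements three complementary
computational criteria for adjudicating such densities, in the form used
for channel binding-site densities:

1. **Relative binding free energy** ΔΔG~bind~ between the two candidate
   species, from alchemical transformation of one species into the other at
   the site and, simultaneously or separately, in bulk solvent. Negative
   values (by this package's convention) favor water.
2. **Absolute binding free energy** ΔG~bind~ of the water candidate: a
   density assignment is only plausible if transferring the molecule from
   bulk into the site is downhill or nearly so.
3. **Comparative stability** in free simulations: censored
   maximum-likelihood residence lifetimes of both candidates, and the RMSF
   of the bound molecule as a disorder proxy.

The package supplies every stage — λ-coupled soft-core Hamiltonians with
analytic ∂H/∂λ, discrete thermodynamic integration (TI), thermodynamic-cycle
assembly with the analytic restraint correction, censored lifetime
estimation, escape detection, and the final conjunctive verdict — together
with a synthetic toy binding-site model that plays the role of the
atomistic simulations and has closed-form ground truth.

## The toy model

A single tagged particle moves in a field of fixed interaction centers
inside a reflecting cubic box. The potential is a sum of Lennard-Jones and
screened Coulomb pair terms (Lorentz–Berthelot combination), an optional
isotropic harmonic cage, and an implicit-solvation offset:

U(x) = Σ~i~ [ 4ε~ij~(σ~ij~¹²/r~i~¹² − σ~ij~⁶/r~i~⁶) + f q~i~q~j~ / (D r~i~) ]
      + k~c~|x − x~c~|²/2 + s·ΔG~solv~

with f = 138.935458 kJ mol⁻¹ nm e⁻², k~B~ = 0.008314462618 kJ mol⁻¹ K⁻¹,
units kJ/mol, nm, ps, K, e throughout. Dynamics are BAOAB-discretized
Langevin at fixed temperature; BAOAB was chosen for its small
configurational sampling error at moderate time steps. Boundaries are
reflecting, the simplest scheme that preserves the equilibrium distribution
in a finite volume.

**Implicit solvent.** There are no explicit solvent particles. Solvent
effects enter twice: a uniform dielectric D scales all Coulomb terms, and
each species carries a position-independent solvation free energy that is
active only in environments flagged solvent-like (`solvation_scale = 1`,
i.e. the bulk box) and absent in the dehydrated pore
(`solvation_scale = 0`). This gives an ion the large desolvation penalty
that dominates water-vs-ion discrimination in occluded sites, while keeping
every free-energy bookkeeping step closed-form checkable: a uniform bulk
box has G = −k~B~T ln V~box~ + ΔG~solv~ exactly. The price is that the
offset exerts no force, so *escape kinetics* feel only the site well, not
the bulk solvation pull — free-simulation lifetimes in the toy are
qualitative, which is all the assignment logic requires of them.

**Packaged study system** (`toy_system()`, values illustrative, not
fitted): a water-like particle whose hydrogen-bonding affinity is lumped
into an effective LJ depth (it carries no charge); a fluoride-like anion
(charge −1, weak LJ, solvation −60 kJ/mol) and a sodium-like cation; a
"3-donor pocket" of polar donors with small positive partial charges at
0.31 nm from the site center; a "tetrahedral 4-dipole cage" of
carbonyl-like centers; and a featureless solvated bulk box. The pocket
parameters were set so that water forms a deep multi-contact well
(≈ −30 kJ/mol) while the anion is only weakly held (≈ −7 kJ/mol) — the
regime in which the water-vs-anion assignment question is sharp. With
these defaults the anion escapes the pocket within tens of picoseconds
whereas water stays bound one to two orders of magnitude longer, so the
stability criterion resolves cleanly at the package's default
one-order-of-magnitude ratio threshold.

## Alchemical Hamiltonians

Transformations interpolate linearly between end states,
V(λ) = (1−λ)V~A~(r~A~) + λV~B~(r~B~), with the Beutler-style soft-core
distance r~A~ = (α σ~sc~⁶ λ^p + r⁶)^(1/6) applied to the vanishing state
(and symmetrically r~B~ with 1−λ), for both LJ and Coulomb terms, with one
shared parameter set α = 0.5, σ~sc~ = 0.3 nm, p = 1. This is the functional
form those three parameters parameterize in the common MD engines, and it
keeps V and ∂V/∂λ finite at r = 0 for 0 < λ < 1. The λ-derivative is
analytic (chain rule through the soft-core distance), and is verified
against central finite differences in the test suite.

Staged decoupling follows the usual absolute-binding protocol: in
`decouple_coulomb` mode the charges and the solvation offset scale with
1−λ while LJ remains full and unsoftened (charges are removed before LJ);
`decouple_lj` then scales LJ and the cage; `restraint_on` couples a
harmonic position restraint as λ·U~r~, whose derivative is exactly U~r~.

## Thermodynamic integration

ΔG = ∫₀¹ ⟨∂H/∂λ⟩ dλ is estimated window-wise: each λ-window is an
independent simulation; the leading burn-in span of each series is
discarded; window means carry block-averaged standard errors (10 blocks by
default), which absorb autocorrelation when blocks exceed the correlation
time. Quadrature is trapezoidal — the minimal-assumption rule, exact for
linear mean profiles — with the error propagated through the trapezoid
weights in quadrature, treating windows as independent. Duplicate λ values
are rejected outright (they indicate a configuration mistake), and a
schedule that does not span [0, 1] flags the result rather than
extrapolating. Uniform schedules default to 41 windows for relative and LJ
legs and 11 for Coulomb/restraint legs, the conventional spacings.

## Absolute cycle and the restraint correction

ΔG~bind~ is assembled from five sub-steps: (a) switching a K~x~ = 200
kJ mol⁻¹ nm⁻² position restraint onto the bound molecule, (b) Coulomb and
(c) LJ decoupling at the site, (d) translating the non-interacting
restrained particle to bulk (exactly zero, hard-coded with zero error),
and (e) releasing the restraint at the standard state. The release is
analytic: the restraint confines a non-interacting particle to
V~eff~ = (2π k~B~T / K~x~)^(3/2), so releasing it into the standard volume
V° contributes −k~B~T ln(V°/V~eff~) — *negative* for V° > V~eff~, since
release into a larger volume is entropically downhill.
`restraint_free_energy()` reports the magnitude (which is what is usually
printed) and carries the signed value as an attribute; `assemble_absolute()`
applies the signed value inside ΔG₁. With that sign, ΔG~bind~ = ΔG₂ − ΔG₁
is exactly the standard-state binding free energy: on the toy system the
identity ΔG~bind~ = G~site~ + k~B~T ln V° − ΔG~solv~ can be derived in
closed form, and the package's cycle-closure study
(`run_closure_study()`, `analysis/04_cycle_closure.R`) verifies the
simulated assembly against the independently computed relative route. The
default V° = 0.02992 nm³ is the molecular volume of pure water, tying
ΔG~bind~ to a water-replacement interpretation; it is overridable.

The bulk decoupling legs simulate a *restrained* particle; the free energy
of first restraining the interacting particle in bulk is exactly the
analytic term for a homogeneous environment, which is why it does not
appear as a separate simulated leg. This mirrors the standard protocol.

## Censored lifetimes

Residence times are modelled as exponential. With M monitored molecules
observed for spans T~s,i~ and m escapes at times t~i~, the
maximum-likelihood lifetime is total time at risk over event count,
τ~ml~ = m⁻¹ [ Σ~censored~ T~s,i~ + Σ t~i~ ]. With no events the likelihood
is monotone and the package reports the total observation time flagged as
a lower bound (the "≳" entries of residence-time tables) instead of
failing. Events are counted per molecule, and spans may differ per molecule
so replicas of different lengths pool naturally. Uncertainty comes from a
parametric bootstrap (whole synthetic escape experiments re-drawn at
τ~ml~ under the same censoring), whose coverage is checked by simulation
in the test suite. No non-exponential residence model is provided.

## Escape detection and RMSF

Published analyses often judge escapes from displacement traces by eye; a
package needs an explicit rule. A molecule is deemed escaped at the first
frame whose distance from the site center exceeds the site's escape radius
*continuously for at least a persistence window* (default 5 ps), so single
recrossing spikes do not count; otherwise it is censored at the trajectory
end. Every trajectory yields exactly one event. RMSF is computed about the
retained-frame mean position (not the initial frame). In the analysis
scripts, RMSF of an escaping molecule is restricted to its bound span —
after escape the statistic would measure box diffusion, not site disorder.

## Verdict logic

The three criteria are combined conjunctively, never averaged: the
relative criterion calls a species when |ΔΔG| exceeds a robustness
threshold (default 20 kJ/mol) *and* two standard errors; the absolute
criterion cannot by itself favor water — plausibility (ΔG~bind~ below
+5 kJ/mol by default) is merely non-opposing, while implausibility opposes
the water assignment; the stability criterion requires one lifetime to
exceed the other by a ratio threshold (default 10), with censored bounds
used conservatively (a lower bound supports only the species it bounds).
A species is called only if at least one criterion favors it and none
opposes; disagreement or silence yields `inconclusive`, with every
criterion's label surfaced in the evidence. The 20 kJ/mol default sits
between the hundreds of kJ/mol of a clear-cut water-vs-anion swap and the
single-digit differences that ion force-field uncertainty can produce; it
is configuration, not a claim about any particular system.

On the packaged toy system the 3-donor pocket resolves as water (relative
and stability criteria in favor, absolute plausibility non-opposing), and
the 4-dipole cage resolves as the cation. In the cage
the toy reaches the cation call through the relative free energy (both
occupants are stable on the simulated timescale); an atomistic system may
instead reach it through stability with an inconclusive ΔΔG — the
combination rule accepts either path, which is the point of running three
criteria.

## Numerical choices

* **Integrator:** BAOAB, default dt = 2 fs (free simulations) with a
  Maxwell–Boltzmann initial velocity; trajectories are bit-reproducible
  given `(seed, params)`. TI production uses dt = 0.5–1 fs: a time-step
  sensitivity study on the toy cycle showed that the stiff water–donor
  contacts need sub-femtosecond steps for the per-window means to be
  unbiased at the package's error level.
* **Friction:** 10 ps⁻¹ (a 0.1 ps coupling time) for free simulations.
  TI legs default to 2 ps⁻¹ in the closure study: equilibrium averages are
  friction-independent, and the lower friction speeds barrier recrossing
  and box mixing for the weakly bound end states, which block-averaged
  errors otherwise underestimate.
* **Quadrature resolution:** chosen by deterministic analysis of exact
  integrands (computable on the toy by grid integration). The restraint
  switch-on integrand of a weakly bound species is steep near λ = 0; 41
  uniform windows bring its trapezoid bias well below the statistical
  error, and the closure study uses 41-window schedules for the relative,
  LJ and restraint legs (11 for the smooth Coulomb legs).
* **Problem sizes:** the shipped analyses use 10 replicas × 500 ps for
  stability, and 0.3 ns per λ-window (30 ps burn-in) for TI — sizes at
  which every assertion in the test suite resolves at its stated
  tolerance on one CPU in minutes. They are package defaults, not
  physical claims.
* **Degenerate inputs:** evaluating a plain (non-soft-core) potential
  exactly on an interacting center raises a singular-configuration error;
  non-finite forces abort a simulation with the step number; empty
  λ-windows (burn-in swallowing all samples), duplicate λ values, and
  escape times exceeding observation spans are all rejected with specific
  errors.

## What the toy validates — and what it cannot

The synthetic model exercises every code path on physics with known
answers: equipartition and Boltzmann sampling of the integrator, Gaussian
closed forms for harmonic TI and RMSF, the analytic restraint correction
against a simulated restraint switch-on, exponential censoring for the
lifetime estimator, and exact thermodynamic cycle closure. Passing these
says the *machinery* is correct.

It says nothing quantitative about atomistic systems: there is no explicit
water, no polarization, no protein flexibility, no finite-size electrostatic
corrections (explicitly out of scope), and lifetimes are picoseconds to
nanoseconds rather than the nanoseconds-to-microseconds of real sites.
Atomistic magnitudes (hundreds of kJ/mol for anion swaps, RMSF of a few
hundredths of a nanometer) are reproduced only as *regimes* — sign,
separation, ordering — not as numbers. Equally, the implicit-solvation
offset is a free-energy device: toy escape kinetics underestimate the pull
of real solvation on an exiting ion.

## Reproducibility

Every simulation consumes an explicit integer seed; one master seed is
fanned out counter-style (`child_seed()`) to stages and λ-windows, so
inserting a stage does not perturb the others. `run_pipeline()` records
the package version, seed, and a hash of the system config in its JSON
report, and a rerun with the same config reproduces the numbers exactly.
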