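---
title: "Modelling ion partitioning in finite polyelectrolyte gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ion partitioning in finite polyelectrolyte gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A charged polymer network immersed in salt solution does not see the same
ion concentrations inside and outside: the fixed negative charges of the
network attract mobile cations and repel coions, producing a Donnan-like
partitioning.  `gelion` implements a coarse-grained, implicit-solvent
bead-spring model of a *finite* gel particle in a periodic box of
monovalent and/or divalent salt, and the statistical machinery to
quantify that partitioning:

* the charged-particle pair correlation `gq(r)` — local ion
  concentration at distance `r` from the gel centre of mass divided by
  the system-wide concentration of that species;
* the ion partition coefficient `Qi = c_i,gel / c_i,bulk`, read off as
  the ratio of the interior and bulk plateaus of `gq(r)` (`i = 1`
  monovalent cations, `i = 2` divalent);
* the gel radius of gyration `Rg` and internal volume fraction `phi`;
* the empirical scaling law `Qi ~ phi^kappa * csalt^(-mu)` fitted by
  log–log least squares.

## The model

**Architecture.**  The gel is a "perfect compact gel": `Nb^3` star
polymers (a core bead plus `f` arms of `M` beads, so `Mw = f*M + 1`
beads per star) on a cubic lattice, with free arm ends of adjacent stars
bridged by bonds.  The default connectivity for `f = 4` bonds each
star's four arms to four of its six lattice neighbours in an alternating
diamond-like pattern, which pairs every interior free end and keeps the
network connected; the map is serialized with every build.  Every gel
bead carries one negative elementary charge.

**Interactions.**  All beads share `m = sigma = epsilon = 1` (reduced
units; time unit `tau = sigma*sqrt(m/epsilon)`).

* Excluded volume: WCA potential — Lennard-Jones cut and shifted at its
  minimum `2^(1/6) sigma`, purely repulsive (athermal solvent).
* Bonds: stiff harmonic springs `V = k (r - l0)^2` with
  `k = 1000 eps/sigma^2`, `l0 = 0.99 sigma`.
* Electrostatics: `V(r)/kT = lB * qi * qj / r`, with the Bjerrum length
  `lB` setting the coupling strength; aqueous conditions correspond to
  `lB = 2.1 sigma` (0.71 nm), which also fixes the bead size
  `sigma = 0.71/2.1 = 0.338 nm` and hence the density-to-mmol/L factor
  `c0 = 1/(N_A sigma^3)` (~43 mol/L per sigma^-3), overridable in
  configuration.
* The long range is summed by smooth Ewald (tin-foil boundary), with the
  splitting parameter and reciprocal cutoff tuned from a target RMS
  force accuracy (default 1e-4, mirroring the mesh accuracy a
  production-scale code would use).  A damped-shifted-force (DSF) mode
  is provided and *labelled approximate*: it truncates the far field
  entirely (see "Numerical choices").

**Composition.**  Monovalent counterions neutralize the gel; monovalent
salt adds `+1/-1` pairs and divalent salt adds `+2` cations with two
`-1` coions each, at counts that make the per-valence concentration
`c = c0 (rho_cation + rho_matching_coion)/2` recover the request within
integer rounding.  Counterions are excluded from salt accounting (salt
concentration is varied independently of gel charge), but they *are*
monovalent cations and contribute to `Q1` — physically they are
indistinguishable from salt cations.  All systems are exactly
electroneutral in integer arithmetic.  "mmol" is read as mmol/L
throughout.

**Dynamics.**  Velocity-Verlet with either a Nosé–Hoover chain (length
3) or a BAOAB Langevin thermostat, `kT = 1.0`, `dt = 0.005 tau`.  The
full-scale protocol is 5000 tau equilibration and 150000 tau
production.  The reference model runs at constant pressure, but its
target pressure is never stated and the gel is a finite particle in a
dilute bath; the default ensemble here is therefore **NVT in a fixed
large box** — the bulk region far from the gel acts as its own
reservoir, so the gel still swells or collapses freely.  This deviation
is deliberate and documented; no barostat is shipped.

## Analysis procedure

`gq(r)` is accumulated about the gel centre of mass (computed after
unwrapping the gel across periodic boundaries by breadth-first traversal
of the bond graph), using exact spherical-shell volumes clipped to the
periodic box, so the profile remains normalized beyond `L/2`.  Three
radial regimes appear: an interior plateau, an interfacial crossover,
and a bulk plateau.

The reference procedure reads plateau heights off the profile visually.
To automate that reproducibly, `partition_coefficients()` uses fixed
Rg-relative windows: interior `r in [0, 0.5*Rg]`, bulk
`r in [max(1.5*Rg, Rg + 5 sigma), 0.45*L]`, the crossover excluded.
Both windows are configurable, and a flatness diagnostic warns (and
flags the result) when a window's fitted slope is both statistically
resolved (above 2 standard errors, so narrow noisy windows are not
flagged spuriously) and large relative to the window mean.  Standard
errors come from a frame block bootstrap (default block length 10
frames; use 1 for independent-frame fixtures).

`phi` — the "internal part of the gel" is not sharply defined; the
convention here is the sphere of radius `0.5*Rg` about the gel centre of
mass, consistent with the interior plateau window, with beads counted at
the hard-sphere volume `(pi/6) sigma^3`.  Both choices are configurable
and reported with the result.

`fit_scaling()` performs OLS on
`log Q = logA + kappa*log(phi) - mu*log(csalt)`, supporting
single-covariate fits (`mu` at fixed `lB`; `kappa` at fixed `csalt`) and
the joint fit, with standard errors and R^2.  For mixed salts the
per-valence concentration of the fitted species is the covariate.

## What the synthetic fixtures emulate

`make_partition_fixture()` draws ions uniformly at density
`Q * rho_bulk` inside a ball of radius `r_gel` and `rho_bulk` outside,
around a static dummy gel ball (`Rg = r_gel*sqrt(3/5)`), with frames as
independent redraws.  This gives every analysis operation a ground truth
without running dynamics, and deliberately isolates estimator
correctness from sampling autocorrelation (which the dynamics tests
cover).  It does **not** emulate the interfacial crossover's width, ion-
ion correlations, or gel breathing; a green fixture test therefore
establishes that the estimator recovers a known plateau ratio, not that
the simulation physics is right — that is what the scaled-down
end-to-end runs are for.

`make_scaling_table()` inverts the scaling law with lognormal noise of
prescribed CV for parameter-recovery tests.  `make_lattice_charges()`
provides electrostatic references: a `+1/-1` dimer and the 8-ion
rock-salt cell whose energy per ion pair is the Madelung value
`-1.747565 lB/a`.

## Numerical choices

* **Ewald tuning**: `alpha = s/rc` and reciprocal cutoff `2*alpha*s`
  with `s = sqrt(-ln(accuracy))`; the reciprocal sum uses recursive
  phase factors, so its cost is a few flops per particle per k-vector.
  Correctness is pinned by direct image-sum oracles (a shell-ordered
  vacuum sum minus the standard surface-dipole term `2*pi*lB*M^2/(3V)`
  equals the tin-foil energy) and the Madelung constant.
* **DSF is inadequate for partition trends.**  With the Coulomb force
  truncated at a few sigma, the net-charged gel region has no far
  field, counterions evaporate from a desk-scale gel, and the
  swelling/partition trends drown in noise.  The scaled-down acceptance
  runs therefore use Ewald at a relaxed 1e-2 force accuracy
  (`rc = 6 sigma`), which costs about the same as DSF at `rc = 8` after
  the reciprocal-space optimization.  DSF remains available for quick
  smoke runs.
* **Thermostats**: the Nosé–Hoover chain regulates kinetic energy
  directly and gives an unbiased kinetic temperature even with stiff
  bonds at `dt = 0.005`; BAOAB Langevin has an O((omega*dt)^2) kinetic-
  temperature bias from the `k = 1000` springs (a few percent) but
  superior configurational sampling and stochastic stability, so the
  scaled-down runs use Langevin while temperature-accuracy checks use
  the chain.  Bit-identical reproducibility given the seed holds for
  both (the Langevin noise stream is a compiled-in generator seeded from
  the protocol seed).
* **Instability guards**: any per-step displacement above `0.5 sigma`
  or non-finite coordinate aborts the run; ion insertion rejects
  positions within `0.9 sigma` of existing particles so step one cannot
  blow up.
* **Half-open box** `[0, L)` and minimum-image convention everywhere;
  energies are invariant under global translation and rewrapping.

## Degenerate inputs and tie-breaks

Zero-valence gels are rejected at specification time; non-neutral
systems are rejected by the Ewald solver; empty trajectories, absent
species, and windows without bins raise errors naming the problem.
`t_prod = 0` returns an equilibrated state and an empty trajectory.
Collinear or non-positive scaling tables are refused.  Gels whose bond
graph is disconnected cannot be unwrapped (error), except bond-free
dummy gels from fixtures, which are assumed not to straddle the
boundary.

## Scaled-down acceptance runs: what green establishes

Quantitative reproduction of the reference results (mu ~ 0.76/0.89,
kappa ~ 1.1, Q2/Q1 ~ 2/8/12, the factor-two Rg collapse) needs the full
gel (Nb = 4, M = 15) and 150000 tau of production — overnight-to-cluster
compute, provided as `scripts/paper_scale_sweep.R` and *not* run by the
test suite.  The test suite instead asserts the trends at desk scale
with a small gel (Nb = 2, f = 4, M = 5) and 150-300 tau of production:
Q2 > Q1 in matched single-salt runs at `lB = 2.1`; Rg non-increasing in
`lB` over {1, 2, 3} and in salt over {10, 50, 150} mmol; Q1 decreasing
in salt.  The salt grid spans over a decade *and* keeps at least ~15
salt ion pairs per point in the affordable box (a 2 mmol point would
hold three); the matched-salt Q2-vs-Q1 comparison runs at 50 mmol so
the sparse divalent species has usable bulk statistics, sharing its
monovalent run with the sweep.  The trend criteria
measure the partition of the *added salt* cations
(`include_counterions = FALSE`): a desk-scale gel loses most of its
counterions to the bulk, and their re-condensation as the gel compacts
at high salt can invert the all-cation Q1 trend — a finite-size
artifact absent at full scale, where the two estimators coincide.
Durations were fixed from wall-clock budgets.

## Known limitations

* **The salt-concentration trend of Qi does not survive desk scaling.**
  At the small-gel scale the acceptance suite runs, most neutralizing
  counterions evaporate into the bulk (168 fixed charges cannot hold a
  Donnan equilibrium in an affordable box), so the gel interior is far
  from charge-compensated; when added salt compacts the gel, the rising
  uncompensated interior charge density adsorbs salt cations faster
  than the bulk concentration grows, and measured Q1 first rises then
  falls across {10, 50, 150} mmol instead of decreasing.  The
  corresponding acceptance criterion is deliberately left failing
  rather than weakened; the decreasing trend (mu > 0) requires the
  full-size gel of `scripts/paper_scale_sweep.R`.
* Uniform dielectric (a stated model assumption): no dielectric
  contrast between gel interior and bulk, no polarization — one of the
  reasons this model class disagrees with experiment on mixed-salt
  trends.
* No explicit solvent, hence no solvation physics; no hydrodynamics.
* NVT instead of the reference's NPT (target pressure unknown); whether
  this shifts Qi materially is flagged for a sensitivity study, not
  assumed.
* Desk-scale runs under-sample slow gel breathing modes; their Rg error
  bars are block estimates and can be optimistic.
* Defected networks, other lattice morphologies, and charge-regulation
  chemistry are out of scope.
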