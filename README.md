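# gelion

Coarse-grained simulation and ion-partition analysis of finite
polyelectrolyte gels in salt solution.

## What it is for

Charged polymer networks — hydrogels, extracellular matrices, the
crowded interior of cells — partition mobile ions unequally between
their interior and the surrounding bath: the fixed network charges pull
cations in and push coions out (Donnan partitioning). `gelion` is for
researchers who want to simulate that effect with an implicit-solvent
bead-spring model and quantify it reproducibly:

* **Build**: a finite "perfect compact gel" of star polymers (core +
  `f` arms of `M` beads, `Mw = f·M + 1`) on an `Nb³` cubic lattice with
  bridged arm ends, every bead carrying one negative charge, plus
  neutralizing counterions and monovalent/divalent salt at prescribed
  mmol/L concentrations — exactly electroneutral, in a periodic box.
* **Simulate**: velocity-Verlet dynamics at `kT = 1 ε`, `Δt = 0.005 τ`
  with a Nosé–Hoover chain or BAOAB Langevin thermostat; WCA excluded
  volume, stiff harmonic bonds (`k = 1000 ε/σ²`, `l₀ = 0.99 σ`), and
  Coulomb interactions `V(r)/kT = l_B q_i q_j / r` summed by smooth
  Ewald (tunable accuracy, default 10⁻⁴) or an approximate
  damped-shifted-force mode.
* **Analyse**: the charged-particle pair correlation `g_q(r)` about the
  gel centre of mass; ion partition coefficients
  `Q_i = c_i,gel / c_i,bulk` from its interior/bulk plateaus; gel radius
  of gyration `R_g` (bond-graph unwrapping across periodic boundaries);
  internal volume fraction `φ`; and least-squares fits of the scaling
  law

  `Q_i ∼ φ^κ · c_salt^(−μ)`

  with standard errors from frame block bootstraps.

Aqueous conditions correspond to a Bjerrum length `l_B = 2.1 σ`
(0.71 nm), which fixes `σ ≈ 0.338 nm` and the reduced-density →
mmol/L conversion (`default_c0()` ≈ 43 mol/L per σ⁻³).

## Worked example

Analyse a synthetic trajectory with known ground truth (interior ion
density 3× bulk for monovalent, 6× for divalent cations):

```r
library(gelion)
fx <- make_partition_fixture(partition_fixture_spec(
  Q_target = c(cation_1 = 3, cation_2 = 6), r_gel = 8, L = 40,
  N_ions = 1500, n_frames = 60, seed = 7))
obs <- gel_observables(fx)
q1 <- partition_coefficients(charged_pair_correlation(fx, "cation_1", 1),
                             obs, window_policy = list(r_in = c(0, 7)))
q2 <- partition_coefficients(charged_pair_correlation(fx, "cation_2", 1),
                             obs, window_policy = list(r_in = c(0, 7)))
print(q1); print(q2)
partition_ratio(q2, q1)
```

```
Partition coefficient (cation_1): Q = 2.995 +/- 0.0159
Partition coefficient (cation_2): Q = 6.056 +/- 0.0333
Q2/Q1 = 2.022 +/- 0.0155
```

`Q` is the ratio of the `g_q(r)` plateau inside the gel (here the ball
of radius 7 σ) to the bulk plateau far outside; both constructed values
are recovered within their standard errors. Fitting the scaling law to
a noisy synthetic table:

```r
tb <- make_scaling_table(kappa = 1.1, mu = 0.89, noise_cv = 0.05, seed = 1)
fit_scaling(tb, covariates = "both")
```

```
Scaling fit  Q ~ phi^kappa csalt^-mu  (n = 20 )
  kappa = 1.123 +/- 0.0127
  mu    = 0.8874 +/- 0.00913
  R^2 = 0.999
```

A real simulation goes through the same pipeline:

```r
st <- build_gel(gel_spec(Nb = 2, f = 4, M = 5), L = 44)
st <- add_ions(st, salt_spec(c_mono = 10), seed = 1)
ff <- ff_params(lB = 2.1, coulomb_method = "ewald",
                coulomb_accuracy = 1e-2, r_cut_real = 6)
traj <- run_protocol(st, ff, protocol_preset("ci-small", seed = 1))
cmd_analyze(traj, out_prefix = "run")   # writes run_observables.csv, run_gq.csv
```

## Command line

```sh
Rscript inst/cli/gelion.R build   config.json system.data
Rscript inst/cli/gelion.R run     config.json out
Rscript inst/cli/gelion.R analyze out.dump    report
Rscript inst/cli/gelion.R sweep   plan.json
Rscript inst/cli/gelion.R fit     sweep_table.csv
```

Configs are JSON mirroring the `gel_spec`/`salt_spec`/`ff_params`/
`protocol_params` fields; every output carries its seed and the gel
connectivity map for byte-identical re-runs.

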