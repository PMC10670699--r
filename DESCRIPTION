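Package: gelion
Title: Coarse-Grained Simulation and Ion-Partition Analysis of Polyelectrolyte Gels
Version: 0.1.0
Authors@R: person("Gelion", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds finite bead-spring polyelectrolyte gel networks (star
    polymers on a cubic lattice), runs coarse-grained Langevin or
    Nose-Hoover molecular dynamics with WCA excluded volume, stiff
    harmonic bonds and Ewald electrostatics in a periodic box, and
    analyses the resulting trajectories: radius of gyration, internal
    volume fraction, the charged-particle pair correlation gq(r) about
    the gel centre of mass, ion partition coefficients Q1/Q2 for
    monovalent and divalent cations, and power-law fits of the partition
    coefficient against gel volume fraction and salt concentration.
    Includes synthetic-fixture generators with known ground truth, LAMMPS
    data/dump and XYZ readers and writers, and a command-line interface
    for build/run/analyze/sweep/fit workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
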