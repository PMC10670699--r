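# Independent oracles used by the test suite.  These are deliberately
# brute-force / closed-form and never share code with the package paths
# they check.

# Direct Coulomb image sum over spherically ordered shells |n| <= nshell.
# A shell-ordered vacuum sum converges to the tin-foil (Ewald) energy
# plus the surface dipole term 2 pi lB |M|^2 / (3 V); that term is
# subtracted here so the oracle matches tin-foil boundary conditions.
direct_coulomb_sum <- function(positions, charge, L, lB, nshell = 8) {
  N <- nrow(positions)
  ns <- -nshell:nshell
  img <- as.matrix(expand.grid(ns, ns, ns))
  img <- img[rowSums(img^2) <= nshell^2, , drop = FALSE] * L
  E <- 0
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (charge[i] == 0 || charge[j] == 0) next
    d0 <- positions[j, ] - positions[i, ]
    r <- sqrt((d0[1] + img[, 1])^2 + (d0[2] + img[, 2])^2 +
              (d0[3] + img[, 3])^2)
    if (i == j) r <- r[r > 1e-12]          # skip self at n = 0
    E <- E + 0.5 * lB * charge[i] * charge[j] * sum(1 / r)
  }
  M <- colSums(positions * charge)
  E - 2 * pi * lB * sum(M^2) / (3 * L^3)
}

# Central finite-difference force check: returns max relative deviation
# between -dE/dx and the reported force, scaled by the RMS force.
fd_force_error <- function(state, ff, h = 2e-5) {
  base <- total_energy_forces(state, ff)
  N <- nrow(state$positions)
  fscale <- sqrt(mean(base$forces^2))
  if (fscale == 0) fscale <- 1
  worst <- 0
  for (i in seq_len(N)) for (d in 1:3) {
    sp <- state; sm <- state
    sp$positions[i, d] <- sp$positions[i, d] + h
    sm$positions[i, d] <- sm$positions[i, d] - h
    ep <- total_energy_forces(sp, ff)$E_total
    em <- total_energy_forces(sm, ff)$E_total
    fd <- -(ep - em) / (2 * h)
    worst <- max(worst, abs(fd - base$forces[i, d]) / fscale)
  }
  worst
}

# Brute-force radius of gyration straight from the definition.
rg_bruteforce <- function(coords) {
  cm <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, cm)^2) / nrow(coords))
}

# Monte Carlo estimate of the centred sphere-box intersection volume.
sphere_box_volume_mc <- function(r, L, n = 2e5) {
  set.seed(99)
  p <- matrix(runif(3 * n, -L / 2, L / 2), n, 3)
  mean(rowSums(p^2) < r^2) * L^3
}

# Small assembled gel + ion system shared across tests (cheap).
tiny_system <- function(c_mono = 20, c_div = 0, L = 30, seed = 11) {
  st <- build_gel(gel_spec(Nb = 1, f = 4, M = 3), L = L)
  add_ions(st, salt_spec(c_mono = c_mono, c_div = c_div), seed = seed)
}
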