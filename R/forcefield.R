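# Scalar potentials (documented, unit-tested closed forms) and wrappers
# around the compiled kernels for full-system energies and forces.

#' WCA pair potential
#'
#' Lennard-Jones cut and shifted at its minimum \eqn{r_{min} = 2^{1/6}
#' \sigma}: \eqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] +
#' \epsilon} for \eqn{r \le r_{min}}, zero beyond.  Purely repulsive
#' (athermal solvent conditions); energy and force are continuous at the
#' cutoff.
#'
#' @param r distance(s) in sigma; must be > 0.
#' @param params a \code{\link{ff_params}} (only epsilon/sigma used).
#' @return list with \code{energy} (eps) and \code{force} (radial
#'   magnitude, positive = repulsive), vectorized over \code{r}.
#' @export
wca_energy <- function(r, params = ff_params()) {
  if (any(r <= 0)) stop("WCA potential undefined for r <= 0")
  s <- params$sigma; eps <- params$epsilon
  rmin <- 2^(1 / 6) * s
  sr6 <- (s / r)^6
  e <- ifelse(r <= rmin, 4 * eps * (sr6^2 - sr6) + eps, 0)
  f <- ifelse(r <= rmin, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = e, force = f)
}

#' Harmonic bond potential
#'
#' Stiff spring \eqn{V_H(r) = k (r - l_0)^2} with k = 1000 eps/sigma^2 and
#' l0 = 0.99 sigma by default.
#'
#' @param r distance(s) in sigma; r >= 0.
#' @param params a \code{\link{ff_params}}.
#' @return energy in eps, vectorized.
#' @export
bond_energy <- function(r, params = ff_params()) {
  if (any(r < 0)) stop("bond length must be non-negative")
  params$k_spring * (r - params$l0)^2
}

#' Bare Coulomb pair energy
#'
#' \eqn{V(r)/kT = l_B q_i q_j / r}.  Periodic images are the business of
#' \code{\link{long_range_energy_forces}}.
#'
#' @param r distance(s), sigma; > 0.
#' @param qi,qj integer valences.
#' @param lB Bjerrum length, sigma.
#' @return energy in kT, vectorized over r.
#' @export
coulomb_pair_energy <- function(r, qi, qj, lB = 2.1) {
  if (any(r <= 0)) stop("Coulomb pair energy undefined for r <= 0")
  lB * qi * qj / r
}

#' Long-range electrostatic energy and forces (smooth Ewald)
#'
#' Ewald-split (real + reciprocal + self) energy and per-particle forces
#' for the periodic system, tin-foil boundary conditions.  The splitting
#' parameter alpha and the reciprocal cutoff are tuned from
#' \code{coulomb_accuracy} so the estimated RMS relative force error is at
#' or below the target; the result is independent of the split within that
#' tolerance.
#'
#' @param state an electroneutral \code{system_state}.
#' @param params \code{\link{ff_params}} with \code{coulomb_method
#'   "ewald"} (or \code{"dsf"} for the labelled approximate mode).
#' @return list: \code{energy} (kT), \code{forces} (N x 3), and the tuned
#'   \code{alpha}, \code{nmax}.
#' @export
long_range_energy_forces <- function(state, params = ff_params()) {
  if (params$coulomb_method == "ewald" && sum(state$charge) != 0L)
    stop("Ewald summation requires an electroneutral system")
  # coulomb only: suppress WCA/bonds by passing no bonds and zero-size beads
  res <- cpp_energy_forces(state$positions, as.numeric(state$charge),
                           matrix(integer(0), 0, 2), state$L,
                           .ff_list(params))
  # cpp computes WCA too; subtract its force contribution by recomputing
  # with charges off
  res0 <- cpp_energy_forces(state$positions, numeric(nrow(state$positions)),
                            matrix(integer(0), 0, 2), state$L,
                            .ff_list(params))
  list(energy = res$E_coul, forces = res$forces - res0$forces,
       alpha = res$ewald_alpha, nmax = res$ewald_nmax)
}

#' Total energies and forces
#'
#' Component energies (WCA, bond, Coulomb) and net per-particle forces
#' with minimum-image convention; short-range terms use a linked-cell
#' list.  Newton's third law holds pairwise by construction.
#'
#' @param state a \code{system_state}.
#' @param params a \code{\link{ff_params}}.
#' @return list: \code{E_wca}, \code{E_bond}, \code{E_coul},
#'   \code{E_total}, \code{forces} (N x 3).
#' @export
total_energy_forces <- function(state, params = ff_params()) {
  cpp_energy_forces(state$positions, as.numeric(state$charge),
                    state$bonds, state$L, .ff_list(params))
}

.ff_list <- function(params) {
  list(lB = params$lB, k_spring = params$k_spring, l0 = params$l0,
       coulomb_method = params$coulomb_method,
       coulomb_accuracy = params$coulomb_accuracy,
       r_cut_real = params$r_cut_real)
}
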