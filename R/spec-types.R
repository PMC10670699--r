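#' Gel architecture specification
#'
#' Declarative description of a finite "perfect compact gel": star polymers
#' (a core bead plus \code{f} arms of \code{M} beads) placed on a cubic
#' lattice of \code{Nb} branch points per direction, with the free ends of
#' adjacent stars bridged by bonds.  Every gel bead carries
#' \code{segment_valence}.
#'
#' The derived star mass is \eqn{M_w = fM + 1} and the total gel mass is
#' \eqn{M_{w,gel} = N_b^3 M_w}.
#'
#' @param Nb branch points (stars) per direction; integer >= 1.
#' @param f arms per star; integer >= 1 (at most 6 on the cubic lattice).
#' @param M segments per arm; integer >= 1.
#' @param segment_valence integer charge per gel bead; must be non-zero.
#' @param lattice_constant star-to-star spacing in sigma.  Default
#'   \code{NULL} places beads so that every bond (intra-arm and bridging)
#'   starts at the harmonic rest length 0.99 sigma, i.e.
#'   \code{(2*M + 1) * 0.99}.
#' @return An object of class \code{gel_spec}.
#' @examples
#' gs <- gel_spec(Nb = 4, f = 4, M = 15)
#' gs$Mw       # 61
#' gs$Mw_gel   # 3904
#' @export
gel_spec <- function(Nb = 4L, f = 4L, M = 15L, segment_valence = -1L,
                     lattice_constant = NULL) {
  Nb <- as.integer(Nb); f <- as.integer(f); M <- as.integer(M)
  segment_valence <- as.integer(segment_valence)
  stopifnot(Nb >= 1L, f >= 1L, M >= 1L)
  if (segment_valence == 0L)
    stop("segment_valence must be non-zero (the gel is a polyelectrolyte)")
  if (is.null(lattice_constant)) lattice_constant <- (2 * M + 1) * 0.99
  stopifnot(lattice_constant > 0)
  # bead spacing along an arm (and across a bridge) implied by the lattice
  dl <- lattice_constant / (2 * M + 1)
  if (dl > 1.5)
    stop("lattice_constant too large: initial bond length ", signif(dl, 4),
         " sigma exceeds 1.5 sigma")
  structure(list(Nb = Nb, f = f, M = M,
                 segment_valence = segment_valence,
                 lattice_constant = lattice_constant,
                 Mw = f * M + 1L,
                 Mw_gel = Nb^3 * (f * M + 1L)),
            class = "gel_spec")
}

#' @export
print.gel_spec <- function(x, ...) {
  cat("Gel spec: Nb =", x$Nb, " f =", x$f, " M =", x$M,
      "(Mw =", x$Mw, ", gel beads =", x$Mw_gel, ")\n")
  cat("  segment valence", x$segment_valence,
      "; lattice constant", signif(x$lattice_constant, 5), "sigma\n")
  invisible(x)
}

#' Salt composition specification
#'
#' Monovalent (+1/-1) and divalent (+2 with two -1 coions) salt
#' concentrations in mmol/L ("mmol" is read as mmol/L).  \code{c0} converts
#' a reduced number density of 1/sigma^3 to mmol/L; see
#' \code{\link{default_c0}}.
#'
#' @param c_mono monovalent salt concentration, mmol/L.
#' @param c_div divalent salt concentration, mmol/L.
#' @param c0 conversion factor, mmol/L per sigma^-3.  Defaults to the
#'   aqueous mapping derived from the Bjerrum length (sigma ~ 0.338 nm).
#' @return An object of class \code{salt_spec}.
#' @export
salt_spec <- function(c_mono = 0, c_div = 0, c0 = default_c0()) {
  stopifnot(c_mono >= 0, c_div >= 0, c0 > 0)
  structure(list(c_mono = c_mono, c_div = c_div, c0 = c0),
            class = "salt_spec")
}

#' @export
print.salt_spec <- function(x, ...) {
  cat("Salt spec:", x$c_mono, "mmol/L monovalent,", x$c_div,
      "mmol/L divalent (c0 =", signif(x$c0, 6), "mmol/L per sigma^-3)\n")
  invisible(x)
}

#' Force-field parameters
#'
#' WCA excluded volume (Lennard-Jones cut and shifted at its minimum
#' \eqn{r_{min} = 2^{1/6}\sigma}), stiff harmonic bonds
#' \eqn{V_H(r) = k (r - l_0)^2}, and Coulomb interactions
#' \eqn{V(r)/kT = l_B q_i q_j / r} with a long-range solver in the
#' periodic box.
#'
#' @param lB Bjerrum length in sigma (aqueous conditions ~ 2.1).
#' @param k_spring bond spring constant, eps/sigma^2 (default 1000).
#' @param l0 bond rest length, sigma (default 0.99).
#' @param coulomb_method \code{"ewald"} (smooth Ewald, tin-foil boundary),
#'   \code{"dsf"} (damped-shifted-force; approximate, for scaled-down
#'   runs), or \code{"none"}.
#' @param coulomb_accuracy target RMS relative force error for the
#'   long-range solver, in (0, 1e-2]; default 1e-4.
#' @param r_cut_real real-space cutoff in sigma (must be < L/2 at use).
#' @param epsilon,sigma energy and length units (fixed at 1 in reduced
#'   units; retained for documentation).
#' @return An object of class \code{ff_params}.
#' @export
ff_params <- function(lB = 2.1, k_spring = 1000, l0 = 0.99,
                      coulomb_method = c("ewald", "dsf", "none"),
                      coulomb_accuracy = 1e-4, r_cut_real = 6,
                      epsilon = 1, sigma = 1) {
  coulomb_method <- match.arg(coulomb_method)
  stopifnot(lB > 0, k_spring > 0, l0 > 0, r_cut_real > 0,
            epsilon > 0, sigma > 0)
  if (!(coulomb_accuracy > 0 && coulomb_accuracy <= 1e-2))
    stop("coulomb_accuracy must lie in (0, 1e-2]")
  structure(list(lB = lB, k_spring = k_spring, l0 = l0,
                 r_min = 2^(1 / 6) * sigma,
                 coulomb_method = coulomb_method,
                 coulomb_accuracy = coulomb_accuracy,
                 r_cut_real = r_cut_real,
                 epsilon = epsilon, sigma = sigma),
            class = "ff_params")
}

#' Simulation protocol parameters
#'
#' Time integration and thermostat settings.  Reduced time unit
#' \eqn{\tau = \sigma \sqrt{m/\epsilon}}.  The full-scale protocol is
#' kT = 1.0 eps, dt = 0.005 tau, 5000 tau equilibration and 150000 tau
#' production; scaled-down presets are available via
#' \code{\link{protocol_preset}}.
#'
#' @param kT reduced temperature (default 1.0).
#' @param dt timestep in tau (default 0.005).
#' @param t_equil equilibration time in tau (discarded).
#' @param t_prod production time in tau.
#' @param sample_every tau between stored trajectory frames.
#' @param thermostat \code{"nose_hoover"} (chain of length 3) or
#'   \code{"langevin"} (BAOAB).
#' @param thermostat_coupling thermostat time constant in tau.
#' @param seed integer RNG seed (velocity init and Langevin noise).
#' @param log_every tau between thermo-log rows.
#' @return An object of class \code{protocol_params}.
#' @export
protocol_params <- function(kT = 1.0, dt = 0.005, t_equil = 5000,
                            t_prod = 150000, sample_every = 5,
                            thermostat = c("nose_hoover", "langevin"),
                            thermostat_coupling = 0.5, seed = 1L,
                            log_every = 5) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, t_equil >= 0, t_prod >= 0, kT > 0,
            sample_every > 0, thermostat_coupling > 0, log_every > 0)
  structure(list(kT = kT, dt = dt, t_equil = t_equil, t_prod = t_prod,
                 sample_every = sample_every, thermostat = thermostat,
                 thermostat_coupling = thermostat_coupling,
                 seed = as.integer(seed), log_every = log_every),
            class = "protocol_params")
}

#' Named protocol presets
#'
#' \code{"paper-full"} mirrors the full-scale constants (dt = 0.005 tau,
#' kT = 1.0, 5000 tau equilibration, 150000 tau production, Nose-Hoover).
#' \code{"ci-small"} is a scaled-down smoke preset (Langevin, 100 tau
#' equilibration, 600 tau production) intended for desk-scale trend runs
#' with damped-shifted-force electrostatics.
#'
#' @param name preset name.
#' @param seed RNG seed.
#' @return A \code{protocol_params} object.
#' @export
protocol_preset <- function(name = c("ci-small", "paper-full"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "paper-full" = protocol_params(kT = 1.0, dt = 0.005, t_equil = 5000,
                                   t_prod = 150000, sample_every = 25,
                                   thermostat = "nose_hoover", seed = seed),
    "ci-small" = protocol_params(kT = 1.0, dt = 0.005, t_equil = 100,
                                 t_prod = 600, sample_every = 2,
                                 thermostat = "langevin", seed = seed))
}
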