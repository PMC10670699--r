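# Time evolution: velocity Verlet with Nose-Hoover chain or Langevin
# (BAOAB) thermostatting, and the equilibration/production protocol.

#' Draw Maxwell-Boltzmann velocities
#'
#' Gaussian components at temperature kT (m = 1), centre-of-mass momentum
#' removed.
#'
#' @param n number of particles.
#' @param kT reduced temperature.
#' @return n x 3 matrix, sigma/tau.
#' @export
mb_velocities <- function(n, kT) {
  v <- matrix(stats::rnorm(3 * n, 0, sqrt(kT)), n, 3)
  sweep(v, 2, colMeans(v))
}

#' One NVE velocity-Verlet step
#'
#' Time-reversible; positions re-wrapped into the box.  Aborts if any
#' displacement exceeds 0.5 sigma in one step (instability guard).
#'
#' @param state a \code{system_state} with velocities.
#' @param params \code{\link{ff_params}}.
#' @param dt timestep, tau.
#' @return the advanced \code{system_state}.
#' @export
nve_step <- function(state, params = ff_params(), dt = 0.005) {
  res <- cpp_run_md(state$positions, state$velocities,
                    as.numeric(state$charge), state$bonds, state$L,
                    .ff_list(params), dt, 1L, "none", 1.0, 0.5, 0L,
                    0L, 0L, 0.5)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state
}

#' One thermostatted step
#'
#' Velocity-Verlet step wrapped in a Nose-Hoover chain (length 3) update,
#' or a BAOAB Langevin step.  The instantaneous kinetic temperature
#' relaxes toward kT.
#'
#' @param state a \code{system_state} (>= 2 particles).
#' @param params \code{\link{ff_params}}.
#' @param protocol \code{\link{protocol_params}} (kT, dt, thermostat,
#'   coupling, seed).
#' @return the advanced \code{system_state}.
#' @export
thermostat_step <- function(state, params = ff_params(),
                            protocol = protocol_params()) {
  if (nrow(state$positions) < 2) stop("thermostat needs >= 2 particles")
  if (protocol$kT <= 0) stop("kT must be positive")
  res <- cpp_run_md(state$positions, state$velocities,
                    as.numeric(state$charge), state$bonds, state$L,
                    .ff_list(params), protocol$dt, 1L, protocol$thermostat,
                    protocol$kT, protocol$thermostat_coupling,
                    protocol$seed, 0L, 0L, 0.5)
  state$positions <- res$positions
  state$velocities <- res$velocities
  state
}

#' Run the equilibration/production protocol
#'
#' Equilibrates for \code{t_equil} tau (frames discarded), then produces
#' for \code{t_prod} tau sampling a frame every \code{sample_every} tau.
#' The thermo log (step, T, component energies) covers both phases.
#' Reproducible bit-for-bit given \code{protocol$seed}.
#'
#' @param state assembled, electroneutral \code{system_state}.
#' @param ff \code{\link{ff_params}}.
#' @param protocol \code{\link{protocol_params}}.
#' @param init_velocities draw Maxwell-Boltzmann start velocities if the
#'   state's velocities are all zero (default TRUE).
#' @return A \code{gel_trajectory}: frames, frame times, thermo log, the
#'   final state, and run metadata.
#' @export
run_protocol <- function(state, ff = ff_params(), protocol = protocol_params(),
                         init_velocities = TRUE) {
  stopifnot(inherits(state, "system_state"))
  if (ff$coulomb_method != "none" && sum(state$charge) != 0L)
    stop("protocol requires an electroneutral system")
  set.seed(protocol$seed)
  if (init_velocities && all(state$velocities == 0))
    state$velocities <- mb_velocities(nrow(state$positions), protocol$kT)

  dt <- protocol$dt
  n_eq <- round(protocol$t_equil / dt)
  n_pr <- round(protocol$t_prod / dt)
  samp <- max(1L, round(protocol$sample_every / dt))
  logev <- max(1L, round(protocol$log_every / dt))

  thermo <- NULL
  if (n_eq > 0) {
    eq <- cpp_run_md(state$positions, state$velocities,
                     as.numeric(state$charge), state$bonds, state$L,
                     .ff_list(ff), dt, n_eq, protocol$thermostat,
                     protocol$kT, protocol$thermostat_coupling,
                     protocol$seed, 0L, logev, 0.5)
    state$positions <- eq$positions
    state$velocities <- eq$velocities
    thermo <- eq$thermo
  }
  frames <- list(); steps <- integer(0)
  if (n_pr > 0) {
    pr <- cpp_run_md(state$positions, state$velocities,
                     as.numeric(state$charge), state$bonds, state$L,
                     .ff_list(ff), dt, n_pr, protocol$thermostat,
                     protocol$kT, protocol$thermostat_coupling,
                     protocol$seed + 1L, samp, logev, 0.5)
    state$positions <- pr$positions
    state$velocities <- pr$velocities
    frames <- pr$frames
    steps <- pr$frame_steps + n_eq
    th <- pr$thermo
    th[, "step"] <- th[, "step"] + n_eq
    thermo <- rbind(thermo, th)
  }
  gel_trajectory(frames = frames,
                 times = steps * dt,
                 state = state, thermo = thermo,
                 meta = list(ff = unclass(ff), protocol = unclass(protocol)))
}
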