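# Synthetic configurations with known ground truth: every analysis
# operation is testable without running dynamics.  Frames are i.i.d.
# redraws (seeded), isolating estimator correctness from sampling
# autocorrelation.

#' Partition fixture specification
#'
#' @param Q_target named list/vector of target partition coefficients per
#'   species (names among cation_1, cation_2, coion); all > 0.
#' @param r_gel interior radius, sigma; must be < L/4.
#' @param L box length, sigma.
#' @param N_ions ions per species.
#' @param n_frames independent frames.
#' @param seed RNG seed.
#' @param include_dummy_gel place static gel beads (uniform ball of
#'   radius r_gel) defining the COM and Rg ~ r_gel sqrt(3/5).
#' @param n_gel_beads dummy gel bead count.
#' @return An object of class \code{partition_fixture_spec}.
#' @export
partition_fixture_spec <- function(Q_target = c(cation_1 = 3),
                                   r_gel = 8, L = 40, N_ions = 400,
                                   n_frames = 50, seed = 1L,
                                   include_dummy_gel = TRUE,
                                   n_gel_beads = 200L) {
  stopifnot(all(Q_target > 0), r_gel > 0, L > 0, N_ions > 0, n_frames >= 1)
  if (r_gel >= L / 4) stop("fixture requires r_gel < L/4 for a bulk region")
  structure(list(Q_target = Q_target, r_gel = r_gel, L = L,
                 N_ions = N_ions, n_frames = n_frames,
                 seed = as.integer(seed),
                 include_dummy_gel = include_dummy_gel,
                 n_gel_beads = as.integer(n_gel_beads)),
            class = "partition_fixture_spec")
}

#' Generate a partition fixture trajectory
#'
#' Ions are placed uniformly inside the ball of radius r_gel at density
#' Q_target x rho_bulk and uniformly outside at rho_bulk; counts are
#' solved from N_ions and the two volumes.  The construction is the
#' oracle: analysing the fixture must recover Q_target.
#'
#' @param spec a \code{\link{partition_fixture_spec}}.
#' @return A \code{gel_trajectory}; ground truth in
#'   \code{meta$ground_truth}.
#' @export
make_partition_fixture <- function(spec) {
  stopifnot(inherits(spec, "partition_fixture_spec"))
  set.seed(spec$seed)
  L <- spec$L; rg <- spec$r_gel
  ctr <- rep(L / 2, 3)
  V_in <- 4 / 3 * pi * rg^3
  V_out <- L^3 - V_in

  sample_ball <- function(n, R) {
    if (n == 0) return(matrix(0, 0, 3))
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- R * stats::runif(n)^(1 / 3)
    sweep(u * r, 2, ctr, `+`)
  }
  sample_out <- function(n) {
    out <- matrix(NA_real_, 0, 3)
    while (nrow(out) < n) {
      p <- matrix(stats::runif(3 * 2 * (n - nrow(out)), 0, L), ncol = 3)
      d2 <- rowSums(sweep(p, 2, ctr)^2)
      out <- rbind(out, p[d2 > rg^2, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }

  species_all <- character(0); counts_in <- integer(0)
  for (sp in names(spec$Q_target)) {
    Q <- spec$Q_target[[sp]]
    # N = rho_out (V_out + Q V_in)  =>  expected counts per region
    n_in <- round(spec$N_ions * Q * V_in / (V_out + Q * V_in))
    n_out <- spec$N_ions - n_in
    if (n_in < 1 || n_out < 50)
      stop("infeasible fixture counts for species ", sp,
           " (interior ", n_in, ", bulk ", n_out, ")")
    counts_in[sp] <- n_in
    species_all <- c(species_all, rep(sp, spec$N_ions))
  }

  gel_pos <- if (spec$include_dummy_gel)
    sample_ball(spec$n_gel_beads, rg) else matrix(0, 0, 3)
  n_gel <- nrow(gel_pos)
  qmap <- c(cation_1 = 1L, cation_2 = 2L, coion = -1L)
  species <- c(rep("gel_segment", n_gel), species_all)
  charge <- c(rep(-1L, n_gel), qmap[species_all])

  frames <- vector("list", spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    ion_pos <- do.call(rbind, lapply(names(spec$Q_target), function(sp) {
      rbind(sample_ball(counts_in[[sp]], rg),
            sample_out(spec$N_ions - counts_in[[sp]]))
    }))
    frames[[fi]] <- rbind(gel_pos, ion_pos)
  }
  st <- system_state(positions = frames[[spec$n_frames]], charge = charge,
                     species = species, bonds = matrix(integer(0), 0, 2),
                     L = L,
                     meta = list(ground_truth = list(
                       Q_target = as.list(spec$Q_target),
                       r_gel = rg, Rg_expected = rg * sqrt(3 / 5),
                       seed = spec$seed)))
  gel_trajectory(frames, seq_len(spec$n_frames), st,
                 meta = st$meta)
}

#' Synthetic scaling table
#'
#' Q = A phi^kappa csalt^-mu exp(eta), eta lognormal with coefficient of
#' variation \code{noise_cv}; used to validate \code{\link{fit_scaling}}
#' parameter recovery.
#'
#' @param kappa,mu true exponents.
#' @param noise_cv lognormal noise CV (>= 0).
#' @param grid data.frame with columns \code{phi}, \code{csalt}.
#' @param A prefactor.
#' @param seed RNG seed.
#' @return data.frame with Q, phi, csalt.
#' @export
make_scaling_table <- function(kappa = 1.1, mu = 0.76, noise_cv = 0,
                               grid = expand.grid(
                                 phi = c(0.05, 0.1, 0.2, 0.4),
                                 csalt = c(1, 2, 5, 10, 20)),
                               A = 1, seed = 1L) {
  if (noise_cv < 0) stop("noise_cv must be non-negative")
  if (nrow(grid) < 2) stop("grid too small: fit needs >= 3 varying points")
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  eta <- if (noise_cv > 0)
    stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog) else 0
  data.frame(Q = A * grid$phi^kappa * grid$csalt^(-mu) * exp(eta),
             phi = grid$phi, csalt = grid$csalt)
}

#' Reference charge lattices with known Coulomb energy
#'
#' \code{"dimer"}: a +1/-1 pair at separation a along x in an otherwise
#' empty box (energy -> -lB/a as L grows).  \code{"rocksalt"}: the 8-ion
#' rock-salt unit cell with nearest-neighbour distance a filling a box of
#' side 2a; its energy per ion pair is -1.747565 lB/a (Madelung).
#'
#' @param kind \code{"dimer"} or \code{"rocksalt"}.
#' @param a separation / nearest-neighbour distance, sigma.
#' @param L box length (dimer only; rocksalt fixes L = 2a).
#' @return A \code{system_state}.
#' @export
make_lattice_charges <- function(kind = c("dimer", "rocksalt"), a = 1,
                                 L = 20) {
  kind <- match.arg(kind)
  if (kind == "dimer") {
    if (a >= L) stop("separation a must be < L")
    pos <- rbind(c(L / 2 - a / 2, L / 2, L / 2),
                 c(L / 2 + a / 2, L / 2, L / 2))
    return(system_state(pos, charge = c(1L, -1L),
                        species = c("cation_1", "coion"),
                        bonds = matrix(integer(0), 0, 2), L = L))
  }
  L <- 2 * a
  idx <- expand.grid(i = 0:1, j = 0:1, k = 0:1)
  pos <- as.matrix(idx) * a + a / 2
  q <- as.integer((-1)^(idx$i + idx$j + idx$k))
  system_state(pos, charge = q,
               species = ifelse(q > 0, "cation_1", "coion"),
               bonds = matrix(integer(0), 0, 2), L = L)
}
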