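# SystemState: the simulator's single source of truth.  Positions are
# wrapped into [0, L); species labels are fixed; charge is integer valence.

.SPECIES <- c("gel_segment", "gel_core", "cation_1", "cation_2", "coion")

#' Construct a system state
#'
#' @param positions N x 3 numeric matrix, sigma; wrapped into [0, L).
#' @param charge integer valences, length N; must sum to zero for an
#'   assembled (ion-bearing) system before simulation with Ewald.
#' @param species character vector, one of \code{gel_segment},
#'   \code{gel_core}, \code{cation_1}, \code{cation_2}, \code{coion}.
#' @param bonds m x 2 integer matrix of 1-based particle indices (each
#'   pair listed once), or a 0-row matrix.
#' @param L cubic box length in sigma; periodic in all three directions.
#' @param velocities N x 3 matrix in sigma/tau (default zero).
#' @param is_counterion logical length N; marks gel-neutralizing
#'   counterions, which are excluded from salt accounting.
#' @param meta list of provenance (seed, connectivity map, c0, ...).
#' @return An object of class \code{system_state}.
#' @export
system_state <- function(positions, charge, species, bonds, L,
                         velocities = NULL, is_counterion = NULL,
                         meta = list()) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, L > 0)
  N <- nrow(positions)
  charge <- as.integer(charge)
  species <- as.character(species)
  stopifnot(length(charge) == N, length(species) == N)
  if (!all(species %in% .SPECIES))
    stop("unknown species label(s): ",
         paste(setdiff(unique(species), .SPECIES), collapse = ", "))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1L | bonds > N)) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("bond joins a particle to itself")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bond")
  }
  if (is.null(velocities)) velocities <- matrix(0, N, 3)
  if (is.null(is_counterion)) is_counterion <- rep(FALSE, N)
  positions <- wrap_positions(positions, L)
  structure(list(positions = positions,
                 velocities = as.matrix(velocities),
                 charge = charge, species = species,
                 bonds = bonds, L = L,
                 is_counterion = is_counterion,
                 meta = meta),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  tab <- table(factor(x$species, levels = .SPECIES))
  cat("System state:", nrow(x$positions), "particles in L =",
      signif(x$L, 5), "sigma box;", nrow(x$bonds), "bonds\n")
  cat(" ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  cat("  net charge:", sum(x$charge), "\n")
  invisible(x)
}

#' Wrap coordinates into the half-open box [0, L)
#' @param x matrix or vector of coordinates.
#' @param L box length.
#' @return wrapped coordinates.
#' @export
wrap_positions <- function(x, L) x - L * floor(x / L)

#' Minimum-image separation
#' @param d displacement(s).
#' @param L box length.
#' @return displacement(s) folded into [-L/2, L/2).
#' @export
min_image <- function(d, L) d - L * round(d / L)

#' Net charge of a state (integer arithmetic)
#' @param state a \code{system_state}.
#' @return integer total valence.
#' @export
net_charge <- function(state) sum(state$charge)

#' Indices of gel beads (segments + cores)
#' @param state a \code{system_state}.
#' @return integer vector.
#' @export
gel_indices <- function(state)
  which(state$species %in% c("gel_segment", "gel_core"))
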