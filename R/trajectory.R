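# Trajectory container and plain-text I/O: LAMMPS data (atom_style full),
# LAMMPS dump (id type q x y z), XYZ, and JSON run configs.

.TYPE_OF <- c(gel_segment = 1L, gel_core = 2L, cation_1 = 3L,
              cation_2 = 4L, coion = 5L)

#' Trajectory container
#'
#' Frames of wrapped positions plus the (final) system state carrying
#' species, charges, bonds and the box.
#'
#' @param frames list of N x 3 matrices.
#' @param times frame times, tau.
#' @param state a \code{system_state} (topology/charges for all frames).
#' @param thermo thermo log matrix or NULL.
#' @param meta run metadata list.
#' @return An object of class \code{gel_trajectory}.
#' @export
gel_trajectory <- function(frames, times, state, thermo = NULL,
                           meta = list()) {
  stopifnot(is.list(frames), length(frames) == length(times))
  structure(list(frames = frames, times = times, state = state,
                 thermo = thermo, meta = meta),
            class = "gel_trajectory")
}

#' @export
print.gel_trajectory <- function(x, ...) {
  cat("Gel trajectory:", length(x$frames), "frames,",
      nrow(x$state$positions), "particles, L =", signif(x$state$L, 5),
      "sigma\n")
  invisible(x)
}

#' Number of frames
#' @param traj a \code{gel_trajectory}.
#' @return integer.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Write a LAMMPS data file (atom_style full)
#'
#' Sections: header with counts/types/box, Masses, Atoms (atom-ID
#' molecule-ID type charge x y z), Bonds.  A provenance JSON (seed,
#' connectivity map, c0) is written alongside as \code{<path>.json}.
#'
#' @param state a \code{system_state}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lammps_data <- function(state, path) {
  N <- nrow(state$positions); nb <- nrow(state$bonds)
  types <- .TYPE_OF[state$species]
  lines <- c(
    "LAMMPS data file generated by gelion",
    "",
    paste(N, "atoms"),
    paste(nb, "bonds"),
    paste(length(.TYPE_OF), "atom types"),
    paste(1, "bond types"),
    "",
    paste(0, state$L, "xlo xhi"),
    paste(0, state$L, "ylo yhi"),
    paste(0, state$L, "zlo zhi"),
    "",
    "Masses",
    "",
    paste(seq_along(.TYPE_OF), 1.0),
    "",
    "Atoms # full",
    "",
    sprintf("%d %d %d %d %.10g %.10g %.10g",
            seq_len(N), 1L, types, state$charge,
            state$positions[, 1], state$positions[, 2],
            state$positions[, 3]))
  if (any(state$velocities != 0))
    lines <- c(lines, "", "Velocities", "",
               sprintf("%d %.10g %.10g %.10g", seq_len(N),
                       state$velocities[, 1], state$velocities[, 2],
                       state$velocities[, 3]))
  if (nb > 0)
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d %d %d %d", seq_len(nb), 1L,
                       state$bonds[, 1], state$bonds[, 2]))
  writeLines(lines, path)
  prov <- list(seed = state$meta$ion_seed,
               connectivity_map = state$meta$connectivity_map,
               c0 = state$meta$salt_spec$c0,
               gel_spec = state$meta$gel_spec,
               salt_spec = state$meta$salt_spec,
               n_counterions = state$meta$n_counterions)
  jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a LAMMPS data file written by \code{\link{write_lammps_data}}
#'
#' @param path file path.
#' @return A \code{system_state} (counterion flags restored from the
#'   provenance JSON when present).
#' @export
read_lammps_data <- function(path) {
  ln <- readLines(path)
  grab <- function(pat) as.numeric(sub(paste0("\\s*", pat, ".*"), "",
                                       ln[grepl(pat, ln)][1]))
  N <- grab("atoms"); nb <- grab("bonds")
  box <- as.numeric(strsplit(trimws(ln[grepl("xlo xhi", ln)][1]),
                             "\\s+")[[1]][1:2])
  L <- box[2] - box[1]
  ai <- which(grepl("^Atoms", ln))[1]
  at <- do.call(rbind, strsplit(trimws(ln[(ai + 2):(ai + 1 + N)]), "\\s+"))
  storage.mode(at) <- "double"
  ord <- order(at[, 1])
  at <- at[ord, , drop = FALSE]
  species <- names(.TYPE_OF)[at[, 3]]
  bonds <- matrix(integer(0), 0, 2)
  if (!is.na(nb) && nb > 0) {
    bi <- which(grepl("^Bonds", ln))[1]
    bt <- do.call(rbind, strsplit(trimws(ln[(bi + 2):(bi + 1 + nb)]), "\\s+"))
    storage.mode(bt) <- "integer"
    bonds <- bt[, 3:4, drop = FALSE]
  }
  vel <- NULL
  vi <- which(grepl("^Velocities", ln))
  if (length(vi) == 1) {
    vt <- do.call(rbind, strsplit(trimws(ln[(vi[1] + 2):(vi[1] + 1 + N)]),
                                  "\\s+"))
    storage.mode(vt) <- "double"
    vel <- vt[order(vt[, 1]), 2:4, drop = FALSE]
  }
  is_counter <- rep(FALSE, N)
  meta <- list()
  pj <- paste0(path, ".json")
  if (file.exists(pj)) {
    prov <- jsonlite::read_json(pj, simplifyVector = TRUE)
    meta <- prov
    nc <- prov$n_counterions
    if (!is.null(nc) && nc > 0) {
      ci <- which(species == "cation_1")[seq_len(nc)]
      is_counter[ci] <- TRUE
    }
  }
  system_state(positions = at[, 5:7], charge = as.integer(at[, 4]),
               species = species, bonds = bonds, L = L,
               velocities = vel, is_counterion = is_counter, meta = meta)
}

#' Write a trajectory as a LAMMPS dump (id type q x y z)
#'
#' @param traj a \code{gel_trajectory}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lammps_dump <- function(traj, path) {
  st <- traj$state
  N <- nrow(st$positions)
  types <- .TYPE_OF[st$species]
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    p <- traj$frames[[fi]]
    writeLines(c("ITEM: TIMESTEP",
                 format(traj$times[fi], scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS", as.character(N),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste(0, st$L), paste(0, st$L), paste(0, st$L),
                 "ITEM: ATOMS id type q x y z",
                 sprintf("%d %d %d %.8g %.8g %.8g", seq_len(N), types,
                         st$charge, p[, 1], p[, 2], p[, 3])), con)
  }
  invisible(path)
}

#' Read a LAMMPS dump written by \code{\link{write_lammps_dump}}
#'
#' Bonds are not carried by dumps; pass \code{state} (e.g. from
#' \code{\link{read_lammps_data}}) to restore topology, otherwise the
#' trajectory has an empty bond list.
#'
#' @param path dump file.
#' @param state optional \code{system_state} supplying bonds/flags.
#' @return A \code{gel_trajectory}.
#' @export
read_lammps_dump <- function(path, state = NULL) {
  ln <- readLines(path)
  ts_at <- which(ln == "ITEM: TIMESTEP")
  frames <- list(); times <- numeric(0)
  species <- NULL; charge <- NULL; L <- NULL
  for (s in ts_at) {
    t <- as.numeric(ln[s + 1])
    N <- as.integer(ln[s + 3])
    box <- as.numeric(strsplit(ln[s + 5], "\\s+")[[1]])
    L <- box[2] - box[1]
    rows <- strsplit(ln[(s + 9):(s + 8 + N)], "\\s+")
    m <- matrix(as.numeric(unlist(rows)), N, 6, byrow = TRUE)
    m <- m[order(m[, 1]), , drop = FALSE]
    frames[[length(frames) + 1]] <- m[, 4:6, drop = FALSE]
    times <- c(times, t)
    if (is.null(species)) {
      species <- names(.TYPE_OF)[m[, 2]]
      charge <- as.integer(m[, 3])
    }
  }
  if (is.null(state)) {
    state <- system_state(positions = frames[[length(frames)]],
                          charge = charge, species = species,
                          bonds = matrix(integer(0), 0, 2), L = L)
  }
  gel_trajectory(frames, times, state)
}

#' Write a trajectory (or single state) in XYZ format
#'
#' Species labels are used as element names.
#'
#' @param traj a \code{gel_trajectory} or \code{system_state}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "system_state"))
    traj <- gel_trajectory(list(traj$positions), 0, traj)
  st <- traj$state
  con <- file(path, "w")
  on.exit(close(con))
  for (fi in seq_along(traj$frames)) {
    p <- traj$frames[[fi]]
    writeLines(c(as.character(nrow(p)),
                 paste0("t=", traj$times[fi], " L=", st$L),
                 sprintf("%s %.8g %.8g %.8g", st$species,
                         p[, 1], p[, 2], p[, 3])), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory written by \code{\link{write_xyz}}
#'
#' @param path file path.
#' @param L box length; taken from the comment line when present.
#' @return A \code{gel_trajectory} (charges inferred from species:
#'   gel beads -1, cation_1 +1, cation_2 +2, coion -1).
#' @export
read_xyz <- function(path, L = NULL) {
  ln <- readLines(path)
  i <- 1; frames <- list(); times <- numeric(0); species <- NULL
  while (i <= length(ln) && nzchar(trimws(ln[i]))) {
    N <- as.integer(ln[i])
    cm <- ln[i + 1]
    if (is.null(L) && grepl("L=", cm))
      L <- as.numeric(sub(".*L=([0-9.eE+-]+).*", "\\1", cm))
    t <- if (grepl("t=", cm))
      as.numeric(sub(".*t=([0-9.eE+-]+).*", "\\1", cm)) else length(times)
    rows <- strsplit(trimws(ln[(i + 2):(i + 1 + N)]), "\\s+")
    sp <- vapply(rows, `[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), N, 3,
                  byrow = TRUE)
    frames[[length(frames) + 1]] <- xyz
    times <- c(times, t)
    if (is.null(species)) species <- sp
    i <- i + 2 + N
  }
  if (is.null(L)) stop("box length unknown: pass L")
  qmap <- c(gel_segment = -1L, gel_core = -1L, cation_1 = 1L,
            cation_2 = 2L, coion = -1L)
  st <- system_state(positions = frames[[length(frames)]],
                     charge = qmap[species], species = species,
                     bonds = matrix(integer(0), 0, 2), L = L)
  gel_trajectory(frames, times, st)
}

#' Write the thermo log as CSV
#' @param traj a \code{gel_trajectory} with a thermo log.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_thermo_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj$thermo), path, row.names = FALSE)
  invisible(path)
}
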