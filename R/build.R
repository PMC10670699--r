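# Gel construction: star polymers on a cubic lattice with bridged free ends.

# Lattice directions (unit steps); at most 6 arms fit a cubic lattice site.
.DIRS <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, 0, 1), c(0, -1, 0), c(0, 0, -1))
rownames(.DIRS) <- c("+x", "-x", "+y", "+z", "-y", "-z")

#' Default inter-star connectivity map
#'
#' Assigns arm directions to lattice sites by parity so that every
#' interior free end is paired: a site of parity p carries arms along the
#' first \code{f} directions of an ordering chosen so the odd-parity set is
#' the mirror image of the even-parity set.  For the paper-like f = 4 case
#' this yields an alternating (diamond-like) pattern: all x-links bridged,
#' y- and z-links bridged on alternating sites, and the network connected.
#'
#' @param f arms per star (1..6).
#' @return list with \code{even} and \code{odd} character vectors of
#'   directions, serialized with build outputs for reproducibility.
#' @export
connectivity_map <- function(f = 4L) {
  f <- as.integer(f)
  if (f < 1L || f > 6L)
    stop("connectivity map incompatible with f = ", f,
         ": a cubic lattice site has 6 neighbors, need 1 <= f <= 6")
  even <- rownames(.DIRS)[seq_len(f)]
  flip <- c("+x" = "-x", "-x" = "+x", "+y" = "-y", "-y" = "+y",
            "+z" = "-z", "-z" = "+z")
  odd <- unname(flip[even])
  list(even = even, odd = odd)
}

#' Build the gel network
#'
#' Places \code{Nb^3} star polymers (core bead + f arms of M beads) on a
#' cubic lattice, joins the free ends of adjacent stars according to the
#' connectivity map, assigns \code{segment_valence} to every gel bead, and
#' centers the gel in the box.  Deterministic given the spec.  No ions are
#' added; the returned state is not electroneutral (see
#' \code{\link{add_ions}}).
#'
#' @param spec a \code{\link{gel_spec}}.
#' @param L box length in sigma.  Default 2.5x the fully swollen gel
#'   diameter estimate \code{2 * lattice_constant * Nb}, so a bulk plateau
#'   exists around the finite gel.
#' @param cmap connectivity map from \code{\link{connectivity_map}}.
#' @return A \code{system_state} containing gel beads and bonds only.
#' @examples
#' st <- build_gel(gel_spec(Nb = 2, f = 4, M = 5, lattice_constant = 10))
#' length(gel_indices(st))  # 8 * 21 = 168
#' @export
build_gel <- function(spec, L = NULL, cmap = connectivity_map(spec$f)) {
  stopifnot(inherits(spec, "gel_spec"))
  if (is.null(L)) L <- 2.5 * 2 * spec$lattice_constant * spec$Nb
  a <- spec$lattice_constant
  Nb <- spec$Nb; f <- spec$f; M <- spec$M
  dl <- a / (2 * M + 1)           # bead spacing along arms and bridges
  if (a * Nb > L) stop("box too small for the gel lattice")

  n_beads <- spec$Mw_gel
  pos <- matrix(0, n_beads, 3)
  species <- character(n_beads)
  # site index helpers
  site_id <- function(i, j, k) ((i - 1) * Nb + (j - 1)) * Nb + k  # 1..Nb^3
  core_of <- integer(Nb^3)
  # free-end bead index per (site, direction)
  free_end <- matrix(NA_integer_, Nb^3, 6,
                     dimnames = list(NULL, rownames(.DIRS)))
  arm_dirs_of <- vector("list", Nb^3)

  idx <- 0L
  for (i in seq_len(Nb)) for (j in seq_len(Nb)) for (k in seq_len(Nb)) {
    s <- site_id(i, j, k)
    parity <- (i + j + k) %% 2L
    dirs <- if (parity == 0L) cmap$even else cmap$odd
    arm_dirs_of[[s]] <- dirs
    centre <- (c(i, j, k) - (Nb + 1) / 2) * a   # gel centered at origin
    idx <- idx + 1L
    core_of[s] <- idx
    pos[idx, ] <- centre
    species[idx] <- "gel_core"
    for (d in dirs) {
      u <- .DIRS[d, ]
      for (m in seq_len(M)) {
        idx <- idx + 1L
        pos[idx, ] <- centre + (m * dl) * u
        species[idx] <- "gel_segment"
        if (m == M) free_end[s, d] <- idx
      }
    }
  }
  stopifnot(idx == n_beads)

  # intra-star bonds: core-first bead, then along each arm
  bonds <- vector("list", Nb^3 * f + 8L)
  bi <- 0L
  for (s in seq_len(Nb^3)) {
    dirs <- arm_dirs_of[[s]]
    first_of_arm <- core_of[s] + 1L +
      (seq_along(dirs) - 1L) * M   # layout: arms stored consecutively
    for (ai in seq_along(dirs)) {
      start <- first_of_arm[ai]
      bi <- bi + 1L
      bonds[[bi]] <- cbind(c(core_of[s], if (M > 1) start + 0:(M - 2)),
                           c(start, if (M > 1) start + 1:(M - 1)))
    }
  }
  # bridging bonds: site s, direction d pairs with neighbor's opposite arm
  opp <- c("+x" = "-x", "-x" = "+x", "+y" = "-y", "-y" = "+y",
           "+z" = "-z", "-z" = "+z")
  for (i in seq_len(Nb)) for (j in seq_len(Nb)) for (k in seq_len(Nb)) {
    s <- site_id(i, j, k)
    for (d in arm_dirs_of[[s]]) {
      u <- .DIRS[d, ]
      ni <- i + u[1]; nj <- j + u[2]; nk <- k + u[3]
      if (any(c(ni, nj, nk) < 1) || any(c(ni, nj, nk) > Nb)) next # dangling
      ns <- site_id(ni, nj, nk)
      if (!(opp[d] %in% arm_dirs_of[[ns]])) next
      if (s < ns) {            # each bridge once
        bi <- bi + 1L
        bonds[[bi]] <- cbind(free_end[s, d], free_end[ns, opp[d]])
      }
    }
  }
  bonds <- do.call(rbind, bonds[seq_len(bi)])

  # connectivity check (single component when the map permits it)
  comp <- .components(n_beads, bonds)
  if (max(comp) > 1L && f >= 4L)
    stop("internal error: f = ", f, " gel network is disconnected")

  st <- system_state(positions = pos + L / 2,  # center gel in the box
                     charge = rep(spec$segment_valence, n_beads),
                     species = species, bonds = bonds, L = L,
                     meta = list(gel_spec = unclass(spec),
                                 connectivity_map = cmap,
                                 n_components = max(comp)))
  st
}

# connected components via BFS on the bond graph
.components <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Conversion factor from reduced density to mmol/L
#'
#' Maps a reduced number density of 1/sigma^3 to mmol/L given the bead
#' size in nm.  The default bead size is inferred from the Bjerrum length
#' mapping for aqueous solutions, lB ~ 0.71 nm and lB ~ 2.1 sigma, giving
#' sigma = 0.71/2.1 ~ 0.338 nm.
#'
#' @param lB_reduced Bjerrum length in sigma at aqueous conditions
#'   (default 2.1).
#' @param lB_nm Bjerrum length in nm at aqueous conditions (default 0.71).
#' @return c0 in mmol/L per sigma^-3, with attributes \code{sigma_nm}.
#' @examples
#' default_c0()            # ~ 43000 mmol/L per sigma^-3
#' @export
default_c0 <- function(lB_reduced = 2.1, lB_nm = 0.71) {
  if (lB_reduced <= 0 || lB_nm <= 0) stop("Bjerrum lengths must be positive")
  sigma_nm <- lB_nm / lB_reduced
  NA_AVOGADRO <- 6.02214076e23
  # density 1/sigma^3 in mol/L: 1 / (N_A * sigma^3[L]); sigma^3 in litres
  c0 <- 1 / (NA_AVOGADRO * (sigma_nm * 1e-9)^3 * 1e3) * 1e3  # mmol/L
  attr(c0, "sigma_nm") <- sigma_nm
  c0
}

#' Add counterions and salt ions
#'
#' Inserts (i) monovalent counterions neutralizing the gel, (ii)
#' monovalent salt pairs (+1 cation / -1 coion) and (iii) divalent salt
#' units (+2 cation / two -1 coions) at counts chosen so that the
#' per-valence salt concentration c = c0 (rho_cation + rho_coion)/2
#' recovers the requested value within integer rounding.  Placement is
#' uniform in the box with rejection of positions within 0.9 sigma of any
#' existing particle (avoids force blow-ups at step one).  Counterions are
#' flagged and excluded from salt accounting.
#'
#' @param state a \code{system_state} containing the gel.
#' @param salt a \code{\link{salt_spec}}.
#' @param seed integer seed (placement is reproducible given the seed).
#' @param overlap_cut rejection distance, sigma.
#' @param max_tries placement attempts per ion before giving up.
#' @return An electroneutral \code{system_state}.
#' @export
add_ions <- function(state, salt, seed = 1L, overlap_cut = 0.9,
                     max_tries = 2000L) {
  stopifnot(inherits(state, "system_state"), inherits(salt, "salt_spec"))
  L <- state$L; V <- L^3
  gel_q <- sum(state$charge)
  if (gel_q > 0)
    stop("gel carries positive charge; monovalent cation counterions ",
         "cannot neutralize it")
  n_counter <- -gel_q                      # +1 counterions
  # mono pair: rho+ = rho- = n/V  => c = c0 n / V
  n_mono <- round(salt$c_mono * V / salt$c0)
  # divalent unit: rho++ = n/V, rho- = 2n/V => c = 1.5 c0 n / V
  n_div <- round(salt$c_div * V / (1.5 * salt$c0))
  n_coion <- n_mono + 2L * n_div
  n_new <- n_counter + n_mono + n_div + n_coion
  if (n_new == 0L) return(state)

  charge_new <- c(rep(1L, n_counter), rep(1L, n_mono), rep(2L, n_div),
                  rep(-1L, n_coion))
  species_new <- c(rep("cation_1", n_counter + n_mono),
                   rep("cation_2", n_div), rep("coion", n_coion))
  counter_new <- c(rep(TRUE, n_counter), rep(FALSE, n_mono + n_div + n_coion))

  set.seed(seed)
  pos_new <- .place_ions(state$positions, n_new, L, overlap_cut, max_tries)

  st <- system_state(
    positions = rbind(state$positions, pos_new),
    charge = c(state$charge, charge_new),
    species = c(state$species, species_new),
    bonds = state$bonds, L = L,
    velocities = rbind(state$velocities, matrix(0, n_new, 3)),
    is_counterion = c(state$is_counterion, counter_new),
    meta = c(state$meta,
             list(salt_spec = unclass(salt), ion_seed = as.integer(seed),
                  n_counterions = n_counter, n_mono_pairs = n_mono,
                  n_div_units = n_div)))
  if (sum(st$charge) != 0L)
    stop("electroneutrality not resolvable in integers (residual charge ",
         sum(st$charge), ")")
  st
}

# uniform insertion with overlap rejection against all placed particles;
# grid-bucketed for speed.
.place_ions <- function(existing, n, L, cut, max_tries) {
  nc <- max(1L, floor(L / max(cut, 1e-6)))
  cw <- L / nc
  key <- function(p) {
    ci <- pmin(pmax(floor(p / cw), 0), nc - 1)
    (ci[, 1] * nc + ci[, 2]) * nc + ci[, 3] + 1
  }
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  push <- function(p) {
    k <- as.character(key(matrix(p, 1)))
    buckets[[k]] <- rbind(buckets[[k]], p)
  }
  if (nrow(existing) > 0) apply(existing, 1, push)
  near_ok <- function(p) {
    ci <- floor(p / cw)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      cc <- (ci + c(dx, dy, dz)) %% nc
      k <- as.character((cc[1] * nc + cc[2]) * nc + cc[3] + 1)
      pts <- buckets[[k]]
      if (!is.null(pts)) {
        d <- min_image(sweep(pts, 2, p), L)
        if (any(rowSums(d^2) < cut^2)) return(FALSE)
      }
    }
    TRUE
  }
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- stats::runif(3, 0, L)
      if (near_ok(p)) { out[i, ] <- p; push(p); placed <- TRUE; break }
    }
    if (!placed)
      stop("ion placement failed: box too crowded after ", max_tries,
           " rejections (ion ", i, " of ", n, ")")
  }
  out
}

#' Salt concentration of an assembled state
#'
#' Per-valence concentration c = c0 (rho_cation + rho_matching_coion)/2
#' over the full box, in mmol/L.  Gel-neutralizing counterions are
#' excluded: csalt accounts for added salt only.
#'
#' @param state an assembled \code{system_state}.
#' @param c0 conversion factor (defaults to the one recorded at
#'   \code{\link{add_ions}} time, else \code{\link{default_c0}()}).
#' @return named numeric: \code{c_mono}, \code{c_div} in mmol/L.
#' @export
salt_concentration <- function(state, c0 = NULL) {
  if (is.null(c0)) {
    c0 <- state$meta$salt_spec$c0
    if (is.null(c0)) c0 <- default_c0()
  }
  V <- state$L^3
  n1 <- sum(state$species == "cation_1" & !state$is_counterion)
  n2 <- sum(state$species == "cation_2")
  # coions split by provenance: one per mono pair, two per divalent unit
  c_mono <- c0 * (n1 / V + n1 / V) / 2
  c_div <- c0 * (n2 / V + 2 * n2 / V) / 2
  c(c_mono = c_mono, c_div = unname(c_div))
}
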