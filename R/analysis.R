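# Gel observables and ion-partition statistics.
#
# The central quantities: the charged-particle pair correlation gq(r) --
# local ion concentration at distance r from the gel centre of mass,
# divided by the system-wide concentration of that species -- and the ion
# partition coefficient Qi, the ratio of the gq(r) plateau heights inside
# and outside the gel (equivalently Qi = c_i,gel / c_i,bulk).  Three
# radial regimes: gel interior plateau, interfacial crossover, bulk
# plateau.

#' Unwrap gel coordinates across periodic boundaries
#'
#' Breadth-first traversal of the bond graph choosing the minimum-image
#' offset per edge; the result is independent of the traversal root up to
#' a global lattice vector.
#'
#' @param positions N x 3 wrapped coordinates (gel beads only).
#' @param bonds m x 2 bond indices into \code{positions}.
#' @param L box length.
#' @return N x 3 unwrapped coordinates.
#' @export
unwrap_coords <- function(positions, bonds, L) {
  n <- nrow(positions)
  if (n == 1) return(positions)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- positions
  seen <- logical(n)
  queue <- 1L; seen[1] <- TRUE
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        out[w, ] <- out[v, ] + min_image(positions[w, ] - positions[v, ], L)
        queue <- c(queue, w)
      }
    }
  }
  if (!all(seen)) stop("gel bond graph is disconnected; cannot unwrap")
  out
}

#' Unwrap the gel beads of a frame
#'
#' @param frame N_all x 3 wrapped frame.
#' @param state the \code{system_state} carrying species and bonds.
#' @return list: \code{coords} (unwrapped gel coordinates), \code{idx}
#'   (gel bead indices), \code{com} (gel centre of mass, wrapped into the
#'   box).
#' @export
unwrap_gel <- function(frame, state) {
  gi <- gel_indices(state)
  if (length(gi) == 0) stop("no gel beads in state")
  b <- state$bonds
  keep <- b[, 1] %in% gi & b[, 2] %in% gi
  b <- b[keep, , drop = FALSE]
  remap <- match(seq_len(nrow(frame)), gi)
  bl <- cbind(match(b[, 1], gi), match(b[, 2], gi))
  if (length(gi) > 1 && nrow(bl) == 0) {
    # bond-free dummy gels (fixtures): assume the gel does not straddle
    # the boundary and use coordinates as-is
    coords <- frame[gi, , drop = FALSE]
  } else {
    coords <- unwrap_coords(frame[gi, , drop = FALSE], bl, state$L)
  }
  com <- colMeans(coords)
  list(coords = coords, idx = gi,
       com = wrap_positions(matrix(com, 1), state$L)[1, ])
}

#' Radius of gyration of the gel
#'
#' Mass-weighted (equal masses) Rg over unwrapped gel beads, averaged over
#' frames, with a block-averaged standard error.
#'
#' @param traj a \code{gel_trajectory}.
#' @param n_blocks blocks for the standard error (default 5).
#' @return list: \code{Rg}, \code{se}, \code{per_frame}.
#' @export
gel_rg <- function(traj, n_blocks = 5) {
  if (n_frames(traj) < 1) stop("empty trajectory")
  per <- vapply(traj$frames, function(fr) {
    u <- unwrap_gel(fr, traj$state)
    sqrt(mean(rowSums(sweep(u$coords, 2, colMeans(u$coords))^2)))
  }, 0.0)
  list(Rg = mean(per), se = .block_se(per, n_blocks), per_frame = per)
}

.block_se <- function(x, n_blocks) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  n_blocks <- max(2L, min(n_blocks, n))
  bl <- split(x, cut(seq_len(n), n_blocks, labels = FALSE))
  m <- vapply(bl, mean, 0.0)
  stats::sd(m) / sqrt(length(m))
}

#' Exact volume of a centred sphere clipped to the periodic box
#'
#' Volume of the intersection of a ball of radius r with the cube of side
#' L about its centre; exact circle-square cross-sections integrated by
#' Simpson's rule (quadrature error negligible at n ~ 400).
#'
#' @param r radius (vectorized).
#' @param L box length.
#' @param n quadrature points.
#' @return volumes.
#' @export
sphere_box_volume <- function(r, L, n = 401) {
  a <- L / 2
  one <- function(r1) {
    if (r1 <= 0) return(0)
    if (r1 <= a) return(4 / 3 * pi * r1^3)
    r1 <- min(r1, a * sqrt(3))
    # cross-section area: circle radius rho centred in square half-width a
    area <- function(z) {
      rho2 <- r1^2 - z^2
      rho <- sqrt(pmax(rho2, 0))
      out <- ifelse(rho <= a, pi * rho2,
             ifelse(rho >= a * sqrt(2), 4 * a^2,
                    pi * rho2 - 4 * (rho2 * acos(pmin(a / pmax(rho, 1e-300), 1)) -
                                     a * sqrt(pmax(rho2 - a^2, 0)))))
      out
    }
    zmax <- min(r1, a)
    z <- seq(0, zmax, length.out = n)
    h <- z[2] - z[1]
    w <- rep(c(4, 2), length.out = n - 2)
    2 * h / 3 * (area(z[1]) + sum(w * area(z[2:(n - 1)])) + area(z[n]))
  }
  vapply(r, one, 0.0)
}

#' Charged-particle pair correlation gq(r)
#'
#' Per-frame histogram of a species' minimum-image distances from the gel
#' centre of mass, divided by the exact (box-clipped) shell volume and by
#' the system-wide number density of that species, averaged over frames.
#' A uniform ideal gas gives gq(r) = 1 in every bin.
#'
#' @param traj a \code{gel_trajectory}.
#' @param species one of \code{cation_1}, \code{cation_2}, \code{coion}
#'   (or gel species).
#' @param bin_width bin width, sigma.
#' @param r_max histogram extent (default 0.5 L; may extend to
#'   \code{sqrt(3)/2 L} thanks to clipped shell volumes).
#' @param include_counterions count gel-neutralizing counterions as part
#'   of their species (default TRUE; they are physically identical to
#'   salt cations).  Set FALSE to follow the added salt ions only --
#'   at desk scale a small gel loses most counterions to the bulk, and
#'   their re-condensation as the gel compacts can mask the salt
#'   species' own Donnan response.
#' @return A \code{radial_profile}: r_centers, gq, counts, per-frame
#'   count matrix, shell volumes, n_frames, species.
#' @export
charged_pair_correlation <- function(traj, species, bin_width = 1,
                                     r_max = NULL,
                                     include_counterions = TRUE) {
  stopifnot(bin_width > 0)
  st <- traj$state
  sel <- which(st$species == species)
  if (!include_counterions) sel <- setdiff(sel, which(st$is_counterion))
  if (length(sel) == 0) stop("species '", species, "' absent from system")
  L <- st$L
  if (is.null(r_max)) r_max <- L / 2
  r_max <- min(r_max, L * sqrt(3) / 2)
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  nb <- length(edges) - 1
  shell <- diff(sphere_box_volume(edges, L))
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  cnt <- matrix(0, nb, nf)
  for (fi in seq_len(nf)) {
    fr <- traj$frames[[fi]]
    com <- unwrap_gel(fr, st)$com
    d <- sqrt(rowSums(min_image(sweep(fr[sel, , drop = FALSE], 2, com),
                                L)^2))
    h <- graphics::hist(d[d < r_max], breaks = edges, plot = FALSE)
    cnt[, fi] <- h$counts
  }
  rho_sys <- length(sel) / L^3
  gq <- rowMeans(cnt) / shell / rho_sys
  structure(list(r_centers = (edges[-1] + edges[-length(edges)]) / 2,
                 gq = gq, counts = rowSums(cnt), counts_per_frame = cnt,
                 shell_volumes = shell, n_frames = nf, species = species,
                 rho_sys = rho_sys, L = L, edges = edges),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat("Radial profile gq(r) for", x$species, ":", length(x$gq), "bins to",
      signif(max(x$edges), 4), "sigma over", x$n_frames, "frames\n")
  invisible(x)
}

#' Gel observables for a trajectory
#'
#' Radius of gyration, centre of mass (last frame), internal volume
#' fraction and the interior radius used for it.
#'
#' @param traj a \code{gel_trajectory}.
#' @param r_interior_factor interior region = sphere of this multiple of
#'   Rg about the gel COM (default 0.5, matching the interior plateau
#'   window).
#' @return list of class \code{gel_observables}: Rg, se_Rg, com, phi,
#'   r_gel_interior.
#' @export
gel_observables <- function(traj, r_interior_factor = 0.5) {
  rg <- gel_rg(traj)
  r_int <- r_interior_factor * rg$Rg
  phi <- internal_volume_fraction(traj, r_interior = r_int)
  com <- unwrap_gel(traj$frames[[n_frames(traj)]], traj$state)$com
  structure(list(Rg = rg$Rg, se_Rg = rg$se, com = com,
                 phi = phi$phi, r_gel_interior = r_int),
            class = "gel_observables")
}

#' Internal volume fraction of the gel
#'
#' phi = (number of gel beads within the interior sphere) x (pi/6) sigma^3
#' / (sphere volume), averaged over frames.  Beads are size-sigma WCA
#' spheres, hence the hard-sphere volume (pi/6) sigma^3.
#'
#' @param traj a \code{gel_trajectory}.
#' @param r_interior interior radius, sigma (default 0.5 x Rg).
#' @return list: \code{phi}, \code{r_interior}, \code{mean_count}.
#' @export
internal_volume_fraction <- function(traj, r_interior = NULL) {
  st <- traj$state
  if (is.null(r_interior)) r_interior <- 0.5 * gel_rg(traj)$Rg
  counts <- vapply(traj$frames, function(fr) {
    u <- unwrap_gel(fr, st)
    d2 <- rowSums(min_image(sweep(fr[u$idx, , drop = FALSE], 2, u$com),
                            st$L)^2)
    sum(d2 < r_interior^2)
  }, 0.0)
  if (all(counts == 0)) stop("no gel beads inside the interior region")
  vol <- sphere_box_volume(r_interior, st$L)
  list(phi = mean(counts) * (pi / 6) / vol, r_interior = r_interior,
       mean_count = mean(counts))
}

#' Ion partition coefficient from a radial profile
#'
#' Qi = mean gq over the interior window / mean gq over the bulk window.
#' Default windows: interior r in [0, 0.5 Rg]; bulk r in
#' [max(1.5 Rg, Rg + 5 sigma), 0.45 L].  The interfacial crossover
#' between them is excluded.  Standard errors by frame block bootstrap.
#' A flatness diagnostic flags windows whose fitted relative slope
#' exceeds \code{flat_tol} (plateau assumption questionable).
#'
#' @param profile a \code{radial_profile}.
#' @param gel_obs a \code{gel_observables} (supplies Rg).
#' @param window_policy optional list overriding \code{r_in} and
#'   \code{r_bulk} (each a length-2 range in sigma).
#' @param n_boot bootstrap replicates.
#' @param block_len bootstrap block length in frames.
#' @param flat_tol relative slope threshold for the flatness warning.
#' @return A \code{partition_result}: Q, c_in, c_bulk, windows, se_Q,
#'   flags.
#' @export
partition_coefficients <- function(profile, gel_obs, window_policy = NULL,
                                   n_boot = 200, block_len = 10,
                                   flat_tol = 0.5) {
  Rg <- gel_obs$Rg
  L <- profile$L
  r_in <- c(0, 0.5 * Rg)
  r_bulk <- c(max(1.5 * Rg, Rg + 5), 0.45 * L)
  if (!is.null(window_policy)) {
    if (!is.null(window_policy$r_in)) r_in <- window_policy$r_in
    if (!is.null(window_policy$r_bulk)) r_bulk <- window_policy$r_bulk
  }
  if (r_in[2] > r_bulk[1])
    stop("interior window overlaps bulk window")
  rc <- profile$r_centers
  in_bins <- which(rc >= r_in[1] & rc <= r_in[2])
  bulk_bins <- which(rc >= r_bulk[1] & rc <= r_bulk[2])
  if (length(in_bins) == 0) stop("interior window contains no bins")
  if (length(bulk_bins) == 0) stop("bulk window contains no bins")

  conc <- function(cnt_rows, bins) {
    # mean density over the window (counts per volume per frame)
    sum(cnt_rows[bins]) / sum(profile$shell_volumes[bins])
  }
  mean_cnt <- rowMeans(profile$counts_per_frame)
  c_in <- conc(mean_cnt, in_bins)
  c_bulk <- conc(mean_cnt, bulk_bins)
  if (c_bulk <= 0) stop("no ions in the bulk window")
  if (c_in <= 0) stop("no ions in the interior window")
  Q <- c_in / c_bulk

  # frame block bootstrap
  nf <- profile$n_frames
  se_Q <- NA_real_
  if (nf >= 2 && n_boot > 0) {
    block_len <- max(1L, min(block_len, nf))
    nblk <- ceiling(nf / block_len)
    starts <- seq(1, nf, by = block_len)
    qb <- replicate(n_boot, {
      pick <- sample(starts, nblk, replace = TRUE)
      idx <- unlist(lapply(pick, function(s) s:min(s + block_len - 1, nf)))
      mc <- rowMeans(profile$counts_per_frame[, idx, drop = FALSE])
      ci <- conc(mc, in_bins); cb <- conc(mc, bulk_bins)
      if (cb > 0 && ci > 0) ci / cb else NA_real_
    })
    se_Q <- stats::sd(qb, na.rm = TRUE)
  }

  flat <- function(bins) {
    if (length(bins) < 3) return(NA_real_)
    g <- profile$gq[bins]; r <- rc[bins]
    if (all(g == 0)) return(NA_real_)
    fit <- suppressWarnings(summary(stats::lm(g ~ r)))
    sl <- fit$coefficients["r", "Estimate"]
    se <- fit$coefficients["r", "Std. Error"]
    # a trend only counts against flatness when it is resolved above
    # the bin-to-bin sampling noise (2 se), else narrow noisy windows
    # would be flagged spuriously
    if (is.finite(se) && abs(sl) < 2 * se) return(0)
    abs(sl) * diff(range(r)) / max(mean(g), 1e-300)
  }
  fl_in <- flat(in_bins); fl_bulk <- flat(bulk_bins)
  flagged <- isTRUE(fl_in > flat_tol) || isTRUE(fl_bulk > flat_tol)
  if (flagged)
    warning("plateau flatness test failed (relative slope interior = ",
            signif(fl_in, 3), ", bulk = ", signif(fl_bulk, 3),
            "); partition coefficient flagged")
  structure(list(Q = Q, c_in = c_in, c_bulk = c_bulk,
                 r_in_window = r_in, r_bulk_window = r_bulk,
                 se_Q = se_Q, species = profile$species,
                 flatness = c(interior = unname(fl_in),
                              bulk = unname(fl_bulk)),
                 flagged = flagged),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Partition coefficient (", x$species, "): Q = ", signif(x$Q, 4),
      " +/- ", signif(x$se_Q, 3), if (x$flagged) "  [FLAGGED]", "\n",
      sep = "")
  invisible(x)
}

#' Ratio of partition coefficients Q2/Q1
#'
#' First-order error propagation:
#' se = ratio * sqrt((se1/Q1)^2 + (se2/Q2)^2).
#'
#' @param result2 \code{partition_result} for divalent ions (numerator).
#' @param result1 \code{partition_result} for monovalent ions.
#' @return list: \code{ratio}, \code{se}.
#' @export
partition_ratio <- function(result2, result1) {
  stopifnot(result1$Q > 0, result2$Q > 0)
  r <- result2$Q / result1$Q
  se <- r * sqrt((result1$se_Q / result1$Q)^2 +
                 (result2$se_Q / result2$Q)^2)
  list(ratio = r, se = se)
}

#' Fit the partition scaling law
#'
#' Ordinary least squares on log Qi = logA + kappa log phi - mu log
#' csalt.  Single-covariate fits (mu only at fixed phi, kappa only at
#' fixed csalt) and the joint fit are supported; covariates constant to
#' within numerical noise are dropped automatically when
#' \code{covariates = "auto"}.
#'
#' @param table data.frame with columns \code{Q}, \code{phi},
#'   \code{csalt} (all positive; >= 3 rows varying in the fitted
#'   covariates).
#' @param covariates \code{"auto"}, \code{"both"}, \code{"phi"}, or
#'   \code{"csalt"}.
#' @return A \code{scaling_fit}: kappa, mu, logA, se_kappa, se_mu,
#'   r_squared, ranges, and the lm fit.
#' @export
fit_scaling <- function(table, covariates = c("auto", "both", "phi",
                                              "csalt")) {
  covariates <- match.arg(covariates)
  stopifnot(all(c("Q", "csalt", "phi") %in% names(table) |
                c("Q", "csalt", "phi") %in% names(table)))
  if (any(table$Q <= 0) || any(table$phi <= 0) || any(table$csalt <= 0))
    stop("all of Q, phi, csalt must be positive for the log-log fit")
  if (nrow(table) < 3) stop("need >= 3 points to fit")
  lq <- log(table$Q); lp <- log(table$phi); lc <- log(table$csalt)
  varies <- function(x) stats::sd(x) > 1e-12 * max(abs(x), 1e-300)
  use_phi <- switch(covariates, auto = varies(lp), both = TRUE,
                    phi = TRUE, csalt = FALSE)
  use_cs <- switch(covariates, auto = varies(lc), both = TRUE,
                   phi = FALSE, csalt = TRUE)
  if (!use_phi && !use_cs) stop("no varying covariate to fit")
  df <- data.frame(lq = lq, lp = lp, lc = lc)
  form <- stats::as.formula(paste("lq ~",
    paste(c(if (use_phi) "lp", if (use_cs) "lc"), collapse = " + ")))
  if ((use_phi && !varies(lp)) || (use_cs && !varies(lc)))
    stop("collinear design: requested covariate does not vary")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) stop("collinear design")
  # noiseless synthetic tables fit perfectly; summary.lm warns about it
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  get <- function(nm, col) if (nm %in% rownames(co)) co[nm, col] else NA_real_
  structure(list(kappa = get("lp", 1), mu = -get("lc", 1),
                 logA = co["(Intercept)", 1],
                 se_kappa = get("lp", 2), se_mu = get("lc", 2),
                 r_squared = sm$r.squared,
                 n = nrow(table),
                 phi_range = range(table$phi),
                 csalt_range = range(table$csalt),
                 fit = fit),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Scaling fit  Q ~ phi^kappa csalt^-mu  (n =", x$n, ")\n")
  if (!is.na(x$kappa))
    cat("  kappa =", signif(x$kappa, 4), "+/-", signif(x$se_kappa, 3), "\n")
  if (!is.na(x$mu))
    cat("  mu    =", signif(x$mu, 4), "+/-", signif(x$se_mu, 3), "\n")
  cat("  R^2 =", signif(x$r_squared, 4), "\n")
  invisible(x)
}
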