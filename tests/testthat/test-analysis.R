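# Observables: unwrapping, Rg, shell volumes, gq(r), Q, phi, scaling fits.

test_that("unwrapping: identity inside the box, shifts across boundaries", {
  pos <- rbind(c(2, 2, 2), c(2.99, 2, 2))
  b <- matrix(c(1L, 2L), 1)
  expect_equal(unwrap_coords(pos, b, 10), pos)
  # bond straddling the boundary
  pos2 <- rbind(c(9.8, 5, 5), c(0.2, 5, 5))
  u <- unwrap_coords(pos2, b, 10)
  expect_equal(u[2, 1], 10.2)
  expect_error(unwrap_coords(rbind(pos, c(7, 7, 7)), b, 10),
               "disconnected")
})

test_that("Rg survives random wrapping (round trip to 1e-10)", {
  set.seed(21)
  st <- build_gel(gel_spec(Nb = 2, f = 4, M = 5), L = 25)
  # random rigid shift so the gel straddles several boundaries
  shift <- c(22, 13.7, 24.2)
  wrapped <- wrap_positions(sweep(st$positions, 2, shift, `+`), st$L)
  u <- unwrap_coords(wrapped, st$bonds, st$L)
  expect_equal(rg_bruteforce(u), rg_bruteforce(st$positions),
               tolerance = 1e-10)
})

test_that("gel_rg closed forms and brute-force agreement", {
  mk <- function(pos) {
    n <- nrow(pos)
    st <- system_state(pos, rep(-1L, n), rep("gel_segment", n),
                       if (n > 1) cbind(1:(n - 1), 2:n)
                       else matrix(integer(0), 0, 2), L = 100)
    gel_trajectory(list(pos), 0, st)
  }
  expect_equal(gel_rg(mk(matrix(5, 4, 3) +
                         cbind(c(0, 1e-9, 0, 1e-9), 0, 0)))$Rg, 0,
               tolerance = 1e-6)
  # two beads at distance d: Rg = d/2
  expect_equal(gel_rg(mk(rbind(c(5, 5, 5), c(8, 5, 5))))$Rg, 1.5)
  # 8 beads at cube corners, edge a: Rg = a sqrt(3)/2; cross-check oracle
  a <- 2
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * a + 10
  # chain bonds connecting the corners (a Hamiltonian path)
  path <- c(1, 2, 4, 3, 7, 8, 6, 5)
  st <- system_state(cube, rep(-1L, 8), rep("gel_segment", 8),
                     cbind(path[-8], path[-1]), L = 100)
  tr <- gel_trajectory(list(cube), 0, st)
  expect_equal(gel_rg(tr)$Rg, a * sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(gel_rg(tr)$Rg, rg_bruteforce(cube), tolerance = 1e-12)
  expect_error(gel_rg(gel_trajectory(list(), numeric(0), st)), "empty")
})

test_that("sphere-box clipped volumes match Monte Carlo and limits", {
  L <- 10
  expect_equal(sphere_box_volume(4, L), 4 / 3 * pi * 64, tolerance = 1e-12)
  expect_equal(sphere_box_volume(L * sqrt(3) / 2, L), L^3, tolerance = 1e-6)
  for (r in c(5.5, 6.5, 8)) {
    expect_equal(sphere_box_volume(r, L), sphere_box_volume_mc(r, L),
                 tolerance = 0.01)
  }
})

test_that("gq(r) of a uniform ideal gas is 1 in every bin (3 se)", {
  fx <- make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 1), r_gel = 8, L = 40, N_ions = 1000,
    n_frames = 30, seed = 31))
  prof <- charged_pair_correlation(fx, "cation_1", bin_width = 2)
  per_gq <- prof$counts_per_frame / prof$shell_volumes / prof$rho_sys
  se <- apply(per_gq, 1, stats::sd) / sqrt(prof$n_frames)
  expect_true(all(abs(prof$gq - 1) <= 3 * se + 0.02))
  expect_error(charged_pair_correlation(fx, "cation_2"), "absent")
})

test_that("partition fixture plateaus recover the constructed Q", {
  fx <- make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 3), r_gel = 8, L = 40, N_ions = 1500,
    n_frames = 60, seed = 32))
  obs <- gel_observables(fx)
  expect_equal(obs$Rg, 8 * sqrt(3 / 5), tolerance = 0.05)
  prof <- charged_pair_correlation(fx, "cation_1", bin_width = 1)
  res <- partition_coefficients(prof, obs)
  expect_equal(res$Q, 3, tolerance = 0.05)
  expect_false(res$flagged)
  expect_true(res$se_Q > 0)
})

test_that("flat profile gives Q = 1; window misuse errors", {
  fx <- make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 1), r_gel = 8, L = 40, N_ions = 1200,
    n_frames = 40, seed = 33))
  obs <- gel_observables(fx)
  prof <- charged_pair_correlation(fx, "cation_1", bin_width = 1.5)
  res <- partition_coefficients(prof, obs,
           window_policy = list(r_in = c(0, 7)))
  expect_equal(res$Q, 1, tolerance = 0.06)
  expect_error(partition_coefficients(prof, obs,
                 window_policy = list(r_in = c(0, 12), r_bulk = c(11, 18))),
               "overlap")
  expect_error(partition_coefficients(prof, obs,
                 window_policy = list(r_bulk = c(19.4, 19.45))),
               "no bins")
})

test_that("non-flat interface window triggers the flatness flag", {
  fx <- make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 8), r_gel = 8, L = 40, N_ions = 1500,
    n_frames = 40, seed = 34))
  obs <- gel_observables(fx)
  prof <- charged_pair_correlation(fx, "cation_1", bin_width = 1)
  # window straddling the density step is not a plateau
  expect_warning(
    res <- partition_coefficients(prof, obs,
             window_policy = list(r_in = c(4, 11))),
    "flatness")
  expect_true(res$flagged)
})

test_that("internal volume fraction counting rule", {
  # beads on a unit lattice filling the interior: phi -> pi/6
  g <- as.matrix(expand.grid(-5:5, -5:5, -5:5)) + 20
  st <- system_state(g, rep(-1L, nrow(g)), rep("gel_segment", nrow(g)),
                     matrix(integer(0), 0, 2), L = 40)
  tr <- gel_trajectory(list(g), 0, st)
  v <- internal_volume_fraction(tr, r_interior = 4.5)
  expect_equal(v$phi, pi / 6, tolerance = 0.05)
  # halving the bead count in the region halves phi
  g2 <- g[seq(1, nrow(g), by = 2), ]
  st2 <- system_state(g2, rep(-1L, nrow(g2)), rep("gel_segment", nrow(g2)),
                      matrix(integer(0), 0, 2), L = 40)
  v2 <- internal_volume_fraction(gel_trajectory(list(g2), 0, st2),
                                 r_interior = 4.5)
  expect_equal(v2$phi / v$phi, 0.5, tolerance = 0.06)
})

test_that("collapsed vs swollen fixtures order phi inversely to Rg", {
  mk <- function(R) make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 1), r_gel = R, L = 48, N_ions = 500,
    n_frames = 5, seed = 35, n_gel_beads = 300))
  small <- mk(6); big <- mk(11)
  os <- gel_observables(small); ob <- gel_observables(big)
  expect_lt(os$Rg, ob$Rg)
  expect_gt(os$phi, ob$phi)
})

test_that("fit_scaling: noiseless recovery is exact", {
  tb <- make_scaling_table(kappa = 1.1, mu = 0, noise_cv = 0,
                           grid = data.frame(phi = c(0.05, 0.1, 0.2, 0.4),
                                             csalt = 5))
  f <- fit_scaling(tb)
  expect_equal(f$kappa, 1.1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  tb2 <- make_scaling_table(kappa = 0, mu = 0.76, noise_cv = 0,
                            grid = data.frame(phi = 0.2,
                                              csalt = c(1, 2, 5, 10, 20)))
  f2 <- fit_scaling(tb2)
  expect_equal(f2$mu, 0.76, tolerance = 1e-10)
  # joint fit
  tb3 <- make_scaling_table(kappa = 1.1, mu = 0.89, noise_cv = 0)
  f3 <- fit_scaling(tb3, covariates = "both")
  expect_equal(f3$kappa, 1.1, tolerance = 1e-10)
  expect_equal(f3$mu, 0.89, tolerance = 1e-10)
})

test_that("fit_scaling input validation", {
  tb <- make_scaling_table()
  tb$Q[1] <- -1
  expect_error(fit_scaling(tb), "positive")
  same <- data.frame(Q = c(1, 1, 1), phi = 0.2, csalt = 5)
  expect_error(fit_scaling(same), "covariate|collinear")
  expect_error(fit_scaling(make_scaling_table()[1:2, ]), ">= 3")
})

test_that("partition_ratio and propagated error vs bootstrap", {
  r1 <- structure(list(Q = 3, se_Q = 0.1), class = "partition_result")
  r2 <- structure(list(Q = 6, se_Q = 0.3), class = "partition_result")
  pr <- partition_ratio(r2, r1)
  expect_equal(pr$ratio, 2)
  expect_equal(pr$se, 2 * sqrt((0.1 / 3)^2 + (0.3 / 6)^2), tolerance = 1e-12)
  expect_equal(partition_ratio(r1, r1)$ratio, 1)
  # first-order propagation vs bootstrap on fixture-derived results
  fx <- make_partition_fixture(partition_fixture_spec(
    Q_target = c(cation_1 = 3, cation_2 = 6), r_gel = 8, L = 40,
    N_ions = 1200, n_frames = 50, seed = 36))
  obs <- gel_observables(fx)
  # fixture frames are i.i.d., so block length 1 matches the truth
  q1 <- partition_coefficients(
    charged_pair_correlation(fx, "cation_1", 1), obs,
    n_boot = 400, block_len = 1)
  # few-bin interior window is noisy for the sparse divalent species;
  # the flatness flag is irrelevant to the se comparison here
  q2 <- suppressWarnings(partition_coefficients(
    charged_pair_correlation(fx, "cation_2", 1), obs,
    n_boot = 400, block_len = 1))
  pr2 <- partition_ratio(q2, q1)
  # bootstrap the ratio directly over frames
  set.seed(40)
  p1 <- charged_pair_correlation(fx, "cation_1", 1)
  p2 <- charged_pair_correlation(fx, "cation_2", 1)
  qb <- replicate(200, {
    idx <- sample(p1$n_frames, replace = TRUE)
    f <- function(p) {
      mc <- rowMeans(p$counts_per_frame[, idx, drop = FALSE])
      rc <- p$r_centers
      ib <- rc <= 0.5 * obs$Rg
      bb <- rc >= max(1.5 * obs$Rg, obs$Rg + 5) & rc <= 0.45 * p$L
      (sum(mc[ib]) / sum(p$shell_volumes[ib])) /
        (sum(mc[bb]) / sum(p$shell_volumes[bb]))
    }
    f(p2) / f(p1)
  })
  expect_lt(abs(pr2$se - stats::sd(qb)) / stats::sd(qb), 0.2)
})
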