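# Integrator and thermostat behaviour.

free_particle <- function(v = c(1, 0, 0)) {
  st <- system_state(matrix(5, 1, 3), 0L, "cation_1",
                     matrix(integer(0), 0, 2), L = 10)
  st$velocities <- matrix(v, 1, 3)
  st
}

test_that("free particle advances v*dt per NVE step", {
  st <- free_particle()
  st1 <- nve_step(st, ff_params(coulomb_method = "none"), dt = 0.005)
  expect_equal(st1$positions[1, 1] - st$positions[1, 1], 0.005,
               tolerance = 1e-12)
})

test_that("harmonic dimer conserves energy and follows the oscillator", {
  # soft spring so omega*dt is small: omega = sqrt(2k/mu), mu = 1/2
  k <- 10; l0 <- 2; A <- 0.05; dt <- 0.001
  ff <- ff_params(k_spring = k, l0 = l0, coulomb_method = "none")
  pos <- matrix(c(10 - (l0 + A) / 2, 10, 10,
                  10 + (l0 + A) / 2, 10, 10), 2, 3, byrow = TRUE)
  st <- system_state(pos, c(0L, 0L), rep("gel_segment", 2),
                     matrix(c(1L, 2L), 1), L = 20)
  e_of <- function(s) {
    r <- sqrt(sum((s$positions[2, ] - s$positions[1, ])^2))
    bond_energy(r, ff) + 0.5 * sum(s$velocities^2)
  }
  e0 <- e_of(st)
  omega <- sqrt(2 * k / 0.5)
  nst <- 10000
  res <- gelion:::cpp_run_md(st$positions, st$velocities, c(0, 0),
                             st$bonds, st$L, gelion:::.ff_list(ff),
                             dt, nst, "none", 1, 0.5, 0, 0L, 0L, 0.5)
  st$positions <- res$positions; st$velocities <- res$velocities
  expect_lt(abs(e_of(st) - e0) / e0, 1e-5)
  # closed-form oracle: r(t) = l0 + A cos(omega t)
  r_t <- sqrt(sum((st$positions[2, ] - st$positions[1, ])^2))
  expect_equal(r_t, l0 + A * cos(omega * nst * dt), tolerance = 1e-3)
})

test_that("NVE is time-reversible to 1e-10 sigma", {
  set.seed(3)
  g <- as.matrix(expand.grid(c(2, 4.5, 7), c(2, 4.5, 7), c(2, 6)))
  pos <- (g + matrix(runif(nrow(g) * 3, -0.2, 0.2), nrow(g), 3))[1:10, ]
  st <- system_state(pos, rep(0L, 10), rep("cation_1", 10),
                     matrix(integer(0), 0, 2), L = 10)
  st$velocities <- matrix(rnorm(30), 10, 3)
  ff <- ff_params(coulomb_method = "none")
  fwd <- st
  for (i in 1:50) fwd <- nve_step(fwd, ff, 0.005)
  fwd$velocities <- -fwd$velocities
  back <- fwd
  for (i in 1:50) back <- nve_step(back, ff, 0.005)
  expect_lt(max(abs(min_image(back$positions - st$positions, 10))), 1e-10)
})

test_that("NVE drift < 1e-3 over 1e4 steps on a 100-particle WCA fluid", {
  set.seed(5)
  L <- 6
  # overlap-free start on a jittered lattice
  g <- as.matrix(expand.grid(seq(0.6, 5.4, length.out = 5),
                             seq(0.6, 5.4, length.out = 5),
                             seq(0.6, 5.4, length.out = 4)))
  pos <- g + matrix(runif(300, -0.05, 0.05), 100, 3)
  st <- system_state(pos, rep(0L, 100), rep("cation_1", 100),
                     matrix(integer(0), 0, 2), L = L)
  ff <- ff_params(coulomb_method = "none")
  # thermalize with Langevin, then measure NVE drift
  res <- gelion:::cpp_run_md(st$positions, mb_velocities(100, 1),
                             rep(0, 100), st$bonds, L,
                             gelion:::.ff_list(ff), 0.005, 1000,
                             "langevin", 1, 1, 42L, 0L, 0L, 0.5)
  res2 <- gelion:::cpp_run_md(res$positions, res$velocities, rep(0, 100),
                              st$bonds, L, gelion:::.ff_list(ff), 0.005,
                              10000, "none", 1, 1, 0L, 0L, 100L, 0.5)
  e <- res2$thermo[, "E_total"]
  expect_lt(max(abs(e - e[1])) / abs(e[1]), 1e-3)
})

test_that("instability guard triggers on huge velocities", {
  st <- free_particle(v = c(500, 0, 0))
  expect_error(nve_step(st, ff_params(coulomb_method = "none"), 0.005),
               "instability")
})

test_that("Nose-Hoover relaxes a hot dilute gas to kT = 1.00 +/- 0.02", {
  set.seed(6)
  n <- 1000; L <- 100
  pos <- matrix(runif(3 * n, 0, L), n, 3)
  st <- system_state(pos, rep(0L, n), rep("cation_1", n),
                     matrix(integer(0), 0, 2), L = L)
  v <- mb_velocities(n, 2)   # start at kT' = 2
  ff <- ff_params(coulomb_method = "none")
  res <- gelion:::cpp_run_md(pos, v, rep(0, n),
                             matrix(integer(0), 0, 2), L,
                             gelion:::.ff_list(ff), 0.005, 20000,
                             "nose_hoover", 1, 0.5, 0L, 0L, 20L, 0.5)
  th <- res$thermo
  after <- th[th[, "step"] * 0.005 > 50, "T"]   # time-average after 50 tau
  expect_equal(mean(after), 1.00, tolerance = 0.02)
})

test_that("Langevin steady state is Maxwell-Boltzmann (KS test)", {
  set.seed(7)
  L <- 8
  g <- as.matrix(expand.grid(seq(0.8, 7.2, length.out = 5),
                             seq(0.8, 7.2, length.out = 5),
                             seq(0.8, 7.2, length.out = 5)))
  n <- nrow(g)
  ff <- ff_params(coulomb_method = "none")
  res <- gelion:::cpp_run_md(g, mb_velocities(n, 1), rep(0, n),
                             matrix(integer(0), 0, 2), L,
                             gelion:::.ff_list(ff), 0.005, 5000,
                             "langevin", 1, 1, 9L, 0L, 0L, 0.5)
  p <- stats::ks.test(as.numeric(res$velocities), "pnorm", 0, 1)$p.value
  expect_gt(p, 0.01)
})

test_that("thermostat rejects degenerate input", {
  st <- free_particle()
  expect_error(thermostat_step(st), ">= 2 particles")
  st2 <- tiny_system()
  pp <- protocol_params()
  pp$kT <- 0
  expect_error(thermostat_step(st2, ff_params(coulomb_method = "none"), pp),
               "kT")
  expect_error(protocol_params(kT = 0))
})

test_that("run_protocol: empty production, determinism, bond lengths", {
  st <- build_gel(gel_spec(Nb = 1, f = 4, M = 5), L = 30)
  st$charge <- rep(0L, nrow(st$positions))  # neutral-gel-only system
  ff <- ff_params(coulomb_method = "none")
  p0 <- protocol_params(t_equil = 1, t_prod = 0, thermostat = "langevin",
                        seed = 2)
  tr0 <- run_protocol(st, ff, p0)
  expect_equal(n_frames(tr0), 0)
  expect_s3_class(tr0$state, "system_state")

  pp <- protocol_params(t_equil = 5, t_prod = 25, sample_every = 1,
                        thermostat = "langevin", seed = 2)
  tr1 <- run_protocol(st, ff, pp)
  tr2 <- run_protocol(st, ff, pp)
  expect_identical(tr1$frames, tr2$frames)   # bit-identical given seed

  # stiff springs: mean bond length ~ l0 within 2 %
  lens <- unlist(lapply(tr1$frames, function(fr) {
    d <- fr[st$bonds[, 1], ] - fr[st$bonds[, 2], ]
    sqrt(rowSums(min_image(d, st$L)^2))
  }))
  expect_lt(abs(mean(lens) - 0.99) / 0.99, 0.02)
})

test_that("mean temperature within 2 % of target over production (NH)", {
  # deterministic thermostat regulates kinetic energy directly, so the
  # kinetic temperature is unbiased even with stiff bonds at dt = 0.005
  st <- build_gel(gel_spec(Nb = 1, f = 4, M = 10), L = 30)
  st$charge <- rep(0L, nrow(st$positions))
  ff <- ff_params(coulomb_method = "none")
  pp <- protocol_params(t_equil = 10, t_prod = 50, sample_every = 10,
                        thermostat = "nose_hoover", seed = 4,
                        log_every = 0.25)
  tr <- run_protocol(st, ff, pp)
  th <- tr$thermo
  Tprod <- th[th[, "step"] > 10 / 0.005, "T"]
  expect_lt(abs(mean(Tprod) - 1), 0.02)
})

test_that("COM momentum is conserved by NVE/Nose-Hoover", {
  st <- tiny_system(c_mono = 20, L = 20)
  ff <- ff_params(lB = 2.1, coulomb_method = "dsf", r_cut_real = 5)
  set.seed(10)
  v <- mb_velocities(nrow(st$positions), 1)
  res <- gelion:::cpp_run_md(st$positions, v, as.numeric(st$charge),
                             st$bonds, st$L, gelion:::.ff_list(ff),
                             0.005, 500, "nose_hoover", 1, 0.5, 0L,
                             0L, 0L, 0.5)
  expect_lt(max(abs(colSums(res$velocities))), 1e-8)
})
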