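test_that("head-on equal-mass hard spheres exchange velocities exactly", {
  res <- run_core(pos = rbind(c(50, 50, 50), c(60, 50, 50)),
                  vel = rbind(c(1, 0, 0), c(-1, 0, 0)),
                  mass = c(1, 1), sigma = 2, wellr = 0, eps = 0)
  expect_equal(res$events$kind, "core")
  expect_equal(res$events$t, 4)  # (10 - 2) / 2
  expect_equal(res$vel[1, ], c(-1, 0, 0))
  expect_equal(res$vel[2, ], c(1, 0, 0))
})

test_that("square-well capture adds the well depth to the kinetic energy", {
  eps <- 0.7
  res <- run_core(pos = rbind(c(40, 50, 50), c(60, 50, 50)),
                  vel = rbind(c(0.5, 0, 0), c(-0.5, 0, 0)),
                  mass = c(2, 2), sigma = 2, wellr = 5, eps = eps,
                  t_end = 16)
  # capture at separation 5: t = (20 - 5) / 1; the core collision at the
  # post-capture closing speed falls after t_end
  expect_equal(res$events$kind[1], "capture")
  expect_equal(res$events$t[1], 15, tolerance = 1e-9)
  ke0 <- 0.5 * 2 * 0.5^2 * 2
  ke_after <- sum(0.5 * 2 * res$vel^2)
  expect_equal(ke_after, ke0 + eps, tolerance = 1e-9)
  # total energy (kinetic + well potential) is conserved
  expect_equal(ke_after + res$potential[length(res$potential)], ke0,
               tolerance = 1e-9)
})

test_that("event sequences of a 4-bead system match a brute-force oracle", {
  # three free beads plus one bead bonded to the first: cores, captures,
  # escapes, bounces and bond reflections all occur
  pos <- rbind(c(50, 50, 50), c(52, 50, 50), c(62, 50.5, 50), c(50, 58, 50.2))
  vel <- rbind(c(0.05, 0.02, 0), c(-0.6, 0, 0.01),
               c(-0.45, -0.02, 0), c(0.01, -0.35, -0.01))
  mass <- c(1.5, 1, 2, 1.2)
  sigma <- 2; wellr <- 4.5; eps <- 0.8
  bonds <- cbind(0, 1, 1.8, 2.2)
  t_end <- 30
  res <- run_core(pos, vel, mass, sigma, wellr, eps, bonds = bonds,
                  t_end = t_end, chain = c(0L, 0L, 1L, 2L))

  oracle <- dmd_brute_oracle(pos, vel, mass, sigma, wellr, eps,
                             bonds = bonds, t_end = t_end)

  expect_gte(nrow(res$events), 8)  # a non-trivial event sequence
  expect_equal(nrow(res$events), nrow(oracle))
  expect_equal(res$events$kind, oracle$kind)
  expect_equal(res$events$t, oracle$t, tolerance = 1e-6)
  expect_equal(pmin(res$events$a, res$events$b), pmin(oracle$i, oracle$j))
  expect_equal(pmax(res$events$a, res$events$b), pmax(oracle$i, oracle$j))
})

test_that("48-chain build matches the full-scale study geometry", {
  sys <- build_cg_system("GNYTMFI", 48, 200, 310, seed = 77)
  expect_equal(length(unique(sys$beads$chain)), 48)
  expect_equal(nrow(sys$beads), 48 * 7 * 4)
  # no inter-chain hard-core overlap (minimum image)
  xyz <- as.matrix(sys$beads[, c("x", "y", "z")])
  maxdiam <- max(sys$tables$sigma)
  ch <- sys$beads$chain
  d2 <- crossbeta:::.pd2(xyz, xyz, 200)
  same <- outer(ch, ch, "==")
  expect_gt(min(d2[!same]), maxdiam^2 * 0.999)
})

test_that("system build is reproducible and momentum-free", {
  a <- build_cg_system("GDIKIVV", 3, 60, 303, seed = 5)
  b <- build_cg_system("GDIKIVV", 3, 60, 303, seed = 5)
  expect_identical(a$beads, b$beads)
  ptot <- colSums(a$beads$mass * cbind(a$beads$vx, a$beads$vy, a$beads$vz))
  expect_lt(max(abs(ptot)), 1e-9)
  one <- build_cg_system("GDIKIVV", 1, 60, 303, seed = 6)
  p1 <- colSums(one$beads$mass * cbind(one$beads$vx, one$beads$vy, one$beads$vz))
  expect_lt(max(abs(p1)), 1e-9)
})

test_that("placement failure in a too-small box is reported", {
  expect_error(build_cg_system("GNYTMFI", 30, 26, 310, seed = 1,
                               max_tries = 30),
               "larger box")
})

test_that("concentration follows n / (N_A V)", {
  expect_equal(concentration(48, 200), 9.9632, tolerance = 1e-4)
  expect_equal(concentration(96, 200), 2 * concentration(48, 200))
  expect_equal(concentration(48, 400), concentration(48, 200) / 8)
})

test_that("kinetic temperature estimates behave like velocity variance", {
  set.seed(31)
  n <- 10000
  mass <- rep(c(15, 50, 100), length.out = n)
  kB <- 0.0019872041
  vel <- matrix(rnorm(3 * n), ncol = 3) * sqrt(kB * 310 / mass)
  fake <- list(beads = tibble::tibble(mass = mass, vx = vel[, 1],
                                      vy = vel[, 2], vz = vel[, 3]))
  expect_lt(abs(measure_temperature(fake) - 310) / 310, 0.03)
  zero <- list(beads = tibble::tibble(mass = mass[1:10], vx = 0, vy = 0, vz = 0))
  expect_equal(measure_temperature(zero), 0)
  twice <- fake
  twice$beads[, c("vx", "vy", "vz")] <- twice$beads[, c("vx", "vy", "vz")] * 2
  expect_equal(measure_temperature(twice), 4 * measure_temperature(fake),
               tolerance = 1e-12)
})

test_that("energy is conserved with the thermostat off", {
  sys <- build_cg_system("GAIDWVK", 4, 42, 303, seed = 41)
  tr <- run_dmd(sys, t_end = 400, thermostat_rate = 0, frame_interval = 40,
                seed = 42)
  expect_gt(tr$n_events, 1e5)
  e0 <- tr$energy$kinetic[1] + tr$energy$potential[1]
  expect_lt(tr$energy_drift / abs(e0), 1e-6)
  # hard constraints hold in every stored frame: bonds inside windows,
  # no core overlap
  f <- tr$frames[[length(tr$frames)]]
  xyz <- as.matrix(f[, c("x", "y", "z")])
  bl <- sys$bonds
  for (k in seq_len(nrow(bl))) {
    dr <- xyz[bl[k, 1], ] - xyz[bl[k, 2], ]
    dr <- dr - 42 * round(dr / 42)
    d <- sqrt(sum(dr^2))
    expect_gte(d, bl[k, 3] - 1e-9)
    expect_lte(d, bl[k, 4] + 1e-9)
  }
})

test_that("the Andersen thermostat holds the set temperature within 3%", {
  sys <- build_cg_system("GAIDWVK", 6, 48, 310, seed = 51)
  tr <- run_dmd(sys, t_end = 600, thermostat_rate = 0.1,
                frame_interval = 15, seed = 52)
  kB <- 0.0019872041
  Tk <- tr$energy$kinetic / (1.5 * nrow(sys$beads) * kB)
  Tbar <- mean(Tk[-(1:5)])
  expect_lt(abs(Tbar - 310) / 310, 0.03)
})

test_that("ghost-collision velocity draws are Maxwell-Boltzmann", {
  sys <- build_cg_system("GAIDWVK", 2, 45, 303, seed = 61)
  tr <- run_dmd(sys, t_end = 300, thermostat_rate = 0.2,
                frame_interval = 300, seed = 62, ghost_log = 30000)
  draws <- tr$ghost_draws
  expect_gt(length(draws), 1000)
  ks <- suppressWarnings(stats::ks.test(draws, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("attractive wells aggregate chains; repulsive cores do not", {
  att <- build_cg_system("GAIDWVK", 3, 30, 303, seed = 71)
  tra <- run_dmd(att, t_end = 2500, thermostat_rate = 0.02,
                 frame_interval = 2500, seed = 72)
  fa <- tra$frames[[length(tra$frames)]]
  expect_equal(largest_aggregate(fa), 3L)
  expect_lt(tra$energy$potential[length(tra$energy$potential)], -5)

  rep_sys <- build_cg_system("GAIDWVK", 3, 30, 303,
                             params = repulsive_params(), seed = 71)
  trr <- run_dmd(rep_sys, t_end = 2500, thermostat_rate = 0.02,
                 frame_interval = 2500, seed = 72)
  expect_true(all(trr$energy$potential == 0))
  expect_equal(beta_content(trr$frames[[1]]), 0)
})

test_that("trajectories are reproducible under a fixed seed", {
  sys <- build_cg_system("GDIKIVV", 2, 45, 303, seed = 81)
  a <- run_dmd(sys, t_end = 150, thermostat_rate = 0.1, frame_interval = 50,
               seed = 82)
  b <- run_dmd(sys, t_end = 150, thermostat_rate = 0.1, frame_interval = 50,
               seed = 82)
  expect_equal(a$frames, b$frames)
  expect_equal(a$n_events, b$n_events)
  expect_equal(a$energy, b$energy)
})
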