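test_that("landscape force recovers the gradient of a quadratic energy", {
  k <- 2.5e-12                      # J / um^2
  energy_fn <- function(p) k * rowSums(p^2)
  for (pos in list(c(1, 2), c(-3, 0.5), c(0.2, -0.7))) {
    f <- magnetic_force(energy_fn, pos, h = 1e-3)
    expected <- -2 * k * pos / 1e-6      # N
    expect_equal(f, expected, tolerance = 1e-6)
  }
  expect_equal(magnetic_force(function(p) rep(1e-20, nrow(p)), c(0, 0)),
               c(0, 0))
})

test_that("dipole pair force matches closed forms for canonical poses", {
  # vertical moments, in-plane separation: pure repulsion 3 mu0 m^2/(4 pi d^4)
  p1 <- magnetic_particle(1.4, 0.14)
  p2 <- magnetic_particle(1.4, 0.14)
  hz <- c(0, 0, 5000)
  d <- 6
  f <- dipole_pair_force(p1, p2, hz, c(d, 0))
  m <- 4 * pi * (1.4e-6)^3 * 0.14 * 5000 / 3
  expect_equal(f, c(3 * (4 * pi * 1e-7) * m^2 / (4 * pi * (d * 1e-6)^4),
                    0, 0), tolerance = 1e-9)

  # moments along the separation axis: attraction, twice the magnitude
  hx <- c(5000, 0, 0)
  fx <- dipole_pair_force(p1, p2, hx, c(d, 0))
  expect_equal(fx[1], -2 * f[1], tolerance = 1e-9)

  # moment 1e-13 A m^2 at 6 um: |F| = 3e-7 m^2/d^4 ~ 2.3 pN
  h_for_m <- 1e-13 * 3 / (4 * pi * (1.4e-6)^3 * 0.14)
  fm <- dipole_pair_force(p1, p2, c(0, 0, h_for_m), c(6, 0))
  expect_equal(sqrt(sum(fm^2)), 3e-7 * (1e-13)^2 / (6e-6)^4,
               tolerance = 1e-6)
  expect_equal(sqrt(sum(fm^2)) * 1e12, 2.3, tolerance = 0.01)

  expect_error(dipole_pair_force(p1, p2, hz, c(0, 0, 0)),
               "singular-separation")
})

test_that("pair force is the negative gradient of the dipole energy", {
  # oracle: numerical gradient of U = -mu0/(4 pi r^3) [3 (m1.rh)(m2.rh) - m1.m2]
  mu0 <- 4 * pi * 1e-7
  pair_energy <- function(m1, m2, r) {
    rm <- sqrt(sum(r^2)); rh <- r / rm
    -mu0 / (4 * pi * rm^3) * (3 * sum(m1 * rh) * sum(m2 * rh) -
                                sum(m1 * m2))
  }
  set.seed(42)
  p1 <- magnetic_particle(1.5, 0.2)
  p2 <- magnetic_particle(2.0, 0.1)
  c1 <- 4 * pi * (1.5e-6)^3 * 0.2 / 3
  c2 <- 4 * pi * (2.0e-6)^3 * 0.1 / 3
  worst <- 0
  for (i in 1:100) {
    h <- rnorm(3) * 5000
    r_um <- rnorm(3) * 5
    while (sqrt(sum(r_um^2)) < 1) r_um <- rnorm(3) * 5
    f <- dipole_pair_force(p1, p2, h, r_um)
    m1 <- c1 * h; m2 <- c2 * h
    g <- numeric(3)
    eps <- 1e-10
    r <- r_um * 1e-6
    for (k in 1:3) {
      dp <- r; dp[k] <- dp[k] + eps
      dm <- r; dm[k] <- dm[k] - eps
      g[k] <- -(pair_energy(m1, m2, dp) - pair_energy(m1, m2, dm)) /
        (2 * eps)
    }
    worst <- max(worst, sqrt(sum((f - g)^2)) / sqrt(sum(g^2)))
  }
  expect_lt(worst, 1e-4)
})

test_that("pair force obeys Newton's third law exactly", {
  p1 <- magnetic_particle(1.5, 0.2)
  p2 <- magnetic_particle(2.5, 0.1)
  h <- c(3000, -2000, 4000)
  r <- c(4, -2, 0)
  f12 <- dipole_pair_force(p1, p2, h, r)
  f21 <- dipole_pair_force(p2, p1, h, -r)
  expect_equal(f12, -f21, tolerance = 1e-15)
})

test_that("time-averaged pair force changes sign at the magic angle", {
  # two coplanar beads, moments following the rotating conical drive with
  # the pair axis fixed: attractive below arctan(1/sqrt(2)) = 35.26 deg
  # elevation, repulsive at 45 deg (equal components)
  p <- magnetic_particle(1.4, 0.14)
  avg_radial <- function(h_vert_oe) {
    f <- external_field(70, h_vert_oe, 0.2)
    ts <- seq(0, 5, length.out = 721)[-721]
    mean(vapply(ts, function(t)
      dipole_pair_force(p, p, external_field_at(f, t), c(4, 0))[1],
      numeric(1)))
  }
  expect_lt(avg_radial(70 * tan(30 * pi / 180)), 0)   # 30 deg: attract
  expect_gt(avg_radial(70), 0)                        # 45 deg: repel
  # threshold bracketing around 35.26 deg
  expect_lt(avg_radial(70 * tan(34 * pi / 180)), 0)
  expect_gt(avg_radial(70 * tan(37 * pi / 180)), 0)
})

test_that("Stokes drag velocity has the right magnitude and scaling", {
  v <- drag_velocity(c(1e-12, 0, 0), 2.5, 1e-3)
  expect_equal(v[1], 1e-12 / (6 * pi * 1e-3 * 2.5e-6) * 1e6,
               tolerance = 1e-12)
  expect_equal(v[1], 21.22, tolerance = 1e-3)
  expect_equal(drag_velocity(c(0, 0, 0), 2.5, 1e-3), c(0, 0, 0))
  expect_equal(drag_velocity(c(1e-12, 0, 0), 5, 1e-3)[1], v[1] / 2)
  expect_error(drag_velocity(c(1, 0, 0), 0, 1e-3), "invalid-argument")
})

test_that("phase-locked bead advances one period per field cycle", {
  tr <- run_canonical(5.5, 0.2, n_periods = 5)
  v <- mean_speed(tr, c(1, 0))
  expect_equal(v, 45 * 0.2, tolerance = 0.02)
})

test_that("bead on a disk orbits without net track progress", {
  disk <- disk_pattern(10)
  bead <- magnetic_particle(2.75, pos = c(13, 0))
  tr <- simulate_transport(bead, disk, sensing_field(),
                           sim_config(duration = 25))[[1]]
  net <- abs(tr$xy[nrow(tr$xy), 1] - tr$xy[1, 1])
  expect_lt(net, 5)
  # but it does move around the disk
  expect_gt(max(abs(tr$xy[, 2])), 5)
})

test_that("zero-amplitude drive leaves the bead stationary", {
  ct <- canonical_track(10)
  bead <- magnetic_particle(2.75, pos = c(105, 0))
  tr <- simulate_transport(bead, ct$pattern, external_field(0, 0, 0.2),
                           sim_config(duration = 5),
                           sources = ct$sources)[[1]]
  expect_equal(tr$xy[nrow(tr$xy), ], tr$xy[1, ], tolerance = 1e-9)
})

test_that("forward-difference integration is dt-convergent", {
  ct <- canonical_track(10)
  run_dt <- function(dt) {
    bead <- magnetic_particle(2.75, pos = c(105, 0))
    tr <- simulate_transport(bead, ct$pattern, sensing_field(),
                             sim_config(dt = dt, duration = 5),
                             sources = ct$sources)[[1]]
    tr$xy[nrow(tr$xy), ]
  }
  e1 <- run_dt(1 / 0.2 / 250)
  e2 <- run_dt(1 / 0.2 / 500)
  expect_lt(sqrt(sum((e1 - e2)^2)) / 45, 0.01)
})

test_that("R-level stepper agrees with the compiled integrator", {
  ct <- canonical_track(10)
  bead <- magnetic_particle(2.75, pos = c(105, 0))
  f <- sensing_field()
  cfg <- sim_config(dt = 0.02, duration = 0.2)
  cpp <- simulate_transport(bead, ct$pattern, f, cfg,
                            sources = ct$sources)[[1]]
  st <- magcircuit:::make_state(list(bead), f, ct$pattern, fluid_env(),
                                film_response(), cfg, ct$sources)
  st$dt <- 0.02
  for (k in 1:10) st <- magcircuit:::step_state(st)
  expect_equal(as.numeric(st$pos),
               cpp$xy[11, ], tolerance = 1e-3)
})

test_that("beads repel and separate when the vertical bias dominates", {
  # strong vertical bias: even a co-rotating doublet is net repulsive
  b1 <- magnetic_particle(1.4, pos = c(50, 50))
  b2 <- magnetic_particle(1.4, pos = c(53.3, 50))
  f <- external_field(20, 70, 0.2)
  trs <- simulate_transport(list(b1, b2), NULL, f,
                            sim_config(duration = 10),
                            bounds = c(0, 0, 100, 100))
  gap <- sqrt(rowSums((trs[[1]]$xy - trs[[2]]$xy)^2)) - 2.8
  expect_gt(gap[length(gap)], gap[1])
})

test_that("speed measurement validates its inputs", {
  tr <- run_canonical(5.5, 0.2, n_periods = 5)
  short <- tr
  keep <- short$times < 2      # less than one period
  short$times <- short$times[keep]
  short$xy <- short$xy[keep, ]
  expect_error(mean_speed(short), "insufficient-data")
  expect_error(critical_frequency(magnetic_particle(2.75),
                                  canonical_track(10)$pattern,
                                  sensing_field(), c(0.2, 0.1)),
               "invalid-argument")
})
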