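test_that("external drive field evaluates and converts units correctly", {
  f <- external_field(70, 70, 0.5, phase0 = 0)
  h0 <- external_field_at(f, 0)
  # 70 Oe = 70 * 1e3/(4 pi) A/m = 5570.4 A/m
  expect_equal(h0, c(70, 0, 70) * 1e3 / (4 * pi), tolerance = 1e-12)
  expect_equal(h0[1], 5570.4, tolerance = 1e-4)

  # periodicity
  expect_equal(external_field_at(f, 1 / 0.5), h0, tolerance = 1e-9)

  # vertical-only drive is constant
  fv <- external_field(0, 70, 1)
  for (t in c(0, 0.3, 0.71))
    expect_equal(external_field_at(fv, t), c(0, 0, 70 * 1e3 / (4 * pi)))

  # rotation sense flips the y component
  fc <- external_field(70, 70, 0.5, sense = "cw")
  expect_equal(external_field_at(fc, 0.3)[2],
               -external_field_at(f, 0.3)[2])
  expect_error(external_field(-1, 70), "invalid-spec")
})

test_that("film magnetization follows the in-plane drive and saturates", {
  film <- film_response()
  expect_equal(film_magnetization(film, c(0, 0, 0)), c(0, 0, 0))

  m <- film_magnetization(film, c(5570, 0, 0))
  expect_gt(m[1], 0)
  expect_equal(m[2], 0)
  # soft film saturates in the 70 Oe drive
  expect_equal(m[1], film$ms)

  # demag-suppressed vertical response: chi/(1+chi) ~ 1
  mz <- film_magnetization(film, c(0, 0, 5570))[3]
  expect_equal(mz, 5570 * 1000 / 1001, tolerance = 1e-9)
})

test_that("stray field matches a brute-force surface-charge oracle", {
  # small square magnet, uniform in-plane magnetization
  sq <- magnet_pattern(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))),
                       thickness = 0.1)
  m <- c(8.6e5, 0, 0)
  pts <- rbind(c(6, 2, 2), c(2, 2, 3), c(-3, 5, 2.5), c(2, -4, 4))
  got <- stray_field(sq, m, pts)

  # oracle: direct fine quadrature of the magnetostatic Coulomb integral
  # over the edge surfaces (charge density M . n on the side faces)
  oracle_field <- function(p) {
    h <- c(0, 0, 0)
    edges <- list(list(a = c(0, 0), b = c(4, 0), n = c(0, -1)),
                  list(a = c(4, 0), b = c(4, 4), n = c(1, 0)),
                  list(a = c(4, 4), b = c(0, 4), n = c(0, 1)),
                  list(a = c(0, 4), b = c(0, 0), n = c(-1, 0)))
    nl <- 400; nz <- 12
    for (e in edges) {
      sigma <- sum(m[1:2] * e$n)          # A/m
      if (sigma == 0) next
      tt <- (seq_len(nl) - 0.5) / nl
      zz <- (seq_len(nz) - 0.5) / nz * 0.1
      len <- sqrt(sum((e$b - e$a)^2))
      dA <- (len * 1e-6 / nl) * (0.1e-6 / nz)
      for (z in zz) {
        ex <- e$a[1] + tt * (e$b[1] - e$a[1])
        ey <- e$a[2] + tt * (e$b[2] - e$a[2])
        dx <- (p[1] - ex) * 1e-6
        dy <- (p[2] - ey) * 1e-6
        dz <- (p[3] - z) * 1e-6
        r3 <- (dx^2 + dy^2 + dz^2)^(3 / 2)
        h <- h + sigma * dA / (4 * pi) *
          c(sum(dx / r3), sum(dy / r3), sum(dz / r3))
      }
    }
    h
  }
  for (i in seq_len(nrow(pts))) {
    ref <- oracle_field(pts[i, ])
    expect_lt(sqrt(sum((got[i, ] - ref)^2)) / sqrt(sum(ref^2)), 0.01,
              label = sprintf("stray field at point %d", i))
  }
})

test_that("stray field is linear in M and superposes over polygons", {
  sq1 <- magnet_pattern(list(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4))))
  sq2 <- magnet_pattern(list(cbind(c(10, 14, 14, 10), c(0, 0, 4, 4))))
  both <- magnet_pattern(c(sq1$polygons, sq2$polygons))
  m <- c(3e5, 2e5, 1e4)
  p <- matrix(c(5, 1, 3), 1)
  expect_equal(stray_field(both, m, p),
               stray_field(sq1, m, p) + stray_field(sq2, m, p),
               tolerance = 1e-9)
  expect_equal(stray_field(sq1, 2 * m, p), 2 * stray_field(sq1, m, p),
               tolerance = 1e-12)
  expect_equal(stray_field(sq1, c(0, 0, 0), p), matrix(0, 1, 3))
  expect_error(stray_field(sq1, m, c(2, 2, 0.05)), "domain")
})

test_that("far field of a magnetized disk decays as 1/r^3", {
  disk <- disk_pattern(2)
  m <- c(8.6e5, 0, 0)
  r1 <- 40; r2 <- 80    # beyond 10 diameters
  h1 <- sqrt(sum(stray_field(disk, m, c(r1, 0, 2))^2))
  h2 <- sqrt(sum(stray_field(disk, m, c(r2, 0, 2))^2))
  expect_lt(abs(h1 / h2 - 8) / 8, 0.05)
})

test_that("vertical bias converts the two-well disk landscape to one well", {
  disk <- disk_pattern(10)
  bead <- magnetic_particle(2.75, 1.0)
  fl <- fluid_env(); fm <- film_response()
  in_plane <- energy_landscape(disk, external_field(70, 0, 0.2), fm, fl,
                               bead, resolution = 0.4)
  conical <- energy_landscape(disk, external_field(70, 70, 0.2), fm, fl,
                              bead, resolution = 0.4)
  expect_equal(count_energy_wells(normalize_minmax(in_plane)), 2)
  expect_equal(count_energy_wells(normalize_minmax(conical)), 1)
})

test_that("landscape is mirror symmetric and scales with bead volume", {
  disk <- disk_pattern(10)
  fl <- fluid_env(); fm <- film_response()
  f <- external_field(70, 70, 0.2)
  b1 <- magnetic_particle(2.75, 1.0)
  L <- energy_landscape(disk, f, fm, fl, b1, resolution = 0.5)
  # mirror about the x axis (field along +x at t = 0)
  ny <- length(L$y)
  expect_equal(L$grid, L$grid[ny:1, ], tolerance = 1e-4)

  # energy scales linearly with chi_p - chi_f at fixed volume
  b2 <- magnetic_particle(2.75, 0.5)
  L2 <- energy_landscape(disk, f, fm, fl, b2, resolution = 0.5)
  expect_equal(L2$grid, L$grid * 0.5, tolerance = 1e-8)
})

test_that("min-max normalization maps to [0,1] and is affine invariant", {
  g <- list(grid = matrix(rnorm(100), 10), x = 1:10, y = 1:10)
  class(g) <- "energy_landscape"
  n1 <- normalize_minmax(g)
  expect_equal(range(n1$grid), c(0, 1))
  g2 <- g; g2$grid <- 3 * g$grid - 7
  expect_equal(normalize_minmax(g2)$grid, n1$grid, tolerance = 1e-12)
  gc <- g; gc$grid <- matrix(1, 10, 10)
  expect_error(normalize_minmax(gc), "degenerate-normalization")
})

test_that("energy profiles sample densely along increasing arclength", {
  ct <- canonical_track(2)
  bead <- magnetic_particle(2.75)
  prof <- energy_profile(ct$pattern, sensing_field(), film_response(),
                         fluid_env(), bead, rbind(c(0, 8), c(45, 8)),
                         sources = ct$sources)
  expect_gte(length(prof$s), 100)
  expect_true(all(diff(prof$s) > 0))
  expect_true(all(is.finite(prof$energy)))
  expect_error(energy_profile(ct$pattern, sensing_field(),
                              film_response(), fluid_env(), bead,
                              matrix(c(0, 0), 1)), "invalid-argument")
})
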