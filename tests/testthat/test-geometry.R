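test_that("drop track has the right period, gaps and polygon count", {
  pat <- make_drop_track(track_spec(drop_length = 30, drop_width = 20,
                                    neck = 15, gap = 15, n_units = 5))
  expect_length(pat$polygons, 5)
  expect_equal(pat$meta$period, 45)
  expect_equal(path_gaps(pat), rep(15, 4), tolerance = 1e-6)

  two <- make_drop_track(track_spec(n_units = 2))
  expect_equal(path_gaps(two), 15, tolerance = 1e-6)
})

test_that("track construction rejects degenerate specifications", {
  expect_error(track_spec(gap = 0), "invalid-spec")
  expect_error(track_spec(neck = 25, drop_width = 20), "invalid-spec")
  expect_error(track_spec(drop_length = -5), "invalid-spec")
  expect_error(track_spec(n_units = 1), "invalid-spec")
})

test_that("track is periodic: unit k+1 is unit k translated by the period", {
  pat <- make_drop_track(track_spec(n_units = 4))
  lambda <- pat$meta$period
  for (k in 1:3) {
    shifted <- pat$polygons[[k]]
    shifted[, 1] <- shifted[, 1] + lambda
    expect_equal(shifted, pat$polygons[[k + 1]], tolerance = 1e-9)
  }
})

test_that("design ratios reproduce the worked bead/gap combinations", {
  r6 <- design_ratios(6, 15, 15)
  expect_equal(r6$beta, 0.4)
  expect_equal(r6$gamma, 0.4)
  r8 <- design_ratios(8, 15, 15)
  expect_equal(r8$beta, 8 / 15)   # ~0.533
  expect_equal(r8$gamma, 8 / 15)
  r1 <- design_ratios(5, 5, 5)
  expect_equal(r1$beta, 1)
  expect_equal(r1$gamma, 1)
})

test_that("design ratios are scale invariant and validate inputs", {
  for (s in c(0.5, 2, 7.3)) {
    a <- design_ratios(6, 15, 12)
    b <- design_ratios(6 * s, 15 * s, 12 * s)
    expect_equal(a$beta, b$beta)
    expect_equal(a$gamma, b$gamma)
  }
  expect_error(design_ratios(0, 15, 15), "invalid-argument")
  expect_error(design_ratios(6, -1, 15), "invalid-argument")
})

test_that("rasterization covers the analytic disk area and superposes", {
  disk <- disk_pattern(5)
  ras <- rasterize_pattern(disk, resolution = 0.2)
  area <- sum(ras$mask) * 0.2^2
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.02)

  expect_error(rasterize_pattern(disk, resolution = 0), "invalid-argument")

  # disjoint polygons rasterize to the union of the separate masks
  two <- magnet_pattern(list(
    cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)),
    cbind(c(20, 24, 24, 20), c(0, 0, 4, 4))))
  ras2 <- rasterize_pattern(two, resolution = 0.5)
  one_a <- rasterize_pattern(magnet_pattern(two$polygons[1]), 0.5)
  expect_equal(sum(ras2$mask), sum(one_a$mask) * 2)
})

test_that("bend styles preserve or enlarge the path gap as designed", {
  arm <- track_spec(n_units = 3)
  for (style in c("multi_drop_corner", "corner_magnet_A",
                  "corner_magnet_B", "inside_corner")) {
    b <- make_bend(bend_spec(style, 90, arm))
    expect_lte(b$meta$path_gap_max, 15 + 1e-6,
               label = paste(style, "max path gap"))
  }
  naive <- make_bend(bend_spec("naive_obtuse", 135, arm))
  expect_gt(naive$meta$corner_gap, 15)

  multi <- make_bend(bend_spec("multi_drop_corner", 90, arm))
  expect_gte(length(multi$meta$corner_index), 3)
})

test_that("bend specification is validated", {
  expect_error(bend_spec("zigzag", 90), "unsupported-style")
  expect_error(bend_spec("corner_magnet_A", 0), "invalid-spec")
  expect_error(bend_spec("corner_magnet_A", 180), "invalid-spec")
})

test_that("patterns export to JSON and SVG", {
  pat <- make_drop_track(track_spec(n_units = 2))
  jf <- tempfile(fileext = ".json")
  sf <- tempfile(fileext = ".svg")
  pattern_to_json(pat, jf)
  pattern_to_svg(pat, sf)
  parsed <- jsonlite::read_json(jf)
  expect_length(parsed$polygons, 2)
  expect_match(readLines(sf, n = 1), "<svg")
})
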