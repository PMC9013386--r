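test_that("binding model is monotone, bounded and validated", {
  m <- binding_model()
  cs <- 10^seq(-14, -8, by = 0.5)
  p3 <- pair_probability(m, cs, "3D")
  expect_true(all(diff(p3) > 0))
  expect_true(all(p3 >= m$p_bg_3d & p3 <= m$p_max))
  expect_equal(pair_probability(m, 0, "3D"), m$p_bg_3d)
  expect_equal(pair_probability(m, 0, "2D"), m$p_bg_2d)
  expect_equal(pair_probability(m, 1e5, "3D"), m$p_max, tolerance = 1e-6)
  expect_equal(pair_probability(m, m$k, "3D"),
               (m$p_bg_3d + m$p_max) / 2)
  expect_error(binding_model(p_bg_2d = 0.01, p_bg_3d = 0.05),
               "invalid-model")
  expect_error(binding_model(p_max = 1.2), "invalid-model")
  expect_error(binding_model(k = 0), "invalid-model")
})

test_that("binding simulation is seeded and respects the model limits", {
  m <- binding_model()
  a <- simulate_binding(1e-11, m, 200, "3D", seed = 5)
  b <- simulate_binding(1e-11, m, 200, "3D", seed = 5)
  expect_identical(a, b)
  expect_equal(a$n_singles + 2 * a$n_pairs, 200)

  # zero analyte in 3D: rate close to the 3D baseline (binomial CI)
  counts <- vapply(1:30, function(s)
    simulate_binding(0, m, 200, "3D", seed = s)$n_pairs, numeric(1))
  rate <- mean(counts) / 100
  se <- sqrt(m$p_bg_3d * (1 - m$p_bg_3d) / (100 * 30))
  expect_lt(abs(rate - m$p_bg_3d), 4 * se)
})

test_that("chamber rendering is deterministic and faithful", {
  sc <- chamber_scene(3, 10, snr = 8, seed = 21)
  r1 <- render_chamber_image(sc)
  r2 <- render_chamber_image(sc)
  expect_identical(r1$image, r2$image)
  expect_equal(nrow(r1$ground_truth), 16)
  expect_equal(sum(!is.na(r1$ground_truth$link)), 6)
  # linked beads touch; unlinked do not overlap
  cen <- sc$centers_um
  for (k in seq_len(nrow(sc$links))) {
    d <- sqrt(sum((cen[sc$links[k, 1], ] - cen[sc$links[k, 2], ])^2))
    expect_equal(d, 2 * sc$radii_um[1], tolerance = 1e-9)
  }
})

test_that("dose series rises with concentration and stays flat in 2D", {
  m <- binding_model()
  ds <- generate_dose_series(10^seq(-13, -9), m, n_beads = 200,
                             replicates = 10, field_mode = "3D",
                             seed = 11)
  med <- tapply(ds$pair_percentage, ds$concentration, median)
  expect_true(all(diff(med) >= 0))
  expect_gt(med[length(med)], med[1] + 20)

  low <- generate_dose_series(c(1e-14, 1e-13), m, n_beads = 200,
                              replicates = 10, field_mode = "2D",
                              seed = 12)
  rate <- mean(low$n_pairs) / 100
  expect_lt(abs(rate - m$p_bg_2d), 0.05)

  single <- generate_dose_series(1e-11, m, replicates = 1, seed = 13)
  expect_equal(nrow(single), 1)
})

test_that("binding parameters are recovered from synthetic series", {
  m <- binding_model(p_bg_2d = 0.15, p_bg_3d = 0.02, p_max = 0.8,
                     k = 1e-11)
  ds <- generate_dose_series(10^seq(-13, -9, by = 0.5), m,
                             n_beads = 200, replicates = 10, seed = 31)
  fit <- recover_binding_params(ds, n_boot = 0)
  expect_lt(abs(log(fit$estimate[["k"]] / 1e-11)), log(2))
  expect_lt(abs(fit$estimate[["p_max"]] - 0.8), 0.1)
  # baseline from the low-concentration chambers within binomial error
  expect_lt(abs(fit$estimate[["p_bg"]] - 0.02), 0.015)

  zeros <- ds
  zeros$n_pairs <- 0
  expect_error(recover_binding_params(zeros), "fit-failure")
  expect_error(recover_binding_params(ds[ds$replicate <= 2, ]),
               "insufficient-data")
})

test_that("encounter simulation separates the two drive modes", {
  r2 <- vapply(1:3, function(s)
    simulate_background_encounters(30, mode = "2D", duration = 30,
                                   seed = s)$n_touching_pairs, numeric(1))
  r3 <- vapply(1:3, function(s)
    simulate_background_encounters(30, mode = "3D", duration = 30,
                                   seed = s)$n_touching_pairs, numeric(1))
  expect_gt(mean(r2), 2 * mean(r3))

  # two distant beads without thermal kicks never meet
  two <- simulate_background_encounters(2, duration = 5, seed = 1)
  expect_lte(two$n_touching_pairs, 1)
  still <- simulate_transport(
    list(magnetic_particle(1.4, pos = c(20, 20)),
         magnetic_particle(1.4, pos = c(80, 80))),
    NULL, external_field(), sim_config(duration = 5),
    bounds = c(0, 0, 100, 100))
  gap <- sqrt(sum((still[[1]]$xy[251, ] - still[[2]]$xy[251, ])^2)) - 2.8
  expect_gt(gap, 50)
})

test_that("encounter generator is reproducible and validates inputs", {
  a <- simulate_background_encounters(10, duration = 10, seed = 9)
  b <- simulate_background_encounters(10, duration = 10, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_error(simulate_background_encounters(1), "invalid-argument")
  expect_error(simulate_background_encounters(50, area_fraction = 0.7),
               "packing")
})
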