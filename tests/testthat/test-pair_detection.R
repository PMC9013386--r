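test_that("noiseless synthetic beads are detected exactly", {
  sc <- chamber_scene(0, 20, seed = 3)
  rend <- render_chamber_image(sc)
  det <- detect_beads(rend$image, radius_range = c(4, 12))
  expect_equal(nrow(det), 20)
  gt <- rend$ground_truth
  for (i in seq_len(nrow(gt))) {
    dd <- sqrt((det$row - gt$row[i])^2 + (det$col - gt$col[i])^2)
    expect_lt(min(dd), 1)
  }
})

test_that("blank and invalid images are handled", {
  blank <- matrix(0.2, 120, 120)
  det <- detect_beads(blank, radius_range = c(4, 12))
  expect_equal(nrow(det), 0)
  expect_error(detect_beads("x"), "invalid-input")
  expect_error(detect_beads(matrix(1, 10, 10), radius_range = c(-1, 5)),
               "invalid-input")
})

test_that("detection reaches 0.95 precision and recall at SNR 5", {
  hits <- 0; n_det <- 0; n_true <- 0
  for (seed in 1:3) {
    sc <- chamber_scene(5, 20, snr = 5, seed = seed, image_px = 420)
    rend <- render_chamber_image(sc)
    det <- detect_beads(rend$image, radius_range = c(4, 12))
    gt <- rend$ground_truth
    used <- rep(FALSE, nrow(det))
    for (i in seq_len(nrow(gt))) {
      dd <- sqrt((det$row - gt$row[i])^2 + (det$col - gt$col[i])^2)
      dd[used] <- Inf
      j <- which.min(dd)
      if (length(j) && dd[j] < gt$radius_px[i]) {
        hits <- hits + 1; used[j] <- TRUE
      }
    }
    n_det <- n_det + nrow(det); n_true <- n_true + nrow(gt)
  }
  expect_gte(hits / n_true, 0.95)    # recall
  expect_gte(hits / n_det, 0.95)     # precision
})

test_that("pair classification follows the touch rule", {
  # two beads exactly at contact distance
  d2 <- data.frame(row = c(50, 50), col = c(50, 64), radius_px = c(7, 7))
  cp <- classify_pairs(d2, tolerance = 0.2)
  expect_equal(cp$n_pairs, 1)
  expect_equal(cp$n_singles, 0)
  expect_equal(cp$pair_percentage, 100)

  # far apart: two singles
  far <- data.frame(row = c(50, 50), col = c(50, 92), radius_px = c(7, 7))
  cf <- classify_pairs(far, tolerance = 0.2)
  expect_equal(cf$n_pairs, 0)
  expect_equal(cf$n_singles, 2)
  expect_equal(cf$pair_percentage, 0)

  # 3 pairs + 14 singles -> 30%
  cp3 <- pair_summary(3, 14)
  expect_equal(cp3$pair_percentage, 30)
})

test_that("bead counts are conserved through classification", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    det <- data.frame(row = runif(n, 0, 200), col = runif(n, 0, 200),
                      radius_px = runif(n, 4, 8))
    cp <- classify_pairs(det)
    expect_equal(cp$n_singles + 2 * cp$n_pairs + sum(cp$cluster_sizes),
                 n)
    if (!is.nan(cp$pair_percentage)) {
      expect_gte(cp$pair_percentage, 0)
      expect_lte(cp$pair_percentage, 100)
    }
  }
})

test_that("detection counts are invariant under rigid image motions", {
  sc <- chamber_scene(2, 8, seed = 5, image_px = 300)
  rend <- render_chamber_image(sc)
  base <- classify_pairs(detect_beads(rend$image, c(4, 12)))
  rot <- t(rend$image)[ncol(rend$image):1, ]   # 90 degree rotation
  rc <- classify_pairs(detect_beads(rot, c(4, 12)))
  expect_equal(rc$n_pairs, base$n_pairs)
  expect_equal(rc$n_singles, base$n_singles)
})

test_that("noiseless rendering round-trips the ground-truth labels", {
  for (seed in c(2, 9)) {
    sc <- chamber_scene(3, 14, seed = seed)
    rend <- render_chamber_image(sc)
    cp <- classify_pairs(detect_beads(rend$image, c(4, 12)))
    expect_equal(cp$n_pairs, 3)
    expect_equal(cp$n_singles, 14)
    expect_equal(cp$pair_percentage, 30)
  }
})

test_that("dose-response table summarizes replicates per concentration", {
  sums <- c(lapply(c(2, 3, 4, 3, 2), pair_summary, n_singles = 16),
            lapply(c(8, 9, 10, 9, 8), pair_summary, n_singles = 4))
  conc <- rep(c(1e-12, 1e-10), each = 5)
  dr <- dose_response(sums, conc)
  expect_equal(nrow(dr), 2)
  expect_equal(dr$n, c(5, 5))
  expect_lt(dr$median[1], dr$median[2])
  one <- dose_response(lapply(c(2, 3, 4, 5, 6), pair_summary,
                              n_singles = 10), rep(1e-11, 5))
  expect_equal(nrow(one), 1)
  expect_equal(one$median,
               stats::median(100 * 2 * (2:6) / (2 * (2:6) + 10)))
  expect_error(dose_response(list(), numeric(0)), "insufficient-data")
})

test_that("field-mode ratio handles plain counts and the zero sentinel", {
  expect_equal(field_mode_ratio(c(14, 14), c(2, 2)), 7)
  expect_equal(field_mode_ratio(c(5, 5), c(0, 0)), Inf)
  expect_error(field_mode_ratio(numeric(0), 1), "insufficient-data")
})
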