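# Stimulus generation: masks, dot statistics, contrast manipulation,
# space-time structure.

test_that("center mask is a seeded irregular disc", {
  # zero perturbation -> exact circular disc
  circ <- make_center_mask(c(96L, 96L), 2.4, 25, 1, outline_amplitude = 0)
  cy <- (96 + 1) / 2
  yy <- matrix(seq_len(96), 96, 96)
  xx <- matrix(seq_len(96), 96, 96, byrow = TRUE)
  expect_identical(circ, sqrt((xx - cy)^2 + (yy - cy)^2) <= 2.4 * 25 / 2)

  # determinism and seed dependence
  m1 <- make_center_mask(c(96L, 96L), 2.4, 25, 1)
  expect_identical(m1, make_center_mask(c(96L, 96L), 2.4, 25, 1))
  m2 <- make_center_mask(c(96L, 96L), 2.4, 25, 2)
  expect_false(identical(m1, m2))

  # areas agree within 10% across seeds
  areas <- vapply(1:30, function(s) {
    sum(make_center_mask(c(96L, 96L), 2.4, 25, s))
  }, numeric(1))
  expect_lt((max(areas) - min(areas)) / mean(areas), 0.10)

  # geometry errors
  expect_error(make_center_mask(c(64L, 64L), 3, 25, 1), "exceeds the frame")
})

test_that("temporal coherence maps to survival probability (identity)", {
  expect_identical(coherence_to_survival(100), 1)        # static dots
  expect_identical(coherence_to_survival(50), 0.5)       # random flicker
  expect_identical(coherence_to_survival(0.75), 0.75)
  expect_identical(coherence_to_survival(75), 0.75)      # percent input
  expect_error(coherence_to_survival(0.4), "coherence")
  expect_error(coherence_to_survival(101), "coherence")
  expect_error(coherence_to_survival(30), "coherence")
})

test_that("spec validation rejects sub-pixel displacement and bad geometry", {
  expect_error(stimulus_spec(center_speed_deg_per_s = 5),
               "positive integer")  # 5 * 25 / 75 = 5/3 px
  expect_error(stimulus_spec(motion_direction_deg = 45),
               "integer per-frame pixel shift")
  expect_error(small_spec(surround_outer_diameter_deg = 2),
               "exceed the center diameter")
  expect_identical(default_stimulus_spec()$n_frames, 300L)
  expect_identical(default_stimulus_spec()$displacement_px, 2L)
})

test_that("generated movies have the configured dot statistics", {
  sq <- generate_sequence(small_spec(rng_seed = 11))
  expect_identical(dim(sq$frames)[3], 15L)  # 0.2 s at 75 Hz
  expect_false(any(sq$center_mask & sq$surround_mask))

  # luminances are the discrete levels of each region (or background gray)
  expect_setequal(unique(as.vector(sq$frames)), c(0, 0.5, 1))

  # density within binomial tolerance (pooled over frames)
  d <- measure_density(sq)
  n_px <- (sum(sq$center_mask) + sum(sq$surround_mask)) * 15
  expect_lt(abs(d - 0.5), 4 * sqrt(0.25 / n_px) + 0.005)

  expect_equal(measure_michelson(sq), 1)
})

test_that("static surround and zero speed give frozen frames", {
  sq <- generate_sequence(small_spec(center_speed_deg_per_s = 0,
                                     surround_temporal_coherence = 1))
  for (t in 2:dim(sq$frames)[3]) {
    expect_identical(sq$frames[, , t], sq$frames[, , 1])
  }
})

test_that("center pixel stream is bit-identical across surround coherence", {
  s1 <- generate_sequence(small_spec(rng_seed = 3))
  s2 <- generate_sequence(small_spec(rng_seed = 3,
                                     surround_temporal_coherence = 0.5))
  idx <- which(s1$center_mask)
  for (t in seq_len(dim(s1$frames)[3])) {
    expect_identical(s1$frames[, , t][idx], s2$frames[, , t][idx])
  }
  # while the surrounds differ
  expect_false(identical(s1$frames, s2$frames))
})

test_that("contrast manipulation rescales levels and conserves region means", {
  sq <- generate_sequence(small_spec(rng_seed = 5,
                                     surround_temporal_coherence = 0.5))
  lo <- set_region_contrast(sq, "surround", 0.5)
  vals <- unique(as.vector(lo$frames[, , 1][lo$surround_mask]))
  expect_setequal(round(vals, 10), c(0.25, 0.75))  # (0.75-0.25)/(0.75+0.25)

  # the two levels stay exactly symmetric about the mean luminance, so the
  # ensemble-mean luminance is conserved; the sample mean can only move
  # toward the mean by its own binomial deviation
  expect_identical(mean(range(lo$frames[, , 1][lo$surround_mask])), 0.5)
  for (t in c(1L, 7L)) {
    before <- mean(sq$frames[, , t][sq$surround_mask])
    after <- mean(lo$frames[, , t][lo$surround_mask])
    expect_lte(abs(after - 0.5), abs(before - 0.5))
    expect_lt(abs(after - before), 4 * sqrt(0.25 / sum(sq$surround_mask)))
  }
  # dot on/off pattern (and hence flicker) unchanged
  expect_identical(lo$frames[, , 3][lo$surround_mask] > 0.5,
                   sq$frames[, , 3][sq$surround_mask] > 0.5)
  # center untouched
  expect_identical(lo$frames[, , 3][lo$center_mask],
                   sq$frames[, , 3][sq$center_mask])

  # identity and error paths
  expect_identical(set_region_contrast(sq, "center", 1)$frames, sq$frames)
  expect_error(set_region_contrast(sq, "background", 0.5))
  expect_error(set_region_contrast(sq, "center", 1.5), "new_contrast")
})

test_that("survival estimate inverts chance agreement", {
  # static surround -> exactly 1
  expect_identical(measure_survival(generate_sequence(small_spec())), 1)

  # survival 0.5 at density 0.5: raw agreement ~ 0.75, estimate ~ 0.5
  sq <- generate_sequence(small_spec(surround_temporal_coherence = 0.5,
                                     duration_s = 1, rng_seed = 8))
  expect_lt(abs(measure_survival(sq) - 0.5), 0.02)

  expect_error(measure_survival(generate_sequence(
    small_spec(duration_s = 1 / 75))), "at least 2 frames")
})

test_that("space-time plots trace the configured kinematics", {
  sq <- generate_sequence(small_spec(rng_seed = 2, duration_s = 0.2))
  stp <- st_plot(sq)
  expect_identical(dim(unclass(stp)), c(15L, 96L))

  # static surround + zero speed: every trace parallel to the time axis
  fz <- st_plot(generate_sequence(small_spec(center_speed_deg_per_s = 0)))
  expect_true(all(apply(unclass(fz), 2, function(col) all(col == col[1]))))

  # upward translation at 2 px/frame: interior center rows of the ST image
  # repeat shifted by the displacement from one frame to the next
  rows_inside <- which(apply(sq$center_mask[, 46:50], 1, all))
  rows_inside <- rows_inside[(rows_inside + 2) %in% rows_inside]
  expect_identical(stp[2, rows_inside], stp[1, rows_inside + 2])

  # identical center band across surround-flicker conditions
  sq2 <- generate_sequence(small_spec(rng_seed = 2, duration_s = 0.2,
                                      surround_temporal_coherence = 0.5))
  stp2 <- st_plot(sq2)
  band_rows <- which(apply(sq$center_mask[, 46:50], 1, all))
  expect_identical(stp[, band_rows], stp2[, band_rows])

  expect_error(st_plot(sq, column_band = 95:100), "outside the frame")
})

test_that("hidden texture cross-correlation recovers the printed speed", {
  sq <- generate_sequence(small_spec(rng_seed = 4))
  es <- estimate_center_speed(sq)
  expect_identical(es$shift, c(-2L, 0L))  # 2 px/frame upward
  expect_equal(es$speed_deg_per_s, 6)    # 2 px * 75 Hz / 25 px/deg
  expect_equal(es$match, 1)              # rigid translation matches exactly
})
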