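test_that("occlusal line construction normalises and rejects degeneracy", {
  l <- occlusal_line(c(0, 0), c(10, 0))
  expect_equal(l$u, c(1, 0))
  expect_equal(occlusal_line(c(0, 0), c(3, 4))$u, c(0.6, 0.8))
  # anchor order must not change the apical sign convention
  expect_equal(occlusal_line(c(10, 0), c(0, 0))$u, c(1, 0))
  expect_error(occlusal_line(c(0, 0), c(0, 0)),
               class = "eruptq_error_occlusal_plane_undefined")
  expect_error(occlusal_line(c(0, 0), c(1e-12, 0)),
               class = "eruptq_error_occlusal_plane_undefined")
})

test_that("perpendicular distance is signed apical-positive", {
  l <- occlusal_line(c(0, 0), c(10, 0))
  expect_equal(perpendicular_distance(l, c(3, 4)), 4)
  expect_equal(perpendicular_distance(l, c(5, 0)), 0)
  expect_equal(perpendicular_distance(l, c(7, -2)), -2)
  # oblique line: rotate the axis-aligned case, read off the rotated y
  l2 <- occlusal_line(c(0, 0), c(3, 4))
  expect_equal(perpendicular_distance(l2, c(4, -3)), -5)
})

test_that("perpendicular distance magnitude matches a dense-sampling oracle", {
  set.seed(42)
  for (i in 1:25) {
    p1 <- runif(2, -50, 50)
    p2 <- runif(2, -50, 50)
    if (sqrt(sum((p2 - p1)^2)) < 1) next
    p <- runif(2, -50, 50)
    d <- perpendicular_distance(occlusal_line(p1, p2), p)
    expect_equal(abs(d), brute_line_distance(p1, p2, p), tolerance = 1e-6)
  }
})

test_that("quotient arithmetic, direction and symmetry", {
  rec <- make_record(measurement_landmarks(4, 16), mm_per_px = 1)
  m <- measure_quotient(rec, "m2_over_m3", round_lengths = TRUE)
  expect_equal(m$q, 0.25)
  expect_equal(m$d_m2, 4)
  expect_equal(m$d_m3, 16)
  m2 <- measure_quotient(rec, "m3_over_m2", round_lengths = TRUE)
  expect_equal(m2$q, 4)
  sym <- make_record(measurement_landmarks(7, 7), mm_per_px = 1)
  expect_equal(measure_quotient(sym, "m2_over_m3")$q, 1)
  expect_equal(measure_quotient(sym, "m3_over_m2")$q, 1)
})

test_that("lengths are rounded half-up to 0.1 mm before division", {
  # 44.49 px at 0.1 mm/px -> 4.449 mm -> 4.4; 44.5 px -> 4.45 mm -> 4.5
  rec <- make_record(measurement_landmarks(44.49, 100), mm_per_px = 0.1)
  m <- measure_quotient(rec, round_lengths = TRUE)
  expect_equal(m$q, 4.4 / 10)
  rec2 <- make_record(measurement_landmarks(44.5, 100), mm_per_px = 0.1)
  expect_equal(measure_quotient(rec2, round_lengths = TRUE)$q, 4.5 / 10)
  # unrounded lengths are carried alongside
  expect_equal(m$d_m2_mm, 4.449)
})

test_that("rounding without calibration is a configuration error", {
  rec <- make_record(measurement_landmarks(4, 16), mm_per_px = NA_real_)
  expect_error(measure_quotient(rec, round_lengths = TRUE),
               class = "eruptq_error_config")
  expect_equal(measure_quotient(rec, round_lengths = FALSE)$q, 0.25)
})

test_that("non-apical CEJ points are a measurement exclusion, not a sign flip", {
  rec <- make_record(measurement_landmarks(-4, 16))
  expect_error(measure_quotient(rec, round_lengths = FALSE),
               class = "eruptq_error_nonpositive_distance")
})

test_that("missing measurement landmarks abort measurement", {
  lm <- measurement_landmarks(4, 16)
  rec <- make_record(lm[lm$label != "M3_MESIAL_CEJ", ])
  expect_error(measure_quotient(rec, round_lengths = FALSE),
               class = "eruptq_error_missing_landmark")
})

test_that("angulation is signed mesial-positive with side-dependent direction", {
  vert <- list(coronal = c(0, 0), apical = c(0, 10))
  expect_equal(tooth_angulation(vert, vert, 38), 0)
  # coronal tip towards -x: mesial for 38, distal for 48
  tilt <- function(deg) {
    a <- deg * pi / 180
    list(coronal = c(-10 * sin(a), 10 - 10 * cos(a)), apical = c(0, 10))
  }
  expect_equal(tooth_angulation(tilt(35), vert, 38), 35)
  expect_equal(tooth_angulation(tilt(35), vert, 48), -35)
  expect_equal(tooth_angulation(tilt(-5), vert, 38), -5)
  # flipped image orientation reverses the sign
  expect_equal(tooth_angulation(tilt(35), vert, 38, orientation = "flipped"),
               -35)
  expect_error(tooth_angulation(list(coronal = c(0, 0), apical = c(0, 0)),
                                vert, 38),
               class = "eruptq_error_geometry")
})

test_that("eligibility accumulates reasons with strict angle boundaries", {
  # exactly 30 degrees mesial is included ("exceeding" is strict)
  rec30 <- make_record(measurement_landmarks(10, 30, angle_deg = 30))
  r <- assess_eligibility(rec30)
  expect_true(r$included)
  expect_equal(r$angle, 30, tolerance = 1e-9)

  rec35 <- make_record(measurement_landmarks(10, 30, angle_deg = 35))
  r35 <- assess_eligibility(rec35)
  expect_false(r35$included)
  expect_equal(r35$reasons, "MESIAL_ANGULATION_GT_30")

  # any distal angulation excludes under the default config ...
  rec_d <- make_record(measurement_landmarks(10, 30, angle_deg = -5))
  expect_equal(assess_eligibility(rec_d)$reasons, "DISTAL_ANGULATION")
  # ... but a tolerance admits slight distal tilts
  rec_d2 <- make_record(measurement_landmarks(10, 30, angle_deg = -0.2))
  expect_false(assess_eligibility(rec_d2)$included)
  expect_true(assess_eligibility(
    rec_d2, eligibility_config(angle_tolerance = 0.5))$included)

  # missing measurement landmark
  lm <- measurement_landmarks(10, 30)
  r_miss <- assess_eligibility(make_record(lm[lm$label != "M3_MESIAL_CEJ", ]))
  expect_false(r_miss$included)
  expect_true("MISSING_LANDMARK" %in% r_miss$reasons)

  # no axis landmarks: eligible, angulation not assessed
  r_nax <- assess_eligibility(make_record(measurement_landmarks(10, 30)))
  expect_true(r_nax$included)
  expect_false(r_nax$angle_assessed)
  expect_true(is.na(r_nax$angle))

  # coincident occlusal anchors
  lm2 <- measurement_landmarks(10, 30)
  lm2$x[lm2$label == "M2_DISTAL_CUSP"] <- 0
  lm2$y[lm2$label == "M2_DISTAL_CUSP"] <- 0
  r_deg <- assess_eligibility(make_record(lm2))
  expect_true("OCCLUSAL_PLANE_UNDEFINED" %in% r_deg$reasons)
})

test_that("quotient is invariant under similarity transforms, distances scale", {
  set.seed(7)
  rec <- make_record(measurement_landmarks(6.5, 22.3))
  base <- measure_quotient(rec, round_lengths = FALSE)
  for (i in 1:50) {
    theta <- runif(1, -pi, pi)
    s <- exp(runif(1, -1.5, 1.5))
    tr <- transform_records(rec, theta, s, runif(1, -500, 500),
                            runif(1, -500, 500))
    m <- measure_quotient(tr, round_lengths = FALSE)
    expect_equal(m$q, base$q, tolerance = 1e-9)
    expect_equal(m$d_m2, s * base$d_m2, tolerance = 1e-9)
    expect_equal(m$d_m3, s * base$d_m3, tolerance = 1e-9)
  }
})

test_that("mirroring x preserves distances and quotient, flips angulation sign", {
  rec <- make_record(measurement_landmarks(6.5, 22.3, angle_deg = 12))
  base <- measure_quotient(rec, round_lengths = FALSE)
  ang <- assess_eligibility(rec)$angle
  mirrored <- rec
  mirrored$landmarks <- lapply(mirrored$landmarks, function(lm) {
    lm$x <- -lm$x
    lm
  })
  m <- measure_quotient(mirrored, round_lengths = FALSE)
  expect_equal(m$d_m2, base$d_m2, tolerance = 1e-12)
  expect_equal(m$d_m3, base$d_m3, tolerance = 1e-12)
  expect_equal(m$q, base$q, tolerance = 1e-12)
  expect_equal(assess_eligibility(mirrored)$angle, -ang, tolerance = 1e-9)
})

test_that("rounded-mode quotient converges to unrounded as lengths grow", {
  # rounding to 0.1 mm perturbs each length by at most 0.05 mm
  rec <- make_record(measurement_landmarks(80, 240), mm_per_px = 0.1)
  q_round <- measure_quotient(rec, round_lengths = TRUE)$q
  q_exact <- measure_quotient(rec, round_lengths = FALSE)$q
  bound <- 0.05 / 8 + 0.05 / 24 + 1e-6
  expect_lt(abs(q_round - q_exact) / q_exact, bound)
})
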