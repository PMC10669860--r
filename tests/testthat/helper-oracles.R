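# Independent oracles and small fixture builders shared across tests.

# Krippendorff's alpha by literal enumeration of every ordered pairable pair,
# kept deliberately loop-based and separate from the package implementation.
brute_alpha <- function(m, metric = "interval") {
  m <- as.matrix(m)
  keep <- rowSums(!is.na(m)) >= 2
  m <- m[keep, , drop = FALSE]
  delta2 <- function(c, k) {
    if (metric == "interval") (c - k)^2 else ((c - k) / (c + k))^2
  }
  num <- 0
  n <- 0
  for (i in seq_len(nrow(m))) {
    v <- m[i, ][!is.na(m[i, ])]
    mu <- length(v)
    n <- n + mu
    s <- 0
    for (a in seq_len(mu)) {
      for (b in seq_len(mu)) {
        if (a != b) s <- s + delta2(v[a], v[b])
      }
    }
    num <- num + s / (mu - 1)
  }
  d_o <- num / n
  pooled <- m[!is.na(m)]
  s <- 0
  for (a in seq_along(pooled)) {
    for (b in seq_along(pooled)) {
      if (a != b) s <- s + delta2(pooled[a], pooled[b])
    }
  }
  d_e <- s / (n * (n - 1))
  1 - d_o / d_e
}

# Spearman's rho by the d^2 formula (valid when there are no ties).
spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force point-to-line distance: minimise the Euclidean distance over
# densely sampled points on the line, with grid refinement around the best
# sample (no projection formula involved).
brute_line_distance <- function(p1, p2, p) {
  lo <- -500
  hi <- 500
  for (stage in 1:5) {
    t <- seq(lo, hi, length.out = 4001)
    d <- sqrt((p1[1] + t * (p2[1] - p1[1]) - p[1])^2 +
                (p1[2] + t * (p2[2] - p1[2]) - p[2])^2)
    best <- t[which.min(d)]
    step <- (hi - lo) / 4000
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  min(d)
}

# One annotation record as a one-row records tibble.
make_record <- function(landmarks,
                        subject_id = "S1", age = 20, sex = "female",
                        side = 38L, rater_id = "R1", session = 1L,
                        mm_per_px = NA_real_) {
  tibble::tibble(
    subject_id = subject_id, age = age, sex = sex, side = as.integer(side),
    rater_id = rater_id, session = as.integer(session),
    mm_per_px = mm_per_px,
    landmarks = list(landmarks)
  )
}

# Measurement landmarks yielding perpendicular distances d2 and d3 (pixels)
# from a horizontal occlusal line, optionally with axis landmarks at a given
# mesial angulation (degrees; side-38 geometry, mesial = -x).
measurement_landmarks <- function(d2, d3, angle_deg = NULL) {
  lm <- tibble::tibble(
    label = c("M1_MESIAL_CUSP", "M2_DISTAL_CUSP", "M2_MESIAL_CEJ",
              "M3_MESIAL_CEJ"),
    x = c(0, 100, 60, 115),
    y = c(0, 0, d2, d3)
  )
  if (!is.null(angle_deg)) {
    a <- angle_deg * pi / 180
    axes <- tibble::tibble(
      label = c("M2_AXIS_CORONAL", "M2_AXIS_APICAL",
                "M3_AXIS_CORONAL", "M3_AXIS_APICAL"),
      x = c(80, 80, 120 - 30 * sin(a), 120 + 35 * sin(a)),
      y = c(10, 75, 60 - 30 * cos(a), 60 + 35 * cos(a))
    )
    lm <- rbind(lm, axes)
  }
  lm
}

# Apply a similarity transform (rotation theta, scale s, translation t) to
# every landmark of a records tibble.
transform_records <- function(records, theta, s, tx, ty) {
  records$landmarks <- lapply(records$landmarks, function(lm) {
    x <- s * (lm$x * cos(theta) - lm$y * sin(theta)) + tx
    y <- s * (lm$x * sin(theta) + lm$y * cos(theta)) + ty
    lm$x <- x
    lm$y <- y
    lm
  })
  records
}

# Random ratings matrix with missing entries for oracle-equivalence checks.
random_ratings <- function(n_units, n_obs, p_missing = 0.2,
                           values = 0:3) {
  m <- matrix(sample(values, n_units * n_obs, replace = TRUE),
              nrow = n_units)
  m[matrix(runif(n_units * n_obs) < p_missing, nrow = n_units)] <- NA
  m
}

# Records for a small synthetic multi-rater study where the quotient is a
# deterministic function of age (used by pipeline tests).
cellwise_records <- function(n_per_cell = 6, raters = list(c("R1", 1L),
                                                           c("R1", 2L),
                                                           c("R2", 1L))) {
  grid <- expand.grid(side = c(38L, 48L), sex = c("female", "male"),
                      i = seq_len(n_per_cell), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    age <- 15 + g$i
    d3 <- 40 - 2 * g$i # erupting with age -> q increasing
    recs <- lapply(raters, function(r) {
      make_record(measurement_landmarks(10, d3),
                  subject_id = sprintf("%s_%s_%02d", g$side, g$sex, g$i),
                  age = age, sex = g$sex, side = g$side,
                  rater_id = r[[1]], session = as.integer(r[[2]]),
                  mm_per_px = 0.1)
    })
    dplyr::bind_rows(recs)
  })
  dplyr::bind_rows(out)
}
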