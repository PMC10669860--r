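# Seeded synthetic cohort generator.
#
# A latent logistic eruption trajectory carries the third molar's mesial CEJ
# towards the occlusal plane with age; landmarks are placed on a canonical
# millimetre template whose perpendicular distances to the occlusal anchors
# equal the latent distances exactly, then projected to pixels with a
# per-radiograph magnification, occlusal tilt and translation, and finally
# jittered per rater and session.

#' Simulator parameters
#'
#' Defaults describe a two-rater reading study on an age-15-to-25 cohort:
#' rater R1 reads every radiograph twice (two sessions), rater R2 once.
#'
#' @param cohort Age-by-sex cohort table (default: the packaged reference
#'   cohort, 423 radiographs).
#' @param eruption_midpoint_mean,eruption_midpoint_sd Mean and SD in years of
#'   the per-subject age at half-maximal eruption (per sex; scalar recycles).
#' @param eruption_slope Logistic slope in 1/years.
#' @param d_m2_mean,d_m2_sd Millimetres: perpendicular distance from the
#'   occlusal line to the second molar's mesial CEJ.
#' @param initial_depth_mean,initial_depth_sd Millimetres: how far below the
#'   second molar's CEJ level the unerupted third molar's CEJ starts.
#' @param side_correlation Correlation of the eruption midpoint between sides
#'   38 and 48 of one subject.
#' @param magnification_mean,magnification_sd Per-radiograph projection
#'   magnification factor.
#' @param occlusal_tilt_sd Degrees: per-radiograph rotation of the molar
#'   block in the image.
#' @param landmark_noise_sd Pixels: iid Gaussian annotation jitter per
#'   rater x session and landmark coordinate.
#' @param mm_per_px_true True detector calibration, mm per pixel at unit
#'   magnification.
#' @param mesial_angle_sd Degrees: spread of the third molar's mesial
#'   angulation.
#' @param p_distal Probability that a third molar is distoangulated.
#' @param raters Character vector of rater ids; the first rater reads twice.
#' @param sessions_for_rater_1 Number of sessions for the first rater.
#' @param emit_calibration Record `mm_per_px` on the simulated annotations?
#' @param seed Integer seed; required, all randomness derives from it.
#' @return A list of class `simulator_params`.
#' @export
simulator_params <- function(cohort = read_cohort_table(),
                             eruption_midpoint_mean = c(female = 19.5, male = 19.5),
                             eruption_midpoint_sd = 2.5,
                             eruption_slope = 0.8,
                             d_m2_mean = 4.5, d_m2_sd = 0.6,
                             initial_depth_mean = 12, initial_depth_sd = 2,
                             side_correlation = 0.8,
                             magnification_mean = 1.25, magnification_sd = 0.05,
                             occlusal_tilt_sd = 4,
                             landmark_noise_sd = 1.5,
                             mm_per_px_true = 0.1,
                             mesial_angle_sd = 8,
                             p_distal = 0.05,
                             raters = c("R1", "R2"),
                             sessions_for_rater_1 = 2L,
                             emit_calibration = TRUE,
                             seed) {
  if (missing(seed) || is.null(seed)) {
    abort("simulator_params requires an explicit integer seed.",
          class = "eruptq_error_config")
  }
  if (length(eruption_midpoint_mean) == 1L) {
    eruption_midpoint_mean <- c(female = unname(eruption_midpoint_mean),
                                male = unname(eruption_midpoint_mean))
  }
  stopifnot(
    all(c("female", "male") %in% names(eruption_midpoint_mean)),
    eruption_midpoint_sd >= 0, d_m2_sd >= 0, initial_depth_sd >= 0,
    side_correlation >= 0, side_correlation <= 1,
    magnification_sd >= 0, occlusal_tilt_sd >= 0, landmark_noise_sd >= 0,
    mm_per_px_true > 0, mesial_angle_sd >= 0,
    p_distal >= 0, p_distal <= 1,
    length(raters) >= 1L, sessions_for_rater_1 >= 1L
  )
  structure(list(
    cohort = cohort,
    eruption_midpoint_mean = eruption_midpoint_mean,
    eruption_midpoint_sd = eruption_midpoint_sd,
    eruption_slope = eruption_slope,
    d_m2_mean = d_m2_mean, d_m2_sd = d_m2_sd,
    initial_depth_mean = initial_depth_mean,
    initial_depth_sd = initial_depth_sd,
    side_correlation = side_correlation,
    magnification_mean = magnification_mean,
    magnification_sd = magnification_sd,
    occlusal_tilt_sd = occlusal_tilt_sd,
    landmark_noise_sd = landmark_noise_sd,
    mm_per_px_true = mm_per_px_true,
    mesial_angle_sd = mesial_angle_sd,
    p_distal = p_distal,
    raters = raters,
    sessions_for_rater_1 = as.integer(sessions_for_rater_1),
    emit_calibration = isTRUE(emit_calibration),
    seed = as.integer(seed)
  ), class = "simulator_params")
}

#' Sample subjects from the cohort table
#'
#' Draws exactly `cohort[age_year, sex]` subjects per cell, with each exact
#' age uniform within its one-year age group.
#'
#' @param params A [simulator_params()] object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return Tibble: `subject_id`, `age` (decimal years), `sex`.
#' @export
sample_subjects <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "simulator_params"))
  set.seed(as.integer(seed))
  cells <- params$cohort %>%
    tidyr::pivot_longer(c("female", "male"), names_to = "sex",
                        values_to = "count")
  out <- cells %>%
    dplyr::rowwise() %>%
    dplyr::reframe(age = .data$age + runif(.data$count), sex = .data$sex)
  if (nrow(out) == 0L) {
    return(tibble(subject_id = character(), age = numeric(), sex = character()))
  }
  out %>%
    mutate(subject_id = sprintf("S%04d", row_number())) %>%
    select("subject_id", "age", "sex")
}

# canonical side-38 template in local millimetre coordinates: occlusal line
# along +x at y = 0, apical = +y, mesial = -x; mirrored in x for side 48
template_landmarks <- function(d_m2, d_m3, angle_deg) {
  a <- angle_deg * pi / 180
  cx <- 27
  cy <- d_m3 + 4
  tibble(
    label = landmark_labels(),
    x = c(0, 21, 12, 23, 16, 16, cx - 6 * sin(a), cx + 7 * sin(a)),
    y = c(0, 0, d_m2, d_m3, 2, 15, cy - 6 * cos(a), cy + 7 * cos(a))
  )
}

#' Latent true geometry per subject and side
#'
#' For each subject and side a latent eruption fraction
#' `s = logistic(slope * (age - t0))` is drawn (eruption midpoints `t0`
#' correlated across sides), and the third molar CEJ depth is
#' `d_m3 = d_m2 + (1 - s) * initial_depth`, so the true quotient
#' `q = d_m2 / d_m3` rises towards 1 with age. Mesial angulation is drawn
#' with a configurable distal contamination rate.
#'
#' @inheritParams sample_subjects
#' @param subjects Tibble from [sample_subjects()].
#' @return Tibble: one row per subject x side with `s`, `d_m2_true`,
#'   `d_m3_true`, `q_true`, `angle_true` and a `landmarks_mm` list-column of
#'   local-millimetre landmark templates whose perpendicular distances to the
#'   occlusal anchors equal the true distances exactly.
#' @export
true_geometry <- function(subjects, params, seed = params$seed + 1L) {
  stopifnot(inherits(params, "simulator_params"))
  set.seed(as.integer(seed))
  n <- nrow(subjects)
  if (n == 0L) {
    return(tibble(subject_id = character(), age = numeric(), sex = character(),
                  side = integer(), s = numeric(), d_m2_true = numeric(),
                  d_m3_true = numeric(), q_true = numeric(),
                  angle_true = numeric(), landmarks_mm = list()))
  }
  rho <- params$side_correlation
  z_shared <- rnorm(n)
  out <- tidyr::crossing(subjects, side = c(38L, 48L)) %>%
    arrange(.data$subject_id, .data$side) %>%
    mutate(
      z_shared = rep(z_shared, each = 2L),
      z_side = rnorm(2L * n),
      t0 = unname(params$eruption_midpoint_mean[.data$sex]) +
        params$eruption_midpoint_sd *
          (sqrt(rho) * .data$z_shared + sqrt(1 - rho) * .data$z_side),
      s = plogis(params$eruption_slope * (.data$age - .data$t0)),
      d_m2_true = pmax(rnorm(2L * n, params$d_m2_mean, params$d_m2_sd), 0.5),
      initial_depth = pmax(rnorm(2L * n, params$initial_depth_mean,
                                 params$initial_depth_sd), 1),
      d_m3_true = .data$d_m2_true + (1 - .data$s) * .data$initial_depth,
      q_true = .data$d_m2_true / .data$d_m3_true,
      distal = rbinom(2L * n, 1L, params$p_distal) == 1L,
      angle_mag = abs(rnorm(2L * n, 0, params$mesial_angle_sd)),
      angle_true = ifelse(.data$distal, -.data$angle_mag, .data$angle_mag)
    ) %>%
    select(-"z_shared", -"z_side", -"t0", -"distal", -"angle_mag",
           -"initial_depth")
  out$landmarks_mm <- purrr::pmap(
    list(out$d_m2_true, out$d_m3_true, out$angle_true, out$side),
    function(d2, d3, ang, side) {
      lm <- template_landmarks(d2, d3, ang)
      if (side == 48L) lm$x <- -lm$x # mirror: mesial becomes +x
      lm
    }
  )
  out
}

#' Render observed annotation records
#'
#' Applies one magnification factor, occlusal tilt and translation per
#' radiograph (shared across raters, who read the same image), then emits one
#' record per rater x session with iid Gaussian landmark jitter. The recorded
#' calibration is `mm_per_px_true / magnification`, so calibrated lengths are
#' in true millimetres.
#'
#' @inheritParams sample_subjects
#' @param truth Tibble from [true_geometry()].
#' @return A records tibble as returned by [read_annotations()].
#' @export
render_observations <- function(truth, params, seed = params$seed + 2L) {
  stopifnot(inherits(params, "simulator_params"))
  set.seed(as.integer(seed))
  n_img <- nrow(truth)
  if (n_img == 0L) return(empty_records())

  img <- truth %>%
    select("subject_id", "age", "sex", "side", "landmarks_mm") %>%
    mutate(
      mag = pmax(rnorm(n_img, params$magnification_mean,
                       params$magnification_sd), 0.5),
      tilt = rnorm(n_img, 0, params$occlusal_tilt_sd) * pi / 180,
      tx = runif(n_img, 200, 1200),
      ty = runif(n_img, 200, 1200)
    )

  sessions <- dplyr::bind_rows(
    tibble(rater_id = params$raters[1],
           session = seq_len(params$sessions_for_rater_1)),
    if (length(params$raters) > 1L) {
      tibble(rater_id = params$raters[-1], session = 1L)
    }
  )

  long <- img %>%
    tidyr::unnest("landmarks_mm") %>%
    mutate(
      # rotate by the radiograph tilt, scale mm -> px, translate
      px = (.data$x * cos(.data$tilt) - .data$y * sin(.data$tilt)) *
        .data$mag / params$mm_per_px_true + .data$tx,
      py = (.data$x * sin(.data$tilt) + .data$y * cos(.data$tilt)) *
        .data$mag / params$mm_per_px_true + .data$ty
    ) %>%
    select("subject_id", "age", "sex", "side", "mag", "label",
           x = "px", y = "py")

  obs <- tidyr::crossing(long, sessions) %>%
    arrange(.data$subject_id, .data$side, .data$rater_id, .data$session,
            .data$label)
  m <- nrow(obs)
  obs <- obs %>%
    mutate(
      x = .data$x + rnorm(m, 0, params$landmark_noise_sd),
      y = .data$y + rnorm(m, 0, params$landmark_noise_sd),
      mm_per_px = if (params$emit_calibration) {
        params$mm_per_px_true / .data$mag
      } else {
        NA_real_
      }
    ) %>%
    select(all_of(ANNOTATION_COLUMNS))
  group_annotations(obs)
}

#' Simulate a complete multi-rater annotated cohort
#'
#' Runs [sample_subjects()], [true_geometry()] and [render_observations()]
#' under the parameter seed. Deterministic: the same parameters produce an
#' identical dataset.
#'
#' @param params A [simulator_params()] object.
#' @return List with `records` (annotation records tibble, ready for the
#'   study pipeline) and `truth` (per radiograph: latent eruption fraction,
#'   true distances, true quotient, true angulation).
#' @export
#' @examples
#' sim <- simulate_cohort(simulator_params(seed = 1))
#' nrow(sim$truth) # 2 sides per subject
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "simulator_params"))
  subjects <- sample_subjects(params)
  truth <- true_geometry(subjects, params)
  records <- render_observations(truth, params)
  list(records = records,
       truth = select(truth, -"landmarks_mm"),
       params = params)
}
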