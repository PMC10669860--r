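# Study orchestration: eligibility filtering, vectorized quotient
# measurement, per-tooth/per-sex correlation with age, and intra-/inter-rater
# reliability.

#' Study configuration
#'
#' @param direction Quotient direction, `"m2_over_m3"` (default) or
#'   `"m3_over_m2"`; recorded in all outputs.
#' @param round_lengths Round lengths to 0.1 mm before forming the quotient
#'   (requires calibrated records).
#' @param eligibility An [eligibility_config()].
#' @param orientation Image orientation for angulation signs.
#' @param alpha_metric `"interval"` (default) or `"ratio"`.
#' @param ci_method Spearman CI method, `"fisher_bw"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples for reliability (and Spearman bootstrap)
#'   intervals.
#' @param seed Integer seed driving every bootstrap.
#' @param correlation_rater,correlation_session Which annotation run feeds
#'   the age correlation (default: the second session of the dual-session
#'   rater).
#' @param intra_rater,intra_sessions The dual-session rater and its two
#'   sessions compared for repeatability.
#' @param inter_rater_a,inter_session_a,inter_rater_b,inter_session_b The two
#'   runs compared for inter-rater reproducibility (default: rater R1
#'   session 2 against rater R2 session 1).
#' @return A list of class `study_config`.
#' @export
study_config <- function(direction = "m2_over_m3",
                         round_lengths = TRUE,
                         eligibility = eligibility_config(),
                         orientation = "standard",
                         alpha_metric = "interval",
                         ci_method = "fisher_bw",
                         n_boot = 2000L,
                         seed = 1L,
                         correlation_rater = "R1", correlation_session = 2L,
                         intra_rater = "R1", intra_sessions = c(1L, 2L),
                         inter_rater_a = "R1", inter_session_a = 2L,
                         inter_rater_b = "R2", inter_session_b = 1L) {
  structure(list(
    direction = direction, round_lengths = round_lengths,
    eligibility = eligibility, orientation = orientation,
    alpha_metric = alpha_metric, ci_method = ci_method,
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    correlation_rater = correlation_rater,
    correlation_session = as.integer(correlation_session),
    intra_rater = intra_rater, intra_sessions = as.integer(intra_sessions),
    inter_rater_a = inter_rater_a,
    inter_session_a = as.integer(inter_session_a),
    inter_rater_b = inter_rater_b,
    inter_session_b = as.integer(inter_session_b)
  ), class = "study_config")
}

#' Vectorized eligibility screening
#'
#' Applies [assess_eligibility()] to every record. A subject excluded on one
#' side may remain in the study on the other side.
#'
#' @param records Records tibble.
#' @param config A [study_config()].
#' @return List: `records` (input plus `included`, `reasons` list-column,
#'   `angle`), `included` (the eligible subset) and `tally` (exclusion counts
#'   by reason; one record may be tallied under several reasons).
#' @export
run_eligibility <- function(records, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  res <- purrr::map(seq_len(nrow(records)), function(i) {
    assess_eligibility(records[i, ], config$eligibility, config$orientation)
  })
  out <- records %>%
    mutate(included = purrr::map_lgl(res, "included"),
           reasons = purrr::map(res, "reasons"),
           angle = purrr::map_dbl(res, "angle"))
  reasons <- unlist(purrr::map(res, "reasons"))
  tally <- if (length(reasons) == 0L) {
    tibble(reason = character(), n = integer())
  } else {
    as_tibble(table(reason = reasons), .name_repair = "minimal") %>%
      rename(n = "n") %>%
      arrange(.data$reason)
  }
  list(records = out, included = filter(out, .data$included), tally = tally)
}

#' Measure eruption quotients for a set of records
#'
#' Vectorized equivalent of [measure_quotient()] over a records tibble; rows
#' that are not measurable (missing landmarks, undefined occlusal line or
#' non-positive perpendicular distances) get `NA` quotients rather than
#' errors.
#'
#' @inheritParams run_eligibility
#' @return The records tibble with `d_m2`, `d_m3` (pixels), `d_m2_mm`,
#'   `d_m3_mm`, `q`, `direction` and `rounded` columns appended.
#' @export
measure_records <- function(records, config = study_config()) {
  w <- records_wide(records)
  ux <- w$x_M2_DISTAL_CUSP - w$x_M1_MESIAL_CUSP
  uy <- w$y_M2_DISTAL_CUSP - w$y_M1_MESIAL_CUSP
  len <- sqrt(ux^2 + uy^2)
  len[len <= 1e-9] <- NA_real_
  ux <- ux / len
  uy <- uy / len
  flip <- !is.na(ux) & ux < 0
  ux[flip] <- -ux[flip]
  uy[flip] <- -uy[flip]
  sd_to <- function(px, py) {
    ux * (py - w$y_M1_MESIAL_CUSP) - uy * (px - w$x_M1_MESIAL_CUSP)
  }
  d2 <- sd_to(w$x_M2_MESIAL_CEJ, w$y_M2_MESIAL_CEJ)
  d3 <- sd_to(w$x_M3_MESIAL_CEJ, w$y_M3_MESIAL_CEJ)
  # anatomical orientation: a frame-negative M2 CEJ distance means the image
  # is inverted relative to the raster convention; flip both signs
  inv <- !is.na(d2) & d2 < 0
  d2[inv] <- -d2[inv]
  d3[inv] <- -d3[inv]
  ok <- !is.na(d2) & !is.na(d3) & d2 > 0 & d3 > 0
  d2[!ok] <- NA_real_
  d3[!ok] <- NA_real_
  d2_mm <- d2 * w$mm_per_px
  d3_mm <- d3 * w$mm_per_px
  if (config$round_lengths) {
    if (any(ok & is.na(w$mm_per_px))) {
      abort("round_lengths = TRUE but some measurable records lack mm_per_px calibration.",
            class = "eruptq_error_config")
    }
    num <- round_half_up(if (config$direction == "m2_over_m3") d2_mm else d3_mm, 1L)
    den <- round_half_up(if (config$direction == "m2_over_m3") d3_mm else d2_mm, 1L)
    den[!is.na(den) & den <= 0] <- NA_real_
    q <- num / den
  } else {
    q <- if (config$direction == "m2_over_m3") d2 / d3 else d3 / d2
  }
  records %>%
    mutate(d_m2 = d2, d_m3 = d3, d_m2_mm = d2_mm, d_m3_mm = d3_mm, q = q,
           direction = config$direction, rounded = config$round_lengths)
}

study_cells <- function() {
  tidyr::crossing(side = c(38L, 48L), sex = c("female", "male")) %>%
    arrange(.data$side, .data$sex)
}

#' Correlation between eruption quotient and age, per tooth and sex
#'
#' Uses the annotation run selected by the configuration (default: second
#' session of the dual-session rater), one quotient per subject x side, and
#' computes Spearman's rho with its 95% confidence interval in each of the
#' four tooth-by-sex cells. Cells with fewer than 5 measured quotients are
#' flagged not estimable.
#'
#' @param measured Output of [measure_records()] (eligible records).
#' @param config A [study_config()].
#' @return Tibble: `side`, `sex`, `rho`, `n`, `lcl`, `ucl`, `level`,
#'   `ci_method`, `estimable`.
#' @export
correlation_study <- function(measured, config = study_config()) {
  sel <- measured %>%
    filter(.data$rater_id == config$correlation_rater,
           .data$session == config$correlation_session,
           !is.na(.data$q))
  study_cells() %>%
    purrr::pmap(function(side, sex) {
      cell <- sel[sel$side == side & sel$sex == sex, ]
      if (nrow(cell) < 5L) {
        return(tibble(side = side, sex = sex, rho = NA_real_,
                      n = nrow(cell), lcl = NA_real_, ucl = NA_real_,
                      level = 0.95, ci_method = NA_character_,
                      estimable = FALSE))
      }
      est <- spearman_estimate(cell$age, cell$q, ci_method = config$ci_method,
                               n_boot = config$n_boot,
                               seed = config$seed + side)
      tibble(side = side, sex = sex, rho = est$rho, n = est$n,
             lcl = est$lcl, ucl = est$ucl, level = est$level,
             ci_method = est$ci_method, estimable = !is.na(est$rho))
    }) %>%
    bind_rows()
}

# build the units x 2 ratings matrix for one tooth-by-sex cell from two
# annotation runs; units = subjects measurable in the run (pairing handled by
# the alpha pairability rule)
cell_ratings <- function(measured, side, sex, run_a, run_b) {
  pick <- function(run, col) {
    measured %>%
      filter(.data$side == !!side, .data$sex == !!sex,
             .data$rater_id == run$rater, .data$session == run$session) %>%
      select("subject_id", !!col := "q")
  }
  wide <- dplyr::full_join(pick(run_a, "obs_a"), pick(run_b, "obs_b"),
                           by = "subject_id") %>%
    arrange(.data$subject_id)
  m <- as.matrix(wide[, c("obs_a", "obs_b")])
  rownames(m) <- wide$subject_id
  m
}

reliability_table <- function(measured, config, run_a, run_b) {
  study_cells() %>%
    purrr::pmap(function(side, sex) {
      m <- cell_ratings(measured, side, sex, run_a, run_b)
      m <- m[rowSums(!is.na(m)) > 0L, , drop = FALSE]
      n_one_session <- sum(rowSums(!is.na(m)) == 1L)
      est <- tryCatch(
        reliability_estimate(m, metric = config$alpha_metric,
                             n_boot = config$n_boot,
                             seed = config$seed + 10L * side +
                               (sex == "male")),
        error = function(e) NULL
      )
      if (is.null(est)) {
        return(tibble(side = side, sex = sex, alpha = NA_real_,
                      metric = config$alpha_metric, n_units = nrow(m),
                      n_dropped = n_one_session, n_pairable = NA_integer_,
                      lcl = NA_real_, ucl = NA_real_, level = 0.95,
                      n_boot = NA_integer_, estimable = FALSE))
      }
      est %>%
        mutate(side = side, sex = sex, estimable = !is.na(.data$alpha)) %>%
        select("side", "sex", "alpha", "metric", "n_units", "n_dropped",
               "n_pairable", "lcl", "ucl", "level", "n_boot", "estimable")
    }) %>%
    bind_rows()
}

#' Intra-rater repeatability per tooth and sex
#'
#' Krippendorff's alpha between the two sessions of the dual-session rater;
#' units are subject x side, restricted to each tooth-by-sex cell. Units
#' measured in only one session cannot be paired and are dropped and counted
#' (`n_dropped`).
#'
#' @inheritParams correlation_study
#' @return Tibble: `side`, `sex`, `alpha`, `metric`, `n_units`, `n_dropped`,
#'   `n_pairable`, `lcl`, `ucl`, `level`, `n_boot`, `estimable`.
#' @export
intra_rater_study <- function(measured, config = study_config()) {
  have <- measured %>%
    filter(.data$rater_id == config$intra_rater) %>%
    pull("session") %>%
    unique()
  if (!all(config$intra_sessions %in% have)) {
    abort("Configured dual-session rater/sessions not present in the data.",
          class = "eruptq_error_config")
  }
  reliability_table(
    measured, config,
    run_a = list(rater = config$intra_rater,
                 session = config$intra_sessions[1]),
    run_b = list(rater = config$intra_rater,
                 session = config$intra_sessions[2])
  )
}

#' Inter-rater reproducibility per tooth and sex
#'
#' Krippendorff's alpha between one run of each of two raters (default:
#' the dual-session rater's second run against the other rater's single
#' run).
#'
#' @inheritParams correlation_study
#' @return As [intra_rater_study()].
#' @export
inter_rater_study <- function(measured, config = study_config()) {
  raters <- unique(measured$rater_id)
  if (!all(c(config$inter_rater_a, config$inter_rater_b) %in% raters)) {
    abort("Inter-rater study needs both configured raters present in the data.",
          class = "eruptq_error_config")
  }
  reliability_table(
    measured, config,
    run_a = list(rater = config$inter_rater_a,
                 session = config$inter_session_a),
    run_b = list(rater = config$inter_rater_b,
                 session = config$inter_session_b)
  )
}

#' Run the complete eruption study
#'
#' Eligibility screening, quotient measurement, the age correlation and both
#' reliability analyses, with a provenance block (configuration, seed,
#' package version). With `out_dir` the report is also written to disk (three
#' TSV tables plus a full-precision JSON blob); identical inputs and
#' configuration produce byte-identical files.
#'
#' @param records Records tibble (e.g. from [read_annotations()] or
#'   [simulate_cohort()]).
#' @param config A [study_config()].
#' @param out_dir Optional output directory for [write_report()].
#' @return A list of class `study_report`: `cohort_summary`, `exclusions`,
#'   `correlation`, `intra_rater`, `inter_rater`, `provenance`.
#' @export
run_full_study <- function(records, config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  elig <- run_eligibility(records, config)
  measured <- measure_records(elig$included, config)

  subjects <- distinct(records, .data$subject_id, .data$sex)
  cohort_summary <- list(
    n_records = nrow(records),
    n_subjects = nrow(subjects),
    n_female = sum(subjects$sex == "female"),
    n_male = sum(subjects$sex == "male"),
    n_records_included = nrow(elig$included),
    n_records_excluded = nrow(records) - nrow(elig$included)
  )

  report <- structure(list(
    cohort_summary = cohort_summary,
    exclusions = elig$tally,
    correlation = correlation_study(measured, config),
    intra_rater = intra_rater_study(measured, config),
    inter_rater = inter_rater_study(measured, config),
    provenance = list(
      package = "eruptq",
      version = as.character(utils::packageVersion("eruptq")),
      seed = config$seed,
      direction = config$direction,
      round_lengths = config$round_lengths,
      alpha_metric = config$alpha_metric,
      ci_method = config$ci_method,
      n_boot = config$n_boot,
      correlation_run = paste0(config$correlation_rater, "/s",
                               config$correlation_session),
      intra_runs = paste0(config$intra_rater, "/s",
                          config$intra_sessions, collapse = " vs "),
      inter_runs = paste0(config$inter_rater_a, "/s", config$inter_session_a,
                          " vs ", config$inter_rater_b, "/s",
                          config$inter_session_b),
      mesial_angle_limit = config$eligibility$mesial_angle_limit,
      distal_angle_limit = config$eligibility$distal_angle_limit,
      angle_tolerance = config$eligibility$angle_tolerance
    )
  ), class = "study_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Eruption quotient study report\n")
  cat(sprintf("  subjects: %d (%d female, %d male); records: %d (%d included)\n",
              x$cohort_summary$n_subjects, x$cohort_summary$n_female,
              x$cohort_summary$n_male, x$cohort_summary$n_records,
              x$cohort_summary$n_records_included))
  cat("  correlation (rho by tooth x sex):\n")
  print(as.data.frame(x$correlation[, c("side", "sex", "rho", "lcl", "ucl")]),
        row.names = FALSE, digits = 3)
  cat("  intra-rater alpha:\n")
  print(as.data.frame(x$intra_rater[, c("side", "sex", "alpha", "lcl", "ucl")]),
        row.names = FALSE, digits = 3)
  cat("  inter-rater alpha:\n")
  print(as.data.frame(x$inter_rater[, c("side", "sex", "alpha", "lcl", "ucl")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a study report to disk
#'
#' Three TSV tables (correlation, intra-rater, inter-rater; estimates and
#' 95% confidence limits to three decimals, `NE` marking cells that are not
#' estimable) plus `report.json` holding every value at full precision with
#' the provenance block. Output is deterministic: rewriting the same report
#' yields byte-identical files.
#'
#' @param report A `study_report` from [run_full_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) ifelse(is.na(x), "NE", sprintf("%.3f", x))

  corr <- report$correlation %>%
    mutate(tooth = .data$side, estimate = fmt(.data$rho),
           lcl95 = fmt(.data$lcl), ucl95 = fmt(.data$ucl)) %>%
    select("tooth", "sex", "estimate", "lcl95", "ucl95", "n")
  readr::write_tsv(corr, file.path(dir, "correlation.tsv"))

  rel <- function(tbl) {
    tbl %>%
      mutate(tooth = .data$side, estimate = fmt(.data$alpha),
             lcl95 = fmt(.data$lcl), ucl95 = fmt(.data$ucl)) %>%
      select("tooth", "sex", "estimate", "lcl95", "ucl95", "n_units")
  }
  readr::write_tsv(rel(report$intra_rater), file.path(dir, "intra_rater.tsv"))
  readr::write_tsv(rel(report$inter_rater), file.path(dir, "inter_rater.tsv"))

  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), na = "null",
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}
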