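# Reading and writing landmark annotation tables and the cohort table.
#
# Annotations travel in long format, one landmark per row:
#   subject_id, age, sex, side, rater_id, session, label, x, y, mm_per_px
# (mm_per_px may be empty). Long format survives partial annotation; records
# are regrouped on read.

ANNOTATION_COLUMNS <- c("subject_id", "age", "sex", "side", "rater_id",
                        "session", "label", "x", "y", "mm_per_px")

#' Landmark label vocabulary
#'
#' The eight recognised landmark labels: the four measurement landmarks
#' (occlusal-line anchors on the first and second molar and the two mesial
#' CEJ points) and the four long-axis landmarks used for angulation.
#'
#' @return Character vector of valid labels.
#' @export
landmark_labels <- function() {
  c("M1_MESIAL_CUSP", "M2_DISTAL_CUSP", "M2_MESIAL_CEJ", "M3_MESIAL_CEJ",
    "M2_AXIS_CORONAL", "M2_AXIS_APICAL", "M3_AXIS_CORONAL", "M3_AXIS_APICAL")
}

#' @rdname landmark_labels
#' @export
measurement_labels <- function() landmark_labels()[1:4]

#' Read landmark annotations
#'
#' Reads an annotation file (long CSV, or a JSON array of equivalent
#' objects), validates it and groups landmarks into one record per
#' (subject, side, rater, session).
#'
#' @param path Path to the annotation file.
#' @param dialect `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return A records tibble: one row per annotation event with columns
#'   `subject_id`, `age`, `sex`, `side`, `rater_id`, `session`, `mm_per_px`
#'   and a `landmarks` list-column of tibbles (`label`, `x`, `y`).
#' @export
read_annotations <- function(path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path),
          class = "eruptq_error_io")
  }
  df <- if (dialect == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
  if (nrow(df) == 0L && !all(ANNOTATION_COLUMNS %in% names(df)) &&
      dialect == "json") {
    # an empty JSON array carries no column information; treat as empty
    return(empty_records())
  }
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("Annotation schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "eruptq_error_schema")
  }
  df <- df %>%
    mutate(subject_id = as.character(.data$subject_id),
           age = as.numeric(.data$age),
           sex = as.character(.data$sex),
           side = as.integer(.data$side),
           rater_id = as.character(.data$rater_id),
           session = as.integer(.data$session),
           label = as.character(.data$label),
           x = as.numeric(.data$x),
           y = as.numeric(.data$y),
           mm_per_px = as.numeric(.data$mm_per_px))
  validate_annotations(df)
  group_annotations(df)
}

validate_annotations <- function(df) {
  missing_cols <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("Annotation schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "eruptq_error_schema")
  }
  if (nrow(df) == 0L) return(invisible(df))
  df$.line <- seq_len(nrow(df)) + 1L # +1 for the header line

  bad_label <- !df$label %in% landmark_labels()
  if (any(bad_label)) {
    abort(paste0("Unknown landmark label(s) at line(s) ",
                 paste(head(df$.line[bad_label], 5L), collapse = ", "), ": ",
                 paste(unique(df$label[bad_label]), collapse = ", ")),
          class = "eruptq_error_validation")
  }
  bad_coord <- !is.finite(df$x) | !is.finite(df$y)
  if (any(bad_coord)) {
    abort(paste0("Non-finite coordinates at line(s) ",
                 paste(head(df$.line[bad_coord], 5L), collapse = ", ")),
          class = "eruptq_error_validation")
  }
  bad_age <- !is.finite(df$age) | df$age < 0 | df$age >= 130
  if (any(bad_age)) {
    abort(paste0("Age out of range [0, 130) at line(s) ",
                 paste(head(df$.line[bad_age], 5L), collapse = ", ")),
          class = "eruptq_error_validation")
  }
  bad_side <- !df$side %in% c(38L, 48L)
  if (any(bad_side)) {
    abort(paste0("Side must be FDI 38 or 48; offending line(s) ",
                 paste(head(df$.line[bad_side], 5L), collapse = ", ")),
          class = "eruptq_error_validation")
  }
  bad_sex <- !df$sex %in% c("female", "male")
  if (any(bad_sex)) {
    abort(paste0("Sex must be 'female' or 'male'; offending line(s) ",
                 paste(head(df$.line[bad_sex], 5L), collapse = ", ")),
          class = "eruptq_error_validation")
  }
  dup <- df %>%
    group_by(.data$subject_id, .data$side, .data$rater_id, .data$session,
             .data$label) %>%
    filter(n() > 1L) %>%
    ungroup()
  if (nrow(dup) > 0L) {
    g <- dup[1L, ]
    abort(paste0("Duplicate landmark label within a record: label ", g$label,
                 " for subject ", g$subject_id, ", side ", g$side,
                 ", rater ", g$rater_id, ", session ", g$session, "."),
          class = "eruptq_error_validation")
  }
  invisible(df)
}

group_annotations <- function(df) {
  if (nrow(df) == 0L) return(empty_records())
  df %>%
    select(all_of(ANNOTATION_COLUMNS)) %>%
    tidyr::nest(landmarks = c("label", "x", "y")) %>%
    arrange(.data$subject_id, .data$side, .data$rater_id, .data$session)
}

empty_records <- function() {
  tibble(subject_id = character(), age = numeric(), sex = character(),
         side = integer(), rater_id = character(), session = integer(),
         mm_per_px = numeric(), landmarks = list())
}

#' Write landmark annotations
#'
#' Inverse of [read_annotations()]: writes the long-format annotation table.
#' Coordinates are serialized at full double precision so that a
#' write-then-read round trip reproduces the records exactly.
#'
#' @param records A records tibble (see [read_annotations()]).
#' @param path Output file path.
#' @param dialect `"auto"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path, dialect = c("auto", "csv", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  long <- records_long(records)
  if (dialect == "csv") {
    out <- long %>%
      mutate(across(c("age", "x", "y", "mm_per_px"),
                    ~ ifelse(is.na(.x), "", sprintf("%.17g", .x))))
    readr::write_csv(out, path, na = "")
  } else {
    jsonlite::write_json(long, path, auto_unbox = FALSE, digits = I(17),
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

records_long <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(!!!setNames(rep(list(character(0)), 10L), ANNOTATION_COLUMNS)) %>%
             mutate(across(c("age", "x", "y", "mm_per_px"), as.numeric),
                    across(c("side", "session"), as.integer)))
  }
  records %>%
    tidyr::unnest("landmarks") %>%
    select(all_of(ANNOTATION_COLUMNS))
}

# wide per-record coordinate table used by the vectorized pipeline:
# one row per record, columns x_<LABEL>, y_<LABEL> (NA when absent)
records_wide <- function(records) {
  keys <- records %>%
    mutate(.record = row_number()) %>%
    select(".record", "subject_id", "age", "sex", "side", "rater_id",
           "session", "mm_per_px")
  coords <- records %>%
    mutate(.record = row_number()) %>%
    select(".record", "landmarks") %>%
    tidyr::unnest("landmarks") %>%
    tidyr::pivot_wider(names_from = "label", values_from = c("x", "y"),
                       names_sep = "_")
  need <- as.vector(outer(c("x", "y"), landmark_labels(), paste, sep = "_"))
  out <- left_join(keys, coords, by = ".record")
  for (col in setdiff(need, names(out))) out[[col]] <- NA_real_
  out
}

#' Read an age-by-sex cohort table
#'
#' The cohort table records the number of radiographs per one-year age group
#' (15 through 25) and sex. CSV schema: columns `age`, `female`, `male`.
#'
#' @param path Path to the cohort CSV. The default is the packaged reference
#'   cohort distribution (423 radiographs: 220 female, 203 male, ages 15-25).
#' @return A tibble with columns `age`, `female`, `male` and 11 rows.
#' @export
#' @examples
#' cohort <- read_cohort_table()
#' cohort_totals(cohort)
read_cohort_table <- function(path = default_cohort_path()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          age = readr::col_integer(),
                          female = readr::col_integer(),
                          male = readr::col_integer()
                        ))
  missing_cols <- setdiff(c("age", "female", "male"), names(df))
  if (length(missing_cols) > 0L) {
    abort(paste0("Cohort table schema error: missing column(s) ",
                 paste(missing_cols, collapse = ", ")),
          class = "eruptq_error_schema")
  }
  missing_ages <- setdiff(15:25, df$age)
  if (length(missing_ages) > 0L) {
    abort(paste0("Cohort table schema error: missing age row(s) ",
                 paste(missing_ages, collapse = ", ")),
          class = "eruptq_error_schema")
  }
  if (any(df$female < 0 | df$male < 0)) {
    abort("Cohort counts must be non-negative.",
          class = "eruptq_error_validation")
  }
  arrange(df, .data$age)
}

default_cohort_path <- function() {
  system.file("extdata", "cohort_counts.csv", package = "eruptq",
              mustWork = TRUE)
}

#' @rdname read_cohort_table
#' @param cohort A cohort tibble as returned by `read_cohort_table()`.
#' @return `cohort_totals`: a named list `total`, `female`, `male`.
#' @export
cohort_totals <- function(cohort) {
  list(total = sum(cohort$female) + sum(cohort$male),
       female = sum(cohort$female),
       male = sum(cohort$male))
}
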