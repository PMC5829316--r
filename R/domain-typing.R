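#' Classify a tibial-rotation angle into Type 1/2/3
#'
#' Tibial-rotation range of motion (degrees) is graded into three types:
#' Type 1 (narrow, angle <= 20), Type 2 (normal, 20 < angle <= 65) and
#' Type 3 (wide, angle > 65). Types 1 and 3 are considered pathological.
#'
#' The boundaries are closed on the left type: exactly 20 degrees is Type 1
#' and exactly 65 degrees is Type 2, so the three intervals [0, 20],
#' (20, 65] and (65, 90] partition the measurable range.
#'
#' @param angle numeric vector of rotation angles in degrees; every value
#'   must lie in \[0, 90\].
#' @return integer vector of type codes in `{1, 2, 3}`, same length as
#'   `angle`.
#' @seealso [is_pathological_type()], [classify_physical_cluster()]
#' @examples
#' classify_rotation_type(c(10, 20, 45, 65, 70))
#' @export
classify_rotation_type <- function(angle) {
  if (!is.numeric(angle) || length(angle) == 0) {
    stop("`angle` must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- which(is.na(angle) | angle < 0 | angle > 90)
  if (length(bad) > 0) {
    stop(sprintf(
      "rotation angle out of [0, 90] degrees at position %d: %s",
      bad[1], format(angle[bad[1]])
    ), call. = FALSE)
  }
  ifelse(angle <= 20, 1L, ifelse(angle <= 65, 2L, 3L))
}

#' Is a rotation type pathological?
#'
#' Narrow (Type 1) and wide (Type 3) rotation ranges are pathological;
#' Type 2 is not.
#'
#' @param type integer vector of type codes in `{1, 2, 3}`.
#' @return logical vector.
#' @export
is_pathological_type <- function(type) {
  if (!all(type %in% 1:3)) {
    stop("`type` must contain only codes 1, 2 or 3", call. = FALSE)
  }
  type != 2L
}

#' Assign subjects to rule-based physical clusters
#'
#' Subjects are stratified into three clusters from their physical
#' attributes: Cluster 1 if age > 30 years; otherwise Cluster 2 if weight
#' <= 60 kg, else Cluster 3. Height (the published threshold is 1.70 m)
#' is concordant with weight in the defining strata and is kept as a
#' clustering feature, but the rule-based label uses age and weight only,
#' so discordant weight/height combinations are still classified.
#'
#' @param age numeric vector, years (> 0).
#' @param weight numeric vector, kilograms (> 0).
#' @param height numeric vector, metres (> 0). Values above 3 are rejected
#'   as probable centimetre inputs.
#' @return integer vector of cluster codes in `{1, 2, 3}`.
#' @examples
#' classify_physical_cluster(age = c(45, 25, 25),
#'                           weight = c(70, 55, 75),
#'                           height = c(1.80, 1.65, 1.82))
#' @export
classify_physical_cluster <- function(age, weight, height) {
  n <- length(age)
  if (n == 0 || length(weight) != n || length(height) != n) {
    stop("`age`, `weight` and `height` must be non-empty and equal length",
         call. = FALSE)
  }
  check_positive(age, "age (years)")
  check_positive(weight, "weight (kg)")
  check_positive(height, "height (m)")
  if (any(height > 3)) {
    i <- which(height > 3)[1]
    stop(sprintf(
      "height %s m at position %d is implausible; heights must be in metres, not centimetres",
      format(height[i]), i
    ), call. = FALSE)
  }
  ifelse(age > 30, 1L, ifelse(weight <= 60, 2L, 3L))
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x <= 0)) {
    i <- which(is.na(x) | x <= 0)[1]
    stop(sprintf("%s must be strictly positive and non-missing (position %d: %s)",
                 what, i, format(x[i])), call. = FALSE)
  }
  invisible(x)
}

#' Validate a subject table
#'
#' Checks that a data frame has the subject columns (`age`, `weight`,
#' `height`, `rter`, `rtir`, `lter`, `ltir`), strictly positive physical
#' attributes, heights in metres and all four angles in \[0, 90\] degrees.
#'
#' @param subjects data frame of subjects.
#' @return `subjects`, invisibly, if valid; otherwise an error naming the
#'   offending column and row.
#' @export
validate_subjects <- function(subjects) {
  needed <- c("age", "weight", "height", subject_angle_cols())
  missing <- setdiff(needed, names(subjects))
  if (length(missing) > 0) {
    stop("subject table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(subjects) == 0) stop("subject table is empty", call. = FALSE)
  for (col in needed) {
    x <- subjects[[col]]
    if (!is.numeric(x) || any(is.na(x))) {
      stop(sprintf("column `%s` must be numeric with no missing values", col),
           call. = FALSE)
    }
  }
  check_positive(subjects$age, "age (years)")
  check_positive(subjects$weight, "weight (kg)")
  check_positive(subjects$height, "height (m)")
  if (any(subjects$height > 3)) {
    stop("height column contains values > 3; heights must be in metres",
         call. = FALSE)
  }
  for (col in subject_angle_cols()) {
    x <- subjects[[col]]
    bad <- which(x < 0 | x > 90)
    if (length(bad) > 0) {
      stop(sprintf("column `%s` row %d: angle %s out of [0, 90] degrees",
                   col, bad[1], format(x[bad[1]])), call. = FALSE)
    }
  }
  invisible(subjects)
}

subject_angle_cols <- function() c("rter", "rtir", "lter", "ltir")

#' Rotation component names
#'
#' The four tibial-rotation components: right/left external/internal
#' rotation.
#'
#' @return character vector `c("rter", "rtir", "lter", "ltir")`.
#' @export
rotation_components <- function() subject_angle_cols()

#' Label a cohort by rotation type and physical cluster
#'
#' Applies [classify_rotation_type()] to one rotation component and
#' [classify_physical_cluster()] to the physical attributes of every
#' subject, preserving row order.
#'
#' @param subjects data frame of subjects (see [validate_subjects()]).
#' @param rotation which rotation component to type, one of
#'   `"rter"`, `"rtir"`, `"lter"`, `"ltir"`.
#' @return data frame with columns `type` (1..3), `pathological`
#'   (logical) and `cluster` (1..3), one row per subject.
#' @examples
#' s <- data.frame(age = 25, weight = 55, height = 1.65,
#'                 rter = 45, rtir = 30, lter = 50, ltir = 28)
#' label_cohort(s, "rter")
#' @export
label_cohort <- function(subjects, rotation = rotation_components()) {
  rotation <- match.arg(rotation)
  validate_subjects(subjects)
  type <- tryCatch(
    classify_rotation_type(subjects[[rotation]]),
    error = function(e) stop(sprintf("while typing `%s`: %s", rotation,
                                     conditionMessage(e)), call. = FALSE)
  )
  cluster <- classify_physical_cluster(subjects$age, subjects$weight,
                                       subjects$height)
  data.frame(type = type,
             pathological = is_pathological_type(type),
             cluster = cluster)
}

#' Read or write a subject CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `age,weight_kg,height_m,rter_deg,rtir_deg,lter_deg,ltir_deg` and one
#' row per subject; in memory the unit suffixes are dropped.
#'
#' @param path file path.
#' @param subjects data frame of subjects.
#' @return `read_subjects()` returns a validated subject data frame;
#'   `write_subjects()` returns `path` invisibly.
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  expected <- subject_csv_header()
  if (!identical(names(raw), expected)) {
    stop("subject CSV header must be exactly: ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  names(raw) <- c("age", "weight", "height", subject_angle_cols())
  validate_subjects(raw)
  raw
}

#' @rdname read_subjects
#' @export
write_subjects <- function(subjects, path) {
  validate_subjects(subjects)
  out <- subjects[, c("age", "weight", "height", subject_angle_cols())]
  names(out) <- subject_csv_header()
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

subject_csv_header <- function() {
  c("age", "weight_kg", "height_m", "rter_deg", "rtir_deg", "lter_deg",
    "ltir_deg")
}
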