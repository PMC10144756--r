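#' Cohort table columns
#'
#' Column contract for a per-eye cohort of pseudophakic eyes with prior myopic
#' laser refractive surgery: `eye_id`, axial length `al_mm`, mean keratometry
#' `k_d`, the manufacturer's `a_constant`, the `iol_model` label (`"UNKNOWN"`
#' when the implanted model was not recorded), the implanted `iol_power_d`,
#' the postoperative spherical equivalent `postop_se_d`, and the record
#' `source` (`"clinic"` or `"literature"`).
#'
#' @return character vector of column names.
#' @export
cohort_columns <- function() {
  c("eye_id", "al_mm", "k_d", "a_constant", "iol_model",
    "iol_power_d", "postop_se_d", "source")
}

.mandatory_numeric <- c("al_mm", "k_d", "a_constant", "iol_power_d", "postop_se_d")

#' Validate a cohort table
#'
#' Applies the record-level plausibility rules: the four biometric/outcome
#' fields and the A-constant must be present and finite, axial length and
#' keratometry must fall inside configurable plausibility windows, and the
#' A-constant must lie in (100, 125).  These are validation guards, not
#' clinical exclusions; clinical exclusion criteria are assumed to have been
#' applied upstream.  Every input row is either returned or listed in the
#' rejection log with exactly one reason (the first rule that failed).
#'
#' @param data a data frame with the [cohort_columns()] (extra columns pass
#'   through).
#' @param al_window,k_window plausibility windows for axial length (mm) and
#'   keratometry (D).
#' @return a tibble of accepted records (row order preserved) of class
#'   `iol_cohort`, with a `rejections` attribute: a tibble with columns
#'   `row`, `eye_id`, `reason`.  Retrieve it with [rejection_log()].
#' @export
validate_cohort <- function(data, al_window = c(15, 40), k_window = c(25, 60)) {
  missing_cols <- setdiff(setdiff(cohort_columns(), c("source", "iol_model")),
                          names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"iol_model" %in% names(data)) data$iol_model <- "UNKNOWN"
  if (!"source" %in% names(data)) data$source <- "clinic"
  data$iol_model <- dplyr::coalesce(as.character(data$iol_model), "UNKNOWN")
  data$source <- dplyr::coalesce(as.character(data$source), "clinic")

  reason <- rep(NA_character_, nrow(data))
  note <- function(cond, why) {
    ifelse(is.na(reason) & cond, why, reason)
  }
  labels <- c(al_mm = "al", k_d = "k", a_constant = "a_constant",
              iol_power_d = "iol_power", postop_se_d = "outcome")
  for (col in .mandatory_numeric) {
    bad <- !is.finite(suppressWarnings(as.numeric(data[[col]])))
    reason <- note(bad, paste0("incomplete ", labels[[col]]))
  }
  reason <- note(!is.na(data$al_mm) & (data$al_mm < al_window[1] | data$al_mm > al_window[2]),
                 "al out of plausibility window")
  reason <- note(!is.na(data$k_d) & (data$k_d < k_window[1] | data$k_d > k_window[2]),
                 "k out of plausibility window")
  reason <- note(!is.na(data$a_constant) & (data$a_constant <= 100 | data$a_constant >= 125),
                 "a_constant out of plausibility window")
  reason <- note(!data$source %in% c("clinic", "literature"), "unknown source label")

  rejections <- tibble::tibble(
    row = which(!is.na(reason)),
    eye_id = as.character(data$eye_id[!is.na(reason)]),
    reason = reason[!is.na(reason)]
  )
  accepted <- data[is.na(reason), , drop = FALSE]
  accepted$eye_id <- as.character(accepted$eye_id)
  structure(accepted,
            rejections = rejections,
            class = c("iol_cohort", class(accepted)))
}

#' @rdname validate_cohort
#' @param cohort a validated cohort.
#' @export
rejection_log <- function(cohort) {
  attr(cohort, "rejections") %||%
    tibble::tibble(row = integer(), eye_id = character(), reason = character())
}

#' Read and write cohort tables
#'
#' `read_cohort()` reads a comma-separated, dot-decimal, single-header cohort
#' CSV (columns per [cohort_columns()]), validates every row with
#' [validate_cohort()], and optionally writes a plain-text rejection log
#' (one `row<TAB>reason` line per rejected row).  Unparseable numeric cells
#' reject the row, never abort the read; a missing mandatory column is a
#' schema error.
#'
#' @param path file path of the cohort CSV.
#' @param log optional path for the rejection log.
#' @inheritParams validate_cohort
#' @return `read_cohort()`: a validated `iol_cohort` tibble (see
#'   [validate_cohort()]).  `write_cohort()`: `path`, invisibly.
#' @examples
#' co <- read_cohort(system.file("extdata", "synthetic_cohort.csv",
#'                               package = "postiol"))
#' co
#' @export
read_cohort <- function(path, log = NULL, al_window = c(15, 40), k_window = c(25, 60)) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(setdiff(cohort_columns(), c("source", "iol_model")), names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in .mandatory_numeric) {
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  }
  cohort <- validate_cohort(raw, al_window = al_window, k_window = k_window)
  if (!is.null(log)) {
    rej <- rejection_log(cohort)
    readr::write_tsv(rej[, c("row", "reason")], log, col_names = FALSE)
  }
  cohort
}

#' @rdname read_cohort
#' @param cohort a cohort table.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(tibble::as_tibble(cohort)[, intersect(cohort_columns(), names(cohort))],
                   path)
  invisible(path)
}

#' Convert a manufacturer A-constant to a formula-native lens constant
#'
#' The standard published linear relations between the SRK A-constant and the
#' native constants of the base formulas: the SRK/T ACD constant, the
#' Holladay 1 surgeon factor, and the Shammas post-LASIK pACD.
#'
#' @param a_const manufacturer A-constant (dimensionless, typically 113-122).
#' @param target one of `"srkt_acd"`, `"holladay_sf"`, `"shammas_pacd"`.
#' @return the formula-native constant, mm scale.
#' @examples
#' convert_constant(118.4, "srkt_acd")     # 5.214
#' convert_constant(118.4, "holladay_sf")  # 1.450
#' convert_constant(118.4, "shammas_pacd") # 4.686
#' @export
convert_constant <- function(a_const,
                             target = c("srkt_acd", "holladay_sf", "shammas_pacd")) {
  target <- match.arg(target)
  switch(target,
    srkt_acd     = 0.62467 * a_const - 68.747,
    holladay_sf  = 0.5663 * a_const - 65.60,
    shammas_pacd = 0.5835 * a_const - 64.40
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
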