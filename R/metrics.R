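#' Refractive prediction error
#'
#' `pe = postop SE - predicted SE`, diopters; positive values are hyperopic
#' surprises (the eye ended up more hyperopic than the method predicted).
#'
#' @param se_post postoperative spherical equivalent, D.
#' @param se_pred method-predicted spherical equivalent, D.
#' @return prediction error, D.
#' @export
prediction_error <- function(se_post, se_pred) {
  se_post - se_pred
}

#' Accuracy metric battery for prediction errors
#'
#' The standard IOL-accuracy battery for one or more groups of prediction
#' errors: signed mean error (ME), median and mean absolute error (MedAE,
#' MAE), the standard error of the absolute errors, their minimum, maximum
#' and interquartile range (linear-interpolation quartiles), a 95% confidence
#' interval `MAE +/- 1.96 SE`, and counts/percentages of eyes within each
#' absolute-error threshold (inclusive comparison, `|PE| <= t`).
#'
#' @param data a data frame with a prediction-error column (e.g. the output
#'   of [predict_refraction()]), or a bare numeric vector of PEs.
#' @param pe column holding the prediction errors (tidy-eval; default `pe`).
#' @param by grouping columns (tidy-eval; default `method` when present).
#' @param thresholds absolute-error thresholds, D.
#' @return a tibble, one row per group: `n`, `me_d`, `medae_d`, `mae_d`,
#'   `se_d`, `min_d`, `max_d`, `iqr_d`, `ci_lo_d`, `ci_hi_d`, and per
#'   threshold `n_within_*` / `pct_within_*`.
#' @export
summarize_errors <- function(data, pe = pe, by = NULL, thresholds = c(0.5, 1)) {
  if (is.numeric(data)) {
    data <- tibble::tibble(pe = data)
  }
  data <- tibble::as_tibble(data)
  by_quo <- rlang::enquo(by)
  pe_quo <- rlang::enquo(pe)
  grouped <- if (rlang::quo_is_null(by_quo)) {
    if ("method" %in% names(data)) dplyr::group_by(data, .data$method) else data
  } else {
    dplyr::group_by(data, dplyr::across(!!by_quo))
  }
  out <- dplyr::summarise(grouped,
                          .battery = list(error_battery(!!pe_quo, thresholds)),
                          .groups = "drop")
  dplyr::select(tidyr::unnest(out, ".battery"), -dplyr::any_of(".battery"))
}

error_battery <- function(pe, thresholds) {
  pe <- pe[!is.na(pe)]
  if (length(pe) == 0) stop("no prediction errors to summarize", call. = FALSE)
  ab <- abs(pe)
  n <- length(pe)
  mae <- mean(ab)
  se <- stats::sd(ab) / sqrt(n)
  if (n == 1) se <- 0
  base <- tibble::tibble(
    n = n,
    me_d = mean(pe),
    medae_d = stats::median(ab),
    mae_d = mae,
    se_d = se,
    min_d = min(ab),
    max_d = max(ab),
    iqr_d = unname(diff(stats::quantile(ab, c(0.25, 0.75), type = 7))),
    ci_lo_d = mae - 1.96 * se,
    ci_hi_d = mae + 1.96 * se
  )
  for (t in thresholds) {
    lbl <- gsub("\\.", "_", formatC(t, format = "fg"))
    base[[paste0("n_within_", lbl)]] <- sum(ab <= t)
    base[[paste0("pct_within_", lbl)]] <- 100 * sum(ab <= t) / n
  }
  base
}
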