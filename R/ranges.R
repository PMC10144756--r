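#' Range schemes over keratometry, axial length, or their ratio
#'
#' A range scheme is an ordered set of strictly increasing cutoffs dividing a
#' biometric variable into left-open, right-closed intervals `(a, b]`, with
#' the lowest range unbounded below and the highest unbounded above —
#' matching the conventional table headers (e.g. "36.0 D < K <= 38.0 D").
#'
#' `range_scheme()` builds one directly; `derive_cutoffs()` derives the three
#' cutoffs of a four-range scheme from the quartiles of the observed values,
#' rounded to the nearest multiple of `step` (half away from zero);
#' `alk_scheme()` is the fixed three-range scheme over AL/K with cutoffs at
#' 2/3 (0.67) and 3/4 (0.75).
#'
#' @param variable one of `"K"`, `"AL"`, `"ALK"`.
#' @param cutoffs strictly increasing breakpoints.
#' @return an object of class `range_scheme` (list with `variable`,
#'   `cutoffs`, `labels`).
#' @export
range_scheme <- function(variable = c("K", "AL", "ALK"), cutoffs) {
  variable <- match.arg(variable)
  if (any(diff(cutoffs) <= 0)) {
    stop("cutoffs must be strictly increasing", call. = FALSE)
  }
  k <- length(cutoffs)
  labels <- c(
    paste0(variable, " <= ", cutoffs[1]),
    if (k > 1) paste0(cutoffs[-k], " < ", variable, " <= ", cutoffs[-1]),
    paste0(variable, " > ", cutoffs[k])
  )
  structure(list(variable = variable, cutoffs = cutoffs, labels = labels),
            class = "range_scheme")
}

#' @rdname range_scheme
#' @param values observed values of the variable (n >= 4).
#' @param step rounding step: 0.5 mm for AL, 1.0 D for K.
#' @param n_ranges number of ranges (fixed at 4).
#' @examples
#' derive_cutoffs(c(24, 26.4, 27.97, 29.6, 34), step = 0.5, variable = "AL")
#' @export
derive_cutoffs <- function(values, step, n_ranges = 4, variable = c("K", "AL", "ALK")) {
  variable <- match.arg(variable)
  values <- values[!is.na(values)]
  if (length(values) < n_ranges) stop("need at least ", n_ranges, " values", call. = FALSE)
  q <- stats::quantile(values, probs = seq_len(n_ranges - 1) / n_ranges, type = 7)
  rounded <- round_to_step(q, step)
  if (anyDuplicated(rounded)) {
    stop("rounded cutoffs coincide (", paste(rounded, collapse = ", "),
         "); use a larger sample or a different step", call. = FALSE)
  }
  range_scheme(variable, unname(rounded))
}

## nearest multiple of step, halves away from zero (round() would go to even)
round_to_step <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

#' @rdname range_scheme
#' @export
alk_scheme <- function() {
  range_scheme("ALK", c(0.67, 0.75))
}

#' Assign values (or eyes) to ranges
#'
#' `assign_range()` maps numeric values to the factor of range labels under
#' the `(a, b]` convention (a boundary value falls in the lower range).
#' `partition_cohort()` appends `alk` and a `range` column for the scheme's
#' variable to a cohort.
#'
#' @param x numeric values.
#' @param scheme a [range_scheme()].
#' @return `assign_range()`: a factor with one level per range.
#' @export
assign_range <- function(x, scheme) {
  cut(x, breaks = c(-Inf, scheme$cutoffs, Inf), labels = scheme$labels,
      right = TRUE)
}

#' @rdname assign_range
#' @param cohort a validated cohort.
#' @export
partition_cohort <- function(cohort, scheme) {
  cohort <- tibble::as_tibble(cohort)
  cohort$alk <- cohort$al_mm / cohort$k_d
  var_col <- switch(scheme$variable, K = cohort$k_d, AL = cohort$al_mm,
                    ALK = cohort$alk)
  cohort$range <- assign_range(var_col, scheme)
  cohort
}

#' Per-range accuracy battery and paired tests
#'
#' Partitions the cohort by a range scheme and, within every range, computes
#' the per-method accuracy battery ([summarize_errors()]), the Friedman test
#' with Bonferroni pairwise comparisons on absolute prediction errors, and
#' Cochran Q tests on the within-threshold indicators.  Ranges with fewer
#' than `min_n` eyes are summarized but their tests are skipped with a
#' warning.
#'
#' @param predictions long prediction table from [predict_refraction()]
#'   (complete: every eye under every method).
#' @param cohort the matching validated cohort (provides K, AL per eye).
#' @param scheme a [range_scheme()].
#' @param min_n minimum eyes per range for testing (default 5).
#' @param thresholds within-threshold levels, D.
#' @return an object of class `iol_range_comparison`: list with `scheme`,
#'   `summaries` (long tibble, range x method battery with a `best_medae`
#'   flag), `tests` (tibble of omnibus results per range), `pairwise`
#'   (tibble of adjusted pairwise comparisons).
#' @export
per_range_comparison <- function(predictions, cohort, scheme, min_n = 5,
                                 thresholds = c(0.5, 1)) {
  cohort <- partition_cohort(cohort, scheme)
  joined <- dplyr::left_join(tibble::as_tibble(predictions),
                             cohort[, c("eye_id", "range")], by = "eye_id")
  summaries <- summarize_errors(joined, by = c(range, method),
                                thresholds = thresholds)
  summaries <- dplyr::mutate(
    dplyr::group_by(summaries, .data$range),
    best_medae = .data$medae_d == min(.data$medae_d))
  summaries <- dplyr::ungroup(summaries)

  tests <- list(); pairwise <- list()
  for (rg in levels(cohort$range)) {
    sub <- joined[!is.na(joined$range) & joined$range == rg, ]
    n_eyes <- length(unique(sub$eye_id))
    if (n_eyes == 0) next
    if (n_eyes < min_n) {
      warning("range '", rg, "' has ", n_eyes, " eyes (< ", min_n,
              "); tests skipped", call. = FALSE)
      next
    }
    wide <- tidyr::pivot_wider(sub[, c("eye_id", "method", "pe")],
                               names_from = "method", values_from = "pe")
    mat <- abs(as.matrix(wide[, -1]))
    fr <- friedman_bonferroni(mat)
    tests[[length(tests) + 1]] <- tibble::tibble(
      range = rg, test = "friedman", statistic = fr$statistic, df = fr$df,
      p_value = fr$p_value)
    pairwise[[length(pairwise) + 1]] <- dplyr::mutate(fr$pairwise, range = rg,
                                                      test = "friedman")
    for (t in thresholds) {
      bin <- (mat <= t) * 1
      res <- tryCatch(cochran_q(bin), error = function(e) NULL)
      lbl <- paste0("cochran_q_", gsub("\\.", "_", formatC(t, format = "fg")))
      if (is.null(res)) {
        tests[[length(tests) + 1]] <- tibble::tibble(
          range = rg, test = lbl, statistic = NA_real_, df = ncol(mat) - 1,
          p_value = NA_real_)
      } else {
        tests[[length(tests) + 1]] <- tibble::tibble(
          range = rg, test = lbl, statistic = res$statistic, df = res$df,
          p_value = res$p_value)
        pairwise[[length(pairwise) + 1]] <- dplyr::mutate(
          dplyr::rename(res$pairwise, z = "q"), range = rg, test = lbl)
      }
    }
  }
  structure(list(scheme = scheme,
                 summaries = summaries,
                 tests = dplyr::bind_rows(tests),
                 pairwise = dplyr::bind_rows(pairwise)),
            class = "iol_range_comparison")
}

#' LOESS trend of prediction errors along a biometric variable
#'
#' Tricube-weighted local polynomial fit (via [stats::loess()]) of the
#' prediction errors against keratometry, axial length or AL/K, evaluated on
#' a 100-point grid over the observed range, one curve per method.
#'
#' @param predictions long prediction table from [predict_refraction()].
#' @param cohort matching validated cohort.
#' @param variable `"K"`, `"AL"` or `"ALK"`.
#' @param span LOESS span (default 0.75).
#' @param degree local polynomial degree (default 1).
#' @param n_grid evaluation grid size.
#' @return a tibble of class `iol_trend`: `variable`, `method`, `x`,
#'   `fitted`, with `span`/`degree` attributes.  Plot with [autoplot()].
#' @export
loess_trend <- function(predictions, cohort, variable = c("K", "AL", "ALK"),
                        span = 0.75, degree = 1, n_grid = 100) {
  variable <- match.arg(variable)
  cohort <- tibble::as_tibble(cohort)
  cohort$alk <- cohort$al_mm / cohort$k_d
  xcol <- switch(variable, K = "k_d", AL = "al_mm", ALK = "alk")
  joined <- dplyr::left_join(tibble::as_tibble(predictions),
                             cohort[, c("eye_id", xcol)], by = "eye_id")
  out <- list()
  for (m in unique(joined$method)) {
    sub <- joined[joined$method == m, ]
    if (nrow(sub) < 10) stop("need at least 10 eyes per method for a trend",
                             call. = FALSE)
    x <- sub[[xcol]]
    grid <- seq(min(x), max(x), length.out = n_grid)
    fit <- tryCatch(
      stats::loess(pe ~ x, data = data.frame(x = x, pe = sub$pe),
                   span = span, degree = degree,
                   control = stats::loess.control(surface = "direct")),
      error = function(e) stop("LOESS failed (span too small?): ",
                               conditionMessage(e), call. = FALSE))
    out[[length(out) + 1]] <- tibble::tibble(
      variable = variable, method = m, x = grid,
      fitted = stats::predict(fit, newdata = data.frame(x = grid)))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "span") <- span
  attr(res, "degree") <- degree
  class(res) <- c("iol_trend", class(res))
  res
}
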