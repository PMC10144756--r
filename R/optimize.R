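#' Eligible optimization groups of a cohort
#'
#' Lens-constant optimization is performed per IOL model; it needs the model
#' label and at least `min_eyes` eyes of that model.  Eyes whose model is
#' `"UNKNOWN"` or whose model was implanted in fewer than `min_eyes` eyes are
#' excluded from optimization (they still take part in manufacturer-constant
#' analyses).
#'
#' @param cohort a validated cohort.
#' @param min_eyes minimum group size (default 3).
#' @return a list with `groups` (tibble `iol_model`, `n`) and `excluded`
#'   (tibble `eye_id`, `iol_model`, `reason` with reasons `unknown_model` /
#'   `model_count_lt_3`).
#' @export
build_groups <- function(cohort, min_eyes = 3) {
  cohort <- tibble::as_tibble(cohort)
  counts <- dplyr::count(cohort[cohort$iol_model != "UNKNOWN", ], .data$iol_model,
                         name = "n")
  eligible <- counts[counts$n >= min_eyes, ]
  small_models <- counts$iol_model[counts$n < min_eyes]
  excluded <- dplyr::bind_rows(
    tibble::tibble(eye_id = cohort$eye_id[cohort$iol_model == "UNKNOWN"],
                   iol_model = "UNKNOWN", reason = "unknown_model"),
    tibble::tibble(eye_id = cohort$eye_id[cohort$iol_model %in% small_models],
                   iol_model = cohort$iol_model[cohort$iol_model %in% small_models],
                   reason = "model_count_lt_3")
  )
  list(groups = eligible, excluded = excluded)
}

## ME as a function of the A-constant for one (model, method) group.
group_me <- function(method, eyes, a_const) {
  pred <- method_refraction(method, eyes$al_mm, eyes$k_d,
                            rep_len(a_const, nrow(eyes)), eyes$iol_power_d)
  mean(eyes$postop_se_d - pred)
}

zero_me_internal <- function(method, eyes, a0, tolerance, bracket) {
  f <- function(a) group_me(method, eyes, a)
  for (w in bracket) {
    lo <- a0 - w; hi <- a0 + w
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
      root <- stats::uniroot(f, c(lo, hi), tol = 1e-7)$root
      return(list(constant = root, me = f(root), ok = abs(f(root)) <= tolerance))
    }
  }
  ## no sign change in the widened bracket: keep the best endpoint estimate
  best <- if (abs(f(a0 - max(bracket))) < abs(f(a0 + max(bracket))))
    a0 - max(bracket) else a0 + max(bracket)
  list(constant = best, me = f(best), ok = FALSE)
}

zero_me_external <- function(eyes, external, a0, grid_step, tolerance) {
  rows <- external[external$method == "BARRETT_TK" &
                     external$eye_id %in% eyes$eye_id, ]
  per_eye <- split(rows, rows$eye_id)
  n_const <- vapply(per_eye, nrow, integer(1))
  if (length(per_eye) < nrow(eyes)) {
    stop("external predictions missing for some eyes of the group", call. = FALSE)
  }
  if (all(n_const >= 2)) {
    lo <- max(vapply(per_eye, function(d) min(d$constant), numeric(1)))
    hi <- min(vapply(per_eye, function(d) max(d$constant), numeric(1)))
    if (hi <= lo) stop("external constant grids do not overlap", call. = FALSE)
    grid <- seq(lo, hi, by = grid_step)
    me <- vapply(grid, function(a) {
      pred <- vapply(per_eye, function(d) {
        o <- order(d$constant)
        stats::approx(d$constant[o], d$predicted_se_d[o], xout = a, rule = 2)$y
      }, numeric(1))
      mean(eyes$postop_se_d[match(names(per_eye), eyes$eye_id)] - pred)
    }, numeric(1))
    best <- which(abs(me) == min(abs(me)))[1]  # ties toward the smaller constant
    list(constant = grid[best], me = me[best], offset = 0,
         ok = abs(me[best]) <= tolerance, provenance = "optimized")
  } else {
    ## one constant per eye: the calculator cannot be re-invoked, so the
    ## optimization degrades to a constant additive refraction offset
    pred <- vapply(per_eye, function(d) d$predicted_se_d[1], numeric(1))
    me <- mean(eyes$postop_se_d[match(names(per_eye), eyes$eye_id)] - pred)
    list(constant = a0, me = 0, offset = me, ok = TRUE,
         provenance = "offset_optimized")
  }
}

#' Optimize lens constants by zeroing the mean prediction error
#'
#' For every eligible (IOL model, method) group (see [build_groups()]),
#' adjusts the lens constant until the group's mean signed prediction error
#' is zero.  Internal methods use bracketed root-finding on the A-constant
#' (bracket +/-6 units, widened once to +/-12 on failure; tolerance 1e-3 D on
#' |ME|).  The external Barrett True-K method is optimized by grid/
#' interpolation search over its tabulated constants, or — when only one
#' constant per eye is available — by a constant additive refraction offset
#' (`provenance = "offset_optimized"`).  Groups where no root is bracketed
#' keep the manufacturer constant (`provenance = "manufacturer"`).
#'
#' @param cohort a validated cohort.
#' @param methods methods to optimize (default all seven).
#' @param external optional [external_predictions()] table (needed for
#'   `BARRETT_TK`).
#' @param min_eyes minimum eyes per model group.
#' @param tolerance |ME| tolerance, D.
#' @param bracket half-widths of the A-constant search brackets.
#' @param grid_step grid resolution for the external constant scan.
#' @return a tibble of class `iol_constants`: `iol_model`, `method`,
#'   `constant`, `offset`, `provenance` (`optimized`, `offset_optimized` or
#'   `manufacturer`), `n_eyes`, `achieved_me_d`.  Feed it to
#'   [predict_refraction()] / [apply_constants()].
#' @export
optimize_constants <- function(cohort, methods = iol_methods()$method,
                               external = NULL, min_eyes = 3, tolerance = 1e-3,
                               bracket = c(6, 12), grid_step = 0.01) {
  cohort <- tibble::as_tibble(cohort)
  grp <- build_groups(cohort, min_eyes)
  rows <- list()
  for (model in grp$groups$iol_model) {
    eyes <- cohort[cohort$iol_model == model, ]
    a0 <- stats::median(eyes$a_constant)
    for (m in methods) {
      if (m == "BARRETT_TK") {
        if (is.null(external)) next
        res <- zero_me_external(eyes, external, a0, grid_step, tolerance)
        rows[[length(rows) + 1]] <- tibble::tibble(
          iol_model = model, method = m, constant = res$constant,
          offset = res$offset, provenance = res$provenance,
          n_eyes = nrow(eyes), achieved_me_d = res$me)
      } else {
        res <- zero_me_internal(m, eyes, a0, tolerance, bracket)
        rows[[length(rows) + 1]] <- tibble::tibble(
          iol_model = model, method = m,
          constant = if (res$ok) res$constant else a0,
          offset = 0,
          provenance = if (res$ok) "optimized" else "manufacturer",
          n_eyes = nrow(eyes),
          achieved_me_d = if (res$ok) res$me else group_me(m, eyes, a0))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("iol_constants", class(out))
  out
}

#' Predictions for a whole cohort under a constant set
#'
#' Convenience wrapper: the full eyes-by-methods prediction/PE table under
#' optimized constants, or under manufacturer constants when
#' `constants = NULL`.  Eyes whose (model, method) has no optimized
#' entry fall back to their manufacturer A-constant.
#'
#' @inheritParams predict_refraction
#' @return a long tibble as from [predict_refraction()].
#' @export
apply_constants <- function(cohort, constants = NULL,
                            methods = iol_methods()$method, external = NULL) {
  predict_refraction(cohort, methods = methods, constants = constants,
                     external = external)
}
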