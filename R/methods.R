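#' No-history IOL power calculation methods
#'
#' The seven no-history methods evaluated by the package, with their fixed
#' base-formula pairings: ALMA, Ferrara, Kim and Latkany ride on SRK/T, Jin on
#' Holladay 1 (aiming at -0.75 D), Shammas on the Shammas-PL formula, and
#' Barrett True-K is an external passthrough (the formula is unpublished; its
#' predictions must be supplied as a table, see [external_predictions()]).
#'
#' @return a tibble with columns `method`, `base_formula`, `native_target_d`.
#' @export
iol_methods <- function() {
  tibble::tibble(
    method = c("ALMA", "BARRETT_TK", "FERRARA", "JIN", "KIM", "LATKANY", "SHAMMAS"),
    base_formula = c("SRKT", "EXTERNAL", "SRKT", "HOLLADAY1", "SRKT", "SRKT", "SHAMMAS_PL"),
    native_target_d = c(0, 0, 0, -0.75, 0, 0, 0)
  )
}

internal_methods <- function() {
  setdiff(iol_methods()$method, "BARRETT_TK")
}

## Coefficient registry for the no-history corrections.  Each entry is the
## regression the method is known for in the comparative post-refractive
## literature; they are locked by golden tests so accidental edits surface.
.corrections <- list(
  shammas = c(slope = 1.14, intercept = -6.8),    # clinically derived K
  kim     = c(slope = 1.114, intercept = -6.10),  # true-net-power style K
  jin     = c(slope = 1.114, intercept = -6.06),  # corrective K, Holladay 1
  ferrara = c(a2 = -0.0006, a1 = 0.0213, a0 = 1.1572), # variable index n(AL)
  alma    = c(slope = 0.0276, intercept = 0.3635),     # radius factor in AL
  latkany = c(power_offset = -0.21)               # flat-K power regression, no-history limit
)

#' Shammas clinically derived keratometry correction
#'
#' `Kc = 1.14 K - 6.8`.  For post-myopic-LRS corneas (K below the fixed point
#' at 6.8 / 0.14 = 48.57 D) the correction lowers the measured keratometry,
#' compensating the steep-measurement bias of standard keratometry after
#' myopic ablation.
#'
#' @param k measured mean keratometry, D.
#' @return corrected keratometry, D.
#' @examples
#' shammas_cd_correct_k(38) # 36.52
#' @export
shammas_cd_correct_k <- function(k) {
  .corrections$shammas[["slope"]] * k + .corrections$shammas[["intercept"]]
}

ferrara_index <- function(al) {
  co <- .corrections$ferrara
  co[["a2"]] * al^2 + co[["a1"]] * al + co[["a0"]]
}

#' Apply a no-history correction to an eye's biometry
#'
#' Returns the modified inputs a method feeds to its base formula: a corrected
#' keratometry (Shammas, Kim, Jin, Ferrara's axial-length-dependent variable
#' keratometric index, ALMA's axial-length radius regression) and/or an IOL
#' power offset (Latkany's flat-K regression in its no-history form).  Each
#' correction is applied exactly once by the prediction engine.
#'
#' @param method one of the internal methods of [iol_methods()] (not
#'   `"BARRETT_TK"`, which has no published internals).
#' @param al axial length, mm.
#' @param k measured mean keratometry, D.
#' @return a list with elements `al`, `k` (modified inputs) and
#'   `power_offset` (D, added to the base-formula power; 0 for K-based methods).
#' @export
apply_correction <- function(method, al, k) {
  switch(method,
    SHAMMAS = list(al = al, k = shammas_cd_correct_k(k), power_offset = 0),
    KIM = list(al = al,
               k = .corrections$kim[["slope"]] * k + .corrections$kim[["intercept"]],
               power_offset = 0),
    JIN = list(al = al,
               k = .corrections$jin[["slope"]] * k + .corrections$jin[["intercept"]],
               power_offset = 0),
    FERRARA = list(al = al, k = k * (ferrara_index(al) - 1) / 0.3375, power_offset = 0),
    ALMA = list(al = al,
                k = k / (.corrections$alma[["slope"]] * al + .corrections$alma[["intercept"]]),
                power_offset = 0),
    LATKANY = list(al = al, k = k,
                   power_offset = .corrections$latkany[["power_offset"]]),
    stop("unknown method: ", method, call. = FALSE)
  )
}

## Predicted spectacle-plane SE for one internal method at the implanted power.
## `a_const` is always on the A-constant scale; conversion to the base
## formula's native constant happens here.
method_refraction <- function(method, al, k, a_const, p_iol) {
  cx <- apply_correction(method, al, k)
  base <- iol_methods()$base_formula[iol_methods()$method == method]
  ## a power offset d means: the method's recommended power is base + d, so at
  ## an implanted power p the method's predicted refraction is base formula's
  ## refraction at p - d.
  p_base <- p_iol - cx$power_offset
  switch(base,
    SRKT = srkt_refraction(cx$al, cx$k, convert_constant(a_const, "srkt_acd"), p_base),
    HOLLADAY1 = holladay1_refraction(cx$al, cx$k,
                                     convert_constant(a_const, "holladay_sf"), p_base),
    SHAMMAS_PL = shammas_pl_refraction(cx$al, cx$k,
                                       convert_constant(a_const, "shammas_pacd"), p_base),
    stop("method has no internal base formula: ", method, call. = FALSE)
  )
}

method_power_one <- function(method, al, k, a_const, target) {
  cx <- apply_correction(method, al, k)
  base <- iol_methods()$base_formula[iol_methods()$method == method]
  p <- switch(base,
    SRKT = srkt_power(cx$al, cx$k, convert_constant(a_const, "srkt_acd"), target),
    HOLLADAY1 = holladay1_power(cx$al, cx$k,
                                convert_constant(a_const, "holladay_sf"), target),
    SHAMMAS_PL = shammas_pl_power(cx$al, cx$k,
                                  convert_constant(a_const, "shammas_pacd"), target),
    stop("method has no internal base formula: ", method, call. = FALSE)
  )
  p + cx$power_offset
}

#' IOL power for a target refraction under a no-history method
#'
#' Inverts the method's prediction chain: returns the IOL power `p` such that
#' the predicted spectacle-plane refraction at `p` equals `target`.  The base
#' vergence formulas are linear in the IOL power, so the closed form is exact;
#' `engine = "root"` solves the same equation by bracketed root-finding
#' (a self-consistency path used in validation).
#'
#' @inheritParams apply_correction
#' @param a_const A-constant.
#' @param target desired postoperative spherical equivalent, D.
#' @param engine `"closed_form"` (default) or `"root"`.
#' @return IOL power, D (vectorized over eyes).
#' @export
emmetropic_power <- function(method, al, k, a_const, target = 0,
                             engine = c("closed_form", "root")) {
  engine <- match.arg(engine)
  if (!method %in% internal_methods()) {
    stop("emmetropic_power requires an internal method, not ", method, call. = FALSE)
  }
  if (engine == "closed_form") {
    return(method_power_one(method, al, k, a_const, target))
  }
  n <- max(length(al), length(k), length(a_const), length(target))
  al <- rep_len(al, n); k <- rep_len(k, n)
  a_const <- rep_len(a_const, n); target <- rep_len(target, n)
  vapply(seq_len(n), function(i) {
    f <- function(p) method_refraction(method, al[i], k[i], a_const[i], p) - target[i]
    lo <- f(-10); hi <- f(60)
    if (sign(lo) == sign(hi)) {
      stop("no sign change in power bracket [-10, 60] D", call. = FALSE)
    }
    stats::uniroot(f, c(-10, 60), tol = 1e-9)$root
  }, numeric(1))
}

#' Register external (Barrett True-K) predictions
#'
#' Wraps a long table of externally computed predicted refractions (columns
#' `eye_id`, `method`, `constant`, `predicted_se_d`) so [predict_refraction()]
#' can serve the Barrett True-K method, whose formula is unpublished.  A table
#' may carry several constants per eye to support lens-constant optimization
#' by interpolation.
#'
#' @param data a data frame or a CSV path with the four columns above.
#' @return a tibble of class `external_predictions`.
#' @export
external_predictions <- function(data) {
  if (is.character(data) && length(data) == 1) {
    data <- readr::read_csv(data, col_types = readr::cols(
      eye_id = readr::col_character(), method = readr::col_character(),
      constant = readr::col_double(), predicted_se_d = readr::col_double()
    ), progress = FALSE)
  }
  need <- c("eye_id", "method", "constant", "predicted_se_d")
  if (!all(need %in% names(data))) {
    stop("external predictions need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)[, need]
  out$eye_id <- as.character(out$eye_id)
  class(out) <- c("external_predictions", class(out))
  out
}

external_lookup <- function(external, eye_id, method, constant, offset = 0) {
  if (is.null(external)) {
    stop("method ", method, " requires registered external predictions (eye ",
         eye_id, ")", call. = FALSE)
  }
  rows <- external[external$eye_id == eye_id & external$method == method, ]
  if (nrow(rows) == 0) {
    stop("no external prediction registered for eye ", eye_id,
         " under method ", method, call. = FALSE)
  }
  hit <- which(abs(rows$constant - constant) < 1e-6)
  if (length(hit) == 0) {
    if (nrow(rows) >= 2) {
      ## interpolate between tabulated constants
      o <- order(rows$constant)
      return(stats::approx(rows$constant[o], rows$predicted_se_d[o],
                           xout = constant, rule = 2)$y + offset)
    }
    stop("no external prediction for eye ", eye_id, " at constant ",
         constant, call. = FALSE)
  }
  rows$predicted_se_d[hit[1]] + offset
}

#' Back-calculate predicted refractions and prediction errors
#'
#' For every (eye, method) pair, computes the refraction the method predicts
#' for the implanted IOL power, and the refractive prediction error
#' `pe = postop_se_d - se_pred` (positive = hyperopic surprise).  Constants
#' default to each eye's manufacturer A-constant; a constants table from
#' [optimize_constants()] (or any tibble with `iol_model`, `method`,
#' `constant`, optionally `offset`) overrides them per (IOL model, method).
#'
#' @param cohort a validated cohort ([validate_cohort()]).
#' @param methods character vector of methods (default all seven).
#' @param constants optional constants table; see [optimize_constants()].
#' @param external optional [external_predictions()] table (required for
#'   `BARRETT_TK`).
#' @return a long tibble: `eye_id`, `method`, `constant`, `se_pred`, `pe`.
#' @export
predict_refraction <- function(cohort, methods = iol_methods()$method,
                               constants = NULL, external = NULL) {
  bad <- setdiff(methods, iol_methods()$method)
  if (length(bad) > 0) stop("unknown method(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  cohort <- tibble::as_tibble(cohort)
  cells <- tidyr::expand_grid(eye_id = cohort$eye_id, method = methods)
  cells <- dplyr::left_join(cells, cohort, by = "eye_id")
  cells$constant <- cells$a_constant
  cells$offset <- 0
  if (!is.null(constants)) {
    lut <- tibble::as_tibble(constants)
    if (!"offset" %in% names(lut)) lut$offset <- 0
    lut <- lut[, c("iol_model", "method", "constant", "offset")]
    names(lut) <- c("iol_model", "method", "constant_opt", "offset_opt")
    cells <- dplyr::left_join(cells, lut, by = c("iol_model", "method"))
    cells$constant <- dplyr::coalesce(cells$constant_opt, cells$constant)
    cells$offset <- dplyr::coalesce(cells$offset_opt, cells$offset)
  }
  se_pred <- numeric(nrow(cells))
  for (m in unique(cells$method)) {
    idx <- cells$method == m
    if (m == "BARRETT_TK") {
      se_pred[idx] <- purrr::pmap_dbl(
        list(cells$eye_id[idx], cells$constant[idx], cells$offset[idx]),
        function(id, cst, off) external_lookup(external, id, "BARRETT_TK", cst, off)
      )
    } else {
      se_pred[idx] <- method_refraction(m, cells$al_mm[idx], cells$k_d[idx],
                                        cells$constant[idx], cells$iol_power_d[idx]) +
        cells$offset[idx]
    }
  }
  tibble::tibble(
    eye_id = cells$eye_id,
    method = cells$method,
    constant = cells$constant,
    se_pred = se_pred,
    pe = prediction_error(cells$postop_se_d, se_pred)
  )
}
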