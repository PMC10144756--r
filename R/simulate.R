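#' Default synthetic IOL catalog
#'
#' A small market of IOL models for the synthetic cohort generator: labeled
#' manufacturer A-constant, the "true" A-constant that actually generated
#' each eye's outcome (post-LRS constants typically drift from the label,
#' which gives the zeroing procedure something to recover), and market
#' shares.  The two rare models create sub-3-eye groups at typical cohort
#' sizes, exercising the optimization-eligibility split.
#'
#' @return tibble `model`, `a_constant`, `a_true`, `share`.
#' @export
default_iol_catalog <- function() {
  tibble::tibble(
    model = c("SYN-A1", "SYN-B2", "SYN-C3", "SYN-D4", "SYN-R1", "SYN-R2"),
    a_constant = c(118.4, 119.0, 118.9, 119.3, 118.0, 118.7),
    a_true = c(118.4, 119.0, 118.9, 119.3, 118.0, 118.7) +
      c(0.6, -0.4, 0.8, 0.3, 0.5, -0.2),
    share = c(0.30, 0.28, 0.22, 0.16, 0.02, 0.02)
  )
}

## (AL, K) pairs from a truncated bivariate normal, by rejection.
sample_biometry <- function(n, al_mean, al_sd, al_range, k_mean, k_sd, k_range,
                            al_k_cor) {
  if (al_mean < al_range[1] - 5 * al_sd || al_mean > al_range[2] + 5 * al_sd ||
      k_mean < k_range[1] - 5 * k_sd || k_mean > k_range[2] + 5 * k_sd) {
    stop("infeasible truncation: mean outside bounds by > 5 sd", call. = FALSE)
  }
  sigma <- matrix(c(al_sd^2, al_k_cor * al_sd * k_sd,
                    al_k_cor * al_sd * k_sd, k_sd^2), 2)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    draw <- MASS::mvrnorm(max(2 * (n - nrow(out)), 10), c(al_mean, k_mean), sigma)
    keep <- draw[, 1] >= al_range[1] & draw[, 1] <= al_range[2] &
      draw[, 2] >= k_range[1] & draw[, 2] <= k_range[2]
    out <- rbind(out, draw[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate a post-myopic-LRS pseudophakic cohort
#'
#' Draws biometry (AL, K) from a truncated bivariate normal matching the
#' moments of a typical post-myopic-LRS cataract cohort (long eyes, flat
#' corneas, negative AL-K correlation), assigns IOL models by market share,
#' implants the power that the ground-truth method would pick for a slightly
#' myopic target (quantized to the manufacturing power step), and sets the
#' postoperative refraction to the truth method's own prediction at that
#' power (computed with the model's *true* constant) plus Gaussian noise.
#' A fraction of records loses its model label (`"UNKNOWN"`), mirroring
#' real-world chart review.
#'
#' The ground-truth sidecar (attribute `"truth"`, a tibble `eye_id`,
#' `truth_method`, `true_model`, `a_true`, `target`, `se_true`) is
#' sufficient to replay all noiseless refractions exactly.
#'
#' @param n_eyes number of eyes.
#' @param seed RNG seed (mandatory: the generator is deterministic given it).
#' @param al_mean,al_sd,al_range axial-length distribution, mm.
#' @param k_mean,k_sd,k_range keratometry distribution, D.
#' @param al_k_cor AL-K correlation.
#' @param catalog IOL catalog (see [default_iol_catalog()]).
#' @param truth_method the generating no-history method, or a function
#'   `(al, k) -> method` for range-dependent truth.
#' @param noise_sd postoperative refraction noise SD, D.
#' @param unknown_fraction fraction of records with `iol_model = "UNKNOWN"`.
#' @param power_step IOL manufacturing step, D.
#' @param targets pool of surgeon target refractions, D.
#' @return a validated `iol_cohort` tibble with a `"truth"` attribute
#'   (retrieve with [truth_sidecar()]).
#' @export
simulate_cohort <- function(n_eyes = 132, seed,
                            al_mean = 27.65, al_sd = 2.11,
                            al_range = c(23.72, 34.20),
                            k_mean = 38.08, k_sd = 2.69,
                            k_range = c(31.56, 43.81),
                            al_k_cor = -0.5,
                            catalog = default_iol_catalog(),
                            truth_method = "SHAMMAS",
                            noise_sd = 0.4,
                            unknown_fraction = 25 / 132,
                            power_step = 0.5,
                            targets = c(0, -0.25, -0.5)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(abs(sum(catalog$share) - 1) < 1e-8)
  withr::local_seed(seed)
  if (n_eyes == 0) {
    empty <- tibble::tibble(
      eye_id = character(0), al_mm = numeric(0), k_d = numeric(0),
      a_constant = numeric(0), iol_model = character(0),
      iol_power_d = numeric(0), postop_se_d = numeric(0), source = character(0))
    out <- validate_cohort(empty)
    attr(out, "truth") <- tibble::tibble()
    return(out)
  }
  bio <- sample_biometry(n_eyes, al_mean, al_sd, al_range, k_mean, k_sd,
                         k_range, al_k_cor)
  al <- bio[, 1]; k <- bio[, 2]
  idx <- sample.int(nrow(catalog), n_eyes, replace = TRUE, prob = catalog$share)
  model <- catalog$model[idx]
  a_label <- catalog$a_constant[idx]
  a_true <- catalog$a_true[idx]
  tm <- if (is.function(truth_method)) {
    vapply(seq_len(n_eyes), function(i) truth_method(al[i], k[i]), character(1))
  } else rep_len(truth_method, n_eyes)
  target <- sample(targets, n_eyes, replace = TRUE)
  p_exact <- vapply(seq_len(n_eyes), function(i)
    emmetropic_power(tm[i], al[i], k[i], a_true[i], target[i]), numeric(1))
  p_iol <- round_to_step(p_exact, power_step)
  se_true <- vapply(seq_len(n_eyes), function(i)
    method_refraction(tm[i], al[i], k[i], a_true[i], p_iol[i]), numeric(1))
  se_post <- se_true + stats::rnorm(n_eyes, 0, noise_sd)

  n_unknown <- round(unknown_fraction * n_eyes)
  unknown <- sample.int(n_eyes, n_unknown)
  labeled <- model
  labeled[unknown] <- "UNKNOWN"

  eye_id <- sprintf("eye%04d", seq_len(n_eyes))
  cohort <- tibble::tibble(
    eye_id = eye_id, al_mm = al, k_d = k, a_constant = a_label,
    iol_model = labeled, iol_power_d = p_iol, postop_se_d = se_post,
    source = "clinic"
  )
  out <- validate_cohort(cohort)
  attr(out, "truth") <- tibble::tibble(
    eye_id = eye_id, truth_method = tm, true_model = model,
    a_true = a_true, target = target, se_true = se_true
  )
  out
}

#' @rdname simulate_cohort
#' @param cohort a simulated cohort.
#' @export
truth_sidecar <- function(cohort) {
  attr(cohort, "truth")
}

#' Simulate a cohort whose best method differs by biometric range
#'
#' Stratified variant of [simulate_cohort()]: eyes are drawn until every
#' range of `scheme` holds exactly `n_per_range` eyes, and each eye's
#' generating method is the one its range prescribes.  With small refraction
#' noise, the per-range accuracy comparison must identify the generating
#' method (lowest MedAE) in every range — the recovery test for the
#' range-based selection logic.
#'
#' @inheritParams simulate_cohort
#' @param scheme a [range_scheme()] over `"K"`, `"AL"` or `"ALK"`.
#' @param methods_by_range character vector, one generating method per range
#'   of `scheme`.
#' @param n_per_range eyes per range.
#' @return as [simulate_cohort()].
#' @export
truth_mixture_cohort <- function(scheme, methods_by_range, n_per_range = 60,
                                 seed, noise_sd = 0.05,
                                 al_mean = 27.65, al_sd = 2.11,
                                 al_range = c(23.72, 34.20),
                                 k_mean = 38.08, k_sd = 2.69,
                                 k_range = c(31.56, 43.81),
                                 al_k_cor = -0.5,
                                 catalog = default_iol_catalog(),
                                 unknown_fraction = 0,
                                 power_step = 0.5,
                                 targets = c(0, -0.25, -0.5)) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_ranges <- length(scheme$labels)
  if (length(methods_by_range) != n_ranges) {
    stop("methods_by_range must name one method per range", call. = FALSE)
  }
  withr::local_seed(seed)
  ## fill per-range quotas by rejection from the full truncated distribution
  quota <- rep(n_per_range, n_ranges)
  al <- numeric(0); k <- numeric(0); rg <- integer(0)
  guard <- 0
  while (any(quota > 0) && guard < 2000) {
    guard <- guard + 1
    bio <- sample_biometry(4 * n_per_range, al_mean, al_sd, al_range,
                           k_mean, k_sd, k_range, al_k_cor)
    v <- switch(scheme$variable, K = bio[, 2], AL = bio[, 1],
                ALK = bio[, 1] / bio[, 2])
    r <- as.integer(assign_range(v, scheme))
    for (j in seq_len(nrow(bio))) {
      if (quota[r[j]] > 0) {
        al <- c(al, bio[j, 1]); k <- c(k, bio[j, 2]); rg <- c(rg, r[j])
        quota[r[j]] <- quota[r[j]] - 1
      }
    }
  }
  if (any(quota > 0)) {
    stop("could not fill all ranges from the biometry distribution", call. = FALSE)
  }
  n <- length(al)
  idx <- sample.int(nrow(catalog), n, replace = TRUE, prob = catalog$share)
  tm <- methods_by_range[rg]
  a_label <- catalog$a_constant[idx]
  target <- sample(targets, n, replace = TRUE)
  p_exact <- vapply(seq_len(n), function(i)
    emmetropic_power(tm[i], al[i], k[i], a_label[i], target[i]), numeric(1))
  p_iol <- round_to_step(p_exact, power_step)
  se_true <- vapply(seq_len(n), function(i)
    method_refraction(tm[i], al[i], k[i], a_label[i], p_iol[i]), numeric(1))
  se_post <- se_true + stats::rnorm(n, 0, noise_sd)
  n_unknown <- round(unknown_fraction * n)
  labeled <- catalog$model[idx]
  if (n_unknown > 0) labeled[sample.int(n, n_unknown)] <- "UNKNOWN"
  eye_id <- sprintf("eye%04d", seq_len(n))
  out <- validate_cohort(tibble::tibble(
    eye_id = eye_id, al_mm = al, k_d = k, a_constant = a_label,
    iol_model = labeled, iol_power_d = p_iol, postop_se_d = se_post,
    source = "clinic"
  ))
  attr(out, "truth") <- tibble::tibble(
    eye_id = eye_id, truth_method = tm, true_model = catalog$model[idx],
    a_true = a_label, target = target, se_true = se_true
  )
  out
}
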