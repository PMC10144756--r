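# Fixtures and independent oracles shared across test files.

make_cohort <- function(al, k, a = 118.4, model = "MX", p = 18, se = -0.5,
                        source = "clinic", id = NULL) {
  n <- max(length(al), length(k))
  validate_cohort(tibble::tibble(
    eye_id = id %||% sprintf("e%03d", seq_len(n)),
    al_mm = rep_len(al, n), k_d = rep_len(k, n),
    a_constant = rep_len(a, n), iol_model = rep_len(model, n),
    iol_power_d = rep_len(p, n), postop_se_d = rep_len(se, n),
    source = rep_len(source, n)
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Grid of plausible post-myopic-LRS eyes used by several property tests.
eye_grid <- function(n_al = 20, n_k = 10) {
  expand.grid(al = seq(23.8, 34, length.out = n_al),
              k = seq(31.6, 43.8, length.out = n_k))
}

# Independent step-by-step transcription of the SRK/T chain, written as a
# literal sequence of published steps (deliberately not calling the package
# internals) to lock the implementation against transcription slips.
oracle_srkt_ref <- function(al, k, a_const, p) {
  acd <- 0.62467 * a_const - 68.747
  r <- 337.5 / k
  lcor <- if (al <= 24.2) al else -3.446 + 1.715 * al - 0.0237 * al^2
  cw <- -5.41 + 0.58412 * lcor + 0.098 * k
  h <- r - sqrt(max(r^2 - cw^2 / 4, 0))
  elp <- h + acd - 3.336
  l <- al + 0.65696 - 0.02029 * al
  na <- 1.336; nc <- 0.333; v <- 12
  (1000 * na * (na * r - nc * l) - p * (l - elp) * (na * r - nc * elp)) /
    (na * (v * (na * r - nc * l) + l * r) -
       0.001 * p * (l - elp) * (v * (na * r - nc * elp) + elp * r))
}

oracle_holladay_ref <- function(al, k, a_const, p) {
  sf <- 0.5663 * a_const - 65.60
  r <- 337.5 / k
  ag <- min(12.5 * al / 23.45, 13.5)
  elp <- 0.56 + r - sqrt(max(r^2 - ag^2 / 4, 0)) + sf
  l <- al + 0.2
  na <- 1.336; nc <- 1 / 3; v <- 12
  (1000 * na * (na * r - nc * l) - p * (l - elp) * (na * r - nc * elp)) /
    (na * (v * (na * r - nc * l) + l * r) -
       0.001 * p * (l - elp) * (v * (na * r - nc * elp) + elp * r))
}

oracle_shammas_ref <- function(al, k, a_const, p) {
  pacd <- 0.5835 * a_const - 64.40
  kc <- 1.14 * k - 6.8
  l2 <- al - 0.1 * (al - 23)
  c2 <- pacd + 0.05
  w <- 1336 / (l2 - c2) - p
  rc <- 1336 / (1336 / w + c2) - kc / 1.0125
  rc / (1 + 0.012 * rc)
}

# Naive metric battery used as the brute-force oracle for summarize_errors().
oracle_battery <- function(pe) {
  ab <- sort(abs(pe))
  n <- length(pe)
  list(me = sum(pe) / n,
       medae = stats::median(ab),
       mae = sum(ab) / n,
       q = unname(stats::quantile(ab, c(.25, .75), type = 7)),
       within05 = sum(ab <= 0.5),
       within10 = sum(ab <= 1))
}

# Friedman chi-square computed directly from rank sums (no ties assumed).
oracle_friedman_chi2 <- function(mat) {
  rk <- t(apply(mat, 1, rank))
  n <- nrow(mat); k <- ncol(mat)
  12 / (n * k * (k + 1)) * sum(colSums(rk)^2) - 3 * n * (k + 1)
}
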