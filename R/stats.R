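#' One-sample t screening of the mean prediction error
#'
#' Two-sided one-sample t-test of the signed prediction errors against zero,
#' used to screen each method for residual systematic bias.
#'
#' @param pes numeric vector of signed prediction errors, D.
#' @return a one-row tibble: `estimate`, `statistic`, `df`, `p_value`.
#' @export
one_sample_t <- function(pes) {
  pes <- pes[!is.na(pes)]
  if (length(pes) < 2) stop("need at least two prediction errors", call. = FALSE)
  if (stats::sd(pes) == 0) stop("zero variance: t statistic undefined", call. = FALSE)
  fit <- stats::t.test(pes, mu = 0)
  tibble::tibble(estimate = unname(fit$estimate),
                 statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = fit$p.value)
}

complete_matrix <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix has missing cells; listwise completeness required",
                       call. = FALSE)
  if (ncol(mat) < 2 || nrow(mat) < 2) {
    stop("need at least 2 methods and 2 eyes", call. = FALSE)
  }
  if (is.null(colnames(mat))) colnames(mat) <- paste0("m", seq_len(ncol(mat)))
  mat
}

#' Friedman test with Bonferroni-corrected pairwise comparisons
#'
#' Omnibus Friedman rank test over an eyes-by-methods matrix of absolute
#' prediction errors (ties get average ranks), followed by pairwise
#' rank-sum z comparisons: `z = (Rbar_i - Rbar_j) / sqrt(k (k + 1) / (6 n))`,
#' two-sided normal p-values multiplied by the number of pairs
#' `k (k - 1) / 2` and capped at 1.
#'
#' @param mat numeric matrix or data frame, rows = eyes, columns = methods;
#'   no missing cells.
#' @return an object of class `iol_friedman`: a list with `statistic`, `df`,
#'   `p_value`, `mean_ranks`, and `pairwise` (tibble `method1`, `method2`,
#'   `z`, `p_raw`, `p_adj`).  [tidy()] returns the pairwise table, [glance()]
#'   the omnibus row.
#' @export
friedman_bonferroni <- function(mat) {
  mat <- complete_matrix(mat)
  fit <- stats::friedman.test(mat)
  ranks <- t(apply(mat, 1, rank))
  rbar <- colMeans(ranks)
  n <- nrow(mat); k <- ncol(mat)
  if (!is.finite(fit$statistic) && all(apply(mat, 1, function(r) length(unique(r)) == 1))) {
    ## every row fully tied (e.g. identical columns): no evidence of any
    ## difference; the tie-corrected statistic is 0/0, read as 0
    fit$statistic <- 0
    fit$p.value <- 1
  }
  pairs <- utils::combn(colnames(mat), 2)
  se <- sqrt(k * (k + 1) / (6 * n))
  z <- (rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  m <- k * (k - 1) / 2
  out <- list(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_ranks = rbar,
    pairwise = tibble::tibble(method1 = pairs[1, ], method2 = pairs[2, ],
                              z = unname(z), p_raw = unname(p_raw),
                              p_adj = pmin(1, unname(p_raw) * m))
  )
  class(out) <- "iol_friedman"
  out
}

cochran_q_statistic <- function(mat) {
  k <- ncol(mat)
  cj <- colSums(mat)
  ri <- rowSums(mat)
  den <- k * sum(ri) - sum(ri^2)
  if (den == 0) {
    ## every row constant across methods, i.e. identical columns: there are
    ## no discordant responses and hence no evidence of any difference
    return(0)
  }
  k * (k - 1) * sum((cj - mean(cj))^2) / den
}

#' Cochran Q test with Bonferroni-corrected pairwise comparisons
#'
#' Compares the proportions of successes (e.g. eyes within +/-0.50 D) across
#' paired binary columns.  `Q = k (k - 1) sum_j (C_j - Cbar)^2 /
#' (k sum_i R_i - sum_i R_i^2)`, referred to a chi-square with `k - 1`
#' degrees of freedom.  Pairwise comparisons are two-column Cochran Q tests
#' (identical to McNemar without continuity correction), Bonferroni-adjusted.
#'
#' @param mat 0/1 matrix or data frame, rows = eyes, columns = methods.
#' @return an object of class `iol_cochran`: `statistic`, `df`, `p_value`,
#'   `proportions`, `pairwise` (`method1`, `method2`, `q`, `p_raw`, `p_adj`).
#'   A matrix (or pair) with no discordant rows carries no evidence of a
#'   difference and is reported as Q = 0, p = 1.
#' @export
cochran_q <- function(mat) {
  mat <- complete_matrix(mat)
  if (!all(mat %in% c(0, 1))) stop("matrix entries must be binary", call. = FALSE)
  q <- cochran_q_statistic(mat)
  k <- ncol(mat)
  pairs <- utils::combn(colnames(mat), 2)
  m <- k * (k - 1) / 2
  pq <- apply(pairs, 2, function(pr) {
    sub <- mat[, pr, drop = FALSE]
    if (!any(rowSums(sub) == 1)) return(c(0, 1))  # no discordant pairs
    qs <- cochran_q_statistic(sub)
    c(qs, stats::pchisq(qs, 1, lower.tail = FALSE))
  })
  out <- list(
    statistic = q,
    df = k - 1,
    p_value = stats::pchisq(q, k - 1, lower.tail = FALSE),
    proportions = colMeans(mat),
    pairwise = tibble::tibble(method1 = pairs[1, ], method2 = pairs[2, ],
                              q = pq[1, ], p_raw = pq[2, ],
                              p_adj = pmin(1, pq[2, ] * m))
  )
  class(out) <- "iol_cochran"
  out
}

#' Normality screening of prediction errors
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with the
#' sample mean and standard deviation, with the exact small-sample p-value
#' (`method = "exact_ks"`, the default) or the Lilliefors correction for
#' estimated parameters (`method = "lilliefors"`).
#'
#' @param x numeric sample (n >= 4).
#' @param method `"exact_ks"` or `"lilliefors"`.
#' @return p-value.
#' @export
ks_normality <- function(x, method = c("exact_ks", "lilliefors")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 4) stop("need at least 4 observations", call. = FALSE)
  if (method == "exact_ks") {
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x), exact = TRUE)$p.value
    )
  } else {
    nortest::lillie.test(x)$p.value
  }
}

#' Cohen's f from partial eta squared
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param partial_eta2 partial eta squared, in `[0, 1)`.
#' @return Cohen's f.
#' @examples
#' cohen_f_from_eta2(0.206) # 0.509
#' @export
cohen_f_from_eta2 <- function(partial_eta2) {
  if (any(partial_eta2 < 0 | partial_eta2 >= 1)) {
    stop("partial eta squared must be in [0, 1)", call. = FALSE)
  }
  sqrt(partial_eta2 / (1 - partial_eta2))
}

#' Power and minimum sample size for a one-group repeated-measures design
#'
#' Noncentral-F power for the within factor of a one-group repeated-measures
#' ANOVA with `m` measurements, effect size Cohen's f, a Greenhouse-Geisser
#' nonsphericity correction `epsilon` applied to both degrees of freedom
#' (`df1 = (m - 1) epsilon`, `df2 = (N - 1) (m - 1) epsilon`), and a default
#' correlation among repeated measures `rho` entering the noncentrality
#' parameter as `lambda = N f^2 m / (1 + (m - 1) rho)`.
#' `rm_sample_size()` returns the smallest N whose achieved power reaches
#' `target_power`.
#'
#' @param n sample size (number of subjects).
#' @param f Cohen's f.
#' @param m number of repeated measurements.
#' @param epsilon nonsphericity correction, in `(0, 1]`.
#' @param rho correlation among repeated measures (default 0.5).
#' @param alpha significance level.
#' @return `rm_power()`: achieved power.  `rm_sample_size()`: smallest
#'   integer N with power `>= target_power`.
#' @examples
#' rm_sample_size(0.509, alpha = 0.05, target_power = 0.85,
#'                m = 7, epsilon = 0.357) # 27
#' @export
rm_power <- function(n, f, m, epsilon, rho = 0.5, alpha = 0.05) {
  stopifnot(epsilon > 0, epsilon <= 1, m >= 2, alpha > 0, alpha < 1)
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  lambda <- n * f^2 * m / (1 + (m - 1) * rho)
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' @rdname rm_power
#' @param target_power required power.
#' @param n_max search cap.
#' @export
rm_sample_size <- function(f, alpha = 0.05, target_power = 0.85, m = 7,
                           epsilon = 1, rho = 0.5, n_max = 1e5) {
  for (n in 2:n_max) {
    if (rm_power(n, f, m, epsilon, rho, alpha) >= target_power) return(n)
  }
  stop("target power unreachable below n_max = ", n_max, call. = FALSE)
}
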