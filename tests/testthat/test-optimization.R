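test_that("group building enforces the known-model and minimum-size rules", {
  co <- make_cohort(al = rep(27, 7), k = rep(38, 7),
                    model = c(rep("X", 5), rep("Y", 2)))
  g <- build_groups(co)
  expect_equal(g$groups$iol_model, "X")
  expect_equal(g$groups$n, 5)
  expect_equal(sum(g$excluded$reason == "model_count_lt_3"), 2)

  co2 <- make_cohort(al = rep(27, 3), k = rep(38, 3), model = "UNKNOWN")
  g2 <- build_groups(co2)
  expect_equal(nrow(g2$groups), 0)
  expect_equal(g2$excluded$reason, rep("unknown_model", 3))
})

test_that("a 132-eye cohort with 25 unknown and 17 sub-3 eyes leaves 90 optimizable", {
  # 90 eyes in models with n >= 3, 25 unknown-model eyes, 17 eyes in sub-3 models
  models <- c(rep("M1", 40), rep("M2", 30), rep("M3", 20), rep("UNKNOWN", 25),
              paste0("rare", c(rep(1:8, each = 2), 9)))
  co <- make_cohort(al = rep(27, 132), k = rep(38, 132), model = models)
  g <- build_groups(co)
  expect_equal(sum(g$groups$n), 90)
  expect_equal(sum(g$excluded$reason == "unknown_model"), 25)
  expect_equal(sum(g$excluded$reason == "model_count_lt_3"), 17)
})

test_that("zeroing recovers generating constants exactly when noise is zero", {
  for (m in c("SHAMMAS", "ALMA", "JIN")) {
    co <- simulate_cohort(40, seed = 70, noise_sd = 0, unknown_fraction = 0,
                          truth_method = m)
    cst <- optimize_constants(co, methods = m)
    truth <- dplyr::distinct(truth_sidecar(co), true_model, a_true)
    j <- dplyr::left_join(cst, truth, by = c(iol_model = "true_model"))
    expect_lt(max(abs(j$constant - j$a_true)), 1e-3)
    expect_lt(max(abs(j$achieved_me_d)), 1e-3)
    expect_true(all(j$provenance == "optimized"))
  }
})

test_that("optimized constants drive every group mean error to within 1e-3 D", {
  co <- simulate_cohort(90, seed = 21, noise_sd = 0.4, unknown_fraction = 0.1)
  methods <- c("ALMA", "SHAMMAS", "KIM", "JIN")
  cst <- optimize_constants(co, methods = methods)
  pred <- apply_constants(co, constants = cst, methods = methods)
  joined <- dplyr::left_join(pred,
                             tibble::as_tibble(co)[, c("eye_id", "iol_model")],
                             by = "eye_id")
  per_group <- dplyr::summarise(
    dplyr::group_by(joined, .data$iol_model, .data$method),
    me = mean(.data$pe), .groups = "drop")
  opt <- dplyr::semi_join(per_group, cst[cst$provenance == "optimized", ],
                          by = c("iol_model", "method"))
  expect_gt(nrow(opt), 0)
  expect_lt(max(abs(opt$me)), 1e-3)
})

test_that("a group already at zero mean error keeps its constant", {
  co <- simulate_cohort(30, seed = 33, noise_sd = 0, unknown_fraction = 0,
                        truth_method = "SHAMMAS",
                        catalog = dplyr::mutate(default_iol_catalog(),
                                                a_true = a_constant))
  cst <- optimize_constants(co, methods = "SHAMMAS")
  expect_lt(max(abs(cst$constant - co$a_constant[match(cst$iol_model, co$iol_model)])),
            1e-5)
})

test_that("zeroing removes the systematic offset to first order in the constant", {
  # small constant perturbation: the prediction is locally affine in the
  # constant, so the optimized PEs approach "PEs minus their group mean";
  # the residual is first-order in the constant shift (the vergence slope
  # d(pe)/d(constant) differs slightly from eye to eye)
  shift_dev <- function(delta, seed) {
    cat_small <- dplyr::mutate(default_iol_catalog(), a_true = a_constant + delta)
    co <- simulate_cohort(50, seed = seed, noise_sd = 0.02, unknown_fraction = 0,
                          truth_method = "KIM", catalog = cat_small)
    before <- predict_refraction(co, methods = "KIM")
    cst <- optimize_constants(co, methods = "KIM")
    after <- predict_refraction(co, methods = "KIM", constants = cst)
    j <- tibble::tibble(eye_id = before$eye_id, pe_b = before$pe,
                        pe_a = after$pe)
    j <- dplyr::left_join(j, tibble::as_tibble(co)[, c("eye_id", "iol_model")],
                          by = "eye_id")
    j <- dplyr::semi_join(j, cst[cst$provenance == "optimized", ],
                          by = "iol_model")
    j <- dplyr::ungroup(dplyr::mutate(dplyr::group_by(j, .data$iol_model),
                                      shifted = .data$pe_b - mean(.data$pe_b)))
    list(dev = max(abs(j$shifted - j$pe_a)),
         me_b = abs(mean(j$pe_b)), me_a = abs(mean(j$pe_a)))
  }
  small <- shift_dev(0.05, 13)
  expect_lt(small$dev, 0.02)
  # |ME| never deteriorates under zeroing
  expect_lte(small$me_a, small$me_b + 1e-9)
  # the residual shrinks with the perturbation (first-order behaviour)
  tiny <- shift_dev(0.005, 13)
  expect_lt(tiny$dev, small$dev / 2)
})

test_that("optimization is deterministic", {
  co <- simulate_cohort(40, seed = 55)
  c1 <- optimize_constants(co, methods = c("ALMA", "SHAMMAS"))
  c2 <- optimize_constants(co, methods = c("ALMA", "SHAMMAS"))
  expect_identical(c1$constant, c2$constant)
})

test_that("external Barrett tables optimize by interpolation over constants", {
  co <- make_cohort(al = c(26, 27, 28, 29), k = c(39, 38, 37, 36),
                    model = "BX", a = 119, p = 19,
                    se = c(-0.2, -0.4, -0.1, -0.3))
  # linear-in-constant external predictions: pred = -1 + 0.4 * (c - 118)
  grid <- seq(117, 121, by = 0.5)
  ext <- external_predictions(
    tidyr::expand_grid(eye_id = co$eye_id, constant = grid) |>
      dplyr::mutate(method = "BARRETT_TK",
                    predicted_se_d = -1 + 0.4 * (constant - 118)))
  cst <- optimize_constants(co, methods = "BARRETT_TK", external = ext)
  # ME(c) = mean(se_post) - (-1 + 0.4 (c - 118)) = 0 at c = 118 + (me+1)/0.4
  c_star <- 118 + (mean(co$postop_se_d) + 1) / 0.4
  expect_equal(cst$constant, c_star, tolerance = 0.011)
  expect_equal(cst$provenance, "optimized")
  expect_lt(abs(cst$achieved_me_d), 0.01)
})

test_that("single-constant Barrett tables degrade to an additive offset", {
  co <- make_cohort(al = c(26, 27, 28), k = c(39, 38, 37), model = "BX",
                    a = 119, p = 19, se = c(-0.2, -0.4, -0.1))
  ext <- external_predictions(tibble::tibble(
    eye_id = co$eye_id, method = "BARRETT_TK", constant = 119,
    predicted_se_d = c(-1.0, -1.2, -0.9)))
  cst <- optimize_constants(co, methods = "BARRETT_TK", external = ext)
  expect_equal(cst$provenance, "offset_optimized")
  pred <- predict_refraction(co, methods = "BARRETT_TK", constants = cst,
                             external = ext)
  expect_lt(abs(mean(pred$pe)), 1e-9)
})

test_that("failed brackets fall back to the manufacturer constant", {
  # a pathological group whose postoperative refractions are far outside any
  # constant's reach within +/-12 A-units
  co <- make_cohort(al = rep(27, 3), k = rep(38, 3), model = "PX", a = 118.4,
                    p = 18, se = c(25, 25, 25))
  cst <- optimize_constants(co, methods = "SHAMMAS")
  expect_equal(cst$provenance, "manufacturer")
  expect_equal(cst$constant, 118.4)
})
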