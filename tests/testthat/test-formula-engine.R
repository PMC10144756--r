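test_that("base formulas agree with an independent step-by-step transcription", {
  g <- eye_grid(8, 6)
  for (i in seq_len(nrow(g))) {
    al <- g$al[i]; k <- g$k[i]
    expect_equal(srkt_refraction(al, k, convert_constant(118.4, "srkt_acd"), 18),
                 oracle_srkt_ref(al, k, 118.4, 18), tolerance = 1e-12)
    expect_equal(holladay1_refraction(al, k, convert_constant(118.4, "holladay_sf"), 18),
                 oracle_holladay_ref(al, k, 118.4, 18), tolerance = 1e-12)
    expect_equal(shammas_pl_refraction(al, shammas_cd_correct_k(k),
                                       convert_constant(118.4, "shammas_pacd"), 18),
                 oracle_shammas_ref(al, k, 118.4, 18), tolerance = 1e-12)
  }
})

test_that("frozen golden predictions lock the vergence chains", {
  acd <- convert_constant(118.4, "srkt_acd")
  expect_equal(srkt_refraction(27.44, 38.34, acd, 18), -2.1633973, tolerance = 1e-6)
  expect_equal(holladay1_refraction(27.44, 38.34, convert_constant(118.4, "holladay_sf"), 18),
               -2.2056525, tolerance = 1e-6)
  expect_equal(shammas_pl_refraction(27.44, shammas_cd_correct_k(38.34),
                                     convert_constant(118.4, "shammas_pacd"), 18),
               0.1190533, tolerance = 1e-6)
  expect_equal(srkt_power(23.5, 43, acd), 21.083617, tolerance = 1e-5)
  expect_equal(srkt_refraction(23.5, 43, acd, srkt_power(23.5, 43, acd) - 1),
               0.6995414, tolerance = 1e-6)
})

test_that("method coefficient registry is locked by frozen emmetropic powers", {
  frozen <- c(ALMA = 19.884212, FERRARA = 21.224329, JIN = 17.366708,
              KIM = 17.352461, LATKANY = 15.197277, SHAMMAS = 18.516151)
  for (m in names(frozen)) {
    expect_equal(emmetropic_power(m, 27.5, 38, 118.4, 0), unname(frozen[m]),
                 tolerance = 1e-5, info = m)
  }
})

test_that("inversion identity holds for every internal method over a 200-eye grid", {
  g <- eye_grid(20, 10)  # 200 eyes
  for (m in c("ALMA", "FERRARA", "JIN", "KIM", "LATKANY", "SHAMMAS")) {
    p <- emmetropic_power(m, g$al, g$k, 118.4, 0)
    ref <- postiol:::method_refraction(m, g$al, g$k, 118.4, p)
    expect_lt(max(abs(ref)), 1e-6)
    p75 <- emmetropic_power(m, g$al, g$k, 118.4, -0.75)
    ref75 <- postiol:::method_refraction(m, g$al, g$k, 118.4, p75)
    expect_lt(max(abs(ref75 + 0.75)), 1e-6)
    # more power is needed for a myopic target
    expect_true(all(p75 > p))
  }
})

test_that("closed-form and root-finding powers agree on a 100-eye grid", {
  g <- eye_grid(10, 10)
  for (m in c("ALMA", "SHAMMAS", "JIN")) {
    p_cf <- emmetropic_power(m, g$al, g$k, 118.4, 0, engine = "closed_form")
    p_rt <- emmetropic_power(m, g$al, g$k, 118.4, 0, engine = "root")
    expect_lt(max(abs(p_cf - p_rt)), 1e-6)
  }
})

test_that("predicted refraction falls with IOL power and rises with the A-constant", {
  # a deeper lens plane (higher A) leaves the same power underplussed, so the
  # predicted refraction moves hyperopic: strictly increasing in A
  g <- eye_grid(6, 5)
  powers <- seq(0, 40, by = 2)
  aconsts <- seq(114, 122, by = 1)
  for (m in c("ALMA", "FERRARA", "JIN", "KIM", "LATKANY", "SHAMMAS")) {
    for (i in seq_len(nrow(g))) {
      refs <- postiol:::method_refraction(m, g$al[i], g$k[i], 118.4, powers)
      expect_true(all(diff(refs) < 0), info = paste(m, "in p_iol"))
      refa <- postiol:::method_refraction(m, g$al[i], g$k[i], aconsts, 18)
      expect_true(all(diff(refa) > 0), info = paste(m, "in A"))
    }
  }
  # an overplussed lens leaves the eye myopic
  p0 <- srkt_power(23.5, 43, convert_constant(118.4, "srkt_acd"))
  expect_lt(srkt_refraction(23.5, 43, convert_constant(118.4, "srkt_acd"), p0 + 3), 0)
})

test_that("Shammas correction lowers post-LRS K and fixes only at 6.8/0.14", {
  expect_equal(shammas_cd_correct_k(38), 36.52)
  expect_equal(shammas_cd_correct_k(40), 38.80)
  fix <- 6.8 / 0.14
  expect_equal(shammas_cd_correct_k(fix), fix)
  k <- seq(30, 48, by = 0.5)
  expect_true(all(shammas_cd_correct_k(k) < k))
  # affine, hence double application is NOT idempotent
  expect_false(isTRUE(all.equal(shammas_cd_correct_k(shammas_cd_correct_k(38)),
                                shammas_cd_correct_k(38))))
})

test_that("corrections modify inputs in the documented direction", {
  cx <- apply_correction("SHAMMAS", 27, 38)
  expect_equal(cx$k, 36.52)
  expect_equal(cx$al, 27)
  # Ferrara's variable index lowers corneal power in long post-LRS eyes
  expect_lt(apply_correction("FERRARA", 30, 38)$k, 38)
  # ALMA's radius regression lowers effective K for typical post-LRS lengths
  expect_lt(apply_correction("ALMA", 27.5, 38)$k, 38)
  expect_equal(apply_correction("LATKANY", 27, 38)$k, 38)
  expect_lt(apply_correction("LATKANY", 27, 38)$power_offset, 0)
  expect_error(apply_correction("NOPE", 27, 38), "unknown method")
})

test_that("predictions are continuous at the published clamp boundaries", {
  eps <- 1e-9
  acd <- convert_constant(118.4, "srkt_acd")
  # the published SRK/T long-eye quadratic does not exactly join AL at
  # 24.2 mm (it evaluates to 24.176 there); the ~0.008 D step is inherited
  # from the published formula and must stay that small
  left <- srkt_refraction(24.2 - eps, 40, acd, 18)
  right <- srkt_refraction(24.2 + eps, 40, acd, 18)
  expect_lt(abs(left - right), 0.02)
  # Holladay anterior-segment cap at AL = 23.45 * 13.5 / 12.5
  al_cap <- 23.45 * 13.5 / 12.5
  sf <- convert_constant(118.4, "holladay_sf")
  expect_lt(abs(holladay1_refraction(al_cap - eps, 40, sf, 18) -
                  holladay1_refraction(al_cap + eps, 40, sf, 18)), 1e-6)
})

test_that("Barrett True-K is a strict passthrough of registered predictions", {
  co <- make_cohort(al = c(26, 28, 30), k = c(39, 38, 36), a = 119.0, p = 19)
  ext <- external_predictions(tibble::tibble(
    eye_id = co$eye_id, method = "BARRETT_TK",
    constant = 119.0, predicted_se_d = c(-0.42, 0.10, -1.00)))
  pred <- predict_refraction(co, methods = "BARRETT_TK", external = ext)
  expect_equal(pred$se_pred, c(-0.42, 0.10, -1.00))
  expect_equal(pred$pe, co$postop_se_d - pred$se_pred)
  expect_error(predict_refraction(co, methods = "BARRETT_TK"), "external")
  expect_error(
    predict_refraction(make_cohort(26, 39, id = "ghost"),
                       methods = "BARRETT_TK", external = ext),
    "ghost")
})

test_that("a full 7-method sweep returns one cell per eye and method", {
  co <- make_cohort(al = c(26, 28, 30), k = c(39, 38, 36))
  ext <- external_predictions(tibble::tibble(
    eye_id = co$eye_id, method = "BARRETT_TK", constant = 118.4,
    predicted_se_d = -0.2))
  pred <- predict_refraction(co, external = ext)
  expect_equal(nrow(pred), 21)
  expect_true(all(is.finite(pred$se_pred)))
  expect_true(all(is.finite(pred$pe)))
})
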