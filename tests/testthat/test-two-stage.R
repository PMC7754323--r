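test_that("per-study ANCOVA agrees with the one-stage fit restricted to one study", {
  ipd <- generate_pseudo_ipd(small_agg()[small_agg()$study == "B", ], seed = 12)
  eff <- fit_study_ancova(ipd)
  one <- fit_one_stage(ipd, model_spec(treatment_random = FALSE,
                                       residual_structure = "pooled"))
  expect_equal(eff$estimate[eff$kind == "treatment"], one$beta1$estimate,
               tolerance = 1e-10)
  expect_equal(eff$se[eff$kind == "treatment"], one$beta1$se,
               tolerance = 1e-10)
})

test_that("degenerate study designs are rejected with the study named", {
  toy <- data.frame(study = "T", arm = rep(c("treated", "control"), each = 2),
                    trt = c(1, 1, 0, 0),
                    y_base = c(1, 1, 2, 2),  # constant within arm: collinear
                    y_final = c(3, 4, 5, 6))
  expect_error(fit_study_ancova(toy), "T")
  single <- data.frame(study = "S", arm = "treated", trt = 1,
                       y_base = rnorm(6), y_final = rnorm(6))
  expect_error(fit_study_ancova(single), "single arm")
})

test_that("pooling: homogeneous effects collapse, DL matches the closed form", {
  same <- data.frame(estimate = rep(-3, 4), se = rep(0.5, 4))
  po <- pool(same, method = "DL")
  expect_equal(po$tau_sq, 0)
  expect_equal(po$estimate, -3)
  # DerSimonian-Laird by its defining formula, independent of the engine
  set.seed(31)
  eff <- data.frame(estimate = rnorm(8, -5, 2), se = runif(8, 0.5, 1.5))
  w <- 1 / eff$se^2
  mu_fe <- sum(w * eff$estimate) / sum(w)
  Q <- sum(w * (eff$estimate - mu_fe)^2)
  tau2 <- max(0, (Q - 7) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (eff$se^2 + tau2)
  mu_re <- sum(ws * eff$estimate) / sum(ws)
  po2 <- pool(eff, method = "DL")
  expect_equal(po2$tau_sq, tau2, tolerance = 1e-10)
  expect_equal(po2$estimate, mu_re, tolerance = 1e-10)
  expect_equal(po2$se, sqrt(1 / sum(ws)), tolerance = 1e-10)
  # order invariance, and the pooled value stays inside the effect range
  po3 <- pool(eff[sample(8), ], method = "DL")
  expect_equal(po3$tau_sq, po2$tau_sq)
  expect_gte(po2$estimate, min(eff$estimate))
  expect_lte(po2$estimate, max(eff$estimate))
  # a single study is returned unchanged
  po1 <- pool(eff[1, ])
  expect_equal(po1$estimate, eff$estimate[1])
  expect_equal(po1$k, 1L)
})

test_that("change-score meta-analysis is exactly invariant to baseline shifts", {
  agg <- hypertension_trials()
  shifted <- hypertension_trials(shifted = TRUE)
  a <- change_score_ma(agg)
  b <- change_score_ma(shifted)
  expect_equal(b$estimate, a$estimate, tolerance = 1e-12)
  expect_equal(b$se, a$se, tolerance = 1e-12)
  expect_equal(b$tau_sq, a$tau_sq, tolerance = 1e-12)
  # single-study input passes the study effect through
  one <- change_score_ma(agg[agg$study == "STOP", ])
  eff <- attr(one, "effects")
  expect_equal(one$estimate, eff$estimate)
})

test_that("final-value and baseline meta-analyses behave as mean differences", {
  agg <- small_agg()
  # equal final means give a zero pooled final-value difference
  eq <- agg
  eq$mean_final <- rep(c(150, 150), 3)
  expect_equal(final_values_ma(eq)$estimate, 0, tolerance = 1e-12)
  # randomized trials: pooled baseline difference compatible with zero
  bal <- baseline_ma(hypertension_trials())
  expect_true(bal$ci[1] < 0 && bal$ci[2] > 0)
  # induced imbalance shows up as a clearly negative baseline difference
  shift <- baseline_ma(hypertension_trials(shifted = TRUE))
  expect_lt(shift$ci[2], 0)
})

test_that("two-stage pooling matches the one-stage stratified fit closely", {
  ipd <- generate_pseudo_ipd(small_agg(), seed = 13)
  ts <- two_stage(ipd)
  one <- fit_one_stage(ipd, model_spec(residual_structure = "by_study"))
  expect_equal(ts$treatment$estimate, one$beta1$estimate, tolerance = 5e-3)
})

test_that("meta-regression guards its preconditions and finds no phantom slopes", {
  eff <- data.frame(estimate = c(-1, -2), se = c(0.5, 0.5))
  expect_error(meta_regression(eff, c(1, 2)), "at least 3")
  eff3 <- data.frame(estimate = c(-1, -2, -3), se = rep(0.5, 3))
  expect_error(meta_regression(eff3, rep(1, 3)), "constant covariate")
  # a covariate unrelated to the effects yields a slope within noise of zero
  set.seed(77)
  k <- 12
  eff <- data.frame(estimate = rnorm(k, -5, 1), se = rep(0.8, k))
  x <- rnorm(k, 170, 10)
  mr <- meta_regression(eff, x)
  expect_lt(abs(mr$slope), 3 * mr$se)
})

test_that("across-trial meta-regression flips sign under induced imbalance", {
  # the ecological-bias illustration: the across-study association between
  # final-value differences and treated-arm baseline reverses when five
  # treated arms are shifted, while the within-trial interaction does not
  slope_of <- function(shifted) {
    agg <- hypertension_trials(shifted = shifted)
    eff <- attr(final_values_ma(agg), "effects")
    mb <- agg$mean_base[agg$arm == "treated"]
    meta_regression(eff, mb)$slope
  }
  expect_lt(slope_of(FALSE), 0)
  expect_gt(slope_of(TRUE), 0)
})

test_that("forest data carries per-study rows, weights, and the pooled row", {
  po <- change_score_ma(small_agg())
  fd <- forest_data(po)
  expect_equal(nrow(fd), 4L)
  expect_equal(fd$study[4], "RE model")
  expect_equal(sum(fd$weight[1:3]), 100)
  expect_equal(fd$estimate[4], po$estimate)
})
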