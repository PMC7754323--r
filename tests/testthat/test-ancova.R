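test_that("the design centers the baseline within study and validates input", {
  ipd <- generate_pseudo_ipd(small_agg(), seed = 2)
  d <- build_design(ipd, model_spec())
  cent <- tapply(d$data$cb, d$data$study, sum)
  expect_true(all(abs(cent) < 1e-8))
  # single-arm study and constant baseline are caught
  one <- as.data.frame(ipd)[ipd$arm == "treated", ]
  expect_error(build_design(one, model_spec()), "single arm")
  flat <- as.data.frame(ipd)
  flat$y_base[flat$study == "A"] <- 100
  expect_error(build_design(flat, model_spec()), "constant baseline")
})

test_that("treated-arm shifts move the centering means by the expected fraction", {
  agg <- small_agg()
  sh <- c(A = -15, B = 10)
  shifted <- apply_baseline_shift(agg, sh)
  d0 <- build_design(generate_pseudo_ipd(agg, seed = 4), model_spec())
  d1 <- build_design(generate_pseudo_ipd(shifted, seed = 4), model_spec())
  # the study centering mean pools both arms, so it moves by
  # shift * n_treated / (n_treated + n_control)
  nt <- tapply(agg$n[agg$arm == "treated"], agg$study[agg$arm == "treated"], sum)
  ntot <- tapply(agg$n, agg$study, sum)
  expected <- d0$centers
  expected[names(sh)] <- expected[names(sh)] +
    sh * (nt[names(sh)] / ntot[names(sh)])
  expect_equal(d1$centers, expected, tolerance = 1e-8)
})

test_that("a single study with pooled residual and no random effects is OLS", {
  ipd <- generate_pseudo_ipd(small_agg()[small_agg()$study == "A", ], seed = 6)
  fit <- fit_one_stage(ipd, model_spec(treatment_random = FALSE,
                                       residual_structure = "pooled"))
  d <- as.data.frame(ipd)
  d$cb <- d$y_base - mean(d$y_base)
  ols <- lm(y_final ~ cb + trt, data = d)
  expect_equal(fit$beta1$estimate, coef(ols)[["trt"]], tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["cb", "estimate"]),
               coef(ols)[["cb"]], tolerance = 1e-10)
})

test_that("the sufficient-statistic REML objective matches a dense-matrix evaluation", {
  sc <- rich_scenario(21, n_studies = 3, n_per_arm = 15)
  ipd <- simulate_ipd(sc)
  fit <- fit_one_stage(ipd, model_spec(residual_structure = "by_study_arm"))
  des <- fit$design
  obj <- reml_objective(des)
  theta <- fit$theta
  # literal construction of V = Z Psi Z' + D over all n rows
  n <- des$n; p <- des$p
  psi <- obj$psi(theta)
  sig <- obj$sigma(theta)
  Zfull <- matrix(0, n, des$q * des$n_studies)
  for (s in seq_along(des$studies)) {
    rows <- des$data$study == des$studies[s]
    Zfull[rows, (s - 1) * des$q + seq_len(des$q)] <- des$Z[rows, , drop = FALSE]
  }
  Psi_big <- kronecker(diag(des$n_studies), psi)
  grp <- match(as.character(des$resid_group), des$sig_levels)
  V <- Zfull %*% Psi_big %*% t(Zfull) + diag(sig[grp]^2)
  Vi <- solve(V)
  X <- des$X; y <- des$y
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  ll_dense <- -0.5 * ((n - p) * log(2 * pi) +
                        determinant(V)$modulus +
                        determinant(XtVX)$modulus +
                        t(r) %*% Vi %*% r)
  expect_equal(obj$loglik(theta), as.numeric(ll_dense), tolerance = 1e-8)
  # and the lme engine agrees on the restricted likelihood at its optimum
  expect_equal(-2 * obj$loglik(theta), fit$minus2_reml, tolerance = 1e-8)
})

test_that("reported fixed effects are the GLS solution at the variance estimates", {
  ipd <- simulate_ipd(rich_scenario(22))
  fit <- fit_one_stage(ipd, model_spec(residual_structure = "by_study"))
  obj <- reml_objective(fit$design)
  g <- obj$gls(fit$theta)
  expect_equal(fit$coefficients$estimate, unname(g$beta), tolerance = 1e-10)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(g$vbeta))),
               tolerance = 1e-10)
  # cross-engine: nlme's own fixed effects agree to optimizer precision
  expect_scaled_equal(unname(nlme::fixef(fit$fit)), fit$coefficients$estimate,
                      1e-5)
})

test_that("residual-variance structures nest in restricted likelihood", {
  ipd <- simulate_ipd(rich_scenario(23))
  m2 <- sapply(c("pooled", "by_arm", "by_study", "by_study_arm"),
               function(st) fit_one_stage(ipd, model_spec(
                 residual_structure = st))$minus2_reml)
  eps <- 1e-6
  expect_lte(m2[["by_arm"]], m2[["pooled"]] + eps)
  expect_lte(m2[["by_study"]], m2[["pooled"]] + eps)
  expect_lte(m2[["by_study_arm"]], m2[["by_arm"]] + eps)
  expect_lte(m2[["by_study_arm"]], m2[["by_study"]] + eps)
})

test_that("between-within intervals use study-level df and fall back to normal", {
  ipd <- simulate_ipd(rich_scenario(24, n_studies = 5))
  fit <- fit_one_stage(ipd, model_spec(residual_structure = "by_study"))
  ci <- confint(fit, "treatment")
  expect_equal(unname(ci["df"]), 4)
  half <- qt(0.975, 4) * fit$beta1$se
  expect_equal(unname(ci["upper"] - ci["lower"]), 2 * half, tolerance = 1e-10)
  # without the study-level random effect the df are residual, hence the
  # interval is essentially the normal-quantile interval
  fit0 <- fit_one_stage(ipd, model_spec(treatment_random = FALSE,
                                        residual_structure = "by_study"))
  ci0 <- confint(fit0, "treatment")
  expect_gt(unname(ci0["df"]), 100)
  znorm <- fit0$beta1$estimate +
    c(-1, 1) * qnorm(0.975) * fit0$beta1$se
  expect_equal(unname(c(ci0["lower"], ci0["upper"])), znorm,
               tolerance = 1e-3)
  expect_error(confint(fit, "interaction"), "not in the fitted model")
})

test_that("Satterthwaite df are finite, positive, and below the residual df", {
  ipd <- simulate_ipd(rich_scenario(25, n_studies = 5))
  fit <- fit_one_stage(ipd, model_spec(residual_structure = "by_study"))
  df <- satterthwaite_df(fit$design, fit$theta, "trt")
  expect_true(is.finite(df) && df > 1)
  expect_lt(df, fit$n_obs - fit$design$p)
})

test_that("omitting the across-trial term changes the interaction estimand under imbalance", {
  agg <- apply_baseline_shift(small_agg(), c(A = -15, B = 10))
  ipd <- generate_pseudo_ipd(agg, seed = 9)
  with_b4 <- fit_one_stage(ipd, model_spec(interaction = TRUE,
                                           residual_structure = "by_study"))
  without_b4 <- fit_one_stage(ipd, model_spec(interaction = TRUE,
                                              across_trial = FALSE,
                                              residual_structure = "by_study"))
  expect_null(without_b4$beta4)
  expect_false(is.null(with_b4$beta4))
  expect_gt(abs(with_b4$beta3$estimate - without_b4$beta3$estimate), 1e-4)
})

test_that("the AIC counts only variance-covariance parameters", {
  ipd <- simulate_ipd(rich_scenario(26, n_studies = 3, n_per_arm = 30))
  fit <- fit_one_stage(ipd, model_spec(residual_structure = "by_arm"))
  # 1 random-effect variance + 2 residual variances
  expect_equal(fit$n_cov_params, 3L)
  expect_equal(AIC(fit), fit$minus2_reml + 2 * 3)
})
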