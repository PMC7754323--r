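#' Fit a one-stage ANCOVA linear mixed model by REML
#'
#' Fits the model described by a [model_spec()] to (pseudo or true) IPD:
#' follow-up outcome on treatment and the study-mean-centered baseline, with
#' stratified or random study effects, an optional treatment-by-baseline
#' interaction (within-trial and across-trial components), a random
#' treatment effect, and one of four within-study residual variance
#' structures. Estimation is restricted maximum likelihood via
#' [nlme::lme()] (or [nlme::gls()] when the model has no random effects),
#' with heteroscedastic residuals expressed as [nlme::varIdent()] weights.
#'
#' Because the restricted likelihood depends on the data only through the
#' per-arm sample moments, fitting this model to pseudo IPD generated from
#' aggregate statistics reproduces the fit to the true IPD exactly.
#'
#' @param ipd an `ipd` data frame ([generate_pseudo_ipd()],
#'   [simulate_ipd()], [read_ipd()]).
#' @param spec a [model_spec()].
#' @param control an [nlme::lmeControl()] list.
#' @return An object of class `"ancova_fit"`: a list with the fixed-effect
#'   table (`coefficients`), the headline effects with SE/df/CI (`beta1`
#'   treatment, `beta3` within-trial interaction, `beta4` across-trial
#'   interaction, as present), the random-effects covariance (`psi`, with
#'   `tau1_sq` etc. named in `tau`), residual SDs per variance group
#'   (`resid_sd`), `minus2_reml`, `aic` (`-2` restricted log-likelihood plus
#'   twice the number of variance-covariance parameters, `n_cov_params`),
#'   convergence information, and the underlying `nlme` fit (`fit`).
#' @export
fit_one_stage <- function(ipd, spec = model_spec(),
                          control = nlme::lmeControl(maxIter = 500,
                                                     msMaxIter = 500,
                                                     tolerance = 1e-10,
                                                     msTol = 1e-9,
                                                     returnObject = FALSE)) {
  design <- build_design(ipd, spec)
  d <- design$data
  wts <- switch(spec$residual_structure,
    by_study_arm = nlme::varIdent(form = ~ 1 | cell),
    by_study = nlme::varIdent(form = ~ 1 | study),
    by_arm = nlme::varIdent(form = ~ 1 | arm),
    pooled = NULL)
  fit <- NULL; converged <- FALSE
  if (design$q > 0L) {
    pd <- if (design$q == 1L || spec$random_effects_cov == "unstructured")
      nlme::pdSymm(design$random) else nlme::pdDiag(design$random)
    quiet_lme <- function(ctrl) withCallingHandlers(
      nlme::lme(design$fixed, random = list(study = pd), weights = wts,
                data = d, method = "REML", control = ctrl),
      warning = function(w) {
        if (grepl("[Ss]ingular precision", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    fit <- tryCatch(quiet_lme(control), error = function(e) e)
    if (inherits(fit, "error")) {
      ctrl2 <- control; ctrl2$opt <- "optim"
      fit <- tryCatch(quiet_lme(ctrl2), error = function(e) e)
    }
    if (inherits(fit, "error"))
      stop("one-stage REML fit failed to converge: ",
           conditionMessage(fit), call. = FALSE)
    converged <- TRUE
  } else {
    fit <- nlme::gls(design$fixed, weights = wts, data = d, method = "REML")
    converged <- TRUE
  }

  obj <- reml_objective(design)
  pol <- .polish_theta(obj, .theta_from_fit(fit, design))
  theta <- pol$theta
  g <- obj$gls(theta)
  beta <- g$beta
  vb <- g$vbeta
  psi <- obj$psi(theta)
  boundary <- FALSE
  if (!is.null(psi)) {
    dimnames(psi) <- list(colnames(design$Z), colnames(design$Z))
    # variance components on the zero boundary are reported as exact zeros
    zero <- diag(psi) < 1e-10
    if (any(zero)) {
      psi[zero, ] <- 0; psi[, zero] <- 0
      boundary <- TRUE
    }
  }
  resid_sd <- obj$sigma(theta)
  n_cov <- obj$npar
  m2 <- -2 * obj$loglik(theta)

  out <- list(spec = spec, design = design, fit = fit,
              coefficients = data.frame(estimate = as.numeric(beta),
                                        se = sqrt(diag(vb)),
                                        row.names = names(beta)),
              psi = psi, tau = .tau_names(psi), resid_sd = resid_sd,
              theta = theta, minus2_reml = m2, n_cov_params = n_cov,
              aic = m2 + 2 * n_cov, converged = converged && pol$ok,
              boundary = boundary,
              iterations = if (design$q > 0L) fit$numIter else NA_integer_,
              n_obs = design$n, n_studies = design$n_studies)
  class(out) <- "ancova_fit"
  for (eff in c("treatment", "interaction", "across_trial")) {
    cn <- .effect_coef(out, eff)
    if (!is.null(cn))
      out[[c(treatment = "beta1", interaction = "beta3",
             across_trial = "beta4")[[eff]]]] <-
        .effect_summary(out, eff, spec$df_method, spec$ci_level)
  }
  out
}

.tau_names <- function(psi) {
  if (is.null(psi)) return(NULL)
  map <- c("(Intercept)" = "tau0_sq", trt = "tau1_sq", trt_r = "tau1_sq",
           cb = "tau2_sq", cbtrt = "tau3_sq", cbtrt_r = "tau3_sq")
  nm <- map[rownames(psi)]
  setNames(diag(psi), ifelse(is.na(nm), rownames(psi), nm))
}

.effect_coef <- function(fit, effect) {
  cn <- switch(effect, treatment = "trt", interaction = "cbtrt",
               across_trial = "mbtrt",
               stop("unknown effect: ", effect, call. = FALSE))
  if (!cn %in% rownames(fit$coefficients)) return(NULL)
  cn
}

.bw_df <- function(fit, effect) {
  N <- fit$n_studies
  resdf <- fit$n_obs - fit$design$p
  spec <- fit$spec
  switch(effect,
    treatment = if (spec$treatment_random) N - 1L else resdf,
    interaction = if (!is.null(fit$psi) &&
                      any(rownames(fit$psi) %in% c("cbtrt", "cbtrt_r")))
      N - 1L else resdf,
    across_trial = N - 2L)
}

.effect_summary <- function(fit, effect, df_method, level) {
  cn <- .effect_coef(fit, effect)
  if (is.null(cn))
    stop("effect \"", effect, "\" is not in the fitted model", call. = FALSE)
  est <- fit$coefficients[cn, "estimate"]
  se <- fit$coefficients[cn, "se"]
  df <- if (df_method == "between_within") .bw_df(fit, effect)
        else satterthwaite_df(fit$design, fit$theta, cn)
  tq <- if (is.finite(df)) qt(1 - (1 - level) / 2, df)
        else stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se, df = df,
       ci = c(est - tq * se, est + tq * se), level = level,
       df_method = df_method)
}

#' Confidence interval for a fitted effect
#'
#' @param object an [fit_one_stage()] result.
#' @param parm `"treatment"` (\eqn{\beta_1}), `"interaction"`
#'   (\eqn{\beta_3}) or `"across_trial"` (\eqn{\beta_4}).
#' @param level confidence level (defaults to the spec's).
#' @param method `"between_within"` or `"satterthwaite"`; defaults to the
#'   spec's df method. Between-within assigns effects carrying a study-level
#'   random effect the between-study degrees of freedom (number of studies
#'   minus one); Satterthwaite uses the REML information matrix
#'   ([satterthwaite_df()]). Infinite df reduces to the normal-quantile
#'   interval.
#' @param ... unused.
#' @return Named vector `c(lower, upper, df)`.
#' @export
confint.ancova_fit <- function(object, parm = "treatment", level = NULL,
                               method = NULL, ...) {
  parm <- match.arg(parm, c("treatment", "interaction", "across_trial"))
  s <- .effect_summary(object, parm,
                       method %||% object$spec$df_method,
                       level %||% object$spec$ci_level)
  c(lower = s$ci[1], upper = s$ci[2], df = s$df)
}

#' Information criterion of a one-stage fit
#'
#' `-2` restricted log-likelihood (all normalizing constants of the
#' restricted likelihood included) plus twice the number of
#' variance-covariance parameters -- the REML convention under which only
#' models with identical fixed-effects structure are comparable, as when
#' ranking the four residual-variance structures.
#'
#' @param object an [fit_one_stage()] result.
#' @param ... unused.
#' @param k unused (signature compatibility).
#' @return The criterion value.
#' @export
AIC.ancova_fit <- function(object, ..., k = 2) object$aic

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("One-stage ANCOVA LMM (%s, residuals %s), REML\n",
              sub("_", " ", x$spec$level), x$spec$residual_structure))
  cat(sprintf("  %d studies, %s observations%s\n", x$n_studies,
              format(x$n_obs, big.mark = ","),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (b in c("beta1", "beta3", "beta4")) {
    e <- x[[b]]
    if (is.null(e)) next
    lab <- c(beta1 = "treatment effect        ",
             beta3 = "within-trial interaction",
             beta4 = "across-trial interaction")[[b]]
    cat(sprintf("  %s % 8.3f  (SE %.3f, %g%% CI %.3f to %.3f, df %.1f)\n",
                lab, e$estimate, e$se, 100 * e$level, e$ci[1], e$ci[2],
                e$df))
  }
  if (!is.null(x$tau))
    cat("  between-study variances:",
        paste(sprintf("%s = %.3f", names(x$tau), x$tau), collapse = ", "),
        "\n")
  cat(sprintf("  -2 REML logLik %.1f;  AIC %.1f (%d covariance parameters)\n",
              x$minus2_reml, x$aic, x$n_cov_params))
  invisible(x)
}
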