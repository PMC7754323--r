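#' Describe a generative scenario for true IPD
#'
#' A scenario generates two-arm trials from the same model family the
#' one-stage fits assume: per study `i`, baselines are normal with mean
#' `mu_baseline[i]` and SD `sigma_baseline[i]`; follow-up is
#' \deqn{Y_F = \beta_{0i} + (\beta_1 + b_{1i}) X + \beta_{2i}(Y_B - \mu_i) +
#'   (\beta_3 + b_{3i})(Y_B - \mu_i) X + \beta_4 \mu_i X + \epsilon}
#' with \eqn{b_{1i} \sim N(0, \tau_1^2)}, \eqn{b_{3i} \sim N(0, \tau_3^2)}
#' and residuals drawn per the chosen variance structure. The generative
#' centering uses the *true* study mean \eqn{\mu_i}; the fitting modules
#' center on observed means, as an analyst must.
#'
#' Defaults emulate a modest blood-pressure-like meta-analysis: study
#' baseline means spread over 150--190 units with SD 15, a treatment effect
#' of -10 with between-study variance 7, baseline slope 0.25, residual SD
#' 18.
#'
#' @param n_studies number of studies (>= 2).
#' @param n_per_arm subjects per arm (scalar or per-study vector, >= 3).
#' @param mu_baseline,sigma_baseline per-study baseline mean and SD
#'   (recycled).
#' @param beta0 per-study control-arm mean outcome at the mean baseline
#'   (recycled).
#' @param beta1 treatment effect.
#' @param beta2 per-study baseline adjustment slope (recycled).
#' @param beta3,beta4 within- and across-trial interaction coefficients.
#' @param tau1_sq,tau3_sq between-study variances of the treatment effect
#'   and of the interaction.
#' @param residual_structure one of `"pooled"`, `"by_arm"`, `"by_study"`,
#'   `"by_study_arm"`.
#' @param sigma_resid residual SDs: length 1, 2 (control, treated),
#'   `n_studies`, or `2 * n_studies` (study-major, control then treated)
#'   matching the structure.
#' @param seed integer seed; the scenario is fully reproducible from it.
#' @return An object of class `"sim_scenario"`.
#' @export
sim_scenario <- function(n_studies = 5, n_per_arm = 100,
                         mu_baseline = seq(150, 190, length.out = n_studies),
                         sigma_baseline = 15,
                         beta0 = 150, beta1 = -10, beta2 = 0.25,
                         beta3 = 0, beta4 = 0,
                         tau1_sq = 7, tau3_sq = 0,
                         residual_structure = c("pooled", "by_arm",
                                                "by_study", "by_study_arm"),
                         sigma_resid = 18, seed = 1L) {
  residual_structure <- match.arg(residual_structure)
  stopifnot(n_studies >= 2, all(n_per_arm >= 3), all(sigma_baseline > 0),
            tau1_sq >= 0, tau3_sq >= 0, all(sigma_resid >= 0))
  nsig <- c(pooled = 1L, by_arm = 2L, by_study = n_studies,
            by_study_arm = 2L * n_studies)[[residual_structure]]
  if (!length(sigma_resid) %in% c(1L, nsig))
    stop("sigma_resid must have length 1 or ", nsig, " for structure ",
         residual_structure, call. = FALSE)
  out <- list(n_studies = as.integer(n_studies),
              n_per_arm = rep_len(n_per_arm, n_studies),
              mu_baseline = rep_len(mu_baseline, n_studies),
              sigma_baseline = rep_len(sigma_baseline, n_studies),
              beta0 = rep_len(beta0, n_studies), beta1 = beta1,
              beta2 = rep_len(beta2, n_studies), beta3 = beta3,
              beta4 = beta4, tau1_sq = tau1_sq, tau3_sq = tau3_sq,
              residual_structure = residual_structure,
              sigma_resid = rep_len(sigma_resid, nsig),
              seed = as.integer(seed))
  class(out) <- "sim_scenario"
  out
}

# residual SD for (study i, arm k: 0 control / 1 treated)
.resid_sd_sim <- function(sc, i, k) {
  switch(sc$residual_structure,
         pooled = sc$sigma_resid[1],
         by_arm = sc$sigma_resid[k + 1L],
         by_study = sc$sigma_resid[i],
         by_study_arm = sc$sigma_resid[2L * (i - 1L) + k + 1L])
}

#' Simulate true IPD from a scenario
#'
#' @param scenario a [sim_scenario()].
#' @return An `ipd` data frame (`study`, `arm`, `trt`, `y_base`, `y_final`),
#'   the same record shape pseudo IPD uses, so the one- and two-stage fits
#'   apply unchanged.
#' @export
simulate_ipd <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sc$seed)
  parts <- vector("list", 2L * sc$n_studies)
  for (i in seq_len(sc$n_studies)) {
    b1i <- sc$beta1 + rnorm(1, 0, sqrt(sc$tau1_sq))
    b3i <- sc$beta3 + rnorm(1, 0, sqrt(sc$tau3_sq))
    for (k in 0:1) {
      n <- sc$n_per_arm[i]
      yb <- rnorm(n, sc$mu_baseline[i], sc$sigma_baseline[i])
      eps <- rnorm(n, 0, .resid_sd_sim(sc, i, k))
      cb <- yb - sc$mu_baseline[i]
      yf <- sc$beta0[i] + b1i * k + sc$beta2[i] * cb + b3i * cb * k +
        sc$beta4 * sc$mu_baseline[i] * k + eps
      parts[[2L * (i - 1L) + k + 1L]] <- data.frame(
        study = sprintf("S%02d", i),
        arm = if (k == 1) "treated" else "control", trt = k,
        y_base = yb, y_final = yf, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, parts)
  out$study <- factor(out$study, levels = unique(out$study))
  rownames(out) <- NULL
  class(out) <- c("ipd", "data.frame")
  out
}

#' Summarize IPD to aggregate form
#'
#' Per (study, arm): sample size, baseline and follow-up sample mean and SD
#' (n-1 denominator), and the baseline--follow-up Pearson correlation --
#' exactly the sufficient statistics the pseudo-IPD generator consumes, so
#' `summarize_to_ad(generate_pseudo_ipd(A, seed))` returns `A`.
#'
#' @param ipd an `ipd` data frame.
#' @inheritParams meta_aggregate
#' @return A [meta_aggregate()].
#' @export
summarize_to_ad <- function(ipd, outcome_label = "outcome",
                            outcome_units = "") {
  d <- as.data.frame(ipd)
  d$study <- as.character(d$study)
  key <- unique(d[, c("study", "arm")])
  rows <- lapply(seq_len(nrow(key)), function(j) {
    di <- d[d$study == key$study[j] & d$arm == key$arm[j], ]
    if (nrow(di) < 3L)
      stop("arm with fewer than 3 subjects: ", key$study[j], "/",
           key$arm[j], call. = FALSE)
    data.frame(study = key$study[j], arm = key$arm[j], n = nrow(di),
               mean_base = mean(di$y_base), sd_base = sd(di$y_base),
               mean_final = mean(di$y_final), sd_final = sd(di$y_final),
               corr = cor(di$y_base, di$y_final),
               stringsAsFactors = FALSE)
  })
  meta_aggregate(do.call(rbind, rows), outcome_label = outcome_label,
                 outcome_units = outcome_units)
}
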