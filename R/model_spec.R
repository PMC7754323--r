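#' Describe one ANCOVA linear mixed model
#'
#' A declarative specification of the one-stage ANCOVA model to fit to
#' (pseudo or true) IPD: follow-up regressed on treatment and the
#' study-mean-centered baseline, with study effects either stratified (fixed
#' per-study intercepts and baseline slopes) or random, an optional
#' treatment-by-baseline interaction split into its within-trial and
#' across-trial components, a random treatment effect with between-study
#' variance \eqn{\tau_1^2}, and one of four within-study residual variance
#' structures.
#'
#' @param level `"stratified_study"`: fixed intercept and baseline slope per
#'   study; `"random_study"`: random intercept and baseline slope.
#' @param interaction add the treatment-by-baseline interaction: a
#'   within-trial term (centered baseline x treatment, coefficient
#'   \eqn{\beta_3}, with a random slope \eqn{b_{3i}}) and, when
#'   `across_trial` is `TRUE`, a single across-trial term (study mean
#'   baseline x treatment, coefficient \eqn{\beta_4}). Omitting the
#'   across-trial term collapses the two estimands into a mixture vulnerable
#'   to ecological bias, so it is kept by default.
#' @param residual_structure within-study residual variances: `"by_study_arm"`
#'   (all free), `"by_study"`, `"by_arm"`, or `"pooled"` (one variance).
#' @param random_effects_cov covariance of the random effects:
#'   `"unstructured"` or `"independent"`. Default: unstructured for the
#'   stratified interaction model (two random effects), independent for
#'   random-study models.
#' @param treatment_random keep the random treatment effect (default); turn
#'   off to constrain \eqn{\tau_1^2 = 0} (common-effect model).
#' @param across_trial include the across-trial interaction column (only
#'   relevant with `interaction`).
#' @param center_groups center the treatment indicator at 0.5 inside the
#'   random-effect design columns (random-study models only; the fixed part
#'   is unchanged).
#' @param df_method degrees of freedom for confidence intervals:
#'   `"between_within"` (effects carrying a study-level random effect get
#'   `N_studies - 1`) or `"satterthwaite"`.
#' @param ci_level confidence level.
#' @return An object of class `"model_spec"`.
#' @seealso [fit_one_stage()]
#' @export
model_spec <- function(level = c("stratified_study", "random_study"),
                       interaction = FALSE,
                       residual_structure = c("by_study", "by_study_arm",
                                              "by_arm", "pooled"),
                       random_effects_cov = NULL,
                       treatment_random = TRUE,
                       across_trial = interaction,
                       center_groups = NULL,
                       df_method = c("between_within", "satterthwaite"),
                       ci_level = 0.95) {
  level <- match.arg(level)
  residual_structure <- match.arg(residual_structure)
  df_method <- match.arg(df_method)
  stopifnot(is.logical(interaction), is.logical(treatment_random),
            ci_level > 0, ci_level < 1)
  if (is.null(center_groups)) center_groups <- level == "random_study"
  if (is.null(random_effects_cov))
    random_effects_cov <-
      if (level == "stratified_study" && interaction) "unstructured"
      else "independent"
  random_effects_cov <- match.arg(random_effects_cov,
                                  c("unstructured", "independent"))
  q <- .n_random(level, interaction, treatment_random)
  if (random_effects_cov == "unstructured" && q < 2)
    stop("random_effects_cov = \"unstructured\" needs at least two random ",
         "effects", call. = FALSE)
  structure(list(level = level, interaction = interaction,
                 residual_structure = residual_structure,
                 random_effects_cov = random_effects_cov,
                 treatment_random = treatment_random,
                 across_trial = isTRUE(across_trial),
                 center_groups = isTRUE(center_groups),
                 df_method = df_method, ci_level = ci_level),
            class = "model_spec")
}

.n_random <- function(level, interaction, treatment_random) {
  if (level == "stratified_study")
    as.integer(treatment_random) + as.integer(interaction)
  else
    2L + as.integer(treatment_random) + as.integer(interaction)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("ANCOVA LMM specification\n")
  cat("  study level:        ", x$level, "\n")
  cat("  interaction:        ", x$interaction,
      if (x$interaction && !x$across_trial) "(across-trial term omitted)",
      "\n")
  cat("  residual variances: ", x$residual_structure, "\n")
  cat("  random effects:     ", .n_random(x$level, x$interaction,
                                          x$treatment_random),
      paste0("(", x$random_effects_cov, ")"), "\n")
  cat("  df method:          ", x$df_method, "  ci level: ", x$ci_level, "\n")
  invisible(x)
}
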