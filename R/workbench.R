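#' Fit the standard battery of models and comparators to one dataset
#'
#' Generates pseudo IPD from aggregate data (reproducibly from `seed`), fits
#' the one-stage ANCOVA models across the requested study levels and
#' residual-variance structures, runs the two-stage analysis and the
#' aggregate-data comparators, and returns everything as one tidy table of
#' full-precision numbers (any rounding is left to the caller). A failing
#' sub-fit is recorded in its row's `error` column and the run continues.
#'
#' @param data a [meta_aggregate()].
#' @param seed master seed for the pseudo-IPD generation (recorded in the
#'   returned attribute `"seed"`).
#' @param interaction report the within-trial interaction \eqn{\beta_3}
#'   instead of the treatment effect \eqn{\beta_1}.
#' @param levels study levels to fit.
#' @param structures residual-variance structures to fit.
#' @param comparators aggregate-data comparators to append (any of
#'   `"two_stage"`, `"change_score"`, `"final_values"`, `"baseline"`).
#' @param pool_method pooling method for the two-stage and AD rows.
#' @param ci_level confidence level throughout.
#' @return Data frame with one row per analysis: `model`, `residual`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `tau_sq`, `aic`, `error`.
#' @export
run_compare <- function(data, seed = 1L, interaction = FALSE,
                        levels = c("stratified_study", "random_study"),
                        structures = c("by_study_arm", "by_study", "by_arm",
                                       "pooled"),
                        comparators = c("two_stage", "change_score",
                                        "final_values", "baseline"),
                        pool_method = "REML", ci_level = 0.95) {
  stopifnot(inherits(data, "meta_aggregate"))
  ipd <- generate_pseudo_ipd(data, seed = seed)
  eff <- if (interaction) "interaction" else "treatment"
  rows <- list()
  add <- function(model, residual, f) {
    res <- tryCatch(f(), error = function(e) conditionMessage(e))
    if (is.character(res))
      rows[[length(rows) + 1L]] <<- data.frame(
        model = model, residual = residual, estimate = NA_real_,
        se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        tau_sq = NA_real_, aic = NA_real_, error = res)
    else
      rows[[length(rows) + 1L]] <<- cbind(
        data.frame(model = model, residual = residual), res,
        data.frame(error = NA_character_))
  }
  for (lv in levels) for (st in structures) {
    add(paste0("one-stage ", sub("_study", "", lv)), st, function() {
      fit <- fit_one_stage(ipd, model_spec(level = lv, interaction = interaction,
                                           residual_structure = st,
                                           ci_level = ci_level))
      e <- if (interaction) fit$beta3 else fit$beta1
      tau <- fit$tau[[if (interaction) "tau3_sq" else "tau1_sq"]]
      data.frame(estimate = e$estimate, se = e$se, ci_low = e$ci[1],
                 ci_high = e$ci[2], tau_sq = tau %||% NA_real_,
                 aic = fit$aic)
    })
  }
  if ("two_stage" %in% comparators)
    add("two-stage", "by_study", function() {
      ts <- two_stage(ipd, interaction = interaction, method = pool_method,
                      level = ci_level)
      po <- if (interaction) ts$interaction else ts$treatment
      data.frame(estimate = po$estimate, se = po$se, ci_low = po$ci[1],
                 ci_high = po$ci[2], tau_sq = po$tau_sq, aic = NA_real_)
    })
  ad <- c(change_score = "change_score_ma", final_values = "final_values_ma",
          baseline = "baseline_ma")
  if (!interaction) for (nm in intersect(names(ad), comparators))
    add(paste0("AD ", sub("_", " ", nm)), "-", function() {
      po <- get(ad[[nm]])(data, method = pool_method, level = ci_level)
      data.frame(estimate = po$estimate, se = po$se, ci_low = po$ci[1],
                 ci_high = po$ci[2], tau_sq = po$tau_sq, aic = NA_real_)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' Sensitivity of the pooled effect to an imputed correlation
#'
#' When baseline--follow-up correlations cannot be recovered from reported
#' data they must be imputed; this sweep overrides every arm's correlation
#' with each candidate value in turn, regenerates the pseudo IPD, and refits
#' the requested one-stage models, so the analyst can see how much the
#' summary effect moves over a plausible correlation range.
#'
#' @param data a [meta_aggregate()] (existing correlations are ignored).
#' @param corrs candidate correlation values.
#' @param seed master seed for each regeneration.
#' @inheritParams run_compare
#' @return Data frame: one row per (correlation, model, structure) with the
#'   same columns as [run_compare()] plus `corr`.
#' @export
sensitivity_correlations <- function(data, corrs = c(0.5, 0.6, 0.7),
                                     seed = 1L,
                                     levels = "stratified_study",
                                     structures = c("by_study_arm",
                                                    "by_study", "by_arm",
                                                    "pooled"),
                                     ci_level = 0.95) {
  out <- lapply(corrs, function(r) {
    dr <- data
    dr$corr <- r
    tab <- run_compare(dr, seed = seed, levels = levels,
                       structures = structures, comparators = character(),
                       ci_level = ci_level)
    cbind(corr = r, tab)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
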