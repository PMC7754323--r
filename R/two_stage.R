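#' Per-study ANCOVA (first stage of the two-stage approach)
#'
#' Ordinary least-squares regression of the follow-up outcome on treatment
#' and the study-mean-centered baseline within one study (plus the centered
#' baseline x treatment term when `interaction`). The centering matches the
#' one-stage models so that interaction coefficients are comparable across
#' the two approaches.
#'
#' @param ipd an `ipd` data frame; may contain one or several studies, each
#'   fitted separately.
#' @param interaction also estimate the treatment-by-baseline interaction.
#' @return A data frame of class `"study_effects"`: one row per (study,
#'   effect) with `study`, `kind` (`"treatment"`/`"interaction"`),
#'   `estimate`, `se`, `df`.
#' @export
fit_study_ancova <- function(ipd, interaction = FALSE) {
  d <- as.data.frame(ipd)
  d$study <- droplevels(as.factor(d$study))
  rows <- lapply(levels(d$study), function(s) {
    di <- d[d$study == s, ]
    if (length(unique(di$trt)) < 2L)
      stop("study ", s, " has a single arm", call. = FALSE)
    need <- if (interaction) 5L else 4L
    if (nrow(di) < need)
      stop("study ", s, ": too few subjects for the ANCOVA", call. = FALSE)
    di$cb <- di$y_base - mean(di$y_base)
    f <- if (interaction) y_final ~ trt + cb + cb:trt else y_final ~ trt + cb
    m <- lm(f, data = di)
    if (any(is.na(coef(m))))
      stop("study ", s, ": rank-deficient ANCOVA design", call. = FALSE)
    co <- summary(m)$coefficients
    kinds <- c(treatment = "trt",
               if (interaction) c(interaction = "trt:cb"))
    data.frame(study = s, kind = names(kinds),
               estimate = co[kinds, "Estimate"],
               se = co[kinds, "Std. Error"],
               df = m$df.residual, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("study_effects", "data.frame")
  out
}

#' Pool study-level effects by meta-analysis
#'
#' Second stage of the two-stage approach, and the pooling engine of the
#' aggregate-data comparators. Random-effects pooling estimates the
#' between-study variance by restricted maximum likelihood (default) or by
#' the DerSimonian-Laird moment estimator; `"FE"` is the common-effect
#' model. Computation is delegated to [metafor::rma.uni()].
#'
#' @param effects a `study_effects` data frame, or any data frame with
#'   columns `estimate` and `se` (one kind of effect at a time).
#' @param method `"REML"`, `"DL"`, or `"FE"`.
#' @param ci `"z"` (normal-based, default), `"t"` (t with k-1 df), or
#'   `"knha"` (Knapp-Hartung).
#' @param level confidence level.
#' @return An object of class `"pooled_result"`: `estimate`, `se`, `ci`,
#'   `tau_sq`, `method`, `k`, and the underlying `metafor` fit (`rma`).
#' @export
pool <- function(effects, method = c("REML", "DL", "FE"), ci = c("z", "t", "knha"),
                 level = 0.95) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  eff <- as.data.frame(effects)
  if ("kind" %in% names(eff) && length(unique(eff$kind)) > 1L)
    stop("pool one kind of effect at a time; got: ",
         paste(unique(eff$kind), collapse = ", "), call. = FALSE)
  stopifnot(all(c("estimate", "se") %in% names(eff)), all(eff$se > 0))
  k <- nrow(eff)
  if (k == 0L) stop("no effects to pool", call. = FALSE)
  if (k == 1L) {
    # single study: return the study effect unchanged (fixed effect)
    z <- stats::qnorm(1 - (1 - level) / 2)
    out <- list(estimate = eff$estimate[1], se = eff$se[1],
                ci = eff$estimate[1] + c(-1, 1) * z * eff$se[1],
                tau_sq = 0, method = "FE", k = 1L, rma = NULL, level = level)
    class(out) <- "pooled_result"
    return(out)
  }
  m <- metafor::rma.uni(yi = eff$estimate, sei = eff$se,
                        method = if (method == "FE") "EE" else method,
                        test = if (ci == "knha") "knha" else "z",
                        level = 100 * level)
  lo <- m$ci.lb; hi <- m$ci.ub; se <- m$se
  if (ci == "t") {
    tq <- qt(1 - (1 - level) / 2, k - 1L)
    lo <- as.numeric(m$beta) - tq * se
    hi <- as.numeric(m$beta) + tq * se
  }
  out <- list(estimate = as.numeric(m$beta), se = se, ci = c(lo, hi),
              tau_sq = if (method == "FE") 0 else m$tau2, method = method,
              k = k, rma = m, level = level)
  class(out) <- "pooled_result"
  out
}

#' Two-stage pseudo-IPD meta-analysis
#'
#' Per-study ANCOVA ([fit_study_ancova()]) followed by random-effects
#' pooling ([pool()]) of the study-specific treatment (and, optionally,
#' interaction) coefficients.
#'
#' @inheritParams fit_study_ancova
#' @inheritParams pool
#' @return A list with the per-study `effects` and the pooled `treatment`
#'   (and `interaction`) [pool()] results.
#' @export
two_stage <- function(ipd, interaction = FALSE, method = "REML", ci = "z",
                      level = 0.95) {
  eff <- fit_study_ancova(ipd, interaction = interaction)
  out <- list(effects = eff,
              treatment = pool(eff[eff$kind == "treatment", ],
                               method = method, ci = ci, level = level))
  if (interaction)
    out$interaction <- pool(eff[eff$kind == "interaction", ],
                            method = method, ci = ci, level = level)
  class(out) <- "two_stage_fit"
  out
}

# per-study summary effects shared by the AD comparators
.ad_effects <- function(data, what = c("change", "final", "baseline")) {
  what <- match.arg(what)
  stopifnot(inherits(data, "meta_aggregate"))
  tr <- data[data$arm == "treated", ]
  ct <- data[data$arm == "control", ]
  ct <- ct[match(tr$study, ct$study), ]
  if (what == "change") {
    sdch <- function(a) {
      out <- a$sd_change
      i <- is.na(out)
      if (any(i)) {
        if (anyNA(a$corr[i]))
          stop("change-score SD unavailable: no correlation for study ",
               paste(a$study[i][is.na(a$corr[i])], collapse = ", "),
               call. = FALSE)
        out[i] <- sd_change_from_corr(a$sd_base[i], a$sd_final[i], a$corr[i])
      }
      out
    }
    est <- (tr$mean_final - tr$mean_base) - (ct$mean_final - ct$mean_base)
    v <- sdch(tr)^2 / tr$n + sdch(ct)^2 / ct$n
    kind <- "change_diff"
  } else if (what == "final") {
    est <- tr$mean_final - ct$mean_final
    v <- tr$sd_final^2 / tr$n + ct$sd_final^2 / ct$n
    kind <- "final_diff"
  } else {
    est <- tr$mean_base - ct$mean_base
    v <- tr$sd_base^2 / tr$n + ct$sd_base^2 / ct$n
    kind <- "baseline_diff"
  }
  out <- data.frame(study = tr$study, kind = kind, estimate = est,
                    se = sqrt(v), df = NA_real_)
  class(out) <- c("study_effects", "data.frame")
  out
}

#' Aggregate-data meta-analyses of change scores, final values, baselines
#'
#' The standard comparators that need no IPD. `change_score_ma()` pools the
#' between-group difference in mean change from baseline, with variance
#' `sd_change_T^2/n_T + sd_change_C^2/n_C`, deriving each arm's change-score
#' SD from its baseline/final SDs and correlation when not reported
#' directly; it is exactly invariant under treated-arm baseline shifts.
#' `final_values_ma()` and `baseline_ma()` pool the unadjusted mean
#' difference at the named timepoint.
#'
#' @param data a [meta_aggregate()].
#' @inheritParams pool
#' @return A [pool()] result with the per-study effects attached as
#'   attribute `"effects"`.
#' @export
change_score_ma <- function(data, method = "REML", ci = "z", level = 0.95) {
  eff <- .ad_effects(data, "change")
  out <- pool(eff, method = method, ci = ci, level = level)
  attr(out, "effects") <- eff
  out
}

#' @rdname change_score_ma
#' @export
final_values_ma <- function(data, method = "REML", ci = "z", level = 0.95) {
  eff <- .ad_effects(data, "final")
  out <- pool(eff, method = method, ci = ci, level = level)
  attr(out, "effects") <- eff
  out
}

#' @rdname change_score_ma
#' @export
baseline_ma <- function(data, method = "REML", ci = "z", level = 0.95) {
  eff <- .ad_effects(data, "baseline")
  out <- pool(eff, method = method, ci = ci, level = level)
  attr(out, "effects") <- eff
  out
}

#' Random-effects meta-regression of study effects on a study covariate
#'
#' The aggregate-data analogue of the across-trial interaction: a weighted
#' regression of per-study effects on a study-level covariate (typically the
#' treated-arm mean baseline) with additive between-study variance. Because
#' across-study associations can be confounded (ecological bias), the slope
#' is not a substitute for the within-trial interaction.
#'
#' @param effects a `study_effects` data frame (one effect per study), e.g.
#'   from [change_score_ma()]'s `"effects"` attribute or [.ad_effects]-style
#'   columns `estimate`, `se`.
#' @param covariate numeric vector, one value per study, in `effects` order.
#' @param method `"REML"` or `"DL"` between-study variance estimator.
#' @param level confidence level.
#' @return List with `slope`, `se`, `ci`, `tau_sq`, `k`, and the `metafor`
#'   fit.
#' @export
meta_regression <- function(effects, covariate, method = c("REML", "DL"),
                            level = 0.95) {
  method <- match.arg(method)
  eff <- as.data.frame(effects)
  k <- nrow(eff)
  if (k < 3L)
    stop("meta-regression needs at least 3 studies", call. = FALSE)
  stopifnot(length(covariate) == k)
  if (var(covariate) == 0)
    stop("constant covariate: slope unidentifiable", call. = FALSE)
  m <- metafor::rma.uni(yi = eff$estimate, sei = eff$se, mods = ~ covariate,
                        method = method, level = 100 * level)
  list(slope = m$beta["covariate", 1], se = m$se[2],
       ci = c(m$ci.lb[2], m$ci.ub[2]), tau_sq = m$tau2, k = k, rma = m)
}

#' Forest-plot data export
#'
#' Per-study effects with CIs and inverse-variance weights plus the pooled
#' row, as a plain data frame ready for plotting or delimited-text export.
#'
#' @param pooled a [pool()] result carrying an `"effects"` attribute, or a
#'   list of `(effects, pooled)`.
#' @param effects the per-study `study_effects` (if not attached).
#' @return Data frame with columns `study`, `estimate`, `lower`, `upper`,
#'   `weight` (normalized random-effects weights, per cent), the pooled row
#'   last with study label `"RE model"`.
#' @export
forest_data <- function(pooled, effects = attr(pooled, "effects")) {
  stopifnot(inherits(pooled, "pooled_result"), !is.null(effects))
  z <- stats::qnorm(1 - (1 - pooled$level) / 2)
  w <- 1 / (effects$se^2 + pooled$tau_sq)
  rbind(
    data.frame(study = as.character(effects$study),
               estimate = effects$estimate,
               lower = effects$estimate - z * effects$se,
               upper = effects$estimate + z * effects$se,
               weight = 100 * w / sum(w)),
    data.frame(study = "RE model", estimate = pooled$estimate,
               lower = pooled$ci[1], upper = pooled$ci[2], weight = NA))
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf(
    "Pooled effect (%s, k = %d): %.3f (SE %.3f, %g%% CI %.3f to %.3f), tau^2 = %.3f\n",
    x$method, x$k, x$estimate, x$se, 100 * x$level, x$ci[1], x$ci[2],
    x$tau_sq))
  invisible(x)
}

#' @export
print.two_stage_fit <- function(x, ...) {
  cat("Two-stage pseudo-IPD ANCOVA meta-analysis\n  treatment:   ")
  print(x$treatment)
  if (!is.null(x$interaction)) {
    cat("  interaction: ")
    print(x$interaction)
  }
  invisible(x)
}
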