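#' Construct a validated aggregate-data object
#'
#' A `meta_aggregate` holds trial-level aggregate statistics of a continuous
#' outcome measured at baseline and follow-up, one row per study arm. It is
#' the unit of input for pseudo-IPD generation and for the aggregate-data
#' meta-analysis comparators.
#'
#' @param data data frame in long layout with columns `study`, `arm`
#'   (`"treated"`/`"control"`), `n`, `mean_base`, `sd_base`, `mean_final`,
#'   `sd_final`, and optionally `corr`, `sd_change`, `se_diff_change`.
#' @param outcome_label,outcome_units descriptive text attached as attributes.
#' @param require_corr if `TRUE`, every arm must carry a baseline--follow-up
#'   correlation (directly or recoverable); if `FALSE` (default) arms with a
#'   missing correlation are accepted and flagged for later recovery by
#'   [recover_correlations()].
#'
#' @details Validation enforces: every study has exactly one treated and one
#'   control arm; study ids unique; `n >= 3` per arm (needed for exact moment
#'   matching); positive standard deviations; correlations strictly inside
#'   (-1, 1), with values within 1e-9 of the boundary rejected rather than
#'   clipped.
#'
#' @return A data frame of class `"meta_aggregate"`.
#' @seealso [read_aggregate()], [recover_correlations()],
#'   [apply_baseline_shift()], [generate_pseudo_ipd()]
#' @export
meta_aggregate <- function(data, outcome_label = "outcome",
                           outcome_units = "", require_corr = FALSE) {
  stopifnot(is.data.frame(data))
  need <- c("study", "arm", .agg_required)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- as.data.frame(data, stringsAsFactors = FALSE)
  out$study <- as.character(out$study)
  out$arm <- .normalize_arm(out$arm)
  for (f in setdiff(.agg_fields, names(out))) out[[f]] <- NA_real_
  out <- out[, c("study", "arm", .agg_fields)]
  for (f in .agg_fields) out[[f]] <- as.numeric(out[[f]])
  class(out) <- c("meta_aggregate", "data.frame")
  attr(out, "outcome_label") <- outcome_label
  attr(out, "outcome_units") <- outcome_units
  validate_meta_aggregate(out, require_corr = require_corr)
  out
}

.normalize_arm <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("treated", "treatment", "t", "active", "1")] <- "treated"
  out[x %in% c("control", "c", "placebo", "sham", "0")] <- "control"
  if (anyNA(out))
    stop("unrecognized arm label(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Validate a meta_aggregate object
#'
#' @param x a `meta_aggregate`.
#' @param require_corr require a correlation on every arm.
#' @return `x`, invisibly, if valid; otherwise an error naming the offending
#'   study and arm.
#' @export
validate_meta_aggregate <- function(x, require_corr = FALSE) {
  if (nrow(x) == 0L) stop("empty aggregate table", call. = FALSE)
  tab <- table(x$study, x$arm)
  bad <- rownames(tab)[tab[, "treated"] != 1L | tab[, "control"] != 1L]
  if (length(bad))
    stop("each study needs exactly one treated and one control arm; check: ",
         paste(bad, collapse = ", "), call. = FALSE)
  where <- paste0(x$study, "/", x$arm)
  chk <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(what, " for ", paste(where[i], collapse = ", "), call. = FALSE)
  }
  chk(!is.finite(x$n) | x$n < 3 | x$n != round(x$n),
      "sample size must be an integer >= 3")
  chk(!is.finite(x$sd_base) | x$sd_base <= 0, "sd_base must be > 0")
  chk(!is.finite(x$sd_final) | x$sd_final <= 0, "sd_final must be > 0")
  chk(!is.finite(x$mean_base), "non-numeric mean_base")
  chk(!is.finite(x$mean_final), "non-numeric mean_final")
  has_r <- !is.na(x$corr)
  chk(has_r & abs(x$corr) >= 1 - .corr_eps,
      "correlation at or numerically on the boundary of (-1, 1)")
  chk(!is.na(x$sd_change) & x$sd_change <= 0, "sd_change must be > 0")
  if (require_corr)
    chk(!has_r, "missing baseline-follow-up correlation")
  invisible(x)
}

#' Read trial-level aggregate data from a delimited file
#'
#' Accepts either a long layout (one row per arm, canonical columns `study`,
#' `arm`, `n`, `mean_base`, `sd_base`, `mean_final`, `sd_final`, `corr`,
#' `sd_change`, `se_diff_change`) or a wide layout (one row per study with
#' per-arm columns suffixed `_treated`/`_control`, e.g. `n_treated`,
#' `mean_base_control`; a study-level `se_diff_change` column is carried onto
#' both arms). Published tables are typically wide; extraction sheets long.
#'
#' @param file path or connection to a comma- or tab-delimited file with a
#'   header row.
#' @param layout `"auto"` (default), `"long"` or `"wide"`.
#' @param column_map optional named character vector mapping canonical names
#'   (long layout) or canonical stems (wide layout) to the file's column
#'   names, e.g. `c(mean_base = "baseline_mean")`.
#' @param sep field separator; `""` (default) infers comma vs tab from the
#'   header line.
#' @inheritParams meta_aggregate
#' @return A [meta_aggregate()]. Arms without a correlation are kept and
#'   flagged for recovery, not rejected.
#' @export
read_aggregate <- function(file, layout = c("auto", "long", "wide"),
                           column_map = NULL, sep = "",
                           outcome_label = "outcome", outcome_units = "") {
  layout <- match.arg(layout)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty table", call. = FALSE)
  if (sep == "") {
    hdr <- lines[1L]
    sep <- if (lengths(regmatches(hdr, gregexpr("\t", hdr))) >
               lengths(regmatches(hdr, gregexpr(",", hdr)))) "\t" else ","
  }
  raw <- read.table(text = paste(lines, collapse = "\n"), header = TRUE,
                    sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty table", call. = FALSE)
  if (!is.null(column_map)) {
    i <- match(column_map, names(raw))
    if (anyNA(i))
      stop("column_map refers to absent column(s): ",
           paste(column_map[is.na(i)], collapse = ", "), call. = FALSE)
    names(raw)[i] <- names(column_map)
  }
  if (layout == "auto")
    layout <- if ("arm" %in% names(raw)) "long" else "wide"
  long <- if (layout == "long") raw else .wide_to_long(raw)
  miss <- setdiff(c("study", "arm", .agg_required), names(long))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  meta_aggregate(long, outcome_label = outcome_label,
                 outcome_units = outcome_units)
}

.wide_to_long <- function(raw) {
  if (!"study" %in% names(raw))
    stop("missing required column(s): study", call. = FALSE)
  suf <- c(treated = "_treated", control = "_control")
  # tolerate the short _t/_c suffix convention
  for (f in .agg_fields) for (a in c("t", "c")) {
    short <- paste0(f, "_", a)
    lng <- paste0(f, if (a == "t") "_treated" else "_control")
    if (short %in% names(raw) && !lng %in% names(raw))
      names(raw)[names(raw) == short] <- lng
  }
  arms <- lapply(names(suf), function(a) {
    cols <- paste0(.agg_fields, suf[[a]])
    found <- cols %in% names(raw)
    d <- data.frame(study = raw$study, arm = a, stringsAsFactors = FALSE)
    for (k in seq_along(.agg_fields))
      d[[.agg_fields[k]]] <- if (found[k]) raw[[cols[k]]] else NA_real_
    if ("se_diff_change" %in% names(raw))
      d$se_diff_change <- raw$se_diff_change
    d
  })
  out <- do.call(rbind, arms)
  out[order(match(out$study, raw$study)), ]
}

#' Write aggregate data to a delimited file
#'
#' Long layout, canonical column names, full floating-point precision so that
#' a write/read round trip returns an equal object.
#'
#' @param x a [meta_aggregate()].
#' @param file destination path.
#' @param sep field separator (default comma).
#' @return `file`, invisibly.
#' @export
write_aggregate <- function(x, file, sep = ",") {
  stopifnot(inherits(x, "meta_aggregate"))
  out <- as.data.frame(x)
  for (f in .agg_fields) out[[f]] <- .fmt_num(out[[f]])
  write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(file)
}

.fmt_num <- function(x) {
  s <- vapply(x, function(v) if (is.na(v)) "" else sprintf("%.17g", v), "")
  s
}

#' Baseline--follow-up correlation from the change-score SD
#'
#' Recovers the within-arm correlation of baseline and follow-up measurements
#' from the three reported standard deviations:
#' \deqn{r = (sd_B^2 + sd_F^2 - sd_{change}^2) / (2 sd_B sd_F)}
#'
#' @param sd_base,sd_final,sd_change positive standard deviations in outcome
#'   units.
#' @return The correlation, strictly inside (-1, 1). Values outside, or within
#'   1e-9 of the boundary, signal an inconsistency error: no joint
#'   distribution has those three SDs.
#' @seealso [sd_change_from_corr()] for the inverse, [corr_from_se_diff()]
#' @export
corr_from_change_sd <- function(sd_base, sd_final, sd_change) {
  stopifnot(all(sd_base > 0), all(sd_final > 0), all(sd_change >= 0))
  r <- (sd_base^2 + sd_final^2 - sd_change^2) / (2 * sd_base * sd_final)
  bad <- abs(r) >= 1 - .corr_eps
  if (any(bad))
    stop("reported SDs are incompatible with any joint distribution ",
         "(implied correlation ", paste(signif(r[bad], 6), collapse = ", "),
         ")", call. = FALSE)
  r
}

#' Change-score SD implied by the baseline--follow-up correlation
#'
#' @param sd_base,sd_final positive standard deviations.
#' @param corr correlation strictly inside (-1, 1).
#' @return `sqrt(sd_base^2 + sd_final^2 - 2 corr sd_base sd_final)`.
#' @export
sd_change_from_corr <- function(sd_base, sd_final, corr) {
  stopifnot(all(sd_base > 0), all(sd_final > 0), all(abs(corr) < 1))
  sqrt(sd_base^2 + sd_final^2 - 2 * corr * sd_base * sd_final)
}

#' Shared correlation from the SE of the difference in mean change
#'
#' When only the standard error of the between-group difference in mean
#' change scores is reported, and the baseline--follow-up correlation is
#' assumed equal in the two arms, the shared correlation is
#' \deqn{r = \frac{sd_{BT}^2/n_T + sd_{FT}^2/n_T + sd_{BC}^2/n_C +
#'   sd_{FC}^2/n_C - se_{diff}^2}{2 sd_{BT} sd_{FT}/n_T +
#'   2 sd_{BC} sd_{FC}/n_C}}
#'
#' @param treated,control lists (or named vectors) with elements `n`,
#'   `sd_base`, `sd_final` for each arm.
#' @param se_diff_change positive standard error of the difference in mean
#'   change.
#' @return The shared correlation, strictly inside (-1, 1); inconsistent
#'   inputs signal an error.
#' @export
corr_from_se_diff <- function(treated, control, se_diff_change) {
  tr <- as.list(treated); ct <- as.list(control)
  stopifnot(tr$n >= 3, ct$n >= 3, tr$sd_base > 0, tr$sd_final > 0,
            ct$sd_base > 0, ct$sd_final > 0, se_diff_change > 0)
  num <- tr$sd_base^2 / tr$n + tr$sd_final^2 / tr$n +
    ct$sd_base^2 / ct$n + ct$sd_final^2 / ct$n - se_diff_change^2
  den <- 2 * tr$sd_base * tr$sd_final / tr$n +
    2 * ct$sd_base * ct$sd_final / ct$n
  r <- num / den
  if (abs(r) >= 1 - .corr_eps)
    stop("reported summaries are incompatible with any joint distribution ",
         "(implied correlation ", signif(r, 6), ")", call. = FALSE)
  r
}

#' Fill in missing correlations from reported alternatives
#'
#' Arms lacking a direct correlation get one recovered from the change-score
#' SD (per arm) or, failing that, from the study-level standard error of the
#' difference in mean change (shared between the two arms, which that formula
#' assumes). When both routes are available the preferred one is used; the
#' two are deliberately never averaged or auto-selected against each other.
#'
#' @param x a [meta_aggregate()].
#' @param prefer which recovery route to try first.
#' @return `x` with `corr` completed on every arm (or an error naming the
#'   study that has no usable route).
#' @export
recover_correlations <- function(x, prefer = c("sd_change", "se_diff")) {
  stopifnot(inherits(x, "meta_aggregate"))
  prefer <- match.arg(prefer)
  for (s in unique(x$study)) {
    i <- which(x$study == s)
    for (route in if (prefer == "sd_change") c("sd", "se") else c("se", "sd")) {
      todo <- i[is.na(x$corr[i])]
      if (!length(todo)) break
      if (route == "sd") {
        ok <- todo[!is.na(x$sd_change[todo])]
        if (length(ok))
          x$corr[ok] <- corr_from_change_sd(x$sd_base[ok], x$sd_final[ok],
                                            x$sd_change[ok])
      } else {
        se <- unique(x$se_diff_change[i])
        se <- se[!is.na(se)]
        if (length(se) == 1L) {
          it <- i[x$arm[i] == "treated"]; ic <- i[x$arm[i] == "control"]
          r <- corr_from_se_diff(
            list(n = x$n[it], sd_base = x$sd_base[it], sd_final = x$sd_final[it]),
            list(n = x$n[ic], sd_base = x$sd_base[ic], sd_final = x$sd_final[ic]),
            se)
          x$corr[todo] <- r
        }
      }
    }
    if (anyNA(x$corr[i]))
      stop("study ", s, ": correlation missing and not recoverable from ",
           "sd_change or se_diff_change", call. = FALSE)
  }
  validate_meta_aggregate(x, require_corr = TRUE)
  x
}

#' Shift treated-arm means to induce (or undo) baseline imbalance
#'
#' Adds the given amount to the treated arm's baseline and follow-up means of
#' the named studies, leaving SDs, sample sizes, correlations and all control
#' arms untouched. Change-score summaries are invariant under any such shift;
#' it is the covariate-adjusted analyses that react to the induced imbalance.
#'
#' @param x a [meta_aggregate()].
#' @param shifts named numeric vector, study id -> shift in outcome units
#'   (negative values lower the treated-arm means).
#' @return The shifted `meta_aggregate`.
#' @export
apply_baseline_shift <- function(x, shifts) {
  stopifnot(inherits(x, "meta_aggregate"), is.numeric(shifts))
  if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
    stop("shifts must be a named vector of study ids", call. = FALSE)
  unknown <- setdiff(names(shifts), unique(x$study))
  if (length(unknown))
    stop("shift given for unknown study id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  for (s in names(shifts)) {
    i <- which(x$study == s & x$arm == "treated")
    x$mean_base[i] <- x$mean_base[i] + shifts[[s]]
    x$mean_final[i] <- x$mean_final[i] + shifts[[s]]
  }
  x
}

#' The ten-trial hypertension aggregate dataset
#'
#' Aggregate systolic blood pressure (SBP, mmHg) data of 10 randomized trials
#' of antihypertensive treatment versus placebo/no treatment: per-arm sample
#' size, baseline and final mean (SD), and the within-arm correlation between
#' baseline and final SBP. The 20 arms total 28,580 patients. The `shifted`
#' variant applies the artificial baseline-imbalance construction: treated-arm
#' baseline and final means lowered by 5 mmHg (ATMH, HEP), 20 mmHg (HDFP,
#' MRC-1) and 10 mmHg (MRC-2), so that five studies have lower baseline
#' values in the treated group.
#'
#' @param shifted apply the artificial treated-arm mean shifts.
#' @return A [meta_aggregate()] of the 10 trials.
#' @seealso [hypertension_shifts()]
#' @export
hypertension_trials <- function(shifted = FALSE) {
  path <- system.file("extdata", "hypertension_trials.csv",
                      package = "pseudoIPD", mustWork = TRUE)
  x <- read_aggregate(path, layout = "wide",
                      outcome_label = "systolic blood pressure",
                      outcome_units = "mmHg")
  if (shifted) x <- apply_baseline_shift(x, hypertension_shifts())
  x
}

#' Treated-arm mean shifts defining the imbalanced hypertension dataset
#'
#' @return Named numeric vector of shifts (mmHg) for the five modified
#'   trials, suitable for [apply_baseline_shift()].
#' @export
hypertension_shifts <- function() {
  c(ATMH = -5, HEP = -5, HDFP = -20, `MRC-1` = -20, `MRC-2` = -10)
}

#' @export
print.meta_aggregate <- function(x, ...) {
  cat(sprintf("Aggregate data: %d studies, %d arms, %s patients (%s%s)\n",
              length(unique(x$study)), nrow(x),
              format(sum(x$n), big.mark = ","),
              attr(x, "outcome_label") %||% "outcome",
              if (nzchar(attr(x, "outcome_units") %||% ""))
                paste0(", ", attr(x, "outcome_units")) else ""))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
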