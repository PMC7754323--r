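#' Generate pseudo subject-level records for one study arm
#'
#' Constructs `n` (baseline, follow-up) pairs whose *sample* mean, SD (n-1
#' denominator) and Pearson correlation equal the supplied aggregates
#' exactly, up to floating point. Because those six numbers are the
#' sufficient statistics of the ANCOVA linear mixed model, any
#' likelihood-based fit of such a model to the pseudo records reproduces the
#' fit to the unobserved true records.
#'
#' The construction: draw two n-vectors from the base distribution;
#' standardize each to sample mean 0 and sample SD 1; regress the second on
#' the first and keep the residuals \eqn{\hat\epsilon} (exactly orthogonal to
#' the first vector, sample variance \eqn{1 - r^{*2}} where \eqn{r^*} is the
#' realized sample correlation); form
#' \eqn{Y_3^* = r Y_1^* + \hat\epsilon \sqrt{(1 - r^2)/(1 - r^{*2})}},
#' the unique rescaling with sample variance 1 and sample correlation exactly
#' `r` with \eqn{Y_1^*}; then destandardize with the target means and SDs.
#'
#' @param n number of subjects (>= 3).
#' @param mean_base,sd_base,mean_final,sd_final target sample moments
#'   (SDs > 0).
#' @param corr target sample correlation, strictly inside (-1, 1).
#' @param base base distribution for the initial draws: `"normal"`,
#'   `"uniform"`, or a function of `n` returning `n` numbers. All downstream
#'   likelihood-based estimates are invariant to this choice; only the
#'   moments enter the likelihood.
#' @param max_retry redraw budget for the measure-zero event that the two
#'   standardized draws are numerically collinear.
#' @return Data frame with columns `y_base`, `y_final`.
#' @export
generate_arm <- function(n, mean_base, sd_base, mean_final, sd_final, corr,
                         base = "normal", max_retry = 10L) {
  if (n < 3) stop("n must be >= 3 for exact moment matching", call. = FALSE)
  stopifnot(sd_base > 0, sd_final > 0, abs(corr) < 1)
  rdist <- if (is.function(base)) base else switch(
    base,
    normal = rnorm,
    uniform = function(n) runif(n),
    stop("unknown base distribution: ", base, call. = FALSE))
  for (try in seq_len(max_retry)) {
    y1 <- rdist(n); y2 <- rdist(n)
    s1 <- sd(y1); s2 <- sd(y2)
    if (s1 == 0 || s2 == 0) next
    y1 <- (y1 - mean(y1)) / s1
    y2 <- (y2 - mean(y2)) / s2
    rstar <- cor(y1, y2)
    if (abs(rstar) < 1 - 1e-12) {
      eps <- y2 - rstar * y1
      y3 <- corr * y1 + eps * sqrt((1 - corr^2) / (1 - rstar^2))
      return(data.frame(y_base = y1 * sd_base + mean_base,
                        y_final = y3 * sd_final + mean_final))
    }
  }
  stop("degenerate base draws after ", max_retry, " attempts", call. = FALSE)
}

#' Generate a pseudo-IPD dataset from aggregate data
#'
#' Runs [generate_arm()] for every (study, arm) cell of a [meta_aggregate()]
#' and stacks the results. Each arm uses its own random substream derived
#' deterministically from the master seed and the (study id, arm) labels, so
#' adding or removing a study leaves every other arm's records unchanged.
#' The caller's RNG state is left untouched.
#'
#' @param data a [meta_aggregate()]; every arm must have a correlation
#'   (recover missing ones first with [recover_correlations()]).
#' @param seed master integer seed, recorded in the provenance attribute.
#' @inheritParams generate_arm
#' @return Data frame of class `c("pseudo_ipd", "ipd")` with columns `study`,
#'   `arm`, `trt` (0/1), `y_base`, `y_final`, and attributes
#'   `provenance = list(seed, base_distribution, generator_version)`,
#'   `outcome_label`, `outcome_units`.
#' @export
generate_pseudo_ipd <- function(data, seed = 1L, base = "normal") {
  stopifnot(inherits(data, "meta_aggregate"))
  validate_meta_aggregate(data, require_corr = TRUE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  parts <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    w <- data[i, ]
    set.seed(.arm_seed(seed, w$study, w$arm))
    rec <- tryCatch(
      generate_arm(w$n, w$mean_base, w$sd_base, w$mean_final, w$sd_final,
                   w$corr, base = base),
      error = function(e) stop("study ", w$study, ", ", w$arm, " arm: ",
                               conditionMessage(e), call. = FALSE))
    parts[[i]] <- data.frame(study = w$study, arm = w$arm,
                             trt = as.integer(w$arm == "treated"), rec,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$study <- factor(out$study, levels = unique(data$study))
  class(out) <- c("pseudo_ipd", "ipd", "data.frame")
  attr(out, "provenance") <- list(
    seed = seed,
    base_distribution = if (is.function(base)) "user function" else base,
    generator_version = as.character(utils::packageVersion("pseudoIPD")))
  attr(out, "outcome_label") <- attr(data, "outcome_label")
  attr(out, "outcome_units") <- attr(data, "outcome_units")
  out
}

# Deterministic substream seed from (master seed, study id, arm label).
# A small string hash keeps arms independent of their position in the table.
.arm_seed <- function(seed, study, arm) {
  h <- 5381
  for (b in utf8ToInt(paste0(study, "\r", arm)))
    h <- (h * 33 + b) %% 2147483647
  as.integer((h * 48271 + as.numeric(seed) * 69621) %% 2147483647)
}

#' Write / read subject-level records as delimited text
#'
#' Round-trip safe at full floating-point precision. Columns: `study`, `arm`,
#' `trt`, `y_base`, `y_final`.
#'
#' @param x an `ipd` data frame ([generate_pseudo_ipd()], [simulate_ipd()]).
#' @param file path.
#' @param sep field separator.
#' @return `write_ipd()`: `file`, invisibly. `read_ipd()`: the `ipd` data
#'   frame.
#' @export
write_ipd <- function(x, file, sep = ",") {
  stopifnot(inherits(x, "ipd"))
  out <- data.frame(study = as.character(x$study), arm = x$arm, trt = x$trt,
                    y_base = sprintf("%.17g", x$y_base),
                    y_final = sprintf("%.17g", x$y_final))
  write.table(out, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(file, sep = ",") {
  d <- read.table(file, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  need <- c("study", "arm", "trt", "y_base", "y_final")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$study <- factor(d$study, levels = unique(d$study))
  d$arm <- .normalize_arm(d$arm)
  d$trt <- as.integer(d$trt)
  class(d) <- c("ipd", "data.frame")
  d
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat(sprintf(
    "Pseudo IPD: %s records, %d studies (seed %s, %s base)\n",
    format(nrow(x), big.mark = ","), nlevels(x$study),
    pv$seed, pv$base_distribution))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
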