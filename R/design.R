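#' Build model matrices and centering metadata for a one-stage fit
#'
#' Prepares the data columns and design matrices the one-stage ANCOVA models
#' share: the baseline covariate centered on each study's observed baseline
#' mean (both arms combined), the 0/1 treatment indicator, the within-trial
#' interaction column (centered baseline x treatment) and the single
#' across-trial column (study mean baseline x treatment), plus per-study
#' stratification columns when the study level is stratified.
#'
#' @param ipd an `ipd` data frame (columns `study`, `arm`, `trt`, `y_base`,
#'   `y_final`).
#' @param spec a [model_spec()].
#' @return A list with the augmented data (`data`), fixed-effects formula and
#'   matrix (`fixed`, `X`), random-effects formula and matrix (`random`,
#'   `Z`, `NULL`-able), residual grouping (`resid_group`, `sig_levels`,
#'   `sig_index`), the centering means (`centers`), and bookkeeping used by
#'   [reml_objective()].
#' @export
build_design <- function(ipd, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- as.data.frame(ipd)
  need <- c("study", "arm", "trt", "y_base", "y_final")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("ipd lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  d$study <- droplevels(as.factor(d$study))
  N <- nlevels(d$study)
  if (N < 2 && spec$level == "random_study")
    stop("random-study models need at least 2 studies", call. = FALSE)
  both <- tapply(d$trt, d$study, function(x) length(unique(x)))
  if (any(both < 2))
    stop("study with a single arm: ",
         paste(names(both)[both < 2], collapse = ", "), call. = FALSE)
  con <- tapply(d$y_base, d$study, function(x) var(x) == 0)
  if (any(con))
    stop("constant baseline within study ",
         paste(names(con)[con], collapse = ", "),
         ": baseline slope unidentifiable", call. = FALSE)

  centers <- vapply(split(d$y_base, d$study), mean, 0)
  d$mb <- centers[as.character(d$study)]
  d$cb <- d$y_base - d$mb
  d$cell <- factor(paste(d$study, d$arm, sep = "/"))
  d$trt_r <- if (spec$center_groups) d$trt - 0.5 else d$trt
  d$cbtrt <- d$cb * d$trt
  d$cbtrt_r <- d$cb * d$trt_r
  d$mbtrt <- d$mb * d$trt

  inter_cols <- if (spec$interaction) {
    if (spec$across_trial) "+ cbtrt + mbtrt" else "+ cbtrt"
  } else ""
  fixed <- if (spec$level == "stratified_study" && N > 1)
    stats::as.formula(paste("y_final ~ 0 + study + study:cb + trt", inter_cols))
  else
    stats::as.formula(paste("y_final ~ cb + trt", inter_cols))

  random <- NULL
  if (spec$level == "stratified_study") {
    if (spec$treatment_random && spec$interaction)
      random <- ~ 0 + trt + cbtrt
    else if (spec$treatment_random)
      random <- ~ 0 + trt
    else if (spec$interaction)
      random <- ~ 0 + cbtrt
  } else {
    terms <- c("trt_r"[spec$treatment_random], "cb",
               "cbtrt_r"[spec$interaction])
    random <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  }

  resid_group <- switch(spec$residual_structure,
    by_study_arm = d$cell,
    by_study = d$study,
    by_arm = factor(d$arm),
    pooled = factor(rep("all", nrow(d))))
  sig_levels <- levels(droplevels(resid_group))
  # sigma index per (study, arm) cell
  cell_info <- unique(data.frame(cell = d$cell, study = d$study, arm = d$arm))
  grp_of_cell <- switch(spec$residual_structure,
    by_study_arm = as.character(cell_info$cell),
    by_study = as.character(cell_info$study),
    by_arm = as.character(cell_info$arm),
    pooled = rep("all", nrow(cell_info)))
  sig_index <- setNames(match(grp_of_cell, sig_levels),
                        as.character(cell_info$cell))

  X <- model.matrix(fixed, d)
  Z <- if (!is.null(random)) model.matrix(random, d) else NULL
  list(data = d, fixed = fixed, random = random, X = X, Z = Z, y = d$y_final,
       q = if (is.null(Z)) 0L else ncol(Z), p = ncol(X),
       n = nrow(d), n_studies = N, studies = levels(d$study),
       resid_group = resid_group, sig_levels = sig_levels,
       sig_index = sig_index, centers = centers, spec = spec)
}
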