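#' Restricted log-likelihood from per-cell sufficient statistics
#'
#' Returns the exact REML objective of the model described by a design
#' (from [build_design()]) as a closed function of the variance parameters,
#' computed from per-(study, arm) cross-product matrices rather than the raw
#' rows. That the objective depends on the data only through those
#' cross-products is the sufficiency property the pseudo-IPD construction
#' exploits; numerically, it also makes each evaluation cost independent of
#' the number of subjects.
#'
#' The parameter vector `theta` stacks (1) the random-effects covariance:
#' for an unstructured \eqn{\Psi}, the log-Cholesky factor column by column
#' (log of each diagonal entry, then the free below-diagonal entries); for
#' independent random effects, one log-SD per effect; and (2) one log
#' residual SD per residual variance group, in `design$sig_levels` order.
#'
#' @param design result of [build_design()].
#' @return A list: `loglik(theta)` the restricted log-likelihood (all
#'   normalizing constants included); `gls(theta)` the generalized
#'   least-squares fixed effects and their covariance at those variance
#'   parameters; `psi(theta)` the implied random-effects covariance matrix;
#'   `sigma(theta)` the residual SD per group; `npar`, `npsi`, `nsig` the
#'   parameter counts; `fixed_names` the coefficient names.
#' @export
reml_objective <- function(design) {
  q <- design$q; p <- design$p
  cov_type <- design$spec$random_effects_cov
  npsi <- if (q == 0L) 0L else if (q == 1L || cov_type == "independent") q
          else q * (q + 1L) / 2L
  nsig <- length(design$sig_levels)
  # The restricted likelihood is exactly invariant under y -> y - c when the
  # constant is in the span of the fixed design (intercept / study dummies),
  # so evaluate with the outcome centered: same value, far better
  # conditioned cross-products. The GLS intercepts are shifted back below.
  c_y <- mean(design$y)
  icpt <- if (any(grepl("^study", colnames(design$X))))
    grep("^study[^:]*$", colnames(design$X)) else
      which(colnames(design$X) == "(Intercept)")
  W <- cbind(design$X, design$Z, design$y - c_y)
  cellf <- design$data$cell
  studyf <- design$data$study
  cp <- lapply(design$studies, function(s) {
    cells <- unique(as.character(cellf[studyf == s]))
    lapply(cells, function(cl) {
      rows <- which(cellf == cl)
      list(M = crossprod(W[rows, , drop = FALSE]), n = length(rows),
           sig = design$sig_index[[cl]])
    })
  })
  names(cp) <- design$studies

  chol_psi <- function(theta) {
    if (q == 0L) return(NULL)
    L <- matrix(0, q, q)
    if (q == 1L || cov_type == "independent") {
      diag(L) <- exp(theta[seq_len(q)])
    } else {
      k <- 1L
      for (j in seq_len(q)) {
        L[j, j] <- exp(theta[k]); k <- k + 1L
        if (j < q) {
          L[(j + 1L):q, j] <- theta[k:(k + q - j - 1L)]
          k <- k + q - j
        }
      }
    }
    L
  }

  core <- function(theta) {
    L <- chol_psi(theta)
    lsig <- theta[npsi + seq_len(nsig)]
    iX <- seq_len(p); iZ <- p + seq_len(q); iy <- p + q + 1L
    ld <- 0; G <- matrix(0, p, p); g <- numeric(p); q0 <- 0; n <- 0L
    for (s in design$studies) {
      S <- 0
      for (e in cp[[s]]) {
        s2 <- exp(2 * lsig[e$sig])
        S <- S + e$M / s2
        ld <- ld + e$n * 2 * lsig[e$sig]
        n <- n + e$n
      }
      A <- S[c(iX, iy), c(iX, iy), drop = FALSE]
      if (q > 0L) {
        K <- diag(q) + t(L) %*% S[iZ, iZ, drop = FALSE] %*% L
        Kc <- chol(K)
        AZL <- S[c(iX, iy), iZ, drop = FALSE] %*% L
        A <- A - AZL %*% chol2inv(Kc) %*% t(AZL)
        ld <- ld + 2 * sum(log(diag(Kc)))
      }
      G <- G + A[iX, iX]; g <- g + A[iX, p + 1L]; q0 <- q0 + A[p + 1L, p + 1L]
    }
    Gc <- chol(G)
    beta <- backsolve(Gc, forwardsolve(t(Gc), g))
    list(G = G, Gc = Gc, beta = beta, rss = q0 - sum(g * beta), ld = ld,
         n = n)
  }

  list(
    loglik = function(theta) {
      cr <- core(theta)
      unname(-0.5 * ((cr$n - p) * log(2 * pi) + cr$ld +
                       2 * sum(log(diag(cr$Gc))) + cr$rss))
    },
    gls = function(theta) {
      cr <- core(theta)
      beta <- as.numeric(cr$beta)
      names(beta) <- colnames(design$X)
      beta[icpt] <- beta[icpt] + c_y
      vb <- chol2inv(cr$Gc)
      dimnames(vb) <- list(colnames(design$X), colnames(design$X))
      list(beta = beta, vbeta = vb)
    },
    psi = function(theta) {
      L <- chol_psi(theta)
      if (is.null(L)) NULL else tcrossprod(L)
    },
    sigma = function(theta)
      setNames(exp(theta[npsi + seq_len(nsig)]), design$sig_levels),
    npar = npsi + nsig, npsi = npsi, nsig = nsig,
    log_coords = c(if (npsi > 0L) .psi_log_coords(q, cov_type),
                   rep(TRUE, nsig)),
    sd_y = sd(design$y),
    fixed_names = colnames(design$X))
}

# Which coordinates of the Psi parametrization are log-SDs (as opposed to
# free off-diagonal Cholesky entries)?
.psi_log_coords <- function(q, cov_type) {
  if (q == 1L || cov_type == "independent") return(rep(TRUE, q))
  unlist(lapply(seq_len(q), function(j) c(TRUE, rep(FALSE, q - j))))
}

# Tight local refinement of the variance parameters from the optimizer's
# stopping point. The restricted likelihood can be extremely flat in the
# between-study variance (few studies), where generic stopping rules leave
# O(1e-2) slack in tau^2; a final nlminb pass on the sufficient-statistic
# objective localizes the optimum to numerical precision, which is what
# makes two fits on datasets with equal sufficient statistics agree to
# ~1e-6 on every reported quantity.
.polish_theta <- function(obj, theta) {
  f <- function(th) {
    v <- tryCatch(-obj$loglik(th), error = function(e) Inf)
    if (!is.finite(v)) Inf else v
  }
  gr <- function(th) tryCatch(-pracma::grad(obj$loglik, th),
                              error = function(e) rep(NA_real_, length(th)))
  o <- tryCatch(
    stats::nlminb(theta, f, gradient = gr,
                  control = list(rel.tol = 1e-14, x.tol = 1e-12,
                                 iter.max = 500, eval.max = 2000)),
    error = function(e) NULL)
  if (is.null(o) || !is.finite(o$objective) || o$objective > f(theta))
    return(list(theta = theta, ok = FALSE))
  th <- o$par
  # A variance component on its zero boundary sends its log-SD to -Inf along
  # a direction the likelihood is exactly flat in; pin such coordinates at a
  # canonical negligible value (SD ~ 2e-8 of the outcome SD) and refine only
  # the free ones -- otherwise the flat direction makes the Hessian singular.
  pinval <- log(max(obj$sd_y, .Machine$double.eps)) - 18
  pinned <- obj$log_coords & th < log(obj$sd_y) - 12
  th[pinned] <- pinval
  # Likelihood-ratio zero test for the remaining variance components: a
  # component whose removal costs less than 1e-7 log-likelihood is
  # statistically indistinguishable from zero, and leaving it to wander on
  # the flat boundary approach would make the reported value depend on where
  # the optimizer happened to stop.
  for (k in which(obj$log_coords & !pinned)) {
    cand <- th; cand[k] <- pinval
    if (f(cand) <= f(th) + 1e-7) {
      th <- cand; pinned[k] <- TRUE
    }
  }
  free <- which(!pinned)
  # a few damped Newton steps localize the optimum to the numerical floor;
  # the flattest ridge directions are where generic stopping rules give up
  if (length(free)) for (it in 1:6) {
    g <- gr(th)[free]
    if (anyNA(g) || max(abs(g)) < 1e-8) break
    H <- tryCatch(pracma::hessian(function(x) {
      t2 <- th; t2[free] <- x; -obj$loglik(t2)
    }, th[free]), error = function(e) NULL)
    if (is.null(H)) break
    step <- tryCatch(solve(H + diag(1e-8, length(free)), g),
                     error = function(e) NULL)
    if (is.null(step) || anyNA(step)) break
    lam <- 1
    repeat {
      cand <- th; cand[free] <- th[free] - lam * step
      if (f(cand) <= f(th) + 1e-12) { th <- cand; break }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (lam < 1e-4) break
  }
  list(theta = th, ok = TRUE, pinned = pinned)
}

# Variance parameters of a fitted lme/gls object on the reml_objective
# parametrization (log-Cholesky / log-SD for Psi, log residual SD per group).
.theta_from_fit <- function(fit, design) {
  q <- design$q
  cov_type <- design$spec$random_effects_cov
  th_psi <- numeric(0)
  if (q > 0L) {
    psi <- .psi_matrix(fit, q)
    if (q == 1L || cov_type == "independent") {
      th_psi <- log(sqrt(pmax(diag(psi), 1e-20)))
    } else {
      L <- t(chol(psi + diag(1e-12 * max(diag(psi), 1e-12), q)))
      th_psi <- numeric(0)
      for (j in seq_len(q)) {
        th_psi <- c(th_psi, log(L[j, j]))
        if (j < q) th_psi <- c(th_psi, L[(j + 1L):q, j])
      }
    }
  }
  sig <- .resid_sd_by_group(fit, design)
  c(th_psi, log(sig))
}

.psi_matrix <- function(fit, q) {
  psi <- as.matrix(nlme::getVarCov(fit))
  stopifnot(nrow(psi) == q)
  psi
}

# residual SD per residual-variance group, in design$sig_levels order
.resid_sd_by_group <- function(fit, design) {
  sig <- fit$sigma
  lv <- design$sig_levels
  if (length(lv) == 1L) return(setNames(sig, lv))
  vs <- fit$modelStruct$varStruct
  mult <- coef(vs, unconstrained = FALSE, allCoef = TRUE)
  out <- setNames(sig * mult[lv], lv)
  if (anyNA(out)) stop("could not map residual variance groups")
  out
}

#' Satterthwaite degrees of freedom for a fixed effect
#'
#' Approximates the degrees of freedom of a fixed-effect t-statistic by
#' matching the first two moments of its squared standard error: the REML
#' information matrix of the variance parameters (numeric Hessian of
#' [reml_objective()]'s restricted log-likelihood) gives the variance of the
#' variance-parameter estimates, and the delta method propagates it to
#' \eqn{\widehat{se}^2}. The result is invariant to the (smooth)
#' parametrization of the variance parameters.
#'
#' @param design a [build_design()] result.
#' @param theta variance parameters on the [reml_objective()] scale.
#' @param coef_name name of the fixed effect.
#' @return Degrees of freedom (may be `NA` if the information matrix is
#'   numerically singular, e.g. at a variance boundary).
#' @export
satterthwaite_df <- function(design, theta, coef_name) {
  obj <- reml_objective(design)
  k <- match(coef_name, obj$fixed_names)
  if (is.na(k)) stop("unknown coefficient: ", coef_name, call. = FALSE)
  g <- function(th) obj$gls(th)$vbeta[k, k]
  out <- tryCatch({
    H <- pracma::hessian(obj$loglik, theta)
    A <- solve(-H)
    gr <- pracma::grad(g, theta)
    vg <- drop(t(gr) %*% A %*% gr)
    if (!is.finite(vg) || vg <= 0) return(NA_real_)
    2 * g(theta)^2 / vg
  }, error = function(e) NA_real_)
  out
}
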