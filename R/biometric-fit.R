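# Maximum-likelihood estimation of the extended ACE model.
#
# Free parameters are unconstrained in sign (simplex + quasi-Newton on a
# penalized objective; infeasible implied covariances receive a large
# penalty rather than hard bounds).  Internally the measured blocks are
# parameterized by (log observed variance, liability loading, mean), a
# bijection of (p, sigma2_AP, mu) that keeps sigma2_AP = loading^2 * var
# structurally nonnegative while leaving A_B, C and covAC free.

#' Model flags for the extended ACE fit
#'
#' @param model shorthand: `"ace"`, `"ae"`, `"ace_prs"`, `"ae_prs"`,
#'   `"ae_prs_e4"`, `"ace_prs_e4"`.
#' @param include_prs,include_e4 measured components to include.
#' @param free_c,free_covac free the shared-environment variance and the
#'   total A-C covariance.
#' @param free_apc additionally free the A_P-C split of covAC (fragile
#'   identification; default puts all covAC on A_B).
#' @param covariates cohort columns entering the liability mean.
#' @param prs_col,e4_col cohort columns holding the measured scores.
#' @param ridge measurement-error variance added to each observed score
#'   (regularizes the model-implied singular MZ twin block as an
#'   alternative to the default pair-level collapse; default 0).
#' @return list of class `biometric_model`.
#' @export
biometric_model <- function(model = NULL,
                            include_prs = FALSE, include_e4 = FALSE,
                            free_c = TRUE, free_covac = FALSE,
                            free_apc = FALSE,
                            covariates = c("sex", "cage", "cage2"),
                            prs_col = "zprs", e4_col = "ze4", ridge = 0) {
  if (!is.null(model)) {
    model <- match.arg(model, c("ace", "ae", "ace_prs", "ae_prs",
                                "ae_prs_e4", "ace_prs_e4"))
    include_prs <- grepl("prs", model)
    include_e4 <- grepl("e4", model)
    free_c <- grepl("^ace", model)
    free_covac <- free_c && include_prs   # baseline ACE has no covAC path
  }
  stopifnot_scalar(ridge, "ridge", 0)
  structure(list(include_prs = include_prs, include_e4 = include_e4,
                 free_c = free_c, free_covac = free_covac,
                 free_apc = free_apc, covariates = covariates,
                 prs_col = prs_col, e4_col = e4_col, ridge = ridge),
            class = "biometric_model")
}

# Free parameter names for a model (before `fixed` removals).
free_param_names <- function(flags) {
  c(if (flags$include_prs) c("log_vP", "lam_P", "mu_P"),
    if (flags$include_e4) c("log_vE4", "lam_E4", "mu_E4"),
    "sigma2_AB",
    if (flags$free_c) "sigma2_C",
    if (flags$free_covac) "sigma_AC",
    if (flags$free_apc) "sigma_APC",
    "b0", paste0("b_", flags$covariates))
}

# theta (named vector) -> biometric_params
theta_to_params <- function(theta, flags, covariates) {
  g <- function(nm, default = 0) if (nm %in% names(theta)) theta[[nm]] else default
  vP <- exp(g("log_vP", -Inf)); lamP <- g("lam_P")
  vE4 <- exp(g("log_vE4", -Inf)); lamE4 <- g("lam_E4")
  sAC <- g("sigma_AC"); sAPC <- g("sigma_APC")
  s2AP <- if (flags$include_prs) lamP^2 * vP else 0
  s2E4 <- if (flags$include_e4) lamE4^2 * vE4 else 0
  p <- if (flags$include_prs && lamP != 0) 1 / lamP else 1
  q <- if (flags$include_e4 && lamE4 != 0) 1 / lamE4 else 1
  # degenerate zero-loading case: keep var(PRS) = vP via sigma2_AP -> 0, p -> Inf
  # handled by direct construction below instead of biometric_params algebra
  pp <- biometric_params(
    sigma2_AP = s2AP, p = p, sigma2_Ae4 = s2E4, q = q,
    sigma2_AB = g("sigma2_AB"), sigma2_C = g("sigma2_C"),
    sigma_APC = sAPC, sigma_ABC = sAC - sAPC,
    beta = setNames(c(g("b0"), vapply(covariates, function(cc)
      g(paste0("b_", cc)), 0)), c("intercept", covariates)),
    mu_prs = g("mu_P"), mu_e4 = g("mu_E4"),
    include_prs = flags$include_prs, include_e4 = flags$include_e4)
  # stash raw measured-block quantities for exact zero-loading handling
  pp$vP <- vP; pp$lamP <- lamP; pp$vE4 <- vE4; pp$lamE4 <- lamE4
  pp
}

# Variant of collapsed_moments working directly on (vP, lamP, vE4, lamE4),
# which stays well defined at zero loadings (lam = 0 keeps var(PRS) = vP
# with no liability path).
collapsed_moments_raw <- function(pp, zygosity, ridge = 0) {
  rg <- if (zygosity == "MZ") 1 else 0.5
  vP <- if (pp$include_prs) pp$vP else 0
  vE4 <- if (pp$include_e4) pp$vE4 else 0
  s2AP <- if (pp$include_prs) pp$lamP^2 * pp$vP else 0
  s2E4 <- if (pp$include_e4) pp$lamE4^2 * pp$vE4 else 0
  pfac <- if (pp$include_prs && pp$lamP != 0) 1 / pp$lamP else 0
  cP_own <- if (pp$include_prs) pp$lamP * vP + pfac * pp$sigma_APC else 0
  cP_cross <- if (pp$include_prs) rg * pp$lamP * vP + pfac * pp$sigma_APC else 0
  cE_own <- if (pp$include_e4) pp$lamE4 * vE4 else 0
  cE_cross <- rg * cE_own
  rtw <- rg * (pp$sigma2_AB + s2AP + s2E4) + pp$sigma2_C + 2 * pp$sigma_AC
  SLL <- matrix(c(1, rtw, rtw, 1), 2, 2)
  if (!pp$include_prs && !pp$include_e4) {
    if (abs(rtw) >= 1 - 1e-10) return(list(feasible = FALSE, penalty = abs(rtw)))
    return(list(feasible = TRUE, d = 0L, Sc = SLL))
  }
  if (zygosity == "MZ") {
    d <- sum(pp$include_prs, pp$include_e4)
    SM <- diag(c(if (pp$include_prs) vP, if (pp$include_e4) vE4), nrow = d)
    SLM <- matrix(0, 2, d); j <- 1
    if (pp$include_prs) { SLM[, j] <- cP_own; j <- j + 1 }
    if (pp$include_e4) SLM[, j] <- cE_own
    muM <- c(if (pp$include_prs) pp$mu_prs, if (pp$include_e4) pp$mu_e4)
  } else {
    d <- 2L * sum(pp$include_prs, pp$include_e4)
    SM <- matrix(0, d, d); SLM <- matrix(0, 2, d); muM <- numeric(d); at <- 0
    if (pp$include_prs) {
      idx <- at + 1:2
      SM[idx, idx] <- matrix(c(vP, rg * vP, rg * vP, vP), 2, 2)
      SLM[, idx] <- matrix(c(cP_own, cP_cross, cP_cross, cP_own), 2, 2)
      muM[idx] <- pp$mu_prs; at <- at + 2
    }
    if (pp$include_e4) {
      idx <- at + 1:2
      SM[idx, idx] <- matrix(c(vE4, rg * vE4, rg * vE4, vE4), 2, 2)
      SLM[, idx] <- matrix(c(cE_own, cE_cross, cE_cross, cE_own), 2, 2)
      muM[idx] <- pp$mu_e4
    }
  }
  if (ridge > 0) {
    # measurement-error ridge: MZ rows carry the mean of two noisy scores
    diag(SM) <- diag(SM) + if (zygosity == "MZ") ridge / 2 else ridge
  }
  ch <- tryCatch(chol(SM), error = function(e) NULL)
  if (is.null(ch)) return(list(feasible = FALSE, penalty = 1 + sum(abs(SM))))
  SMinv <- chol2inv(ch)
  W <- SLM %*% SMinv
  Sc <- SLL - W %*% t(SLM)
  if (Sc[1, 1] <= 1e-10 || Sc[2, 2] <= 1e-10) {
    return(list(feasible = FALSE, penalty = 1 + abs(min(diag(Sc)))))
  }
  rho <- Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
  if (abs(rho) >= 1 - 1e-10) return(list(feasible = FALSE, penalty = abs(rho)))
  list(feasible = TRUE, d = d, SMinv = SMinv, W = W, Sc = Sc, muM = muM,
       logdet = 2 * sum(log(diag(ch))))
}

# Arrange complete pairs of a cohort into per-zygosity arrays.
biometric_data <- function(cohort, flags, use_singletons = FALSE) {
  cp <- complete_pairs(cohort)
  if (nrow(cp) == 0) stop("no complete pairs available")
  out <- list()
  for (z in c("MZ", "DZ")) {
    cz <- cp[cp$zygosity == z, , drop = FALSE]
    cz <- cz[order(cz$pair_id, cz$twin), , drop = FALSE]
    if (nrow(cz) == 0) { out[[z]] <- NULL; next }
    i1 <- seq(1, nrow(cz), 2); i2 <- i1 + 1
    Xc <- as.matrix(cz[, flags$covariates, drop = FALSE])
    M <- NULL
    if (flags$include_prs || flags$include_e4) {
      prs <- if (flags$include_prs) cz[[flags$prs_col]] else NULL
      e4 <- if (flags$include_e4) cz[[flags$e4_col]] else NULL
      if (flags$include_prs && is.null(prs))
        stop(sprintf("column `%s` not found in cohort", flags$prs_col))
      if (flags$include_e4 && is.null(e4))
        stop(sprintf("column `%s` not found in cohort", flags$e4_col))
      if (z == "MZ") {
        M <- cbind(if (flags$include_prs) (prs[i1] + prs[i2]) / 2,
                   if (flags$include_e4) (e4[i1] + e4[i2]) / 2)
      } else {
        M <- cbind(if (flags$include_prs) cbind(prs[i1], prs[i2]),
                   if (flags$include_e4) cbind(e4[i1], e4[i2]))
      }
    }
    out[[z]] <- list(y1 = cz$ad[i1], y2 = cz$ad[i2],
                     X1 = Xc[i1, , drop = FALSE], X2 = Xc[i2, , drop = FALSE],
                     M = M, n = length(i1))
  }
  if (all(vapply(out, is.null, TRUE))) stop("no complete pairs of either zygosity")
  out
}

biometric_negll <- function(theta, flags, dat) {
  pp <- theta_to_params(theta, flags, flags$covariates)
  nll <- 0
  for (z in names(dat)) {
    dz <- dat[[z]]
    if (is.null(dz)) next
    mom <- collapsed_moments_raw(pp, z, ridge = flags$ridge %||% 0)
    if (!mom$feasible) return(1e8 * (1 + mom$penalty))
    eta1 <- pp$beta[["intercept"]] +
      as.vector(dz$X1 %*% pp$beta[-1])
    eta2 <- pp$beta[["intercept"]] +
      as.vector(dz$X2 %*% pp$beta[-1])
    ll <- zyg_loglik(mom, dz$M, eta1, eta2, dz$y1, dz$y2)
    nll <- nll - sum(ll)
  }
  if (!is.finite(nll)) 1e10 else nll
}

# Deterministic moment-based start plus optional seeded jitters.
biometric_starts <- function(flags, dat, cohort, fixed, n_starts, seed) {
  cp <- complete_pairs(cohort)
  g0 <- suppressWarnings(glm(ad ~ ., family = binomial("probit"),
                             data = cbind(ad = cp$ad,
                                          cp[, flags$covariates, drop = FALSE])))
  b <- coef(g0)
  base <- c()
  if (flags$include_prs) {
    v <- var(cp[[flags$prs_col]]); m <- mean(cp[[flags$prs_col]])
    base <- c(base, log_vP = log(max(v, 1e-3)), lam_P = 0.25, mu_P = m)
  }
  if (flags$include_e4) {
    v <- var(cp[[flags$e4_col]]); m <- mean(cp[[flags$e4_col]])
    base <- c(base, log_vE4 = log(max(v, 1e-3)), lam_E4 = 0.25, mu_E4 = m)
  }
  base <- c(base, sigma2_AB = 0.5)
  if (flags$free_c) base <- c(base, sigma2_C = 0.05)
  if (flags$free_covac) base <- c(base, sigma_AC = 0)
  if (flags$free_apc) base <- c(base, sigma_APC = 0)
  base <- c(base, b0 = unname(b[1]),
            setNames(unname(b[-1]), paste0("b_", flags$covariates)))
  starts <- list(base)
  alt <- base
  alt["sigma2_AB"] <- 0.75
  if (flags$include_prs) alt["lam_P"] <- 0.1
  if (flags$include_e4) alt["lam_E4"] <- 0.1
  starts <- c(starts, list(alt))
  if (n_starts > 2) {
    starts <- c(starts, with_seed(derive_seed(seed, 77), {
      lapply(seq_len(n_starts - 2), function(i)
        base + rnorm(length(base), 0, 0.15))
    }))
  }
  lapply(starts[seq_len(n_starts)], function(st) {
    st <- st[setdiff(names(st), names(fixed))]
    st
  })
}

#' Fit the extended ACE liability-threshold model
#'
#' Maximum-likelihood estimation on complete twin pairs, unconstrained in
#' sign for the background, shared-environment and covariance components
#' (the unique-environment share is derived from the unit-variance
#' constraint).
#'
#' @param cohort a `twin_cohort`.
#' @param model a [biometric_model()] or shorthand string.
#' @param fixed named list of parameters to hold fixed (e.g.
#'   `list(lam_P = 0)` to drop the PRS liability path), used for nested
#'   model tests and profile confidence intervals.
#' @param n_starts number of optimization starts (deterministic base +
#'   alternative + seeded jitters).
#' @param se compute standard errors (numerical Hessian + delta method).
#' @param ci components for which to compute 95% profile-likelihood
#'   confidence intervals, or `NULL`.
#' @param seed seed for start jitter.
#' @param use_singletons reserved; singleton contributions are excluded
#'   (complete-pairs analysis).
#' @return an object of class `biometric_fit`: parameter estimates,
#'   standardized variance shares with SEs, -2 log-likelihood, AIC/BIC,
#'   profile CIs when requested, and convergence diagnostics.
#' @export
fit_biometric <- function(cohort, model = "ace", fixed = list(),
                          n_starts = 2, se = TRUE, ci = NULL, seed = 1,
                          use_singletons = FALSE) {
  flags <- if (inherits(model, "biometric_model")) model else
    biometric_model(model)
  dat <- biometric_data(cohort, flags, use_singletons)
  free_all <- free_param_names(flags)
  if (!all(names(fixed) %in% free_all)) {
    stop("`fixed` names must be free parameters of the model")
  }
  free <- setdiff(free_all, names(fixed))
  obj_raw <- function(th_named) {
    biometric_negll(th_named, flags, dat)
  }
  obj <- function(th_free) {
    th <- c(th_free, unlist(fixed))
    names(th) <- c(free, names(fixed))
    obj_raw(th)
  }
  starts <- biometric_starts(flags, dat, cohort, fixed, n_starts, seed)
  best <- NULL
  diag_starts <- list()
  for (st in starts) {
    st <- st[free]
    o1 <- tryCatch(
      nlminb(st, obj, control = list(rel.tol = 1e-11, iter.max = 800)),
      error = function(e) NULL)
    if (is.null(o1)) { diag_starts <- c(diag_starts, list("nlminb error")); next }
    o2 <- tryCatch(
      optim(o1$par, obj, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-12)),
      error = function(e) NULL)
    cand <- if (!is.null(o2) && o2$value < o1$objective) {
      list(par = o2$par, value = o2$value, conv = o2$convergence == 0)
    } else list(par = o1$par, value = o1$objective, conv = o1$convergence == 0)
    diag_starts <- c(diag_starts, list(cand$value))
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || best$value >= 1e8) {
    stop("all optimization starts failed; per-start values: ",
         paste(unlist(diag_starts), collapse = ", "))
  }
  theta <- setNames(best$par, free)
  m2ll <- 2 * best$value
  th_all <- c(theta, unlist(fixed)); names(th_all) <- c(free, names(fixed))
  pp <- theta_to_params(th_all, flags, flags$covariates)

  share_fun <- function(th_free) {
    th <- c(th_free, unlist(fixed)); names(th) <- c(free, names(fixed))
    q <- theta_to_params(th, flags, flags$covariates)
    s2AP <- if (flags$include_prs) q$lamP^2 * q$vP else 0
    s2E4 <- if (flags$include_e4) q$lamE4^2 * q$vE4 else 0
    sAC <- q$sigma_AC
    c(sigma2_AP = s2AP, sigma2_Ae4 = s2E4, sigma2_AB = q$sigma2_AB,
      sigma2_C = q$sigma2_C, covAC = sAC,
      sigma2_E = 1 - s2AP - s2E4 - q$sigma2_AB - q$sigma2_C - 2 * sAC,
      total_A = s2AP + s2E4 + q$sigma2_AB + 2 * sAC)
  }
  shares <- share_fun(theta)

  se_theta <- rep(NA_real_, length(theta))
  se_shares <- rep(NA_real_, length(shares))
  vcov_th <- NULL
  if (se) {
    H <- tryCatch(optimHess(theta, obj), error = function(e) NULL)
    if (!is.null(H)) {
      # obj is -logLik, so the inverse Hessian is the usual observed-
      # information covariance
      vcov_th <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov_th)) {
        se_theta <- sqrt(pmax(diag(vcov_th), 0))
        J <- numeric_jacobian(share_fun, theta)
        se_shares <- sqrt(pmax(diag(J %*% vcov_th %*% t(J)), 0))
      }
    }
  }
  names(se_shares) <- names(shares)
  k <- length(free) + 1L   # + derived E, matching SEM reporting convention
  n_pairs <- sum(vapply(dat, function(d) if (is.null(d)) 0L else d$n, 0L))
  crit <- fit_criteria_sem(m2ll, k, n_pairs)
  fit <- structure(list(
    theta = theta, se_theta = setNames(se_theta, free),
    params = pp, shares = shares, se_shares = se_shares,
    minus2LL = m2ll, logLik = -m2ll / 2, deviance = m2ll,
    k = k, n_pairs = n_pairs,
    aic = crit[["AIC"]], bic = crit[["BIC"]],
    flags = flags, fixed = fixed, free = free,
    objective = obj, objective_raw = obj_raw, vcov_theta = vcov_th,
    converged = best$conv, start_values = diag_starts
  ), class = "biometric_fit")
  if (!is.null(ci)) {
    fit$ci <- do.call(rbind, lapply(ci, function(comp)
      profile_ci(fit, comp)))
    rownames(fit$ci) <- ci
  }
  fit
}

numeric_jacobian <- function(f, x, h = 1e-5) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("Extended ACE liability model (%d complete pairs)\n", x$n_pairs))
  tab <- data.frame(Est = round(x$shares, 4), SE = round(x$se_shares, 4))
  print(tab)
  cat(sprintf("-2LL %.2f  k %d  AIC %.2f  BIC %.2f  converged %s\n",
              x$minus2LL, x$k, x$aic, x$bic, x$converged))
  if (!is.null(x$ci)) { cat("95% profile CIs:\n"); print(round(x$ci, 4)) }
  invisible(x)
}

#' Likelihood-ratio comparison of nested biometric models
#'
#' @param fit_full,fit_reduced `biometric_fit` objects on the same data; the
#'   reduced model's free parameters must be a subset of the full model's.
#' @return list of class `model_comparison` with `delta_chisq`, `df`, `p`
#'   and the dropped parameter names.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  if (!all(fit_reduced$free %in% fit_full$free)) {
    stop("models are not nested: reduced free parameters not a subset")
  }
  dropped <- setdiff(fit_full$free, fit_reduced$free)
  df <- length(dropped)
  if (df == 0) {
    return(structure(list(delta_chisq = 0, df = 0L, p = 1,
                          dropped = character(0)), class = "model_comparison"))
  }
  delta <- fit_reduced$minus2LL - fit_full$minus2LL
  if (delta < -1e-4) stop("reduced model fits better than full: check nesting/convergence")
  delta <- max(delta, 0)
  structure(list(delta_chisq = delta, df = df,
                 p = pchisq(delta, df, lower.tail = FALSE),
                 dropped = dropped), class = "model_comparison")
}

#' SEM-convention information criteria
#'
#' AIC = -2LL + 2k and BIC = -2LL + k log(n pairs), the convention of
#' structural-equation twin modelling reports.
#'
#' @param minus2LL -2 log-likelihood.
#' @param k number of free parameters (including the derived E component).
#' @param n_pairs number of complete pairs.
#' @return named vector with `AIC` and `BIC`.
#' @export
fit_criteria_sem <- function(minus2LL, k, n_pairs) {
  stopifnot_scalar(k, "k", 0)
  stopifnot_scalar(n_pairs, "n_pairs", 1)
  c(AIC = minus2LL + 2 * k, BIC = minus2LL + k * log(n_pairs))
}

# One-dimensional profile search: find c with profiled -2LL = target,
# between `inside` (below target) and `outside`.
profile_root <- function(pdev, inside, outside, target, tol = 1e-4) {
  f_out <- pdev(outside)
  if (f_out < target) return(list(bound = outside, open = TRUE))
  for (i in 1:60) {
    mid <- (inside + outside) / 2
    if (pdev(mid) < target) inside <- mid else outside <- mid
    if (abs(outside - inside) < tol) break
  }
  list(bound = (inside + outside) / 2, open = FALSE)
}

#' Profile-likelihood confidence interval for a variance component
#'
#' Bounds where the profiled -2 log-likelihood rises by the chi-square(1)
#' quantile above its minimum, re-optimizing all other parameters.  Falls
#' back to a Wald interval (with a flag) if the profile search fails.
#'
#' @param fit a converged `biometric_fit`.
#' @param component one of `"sigma2_AP"`, `"sigma2_Ae4"`, `"sigma2_AB"`,
#'   `"sigma2_C"`, `"covAC"`, `"sigma2_E"`.
#' @param level confidence level (default 0.95; 0 gives a degenerate
#'   interval at the estimate).
#' @return named vector `c(lower, upper)` with attribute `open` flagging
#'   bounds that hit the search box.
#' @export
profile_ci <- function(fit, component, level = 0.95) {
  stopifnot_scalar(level, "level", 0, 1 - 1e-12)
  if (!component %in% names(fit$shares)) {
    stop(sprintf("unknown component `%s`", component))
  }
  est <- fit$shares[[component]]
  if (level == 0) return(c(lower = est, upper = est))
  flags <- fit$flags
  active <- switch(component,
    sigma2_AP = flags$include_prs && "lam_P" %in% fit$free,
    sigma2_Ae4 = flags$include_e4 && "lam_E4" %in% fit$free,
    sigma2_AB = "sigma2_AB" %in% fit$free,
    sigma2_C = "sigma2_C" %in% fit$free,
    covAC = "sigma_AC" %in% fit$free,
    sigma2_E = TRUE,
    stop(sprintf("unknown component `%s`", component)))
  if (!active) stop(sprintf("component `%s` is fixed in this model", component))
  crit <- qchisq(level, 1)
  target <- fit$minus2LL + crit

  pdev <- profiled_deviance_fun(fit, component)
  # rough width for bracketing
  w <- fit$se_shares[[component]]
  if (!is.finite(w) || w <= 0) w <- 0.1
  # measured-component shares are structurally nonnegative
  lower_box <- if (component %in% c("sigma2_AP", "sigma2_Ae4")) 0 else est - 8 * w
  upper_box <- est + 8 * w
  lo <- profile_root(pdev, est, lower_box, target)
  hi <- profile_root(pdev, est, upper_box, target)
  out <- c(lower = lo$bound, upper = hi$bound)
  attr(out, "open") <- c(lower = lo$open, upper = hi$open)
  out
}

# Build c -> profiled -2LL by constrained refits from the fitted optimum.
profiled_deviance_fun <- function(fit, component) {
  flags <- fit$flags
  free <- fit$free
  fixed <- fit$fixed
  theta_hat <- fit$theta
  function(cval) {
    if (component == "sigma2_AP") {
      # fix lam_P = sign(lam_hat)*sqrt(c / vP), vP free: substitute inside
      sgn <- if (theta_hat[["lam_P"]] >= 0) 1 else -1
      if (cval < 0) return(Inf)
      free2 <- setdiff(free, "lam_P")
      objc <- function(thf) {
        th <- c(thf, unlist(fixed)); names(th) <- c(free2, names(fixed))
        lam <- sgn * sqrt(cval / exp(th[["log_vP"]]))
        th2 <- c(th, lam_P = lam)
        names(th2) <- c(names(th), "lam_P")
        fit$objective_raw(th2)
      }
      st <- theta_hat[free2]
      o <- tryCatch(nlminb(st, objc, control = list(rel.tol = 1e-10, iter.max = 400)),
                    error = function(e) NULL)
      if (is.null(o)) return(Inf)
      return(2 * o$objective)
    }
    if (component == "sigma2_Ae4") {
      sgn <- if (theta_hat[["lam_E4"]] >= 0) 1 else -1
      if (cval < 0) return(Inf)
      free2 <- setdiff(free, "lam_E4")
      objc <- function(thf) {
        th <- c(thf, unlist(fixed)); names(th) <- c(free2, names(fixed))
        lam <- sgn * sqrt(cval / exp(th[["log_vE4"]]))
        th2 <- c(th, lam_E4 = lam)
        names(th2) <- c(names(th), "lam_E4")
        fit$objective_raw(th2)
      }
      st <- theta_hat[free2]
      o <- tryCatch(nlminb(st, objc, control = list(rel.tol = 1e-10, iter.max = 400)),
                    error = function(e) NULL)
      if (is.null(o)) return(Inf)
      return(2 * o$objective)
    }
    if (component == "sigma2_E") {
      # fix E by deriving sigma2_AB = 1 - E - (others)
      if (!"sigma2_AB" %in% free) return(Inf)
      free2 <- setdiff(free, "sigma2_AB")
      objc <- function(thf) {
        th <- c(thf, unlist(fixed)); names(th) <- c(free2, names(fixed))
        g <- function(nm) if (nm %in% names(th)) th[[nm]] else 0
        s2AP <- if (flags$include_prs) th[["lam_P"]]^2 * exp(th[["log_vP"]]) else 0
        s2E4 <- if (flags$include_e4) th[["lam_E4"]]^2 * exp(th[["log_vE4"]]) else 0
        ab <- 1 - cval - s2AP - s2E4 - g("sigma2_C") - 2 * g("sigma_AC")
        th2 <- c(th, sigma2_AB = ab)
        names(th2) <- c(names(th), "sigma2_AB")
        fit$objective_raw(th2)
      }
      st <- theta_hat[free2]
      o <- tryCatch(nlminb(st, objc, control = list(rel.tol = 1e-10, iter.max = 400)),
                    error = function(e) NULL)
      if (is.null(o)) return(Inf)
      return(2 * o$objective)
    }
    par_name <- switch(component, sigma2_AB = "sigma2_AB",
                       sigma2_C = "sigma2_C", covAC = "sigma_AC")
    free2 <- setdiff(free, par_name)
    objc <- function(thf) {
      th2 <- c(thf, setNames(cval, par_name), unlist(fixed))
      names(th2) <- c(free2, par_name, names(fixed))
      fit$objective_raw(th2)
    }
    st <- theta_hat[free2]
    o <- tryCatch(nlminb(st, objc, control = list(rel.tol = 1e-10, iter.max = 400)),
                  error = function(e) NULL)
    if (is.null(o)) return(Inf)
    2 * o$objective
  }
}

#' Monte-Carlo power for dropping a variance component
#'
#' Simulates replicate cohorts under the generating configuration, fits the
#' full and reduced models and reports the fraction of replicates in which
#' the likelihood-ratio test rejects at `alpha`.
#'
#' @param config generating [cohort_sim_config()] (direct mode).
#' @param model full-model flags ([biometric_model()] or shorthand).
#' @param drop named list of parameter fixings defining the reduced model,
#'   e.g. `list(sigma2_AB = 0)` or `list(lam_P = 0)`.
#' @param alpha test size.
#' @param n_reps number of replicates (>= 50).
#' @param seed integer seed.
#' @return list with `power`, `mc_se`, binomial 95% interval, `n_reps`.
#' @export
power_sim <- function(config, model, drop, alpha = 0.05, n_reps = 100,
                      seed = 1) {
  stopifnot_scalar(n_reps, "n_reps", 50)
  stopifnot_scalar(alpha, "alpha", 0, 1)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, r)
    cohort <- simulate_liability_cohort(cfg)
    full <- fit_biometric(cohort, model, se = FALSE, n_starts = 1)
    red <- fit_biometric(cohort, model, fixed = drop, se = FALSE, n_starts = 1)
    cmp <- tryCatch(compare_models(full, red), error = function(e) NULL)
    rej[r] <- !is.null(cmp) && cmp$p < alpha
  }
  pw <- mean(rej)
  se <- sqrt(pw * (1 - pw) / n_reps)
  list(power = pw, mc_se = se,
       ci95 = c(max(0, pw - 1.96 * se), min(1, pw + 1.96 * se)),
       n_reps = n_reps)
}
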