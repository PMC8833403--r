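# Extended ACE liability-threshold model with measured polygenic components.
#
# Liability of each twin is decomposed into a latent polygenic factor A_P
# (perfectly indexed by the observed standardized PRS, scaled by p so that
# var(PRS) = p^2 * sigma2_AP), an optional measured APOE epsilon-4 factor
# (scaling q), background additive genetic variance A_B, shared environment
# C (optionally covarying with the A factors, sigma_AC = sigma_APC +
# sigma_ABC), and unique environment E.  E is eliminated through the
# unit-variance constraint
#     1 = sigma2_AP (+ sigma2_Ae4) + sigma2_AB + sigma2_C + 2*sigma_AC + sigma2_E,
# which keeps the remaining parameter space unconstrained in sign, as
# required for unbiased fit statistics near variance boundaries.
# Cross-twin genetic correlations are 1 (MZ) and 1/2 (DZ); C is shared with
# correlation 1 in both.  The liability threshold is fixed at 0 and the
# liability mean carries the covariate effects.

#' Structural parameters of the extended ACE model
#'
#' @param sigma2_AP liability variance of the latent PRS factor.
#' @param p scaling of the observed PRS on A_P (var(PRS) = p^2 * sigma2_AP).
#' @param sigma2_Ae4 liability variance of the measured epsilon-4 factor.
#' @param q scaling of the observed epsilon-4 score on its factor.
#' @param sigma2_AB background additive genetic variance.
#' @param sigma2_C shared-environment variance.
#' @param sigma_APC,sigma_ABC components of the A-C covariance.
#' @param beta named liability mean coefficients (intercept first).
#' @param mu_prs,mu_e4 means of the measured variables.
#' @param include_prs,include_e4 which measured components are active.
#' @return an object of class `biometric_params`; `sigma2_E` is derived.
#' @export
biometric_params <- function(sigma2_AP = 0, p = 1, sigma2_Ae4 = 0, q = 1,
                             sigma2_AB = 0, sigma2_C = 0,
                             sigma_APC = 0, sigma_ABC = 0,
                             beta = c(intercept = 0), mu_prs = 0, mu_e4 = 0,
                             include_prs = sigma2_AP != 0,
                             include_e4 = sigma2_Ae4 != 0) {
  sigma_AC <- sigma_APC + sigma_ABC
  sigma2_E <- 1 - sigma2_AP - sigma2_Ae4 - sigma2_AB - sigma2_C - 2 * sigma_AC
  structure(list(sigma2_AP = sigma2_AP, p = p, sigma2_Ae4 = sigma2_Ae4, q = q,
                 sigma2_AB = sigma2_AB, sigma2_C = sigma2_C,
                 sigma_APC = sigma_APC, sigma_ABC = sigma_ABC,
                 sigma_AC = sigma_AC, sigma2_E = sigma2_E,
                 beta = beta, mu_prs = mu_prs, mu_e4 = mu_e4,
                 include_prs = include_prs, include_e4 = include_e4),
            class = "biometric_params")
}

#' Model-implied pair covariance matrix
#'
#' Ordered (PRS1, PRS2[, E41, E42], L1, L2).  For MZ pairs the PRS (and
#' epsilon-4) blocks are singular by construction (cross-twin correlation 1);
#' the likelihood therefore collapses them to one pair-level value, but the
#' full matrix is exposed here for inspection and testing.
#'
#' @param params a [biometric_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return covariance matrix with dimnames, class `implied_pair_covariance`.
#' @export
build_pair_covariance <- function(params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  rg <- if (zygosity == "MZ") 1 else 0.5
  pp <- params
  vars <- character(0); blocks <- list()
  vP <- pp$p^2 * pp$sigma2_AP
  vE4 <- pp$q^2 * pp$sigma2_Ae4
  lamP <- if (pp$p != 0) pp$p * pp$sigma2_AP else 0   # cov(L, PRS) own-twin, APC aside
  lamE4 <- if (pp$q != 0) pp$q * pp$sigma2_Ae4 else 0
  nm <- c(if (pp$include_prs) c("PRS1", "PRS2"),
          if (pp$include_e4) c("E41", "E42"),
          "L1", "L2")
  d <- length(nm)
  S <- matrix(0, d, d, dimnames = list(nm, nm))
  if (pp$include_prs) {
    S["PRS1", "PRS1"] <- S["PRS2", "PRS2"] <- vP
    S["PRS1", "PRS2"] <- S["PRS2", "PRS1"] <- rg * vP
    own <- lamP + pp$p * pp$sigma_APC
    cross <- rg * lamP + pp$p * pp$sigma_APC
    S["L1", "PRS1"] <- S["PRS1", "L1"] <- own
    S["L2", "PRS2"] <- S["PRS2", "L2"] <- own
    S["L1", "PRS2"] <- S["PRS2", "L1"] <- cross
    S["L2", "PRS1"] <- S["PRS1", "L2"] <- cross
  }
  if (pp$include_e4) {
    S["E41", "E41"] <- S["E42", "E42"] <- vE4
    S["E41", "E42"] <- S["E42", "E41"] <- rg * vE4
    S["L1", "E41"] <- S["E41", "L1"] <- lamE4
    S["L2", "E42"] <- S["E42", "L2"] <- lamE4
    S["L1", "E42"] <- S["E42", "L1"] <- rg * lamE4
    S["L2", "E41"] <- S["E41", "L2"] <- rg * lamE4
  }
  S["L1", "L1"] <- S["L2", "L2"] <- 1
  rtw <- rg * (pp$sigma2_AB + pp$sigma2_AP + pp$sigma2_Ae4) +
    pp$sigma2_C + 2 * pp$sigma_AC
  S["L1", "L2"] <- S["L2", "L1"] <- rtw
  structure(S, zygosity = zygosity, class = c("implied_pair_covariance", "matrix"))
}

# Collapsed moments used by the likelihood for one zygosity group.
# MZ uses pair-level measured values (the singular twin blocks collapse to
# a single variable); DZ keeps per-twin values.  Returns NULL moments for a
# binary-only model.  `feasible = FALSE` carries a penalty magnitude.
collapsed_moments <- function(params, zygosity) {
  pp <- params
  rg <- if (zygosity == "MZ") 1 else 0.5
  vP <- pp$p^2 * pp$sigma2_AP
  vE4 <- pp$q^2 * pp$sigma2_Ae4
  cP_own <- pp$p * pp$sigma2_AP + pp$p * pp$sigma_APC
  cP_cross <- pp$p * (rg * pp$sigma2_AP + pp$sigma_APC)
  cE_own <- pp$q * pp$sigma2_Ae4
  cE_cross <- rg * cE_own
  rtw <- rg * (pp$sigma2_AB + pp$sigma2_AP + pp$sigma2_Ae4) +
    pp$sigma2_C + 2 * pp$sigma_AC
  SLL <- matrix(c(1, rtw, rtw, 1), 2, 2)

  if (!pp$include_prs && !pp$include_e4) {
    if (abs(rtw) >= 1 - 1e-10) {
      return(list(feasible = FALSE, penalty = abs(rtw)))
    }
    return(list(feasible = TRUE, d = 0L, Sc = SLL))
  }
  if (zygosity == "MZ") {
    nm <- c(if (pp$include_prs) "wP", if (pp$include_e4) "wE4")
    d <- length(nm)
    SM <- diag(c(if (pp$include_prs) vP, if (pp$include_e4) vE4),
               nrow = d)
    SLM <- matrix(0, 2, d)
    j <- 1
    if (pp$include_prs) { SLM[, j] <- cP_own; j <- j + 1 }
    if (pp$include_e4) SLM[, j] <- cE_own
    muM <- c(if (pp$include_prs) pp$mu_prs, if (pp$include_e4) pp$mu_e4)
  } else {
    d <- 0L; SMl <- list(); SLMl <- list(); muM <- numeric(0)
    if (pp$include_prs) {
      SMl <- c(SMl, list(matrix(c(vP, rg * vP, rg * vP, vP), 2, 2)))
      SLMl <- c(SLMl, list(matrix(c(cP_own, cP_cross, cP_cross, cP_own), 2, 2)))
      muM <- c(muM, rep(pp$mu_prs, 2)); d <- d + 2L
    }
    if (pp$include_e4) {
      SMl <- c(SMl, list(matrix(c(vE4, rg * vE4, rg * vE4, vE4), 2, 2)))
      SLMl <- c(SLMl, list(matrix(c(cE_own, cE_cross, cE_cross, cE_own), 2, 2)))
      muM <- c(muM, rep(pp$mu_e4, 2)); d <- d + 2L
    }
    SM <- matrix(0, d, d); SLM <- matrix(0, 2, d)
    at <- 0
    for (bi in seq_along(SMl)) {
      idx <- at + 1:2
      SM[idx, idx] <- SMl[[bi]]
      SLM[, idx] <- SLMl[[bi]]
      at <- at + 2
    }
  }
  ch <- tryCatch(chol(SM), error = function(e) NULL)
  if (is.null(ch)) {
    return(list(feasible = FALSE, penalty = 1 + sum(abs(SM))))
  }
  SMinv <- chol2inv(ch)
  W <- SLM %*% SMinv
  Sc <- SLL - W %*% t(SLM)
  if (Sc[1, 1] <= 1e-10 || Sc[2, 2] <= 1e-10) {
    return(list(feasible = FALSE, penalty = 1 + abs(min(diag(Sc)))))
  }
  rho <- Sc[1, 2] / sqrt(Sc[1, 1] * Sc[2, 2])
  if (abs(rho) >= 1 - 1e-10) {
    return(list(feasible = FALSE, penalty = abs(rho)))
  }
  list(feasible = TRUE, d = d, SM = SM, chol = ch, SMinv = SMinv,
       W = W, Sc = Sc, muM = muM,
       logdet = 2 * sum(log(diag(ch))))
}

# Vectorized log-likelihood for all pairs of one zygosity.
# M: pairs x d matrix of measured values (NULL when d = 0);
# eta1, eta2: liability means; y1, y2: statuses.
zyg_loglik <- function(mom, M, eta1, eta2, y1, y2) {
  n <- length(y1)
  ll <- numeric(n)
  mu1 <- eta1; mu2 <- eta2
  if (mom$d > 0) {
    R <- sweep(M, 2, mom$muM)
    # Gaussian log density of the measured block
    quad <- rowSums((R %*% mom$SMinv) * R)
    ll <- ll - 0.5 * (mom$d * log(2 * pi) + mom$logdet + quad)
    A <- R %*% t(mom$W)
    mu1 <- mu1 + A[, 1]
    mu2 <- mu2 + A[, 2]
  }
  s1 <- sqrt(mom$Sc[1, 1]); s2 <- sqrt(mom$Sc[2, 2])
  rho <- mom$Sc[1, 2] / (s1 * s2)
  pr <- rect_prob(mu1, mu2, s1, s2, rho, y1, y2)
  ll + log(pmax(pr, 1e-300))
}

#' Log-likelihood contribution of a single twin pair
#'
#' Continuous-block Gaussian density of the measured variables plus the
#' conditional bivariate-normal rectangle probability of the binary
#' outcomes, with the liability threshold fixed at 0.  MZ pairs use a single
#' pair-level value for each measured variable (their model-implied twin
#' block is singular).
#'
#' @param obs list with elements `y` (length-2 binary statuses), `eta`
#'   (length-2 liability means from covariates), and optionally `prs` and
#'   `e4` (length-2 measured values, averaged for MZ).
#' @param params a [biometric_params()].
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return scalar log-likelihood contribution.
#' @export
pair_loglik <- function(obs, params, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  if (any(!is.finite(obs$eta))) stop("non-finite covariate effects")
  mom <- collapsed_moments(params, zygosity)
  if (!mom$feasible) {
    stop("implied covariance not positive definite at these parameters")
  }
  M <- NULL
  if (mom$d > 0) {
    vals <- c(if (params$include_prs) obs$prs, if (params$include_e4) obs$e4)
    if (zygosity == "MZ") {
      m <- c(if (params$include_prs) mean(obs$prs),
             if (params$include_e4) mean(obs$e4))
    } else {
      m <- vals
    }
    M <- matrix(m, 1)
  }
  as.numeric(zyg_loglik(mom, M, obs$eta[1], obs$eta[2], obs$y[1], obs$y[2]))
}
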