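# Mixed-effects probit/logit regression for clustered twin data.
#
# The model is a pair-level random-intercept binary regression with
# zygosity-specific random variances:
#   link(P(y_ij = 1 | u_j)) = x_ij' beta + u_j,  u_j ~ N(0, v_MZ or v_DZ).
# The marginal likelihood integrates u out per pair by adaptive
# Gauss-Hermite quadrature (Laplace-recentred nodes), which keeps the
# binary pair clusters accurate at modest node counts.  Incomplete pairs
# contribute one-member clusters.

LINKS <- list(
  probit = list(
    logF = function(t) pnorm(t, log.p = TRUE),
    lambda = function(t) exp(dnorm(t, log = TRUE) - pnorm(t, log.p = TRUE)),
    dlambda = function(t, lam) -t * lam - lam^2,
    pfun = pnorm
  ),
  logit = list(
    logF = function(t) plogis(t, log.p = TRUE),
    lambda = function(t) plogis(-t),
    dlambda = function(t, lam) -lam * (1 - lam),
    pfun = plogis
  )
)

#' Fixed-effect design matrix for the twin probit model
#'
#' Builds the design from cohort columns.  The special names `mz` (MZ
#' zygosity indicator) and `array` (PsychArray = 1, OmniExpress = 0) are
#' derived; all other names must be numeric cohort columns.
#'
#' @param cohort a `twin_cohort`.
#' @param predictors character vector of predictor names (intercept added
#'   automatically).
#' @return numeric design matrix.
#' @keywords internal
build_design <- function(cohort, predictors) {
  n <- nrow(cohort)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (p in predictors) {
    col <- switch(p,
      mz = as.numeric(cohort$zygosity == "MZ"),
      array = as.numeric(cohort$array == "PsychArray"),
      {
        v <- cohort[[p]]
        if (is.null(v)) stop(sprintf("predictor `%s` not found in cohort", p))
        as.numeric(v)
      })
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- p
  }
  X
}

# Cluster layout: one row per pair, indices of member rows (NA for singletons).
cluster_layout <- function(cohort) {
  ord <- order(cohort$pair_id, cohort$twin)
  pid <- cohort$pair_id[ord]
  first <- !duplicated(pid)
  i1 <- ord[first]
  i2 <- rep(NA_integer_, sum(first))
  second <- which(!first)
  i2[match(pid[second], pid[first])] <- ord[second]
  list(i1 = i1, i2 = i2,
       mz = cohort$zygosity[i1] == "MZ",
       n_clusters = sum(first))
}

# Marginal log-likelihood of all clusters given eta, y and per-cluster v.
# Clusters with v = 0 get the independence likelihood.
cluster_loglik <- function(eta, y, lay, v, link, gh) {
  q <- 2 * y - 1
  t1 <- q[lay$i1] * eta[lay$i1]
  has2 <- !is.na(lay$i2)
  q2 <- ifelse(has2, q[lay$i2], 0)
  e2 <- ifelse(has2, eta[lay$i2], 0)
  out <- numeric(lay$n_clusters)

  zero <- v <= 0
  if (any(zero)) {
    ll0 <- link$logF(t1[zero])
    h2 <- has2[zero]
    if (any(h2)) {
      ll0[h2] <- ll0[h2] + link$logF((q2 * e2)[zero][h2])
    }
    out[zero] <- ll0
  }
  if (any(!zero)) {
    idx <- which(!zero)
    vv <- v[idx]
    qa <- q[lay$i1][idx]; ea <- eta[lay$i1][idx]
    hb <- has2[idx]
    qb <- q2[idx]; eb <- e2[idx]
    hfun <- function(u) {
      ta <- qa * (ea + u)
      val <- -u^2 / (2 * vv) + link$logF(ta)
      tb <- qb * (eb + u)
      val[hb] <- val[hb] + link$logF(tb[hb])
      val
    }
    # Newton iterations for the per-cluster mode (log-concave integrand)
    u <- rep(0, length(idx))
    for (it in 1:25) {
      ta <- qa * (ea + u); la <- link$lambda(ta)
      g1 <- -u / vv + qa * la
      g2 <- -1 / vv + link$dlambda(ta, la)
      tb <- qb * (eb + u); lb <- link$lambda(tb)
      g1[hb] <- g1[hb] + (qb * lb)[hb]
      g2[hb] <- g2[hb] + link$dlambda(tb, lb)[hb]
      step <- g1 / g2
      step <- pmin(pmax(step, -4), 4)
      u <- u - step
      if (max(abs(step)) < 1e-10) break
    }
    sig <- 1 / sqrt(-g2)
    # adaptive GH: integral e^{h(u)} du = sig * sum_m w_m e^{h(u+sig z_m)}/phi(z_m)
    M <- matrix(0, length(idx), nrow(gh))
    for (m in seq_len(nrow(gh))) {
      M[, m] <- log(gh[m, "w"]) + hfun(u + sig * gh[m, "z"]) - gh[m, "ldnorm"]
    }
    mx <- apply(M, 1, max)
    out[idx] <- log(sig) + mx + log(rowSums(exp(M - mx))) -
      0.5 * log(2 * pi * vv)
  }
  out
}

#' Fit the mixed-effects probit (or logit) twin regression
#'
#' Maximizes the marginal likelihood of a pair-level random-intercept model
#' with separate MZ and DZ random variances.
#'
#' @param cohort a `twin_cohort` (both complete and incomplete pairs used).
#' @param predictors fixed-effect names, see [build_design()]; default the
#'   covariates-only baseline `c("mz", "sex", "cage", "cage2", "array")`.
#' @param link `"probit"` (default) or `"logit"`.
#' @param nq number of quadrature nodes (default 21).
#' @param fix_v optional named vector fixing random variances, e.g.
#'   `c(MZ = 0, DZ = 0)`; fixed variances are excluded from k.
#' @return an object of class `mixed_probit_fit` with the coefficient table,
#'   random variances and their standard errors, log-likelihood, deviance,
#'   mixor-convention AIC/SBC, intra-pair ICCs and convergence diagnostics.
#' @export
fit_mixed_probit <- function(cohort,
                             predictors = c("mz", "sex", "cage", "cage2", "array"),
                             link = c("probit", "logit"), nq = 21,
                             fix_v = NULL) {
  link_name <- match.arg(link)
  lk <- LINKS[[link_name]]
  y <- cohort$ad
  if (length(unique(y)) < 2) {
    stop("degenerate response: outcome must contain both cases and controls")
  }
  X <- build_design(cohort, predictors)
  lay <- cluster_layout(cohort)
  gh <- lme4::GHrule(nq)
  free_v <- setdiff(c("MZ", "DZ"), names(fix_v))
  for (z in free_v) {
    nz <- sum(if (z == "MZ") lay$mz else !lay$mz)
    if (nz < 2) stop(sprintf("need at least 2 %s pairs to free v_%s", z, z))
  }

  # warm start from the independence GLM
  glm0 <- suppressWarnings(
    glm.fit(X, y, family = binomial(link = link_name))
  )
  beta0 <- glm0$coefficients
  sep_flag <- any(abs(beta0) > 15)

  p <- ncol(X)
  theta0 <- c(beta0, rep(log(0.5), length(free_v)))
  vfun <- function(theta) {
    v <- c(MZ = 0, DZ = 0)
    v[names(fix_v)] <- fix_v
    if (length(free_v)) v[free_v] <- exp(theta[p + seq_along(free_v)])
    v
  }
  negll <- function(theta) {
    eta <- as.vector(X %*% theta[seq_len(p)])
    v <- vfun(theta)
    vcl <- ifelse(lay$mz, v["MZ"], v["DZ"])
    ll <- sum(cluster_loglik(eta, y, lay, vcl, lk, gh))
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- nlminb(theta0, negll, control = list(rel.tol = 1e-12, iter.max = 500))
  conv_any <- opt$convergence == 0
  opt2 <- optim(opt$par, negll, method = "BFGS",
                control = list(maxit = 200, reltol = 1e-12))
  if (opt2$value < opt$objective) {
    conv_any <- conv_any || opt2$convergence == 0
    opt <- list(par = opt2$par, objective = opt2$value)
  }
  # final polish: quadrature-based likelihoods are smooth, so a tight
  # restart squeezes out the last few digits
  opt3 <- nlminb(opt$par, negll,
                 control = list(rel.tol = 1e-14, x.tol = 1e-12, iter.max = 200))
  if (opt3$objective <= opt$objective) {
    conv_any <- conv_any || opt3$convergence == 0
    opt <- list(par = opt3$par, objective = opt3$objective)
  }
  theta <- opt$par
  ll <- -negll(theta)

  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  se_theta <- rep(NA_real_, length(theta))
  if (!is.null(H)) {
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv)) se_theta <- sqrt(pmax(diag(cv), 0))
  }

  beta <- theta[seq_len(p)]
  se_b <- se_theta[seq_len(p)]
  v <- vfun(theta)
  se_v <- c(MZ = NA_real_, DZ = NA_real_)
  if (length(free_v)) {
    # delta method: se(v) = v * se(log v)
    se_v[free_v] <- v[free_v] * se_theta[p + seq_along(free_v)]
  }
  coefs <- data.frame(
    term = colnames(X), estimate = beta, se = se_b,
    z = beta / se_b, p = 2 * pnorm(-abs(beta / se_b)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  k <- p + length(free_v)
  n_clusters <- lay$n_clusters
  crit <- fit_criteria_mixor(ll, k, n_clusters)
  fit <- structure(list(
    coefficients = coefs,
    v = v, se_v = se_v,
    logLik = ll, deviance = -2 * ll,
    k = k, n_ind = length(y), n_pairs = n_clusters,
    aic = crit[["AIC"]], sbc = crit[["SBC"]],
    icc = c(MZ = icc(v[["MZ"]], link_name), DZ = icc(v[["DZ"]], link_name)),
    link = link_name, nq = nq, predictors = predictors,
    fix_v = fix_v,
    converged = is.finite(ll) && conv_any,
    separation = sep_flag,
    eta = as.vector(X %*% beta), y = y
  ), class = "mixed_probit_fit")
  fit
}

#' @export
print.mixed_probit_fit <- function(x, ...) {
  cat(sprintf("Mixed-effects %s regression (%d individuals, %d pairs)\n",
              x$link, x$n_ind, x$n_pairs))
  print(transform(x$coefficients, estimate = round(estimate, 3),
                  se = round(se, 3), z = round(z, 2),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("Random.MZ %.3f (SE %.3f)  Random.DZ %.3f (SE %.3f)\n",
              x$v[["MZ"]], x$se_v[["MZ"]], x$v[["DZ"]], x$se_v[["DZ"]]))
  cat(sprintf("ICC.MZ %.3f  ICC.DZ %.3f\n", x$icc[["MZ"]], x$icc[["DZ"]]))
  cat(sprintf("Deviance %.2f  AIC %.2f  SBC %.2f\n", x$deviance, x$aic, x$sbc))
  invisible(x)
}

#' Residual intraclass correlation from a random-intercept variance
#'
#' For the probit link the latent residual variance is 1, giving
#' ICC = v / (1 + v); for the logit link it is pi^2/3.
#'
#' @param v random-intercept variance (>= 0).
#' @param link `"probit"` or `"logit"`.
#' @return the intra-cluster correlation of the latent response.
#' @export
icc <- function(v, link = c("probit", "logit")) {
  link <- match.arg(link)
  if (any(v < 0)) stop("`v` must be nonnegative")
  resid_var <- if (link == "probit") 1 else pi^2 / 3
  v / (v + resid_var)
}

#' Likelihood-ratio (deviance difference) test
#'
#' @param fit_small,fit_big nested fits (`mixed_probit_fit` or
#'   `biometric_fit`) or plain deviance / -2LL values.
#' @param df degrees of freedom (number of added parameters); inferred from
#'   the fits' k when omitted.
#' @return list with `delta_chisq`, `df`, `p`.
#' @export
lrt <- function(fit_small, fit_big, df = NULL) {
  dev <- function(f) {
    if (is.numeric(f)) f
    else if (!is.null(f$deviance)) f$deviance
    else f$minus2LL
  }
  kof <- function(f) if (is.numeric(f)) NA_integer_ else f$k
  d_small <- dev(fit_small); d_big <- dev(fit_big)
  if (is.null(df)) {
    df <- kof(fit_big) - kof(fit_small)
    if (is.na(df)) stop("`df` must be given when deviances are supplied directly")
  }
  delta <- d_small - d_big
  if (delta < -1e-6) {
    stop("larger model fits worse than the nested model: check nesting")
  }
  delta <- max(delta, 0)
  list(delta_chisq = delta, df = df,
       p = pchisq(delta, df, lower.tail = FALSE))
}

#' mixor-convention information criteria
#'
#' The reporting convention used with clustered ordinal/binary mixed models:
#' AIC = logLik - k and SBC = logLik - (k/2) log(n clusters), i.e. larger is
#' better and k counts fixed effects plus free random variances.
#'
#' @param logLik maximized log-likelihood.
#' @param k number of estimated parameters (>= 1).
#' @param n_clusters number of clusters (>= 1).
#' @return named vector with `AIC` and `SBC`.
#' @export
fit_criteria_mixor <- function(logLik, k, n_clusters) {
  stopifnot_scalar(k, "k", 0)
  stopifnot_scalar(n_clusters, "n_clusters", 1)
  c(AIC = logLik - k, SBC = logLik - (k / 2) * log(n_clusters))
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2 rescaled to a maximum of 1, computed from the deviances of a
#' fit and a nested reference model on the same data.  The reference
#' defaults to the covariates-only baseline convention (incremental R2 for a
#' polygenic score); an intercept-only reference gives the absolute value.
#'
#' @param fit a fitted model (or its deviance).
#' @param reference_fit the nested reference model (or its deviance).
#' @param n number of individuals.
#' @return Nagelkerke R-squared (attribute `cox_snell`).
#' @export
nagelkerke <- function(fit, reference_fit, n) {
  stopifnot_scalar(n, "n", 1)
  dev <- function(f) if (is.numeric(f)) f else f$deviance
  d_fit <- dev(fit); d_ref <- dev(reference_fit)
  r2_cs <- 1 - exp((d_fit - d_ref) / n)
  r2_max <- 1 - exp(-d_ref / n)
  out <- r2_cs / r2_max
  attr(out, "cox_snell") <- r2_cs
  out
}

#' Case/control summary of a standardized score
#'
#' Group means and SDs of a (standardized) polygenic score by disease
#' status, and the effect-size difference z = mean(cases) - mean(controls),
#' which is in SD units for a score standardized in the full sample.
#'
#' @param cohort a `twin_cohort` (or any data.frame with an `ad` column).
#' @param score_col name of the score column.
#' @return list with `mean_case`, `mean_control`, `sd_case`, `sd_control`,
#'   `z`.
#' @export
prs_case_control_summary <- function(cohort, score_col = "zprs") {
  s <- cohort[[score_col]]
  if (is.null(s)) stop(sprintf("column `%s` not found", score_col))
  y <- cohort$ad
  list(mean_case = mean(s[y == 1]), mean_control = mean(s[y == 0]),
       sd_case = sd(s[y == 1]), sd_control = sd(s[y == 0]),
       z = mean(s[y == 1]) - mean(s[y == 0]))
}

#' Area under the ROC curve of marginal predictions
#'
#' Rank-based concordance between the fixed-effects-only (random effects
#' integrated out) predicted probabilities and the outcome; ties count half.
#'
#' @param fit a `mixed_probit_fit`.
#' @param cohort optional `twin_cohort` to score (defaults to the fitting
#'   data stored in the fit).
#' @return AUC in [0, 1].
#' @export
auc <- function(fit, cohort = NULL) {
  if (is.null(cohort)) {
    score <- LINKS[[fit$link]]$pfun(fit$eta)
    y <- fit$y
  } else {
    X <- build_design(cohort, fit$predictors)
    score <- LINKS[[fit$link]]$pfun(as.vector(X %*% fit$coefficients$estimate))
    y <- cohort$ad
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("degenerate outcome: AUC undefined")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
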