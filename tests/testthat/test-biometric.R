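test_that("implied pair covariance follows the twin-correlation algebra", {
  pp <- biometric_params(sigma2_AP = 0.101, p = 1 / sqrt(0.101),
                         sigma2_AB = 0.614, include_prs = TRUE)
  S_mz <- build_pair_covariance(pp, "MZ")
  S_dz <- build_pair_covariance(pp, "DZ")
  expect_equal(S_mz["L1", "L2"], 0.715, tolerance = 1e-12)
  expect_equal(S_dz["L1", "L2"], 0.3575, tolerance = 1e-12)
  expect_equal(S_mz["L1", "L1"], 1)
  expect_true(isSymmetric(unclass(S_mz)))
  # with p scaled so var(PRS) = 1, the MZ PRS block is [[1,1],[1,1]]
  expect_equal(unclass(S_mz[c("PRS1", "PRS2"), c("PRS1", "PRS2")]),
               matrix(1, 2, 2), ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(abs(det(S_mz[c("PRS1", "PRS2"), c("PRS1", "PRS2")])), 1e-12)
  # no familial components: MZ and DZ identical, off-diagonals zero
  p0 <- biometric_params(sigma2_AB = 0)
  expect_equal(unclass(build_pair_covariance(p0, "MZ")),
               unclass(build_pair_covariance(p0, "DZ")),
               ignore_attr = TRUE)
  expect_equal(build_pair_covariance(p0, "MZ")["L1", "L2"], 0)
})

test_that("pair_loglik factorizes when only E is present", {
  pp <- biometric_params(sigma2_AB = 0)   # E = 1
  obs <- list(y = c(1, 0), eta = c(-0.4, 0.3))
  got <- pair_loglik(obs, pp, "DZ")
  expected <- pnorm(-0.4, log.p = TRUE) + pnorm(-0.3, log.p = TRUE)
  # threshold 0: P(AD) = P(L > 0) = Phi(eta)
  expect_equal(got, expected, tolerance = 1e-10)
  expect_error(pair_loglik(list(y = c(1, 0), eta = c(NA, 0)), pp, "DZ"),
               "non-finite")
})

test_that("conditional moments match the hand Schur complement", {
  pp <- biometric_params(sigma2_AP = 0.2, p = 1 / sqrt(0.2),
                         sigma2_AB = 0.4, include_prs = TRUE)
  S <- unclass(build_pair_covariance(pp, "DZ"))
  SM <- S[1:2, 1:2]; SLM <- S[3:4, 1:2]; SLL <- S[3:4, 3:4]
  Sc_hand <- SLL - SLM %*% solve(SM) %*% t(SLM)
  pp2 <- pp; pp2$vP <- pp$p^2 * 0.2; pp2$lamP <- 1 / pp$p
  pp2$vE4 <- 0; pp2$lamE4 <- 0
  mom <- twinprs:::collapsed_moments_raw(pp2, "DZ")
  expect_equal(mom$Sc, unname(Sc_hand), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mom$SMinv, unname(solve(SM)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pair_loglik agrees with a Monte-Carlo orthant oracle", {
  set.seed(61)
  pp <- biometric_params(sigma2_AP = 0.12, p = 1 / sqrt(0.12),
                         sigma2_AB = 0.5, sigma2_C = 0.08,
                         beta = c(intercept = -0.5), include_prs = TRUE)
  for (zyg in c("DZ", "MZ")) {
    S <- unclass(build_pair_covariance(pp, zyg))
    for (i in 1:10) {
      y <- rbinom(2, 1, 0.5)
      eta <- rnorm(2, -0.5, 0.4)
      if (zyg == "DZ") {
        m <- as.vector(crossprod(chol(S[1:2, 1:2]), rnorm(2)))
        dens <- dmvnorm_log(m, rep(0, 2), S[1:2, 1:2])
        W <- S[3:4, 1:2] %*% solve(S[1:2, 1:2])
        Sc <- S[3:4, 3:4] - W %*% t(S[3:4, 1:2])
        mu <- eta + as.vector(W %*% m)
      } else {
        # MZ: one pair-level measured value
        vP <- S["PRS1", "PRS1"]
        m <- rnorm(1, 0, sqrt(vP))
        dens <- dnorm(m, 0, sqrt(vP), log = TRUE)
        w <- S[c("L1", "L2"), "PRS1"] / vP
        Sc <- S[3:4, 3:4] - outer(w, S[c("L1", "L2"), "PRS1"])
        mu <- eta + w * m
      }
      obs <- list(y = y, eta = eta, prs = rep(m, length.out = 2))
      got <- pair_loglik(obs, pp, zyg)
      mc <- rect_mc(mu, Sc, y, n = 2e5)
      expect_gt(mc$p, 0)
      expect_lt(abs(exp(got - dens) - mc$p), 3.5 * mc$se + 1e-6)
    }
  }
})

test_that("SEM criteria reproduce the reporting arithmetic", {
  c_full <- fit_criteria_sem(888.71, 7, 449)
  expect_equal(unname(c_full["AIC"]), 902.71, tolerance = 1e-9)
  expect_lt(abs(c_full[["BIC"]] - 931.46), 0.005)
  c_red <- fit_criteria_sem(889.52, 6, 449)
  expect_equal(unname(c_red["AIC"]), 901.52, tolerance = 1e-9)
  expect_lt(abs(c_red[["BIC"]] - 926.16), 0.005)
  expect_equal(unname(fit_criteria_sem(100, 0, 10)["AIC"]), 100)
})

test_that("model k counts match the SEM convention across specifications", {
  cfg <- world_ae_prs_e4(120, 120, seed = 62)
  co <- simulate_liability_cohort(cfg)
  ks <- c(ace = 7, ae = 6, ace_prs = 11, ae_prs = 9, ae_prs_e4 = 12,
          ace_prs_e4 = 14)
  for (m in names(ks)) {
    f <- fit_biometric(co, m, se = FALSE, n_starts = 1)
    expect_equal(f$k, unname(ks[m]), info = m)
    # unit-variance share conservation on every fit
    sh <- f$shares
    expect_equal(unname(sh["sigma2_AP"] + sh["sigma2_Ae4"] + sh["sigma2_AB"] +
                          sh["sigma2_C"] + 2 * sh["covAC"] + sh["sigma2_E"]),
                 1, tolerance = 1e-8)
    expect_equal(unname(sh["total_A"]),
                 unname(sh["sigma2_AP"] + sh["sigma2_Ae4"] + sh["sigma2_AB"] +
                          2 * sh["covAC"]), tolerance = 1e-10)
  }
})

test_that("AE fit recovers the generating shares and matches Falconer", {
  cfg <- world_ae(2500, 2500, seed = 63)
  co <- simulate_liability_cohort(cfg)
  f <- fit_biometric(co, "ae", n_starts = 1)
  expect_lt(abs(f$shares[["sigma2_AB"]] - 0.707), 3 * f$se_shares[["sigma2_AB"]])
  t1 <- co$twin == 1
  r_mz <- tetrachoric(table(co$ad[t1 & co$zygosity == "MZ"],
                            co$ad[!t1 & co$zygosity == "MZ"]))
  r_dz <- tetrachoric(table(co$ad[t1 & co$zygosity == "DZ"],
                            co$ad[!t1 & co$zygosity == "DZ"]))
  # classical Falconer relationship on large cohorts (tetrachorics are
  # marginal, covariate-inflated versions of the model correlations, so the
  # comparison is loose)
  expect_lt(abs(f$shares[["total_A"]] - 2 * (r_mz - r_dz)), 0.1)
})

test_that("C-only worlds are attributed to C, not A", {
  cfg <- cohort_sim_config(1200, 1200, sigma2_AB = 0, sigma2_C = 0.5,
                           sigma2_E = 0.5, prevalence = 0.27, seed = 64)
  co <- simulate_liability_cohort(cfg)
  f <- fit_biometric(co, "ace", se = FALSE, n_starts = 2)
  expect_gt(f$shares[["sigma2_C"]], 0.3)
  expect_lt(abs(f$shares[["sigma2_AB"]]), 0.2)
  # implied MZ/DZ correlations approximately equal
  ppf <- biometric_params(sigma2_AB = f$shares[["sigma2_AB"]],
                          sigma2_C = f$shares[["sigma2_C"]])
  r_mz <- build_pair_covariance(ppf, "MZ")["L1", "L2"]
  r_dz <- build_pair_covariance(ppf, "DZ")["L1", "L2"]
  expect_lt(abs(r_mz - r_dz), 0.12)
})

test_that("direct and genotype modes give matching biometric estimates", {
  cfg_d <- world_ae_prs(900, 900, seed = 65)
  co_d <- simulate_liability_cohort(cfg_d)
  f_d <- fit_biometric(co_d, "ae_prs", se = FALSE, n_starts = 1)
  pool <- simulate_haplotype_pool(40, 5, c(0.1, 0.5), rho = 0.4, seed = 66)
  panel <- simulate_twin_genotypes(pool, 900, 900, seed = 67)
  wts <- setNames(rnorm(200, 0, 0.1), pool$snps$id)
  cfg_g <- world_ae_prs(900, 900, seed = 68, mode = "genotype")
  co_g <- simulate_liability_cohort(cfg_g, panel, wts)
  f_g <- fit_biometric(co_g, "ae_prs", se = FALSE, n_starts = 1)
  expect_lt(abs(f_d$shares[["sigma2_AP"]] - f_g$shares[["sigma2_AP"]]), 0.05)
  expect_lt(abs(f_d$shares[["sigma2_AB"]] - f_g$shares[["sigma2_AB"]]), 0.08)
})

test_that("a small measurement-error ridge leaves estimates nearly unchanged", {
  cfg <- world_ae_prs(400, 400, seed = 73)
  co <- simulate_liability_cohort(cfg)
  f0 <- fit_biometric(co, "ae_prs", se = FALSE, n_starts = 1)
  fr <- fit_biometric(co, biometric_model("ae_prs", ridge = 0.01),
                      se = FALSE, n_starts = 1)
  expect_lt(abs(f0$shares[["sigma2_AP"]] - fr$shares[["sigma2_AP"]]), 0.02)
  expect_lt(abs(f0$shares[["sigma2_AB"]] - fr$shares[["sigma2_AB"]]), 0.04)
})

test_that("compare_models enforces nesting and handles identical models", {
  cfg <- world_ae(150, 150, seed = 69)
  co <- simulate_liability_cohort(cfg)
  fa <- fit_biometric(co, "ae", se = FALSE, n_starts = 1)
  fc <- fit_biometric(co, "ace", se = FALSE, n_starts = 1)
  cmp <- compare_models(fc, fa)
  expect_equal(cmp$df, 1)
  expect_gte(cmp$delta_chisq, 0)
  expect_identical(cmp$dropped, "sigma2_C")
  same <- compare_models(fa, fa)
  expect_equal(same$delta_chisq, 0)
  expect_equal(same$p, 1)
  expect_error(compare_models(fa, fc), "not nested|nesting")
})

test_that("profile CI equals the Wald interval for a quadratic deviance", {
  # synthetic fit whose -logLik is exactly quadratic and separable
  flags <- biometric_model("ae")
  fake <- structure(list(
    shares = c(sigma2_AP = 0, sigma2_Ae4 = 0, sigma2_AB = 0.5, sigma2_C = 0,
               covAC = 0, sigma2_E = 0.5, total_A = 0.5),
    se_shares = c(sigma2_AP = NA, sigma2_Ae4 = NA, sigma2_AB = 0.1,
                  sigma2_C = NA, covAC = NA, sigma2_E = 0.1, total_A = 0.1),
    theta = c(sigma2_AB = 0.5, b0 = 0, b_sex = 0, b_cage = 0, b_cage2 = 0),
    minus2LL = 0, flags = flags, fixed = list(),
    free = c("sigma2_AB", "b0", "b_sex", "b_cage", "b_cage2"),
    objective_raw = function(th) {
      0.5 * ((th[["sigma2_AB"]] - 0.5)^2 / 0.01 + th[["b0"]]^2 / 0.04 +
               th[["b_sex"]]^2 + th[["b_cage"]]^2 + th[["b_cage2"]]^2)
    }), class = "biometric_fit")
  ci <- profile_ci(fake, "sigma2_AB")
  expect_equal(unname(ci["lower"]), 0.5 - 1.96 * 0.1, tolerance = 1e-3)
  expect_equal(unname(ci["upper"]), 0.5 + 1.96 * 0.1, tolerance = 1e-3)
  expect_equal(profile_ci(fake, "sigma2_AB", level = 0),
               c(lower = 0.5, upper = 0.5))
  expect_error(profile_ci(fake, "sigma2_C"), "fixed")
  expect_error(profile_ci(fake, "nonsense"), "unknown")
})

test_that("profile CI brackets the estimate on a fitted model", {
  cfg <- world_ae(500, 500, seed = 70)
  co <- simulate_liability_cohort(cfg)
  f <- fit_biometric(co, "ae", n_starts = 1)
  ci <- profile_ci(f, "sigma2_AB")
  expect_lt(ci[["lower"]], f$shares[["sigma2_AB"]])
  expect_gt(ci[["upper"]], f$shares[["sigma2_AB"]])
  # roughly Wald-width for this well-behaved model
  wald <- 1.96 * f$se_shares[["sigma2_AB"]]
  expect_lt(abs((ci[["upper"]] - ci[["lower"]]) / 2 - wald), 0.6 * wald)
})

test_that("the C-drop LRT is calibrated under the null (unbounded estimation)", {
  cfg <- cohort_sim_config(75, 75, sigma2_AB = 0.5, sigma2_E = 0.5,
                           prevalence = 0.27, seed = 0)
  pw <- power_sim(cfg, "ace", drop = list(sigma2_C = 0), alpha = 0.05,
                  n_reps = 200, seed = 71)
  expect_lt(abs(pw$power - 0.05), 0.035)
})

test_that("power approaches 1 for large effects and is seed-reproducible", {
  cfg <- cohort_sim_config(150, 150, sigma2_AB = 0.8, sigma2_E = 0.2,
                           prevalence = 0.3, seed = 0)
  pw1 <- power_sim(cfg, "ae", drop = list(sigma2_AB = 0), alpha = 0.05,
                   n_reps = 50, seed = 72)
  expect_gte(pw1$power, 0.9)
  pw2 <- power_sim(cfg, "ae", drop = list(sigma2_AB = 0), alpha = 0.05,
                   n_reps = 50, seed = 72)
  expect_identical(pw1, pw2)
  expect_error(power_sim(cfg, "ae", drop = list(sigma2_AB = 0), n_reps = 10),
               "n_reps")
})
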