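# Liability-threshold twin cohort simulation.
#
# Each twin's liability is a unit-variance sum of a measured polygenic
# component (A_P), an optional measured APOE epsilon-4 component, background
# additive genetic variance (A_B), shared environment (C, optionally
# correlated with the A components), and unique environment (E), plus fixed
# covariate effects.  Disease status is the indicator that total liability
# exceeds a threshold solved so the marginal prevalence matches the target
# in expectation over the covariate distribution.

#' Configuration for a simulated twin cohort
#'
#' Variance shares are liability-scale fractions and must satisfy the
#' unit-variance decomposition
#' `sigma2_AP + sigma2_Ae4 + sigma2_AB + sigma2_C + 2*covAC_total + sigma2_E = 1`
#' to within 1e-9.
#'
#' @param n_mz,n_dz pair counts.
#' @param sigma2_AP liability variance share of the measured polygenic score.
#' @param sigma2_Ae4 share of the measured APOE epsilon-4 count (0 disables).
#' @param sigma2_AB background additive genetic share.
#' @param sigma2_C shared-environment share.
#' @param covAC_total total A-C covariance (enters the variance twice).
#' @param sigma2_E unique-environment share.
#' @param covac_on_AP fraction of `covAC_total` assigned to the A_P-C path
#'   (the remainder goes to A_B-C); default 0, i.e. all on the background.
#' @param prevalence target marginal disease prevalence.
#' @param beta_sex,beta_age,beta_age2 probit-scale covariate effects on the
#'   liability (sex coded 0 = male, 1 = female; age centered on 80 years and
#'   divided by 10).
#' @param p_male probability an individual is male (DZ twins sexed
#'   independently, MZ pairs share sex).
#' @param age_mean,age_sd distribution of age at last follow-up (years),
#'   shared within a pair.
#' @param e2_freq,e4_freq APOE epsilon-2 and epsilon-4 haplotype frequencies.
#' @param incomplete_rate fraction of pairs made incomplete by
#'   [apply_missingness()].
#' @param mz_impute_rate fraction of MZ pairs with only one twin genotyped
#'   (co-twin score copy-imputed).
#' @param mode `"direct"` draws the polygenic component from its latent
#'   normal distribution; `"genotype"` computes it from simulated genotypes
#'   with true weights.
#' @param keep_latent store the true latent components (debug/oracle use).
#' @param seed integer seed.
#' @return an object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_mz, n_dz,
                              sigma2_AP = 0, sigma2_Ae4 = 0,
                              sigma2_AB = 0.707, sigma2_C = 0,
                              covAC_total = 0, sigma2_E = 0.293,
                              covac_on_AP = 0,
                              prevalence = 431 / 1586,
                              beta_sex = 0.44, beta_age = 0.97,
                              beta_age2 = -0.55,
                              p_male = 0.44, age_mean = 85.28, age_sd = 7.02,
                              e2_freq = 0.094, e4_freq = 0.164,
                              incomplete_rate = 0, mz_impute_rate = 0,
                              mode = c("direct", "genotype"),
                              keep_latent = FALSE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot_scalar(n_mz, "n_mz", 0); stopifnot_scalar(n_dz, "n_dz", 0)
  stopifnot_scalar(prevalence, "prevalence", 1e-6, 1 - 1e-6)
  stopifnot_scalar(incomplete_rate, "incomplete_rate", 0, 1)
  stopifnot_scalar(mz_impute_rate, "mz_impute_rate", 0, 1)
  stopifnot_scalar(covac_on_AP, "covac_on_AP", 0, 1)
  total <- sigma2_AP + sigma2_Ae4 + sigma2_AB + sigma2_C +
    2 * covAC_total + sigma2_E
  if (abs(total - 1) > 1e-9) {
    stop(sprintf(paste0("variance shares must satisfy the unit-liability ",
                        "decomposition: got total %.12f"), total))
  }
  if (covAC_total != 0 && sigma2_C <= 0) {
    stop("covAC_total != 0 requires sigma2_C > 0")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

# Threshold such that E[Phi(x'beta - tau)] = prevalence, integrating over the
# covariate distribution (sex Bernoulli, age Gauss-Hermite), so prevalence is
# controlled in expectation rather than by empirical quantile.
solve_threshold <- function(config) {
  gh <- lme4::GHrule(40)
  age <- config$age_mean + config$age_sd * gh[, "z"]
  w_age <- gh[, "w"]
  ca <- (age - 80) / 10
  eta_age <- config$beta_age * ca + config$beta_age2 * ca^2
  p_f <- 1 - config$p_male
  prev <- function(tau) {
    sum(w_age * ((1 - p_f) * pnorm(eta_age - tau) +
                   p_f * pnorm(config$beta_sex + eta_age - tau))) -
      config$prevalence
  }
  uniroot(prev, c(-20, 20), tol = 1e-10)$root
}

# Bivariate latent draws with cross-twin correlation r (per pair).
# Returns 2*n vector interleaved twin1, twin2.
latent_pair <- function(n_pairs, r_twin) {
  z1 <- rnorm(n_pairs)
  z2 <- r_twin * z1 + sqrt(1 - r_twin^2) * rnorm(n_pairs)
  as.vector(rbind(z1, z2))
}

#' Simulate a liability-threshold twin cohort
#'
#' @param config a [cohort_sim_config()].
#' @param panel optional `genotype_panel` (required in genotype mode) whose
#'   pair structure must match the config counts.
#' @param prs_weights optional named numeric vector of true per-allele
#'   weights (genotype mode).
#' @return a `twin_cohort` data.frame, one row per twin, with pair metadata,
#'   covariates, standardized polygenic score `zprs`, APOE allele counts,
#'   standardized epsilon-4 score `ze4`, and disease status `ad`.
#' @export
simulate_liability_cohort <- function(config, panel = NULL, prs_weights = NULL) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n_mz <- config$n_mz; n_dz <- config$n_dz
  n_pairs <- n_mz + n_dz
  if (config$mode == "genotype" && (is.null(panel) || is.null(prs_weights))) {
    stop("genotype mode requires `panel` and `prs_weights`")
  }
  ind <- pair_frame(n_mz, n_dz)
  mz_row <- ind$zygosity == "MZ"
  r_g <- ifelse(mz_row[ind$twin == 1], 1, 0.5)

  seed <- config$seed
  # Covariates
  cov_dat <- with_seed(derive_seed(seed, 1), {
    age_p <- rnorm(n_pairs, config$age_mean, config$age_sd)
    sex1 <- rbinom(n_pairs, 1, 1 - config$p_male)        # 1 = female
    sex2 <- ifelse(mz_row[ind$twin == 1],
                   sex1, rbinom(n_pairs, 1, 1 - config$p_male))
    list(age = rep(age_p, each = 2), sex = as.vector(rbind(sex1, sex2)))
  })
  age <- cov_dat$age
  sex <- cov_dat$sex
  cage <- (age - 80) / 10

  s <- sqrt(c(AP = config$sigma2_AP, AE4 = config$sigma2_Ae4,
              AB = config$sigma2_AB, C = config$sigma2_C,
              E = config$sigma2_E))

  # A_P: standardized polygenic score with MZ/DZ cross-twin correlation
  if (config$mode == "direct") {
    aP <- with_seed(derive_seed(seed, 2), latent_pair(n_pairs, r_g))
    zprs <- aP
  } else {
    if (nrow(panel$ind) != 2 * n_pairs ||
        !identical(panel$ind$zygosity, ind$zygosity)) {
      stop("panel pair structure does not match config counts")
    }
    wts <- prs_weights[colnames(panel$dosage)]
    if (anyNA(wts)) stop("`prs_weights` must cover all panel SNPs")
    raw <- as.vector(panel$dosage %*% wts)
    if (sd(raw) == 0) stop("true-weight score is constant; cannot standardize")
    zprs <- (raw - mean(raw)) / sd(raw)
    aP <- zprs
  }

  # APOE epsilon counts (always simulated; enter liability only if share > 0)
  apoe <- simulate_apoe_counts(n_pairs, mz_row[ind$twin == 1],
                               c(config$e2_freq, 1 - config$e2_freq - config$e4_freq,
                                 config$e4_freq),
                               derive_seed(seed, 3))
  f4 <- config$e4_freq
  ze4 <- (apoe$e4 - 2 * f4) / sqrt(2 * f4 * (1 - f4))

  comp <- with_seed(derive_seed(seed, 4), {
    aB <- latent_pair(n_pairs, r_g)
    e <- rnorm(2 * n_pairs)
    c0 <- rnorm(n_pairs)
    list(aB = aB, e = e, c0 = c0)
  })
  aB <- comp$aB

  # Shared environment, optionally correlated with the A components.
  # c = dP*uP + dB*uB + sqrt(1 - dP^2 - dB^2)*c0 where uX is the unit-variance
  # pair mean of component X, giving cov(aX_i, c) = dX*sqrt((1+r_g)/2).
  cshare <- numeric(2 * n_pairs)
  if (config$sigma2_C > 0) {
    sAC_P <- config$covAC_total * config$covac_on_AP
    sAC_B <- config$covAC_total - sAC_P
    rho_Pc <- if (sAC_P != 0) sAC_P / (s["AP"] * s["C"]) else 0
    rho_Bc <- if (sAC_B != 0) sAC_B / (s["AB"] * s["C"]) else 0
    if ((rho_Pc != 0 && s["AP"] == 0) || (rho_Bc != 0 && s["AB"] == 0)) {
      stop("covAC assigned to a component with zero variance")
    }
    t1 <- ind$twin == 1
    scale_u <- sqrt((1 + r_g) / 2)
    # (x1+x2)/sqrt(2(1+r)) has unit variance; cov with x_i is sqrt((1+r)/2)
    uP <- if (s["AP"] > 0) (aP[t1] + aP[!t1]) / sqrt(2 * (1 + r_g)) else rep(0, n_pairs)
    uB <- (aB[t1] + aB[!t1]) / sqrt(2 * (1 + r_g))
    dP <- if (rho_Pc != 0) rho_Pc / scale_u else rep(0, n_pairs)
    dB <- if (rho_Bc != 0) rho_Bc / scale_u else rep(0, n_pairs)
    rem <- 1 - dP^2 - dB^2
    if (any(rem < 0)) stop("requested covAC exceeds the attainable correlation")
    cpair <- dP * uP + dB * uB + sqrt(rem) * comp$c0
    cshare <- rep(cpair, each = 2)
  }

  liab <- s["AP"] * aP + s["AE4"] * ze4 + s["AB"] * aB +
    s["C"] * cshare + s["E"] * comp$e
  eta <- config$beta_sex * sex + config$beta_age * cage +
    config$beta_age2 * cage^2
  tau <- solve_threshold(config)
  ad <- as.integer(liab + eta > tau)

  arr <- if (!is.null(panel)) panel$ind$array else
    with_seed(derive_seed(seed, 5),
              sample(c("PsychArray", "OmniExpress"), 2 * n_pairs, replace = TRUE,
                     prob = c(1451 / 1586, 1 - 1451 / 1586)))

  cohort <- data.frame(
    id = ind$id, pair_id = ind$pair_id, twin = ind$twin,
    zygosity = ind$zygosity,
    sex = sex, age = age, cage = cage, cage2 = cage^2,
    ad = ad, array = arr,
    complete_pair = TRUE, prs_imputed = FALSE,
    zprs = zprs, e2_count = apoe$e2, e4_count = apoe$e4, ze4 = ze4,
    stringsAsFactors = FALSE
  )
  if (isTRUE(config$keep_latent)) {
    cohort$lat_AP <- aP; cohort$lat_AB <- aB
    cohort$lat_C <- cshare; cohort$lat_E <- comp$e
    cohort$liability <- liab
  }
  attr(cohort, "threshold") <- tau
  attr(cohort, "config") <- config
  class(cohort) <- c("twin_cohort", "data.frame")
  cohort
}

#' Apply pair incompleteness and MZ genotype missingness
#'
#' Marks a random subset of pairs incomplete (one member dropped from the
#' phenotype analysis set) and, for a random subset of MZ pairs, removes one
#' twin's genotypes and flags the retained co-twin-copied score as imputed.
#'
#' @param cohort a `twin_cohort`.
#' @param panel optional matching `genotype_panel` (rows NA'd for missing
#'   genotypes).
#' @param incomplete_rate fraction of pairs made incomplete.
#' @param mz_impute_rate fraction of MZ pairs with one twin's genotypes removed.
#' @param seed integer seed.
#' @return list with elements `cohort` and `panel`.
#' @export
apply_missingness <- function(cohort, panel = NULL,
                              incomplete_rate = 0, mz_impute_rate = 0,
                              seed = 1) {
  stopifnot_scalar(incomplete_rate, "incomplete_rate", 0, 1)
  stopifnot_scalar(mz_impute_rate, "mz_impute_rate", 0, 1)
  pairs <- unique(cohort$pair_id)
  with_seed(seed, {
    n_inc <- round(incomplete_rate * length(pairs))
    inc <- if (n_inc > 0) sample(pairs, n_inc) else integer(0)
    drop_twin <- sample(1:2, length(inc), replace = TRUE)
    drop_rows <- cohort$pair_id %in% inc &
      cohort$twin == drop_twin[match(cohort$pair_id, inc)]
    cohort$complete_pair[cohort$pair_id %in% inc] <- FALSE
    cohort <- cohort[!drop_rows, , drop = FALSE]

    mz_pairs <- unique(cohort$pair_id[cohort$zygosity == "MZ" & cohort$complete_pair])
    n_imp <- round(mz_impute_rate * length(mz_pairs))
    imp <- if (n_imp > 0) sample(mz_pairs, n_imp) else integer(0)
    if (length(imp)) {
      imp_twin <- sample(1:2, length(imp), replace = TRUE)
      miss <- cohort$pair_id %in% imp &
        cohort$twin == imp_twin[match(cohort$pair_id, imp)]
      cohort$prs_imputed[miss] <- TRUE
      # copy-imputation: the ungenotyped twin inherits the co-twin's score
      for (p in imp) {
        rows <- which(cohort$pair_id == p)
        src <- rows[!cohort$prs_imputed[rows]]
        dst <- rows[cohort$prs_imputed[rows]]
        cohort$zprs[dst] <- cohort$zprs[src]
      }
      if (!is.null(panel)) {
        miss_ids <- cohort$id[miss]
        panel$dosage[rownames(panel$dosage) %in% miss_ids, ] <- NA_real_
      }
    }
  })
  list(cohort = cohort, panel = panel)
}

#' Subset a cohort to complete pairs
#'
#' @param cohort a `twin_cohort`.
#' @return the rows belonging to pairs with both members present.
#' @export
complete_pairs <- function(cohort) {
  tab <- table(cohort$pair_id)
  keep <- cohort$pair_id %in% as.integer(names(tab)[tab == 2]) &
    cohort$complete_pair
  cohort[keep, , drop = FALSE]
}
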