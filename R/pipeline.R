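# Pipeline orchestration and command-line interface.
#
# A run configuration selects stages (simulate -> prs -> regress ->
# twinfit), carries every module's settings and one master seed; identical
# config + seed reproduces the report byte-for-byte (wall-time aside).

#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own
#'   sub-stream from it.
#' @param out_dir directory for intermediates and the report.
#' @param stages stages to run, in order.
#' @return named list (a `RunConfig`).
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("twinprs_run_"),
                               stages = c("simulate", "prs", "regress", "twinfit")) {
  list(
    seed = seed, out_dir = out_dir, stages = stages, log_level = "info",
    sim = list(n_mz = 100, n_dz = 100, n_blocks = 30, block_size = 10,
               rho = 0.7, freq_min = 0.05, freq_max = 0.5,
               n_causal = 60, beta_sd = 0.06, n_gwas = 60000,
               sigma2_AP = 0.101, sigma2_AB = 0.614, sigma2_C = 0,
               covAC_total = 0, sigma2_Ae4 = 0, sigma2_E = 0.285,
               prevalence = 431 / 1586,
               incomplete_rate = 0, mz_impute_rate = 0),
    prs = list(clump_r2 = 0.01, clump_window_bp = 250000,
               maf_floor = 0.01, info_floor = 0.8, n_pcs = 4,
               use_threshold = 1e-5),
    regress = list(link = "probit", nq = 21,
                   predictors = c("mz", "sex", "cage", "cage2", "array", "zprs")),
    twinfit = list(model = "ae_prs", n_starts = 2),
    power = list(model = "ae", drop = "sigma2_AB", alpha = 0.05,
                 n_reps = 100, n_mz = 200, n_dz = 250)
  )
}

#' Run the simulation -> PRS -> regression -> biometric pipeline
#'
#' Executes the requested stages in order, persisting intermediates under
#' `config$out_dir`; a stage failure marks the stage failed and skips
#' dependent stages.
#'
#' @param config a run configuration list (see [default_run_config()]).
#' @return a `RunReport` list (also written to `<out_dir>/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed) || is.null(config$out_dir)) {
    stop("config must carry `seed` and `out_dir`")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(version = as.character(utils::packageVersion("twinprs")),
                 seed = config$seed, config = config, stages = list())
  state <- new.env()
  failed <- FALSE
  for (stage in config$stages) {
    if (failed) {
      report$stages[[stage]] <- list(status = "skipped")
      next
    }
    res <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, state),
             prs = stage_prs(config, state),
             regress = stage_regress(config, state),
             twinfit = stage_twinfit(config, state),
             power = stage_power(config, state),
             stop(sprintf("unknown stage `%s`", stage))),
      error = function(e) e)
    if (inherits(res, "error")) {
      report$stages[[stage]] <- list(status = "failed",
                                     error = conditionMessage(res))
      failed <- TRUE
    } else {
      report$stages[[stage]] <- c(list(status = "ok"), res)
    }
  }
  report$wall_time_s <- as.numeric(proc.time()[["elapsed"]])
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

stage_simulate <- function(config, state) {
  sc <- config$sim
  pool <- simulate_haplotype_pool(sc$n_blocks, sc$block_size,
                                  c(sc$freq_min, sc$freq_max), sc$rho,
                                  seed = derive_seed(config$seed, 11))
  panel <- simulate_twin_genotypes(pool, sc$n_mz, sc$n_dz,
                                   seed = derive_seed(config$seed, 12))
  panel <- simulate_apoe(panel, seed = derive_seed(config$seed, 13))
  m <- nrow(pool$snps)
  true_betas <- with_seed(derive_seed(config$seed, 14), {
    b <- numeric(m)
    causal <- sample.int(m, min(sc$n_causal, m))
    b[causal] <- rnorm(length(causal), 0, sc$beta_sd)
    b
  })
  ss <- simulate_gwas_sumstats(pool, true_betas, sc$n_gwas,
                               seed = derive_seed(config$seed, 15))
  wts <- setNames(c(true_betas, 0.35, -0.2), panel$snps$id)  # APOE effects
  cfg <- cohort_sim_config(
    n_mz = sc$n_mz, n_dz = sc$n_dz,
    sigma2_AP = sc$sigma2_AP, sigma2_Ae4 = sc$sigma2_Ae4,
    sigma2_AB = sc$sigma2_AB, sigma2_C = sc$sigma2_C,
    covAC_total = sc$covAC_total, sigma2_E = sc$sigma2_E,
    prevalence = sc$prevalence, mode = "genotype",
    seed = derive_seed(config$seed, 16))
  cohort <- simulate_liability_cohort(cfg, panel, wts)
  mis <- apply_missingness(cohort, panel, sc$incomplete_rate,
                           sc$mz_impute_rate,
                           seed = derive_seed(config$seed, 17))
  state$panel <- mis$panel
  state$cohort <- mis$cohort
  state$sumstats <- ss
  files <- c(genotypes = file.path(config$out_dir, "genotypes.tsv"),
             cohort = file.path(config$out_dir, "cohort.tsv"),
             sumstats = file.path(config$out_dir, "sumstats.tsv"))
  write_genotypes(mis$panel, files[["genotypes"]])
  write_cohort(mis$cohort, files[["cohort"]])
  write_sumstats(ss, files[["sumstats"]])
  list(n_individuals = nrow(mis$cohort), n_snps = ncol(mis$panel$dosage),
       n_cases = sum(mis$cohort$ad),
       digests = as.list(setNames(unname(tools::md5sum(files)), names(files))))
}

stage_prs <- function(config, state) {
  pc <- config$prs
  pcfg <- prs_config(clump_r2 = pc$clump_r2,
                     clump_window_bp = pc$clump_window_bp,
                     maf_floor = pc$maf_floor, info_floor = pc$info_floor,
                     n_pcs = pc$n_pcs)
  prs <- build_prs_panel(state$panel, state$sumstats, pcfg)
  state$prs <- prs
  # attach the selected threshold's scores (cohort rows may be a subset of
  # the panel after missingness)
  thr_full <- paste0("prs_", format(pc$use_threshold, trim = TRUE,
                                    scientific = pc$use_threshold < 1e-2))
  idx <- match(state$cohort$id, prs$id)
  state$cohort$zprs <- prs[[thr_full]][idx]
  # copy-impute scores for flagged MZ co-twins whose genotypes were removed
  for (p in unique(state$cohort$pair_id[state$cohort$prs_imputed])) {
    rows <- which(state$cohort$pair_id == p)
    src <- rows[!state$cohort$prs_imputed[rows]]
    dst <- rows[state$cohort$prs_imputed[rows]]
    if (length(src) == 1) state$cohort$zprs[dst] <- state$cohort$zprs[src]
  }
  # measured APOE alleles from the panel
  al <- apoe_alleles(round(state$panel$dosage[, "rs429358"]),
                     round(state$panel$dosage[, "rs7412"]))
  aidx <- match(state$cohort$id, state$panel$ind$id)
  state$cohort$e2_count <- al$e2[aidx]
  state$cohort$e4_count <- al$e4[aidx]
  utils::write.table(prs, file.path(config$out_dir, "prs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(n_index_snps = as.list(as.data.frame(attr(prs, "n_snps"))),
       threshold_used = pc$use_threshold)
}

stage_regress <- function(config, state) {
  rc <- config$regress
  cohort <- state$cohort[!is.na(state$cohort$zprs), , drop = FALSE]
  base <- fit_mixed_probit(cohort, setdiff(rc$predictors, "zprs"),
                           link = rc$link, nq = rc$nq)
  full <- fit_mixed_probit(cohort, rc$predictors, link = rc$link, nq = rc$nq)
  test <- lrt(base, full)
  state$regress <- list(base = base, full = full)
  list(
    coefficients = full$coefficients,
    random = list(MZ = unname(full$v["MZ"]), DZ = unname(full$v["DZ"])),
    icc = as.list(full$icc),
    deviance = full$deviance, aic = full$aic, sbc = full$sbc,
    auc = auc(full),
    nagelkerke_vs_baseline = as.numeric(nagelkerke(full, base, full$n_ind)),
    lrt = test
  )
}

stage_twinfit <- function(config, state) {
  tc <- config$twinfit
  cohort <- state$cohort[!is.na(state$cohort$zprs), , drop = FALSE]
  fit <- fit_biometric(cohort, tc$model, n_starts = tc$n_starts,
                       seed = derive_seed(config$seed, 31))
  state$twinfit <- fit
  list(shares = as.list(fit$shares), se = as.list(fit$se_shares),
       minus2LL = fit$minus2LL, k = fit$k, aic = fit$aic, bic = fit$bic,
       n_pairs = fit$n_pairs, converged = fit$converged)
}

stage_power <- function(config, state) {
  pc <- config$power
  sc <- config$sim
  gen <- cohort_sim_config(
    n_mz = pc$n_mz, n_dz = pc$n_dz,
    sigma2_AP = sc$sigma2_AP, sigma2_Ae4 = sc$sigma2_Ae4,
    sigma2_AB = sc$sigma2_AB, sigma2_C = sc$sigma2_C,
    covAC_total = sc$covAC_total, sigma2_E = sc$sigma2_E,
    prevalence = sc$prevalence, seed = 0)
  drop <- setNames(list(0), pc$drop)
  pw <- power_sim(gen, pc$model, drop, alpha = pc$alpha,
                  n_reps = pc$n_reps, seed = derive_seed(config$seed, 41))
  list(component = pc$drop, power = pw$power, mc_se = pw$mc_se,
       n_reps = pw$n_reps)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `prs`, `regress`, `twinfit`, `power`,
#' `pipeline`.  All run through [run_pipeline()] with the stage list set
#' accordingly; `--config` supplies a JSON configuration and `--seed`
#' overrides its seed.
#'
#' @param args character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the run report.
#' @export
twinprs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: twinprs <simulate|prs|regress|twinfit|power|pipeline> [--config F] [--seed N] [--out D]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL)
  ))
  opts <- optparse::parse_args(parser, args = args[-1])
  config <- if (!is.null(opts$config)) read_run_config(opts$config) else
    default_run_config()
  if (!is.null(opts$seed)) config$seed <- opts$seed
  if (!is.null(opts$out)) config$out_dir <- opts$out
  if (is.null(config$out_dir)) config$out_dir <- "twinprs_out"
  stage_sets <- list(
    simulate = "simulate",
    prs = c("simulate", "prs"),
    regress = c("simulate", "prs", "regress"),
    twinfit = c("simulate", "prs", "twinfit"),
    power = "power",
    pipeline = c("simulate", "prs", "regress", "twinfit"))
  if (!cmd %in% names(stage_sets)) stop(sprintf("unknown subcommand `%s`", cmd))
  config$stages <- stage_sets[[cmd]]
  report <- run_pipeline(config)
  cat(sprintf("report written to %s\n",
              file.path(config$out_dir, "report.json")))
  invisible(report)
}
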