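# Clumping-and-thresholding polygenic risk scores.

#' PRS construction configuration
#'
#' @param p_thresholds GWAS p-value inclusion thresholds; default the eight
#'   conventional cutoffs 1, 0.5, 0.05, 0.01, 1e-3, 1e-4, 1e-5, 5e-8.
#' @param clump_r2 squared allelic correlation above which a SNP is pruned
#'   against a more significant index SNP.
#' @param clump_window_bp window (bp) within which LD is evaluated; SNPs
#'   farther apart on a chromosome are treated as independent.  `Inf` gives
#'   genome-wide-within-chromosome clumping.
#' @param maf_floor minimum panel minor allele frequency.
#' @param info_floor minimum imputation info score (exclusive bound).
#' @param apoe_chr,apoe_start,apoe_end APOE region (closed interval,
#'   GRCh37-style defaults chr19:44,400,000-46,500,000).
#' @param n_pcs number of ancestry principal components to residualize on.
#' @return an object of class `prs_config`.
#' @export
prs_config <- function(p_thresholds = c(1, 0.5, 0.05, 0.01, 1e-3, 1e-4, 1e-5, 5e-8),
                       clump_r2 = 0.01, clump_window_bp = 250000,
                       maf_floor = 0.01, info_floor = 0.8,
                       apoe_chr = 19L, apoe_start = 44400000L,
                       apoe_end = 46500000L, n_pcs = 4L) {
  if (any(p_thresholds <= 0) || any(p_thresholds > 1)) {
    stop("`p_thresholds` must lie in (0, 1]")
  }
  stopifnot_scalar(clump_r2, "clump_r2", 1e-12, 1)
  stopifnot_scalar(maf_floor, "maf_floor", 1e-12, 0.5 - 1e-12)
  structure(list(p_thresholds = sort(p_thresholds, decreasing = TRUE),
                 clump_r2 = clump_r2, clump_window_bp = clump_window_bp,
                 maf_floor = maf_floor, info_floor = info_floor,
                 apoe_chr = apoe_chr, apoe_start = apoe_start,
                 apoe_end = apoe_end, n_pcs = as.integer(n_pcs)),
            class = "prs_config")
}

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Quality-control filter and allele harmonization of summary statistics
#'
#' Removes strand-ambiguous SNPs, SNPs absent from the genotype panel, SNPs
#' below the panel MAF floor or at/below the info floor, and flips effect
#' signs where the summary-statistics effect allele matches the panel's
#' other allele.  Irreconcilable allele pairs are dropped with a logged
#' count, not an error.
#'
#' @param sumstats a `sumstats` data.frame (columns SNP, CHR, BP, A1, A2,
#'   BETA, P, optionally INFO).
#' @param panel a `genotype_panel`.
#' @param config a [prs_config()].
#' @return the filtered, harmonized `sumstats`, with attribute `qc_counts`.
#' @export
qc_filter <- function(sumstats, panel, config = prs_config()) {
  counts <- c(input = nrow(sumstats))
  keep <- !is_ambiguous(toupper(sumstats$A1), toupper(sumstats$A2))
  counts["ambiguous"] <- sum(!keep)
  ss <- sumstats[keep, , drop = FALSE]

  idx <- match(ss$SNP, panel$snps$id)
  counts["absent"] <- sum(is.na(idx))
  ss <- ss[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  f <- colMeans(panel$dosage[, idx, drop = FALSE], na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  info <- if (!is.null(ss$INFO)) ss$INFO else panel$snps$info[idx]
  ok <- maf >= config$maf_floor & info > config$info_floor
  counts["maf_info"] <- sum(!ok)
  ss <- ss[ok, , drop = FALSE]
  idx <- idx[ok]

  pa1 <- toupper(panel$snps$a1[idx]); pa2 <- toupper(panel$snps$a2[idx])
  sa1 <- toupper(ss$A1); sa2 <- toupper(ss$A2)
  same <- sa1 == pa1 & sa2 == pa2
  flip <- sa1 == pa2 & sa2 == pa1
  counts["allele_mismatch"] <- sum(!(same | flip))
  ss$BETA[flip] <- -ss$BETA[flip]
  ss$A1[flip] <- pa1[flip]; ss$A2[flip] <- pa2[flip]
  ss <- ss[same | flip, , drop = FALSE]
  tw_log("qc_filter: %d -> %d SNPs (ambiguous %d, absent %d, maf/info %d, allele %d)",
         counts["input"], nrow(ss), counts["ambiguous"], counts["absent"],
         counts["maf_info"], counts["allele_mismatch"])
  attr(ss, "qc_counts") <- counts
  ss
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken on chromosome then
#' position) and accepts a SNP iff its squared dosage correlation with every
#' already-accepted SNP on the same chromosome within the window is below
#' `clump_r2`.
#'
#' @param sumstats filtered `sumstats`.
#' @param panel `genotype_panel` covering all SNPs in `sumstats`.
#' @param config a [prs_config()].
#' @return character vector of index SNP ids.
#' @export
ld_clump <- function(sumstats, panel, config = prs_config()) {
  if (nrow(sumstats) == 0) return(character(0))
  ord <- order(sumstats$P, sumstats$CHR, sumstats$BP)
  ss <- sumstats[ord, , drop = FALSE]
  col <- match(ss$SNP, colnames(panel$dosage))
  if (anyNA(col)) stop("panel does not cover all summary-statistic SNPs")
  G <- panel$dosage[, col, drop = FALSE]
  # centered columns for fast pairwise correlation
  G <- sweep(G, 2, colMeans(G, na.rm = TRUE))
  G[is.na(G)] <- 0
  ssq <- colSums(G^2)
  accepted <- integer(0)
  for (j in seq_len(nrow(ss))) {
    if (ssq[j] == 0) next  # monomorphic: no LD definable, skip defensively
    near <- accepted[ss$CHR[accepted] == ss$CHR[j] &
                       abs(ss$BP[accepted] - ss$BP[j]) <= config$clump_window_bp]
    ok <- TRUE
    if (length(near)) {
      r2 <- (crossprod(G[, near, drop = FALSE], G[, j])^2) /
        (ssq[near] * ssq[j])
      ok <- all(r2 < config$clump_r2)
    }
    if (ok) accepted <- c(accepted, j)
  }
  ss$SNP[accepted]
}

#' Compute raw allele-weighted scores
#'
#' score_i = sum over index SNPs with p <= threshold of beta * dosage.
#' Missing dosages are mean-imputed per SNP (count logged).
#'
#' @param panel a `genotype_panel`.
#' @param sumstats harmonized `sumstats`.
#' @param threshold p-value cutoff.
#' @param index_snps ids retained by [ld_clump()].
#' @return named numeric vector of raw scores (attribute `n_snps`).
#' @export
compute_prs <- function(panel, sumstats, threshold, index_snps) {
  use <- sumstats$SNP %in% index_snps & sumstats$P <= threshold
  snps <- sumstats$SNP[use]
  if (length(snps) == 0) {
    out <- setNames(numeric(nrow(panel$ind)), panel$ind$id)
    attr(out, "n_snps") <- 0L
    return(out)
  }
  G <- panel$dosage[, match(snps, colnames(panel$dosage)), drop = FALSE]
  n_miss <- sum(is.na(G))
  if (n_miss > 0) {
    tw_log("compute_prs: mean-imputing %d missing dosages", n_miss)
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  out <- as.vector(G %*% sumstats$BETA[use])
  names(out) <- panel$ind$id
  attr(out, "n_snps") <- length(snps)
  out
}

#' Remove SNPs in the APOE region
#'
#' Drops SNPs on the APOE chromosome with position in the closed interval
#' `[apoe_start, apoe_end]`.
#'
#' @param sumstats a `sumstats` data.frame.
#' @param config a [prs_config()].
#' @return the filtered `sumstats`.
#' @export
exclude_apoe_region <- function(sumstats, config = prs_config()) {
  drop <- sumstats$CHR == config$apoe_chr &
    sumstats$BP >= config$apoe_start & sumstats$BP <= config$apoe_end
  sumstats[!drop, , drop = FALSE]
}

#' Build the full PRS panel across thresholds and variant sets
#'
#' Runs QC, clumps the full and APOE-excluded summary statistics separately,
#' scores every threshold, residualizes on ancestry PCs and standardizes
#' within array.
#'
#' @param panel a `genotype_panel`.
#' @param sumstats raw `sumstats`.
#' @param config a [prs_config()].
#' @return a data.frame keyed by individual id with one standardized-score
#'   column per (threshold, variant set), named like `prs_1e-05` /
#'   `prs_noapoe_1e-05`, plus attribute `n_snps` (matrix of SNP counts).
#' @export
build_prs_panel <- function(panel, sumstats, config = prs_config()) {
  ss <- qc_filter(sumstats, panel, config)
  sets <- list(full = ss, noapoe = exclude_apoe_region(ss, config))
  pcs <- pca_ancestry(panel, config$n_pcs)
  out <- data.frame(id = panel$ind$id, stringsAsFactors = FALSE)
  n_snps <- matrix(0L, length(config$p_thresholds), 2,
                   dimnames = list(format(config$p_thresholds, trim = TRUE),
                                   names(sets)))
  for (set in names(sets)) {
    idx <- ld_clump(sets[[set]], panel, config)
    for (i in seq_along(config$p_thresholds)) {
      thr <- config$p_thresholds[i]
      raw <- compute_prs(panel, sets[[set]], thr, idx)
      n_snps[i, set] <- attr(raw, "n_snps")
      z <- residualize_standardize(raw, pcs, panel$ind$array)
      nm <- paste0(if (set == "full") "prs_" else "prs_noapoe_",
                   format(thr, trim = TRUE, scientific = thr < 1e-2))
      out[[nm]] <- z
    }
  }
  attr(out, "n_snps") <- n_snps
  out
}
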