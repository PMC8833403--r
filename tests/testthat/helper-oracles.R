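# Independent oracles and small fixture builders used across the suite.

# Bivariate normal upper-orthant probability by 1-D numerical integration
# (base R only; independent of the package's quadrature implementation).
bvn_oracle <- function(h, k, rho) {
  if (rho == 0) return(pnorm(-h) * pnorm(-k))
  if (rho == 1) return(pnorm(-max(h, k)))
  if (rho == -1) return(max(0, 1 - pnorm(h) - pnorm(k)))
  integrate(function(y) dnorm(y) * pnorm((rho * y - h) / sqrt(1 - rho^2)),
            k, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Exhaustive greedy clumping oracle: computes the full pairwise r^2 matrix
# up front (no windowing tricks, no incremental state).
clump_oracle <- function(sumstats, panel, r2_max, window_bp) {
  ord <- order(sumstats$P, sumstats$CHR, sumstats$BP)
  ss <- sumstats[ord, , drop = FALSE]
  G <- panel$dosage[, match(ss$SNP, colnames(panel$dosage)), drop = FALSE]
  R2 <- suppressWarnings(cor(G))^2
  R2[is.na(R2)] <- 0
  kept <- integer(0)
  for (j in seq_len(nrow(ss))) {
    ok <- TRUE
    for (a in kept) {
      if (ss$CHR[a] == ss$CHR[j] &&
          abs(ss$BP[a] - ss$BP[j]) <= window_bp &&
          R2[a, j] >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  ss$SNP[kept]
}

# Log density of a multivariate normal (small dimensions, plain algebra).
dmvnorm_log <- function(x, mu, S) {
  d <- length(mu)
  ch <- chol(S)
  z <- backsolve(ch, x - mu, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

# Monte-Carlo estimate of P(sign-pattern rectangle) for liabilities with
# means mu (length 2), covariance S (2x2), statuses y.
rect_mc <- function(mu, S, y, n = 2e5) {
  ch <- chol(S)
  Z <- matrix(rnorm(2 * n), n, 2) %*% ch
  L1 <- Z[, 1] + mu[1]; L2 <- Z[, 2] + mu[2]
  hit <- (L1 > 0) == (y[1] == 1) & (L2 > 0) == (y[2] == 1)
  p <- mean(hit)
  list(p = p, se = sqrt(p * (1 - p) / n))
}

# Minimal genotype panel built from an explicit dosage matrix.
make_panel <- function(dosage, chr, pos, a1, a2, zygosity = NULL,
                       info = NULL, freq = NULL) {
  n <- nrow(dosage); m <- ncol(dosage)
  stopifnot(n %% 2 == 0)
  n_pairs <- n / 2
  if (is.null(zygosity)) zygosity <- rep("DZ", n_pairs)
  ind <- data.frame(
    id = sprintf("P%05d_T%d", rep(seq_len(n_pairs), each = 2), rep(1:2, n_pairs)),
    pair_id = rep(seq_len(n_pairs), each = 2),
    twin = rep(1:2, n_pairs),
    zygosity = rep(zygosity, each = 2),
    array = rep(c("PsychArray", "OmniExpress"), length.out = n),
    stringsAsFactors = FALSE)
  rownames(dosage) <- ind$id
  snps <- data.frame(
    id = colnames(dosage), chr = chr, pos = pos, a1 = a1, a2 = a2,
    freq = if (is.null(freq)) colMeans(dosage) / 2 else freq,
    info = if (is.null(info)) rep(0.95, m) else info,
    block = seq_len(m), stringsAsFactors = FALSE)
  structure(list(dosage = dosage, ind = ind, snps = snps),
            class = "genotype_panel")
}

make_sumstats <- function(id, chr, pos, a1, a2, beta, p, info = NULL) {
  out <- data.frame(SNP = id, CHR = chr, BP = pos, A1 = a1, A2 = a2,
                    BETA = beta, P = p, stringsAsFactors = FALSE)
  if (!is.null(info)) out$INFO <- info
  class(out) <- c("sumstats", "data.frame")
  out
}

# Generating configuration shortcuts (the cohort "worlds" used repeatedly):
# reduced AE world (A = 0.707), reduced AE+PRS world, and the AE+PRS+e4
# world, at the headline variance shares.
world_ae <- function(n_mz, n_dz, seed)
  cohort_sim_config(n_mz, n_dz, sigma2_AB = 0.707, sigma2_E = 0.293,
                    prevalence = 0.27, seed = seed)
world_ae_prs <- function(n_mz, n_dz, seed, ...)
  cohort_sim_config(n_mz, n_dz, sigma2_AP = 0.101, sigma2_AB = 0.614,
                    sigma2_E = 0.285, prevalence = 0.27, seed = seed, ...)
world_ae_prs_e4 <- function(n_mz, n_dz, seed)
  cohort_sim_config(n_mz, n_dz, sigma2_AP = 0.021, sigma2_Ae4 = 0.093,
                    sigma2_AB = 0.596, sigma2_E = 0.290,
                    prevalence = 0.27, seed = seed)
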