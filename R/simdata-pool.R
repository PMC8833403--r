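# Synthetic SNP panels with block LD and twin genotype sharing.
#
# LD is modelled by a latent-Gaussian AR(1) process within blocks: a
# haplotype carries the effect allele at SNP j iff z_j < qnorm(freq_j),
# where z is AR(1) with parameter rho inside a block and independent across
# blocks.  This gives tunable, analytically checkable allelic correlation
# and makes exhaustive clumping oracles cheap.

NON_AMBIGUOUS_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("G", "A"),
  c("C", "T"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Simulate a haplotype pool with block-LD structure
#'
#' @param n_blocks number of independent LD blocks.
#' @param block_size SNPs per block.
#' @param freq_range range of effect-allele frequencies, within (0, 0.5].
#' @param rho latent-Gaussian AR(1) correlation within blocks, in [0, 1).
#' @param seed integer seed.
#' @param chr chromosome label for all blocks.
#' @param pos_start first base-pair position.
#' @param spacing_bp within-block inter-SNP spacing (bp).
#' @param block_gap_bp gap between consecutive blocks (bp); keep larger than
#'   any clumping window so blocks stay independent for clumping purposes.
#' @param info_range range of simulated imputation info scores, within (0, 1].
#' @return an object of class `haplotype_pool` with elements `snps`
#'   (metadata data.frame), `rho`, `block_sizes`.
#' @export
simulate_haplotype_pool <- function(n_blocks, block_size,
                                    freq_range = c(0.05, 0.5),
                                    rho = 0, seed = 1,
                                    chr = 1L, pos_start = 1e5,
                                    spacing_bp = 1e4, block_gap_bp = 2e6,
                                    info_range = c(0.81, 1)) {
  stopifnot_scalar(n_blocks, "n_blocks", 1)
  stopifnot_scalar(block_size, "block_size", 1)
  stopifnot_scalar(rho, "rho", 0, 1 - 1e-12)
  if (length(freq_range) != 2 || any(freq_range <= 0) || any(freq_range > 0.5) ||
      freq_range[1] > freq_range[2]) {
    stop("`freq_range` must be an increasing pair within (0, 0.5]")
  }
  m <- n_blocks * block_size
  with_seed(seed, {
    block <- rep(seq_len(n_blocks), each = block_size)
    within <- sequence(rep(block_size, n_blocks)) - 1L
    pos <- pos_start + (block - 1L) * block_gap_bp + within * spacing_bp
    freq <- runif(m, freq_range[1], freq_range[2])
    info <- runif(m, info_range[1], info_range[2])
    al <- NON_AMBIGUOUS_PAIRS[sample.int(nrow(NON_AMBIGUOUS_PAIRS), m, replace = TRUE), ,
                              drop = FALSE]
    snps <- data.frame(
      id = sprintf("snp_%d_%d", block, within + 1L),
      chr = as.integer(chr), pos = as.integer(pos),
      a1 = al[, 1], a2 = al[, 2],
      freq = freq, info = info, block = block,
      stringsAsFactors = FALSE
    )
    structure(list(snps = snps, rho = rho,
                   block_sizes = rep(block_size, n_blocks)),
              class = "haplotype_pool")
  })
}

# Draw n haplotypes (n x m 0/1 matrix of effect-allele indicators).
# Uses the current RNG stream; callers seed it.
draw_haplotypes <- function(pool, n) {
  snps <- pool$snps
  m <- nrow(snps)
  z <- matrix(rnorm(n * m), n, m)
  rho <- pool$rho
  if (rho > 0) {
    blk <- snps$block
    for (j in seq_len(m)[-1]) {
      if (blk[j] == blk[j - 1]) {
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
  }
  h <- sweep(z, 2, qnorm(snps$freq), "<")
  storage.mode(h) <- "integer"
  h
}

#' Simulate twin-pair genotype dosages from a haplotype pool
#'
#' Each pair receives two parents with two haplotypes each.  DZ twins each
#' draw one gamete per parent independently (haplotype choice per LD block,
#' free recombination between blocks, none within); MZ twins share the same
#' zygote, so their dosage rows are identical.
#'
#' @param pool a `haplotype_pool`.
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param seed integer seed.
#' @param array_labels labels of the two genotyping arrays.
#' @param array_prop proportion of individuals on the first array.
#' @return an object of class `genotype_panel`: `dosage` (individuals x SNPs
#'   matrix), `ind` (individual metadata), `snps` (SNP metadata).
#' @export
simulate_twin_genotypes <- function(pool, n_mz, n_dz, seed = 1,
                                    array_labels = c("PsychArray", "OmniExpress"),
                                    array_prop = 1451 / 1586) {
  stopifnot_scalar(n_mz, "n_mz", 0)
  stopifnot_scalar(n_dz, "n_dz", 0)
  n_pairs <- n_mz + n_dz
  snps <- pool$snps
  m <- nrow(snps)
  ind <- pair_frame(n_mz, n_dz)
  if (n_pairs == 0) {
    return(structure(list(dosage = matrix(0, 0, m,
                                          dimnames = list(NULL, snps$id)),
                          ind = cbind(ind, array = character(0)),
                          snps = snps),
                     class = "genotype_panel"))
  }
  with_seed(seed, {
    H <- draw_haplotypes(pool, 4L * n_pairs)
    dos <- inherit_dosages(H, snps$block, ind)
    colnames(dos) <- snps$id
    rownames(dos) <- ind$id
    ind$array <- sample(array_labels, nrow(ind), replace = TRUE,
                        prob = c(array_prop, 1 - array_prop))
    structure(list(dosage = dos, ind = ind, snps = snps),
              class = "genotype_panel")
  })
}

# Standard pair/individual scaffold: one row per twin, twin 1 then twin 2.
pair_frame <- function(n_mz, n_dz) {
  n_pairs <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  data.frame(
    id = sprintf("P%05d_T%d", rep(seq_len(n_pairs), each = 2), rep(1:2, n_pairs)),
    pair_id = rep(seq_len(n_pairs), each = 2),
    twin = rep(1:2, n_pairs),
    zygosity = rep(zyg, each = 2),
    stringsAsFactors = FALSE
  )
}

# Meiosis: per pair, haplotype rows 4p-3..4p are mother(1,2), father(3,4).
# Gamete choice is per block; MZ twins reuse twin 1's choices.
inherit_dosages <- function(H, block, ind) {
  n_pairs <- max(ind$pair_id)
  n_blocks <- max(block)
  m <- ncol(H)
  dos <- matrix(0L, 2L * n_pairs, m)
  mz <- ind$zygosity[ind$twin == 1] == "MZ"
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    cm1 <- sample.int(2L, n_pairs, replace = TRUE)   # twin 1 maternal choice
    cf1 <- sample.int(2L, n_pairs, replace = TRUE)
    cm2 <- sample.int(2L, n_pairs, replace = TRUE)
    cf2 <- sample.int(2L, n_pairs, replace = TRUE)
    cm2[mz] <- cm1[mz]
    cf2[mz] <- cf1[mz]
    base <- 4L * (seq_len(n_pairs) - 1L)
    dos[seq(1, 2 * n_pairs, by = 2), cols] <-
      H[base + cm1, cols, drop = FALSE] + H[base + 2L + cf1, cols, drop = FALSE]
    dos[seq(2, 2 * n_pairs, by = 2), cols] <-
      H[base + cm2, cols, drop = FALSE] + H[base + 2L + cf2, cols, drop = FALSE]
  }
  dos
}

# APOE haplotype system: epsilon-2 = (rs429358-T, rs7412-T),
# epsilon-3 = (T, C), epsilon-4 = (C, C).  Effect alleles are stored as the
# rs429358 C dosage (counts epsilon-4) and rs7412 T dosage (counts epsilon-2).

#' Append APOE rs429358/rs7412 dosages to a genotype panel
#'
#' Draws epsilon-2/3/4 haplotypes at the given frequencies for each parental
#' haplotype and transmits them with the same MZ/DZ sharing as the rest of
#' the genome.
#'
#' @param panel a `genotype_panel`.
#' @param hap_freqs frequencies of (epsilon-2, epsilon-3, epsilon-4), summing to 1.
#' @param seed integer seed.
#' @return the panel with two extra SNP columns (`rs429358`, `rs7412`)
#'   placed in the APOE region on chromosome 19.
#' @export
simulate_apoe <- function(panel, hap_freqs = c(0.094, 0.742, 0.164), seed = 1) {
  if (length(hap_freqs) != 3 || any(hap_freqs < 0) ||
      abs(sum(hap_freqs) - 1) > 1e-8) {
    stop("`hap_freqs` must be three nonnegative frequencies summing to 1")
  }
  ind <- panel$ind
  n_pairs <- if (nrow(ind)) max(ind$pair_id) else 0L
  counts <- simulate_apoe_counts(n_pairs, ind$zygosity[ind$twin == 1] == "MZ",
                                 hap_freqs, seed)
  extra <- cbind(rs429358 = counts$e4, rs7412 = counts$e2)
  rownames(extra) <- ind$id
  snps2 <- data.frame(
    id = c("rs429358", "rs7412"),
    chr = 19L, pos = c(45411941L, 45412079L),
    a1 = c("C", "T"), a2 = c("T", "C"),
    freq = c(hap_freqs[3], hap_freqs[1]),
    info = 1, block = max(c(0L, panel$snps$block)) + 1L,
    stringsAsFactors = FALSE
  )
  panel$dosage <- cbind(panel$dosage, extra)
  panel$snps <- rbind(panel$snps, snps2)
  panel
}

# Per-twin epsilon-2 and epsilon-4 allele counts with twin sharing.
# Returns list(e2, e4) of length 2*n_pairs (twin 1, twin 2 interleaved).
simulate_apoe_counts <- function(n_pairs, mz, hap_freqs, seed) {
  if (n_pairs == 0) return(list(e2 = integer(0), e4 = integer(0)))
  with_seed(seed, {
    # 4 parental haplotypes per pair: values 2, 3, 4
    hap <- matrix(sample(c(2L, 3L, 4L), 4L * n_pairs, replace = TRUE,
                         prob = hap_freqs), n_pairs, 4)
    cm1 <- sample.int(2L, n_pairs, TRUE); cf1 <- sample.int(2L, n_pairs, TRUE)
    cm2 <- sample.int(2L, n_pairs, TRUE); cf2 <- sample.int(2L, n_pairs, TRUE)
    cm2[mz] <- cm1[mz]; cf2[mz] <- cf1[mz]
    idx <- seq_len(n_pairs)
    t1 <- cbind(hap[cbind(idx, cm1)], hap[cbind(idx, 2L + cf1)])
    t2 <- cbind(hap[cbind(idx, cm2)], hap[cbind(idx, 2L + cf2)])
    e2 <- integer(2 * n_pairs); e4 <- integer(2 * n_pairs)
    e2[seq(1, 2 * n_pairs, 2)] <- rowSums(t1 == 2L)
    e2[seq(2, 2 * n_pairs, 2)] <- rowSums(t2 == 2L)
    e4[seq(1, 2 * n_pairs, 2)] <- rowSums(t1 == 4L)
    e4[seq(2, 2 * n_pairs, 2)] <- rowSums(t2 == 4L)
    list(e2 = e2, e4 = e4)
  })
}

#' Simulate GWAS summary statistics for a haplotype pool
#'
#' Effect estimates are drawn around the true per-allele effects with the
#' standard single-SNP sampling error se = 1/sqrt(2 n f (1 - f)); two-sided
#' p-values come from the Wald statistic.
#'
#' @param pool a `haplotype_pool`.
#' @param true_betas numeric vector, one per SNP in the pool.
#' @param n_gwas effective GWAS sample size (>= 10).
#' @param seed integer seed.
#' @param se_floor lower bound on the sampling standard error.
#' @return a `sumstats` data.frame with columns SNP, CHR, BP, A1, A2, BETA,
#'   P, INFO.
#' @export
simulate_gwas_sumstats <- function(pool, true_betas, n_gwas, seed = 1,
                                   se_floor = 1e-8) {
  snps <- pool$snps
  if (length(true_betas) != nrow(snps)) {
    stop("`true_betas` must have one value per SNP in the pool")
  }
  stopifnot_scalar(n_gwas, "n_gwas", 10)
  with_seed(seed, {
    f <- snps$freq
    se <- pmax(1 / sqrt(2 * n_gwas * f * (1 - f)), se_floor)
    beta_hat <- rnorm(nrow(snps), true_betas, se)
    p <- pmax(2 * pnorm(-abs(beta_hat / se)), 1e-300)
    out <- data.frame(
      SNP = snps$id, CHR = snps$chr, BP = snps$pos,
      A1 = snps$a1, A2 = snps$a2,
      BETA = beta_hat, SE = se, P = p, INFO = snps$info,
      stringsAsFactors = FALSE
    )
    class(out) <- c("sumstats", "data.frame")
    out
  })
}
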