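test_that("qc_filter removes ambiguous/rare/low-info SNPs and harmonizes alleles", {
  dos <- cbind(s1 = c(2, 1, 0, 1, 2, 0), s2 = c(0, 1, 2, 1, 0, 2),
               s3 = c(1, 1, 0, 2, 1, 0), s4 = c(0, 0, 0, 0, 0, 1),
               s5 = c(2, 1, 1, 0, 2, 1))
  panel <- make_panel(dos, chr = 1, pos = c(100, 200, 300, 400, 500),
                      a1 = c("A", "C", "G", "C", "A"),
                      a2 = c("G", "T", "A", "T", "T"))
  panel$snps$freq <- colMeans(dos) / 2
  ss <- make_sumstats(
    id = c("s1", "s2", "s3", "s4", "s5", "s9"),
    chr = 1, pos = c(100, 200, 300, 400, 500, 900),
    a1 = c("A", "T", "C", "C", "A", "A"),   # s2 swapped, s3 mismatched
    a2 = c("G", "C", "T", "T", "T", "G"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    p = rep(0.01, 6), info = c(0.9, 0.9, 0.9, 0.5, 0.9, 0.9))
  out <- qc_filter(ss, panel, prs_config(maf_floor = 0.05, info_floor = 0.8))
  # s5 is A/T ambiguous; s9 absent; s4 fails info; s3 alleles irreconcilable
  expect_setequal(out$SNP, c("s1", "s2"))
  expect_equal(out$BETA[out$SNP == "s1"], 0.1)    # aligned, untouched
  expect_equal(out$BETA[out$SNP == "s2"], -0.2)   # flipped to panel A1
  expect_equal(out$A1[out$SNP == "s2"], "C")
  # MAF floor: a monomorphic-ish SNP is dropped
  ss2 <- make_sumstats("s4", 1, 400, "C", "T", 0.4, 0.01, info = 0.95)
  out2 <- qc_filter(ss2, panel, prs_config(maf_floor = 0.1, info_floor = 0.8))
  expect_equal(nrow(out2), 0)
})

test_that("ld_clump keeps the most significant of correlated SNPs", {
  set.seed(1)
  g <- rbinom(200, 2, 0.4)
  dos <- cbind(dup1 = g, dup2 = g, ind1 = rbinom(200, 2, 0.4))
  panel <- make_panel(dos, 1, c(1000, 2000, 3000), c("A", "C", "G"),
                      c("G", "T", "A"))
  ss <- make_sumstats(c("dup1", "dup2", "ind1"), 1, c(1000, 2000, 3000),
                      c("A", "C", "G"), c("G", "T", "A"),
                      beta = c(0.2, 0.2, 0.1), p = c(1e-6, 1e-4, 1e-3))
  kept <- ld_clump(ss, panel, prs_config())
  expect_setequal(kept, c("dup1", "ind1"))
  # mutually independent SNPs all kept
  set.seed(2)
  dosi <- matrix(rbinom(200 * 4, 2, 0.3), 200, 4,
                 dimnames = list(NULL, paste0("i", 1:4)))
  pani <- make_panel(dosi, 1, (1:4) * 1e6, rep("A", 4), rep("G", 4))
  ssi <- make_sumstats(paste0("i", 1:4), 1, (1:4) * 1e6, rep("A", 4),
                       rep("G", 4), rep(0.1, 4), c(0.5, 0.1, 0.9, 0.2))
  expect_setequal(ld_clump(ssi, pani, prs_config()), paste0("i", 1:4))
})

test_that("ld_clump matches the exhaustive greedy oracle on random LD blocks", {
  for (s in 1:4) {
    pool <- simulate_haplotype_pool(3, 10, c(0.1, 0.5), rho = 0.8,
                                    seed = 100 + s)
    panel <- simulate_twin_genotypes(pool, 0, 250, seed = 200 + s)
    ss <- simulate_gwas_sumstats(pool, rep(0, 30), n_gwas = 1e4, seed = 300 + s)
    cfg <- prs_config(clump_r2 = 0.1, clump_window_bp = Inf)
    expect_identical(ld_clump(ss, panel, cfg),
                     clump_oracle(ss, panel, 0.1, Inf))
    cfg2 <- prs_config(clump_r2 = 0.01, clump_window_bp = 250000)
    expect_identical(ld_clump(ss, panel, cfg2),
                     clump_oracle(ss, panel, 0.01, 250000))
  }
})

test_that("clumping an already-clumped set is idempotent", {
  pool <- simulate_haplotype_pool(4, 8, c(0.1, 0.5), rho = 0.9, seed = 7)
  panel <- simulate_twin_genotypes(pool, 0, 300, seed = 8)
  ss <- simulate_gwas_sumstats(pool, rep(0, 32), 1e4, seed = 9)
  k1 <- ld_clump(ss, panel, prs_config())
  ss2 <- ss[ss$SNP %in% k1, ]
  expect_identical(ld_clump(ss2, panel, prs_config()), k1)
})

test_that("compute_prs is the weighted allele count with mean imputation", {
  dos <- rbind(c(2, 1, 0), c(0, 2, 1))
  dos <- rbind(dos, dos)   # 4 individuals = 2 pairs
  colnames(dos) <- c("a", "b", "c")
  panel <- make_panel(dos, 1, c(1, 2, 3) * 1e6, rep("A", 3), rep("G", 3))
  ss <- make_sumstats(c("a", "b", "c"), 1, c(1, 2, 3) * 1e6, rep("A", 3),
                      rep("G", 3), beta = c(0.2, -0.1, 0.5),
                      p = c(1e-8, 1e-8, 1e-8))
  sc <- compute_prs(panel, ss, 1, c("a", "b", "c"))
  expect_equal(unname(sc[1]), 2 * 0.2 - 0.1 + 0)
  expect_equal(unname(sc[2]), 0 - 0.2 + 0.5)
  # empty set -> all zero
  sc0 <- compute_prs(panel, ss, 1e-12, c("a", "b", "c"))
  expect_true(all(sc0 == 0))
  expect_equal(attr(sc0, "n_snps"), 0L)
  # missing dosage mean-imputed
  panel$dosage[1, "a"] <- NA
  scm <- compute_prs(panel, ss, 1, c("a"))
  expect_equal(unname(scm[1]), mean(c(0, 2, 0)) * 0.2)
})

test_that("MZ pairs with identical genotypes get identical scores", {
  pool <- simulate_haplotype_pool(2, 5, c(0.2, 0.5), 0.5, seed = 11)
  panel <- simulate_twin_genotypes(pool, 30, 0, seed = 12)
  ss <- simulate_gwas_sumstats(pool, rnorm(10, 0, 0.1), 1e4, seed = 13)
  sc <- compute_prs(panel, ss, 1, ss$SNP)
  t1 <- panel$ind$twin == 1
  expect_equal(unname(sc[t1]), unname(sc[!t1]))
})

test_that("APOE-region exclusion uses a closed interval on the right chromosome", {
  ss <- make_sumstats(paste0("r", 1:4), chr = c(19, 19, 19, 7),
                      pos = c(44400000, 46500000, 44399999, 44400000),
                      rep("A", 4), rep("G", 4), rep(0.1, 4), rep(0.5, 4))
  out <- exclude_apoe_region(ss, prs_config())
  expect_setequal(out$SNP, c("r3", "r4"))
  # synthetic count check: 10 in-region of 100
  ss2 <- make_sumstats(paste0("q", 1:100),
                       chr = c(rep(19, 10), rep(1, 90)),
                       pos = c(seq(44500000, by = 1000, length.out = 10),
                               seq(1e6, by = 1e4, length.out = 90)),
                       rep("A", 100), rep("G", 100), rep(0.1, 100),
                       rep(0.5, 100))
  expect_equal(nrow(exclude_apoe_region(ss2, prs_config())), 90)
})

test_that("ancestry PCs separate divergent subpopulations", {
  set.seed(21)
  n1 <- 120; n2 <- 120; m <- 60
  f1 <- runif(m, 0.1, 0.5); f2 <- pmin(0.95, f1 + 0.35)
  dos <- rbind(
    matrix(rbinom(n1 * m, 2, rep(f1, each = n1)), n1, m),
    matrix(rbinom(n2 * m, 2, rep(f2, each = n2)), n2, m))
  colnames(dos) <- paste0("v", 1:m)
  panel <- make_panel(dos, 1, (1:m) * 1e4, rep("A", m), rep("G", m))
  pcs <- pca_ancestry(panel, 2)
  grp <- rep(c(0, 1), c(n1, n2))
  expect_gt(abs(cor(pcs[, 1], grp)), 0.9)
  # degenerate panel: all rows identical
  panel2 <- make_panel(matrix(1, 10, 4, dimnames = list(NULL, paste0("z", 1:4))),
                       1, 1:4, rep("A", 4), rep("G", 4))
  expect_error(pca_ancestry(panel2, 2), "monomorphic|rank")
  expect_error(pca_ancestry(panel, 500), "rank")
})

test_that("residualize_standardize matches hand OLS and the z-score contract", {
  set.seed(22)
  # hand-built 6-person, 1-PC case
  scores <- c(1.2, 0.5, -0.3, 2.0, 0.8, -1.1)
  pc <- matrix(c(0.3, -0.2, 0.1, 0.5, -0.4, 0.05), ncol = 1)
  arrays <- rep("A1", 6)
  fit <- lm(scores ~ pc)
  expected <- unname(scale(resid(fit))[, 1])
  got <- residualize_standardize(scores, pc, arrays)
  expect_equal(unname(got), expected, tolerance = 1e-10)
  # mean 0 / variance 1 within each array group
  sc2 <- rnorm(50); pcs2 <- matrix(rnorm(100), 50, 2)
  arr2 <- rep(c("PsychArray", "OmniExpress"), 25)
  z <- residualize_standardize(sc2, pcs2, arr2)
  for (a in unique(arr2)) {
    expect_lt(abs(mean(z[arr2 == a])), 1e-8)
    expect_lt(abs(var(z[arr2 == a]) - 1), 1e-8)
  }
  # orthogonal PCs: residualization reduces to centering, then z-scoring
  pc_orth <- matrix(rnorm(50), 50, 1)
  pc_orth <- pc_orth - mean(pc_orth)
  sc3 <- rnorm(50)
  sc3 <- sc3 - as.vector(pc_orth %*% (crossprod(pc_orth, sc3) / sum(pc_orth^2)))
  z3 <- residualize_standardize(sc3, pc_orth, rep("A", 50))
  expect_equal(unname(z3), as.vector(scale(sc3)), tolerance = 1e-8)
  expect_error(residualize_standardize(1:3, NULL, c("A", "A", "B")),
               "size < 2")
})

test_that("apoe_alleles resolves the two-marker diplotypes", {
  expect_equal(apoe_alleles(0, 2), data.frame(e2 = 2L, e4 = 0L))
  expect_equal(apoe_alleles(1, 1), data.frame(e2 = 1L, e4 = 1L))
  expect_equal(apoe_alleles(2, 0), data.frame(e2 = 0L, e4 = 2L))
  expect_equal(apoe_alleles(0, 0), data.frame(e2 = 0L, e4 = 0L))
  expect_error(apoe_alleles(2, 2), "impossible")
  expect_error(apoe_alleles(2, 1), "impossible")
  expect_error(apoe_alleles(0.5, 0), "integers")
})

test_that("PRS panel is monotone in the threshold and decomposes by region", {
  pool <- simulate_haplotype_pool(6, 5, c(0.1, 0.5), rho = 0.6, seed = 31)
  # move one block into the APOE region on chr 19
  inblk <- pool$snps$block == 6
  pool$snps$chr[inblk] <- 19L
  pool$snps$pos[inblk] <- seq(44500000L, by = 10000L, length.out = sum(inblk))
  panel <- simulate_twin_genotypes(pool, 50, 250, seed = 32)
  ss <- simulate_gwas_sumstats(pool, rnorm(30, 0, 0.05), 2e4, seed = 33)
  cfg <- prs_config(maf_floor = 0.01, info_floor = 0.8)
  prs <- build_prs_panel(panel, ss, cfg)
  ns <- attr(prs, "n_snps")
  expect_true(all(diff(ns[, "full"]) <= 0))     # thresholds stored loosest-first
  expect_true(all(diff(ns[, "noapoe"]) <= 0))
  expect_true(all(ns[, "noapoe"] <= ns[, "full"]))
  # full - noAPOE raw score equals the in-region index score (independent
  # blocks: clumping choices unaffected by region removal)
  ssq <- qc_filter(ss, panel, cfg)
  idx_full <- ld_clump(ssq, panel, cfg)
  idx_no <- ld_clump(exclude_apoe_region(ssq, cfg), panel, cfg)
  expect_true(all(idx_no %in% idx_full))
  raw_full <- compute_prs(panel, ssq, 1, idx_full)
  raw_no <- compute_prs(panel, ssq, 1, idx_no)
  raw_region <- compute_prs(panel, ssq, 1, setdiff(idx_full, idx_no))
  expect_equal(as.numeric(raw_full - raw_no), as.numeric(raw_region),
               tolerance = 1e-12)
  # raw-score variance non-decreasing in SNP count on independent SNPs
  pool_i <- simulate_haplotype_pool(12, 1, c(0.2, 0.5), 0, seed = 34)
  panel_i <- simulate_twin_genotypes(pool_i, 0, 200, seed = 35)
  ss_i <- simulate_gwas_sumstats(pool_i, rep(0.1, 12), 5e3, seed = 36)
  idx_i <- ld_clump(ss_i, panel_i, prs_config())
  vs <- vapply(c(1, 0.5, 0.05),
               function(th) var(compute_prs(panel_i, ss_i, th, idx_i)), 0)
  expect_true(all(diff(vs) <= 1e-12))
})
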