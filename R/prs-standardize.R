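# Ancestry PCs, score standardization, APOE epsilon-allele derivation.

#' Ancestry principal components of a genotype panel
#'
#' Top-k left singular directions of the column-standardized dosage matrix.
#' To avoid the bias from duplicated genomes, loadings are fitted excluding
#' one member of each MZ pair; coordinates are then projected for everyone.
#'
#' @param panel a `genotype_panel`.
#' @param k number of components (>= 1).
#' @return numeric matrix (individuals x k) of PC coordinates.
#' @export
pca_ancestry <- function(panel, k = 4L) {
  stopifnot_scalar(k, "k", 1)
  G <- panel$dosage
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na_idx <- which(is.na(G), arr.ind = TRUE)
    G[na_idx] <- mu[na_idx[, 2]]
  }
  sds <- apply(G, 2, sd)
  use_col <- sds > 0
  if (!any(use_col)) stop("all SNPs monomorphic: principal components undefined")
  Gs <- scale(G[, use_col, drop = FALSE])
  fit_rows <- !(panel$ind$zygosity == "MZ" & panel$ind$twin == 2)
  Gf <- Gs[fit_rows, , drop = FALSE]
  # center the fitting subset so loadings come from its covariance
  ctr <- colMeans(Gf)
  Gf <- sweep(Gf, 2, ctr)
  if (k > min(dim(Gf)) - 1) stop("`k` exceeds the rank of the dosage matrix")
  sv <- svd(Gf, nu = 0, nv = k)
  if (sv$d[k] < 1e-8) stop("`k` exceeds the rank of the dosage matrix")
  pcs <- sweep(Gs, 2, ctr) %*% sv$v
  rownames(pcs) <- panel$ind$id
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Residualize scores on ancestry PCs and standardize within array
#'
#' Ordinary least-squares residual of the raw score on the PCs, then
#' z-scored within each array group.
#'
#' @param scores named numeric vector of raw scores.
#' @param pcs matrix of PC coordinates (same row order), or NULL to skip
#'   residualization.
#' @param array_labels one array label per individual.
#' @return numeric vector of standardized scores (mean 0, variance 1 within
#'   each array group).
#' @export
residualize_standardize <- function(scores, pcs, array_labels) {
  n <- length(scores)
  if (length(array_labels) != n) stop("one array label per individual required")
  if (any(table(array_labels) < 2)) {
    stop("array group of size < 2: cannot standardize")
  }
  res <- if (is.null(pcs)) {
    scores - mean(scores)
  } else {
    if (nrow(pcs) != n) stop("`pcs` rows must match `scores`")
    resid(lm.fit(cbind(1, pcs), as.numeric(scores)))
  }
  out <- numeric(n)
  for (a in unique(array_labels)) {
    i <- array_labels == a
    s <- sd(res[i])
    if (s == 0) stop("constant score within array group: cannot standardize")
    out[i] <- (res[i] - mean(res[i])) / s
  }
  names(out) <- names(scores)
  out
}

#' APOE epsilon-allele counts from the two-marker genotype
#'
#' Resolves the epsilon-2 and epsilon-4 allele counts from the rs429358 C
#' dosage and rs7412 T dosage under the three-haplotype system (epsilon-2 =
#' T/T, epsilon-3 = T/C, epsilon-4 = C/C at rs429358/rs7412); the double
#' heterozygote is resolved as epsilon-2/epsilon-4 (epsilon-1 and epsilon-3r
#' treated as absent).
#'
#' @param c429358 integer rs429358 C-allele dosage (0-2).
#' @param t7412 integer rs7412 T-allele dosage (0-2).
#' @return data.frame with columns `e2` and `e4`.
#' @export
apoe_alleles <- function(c429358, t7412) {
  c4 <- as.integer(c429358); t2 <- as.integer(t7412)
  if (any(is.na(c4)) || any(is.na(t2)) ||
      any(c4 != c429358) || any(t2 != t7412) ||
      any(c4 < 0 | c4 > 2) || any(t2 < 0 | t2 > 2)) {
    stop("dosages must be integers in 0..2")
  }
  bad <- c4 + t2 > 2
  if (any(bad)) {
    stop(sprintf(paste0("genotype impossible under the epsilon-2/3/4 haplotype ",
                        "system at %d position(s): C-dosage + T-dosage > 2"),
                 sum(bad)))
  }
  data.frame(e2 = t2, e4 = c4)
}
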