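# File formats: TSV readers/writers with validation, VCF dosage import.
# TSV (tab-separated, UTF-8, '.' decimal) is the canonical interchange;
# VCF support is read-only convenience.

SUMSTATS_COLS <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "P")

#' Read GWAS summary statistics from TSV
#'
#' Required columns SNP, CHR, BP, A1, A2, BETA, P (INFO optional).
#' Duplicate SNP ids, non-finite effects and p-values outside (0, 1] are
#' rejected with the offending line number.
#'
#' @param path TSV file path.
#' @return a validated `sumstats` data.frame.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ss <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(SUMSTATS_COLS, names(ss))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  bad_p <- which(!is.finite(ss$P) | ss$P <= 0 | ss$P > 1)
  if (length(bad_p)) {
    stop(sprintf("p-value outside (0, 1] at line %d", bad_p[1] + 1L))
  }
  bad_b <- which(!is.finite(ss$BETA))
  if (length(bad_b)) {
    stop(sprintf("non-finite effect size at line %d", bad_b[1] + 1L))
  }
  dup <- ss$SNP[duplicated(ss$SNP)]
  if (length(dup)) {
    stop(sprintf("duplicated SNP id: %s", dup[1]))
  }
  class(ss) <- c("sumstats", "data.frame")
  ss
}

#' Write summary statistics to TSV
#' @param sumstats a `sumstats` data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(sumstats, path) {
  utils::write.table(sumstats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel to TSV
#'
#' Emits `<path>` with individual metadata columns (id, pair_id, twin,
#' zygosity, array) followed by one dosage column per SNP, and
#' `<path>.snps.tsv` with the SNP metadata.
#'
#' @param panel a `genotype_panel`.
#' @param path output path.
#' @export
write_genotypes <- function(panel, path) {
  df <- cbind(panel$ind, as.data.frame(panel$dosage, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$snps, paste0(path, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype panel from TSV or VCF
#'
#' TSV expects the layout written by [write_genotypes()].  For VCF, dosages
#' come from the DS FORMAT field when present, else from GT allele counts;
#' pair metadata is taken from `ind` or parsed from sample ids of the form
#' `P<pair>_T<twin>`.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param ind optional individual metadata data.frame (VCF only).
#' @return a `genotype_panel`.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), ind = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    meta_cols <- c("id", "pair_id", "twin", "zygosity", "array")
    if (!all(meta_cols %in% names(df))) {
      stop("genotype TSV must carry columns id, pair_id, twin, zygosity, array")
    }
    dos <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
    rownames(dos) <- df$id
    snps <- utils::read.delim(paste0(path, ".snps.tsv"),
                              stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
      stop("VCF input requires the VariantAnnotation package")
    }
    vcf <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(vcf)
    if ("DS" %in% names(gt)) {
      dos <- t(gt$DS)
    } else if ("GT" %in% names(gt)) {
      g <- gt$GT
      cnt <- matrix(vapply(strsplit(gsub("\\|", "/", g), "/"),
                           function(a) sum(a != "0" & a != "."), 0),
                    nrow(g), ncol(g), dimnames = dimnames(g))
      dos <- t(cnt)
    } else stop("VCF carries neither DS nor GT")
    rd <- SummarizedExperiment::rowRanges(vcf)
    snps <- data.frame(
      id = names(rd),
      chr = as.character(GenomicRanges::seqnames(rd)),
      pos = GenomicRanges::start(rd),
      a1 = vapply(VariantAnnotation::alt(vcf), function(a) as.character(a[1]), ""),
      a2 = as.character(VariantAnnotation::ref(vcf)),
      freq = colMeans(dos) / 2, info = 1,
      block = NA_integer_, stringsAsFactors = FALSE)
    colnames(dos) <- snps$id
    if (is.null(ind)) {
      sm <- rownames(dos)
      pid <- suppressWarnings(as.integer(sub("^P0*([0-9]+)_T[12]$", "\\1", sm)))
      twin <- suppressWarnings(as.integer(sub("^P[0-9]+_T([12])$", "\\1", sm)))
      ind <- data.frame(id = sm, pair_id = pid, twin = twin,
                        zygosity = NA_character_, array = NA_character_,
                        stringsAsFactors = FALSE)
    }
    df <- ind
  }
  if (any(is.finite(dos) & (dos < 0 | dos > 2))) {
    stop("dosage out of range [0, 2]")
  }
  if (format == "tsv") ind <- df[, c("id", "pair_id", "twin", "zygosity", "array")]
  structure(list(dosage = dos, ind = ind, snps = snps),
            class = "genotype_panel")
}

#' Write a twin cohort to TSV
#' @param cohort a `twin_cohort`.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a twin cohort from TSV
#' @param path input path.
#' @return a `twin_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "pair_id", "twin", "zygosity", "sex", "age", "cage",
            "cage2", "ad", "array")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("cohort TSV missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(df$ad %in% c(0, 1))) stop("disease status must be binary 0/1")
  class(df) <- c("twin_cohort", "data.frame")
  df
}

#' Read/write a run configuration (JSON)
#'
#' Configurations round-trip exactly: write then read returns an identical
#' structure.
#'
#' @param path JSON file path.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_run_config
#' @param config named list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
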