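# The gwas_study container: samples x SNPs genotype matrix (minor-allele
# counts 0/1/2, NA = missing) plus binary phenotype and optional covariates.

#' Construct a GWAS genotype study
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns,
#'   values in {0, 1, 2, NA}; must carry row and column names (sample and
#'   SNP ids).
#' @param phenotype Optional binary vector (1 = case, 0 = control), one per
#'   sample.
#' @param covariates Optional data frame of per-sample covariates (e.g.
#'   sex, age), one row per sample.
#'
#' @return An object of class `"gwas_study"`.
#' @export
gwas_study <- function(genotypes, phenotype = NULL, covariates = NULL) {
  if (!is.matrix(genotypes) || is.null(rownames(genotypes)) ||
      is.null(colnames(genotypes)))
    stop_input("`genotypes` must be a matrix with sample row names and SNP column names")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L)))
    stop_input("genotype values must be 0, 1, 2 or NA")
  if (!is.null(phenotype)) {
    if (length(phenotype) != nrow(genotypes))
      stop_input("`phenotype` length must match the number of samples")
    if (!all(phenotype %in% c(0L, 1L)))
      stop_input("`phenotype` must be binary (1 = case, 0 = control)")
  }
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (nrow(covariates) != nrow(genotypes))
      stop_input("`covariates` must have one row per sample")
  }
  structure(
    list(genotypes = genotypes,
         sample_ids = rownames(genotypes),
         snp_ids = colnames(genotypes),
         phenotype = if (is.null(phenotype)) NULL else as.integer(phenotype),
         covariates = covariates),
    class = "gwas_study"
  )
}

#' @export
print.gwas_study <- function(x, ...) {
  cat("<gwas_study> ", length(x$sample_ids), " samples x ",
      length(x$snp_ids), " SNPs", sep = "")
  if (!is.null(x$phenotype))
    cat("; ", sum(x$phenotype == 1L), " cases / ",
        sum(x$phenotype == 0L), " controls", sep = "")
  if (!is.null(x$covariates))
    cat("; covariates: ", paste(names(x$covariates), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

n_samples <- function(study) length(study$sample_ids)
n_snps_study <- function(study) length(study$snp_ids)
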