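#' Configuration for the synthetic GWAS generator
#'
#' Bundles and validates every parameter of the synthetic study generator:
#' cohort sizes, the allele-frequency range, the linkage-disequilibrium (LD)
#' block model, the SNP-to-gene map, the pathway database and the planted
#' causal signal. The defaults reproduce the scale of a dilated
#' cardiomyopathy case-control screen (909 cases, 2,120 controls, 241
#' pathways) with a desk-scale SNP panel.
#'
#' @param n_cases,n_controls Number of cases / controls to retain.
#' @param n_snps Number of SNPs on the simulated array.
#' @param allele_freq_low,allele_freq_high Range of per-SNP minor allele
#'   frequencies, drawn uniformly; both in (0, 0.5].
#' @param ld_block_size Number of consecutive SNPs per LD block.
#' @param ld_r Probability that a haplotype allele is copied from the block
#'   anchor rather than drawn independently; 0 gives independent SNPs.
#' @param missing_rate i.i.d. genotype missingness probability in [0, 1).
#' @param n_genes Number of genes; SNPs are assigned to genes in contiguous
#'   runs.
#' @param snps_per_gene_mean,snps_per_gene_dispersion Mean and dispersion
#'   (negative-binomial `size`) of the SNPs-per-gene count law; small
#'   dispersion gives a long-tailed gene-size distribution ("long" genes).
#' @param multi_gene_fraction Fraction of SNPs additionally mapped to the
#'   neighbouring gene (many-to-many map).
#' @param n_pathways Number of gene-set pathways.
#' @param pathway_size_low,pathway_size_high Pathway sizes drawn uniformly
#'   in this range.
#' @param pathway_overlap_fraction Fraction of each pathway's genes shared
#'   with a previously generated pathway; 0 switches to disjoint sampling.
#' @param causal_pathways Character vector of pathway ids (e.g. `"pw001"`)
#'   that carry a planted association signal.
#' @param n_causal_snps_per_pathway Number of causal SNPs planted per causal
#'   pathway, each in a distinct gene of that pathway.
#' @param causal_odds_ratio Per-allele odds ratio at each causal SNP.
#' @param seed Integer seed; every generator output is a pure function of
#'   the configuration including this seed.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_gwas()], [simulate_genotypes()], [build_snp_gene_map()]
#' @export
#' @examples
#' cfg <- sim_config(n_cases = 50, n_controls = 50, n_snps = 200,
#'                   n_genes = 40, n_pathways = 8, seed = 1)
#' cfg$n_snps
sim_config <- function(n_cases = 909,
                       n_controls = 2120,
                       n_snps = 5000,
                       allele_freq_low = 0.05,
                       allele_freq_high = 0.5,
                       ld_block_size = 10,
                       ld_r = 0.8,
                       missing_rate = 0.01,
                       n_genes = 1000,
                       snps_per_gene_mean = 5,
                       snps_per_gene_dispersion = 1,
                       multi_gene_fraction = 0.05,
                       n_pathways = 241,
                       pathway_size_low = 10,
                       pathway_size_high = 50,
                       pathway_overlap_fraction = 0.1,
                       causal_pathways = character(),
                       n_causal_snps_per_pathway = 10,
                       causal_odds_ratio = 1.5,
                       seed = 1) {
  cfg <- list(
    n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
    allele_freq_low = allele_freq_low, allele_freq_high = allele_freq_high,
    ld_block_size = ld_block_size, ld_r = ld_r, missing_rate = missing_rate,
    n_genes = n_genes, snps_per_gene_mean = snps_per_gene_mean,
    snps_per_gene_dispersion = snps_per_gene_dispersion,
    multi_gene_fraction = multi_gene_fraction,
    n_pathways = n_pathways, pathway_size_low = pathway_size_low,
    pathway_size_high = pathway_size_high,
    pathway_overlap_fraction = pathway_overlap_fraction,
    causal_pathways = as.character(causal_pathways),
    n_causal_snps_per_pathway = n_causal_snps_per_pathway,
    causal_odds_ratio = causal_odds_ratio,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field) {
    if (!is_count(cfg[[field]]))
      stop_config(paste0("invalid configuration field `", field,
                         "`: must be a single integer >= 1"))
  }
  for (f in c("n_cases", "n_controls", "n_snps", "ld_block_size", "n_genes",
              "n_pathways", "pathway_size_low", "pathway_size_high",
              "n_causal_snps_per_pathway")) chk_count(f)
  if (!is_prob(cfg$allele_freq_low, 0, 0.5, open_lo = TRUE) ||
      !is_prob(cfg$allele_freq_high, 0, 0.5, open_lo = TRUE) ||
      cfg$allele_freq_low > cfg$allele_freq_high)
    stop_config("invalid configuration field `allele_freq_low`/`allele_freq_high`: need 0 < low <= high <= 0.5")
  if (!is_prob(cfg$ld_r))
    stop_config("invalid configuration field `ld_r`: must be in [0, 1]")
  if (!is_prob(cfg$missing_rate, open_hi = TRUE))
    stop_config("invalid configuration field `missing_rate`: must be in [0, 1)")
  if (cfg$ld_block_size > cfg$n_snps)
    stop_config("invalid configuration field `ld_block_size`: exceeds `n_snps`")
  if (cfg$n_genes > cfg$n_snps)
    stop_config("invalid configuration field `n_genes`: exceeds `n_snps`")
  if (!is.numeric(cfg$snps_per_gene_mean) || cfg$snps_per_gene_mean < 1)
    stop_config("invalid configuration field `snps_per_gene_mean`: must be >= 1")
  if (!is.numeric(cfg$snps_per_gene_dispersion) || cfg$snps_per_gene_dispersion <= 0)
    stop_config("invalid configuration field `snps_per_gene_dispersion`: must be > 0")
  if (!is_prob(cfg$multi_gene_fraction))
    stop_config("invalid configuration field `multi_gene_fraction`: must be in [0, 1]")
  if (cfg$pathway_size_low > cfg$pathway_size_high)
    stop_config("invalid configuration field `pathway_size_low`: exceeds `pathway_size_high`")
  if (cfg$pathway_size_high > cfg$n_genes)
    stop_config("invalid configuration field `pathway_size_high`: pathway size exceeds gene universe")
  if (!is_prob(cfg$pathway_overlap_fraction))
    stop_config("invalid configuration field `pathway_overlap_fraction`: must be in [0, 1]")
  if (!is.numeric(cfg$causal_odds_ratio) || cfg$causal_odds_ratio <= 0)
    stop_config("invalid configuration field `causal_odds_ratio`: must be > 0")
  if (length(cfg$causal_pathways) &&
      !all(cfg$causal_pathways %in% pathway_ids(cfg$n_pathways)))
    stop_config("invalid configuration field `causal_pathways`: unknown pathway id")
  if (length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop_config("invalid configuration field `seed`: must be a single integer")
  invisible(cfg)
}

pathway_ids <- function(n) sprintf("pw%03d", seq_len(n))
gene_ids <- function(n) sprintf("g%04d", seq_len(n))
snp_ids <- function(n) sprintf("snp%05d", seq_len(n))

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cases, " cases / ", x$n_controls, " controls, ",
      x$n_snps, " SNPs in ", x$n_genes, " genes, ", x$n_pathways,
      " pathways", sep = "")
  if (length(x$causal_pathways))
    cat("; causal: ", paste(x$causal_pathways, collapse = ", "),
        " (OR ", x$causal_odds_ratio, ")", sep = "")
  cat("\n")
  invisible(x)
}
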