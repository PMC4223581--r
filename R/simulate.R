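# Synthetic GWAS generator: genotypes with LD blocks, retrospective
# case-control phenotype assignment, and the full study bundle with truth.

#' Simulate a genotype matrix with LD blocks
#'
#' Each SNP draws an allele frequency uniformly in
#' `[allele_freq_low, allele_freq_high]`. SNPs are grouped into consecutive
#' blocks of `ld_block_size`; within a block each of a sample's two
#' haplotypes copies the block-anchor allele with probability `ld_r` and is
#' otherwise drawn independently at the SNP's own frequency. Genotypes are
#' the sum of the two haplotype alleles and are then masked missing i.i.d.
#' at `missing_rate`. The output is a pure function of the configuration
#' (including its seed).
#'
#' @param config A [sim_config()].
#' @return A [gwas_study()] with phenotype unset.
#' @export
#' @examples
#' study <- simulate_genotypes(sim_config(n_cases = 10, n_controls = 10,
#'                                        n_snps = 50, n_genes = 10,
#'                                        missing_rate = 0, seed = 7))
#' dim(study$genotypes)
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  n <- config$n_cases + config$n_controls
  simulate_genotype_pool(config, n, seed = derive_seed(config$seed, 1L))
}

# Per-SNP allele frequencies are a property of the simulated array: drawn
# once from the config seed so every genotype batch shares them.
snp_frequencies <- function(config) {
  withr::with_seed(derive_seed(config$seed, 11L),
                   runif(config$n_snps, config$allele_freq_low,
                         config$allele_freq_high))
}

# Core generator for an arbitrary pool size; used both for the public
# surface and for the retrospective-sampling batches in assign_phenotypes().
simulate_genotype_pool <- function(config, n, seed, id_offset = 0L) {
  z <- config$n_snps
  freqs <- snp_frequencies(config)
  withr::with_seed(seed, {
    G <- matrix(0L, nrow = n, ncol = z)
    block_starts <- seq(1L, z, by = config$ld_block_size)
    for (h in 1:2) {
      hap <- matrix(0L, nrow = n, ncol = z)
      for (b in block_starts) {
        b_end <- min(b + config$ld_block_size - 1L, z)
        anchor <- rbinom(n, 1L, freqs[b])
        hap[, b] <- anchor
        for (j in seq(b + 1L, length.out = b_end - b)) {
          copy <- rbinom(n, 1L, config$ld_r)
          hap[, j] <- ifelse(copy == 1L, anchor, rbinom(n, 1L, freqs[j]))
        }
      }
      G <- G + hap
    }
    if (config$missing_rate > 0) {
      G[matrix(runif(n * z) < config$missing_rate, nrow = n)] <- NA_integer_
    }
    rownames(G) <- sprintf("S%05d", id_offset + seq_len(n))
    colnames(G) <- snp_ids(z)
    gwas_study(G)
  })
}

#' Assign case-control phenotypes under a logistic disease model
#'
#' Disease probability per sample follows a logistic model with per-allele
#' log-odds `log(odds_ratio)` at every causal SNP; the intercept is
#' calibrated by root-finding so the marginal case fraction is
#' `target_case_fraction`, keeping the retrospective quota sampling cheap.
#' Samples are drawn in genotype batches and retained until exactly
#' `n_cases` cases and `n_controls` controls are kept (case-control design,
#' not a prevalence cohort). Missing genotypes contribute no risk.
#'
#' Covariates (sex, age) are generated phenotype-independent, supporting the
#' covariate-adjusted logistic association option without confounding.
#'
#' @param study A [gwas_study()] serving as the first genotype batch.
#' @param truth_snps Character vector of causal SNP ids (may be empty).
#' @param odds_ratio Per-allele odds ratio at each causal SNP; 1 = null.
#' @param config The [sim_config()] that produced `study` (supplies quotas
#'   and the seed for additional batches).
#' @param map Optional SNP-to-gene map tibble; when supplied the causal gene
#'   set is recorded in the returned truth.
#' @param target_case_fraction Marginal disease probability the intercept is
#'   calibrated to.
#' @param max_batches Iteration cap on genotype batches before a generation
#'   error is raised.
#'
#' @return A list with elements `study` (phenotype and covariates set,
#'   exactly `n_cases + n_controls` samples, cases first) and `truth`
#'   (list: `causal_snps`, `causal_genes`, `enriched_pathways`).
#' @export
assign_phenotypes <- function(study, truth_snps, odds_ratio, config,
                              map = NULL, target_case_fraction = 0.3,
                              max_batches = 100L) {
  validate_sim_config(config)
  truth_snps <- as.character(truth_snps)
  if (!all(truth_snps %in% study$snp_ids))
    stop_input("`truth_snps` must be a subset of the study's SNP ids")
  if (!is.numeric(odds_ratio) || odds_ratio <= 0)
    stop_config("invalid configuration field `causal_odds_ratio`: must be > 0")
  beta <- log(odds_ratio)

  burden <- function(st) {
    if (length(truth_snps) == 0L || beta == 0)
      return(numeric(nrow(st$genotypes)))
    rowSums(st$genotypes[, truth_snps, drop = FALSE], na.rm = TRUE)
  }

  # Calibrate the intercept on the first batch's burden distribution.
  b0 <- calibrate_intercept(burden(study), beta, target_case_fraction)

  need_cases <- config$n_cases
  need_ctrls <- config$n_controls
  kept_case <- list()
  kept_ctrl <- list()
  batch <- study
  withr::with_seed(derive_seed(config$seed, 5L), {
    for (iter in seq_len(max_batches)) {
      eta <- b0 + beta * burden(batch)
      y <- rbinom(length(eta), 1L, plogis(eta))
      if (need_cases > 0L && any(y == 1L)) {
        take <- head(which(y == 1L), need_cases)
        kept_case[[length(kept_case) + 1L]] <-
          batch$genotypes[take, , drop = FALSE]
        need_cases <- need_cases - length(take)
      }
      if (need_ctrls > 0L && any(y == 0L)) {
        take <- head(which(y == 0L), need_ctrls)
        kept_ctrl[[length(kept_ctrl) + 1L]] <-
          batch$genotypes[take, , drop = FALSE]
        need_ctrls <- need_ctrls - length(take)
      }
      if (need_cases == 0L && need_ctrls == 0L) break
      if (iter == max_batches)
        stop_runtime("generation error: case/control quotas not reached within the batch cap")
      batch <- simulate_genotype_pool(
        config, n_samples(study),
        seed = derive_seed(config$seed, 100L + iter),
        id_offset = iter * n_samples(study))
    }
    G <- rbind(do.call(rbind, kept_case), do.call(rbind, kept_ctrl))
    rownames(G) <- c(sprintf("case%05d", seq_len(config$n_cases)),
                     sprintf("ctrl%05d", seq_len(config$n_controls)))
    phenotype <- rep(c(1L, 0L), c(config$n_cases, config$n_controls))
    covariates <- tibble(
      sex = rbinom(nrow(G), 1L, 0.5),
      age = round(rnorm(nrow(G), 55, 10), 1)
    )
    out <- gwas_study(G, phenotype = phenotype, covariates = covariates)
  })

  truth <- list(
    causal_snps = truth_snps,
    causal_genes = if (is.null(map)) character() else
      sort(unique(map$gene_id[map$snp_id %in% truth_snps])),
    enriched_pathways = config$causal_pathways
  )
  list(study = out, truth = truth)
}

calibrate_intercept <- function(burden, beta, target) {
  f <- function(b0) mean(plogis(b0 + beta * burden)) - target
  uniroot(f, lower = -50, upper = 50, tol = 1e-8)$root
}

#' Simulate a complete synthetic GWAS study
#'
#' Orchestrates the full generator: genotype pool, SNP-to-gene map, causal
#' SNP selection inside the configured causal pathways, retrospective
#' phenotype assignment, and the pathway database (with every causal
#' pathway guaranteed to contain its causal genes).
#'
#' Causal SNPs are chosen one per gene from distinct genes so each causal
#' pathway receives `n_causal_snps_per_pathway` independently associated
#' genes.
#'
#' @param config A [sim_config()].
#' @return A list of class `"gwas_sim"` with elements `study`, `map`
#'   (tibble: snp_id, gene_id), `pathways` (tibble: pathway, description,
#'   gene), `truth` and `config`.
#' @export
#' @examples
#' sim <- simulate_gwas(sim_config(n_cases = 30, n_controls = 30,
#'                                 n_snps = 200, n_genes = 40,
#'                                 n_pathways = 6, pathway_size_low = 5,
#'                                 pathway_size_high = 10,
#'                                 causal_pathways = "pw001",
#'                                 n_causal_snps_per_pathway = 3, seed = 2))
#' sim$truth$enriched_pathways
simulate_gwas <- function(config) {
  validate_sim_config(config)
  map <- build_snp_gene_map(config)
  pool <- simulate_genotypes(config)

  causal_by_pathway <- list()
  causal_snps <- character()
  if (length(config$causal_pathways)) {
    withr::with_seed(derive_seed(config$seed, 4L), {
      genes_avail <- unique(map$gene_id)
      for (pw in config$causal_pathways) {
        gsel <- sample(genes_avail, config$n_causal_snps_per_pathway)
        genes_avail <- setdiff(genes_avail, gsel)
        snp_sel <- vapply(gsel, function(g) {
          cand <- map$snp_id[map$gene_id == g]
          cand[sample.int(length(cand), 1L)]
        }, character(1))
        # multi-gene SNPs drag their neighbour gene into the pathway too,
        # so the causal gene set is everything the selected SNPs map to
        causal_by_pathway[[pw]] <-
          sort(unique(map$gene_id[map$snp_id %in% snp_sel]))
        causal_snps <- c(causal_snps, unname(snp_sel))
      }
    })
  }

  assigned <- assign_phenotypes(pool, causal_snps, config$causal_odds_ratio,
                                config, map = map)
  pathways <- build_pathway_db(config, map,
                               causal_genes = causal_by_pathway)
  structure(
    list(study = assigned$study, map = map, pathways = pathways,
         truth = assigned$truth, config = config),
    class = "gwas_sim"
  )
}

#' @export
print.gwas_sim <- function(x, ...) {
  cat("<gwas_sim> synthetic GWAS study\n")
  print(x$study)
  cat("  map: ", length(unique(x$map$snp_id)), " SNPs -> ",
      length(unique(x$map$gene_id)), " genes; ",
      length(unique(x$pathways$pathway)), " pathways\n", sep = "")
  if (length(x$truth$causal_snps))
    cat("  truth: ", length(x$truth$causal_snps), " causal SNPs in ",
        length(x$truth$causal_genes), " genes; enriched: ",
        paste(x$truth$enriched_pathways, collapse = ", "), "\n", sep = "")
  invisible(x)
}
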