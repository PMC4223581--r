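# Synthetic annotation: the SNP-to-gene map and the pathway database.

#' Build a synthetic SNP-to-gene map
#'
#' Genes receive contiguous runs of SNPs whose lengths are drawn from a
#' shifted negative-binomial law (`1 + NB(mu = mean - 1, size =
#' dispersion)`), then rescaled so the run lengths sum exactly to `n_snps`.
#' Small dispersion produces a long right tail, i.e. genes carrying far
#' more SNPs than average — the gene-size heterogeneity that drives the
#' size bias of the one-significant-SNP gene rule. A `multi_gene_fraction`
#' of SNPs is additionally mapped to the neighbouring gene, so the map is
#' many-to-many; every SNP maps to at least one gene.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `snp_id`, `gene_id`; SNPs mapping to two
#'   genes appear in two rows.
#' @export
#' @examples
#' map <- build_snp_gene_map(sim_config(n_snps = 100, n_genes = 20,
#'                                      multi_gene_fraction = 0, seed = 3))
#' length(unique(map$snp_id))
build_snp_gene_map <- function(config) {
  validate_sim_config(config)
  if (config$n_genes > config$n_snps)
    stop_config("invalid configuration field `n_genes`: exceeds `n_snps`")
  withr::with_seed(derive_seed(config$seed, 2L), {
    sizes <- gene_run_lengths(config$n_genes, config$n_snps,
                              config$snps_per_gene_mean,
                              config$snps_per_gene_dispersion)
    gid <- rep(gene_ids(config$n_genes), times = sizes)
    map <- tibble(snp_id = snp_ids(config$n_snps), gene_id = gid)
    n_multi <- floor(config$multi_gene_fraction * config$n_snps)
    if (n_multi > 0L && config$n_genes > 1L) {
      idx <- sort(sample.int(config$n_snps, n_multi))
      gene_index <- rep(seq_len(config$n_genes), times = sizes)
      neighbour <- ifelse(gene_index[idx] < config$n_genes,
                          gene_index[idx] + 1L, gene_index[idx] - 1L)
      extra <- tibble(snp_id = map$snp_id[idx],
                      gene_id = gene_ids(config$n_genes)[neighbour])
      map <- dplyr::distinct(bind_rows(map, extra))
    }
    arrange(map, .data$snp_id, .data$gene_id)
  })
}

# Draw per-gene SNP counts (all >= 1) summing exactly to n_snps.
gene_run_lengths <- function(n_genes, n_snps, mean, dispersion) {
  raw <- 1 + rnbinom(n_genes, mu = max(mean - 1, 1e-6), size = dispersion)
  sizes <- pmax(1L, as.integer(round(raw * n_snps / sum(raw))))
  diff <- sum(sizes) - n_snps
  while (diff != 0L) {
    if (diff > 0L) {
      shrinkable <- which(sizes > 1L)
      pick <- shrinkable[sample.int(length(shrinkable),
                                    min(diff, length(shrinkable)))]
      sizes[pick] <- sizes[pick] - 1L
    } else {
      pick <- sample.int(n_genes, min(-diff, n_genes))
      sizes[pick] <- sizes[pick] + 1L
    }
    diff <- sum(sizes) - n_snps
  }
  sizes
}

#' Build a synthetic pathway database
#'
#' Pathway sizes are uniform in `[pathway_size_low, pathway_size_high]`.
#' With a positive `pathway_overlap_fraction`, that fraction of each
#' pathway's genes is copied from a previously generated pathway (shared
#' genes); with overlap 0 the generator switches to disjoint sampling and
#' pathways are exactly non-overlapping. Every pathway listed in
#' `causal_genes` is forced to contain its designated causal genes.
#'
#' @param config A [sim_config()].
#' @param map The SNP-to-gene map tibble defining the gene universe.
#' @param causal_genes Optional named list, pathway id -> character vector
#'   of genes that pathway must contain.
#' @return A tibble with columns `pathway`, `description`, `gene` (long
#'   format, one row per pathway membership), serialisable as GMT via
#'   [write_gmt()].
#' @export
build_pathway_db <- function(config, map, causal_genes = NULL) {
  validate_sim_config(config)
  universe <- sort(unique(map$gene_id))
  if (config$pathway_size_high > length(universe))
    stop_config("invalid configuration field `pathway_size_high`: pathway size exceeds gene universe")
  ids <- pathway_ids(config$n_pathways)
  if (!is.null(causal_genes) && length(causal_genes) &&
      !all(names(causal_genes) %in% ids))
    stop_config("invalid configuration field `causal_pathways`: unknown pathway id")

  withr::with_seed(derive_seed(config$seed, 3L), {
    sizes <- sample(config$pathway_size_low:config$pathway_size_high,
                    config$n_pathways, replace = TRUE)
    sets <- vector("list", config$n_pathways)
    if (config$pathway_overlap_fraction == 0) {
      if (sum(sizes) > length(universe))
        stop_config("invalid configuration field `n_pathways`: disjoint pathways exceed the gene universe")
      pool <- sample(universe)
      ends <- cumsum(sizes)
      for (p in seq_along(ids))
        sets[[p]] <- pool[seq(ends[p] - sizes[p] + 1L, ends[p])]
    } else {
      for (p in seq_along(ids)) {
        n_ov <- if (p == 1L) 0L else
          round(config$pathway_overlap_fraction * sizes[p])
        shared <- character()
        if (n_ov > 0L) {
          donor <- sets[[sample.int(p - 1L, 1L)]]
          shared <- sample(donor, min(n_ov, length(donor)))
        }
        fresh <- sample(setdiff(universe, shared), sizes[p] - length(shared))
        sets[[p]] <- c(shared, fresh)
      }
    }
    names(sets) <- ids
    for (pw in names(causal_genes)) {
      forced <- intersect(causal_genes[[pw]], universe)
      rest <- setdiff(sets[[pw]], forced)
      keep <- max(length(sets[[pw]]) - length(forced), 0L)
      sets[[pw]] <- c(forced, head(rest, keep))
    }
  })

  tibble(
    pathway = rep(ids, lengths(sets)),
    description = "synthetic pathway",
    gene = unlist(sets, use.names = FALSE)
  )
}
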