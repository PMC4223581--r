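# SNP-to-gene significance mapping: a gene is significant when at least
# one of its SNPs is, plus size-normalised scoring variants.

#' Gene universe of a SNP-to-gene map
#'
#' @param map Tibble with columns `snp_id`, `gene_id` (one row per
#'   mapping; multi-gene SNPs appear in several rows).
#' @return Sorted character vector of distinct gene ids.
#' @export
gene_universe <- function(map) {
  if (nrow(map) == 0L) stop_input("empty SNP-to-gene map")
  sort(unique(map$gene_id))
}

# Resolve which p-value column of an association input feeds the gene rule:
# GC-adjusted p when present (the adjusted analysis), else raw.
snp_p_column <- function(x) {
  if ("p_gc" %in% names(x)) "p_gc"
  else if ("p" %in% names(x)) "p"
  else if ("p_raw" %in% names(x)) "p_raw"
  else stop_input("association input needs a `p_gc`, `p` or `p_raw` column")
}

#' Map per-SNP p-values to a significant-gene set
#'
#' A gene is significant iff at least one SNP mapped to it has `p < alpha`
#' (strict inequality; ties at exactly `alpha` do not count). Multi-gene
#' SNPs contribute to all of their genes. SNPs absent from the map are
#' dropped with an informative message; genes with no tested SNP are not
#' part of the universe. When the input carries a `p_gc` column (genomic
#' control applied) it is used, otherwise `p`/`p_raw`.
#'
#' Under the null a gene with `k` independent SNPs is significant with
#' probability `1 - (1 - alpha)^k`, so gene-size heterogeneity biases this
#' rule towards large genes; the permutation strategies exist to absorb
#' exactly that bias.
#'
#' @param snp_ps A [run_association()] result, or any tibble with `snp_id`
#'   and a p-value column.
#' @param map SNP-to-gene map tibble (`snp_id`, `gene_id`).
#' @param alpha Per-SNP significance level in (0, 1).
#' @return A tibble of class `"gene_significance"` with columns `gene`,
#'   `n_snps`, `n_sig_snps`, `min_p`, `significant`, and attributes
#'   `alpha`, `n_dropped_snps`.
#' @export
#' @examples
#' map <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s3", "s4"),
#'                       gene_id = c("A", "A", "A", "B", "C"))
#' ps <- tibble::tibble(snp_id = c("s1", "s2", "s3", "s4"),
#'                      p = c(0.2, 0.03, 0.01, 0.5))
#' map_significant_genes(ps, map, alpha = 0.05)
map_significant_genes <- function(snp_ps, map, alpha = 0.05) {
  if (!is_prob(alpha, open_lo = TRUE, open_hi = TRUE))
    stop_config("`alpha` must lie in (0, 1)")
  pcol <- snp_p_column(snp_ps)
  dat <- tibble(snp_id = snp_ps$snp_id, p = snp_ps[[pcol]])
  n_dropped <- sum(!dat$snp_id %in% map$snp_id)
  if (n_dropped == nrow(dat))
    stop_input("no SNP in the association input overlaps the SNP-to-gene map")
  if (n_dropped > 0L)
    rlang::inform(paste0(n_dropped, " SNP(s) not present in the map were dropped"))
  joined <- inner_join(dat, map, by = "snp_id", relationship = "many-to-many")
  out <- joined |>
    group_by(gene = .data$gene_id) |>
    summarise(n_snps = n(),
              n_sig_snps = sum(.data$p < alpha, na.rm = TRUE),
              min_p = min(.data$p, na.rm = TRUE),
              .groups = "drop") |>
    mutate(significant = .data$n_sig_snps >= 1L) |>
    arrange(.data$gene)
  attr(out, "alpha") <- alpha
  attr(out, "n_dropped_snps") <- n_dropped
  class(out) <- c("gene_significance", class(tibble()))
  out
}

significant_genes <- function(sig) sig$gene[sig$significant]

#' Size-normalised gene scores
#'
#' Alternatives to the binary one-significant-SNP rule that divide the
#' significant-SNP count by gene size: `"count_ratio"` uses the number of
#' tested SNPs on the gene, `"per_length"` divides by an externally
#' supplied gene length (the SNPs-per-gene count serves as proxy when no
#' lengths are given). On null data the count ratio has mean `alpha`
#' regardless of gene size, removing the long-gene bias of the binary
#' rule; converting scores to a significant set requires a user-chosen
#' cutoff.
#'
#' @inheritParams map_significant_genes
#' @param mode `"count_ratio"` or `"per_length"`.
#' @param lengths Optional named numeric vector of gene lengths for
#'   `"per_length"`.
#' @return A tibble with columns `gene`, `n_snps`, `n_sig_snps`, `score`.
#' @export
normalized_gene_score <- function(snp_ps, map, alpha = 0.05,
                                  mode = c("count_ratio", "per_length"),
                                  lengths = NULL) {
  mode <- match.arg(mode)
  sig <- map_significant_genes(snp_ps, map, alpha)
  if (mode == "count_ratio") {
    score <- sig$n_sig_snps / sig$n_snps
  } else {
    len <- if (is.null(lengths)) setNames(sig$n_snps, sig$gene)
           else lengths[sig$gene]
    if (anyNA(len)) stop_input("`lengths` must cover every gene in the map")
    score <- sig$n_sig_snps / as.numeric(len)
  }
  tibble(gene = sig$gene, n_snps = sig$n_snps,
         n_sig_snps = sig$n_sig_snps, score = score)
}
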