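# Independent oracles and shared fixtures. Everything here deliberately
# avoids the package's own code paths: enumeration and brute force only.

# Exhaustive hypergeometric tail by enumerating every possible placement of
# the g significant genes among the h universe genes (the first i genes are
# "the pathway") and counting placements with >= k (or <= k) pathway hits.
# Subset enumeration is cached per (h, g) so property sweeps stay cheap.
combn_cache <- new.env(parent = emptyenv())

enum_subsets <- function(h, g) {
  key <- paste(h, g, sep = "_")
  if (is.null(combn_cache[[key]]))
    combn_cache[[key]] <- utils::combn(h, g)
  combn_cache[[key]]
}

enum_hyper_p <- function(k, i, g, h, tail = c("enriched", "depleted")) {
  tail <- match.arg(tail)
  subs <- enum_subsets(h, g)                 # g x C(h, g)
  hits <- colSums(subs <= i)                 # pathway = genes 1..i
  if (tail == "enriched") mean(hits >= k) else mean(hits <= k)
}

# Exact case-control label-permutation p-value of the trend statistic for
# one genotype column: enumerate every assignment of the case labels.
# `mid = TRUE` gives the mid-p (half weight on the tied atom), the natural
# discreteness-corrected analogue of a continuous p-value.
exact_trend_perm_p <- function(g, y, mid = FALSE) {
  n <- length(y)
  stat <- function(yy) {
    if (stats::var(g) == 0) return(0)
    n * stats::cor(g, yy)^2
  }
  obs <- stat(y)
  case_sets <- utils::combn(n, sum(y))
  perms <- apply(case_sets, 2, function(idx) {
    yy <- integer(n); yy[idx] <- 1L
    stat(yy)
  })
  if (mid) mean(perms > obs + 1e-9) + 0.5 * mean(abs(perms - obs) < 1e-9)
  else mean(perms >= obs - 1e-12)
}

# Small deterministic study built by hand (no generator involved): 8
# samples x 4 SNPs, one constant SNP.
toy_study <- function() {
  G <- cbind(
    snp1 = c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L),  # perfectly associated
    snp2 = c(1L, 0L, 2L, 1L, 1L, 2L, 0L, 1L),  # mixed
    snp3 = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L),  # constant (het)
    snp4 = c(0L, 1L, 1L, 2L, 0L, 1L, 1L, 2L)   # identical across groups
  )
  rownames(G) <- paste0("s", 1:8)
  gwas_study(G, phenotype = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
}

# A small but non-trivial synthetic scene shared by several test files.
small_sim <- function(seed = 42, or = 1, causal = character(),
                      n_snps = 500, n_genes = 100, n_pathways = 12) {
  simulate_gwas(sim_config(
    n_cases = 100, n_controls = 100, n_snps = n_snps, n_genes = n_genes,
    snps_per_gene_mean = n_snps / n_genes, n_pathways = n_pathways,
    pathway_size_low = min(5, n_genes %/% 3),
    pathway_size_high = min(15, n_genes %/% 2),
    causal_pathways = causal, n_causal_snps_per_pathway = 5,
    causal_odds_ratio = or, missing_rate = 0.01, seed = seed))
}
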