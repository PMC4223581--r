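# The three permutation null constructions and their aggregation:
#   columns    - shuffle case-control labels, re-run association -> genes -> ORA
#   rows_snp   - shuffle the per-SNP p-values across SNP ids (p multiset fixed)
#   rows_gene  - shuffle the per-gene significance labels (gene count fixed)

#' Plan a permutation battery
#'
#' @param strategy `"columns"` (case-control label shuffles, the gold
#'   standard), `"rows_snp"` (SNP p-value shuffles; the option when only
#'   aggregated SNP statistics are available) or `"rows_gene"` (gene label
#'   shuffles, the competitive null).
#' @param n_perms Number of permutations (N_tot).
#' @param seed Base seed; each run gets its own stream derived from
#'   `(seed, run index)`, so results do not depend on execution order.
#' @param alpha Per-SNP significance level for the gene rule.
#' @param pseudo_count Add a pseudo-count to the permutation p-value
#'   (`(count + 1) / (N + 1)`) so it can never be exactly zero.
#' @param tail Which per-run pathway p-value feeds the comparison:
#'   `"enriched"` (default), `"depleted"`, or `"two_tailed"` (the smaller
#'   of the two tails per run).
#' @param recompute_gc For the columns strategy: recompute genomic control
#'   inside every permutation run (off by default; the trend statistics
#'   under label shuffles are null-calibrated, and per-run GC is the
#'   dominant extra cost).
#' @param comparison `"le"` (default) counts permutation runs at least as
#'   significant as the original, i.e. `p_n <= p_original`; `"ge"` counts
#'   `p_n >= p_original` instead.
#' @param min_pathway_genes Pathway exclusion threshold, as in [run_ora()].
#' @return A list of class `"permutation_plan"`.
#' @export
permutation_plan <- function(strategy = c("columns", "rows_snp", "rows_gene"),
                             n_perms = 2000, seed = 1, alpha = 0.05,
                             pseudo_count = FALSE,
                             tail = c("enriched", "depleted", "two_tailed"),
                             recompute_gc = FALSE,
                             comparison = c("le", "ge"),
                             min_pathway_genes = 2) {
  strategy <- match.arg(strategy)
  tail <- match.arg(tail)
  comparison <- match.arg(comparison)
  if (!is_count(n_perms)) stop_config("`n_perms` must be an integer >= 1")
  if (!is_prob(alpha, open_lo = TRUE, open_hi = TRUE))
    stop_config("`alpha` must lie in (0, 1)")
  structure(list(strategy = strategy, n_perms = as.integer(n_perms),
                 seed = seed, alpha = alpha, pseudo_count = pseudo_count,
                 tail = tail, recompute_gc = recompute_gc,
                 comparison = comparison,
                 min_pathway_genes = min_pathway_genes),
            class = "permutation_plan")
}

#' Permutation p-value from per-run pathway p-values
#'
#' `p_perm = #\{n : p_n <= p_original\} / N_tot` — the fraction of
#' permutation runs at least as significant as the original analysis, with
#' ties counting as at-least-as-significant (conservative). With
#' `pseudo_count = TRUE` the estimate is `(count + 1) / (N_tot + 1)`,
#' which avoids exact zeros when no run reaches the original significance.
#' `comparison = "ge"` counts runs with `p_n >= p_original` instead.
#'
#' @param perm_ps Per-run p-values for one pathway (all in [0, 1]).
#' @param p_original The pathway's p-value on the unpermuted data.
#' @param pseudo_count Logical.
#' @param comparison `"le"` or `"ge"`.
#' @return A single permutation p-value.
#' @export
#' @examples
#' perm_pvalue(c(0.01, 0.20, 0.50, 0.90), 0.21)                      # 0.5
#' perm_pvalue(c(0.01, 0.20, 0.50, 0.90), 0.21, pseudo_count = TRUE) # 0.6
perm_pvalue <- function(perm_ps, p_original, pseudo_count = FALSE,
                        comparison = c("le", "ge")) {
  comparison <- match.arg(comparison)
  if (length(perm_ps) == 0L) stop_input("`perm_ps` must be non-empty")
  if (any(perm_ps < 0 | perm_ps > 1, na.rm = TRUE) ||
      p_original < 0 || p_original > 1)
    stop_input("p-values must lie in [0, 1]")
  count <- if (comparison == "le") sum(perm_ps <= p_original)
           else sum(perm_ps >= p_original)
  n <- length(perm_ps)
  if (pseudo_count) (count + 1) / (n + 1) else count / n
}

#' Shuffle case-control labels once and re-run the association stage
#'
#' The phenotype vector is permuted uniformly at random over samples
#' (genotypes and covariates untouched), and the fast trend test is re-run
#' on the given SNP set. Case and control totals are preserved by
#' construction.
#'
#' @param study A [gwas_study()] with phenotype.
#' @param seed Seed for this single permutation.
#' @param snp_ids SNPs to test (default: all; the engine passes the
#'   QC-retained set).
#' @param recompute_gc Recompute genomic control on the permuted run?
#' @param lambda Optional fixed inflation factor to divide the permuted
#'   chi-square statistics by (used when `recompute_gc = FALSE` to keep
#'   permuted runs on the scale of a GC-adjusted original analysis).
#' @return A tibble (`snp_id`, `chi2`, `p_raw`, `p_gc`).
#' @export
permute_columns_once <- function(study, seed, snp_ids = study$snp_ids,
                                 recompute_gc = FALSE, lambda = NULL) {
  y <- withr::with_seed(seed, sample(study$phenotype))
  G <- study$genotypes[, snp_ids, drop = FALSE]
  chi2 <- as.numeric(trend_chi2_matrix(G, matrix(y, ncol = 1)))
  if (!recompute_gc && !is.null(lambda)) chi2 <- chi2 / lambda
  out <- tibble(snp_id = snp_ids, chi2 = chi2,
                p_raw = pchisq(chi2, df = 1, lower.tail = FALSE))
  if (recompute_gc) genomic_control(out)
  else { out$p_gc <- out$p_raw; out }
}

#' Shuffle the per-SNP p-values across SNP identifiers once
#'
#' The multiset of p-values is preserved exactly — only the bijection
#' between SNP ids and p-values is redrawn uniformly — so the number of
#' significant SNPs cannot vary across runs. Linkage disequilibrium
#' structure, however, is destroyed.
#'
#' @param assoc Tibble with `snp_id` and a p-value column (at least 2 SNPs).
#' @param seed Seed for this single permutation.
#' @return A tibble (`snp_id`, `p`) with the permuted assignment.
#' @export
permute_rows_snp_once <- function(assoc, seed) {
  if (nrow(assoc) < 2L) stop_input("row permutation needs at least 2 SNPs")
  p <- assoc[[snp_p_column(assoc)]]
  idx <- withr::with_seed(seed, sample.int(length(p)))
  tibble(snp_id = assoc$snp_id, p = p[idx])
}

#' Shuffle gene significance labels once
#'
#' The per-gene significance indicators are permuted uniformly across the
#' gene universe; pathway memberships are untouched and the number of
#' significant genes is exactly invariant. This is the competitive null:
#' the significant set becomes a uniform draw of the same size from the
#' universe, which is precisely the hypergeometric model.
#'
#' @param sig A [map_significant_genes()] result (universe of >= 2 genes).
#' @param seed Seed for this single permutation.
#' @return A `gene_significance`-like tibble with permuted `significant`.
#' @export
permute_rows_gene_once <- function(sig, seed) {
  if (nrow(sig) < 2L) stop_input("gene permutation needs a universe of >= 2 genes")
  idx <- withr::with_seed(seed, sample.int(nrow(sig)))
  out <- sig
  out$significant <- sig$significant[idx]
  out$n_sig_snps <- sig$n_sig_snps[idx]
  out$min_p <- sig$min_p[idx]
  out
}

# --- engine internals ------------------------------------------------------

# Sparse gene x SNP incidence from a map, restricted to given snp order.
gene_snp_incidence <- function(map, snps, genes) {
  m <- filter(map, .data$snp_id %in% snps, .data$gene_id %in% genes)
  Matrix::sparseMatrix(
    i = match(m$gene_id, genes), j = match(m$snp_id, snps),
    x = 1, dims = c(length(genes), length(snps)),
    dimnames = list(genes, snps))
}

# Sparse pathway x gene incidence.
pathway_gene_incidence <- function(db, pathways, genes) {
  d <- filter(db, .data$pathway %in% pathways, .data$gene %in% genes)
  d <- dplyr::distinct(d, .data$pathway, .data$gene)
  Matrix::sparseMatrix(
    i = match(d$pathway, pathways), j = match(d$gene, genes),
    x = 1, dims = c(length(pathways), length(genes)),
    dimnames = list(pathways, genes))
}

# Per-run pathway p for the planned tail from count matrices.
tail_p_matrix <- function(K, i_vec, g_vec, h, tail) {
  if (tail == "two_tailed") {
    pmin(hyper_p_matrix(K, i_vec, g_vec, h, "enriched"),
         hyper_p_matrix(K, i_vec, g_vec, h, "depleted"))
  } else {
    hyper_p_matrix(K, i_vec, g_vec, h, tail)
  }
}

tail_p_original <- function(ora, tail) {
  switch(tail,
         enriched = ora$p_enriched,
         depleted = ora$p_depleted,
         two_tailed = pmin(ora$p_enriched, ora$p_depleted))
}

# Aggregate run-level matrices into the per-pathway summary.
summarise_perm <- function(pathways, i_vec, k0, p_orig, PM, K, g_vec, h,
                           plan) {
  n_more <- if (plan$comparison == "le") rowSums(PM <= p_orig)
            else rowSums(PM >= p_orig)
  denom <- if (plan$pseudo_count) plan$n_perms + 1 else plan$n_perms
  numer <- if (plan$pseudo_count) n_more + 1 else n_more
  expect <- outer(i_vec, g_vec) / h          # pathways x runs: g*i/h
  tibble(pathway = pathways, i = i_vec, k_original = k0,
         p_original = p_orig,
         n_as_or_more = as.integer(unname(n_more)),
         p_perm = unname(numer / denom),
         frac_enriched = unname(rowMeans(K > expect)),
         frac_depleted = unname(rowMeans(K < expect)),
         frac_tied = unname(rowMeans(K == expect)))
}

new_gwas_perm <- function(summary, runs, perm_p, original_ora, plan, h,
                          n_sig_genes_original) {
  structure(list(summary = summary, runs = runs, perm_p = perm_p,
                 original = original_ora, plan = plan, h = h,
                 n_sig_genes_original = n_sig_genes_original),
            class = "gwas_perm")
}

# Shared tail: gene-significance indicator matrix -> pathway summary.
finish_engine <- function(GS, sig0, db, plan, assoc_note = NULL) {
  universe <- sig0$gene
  h <- length(universe)
  ora0 <- run_ora(sig0, db, min_pathway_genes = plan$min_pathway_genes)
  live <- ora0$pathway[!ora0$excluded]
  ora_live <- ora0[match(live, ora0$pathway), ]
  Pw <- pathway_gene_incidence(db, live, universe)
  K <- as.matrix(Pw %*% GS)
  g_vec <- colSums(GS)
  PM <- tail_p_matrix(K, ora_live$i, g_vec, h, plan$tail)
  p_orig <- tail_p_original(ora_live, plan$tail)
  summary <- summarise_perm(live, ora_live$i, ora_live$k, p_orig, PM, K,
                            g_vec, h, plan)
  runs <- tibble(run = seq_len(plan$n_perms),
                 n_significant_genes = as.integer(g_vec))
  rownames(PM) <- live
  new_gwas_perm(summary, runs, PM, ora0, plan, h,
                sum(sig0$significant))
}

run_seed <- function(plan, i) derive_seed(plan$seed, 1000L + i)

# --- the three engines -----------------------------------------------------

engine_columns <- function(study, map, db, plan, thresholds) {
  assoc0 <- run_association(study, thresholds, test = "trend",
                            apply_gc = TRUE)
  sig0 <- map_significant_genes(assoc0, map, plan$alpha)
  keep <- assoc0$snp_id
  G <- study$genotypes[, keep, drop = FALSE]
  n <- nrow(G)
  Y <- vapply(seq_len(plan$n_perms),
              function(i) withr::with_seed(run_seed(plan, i),
                                           sample(study$phenotype)),
              integer(n))
  chi2 <- trend_chi2_matrix(G, Y)            # SNPs x runs
  if (plan$recompute_gc) {
    lambda <- pmax(1, apply(chi2, 2, median, na.rm = TRUE) / CHISQ1_MEDIAN)
    chi2 <- sweep(chi2, 2, lambda, "/")
  } else {
    # keep permuted runs on the same scale as the GC-adjusted original:
    # reuse the original run's inflation factor as a constant correction
    chi2 <- chi2 / (attr(assoc0, "lambda_gc") %||% 1)
  }
  P <- pchisq(chi2, df = 1, lower.tail = FALSE)
  S <- (P < plan$alpha) * 1
  S[is.na(S)] <- 0
  A <- gene_snp_incidence(map, keep, sig0$gene)
  GS <- as.matrix(A %*% S) > 0
  finish_engine(GS, sig0, db, plan)
}

engine_rows_snp <- function(assoc, map, db, plan) {
  if (nrow(assoc) < 2L) stop_input("row permutation needs at least 2 SNPs")
  sig0 <- map_significant_genes(assoc, map, plan$alpha)
  p0 <- assoc[[snp_p_column(assoc)]]
  S0 <- (p0 < plan$alpha) * 1
  z <- length(S0)
  S <- vapply(seq_len(plan$n_perms),
              function(i) S0[withr::with_seed(run_seed(plan, i),
                                              sample.int(z))],
              numeric(z))
  A <- gene_snp_incidence(map, assoc$snp_id, sig0$gene)
  GS <- as.matrix(A %*% S) > 0
  finish_engine(GS, sig0, db, plan)
}

engine_rows_gene <- function(sig, db, plan) {
  if (nrow(sig) < 2L)
    stop_input("gene permutation needs a universe of >= 2 genes")
  s0 <- sig$significant * 1
  GS <- vapply(seq_len(plan$n_perms),
               function(i) s0[withr::with_seed(run_seed(plan, i),
                                               sample.int(length(s0)))],
               numeric(length(s0))) > 0
  finish_engine(GS, sig, db, plan)
}

#' Run a permutation battery
#'
#' Executes `plan$n_perms` seeded permutation runs of the chosen strategy,
#' re-deriving per-run pathway p-values, and aggregates them into the
#' per-pathway permutation summary: the count and fraction of runs at
#' least as significant as the original analysis, and the
#' enriched/depleted/tied run fractions (a run counts as enriched for a
#' pathway when `k * h > g * i`, i.e. the pathway holds more significant
#' genes than expected). Fully reproducible from `(inputs, plan$seed)` and
#' independent of execution order.
#'
#' The first argument must match the strategy: a [gwas_study()] for
#' `"columns"`, an association table for `"rows_snp"`, a
#' [map_significant_genes()] result for `"rows_gene"` — a mismatch is a
#' configuration error (e.g. case-control permutations are impossible when
#' only aggregated SNP statistics are available).
#'
#' @param x Strategy input (see Details).
#' @param map SNP-to-gene map tibble (ignored for `"rows_gene"`).
#' @param db Pathway tibble.
#' @param plan A [permutation_plan()].
#' @param thresholds [qc_thresholds()] for the original association run
#'   (columns strategy only). QC is computed once on the original labels;
#'   the retained SNP set is held fixed across permutations.
#' @return An object of class `"gwas_perm"`: list with `summary` (tibble:
#'   `pathway`, `i`, `k_original`, `p_original`, `n_as_or_more`, `p_perm`,
#'   `frac_enriched`, `frac_depleted`, `frac_tied`), `runs` (tibble:
#'   `run`, `n_significant_genes`), `perm_p` (pathways x runs matrix of
#'   per-run tail p-values), `original` (the unpermuted [run_ora()]
#'   result), `plan`, `h`, `n_sig_genes_original`.
#' @export
run_permutations <- function(x, map = NULL, db, plan,
                             thresholds = qc_thresholds()) {
  switch(plan$strategy,
    columns = {
      if (!inherits(x, "gwas_study"))
        stop_config("configuration error: case-control (column) permutations need raw genotype data, not aggregated statistics")
      engine_columns(x, map, db, plan, thresholds)
    },
    rows_snp = {
      if (inherits(x, "gwas_study") || !"snp_id" %in% names(x))
        stop_config("configuration error: SNP (row I) permutations need a per-SNP association table")
      engine_rows_snp(x, map, db, plan)
    },
    rows_gene = {
      if (!"significant" %in% names(x))
        stop_config("configuration error: gene (row II) permutations need a gene significance table")
      engine_rows_gene(x, db, plan)
    }
  )
}

#' @export
print.gwas_perm <- function(x, ...) {
  cat("<gwas_perm> ", x$plan$strategy, " strategy, ", x$plan$n_perms,
      " permutations, ", nrow(x$summary), " pathways\n", sep = "")
  cat("  original significant genes: ", x$n_sig_genes_original,
      "; permuted mean: ", round(mean(x$runs$n_significant_genes), 1),
      "\n", sep = "")
  cat("  pathways with p_perm <= 0.05: ",
      sum(x$summary$p_perm <= 0.05), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.gwas_perm <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.gwas_perm <- function(x, ...) {
  zres <- tryCatch(
    gene_count_zscore(x$n_sig_genes_original, x$runs$n_significant_genes),
    permpath_error = function(e) list(z = NA_real_, p = NA_real_))
  tibble(strategy = x$plan$strategy, n_perms = x$plan$n_perms,
         n_pathways = nrow(x$summary),
         mean_p_perm = mean(x$summary$p_perm),
         n_sig_pathways = sum(x$summary$p_perm <= 0.05),
         gene_count_z = zres$z, gene_count_p = zres$p)
}

#' Enriched/depleted/tied run fractions
#'
#' A permutation run counts as enriched for a pathway when the pathway
#' holds more significant genes than expected under uniform placement
#' (`k * h > g * i`), depleted when fewer, tied at exact equality; the
#' three fractions partition the runs.
#'
#' @param k Matrix (pathways x runs) of significant-gene counts per pathway.
#' @param g Per-run totals of significant genes.
#' @param i Per-pathway universe gene counts.
#' @param h Universe size.
#' @return A tibble with columns `pathway` (row names of `k` or index),
#'   `frac_enriched`, `frac_depleted`, `frac_tied`.
#' @export
enrich_deplete_fractions <- function(k, g, i, h) {
  expect <- outer(i, g) / h
  tibble(pathway = rownames(k) %||% as.character(seq_len(nrow(k))),
         frac_enriched = unname(rowMeans(k > expect)),
         frac_depleted = unname(rowMeans(k < expect)),
         frac_tied = unname(rowMeans(k == expect)))
}

#' Z-score comparison of the significant-gene count against permutations
#'
#' `z = (original - mean(perm_counts)) / sd(perm_counts)` with a two-sided
#' normal p-value; used to ask whether a permutation strategy shifts the
#' number of significant genes relative to the original analysis.
#'
#' @param original_count Significant-gene count of the unpermuted analysis.
#' @param perm_counts Per-run significant-gene counts (>= 2 runs with
#'   nonzero spread).
#' @return A list with elements `z` and `p`.
#' @export
#' @examples
#' gene_count_zscore(6226, c(5400, 5500, 5600))
gene_count_zscore <- function(original_count, perm_counts) {
  if (length(perm_counts) < 2L)
    stop_input("need at least 2 permutation counts")
  s <- sd(perm_counts)
  if (s == 0)
    stop_input("zero spread in permutation counts: z-score undefined")
  z <- (original_count - mean(perm_counts)) / s
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Permutation-space combinatorics
#'
#' For a study with `x` cases, `y` controls, `z` SNPs and `g_genes` genes:
#' `choose(x + y, y)` distinct case-control label permutations are
#' possible, versus up to `z!` SNP-label and `g_genes!` gene-label
#' permutations. The binomial coefficient is returned exactly while it is
#' representable in a double (< 2^53), `NA` beyond that; the log10 values
#' are always reported. For typical GWAS `z >> x + y`, so vastly more row
#' permutations exist than column permutations.
#'
#' @param x,y Case and control counts.
#' @param z Number of SNPs.
#' @param g_genes Number of genes.
#' @return A list: `n_case_control` (exact or NA),
#'   `log10_case_control`, `log10_snp_factorial`, `log10_gene_factorial`.
#' @export
#' @examples
#' count_case_control_permutations(x = 2, y = 2, z = 10, g_genes = 5)
count_case_control_permutations <- function(x, y, z, g_genes) {
  for (v in list(x, y, z, g_genes))
    if (!is_count(v)) stop_config("all counts must be integers >= 1")
  lg10 <- (lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1)) / log(10)
  exact <- choose(x + y, y)
  list(
    n_case_control = if (exact < 2^53) exact else NA_real_,
    log10_case_control = lg10,
    log10_snp_factorial = lgamma(z + 1) / log(10),
    log10_gene_factorial = lgamma(g_genes + 1) / log(10)
  )
}
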