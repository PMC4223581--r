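# End-to-end orchestration, the alpha sensitivity sweep and the
# strategy-comparison report.

#' Run the full pathway-permutation pipeline
#'
#' Original association analysis (or user-supplied summary statistics),
#' gene mapping, hypergeometric over-representation analysis, one
#' permutation battery per enabled strategy, a convergence curve for each
#' strategy's most borderline significant pathway, and a comparison report
#' (per-strategy significant-pathway sets, their Venn overlap, gene-count
#' z-scores and mean permutation p per strategy). All stages are seeded
#' and byte-reproducible; with `out_dir` set, every table is also written
#' as TSV.
#'
#' Case-control (`"columns"`) permutations require raw genotypes; enabling
#' them in summary-statistics mode (an association table but no study) is
#' a configuration error, since shuffling case-control labels is
#' impossible without the raw data.
#'
#' @param study A [gwas_study()] with phenotype, or `NULL` in
#'   summary-statistics mode.
#' @param assoc Optional precomputed association table (tibble with
#'   `snp_id` and a p-value column); computed from `study` when missing.
#' @param map SNP-to-gene map tibble.
#' @param db Pathway tibble.
#' @param thresholds [qc_thresholds()] for the association stage.
#' @param alpha_snp Per-SNP significance level (default 0.05).
#' @param alpha_pathway Pathway significance level applied to BH-adjusted
#'   original q-values and to (unadjusted) permutation p-values.
#' @param strategies Permutation strategies to run.
#' @param n_perms Permutations per strategy (default 2,000).
#' @param seed Base seed.
#' @param test Association test for the original run (columns batteries
#'   always use the fast trend test).
#' @param convergence_sizes Subsample-size grid for the convergence stage;
#'   sizes above `n_perms` are dropped.
#' @param out_dir Optional output directory for TSV artifacts.
#' @return A list of class `"permpath_pipeline"` with elements `assoc`,
#'   `gene_sig`, `ora`, `perms` (one `gwas_perm` per strategy),
#'   `convergence` (one curve per strategy), `report` and `seed`.
#' @export
run_pipeline <- function(study = NULL, assoc = NULL, map, db,
                         thresholds = qc_thresholds(),
                         alpha_snp = 0.05, alpha_pathway = 0.05,
                         strategies = "columns",
                         n_perms = 2000, seed = 1,
                         test = c("trend", "logistic"),
                         convergence_sizes = c(100, 250, 500, 1000, 2000,
                                               5000, 10000, 15000),
                         out_dir = NULL) {
  test <- match.arg(test)
  strategies <- match.arg(strategies,
                          c("columns", "rows_snp", "rows_gene"),
                          several.ok = TRUE)
  if (is.null(study) && is.null(assoc))
    stop_config("configuration error: supply `study` (genotype mode) or `assoc` (summary-statistics mode)")
  if (is.null(study) && "columns" %in% strategies)
    stop_config("configuration error: case-control permutations are not possible in summary-statistics mode (no raw genotype data)")

  if (is.null(assoc))
    assoc <- run_association(study, thresholds, test = test)
  gene_sig <- map_significant_genes(assoc, map, alpha_snp)
  ora <- run_ora(gene_sig, db)

  perms <- list()
  for (s in strategies) {
    plan <- permutation_plan(strategy = s, n_perms = n_perms,
                             seed = derive_seed(seed, match(
                               s, c("columns", "rows_snp", "rows_gene"))),
                             alpha = alpha_snp)
    input <- switch(s, columns = study, rows_snp = assoc,
                    rows_gene = gene_sig)
    perms[[s]] <- run_permutations(input, map, db, plan,
                                   thresholds = thresholds)
  }

  convergence <- purrr::imap(perms, function(pm, s) {
    sizes <- convergence_sizes[convergence_sizes <= n_perms]
    target <- pipeline_convergence_target(pm)
    if (length(sizes) == 0L || is.na(target)) return(NULL)
    curve <- subsample_cv(
      pm$perm_p[target, ] , p_original =
        pm$summary$p_original[pm$summary$pathway == target],
      sizes = sizes, seed = derive_seed(seed, 50L + match(
        s, c("columns", "rows_snp", "rows_gene"))),
      pseudo_count = TRUE)
    attr(curve, "pathway") <- target
    curve
  })

  report <- pipeline_report(ora, perms, alpha_pathway)

  out <- structure(
    list(assoc = assoc, gene_sig = gene_sig, ora = ora, perms = perms,
         convergence = convergence, report = report, seed = seed),
    class = "permpath_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

# The most borderline pathway near p_perm = 0.05 (the interesting regime
# for convergence); NA when no pathway has a positive p_perm.
pipeline_convergence_target <- function(pm) {
  s <- pm$summary[pm$summary$p_perm > 0, ]
  if (nrow(s) == 0L) return(NA_character_)
  s$pathway[which.min(abs(s$p_perm - 0.05))]
}

pipeline_report <- function(ora, perms, alpha_pathway) {
  orig_set <- ora$pathway[!ora$excluded &
                            coalesce(ora$q_enriched <= alpha_pathway, FALSE)]
  sets <- c(list(original = orig_set),
            lapply(perms, function(pm)
              pm$summary$pathway[pm$summary$p_perm <= alpha_pathway]))
  strat_stats <- purrr::imap_dfr(perms, function(pm, s) {
    zres <- tryCatch(
      gene_count_zscore(pm$n_sig_genes_original,
                        pm$runs$n_significant_genes),
      permpath_error = function(e) list(z = NA_real_, p = NA_real_))
    tibble(strategy = s,
           mean_p_perm = mean(pm$summary$p_perm),
           n_significant = sum(pm$summary$p_perm <= alpha_pathway),
           mean_genes_perm = mean(pm$runs$n_significant_genes),
           gene_count_z = zres$z, gene_count_p = zres$p)
  })
  list(significant_sets = sets,
       venn = venn_overlap(sets),
       strategy_stats = strat_stats,
       mean_p_original = mean(ora$p_enriched, na.rm = TRUE))
}

write_pipeline <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assoc_tsv(out$assoc, file.path(out_dir, "association.tsv"))
  readr::write_tsv(as_tibble(out$gene_sig),
                   file.path(out_dir, "gene_significance.tsv"))
  readr::write_tsv(as_tibble(out$ora), file.path(out_dir, "ora.tsv"))
  for (s in names(out$perms)) {
    readr::write_tsv(out$perms[[s]]$summary,
                     file.path(out_dir, paste0("perm_", s, "_summary.tsv")))
    readr::write_tsv(out$perms[[s]]$runs,
                     file.path(out_dir, paste0("perm_", s, "_runs.tsv")))
    if (!is.null(out$convergence[[s]]))
      readr::write_tsv(as_tibble(out$convergence[[s]]),
                       file.path(out_dir,
                                 paste0("convergence_", s, ".tsv")))
  }
  readr::write_tsv(out$report$venn, file.path(out_dir, "venn.tsv"))
  readr::write_tsv(out$report$strategy_stats,
                   file.path(out_dir, "strategy_stats.tsv"))
  invisible(out_dir)
}

#' @export
print.permpath_pipeline <- function(x, ...) {
  cat("<permpath_pipeline>\n")
  cat("  SNPs retained: ", nrow(x$assoc),
      " (lambda_gc = ", signif(attr(x$assoc, "lambda_gc"), 4), ")\n",
      sep = "")
  cat("  significant genes: ", sum(x$gene_sig$significant), " of ",
      nrow(x$gene_sig), "\n", sep = "")
  cat("  pathways (BH q <= 0.05): ",
      sum(x$ora$q_enriched <= 0.05, na.rm = TRUE), " enriched\n", sep = "")
  for (s in names(x$perms))
    cat("  ", s, ": ", sum(x$perms[[s]]$summary$p_perm <= 0.05),
        " pathways at p_perm <= 0.05\n", sep = "")
  invisible(x)
}

#' Alpha-sensitivity sweep
#'
#' Recomputes the significant-gene set and the pathway analysis across a
#' strictly decreasing grid of per-SNP significance levels. Gene sets are
#' nested, so the counts are monotone non-increasing; pathway counts use
#' BH-adjusted enrichment q-values at `alpha_pathway`.
#'
#' @param assoc Association table (tibble with `snp_id` and a p column).
#' @param map SNP-to-gene map tibble.
#' @param db Pathway tibble.
#' @param alphas Strictly decreasing per-SNP levels.
#' @param alpha_pathway Pathway-level threshold on q_enriched.
#' @return A tibble with columns `alpha`, `n_significant_genes`,
#'   `frac_of_first`, `n_significant_pathways`.
#' @export
alpha_sweep <- function(assoc, map, db,
                        alphas = c(0.05, 0.01, 0.001, 0.0001),
                        alpha_pathway = 0.05) {
  if (any(diff(alphas) >= 0))
    stop_config("`alphas` must be strictly decreasing")
  rows <- purrr::map_dfr(alphas, function(a) {
    sig <- map_significant_genes(assoc, map, a)
    n_genes <- sum(sig$significant)
    ora <- suppressWarnings(run_ora(sig, db))
    tibble(alpha = a, n_significant_genes = n_genes,
           n_significant_pathways =
             sum(ora$q_enriched <= alpha_pathway, na.rm = TRUE))
  })
  mutate(rows, frac_of_first =
           .data$n_significant_genes / .data$n_significant_genes[1],
         .after = "n_significant_genes")
}

#' Venn cell counts over named sets
#'
#' Counts every exclusive region of the Venn diagram over two or more
#' named sets (e.g. the significant-pathway sets of the original analysis
#' and the permutation strategies). Cells partition the union, so the cell
#' counts sum to the union size.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return A tibble with one row per non-empty membership pattern:
#'   `region` (set names joined by `&`), logical membership columns, `n`.
#' @export
#' @examples
#' venn_overlap(list(a = c("x", "y"), b = c("y", "z")))
venn_overlap <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)))
    stop_input("`sets` must be a named list of at least 2 sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (is.null(dim(member)))
    member <- matrix(member, nrow = length(universe))
  pattern <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  patterns <- table(pattern)
  out <- purrr::map_dfr(names(patterns), function(pt) {
    in_sets <- strsplit(pt, "&", fixed = TRUE)[[1]]
    row <- as.list(setNames(names(sets) %in% in_sets, names(sets)))
    tibble(region = pt, !!!row, n = as.integer(patterns[[pt]]))
  })
  arrange(out, dplyr::desc(.data$n))
}
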