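test_that("perm_pvalue counts at-least-as-significant runs with optional pseudo-count", {
  expect_equal(perm_pvalue(c(0.01, 0.20, 0.50, 0.90), 0.21), 0.5)
  expect_equal(perm_pvalue(c(0.01, 0.20, 0.50, 0.90), 0.21,
                           pseudo_count = TRUE), 0.6)
  # no run reaches an original p of 0
  expect_equal(perm_pvalue(c(0.1, 0.2), 0), 0)
  expect_equal(perm_pvalue(c(0.1, 0.2), 0, pseudo_count = TRUE), 1 / 3)
  # complete ties count as at-least-as-significant
  expect_equal(perm_pvalue(rep(0.3, 5), 0.3), 1)
  # the printed >= variant
  expect_equal(perm_pvalue(c(0.01, 0.20, 0.50, 0.90), 0.21,
                           comparison = "ge"), 0.5)
  expect_error(perm_pvalue(numeric(0), 0.5), class = "permpath_input_error")

  # minimum attainable p_perm is 1/N (1/(N+1) with pseudo-count)
  withr::with_seed(8, {
    for (rep in 1:20) {
      ps <- runif(sample(3:30, 1))
      p0 <- runif(1)
      expect_gte(perm_pvalue(ps, p0, pseudo_count = TRUE),
                 1 / (length(ps) + 1))
      raw <- perm_pvalue(ps, p0)
      expect_true(raw == 0 || raw >= 1 / length(ps))
    }
  })
})

test_that("column permutations preserve case and control totals", {
  sim <- small_sim(seed = 14, or = 2, causal = "pw001")
  perm <- permute_columns_once(sim$study, seed = 3)
  expect_identical(nrow(perm), length(sim$study$snp_ids))
  y1 <- withr::with_seed(3, sample(sim$study$phenotype))
  expect_identical(sum(y1), sum(sim$study$phenotype))
  # same seed, same permutation
  expect_identical(permute_columns_once(sim$study, seed = 3),
                   permute_columns_once(sim$study, seed = 3))
})

test_that("SNP permutations preserve the p-value multiset and significant count", {
  sim <- small_sim(seed = 14, or = 2, causal = "pw001")
  assoc <- run_association(sim$study, qc_thresholds())
  perm <- permute_rows_snp_once(assoc, seed = 5)
  expect_identical(sort(perm$p), sort(assoc$p_gc))
  expect_identical(sum(perm$p < 0.05), sum(assoc$p_gc < 0.05))
  expect_error(permute_rows_snp_once(assoc[1, ], seed = 1),
               class = "permpath_input_error")
})

test_that("gene permutations preserve the significant-gene count exactly", {
  sim <- small_sim(seed = 14, or = 2, causal = "pw001")
  assoc <- run_association(sim$study, qc_thresholds())
  sig <- map_significant_genes(assoc, sim$map, 0.05)
  perm <- permute_rows_gene_once(sig, seed = 11)
  expect_identical(sum(perm$significant), sum(sig$significant))
  expect_identical(sort(perm$gene), sort(sig$gene))

  # two-gene universe: exactly two possible assignments
  tiny <- sig[1:2, ]
  tiny$significant <- c(TRUE, FALSE)
  outcomes <- vapply(1:20, function(s)
    which(permute_rows_gene_once(tiny, seed = s)$significant),
    integer(1))
  expect_setequal(unique(outcomes), 1:2)
})

test_that("run_permutations rejects strategy/input mismatches", {
  sim <- small_sim(seed = 14)
  assoc <- run_association(sim$study, qc_thresholds())
  expect_error(
    run_permutations(assoc, sim$map, sim$pathways,
                     permutation_plan("columns", n_perms = 2)),
    class = "permpath_config_error")
  expect_error(
    run_permutations(sim$study, sim$map, sim$pathways,
                     permutation_plan("rows_snp", n_perms = 2)),
    class = "permpath_config_error")
  expect_error(
    run_permutations(assoc, sim$map, sim$pathways,
                     permutation_plan("rows_gene", n_perms = 2)),
    class = "permpath_config_error")
})

test_that("permutation batteries are reproducible and respect invariants", {
  sim <- small_sim(seed = 33, or = 2, causal = "pw001")
  assoc <- run_association(sim$study, qc_thresholds())
  sig <- map_significant_genes(assoc, sim$map, 0.05)

  plan <- permutation_plan("rows_snp", n_perms = 50, seed = 6)
  a <- run_permutations(assoc, sim$map, sim$pathways, plan)
  b <- run_permutations(assoc, sim$map, sim$pathways, plan)
  expect_identical(a$summary, b$summary)
  expect_identical(a$perm_p, b$perm_p)

  # single-run boundary: p_perm is 0 or 1 without pseudo-count
  one <- run_permutations(sig, sim$map, sim$pathways,
                          permutation_plan("rows_gene", n_perms = 1, seed = 2))
  expect_true(all(one$summary$p_perm %in% c(0, 1)))

  # rows_gene preserves the significant-gene count in every run
  pg <- run_permutations(sig, sim$map, sim$pathways,
                         permutation_plan("rows_gene", n_perms = 30, seed = 4))
  expect_true(all(pg$runs$n_significant_genes == sum(sig$significant)))

  # enrichment fractions partition the runs
  s <- a$summary
  expect_equal(s$frac_enriched + s$frac_depleted + s$frac_tied,
               rep(1, nrow(s)))
  expect_true(all(s$p_perm >= 0 & s$p_perm <= 1))
  expect_true(all(s$n_as_or_more <= plan$n_perms))
})

test_that("planted effects shift gene counts in opposite directions for columns and rows I", {
  sim <- small_sim(seed = 52, or = 2.5, causal = "pw001",
                   n_snps = 800, n_genes = 160)
  assoc <- run_association(sim$study, qc_thresholds())

  pc <- run_permutations(sim$study, sim$map, sim$pathways,
                         permutation_plan("columns", n_perms = 60, seed = 9))
  # shuffling labels destroys the planted signal: fewer significant genes
  expect_lt(mean(pc$runs$n_significant_genes), pc$n_sig_genes_original)

  # LD clusters significant SNPs in few genes; scattering them across SNPs
  # hits more genes
  pr <- run_permutations(assoc, sim$map, sim$pathways,
                         permutation_plan("rows_snp", n_perms = 60, seed = 9))
  expect_gt(mean(pr$runs$n_significant_genes), pr$n_sig_genes_original * 0.95)
})

test_that("enrich_deplete_fractions and the gene-count z-score compute as defined", {
  k <- matrix(c(2, 2, 2, 0, 1, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("even", "vary"), NULL))
  # h=10, i=4, g=5 -> expectation g*i/h = 2 for every run
  fr <- enrich_deplete_fractions(k, g = c(5, 5, 5), i = c(4, 4), h = 10)
  expect_equal(fr$frac_tied[fr$pathway == "even"], 1)
  expect_equal(fr$frac_enriched[fr$pathway == "vary"], 1 / 3)
  expect_equal(fr$frac_depleted[fr$pathway == "vary"], 2 / 3)
  expect_equal(fr$frac_tied[fr$pathway == "vary"], 0)
  expect_equal(fr$frac_enriched + fr$frac_depleted + fr$frac_tied, c(1, 1))
})

test_that("gene-count z-score matches its formula and flags degeneracy", {
  res <- gene_count_zscore(6226, c(5400, 5500, 5600))
  expect_equal(res$z, (6226 - 5500) / 100)
  expect_equal(res$z, 7.26)
  expect_equal(res$p, 2 * pnorm(-7.26))
  expect_lt(res$p, 1e-12)

  eq <- gene_count_zscore(10, c(9, 10, 11))
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # antisymmetry
  expect_equal(gene_count_zscore(5, c(7, 9, 11))$z,
               -gene_count_zscore(9, c(3, 5, 7))$z)
  expect_error(gene_count_zscore(5, c(3, 3, 3)),
               class = "permpath_input_error")
})

test_that("permutation-space combinatorics", {
  res <- count_case_control_permutations(x = 2, y = 2, z = 10, g_genes = 5)
  expect_equal(res$n_case_control, 6)          # 4!/(2!2!)
  expect_equal(res$log10_case_control, log10(6), tolerance = 1e-12)
  # symmetry C(x+y, y) = C(x+y, x)
  a <- count_case_control_permutations(x = 5, y = 9, z = 10, g_genes = 5)
  b <- count_case_control_permutations(x = 9, y = 5, z = 10, g_genes = 5)
  expect_equal(a$n_case_control, b$n_case_control)
  # z >> x + y: far more row permutations than column permutations
  gw <- count_case_control_permutations(x = 909, y = 2120, z = 5000,
                                        g_genes = 1000)
  expect_gt(gw$log10_snp_factorial, gw$log10_case_control)
  expect_gt(gw$log10_gene_factorial, gw$log10_case_control)
  expect_true(is.na(gw$n_case_control))        # beyond exact doubles
})
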