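test_that("hypergeometric tails match hand-enumerated values", {
  # h=10, i=5, g=4: C(5,4)C(5,0)/C(10,4) = 5/210 etc., enumerated by brute
  # force over all 210 significant-set placements
  expect_equal(hypergeom_enriched_p(4, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enriched_p(3, 5, 4, 10), 55 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_depleted_p(0, 5, 4, 10), 5 / 210, tolerance = 1e-12)
  expect_equal(enum_hyper_p(4, 5, 4, 10, "enriched"), 5 / 210)
  expect_equal(enum_hyper_p(3, 5, 4, 10, "enriched"), 55 / 210)

  expect_equal(hypergeom_enriched_p(0, 5, 4, 10), 1)   # whole support
  expect_equal(hypergeom_depleted_p(4, 5, 4, 10), 1)   # k = g <= i
  expect_error(hypergeom_enriched_p(5, 4, 4, 10),
               class = "permpath_input_error")
})

test_that("tails agree with exhaustive enumeration and phyper over random counts", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      h <- sample(4:14, 1)
      i <- sample(1:(h - 1), 1)
      g <- sample(1:(h - 1), 1)
      k <- sample(max(0, g - (h - i)):min(g, i), 1)
      pe <- hypergeom_enriched_p(k, i, g, h)
      pd <- hypergeom_depleted_p(k, i, g, h)
      expect_equal(pe, enum_hyper_p(k, i, g, h, "enriched"),
                   tolerance = 1e-12)
      expect_equal(pd, enum_hyper_p(k, i, g, h, "depleted"),
                   tolerance = 1e-12)
      # independent distribution-function cross-check
      expect_equal(pe, phyper(k - 1, i, h - i, g, lower.tail = FALSE),
                   tolerance = 1e-12)
      expect_equal(pd, phyper(k, i, h - i, g), tolerance = 1e-12)
      # tail complementarity: p_enr(k) + p_dep(k) - P(X = k) = 1
      expect_equal(pe + pd - dhyper(k, i, h - i, g), 1, tolerance = 1e-12)
    }
  })
})

test_that("log-space tails are stable for large universes", {
  p <- hypergeom_enriched_p(k = 120, i = 400, g = 2000, h = 1e5)
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_equal(p, phyper(119, 400, 1e5 - 400, 2000, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("BH adjustment reproduces hand-computed envelopes", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.04)), c(0.015, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.5, 0.5)), c(0.5, 0.5))
  p <- c(0.04, 0.01, 0.02, 0.03)   # order preserved
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "permpath_input_error")
})

test_that("GMT reader handles duplicates, errors and fgsea cross-check", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst\tA\tB\tC\tB", "pw2\tsecond\tC\tD"), path)
  db <- read_gmt(path)
  expect_identical(db$gene[db$pathway == "pw1"], c("A", "B", "C"))
  expect_identical(db$gene[db$pathway == "pw2"], c("C", "D"))

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst\tA", "broken_line"), bad)
  expect_error(read_gmt(bad), "line 2", class = "permpath_input_error")

  if (requireNamespace("fgsea", quietly = TRUE)) {
    ref <- fgsea::gmtPathways(path)
    expect_identical(lapply(split(db$gene, db$pathway), sort),
                     lapply(ref, function(g) sort(unique(g)))[names(ref)])
  }
})

test_that("restriction halves i when half the pathway leaves the universe", {
  db <- tibble::tibble(pathway = "pw", description = "d",
                       gene = paste0("g", 1:8))
  r <- restrict_pathways(db, paste0("g", 1:4))
  expect_identical(nrow(r), 4L)
})

test_that("run_ora applies the exclusion rule and both tails", {
  sig <- tibble::tibble(gene = paste0("g", 1:10),
                        n_snps = 1L, n_sig_snps = c(rep(1L, 4), rep(0L, 6)),
                        min_p = 0.01, significant = c(rep(TRUE, 4), rep(FALSE, 6)))
  db <- tibble::tibble(
    pathway = c(rep("big", 5), "tiny", rep("other", 3)),
    description = "d",
    gene = c(paste0("g", 1:5), "g1", paste0("g", 8:10)))
  res <- run_ora(sig, db)
  expect_true(res$excluded[res$pathway == "tiny"])
  expect_match(res$reason[res$pathway == "tiny"], "fewer than 2 universe")
  expect_true(is.na(res$p_enriched[res$pathway == "tiny"]))
  # enriched p for "big": k=4, i=5, g=4, h=10 -> 5/210
  expect_equal(res$p_enriched[res$pathway == "big"], 5 / 210,
               tolerance = 1e-12)
  expect_true(all(res$q_enriched >= res$p_enriched, na.rm = TRUE))

  # k-based exclusion variant
  res_k <- run_ora(sig, db, exclude_on = "significant")
  expect_true(res_k$excluded[res_k$pathway == "other"])  # k = 0 there

  # empty significant set: every enrichment p is 1
  sig0 <- sig; sig0$significant <- FALSE; sig0$n_sig_snps <- 0L
  expect_warning(res0 <- run_ora(sig0, db), "empty significant")
  expect_true(all(res0$p_enriched[!res0$excluded] == 1))

  # pure function: identical inputs -> identical results
  expect_identical(as.data.frame(run_ora(sig, db)), as.data.frame(res))
})

test_that("random small instances match the exhaustive placement oracle", {
  withr::with_seed(7, {
    for (rep in 1:10) {
      h <- sample(6:12, 1)
      genes <- paste0("g", seq_len(h))
      g <- sample(2:(h - 2), 1)
      sig_genes <- sample(genes, g)
      sig <- tibble::tibble(gene = genes, n_snps = 1L,
                            n_sig_snps = as.integer(genes %in% sig_genes),
                            min_p = 0.5,
                            significant = genes %in% sig_genes)
      i <- sample(2:(h - 1), 1)
      db <- tibble::tibble(pathway = "pw", description = "d",
                           gene = genes[seq_len(i)])
      res <- run_ora(sig, db)
      k <- sum(sig_genes %in% genes[seq_len(i)])
      expect_equal(res$p_enriched, enum_hyper_p(k, i, g, h, "enriched"),
                   tolerance = 1e-12)
      expect_equal(res$p_depleted, enum_hyper_p(k, i, g, h, "depleted"),
                   tolerance = 1e-12)
    }
  })
})

test_that("overlap re-test reports intersections and weakens shared signals", {
  # disjoint pathways: empty intersections, re-test identical
  sig <- tibble::tibble(gene = paste0("g", 1:12), n_snps = 1L,
                        n_sig_snps = as.integer(1:12 <= 4), min_p = 0.5,
                        significant = 1:12 <= 4)
  db <- tibble::tibble(pathway = rep(c("a", "b"), each = 4),
                       description = "d",
                       gene = paste0("g", 1:8))
  rt <- pathway_overlap_retest(sig, db, c("a", "b"), mode = "shared")
  expect_identical(rt$shared$n_shared, 0L)
  expect_identical(as.data.frame(rt$ora), as.data.frame(run_ora(sig, db)))

  # full containment: the intersection is the smaller set
  db2 <- dplyr::bind_rows(db,
    tibble::tibble(pathway = "sub", description = "d", gene = paste0("g", 1:2)))
  rt2 <- pathway_overlap_retest(sig, db2, c("a", "sub"), mode = "shared")
  expect_identical(sort(unlist(rt2$shared$genes)), c("g1", "g2"))

  expect_error(pathway_overlap_retest(sig, db, "nope"),
               class = "permpath_input_error")

  # shared significant genes carry both pathways: removing them raises both p's
  db3 <- tibble::tibble(
    pathway = rep(c("x", "y"), each = 5), description = "d",
    gene = c("g1", "g2", "g5", "g6", "g7", "g1", "g2", "g8", "g9", "g10"))
  base <- run_ora(sig, db3)
  rt3 <- pathway_overlap_retest(sig, db3, c("x", "y"), mode = "shared")
  for (pw in c("x", "y"))
    expect_gt(rt3$ora$p_enriched[rt3$ora$pathway == pw],
              base$p_enriched[base$pathway == pw])

  # remove_all: the named pathways disappear and their genes leave the universe
  rt4 <- pathway_overlap_retest(sig, db3, "x", mode = "remove_all")
  expect_false("x" %in% rt4$ora$pathway)
  expect_lt(rt4$ora$h[1], base$h[1])
})
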