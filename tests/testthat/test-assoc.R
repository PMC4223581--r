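test_that("QC statistics match hand-computed values", {
  G <- cbind(
    all_het = rep(1L, 100),
    hwe_exact = rep(c(0L, 1L, 2L), c(25, 50, 25)),
    hwe_extreme = rep(c(0L, 1L, 2L), c(50, 0, 50))
  )
  rownames(G) <- paste0("s", 1:100)
  study <- gwas_study(G, phenotype = rep(0L, 100))
  qc <- snp_qc_stats(study)
  expect_equal(qc$call_rate, rep(1, 3))
  expect_equal(qc$maf, rep(0.5, 3))
  # exact HWE proportions: chi2 = 0, p = 1
  expect_equal(qc$hwe_p_controls[qc$snp_id == "hwe_exact"], 1)
  # (50-25)^2/25 + (0-50)^2/50 + (50-25)^2/25 = 100
  expect_equal(qc$hwe_p_controls[qc$snp_id == "hwe_extreme"],
               pchisq(100, 1, lower.tail = FALSE))
  expect_lt(qc$hwe_p_controls[qc$snp_id == "hwe_extreme"], 2e-23)
})

test_that("in-package HWE test agrees with chisq.test on a fixture", {
  g <- rep(c(0L, 1L, 2L), c(30, 45, 25))
  p_hat <- (45 + 2 * 25) / 200
  expected <- c((1 - p_hat)^2, 2 * p_hat * (1 - p_hat), p_hat^2)
  ref <- suppressWarnings(
    stats::chisq.test(c(30, 45, 25), p = expected))
  ours <- permpath:::hwe_chisq_p(matrix(g, ncol = 1))
  # chisq.test computes the statistic independently; one df is lost to the
  # estimated allele frequency, hence the df = 1 tail
  expect_equal(ours, pchisq(unname(ref$statistic), df = 1,
                            lower.tail = FALSE), tolerance = 1e-12)
})

test_that("QC filter applies every exclusion rule and is idempotent", {
  qc <- tibble::tibble(
    snp_id = c("ok", "low_maf", "low_call", "call_boundary", "hwe_ctrl",
               "hwe_case", "all_missing"),
    maf = c(0.3, 0.02, 0.3, 0.3, 0.3, 0.3, NA),
    call_rate = c(1, 1, 0.9, 0.95, 1, 1, 0),
    hwe_p_controls = c(0.5, 0.5, 0.5, 0.5, 0.01, 0.5, NA),
    hwe_p_cases = c(0.5, 0.5, 0.5, 0.5, 0.5, 1e-4, NA))
  thr <- qc_thresholds(maf_min = 0.03, call_rate_min = 0.95,
                       hwe_alpha_controls = 0.05, hwe_alpha_cases = 0.001)
  kept <- qc_filter(qc, thr)
  # the call-rate boundary (exactly 95%) is excluded too
  expect_identical(kept, "ok")
  expect_identical(qc_filter(qc[qc$snp_id %in% kept, ], thr), kept)

  # disabling the cases rule readmits the case-HWE failure
  thr2 <- qc_thresholds(hwe_alpha_cases = NA)
  expect_true("hwe_case" %in% qc_filter(qc, thr2))
  # all passing -> identity
  expect_identical(qc_filter(qc[1, ], thr), "ok")
})

test_that("trend test matches hand values and degenerate cases", {
  res <- trend_test(c(2, 2, 2, 2, 0, 0, 0, 0), c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(res$chi2, 8)                       # N * r^2 with r = 1
  expect_equal(res$p, pchisq(8, 1, lower.tail = FALSE))
  expect_equal(res$p, 0.004678, tolerance = 1e-4)

  # identical genotype distributions in cases and controls
  same <- trend_test(c(0, 1, 2, 0, 1, 2), c(1, 1, 1, 0, 0, 0))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  # label-code swap invariance (two-sided 1-df statistic)
  g <- c(0, 1, 2, 2, 1, 0, 1, 2)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  expect_equal(trend_test(g, y)$chi2, trend_test(g, 1 - y)$chi2)

  expect_error(trend_test(c(NA, NA), c(1, 0)), class = "permpath_error")
})

test_that("asymptotic trend p tracks the exact label-permutation null at small n", {
  # the exact conditional null of N*r^2 is very discrete at n = 12, so the
  # continuous chi-square p is compared against the exact mid-p (half
  # weight on ties); ordering must agree with the plain exact p
  withr::with_seed(31, {
    res <- t(replicate(30, {
      repeat {
        g <- rbinom(12, 2, 0.5)
        if (all(table(factor(g, 0:2)) >= 2)) break
      }
      y <- rep(c(1L, 0L), each = 6)
      c(asym = trend_test(g, y)$p,
        exact = exact_trend_perm_p(g, y),
        mid = exact_trend_perm_p(g, y, mid = TRUE))
    }))
  })
  diffs <- abs(res[, "asym"] - res[, "mid"])
  expect_lt(max(diffs), 0.2)
  expect_lt(mean(diffs), 0.08)
  expect_gt(cor(res[, "asym"], res[, "exact"], method = "spearman"), 0.9)
})

test_that("logistic association agrees with the trend test and flags degeneracy", {
  sim <- small_sim(seed = 23, or = 2, causal = "pw001")
  snp <- sim$truth$causal_snps[1]
  g <- sim$study$genotypes[, snp]
  y <- sim$study$phenotype
  tt <- trend_test(g, y)
  lg <- logistic_assoc(g, y)
  expect_lt(abs(lg$chi2 - tt$chi2) / tt$chi2, 0.10)
  # likelihood-ratio flavour close to Wald at this n
  lrt <- logistic_assoc(g, y, method = "lrt")
  expect_lt(abs(lrt$chi2 - lg$chi2) / lg$chi2, 0.15)

  expect_equal(logistic_assoc(rep(1, 8), c(1, 1, 1, 1, 0, 0, 0, 0))$p, 1)
  # covariate perfectly predicting the phenotype -> separation
  expect_error(
    logistic_assoc(c(0, 1, 2, 0, 1, 2, 1, 0), c(1, 1, 1, 1, 0, 0, 0, 0),
                   covariates = data.frame(x = c(1, 1, 1, 1, 0, 0, 0, 0))),
    class = "permpath_separation_error")
})

test_that("genomic control scales chi-squares by the clamped median ratio", {
  m1 <- qchisq(0.5, 1)
  # all chi2 at the null median -> lambda 1, p_gc = p_raw
  a <- tibble::tibble(chi2 = rep(m1, 5),
                      p_raw = pchisq(rep(m1, 5), 1, lower.tail = FALSE))
  a1 <- genomic_control(a)
  expect_equal(attr(a1, "lambda_gc"), 1)
  expect_equal(a1$p_gc, a1$p_raw)

  # median chi2 = 2 * m1 -> lambda 2; a chi2 of 8 becomes 4
  b <- tibble::tibble(chi2 = c(2 * m1, 2 * m1, 2 * m1, 8))
  b1 <- genomic_control(b)
  expect_equal(attr(b1, "lambda_gc"), 2)
  expect_equal(b1$p_gc[4], pchisq(4, 1, lower.tail = FALSE))
  expect_equal(b1$p_gc[4], 0.0455, tolerance = 1e-3)

  # deflation clamp: lambda never below 1
  c1 <- genomic_control(tibble::tibble(chi2 = rep(0.1, 5)))
  expect_equal(attr(c1, "lambda_gc"), 1)
})

test_that("run_association composes the stages deterministically", {
  study <- toy_study()
  thr <- qc_thresholds(maf_min = 0, call_rate_min = 0,
                       hwe_alpha_controls = NA, hwe_alpha_cases = NA)
  a <- run_association(study, thr, apply_gc = FALSE)
  expect_identical(a$snp_id, study$snp_ids)
  expect_equal(a$p_raw[a$snp_id == "snp3"], 1)  # constant SNP
  expect_equal(a$p_raw[a$snp_id == "snp4"], 1)  # identical groups
  expect_lt(a$p_raw[a$snp_id == "snp1"], 0.01)
  b <- run_association(study, thr, apply_gc = FALSE)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # p_gc >= p_raw whenever lambda > 1
  sim <- small_sim(seed = 88, or = 2, causal = "pw001")
  ga <- run_association(sim$study, qc_thresholds())
  if (attr(ga, "lambda_gc") > 1) expect_true(all(ga$p_gc >= ga$p_raw))
  expect_true(all(ga$p_raw >= 0 & ga$p_raw <= 1))
  expect_true(all(ga$p_gc >= 0 & ga$p_gc <= 1))
})

test_that("null per-SNP rejection rates sit at their nominal levels", {
  sim <- small_sim(seed = 91, or = 1, n_snps = 1000, n_genes = 200)
  a <- run_association(sim$study, qc_thresholds())
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(a$p_gc < alpha)
    expect_lt(abs(frac - alpha),
              3 * sqrt(alpha * (1 - alpha) / nrow(a)) + 0.005)
  }
})
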