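# Per-SNP quality control, 1-df association tests and genomic control.

#' Quality-control thresholds for SNP filtering
#'
#' Defaults follow a typical case-control screen: minor allele frequency
#' below 3%, call rate at or below 95%, or Hardy-Weinberg deviation at
#' level 0.05 in controls / 0.001 in cases excludes a SNP. Set
#' `hwe_alpha_cases = NA` to disable the case-stratum rule (as in designs
#' that test HWE in controls only).
#'
#' @param maf_min Minimum minor allele frequency (strict: `maf < maf_min`
#'   is removed).
#' @param call_rate_min Call-rate bound; SNPs with `call_rate <=
#'   call_rate_min` are removed (the boundary itself is excluded).
#' @param hwe_alpha_controls,hwe_alpha_cases Hardy-Weinberg significance
#'   levels per phenotype stratum; `NA` disables a stratum.
#' @return A list of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(maf_min = 0.03, call_rate_min = 0.95,
                          hwe_alpha_controls = 0.05,
                          hwe_alpha_cases = 0.001) {
  for (v in c(maf_min, call_rate_min))
    if (!is_prob(v)) stop_config("QC thresholds must lie in [0, 1]")
  for (v in c(hwe_alpha_controls, hwe_alpha_cases))
    if (!is.na(v) && !is_prob(v)) stop_config("QC thresholds must lie in [0, 1]")
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min,
                 hwe_alpha_controls = hwe_alpha_controls,
                 hwe_alpha_cases = hwe_alpha_cases),
            class = "qc_thresholds")
}

#' Per-SNP QC statistics
#'
#' Computes, per SNP: call rate (fraction of non-missing genotypes), minor
#' allele frequency among non-missing genotypes, and a 1-df chi-square
#' Hardy-Weinberg goodness-of-fit p-value in each phenotype stratum. A SNP
#' with all genotypes missing gets call rate 0 and undefined (NA) MAF and
#' HWE p-values. Without a phenotype the pooled HWE p is reported in the
#' controls column and the cases column is NA.
#'
#' @param study A [gwas_study()].
#' @return A tibble with columns `snp_id`, `maf`, `call_rate`,
#'   `hwe_p_controls`, `hwe_p_cases`.
#' @export
snp_qc_stats <- function(study) {
  G <- study$genotypes
  call_rate <- colMeans(!is.na(G))
  f <- colMeans(G, na.rm = TRUE) / 2
  f[is.nan(f)] <- NA_real_
  maf <- pmin(f, 1 - f)
  if (!is.null(study$phenotype)) {
    hwe_ctrl <- hwe_chisq_p(G[study$phenotype == 0L, , drop = FALSE])
    hwe_case <- hwe_chisq_p(G[study$phenotype == 1L, , drop = FALSE])
  } else {
    hwe_ctrl <- hwe_chisq_p(G)
    hwe_case <- rep(NA_real_, ncol(G))
  }
  tibble(snp_id = study$snp_ids, maf = unname(maf),
         call_rate = unname(call_rate),
         hwe_p_controls = hwe_ctrl, hwe_p_cases = hwe_case)
}

# Vectorised 1-df chi-square HWE goodness-of-fit across the columns of a
# genotype matrix. Expected counts n*( (1-p)^2, 2p(1-p), p^2 ) with p the
# observed allele frequency; cells with zero expectation contribute zero
# (they can only pair with zero observed counts). All-missing -> NA.
hwe_chisq_p <- function(G) {
  n0 <- colSums(G == 0L, na.rm = TRUE)
  n1 <- colSums(G == 1L, na.rm = TRUE)
  n2 <- colSums(G == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  cell <- function(obs, exp) ifelse(exp > 0, (obs - exp)^2 / exp, 0)
  chi2 <- cell(n0, e0) + cell(n1, e1) + cell(n2, e2)
  out <- pchisq(chi2, df = 1, lower.tail = FALSE)
  out[n == 0L] <- NA_real_
  unname(out)
}

#' Filter SNPs on QC thresholds
#'
#' A SNP is removed iff `maf < maf_min`, or `call_rate <= call_rate_min`,
#' or `hwe_p_controls < hwe_alpha_controls`, or (when the cases rule is
#' enabled) `hwe_p_cases < hwe_alpha_cases`. Undefined HWE p-values do not
#' remove a SNP (such SNPs are typically monomorphic or fully missing and
#' caught by the MAF/call-rate rules). Input order is preserved and the
#' filter is idempotent.
#'
#' @param qc Tibble from [snp_qc_stats()].
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of retained SNP ids.
#' @export
qc_filter <- function(qc, thresholds = qc_thresholds()) {
  t <- thresholds
  drop <- coalesce(qc$maf < t$maf_min, TRUE) |
    qc$call_rate <= t$call_rate_min
  if (!is.na(t$hwe_alpha_controls))
    drop <- drop | coalesce(qc$hwe_p_controls < t$hwe_alpha_controls, FALSE)
  if (!is.na(t$hwe_alpha_cases))
    drop <- drop | coalesce(qc$hwe_p_cases < t$hwe_alpha_cases, FALSE)
  qc$snp_id[!drop]
}

#' Cochran-Armitage trend test (additive 1-df model)
#'
#' The trend statistic with additive weights (0, 1, 2) computed through the
#' identity `chi2 = N * r^2`, where `r` is the Pearson correlation between
#' genotype and the binary phenotype over non-missing samples; the p-value
#' is the 1-df chi-square upper tail. A genotype column with zero variance
#' gives `chi2 = 0`, `p = 1`.
#'
#' @param genotype Vector of genotypes in {0, 1, 2, NA}.
#' @param phenotype Binary vector (1 = case, 0 = control).
#' @return A list with elements `chi2` and `p`.
#' @export
#' @examples
#' trend_test(c(2, 2, 2, 2, 0, 0, 0, 0), c(1, 1, 1, 1, 0, 0, 0, 0))
trend_test <- function(genotype, phenotype) {
  ok <- !is.na(genotype) & !is.na(phenotype)
  g <- genotype[ok]; y <- phenotype[ok]
  if (length(g) == 0L)
    stop_input("all genotypes missing: trend test undefined")
  if (length(unique(y)) < 2L)
    stop_input("trend test needs at least one case and one control among non-missing samples")
  if (var(g) == 0) return(list(chi2 = 0, p = 1))
  r <- cor(g, y)
  chi2 <- length(g) * r^2
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Vectorised trend statistics for a genotype matrix G (samples x SNPs, NA
# allowed) against one or many binary phenotype vectors Y (samples x
# permutations). Returns a SNPs x permutations chi-square matrix. Built on
# the per-SNP sufficient statistics so a whole permutation battery is two
# crossprod() calls.
trend_chi2_matrix <- function(G, Y) {
  Y <- as.matrix(Y)
  M <- !is.na(G)
  Z <- G; Z[!M] <- 0L
  storage.mode(Z) <- "double"; storage.mode(M) <- "double"
  nj <- colSums(M)
  sx <- colSums(Z)
  sxx <- colSums(Z^2)
  sxy <- crossprod(Z, Y)                      # SNPs x perms
  sy <- if (all(M == 1)) {
    matrix(colSums(Y), nrow = ncol(G), ncol = ncol(Y), byrow = TRUE)
  } else {
    crossprod(M, Y)
  }
  num <- nj * sxy - sx * sy
  den2 <- (nj * sxx - sx^2) * (nj * sy - sy^2)  # y binary: sum(y^2) = sum(y)
  chi2 <- ifelse(den2 > 0, nj * num^2 / den2, 0)
  chi2[nj == 0, ] <- NA_real_
  chi2
}

#' Covariate-adjusted logistic association test
#'
#' Tests the additive-coded genotype effect in a logistic regression with
#' optional covariates, by a 1-df Wald test (default) or likelihood-ratio
#' test. Without covariates it agrees asymptotically with [trend_test()].
#' Complete separation or non-convergence raises a classed error
#' (`permpath_separation_error` / `permpath_convergence_error`); callers
#' such as [run_association()] catch it and drop the SNP.
#'
#' @param genotype Vector of genotypes in {0, 1, 2, NA}.
#' @param phenotype Binary vector (1 = case, 0 = control).
#' @param covariates Optional data frame of per-sample covariates.
#' @param method `"wald"` or `"lrt"`.
#' @return A list with elements `chi2` and `p`.
#' @export
logistic_assoc <- function(genotype, phenotype, covariates = NULL,
                           method = c("wald", "lrt")) {
  method <- match.arg(method)
  df <- data.frame(y = phenotype, g = genotype)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  if (length(unique(df$y)) < 2L)
    stop_input("logistic test needs at least one case and one control")
  if (var(df$g) == 0) return(list(chi2 = 0, p = 1))

  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  # glm does not always warn on separation; boundary fitted probabilities
  # are the reliable symptom
  if (separated || any(fit$fitted.values > 1 - 1e-8) ||
      any(fit$fitted.values < 1e-8))
    pp_stop("complete or quasi-complete separation in logistic model",
            "permpath_separation_error")
  if (!fit$converged)
    pp_stop("logistic model did not converge", "permpath_convergence_error")
  if (method == "wald") {
    est <- summary(fit)$coefficients["g", ]
    chi2 <- unname((est["Estimate"] / est["Std. Error"])^2)
  } else {
    fit0 <- glm(y ~ . - g, data = df, family = binomial())
    chi2 <- fit0$deviance - fit$deviance
  }
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Genomic-control correction
#'
#' The genomic inflation factor is the median of the per-SNP 1-df
#' chi-square statistics divided by the 1-df chi-square median
#' (about 0.4549), clamped below at 1 (deflation of test statistics only,
#' the standard convention). Adjusted p-values are the 1-df upper tail of
#' `chi2 / lambda`.
#'
#' @param assoc Tibble with a `chi2` column (and anything else, preserved).
#' @return The input with a `p_gc` column added/overwritten and the
#'   inflation factor stored in attribute `"lambda_gc"`.
#' @export
genomic_control <- function(assoc) {
  chi2 <- assoc$chi2
  if (all(is.na(chi2)))
    stop_input("genomic control needs at least one SNP with a defined chi2")
  lambda <- max(1, median(chi2, na.rm = TRUE) / CHISQ1_MEDIAN)
  assoc$p_gc <- pchisq(chi2 / lambda, df = 1, lower.tail = FALSE)
  attr(assoc, "lambda_gc") <- lambda
  assoc
}

#' Run the per-SNP association stage
#'
#' QC statistics, threshold filtering, the per-SNP 1-df association test
#' (fast trend test or covariate-adjusted logistic regression) and optional
#' genomic control, composed into the SNP association table consumed by
#' gene mapping and by the permutation engine. Deterministic given its
#' inputs. Logistic fits that separate or fail to converge are dropped with
#' a warning.
#'
#' @param study A [gwas_study()] with phenotype set.
#' @param thresholds A [qc_thresholds()].
#' @param test `"trend"` (default; no covariates, vectorised) or
#'   `"logistic"` (uses `study$covariates` when present).
#' @param apply_gc Apply genomic control? When `FALSE`, `p_gc` equals
#'   `p_raw` and `lambda_gc` is recorded as 1.
#' @return A tibble of class `"snp_assoc"` with columns `snp_id`, `maf`,
#'   `call_rate`, `hwe_p_controls`, `hwe_p_cases`, `chi2`, `p_raw`, `p_gc`,
#'   one row per retained SNP, and attributes `lambda_gc`, `test_kind`,
#'   `thresholds`, `n_removed_qc`, `n_dropped_fit`.
#' @export
run_association <- function(study, thresholds = qc_thresholds(),
                            test = c("trend", "logistic"),
                            apply_gc = TRUE) {
  test <- match.arg(test)
  if (is.null(study$phenotype))
    stop_input("`study` has no phenotype; association testing needs case-control labels")
  qc <- snp_qc_stats(study)
  keep <- qc_filter(qc, thresholds)
  if (length(keep) == 0L)
    stop_runtime("zero SNPs survive QC filtering")
  qc <- qc[match(keep, qc$snp_id), ]
  G <- study$genotypes[, keep, drop = FALSE]
  y <- study$phenotype

  if (test == "trend") {
    chi2 <- as.numeric(trend_chi2_matrix(G, matrix(y, ncol = 1)))
    n_dropped <- 0L
  } else {
    res <- purrr::map(seq_along(keep), function(j) {
      tryCatch(logistic_assoc(G[, j], y, study$covariates),
               permpath_error = function(e) list(chi2 = NA_real_, p = NA_real_))
    })
    chi2 <- purrr::map_dbl(res, "chi2")
    n_dropped <- sum(is.na(chi2))
    if (n_dropped > 0L)
      rlang::warn(paste0(n_dropped, " SNP(s) dropped: logistic fit separated or failed to converge"))
  }
  out <- qc
  out$chi2 <- chi2
  out$p_raw <- pchisq(chi2, df = 1, lower.tail = FALSE)
  out <- out[!is.na(out$chi2), , drop = FALSE]
  if (nrow(out) == 0L)
    stop_runtime("zero SNPs with a defined association statistic")
  if (apply_gc) {
    out <- genomic_control(out)
  } else {
    out$p_gc <- out$p_raw
    attr(out, "lambda_gc") <- 1
  }
  attr(out, "test_kind") <- test
  attr(out, "thresholds") <- thresholds
  attr(out, "n_removed_qc") <- length(study$snp_ids) - length(keep)
  attr(out, "n_dropped_fit") <- n_dropped
  class(out) <- c("snp_assoc", class(tibble()))
  out
}

#' @exportS3Method generics::glance
glance.snp_assoc <- function(x, ...) {
  tibble(n_snps = nrow(x),
         n_removed_qc = attr(x, "n_removed_qc") %||% NA_integer_,
         lambda_gc = attr(x, "lambda_gc") %||% NA_real_,
         test_kind = attr(x, "test_kind") %||% NA_character_,
         min_p_gc = min(x$p_gc, na.rm = TRUE))
}
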