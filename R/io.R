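# Plain-text readers and writers for the formats the pipeline exchanges:
# GMT gene sets, transposed genotype TSV, SNP-to-gene map TSV, association
# TSV and PLINK-style .ped/.map.

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one pathway per line as
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`. Duplicate genes
#' within a line are de-duplicated on read; a line with fewer than three
#' fields raises a parse error naming the line number.
#'
#' @param path File path.
#' @return `read_gmt()`: a pathway tibble (`pathway`, `description`,
#'   `gene`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop_input(paste0("malformed GMT line ", bad[1],
                      ": fewer than 3 tab-separated fields"))
  purrr::map_dfr(parts, function(f) {
    tibble(pathway = f[1], description = f[2],
           gene = unique(f[-(1:2)]))
  })
}

#' @param db Pathway tibble (`pathway`, `gene`, optional `description`).
#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  desc <- if ("description" %in% names(db)) db$description else ""
  split_genes <- split(db$gene, db$pathway)
  split_desc <- vapply(split(desc, db$pathway), `[`, character(1), 1)
  ids <- unique(db$pathway)      # preserve first-appearance order
  lines <- vapply(ids, function(p) {
    paste(c(p, split_desc[[p]], unique(split_genes[[p]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a genotype study as transposed TSV
#'
#' Rows are SNPs, columns samples, with a header row of sample ids. The
#' phenotype occupies a leading pseudo-row named `__phenotype__` (empty
#' when unset); covariates, when present, follow as `__covar_<name>__`
#' rows. Missing genotypes are written as `NA`.
#'
#' @param study A [gwas_study()].
#' @param path File path.
#' @export
write_genotype_tsv <- function(study, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("snp_id", study$sample_ids), collapse = "\t"), con)
  if (!is.null(study$phenotype))
    writeLines(paste(c("__phenotype__", study$phenotype), collapse = "\t"),
               con)
  if (!is.null(study$covariates)) {
    for (nm in names(study$covariates))
      writeLines(paste(c(paste0("__covar_", nm, "__"),
                         study$covariates[[nm]]), collapse = "\t"), con)
  }
  utils::write.table(t(study$genotypes), con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @return `read_genotype_tsv()`: a [gwas_study()].
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sample_ids <- fields[[1]][-1]
  body <- fields[-1]
  keys <- vapply(body, `[`, character(1), 1)
  pheno <- NULL
  covs <- list()
  snp_rows <- list()
  for (r in seq_along(body)) {
    key <- keys[r]
    vals <- body[[r]][-1]
    if (key == "__phenotype__") {
      pheno <- as.integer(vals)
    } else if (grepl("^__covar_.*__$", key)) {
      nm <- sub("^__covar_(.*)__$", "\\1", key)
      covs[[nm]] <- utils::type.convert(vals, as.is = TRUE)
    } else {
      snp_rows[[key]] <- suppressWarnings(as.integer(vals))
    }
  }
  G <- do.call(cbind, snp_rows)
  rownames(G) <- sample_ids
  gwas_study(G, phenotype = pheno,
             covariates = if (length(covs)) as_tibble(covs) else NULL)
}

#' Read and write a SNP-to-gene map TSV
#'
#' Two tab-separated columns, `snp_id` and `gene_id`, one row per mapping
#' (multi-gene SNPs appear on several rows).
#'
#' @param map Map tibble.
#' @param path File path.
#' @export
write_snp_gene_map <- function(map, path) {
  readr::write_tsv(map[, c("snp_id", "gene_id")], path)
  invisible(path)
}

#' @rdname write_snp_gene_map
#' @export
read_snp_gene_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), gene_id = readr::col_character()))
  if (!all(c("snp_id", "gene_id") %in% names(m)))
    stop_input("map TSV needs columns `snp_id` and `gene_id`")
  m
}

#' Write an association table as TSV
#'
#' Writes the per-SNP table with a leading comment line recording the
#' genomic inflation factor, test kind and QC thresholds.
#'
#' @param assoc A [run_association()] result.
#' @param path File path.
#' @export
write_assoc_tsv <- function(assoc, path) {
  t <- attr(assoc, "thresholds")
  hdr <- sprintf(
    "# lambda_gc=%.6g test_kind=%s maf_min=%s call_rate_min=%s hwe_alpha_controls=%s hwe_alpha_cases=%s",
    attr(assoc, "lambda_gc") %||% NA,
    attr(assoc, "test_kind") %||% "NA",
    t$maf_min %||% NA, t$call_rate_min %||% NA,
    t$hwe_alpha_controls %||% NA, t$hwe_alpha_cases %||% NA)
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(assoc), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    snp_id = readr::col_character(), .default = readr::col_double()))
}

#' Write a study as PLINK-style .ped/.map text files
#'
#' Minimal PLINK classic text export: the `.ped` file carries family/
#' individual ids, dummy parents, sex (from a `sex` covariate when
#' present), phenotype coded 1 = control / 2 = case, and two allele
#' columns per SNP with alleles `A` (major) and `B` (minor), `0 0` for
#' missing. The `.map` file lists `chr snp_id 0 position` with synthetic
#' positions. Genomic coordinates are not modelled, so the map is
#' placeholder only.
#'
#' @param study A [gwas_study()].
#' @param prefix Path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @export
write_ped_map <- function(study, prefix) {
  G <- study$genotypes
  alleles <- c("A A", "A B", "B B")
  geno_chr <- matrix("0 0", nrow = nrow(G), ncol = ncol(G))
  ok <- !is.na(G)
  geno_chr[ok] <- alleles[G[ok] + 1L]
  sex <- if (!is.null(study$covariates) && "sex" %in% names(study$covariates))
    study$covariates$sex + 1L else rep(0L, nrow(G))
  pheno <- if (is.null(study$phenotype)) rep(0L, nrow(G))
           else study$phenotype + 1L
  ped <- cbind(study$sample_ids, study$sample_ids, "0", "0", sex, pheno,
               geno_chr)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  map <- cbind("1", study$snp_ids, "0", seq_along(study$snp_ids))
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_ped_map
#' @export
read_ped_map <- function(prefix) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           colClasses = "character")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = " ",
                           colClasses = "character")
  snps <- map[[2]]
  n_snp <- length(snps)
  # two allele columns per SNP after the 6 leading fields
  code_pair <- function(a1, a2) {
    out <- rep(NA_integer_, length(a1))
    known <- a1 != "0" & a2 != "0"
    out[known] <- (a1[known] == "B") + (a2[known] == "B")
    out
  }
  G <- vapply(seq_len(n_snp), function(j) {
    code_pair(ped[[6 + 2 * j - 1]], ped[[6 + 2 * j]])
  }, integer(nrow(ped)))
  if (is.null(dim(G))) G <- matrix(G, nrow = nrow(ped))
  rownames(G) <- ped[[2]]
  colnames(G) <- snps
  pheno_raw <- as.integer(ped[[6]])
  pheno <- if (all(pheno_raw %in% c(1L, 2L))) pheno_raw - 1L else NULL
  gwas_study(G, phenotype = pheno)
}
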