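# Hypergeometric over-representation analysis: exact enrichment and
# depletion tails, BH adjustment, the small-pathway exclusion rule and the
# overlap-gene re-test.

# Scalar log-space tail sums. With g significant genes among h, and i of
# the h on the pathway, the enriched tail is
#   sum_{j = k}^{min(g, i)} C(i, j) C(h - i, g - j) / C(h, g)
# and the depleted tail runs j = max(0, g - (h - i)) .. k. Terms outside
# the support have C(i, j) = 0 and drop out of the log-space sum.
hyper_tail_log <- function(j, i, g, h) {
  lchoose(i, j) + lchoose(h - i, g - j) - lchoose(h, g)
}

hyper_enriched_one <- function(k, i, g, h) {
  lo <- max(k, 0, g - (h - i))
  hi <- min(g, i)
  if (lo > hi) return(0)
  min(exp(log_sum_exp(hyper_tail_log(lo:hi, i, g, h))), 1)
}

hyper_depleted_one <- function(k, i, g, h) {
  lo <- max(0, g - (h - i))
  hi <- min(k, g, i)
  if (hi < lo) return(0)
  min(exp(log_sum_exp(hyper_tail_log(lo:hi, i, g, h))), 1)
}

check_ora_counts <- function(k, i, g, h) {
  bad <- is.na(k) | is.na(i) | is.na(g) | is.na(h) |
    k < 0 | k > pmin(g, i) | i > h | g > h | i < 0 | g < 0 | h < 1
  if (any(bad))
    stop_input("invalid over-representation counts: need 0 <= k <= min(g, i), i <= h, g <= h")
}

#' Exact hypergeometric enrichment and depletion p-values
#'
#' For a universe of `h` genes of which `i` lie on the pathway, and `g`
#' significant genes of which `k` lie on the pathway, the enrichment
#' p-value is the upper hypergeometric tail P(X >= k) and the depletion
#' p-value the lower tail P(X <= k). Tail sums are computed in log space
#' (numerically stable for universes up to ~1e5 genes). All four arguments
#' are recycled to a common length.
#'
#' @param k Significant genes on the pathway.
#' @param i Universe genes on the pathway.
#' @param g Significant genes in the universe.
#' @param h Universe size.
#' @return Numeric vector of p-values in [0, 1].
#' @export
#' @examples
#' hypergeom_enriched_p(k = 4, i = 5, g = 4, h = 10)  # 5/210
#' hypergeom_depleted_p(k = 0, i = 5, g = 4, h = 10)  # 5/210
hypergeom_enriched_p <- function(k, i, g, h) {
  n <- max(length(k), length(i), length(g), length(h))
  k <- rep_len(k, n); i <- rep_len(i, n)
  g <- rep_len(g, n); h <- rep_len(h, n)
  check_ora_counts(k, i, g, h)
  vapply(seq_len(n),
         function(t) hyper_enriched_one(k[t], i[t], g[t], h[t]),
         numeric(1))
}

#' @rdname hypergeom_enriched_p
#' @export
hypergeom_depleted_p <- function(k, i, g, h) {
  n <- max(length(k), length(i), length(g), length(h))
  k <- rep_len(k, n); i <- rep_len(i, n)
  g <- rep_len(g, n); h <- rep_len(h, n)
  check_ora_counts(k, i, g, h)
  vapply(seq_len(n),
         function(t) hyper_depleted_one(k[t], i[t], g[t], h[t]),
         numeric(1))
}

# Fast path for the permutation engine: matrix of k values (pathways x
# runs), per-pathway i, per-run g, scalar h. No recycling checks; inputs
# come from internal counting and are valid by construction.
hyper_p_matrix <- function(K, i_vec, g_vec, h, tail) {
  fun <- if (tail == "enriched") hyper_enriched_one else hyper_depleted_one
  out <- matrix(NA_real_, nrow = nrow(K), ncol = ncol(K))
  for (r in seq_len(nrow(K))) {
    ir <- i_vec[r]
    out[r, ] <- vapply(seq_len(ncol(K)),
                       function(c) fun(K[r, c], ir, g_vec[c], h),
                       numeric(1))
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: `q(i)` is the minimum over
#' ranks `j >= rank(i)` of `m * p(j) / j`, capped at 1, returned in the
#' input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Restrict a pathway database to a gene universe
#'
#' Intersects every pathway's gene set with `universe`. Pathways whose
#' intersection is empty disappear from the long-format tibble but are
#' still reported (and excluded) by [run_ora()], which recomputes the
#' per-pathway universe count `i` itself.
#'
#' @param db Pathway tibble (`pathway`, optional `description`, `gene`).
#' @param universe Character vector of gene ids.
#' @return The filtered pathway tibble.
#' @export
restrict_pathways <- function(db, universe) {
  filter(db, .data$gene %in% universe)
}

#' Hypergeometric over-representation analysis across a pathway database
#'
#' Computes both exact tails per pathway against the significant-gene set,
#' excludes pathways with fewer than `min_pathway_genes` genes in the
#' universe (the default rule; `exclude_on = "significant"` instead
#' excludes on fewer than `min_pathway_genes` significant pathway genes,
#' the ALIGATOR-style variant), and applies Benjamini-Hochberg adjustment
#' separately to the enriched and depleted p-value families across the
#' non-excluded pathways (`bh_family = "joint"` pools both tails). With an
#' empty significant set every enrichment p is 1 (degenerate but defined).
#'
#' @param sig A [map_significant_genes()] result (or any tibble with
#'   `gene` and logical `significant` columns; the universe is its `gene`
#'   column).
#' @param db Pathway tibble (`pathway`, `gene`, optional `description`).
#' @param min_pathway_genes Exclusion threshold (default 2: pathways with
#'   fewer than two universe genes are excluded).
#' @param exclude_on `"universe"` (default, i-based) or `"significant"`
#'   (k-based).
#' @param bh_family `"separate"` (default) or `"joint"`.
#' @return A tibble of class `"ora_result"` with columns `pathway`, `i`,
#'   `k`, `g`, `h`, `p_enriched`, `q_enriched`, `p_depleted`,
#'   `q_depleted`, `excluded`, `reason`.
#' @export
run_ora <- function(sig, db, min_pathway_genes = 2,
                    exclude_on = c("universe", "significant"),
                    bh_family = c("separate", "joint")) {
  exclude_on <- match.arg(exclude_on)
  bh_family <- match.arg(bh_family)
  universe <- sig$gene
  h <- length(universe)
  sig_set <- significant_genes(sig)
  g <- length(sig_set)
  if (g == 0L)
    rlang::warn("empty significant-gene set: every enrichment p-value is 1")

  db_u <- restrict_pathways(db, universe)
  all_pw <- unique(db$pathway)
  counts <- db_u |>
    group_by(pathway = .data$pathway) |>
    summarise(i = dplyr::n_distinct(.data$gene),
              k = dplyr::n_distinct(intersect(.data$gene, sig_set)),
              .groups = "drop")
  counts <- left_join(tibble(pathway = all_pw), counts, by = "pathway") |>
    mutate(i = coalesce(.data$i, 0L), k = coalesce(.data$k, 0L))

  excl_count <- if (exclude_on == "universe") counts$i else counts$k
  excluded <- excl_count < min_pathway_genes
  reason <- ifelse(excluded,
                   paste0("fewer than ", min_pathway_genes,
                          if (exclude_on == "universe") " universe genes"
                          else " significant genes"),
                   NA_character_)

  p_enr <- p_dep <- rep(NA_real_, nrow(counts))
  live <- !excluded
  if (any(live)) {
    p_enr[live] <- hypergeom_enriched_p(counts$k[live], counts$i[live], g, h)
    p_dep[live] <- hypergeom_depleted_p(counts$k[live], counts$i[live], g, h)
  }
  q_enr <- q_dep <- rep(NA_real_, nrow(counts))
  if (any(live)) {
    if (bh_family == "separate") {
      q_enr[live] <- bh_adjust(p_enr[live])
      q_dep[live] <- bh_adjust(p_dep[live])
    } else {
      q <- bh_adjust(c(p_enr[live], p_dep[live]))
      q_enr[live] <- q[seq_len(sum(live))]
      q_dep[live] <- q[sum(live) + seq_len(sum(live))]
    }
  }
  out <- tibble(pathway = counts$pathway, i = counts$i, k = counts$k,
                g = g, h = h,
                p_enriched = p_enr, q_enriched = q_enr,
                p_depleted = p_dep, q_depleted = q_dep,
                excluded = excluded, reason = reason)
  attr(out, "min_pathway_genes") <- min_pathway_genes
  attr(out, "exclude_on") <- exclude_on
  class(out) <- c("ora_result", class(tibble()))
  out
}

#' @exportS3Method generics::glance
glance.ora_result <- function(x, ...) {
  tibble(n_pathways = nrow(x),
         n_excluded = sum(x$excluded),
         n_sig_enriched = sum(x$q_enriched <= 0.05, na.rm = TRUE),
         n_sig_depleted = sum(x$q_depleted <= 0.05, na.rm = TRUE),
         g = x$g[1], h = x$h[1])
}

#' Pathway overlap inspection and re-test
#'
#' Reports the pairwise gene intersections among the named pathways and
#' re-runs the over-representation analysis after removing overlap:
#' `mode = "shared"` removes the pairwise-shared genes from the named
#' pathways only (do the pathways stay significant without their common
#' genes?); `mode = "remove_all"` removes every gene of the named pathways
#' from the universe and the significant set and re-tests the remaining
#' pathways (is the signal carried by these pathways alone?).
#'
#' @param sig A [map_significant_genes()] result.
#' @param db Pathway tibble.
#' @param pathway_ids Pathways to inspect; must all exist in `db`.
#' @param mode `"shared"` or `"remove_all"`.
#' @inheritParams run_ora
#' @return A list with elements `shared` (tibble: `pathway_a`,
#'   `pathway_b`, `n_shared`, `genes` list-column) and `ora` (the re-run
#'   [run_ora()] result).
#' @export
pathway_overlap_retest <- function(sig, db, pathway_ids,
                                   mode = c("shared", "remove_all"),
                                   min_pathway_genes = 2) {
  mode <- match.arg(mode)
  if (!all(pathway_ids %in% db$pathway))
    stop_input("unknown pathway id in `pathway_ids`")
  sets <- lapply(pathway_ids,
                 function(p) unique(db$gene[db$pathway == p]))
  names(sets) <- pathway_ids

  pairs <- if (length(pathway_ids) >= 2L)
    utils::combn(pathway_ids, 2L, simplify = FALSE) else list()
  shared <- purrr::map_dfr(pairs, function(pr) {
    genes <- intersect(sets[[pr[1]]], sets[[pr[2]]])
    tibble(pathway_a = pr[1], pathway_b = pr[2],
           n_shared = length(genes), genes = list(genes))
  })
  if (nrow(shared) == 0L)
    shared <- tibble(pathway_a = character(), pathway_b = character(),
                     n_shared = integer(), genes = list())

  if (mode == "shared") {
    drop_genes <- unique(unlist(shared$genes))
    db2 <- filter(db, !(.data$pathway %in% pathway_ids &
                          .data$gene %in% drop_genes))
    sig2 <- sig
  } else {
    all_genes <- unique(unlist(sets))
    db2 <- filter(db, !.data$pathway %in% pathway_ids,
                  !.data$gene %in% all_genes)
    sig2 <- filter(sig, !.data$gene %in% all_genes)
    class(sig2) <- class(sig)
    attr(sig2, "alpha") <- attr(sig, "alpha")
  }
  list(shared = shared,
       ora = run_ora(sig2, db2, min_pathway_genes = min_pathway_genes))
}
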