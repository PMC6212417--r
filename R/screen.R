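## The miRNA selection cascade: functionally active miRNAs (activity
## positively correlated with own expression, activity-correlated genes
## enriched for predicted targets), key miRNAs (many negatively associated
## functional targets), differential expression vs normal tissue, and the
## three-way intersection.

#' Correlation between a miRNA's activity and its own expression
#'
#' @param activity per-sample inferred activity.
#' @param mirna_row per-sample miRNA expression.
#' @return list with `r`, `p.value`, `n` (`NA` for constant vectors).
#' @export
correlate_activity_expression <- function(activity, mirna_row) {
  pearson_test(activity, mirna_row)
}

#' Functional targets of one miRNA
#'
#' Correlates the inferred activity with each predicted target's expression,
#' adjusts the p-values with Benjamini-Hochberg across the miRNA's targets,
#' and returns the genes passing the FDR threshold; the functional (negative)
#' subset drives the key-miRNA flag.
#'
#' @param activity per-sample inferred activity.
#' @param expr genes x samples expression matrix (same samples).
#' @param targets predicted target genes of the miRNA.
#' @param fdr_threshold BH FDR threshold (default 0.01).
#' @return list: `table` (gene, r, p, fdr for every in-matrix target),
#'   `significant` (rows passing the threshold, with `direction`),
#'   `negative` (character vector of significant genes with `r < 0`).
#' @export
functional_targets <- function(activity, expr, targets, fdr_threshold = 0.01) {
  genes <- intersect(targets, rownames(expr))
  if (length(genes) == 0) {
    warning("no target genes present in the expression matrix")
    tab <- data.frame(gene = character(0), r = numeric(0), p = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
    return(list(table = tab, significant = cbind(tab, direction = character(0)),
                negative = character(0)))
  }
  r <- row_cor(expr[genes, , drop = FALSE], activity, zero_for_constant = FALSE)
  n <- length(activity)
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- ifelse(is.na(r), NA_real_,
              ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tstat), df = n - 2)))
  fdr <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(gene = genes, r = r, p = p, fdr = fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  sig <- tab[!is.na(tab$fdr) & tab$fdr <= fdr_threshold, , drop = FALSE]
  sig$direction <- ifelse(sig$r < 0, "negative", "positive")
  list(table = tab, significant = sig, negative = sig$gene[sig$r < 0])
}

#' Enrichment of activity-correlated genes for predicted targets
#'
#' Builds the 2x2 table {correlated with activity vs not} x {predicted target
#' vs not} over the expression gene universe and returns the one-sided
#' (over-representation) hypergeometric p-value.  The correlated set is
#' defined at a permutation FDR on `|r|`: the null pools correlations of
#' permuted activity vectors against all genes.
#'
#' @param activity per-sample inferred activity.
#' @param expr genes x samples expression matrix.
#' @param targets predicted target genes.
#' @param correlated_gene_fdr permutation FDR threshold on `|r|` (default 0.05).
#' @param n_perm permutations for the correlation null (default 200).
#' @param seed seed for the permutations.
#' @return list: `p` (FET p-value), `n_correlated`, `overlap`, `cutoff`
#'   (minimum `|r|` in the correlated set; `Inf` when empty).
#' @export
target_enrichment <- function(activity, expr, targets,
                              correlated_gene_fdr = 0.05, n_perm = 200L,
                              seed = 1L) {
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(length(activity)))
  aperm <- matrix(activity[perms], ncol = n_perm)
  r_obs <- row_cor(expr, activity)
  r_null <- stats::cor(t(expr), aperm)       # genes x n_perm
  fdr <- empirical_fdr(abs(r_obs), abs(as.vector(r_null)))
  correlated <- rownames(expr)[fdr <= correlated_gene_fdr]
  enrichment_fet(correlated, targets, rownames(expr))
}

## shared 2x2 helper: one-sided over-representation of set1 within set2
enrichment_fet <- function(correlated, targets, universe) {
  correlated <- intersect(correlated, universe)
  targets <- intersect(targets, universe)
  if (length(correlated) == 0) {
    return(list(p = 1, n_correlated = 0L, overlap = 0L, cutoff = Inf))
  }
  ov <- length(intersect(correlated, targets))
  list(p = hyper_test(ov, length(targets), length(correlated),
                      length(universe), alternative = "greater"),
       n_correlated = length(correlated), overlap = ov, cutoff = NA_real_)
}

#' Flag functionally active miRNAs
#'
#' A miRNA is functionally active when its activity-expression correlation is
#' positive and significant at the permutation FDR, and its activity-
#' correlated genes are enriched for its predicted targets at the permutation
#' FDR.
#'
#' @param r activity-expression correlations.
#' @param r_fdr permutation FDR of the correlations (positive orientation).
#' @param enrichment_fdr permutation FDR of the target enrichment.
#' @param fdr flag threshold (default 0.05).
#' @return logical vector.
#' @export
flag_functionally_active <- function(r, r_fdr, enrichment_fdr, fdr = 0.05) {
  out <- !is.na(r) & r > 0 & !is.na(r_fdr) & r_fdr <= fdr &
    !is.na(enrichment_fdr) & enrichment_fdr <= fdr
  out
}

#' Flag key miRNAs by functional-target count
#'
#' @param counts per-miRNA counts of negatively associated functional targets.
#' @param min_count minimum count to be "key" (default 10, consistent with
#'   the >= 10-target filter; the field quantity "a large number" has no
#'   printed cutoff).
#' @return logical vector.
#' @export
flag_key <- function(counts, min_count = 10L) {
  counts >= min_count
}

#' Differential miRNA expression, tumor vs normal
#'
#' Two-sided Wilcoxon-Mann-Whitney per miRNA (exact when the smaller group
#' has at most 8 samples, normal approximation with tie correction
#' otherwise); flagged when `p < p_threshold`.
#'
#' @param tumor_mirna,normal_mirna miRNAs x samples matrices sharing rownames.
#' @param p_threshold flag threshold (default 1e-5, corresponding to FDR
#'   below 1% in the reference analysis).
#' @return data.frame: `mirna`, `p`, `flag`.
#' @export
diff_expression_vs_normal <- function(tumor_mirna, normal_mirna,
                                      p_threshold = 1e-5) {
  assert_that(ncol(normal_mirna) >= 1, "need at least one normal sample")
  shared <- intersect(rownames(tumor_mirna), rownames(normal_mirna))
  p <- vapply(shared, function(k) {
    wmw_test(tumor_mirna[k, ], normal_mirna[k, ])$p.value
  }, numeric(1))
  data.frame(mirna = shared, p = p, flag = p < p_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Intersect the three screen flags
#'
#' @param screen_table a [screen_mirnas()] table with logical columns
#'   `functionally_active`, `key`, `diff_expressed`.
#' @return character vector of functional-key miRNA IDs.
#' @export
intersect_functional_key <- function(screen_table) {
  keep <- screen_table$functionally_active & screen_table$key &
    screen_table$diff_expressed
  keep[is.na(keep)] <- FALSE
  screen_table$mirna[keep]
}

#' Full miRNA screen
#'
#' For each miRNA with an inferred activity row: activity-expression
#' correlation with a permutation FDR (activity permuted, statistic = r,
#' positive orientation); target enrichment of the activity-correlated gene
#' set (permutation FDR 5% on `|r|` defines the set, permutation FDR across
#' miRNAs on the -log10 FET p flags enrichment); functional targets at BH FDR
#' `functional_fdr` with the negative subset counted for the key flag; and
#' tumor-vs-normal differential expression.  Permutation nulls are pooled
#' across miRNAs.
#'
#' @param activities miRNAs x samples inferred activity matrix (tumors).
#' @param expr genes x samples expression matrix (same tumor samples).
#' @param mirna miRNAs x samples expression matrix (same tumor samples).
#' @param targets named list of predicted target gene vectors.
#' @param normal_mirna miRNAs x normal-samples expression matrix (optional;
#'   without it the differential-expression flag is `NA`).
#' @param n_perm permutations (default 1000).
#' @param seed master seed; per-miRNA permutations are derived from it.
#' @param fdr_active flag threshold for functional activity (default 0.05).
#' @param correlated_gene_fdr FDR defining the correlated gene set.
#' @param functional_fdr BH FDR for functional targets (default 0.01).
#' @param key_min_targets minimum functional-target count for key miRNAs.
#' @param p_de p-value threshold for differential expression (default 1e-5).
#' @return list: `table` (one row per miRNA with all statistics and flags),
#'   `functional_targets` (named list of per-miRNA target tables).
#' @export
screen_mirnas <- function(activities, expr, mirna, targets,
                          normal_mirna = NULL, n_perm = 1000L, seed = 1L,
                          fdr_active = 0.05, correlated_gene_fdr = 0.05,
                          functional_fdr = 0.01, key_min_targets = 10L,
                          p_de = 1e-5) {
  mirnas <- rownames(activities)
  assert_that(length(mirnas) >= 1, "no activities supplied")
  assert_that(identical(colnames(activities), colnames(expr)),
              "activity and expression matrices must share the sample ordering")
  assert_that(all(mirnas %in% rownames(mirna)),
              "every activity row needs a matching miRNA expression row")
  n <- ncol(expr)
  exprT <- t(expr)
  r_ae <- p_ae <- numeric(length(mirnas))
  enr_p <- numeric(length(mirnas))
  n_functional <- integer(length(mirnas))
  null_r <- vector("list", length(mirnas))
  null_enr <- vector("list", length(mirnas))
  ft_list <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    k <- mirnas[i]
    a <- activities[k, ]
    set.seed(stage_seed(seed, paste0("screen_", k)))
    perms <- replicate(n_perm, sample.int(n))
    aperm <- matrix(a[perms], ncol = n_perm)

    ct <- correlate_activity_expression(a, mirna[k, ])
    r_ae[i] <- ct$r; p_ae[i] <- ct$p.value
    m_row <- mirna[k, ]
    null_r[[i]] <- if (stats::sd(m_row) > 0 && stats::sd(a) > 0) {
      as.vector(stats::cor(aperm, m_row))
    } else {
      rep(NA_real_, n_perm)
    }

    r_genes <- row_cor(expr, a)
    r_null_genes <- stats::cor(exprT, aperm)     # genes x n_perm
    r_null_genes[is.na(r_null_genes)] <- 0
    gene_fdr <- empirical_fdr(abs(r_genes), abs(as.vector(r_null_genes)))
    correlated <- rownames(expr)[gene_fdr <= correlated_gene_fdr]
    cutoff <- if (length(correlated) > 0) {
      min(abs(r_genes)[gene_fdr <= correlated_gene_fdr])
    } else {
      Inf
    }
    tg <- intersect(targets[[k]] %||% character(0), rownames(expr))
    enr_p[i] <- enrichment_fet(correlated, tg, rownames(expr))$p
    ## null enrichment: same |r| cutoff applied to each permutation's profile
    tv <- rownames(expr) %in% tg
    G <- nrow(expr)
    null_enr[[i]] <- vapply(seq_len(n_perm), function(bcol) {
      cs <- abs(r_null_genes[, bcol]) >= cutoff
      nc <- sum(cs)
      if (nc == 0) return(1)
      hyper_test(sum(cs & tv), length(tg), nc, G, alternative = "greater")
    }, numeric(1))

    ft <- functional_targets(a, expr, targets[[k]] %||% character(0),
                             functional_fdr)
    ft_list[[i]] <- ft
    n_functional[i] <- length(ft$negative)
  }
  names(ft_list) <- mirnas
  r_fdr <- empirical_fdr(r_ae, unlist(null_r))
  enr_fdr <- empirical_fdr(-log10(pmax(enr_p, 1e-300)),
                           -log10(pmax(unlist(null_enr), 1e-300)))
  active <- flag_functionally_active(r_ae, r_fdr, enr_fdr, fdr_active)
  key <- flag_key(n_functional, key_min_targets)
  if (!is.null(normal_mirna)) {
    de <- diff_expression_vs_normal(mirna[mirnas, , drop = FALSE],
                                    normal_mirna[intersect(mirnas, rownames(normal_mirna)),
                                                 , drop = FALSE],
                                    p_de)
    de_p <- de$p[match(mirnas, de$mirna)]
    de_flag <- de$flag[match(mirnas, de$mirna)]
  } else {
    de_p <- rep(NA_real_, length(mirnas))
    de_flag <- rep(NA, length(mirnas))
  }
  tab <- data.frame(mirna = mirnas, r_activity_expression = r_ae,
                    p_activity_expression = p_ae, r_fdr = r_fdr,
                    enrichment_p = enr_p, enrichment_fdr = enr_fdr,
                    n_functional_targets = n_functional,
                    wmw_p_vs_normal = de_p,
                    functionally_active = active, key = key,
                    diff_expressed = de_flag,
                    row.names = NULL, stringsAsFactors = FALSE)
  tab$functional_key <- tab$functionally_active & tab$key & tab$diff_expressed
  list(table = tab, functional_targets = ft_list)
}
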