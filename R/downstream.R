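## Post-screen association analyses: pathway enrichment of functional
## targets, p53 gene-set overlap (FET) and correlation-shift (KS) tests,
## activity-group differential expression with Connectivity-Map signature
## export, mutation-activity association, and immune-infiltration scoring.

#' Pathway enrichment of a functional-target gene set
#'
#' One-sided hypergeometric test of the target set against each pathway,
#' restricted to the declared universe (the genes that were tested for
#' correlation).
#'
#' @param functional_targets gene set to test (subset of the universe).
#' @param collection named list of pathway gene sets (GMT).
#' @param universe gene universe.
#' @param p_threshold flag threshold (default 1e-4, corresponding to FDR
#'   below 1% in the reference analysis).
#' @return data.frame: `pathway`, `size_in_universe`, `overlap`, `p`, `flag`.
#' @export
pathway_enrichment <- function(functional_targets, collection, universe,
                               p_threshold = 1e-4) {
  targets <- intersect(functional_targets, universe)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    if (length(pw) == 0) {
      return(data.frame(pathway = nm, size_in_universe = 0L, overlap = 0L,
                        p = 1, stringsAsFactors = FALSE))
    }
    ov <- length(intersect(targets, pw))
    data.frame(pathway = nm, size_in_universe = length(pw), overlap = ov,
               p = hyper_test(ov, length(pw), length(targets),
                              length(universe), alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag <- out$p < p_threshold
  out
}

#' Overlap of two gene sets by Fisher's exact test
#'
#' Same one-sided hypergeometric kernel as [pathway_enrichment()], for a
#' single pair of sets (e.g., a miRNA's direct targets vs a p53-associated
#' signature).
#'
#' @param set1,set2 gene sets.
#' @param universe gene universe.
#' @return list with `p`, `overlap`, `n1`, `n2` (sizes inside the universe).
#' @export
geneset_overlap_fet <- function(set1, set2, universe) {
  s1 <- intersect(set1, universe)
  s2 <- intersect(set2, universe)
  if (length(s1) == 0 || length(s2) == 0) {
    return(list(p = 1, overlap = 0L, n1 = length(s1), n2 = length(s2)))
  }
  ov <- length(intersect(s1, s2))
  list(p = hyper_test(ov, length(s1), length(s2), length(universe),
                      alternative = "greater"),
       overlap = ov, n1 = length(s1), n2 = length(s2))
}

#' Correlation-distribution shift of a gene set (KS test)
#'
#' Correlates the activity with every universe gene's expression, then runs a
#' two-sample KS test between the correlations of set members and the rest.
#' Also reports the sign of the median difference (negative = the set is
#' enriched for genes negatively correlated with the activity).
#'
#' @param activity per-sample inferred activity.
#' @param expr genes x samples expression matrix.
#' @param gene_set gene set to test (at least 3 members in the universe).
#' @param universe gene universe (default: all matrix rows).
#' @return list: `statistic`, `p.value`, `median_diff` (set minus rest),
#'   `n_set`.
#' @export
geneset_correlation_ks <- function(activity, expr, gene_set,
                                   universe = rownames(expr)) {
  universe <- intersect(universe, rownames(expr))
  inset <- intersect(gene_set, universe)
  assert_that(length(inset) >= 3,
              "gene set must have at least 3 genes in the universe")
  rest <- setdiff(universe, inset)
  assert_that(length(rest) >= 1, "the set covers the whole universe")
  r <- row_cor(expr[universe, , drop = FALSE], activity)
  names(r) <- universe
  ks <- ks2_test(r[inset], r[rest])
  list(statistic = ks$statistic, p.value = ks$p.value,
       median_diff = stats::median(r[inset]) - stats::median(r[rest]),
       n_set = length(inset))
}

## vectorized tie-corrected WMW z (with continuity correction) for every row
## of X, comparing columns where z1 == 1 against the rest
rowwise_wmw_z <- function(rank_mat, tie_term, z1) {
  n1 <- sum(z1); n2 <- length(z1) - n1; n <- n1 + n2
  w1 <- as.vector(rank_mat %*% z1)
  u1 <- w1 - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  zc <- u1 - n1 * n2 / 2
  zc <- zc - sign(zc) * 0.5
  ifelse(sigma2 > 0, zc / sqrt(sigma2), 0)
}

#' Differential expression between activity groups
#'
#' Per-gene two-sided WMW test (normal approximation with tie correction) of
#' overactive vs underactive samples; significance is decided against a null
#' built by permuting the group labels `n_perm` times with the statistics
#' pooled across genes, at the configured empirical FDR.  Direction comes
#' from the median difference.
#'
#' @param expr genes x samples expression matrix.
#' @param groups a [dichotomize_by_median()] result (or a named factor with
#'   levels underactive/overactive) covering the matrix samples.
#' @param n_perm label permutations (default 500).
#' @param seed seed for the permutations.
#' @param fdr empirical FDR threshold (default 0.05).
#' @return `miract_designature`: list with `up` (higher in overactive),
#'   `down`, `table` (gene, z, p, fdr, direction), `n_over`, `n_under`.
#' @export
de_by_activity_group <- function(expr, groups, n_perm = 500L, seed = 1L,
                                 fdr = 0.05) {
  labels <- if (is.list(groups)) groups$labels else groups
  labels <- labels[colnames(expr)]
  assert_that(!anyNA(labels), "every sample needs a group label")
  z1 <- as.numeric(labels == "overactive")
  assert_that(sum(z1) >= 3 && sum(1 - z1) >= 3,
              "both groups need at least 3 samples")
  rank_mat <- t(apply(expr, 1, rank))
  tie_term <- apply(rank_mat, 1, function(r) {
    tt <- table(r); sum(tt^3 - tt)
  })
  zstat <- rowwise_wmw_z(rank_mat, tie_term, z1)
  p <- pmin(1, 2 * stats::pnorm(-abs(zstat)))
  set.seed(seed)
  null_stat <- unlist(lapply(seq_len(n_perm), function(b) {
    abs(rowwise_wmw_z(rank_mat, tie_term, z1[sample.int(length(z1))]))
  }))
  fdr_vec <- empirical_fdr(abs(zstat), null_stat)
  med_diff <- apply(expr[, z1 == 1, drop = FALSE], 1, stats::median) -
    apply(expr[, z1 == 0, drop = FALSE], 1, stats::median)
  direction <- ifelse(med_diff > 0, "up", ifelse(med_diff < 0, "down", "none"))
  sig <- !is.na(fdr_vec) & fdr_vec <= fdr & p < 1
  tab <- data.frame(gene = rownames(expr), z = zstat, p = p, fdr = fdr_vec,
                    direction = direction, significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(up = tab$gene[sig & direction == "up"],
                 down = tab$gene[sig & direction == "down"],
                 table = tab, n_over = sum(z1), n_under = sum(1 - z1)),
            class = "miract_designature")
}

#' Export a differential-expression signature in Connectivity-Map .grp format
#'
#' Writes `up.grp` and `down.grp`: plain text, one uppercase gene identifier
#' per line, no header.  Duplicates are removed with a warning.
#'
#' @param signature a [de_by_activity_group()] result, or a list with `up`
#'   and `down` character vectors.
#' @param directory output directory (created if missing).
#' @param prefix optional file-name prefix.
#' @return character vector of the two file paths.
#' @export
export_cmap_signature <- function(signature, directory, prefix = "") {
  up <- toupper(signature$up %||% character(0))
  down <- toupper(signature$down %||% character(0))
  if (length(up) == 0 && length(down) == 0) {
    miract_error("both gene lists are empty; nothing to export")
  }
  if (anyDuplicated(up) || anyDuplicated(down)) {
    warning("duplicate gene identifiers removed from the signature")
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  up_path <- file.path(directory, paste0(prefix, "up.grp"))
  down_path <- file.path(directory, paste0(prefix, "down.grp"))
  writeLines(unique(up), up_path)
  writeLines(unique(down), down_path)
  c(up = up_path, down = down_path)
}

#' Association between somatic mutation status and miRNA activity
#'
#' Per gene: a WMW test of the continuous activity by mutation status, and a
#' two-sided FET on the 2x2 table {mutated} x {overactive by median split};
#' flagged when either p-value is below `p_threshold`.  Genes mutated in no
#' or all samples are skipped with a reason.
#'
#' @param mutations genes x samples 0/1 matrix.
#' @param activity named per-sample activity vector.
#' @param p_threshold flag threshold (default 0.003).
#' @return data.frame: `gene`, `n_mut`, `wmw_p`, `fet_p`, `flag`, `skipped`,
#'   `reason`.
#' @export
mutation_activity_association <- function(mutations, activity,
                                          p_threshold = 0.003) {
  shared <- intersect(colnames(mutations), names(activity))
  assert_that(length(shared) >= 4, "too few samples shared with the activity")
  mut <- mutations[, shared, drop = FALSE]
  a <- activity[shared]
  over <- dichotomize_by_median(a)$labels == "overactive"
  rows <- lapply(rownames(mut), function(g) {
    m <- mut[g, ] == 1
    if (all(m) || all(!m)) {
      return(data.frame(gene = g, n_mut = sum(m), wmw_p = NA_real_,
                        fet_p = NA_real_, flag = NA, skipped = TRUE,
                        reason = "mutated in none or all samples",
                        stringsAsFactors = FALSE))
    }
    wp <- wmw_test(a[m], a[!m])$p.value
    fp <- hyper_test(sum(m & over), sum(m), sum(over), length(a),
                     alternative = "two.sided")
    data.frame(gene = g, n_mut = sum(m), wmw_p = wp, fet_p = fp,
               flag = min(wp, fp) < p_threshold, skipped = FALSE, reason = "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Immune-infiltration score and its association with activity groups
#'
#' The per-sample score is the sum of expression over the marker genes
#' present in the matrix (missing markers are dropped and counted); groups
#' are compared with a Welch two-sample t-test.
#'
#' @param expr genes x samples expression matrix.
#' @param marker_genes immune-cell marker gene list.
#' @param groups a [dichotomize_by_median()] result or named factor.
#' @return list: `score` (named vector), `t`, `p.value`, `n_markers_used`,
#'   `n_markers_missing`.
#' @export
immune_score_association <- function(expr, marker_genes, groups) {
  present <- intersect(marker_genes, rownames(expr))
  missing <- length(marker_genes) - length(present)
  if (missing > 0) message(missing, " marker genes absent from the matrix")
  assert_that(length(present) >= 1, "no marker genes present in the matrix")
  score <- colSums(expr[present, , drop = FALSE])
  labels <- if (is.list(groups)) groups$labels else groups
  labels <- labels[names(score)]
  x <- score[labels == "overactive"]
  y <- score[labels == "underactive"]
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
    return(list(score = score, t = 0, p.value = 1,
                n_markers_used = length(present), n_markers_missing = missing))
  }
  tt <- stats::t.test(x, y)
  list(score = score, t = unname(tt$statistic), p.value = tt$p.value,
       n_markers_used = length(present), n_markers_missing = missing)
}
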