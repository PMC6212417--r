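## Core miRNA-activity inference.  Three steps per miRNA: (1) a baseline
## expression level for each predicted target gene, estimated as the mean over
## samples where the miRNA is lowly expressed (where it should have had no
## impact); (2) degradation = observed expression minus baseline; (3) a
## per-sample linear fit of degradation on baseline through the origin, whose
## sign-flipped slope is the activity.  An IRLS loop re-weights target genes by
## their anti-correlation with the current activity estimate, so predicted
## targets that behave like functional targets dominate the fit.

#' Filter miRNAs by expression prevalence and target count
#'
#' A miRNA is retained iff its zero-RPM fraction (values equal to 0 on the
#' log2(RPM+1) scale) is at most `zero_fraction_max` and it has at least
#' `min_targets` predicted targets present in the expression gene universe.
#'
#' @param mirna miRNAs x samples matrix of log2(RPM+1).
#' @param targets named list: miRNA ID -> character vector of target genes.
#' @param gene_universe genes present in the expression matrix.
#' @param zero_fraction_max maximum tolerated zero fraction (default 0.85).
#' @param min_targets minimum in-universe target count (default 10).
#' @return data.frame: `mirna`, `retained`, `reason` (`""`, `zero_fraction`,
#'   `min_targets`, or `no_targets`), `zero_fraction`, `n_targets`.
#' @export
filter_mirnas <- function(mirna, targets, gene_universe,
                          zero_fraction_max = 0.85, min_targets = 10L) {
  zf <- rowMeans(mirna == 0)
  nt <- vapply(rownames(mirna), function(k) {
    if (is.null(targets[[k]])) return(NA_integer_)
    length(intersect(targets[[k]], gene_universe))
  }, integer(1))
  reason <- character(nrow(mirna))
  reason[is.na(nt)] <- "no_targets"
  reason[!is.na(nt) & nt < min_targets] <- "min_targets"
  reason[zf > zero_fraction_max] <- "zero_fraction"
  data.frame(mirna = rownames(mirna), retained = reason == "",
             reason = reason, zero_fraction = zf,
             n_targets = ifelse(is.na(nt), 0L, nt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select baseline samples for one miRNA
#'
#' The `max(ceiling(fraction * n), min_baseline_samples)` samples with the
#' lowest miRNA expression; ties at the cut are resolved by ascending sample
#' ID.  Fewer than 20 samples is an error: the procedure needs at least 20
#' samples per group to infer activity reliably.
#'
#' @param mirna_row named per-sample expression vector for one miRNA.
#' @param fraction fraction of samples used as baseline (default 0.05).
#' @param min_baseline_samples lower bound on the baseline size (default 3).
#' @return character vector of baseline sample IDs.
#' @export
select_baseline_samples <- function(mirna_row, fraction = 0.05,
                                    min_baseline_samples = 3L) {
  n <- length(mirna_row)
  if (n < 20) miract_error("insufficient_samples: need at least 20 samples")
  assert_that(!is.null(names(mirna_row)), "mirna_row must be named by sample")
  k <- max(ceiling(fraction * n), min_baseline_samples)
  ord <- order(mirna_row, names(mirna_row))
  if (length(unique(mirna_row)) == 1) {
    warning("all miRNA expression values tied; baseline is degenerate ",
            "(first ", k, " sample IDs in lexical order)")
  }
  names(mirna_row)[ord[seq_len(k)]]
}

#' Estimate per-gene baseline expression
#'
#' @param expr genes x samples expression matrix.
#' @param baseline_samples sample IDs in the baseline set.
#' @param target_genes target genes of the miRNA.
#' @return list with `baseline_samples` and named vector `b` of baseline
#'   means over the in-matrix target genes.
#' @export
estimate_baseline <- function(expr, baseline_samples, target_genes) {
  assert_that(all(baseline_samples %in% colnames(expr)),
              "baseline samples absent from the expression matrix")
  genes <- intersect(target_genes, rownames(expr))
  if (length(genes) == 0) {
    miract_error("no target genes present in the expression matrix")
  }
  b <- rowMeans(expr[genes, baseline_samples, drop = FALSE])
  list(baseline_samples = baseline_samples, b = b)
}

#' Degradation levels: observed expression minus baseline
#'
#' @param expr genes x samples expression matrix.
#' @param baseline a [estimate_baseline()] result.
#' @return target-genes x samples matrix `d = x - b`.
#' @export
compute_degradation <- function(expr, baseline) {
  genes <- names(baseline$b)
  expr[genes, , drop = FALSE] - baseline$b
}

#' Weighted through-origin fit of degradation on baseline for one sample
#'
#' `slope = sum(w * b * d) / sum(w * b^2)`.
#'
#' @param d per-gene degradation for one sample.
#' @param b per-gene baseline.
#' @param w per-gene weights.
#' @return the slope (the sign-flipped activity).
#' @export
fit_activity_one_sample <- function(d, b, w) {
  denom <- sum(w * b^2)
  if (!is.finite(denom) || denom <= 0) {
    miract_error("degenerate_fit: sum(w * b^2) must be positive")
  }
  sum(w * b * d) / denom
}

## IRLS loop shared by both variants, starting from a fixed baseline.
irls_activity <- function(expr, baseline, eps = 1e-6, tol = 1e-6,
                          max_iter = 100L, intercept = FALSE) {
  b <- baseline$b
  genes <- names(b)
  X <- expr[genes, , drop = FALSE]
  D <- X - b
  w <- rep(1 / length(b), length(b))
  names(w) <- genes
  a_prev <- rep(Inf, ncol(X))
  converged <- FALSE
  iter <- 0L
  r <- rep(0, length(b))
  slope_fun <- if (intercept) {
    function(w) {
      bw <- sum(w * b); bb <- sum(w * b^2)
      dv <- as.vector(t(D) %*% w)
      varb <- bb - bw^2
      if (varb <= 0) miract_error("degenerate_fit: zero weighted variance of baseline")
      (as.vector(t(D * b) %*% w) - bw * dv) / varb
    }
  } else {
    function(w) as.vector(crossprod(D, w * b)) / sum(w * b^2)
  }
  delta <- Inf
  repeat {
    iter <- iter + 1L
    a <- -slope_fun(w)                 # larger activity = more degradation
    r <- row_cor(X, a)
    w <- pmax(eps, -r)
    w <- w / sum(w)
    delta <- max(abs(a - a_prev))
    a_prev <- a
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged) {
    warning("activity inference did not converge within ", max_iter,
            " iterations (max |delta a| = ", signif(delta, 3), ")")
  }
  names(a) <- colnames(X)
  names(r) <- genes
  list(activity = a, weights = w, correlations = r, iterations = iter,
       converged = converged, baseline_samples = baseline$baseline_samples,
       baseline = b)
}

#' Infer per-sample miRNA activity (standard variant)
#'
#' Baseline samples are those with the lowest miRNA expression; the IRLS loop
#' then alternates per-sample through-origin fits with target re-weighting
#' `w_g` proportional to `max(eps, -cor(activity, expr_g))` until the maximum
#' activity change drops below `tol` or `max_iter` iterations.  Entirely
#' deterministic.
#'
#' @param expr genes x samples expression matrix (log2 scale).
#' @param mirna_row named per-sample miRNA expression vector.
#' @param targets character vector of predicted target genes.
#' @param fraction,min_baseline_samples baseline selection rule
#'   (see [select_baseline_samples()]).
#' @param eps weight floor for positively correlated genes.
#' @param tol convergence tolerance on `max |delta a|`.
#' @param max_iter iteration cap; non-convergence is a warning, not an error.
#' @param intercept fit with an intercept instead of through the origin
#'   (default `FALSE`, the stated degradation model).
#' @return `miract_activity`: list with per-sample `activity`, per-gene
#'   `weights` (sum to 1) and `correlations`, `iterations`, `converged`,
#'   `variant`, `baseline_samples`, `baseline`.
#' @export
infer_activity <- function(expr, mirna_row, targets, fraction = 0.05,
                           min_baseline_samples = 3L, eps = 1e-6,
                           tol = 1e-6, max_iter = 100L, intercept = FALSE) {
  assert_that(identical(sort(names(mirna_row)), sort(colnames(expr))),
              "mirna_row samples must match the expression matrix")
  mirna_row <- mirna_row[colnames(expr)]
  bs <- select_baseline_samples(mirna_row, fraction, min_baseline_samples)
  baseline <- estimate_baseline(expr, bs, targets)
  out <- irls_activity(expr, baseline, eps, tol, max_iter, intercept)
  out$variant <- "standard"
  class(out) <- "miract_activity"
  out
}

#' Infer miRNA activity from mRNA expression only
#'
#' When no miRNA expression is available, baseline samples are chosen from the
#' per-sample sum of z-scored expression over the miRNA's negatively
#' associated functional targets.  Low activity implies high functional-target
#' expression, so the default takes the 5% of samples with the *highest*
#' target sum as baseline (`baseline_extreme = "high_target_sum"`); the
#' literal low-sum reading is available as `"low_target_sum"`.  From the
#' baseline onwards the procedure is identical to the standard variant.
#'
#' @inheritParams infer_activity
#' @param functional_targets_negative functional target genes negatively
#'   associated with the miRNA's activity (from a reference cohort screen).
#' @param baseline_extreme which extreme of the target-sum score marks the
#'   baseline (default `"high_target_sum"` = lowest implied activity).
#' @return `miract_activity` with `variant = "mrna_only"`.
#' @export
infer_activity_mrna_only <- function(expr, targets, functional_targets_negative,
                                     fraction = 0.05, min_baseline_samples = 3L,
                                     baseline_extreme = c("high_target_sum",
                                                          "low_target_sum"),
                                     eps = 1e-6, tol = 1e-6, max_iter = 100L,
                                     intercept = FALSE) {
  baseline_extreme <- match.arg(baseline_extreme)
  n <- ncol(expr)
  if (n < 20) miract_error("insufficient_samples: need at least 20 samples")
  fg <- intersect(functional_targets_negative, rownames(expr))
  assert_that(length(fg) >= 1, "no functional targets present in the matrix")
  sub <- expr[fg, , drop = FALSE]
  sds <- apply(sub, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant functional-target rows dropped (z-score undefined)")
    sub <- sub[sds > 0, , drop = FALSE]
    assert_that(nrow(sub) >= 1, "all functional-target rows are constant")
  }
  z <- (sub - rowMeans(sub)) / apply(sub, 1, stats::sd)
  score <- colSums(z)
  k <- max(ceiling(fraction * n), min_baseline_samples)
  ord <- if (baseline_extreme == "high_target_sum") {
    order(-score, colnames(expr))
  } else {
    order(score, colnames(expr))
  }
  bs <- colnames(expr)[ord[seq_len(k)]]
  baseline <- estimate_baseline(expr, bs, targets)
  out <- irls_activity(expr, baseline, eps, tol, max_iter, intercept)
  out$variant <- "mrna_only"
  out$target_sum_score <- score
  class(out) <- "miract_activity"
  out
}

#' @export
print.miract_activity <- function(x, ...) {
  cat("miRNA activity profile (", x$variant, "): ", length(x$activity),
      " samples, ", length(x$weights), " target genes, ", x$iterations,
      " iterations, converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Infer activities for every retained miRNA
#'
#' Applies [filter_mirnas()] then [infer_activity()] (or the mRNA-only
#' variant) per miRNA, assembling a miRNAs x samples activity matrix.
#'
#' @param expr genes x samples expression matrix.
#' @param mirna miRNAs x samples expression matrix (`NULL` for mRNA-only).
#' @param targets named list of predicted target gene vectors.
#' @param variant `"standard"` or `"mrna_only"`.
#' @param functional_targets named list of negatively associated functional
#'   targets per miRNA (mRNA-only variant).
#' @param filter apply [filter_mirnas()] first (standard variant).
#' @param ... passed to the per-miRNA inference.
#' @return list with `activity` (matrix), `profiles` (per-miRNA
#'   `miract_activity`), `filter` (the filter table, or `NULL`).
#' @export
infer_activity_matrix <- function(expr, mirna = NULL, targets,
                                  variant = c("standard", "mrna_only"),
                                  functional_targets = NULL, filter = TRUE,
                                  ...) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    assert_that(!is.null(mirna), "standard variant needs the miRNA matrix")
    assert_that(identical(colnames(expr), colnames(mirna)),
                "mRNA and miRNA matrices must share the sample ordering")
    flt <- if (filter) {
      filter_mirnas(mirna, targets, rownames(expr))
    } else {
      data.frame(mirna = rownames(mirna), retained = TRUE, reason = "",
                 stringsAsFactors = FALSE)
    }
    keep <- flt$mirna[flt$retained]
    profiles <- lapply(keep, function(k) {
      infer_activity(expr, mirna[k, ], targets[[k]], ...)
    })
  } else {
    assert_that(!is.null(functional_targets),
                "mRNA-only variant needs per-miRNA functional targets")
    flt <- NULL
    keep <- names(functional_targets)
    keep <- keep[vapply(functional_targets, length, integer(1)) > 0]
    profiles <- lapply(keep, function(k) {
      infer_activity_mrna_only(expr, targets[[k]], functional_targets[[k]], ...)
    })
  }
  names(profiles) <- keep
  act <- if (length(keep) > 0) {
    do.call(rbind, lapply(profiles, `[[`, "activity"))
  } else {
    matrix(numeric(0), 0, ncol(expr), dimnames = list(NULL, colnames(expr)))
  }
  rownames(act) <- keep
  list(activity = act, profiles = profiles, filter = flt)
}
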