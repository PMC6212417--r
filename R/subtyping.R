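## Two-step correlation classifier: step 1 assigns each tumor to the class
## (I-IV) whose signature centroid its signature-gene vector correlates with
## best; step 2 splits class I/II tumors into Luminal vs p53-like by the sign
## of their correlation with a p53 signature.  Class III = Basal, IV = ClassIV.

#' Build subtype signature centroids from reference-labelled samples
#'
#' The centroid of class `c` at gene `g` is the mean expression of `g` over
#' samples labelled `c`, restricted to the signature genes.  Signature genes
#' absent from the matrix are dropped with a warning.
#'
#' @param expr genes x samples expression matrix.
#' @param reference_labels per-sample class in `c("I","II","III","IV")`,
#'   aligned with `colnames(expr)` (names honoured when present).
#' @param signature_genes character vector of signature gene IDs.
#' @return `miract_centroids`: list with `signature_genes` and a genes x 4
#'   `centroids` matrix (columns I-IV).
#' @export
build_centroids <- function(expr, reference_labels, signature_genes) {
  if (!is.null(names(reference_labels))) {
    reference_labels <- reference_labels[colnames(expr)]
  }
  assert_that(length(reference_labels) == ncol(expr),
              "one reference label per sample is required")
  classes <- c("I", "II", "III", "IV")
  assert_that(all(reference_labels %in% classes),
              "reference labels must be I, II, III or IV")
  missing_cls <- setdiff(classes, reference_labels)
  if (length(missing_cls) > 0) {
    miract_error(paste0("reference class with no samples: ",
                        paste(missing_cls, collapse = ", ")))
  }
  assert_that(!anyDuplicated(signature_genes), "duplicate signature genes")
  keep <- signature_genes[signature_genes %in% rownames(expr)]
  dropped <- setdiff(signature_genes, keep)
  if (length(dropped) > 0) {
    warning(length(dropped), " signature genes absent from the matrix were dropped")
  }
  if (length(keep) < 2) {
    miract_error("fewer than 2 signature genes survive; cannot build centroids")
  }
  sub <- expr[keep, , drop = FALSE]
  cen <- vapply(classes, function(cl) {
    rowMeans(sub[, reference_labels == cl, drop = FALSE])
  }, numeric(length(keep)))
  structure(list(signature_genes = keep, centroids = cen),
            class = "miract_centroids")
}

## Pearson correlation of one sample vector with each centroid column;
## NA when either side is constant (correlation undefined).
cor_with_centroids <- function(v, cen) {
  vapply(seq_len(ncol(cen)), function(j) {
    if (stats::sd(v) == 0 || stats::sd(cen[, j]) == 0) return(NA_real_)
    stats::cor(v, cen[, j])
  }, numeric(1))
}

#' Step 1: assign samples to class I-IV by highest centroid correlation
#'
#' Ties are broken by the fixed class order I < II < III < IV with a warning;
#' samples whose signature vector is constant (correlation undefined) are
#' flagged unclassifiable (`NA` class) and excluded downstream.
#'
#' @param expr genes x samples expression matrix.
#' @param centroids a [build_centroids()] object.
#' @return data.frame: `sample_id`, `step1_class`, `r_I`..`r_IV`.
#' @export
assign_step1 <- function(expr, centroids) {
  assert_that(inherits(centroids, "miract_centroids"), "not a miract_centroids")
  shared <- intersect(centroids$signature_genes, rownames(expr))
  if (length(shared) < length(centroids$signature_genes)) {
    warning(length(centroids$signature_genes) - length(shared),
            " centroid genes absent from the matrix were dropped")
  }
  assert_that(length(shared) >= 2,
              "fewer than 2 signature genes shared with the matrix")
  cen <- centroids$centroids[shared, , drop = FALSE]
  sub <- expr[shared, , drop = FALSE]
  classes <- c("I", "II", "III", "IV")
  res <- t(apply(sub, 2, cor_with_centroids, cen = cen))
  colnames(res) <- paste0("r_", classes)
  cls <- character(ncol(sub))
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    if (all(is.na(r))) {
      cls[i] <- NA_character_
      warning("sample ", colnames(sub)[i],
              " has an undefined centroid correlation; flagged unclassifiable")
      next
    }
    best <- which(r == max(r, na.rm = TRUE))
    if (length(best) > 1) {
      warning("correlation tie for sample ", colnames(sub)[i],
              "; broken by class order I<II<III<IV")
    }
    cls[i] <- classes[best[1]]
  }
  data.frame(sample_id = colnames(sub), step1_class = cls, res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Step 2: split luminal-like (class I/II) samples into Luminal vs p53-like
#'
#' Correlates each sample's p53-signature-gene vector with the per-gene
#' signature values; strictly positive correlation reads as p53-like,
#' non-positive correlation (including the exact boundary) as Luminal.
#'
#' @param expr genes x samples expression matrix.
#' @param samples sample IDs assigned to class I or II in step 1.
#' @param p53_signature data.frame with columns `gene`, `value`.
#' @return data.frame: `sample_id`, `r_p53`, `label`.
#' @export
assign_step2 <- function(expr, samples, p53_signature) {
  keep <- p53_signature$gene %in% rownames(expr)
  if (!all(keep)) {
    warning(sum(!keep), " p53-signature genes absent from the matrix were dropped")
  }
  sig <- p53_signature[keep, , drop = FALSE]
  assert_that(nrow(sig) >= 2, "fewer than 2 p53-signature genes available")
  sub <- expr[sig$gene, samples, drop = FALSE]
  r <- vapply(seq_along(samples), function(i) {
    v <- sub[, i]
    if (stats::sd(v) == 0 || stats::sd(sig$value) == 0) return(NA_real_)
    stats::cor(v, sig$value)
  }, numeric(1))
  label <- ifelse(is.na(r), NA_character_,
                  ifelse(r > 0, "p53-like", "Luminal"))
  if (anyNA(r)) {
    warning(sum(is.na(r)), " samples with undefined p53 correlation flagged unclassifiable")
  }
  data.frame(sample_id = samples, r_p53 = r, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify samples into Luminal / p53-like / Basal / ClassIV
#'
#' Composition of the two steps: class III maps to Basal, class IV to
#' ClassIV, class I/II to the step-2 result.
#'
#' @inheritParams assign_step1
#' @param p53_signature data.frame with columns `gene`, `value`.
#' @return data.frame: `sample_id`, `step1_class`, `label`, `r_I`..`r_IV`,
#'   `r_p53`.  Unclassifiable samples carry `NA` labels.
#' @export
classify_subtypes <- function(expr, centroids, p53_signature) {
  s1 <- assign_step1(expr, centroids)
  label <- rep(NA_character_, nrow(s1))
  label[!is.na(s1$step1_class) & s1$step1_class == "III"] <- "Basal"
  label[!is.na(s1$step1_class) & s1$step1_class == "IV"] <- "ClassIV"
  lum_like <- s1$sample_id[!is.na(s1$step1_class) & s1$step1_class %in% c("I", "II")]
  r_p53 <- rep(NA_real_, nrow(s1))
  if (length(lum_like) > 0) {
    s2 <- assign_step2(expr, lum_like, p53_signature)
    idx <- match(s2$sample_id, s1$sample_id)
    label[idx] <- s2$label
    r_p53[idx] <- s2$r_p53
  }
  cbind(s1[, c("sample_id", "step1_class")],
        data.frame(label = label, stringsAsFactors = FALSE),
        s1[, c("r_I", "r_II", "r_III", "r_IV")],
        data.frame(r_p53 = r_p53))
}
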