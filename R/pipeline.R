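## End-to-end orchestration: classify -> restrict to the configured subtype
## -> filter miRNAs -> infer activities -> screen -> survival screen ->
## downstream analyses, with a single master seed fanned out deterministically
## to the stages and all interchange via plain-text files.

#' Deterministic per-stage seed derived from the master seed
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer below 2^31.
#' @export
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483647L)
}

#' Build a pipeline run configuration
#'
#' File paths may be `NULL` when the corresponding stage should be skipped
#' (no miRNA matrix switches the run to the mRNA-only variant; no mutation
#' table skips the mutation association, and so on).
#'
#' @param mrna,targets,centroids,p53_signature,survival required input paths.
#' @param mirna miRNA matrix path (`NULL` = mRNA-only mode; then
#'   `functional_targets` must point to a two-column `mirna<TAB>gene` TSV).
#' @param mutations,genesets,markers optional input paths.
#' @param normals optional path to a file listing normal sample IDs (one per
#'   line); those columns are held out of classification and used for the
#'   tumor-vs-normal comparison.
#' @param functional_targets optional path used in mRNA-only mode.
#' @param subtype subtype to analyze (default `"p53-like"`).
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_perm_screen,n_perm_survival,n_perm_de permutation counts.
#' @param key_min_targets,fdr_active,functional_fdr,p_de,p_mutation stage
#'   thresholds (module defaults).
#' @param baseline_extreme baseline rule for the mRNA-only variant.
#' @return `miract_run_config` list.
#' @export
run_config <- function(mrna, targets, centroids, p53_signature, survival,
                       mirna = NULL, mutations = NULL, genesets = NULL,
                       markers = NULL, normals = NULL,
                       functional_targets = NULL,
                       subtype = "p53-like", out_dir = "miract_out",
                       seed = 1L, n_perm_screen = 1000L,
                       n_perm_survival = 1000L, n_perm_de = 500L,
                       key_min_targets = 10L, fdr_active = 0.05,
                       functional_fdr = 0.01, p_de = 1e-5,
                       p_mutation = 0.003,
                       baseline_extreme = "high_target_sum") {
  cfg <- list(mrna = mrna, targets = targets, centroids = centroids,
              p53_signature = p53_signature, survival = survival,
              mirna = mirna, mutations = mutations, genesets = genesets,
              markers = markers, normals = normals,
              functional_targets = functional_targets,
              subtype = subtype, out_dir = out_dir, seed = as.integer(seed),
              n_perm_screen = as.integer(n_perm_screen),
              n_perm_survival = as.integer(n_perm_survival),
              n_perm_de = as.integer(n_perm_de),
              key_min_targets = as.integer(key_min_targets),
              fdr_active = fdr_active, functional_fdr = functional_fdr,
              p_de = p_de, p_mutation = p_mutation,
              baseline_extreme = baseline_extreme)
  for (f in c("mrna", "targets", "centroids", "p53_signature", "survival")) {
    assert_that(!is.null(cfg[[f]]), paste0("config is missing ", f))
    assert_that(file.exists(cfg[[f]]),
                paste0("input file not found: ", cfg[[f]]))
  }
  for (f in c("mirna", "mutations", "genesets", "markers", "normals",
              "functional_targets")) {
    if (!is.null(cfg[[f]])) {
      assert_that(file.exists(cfg[[f]]),
                  paste0("input file not found: ", cfg[[f]]))
    }
  }
  structure(cfg, class = "miract_run_config")
}

read_two_col_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_that(ncol(df) >= 2, "functional-target map needs two columns")
  split(as.character(df[[2]]), as.character(df[[1]]))
}

write_table_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- format_num(df[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: input validation; subtype classification of tumor samples;
#' restriction to the configured subtype (at least 20 samples enforced);
#' miRNA filtering; activity inference (standard, or mRNA-only when no miRNA
#' matrix is configured); the miRNA screen (needs the miRNA matrix); the
#' median-split survival screen; and the downstream analyses whose inputs
#' were provided.  All outputs are plain-text files in `out_dir`; the run is
#' a pure function of (inputs, config, seed).  `report.json` carries counts,
#' exclusions and timings (and is the only non-deterministic output).
#'
#' @param config a [run_config()].
#' @return invisibly, the run report list.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "miract_run_config"), "not a miract_run_config")
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), paste0(...), "\n",
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  report <- list(version = as.character(utils::packageVersion("miract")),
                 seed = config$seed, subtype = config$subtype,
                 mode = if (is.null(config$mirna)) "mrna_only" else "standard",
                 stages = list())
  mark <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    logf(stage, ": ", paste(names(list(...)), unlist(list(...)),
                            sep = "=", collapse = ", "))
  }

  diags <- validate_inputs(config$mrna, config$mirna, config$survival)
  if (any(diags$level == "fatal")) {
    miract_error(paste0("input validation failed: ",
                        paste(diags$message[diags$level == "fatal"],
                              collapse = "; ")))
  }
  expr <- read_expression_tsv(config$mrna)
  targets <- read_gmt(config$targets)
  centroids <- read_centroids_tsv(config$centroids)
  p53 <- read_signature_tsv(config$p53_signature)
  surv <- read_survival_tsv(config$survival)
  mirna <- if (!is.null(config$mirna)) read_expression_tsv(config$mirna)
  normal_ids <- if (!is.null(config$normals)) {
    ids <- readLines(config$normals)
    ids[nzchar(ids)]
  } else {
    character(0)
  }
  tumor_ids <- setdiff(colnames(expr), normal_ids)
  mark("load", n_genes = nrow(expr), n_samples = ncol(expr),
       n_tumors = length(tumor_ids), n_normals = length(normal_ids),
       n_target_sets = length(targets))

  ## classification (tumors only)
  labels <- classify_subtypes(expr[, tumor_ids, drop = FALSE], centroids, p53)
  write_table_tsv(labels, file.path(config$out_dir, "labels.tsv"))
  in_subtype <- labels$sample_id[!is.na(labels$label) &
                                   labels$label == config$subtype]
  mark("classify", n_classified = sum(!is.na(labels$label)),
       n_unclassifiable = sum(is.na(labels$label)),
       n_in_subtype = length(in_subtype))
  if (length(in_subtype) < 20) {
    miract_error(paste0("subtype ", config$subtype, " has ",
                        length(in_subtype),
                        " samples; at least 20 samples are required"))
  }
  sexpr <- expr[, in_subtype, drop = FALSE]

  ## activity inference
  if (!is.null(mirna)) {
    smirna <- mirna[, in_subtype, drop = FALSE]
    inf <- infer_activity_matrix(sexpr, smirna, targets, variant = "standard")
    write_table_tsv(inf$filter, file.path(config$out_dir, "mirna_filter.tsv"))
    excluded <- sum(!inf$filter$retained)
  } else {
    ftmap <- read_two_col_map(config$functional_targets %||%
                                miract_error("mRNA-only mode needs functional_targets"))
    inf <- infer_activity_matrix(sexpr, NULL, targets, variant = "mrna_only",
                                 functional_targets = ftmap,
                                 baseline_extreme = config$baseline_extreme)
    excluded <- 0L
  }
  act <- inf$activity
  assert_that(nrow(act) >= 1, "no miRNA passed the filter")
  write_expression_tsv(act, file.path(config$out_dir, "activities.tsv"),
                       id_col = "mirna")
  mark("activity", n_inferred = nrow(act), n_excluded = excluded,
       variant = report$mode)

  ## miRNA screen (standard mode only: needs miRNA expression)
  top_mirna <- NULL
  if (!is.null(mirna)) {
    normal_mirna <- if (length(normal_ids) > 0) {
      mirna[, normal_ids, drop = FALSE]
    }
    scr <- screen_mirnas(act, sexpr, smirna, targets,
                         normal_mirna = normal_mirna,
                         n_perm = config$n_perm_screen,
                         seed = stage_seed(config$seed, "screen"),
                         fdr_active = config$fdr_active,
                         functional_fdr = config$functional_fdr,
                         key_min_targets = config$key_min_targets,
                         p_de = config$p_de)
    write_table_tsv(scr$table, file.path(config$out_dir, "screen.tsv"))
    ft_rows <- do.call(rbind, lapply(names(scr$functional_targets), function(k) {
      s <- scr$functional_targets[[k]]$significant
      if (nrow(s) == 0) return(NULL)
      cbind(mirna = k, s)
    }))
    if (!is.null(ft_rows)) {
      write_table_tsv(ft_rows, file.path(config$out_dir,
                                         "functional_targets.tsv"))
    }
    mark("screen", n_functionally_active = sum(scr$table$functionally_active,
                                               na.rm = TRUE),
         n_key = sum(scr$table$key, na.rm = TRUE),
         n_functional_key = length(intersect_functional_key(scr$table)))
  } else {
    logf("screen: skipped (mRNA-only mode, no miRNA expression matrix)")
    mark("screen", skipped = TRUE)
    scr <- NULL
  }

  ## survival screen
  ss <- survival_screen(act, surv, n_perm = config$n_perm_survival,
                        seed = stage_seed(config$seed, "survival"))
  write_table_tsv(ss, file.path(config$out_dir, "survival_screen.tsv"))
  mark("survival", n_tested = sum(!ss$skipped), n_skipped = sum(ss$skipped),
       n_fdr05 = sum(ss$fdr <= 0.05, na.rm = TRUE))
  ok <- which(!ss$skipped)
  if (length(ok) > 0) {
    top_mirna <- ss$mirna[ok[which.min(ss$p[ok])]]
    km_groups <- dichotomize_by_median(act[top_mirna, ])
    svs <- surv[match(intersect(colnames(act), surv$sample_id),
                      surv$sample_id), ]
    for (grp in levels(km_groups$labels)) {
      ids <- intersect(names(km_groups$labels)[km_groups$labels == grp],
                       svs$sample_id)
      km <- km_estimate(svs$time[match(ids, svs$sample_id)],
                        svs$event[match(ids, svs$sample_id)])
      write_table_tsv(km, file.path(config$out_dir,
                                    paste0("km_", top_mirna, "_", grp, ".tsv")))
    }
  }

  ## downstream analyses
  if (!is.null(top_mirna)) {
    groups <- dichotomize_by_median(act[top_mirna, ])
    de <- de_by_activity_group(sexpr, groups, n_perm = config$n_perm_de,
                               seed = stage_seed(config$seed, "de"))
    write_table_tsv(de$table[de$table$significant, , drop = FALSE],
                    file.path(config$out_dir, "de_signature.tsv"))
    if (length(de$up) + length(de$down) > 0) {
      export_cmap_signature(de, config$out_dir,
                            prefix = paste0(top_mirna, "_"))
    }
    mark("de", mirna = top_mirna, n_up = length(de$up),
         n_down = length(de$down))
    if (!is.null(config$mutations)) {
      mut <- read_mutations_tsv(config$mutations)
      ma <- mutation_activity_association(mut, act[top_mirna, ],
                                          p_threshold = config$p_mutation)
      write_table_tsv(ma, file.path(config$out_dir,
                                    "mutation_association.tsv"))
      mark("mutation", n_tested = sum(!ma$skipped),
           n_flagged = sum(ma$flag, na.rm = TRUE))
    }
    if (!is.null(config$genesets) && !is.null(scr)) {
      gs <- read_gmt(config$genesets)
      ft <- scr$functional_targets[[top_mirna]]$negative
      pe <- pathway_enrichment(ft, gs, rownames(sexpr))
      write_table_tsv(pe, file.path(config$out_dir,
                                    "pathway_enrichment.tsv"))
      mark("pathways", n_pathways = nrow(pe),
           n_flagged = sum(pe$flag))
    }
    if (!is.null(config$markers)) {
      markers <- readLines(config$markers)
      markers <- markers[nzchar(markers)]
      im <- immune_score_association(sexpr, markers, groups)
      write_table_tsv(data.frame(sample_id = names(im$score),
                                 score = im$score,
                                 group = as.character(groups$labels[names(im$score)])),
                      file.path(config$out_dir, "immune_scores.tsv"))
      mark("immune", t = im$t, p = im$p.value,
           n_markers_used = im$n_markers_used)
    }
  }

  report$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("done in ", round(report$elapsed_sec, 1), " s")
  invisible(report)
}
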