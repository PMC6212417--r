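## Synthetic cohort generator.  Emulates the statistical structure the
## activity-inference model assumes: latent per-sample miRNA activities,
## proportional degradation of functional target genes, expression-coupled
## miRNA readouts, subtype centroid structure on a disjoint signature block,
## activity-dependent survival, matched normals, and activity-linked mutations.

#' Simulation configuration
#'
#' Defaults describe the cohort used throughout the test suite: 120 tumors and
#' 25 normals, 2000 genes, 20 miRNAs with 60 predicted targets each of which
#' 70% are functional, degradation effect 0.4 per activity unit on the log2
#' scale, mRNA/miRNA noise SD 0.5, four subtypes with a 2-log2-unit centroid
#' shift, a protective prognostic miRNA (log-hazard -0.5 per activity unit),
#' 30% censoring and 20 mutation-tested genes of which the first is linked to
#' low activity of the prognostic miRNA.
#'
#' @param n_samples number of tumor samples.
#' @param n_normals number of matched normal samples (activity fixed at 0).
#' @param n_genes number of genes.
#' @param n_mirnas number of miRNAs.
#' @param targets_per_mirna predicted targets per miRNA (disjoint blocks).
#' @param functional_fraction fraction of predicted targets that are
#'   functional (length 1 or `n_mirnas`).
#' @param activity_scale scale of the half-normal latent activities.
#' @param degradation_effect multiplicative degradation per activity unit
#'   (beta; length 1 or `n_mirnas`).
#' @param mirna_coupling activity-to-miRNA-expression coupling in `[0,1]`
#'   (length 1 or `n_mirnas`).
#' @param noise_sd_mrna,noise_sd_mirna Gaussian noise SDs (log2 scale).
#' @param n_subtypes number of subtypes (1 to 4; 4 = Luminal, p53-like,
#'   Basal, ClassIV).
#' @param centroid_shift additive shift on each subtype's signature block.
#' @param prognostic_mirna_index which miRNA drives the survival hazard.
#' @param log_hazard_per_activity gamma; negative = higher activity protects.
#' @param censoring_rate expected fraction of censored tumors, in `[0, 1)`.
#' @param mutation_gene_count genes in the mutation table; gene 1 is linked
#'   to low prognostic-miRNA activity, the rest are independent background.
#' @param seed integer seed; the whole cohort is a pure function of the config.
#' @return a validated `miract_sim_config` list.
#' @export
simulation_config <- function(n_samples = 120L, n_normals = 25L,
                              n_genes = 2000L, n_mirnas = 20L,
                              targets_per_mirna = 60L,
                              functional_fraction = 0.7,
                              activity_scale = 0.8,
                              degradation_effect = 0.4,
                              mirna_coupling = 0.8,
                              noise_sd_mrna = 0.5, noise_sd_mirna = 0.5,
                              n_subtypes = 4L, centroid_shift = 2,
                              prognostic_mirna_index = 1L,
                              log_hazard_per_activity = -0.5,
                              censoring_rate = 0.3,
                              mutation_gene_count = 20L,
                              seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_normals = as.integer(n_normals),
              n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              targets_per_mirna = as.integer(targets_per_mirna),
              functional_fraction = functional_fraction,
              activity_scale = activity_scale,
              degradation_effect = degradation_effect,
              mirna_coupling = mirna_coupling,
              noise_sd_mrna = noise_sd_mrna, noise_sd_mirna = noise_sd_mirna,
              n_subtypes = as.integer(n_subtypes), centroid_shift = centroid_shift,
              prognostic_mirna_index = as.integer(prognostic_mirna_index),
              log_hazard_per_activity = log_hazard_per_activity,
              censoring_rate = censoring_rate,
              mutation_gene_count = as.integer(mutation_gene_count),
              seed = as.integer(seed),
              ## fixed world constants (documented in the methods vignette)
              sig_block_size = 25L, mirna_offset = 3, mirna_scale = 2,
              baseline_hazard = 0.05,
              mutation_logit_intercept = -1, mutation_logit_slope = 3,
              mutation_background_rate = 0.15)
  validate_sim_config(cfg)
  structure(cfg, class = "miract_sim_config")
}

validate_sim_config <- function(cfg) {
  for (f in c("n_samples", "n_genes", "n_mirnas", "targets_per_mirna",
              "n_subtypes"))
    assert_that(is_count(cfg[[f]]), paste0(f, " must be a count >= 1"))
  assert_that(cfg$n_normals >= 0 && cfg$n_normals == round(cfg$n_normals),
              "n_normals must be a non-negative count")
  assert_that(cfg$mutation_gene_count >= 0, "mutation_gene_count must be >= 0")
  for (f in c("functional_fraction", "mirna_coupling"))
    assert_that(all(cfg[[f]] >= 0 & cfg[[f]] <= 1),
                paste0(f, " must be within [0, 1]"))
  assert_that(is_proportion(cfg$censoring_rate) && cfg$censoring_rate < 1,
              "censoring_rate must be within [0, 1)")
  assert_that(cfg$activity_scale > 0, "activity_scale must be positive")
  assert_that(all(cfg$degradation_effect >= 0),
              "degradation_effect must be non-negative")
  assert_that(cfg$noise_sd_mrna >= 0 && cfg$noise_sd_mirna >= 0,
              "noise SDs must be non-negative")
  assert_that(cfg$n_subtypes <= 4, "at most 4 subtypes are supported")
  for (f in c("functional_fraction", "degradation_effect", "mirna_coupling"))
    assert_that(length(cfg[[f]]) %in% c(1L, cfg$n_mirnas),
                paste0(f, " must have length 1 or n_mirnas"))
  if (cfg$n_subtypes > 1) {
    assert_that(cfg$n_samples >= 20 * cfg$n_subtypes,
                "need at least 20 samples per subtype to simulate subtyping")
  }
  assert_that(cfg$prognostic_mirna_index >= 1 &&
                cfg$prognostic_mirna_index <= cfg$n_mirnas,
              "prognostic_mirna_index out of range")
  needed <- cfg$n_mirnas * cfg$targets_per_mirna +
    cfg$n_subtypes * cfg$sig_block_size + cfg$sig_block_size
  assert_that(cfg$n_genes >= needed,
              paste0("n_genes must be at least ", needed,
                     " to hold disjoint target and signature blocks"))
  invisible(cfg)
}

subtype_names <- function(k) c("Luminal", "p53-like", "Basal", "ClassIV")[seq_len(k)]
step1_names <- function(k) c("I", "II", "III", "IV")[seq_len(k)]

## expected censored fraction for T ~ Exp(mu), C ~ U(0, cmax) is
## (1 - exp(-mu*cmax)) / (mu*cmax); invert for cmax given a target rate.
censoring_cmax <- function(target, mu) {
  if (target <= 0) return(Inf)
  f <- function(x) (1 - exp(-x)) / x - target
  x <- stats::uniroot(f, lower = 1e-9, upper = 1e6, tol = 1e-12)$root
  x / mu
}

#' Generate a synthetic cohort with known ground truth
#'
#' Model, per miRNA `k` and tumor sample `s`: latent activity
#' `alpha[k,s] = activity_scale * |N(0,1)|` (half-normal, so low-activity
#' samples exist to act as baselines); a functional target `g` has
#' `x[g,s] = b[g] * (1 - beta[k] * alpha[k,s]) + N(0, sd_mrna)` with baseline
#' `b[g] ~ U(4, 12)` on the log2 scale; non-functional targets and non-targets
#' are `b[g]` plus subtype centroid shifts (signature block only) plus noise.
#' The miRNA readout is `lambda[k] * alpha[k,s] * c + offset + N(0, sd_mirna)`,
#' clipped at 0.  Survival is exponential with log-hazard
#' `gamma * alpha[k*, s]` under independent uniform censoring; mutations are
#' Bernoulli with logit linked to `-alpha[k*, s]` for the designated gene.
#' Normal samples have activity exactly 0.  Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @return a `miract_cohort` list: `mrna`, `mirna`, `targets`, `functional`,
#'   `true_activity`, `true_baseline`, `subtype_truth`, `step1_truth`,
#'   `signature_genes`, `p53_signature`, `survival`, `mutations`,
#'   `linked_mutation_gene`, `normal_ids`, `tumor_ids`, `config`.
#' @export
generate_cohort <- function(config = simulation_config()) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  nT <- cfg$n_samples; nN <- cfg$n_normals; nS <- nT + nN
  tumor_ids <- sprintf("T%03d", seq_len(nT))
  normal_ids <- if (nN > 0) sprintf("N%03d", seq_len(nN)) else character(0)
  samples <- c(tumor_ids, normal_ids)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  mirnas <- sprintf("miR-%03d", seq_len(cfg$n_mirnas))

  beta <- rep_len(cfg$degradation_effect, cfg$n_mirnas)
  lambda <- rep_len(cfg$mirna_coupling, cfg$n_mirnas)
  pifun <- rep_len(cfg$functional_fraction, cfg$n_mirnas)

  ## latent activities; normals sit at exactly 0
  alpha <- matrix(0, cfg$n_mirnas, nS, dimnames = list(mirnas, samples))
  alpha[, tumor_ids] <- cfg$activity_scale *
    abs(matrix(stats::rnorm(cfg$n_mirnas * nT), cfg$n_mirnas, nT))
  frac_ill <- mean(sweep(alpha[, tumor_ids, drop = FALSE], 1, beta, `*`) >= 1)
  if (frac_ill > 0.01) {
    miract_error(paste0(
      "ill-posed simulation: degradation_effect * activity >= 1 for ",
      round(100 * frac_ill, 2), "% of draws (> 1%); expression would go negative"))
  }

  ## disjoint target blocks, then subtype signature blocks, then p53 block
  ntarg <- cfg$n_mirnas * cfg$targets_per_mirna
  targets <- split(genes[seq_len(ntarg)],
                   rep(mirnas, each = cfg$targets_per_mirna))[mirnas]
  functional <- lapply(seq_len(cfg$n_mirnas), function(k) {
    tg <- targets[[k]]
    nf <- round(pifun[k] * length(tg))
    if (nf == 0) character(0) else sort(sample(tg, nf))
  })
  names(functional) <- mirnas
  sig_start <- ntarg
  sig_genes <- genes[sig_start + seq_len(cfg$n_subtypes * cfg$sig_block_size)]
  sig_blocks <- split(sig_genes, rep(seq_len(cfg$n_subtypes),
                                     each = cfg$sig_block_size))
  p53_genes <- genes[sig_start + cfg$n_subtypes * cfg$sig_block_size +
                       seq_len(cfg$sig_block_size)]
  p53_values <- stats::rnorm(length(p53_genes))
  p53_signature <- data.frame(gene = p53_genes, value = p53_values,
                              stringsAsFactors = FALSE)

  ## subtype truth: balanced assignment of tumors, normals labelled "Normal"
  st_names <- subtype_names(cfg$n_subtypes)
  subtype_truth <- stats::setNames(rep("Normal", nS), samples)
  subtype_truth[tumor_ids] <- rep_len(st_names, nT)
  step1_truth <- stats::setNames(rep(NA_character_, nS), samples)
  step1_truth[tumor_ids] <- step1_names(cfg$n_subtypes)[
    match(subtype_truth[tumor_ids], st_names)]

  ## mRNA matrix
  b <- stats::setNames(stats::runif(cfg$n_genes, 4, 12), genes)
  X <- matrix(b, cfg$n_genes, nS, dimnames = list(genes, samples))
  for (k in seq_len(cfg$n_mirnas)) {
    fg <- functional[[k]]
    if (length(fg) > 0 && beta[k] > 0) {
      X[fg, ] <- b[fg] %o% (1 - beta[k] * alpha[k, ])
    }
  }
  if (cfg$n_subtypes > 1 && cfg$centroid_shift != 0) {
    for (c_idx in seq_len(cfg$n_subtypes)) {
      in_c <- names(subtype_truth)[subtype_truth == st_names[c_idx]]
      X[sig_blocks[[c_idx]], in_c] <- X[sig_blocks[[c_idx]], in_c] +
        cfg$centroid_shift
    }
    ## p53-like vs Luminal separation on the dedicated signature block
    if (cfg$n_subtypes >= 2) {
      p53s <- names(subtype_truth)[subtype_truth == "p53-like"]
      lums <- names(subtype_truth)[subtype_truth == "Luminal"]
      if (length(p53s) > 0)
        X[p53_genes, p53s] <- X[p53_genes, p53s] + cfg$centroid_shift * p53_values
      if (length(lums) > 0)
        X[p53_genes, lums] <- X[p53_genes, lums] - cfg$centroid_shift * p53_values
    }
  }
  if (cfg$noise_sd_mrna > 0) {
    X <- X + matrix(stats::rnorm(length(X), sd = cfg$noise_sd_mrna),
                    nrow(X), ncol(X))
  }

  ## miRNA readout, clipped at 0 like log2(RPM + 1) data
  M <- cfg$mirna_offset + (lambda * cfg$mirna_scale) * alpha
  if (cfg$noise_sd_mirna > 0) {
    M <- M + matrix(stats::rnorm(length(M), sd = cfg$noise_sd_mirna),
                    nrow(M), ncol(M))
  }
  M <- pmax(M, 0)
  dimnames(M) <- list(mirnas, samples)

  ## survival (tumors only): exponential with log-hazard gamma * alpha[k*]
  ak <- alpha[cfg$prognostic_mirna_index, tumor_ids]
  rate <- cfg$baseline_hazard * exp(cfg$log_hazard_per_activity * ak)
  t_event <- stats::rexp(nT, rate = rate)
  if (cfg$censoring_rate > 0) {
    cmax <- censoring_cmax(cfg$censoring_rate, mean(rate))
    t_cens <- stats::runif(nT, 0, cmax)
  } else {
    t_cens <- rep(Inf, nT)
  }
  survival <- data.frame(sample_id = tumor_ids,
                         time = pmin(t_event, t_cens),
                         event = as.integer(t_event <= t_cens),
                         stringsAsFactors = FALSE)

  ## mutations (tumors only); gene 1 linked to low prognostic activity
  mutations <- NULL
  linked <- NA_character_
  if (cfg$mutation_gene_count > 0) {
    mut_genes <- sprintf("MGENE%03d", seq_len(cfg$mutation_gene_count))
    linked <- mut_genes[1]
    p_linked <- stats::plogis(cfg$mutation_logit_intercept +
                                cfg$mutation_logit_slope * (-ak))
    mutations <- matrix(0L, cfg$mutation_gene_count, nT,
                        dimnames = list(mut_genes, tumor_ids))
    mutations[1, ] <- stats::rbinom(nT, 1, p_linked)
    if (cfg$mutation_gene_count > 1) {
      mutations[-1, ] <- stats::rbinom((cfg$mutation_gene_count - 1) * nT, 1,
                                       cfg$mutation_background_rate)
    }
  }

  structure(list(mrna = X, mirna = M, targets = targets,
                 functional = functional, true_activity = alpha,
                 true_baseline = b, subtype_truth = subtype_truth,
                 step1_truth = step1_truth, signature_genes = sig_genes,
                 p53_signature = p53_signature, survival = survival,
                 mutations = mutations, linked_mutation_gene = linked,
                 normal_ids = normal_ids, tumor_ids = tumor_ids,
                 config = cfg),
            class = "miract_cohort")
}

#' @export
print.miract_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$tumor_ids), "tumors,",
      length(x$normal_ids), "normals,", nrow(x$mrna), "genes,",
      nrow(x$mirna), "miRNAs\n")
  cat("Subtypes:", paste(unique(x$subtype_truth[x$tumor_ids]), collapse = ", "),
      "| seed", x$config$seed, "\n")
  invisible(x)
}

#' Write cohort fixtures to a directory
#'
#' Writes `mrna.tsv`, `mirna.tsv`, `targets.gmt`, `survival.tsv`,
#' `mutations.tsv`, `truth.tsv` (true activities), `truth_subtypes.tsv`,
#' `functional_targets.tsv`, `centroids.tsv` (built from the truth labels),
#' `p53_signature.tsv`, `normals.txt` and a `manifest.json` with md5
#' checksums.  Everything round-trips losslessly through the readers.
#'
#' @param cohort a `miract_cohort`.
#' @param directory output directory (created if missing).
#' @param overwrite allow overwriting a directory that already has a manifest.
#' @return invisibly, the manifest as a named list of file paths.
#' @export
write_fixtures <- function(cohort, directory, overwrite = FALSE) {
  assert_that(inherits(cohort, "miract_cohort"), "not a miract_cohort")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(directory, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    miract_error(paste0("manifest already exists in ", directory,
                        "; use overwrite = TRUE"))
  }
  p <- function(f) file.path(directory, f)
  write_expression_tsv(cohort$mrna, p("mrna.tsv"), id_col = "gene")
  write_expression_tsv(cohort$mirna, p("mirna.tsv"), id_col = "mirna")
  write_gmt(cohort$targets, p("targets.gmt"))
  write_survival_tsv(cohort$survival, p("survival.tsv"))
  files <- c("mrna.tsv", "mirna.tsv", "targets.gmt", "survival.tsv")
  if (!is.null(cohort$mutations)) {
    write_expression_tsv(cohort$mutations, p("mutations.tsv"), id_col = "gene")
    files <- c(files, "mutations.tsv")
  }
  write_expression_tsv(cohort$true_activity, p("truth.tsv"), id_col = "mirna")
  writeLines(c("sample_id\tstep1_class\tlabel",
               paste(names(cohort$subtype_truth),
                     ifelse(is.na(cohort$step1_truth), "NA", cohort$step1_truth),
                     cohort$subtype_truth, sep = "\t")),
             p("truth_subtypes.tsv"))
  ft <- do.call(rbind, lapply(names(cohort$functional), function(k) {
    if (length(cohort$functional[[k]]) == 0) return(NULL)
    data.frame(mirna = k, gene = cohort$functional[[k]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(ft)) ft <- data.frame(mirna = character(0), gene = character(0))
  writeLines(c("mirna\tgene", paste(ft$mirna, ft$gene, sep = "\t")),
             p("functional_targets.tsv"))
  files <- c(files, "truth.tsv", "truth_subtypes.tsv", "functional_targets.tsv")
  if (cohort$config$n_subtypes == 4) {
    cen <- build_centroids(cohort$mrna[, cohort$tumor_ids, drop = FALSE],
                           cohort$step1_truth[cohort$tumor_ids],
                           cohort$signature_genes)
    write_centroids_tsv(cen, p("centroids.tsv"))
    write_signature_tsv(cohort$p53_signature, p("p53_signature.tsv"))
    files <- c(files, "centroids.tsv", "p53_signature.tsv")
  }
  writeLines(cohort$normal_ids, p("normals.txt"))
  files <- c(files, "normals.txt")
  manifest <- lapply(stats::setNames(files, sub("\\..*$", "", files)),
                     function(f) {
    list(path = f, md5 = unname(tools::md5sum(p(f))))
  })
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
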