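test_that("miRNA filter applies the zero-fraction and target-count rules", {
  m <- matrix(1, 3, 100, dimnames = list(c("mA", "mB", "mC"),
                                         sprintf("S%03d", 1:100)))
  m["mA", 1:90] <- 0                     # zero in 90/100 samples
  targets <- list(mA = paste0("G", 1:50), mB = paste0("G", 1:9),
                  mC = paste0("G", 1:50))
  flt <- filter_mirnas(m, targets, gene_universe = paste0("G", 1:60))
  expect_equal(flt$reason, c("zero_fraction", "min_targets", ""))
  expect_equal(flt$retained, c(FALSE, FALSE, TRUE))
  # exactly 85% zeros is still retained; targets absent from the universe
  # do not count
  m2 <- matrix(1, 2, 100, dimnames = list(c("mD", "mE"), sprintf("S%03d", 1:100)))
  m2["mD", 1:85] <- 0
  flt2 <- filter_mirnas(m2, list(mD = paste0("G", 1:20),
                                 mE = paste0("X", 1:20)),
                        gene_universe = paste0("G", 1:60))
  expect_true(flt2$retained[1])
  expect_equal(flt2$reason[2], "min_targets")
  # miRNA absent from the target map
  flt3 <- filter_mirnas(m2, list(mD = paste0("G", 1:20)),
                        gene_universe = paste0("G", 1:60))
  expect_equal(flt3$reason[2], "no_targets")
})

test_that("baseline sample selection follows the max(ceil(fn), min) rule", {
  v <- stats::setNames(seq_len(100), sprintf("S%03d", 1:100))
  expect_equal(select_baseline_samples(v), sprintf("S%03d", 1:5))
  v40 <- stats::setNames(seq_len(40), sprintf("S%03d", 1:40))
  expect_length(select_baseline_samples(v40), 3)   # ceil(2) < min 3
  expect_error(select_baseline_samples(v40[1:19]), "insufficient_samples")
  # ties at the cut resolved by ascending sample ID
  vt <- stats::setNames(rep(0, 40), sprintf("S%03d", 40:1))
  expect_warning(bs <- select_baseline_samples(vt), "degenerate")
  expect_equal(bs, sprintf("S%03d", 1:3))
})

test_that("baseline and degradation follow their defining identities", {
  expr <- matrix(c(2, 4, 4, 8, 6, 6), nrow = 2,
                 dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
  bl <- estimate_baseline(expr, c("S1", "S2"), c("G1", "G2"))
  expect_equal(unname(bl$b), c(3, 6))
  bl1 <- estimate_baseline(expr, "S1", c("G1", "G2"))
  expect_equal(unname(bl1$b), expr[, "S1"], ignore_attr = TRUE)
  expect_error(estimate_baseline(expr, "S1", c("NOPE")), "no target genes")

  d <- compute_degradation(expr, bl)
  expect_equal(d["G1", "S3"], 6 - 3)
  expect_equal(unname(rowMeans(d[, c("S1", "S2")])), c(0, 0))  # by construction
  expect_equal(compute_degradation(expr, bl1), expr - expr[, "S1"],
               ignore_attr = TRUE)
})

test_that("one-sample weighted fit matches the closed form and a library oracle", {
  b <- c(2, 4, 6)
  expect_equal(fit_activity_one_sample(-0.5 * b, b, c(0.2, 0.5, 0.3)), -0.5)
  w <- c(0, 0, 1)
  expect_equal(fit_activity_one_sample(c(9, 9, -3.6), b, w), -3.6 / 6)
  expect_equal(fit_activity_one_sample(c(-1, -2, -3.6), b, rep(1 / 3, 3)),
               -31.6 / 56, tolerance = 1e-12)     # -0.5643 (4 s.f.)
  expect_error(fit_activity_one_sample(c(1, 2, 3), c(0, 0, 0), rep(1, 3)),
               "degenerate_fit")
  set.seed(8)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    b <- runif(n, 1, 10); d <- rnorm(n); w <- runif(n, 0.01, 1)
    fit <- stats::lm(d ~ 0 + b, weights = w)
    expect_equal(fit_activity_one_sample(d, b, w), unname(coef(fit)),
                 tolerance = 1e-10)
  }
})

test_that("noiseless single-miRNA inference recovers the truth exactly", {
  co <- cached_cohort(n_samples = 40, n_normals = 0, n_genes = 300,
                      n_mirnas = 3, targets_per_mirna = 30, n_subtypes = 1,
                      noise_sd_mrna = 0, noise_sd_mirna = 0,
                      functional_fraction = 1, mirna_coupling = 1, seed = 4)
  prof <- infer_activity(co$mrna[, co$tumor_ids], co$mirna[1, co$tumor_ids],
                         co$targets[[1]])
  expect_true(prof$converged)
  expect_gte(cor(prof$activity, co$true_activity[1, co$tumor_ids]), 0.999)
  expect_true(all(prof$correlations < 0))
  expect_equal(sum(prof$weights), 1, tolerance = 1e-12)
  expect_true(all(prof$weights >= 0))
})

test_that("activities are deterministic and order-preserving under affine shifts", {
  co <- small_cohort(seed = 1)
  tm <- tumor_mats(co)
  p1 <- infer_activity(tm$expr, tm$mirna[2, ], co$targets[[2]])
  p2 <- infer_activity(tm$expr, tm$mirna[2, ], co$targets[[2]])
  expect_identical(p1, p2)
  # adding a constant to all target-gene expression shifts b and d
  # consistently; activities change only by a common positive scale
  shifted <- tm$expr
  shifted[co$targets[[2]], ] <- shifted[co$targets[[2]], ] + 5
  p3 <- infer_activity(shifted, tm$mirna[2, ], co$targets[[2]])
  expect_gt(cor(p1$activity, p3$activity), 0.9999)
  fit <- stats::lm(p3$activity ~ p1$activity)
  expect_gt(unname(coef(fit)[2]), 0)   # common positive scale, order preserved
  expect_gt(cor(p1$activity, p3$activity, method = "spearman"), 0.999)
})

test_that("inferred activity correlates positively with miRNA expression (beta > 0)", {
  co <- small_cohort(seed = 1)
  tm <- tumor_mats(co)
  r <- vapply(rownames(tm$mirna), function(k) {
    prof <- infer_activity(tm$expr, tm$mirna[k, ], co$targets[[k]])
    cor(prof$activity, tm$mirna[k, ])
  }, numeric(1))
  expect_true(all(r > 0))
})

test_that("recovery degrades monotonically with mRNA noise", {
  med_r <- vapply(c(0.25, 1, 4), function(sdx) {
    co <- cached_cohort(n_samples = 60, n_normals = 0, n_genes = 500,
                        n_mirnas = 6, targets_per_mirna = 40, n_subtypes = 1,
                        noise_sd_mrna = sdx, seed = 12)
    tm <- tumor_mats(co)
    stats::median(vapply(rownames(tm$mirna), function(k) {
      prof <- infer_activity(tm$expr, tm$mirna[k, ], co$targets[[k]])
      cor(prof$activity, tm$alpha[k, ])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_r) < 0))
})

test_that("mRNA-only variant: baseline rule, agreement with the standard variant", {
  co <- cached_cohort(n_samples = 40, n_normals = 0, n_genes = 300,
                      n_mirnas = 3, targets_per_mirna = 30, n_subtypes = 1,
                      noise_sd_mrna = 0, noise_sd_mirna = 0,
                      functional_fraction = 1, mirna_coupling = 1, seed = 4)
  tum <- co$tumor_ids
  std <- infer_activity(co$mrna[, tum], co$mirna[1, tum], co$targets[[1]])
  mo <- infer_activity_mrna_only(co$mrna[, tum], co$targets[[1]],
                                 co$functional[[1]])
  expect_equal(mo$variant, "mrna_only")
  expect_gte(cor(std$activity, mo$activity), 0.999)   # affine-equivalent

  # n = 20 samples -> ceil(1) < 3 -> 3 baseline samples
  sub <- co$mrna[, tum[1:20]]
  mo20 <- infer_activity_mrna_only(sub, co$targets[[1]], co$functional[[1]])
  expect_length(mo20$baseline_samples, 3)
  expect_error(infer_activity_mrna_only(co$mrna[, tum[1:19]], co$targets[[1]],
                                        co$functional[[1]]),
               "insufficient_samples")

  # the two baseline-extreme readings pick opposite ends of the score
  hi <- infer_activity_mrna_only(co$mrna[, tum], co$targets[[1]],
                                 co$functional[[1]],
                                 baseline_extreme = "high_target_sum")
  lo <- infer_activity_mrna_only(co$mrna[, tum], co$targets[[1]],
                                 co$functional[[1]],
                                 baseline_extreme = "low_target_sum")
  expect_length(intersect(hi$baseline_samples, lo$baseline_samples), 0)
  # default reading puts the baseline at the low-activity end
  expect_lt(mean(co$true_activity[1, hi$baseline_samples]),
            mean(co$true_activity[1, lo$baseline_samples]))

  # constant functional-target rows are dropped with a warning
  bad <- co$mrna[, tum]
  bad[co$functional[[1]][1], ] <- 5
  expect_warning(infer_activity_mrna_only(bad, co$targets[[1]],
                                          co$functional[[1]]),
                 "constant")
})

test_that("variant concordance holds at default noise", {
  co <- small_cohort(seed = 2)
  tm <- tumor_mats(co)
  for (k in rownames(tm$mirna)[1:3]) {
    std <- infer_activity(tm$expr, tm$mirna[k, ], co$targets[[k]])
    ft <- functional_targets(std$activity, tm$expr, co$targets[[k]])$negative
    mo <- infer_activity_mrna_only(tm$expr, co$targets[[k]], ft)
    expect_gte(cor(std$activity, mo$activity), 0.8)
  }
})

test_that("infer_activity_matrix assembles filtered profiles", {
  co <- small_cohort(seed = 1)
  tm <- tumor_mats(co)
  inf <- infer_activity_matrix(tm$expr, tm$mirna, co$targets)
  expect_equal(dim(inf$activity), c(nrow(tm$mirna), ncol(tm$expr)))
  expect_named(inf$profiles, rownames(tm$mirna))
  expect_true(all(inf$filter$retained))
})
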