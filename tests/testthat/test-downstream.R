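test_that("pathway enrichment shares the validated hypergeometric kernel", {
  universe <- paste0("G", 1:50)
  targets <- paste0("G", 1:3)
  coll <- list(same = targets, disjoint = paste0("G", 10:20),
               outside = paste0("X", 1:5))
  pe <- pathway_enrichment(targets, coll, universe)
  # pathway identical to the target set: p = 1 / C(50, 3)
  expect_equal(pe$p[pe$pathway == "same"], 1 / choose(50, 3),
               tolerance = 1e-12)
  expect_equal(pe$p[pe$pathway == "same"],
               enum_hyper_greater(3, 3, 3, 50), tolerance = 1e-12)
  expect_equal(pe$p[pe$pathway == "disjoint"], 1)
  expect_equal(pe$p[pe$pathway == "outside"], 1)
  expect_false(any(pe$flag[-1]))
})

test_that("gene-set overlap FET: identical sets, independence, empty set", {
  universe <- paste0("G", 1:12)
  res <- geneset_overlap_fet(paste0("G", 1:4), paste0("G", 1:4), universe)
  expect_equal(res$p, enum_hyper_greater(4, 4, 4, 12), tolerance = 1e-12)
  # one-gene overlap at the independence expectation is unremarkable
  res2 <- geneset_overlap_fet(paste0("G", 1:3), paste0("G", 3:6), universe)
  expect_gt(res2$p, 0.05)
  expect_equal(geneset_overlap_fet(character(0), paste0("G", 1:4),
                                   universe)$p, 1)
})

test_that("gene-set correlation KS: boundary case, calibration, degenerate input", {
  set.seed(10)
  n <- 60
  a <- rnorm(n)
  expr <- matrix(rnorm(100 * n), 100, n,
                 dimnames = list(paste0("G", 1:100), paste0("S", 1:n)))
  # set = the 10 most negatively correlated genes: verify against a direct
  # CDF construction on the correlation vector
  r <- as.vector(cor(t(expr), a))
  names(r) <- rownames(expr)
  worst10 <- names(sort(r))[1:10]
  res <- geneset_correlation_ks(a, expr, worst10)
  ks_direct <- suppressWarnings(stats::ks.test(r[worst10],
                                               r[setdiff(names(r), worst10)],
                                               exact = FALSE))
  expect_equal(res$statistic, unname(ks_direct$statistic), tolerance = 1e-12)
  expect_equal(res$statistic, 1)         # fully separated tails
  expect_lt(res$median_diff, 0)
  expect_lt(res$p.value, 1e-6)

  # null calibration: random sets give uniform-ish p over 100 seeds
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    geneset_correlation_ks(a, expr, sample(rownames(expr), 15))$p.value
  }, numeric(1))
  expect_lt(mean(pvals < 0.01), 0.06)
  expect_gt(mean(pvals), 0.25)

  expect_error(geneset_correlation_ks(a, expr, paste0("G", 1:2)),
               "at least 3")
})

test_that("activity-group DE: null calibration, planted power, antisymmetry", {
  set.seed(3)
  n <- 60
  labels <- factor(rep(c("underactive", "overactive"), each = 30),
                   levels = c("underactive", "overactive"))
  names(labels) <- paste0("S", 1:n)
  # null: both groups identical distribution
  fp <- vapply(1:10, function(s) {
    set.seed(s + 100)
    em <- matrix(rnorm(200 * n), 200, n,
                 dimnames = list(paste0("G", 1:200), names(labels)))
    sum(de_by_activity_group(em, labels, n_perm = 100,
                             seed = s)$table$significant)
  }, numeric(1))
  expect_lte(mean(fp), 0.05 * 200)

  # planted 3-sigma shift in 20 genes
  set.seed(1)
  em <- matrix(rnorm(200 * n), 200, n,
               dimnames = list(paste0("G", 1:200), names(labels)))
  em[1:20, labels == "overactive"] <- em[1:20, labels == "overactive"] + 3
  de <- de_by_activity_group(em, labels, n_perm = 200, seed = 1)
  expect_gte(sum(paste0("G", 1:20) %in% de$up), 18)
  expect_lte(length(setdiff(c(de$up, de$down), paste0("G", 1:20))), 5)
  expect_length(intersect(de$up, de$down), 0)

  # constant genes never appear
  em[21, ] <- 5
  de2 <- de_by_activity_group(em, labels, n_perm = 100, seed = 2)
  expect_equal(de2$table$p[21], 1)
  expect_false("G21" %in% c(de2$up, de2$down))

  # swapping the group labels swaps up and down exactly
  flipped <- labels
  levels(flipped) <- c("overactive", "underactive")
  de3 <- de_by_activity_group(em, flipped, n_perm = 200, seed = 1)
  expect_setequal(de3$up, de2$down)
  expect_setequal(de3$down, de2$up)
})

test_that("CMAP export writes clean .grp files", {
  d <- withr::local_tempdir()
  sig <- list(up = paste0("up", 1:52), down = paste0("dn", 1:77))
  paths <- export_cmap_signature(sig, d)
  expect_length(readLines(paths["up"]), 52)
  expect_length(readLines(paths["down"]), 77)
  expect_true(all(readLines(paths["up"]) == toupper(readLines(paths["up"]))))
  expect_setequal(readLines(paths["up"]), toupper(sig$up))   # round trip

  expect_warning(p2 <- export_cmap_signature(list(up = c("a", "a", "b"),
                                                  down = "c"), d,
                                             prefix = "dup_"),
                 "duplicate")
  expect_length(readLines(p2["up"]), 2)
  expect_error(export_cmap_signature(list(up = character(0),
                                          down = character(0)), d),
               "empty")
})

test_that("mutation-activity association: planted link and FET example", {
  # planted generator link, seeds 1-5: linked gene attains the lowest WMW p
  for (s in 1:5) {
    co <- default_cohort(seed = s)
    a <- co$true_activity[co$config$prognostic_mirna_index, co$tumor_ids]
    ma <- mutation_activity_association(co$mutations, a)
    ok <- !ma$skipped
    best <- ma$gene[ok][which.min(ma$wmw_p[ok])]
    expect_equal(best, co$linked_mutation_gene, label = paste("seed", s))
  }
  # null calibration: background genes flagged at ~ nominal rate
  flags <- unlist(lapply(1:5, function(s) {
    co <- default_cohort(seed = s)
    a <- co$true_activity[co$config$prognostic_mirna_index, co$tumor_ids]
    ma <- mutation_activity_association(co$mutations, a)
    ma$flag[!ma$skipped & ma$gene != co$linked_mutation_gene]
  }))
  expect_lte(mean(flags), 0.05)
  # genes mutated in all or no samples are skipped
  mut <- rbind(allm = rep(1L, 10), none = rep(0L, 10),
               some = c(rep(1L, 3), rep(0L, 7)))
  colnames(mut) <- paste0("S", 1:10)
  a10 <- stats::setNames(rnorm(10), paste0("S", 1:10))
  ma2 <- mutation_activity_association(mut, a10)
  expect_equal(ma2$skipped, c(TRUE, TRUE, FALSE))
})

test_that("immune score: degenerate groups, single marker, planted shift", {
  n <- 60
  labels <- factor(rep(c("underactive", "overactive"), each = 30),
                   levels = c("underactive", "overactive"))
  names(labels) <- paste0("S", 1:n)
  expr <- matrix(5, 3, n, dimnames = list(paste0("M", 1:3), names(labels)))
  res <- immune_score_association(expr, paste0("M", 1:3), labels)
  expect_equal(res$t, 0)
  expect_equal(res$p.value, 1)

  set.seed(2)
  expr2 <- matrix(rnorm(10 * n, 5), 10, n,
                  dimnames = list(paste0("M", 1:10), names(labels)))
  res2 <- immune_score_association(expr2, "M1", labels)
  expect_equal(res2$score, expr2["M1", ])
  expect_equal(res2$n_markers_used, 1)

  expr2[, labels == "overactive"] <- expr2[, labels == "overactive"] + 2
  res3 <- immune_score_association(expr2, paste0("M", 1:10), labels)
  expect_lt(res3$p.value, 0.01)
  expect_gt(res3$t, 0)
  expect_error(immune_score_association(expr2, "NOPE", labels), "no marker")
})
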