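# Cohorts are pure functions of their config, so a session-level cache keeps
# the suite fast without risking cross-test contamination.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(...) {
  cfg <- simulation_config(...)
  key <- paste(deparse(cfg[names(cfg) != "seed"]), cfg$seed, collapse = "")
  key <- digest_key(key)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

digest_key <- function(s) {
  v <- utf8ToInt(paste(s, collapse = ""))
  paste0("k", sum(v * (seq_along(v) %% 97 + 1)) %% 1e9, "_", length(v))
}

# a compact single-subtype cohort for the activity/screen unit tests
small_cohort <- function(seed = 1, ...) {
  cached_cohort(n_samples = 60, n_normals = 25, n_genes = 500, n_mirnas = 6,
                targets_per_mirna = 40, n_subtypes = 1, seed = seed, ...)
}

default_cohort <- function(seed = 1, ...) cached_cohort(seed = seed, ...)

tumor_mats <- function(co) {
  list(expr = co$mrna[, co$tumor_ids, drop = FALSE],
       mirna = co$mirna[, co$tumor_ids, drop = FALSE],
       alpha = co$true_activity[, co$tumor_ids, drop = FALSE])
}

# independent exhaustive hypergeometric tail by combinatorial counting
enum_hyper_greater <- function(overlap, size1, size2, n_universe) {
  js <- max(0, size1 + size2 - n_universe):min(size1, size2)
  pr <- choose(size1, js) * choose(n_universe - size1, size2 - js) /
    choose(n_universe, size2)
  sum(pr[js >= overlap])
}

enum_hyper_two_sided <- function(overlap, size1, size2, n_universe) {
  js <- max(0, size1 + size2 - n_universe):min(size1, size2)
  pr <- choose(size1, js) * choose(n_universe - size1, size2 - js) /
    choose(n_universe, size2)
  pobs <- pr[js == overlap]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# exhaustive WMW two-sided p by enumerating every group assignment
enum_wmw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wobs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  ple <- mean(ws <= wobs + 1e-9)
  pge <- mean(ws >= wobs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# independent asymptotic Kolmogorov survival function (long alternating series)
oracle_kolmogorov_q <- function(lambda) {
  if (lambda <= 0) return(1)
  j <- 1:2000
  min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
}
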