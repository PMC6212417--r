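## Median-split survival screening: per miRNA, samples above the median
## activity form the overactive group, a two-group log-rank test compares the
## Kaplan-Meier curves, and an empirical FDR is built by permuting each
## miRNA's activity vector and pooling the null statistics across miRNAs.

#' Dichotomize a per-sample vector at its median
#'
#' Values strictly above the median are "overactive"; values at or below are
#' "underactive" (ties at the median go down, so the split is deterministic).
#'
#' @param values named per-sample numeric vector (at least 2 samples).
#' @return list with `labels` (named factor overactive/underactive) and
#'   `median`.
#' @export
dichotomize_by_median <- function(values) {
  assert_that(length(values) >= 2, "need at least 2 samples to split")
  if (length(unique(values)) == 1) {
    miract_error("degenerate_split: all values equal")
  }
  med <- stats::median(values)
  lab <- factor(ifelse(values > med, "overactive", "underactive"),
                levels = c("underactive", "overactive"))
  names(lab) <- names(values)
  if (all(lab == "underactive")) {
    miract_error("degenerate_split: no sample above the median")
  }
  list(labels = lab, median = med)
}

#' Kaplan-Meier product-limit estimator
#'
#' @param time non-negative follow-up times.
#' @param event 1 = death observed, 0 = censored.
#' @return data.frame at each distinct time: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.  With no events the curve stays at 1.
#' @export
km_estimate <- function(time, event) {
  assert_that(all(time >= 0), "negative survival time")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time)
  n <- length(time)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

## median survival time: first time the KM curve drops to <= 0.5 (Inf if never)
km_median <- function(time, event) {
  km <- km_estimate(time, event)
  idx <- which(km$surv <= 0.5)
  if (length(idx) == 0) Inf else km$time[idx[1]]
}

#' Two-group log-rank test
#'
#' The standard O-E statistic summed over distinct event times with the
#' hypergeometric variance, referred to a 1-d.f. chi-square.
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level factor or vector.
#' @return list with `chi2`, `p.value`, `observed` and `expected` events in
#'   the first group.  No events at all gives `p = 1` with a warning.
#' @export
logrank_test <- function(time, event, group) {
  g <- as.factor(group)
  assert_that(nlevels(g) == 2, "log-rank test needs exactly two groups")
  assert_that(all(table(g) > 0), "both groups must be non-empty")
  if (sum(event) == 0) {
    warning("no events; log-rank test is uninformative")
    return(list(chi2 = 0, p.value = 1, observed = 0, expected = 0))
  }
  z <- as.numeric(g == levels(g)[1])
  res <- logrank_chi2_perm(time, event, matrix(z, nrow = 1))
  list(chi2 = res$chi2[1], p.value = stats::pchisq(res$chi2[1], df = 1,
                                                   lower.tail = FALSE),
       observed = res$o1[1], expected = res$e1[1])
}

## Vectorized log-rank chi-square for many group-1 indicator rows at once.
## Z is permutations x samples (0/1); returns chi2 per row.
logrank_chi2_perm <- function(time, event, Z) {
  taus <- sort(unique(time[event == 1]))
  J <- length(taus)
  if (J == 0) {
    return(list(chi2 = rep(0, nrow(Z)), o1 = rep(0, nrow(Z)),
                e1 = rep(0, nrow(Z))))
  }
  R <- outer(time, taus, `>=`) * 1              # n x J at-risk
  Dm <- (outer(time, taus, `==`) & event == 1) * 1
  n_j <- colSums(R)
  d_j <- colSums(Dm)
  N1 <- Z %*% R                                  # perms x J
  O1 <- Z %*% Dm
  E1 <- sweep(sweep(N1, 2, n_j, `/`), 2, d_j, `*`)
  frac <- sweep(N1, 2, n_j, `/`)
  vscale <- d_j * ifelse(n_j > 1, (n_j - d_j) / (n_j - 1), 0)
  V <- sweep(frac * (1 - frac), 2, vscale, `*`)
  num <- rowSums(O1 - E1)^2
  den <- rowSums(V)
  chi2 <- ifelse(den > 0, num / den, 0)
  list(chi2 = chi2, o1 = rowSums(O1), e1 = rowSums(E1))
}

#' Median-split survival screen over all miRNAs
#'
#' Per miRNA: median split of the activity vector, log-rank test, and an
#' empirical FDR from `n_perm` activity-vector permutations (null chi-square
#' statistics pooled across miRNAs).  `direction` is +1 when the overactive
#' group has the longer median survival, -1 when shorter, 0 on ties.
#'
#' @param activities miRNAs x samples activity (or expression) matrix.
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param n_perm permutations (default 1000).
#' @param seed master seed.
#' @return data.frame: `mirna`, `n_over`, `n_under`, `chi2`, `p`, `fdr`,
#'   `direction`, `skipped`, `reason`.  Samples missing survival records are
#'   dropped with a message; degenerate splits are skipped with a reason.
#' @export
survival_screen <- function(activities, survival, n_perm = 1000L, seed = 1L) {
  shared <- intersect(colnames(activities), survival$sample_id)
  dropped <- ncol(activities) - length(shared)
  if (dropped > 0) {
    message(dropped, " samples without survival records dropped from the screen")
  }
  assert_that(length(shared) >= 20,
              "need at least 20 samples with survival records")
  sv <- survival[match(shared, survival$sample_id), ]
  time <- sv$time; event <- sv$event
  mirnas <- rownames(activities)
  out <- data.frame(mirna = mirnas, n_over = NA_integer_, n_under = NA_integer_,
                    chi2 = NA_real_, p = NA_real_, fdr = NA_real_,
                    direction = NA_real_, skipped = FALSE, reason = "",
                    row.names = NULL, stringsAsFactors = FALSE)
  null_chi2 <- vector("list", length(mirnas))
  for (i in seq_along(mirnas)) {
    a <- activities[mirnas[i], shared]
    split <- tryCatch(dichotomize_by_median(a), miract_error = function(e) e)
    if (inherits(split, "error")) {
      out$skipped[i] <- TRUE
      out$reason[i] <- conditionMessage(split)
      next
    }
    z <- as.numeric(split$labels == "overactive")
    obs <- logrank_chi2_perm(time, event, matrix(z, nrow = 1))
    out$n_over[i] <- sum(z); out$n_under[i] <- sum(1 - z)
    out$chi2[i] <- obs$chi2[1]
    out$p[i] <- stats::pchisq(obs$chi2[1], df = 1, lower.tail = FALSE)
    m_over <- km_median(time[z == 1], event[z == 1])
    m_under <- km_median(time[z == 0], event[z == 0])
    out$direction[i] <- sign_with_inf(m_over, m_under)
    set.seed(stage_seed(seed, paste0("survival_", mirnas[i])))
    Zp <- t(replicate(n_perm, z[sample.int(length(z))]))
    null_chi2[[i]] <- logrank_chi2_perm(time, event, Zp)$chi2
  }
  out$fdr <- empirical_fdr(out$chi2, unlist(null_chi2))
  out
}

sign_with_inf <- function(a, b) {
  if (is.infinite(a) && is.infinite(b)) return(0)
  if (a > b) 1 else if (a < b) -1 else 0
}
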