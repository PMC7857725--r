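#' Chance probability of dual response-type selectivity
#'
#' The product of the per-area proportions of vocalization- and
#' hand-correlated units; optionally multiplied by the probability that two
#' independently signed units share the same modulation direction
#' (`p_exc_v * p_exc_h + p_sup_v * p_sup_h`).
#'
#' @param n_vocal,n_hand Selective unit counts.
#' @param n_total Units recorded in the area (> 0).
#' @param direction_match Multiply by the same-sign probability.
#' @param sign_counts Named list/vector with `exc_vocal`, `sup_vocal`,
#'   `exc_hand`, `sup_hand` counts (required when `direction_match`).
#' @return Chance probability p0.
#' @export
overlap_chance <- function(n_vocal, n_hand, n_total, direction_match = FALSE,
                           sign_counts = NULL) {
  if (n_total == 0) stop("domain error: n_total = 0")
  stopifnot(n_vocal <= n_total, n_hand <= n_total)
  p0 <- (n_vocal / n_total) * (n_hand / n_total)
  if (direction_match) {
    sc <- sign_counts
    if (n_vocal > 0 && n_hand > 0) {
      pv <- sc[["exc_vocal"]] / n_vocal
      ph <- sc[["exc_hand"]] / n_hand
      p0 <- p0 * (pv * ph + (1 - pv) * (1 - ph))
    }
  }
  p0
}

#' Exact binomial test of the dual-selectivity count
#'
#' Tail probability of observing `k_both` or more (alternative "greater")
#' dual-selective units out of `n_total` under chance probability `p0`, or
#' the standard two-sided exact binomial p-value.
#'
#' @param k_both Observed dual-selective units.
#' @param n_total Units in the area.
#' @param p0 Chance probability from [overlap_chance()].
#' @param alternative "greater" (default) or "two_sided".
#' @return p-value.
#' @export
overlap_binomial_test <- function(k_both, n_total, p0,
                                  alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(k_both >= 0, k_both <= n_total, p0 >= 0, p0 <= 1)
  if (alternative == "greater")
    stats::pbinom(k_both - 1, n_total, p0, lower.tail = FALSE)
  else
    stats::binom.test(k_both, n_total, p0)$p.value
}

#' Pearson chi-squared comparison of two proportions
#'
#' 2x2 Pearson chi-squared test without continuity correction (df = 1);
#' used to compare the prevalence of vocalization- versus hand-correlated
#' units.
#'
#' @param k1,n1 First proportion (successes, trials).
#' @param k2,n2 Second proportion.
#' @return List with `statistic` and `p`.
#' @export
proportion_chi2 <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0)
  tab <- rbind(c(k1, n1 - k1), c(k2, n2 - k2))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    return(list(statistic = 0, p = 1))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Per-area overlap report
#'
#' For each area: selective-unit counts, both chance variants (bare product
#' and direction-matched), the one-sided exact binomial test of the observed
#' dual-selective count against each, and the chi-squared comparison of the
#' vocal versus hand proportions.
#'
#' @param classifications Data frame from [classify_units()] (possibly
#'   pooled over sessions).
#' @param alternative Binomial alternative; default "greater".
#' @param eligible_only Restrict denominators to eligible units; default
#'   TRUE.
#' @return Data frame, one row per area.
#' @export
overlap_report <- function(classifications, alternative = "greater",
                           eligible_only = TRUE) {
  cl <- classifications
  if (eligible_only) cl <- cl[cl$eligible, , drop = FALSE]
  do.call(rbind, lapply(split(cl, cl$area), function(g) {
    n <- nrow(g)
    nv <- sum(g$is_vocal); nh <- sum(g$is_hand); nb <- sum(g$is_both)
    sc <- list(exc_vocal = sum(g$vocal_sign == "excited"),
               sup_vocal = sum(g$vocal_sign == "suppressed"),
               exc_hand = sum(g$hand_sign == "excited"),
               sup_hand = sum(g$hand_sign == "suppressed"))
    p0 <- overlap_chance(nv, nh, n)
    p0_dir <- overlap_chance(nv, nh, n, direction_match = TRUE,
                             sign_counts = sc)
    test_ok <- p0 > 0
    chi <- proportion_chi2(nv, n, nh, n)
    data.frame(
      area = g$area[1], n_total = n, n_vocal = nv, n_hand = nh, n_both = nb,
      p_vocal = nv / n, p_hand = nh / n,
      p0_chance = p0, p0_chance_dir = p0_dir,
      binom_p = if (test_ok) overlap_binomial_test(nb, n, p0, alternative)
                else NA_real_,
      binom_p_dir = if (p0_dir > 0)
        overlap_binomial_test(nb, n, p0_dir, alternative) else NA_real_,
      chi2_stat = chi$statistic, chi2_p = chi$p)
  }))
}
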