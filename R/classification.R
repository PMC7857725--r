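#' Eligibility filter for premotor analyses
#'
#' Keeps units with a mean discharge rate above 1 Hz, at least `min_hits`
#' hit trials in each block (after the 450 ms reaction-time cut), and no
#' eye-movement exclusion from [screen_units()].
#'
#' @param s A `premovoc_session`.
#' @param screen Screening data frame, or NULL to skip the eye criterion.
#' @param min_rate Minimum mean rate (Hz); default 1.
#' @param min_hits Minimum hits per block; default 7.
#' @param min_rt Reaction-time cut (s); default 0.45.
#' @return Character vector of eligible unit ids.
#' @export
inclusion_filter <- function(s, screen = NULL, min_rate = 1, min_hits = 7,
                             min_rt = 0.45) {
  n_v <- nrow(select_trials(s, "vocal", "hit", min_rt))
  n_m <- nrow(select_trials(s, "manual", "hit", min_rt))
  ids <- vapply(s$units, `[[`, "", "unit_id")
  ok <- vapply(s$units, function(u) u$mean_rate > min_rate, TRUE) &
    n_v >= min_hits & n_m >= min_hits
  if (!is.null(screen))
    ok <- ok & !screen$excluded[match(ids, screen$unit_id)]
  ids[ok]
}

#' Paired baseline/premotor firing rates
#'
#' For each qualifying hit trial (reaction time >= 450 ms), the baseline
#' rate in the 450 ms before go-cue onset and the premotor rate in the
#' 450 ms before response onset.
#'
#' @param unit Unit record.
#' @param s A `premovoc_session`.
#' @param block "vocal" or "manual".
#' @param window_len Window length (s); default 0.45.
#' @return Data frame with columns `baseline`, `premotor` (Hz).
#' @export
premotor_pairs <- function(unit, s, block, window_len = 0.45) {
  tr <- select_trials(s, block, "hit", min_rt = window_len)
  if (nrow(tr) == 0)
    return(data.frame(baseline = numeric(0), premotor = numeric(0)))
  data.frame(
    baseline = rate_in_window(unit$spike_times, tr$t_go_on,
                              c(-window_len, 0)),
    premotor = rate_in_window(unit$spike_times, tr$t_response,
                              c(-window_len, 0)))
}

#' Wilcoxon signed-rank test of premotor modulation
#'
#' Two-sided paired test of premotor against baseline rates. The response
#' sign (excited/suppressed) is the sign of the median paired difference and
#' is reported only when p < alpha.
#'
#' @param pairs Data frame from [premotor_pairs()].
#' @param min_pairs Minimum trials; default 7.
#' @param alpha Significance level; default 0.05.
#' @return List with `p`, `sign` ("excited"/"suppressed"/"none"), `n`.
#' @export
response_correlation_test <- function(pairs, min_pairs = 7, alpha = 0.05) {
  n <- nrow(pairs)
  if (n < min_pairs) return(list(p = NA_real_, sign = "none", n = n))
  d <- pairs$premotor - pairs$baseline
  if (all(d == 0)) return(list(p = 1, sign = "none", n = n))
  p <- suppressWarnings(stats::wilcox.test(pairs$premotor, pairs$baseline,
                                           paired = TRUE)$p.value)
  sgn <- "none"
  if (!is.na(p) && p < alpha)
    sgn <- if (stats::median(d) > 0) "excited" else "suppressed"
  list(p = p, sign = sgn, n = n)
}

#' Mann-Whitney test of go-cue preference
#'
#' Two-sided test of premotor rates grouped by the two go-cue identities of
#' a block. Units preferring one cue are excluded from classification for
#' that block to avoid sensory confounds.
#'
#' @param unit Unit record.
#' @param s A `premovoc_session`.
#' @param block "vocal" or "manual".
#' @param min_per_cue Minimum trials per cue identity; default 3.
#' @return List with `p` (NA when a cue identity is missing or too sparse)
#'   and `n` per cue.
#' @export
cue_preference_test <- function(unit, s, block, min_per_cue = 3) {
  tr <- select_trials(s, block, "hit", min_rt = 0.45)
  rates <- rate_in_window(unit$spike_times, tr$t_response, c(-0.45, 0))
  a <- rates[tr$cue_id == "A"]
  b <- rates[tr$cue_id == "B"]
  if (length(a) < min_per_cue || length(b) < min_per_cue)
    return(list(p = NA_real_, n = c(length(a), length(b))))
  if (length(unique(c(a, b))) == 1)
    return(list(p = 1, n = c(length(a), length(b))))
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  list(p = p, n = c(length(a), length(b)))
}

#' PSTH-based premotor latency
#'
#' Trial-averaged response-aligned PSTH in non-overlapping 50 ms bins. The
#' threshold band is the baseline bin-mean average plus/minus three times
#' the standard deviation of the baseline bin means (450 ms before go-cue
#' onset, 9 bins). The latency is the time before response of the first bin
#' of the earliest run of at least `run_len` consecutive bins outside the
#' band on the unit's sign side; runs must begin before response onset but
#' may extend past it. Absent (NA) when no such run exists.
#'
#' @param unit Unit record.
#' @param s A `premovoc_session`.
#' @param block "vocal" or "manual".
#' @param sign "excited" or "suppressed" (side of the crossing).
#' @param scan_window PSTH window relative to response (s); default
#'   `c(-3, 1)` so runs can extend past the response.
#' @param bin Bin width (s); default 0.05.
#' @param run_len Required consecutive bins; default 20.
#' @return Latency in seconds before response (positive), or NA.
#' @export
psth_latency <- function(unit, s, block, sign, scan_window = c(-3, 1),
                         bin = 0.05, run_len = 20) {
  tr <- select_trials(s, block, "hit", min_rt = 0.45)
  if (nrow(tr) == 0) return(NA_real_)
  ar <- align_rates(unit, tr$t_response, scan_window, bin)
  psth <- colMeans(ar$matrix)
  bl <- align_rates(unit, tr$t_go_on, c(-0.45, 0), bin)
  bl_means <- colMeans(bl$matrix)
  mu <- mean(bl_means); sdev <- stats::sd(bl_means)
  psth_latency_from_curve(psth, ar$times, mu, sdev, sign, run_len)
}

#' Latency rule applied to a precomputed PSTH
#'
#' @param psth Trial-averaged rate per bin (Hz).
#' @param times Bin left edges relative to response (s).
#' @param baseline_mean,baseline_sd Baseline statistics (Hz).
#' @param sign "excited" (upper band crossing) or "suppressed" (lower).
#' @param run_len Required consecutive out-of-band bins.
#' @return Latency (s before response) or NA.
#' @export
psth_latency_from_curve <- function(psth, times, baseline_mean, baseline_sd,
                                    sign, run_len = 20) {
  out <- if (sign == "suppressed")
    psth < baseline_mean - 3 * baseline_sd
  else
    psth > baseline_mean + 3 * baseline_sd
  st <- run_starts(out, run_len)
  st <- st[times[st] < 0]
  if (length(st) == 0) return(NA_real_)
  -times[st[1]]
}

#' Cued-versus-spontaneous premotor contrast
#'
#' Two-sided Mann-Whitney test comparing premotor (450 ms) rates before
#' cued responses against rates before spontaneous responses of the same
#' kind. Requires at least three spontaneous events.
#'
#' @param unit Unit record.
#' @param s A `premovoc_session`.
#' @param block "vocal" (calls) or "manual" (bar releases).
#' @param min_spont Minimum spontaneous events; default 3.
#' @return List with `p` (NA when too few events), `n_cued`, `n_spont`.
#' @export
spontaneous_contrast <- function(unit, s, block, min_spont = 3) {
  kind <- if (block == "vocal") "call" else "bar_release"
  sp_t <- s$spontaneous$time_s[s$spontaneous$kind == kind]
  tr <- select_trials(s, block, "hit", min_rt = 0.45)
  if (length(sp_t) < min_spont || nrow(tr) == 0)
    return(list(p = NA_real_, n_cued = nrow(tr), n_spont = length(sp_t)))
  cued <- rate_in_window(unit$spike_times, tr$t_response, c(-0.45, 0))
  spont <- rate_in_window(unit$spike_times, sp_t, c(-0.45, 0))
  if (length(unique(c(cued, spont))) == 1)
    return(list(p = 1, n_cued = length(cued), n_spont = length(spont)))
  p <- suppressWarnings(stats::wilcox.test(cued, spont)$p.value)
  list(p = p, n_cued = length(cued), n_spont = length(spont))
}

#' Classify all units of a session
#'
#' Runs the eligibility filter, per-block cue-preference exclusion,
#' premotor-versus-baseline signed-rank tests with signs, PSTH latencies for
#' classified response types, and the cued-versus-spontaneous contrast.
#'
#' @param s A `premovoc_session`.
#' @param screen Screening table from [screen_units()] (or NULL).
#' @param alpha Significance level; default 0.05.
#' @param run_len Latency run length; default 20.
#' @param global_cue_exclusion If TRUE a cue preference in either block
#'   excludes the unit from both blocks; default FALSE (per-block).
#' @return Data frame, one row per unit, with eligibility, p-values, signs,
#'   class flags, and latencies.
#' @export
classify_units <- function(s, screen = NULL, alpha = 0.05, run_len = 20,
                           global_cue_exclusion = FALSE) {
  eligible <- inclusion_filter(s, screen)
  rows <- lapply(s$units, function(u) {
    el <- u$unit_id %in% eligible
    res <- data.frame(unit_id = u$unit_id, area = u$area, eligible = el,
                      cue_pref_p_vocal = NA_real_, cue_pref_p_manual = NA_real_,
                      excluded_cue_pref_vocal = FALSE,
                      excluded_cue_pref_manual = FALSE,
                      vocal_p = NA_real_, hand_p = NA_real_,
                      vocal_sign = "none", hand_sign = "none",
                      is_vocal = FALSE, is_hand = FALSE, is_both = FALSE,
                      psth_latency_vocal = NA_real_,
                      psth_latency_hand = NA_real_,
                      spont_p_vocal = NA_real_, spont_p_manual = NA_real_)
    if (!el) return(res)
    cue_v <- cue_preference_test(u, s, "vocal")
    cue_m <- cue_preference_test(u, s, "manual")
    res$cue_pref_p_vocal <- cue_v$p
    res$cue_pref_p_manual <- cue_m$p
    ex_v <- !is.na(cue_v$p) && cue_v$p < alpha
    ex_m <- !is.na(cue_m$p) && cue_m$p < alpha
    if (global_cue_exclusion && (ex_v || ex_m)) ex_v <- ex_m <- TRUE
    res$excluded_cue_pref_vocal <- ex_v
    res$excluded_cue_pref_manual <- ex_m
    if (!ex_v) {
      t_v <- response_correlation_test(premotor_pairs(u, s, "vocal"),
                                       alpha = alpha)
      res$vocal_p <- t_v$p
      res$vocal_sign <- t_v$sign
      res$is_vocal <- t_v$sign != "none"
      if (res$is_vocal)
        res$psth_latency_vocal <- psth_latency(u, s, "vocal", t_v$sign,
                                               run_len = run_len)
    }
    if (!ex_m) {
      t_m <- response_correlation_test(premotor_pairs(u, s, "manual"),
                                       alpha = alpha)
      res$hand_p <- t_m$p
      res$hand_sign <- t_m$sign
      res$is_hand <- t_m$sign != "none"
      if (res$is_hand)
        res$psth_latency_hand <- psth_latency(u, s, "manual", t_m$sign,
                                              run_len = run_len)
    }
    res$is_both <- res$is_vocal && res$is_hand
    if (res$is_vocal)
      res$spont_p_vocal <- spontaneous_contrast(u, s, "vocal")$p
    if (res$is_hand)
      res$spont_p_manual <- spontaneous_contrast(u, s, "manual")$p
    res
  })
  do.call(rbind, rows)
}

#' Normalized, rectified population activity curve
#'
#' Each unit's response-aligned PSTH is z-normalized by its baseline bin
#' mean and SD; suppressed units are reflected about zero (negative
#' deflections become positive deflections of equal magnitude); curves are
#' then averaged across units with a SEM.
#'
#' @param s A `premovoc_session`.
#' @param classifications Data frame from [classify_units()].
#' @param block "vocal" or "manual" (which trials to align).
#' @param response_type Which classified population to average: "vocal" or
#'   "hand".
#' @param window Alignment window (s); default `c(-2, 1)`.
#' @param bin Bin width (s); default 0.05.
#' @return List with `times`, `mean`, `sem`, `n_units`.
#' @export
population_curve <- function(s, classifications, block,
                             response_type = block_to_type(block),
                             window = c(-2, 1), bin = 0.05) {
  cl <- classifications
  sel <- if (response_type == "vocal") cl$is_vocal else cl$is_hand
  ids <- cl$unit_id[sel]
  signs <- (if (response_type == "vocal") cl$vocal_sign else
              cl$hand_sign)[sel]
  if (length(ids) == 0) stop("no classified units for ", response_type)
  tr <- select_trials(s, block, "hit", min_rt = 0.45)
  curves <- NULL
  times <- NULL
  for (i in seq_along(ids)) {
    u <- s$units[[which(vapply(s$units, `[[`, "", "unit_id") == ids[i])]]
    ar <- align_rates(u, tr$t_response, window, bin)
    psth <- colMeans(ar$matrix)
    bl <- colMeans(align_rates(u, tr$t_go_on, c(-0.45, 0), bin)$matrix)
    mu <- mean(bl); sdev <- max(stats::sd(bl), 1e-9)
    z <- (psth - mu) / sdev
    if (signs[i] == "suppressed") z <- -z
    curves <- rbind(curves, z)
    times <- ar$times
  }
  list(times = times, mean = colMeans(curves),
       sem = apply(curves, 2, stats::sd) / sqrt(nrow(curves)),
       n_units = nrow(curves))
}

block_to_type <- function(block) if (block == "vocal") "vocal" else "hand"
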