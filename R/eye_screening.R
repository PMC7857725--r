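#' Detect saccades in an eye trace
#'
#' A saccade onset is the first sample at which the Euclidean gaze
#' displacement over the following 4 ms exceeds 4 degrees of visual angle.
#' Candidates within the refractory interval after a detected onset are
#' merged into that event so one physical saccade yields one detection.
#' The direction vector compares gaze 50 ms before onset with gaze 50 ms
#' after onset; candidates lacking 100 ms of surrounding trace are dropped
#' with a warning.
#'
#' @param eye Eye trace (`list(sample_rate, t0, x, y)`), sample rate >= 250 Hz.
#' @param threshold_deg Displacement threshold (degrees); default 4.
#' @param threshold_window Displacement interval (s); default 0.004.
#' @param refractory Merge window after an onset (s); default 0.020.
#' @return Data frame: `t_onset`, `direction_deg` in [0, 360),
#'   `direction_bin` (1-8), `amplitude` (degrees over the +/-50 ms span).
#' @export
detect_saccades <- function(eye, threshold_deg = 4, threshold_window = 0.004,
                            refractory = 0.020) {
  sr <- eye$sample_rate
  stopifnot(sr >= 250)
  k <- max(1L, round(threshold_window * sr))
  n <- length(eye$x)
  if (n <= k)
    return(data.frame(t_onset = numeric(0), direction_deg = numeric(0),
                      direction_bin = integer(0), amplitude = numeric(0)))
  idx <- seq_len(n - k)
  disp <- sqrt((eye$x[idx + k] - eye$x[idx])^2 +
                 (eye$y[idx + k] - eye$y[idx])^2)
  cand <- which(disp > threshold_deg)
  if (length(cand) == 0)
    return(data.frame(t_onset = numeric(0), direction_deg = numeric(0),
                      direction_bin = integer(0), amplitude = numeric(0)))
  refr <- max(1L, round(refractory * sr))
  onsets <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last > refr) {
      onsets <- c(onsets, i)
      last <- i
    } else last <- i  # extend refractory through the ongoing event
  }
  h <- round(0.050 * sr)
  keep <- onsets - h >= 1 & onsets + h <= n
  if (any(!keep))
    warning(sum(!keep), " saccade candidate(s) dropped: <100 ms of trace")
  onsets <- onsets[keep]
  dx <- eye$x[onsets + h] - eye$x[onsets - h]
  dy <- eye$y[onsets + h] - eye$y[onsets - h]
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  data.frame(t_onset = eye$t0 + (onsets - 1) / sr, direction_deg = ang,
             direction_bin = vapply(seq_along(dx), function(i)
               direction_bin(dx[i], dy[i]), 1L),
             amplitude = sqrt(dx^2 + dy^2))
}

#' Map a direction vector to one of eight 45-degree sectors
#'
#' Bin 1 is centered on 0 degrees (rightward); bin k covers
#' `[(k-1)*45 - 22.5, (k-1)*45 + 22.5)` degrees, angles taken mod 360, so
#' the bins partition the circle.
#'
#' @param dx,dy Direction vector components (not both zero).
#' @return Integer bin 1-8.
#' @export
direction_bin <- function(dx, dy) {
  if (dx == 0 && dy == 0) stop("undefined direction: zero vector")
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  as.integer(floor(((ang + 22.5) %% 360) / 45)) + 1L
}

#' Kruskal-Wallis test of saccade-direction tuning
#'
#' Per-saccade firing rates in a 200 ms window centered on saccade onset
#' (`[-0.1, +0.1)` s), grouped by the eight direction bins (empty bins
#' dropped); the tie-corrected Kruskal-Wallis statistic is referred to a
#' chi-squared distribution with groups - 1 df.
#'
#' @param unit Unit record with sorted `spike_times`.
#' @param saccades Data frame from [detect_saccades()].
#' @param window Rate window around onset (s); default `c(-0.1, 0.1)`.
#' @return List with `p`, `statistic`, `df`, `n_groups`; `p` is NA when
#'   fewer than two non-empty direction groups exist.
#' @export
saccade_tuning_test <- function(unit, saccades, window = c(-0.1, 0.1)) {
  if (nrow(saccades) < 2)
    return(list(p = NA_real_, statistic = NA_real_, df = NA_integer_,
                n_groups = 0L))
  rates <- rate_in_window(unit$spike_times, saccades$t_onset, window)
  grp <- factor(saccades$direction_bin)
  grp <- droplevels(grp)
  if (nlevels(grp) < 2)
    return(list(p = NA_real_, statistic = NA_real_, df = NA_integer_,
                n_groups = nlevels(grp)))
  if (stats::var(rates) == 0)   # all identical: no tuning by definition
    return(list(p = 1, statistic = 0, df = nlevels(grp) - 1L,
                n_groups = nlevels(grp)))
  kw <- stats::kruskal.test(rates, grp)
  list(p = kw$p.value, statistic = unname(kw$statistic),
       df = unname(kw$parameter), n_groups = nlevels(grp))
}

#' Detect cue fixation epochs
#'
#' Maximal saccade-free intervals during cue epochs (pre-cue onset through
#' go-cue offset) in which gaze stays within `tol_deg` of the cue position;
#' intervals shorter than 200 ms are discarded.
#'
#' @param eye Eye trace.
#' @param cue_epochs Data frame with `t_lo`, `t_hi` (s) per epoch.
#' @param saccades Saccade data frame (their samples break fixations).
#' @param cue_pos Cue position `c(x, y)` in degrees; default origin.
#' @param tol_deg Gaze tolerance (degrees); default 2.
#' @param min_duration Minimum epoch length (s); default 0.2.
#' @return Data frame: `t_onset`, `duration`.
#' @export
detect_fixations <- function(eye, cue_epochs, saccades = NULL,
                             cue_pos = c(0, 0), tol_deg = 2,
                             min_duration = 0.2) {
  sr <- eye$sample_rate
  n <- length(eye$x)
  ts <- eye$t0 + (seq_len(n) - 1) / sr
  near <- sqrt((eye$x - cue_pos[1])^2 + (eye$y - cue_pos[2])^2) < tol_deg
  if (!is.null(saccades) && nrow(saccades))
    for (i in seq_len(nrow(saccades))) {
      j <- which(ts >= saccades$t_onset[i] - 0.002 &
                   ts <= saccades$t_onset[i] + 0.020)
      near[j] <- FALSE
    }
  out <- list()
  min_len <- ceiling(min_duration * sr)
  for (e in seq_len(nrow(cue_epochs))) {
    i0 <- max(1L, ceiling((cue_epochs$t_lo[e] - eye$t0) * sr) + 1L)
    i1 <- min(n, floor((cue_epochs$t_hi[e] - eye$t0) * sr))
    if (i1 - i0 + 1 < min_len) next
    flag <- near[i0:i1]
    st <- run_starts(flag, min_len)
    if (length(st) == 0) next
    r <- rle(flag)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= min_len
    out[[length(out) + 1]] <- data.frame(
      t_onset = ts[i0 + starts[ok] - 1L],
      duration = r$lengths[ok] / sr)
  }
  if (length(out) == 0)
    return(data.frame(t_onset = numeric(0), duration = numeric(0)))
  do.call(rbind, out)
}

#' Wilcoxon signed-rank test for fixation-onset responses
#'
#' One-sided paired test for a firing-rate increase 100-200 ms after
#' fixation onset relative to the 100 ms immediately before onset. Requires
#' at least `min_epochs` fixation epochs (the exact test cannot reach
#' p < 0.05 below five pairs).
#'
#' @param unit Unit record.
#' @param fixations Data frame from [detect_fixations()].
#' @param min_epochs Minimum number of epochs; default 5.
#' @return List with `p` (NA when skipped) and `n`.
#' @export
fixation_test <- function(unit, fixations, min_epochs = 5) {
  n <- nrow(fixations)
  if (n < min_epochs) return(list(p = NA_real_, n = n))
  post <- rate_in_window(unit$spike_times, fixations$t_onset, c(0.1, 0.2))
  pre <- rate_in_window(unit$spike_times, fixations$t_onset, c(-0.1, 0))
  d <- post - pre
  d <- d[d != 0]
  if (length(d) == 0) return(list(p = 1, n = n))
  list(p = signed_rank_exact_p(d), n = n)
}

#' One-sided signed-rank tail probability
#'
#' P(W+ >= observed) under the null sign-flip distribution, with midranks
#' for tied absolute differences. Exact (sign-pattern convolution) up to
#' `max_exact` nonzero differences, normal approximation with tie correction
#' above; zero differences must be removed beforehand.
#'
#' @param d Nonzero paired differences.
#' @param max_exact Largest n for the exact computation; default 25.
#' @return One-sided (greater) p-value.
#' @export
signed_rank_exact_p <- function(d, max_exact = 25) {
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  if (n <= max_exact) {
    # convolve over half-rank units so midranks stay integral
    r2 <- as.integer(round(2 * r))
    p <- c(1, rep(0, sum(r2)))
    for (rk in r2) {
      shifted <- c(rep(0, rk), p[seq_len(length(p) - rk)])
      p <- (p + shifted) / 2
    }
    w2 <- round(2 * w_obs)
    return(sum(p[(w2 + 1):length(p)]))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  stats::pnorm(w_obs - 0.5, mu, sqrt(sig2), lower.tail = FALSE)
}

#' Screen all units for eye-movement confounds
#'
#' Applies the saccade-direction tuning test to every unit; units not
#' flagged as saccade-related are then tested for fixation-onset responses.
#' Units significant in either test (p < 0.05) are excluded from the
#' premotor analyses.
#'
#' @param s A `premovoc_session`.
#' @param alpha Significance level; default 0.05.
#' @param saccades,fixations Optional precomputed event tables; detected
#'   from the session's eye trace when NULL.
#' @return Data frame: `unit_id`, `saccade_p`, `is_saccade_unit`,
#'   `fixation_p`, `is_fixation_unit`, `excluded`.
#' @export
screen_units <- function(s, alpha = 0.05, saccades = NULL,
                         fixations = NULL) {
  if (is.null(saccades)) saccades <- detect_saccades(s$eye)
  if (is.null(fixations)) {
    tr <- s$trials
    epochs <- data.frame(
      t_lo = tr$t_precue_on,
      t_hi = ifelse(is.na(tr$t_go_on),
                    tr$t_precue_on + s$task$go_duration + s$task$pre_cue_max,
                    tr$t_go_on + s$task$go_duration))
    fixations <- detect_fixations(s$eye, epochs, saccades)
  }
  rows <- lapply(s$units, function(u) {
    st <- saccade_tuning_test(u, saccades)
    is_sac <- !is.na(st$p) && st$p < alpha
    fp <- NA_real_; is_fix <- FALSE
    if (!is_sac) {
      ft <- fixation_test(u, fixations)
      fp <- ft$p
      is_fix <- !is.na(fp) && fp < alpha
    }
    data.frame(unit_id = u$unit_id, saccade_p = st$p,
               is_saccade_unit = is_sac, fixation_p = fp,
               is_fixation_unit = is_fix, excluded = is_sac || is_fix)
  })
  do.call(rbind, rows)
}
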