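#' Area under the ROC curve for two rate samples
#'
#' Nonparametric discriminability of two distributions: the probability that
#' a random draw from `x` exceeds one from `y`, counting ties as one half
#' (`(wins + 0.5 * ties) / (n_x * n_y)`), computed through the rank-sum
#' identity. Vocal trials are conventionally the positive class `x`.
#'
#' @param x,y Non-empty numeric samples (positive class first).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("domain error: empty sample in auroc")
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

roc_window_centers <- function(window = c(-2, 1), width = 0.2, step = 0.01) {
  seq(window[1] + width / 2, window[2] - width / 2, by = step)
}

roc_rate_matrix <- function(unit, events, centers, width = 0.2) {
  # trials x windows rate matrix for overlapping windows
  sp <- unit$spike_times
  m <- matrix(0, nrow = length(events), ncol = length(centers))
  for (i in seq_along(events)) {
    rel <- sp - events[i]
    rel <- rel[rel >= centers[1] - width / 2 & rel < centers[length(centers)] + width / 2]
    rel <- sort(rel)
    m[i, ] <- (findInterval(centers + width / 2, rel, left.open = TRUE) -
                 findInterval(centers - width / 2, rel, left.open = TRUE)) / width
  }
  m
}

auroc_from_ranks <- function(rank_mat, pos_idx, ny) {
  # columnwise AUROC from a midrank matrix given positive-class row indices
  nx <- length(pos_idx)
  (colSums(rank_mat[pos_idx, , drop = FALSE]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Sliding-window AUROC trace for one unit
#'
#' Spike rates in overlapping 200 ms windows stepped by 10 ms over
#' `[-2, 1]` s around response onset; one AUROC (vocal vs manual hit trials)
#' per window. Windows in which every trial of both conditions has an
#' identical rate (e.g. a silent unit) return 0.5.
#'
#' @param unit Unit record.
#' @param vocal_events,manual_events Response-onset times of the hit trials
#'   of each condition (s); at least `min_trials` each.
#' @param window Alignment span (s); default `c(-2, 1)`.
#' @param width,step Window width and increment (s); defaults 0.2 and 0.01.
#' @param min_trials Minimum trials per condition; default 7.
#' @return List with `unit_id`, `window_centers`, `auroc`, plus the rate
#'   matrices needed by [permutation_bounds()].
#' @export
sliding_auroc <- function(unit, vocal_events, manual_events,
                          window = c(-2, 1), width = 0.2, step = 0.01,
                          min_trials = 7) {
  if (length(vocal_events) < min_trials || length(manual_events) < min_trials)
    stop("insufficient trials for sliding ROC (need >= ", min_trials,
         " per condition)")
  centers <- roc_window_centers(window, width, step)
  rates <- rbind(roc_rate_matrix(unit, vocal_events, centers, width),
                 roc_rate_matrix(unit, manual_events, centers, width))
  labels <- rep(c(TRUE, FALSE), c(length(vocal_events), length(manual_events)))
  rank_mat <- apply(rates, 2, rank)
  a <- auroc_from_ranks(rank_mat, which(labels), sum(!labels))
  list(unit_id = unit$unit_id, window_centers = centers, auroc = a,
       rank_mat = rank_mat, labels = labels)
}

#' Permutation null bounds for a sliding AUROC trace
#'
#' Condition labels are shuffled once per permutation across the whole time
#' course (preserving within-trial temporal correlation) and the full AUROC
#' trace recomputed; per-window empirical 2.5th/97.5th percentiles form the
#' significance bounds. Deterministic given the seed.
#'
#' @param trace Result of [sliding_auroc()].
#' @param n_perm Number of permutations; default 1000.
#' @param seed Integer seed.
#' @param probs Percentile pair; default `c(0.025, 0.975)`.
#' @return List with `lower`, `upper` (per window), and `significant`
#'   (observed AUROC strictly outside the bounds).
#' @export
permutation_bounds <- function(trace, n_perm = 1000, seed = 1,
                               probs = c(0.025, 0.975)) {
  set.seed(seed)
  n <- length(trace$labels)
  nx <- sum(trace$labels)
  ny <- n - nx
  null_mat <- matrix(0, nrow = n_perm, ncol = ncol(trace$rank_mat))
  for (p in seq_len(n_perm)) {
    pos <- sample.int(n, nx)
    null_mat[p, ] <- auroc_from_ranks(trace$rank_mat, pos, ny)
  }
  lower <- apply(null_mat, 2, stats::quantile, probs = probs[1])
  upper <- apply(null_mat, 2, stats::quantile, probs = probs[2])
  list(lower = lower, upper = upper,
       significant = trace$auroc < lower | trace$auroc > upper,
       null_mean = colMeans(null_mat))
}

#' Coding latency from a significant-window pattern
#'
#' Center time of the first window of the earliest run of at least
#' `run_len` consecutive significant windows; NA when no such run exists.
#'
#' @param centers Window center times (s).
#' @param significant Logical vector per window.
#' @param run_len Required consecutive windows; default 3.
#' @return Latency (s, window-center time) or NA.
#' @export
roc_latency <- function(centers, significant, run_len = 3) {
  st <- run_starts(significant, run_len)
  if (length(st) == 0) return(NA_real_)
  centers[st[1]]
}

#' Coding strength of an AUROC trace
#'
#' Mean absolute deviation of the AUROC from 0.5 over the windows whose
#' centers fall in the given epoch (default the 450 ms premotor window).
#'
#' @param centers Window center times (s).
#' @param auroc_values AUROC per window.
#' @param epoch Half-open epoch `[lo, hi)` (s); default `c(-0.45, 0)`.
#' @return Mean `|AUROC - 0.5|`.
#' @export
coding_strength <- function(centers, auroc_values, epoch = c(-0.45, 0)) {
  sel <- centers >= epoch[1] & centers < epoch[2]
  mean(abs(auroc_values[sel] - 0.5))
}

#' Full sliding-ROC analysis for one unit
#'
#' @param unit Unit record.
#' @param s A `premovoc_session`.
#' @param n_perm Permutations; default 1000.
#' @param seed Seed for the permutation stream.
#' @param min_rt Reaction-time cut (s); default 0.45.
#' @param ... Passed to [sliding_auroc()].
#' @return List with the trace, bounds, `latency`, and `strength`.
#' @export
roc_analysis <- function(unit, s, n_perm = 1000, seed = 1, min_rt = 0.45,
                         ...) {
  ev_v <- select_trials(s, "vocal", "hit", min_rt)$t_response
  ev_m <- select_trials(s, "manual", "hit", min_rt)$t_response
  tr <- sliding_auroc(unit, ev_v, ev_m, ...)
  b <- permutation_bounds(tr, n_perm = n_perm, seed = seed)
  list(unit_id = unit$unit_id, window_centers = tr$window_centers,
       auroc = tr$auroc, lower = b$lower, upper = b$upper,
       significant = b$significant,
       latency = roc_latency(tr$window_centers, b$significant),
       strength = coding_strength(tr$window_centers, tr$auroc))
}
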