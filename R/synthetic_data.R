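#' Neuron ground-truth profile
#'
#' Describes the rate model of one simulated unit: a baseline Poisson rate
#' multiplicatively modulated by a linear premotor ramp before cued responses
#' of the preferred type(s), plus optional saccade- and fixation-locked
#' gains. Vocal ramps start earlier (default 1.0 s before call onset) than
#' hand ramps (default 0.3 s), mirroring the long vocal preparatory activity
#' and the brief pre-release build-up seen in frontal-cortex recordings.
#'
#' @param selectivity "vocal", "hand", "both", or "none".
#' @param sign_vocal,sign_hand "excited", "suppressed", or "none".
#' @param baseline_rate Baseline rate (Hz), > 0.
#' @param modulation_gain Peak multiplicative gain at response onset for
#'   excited modulation (> 1) or the suppressed floor (< 1 when the sign is
#'   "suppressed"); gains are clipped at 0.
#' @param ramp_onset_vocal,ramp_onset_hand Ramp start (s before response).
#' @param saccade_gain,fixation_gain Multiplicative gain applied in a 0.2 s
#'   window at saccade/fixation onsets (1 = no effect). Saccade modulation
#'   is direction-tuned: the gain applies only to saccades within 90 degrees
#'   of `saccade_pref_dir`, so saccade units are detectable by the
#'   direction-tuning screen.
#' @param saccade_pref_dir Preferred saccade direction (degrees).
#' @return A `neuron_profile` list.
#' @export
neuron_profile <- function(selectivity = "none",
                           sign_vocal = "none", sign_hand = "none",
                           baseline_rate = 10, modulation_gain = 2,
                           ramp_onset_vocal = 1.0, ramp_onset_hand = 0.3,
                           saccade_gain = 1, fixation_gain = 1,
                           saccade_pref_dir = 0) {
  stopifnot(baseline_rate > 0, modulation_gain >= 0,
            ramp_onset_vocal > 0, ramp_onset_hand > 0,
            saccade_gain >= 0, fixation_gain >= 0)
  structure(list(selectivity = selectivity, sign_vocal = sign_vocal,
                 sign_hand = sign_hand, baseline_rate = baseline_rate,
                 modulation_gain = modulation_gain,
                 ramp_onset_vocal = ramp_onset_vocal,
                 ramp_onset_hand = ramp_onset_hand,
                 saccade_gain = saccade_gain, fixation_gain = fixation_gain,
                 saccade_pref_dir = saccade_pref_dir),
            class = "neuron_profile")
}

#' Simulation configuration
#'
#' Defaults encode the study conditions of the task: blocks alternating
#' after 25 hits, 20% catch trials, near-perfect manual performance versus
#' roughly 50% vocal hit rates, lognormal reaction times with means of about
#' 0.52 s (manual) and 1.8 s (vocal), call durations of 97 +/- 40 ms, and
#' sessions of four blocks per condition.
#'
#' @param n_units Named integer vector of units per area.
#' @param class_proportions Named numeric vector over selectivity classes
#'   `c(none, vocal, hand, both)`, summing to 1.
#' @param p_suppressed Probability a selective response type is suppressed
#'   rather than excited.
#' @param p_saccade_unit,p_fixation_unit Probability a unit carries
#'   saccade-/fixation-locked modulation (gain 3 / 2).
#' @param hit_rate_vocal,hit_rate_manual Per-go-trial hit probabilities.
#' @param fa_rate Probability of a false alarm in a catch trial.
#' @param rt_vocal_mean,rt_vocal_sdlog,rt_manual_mean,rt_manual_sdlog
#'   Lognormal reaction-time parameters (mean on the natural scale, s).
#' @param call_duration_mean,call_duration_sd Call duration (s).
#' @param release_duration Bar-release movement duration (s).
#' @param n_blocks Total blocks (alternating vocal/manual).
#' @param baseline_rate_mean Mean of the exponential baseline-rate
#'   distribution, shifted by +1 Hz so all units clear the 1 Hz screen (Hz).
#' @param modulation_gain Peak gain for excited selective units; suppressed
#'   units use its reciprocal.
#' @param spont_call_rate,spont_release_rate Spontaneous event rates
#'   (events/min) in inter-trial intervals.
#' @param eye_noise_sd Fixational jitter (degrees).
#' @param saccade_rate Saccade rate (Hz) during fixation-saccade alternation.
#' @param fix_on_cue_prob Probability a fixation during a cue epoch lands on
#'   the cue.
#' @param iti_mean Mean inter-trial interval (s).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_units = c(PMrv = 8L, ASi = 8L, VPA = 8L),
                       class_proportions = c(none = 0.55, vocal = 0.22,
                                             hand = 0.13, both = 0.10),
                       p_suppressed = 0.5,
                       p_saccade_unit = 0.10, p_fixation_unit = 0.05,
                       hit_rate_vocal = 0.5, hit_rate_manual = 1.0,
                       fa_rate = 0.02,
                       rt_vocal_mean = 1.8, rt_vocal_sdlog = 0.25,
                       rt_manual_mean = 0.52, rt_manual_sdlog = 0.15,
                       call_duration_mean = 0.097, call_duration_sd = 0.040,
                       release_duration = 0.2,
                       n_blocks = 8L,
                       baseline_rate_mean = 8,
                       modulation_gain = 3,
                       spont_call_rate = 0.5, spont_release_rate = 0.5,
                       eye_noise_sd = 0.1, saccade_rate = 0.5,
                       fix_on_cue_prob = 0.8,
                       iti_mean = 1.5,
                       seed = 1L) {
  stopifnot(hit_rate_vocal >= 0, hit_rate_vocal <= 1,
            hit_rate_manual >= 0, hit_rate_manual <= 1,
            abs(sum(class_proportions) - 1) < 1e-9,
            all(class_proportions >= 0))
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

rlnorm_mean <- function(n, mean, sdlog) {
  # lognormal with given natural-scale mean
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

simulate_trials <- function(cfg, task) {
  rows <- list()
  spont <- list()
  t <- 5          # lead-in before first trial
  idx <- 0L
  for (b in seq_len(cfg$n_blocks)) {
    block <- if (b %% 2 == 1) "vocal" else "manual"
    kind <- if (block == "vocal") "call" else "bar_release"
    hr <- if (block == "vocal") cfg$hit_rate_vocal else cfg$hit_rate_manual
    hits <- 0L
    while (hits < task$block_switch_hits) {
      idx <- idx + 1L
      t_start <- t
      t_precue <- t_start + 0.2
      pre <- stats::runif(1, task$pre_cue_min, task$pre_cue_max)
      is_catch <- stats::runif(1) < task$catch_fraction
      t_go <- NA_real_; t_resp <- NA_real_; rt <- NA_real_
      resp_kind <- "none"; cue <- NA_character_
      if (is_catch) {
        t_end <- t_precue + pre + task$go_duration
        if (stats::runif(1) < cfg$fa_rate) {
          resp_kind <- kind
          t_resp <- t_precue + pre + stats::runif(1, 0.3, task$go_duration - 0.1)
          outcome <- "false_alarm"
        } else outcome <- "correct_rejection"
      } else {
        cue <- sample(c("A", "B"), 1)
        t_go <- t_precue + pre
        t_end <- t_go + task$go_duration
        if (stats::runif(1) < hr) {
          mu <- if (block == "vocal") cfg$rt_vocal_mean else cfg$rt_manual_mean
          sl <- if (block == "vocal") cfg$rt_vocal_sdlog else cfg$rt_manual_sdlog
          rt <- rlnorm_mean(1, mu, sl)
          while (rt >= task$go_duration - 0.05) rt <- rlnorm_mean(1, mu, sl)
          t_resp <- t_go + rt
          resp_kind <- kind
          outcome <- "hit"
          hits <- hits + 1L
        } else outcome <- "miss"
      }
      rows[[idx]] <- data.frame(
        index = idx, block = block, cue_id = cue, t_start = t_start,
        t_precue_on = t_precue, t_go_on = t_go, t_response = t_resp,
        response_kind = resp_kind, outcome = outcome, rt = rt,
        stringsAsFactors = FALSE)
      # inter-trial interval with possible spontaneous events
      iti <- stats::rexp(1, 1 / cfg$iti_mean) + 0.5
      for (sk in c("call", "bar_release")) {
        rate <- (if (sk == "call") cfg$spont_call_rate else
                   cfg$spont_release_rate) / 60
        n_ev <- stats::rpois(1, rate * iti)
        if (n_ev > 0)
          spont[[length(spont) + 1]] <- data.frame(
            time_s = t_end + sort(stats::runif(n_ev, 0.1, iti - 0.05)),
            kind = sk, stringsAsFactors = FALSE)
      }
      t <- t_end + iti
    }
  }
  list(trials = do.call(rbind, rows),
       spontaneous = if (length(spont)) do.call(rbind, spont) else
         data.frame(time_s = numeric(0), kind = character(0)),
       duration = t + 5)
}

sample_profiles <- function(cfg) {
  classes <- names(cfg$class_proportions)
  n_tot <- sum(cfg$n_units)
  sel <- sample(classes, n_tot, replace = TRUE, prob = cfg$class_proportions)
  areas <- rep(names(cfg$n_units), cfg$n_units)
  lapply(seq_len(n_tot), function(i) {
    s <- sel[i]
    pick_sign <- function() if (stats::runif(1) < cfg$p_suppressed)
      "suppressed" else "excited"
    sv <- if (s %in% c("vocal", "both")) pick_sign() else "none"
    sh <- if (s %in% c("hand", "both")) pick_sign() else "none"
    sac <- if (stats::runif(1) < cfg$p_saccade_unit) 3 else 1
    fix <- if (sac == 1 && stats::runif(1) < cfg$p_fixation_unit) 2 else 1
    p <- neuron_profile(
      selectivity = s, sign_vocal = sv, sign_hand = sh,
      baseline_rate = 1 + stats::rexp(1, 1 / cfg$baseline_rate_mean),
      modulation_gain = cfg$modulation_gain,
      saccade_gain = sac, fixation_gain = fix,
      saccade_pref_dir = sample(0:7, 1) * 45)
    p$area <- areas[i]
    p$unit_id <- sprintf("%s_u%03d", areas[i], i)
    p
  })
}

#' Simulate one unit's spike train
#'
#' Inhomogeneous Poisson process generated by thinning. The rate is
#' `baseline * m(t)` where `m(t)` ramps linearly from 1 (at
#' `response - ramp_onset`) to the profile's gain at cued response onset of a
#' preferred type, returns to 1 over the response duration, and equals 1
#' around spontaneous responses (no premotor modulation). Saccade and
#' fixation gains multiply the rate in 0.2 s windows at those event onsets.
#' Suppressed modulation uses the reciprocal gain (clipped at 0).
#'
#' @param profile A [neuron_profile()].
#' @param trials Trials data frame (hit trials drive the ramps).
#' @param duration Session duration (s).
#' @param response_durations Numeric vector (per hit trial) of response
#'   durations (s), recycled.
#' @param saccades Data frame with `t_onset` and `direction_deg` (the
#'   saccade gain applies only within 90 degrees of the preferred
#'   direction).
#' @param fixation_times Fixation onsets (s).
#' @return Sorted numeric spike times.
#' @export
simulate_unit_spikes <- function(profile, trials, duration,
                                 response_durations = 0.15,
                                 saccades = NULL,
                                 fixation_times = numeric(0)) {
  saccade_times <- numeric(0)
  if (!is.null(saccades) && nrow(saccades) && profile$saccade_gain != 1) {
    dd <- abs(((saccades$direction_deg - profile$saccade_pref_dir) + 180) %%
                360 - 180)
    saccade_times <- saccades$t_onset[dd <= 90]
  }
  knots_t <- c(0)
  knots_m <- c(1)
  add_ramp <- function(t_resp, onset, gain, dur) {
    knots_t <<- c(knots_t, t_resp - onset, t_resp, t_resp + dur)
    knots_m <<- c(knots_m, 1, gain, 1)
  }
  hits <- trials[trials$outcome == "hit", , drop = FALSE]
  rd <- rep_len(response_durations, max(1, nrow(hits)))
  sel <- profile$selectivity
  for (i in seq_len(nrow(hits))) {
    blk <- hits$block[i]
    modulated <- (blk == "vocal" && sel %in% c("vocal", "both")) ||
      (blk == "manual" && sel %in% c("hand", "both"))
    if (!modulated) next
    sign <- if (blk == "vocal") profile$sign_vocal else profile$sign_hand
    gain <- if (sign == "suppressed") max(0, 1 / profile$modulation_gain)
            else profile$modulation_gain
    onset <- if (blk == "vocal") profile$ramp_onset_vocal else
      profile$ramp_onset_hand
    add_ramp(hits$t_response[i], onset, gain, rd[i])
  }
  o <- order(knots_t)
  knots_t <- knots_t[o]; knots_m <- knots_m[o]
  ramp_at <- function(tt) {
    if (length(knots_t) == 1) return(rep(1, length(tt)))
    stats::approx(knots_t, knots_m, xout = tt, rule = 2)$y
  }
  eye_at <- function(tt) {
    g <- rep(1, length(tt))
    if (profile$saccade_gain != 1 && length(saccade_times))
      g <- g * ifelse(
        count_in_windows_points(tt, saccade_times, 0, 0.2),
        profile$saccade_gain, 1)
    # fixation response follows onset with a 50 ms visual latency
    if (profile$fixation_gain != 1 && length(fixation_times))
      g <- g * ifelse(
        count_in_windows_points(tt, fixation_times, 0.05, 0.25),
        profile$fixation_gain, 1)
    g
  }
  # ramp, saccade, and fixation windows may overlap, so bound multiplicatively
  lambda_max <- profile$baseline_rate * max(1, profile$modulation_gain) *
    max(1, profile$saccade_gain) * max(1, profile$fixation_gain)
  n_cand <- stats::rpois(1, lambda_max * duration)
  cand <- sort(stats::runif(n_cand, 0, duration))
  lam <- profile$baseline_rate * ramp_at(cand) * eye_at(cand)
  keep <- stats::runif(n_cand) < lam / lambda_max
  cand[keep]
}

count_in_windows_points <- function(tt, onsets, lo, hi) {
  # TRUE for points tt lying in [onset+lo, onset+hi) of any onset
  onsets <- sort(onsets)
  i <- findInterval(tt - lo, onsets)
  hit <- i >= 1
  hit[hit] <- (tt[hit] - lo - onsets[i[hit]]) < (hi - lo)
  hit
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Simulate a 1 kHz eye trace with fixations and saccades
#'
#' Piecewise-fixation trace: fixation epochs carry Gaussian jitter around a
#' fixation target, interrupted by saccades with minimum-jerk position
#' profiles. Amplitudes are 4.5-15 degrees and durations scale with
#' amplitude (`max(4, 0.8*A)` ms) so that every true saccade displaces gaze
#' by more than 4 degrees within 4 ms at peak velocity -- the detectability
#' property the downstream screen relies on. During cue epochs the fixation
#' target is the cue position (origin) with probability `fix_on_cue_prob`.
#'
#' @param trials Trials data frame (defines cue epochs).
#' @param duration Session duration (s).
#' @param cfg A [sim_config()].
#' @return List with `eye` (trace), `saccades` (truth data frame: t_onset,
#'   direction_deg, amplitude), `fixations` (t_onset, duration, on_cue).
#' @export
simulate_eye_trace <- function(trials, duration, cfg) {
  sr <- 1000
  n <- ceiling(duration * sr)
  ts <- (0:(n - 1)) / sr
  x <- numeric(n); y <- numeric(n)
  cue_lo <- trials$t_precue_on
  cue_hi <- ifelse(is.na(trials$t_go_on),
                   trials$t_precue_on + 8, trials$t_go_on + 3)
  in_cue <- function(t) any(t >= cue_lo & t < cue_hi)
  sac <- list(); fx <- list()
  t <- 0; pos <- c(0, 0)
  mean_fix <- if (cfg$saccade_rate > 0) 1 / cfg$saccade_rate else Inf
  while (t < duration) {
    fix_dur <- if (is.finite(mean_fix))
      max(0.25, stats::rexp(1, 1 / mean_fix)) else duration - t + 1
    fix_dur <- min(fix_dur, duration - t)
    on_cue <- in_cue(t + fix_dur / 2) && stats::runif(1) < cfg$fix_on_cue_prob
    target <- if (on_cue) c(0, 0) else pos
    i0 <- floor(t * sr) + 1; i1 <- min(n, floor((t + fix_dur) * sr))
    if (i1 >= i0) {
      m <- i1 - i0 + 1
      x[i0:i1] <- target[1] + stats::rnorm(m, 0, cfg$eye_noise_sd)
      y[i0:i1] <- target[2] + stats::rnorm(m, 0, cfg$eye_noise_sd)
      fx[[length(fx) + 1]] <- data.frame(t_onset = t, duration = fix_dur,
                                         on_cue = on_cue)
    }
    pos <- target
    t <- t + fix_dur
    if (t >= duration || !is.finite(mean_fix)) break
    # saccade
    amp <- stats::runif(1, 4.5, 15)
    dir8 <- sample(0:7, 1) * 45
    # keep gaze within +/-20 degrees: flip direction if needed
    dx <- amp * cospi(dir8 / 180); dy <- amp * sinpi(dir8 / 180)
    if (abs(pos[1] + dx) > 20) dx <- -dx
    if (abs(pos[2] + dy) > 20) dy <- -dy
    dur <- max(0.004, 0.0008 * amp)
    i0 <- floor(t * sr) + 1; i1 <- min(n, ceiling((t + dur) * sr))
    if (i1 > i0) {
      tau <- ((i0:i1) - i0) / ((t + dur - t) * sr)
      prof <- min_jerk(pmin(1, tau))
      x[i0:i1] <- pos[1] + dx * prof
      y[i0:i1] <- pos[2] + dy * prof
    }
    sac[[length(sac) + 1]] <- data.frame(
      t_onset = t, direction_deg = (atan2(dy, dx) * 180 / pi) %% 360,
      amplitude = sqrt(dx^2 + dy^2))
    pos <- pos + c(dx, dy)
    t <- t + dur
  }
  list(eye = list(sample_rate = sr, t0 = 0, x = x, y = y),
       saccades = if (length(sac)) do.call(rbind, sac) else
         data.frame(t_onset = numeric(0), direction_deg = numeric(0),
                    amplitude = numeric(0)),
       fixations = if (length(fx)) do.call(rbind, fx) else
         data.frame(t_onset = numeric(0), duration = numeric(0),
                    on_cue = logical(0)))
}

#' Generate a complete synthetic session with ground truth
#'
#' Deterministic given `cfg$seed`. Produces block-alternating vocal/manual
#' trials (blocks end after the configured number of hits), catch trials,
#' lognormal reaction times, spontaneous inter-trial responses, an eye trace
#' with labeled saccades/fixations, and inhomogeneous-Poisson units whose
#' premotor ramps follow their ground-truth profiles.
#'
#' @param cfg A [sim_config()].
#' @return List with `session` (a `premovoc_session`) and `truth`
#'   (profiles, saccades, fixations, response durations).
#' @export
generate_session <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  task <- task_config()
  beh <- simulate_trials(cfg, task)
  eye <- simulate_eye_trace(beh$trials, beh$duration, cfg)
  profiles <- sample_profiles(cfg)
  n_hits <- sum(beh$trials$outcome == "hit")
  resp_dur <- pmax(0.02, stats::rnorm(n_hits, cfg$call_duration_mean,
                                      cfg$call_duration_sd))
  units <- lapply(profiles, function(p) {
    list(unit_id = p$unit_id, area = p$area,
         spike_times = simulate_unit_spikes(
           p, beh$trials, beh$duration, resp_dur,
           saccades = eye$saccades,
           fixation_times = eye$fixations$t_onset))
  })
  s <- new_session(sprintf("sim_seed%d", cfg$seed), task, beh$trials, units,
                   eye$eye, beh$spontaneous, beh$duration)
  truth <- list(profiles = profiles, saccades = eye$saccades,
                fixations = eye$fixations, response_durations = resp_dur,
                config = cfg)
  list(session = s, truth = truth)
}
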