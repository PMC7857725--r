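#' Task configuration for the go/nogo protocol
#'
#' Encodes the trial-structure constants of the detection task: a pre-cue
#' (nogo) period of randomized duration, a 3 s go epoch, catch trials without
#' a go cue, two cue stimuli per response type, and block switches after a
#' fixed number of correctly performed go trials.
#'
#' @param pre_cue_min,pre_cue_max Pre-cue duration range (s); default 1 to 5.
#' @param go_duration Go-cue presentation time (s); default 3.
#' @param catch_fraction Fraction of trials without a go cue; default 0.2.
#' @param cues_per_type Number of distinct go cues per block type; default 2.
#' @param block_switch_hits Correct go trials required before a block switch;
#'   default 25.
#' @return A `task_config` list.
#' @export
task_config <- function(pre_cue_min = 1, pre_cue_max = 5, go_duration = 3,
                        catch_fraction = 0.2, cues_per_type = 2L,
                        block_switch_hits = 25L) {
  stopifnot(pre_cue_min > 0, pre_cue_min <= pre_cue_max,
            catch_fraction >= 0, catch_fraction < 1,
            block_switch_hits >= 1)
  structure(list(pre_cue_min = pre_cue_min, pre_cue_max = pre_cue_max,
                 go_duration = go_duration, catch_fraction = catch_fraction,
                 cues_per_type = as.integer(cues_per_type),
                 block_switch_hits = as.integer(block_switch_hits)),
            class = "task_config")
}

TRIAL_COLUMNS <- c("index", "block", "cue_id", "t_start", "t_precue_on",
                   "t_go_on", "t_response", "response_kind", "outcome", "rt")

OUTCOMES <- c("hit", "miss", "false_alarm", "correct_rejection",
              "wrong_effector", "aborted")

#' Construct a recording-session object
#'
#' A session bundles the trials table, per-unit spike trains, the 1 kHz eye
#' trace, spontaneous (un-cued) response events, and metadata for one
#' recording day. All times are seconds from recording start.
#'
#' @param session_id Character identifier.
#' @param task A [task_config()].
#' @param trials Data frame with columns `index`, `block` ("vocal"/"manual"),
#'   `cue_id` ("A"/"B"), `t_start`, `t_precue_on`, `t_go_on` (NA on catch
#'   trials), `t_response` (NA when absent), `response_kind`
#'   ("call"/"bar_release"/"none"), `outcome`, `rt`.
#' @param units List of unit records, each `list(unit_id, area, spike_times)`
#'   with sorted spike times; `mean_rate` is derived.
#' @param eye List with `sample_rate` (Hz), `t0` (s), and numeric vectors
#'   `x`, `y` (degrees of visual angle).
#' @param spontaneous Data frame with columns `time_s`, `kind`
#'   ("call"/"bar_release"); may have zero rows.
#' @param duration Session duration (s).
#' @param validate Check invariants (default TRUE).
#' @return A `premovoc_session` object.
#' @export
new_session <- function(session_id, task, trials, units, eye, spontaneous,
                        duration, validate = TRUE) {
  units <- lapply(units, function(u) {
    u$spike_times <- as.numeric(u$spike_times)
    u$mean_rate <- length(u$spike_times) / duration
    u[c("unit_id", "area", "spike_times", "mean_rate")]
  })
  s <- structure(list(session_id = session_id, task = task,
                      trials = trials, units = units, eye = eye,
                      spontaneous = spontaneous, duration = duration),
                 class = "premovoc_session")
  if (validate) validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks trial chronology, the catch-trial/go-cue correspondence, reaction
#' times, sorted in-range spike times, and eye-trace shape. Stops with a
#' message naming the offending trial or unit.
#'
#' @param s A `premovoc_session`.
#' @return Invisibly `s`.
#' @export
validate_session <- function(s) {
  tr <- s$trials
  if (!all(TRIAL_COLUMNS %in% names(tr)))
    stop("trials table missing columns: ",
         paste(setdiff(TRIAL_COLUMNS, names(tr)), collapse = ", "))
  for (i in seq_len(nrow(tr))) {
    row <- tr[i, ]
    lbl <- paste0("trial ", row$index)
    tms <- c(row$t_start, row$t_precue_on, row$t_go_on, row$t_response)
    tms <- tms[!is.na(tms)]
    if (any(diff(tms) <= 0)) stop("validation error: non-increasing times in ", lbl)
    if (!is.na(row$rt)) {
      if (is.na(row$t_go_on) || is.na(row$t_response))
        stop("validation error: rt without go/response in ", lbl)
      if (abs(row$rt - (row$t_response - row$t_go_on)) > 1e-9 || row$rt < 0)
        stop("validation error: inconsistent rt in ", lbl)
    }
    if (!row$outcome %in% OUTCOMES) stop("validation error: bad outcome in ", lbl)
  }
  for (u in s$units) {
    sp <- u$spike_times
    if (is.unsorted(sp, strictly = FALSE))
      stop("validation error: unsorted spike times in unit ", u$unit_id)
    if (length(sp) && (sp[1] < 0 || sp[length(sp)] > s$duration))
      stop("validation error: spike outside session in unit ", u$unit_id)
  }
  if (length(s$eye$x) != length(s$eye$y))
    stop("validation error: eye x/y length mismatch")
  if (nrow(s$spontaneous) &&
      (any(s$spontaneous$time_s < 0) || any(s$spontaneous$time_s > s$duration)))
    stop("validation error: spontaneous event outside session")
  invisible(s)
}

#' Write a session bundle to disk
#'
#' The bundle is a directory holding `meta.json` (id, duration, task config,
#' unit table), `trials.csv`, `spikes.csv` (unit_id, time_s), `eye.csv`
#' (t_s, x_deg, y_deg), and `spontaneous.csv` (time_s, kind). Times are
#' written with full precision so [read_session()] round-trips exactly.
#'
#' @param s A `premovoc_session`.
#' @param path Directory to create/fill.
#' @export
write_session <- function(s, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("I/O error: cannot create ", path)
  meta <- list(
    session_id = s$session_id, duration = s$duration,
    task = unclass(s$task),
    units = data.frame(unit_id = vapply(s$units, `[[`, "", "unit_id"),
                       area = vapply(s$units, `[[`, "", "area")),
    eye = list(sample_rate = s$eye$sample_rate, t0 = s$eye$t0))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  wr <- function(df, f) utils::write.csv(df, file.path(path, f),
                                         row.names = FALSE, quote = FALSE)
  tr <- s$trials
  tr_out <- tr
  num <- vapply(tr_out, is.numeric, TRUE)
  tr_out[num] <- lapply(tr_out[num], function(v) sprintf("%.17g", v))
  tr_out[] <- lapply(tr_out, function(v) ifelse(is.na(v) | v == "NA", "", v))
  wr(tr_out, "trials.csv")
  sp <- data.frame(
    unit_id = rep(vapply(s$units, `[[`, "", "unit_id"),
                  vapply(s$units, function(u) length(u$spike_times), 0L)),
    time_s = sprintf("%.17g", unlist(lapply(s$units, `[[`, "spike_times"),
                                     use.names = FALSE)))
  if (nrow(sp) == 0) sp <- data.frame(unit_id = character(0), time_s = character(0))
  wr(sp, "spikes.csv")
  t_s <- s$eye$t0 + (seq_along(s$eye$x) - 1) / s$eye$sample_rate
  wr(data.frame(t_s = sprintf("%.17g", t_s),
                x_deg = sprintf("%.17g", s$eye$x),
                y_deg = sprintf("%.17g", s$eye$y)), "eye.csv")
  sponto <- s$spontaneous
  if (nrow(sponto)) sponto$time_s <- sprintf("%.17g", sponto$time_s)
  wr(sponto, "spontaneous.csv")
  invisible(NULL)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]; validates all invariants on load.
#'
#' @param path Bundle directory.
#' @return A `premovoc_session`.
#' @export
read_session <- function(path) {
  need <- c("meta.json", "trials.csv", "spikes.csv", "eye.csv", "spontaneous.csv")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("format error: missing bundle file ", f)
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  rd <- function(f) utils::read.csv(file.path(path, f), stringsAsFactors = FALSE)
  tr <- rd("trials.csv")
  for (cl in c("t_go_on", "t_response", "rt"))
    tr[[cl]] <- suppressWarnings(as.numeric(tr[[cl]]))
  for (cl in c("response_kind", "cue_id"))
    tr[[cl]][is.na(tr[[cl]]) | tr[[cl]] == ""] <- if (cl == "response_kind") "none" else NA
  sp <- rd("spikes.csv")
  ut <- meta$units
  units <- lapply(seq_len(nrow(ut)), function(i) {
    list(unit_id = ut$unit_id[i], area = ut$area[i],
         spike_times = sp$time_s[sp$unit_id == ut$unit_id[i]])
  })
  ey <- rd("eye.csv")
  eye <- list(sample_rate = meta$eye$sample_rate, t0 = meta$eye$t0,
              x = ey$x_deg, y = ey$y_deg)
  sponto <- rd("spontaneous.csv")
  if (nrow(sponto) == 0)
    sponto <- data.frame(time_s = numeric(0), kind = character(0))
  tk <- do.call(task_config, as.list(meta$task))
  new_session(meta$session_id, tk, tr, units, eye, sponto, meta$duration)
}

#' Event-aligned firing-rate matrix
#'
#' Bins a unit's spikes relative to a set of alignment events. Bin `j` of
#' event `i` covers the half-open interval
#' `[event_i + t_lo + (j-1)*bin, event_i + t_lo + j*bin)`; a trailing
#' partial bin is dropped.
#'
#' @param unit Unit record (`list(unit_id, spike_times, ...)`).
#' @param events Numeric event times (s); may be empty.
#' @param window Length-2 numeric `c(t_lo, t_hi)` relative to the event.
#' @param bin_width Bin width (s).
#' @param align_event Label stored in the result (metadata only).
#' @return List with `unit_id`, `align_event`, `window`, `bin_width`,
#'   `times` (bin left edges relative to event), and `matrix`
#'   (events x bins, Hz).
#' @export
align_rates <- function(unit, events, window, bin_width,
                        align_event = "response") {
  stopifnot(window[1] < window[2], bin_width > 0)
  n_bins <- floor((window[2] - window[1]) / bin_width + 1e-9)
  edges <- window[1] + bin_width * (0:n_bins)
  m <- matrix(0, nrow = length(events), ncol = n_bins)
  sp <- unit$spike_times
  for (i in seq_along(events)) {
    rel <- sp - events[i]
    rel <- rel[rel >= edges[1] & rel < edges[n_bins + 1]]
    if (length(rel))
      m[i, ] <- tabulate(findInterval(rel, edges,
                                      rightmost.closed = FALSE), n_bins)
  }
  list(unit_id = unit$unit_id, align_event = align_event, window = window,
       bin_width = bin_width, times = edges[-(n_bins + 1)],
       matrix = m / bin_width, trial_indices = seq_along(events))
}

#' Gaussian-smooth a PSTH
#'
#' Convolves a rate sequence with a normalized Gaussian kernel truncated at
#' +/- 4 sigma, preserving length (edges renormalized so a constant input is
#' unchanged).
#'
#' @param psth Numeric rate sequence.
#' @param bin_width Bin width (s) of `psth`.
#' @param sigma Kernel standard deviation (s); default 0.150.
#' @return Smoothed sequence, same length.
#' @export
smooth_psth <- function(psth, bin_width, sigma = 0.150) {
  stopifnot(sigma > 0, bin_width > 0)
  half <- ceiling(4 * sigma / bin_width)
  k <- stats::dnorm((-half:half) * bin_width, sd = sigma)
  k <- k / sum(k)
  n <- length(psth)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    w <- k[j - i + half + 1]
    out[i] <- sum(psth[j] * w) / sum(w)
  }
  out
}

#' Filter trials by block, outcome, and minimum reaction time
#'
#' Order-preserving trial selection; used to restrict analyses to hit trials
#' with reaction times of at least 450 ms (premotor window length).
#'
#' @param s A `premovoc_session`.
#' @param block "vocal", "manual", or NULL for both.
#' @param outcome Character vector of outcomes to keep, or NULL for all.
#' @param min_rt Minimum reaction time (s), or NULL.
#' @return Subset of the trials data frame.
#' @export
select_trials <- function(s, block = NULL, outcome = NULL, min_rt = NULL) {
  tr <- s$trials
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(block)) keep <- keep & tr$block == block
  if (!is.null(outcome)) keep <- keep & tr$outcome %in% outcome
  if (!is.null(min_rt)) keep <- keep & !is.na(tr$rt) & tr$rt >= min_rt
  tr[keep, , drop = FALSE]
}
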