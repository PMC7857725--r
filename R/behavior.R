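#' Hit and false-alarm counts for one block type
#'
#' Hits are correct responses during the go epoch of the matching block.
#' False alarms for a block's response type are that response produced in
#' catch trials of the same block plus in any trial of the other block; the
#' denominator is the number of those opportunity trials. This matches the
#' session narrative in which 4 bar releases among 179 vocal-block trials
#' give a 2.2% manual false-alarm rate.
#'
#' @param s A `premovoc_session`.
#' @param block "vocal" or "manual".
#' @return List with `n_hits`, `n_go`, `n_fa`, `n_fa_opportunities`.
#' @export
response_rates <- function(s, block) {
  tr <- s$trials
  kind <- if (block == "vocal") "call" else "bar_release"
  go <- tr$block == block & !is.na(tr$t_go_on)
  n_go <- sum(go)
  n_hits <- sum(go & tr$outcome == "hit")
  opp <- (tr$block == block & is.na(tr$t_go_on)) | tr$block != block
  n_fa_opp <- sum(opp)
  n_fa <- sum(opp & tr$response_kind == kind &
                tr$outcome %in% c("false_alarm", "wrong_effector"))
  list(n_hits = n_hits, n_go = n_go, n_fa = n_fa,
       n_fa_opportunities = n_fa_opp)
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(HR) - z(FA)` with standard-normal quantiles. Degenerate rates
#' (0 or 1) are handled by the chosen correction: `"loglinear"` adds 0.5 to
#' the hit/false-alarm counts and 1 to the trial counts before forming
#' rates; `"clip"` bounds rates to `[1/(2n), 1 - 1/(2n)]`; `"none"` raises
#' an error on degenerate rates.
#'
#' @param hr Hit rate in `[0, 1]`.
#' @param fa False-alarm rate in `[0, 1]`.
#' @param n_go,n_fa_opp Trial counts behind the two rates (required for the
#'   corrections).
#' @param correction "loglinear" (default), "clip", or "none".
#' @return d' (numeric scalar).
#' @export
d_prime <- function(hr, fa, n_go = NULL, n_fa_opp = NULL,
                    correction = c("loglinear", "clip", "none")) {
  correction <- match.arg(correction)
  stopifnot(hr >= 0, hr <= 1, fa >= 0, fa <= 1)
  if (correction != "none") stopifnot(n_go > 0, n_fa_opp > 0)
  adj <- switch(correction,
    loglinear = c((hr * n_go + 0.5) / (n_go + 1),
                  (fa * n_fa_opp + 0.5) / (n_fa_opp + 1)),
    clip = c(min(max(hr, 1 / (2 * n_go)), 1 - 1 / (2 * n_go)),
             min(max(fa, 1 / (2 * n_fa_opp)), 1 - 1 / (2 * n_fa_opp))),
    none = {
      if (hr %in% c(0, 1) || fa %in% c(0, 1))
        stop("domain error: degenerate rate with correction = 'none'")
      c(hr, fa)
    })
  stats::qnorm(adj[1]) - stats::qnorm(adj[2])
}

#' Reaction-time summary over hit trials
#'
#' @param s A `premovoc_session`.
#' @param block "vocal" or "manual".
#' @return List with `mean`, `median`, `sd`, `n` (seconds), or NULL when the
#'   block has no hits.
#' @export
reaction_time_summary <- function(s, block) {
  rt <- select_trials(s, block = block, outcome = "hit")$rt
  rt <- rt[!is.na(rt)]
  if (length(rt) == 0) return(NULL)
  list(mean = mean(rt), median = stats::median(rt),
       sd = if (length(rt) > 1) stats::sd(rt) else 0, n = length(rt))
}

#' Behavioral summary per block
#'
#' Combines [response_rates()], [d_prime()] and [reaction_time_summary()]
#' into one row per block; a d' of at least 1.5 marks the session as under
#' stimulus control for that response type.
#'
#' @param s A `premovoc_session`.
#' @param correction d' correction passed to [d_prime()].
#' @param d_threshold Detection threshold on d'; default 1.5.
#' @return Data frame, one row per block.
#' @export
behavior_summary <- function(s, correction = "loglinear", d_threshold = 1.5) {
  do.call(rbind, lapply(c("vocal", "manual"), function(b) {
    r <- response_rates(s, b)
    if (r$n_go == 0)
      return(data.frame(block = b, n_go = 0L, n_hits = 0L, hit_rate = NA,
                        n_fa_opportunities = 0L, n_fa = 0L, fa_rate = NA,
                        d_prime = NA, rt_mean = NA, rt_median = NA,
                        rt_sd = NA, above_threshold = NA,
                        correction = correction))
    hr <- r$n_hits / r$n_go
    fa <- r$n_fa / r$n_fa_opportunities
    dp <- d_prime(hr, fa, r$n_go, r$n_fa_opportunities, correction)
    rts <- reaction_time_summary(s, b)
    data.frame(block = b, n_go = r$n_go, n_hits = r$n_hits, hit_rate = hr,
               n_fa_opportunities = r$n_fa_opportunities, n_fa = r$n_fa,
               fa_rate = fa, d_prime = dp,
               rt_mean = if (is.null(rts)) NA else rts$mean,
               rt_median = if (is.null(rts)) NA else rts$median,
               rt_sd = if (is.null(rts)) NA else rts$sd,
               above_threshold = dp >= d_threshold,
               correction = correction)
  }))
}
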