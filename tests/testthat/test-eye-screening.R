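flat_eye <- function(n = 5000, sd = 0, sr = 1000) {
  list(sample_rate = sr, t0 = 0,
       x = rnorm(n, 0, sd), y = rnorm(n, 0, sd))
}

test_that("saccade detection fires on fast steps and ignores slow/small ones", {
  expect_equal(nrow(detect_saccades(flat_eye())), 0)

  # 6-degree step completed in 2 ms at t = 1.0 s
  eye <- flat_eye(3000)
  eye$x[1002:3000] <- 6
  eye$x[1001] <- 3
  sac <- detect_saccades(eye)
  expect_equal(nrow(sac), 1)
  # onset resolution is bounded by the 4 ms displacement window
  expect_lte(abs(sac$t_onset - 1.0), 0.004)
  expect_equal(sac$direction_bin, 1)

  # 3-degree displacement over 4 ms: below threshold
  eye2 <- flat_eye(3000)
  eye2$x[1001:3000] <- 3
  expect_equal(nrow(detect_saccades(eye2)), 0)

  # noise with bounded 4 ms displacement never triggers (sd = 0.5 deg)
  set.seed(12)
  eye3 <- flat_eye(20000, sd = 0.5)
  d4 <- sqrt((eye3$x[5:20000] - eye3$x[1:19996])^2 +
               (eye3$y[5:20000] - eye3$y[1:19996])^2)
  expect_lt(max(d4), 4)
  expect_equal(nrow(detect_saccades(eye3)), 0)

  # one physical saccade yields one event (merge refractory)
  sim <- small_session()
  det <- suppressWarnings(detect_saccades(sim$session$eye))
  expect_lt(abs(nrow(det) - nrow(sim$truth$saccades)), 3)
  # detected onsets sit within 5 ms of true onsets
  near <- vapply(det$t_onset, function(t)
    min(abs(sim$truth$saccades$t_onset - t)), 0)
  expect_lt(stats::median(near), 0.005)
})

test_that("direction bins partition the circle with bin 1 centered rightward", {
  expect_equal(direction_bin(1, 0), 1L)
  expect_equal(direction_bin(0, 1), 3L)
  ang <- 22.5 * pi / 180
  expect_equal(direction_bin(cos(ang), sin(ang)), 2L)  # boundary goes up
  expect_error(direction_bin(0, 0), "zero vector")
  set.seed(4)
  th <- runif(500, 0, 2 * pi)
  bins <- vapply(seq_along(th), function(i)
    direction_bin(cos(th[i]), sin(th[i])), 1L)
  expect_true(all(bins %in% 1:8))
  # centers map to their own bin
  for (k in 1:8) {
    a <- (k - 1) * 45 * pi / 180
    expect_equal(direction_bin(cos(a), sin(a)), k)
  }
})

test_that("saccade tuning test equals the rank-statistic oracle", {
  # constant rates: H = 0, p = 1
  sac <- data.frame(t_onset = seq(10, 90, by = 10), direction_bin = rep(1:3, 3))
  u0 <- make_unit(as.vector(outer(seq(10, 90, by = 10), c(-0.05, 0.05), `+`)))
  r0 <- saccade_tuning_test(u0, sac)
  expect_equal(r0$p, 1)
  expect_equal(r0$statistic, 0)

  # groups [1,2,3], [4,5,6], [7,8,9] (spike counts in the 200 ms window)
  sac2 <- data.frame(t_onset = seq(10, 90, by = 10),
                     direction_bin = rep(1:3, each = 3))
  sp <- unlist(lapply(seq_len(9), function(i)
    seq(10 * i - 0.09, by = 0.18 / max(1, i), length.out = i)))
  u <- make_unit(sp)
  res <- saccade_tuning_test(u, sac2)
  rates <- rate_in_window(u$spike_times, sac2$t_onset, c(-0.1, 0.1))
  expect_equal(rates, 5 * (1:9))
  h_or <- kw_statistic_oracle(rates, sac2$direction_bin)
  expect_equal(res$statistic, h_or, tolerance = 1e-12)
  expect_equal(res$p, pchisq(h_or, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$df, 2)

  # fewer than two non-empty groups: skipped
  sac3 <- data.frame(t_onset = c(10, 20), direction_bin = c(1, 1))
  expect_true(is.na(saccade_tuning_test(u, sac3)$p))
})

test_that("kruskal-wallis matches the oracle on random tied data (n <= 10)", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(6:10, 1)
    g <- sample(1:3, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    v <- sample(0:4, n, replace = TRUE)
    if (var(v) == 0) next
    kw <- kruskal.test(v, factor(g))
    expect_equal(unname(kw$statistic), kw_statistic_oracle(v, g),
                 tolerance = 1e-10)
  }
})

test_that("fixation detection finds cue fixations and misses off-cue gaze", {
  eye <- flat_eye(5000, sd = 0.05)
  epochs <- data.frame(t_lo = 1, t_hi = 4)
  fx <- detect_fixations(eye, epochs)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration, 3, tolerance = 0.01)

  eye5 <- flat_eye(5000, sd = 0.05)
  eye5$x <- eye5$x + 5
  expect_equal(nrow(detect_fixations(eye5, epochs)), 0)

  # recall of true on-cue fixations in the simulated session
  sim <- small_session()
  s <- sim$session
  sac <- suppressWarnings(detect_saccades(s$eye))
  tr <- s$trials
  epochs2 <- data.frame(t_lo = tr$t_precue_on,
                        t_hi = ifelse(is.na(tr$t_go_on), tr$t_precue_on + 8,
                                      tr$t_go_on + 3))
  fx2 <- detect_fixations(s$eye, epochs2, sac)
  truth <- sim$truth$fixations
  truth <- truth[truth$on_cue & truth$duration >= 0.3, ]
  covered <- vapply(seq_len(nrow(truth)), function(i) {
    any(fx2$t_onset < truth$t_onset[i] + truth$duration[i] - 0.2 &
          fx2$t_onset + fx2$duration > truth$t_onset[i] + 0.2)
  }, TRUE)
  expect_gte(mean(covered), 0.95)
})

test_that("fixation test equals the exact signed-rank tail", {
  fx <- data.frame(t_onset = seq(10, 100, by = 10), duration = 0.5)
  # all post > pre: 2 spikes in [0.1, 0.2), none before
  sp <- as.vector(outer(fx$t_onset, c(0.12, 0.17), `+`))
  u <- make_unit(sp)
  r <- fixation_test(u, fx)
  expect_equal(r$p, 1 / 1024, tolerance = 1e-12)
  # enumeration oracle: one-sided minimum over 2^10 sign patterns
  expect_equal(r$p, 1 / 2^10)

  # identical rates: not flagged
  sp2 <- as.vector(outer(fx$t_onset, c(-0.05, 0.15), `+`))
  expect_gte(fixation_test(make_unit(sp2), fx)$p, 0.5)

  # too few epochs: skipped
  expect_true(is.na(fixation_test(u, fx[1:4, ])$p))
})

test_that("screening excludes eye-modulated units and spares others", {
  sim <- small_session()
  trials <- sim$session$trials
  dur <- sim$session$duration
  set.seed(31)
  sac_unit <- make_unit(simulate_unit_spikes(
    neuron_profile(baseline_rate = 12, saccade_gain = 3), trials, dur,
    saccades = sim$truth$saccades), id = "sac")
  fix_unit <- make_unit(simulate_unit_spikes(
    neuron_profile(baseline_rate = 12, fixation_gain = 2.5), trials, dur,
    fixation_times = sim$truth$fixations$t_onset), id = "fix")
  s <- sim$session
  s$units <- list(sac_unit, fix_unit)
  scr <- suppressWarnings(screen_units(s))
  expect_true(scr$excluded[scr$unit_id == "sac"])
  expect_true(scr$excluded[scr$unit_id == "fix"])
  # fixation test runs only when the saccade test is negative
  expect_true(is.na(scr$fixation_p[scr$is_saccade_unit]) ||
                !any(scr$is_saccade_unit))

  # no saccades detected: nobody flagged as a saccade unit
  s2 <- s
  s2$eye <- flat_eye(round(dur * 10), sr = 1000)
  s2$eye$x <- rep(0, length(s2$eye$x)); s2$eye$y <- s2$eye$x
  scr2 <- screen_units(s2)
  expect_false(any(scr2$is_saccade_unit))
})
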