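test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_blocks = 2, seed = 77,
                    n_units = c(PMrv = 2L, ASi = 2L, VPA = 2L))
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$session$trials, b$session$trials)
  expect_identical(lapply(a$session$units, `[[`, "spike_times"),
                   lapply(b$session$units, `[[`, "spike_times"))
  expect_identical(a$session$eye$x, b$session$eye$x)
  expect_identical(a$truth$saccades, b$truth$saccades)
})

test_that("behavioral structure matches the configured task", {
  sim <- small_session()
  tr <- sim$session$trials
  # blocks alternate vocal/manual
  blocks <- rle(tr$block)$values
  expect_true(all(blocks == rep(c("vocal", "manual"),
                                length.out = length(blocks))))
  # perfect manual hit rate is forced by hit_rate_manual = 1
  man_go <- tr$block == "manual" & !is.na(tr$t_go_on)
  expect_true(all(tr$outcome[man_go] == "hit"))
  # catch trials have no go cue and vice versa
  expect_true(all(is.na(tr$t_go_on) ==
                    (tr$outcome %in% c("correct_rejection", "false_alarm"))))
})

test_that("catch fraction stays in the binomial 99% interval at large n", {
  cfg <- sim_config(n_blocks = 60, hit_rate_vocal = 1, seed = 5)
  beh <- premovoc:::simulate_trials(cfg, task_config())
  n <- nrow(beh$trials)
  expect_gt(n, 1800)
  frac <- mean(is.na(beh$trials$t_go_on))
  half <- 2.576 * sqrt(0.2 * 0.8 / n)
  expect_gt(frac, 0.2 - half)
  expect_lt(frac, 0.2 + half)
})

test_that("reaction times match the configured lognormal means", {
  sim <- small_session()
  s <- sim$session
  cfg <- sim$truth$config
  for (b in c("vocal", "manual")) {
    rt <- select_trials(s, b, "hit")$rt
    target <- if (b == "vocal") cfg$rt_vocal_mean else cfg$rt_manual_mean
    expect_lt(abs(mean(rt) - target), 3 * sd(rt) / sqrt(length(rt)))
  }
  expect_lt(mean(select_trials(s, "manual", "hit")$rt),
            mean(select_trials(s, "vocal", "hit")$rt))
})

test_that("unit rate model realizes premotor ramps and flat spontaneous epochs", {
  sim <- small_session()
  trials <- sim$session$trials
  dur <- sim$session$duration
  # gain 1: homogeneous Poisson, premotor rate within 3 SE of baseline
  set.seed(1)
  flat <- neuron_profile(selectivity = "vocal", sign_vocal = "excited",
                         baseline_rate = 10, modulation_gain = 1)
  sp <- simulate_unit_spikes(flat, trials, dur)
  ev <- trials$t_response[trials$block == "vocal" & trials$outcome == "hit"]
  r <- rate_in_window(sort(sp), ev, c(-0.45, 0))
  expect_lt(abs(mean(r) - 10), 3 * sd(r) / sqrt(length(r)))

  # excited vocal gain 3: premotor exceeds baseline (one-sided p < 0.01)
  set.seed(2)
  exc <- neuron_profile(selectivity = "vocal", sign_vocal = "excited",
                        baseline_rate = 10, modulation_gain = 3)
  sp2 <- sort(simulate_unit_spikes(exc, trials, dur))
  pre <- rate_in_window(sp2, ev, c(-0.45, 0))
  base <- rate_in_window(sp2, trials$t_go_on[trials$block == "vocal" &
                                               trials$outcome == "hit"],
                         c(-0.45, 0))
  expect_lt(t.test(pre, base, alternative = "greater")$p.value, 0.01)

  # spontaneous calls carry no premotor modulation
  spont <- sim$session$spontaneous
  sp_ev <- spont$time_s[spont$kind == "call"]
  if (length(sp_ev) >= 3) {
    rs <- rate_in_window(sp2, sp_ev, c(-0.45, 0))
    expect_lt(abs(mean(rs) - 10),
              3 * max(sd(rs) / sqrt(length(rs)), 1))
  }
})

test_that("eye traces have detectable saccades and quiet fixations", {
  sim <- small_session()
  eye <- sim$session$eye
  truth <- sim$truth$saccades
  sr <- eye$sample_rate
  # every true saccade displaces gaze by > 4 degrees within 4 ms near onset
  for (i in seq_len(min(50, nrow(truth)))) {
    i0 <- floor(truth$t_onset[i] * sr) + 1
    span <- i0:min(length(eye$x) - 4, i0 + 20)
    disp <- sqrt((eye$x[span + 4] - eye$x[span])^2 +
                   (eye$y[span + 4] - eye$y[span])^2)
    expect_gt(max(disp), 4)
  }
  # zero noise, zero saccade rate: constant trace
  cfg0 <- sim_config(n_blocks = 2, seed = 3, eye_noise_sd = 0,
                     saccade_rate = 0)
  beh <- premovoc:::simulate_trials(cfg0, task_config())
  tr0 <- simulate_eye_trace(beh$trials, beh$duration, cfg0)
  expect_equal(diff(range(tr0$eye$x)), 0)
  expect_equal(nrow(tr0$saccades), 0)
})

test_that("generated unit classes follow the configured proportions", {
  cfg <- sim_config(n_units = c(VPA = 400L), seed = 9)
  set.seed(cfg$seed)
  profs <- premovoc:::sample_profiles(cfg)
  obs <- table(factor(vapply(profs, `[[`, "", "selectivity"),
                      levels = names(cfg$class_proportions)))
  p <- chisq.test(obs, p = cfg$class_proportions)$p.value
  expect_gt(p, 0.001)
})
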