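test_that("inclusion filter enforces rate, hit-count, and screening criteria", {
  sim <- small_session()
  s <- sim$session
  # brute-force predicate equality
  scr <- data.frame(unit_id = vapply(s$units, `[[`, "", "unit_id"),
                    excluded = rep(c(FALSE, TRUE), length.out =
                                     length(s$units)))
  got <- inclusion_filter(s, scr)
  nv <- nrow(select_trials(s, "vocal", "hit", 0.45))
  nm <- nrow(select_trials(s, "manual", "hit", 0.45))
  want <- vapply(s$units, function(u)
    u$mean_rate > 1 && nv >= 7 && nm >= 7 &&
      !scr$excluded[scr$unit_id == u$unit_id], TRUE)
  expect_identical(got, vapply(s$units, `[[`, "", "unit_id")[want])

  # a 0.5 Hz unit is dropped
  slow <- s
  slow$units <- list(make_unit(seq(1, s$duration - 1,
                                   length.out = round(0.5 * s$duration))))
  slow$units[[1]]$mean_rate <- 0.5
  expect_length(inclusion_filter(slow), 0)

  # fewer than 7 vocal hits drops every unit
  few <- s
  hit_idx <- which(few$trials$block == "vocal" & few$trials$outcome == "hit")
  few$trials$outcome[hit_idx[-(1:6)]] <- "miss"
  few$trials$t_response[hit_idx[-(1:6)]] <- NA
  few$trials$response_kind[hit_idx[-(1:6)]] <- "none"
  few$trials$rt[hit_idx[-(1:6)]] <- NA
  expect_length(inclusion_filter(few), 0)
})

test_that("premotor pairs count spikes in the two 450 ms windows", {
  hits <- data.frame(block = "vocal", t_go_on = c(10, 30), rt = c(1.5, 1.5))
  u <- make_unit(c(10 - 0.4, 10 - 0.2,                     # 2 baseline spikes
                   11.5 - 0.44 + (1:9) * 0.04))            # 9 premotor spikes
  s <- toy_session(hits, units = list(u))
  p <- premotor_pairs(s$units[[1]], s, "vocal")
  expect_equal(p$baseline, c(2 / 0.45, 0), tolerance = 1e-12)
  expect_equal(p$premotor, c(9 / 0.45, 0), tolerance = 1e-12)
  expect_equal(round(p$baseline[1], 2), 4.44)
  expect_equal(p$premotor[1], 20)

  # short-RT trials are excluded from the pairing
  hits2 <- data.frame(block = "manual", t_go_on = c(10, 30), rt = c(0.3, 0.6))
  s2 <- toy_session(hits2, units = list(u))
  expect_equal(nrow(premotor_pairs(s2$units[[1]], s2, "manual")), 1)
})

test_that("signed-rank classification test matches exact enumeration", {
  same <- data.frame(baseline = c(1, 2, 3, 4, 5, 6, 7),
                     premotor = c(1, 2, 3, 4, 5, 6, 7))
  r <- response_correlation_test(same)
  expect_equal(r$p, 1)
  expect_equal(r$sign, "none")

  up <- data.frame(baseline = 1:8, premotor = 1:8 + runif(8, 1, 2))
  r2 <- response_correlation_test(up)
  expect_equal(r2$p, 2 / 256, tolerance = 1e-12)
  expect_equal(r2$sign, "excited")

  # too few pairs: skipped
  expect_true(is.na(response_correlation_test(up[1:5, ])$p))

  # random tie-free cases equal the enumeration oracle
  set.seed(21)
  for (i in 1:15) {
    n <- sample(7:8, 1)
    b <- rnorm(n); m <- rnorm(n, 0.5)
    p_pkg <- response_correlation_test(data.frame(baseline = b,
                                                  premotor = m))$p
    expect_equal(p_pkg, exact_signed_rank_p(m, b), tolerance = 1e-10)
  }
})

test_that("cue preference test matches the exact Mann-Whitney tail", {
  hits <- data.frame(block = "vocal", t_go_on = seq(10, 60, by = 10), rt = 1)
  # cue A counts 1,2,3; cue B counts 10,11,12
  cue <- c("A", "B", "A", "B", "A", "B")
  counts <- c(1, 10, 2, 11, 3, 12)
  tr_resp <- hits$t_go_on + 1
  sp <- unlist(lapply(seq_along(counts), function(i)
    tr_resp[i] - 0.45 + (seq_len(counts[i]) - 0.5) * 0.44 / counts[i]))
  s <- toy_session(hits, units = list(make_unit(sp)), cue_ids = cue)
  r <- cue_preference_test(s$units[[1]], s, "vocal")
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_equal(r$p, exact_mann_whitney_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-10)

  # identical groups: p = 1; one cue absent: skipped
  sp2 <- unlist(lapply(tr_resp, function(t) t - 0.3))
  s2 <- toy_session(hits, units = list(make_unit(sp2)), cue_ids = cue)
  expect_equal(cue_preference_test(s2$units[[1]], s2, "vocal")$p, 1)
  s3 <- toy_session(hits, units = list(make_unit(sp)),
                    cue_ids = rep("A", 6))
  expect_true(is.na(cue_preference_test(s3$units[[1]], s3, "vocal")$p))

  # random tie-free cases equal the enumeration oracle
  set.seed(5)
  for (i in 1:15) {
    x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1), 0.8)
    expect_equal(suppressWarnings(wilcox.test(x, y)$p.value),
                 exact_mann_whitney_p(x, y), tolerance = 1e-10)
  }
})

test_that("PSTH latency follows the consecutive-bin threshold rule", {
  times <- seq(-3, 1 - 0.05, by = 0.05)
  flat <- rep(10, length(times))
  expect_true(is.na(psth_latency_from_curve(flat, times, 10, 1, "excited")))

  step_up <- ifelse(times >= -1.2, 30, 10)
  lat <- psth_latency_from_curve(step_up, times, 10, 1, "excited")
  expect_lte(abs(lat - 1.2), 0.05)

  step_dn <- ifelse(times >= -0.8, 2, 10)
  lat2 <- psth_latency_from_curve(step_dn, times, 10, 1, "suppressed")
  expect_lte(abs(lat2 - 0.8), 0.05)
  # the suppressed run must use the lower band: no excited crossing here
  expect_true(is.na(psth_latency_from_curve(step_dn, times, 10, 1,
                                            "excited")))

  # runs that start after the response do not count
  late <- ifelse(times >= 0.1, 30, 10)
  expect_true(is.na(psth_latency_from_curve(late, times, 10, 1, "excited")))

  # a run shorter than run_len is ignored
  brief <- ifelse(times >= -0.5 & times < -0.1, 30, 10)
  expect_true(is.na(psth_latency_from_curve(brief, times, 10, 1, "excited")))
  expect_equal(psth_latency_from_curve(brief, times, 10, 1, "excited",
                                       run_len = 5), 0.5)
})

test_that("cued responses differ from spontaneous ones only when modulated", {
  sim <- small_session()
  trials <- sim$session$trials
  dur <- sim$session$duration
  set.seed(6)
  mod <- neuron_profile(selectivity = "vocal", sign_vocal = "excited",
                        baseline_rate = 12, modulation_gain = 3)
  u <- make_unit(simulate_unit_spikes(mod, trials, dur), id = "m")
  s <- sim$session
  s$units <- list(u)
  r <- spontaneous_contrast(s$units[[1]], s, "vocal")
  expect_gte(r$n_spont, 3)
  expect_lt(r$p, 0.05)

  # fewer than three spontaneous events: absent
  s2 <- s
  s2$spontaneous <- s$spontaneous[1:2, ]
  expect_true(is.na(spontaneous_contrast(s2$units[[1]], s2, "vocal")$p))
})

test_that("population curves are baseline-centered and reflection-invariant", {
  sim <- small_session()
  s <- sim$session
  set.seed(41)
  exc <- make_unit(simulate_unit_spikes(
    neuron_profile(selectivity = "vocal", sign_vocal = "excited",
                   baseline_rate = 15, modulation_gain = 3),
    s$trials, s$duration), id = "e")
  s$units <- list(exc)
  cl1 <- data.frame(unit_id = "e", area = "VPA", is_vocal = TRUE,
                    is_hand = FALSE, vocal_sign = "excited",
                    hand_sign = "none")
  pc <- population_curve(s, cl1, "vocal")
  expect_equal(pc$n_units, 1)
  # single unit: curve is its own normalized PSTH (sem undefined -> NA ok)
  expect_gt(mean(pc$mean[pc$times >= -0.45 & pc$times < 0]),
            mean(pc$mean[pc$times < -1.5]))

  # relabeling the unit suppressed reflects the curve exactly
  cl2 <- cl1
  cl2$vocal_sign <- "suppressed"
  pc2 <- population_curve(s, cl2, "vocal")
  expect_equal(pc2$mean, -pc$mean, tolerance = 1e-12)
  expect_equal(mean(abs(pc2$mean)), mean(abs(pc$mean)), tolerance = 1e-12)
})
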