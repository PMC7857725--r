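gpfa_times <- function(n = 40, bw = 0.02) bw * (seq_len(n) - 0.5)

test_that("binning conserves counts and transforms them", {
  pool <- list(list(unit_id = "a", spike_times = c(10.01, 10.03, 10.05),
                    events = list(), rts = list()),
               list(unit_id = "b", spike_times = numeric(0),
                    events = list(), rts = list()))
  cfg <- gpfa_config(q = 1, bin_width = 0.02, align_window = c(0, 0.1),
                     sqrt_transform = FALSE)
  bt <- bin_and_transform(pool, list(10, 10), cfg)
  expect_equal(sum(bt$Y[[1]][1, ]), 3)          # conservation
  expect_true(all(bt$Y[[1]][2, ] == 0))         # silent unit
  cfg2 <- gpfa_config(q = 1, bin_width = 0.02, align_window = c(0, 0.1))
  bt2 <- bin_and_transform(pool, list(10, 10), cfg2)
  expect_equal(bt2$Y[[1]][1, ], sqrt(bt$Y[[1]][1, ]))
  expect_equal(bt2$times, 0.02 * (1:5) - 0.01)
})

test_that("EM increases the likelihood and recovers a known model", {
  times <- gpfa_times(75)
  sim <- simulate_gpfa_data(30, 3, 40, times, tau = c(0.05, 0.15, 0.3),
                            noise_sd = 0.5, seed = 2)
  m <- fit_gpfa(sim$Y, times, gpfa_config(q = 3, em_max_iter = 300, n_restarts = 3, seed = 7))
  lt <- m$loglik_trace
  expect_true(all(diff(lt) >= -1e-6 * abs(lt[-length(lt)])))
  expect_lt(subspace_angle(m$C, sim$C), 15)
  tau_err <- abs(sort(m$tau) - sort(sim$tau)) / sort(sim$tau)
  expect_true(all(tau_err < 0.3))
  # dimension guard
  expect_error(fit_gpfa(sim$Y, times, gpfa_config(q = 31)), "n_units")
})

test_that("orthonormalization preserves the reconstruction and orders variance", {
  times <- gpfa_times(30)
  sim <- simulate_gpfa_data(15, 4, 6, times, tau = 0.1, seed = 3)
  m <- fit_gpfa(sim$Y, times, gpfa_config(q = 4, em_max_iter = 5, seed = 1))
  o <- orthonormalize(m)
  expect_equal(sum(o$explained_covariance), 1, tolerance = 1e-12)
  expect_true(all(diff(o$explained_covariance) <= 1e-12))
  for (j in 1:3)
    expect_equal(m$C %*% m$latents[[j]],
                 o$basis %*% o$trajectories[[j]], tolerance = 1e-9)

  # an already-orthonormal loading map leaves latents unchanged (up to
  # permutation and sign)
  m2 <- m
  m2$C <- qr.Q(qr(m$C)) %*% diag(c(4, 3, 2, 1))
  o2 <- orthonormalize(m2)
  for (j in 1:2) {
    a <- m2$latents[[j]] * c(4, 3, 2, 1)
    b <- o2$trajectories[[j]]
    M <- abs(stats::cor(t(a), t(b)))
    expect_true(all(apply(M, 1, max) > 1 - 1e-6))
  }
})

test_that("white-noise data spread covariance evenly across latents", {
  times <- gpfa_times(30)
  tops <- vapply(1:3, function(sd) {
    set.seed(sd)
    Y <- lapply(1:20, function(j) matrix(rnorm(16 * 30), 16, 30))
    m <- fit_gpfa(Y, times, gpfa_config(q = 4, em_max_iter = 8, seed = sd))
    orthonormalize(m)$explained_covariance[1]
  }, 0)
  expect_lt(mean(tops), 0.6)   # far from rank-one structure
  expect_gt(mean(tops), 0.25 - 0.15)
})

test_that("split halves are deterministic and degenerate correctly", {
  traj <- lapply(1:4, function(i) matrix(i, 3, 10))
  labels <- c("vocal", "vocal", "manual", "manual")
  h1 <- split_half_trajectories(traj, labels, top_dims = 2, seed = 5)
  h2 <- split_half_trajectories(traj, labels, top_dims = 2, seed = 5)
  expect_identical(h1, h2)
  # two identical trials per condition: both halves identical
  traj2 <- list(matrix(1, 3, 10), matrix(1, 3, 10),
                matrix(2, 3, 10), matrix(2, 3, 10))
  h3 <- split_half_trajectories(traj2, labels, top_dims = 3, seed = 1)
  expect_equal(h3$vocal[[1]], h3$vocal[[2]])
  expect_equal(dim(h3$vocal[[1]]), c(3, 10))
})

test_that("distance curves vanish for identical or offset trajectories and are rotation-invariant", {
  times <- gpfa_times(25)
  bw <- 0.02
  set.seed(8)
  base <- matrix(rnorm(3 * 25), 3, 25)
  rts <- c(vocal = 0.2, manual = 0.2)
  same <- list(vocal = list(base, base), manual = list(base, base))
  dc <- distance_curves(same, times, bw, rts)
  expect_true(all(dc$within_vocal == 0))
  expect_true(all(dc$cross == 0))

  # constant offset between conditions disappears after baseline subtraction
  off <- list(vocal = list(base, base), manual = list(base + 2, base + 2))
  dc2 <- distance_curves(off, times, bw, rts)
  expect_equal(max(abs(dc2$cross)), 0, tolerance = 1e-9)
  expect_equal(dc2$raw$cross, rep(2 * sqrt(3), 25), tolerance = 1e-9)

  # global rotation leaves every distance curve unchanged
  other <- matrix(rnorm(3 * 25), 3, 25)
  halves <- list(vocal = list(base, other), manual = list(base + 1, other - 1))
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  rot <- lapply(halves, function(h) lapply(h, function(m) R %*% m))
  d0 <- distance_curves(halves, times, bw, rts)
  d1 <- distance_curves(rot, times, bw, rts)
  expect_equal(d0$within_vocal, d1$within_vocal, tolerance = 1e-9)
  expect_equal(d0$cross, d1$cross, tolerance = 1e-9)
})

test_that("baseline bins fall back to the earliest grid bins for long RTs", {
  times <- seq(-2, 1, by = 0.02) + 0.01
  times <- times[times < 1]
  sel <- premovoc:::baseline_bins(times, 0.02, mean_go = -1.8)
  expect_true(all(times[sel] < -1.8))   # pre-go bins only
  sel2 <- premovoc:::baseline_bins(times, 0.02, mean_go = -3)
  expect_equal(sel2, which(times <= times[1] + 0.5))  # fallback window
})

test_that("a single repeat equals the unaveraged pipeline run", {
  sim <- small_session()
  pool <- build_pseudopopulation(list(sim$session), "VPA", 10)
  expect_gte(length(pool), 4)
  cfg <- gpfa_config(q = 3, n_trials_per_condition = 8, n_repeats = 1,
                     em_max_iter = 4, top_dims = 2, seed = 13)
  r1 <- repeated_population_analysis(pool, cfg)
  r2 <- repeated_population_analysis(pool, cfg)
  expect_identical(r1$cross, r2$cross)
  expect_equal(length(r1$cross), length(r1$times))
})
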