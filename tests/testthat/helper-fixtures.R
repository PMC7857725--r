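# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Small mixed-population session with ground truth (2 blocks, 24 units).
small_session <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_session(sim_config(n_blocks = 2, seed = 101))
  }
  .fixture_env$small
}

make_unit <- function(spikes, id = "u1", area = "VPA") {
  list(unit_id = id, area = area, spike_times = sort(spikes),
       mean_rate = NA)
}

# Minimal hand-built session: `hits` rows of (block, t_go_on, rt); all hits.
toy_session <- function(hits, duration = NULL, units = list(),
                        spontaneous = NULL, cue_ids = NULL) {
  n <- nrow(hits)
  if (is.null(cue_ids)) cue_ids <- rep(c("A", "B"), length.out = n)
  tr <- data.frame(
    index = seq_len(n), block = hits$block, cue_id = cue_ids,
    t_start = hits$t_go_on - 3, t_precue_on = hits$t_go_on - 2.5,
    t_go_on = hits$t_go_on, t_response = hits$t_go_on + hits$rt,
    response_kind = ifelse(hits$block == "vocal", "call", "bar_release"),
    outcome = "hit", rt = hits$rt, stringsAsFactors = FALSE)
  if (is.null(duration)) duration <- max(tr$t_response) + 5
  if (is.null(spontaneous))
    spontaneous <- data.frame(time_s = numeric(0), kind = character(0))
  eye <- list(sample_rate = 1000, t0 = 0, x = numeric(1000), y = numeric(1000))
  new_session("toy", task_config(), tr, units, eye, spontaneous, duration)
}

# Unit whose premotor-window spike counts are prescribed per trial: puts
# `counts[i]` spikes in the 450 ms before trial i's response.
unit_with_premotor_counts <- function(tr, counts, baseline_counts = 0) {
  sp <- numeric(0)
  for (i in seq_len(nrow(tr))) {
    if (counts[i] > 0)
      sp <- c(sp, tr$t_response[i] - 0.45 +
                (seq_len(counts[i]) - 0.5) / counts[i] * 0.44)
    if (baseline_counts > 0)
      sp <- c(sp, tr$t_go_on[i] - 0.45 +
                (seq_len(baseline_counts) - 0.5) / baseline_counts * 0.44)
  }
  make_unit(sp)
}

# Exact enumeration oracles -------------------------------------------------

# Two-sided paired signed-rank p by enumerating all sign assignments.
exact_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  min(1, 2 * min(mean(w_all <= w_obs + 1e-12), mean(w_all >= w_obs - 1e-12)))
}

# Two-sided Mann-Whitney p by enumerating all label assignments.
exact_mann_whitney_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  r <- rank(v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  u_all <- apply(combs, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs + 1e-12), mean(u_all >= u_obs - 1e-12)))
}

# Kruskal-Wallis tie-corrected statistic by direct rank computation.
kw_statistic_oracle <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(g) length(g) * (mean(g))^2)) -
    3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Brute-force AUROC by pair counting with half-credit ties.
auroc_oracle <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
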