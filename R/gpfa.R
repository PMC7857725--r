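#' GPFA configuration
#'
#' Defaults mirror the population analysis conditions: eight latent
#' dimensions on 20 ms non-overlapping bins over a (-2, +1) s
#' response-aligned window, 15 trials sampled per condition, 100 repeats of
#' the sampling + fit procedure, and the top three orthonormalized
#' dimensions for trajectories.
#'
#' @param q Latent dimensions; default 8.
#' @param bin_width Bin width (s); default 0.020.
#' @param align_window Response-aligned span (s); default `c(-2, 1)`.
#' @param n_trials_per_condition Trials sampled per condition; default 15.
#' @param n_repeats Sampling repeats; default 100.
#' @param top_dims Orthonormalized dimensions kept; default 3.
#' @param em_max_iter EM iteration cap; default 50.
#' @param em_tol Relative log-likelihood convergence tolerance; default 1e-6.
#' @param n_restarts EM restarts from different factor-analysis
#'   initializations; the fit with the highest final log-likelihood is kept
#'   (EM for this model has local optima). Default 1.
#' @param sqrt_transform Square-root transform binned counts; default TRUE.
#' @param sigma_n2 Per-latent GP jitter variance; the signal variance is
#'   fixed at `1 - sigma_n2` (latent scale is absorbed into the loadings).
#' @param tau_init Initial GP timescale (s); default 0.1.
#' @param baseline_window Pre-go baseline window (s before go cue);
#'   default `c(-0.6, -0.1)`.
#' @param seed Integer seed.
#' @return A `gpfa_config` list.
#' @export
gpfa_config <- function(q = 8L, bin_width = 0.020, align_window = c(-2, 1),
                        n_trials_per_condition = 15L, n_repeats = 100L,
                        top_dims = min(3L, q), em_max_iter = 50L,
                        em_tol = 1e-6, n_restarts = 1L,
                        sqrt_transform = TRUE, sigma_n2 = 1e-3,
                        tau_init = 0.1, baseline_window = c(-0.6, -0.1),
                        seed = 1L) {
  stopifnot(q >= 1, top_dims <= q, bin_width > 0)
  structure(as.list(environment()), class = "gpfa_config")
}

se_kernel <- function(times, tau, sigma_n2) {
  sf2 <- 1 - sigma_n2
  D2 <- outer(times, times, `-`)^2
  K <- sf2 * exp(-D2 / (2 * tau^2))
  diag(K) <- diag(K) + sigma_n2
  K
}

#' Pseudo-population trial pools for one area
#'
#' Units recorded in the area with at least `min_trials` hit trials per
#' condition; each unit contributes its own per-condition pools of response
#' events (and reaction times, needed for baseline mapping).
#'
#' @param sessions List of `premovoc_session` objects.
#' @param area Area label.
#' @param min_trials Minimum hits per condition (15 or 17 in the source
#'   analysis).
#' @param unit_ids Restrict to these units (e.g. after screening); NULL for
#'   all.
#' @return List of per-unit pools: `unit_id`, `spike_times`, `events`
#'   (list vocal/manual of response times), `rts` (matching reaction times).
#' @export
build_pseudopopulation <- function(sessions, area, min_trials = 15,
                                   unit_ids = NULL) {
  pool <- list()
  for (s in sessions) {
    ev <- lapply(c(vocal = "vocal", manual = "manual"), function(b)
      select_trials(s, b, "hit"))
    for (u in s$units) {
      if (u$area != area) next
      if (!is.null(unit_ids) && !(u$unit_id %in% unit_ids)) next
      if (nrow(ev$vocal) < min_trials || nrow(ev$manual) < min_trials) next
      pool[[length(pool) + 1]] <- list(
        unit_id = u$unit_id, spike_times = u$spike_times,
        events = list(vocal = ev$vocal$t_response,
                      manual = ev$manual$t_response),
        rts = list(vocal = ev$vocal$rt, manual = ev$manual$rt))
    }
  }
  pool
}

#' Bin and transform pseudo-trials
#'
#' Response-aligned spike counts per 20 ms bin for each sampled trial,
#' square-root transformed (variance stabilization of Poisson counts)
#' unless disabled.
#'
#' @param pool Pseudo-population from [build_pseudopopulation()].
#' @param sampled Per-unit list of sampled event times: `sampled[[i]]` is a
#'   numeric vector of length N (pseudo-trials) for unit i.
#' @param cfg A [gpfa_config()].
#' @return List with `Y` (list of N matrices, units x bins) and `times`
#'   (bin centers, s relative to response).
#' @export
bin_and_transform <- function(pool, sampled, cfg) {
  w <- cfg$align_window
  bw <- cfg$bin_width
  n_bins <- floor((w[2] - w[1]) / bw + 1e-9)
  centers <- w[1] + bw * (seq_len(n_bins) - 0.5)
  n_units <- length(pool)
  N <- length(sampled[[1]])
  Y <- lapply(seq_len(N), function(j) matrix(0, n_units, n_bins))
  for (i in seq_len(n_units)) {
    sp <- pool[[i]]$spike_times
    for (j in seq_len(N)) {
      ev <- sampled[[i]][j]
      lo <- ev + w[1] + bw * (seq_len(n_bins) - 1)
      cts <- count_in_windows(sp, lo, lo + bw)
      Y[[j]][i, ] <- if (cfg$sqrt_transform) sqrt(cts) else cts
    }
  }
  list(Y = Y, times = centers)
}

fa_init <- function(Ymat, q, n_iter = 30, seed = 1) {
  # plain factor analysis by EM on iid samples (columns of Ymat), from a
  # seed-determined random start
  set.seed(seed)
  n <- nrow(Ymat); m <- ncol(Ymat)
  d <- rowMeans(Ymat)
  Yc <- Ymat - d
  S_diag <- rowMeans(Yc^2)
  C <- matrix(stats::rnorm(n * q, sd = sqrt(mean(S_diag) / q)), n, q)
  R <- pmax(S_diag, 1e-4)
  for (it in seq_len(n_iter)) {
    CR <- C / R
    M <- solve(diag(q) + crossprod(CR, C))    # posterior cov of x
    Ex <- M %*% crossprod(CR, Yc)             # q x m
    Exx <- m * M + tcrossprod(Ex)
    SYX <- tcrossprod(Yc, Ex)                 # n x q
    C <- SYX %*% solve(Exx)
    R <- pmax(S_diag - rowSums(C * SYX) / m, 1e-4)
  }
  list(C = C, d = d, R = R)
}

gpfa_estep <- function(Ylist, C, d, R, Ks, compute_ll = TRUE) {
  # Ks: list of per-latent T x T kernel matrices
  q <- ncol(C); Tn <- ncol(Ylist[[1]]); n <- nrow(C); N <- length(Ylist)
  qT <- q * Tn
  idx <- lapply(seq_len(q), function(k) (k - 1) * Tn + seq_len(Tn))
  Kinv <- vector("list", q)
  logdetK <- 0
  for (k in seq_len(q)) {
    ch <- chol(Ks[[k]])
    Kinv[[k]] <- chol2inv(ch)
    logdetK <- logdetK + 2 * sum(log(diag(ch)))
  }
  G <- crossprod(C / R, C)                    # C' R^-1 C (q x q)
  A <- matrix(0, qT, qT)
  for (k in seq_len(q)) A[idx[[k]], idx[[k]]] <- Kinv[[k]]
  for (k in seq_len(q)) for (k2 in seq_len(q)) {
    ii <- idx[[k]]; jj <- idx[[k2]]
    A[cbind(ii, jj)] <- A[cbind(ii, jj)] + G[k, k2]
  }
  chA <- chol(A)
  Sigma <- chol2inv(chA)
  logdetA <- 2 * sum(log(diag(chA)))
  CRt <- t(C / R)                             # q x n
  Bmat <- matrix(0, qT, N)
  quad_v <- numeric(N)
  for (j in seq_len(N)) {
    Yc <- Ylist[[j]] - d
    V <- CRt %*% Yc                           # q x T
    Bmat[, j] <- as.vector(t(V))              # latent-major
    if (compute_ll) quad_v[j] <- sum(Yc^2 / R)
  }
  Mu <- Sigma %*% Bmat                        # qT x N posterior means
  ll <- NA_real_
  if (compute_ll) {
    quad_b <- colSums(Bmat * Mu)
    ll <- sum(-0.5 * (n * Tn * log(2 * pi) + Tn * sum(log(R)) +
                        logdetK + logdetA + quad_v - quad_b))
  }
  list(Sigma = Sigma, Mu = Mu, idx = idx, loglik = ll)
}

#' Fit a Gaussian-process factor analysis model
#'
#' EM for the model `y_t = C x_t + d + eps`, `eps ~ N(0, R)` (diagonal),
#' with each latent an independent zero-mean Gaussian process with
#' squared-exponential covariance
#' `k(t, t') = (1 - sigma_n2) exp(-(t - t')^2 / (2 tau_k^2)) + sigma_n2 [t = t']`.
#' The E-step is the exact joint Gaussian posterior over all latents and
#' time points; the M-step updates C, d, R in closed form and each tau by a
#' one-dimensional maximization of the expected complete-data
#' log-likelihood. C, d, R are initialized from a factor analysis fitted by
#' EM from a seed-determined start. The marginal log-likelihood trace is
#' non-decreasing.
#'
#' @param Ylist List of trials; each a units x bins numeric matrix (already
#'   transformed).
#' @param times Bin centers (s).
#' @param cfg A [gpfa_config()].
#' @return A `gpfa_model`: `C`, `d`, `R`, `tau`, `sigma_n2`, `times`,
#'   `loglik_trace`, plus the final posterior latent means per trial
#'   (`latents`, list of q x T matrices).
#' @export
fit_gpfa <- function(Ylist, times, cfg = gpfa_config()) {
  if (cfg$n_restarts > 1) {
    fits <- lapply(seq_len(cfg$n_restarts), function(r) {
      cfg_r <- cfg
      cfg_r$n_restarts <- 1L
      cfg_r$seed <- derive_seed(cfg$seed, paste0("restart_", r))
      fit_gpfa(Ylist, times, cfg_r)
    })
    ll <- vapply(fits, function(f)
      f$loglik_trace[length(f$loglik_trace)], 0)
    return(fits[[which.max(ll)]])
  }
  q <- cfg$q
  n <- nrow(Ylist[[1]]); Tn <- ncol(Ylist[[1]]); N <- length(Ylist)
  if (N < 2) stop("config error: need >= 2 trials")
  if (n <= q) stop("config error: n_units must exceed q")
  init <- fa_init(do.call(cbind, Ylist), q, seed = cfg$seed)
  C <- init$C; d <- init$d; R <- init$R
  tau <- rep(cfg$tau_init, q)
  sn2 <- cfg$sigma_n2
  ll_trace <- numeric(0)
  es <- NULL
  for (it in seq_len(cfg$em_max_iter)) {
    Ks <- lapply(tau, se_kernel, times = times, sigma_n2 = sn2)
    es <- gpfa_estep(Ylist, C, d, R, Ks)
    if (!is.finite(es$loglik))
      stop("numerical error: non-finite likelihood at iteration ", it)
    ll_trace <- c(ll_trace, es$loglik)
    if (it > 1) {
      rel <- (es$loglik - ll_trace[it - 1]) / abs(ll_trace[it - 1])
      if (abs(rel) < cfg$em_tol) break
    }
    # --- M-step: C, d, R --------------------------------------------------
    idx <- es$idx
    P <- matrix(0, q, q)       # sum_t posterior cov diag blocks (per trial)
    for (k in seq_len(q)) for (k2 in seq_len(q))
      P[k, k2] <- sum(diag(es$Sigma[idx[[k]], idx[[k2]], drop = FALSE]))
    Sxx <- N * P
    Sx <- numeric(q)
    SYX <- matrix(0, n, q)
    Sy <- numeric(n)
    syy <- numeric(n)
    for (j in seq_len(N)) {
      Muj <- matrix(es$Mu[, j], Tn, q)        # T x q (latent-major unfold)
      Sxx <- Sxx + crossprod(Muj)
      Sx <- Sx + colSums(Muj)
      SYX <- SYX + Ylist[[j]] %*% Muj
      Sy <- Sy + rowSums(Ylist[[j]])
      syy <- syy + rowSums(Ylist[[j]]^2)
    }
    NT <- N * Tn
    SXX <- rbind(cbind(Sxx, Sx), c(Sx, NT))
    SYXa <- cbind(SYX, Sy)
    Cd <- SYXa %*% solve(SXX)
    C <- Cd[, seq_len(q), drop = FALSE]
    d <- Cd[, q + 1]
    R <- pmax((syy - rowSums(Cd * SYXa)) / NT, 1e-4)
    # --- M-step: tau ------------------------------------------------------
    for (k in seq_len(q)) {
      Sk <- N * es$Sigma[idx[[k]], idx[[k]]]
      for (j in seq_len(N)) {
        mk <- es$Mu[idx[[k]], j]
        Sk <- Sk + tcrossprod(mk)
      }
      obj <- function(lt) {
        K <- se_kernel(times, exp(lt), sn2)
        ch <- tryCatch(chol(K), error = function(e) NULL)
        if (is.null(ch)) return(-1e12)
        -0.5 * (N * 2 * sum(log(diag(ch))) +
                  sum(chol2inv(ch) * Sk))
      }
      opt <- stats::optimize(obj, interval = log(c(0.005, 3)), maximum = TRUE)
      if (opt$objective > obj(log(tau[k]))) tau[k] <- exp(opt$maximum)
    }
  }
  lat <- lapply(seq_len(N), function(j) t(matrix(es$Mu[, j], Tn, q)))
  structure(list(C = C, d = d, R = R, tau = tau, sigma_n2 = sn2,
                 times = times, loglik_trace = ll_trace, latents = lat,
                 config = cfg),
            class = "gpfa_model")
}

#' Orthonormalize GPFA trajectories
#'
#' Singular-value decomposition of the loading matrix `C = U S V'`; latents
#' are re-expressed in the orthonormal basis `U` (coordinates `S V' x`),
#' ordered by singular value, with explained covariance fractions
#' `s_k^2 / sum s_j^2`. The reconstruction `C x` is unchanged.
#'
#' @param model A fitted `gpfa_model`.
#' @param latents Optional list of q x T latent matrices; defaults to the
#'   model's posterior means.
#' @return List with `trajectories` (list of q x T matrices in the
#'   orthonormal basis), `basis` (U), `explained_covariance`.
#' @export
orthonormalize <- function(model, latents = model$latents) {
  sv <- svd(model$C)
  TT <- diag(sv$d, nrow = length(sv$d)) %*% t(sv$v)
  list(trajectories = lapply(latents, function(x) TT %*% x),
       basis = sv$u,
       explained_covariance = sv$d^2 / sum(sv$d^2))
}

#' Split-half average trajectories per condition
#'
#' Randomly splits each condition's trials into two halves (sizes differing
#' by at most one) and averages the top `top_dims` orthonormalized latent
#' dimensions within each half.
#'
#' @param trajectories List of q x T orthonormalized latent matrices.
#' @param labels Character vector ("vocal"/"manual") per trial.
#' @param top_dims Dimensions kept; default 3.
#' @param seed Split seed.
#' @return Nested list `[[condition]][[half]]` of top_dims x T matrices.
#' @export
split_half_trajectories <- function(trajectories, labels, top_dims = 3,
                                    seed = 1) {
  set.seed(seed)
  out <- list()
  for (cond in unique(labels)) {
    i <- which(labels == cond)
    stopifnot(length(i) >= 2)
    i <- sample(i)
    h1 <- i[seq_len(floor(length(i) / 2))]
    h2 <- setdiff(i, h1)
    avg <- function(ii) {
      acc <- Reduce(`+`, trajectories[ii])
      (acc / length(ii))[seq_len(top_dims), , drop = FALSE]
    }
    out[[cond]] <- list(avg(h1), avg(h2))
  }
  out
}

baseline_bins <- function(times, bin_width, mean_go, window = c(-0.6, -0.1)) {
  # grid bins (centers `times`) covering >= 50% of the pre-go baseline
  # window mapped to response-aligned time; fallback: earliest 0.5 s
  lo <- mean_go + window[1]; hi <- mean_go + window[2]
  cover <- pmin(times + bin_width / 2, hi) - pmax(times - bin_width / 2, lo)
  sel <- which(cover >= bin_width / 2)
  if (length(sel) == 0)
    sel <- which(times <= times[1] + 0.5)
  sel
}

#' Within- and cross-response trajectory distance curves
#'
#' Euclidean distances over time between the two same-condition half
#' trajectories (within-response coding) and the mean over the four
#' vocal x manual half pairs (cross-response coding). Each curve's mean over
#' its baseline bins -- the 100-600 ms pre-go window mapped onto the
#' response-aligned grid via the condition's mean reaction time -- is
#' subtracted.
#'
#' @param halves Output of [split_half_trajectories()] with conditions
#'   "vocal" and "manual".
#' @param times Bin centers (s relative to response).
#' @param bin_width Grid bin width (s).
#' @param mean_rt Named numeric `c(vocal=, manual=)` mean reaction times (s).
#' @param baseline_window Pre-go window (s); default `c(-0.6, -0.1)`.
#' @return List with `times`, `within_vocal`, `within_manual`, `cross`
#'   (baseline-subtracted), and the raw (unsubtracted) curves.
#' @export
distance_curves <- function(halves, times, bin_width, mean_rt,
                            baseline_window = c(-0.6, -0.1)) {
  dist_t <- function(a, b) sqrt(colSums((a - b)^2))
  wv <- dist_t(halves$vocal[[1]], halves$vocal[[2]])
  wm <- dist_t(halves$manual[[1]], halves$manual[[2]])
  cr <- (dist_t(halves$vocal[[1]], halves$manual[[1]]) +
           dist_t(halves$vocal[[1]], halves$manual[[2]]) +
           dist_t(halves$vocal[[2]], halves$manual[[1]]) +
           dist_t(halves$vocal[[2]], halves$manual[[2]])) / 4
  bsub <- function(v, go) v - mean(v[baseline_bins(times, bin_width, go,
                                                   baseline_window)])
  go_v <- -mean_rt[["vocal"]]; go_m <- -mean_rt[["manual"]]
  list(times = times,
       within_vocal = bsub(wv, go_v),
       within_manual = bsub(wm, go_m),
       cross = bsub(cr, mean(c(go_v, go_m))),
       raw = list(within_vocal = wv, within_manual = wm, cross = cr))
}

#' Repeated pseudo-population GPFA distance analysis
#'
#' For each repeat: sample `n_trials_per_condition` hit trials per condition
#' independently for every unit, bin and transform, fit GPFA on all
#' pseudo-trials of both conditions jointly, orthonormalize, split each
#' condition into halves, and compute baseline-subtracted distance curves.
#' Curves are averaged across repeats with a SEM. Deterministic given
#' `cfg$seed`.
#'
#' @param pool Pseudo-population from [build_pseudopopulation()].
#' @param cfg A [gpfa_config()].
#' @return List with `times`, mean `within_vocal`, `within_manual`, `cross`,
#'   per-curve `sem`, `n_repeats`, `n_units`, and the last repeat's fitted
#'   model and explained covariance.
#' @export
repeated_population_analysis <- function(pool, cfg = gpfa_config()) {
  n_units <- length(pool)
  ntr <- cfg$n_trials_per_condition
  pool <- Filter(function(u)
    length(u$events$vocal) >= ntr && length(u$events$manual) >= ntr, pool)
  if (length(pool) < n_units)
    message(n_units - length(pool), " unit(s) dropped: insufficient trials")
  n_units <- length(pool)
  if (n_units <= cfg$q) stop("config error: n_units must exceed q")
  acc <- list(within_vocal = NULL, within_manual = NULL, cross = NULL)
  model <- NULL; expl <- NULL; times <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    set.seed(derive_seed(cfg$seed, paste0("gpfa_repeat_", r)))
    sampled <- vector("list", n_units)
    rt_v <- rt_m <- numeric(0)
    for (i in seq_len(n_units)) {
      u <- pool[[i]]
      iv <- sample(seq_along(u$events$vocal), ntr)
      im <- sample(seq_along(u$events$manual), ntr)
      sampled[[i]] <- c(u$events$vocal[iv], u$events$manual[im])
      rt_v <- c(rt_v, u$rts$vocal[iv]); rt_m <- c(rt_m, u$rts$manual[im])
    }
    bt <- bin_and_transform(pool, sampled, cfg)
    times <- bt$times
    labels <- rep(c("vocal", "manual"), each = ntr)
    model <- fit_gpfa(bt$Y, bt$times, cfg)
    ortho <- orthonormalize(model)
    expl <- ortho$explained_covariance
    halves <- split_half_trajectories(ortho$trajectories, labels,
                                      cfg$top_dims,
                                      seed = derive_seed(cfg$seed,
                                                         paste0("split_", r)))
    dc <- distance_curves(halves, bt$times, cfg$bin_width,
                          c(vocal = mean(rt_v), manual = mean(rt_m)),
                          cfg$baseline_window)
    for (nm in names(acc)) acc[[nm]] <- rbind(acc[[nm]], dc[[nm]])
  }
  summarize <- function(m) list(mean = colMeans(m),
                                sem = apply(m, 2, stats::sd) /
                                  sqrt(nrow(m)))
  sv <- summarize(acc$within_vocal)
  sm <- summarize(acc$within_manual)
  sc <- summarize(acc$cross)
  list(times = times, within_vocal = sv$mean, within_manual = sm$mean,
       cross = sc$mean,
       sem = list(within_vocal = sv$sem, within_manual = sm$sem,
                  cross = sc$sem),
       n_repeats = cfg$n_repeats, n_units = n_units,
       model = model, explained_covariance = expl)
}

#' Simulate data from a known GPFA model
#'
#' Draws latents from squared-exponential Gaussian processes and
#' observations `y = C x + d + noise`; used for parameter-recovery checks.
#'
#' @param n_units,q,n_trials Dimensions.
#' @param times Bin centers (s).
#' @param tau Per-latent timescales (s), recycled to length q.
#' @param noise_sd Observation noise SD (per unit, recycled).
#' @param seed Seed.
#' @return List with `Y` (trial list), `C`, `d`, `tau`, `times`.
#' @export
simulate_gpfa_data <- function(n_units, q, n_trials, times,
                               tau = 0.1, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  tau <- rep_len(tau, q)
  C <- matrix(stats::rnorm(n_units * q), n_units, q)
  d <- stats::runif(n_units, 1, 3)
  noise_sd <- rep_len(noise_sd, n_units)
  Tn <- length(times)
  chKs <- lapply(tau, function(tk) chol(se_kernel(times, tk, 1e-6)))
  Y <- lapply(seq_len(n_trials), function(j) {
    X <- t(vapply(chKs, function(ch)
      as.vector(crossprod(ch, stats::rnorm(Tn))), numeric(Tn)))
    C %*% X + d + matrix(stats::rnorm(n_units * Tn, sd = noise_sd),
                         n_units, Tn)
  })
  list(Y = Y, C = C, d = d, tau = tau, times = times)
}

#' Principal angle between two loading subspaces
#'
#' Largest principal angle (degrees) between the column spans of two
#' matrices; used to assess loading-subspace recovery.
#'
#' @param A,B Matrices with the same row count.
#' @return Angle in degrees.
#' @export
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(s)))) * 180 / pi
}
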