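#' Single-trial filtered firing rate
#'
#' Converts binned spike counts to an instantaneous rate by convolution with
#' a Gaussian kernel (default SD 50 ms).  Each spike contributes a bump
#' integrating to ~1 (up to edge truncation).
#'
#' @param counts Integer vector of binned counts (one neuron, one trial) or
#'   a matrix (neurons x bins).
#' @param dt Bin width in seconds.
#' @param kernel_sd Kernel standard deviation in seconds (default 0.05).
#' @return Rate trace(s) in Hz, same shape as `counts`.
#' @export
single_trial_rate <- function(counts, dt, kernel_sd = 0.05) {
  k <- ceiling(4 * kernel_sd / dt)
  kern <- dnorm(seq(-k, k) * dt, sd = kernel_sd)
  kern <- kern / sum(kern) / dt
  smooth1 <- function(y) {
    T <- length(y)
    out <- numeric(T)
    for (t in seq_len(T)) {
      j <- max(1, t - k):min(T, t + k)
      out[t] <- sum(y[j] * kern[j - t + k + 1])
    }
    out
  }
  if (is.matrix(counts)) t(apply(counts, 1, smooth1)) else smooth1(counts)
}

#' Final click difference of every trial
#'
#' Right minus left click counts, the evidence-strength summary used for
#' PSTH grouping and psychometric fits.
#'
#' @param session A [ddm_session()].
#' @return Numeric vector, one value per trial.
#' @export
final_click_diff <- function(session) {
  vapply(session$trials, function(tr)
    length(tr$right_times) - length(tr$left_times), numeric(1))
}

# Equal-sized trial groups by final click difference (rank split).
evidence_groups <- function(dclick, groups = 2L) {
  rk <- rank(dclick, ties.method = "first")
  as.integer(cut(rk, breaks = groups, labels = FALSE))
}

#' Peri-stimulus time histogram by evidence strength
#'
#' Filters each trial's spikes ([single_trial_rate()]), splits the trials
#' into equal-sized groups by final click difference, and averages raggedly
#' (at time `t`, whichever trials have data at `t` contribute).
#'
#' @param session A [ddm_session()].
#' @param dt Bin width in seconds.
#' @param groups Number of evidence groups (default 2).
#' @param kernel_sd Filter SD in seconds.
#' @return Object of class `ddm_psth`: `rate` array (neurons x groups x
#'   bins), `n_trials` (groups x bins contribution counts), `time`,
#'   `group_of` (per-trial group).
#' @export
psth <- function(session, dt = 0.01, groups = 2L, kernel_sd = 0.05) {
  build_psth(rate_traces(session, dt, kernel_sd), session, dt, groups)
}

rate_traces <- function(session, dt, kernel_sd = 0.05) {
  ids <- session$neurons$id
  lat <- setNames(session$neurons$latency, ids)
  lapply(session$trials, function(tr) {
    T <- n_time_bins(tr$duration, dt)
    out <- matrix(NA_real_, length(ids), T, dimnames = list(ids, NULL))
    for (id in names(tr$spikes)) {
      y <- bin_spikes(tr$spikes[[id]], dt, tr$duration, lat[[id]])
      out[id, ] <- single_trial_rate(as.numeric(y[1, ]), dt, kernel_sd)
    }
    out
  })
}

build_psth <- function(traces, session, dt, groups) {
  ids <- session$neurons$id
  g <- evidence_groups(final_click_diff(session), groups)
  Tmax <- max(vapply(traces, ncol, integer(1)))
  rate <- array(0, dim = c(length(ids), groups, Tmax),
                dimnames = list(ids, NULL, NULL))
  cnt <- array(0, dim = c(length(ids), groups, Tmax))
  for (k in seq_along(traces)) {
    tk <- traces[[k]]
    T <- ncol(tk)
    for (i in seq_along(ids)) {
      if (anyNA(tk[i, 1])) next
      rate[i, g[k], 1:T] <- rate[i, g[k], 1:T] + tk[i, ]
      cnt[i, g[k], 1:T] <- cnt[i, g[k], 1:T] + 1
    }
  }
  rate <- rate / ifelse(cnt > 0, cnt, NA)
  structure(list(rate = rate, n_trials = cnt, time = seq_len(Tmax) * dt,
                 group_of = g, groups = groups),
            class = "ddm_psth")
}

#' Model-predicted (synthetic) PSTH
#'
#' For each trial, the model's expected firing rate is averaged over
#' `n_noise_reals` independent realizations of the latent noise (using the
#' trial's actual stimulus), then grouped and averaged exactly like the
#' empirical PSTH.
#'
#' @param theta Flat named parameter vector.
#' @param data A [ddm_session()].
#' @param spec A [model_spec()].
#' @param n_noise_reals Latent-noise realizations per trial (default 20).
#' @param groups Number of evidence groups.
#' @param sim_step Simulation step in seconds.
#' @return A `ddm_psth` object of model expected rates.
#' @export
synthetic_psth <- function(theta, data, spec, n_noise_reals = 20L,
                           groups = 2L, sim_step = 1e-3) {
  session <- data
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  traces <- lapply(prep$trials, function(tr) {
    T <- tr$T
    abar <- matrix(0, n_noise_reals, T)
    train <- click_train_from_prep(tr)
    adapted <- adapt_clicks(train, th$theta_a[["phi"]],
                            th$theta_a[["tau_phi"]])
    sc <- signed_clicks(train, adapted)
    for (r in seq_len(n_noise_reals)) {
      sim <- cpp_sim_paths(sc$times, sc$mags, T * spec$dt + spec$dt / 2,
                           tr$duration, sim_step,
                           th$theta_a[["sigma2_i"]], th$theta_a[["B"]],
                           th$theta_a[["lambda"]], th$theta_a[["sigma2_a"]],
                           th$theta_a[["sigma2_s"]], 1L, spec$dt, T)
      abar[r, ] <- sim$bin_avg
    }
    ids <- prep$neuron_ids
    out <- matrix(NA_real_, length(ids), T, dimnames = list(ids, NULL))
    for (r2 in seq_along(tr$neuron_ids)) {
      arg <- outer(rep(1, n_noise_reals), tr$theta0[r2, ]) +
        th$slopes[tr$neuron_ids[r2]] * abar
      out[tr$neuron_ids[r2], ] <- colMeans(matrix(softplus(arg),
                                                  n_noise_reals, T))
    }
    out
  })
  build_psth(traces, session, spec$dt, groups)
}

click_train_from_prep <- function(tr) {
  click_train(tr$times[tr$side == 0L], tr$times[tr$side == 1L], tr$duration)
}

#' Coefficient of determination between empirical and model PSTHs
#'
#' `1 - SSE/SST` pooled over the evidence groups and a time window, per
#' neuron.  SST is relative to the grand mean over groups and window times.
#'
#' @param empirical,synthetic `ddm_psth` objects on matched bins.
#' @param window Time window in seconds, `c(lo, hi)`, intersected with the
#'   available bins.  Default `c(-0.2, 0.5)` relative to stimulus onset (the
#'   pre-onset part only matters when traces extend before onset).
#' @return Named vector of per-neuron R^2.
#' @export
psth_r2 <- function(empirical, synthetic, window = c(-0.2, 0.5)) {
  tt <- empirical$time
  keep <- which(tt >= window[1] & tt <= window[2])
  if (!length(keep)) stop("empty comparison window")
  ids <- dimnames(empirical$rate)[[1]]
  out <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(ids)) {
    r <- empirical$rate[i, , keep, drop = TRUE]
    f <- synthetic$rate[i, , keep, drop = TRUE]
    ok <- is.finite(r) & is.finite(f)
    if (!any(ok)) { out[i] <- NA_real_; next }
    sst <- sum((r[ok] - mean(r[ok]))^2)
    if (sst == 0) { out[i] <- NA_real_; next }
    out[i] <- 1 - sum((r[ok] - f[ok])^2) / sst
  }
  out
}

#' Shuffle-corrected cross-correlation of a neuron pair
#'
#' The raw cross-correlation (normalized by one neuron's mean rate, with the
#' other's mean rate subtracted) minus the cross-correlation of the
#' condition PSTHs: excess (trial-to-trial) correlation beyond what the mean
#' responses predict.  Only bins valid on both traces contribute
#' (ragged-trial `N_k(tau)` counting).
#'
#' @param counts_m,counts_n Lists of per-trial binned counts (or rate
#'   traces) of neurons `m` and `n`, simultaneously recorded.
#' @param psth_m,psth_n Per-trial-group expected rates: matrices `groups x
#'   Tmax` (e.g. slices of a `ddm_psth`).
#' @param group_of Per-trial group index (for the PSTH correction term).
#' @param dt Bin width, seconds.
#' @param tau_range Lag range in seconds (default +-0.8 s).
#' @return Data frame `tau`, `raw`, `psth`, `corrected`.
#' @export
xcorr_shuffle_corrected <- function(counts_m, counts_n, psth_m, psth_n,
                                    group_of, dt, tau_range = 0.8) {
  taus <- seq(-round(tau_range / dt), round(tau_range / dt))
  K <- length(counts_m)
  rate_m <- unlist(counts_m) / dt
  rate_n <- unlist(counts_n) / dt
  mm <- mean(rate_m); mn <- mean(rate_n)
  raw <- vapply(taus, function(tl) {
    acc <- 0; used <- 0
    for (k in seq_len(K)) {
      yn <- counts_n[[k]] / dt; ym <- counts_m[[k]] / dt
      T <- length(yn)
      tt <- seq_len(T)
      ts <- tt - tl
      ok <- ts >= 1 & ts <= T
      if (!any(ok)) next
      acc <- acc + sum(yn[tt[ok]] * ym[ts[ok]]) / sum(ok)
      used <- used + 1
    }
    if (used == 0) return(NA_real_)
    acc / used / mm - mn
  }, numeric(1))
  psth_term <- vapply(taus, function(tl) {
    acc <- 0; used <- 0
    for (g in seq_len(nrow(psth_m))) {
      rn <- psth_n[g, ]; rm <- psth_m[g, ]
      ok0 <- is.finite(rn) & is.finite(rm)
      T <- max(which(ok0), 0)
      if (T == 0) next
      tt <- seq_len(T); ts <- tt - tl
      ok <- ts >= 1 & ts <= T
      ok[ok] <- ok0[tt[ok]] & ok0[ts[ok]]
      if (!any(ok)) next
      acc <- acc + sum(rn[tt[ok]] * rm[ts[ok]]) / sum(ok)
      used <- used + 1
    }
    if (used == 0) return(NA_real_)
    acc / used / mm - mn
  }, numeric(1))
  data.frame(tau = taus * dt, raw = raw, psth = psth_term,
             corrected = raw - psth_term)
}

#' Psychometric curve with lapse
#'
#' Logistic regression of choice on the final click difference, with a bias
#' and a single lapse parameter scaling the asymptotes.
#'
#' @param choices 0/1 vector.
#' @param dclick Final click difference per trial.
#' @return Object of class `psychometric`: the fitted `lapse_glm` plus a
#'   `curve(x)` function.
#' @export
psychometric <- function(choices, dclick) {
  if (length(unique(dclick)) < 2) stop("need >= 2 distinct click differences")
  fit <- bernoulli_glm(matrix(dclick, ncol = 1), choices)
  structure(list(fit = fit,
                 bias = fit$coef[1], slope = fit$coef[2],
                 gamma = fit$gamma,
                 curve = function(x) predict(fit, matrix(x, ncol = 1)),
                 range = range(dclick)),
            class = "psychometric")
}

#' R^2 between two psychometric curves
#'
#' Coefficient of determination of one fitted curve against another over the
#' observed click-difference range.
#'
#' @param emp,syn `psychometric` objects.
#' @param at Evaluation points; defaults to the integer click differences in
#'   the shared observed range.
#' @return Scalar R^2.
#' @export
psychometric_r2 <- function(emp, syn, at = NULL) {
  if (is.null(at)) {
    rr <- c(max(emp$range[1], syn$range[1]), min(emp$range[2], syn$range[2]))
    at <- seq(floor(rr[1]), ceiling(rr[2]))
  }
  y <- emp$curve(at); f <- syn$curve(at)
  1 - sum((y - f)^2) / sum((y - mean(y))^2)
}

#' Detect putative change-of-mind events
#'
#' Scans a posterior-mean trace for crossings of the decision criterion that
#' (i) stay on one side for at least `pre` seconds before and `post` seconds
#' after the crossing, and (ii) reach an absolute magnitude of at least
#' `magnitude` somewhere in that window.
#'
#' @param trace Posterior-mean trace (clicks) on a uniform time grid.
#' @param dt Grid step in seconds.
#' @param c Decision criterion.
#' @param pre,post Dwell requirements in seconds (defaults 0.05).
#' @param magnitude Minimum absolute excursion within the window (default 2).
#' @return Data frame `time`, `direction` (`"L2R"`/`"R2L"`), zero rows if
#'   none.
#' @export
detect_com <- function(trace, dt, c = 0, pre = 0.05, post = 0.05,
                       magnitude = 2) {
  T <- length(trace)
  nb_pre <- round(pre / dt)
  nb_post <- round(post / dt)
  empty <- data.frame(time = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  if (T * dt < pre + post) {
    warning("trace shorter than the dwell window: no events reported")
    return(empty)
  }
  s <- sign(trace - c)
  cross <- which(s[-T] != 0 & s[-1] != 0 & s[-T] != s[-1])
  out <- empty
  for (i in cross) {
    lo <- i - nb_pre + 1; hi <- i + nb_post
    if (lo < 1 || hi > T) next
    if (!all(s[lo:i] == s[i]) || !all(s[(i + 1):hi] == s[i + 1])) next
    if (max(abs(trace[lo:hi])) < magnitude) next
    out <- rbind(out, data.frame(
      time = i * dt,
      direction = if (s[i + 1] > 0) "L2R" else "R2L",
      stringsAsFactors = FALSE))
  }
  out
}

#' Participation ratio of a neural population
#'
#' `(sum lambda)^2 / sum lambda^2` over the eigenvalues of the firing-rate
#' covariance matrix: the effective dimensionality, between 1 (rank one) and
#' the number of neurons (independent, equal-variance channels).
#'
#' @param rates Matrix of filtered rates, samples x neurons (stack trials
#'   and time bins along rows), or a precomputed covariance matrix
#'   (`is_cov = TRUE`).
#' @param is_cov Is `rates` already a covariance matrix?
#' @return Scalar in `[1, N]`.
#' @export
participation_ratio <- function(rates, is_cov = FALSE) {
  C <- if (is_cov) rates else cov(rates)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) == 0) stop("rank-0 covariance")
  sum(ev)^2 / sum(ev^2)
}

#' Select choice-tuned neurons
#'
#' Keeps neurons whose stimulus-period mean firing rate differs between
#' left- and right-choice trials by a two-sided t-test at `alpha`.
#'
#' @param session A [ddm_session()].
#' @param alpha Significance threshold (default 0.01).
#' @return Character vector of kept neuron ids; p-values as attribute.
#' @export
select_tuned_neurons <- function(session, alpha = 0.01) {
  ids <- session$neurons$id
  ch <- vapply(session$trials, `[[`, numeric(1), "choice")
  keep <- character(0); pvals <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    rate <- vapply(session$trials, function(tr) {
      s <- tr$spikes[[id]]
      if (is.null(s)) NA_real_ else length(s) / tr$duration
    }, numeric(1))
    ok <- !is.na(rate)
    rl <- rate[ok & ch == 0]; rr <- rate[ok & ch == 1]
    if (length(rl) < 2 || length(rr) < 2)
      stop("need >= 2 trials per choice class for neuron ", id)
    p <- tryCatch(t.test(rl, rr)$p.value, error = function(e) 1)
    pvals[id] <- p
    if (is.finite(p) && p < alpha) keep <- c(keep, id)
  }
  attr(keep, "p_values") <- pvals
  keep
}

#' Regress response latency on change-of-mind timing
#'
#' Ordinary least squares of response latency on event time relative to
#' stimulus offset, with a two-sided t-test on the slope.
#'
#' @param event_times Event times relative to stimulus end (s), one per
#'   event.
#' @param latencies Response latency for the corresponding trials (s).
#' @return List: `slope`, `intercept`, `p_value`, `fit` (the `lm`).
#' @export
com_latency_regression <- function(event_times, latencies) {
  if (length(event_times) < 3) stop("need >= 3 events")
  if (length(unique(event_times)) < 2) stop("constant regressor")
  fit <- lm(latencies ~ event_times)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       p_value = sm$coefficients[2, 4], fit = fit)
}
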