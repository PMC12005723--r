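# Shared fixtures and independent oracles, built in code at test time.

# ---------------------------------------------------------------------------
# Exhaustive-path oracle: enumerate every path a_0..a_T of the discretized
# chain and sum P(a_0) prod_t M_t[a_t, a_{t-1}] g_t(a_t) h(a_T).  Independent
# of the forward-backward implementation (direct tensor enumeration).
# ---------------------------------------------------------------------------
brute_paths <- function(n, T) {
  as.matrix(expand.grid(rep(list(seq_len(n)), T + 1)))
}

brute_path_probs <- function(p0, Ms, logfac = NULL, cf = NULL,
                             paths = brute_paths(length(p0), length(Ms))) {
  T <- length(Ms)
  pr <- p0[paths[, 1]]
  for (t in seq_len(T)) {
    pr <- pr * Ms[[t]][cbind(paths[, t + 1], paths[, t])]
    if (!is.null(logfac)) pr <- pr * exp(logfac[paths[, t + 1], t])
  }
  if (!is.null(cf)) pr <- pr * cf[paths[, T + 1]]
  pr
}

brute_marginal <- function(pr, paths, t, n) {
  # marginal over a_t (t in 0..T) given unnormalized path probabilities
  m <- vapply(seq_len(n), function(i) sum(pr[paths[, t + 1] == i]),
              numeric(1))
  m / sum(m)
}

# Choice factor: each bin a uniform interval of one grid width; H is the
# fraction of the interval above c (1/2 when c is at the bin center).
brute_choice_factor <- function(centers, choice, c, gamma) {
  w <- centers[3] - centers[2]
  H <- pmin(pmax((centers + w / 2 - c) / w, 0), 1)
  pr <- gamma / 2 + (1 - gamma) * H
  if (choice == 1) pr else 1 - pr
}

# Spike log-factors recomputed from the exported observation primitives.
brute_logfac <- function(centers, slopes, theta0, y, dt,
                         family = "poisson", disp = NULL) {
  n <- length(centers); T <- ncol(y)
  out <- matrix(0, n, T)
  for (t in seq_len(T)) for (i in seq_len(n)) {
    for (nn in seq_len(nrow(y))) {
      r <- conditional_intensity(centers[i], slopes[nn], theta0[nn, t])
      out[i, t] <- out[i, t] +
        if (family == "poisson") poisson_loglik(y[nn, t], r, dt)
        else negbin_loglik(y[nn, t], r, disp[nn], dt)
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Tiny fixtures
# ---------------------------------------------------------------------------

# A tiny two-neuron session: short trials so the path space is enumerable.
tiny_session <- function(K = 3, duration = 0.05, seed = 42) {
  set.seed(seed)
  trials <- lapply(seq_len(K), function(k) {
    nl <- rpois(1, 1.5); nr <- rpois(1, 1.5)
    list(left_times = sort(runif(nl, 0, duration)),
         right_times = sort(runif(nr, 0, duration)),
         duration = duration, choice = rbinom(1, 1, 0.5),
         spikes = list(nA = sort(runif(rpois(1, 2), 0, duration)),
                       nB = sort(runif(rpois(1, 2), 0, duration))),
         session_id = 1L)
  })
  ddm_session(trials)
}

tiny_theta <- function(spec, ids = c("nA", "nB")) {
  th_a <- accumulator_params(sigma2_i = 0.5, B = 4, lambda = -0.5,
                             sigma2_a = 4, sigma2_s = 0.5, phi = 0.6,
                             tau_phi = 0.08)
  pack_theta(th_a, c(c = 0.3, gamma = 0.1),
             slopes = setNames(c(1.5, -1), ids),
             dispersion = if (spec$obs_family == "negbinomial")
               setNames(c(3, 5), ids),
             spec = spec, neuron_ids = ids)
}

# Reconstruct a trial's per-bin transition operators from the exported API
# (adapt + bin + transition_matrix), independently of the filter internals.
trial_operators <- function(session, k, theta, spec) {
  tr <- session$trials[[k]]
  train <- click_train(tr$left_times, tr$right_times, tr$duration)
  th_a <- theta[c("sigma2_i", "B", "lambda", "sigma2_a", "sigma2_s",
                  "phi", "tau_phi")]
  grid <- make_grid(th_a[["B"]], spec$n)
  mags <- adapt_clicks(train, th_a[["phi"]], th_a[["tau_phi"]])
  st <- bin_stimulus(train, mags, spec$dt)
  Ms <- lapply(seq_len(st$n_bins), function(t)
    transition_matrix(th_a, st$delta[t], st$sigma[t], spec$dt, grid,
                      spec$refine))
  list(grid = grid, Ms = Ms,
       p0 = initial_distribution(th_a[["sigma2_i"]], grid, spec$refine,
                                 correct = spec$settle_correction),
       stim = st)
}

# note-free access to per-trial binned spikes/baselines as the model sees them
tiny_prep <- function(session, spec) {
  suppressWarnings(prepare_session(session, spec))
}

# Default accumulator parameters used across the simulation-based tests:
# the declared plausible regime (leaky accumulation, moderate bound,
# diffusion-dominated noise, strong fast adaptation).
plausible_theta_a <- function(lambda = -1) {
  accumulator_params(sigma2_i = 1, B = 15, lambda = lambda, sigma2_a = 20,
                     sigma2_s = 1, phi = 0.3, tau_phi = 0.05)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
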