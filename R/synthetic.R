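#' Synthetic-session configuration
#'
#' The stated world of the generator: Poisson click trains at a 40 Hz total
#' rate with per-trial right-rate fractions spanning easy to hard
#' (1:39 to 39:1), durations uniform on 0.2-1.0 s (rounded up to the model
#' grid), physiologically plausible accumulator parameters, softplus tuning
#' with RBF baselines, and lapse-contaminated threshold choices.
#'
#' @param n_trials,n_neurons Counts.
#' @param theta_a True [accumulator_params()].
#' @param theta_d True `c(c = ..., gamma = ...)`.
#' @param slopes True tuning slopes (length `n_neurons`; default
#'   alternating +-3).
#' @param rbf_weights Baseline RBF weights, `n_basis x n_neurons` (default
#'   all 8, i.e. baseline rates of roughly 10-20 Hz).
#' @param total_rate Total click rate, Hz (default 40).
#' @param right_frac_range Range of the per-trial right-rate fraction
#'   (default `c(0.025, 0.975)`).
#' @param duration_range Stimulus duration range in seconds (default
#'   0.2-1.0).
#' @param dt Model time step (s).
#' @param sim_step Euler-Maruyama step (s, default 1e-4; must be <= dt/10).
#' @param noise `"shared"` (one accumulator for all neurons and the choice)
#'   or `"independent"` (per-neuron accumulators; the choice follows a
#'   randomly selected one).
#' @param obs_family `"poisson"` or `"negbinomial"`.
#' @param dispersion Per-neuron NB dispersions (negbinomial only).
#' @param n_basis Number of baseline basis functions.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 2000L, n_neurons = 5L,
                       theta_a = accumulator_params(),
                       theta_d = c(c = 0, gamma = 0.05),
                       slopes = NULL, rbf_weights = NULL,
                       total_rate = 40, right_frac_range = c(0.025, 0.975),
                       duration_range = c(0.2, 1.0), dt = 0.01,
                       sim_step = 1e-4,
                       noise = c("shared", "independent"),
                       obs_family = c("poisson", "negbinomial"),
                       dispersion = NULL, n_basis = 6L) {
  noise <- match.arg(noise)
  obs_family <- match.arg(obs_family)
  if (sim_step > dt / 10) stop("`sim_step` must be <= dt/10")
  if (total_rate < 0) stop("`total_rate` must be >= 0")
  if (is.null(slopes))
    slopes <- rep_len(c(3, -3), n_neurons)
  if (is.null(rbf_weights))
    rbf_weights <- matrix(8, n_basis, n_neurons)
  if (obs_family == "negbinomial" && is.null(dispersion))
    dispersion <- rep(2, n_neurons)
  structure(list(n_trials = as.integer(n_trials),
                 n_neurons = as.integer(n_neurons),
                 theta_a = theta_a, theta_d = theta_d, slopes = slopes,
                 rbf_weights = rbf_weights, total_rate = total_rate,
                 right_frac_range = right_frac_range,
                 duration_range = duration_range, dt = dt,
                 sim_step = sim_step, noise = noise,
                 obs_family = obs_family, dispersion = dispersion,
                 n_basis = as.integer(n_basis)),
            class = "sim_config")
}

#' Generate one Poisson click train
#'
#' Left/right clicks are independent Poisson processes whose rates sum to
#' `total_rate`, with the rightward fraction drawn uniformly from
#' `right_frac_range`; the duration is uniform on `duration_range`, rounded
#' up to a multiple of `dt`.
#'
#' @param cfg A [sim_config()].
#' @return A [click_train()] with attributes `right_frac`.
#' @export
gen_click_train <- function(cfg) {
  dur <- runif(1, cfg$duration_range[1], cfg$duration_range[2])
  dur <- ceiling(dur / cfg$dt - 1e-9) * cfg$dt
  frac <- runif(1, cfg$right_frac_range[1], cfg$right_frac_range[2])
  rR <- cfg$total_rate * frac
  rL <- cfg$total_rate - rR
  nR <- rpois(1, rR * dur); nL <- rpois(1, rL * dur)
  tr <- click_train(sort(runif(nL, 0, dur)), sort(runif(nR, 0, dur)), dur)
  attr(tr, "right_frac") <- frac
  tr
}

#' Simulate latent accumulator paths
#'
#' Euler-Maruyama integration of the bounded accumulator for one stimulus:
#' drift `lambda a`, diffusion `sigma2_a`, clicks applied at their exact
#' times with adapted magnitude plus click noise of variance
#' `sigma2_s * |magnitude|`; the path freezes at the bound (sticky).
#'
#' @param theta_a [accumulator_params()].
#' @param train A [click_train()].
#' @param step Integration step (s).
#' @param n_reps Number of independent noise realizations.
#' @param dt_out If > 0, also return per-spike-bin averages of repetition 1
#'   (half-offset convention), simulating to `T dt + dt/2`.
#' @return List: `a_choice` (state at stimulus end, length `n_reps`),
#'   `a_end`, `bin_avg` (when `dt_out > 0`).
#' @export
simulate_latent <- function(theta_a, train, step = 1e-4, n_reps = 1L,
                            dt_out = 0) {
  if (step <= 0) stop("`step` must be positive")
  adapted <- adapt_clicks(train, theta_a[["phi"]], theta_a[["tau_phi"]])
  sc <- signed_clicks(train, adapted)
  T <- if (dt_out > 0) n_time_bins(train$duration, dt_out) else 0L
  t_end <- if (dt_out > 0) T * dt_out + dt_out / 2 else train$duration
  cpp_sim_paths(sc$times, sc$mags, t_end, train$duration, step,
                theta_a[["sigma2_i"]], theta_a[["B"]], theta_a[["lambda"]],
                theta_a[["sigma2_a"]], theta_a[["sigma2_s"]],
                as.integer(n_reps), dt_out, T)
}

#' Simulate spike counts from a latent path
#'
#' Poisson (or negative binomial) counts at `softplus(slope a + theta0)`
#' evaluated on the bin-averaged path.
#'
#' @param bin_avg Bin-averaged accumulator values (length T).
#' @param slopes Per-neuron tuning slopes.
#' @param theta0 Baseline arguments, neurons x T.
#' @param dt Bin width (s).
#' @param obs_family `"poisson"` or `"negbinomial"`.
#' @param dispersion Per-neuron NB dispersions.
#' @return Integer matrix neurons x T.
#' @export
simulate_spikes <- function(bin_avg, slopes, theta0, dt,
                            obs_family = "poisson", dispersion = NULL) {
  N <- length(slopes); T <- length(bin_avg)
  y <- matrix(0L, N, T)
  for (i in seq_len(N)) {
    mu <- softplus(slopes[i] * bin_avg + theta0[i, seq_len(T)]) * dt
    y[i, ] <- if (obs_family == "poisson") rpois(T, mu)
              else rnbinom(T, size = dispersion[i], mu = mu)
  }
  y
}

#' Simulate a lapse-threshold choice
#'
#' @param a_T Final accumulator value.
#' @param c Criterion.
#' @param gamma Lapse probability.
#' @return 0 (left) or 1 (right).
#' @export
simulate_choice <- function(a_T, c, gamma) {
  if (runif(1) < gamma) return(rbinom(1, 1, 0.5))
  as.integer(a_T > c)
}

#' Generate a complete synthetic session
#'
#' End-to-end generator: click trains, latent paths (shared or per-neuron
#' independent noise), spikes, choices, packaged as a [ddm_session()]
#' loadable by all fitting routines.  Spike counts are converted to spike
#' times drawn uniformly within their bin so the session round-trips through
#' [bin_spikes()].
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the dataset is bitwise-reproducible given
#'   `(cfg, seed)`.
#' @return List: `session` ([ddm_session()]), `truth` (generating
#'   parameters, including the flat vector for each model variant),
#'   `a_final` (per-trial latent endpoints; matrix for independent noise).
#' @export
make_dataset <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  N <- cfg$n_neurons
  ids <- sprintf("n%02d", seq_len(N))
  basis <- rbf_design(cfg$duration_range[2], cfg$dt, cfg$n_basis)
  theta0_full <- sapply(seq_len(N), function(i)
    eval_baseline(cfg$rbf_weights[, i], basis, basis$n_bins))  # T x N
  trials <- vector("list", cfg$n_trials)
  a_final <- if (cfg$noise == "shared") numeric(cfg$n_trials)
             else matrix(0, cfg$n_trials, N)
  for (k in seq_len(cfg$n_trials)) {
    train <- gen_click_train(cfg)
    T <- n_time_bins(train$duration, cfg$dt)
    th0 <- t(theta0_full[seq_len(T), , drop = FALSE])
    if (cfg$noise == "shared") {
      sim <- simulate_latent(cfg$theta_a, train, cfg$sim_step, 1L, cfg$dt)
      y <- simulate_spikes(sim$bin_avg, cfg$slopes, th0, cfg$dt,
                           cfg$obs_family, cfg$dispersion)
      aT <- sim$a_choice[1]
      a_final[k] <- aT
    } else {
      y <- matrix(0L, N, T)
      aTs <- numeric(N)
      for (i in seq_len(N)) {
        sim <- simulate_latent(cfg$theta_a, train, cfg$sim_step, 1L, cfg$dt)
        y[i, ] <- simulate_spikes(sim$bin_avg, cfg$slopes[i],
                                  th0[i, , drop = FALSE], cfg$dt,
                                  cfg$obs_family, cfg$dispersion[i])
        aTs[i] <- sim$a_choice[1]
      }
      a_final[k, ] <- aTs
      aT <- aTs[sample.int(N, 1)]
    }
    choice <- simulate_choice(aT, cfg$theta_d[["c"]], cfg$theta_d[["gamma"]])
    spikes <- counts_to_times(y, cfg$dt, train$duration)
    names(spikes) <- ids
    trials[[k]] <- list(left_times = train$left_times,
                        right_times = train$right_times,
                        duration = train$duration, choice = choice,
                        spikes = spikes, session_id = 1L)
  }
  session <- ddm_session(trials,
                         neurons = data.frame(id = ids, region = "synthetic",
                                              latency = 0,
                                              stringsAsFactors = FALSE),
                         meta = list(source = "pulseDDM::make_dataset",
                                     seed = seed, noise = cfg$noise))
  spec <- model_spec(if (cfg$noise == "shared") "joint-shared"
                     else "joint-independent",
                     cfg$obs_family, dt = cfg$dt)
  truth <- list(theta_a = cfg$theta_a, theta_d = cfg$theta_d,
                slopes = setNames(cfg$slopes, ids),
                dispersion = if (!is.null(cfg$dispersion))
                  setNames(cfg$dispersion, ids),
                rbf_weights = cfg$rbf_weights, noise = cfg$noise,
                theta = pack_theta(cfg$theta_a, cfg$theta_d,
                                   setNames(cfg$slopes, ids),
                                   cfg$dispersion, spec, ids))
  list(session = session, truth = truth, a_final = a_final)
}

# Spike counts -> spike times uniform within each bin's half-offset window.
counts_to_times <- function(y, dt, duration) {
  lapply(seq_len(nrow(y)), function(i) {
    tt <- numeric(0)
    for (t in which(y[i, ] > 0)) {
      lo <- max(0, t * dt - dt / 2)
      hi <- t * dt + dt / 2
      tt <- c(tt, runif(y[i, t], lo, hi))
    }
    sort(tt)
  })
}

#' Parameter-recovery report
#'
#' Tabulates per-parameter truth, estimate, Laplace interval, and whether
#' the truth falls inside the interval.
#'
#' @param truth The `truth` element of [make_dataset()] (or a flat named
#'   vector).
#' @param fit A [fit_mle()] result with confidence intervals.
#' @return Data frame: `parameter`, `true`, `estimate`, `lower`, `upper`,
#'   `inside`, `abs_error`.
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  tv <- if (is.list(truth)) truth$theta else truth
  ci <- fit$ci %||% laplace_ci(fit)
  nm <- fit$param_names
  tr <- unname(tv[nm])
  data.frame(parameter = nm, true = tr, estimate = unname(fit$theta_hat[nm]),
             lower = ci$lower, upper = ci$upper,
             inside = tr >= ci$lower & tr <= ci$upper,
             abs_error = abs(tr - unname(fit$theta_hat[nm])),
             stringsAsFactors = FALSE)
}
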