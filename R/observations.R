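#' Radial-basis-function baseline design
#'
#' Six unnormalized Gaussian bumps whose means tile `[0, max_duration]`
#' uniformly; the shared variance equals the spacing between means (taken
#' literally, in squared units of the time axis).  Used to capture each
#' neuron's time-varying, stimulus-independent baseline.
#'
#' @param max_duration Longest trial length in seconds.
#' @param dt Time bin width in seconds (bins centered at `t * dt`, matching
#'   the spike-bin convention).
#' @param n_basis Number of basis functions (default 6).
#' @return Object of class `rbf_basis`: fields `means`, `variance`, `dt`,
#'   `n_bins`, and `X` (`n_bins x n_basis` basis matrix).
#' @export
rbf_design <- function(max_duration, dt, n_basis = 6L) {
  stopifnot(max_duration > 0, dt > 0, n_basis >= 2)
  means <- seq(0, max_duration, length.out = n_basis)
  spacing <- means[2] - means[1]
  variance <- spacing
  T <- n_time_bins(max_duration, dt)
  tt <- seq_len(T) * dt
  X <- sapply(means, function(mu) exp(-(tt - mu)^2 / (2 * variance)))
  structure(list(means = means, variance = variance, dt = dt, n_bins = T,
                 times = tt, X = X),
            class = "rbf_basis")
}

# Evaluate the pre-softplus baseline argument theta0(t) for bins 1..T.
eval_baseline <- function(weights, basis, T) {
  T <- min(T, basis$n_bins)
  as.numeric(basis$X[seq_len(T), , drop = FALSE] %*% weights)
}

#' Fit per-neuron baseline weights
#'
#' Maximizes the Poisson likelihood of a neuron's binned spikes under the
#' intensity `softplus(sum_i w_i RBF_i(t))`, pooling all trials (ragged trial
#' lengths allowed).  The fitted `theta0(t) = sum_i w_i RBF_i(t)` is held
#' fixed during joint model fitting.  With `link = "linear"` the literal
#' clamped-linear intensity `max(theta0, eps)` is used instead.
#'
#' @param counts List of integer vectors (one per trial) or a matrix
#'   (trials x bins) of one neuron's binned spike counts.
#' @param basis An [rbf_design()] object.
#' @param link `"softplus"` (default) or `"linear"`.
#' @return List with `weights`, `theta0` (per-bin argument over the full
#'   basis window), `converged`.
#' @export
fit_baseline <- function(counts, basis, link = c("softplus", "linear")) {
  link <- match.arg(link)
  if (is.matrix(counts)) counts <- split(counts, row(counts))
  Ts <- vapply(counts, length, integer(1))
  if (!length(Ts) || any(Ts < 1)) stop("need >= 1 trial with >= 1 bin")
  X <- do.call(rbind, lapply(Ts, function(T)
    basis$X[seq_len(min(T, basis$n_bins)), , drop = FALSE]))
  y <- unlist(lapply(seq_along(counts), function(k)
    counts[[k]][seq_len(min(Ts[k], basis$n_bins))]))
  dt <- basis$dt
  if (all(y == 0)) {
    warning("all-zero spike train: baseline driven to the intensity floor")
    w <- rep(-20, ncol(X))
    return(list(weights = w, theta0 = eval_baseline(w, basis, basis$n_bins),
                converged = TRUE))
  }
  negll <- function(w) {
    eta <- as.numeric(X %*% w)
    r <- if (link == "softplus") pmax(log1p(exp(pmin(eta, 30))),
                                      ifelse(eta > 30, eta, 0)) else eta
    r <- pmax(r, 1e-6)
    -sum(y * log(r * dt) - r * dt)
  }
  grad <- function(w) {
    eta <- as.numeric(X %*% w)
    if (link == "softplus") {
      r <- pmax(ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))), 1e-6)
      dr <- plogis(eta)
    } else {
      r <- pmax(eta, 1e-6)
      dr <- as.numeric(eta > 1e-6)
    }
    -as.numeric(t(X) %*% ((y / r - dt) * dr))
  }
  init <- rep(mean(y) / dt + 1, ncol(X))
  fit <- optim(init, negll, grad, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-9))
  list(weights = fit$par,
       theta0 = eval_baseline(fit$par, basis, basis$n_bins),
       converged = fit$convergence == 0)
}

#' Conditional spike intensity
#'
#' `softplus(slope * a + theta0_t)`, the expected firing rate (Hz) of a
#' neuron given the accumulator value `a`.
#'
#' @param a Accumulator value(s), clicks.
#' @param slope Tuning slope (per click).
#' @param theta0_t Baseline argument (pre-softplus) at this time.
#' @return Rate(s) in Hz, strictly positive.
#' @export
conditional_intensity <- function(a, slope, theta0_t) {
  softplus(slope * a + theta0_t)
}

#' Poisson spike-count log-likelihood
#'
#' Full Poisson log-pmf (including the `-log y!` normalization) of a count
#' in a bin of width `dt` at rate `rate` Hz.
#'
#' @param y Non-negative integer count(s).
#' @param rate Rate(s), Hz (> 0).
#' @param dt Bin width, seconds.
#' @return Log-probability (vectorized).
#' @export
poisson_loglik <- function(y, rate, dt) {
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integers")
  dpois(y, rate * dt, log = TRUE)
}

#' Negative-binomial spike-count log-likelihood
#'
#' NB parameterized by `dispersion` (size) and success probability
#' `dispersion / (rate dt + dispersion)`, so the mean is `rate * dt`; the
#' Poisson model is the `dispersion -> Inf` limit.
#'
#' @param y Non-negative integer count(s).
#' @param rate Rate(s), Hz.
#' @param dispersion Dispersion (> 0); variance is `mu (1 + mu/dispersion)`.
#' @param dt Bin width, seconds.
#' @return Log-probability (vectorized).
#' @export
negbin_loglik <- function(y, rate, dispersion, dt) {
  if (any(dispersion <= 0)) stop("`dispersion` must be positive")
  if (any(y < 0) || any(y != round(y))) stop("`y` must be non-negative integers")
  dnbinom(y, size = dispersion, mu = rate * dt, log = TRUE)
}

#' Probability of a rightward choice
#'
#' With probability `gamma` the choice is a coin flip; otherwise it is
#' rightward iff the final accumulator value exceeds the criterion `c`.  On
#' the discrete grid each bin's mass is treated as spread uniformly over one
#' grid width, so the Heaviside factor is evaluated as the fraction of the
#' bin above `c`: mass in a bin whose center equals `c` counts half (the
#' `H(0) = 1/2` tie convention) and the probability is continuous and
#' piecewise linear in `c` (which also keeps the likelihood differentiable
#' for the optimizer).
#'
#' @param pT Probability vector over grid bins at the final time.
#' @param grid A [make_grid()] object.
#' @param c Decision criterion, clicks.
#' @param gamma Lapse probability in `[0, 1]`.
#' @return `P(choose right)`, within `[gamma/2, 1 - gamma/2]`.
#' @export
choice_prob <- function(pT, grid, c, gamma) {
  if (gamma < 0 || gamma > 1) stop("`gamma` must be in [0, 1]")
  H <- heaviside_frac(grid, c)
  gamma / 2 + (1 - gamma) * sum(pT * H)
}

# Fraction of each bin's (uniform, one grid width) interval above c.
heaviside_frac <- function(grid, c) {
  w <- grid$width
  pmin(pmax((grid$centers + w / 2 - c) / w, 0), 1)
}

# Per-bin choice factor P(d | a in bin i) used as the terminal HMM factor.
choice_factor <- function(grid, choice, c, gamma) {
  pr <- gamma / 2 + (1 - gamma) * heaviside_frac(grid, c)
  if (choice == 1) pr else 1 - pr
}
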