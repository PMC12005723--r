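# ---------------------------------------------------------------------------
# Parameter packing.  The full parameter vector is, in order:
#   sigma2_i, B, lambda, sigma2_a, sigma2_s, phi, tau_phi   (theta_a)
#   c, gamma                                                (theta_d)
#   slope_<id> per neuron                                   (theta_y, joint)
#   disp_<id> per neuron                                    (negbinomial only)
# ---------------------------------------------------------------------------

theta_a_names <- c("sigma2_i", "B", "lambda", "sigma2_a", "sigma2_s",
                   "phi", "tau_phi")

param_names <- function(spec, neuron_ids) {
  nm <- c(theta_a_names, "c", "gamma")
  if (spec$variant != "choice-only") {
    nm <- c(nm, paste0("slope_", neuron_ids))
    if (spec$obs_family == "negbinomial")
      nm <- c(nm, paste0("disp_", neuron_ids))
  }
  nm
}

#' Pack structured parameters into the flat vector used by the optimizer
#'
#' @param theta_a [accumulator_params()] or named length-7 vector.
#' @param theta_d Named vector `c(c = ..., gamma = ...)`.
#' @param slopes Named (by neuron id) or plain numeric vector of tuning
#'   slopes (joint variants).
#' @param dispersion Per-neuron dispersions (negative-binomial family).
#' @param spec A [model_spec()].
#' @param neuron_ids Neuron ids, in registry order.
#' @return Named numeric vector.
#' @export
pack_theta <- function(theta_a, theta_d, slopes = NULL, dispersion = NULL,
                       spec, neuron_ids = names(slopes)) {
  out <- c(unclass(theta_a)[theta_a_names],
           c = unname(theta_d[["c"]]), gamma = unname(theta_d[["gamma"]]))
  if (spec$variant != "choice-only") {
    s <- unname(slopes)
    names(s) <- paste0("slope_", neuron_ids)
    out <- c(out, s)
    if (spec$obs_family == "negbinomial") {
      d <- unname(dispersion)
      names(d) <- paste0("disp_", neuron_ids)
      out <- c(out, d)
    }
  }
  out
}

unpack_theta <- function(th, spec, neuron_ids) {
  out <- list(theta_a = th[theta_a_names],
              c = th[["c"]], gamma = th[["gamma"]])
  if (spec$variant != "choice-only") {
    out$slopes <- setNames(th[paste0("slope_", neuron_ids)], neuron_ids)
    if (spec$obs_family == "negbinomial")
      out$dispersion <- setNames(th[paste0("disp_", neuron_ids)], neuron_ids)
  }
  out
}

bounds_for <- function(nm, bounds = default_bounds()) {
  base <- sub("_(.*)$", "", nm)
  lo <- numeric(length(nm)); hi <- numeric(length(nm))
  for (i in seq_along(nm)) {
    key <- if (nm[i] %in% names(bounds)) nm[i]
           else if (startsWith(nm[i], "slope_")) "slope"
           else if (startsWith(nm[i], "disp_")) "dispersion"
           else stop("no bound for parameter ", nm[i])
    lo[i] <- bounds[[key]][1]; hi[i] <- bounds[[key]][2]
  }
  cbind(lo = lo, hi = hi)
}

# log-transform for strictly positive parameters, logit for gamma.
transform_kind <- function(nm) {
  ifelse(nm %in% c("sigma2_i", "B", "sigma2_a", "sigma2_s", "phi",
                   "tau_phi") | startsWith(nm, "disp_"), "log",
         ifelse(nm == "gamma", "logit", "id"))
}

to_internal <- function(x, kind) {
  y <- x
  y[kind == "log"] <- log(pmax(x[kind == "log"], 1e-12))
  g <- kind == "logit"
  y[g] <- qlogis(pmin(pmax(x[g], 1e-9), 1 - 1e-9))
  y
}

from_internal <- function(y, kind) {
  x <- y
  x[kind == "log"] <- exp(y[kind == "log"])
  x[kind == "logit"] <- plogis(y[kind == "logit"])
  x
}

# ---------------------------------------------------------------------------
# Core per-trial likelihood machinery
# ---------------------------------------------------------------------------

# Shared context for one parameter setting: grid, initial distribution and
# the no-click transition operator.
make_ll_context <- function(theta_a, spec) {
  grid <- make_grid(theta_a[["B"]], spec$n)
  corr <- spec$settle_correction %||% TRUE
  p0 <- cpp_initial_dist(grid$centers, theta_a[["sigma2_i"]], spec$refine,
                         corr)
  M0 <- cpp_transition_matrix(grid$centers, theta_a[["lambda"]], spec$dt,
                              0, theta_a[["sigma2_a"]] * spec$dt *
                                cpp_ou_vfac(theta_a[["lambda"]], spec$dt),
                              spec$refine, corr)
  list(grid = grid, p0 = p0, M0 = M0, correct = corr)
}

trial_stim <- function(trial, theta_a, spec) {
  if (length(trial$times)) {
    mags <- cpp_adapt_clicks(trial$times, trial$side, theta_a[["phi"]],
                             theta_a[["tau_phi"]], TRUE)$mags
    cpp_bin_clicks(trial$times, trial$side, mags, spec$dt, trial$T)
  } else {
    list(delta = numeric(trial$T), sigma = numeric(trial$T))
  }
}

trial_logfac <- function(trial, slopes, dispersion, ctx, spec, sub = NULL) {
  if (is.null(trial$y)) return(matrix(0, 0, 0))
  rows <- if (is.null(sub)) seq_along(trial$neuron_ids) else sub
  if (!length(rows)) return(matrix(0, 0, 0))
  fam <- if (spec$obs_family == "negbinomial") 1L else 0L
  sl <- unname(slopes[trial$neuron_ids[rows]])
  dp <- if (fam == 1L) unname(dispersion[trial$neuron_ids[rows]])
        else rep(1, length(rows))
  cpp_spike_logfac(ctx$grid$centers, sl,
                   trial$theta0[rows, , drop = FALSE],
                   trial$y[rows, , drop = FALSE],
                   spec$dt, fam, dp)
}

trial_forward <- function(trial, theta_a, ctx, spec, logfac = matrix(0, 0, 0),
                          want_alpha = FALSE, want_M = FALSE) {
  st <- trial_stim(trial, theta_a, spec)
  cpp_trial_filter(ctx$grid$centers, theta_a[["lambda"]], spec$dt,
                   theta_a[["sigma2_a"]], theta_a[["sigma2_s"]],
                   st$delta, st$sigma, logfac, ctx$p0, ctx$M0, spec$refine,
                   want_alpha, want_M, ctx$correct)
}

# ---------------------------------------------------------------------------
# Log-likelihoods
# ---------------------------------------------------------------------------

#' Joint (shared-accumulator) log-likelihood
#'
#' Single forward pass per trial over the discretized accumulator chain,
#' weighting by the per-bin spike likelihoods of every neuron recorded on
#' that trial and by the lapse-threshold choice factor at the final bin.
#'
#' @param theta Flat named parameter vector (see [pack_theta()]).
#' @param data A [ddm_session()] or [prepare_session()] result.
#' @param spec A [model_spec()] with a joint variant.
#' @param trial_subset Optional integer indices of trials to include.
#' @return Total log-likelihood in nats.
#' @export
joint_loglik <- function(theta, data, spec, trial_subset = NULL) {
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  ctx <- make_ll_context(th$theta_a, spec)
  idx <- trial_subset %||% seq_len(prep$K)
  ll <- 0
  for (k in idx) {
    trial <- prep$trials[[k]]
    lf <- trial_logfac(trial, th$slopes, th$dispersion, ctx, spec)
    fw <- trial_forward(trial, th$theta_a, ctx, spec, lf)
    if (!is.finite(fw$loglik))
      stop(sprintf("non-finite likelihood at trial %d (bin %d)",
                   trial$index, fw$bad_bin))
    cf <- choice_factor(ctx$grid, trial$choice, th$c, th$gamma)
    lc <- sum(fw$pT * cf)
    if (lc <= 0) stop(sprintf("zero choice likelihood at trial %d", trial$index))
    ll <- ll + fw$loglik + log(lc)
  }
  ll
}

#' Choice-only log-likelihood
#'
#' The same latent chain without spike factors: forward prior propagated to
#' the final bin, then the lapse-threshold choice factor.
#'
#' @inheritParams joint_loglik
#' @return Total log-likelihood in nats.
#' @export
choice_only_loglik <- function(theta, data, spec = NULL,
                               trial_subset = NULL) {
  if (is.null(spec)) spec <- model_spec("choice-only")
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  ctx <- make_ll_context(th$theta_a, spec)
  idx <- trial_subset %||% seq_len(prep$K)
  ll <- 0
  for (k in idx) {
    trial <- prep$trials[[k]]
    fw <- trial_forward(trial, th$theta_a, ctx, spec)
    cf <- choice_factor(ctx$grid, trial$choice, th$c, th$gamma)
    lc <- sum(fw$pT * cf)
    if (lc <= 0) stop(sprintf("zero choice likelihood at trial %d", trial$index))
    ll <- ll + log(lc)
  }
  ll
}

#' Independent-noise log-likelihood
#'
#' Each neuron is driven by its own accumulator (independent noise, shared
#' parameters): the spike likelihood is the product over per-neuron forward
#' passes, and the choice probability is the arithmetic mean of the
#' per-accumulator choice probabilities.
#'
#' @inheritParams joint_loglik
#' @return Total log-likelihood in nats.
#' @export
independent_loglik <- function(theta, data, spec, trial_subset = NULL) {
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  ctx <- make_ll_context(th$theta_a, spec)
  idx <- trial_subset %||% seq_len(prep$K)
  ll <- 0
  for (k in idx) {
    trial <- prep$trials[[k]]
    if (is.null(trial$y) || nrow(trial$y) == 0)
      stop(sprintf("trial %d has no recorded neurons", trial$index))
    # per-bin operators shared by all of the trial's accumulators
    fw0 <- trial_forward(trial, th$theta_a, ctx, spec, want_M = TRUE)
    cf <- choice_factor(ctx$grid, trial$choice, th$c, th$gamma)
    pc <- 0
    for (r in seq_along(trial$neuron_ids)) {
      lf <- trial_logfac(trial, th$slopes, th$dispersion, ctx, spec, sub = r)
      fn <- cpp_filter_given_M(fw0$M, lf, ctx$p0, FALSE)
      if (!is.finite(fn$loglik))
        stop(sprintf("non-finite likelihood at trial %d", trial$index))
      ll <- ll + fn$loglik
      pc <- pc + sum(fn$pT * cf)
    }
    pc <- pc / length(trial$neuron_ids)
    if (pc <= 0) stop(sprintf("zero choice likelihood at trial %d", trial$index))
    ll <- ll + log(pc)
  }
  ll
}

variant_loglik <- function(theta, prep, spec, trial_subset = NULL) {
  switch(spec$variant,
         "joint-shared" = joint_loglik(theta, prep, spec, trial_subset),
         "joint-independent" = independent_loglik(theta, prep, spec,
                                                  trial_subset),
         "choice-only" = choice_only_loglik(theta, prep, spec, trial_subset))
}

# ---------------------------------------------------------------------------
# Maximum likelihood fitting
# ---------------------------------------------------------------------------

# Default optimizer start: physiologically plausible accumulator values and
# rough per-neuron slope estimates (rate difference between right- and
# left-evidence trials against a nominal accumulator excursion).
default_start <- function(nm, prep, spec) {
  st <- c(sigma2_i = 1, B = 20, lambda = 0, sigma2_a = 10, sigma2_s = 1,
          phi = 0.8, tau_phi = 0.1, c = 0, gamma = 0.02)
  sl_names <- nm[startsWith(nm, "slope_")]
  if (length(sl_names)) {
    ids <- sub("^slope_", "", sl_names)
    dsum <- setNames(rep(0, length(ids)), ids)
    dpos <- dneg <- npos <- nneg <- dsum
    for (tr in prep$trials) {
      if (is.null(tr$y)) next
      dc <- sum(tr$side == 1L) - sum(tr$side == 0L)
      if (dc == 0) next
      r <- rowSums(tr$y) / (tr$T * spec$dt)
      for (j in seq_along(tr$neuron_ids)) {
        id <- tr$neuron_ids[j]
        if (!id %in% ids) next
        if (dc > 0) { dpos[id] <- dpos[id] + r[j]; npos[id] <- npos[id] + 1 }
        else { dneg[id] <- dneg[id] + r[j]; nneg[id] <- nneg[id] + 1 }
      }
    }
    sl <- (dpos / pmax(npos, 1) - dneg / pmax(nneg, 1)) / 8
    sl[!is.finite(sl)] <- 0
    st <- c(st, setNames(pmin(pmax(sl, -5), 5), sl_names))
  }
  dp_names <- nm[startsWith(nm, "disp_")]
  if (length(dp_names)) st <- c(st, setNames(rep(10, length(dp_names)),
                                             dp_names))
  unname(st[nm])
}

#' Fit a model by box-constrained maximum likelihood
#'
#' Quasi-Newton (L-BFGS-B) ascent on the log-likelihood in an internally
#' transformed space (log for positive-domain parameters, logit for the
#' lapse), with finite-difference gradients, optional multi-start, and the
#' printed optimization domain as box constraints.  Deterministic given
#' `(init, seed)`.
#'
#' @param spec A [model_spec()].
#' @param data A [ddm_session()] or [prepare_session()] result.
#' @param bounds Named list of `c(lo, hi)` domains (see `default_bounds`).
#' @param init Optional named initial parameter vector (must be within
#'   bounds); used as the first start.
#' @param seed Integer seed controlling start jitter.
#' @param n_starts Number of optimizer starts (default 3).
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @param factr L-BFGS-B convergence factor.
#' @param hessian Compute the finite-difference Hessian at the optimum?
#' @param baselines Optional precomputed [fit_baselines()] result.
#' @return Object of class `ddm_fit`: `theta_hat`, `loglik`, `hessian`,
#'   `ci` (via [laplace_ci()] when `hessian = TRUE`), `convergence`.
#' @export
fit_mle <- function(spec, data, bounds = default_bounds(), init = NULL,
                    seed = 1L, n_starts = 3L, maxit = 150L, factr = 1e8,
                    hessian = TRUE, baselines = NULL) {
  prep <- as_prep(data, spec, baselines)
  nm <- param_names(spec, prep$neuron_ids)
  bb <- bounds_for(nm, bounds)
  kind <- transform_kind(nm)
  lo_i <- to_internal(bb[, "lo"], kind)
  hi_i <- to_internal(bb[, "hi"], kind)
  lo_i[kind == "logit"] <- -20; hi_i[kind == "logit"] <- 20
  d <- length(nm)

  cache <- new.env(parent = emptyenv())
  negll <- function(y) {
    x <- setNames(from_internal(y, kind), nm)
    v <- tryCatch(variant_loglik(x, prep, spec), error = function(e) NA_real_)
    v <- if (!is.finite(v)) 1e12 else -v
    cache$x <- y; cache$f <- v
    v
  }
  # forward-difference gradient, reusing the cached objective value
  negll_gr <- function(y) {
    f0 <- if (!is.null(cache$x) && identical(cache$x, y)) cache$f
          else negll(y)
    h <- 1e-6 * (1 + abs(y))
    vapply(seq_along(y), function(i) {
      yp <- y; yp[i] <- y[i] + h[i]
      (negll(yp) - f0) / h[i]
    }, numeric(1))
  }

  # starts: a physiological default (mild adaptation, interior bound,
  # data-driven slope signs) plus +-10% domain-width jitters from the seed
  set.seed(as.integer(seed) %% .Machine$integer.max)
  mid <- to_internal(default_start(nm, prep, spec), kind)
  wid <- pmin(hi_i - lo_i, 8)
  starts <- list()
  if (!is.null(init)) {
    if (any(init[nm] < bb[, "lo"] - 1e-12 | init[nm] > bb[, "hi"] + 1e-12))
      stop("`init` outside the optimization domain")
    starts[[1]] <- to_internal(unname(init[nm]), kind)
  } else {
    starts[[1]] <- pmin(pmax(mid, lo_i), hi_i)
  }
  while (length(starts) < n_starts)
    starts[[length(starts) + 1L]] <-
      pmin(pmax(mid + runif(d, -0.1, 0.1) * wid, lo_i), hi_i)

  best <- NULL
  diags <- list()
  for (s in seq_along(starts)) {
    fit <- tryCatch(
      optim(starts[[s]], negll, gr = negll_gr, method = "L-BFGS-B",
            lower = lo_i, upper = hi_i,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) next
    diags[[s]] <- list(value = -fit$value, convergence = fit$convergence,
                       counts = fit$counts, message = fit$message)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  if (best$value >= 1e12)
    warning("objective non-finite at optimum; returning best-so-far")

  theta_hat <- setNames(from_internal(best$par, kind), nm)
  theta_hat <- pmin(pmax(theta_hat, bb[, "lo"]), bb[, "hi"])
  natural_ll <- function(x) {
    x <- setNames(pmax(x, ifelse(kind == "log", 1e-12, -Inf)), nm)
    v <- tryCatch(variant_loglik(x, prep, spec), error = function(e) NA_real_)
    if (!is.finite(v)) NA_real_ else v
  }
  out <- structure(list(
    theta_hat = theta_hat,
    theta = unpack_theta(theta_hat, spec, prep$neuron_ids),
    loglik = -best$value,
    spec = spec, bounds = bb, param_names = nm, kind = kind,
    natural_ll = natural_ll,
    hessian = NULL, ci = NULL,
    convergence = list(code = best$convergence, counts = best$counts,
                       message = best$message, seed = seed,
                       starts = diags),
    neuron_ids = prep$neuron_ids,
    baselines = prep$baselines
  ), class = "ddm_fit")
  if (hessian) {
    out$hessian <- fd_hessian(natural_ll, theta_hat, bb)
    out$ci <- laplace_ci(out)
  }
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("<ddm_fit> %s / %s, logLik = %.2f\n",
              x$spec$variant, x$spec$obs_family, x$loglik))
  print(round(x$theta_hat, 4))
  invisible(x)
}

# Central finite-difference Hessian with steps clipped to the domain.
fd_hessian <- function(f, x, bb, rel = 1e-3) {
  d <- length(x)
  h <- pmax(rel * pmax(abs(x), 0.1), 1e-6)
  h <- pmin(h, pmax((bb[, "hi"] - bb[, "lo"]) / 10, 1e-8))
  f0 <- f(x)
  H <- matrix(NA_real_, d, d)
  fp <- numeric(d); fm <- numeric(d)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- x[i] + h[i]
    xm <- x; xm[i] <- x[i] - h[i]
    fp[i] <- f(xp); fm[i] <- f(xm)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  for (i in seq_len(d)) for (j in seq_len(i - 1)) {
    xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h[c(i, j)]
    xpm <- x; xpm[i] <- x[i] + h[i]; xpm[j] <- x[j] - h[j]
    xmp <- x; xmp[i] <- x[i] - h[i]; xmp[j] <- x[j] + h[j]
    xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h[c(i, j)]
    H[i, j] <- H[j, i] <-
      (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h[i] * h[j])
  }
  dimnames(H) <- list(names(x), names(x))
  H
}

#' Laplace confidence intervals
#'
#' Per-parameter `+-2 sqrt(diag(H^-1))` intervals from the Hessian of the
#' log-likelihood at the optimum, truncated at the optimization domain.
#' Non-positive-semidefinite Hessians are repaired by (a) re-evaluating the
#' Hessian in log space for positive-domain parameters and (b) replacing
#' remaining negative eigenvalues with twice the quadratic coefficient of a
#' numerical line search along the offending eigenvector; irreparable
#' directions yield `NA` intervals.
#'
#' @param fit A [fit_mle()] result.
#' @return Data frame: `parameter`, `estimate`, `sd`, `lower`, `upper`,
#'   `method`.
#' @export
laplace_ci <- function(fit) {
  stopifnot(inherits(fit, "ddm_fit"))
  x <- fit$theta_hat
  bb <- fit$bounds
  H <- fit$hessian
  if (is.null(H)) H <- fd_hessian(fit$natural_ll, x, bb)
  nm <- fit$param_names
  method <- "hessian"
  sdv <- ci_from_hessian(H)
  lower <- upper <- rep(NA_real_, length(x))

  if (anyNA(sdv)) {
    # (a) re-evaluate in transformed (log/logit) space
    kind <- fit$kind
    ft <- function(y) fit$natural_ll(from_internal(y, kind))
    yhat <- to_internal(unname(x), kind)
    bbt <- cbind(lo = to_internal(bb[, "lo"], kind),
                 hi = to_internal(bb[, "hi"], kind))
    bbt[kind == "logit", ] <- cbind(-20, 20)[rep(1, sum(kind == "logit")), ]
    Ht <- fd_hessian(ft, setNames(yhat, nm), bbt)
    sdt <- ci_from_hessian(Ht)
    if (!anyNA(sdt)) {
      method <- "log-space"
      lo_t <- yhat - 2 * sdt; hi_t <- yhat + 2 * sdt
      lower <- from_internal(lo_t, kind)
      upper <- from_internal(hi_t, kind)
      sdv <- (upper - lower) / 4   # natural-scale summary of the interval
    }
  }
  if (anyNA(sdv)) {
    # (b) eigen-repair by quadratic line search
    Hr <- repair_hessian(H, fit$natural_ll, x, bb)
    sdv <- ci_from_hessian(Hr)
    if (!anyNA(sdv)) method <- "eigen-repair"
  }
  if (all(is.na(lower))) {
    lower <- x - 2 * sdv
    upper <- x + 2 * sdv
  }
  lower <- pmax(lower, bb[, "lo"])
  upper <- pmin(upper, bb[, "hi"])
  data.frame(parameter = nm, estimate = unname(x), sd = unname(sdv),
             lower = unname(lower), upper = unname(upper),
             method = method, stringsAsFactors = FALSE)
}

# per-parameter SD = sqrt(diag((-H)^-1)); NA if the Hessian is unusable
ci_from_hessian <- function(H) {
  if (is.null(H) || anyNA(H)) return(rep(NA_real_, nrow(H %||% matrix(NA, 1, 1))))
  eg <- eigen(-H, symmetric = TRUE)
  if (any(eg$values <= 1e-12)) return(rep(NA_real_, nrow(H)))
  inv <- eg$vectors %*% diag(1 / eg$values, nrow(H)) %*% t(eg$vectors)
  dg <- diag(inv)
  if (any(dg <= 0)) return(rep(NA_real_, nrow(H)))
  sqrt(dg)
}

repair_hessian <- function(H, f, x, bb) {
  if (anyNA(H)) return(NULL)
  eg <- eigen(-H, symmetric = TRUE)
  vals <- eg$values
  for (i in which(vals <= 1e-12)) {
    v <- eg$vectors[, i]
    # step range limited by the domain along +-v
    smax <- Inf
    for (j in seq_along(x)) {
      if (abs(v[j]) < 1e-12) next
      smax <- min(smax,
                  min(bb[j, "hi"] - x[j], x[j] - bb[j, "lo"]) / abs(v[j]))
    }
    smax <- min(smax, 0.5 * max(abs(x) + 1))
    if (!is.finite(smax) || smax <= 0) return(NULL)
    ss <- seq(-smax, smax, length.out = 11)
    ys <- vapply(ss, function(s) f(x + s * v), numeric(1))
    ok <- is.finite(ys)
    if (sum(ok) < 5) return(NULL)
    qf <- lm(ys[ok] ~ ss[ok] + I(ss[ok]^2))
    a <- coef(qf)[[3]]
    if (!is.finite(a) || a >= 0) return(NULL)
    vals[i] <- -2 * a
  }
  -(eg$vectors %*% diag(vals, length(vals)) %*% t(eg$vectors))
}

# ---------------------------------------------------------------------------
# Cross-validation and null models
# ---------------------------------------------------------------------------

#' Stratified k-fold trial split
#'
#' Randomly partitions the trials of each recording session into `k` folds
#' (so every fold's test set covers every session).  Deterministic given
#' `seed`.
#'
#' @param session A [ddm_session()] (or `ddm_prep`).
#' @param k Number of folds (>= 2; default 5 gives 80/20 splits).
#' @param seed Integer seed.
#' @return List of `k` elements, each `list(train = idx, test = idx)`.
#' @export
kfold_split <- function(session, k = 5L, seed = 1L) {
  if (k < 2) stop("`k` must be >= 2")
  sid <- if (inherits(session, "ddm_prep"))
    vapply(session$trials, `[[`, integer(1), "session_id")
  else vapply(session$trials, function(tr) as.integer(tr$session_id %||% 1L),
              integer(1))
  K <- length(sid)
  if (K < k) stop("fewer trials than folds")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  fold <- integer(K)
  for (s in unique(sid)) {
    idx <- which(sid == s)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

#' Cross-validated log-likelihood improvement in bits per trial
#'
#' `(ll_model - ll_null) / (K * ln 2)`: the per-trial log-likelihood gain of
#' a model over a null, in base-2 units.
#'
#' @param ll_model,ll_null Total log-likelihoods in nats.
#' @param K Number of trials.
#' @return Bits per trial.
#' @export
bits_per_trial <- function(ll_model, ll_null, K) {
  if (K <= 0) stop("`K` must be positive")
  (ll_model - ll_null) / (K * log(2))
}

#' Null choice and spike models
#'
#' The null choice model is a Bernoulli at the empirical rightward-choice
#' rate; the null spike model holds every neuron at its fitted time-varying
#' baseline rate (slope 0).
#'
#' @param data A [ddm_session()] or `ddm_prep`.
#' @param spec A [model_spec()].
#' @param p_right Optional Bernoulli rate (e.g. estimated on training data);
#'   defaults to the empirical rate of `trial_subset`.
#' @param trial_subset Optional trial indices to evaluate on.
#' @return List: `choice_ll`, `spike_ll`, `p_right`.
#' @export
null_models <- function(data, spec, p_right = NULL, trial_subset = NULL) {
  prep <- as_prep(data, spec)
  idx <- trial_subset %||% seq_len(prep$K)
  ch <- vapply(prep$trials[idx], `[[`, numeric(1), "choice")
  p <- p_right %||% mean(ch)
  eps <- 1e-12
  choice_ll <- sum(ch * log(pmax(p, eps)) + (1 - ch) * log(pmax(1 - p, eps)))
  spike_ll <- 0
  if (spec$variant != "choice-only") {
    for (k in idx) {
      trial <- prep$trials[[k]]
      if (is.null(trial$y)) next
      r <- softplus(as.numeric(trial$theta0))
      spike_ll <- spike_ll +
        sum(dpois(as.integer(trial$y), r * spec$dt, log = TRUE))
    }
  }
  list(choice_ll = choice_ll, spike_ll = spike_ll, p_right = p)
}
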