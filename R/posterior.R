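#' Posterior over the latent accumulator for one trial
#'
#' Forward-backward smoothing over the discretized accumulator chain,
#' conditioned on any subset of the trial's observations: nothing (the
#' forward prior), the choice, the spikes, or both.
#'
#' @param theta Flat named parameter vector ([pack_theta()]).
#' @param data A [ddm_session()] or [prepare_session()] result.
#' @param trial Trial index.
#' @param spec A [model_spec()].
#' @param condition One of `"none"`, `"choice"`, `"spikes"`,
#'   `"spikes+choice"`.
#' @param exclude_bounds Exclude bound-bin mass when computing the reported
#'   mean/SD (display convention for decision-commitment mass)?  Default
#'   `FALSE`.
#' @return Object of class `latent_posterior`: `post` (`n x (T+1)` matrix,
#'   column 1 is time 0), `time`, `mean`, `sd`, `condition`, `grid`.
#' @export
posterior_latent <- function(theta, data, trial, spec,
                             condition = c("spikes+choice", "spikes",
                                           "choice", "none"),
                             exclude_bounds = FALSE) {
  condition <- match.arg(condition)
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  ctx <- make_ll_context(th$theta_a, spec)
  tr <- prep$trials[[trial]]
  use_spikes <- condition %in% c("spikes", "spikes+choice") &&
    !is.null(tr$y) && nrow(tr$y) > 0
  use_choice <- condition %in% c("choice", "spikes+choice")
  lf <- if (use_spikes) trial_logfac(tr, th$slopes, th$dispersion, ctx, spec)
        else matrix(0, 0, 0)
  fw <- trial_forward(tr, th$theta_a, ctx, spec, lf,
                      want_alpha = TRUE, want_M = TRUE)
  n <- ctx$grid$n; T <- tr$T
  alpha <- cbind(ctx$p0, fw$alpha, deparse.level = 0)
  gfac <- if (use_spikes) exp(sweep(lf, 2, apply(lf, 2, max), "-"))
          else matrix(1, n, T)
  h <- if (use_choice) choice_factor(ctx$grid, tr$choice, th$c, th$gamma)
       else rep(1, n)
  # backward recursion: beta_t(i) propto P(y_{t+1:T}, d | a_t = i)
  beta <- matrix(0, n, T + 1)
  beta[, T + 1] <- h / max(h)
  for (t in T:1) {
    bt <- gfac[, t] * beta[, t + 1]
    bprev <- crossprod(fw$M[[t]], bt)
    beta[, t] <- bprev / max(bprev)
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  mom <- apply(post, 2, grid_moments, grid = ctx$grid,
               exclude_bounds = exclude_bounds)
  structure(list(post = post, time = c(0, seq_len(T)) * spec$dt,
                 mean = mom["mean", ], sd = sqrt(pmax(mom["var", ], 0)),
                 condition = condition, grid = ctx$grid,
                 exclude_bounds = exclude_bounds),
            class = "latent_posterior")
}

#' Per-time-bin moments of a latent posterior
#'
#' @param post A [posterior_latent()] result.
#' @param exclude_bounds Exclude bound-bin mass (renormalizing over interior
#'   bins) before computing moments?
#' @return Data frame with `time`, `mean`, `sd`.
#' @export
posterior_moments <- function(post, exclude_bounds = post$exclude_bounds) {
  stopifnot(inherits(post, "latent_posterior"))
  mom <- apply(post$post, 2, grid_moments, grid = post$grid,
               exclude_bounds = exclude_bounds)
  data.frame(time = post$time, mean = mom["mean", ],
             sd = sqrt(pmax(mom["var", ], 0)))
}

#' Predict the choice of one trial
#'
#' Propagates the trial to the final bin, conditioning on spikes when
#' `use_spikes = TRUE` (the joint decoder) or on the stimulus alone (the
#' choice-only decoder), and applies the lapse-threshold choice rule.  A
#' predicted rightward choice is `p_right > 0.5`.
#'
#' @inheritParams posterior_latent
#' @param use_spikes Condition on the trial's spikes?
#' @return List: `p_right`, `predicted` (0/1), `correct` (matches recorded
#'   choice), `ll_contribution` (log-probability of the recorded choice).
#' @export
predict_choice <- function(theta, data, trial, spec, use_spikes = TRUE) {
  prep <- as_prep(data, spec)
  th <- unpack_theta(theta, spec, prep$neuron_ids)
  ctx <- make_ll_context(th$theta_a, spec)
  tr <- prep$trials[[trial]]
  lf <- if (use_spikes && !is.null(tr$y) && nrow(tr$y) > 0)
    trial_logfac(tr, th$slopes, th$dispersion, ctx, spec)
  else matrix(0, 0, 0)
  fw <- trial_forward(tr, th$theta_a, ctx, spec, lf)
  pT <- fw$pT / sum(fw$pT)
  pr <- choice_prob(pT, ctx$grid, th$c, th$gamma)
  pred <- as.integer(pr > 0.5)
  list(p_right = pr, predicted = pred,
       correct = pred == tr$choice,
       ll_contribution = log(ifelse(tr$choice == 1, pr, 1 - pr)))
}

#' Lapse-scaled Bernoulli GLM (logistic regression baseline decoder)
#'
#' Standard logistic regression with a bias plus a single lapse parameter
#' that scales the asymptotes of the inverse link:
#' `p = gamma/2 + (1 - gamma) * plogis(b0 + X b)`.
#'
#' @param X Feature matrix (trials x features), e.g. final click difference
#'   and per-neuron trailing-window spike counts.
#' @param choices 0/1 vector.
#' @param lapse Fit the lapse parameter? (`FALSE` pins it at 0.)
#' @return Object of class `lapse_glm`: `coef`, `gamma`, `loglik`.
#' @export
bernoulli_glm <- function(X, choices, lapse = TRUE) {
  X <- as.matrix(X)
  d <- ncol(X)
  if (length(unique(choices)) < 2)
    warning("all choices identical: fit is lapse-bounded")
  negll <- function(par) {
    eta <- par[1] + X %*% par[1 + seq_len(d)]
    g <- if (lapse) plogis(par[d + 2]) else 0
    p <- g / 2 + (1 - g) * plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(choices * log(p) + (1 - choices) * log(1 - p))
  }
  init0 <- tryCatch(
    coef(suppressWarnings(stats::glm.fit(cbind(1, X), choices,
                                         family = stats::binomial()))),
    error = function(e) rep(0, d + 1))
  init0[!is.finite(init0)] <- 0
  init <- c(init0, if (lapse) qlogis(0.02))
  fit <- optim(init, negll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-10))
  gam <- if (lapse) plogis(fit$par[d + 2]) else 0
  structure(list(coef = fit$par[seq_len(d + 1)], gamma = gam,
                 loglik = -fit$value, converged = fit$convergence == 0,
                 lapse = lapse),
            class = "lapse_glm")
}

#' @export
predict.lapse_glm <- function(object, newdata, ...) {
  eta <- object$coef[1] + as.matrix(newdata) %*% object$coef[-1]
  as.numeric(object$gamma / 2 + (1 - object$gamma) * plogis(eta))
}

#' Trailing-window GLM features of a session
#'
#' Final cumulative click difference plus each neuron's spike count in a
#' window measured backward from stimulus offset (`window = Inf` uses the
#' whole trial).  Neurons missing on a trial contribute 0.
#'
#' @param session A [ddm_session()].
#' @param window Window length in seconds (e.g. 0.05, 0.1, ..., or `Inf`).
#' @return Matrix, trials x (1 + n_neurons).
#' @export
glm_features <- function(session, window = Inf) {
  ids <- session$neurons$id
  t(vapply(session$trials, function(tr) {
    t0 <- max(0, tr$duration - window)
    cnt <- vapply(ids, function(id) {
      s <- tr$spikes[[id]]
      if (is.null(s)) 0 else sum(s >= t0 & s <= tr$duration + 1e-9)
    }, numeric(1))
    c(dclick = length(tr$right_times) - length(tr$left_times), cnt)
  }, numeric(1 + length(ids))))
}

#' Poisson GLM on the deterministic adapted-click accumulator
#'
#' An independent check on the sign of the leak parameter: the accumulator
#' follows the noise-free dynamics `da = lambda a dt + Delta(t) dt` (adapted,
#' exponentially filtered click input), optionally with a sticky bound, and
#' each neuron's spikes are Poisson at `softplus(slope a_t + theta0_t)`.
#' `lambda`, `B`, `phi`, `tau_phi` and the slopes are fit by (quasi-Newton)
#' likelihood ascent with the usual box constraints.
#'
#' @param data A [ddm_session()] or [prepare_session()] result (joint spec).
#' @param spec A [model_spec()] (Poisson family).
#' @param bounded Include the sticky absorbing bound?
#' @param maxit Optimizer iteration cap.
#' @return List: `par` (named), `loglik`, `convergence`.
#' @export
poisson_glm <- function(data, spec = model_spec(), bounded = TRUE,
                        maxit = 200L) {
  prep <- as_prep(data, spec)
  N <- length(prep$neuron_ids)
  nm <- c("lambda", "B", "phi", "tau_phi",
          paste0("slope_", prep$neuron_ids))
  bb <- bounds_for(nm)
  kind <- transform_kind(nm)
  Tall <- vapply(prep$trials, `[[`, integer(1), "T")

  det_path <- function(lambda, B, phi, tau_phi, use_bound) {
    lapply(prep$trials, function(tr) {
      st <- if (length(tr$times)) {
        mags <- cpp_adapt_clicks(tr$times, tr$side, phi, tau_phi, TRUE)$mags
        cpp_bin_clicks(tr$times, tr$side, mags, spec$dt, tr$T)
      } else list(delta = numeric(tr$T))
      a <- numeric(tr$T)
      prev <- 0
      ld <- lambda * spec$dt
      fac <- if (abs(ld) < 1e-10) 1 else expm1(ld) / ld
      edt <- exp(ld)
      frozen <- FALSE
      for (t in seq_len(tr$T)) {
        if (!frozen) {
          prev <- prev * edt + st$delta[t] * fac
          if (use_bound && abs(prev) >= B) {
            prev <- sign(prev) * B
            frozen <- TRUE
          }
        }
        a[t] <- prev
      }
      a
    })
  }

  negll <- function(ipar) {
    x <- from_internal(ipar, kind)
    paths <- det_path(x[1], x[2], x[3], x[4], bounded)
    sl <- x[4 + seq_len(N)]
    ll <- 0
    for (k in seq_len(prep$K)) {
      tr <- prep$trials[[k]]
      if (is.null(tr$y)) next
      for (r in seq_along(tr$neuron_ids)) {
        arg <- sl[tr$neuron_idx[r]] * paths[[k]] + tr$theta0[r, ]
        rate <- pmax(ifelse(arg > 30, arg, log1p(exp(pmin(arg, 30)))), 1e-6)
        ll <- ll + sum(tr$y[r, ] * log(rate * spec$dt) - rate * spec$dt)
      }
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  init <- setNames(c(0, log(20), log(0.5), log(0.1), rep(0, N)), nm)
  lo <- to_internal(bb[, "lo"], kind); hi <- to_internal(bb[, "hi"], kind)
  fit <- optim(pmin(pmax(init, lo), hi), negll, method = "L-BFGS-B",
               lower = lo, upper = hi,
               control = list(maxit = maxit, factr = 1e9,
                              ndeps = rep(1e-5, length(nm))))
  list(par = setNames(from_internal(fit$par, kind), nm),
       loglik = -fit$value, convergence = fit$convergence)
}
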