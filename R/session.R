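#' Model specification
#'
#' Bundles the model variant, observation family, and numerical settings
#' used by the likelihood and fitting routines.
#'
#' @param variant `"joint-shared"` (one accumulator shared by all neurons and
#'   the choice), `"joint-independent"` (one accumulator per neuron with
#'   independent noise, choice from a randomly selected accumulator), or
#'   `"choice-only"`.
#' @param obs_family `"poisson"` or `"negbinomial"` (ignored for
#'   choice-only).
#' @param n Number of spatial bins for the accumulator grid (odd; default
#'   53).
#' @param dt Time step in seconds (default 0.01).
#' @param refine Sub-grid refinement factor for the transition operator.
#' @param n_basis Number of baseline radial basis functions (default 6).
#' @return Object of class `ddm_spec`.
#' @export
model_spec <- function(variant = c("joint-shared", "joint-independent",
                                   "choice-only"),
                       obs_family = c("poisson", "negbinomial"),
                       n = 53L, dt = 0.01, refine = 10L, n_basis = 6L,
                       settle_correction = TRUE) {
  variant <- match.arg(variant)
  obs_family <- match.arg(obs_family)
  structure(list(variant = variant, obs_family = obs_family,
                 n = as.integer(n), dt = dt, refine = as.integer(refine),
                 n_basis = as.integer(n_basis),
                 settle_correction = settle_correction),
            class = "ddm_spec")
}

#' Assemble a session data object
#'
#' A session holds the trials (click trains, choices, per-neuron spike
#' times) and the neuron registry.  Neurons need not be recorded on every
#' trial (ragged layout); only neurons recorded on a trial contribute to its
#' likelihood.
#'
#' @param trials List of trials; each a list with fields `left_times`,
#'   `right_times`, `duration`, `choice` (0 = left, 1 = right), `spikes`
#'   (named list of spike-time vectors, names = neuron ids), and optionally
#'   `session_id` (integer, default 1).
#' @param neurons Data frame with columns `id` (character), `region`
#'   (character) and `latency` (seconds); defaults to zero-latency neurons
#'   inferred from the trials.
#' @param meta Optional named list of provenance metadata.
#' @return Object of class `ddm_session`.
#' @export
ddm_session <- function(trials, neurons = NULL, meta = list()) {
  ids <- unique(unlist(lapply(trials, function(tr) names(tr$spikes))))
  if (is.null(neurons)) {
    ids <- ids %||% character(0)
    neurons <- data.frame(id = ids,
                          region = rep("synthetic", length(ids)),
                          latency = rep(0, length(ids)),
                          stringsAsFactors = FALSE)
  }
  for (k in seq_along(trials)) {
    tr <- trials[[k]]
    for (f in c("left_times", "right_times", "duration", "choice"))
      if (is.null(tr[[f]]))
        stop(sprintf("trial %d: missing field `%s`", k, f))
    if (!tr$choice %in% c(0, 1))
      stop(sprintf("trial %d: `choice` must be 0 or 1", k))
    if (is.null(tr$spikes)) trials[[k]]$spikes <- setNames(list(), character(0))
    if (is.null(tr$session_id)) trials[[k]]$session_id <- 1L
    bad <- setdiff(names(trials[[k]]$spikes), neurons$id)
    if (length(bad))
      stop(sprintf("trial %d: spikes for unregistered neuron(s) %s",
                   k, paste(bad, collapse = ", ")))
  }
  structure(list(format = "pulseddm-session", version = "1.0",
                 neurons = neurons, trials = trials, meta = meta),
            class = "ddm_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ddm_session <- function(x, ...) {
  cat(sprintf("<ddm_session> %d trials, %d neurons (%s)\n",
              length(x$trials), nrow(x$neurons),
              paste(unique(x$neurons$region), collapse = ", ")))
  invisible(x)
}

#' Fit all per-neuron baselines of a session
#'
#' Pre-fits the RBF baseline weights of every neuron from its binned spikes
#' (pooled over the trials it was recorded on).  Baselines are fit once and
#' held fixed during joint model fitting.
#'
#' @param session A [ddm_session()].
#' @param spec A [model_spec()].
#' @return List keyed by neuron id: `weights`, `theta0`, plus the shared
#'   `basis` as attribute.
#' @export
fit_baselines <- function(session, spec) {
  max_dur <- max(vapply(session$trials, function(tr) tr$duration, numeric(1)))
  basis <- rbf_design(max_dur, spec$dt, spec$n_basis)
  lat <- setNames(session$neurons$latency, session$neurons$id)
  out <- list()
  for (id in session$neurons$id) {
    counts <- list()
    for (tr in session$trials) {
      if (!id %in% names(tr$spikes)) next
      y <- bin_spikes(tr$spikes[[id]], spec$dt, tr$duration, lat[[id]])
      counts[[length(counts) + 1L]] <- as.integer(y[1, ])
    }
    if (!length(counts)) {
      out[[id]] <- list(weights = rep(0, spec$n_basis),
                        theta0 = rep(0, basis$n_bins), converged = NA)
    } else {
      out[[id]] <- fit_baseline(counts, basis)
    }
  }
  attr(out, "basis") <- basis
  out
}

# Precompute everything about a session that does not depend on the model
# parameters: per-trial click streams, spike-count matrices, baseline
# arguments.  Internal workhorse behind the likelihood functions.
#' Precompute the likelihood design of a session
#'
#' @param session A [ddm_session()].
#' @param spec A [model_spec()].
#' @param baselines Optional result of [fit_baselines()]; computed when
#'   missing (not needed for choice-only models).
#' @return Object of class `ddm_prep`.
#' @export
prepare_session <- function(session, spec, baselines = NULL) {
  stopifnot(inherits(session, "ddm_session"), inherits(spec, "ddm_spec"))
  need_spikes <- spec$variant != "choice-only"
  if (need_spikes && is.null(baselines))
    baselines <- fit_baselines(session, spec)
  lat <- setNames(session$neurons$latency, session$neurons$id)
  ids <- session$neurons$id
  trials <- lapply(seq_along(session$trials), function(k) {
    tr <- session$trials[[k]]
    T <- n_time_bins(tr$duration, spec$dt)
    train <- click_train(tr$left_times, tr$right_times, tr$duration)
    mc <- merge_clicks(train)
    rec <- names(tr$spikes)
    y <- NULL; theta0 <- NULL
    if (need_spikes && length(rec)) {
      y <- do.call(rbind, lapply(rec, function(id)
        bin_spikes(tr$spikes[[id]], spec$dt, tr$duration, lat[[id]])[1, ]))
      theta0 <- do.call(rbind, lapply(rec, function(id)
        baselines[[id]]$theta0[seq_len(T)]))
    }
    list(index = k, T = T, times = mc$times, side = mc$side,
         duration = tr$duration, choice = tr$choice,
         neuron_ids = rec, neuron_idx = match(rec, ids),
         y = y, theta0 = theta0, session_id = tr$session_id %||% 1L)
  })
  structure(list(trials = trials, neuron_ids = ids, spec = spec,
                 baselines = baselines,
                 K = length(trials)),
            class = "ddm_prep")
}

as_prep <- function(data, spec, baselines = NULL) {
  if (inherits(data, "ddm_prep")) data
  else prepare_session(data, spec, baselines)
}
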