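#' Construct a click train
#'
#' A click train holds the left and right pulse times of one trial of a
#' pulse-based evidence accumulation task, together with the stimulus
#' duration.
#'
#' @param left_times,right_times Ascending click times in seconds, within
#'   `[0, duration]`.
#' @param duration Stimulus duration in seconds (> 0).
#' @return An object of class `click_train`.
#' @export
click_train <- function(left_times = numeric(0), right_times = numeric(0),
                        duration) {
  left_times <- as.numeric(left_times)
  right_times <- as.numeric(right_times)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("`duration` must be a single positive number")
  if (is.unsorted(left_times) || is.unsorted(right_times))
    stop("click times must be ascending")
  if (any(left_times < 0 | left_times > duration) ||
      any(right_times < 0 | right_times > duration))
    stop("click times must lie in [0, duration]")
  structure(list(left_times = left_times, right_times = right_times,
                 duration = duration),
            class = "click_train")
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %d left / %d right clicks, %.3f s\n",
              length(x$left_times), length(x$right_times), x$duration))
  invisible(x)
}

# Merge the two sides into one time-ordered stream; ties are processed
# left-first (an arbitrary but fixed convention, order-dependence with shared
# adaptation is third-decimal at most).
merge_clicks <- function(train) {
  times <- c(train$left_times, train$right_times)
  side <- c(rep(0L, length(train$left_times)),
            rep(1L, length(train$right_times)))
  o <- order(times, side)
  n_ties <- sum(duplicated(times))
  list(times = times[o], side = side[o], order = o, n_ties = n_ties)
}

#' Apply sensory adaptation to a click train
#'
#' Each click's effective magnitude is the adaptation state `C` just before
#' the click.  Between clicks `C` relaxes to 1 as `dC/dt = (1 - C)/tau_phi`;
#' at each click `C` jumps multiplicatively to `phi * C`.  `C(0) = 1`, so an
#' isolated click always has magnitude 1.  By default both sides share a
#' single adaptation state (cross-side depression); set `shared = FALSE` for
#' per-side states.
#'
#' @param train A [click_train()].
#' @param phi Adaptation strength (> 0); `phi < 1` is depression, `phi > 1`
#'   facilitation, `phi = 1` no adaptation.
#' @param tau_phi Adaptation recovery timescale in seconds (> 0).
#' @param shared Share one adaptation state across sides? Default `TRUE`.
#' @return An object of class `adapted_clicks` with fields `left_mags`,
#'   `right_mags`.
#' @export
adapt_clicks <- function(train, phi, tau_phi, shared = TRUE) {
  stopifnot(inherits(train, "click_train"))
  if (!is.finite(phi) || phi <= 0) stop("`phi` must be positive")
  if (!is.finite(tau_phi) || tau_phi <= 0) stop("`tau_phi` must be positive")
  mc <- merge_clicks(train)
  if (phi == 1) {
    mags <- rep(1, length(mc$times))
  } else {
    mags <- cpp_adapt_clicks(mc$times, mc$side, phi, tau_phi, shared)$mags
  }
  if (mc$n_ties > 0 && shared)
    message(sprintf("%d simultaneous clicks processed left-first", mc$n_ties))
  # un-sort back to the per-side lists
  full <- numeric(length(mags))
  full[mc$order] <- mags
  nl <- length(train$left_times)
  structure(list(left_mags = full[seq_len(nl)],
                 right_mags = full[nl + seq_along(train$right_times)]),
            class = "adapted_clicks")
}

# Signed, time-ordered (time, magnitude) stream used by the simulator.
signed_clicks <- function(train, adapted) {
  mc <- merge_clicks(train)
  mags <- c(-adapted$left_mags, adapted$right_mags)[mc$order]
  list(times = mc$times, mags = mags)
}

n_time_bins <- function(duration, dt) {
  as.integer(ceiling(duration / dt - 1e-9))
}

#' Bin adapted clicks onto the model time grid
#'
#' Click bin `t` covers `[(t-1) dt, t dt)` (final clicks at exactly
#' `duration` fall into the last bin).  The per-bin adapted click difference
#' `delta` (right minus left) and sum `sigma` drive the latent dynamics.
#' Spike bins are offset by `dt/2` so that spike bin `t` spans the forward
#' edge of click bin `t` (see [bin_spikes()]); the offset is recorded in the
#' returned object.
#'
#' @param train A [click_train()].
#' @param mags An [adapt_clicks()] result for the same train.
#' @param dt Time bin width in seconds (> 0).
#' @return An object of class `binned_stimulus` with fields `delta`, `sigma`,
#'   `dt`, `n_bins`, `spike_offset`.
#' @export
bin_stimulus <- function(train, mags, dt) {
  stopifnot(inherits(train, "click_train"))
  if (dt <= 0) stop("`dt` must be positive")
  T <- n_time_bins(train$duration, dt)
  idx <- function(times) {
    i <- floor(times / dt + 1e-9) + 1L
    pmin(i, T)
  }
  delta <- numeric(T); sigma <- numeric(T)
  il <- idx(train$left_times); ir <- idx(train$right_times)
  for (k in seq_along(il)) {
    delta[il[k]] <- delta[il[k]] - mags$left_mags[k]
    sigma[il[k]] <- sigma[il[k]] + mags$left_mags[k]
  }
  for (k in seq_along(ir)) {
    delta[ir[k]] <- delta[ir[k]] + mags$right_mags[k]
    sigma[ir[k]] <- sigma[ir[k]] + mags$right_mags[k]
  }
  structure(list(delta = delta, sigma = sigma, dt = dt, n_bins = T,
                 spike_offset = dt / 2),
            class = "binned_stimulus")
}

#' Bin spike times with the half-offset convention
#'
#' Spike times are first shifted backward by the neuron's response latency,
#' then counted in bins offset by `dt/2` relative to the click bins: spike
#' bin `t` covers `(t dt - dt/2, t dt + dt/2]`.  Shifted spikes that land
#' before time 0 are dropped (their count is recorded in the `"dropped"`
#' attribute); spikes in `[0, dt/2]` are clamped into bin 1 and spikes beyond
#' the last bin's window are dropped.
#'
#' @param spike_times List of numeric vectors (seconds), one per neuron, or a
#'   single numeric vector.
#' @param dt Bin width in seconds.
#' @param duration Stimulus duration in seconds; the number of bins is
#'   `ceiling(duration / dt)`.
#' @param latency Response latency in seconds (>= 0), subtracted from all
#'   spike times before binning.
#' @return Integer matrix, neurons x bins, with attribute `"dropped"`.
#' @export
bin_spikes <- function(spike_times, dt, duration, latency = 0) {
  if (latency < 0) stop("`latency` must be >= 0")
  if (is.numeric(spike_times)) spike_times <- list(spike_times)
  T <- n_time_bins(duration, dt)
  out <- matrix(0L, nrow = length(spike_times), ncol = T)
  dropped <- 0L
  for (i in seq_along(spike_times)) {
    s <- as.numeric(spike_times[[i]]) - latency
    neg <- sum(s < 0)
    dropped <- dropped + neg
    s <- s[s >= 0]
    b <- ceiling((s - dt / 2) / dt - 1e-9)
    b[b < 1L] <- 1L
    over <- b > T
    dropped <- dropped + sum(over)
    b <- b[!over]
    if (length(b)) {
      tb <- tabulate(b, nbins = T)
      out[i, ] <- as.integer(tb)
    }
  }
  attr(out, "dropped") <- dropped
  out
}
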