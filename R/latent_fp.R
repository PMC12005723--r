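#' Accumulator dynamics parameters
#'
#' The seven parameters governing the latent accumulator: initial variance
#' `sigma2_i` (clicks^2), bound `B` (clicks), drift/leak rate `lambda` (1/s;
#' negative = leaky, positive = unstable), diffusion variance rate `sigma2_a`
#' (clicks^2/s), per-unit-click noise variance `sigma2_s` (clicks^2),
#' adaptation strength `phi` and timescale `tau_phi` (s).
#'
#' @param sigma2_i,B,lambda,sigma2_a,sigma2_s,phi,tau_phi Numeric scalars.
#' @return Named numeric vector of class `accumulator_params`.
#' @export
accumulator_params <- function(sigma2_i = 1, B = 15, lambda = -1,
                               sigma2_a = 20, sigma2_s = 1, phi = 0.3,
                               tau_phi = 0.05) {
  th <- c(sigma2_i = sigma2_i, B = B, lambda = lambda, sigma2_a = sigma2_a,
          sigma2_s = sigma2_s, phi = phi, tau_phi = tau_phi)
  if (!all(is.finite(th))) stop("accumulator parameters must be finite")
  if (B <= 0) stop("`B` must be positive")
  if (sigma2_i < 0 || sigma2_a < 0 || sigma2_s < 0)
    stop("variance parameters must be >= 0")
  if (phi <= 0 || tau_phi <= 0) stop("`phi` and `tau_phi` must be positive")
  structure(th, class = "accumulator_params")
}

#' Discretize the accumulator axis
#'
#' Builds the spatial grid used by the Fokker-Planck propagation: the two
#' outer bins sit exactly at the absorbing bounds `-B` and `+B`; the `n - 2`
#' interior bins uniformly tile `(-B, B)` with width `2 B / (n - 2)` and a
#' center bin at 0.  `n` must be odd so that the grid is symmetric with a
#' zero-centered bin.
#'
#' @param B Bound magnitude in clicks (> 0).
#' @param n Odd number of bins, `n >= 5`.  Default 53.
#' @return Object of class `latent_grid` with fields `n`, `centers`, `width`,
#'   `bound_bins`.
#' @export
make_grid <- function(B, n = 53L) {
  n <- as.integer(n)
  if (n %% 2L == 0L || n < 5L) stop("`n` must be odd and >= 5")
  if (B <= 0) stop("`B` must be positive")
  width <- 2 * B / (n - 2)
  m <- (n - 3L) %/% 2L
  centers <- c(-B, seq(-m, m) * width, B)
  structure(list(n = n, centers = centers, width = width,
                 bound_bins = c(1L, n)),
            class = "latent_grid")
}

#' Initial distribution of the accumulator
#'
#' Settles a zero-mean Gaussian of variance `sigma2_i` onto the grid with the
#' two-nearest-bin linear weighting rule; mass beyond the bounds accrues to
#' the bound bins.  `sigma2_i = 0` gives a point mass at the center bin.
#'
#' @param sigma2_i Initial variance (clicks^2, >= 0).
#' @param grid A [make_grid()] object.
#' @param refine Sub-grid refinement factor for discretizing the Gaussian.
#' @param correct Subtract the expected settling variance inflation
#'   (`width^2/6`) from the Gaussian before settling?  Default `FALSE`: the
#'   one-time initial projection follows the literal settling rule; the
#'   likelihood machinery uses the corrected variant so that propagated
#'   moments track the continuous process.
#' @return Probability vector over the grid bins (sums to 1).
#' @export
initial_distribution <- function(sigma2_i, grid, refine = 10L,
                                 correct = FALSE) {
  stopifnot(inherits(grid, "latent_grid"), sigma2_i >= 0)
  cpp_initial_dist(grid$centers, sigma2_i, refine, correct)
}

#' One-step Markov transition operator
#'
#' Column `j` of the returned matrix holds the destination of probability
#' mass starting in bin `j` after one time step: the deterministic drift
#' update (exact linear-ODE integration of `da = lambda a dt` plus the click
#' impulse `delta_t`), convolved with a Gaussian of variance
#' `sigma2_a dt + sigma2_s sigma_t` discretized on a refined sub-grid and
#' settled onto the two nearest bins.  Bound-bin columns are identity
#' (absorbing).  Columns sum to 1.
#'
#' @param theta_a [accumulator_params()] (only `lambda`, `sigma2_a`,
#'   `sigma2_s` are used here).
#' @param delta_t Adapted click difference in this bin.
#' @param sigma_t Adapted click sum in this bin (>= 0).
#' @param dt Time step in seconds.
#' @param grid A [make_grid()] object.
#' @param refine Refinement factor (>= 7 recommended; default 10).
#' @param correct Subtract the expected two-bin settling variance inflation
#'   (`width^2/6`) from the spread kernel so the operator's one-step
#'   variance matches the Fokker-Planck diffusion coefficient (default
#'   `TRUE`).
#' @return `n x n` column-stochastic matrix.
#' @export
transition_matrix <- function(theta_a, delta_t, sigma_t, dt, grid,
                              refine = 10L, correct = TRUE) {
  stopifnot(inherits(grid, "latent_grid"), dt > 0)
  v <- (theta_a[["sigma2_a"]] * dt + theta_a[["sigma2_s"]] * sigma_t) *
    cpp_ou_vfac(theta_a[["lambda"]], dt)
  cpp_transition_matrix(grid$centers, theta_a[["lambda"]], dt, delta_t, v,
                        refine, correct)
}

#' Propagate a state distribution one step
#'
#' @param p Probability vector over grid bins.
#' @param M Transition matrix from [transition_matrix()].
#' @return `M %*% p` as a vector (still sums to 1).
#' @export
propagate <- function(p, M) {
  if (length(p) != ncol(M)) stop("dimension mismatch between `p` and `M`")
  as.numeric(M %*% p)
}

#' Forward propagation of the latent prior
#'
#' Propagates the initial distribution through every time bin of a binned
#' stimulus with no observation conditioning (the prior of the hidden Markov
#' chain).
#'
#' @param theta_a [accumulator_params()].
#' @param stimulus A [bin_stimulus()] object.
#' @param grid A [make_grid()] object.
#' @param refine Refinement factor.
#' @param correct Apply the settling variance correction (see
#'   [transition_matrix()])?
#' @return Matrix `n x (T + 1)`: column 1 is the initial distribution,
#'   column `t + 1` the distribution after bin `t`.
#' @export
forward_prior <- function(theta_a, stimulus, grid, refine = 10L,
                          correct = TRUE) {
  stopifnot(inherits(stimulus, "binned_stimulus"))
  p0 <- initial_distribution(theta_a[["sigma2_i"]], grid, refine, correct)
  M0 <- cpp_transition_matrix(grid$centers, theta_a[["lambda"]],
                              stimulus$dt, 0,
                              theta_a[["sigma2_a"]] * stimulus$dt *
                                cpp_ou_vfac(theta_a[["lambda"]], stimulus$dt),
                              refine, correct)
  res <- cpp_trial_filter(grid$centers, theta_a[["lambda"]], stimulus$dt,
                          theta_a[["sigma2_a"]], theta_a[["sigma2_s"]],
                          stimulus$delta, stimulus$sigma,
                          matrix(0, 0, 0), p0, M0, refine,
                          TRUE, FALSE, correct)
  cbind(p0, res$alpha, deparse.level = 0)
}

# Mean and variance of a distribution over grid centers.
grid_moments <- function(p, grid, exclude_bounds = FALSE) {
  x <- grid$centers
  if (exclude_bounds) {
    keep <- seq(2L, grid$n - 1L)
    x <- x[keep]; p <- p[keep]
    s <- sum(p)
    if (s <= 0) return(c(mean = NA_real_, var = NA_real_))
    p <- p / s
  }
  m <- sum(p * x)
  c(mean = m, var = sum(p * (x - m)^2))
}
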