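test_that("make_grid places bounds, center, and uniform interior bins", {
  g <- make_grid(40, 53)
  expect_equal(g$n, 53L)
  expect_equal(g$centers[1], -40)
  expect_equal(g$centers[53], 40)
  expect_equal(g$width, 2 * 40 / 51, tolerance = 1e-12)
  expect_equal(g$centers[27], 0)
  # antisymmetry
  expect_equal(g$centers, -rev(g$centers))
  # uniform interior spacing
  expect_equal(diff(g$centers[2:52]), rep(g$width, 50), tolerance = 1e-12)
  expect_error(make_grid(10, 6), "odd")
  expect_error(make_grid(-1, 5), "positive")
})

test_that("initial_distribution settles a Gaussian onto the grid", {
  g <- make_grid(10, 53)
  p <- initial_distribution(0, g)
  expect_equal(p[g$centers == 0], 1)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  p1 <- initial_distribution(1, g)
  expect_equal(sum(p1 * g$centers), 0, tolerance = 1e-12)  # symmetry
  expect_equal(sum(p1), 1, tolerance = 1e-10)

  # Monte-Carlo settling oracle: sample, settle each draw onto the two
  # nearest bins, compare lumped variance (literal rule: correct = FALSE)
  set.seed(123)
  x <- rnorm(1e6, 0, 2)
  cts <- g$centers
  settle_var <- local({
    idx <- findInterval(x, cts)
    idx[idx < 1] <- 1; idx[idx > 52] <- 52
    lo <- cts[idx]; hi <- cts[idx + 1]
    w <- (x - lo) / (hi - lo)
    w[x <= cts[1]] <- 0; w[x >= cts[53]] <- 1
    m2 <- mean((1 - w) * lo^2 + w * hi^2)
    m1 <- mean((1 - w) * lo + w * hi)
    m2 - m1^2
  })
  p4 <- initial_distribution(4, g, correct = FALSE)
  v4 <- sum(p4 * g$centers^2) - sum(p4 * g$centers)^2
  se <- 4 * sqrt(2 / 1e6)
  expect_lt(abs(v4 - settle_var), 3 * se)
})

test_that("transition matrix is column-stochastic with absorbing bounds", {
  th <- accumulator_params(sigma2_i = 1, B = 10, lambda = -1, sigma2_a = 5,
                           sigma2_s = 2, phi = 0.5, tau_phi = 0.05)
  g <- make_grid(10, 21)
  for (d in c(-2, 0, 1.5)) {
    M <- transition_matrix(th, d, abs(d), 0.01, g)
    expect_true(all(M >= 0))
    expect_equal(colSums(M), rep(1, 21), tolerance = 1e-10)
    expect_equal(M[, 1], c(1, rep(0, 20)))
    expect_equal(M[, 21], c(rep(0, 20), 1))
  }
  # zero drift/noise/clicks -> identity
  th0 <- accumulator_params(sigma2_i = 0, B = 10, lambda = 0, sigma2_a = 0,
                            sigma2_s = 0, phi = 1, tau_phi = 0.1)
  M0 <- transition_matrix(th0, 0, 0, 0.01, g)
  expect_equal(M0, diag(21))
})

test_that("one transition step reproduces analytic Gaussian propagation", {
  # lambda = 0, click impulse 1.0, variance 0.25: mean shifts by 1,
  # variance grows by 0.25, within a settling tolerance of width^2/4
  th <- accumulator_params(sigma2_i = 0, B = 20, lambda = 0, sigma2_a = 25,
                           sigma2_s = 0, phi = 1, tau_phi = 0.1)
  g <- make_grid(20, 53)
  M <- transition_matrix(th, 1.0, 0, 0.01, g)
  p <- initial_distribution(0.5, g)
  q <- propagate(p, M)
  m0 <- sum(p * g$centers); v0 <- sum(p * (g$centers - m0)^2)
  m1 <- sum(q * g$centers); v1 <- sum(q * (g$centers - m1)^2)
  tol <- g$width^2 / 4
  expect_lt(abs(m1 - (m0 + 1.0)), tol)
  expect_lt(abs(v1 - (v0 + 0.25)), tol)
})

test_that("deterministic drift uses the exact linear-ODE update", {
  # with noise 0 the settled mean must equal a e^{l dt} + d (e^{l dt}-1)/(l dt)
  th <- accumulator_params(sigma2_i = 0, B = 20, lambda = 2, sigma2_a = 0,
                           sigma2_s = 0, phi = 1, tau_phi = 0.1)
  g <- make_grid(20, 201)
  M <- transition_matrix(th, 0.7, 0, 0.02, g)
  j <- which.min(abs(g$centers - 5))
  mu <- sum(M[, j] * g$centers)
  expect_lt(abs(mu - (g$centers[j] * exp(0.04) +
                      0.7 * expm1(0.04) / 0.04)), g$width)
})

test_that("propagate conserves mass and respects absorption", {
  g <- make_grid(8, 15)
  th <- accumulator_params(sigma2_i = 0, B = 8, lambda = 1, sigma2_a = 10,
                           sigma2_s = 1, phi = 0.5, tau_phi = 0.05)
  M <- transition_matrix(th, 2, 2, 0.01, g)
  expect_error(propagate(rep(0.1, 10), M), "dimension")
  # point mass at a bound bin is a fixed point
  e1 <- c(1, rep(0, 14))
  expect_equal(propagate(e1, M), e1)
  set.seed(2)
  p <- runif(15); p <- p / sum(p)
  q <- propagate(p, M)
  expect_true(all(q >= 0))
  expect_equal(sum(q), 1, tolerance = 1e-10)
})

test_that("forward_prior: degenerate, symmetric, and conservation cases", {
  th0 <- accumulator_params(sigma2_i = 0, B = 5, lambda = 0, sigma2_a = 0,
                            sigma2_s = 0, phi = 1, tau_phi = 0.1)
  g <- make_grid(5, 11)
  tr <- click_train(c(), c(), 0.1)
  st <- bin_stimulus(tr, adapt_clicks(tr, 1, 0.1), 0.01)
  P <- forward_prior(th0, st, g)
  expect_equal(dim(P), c(11L, 11L))
  expect_true(all(P[g$centers == 0, ] == 1))

  # mirror stimulus + symmetric parameters -> antisymmetric distribution
  th <- accumulator_params(sigma2_i = 1, B = 5, lambda = -1, sigma2_a = 2,
                           sigma2_s = 0.5, phi = 0.5, tau_phi = 0.05)
  trL <- click_train(c(0.02, 0.05), c(0.08), 0.1)
  trR <- click_train(c(0.08), c(0.02, 0.05), 0.1)
  PL <- forward_prior(th, bin_stimulus(trL, adapt_clicks(trL, 0.5, 0.05),
                                       0.01), g)
  PR <- forward_prior(th, bin_stimulus(trR, adapt_clicks(trR, 0.5, 0.05),
                                       0.01), g)
  expect_equal(PL, PR[rev(seq_len(11)), ], tolerance = 1e-12)
  # mass conservation at every step
  expect_equal(colSums(PL), rep(1, 11), tolerance = 1e-10)
})

test_that("bound mass is non-decreasing and no-bound mean tracks clicks", {
  th <- accumulator_params(sigma2_i = 0.5, B = 6, lambda = 0.5, sigma2_a = 8,
                           sigma2_s = 1, phi = 0.4, tau_phi = 0.05)
  g <- make_grid(6, 21)
  set.seed(9)
  tr <- click_train(sort(runif(6, 0, 0.3)), sort(runif(12, 0, 0.3)), 0.3)
  st <- bin_stimulus(tr, adapt_clicks(tr, 0.4, 0.05), 0.01)
  P <- forward_prior(th, st, g)
  bound_mass <- P[1, ] + P[21, ]
  expect_true(all(diff(bound_mass) >= -1e-12))

  # lambda = 0, no noise, huge bound: mean equals cumulative adapted
  # difference up to settling tolerance
  th2 <- accumulator_params(sigma2_i = 0, B = 30, lambda = 0, sigma2_a = 0,
                            sigma2_s = 0, phi = 0.4, tau_phi = 0.05)
  g2 <- make_grid(30, 201)
  P2 <- forward_prior(th2, st, g2)
  mean_T <- sum(P2[, ncol(P2)] * g2$centers)
  expect_lt(abs(mean_T - sum(st$delta)), g2$width)
})

test_that("trial log-likelihood is stable under grid doubling", {
  sess <- tiny_session(K = 4, duration = 0.1, seed = 3)
  spec53 <- model_spec("joint-shared", n = 53)
  spec105 <- model_spec("joint-shared", n = 105)
  bl <- fit_baselines(sess, spec53)
  th <- tiny_theta(spec53)
  ll53 <- joint_loglik(th, prepare_session(sess, spec53, bl), spec53)
  ll105 <- joint_loglik(th, prepare_session(sess, spec105, bl), spec105)
  expect_lt(abs(ll53 - ll105) / abs(ll105), 0.01)
})
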