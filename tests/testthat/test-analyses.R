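test_that("single_trial_rate integrates to the spike count", {
  dt <- 0.01
  expect_equal(single_trial_rate(rep(0L, 100), dt), rep(0, 100))
  # one interior spike: bump integrates to ~1
  y <- rep(0L, 100); y[50] <- 1L
  r <- single_trial_rate(y, dt)
  expect_equal(sum(r) * dt, 1, tolerance = 1e-6)
  # constant-rate train: trace mean ~ rate away from the edges
  set.seed(1)
  y2 <- rpois(2000, 30 * dt)
  r2 <- single_trial_rate(y2, dt)
  expect_equal(mean(r2[100:1900]), 30, tolerance = 2)
})

test_that("psth groups trials by evidence and averages raggedly", {
  set.seed(2)
  # two neurons, trials of two lengths; neuron rates depend on the group
  trials <- lapply(1:40, function(k) {
    right <- k > 20
    dur <- if (k %% 2 == 0) 0.3 else 0.5
    nr <- if (right) 8 else 2
    nl <- if (right) 2 else 8
    list(left_times = sort(runif(nl, 0, dur)),
         right_times = sort(runif(nr, 0, dur)),
         duration = dur, choice = as.numeric(right),
         spikes = list(nA = sort(runif(if (right) 30 else 10, 0, dur))))
  })
  sess <- ddm_session(trials)
  ph <- psth(sess, dt = 0.01, groups = 2)
  expect_equal(dim(ph$rate)[2], 2L)
  # group 2 (right evidence) has the higher rate where defined
  ok <- is.finite(ph$rate[1, 1, ]) & is.finite(ph$rate[1, 2, ])
  expect_gt(mean(ph$rate[1, 2, ok]) - mean(ph$rate[1, 1, ok]), 5)
  # ragged: late bins only get contributions from long trials
  expect_true(all(ph$n_trials[1, , 40] <= ph$n_trials[1, , 10]))
})

test_that("psth_r2 matches the hand-built arithmetic oracle", {
  # r = (1,2,3), f = (1,2,4) in both groups -> R2 = 1 - 1/2 = 0.5
  rate_e <- array(rep(c(1, 2, 3), each = 2), dim = c(1, 2, 3))
  rate_s <- array(rep(c(1, 2, 4), each = 2), dim = c(1, 2, 3))
  dimnames(rate_e) <- dimnames(rate_s) <- list("nA", NULL, NULL)
  emp <- structure(list(rate = rate_e, time = c(0.01, 0.02, 0.03)),
                   class = "ddm_psth")
  syn <- structure(list(rate = rate_s, time = c(0.01, 0.02, 0.03)),
                   class = "ddm_psth")
  expect_equal(unname(psth_r2(emp, syn, window = c(0, 1))["nA"]), 0.5)
  expect_equal(unname(psth_r2(emp, emp, window = c(0, 1))["nA"]), 1)
  # synthetic = grand mean -> 0
  gm <- array(2, dim = c(1, 2, 3), dimnames = list("nA", NULL, NULL))
  syn0 <- structure(list(rate = gm, time = emp$time), class = "ddm_psth")
  expect_equal(unname(psth_r2(emp, syn0, window = c(0, 1))["nA"]), 0)
})

test_that("shuffle-corrected xcorr vanishes for independent neurons", {
  set.seed(3)
  dt <- 0.01; T <- 60; K <- 400
  cm <- lapply(1:K, function(k) rpois(T, 20 * dt))
  cn <- lapply(1:K, function(k) rpois(T, 15 * dt))
  pm <- matrix(20, 2, T); pn <- matrix(15, 2, T)
  g <- rep(1:2, each = K / 2)
  xc <- xcorr_shuffle_corrected(cm, cn, pm, pn, g, dt, tau_range = 0.2)
  # Monte-Carlo scale of the raw estimator at tau != 0
  mc_se <- 3 * sd(xc$corrected[xc$tau != 0])
  expect_lt(max(abs(xc$corrected[xc$tau != 0])), 3 * mc_se + 3)
  expect_lt(abs(mean(xc$corrected)), 2)

  # common latent drive -> positive central peak
  set.seed(4)
  lat <- lapply(1:K, function(k) cumsum(rnorm(T, 0, 0.4)))
  cm2 <- lapply(lat, function(l) rpois(T, pmax(20 + 8 * l, 0.1) * dt))
  cn2 <- lapply(lat, function(l) rpois(T, pmax(15 + 6 * l, 0.1) * dt))
  xc2 <- xcorr_shuffle_corrected(cm2, cn2, pm, pn, g, dt, tau_range = 0.2)
  # positive central peak, clearly above the independent-case fluctuations
  expect_gt(xc2$corrected[xc2$tau == 0], 5 * sd(xc$corrected))
  expect_gt(xc2$corrected[xc2$tau == 0], max(abs(xc$corrected)))
})

test_that("psychometric recovers a lapse-logistic and its R2 behaves", {
  set.seed(5)
  n <- 4000
  dc <- sample(-15:15, n, replace = TRUE)
  gam <- 0.1
  p <- gam / 2 + (1 - gam) * plogis(0.2 + 0.35 * dc)
  ch <- rbinom(n, 1, p)
  ps <- psychometric(ch, dc)
  expect_equal(unname(ps$slope), 0.35, tolerance = 0.08)
  expect_equal(unname(ps$gamma), 0.1, tolerance = 0.05)
  # asymptotes near gamma/2 and 1 - gamma/2
  expect_lt(abs(ps$curve(30) - 0.95), 0.05)
  expect_lt(abs(ps$curve(-30) - 0.05), 0.05)
  # symmetric evidence, symmetric choices -> bias ~ 0
  ps2 <- psychometric(c(ch, 1 - ch), c(dc, -dc))
  expect_lt(abs(unname(ps2$bias)), 0.1)
  # R2 of a curve against itself is 1
  expect_equal(psychometric_r2(ps, ps), 1)
  expect_error(psychometric(c(0, 1), c(2, 2)), "distinct")
})

test_that("detect_com enforces dwell and magnitude criteria", {
  dt <- 0.01
  # monotone trace never crossing: no events
  expect_equal(nrow(detect_com(seq(-3, 3, length.out = 100) + 10, dt)), 0L)
  # -3 for 80 ms then +3 for 80 ms: exactly one event
  tr <- c(rep(-3, 8), rep(3, 8))
  ev <- detect_com(tr, dt, c = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "L2R")
  expect_equal(ev$time, 8 * dt)
  # magnitude 1.5 only: rejected
  ev2 <- detect_com(c(rep(-1.5, 8), rep(1.5, 8)), dt, c = 0)
  expect_equal(nrow(ev2), 0L)
  # dwell violated: flickers back within 50 ms
  tr3 <- c(rep(-3, 8), rep(3, 3), rep(-3, 8))
  expect_equal(nrow(detect_com(tr3, dt, c = 0)), 0L)
  # too-short trace warns and returns nothing
  expect_warning(ev4 <- detect_com(c(-3, 3), dt, c = 0), "shorter")
  expect_equal(nrow(ev4), 0L)
})

test_that("detect_com is invariant to 2x finer resampling", {
  set.seed(6)
  for (rep in 1:20) {
    tr <- cumsum(rnorm(120, 0, 1.2))
    e1 <- detect_com(tr, 0.01, c = 0)
    tr2 <- rep(tr, each = 2)  # piecewise-constant 2x oversampling
    e2 <- detect_com(tr2, 0.005, c = 0)
    expect_equal(nrow(e1), nrow(e2))
  }
})

test_that("participation_ratio matches analytic cases", {
  expect_equal(participation_ratio(diag(c(2, 1)), is_cov = TRUE), 9 / 5)
  # rank-1
  v <- c(1, 2, 3)
  expect_equal(participation_ratio(v %o% v, is_cov = TRUE), 1)
  # N independent equal-variance channels -> N as samples grow
  set.seed(7)
  X <- matrix(rnorm(20000 * 10), ncol = 10)
  expect_equal(participation_ratio(X), 10, tolerance = 0.2)
  # invariance to relabeling and global rescaling
  C <- cov(X)
  perm <- sample(10)
  expect_equal(participation_ratio(C[perm, perm], is_cov = TRUE),
               participation_ratio(C, is_cov = TRUE))
  expect_equal(participation_ratio(4 * C, is_cov = TRUE),
               participation_ratio(C, is_cov = TRUE))
  expect_error(participation_ratio(matrix(0, 3, 3), is_cov = TRUE), "rank-0")
})

test_that("select_tuned_neurons keeps tuned, drops untuned", {
  set.seed(8)
  trials <- lapply(1:400, function(k) {
    ch <- k %% 2
    rate_t <- if (ch == 1) 20 else 10   # tuned
    list(left_times = numeric(0), right_times = numeric(0), duration = 0.5,
         choice = ch,
         spikes = list(tuned = sort(runif(rpois(1, rate_t * 0.5), 0, 0.5)),
                       flat = sort(runif(rpois(1, 15 * 0.5), 0, 0.5))))
  })
  sess <- ddm_session(trials)
  keep <- select_tuned_neurons(sess)
  expect_true("tuned" %in% keep)
  expect_false("flat" %in% keep)
  expect_error(select_tuned_neurons(ddm_session(trials[1:2])), ">= 2 trials")
})

test_that("com_latency_regression recovers a linear relation", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  set.seed(14)
  y <- 0.05 + 0.8 * x + rnorm(5, 0, 1e-8)
  r <- com_latency_regression(x, y)
  expect_equal(r$slope, 0.8, tolerance = 1e-6)
  expect_equal(r$intercept, 0.05, tolerance = 1e-5)
  # shuffled pairs: slope ~ 0 on average (permutation check)
  set.seed(9)
  xs <- runif(200); ys <- 0.3 + 0.5 * xs + rnorm(200, 0, 0.05)
  slopes <- replicate(200, com_latency_regression(sample(xs), ys)$slope)
  expect_lt(abs(mean(slopes)), 0.03)
  expect_error(com_latency_regression(c(1, 2), c(1, 2)), ">= 3")
  expect_error(com_latency_regression(rep(1, 5), rnorm(5)), "constant")
  # duplicate x with varying y still gives a finite slope
  r2 <- com_latency_regression(c(0.1, 0.1, 0.2, 0.3), c(1, 2, 1.5, 2.5))
  expect_true(is.finite(r2$slope))
})

test_that("synthetic_psth equals the softplus baseline when slopes are 0", {
  set.seed(10)
  cfg <- sim_config(n_trials = 30, n_neurons = 2,
                    duration_range = c(0.3, 0.3))
  ds <- make_dataset(cfg, 7)
  spec <- model_spec("joint-shared", n = 27)
  th <- ds$truth$theta
  th[grep("^slope_", names(th))] <- 0
  sp <- synthetic_psth(th, ds$session, spec, n_noise_reals = 3)
  prep <- prepare_session(ds$session, spec)
  base <- softplus(prep$trials[[1]]$theta0[1, ])
  got <- sp$rate[1, 1, seq_along(base)]
  expect_equal(unname(got), base, tolerance = 1e-8)
})
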