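# Likelihoods are validated against the exhaustive-path oracle on tiny
# instances (7-bin grid, ~5 time bins) in test-acceptance.R; here we check
# structural identities, the optimizer, intervals, and CV plumbing.

spec7 <- model_spec("joint-shared", n = 7, dt = 0.01)

test_that("joint LL factorizes when slopes are 0 and gamma = 1", {
  sess <- tiny_session(K = 4, duration = 0.05, seed = 1)
  prep <- tiny_prep(sess, spec7)
  th <- tiny_theta(spec7)
  th[c("slope_nA", "slope_nB")] <- 0
  th["gamma"] <- 1
  ll <- joint_loglik(th, prep, spec7)
  nulls <- null_models(prep, spec7)
  expect_equal(ll, nulls$spike_ll + 4 * log(0.5), tolerance = 1e-8)
})

test_that("joint LL is invariant under trial reordering", {
  sess <- tiny_session(K = 5, duration = 0.05, seed = 2)
  prep <- tiny_prep(sess, spec7)
  th <- tiny_theta(spec7)
  ll <- joint_loglik(th, prep, spec7)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(joint_loglik(th, prep, spec7, trial_subset = perm), ll,
               tolerance = 1e-12)
})

test_that("choice-only LL has the expected degenerate limits", {
  sess <- tiny_session(K = 6, duration = 0.05, seed = 3)
  specc <- model_spec("choice-only", n = 7)
  prep <- prepare_session(sess, specc)
  th <- tiny_theta(specc)[1:9]
  th["gamma"] <- 1
  expect_equal(choice_only_loglik(th, prep, specc), 6 * log(0.5),
               tolerance = 1e-12)

  # stimulus-free symmetric trials with c = 0, gamma = 0 -> P(R) = 1/2
  trials <- lapply(1:4, function(k)
    list(left_times = numeric(0), right_times = numeric(0), duration = 0.05,
         choice = k %% 2, spikes = NULL))
  sess2 <- ddm_session(trials)
  prep2 <- prepare_session(sess2, specc)
  th2 <- th
  th2[c("c", "gamma")] <- 0
  th2["sigma2_i"] <- 1
  expect_equal(choice_only_loglik(th2, prep2, specc), 4 * log(0.5),
               tolerance = 1e-9)
})

test_that("independent and joint LL coincide for single-neuron sessions", {
  set.seed(6)
  trials <- lapply(1:5, function(k)
    list(left_times = sort(runif(2, 0, 0.05)),
         right_times = sort(runif(2, 0, 0.05)), duration = 0.05,
         choice = rbinom(1, 1, 0.5),
         spikes = list(nA = sort(runif(3, 0, 0.05)))))
  sess <- ddm_session(trials)
  spec_j <- model_spec("joint-shared", n = 7)
  spec_i <- model_spec("joint-independent", n = 7)
  bl <- fit_baselines(sess, spec_j)
  prep_j <- prepare_session(sess, spec_j, bl)
  prep_i <- prepare_session(sess, spec_i, bl)
  th <- tiny_theta(spec_j, ids = "nA")
  expect_equal(independent_loglik(th, prep_i, spec_i),
               joint_loglik(th, prep_j, spec_j), tolerance = 1e-12)
})

test_that("independent choice term averages per-accumulator probabilities", {
  # two neurons whose accumulators give P(R) = p1 and p2 -> trial P(R) is
  # their mean; verified via the exported choice_prob on the two filtered
  # final distributions versus the likelihood difference of the two choices
  sess <- tiny_session(K = 1, duration = 0.05, seed = 9)
  spec_i <- model_spec("joint-independent", n = 7)
  prep <- tiny_prep(sess, spec_i)
  th <- tiny_theta(spec_i)
  ll_r <- independent_loglik(th, prep, spec_i)
  # flip the choice; spike terms cancel in the difference
  sess2 <- sess
  sess2$trials[[1]]$choice <- 1 - sess$trials[[1]]$choice
  prep2 <- prepare_session(sess2, spec_i, prep$baselines)
  ll_l <- independent_loglik(th, prep2, spec_i)
  p_obs <- exp(ll_r) / (exp(ll_r) + exp(ll_l))
  # direct check of the averaging identity using single-neuron sessions
  singles <- vapply(c("nA", "nB"), function(id) {
    tr <- sess$trials[[1]]
    tr$spikes <- tr$spikes[id]
    s1 <- ddm_session(list(tr))
    sp <- model_spec("joint-shared", n = 7)
    p1 <- prepare_session(s1, sp, prep$baselines[id])
    th1 <- tiny_theta(sp, ids = id)
    th1[paste0("slope_", id)] <- th[paste0("slope_", id)]
    predict_choice(th1, p1, 1, sp)$p_right
  }, numeric(1))
  want <- mean(singles)
  got <- if (sess$trials[[1]]$choice == 1) p_obs else 1 - p_obs
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("fit_mle improves on the truth, respects bounds, is deterministic", {
  set.seed(31)
  cfg <- sim_config(n_trials = 60, n_neurons = 2, duration_range = c(0.2, 0.4))
  ds <- make_dataset(cfg, 5)
  spec <- model_spec("joint-shared", n = 27)
  prep <- prepare_session(ds$session, spec)
  fit <- fit_mle(spec, prep, seed = 2, n_starts = 1, maxit = 12,
                 hessian = FALSE)
  bb <- fit$bounds
  expect_true(all(fit$theta_hat >= bb[, "lo"] - 1e-9))
  expect_true(all(fit$theta_hat <= bb[, "hi"] + 1e-9))
  expect_gte(fit$loglik, joint_loglik(ds$truth$theta, prep, spec))
  # determinism: same seed and init -> identical theta_hat
  fit2 <- fit_mle(spec, prep, seed = 2, n_starts = 1, maxit = 12,
                  hessian = FALSE)
  expect_identical(fit$theta_hat, fit2$theta_hat)
  expect_error(fit_mle(spec, prep, init = ds$truth$theta * 0, seed = 1),
               "domain")
})

test_that("laplace_ci is exact on a Gaussian toy likelihood", {
  # Gaussian mean with known sigma: interval is mean +- 2 sigma/sqrt(n)
  set.seed(12)
  x <- rnorm(50, 2, 1.5)
  f <- function(th) sum(dnorm(x, th, 1.5, log = TRUE))
  xhat <- mean(x)
  H <- pulseDDM:::fd_hessian(f, c(mu = xhat),
                             cbind(lo = -10, hi = 10))
  fake <- structure(list(theta_hat = c(mu = xhat), hessian = H,
                         bounds = cbind(lo = -10, hi = 10),
                         param_names = "mu", kind = "id",
                         natural_ll = function(v) f(v)),
                    class = "ddm_fit")
  ci <- laplace_ci(fake)
  expect_equal(ci$sd, 1.5 / sqrt(50), tolerance = 1e-4)
  expect_equal(ci$lower, xhat - 2 * 1.5 / sqrt(50), tolerance = 1e-4)
  expect_equal(ci$upper, xhat + 2 * 1.5 / sqrt(50), tolerance = 1e-4)
})

test_that("hessian eigen-repair yields a usable PSD surrogate", {
  # locally convex but globally concave along b: the raw Hessian has a
  # negative eigenvalue of -H; the line-search repair recovers the global
  # quadratic curvature
  f <- function(v) -v[1]^2 + 0.2 * v[2]^2 - 4 * v[2]^4
  x <- c(a = 0, b = 0)
  bb <- cbind(lo = c(-5, -5), hi = c(5, 5))
  H <- pulseDDM:::fd_hessian(f, x, bb)
  expect_true(any(eigen(-H, symmetric = TRUE)$values <= 1e-12))
  Hr <- pulseDDM:::repair_hessian(H, f, x, bb)
  expect_false(is.null(Hr))
  expect_true(all(eigen(-Hr, symmetric = TRUE)$values > 0))
})

test_that("kfold_split partitions trials per session deterministically", {
  trials <- lapply(1:100, function(k)
    list(left_times = numeric(0), right_times = numeric(0), duration = 0.3,
         choice = k %% 2, spikes = NULL,
         session_id = if (k <= 50) 1L else 2L))
  sess <- ddm_session(trials)
  folds <- kfold_split(sess, k = 5, seed = 3)
  expect_length(folds, 5)
  test_sets <- lapply(folds, `[[`, "test")
  expect_equal(sort(unlist(test_sets)), 1:100)
  expect_true(all(vapply(test_sets, length, integer(1)) == 20))
  # stratification: each test fold covers both sessions equally
  for (ts in test_sets) expect_equal(sum(ts <= 50), 10)
  for (f in folds) expect_length(intersect(f$train, f$test), 0)
  folds2 <- kfold_split(sess, k = 5, seed = 3)
  expect_identical(folds, folds2)
  expect_error(kfold_split(ddm_session(trials[1:3]), k = 5), "fewer")
})

test_that("bits_per_trial follows the definition", {
  expect_equal(bits_per_trial(-100, -100, 10), 0)
  expect_equal(bits_per_trial(-50 + 20 * log(2), -50, 20), 1)
  expect_equal(bits_per_trial(-9, -10, 10), 1 / (10 * log(2)),
               tolerance = 1e-12)
  expect_error(bits_per_trial(0, 0, 0), "positive")
})

test_that("null models match their closed forms", {
  trials <- lapply(1:10, function(k)
    list(left_times = numeric(0), right_times = numeric(0), duration = 0.1,
         choice = 1, spikes = NULL))
  sess <- ddm_session(trials)
  specc <- model_spec("choice-only", n = 7)
  n_all_right <- null_models(sess, specc)
  expect_equal(n_all_right$choice_ll, 0)
  trials5 <- trials
  for (k in 1:5) trials5[[k]]$choice <- 0
  n_half <- null_models(ddm_session(trials5), specc)
  expect_equal(n_half$choice_ll, 10 * log(0.5))
})

test_that("finite-difference gradient direction matches a coarse check", {
  # the internal objective's FD gradient should match central differences
  sess <- tiny_session(K = 3, duration = 0.05, seed = 13)
  prep <- tiny_prep(sess, spec7)
  th <- tiny_theta(spec7)
  f <- function(v) { th2 <- th; th2[] <- v; joint_loglik(th2, prep, spec7) }
  g_fwd <- vapply(seq_along(th), function(i) {
    h <- 1e-6 * (1 + abs(th[i]))
    e <- th; e[i] <- e[i] + h
    (f(e) - f(th)) / h
  }, numeric(1))
  g_cen <- vapply(seq_along(th), function(i) {
    h <- 1e-5 * (1 + abs(th[i]))
    ep <- th; ep[i] <- ep[i] + h
    em <- th; em[i] <- em[i] - h
    (f(ep) - f(em)) / (2 * h)
  }, numeric(1))
  expect_equal(g_fwd, g_cen, tolerance = 1e-3)
})
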