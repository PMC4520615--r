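cfg_ms <- sim_config(dt = 0.001, horizon_steps = 100L)

test_that("one-step prediction advances mean and covariance correctly", {
  cfg0 <- sim_config(dt = 0.001, sigma_theta_noise = 0, sigma_omega_noise = 0)
  lm0 <- linear_model(cfg0)
  b <- gaussian_belief(c(0, 10), matrix(0, 2, 2))
  p <- kf_predict_one(b, lm0)
  expect_equal(p$mean, c(0.01, 10))
  expect_equal(p$cov, matrix(0, 2, 2))
  # identity covariance, Q = 0: Sigma' = A A^T
  bI <- gaussian_belief(c(0, 0), diag(2))
  pI <- kf_predict_one(bI, lm0)
  dt <- 0.001
  expect_equal(pI$cov, matrix(c(1 + dt^2, dt, dt, 1), 2, 2))
  # with process noise, repeated prediction never shrinks the trace
  lm <- linear_model(cfg_ms)
  b2 <- gaussian_belief(c(0, 0), diag(c(1, 1)))
  tr <- numeric(1000)
  for (i in 1:1000) {
    b2 <- kf_predict_one(b2, lm)
    tr[i] <- sum(diag(b2$cov))
  }
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("measurement update behaves at the informative and flat limits", {
  cfg <- cfg_ms
  # uninformative observation: huge R leaves the belief unchanged
  lmBig <- linear_model(cfg, itd_model("linear", noise_sd = 1e9))
  b <- gaussian_belief(c(5, -3), matrix(c(4, 0.5, 0.5, 2), 2, 2),
                       step = 1L, last_obs = 0L)
  u <- kf_update(b, 100, lmBig)
  expect_equal(u$mean, b$mean, tolerance = 1e-6)
  expect_equal(u$cov, b$cov, tolerance = 1e-6)
  # exact observation pins the observed component
  lm0 <- linear_model(cfg, itd_model("linear", noise_sd = 0))
  bI <- gaussian_belief(c(0, 0), diag(2), step = 1L, last_obs = 0L)
  u0 <- kf_update(bI, 26.7, lm0)
  expect_equal(u0$mean[1], 10)
  expect_equal(u0$cov[1, 1], 0, tolerance = 1e-12)
  # degenerate: no noise anywhere
  b0 <- gaussian_belief(c(0, 0), matrix(0, 2, 2), step = 1L, last_obs = 0L)
  expect_error(kf_update(b0, 1, lm0), "degenerate")
})

test_that("two-step filter matches the batch conjugate-Gaussian oracle", {
  cfg <- cfg_ms
  obs <- itd_model("linear")
  lm <- linear_model(cfg, obs)
  sw <- constant_velocity_sweep(0, 10, cfg$dt, cfg)  # two steps
  y <- as.numeric(observe(sw, obs, seed = 11))
  fit <- itd_track(structure(y, dt = cfg$dt, class = "itd_sequence"), cfg, obs)
  oracle <- batch_posterior_x2(cfg$prior_mean, prior_cov(cfg),
                               lm$A, lm$C, lm$Q, lm$R, y)
  f2 <- fit$filtered[2, ]
  expect_equal(c(f2$mean_theta_unwrapped, f2$mean_omega), oracle$mean,
               tolerance = 1e-9)
  expect_equal(matrix(c(f2$s11, f2$s12, f2$s12, f2$s22), 2, 2), oracle$cov,
               tolerance = 1e-9)
})

test_that("n-step extrapolation matches the explicit noise-sum loop", {
  cfg <- cfg_ms
  lm <- linear_model(cfg)
  b <- gaussian_belief(c(0, 10), matrix(c(2, 0.3, 0.3, 1), 2, 2),
                       step = 5L, last_obs = 5L)
  expect_identical(kf_predict_n(b, lm, 0), b)
  p100 <- kf_predict_n(b, lm, 100)
  expect_equal(p100$mean[1], 1, tolerance = 1e-12)
  for (n in c(1, 7, 100, 250)) {
    a <- kf_predict_n(b, lm, n, method = "closed_form")
    l <- kf_predict_n(b, lm, n, method = "loop")
    expect_equal(a$cov, l$cov, tolerance = 1e-12)
    expect_equal(a$mean, l$mean, tolerance = 1e-12)
  }
})

test_that("prediction trails then leads a moving source by the horizon", {
  cfg <- default_cfg
  sw <- constant_velocity_sweep(20, 50, 1, cfg)
  itd <- observe(sw, itd_model("linear"), seed = 2)
  fit <- itd_track(itd, cfg)
  p <- fit$predicted
  lead <- cfg$horizon_steps * cfg$dt
  future <- 20 + 50 * p$t_seconds  # true direction at the prediction target
  late <- p$t_seconds >= 0.6 & p$t_seconds <= 1.0
  expect_lt(sqrt(mean((p$mean_theta_unwrapped[late] - future[late])^2)), 1.5)
  # early on the prior holds the prediction back: it trails the target
  early <- p$k <= 8
  expect_gt(mean(future[early] - p$mean_theta_unwrapped[early]), 2)
  # the predictive posterior is always wider than the tracking posterior
  expect_true(all(p$s11 + p$s22 >= fit$filtered$s11 + fit$filtered$s22))
})

test_that("covariance recursion is observation-independent", {
  cfg <- default_cfg
  sw <- constant_velocity_sweep(0, 30, 0.5, cfg)
  f1 <- itd_track(observe(sw, itd_model("linear"), seed = 1), cfg)
  f2 <- itd_track(observe(sw, itd_model("linear"), seed = 99), cfg)
  expect_identical(f1$filtered[, c("s11", "s12", "s22")],
                   f2$filtered[, c("s11", "s12", "s22")])
  expect_false(identical(f1$filtered$mean_theta, f2$filtered$mean_theta))
})

test_that("tracking converges to a noiseless constant-velocity source", {
  cfg <- sim_config(prior_corr = 0)
  obs0 <- itd_model("linear", noise_sd = 1e-6)
  sw <- constant_velocity_sweep(-10, 40, 0.5, cfg)
  fit <- itd_track(observe(sw, obs0, seed = 1), cfg, obs0)
  late <- sw$t_seconds > 0.2
  expect_lt(max(abs(fit$filtered$mean_theta[late] - sw$theta_deg[late])), 0.05)
})
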