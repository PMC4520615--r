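test_that("particle initialisation draws from the prior", {
  cfg <- default_cfg
  e1 <- pf_init(cfg, m = 1, seed = 1)
  expect_length(e1$theta, 1)
  expect_equal(e1$weights, 1)
  e <- pf_init(cfg, m = 1e5, seed = 2)
  expect_equal(sd(e$theta), 23.3, tolerance = 3 * 23.3 / sqrt(2e5))
  expect_lt(abs(cor(e$theta, e$omega) - (-0.05)), 3 / sqrt(1e5))
})

test_that("likelihood weighting matches the closed-form Gaussian ratio", {
  lin <- itd_model("linear")
  two <- particle_ensemble(c(0, 90), c(0, 0))
  w <- pf_weight(two, 0, lin)
  expect_equal(w$weights[2] / w$weights[1],
               exp(-(2.67 * 90)^2 / (2 * 12.5^2)))
  expect_equal(w$weights[1], 1, tolerance = 1e-12)
  # near-flat likelihood leaves weights uniform
  flat <- pf_weight(two, 0, itd_model("linear", noise_sd = 1e12))
  expect_equal(flat$weights, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(pf_ess(flat), 2, tolerance = 1e-6)
  # weights always renormalise over random ensembles
  set.seed(3)
  for (i in 1:10) {
    e <- particle_ensemble(runif(50, -90, 90), rnorm(50), runif(50))
    expect_equal(sum(pf_weight(e, rnorm(1, 0, 30), lin)$weights), 1,
                 tolerance = 1e-9)
  }
  # log-space weighting survives extreme innovations without underflow
  far <- particle_ensemble(c(89, 90), c(0, 0))
  wf <- pf_weight(far, -1e5, lin)
  expect_equal(sum(wf$weights), 1, tolerance = 1e-9)
  # a non-finite observation is flagged as degenerate
  expect_error(pf_weight(far, Inf, lin), "degenerate likelihood")
})

test_that("resampling is multinomial with the stated expectations", {
  e <- particle_ensemble(c(1, 2, 3), c(0, 0, 0), c(0, 1, 0))
  r <- pf_resample(e, seed = 1)
  expect_true(all(r$theta == 2))
  expect_equal(r$weights, rep(1 / 3, 3))
  # expected copy count of particle j is m * w_j
  m <- 200
  w <- (1:m) / sum(1:m)
  ens <- particle_ensemble(seq_len(m), numeric(m), w)
  counts <- numeric(m)
  set.seed(4)
  reps <- 400
  for (i in seq_len(reps)) {
    r <- pf_resample(ens)
    counts <- counts + tabulate(match(r$theta, seq_len(m)), m)
  }
  exp_counts <- m * w
  se <- sqrt(m * w * (1 - w) / reps)
  expect_true(all(abs(counts / reps - exp_counts) < 4 * se + 0.05))
  # uniform weights: resampled spread matches the original distribution
  set.seed(5)
  big <- particle_ensemble(rnorm(2e4, 10, 5), numeric(2e4))
  rb <- pf_resample(big)
  expect_lt(suppressWarnings(ks.test(rb$theta, big$theta)$statistic), 0.02)
})

test_that("n-step propagation is the generative dynamics in distribution", {
  cfg0 <- sim_config(dt = 0.001, sigma_theta_noise = 0, sigma_omega_noise = 0)
  e <- particle_ensemble(rep(0, 100), rep(10, 100))
  expect_identical(pf_predict_n(e, cfg0, 0), e)
  p <- pf_predict_n(e, cfg0, 100, seed = 1)
  expect_true(all(abs(p$theta - 1) < 1e-12))
  # exact joint draw vs explicit stepping: same first and second moments
  cfg <- default_cfg
  e2 <- particle_ensemble(rep(0, 4e4), rep(20, 4e4))
  a <- pf_predict_n(e2, cfg, 10, seed = 2, exact = TRUE)
  b <- pf_predict_n(e2, cfg, 10, seed = 3, exact = FALSE)
  expect_equal(mean(a$theta), mean(b$theta), tolerance = 0.05)
  expect_equal(sd(a$theta), sd(b$theta), tolerance = 0.05)
  expect_equal(sd(a$omega), sd(b$omega), tolerance = 0.02)
  # and both match the Kalman n-step covariance on the same setup
  lm <- linear_model(cfg)
  kb <- kf_predict_n(gaussian_belief(c(0, 20), matrix(0, 2, 2),
                                     step = 0L, last_obs = 0L), lm, 10)
  expect_equal(var(a$theta), kb$cov[1, 1], tolerance = 0.1)
  expect_equal(cov(a$theta, a$omega), kb$cov[1, 2], tolerance = 0.05)
})

test_that("the circular-mean estimate behaves on known distributions", {
  expect_equal(pf_estimate(particle_ensemble(rep(37, 5), numeric(5))), 37)
  expect_equal(pf_estimate(particle_ensemble(c(-45, 45), c(0, 0))), 0)
  set.seed(6)
  wn <- particle_ensemble(wrap_deg(rnorm(2e4, 20, 10)), numeric(2e4))
  expect_equal(pf_estimate(wn), 20, tolerance = 3 * 10 / sqrt(2e4) + 0.1)
  # opposite equal-weight particles have no resultant
  expect_error(circ_mean_deg(c(0, 180), c(1, 1)), "zero length")
})

test_that("particle and Kalman predictions agree on the linear model", {
  cfg <- default_cfg
  run <- fit_sweep(start = 10, v = 40, duration = 0.6, seed = 9)
  pf <- itd_track(run$itd, cfg, method = "particle", m = 4000, seed = 10)
  burn <- run$fit$predicted$k > 15
  d <- ang_diff_deg(pf$predicted$mean_theta[burn],
                    run$fit$predicted$mean_theta[burn])
  expect_lt(mean(abs(d)), 1)
})

test_that("estimate variance shrinks like 1/m", {
  cfg <- default_cfg
  lin <- itd_model("linear")
  ms <- c(100, 1000, 10000)
  set.seed(11)
  v <- sapply(ms, function(m) {
    est <- replicate(40, {
      e <- pf_weight(pf_init(cfg, m), 26.7, lin)
      pf_estimate(e)
    })
    var(est)
  })
  slope <- coef(lm(log(v) ~ log(ms)))[2]
  expect_lt(slope, -0.6)
  expect_gt(slope, -1.4)
})
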