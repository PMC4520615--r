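make_fixed_pop <- function(thetas, cfg = default_cfg) {
  build_population(cfg, N = length(thetas), proposal = "custom",
                   proposal_sample = function(n)
                     data.frame(theta = thetas, omega = numeric(n)),
                   proposal_density = function(theta) rep(1 / 360, length(theta)))
}

test_that("preferred stimuli follow the proposal density", {
  cfg <- default_cfg
  pop <- build_population(cfg, N = 5000, seed = 1)
  expect_equal(sd(pop$preferred$theta), 23.3, tolerance = 3 * 23.3 / sqrt(1e4))
  expect_s3_class(build_population(cfg, N = 1, seed = 2), "itd_population")
  # joint tuning carries the prior's direction-velocity correlation
  pj <- build_population(cfg, N = 2e4, tuning = "joint", seed = 3)
  expect_lt(abs(cor(pj$preferred$theta, pj$preferred$omega) - (-0.05)),
            3 / sqrt(2e4))
  # uniform proposal is flat over its support
  pu <- build_population(cfg, N = 2e4, proposal = "uniform", seed = 4)
  h <- table(cut(pu$preferred$theta, seq(-90, 90, by = 10)))
  expect_gt(chisq.test(h)$p.value, 1e-4)
})

test_that("rates equal the scaled posterior/proposal ratio", {
  cfg <- default_cfg
  pop <- build_population(cfg, N = 2000, seed = 5)
  # posterior identical to the proposal: every neuron fires at the peak rate
  prior_b <- prior_belief(cfg)
  r <- compute_rates(pop, prior_b)
  expect_true(all(abs(r - pop$peak_rate) < 1e-9))
  # sharp posterior at 30 deg drives a neuron preferring (almost) 30 deg;
  # the proposal divisor shifts the optimum slightly outward
  sharp <- gaussian_belief(c(30, 0), diag(c(4, 4)), step = 10L, last_obs = 10L)
  rs <- compute_rates(pop, sharp)
  expect_lt(abs(pop$preferred$theta[which.max(rs)] - 30), 1.5)
  expect_equal(max(rs), pop$peak_rate)
  # brute force over neurons confirms the ratio ordering
  ratio <- dnorm(pop$preferred$theta, 30, 2) /
    dnorm(pop$preferred$theta, 0, 23.3)
  expect_equal(order(rs)[1:2000], order(pop$peak_rate * ratio / max(ratio))[1:2000])
})

test_that("Poisson spiking has Poisson moments", {
  expect_true(all(poissonify(rep(0, 100), 0.01, seed = 1) == 0))
  counts <- poissonify(rep(10, 1e5), 0.01, seed = 2)
  expect_lt(abs(mean(counts) - 0.1), 3 * sqrt(0.1 / 1e5))
  expect_lt(abs(var(counts) - 0.1), 0.01)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05)
  expect_error(poissonify(c(-1, 2), 0.01), "nonnegative")
})

test_that("the population vector points where the activity points", {
  pop <- make_fixed_pop(c(-45, 25, 45))
  act <- c(0, 3, 0)
  expect_equal(population_vector(pop, act), 25)
  expect_equal(population_vector(pop, c(2, 0, 2)), 0)
  expect_error(population_vector(pop, c(0, 0, 0)), "zero length")
  expect_true(is.na(population_vector(pop, c(0, 0, 0), on_zero = "na")))
})

test_that("deterministic PV converges to the Bayesian prediction direction", {
  cfg <- default_cfg
  belief <- gaussian_belief(c(25, 5), matrix(c(9, 0.5, 0.5, 4), 2, 2),
                            step = 50L, last_obs = 50L)
  bv <- bv_direction(belief)
  expect_equal(bv, 25)
  Ns <- c(500, 5000, 50000)
  set.seed(6)
  err <- sapply(Ns, function(N) {
    median(abs(replicate(12, {
      pop <- build_population(cfg, N = N)
      ang_diff_deg(population_vector(pop, compute_rates(pop, belief)), bv)
    })))
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1)
  slope <- coef(stats::lm(log(err) ~ log(Ns)))[2]
  expect_lt(slope, -0.25)
  expect_gt(slope, -0.8)
})

test_that("the PV direction is invariant to the proposal density", {
  cfg <- default_cfg
  belief <- gaussian_belief(c(20, 0), diag(c(9, 4)), step = 5L, last_obs = 5L)
  pop_prior <- build_population(cfg, N = 50000, seed = 8)
  pop_unif <- build_population(cfg, N = 50000, proposal = "uniform", seed = 9)
  pv_prior <- population_vector(pop_prior, compute_rates(pop_prior, belief))
  pv_unif <- population_vector(pop_unif, compute_rates(pop_unif, belief))
  expect_lt(abs(ang_diff_deg(pv_prior, pv_unif)), 2)
  expect_lt(abs(ang_diff_deg(pv_prior, 20)), 2)
})

test_that("Poisson-mode PV is unbiased for the deterministic PV", {
  cfg <- default_cfg
  pop <- build_population(cfg, N = 3000, seed = 10)
  belief <- gaussian_belief(c(10, 0), diag(c(9, 4)), step = 5L, last_obs = 5L)
  rates <- compute_rates(pop, belief)
  pv_det <- population_vector(pop, rates)
  set.seed(11)
  draws <- replicate(300, {
    population_vector(pop, poissonify(rates, 0.05), on_zero = "na")
  })
  expect_lt(abs(ang_diff_deg(mean(draws, na.rm = TRUE), pv_det)), 0.5)
})

test_that("kernel-density rates from particle beliefs track Gaussian ones", {
  cfg <- default_cfg
  pop <- build_population(cfg, N = 800, seed = 12)
  set.seed(13)
  ens <- particle_ensemble(rnorm(5000, 15, 4), rnorm(5000, 0, 2), step = 9L)
  belief <- gaussian_belief(c(15, 0), diag(c(16, 4)), step = 9L, last_obs = 9L)
  r_kde <- compute_rates(pop, ens)
  r_g <- compute_rates(pop, belief)
  pvs <- c(population_vector(pop, r_kde), population_vector(pop, r_g))
  expect_lt(abs(ang_diff_deg(pvs[1], pvs[2])), 1.5)
})

test_that("decoding a track yields aligned Bayes and PV series", {
  cfg <- default_cfg
  run <- fit_sweep(start = 0, v = 40, duration = 0.6, seed = 14)
  pop <- build_population(cfg, N = 3000, seed = 15)
  dec <- pv_decode(run$fit, pop, seed = 16)
  expect_equal(nrow(dec), 61)
  expect_true(all(is.finite(dec$pv_det)))
  expect_true(all(is.finite(dec$pv_poisson)))
  expect_lt(rms_angular(dec$pv_det, dec$bayes), 3)
  # deterministic PV outperforms the spiking readout on average
  expect_lt(rms_angular(dec$pv_det, dec$bayes),
            rms_angular(dec$pv_poisson, dec$bayes) + 0.5)
})
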