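cfg_rf <- default_cfg

test_that("a static source pins the receptive field at the static preferred ITD", {
  rf <- receptive_field(c(0, 0), 0, cfg_rf)
  expect_equal(max(abs(rf$shift), na.rm = TRUE), 0, tolerance = 1e-8)
  expect_equal(rf$static_itd, 0)
  rf20 <- receptive_field(c(20, 0), 0, cfg_rf)
  expect_equal(rf20$static_itd, 2.67 * 20)
  # for an eccentric neuron the central prior genuinely displaces the
  # early best ITD outward; once the prior has washed out the best ITD
  # settles at the static preferred ITD
  expect_lt(max(abs(rf20$shift[rf20$time_centres > 0.3]), na.rm = TRUE), 0.5)
})

test_that("the shift is delayed, then approaches the sensorimotor lead", {
  rf <- receptive_field(c(0, 0), 40, cfg_rf, velocity_units = "itd_us_s")
  s <- rf$shift
  t <- rf$time_centres
  terminal <- mean(s[t > 0.8])
  expect_equal(terminal, 4, tolerance = 0.4)  # 40 us/s x 0.1 s lead
  # sluggish onset: almost no shift while the prior dominates
  expect_lt(mean(abs(s[t < 0.06])), 0.3 * terminal)
  # receptive fields sharpen monotonically with time
  expect_true(all(diff(rf$width) < 0.5))
  expect_lt(tail(rf$width, 1), 0.55 * rf$width[1])
})

test_that("shift magnitude grows with source speed", {
  sv <- shift_vs_velocity(c(0, 0), c(5, 20, 40, 80), config = cfg_rf)
  term <- sapply(split(sv, sv$velocity_itd_us_s), function(d)
    mean(d$shift_us[d$time_s > 0.8], na.rm = TRUE))
  expect_true(all(diff(term[order(as.numeric(names(term)))]) > 0))
  expect_equal(unname(term[order(as.numeric(names(term)))]),
               c(5, 20, 40, 80) * 0.1, tolerance = 0.35)
  sv0 <- shift_vs_velocity(c(0, 0), 0, config = cfg_rf)
  expect_lt(max(abs(sv0$shift_us), na.rm = TRUE), 1e-8)
})

test_that("shift asymmetry grows with eccentricity and needs the central prior", {
  g <- asymmetry_profile(c(0, 35, 70), velocity = 15, config = cfg_rf)
  idx <- g$index$asymmetry_index_us
  expect_true(all(diff(idx) > 0))
  u <- asymmetry_profile(c(0, 70), velocity = 15, config = cfg_rf,
                         prior = "uniform")
  expect_lt(max(u$index$asymmetry_index_us), 1)
  expect_lt(max(u$index$asymmetry_index_us), 0.2 * idx[3])
  # mirror symmetry at the midline holds for the raw curves too
  mid <- subset(g$curves, preferred_theta == 0)
  ccw <- mid$shift_raw_us[mid$sense == "ccw"]
  cw <- mid$shift_raw_us[mid$sense == "cw"]
  expect_lt(max(abs(ccw + cw), na.rm = TRUE), 0.5)
})

test_that("parameter sweeps reproduce the baseline at factor one and widen with noise", {
  base <- receptive_field(c(0, 0), 15, cfg_rf)
  ps <- parameter_sweep(c(0, 0), "itd_noise_sd", factors = c(0.5, 1, 2),
                        velocity = 15, config = cfg_rf)
  at1 <- subset(ps, factor == 1)
  expect_equal(at1$shift_us, base$shift, tolerance = 1e-10)
  expect_equal(at1$width_us, base$width, tolerance = 1e-10)
  lw <- sapply(split(ps, ps$factor), function(d)
    mean(d$width_us[d$time_s > 0.5], na.rm = TRUE))
  expect_true(all(diff(lw[order(as.numeric(names(lw)))]) > 0))
  # robustness: halving or doubling any dynamics/prior parameter moves the
  # late shift by less than half the lead
  for (par in c("theta_noise_sd", "prior_theta_sd")) {
    pp <- parameter_sweep(c(0, 0), par, factors = c(0.5, 2),
                          velocity = 15, config = cfg_rf)
    late <- sapply(split(pp, pp$factor), function(d)
      mean(d$shift_us[d$time_s > 0.8], na.rm = TRUE))
    expect_lt(max(abs(late - 4)), 2)
  }
})

test_that("the sampled protocol converges to the expected map", {
  exp_rf <- receptive_field(c(0, 0), 15, cfg_rf)
  smp_rf <- receptive_field(c(0, 0), 15, cfg_rf, method = "sampled",
                            trials = 25, seed = 21)
  t <- exp_rf$time_centres
  late <- t > 0.5
  expect_equal(mean(smp_rf$shift[late], na.rm = TRUE),
               mean(exp_rf$shift[late], na.rm = TRUE), tolerance = 1.2)
  expect_equal(mean(smp_rf$width[late], na.rm = TRUE),
               mean(exp_rf$width[late], na.rm = TRUE), tolerance = 0.25 *
                 mean(exp_rf$width[late], na.rm = TRUE))
})

test_that("a neuron far outside the protocol's coverage is flagged empty", {
  # a tight prior keeps the posterior pinned far from the neuron at every
  # step, so its rate underflows to zero over the whole protocol
  cfg_tight <- sim_config(prior_sd = c(1, 5))
  expect_warning(
    receptive_field(c(90, 0), 0, cfg_tight, starts = c(40, 45)),
    "empty receptive field")
})
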