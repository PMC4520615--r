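# shared fixtures and independent oracles

default_cfg <- sim_config()

# a small linear-world sweep fit used by several files
fit_sweep <- function(start = 20, v = 50, duration = 0.5, seed = 1,
                      cfg = default_cfg, obs = itd_model("linear")) {
  sw <- constant_velocity_sweep(start, v, duration, cfg)
  itd <- observe(sw, obs, seed = seed)
  list(sweep = sw, itd = itd, fit = itd_track(itd, cfg, obs))
}

# brute-force Spearman with average ranks for ties (Pearson on mid-ranks),
# independent of stats::cor(method = "spearman")
spearman_oracle <- function(x, y) {
  rk <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (1 + sum(v == vi)) / 2)
  }
  rx <- rk(x); ry <- rk(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# batch conjugate-Gaussian posterior of x2 given (y1, y2) for the linear
# state-space model, by explicit joint-Gaussian conditioning (independent
# of the Kalman recursion)
batch_posterior_x2 <- function(m0, S0, A, C, Q, R, y) {
  m1 <- A %*% m0; m2 <- A %*% m1
  S1 <- A %*% S0 %*% t(A) + Q
  S2 <- A %*% S1 %*% t(A) + Q
  C12 <- S1 %*% t(A)                       # Cov(x1, x2)
  Syy <- rbind(
    c(C %*% S1 %*% t(C) + R, C %*% C12 %*% t(C)),
    c(C %*% C12 %*% t(C), C %*% S2 %*% t(C) + R))
  Sxy <- cbind(t(C12) %*% t(C), S2 %*% t(C))  # Cov(x2, (y1, y2))
  mu_y <- c(C %*% m1, C %*% m2)
  K <- Sxy %*% solve(Syy)
  list(mean = drop(m2 + K %*% (y - mu_y)),
       cov = S2 - K %*% t(Sxy))
}
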