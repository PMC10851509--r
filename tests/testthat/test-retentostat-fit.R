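test_that("point-wise growth rate matches its defining log-ratio", {
  pm <- pointwise_mu(c(0, 24), c(5, 10))
  expect_equal(pm$mu, log(2) / 24)
  expect_equal(pm$t_mid, 12)
  expect_equal(pointwise_mu(c(0, 24, 48), c(5, 5, 5))$mu, c(0, 0))
  expect_error(pointwise_mu(c(0, 24), c(5, -1)), "positive")

  # against the ODE oracle at near-zero growth: interval log-ratio mu
  # approximates the simulator's mu to within 1%
  tr <- simulate_retentostat(default_cfg(), reten_params(),
                             t_end = 672, output_dt = 24)
  pm2 <- pointwise_mu(tr$t, tr$C_X)
  late <- pm2$t_mid > 400
  mu_true <- stats::approx(tr$t, tr$mu, xout = pm2$t_mid[late])$y
  expect_true(all(abs(pm2$mu[late] - mu_true) / mu_true < 0.01))
})

test_that("biomass-accumulation fit recovers the maintenance coefficient on noise-free data", {
  cfg <- default_cfg()
  qp <- qp_gompertz_default()
  for (m_S_true in c(0.002, 0.0037, 0.008)) {
    p_true <- pirt_params(m_S_true, 0.544)
    obs <- make_retentostat_observations(cfg, p_true, qp, noise = no_noise())
    fit <- fit_retentostat(obs, cfg, pirt_params(0.005, 0.544), qp_model = qp)
    expect_lt(abs(fit$m_S_hat - m_S_true) / m_S_true, 1e-6)
    expect_true(fit$converged)
  }
})

test_that("terminal growth rate comes from the same code path as the simulator", {
  cfg <- default_cfg()
  qp <- qp_gompertz_default()
  obs <- make_retentostat_observations(cfg, reten_params(), qp,
                                       noise = no_noise())
  fit <- fit_retentostat(obs, cfg, pirt_params(0.005, 0.544), qp_model = qp)
  redo <- simulate_retentostat(cfg, pirt_params(fit$m_S_hat, 0.544), qp,
                               times = obs$t, C_X0 = obs$C_Xv[1])
  expect_identical(fit$terminal_mu, redo$mu[nrow(redo)])
})

test_that("the fit is a fixed point of its own prediction", {
  cfg <- default_cfg()
  qp <- qp_gompertz_default()
  obs <- make_retentostat_observations(cfg, reten_params(), qp,
                                       noise = noise_spec(seed = 7))
  fit <- fit_retentostat(obs, cfg, pirt_params(0.005, 0.544), qp_model = qp)
  obs2 <- retentostat_obs(t = obs$t, C_X = fit$trajectory$C_X)
  fit2 <- fit_retentostat(obs2, cfg, pirt_params(0.005, 0.544), qp_model = qp)
  expect_lt(abs(fit2$m_S_hat - fit$m_S_hat), 1e-10)
})

test_that("fit tolerates measurement noise with small dispersion", {
  cfg <- default_cfg()
  qp <- qp_gompertz_default()
  p_true <- reten_params()
  est <- vapply(1:5, function(s) {
    obs <- make_retentostat_observations(
      cfg, p_true, qp,
      noise = noise_spec(cv_cx = 0.03, viability_floor = 1, seed = 100 + s))
    fit_retentostat(obs, cfg, pirt_params(0.005, 0.544), qp_model = qp)$m_S_hat
  }, numeric(1))
  expect_lt(stats::sd(est) / p_true$m_S, 0.05)
  expect_lt(abs(mean(est) - p_true$m_S) / p_true$m_S, 0.03)
})

test_that("fit object exposes the standard model-object interface", {
  cfg <- default_cfg()
  obs <- make_retentostat_observations(cfg, reten_params(),
                                       qp_gompertz_default(),
                                       noise = no_noise())
  fit <- fit_retentostat(obs, cfg, pirt_params(0.005, 0.544),
                         qp_model = qp_gompertz_default())
  expect_named(coef(fit), c("m_S", "Y_XS_max", "Y_PS_max"))
  expect_equal(length(residuals(fit)), nrow(obs))
  expect_lt(sum(residuals(fit)^2), 1e-12)
  expect_equal(fitted(fit), fit$trajectory$C_X)
  pr <- predict(fit, times = seq(0, 240, by = 48))
  expect_equal(nrow(pr), 6)
  expect_output(print(fit), "terminal mu")
  expect_error(fit_retentostat(obs[1:4, ], cfg, pirt_params(0.005, 0.544)),
               "7 days")
})

test_that("(mu, q_P) pairs from a noiseless producer culture lie on the attenuated curve", {
  cfg <- default_cfg()
  qp <- qp_gompertz_default()
  obs <- make_retentostat_observations(cfg, reten_params(), qp,
                                       noise = no_noise())
  pairs <- qp_mu_pairs(obs, cfg)
  expect_equal(nrow(pairs), nrow(obs) - 1)
  atten <- washout_attenuation(cfg$phi, 24)
  late <- pairs$t_mid > 48
  expect_true(all(abs(pairs$q_P[late] / qp_at(qp, pairs$mu[late]) - atten)
                  < 0.01 * atten))
  # single interval -> single pair
  expect_equal(nrow(qp_mu_pairs(obs[1:2, ], default_cfg())), 1)
  # no production: all q_P zero
  obs0 <- retentostat_obs(t = obs$t, C_X = obs$C_X,
                          C_P = rep(0, nrow(obs)))
  expect_true(all(qp_mu_pairs(obs0, cfg)$q_P == 0))
})
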