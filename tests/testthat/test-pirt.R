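test_that("Pirt balance evaluates the growth/maintenance/product partition", {
  p <- chemo_params()
  # growth and product terms vanish at mu = 0, q_P = 0
  expect_equal(pirt_qs(0, p), 0.00437)
  expect_equal(pirt_qs(0.1, p), 0.1 / 0.544 + 0.00437)
  expect_equal(pirt_qs(0.17, p, q_P = 0.00064),
               0.17 / 0.544 + 0.00437 + 0.00064 / 0.609)
  expect_error(pirt_qs(-0.1, p), "non-negative")
  expect_error(pirt_qs(0.1, p, q_P = NaN), "finite")
})

test_that("product correction undoes the product term exactly", {
  p <- chemo_params()
  expect_equal(growth_corrected_qs(0.188, 0), 0.188)
  expect_equal(growth_corrected_qs(0.317921, 0.00064, 0.609),
               0.317921 - 0.00064 / 0.609)
  # algebraic round trip: correcting a forward-evaluated q_S leaves
  # growth + maintenance only
  for (mu in c(0.015, 0.07, 0.17)) {
    qp <- 0.0005 * mu / 0.17
    expect_equal(growth_corrected_qs(pirt_qs(mu, p, qp), qp, p$Y_PS_max),
                 mu / p$Y_XS_max + p$m_S)
  }
})

test_that("doubling time converts growth rate with ln(2)/mu in days", {
  expect_equal(doubling_time(log(2)), 1 / 24)
  expect_equal(doubling_time(0.025), log(2) / 0.025 / 24, tolerance = 1e-12)
  expect_lt(abs(doubling_time(0.025) - 1.155), 1e-3)
  # identity mu * t_d = ln 2 across magnitudes
  for (mu in 10^seq(-4, 0, by = 1))
    expect_equal(doubling_time(mu) * 24 * mu, log(2))
  expect_error(doubling_time(0), "positive")
})

test_that("windowed regression recovers generating parameters exactly on noise-free data", {
  d <- make_chemostat_dataset(chemo_params(), noise = no_noise())
  w <- sliding_window_fit(d, window = 3)
  expect_equal(nrow(w), 5)  # 7 setpoints -> 5 windows of 3
  expect_true(all(abs(w$m_S - 0.00437) / 0.00437 < 1e-10))
  expect_true(all(abs(w$Y_XS_max - 0.544) / 0.544 < 1e-10))
  expect_true(all(w$valid))

  # producer dataset: subtracting the product term reproduces the
  # non-producer window estimates identically
  qp <- qp_gompertz_default()
  dp <- make_chemostat_dataset(chemo_params(), qp, noise = no_noise())
  dn <- chemostat_dataset(mu = dp$mu,
                          q_S = growth_corrected_qs(dp$q_S, dp$q_P, 0.609))
  wp <- sliding_window_fit(dp, Y_PS_max = 0.609)
  wn <- sliding_window_fit(dn, Y_PS_max = 0.609)
  expect_equal(wp$m_S, wn$m_S)
  expect_equal(wp$Y_XS_max, wn$Y_XS_max)
})

test_that("degenerate windows are refused", {
  d <- chemostat_dataset(mu = c(0.02, 0.02, 0.05, 0.05),
                         q_S = c(0.04, 0.041, 0.1, 0.099))
  expect_error(sliding_window_fit(d, window = 3), "degenerate window")
})

test_that("low-mu averaging pools exactly the windows below the threshold", {
  # 7 default setpoints, lowest 5 at <= 0.1 -> exactly 3 windows of size 3
  d <- make_chemostat_dataset(chemo_params(), noise = no_noise())
  w <- sliding_window_fit(d)
  p <- average_low_mu_params(w, mu_threshold = 0.100)
  expect_equal(attr(p, "n_windows"), 3L)
  expect_equal(p$m_S, 0.00437, tolerance = 1e-10)
  expect_equal(p$Y_XS_max, 0.544, tolerance = 1e-10)
  expect_equal(attr(p, "sd_m_S"), 0, tolerance = 1e-12)

  # arithmetic-mean semantics on hand-made windows
  w2 <- w[1:3, ]
  w2$m_S <- c(0.004, 0.0044, 0.0047)
  class(w2) <- class(w)
  p2 <- average_low_mu_params(w2)
  expect_equal(p2$m_S, mean(c(0.004, 0.0044, 0.0047)))

  expect_error(average_low_mu_params(w, mu_threshold = 0.001),
               "no valid window")
})

test_that("maintenance estimate is unbiased under multiplicative noise", {
  truth <- 0.00437
  est <- vapply(seq_len(200), function(i) {
    d <- make_chemostat_dataset(chemo_params(),
                                noise = noise_spec(cv_qs = 0.05, seed = 5000 + i))
    # heavy noise can flag individual windows; those warnings are the
    # designed reporting behaviour, not a failure of the study
    suppressWarnings(fit_pirt(d)$params$m_S)
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), se)
})

test_that("fit_pirt returns a usable model object", {
  d <- make_chemostat_dataset(chemo_params(), qp_gompertz_default(),
                              noise = noise_spec(seed = 11))
  f <- fit_pirt(d)
  expect_s3_class(f, "pirt_fit")
  expect_named(coef(f), c("m_S", "Y_XS_max", "Y_PS_max"))
  expect_equal(coef(f)[["m_S"]], 0.00437, tolerance = 0.15)
  expect_equal(predict(f, mu = 0.025),
               pirt_qs(0.025, f$params))
  expect_output(print(f), "m_S")
})
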