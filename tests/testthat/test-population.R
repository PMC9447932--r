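test_that("gain profile matches its closed-form anchor points", {
  m <- pop_model()
  expect_equal(gain_profile(m, 30, gamma_m = 0), rep(1, 100))
  g <- gain_profile(m, m$phi[13], gamma_m = 0.3, gamma_s = 1)
  expect_equal(g[13], 1 - 0.3)  # cos^3(0) = 1 at the adapter
  expect_true(all(g >= 0.7 & g <= 1))
  # rectified zero-crossing: 45 deg away in orientation = 90 deg doubled
  g45 <- gain_profile(m, 0, 0.3, 1)
  expect_equal(g45[which.min(abs(m$phi - 45))], 1, tolerance = 1e-6)
  expect_error(gain_profile(m, 0, gamma_m = 1.2), class = "serialdep_error_gain")
  expect_error(gain_profile(m, 0, 0.3, gamma_s = 0), class = "serialdep_error_gain")
})

test_that("population response has the stated von Mises form", {
  m <- pop_model(kappa = 1, rate = 5)
  r <- pop_response(m, theta = m$phi[7])
  expect_equal(r[7], 5)  # peak unadapted rate = R
  # orthogonal orientation: R * exp(-2 kappa)
  orth <- which.min(abs(m$phi - wrap_ori(m$phi[7] + 90) %% 180))
  expect_equal(r[orth], 5 * exp(-2), tolerance = 1e-6)
  # adapted at the previous stimulus: peak reduced by (1 - gamma_m)
  ra <- pop_response(m, m$phi[7], theta_prev = m$phi[7], gamma_m = 0.3)
  expect_equal(ra[7], 5 * 0.7)
  expect_true(all(pop_response(m, 123.4, 10, 0.5, 2) >= 0))
})

test_that("unaware decoding is self-consistent and repelled from the adapter", {
  m <- pop_model()
  # noiseless unadapted input decodes to itself
  for (th in c(0, 33, 90.5)) {
    pr <- decode_profile(pop_response(m, th), m, "unaware")
    expect_equal(wrap_ori(profile_map(pr) - th), 0, tolerance = 0.51)
  }
  # adapted input at 0 < |delta| < 45: MAP repelled from the previous stimulus
  for (dlt in c(20, 30, -25)) {
    resp <- pop_response(m, 60, 60 + dlt, gamma_m = 0.3, gamma_s = 1)
    err <- wrap_ori(profile_map(decode_profile(resp, m, "unaware")) - 60)
    expect_gt(err * -sign(dlt), 0.5)  # pushed away from theta_prev
  }
  # symmetric cases are unbiased
  for (dlt in c(0, 90)) {
    resp <- pop_response(m, 60, 60 + dlt, gamma_m = 0.3, gamma_s = 1)
    expect_equal(wrap_ori(profile_map(decode_profile(resp, m, "unaware")) - 60),
                 0, tolerance = 0.51)
  }
  expect_error(decode_profile(c(-1, rep(1, 99)), m), class = "serialdep_error_resp")
  expect_error(decode_profile(rep(1, 100), m, "aware"),
               class = "serialdep_error_prev")
})

test_that("aware decoding undoes adaptation exactly; overaware overshoots", {
  m <- pop_model()
  set.seed(41)
  for (i in 1:5) {
    th <- runif(1, 0, 180)
    tp <- runif(1, 0, 180)
    resp <- pop_response(m, th, tp, gamma_m = 0.3, gamma_s = 1)
    aw <- decode_profile(resp, m, "aware", theta_prev = tp,
                         gamma_m = 0.3, gamma_s = 1)
    expect_equal(abs(wrap_ori(profile_map(aw) - th)), 0, tolerance = 0.51)
  }
  # reductions: gamma_m = 0 and matched assumed adaptation
  resp <- pop_response(m, 50, 80, gamma_m = 0.3, gamma_s = 1)
  aw <- decode_profile(resp, m, "aware", 80, gamma_m = 0.3, gamma_s = 1)
  oa_same <- decode_profile(resp, m, "overaware", 80, gamma_m = 0.3,
                            gamma_s = 1, gamma_m2 = 0.3, gamma_s2 = 1)
  expect_equal(oa_same$loglik, aw$loglik, tolerance = 1e-10)
  un <- decode_profile(pop_response(m, 50), m, "unaware")
  aw0 <- decode_profile(pop_response(m, 50), m, "aware", 80, gamma_m = 0)
  expect_equal(aw0$loglik, un$loglik, tolerance = 1e-10)
  # inflated assumed adaptation attracts; deflated leaves residual repulsion
  oa_hi <- decode_profile(resp, m, "overaware", 80, gamma_m = 0.3,
                          gamma_s = 1, gamma_m2 = 0.45, gamma_s2 = 1)
  expect_gt(wrap_ori(profile_map(oa_hi) - 50), 0.5)
  oa_lo <- decode_profile(resp, m, "overaware", 80, gamma_m = 0.3,
                          gamma_s = 1, gamma_m2 = 0.15, gamma_s2 = 1)
  expect_lt(wrap_ori(profile_map(oa_lo) - 50), -0.5)
})

test_that("contiguity prior mixes a circular Gaussian with a uniform floor", {
  grid <- seq(0, 179, 1)
  p <- contiguity_prior(grid, theta_prev = 40, p_same = 0.64, psi = 20)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(grid[which.max(p)], 40)
  expect_true(all(p >= (1 - 0.64) / length(grid) - 1e-12))
  # flat prior: posterior MAP equals the likelihood MAP
  m <- pop_model()
  resp <- pop_response(m, 70, 100, gamma_m = 0.3)
  b0 <- decode_profile(resp, m, "bayes_unaware", 100, gamma_m = 0.3, p_same = 0)
  u <- decode_profile(resp, m, "unaware")
  expect_equal(profile_map(b0), profile_map(u))
  # flat likelihood: the prior dominates
  bflat <- decode_profile(rep(1, 100), m, "bayes_unaware", 100,
                          gamma_m = 0, psi = 15)
  expect_equal(profile_map(bflat), 100, tolerance = 0.51)
  expect_equal(sum(bflat$posterior), 1, tolerance = 1e-10)
})

test_that("noiseless bias curves are odd with the canonical sign ordering", {
  m <- pop_model()
  delta <- seq(-90, 90, 15)
  curves <- list(
    unaware = model_bias_curve(m, "unaware", delta, gamma_m = 0.3, gamma_s = 1),
    aware = model_bias_curve(m, "aware", delta, gamma_m = 0.3, gamma_s = 1),
    overaware = model_bias_curve(m, "overaware", delta, gamma_m = 0.3,
                                 gamma_s = 1, gamma_m2 = 0.45, gamma_s2 = 1),
    bayes_aware = model_bias_curve(m, "bayes_aware", delta, gamma_m = 0.3,
                                   gamma_s = 1, psi = 20),
    bayes_unaware = model_bias_curve(m, "bayes_unaware", delta, gamma_m = 0.3,
                                     gamma_s = 1, psi = 20))
  for (nm in names(curves)) {
    b <- curves[[nm]]$bias
    expect_equal(b[delta == 0], 0, tolerance = 0.1)
    expect_equal(abs(b[delta == 90]), 0, tolerance = 0.1)
    expect_equal(b, -rev(b), tolerance = 0.2)  # odd symmetry
  }
  at30 <- function(nm) curves[[nm]]$bias[delta == 30]
  expect_lt(at30("unaware"), -1)
  expect_equal(at30("aware"), 0, tolerance = 0.1)
  expect_gt(at30("overaware"), 0.5)
  expect_gt(at30("bayes_aware"), 0.1)
  # reduction chain: no adaptation collapses every decoder to unbiased ML
  for (dec in c("unaware", "aware", "overaware")) {
    b0 <- model_bias_curve(m, dec, delta, gamma_m = 0, gamma_s = 1,
                           gamma_m2 = 0, gamma_s2 = 1)
    expect_equal(b0$bias, rep(0, length(delta)), tolerance = 0.1)
  }
})

test_that("Poisson-sampled decoding is reproducible with sensible variance", {
  m <- pop_model()
  e1 <- sim_decoder_errors(m, "unaware", n_trials = 300, gamma_m = 0.3, seed = 5)
  e2 <- sim_decoder_errors(m, "unaware", n_trials = 300, gamma_m = 0.3, seed = 5)
  expect_identical(e1, e2)
  # doubling the rate sharpens the likelihood
  m2 <- pop_model(rate = 10)
  e_hi <- sim_decoder_errors(m2, "unaware", 600, gamma_m = 0, seed = 6)
  e_lo <- sim_decoder_errors(m, "unaware", 600, gamma_m = 0, seed = 6)
  expect_lt(circ_sd_deg(e_hi$error), circ_sd_deg(e_lo$error))
})
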