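test_that("encoding stage recovers the bias curve and flags the null", {
  m <- pop_model()
  eng <- serialdep:::make_unaware_engine(m)
  set.seed(71)
  d <- runif(800, -90, 90)
  e <- wrap_ori(eng(0.3, 1, d) + rnorm(800, 0, 8))
  f <- fit_encoding(e, d, m)
  # the (gamma_m, gamma_s) pair trades off along a near-degenerate ridge, so
  # recovery is asserted in curve space, where the model is identified
  dd <- seq(-90, 90, 5)
  expect_lt(max(abs(eng(f$gamma_m, f$gamma_s, dd) - eng(0.3, 1, dd))), 1)
  # refinement never worse than the truth's objective
  expect_lte(f$rss, sum((e - eng(0.3, 1, d))^2))
  # zero-bias errors: adaptation magnitude collapses to ~0
  e0 <- rnorm(800, 0, 8)
  f0 <- fit_encoding(e0, d, m)
  expect_lt(max(abs(eng(f0$gamma_m, f0$gamma_s, dd))), 1)
  expect_s3_class(f, "encoding_fit")
  expect_named(glance(f), c("gamma_m", "gamma_s", "rss", "n_folds"))
})

test_that("readout stage recovers an overaware observer's bias curve", {
  m <- pop_model()
  gen <- model_bias_curve(m, "overaware", delta = seq(-90, 90, 2),
                          gamma_m = 0.3, gamma_s = 1,
                          gamma_m2 = 0.5, gamma_s2 = 1)
  bf <- function(d) approx(gen$delta, gen$bias, xout = d, rule = 2)$y
  trl <- sim_trials(n_blocks = 10, trials_per_block = 80, seed = 72)
  trl <- sim_responses(trl, bias_fun = bf, sigma = 5, seed = 73)
  fit <- fit_readout(trl, encoding = c(0.3, 1), model = m,
                     decoder = "overaware")
  rec <- model_bias_curve(m, "overaware", delta = seq(-90, 90, 2),
                          gamma_m = 0.3, gamma_s = 1,
                          gamma_m2 = fit$gamma_m2, gamma_s2 = fit$gamma_s2)
  expect_lt(max(abs(rec$bias - gen$bias)), 1.5)
  expect_equal(attr(fit, "sigma"), 5, tolerance = 1)
  expect_named(tidy(fit), c("fold", "term", "estimate"))
  # unbiased observer: fitted overaware bias collapses toward zero
  tr0 <- sim_responses(trl, amplitude = 0, sigma = 5, seed = 74)
  f0 <- fit_readout(tr0, encoding = c(0.3, 1), model = m,
                    decoder = "overaware")
  rec0 <- model_bias_curve(m, "overaware", delta = seq(-90, 90, 10),
                           gamma_m = 0.3, gamma_s = 1,
                           gamma_m2 = f0$gamma_m2, gamma_s2 = f0$gamma_s2)
  expect_lt(max(abs(rec0$bias)), 1.5)
})

test_that("Bayesian readouts are fit per fold on shared folds and compared", {
  m <- pop_model()
  gen <- model_bias_curve(m, "bayes_aware", delta = seq(-90, 90, 2),
                          gamma_m = 0.3, gamma_s = 1, psi = 20)
  # behavioral-scale generating observer: rate 1.7 sharpens prior influence
  m_b <- pop_model(rate = 1.7)
  gen_b <- model_bias_curve(m_b, "bayes_aware", delta = seq(-90, 90, 2),
                            gamma_m = 0.3, gamma_s = 1, psi = 20)
  bf <- function(d) approx(gen_b$delta, gen_b$bias, xout = d, rule = 2)$y
  folds <- rep(1:2, each = 200)
  # data generated by a bayes-aware observer favor the bayes-aware readout
  # in the majority of seeds (the bayes-unaware readout can imitate the bias
  # curve, so single datasets occasionally tie or flip)
  wins <- sapply(1:5, function(s) {
    trl <- sim_trials(n_blocks = 8, trials_per_block = 50, seed = 74 + s)
    trl <- sim_responses(trl, bias_fun = bf, sigma = 5, seed = 80 + s)
    fit_ba <- fit_readout(trl, encoding = c(0.3, 1), model = m,
                          decoder = "bayes_aware", folds = folds, grid_n = 15)
    fit_bu <- fit_readout(trl, encoding = c(0.3, 1), model = m,
                          decoder = "bayes_unaware", folds = folds,
                          grid_n = 15)
    cmp <- compare_readouts(fit_ba, fit_bu)
    cmp$loglik[cmp$decoder == "bayes_aware"] >=
      cmp$loglik[cmp$decoder == "bayes_unaware"]
  })
  expect_gte(sum(wins), 3)
  trl <- sim_trials(n_blocks = 8, trials_per_block = 50, seed = 75)
  trl <- sim_responses(trl, bias_fun = bf, sigma = 5, seed = 76)
  fit_ba <- fit_readout(trl, encoding = c(0.3, 1), model = m,
                        decoder = "bayes_aware", folds = folds, grid_n = 10)
  expect_equal(fit_ba$fold, 1:2)
  # identical fits give identical pooled likelihoods
  cmp2 <- compare_readouts(fit_ba, fit_ba)
  expect_equal(cmp2$loglik[1], cmp2$loglik[2])
  bad <- fit_readout(trl, encoding = c(0.3, 1), model = m,
                     decoder = "bayes_aware", folds = rep(1:4, each = 100),
                     grid_n = 8)
  expect_error(compare_readouts(fit_ba, bad), class = "serialdep_error_folds")
})

test_that("Jensen-Shannon divergence is a bounded metric-like score", {
  p <- c(0.2, 0.3, 0.5)
  expect_equal(js_divergence(p, p), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2))
  expect_gt(js_divergence(p, rev(p)), 0)
  set.seed(77)
  e <- rnorm(2000, 0, 10)
  expect_lt(error_js(e, e), 1e-12)
  expect_gt(error_js(e, rnorm(2000, 0, 40)), 0.05)
})

test_that("variance evaluation reproduces the close/far signature", {
  m <- pop_model()
  enc <- fit_encoding(dog(runif(50, -90, 90), -4, 0.03), runif(50, -90, 90), m,
                      grid_n = 8)
  enc$gamma_m <- 0.3
  enc$gamma_s <- 1
  rv <- readout_variance(enc, n_sim = 2000, seed = 78,
                         reference = sim_decoder_errors(m, "unaware", 500,
                                                        gamma_m = 0.3,
                                                        seed = 79)$error)
  expect_gt(rv$summary$sigma_close, rv$summary$sigma_far)
  expect_gt(rv$summary$js, 0)
  expect_lt(rv$summary$js, log(2))
})
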