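test_that("response probability follows the guess-rate-bounded normal CDF", {
  expect_equal(response_prob(0, mu = 0, sigma = 3), 0.5)
  expect_equal(response_prob(5, mu = 5, sigma = 0.7), 0.5)
  expect_equal(response_prob(1e6, 0, 5, 0.25), 0.875)
  expect_equal(response_prob(-1e6, 0, 5, 0.25), 0.125)
  # normal CDF table value at one SD above the mean
  expect_equal(response_prob(5 + 2, mu = 2, sigma = 5, guess_rate = 0.25),
               0.25 / 2 + 0.75 * pnorm(1))
  # monotone in the probe offset
  p <- response_prob(seq(-20, 20, 0.5), mu = -3, sigma = 4)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0.125 & p <= 0.875))
})

test_that("psychometric fit recovers generating bias and precision", {
  set.seed(21)
  d <- tibble::tibble(probe_offset = runif(4000, -15, 15), delta = 0)
  d <- sim_responses(d, bias_fun = function(x) -2, sigma = 5, seed = 22)
  f <- fit_psychometric(d)
  expect_equal(f$mu, -2, tolerance = 0.5)
  expect_equal(f$sigma, 5, tolerance = 0.5)
  expect_lt(f$mu, 0)  # sign consistency
  expect_identical(f$guess_rate, 0.25)  # held fixed, never estimated
  expect_false(f$boundary)
  expect_equal(tidy(f)$estimate, c(f$mu, f$sigma))
  expect_equal(glance(f)$nll, f$nll)
  # one-class responses flagged, not silently diverged
  d1 <- d
  d1$response <- "cw"
  expect_true(fit_psychometric(d1)$boundary)
  expect_error(fit_psychometric(tibble::tibble(probe_offset = rep(1, 5),
                                               response = rep("cw", 5))),
               class = "serialdep_error_support")
})

test_that("likelihood has a guess-rate floor so the NLL stays finite", {
  set.seed(23)
  d <- tibble::tibble(probe_offset = runif(200, -10, 10), delta = 0)
  d <- sim_responses(d, sigma = 5, seed = 24)
  # grossly wrong parameters still give finite NLL (floor = guess_rate/2)
  p <- response_prob(d$probe_offset, mu = 40, sigma = 0.2)
  cw <- as.numeric(d$response == "cw")
  expect_true(is.finite(-sum(cw * log(p) + (1 - cw) * log(1 - p))))
})

test_that("behavioral DoG fit recovers amplitude and width", {
  tr <- sim_trials(n_blocks = 40, trials_per_block = 30, seed = 25)
  tr <- sim_responses(tr, amplitude = 4.5, width = 0.04, sigma = 5, seed = 26)
  f <- fit_dog(tr)
  expect_equal(f$amplitude, 4.5, tolerance = 1.5)
  expect_equal(f$sigma, 5, tolerance = 1)
  expect_gt(f$fwhm, 15)
  # null observer: amplitude near zero
  tr0 <- sim_responses(tr, amplitude = 0, sigma = 5, seed = 27)
  expect_lt(abs(fit_dog(tr0)$amplitude), 1.5)
  expect_error(fit_dog(dplyr::mutate(tr, delta = 1)),
               class = "serialdep_error_support")
})

test_that("least-squares DoG fit has the attraction-positive sign convention", {
  set.seed(28)
  d <- runif(600, -90, 90)
  att <- dog(d, 8, 0.04) + rnorm(600, 0, 4)
  rep_ <- dog(d, -8, 0.04) + rnorm(600, 0, 4)
  expect_gt(fit_dog_ls(att, d)$amplitude, 4)
  expect_lt(fit_dog_ls(rep_, d)$amplitude, -4)
  expect_lt(abs(fit_dog_ls(rnorm(600, 0, 4), d)$amplitude), 2.5)
})

test_that("sliding window is half-open and centered as documented", {
  tr <- tibble::tibble(delta = c(-0.001, 0, 10, 31.99, 32, 50),
                       error = 1:6)
  sw <- sliding_bias(tr, window = 32, step = 2, estimator = "circular",
                     min_n = 1)
  got <- sw[sw$center == 16, ]
  expect_equal(got$n, 3L)  # exactly delta in [0, 32)
  # empty windows flagged missing, not zero
  sw2 <- sliding_bias(tibble::tibble(delta = rep(0, 20), error = rnorm(20)),
                      window = 10, step = 45, estimator = "circular", min_n = 1)
  expect_true(is.na(sw2$bias[sw2$center == 90]))
  expect_false(is.na(sw2$bias[sw2$center == 0]))
})

test_that("sliding psychometric bias tracks a DoG observer", {
  tr <- sim_trials(n_blocks = 60, trials_per_block = 30, seed = 29)
  tr <- sim_responses(tr, amplitude = 6, width = 0.03, sigma = 5, seed = 30)
  sw <- sliding_bias(tr, step = 8, min_n = 40)
  ok <- !is.na(sw$bias)
  pred <- dog(sw$center[ok], 6, 0.03)
  expect_gt(cor(sw$bias[ok], pred), 0.8)
})

test_that("close/far precision splits, folds and resamples as documented", {
  set.seed(31)
  n <- 4000
  d <- tibble::tibble(delta = runif(n, -90, 90),
                      probe_offset = runif(n, -12, 12))
  sig <- ifelse(abs(d$delta) < 30, 4, 8)  # far trials noisier
  p <- response_prob(d$probe_offset, 0, 1) * 0  # placeholder
  p <- 0.125 + 0.75 * pnorm(d$probe_offset / sig)
  d$response <- ifelse(runif(n) < p, "cw", "ccw")
  out <- precision_close_far(d, threshold = 30, seed = 32)
  expect_equal(out$bin, c("close", "far"))
  expect_gt(out$sigma[out$bin == "far"], out$sigma[out$bin == "close"])
  # equal generating sigma: medians agree within resampling error
  p2 <- 0.125 + 0.75 * pnorm(d$probe_offset / 5)
  d2 <- d
  d2$response <- ifelse(runif(n) < p2, "cw", "ccw")
  out2 <- precision_close_far(d2, threshold = 30, seed = 33)
  expect_equal(out2$sigma[1], out2$sigma[2], tolerance = 0.2 * out2$sigma[1])
  expect_error(precision_close_far(d, threshold = 95),
               class = "serialdep_error_threshold")
})
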