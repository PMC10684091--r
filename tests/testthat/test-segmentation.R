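test_that("segment_loglik obeys the 0*log(0) convention and closed form", {
  expect_equal(segment_loglik(0, 5), 0)
  expect_equal(segment_loglik(4, 4), 0)
  expect_equal(segment_loglik(3, 4), 3 * log(0.75) + log(0.25),
               tolerance = 1e-10)
  expect_error(segment_loglik(1, 0), "m")
  expect_error(segment_loglik(5, 4), "k")
})

test_that("enumerate_models spans the composition space", {
  expect_length(enumerate_models(c(1, 0, 1)), 4)           # 2^(n-1)
  expect_length(enumerate_models(1), 1)
  expect_length(enumerate_models(c(1, 0, 1), max_segments = 2), 3)

  # planted block: the 2-segment model at the true breakpoint is the MLE
  labels <- c(rep(1, 5), rep(0, 5))
  models <- enumerate_models(labels)
  ll <- vapply(models, `[[`, numeric(1), "log_likelihood")
  best <- models[[which.max(ll)]]
  expect_equal(best$log_likelihood, 0)
  two_seg <- vapply(models, function(m) m$n_segments == 2L &&
                      identical(m$breakpoints, 5L), logical(1))
  expect_equal(max(ll), models[[which(two_seg)]]$log_likelihood)

  expect_error(enumerate_models(rbinom(25, 1, 0.5)), "dp_model_average")
})

test_that("degenerate vectors give flat profiles with dominant 1-segment model", {
  p0 <- model_average(rep(0, 8))
  expect_equal(p0$rate, rep(0, 8))
  expect_equal(p0$lower95, rep(0, 8))
  p1 <- model_average(rep(1, 8))
  expect_equal(p1$rate, rep(1, 8))
  # the single-segment model minimizes the criterion on constant data
  models <- enumerate_models(rep(0, 8))
  ic <- vapply(models, `[[`, numeric(1), "ic_value")
  ns <- vapply(models, `[[`, integer(1), "n_segments")
  expect_equal(ns[which.min(ic)], 1L)

  # max_segments = 1 through the DP: flat profile at the global rate
  lab <- c(1, 1, 0, 0, 0, 1, 0, 0)
  pd <- dp_model_average(lab, max_segments = 1)
  expect_equal(pd$rate, rep(mean(lab), 8))
})

test_that("DP equals exhaustive enumeration across criteria and bounds", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    crit <- sample(c("BIC", "AIC", "AICc"), 1)
    ms <- sample(c(n, sample(2:n, 1)), 1)
    pe <- model_average(labels, crit, max_segments = ms)
    pd <- dp_model_average(labels, crit, max_segments = ms)
    expect_equal(pd$rate, pe$rate, tolerance = 1e-9)
    expect_equal(pd$lower95, pe$lower95, tolerance = 1e-9)
    expect_equal(pd$upper95, pe$upper95, tolerance = 1e-9)
  }
})

test_that("profiles are bounded, enveloped and mirror-symmetric", {
  set.seed(6)
  for (rep in 1:10) {
    labels <- rbinom(sample(20:60, 1), 1, 0.3)
    pr <- dp_model_average(labels, "BIC", 10)
    expect_true(all(pr$rate >= 0 & pr$rate <= 1))
    expect_true(all(pr$lower95 <= pr$rate & pr$rate <= pr$upper95))
    rev_pr <- dp_model_average(rev(labels), "BIC", 10)
    expect_equal(rev(rev_pr$rate), pr$rate, tolerance = 1e-9)
    expect_equal(rev(rev_pr$lower95), pr$lower95, tolerance = 1e-9)
  }
})

test_that("binned envelope tracks the exact envelope at grid resolution", {
  set.seed(9)
  for (rep in 1:5) {
    labels <- rbinom(60, 1, runif(1, 0.2, 0.6))
    pe <- dp_model_average(labels, "BIC", 20, .exact_envelope = TRUE)
    pb <- dp_model_average(labels, "BIC", 20, .exact_envelope = FALSE)
    expect_equal(pb$rate, pe$rate, tolerance = 1e-12)
    expect_lt(max(abs(pb$lower95 - pe$lower95)), 2 / 1023)
    expect_lt(max(abs(pb$upper95 - pe$upper95)), 2 / 1023)
  }
})

test_that("BIC profiles are at least as flat as AIC profiles", {
  # flatness = mean absolute deviation from the global label rate; the BIC
  # penalty log(n) exceeds the AIC penalty 2 for n >= 8, so BIC weight
  # concentrates on coarser models
  set.seed(12)
  flatter <- 0
  for (rep in 1:50) {
    n <- sample(10:14, 1)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pb <- model_average(labels, "BIC")
    pa <- model_average(labels, "AIC")
    fb <- mean(abs(pb$rate - mean(labels)))
    fa <- mean(abs(pa$rate - mean(labels)))
    expect_lte(fb, fa + 1e-9)
  }
})

test_that("planted high-rate blocks raise the DP profile", {
  set.seed(31)
  n <- 600
  block <- c(1:40, (n - 39):n)
  labels <- integer(n)
  labels[block] <- rbinom(length(block), 1, 0.6)
  labels[-block] <- rbinom(n - length(block), 1, 0.05)
  pr <- dp_model_average(labels, "BIC", 30)
  expect_gt(mean(pr$rate[block]) - mean(pr$rate[-block]), 0.2)
})
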