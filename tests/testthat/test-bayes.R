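# Gibbs sampler, posterior volumes and posterior overlap. Chains here are
# short: the conjugate sampler draws from exact conditionals, so mixing is
# immediate and a few hundred retained draws suffice for the checks.

short_fit <- function(x, seed = NULL, prior = jeffreys_prior()) {
  fit_posterior(x, iterations = 1500, burn_in = 500, thin = 5,
                seed = seed, prior = prior)
}

test_that("retained draw count follows floor((iterations - burn_in)/thin)", {
  set.seed(1)
  x <- MASS::mvrnorm(20, rep(0, 3), diag(3))
  f <- short_fit(x)
  expect_identical(f$settings$retained, 200L)
  expect_identical(nrow(f$means), 200L)
  expect_identical(dim(f$covariances)[3], 200L)
  f2 <- fit_posterior(x, iterations = 103, burn_in = 10, thin = 7)
  expect_identical(f2$settings$retained, (103L - 10L) %/% 7L)
  expect_error(fit_posterior(x, iterations = 10, burn_in = 20), "settings")
  expect_error(fit_posterior(x[1:3, ]), "insufficient data")
})

test_that("fixed seeds reproduce draws exactly", {
  set.seed(2)
  x <- MASS::mvrnorm(15, rep(0, 3), diag(3))
  f1 <- short_fit(x, seed = 99)
  f2 <- short_fit(x, seed = 99)
  expect_identical(f1$means, f2$means)
  expect_identical(f1$covariances, f2$covariances)
})

test_that("every covariance draw is symmetric positive definite", {
  set.seed(3)
  x <- MASS::mvrnorm(8, c(1, 2, 3), diag(c(0.5, 0.2, 0.3)))
  for (prior in list(jeffreys_prior(), niw_prior())) {
    f <- short_fit(x, seed = 4, prior = prior)
    ok <- vapply(seq_len(f$settings$retained), function(i) {
      s <- f$covariances[, , i]
      max(abs(s - t(s))) < 1e-10 &&
        !inherits(try(chol(s), silent = TRUE), "try-error")
    }, logical(1))
    expect_true(all(ok))
  }
})

test_that("the posterior recovers generating parameters at large n", {
  set.seed(4)
  mu <- c(-16, 12.5, 19)
  sigma <- diag(c(0.5, 0.2, 0.3))
  x <- MASS::mvrnorm(500, mu, sigma)
  f <- short_fit(x, seed = 5)
  pm <- colMeans(f$means)
  psd <- apply(f$means, 2, sd)
  expect_true(all(abs(pm - mu) < 3 * psd))
  # posterior median 1-sigma volume close to the sample SEV
  vp <- volume_posterior(f, coverage = sigma1_coverage())
  expect_equal(vp$median, sev(ellipsoid_from_sample(x)), tolerance = 0.05)
})

test_that("volume draws follow the chi-square coverage scaling law", {
  # hand-built degenerate posterior: every covariance the identity
  m <- 50L
  draws <- structure(
    list(means = matrix(0, m, 3),
         covariances = array(rep(diag(3), m), c(3, 3, m)),
         settings = list(retained = m)),
    class = "posterior_draws")
  v1 <- volume_posterior(draws, coverage = sigma1_coverage())
  expect_equal(v1$median, 4 * pi / 3)
  expect_equal(v1$iqr_75 - v1$iqr_25, 0)
  v75 <- volume_posterior(draws, coverage = 0.75)
  expect_equal(v75$draws, v1$draws * qchisq(0.75, 3)^1.5)
  expect_error(volume_posterior(draws, coverage = 1.2), "invalid coverage")
})

test_that("posterior volume spread contracts as n grows", {
  set.seed(6)
  sds <- sapply(c(10, 50, 250), function(n) {
    x <- MASS::mvrnorm(n, rep(0, 3), diag(3))
    f <- short_fit(x, seed = n)
    sd(volume_posterior(f, coverage = sigma1_coverage())$draws)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("95% volume credible intervals are close to nominal at n = 30", {
  set.seed(7)
  true_vol <- 4 * pi / 3
  hits <- replicate(100, {
    x <- MASS::mvrnorm(30, rep(0, 3), diag(3))
    v <- volume_posterior(short_fit(x), coverage = sigma1_coverage())$draws
    ci <- quantile(v, c(0.025, 0.975))
    ci[1] <= true_vol && true_vol <= ci[2]
  })
  expect_gte(sum(hits), 90)
  expect_lte(sum(hits), 99)
})

test_that("posterior overlap hits the interpretive extremes", {
  set.seed(8)
  x <- MASS::mvrnorm(30, rep(0, 3), diag(3))
  f <- fit_posterior(x, iterations = 140, burn_in = 40, thin = 2, seed = 9)
  # a group against itself: all 100%, zero-width interval
  self <- overlap_posterior(f, f, coverage = 0.75, subdivision = 1,
                            base_n = 8)
  expect_equal(self$first_in_second$median, 100)
  expect_equal(self$first_in_second$ci_upper - self$first_in_second$ci_lower,
               0)
  # groups 100 per mil apart in d13C: never any overlap
  xfar <- sweep(x, 2, c(100, 0, 0), "+")
  ffar <- fit_posterior(xfar, iterations = 140, burn_in = 40, thin = 2,
                        seed = 10)
  far <- overlap_posterior(f, ffar, coverage = 0.75, subdivision = 1,
                           base_n = 8)
  expect_equal(far$first_in_second$median, 0)
  expect_equal(far$second_in_first$median, 0)
  # draw sets must pair by index
  fshort <- fit_posterior(x, iterations = 120, burn_in = 40, thin = 2)
  expect_error(overlap_posterior(f, fshort), "pairing error")
})

test_that("same-distribution groups show significant overlap", {
  set.seed(10)
  sigma <- diag(c(0.5, 0.2, 0.3))
  xa <- MASS::mvrnorm(50, c(-16, 12.5, 19), sigma)
  xb <- MASS::mvrnorm(50, c(-16, 12.5, 19), sigma)
  fa <- fit_posterior(xa, iterations = 160, burn_in = 60, thin = 2, seed = 11)
  fb <- fit_posterior(xb, iterations = 160, burn_in = 60, thin = 2, seed = 12)
  op <- overlap_posterior(fa, fb, coverage = 0.75, subdivision = 1,
                          base_n = 8)
  expect_gt(op$first_in_second$median, 60)
  expect_gt(op$second_in_first$median, 60)
  expect_true(classify_overlap(op$first_in_second$median))
})

test_that("the 60% significance rule is a sharp threshold", {
  expect_true(classify_overlap(63))
  expect_true(classify_overlap(74))
  expect_true(classify_overlap(60))
  expect_false(classify_overlap(59.99))
  expect_false(classify_overlap(0))
  expect_error(classify_overlap(101), "0, 100")
  expect_error(classify_overlap(-1), "0, 100")
})

test_that("posterior-median volume is biased low at small n, not at n = 50", {
  b <- small_sample_bias_sim(c(5, 8, 50), replicates = 40, seed = 13,
                             iterations = 600, burn_in = 200, thin = 2)
  expect_lt(b$median_bias[b$n == 5], 0)
  expect_lt(b$median_bias[b$n == 8], 0)
  expect_lt(abs(b$median_bias[b$n == 50]),
            abs(b$median_bias[b$n == 8]))
  expect_error(small_sample_bias_sim(5, replicates = 0), "replicates")
  expect_error(small_sample_bias_sim(3, replicates = 10), ">= 4")
})
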