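test_that("the Gaussian likelihood behaves like a density", {
  expect_equal(likelihood(3, 15, at = 3), 1 / (15 * sqrt(2 * pi)))
  expect_equal(likelihood(0, 10, at = 4), likelihood(0, 10, at = -4))
  x <- seq(-200, 200, by = 0.05)
  expect_lt(abs(trapz(x, likelihood(10, 20, at = x)) - 1), 1e-6)
  expect_error(likelihood(0, 0, at = 0), "delta")
  expect_error(likelihood(0, -1, at = 0), "nonnegative")
})

test_that("posterior is the renormalized prior-likelihood product", {
  pri <- make_exp1_prior("right")
  # uninformative likelihood returns the prior
  expect_equal(posterior(pri, 12.3, Inf)$mass, pri$probs)
  # delta likelihood collapses on the nearest atom
  p0 <- posterior(pri, 1.2, 0)
  expect_equal(p0$mass, c(1, rep(0, 6)))
  # off-support sensed value vs a direct product-and-normalize oracle
  w <- pri$probs * dnorm(pri$support, 22.5, 15)
  expect_equal(posterior(pri, 22.5, 15)$mass, w / sum(w), tolerance = 1e-12)
  # normalization across random inputs
  set.seed(41)
  for (i in 1:25) {
    d <- random_dist()
    m <- posterior(d, runif(1, -40, 40), runif(1, 0.5, 40))$mass
    expect_lt(abs(sum(m) - 1), 1e-10)
    expect_true(all(m >= 0))
  }
  expect_error(posterior(pri, 1e6, 1e-320), "underflow")
})

test_that("smoothed posteriors integrate prior mass over a grid", {
  pri <- make_exp1_prior("right")
  ps <- posterior(pri, 22.5, 15, method = "smoothed", bandwidth = 2)
  expect_lt(abs(sum(ps$mass) - 1), 1e-10)
  # the smoothed posterior mean is close to the discrete posterior mean
  md <- posterior(pri, 22.5, 15)
  expect_lt(abs(sum(ps$x * ps$mass) - sum(md$x * md$mass)), 1)
})

test_that("expected power loss matches closed forms", {
  expect_equal(power_loss(10, 5, 1), 5)
  expect_equal(power_loss(10, 5, 2), 25)
  expect_equal(power_loss(-3.7, -3.7, 1.42), 0)
  one <- posterior_grid(4, 1)
  expect_equal(expected_loss(7, 1.3, one), 3^1.3)
  # bias-variance identity for the quadratic loss
  set.seed(7)
  for (i in 1:10) {
    d <- random_dist()
    post <- posterior_grid(d$support, d$probs)
    mu <- sum(post$x * post$mass)
    v <- sum(post$mass * (post$x - mu)^2)
    xc <- runif(1, -20, 20)
    expect_equal(expected_loss(xc, 2, post), v + (mu - xc)^2,
                 tolerance = 1e-10)
  }
})

test_that("optimal compensation tracks mean, median and mode of the posterior", {
  pri <- make_exp1_prior("right")
  post <- posterior(pri, 0, Inf)
  expect_equal(optimal_compensation(post, 2)$aim_mm, -10, tolerance = 1e-7)
  expect_equal(optimal_compensation(post, 1)$aim_mm, -5)
  # alpha -> 0 approaches the (negated) mode
  expect_lt(abs(optimal_compensation(post, 0.05)$aim_mm - 0), 0.01)
  # alpha = 2 equals the negated posterior mean for arbitrary posteriors
  set.seed(13)
  for (i in 1:20) {
    d <- random_dist()
    post <- posterior(d, runif(1, -30, 30), runif(1, 1, 30))
    expect_equal(optimal_compensation(post, 2)$aim_mm,
                 -sum(post$x * post$mass), tolerance = 1e-6)
  }
})

test_that("optimizer agrees with a dense-grid argmin oracle", {
  set.seed(99)
  for (i in 1:30) {
    d <- random_dist()
    alpha <- runif(1, 0.5, 3)
    post <- posterior(d, runif(1, -30, 30), runif(1, 1, 30))
    oracle <- -oracle_argmin_loss(post$x, post$mass, alpha)
    expect_lt(abs(optimal_compensation(post, alpha)$aim_mm - oracle), 0.02)
  }
})

test_that("prediction surfaces interpolate between full and no compensation", {
  pri <- make_exp1_prior("right")
  surf <- prediction_surface(pri, 2, c(dot = 1, cloud15 = 15, cloud30 = 30))
  expect_equal(nrow(surf), 28L)
  none <- surf$comp_opt_mm[surf$cue == "none"]
  expect_equal(none, rep(-10, 7), tolerance = 1e-4)
  # perfect information compensates each shift fully
  surf0 <- prediction_surface(pri, 2,
                              c(dot = 0, cloud15 = 0, cloud30 = 0))
  expect_equal(surf0$comp_opt_mm[surf0$cue == "dot"], -pri$support,
               tolerance = 1e-9)
  # intermediate uncertainty: each cell matches a direct posterior-mean
  # oracle, and the compensation line flattens from slope -1 (perfect
  # information) towards slope 0 (prior only)
  mid <- surf$comp_opt_mm[surf$cue == "cloud15"]
  oracle <- vapply(pri$support, function(s) {
    m <- posterior(pri, s, 15)$mass
    -sum(pri$support * m)
  }, numeric(1L))
  expect_equal(mid, oracle, tolerance = 1e-6)
  slope <- coef(lm(mid ~ pri$support))[2L]
  expect_gt(slope, -1)
  expect_lt(slope, 0)
})
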