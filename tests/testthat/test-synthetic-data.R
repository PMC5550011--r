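test_that("noise-free cue-uncertainty simulants follow the Bayesian policy", {
  pri <- make_exp1_prior("right")
  p <- sim_participant("x", "Error_SR", motor_sd = 0, seed = 8L)
  rec <- simulate_exp1_participant(p, pri, n_trials = 400L)
  expect_equal(nrow(rec), 400L)
  # cursor = hand + shift exactly on every row
  expect_identical(rec$cursor_x_mm, rec$hand_x_mm + rec$shift_mm)
  # withheld feedback: squared-error policy sits at minus the prior mean
  expect_equal(rec$hand_x_mm[rec$cue == "none"],
               rep(-10, sum(rec$cue == "none")), tolerance = 1e-4)
  # error-only group never receives reward
  expect_false(any(rec$reward))
  expect_true(any(rec$hit))
})

test_that("perfect sensing yields perfect hits on visible-cue trials", {
  pri <- make_exp1_prior("right")
  p <- sim_participant("x", "ReinfError_SR", motor_sd = 0,
                       sigma_sensed = c(dot = 0, cloud15 = 0, cloud30 = 0),
                       seed = 2L)
  rec <- simulate_exp1_participant(p, pri, n_trials = 300L)
  vis <- rec$cue != "none"
  expect_equal(rec$cursor_x_mm[vis], rep(0, sum(vis)), tolerance = 1e-9)
  # reinforced group: reward mirrors the hit flag
  expect_identical(rec$reward, rec$hit)
})

test_that("the loss exponent shifts mean compensation by median minus mean", {
  pri <- make_exp1_prior("right")
  sig_inf <- c(dot = Inf, cloud15 = Inf, cloud30 = Inf)
  p2 <- sim_participant("a", "Error_SR", alpha = 2, sigma_sensed = sig_inf,
                        motor_sd = 0, seed = 4L)
  p1 <- sim_participant("b", "Error_SR", alpha = 1, sigma_sensed = sig_inf,
                        motor_sd = 0, seed = 4L)
  r2 <- simulate_exp1_participant(p2, pri, n_trials = 100L)
  r1 <- simulate_exp1_participant(p1, pri, n_trials = 100L)
  # alpha = 2 aims at -mean (-10), alpha = 1 at -median (-5): 5 mm apart
  expect_equal(mean(r1$hand_x_mm) - mean(r2$hand_x_mm), 5, tolerance = 1e-4)
})

test_that("target-feedback simulants converge to their policy's aim", {
  d <- make_exp2_prior("right")
  p <- sim_participant("m", "Error", policy = "min_power_error",
                       motor_sd = 1e-9, seed = 5L)
  rec <- simulate_exp2_participant(p, d, learning = FALSE)
  expect_equal(rec$hand_x_mm, rep(5.6, 500), tolerance = 1e-6)
  # mode-seeking policy with vanishing noise compensates the mode
  pm <- sim_participant("r", "Reinforcement", policy = "max_hits",
                        motor_sd = 0.05, seed = 6L)
  rm <- simulate_exp2_participant(pm, d, learning = FALSE,
                                  max_hits_variant = "mode")
  expect_equal(mean(rm$hand_x_mm), 14, tolerance = 0.1)
  # with learning, the post-asymptote window sits at the asymptotic aim
  pl <- sim_participant("l", "Reinforcement", policy = "max_hits",
                        motor_sd = 10.6, seed = 7L)
  rl <- simulate_exp2_participant(pl, d)
  aim <- attr(rl, "aim_asymptote_mm")
  late <- rl$hand_x_mm[rl$trial > 100]
  expect_lt(abs(mean(late) - aim), 3 * 10.6 / sqrt(400))
})

test_that("mode-seeking simulants are rewarded more often than mean-seeking ones", {
  d <- make_exp2_prior("right")
  hits <- vapply(1:10, function(s) {
    pm <- sim_participant("r", "Reinforcement", policy = "max_hits",
                          motor_sd = 9, seed = s)
    pe <- sim_participant("e", "Reinforcement", policy = "min_power_error",
                          motor_sd = 9, seed = s + 100L)
    rm <- simulate_exp2_participant(pm, d, learning = FALSE)
    re <- simulate_exp2_participant(pe, d, learning = FALSE)
    c(mean(rm$reward), mean(re$reward))
  }, numeric(2L))
  expect_gt(mean(hits[1, ]), mean(hits[2, ]))
})

test_that("cloud dots are seeded bivariate normals via Box-Muller", {
  dots <- generate_cloud_dots(c(3, -2), sigma = 15, n = 25, seed = 9L)
  expect_equal(nrow(dots), 25L)
  # 99% chi-square envelope for a sample SD at n = 25
  env <- 15 * sqrt(qchisq(c(0.005, 0.995), 24) / 24)
  expect_gt(sd(dots$x_mm), env[1]); expect_lt(sd(dots$x_mm), env[2])
  expect_gt(sd(dots$y_mm), env[1]); expect_lt(sd(dots$y_mm), env[2])
  expect_identical(dots, generate_cloud_dots(c(3, -2), 15, 25, seed = 9L))
  big <- generate_cloud_dots(c(10, 0), sigma = 15, n = 10000, seed = 10L)
  expect_lt(abs(mean(big$x_mm) - 10), 3 * 15 / sqrt(10000))
  expect_lt(abs(mean(big$y_mm) - 0), 3 * 15 / sqrt(10000))
})

test_that("cohort simulation is reproducible and fully manifested", {
  cfg <- default_exp1_config(n_per_group = 1L, n_trials = 60L, seed = 77L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  out1 <- simulate_cohort(cfg, d1)
  out2 <- simulate_cohort(cfg, d2)
  expect_length(out1$files, 3L)
  expect_equal(nrow(read.csv(out1$files[1])), 60L)
  # byte-identical logs for the same master seed
  for (i in seq_along(out1$files))
    expect_identical(unname(tools::md5sum(out1$files[i])),
                     unname(tools::md5sum(out2$files[i])))
  expect_identical(out1$manifest$config_hash, out2$manifest$config_hash)
  bad <- cfg; bad$groups[[1]]$name <- "NotAGroup"
  expect_error(simulate_cohort(bad, withr::local_tempdir()), "invalid group")
})
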