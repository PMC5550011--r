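make_exp1_log <- function(alpha = 2, sigma = c(dot = 1, cloud15 = 15, cloud30 = 30),
                          motor_sd = 0, seed = 1L, skew = "right",
                          n_trials = 2000L) {
  p <- sim_participant("t", "Error_SR", alpha = alpha, sigma_sensed = sigma,
                       motor_sd = motor_sd, seed = seed)
  simulate_exp1_participant(p, make_exp1_prior(skew), n_trials = n_trials)
}

test_that("condition averaging reproduces a direct group-by", {
  rec <- make_exp1_log(motor_sd = 2, seed = 3L)
  tab <- condition_averages(rec, last_n = 1000L)
  expect_s3_class(tab, "condition_table")
  expect_equal(nrow(tab), 28L)
  expect_equal(sum(tab$n_trials), 1000L)
  # independent group-by oracle on the analysis window
  win <- rec[rec$trial > 1000, ]
  oracle <- tapply(win$hand_x_mm, list(win$shift_mm, win$cue), mean)
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$comp_mean_mm[r],
                 oracle[as.character(tab$shift_mm[r]), tab$cue[r]])
  # constant series: every cell mean equals the constant
  rec2 <- rec; rec2$hand_x_mm <- 4.2
  expect_true(all(condition_averages(rec2)$comp_mean_mm == 4.2))
  expect_error(condition_averages(rec, last_n = 3000L), "exceeds")
  # an emptied cell is reported by name
  rec3 <- rec[!(rec$shift_mm == 30 & rec$cue == "cloud30"), ]
  rec3$trial <- seq_len(nrow(rec3))
  expect_error(condition_averages(rec3, last_n = nrow(rec3)),
               "shift 30, cloud30")
})

test_that("fit weights equalize cues and track shift frequency", {
  w <- fit_weights(make_exp1_prior("right"))
  expect_equal(nrow(w), 28L)
  sums <- tapply(w$weight, w$cue, sum)
  expect_equal(as.numeric(sums), rep(1, 4))
  expect_equal(w$weight[w$shift_mm == 0], rep(9 / 21, 4))
  u <- shift_distribution(seq(0, 30, 5), rep(1 / 7, 7))
  expect_true(all(fit_weights(u)$weight == 1 / 7))
})

test_that("noiseless tables round-trip through the four-parameter fit", {
  pri <- make_exp1_prior("right")
  tab <- condition_averages(make_exp1_log(alpha = 2, seed = 5L))
  fit <- fit_bayes_model(tab, pri)
  expect_true(fit$converged)
  expect_lt(abs(fit$alpha_opt - 2) / 2, 0.01)
  expect_lt(max(abs(fit$sigma_opt - c(1, 15, 30)) / c(1, 15, 30)), 0.01)
  # objective at the optimum is no worse than at the generating parameters
  w <- fit_weights(pri)
  w <- w[order(w$cue, w$shift_mm), ]
  surf_true <- prediction_surface(pri, 2, c(dot = 1, cloud15 = 15, cloud30 = 30))
  surf_true <- surf_true[order(surf_true$cue, surf_true$shift_mm), ]
  obj_true <- sum(w$weight * abs(tab$comp_mean_mm - surf_true$comp_opt_mm))
  expect_lte(fit$objective, obj_true + 1e-6)

  fit1 <- fit_bayes_model(condition_averages(make_exp1_log(alpha = 1, seed = 6L)),
                          pri)
  expect_lt(abs(fit1$alpha_opt - 1), 0.05)
})

test_that("the fit is invariant to flipping left-skew data", {
  p <- sim_participant("t", "Error_SL", alpha = 2, motor_sd = 2, seed = 11L)
  rec <- simulate_exp1_participant(p, make_exp1_prior("left"))
  fit_sl <- fit_bayes_model(condition_averages(rec), make_exp1_prior("left"))
  # flip shifts about the common distribution mean (10 mm) and compensation
  # about the aligned optimal compensation (-10 mm)
  flipped <- rec
  flipped$shift_mm <- flip_values(rec$shift_mm, 10)
  flipped$hand_x_mm <- flip_values(rec$hand_x_mm, -10)
  flipped$cursor_x_mm <- flipped$hand_x_mm + flipped$shift_mm
  fit_fl <- fit_bayes_model(condition_averages(flipped), make_exp1_prior("right"))
  expect_lt(abs(fit_sl$alpha_opt - fit_fl$alpha_opt), 0.02)
})

test_that("predictions from a recovered fit close the loop", {
  pri <- make_exp1_prior("right")
  tab <- condition_averages(make_exp1_log(alpha = 2, seed = 7L))
  fit <- fit_bayes_model(tab, pri)
  pred <- predict_from_fit(fit, pri)
  # withheld-feedback predictions are shift-independent
  expect_lt(diff(range(pred$comp_pred_mm[pred$cue == "none"])), 1e-6)
  expect_lt(max(abs(pred$comp_pred_mm - tab$comp_mean_mm)), 0.05)
  expect_gt(variance_explained(tab, pred), 99.99)
})

test_that("per-cue linear fits match closed-form least squares", {
  # full compensation: slope -1, intercept 0 on visible cues
  rec <- {
    p <- sim_participant("t", "Error_SR", motor_sd = 0,
                         sigma_sensed = c(dot = 0, cloud15 = 0, cloud30 = 0),
                         seed = 12L)
    simulate_exp1_participant(p, make_exp1_prior("right"))
  }
  lf <- linear_condition_fit(rec)
  vis <- lf$cue != "none"
  expect_equal(lf$slope[vis], rep(-1, 3), tolerance = 1e-6)
  expect_equal(lf$intercept_mm[vis], rep(0, 3), tolerance = 1e-6)
  # withheld feedback, squared-error observer: flat line at -prior mean
  expect_equal(lf$slope[!vis], 0, tolerance = 1e-6)
  expect_equal(lf$intercept_mm[!vis], -10, tolerance = 1e-4)
  # normal-equations oracle on noisy cell means
  recn <- make_exp1_log(motor_sd = 3, seed = 13L)
  tab <- condition_averages(recn)
  lfn <- linear_condition_fit(recn)
  for (cue in unique(tab$cue)) {
    cell <- tab[tab$cue == cue, ]
    x <- cell$shift_mm; y <- cell$comp_mean_mm
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    expect_equal(lfn$slope[lfn$cue == cue], b)
    expect_equal(lfn$intercept_mm[lfn$cue == cue], a)
  }
})
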