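# Synthetic participants: trial-log generators with the statistical
# structure the downstream analyses assume.
#
# A simulated participant is a Bayesian observer-actor: on each trial the
# policy maps the sensed shift (equal to the true shift centroid unless
# sensing noise is enabled) to a compensation, and Gaussian execution noise
# (motor_sd) perturbs the final hand position. Cursor position is hand
# position plus the scheduled shift, exactly.

.exp1_groups <- c("Error_SR", "Error_SL", "ReinfError_SR")
.exp2_groups <- c("Reinforcement", "Error", "ReinfError")

#' Simulated participant parameters
#'
#' @param id participant identifier (character or integer).
#' @param group group label. 2000-trial design: `Error_SR`, `Error_SL`,
#'   `ReinfError_SR`. 500-trial design: `Reinforcement`, `Error`,
#'   `ReinfError`. Groups whose name contains `Reinf` receive the reward
#'   flag on target hits.
#' @param alpha true loss exponent (> 0) of the generating policy.
#' @param sigma_sensed named numeric: sensory SD (mm) for cues `dot`,
#'   `cloud15`, `cloud30`. The withheld cue is always infinite.
#' @param motor_sd execution noise SD (mm) of final hand position.
#' @param policy 500-trial aiming policy: `"min_power_error"`, `"max_hits"`
#'   or `"fixed"` (requires `aim_mm`).
#' @param aim_mm fixed aim (mm) when `policy = "fixed"`.
#' @param sensing_sd optional Gaussian sensing noise SD (mm) on the sensed
#'   centroid; 0 (the default) reproduces the assumption that the sensed
#'   centroid matches the true shift.
#' @param seed integer seed driving every stochastic draw for this
#'   participant.
#' @return An object of class `sim_participant`.
#' @export
sim_participant <- function(id, group,
                            alpha = 2,
                            sigma_sensed = c(dot = 1, cloud15 = 15, cloud30 = 30),
                            motor_sd = 2,
                            policy = c("min_power_error", "max_hits", "fixed"),
                            aim_mm = NULL,
                            sensing_sd = 0,
                            seed = 1L) {
  policy <- match.arg(policy)
  if (!group %in% c(.exp1_groups, .exp2_groups))
    stop("unknown group '", group, "'")
  stopifnot(alpha > 0, motor_sd >= 0, sensing_sd >= 0)
  if (!all(c("dot", "cloud15", "cloud30") %in% names(sigma_sensed)))
    stop("'sigma_sensed' must name dot, cloud15 and cloud30")
  if (any(sigma_sensed < 0)) stop("'sigma_sensed' must be nonnegative")
  if (policy == "fixed" && is.null(aim_mm))
    stop("policy 'fixed' requires 'aim_mm'")
  structure(list(id = as.character(id), group = group, alpha = alpha,
                 sigma_sensed = sigma_sensed, motor_sd = motor_sd,
                 policy = policy, aim_mm = aim_mm, sensing_sd = sensing_sd,
                 seed = as.integer(seed)),
            class = "sim_participant")
}

.is_reinforced <- function(group) grepl("Reinf", group)

.trial_record <- function(p, schedule, sensed, hand, hit_radius_mm) {
  cursor <- hand + schedule$shift_mm
  hit <- abs(cursor) <= hit_radius_mm
  data.frame(participant_id = p$id, group = p$group,
             trial = schedule$trial, cue = schedule$cue,
             shift_mm = schedule$shift_mm, sensed_mm = sensed,
             hand_x_mm = hand, cursor_x_mm = cursor,
             hit = hit,
             reward = hit & .is_reinforced(p$group),
             stringsAsFactors = FALSE)
}

#' Simulate a 2000-trial cue-uncertainty participant
#'
#' Draws a shift/cue schedule, applies the Bayesian power-loss policy per
#' trial (posterior of the prior and the cue's Gaussian likelihood, negated
#' expected-loss minimizer), and adds execution noise. With the default
#' noiseless sensing, the policy is precomputed once per (shift, cue) cell.
#'
#' @param p a [sim_participant] in a 2000-trial group.
#' @param prior a [shift_distribution] (the participant's true shift
#'   schedule and, asymptotically, their learned prior).
#' @param n_trials trial count, default 2000.
#' @param hit_radius_mm reward radius (mm): half the 14 mm target diameter.
#' @return A trial-record data.frame with columns `participant_id`, `group`,
#'   `trial`, `cue`, `shift_mm`, `sensed_mm`, `hand_x_mm`, `cursor_x_mm`,
#'   `hit`, `reward`.
#' @export
simulate_exp1_participant <- function(p, prior, n_trials = 2000L,
                                      hit_radius_mm = 7) {
  stopifnot(inherits(p, "sim_participant"), inherits(prior, "shift_distribution"))
  if (!p$group %in% .exp1_groups)
    stop("group '", p$group, "' is not a 2000-trial design group")
  sigmas <- c(p$sigma_sensed[c("dot", "cloud15", "cloud30")], none = Inf)
  withr::with_seed(p$seed, {
    schedule <- sample_schedule_exp1(prior, n_trials,
                                     seed = sample.int(.Machine$integer.max, 1L))
    if (p$sensing_sd == 0) {
      sensed <- schedule$shift_mm
      surf <- .comp_surface(prior, p$alpha, sigmas)
      key <- paste(surf$shift_mm, surf$cue)
      comp <- surf$comp_opt_mm[match(paste(schedule$shift_mm, schedule$cue), key)]
      if (anyNA(comp))
        stop("no sensory SD available for a sampled cue")
    } else {
      sensed <- schedule$shift_mm + stats::rnorm(n_trials, 0, p$sensing_sd)
      comp <- vapply(seq_len(n_trials), function(t) {
        optimal_compensation(
          posterior(prior, sensed[t], sigmas[[schedule$cue[t]]]),
          p$alpha)$aim_mm
      }, numeric(1L))
    }
    hand <- comp + stats::rnorm(n_trials, 0, p$motor_sd)
  })
  .trial_record(p, schedule, sensed, hand, hit_radius_mm)
}

#' Simulate a 500-trial target-feedback participant
#'
#' The asymptotic aim follows the participant's policy (error-based
#' squared-error minimization, reinforcement-based hit maximization, or a
#' fixed aim). Optionally the aim approaches its asymptote from 0 along a
#' single exponential with time constant `tau_trials`, purely so binned
#' series have a realistic learning phase; with the default 25 trials the
#' asymptote is reached well before trial 100 and analyses use only the
#' asymptotic window.
#'
#' @param p a [sim_participant] in a 500-trial group.
#' @param d a [shift_distribution] (three-point design).
#' @param learning logical: include the exponential approach phase.
#' @param tau_trials learning time constant (trials).
#' @param max_hits_variant `"width"` (maximize hits on the 14 mm target, the
#'   default) or `"mode"` (verbatim mode alignment).
#' @param target displayed target position (mm).
#' @inheritParams simulate_exp1_participant
#' @return A trial-record data.frame (500 rows, cue `target_only`).
#' @export
simulate_exp2_participant <- function(p, d, learning = TRUE, tau_trials = 25,
                                      max_hits_variant = c("width", "mode"),
                                      target = 0, hit_radius_mm = 7) {
  stopifnot(inherits(p, "sim_participant"), inherits(d, "shift_distribution"))
  max_hits_variant <- match.arg(max_hits_variant)
  if (!p$group %in% .exp2_groups)
    stop("group '", p$group, "' is not a 500-trial design group")
  # the aim computation needs a resolvable noise SD; min_sq is
  # noise-invariant, and for max_hits a 0.2 mm floor is indistinguishable
  # from the zero-noise mode-compensation limit at the 0.02 mm grid
  sd_eff <- max(p$motor_sd, 0.2)
  aim_asym <- switch(p$policy,
    min_power_error = aim_min_sq_error(d, sd_eff, target = target)$aim_mm,
    max_hits = if (max_hits_variant == "width")
      aim_max_hits_width(d, sd_eff, target = target)$aim_mm
    else aim_max_hits_mode(d, sd_eff, target = target)$aim_mm,
    fixed = p$aim_mm)
  withr::with_seed(p$seed, {
    schedule <- sample_schedule_exp2(d, seed = sample.int(.Machine$integer.max, 1L))
    n <- nrow(schedule)
    aim_t <- if (learning)
      aim_asym * (1 - exp(-(schedule$trial - 1) / tau_trials)) else
      rep(aim_asym, n)
    hand <- aim_t + stats::rnorm(n, 0, p$motor_sd)
  })
  rec <- .trial_record(p, schedule, sensed = schedule$shift_mm, hand,
                       hit_radius_mm)
  attr(rec, "aim_asymptote_mm") <- aim_asym
  rec
}

#' Generate a visual-uncertainty dot cloud via Box-Muller
#'
#' The medium and large cue clouds are 25 dots from an isotropic bivariate
#' normal around the (shifted) cursor centroid, generated with the
#' Box-Muller transform from seeded uniforms.
#'
#' @param centroid numeric length-2 (x, y) in mm.
#' @param sigma per-axis SD (mm), positive.
#' @param n number of dots.
#' @param seed integer seed.
#' @return data.frame with columns `x_mm`, `y_mm`.
#' @export
generate_cloud_dots <- function(centroid = c(0, 0), sigma, n = 25L, seed = 1L) {
  stopifnot(length(centroid) == 2L, sigma > 0, n >= 1L)
  withr::with_seed(seed, {
    u1 <- stats::runif(n)
    u2 <- stats::runif(n)
  })
  r <- sqrt(-2 * log(u1))
  data.frame(x_mm = centroid[1] + sigma * r * cos(2 * pi * u2),
             y_mm = centroid[2] + sigma * r * sin(2 * pi * u2))
}

#' Default cohort configurations
#'
#' The 2000-trial design has three groups of 10 (error-only right-skew,
#' error-only left-skew, reinforcement-plus-error right-skew); every group
#' follows the squared-error Bayesian policy (alpha = 2) with sensory SDs
#' (1, 15, 30) mm for the three visible cues and 2 mm execution noise. The
#' 500-trial design has three groups of 30, split equally between right and
#' left skew, with the group-average movement variabilities of 10.6 mm
#' (reinforcement-only, mode-seeking policy), 9.2 mm (error-only) and 8.8 mm
#' (reinforcement plus error), the latter two mean-seeking.
#'
#' @param n_per_group participants per group.
#' @param n_trials trials per participant (2000-trial design only).
#' @param seed master seed.
#' @return A config list accepted by [simulate_cohort()] and
#'   [run_pipeline()].
#' @export
default_exp1_config <- function(n_per_group = 10L, n_trials = 2000L,
                                seed = 1L) {
  list(experiment = 1L, seed = as.integer(seed), n_trials = as.integer(n_trials),
       groups = list(
         list(name = "Error_SR", n = n_per_group, skew = "right"),
         list(name = "Error_SL", n = n_per_group, skew = "left"),
         list(name = "ReinfError_SR", n = n_per_group, skew = "right")),
       alpha = 2, sigma_sensed = c(dot = 1, cloud15 = 15, cloud30 = 30),
       motor_sd = 2, last_n = 1000L, restarts = 8L)
}

#' @rdname default_exp1_config
#' @export
default_exp2_config <- function(n_per_group = 30L, seed = 1L) {
  list(experiment = 2L, seed = as.integer(seed),
       groups = list(
         list(name = "Reinforcement", n = n_per_group, policy = "max_hits",
              motor_sd = 10.6),
         list(name = "Error", n = n_per_group, policy = "min_power_error",
              motor_sd = 9.2),
         list(name = "ReinfError", n = n_per_group, policy = "min_power_error",
              motor_sd = 8.8)),
       last_n = 400L, n_resamples = 1e5)
}

#' Simulate a cohort and write per-participant trial logs
#'
#' Derives one seed per participant from the master seed, simulates each
#' trial log, writes it as CSV, and records every parameter in a manifest
#' JSON so the cohort is reproducible from the manifest alone.
#'
#' In the 500-trial design, group entries split participants equally between
#' right and left skew unless a `skew` is given explicitly.
#'
#' @param config a config list; see [default_exp1_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with `manifest` (the manifest list) and `files`
#'   (paths of the written trial logs).
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(is.list(config), config$experiment %in% c(1L, 2L))
  valid <- if (config$experiment == 1L) .exp1_groups else .exp2_groups
  for (g in config$groups) {
    if (!g$name %in% valid) stop("invalid group name '", g$name, "'")
    if (is.null(g$n) || g$n <= 0) stop("group '", g$name, "' needs n > 0")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n_total <- sum(vapply(config$groups, `[[`, numeric(1L), "n"))
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max, n_total))
  files <- character(0)
  rows <- list()
  k <- 0L
  for (g in config$groups) {
    for (j in seq_len(g$n)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g$name, j)
      if (config$experiment == 1L) {
        skew <- g$skew %||% "right"
        p <- sim_participant(id, g$name,
                             alpha = g$alpha %||% config$alpha %||% 2,
                             sigma_sensed = g$sigma_sensed %||%
                               config$sigma_sensed %||%
                               c(dot = 1, cloud15 = 15, cloud30 = 30),
                             motor_sd = g$motor_sd %||% config$motor_sd %||% 2,
                             seed = seeds[k])
        rec <- simulate_exp1_participant(p, make_exp1_prior(skew),
                                         n_trials = config$n_trials %||% 2000L)
      } else {
        skew <- g$skew %||% if (j <= ceiling(g$n / 2)) "right" else "left"
        p <- sim_participant(id, g$name,
                             motor_sd = g$motor_sd %||% config$motor_sd %||% 9,
                             policy = g$policy %||% "min_power_error",
                             aim_mm = g$aim_mm,
                             seed = seeds[k])
        rec <- simulate_exp2_participant(p, make_exp2_prior(skew))
      }
      path <- file.path(out_dir, paste0(id, ".csv"))
      write_trial_log(rec, path)
      files <- c(files, path)
      rows[[k]] <- data.frame(participant_id = id, group = g$name,
                              skew = skew, seed = seeds[k],
                              motor_sd = p$motor_sd, alpha = p$alpha,
                              policy = p$policy,
                              file = basename(path),
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- list(package = "reachloss",
                   version = as.character(utils::packageVersion("reachloss")),
                   experiment = config$experiment,
                   master_seed = config$seed,
                   config_hash = .config_hash(config),
                   participants = do.call(rbind, rows))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(manifest = manifest, files = files))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
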