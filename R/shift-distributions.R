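# Discrete lateral-shift distributions and trial schedules.
#
# All positions are in mm along the lateral (x) axis, relative to the
# displayed target centre; positive = rightward.

#' Discrete lateral-shift distribution
#'
#' Constructs a discrete probability distribution over lateral cursor shifts.
#' The experiments perturb the cursor on every trial by a shift drawn from a
#' skewed discrete distribution whose mean and mode are separated, which is
#' what dissociates mean-seeking (error-based) from mode-seeking
#' (reinforcement-based) aiming policies.
#'
#' @param support numeric vector of shift values (mm), strictly increasing.
#' @param probs numeric vector of probabilities, same length as `support`,
#'   nonnegative, summing to 1 (within 1e-12; renormalized exactly).
#' @param label character tag, e.g. `"exp1_SR"`.
#' @param skew one of `"right"`, `"left"`, `"none"`.
#' @return An object of class `shift_distribution`: a list with elements
#'   `support`, `probs`, `label`, `skew`.
#' @examples
#' d <- shift_distribution(c(-14, 0, 14), c(0.6, 0.2, 0.2), "exp2_SR", "right")
#' distribution_stats(d)
#' @export
shift_distribution <- function(support, probs, label = "custom",
                               skew = c("none", "right", "left")) {
  skew <- match.arg(skew)
  support <- as.numeric(support)
  probs <- as.numeric(probs)
  if (length(support) != length(probs) || length(support) < 1L)
    stop("'support' and 'probs' must be non-empty and of equal length")
  if (any(!is.finite(support)) || any(diff(support) <= 0))
    stop("'support' must be finite and strictly increasing")
  if (any(probs < 0)) stop("'probs' must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12)
    stop("'probs' must sum to 1 (got ", format(sum(probs)), ")")
  probs <- probs / sum(probs)
  structure(list(support = support, probs = probs, label = label, skew = skew),
            class = "shift_distribution")
}

#' @export
print.shift_distribution <- function(x, ...) {
  cat("Lateral-shift distribution '", x$label, "' (skew: ", x$skew, ")\n",
      sep = "")
  print(data.frame(shift_mm = x$support, prob = round(x$probs, 6)),
        row.names = FALSE)
  s <- distribution_stats(x)
  cat(sprintf("mean = %.4g mm, median = %.4g mm, mode = %.4g mm\n",
              s$mean, s$median, s$mode))
  invisible(x)
}

#' Skewed lateral-shift prior used in the 2000-trial experiment
#'
#' Seven equally spaced shifts at 5 mm intervals. The modal shift sits at one
#' end of the range and occurs with relative frequency 9/21 (~42.9%); each of
#' the other six shifts occurs with frequency 2/21 (~9.5%). The right-skewed
#' variant spans 0 to 30 mm (mean 10, median 5, mode 0); the left-skewed
#' variant spans -10 to 20 mm (mean 10, median 15, mode 20). The probabilities
#' are stored as exact rationals so the printed moments are reproduced
#' exactly.
#'
#' @param skew `"right"` or `"left"`.
#' @return A [shift_distribution].
#' @examples
#' distribution_stats(make_exp1_prior("right")) # mean 10, median 5, mode 0
#' @export
make_exp1_prior <- function(skew = c("right", "left")) {
  skew <- match.arg(skew)
  if (skew == "right") {
    support <- seq(0, 30, by = 5)
    probs <- c(9, 2, 2, 2, 2, 2, 2) / 21
  } else {
    support <- seq(-10, 20, by = 5)
    probs <- c(2, 2, 2, 2, 2, 2, 9) / 21
  }
  shift_distribution(support, probs, paste0("exp1_S", toupper(substr(skew, 1, 1))),
                     skew)
}

#' Three-point lateral-shift distribution used in the 500-trial experiment
#'
#' Support at -14, 0 and +14 mm (the spacing matches the 14 mm target
#' diameter). The modal shift occurs on 60% of trials and each of the other
#' two on 20%. Right skew puts the mode at -14 mm (mean -5.6, median -14);
#' left skew mirrors it (mode +14 mm, mean +5.6).
#'
#' @inheritParams make_exp1_prior
#' @return A [shift_distribution].
#' @export
make_exp2_prior <- function(skew = c("right", "left")) {
  skew <- match.arg(skew)
  probs <- if (skew == "right") c(0.6, 0.2, 0.2) else c(0.2, 0.2, 0.6)
  shift_distribution(c(-14, 0, 14), probs,
                     paste0("exp2_S", toupper(substr(skew, 1, 1))), skew)
}

#' Summary statistics of a shift distribution
#'
#' @param d a [shift_distribution].
#' @return A list with `mean`, `median` (weighted median: smallest support
#'   value whose cumulative probability reaches 0.5), `mode` (support value of
#'   maximum probability) and `mode_tied` (TRUE when the maximal probability
#'   is shared and the smallest such value was returned).
#' @export
distribution_stats <- function(d) {
  stopifnot(inherits(d, "shift_distribution"))
  m <- sum(d$support * d$probs)
  med <- d$support[which(cumsum(d$probs) >= 0.5 - 1e-12)[1L]]
  pmax_ <- max(d$probs)
  tied <- sum(abs(d$probs - pmax_) < 1e-12) > 1L
  if (tied && grepl("^exp[12]_S[RL]$", d$label))
    stop("built-in distribution has a tied mode; this should not happen")
  if (tied)
    warning("tied modal probability; returning the smallest modal support value")
  mode_ <- d$support[which(abs(d$probs - pmax_) < 1e-12)[1L]]
  list(mean = m, median = med, mode = mode_, mode_tied = tied)
}

#' Cue labels and their presentation odds in the 2000-trial experiment
#'
#' Mid-reach error feedback was shown as a single dot, a medium (15 mm SD)
#' cloud, a large (30 mm SD) cloud, or withheld, in a 3:1:1:1 ratio.
#' @keywords internal
.exp1_cues <- c("dot", "cloud15", "cloud30", "none")
.exp1_cue_probs <- c(3, 1, 1, 1) / 6

#' Sample a trial schedule with replacement (2000-trial design)
#'
#' Shifts are drawn i.i.d. from `d` and cue conditions independently per trial
#' with dot : cloud15 : cloud30 : none odds of 3:1:1:1.
#'
#' @param d a [shift_distribution].
#' @param n_trials number of trials (default 2000).
#' @param seed integer seed; the schedule is reproducible for a fixed seed.
#' @return A data.frame of class `trial_schedule` with columns `trial`,
#'   `shift_mm`, `cue`.
#' @export
sample_schedule_exp1 <- function(d, n_trials = 2000L, seed = 1L) {
  stopifnot(inherits(d, "shift_distribution"), n_trials > 0)
  withr::with_seed(seed, {
    shifts <- sample(d$support, n_trials, replace = TRUE, prob = d$probs)
    cues <- sample(.exp1_cues, n_trials, replace = TRUE, prob = .exp1_cue_probs)
  })
  out <- data.frame(trial = seq_len(n_trials), shift_mm = shifts, cue = cues,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Sample a fixed-multiset trial schedule (500-trial design)
#'
#' The 500 shifts are a fixed multiset -- 300 copies of the modal shift and
#' 100 of each of the other two -- presented in a seeded uniform random order
#' ("sampling until depletion"). Feedback in this design occurs only at the
#' target, so every trial carries the cue `target_only`.
#'
#' @param d a three-point [shift_distribution] with probabilities 0.6/0.2/0.2.
#' @param seed integer seed.
#' @return A data.frame of class `trial_schedule` with columns `trial`,
#'   `shift_mm`, `cue`.
#' @export
sample_schedule_exp2 <- function(d, seed = 1L) {
  stopifnot(inherits(d, "shift_distribution"))
  counts <- round(d$probs * 500)
  if (length(d$support) != 3L || sum(counts) != 500L ||
      max(abs(counts - d$probs * 500)) > 1e-9)
    stop("'d' must be a three-point distribution with probabilities in ",
         "multiples of 1/500 (e.g. make_exp2_prior())")
  pool <- rep(d$support, counts)
  shifts <- withr::with_seed(seed, sample(pool))
  out <- data.frame(trial = seq_along(shifts), shift_mm = shifts,
                    cue = "target_only", stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  class(out) <- c("trial_schedule", "data.frame")
  out
}

#' Reflect values about a pivot
#'
#' Mirrors lateral positions about `pivot`: `v -> 2 * pivot - v`. Used to
#' "flip" data recorded under the left-skewed distribution about the position
#' where the two skewed distributions align (the common mean, 10 mm, in the
#' 2000-trial design; 0 mm in the 500-trial design), so both skews can be
#' pooled.
#'
#' @param values numeric vector (mm).
#' @param pivot numeric scalar (mm).
#' @return Numeric vector of reflected values; flipping twice is the identity.
#' @export
flip_values <- function(values, pivot) {
  stopifnot(is.numeric(values), is.numeric(pivot), length(pivot) == 1L)
  2 * pivot - values
}

#' Write / read a shift distribution as JSON
#'
#' @param d a [shift_distribution].
#' @param path file path.
#' @return `write_distribution` returns `path` invisibly; `read_distribution`
#'   returns a [shift_distribution].
#' @export
write_distribution <- function(d, path) {
  stopifnot(inherits(d, "shift_distribution"))
  jsonlite::write_json(
    list(label = d$label, support_mm = d$support, probs = d$probs,
         skew = d$skew),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("label", "support_mm", "probs", "skew"))
    if (is.null(x[[f]])) stop("distribution JSON missing field '", f, "'")
  shift_distribution(x$support_mm, x$probs, x$label, x$skew)
}
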