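# Cursor-position densities and optimal aim points for the target-feedback
# (500-trial) design.
#
# The cursor lands at hand position plus the scheduled lateral shift, and
# the hand lands at the aimed position plus Gaussian execution noise
# (SD sigma_mv). The cursor density is therefore the convolution of the
# Gaussian hand density with the discrete shift distribution: a Gaussian
# mixture. Two optimal aims are dissociated: the error-based aim that
# minimizes expected squared cursor error about the target (tracks the
# negated mixture mean, independent of sigma_mv), and the reinforcement-based
# aim that maximizes target hits (tracks the negated mixture mode, which
# moves with sigma_mv).

#' Uniform evaluation grid
#'
#' @param lo,hi bounds (mm), `lo < hi`.
#' @param step resolution (mm).
#' @return Object of class `mm_grid`: list with `lo`, `hi`, `step`, `x`.
#'   The default spans -80 to 80 mm at 0.02 mm, covering every built-in shift
#'   plus 5 SD of the largest movement-noise level considered.
#' @export
make_grid <- function(lo = -80, hi = 80, step = 0.02) {
  stopifnot(lo < hi, step > 0)
  x <- seq(lo, hi, by = step)
  if (length(x) < 3L) stop("grid must have at least 3 points")
  structure(list(lo = lo, hi = hi, step = step, x = x), class = "mm_grid")
}

#' Cursor-position density for a given aim
#'
#' Convolution of the Gaussian hand density (mean `x_aim`, SD `sigma_mv`)
#' with the discrete shift distribution, evaluated on a uniform grid and
#' normalized: a mixture with one Gaussian component per support shift.
#'
#' @param x_aim aimed hand position (mm).
#' @param sigma_mv movement variability (mm), positive.
#' @param d a [shift_distribution].
#' @param grid an [make_grid()] grid; must cover the mixture (an error is
#'   raised when 1e-3 or more of the probability mass falls outside it).
#' @return A [posterior_grid] on the grid points.
#' @export
cursor_density <- function(x_aim, sigma_mv, d, grid = make_grid()) {
  stopifnot(inherits(d, "shift_distribution"), inherits(grid, "mm_grid"),
            is.numeric(sigma_mv), sigma_mv > 0)
  x <- grid$x
  f <- numeric(length(x))
  for (k in seq_along(d$support))
    f <- f + d$probs[k] * stats::dnorm(x, x_aim + d$support[k], sigma_mv)
  covered <- sum(f) * grid$step
  if (1 - covered >= 1e-3)
    stop(sprintf("grid [%g, %g] clips %.2g of the cursor density; widen it",
                 grid$lo, grid$hi, 1 - covered))
  posterior_grid(x, f, step = grid$step)
}

# Mode of a gridded density: argmax with parabolic refinement through the
# top three points. A flat plateau of near-maximal values is resolved to the
# centre of its leftmost contiguous run.
.density_mode <- function(dens) {
  x <- dens$x
  m <- dens$mass
  top <- max(m)
  near <- which(m >= top * (1 - 1e-12))
  if (length(near) > 1L) {
    runs <- split(near, cumsum(c(1L, diff(near) != 1L)))
    first <- runs[[1L]]
    return(list(mode = mean(x[range(first)]), plateau = TRUE))
  }
  i <- near
  g <- length(x)
  if (i == 1L || i == g) return(list(mode = x[i], plateau = FALSE))
  e1 <- m[i - 1L]; e2 <- m[i]; e3 <- m[i + 1L]
  den <- e1 - 2 * e2 + e3
  off <- if (den < 0) 0.5 * (e1 - e3) / den * dens$step else 0
  off <- max(min(off, dens$step), -dens$step)
  list(mode = x[i] + off, plateau = FALSE)
}

#' Aim that minimizes expected squared cursor error
#'
#' The expected squared error of the cursor about the target is
#' `sigma_mv^2 + sum_i p_i (aim + s_i - target)^2`, minimized at
#' `aim = -(mean(d) - target)` regardless of movement variability. The
#' closed form is returned together with a numerical minimization of the
#' expected-loss integral over the gridded cursor density, as a consistency
#' diagnostic.
#'
#' @inheritParams cursor_density
#' @param target displayed target position (mm), default 0.
#' @return An `aim_solution` with `criterion = "min_power_error"`,
#'   `alpha = 2`, `aim_mm` (closed form) and `aim_numeric_mm` (grid-based
#'   numerical argmin).
#' @examples
#' aim_min_sq_error(make_exp2_prior("right"), sigma_mv = 10.6)$aim_mm # 5.6
#' @export
aim_min_sq_error <- function(d, sigma_mv, target = 0, grid = make_grid()) {
  stopifnot(inherits(d, "shift_distribution"), sigma_mv > 0)
  mu <- sum(d$support * d$probs)
  aim <- -(mu - target)
  aim_numeric <- if (sigma_mv >= 5 * grid$step) {
    el <- function(a) {
      dens <- cursor_density(a, sigma_mv, d, grid)
      sum(dens$mass * (dens$x - target)^2)
    }
    stats::optimize(el, c(aim - 10, aim + 10), tol = 1e-6)$minimum
  } else {
    # the gridded density cannot resolve noise this small; the closed form
    # is exact and noise-invariant
    aim
  }
  structure(list(aim_mm = aim, aim_numeric_mm = aim_numeric,
                 criterion = "min_power_error", alpha = 2,
                 objective = sigma_mv^2 + sum(d$probs * (aim + d$support - target)^2),
                 ambiguous = FALSE),
            class = "aim_solution")
}

#' Aim that maximizes target hits (mode alignment)
#'
#' Minimizing the 0-1 loss aligns the mode of the cursor density with the
#' target. The aim is found by minimizing the distance between the density
#' mode and the target over candidate aims: the mode of the aim-0 density is
#' located on the grid (argmax with parabolic refinement), the implied aim is
#' taken as a starting point, and a local scan over aims selects the
#' minimizer. When several aims tie (equal-height peaks), the smallest-|aim|
#' solution is returned and flagged.
#'
#' @inheritParams aim_min_sq_error
#' @return An `aim_solution` with `criterion = "max_hits_mode"`; `objective`
#'   is the residual |mode - target| at the optimum.
#' @examples
#' aim_max_hits_mode(make_exp2_prior("right"), sigma_mv = 10.6)$aim_mm
#' @export
aim_max_hits_mode <- function(d, sigma_mv, target = 0, grid = make_grid()) {
  stopifnot(inherits(d, "shift_distribution"), sigma_mv > 0)
  mode_dist <- function(a)
    abs(.density_mode(cursor_density(a, sigma_mv, d, grid))$mode - target)
  m0 <- .density_mode(cursor_density(0, sigma_mv, d, grid))
  start <- target - m0$mode
  aims <- seq(start - 0.5, start + 0.5, by = 0.01)
  vals <- vapply(aims, mode_dist, numeric(1L))
  best <- min(vals)
  cands <- aims[vals <= best + 1e-9]
  ambiguous <- m0$plateau || (max(cands) - min(cands)) > 0.05
  aim <- cands[which.min(abs(cands))]
  structure(list(aim_mm = aim, criterion = "max_hits_mode",
                 objective = best, ambiguous = ambiguous),
            class = "aim_solution")
}

#' Aim that maximizes the probability of hitting a finite target
#'
#' The task rewards any cursor landing within the target of diameter
#' `target_width`, so the operational reinforcement optimum maximizes
#' `P(|cursor - target| <= target_width / 2)`, available in closed form as a
#' sum of Gaussian-CDF differences over the mixture components. Maximized by
#' a coarse scan plus bounded scalar refinement. As `target_width -> 0` this
#' recovers the mode-alignment aim.
#'
#' @inheritParams aim_min_sq_error
#' @param target_width target diameter (mm), positive; default 14, the task's
#'   target size.
#' @return An `aim_solution` with `criterion = "max_hits_width"`; `objective`
#'   is the hit probability at the optimum.
#' @examples
#' aim_max_hits_width(make_exp2_prior("right"), sigma_mv = 10.6)$aim_mm
#' @export
aim_max_hits_width <- function(d, sigma_mv, target = 0, target_width = 14) {
  stopifnot(inherits(d, "shift_distribution"), sigma_mv > 0, target_width > 0)
  w2 <- target_width / 2
  hitp <- function(a) {
    m <- a + d$support - target
    sum(d$probs * (stats::pnorm((w2 - m) / sigma_mv) -
                   stats::pnorm((-w2 - m) / sigma_mv)))
  }
  lo <- target - max(d$support) - 3 * sigma_mv
  hi <- target - min(d$support) + 3 * sigma_mv
  scan <- seq(lo, hi, by = 0.05)
  vals <- vapply(scan, hitp, numeric(1L))
  a0 <- scan[which.max(vals)]
  o <- stats::optimize(hitp, c(a0 - 0.05, a0 + 0.05), maximum = TRUE,
                       tol = 1e-8)
  structure(list(aim_mm = o$maximum, criterion = "max_hits_width",
                 target_width = target_width, objective = o$objective,
                 ambiguous = FALSE),
            class = "aim_solution")
}
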