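# Posterior over lateral shifts and optimal compensation under a power loss.
#
# The observer combines a learned prior over lateral shifts with a Gaussian
# likelihood for the sensed cursor centroid (SD set by the visual cue:
# single dot, medium cloud, large cloud, or withheld = infinite). The actor
# then compensates by the negated minimizer of the expected power loss
# |shift - x|^alpha over the posterior: alpha = 2 tracks the posterior mean,
# alpha = 1 the posterior median, alpha -> 0 the posterior mode.

#' Probability mass over lateral-shift values
#'
#' Lightweight container for a normalized probability mass on an ordered set
#' of lateral positions: either the discrete atoms of a shift prior or a
#' uniform mm grid (for kernel-smoothed priors and cursor densities).
#'
#' @param x ordered numeric positions (mm).
#' @param mass nonnegative weights; renormalized to sum to 1.
#' @param step grid spacing in mm, or `NA` for atomic (non-uniform) support.
#' @return An object of class `posterior_grid` with elements `x`, `mass`,
#'   `step`.
#' @export
posterior_grid <- function(x, mass, step = NA_real_) {
  stopifnot(is.numeric(x), is.numeric(mass), length(x) == length(mass),
            length(x) >= 1L, all(diff(x) > 0))
  if (any(mass < 0) || !all(is.finite(mass)))
    stop("'mass' must be finite and nonnegative")
  tot <- sum(mass)
  if (tot <= 0) stop("'mass' sums to zero")
  structure(list(x = x, mass = mass / tot, step = step),
            class = "posterior_grid")
}

#' @export
print.posterior_grid <- function(x, ...) {
  cat("Probability mass on", length(x$x), "points in [",
      min(x$x), ",", max(x$x), "] mm",
      if (is.na(x$step)) "(atomic support)\n" else
        sprintf("(grid step %g mm)\n", x$step))
  cat(sprintf("mean = %.4g mm\n", sum(x$x * x$mass)))
  invisible(x)
}

#' Gaussian likelihood of a sensed cursor centroid
#'
#' Density of the sensed centroid given a candidate true shift, assumed
#' normal with cue-dependent standard deviation. Evaluated as a function of
#' the candidate shift (`at`) for a fixed sensed value, which is how it
#' enters the posterior.
#'
#' @param x_sensed sensed centroid (mm).
#' @param sigma_sensed sensory SD (mm); must be finite and positive here.
#'   A zero SD means a delta-function likelihood and is handled by
#'   [posterior()] directly; an infinite SD means an uninformative likelihood.
#' @param at numeric vector of candidate shift values (mm).
#' @return Density values at `at`.
#' @export
likelihood <- function(x_sensed, sigma_sensed, at) {
  if (!is.finite(sigma_sensed) || sigma_sensed < 0)
    stop("'sigma_sensed' must be finite and nonnegative")
  if (sigma_sensed == 0)
    stop("'sigma_sensed' = 0 is a delta-function likelihood; ",
         "use posterior(), which places all mass on the nearest atom")
  stats::dnorm(at, mean = x_sensed, sd = sigma_sensed)
}

#' Posterior over lateral shifts
#'
#' Point-wise product of the prior mass and the Gaussian likelihood of the
#' sensed centroid, renormalized. With `sigma_sensed = Inf` the likelihood is
#' uninformative and the posterior equals the prior; with `sigma_sensed = 0`
#' all mass falls on the support atom nearest the sensed value.
#'
#' By default the posterior lives on the prior's discrete atoms. With
#' `method = "smoothed"` the prior is first convolved with a Gaussian kernel
#' of SD `bandwidth` and the posterior is computed on a uniform grid, which
#' accommodates sensed values off the discrete support.
#'
#' @param prior a [shift_distribution].
#' @param x_sensed sensed centroid (mm).
#' @param sigma_sensed sensory SD (mm); may be `Inf` or 0.
#' @param method `"discrete"` (default) or `"smoothed"`.
#' @param bandwidth kernel SD (mm) for the smoothed prior.
#' @param grid_step grid resolution (mm) for the smoothed prior.
#' @return A [posterior_grid].
#' @examples
#' post <- posterior(make_exp1_prior("right"), x_sensed = 22.5,
#'                   sigma_sensed = 15)
#' optimal_compensation(post, alpha = 2)
#' @export
posterior <- function(prior, x_sensed, sigma_sensed,
                      method = c("discrete", "smoothed"),
                      bandwidth = 2, grid_step = 0.1) {
  stopifnot(inherits(prior, "shift_distribution"))
  method <- match.arg(method)
  if (is.na(sigma_sensed) || sigma_sensed < 0)
    stop("'sigma_sensed' must be nonnegative (Inf allowed)")
  if (method == "discrete") {
    x <- prior$support
    lp <- log(prior$probs)
  } else {
    stopifnot(bandwidth > 0, grid_step > 0)
    x <- seq(min(prior$support) - 4 * bandwidth,
             max(prior$support) + 4 * bandwidth, by = grid_step)
    dens <- rowSums(vapply(seq_along(prior$support), function(k)
      prior$probs[k] * stats::dnorm(x, prior$support[k], bandwidth),
      numeric(length(x))))
    lp <- log(dens)
  }
  if (is.infinite(sigma_sensed)) {
    lw <- lp
  } else if (sigma_sensed == 0) {
    lw <- rep(-Inf, length(x))
    lw[which.min(abs(x - x_sensed))] <- 0
  } else {
    lw <- lp + stats::dnorm(x, x_sensed, sigma_sensed, log = TRUE)
  }
  if (all(!is.finite(lw)))
    stop("posterior underflow: likelihood has no overlap with the prior ",
         "support (check x_sensed / sigma_sensed)")
  w <- exp(lw - max(lw[is.finite(lw)]))
  w[!is.finite(w)] <- 0
  posterior_grid(x, w, step = if (method == "smoothed") grid_step else NA_real_)
}

#' Power loss
#'
#' `|x_shift - x_comp|^alpha`. The exponent controls how strongly large
#' errors are penalized relative to small ones: 1 = absolute error,
#' 2 = squared error.
#'
#' @param x_shift,x_comp numeric (mm); recycled.
#' @param alpha positive exponent.
#' @return Loss values.
#' @export
power_loss <- function(x_shift, x_comp, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  abs(x_shift - x_comp)^alpha
}

#' Expected power loss under a posterior
#'
#' Discrete realization of the expected-loss integral:
#' `sum_i mass_i * |x_i - x_comp|^alpha`.
#'
#' @param x_comp numeric vector of candidate compensation magnitudes (mm).
#' @param alpha positive exponent.
#' @param post a [posterior_grid].
#' @return Expected loss at each `x_comp`.
#' @export
expected_loss <- function(x_comp, alpha, post) {
  stopifnot(inherits(post, "posterior_grid"), alpha > 0)
  as.numeric(abs(outer(x_comp, post$x, "-"))^alpha %*% post$mass)
}

#' Optimal compensation under a power loss
#'
#' Returns the negated minimizer of the expected power loss over the
#' posterior: the compensation counteracts the estimated shift, so it is
#' equal and opposite to the loss-minimizing point estimate. For `alpha = 2`
#' this is minus the posterior mean; for `alpha = 1` minus the posterior
#' median; as `alpha -> 0` it approaches minus the posterior mode.
#'
#' The minimizer is located by a dense scan over the posterior's support
#' range (the support atoms are always included as candidates) followed, for
#' smooth losses (`alpha > 1`), by bounded scalar refinement. When the
#' minimum is attained on a plateau (possible for `alpha <= 1`), the
#' minimizer closest to the posterior mean is returned and the solution is
#' flagged ambiguous.
#'
#' @inheritParams expected_loss
#' @param post a [posterior_grid].
#' @param grid_step scan resolution (mm).
#' @return An object of class `aim_solution`: list with `aim_mm` (the
#'   compensation, mm), `criterion = "min_power_error"`, `alpha`, `objective`
#'   (expected loss at the optimum) and `ambiguous`.
#' @examples
#' pri <- make_exp1_prior("right")
#' post <- posterior(pri, x_sensed = 0, sigma_sensed = Inf)
#' optimal_compensation(post, alpha = 2)$aim_mm # -10: minus the prior mean
#' optimal_compensation(post, alpha = 1)$aim_mm # -5: minus the prior median
#' @export
optimal_compensation <- function(post, alpha, grid_step = 0.005) {
  stopifnot(inherits(post, "posterior_grid"), alpha > 0, grid_step > 0)
  rng <- range(post$x)
  grid <- if (diff(rng) == 0) rng[1] else
    unique(sort(c(seq(rng[1], rng[2], by = grid_step), post$x)))
  el <- expected_loss(grid, alpha, post)
  emin <- min(el)
  tol <- max(1e-10, 1e-10 * abs(emin))
  cands <- grid[el - emin <= tol]
  ambiguous <- (max(cands) - min(cands)) > 2 * grid_step
  mu <- sum(post$x * post$mass)
  xstar <- cands[which.min(abs(cands - mu))]
  obj <- emin
  if (alpha > 1 && diff(rng) > 0) {
    lo <- max(rng[1], xstar - grid_step)
    hi <- min(rng[2], xstar + grid_step)
    o <- stats::optimize(function(z) expected_loss(z, alpha, post),
                         c(lo, hi), tol = 1e-9)
    if (o$objective <= obj) {
      xstar <- o$minimum
      obj <- o$objective
    }
  }
  structure(list(aim_mm = -xstar, criterion = "min_power_error",
                 alpha = alpha, objective = obj, ambiguous = ambiguous),
            class = "aim_solution")
}

#' @export
print.aim_solution <- function(x, ...) {
  cat(sprintf("Optimal aim: %.3f mm  [criterion: %s%s, objective %.6g%s]\n",
              x$aim_mm, x$criterion,
              if (!is.null(x$alpha)) sprintf(", alpha = %g", x$alpha) else
                if (!is.null(x$target_width))
                  sprintf(", target width = %g mm", x$target_width) else "",
              x$objective,
              if (isTRUE(x$ambiguous)) ", AMBIGUOUS plateau" else ""))
  invisible(x)
}

# Vectorized optimal-compensation surface over all (shift, cue) cells.
#
# Shares one loss matrix across cells: with sensed centroid set equal to each
# support shift, the posterior for cell (i, j) is a row of a K x K matrix per
# cue, and the expected loss for every candidate compensation on a dense grid
# is a single matrix product. The per-cell minimizer is refined by a
# parabolic fit through the three bracketing grid points (clamped to one grid
# step; skipped at range boundaries).
.posterior_rows <- function(prior, sigmas) {
  s <- prior$support
  K <- length(s)
  rows <- lapply(sigmas, function(sig) {
    if (is.infinite(sig)) {
      matrix(prior$probs, K, K, byrow = TRUE)
    } else if (sig == 0) {
      diag(K)
    } else {
      W <- stats::dnorm(outer(s, s, "-"), sd = sig) *
        matrix(prior$probs, K, K, byrow = TRUE)
      W / rowSums(W)
    }
  })
  do.call(rbind, rows)                         # (K * ncue) x K, row = cell
}

# Minimizer sweep shared by .comp_surface and the fit objective: returns the
# negated expected-loss argmin for every cell (cue blocks in the order of
# `sigmas`, shifts within each block).
.comp_cells <- function(prior, alpha, sigmas, grid_step = 0.02) {
  s <- prior$support
  P <- .posterior_rows(prior, sigmas)
  x <- seq(min(s), max(s), by = grid_step)
  if (x[length(x)] < max(s)) x <- c(x, max(s))
  L <- abs(outer(x, s, "-"))^alpha             # g x K
  EL <- L %*% t(P)                             # g x ncell
  idx <- max.col(-t(EL), ties.method = "first")
  g <- length(x)
  xstar <- x[idx]
  # parabolic refinement assumes a smooth minimum; for alpha <= 1 the
  # expected loss is kinked at the atoms (where the minimizer sits), so the
  # grid argmin is kept as-is there
  interior <- alpha > 1 & idx > 1L & idx < g
  if (any(interior)) {
    ii <- idx[interior]
    cols <- which(interior)
    e1 <- EL[cbind(ii - 1L, cols)]
    e2 <- EL[cbind(ii, cols)]
    e3 <- EL[cbind(ii + 1L, cols)]
    den <- e1 - 2 * e2 + e3
    shift <- ifelse(den > 0, 0.5 * (e1 - e3) / den * grid_step, 0)
    shift <- pmax(pmin(shift, grid_step), -grid_step)
    xstar[interior] <- x[ii] + shift
  }
  -xstar
}

.comp_surface <- function(prior, alpha, sigmas, grid_step = 0.02) {
  cues <- names(sigmas)
  if (is.null(cues) || any(!nzchar(cues)))
    stop("'sigmas' must be a named vector of per-cue sensory SDs")
  K <- length(prior$support)
  data.frame(shift_mm = rep(prior$support, times = length(cues)),
             cue = rep(cues, each = K),
             comp_opt_mm = .comp_cells(prior, alpha, sigmas, grid_step),
             alpha = alpha,
             sigma_mm = rep(unname(sigmas), each = K),
             stringsAsFactors = FALSE)
}

#' Optimal-compensation surface over all shifts and cues
#'
#' For every support shift of the prior (with the sensed centroid set equal
#' to the shift) and every cue condition, computes the power-loss optimal
#' compensation. Rows for the withheld-feedback cue (`sigma = Inf`) are
#' constant across shifts because the posterior collapses to the prior.
#'
#' @param prior a [shift_distribution].
#' @param alpha positive loss exponent.
#' @param sigmas named numeric vector of sensory SDs (mm) for the cues
#'   `dot`, `cloud15`, `cloud30`; a `none = Inf` entry is appended if absent.
#' @param grid_step minimizer scan resolution (mm).
#' @return A tidy data.frame with columns `shift_mm`, `cue`, `comp_opt_mm`,
#'   `alpha`, `sigma_mm`.
#' @examples
#' prediction_surface(make_exp1_prior("right"), alpha = 2,
#'                    sigmas = c(dot = 1, cloud15 = 15, cloud30 = 30))
#' @export
prediction_surface <- function(prior, alpha, sigmas, grid_step = 0.02) {
  stopifnot(inherits(prior, "shift_distribution"), alpha > 0)
  need <- c("dot", "cloud15", "cloud30")
  if (!all(need %in% names(sigmas)))
    stop("'sigmas' must name at least: ", paste(need, collapse = ", "))
  if (!("none" %in% names(sigmas))) sigmas <- c(sigmas, none = Inf)
  .comp_surface(prior, alpha, sigmas, grid_step)
}
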