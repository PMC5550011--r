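# Condition averaging and the four-parameter observer fit.
#
# The fit recovers the loss exponent alpha and the three sensory SDs
# (single dot, medium cloud, large cloud) from a participant's 28-cell table
# of mean compensation per (shift, cue) condition. The withheld-feedback
# column (sigma = Inf) predicts a shift-independent compensation that
# depends only on alpha, which anchors the exponent. The objective is the
# weighted least absolute error between observed and model-optimal
# compensation, minimized by multi-start Nelder-Mead on log-transformed
# parameters.

#' Condition-average a trial log
#'
#' Mean compensation (final hand x) per (shift, cue) cell over the last
#' `last_n` trials, so only post-learning behavior enters the fit.
#'
#' @param records trial-record data.frame (one participant) with columns
#'   `trial`, `cue`, `shift_mm`, `hand_x_mm`.
#' @param last_n number of final trials to average (default 1000).
#' @return A data.frame of class `condition_table` with columns `shift_mm`,
#'   `cue`, `comp_mean_mm`, `n_trials`, sorted by cue then shift. For the
#'   built-in 2000-trial design this is 7 shifts x 4 cues = 28 rows; an
#'   error lists any empty cell.
#' @export
condition_averages <- function(records, last_n = 1000L) {
  stopifnot(is.data.frame(records),
            all(c("trial", "cue", "shift_mm", "hand_x_mm") %in% names(records)))
  if (last_n > nrow(records))
    stop("'last_n' exceeds the number of trials (", nrow(records), ")")
  shifts <- sort(unique(records$shift_mm))
  cues <- intersect(c(.exp1_cues, "target_only"), unique(records$cue))
  win <- records[order(records$trial), ][seq(nrow(records) - last_n + 1L,
                                             nrow(records)), ]
  cells <- expand.grid(shift_mm = shifts, cue = cues,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(win$shift_mm, win$cue)
  cellkey <- paste(cells$shift_mm, cells$cue)
  cells$comp_mean_mm <- vapply(cellkey, function(k)
    mean(win$hand_x_mm[key == k]), numeric(1L), USE.NAMES = FALSE)
  cells$n_trials <- vapply(cellkey, function(k) sum(key == k), integer(1L),
                           USE.NAMES = FALSE)
  empty <- cells$n_trials == 0L
  if (any(empty))
    stop("empty condition cells in the analysis window: ",
         paste(sprintf("(shift %g, %s)", cells$shift_mm[empty],
                       cells$cue[empty]), collapse = ", "))
  cells <- cells[order(cells$cue, cells$shift_mm), ]
  rownames(cells) <- NULL
  class(cells) <- c("condition_table", "data.frame")
  cells
}

#' Fitting weights per condition cell
#'
#' Within each cue the weight of shift i is the prior probability of that
#' shift, so the four cue conditions contribute equally to the objective
#' while shifts within a cue are emphasized in proportion to how often they
#' were experienced.
#'
#' @param prior a [shift_distribution].
#' @param cues character vector of cue labels (default the four cue
#'   conditions of the 2000-trial design).
#' @return data.frame with columns `shift_mm`, `cue`, `weight`; weights sum
#'   to 1 within each cue.
#' @export
fit_weights <- function(prior, cues = .exp1_cues) {
  stopifnot(inherits(prior, "shift_distribution"))
  out <- expand.grid(shift_mm = prior$support, cue = cues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$weight <- rep(prior$probs, times = length(cues))
  out[order(out$cue, out$shift_mm), c("shift_mm", "cue", "weight")]
}

#' Fit the four-parameter Bayesian observer model
#'
#' Minimizes the weighted least-absolute-error between the condition-averaged
#' compensation and the model's optimal compensation over the loss exponent
#' `alpha` and the three sensory SDs (dot, cloud15, cloud30); the
#' withheld-feedback SD is fixed at infinity. Nelder-Mead runs from
#' `restarts` start points (alpha in 1, 1.5, 2, 2.5 crossed with two sigma
#' scalings) on log-transformed parameters, keeping the best optimum.
#'
#' @param table a [condition_averages()] table covering the 4 cue conditions.
#' @param prior the [shift_distribution] the participant experienced.
#' @param restarts number of start points (default 8; capped at the 8
#'   built-in starts).
#' @param grid_step compensation-scan resolution (mm) inside the objective.
#' @param maxit,reltol Nelder-Mead control per start; a cyclic coordinate
#'   polish follows the best start.
#' @return An object of class `fit_result`: `alpha_opt`, `sigma_opt` (named
#'   dot/cloud15/cloud30, mm), `objective`, `n_restarts`, `converged`,
#'   `start_objectives`.
#' @export
fit_bayes_model <- function(table, prior, restarts = 8L, grid_step = 0.02,
                            maxit = 500L, reltol = 1e-9) {
  stopifnot(inherits(table, "condition_table"),
            inherits(prior, "shift_distribution"))
  if (!all(.exp1_cues %in% table$cue))
    stop("table must contain the cues: ", paste(.exp1_cues, collapse = ", "))
  tab <- table[order(table$cue, table$shift_mm), ]
  w <- fit_weights(prior, cues = .exp1_cues)
  wtab <- merge(tab, w, by = c("shift_mm", "cue"), sort = FALSE)
  wtab <- wtab[order(wtab$cue, wtab$shift_mm), ]
  sig_names <- c("dot", "cloud15", "cloud30")

  # cue blocks of .comp_cells must follow wtab's (alphabetical) cue order
  cue_order <- sort(c(sig_names, "none"))
  objective <- function(par) {
    alpha <- exp(par[1L])
    sig <- exp(par[2:4])
    if (alpha > 20 || any(sig > 1e4)) return(1e6)
    sigmas <- c(stats::setNames(sig, sig_names), none = Inf)[cue_order]
    comp <- .comp_cells(prior, alpha, sigmas, grid_step = grid_step)
    sum(wtab$weight * abs(wtab$comp_mean_mm - comp))
  }

  starts <- expand.grid(alpha = c(1, 1.5, 2, 2.5), scale = c(0.5, 1.5))
  starts <- starts[seq_len(min(restarts, nrow(starts))), , drop = FALSE]
  base_sig <- c(5, 15, 30)
  best <- NULL
  start_obj <- numeric(0)
  for (r in seq_len(nrow(starts))) {
    p0 <- c(log(starts$alpha[r]), log(base_sig * starts$scale[r]))
    fit <- tryCatch(
      stats::optim(p0, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    start_obj <- c(start_obj, fit$value)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimizer failed on all ", nrow(starts), " starts")
  # Cyclic coordinate polish: the objective can be nearly flat in a sensory
  # SD that is small relative to the 5 mm atom spacing (the posterior is
  # close to a delta there), which simplex steps resolve poorly. Bounded 1-D
  # refinement of each log-parameter in turn recovers such parameters to
  # high precision because the objective is deterministic.
  par <- best$par
  val <- best$value
  for (sweep in 1:3) {
    for (k in 1:4) {
      o <- stats::optimize(function(z) {
        p <- par; p[k] <- z; objective(p)
      }, c(par[k] - 0.7, par[k] + 0.7), tol = 1e-10)
      if (o$objective <= val) {
        par[k] <- o$minimum
        val <- o$objective
      }
    }
  }
  structure(list(alpha_opt = exp(par[1L]),
                 sigma_opt = stats::setNames(exp(par[2:4]), sig_names),
                 objective = val,
                 n_restarts = nrow(starts),
                 converged = best$convergence == 0L || val < best$value,
                 start_objectives = start_obj),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Observer fit: alpha = %.3f; sigma (dot, cloud15, cloud30) = (%.2f, %.2f, %.2f) mm\n",
    x$alpha_opt, x$sigma_opt[1L], x$sigma_opt[2L], x$sigma_opt[3L]))
  cat(sprintf("weighted |error| objective = %.5g (%d starts, converged: %s)\n",
              x$objective, x$n_restarts, x$converged))
  invisible(x)
}

#' Model-predicted condition table from a fit
#'
#' @param fit a [fit_bayes_model()] result.
#' @param prior the [shift_distribution] used in the fit.
#' @param grid_step compensation-scan resolution (mm).
#' @return data.frame with columns `shift_mm`, `cue`, `comp_pred_mm`, sorted
#'   like a [condition_averages()] table.
#' @export
predict_from_fit <- function(fit, prior, grid_step = 0.02) {
  stopifnot(inherits(fit, "fit_result"), inherits(prior, "shift_distribution"))
  surf <- .comp_surface(prior, fit$alpha_opt,
                        c(fit$sigma_opt, none = Inf), grid_step = grid_step)
  surf <- surf[order(surf$cue, surf$shift_mm), ]
  out <- data.frame(shift_mm = surf$shift_mm, cue = surf$cue,
                    comp_pred_mm = surf$comp_opt_mm,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Variance explained by model predictions
#'
#' Fraction of variance of the 28 cell means captured by the predicted
#' surface, as a percentage.
#'
#' @param table a [condition_averages()] table.
#' @param pred a [predict_from_fit()] table for the same cells.
#' @return Percentage in `[-Inf, 100]`.
#' @export
variance_explained <- function(table, pred) {
  m <- merge(table, pred, by = c("shift_mm", "cue"))
  ss_res <- sum((m$comp_mean_mm - m$comp_pred_mm)^2)
  ss_tot <- sum((m$comp_mean_mm - mean(m$comp_mean_mm))^2)
  if (ss_tot == 0) stop("zero variance across condition cells")
  100 * (1 - ss_res / ss_tot)
}

#' Per-cue linear fit of compensation versus shift
#'
#' Ordinary least squares of the 7 cell means on shift magnitude, one line
#' per cue. Full compensation gives slope -1; complete reliance on the prior
#' gives slope 0 with the prior-optimal intercept.
#'
#' @inheritParams condition_averages
#' @return data.frame with columns `cue`, `slope`, `intercept_mm`,
#'   `r_squared`.
#' @export
linear_condition_fit <- function(records, last_n = 1000L) {
  tab <- condition_averages(records, last_n = last_n)
  out <- do.call(rbind, lapply(split(tab, tab$cue), function(cell) {
    if (length(unique(cell$shift_mm)) < 2L)
      stop("fewer than 2 distinct shifts for cue '", cell$cue[1L], "'")
    fit <- stats::lm(comp_mean_mm ~ shift_mm, data = cell)
    ss_tot <- sum((cell$comp_mean_mm - mean(cell$comp_mean_mm))^2)
    data.frame(cue = cell$cue[1L],
               slope = unname(stats::coef(fit)[2L]),
               intercept_mm = unname(stats::coef(fit)[1L]),
               r_squared = if (ss_tot > 0)
                 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
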