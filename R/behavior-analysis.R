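# Descriptive analyses of trial logs: binning, asymptote means, movement
# variability and the variability-compensation correlation.

#' Bin a trial series
#'
#' Bin 0 averages the first `head` trials (behavior immediately after
#' perturbation onset); bins 1..K each average `bin_size` consecutive trials
#' starting from trial 1. Note that bin 0 therefore overlaps bin 1 -- trials
#' 1 to `head` also belong to bin 1 -- mirroring the figure convention of
#' plotting early behavior alongside the full binned series. A trailing
#' partial bin is dropped with a warning.
#'
#' @param records trial-record data.frame with columns `trial`, `hand_x_mm`.
#' @param bin_size trials per bin (default 10).
#' @param head trials in bin 0 (default 3).
#' @return data.frame with columns `bin`, `n_trials`, `mean_mm`, `sd_mm`.
#' @export
bin_trials <- function(records, bin_size = 10L, head = 3L) {
  stopifnot(is.data.frame(records),
            all(c("trial", "hand_x_mm") %in% names(records)),
            bin_size >= 1L, head >= 1L)
  x <- records$hand_x_mm[order(records$trial)]
  n <- length(x)
  if (n < head) stop("fewer than ", head, " trials")
  K <- n %/% bin_size
  if (n %% bin_size != 0L)
    warning("dropping trailing partial bin of ", n %% bin_size, " trials")
  segs <- c(list(x[seq_len(head)]),
            lapply(seq_len(K), function(k)
              x[seq((k - 1L) * bin_size + 1L, k * bin_size)]))
  data.frame(bin = 0:K,
             n_trials = vapply(segs, length, integer(1L)),
             mean_mm = vapply(segs, mean, numeric(1L)),
             sd_mm = vapply(segs, stats::sd, numeric(1L)))
}

#' Asymptotic mean compensation
#'
#' Mean final hand position over the last `last_n` trials, the window in
#' which behavior has stabilized.
#'
#' @inheritParams bin_trials
#' @param last_n number of final trials (default 400 of the 500).
#' @return Mean compensation (mm).
#' @export
asymptote_mean <- function(records, last_n = 400L) {
  x <- records$hand_x_mm[order(records$trial)]
  if (last_n > length(x)) stop("'last_n' exceeds the number of trials")
  mean(x[seq(length(x) - last_n + 1L, length(x))])
}

#' Movement variability
#'
#' Sample standard deviation (n - 1 denominator) of final hand position over
#' the asymptotic window.
#'
#' @inheritParams asymptote_mean
#' @return SD of hand position (mm).
#' @export
movement_variability <- function(records, last_n = 400L) {
  stopifnot(last_n >= 2L)
  x <- records$hand_x_mm[order(records$trial)]
  if (last_n > length(x)) stop("'last_n' exceeds the number of trials")
  stats::sd(x[seq(length(x) - last_n + 1L, length(x))])
}

#' Coefficient of determination between variability and compensation
#'
#' Squared Pearson correlation across participants between movement
#' variability and asymptotic compensation.
#'
#' @param variability numeric vector, one value per participant (mm).
#' @param compensation numeric vector, same length (mm).
#' @return R-squared in `[0, 1]`.
#' @export
variability_compensation_r2 <- function(variability, compensation) {
  stopifnot(length(variability) == length(compensation),
            length(variability) >= 3L)
  if (stats::sd(variability) == 0 || stats::sd(compensation) == 0)
    stop("zero variance in one of the variables")
  stats::cor(variability, compensation)^2
}
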