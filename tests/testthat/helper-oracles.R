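# Shared oracles, kept independent of the implementation paths they check.

# trapezoidal quadrature
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# direct weighted moments over discrete atoms
oracle_mean <- function(support, probs) sum(support * probs)
oracle_median <- function(support, probs)
  support[which(cumsum(probs) >= 0.5 - 1e-12)[1L]]

# a random discrete shift distribution for property loops
random_dist <- function(k = sample(3:9, 1L)) {
  support <- sort(stats::runif(k, -30, 30))
  while (any(diff(support) < 0.5)) support <- sort(stats::runif(k, -30, 30))
  probs <- stats::rgamma(k, 1) + 0.05
  shift_distribution(support, probs / sum(probs))
}

# dense-grid argmin of the expected power loss (brute force)
oracle_argmin_loss <- function(support, probs, alpha, step = 0.01) {
  x <- seq(min(support), max(support), by = step)
  el <- vapply(x, function(z) sum(probs * abs(support - z)^alpha), numeric(1L))
  x[which.min(el)]
}
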