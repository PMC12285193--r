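#' Negative binomial log probability, mean-dispersion parameterization
#'
#' Log probability mass of the negative binomial with mean \code{mean} and
#' inverse-dispersion \code{dispersion} (theta), the convention common to
#' single-cell count models: \code{variance = mean + mean^2 / dispersion}.
#' As \code{dispersion} grows the distribution approaches Poisson(mean).
#'
#' @param x non-negative integer count(s).
#' @param mean positive mean(s).
#' @param dispersion positive dispersion(s) theta.
#' @return Log probability mass, vectorized over arguments.
#' @export
nb_log_prob <- function(x, mean, dispersion) {
  if (any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    stop("x must be non-negative integers")
  }
  stopifnot(all(mean > 0), all(dispersion > 0))
  stats::dnbinom(round(x), size = dispersion, mu = mean, log = TRUE)
}

# Gradient of sum(nb_log_prob) with respect to the mean and to log(theta).
# Used by the ELBO backward pass. All arguments may be matrices (cells x genes)
# with theta a length-G vector recycled across rows.
nb_grad <- function(x, mean, theta_row) {
  dmean <- x / mean - sweep(x, 2, theta_row, "+") / sweep(mean, 2, theta_row, "+")
  tm <- sweep(mean, 2, theta_row, "+")
  th <- matrix(theta_row, nrow(x), ncol(x), byrow = TRUE)
  dtheta <- digamma(x + th) - digamma(th) + log(th) + 1 - log(tm) - (th + x) / tm
  list(dmean = dmean, dlog_theta = colSums(dtheta * th))
}
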