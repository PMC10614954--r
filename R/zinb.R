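## Core likelihood pieces of the count model. The negative binomial is
## parameterized by its mean m and dispersion r (variance m + m^2/r); the
## zero-inflated mixture puts mass pi = sigmoid(dropout_logit) on an exact
## zero. Written via lgamma in log space so the same expressions drive the
## analytic gradients used in training.

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[a == -Inf & b == -Inf] <- -Inf
  out
}

#' Zero-inflated negative binomial log-likelihood
#'
#' log of pi * [x = 0] + (1 - pi) * NB(x; mean, size), with
#' pi = sigmoid(dropout_logit) and NB the negative binomial with mean
#' \code{mean} and dispersion \code{size} (variance mean + mean^2/size).
#' Vectorized with recycling; the zero branch uses a stable log-sum-exp.
#'
#' @param x non-negative integer counts.
#' @param mean NB mean, >= 0 (for a depth-factored model this is depth
#'   times the per-gene rate).
#' @param size NB dispersion r, > 0.
#' @param dropout_logit real dropout logit (may be +/-Inf).
#' @return numeric log-likelihoods, same length as the recycled inputs.
#' @export
zinbLogLik <- function(x, mean, size, dropout_logit) {
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (any(size <= 0)) stop("size (dispersion) must be > 0")
  if (any(mean < 0)) stop("mean must be >= 0")
  n <- max(length(x), length(mean), length(size), length(dropout_logit))
  x <- rep_len(x, n); m <- rep_len(mean, n)
  r <- rep_len(size, n); lg <- rep_len(dropout_logit, n)
  log_pi <- stats::plogis(lg, log.p = TRUE)
  log_1mpi <- stats::plogis(-lg, log.p = TRUE)
  # NB log-pmf; x * log(m) needs care at m = 0
  lratio <- log(r) - log(r + m)
  lognb <- lgamma(x + r) - lgamma(r) - lgamma(x + 1) +
    r * lratio + x * (log(m) - log(r + m))
  lognb[x == 0] <- (r * lratio)[x == 0]
  lognb[m == 0 & x > 0] <- -Inf
  out <- log_1mpi + lognb
  z <- x == 0
  out[z] <- .logsumexp2(log_pi[z], (log_1mpi + lognb)[z])
  out
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form 0.5 * sum(mu^2 + exp(logvar) - logvar - 1); non-negative,
#' zero exactly when mu = 0 and logvar = 0.
#'
#' @param mu posterior mean vector.
#' @param logvar posterior log-variance vector (same length).
#' @return numeric(1).
#' @export
klDiagGaussian <- function(mu, logvar) {
  if (length(mu) != length(logvar)) stop("length mismatch")
  0.5 * sum(mu^2 + exp(logvar) - logvar - 1)
}
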