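#' Zero-inflated negative binomial probability mass
#'
#' P(X = x) = pi * [x == 0] + (1 - pi) * NB(x; mu, theta), with NB in the
#' mean/dispersion parameterization: Var = mu + mu^2 / theta.
#'
#' @param x nonnegative integer counts.
#' @param pi dropout probability in (0, 1).
#' @param mu NB mean (> 0).
#' @param theta NB dispersion (> 0).
#' @param log return log-probability.
#' @return probability mass (or its log), same shape as \code{x}.
#' @export
dzinb <- function(x, pi, mu, theta, log = FALSE) {
  nb_log <- stats::dnbinom(x, mu = mu, size = theta, log = TRUE)
  lp <- ifelse(x == 0,
               pmax2_logsum(log(pi), log1p(-pi) + nb_log),
               log1p(-pi) + nb_log)
  if (log) lp else exp(lp)
}

# elementwise logsumexp of two terms
pmax2_logsum <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

zinb_clip_pi <- c(1e-6, 1 - 1e-6)
zinb_clip_val <- c(1e-5, 1e6)

#' Mean ZINB negative log-likelihood
#'
#' Computed entirely in log space; the zero branch uses
#' logsumexp(log pi, log(1 - pi) + theta * (log theta - log(theta + mu))) so
#' the mixture never underflows.
#'
#' @param x_raw count matrix (or vector/scalar).
#' @param pi,mu,theta ZINB parameters, same shape as \code{x_raw} (scalars
#'   recycle). Values are clipped to (1e-6, 1-1e-6) for \code{pi} and
#'   [1e-5, 1e6] for \code{mu}, \code{theta} before evaluation.
#' @return the mean over all entries of -log P_ZINB(x | pi, mu, theta).
#' @export
zinb_nll <- function(x_raw, pi, mu, theta) {
  if (anyNA(pi) || anyNA(mu) || anyNA(theta))
    stop("NaN/NA in ZINB parameters")
  pi <- pmin(pmax(pi, zinb_clip_pi[1]), zinb_clip_pi[2])
  mu <- pmin(pmax(mu, zinb_clip_val[1]), zinb_clip_val[2])
  theta <- pmin(pmax(theta, zinb_clip_val[1]), zinb_clip_val[2])
  x <- as.vector(x_raw)
  pi <- rep_len(as.vector(pi), length(x))
  mu <- rep_len(as.vector(mu), length(x))
  theta <- rep_len(as.vector(theta), length(x))

  lt <- theta * (log(theta) - log(theta + mu))  # log NB(0)
  zero <- x == 0
  nll <- numeric(length(x))
  if (any(zero)) {
    nll[zero] <- -pmax2_logsum(log(pi[zero]),
                               log1p(-pi[zero]) + lt[zero])
  }
  if (any(!zero)) {
    i <- !zero
    lnb <- lgamma(x[i] + theta[i]) - lgamma(theta[i]) - lgamma(x[i] + 1) +
      lt[i] + x[i] * (log(mu[i]) - log(theta[i] + mu[i]))
    nll[i] <- -(log1p(-pi[i]) + lnb)
  }
  mean(nll)
}

#' Gradient of the mean ZINB negative log-likelihood
#'
#' Analytic per-entry derivatives of \code{\link{zinb_nll}} with respect to
#' pi, mu, and theta (already divided by the number of entries, so they are
#' gradients of the mean).
#'
#' @inheritParams zinb_nll
#' @return list with matrices/vectors \code{dpi}, \code{dmu}, \code{dtheta}
#'   shaped like \code{x_raw}.
#' @export
zinb_nll_grad <- function(x_raw, pi, mu, theta) {
  dm <- dim(x_raw)
  x <- as.vector(x_raw)
  n <- length(x)
  pi <- pmin(pmax(rep_len(as.vector(pi), n), zinb_clip_pi[1]), zinb_clip_pi[2])
  mu <- pmin(pmax(rep_len(as.vector(mu), n), zinb_clip_val[1]), zinb_clip_val[2])
  theta <- pmin(pmax(rep_len(as.vector(theta), n), zinb_clip_val[1]),
                zinb_clip_val[2])

  dpi <- dmu <- dth <- numeric(n)
  zero <- x == 0
  if (any(zero)) {
    i <- zero
    lt <- theta[i] * (log(theta[i]) - log(theta[i] + mu[i]))
    tnb <- exp(lt)                        # NB(0)
    p0 <- pi[i] + (1 - pi[i]) * tnb
    dpi[i] <- -(1 - tnb) / p0
    dmu[i] <- (1 - pi[i]) * tnb * theta[i] / ((theta[i] + mu[i]) * p0)
    dlt_dth <- log(theta[i] / (theta[i] + mu[i])) + 1 -
      theta[i] / (theta[i] + mu[i])
    dth[i] <- -(1 - pi[i]) * tnb * dlt_dth / p0
  }
  if (any(!zero)) {
    i <- !zero
    dpi[i] <- 1 / (1 - pi[i])
    dmu[i] <- (x[i] + theta[i]) / (theta[i] + mu[i]) - x[i] / mu[i]
    dlnb_dth <- digamma(x[i] + theta[i]) - digamma(theta[i]) +
      log(theta[i] / (theta[i] + mu[i])) + 1 -
      theta[i] / (theta[i] + mu[i]) - x[i] / (theta[i] + mu[i])
    dth[i] <- -dlnb_dth
  }
  shape <- function(v) { if (!is.null(dm)) dim(v) <- dm; v }
  list(dpi = shape(dpi / n), dmu = shape(dmu / n), dtheta = shape(dth / n))
}

# Fused mean-NLL + gradients in a single pass over the matrix. Assumes the
# parameters are already clipped to their valid ranges (as zae_decode
# guarantees); hot path of training, kept branch-free.
zinb_fused <- function(x, pi_, mu, theta) {
  n <- length(x)
  tp <- theta + mu
  ltp <- log(tp)
  lth <- log(theta)
  lt <- theta * (lth - ltp)            # log NB(0)
  z <- x == 0
  nz <- !z

  # zero branch (evaluated everywhere, blended by mask)
  tnb <- exp(lt)
  p0 <- pi_ + (1 - pi_) * tnb
  nll_zero <- -log(p0)
  dlt_dth <- lth - ltp + 1 - theta / tp
  # positive branch
  lnb <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) + lt +
    x * (log(mu) - ltp)
  nll_pos <- -(log1p(-pi_) + lnb)

  loss <- (sum(nll_zero[z]) + sum(nll_pos[nz])) / n

  dpi <- dmu <- dth <- x * 0
  dpi[z] <- (-(1 - tnb) / p0)[z]
  dmu[z] <- ((1 - pi_) * tnb * theta / (tp * p0))[z]
  dth[z] <- (-(1 - pi_) * tnb * dlt_dth / p0)[z]
  dpi[nz] <- (1 / (1 - pi_))[nz]
  dmu[nz] <- ((x + theta) / tp - x / mu)[nz]
  dth[nz] <- -(digamma(x + theta) - digamma(theta) + dlt_dth - x / tp)[nz]
  list(loss = loss, dpi = dpi / n, dmu = dmu / n, dtheta = dth / n)
}
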