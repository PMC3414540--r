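# Habitat-driven abundance process: Poisson group counts per cell with
# lognormal overdispersion on the intensity, and the associated Gibbs/MH
# updates for the cell log-intensities, habitat coefficients and precision.

#' Update cell log-intensities
#'
#' For sampled cells, one Metropolis-Hastings step per cell targeting
#' \eqn{Poisson(G_j \mid A_j e^{v_j}) \times N(v_j \mid x_j'\beta,
#' 1/\tau_v)} with a uniform random-walk proposal; unsampled cells carry no
#' count information and are drawn directly from the normal prior.
#' Vectorized over cells.
#'
#' @param v current log-intensities.
#' @param G current group counts (ignored for unsampled cells).
#' @param eta habitat linear predictor \eqn{X^{hab}\beta}.
#' @param tau_v process precision.
#' @param area cell areas (scaled).
#' @param sampled logical vector.
#' @param width half-width(s) of the uniform proposal, recycled.
#' @return list with \code{v} and MH \code{accept} rate over sampled cells.
#' @export
update_v <- function(v, G, eta, tau_v, area, sampled, width = 0.5) {
  n <- length(v)
  sampled <- rep_len(sampled, n)
  width <- rep_len(width, n)
  acc <- NA_real_
  if (any(sampled)) {
    i <- which(sampled)
    cand <- v[i] + stats::runif(length(i), -width[i], width[i])
    lr <- G[i] * (cand - v[i]) - area[i] * (exp(cand) - exp(v[i])) -
      tau_v / 2 * ((cand - eta[i])^2 - (v[i] - eta[i])^2)
    take <- log(stats::runif(length(i))) < lr
    v[i][take] <- cand[take]
    acc <- mean(take)
  }
  if (any(!sampled)) {
    j <- which(!sampled)
    v[j] <- stats::rnorm(length(j), eta[j], 1 / sqrt(tau_v))
  }
  list(v = v, accept = acc)
}

# Full conditional for beta_hab: conjugate normal for v = X beta + noise
# with precision tau_v, combined with the N(prior_mean, prior_sd^2) prior.
beta_hab_fullcond <- function(v, X, tau_v, prior_sd = 10, prior_mean = 0) {
  p <- ncol(X)
  prec <- tau_v * crossprod(X) + diag(1 / prior_sd^2, p)
  b <- tau_v * crossprod(X, v) + prior_mean / prior_sd^2
  R <- tryCatch(chol(prec), error = function(e)
    stop("singular habitat design"))
  m <- backsolve(R, backsolve(R, b, transpose = TRUE))
  list(mean = drop(m), chol_prec = R)
}

#' Gibbs update of habitat coefficients
#'
#' Conjugate multivariate-normal draw for the linear model of the cell
#' log-intensities on the habitat design (noise precision \eqn{\tau_v}),
#' with independent normal priors. Only cells entering the process model
#' (typically the sampled ones) should be supplied.
#'
#' @param v log-intensities of the cells entering the model.
#' @param X habitat design matrix for those cells.
#' @param tau_v process precision.
#' @param prior_sd,prior_mean normal prior on each coefficient.
#' @return sampled coefficient vector.
#' @export
gibbs_update_beta_hab <- function(v, X, tau_v, prior_sd = 10,
                                  prior_mean = 0) {
  fc <- beta_hab_fullcond(v, X, tau_v, prior_sd, prior_mean)
  z <- stats::rnorm(length(fc$mean))
  drop(fc$mean + backsolve(fc$chol_prec, z))
}

#' Gibbs update of the process precision
#'
#' Conjugate gamma draw: \eqn{\tau_v \sim Gamma(a + n/2, b + SSR/2)} where
#' SSR is the sum of squared residuals \eqn{v - X\beta} over the \eqn{n}
#' cells entering the process model.
#'
#' @param v log-intensities.
#' @param X habitat design matrix.
#' @param beta current habitat coefficients.
#' @param a,b gamma prior shape and rate.
#' @return sampled precision.
#' @export
gibbs_update_tau_v <- function(v, X, beta, a = 1, b = 0.01) {
  n <- length(v)
  ssr <- if (n) sum((v - drop(X %*% beta))^2) else 0
  stats::rgamma(1, shape = a + n / 2, rate = b + ssr / 2)
}

#' Expected group count per cell
#'
#' Poisson intensity with area offset: \eqn{A_j \exp(v_j)}.
#'
#' @param area cell areas (scaled to their mean).
#' @param v cell log-intensities.
#' @return expected number of groups per cell.
#' @export
intensity <- function(area, v) {
  stopifnot(length(area) == length(v), all(area > 0))
  area * exp(v)
}
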