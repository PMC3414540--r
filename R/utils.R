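# Shared numerical routines: bivariate-normal CDF, truncated-normal and
# zero-truncated Poisson samplers, Dirichlet draws, chain bookkeeping.

# Gauss-Legendre nodes/weights (half rules) used by the Genz BVN algorithm.
.gl6x <- c(0.9324695142031522, 0.6612093864662647, 0.2386191860831970)
.gl6w <- c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904)
.gl12x <- c(0.9815606342467191, 0.9041172563704750, 0.7699026741943050,
            0.5873179542866171, 0.3678314989981802, 0.1252334085114692)
.gl12w <- c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
            0.2031674267230659, 0.2334925365383547, 0.2491470458134029)
.gl20x <- c(0.9931285991850949, 0.9639719272779138, 0.9122344282513259,
            0.8391169718222188, 0.7463319064601508, 0.6360536807265150,
            0.5108670019508271, 0.3737060887154196, 0.2277858511416451,
            0.07652652113349733)
.gl20w <- c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
            0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
            0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
            0.1527533871307259)

# Upper-orthant probability P(X > h, Y > k), standard bivariate normal with
# correlation r.  Genz (2004) adaptation of Drezner & Wesolowsky; vectorized.
# Absolute accuracy ~1e-15 (well inside the 1e-10 contract).
.bvnu <- function(h, k, r) {
  n <- length(h)
  out <- numeric(n)
  ar <- abs(r)

  # moderate correlation: quadrature in asin(r)
  mod <- which(ar < 0.925)
  if (length(mod)) {
    for (band in 1:3) {
      if (band == 1L) { sel <- mod[ar[mod] < 0.3]; gx <- .gl6x; gw <- .gl6w }
      else if (band == 2L) { sel <- mod[ar[mod] >= 0.3 & ar[mod] < 0.75]; gx <- .gl12x; gw <- .gl12w }
      else { sel <- mod[ar[mod] >= 0.75]; gx <- .gl20x; gw <- .gl20w }
      if (!length(sel)) next
      hh <- h[sel]; kk <- k[sel]; rr <- r[sel]
      hs <- (hh * hh + kk * kk) / 2
      hk <- hh * kk
      asr <- asin(rr)
      bvn <- numeric(length(sel))
      for (i in seq_along(gx)) for (is in c(-1, 1)) {
        sn <- sin(asr * (is * gx[i] + 1) / 2)
        bvn <- bvn + gw[i] * exp((sn * hk - hs) / (1 - sn * sn))
      }
      out[sel] <- bvn * asr / (4 * pi) +
        stats::pnorm(-hh) * stats::pnorm(-kk)
    }
  }

  # |r| near 1: tail expansion plus quadrature on the complement
  ext <- which(ar >= 0.925)
  if (length(ext)) {
    hh <- h[ext]; kk <- k[ext]; rr <- r[ext]
    neg <- rr < 0
    kk[neg] <- -kk[neg]
    hk <- hh * kk
    bvn <- numeric(length(ext))
    sub1 <- ar[ext] < 1
    if (any(sub1)) {
      h1 <- hh[sub1]; k1 <- kk[sub1]; hk1 <- hk[sub1]; r1 <- rr[sub1]
      as <- (1 - r1) * (1 + r1)
      a <- sqrt(as)
      bs <- (h1 - k1)^2
      cc <- (4 - hk1) / 8
      dd <- (12 - hk1) / 16
      asr <- -(bs / as + hk1) / 2
      b1 <- numeric(length(h1))
      ok <- asr > -100
      b1[ok] <- (a * exp(asr) * (1 - cc * (bs - as) * (1 - dd * bs / 5) / 3 +
                                   cc * dd * as * as / 5))[ok]
      ok2 <- -hk1 < 100
      if (any(ok2)) {
        b <- sqrt(bs)
        sp <- sqrt(2 * pi) * stats::pnorm(-b / a)
        b1[ok2] <- b1[ok2] - (exp(-hk1 / 2) * sp * b *
                                (1 - cc * bs * (1 - dd * bs / 5) / 3))[ok2]
      }
      a2 <- a / 2
      for (i in seq_along(.gl20x)) for (is in c(-1, 1)) {
        xs <- (a2 * (is * .gl20x[i] + 1))^2
        rs <- sqrt(1 - xs)
        asr <- -(bs / xs + hk1) / 2
        ok <- asr > -100
        if (any(ok)) {
          sp <- 1 + cc * xs * (1 + dd * xs)
          ep <- exp(-hk1 * (1 - rs) / (2 * (1 + rs))) / rs
          b1[ok] <- b1[ok] + (a2 * .gl20w[i] * exp(asr) * (ep - sp))[ok]
        }
      }
      bvn[sub1] <- -b1 / (2 * pi)
    }
    pos <- !neg
    bvn[pos] <- bvn[pos] + stats::pnorm(-pmax(hh[pos], kk[pos]))
    if (any(neg)) {
      bvn[neg] <- -bvn[neg] +
        pmax(0, stats::pnorm(kk[neg]) - stats::pnorm(hh[neg]))
    }
    out[ext] <- bvn
  }
  pmin(pmax(out, 0), 1)
}

#' Bivariate standard-normal CDF
#'
#' Computes \eqn{P(X \le h, Y \le k)} for a standard bivariate normal pair
#' with correlation \code{r}, using a deterministic quadrature routine
#' (absolute accuracy far below 1e-10). Vectorized over all three arguments.
#'
#' @param h,k upper integration limits.
#' @param r correlation(s) in \eqn{[-1, 1]}.
#' @return vector of probabilities.
#' @export
pbvnorm <- function(h, k, r) {
  n <- max(length(h), length(k), length(r))
  h <- rep_len(as.numeric(h), n)
  k <- rep_len(as.numeric(k), n)
  r <- rep_len(as.numeric(r), n)
  stopifnot(all(is.finite(r)), all(abs(r) <= 1))
  .bvnu(-h, -k, r)
}

# Truncated-normal sampler, vectorized, tail-robust (inverse-CDF in the
# upper-tail parameterization so one-sided extreme truncations stay exact).
rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- numeric(n)
  lo <- is.infinite(a) & a < 0    # (-Inf, b]: reflect the right-tail case
  hi <- is.infinite(b) & b > 0    # [a, Inf)
  two <- !lo & !hi
  if (any(hi)) {
    pa <- stats::pnorm(a[hi], lower.tail = FALSE)
    z[hi] <- stats::qnorm(stats::runif(sum(hi)) * pa, lower.tail = FALSE)
  }
  if (any(lo)) {
    pb <- stats::pnorm(-b[lo], lower.tail = FALSE)
    z[lo] <- -stats::qnorm(stats::runif(sum(lo)) * pb, lower.tail = FALSE)
  }
  if (any(two)) {
    pa <- stats::pnorm(a[two]); pb <- stats::pnorm(b[two])
    z[two] <- stats::qnorm(pa + stats::runif(sum(two)) * (pb - pa))
  }
  # guard against roundoff pushing a draw across the truncation boundary
  pmin(pmax(mean + sd * z, lower), upper)
}

# Zero-truncated Poisson pmf and exact inverse-CDF sampler.
dztpois <- function(x, lambda, log = FALSE) {
  lambda <- rep_len(lambda, length(x))
  lp <- rep(-Inf, length(x))
  ok <- x >= 1 & x == floor(x)
  lp[ok] <- stats::dpois(x[ok], lambda[ok], log = TRUE) -
    stats::ppois(0, lambda[ok], lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  f0 <- stats::dpois(0, lambda)
  u <- f0 + stats::runif(n) * (1 - f0)
  pmax(1L, stats::qpois(u, lambda))
}

rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Retained-draw bookkeeping
#'
#' Number of posterior samples kept by a run: iterations after burn-in,
#' thinned, summed over chains.
#'
#' @param n_iter iterations per chain.
#' @param burn_in initial iterations discarded per chain.
#' @param thin keep one of every \code{thin} iterations.
#' @param n_chains number of chains.
#' @return integer count of retained draws.
#' @export
n_retained <- function(n_iter, burn_in, thin = 1L, n_chains = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1)
  as.integer(n_chains) * as.integer(ceiling((n_iter - burn_in) / thin))
}

# indices (within one chain) of retained iterations; first kept iteration is
# burn_in + 1 so the count matches n_retained() for every (n_iter, burn, thin)
.retained_iters <- function(n_iter, burn_in, thin) {
  seq.int(burn_in + 1, n_iter, by = thin)
}
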