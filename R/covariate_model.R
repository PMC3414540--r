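# Parametric population models for individual covariates (distance, group
# size, categorical marks): density evaluation, exact sampling, and posterior
# updates for their hyperparameters.

#' Declare a population model for an individual covariate
#'
#' Groups of animals carry individual covariates (perpendicular distance,
#' group size, species, exposure, ...). For groups never detected these are
#' latent, so each modeled covariate needs a population-level distribution.
#' Supported families: \code{uniform} (distance; parameters always fixed),
#' \code{categorical}, \code{poisson}, zero-truncated Poisson
#' (\code{poisson_zt}), and overdispersed variants (\code{poisson_od},
#' \code{poisson_zt_od}) in which the count has rate \eqn{\exp(\theta +
#' \epsilon)} with a per-group random effect \eqn{\epsilon \sim N(0,
#' \sigma^2)}.
#'
#' @param family one of \code{"uniform"}, \code{"categorical"},
#'   \code{"poisson"}, \code{"poisson_zt"}, \code{"poisson_od"},
#'   \code{"poisson_zt_od"}.
#' @param min,max support of the uniform family.
#' @param levels character vector of category labels (categorical family).
#' @param probs initial category probabilities; default uniform.
#' @param alpha Dirichlet prior concentrations, recycled over levels.
#'   Default 10 per level, the conjugate prior used for species and exposure
#'   marks in the motivating analyses.
#' @param theta initial log rate (Poisson families).
#' @param sigma initial overdispersion SD (overdispersed families).
#' @param fixed if \code{TRUE}, parameters are held at their initial values
#'   rather than estimated.
#' @param theta_mean,theta_sd normal hyperprior on the log rate.
#' @param sigma_max upper bound of the uniform hyperprior on \code{sigma}.
#' @return an object of class \code{rjds_covmodel}.
#' @export
covariate_model <- function(family = c("uniform", "categorical", "poisson",
                                       "poisson_zt", "poisson_od",
                                       "poisson_zt_od"),
                            min = 0, max = 1,
                            levels = NULL, probs = NULL, alpha = 10,
                            theta = 0, sigma = 0.5, fixed = FALSE,
                            theta_mean = 0, theta_sd = 1, sigma_max = 2) {
  family <- match.arg(family)
  m <- list(family = family, fixed = fixed)
  if (family == "uniform") {
    stopifnot(max > min)
    m$min <- min; m$max <- max
    m$fixed <- TRUE  # distance-type priors are never estimated
  } else if (family == "categorical") {
    if (is.null(levels)) stop("categorical covariate model needs 'levels'")
    k <- length(levels)
    if (is.null(probs)) probs <- rep(1 / k, k)
    stopifnot(length(probs) == k, all(probs > 0), abs(sum(probs) - 1) < 1e-8)
    alpha <- rep_len(alpha, k)
    stopifnot(all(alpha > 0))
    m$levels <- as.character(levels); m$probs <- probs; m$alpha <- alpha
  } else {
    stopifnot(is.finite(theta), sigma >= 0, theta_sd > 0, sigma_max > 0)
    m$theta <- theta
    m$theta_mean <- theta_mean; m$theta_sd <- theta_sd
    if (grepl("_od", family)) {
      m$sigma <- sigma; m$sigma_max <- sigma_max
    }
  }
  class(m) <- "rjds_covmodel"
  m
}

.is_od <- function(model) model$family %in% c("poisson_od", "poisson_zt_od")
.is_zt <- function(model) model$family %in% c("poisson_zt", "poisson_zt_od")

#' Density / mass of an individual-covariate model
#'
#' Evaluates the population pmf/pdf \eqn{g(z \mid \theta)}. Overdispersed
#' Poisson families condition on the supplied log-scale random effect(s)
#' \code{eps}: the rate is \eqn{\exp(\theta + \epsilon)}. Values outside the
#' support return 0 (or \code{-Inf} on the log scale).
#'
#' @param z covariate value(s); integer codes for categorical models.
#' @param model an \code{\link{covariate_model}} object.
#' @param eps random effect(s), recycled; ignored by non-overdispersed
#'   families.
#' @param log return log density?
#' @return numeric vector of (log) densities.
#' @export
covariate_density <- function(z, model, eps = 0, log = FALSE) {
  out <- switch(model$family,
    uniform = stats::dunif(z, model$min, model$max, log = TRUE),
    categorical = {
      zi <- .cat_code(z, model)
      lp <- rep(-Inf, length(z))
      ok <- !is.na(zi)
      lp[ok] <- log(model$probs[zi[ok]])
      lp
    },
    {
      rate <- exp(model$theta + if (.is_od(model)) rep_len(eps, length(z)) else 0)
      rate <- rep_len(rate, length(z))
      if (.is_zt(model)) dztpois(z, rate, log = TRUE)
      else {
        lp <- rep(-Inf, length(z))
        ok <- z >= 0 & z == floor(z)
        lp[ok] <- stats::dpois(z[ok], rate[ok], log = TRUE)
        lp
      }
    })
  if (log) out else exp(out)
}

# map covariate values (labels or codes) to integer level codes
.cat_code <- function(z, model) {
  if (is.character(z) || is.factor(z)) match(as.character(z), model$levels)
  else { zi <- as.integer(z); zi[zi < 1 | zi > length(model$levels)] <- NA; zi }
}

#' Sample from an individual-covariate model
#'
#' Exact draws from \eqn{g(\cdot \mid \theta)}. Overdispersed families first
#' draw \eqn{\epsilon \sim N(0, \sigma^2)} then the count; zero-truncated
#' draws use the exact inverse-CDF of the truncated law.
#'
#' @param n number of draws.
#' @param model an \code{\link{covariate_model}} object.
#' @return a list with \code{value} (numeric/integer vector; categorical
#'   values are integer codes) and \code{eps} (random effects, 0 for
#'   non-overdispersed families).
#' @export
covariate_sample <- function(n, model) {
  eps <- if (.is_od(model)) stats::rnorm(n, 0, model$sigma) else numeric(n)
  value <- switch(model$family,
    uniform = stats::runif(n, model$min, model$max),
    categorical = sample.int(length(model$levels), n, replace = TRUE,
                             prob = model$probs),
    {
      rate <- exp(model$theta + eps)
      if (.is_zt(model)) rztpois(n, rate) else stats::rpois(n, rate)
    })
  list(value = value, eps = eps)
}

#' Posterior update of covariate-model parameters
#'
#' One MCMC update of \eqn{\theta} given the covariate values of all groups
#' currently in the population (observed and latent). Categorical models use
#' the conjugate Dirichlet Gibbs draw \eqn{Dirichlet(\alpha + counts)};
#' Poisson-family log rates (and the overdispersion SD) use
#' Metropolis-Hastings with uniform random-walk proposals.
#'
#' @param model an \code{\link{covariate_model}} object.
#' @param values covariate values of groups in the population.
#' @param eps matching random effects (overdispersed families).
#' @param width half-width of the uniform random-walk proposal.
#' @return list with the updated \code{model} and an \code{accept} vector
#'   (per tuned parameter; conjugate updates report 1).
#' @export
update_covariate_theta <- function(model, values, eps = NULL, width = 0.2) {
  if (model$fixed || model$family == "uniform") {
    return(list(model = model, accept = numeric(0)))
  }
  if (model$family == "categorical") {
    zi <- .cat_code(values, model)
    counts <- tabulate(zi, nbins = length(model$levels))
    model$probs <- rdirichlet(model$alpha + counts)
    return(list(model = model, accept = 1))
  }
  if (is.null(eps)) eps <- numeric(length(values))
  acc <- c(theta = 0)
  loglik <- function(th) sum(covariate_density(values, `$<-`(model, "theta", th),
                                               eps = eps, log = TRUE))
  cand <- model$theta + stats::runif(1, -width, width)
  lr <- loglik(cand) - loglik(model$theta) +
    stats::dnorm(cand, model$theta_mean, model$theta_sd, log = TRUE) -
    stats::dnorm(model$theta, model$theta_mean, model$theta_sd, log = TRUE)
  if (is.finite(lr) && log(stats::runif(1)) < lr) {
    model$theta <- cand; acc["theta"] <- 1
  }
  if (.is_od(model)) {
    acc <- c(acc, sigma = 0)
    cand <- model$sigma + stats::runif(1, -width, width)
    if (cand > 0 && cand < model$sigma_max) {
      lr <- sum(stats::dnorm(eps, 0, cand, log = TRUE)) -
        sum(stats::dnorm(eps, 0, model$sigma, log = TRUE))
      if (is.finite(lr) && log(stats::runif(1)) < lr) {
        model$sigma <- cand; acc["sigma"] <- 1
      }
    }
  }
  list(model = model, accept = acc)
}

# Vectorized MH update of per-group overdispersion random effects given the
# current counts; target Pois-family(z | exp(theta+eps)) * N(eps | 0, sigma^2).
update_covariate_eps <- function(model, values, eps, width = 0.5) {
  if (!.is_od(model)) return(list(eps = eps, accept = NA_real_))
  n <- length(values)
  cand <- eps + stats::runif(n, -width, width)
  lr <- covariate_density(values, model, eps = cand, log = TRUE) -
    covariate_density(values, model, eps = eps, log = TRUE) +
    stats::dnorm(cand, 0, model$sigma, log = TRUE) -
    stats::dnorm(eps, 0, model$sigma, log = TRUE)
  take <- log(stats::runif(n)) < lr
  eps[take] <- cand[take]
  list(eps = eps, accept = mean(take))
}

# expected value of the group-size model (used for reporting/tests)
covariate_mean <- function(model, n_mc = 10000) {
  switch(model$family,
    uniform = (model$min + model$max) / 2,
    categorical = sum(seq_along(model$probs) * model$probs),
    poisson = exp(model$theta),
    poisson_zt = { l <- exp(model$theta); l / (1 - exp(-l)) },
    mean(covariate_sample(n_mc, model)$value))
}
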